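#' Fit a constrained CJS model by maximum likelihood
#'
#' Maximizes the m-array multinomial likelihood by quasi-Newton (BFGS)
#' iteration with analytic gradients and seeded multi-start: the first start
#' is the null point (all probabilities 0.5), the remainder are random
#' normal draws on the logit scale. The best converged optimum is polished
#' until the gradient norm falls below `tol` (or flagged unconverged).
#'
#' @param marray a [build_marray] result.
#' @param spec a [cjs_model_spec], or a grammar string pair via
#'   `survival`/`resight`.
#' @param covariates named list of [covariate_series] bound to the formulas.
#' @param n_starts number of optimizer starts (>= 1).
#' @param tol convergence tolerance on the max absolute gradient.
#' @param seed seed for the random starts.
#' @param p_fixed optionally fix all resighting probabilities (e.g. `1`).
#' @param n_eff effective sample size for AICc; defaults to the total
#'   number of observations in the data (initial captures + resights),
#'   the convention that reproduces E-SURGE style AICc values.
#' @param hessian compute the Hessian (needed for CIs and the estimable
#'   parameter count)? Disable for speed in large simulation studies.
#' @param design optionally a prebuilt [build_design] (skips compilation).
#' @return a `cjs_fit` object: `beta`, `vcov`, `deviance`, `np` (estimable
#'   parameters), `np_nominal`, `aicc`, `n_eff`, `real` (back-transformed
#'   estimates with 95% Wald CIs per parameter cell), `converged`,
#'   `grad_norm`, `design`.
#' @export
fit_cjs <- function(marray, spec, covariates = list(), n_starts = 5L,
                    tol = 1e-8, seed = 1L, p_fixed = NULL, n_eff = NULL,
                    hessian = TRUE, design = NULL) {
  stopifnot(inherits(marray, "marray"))
  if (is.character(spec))
    stop("spec must be a cjs_model_spec (use cjs_model_spec(survival, resight))")
  if (is.null(design)) {
    cohorts <- lapply(split(marray$meta$cohort, marray$meta$group), unique)
    design <- build_design(spec, marray$occasions, groups = marray$groups,
                           covariates = covariates, cohorts = cohorts)
  }
  ctx <- cjs_context(marray, design)
  npar <- if (is.null(p_fixed)) design$npar else ncol(design$phi$X)
  if (npar == 0L) stop("model has no free parameters")
  fn <- function(b) as.numeric(cjs_eval(b, ctx, design, p_fixed))
  gr <- function(b) attr(cjs_eval(b, ctx, design, p_fixed,
                                  want_grad = TRUE), "gradient")
  starts <- local_seed(seed, {
    c(list(numeric(npar)),
      if (n_starts > 1L)
        lapply(seq_len(n_starts - 1L), function(i)
          stats::rnorm(npar, 0, 1)))
  })
  best <- NULL
  for (b0 in starts) {
    opt <- try(stats::optim(b0, fn, gr, method = "BFGS",
                            control = list(maxit = 500,
                                           reltol = 1e-12)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("all optimizer starts failed")
  # polish: restart BFGS from the optimum until the gradient is flat
  converged <- FALSE
  for (round in 1:4) {
    gnorm <- max(abs(gr(best$par)))
    if (gnorm < max(tol, 1e-8 * (1 + abs(best$value)))) {
      converged <- TRUE; break
    }
    opt <- try(stats::optim(best$par, fn, gr, method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-14)),
               silent = TRUE)
    if (inherits(opt, "try-error") || opt$value > best$value - 1e-12) {
      converged <- gnorm < 1e-3 * (1 + abs(best$value))
      break
    }
    best <- opt
  }
  dev <- best$value
  beta <- best$par
  H <- NULL; vcov <- NULL; np <- ncol(design$phi$X) +
    if (is.null(p_fixed)) ncol(design$p$X) else 0L
  if (hessian) {
    H <- grad_jacobian(gr, beta)
    H <- (H + t(H)) / 2
    np <- hessian_rank(H)
    vcov <- 2 * pseudo_inverse(H)    # cov of beta for nll = dev/2
  }
  if (is.null(n_eff)) n_eff <- marray$n_observations
  aicc <- compute_aicc(dev, np, n_eff)
  real <- real_estimates(design, beta, vcov, p_fixed)
  structure(list(beta = beta, vcov = vcov, deviance = dev,
                 np = np, np_nominal = npar, aicc = aicc, n_eff = n_eff,
                 real = real, converged = converged,
                 grad_norm = max(abs(gr(beta))),
                 p_fixed = p_fixed, design = design,
                 spec = design$spec),
            class = "cjs_fit")
}

# central-difference Jacobian of the gradient = Hessian of the deviance
grad_jacobian <- function(gr, x, h = 1e-5) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (i in seq_len(n)) {
    e <- numeric(n); e[i] <- h * max(1, abs(x[i]))
    J[, i] <- (gr(x + e) - gr(x - e)) / (2 * e[i])
  }
  J
}

pseudo_inverse <- function(H, rtol = 1e-6) {
  sv <- svd(H)
  keep <- sv$d > rtol * max(sv$d)
  d <- ifelse(keep, 1 / sv$d, 0)
  sv$v %*% (d * t(sv$u))
}

#' Count estimable parameters from the Hessian spectrum
#'
#' The numerical rank of the deviance Hessian at the optimum: singular
#' values below `rtol` times the largest are treated as zero. This captures
#' intrinsic confounding (e.g. the terminal \eqn{\phi_{T-1} \times p_T}
#' product of the fully time-dependent CJS model).
#'
#' @param fit a `cjs_fit`, or a Hessian matrix.
#' @param rtol relative singular-value tolerance.
#' @return integer rank.
#' @export
count_estimable <- function(fit, rtol = 1e-6) {
  H <- if (inherits(fit, "cjs_fit")) {
    if (is.null(fit$vcov))
      stop("fit was computed without a Hessian; refit with hessian = TRUE")
    return(fit$np)
  } else fit
  hessian_rank(H, rtol)
}

hessian_rank <- function(H, rtol = 1e-6) {
  sv <- svd(H)$d
  if (!length(sv) || max(sv) == 0) return(0L)
  sum(sv > rtol * max(sv))
}

# back-transformed per-cell estimates with 95% Wald CIs on the logit scale
real_estimates <- function(design, beta, vcov, p_fixed = NULL) {
  n_phi <- ncol(design$phi$X)
  blocks <- list(phi = list(side = design$phi, off = 0L, n = n_phi))
  if (is.null(p_fixed))
    blocks$p <- list(side = design$p, off = n_phi, n = ncol(design$p$X))
  out <- list()
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    eta <- drop(b$side$X %*% beta[b$off + seq_len(b$n)])
    est <- stats::plogis(eta)
    if (!is.null(vcov)) {
      V <- vcov[b$off + seq_len(b$n), b$off + seq_len(b$n), drop = FALSE]
      se <- sqrt(pmax(rowSums((b$side$X %*% V) * b$side$X), 0))
      lcl <- stats::plogis(eta - 1.96 * se)
      ucl <- stats::plogis(eta + 1.96 * se)
    } else lcl <- ucl <- rep(NA_real_, length(est))
    cells <- b$side$cells
    out[[nm]] <- data.frame(parameter = nm, group = cells$group,
                            age_class = b$side$classes$label[cells$class],
                            occasion = cells$k, year = cells$year,
                            estimate = est, lcl = lcl, ucl = ucl,
                            stringsAsFactors = FALSE)
  }
  if (!is.null(p_fixed))
    out$p <- data.frame(parameter = "p", group = NA_character_,
                        age_class = "all", occasion = NA_integer_,
                        year = NA_integer_, estimate = p_fixed,
                        lcl = p_fixed, ucl = p_fixed,
                        stringsAsFactors = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.cjs_fit <- function(x, ...) {
  cat("CJS fit:", x$spec$survival, "|",
      if (is.null(x$p_fixed)) x$spec$resight
      else sprintf("p fixed at %g", x$p_fixed), "\n")
  cat(sprintf("  deviance %.2f, np %d (nominal %d), AICc %.2f (n_eff %d)\n",
              x$deviance, x$np, x$np_nominal, x$aicc, x$n_eff))
  if (!x$converged) cat("  WARNING: optimizer did not converge",
                        sprintf("(gradient norm %.2g)\n", x$grad_norm))
  invisible(x)
}

#' Small-sample corrected AIC
#'
#' \deqn{AICc = Dev + 2 np + \frac{2 np (np+1)}{n_{eff} - np - 1}}
#'
#' @param dev model deviance (relative -2 log likelihood).
#' @param np number of estimable parameters.
#' @param n_eff effective sample size (here: total number of observations).
#' @return AICc value.
#' @export
compute_aicc <- function(dev, np, n_eff) {
  stopifnot(is.finite(dev), np >= 0, n_eff > 0)
  if (n_eff <= np + 1)
    stop("AICc undefined: n_eff must exceed np + 1")
  dev + 2 * np + 2 * np * (np + 1) / (n_eff - np - 1)
}

#' Rank fitted models by AICc
#'
#' @param fits list of `cjs_fit` objects (optionally named), or a
#'   data.frame with columns `model`, `np`, `deviance`, `aicc`.
#' @param names model labels; defaults to list names.
#' @return data.frame sorted by AICc (ties broken by fewer parameters)
#'   with a `delta_aicc` column.
#' @export
model_selection_table <- function(fits, names = NULL) {
  if (is.data.frame(fits)) {
    tab <- fits
  } else {
    neff <- unique(vapply(fits, `[[`, 0, "n_eff"))
    if (length(neff) != 1L)
      stop("all fits must share the same n_eff (same dataset)")
    if (is.null(names))
      names <- if (!is.null(base::names(fits))) base::names(fits)
               else vapply(fits, function(f)
                 paste(f$spec$survival, f$spec$resight, sep = " | "), "")
    tab <- data.frame(model = names,
                      np = vapply(fits, `[[`, 0L, "np"),
                      deviance = vapply(fits, `[[`, 0, "deviance"),
                      aicc = vapply(fits, `[[`, 0, "aicc"),
                      stringsAsFactors = FALSE)
  }
  tab <- tab[order(tab$aicc, tab$np), , drop = FALSE]
  tab$delta_aicc <- tab$aicc - min(tab$aicc)
  rownames(tab) <- NULL
  tab
}

# evaluate expr with a local, restored RNG state
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}
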