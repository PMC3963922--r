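# ---- CJS m-array multinomial likelihood -----------------------------------
#
# For a release stratum (group g, cohort c, release occasion i), the
# probability of first re-encounter at occasion j > i is
#   pi_ij = prod_{k=i}^{j-1} phi_{age,k} * prod_{k=i+1}^{j-1} (1-p_{age,k})
#           * p_{age,j}
# with ages age = k - c + 1 (survival over interval k) and j - c
# (resighting at j). The never-seen cell is 1 - sum_j pi_ij. The deviance
# is -2 log multinomial likelihood with the multinomial coefficients
# dropped (a model-independent constant).

# Precompute index matrices tying each stratum's cells to design rows.
cjs_context <- function(marray, design) {
  T <- length(marray$occasions)
  if (!identical(as.integer(marray$occasions),
                 as.integer(design$occasions)))
    stop("m-array and design occasion axes differ")
  keep <- marray$meta$occasion < T      # final-occasion releases: no cells
  meta <- marray$meta[keep, , drop = FALSE]
  m <- marray$m[keep, , drop = FALSE]
  S <- nrow(meta)
  gi <- match(meta$group, design$groups)
  if (anyNA(gi)) stop("m-array group absent from design")
  PHI <- matrix(NA_integer_, S, T - 1L)   # interval k = 1..T-1
  P <- matrix(NA_integer_, S, T)          # occasion j = 2..T
  for (s in seq_len(S)) {
    i <- meta$occasion[s]; c0 <- meta$cohort[s]
    ks <- i:(T - 1L)
    PHI[s, ks] <- design$phi$idx[cbind(gi[s], ks - c0 + 1L, ks)]
    js <- (i + 1L):T
    P[s, js] <- design$p$idx[cbind(gi[s], js - c0, js)]
  }
  phi_valid <- outer(meta$occasion, seq_len(T - 1L), `<=`)
  p_valid <- outer(meta$occasion + 1L, seq_len(T), `<=`)
  if (anyNA(PHI[phi_valid]) || anyNA(P[p_valid]))
    stop("design does not cover every m-array cell")
  # cumulative-sum helper matrices (upper triangular of ones)
  list(S = S, T = T, meta = meta, m = m,
       PHI = PHI, P = P,
       phi_valid = phi_valid,
       p_valid = p_valid,
       UT1 = upper.tri(diag(T - 1L), diag = TRUE) * 1,   # cumsum along k
       UTT = upper.tri(diag(T), diag = TRUE) * 1)
}

# deviance and (optionally) its gradient wrt beta = c(beta_phi, beta_p)
cjs_eval <- function(beta, ctx, design, p_fixed = NULL, want_grad = FALSE) {
  n_phi <- ncol(design$phi$X)
  beta_phi <- beta[seq_len(n_phi)]
  eta_phi <- drop(design$phi$X %*% beta_phi)
  phi_vals <- stats::plogis(eta_phi)
  if (is.null(p_fixed)) {
    beta_p <- beta[n_phi + seq_len(ncol(design$p$X))]
    eta_p <- drop(design$p$X %*% beta_p)
    p_vals <- stats::plogis(eta_p)
  } else {
    p_vals <- rep(p_fixed, nrow(design$p$cells))
  }
  if (any(!is.finite(phi_vals)) || any(!is.finite(p_vals)))
    stop("non-finite linear predictor")
  S <- ctx$S; T <- ctx$T
  eps <- 1e-300

  LA <- matrix(0, S, T - 1L)
  LA[ctx$phi_valid] <- log(pmax(phi_vals[ctx$PHI[ctx$phi_valid]], eps))
  LB <- matrix(0, S, T)
  LP <- matrix(0, S, T)
  pv <- ctx$p_valid
  LB[pv] <- log(pmax(1 - p_vals[ctx$P[pv]], eps))
  LP[pv] <- log(pmax(p_vals[ctx$P[pv]], eps))

  cumLA <- LA %*% ctx$UT1                  # cumLA[s,k] = sum_{k'<=k} LA
  cumLB <- LB %*% ctx$UTT
  # lcell[s, j] = cumLA[s, j-1] + cumLB[s, j-1] + LP[s, j],  j = 2..T
  lcell <- matrix(-Inf, S, T)
  lcell[, 2:T] <- cumLA[, 1:(T - 1L), drop = FALSE] +
    cumLB[, 1:(T - 1L), drop = FALSE] + LP[, 2:T, drop = FALSE]
  lcell[!pv] <- -Inf
  pi_cells <- exp(lcell)
  pi0 <- pmax(1 - rowSums(pi_cells), 0)
  ll <- sum(ctx$m[pv] * lcell[pv]) +
    sum(ifelse(ctx$meta$never > 0,
               ctx$meta$never * log(pmax(pi0, eps)), 0))
  dev <- -2 * ll
  if (!want_grad) return(dev)

  # weights w[s,j] = m[s,j] - never_s * pi[s,j]/pi0_s
  ratio <- ifelse(ctx$meta$never > 0,
                  ctx$meta$never / pmax(pi0, eps), 0)
  w <- ctx$m - ratio * pi_cells
  w[!pv] <- 0
  # cw[s,j] = sum_{j' >= j} w[s,j']
  cw <- t(apply(w, 1L, function(x) rev(cumsum(rev(x)))))
  if (S == 1L) cw <- matrix(cw, 1L)
  zero <- numeric(ncol(design$phi$X))
  # d dev / d log phi at cell r: -2 * sum over (s,k) mapped to r of cw[s,k+1]
  contrib_phi <- cw[, 2:T, drop = FALSE]           # aligned with k = 1..T-1
  idx <- ctx$PHI[ctx$phi_valid]
  g_logphi <- zero
  acc <- rowsum(contrib_phi[ctx$phi_valid], idx)
  g_logphi[as.integer(rownames(acc))] <- -2 * acc[, 1L]
  g_eta_phi <- g_logphi * (1 - phi_vals)
  grad_phi <- drop(crossprod(design$phi$X, g_eta_phi))

  if (is.null(p_fixed)) {
    cwT <- cbind(cw[, 2:T, drop = FALSE], 0)       # cw[s, j+1] for j = 1..T
    g_logp <- numeric(length(p_vals))
    g_log1mp <- numeric(length(p_vals))
    idp <- ctx$P[pv]
    accp <- rowsum(w[pv], idp)
    g_logp[as.integer(rownames(accp))] <- -2 * accp[, 1L]
    accq <- rowsum(cwT[pv], idp)
    g_log1mp[as.integer(rownames(accq))] <- -2 * accq[, 1L]
    g_eta_p <- g_logp * (1 - p_vals) - g_log1mp * p_vals
    grad_p <- drop(crossprod(design$p$X, g_eta_p))
    attr(dev, "gradient") <- c(grad_phi, grad_p)
  } else {
    attr(dev, "gradient") <- grad_phi
  }
  dev
}

#' CJS deviance of a parameter vector
#'
#' Evaluates \eqn{-2\log L} of the m-array multinomial likelihood at a
#' logit-scale coefficient vector. Multinomial coefficients are omitted
#' consistently, so deviance *differences* between models on the same data
#' are exact.
#'
#' @param design a [build_design] result.
#' @param beta coefficient vector, length `design$npar` (survival block
#'   first), or length `ncol(design$phi$X)` when `p_fixed` is given.
#' @param marray a [build_marray] result on the same occasion axis.
#' @param p_fixed optionally fix all resighting probabilities to this value
#'   (no p parameters are estimated).
#' @return the deviance (numeric scalar).
#' @export
cjs_deviance <- function(design, beta, marray, p_fixed = NULL) {
  want <- ncol(design$phi$X) + if (is.null(p_fixed)) ncol(design$p$X) else 0L
  if (length(beta) != want)
    stop("beta must have length ", want)
  ctx <- cjs_context(marray, design)
  as.numeric(cjs_eval(beta, ctx, design, p_fixed = p_fixed))
}
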