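#' Compile a model specification into a linear-predictor design
#'
#' Enumerates the feasible parameter cells — survival: (group, age class,
#' year interval); resighting: (group, age class, occasion) — given the
#' marking cohorts present, and builds one logit-scale design matrix per
#' parameter from the grammar. Within a `/`-segment, `.` compiles to a full
#' interaction and `+` to an additive term; segments are independent blocks.
#' Covariates are standardized (zero mean, unit population sd) before they
#' are bound.
#'
#' @param spec a [cjs_model_spec] (or two grammar strings via `survival`
#'   and `resight` in `...`).
#' @param occasions calendar years of the occasions.
#' @param groups colony labels.
#' @param covariates named list of [covariate_series] (or named year->value
#'   numeric vectors) for every covariate the formulas reference.
#' @param cohorts list (per group) of occasion indices at which cohorts were
#'   marked; defaults to all occasions but the last, for every group.
#' @return a `cjs_design` object with per-parameter design blocks (`phi`,
#'   `p`), the nominal parameter count `npar`, and cell lookup tables used
#'   by the likelihood.
#' @export
build_design <- function(spec, occasions, groups = "colony1",
                         covariates = list(), cohorts = NULL) {
  stopifnot(inherits(spec, "cjs_model_spec"))
  T <- length(occasions)
  if (T < 2L) stop("need at least two occasions")
  groups <- as.character(groups)
  if (is.null(cohorts))
    cohorts <- stats::setNames(rep(list(seq_len(T - 1L)), length(groups)),
                               groups)
  if (!all(groups %in% names(cohorts)))
    stop("cohorts must be a named list covering every group")
  covariates <- lapply(covariates, as_covariate_series)
  covariates <- lapply(covariates, function(cv)
    if (cv$standardized) cv else standardize(cv))

  # feasible (group, age, time) cells derived from the cohort structure
  phi_cells <- enumerate_cells(groups, cohorts, T, side = "phi")
  p_cells <- enumerate_cells(groups, cohorts, T, side = "p")

  phi <- build_side(spec$phi, phi_cells, occasions, groups, covariates,
                    side = "phi")
  p <- build_side(spec$p, p_cells, occasions, groups, covariates,
                  side = "p")

  structure(list(phi = phi, p = p, occasions = occasions, groups = groups,
                 cohorts = cohorts, npar = ncol(phi$X) + ncol(p$X),
                 spec = spec),
            class = "cjs_design")
}

# all (group, age, k) combinations reachable from some cohort
enumerate_cells <- function(groups, cohorts, T, side) {
  out <- list()
  for (g in groups) {
    cs <- cohorts[[g]]
    if (side == "phi") {
      # interval k = occasion k -> k+1; age class of the interval is
      # age-at-start + 1 (first interval after fledging = age 1)
      grid <- expand.grid(cohort = cs, k = seq_len(T - 1L))
      grid <- grid[grid$k >= grid$cohort, , drop = FALSE]
      grid$age <- grid$k - grid$cohort + 1L
    } else {
      # resighting at occasion j; age j - cohort (1 = yearling)
      grid <- expand.grid(cohort = cs, k = 2:T)
      grid <- grid[grid$k > grid$cohort, , drop = FALSE]
      grid$age <- grid$k - grid$cohort
    }
    cells <- unique(grid[, c("age", "k")])
    out[[g]] <- data.frame(group = g, age = cells$age, k = cells$k,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$group, res$age, res$k), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# compile one side (phi or p) to a block design matrix over its cells
build_side <- function(pf, cells, occasions, groups, covariates, side) {
  covs <- formula_covariates(pf)
  missing_cov <- setdiff(covs, names(covariates))
  if (length(missing_cov))
    stop("unknown covariate(s) in '", pf$text, "': ",
         paste(missing_cov, collapse = ", "),
         " (bind them via the covariates argument; fill gaps with",
         " fill_covariate_gaps() first)")
  classes <- pf$classes
  cells$class <- classify_age(cells$age, classes)
  cells$segment <- classes$segment[cells$class]
  # collapse to unique design cells: one parameter cell per
  # (group, class, time)
  key <- paste(cells$group, cells$class, cells$k, sep = "\r")
  uc <- cells[!duplicated(key), c("group", "class", "segment", "k"),
              drop = FALSE]
  uc <- uc[order(uc$segment, uc$group, uc$class, uc$k), , drop = FALSE]
  rownames(uc) <- NULL
  uc$year <- occasions[uc$k]

  Xs <- list()
  for (s in seq_along(pf$segments)) {
    seg <- pf$segments[[s]]
    rows <- which(uc$segment == s)
    if (!length(rows)) next
    dat <- data.frame(
      ac = factor(classes$label[uc$class[rows]],
                  levels = classes$label[classes$segment == s]),
      t = factor(uc$k[rows], levels = sort(unique(uc$k[rows]))),
      col = factor(uc$group[rows], levels = groups))
    dat$ac <- droplevels(dat$ac)
    for (cv in covs)
      dat[[cv]] <- covariate_at(covariates[[cv]], uc$year[rows])
    # factor effects that cannot vary here (one time level, one colony)
    # collapse to the intercept
    seg_eff <- Filter(function(e)
      !(e$name == "t" && nlevels(droplevels(dat$t)) < 2L) &&
        !(e$name == "col" && nlevels(droplevels(dat$col)) < 2L),
      seg$effects)
    fstr <- segment_formula(list(effects = seg_eff),
                            n_classes = nlevels(droplevels(dat$ac)))
    X <- stats::model.matrix(stats::as.formula(fstr), dat)
    # drop columns for level combinations absent from the feasible cells,
    # then reduce to a full-column-rank basis (pivoted QR), so the nominal
    # parameter count reflects the structure actually identifiable from
    # the cohort layout
    X <- X[, colSums(abs(X)) > 0, drop = FALSE]
    q <- qr(X)
    if (q$rank < ncol(X))
      X <- X[, sort(q$pivot[seq_len(q$rank)]), drop = FALSE]
    colnames(X) <- paste0(side, s, ":", colnames(X))
    Xs[[s]] <- list(rows = rows, X = X)
  }
  ncols <- vapply(Xs, function(b) if (is.null(b)) 0L else ncol(b$X), 0L)
  X <- matrix(0, nrow(uc), sum(ncols))
  cn <- character(0); at <- 0L
  for (b in Xs) {
    if (is.null(b)) next
    X[b$rows, at + seq_len(ncol(b$X))] <- b$X
    cn <- c(cn, colnames(b$X)); at <- at + ncol(b$X)
  }
  colnames(X) <- cn
  # lookup array: (group, age, k) -> row of uc / X
  A_max <- max(cells$age)
  idx <- array(NA_integer_,
               dim = c(length(groups), A_max, max(cells$k)),
               dimnames = list(groups, NULL, NULL))
  for (r in seq_len(nrow(cells))) {
    gi <- match(cells$group[r], groups)
    row <- match(paste(cells$group[r], cells$class[r], cells$k[r],
                       sep = "\r"),
                 paste(uc$group, uc$class, uc$k, sep = "\r"))
    idx[gi, cells$age[r], cells$k[r]] <- row
  }
  list(cells = uc, X = X, idx = idx, classes = classes, text = pf$text)
}

# grammar segment -> R model formula; interaction '.' crosses the running
# term (main effects included), '+' adds
segment_formula <- function(seg, n_classes) {
  f <- if (n_classes > 1L) "ac" else NULL
  for (e in seg$effects) {
    if (is.null(f)) f <- e$name
    else if (is.na(e$op) || e$op == ".")
      f <- paste0("(", f, ")*", e$name)
    else f <- paste0(f, "+", e$name)
  }
  if (is.null(f)) f <- "1"
  paste("~", f)
}

#' @export
print.cjs_design <- function(x, ...) {
  cat("CJS design:", x$spec$survival, "|", x$spec$resight, "\n")
  cat(sprintf("  survival : %d cells, %d parameters\n",
              nrow(x$phi$cells), ncol(x$phi$X)))
  cat(sprintf("  resight  : %d cells, %d parameters\n",
              nrow(x$p$cells), ncol(x$p$X)))
  cat(sprintf("  nominal parameter count: %d\n", x$npar))
  invisible(x)
}
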