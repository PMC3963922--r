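#' Goodness-of-fit of the time-dependent CJS model
#'
#' Contingency-table decomposition in the U-CARE tradition, computed per
#' colony on the multi-cohort data and summed into a global chi-square:
#'
#' * `TEST3.SR(i)`: among birds detected at occasion `i`, newly marked vs
#'   previously marked, crossed with re-encountered later yes/no
#'   (transience / marking effect).
#' * `TEST3.Sm(i)`: same split, crossed with the occasion of next
#'   encounter, among those re-encountered.
#' * `TEST2.CT(i)`: among birds known alive at `i` (detected before and
#'   after), detected at `i` vs not, crossed with next encounter at `i+1`
#'   vs later (trap-dependence).
#' * `TEST2.CL(i)`: same split, crossed with the exact occasion of next
#'   encounter among birds next seen after `i+1`.
#'
#' Each table is Pearson-tested after pooling cells with expected count
#' below 2 toward their neighbours; tables that cannot reach a valid 2x2
#' are flagged degenerate (df 0) and excluded from the global sum. Only
#' the chi-square forms are computed (no directional z variants).
#'
#' With `by_cohort = TRUE` the components are computed separately within
#' each marking cohort and summed, mirroring the cohort-wise protocol used
#' when the general model is age-structured: all birds in a cohort share an
#' age, so genuine age effects (which the model accommodates) cannot
#' masquerade as transience. TEST3 is then degenerate by construction and
#' the information comes from the TEST2 family.
#'
#' @param set a [capture_histories] object (>= 3 occasions).
#' @param by_cohort compute components within marking cohorts?
#' @return list of `gof_component` records: `name`, `group`, `occasion`,
#'   `chi2`, `df`, `degenerate`, `table`.
#' @export
gof_components <- function(set, by_cohort = FALSE) {
  T <- length(set$occasions)
  if (T < 3L) stop("goodness-of-fit needs at least 3 occasions")
  if (by_cohort) {
    fd <- first_detection(set)
    comps <- list()
    for (co in sort(unique(fd))) {
      idx <- fd == co
      sub <- capture_histories(set$detections[idx, , drop = FALSE],
                               set$occasions,
                               group = paste0(set$group[idx], ":cohort",
                                              set$occasions[co]))
      comps <- c(comps, gof_components(sub))
    }
    return(comps)
  }
  comps <- list()
  for (g in unique(set$group)) {
    H <- set$detections[set$group == g, , drop = FALSE]
    fd <- max.col(H == 1L, ties.method = "first")
    ld <- max.col(H == 1L, ties.method = "last")
    nxt <- function(ind, i) {        # occasion of next detection after i
      j <- which(H[ind, ] == 1L & seq_len(T) > i)
      if (length(j)) j[1L] else NA_integer_
    }
    for (i in 2:(T - 1L)) {
      at_i <- which(H[, i] == 1L)
      newly <- fd[at_i] == i
      seen_later <- ld[at_i] > i
      # TEST3.SR: new/old x seen-again
      tab <- table(factor(ifelse(newly, "new", "old"),
                          levels = c("new", "old")),
                   factor(ifelse(seen_later, "again", "never"),
                          levels = c("again", "never")))
      comps[[length(comps) + 1L]] <-
        gof_chisq(unclass(tab), "TEST3.SR", g, set$occasions[i])
      # TEST3.Sm: among seen again, when
      sub <- at_i[seen_later]
      if (length(sub)) {
        nj <- vapply(sub, nxt, 0L, i = i)
        tab <- table(factor(ifelse(fd[sub] == i, "new", "old"),
                            levels = c("new", "old")),
                     factor(nj, levels = (i + 1L):T))
        comps[[length(comps) + 1L]] <-
          gof_chisq(unclass(tab), "TEST3.Sm", g, set$occasions[i])
      }
      # TEST2: known alive at i = detected before and after i
      before <- fd < i
      after <- ld > i
      alive <- which(before & after)
      if (length(alive)) {
        caught <- H[alive, i] == 1L
        nj <- vapply(alive, nxt, 0L, i = i)
        tab <- table(factor(ifelse(caught, "at_i", "not_at_i"),
                            levels = c("at_i", "not_at_i")),
                     factor(ifelse(nj == i + 1L, "next", "later"),
                            levels = c("next", "later")))
        comps[[length(comps) + 1L]] <-
          gof_chisq(unclass(tab), "TEST2.CT", g, set$occasions[i])
        lat <- nj > i + 1L
        if (any(lat) && i + 2L <= T) {
          tab <- table(factor(ifelse(caught[lat], "at_i", "not_at_i"),
                              levels = c("at_i", "not_at_i")),
                       factor(nj[lat], levels = (i + 2L):T))
          comps[[length(comps) + 1L]] <-
            gof_chisq(unclass(tab), "TEST2.CL", g, set$occasions[i])
        }
      }
    }
  }
  comps
}

# Pearson chi-square with expected-count-2 neighbour pooling
gof_chisq <- function(tab, name, group, occasion, threshold = 2) {
  tab <- as.matrix(tab)
  pooled <- pool_table(tab, threshold)
  degen <- is.null(pooled) || any(dim(pooled) < 2L)
  if (degen) {
    chi2 <- 0; df <- 0L
  } else {
    E <- outer(rowSums(pooled), colSums(pooled)) / sum(pooled)
    chi2 <- sum((pooled - E)^2 / E)
    df <- (nrow(pooled) - 1L) * (ncol(pooled) - 1L)
  }
  structure(list(name = name, group = group, occasion = occasion,
                 chi2 = chi2, df = df, degenerate = degen,
                 table = tab, pooled = if (degen) NULL else pooled),
            class = "gof_component")
}

# merge the row/column holding the smallest expected count into its
# neighbour until all expectations reach the threshold (or give up)
pool_table <- function(tab, threshold = 2) {
  repeat {
    if (any(dim(tab) < 2L) || sum(tab) == 0) return(NULL)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (all(E >= threshold)) return(tab)
    worst <- which(E == min(E), arr.ind = TRUE)[1L, ]
    if (ncol(tab) > 2L) {
      j <- worst[["col"]]
      k <- if (j == ncol(tab)) j - 1L else j + 1L
      tab[, k] <- tab[, k] + tab[, j]
      tab <- tab[, -j, drop = FALSE]
    } else if (nrow(tab) > 2L) {
      r <- worst[["row"]]
      k <- if (r == nrow(tab)) r - 1L else r + 1L
      tab[k, ] <- tab[k, ] + tab[r, ]
      tab <- tab[-r, , drop = FALSE]
    } else return(NULL)     # 2x2 below threshold: degenerate
  }
}

#' Global goodness-of-fit test
#'
#' Sums the chi-square statistics and degrees of freedom of all
#' non-degenerate components and reports the upper-tail p-value.
#'
#' @param components output of [gof_components].
#' @return a `gof_result`: `chi2`, `df`, `p`, `components`.
#' @export
gof_global <- function(components) {
  if (!length(components)) stop("empty component list")
  keep <- !vapply(components, `[[`, TRUE, "degenerate")
  if (!any(keep)) {
    warning("all goodness-of-fit components degenerate")
    return(structure(list(chi2 = 0, df = 0L, p = NA_real_,
                          components = components),
                     class = "gof_result"))
  }
  chi2 <- sum(vapply(components[keep], `[[`, 0, "chi2"))
  df <- as.integer(sum(vapply(components[keep], function(x)
    as.numeric(x$df), 0)))
  structure(list(chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE),
                 components = components),
            class = "gof_result")
}

#' One-call CJS goodness-of-fit
#'
#' @param set a [capture_histories] object.
#' @param by_cohort compute components within marking cohorts (see
#'   [gof_components])?
#' @return a `gof_result` (see [gof_global]).
#' @export
gof_cjs <- function(set, by_cohort = FALSE)
  gof_global(gof_components(set, by_cohort = by_cohort))

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("Global CJS goodness-of-fit: chi2 = %.2f, df = %d, P = %.3f\n",
              x$chi2, x$df, x$p))
  nd <- sum(!vapply(x$components, `[[`, TRUE, "degenerate"))
  cat(sprintf("  %d components (%d informative, %d degenerate)\n",
              length(x$components), nd, length(x$components) - nd))
  invisible(x)
}
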