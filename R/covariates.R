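#' Annual environmental covariate series
#'
#' A year-indexed numeric series (fish landings, marshland inundation,
#' winter NAO, ...) used as a survival covariate. Values may be missing
#' (`NA`) in interior years; see [fill_covariate_gaps].
#'
#' @param name covariate name as used in model formulas (e.g. `"FISH"`).
#' @param years integer calendar years, strictly increasing.
#' @param values numeric values (NA = missing).
#' @param standardized has the series already been standardized?
#' @return an object of class `covariate_series`.
#' @export
covariate_series <- function(name, years, values, standardized = FALSE) {
  years <- as.integer(years)
  if (is.unsorted(years, strictly = TRUE))
    stop("years must be strictly increasing")
  if (length(years) != length(values))
    stop("years and values must have equal length")
  structure(list(name = name, years = years, values = as.numeric(values),
                 standardized = isTRUE(standardized), original = NULL),
            class = "covariate_series")
}

as_covariate_series <- function(x, name = "covariate") {
  if (inherits(x, "covariate_series")) return(x)
  if (is.numeric(x) && !is.null(names(x)))
    return(covariate_series(name, as.integer(names(x)), unname(x)))
  stop("covariates must be covariate_series or named year->value vectors")
}

#' @export
print.covariate_series <- function(x, ...) {
  cat(sprintf("covariate %s: %d years (%d-%d)%s%s\n", x$name,
              length(x$years), min(x$years), max(x$years),
              if (anyNA(x$values)) sprintf(", %d missing",
                                           sum(is.na(x$values))) else "",
              if (x$standardized) ", standardized" else ""))
  invisible(x)
}

#' Read a 2-column year,value covariate file
#'
#' @param path plain-text file with two columns (year, value), comma or
#'   whitespace separated, optional header.
#' @param name covariate name; defaults to the file name stem.
#' @return a [covariate_series].
#' @export
read_covariate <- function(path, name = NULL) {
  if (is.null(name))
    name <- toupper(sub("\\.[^.]*$", "", basename(path)))
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  header <- grepl("[A-Za-z]", first)
  tab <- utils::read.table(path, sep = sep, header = header,
                           strip.white = TRUE)
  covariate_series(name, tab[[1]], tab[[2]])
}

#' Standardize a covariate series
#'
#' Centers to zero mean and scales to unit *population* standard deviation
#' (denominator n), so slope estimates are comparable across covariates.
#' Missing values are ignored in the moments and preserved. Idempotent.
#'
#' @param series a [covariate_series].
#' @return the standardized series, with the original values retained in
#'   `$original` for reporting.
#' @export
standardize <- function(series) {
  stopifnot(inherits(series, "covariate_series"))
  v <- series$values
  obs <- v[!is.na(v)]
  if (length(obs) < 2L) stop("need at least 2 values to standardize")
  m <- mean(obs)
  s <- sqrt(mean((obs - m)^2))
  if (s == 0) stop("cannot standardize a constant series (zero variance)")
  out <- series
  out$original <- if (is.null(series$original)) v else series$original
  out$values <- (v - m) / s
  out$standardized <- TRUE
  out
}

#' Fill interior gaps by monotone piecewise cubic Hermite interpolation
#'
#' Missing interior years are interpolated with a shape-preserving cubic
#' Hermite spline (Fritsch-Carlson slopes, `stats::splinefun` method
#' `"monoH.FC"`): the interpolant never overshoots locally monotone data
#' and reproduces linear stretches exactly. Observed values are untouched.
#' Gaps at either boundary are an error (no extrapolation).
#'
#' @param series a [covariate_series], possibly with `NA` interior values.
#' @return the series with all years filled.
#' @export
fill_covariate_gaps <- function(series) {
  stopifnot(inherits(series, "covariate_series"))
  v <- series$values
  if (!anyNA(v)) return(series)
  obs <- !is.na(v)
  if (sum(obs) < 2L) stop("need at least 2 observed values")
  if (is.na(v[1L]) || is.na(v[length(v)]))
    stop("gap at series boundary: interpolation only fills interior years")
  f <- stats::splinefun(series$years[obs], v[obs], method = "monoH.FC")
  out <- series
  out$values[!obs] <- f(series$years[!obs])
  out
}

# covariate value at given calendar years (error on missing coverage)
covariate_at <- function(series, years) {
  i <- match(years, series$years)
  if (anyNA(i) || anyNA(series$values[i]))
    stop("covariate ", series$name, " does not cover years ",
         paste(years[is.na(i) | is.na(series$values[i])], collapse = ", "),
         " (fill gaps with fill_covariate_gaps())")
  series$values[i]
}

#' Analysis of deviance (ANODEV) for a covariate effect
#'
#' Compares three nested fits of the same data and resighting structure:
#' a model with the focal parameter constant (`cst`), the covariate model
#' (`cov`), and the corresponding time-dependent model (`t`). The F ratio
#' tests whether the temporal variation captured by the covariate is a
#' significant share of the variation captured by the full time model:
#' \deqn{F = \frac{(Dev_{cst}-Dev_{cov})/(np_{cov}-np_{cst})}
#'             {(Dev_{cov}-Dev_{t})/(np_{t}-np_{cov})}}
#' and \eqn{r^2 = (Dev_{cst}-Dev_{cov})/(Dev_{cst}-Dev_{t})} is the
#' fraction of temporal deviance explained.
#'
#' Degrees of freedom come from the supplied parameter counts, not from a
#' numerical rank recomputation. Slightly negative numerators (optimizer
#' noise) are clipped to zero with a warning.
#'
#' @param dev_cst,np_cst deviance and parameter count of the constant model.
#' @param dev_cov,np_cov of the covariate model.
#' @param dev_t,np_t of the time-dependent model.
#' @return an `anodev` object: `F`, `df1`, `df2`, `p`, `r2`.
#' @export
anodev <- function(dev_cst, np_cst, dev_cov, np_cov, dev_t, np_t) {
  if (inherits(dev_cst, "cjs_fit")) {
    fit <- dev_cst; dev_cst <- fit$deviance; np_cst <- fit$np
  }
  if (inherits(dev_cov, "cjs_fit")) {
    fit <- dev_cov; dev_cov <- fit$deviance; np_cov <- fit$np
  }
  if (inherits(dev_t, "cjs_fit")) {
    fit <- dev_t; dev_t <- fit$deviance; np_t <- fit$np
  }
  if (!(np_cst < np_cov && np_cov < np_t))
    stop("parameter counts must be nested: np_cst < np_cov < np_t")
  if (dev_cst < dev_t)
    stop("dev_cst < dev_t: constant and time reference models inverted")
  num <- dev_cst - dev_cov
  den <- dev_cov - dev_t
  if (num < 0) {
    warning("dev_cov > dev_cst (optimizer noise); clipping to 0")
    num <- 0
  }
  if (den < 0) {
    warning("dev_t > dev_cov (optimizer noise); clipping to 0")
    den <- 0
  }
  df1 <- np_cov - np_cst
  df2 <- np_t - np_cov
  Fstat <- if (den == 0) {
    if (num == 0) 0 else Inf
  } else (num / df1) / (den / df2)
  tot <- dev_cst - dev_t
  r2 <- if (tot == 0) 0 else num / tot
  p <- if (is.finite(Fstat)) stats::pf(Fstat, df1, df2, lower.tail = FALSE)
       else 0
  structure(list(F = Fstat, df1 = df1, df2 = df2, p = p, r2 = r2),
            class = "anodev")
}

#' @export
print.anodev <- function(x, ...) {
  cat(sprintf("ANODEV: F(%d,%d) = %.2f, p = %.3f, r2 = %.2f\n",
              x$df1, x$df2, x$F, x$p, x$r2))
  invisible(x)
}
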