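#' Nest-census series
#'
#' @param years integer calendar years (strictly increasing); gap years are
#'   simply absent.
#' @param counts positive nest counts, one per year.
#' @param region region label.
#' @return a `census_series` object.
#' @export
census_series <- function(years, counts, region = "region") {
  years <- as.integer(years)
  if (is.unsorted(years, strictly = TRUE))
    stop("years must be strictly increasing")
  if (length(years) != length(counts))
    stop("years and counts must have equal length")
  if (any(counts <= 0)) stop("census counts must be positive")
  structure(list(region = region, years = years,
                 counts = as.numeric(counts)),
            class = "census_series")
}

#' @export
print.census_series <- function(x, ...) {
  cat(sprintf("census %s: %d years (%d-%d), N %g-%g\n", x$region,
              length(x$years), min(x$years), max(x$years),
              min(x$counts), max(x$counts)))
  invisible(x)
}

#' Read a 2-column year,count census file
#' @param path plain-text file; comma or whitespace separated, optional
#'   header.
#' @param region region label; defaults to the file name stem.
#' @return a [census_series].
#' @export
read_census <- function(path, region = NULL) {
  if (is.null(region)) region <- sub("\\.[^.]*$", "", basename(path))
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  header <- grepl("[A-Za-z]", first)
  tab <- utils::read.table(path, sep = sep, header = header,
                           strip.white = TRUE)
  census_series(tab[[1]], tab[[2]], region)
}

#' Sum regional census series into one series
#'
#' Years in which any region is unobserved are treated as census gaps
#' (`require_all = TRUE`, the default) or summed over the observed regions
#' (`require_all = FALSE`).
#'
#' @param series list of [census_series].
#' @param region label of the combined series.
#' @param require_all drop years missing from any region?
#' @return a [census_series].
#' @export
sum_census <- function(series, region = "combined", require_all = TRUE) {
  yrs <- sort(unique(unlist(lapply(series, `[[`, "years"))))
  mat <- vapply(series, function(s) s$counts[match(yrs, s$years)],
                numeric(length(yrs)))
  mat <- matrix(mat, nrow = length(yrs))
  keep <- if (require_all) rowSums(is.na(mat)) == 0L
          else rowSums(!is.na(mat)) > 0L
  census_series(yrs[keep], rowSums(mat[keep, , drop = FALSE], na.rm = TRUE),
                region)
}

#' Annual breeding success
#'
#' Fledglings counted in the creche divided by nests counted; may exceed 1
#' with multi-chick broods.
#'
#' @param nests positive nest count.
#' @param fledglings non-negative fledgling count.
#' @return fledglings per nest.
#' @export
breeding_success <- function(nests, fledglings) {
  if (any(nests <= 0)) stop("breeding success undefined for nests <= 0")
  if (any(fledglings < 0)) stop("fledgling counts must be non-negative")
  fledglings / nests
}

#' Two-sample t test from summary statistics
#'
#' Compares two group means given their standard errors, as when only
#' published means and SEs are available:
#' \eqn{t = |m_2 - m_1| / \sqrt{SE_1^2 + SE_2^2}}, df = n1 + n2 - 2,
#' two-sided p.
#'
#' @param mean1,se1,n1 first group mean, standard error, sample size.
#' @param mean2,se2,n2 second group.
#' @return list `t`, `df`, `p`.
#' @export
summary_t_test <- function(mean1, se1, n1, mean2, se2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, se1 > 0, se2 > 0)
  t <- abs(mean2 - mean1) / sqrt(se1^2 + se2^2)
  df <- n1 + n2 - 2L
  list(t = t, df = df, p = 2 * stats::pt(t, df, lower.tail = FALSE))
}

#' Annual population growth rates
#'
#' \eqn{\lambda_t = N_{t+1}/N_t} for consecutive-year census pairs only;
#' pairs spanning gaps are excluded (the stochastic estimator handles
#' unequal intervals).
#'
#' @param series a [census_series].
#' @return named numeric vector, names = starting year of each transition.
#' @export
annual_lambda <- function(series) {
  stopifnot(inherits(series, "census_series"))
  if (length(series$years) < 2L) stop("need at least 2 census years")
  d <- diff(series$years)
  keep <- d == 1L
  stats::setNames((series$counts[-1L] / series$counts[-length(series$counts)])[keep],
                  series$years[-length(series$years)][keep])
}

#' Stochastic population growth by Dennis regression
#'
#' For each pair of successive censuses separated by \eqn{\tau_i} years,
#' regress \eqn{y_i = \log(N_{i+1}/N_i)/\sqrt{\tau_i}} on
#' \eqn{x_i = \sqrt{\tau_i}} without intercept. The slope estimates the mean
#' log growth rate \eqn{\mu}, the residual mean square the environmental
#' variance \eqn{\sigma^2}, and \eqn{\lambda_s = e^{\hat\mu}} (median
#' growth) with CI \eqn{\exp(\hat\mu \pm t_{\alpha/2, q-1} SE(\hat\mu))}.
#' Gaps in the census are handled exactly by the unequal intervals.
#'
#' @param series a [census_series] with at least 3 census points.
#' @param alpha CI level is `1 - alpha`.
#' @param lognormal_mean report \eqn{\exp(\hat\mu + \hat\sigma^2/2)}
#'   (lognormal mean growth) instead of the median-growth default?
#' @return a `growth_estimate`: `mu_hat`, `sigma2_hat`, `lambda_s`, `ci`,
#'   `q` (number of transitions), `se_mu`, `decline_flag` (CI lower limit
#'   below 1).
#' @export
dennis_stochastic_lambda <- function(series, alpha = 0.05,
                                     lognormal_mean = FALSE) {
  stopifnot(inherits(series, "census_series"))
  if (length(series$years) < 3L)
    stop("need at least 3 census points (2 transitions)")
  tau <- diff(series$years)
  x <- sqrt(tau)
  y <- log(series$counts[-1L] / series$counts[-length(series$counts)]) / x
  q <- length(x)
  mu <- sum(x * y) / sum(x^2)
  sigma2 <- sum((y - mu * x)^2) / (q - 1L)
  se_mu <- sqrt(sigma2 / sum(x^2))
  tq <- stats::qt(1 - alpha / 2, q - 1L)
  lam <- if (lognormal_mean) exp(mu + sigma2 / 2) else exp(mu)
  ci <- exp(c(mu - tq * se_mu, mu + tq * se_mu))
  if (lognormal_mean) ci <- ci * exp(sigma2 / 2)
  structure(list(mu_hat = mu, sigma2_hat = sigma2, lambda_s = lam,
                 ci = ci, q = q, se_mu = se_mu, alpha = alpha,
                 decline_flag = ci[1L] < 1,
                 region = series$region),
            class = "growth_estimate")
}

#' @export
print.growth_estimate <- function(x, ...) {
  cat(sprintf("stochastic growth (%s): lambda_s = %.3f (%d%% CI %.3f-%.3f, q = %d)\n",
              x$region, x$lambda_s, round(100 * (1 - x$alpha)),
              x$ci[1L], x$ci[2L], x$q))
  if (x$decline_flag)
    cat("  CI lower limit below 1: long-term decline cannot be ruled out\n")
  invisible(x)
}

#' Geometric mean growth rate
#'
#' @param lambdas positive annual growth rates.
#' @return `exp(mean(log(lambdas)))`.
#' @export
geometric_mean_lambda <- function(lambdas) {
  if (any(lambdas <= 0)) stop("growth rates must be positive")
  exp(mean(log(lambdas)))
}
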