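#' Vital rates for a stage-structured projection
#'
#' Female-based rates for a pre-breeding-census projection: fecundity in
#' fledglings per breeding pair per year, first-year (fledging to age 1)
#' and adult (age 1 onwards) apparent survival, and an age-specific
#' recruitment schedule: the probability of first breeding at each age,
#' ending with certain recruitment at a terminal age.
#'
#' @param fecundity fledglings per pair per year (>= 0).
#' @param phi_first_year first-year survival probability.
#' @param phi_adult adult survival probability.
#' @param recruitment named numeric vector, names = ages, values = the
#'   probability that a not-yet-breeding bird of that age recruits; the
#'   last entry must be 1. The default (ages 2-5, linearly increasing)
#'   stands in for delayed accession to reproduction typical of gulls.
#' @param sex_ratio fraction of fledglings that are female.
#' @return a `vital_rates` object.
#' @export
vital_rates <- function(fecundity, phi_first_year, phi_adult,
                        recruitment = c(`2` = 0.25, `3` = 0.5, `4` = 0.75,
                                        `5` = 1),
                        sex_ratio = 0.5) {
  ages <- as.integer(names(recruitment))
  if (anyNA(ages) || is.unsorted(ages, strictly = TRUE) || ages[1L] < 2L)
    stop("recruitment must be named by increasing ages >= 2")
  if (any(recruitment < 0 | recruitment > 1))
    stop("recruitment probabilities must lie in [0, 1]")
  if (recruitment[length(recruitment)] != 1)
    stop("the terminal recruitment probability must be 1")
  if (any(diff(ages) != 1L))
    stop("recruitment ages must be consecutive")
  stopifnot(fecundity >= 0, phi_first_year >= 0, phi_first_year <= 1,
            phi_adult >= 0, phi_adult <= 1, sex_ratio >= 0, sex_ratio <= 1)
  structure(list(fecundity = fecundity, phi_first_year = phi_first_year,
                 phi_adult = phi_adult, recruitment = recruitment,
                 sex_ratio = sex_ratio),
            class = "vital_rates")
}

#' Build the pre-breeding-census stage matrix
#'
#' Stages are pre-breeders of age 1, ..., k-1 (k = terminal recruitment
#' age) and a breeder stage. Over one year a pre-breeder of age `a`
#' survives with adult survival and recruits with the age-(a+1)
#' recruitment probability; breeders survive with adult survival and
#' produce `sex_ratio * fecundity * phi_first_year` female recruits into
#' the age-1 stage (pre-breeding census: offspring must survive their
#' first year to be counted).
#'
#' @param rates a [vital_rates] object.
#' @return a `stage_matrix`: non-negative square matrix with stage labels,
#'   projecting `n_{t+1} = A %*% n_t`.
#' @export
build_stage_matrix <- function(rates) {
  stopifnot(inherits(rates, "vital_rates"))
  r <- rates$recruitment
  k <- max(as.integer(names(r)))          # terminal recruitment age
  npre <- k - 1L                          # pre-breeder stages: ages 1..k-1
  n <- npre + 1L
  A <- matrix(0, n, n)
  labs <- c(paste0("age", seq_len(npre)), "breeder")
  dimnames(A) <- list(labs, labs)
  rec_at <- function(age) if (as.character(age) %in% names(r))
    r[[as.character(age)]] else 0
  for (a in seq_len(npre)) {
    ra <- rec_at(a + 1L)
    A[n, a] <- rates$phi_adult * ra                    # recruit
    if (a < npre)
      A[a + 1L, a] <- rates$phi_adult * (1 - ra)       # stay pre-breeder
  }
  A[n, n] <- rates$phi_adult                           # breeder survival
  A[1L, n] <- rates$sex_ratio * rates$fecundity * rates$phi_first_year
  class(A) <- c("stage_matrix", class(A))
  A
}

#' Asymptotic population growth rate
#'
#' Dominant eigenvalue modulus of a non-negative projection matrix.
#'
#' @param A a square non-negative matrix.
#' @return the asymptotic growth rate (numeric scalar).
#' @export
asymptotic_lambda <- function(A) {
  A <- unclass(as.matrix(A))
  if (nrow(A) != ncol(A)) stop("matrix must be square")
  if (any(A < 0)) stop("matrix entries must be non-negative")
  max(Mod(eigen(A, only.values = TRUE)$values))
}

#' Project a stage-structured population
#'
#' @param matrices a single stage matrix (constant projection) or a list of
#'   annual matrices, one per projected year.
#' @param n0 initial stage vector.
#' @param years number of years to project (defaults to
#'   `length(matrices)` when annual matrices are given).
#' @return list with `trajectory` (stage x year matrix including year 0),
#'   `total` (total-size series), and `geometric_mean_growth` of the
#'   annual totals.
#' @export
project <- function(matrices, n0, years = NULL) {
  if (is.matrix(matrices)) {
    if (is.null(years)) stop("years is required with a constant matrix")
    matrices <- rep(list(unclass(matrices)), years)
  } else {
    matrices <- lapply(matrices, unclass)
    if (is.null(years)) years <- length(matrices)
    if (length(matrices) != years)
      stop("need one matrix per projected year")
  }
  n <- length(n0)
  if (any(vapply(matrices, function(A) !all(dim(A) == n), TRUE)))
    stop("matrix dimensions must match the stage vector")
  traj <- matrix(0, n, years + 1L)
  traj[, 1L] <- n0
  for (t in seq_len(years)) traj[, t + 1L] <- matrices[[t]] %*% traj[, t]
  total <- colSums(traj)
  gm <- if (all(total > 0)) geometric_mean_lambda(total[-1L] / total[-length(total)])
        else NA_real_
  list(trajectory = traj, total = total, geometric_mean_growth = gm)
}

#' Marked-fraction immigration correction
#'
#' Scales the observed number of marked immigrants at a destination colony
#' by the fraction of fledglings marked at the origin and the annual
#' resighting probability at the destination, to estimate the total number
#' of immigrants and their share of the breeding population.
#'
#' @param observed observed (marked) immigrants.
#' @param m_r proportion of fledglings marked at the origin colony (0,1].
#' @param p_s annual resighting probability at the destination (0,1].
#' @param n_breeders breeding population size at the destination.
#' @param year optional year label.
#' @return an `immigration_estimate`: `observed`, `corrected`
#'   (`observed / (m_r * p_s)`), `proportion_of_breeders`.
#' @export
estimate_immigrants <- function(observed, m_r, p_s, n_breeders,
                                year = NA_integer_) {
  stopifnot(observed >= 0, n_breeders > 0)
  if (!(m_r > 0 && m_r <= 1) || !(p_s > 0 && p_s <= 1))
    stop("m_r and p_s must lie in (0, 1]")
  corrected <- observed / (m_r * p_s)
  structure(list(year = year, observed = observed, m_r = m_r, p_s = p_s,
                 corrected = corrected,
                 proportion_of_breeders = corrected / n_breeders),
            class = "immigration_estimate")
}

#' @export
print.immigration_estimate <- function(x, ...) {
  cat(sprintf("immigrants: %g observed -> %.2f corrected (%.1f%% of breeders)\n",
              x$observed, x$corrected, 100 * x$proportion_of_breeders))
  invisible(x)
}
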