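# Independent oracles and fixture builders shared across test files.
# Everything here is deliberately naive (per-individual products, power
# iteration, brute-force grids) and never calls the code paths it checks.

# build a capture_histories object from detection strings like "1011"
hist_set <- function(strings, years = NULL, group = "colony1") {
  det <- do.call(rbind, lapply(strsplit(strings, ""), as.integer))
  if (is.null(years)) years <- 2000L + seq_len(ncol(det)) - 1L
  capture_histories(det, years, group = group)
}

# cell-value lookup from a fitted/asserted design + beta: returns
# functions phi(g, age, k) and p(g, age, j) on the probability scale
design_cell_values <- function(design, beta, p_fixed = NULL) {
  n_phi <- ncol(design$phi$X)
  phi_vals <- stats::plogis(drop(design$phi$X %*% beta[seq_len(n_phi)]))
  p_vals <- if (is.null(p_fixed))
    stats::plogis(drop(design$p$X %*% beta[n_phi + seq_len(ncol(design$p$X))]))
  else NULL
  list(
    phi = function(g, age, k) {
      r <- design$phi$idx[g, age, k]
      phi_vals[r]
    },
    p = function(g, age, j) {
      if (!is.null(p_fixed)) return(p_fixed)
      r <- design$p$idx[g, age, j]
      p_vals[r]
    })
}

# brute-force per-individual CJS deviance: product over each history of
# survival/detection/non-detection terms and the chi (never-seen-again)
# recursion, conditioned on first detection. Exactly -2 sum log L with the
# same (absent) multinomial constants as the m-array likelihood.
brute_force_cjs_deviance <- function(set, design, beta, p_fixed = NULL) {
  cv <- design_cell_values(design, beta, p_fixed)
  T <- length(set$occasions)
  ll <- 0
  for (ind in seq_len(nrow(set$detections))) {
    h <- set$detections[ind, ]
    g <- match(set$group[ind], design$groups)
    occ <- which(h == 1L)
    c0 <- occ[1L]
    li <- 0
    if (length(occ) > 1L) {
      for (l in seq_len(length(occ) - 1L)) {
        from <- occ[l]; to <- occ[l + 1L]
        for (k in from:(to - 1L))
          li <- li + log(cv$phi(g, k - c0 + 1L, k))
        if (to - 1L >= from + 1L)
          for (j in (from + 1L):(to - 1L))
            li <- li + log(1 - cv$p(g, j - c0, j))
        li <- li + log(cv$p(g, to - c0, to))
      }
    }
    last <- occ[length(occ)]
    # chi recursion from the last detection
    chi <- 1
    if (last < T) {
      for (i in (T - 1L):last) {
        phi_i <- cv$phi(g, i - c0 + 1L, i)
        p_next <- cv$p(g, i + 1L - c0, i + 1L)
        chi <- 1 - phi_i + phi_i * (1 - p_next) * chi
      }
    }
    ll <- ll + li + log(chi)
  }
  -2 * ll
}

# power-iteration dominant eigenvalue (independent of eigen())
power_iteration_lambda <- function(A, iter = 10000, tol = 1e-13) {
  v <- rep(1, nrow(A)) / nrow(A)
  lam <- 0
  for (i in seq_len(iter)) {
    w <- A %*% v
    nl <- sqrt(sum(w^2))
    if (nl == 0) return(0)
    w <- w / nl
    if (max(abs(w - v)) < tol && i > 5) { lam <- nl; break }
    v <- w
    lam <- nl
  }
  lam
}

# random small capture-resight instance for likelihood equivalence tests
random_small_instance <- function(seed) {
  cfg <- local({
    set.seed(seed)
    T <- sample(3:5, 1)
    ncoh <- sample(1:(T - 1), 1)
    sizes <- sample(3:10, ncoh, replace = TRUE)
    names(sizes) <- (2000:(2000 + T - 1))[seq_len(ncoh)]
    simulation_config(2000:(2000 + T - 1), sizes,
                      survival = list(first_year = runif(1, .3, .9),
                                      adult = runif(1, .5, .95)),
                      resight = runif(1, .3, .9),
                      seed = seed + 1000)
  })
  simulate_histories(cfg)
}

# deterministic replicate seeds below 2^31 derived from a master seed
replicate_seeds <- function(master, n) {
  (as.integer(master) * 1009L + 17L * seq_len(n)) %% 2147483562L + 1L
}
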