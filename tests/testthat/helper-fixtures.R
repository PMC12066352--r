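# Shared fixtures and independent oracles for the test suite.

# symmetric random edge matrix with zero diagonal
random_omega <- function(p, scale = 0.4) {
  m <- matrix(0, p, p)
  m[upper.tri(m)] <- stats::runif(p * (p - 1) / 2, -scale, scale)
  m + t(m)
}

random_params <- function(p, encoding = "pm1", beta = NULL) {
  ising_params(random_omega(p), stats::runif(p, -0.5, 0.5),
               beta = beta %||% stats::runif(1, 0.3, 2.5),
               encoding = encoding)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force oracle for the panel log-likelihood: its own
# enumeration (expand.grid), its own energy formula, per-row summation —
# shares no code with the package internals.
loglik_bruteforce <- function(X, omega, tau, beta, encoding = "pm1") {
  p <- length(tau)
  alpha <- if (encoding == "pm1") c(-1, 1) else c(0, 1)
  states <- as.matrix(expand.grid(rep(list(alpha), p)))
  energy <- apply(states, 1, function(s) {
    -(sum(tau * s) + 0.5 * sum(s * (omega %*% s)))
  })
  w <- exp(-beta * energy)
  Z <- sum(w)
  key <- apply(states, 1, paste, collapse = ",")
  logp <- stats::setNames(log(w / Z), key)
  sum(logp[apply(X, 1, paste, collapse = ",")])
}

# single-group p = 2 saturated MLE by an independent Newton solve on the
# 2x2 table: three natural parameters (tau1, tau2, omega12) matched to the
# observed moments by damped Newton on the moment equations
saturated2_oracle <- function(counts_mm, counts_mp, counts_pm, counts_pp) {
  n <- counts_mm + counts_mp + counts_pm + counts_pp
  obs <- c(
    (counts_pm + counts_pp - counts_mm - counts_mp) / n,  # E x1
    (counts_mp + counts_pp - counts_mm - counts_pm) / n,  # E x2
    (counts_mm + counts_pp - counts_mp - counts_pm) / n   # E x1 x2
  )
  states <- rbind(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  moments <- function(th) {
    e <- states %*% c(th[1], th[2]) + th[3] * states[, 1] * states[, 2]
    pr <- exp(e) / sum(exp(e))
    c(sum(pr * states[, 1]), sum(pr * states[, 2]),
      sum(pr * states[, 1] * states[, 2]))
  }
  th <- c(0, 0, 0)
  for (it in 1:200) {
    f <- moments(th) - obs
    if (max(abs(f)) < 1e-12) break
    J <- vapply(1:3, function(j) {
      h <- 1e-6
      tp <- th; tp[j] <- tp[j] + h
      (moments(tp) - moments(th)) / h
    }, numeric(3))
    th <- th - solve(J, f)
  }
  list(tau = th[1:2], omega12 = th[3])
}

# small 2-wave design used in several estimation tests
small_design <- function(n = 1500, seed = 1, p = 4, betas = c(1, 0.8)) {
  om <- random_omega_fixed(p)
  waves <- tibble::tibble(age = seq(10, by = 1, length.out = length(betas)),
                          n = n, beta = betas)
  tau <- matrix(rep(seq(-0.3, -0.1, length.out = p), length(betas)),
                length(betas), p, byrow = TRUE)
  cohort_design(om, waves, tau, seed = seed)
}

# deterministic mildly dense edge matrix (no RNG involvement)
random_omega_fixed <- function(p) {
  m <- matrix(0.1, p, p)
  if (p > 1) m[cbind(seq_len(p - 1), seq_len(p - 1) + 1)] <- 0.3
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

expect_tibble <- function(x) testthat::expect_s3_class(x, "tbl_df")

beta_hat_test <- function(fit) vapply(fit$params, `[[`, 0, "beta")
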