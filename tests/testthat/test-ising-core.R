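# Exact probability, likelihood, entropy and transform machinery.

test_that("hamiltonian matches the quadratic potential on hand cases", {
  pr <- ising_params(matrix(c(0, 1, 1, 0), 2), tau = c(0, 0))
  expect_equal(ising_hamiltonian(c(1, 1), pr), -1)
  expect_equal(ising_hamiltonian(c(1, -1), pr), 1)
  pr3 <- ising_params(0, tau = c(0.5, 0, 0))
  expect_equal(ising_hamiltonian(c(1, -1, -1), pr3), -0.5)
  # matrix input vectorizes over rows
  expect_equal(ising_hamiltonian(rbind(c(1, 1), c(1, -1)), pr), c(-1, 1))
})

test_that("hamiltonian validates dimension and alphabet", {
  pr <- ising_params(0, tau = c(0, 0))
  expect_error(ising_hamiltonian(c(1, 1, 1), pr), "length")
  expect_error(ising_hamiltonian(c(0, 1), pr), "alphabet")
})

test_that("state distribution: uniform, logistic closed form, alignment", {
  u <- ising_state_distribution(ising_params(0, c(0, 0, 0), beta = 3.7))
  expect_equal(u$prob, rep(1 / 8, 8), tolerance = 1e-12)
  expect_equal(attr(u, "logZ"), log(8))

  # one item: P(x = 1) = plogis(2 tau) under PM1
  d1 <- ising_state_distribution(ising_params(0, 0.5))
  expect_equal(d1$prob[d1$item_1 == 1], 1 / (1 + exp(-1)), tolerance = 1e-10)

  # positive coupling at high beta: aligned states dominate and are equal
  d2 <- ising_state_distribution(
    ising_params(matrix(c(0, .8, .8, 0), 2), c(0, 0), beta = 3))
  aligned <- d2$prob[d2$item_1 == d2$item_2]
  expect_equal(aligned[1], aligned[2])
  expect_true(all(aligned > max(d2$prob[d2$item_1 != d2$item_2])))
})

test_that("probabilities normalize across random parameter draws", {
  withr::with_seed(42, {
    for (i in 1:100) {
      p <- sample(1:8, 1)
      prm <- random_params(p, encoding = sample(c("pm1", "zo"), 1))
      sd <- ising_state_distribution(prm)
      expect_equal(sum(sd$prob), 1, tolerance = 1e-10)
      expect_true(all(sd$prob >= 0))
      expect_equal(nrow(sd), 2^p)
    }
  })
})

test_that("tau = 0 under PM1 gives the global spin-flip symmetry", {
  withr::with_seed(7, {
    prm <- ising_params(random_omega(5), rep(0, 5), beta = 1.4)
    sd <- ising_state_distribution(prm)
    S <- as.matrix(sd[, 1:5])
    # match each state with its negation
    key <- apply(S, 1, paste, collapse = ",")
    neg <- apply(-S, 1, paste, collapse = ",")
    expect_equal(sd$prob, sd$prob[match(neg, key)])
  })
})

test_that("enumeration refuses p over the limit, naming it", {
  expect_error(ising_state_distribution(ising_params(0, rep(0, 21))),
               "p <= 20")
})

test_that("log-likelihood via sufficient statistics equals brute force", {
  withr::with_seed(11, {
    prm <- random_params(4, beta = 1.3)
    X <- as.matrix(sample_ising(prm, 50, seed = 99))
    ll <- ising_loglik(X, prm)
    oracle <- loglik_bruteforce(X, prm$omega, prm$tau, prm$beta)
    expect_equal(ll, oracle, tolerance = 1e-10)
  })
})

test_that("log-likelihood is additive: n = 1 definition and row duplication", {
  prm <- ising_params(matrix(c(0, .4, .4, 0), 2), c(0.2, -0.1), beta = 1.7)
  x <- matrix(c(1, -1), 1)
  expect_equal(ising_loglik(x, prm),
               -prm$beta * ising_hamiltonian(c(1, -1), prm) -
                 log_partition(prm))
  X <- as.matrix(sample_ising(prm, 25, seed = 3))
  expect_equal(ising_loglik(rbind(X, X), prm), 2 * ising_loglik(X, prm))
})

test_that("log-likelihood refuses missing cells with guidance", {
  prm <- ising_params(0, c(0, 0))
  X <- matrix(c(1, NA, -1, 1), 2)
  expect_error(ising_loglik(X, prm), "listwise")
})

test_that("Gibbs entropy: uniform maximum, beta monotonicity, point mass", {
  expect_equal(gibbs_entropy(ising_params(0, c(0, 0, 0))), 3 * log(2),
               tolerance = 1e-12)
  om <- matrix(c(0, .6, .6, 0), 2)
  s <- vapply(c(0.5, 1, 2), function(b) {
    gibbs_entropy(ising_params(om, c(0.1, -0.1), beta = b))
  }, 0)
  expect_true(s[3] < s[2] && s[2] < s[1])
  expect_lt(gibbs_entropy(ising_params(0, 10, beta = 10)), 1e-6)
  # bits option is a display conversion
  expect_equal(gibbs_entropy(ising_params(0, c(0, 0)), base = 2), 2)
})

test_that("beta -> 0 limit restores the uniform distribution", {
  withr::with_seed(5, {
    prm <- ising_params(random_omega(4), runif(4, -1, 1), beta = 1e-8)
    expect_equal(gibbs_entropy(prm), 4 * log(2), tolerance = 1e-8)
  })
})

test_that("encoding transform reproduces the identical distribution", {
  prm <- ising_params(matrix(c(0, .25, .25, 0), 2), c(0.1, -0.2))
  zo <- encode_params(prm, "zo")
  expect_equal(zo$omega[1, 2], 1.0)
  expect_equal(zo$tau, c(-0.3, -0.9))
  # oracle: enumerate both distributions on matched (relabelled) states
  tv <- sum(abs(ising_state_distribution(prm)$prob -
                  ising_state_distribution(zo)$prob))
  expect_lt(tv, 1e-12)
})

test_that("encoding transform: independent items, round trip, loglik offset", {
  tau <- c(0.3, -0.4, 0.1)
  ind <- encode_params(ising_params(0, tau), "zo")
  expect_equal(ind$tau, 2 * tau)
  expect_equal(max(abs(ind$omega)), 0)

  withr::with_seed(21, {
    prm <- random_params(4, beta = 1.6)
    back <- encode_params(encode_params(prm, "zo"), "pm1")
    expect_equal(back$omega, prm$omega, tolerance = 1e-12)
    expect_equal(back$tau, prm$tau, tolerance = 1e-12)
    expect_equal(back$beta, prm$beta)

    # per-configuration probabilities identical; loglik differs by a
    # data-independent constant
    zo <- encode_params(prm, "zo")
    expect_equal(ising_state_distribution(prm)$prob,
                 ising_state_distribution(zo)$prob, tolerance = 1e-10)
    Xpm <- as.matrix(sample_ising(prm, 30, seed = 8))
    Xzo <- (Xpm + 1) / 2
    d1 <- ising_loglik(Xpm, prm) - ising_loglik(Xzo, zo)
    Xpm2 <- as.matrix(sample_ising(prm, 40, seed = 9))
    d2 <- ising_loglik(Xpm2, prm) - ising_loglik((Xpm2 + 1) / 2, zo)
    expect_equal(d1 / 30, d2 / 40, tolerance = 1e-10)
  })
})

test_that("encode_params refuses a no-op transform", {
  expect_error(encode_params(ising_params(0, c(0, 0)), "pm1"), "already")
})

test_that("global strength sums absolute edges and scales linearly in beta", {
  om <- matrix(0, 3, 3)
  om[1, 2] <- om[2, 1] <- 0.5
  om[1, 3] <- om[3, 1] <- -0.25
  expect_equal(global_strength(ising_params(om, rep(0, 3))), 0.75)
  pr6 <- ising_params(om, rep(0, 3), beta = 0.6)
  expect_equal(global_strength(pr6, temperature_scaled = TRUE), 0.45)
  expect_equal(global_strength(pr6, temperature_scaled = TRUE) /
                 global_strength(pr6), 0.6)
})
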