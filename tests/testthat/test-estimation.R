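# Multigroup maximum likelihood: identification, recovery, constraints,
# pruning, bootstrap.

test_that("free-parameter counts follow the constraint level", {
  d <- generate_cohort(small_design(n = 300, seed = 2))
  p <- 4; E <- p * (p - 1) / 2; G <- 2
  ks <- c(saturated = G * (p + E),
          equal_edges = E + G * p + (G - 1),
          equal_edges_thresholds = E + p + (G - 1),
          equal_all = E + p)
  for (lev in names(ks)) {
    fit <- fit_ising_mg(d, mg_spec(lev))
    expect_equal(fit$k, unname(ks[lev]))
    expect_equal(length(fit$se), fit$k)
  }
})

test_that("wave-1 beta is exactly 1 whenever beta varies", {
  d <- generate_cohort(small_design(n = 400, seed = 3))
  for (lev in c("equal_edges", "equal_edges_thresholds")) {
    fit <- fit_ising_mg(d, mg_spec(lev))
    expect_identical(fit$params[[1]]$beta, 1)
  }
  # and all betas are 1 when fixed
  fit_sat <- fit_ising_mg(d, mg_spec("saturated"))
  expect_identical(vapply(fit_sat$params, `[[`, 0, "beta"), c(1, 1))
})

test_that("single-group saturated p=2 fit attains the empirical cells", {
  X <- rbind(matrix(c(-1, -1), 40, 2, byrow = TRUE),
             matrix(c(-1, 1), 10, 2, byrow = TRUE),
             matrix(c(1, -1), 10, 2, byrow = TRUE),
             matrix(c(1, 1), 40, 2, byrow = TRUE))
  d <- tibble::tibble(id = 1:100, wave = 1, age = 10,
                      item_1 = X[, 1], item_2 = X[, 2])
  fit <- fit_ising_mg(d, mg_spec("saturated"), gtol = 1e-10)
  sd <- ising_state_distribution(fit$params[[1]])
  expect_equal(sd$prob, c(.4, .1, .1, .4), tolerance = 1e-6)

  # independent oracle: moment-matching Newton solve on the 2x2 table
  or <- saturated2_oracle(40, 10, 10, 40)
  expect_equal(fit$params[[1]]$tau, or$tau, tolerance = 1e-6)
  expect_equal(fit$params[[1]]$omega[1, 2], or$omega12, tolerance = 1e-6)
})

test_that("beta trajectory is recovered on the four-wave fixture", {
  d <- generate_cohort(recovery_design(5000, seed = 17))
  fit <- fit_ising_mg(d, mg_spec("equal_edges"))
  expect_true(fit$converged)
  err <- abs(beta_hat_test(fit) - c(1, .85, .70, .60))
  expect_lt(mean(err), 0.03)   # single-seed check; the 50-seed mean is tighter
  expect_lt(max(err), 0.06)
})

test_that("equal_all on replicated panels equals G x single-group loglik", {
  prm <- ising_params(random_omega_fixed(3), c(-0.2, 0, 0.1))
  X <- sample_ising(prm, 500, seed = 30)
  one <- dplyr::bind_cols(tibble::tibble(id = 1:500, wave = 1, age = 10), X)
  three <- dplyr::bind_rows(
    one,
    dplyr::mutate(one, wave = 2, age = 11),
    dplyr::mutate(one, wave = 3, age = 12)
  )
  f1 <- fit_ising_mg(one, mg_spec("saturated"), gtol = 1e-9)
  f3 <- fit_ising_mg(three, mg_spec("equal_all"), gtol = 1e-9)
  expect_equal(f3$loglik, 3 * f1$loglik, tolerance = 1e-8)
})

test_that("log-likelihoods are nested across constraint levels", {
  d <- generate_cohort(small_design(n = 600, seed = 5))
  lls <- vapply(c("saturated", "equal_edges", "equal_edges_thresholds",
                  "equal_all"),
                function(lev) fit_ising_mg(d, mg_spec(lev))$loglik, 0)
  expect_true(all(diff(lls) <= 1e-6))
})

test_that("the optimum matches a derivative-free optimizer from random starts", {
  d <- generate_cohort(small_design(n = 400, seed = 7, p = 3))
  spec <- mg_spec("equal_edges")
  fit <- fit_ising_mg(d, spec, gtol = 1e-9)
  # independent route: Nelder-Mead on the same likelihood surface from 10
  # random starts, best result compared with the quasi-Newton optimum
  nll <- function(theta) {
    om <- matrix(0, 3, 3)
    om[upper.tri(om)] <- theta[1:3]
    om <- om + t(om)
    ll <- 0
    for (g in 1:2) {
      tau <- theta[3 + (g - 1) * 3 + 1:3]
      beta <- if (g == 1) 1 else exp(theta[10])
      prm <- ising_params(om, tau, beta = beta)
      X <- as.matrix(d[d$wave == g, paste0("item_", 1:3)])
      ll <- ll + ising_loglik(X, prm)
    }
    -ll
  }
  best <- Inf
  withr::with_seed(13, {
    for (i in 1:10) {
      st <- stats::runif(10, -0.5, 0.5)
      val <- Inf
      for (cyc in 1:12) {     # restart NM until it stops improving
        o <- stats::optim(st, nll, method = "Nelder-Mead",
                          control = list(maxit = 5000, reltol = 1e-14))
        st <- o$par
        if (val - o$value < 1e-9) { val <- o$value; break }
        val <- o$value
      }
      best <- min(best, val)
    }
  })
  expect_lt(abs(-fit$loglik - best), 1e-6)
})

test_that("beta-free levels refuse a single group", {
  d <- generate_cohort(small_design(n = 100, seed = 9, betas = 1))
  expect_error(fit_ising_mg(d, mg_spec("equal_edges")), "unidentified")
  expect_s3_class(fit_ising_mg(d, mg_spec("equal_all")), "mg_fit")
})

test_that("near-zero edges with free beta trigger the identifiability warning", {
  om <- matrix(0, 3, 3)
  waves <- tibble::tibble(age = 10:11, n = 800, beta = c(1, 0.8))
  des <- cohort_design(om, waves, rep(-0.2, 3), seed = 10)
  d <- generate_cohort(des)
  expect_warning(fit_ising_mg(d, mg_spec("equal_edges")), "weakly identified")
})

test_that("pruning keeps the true edge and drops spurious ones", {
  # single strong edge among p = 5 items, 2 waves
  om <- matrix(0, 5, 5)
  om[1, 2] <- om[2, 1] <- 0.8
  waves <- tibble::tibble(age = 10:11, n = 4000, beta = c(1, 0.8))
  des <- cohort_design(om, waves, rep(-0.1, 5), seed = 20)
  d <- generate_cohort(des)
  fit <- fit_ising_mg(d, mg_spec("equal_edges", "sparse"))
  retained <- fit$spec$retained_edges
  # the true edge (1,2) is index 1 in the upper-tri ordering
  expect_true(retained[1])
  expect_lt(sum(retained[-1]), 3)
})

test_that("no edges are pruned when all effects are large", {
  om <- matrix(0.5, 4, 4); diag(om) <- 0
  waves <- tibble::tibble(age = 10:11, n = 4000, beta = c(1, 0.9))
  des <- cohort_design(om, waves, rep(0, 4), seed = 21)
  d <- generate_cohort(des)
  fit <- fit_ising_mg(d, mg_spec("equal_edges", "sparse"))
  expect_true(all(fit$spec$retained_edges))
})

test_that("false-positive edge retention stays near the nominal level", {
  # true graph: one strong edge; count spurious retained edges over seeds
  om <- matrix(0, 5, 5)
  om[1, 2] <- om[2, 1] <- 0.8
  waves <- tibble::tibble(age = 10:11, n = 4000, beta = c(1, 0.8))
  fp <- 0; total <- 0
  for (s in 1:20) {
    des <- cohort_design(om, waves, rep(-0.1, 5), seed = 300 + s)
    d <- generate_cohort(des)
    fit <- suppressWarnings(fit_ising_mg(d, mg_spec("equal_edges", "sparse")))
    fp <- fp + sum(fit$spec$retained_edges[-1])
    total <- total + 9
  }
  expect_lte(fp / total, 2 * 0.01 + 0.02)  # 2*alpha with Monte Carlo slack
})

test_that("bootstrap is reproducible and close to the analytic intervals", {
  d <- generate_cohort(recovery_design(1500, seed = 23))
  fit <- fit_ising_mg(d, mg_spec("equal_edges"))
  b1 <- bootstrap_beta(fit, B = 2, seed = 99)
  b2 <- bootstrap_beta(fit, B = 2, seed = 99)
  expect_identical(b1$intervals, b2$intervals)

  b3 <- bootstrap_beta(fit, B = 60, seed = 100)
  tr <- temperature_trajectory(fit, bootstrap = b3)
  aw <- (tr$ci_hi - tr$ci_lo)[-1]
  bw <- (tr$boot_hi - tr$boot_lo)[-1]
  expect_true(all(bw / aw < 2 & bw / aw > 0.5))
})
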