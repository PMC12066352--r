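# Temperature, entropy, connectivity, summaries, stratification.

test_that("temperature is the exact reciprocal of beta, wave 1 anchored", {
  d <- generate_cohort(recovery_design(1200, seed = 41))
  fit <- fit_ising_mg(d, mg_spec("equal_edges"))
  tr <- temperature_trajectory(fit)
  expect_identical(tr$temperature[1], 1)
  expect_equal(tr$temperature * tr$beta, rep(1, 4), tolerance = 1e-15)
  expect_true(all(tr$ci_lo <= tr$temperature & tr$temperature <= tr$ci_hi))
})

test_that("trajectory refuses specs without free beta", {
  d <- generate_cohort(recovery_design(300, seed = 42))
  fit <- fit_ising_mg(d, mg_spec("equal_all"))
  expect_error(temperature_trajectory(fit), "equal_edges")
})

test_that("entropy declines along a cooling trajectory with fixed thresholds", {
  om <- random_omega_fixed(6)
  waves <- tibble::tibble(age = 10:13, n = 2500,
                          beta = c(1, 1 / .85, 1 / .70, 1 / .60))
  des <- cohort_design(om, waves, rep(-0.2, 6), seed = 43)
  d <- generate_cohort(des)
  fit <- fit_ising_mg(d, mg_spec("equal_edges_thresholds"))
  tr <- temperature_trajectory(fit)
  expect_true(all(diff(tr$entropy_nats) < 0))
  # single source of truth: the trajectory entropy is gibbs_entropy
  expect_equal(tr$entropy_nats[2], gibbs_entropy(fit$params[[2]]))
})

test_that("symptom summaries count endorsed items on the 0/1 scale", {
  d <- tibble::tibble(id = 1:3, wave = 1, age = 10,
                      item_1 = c(-1, -1, -1), item_2 = c(-1, -1, -1))
  ss <- symptom_summary(d)
  expect_equal(ss$mean_score, 0)
  expect_equal(ss$sd_score, 0)

  d2 <- tibble::tibble(id = 1:2, wave = 1, age = 10,
                       item_1 = c(1, -1), item_2 = c(1, -1))
  ss2 <- symptom_summary(d2)
  expect_equal(ss2$mean_score, 1)
  expect_equal(ss2$sd_score, sqrt(2))

  big <- sample_ising(ising_params(0, rep(0, 6)), 40000, seed = 44)
  d3 <- dplyr::bind_cols(tibble::tibble(id = 1:40000, wave = 1, age = 10), big)
  expect_lt(abs(symptom_summary(d3)$mean_score - 3), 0.05)
})

test_that("connectivity scaling ratio equals beta exactly under shared edges", {
  d <- generate_cohort(recovery_design(1200, seed = 45))
  fit <- fit_ising_mg(d, mg_spec("equal_edges"))
  cs <- connectivity_scaling(fit)
  expect_lt(max(abs(cs$ratio - cs$beta)), 1e-10)
  expect_equal(cs$strength_scaled, cs$beta_x_strength_wave1,
               tolerance = 1e-10)

  # per-group edges: ratios need not equal beta, table still produced
  sat <- fit_ising_mg(d, mg_spec("saturated"))
  cs2 <- connectivity_scaling(sat)
  expect_equal(nrow(cs2), 4L)
})

test_that("interaction test: parallel lines, slope difference, label swap", {
  rows <- tibble::tibble(age = rep(10:13, 2),
                         stratum = rep(c("a", "b"), each = 4),
                         temperature = c(1, .9, .8, .7, 1.05, .95, .85, .75))
  it <- interaction_test(rows)
  expect_lt(abs(it$estimate), 1e-10)
  expect_equal(it$p.value, 1)

  withr::with_seed(46, {
    noise <- stats::rnorm(8, 0, 1e-7)
    rows2 <- rows
    rows2$temperature <- c(1, .9, .8, .7, 1, .89, .78, .67) + noise
  })
  it2 <- interaction_test(rows2)
  expect_equal(it2$estimate, -0.01, tolerance = 1e-4)
  expect_lt(it2$estimate, 0)

  rows3 <- rows2
  rows3$stratum <- rep(c("b", "a"), each = 4)
  expect_equal(interaction_test(rows3)$estimate, -it2$estimate,
               tolerance = 1e-12)
})

test_that("interaction test validates its input layout", {
  expect_error(interaction_test(tibble::tibble(
    age = c(10, 10), stratum = c("a", "b"), temperature = c(1, 1))),
    "two ages")
  expect_error(interaction_test(tibble::tibble(
    age = c(10, 11), stratum = c("a", "a"), temperature = c(1, 1))),
    "two strata")
  expect_error(interaction_test(tibble::tibble(
    age = c(10, 11, 10), stratum = c("a", "a", "b"),
    temperature = c(1, .9, 1))), "two or more ages")
})

test_that("stratified fits anchor each stratum at T = 1 and detect faster cooling", {
  om <- random_omega_fixed(5)
  waves_a <- tibble::tibble(age = 10:12, n = 3000, beta = c(1, 1 / .75, 1 / .55))
  waves_b <- tibble::tibble(age = 10:12, n = 3000, beta = c(1, 1 / .9, 1 / .85))
  da <- generate_cohort(cohort_design(om, waves_a, rep(-0.15, 5), seed = 47))
  db <- generate_cohort(cohort_design(om, waves_b, rep(-0.15, 5), seed = 48))
  d <- dplyr::bind_rows(dplyr::mutate(da, stratum = "A"),
                        dplyr::mutate(db, stratum = "B"))
  sf <- stratified_fit(d, spec = mg_spec("equal_edges"))
  expect_identical(sf$trajectories$A$temperature[1], 1)
  expect_identical(sf$trajectories$B$temperature[1], 1)
  expect_lt(sf$trajectories$A$temperature[3], sf$trajectories$B$temperature[3])
  expect_s3_class(sf$interaction, "tbl_df")
})

test_that("a single stratum reproduces the unstratified pipeline", {
  d <- generate_cohort(recovery_design(500, seed = 49))
  fit <- fit_ising_mg(d, mg_spec("equal_edges"))
  d$stratum <- "only"
  sf <- stratified_fit(d, spec = mg_spec("equal_edges"))
  expect_equal(sf$trajectories$only$beta, temperature_trajectory(fit)$beta,
               tolerance = 1e-8)
  expect_null(sf$interaction)
})

test_that("autoplot methods return ggplot objects", {
  d <- generate_cohort(recovery_design(400, seed = 50))
  fit <- fit_ising_mg(d, mg_spec("equal_edges"))
  tr <- temperature_trajectory(fit)
  expect_s3_class(autoplot(tr), "ggplot")
  sel <- suppressWarnings(select_model(d))
  expect_s3_class(autoplot(sel), "ggplot")
})
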