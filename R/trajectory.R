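#' Network temperature trajectory across measurement occasions
#'
#' Extracts the per-wave inverse temperature \eqn{\hat\beta_g} from a
#' fitted multigroup Ising model with free \eqn{\beta} and reports the
#' temperature \eqn{T_g = 1/\hat\beta_g} (wave 1 fixed at 1 for
#' identification), an analytic 95\% CI obtained by the delta method on
#' \eqn{\log\beta} and transformed to the T scale, the Gibbs entropy of
#' each wave's fitted distribution, the \eqn{\beta}-scaled global
#' strength, and the observed sum-score mean and variance. Temperatures
#' are relative to the first occasion; they are not absolute quantities
#' and must not be compared across independently identified fits.
#'
#' @param fit An `mg_fit` whose specification frees beta
#'   (`"equal_edges"` or `"equal_edges_thresholds"`).
#' @param bootstrap Optional [bootstrap_beta()] result on the same fit;
#'   its percentile intervals are merged in as `boot_lo`/`boot_hi`.
#' @param conf_level Confidence level for the analytic interval.
#' @return A tibble of class `temp_trajectory`, one row per wave:
#'   `wave, age, beta, temperature, ci_lo, ci_hi, boot_lo, boot_hi,
#'   entropy_nats, strength, mean_score, var_score`.
#' @examples
#' d <- generate_cohort(abcd_like_design(n_per_wave = 400, seed = 2))
#' fit <- fit_ising_mg(d, mg_spec("equal_edges"))
#' temperature_trajectory(fit)
#' @export
temperature_trajectory <- function(fit, bootstrap = NULL,
                                   conf_level = 0.95) {
  stopifnot(inherits(fit, "mg_fit"))
  if (!fit$parmap$free_beta) {
    stop("spec '", fit$spec$constraint, "' does not free beta; use ",
         "'equal_edges' or 'equal_edges_thresholds'")
  }
  pm <- fit$parmap
  G <- pm$G
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  betas <- beta_hat(fit)
  ci <- t(vapply(seq_len(G), function(g) {
    if (g == 1) return(c(1, 1))
    ib <- pm$idx_logbeta(g)
    se_lb <- fit$se[ib]
    lb <- fit$theta[ib]
    # T = exp(-log beta): monotone, so transform the log-beta interval
    c(exp(-(lb + z * se_lb)), exp(-(lb - z * se_lb)))
  }, numeric(2)))
  entropy <- vapply(fit$params, gibbs_entropy, 0)
  strength <- vapply(fit$params, global_strength, 0,
                     temperature_scaled = TRUE)
  out <- tibble::tibble(
    wave = fit$waves, age = fit$ages,
    beta = betas, temperature = 1 / betas,
    ci_lo = ci[, 1], ci_hi = ci[, 2],
    boot_lo = NA_real_, boot_hi = NA_real_,
    entropy_nats = entropy, strength = strength,
    mean_score = fit$panel_summary$mean_score,
    var_score = fit$panel_summary$var_score
  )
  if (!is.null(bootstrap)) {
    stopifnot(inherits(bootstrap, "beta_bootstrap"))
    out$boot_lo <- bootstrap$intervals$temp_lo
    out$boot_hi <- bootstrap$intervals$temp_hi
  }
  class(out) <- c("temp_trajectory", class(out))
  out
}

#' Per-wave symptom sum-score summaries
#'
#' Sums endorsed items per individual on the \{0, 1\} scale (regardless of
#' the internal encoding, so summaries match questionnaire conventions)
#' and reports the per-wave mean, standard deviation, and variance —
#' the observable symptom summaries against which temperature and entropy
#' trajectories are compared.
#'
#' @param data Long-format cohort data with complete item columns.
#' @param encoding Encoding of the item columns.
#' @return A tibble: `wave, age, n, mean_score, sd_score, var_score`.
#' @export
symptom_summary <- function(data, encoding = c("pm1", "zo")) {
  encoding <- match.arg(encoding)
  panels <- as_panels(data, encoding)
  panels_sumscore(panels, encoding)
}

#' Connectivity scaling by inverse temperature
#'
#' Under a shared edge matrix, the temperature-scaled global strength of
#' wave g equals \eqn{\beta_g} times the first wave's strength exactly
#' (the absolute-sum statistic is positively homogeneous), so the
#' per-wave ratio to wave 1 recovers \eqn{\beta_g}. With per-group edges
#' (saturated fits) the ratio generally differs from \eqn{\beta_g}; the
#' table is produced either way.
#'
#' @param fit An `mg_fit`.
#' @return A tibble: `wave, age, beta, strength_scaled,
#'   beta_x_strength_wave1, ratio`.
#' @export
connectivity_scaling <- function(fit) {
  stopifnot(inherits(fit, "mg_fit"))
  betas <- beta_hat(fit)
  scaled <- vapply(fit$params, global_strength, 0, temperature_scaled = TRUE)
  s1 <- global_strength(fit$params[[1]], temperature_scaled = FALSE)
  tibble::tibble(
    wave = fit$waves, age = fit$ages, beta = betas,
    strength_scaled = scaled,
    beta_x_strength_wave1 = betas * s1,
    ratio = scaled / s1
  )
}

#' Stratified temperature trajectories with an interaction test
#'
#' Fits the multigroup model independently within each stratum (each with
#' its own wave-1 identification, so trajectories are relative cooling
#' rates, not absolute temperatures) and tests whether the rate of
#' temperature change differs between strata via [interaction_test()].
#'
#' @param data Long-format cohort data with an additional stratum column.
#' @param stratum Name of the stratum column (default `"stratum"`).
#' @param spec An [mg_spec()] with free beta.
#' @return An object of class `stratified_fit`: list with `trajectories`
#'   (named list of [temperature_trajectory()] tibbles), `fits`, and
#'   `interaction` (tibble from [interaction_test()], `NULL` with a single
#'   stratum).
#' @export
stratified_fit <- function(data, stratum = "stratum", spec = mg_spec("equal_edges")) {
  data <- tibble::as_tibble(data)
  if (!stratum %in% names(data)) {
    stop("column '", stratum, "' not found in `data`")
  }
  labels <- data[[stratum]]
  if (anyNA(labels)) stop("every individual must carry a stratum label")
  cells <- table(labels, data$wave)
  if (any(cells == 0)) {
    stop("every stratum must be observed at every wave; empty cells: ",
         paste(which(cells == 0), collapse = ", "))
  }
  strata <- sort(unique(labels))
  fits <- purrr::map(strata, function(s) {
    fit_ising_mg(data[labels == s, setdiff(names(data), stratum)], spec)
  })
  names(fits) <- strata
  trajectories <- purrr::map(fits, temperature_trajectory)
  interaction <- NULL
  if (length(strata) >= 2) {
    rows <- purrr::imap_dfr(trajectories, function(tr, s) {
      tibble::tibble(age = tr$age, stratum = s, temperature = tr$temperature)
    })
    interaction <- interaction_test(rows)
  }
  structure(list(trajectories = trajectories, fits = fits,
                 interaction = interaction, strata = strata,
                 note = paste("temperatures are relative trajectories,",
                              "each anchored at 1 at the first wave;",
                              "absolute cross-stratum comparison is not",
                              "meaningful")),
            class = "stratified_fit")
}

#' @export
print.stratified_fit <- function(x, ...) {
  cat("<stratified_fit> strata:", paste(x$strata, collapse = ", "), "\n")
  for (s in x$strata) {
    cat("--", s, "\n")
    print(x$trajectories[[s]][, c("wave", "age", "beta", "temperature")])
  }
  if (!is.null(x$interaction)) {
    cat("-- age x stratum interaction\n")
    print(x$interaction)
  }
  invisible(x)
}

#' Age-by-stratum interaction on network temperature
#'
#' Fits a linear mixed-effects regression with temperature as the
#' outcome, age, stratum, and their interaction as fixed effects, and a
#' random intercept for age level, then reports the age-by-stratum
#' fixed effect with its two-sided p-value. With few age levels the
#' random-intercept variance is frequently estimated at zero (a singular
#' fit); that degenerate case reduces to ordinary least squares and is
#' handled by falling back to `lm()` whenever the mixed fit fails. Point
#' estimates of temperature enter unweighted (their uncertainties are not
#' propagated). When the fit is exactly saturated (zero residual
#' variance) the t statistic is 0/0; the convention here is p = 1 for a
#' numerically zero coefficient.
#'
#' @param data A data frame with columns `age` (numeric), `stratum`
#'   (2+ levels), `temperature`.
#' @return A tibble, one row per interaction term: `term, estimate,
#'   std.error, p.value, method`.
#' @export
interaction_test <- function(data) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("age", "stratum", "temperature") %in% names(data)))
  if (dplyr::n_distinct(data$age) < 2) stop("need at least two ages")
  if (dplyr::n_distinct(data$stratum) < 2) stop("need at least two strata")
  tab <- table(data$stratum, data$age)
  if (any(rowSums(tab > 0) < 2)) {
    stop("each stratum must be observed at two or more ages")
  }
  data$stratum <- factor(data$stratum)
  data$age_level <- factor(data$age)
  res <- tryCatch({
    m <- suppressMessages(suppressWarnings(
      lmerTest::lmer(temperature ~ age * stratum + (1 | age_level),
                     data = data,
                     control = lme4::lmerControl(check.conv.singular = "ignore"))
    ))
    co <- stats::coef(summary(m))
    list(co = co, method = "lmm")
  }, error = function(e) NULL)
  if (is.null(res)) {
    m <- stats::lm(temperature ~ age * stratum, data = data)
    co <- stats::coef(summary(m))
    res <- list(co = co, method = "ols")
  }
  co <- res$co
  rows <- grepl("^age:stratum", rownames(co))
  est <- co[rows, "Estimate"]
  se <- co[rows, "Std. Error"]
  pcol <- grep("^Pr\\(", colnames(co), value = TRUE)
  p <- if (length(pcol)) co[rows, pcol] else {
    2 * stats::pnorm(-abs(est / se))
  }
  p <- ifelse(is.finite(p), p, ifelse(abs(est) < 1e-10, 1, NA_real_))
  tibble::tibble(term = rownames(co)[rows], estimate = unname(est),
                 std.error = unname(se), p.value = unname(p),
                 method = res$method)
}
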