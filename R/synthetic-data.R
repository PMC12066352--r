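#' Design for a synthetic longitudinal symptom cohort
#'
#' Describes a cohort observed at several measurement occasions (waves):
#' a shared edge-weight matrix, wave-specific thresholds, and a
#' wave-specific inverse-temperature trajectory. The first wave's
#' \eqn{\beta} must equal 1, mirroring the identification convention of the
#' multigroup estimator (temperature is relative to the first occasion).
#'
#' @param omega Shared symmetric p x p edge-weight matrix.
#' @param waves A data frame with one row per wave and columns `age`
#'   (years), `n` (individuals), and `beta` (inverse temperature;
#'   `beta[1]` must be 1).
#' @param tau A waves x p matrix of thresholds (row g = wave g), or a
#'   length-p vector recycled across waves.
#' @param encoding `"pm1"` or `"zo"`.
#' @param seed Integer seed governing all sampling for this design.
#' @param item_names Optional item names.
#'
#' @return An object of class `cohort_design`.
#' @seealso [generate_cohort()], [abcd_like_design()]
#' @export
cohort_design <- function(omega, waves, tau, encoding = c("pm1", "zo"),
                          seed = 1L, item_names = NULL) {
  encoding <- match.arg(encoding)
  waves <- tibble::as_tibble(waves)
  stopifnot(all(c("age", "n", "beta") %in% names(waves)))
  waves$age <- as.numeric(waves$age)
  waves$n <- as.integer(waves$n)
  waves$beta <- as.numeric(waves$beta)
  G <- nrow(waves)
  if (G < 1) stop("at least one wave is required")
  if (any(waves$n < 1)) stop("all wave sizes must be >= 1")
  if (abs(waves$beta[1] - 1) > 0) {
    stop("beta of wave 1 must equal 1 (identification convention)")
  }
  if (any(waves$beta <= 0)) stop("all beta must be positive")
  if (is.null(dim(tau))) tau <- matrix(tau, G, length(tau), byrow = TRUE)
  p <- ncol(tau)
  if (nrow(tau) != G) stop("`tau` must have one row per wave")
  # validate omega/tau jointly through the parameter constructor
  pr <- ising_params(omega, tau[1, ], beta = 1, encoding = encoding,
                     item_names = item_names)
  structure(
    list(p = p, omega = pr$omega, tau = tau, waves = waves,
         encoding = encoding, seed = as.integer(seed),
         item_names = pr$item_names),
    class = "cohort_design"
  )
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("<cohort_design> ", x$p, " items, ", nrow(x$waves), " waves, encoding ",
      toupper(x$encoding), ", seed ", x$seed, "\n", sep = "")
  print(x$waves)
  invisible(x)
}

# dense edge structure used by the built-in designs: a positive chain of
# 0.3 over a weak 0.12 background, the qualitative shape of estimated
# emotional-symptom networks (all edges positive, neighbours strongest)
default_omega6 <- function() {
  p <- 6
  om <- matrix(0.12, p, p)
  om[cbind(1:5, 2:6)] <- 0.3
  om <- (om + t(om)) / 2
  diag(om) <- 0
  om
}

# wave-varying thresholds: an item profile (some symptoms rarer than
# others) plus a small upward drift across waves, so external fields
# genuinely change over time as in the best-fitting model class
default_tau <- function(G, p = 6) {
  base <- seq(-0.35, -0.15, length.out = p)
  drift <- seq(0, 0.25, length.out = G)
  outer(drift, base, `+`)
}

#' Built-in synthetic cohort designs
#'
#' `abcd_like_design()` is the default fixture: shaped like the smallest
#' cohort instrument modelled here (a six-item emotional-symptom
#' questionnaire administered across adolescence) — 8 waves at ages
#' 10--17, a dense positive edge structure shared across waves,
#' wave-varying thresholds (symptom endorsement drifts across
#' development), and an inverse temperature rising so that temperature
#' T = 1/beta declines linearly from 1 to 0.6: the cooling pattern the
#' estimator is meant to recover.
#'
#' `recovery_design()` is the compact 4-wave variant used for parameter
#' and selection recovery: p = 6 items, ages 10--13, the same edge
#' structure, wave-varying thresholds, and beta = (1, 0.85, 0.70, 0.60).
#'
#' @param n_per_wave Individuals per wave (defaults: 1500 and 5000).
#' @param seed Design seed.
#' @return A [cohort_design].
#' @export
abcd_like_design <- function(n_per_wave = 1500, seed = 1L) {
  ages <- 10:17
  G <- length(ages)
  t_traj <- seq(1, 0.6, length.out = G)
  waves <- tibble::tibble(age = ages, n = n_per_wave, beta = 1 / t_traj)
  cohort_design(default_omega6(), waves, default_tau(G), encoding = "pm1",
                seed = seed)
}

#' @rdname abcd_like_design
#' @export
recovery_design <- function(n_per_wave = 5000, seed = 1L) {
  waves <- tibble::tibble(age = 10:13, n = n_per_wave,
                          beta = c(1, 0.85, 0.70, 0.60))
  cohort_design(default_omega6(), waves, default_tau(4), encoding = "pm1",
                seed = seed)
}

#' Draw i.i.d. samples from a small-p Ising model
#'
#' Exact sampling by inverse CDF over the enumerated state distribution:
#' no burn-in or mixing concerns. Identical `(params, n, seed)` always
#' yield the identical panel.
#'
#' @param params An [ising_params] object with at most 20 items.
#' @param n Number of independent draws.
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @return A tibble with n rows and one column per item.
#' @export
sample_ising <- function(params, n, seed = NULL) {
  sd <- ising_state_distribution(params)
  p <- n_items(params)
  S <- as.matrix(sd[, seq_len(p)])
  cdf <- cumsum(sd$prob)
  cdf[length(cdf)] <- 1
  draw <- function() findInterval(stats::runif(n), cdf, left.open = TRUE) + 1L
  idx <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  out <- tibble::as_tibble(as.data.frame(S[idx, , drop = FALSE]))
  names(out) <- params$item_names
  out
}

#' Generate a longitudinal synthetic cohort
#'
#' One cross-sectional panel per wave, wave g drawn from
#' `ising_params(omega, tau[g, ], beta[g])`. Waves are sampled
#' independently (no within-person autocorrelation), matching the model
#' class the multigroup estimator fits: independent cross-sectional
#' networks tied by equality constraints.
#'
#' @param design A [cohort_design].
#' @return A long-format tibble with columns `id`, `wave`, `age`, and one
#'   column per item. `id` is unique within wave.
#' @examples
#' d <- abcd_like_design(n_per_wave = 50)
#' cohort <- generate_cohort(d)
#' dplyr::count(cohort, wave, age)
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  G <- nrow(design$waves)
  purrr::map_dfr(seq_len(G), function(g) {
    pr <- ising_params(design$omega, design$tau[g, ],
                       beta = design$waves$beta[g],
                       encoding = design$encoding,
                       item_names = design$item_names)
    panel <- sample_ising(pr, design$waves$n[g],
                          seed = design$seed + 1000L * g)
    dplyr::bind_cols(
      tibble::tibble(id = seq_len(nrow(panel)),
                     wave = g, age = design$waves$age[g]),
      panel
    )
  })
}

#' Mask cells completely at random
#'
#' Each item cell is independently set to `NA` with probability `rate`;
#' the mask is reproducible by seed. Intended for exercising the
#' missing-data policies of the readers — the estimator itself requires
#' complete panels.
#'
#' @param data A cohort tibble as produced by [generate_cohort()] (item
#'   columns are every column except `id`, `wave`, `age`), or any data
#'   frame of item columns only.
#' @param rate Masking probability in `[0, 1)`.
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @return `data` with masked cells set to `NA`.
#' @export
inject_mcar <- function(data, rate, seed = NULL) {
  if (!is.numeric(rate) || length(rate) != 1 || rate < 0 || rate >= 1) {
    stop("`rate` must be a single value in [0, 1)")
  }
  if (rate == 0) return(data)
  item_cols <- setdiff(names(data), c("id", "wave", "age"))
  nc <- nrow(data) * length(item_cols)
  draw <- function() stats::runif(nc) < rate
  mask <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  m <- matrix(mask, nrow(data), length(item_cols))
  for (j in seq_along(item_cols)) {
    data[[item_cols[j]]][m[, j]] <- NA
  }
  data
}

# Split a long cohort tibble into per-wave matrices.
# Returns a list of list(X, wave, age, n); waves ordered by ascending age
# unless order_by_age = FALSE (then by wave index).
as_panels <- function(data, encoding, order_by_age = TRUE) {
  data <- tibble::as_tibble(data)
  need <- c("wave", "age")
  if (!all(need %in% names(data))) {
    stop("long data must have `wave` and `age` columns")
  }
  item_cols <- setdiff(names(data), c("id", "wave", "age", "stratum"))
  if (length(item_cols) == 0) stop("no item columns found")
  info <- dplyr::distinct(data, .data$wave, .data$age)
  if (anyDuplicated(info$wave)) stop("each wave must have a single age")
  info <- if (order_by_age) dplyr::arrange(info, .data$age, .data$wave)
          else dplyr::arrange(info, .data$wave)
  panels <- purrr::map(seq_len(nrow(info)), function(g) {
    rows <- data[data$wave == info$wave[g], item_cols, drop = FALSE]
    X <- as.matrix(rows)
    if (anyNA(X)) {
      stop("wave ", info$wave[g], " contains missing values; the estimator ",
           "requires complete panels (see read_symptom_csv missing policies)")
    }
    check_state_alphabet(X, encoding)
    list(X = X, wave = info$wave[g], age = info$age[g], n = nrow(X))
  })
  attr(panels, "item_names") <- item_cols
  panels
}
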