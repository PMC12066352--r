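#' Ising model parameters for one group / measurement occasion
#'
#' Bundles the symmetric edge-weight matrix \eqn{\Omega}, the threshold
#' (external field) vector \eqn{\tau}, and the inverse temperature
#' \eqn{\beta} of a binary Markov random field
#' \deqn{P(X = x) = \exp\{-\beta H(x)\} / Z,}
#' where the potential is \eqn{H(x) = -(\tau^\top x + \tfrac12 x^\top \Omega x)}
#' so that positive thresholds favour endorsement and positive edges favour
#' alignment of connected symptoms. The Boltzmann constant is absorbed
#' (set to 1), so temperature is exactly \eqn{T = 1/\beta}.
#'
#' @param omega Symmetric p x p numeric matrix with zero diagonal (edge
#'   weights, unitless). A scalar 0 is expanded to a zero matrix of size
#'   `length(tau)`.
#' @param tau Numeric vector of length p (thresholds / external fields).
#' @param beta Positive scalar inverse temperature. Default 1.
#' @param encoding Node-state alphabet: `"pm1"` for \{-1, +1\} (the primary
#'   encoding) or `"zo"` for \{0, 1\} (present/absent).
#' @param item_names Optional character vector of item names.
#'
#' @return An object of class `ising_params`.
#' @examples
#' ising_params(omega = matrix(c(0, .5, .5, 0), 2), tau = c(0, 0), beta = 2)
#' @export
ising_params <- function(omega, tau, beta = 1, encoding = c("pm1", "zo"),
                         item_names = NULL) {
  encoding <- match.arg(encoding)
  tau <- as.numeric(tau)
  p <- length(tau)
  if (p < 1) stop("at least one item is required (length(tau) >= 1)")
  if (is.null(dim(omega)) && length(omega) == 1 && omega == 0) {
    omega <- matrix(0, p, p)
  }
  omega <- as.matrix(omega)
  if (!all(dim(omega) == c(p, p))) {
    stop("`omega` must be ", p, " x ", p, " to match length(tau)")
  }
  if (max(abs(omega - t(omega))) > 1e-12) stop("`omega` must be symmetric")
  if (any(diag(omega) != 0)) stop("`omega` must have a zero diagonal")
  if (!is.numeric(beta) || length(beta) != 1 || !is.finite(beta) || beta <= 0) {
    stop("`beta` must be a positive finite scalar")
  }
  if (is.null(item_names)) item_names <- paste0("item_", seq_len(p))
  structure(
    list(omega = omega, tau = tau, beta = beta, encoding = encoding,
         item_names = item_names),
    class = "ising_params"
  )
}

#' @export
print.ising_params <- function(x, ...) {
  p <- length(x$tau)
  cat("<ising_params> ", p, " items, encoding ", toupper(x$encoding),
      ", beta = ", format(x$beta), " (T = ", format(1 / x$beta), ")\n", sep = "")
  cat("  tau:   ", paste(format(round(x$tau, 3)), collapse = " "), "\n")
  cat("  |omega| edge sum: ", format(sum(abs(x$omega[upper.tri(x$omega)]))), "\n")
  invisible(x)
}

n_items <- function(params) length(params$tau)

#' @method tidy ising_params
#' @export
tidy.ising_params <- function(x, ...) {
  p <- n_items(x)
  ut <- which(upper.tri(x$omega), arr.ind = TRUE)
  edges <- tibble::tibble(
    term = paste0("omega[", x$item_names[ut[, 1]], ",", x$item_names[ut[, 2]], "]"),
    type = "edge", estimate = x$omega[ut]
  )
  thr <- tibble::tibble(
    term = paste0("tau[", x$item_names, "]"), type = "threshold",
    estimate = x$tau
  )
  dplyr::bind_rows(
    edges, thr,
    tibble::tibble(term = "beta", type = "inverse_temperature", estimate = x$beta)
  )
}

# alphabet for an encoding, low state first
encoding_alphabet <- function(encoding) {
  switch(encoding, pm1 = c(-1, 1), zo = c(0, 1),
         stop("unknown encoding: ", encoding))
}

# Hard cap on exact enumeration: 2^20 states. The instruments modelled here
# have 5-13 items, all enumerable; no approximate partition function exists
# in this package.
ENUM_LIMIT <- 20L

check_enum_limit <- function(p) {
  if (p > ENUM_LIMIT) {
    stop("exact enumeration is limited to p <= ", ENUM_LIMIT,
         " items (requested p = ", p, "); no approximate partition ",
         "function is implemented")
  }
}

# All 2^p configurations as a (2^p x p) matrix over the encoding alphabet.
# Column 1 varies slowest so that row order is the binary counting order.
# Cached per (p, encoding) within a session.
.state_cache <- new.env(parent = emptyenv())

state_matrix <- function(p, encoding) {
  check_enum_limit(p)
  key <- paste0(encoding, p)
  if (!is.null(.state_cache[[key]])) return(.state_cache[[key]])
  alpha <- encoding_alphabet(encoding)
  grid <- as.matrix(expand.grid(rep(list(alpha), p))[, p:1, drop = FALSE])
  dimnames(grid) <- NULL
  .state_cache[[key]] <- grid
  grid
}

check_state_alphabet <- function(x, encoding) {
  alpha <- encoding_alphabet(encoding)
  bad <- setdiff(unique(as.vector(x)), alpha)
  if (length(bad) > 0) {
    stop("state values ", paste(bad, collapse = ", "),
         " are outside the ", toupper(encoding), " alphabet {",
         paste(alpha, collapse = ", "), "}")
  }
  invisible(TRUE)
}

#' Configuration energy (Hamiltonian)
#'
#' Computes \eqn{H(x) = -(\tau^\top x + \frac12 x^\top \Omega x)} for one or
#' several configurations. Lower energy means higher probability.
#'
#' @param x A length-p state vector, or an n x p matrix / data frame of
#'   states (one configuration per row), over the alphabet of
#'   `params$encoding`.
#' @param params An [ising_params] object.
#' @return A numeric vector of energies, one per configuration.
#' @examples
#' pr <- ising_params(matrix(c(0, 1, 1, 0), 2), tau = c(0, 0))
#' ising_hamiltonian(c(1, 1), pr)   # -1: aligned, low energy
#' ising_hamiltonian(c(1, -1), pr)  # +1
#' @export
ising_hamiltonian <- function(x, params) {
  stopifnot(inherits(params, "ising_params"))
  p <- n_items(params)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) {
    if (length(x) != p) stop("state vector has length ", length(x),
                             " but the model has p = ", p, " items")
    x <- matrix(x, nrow = 1)
  }
  if (ncol(x) != p) stop("state matrix has ", ncol(x),
                         " columns but the model has p = ", p, " items")
  check_state_alphabet(x, params$encoding)
  -(drop(x %*% params$tau) + 0.5 * rowSums((x %*% params$omega) * x))
}

#' Exact state distribution of a small-p Ising model
#'
#' Enumerates all \eqn{2^p} configurations and returns their Boltzmann
#' probabilities \eqn{P(x) = \exp\{-\beta H(x)\}/Z}. The log partition
#' function is computed with log-sum-exp so it stays finite for large
#' \eqn{|\beta H|}.
#'
#' @param params An [ising_params] object with at most 20 items.
#' @return A tibble with one row per configuration: the item columns, the
#'   energy, and the probability; the log partition function is attached as
#'   attribute `"logZ"` (also retrievable with [log_partition()]).
#' @examples
#' sd <- ising_state_distribution(ising_params(0, tau = c(0, 0, 0)))
#' all.equal(sd$prob, rep(1/8, 8))   # uniform at zero coupling
#' @export
ising_state_distribution <- function(params) {
  stopifnot(inherits(params, "ising_params"))
  if (!all(is.finite(params$omega)) || !all(is.finite(params$tau))) {
    stop("non-finite parameters")
  }
  p <- n_items(params)
  S <- state_matrix(p, params$encoding)
  H <- -(drop(S %*% params$tau) + 0.5 * rowSums((S %*% params$omega) * S))
  lp <- -params$beta * H
  m <- max(lp)
  logZ <- m + log(sum(exp(lp - m)))
  out <- tibble::as_tibble(as.data.frame(S))
  names(out) <- params$item_names
  out$energy <- H
  out$prob <- exp(lp - logZ)
  attr(out, "logZ") <- logZ
  out
}

#' @rdname ising_state_distribution
#' @export
log_partition <- function(params) {
  attr(ising_state_distribution(params), "logZ")
}

#' Log-likelihood of a binary panel under an Ising model
#'
#' Computed through sufficient statistics (per-item sums and the pairwise
#' cross-product matrix), so the cost after one pass over the data is
#' independent of n:
#' \deqn{\ell = \beta\,(\tau^\top s + \textstyle\sum_{i<j}\omega_{ij} c_{ij}) - n \log Z.}
#' This equals the direct per-row sum of log probabilities.
#'
#' @param data An n x p matrix or data frame of states over the alphabet of
#'   `params$encoding` (item columns only), with no missing entries.
#' @param params An [ising_params] object.
#' @return The log-likelihood (a scalar).
#' @export
ising_loglik <- function(data, params) {
  stopifnot(inherits(params, "ising_params"))
  X <- as.matrix(data)
  if (anyNA(X)) {
    stop("panel contains missing values; use read_symptom_csv(..., ",
         "missing = \"listwise\") or inject_mcar-free data")
  }
  if (ncol(X) != n_items(params)) {
    stop("panel has ", ncol(X), " items but the model has ", n_items(params))
  }
  check_state_alphabet(X, params$encoding)
  ss <- panel_suffstats(X)
  logZ <- log_partition(params)
  params$beta * suffstat_energy(ss, params$omega, params$tau) -
    nrow(X) * logZ
}

# sufficient statistics of a panel: n, per-item sums s, upper-triangle
# cross-product sums C (full p x p matrix, only i<j used)
panel_suffstats <- function(X) {
  list(n = nrow(X), s = colSums(X), C = crossprod(X))
}

# sum over observations of -H(x) expressed through sufficient statistics
suffstat_energy <- function(ss, omega, tau) {
  sum(tau * ss$s) + 0.5 * sum(omega * ss$C)
}

#' Gibbs entropy of an Ising model (nats)
#'
#' \eqn{S = -\sum_x P(x) \log P(x)} over the full configuration
#' enumeration. Maximal, \eqn{p \log 2}, in the infinite-temperature limit
#' \eqn{\beta \to 0}; non-increasing in \eqn{\beta} at fixed
#' \eqn{(\Omega, \tau)} since \eqn{dS/d\beta = -\beta\,\mathrm{Var}(H)}.
#'
#' @param params An [ising_params] object with at most 20 items.
#' @param base Logarithm base; the default `exp(1)` gives nats, `2` gives
#'   bits (a display conversion only).
#' @return Entropy (scalar, >= 0).
#' @export
gibbs_entropy <- function(params, base = exp(1)) {
  sd <- ising_state_distribution(params)
  pr <- sd$prob[sd$prob > 0]
  -sum(pr * log(pr)) / log(base)
}

#' Transform parameters between the \{-1,+1\} and \{0,1\} encodings
#'
#' Returns parameters defining the identical distribution on relabelled
#' states. For PM1 -> ZO: \eqn{\omega' = 4\omega},
#' \eqn{\tau'_i = 2\tau_i - 2\sum_{j \ne i} \omega_{ij}} (an additive
#' constant is absorbed into the partition function); \eqn{\beta} is
#' unchanged. The round trip is the identity.
#'
#' @param params An [ising_params] object.
#' @param to Target encoding, `"pm1"` or `"zo"`; must differ from
#'   `params$encoding`.
#' @return An [ising_params] object in the target encoding.
#' @export
encode_params <- function(params, to = c("zo", "pm1")) {
  stopifnot(inherits(params, "ising_params"))
  to <- match.arg(to)
  if (to == params$encoding) {
    stop("parameters are already in the ", toupper(to), " encoding")
  }
  om <- params$omega
  tau <- params$tau
  if (params$encoding == "pm1") {       # x = 2y - 1
    om2 <- 4 * om
    tau2 <- 2 * tau - 2 * rowSums(om)
  } else {                              # y = (x + 1) / 2
    om2 <- om / 4
    tau2 <- tau / 2 + rowSums(om) / 4
  }
  ising_params(om2, tau2, beta = params$beta, encoding = to,
               item_names = params$item_names)
}

#' Global strength (connectivity) of an Ising network
#'
#' Sum of absolute edge weights \eqn{\sum_{i<j} |\omega_{ij}|}; with
#' `temperature_scaled = TRUE` the effective, \eqn{\beta}-scaled weights
#' \eqn{\sum_{i<j} |\beta\,\omega_{ij}|} are summed, so the scaled/unscaled
#' ratio equals \eqn{\beta} exactly.
#'
#' @param params An [ising_params] object.
#' @param temperature_scaled Scale edges by the inverse temperature first?
#' @return The global strength (scalar).
#' @export
global_strength <- function(params, temperature_scaled = FALSE) {
  stopifnot(inherits(params, "ising_params"))
  s <- sum(abs(params$omega[upper.tri(params$omega)]))
  if (temperature_scaled) params$beta * s else s
}
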