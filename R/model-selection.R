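#' Fit indices for a constrained model against the saturated reference
#'
#' The saturated dense model (all parameters free per group) has zero
#' degrees of freedom and serves as the reference, as in structural
#' equation modelling. Returned indices:
#' \itemize{
#'   \item AIC \eqn{= -2\ell + 2k} and BIC \eqn{= -2\ell + k\log N}, with
#'     \eqn{N} the pooled number of individuals across waves;
#'   \item \eqn{\chi^2 = 2(\ell_{sat} - \ell_{model})} on
#'     \eqn{df = k_{sat} - k_{model}} with its survival-function p-value;
#'   \item RMSEA \eqn{= \sqrt{\max(\chi^2 - df, 0) / (df\,(N - 1))}}
#'     (single-population form, pooled N; 0 when df = 0).
#' }
#'
#' @param fit An `mg_fit` for the model of interest.
#' @param saturated The saturated dense `mg_fit` on the same data.
#' @return A one-row tibble of class `fit_indices`.
#' @export
fit_indices <- function(fit, saturated) {
  stopifnot(inherits(fit, "mg_fit"), inherits(saturated, "mg_fit"))
  if (saturated$spec$constraint != "saturated" ||
      !all(saturated$spec$retained_edges)) {
    stop("`saturated` must be the dense saturated fit")
  }
  if (max(abs(fit$fingerprint - saturated$fingerprint)) > 1e-6) {
    stop("`fit` and `saturated` were not fitted to the same data")
  }
  n <- fit$n_total
  chisq <- max(2 * (saturated$loglik - fit$loglik), 0)
  df <- saturated$k - fit$k
  if (df < 0) stop("model has more free parameters than the saturated fit")
  p <- if (df == 0) NA_real_ else stats::pchisq(chisq, df, lower.tail = FALSE)
  rmsea <- if (df == 0) 0 else sqrt(max(chisq - df, 0) / (df * (n - 1)))
  out <- tibble::tibble(
    aic = -2 * fit$loglik + 2 * fit$k,
    bic = -2 * fit$loglik + fit$k * log(n),
    chisq = chisq, df = df, p_chisq = p, rmsea = rmsea
  )
  class(out) <- c("fit_indices", class(out))
  out
}

# rank of a constraint level in the nesting chain (higher = more restricted)
constraint_rank <- function(constraint) {
  match(constraint, c("saturated", "equal_edges", "equal_edges_thresholds",
                      "equal_all"))
}

#' Likelihood-ratio test between nested multigroup fits
#'
#' The restricted model's tied-parameter map must be a superset of the
#' general model's (a later constraint level, and/or a retained-edge set
#' contained in the general one). Returns the LR statistic
#' \eqn{2(\ell_{general} - \ell_{restricted})}, the difference in free
#' parameters, and the chi-squared p-value.
#'
#' @param fit_restricted,fit_general Nested `mg_fit` objects on the same
#'   data.
#' @return A one-row tibble: `lr_stat`, `df_diff`, `p.value`.
#' @export
nested_compare <- function(fit_restricted, fit_general) {
  stopifnot(inherits(fit_restricted, "mg_fit"), inherits(fit_general, "mg_fit"))
  if (max(abs(fit_restricted$fingerprint - fit_general$fingerprint)) > 1e-6) {
    stop("fits were not produced from the same data")
  }
  r_rank <- constraint_rank(fit_restricted$spec$constraint)
  g_rank <- constraint_rank(fit_general$spec$constraint)
  edge_sub <- all(fit_general$spec$retained_edges |
                    !fit_restricted$spec$retained_edges)
  if (r_rank < g_rank || !edge_sub || fit_restricted$k > fit_general$k) {
    stop("`fit_restricted` is not nested in `fit_general`")
  }
  lr <- max(2 * (fit_general$loglik - fit_restricted$loglik), 0)
  df <- fit_general$k - fit_restricted$k
  p <- if (df == 0) 1 else stats::pchisq(lr, df, lower.tail = FALSE)
  tibble::tibble(lr_stat = lr, df_diff = df, p.value = p)
}

#' Fit the full model-selection grid and choose the best model
#'
#' Fits all four constraint levels crossed with dense and sparse
#' structures — eight models per cohort when there are two or more waves
#' (with a single wave only the two saturated structures are estimable,
#' since freeing beta requires a second occasion). The chosen model is the
#' one with the lowest BIC among converged models with RMSEA below
#' `rmsea_cutoff`; if none passes, the lowest-BIC converged model is
#' chosen and flagged (`rmsea_pass = FALSE`). The full table is always
#' returned so other selection rules can be applied.
#'
#' @param data Long-format cohort data (see [fit_ising_mg()]).
#' @param encoding Data encoding, `"pm1"` or `"zo"`.
#' @param sparse_alpha Pruning significance level for the sparse fits.
#' @param rmsea_cutoff RMSEA admissibility threshold (default 0.05).
#' @return An object of class `mg_selection`: list with `table` (one row
#'   per model), `fits`, `chosen` (the winning `mg_fit`), `chosen_spec`,
#'   `rmsea_pass`.
#' @export
select_model <- function(data, encoding = c("pm1", "zo"),
                         sparse_alpha = 0.01, rmsea_cutoff = 0.05) {
  encoding <- match.arg(encoding)
  G <- dplyr::n_distinct(tibble::as_tibble(data)$wave)
  levels <- if (G >= 2) {
    c("saturated", "equal_edges", "equal_edges_thresholds", "equal_all")
  } else "saturated"
  grid <- tidyr::expand_grid(constraint = levels,
                             structure = c("dense", "sparse"))
  fits <- purrr::pmap(grid, function(constraint, structure) {
    fit_ising_mg(data, mg_spec(constraint, structure,
                               sparse_alpha = sparse_alpha,
                               encoding = encoding))
  })
  saturated <- fits[[which(grid$constraint == "saturated" &
                             grid$structure == "dense")]]
  table <- purrr::imap_dfr(fits, function(f, i) {
    dplyr::bind_cols(
      tibble::tibble(model = grid$constraint[i],
                     structure = grid$structure[i],
                     k = f$k, loglik = f$loglik,
                     edges_retained = sum(f$spec$retained_edges)),
      fit_indices(f, saturated),
      tibble::tibble(converged = f$converged)
    )
  })
  eligible <- which(table$converged & table$rmsea < rmsea_cutoff)
  rmsea_pass <- length(eligible) > 0
  if (!rmsea_pass) {
    eligible <- which(table$converged)
    if (length(eligible) == 0) stop("no model converged")
    warning("no converged model attains RMSEA < ", rmsea_cutoff,
            "; choosing the lowest-BIC model overall")
  }
  chosen_i <- eligible[which.min(table$bic[eligible])]
  table$chosen <- seq_len(nrow(table)) == chosen_i
  structure(
    list(table = table, fits = fits, chosen = fits[[chosen_i]],
         chosen_spec = fits[[chosen_i]]$spec, rmsea_pass = rmsea_pass,
         rmsea_cutoff = rmsea_cutoff),
    class = "mg_selection"
  )
}

#' @export
print.mg_selection <- function(x, ...) {
  cat("<mg_selection> ", nrow(x$table), " models fitted; chosen: ",
      x$chosen$spec$constraint, " / ", x$chosen$spec$structure,
      if (!x$rmsea_pass) "  [no model passed the RMSEA cutoff]", "\n",
      sep = "")
  print(x$table)
  invisible(x)
}

#' @method tidy mg_selection
#' @export
tidy.mg_selection <- function(x, ...) x$table

#' @method glance mg_selection
#' @export
glance.mg_selection <- function(x, ...) {
  tibble::tibble(
    n_models = nrow(x$table),
    chosen_model = x$chosen$spec$constraint,
    chosen_structure = x$chosen$spec$structure,
    chosen_bic = x$table$bic[x$table$chosen],
    chosen_rmsea = x$table$rmsea[x$table$chosen],
    rmsea_pass = x$rmsea_pass
  )
}
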