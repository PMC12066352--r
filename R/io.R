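#' Read binarized symptom panels from CSV
#'
#' Two layouts are supported. `"long"`: one file with columns `id`,
#' `wave`, `age`, and `item_*` columns. `"wide"`: one file per wave (item
#' columns only, or with an `id` column), with `ages` supplying one age
#' per file; waves are numbered in file order. Item values are validated
#' against the declared encoding alphabet. Missing cells are handled by
#' policy: `"error"` aborts naming the first offending row/column;
#' `"listwise"` drops incomplete rows wave by wave (the complete-cases
#' path) and reports the counts via message and the `"dropped"`
#' attribute.
#'
#' @param path File path (long layout) or character vector of per-wave
#'   file paths (wide layout).
#' @param layout `"long"` or `"wide"`.
#' @param encoding Expected alphabet, `"pm1"` (\{-1, 1\}) or `"zo"`
#'   (\{0, 1\}).
#' @param missing `"error"` or `"listwise"`.
#' @param ages Numeric vector of ages, required for the wide layout.
#' @param likert_recode If `TRUE`, 3-level inputs coded 0/1/2 ("not
#'   true" / "sometimes" / "true") are first collapsed to binary with
#'   "sometimes" subsumed into "true" (0 -> absent, 1 and 2 -> present),
#'   then mapped onto the requested encoding.
#' @return A long-format tibble (`id`, `wave`, `age`, item columns) with
#'   attribute `"dropped"` (per-wave listwise-deletion counts).
#' @export
read_symptom_csv <- function(path, layout = c("long", "wide"),
                             encoding = c("pm1", "zo"),
                             missing = c("error", "listwise"),
                             ages = NULL, likert_recode = FALSE) {
  layout <- match.arg(layout)
  encoding <- match.arg(encoding)
  missing <- match.arg(missing)
  if (layout == "long") {
    data <- readr::read_csv(path, show_col_types = FALSE)
    need <- c("id", "wave", "age")
    if (!all(need %in% names(data))) {
      stop("long layout requires columns id, wave, age")
    }
  } else {
    if (is.null(ages) || length(ages) != length(path)) {
      stop("wide layout needs one age per file")
    }
    data <- purrr::map_dfr(seq_along(path), function(g) {
      d <- readr::read_csv(path[g], show_col_types = FALSE)
      if (!"id" %in% names(d)) d <- dplyr::bind_cols(tibble::tibble(id = seq_len(nrow(d))), d)
      dplyr::bind_cols(d["id"], tibble::tibble(wave = g, age = ages[g]),
                       d[setdiff(names(d), "id")])
    })
  }
  item_cols <- setdiff(names(data), c("id", "wave", "age"))
  if (length(item_cols) == 0) stop("no item columns found")
  items_per_wave <- dplyr::summarise(
    dplyr::group_by(data, .data$wave),
    any_all_na = any(vapply(dplyr::pick(dplyr::everything()),
                            function(col) all(is.na(col)), TRUE))
  )
  if (any(items_per_wave$any_all_na)) {
    stop("inconsistent item sets across waves (an item is entirely ",
         "missing in some wave)")
  }
  if (likert_recode) data <- recode_likert(data, encoding)
  alpha <- encoding_alphabet(encoding)
  for (col in item_cols) {
    bad <- !is.na(data[[col]]) & !(data[[col]] %in% alpha)
    if (any(bad)) {
      stop("column '", col, "' row ", which(bad)[1], " has value \"",
           data[[col]][which(bad)[1]], "\" outside the ", toupper(encoding),
           " alphabet {", paste(alpha, collapse = ", "), "}")
    }
  }
  dropped <- tibble::tibble(wave = integer(0), dropped = integer(0))
  incomplete <- !stats::complete.cases(data[item_cols])
  if (any(incomplete)) {
    if (missing == "error") {
      i <- which(incomplete)[1]
      j <- item_cols[which(is.na(data[i, item_cols]))[1]]
      stop("missing cell at row ", i, ", column '", j, "' (wave ",
           data$wave[i], "); use missing = \"listwise\" to drop ",
           "incomplete rows")
    }
    dropped <- dplyr::count(data[incomplete, ], .data$wave, name = "dropped")
    message("listwise deletion dropped ",
            paste0(dropped$dropped, " row(s) in wave ", dropped$wave,
                   collapse = "; "))
    data <- data[!incomplete, ]
    empty <- setdiff(unique(c(dropped$wave)), unique(data$wave))
    if (length(empty)) {
      stop("wave ", paste(empty, collapse = ", "),
           " is empty after listwise deletion")
    }
  }
  attr(data, "dropped") <- dropped
  data
}

#' Collapse 3-level Likert items to binary
#'
#' Maps \{0 = not true, 1 = sometimes, 2 = true\} to absent/present with
#' "sometimes" subsumed into "true", then onto the requested encoding
#' (absent -> -1 or 0; present -> 1).
#'
#' @param data Long-format data with item columns coded 0/1/2.
#' @param encoding Target alphabet.
#' @return `data` with item columns recoded.
#' @export
recode_likert <- function(data, encoding = c("pm1", "zo")) {
  encoding <- match.arg(encoding)
  item_cols <- setdiff(names(data), c("id", "wave", "age", "stratum"))
  low <- encoding_alphabet(encoding)[1]
  for (col in item_cols) {
    v <- data[[col]]
    bad <- !is.na(v) & !(v %in% 0:2)
    if (any(bad)) {
      stop("column '", col, "' has non-Likert value \"",
           v[which(bad)[1]], "\" (expected 0, 1, 2)")
    }
    data[[col]] <- ifelse(is.na(v), NA_real_, ifelse(v == 0, low, 1))
  }
  data
}

#' Write a long-format cohort to CSV
#'
#' @param data Long cohort tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_symptom_csv <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data), path)
  invisible(path)
}

#' Read/write a cohort design as YAML or JSON
#'
#' Serializes a [cohort_design()] with keys `p`, `encoding`, `seed`,
#' `item_names`, `omega` (row-major list), and `waves` (list of
#' \{age, n, tau, beta\}). Format is chosen by file extension
#' (`.yaml`/`.yml` vs `.json`).
#'
#' @param design A `cohort_design`.
#' @param path File path.
#' @return For `write_design`: `path`, invisibly. For `read_design`: a
#'   `cohort_design`.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "cohort_design"))
  obj <- list(
    p = design$p, encoding = design$encoding, seed = design$seed,
    item_names = design$item_names,
    omega = apply(design$omega, 1, as.numeric, simplify = FALSE),
    waves = purrr::map(seq_len(nrow(design$waves)), function(g) {
      list(age = design$waves$age[g], n = design$waves$n[g],
           tau = as.numeric(design$tau[g, ]), beta = design$waves$beta[g])
    })
  )
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path)
  }
  omega <- do.call(rbind, lapply(obj$omega, function(r) as.numeric(unlist(r))))
  waves <- purrr::map_dfr(obj$waves, function(w) {
    tibble::tibble(age = as.numeric(w$age), n = as.numeric(w$n),
                   beta = as.numeric(w$beta))
  })
  tau <- do.call(rbind,
                 purrr::map(obj$waves, function(w) as.numeric(unlist(w$tau))))
  cohort_design(omega, waves, tau, encoding = obj$encoding,
                seed = obj$seed,
                item_names = as.character(unlist(obj$item_names)))
}

fmt_num <- function(x) {
  ifelse(is.na(x), NA_character_, formatC(x, digits = 10, format = "g"))
}

# write a tibble as CSV with numerics at 10 significant digits so reruns
# with the same seed are byte-identical
write_csv10 <- function(tb, path) {
  tb <- dplyr::mutate(tb, dplyr::across(dplyr::where(is.numeric), fmt_num))
  readr::write_csv(tb, path, na = "")
  invisible(path)
}

edge_list <- function(fit) {
  purrr::imap_dfr(fit$params, function(pr, g) {
    ei <- edge_index(length(pr$tau))
    keep <- fit$spec$retained_edges
    ei <- ei[keep, , drop = FALSE]
    tibble::tibble(wave = fit$waves[g], i = ei[, 1], j = ei[, 2],
                   item_i = pr$item_names[ei[, 1]],
                   item_j = pr$item_names[ei[, 2]],
                   weight = pr$omega[ei])
  })
}

fit_to_list <- function(fit) {
  list(
    spec = list(constraint = fit$spec$constraint,
                structure = fit$spec$structure,
                sparse_alpha = fit$spec$sparse_alpha,
                encoding = fit$spec$encoding,
                retained_edges = as.integer(which(fit$spec$retained_edges))),
    loglik = fit$loglik, k = fit$k, n_total = fit$n_total,
    n_per_wave = as.integer(fit$n_g),
    waves = as.integer(fit$waves), ages = fit$ages,
    item_names = fit$item_names,
    groups = purrr::imap(fit$params, function(pr, g) {
      list(wave = fit$waves[g], age = fit$ages[g], beta = pr$beta,
           tau = pr$tau,
           omega = apply(pr$omega, 1, as.numeric, simplify = FALSE))
    }),
    se = as.list(fit$se),
    convergence = list(converged = fit$converged,
                       iterations = fit$iterations,
                       gradient_norm = fit$gradient_norm)
  )
}

#' Write pipeline results to a directory
#'
#' Writes whatever components are supplied — a fit (JSON + edge-list
#' CSV), a selection table (CSV), a trajectory (CSV), a stratified result
#' (JSON) — plus a plain-text run log carrying the seed, a configuration
#' hash, and a data fingerprint, and returns a manifest of everything
#' written. Numeric CSV content is formatted at 10 significant digits, so
#' a rerun with the same configuration and seed is byte-identical.
#'
#' @param results Named list; recognized names: `fit` (`mg_fit`),
#'   `selection` (`mg_selection`), `trajectory` (`temp_trajectory`),
#'   `bootstrap` (`beta_bootstrap`), `stratified` (`stratified_fit`),
#'   `cohort` (long tibble), `seed`, `config` (any list, logged).
#' @param dir Output directory (created if needed).
#' @return A tibble manifest (`file`, `description`).
#' @export
write_results <- function(results, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stop("cannot create directory ", dir)
  }
  manifest <- list()
  add <- function(file, description) {
    manifest[[length(manifest) + 1]] <<- tibble::tibble(
      file = file, description = description)
  }
  fingerprint <- NULL
  if (!is.null(results$fit)) {
    jsonlite::write_json(fit_to_list(results$fit), file.path(dir, "fit.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    add("fit.json", "multigroup fit: spec, per-wave parameters, convergence")
    write_csv10(edge_list(results$fit), file.path(dir, "edges.csv"))
    add("edges.csv", "edge list (wave, i, j, weight)")
    fingerprint <- results$fit$fingerprint
  }
  if (!is.null(results$selection)) {
    write_csv10(results$selection$table, file.path(dir, "selection.csv"))
    add("selection.csv", "model-selection grid with fit indices and chosen flag")
    if (is.null(results$fit)) {
      fingerprint <- results$selection$chosen$fingerprint
    }
  }
  if (!is.null(results$trajectory)) {
    write_csv10(results$trajectory, file.path(dir, "trajectory.csv"))
    add("trajectory.csv", "per-wave temperature, CIs, entropy, strength, sum scores")
  }
  if (!is.null(results$bootstrap)) {
    write_csv10(results$bootstrap$intervals, file.path(dir, "bootstrap.csv"))
    add("bootstrap.csv", "bootstrap percentile intervals for beta and T")
  }
  if (!is.null(results$stratified)) {
    st <- results$stratified
    obj <- list(
      strata = as.character(st$strata),
      note = st$note,
      trajectories = purrr::map(st$trajectories, function(tr) {
        lapply(as.list(tr), as.numeric)
      }),
      interaction = if (!is.null(st$interaction)) {
        as.list(st$interaction[1, ])
      }
    )
    jsonlite::write_json(obj, file.path(dir, "stratified.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    add("stratified.json", "per-stratum trajectories and interaction test")
  }
  if (!is.null(results$cohort)) {
    write_symptom_csv(results$cohort, file.path(dir, "cohort.csv"))
    add("cohort.csv", "long-format cohort data")
  }
  cfg <- results$config %||% list()
  log_lines <- c(
    paste0("nettemp run log ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    paste0("seed: ", results$seed %||% "NA"),
    paste0("config_hash: ", config_hash(cfg)),
    paste0("data_fingerprint: ",
           if (is.null(fingerprint)) "NA"
           else paste(fmt_num(fingerprint), collapse = ",")),
    paste0("files: ", paste(vapply(manifest, function(m) m$file, ""),
                            collapse = ", "))
  )
  writeLines(log_lines, file.path(dir, "run.log"))
  add("run.log", "seeds, config hash, data fingerprint")
  dplyr::bind_rows(manifest)
}

# small stable polynomial hash of the deparsed config; no external digest
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 1000000007
  sprintf("%08x", h)
}
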