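#' Specify a multigroup Ising model
#'
#' A model specification is a constraint level crossed with a structure.
#' The four nested constraint levels tie parameters across groups
#' (measurement occasions):
#' \describe{
#'   \item{`"saturated"`}{all edge weights and thresholds free per group;
#'     every \eqn{\beta_g = 1} (the overall scale is unidentified).}
#'   \item{`"equal_edges"`}{one shared edge matrix; thresholds free per
#'     group; \eqn{\beta_1 = 1} fixed for identification and
#'     \eqn{\beta_g} free for \eqn{g \ge 2} — temperature becomes
#'     identified from the second occasion onwards.}
#'   \item{`"equal_edges_thresholds"`}{shared edges and shared thresholds;
#'     \eqn{\beta_1 = 1}, later \eqn{\beta_g} free.}
#'   \item{`"equal_all"`}{shared edges, thresholds, and temperature; all
#'     \eqn{\beta_g = 1}.}
#' }
#' Structure is `"dense"` (all edges retained) or `"sparse"` (edges removed
#' by backward-stepwise Wald pruning at `sparse_alpha`, shared across
#' groups).
#'
#' @param constraint Constraint level (see Details).
#' @param structure `"dense"` or `"sparse"`.
#' @param sparse_alpha Two-sided significance level used when pruning
#'   edges; default 0.01.
#' @param encoding Node-state alphabet of the data, `"pm1"` or `"zo"`.
#' @return An object of class `mg_spec`.
#' @export
mg_spec <- function(constraint = c("saturated", "equal_edges",
                                   "equal_edges_thresholds", "equal_all"),
                    structure = c("dense", "sparse"),
                    sparse_alpha = 0.01,
                    encoding = c("pm1", "zo")) {
  constraint <- match.arg(constraint)
  structure <- match.arg(structure)
  encoding <- match.arg(encoding)
  if (!is.numeric(sparse_alpha) || sparse_alpha <= 0 || sparse_alpha >= 1) {
    stop("`sparse_alpha` must lie in (0, 1)")
  }
  structure(
    list(constraint = constraint, structure = structure,
         sparse_alpha = sparse_alpha, encoding = encoding,
         retained_edges = NULL),
    class = "mg_spec"
  )
}

#' @export
print.mg_spec <- function(x, ...) {
  cat("<mg_spec> ", x$constraint, " / ", x$structure, sep = "")
  if (!is.null(x$retained_edges)) {
    cat(" (", sum(x$retained_edges), " of ", length(x$retained_edges),
        " edges retained)", sep = "")
  }
  cat(", encoding ", toupper(x$encoding), "\n", sep = "")
  invisible(x)
}

constraint_sharing <- function(constraint) {
  switch(constraint,
    saturated              = list(shared_w = FALSE, shared_tau = FALSE, free_beta = FALSE),
    equal_edges            = list(shared_w = TRUE,  shared_tau = FALSE, free_beta = TRUE),
    equal_edges_thresholds = list(shared_w = TRUE,  shared_tau = TRUE,  free_beta = TRUE),
    equal_all              = list(shared_w = TRUE,  shared_tau = TRUE,  free_beta = FALSE),
    stop("unknown constraint level: ", constraint)
  )
}

# Upper-triangle edge ordering used everywhere: column-major upper.tri,
# i.e. (1,2),(1,3),(2,3),(1,4),... edge_index(p) gives the (i, j) pairs.
edge_index <- function(p) {
  which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
}

# Free-parameter layout for a spec: w blocks, tau blocks, log-beta block.
build_parmap <- function(spec, G, p) {
  sh <- constraint_sharing(spec$constraint)
  if (sh$free_beta && G < 2) {
    stop("constraint level '", spec$constraint, "' frees beta, which is ",
         "unidentified with a single group; use 'saturated' or 'equal_all'")
  }
  E_all <- p * (p - 1) / 2
  retained <- spec$retained_edges %||% rep(TRUE, E_all)
  if (length(retained) != E_all) stop("retained-edge mask has wrong length")
  E <- sum(retained)
  nw <- if (sh$shared_w) E else G * E
  ntau <- if (sh$shared_tau) p else G * p
  nb <- if (sh$free_beta) G - 1L else 0L
  idx_w <- function(g) {
    if (E == 0) return(integer(0))
    if (sh$shared_w) seq_len(E) else (g - 1L) * E + seq_len(E)
  }
  idx_tau <- function(g) {
    off <- nw
    if (sh$shared_tau) off + seq_len(p) else off + (g - 1L) * p + seq_len(p)
  }
  idx_logbeta <- function(g) {                 # g >= 2 when free_beta
    if (!sh$free_beta || g == 1L) return(integer(0))
    nw + ntau + (g - 1L)
  }
  names_theta <- c(
    if (nw > 0) {
      ei <- edge_index(p)[retained, , drop = FALSE]
      lab <- paste0("omega[", ei[, 1], ",", ei[, 2], "]")
      if (sh$shared_w) lab
      else as.vector(vapply(seq_len(G), function(g) paste0(lab, ".g", g),
                            character(E)))
    },
    if (sh$shared_tau) paste0("tau[", seq_len(p), "]")
    else as.vector(vapply(seq_len(G),
                          function(g) paste0("tau[", seq_len(p), "].g", g),
                          character(p))),
    if (nb > 0) paste0("logbeta.g", 2:G)
  )
  list(G = G, p = p, retained = retained, E = E,
       shared_w = sh$shared_w, shared_tau = sh$shared_tau,
       free_beta = sh$free_beta,
       k = nw + ntau + nb, n_theta = nw + ntau + nb,
       idx_w = idx_w, idx_tau = idx_tau, idx_logbeta = idx_logbeta,
       names = names_theta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Pairwise-product design over states for the retained edges:
# Q[s, e] = S[s, i_e] * S[s, j_e]. Cached per call site (cheap anyway).
edge_design <- function(S, retained) {
  p <- ncol(S)
  ei <- edge_index(p)[retained, , drop = FALSE]
  if (nrow(ei) == 0) return(matrix(0, nrow(S), 0))
  S[, ei[, 1], drop = FALSE] * S[, ei[, 2], drop = FALSE]
}

# Per-group sufficient statistics reduced to the retained edge set.
reduce_suffstats <- function(ss_list, retained, p) {
  ut <- upper.tri(matrix(0, p, p))
  lapply(ss_list, function(ss) {
    list(n = ss$n, s = ss$s, c = ss$C[ut][retained])
  })
}

group_pars <- function(theta, pm, g) {
  w <- if (pm$E > 0) theta[pm$idx_w(g)] else numeric(0)
  tau <- theta[pm$idx_tau(g)]
  ib <- pm$idx_logbeta(g)
  beta <- if (length(ib)) exp(theta[ib]) else 1
  list(w = w, tau = tau, beta = beta)
}

# Negative log-likelihood and gradient over the free parameter vector.
# S: state matrix; Q: edge design; ssr: reduced suffstats per group.
make_objective <- function(S, Q, ssr, pm) {
  n_states <- nrow(S)
  fn <- function(theta) {
    nll <- 0
    for (g in seq_len(pm$G)) {
      gp <- group_pars(theta, pm, g)
      eneg <- drop(S %*% gp$tau)
      if (pm$E > 0) eneg <- eneg + drop(Q %*% gp$w)
      lp <- gp$beta * eneg
      m <- max(lp)
      logZ <- m + log(sum(exp(lp - m)))
      A <- sum(gp$tau * ssr[[g]]$s) + sum(gp$w * ssr[[g]]$c)
      nll <- nll - (gp$beta * A - ssr[[g]]$n * logZ)
    }
    nll
  }
  gr <- function(theta) {
    grad <- numeric(pm$n_theta)
    for (g in seq_len(pm$G)) {
      gp <- group_pars(theta, pm, g)
      eneg <- drop(S %*% gp$tau)
      if (pm$E > 0) eneg <- eneg + drop(Q %*% gp$w)
      lp <- gp$beta * eneg
      m <- max(lp)
      pr <- exp(lp - m)
      pr <- pr / sum(pr)
      n_g <- ssr[[g]]$n
      g_tau <- gp$beta * (ssr[[g]]$s - n_g * drop(crossprod(S, pr)))
      grad[pm$idx_tau(g)] <- grad[pm$idx_tau(g)] + g_tau
      if (pm$E > 0) {
        g_w <- gp$beta * (ssr[[g]]$c - n_g * drop(crossprod(Q, pr)))
        grad[pm$idx_w(g)] <- grad[pm$idx_w(g)] + g_w
      }
      ib <- pm$idx_logbeta(g)
      if (length(ib)) {
        A <- sum(gp$tau * ssr[[g]]$s) + sum(gp$w * ssr[[g]]$c)
        grad[ib] <- grad[ib] + gp$beta * (A - n_g * sum(pr * eneg))
      }
    }
    -grad
  }
  list(fn = fn, gr = gr)
}

# Deterministic starting values: independent-item logistic thresholds,
# zero edges, log beta = 0.
init_theta <- function(ssr, pm, encoding) {
  theta <- numeric(pm$n_theta)
  to_tau <- function(s, n) {
    phat <- if (encoding == "pm1") (s / n + 1) / 2 else s / n
    phat <- pmin(pmax(phat, 1 / (2 * n)), 1 - 1 / (2 * n))
    if (encoding == "pm1") 0.5 * stats::qlogis(phat) else stats::qlogis(phat)
  }
  if (pm$shared_tau) {
    s <- Reduce(`+`, lapply(ssr, `[[`, "s"))
    n <- sum(vapply(ssr, `[[`, 0, "n"))
    theta[pm$idx_tau(1)] <- to_tau(s, n)
  } else {
    for (g in seq_len(pm$G)) {
      theta[pm$idx_tau(g)] <- to_tau(ssr[[g]]$s, ssr[[g]]$n)
    }
  }
  theta
}

# Core optimizer: quasi-Newton (BFGS) with analytic gradient, followed by
# Newton polishing with the numerical Hessian when the gradient tolerance
# asks for more precision than BFGS delivers. Declared converged when the
# per-observation gradient max-norm is below `gtol`.
optimize_theta <- function(obj, theta0, n_total, maxit = 500,
                           reltol = 1e-10, gtol = 1e-5, rounds = 3) {
  theta <- theta0
  total_it <- 0L
  gnorm <- Inf
  for (r in seq_len(rounds)) {
    opt <- stats::optim(theta, obj$fn, obj$gr, method = "BFGS",
                        control = list(maxit = maxit, reltol = reltol))
    theta <- opt$par
    total_it <- total_it + opt$counts[["function"]]
    gnorm <- max(abs(obj$gr(theta))) / n_total
    if (gnorm < gtol) break
  }
  if (gnorm >= gtol) {
    f_cur <- obj$fn(theta)
    for (it in seq_len(25)) {
      H <- stats::optimHess(theta, obj$fn, obj$gr)
      g <- obj$gr(theta)
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) break
      lambda <- 1
      repeat {
        cand <- theta - lambda * step
        f_new <- obj$fn(cand)
        if (is.finite(f_new) && f_new <= f_cur + 1e-12 * abs(f_cur)) break
        lambda <- lambda / 2
        if (lambda < 1e-6) break
      }
      if (lambda < 1e-6) break
      theta <- cand
      f_cur <- f_new
      total_it <- total_it + 1L
      gnorm <- max(abs(obj$gr(theta))) / n_total
      if (gnorm < gtol) break
    }
  }
  list(theta = theta, value = -obj$fn(theta), gnorm = gnorm,
       converged = gnorm < gtol, iterations = total_it)
}

#' Fit a multigroup Ising model by maximum likelihood
#'
#' Maximizes the pooled log-likelihood
#' \eqn{\sum_g \ell(\mathrm{panel}_g; \Omega_g, \tau_g, \beta_g)} over the
#' free parameters implied by the specification's equality constraints,
#' using quasi-Newton iteration with analytic gradients and exact
#' enumeration for all model expectations. \eqn{\beta} is parameterized as
#' \eqn{\log\beta} wherever it is free, so positivity needs no constrained
#' optimization; \eqn{\beta_1 \equiv 1} identifies the scale. Standard
#' errors come from the inverse numerical Hessian of the negative
#' log-likelihood at the optimum. For a `"sparse"` specification the dense
#' model at the same constraint level is fitted first and then pruned (see
#' [prune_edges()]).
#'
#' @param data Long-format cohort data: columns `id` (optional), `wave`,
#'   `age`, and one column per item, complete (no `NA`). Waves are ordered
#'   by ascending age; the first wave after ordering anchors the
#'   identification.
#' @param spec An [mg_spec()].
#' @param order_by_age Order waves by ascending age (default) or by wave
#'   index.
#' @param start Optional warm-start parameter vector (internal use).
#' @param se Compute the Hessian-based covariance (default TRUE; switched
#'   off internally during bootstrap refits).
#' @param maxit,gtol Optimizer controls: BFGS iteration cap per round and
#'   scaled gradient max-norm tolerance.
#' @return An object of class `mg_fit`; see [tidy.mg_fit()] and
#'   [glance.mg_fit()].
#' @examples
#' d <- generate_cohort(abcd_like_design(n_per_wave = 300, seed = 4))
#' fit <- fit_ising_mg(d, mg_spec("equal_edges"))
#' glance(fit)
#' @export
fit_ising_mg <- function(data, spec = mg_spec(), order_by_age = TRUE,
                         start = NULL, se = TRUE, maxit = 500, gtol = 1e-5) {
  stopifnot(inherits(spec, "mg_spec"))
  panels <- as_panels(data, spec$encoding, order_by_age = order_by_age)
  fit <- fit_panels(panels, spec, start = start, se = se,
                    maxit = maxit, gtol = gtol)
  fit$data <- tibble::as_tibble(data)
  fit$order_by_age <- order_by_age
  if (spec$structure == "sparse" && is.null(spec$retained_edges)) {
    fit <- prune_edges(fit)
  }
  fit
}

# Fit from a panel list (internal engine; no pruning, no data retention).
fit_panels <- function(panels, spec, start = NULL, se = TRUE,
                       maxit = 500, gtol = 1e-5) {
  item_names <- attr(panels, "item_names")
  G <- length(panels)
  p <- length(item_names)
  pm <- build_parmap(spec, G, p)
  S <- state_matrix(p, spec$encoding)
  Q <- edge_design(S, pm$retained)
  ss <- lapply(panels, function(pl) panel_suffstats(pl$X))
  ssr <- reduce_suffstats(ss, pm$retained, p)
  obj <- make_objective(S, Q, ssr, pm)
  theta0 <- start %||% init_theta(ssr, pm, spec$encoding)
  n_total <- sum(vapply(panels, `[[`, 0, "n"))
  res <- optimize_theta(obj, theta0, n_total, maxit = maxit, gtol = gtol)
  if (!res$converged) {
    warning("multigroup fit did not reach the gradient tolerance (scaled ",
            "max-norm ", format(res$gnorm, digits = 3), "); returning the ",
            "best iterate with converged = FALSE")
  }
  vcov <- se_theta <- NULL
  if (se) {
    H <- stats::optimHess(res$theta, obj$fn, obj$gr)
    vcov <- tryCatch(solve(H), error = function(e) MASS::ginv(H))
    dimnames(vcov) <- list(pm$names, pm$names)
    se_theta <- sqrt(pmax(diag(vcov), 0))
    names(se_theta) <- pm$names
  }
  params <- lapply(seq_len(G), function(g) {
    gp <- group_pars(res$theta, pm, g)
    om <- matrix(0, p, p)
    ei <- edge_index(p)[pm$retained, , drop = FALSE]
    om[ei] <- gp$w
    om <- om + t(om)
    ising_params(om, gp$tau, beta = gp$beta, encoding = spec$encoding,
                 item_names = item_names)
  })
  if (pm$free_beta && !is.null(se_theta)) {
    # beta only scales the potential; with no clearly nonzero edge the
    # scale is ill-determined
    wz <- if (pm$E > 0) {
      abs(res$theta[pm$idx_w(1)]) / pmax(se_theta[pm$idx_w(1)], 1e-12)
    } else 0
    if (all(wz < 2)) {
      warning("no edge weight is clearly nonzero; with ~0 interactions the ",
              "inverse temperature is weakly identified — interpret beta ",
              "with care")
    }
  }
  spec$retained_edges <- pm$retained
  structure(
    list(spec = spec, params = params, parmap = pm, theta = res$theta,
         loglik = res$value, k = pm$k,
         n_total = n_total, n_g = vapply(panels, `[[`, 0, "n"),
         se = se_theta, vcov = vcov,
         converged = res$converged, iterations = res$iterations,
         gradient_norm = res$gnorm,
         waves = vapply(panels, `[[`, 0, "wave"),
         ages = vapply(panels, `[[`, 0, "age"),
         item_names = item_names,
         fingerprint = fit_fingerprint(ss),
         panel_summary = panels_sumscore(panels, spec$encoding)),
    class = "mg_fit"
  )
}

# data fingerprint used to refuse cross-data index comparisons
fit_fingerprint <- function(ss) {
  c(n = sum(vapply(ss, `[[`, 0, "n")),
    s = sum(vapply(ss, function(x) sum(x$s), 0)),
    c2 = sum(vapply(ss, function(x) sum(x$C), 0)))
}

# per-wave mean/sd of the 0/1-scored item-sum, regardless of encoding
panels_sumscore <- function(panels, encoding) {
  purrr::map_dfr(panels, function(pl) {
    sums <- rowSums(pl$X)
    if (encoding == "pm1") sums <- (sums + ncol(pl$X)) / 2
    tibble::tibble(wave = pl$wave, age = pl$age, n = pl$n,
                   mean_score = mean(sums),
                   sd_score = stats::sd(sums),
                   var_score = stats::var(sums))
  })
}

#' @export
print.mg_fit <- function(x, ...) {
  cat("<mg_fit> ", x$spec$constraint, " / ", x$spec$structure, ", ",
      x$parmap$G, " waves, ", x$parmap$p, " items, n = ", x$n_total,
      "\n", sep = "")
  cat("  loglik ", format(x$loglik), ", k = ", x$k,
      ", converged: ", x$converged, "\n", sep = "")
  cat("  beta: ", paste(format(round(beta_hat(x), 4)), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

beta_hat <- function(fit) vapply(fit$params, `[[`, 0, "beta")

#' Tidy and summarize multigroup Ising fits
#'
#' `tidy()` returns one row per free parameter with its estimate and
#' standard error; `glance()` returns a one-row model summary.
#'
#' @param x An `mg_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy mg_fit
#' @export
tidy.mg_fit <- function(x, ...) {
  tibble::tibble(
    term = x$parmap$names,
    estimate = x$theta,
    std.error = if (is.null(x$se)) NA_real_ else x$se
  )
}

#' @rdname tidy.mg_fit
#' @method glance mg_fit
#' @export
glance.mg_fit <- function(x, ...) {
  tibble::tibble(
    constraint = x$spec$constraint, structure = x$spec$structure,
    logLik = x$loglik, k = x$k, n = x$n_total, n_waves = x$parmap$G,
    edges_retained = sum(x$spec$retained_edges),
    converged = x$converged, gradient_norm = x$gradient_norm
  )
}

#' @export
logLik.mg_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n_total,
            class = "logLik")
}

# Wald p-value per retained edge; for per-group edge parameters the edge's
# p is the minimum across groups (an edge is kept if significant anywhere),
# since the retained-edge mask is shared across groups.
edge_wald <- function(fit) {
  pm <- fit$parmap
  if (pm$E == 0) return(tibble::tibble(edge = integer(0)))
  idx_all <- which(pm$retained)
  if (pm$shared_w) {
    est <- fit$theta[pm$idx_w(1)]
    se <- fit$se[pm$idx_w(1)]
    pval <- 2 * stats::pnorm(-abs(est / se))
  } else {
    pmat <- vapply(seq_len(pm$G), function(g) {
      est <- fit$theta[pm$idx_w(g)]
      se <- fit$se[pm$idx_w(g)]
      2 * stats::pnorm(-abs(est / se))
    }, numeric(pm$E))
    pmat <- matrix(pmat, nrow = pm$E)
    pval <- apply(pmat, 1, min)
  }
  ei <- edge_index(pm$p)[pm$retained, , drop = FALSE]
  tibble::tibble(edge = idx_all, i = ei[, 1], j = ei[, 2], p.value = pval)
}

#' Prune non-significant edges from a dense multigroup fit
#'
#' Backward stepwise pruning: repeatedly remove the retained edge with the
#' largest two-sided Wald p-value above `sparse_alpha` (ties broken by the
#' lexicographically smallest (i, j) pair) and refit, until every retained
#' edge is significant. The retained-edge set is shared across groups. If
#' every edge is pruned the independence structure is returned with a
#' warning.
#'
#' @param fit A converged dense `mg_fit` (from [fit_ising_mg()]).
#' @return A sparse `mg_fit` whose `$spec$retained_edges` records the mask.
#' @export
prune_edges <- function(fit) {
  stopifnot(inherits(fit, "mg_fit"))
  alpha <- fit$spec$sparse_alpha
  panels <- refit_panels(fit)
  cur <- fit
  repeat {
    ew <- edge_wald(cur)
    cand <- ew[!is.na(ew$p.value) & ew$p.value > alpha, , drop = FALSE]
    if (nrow(cand) == 0) break
    worst <- cand[order(-cand$p.value, cand$i, cand$j), ][1, ]
    retained <- cur$spec$retained_edges
    retained[worst$edge] <- FALSE
    if (!any(retained)) {
      warning("all edges pruned; returning the independence structure")
    }
    spec2 <- cur$spec
    spec2$structure <- "sparse"
    spec2$retained_edges <- retained
    # warm start: drop the removed edge's entries from the current theta
    start <- warm_start_drop(cur, retained)
    cur <- fit_panels(panels, spec2, start = start)
    if (!any(retained)) break
  }
  cur$spec$structure <- "sparse"
  cur$data <- fit$data
  cur$order_by_age <- fit$order_by_age
  cur
}

# rebuild the panel list held implicitly by a fit (from its stored data)
refit_panels <- function(fit) {
  if (is.null(fit$data)) stop("fit does not retain its data")
  as_panels(fit$data, fit$spec$encoding,
            order_by_age = fit$order_by_age %||% TRUE)
}

# map a theta from a larger retained set onto a smaller one
warm_start_drop <- function(fit, retained_new) {
  pm_old <- fit$parmap
  keep <- retained_new[pm_old$retained]   # within old retained ordering
  th <- fit$theta
  if (pm_old$E == 0) return(th)
  w_keep <- unlist(lapply(seq_len(if (pm_old$shared_w) 1 else pm_old$G),
                          function(g) th[pm_old$idx_w(g)][keep]))
  rest <- th[-unlist(lapply(seq_len(if (pm_old$shared_w) 1 else pm_old$G),
                            pm_old$idx_w))]
  c(w_keep, rest)
}

#' Case bootstrap for inverse temperature and temperature
#'
#' Resamples individuals with replacement within each wave, refits the
#' model (same specification and retained-edge mask, warm-started from the
#' point fit), and returns 2.5/97.5 percentile intervals of
#' \eqn{\hat\beta_g} and \eqn{\hat T_g = 1/\hat\beta_g} per wave.
#' Non-converged replicates are dropped and counted; a warning is issued
#' if more than 10\% fail. Replicate b draws its resampling indices from
#' seed `seed + b`, so runs are reproducible and replicates independent.
#'
#' @param fit An `mg_fit` from [fit_ising_mg()] (must retain its data).
#' @param B Number of bootstrap replicates (>= 2); the conventional
#'   production choice is 1000.
#' @param seed Integer seed.
#' @return An object of class `beta_bootstrap`: a list with `intervals`
#'   (tibble per wave), `replicates` (B x G matrix of beta draws),
#'   `n_failed`.
#' @export
bootstrap_beta <- function(fit, B = 1000, seed = 1L) {
  stopifnot(inherits(fit, "mg_fit"), B >= 2)
  panels <- refit_panels(fit)
  G <- length(panels)
  reps <- matrix(NA_real_, B, G)
  failed <- 0L
  for (b in seq_len(B)) {
    pb <- withr::with_seed(seed + b, lapply(panels, function(pl) {
      idx <- sample.int(pl$n, pl$n, replace = TRUE)
      list(X = pl$X[idx, , drop = FALSE], wave = pl$wave, age = pl$age,
           n = pl$n)
    }))
    attr(pb, "item_names") <- attr(panels, "item_names")
    rf <- suppressWarnings(
      tryCatch(fit_panels(pb, fit$spec, start = fit$theta, se = FALSE),
               error = function(e) NULL)
    )
    if (is.null(rf) || !rf$converged) {
      failed <- failed + 1L
    } else {
      reps[b, ] <- beta_hat(rf)
    }
  }
  if (failed > 0.1 * B) {
    warning(failed, " of ", B, " bootstrap replicates failed to converge")
  }
  ok <- stats::complete.cases(reps)
  qs <- apply(reps[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(0.025, 0.975), names = FALSE)
  intervals <- tibble::tibble(
    wave = fit$waves, age = fit$ages,
    beta = beta_hat(fit),
    beta_lo = qs[1, ], beta_hi = qs[2, ],
    temp_lo = 1 / qs[2, ], temp_hi = 1 / qs[1, ]
  )
  structure(list(intervals = intervals, replicates = reps,
                 n_failed = failed, B = B, seed = seed),
            class = "beta_bootstrap")
}

#' @export
print.beta_bootstrap <- function(x, ...) {
  cat("<beta_bootstrap> B = ", x$B, " (", x$n_failed, " failed)\n", sep = "")
  print(x$intervals)
  invisible(x)
}

#' @method tidy beta_bootstrap
#' @export
tidy.beta_bootstrap <- function(x, ...) x$intervals
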