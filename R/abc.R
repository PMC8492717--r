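## ---- reference table -------------------------------------------------------

#' Build an ABC reference table
#'
#' For each row: draw scenario parameters from the priors (ordering
#' constraints enforced by rejection), simulate a dataset under the
#' scenario, and record the summary-statistic vector.  Fully
#' reproducible from `seed`.
#'
#' @param scenarios list of `mt_scenario` objects (>= 2 for model
#'   choice).
#' @param priors an `mt_priors`.
#' @param n_per_scenario simulated datasets per scenario.  Published
#'   ABC analyses of this kind use up to one million per scenario; the
#'   default here is a desk-scale setting.
#' @param samples named integer vector of per-population sample sizes.
#' @param L locus length (bp).
#' @param seed integer RNG seed.
#' @param verbose log progress every `n_per_scenario/10` rows.
#' @return `mt_reftable`: list with `scenario` (factor), `params`
#'   (data frame, `NA` for symbols a scenario does not use), `stats`
#'   (matrix), plus `scenarios`, `priors`, `samples`, `L`, `pops`.
#' @export
build_reference_table <- function(scenarios, priors, n_per_scenario = 20000L,
                                  samples, L = 600L, seed = 1L,
                                  verbose = FALSE) {
  if (length(scenarios) < 1L) stop("need at least one scenario", call. = FALSE)
  pops <- scenarios[[1]]$pops
  for (s in scenarios) stopifnot(identical(s$pops, pops))
  set.seed(seed)
  all_syms <- unique(unlist(lapply(scenarios, .scenario_symbols)))
  all_syms <- c(all_syms, "mu", "kappa")
  nrow_tot <- n_per_scenario * length(scenarios)
  par_mat <- matrix(NA_real_, nrow_tot, length(all_syms),
                    dimnames = list(NULL, all_syms))
  stat_mat <- NULL
  scen_id <- character(nrow_tot)
  r <- 0L
  for (s in scenarios) {
    for (i in seq_len(n_per_scenario)) {
      r <- r + 1L
      pars <- draw_params(s, priors)
      sim <- simulate_dataset(s, pars, samples, L, as_alignment = FALSE)
      v <- summary_stats(sim, pops = pops)
      if (is.null(stat_mat))
        stat_mat <- matrix(NA_real_, nrow_tot, length(v),
                           dimnames = list(NULL, names(v)))
      stat_mat[r, ] <- v
      par_mat[r, names(pars)] <- unlist(pars)
      scen_id[r] <- s$id
      if (verbose && i %% max(1L, n_per_scenario %/% 10L) == 0L)
        message(sprintf("[reference table] scenario %s: %d / %d",
                        s$id, i, n_per_scenario))
    }
  }
  structure(list(scenario = factor(scen_id, levels = vapply(scenarios, `[[`,
                                                            "", "id")),
                 params = as.data.frame(par_mat),
                 stats = stat_mat,
                 scenarios = scenarios, priors = priors,
                 samples = samples, L = L, pops = pops, seed = seed),
            class = "mt_reftable")
}

#' @export
print.mt_reftable <- function(x, ...) {
  cat(sprintf("ABC reference table: %d rows (%s), %d summary statistics\n",
              nrow(x$stats),
              paste(sprintf("%s: %d", levels(x$scenario),
                            as.integer(table(x$scenario))), collapse = ", "),
              ncol(x$stats)))
  invisible(x)
}

#' Persist / load a reference table as TSV
#' @param rt an `mt_reftable`.
#' @param path output path.
#' @export
write_reference_table <- function(rt, path) {
  stopifnot(inherits(rt, "mt_reftable"))
  df <- data.frame(scenario = as.character(rt$scenario), rt$params,
                   rt$stats, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rt)
}

## robust per-statistic scale: MAD, falling back to SD, else dropped
.stat_scales <- function(stats) {
  apply(stats, 2L, function(v) {
    s <- stats::mad(v)
    if (s <= 0) s <- stats::sd(v)
    s
  })
}

## Euclidean distance of every (normalized) row to the observed vector
.abc_distances <- function(stats, observed, scales) {
  keep <- which(is.finite(scales) & scales > 0)
  Z <- sweep(stats[, keep, drop = FALSE], 2L, scales[keep], "/")
  z0 <- observed[keep] / scales[keep]
  sqrt(rowSums(sweep(Z, 2L, z0)^2))
}

.epanechnikov <- function(d, bw) {
  ## bw = 0 happens when every retained simulation matches the observed
  ## vector exactly (e.g. all-monomorphic data): weight uniformly
  if (!is.finite(bw) || bw <= 0) return(rep(1, length(d)))
  w <- 1 - (d / bw)^2
  w[w < 0] <- 0
  w
}

## ---- PCA pre-evaluation ----------------------------------------------------

#' PCA pre-evaluation of simulated vs observed summary statistics
#'
#' Principal components of the normalized reference-table statistics;
#' the observed vector is projected into the same space and flagged if
#' its Mahalanobis radius in the first two components exceeds the 99th
#' percentile of the simulated cloud.
#'
#' @param rt an `mt_reftable`.
#' @param observed observed summary-statistic vector (same order as
#'   `rt$stats`).
#' @return List with `scores` (first two PCs of simulations),
#'   `observed_scores`, `mahalanobis_observed`, `radius99`, `flag`,
#'   `dropped` (zero-variance statistics).
#' @export
preevaluate_pca <- function(rt, observed) {
  stopifnot(inherits(rt, "mt_reftable"))
  sdv <- apply(rt$stats, 2L, stats::sd)
  keep <- which(sdv > 0)
  dropped <- colnames(rt$stats)[sdv <= 0]
  if (length(dropped))
    warning("zero-variance statistic(s) dropped: ",
            paste(dropped, collapse = ", "))
  if (length(keep) < 2L)
    stop("need >= 2 statistics with nonzero variance", call. = FALSE)
  pc <- stats::prcomp(rt$stats[, keep, drop = FALSE], center = TRUE,
                      scale. = TRUE)
  k <- min(2L, ncol(pc$x))
  sc <- pc$x[, seq_len(k), drop = FALSE]
  obs_sc <- stats::predict(pc, t(observed[keep]))[, seq_len(k), drop = FALSE]
  S <- stats::cov(sc)
  ctr <- colMeans(sc)
  md <- function(x) sqrt(drop(t(x - ctr) %*% solve(S) %*% (x - ctr)))
  m_obs <- md(drop(obs_sc))
  m_sim <- sqrt(stats::mahalanobis(sc, ctr, S))
  r99 <- stats::quantile(m_sim, 0.99, names = FALSE)
  list(scores = sc, observed_scores = drop(obs_sc),
       mahalanobis_observed = m_obs, radius99 = r99,
       flag = m_obs > r99, dropped = dropped)
}

## ---- model choice ----------------------------------------------------------

#' ABC model choice by polychotomous weighted logistic regression
#'
#' Statistics are normalized by their reference-table MAD; the
#' `tolerance` fraction of simulations closest (Euclidean) to the
#' observed vector is retained; a multinomial logistic regression of
#' the scenario indicator on the centred statistics, weighted by an
#' Epanechnikov kernel of the distances, is evaluated at the observed
#' point.  95% CIs come from the delta method on the fitted linear
#' predictors.  On separation (or `estimator = "frequency"`) the
#' categorical weighted-frequency estimator is used instead; with
#' `tolerance >= 1` (no rejection) the frequency weights are uniform,
#' so probabilities reduce to plain per-scenario row fractions.
#'
#' @param rt an `mt_reftable` built from >= 2 scenarios.
#' @param observed observed summary-statistic vector.
#' @param tolerance fraction of simulations retained.
#' @param estimator `"logistic"` (with automatic frequency fallback)
#'   or `"frequency"`.
#' @return `mt_modelchoice`: data frame `table` (scenario, posterior,
#'   CI bounds, retained count), `winner`, `method` used.
#' @export
model_choice <- function(rt, observed, tolerance = 0.01,
                         estimator = c("logistic", "frequency")) {
  stopifnot(inherits(rt, "mt_reftable"))
  estimator <- match.arg(estimator)
  K <- nlevels(rt$scenario)
  if (K < 2L) stop("model choice needs >= 2 scenarios", call. = FALSE)
  n_keep <- max(ceiling(tolerance * nrow(rt$stats)), 10L * K)
  scales <- .stat_scales(rt$stats)
  d <- .abc_distances(rt$stats, observed, scales)
  ## threshold-inclusive retention: every row at the cutoff distance is
  ## kept, so heavy ties (e.g. monomorphic data) cannot bias the
  ## retained set towards whichever scenario was simulated first
  d_thr <- sort(d)[min(n_keep, length(d))]
  idx <- which(d <= d_thr)
  bw <- max(d[idx]) * (1 + 1e-12)
  w <- if (tolerance >= 1) rep(1, length(idx))
       else .epanechnikov(d[idx], bw)
  if (all(w <= 0)) w <- rep(1, length(idx))
  y <- as.integer(rt$scenario[idx])
  keep_c <- which(is.finite(scales) & scales > 0)
  X <- sweep(rt$stats[idx, keep_c, drop = FALSE], 2L, scales[keep_c], "/")
  X <- sweep(X, 2L, observed[keep_c] / scales[keep_c])
  ## drop collinear columns among retained rows
  Xsd <- apply(X, 2L, stats::sd)
  X <- X[, Xsd > 1e-10, drop = FALSE]
  method <- "logistic"
  fit <- NULL
  missing_scen <- setdiff(seq_len(K), unique(y))
  if (!length(missing_scen) && estimator == "logistic")
    fit <- .multinom_fit(y, X, w / mean(w))
  if (is.null(fit)) {
    if (length(missing_scen))
      warning("scenario(s) absent from the retained set: ",
              paste(levels(rt$scenario)[missing_scen], collapse = ", "),
              "; degenerate CI")
    else if (estimator == "logistic")
      warning("logistic regression failed (separation?); ",
              "falling back to the categorical frequency estimator")
    method <- "frequency"
    wsum <- vapply(seq_len(K), function(k) sum(w[y == k]), numeric(1))
    pr <- wsum / sum(wsum)
    se <- sqrt(pr * (1 - pr) / length(idx))
  } else {
    pz <- .multinom_probs_at_zero(fit)
    pr <- pz$prob; se <- pz$se
  }
  lo <- pmax(pr - 1.96 * se, 0); hi <- pmin(pr + 1.96 * se, 1)
  tab <- data.frame(scenario = levels(rt$scenario),
                    posterior = pr, ci_low = lo, ci_high = hi,
                    retained = as.integer(table(factor(y, levels = seq_len(K)))))
  structure(list(table = tab,
                 winner = levels(rt$scenario)[which.max(pr)],
                 method = method, n_retained = length(idx)),
            class = "mt_modelchoice")
}

#' @export
print.mt_modelchoice <- function(x, ...) {
  cat("ABC model choice (", x$method, " estimator, ", x$n_retained,
      " retained)\n", sep = "")
  tab <- x$table
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %s%s: %.4f (%.4f - %.4f)\n",
                tab$scenario[i],
                ifelse(tab$scenario[i] == x$winner, " [winner]", ""),
                tab$posterior[i], tab$ci_low[i], tab$ci_high[i]))
  invisible(x)
}

#' Export a model-choice result as JSON
#' @param mc an `mt_modelchoice`.
#' @param path output path.
#' @export
write_model_choice <- function(mc, path) {
  stopifnot(inherits(mc, "mt_modelchoice"))
  tab <- mc$table
  tab$winner <- tab$scenario == mc$winner
  jsonlite::write_json(list(method = mc$method, n_retained = mc$n_retained,
                            scenarios = tab),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(mc)
}

#' Prior-based posterior predictive (misclassification) error
#'
#' Simulates `n_test` pseudo-observed datasets (scenario drawn
#' uniformly, parameters from the priors), runs [model_choice()] on
#' each against `rt`, and reports the fraction whose winner differs
#' from the generating scenario.
#'
#' @inheritParams model_choice
#' @param n_test number of pseudo-observed datasets.
#' @param seed RNG seed.
#' @return List with `error` and the per-pod `truth`/`winner` vectors.
#' @export
scenario_choice_error <- function(rt, n_test = 1000L, tolerance = 0.01,
                                  seed = 1L) {
  stopifnot(inherits(rt, "mt_reftable"))
  if (n_test <= 0L) stop("n_test must be positive", call. = FALSE)
  set.seed(seed)
  K <- length(rt$scenarios)
  truth <- character(n_test); winner <- character(n_test)
  for (i in seq_len(n_test)) {
    s <- rt$scenarios[[sample.int(K, 1L)]]
    pars <- draw_params(s, rt$priors)
    sim <- simulate_dataset(s, pars, rt$samples, rt$L, as_alignment = FALSE)
    obs <- summary_stats(sim, pops = rt$pops)
    mc <- suppressWarnings(model_choice(rt, obs, tolerance))
    truth[i] <- s$id; winner[i] <- mc$winner
  }
  list(error = mean(truth != winner), truth = truth, winner = winner)
}

## ---- parameter estimation --------------------------------------------------

.wquantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

#' ABC parameter estimation by weighted local linear regression
#'
#' Reference-table rows of the winner scenario are ranked by distance
#' to the observed statistics; the closest `tolerance` fraction is
#' retained.  Each parameter is mapped onto the real line by a logit
#' transform over its prior bounds, regressed on the centred statistics
#' with Epanechnikov weights, and adjusted to the observed point
#' (theta* = theta - b (s - s_obs)); the back-transform guarantees the
#' posterior stays inside the prior support.
#'
#' @param rt an `mt_reftable`.
#' @param winner scenario id to estimate under.
#' @param observed observed summary-statistic vector.
#' @param tolerance fraction retained (of the winner's rows).
#' @return `mt_posterior`: list with `sample` (adjusted draws), `weights`,
#'   `summary` (data frame: parameter, median, q2.5, q97.5).
#' @export
estimate_parameters <- function(rt, winner, observed, tolerance = 0.01) {
  stopifnot(inherits(rt, "mt_reftable"))
  rows <- which(as.character(rt$scenario) == winner)
  if (length(rows) < 50L)
    stop("need >= 50 reference rows for scenario '", winner, "'",
         call. = FALSE)
  s <- rt$scenarios[[match(winner, vapply(rt$scenarios, `[[`, "", "id"))]]
  syms <- c(.scenario_symbols(s), "mu", "kappa")
  scales <- .stat_scales(rt$stats[rows, , drop = FALSE])
  d <- .abc_distances(rt$stats[rows, , drop = FALSE], observed, scales)
  n_keep <- max(ceiling(tolerance * length(rows)), 50L)
  d_thr <- sort(d)[min(n_keep, length(d))]
  keep_r <- which(d <= d_thr)
  idx <- rows[keep_r]
  dk <- d[keep_r]
  bw <- max(dk) * (1 + 1e-12)
  w <- .epanechnikov(dk, bw)
  if (all(w <= 0)) w <- rep(1, length(idx))
  keep_c <- which(is.finite(scales) & scales > 0)
  X <- sweep(rt$stats[idx, keep_c, drop = FALSE], 2L, scales[keep_c], "/")
  X <- sweep(X, 2L, observed[keep_c] / scales[keep_c])
  Xsd <- apply(X, 2L, stats::sd)
  X <- X[, Xsd > 1e-10, drop = FALSE]
  eps <- 1e-9
  theta_adj <- matrix(NA_real_, length(idx), length(syms),
                      dimnames = list(NULL, syms))
  for (sym in syms) {
    pr <- if (sym %in% c("mu", "kappa")) rt$priors$priors[[sym]]
          else .prior_for(rt$priors, sym)
    th <- rt$params[idx, sym]
    u <- pmin(pmax((th - pr$min) / (pr$max - pr$min), eps), 1 - eps)
    z <- log(u / (1 - u))
    Xw <- cbind(1, X) * sqrt(w)
    zw <- z * sqrt(w)
    qr_ <- qr(Xw)
    if (qr_$rank < ncol(Xw)) {
      ## ridge fallback for singular designs
      warning("singular local regression for '", sym, "'; ridge fallback")
      A <- crossprod(Xw) + diag(1e-6, ncol(Xw))
      coefs <- solve(A, crossprod(Xw, zw))
    } else coefs <- qr.coef(qr_, zw)
    zstar <- z - drop(X %*% coefs[-1])
    ustar <- 1 / (1 + exp(-zstar))
    theta_adj[, sym] <- pr$min + (pr$max - pr$min) * ustar
  }
  summ <- do.call(rbind, lapply(syms, function(sym) {
    q <- .wquantile(theta_adj[, sym], w, c(0.5, 0.025, 0.975))
    data.frame(parameter = sym, median = q[1], q2.5 = q[2], q97.5 = q[3])
  }))
  structure(list(sample = theta_adj, weights = w / sum(w), summary = summ,
                 winner = winner, n_retained = length(idx)),
            class = "mt_posterior")
}

#' @export
print.mt_posterior <- function(x, ...) {
  cat("ABC posterior for scenario", x$winner, "(", x$n_retained,
      "retained )\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Relative median absolute error (RMAE) of the parameter estimator
#'
#' For `n_pods` pseudo-observed datasets simulated under `winner` with
#' known parameters, RMAE(theta) = median |theta_hat - theta_true| /
#' theta_true, where theta_hat is the posterior median from
#' [estimate_parameters()].  Values above 0.2 are conventionally
#' flagged as not fully reliable.
#'
#' @inheritParams estimate_parameters
#' @param n_pods number of pseudo-observed datasets.
#' @param seed RNG seed.
#' @param flag_threshold RMAE above this is flagged.
#' @param estimator optional replacement estimator
#'   `function(rt, winner, observed, tolerance, truth)` returning a
#'   named vector of point estimates; used to validate the RMAE
#'   machinery itself (e.g. a perfect or a prior-median estimator).
#'   `NULL` uses the ABC posterior median.
#' @return data frame: parameter, rmae, flagged.
#' @export
parameter_rmae <- function(rt, winner, n_pods = 50L, tolerance = 0.01,
                           seed = 1L, flag_threshold = 0.2,
                           estimator = NULL) {
  stopifnot(inherits(rt, "mt_reftable"))
  set.seed(seed)
  s <- rt$scenarios[[match(winner, vapply(rt$scenarios, `[[`, "", "id"))]]
  syms <- c(.scenario_symbols(s), "mu", "kappa")
  err <- matrix(NA_real_, n_pods, length(syms),
                dimnames = list(NULL, syms))
  for (i in seq_len(n_pods)) {
    pars <- draw_params(s, rt$priors)
    sim <- simulate_dataset(s, pars, rt$samples, rt$L, as_alignment = FALSE)
    obs <- summary_stats(sim, pops = rt$pops)
    med <- if (is.null(estimator)) {
      post <- suppressWarnings(estimate_parameters(rt, winner, obs, tolerance))
      stats::setNames(post$summary$median, post$summary$parameter)
    } else {
      estimator(rt, winner, obs, tolerance, unlist(pars))
    }
    for (sym in syms) {
      tv <- pars[[sym]]
      if (is.null(tv) || tv == 0) next  # zero truth -> skipped
      err[i, sym] <- abs(med[[sym]] - tv) / tv
    }
  }
  rmae <- apply(err, 2L, stats::median, na.rm = TRUE)
  data.frame(parameter = syms, rmae = rmae,
             flagged = rmae > flag_threshold, row.names = NULL)
}

#' Posterior-predictive goodness of fit of the winner scenario
#'
#' Simulates `n_ppc` datasets with parameters resampled from the
#' adjusted posterior and reports, per summary statistic, the two-sided
#' tail probability of the observed value in the posterior-predictive
#' distribution (with the (r+1)/(n+1) finite-sample convention).
#'
#' @param rt an `mt_reftable`.
#' @param posterior an `mt_posterior` from [estimate_parameters()].
#' @param observed observed summary-statistic vector.
#' @param n_ppc number of posterior-predictive simulations.
#' @param seed RNG seed.
#' @return data frame: statistic, observed, tail_prob.
#' @export
goodness_of_fit <- function(rt, posterior, observed, n_ppc = 200L, seed = 1L) {
  stopifnot(inherits(rt, "mt_reftable"), inherits(posterior, "mt_posterior"))
  if (n_ppc <= 0L) stop("n_ppc must be positive", call. = FALSE)
  set.seed(seed)
  s <- rt$scenarios[[match(posterior$winner,
                           vapply(rt$scenarios, `[[`, "", "id"))]]
  sims <- matrix(NA_real_, n_ppc, ncol(rt$stats),
                 dimnames = list(NULL, colnames(rt$stats)))
  ## regression adjustment acts per parameter, so a few adjusted rows
  ## can break ordering constraints; resample among the valid ones
  valid <- which(vapply(seq_len(nrow(posterior$sample)), function(r)
    is.null(.check_constraints(s, as.list(posterior$sample[r, ]))), TRUE))
  if (!length(valid))
    stop("no posterior draw satisfies the scenario constraints", call. = FALSE)
  rows <- valid[sample.int(length(valid), n_ppc, replace = TRUE,
                           prob = posterior$weights[valid])]
  for (i in seq_len(n_ppc)) {
    pars <- as.list(posterior$sample[rows[i], ])
    sim <- simulate_dataset(s, pars, rt$samples, rt$L, as_alignment = FALSE)
    sims[i, ] <- summary_stats(sim, pops = rt$pops)
  }
  tail_prob <- vapply(seq_len(ncol(sims)), function(j) {
    lo <- (sum(sims[, j] <= observed[j]) + 1) / (n_ppc + 1)
    hi <- (sum(sims[, j] >= observed[j]) + 1) / (n_ppc + 1)
    min(1, 2 * min(lo, hi))
  }, numeric(1))
  data.frame(statistic = colnames(sims), observed = as.numeric(observed),
             tail_prob = tail_prob, row.names = NULL)
}
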