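#' Confusion-matrix metrics for one replicate
#'
#' Scores per-subnetwork detection calls against the simulation truth
#' (positives = phenotype-specific subnetworks). Precision is \code{NaN}
#' when no subnetwork is called (no positive predictions); the F-measure is
#' \code{2 * precision * TPR / (precision + TPR)} and \code{NaN} whenever
#' precision is undefined or both terms are zero.
#'
#' @param calls Logical vector of per-subnetwork decisions.
#' @param truth Logical vector of per-subnetwork ground truth.
#' @return Named numeric vector: \code{accuracy}, \code{precision},
#'   \code{tpr}, \code{tnr}, \code{f_measure}.
#' @export
score_replicate <- function(calls, truth) {
  stopifnot(length(calls) == length(truth))
  calls <- as.logical(calls)
  truth <- as.logical(truth)
  tp <- sum(calls & truth)
  fp <- sum(calls & !truth)
  tn <- sum(!calls & !truth)
  fn <- sum(!calls & truth)
  accuracy <- (tp + tn) / length(truth)
  precision <- if (tp + fp == 0) NaN else tp / (tp + fp)
  tpr <- if (tp + fn == 0) NaN else tp / (tp + fn)
  tnr <- if (tn + fp == 0) NaN else tn / (tn + fp)
  f <- if (is.nan(precision) || (precision + tpr) == 0) NaN else
    2 * precision * tpr / (precision + tpr)
  c(accuracy = accuracy, precision = precision, tpr = tpr, tnr = tnr,
    f_measure = f)
}

#' Run one simulated replicate through one or more detectors
#'
#' Simulates a panel from \code{config}, runs each requested method's
#' per-subnetwork test at level \code{alpha}, and scores the calls against
#' the panel's truth.
#'
#' @param config A \code{sim_config} (its seed governs the panel).
#' @param methods Character subset of \code{c("celldgn", "samgs", "gsca",
#'   "dgndetector")}.
#' @param T Permutations per test (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param query_policy Query policy for the KL-ratio test.
#' @param lambda,lambda_selection,bandwidth Estimation controls passed to
#'   \code{\link{estimate_networks}} (celldgn only). The defaults are the
#'   simulation study's settings: adaptive nearest-neighbour bandwidths and
#'   a fixed penalty of 0.1.
#' @return Data frame with one row per method: the five metrics plus
#'   bookkeeping columns.
#' @export
run_replicate <- function(config,
                          methods = c("celldgn", "samgs", "gsca",
                                      "dgndetector"),
                          T = 1000L, alpha = 0.05,
                          query_policy = "extreme",
                          lambda = 0.1, lambda_selection = "fixed",
                          bandwidth = "adaptive") {
  methods <- match.arg(methods, several.ok = TRUE)
  panel <- simulate_panel(config)
  ph <- pheno_indices(panel)
  networks <- NULL
  test_seed <- config$seed + 1L

  rows <- lapply(methods, function(method) {
    if (method == "celldgn") {
      if (is.null(networks)) {
        networks <<- estimate_networks(panel$expression, panel$modulator,
                                       cells = sort(c(ph$A, ph$B)),
                                       bandwidth = bandwidth,
                                       lambda = lambda,
                                       lambda_selection = lambda_selection)
      }
      calls <- call_dgns(networks, panel$expression, panel$partition,
                         ph$A, ph$B, modulator = panel$modulator,
                         query_policy = query_policy,
                         T = T, alpha = alpha, seed = test_seed)$significant
    } else {
      calls <- baseline_test(panel$expression, panel$partition, ph$A, ph$B,
                             method = method, T = T, alpha = alpha,
                             seed = test_seed)$significant
    }
    metrics <- score_replicate(calls, panel$truth)
    cbind(data.frame(method = method, topology = config$topology,
                     mu_B = config$mu_B, p = config$p,
                     seed = config$seed, stringsAsFactors = FALSE),
          as.data.frame(as.list(metrics)))
  })
  do.call(rbind, rows)
}

#' Monte Carlo evaluation grid over scenarios, topologies and methods
#'
#' Replicates the simulation study's metric grid: for each combination of
#' topology and mean-shift scenario, \code{reps} independent panels are
#' simulated, each method's per-subnetwork calls are scored, and metrics are
#' averaged over replicates (per-replicate averaging; \code{NaN} metrics are
#' dropped from the average). Monte Carlo standard errors accompany every
#' mean.
#'
#' @param topologies Character vector of topologies.
#' @param mu_Bs Numeric vector of phenotype-B mean shifts (scenarios).
#' @param methods Methods to run (see \code{\link{run_replicate}}).
#' @param reps Replicates per grid cell (default 100).
#' @param p,n,n_A,n_B,n_subnetworks Panel dimensions (defaults 100 genes,
#'   120 cells, 40/40 phenotype split, 10 subnetworks).
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @param T,alpha,query_policy,lambda,lambda_selection,bandwidth Passed to
#'   \code{\link{run_replicate}}.
#' @param verbose Print progress (default \code{FALSE}).
#' @return Data frame of class \code{metric_table}: one row per
#'   (topology, mu_B, method) with metric means, standard errors and
#'   replicate counts.
#' @export
run_grid <- function(topologies = c("random", "scale_free", "hub", "cluster",
                                    "band"),
                     mu_Bs = c(0, 1, 5),
                     methods = c("celldgn", "samgs", "gsca", "dgndetector"),
                     reps = 100L, p = 100L, n = 120L, n_A = 40L, n_B = 40L,
                     n_subnetworks = 10L, seed = 1L, T = 1000L, alpha = 0.05,
                     query_policy = "extreme", lambda = 0.1,
                     lambda_selection = "fixed", bandwidth = "adaptive",
                     verbose = FALSE) {
  if (reps < 1) stop("'reps' must be at least 1", call. = FALSE)
  set.seed(seed)
  cells <- expand.grid(topology = topologies, mu_B = mu_Bs,
                       stringsAsFactors = FALSE)
  rep_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 nrow(cells) * reps),
                      nrow(cells), reps)
  out <- list()
  for (ci in seq_len(nrow(cells))) {
    topo <- cells$topology[ci]
    mu <- cells$mu_B[ci]
    per_rep <- list()
    for (r in seq_len(reps)) {
      cfg <- sim_config(n = n, n_A = n_A, n_B = n_B, p = p,
                        n_subnetworks = n_subnetworks, topology = topo,
                        mu_B = mu, seed = rep_seeds[ci, r])
      res <- tryCatch(
        run_replicate(cfg, methods = methods, T = T, alpha = alpha,
                      query_policy = query_policy, lambda = lambda,
                      lambda_selection = lambda_selection,
                      bandwidth = bandwidth),
        error = function(e) {
          warning(sprintf("replicate dropped (%s, mu_B=%g, rep %d): %s",
                          topo, mu, r, conditionMessage(e)))
          NULL
        })
      per_rep[[r]] <- res
      if (verbose)
        message(sprintf("  %s mu_B=%g rep %d/%d done", topo, mu, r, reps))
    }
    all_rep <- do.call(rbind, per_rep)
    if (is.null(all_rep)) next
    metric_cols <- c("accuracy", "precision", "tpr", "tnr", "f_measure")
    for (method in unique(all_rep$method)) {
      sub <- all_rep[all_rep$method == method, metric_cols, drop = FALSE]
      means <- vapply(sub, function(v) mean(v[!is.nan(v)]), numeric(1))
      ses <- vapply(sub, function(v) {
        v <- v[!is.nan(v)]
        if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
      }, numeric(1))
      row <- data.frame(topology = topo, mu_B = mu, method = method,
                        reps = nrow(sub), stringsAsFactors = FALSE)
      row[metric_cols] <- as.list(means)
      row[paste0(metric_cols, "_se")] <- as.list(ses)
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("metric_table", "data.frame")
  attr(res, "seed") <- seed
  res
}
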