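#' SAM-GS gene-set statistic
#'
#' Sum over genes of the squared mean difference between the two phenotypes,
#' divided by a variance-stabilised gene-specific scatter:
#' \code{sum_j (xbar_j - ybar_j)^2 / (s_j + s0)} with
#' \code{s_j = sqrt(a * (SS_x + SS_y))},
#' \code{a = (1/nA + 1/nB) / (nA + nB - 2)}. Large values flag gene sets with
#' mean-expression differences between phenotypes.
#'
#' @param X \code{nA x p} expression matrix of phenotype A.
#' @param Y \code{nB x p} expression matrix of phenotype B (same gene order).
#' @param s0 Variance-stabilisation constant; default: median of the
#'   \code{s_j} over the set's genes.
#' @return Nonnegative scalar.
#' @export
samgs_statistic <- function(X, Y, s0 = NULL) {
  check_two_group(X, Y)
  nA <- nrow(X)
  nB <- nrow(Y)
  a <- (1 / nA + 1 / nB) / (nA + nB - 2)
  xbar <- colMeans(X)
  ybar <- colMeans(Y)
  ssx <- colSums(sweep(X, 2L, xbar)^2)
  ssy <- colSums(sweep(Y, 2L, ybar)^2)
  sj <- sqrt(a * (ssx + ssy))
  if (is.null(s0)) s0 <- stats::median(sj)
  if (s0 < 0) stop("'s0' must be nonnegative", call. = FALSE)
  denom <- pmax(sj + s0, 1e-12)
  sum((xbar - ybar)^2 / denom)
}

#' GSCA differential co-expression statistic
#'
#' Mean over the \code{p * (p - 1)} ordered gene pairs of the squared
#' difference in Pearson correlation between the two phenotypes. Constant
#' genes contribute zero correlations.
#'
#' @inheritParams samgs_statistic
#' @return Nonnegative scalar.
#' @export
gsca_statistic <- function(X, Y) {
  check_two_group(X, Y)
  p <- ncol(X)
  if (p < 2) stop("'X' and 'Y' need at least 2 genes", call. = FALSE)
  cA <- safe_cor(X)
  cB <- safe_cor(Y)
  d <- (cA - cB)^2
  diag(d) <- 0
  sum(d) / (p * (p - 1))
}

safe_cor <- function(X) {
  sds <- apply(X, 2L, stats::sd)
  cc <- suppressWarnings(stats::cor(X))
  cc[is.na(cc)] <- 0
  if (any(sds == 0)) cc[sds == 0, ] <- cc[, sds == 0] <- 0
  diag(cc) <- 1
  cc
}

#' Pool a phenotype's cell lines into one Gaussian network summary
#'
#' Phenotype-level summary used by the pooled Gaussian KL detector: mean is
#' the per-gene average, covariance is the sample covariance of the group's
#' cell lines (PD-repaired when needed). By default the summary is put on
#' the same scale-free basis used throughout the package for network
#' comparison: the covariance is reduced to its correlation matrix and the
#' mean divided by the per-gene standard deviations, so the divergence
#' reflects co-regulation structure and standardized mean shifts rather
#' than amplitude.
#'
#' @param X \code{n x p} expression matrix of one phenotype's cell lines.
#' @param standardize Scale-free summary (default \code{TRUE}).
#' @param eps PD-repair eigenvalue floor.
#' @return A \code{gaussian_summary}.
#' @export
pooled_summary <- function(X, standardize = TRUE, eps = 1e-6) {
  mu <- colMeans(X)
  sig <- repair_pd(stats::cov(X), eps)
  if (standardize) {
    s <- sqrt(diag(sig))
    mu <- mu / s
    sig <- sig / (s %o% s)
  }
  gaussian_summary(mu, sig, check = FALSE)
}

#' Pooled Gaussian KL detector statistic
#'
#' Kullback-Leibler divergence between the two phenotype-level Gaussian
#' summaries: each phenotype is represented by a single pooled distribution
#' and their divergence \code{KL(A || B)} measures how far the two
#' phenotype-level networks (means plus covariance structure) are apart.
#'
#' @inheritParams samgs_statistic
#' @param summary_A,summary_B Optional precomputed \code{gaussian_summary}
#'   objects; when supplied, \code{X}/\code{Y} are ignored.
#' @return Nonnegative scalar.
#' @export
dgn_detector_statistic <- function(X = NULL, Y = NULL,
                                   summary_A = NULL, summary_B = NULL) {
  if (is.null(summary_A)) summary_A <- pooled_summary(X)
  if (is.null(summary_B)) summary_B <- pooled_summary(Y)
  gaussian_kl(summary_A, summary_B)
}

#' Permutation p-value for a two-group baseline statistic
#'
#' Shuffles the row labels of the pooled expression matrix (preserving group
#' sizes), recomputes the statistic for each shuffle and reports the
#' upper-tail p-value \code{#(observed <= permuted) / T}.
#'
#' @param statistic_fn Function \code{(X, Y) -> scalar}.
#' @param X,Y The two phenotype matrices.
#' @param T Number of permutations (default 1000).
#' @param seed Optional integer seed.
#' @param alpha Significance level (default 0.05).
#' @return List with \code{statistic}, \code{perm_stats}, \code{p_value},
#'   \code{significant}.
#' @export
baseline_permutation <- function(statistic_fn, X, Y, T = 1000L, seed = NULL,
                                 alpha = 0.05) {
  if (T < 1) stop("'T' must be at least 1", call. = FALSE)
  check_two_group(X, Y)
  if (!is.null(seed)) set.seed(seed)
  obs <- statistic_fn(X, Y)
  pooled <- rbind(X, Y)
  nA <- nrow(X)
  n <- nrow(pooled)
  perm_stats <- vapply(seq_len(T), function(t) {
    idx <- sample.int(n, nA)
    statistic_fn(pooled[idx, , drop = FALSE], pooled[-idx, , drop = FALSE])
  }, numeric(1))
  p <- sum(obs <= perm_stats) / T
  list(statistic = obs, perm_stats = perm_stats, p_value = p,
       significant = p < alpha)
}

check_two_group <- function(X, Y) {
  if (!is.matrix(X) || !is.matrix(Y) || ncol(X) != ncol(Y))
    stop("'X' and 'Y' must be matrices with a shared gene order",
         call. = FALSE)
  if (nrow(X) < 2 || nrow(Y) < 2)
    stop("both phenotypes need at least 2 cell lines", call. = FALSE)
  invisible(NULL)
}

#' Run a baseline detector across a subnetwork partition
#'
#' Applies one of the two-group baseline statistics blockwise with a
#' permutation null, mirroring the KL-ratio caller's interface so all
#' methods feed the same evaluation pipeline.
#'
#' @param expression \code{n x p} expression matrix.
#' @param partition List of gene-index blocks.
#' @param pheno_A,pheno_B Phenotype index sets (rows of \code{expression}).
#' @param method \code{"samgs"}, \code{"gsca"} or \code{"dgndetector"}.
#' @param T Number of permutations (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed (default 1).
#' @return Data frame with one row per block: \code{subnetwork},
#'   \code{n_genes}, \code{statistic}, \code{p_value}, \code{significant}.
#' @export
baseline_test <- function(expression, partition, pheno_A, pheno_B,
                          method = c("samgs", "gsca", "dgndetector"),
                          T = 1000L, alpha = 0.05, seed = 1L) {
  method <- match.arg(method)
  stat_fn <- switch(method,
                    samgs = samgs_statistic,
                    gsca = gsca_statistic,
                    dgndetector = function(X, Y) dgn_detector_statistic(X, Y))
  set.seed(seed)
  rows <- lapply(seq_along(partition), function(nw) {
    genes <- partition[[nw]]
    id <- if (!is.null(names(partition))) names(partition)[nw] else
      as.character(nw)
    X <- expression[pheno_A, genes, drop = FALSE]
    Y <- expression[pheno_B, genes, drop = FALSE]
    res <- baseline_permutation(stat_fn, X, Y, T = T, alpha = alpha)
    data.frame(subnetwork = id, n_genes = length(genes),
               statistic = res$statistic, p_value = res$p_value,
               significant = res$significant, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "method") <- method
  out
}
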