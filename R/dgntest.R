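#' Between-phenotype heterogeneity of a query network
#'
#' Mean KL divergence from the query cell line's network summary to the
#' network summaries of the opposite phenotype's cell lines.
#'
#' @param query Index of the query cell line (must not belong to
#'   \code{pheno_A}).
#' @param summaries List of \code{gaussian_summary} objects indexed by cell
#'   line.
#' @param pheno_A Nonempty integer index set of the opposite phenotype.
#' @return Nonnegative scalar.
#' @export
d_between <- function(query, summaries, pheno_A) {
  if (length(pheno_A) == 0)
    stop("'pheno_A' must be nonempty", call. = FALSE)
  if (query %in% pheno_A)
    stop("the query cell must not belong to 'pheno_A'", call. = FALSE)
  mean(vapply(pheno_A,
              function(i) gaussian_kl(summaries[[query]], summaries[[i]]),
              numeric(1)))
}

#' Within-phenotype homogeneity of a query network
#'
#' Mean KL divergence from the query network summary to the summaries of its
#' own phenotype's cell lines. When the query belongs to the set, its
#' self-divergence (zero) is included in the average, matching the plain sum
#' over the phenotype.
#'
#' @inheritParams d_between
#' @param pheno_B Nonempty integer index set of the query's phenotype.
#' @return Nonnegative scalar.
#' @export
d_within <- function(query, summaries, pheno_B) {
  if (length(pheno_B) == 0)
    stop("'pheno_B' must be nonempty", call. = FALSE)
  mean(vapply(pheno_B,
              function(j) {
                if (j == query) 0
                else gaussian_kl(summaries[[query]], summaries[[j]])
              },
              numeric(1)))
}

#' KL-divergence ratio statistic
#'
#' \code{d_between / d_within}: between-phenotype heterogeneity over
#' within-phenotype homogeneity. Large values indicate that the query network
#' differs from the opposite phenotype while recurring within its own
#' phenotype, i.e. that the subnetwork is phenotype-specific. When the
#' within term is below \code{eps} the ratio is \code{Inf} (with a warning).
#'
#' @inheritParams d_between
#' @param pheno_B Index set of the query's phenotype.
#' @param eps Degeneracy guard on the denominator.
#' @return Scalar ratio (possibly \code{Inf}).
#' @export
kl_ratio <- function(query, summaries, pheno_A, pheno_B, eps = 1e-12) {
  db <- d_between(query, summaries, pheno_A)
  dw <- d_within(query, summaries, pheno_B)
  if (dw < eps) {
    warning("within-phenotype divergence is degenerate; returning Inf")
    return(Inf)
  }
  db / dw
}

# KL from the query to every cell in `cells` (query itself contributes 0).
kl_to_cells <- function(query, summaries, cells) {
  vapply(cells, function(i) {
    if (i == query) 0 else gaussian_kl(summaries[[query]], summaries[[i]])
  }, numeric(1))
}

# Permutation index matrix: each row selects n_A of the pooled non-query
# cells (positions into `pool`) to act as phenotype A.
permutation_matrix <- function(n_pool, n_A, T) {
  t(vapply(seq_len(T), function(i) sample.int(n_pool, n_A), integer(n_A)))
}

#' Permutation test of the KL-ratio for one subnetwork
#'
#' Computes the observed KL-ratio of the query cell line and its permutation
#' null: phenotype labels of the pooled comparison cells are reshuffled
#' preserving the group sizes, while the query keeps its role (it always
#' counts in its own phenotype). All pairwise divergences from the query are
#' computed once and reused across permutations. The p-value is the fraction
#' of permuted ratios at or above the observed one; with \code{smooth = TRUE}
#' the conventional \code{(1 + #exceed) / (1 + T)} variant is used instead.
#'
#' @inheritParams kl_ratio
#' @param pheno_B Index set of the query's phenotype (must contain
#'   \code{query}).
#' @param T Number of permutations (at least 1; default 1000).
#' @param alpha Significance level (default 0.05).
#' @param seed Optional integer seed.
#' @param smooth Use the add-one smoothed p-value (default \code{FALSE}).
#' @return A \code{dgn_result}: list with \code{query}, \code{d_between},
#'   \code{d_within}, \code{ratio}, \code{perm_stats}, \code{p_value},
#'   \code{significant}.
#' @export
permutation_test <- function(query, summaries, pheno_A, pheno_B, T = 1000L,
                             alpha = 0.05, seed = NULL, smooth = FALSE) {
  if (T < 1) stop("'T' must be at least 1", call. = FALSE)
  if (!(query %in% pheno_B))
    stop("the query cell must belong to 'pheno_B'", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  others_B <- setdiff(pheno_B, query)
  pool <- c(pheno_A, others_B)
  kl_pool <- kl_to_cells(query, summaries, pool)
  n_A <- length(pheno_A)
  n_B <- length(pheno_B)
  obs_between <- mean(kl_pool[seq_len(n_A)])
  obs_within <- sum(kl_pool[-seq_len(n_A)]) / n_B   # + self term 0
  obs <- ratio_or_inf(obs_between, obs_within)
  perm <- permutation_matrix(length(pool), n_A, T)
  perm_stats <- perm_ratios(kl_pool, perm, n_A, n_B)
  p_value <- if (smooth) {
    (1 + sum(obs <= perm_stats)) / (1 + T)
  } else {
    sum(obs <= perm_stats) / T
  }
  structure(list(query = query, d_between = obs_between,
                 d_within = obs_within, ratio = obs,
                 perm_stats = perm_stats, p_value = p_value,
                 significant = p_value < alpha, alpha = alpha, T = T),
            class = "dgn_result")
}

ratio_or_inf <- function(db, dw, eps = 1e-12) {
  if (dw < eps) Inf else db / dw
}

# Ratios for each permutation row: columns of `perm` index into kl_pool for
# the permuted A group; the rest of the pool plus the query form permuted B.
perm_ratios <- function(kl_pool, perm, n_A, n_B) {
  total <- sum(kl_pool)
  apply(perm, 1L, function(sel) {
    between <- sum(kl_pool[sel])
    ratio_or_inf(between / n_A, (total - between) / n_B)
  })
}

#' @export
print.dgn_result <- function(x, ...) {
  cat(sprintf(
    "dgn_result: query %s, ratio = %.3f (between %.3f / within %.3f), p = %.4g%s\n",
    as.character(x$query), x$ratio, x$d_between, x$d_within, x$p_value,
    if (x$significant) " *" else ""))
  invisible(x)
}

#' Identify differentially regulated subnetworks across a partition
#'
#' Runs the KL-ratio permutation test on every gene block of a partition.
#' For each block, every labelled cell line's network is restricted to the
#' block's genes (\code{\link{block_summary}}), the query cell is chosen by
#' \code{query_policy}, and the permutation test is applied. With policy
#' \code{"extreme"} the query is the focal-phenotype cell with the most
#' extreme modulator (the last B cell); with \code{"median_all"} every
#' focal-phenotype cell serves as query and the per-permutation statistic is
#' the median ratio across queries.
#'
#' @param networks A \code{cell_line_networks} list (indexed by cell line).
#' @param expression The \code{n x p} expression matrix the networks were
#'   estimated from.
#' @param partition List of gene-index blocks.
#' @param pheno_A,pheno_B Integer index sets of the two phenotypes; B is the
#'   focal phenotype supplying the query.
#' @param modulator Optional modulator vector used to pick the extreme query
#'   (default: highest index in \code{pheno_B}).
#' @param query_policy \code{"extreme"} (default) or \code{"median_all"}.
#' @param T Number of permutations (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed (default 1).
#' @param block_from Covariance restriction rule passed to
#'   \code{\link{block_summary}}.
#' @param block_standardize Compare scale-free network summaries (see
#'   \code{\link{block_summary}}; default \code{TRUE}).
#' @param adjust Optional multiple-testing adjustment across blocks
#'   (\code{"none"}, default, or \code{"BH"}).
#' @return Data frame of class \code{dgn_calls} with one row per tested
#'   block: \code{subnetwork}, \code{n_genes}, \code{query},
#'   \code{d_between}, \code{d_within}, \code{ratio}, \code{p_value},
#'   \code{significant}. Blocks with fewer than 2 genes are skipped with a
#'   message.
#' @export
call_dgns <- function(networks, expression, partition, pheno_A, pheno_B,
                      modulator = NULL,
                      query_policy = c("extreme", "median_all"),
                      T = 1000L, alpha = 0.05, seed = 1L,
                      block_from = c("precision", "covariance"),
                      block_standardize = TRUE,
                      adjust = c("none", "BH")) {
  query_policy <- match.arg(query_policy)
  block_from <- match.arg(block_from)
  adjust <- match.arg(adjust)
  if (!length(partition) || any(!vapply(partition, length, 0L)))
    stop("'partition' blocks must be nonempty", call. = FALSE)
  set.seed(seed)

  have <- as.integer(names(networks))
  labelled <- sort(c(pheno_A, pheno_B))
  if (!all(labelled %in% have))
    stop("networks are missing for some labelled cell lines", call. = FALSE)

  query_star <- if (!is.null(modulator)) {
    pheno_B[which.max(modulator[pheno_B])]
  } else {
    max(pheno_B)
  }
  n_A <- length(pheno_A)
  n_B <- length(pheno_B)

  # one shared set of label permutations across blocks
  if (query_policy == "extreme") {
    pool <- c(pheno_A, setdiff(pheno_B, query_star))
    perm <- permutation_matrix(length(pool), n_A, T)
  } else {
    perm <- permutation_matrix(n_A + n_B, n_A, T)
  }

  rows <- lapply(seq_along(partition), function(nw) {
    genes <- partition[[nw]]
    id <- if (!is.null(names(partition))) names(partition)[nw] else
      as.character(nw)
    if (length(genes) < 2L) {
      message(sprintf("subnetwork %s has fewer than 2 genes; skipped", id))
      return(NULL)
    }
    summaries <- vector("list", nrow(expression))
    for (i in labelled) {
      summaries[[i]] <- block_summary(networks[[as.character(i)]],
                                      expression[i, ], genes,
                                      from = block_from,
                                      standardize = block_standardize)
    }
    if (query_policy == "extreme") {
      kl_pool <- kl_to_cells(query_star, summaries, pool)
      between <- mean(kl_pool[seq_len(n_A)])
      within <- sum(kl_pool[-seq_len(n_A)]) / n_B
      obs <- ratio_or_inf(between, within)
      perm_stats <- perm_ratios(kl_pool, perm, n_A, n_B)
    } else {
      res <- median_ratio_stats(summaries, pheno_A, pheno_B, perm)
      between <- res$between
      within <- res$within
      obs <- res$obs
      perm_stats <- res$perm_stats
    }
    p <- sum(obs <= perm_stats) / T
    data.frame(subnetwork = id, n_genes = length(genes),
               query = query_star, d_between = between, d_within = within,
               ratio = obs, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- if (adjust == "BH") stats::p.adjust(out$p_value, "BH")
                    else out$p_value
  out$significant <- out$p_adjusted < alpha
  class(out) <- c("dgn_calls", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "T") <- T
  attr(out, "query_policy") <- query_policy
  out
}

# Median-over-queries mode: full pairwise KL matrix from every B cell to all
# labelled cells; the statistic is the median of per-query ratios, and each
# permutation relabels the pooled cells (queries keep counting themselves in
# their own group).
median_ratio_stats <- function(summaries, pheno_A, pheno_B, perm) {
  cells <- c(pheno_A, pheno_B)
  n_A <- length(pheno_A)
  n_B <- length(pheno_B)
  K <- t(vapply(pheno_B, function(q) kl_to_cells(q, summaries, cells),
                numeric(length(cells))))
  a_cols <- seq_len(n_A)
  between_q <- rowMeans(K[, a_cols, drop = FALSE])
  within_q <- rowSums(K[, -a_cols, drop = FALSE]) / n_B
  obs_q <- ifelse(within_q < 1e-12, Inf, between_q / within_q)
  tot <- rowSums(K)
  perm_stats <- apply(perm, 1L, function(sel) {
    btw <- rowSums(K[, sel, drop = FALSE])
    stats::median(ifelse((tot - btw) / n_B < 1e-12, Inf,
                         (btw / n_A) / ((tot - btw) / n_B)))
  })
  list(between = stats::median(between_q), within = stats::median(within_q),
       obs = stats::median(obs_q), perm_stats = perm_stats)
}
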