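#' Configuration for a synthetic cell line panel
#'
#' Bundles the design of the two-phenotype simulation: \code{n} cell lines
#' ordered by a continuous modulator drawn from U(0, 3), split into the
#' \code{n_A} lowest-modulator cells (phenotype A), the \code{n_B}
#' highest-modulator cells (phenotype B) and an unassigned intermediate band;
#' \code{p} genes partitioned into \code{n_subnetworks} equal blocks, the
#' first half common to both phenotypes and the second half phenotype-specific.
#' Common and A-side specific blocks take \code{topology}; B-side specific
#' blocks are banded. When \code{topology = "band"} the B-side matrix is
#' instead derived from the A-side banded matrix by removing half of its edges
#' (the shared-band scenario), so that the phenotypes differ only by rewiring
#' within one topology class.
#'
#' @param n Total number of cell lines (default 120).
#' @param n_A,n_B Phenotype group sizes (defaults 40 and 40; the remaining
#'   cells are intermediate and belong to neither phenotype).
#' @param p Total number of genes (default 100).
#' @param n_subnetworks Number of equal-sized gene blocks (default 10; must be
#'   even and divide \code{p}).
#' @param topology Topology of the common and A-specific blocks: one of
#'   \code{"random"}, \code{"scale_free"}, \code{"hub"}, \code{"cluster"},
#'   \code{"band"}.
#' @param mu_B Mean shift applied to phenotype-B cells on the specific blocks
#'   (scenarios use 0, 1 or 5; default 0).
#' @param edge_weight Edge weight of generated precision matrices.
#' @param diag_jitter Diagonal loading of generated precision matrices.
#' @param degrade_fraction Fraction of A-side edges removed to build the
#'   B-side matrix in the shared-band scenario (default 0.5).
#' @param v_min Floor applied to the per-cell precision scale factors to keep
#'   every scaled matrix safely invertible (default 0.05).
#' @param seed Integer seed governing every random draw of the panel.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n = 120L, n_A = 40L, n_B = 40L, p = 100L,
                       n_subnetworks = 10L,
                       topology = c("random", "scale_free", "hub", "cluster",
                                    "band"),
                       mu_B = 0, edge_weight = 0.3, diag_jitter = 0.1,
                       degrade_fraction = 0.5, v_min = 0.05, seed = 1L) {
  topology <- match.arg(topology)
  if (p %% n_subnetworks != 0)
    stop("'p' must be a multiple of 'n_subnetworks'", call. = FALSE)
  if (n_subnetworks %% 2 != 0)
    stop("'n_subnetworks' must be even (half common, half specific)",
         call. = FALSE)
  if (n_A + n_B > n)
    stop("'n_A' + 'n_B' must not exceed 'n'", call. = FALSE)
  structure(list(n = as.integer(n), n_A = as.integer(n_A),
                 n_B = as.integer(n_B), p = as.integer(p),
                 n_subnetworks = as.integer(n_subnetworks),
                 genes_per_subnetwork = as.integer(p / n_subnetworks),
                 topology = topology, mu_B = mu_B,
                 edge_weight = edge_weight, diag_jitter = diag_jitter,
                 degrade_fraction = degrade_fraction,
                 v_min = v_min, seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw sorted modulator values
#'
#' Cell line modulators (e.g. log IC50 surrogates) are drawn i.i.d. from
#' U(0, 3) and sorted increasingly, so cell index order equals modulator
#' order.
#'
#' @param n Number of cell lines (at least 2).
#' @param seed Optional integer seed.
#' @return Strictly increasing numeric vector of length \code{n} in (0, 3).
#' @export
draw_modulators <- function(n, seed = NULL) {
  if (n < 2) stop("'n' must be at least 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  m <- sort(stats::runif(n, 0, 3))
  while (any(diff(m) <= 0)) {       # ties have probability 0 but are repaired
    m <- m + cumsum(c(0, diff(m) <= 0)) * 1e-12
  }
  m
}

#' Scale one baseline precision matrix into cell line-specific matrices
#'
#' Each cell line receives \code{Omega_i = v_i * base} where the scale factors
#' \code{v_i} are drawn i.i.d. from U(0, 3) and then rank-matched to the
#' modulator (sorted so that \code{v} increases with \code{m}). All matrices
#' share the baseline's sparsity pattern; only interaction strengths differ.
#' Scales are floored at \code{v_min} so every matrix stays well-conditioned.
#'
#' @param base A positive-definite \code{precision_matrix}.
#' @param modulator Numeric modulator vector, one value per cell line.
#' @param seed Optional integer seed.
#' @param v_min Floor for the scale factors (default 0.05).
#' @return List with \code{matrices} (one precision matrix per cell line) and
#'   \code{v} (the applied scale factors).
#' @export
cellline_precisions <- function(base, modulator, seed = NULL, v_min = 0.05) {
  if (!is_positive_definite(base))
    stop("'base' must be positive definite", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  v <- draw_scales(length(modulator), modulator, v_min)
  mats <- lapply(v, function(vi) new_precision(vi * unclass_matrix(base),
                                               topology = "scaled"))
  list(matrices = mats, v = v)
}

# i.i.d. U(0,3) scales rank-matched to the modulator, floored at v_min
draw_scales <- function(n, modulator, v_min) {
  v <- sort(stats::runif(n, 0, 3))[rank(modulator, ties.method = "first")]
  pmax(v, v_min)
}

#' Simulate a full two-phenotype cell line panel
#'
#' Generates modulators, baseline block precision matrices, per-cell scale
#' factors and multivariate-normal expression for every cell line. Common
#' blocks use the shared baseline for all cells with mean zero; specific
#' blocks use the A-side baseline (mean 0) for phenotype-A and intermediate
#' cells and the B-side baseline (mean \code{mu_B} on every gene) for
#' phenotype-B cells. Expression for cell \code{i} on a block with baseline
#' \code{Omega} is drawn from \code{N(mu, (v_i * Omega)^{-1})}.
#'
#' @param config A \code{sim_config}.
#' @return A list of class \code{cell_line_panel} with elements
#'   \code{expression} (\code{n x p} matrix), \code{modulator},
#'   \code{labels} (factor with levels A, unassigned, B), \code{partition}
#'   (list of gene-index blocks), \code{truth} (logical, \code{TRUE} for
#'   phenotype-specific blocks), \code{v} (scale factors), \code{bases}
#'   (the baseline precision matrices) and \code{config}.
#' @examples
#' panel <- simulate_panel(sim_config(n = 30, n_A = 10, n_B = 10, p = 20,
#'                                    n_subnetworks = 2, seed = 7))
#' dim(panel$expression)
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n
  k <- config$genes_per_subnetwork
  nsub <- config$n_subnetworks
  n_common <- nsub %/% 2L

  m <- draw_modulators(n)
  v <- draw_scales(n, m, config$v_min)

  labels <- factor(rep("unassigned", n),
                   levels = c("A", "unassigned", "B"))
  labels[seq_len(config$n_A)] <- "A"
  labels[seq.int(n - config$n_B + 1L, n)] <- "B"

  gen_base <- function(topology) {
    adjacency_to_precision(generate_adjacency(k, topology),
                           edge_weight = config$edge_weight,
                           diag_jitter = config$diag_jitter)
  }
  shared_band <- config$topology == "band"
  common <- replicate(n_common, gen_base(config$topology), simplify = FALSE)
  base_A <- replicate(nsub - n_common, gen_base(config$topology),
                      simplify = FALSE)
  base_B <- lapply(base_A, function(om) {
    if (shared_band) {
      degrade_edges(om, config$degrade_fraction,
                    diag_jitter = config$diag_jitter)
    } else {
      gen_base("band")
    }
  })

  partition <- split(seq_len(config$p), rep(seq_len(nsub), each = k))
  names(partition) <- paste0("sub", seq_len(nsub))
  truth <- c(rep(FALSE, n_common), rep(TRUE, nsub - n_common))

  expr <- matrix(0, n, config$p)
  is_B <- labels == "B"
  for (nw in seq_len(nsub)) {
    idx <- partition[[nw]]
    if (nw <= n_common) {
      expr[, idx] <- rmvn_scaled(common[[nw]], v, mu = 0)
    } else {
      a_rows <- which(!is_B)
      b_rows <- which(is_B)
      expr[a_rows, idx] <- rmvn_scaled(base_A[[nw - n_common]], v[a_rows],
                                       mu = 0)
      expr[b_rows, idx] <- rmvn_scaled(base_B[[nw - n_common]], v[b_rows],
                                       mu = config$mu_B)
    }
  }
  dimnames(expr) <- list(paste0("cl", seq_len(n)),
                         paste0("g", seq_len(config$p)))

  structure(list(expression = expr, modulator = m, labels = labels,
                 partition = partition, truth = truth, v = v,
                 bases = list(common = common, A = base_A, B = base_B),
                 config = config),
            class = "cell_line_panel")
}

# one MVN row per scale factor: x_i ~ N(mu, (v_i * Omega)^{-1})
rmvn_scaled <- function(omega, v, mu) {
  p <- nrow(omega)
  R <- chol(chol2inv(chol(unclass_matrix(omega))))   # Sigma0 = R'R
  z <- matrix(stats::rnorm(length(v) * p), length(v), p)
  sweep(z %*% R, 1L, sqrt(v), "/") + mu
}

#' @export
print.cell_line_panel <- function(x, ...) {
  cat(sprintf(
    "cell_line_panel: %d cell lines x %d genes, %d subnetworks (%s, mu_B = %g)\n",
    nrow(x$expression), ncol(x$expression), length(x$partition),
    x$config$topology, x$config$mu_B))
  cat(sprintf("  phenotype A: %d, B: %d, unassigned: %d\n",
              sum(x$labels == "A"), sum(x$labels == "B"),
              sum(x$labels == "unassigned")))
  invisible(x)
}

#' Phenotype index sets of a panel
#'
#' @param panel A \code{cell_line_panel}.
#' @return List with integer vectors \code{A} and \code{B}.
#' @export
pheno_indices <- function(panel) {
  list(A = which(panel$labels == "A"), B = which(panel$labels == "B"))
}
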