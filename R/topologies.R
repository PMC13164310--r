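#' Generate a binary adjacency matrix with a predefined topology
#'
#' Produces the symmetric, zero-diagonal adjacency of a sparse graph of one of
#' five structural classes used as baseline conditional-dependence skeletons
#' for simulated gene subnetworks.
#'
#' Topologies:
#' \describe{
#'   \item{random}{Erdos-Renyi: each pair is an edge independently with
#'     probability \code{prob} (default gives 3 expected neighbours per node).}
#'   \item{scale_free}{Barabasi-Albert preferential attachment: nodes are added
#'     one at a time, each attaching to one existing node with probability
#'     proportional to its current degree, yielding a connected tree with a
#'     right-skewed degree sequence.}
#'   \item{hub}{Nodes are split into \code{n_hubs} groups; each group is a star
#'     centred on its hub.}
#'   \item{cluster}{Nodes are split into \code{n_clusters} blocks; within-block
#'     pairs are edges with probability \code{cluster_prob}, between-block
#'     pairs never.}
#'   \item{band}{Entries with \code{0 < |i - j| <= bandwidth} are edges.}
#' }
#'
#' @param p Number of nodes (at least 3).
#' @param topology One of \code{"random"}, \code{"scale_free"}, \code{"hub"},
#'   \code{"cluster"}, \code{"band"}.
#' @param seed Optional integer seed; when supplied the draw is reproducible.
#' @param prob Edge probability for \code{random} (default \code{3 / (p - 1)},
#'   i.e. 3 expected neighbours per node).
#' @param bandwidth Band half-width for \code{band} (default 1, tridiagonal).
#' @param n_hubs Number of star groups for \code{hub} (default
#'   \code{max(1, round(p / 10))}).
#' @param n_clusters Number of blocks for \code{cluster} (default 2).
#' @param cluster_prob Within-block edge probability for \code{cluster}
#'   (default 0.5).
#' @return A \code{p x p} binary symmetric matrix with zero diagonal.
#' @examples
#' a <- generate_adjacency(10, "hub", seed = 1)
#' range(rowSums(a))
#' @export
generate_adjacency <- function(p, topology = c("random", "scale_free", "hub",
                                               "cluster", "band"),
                               seed = NULL,
                               prob = 3 / (p - 1),
                               bandwidth = 1L,
                               n_hubs = max(1L, round(p / 10)),
                               n_clusters = 2L,
                               cluster_prob = 0.5) {
  topology <- match.arg(topology)
  if (!is.numeric(p) || length(p) != 1L || p < 3)
    stop("'p' must be a single integer >= 3", call. = FALSE)
  p <- as.integer(p)
  if (!is.null(seed)) set.seed(seed)

  adj <- switch(topology,
    random = {
      g <- igraph::sample_gnp(p, min(max(prob, 0), 1))
      as_adjacency(g, p)
    },
    scale_free = {
      g <- igraph::sample_pa(p, power = 1, m = 1, directed = FALSE)
      as_adjacency(g, p)
    },
    hub = {
      groups <- split(seq_len(p), rep(seq_len(n_hubs), length.out = p))
      a <- matrix(0L, p, p)
      for (g in groups) {
        hub <- g[1L]
        spokes <- g[-1L]
        a[hub, spokes] <- 1L
        a[spokes, hub] <- 1L
      }
      a
    },
    cluster = {
      blocks <- split(seq_len(p), rep(seq_len(n_clusters), length.out = p))
      a <- matrix(0L, p, p)
      for (b in blocks) {
        if (length(b) < 2L) next
        pairs <- utils::combn(b, 2L)
        on <- stats::runif(ncol(pairs)) < cluster_prob
        a[t(pairs[, on, drop = FALSE])] <- 1L
        a[t(pairs[2:1, on, drop = FALSE])] <- 1L
      }
      a
    },
    band = {
      a <- abs(row(diag(p)) - col(diag(p)))
      matrix(as.integer(a > 0 & a <= bandwidth), p, p)
    }
  )
  storage.mode(adj) <- "integer"
  dimnames(adj) <- NULL
  adj
}

as_adjacency <- function(g, p) {
  a <- matrix(0L, p, p)
  e <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(e)) {
    a[e] <- 1L
    a[e[, 2:1, drop = FALSE]] <- 1L
  }
  diag(a) <- 0L
  a
}

#' Turn an adjacency pattern into a positive-definite precision matrix
#'
#' Assigns a constant weight to every edge and loads the diagonal so that the
#' result is symmetric positive definite with smallest eigenvalue equal to
#' \code{diag_jitter} plus any deficit of the off-diagonal part: the diagonal
#' is set to \code{|lambda_min(edge_weight * adj)| + diag_jitter}. With
#' \code{normalize = TRUE} (default) the matrix is then rescaled so its
#' inverse is a correlation matrix (unit marginal variances), the standard
#' construction for simulated Gaussian graphical models. Either way the
#' off-diagonal support of the result equals the input adjacency exactly.
#'
#' @param adj Binary symmetric matrix with zero diagonal.
#' @param edge_weight Weight given to every edge (default 0.3).
#' @param diag_jitter Extra diagonal loading beyond PD repair (default 0.1).
#' @param normalize Rescale so the implied covariance is a correlation
#'   matrix (default \code{TRUE}).
#' @return A \code{precision_matrix}: a numeric matrix with attribute
#'   \code{topology}.
#' @examples
#' om <- adjacency_to_precision(generate_adjacency(5, "band"), 0.5)
#' min(eigen(om, symmetric = TRUE, only.values = TRUE)$values) > 0
#' @export
adjacency_to_precision <- function(adj, edge_weight = 0.3, diag_jitter = 0.1,
                                   normalize = TRUE) {
  check_adjacency(adj)
  omega <- edge_weight * (adj != 0)
  storage.mode(omega) <- "double"
  lam <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
  diag(omega) <- abs(lam) + diag_jitter
  if (normalize) {
    # unit-variance rescaling: solve(cov2cor(solve(omega))) preserves both
    # the support and positive definiteness
    s <- sqrt(diag(chol2inv(chol(omega))))
    omega <- omega * (s %o% s)
    omega <- (omega + t(omega)) / 2
  }
  new_precision(omega, topology = attr(adj, "topology"))
}

#' Remove a fraction of edges from a precision matrix
#'
#' Deletes \code{round(fraction * E)} of the \code{E} off-diagonal edges,
#' chosen uniformly at random, zeroing the corresponding entries symmetrically,
#' then re-repairs the diagonal so the result stays positive definite. Used to
#' derive a degraded phenotype-B precision matrix from a shared banded
#' phenotype-A matrix.
#'
#' @param precision A symmetric precision matrix.
#' @param fraction Fraction of edges to remove, strictly in (0, 1).
#' @param seed Optional integer seed.
#' @param diag_jitter Diagonal loading used for the PD re-repair (default 0.1).
#' @param normalize Rescale the repaired matrix to unit implied variances
#'   (default \code{TRUE}, matching \code{\link{adjacency_to_precision}}).
#' @return A \code{precision_matrix} whose support is a subset of the input's.
#' @export
degrade_edges <- function(precision, fraction, seed = NULL, diag_jitter = 0.1,
                          normalize = TRUE) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1)
    stop("'fraction' must lie strictly in (0, 1)", call. = FALSE)
  om <- unclass_matrix(precision)
  idx <- which(upper.tri(om) & om != 0)
  if (length(idx) < 2L)
    stop("precision matrix must have at least 2 off-diagonal edges",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  drop <- sample(idx, round(fraction * length(idx)))
  rc <- arrayInd(drop, dim(om))
  om[rc] <- 0
  om[rc[, 2:1, drop = FALSE]] <- 0
  diag(om) <- 0
  lam <- min(eigen(om, symmetric = TRUE, only.values = TRUE)$values)
  diag(om) <- abs(lam) + diag_jitter
  if (normalize) {
    s <- sqrt(diag(chol2inv(chol(om))))
    om <- om * (s %o% s)
    om <- (om + t(om)) / 2
  }
  new_precision(om, topology = "degraded")
}

new_precision <- function(values, topology = NULL) {
  structure(values, class = "precision_matrix",
            topology = if (is.null(topology)) "unknown" else topology)
}

unclass_matrix <- function(x) {
  x <- unclass(x)
  attr(x, "topology") <- NULL
  x
}

#' @export
print.precision_matrix <- function(x, ...) {
  p <- nrow(x)
  e <- sum(x[upper.tri(x)] != 0)
  cat(sprintf("precision_matrix: %d nodes, %d edges (topology: %s)\n",
              p, e, attr(x, "topology")))
  invisible(x)
}

check_adjacency <- function(adj) {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj))
    stop("adjacency must be a square matrix", call. = FALSE)
  if (any(diag(adj) != 0))
    stop("adjacency must have a zero diagonal", call. = FALSE)
  if (!isTRUE(all.equal(unname(adj * 1), unname(t(adj) * 1))))
    stop("adjacency must be symmetric", call. = FALSE)
  invisible(adj)
}

#' Test positive definiteness by Cholesky
#'
#' @param x Symmetric numeric matrix.
#' @return \code{TRUE} if \code{chol(x)} succeeds.
#' @export
is_positive_definite <- function(x) {
  x <- unclass_matrix(x)
  !inherits(try(chol(x), silent = TRUE), "try-error")
}

#' Off-diagonal support of a matrix
#'
#' @param x Square matrix.
#' @param tol Entries with absolute value at or below \code{tol} count as zero.
#' @return Binary symmetric matrix marking nonzero off-diagonal entries.
#' @export
precision_support <- function(x, tol = 0) {
  x <- unclass_matrix(x)
  s <- (abs(x) > tol) * 1L
  diag(s) <- 0L
  s
}
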