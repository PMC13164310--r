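#' Select the most variable genes
#'
#' Returns the column indices of the \code{k} genes with the largest variance
#' across cell lines; ties break deterministically by gene order.
#'
#' @param expression \code{n x p} expression matrix (cell lines in rows).
#' @param k Number of genes to keep (\code{1 <= k <= p}).
#' @return Integer vector of length \code{k}, sorted by decreasing variance.
#' @export
select_top_variance_genes <- function(expression, k) {
  p <- ncol(expression)
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("'k' must be a positive integer", call. = FALSE)
  if (k > p) stop("'k' must not exceed the number of genes", call. = FALSE)
  v <- apply(expression, 2L, stats::var)
  order(v, decreasing = TRUE)[seq_len(k)]
}

#' Threshold a precision matrix to its strongest edges
#'
#' Keeps the \code{ceiling(top_fraction * p * (p - 1) / 2)} unordered
#' off-diagonal pairs with the largest absolute weight (zero-weight pairs are
#' never edges; ties break lexicographically by gene pair), drops isolated
#' nodes, and decomposes the retained graph into connected components.
#'
#' @param omega Symmetric precision (edge-weight) matrix, optionally with
#'   column names as gene identifiers.
#' @param top_fraction Fraction of unordered pairs to retain, in (0, 1).
#' @return A \code{thresholded_network}: list with \code{nodes} (retained
#'   gene indices), \code{edges} (data frame \code{gene_i}, \code{gene_j},
#'   \code{weight}, \code{sign}), \code{components} (list of gene-index
#'   sets) and \code{cutoff} (smallest retained absolute weight).
#' @export
threshold_edges <- function(omega, top_fraction) {
  if (!is.numeric(top_fraction) || length(top_fraction) != 1L ||
      top_fraction <= 0 || top_fraction >= 1)
    stop("'top_fraction' must lie strictly in (0, 1)", call. = FALSE)
  om <- if (inherits(omega, "cell_line_network")) omega$omega else
    unclass_matrix(omega)
  p <- nrow(om)
  ut <- which(upper.tri(om))
  w <- om[ut]
  keep_n <- min(ceiling(top_fraction * length(ut)), sum(w != 0))
  if (keep_n == 0) {
    return(structure(list(nodes = integer(0),
                          edges = data.frame(gene_i = integer(0),
                                             gene_j = integer(0),
                                             weight = numeric(0),
                                             sign = character(0)),
                          components = list(), cutoff = NA_real_),
                     class = "thresholded_network"))
  }
  rc <- arrayInd(ut, dim(om))
  # order: |weight| decreasing, then lexicographic (i, j) for determinism
  ord <- order(-abs(w), rc[, 1L], rc[, 2L])
  sel <- ord[seq_len(keep_n)]
  edges <- data.frame(gene_i = rc[sel, 1L], gene_j = rc[sel, 2L],
                      weight = w[sel],
                      sign = ifelse(w[sel] >= 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  nodes <- sort(unique(c(edges$gene_i, edges$gene_j)))
  g <- igraph::graph_from_data_frame(
    edges[, c("gene_i", "gene_j")], directed = FALSE,
    vertices = data.frame(name = nodes))
  comp <- igraph::components(g)
  components <- split(nodes, comp$membership)
  components <- components[order(-vapply(components, length, 0L))]
  names(components) <- paste0("component", seq_along(components))
  structure(list(nodes = nodes, edges = edges, components = components,
                 cutoff = min(abs(edges$weight))),
            class = "thresholded_network")
}

#' @export
print.thresholded_network <- function(x, ...) {
  cat(sprintf(
    "thresholded_network: %d nodes, %d edges, %d connected components\n",
    length(x$nodes), nrow(x$edges), length(x$components)))
  invisible(x)
}

#' Degree statistics of a thresholded network
#'
#' Per-node degrees, per-component mean degree and the top-degree (hub) gene
#' of each component.
#'
#' @param network A \code{thresholded_network} with at least one edge.
#' @param per_component Also summarise per component (default \code{TRUE}).
#' @return List with \code{degrees} (named vector), \code{mean_degree} and,
#'   when requested, \code{components} (data frame: component, size,
#'   mean_degree, hub, hub_degree).
#' @export
degree_summary <- function(network, per_component = TRUE) {
  stopifnot(inherits(network, "thresholded_network"))
  if (!nrow(network$edges)) stop("network has no edges", call. = FALSE)
  ends <- c(network$edges$gene_i, network$edges$gene_j)
  deg <- table(factor(ends, levels = network$nodes))
  degrees <- as.numeric(deg)
  names(degrees) <- network$nodes
  out <- list(degrees = degrees, mean_degree = mean(degrees))
  if (per_component) {
    comp_rows <- lapply(seq_along(network$components), function(ci) {
      genes <- network$components[[ci]]
      d <- degrees[as.character(genes)]
      hub <- genes[which.max(d)]
      data.frame(component = names(network$components)[ci],
                 size = length(genes), mean_degree = mean(d),
                 hub = hub, hub_degree = max(d), stringsAsFactors = FALSE)
    })
    out$components <- do.call(rbind, comp_rows)
  }
  out
}
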