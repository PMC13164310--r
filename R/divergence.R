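#' Construct a Gaussian network summary
#'
#' A cell line's network is summarised as a multivariate normal distribution
#' \code{N(mu, sigma)}: \code{mu} is the observed expression vector of the
#' cell line and \code{sigma} the covariance obtained from its estimated
#' precision matrix.
#'
#' @param mu Numeric mean vector.
#' @param sigma Symmetric positive-definite covariance matrix matching
#'   \code{mu}.
#' @param check If \code{TRUE} (default) validate symmetry and positive
#'   definiteness.
#' @return A \code{gaussian_summary} (list with \code{mu}, \code{sigma} and a
#'   cached Cholesky factor).
#' @export
gaussian_summary <- function(mu, sigma, check = TRUE) {
  if (is.null(dim(sigma))) sigma <- matrix(sigma, 1L, 1L)
  if (length(mu) != nrow(sigma) || nrow(sigma) != ncol(sigma))
    stop("dimensions of 'mu' and 'sigma' disagree", call. = FALSE)
  if (check) {
    if (max(abs(sigma - t(sigma))) > 1e-8)
      stop("'sigma' must be symmetric", call. = FALSE)
    ch <- try(chol(sigma), silent = TRUE)
    if (inherits(ch, "try-error"))
      stop("'sigma' must be positive definite", call. = FALSE)
  } else {
    ch <- try(chol(sigma), silent = TRUE)
    if (inherits(ch, "try-error")) {   # numerical touch-up only
      sigma <- repair_pd(sigma)
      ch <- chol(sigma)
    }
  }
  structure(list(mu = as.numeric(mu), sigma = sigma, chol = ch),
            class = "gaussian_summary")
}

#' Kullback-Leibler divergence between two Gaussian network summaries
#'
#' Closed form for multivariate normals,
#' \deqn{KL(a \| b) = \tfrac12\left[\log\frac{|\Sigma_b|}{|\Sigma_a|} - p
#'   + \mathrm{tr}(\Sigma_b^{-1}\Sigma_a)
#'   + (\mu_a-\mu_b)^\top \Sigma_b^{-1} (\mu_a-\mu_b)\right],}
#' computed via Cholesky factors (log-determinants and triangular solves),
#' never an explicit determinant. The divergence is directed: \code{a} is the
#' query distribution, \code{b} the comparison.
#'
#' @param a,b \code{gaussian_summary} objects of equal dimension.
#' @return Nonnegative scalar divergence.
#' @examples
#' a <- gaussian_summary(c(0, 0), diag(2))
#' b <- gaussian_summary(c(1, 0), diag(2))
#' gaussian_kl(a, b)   # 0.5
#' @export
gaussian_kl <- function(a, b) {
  stopifnot(inherits(a, "gaussian_summary"), inherits(b, "gaussian_summary"))
  p <- length(a$mu)
  if (length(b$mu) != p)
    stop("summaries must have matching dimension", call. = FALSE)
  Ra <- a$chol
  Rb <- b$chol
  logdet <- 2 * (sum(log(diag(Rb))) - sum(log(diag(Ra))))
  # tr(Sigma_b^{-1} Sigma_a) = || Rb^{-T} Ra^{T} ||_F^2
  M <- forwardsolve(t(Rb), t(Ra))
  tr <- sum(M^2)
  d <- a$mu - b$mu
  q <- sum(forwardsolve(t(Rb), d)^2)
  0.5 * (logdet - p + tr + q)
}

#' Clip eigenvalues to repair positive definiteness
#'
#' Symmetrises the input and raises any eigenvalue below \code{eps} to
#' \code{eps}.
#'
#' @param x Square numeric matrix.
#' @param eps Eigenvalue floor (default 1e-6).
#' @return Symmetric positive-definite matrix.
#' @export
repair_pd <- function(x, eps = 1e-6) {
  x <- (x + t(x)) / 2
  e <- eigen(x, symmetric = TRUE)
  if (min(e$values) >= eps) return(x)
  v <- pmax(e$values, eps)
  y <- e$vectors %*% (v * t(e$vectors))
  (y + t(y)) / 2
}

#' Restrict a cell line network to a gene block
#'
#' Builds the Gaussian summary of one subnetwork: the mean is the cell line's
#' observed expression on the block's genes; the covariance is, by default,
#' the inverse of the principal submatrix of the estimated precision matrix
#' on those genes (\code{from = "precision"}; the block's conditional
#' structure), or alternatively the principal submatrix of the covariance
#' (\code{from = "covariance"}).
#'
#' @param network A \code{cell_line_network}.
#' @param expression_row Observed expression vector of the cell line (full
#'   gene set).
#' @param genes Integer indices of the block's genes.
#' @param from \code{"precision"} (default) or \code{"covariance"}.
#' @param standardize Compare networks on a scale-free basis (default
#'   \code{TRUE}): the block covariance is reduced to its correlation matrix
#'   and the observed expression is whitened by the cell line's own
#'   amplitude scale (the square root of the block covariance diagonal), so
#'   the divergence reflects regulatory structure and standardized
#'   expression rather than overall interaction amplitude.
#' @param eps PD-repair eigenvalue floor.
#' @return A \code{gaussian_summary} of dimension \code{length(genes)}.
#' @export
block_summary <- function(network, expression_row, genes,
                          from = c("precision", "covariance"),
                          standardize = TRUE, eps = 1e-6) {
  from <- match.arg(from)
  mu <- expression_row[genes]
  if (from == "precision") {
    om <- network$omega[genes, genes, drop = FALSE]
    ch <- try(chol(om), silent = TRUE)
    if (inherits(ch, "try-error")) {
      om <- repair_pd(om, eps)
      ch <- chol(om)
    }
    sig <- chol2inv(ch)
    sig <- (sig + t(sig)) / 2
  } else {
    sig <- network$sigma[genes, genes, drop = FALSE]
    sig <- repair_pd(sig, eps)
  }
  if (standardize) {
    s <- sqrt(diag(sig))
    mu <- mu / s
    sig <- sig / (s %o% s)
  }
  gaussian_summary(mu, sig, check = FALSE)
}
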