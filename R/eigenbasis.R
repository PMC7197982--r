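#' Principal coordinates analysis of a haplotype distance matrix
#'
#' Double-centers the (squared) distance matrix,
#' \eqn{B = J A J} with \eqn{J = I - 11'/n}, eigendecomposes \eqn{B}, and
#' retains the eigenvalues above \code{tol} times the largest together with
#' their unit-norm eigenvectors. Non-positive (and sub-tolerance)
#' eigenvalues, which arise for non-Euclidean inputs such as genetic or
#' patristic distances, are dropped and counted; a warning is issued when
#' the dropped mass exceeds 5\% of the total absolute spectrum.
#'
#' With \code{inputIsSquared = FALSE} (standard PCoA), \eqn{A = -d^2/2}.
#' With \code{inputIsSquared = TRUE}, the input is treated as already being
#' on the squared-Euclidean scale, \eqn{A = -d/2}. The latter is the
#' convention used by phylogenetic eigenvector regression: for an
#' ultrametric genealogy the double-centered patristic distance matrix
#' equals the centered Brownian-motion covariance among tips, which is what
#' makes PSR curves linear in expectation under neutral drift.
#'
#' Each eigenvector's sign is fixed so that its largest-magnitude entry is
#' positive, for reproducible overlays.
#'
#' @param dm Symmetric distance matrix with zero diagonal; dimnames give the
#'   haplotype ids.
#' @param tol Relative eigenvalue tolerance (default 1e-10 of the largest).
#' @param inputIsSquared Treat the input as squared distances (see Details).
#' @return An \linkS4class{EigenBasis}.
#' @export
pcoaBasis <- function(dm, tol = 1e-10, inputIsSquared = FALSE) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3L) stop("too few haplotypes (need at least 3)")
  if (ncol(dm) != n || max(abs(dm - t(dm))) > 1e-12 || any(diag(dm) != 0))
    stop("distance matrix must be symmetric with a zero diagonal")
  if (tol <= 0) stop("tol must be positive")
  ids <- rownames(dm)
  if (is.null(ids)) ids <- paste0("H", seq_len(n))
  A <- if (inputIsSquared) -dm / 2 else -(dm * dm) / 2
  B <- A - matrix(rowMeans(A), n, n) -
       matrix(colMeans(A), n, n, byrow = TRUE) + mean(A)
  e <- eigen(B, symmetric = TRUE)
  if (max(e$values) <= 0) stop("degenerate distance matrix")
  keep <- e$values > tol * max(e$values)
  if (!any(keep)) stop("degenerate distance matrix")
  vals <- e$values[keep]
  vecs <- e$vectors[, keep, drop = FALSE]
  # sign convention: largest-magnitude entry positive
  for (k in seq_len(ncol(vecs))) {
    if (vecs[which.max(abs(vecs[, k])), k] < 0) vecs[, k] <- -vecs[, k]
  }
  rownames(vecs) <- ids
  colnames(vecs) <- paste0("E", seq_len(ncol(vecs)))
  droppedMass <- sum(abs(e$values[!keep]))
  if (droppedMass > 0.05 * sum(abs(e$values)))
    warning(sprintf(
      "dropped eigenvalue mass is %.1f%% of the absolute spectrum",
      100 * droppedMass / sum(abs(e$values))))
  new("EigenBasis", ids = ids, values = vals, relValues = vals / sum(vals),
      vectors = vecs, droppedNonpositive = sum(!keep))
}

#' Principal-coordinate scores scaled by the square-root eigenvalues
#'
#' Returns the coordinate matrix \eqn{v_k \sqrt{\lambda_k}} whose pairwise
#' Euclidean distances reconstruct the input distances when these were
#' Euclidean.
#'
#' @param basis An \linkS4class{EigenBasis}.
#' @return Numeric matrix haplotypes x axes.
#' @export
scaledCoordinates <- function(basis) {
  stopifnot(is(basis, "EigenBasis"))
  sweep(basis@vectors, 2L, sqrt(basis@values), "*")
}
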