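#' Fit a phylogenetic signal-representation curve
#'
#' Regresses the trait on an intercept plus the first \eqn{k} eigenvectors
#' for \eqn{k = 1, \ldots, K} and records the cumulative coefficient of
#' determination \eqn{R^2_k} against the cumulative relative eigenvalue
#' \eqn{x_k}. Because the eigenvectors are centered, mutually orthogonal and
#' unit-norm, the nested OLS fits reduce to accumulating squared projections
#' of the centered trait; the result is identical to refitting the normal
#' equations at every \eqn{k}.
#'
#' @param basis An \linkS4class{EigenBasis}.
#' @param trait Numeric trait vector, either named by haplotype id or in the
#'   row order of the basis.
#' @param name Trait name stored on the curve.
#' @return A \linkS4class{PSRCurve} with the point (0, 0) prepended.
#' @export
fitPSRCurve <- function(basis, trait, name = "trait") {
  stopifnot(is(basis, "EigenBasis"))
  n <- length(basis@ids)
  if (!is.null(names(trait))) {
    if (!all(basis@ids %in% names(trait)))
      stop("trait is missing values for some haplotypes")
    trait <- trait[basis@ids]
  } else if (length(trait) != n) {
    stop(sprintf("trait length %d does not match %d haplotypes",
                 length(trait), n))
  }
  if (anyNA(trait)) stop("trait contains missing values")
  y <- trait - mean(trait)
  sst <- sum(y^2)
  if (sst == 0) stop("zero trait variance")
  proj <- as.vector(crossprod(basis@vectors, y))^2
  r2 <- pmin(cumsum(proj) / sst, 1)
  K <- length(r2)
  new("PSRCurve", trait = name,
      x = c(0, cumsum(basis@relValues)),
      r2 = c(0, r2), k = 0:K)
}

#' Signed PSR area against the Brownian-motion diagonal
#'
#' Trapezoidal integral of \eqn{R^2(x) - x} over the curve's x-range, with
#' linear interpolation between consecutive curve points. Negative values
#' indicate a curve below the 1:1 line (Ornstein-Uhlenbeck-like constraint),
#' positive values a curve above it (burst-like divergence).
#'
#' @param curve A \linkS4class{PSRCurve}.
#' @return A \linkS4class{PSRArea} (no p-value attached).
#' @export
psrArea <- function(curve) {
  stopifnot(is(curve, "PSRCurve"))
  f <- curve@r2 - curve@x
  a <- sum((f[-length(f)] + f[-1L]) / 2 * diff(curve@x))
  new("PSRArea", trait = curve@trait, area = a,
      pValue = numeric(), nullAreas = numeric())
}

# all permutations of seq_len(n), in lexicographic order (n <= 8)
allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- allPermutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (i in seq_len(nrow(sub))) {
      r <- r + 1L
      out[r, ] <- c(first, rest[sub[i, ]])
    }
  }
  out
}

#' Permutation null for a PSR curve and area
#'
#' Permutes the trait values across haplotype tips (the standard null of no
#' phylogenetic signal), refits the PSR curve for each permutation, and
#' returns a pointwise quantile envelope together with a two-tailed
#' permutation p-value on the magnitude of the signed area,
#' \eqn{p = (1 + \#\{|A_{null}| \ge |A_{obs}|\}) / (n_{rand} + 1)}.
#'
#' With \code{exhaustive = TRUE} all \eqn{n!} tip permutations are
#' enumerated (requires \eqn{n \le 8}) and the p-value is the exact fraction
#' \eqn{\#\{|A_{\pi}| \ge |A_{obs}|\} / n!}, the identity permutation
#' included.
#'
#' @param basis An \linkS4class{EigenBasis}.
#' @param trait Trait vector as in \code{\link{fitPSRCurve}}.
#' @param nRand Number of randomizations (default 999).
#' @param seed Integer seed for the permutation generator.
#' @param name Trait name.
#' @param probs Lower/upper envelope quantiles.
#' @param exhaustive Enumerate all permutations instead of sampling.
#' @return A list with elements \code{area} (a \linkS4class{PSRArea} carrying
#'   the p-value and null areas), \code{envelope}
#'   (a \linkS4class{NullEnvelope}) and \code{curve} (the observed
#'   \linkS4class{PSRCurve}).
#' @export
nullEnvelope <- function(basis, trait, nRand = 999L, seed = 1L,
                         name = "trait", probs = c(0.025, 0.975),
                         exhaustive = FALSE) {
  stopifnot(is(basis, "EigenBasis"))
  nRand <- as.integer(nRand)
  if (!exhaustive && nRand < 1L) stop("nRand must be >= 1")
  curve <- fitPSRCurve(basis, trait, name = name)
  obs <- psrArea(curve)
  n <- length(basis@ids)
  if (!is.null(names(trait))) trait <- trait[basis@ids]
  y <- trait - mean(trait)
  sst <- sum(y^2)
  if (exhaustive) {
    if (n > 8L) stop("exhaustive enumeration limited to n <= 8")
    perms <- allPermutations(n)
  } else {
    set.seed(as.integer(seed))
    perms <- t(replicate(nRand, sample.int(n)))
  }
  V <- basis@vectors
  x <- c(0, cumsum(basis@relValues))
  dx <- diff(x)
  nullR2 <- matrix(0, nrow(perms), length(x))
  nullAreas <- numeric(nrow(perms))
  for (i in seq_len(nrow(perms))) {
    r2 <- pmin(cumsum(as.vector(crossprod(V, y[perms[i, ]]))^2) / sst, 1)
    f <- c(0, r2) - x
    nullAreas[i] <- sum((f[-length(f)] + f[-1L]) / 2 * dx)
    nullR2[i, ] <- c(0, r2)
  }
  tol <- 1e-12
  p <- if (exhaustive) {
    mean(abs(nullAreas) >= abs(obs@area) - tol)
  } else {
    (1 + sum(abs(nullAreas) >= abs(obs@area) - tol)) / (nrow(perms) + 1)
  }
  env <- new("NullEnvelope", x = x,
             lo = apply(nullR2, 2L, stats::quantile, probs = probs[1L]),
             hi = apply(nullR2, 2L, stats::quantile, probs = probs[2L]),
             nRand = nrow(perms), seed = as.integer(seed))
  area <- new("PSRArea", trait = curve@trait, area = obs@area,
              pValue = p, nullAreas = nullAreas)
  list(area = area, envelope = env, curve = curve)
}

#' Detect the largest R-squared shifts along a PSR curve
#'
#' Computes the per-eigenvector increments \eqn{\Delta R^2_k} (with
#' \eqn{\Delta R^2_1 = R^2_1}, so the increments total \eqn{R^2_K}) and
#' ranks the \code{topN} largest, ties broken by smaller \eqn{k}. The
#' top-ranked eigenvector is the one plotted over haplotype networks.
#'
#' @param curve A \linkS4class{PSRCurve} with at least two fitted points.
#' @param topN Number of peak indices to report.
#' @return A \linkS4class{PeakReport}.
#' @export
detectR2Peaks <- function(curve, topN = 1L) {
  stopifnot(is(curve, "PSRCurve"))
  topN <- as.integer(topN)
  if (topN < 1L) stop("topN must be >= 1")
  K <- max(curve@k)
  if (K < 2L) stop("curve has fewer than two fitted points")
  delta <- diff(curve@r2)   # delta at k=1 equals R2_1 since r2[1] = 0
  ord <- order(-delta, seq_len(K))
  new("PeakReport", trait = curve@trait, k = seq_len(K), delta = delta,
      topK = as.integer(ord[seq_len(min(topN, K))]))
}

# half-away-from-zero rounding used for display, matching printed tables
roundHalfAway <- function(x, digits = 2L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Average signed PSR areas by trait class
#'
#' Groups per-variable PSR areas into the altitude (A), temperature (T) and
#' precipitation (P) classes and reports the arithmetic mean per class, both
#' at full precision and rounded to two decimals (half away from zero) for
#' display.
#'
#' @param areas A list of \linkS4class{PSRArea} objects, or a named numeric
#'   vector of signed areas.
#' @param classMap Named character vector, variable name -> class letter, as
#'   returned by \code{\link{loadTraitClasses}}.
#' @return A data frame with columns \code{class}, \code{n}, \code{meanArea}
#'   and \code{displayArea}, one row per class present, in A, T, P order.
#' @export
summarizeClassAreas <- function(areas, classMap) {
  if (is.list(areas)) {
    vals <- vapply(areas, function(a) a@area, numeric(1L))
    names(vals) <- vapply(areas, function(a) a@trait, character(1L))
    areas <- vals
  }
  unmapped <- setdiff(names(areas), names(classMap))
  if (length(unmapped))
    stop(sprintf("no trait class for variable '%s'", unmapped[1L]))
  cls <- classMap[names(areas)]
  lev <- intersect(c("A", "T", "P"), unique(cls))
  mean_by <- vapply(lev, function(l) mean(areas[cls == l]), numeric(1L))
  data.frame(class = lev,
             n = as.integer(table(factor(cls, levels = lev))),
             meanArea = unname(mean_by),
             displayArea = roundHalfAway(unname(mean_by)),
             row.names = NULL)
}
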