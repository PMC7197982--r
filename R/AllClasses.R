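#' @import methods
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet width
#' @importFrom IRanges IRanges start end CharacterList
#' @importFrom S4Vectors mcols mcols<-
NULL

#' Aligned haplotype sequences with a column mask
#'
#' Holds a multiple sequence alignment (one record per individual) together
#' with the set of alignment columns excluded from analysis, e.g. columns
#' inside hypervariable poly-A/T runs. Columns are 1-based throughout.
#'
#' @slot seqs A \link[Biostrings]{DNAStringSet} of equal-width sequences over
#'   \code{A,C,G,T,N,-}, named by individual id.
#' @slot mask Sorted integer vector of masked column indices.
#' @export
setClass("AlignedSeqSet",
  representation(seqs = "DNAStringSet", mask = "integer"))

setValidity("AlignedSeqSet", function(object) {
  n <- length(object@seqs)
  if (n == 0L) return("no sequences")
  w <- Biostrings::width(object@seqs)
  if (length(unique(w)) != 1L)
    return("sequences do not share a common alignment length")
  ids <- names(object@seqs)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    return("individual ids must be unique and non-empty")
  if (length(object@mask) &&
      (min(object@mask) < 1L || max(object@mask) > w[1L]))
    return("mask columns outside the alignment")
  if (is.unsorted(object@mask, strictly = TRUE) && length(object@mask) > 1L)
    return("mask must be sorted and unique")
  TRUE
})

#' Haplotype table
#'
#' Result of collapsing an alignment: one row per distinct haplotype, defined
#' jointly by nucleotide states at the identity columns and by presence of
#' coded indel events.
#'
#' @slot ids Haplotype ids \code{"H1"}, \code{"H2"}, ... in order of first
#'   appearance.
#' @slot seqs Representative full-length aligned sequence per haplotype.
#' @slot nucStates Character vector (named by haplotype id) of states at the
#'   identity columns.
#' @slot indelStates Logical matrix, haplotypes x indel events.
#' @slot events \link[IRanges]{IRanges} of coded indel events with a
#'   \code{carriers} metadata column.
#' @slot membership Named character, individual id -> haplotype id.
#' @slot counts Named integer, carriers per haplotype.
#' @slot identityColumns Integer columns used for the nucleotide identity key.
#' @slot mask Masked columns inherited from the alignment.
#' @export
setClass("HaplotypeTable",
  representation(ids = "character", seqs = "DNAStringSet",
    nucStates = "character", indelStates = "matrix", events = "IRanges",
    membership = "character", counts = "integer",
    identityColumns = "integer", mask = "integer"))

setValidity("HaplotypeTable", function(object) {
  n <- length(object@ids)
  if (length(object@seqs) != n || length(object@nucStates) != n ||
      nrow(object@indelStates) != n || length(object@counts) != n)
    return("inconsistent haplotype slots")
  if (sum(object@counts) != length(object@membership))
    return("counts do not sum to the number of individuals")
  if (!all(object@membership %in% object@ids))
    return("membership refers to unknown haplotype ids")
  key <- paste(object@nucStates,
               apply(object@indelStates, 1L, paste, collapse = ""))
  if (anyDuplicated(key))
    return("two haplotypes share identical nucleotide and indel states")
  TRUE
})

#' Principal-coordinate eigenbasis of a haplotype distance matrix
#'
#' @slot ids Haplotype ids (row order of \code{vectors}).
#' @slot values Retained eigenvalues, strictly positive and non-increasing.
#' @slot relValues Eigenvalues renormalised over the retained set (sum 1).
#' @slot vectors Unit-norm eigenvector matrix, haplotypes x axes.
#' @slot droppedNonpositive Number of eigenvalues dropped as non-positive or
#'   below tolerance.
#' @export
setClass("EigenBasis",
  representation(ids = "character", values = "numeric", relValues = "numeric",
    vectors = "matrix", droppedNonpositive = "integer"))

setValidity("EigenBasis", function(object) {
  k <- length(object@values)
  n <- length(object@ids)
  if (k == 0L) return("no retained eigenvalues")
  if (any(object@values <= 0)) return("retained eigenvalues must be positive")
  if (is.unsorted(rev(object@values))) return("eigenvalues must be non-increasing")
  if (abs(sum(object@relValues) - 1) > 1e-9)
    return("relative eigenvalues must sum to 1")
  if (ncol(object@vectors) != k || nrow(object@vectors) != n)
    return("eigenvector matrix dimensions inconsistent")
  if (k > n - 1L) return("more axes than n - 1")
  g <- crossprod(object@vectors)
  if (max(abs(g - diag(k))) > 1e-8)
    return("eigenvector columns are not orthonormal")
  TRUE
})

#' Phylogenetic signal-representation curve
#'
#' Cumulative regression R-squared of a trait on successive eigenvectors,
#' plotted against cumulative relative eigenvalues; the point (0, 0) is
#' prepended.
#'
#' @slot trait Trait name.
#' @slot x Cumulative relative eigenvalues (first element 0).
#' @slot r2 Cumulative R-squared (first element 0), non-decreasing.
#' @slot k Number of eigenvectors at each point (first element 0).
#' @export
setClass("PSRCurve",
  representation(trait = "character", x = "numeric", r2 = "numeric",
    k = "integer"))

setValidity("PSRCurve", function(object) {
  if (length(object@x) != length(object@r2) ||
      length(object@x) != length(object@k))
    return("x, r2 and k differ in length")
  if (object@x[1L] != 0 || object@r2[1L] != 0)
    return("curve must start at (0, 0)")
  if (any(diff(object@x) <= 0)) return("x must be strictly increasing")
  if (any(diff(object@r2) < -1e-12)) return("r2 must be non-decreasing")
  TRUE
})

#' Signed PSR area
#'
#' Signed area between a PSR curve and the 1:1 Brownian-motion diagonal;
#' negative below the diagonal (Ornstein-Uhlenbeck-like constraint), positive
#' above (burst-like divergence).
#'
#' @slot trait Trait name.
#' @slot area Signed area; bounded by 0.5 in magnitude.
#' @slot pValue Permutation p-value; length 0 when no null was run.
#' @slot nullAreas Null areas from the permutation scheme (possibly empty).
#' @export
setClass("PSRArea",
  representation(trait = "character", area = "numeric", pValue = "numeric",
    nullAreas = "numeric"))

setValidity("PSRArea", function(object) {
  if (abs(object@area) > 0.5 + 1e-9) return("|area| exceeds 0.5")
  if (length(object@pValue) > 1L) return("pValue must have length 0 or 1")
  if (length(object@pValue) == 1L &&
      (object@pValue <= 0 || object@pValue > 1))
    return("pValue must lie in (0, 1]")
  TRUE
})

#' Pointwise null envelope of PSR curves under trait permutation
#'
#' @slot x Curve x coordinates (cumulative relative eigenvalues, with 0).
#' @slot lo,hi Pointwise lower/upper quantile curves.
#' @slot nRand Number of randomizations.
#' @slot seed Seed used for the permutations.
#' @export
setClass("NullEnvelope",
  representation(x = "numeric", lo = "numeric", hi = "numeric",
    nRand = "integer", seed = "integer"))

setValidity("NullEnvelope", function(object) {
  if (any(object@lo > object@hi + 1e-12)) return("lo exceeds hi")
  if (object@nRand < 1L) return("nRand must be >= 1")
  TRUE
})

#' R-squared peak report
#'
#' Per-eigenvector increments of the PSR curve and the indices of the largest
#' shifts, used to choose the eigenvector plotted over haplotype networks.
#'
#' @slot trait Trait name.
#' @slot k Eigenvector indices 1..K.
#' @slot delta R-squared increment at each k (delta at k = 1 equals R2_1).
#' @slot topK Indices of the largest increments, ties broken by smaller k.
#' @export
setClass("PeakReport",
  representation(trait = "character", k = "integer", delta = "numeric",
    topK = "integer"))

#' Per-haplotype bioclimatic niche table
#'
#' @slot values Matrix haplotypes x variables of niche means.
#' @slot nCarriers Named integer, individuals averaged per haplotype.
#' @export
setClass("NicheTable",
  representation(values = "matrix", nCarriers = "integer"))

setValidity("NicheTable", function(object) {
  if (!identical(rownames(object@values), names(object@nCarriers)))
    return("row names and carrier counts disagree")
  if (any(object@nCarriers < 1L)) return("haplotype with zero carriers")
  TRUE
})

#' One-dimensional K-means rank overlay
#'
#' @slot eigenvectorIndex Index of the eigenvector the scores came from
#'   (\code{NA} when ranks were built from arbitrary scores).
#' @slot ranks Named integer, haplotype id -> group in 1..g (ascending
#'   centers).
#' @slot centers Sorted cluster centers.
#' @export
setClass("RankOverlay",
  representation(eigenvectorIndex = "integer", ranks = "integer",
    centers = "numeric"))

setValidity("RankOverlay", function(object) {
  g <- length(object@centers)
  if (is.unsorted(object@centers)) return("centers must be sorted")
  if (!all(object@ranks %in% seq_len(g))) return("ranks outside 1..g")
  if (!all(seq_len(g) %in% object@ranks)) return("empty rank group")
  TRUE
})

#' Median-joining haplotype network
#'
#' @slot graph An \link[igraph]{igraph} graph; vertices are observed
#'   haplotypes plus inferred median vectors (\code{"mv1"}, ...), edges carry
#'   the number of differing characters as weight.
#' @slot observedIds Ids of the observed haplotypes.
#' @export
setClass("HaplotypeNetwork",
  representation(graph = "ANY", observedIds = "character"))

setValidity("HaplotypeNetwork", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph slot must hold an igraph graph")
  if (!all(object@observedIds %in% igraph::V(g)$name))
    return("observed haplotype missing from the network")
  if (igraph::vcount(g) > 1L && !igraph::is_connected(g))
    return("network must be connected")
  if (igraph::ecount(g) > 0L && any(igraph::E(g)$weight < 1))
    return("edge weights must be >= 1")
  TRUE
})

#' Synthetic dataset bundle
#'
#' A download-free stand-in for the study inputs: an individual-level
#' alignment, the true genealogy and trait values, and a per-individual
#' climate table.
#'
#' @slot alignment \linkS4class{AlignedSeqSet} with one record per individual.
#' @slot tree The true genealogy (\link[ape]{phylo}), tips = haplotypes.
#' @slot traits Named numeric, true trait value per haplotype.
#' @slot model Trait model label: \code{"BM"}, \code{"OU"} or \code{"EB"}.
#' @slot individuals Data frame: individual_id, lon, lat, 20 variables.
#' @slot haplotypeMeans Matrix haplotypes x variables of true niche means.
#' @export
setClass("SyntheticDataset",
  representation(alignment = "AlignedSeqSet", tree = "ANY",
    traits = "numeric", model = "character", individuals = "data.frame",
    haplotypeMeans = "matrix"))
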