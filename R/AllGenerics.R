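#' @name psrniche-accessors
#' @title Accessors for psrniche classes
#' @description Small accessor generics used across the package instead of
#'   direct slot access.
#' @param x An object of the documented class.
#' @param object An object of the documented class.
NULL

#' @rdname psrniche-accessors
#' @export
setGeneric("haplotypeIds", function(x) standardGeneric("haplotypeIds"))

#' @rdname psrniche-accessors
#' @export
setGeneric("maskedColumns", function(x) standardGeneric("maskedColumns"))

#' @rdname psrniche-accessors
#' @export
setGeneric("alignedSeqs", function(x) standardGeneric("alignedSeqs"))

#' @rdname psrniche-accessors
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))

#' @rdname psrniche-accessors
#' @export
setGeneric("haplotypeCounts", function(x) standardGeneric("haplotypeCounts"))

#' @rdname psrniche-accessors
#' @export
setGeneric("indelEvents", function(x) standardGeneric("indelEvents"))

#' @rdname psrniche-accessors
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @rdname psrniche-accessors
#' @export
setGeneric("relEigenvalues", function(x) standardGeneric("relEigenvalues"))

#' @rdname psrniche-accessors
#' @export
setGeneric("eigenvectors", function(x) standardGeneric("eigenvectors"))

#' @rdname psrniche-accessors
#' @export
setGeneric("psrPoints", function(x) standardGeneric("psrPoints"))

#' @rdname psrniche-accessors
#' @export
setGeneric("areaValue", function(x) standardGeneric("areaValue"))

#' @rdname psrniche-accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname psrniche-accessors
#' @export
setGeneric("nicheValues", function(x) standardGeneric("nicheValues"))

#' @rdname psrniche-accessors
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))

#' @rdname psrniche-accessors
#' @export
setGeneric("observedHaplotypes", function(x) standardGeneric("observedHaplotypes"))

#' @rdname psrniche-accessors
#' @export
setGeneric("rankGroups", function(x) standardGeneric("rankGroups"))

#' @rdname psrniche-accessors
setMethod("haplotypeIds", "HaplotypeTable", function(x) x@ids)

#' @rdname psrniche-accessors
setMethod("haplotypeIds", "EigenBasis", function(x) x@ids)

#' @rdname psrniche-accessors
setMethod("haplotypeIds", "NicheTable", function(x) rownames(x@values))

#' @rdname psrniche-accessors
setMethod("maskedColumns", "AlignedSeqSet", function(x) x@mask)

#' @rdname psrniche-accessors
setMethod("alignedSeqs", "AlignedSeqSet", function(x) x@seqs)

#' @rdname psrniche-accessors
setMethod("alignedSeqs", "HaplotypeTable", function(x) x@seqs)

#' @rdname psrniche-accessors
setMethod("membership", "HaplotypeTable", function(x) x@membership)

#' @rdname psrniche-accessors
setMethod("haplotypeCounts", "HaplotypeTable", function(x) x@counts)

#' @rdname psrniche-accessors
setMethod("indelEvents", "HaplotypeTable", function(x) x@events)

#' @rdname psrniche-accessors
setMethod("eigenvalues", "EigenBasis", function(x) x@values)

#' @rdname psrniche-accessors
setMethod("relEigenvalues", "EigenBasis", function(x) x@relValues)

#' @rdname psrniche-accessors
setMethod("eigenvectors", "EigenBasis", function(x) x@vectors)

#' @rdname psrniche-accessors
setMethod("psrPoints", "PSRCurve", function(x)
  data.frame(k = x@k, x = x@x, r2 = x@r2))

#' @rdname psrniche-accessors
setMethod("areaValue", "PSRArea", function(x) x@area)

#' @rdname psrniche-accessors
setMethod("pValue", "PSRArea", function(x)
  if (length(x@pValue)) x@pValue else NA_real_)

#' @rdname psrniche-accessors
setMethod("nicheValues", "NicheTable", function(x) x@values)

#' @rdname psrniche-accessors
setMethod("networkGraph", "HaplotypeNetwork", function(x) x@graph)

#' @rdname psrniche-accessors
setMethod("observedHaplotypes", "HaplotypeNetwork", function(x) x@observedIds)

#' @rdname psrniche-accessors
setMethod("rankGroups", "RankOverlay", function(x) x@ranks)

#' @rdname psrniche-accessors
setMethod("show", "AlignedSeqSet", function(object) {
  cat(sprintf("AlignedSeqSet: %d sequences x %d columns (%d masked)\n",
    length(object@seqs), Biostrings::width(object@seqs)[1L],
    length(object@mask)))
})

#' @rdname psrniche-accessors
setMethod("show", "HaplotypeTable", function(object) {
  cat(sprintf(
    "HaplotypeTable: %d haplotypes from %d individuals, %d indel events\n",
    length(object@ids), length(object@membership), length(object@events)))
})

#' @rdname psrniche-accessors
setMethod("show", "EigenBasis", function(object) {
  cat(sprintf(
    "EigenBasis: %d haplotypes, %d retained axes (%d dropped), lambda_1 = %.4g\n",
    length(object@ids), length(object@values), object@droppedNonpositive,
    object@values[1L]))
})

#' @rdname psrniche-accessors
setMethod("show", "PSRCurve", function(object) {
  cat(sprintf("PSRCurve '%s': %d eigenvectors, R2_K = %.4f\n",
    object@trait, max(object@k), object@r2[length(object@r2)]))
})

#' @rdname psrniche-accessors
setMethod("show", "PSRArea", function(object) {
  p <- if (length(object@pValue)) sprintf(", p = %.4g", object@pValue) else ""
  cat(sprintf("PSRArea '%s': %+0.4f%s\n", object@trait, object@area, p))
})

#' @rdname psrniche-accessors
setMethod("show", "NicheTable", function(object) {
  cat(sprintf("NicheTable: %d haplotypes x %d variables\n",
    nrow(object@values), ncol(object@values)))
})

#' @rdname psrniche-accessors
setMethod("show", "HaplotypeNetwork", function(object) {
  g <- object@graph
  cat(sprintf(
    "HaplotypeNetwork: %d observed haplotypes, %d median vectors, %d edges\n",
    length(object@observedIds),
    igraph::vcount(g) - length(object@observedIds), igraph::ecount(g)))
})

#' @rdname psrniche-accessors
setMethod("show", "SyntheticDataset", function(object) {
  cat(sprintf(
    "SyntheticDataset (%s): %d haplotypes, %d individuals, %d columns\n",
    object@model, length(object@traits), nrow(object@individuals),
    Biostrings::width(object@alignment@seqs)[1L]))
})
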