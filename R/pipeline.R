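stageTry <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Run the full PSR niche-conservatism pipeline
#'
#' Executes every stage end to end: haplotype collapsing with poly-A/T
#' masking and indel coding, Tajima-Nei distances, principal-coordinate
#' eigenvector extraction, per-haplotype niche averaging, one PSR curve and
#' signed area (with permutation null) per niche variable, the class-level
#' area summary, and a median-joining network overlaid with K-means ranks
#' of the eigenvector showing the most frequent largest R-squared shift.
#' All outputs are written as CSV (plus a haplotype FASTA); the run is
#' deterministic given the seed.
#'
#' @param alignmentFile Aligned FASTA, one record per individual.
#' @param individualsFile CSV with individual_id, lon, lat and the 20 niche
#'   variables.
#' @param classFile Optional trait-class CSV; defaults to the packaged map.
#' @param outDir Output directory.
#' @param minPolyRun Poly-A/T masking threshold (see
#'   \code{\link{maskHypervariableColumns}}).
#' @param deletion Site-deletion mode for distances.
#' @param tol PCoA eigenvalue tolerance.
#' @param inputIsSquared Treat distances as squared-scale in the PCoA (the
#'   PSR convention; see \code{\link{pcoaBasis}}).
#' @param nRand Randomizations per trait for the permutation null.
#' @param seed Integer seed for the nulls.
#' @param epsilon Median-joining network tolerance.
#' @param groups Number of K-means rank groups for the overlay.
#' @return Invisibly, a list with all intermediate objects: \code{table},
#'   \code{distances}, \code{basis}, \code{niche}, \code{curves},
#'   \code{areas}, \code{peaks}, \code{classSummary}, \code{network},
#'   \code{overlayEigenvector}, \code{files}.
#' @export
runPSRPipeline <- function(alignmentFile, individualsFile, classFile = NULL,
                           outDir, minPolyRun = 6L,
                           deletion = "complete", tol = 1e-10,
                           inputIsSquared = TRUE, nRand = 999L, seed = 1L,
                           epsilon = 0L, groups = 4L) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  aln <- stageTry("haplotypes", {
    a <- readAlignedFasta(alignmentFile)
    maskHypervariableColumns(a, minRun = minPolyRun)
  })
  events <- stageTry("haplotypes", codeIndels(aln))
  tab <- stageTry("haplotypes", collapseHaplotypes(aln, events))
  dm <- stageTry("haplotypes", tajimaNeiMatrix(tab, deletion = deletion))
  basis <- stageTry("eigenbasis",
    pcoaBasis(dm, tol = tol, inputIsSquared = inputIsSquared))
  classes <- stageTry("niche", loadTraitClasses(classFile))
  individuals <- stageTry("niche", {
    df <- utils::read.csv(individualsFile, check.names = FALSE)
    buildNicheTable(df, membership(tab))
  })
  vars <- colnames(nicheValues(individuals))
  curves <- list(); areas <- list(); peaks <- list()
  for (i in seq_along(vars)) {
    v <- vars[i]
    res <- stageTry("psr", nullEnvelope(basis,
      stats::setNames(nicheValues(individuals)[basis@ids, v], basis@ids),
      nRand = nRand, seed = as.integer(seed) + i, name = v))
    curves[[v]] <- res$curve
    areas[[v]] <- res$area
    peaks[[v]] <- detectR2Peaks(res$curve, topN = 3L)
  }
  classSummary <- stageTry("psr", summarizeClassAreas(areas, classes))
  topKs <- vapply(peaks, function(p) p@topK[1L], integer(1L))
  kStar <- as.integer(names(sort(table(topKs), decreasing = TRUE))[1L])
  net <- stageTry("network", {
    chars <- characterMatrix(tab)
    n0 <- buildMJNetwork(chars, epsilon = epsilon)
    overlayEigenvector(n0, basis, k = kStar,
                       g = min(groups, length(unique(basis@vectors[, kStar]))))
  })
  files <- writePipelineOutputs(outDir, tab, dm, basis, individuals,
                                curves, areas, peaks, classSummary, net,
                                classes, kStar)
  invisible(list(table = tab, distances = dm, basis = basis,
                 niche = individuals, curves = curves, areas = areas,
                 peaks = peaks, classSummary = classSummary, network = net,
                 overlayEigenvector = kStar, files = files))
}

writePipelineOutputs <- function(outDir, tab, dm, basis, niche, curves,
                                 areas, peaks, classSummary, net, classes,
                                 kStar) {
  p <- function(f) file.path(outDir, f)
  Biostrings::writeXStringSet(tab@seqs, p("haplotypes.fasta"))
  utils::write.csv(data.frame(individual_id = names(tab@membership),
                              haplotype_id = unname(tab@membership)),
                   p("membership.csv"), row.names = FALSE)
  ev <- tab@events
  utils::write.csv(data.frame(
    start_1based = IRanges::start(ev), end_1based = IRanges::end(ev),
    carriers = vapply(as.list(S4Vectors::mcols(ev)$carriers),
                      paste, character(1L), collapse = ";")),
    p("indel_events.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(dm), p("distances.csv"))
  utils::write.csv(data.frame(
    k = seq_along(basis@values), lambda = basis@values,
    rel_lambda = basis@relValues,
    cum_rel_lambda = cumsum(basis@relValues)),
    p("eigenvalues.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(eigenvectors(basis)),
                   p("eigenvectors.csv"))
  utils::write.csv(data.frame(haplotype_id = haplotypeIds(niche),
                              n_carriers = unname(niche@nCarriers),
                              nicheValues(niche), check.names = FALSE),
                   p("niche.csv"), row.names = FALSE)
  cv <- do.call(rbind, lapply(curves, function(cu)
    data.frame(trait = cu@trait, psrPoints(cu))))
  utils::write.csv(cv, p("psr_curves.csv"), row.names = FALSE)
  ar <- do.call(rbind, lapply(names(areas), function(v)
    data.frame(trait = v, class = unname(classes[v]),
               area = areas[[v]]@area,
               p_value = pValue(areas[[v]]),
               top_k = peaks[[v]]@topK[1L])))
  utils::write.csv(ar, p("psr_areas.csv"), row.names = FALSE)
  utils::write.csv(classSummary, p("class_summary.csv"), row.names = FALSE)
  utils::write.csv(networkEdges(net), p("network_edges.csv"),
                   row.names = FALSE)
  g <- networkGraph(net)
  utils::write.csv(data.frame(
    node = igraph::V(g)$name, median = igraph::V(g)$median,
    rank = igraph::V(g)$rank, overlay_eigenvector = kStar),
    p("network_nodes.csv"), row.names = FALSE)
  list.files(outDir, full.names = TRUE)
}
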