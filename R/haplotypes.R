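#' Code contiguous gap runs as single indel events
#'
#' Each maximal contiguous gap block is coded as one mutational event,
#' regardless of its length. Two gap runs in different individuals belong to
#' the same event only when they span exactly the same columns. Masked
#' columns are excluded before run detection, so contiguity is evaluated on
#' the retained columns.
#'
#' @param aln An \linkS4class{AlignedSeqSet}.
#' @return An \link[IRanges]{IRanges} (1-based, inclusive, in original
#'   alignment coordinates), sorted by start, with a \code{carriers}
#'   metadata column listing the individuals sharing each event.
#' @export
codeIndels <- function(aln) {
  stopifnot(is(aln, "AlignedSeqSet"))
  mat <- alnMatrix(aln)
  checkAlphabet(mat)
  keep <- setdiff(seq_len(ncol(mat)), aln@mask)
  if (length(keep) == 0L)
    return(IRanges::IRanges())
  sub <- mat[, keep, drop = FALSE]
  events <- list()   # key "start:end" (retained-coordinate span) -> carriers
  for (i in seq_len(nrow(sub))) {
    r <- rle(sub[i, ] == "-")
    e <- cumsum(r$lengths)
    s <- e - r$lengths + 1L
    for (j in which(r$values)) {
      key <- paste0(s[j], ":", e[j])
      events[[key]] <- c(events[[key]], rownames(sub)[i])
    }
  }
  if (length(events) == 0L) return(IRanges::IRanges())
  spans <- do.call(rbind, strsplit(names(events), ":", fixed = TRUE))
  st <- keep[as.integer(spans[, 1L])]
  en <- keep[as.integer(spans[, 2L])]
  o <- order(st, en)
  ir <- IRanges::IRanges(start = st[o], end = en[o])
  S4Vectors::mcols(ir)$carriers <- IRanges::CharacterList(events[o])
  ir
}

#' Collapse aligned individuals into haplotypes
#'
#' Individuals sharing identical nucleotide states at the identity columns
#' and an identical indel-event presence vector are collapsed into one
#' haplotype. Haplotype ids \code{"H1"}, \code{"H2"}, ... are assigned in
#' order of first appearance in the input.
#'
#' By default, columns containing an ambiguous base (\code{N}) in any record
#' are excluded from the identity key, so sequencing artifacts do not inflate
#' the haplotype count; with \code{strict = TRUE} those columns are kept and
#' \code{N} matches only \code{N}.
#'
#' @param aln An \linkS4class{AlignedSeqSet} (masked columns are never part
#'   of the identity).
#' @param events Indel events from \code{\link{codeIndels}}; computed from
#'   \code{aln} when missing.
#' @param strict Keep N-containing columns in the identity key.
#' @return A \linkS4class{HaplotypeTable}.
#' @export
collapseHaplotypes <- function(aln, events = codeIndels(aln),
                               strict = FALSE) {
  stopifnot(is(aln, "AlignedSeqSet"))
  mat <- alnMatrix(aln)
  checkAlphabet(mat)
  ids <- rownames(mat)
  keep <- setdiff(seq_len(ncol(mat)), aln@mask)
  if (!strict && length(keep)) {
    hasN <- colSums(mat[, keep, drop = FALSE] == "N") > 0L
    keep <- keep[!hasN]
  }
  nev <- length(events)
  pres <- matrix(FALSE, nrow(mat), max(nev, 1L))[, seq_len(nev), drop = FALSE]
  rownames(pres) <- ids
  if (nev) {
    carr <- S4Vectors::mcols(events)$carriers
    for (j in seq_len(nev)) pres[as.character(carr[[j]]), j] <- TRUE
  }
  nucKey <- apply(mat[, keep, drop = FALSE], 1L, paste, collapse = "")
  if (length(keep) == 0L) nucKey <- rep("", nrow(mat))
  key <- paste(nucKey, apply(pres, 1L, paste, collapse = ""), sep = "|")
  first <- !duplicated(key)
  hid <- paste0("H", match(key, key[first]))
  reps <- ids[first]
  hids <- paste0("H", seq_len(sum(first)))
  counts <- as.integer(table(factor(hid, levels = hids)))
  new("HaplotypeTable",
      ids = hids,
      seqs = stats::setNames(aln@seqs[reps], hids),
      nucStates = stats::setNames(nucKey[first], hids),
      indelStates = {
        m <- pres[reps, , drop = FALSE]; rownames(m) <- hids; m
      },
      events = events,
      membership = stats::setNames(hid, ids),
      counts = stats::setNames(counts, hids),
      identityColumns = as.integer(keep),
      mask = aln@mask)
}

# Tajima-Nei distance between two aligned character vectors (comparable
# columns only; both entries in {A,C,G,T}).
tajimaNeiPair <- function(a, b, labelA, labelB) {
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  L <- sum(ok)
  if (L == 0L)
    stop(sprintf("zero comparable sites between %s and %s", labelA, labelB))
  a <- a[ok]; b <- b[ok]
  p <- mean(a != b)
  if (p == 0) return(0)
  bases <- c("A", "C", "G", "T")
  g <- (table(factor(a, levels = bases)) +
        table(factor(b, levels = bases))) / (2 * L)
  # unordered mismatch-pair relative frequencies among all comparable sites
  h <- 0
  for (i in 1:3) for (j in (i + 1):4) {
    xij <- sum((a == bases[i] & b == bases[j]) |
               (a == bases[j] & b == bases[i])) / L
    if (xij > 0) h <- h + xij^2 / (2 * g[i] * g[j])
  }
  bb <- 0.5 * (1 - sum(g^2) + p^2 / h)
  if (p / bb >= 1)
    stop(sprintf("distance saturated between %s and %s (p/b = %.3f >= 1)",
                 labelA, labelB, p / bb))
  as.numeric(-bb * log(1 - p / bb))
}

#' Tajima-Nei distance matrix among haplotypes
#'
#' Computes the equal-input nucleotide distance of Tajima and Nei,
#' \eqn{d = -b \log(1 - p/b)} with
#' \eqn{b = (1 - \sum_i g_i^2 + p^2/h)/2} and
#' \eqn{h = \sum_{i<j} x_{ij}^2 / (2 g_i g_j)}, where \eqn{p} is the
#' proportion of differing comparable sites, \eqn{g_i} the base frequencies
#' pooled over the pair and \eqn{x_{ij}} the relative frequencies of
#' unordered mismatch pairs. Masked columns never enter the computation, and
#' coded indel events are excluded from the distance by default since the
#' model is substitution-based.
#'
#' @param tab A \linkS4class{HaplotypeTable}.
#' @param deletion \code{"complete"} drops columns with a gap or \code{N} in
#'   any haplotype before computing distances; \code{"pairwise"} drops them
#'   per pair.
#' @param indelDistance \code{"exclude"} (default) ignores indel events;
#'   \code{"add-events"} adds (event mismatches)/(comparable sites) to each
#'   pairwise distance for sensitivity analysis.
#' @return A symmetric numeric matrix with zero diagonal, dimnames the
#'   haplotype ids, in substitutions per site.
#' @export
tajimaNeiMatrix <- function(tab, deletion = c("complete", "pairwise"),
                            indelDistance = c("exclude", "add-events")) {
  stopifnot(is(tab, "HaplotypeTable"))
  deletion <- match.arg(deletion)
  indelDistance <- match.arg(indelDistance)
  n <- length(tab@ids)
  if (n < 2L) stop("at least two haplotypes are required")
  mat <- matrix(unlist(strsplit(as.character(tab@seqs), "", fixed = TRUE),
                       use.names = FALSE), nrow = n, byrow = TRUE)
  rownames(mat) <- tab@ids
  keep <- setdiff(seq_len(ncol(mat)), tab@mask)
  mat <- mat[, keep, drop = FALSE]
  if (deletion == "complete") {
    good <- colSums(!(mat == "-" | mat == "N")) == n
    mat <- mat[, good, drop = FALSE]
  }
  d <- matrix(0, n, n, dimnames = list(tab@ids, tab@ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    dij <- tajimaNeiPair(mat[i, ], mat[j, ], tab@ids[i], tab@ids[j])
    if (indelDistance == "add-events" && ncol(tab@indelStates)) {
      cmp <- sum(mat[i, ] %in% c("A", "C", "G", "T") &
                 mat[j, ] %in% c("A", "C", "G", "T"))
      dij <- dij + sum(tab@indelStates[i, ] != tab@indelStates[j, ]) / cmp
    }
    d[i, j] <- d[j, i] <- dij
  }
  d
}
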