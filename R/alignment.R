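ALN_ALPHABET <- c("A", "C", "G", "T", "-", "N")

#' Construct an aligned sequence set
#'
#' @param seqs A named character vector or \link[Biostrings]{DNAStringSet} of
#'   equal-length aligned sequences (alphabet \code{A,C,G,T,N,-}), one record
#'   per individual.
#' @param mask Integer vector of 1-based masked column indices.
#' @return An \linkS4class{AlignedSeqSet}.
#' @export
AlignedSeqSet <- function(seqs, mask = integer()) {
  if (length(seqs) == 0L) stop("no sequences")
  if (!methods::is(seqs, "DNAStringSet")) {
    ids <- names(seqs)
    chr <- toupper(as.character(seqs))
    bad <- grepl("[^ACGTN-]", chr)
    if (any(bad))
      stop(sprintf(
        "record '%s' contains characters outside {A,C,G,T,-,N}",
        if (is.null(ids)) which(bad)[1L] else ids[which(bad)[1L]]))
    seqs <- Biostrings::DNAStringSet(chr)
    names(seqs) <- ids
  }
  new("AlignedSeqSet", seqs = seqs,
      mask = sort(unique(as.integer(mask))))
}

#' Read an aligned FASTA file
#'
#' Reads a gapped FASTA alignment (gap character \code{"-"}), one record per
#' individual. Record ids are taken from the first whitespace-delimited token
#' of each header.
#'
#' @param path Path to the FASTA file.
#' @return An \linkS4class{AlignedSeqSet} with an empty mask.
#' @export
readAlignedFasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  AlignedSeqSet(seqs)
}

# character matrix view of the alignment (individuals x columns)
alnMatrix <- function(aln) {
  s <- as.character(aln@seqs)
  m <- matrix(unlist(strsplit(s, "", fixed = TRUE), use.names = FALSE),
              nrow = length(s), byrow = TRUE)
  rownames(m) <- names(aln@seqs)
  m
}

checkAlphabet <- function(mat) {
  bad <- !(mat %in% ALN_ALPHABET)
  if (any(bad)) {
    rec <- rownames(mat)[which(bad, arr.ind = TRUE)[1L, 1L]]
    stop(sprintf("record '%s' contains characters outside {A,C,G,T,-,N}", rec))
  }
  invisible(TRUE)
}

#' Majority-consensus sequence of an alignment
#'
#' Per column, the most frequent character among \code{A,C,G,T,N}; gaps are
#' ignored. Ties are broken in the fixed order A, C, G, T, N; all-gap columns
#' yield \code{"-"}.
#'
#' @param aln An \linkS4class{AlignedSeqSet}.
#' @return A single character string of the alignment width.
#' @export
consensusSequence <- function(aln) {
  mat <- alnMatrix(aln)
  checkAlphabet(mat)
  states <- c("A", "C", "G", "T", "N")
  apply(mat, 2L, function(col) {
    counts <- table(factor(col[col != "-"], levels = states))
    if (sum(counts) == 0L) "-" else states[which.max(counts)]
  }) |> paste(collapse = "")
}

#' Mask hypervariable poly-A/T columns
#'
#' Extends the alignment mask with every column lying inside a mononucleotide
#' A-run or T-run of length at least \code{minRun} in the majority-consensus
#' sequence. Such homopolymer runs in chloroplast spacers are prone to
#' slippage and homoplasy, so their variation is excluded from haplotype
#' identification and distances.
#'
#' @param aln An \linkS4class{AlignedSeqSet}.
#' @param minRun Minimum homopolymer run length to mask (default 6).
#' @return The alignment with an extended mask; records are unchanged.
#' @export
maskHypervariableColumns <- function(aln, minRun = 6L) {
  stopifnot(is(aln, "AlignedSeqSet"))
  if (length(aln@seqs) == 0L) stop("no sequences")
  minRun <- as.integer(minRun)
  if (minRun < 1L) stop("minRun must be >= 1")
  cons <- strsplit(consensusSequence(aln), "", fixed = TRUE)[[1L]]
  runs <- rle(cons)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  hit <- runs$values %in% c("A", "T") & runs$lengths >= minRun
  extra <- unlist(mapply(function(s, e) s:e, starts[hit], ends[hit],
                         SIMPLIFY = FALSE), use.names = FALSE)
  new("AlignedSeqSet", seqs = aln@seqs,
      mask = sort(unique(c(aln@mask, as.integer(extra)))))
}
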