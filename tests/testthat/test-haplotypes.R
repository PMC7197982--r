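test_that("poly-A/T masking follows consensus homopolymer runs", {
  a <- AlignedSeqSet(c(x = "ACGTACGT", y = "ACGTACGT"))
  expect_identical(maskedColumns(maskHypervariableColumns(a, 6)), integer(0))

  b <- AlignedSeqSet(c(x = "ACAAAAAAGT", y = "ACAAAAAAGT"))
  expect_identical(maskedColumns(maskHypervariableColumns(b, 6)), 3:8)

  # degenerate threshold masks every consensus A/T column
  m1 <- maskedColumns(maskHypervariableColumns(b, 1))
  expect_identical(m1, which(strsplit("ACAAAAAAGT", "")[[1]] %in% c("A", "T")))

  # gaps are ignored in the consensus: a gapped A-run still masks
  g <- AlignedSeqSet(c(x = "CAAAAAAC", y = "CAA-AAAC", z = "CAAAAAAC"))
  expect_identical(maskedColumns(maskHypervariableColumns(g, 6)), 2:7)

  expect_error(maskHypervariableColumns(AlignedSeqSet(c(a = "ACGT")), 0),
               "minRun")
})

test_that("indel events are maximal gap runs keyed by exact column span", {
  expect_length(codeIndels(AlignedSeqSet(c(a = "ACGT", b = "ACGT"))), 0)

  a <- AlignedSeqSet(c(s1 = "ACGTA", s2 = "AC-TA", s3 = "AC-TA"))
  ev <- codeIndels(a)
  expect_length(ev, 1)
  expect_identical(IRanges::start(ev), 3L)
  expect_identical(IRanges::end(ev), 3L)
  expect_setequal(as.character(S4Vectors::mcols(ev)$carriers[[1]]),
                  c("s2", "s3"))

  # different spans are different events even when they overlap
  b <- AlignedSeqSet(c(s1 = "A--TA", s2 = "A-GTA"))
  ev2 <- codeIndels(b)
  expect_length(ev2, 2)
  expect_identical(IRanges::start(ev2), c(2L, 2L))
  expect_identical(IRanges::end(ev2), c(2L, 3L))
  expect_identical(as.character(S4Vectors::mcols(ev2)$carriers[[1]]), "s2")
  expect_identical(as.character(S4Vectors::mcols(ev2)$carriers[[2]]), "s1")
})

test_that("haplotype collapsing distinguishes substitutions from indels", {
  a <- AlignedSeqSet(c(i1 = "ACGTA", i2 = "AC-TA", i3 = "AC-TA",
                       i4 = "ACGTA", i5 = "ACTTA"))
  tab <- collapseHaplotypes(a)
  expect_identical(haplotypeIds(tab), c("H1", "H2", "H3"))
  expect_identical(unname(haplotypeCounts(tab)), c(2L, 2L, 1L))
  expect_identical(unname(membership(tab)[c("i1", "i2", "i5")]),
                   c("H1", "H2", "H3"))

  # identity: two identical records collapse to one haplotype
  t2 <- collapseHaplotypes(AlignedSeqSet(c(a = "ACGT", b = "ACGT")))
  expect_length(haplotypeIds(t2), 1)
  expect_identical(unname(haplotypeCounts(t2)), 2L)

  # all-distinct records stay distinct
  t3 <- collapseHaplotypes(AlignedSeqSet(c(a = "ACGT", b = "AGGT",
                                           c = "ATGT")))
  expect_identical(unname(haplotypeCounts(t3)), c(1L, 1L, 1L))

  expect_error(collapseHaplotypes(AlignedSeqSet(c(ok = "ACGT",
                                                  bad = "ACXT"))),
               "bad")
})

test_that("N handling: lenient by default, distinguishing under strict", {
  a <- AlignedSeqSet(c(i1 = "ACGTA", i2 = "ANGTA"))
  expect_length(haplotypeIds(collapseHaplotypes(a)), 1)
  expect_length(haplotypeIds(collapseHaplotypes(a, strict = TRUE)), 2)
})

test_that("collapsing is idempotent and order-invariant", {
  set.seed(7)
  bases <- c("A", "C", "G", "T")
  recs <- replicate(12, paste(sample(bases, 8, TRUE), collapse = ""))
  recs[4] <- recs[1]; recs[9] <- recs[2]
  names(recs) <- paste0("i", 1:12)
  tab <- collapseHaplotypes(AlignedSeqSet(recs))
  # idempotence: collapsing the representatives yields the same table shape
  reps <- setNames(as.character(alignedSeqs(tab)), haplotypeIds(tab))
  tab2 <- collapseHaplotypes(AlignedSeqSet(reps))
  expect_identical(length(haplotypeIds(tab2)), length(haplotypeIds(tab)))
  expect_true(all(haplotypeCounts(tab2) == 1L))
  # permutation of record order only relabels haplotypes
  perm <- sample(12)
  tabP <- collapseHaplotypes(AlignedSeqSet(recs[perm]))
  expect_identical(sort(unname(haplotypeCounts(tabP))),
                   sort(unname(haplotypeCounts(tab))))
})

test_that("masking more columns never increases the haplotype count", {
  set.seed(11)
  bases <- c("A", "C", "G", "T")
  recs <- setNames(replicate(10,
    paste(sample(bases, 12, TRUE), collapse = "")), paste0("i", 1:10))
  counts <- vapply(list(integer(0), 1:2, 1:6, 1:10), function(m)
    length(haplotypeIds(collapseHaplotypes(AlignedSeqSet(recs, mask = m)))),
    integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("Tajima-Nei collapses to Jukes-Cantor under symmetric composition", {
  # 24 sites: every unordered mismatch pair twice (p = 1/2), matches
  # balanced so pooled base frequencies are uniform
  pairs <- list(c("A", "C"), c("A", "G"), c("A", "T"),
                c("C", "G"), c("C", "T"), c("G", "T"))
  a <- unlist(lapply(pairs, function(p) rep(p[1], 2)))
  b <- unlist(lapply(pairs, function(p) rep(p[2], 2)))
  for (x in c("A", "C", "G", "T")) { a <- c(a, rep(x, 3)); b <- c(b, rep(x, 3)) }
  tab <- collapseHaplotypes(AlignedSeqSet(
    c(h1 = paste(a, collapse = ""), h2 = paste(b, collapse = ""))))
  d <- tajimaNeiMatrix(tab)
  expect_lt(abs(d["H1", "H2"] - (-0.75 * log(1 - 4 * 0.5 / 3))), 1e-12)

  # identical sequences are at distance zero
  expect_identical(d["H1", "H1"], 0)
})

test_that("Tajima-Nei matches a literal per-pair reimplementation", {
  set.seed(3)
  bases <- c("A", "C", "G", "T")
  # related sequences: a shared ancestor with ~10% private mutations each,
  # keeping pairwise divergence well below saturation
  anc <- sample(bases, 120, TRUE, prob = c(.4, .25, .2, .15))
  recs <- setNames(vapply(1:6, function(i) {
    s <- anc
    mut <- sample(120, 12)
    s[mut] <- vapply(s[mut], function(bb)
      sample(setdiff(bases, bb), 1), character(1))
    paste(s, collapse = "")
  }, character(1)), paste0("i", 1:6))
  tab <- collapseHaplotypes(AlignedSeqSet(recs))
  d <- tajimaNeiMatrix(tab)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(is.finite(d)))
  # oracle: direct formula evaluation, independent loop structure
  mat <- do.call(rbind, strsplit(as.character(alignedSeqs(tab)), ""))
  for (i in 1:5) for (j in (i + 1):6) {
    x <- mat[i, ]; y <- mat[j, ]
    p <- mean(x != y)
    if (p == 0) { expect_identical(d[i, j], 0); next }
    g <- sapply(bases, function(bb) (sum(x == bb) + sum(y == bb)) /
                  (2 * length(x)))
    h <- 0
    cmb <- combn(4, 2)
    for (cidx in seq_len(ncol(cmb))) {
      b1 <- bases[cmb[1, cidx]]; b2 <- bases[cmb[2, cidx]]
      xij <- mean((x == b1 & y == b2) | (x == b2 & y == b1))
      if (xij > 0) h <- h + xij^2 / (2 * g[b1] * g[b2])
    }
    bcoef <- unname(0.5 * (1 - sum(g^2) + p^2 / h))
    expect_equal(unname(d[i, j]), -bcoef * log(1 - p / bcoef),
                 tolerance = 1e-12)
  }
})

test_that("saturated pairs and gap-only overlap raise informative errors", {
  # near-complete divergence under uniform composition saturates the log
  a <- paste(rep(c("A", "C", "G", "T"), 10), collapse = "")
  b <- paste(rep(c("C", "A", "T", "G"), 10), collapse = "")
  tab <- collapseHaplotypes(AlignedSeqSet(c(h1 = a, h2 = b)))
  expect_error(tajimaNeiMatrix(tab), "saturated")

  tab2 <- collapseHaplotypes(AlignedSeqSet(c(h1 = "AC--", h2 = "--GT",
                                             h3 = "ACGT")))
  expect_error(tajimaNeiMatrix(tab2, deletion = "pairwise"),
               "zero comparable sites")
})

test_that("complete vs pairwise deletion and indel-distance options differ as designed", {
  a <- AlignedSeqSet(c(i1 = "ACGTACGT", i2 = "AC-TACGA", i3 = "ACGTACGA"))
  tab <- collapseHaplotypes(a)
  dc <- tajimaNeiMatrix(tab, deletion = "complete")
  dp <- tajimaNeiMatrix(tab, deletion = "pairwise")
  # complete deletion drops the gapped column for every pair; the pair
  # (i1,i3) has no gap so pairwise deletion keeps one extra column
  expect_false(isTRUE(all.equal(dc["H1", "H3"], dp["H1", "H3"])))
  # indel events excluded by default: H1 vs H2 distance ignores the gap
  dAdd <- tajimaNeiMatrix(tab, indelDistance = "add-events")
  expect_gt(dAdd["H1", "H2"], dc["H1", "H2"])
})
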