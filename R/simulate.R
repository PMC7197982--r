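#' Simulate a Kingman-coalescent genealogy
#'
#' Successive coalescence times are exponential with rate
#' \eqn{\binom{j}{2}} for \eqn{j = n, \ldots, 2} lineages, merging a
#' uniformly random pair at each event. Time is in coalescent units, so the
#' expected tree depth is \eqn{2(1 - 1/n)}.
#'
#' @param n Number of tips (haplotypes), at least 3.
#' @param seed Optional integer seed.
#' @param labels Tip labels (default \code{"H1"}, ...).
#' @return An ultrametric \link[ape]{phylo} tree.
#' @export
simulateGenealogy <- function(n, seed = NULL, labels = paste0("H", seq_len(n))) {
  n <- as.integer(n)
  if (n < 3L) stop("need at least 3 tips")
  if (!is.null(seed)) set.seed(as.integer(seed))
  height <- numeric(2L * n - 1L)
  edge <- matrix(0L, 2L * n - 2L, 2L)
  elen <- numeric(2L * n - 2L)
  ei <- 0L
  # internal ids 2n-1 downwards so that the root (last coalescence) is n+1,
  # as ape requires
  intid <- 2L * n - 1L
  active <- seq_len(n)
  t <- 0
  for (j in n:2) {
    t <- t + stats::rexp(1L, rate = j * (j - 1) / 2)
    pair <- sample.int(length(active), 2L)
    parent <- intid
    intid <- intid - 1L
    height[parent] <- t
    for (child in active[pair]) {
      ei <- ei + 1L
      edge[ei, ] <- c(parent, child)
      elen[ei] <- height[parent] - height[child]
    }
    active <- c(active[-pair], parent)
  }
  tr <- list(edge = edge, edge.length = elen,
             tip.label = labels, Nnode = n - 1L)
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

# tip ids descending from the child end of each edge
edgeDescendants <- function(tree) {
  ntip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- i
  for (r in seq_len(nrow(po$edge))) {
    p <- po$edge[r, 1L]; ch <- po$edge[r, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  lapply(seq_len(nrow(tree$edge)),
         function(r) below[[tree$edge[r, 2L]]])
}

#' Simulate haplotype sequences on a genealogy
#'
#' Places substitutions on branches as a Poisson process with rate
#' \eqn{\theta/2} per unit branch length under the infinite-sites model:
#' every mutation occupies a previously unused alignment column, so the
#' pairwise mismatch count equals the number of mutations on the connecting
#' path. Indel events (optional) are placed the same way as contiguous gap
#' blocks with geometric length, carried by all tips below the branch.
#'
#' @param tree A \link[ape]{phylo} genealogy with branch lengths.
#' @param seqLength Alignment width in columns.
#' @param theta Scaled mutation parameter (expected pairwise differences).
#' @param indelRate Indel events per unit branch length.
#' @param indelMeanLength Mean gap-block length (geometric, minimum 1).
#' @param seed Optional integer seed.
#' @return An \linkS4class{AlignedSeqSet} with one record per tip.
#' @export
simulateSequences <- function(tree, seqLength = 600L, theta = 8,
                              indelRate = 0, indelMeanLength = 2,
                              seed = NULL) {
  seqLength <- as.integer(seqLength)
  if (seqLength < 1L) stop("seqLength must be >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  ntip <- length(tree$tip.label)
  bl <- tree$edge.length
  nmut <- stats::rpois(length(bl), theta / 2 * bl)
  nind <- stats::rpois(length(bl), indelRate * bl)
  desc <- edgeDescendants(tree)
  bases <- c("A", "C", "G", "T")
  root <- sample(bases, seqLength, replace = TRUE)
  mat <- matrix(rep(root, each = ntip), nrow = ntip)
  free <- rep(TRUE, seqLength)
  # substitutions: one fresh column per mutation
  for (r in seq_along(bl)) {
    if (nmut[r] == 0L) next
    avail <- which(free)
    if (length(avail) < nmut[r]) stop("sequence too short")
    cols <- if (length(avail) == 1L) avail else
      sample(avail, nmut[r])
    free[cols] <- FALSE
    for (col in cols) {
      derived <- sample(setdiff(bases, mat[1L, col]), 1L)
      mat[desc[[r]], col] <- derived
    }
  }
  # indels: contiguous fresh blocks
  for (r in seq_along(bl)) {
    if (nind[r] == 0L) next
    for (k in seq_len(nind[r])) {
      len <- 1L + stats::rgeom(1L, 1 / indelMeanLength)
      runs <- rle(free)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      ok <- which(runs$values & runs$lengths >= len)
      if (length(ok) == 0L) stop("sequence too short")
      pick <- ok[sample.int(length(ok), 1L)]
      offset <- sample.int(runs$lengths[pick] - len + 1L, 1L) - 1L
      cols <- (starts[pick] + offset):(starts[pick] + offset + len - 1L)
      free[cols] <- FALSE
      mat[desc[[r]], cols] <- "-"
    }
  }
  AlignedSeqSet(stats::setNames(apply(mat, 1L, paste, collapse = ""),
                                tree$tip.label))
}

#' Simulate trait evolution on a genealogy
#'
#' Root-to-tip simulation under one of three models. BM: Gaussian
#' increments with variance \eqn{\sigma^2 \cdot} branch length. OU: exact
#' transition sampling of an Ornstein-Uhlenbeck process with attraction
#' \eqn{\alpha} toward 0 and stationary variance \eqn{\sigma^2/(2\alpha)};
#' the root is drawn from the stationary distribution. EB (early burst):
#' BM whose instantaneous rate decays as \eqn{\sigma^2 e^{-\lambda t}} with
#' time \eqn{t} from the root.
#'
#' @param tree A \link[ape]{phylo} genealogy.
#' @param model One of \code{"BM"}, \code{"OU"}, \code{"EB"}.
#' @param sigma2 Base diffusion rate.
#' @param alpha OU attraction strength (required positive under OU).
#' @param decay EB rate-decay constant (per unit time).
#' @param seed Optional integer seed.
#' @return Named numeric vector of tip trait values.
#' @export
simulateTrait <- function(tree, model = c("BM", "OU", "EB"), sigma2 = 1,
                          alpha = 5, decay = 1.5, seed = NULL) {
  model <- match.arg(model)
  if (model == "OU" && (is.null(alpha) || alpha <= 0))
    stop("alpha must be positive under OU")
  if (!is.null(seed)) set.seed(as.integer(seed))
  ntip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "cladewise")
  tfromroot <- ape::node.depth.edgelength(tr)
  x <- numeric(ntip + tr$Nnode)
  if (model == "OU") x[ntip + 1L] <- stats::rnorm(1L, 0, sqrt(sigma2 / (2 * alpha)))
  for (r in seq_len(nrow(tr$edge))) {
    p <- tr$edge[r, 1L]; ch <- tr$edge[r, 2L]; len <- tr$edge.length[r]
    x[ch] <- switch(model,
      BM = x[p] + stats::rnorm(1L, 0, sqrt(sigma2 * len)),
      OU = x[p] * exp(-alpha * len) +
        stats::rnorm(1L, 0, sqrt(sigma2 / (2 * alpha) *
                                   (1 - exp(-2 * alpha * len)))),
      EB = x[p] + stats::rnorm(1L, 0, sqrt(
        sigma2 * (exp(-decay * tfromroot[p]) -
                  exp(-decay * tfromroot[ch])) / decay)))
  }
  stats::setNames(x[seq_len(ntip)], tr$tip.label)
}

#' Simulate a per-individual climate table around haplotype niche means
#'
#' Draws the number of individuals per haplotype as 1 + Poisson(mean - 1),
#' builds a haplotype-level mean for each of the 20 niche variables as the
#' simulated trait value plus an independent per-variable offset, and adds
#' independent Gaussian noise per individual. Coordinates are jittered
#' around a per-haplotype center inside the subtropical-grassland window.
#'
#' @param traits Named numeric vector of per-haplotype trait values.
#' @param meanIndividuals Expected individuals per haplotype (>= 1).
#' @param climateNoiseSd Within-haplotype noise standard deviation.
#' @param offsetSd Standard deviation of the per-variable offsets.
#' @param seed Optional integer seed.
#' @return A list with \code{individuals} (data frame: individual_id, lon,
#'   lat, 20 variables), \code{membership} (individual -> haplotype) and
#'   \code{haplotypeMeans} (matrix of the true niche means).
#' @export
simulateIndividualTable <- function(traits, meanIndividuals = 4,
                                    climateNoiseSd = 0.5, offsetSd = 2,
                                    seed = NULL) {
  if (is.null(names(traits))) stop("traits must be named by haplotype id")
  if (meanIndividuals < 1) stop("meanIndividuals must be >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  vars <- bioclimVariables()$variable
  nh <- length(traits)
  offsets <- stats::rnorm(length(vars), 0, offsetSd)
  means <- outer(unname(traits), offsets, "+")
  dimnames(means) <- list(names(traits), vars)
  m <- 1L + stats::rpois(nh, meanIndividuals - 1)
  centerLon <- stats::runif(nh, -60, -48)
  centerLat <- stats::runif(nh, -35, -22)
  rows <- vector("list", nh)
  for (h in seq_len(nh)) {
    vals <- matrix(stats::rnorm(m[h] * length(vars), 0, climateNoiseSd),
                   m[h], length(vars))
    vals <- sweep(vals, 2L, means[h, ], "+")
    colnames(vals) <- vars
    rows[[h]] <- data.frame(
      individual_id = paste0(names(traits)[h], "_i", seq_len(m[h])),
      lon = centerLon[h] + stats::rnorm(m[h], 0, 0.05),
      lat = centerLat[h] + stats::rnorm(m[h], 0, 0.05),
      vals, check.names = FALSE)
  }
  individuals <- do.call(rbind, rows)
  rownames(individuals) <- NULL
  membership <- stats::setNames(rep(names(traits), m),
                                individuals$individual_id)
  list(individuals = individuals, membership = membership,
       haplotypeMeans = means)
}

#' Simulate a complete synthetic dataset
#'
#' Generates the full input bundle the pipeline consumes: a coalescent
#' genealogy over \code{nHaplotypes} tips, infinite-sites sequences with
#' optional indels (replicated to one alignment record per individual), a
#' trait evolved under the chosen model, and a per-individual climate
#' table. Tips whose sequences would collapse together receive one private
#' substitution each, so the alignment collapses back to exactly
#' \code{nHaplotypes} haplotypes.
#'
#' @param nHaplotypes Number of haplotypes (coalescent tips).
#' @param seqLength Alignment width.
#' @param theta Scaled mutation parameter.
#' @param indelRate Indel events per unit branch length.
#' @param traitModel \code{"BM"}, \code{"OU"} or \code{"EB"}.
#' @param sigma2,alpha,decay Trait-model parameters (see
#'   \code{\link{simulateTrait}}).
#' @param meanIndividuals Expected individuals per haplotype.
#' @param climateNoiseSd Within-haplotype climate noise SD.
#' @param seed Mandatory integer seed; the whole dataset is reproducible
#'   from it.
#' @return A \linkS4class{SyntheticDataset}.
#' @export
simulateDataset <- function(nHaplotypes = 64L, seqLength = 600L, theta = 8,
                            indelRate = 0.5, traitModel = "BM", sigma2 = 1,
                            alpha = 5, decay = 1.5, meanIndividuals = 4,
                            climateNoiseSd = 0.5, seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(as.integer(seed))
  tree <- simulateGenealogy(nHaplotypes)
  haps <- simulateSequences(tree, seqLength = seqLength, theta = theta,
                            indelRate = indelRate)
  # condition on distinct haplotypes: give duplicated tips a private
  # substitution at a fresh column
  mat <- alnMatrix(haps)
  repeat {
    key <- apply(mat, 1L, paste, collapse = "")
    dup <- which(duplicated(key))
    if (length(dup) == 0L) break
    used <- apply(mat, 2L, function(col) length(unique(col)) > 1L)
    avail <- which(!used)
    if (length(avail) < length(dup)) stop("sequence too short")
    cols <- if (length(avail) == 1L) avail else sample(avail, length(dup))
    for (i in seq_along(dup)) {
      col <- cols[i]
      mat[dup[i], col] <- sample(setdiff(c("A", "C", "G", "T"),
                                         mat[dup[i], col]), 1L)
    }
  }
  traits <- simulateTrait(tree, model = traitModel, sigma2 = sigma2,
                          alpha = alpha, decay = decay)
  ind <- simulateIndividualTable(traits, meanIndividuals = meanIndividuals,
                                 climateNoiseSd = climateNoiseSd)
  hapSeq <- apply(mat, 1L, paste, collapse = "")
  perInd <- stats::setNames(hapSeq[ind$membership],
                            names(ind$membership))
  new("SyntheticDataset",
      alignment = AlignedSeqSet(perInd),
      tree = tree, traits = traits, model = traitModel,
      individuals = ind$individuals, haplotypeMeans = ind$haplotypeMeans)
}

#' Write a synthetic dataset to disk
#'
#' Emits exactly the formats the pipeline consumes: an aligned FASTA (one
#' record per individual), the individuals CSV, the trait-class CSV, plus
#' truth files (Newick tree, trait CSV, model label).
#'
#' @param ds A \linkS4class{SyntheticDataset}.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the file paths written.
#' @export
writeDataset <- function(ds, dir) {
  stopifnot(is(ds, "SyntheticDataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    alignment = file.path(dir, "alignment.fasta"),
    individuals = file.path(dir, "individuals.csv"),
    classes = file.path(dir, "classes.csv"),
    tree = file.path(dir, "truth_tree.nwk"),
    traits = file.path(dir, "truth_traits.csv"),
    model = file.path(dir, "truth_model.txt"))
  Biostrings::writeXStringSet(ds@alignment@seqs, paths["alignment"])
  utils::write.csv(ds@individuals, paths["individuals"], row.names = FALSE)
  v <- bioclimVariables()
  utils::write.csv(data.frame(variable = v$variable, class = v$class),
                   paths["classes"], row.names = FALSE)
  ape::write.tree(ds@tree, paths["tree"])
  utils::write.csv(data.frame(haplotype_id = names(ds@traits),
                              trait = unname(ds@traits)),
                   paths["traits"], row.names = FALSE)
  writeLines(ds@model, paths["model"])
  invisible(paths)
}
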