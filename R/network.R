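#' Character matrix for network construction
#'
#' One row per haplotype: variable nucleotide columns plus one binary
#' column per coded indel event. Positions deleted in a haplotype are
#' encoded as the wildcard state \code{"?"}, which never contributes to
#' network distances — the corresponding gap is carried by the event
#' column, so an indel counts as exactly one mutational step while
#' substitutions at the same column between non-carriers still count.
#' Columns with fewer than two distinct non-wildcard states are removed.
#'
#' @param tab A \linkS4class{HaplotypeTable}.
#' @return Character matrix, rownames the haplotype ids.
#' @export
characterMatrix <- function(tab) {
  stopifnot(is(tab, "HaplotypeTable"))
  n <- length(tab@ids)
  nuc <- matrix(unlist(strsplit(tab@nucStates, "", fixed = TRUE),
                       use.names = FALSE),
                nrow = n, byrow = TRUE)[, , drop = FALSE]
  if (length(tab@identityColumns)) {
    colnames(nuc) <- paste0("c", tab@identityColumns)
    nuc[nuc == "-"] <- "?"
  }
  ev <- matrix(character(0), n, 0L)
  if (ncol(tab@indelStates)) {
    ev <- ifelse(tab@indelStates, "1", "0")
    colnames(ev) <- paste0("indel", seq_len(ncol(ev)))
  }
  chars <- cbind(nuc, ev)
  rownames(chars) <- tab@ids
  variable <- apply(chars, 2L, function(x)
    length(unique(x[x != "?"])) > 1L)
  chars[, variable, drop = FALSE]
}

hammingMatrix <- function(chars) {
  n <- nrow(chars)
  d <- matrix(0L, n, n, dimnames = list(rownames(chars), rownames(chars)))
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- sum(chars[i, ] != chars[j, ] &
                              chars[i, ] != "?" & chars[j, ] != "?")
  }
  d
}

# minimum-spanning network: process distance levels in ascending order; at
# each merge step keep every cross-component link within eps of the minimal
# connecting weight. Returns an edge matrix (i, j, w).
msnEdges <- function(d, eps = 0L) {
  n <- nrow(d)
  if (n < 2L) return(matrix(0L, 0L, 3L))
  comp <- seq_len(n)
  edges <- NULL
  while (length(unique(comp)) > 1L) {
    cross <- outer(comp, comp, "!=") & upper.tri(d)
    delta <- min(d[cross])
    sel <- which(cross & d <= delta + eps, arr.ind = TRUE)
    edges <- rbind(edges, cbind(sel, d[sel]))
    for (r in seq_len(nrow(sel))) {
      ci <- comp[sel[r, 1L]]; cj <- comp[sel[r, 2L]]
      if (ci != cj) comp[comp == cj] <- ci
    }
  }
  edges
}

mstCost <- function(d) {
  # Prim's algorithm on a full distance matrix
  n <- nrow(d)
  if (n < 2L) return(0)
  inTree <- c(TRUE, rep(FALSE, n - 1L))
  best <- d[1L, ]
  cost <- 0
  for (step in seq_len(n - 1L)) {
    cand <- which(!inTree)
    v <- cand[which.min(best[cand])]
    cost <- cost + best[v]
    inTree[v] <- TRUE
    best <- pmin(best, d[v, ])
  }
  cost
}

# quasi-medians of three character vectors: majority state per column; where
# all three states differ every observed state is kept, spawning all
# combinations.
quasiMedians <- function(a, b, c, cap = 1000L) {
  states <- mapply(function(x, y, z) {
    s <- c(x, y, z)
    t <- sort(table(s), decreasing = TRUE)
    if (t[1L] >= 2L) names(t)[1L] else unique(s)
  }, a, b, c, SIMPLIFY = FALSE)
  ncomb <- prod(lengths(states))
  if (ncomb > cap)
    stop(sprintf("median vector cap exceeded (%d candidates > %d)",
                 ncomb, cap))
  as.matrix(expand.grid(states, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE))
}

#' Build a median-joining haplotype network
#'
#' Connects observed haplotypes through a minimum-spanning network over
#' Hamming distances (keeping, at each merge step, all links within
#' \code{epsilon} of the minimal connecting weight), then iteratively adds
#' majority-state (quasi-)median vectors of triplets connected in the
#' network whenever a median reduces the total spanning cost, and finally
#' deletes obsolete median vectors (degree at most one). The procedure is
#' deterministic for a fixed row ordering of \code{chars}.
#'
#' @param chars Character matrix from \code{\link{characterMatrix}}.
#' @param epsilon Non-negative weight tolerance of the spanning network
#'   (default 0, the most parsimonious network).
#' @param medianCap Maximum number of candidate vectors spawned by ties in
#'   one triplet (error beyond).
#' @return A \linkS4class{HaplotypeNetwork}; median vectors are named
#'   \code{"mv1"}, \code{"mv2"}, ... and flagged by the vertex attribute
#'   \code{median}.
#' @export
buildMJNetwork <- function(chars, epsilon = 0L, medianCap = 1000L) {
  if (is.null(dim(chars)) || nrow(chars) == 0L) stop("empty character matrix")
  if (epsilon < 0L) stop("epsilon must be >= 0")
  observed <- rownames(chars)
  if (is.null(observed)) stop("character matrix must have rownames")
  seqs <- chars
  nmv <- 0L
  repeat {
    d <- hammingMatrix(seqs)
    e <- msnEdges(d, epsilon)
    adj <- matrix(FALSE, nrow(seqs), nrow(seqs))
    if (nrow(e)) adj[e[, 1:2, drop = FALSE]] <- TRUE
    adj <- adj | t(adj)
    # candidate medians from triplets sharing a hub in the current network
    existing <- apply(seqs, 1L, paste, collapse = "\r")
    cand <- NULL
    nseq <- nrow(seqs)
    for (u in seq_len(nseq)) {
      nb <- which(adj[u, ])
      if (length(nb) < 2L) next
      for (i in seq_len(length(nb) - 1L)) for (j in (i + 1L):length(nb)) {
        q <- quasiMedians(seqs[u, ], seqs[nb[i], ], seqs[nb[j], ],
                          cap = medianCap)
        cand <- rbind(cand, q)
      }
    }
    if (is.null(cand)) break
    key <- apply(cand, 1L, paste, collapse = "\r")
    cand <- cand[!duplicated(key) & !(key %in% existing), , drop = FALSE]
    if (nrow(cand) == 0L) break
    # greedy: add the candidate giving the largest spanning-cost reduction
    cost0 <- mstCost(d)
    bestGain <- 0; bestRow <- 0L
    for (r in seq_len(nrow(cand))) {
      dc <- apply(seqs, 1L, function(s)
        sum(s != cand[r, ] & s != "?" & cand[r, ] != "?"))
      d2 <- rbind(cbind(d, dc), c(dc, 0L))
      gain <- cost0 - mstCost(d2)
      if (gain > bestGain + 1e-9) { bestGain <- gain; bestRow <- r }
    }
    if (bestRow == 0L) break
    nmv <- nmv + 1L
    seqs <- rbind(seqs, cand[bestRow, , drop = FALSE])
    rownames(seqs)[nrow(seqs)] <- paste0("mv", nmv)
  }
  # prune median vectors of degree <= 1
  repeat {
    d <- hammingMatrix(seqs)
    e <- msnEdges(d, epsilon)
    deg <- tabulate(c(e[, 1L], e[, 2L]), nbins = nrow(seqs))
    drop <- which(deg <= 1L & !(rownames(seqs) %in% observed))
    if (length(drop) == 0L || nrow(seqs) == 1L) break
    seqs <- seqs[-drop, , drop = FALSE]
  }
  g <- igraph::make_empty_graph(n = nrow(seqs), directed = FALSE)
  igraph::V(g)$name <- rownames(seqs)
  igraph::V(g)$median <- !(rownames(seqs) %in% observed)
  if (nrow(seqs) > 1L) {
    e <- msnEdges(hammingMatrix(seqs), epsilon)
    g <- igraph::add_edges(g, t(e[, 1:2, drop = FALSE]))
    igraph::E(g)$weight <- e[, 3L]
  }
  new("HaplotypeNetwork", graph = g, observedIds = observed)
}

#' Globally optimal one-dimensional K-means
#'
#' Exact 1-D K-means by dynamic programming on the sorted values: the
#' optimal clusters are contiguous intervals, and the within-cluster sum of
#' squares is minimized globally (unlike Lloyd iterations). Ranks are
#' numbered 1..g by ascending cluster center.
#'
#' @param scores Named numeric vector (haplotype id -> score).
#' @param g Number of groups; must not exceed the number of distinct scores.
#' @return A \linkS4class{RankOverlay}.
#' @export
kmeansRanks1D <- function(scores, g) {
  g <- as.integer(g)
  if (g < 1L) stop("g must be >= 1")
  if (g > length(unique(scores))) stop("too many groups")
  if (is.null(names(scores))) names(scores) <- seq_along(scores)
  o <- order(scores)
  x <- scores[o]
  n <- length(x)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  sse <- function(i, j) {   # cost of cluster x[i..j]
    s <- cs[j] - if (i > 1L) cs[i - 1L] else 0
    s2 <- cs2[j] - if (i > 1L) cs2[i - 1L] else 0
    s2 - s^2 / (j - i + 1L)
  }
  D <- matrix(Inf, g, n)
  back <- matrix(0L, g, n)
  for (i in seq_len(n)) D[1L, i] <- sse(1L, i)
  if (g > 1L) for (m in 2:g) for (i in m:n) {
    for (j in m:i) {   # cluster m covers x[j..i]
      v <- D[m - 1L, j - 1L] + sse(j, i)
      if (v < D[m, i] - 1e-12) { D[m, i] <- v; back[m, i] <- j }
    }
  }
  bounds <- integer(g + 1L); bounds[g + 1L] <- n
  i <- n
  if (g > 1L) for (m in g:2) { j <- back[m, i]; bounds[m] <- j - 1L; i <- j - 1L }
  bounds[1L] <- 0L
  rank <- integer(n)
  centers <- numeric(g)
  for (m in seq_len(g)) {
    idx <- (bounds[m] + 1L):bounds[m + 1L]
    rank[idx] <- m
    centers[m] <- mean(x[idx])
  }
  ranks <- integer(length(scores))
  ranks[o] <- rank
  names(ranks) <- names(scores)
  new("RankOverlay", eigenvectorIndex = NA_integer_, ranks = ranks,
      centers = centers)
}

#' Overlay eigenvector ranks on a haplotype network
#'
#' Groups the scores of eigenvector \code{k} into \code{g} ranks with exact
#' 1-D K-means and attaches the rank as the vertex attribute \code{rank} of
#' the network's observed nodes; median vectors get \code{NA}. Used to
#' shade network nodes by evolutionary representativeness.
#'
#' @param net A \linkS4class{HaplotypeNetwork}.
#' @param basis An \linkS4class{EigenBasis} covering the observed nodes.
#' @param k Eigenvector index.
#' @param g Number of rank groups (default 4).
#' @return The network with rank attributes set, plus the overlay stored in
#'   the graph attribute \code{overlay}.
#' @export
overlayEigenvector <- function(net, basis, k, g = 4L) {
  stopifnot(is(net, "HaplotypeNetwork"), is(basis, "EigenBasis"))
  k <- as.integer(k)
  if (k < 1L || k > ncol(basis@vectors))
    stop(sprintf("eigenvector index %d out of range 1..%d",
                 k, ncol(basis@vectors)))
  obs <- net@observedIds
  if (!all(obs %in% basis@ids))
    stop("observed haplotype missing from the eigenbasis")
  scores <- stats::setNames(basis@vectors[obs, k], obs)
  ov <- kmeansRanks1D(scores, g)
  ov@eigenvectorIndex <- k
  gph <- net@graph
  vr <- rep(NA_integer_, igraph::vcount(gph))
  vr[match(obs, igraph::V(gph)$name)] <- ov@ranks[obs]
  igraph::V(gph)$rank <- vr
  gph <- igraph::set_graph_attr(gph, "overlay", ov)
  new("HaplotypeNetwork", graph = gph, observedIds = obs)
}

#' Edge list of a haplotype network
#'
#' @param net A \linkS4class{HaplotypeNetwork}.
#' @return Data frame with columns \code{from}, \code{to}, \code{weight}.
#' @export
networkEdges <- function(net) {
  stopifnot(is(net, "HaplotypeNetwork"))
  e <- igraph::as_edgelist(net@graph)
  data.frame(from = e[, 1L], to = e[, 2L],
             weight = if (igraph::ecount(net@graph))
               igraph::E(net@graph)$weight else numeric(0))
}
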