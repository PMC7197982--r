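# Independent oracles and fixture builders shared across tests.

# random Euclidean point configuration -> (distance matrix, coordinates)
euclideanFixture <- function(n, dims = 3, seed = 1) {
  set.seed(seed)
  pts <- matrix(rnorm(n * dims), n, dims)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("H", seq_len(n)), paste0("H", seq_len(n)))
  list(d = d, pts = pts)
}

# brute-force cumulative R2 by refitting OLS normal equations at every k
oracleR2 <- function(vectors, trait) {
  y <- as.numeric(trait)
  n <- length(y)
  vapply(seq_len(ncol(vectors)), function(k) {
    X <- cbind(1, vectors[, seq_len(k), drop = FALSE])
    beta <- solve(crossprod(X), crossprod(X, y))
    sse <- sum((y - X %*% beta)^2)
    1 - sse / sum((y - mean(y))^2)
  }, numeric(1))
}

# fine-grid numeric integration of (r2(x) - x) with linear interpolation;
# the curve's own knots are added to the grid so kinks are represented
oracleArea <- function(x, r2, npts = 1e5) {
  xs <- sort(unique(c(seq(min(x), max(x), length.out = npts), x)))
  f <- approx(x, r2, xout = xs)$y - xs
  sum((f[-1] + f[-length(f)]) / 2 * diff(xs))
}

# exhaustive 1-D k-means over all contiguous partitions of sorted values
oracleKmeans1D <- function(x, g) {
  o <- order(x); xs <- x[o]; n <- length(xs)
  cuts <- combn(seq_len(n - 1), g - 1, simplify = FALSE)
  if (g == 1) cuts <- list(integer(0))
  best <- Inf; bestAssign <- NULL
  for (cut in cuts) {
    b <- c(0, cut, n)
    w <- 0; assign <- integer(n)
    for (m in seq_len(g)) {
      idx <- (b[m] + 1):b[m + 1]
      w <- w + sum((xs[idx] - mean(xs[idx]))^2)
      assign[idx] <- m
    }
    if (w < best - 1e-12) { best <- w; bestAssign <- assign }
  }
  out <- integer(n); out[o] <- bestAssign
  list(wcss = best, assign = out)
}

# MST total cost over a distance matrix (Kruskal with union-find)
oracleMSTCost <- function(d) {
  n <- nrow(d)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  pairs <- pairs[order(d[pairs]), , drop = FALSE]
  comp <- seq_len(n); cost <- 0
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (comp[i] != comp[j]) {
      cost <- cost + d[i, j]
      comp[comp == comp[j]] <- comp[i]
    }
  }
  cost
}

# minimal total edge cost of a Steiner star/tree over binary sequences,
# found by exhaustive search over all candidate internal vertices
oracleSteinerTriplet <- function(chars) {
  m <- ncol(chars)
  states <- expand.grid(rep(list(c("0", "1")), m), stringsAsFactors = FALSE)
  best <- oracleMSTCost(hammingOracle(chars))
  for (r in seq_len(nrow(states))) {
    aug <- rbind(chars, unlist(states[r, ]))
    best <- min(best, oracleMSTCost(hammingOracle(aug)))
  }
  best
}

hammingOracle <- function(chars) {
  n <- nrow(chars)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sum(chars[i, ] != chars[j, ])
  d
}

# spreadsheet-style group-by mean
oracleGroupMean <- function(df, vars, group) {
  sapply(vars, function(v) tapply(df[[v]], group, mean))
}

# network spanning cost: total weight of an MST of the network graph,
# computed on the graph's own edges
networkSpanningCost <- function(net) {
  g <- networkGraph(net)
  sum(igraph::E(igraph::mst(g, weights = igraph::E(g)$weight))$weight)
}
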