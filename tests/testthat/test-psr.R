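basisFixture <- function(n, seed = 1, dims = 4) {
  pcoaBasis(euclideanFixture(n, dims = dims, seed = seed)$d)
}

test_that("PSR curves match the brute-force normal-equations oracle", {
  for (seed in 1:10) {
    b <- basisFixture(6 + seed %% 5, seed = seed)
    set.seed(seed + 100)
    y <- setNames(rnorm(length(haplotypeIds(b))), haplotypeIds(b))
    cu <- fitPSRCurve(b, y)
    pts <- psrPoints(cu)
    expect_identical(pts$x[1], 0)
    expect_identical(pts$r2[1], 0)
    expect_true(all(diff(pts$r2) >= -1e-12))
    expect_equal(pts$r2[-1], oracleR2(eigenvectors(b), y),
                 tolerance = 1e-10)
  }
})

test_that("a trait equal to an eigenvector saturates at that axis", {
  b <- basisFixture(8, seed = 3)
  y <- setNames(eigenvectors(b)[, 1], haplotypeIds(b))
  r2 <- psrPoints(fitPSRCurve(b, y))$r2[-1]
  expect_equal(r2, rep(1, length(r2)), tolerance = 1e-10)

  # rank-1 basis spans a collinear trait exactly: curve {(0,0),(1,1)}
  pos <- c(0, 1, 3, 6)
  D <- abs(outer(pos, pos, "-"))
  dimnames(D) <- list(paste0("H", 1:4), paste0("H", 1:4))
  cu <- fitPSRCurve(pcoaBasis(D), setNames(pos, paste0("H", 1:4)))
  expect_equal(psrPoints(cu)$x, c(0, 1))
  expect_equal(psrPoints(cu)$r2, c(0, 1), tolerance = 1e-10)

  expect_error(fitPSRCurve(b, setNames(rep(1, 8), haplotypeIds(b))),
               "zero trait variance")
  expect_error(fitPSRCurve(b, rnorm(5)), "length")
})

test_that("signed areas agree with fine-grid integration and stay bounded", {
  # hand examples
  diagCurve <- new("PSRCurve", trait = "t", x = c(0, 0.4, 1),
                   r2 = c(0, 0.4, 1), k = 0:2)
  expect_equal(areaValue(psrArea(diagCurve)), 0)
  stepCurve <- new("PSRCurve", trait = "t", x = c(0, 0.5, 1),
                   r2 = c(0, 1, 1), k = 0:2)
  expect_equal(areaValue(psrArea(stepCurve)), 0.25)
  # random curves vs numeric-integration oracle
  set.seed(42)
  for (rep in 1:20) {
    K <- sample(3:12, 1)
    x <- c(0, sort(runif(K - 1)), 1)
    r2 <- c(0, sort(runif(K - 1)), 1)
    cu <- new("PSRCurve", trait = "t", x = x, r2 = r2, k = 0:K)
    a <- areaValue(psrArea(cu))
    expect_lt(abs(a - oracleArea(x, r2)), 1e-9)
    expect_lte(abs(a), 0.5)
  }
})

test_that("curve and area are invariant to joint relabelling", {
  fx <- euclideanFixture(9, seed = 17)
  b <- pcoaBasis(fx$d)
  set.seed(18)
  y <- setNames(rnorm(9), haplotypeIds(b))
  a1 <- areaValue(psrArea(fitPSRCurve(b, y)))
  perm <- sample(9)
  b2 <- pcoaBasis(fx$d[perm, perm])
  a2 <- areaValue(psrArea(fitPSRCurve(b2, y)))
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("Euclidean bases give complete curves ending at (1,1)", {
  for (seed in 1:5) {
    b <- basisFixture(7, seed = seed, dims = 3)
    set.seed(seed)
    y <- setNames(rnorm(7), haplotypeIds(b))
    pts <- psrPoints(fitPSRCurve(b, y))
    expect_lt(abs(pts$x[nrow(pts)] - 1), 1e-12)
    expect_lt(abs(pts$r2[nrow(pts)] - 1), 1e-8)
  }
})

test_that("permutation null: envelope shape, p-value range, determinism", {
  b <- basisFixture(8, seed = 23)
  set.seed(5)
  y <- setNames(rnorm(8), haplotypeIds(b))
  r1 <- nullEnvelope(b, y, nRand = 99, seed = 11)
  r2 <- nullEnvelope(b, y, nRand = 99, seed = 11)
  expect_identical(r1$area@nullAreas, r2$area@nullAreas)
  expect_identical(pValue(r1$area), pValue(r2$area))
  expect_gt(pValue(r1$area), 0)
  expect_lte(pValue(r1$area), 1)
  env <- r1$envelope
  expect_true(all(env@lo <= env@hi + 1e-12))
  expect_error(nullEnvelope(b, y, nRand = 0), "nRand")
})

test_that("exhaustive permutation p equals an independent enumeration", {
  for (n in 4:5) {
    fx <- euclideanFixture(n, seed = n)
    b <- pcoaBasis(fx$d)
    set.seed(n + 50)
    y <- setNames(rnorm(n), haplotypeIds(b))
    res <- nullEnvelope(b, y, seed = 1, exhaustive = TRUE)
    # oracle: every permutation through the OLS oracle and trapezoid rule
    perms <- psrniche:::allPermutations(n)
    x <- c(0, cumsum(relEigenvalues(b)))
    areas <- apply(perms, 1, function(p) {
      r2 <- c(0, oracleR2(eigenvectors(b), unname(y)[p]))
      sum((head(r2 - x, -1) + tail(r2 - x, -1)) / 2 * diff(x))
    })
    obs <- areas[1]  # identity permutation is the first in lexicographic order
    expect_equal(pValue(res$area),
                 mean(abs(areas) >= abs(obs) - 1e-12))
    expect_identical(res$envelope@nRand, as.integer(factorial(n)))
  }
})

test_that("null p-values are approximately uniform under the null", {
  b <- basisFixture(7, seed = 31)
  set.seed(99)
  ps <- replicate(100, {
    y <- setNames(rnorm(7), haplotypeIds(b))
    pValue(nullEnvelope(b, y, nRand = 59, seed = sample.int(1e6, 1))$area)
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.15)
})

test_that("R2 peak detection ranks increments with small-k tie-break", {
  cu <- new("PSRCurve", trait = "t", x = c(0, 0.25, 0.5, 0.75, 1),
            r2 = c(0, 0.1, 0.15, 0.60, 0.62), k = 0:4)
  pk <- detectR2Peaks(cu, topN = 2)
  expect_identical(pk@topK[1], 3L)
  expect_equal(pk@delta[3], 0.45)
  expect_equal(sum(pk@delta), 0.62)

  lin <- new("PSRCurve", trait = "t", x = c(0, 0.25, 0.5, 0.75, 1),
             r2 = c(0, 0.25, 0.5, 0.75, 1), k = 0:4)
  expect_identical(detectR2Peaks(lin)@topK[1], 1L)

  # constructed trait on eigenvector 5 peaks at k = 5
  b <- basisFixture(10, seed = 41, dims = 6)
  y <- setNames(eigenvectors(b)[, 5], haplotypeIds(b))
  pk5 <- detectR2Peaks(fitPSRCurve(b, y))
  expect_identical(pk5@topK[1], 5L)

  expect_error(detectR2Peaks(cu, topN = 0), "topN")
})

test_that("class summaries reproduce the published genus-level means", {
  pub <- publishedPSRAreas()
  cm <- defaultTraitClasses()
  cal <- summarizeClassAreas(setNames(pub$calibrachoa, pub$variable), cm)
  pet <- summarizeClassAreas(setNames(pub$petunia, pub$variable), cm)
  expect_identical(cal$n, c(1L, 11L, 8L))
  expect_lt(abs(cal$meanArea[cal$class == "T"] - (-0.02)), 0.01)
  expect_lt(abs(cal$meanArea[cal$class == "P"] - (-0.14)), 0.01)
  expect_equal(cal$meanArea[cal$class == "A"], 0.08)
  expect_lt(abs(pet$meanArea[pet$class == "T"] - (-0.12)), 0.01)
  expect_lt(abs(pet$meanArea[pet$class == "P"] - (-0.17)), 0.01)
  expect_equal(pet$meanArea[pet$class == "A"], 0.04)
  # display rounding is half-away-from-zero at 2 decimals
  expect_identical(cal$displayArea[cal$class == "P"], -0.15)

  expect_error(summarizeClassAreas(c(Unknown = 0.1), cm), "Unknown")
})
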