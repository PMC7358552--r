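test_that("Chao1 matches the bias-corrected formula", {
  expect_equal(chao1(c(5, 3, 1, 1, 2)), 5.5)
  expect_equal(chao1(c(4, 3, 5, 9)), 4)        # F1 = F2 = 0
  expect_equal(chao1(c(1, 1)), 3)              # F2 = 0 handled by +1
  expect_warning(z <- chao1(c(0, 0)), "empty")
  expect_equal(z, 0)
  expect_error(chao1(c(-1, 2)), "non-negative")

  # brute-force recount oracle on random samples
  set.seed(10)
  for (i in 1:200) {
    v <- rpois(30, 1.2)
    if (sum(v) == 0) next
    f1 <- sum(v == 1); f2 <- sum(v == 2)
    expect_equal(chao1(v), sum(v > 0) + f1 * (f1 - 1) / (2 * (f2 + 1)))
  }
})

test_that("Bray-Curtis agrees with a straight-loop oracle", {
  m <- rbind(a = c(6, 2), b = c(2, 2), c = c(6, 2), d = c(0, 5))
  colnames(m) <- c("OTU_1", "OTU_2")
  d <- brayCurtis(m)
  expect_equal(d["a", "b"], 1 / 3)
  expect_equal(d["a", "c"], 0)                 # identical samples
  expect_equal(brayCurtis(rbind(x = c(3, 0), y = c(0, 8)))["x", "y"], 1)

  for (s in 1:5) {
    r <- makeCounts(6, 15, seed = s)
    expect_lt(max(abs(brayCurtis(r) - refBrayCurtis(r))), 1e-12)
  }

  zz <- rbind(a = c(0, 0), b = c(0, 0), c = c(1, 2))
  expect_warning(dz <- brayCurtis(zz), "all-zero")
  expect_equal(dz["a", "b"], 0)
})

test_that("PCoA reproduces Euclidean configurations", {
  set.seed(3)
  pts <- matrix(rnorm(8), 4, 2, dimnames = list(paste0("S", 1:4), NULL))
  d <- as.matrix(dist(pts))
  ord <- pcoaOrdination(d)
  expect_lt(max(abs(as.matrix(dist(ord$axes)) - d)), 1e-8)
  # positive-eigenvalue sum equals total centered sum of squares
  expect_lt(abs(sum(ord$eigenvalues) - sum(d^2) / (2 * nrow(d))), 1e-8)
  expect_true(all(diff(ord$eigenvalues) <= 1e-12))
  expect_lte(sum(ord$proportion_explained), 1 + 1e-12)

  d2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  ord2 <- pcoaOrdination(d2)
  expect_equal(unname(sort(abs(ord2$axes[, 1]))), c(1.5, 1.5))

  perm <- c(3, 1, 4, 2)
  ordp <- pcoaOrdination(d[perm, perm])
  expect_equal(ordp$eigenvalues, ord$eigenvalues, tolerance = 1e-10)

  dns <- d; dns[1, 2] <- dns[1, 2] + 1
  expect_error(pcoaOrdination(dns), "symmetric")
})

test_that("PERMANOVA and ANOSIM behave at the separation limits", {
  set.seed(7)
  far <- rbind(matrix(rnorm(10, 0, 0.1), 5), matrix(rnorm(10, 50, 0.1), 5))
  rownames(far) <- paste0("S", 1:10)
  d <- as.matrix(dist(far))
  g <- rep(c("a", "b"), each = 5)
  res <- permanovaTest(d, g, permutations = 199, seed = 1)
  # near the attainable floor: only group-preserving label permutations
  # (rare at n = 10) can reproduce the observed F
  expect_lte(res$p_value, 5 / 200)
  expect_gt(res$R2, 0.9)
  res2 <- permanovaTest(d, g, permutations = 199, seed = 1)
  expect_identical(res$p_value, res2$p_value)  # seeded determinism
  an <- anosimTest(d, g, permutations = 199, seed = 1)
  expect_equal(an$statistic, 1)
  expect_error(permanovaTest(d, c("a", rep("b", 9)), 99), ">= 2 members")
})

test_that("Mantel recovers identity and degenerate partials", {
  set.seed(8)
  pts <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("S", 1:10), NULL))
  d1 <- as.matrix(dist(pts))
  res <- mantelTest(d1, d1, permutations = 99, seed = 2)
  expect_equal(res$statistic, 1)
  expect_equal(res$p_value, 1 / 100)

  expect_warning(pres <- mantelTest(d1, d1, permutations = 99,
                                    partial = d1, seed = 2),
                 "degenerate")
  expect_equal(pres$statistic, 0)

  d2 <- d1; rownames(d2) <- colnames(d2) <- paste0("X", 1:10)
  expect_error(mantelTest(d1, d2), "mismatch")
})

test_that("partial Mantel controls for a shared driver", {
  set.seed(9)
  n <- 12
  z <- matrix(rnorm(n * 2), n)
  dz <- as.matrix(dist(z))
  rownames(dz) <- colnames(dz) <- paste0("S", 1:n)
  noise <- function() {
    p <- matrix(rnorm(n * 2), n)
    d <- as.matrix(dist(p)); dimnames(d) <- dimnames(dz); d
  }
  d1 <- dz + 0.2 * noise()
  d2 <- dz + 0.2 * noise()
  plain <- mantelTest(d1, d2, permutations = 199, seed = 3)
  partial <- mantelTest(d1, d2, permutations = 199, partial = dz, seed = 3)
  expect_lt(abs(partial$statistic), abs(plain$statistic))
})

test_that("feature-weight correlations respect monotonicity and ties", {
  set.seed(12)
  w <- runif(10, 20, 100)
  up <- rank(w) * 5
  m <- cbind(up = up, flat = rep(7, 10), noise = 100 - up - 7)
  rownames(m) <- paste0("S", 1:10)
  res <- featureWeightCorrelation(m, weights = w)
  expect_equal(res$rho[res$otu_id == "up"], 1)
  expect_true(is.na(res$rho[res$otu_id == "flat"]))

  resRev <- featureWeightCorrelation(m, weights = -w)
  expect_equal(resRev$rho[resRev$otu_id == "up"], -1)
  expect_equal(res$rho[res$otu_id == "noise"],
               -resRev$rho[resRev$otu_id == "noise"])
})
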