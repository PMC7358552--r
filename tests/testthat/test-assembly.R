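test_that("betaMNTD matches hand evaluations and a double-loop oracle", {
  tree4 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  x <- c(A = 1); y <- c(C = 1)
  expect_equal(bmntd(x, y, tree4), 4)                # path A->C
  expect_equal(bmntd(c(A = 3, C = 1), c(A = 3, C = 1), tree4), 0)

  star <- ape::read.tree(text = "(A:2,B:2,C:2,D:2);")
  expect_equal(bmntd(c(A = 5, B = 1), c(C = 2, D = 2), star), 4)  # 2b

  expect_error(bmntd(c(Z = 1), y, tree4), "absent from tree: Z")

  set.seed(71)
  for (i in 1:15) {
    tr <- ape::rcoal(8, tip.label = paste0("t", 1:8))
    D <- cophenetic(tr)
    x <- setNames(rpois(8, 2), tr$tip.label)
    y <- setNames(rpois(8, 2), tr$tip.label)
    if (sum(x) == 0 || sum(y) == 0) next
    expect_equal(bmntd(x, y, tr), unname(refBmntd(x, y, D)),
                 tolerance = 1e-12)
  }
})

test_that("betaMNTD agrees with picante's comdistnt on random pairs", {
  skip_if_not_installed("picante")
  set.seed(72)
  tr <- ape::rcoal(12, tip.label = paste0("t", 1:12))
  m <- matrix(rpois(24, 3), 2, 12,
              dimnames = list(c("x", "y"), tr$tip.label))
  m[1, 1] <- m[1, 1] + 1; m[2, 2] <- m[2, 2] + 1
  ref <- as.matrix(picante::comdistnt(m, cophenetic(tr),
                                      abundance.weighted = TRUE))["x", "y"]
  expect_equal(bmntd(m["x", ], m["y", ], tr), unname(ref),
               tolerance = 1e-10)
})

test_that("betaNTI is a standardized effect against the tip-shuffle null", {
  tr <- ape::rcoal(10, tip.label = paste0("t", 1:10))
  x <- setNames(c(5, 3, 0, 0, 1, 0, 0, 0, 2, 0), tr$tip.label)
  # identical communities: observed betaMNTD = 0 and every tip shuffle
  # maps shared taxa together, so the null is degenerate at 0
  expect_warning(res <- bnti(x, x, tr, nNull = 99, seed = 1), "zero spread")
  expect_lte(res$bnti, 0)            # observed 0 is the distribution minimum
  expect_equal(res$bmntd_obs, 0)

  y <- x; y[3] <- 4                  # near-identical pair, proper null
  r1 <- bnti(x, y, tr, nNull = 99, seed = 1)
  r2 <- bnti(x, y, tr, nNull = 99, seed = 1)
  expect_identical(r1$bnti, r2$bnti)
  expect_error(bnti(x, x, tr, nNull = 10), ">= 99")

  star <- ape::read.tree(text = "(A:1,B:1,C:1);")
  expect_warning(r0 <- bnti(c(A = 1), c(B = 1), star, nNull = 99, seed = 1),
                 "zero spread")
  expect_equal(r0$bnti, 0)
})

test_that("moving a community into the opposite clade raises betaNTI", {
  # two deep clades; y drawn from x's clade vs from the opposite clade
  tr <- ape::read.tree(text = paste0(
    "((a1:1,(a2:0.5,a3:0.5):0.5):4,(b1:1,(b2:0.5,b3:0.5):0.5):4);"))
  x <- c(a1 = 4, a2 = 3, a3 = 3)
  ySame <- c(a2 = 5, a3 = 5)
  yOpp <- c(b1 = 4, b2 = 3, b3 = 3)
  d <- vapply(1:10, function(s) {
    bnti(x, yOpp, tr, nNull = 199, seed = s)$bnti -
      bnti(x, ySame, tr, nNull = 199, seed = s)$bnti
  }, numeric(1))
  expect_gt(mean(d), 0)
})

test_that("Raup-Crick hits its distribution limits", {
  # metacommunity with two common taxa everywhere
  m <- matrix(c(50, 50, 48, 52, 51, 49, 50, 50), 4, 2, byrow = TRUE,
              dimnames = list(paste0("S", 1:4), c("OTU_1", "OTU_2")))
  rc <- rcBray(m["S1", ], m["S1", ], m, nNull = 199, seed = 1)
  expect_lt(rc, -0.9)               # identical pair below almost all nulls

  # disjoint richness-4 pair over an 8-taxon pool where co-occurrence is
  # the norm: null pairs almost always overlap, observed BC = 1 sits at
  # the top of the null distribution
  set.seed(2)
  bg <- matrix(rpois(6 * 8, 20) + 1, 6, 8)
  m2 <- rbind(bg,
              S7 = c(30, 30, 30, 30, 0, 0, 0, 0),
              S8 = c(0, 0, 0, 0, 30, 30, 30, 30))
  dimnames(m2) <- list(paste0("S", 1:8), paste0("OTU_", 1:8))
  rc2 <- rcBray(m2["S7", ], m2["S8", ], m2, nNull = 199, seed = 1)
  expect_gt(rc2, 0.9)

  expect_identical(rcBray(m["S1", ], m["S2", ], m, nNull = 99, seed = 5),
                   rcBray(m["S1", ], m["S2", ], m, nNull = 99, seed = 5))
})

test_that("Raup-Crick centers near zero for null-assembled pairs", {
  # samples generated by the null's own mechanism: RC should be centered
  set.seed(73)
  S <- 40
  relab <- rexp(S); relab <- relab / sum(relab)
  draw <- function() {
    idx <- sample(S, 15, prob = rep(1, S))
    v <- numeric(S)
    v[idx] <- rmultinom(1, 500, relab[idx] / sum(relab[idx]))
    while (any(v[idx] == 0)) {     # enforce richness 15 like the null does
      idx <- sample(S, 15)
      v <- numeric(S); v[idx] <- rmultinom(1, 500, relab[idx] / sum(relab[idx]))
    }
    v
  }
  m <- t(vapply(1:20, function(i) draw(), numeric(S)))
  dimnames(m) <- list(paste0("S", 1:20), paste0("OTU_", 1:S))
  rcs <- vapply(1:10, function(k)
    rcBray(m[2 * k - 1, ], m[2 * k, ], m, nNull = 199, seed = k)[1],
    numeric(1))
  expect_lt(abs(mean(rcs)), 0.35)
})

test_that("process classification is total, deterministic, and anchored", {
  expect_equal(classifyProcess(2.5, 0), "heterogeneous_selection")
  expect_equal(classifyProcess(-2.5, 0.99), "homogeneous_selection")
  expect_equal(classifyProcess(0, -0.97), "homogenizing_dispersal")
  expect_equal(classifyProcess(0, 0.97), "dispersal_limitation")
  expect_equal(classifyProcess(0, 0), "undominated")
  # boundaries go to the non-selection / undominated side
  expect_equal(classifyProcess(2, 0.99), "dispersal_limitation")
  expect_equal(classifyProcess(-2, -0.95), "undominated")
  expect_error(classifyProcess(0, 1.5), "\\[-1, 1\\]")
})

test_that("assembly profiles are exact fractions over within-group pairs", {
  tr <- simulatePhylogeny(30, seed = 5)
  set.seed(74)
  m <- matrix(rpois(30 * 6, 4), 30, 6,
              dimnames = list(tr$tip.label, paste0("S", 1:6)))
  meta <- data.frame(sample_id = paste0("S", 1:6),
                     habitat = rep(c("skin", "gill"), each = 3),
                     body_weight_g = runif(6, 30, 90))
  mex <- MetacomExperiment(m, meta, tr)
  prof <- assemblyProfile(mex, nNull = 99, seed = 2)
  expect_equal(sort(prof$group), c("gill", "skin"))
  expect_true(all(prof$n_pairs == 3))          # 3 samples -> 3 pairs
  fr <- as.matrix(prof[, PROCESSES])
  expect_true(all(abs(rowSums(fr) - 1) < 1e-12))
  expect_true(all(fr >= 0 & fr <= 1))

  noTree <- MetacomExperiment(m, meta)
  expect_error(pairwiseTurnover(noTree), "tree")
})
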