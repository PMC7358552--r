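test_that("OTU table TSV round-trips and validates", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("#OTU ID\tS1\tS2", "OTU_1\t5\t0", "OTU_2\t1\t2", "OTU_3\t0\t7"),
             tsv)
  m <- readOtuTable(tsv)
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(sum(m), 15)
  expect_equal(m["OTU_2", "S2"], 2)

  out <- tempfile(fileext = ".tsv")
  writeOtuTable(m, out)
  expect_equal(readOtuTable(out), m)

  dup <- tempfile(fileext = ".tsv")
  writeLines(c("#OTU ID\tS1\tS1", "OTU_1\t5\t0"), dup)
  expect_error(readOtuTable(dup), "duplicate sample id")

  neg <- tempfile(fileext = ".tsv")
  writeLines(c("#OTU ID\tS1", "OTU_1\t-2"), neg)
  expect_error(readOtuTable(neg), "negative")

  frac <- tempfile(fileext = ".tsv")
  writeLines(c("#OTU ID\tS1", "OTU_1\t1.5"), frac)
  expect_error(readOtuTable(frac), "non-integer")

  empty <- tempfile(fileext = ".tsv")
  writeLines("#OTU ID\tS1", empty)
  expect_error(readOtuTable(empty), "empty")
})

test_that("samples-as-rows dialect is transposed on input", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("#Sample ID\tOTU_1\tOTU_2", "S1\t5\t1", "S2\t0\t2"), tsv)
  m <- readOtuTable(tsv)
  expect_equal(rownames(m), c("OTU_1", "OTU_2"))
  expect_equal(m["OTU_1", "S1"], 5)
})

test_that("metadata reader validates habitats and weights", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\thabitat\tbody_weight_g\tsite\tmonth",
               "F001\thindgut\t62.5\tS1\tJune",
               "W001\twater\t\tS1\tJune"), tsv)
  df <- readSampleData(tsv)
  expect_equal(df$body_weight_g, c(62.5, NA))
  expect_equal(df$habitat[1], "hindgut")

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\thabitat\tbody_weight_g\tsite\tmonth",
               "F001\tfin\t62.5\tS1\tJune"), bad)
  expect_error(readSampleData(bad), "skin, gill, stomach, hindgut, water")

  neg <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\thabitat\tbody_weight_g\tsite\tmonth",
               "F001\tskin\t-5\tS1\tJune"), neg)
  expect_error(readSampleData(neg), "positive")
})

test_that("newick reader checks tips and preserves cophenetic distances", {
  nwk <- tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", nwk)
  tree <- readTreeFile(nwk)
  D <- cophenetic(tree)
  expect_equal(D["A", "B"], 2)
  expect_equal(D["A", "C"], 4)

  dup <- tempfile(fileext = ".nwk")
  writeLines("((A:1,A:1):1,C:2);", dup)
  expect_error(readTreeFile(dup), "duplicate tip label")

  nolen <- tempfile(fileext = ".nwk")
  writeLines("((A,B),C);", nolen)
  expect_error(readTreeFile(nolen), "length")

  out <- tempfile(fileext = ".nwk")
  ape::write.tree(tree, out)
  expect_lt(max(abs(cophenetic(readTreeFile(out))[rownames(D), rownames(D)] - D)),
            1e-12)
})

test_that("rarefaction normalizes to exact depth without replacement", {
  expect_identical(RAREFACTION_DEPTH, 23875L)

  m <- makeCounts(3, 5, seed = 2)
  m[1, ] <- c(10, 5, 3, 2, 0)  # total 20
  r <- rarefySamples(m, depth = 20, seed = 1)
  expect_equal(r["S1", ], m[1, ])  # already at depth: unchanged

  one <- matrix(c(1000, 0), 1, 2,
                dimnames = list("S1", c("OTU_1", "OTU_2")))
  for (s in 1:3)
    expect_equal(unname(rarefySamples(one, 10, seed = s)["S1", ]), c(10, 0))

  expect_error(rarefySamples(m, depth = 0), "positive")
  expect_error(rarefySamples(m, depth = 1e6), "fewer than")

  big <- makeCounts(4, 8, seed = 3, lambda = 30)
  r1 <- rarefySamples(big, 100, seed = 42)
  r2 <- rarefySamples(big, 100, seed = 42)
  expect_identical(r1, r2)                      # same seed, same draw
  expect_true(all(rowSums(r1) == 100))
  expect_true(all(r1 <= big))                   # never exceeds input

  low <- big; low[2, ] <- 0
  expect_warning(r3 <- rarefySamples(low, 100, seed = 1), "S2")
  expect_equal(nrow(r3), 3)
})

test_that("rarefaction cell means match the hypergeometric expectation", {
  counts <- matrix(c(50, 30, 20), 1, 3,
                   dimnames = list("S1", paste0("OTU_", 1:3)))
  depth <- 25; N <- 100
  draws <- vapply(seq_len(1000), function(s)
    rarefySamples(counts, depth, seed = s)[1, ], numeric(3))
  p <- counts[1, ] / N
  expect_mean <- depth * p
  se <- sqrt(depth * p * (1 - p) * (N - depth) / (N - 1) / 1000)
  expect_true(all(abs(rowMeans(draws) - expect_mean) < 3 * se))
})

test_that("MetacomExperiment enforces its invariants", {
  m <- makeCounts(4, 6, seed = 5)
  meta <- data.frame(sample_id = rownames(m),
                     habitat = c("skin", "skin", "water", "gill"),
                     body_weight_g = c(50, 60, NA, 70))
  mex <- MetacomExperiment(t(m), meta)
  expect_s4_class(mex, "MetacomExperiment")
  expect_equal(unname(habitats(mex)["S3"]), "water")

  bad <- meta; bad$habitat[1] <- "fin"
  expect_error(MetacomExperiment(t(m), bad), "unknown habitat")
  bad2 <- meta; bad2$body_weight_g[1] <- NA
  expect_error(MetacomExperiment(t(m), bad2), "body_weight_g")
  m2 <- t(m); m2[1, 1] <- -1
  expect_error(MetacomExperiment(m2, meta), "non-negative")
  m3 <- t(m); m3[2, 2] <- 1.5
  expect_error(MetacomExperiment(m3, meta), "integral")
})
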