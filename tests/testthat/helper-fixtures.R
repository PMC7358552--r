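# Fixture builders and independent reference implementations used as
# oracles. References are deliberately naive (straight loops) and kept
# separate from the package's computation paths.

makeCounts <- function(nSamples, nOtus, seed = 1, lambda = 8) {
  set.seed(seed)
  m <- matrix(rpois(nSamples * nOtus, lambda), nSamples, nOtus,
              dimnames = list(paste0("S", seq_len(nSamples)),
                              paste0("OTU_", seq_len(nOtus))))
  m
}

tinyMex <- function(nPerHab = 4, habs = c("skin", "gill"), nOtus = 12,
                    seed = 1, tree = NULL) {
  set.seed(seed)
  n <- nPerHab * length(habs)
  m <- matrix(rpois(nOtus * n, 10), nOtus, n,
              dimnames = list(paste0("OTU_", seq_len(nOtus)),
                              paste0("S", seq_len(n))))
  meta <- data.frame(sample_id = colnames(m),
                     habitat = rep(habs, each = nPerHab),
                     body_weight_g = ifelse(rep(habs, each = nPerHab) == "water",
                                            NA, runif(n, 30, 120)))
  MetacomExperiment(m, meta, tree)
}

# straight-loop Bray-Curtis
refBrayCurtis <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- sum(abs(m[i, ] - m[j, ]))
    den <- sum(m[i, ] + m[j, ])
    d[i, j] <- if (den == 0) 0 else num / den
  }
  d
}

# double-loop abundance-weighted betaMNTD
refBmntd <- function(x, y, D) {
  x <- x[x > 0]; y <- y[y > 0]
  fx <- x / sum(x); fy <- y / sum(y)
  s <- 0
  for (i in names(fx)) s <- s + fx[[i]] * min(D[i, names(fy)])
  for (j in names(fy)) s <- s + fy[[j]] * min(D[j, names(fx)])
  s / 2
}

# all permutations of 1..n (for exhaustive tip-shuffle enumeration)
allPerms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in allPerms(n - 1)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1]] <- append(p, n, after = k - 1)
    }
  }
  out
}
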