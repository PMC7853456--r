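test_that("Rogers-Huff r is the dosage Pearson correlation", {
  x <- c(0, 1, 2, 2, 1, 0)
  expect_equal(rogersHuffR(x, x), 1)
  expect_equal(rogersHuffR(x, 2 - x), -1)
  y <- c(0, 2, 1, 2, 0, 1)
  expect_equal(rogersHuffR(x, y), cor(x, y))
  ## pairwise deletion and zero-variance flagging
  expect_equal(rogersHuffR(c(x, NA), c(y, 0)), cor(x, y))
  expect_true(is.na(rogersHuffR(rep(1, 6), y)))
})

test_that("tagging variants need high LD, diploid tracks and phased presence", {
  ## 6 variants: rows 2,4,5 in perfect LD with focal row 3; row 6 high LD
  ## but in a tetraploid window; row 1 independent
  set.seed(2)
  foc <- rbinom(40, 2, 0.5)
  dosRows <- rbind(rbinom(40, 2, 0.5), foc, foc, foc, foc, foc)
  pos <- c(100L, 200L, 300L, 400L, 500L, 600L)
  gm <- GenotypeMatrix("2R", pos,
    allele1 = pmin(dosRows, 1L), allele2 = pmax(dosRows - 1L, 0L),
    sampleIds = paste0("s", 1:40))
  tracks <- data.frame(start = c(1L, 551L), end = c(550L, 650L),
                       haplotype_score = c(2.0, 4.0), coverage = c(2.1, 4.2))
  tags <- findTaggingVariants(gm, focalSite = 300L, tracks = tracks,
                              phasedPositions = c(100L, 200L, 400L, 500L, 600L))
  expect_setequal(tags$position, c(200L, 400L, 500L))
  expect_false(300L %in% tags$position)  # focal excluded from its own output

  ## all-tetraploid track: filter dominates, empty result
  tracks2 <- data.frame(start = 1L, end = 650L,
                        haplotype_score = 4, coverage = 4)
  expect_equal(nrow(findTaggingVariants(gm, 300L, tracks2,
                                        phasedPositions = pos)), 0L)
})

test_that("haplotype network collapses identical haplotypes and keeps one-step MST edges", {
  ## all identical: one node, no edges
  h <- matrix(rep(c(0L, 1L, 0L), 6), nrow = 3)
  hm <- HaplotypeMatrix("2R", c(10L, 20L, 30L), h)
  net <- buildHaplotypeNetwork(hm)
  expect_equal(nrow(net$nodes), 1L)
  expect_equal(net$nodes$size, 6L)
  expect_equal(nrow(net$edges), 0L)

  ## three clusters at mutual distances 1, 1, 2: the two distance-1 edges
  ## survive, and the MST weight equals the brute-force optimum
  h2 <- cbind(c(0L, 0L, 0L), c(0L, 0L, 0L),
              c(1L, 0L, 0L), c(0L, 0L, 1L))
  hm2 <- HaplotypeMatrix("2R", c(10L, 20L, 30L), h2)
  net2 <- buildHaplotypeNetwork(hm2)
  expect_equal(nrow(net2$nodes), 3L)
  expect_equal(sum(net2$nodes$size), 4L)
  expect_equal(nrow(net2$edges), 2L)
  expect_equal(sort(net2$edges$distance), c(1, 1))
  key <- apply(haplotypes(hm2), 2, paste, collapse = "")
  reps <- haplotypes(hm2)[, !duplicated(key), drop = FALSE]
  d <- as.matrix(dist(t(reps), method = "manhattan"))
  expect_equal(sum(net2$mst_edges$distance), bruteMstWeight(d))

  ## sweep simulation: the largest cluster is enriched for the swept allele
  hm3 <- simulateSweep(sweepSimConfig(nHaplotypes = 100, nVariants = 60,
                                      focalIndex = 30L, seed = 5))
  tag <- haplotypes(hm3)[30, ]
  net3 <- buildHaplotypeNetwork(hm3, tagAlleles = tag)
  big <- which.max(net3$nodes$size)
  expect_gt(net3$nodes$tag_freq[big], mean(tag))
})

test_that("MST agrees with an independent implementation on random distance matrices", {
  skip_if_not_installed("igraph")
  set.seed(77)
  for (i in 1:10) {
    n <- sample(4:9, 1)
    h <- matrix(rbinom(12 * n, 1, 0.5), ncol = n)
    d <- as.matrix(dist(t(h), method = "manhattan"))
    mst <- dupsweep:::kruskalMst(d)
    g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                             weighted = TRUE)
    ref <- igraph::mst(g)
    expect_equal(sum(mst$weight), sum(igraph::E(ref)$weight))
  }
})

test_that("Garud H statistics and haplotype diversity match hand computations", {
  h <- matrix(0L, 4, 6)  # all identical
  expect_equal(garudH(h), list(h1 = 1, h12 = 1, h2 = 0, h2_h1 = 0))
  expect_equal(haplotypeDiversity(h), 0)

  ## two clusters at 0.5/0.5
  h2 <- cbind(matrix(0L, 3, 4), matrix(1L, 3, 4))
  g <- garudH(h2)
  expect_equal(g$h1, 0.5)
  expect_equal(g$h12, 1.0)
  expect_equal(g$h2, 0.25)
  expect_equal(g$h2_h1, 0.5)

  ## clusters of sizes 2, 1, 1 (n = 4)
  h3 <- cbind(c(0L, 0L), c(0L, 0L), c(1L, 0L), c(0L, 1L))
  expect_equal(haplotypeDiversity(h3), (1 - (0.25 + 0.0625 + 0.0625)) * 4 / 3)

  ## all distinct: diversity exactly 1 under the unbiased correction
  h4 <- diag(4L)
  expect_equal(haplotypeDiversity(h4), 1)

  ## identity H12 - H1 = 2 p1 p2 over random windows
  set.seed(10)
  for (i in 1:20) {
    w <- matrix(rbinom(5 * 12, 1, 0.5), nrow = 5)
    g <- garudH(w)
    p <- dupsweep:::haplotypeClusterFreqs(w)
    p2 <- if (length(p) >= 2) p[2] else 0
    expect_equal(g$h12 - g$h1, 2 * p[1] * p2, tolerance = 1e-12)
    expect_gte(g$h12, g$h1)
    expect_lt(g$h2 / g$h1, 1)
  }
})

test_that("EHH starts at 1, never increases, and matches pair counting", {
  ## 4 haplotypes splitting 2/2 at the first step away from the core
  h <- rbind(c(0L, 0L, 0L, 0L), c(0L, 0L, 1L, 1L))
  e <- ehhDecay(h, 1L, "down")
  expect_equal(e$ehh[1], 1.0)
  expect_equal(e$ehh[2], 1 / 3)

  set.seed(13)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    h <- matrix(rbinom(10 * n, 1, 0.5), nrow = 10)
    core <- sample(2:9, 1)
    for (dir in c("down", "up")) {
      e <- ehhDecay(h, core, dir)
      expect_true(all(diff(e$ehh) <= 1e-12))
      for (s in seq_len(nrow(e))) {
        expect_equal(e$ehh[s], bruteEhh(h, core, e$variant_index[s]),
                     tolerance = 1e-12)
      }
    }
  }
  expect_error(ehhDecay(matrix(0L, 3, 1), 1L), "2 haplotypes")
})

test_that("flank averages carry leave-one-haplotype-out jackknife errors", {
  hm <- simulateSweep(sweepSimConfig(nHaplotypes = 12, nVariants = 40, seed = 9))
  ## haplotype-count statistic is insensitive to any single haplotype only
  ## through its constant value: SE must be 0
  res0 <- flankAverageWithJackknife(hm, function(w) 1, windowSize = 20L)
  expect_equal(res0$se, 0)

  ## H1 flank average matches direct leave-one-out enumeration
  res <- flankAverageWithJackknife(hm, function(w) garudH(w)$h1,
                                   windowSize = 20L, overlap = 0.2)
  h <- haplotypes(hm)
  starts <- c(0L, 16L)
  avg <- function(mat) mean(sapply(starts, function(s)
    garudH(mat[(s + 1):(s + 20), , drop = FALSE])$h1))
  loo <- sapply(1:12, function(i) avg(h[, -i, drop = FALSE]))
  expect_equal(res$mean, avg(h))
  expect_equal(res$se, sqrt(11 / 12 * sum((loo - mean(loo))^2)), tolerance = 1e-12)

  ## SE shrinks with haplotype count on iid simulations (averaged over seeds)
  ses <- sapply(c(10, 40), function(n) {
    mean(sapply(1:10, function(s) {
      hmN <- simulateSweep(sweepSimConfig(nHaplotypes = n, nVariants = 40,
                                          recombScale = 1, seed = s))
      flankAverageWithJackknife(hmN, function(w) garudH(w)$h1,
                                windowSize = 10L)$se
    }))
  })
  expect_lt(ses[2], ses[1])
})

test_that("windowed sweep profile uses 20%-overlap windows and carrier H12 exceeds background", {
  hm <- simulateSweep(sweepSimConfig(nHaplotypes = 120, nVariants = 200,
                                     focalIndex = 100L, seed = 4))
  swept <- attr(hm, "swept")
  prof <- sweepProfile(hm[, which(swept)], windowSize = 50L, overlap = 0.2)
  expect_equal(prof$first_variant[2] - prof$first_variant[1], 40L)  # step = 0.8 w
  profB <- sweepProfile(hm[, which(!swept)], windowSize = 50L, overlap = 0.2)
  mid <- which.min(abs(prof$first_variant - 75))
  expect_gt(prof$h12[mid], profB$h12[mid])
  expect_lt(prof$diversity[mid], profB$diversity[mid])
})
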