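test_that("similarity matrix equals the brute-force pairwise oracle", {
  set.seed(21)
  d <- tibble::tibble(pt217 = rnorm(30), pt111 = rnorm(30),
                      nfl_csf = abs(rnorm(30)) + 1, ykl40_csf = rnorm(30),
                      mmse = rnorm(30))
  sim <- build_similarity(d)
  expect_equal(sim$sim, oracle_similarity(as.matrix(d[, sim$markers])),
               tolerance = 1e-12)
  expect_true(all(sim$n_pairs == 30L))
  expect_equal(diag(sim$sim), rep(1, 5), ignore_attr = TRUE)
})

test_that("similarity respects the pairwise-complete mask", {
  set.seed(22)
  d <- tibble::tibble(pt217 = rnorm(40), pt111 = rnorm(40))
  d$pt217[1:20] <- NA   # present 21..40
  d$pt111[31:40] <- NA  # present 1..30; overlap 21..30 = 10 subjects
  sim <- build_similarity(d, min_pairs = 3)
  expect_identical(sim$n_pairs["pt217", "pt111"], 10L)
  expect_identical(sim$n_pairs["pt217", "pt217"], 20L)
  ok <- 21:30
  expect_equal(sim$sim["pt217", "pt111"],
               abs(cor(d$pt217[ok], d$pt111[ok], method = "spearman")))
  # too few complete pairs flags the entry undefined and linkage refuses it
  d$pt111[22:30] <- NA
  sim2 <- build_similarity(d, min_pairs = 3)
  expect_true(is.na(sim2$sim["pt217", "pt111"]))
  expect_error(wpgma_linkage(sim2), "undefined")
})

test_that("WPGMA reproduces hand-computed linkages", {
  # two leaves at similarity 0.7 merge at distance 0.3
  s2 <- matrix(c(1, 0.7, 0.7, 1), 2, dimnames = list(c("A", "B"), c("A", "B")))
  d2 <- wpgma_linkage(s2)
  expect_equal(d2$height, 0.3)

  # d(AB)=0.1, d(AC)=0.4, d(BC)=0.6: AB at 0.1, then (AB)C at 0.5
  s3 <- matrix(1, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  s3["A", "B"] <- s3["B", "A"] <- 0.9
  s3["A", "C"] <- s3["C", "A"] <- 0.6
  s3["B", "C"] <- s3["C", "B"] <- 0.4
  d3 <- wpgma_linkage(s3)
  expect_equal(d3$height, c(0.1, 0.5))
  expect_identical(d3$merge[1, ], c(-2L, -1L)[order(c(-2L, -1L))])
  cl <- cut_clusters(d3, 2)
  expect_identical(cl$cluster[cl$marker == "A"], cl$cluster[cl$marker == "B"])
  expect_false(cl$cluster[cl$marker == "C"] == cl$cluster[cl$marker == "A"])
})

test_that("WPGMA recovers ultrametric heights exactly", {
  # ((A,B):0.2, (C,D):0.3):0.8 as an ultrametric distance matrix
  lab <- LETTERS[1:4]
  d <- matrix(0.8, 4, 4, dimnames = list(lab, lab))
  diag(d) <- 0
  d["A", "B"] <- d["B", "A"] <- 0.2
  d["C", "D"] <- d["D", "C"] <- 0.3
  dend <- wpgma_linkage(1 - d)
  expect_equal(sort(dend$height), c(0.2, 0.3, 0.8))
  cl <- cut_clusters(dend, 2)
  expect_identical(cl$cluster[1], cl$cluster[2])
  expect_identical(cl$cluster[3], cl$cluster[4])
})

test_that("WPGMA agrees with the hclust mcquitty oracle", {
  set.seed(31)
  for (i in 1:5) {
    x <- matrix(rnorm(200), 20, 10)
    s <- abs(cor(x, method = "spearman"))
    dimnames(s) <- list(paste0("m", 1:10), paste0("m", 1:10))
    mine <- wpgma_linkage(s)
    ref <- stats::hclust(stats::as.dist(1 - s), method = "mcquitty")
    expect_equal(sort(mine$height), sort(ref$height), tolerance = 1e-12)
    for (k in c(2, 4, 7)) {
      a <- cut_clusters(mine, k)$cluster
      b <- stats::cutree(ref, k)
      expect_equal(mclust::adjustedRandIndex(a, b), 1)
    }
  }
})

test_that("hierarchical cuts nest", {
  set.seed(32)
  x <- matrix(rnorm(300), 30, 10)
  s <- abs(cor(x, method = "spearman"))
  dimnames(s) <- list(paste0("m", 1:10), paste0("m", 1:10))
  dend <- wpgma_linkage(s)
  expect_identical(length(unique(cut_clusters(dend, 1)$cluster)), 1L)
  expect_identical(length(unique(cut_clusters(dend, 10)$cluster)), 10L)
  for (k in 2:10) {
    fine <- cut_clusters(dend, k)$cluster
    coarse <- cut_clusters(dend, k - 1)$cluster
    # every fine cluster lies inside exactly one coarse cluster
    expect_true(all(tapply(coarse, fine, function(v) length(unique(v))) == 1))
  }
  expect_error(cut_clusters(dend, 0), "range")
  expect_error(cut_clusters(dend, 11), "range")
})

test_that("elbow rule finds planted kinks and handles degenerate panels", {
  # rank-1 panel: one factor, elbow at 1
  set.seed(33)
  f <- rnorm(300)
  x1 <- sapply(1:8, function(j) f + rnorm(300, sd = 0.05))
  colnames(x1) <- paste0("m", 1:8)
  el1 <- elbow_point(pca_scree(x1))
  expect_identical(el1, 1L)

  # independent noise: flat scree, elbow small
  xn <- matrix(rnorm(400 * 8), 400, 8)
  colnames(xn) <- paste0("m", 1:8)
  el <- select_k_elbow(tibble::as_tibble(xn), n_permutations = 50, seed = 4,
                       markers = colnames(xn))
  expect_lte(el$k, 2L)

  # holdout leaving fewer than 3 subjects is an error
  expect_error(select_k_elbow(tibble::as_tibble(xn[1:3, ]),
                              n_permutations = 5, holdout_fraction = 0.4,
                              seed = 1, markers = colnames(xn)),
               "fewer than 3")
})

test_that("edge list thresholds strictly and sorts descending", {
  set.seed(34)
  n <- 200
  a <- rnorm(n); b <- a + rnorm(n, sd = 0.3) # planted strong pair
  d <- tibble::tibble(pt217 = a, pt111 = b, nfl_csf = abs(rnorm(n)) + 1,
                      mmse = rnorm(n))
  sim <- build_similarity(d)
  e <- edge_list(sim, 0.5)
  expect_identical(nrow(e), 1L)
  expect_setequal(c(e$marker_a, e$marker_b), c("pt217", "pt111"))
  expect_identical(nrow(edge_list(sim, 1.0)), 0L)
  e0 <- edge_list(sim, 0)
  expect_identical(nrow(e0), 6L) # p(p-1)/2 on complete data
  expect_true(all(diff(e0$similarity) <= 0))
})

test_that("dendrograms export to Newick with matching topology", {
  co <- generate_cohort(cohort_preset("entire_cohort", seed = 9))
  p <- preprocess(exclude_sparse_subjects(co$panel))
  dend <- wpgma_linkage(build_similarity(p))
  nwk <- as_newick(dend)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, dend$labels)
  expect_identical(ape::Ntip(phy), 27L)
})
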