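test_that("the default preset reproduces the study group sizes exactly", {
  co <- generate_cohort(cohort_preset("entire_cohort", seed = 1))
  tab <- table(co$panel$group)
  expect_identical(unname(tab[c("cn_aneg", "cn_apos", "ci")]),
                   table(factor(rep(c("a", "b", "c"), c(211, 228, 88))))[1:3],
                   ignore_attr = TRUE)
  expect_identical(nrow(co$panel), 527L)
  # amyloid positivity is exactly the inclusive Centiloid rule
  expect_identical(co$panel$amyloid_positive, co$panel$centiloid >= 16.4)
  expect_identical(co$panel$cdr_group == "CDRgt0", co$panel$group == "ci")
})

test_that("a fixed seed gives a byte-identical cohort", {
  a <- generate_cohort(cohort_preset("entire_cohort", seed = 17))
  b <- generate_cohort(cohort_preset("entire_cohort", seed = 17))
  expect_identical(a$panel, b$panel)
  expect_identical(a$truth, b$truth)
  c2 <- generate_cohort(cohort_preset("entire_cohort", seed = 18))
  expect_false(identical(a$panel, c2$panel))
})

test_that("unit loadings with zero noise give within-block |rho| = 1", {
  blocks <- lapply(admarkers:::default_blocks(), function(b) {
    b$loading <- 1
    b$member_loadings <- NULL
    b
  })
  spec <- cohort_spec(blocks = blocks, satellite_loadings = list(),
                      effect_matrix = admarkers:::default_effect_matrix() * 0,
                      marker_shifts = NULL, noise_sd = 1e-9,
                      missing_rates = setNames(rep(0, 27), ad_marker_names()),
                      sparse_subject_rate = 0, seed = 3)
  co <- generate_cohort(spec)
  mem <- spec$blocks$dysfunction$members
  x <- as.matrix(co$panel[, mem])
  cm <- abs(cor(x, method = "spearman"))
  expect_true(all(cm > 1 - 1e-9))
})

test_that("planted blocks are more correlated within than between", {
  diffs <- sapply(1:20, function(s) {
    co <- generate_cohort(cohort_preset("entire_cohort", seed = 200 + s))
    x <- as.matrix(co$panel[, ad_marker_names()])
    x[, c("nfl_csf", "nfl_plasma")] <- log(x[, c("nfl_csf", "nfl_plasma")])
    cm <- abs(suppressWarnings(
      cor(x, use = "pairwise.complete.obs", method = "spearman")))
    blk <- co$truth$block[colnames(cm)]
    # within-block coherence: the mean over blocks of each block's mean
    # internal |rho|, against the mean cross-block |rho|
    within_by_block <- sapply(setdiff(unique(blk), "none"), function(b) {
      sub <- cm[blk == b, blk == b]
      mean(sub[upper.tri(sub)])
    })
    between <- outer(blk, blk, "!=") & blk != "none" &
      matrix(blk, 27, 27, byrow = TRUE) != "none"
    mean(within_by_block) - mean(cm[which(between)])
  })
  expect_true(all(diffs >= 0.3))
})

test_that("marginal missingness matches the specified rates", {
  rates <- sapply(1:100, function(s) {
    co <- generate_cohort(cohort_preset("entire_cohort", seed = 700 + s))
    colMeans(is.na(co$panel[, ad_marker_names()]))
  })
  # forced sparse subjects add about 0.52 * sparse_subject_rate on top of the
  # 10% MCAR rate
  extra <- 0.52 * 0.02
  expect_true(all(abs(rowMeans(rates) - (0.10 * (1 - extra) + extra)) < 0.02))
})

test_that("the factor model attains its analytic within-block correlation", {
  l <- 0.7; s <- 1.3
  blocks <- list(dysfunction = list(
    members = c("ng_csf", "snap25_csf", "vilip1_csf", "ykl40_csf",
                "strem2_csf"), loading = l))
  em <- matrix(0, 1, 3, dimnames = list("dysfunction",
                                        c("cn_aneg", "cn_apos", "ci")))
  spec <- cohort_spec(group_sizes = c(cn_aneg = 10000L, cn_apos = 0L, ci = 0L),
                      blocks = blocks, satellite_loadings = list(),
                      effect_matrix = em, marker_shifts = NULL, noise_sd = s,
                      missing_rates = setNames(rep(0, 27), ad_marker_names()),
                      sparse_subject_rate = 0, seed = 5)
  co <- generate_cohort(spec)
  x <- as.matrix(co$panel[, blocks$dysfunction$members])
  expected <- l^2 / (l^2 + (1 - l^2) * s^2)
  cm <- cor(x)
  expect_equal(mean(cm[upper.tri(cm)]), expected, tolerance = 0.02)
})

test_that("demographics track the published group moments", {
  set.seed(9)
  big <- generate_demographics(c(cn_aneg = 10000L, cn_apos = 10000L,
                                 ci = 10000L))
  ages <- tapply(big$age, big$group, mean)
  expect_true(all(abs(ages[c("cn_aneg", "cn_apos", "ci")] -
                        c(69.72, 71.67, 72.11)) < 0.2))
  apoe <- tapply(big$apoe4_carrier, big$group, mean)
  expect_true(all(abs(apoe[c("cn_aneg", "cn_apos", "ci")] -
                        c(0.248, 0.414, 0.575)) < 0.03))
  exact <- generate_demographics(c(cn_aneg = 5L, cn_apos = 0L, ci = 0L),
                                 zero_variance = TRUE)
  expect_true(all(exact$age == 69.72))
})

test_that("presets encode their regimes", {
  expect_error(cohort_preset("not_a_preset"))
  sep <- generate_cohort(cohort_preset("single_separator", seed = 2))
  expect_identical(sep$panel$pt217,
                   as.numeric(sep$panel$amyloid_positive))
  pre <- generate_cohort(cohort_preset("preclinical_only", seed = 2))
  expect_true(all(pre$panel$group == "cn_apos"))
  expect_identical(nrow(pre$panel), 228L)
  imp <- generate_cohort(cohort_preset("impaired_only", seed = 2))
  expect_identical(nrow(imp$panel), 88L)
  nul <- generate_cohort(cohort_preset("null_panel", seed = 2))
  x <- as.matrix(nul$panel[, ad_marker_names()])
  x[, c("nfl_csf", "nfl_plasma")] <- log(x[, c("nfl_csf", "nfl_plasma")])
  cm <- abs(suppressWarnings(
    cor(x, use = "pairwise.complete.obs", method = "spearman")))
  expect_lt(max(cm[upper.tri(cm)]), 0.25) # no structure beyond sampling noise
})
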