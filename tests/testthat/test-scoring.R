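test_that("BH q-values match the brute-force step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  set.seed(81)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-15)
  }
  # order equivariance
  p <- runif(20)
  perm <- sample(20)
  expect_equal(bh_fdr(p[perm]), bh_fdr(p)[perm])
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("IRS sums capped -log10 p over FDR-significant cells", {
  # nothing passes FDR -> 0
  expect_equal(irs_score(runif(50, 0.5, 1)), 0)
  # two passing cells with -log10 p = 3 and 5 -> 8
  expect_equal(irs_score(c(1e-3, 1e-5)), 8)
  # extreme p contributes the cap
  expect_equal(irs_score(1e-50, cap = 20), 20)
  # equals the integrated area under the significant-count curve
  set.seed(82)
  p <- c(10^(-runif(30, 1.5, 12)), runif(200, 0.2, 1))
  cap <- 20
  q <- bh_fdr(p)
  keep <- q < 0.05
  grid <- seq(0, cap, length.out = 200001)
  nl <- pmin(-log10(p[keep]), cap)
  area <- sum(vapply(grid, function(t) sum(nl >= t), numeric(1))) *
    (grid[2] - grid[1])
  expect_equal(irs_score(p), area, tolerance = 1e-3)
  # exact identity: sum of capped -log10 p IS the area under N(t)
  expect_equal(irs_score(p), sum(nl), tolerance = 1e-9)
  # relative IRS divides by the largest score
  expect_equal(relative_irs(c(a = 2, b = 8, c = 4)),
               c(a = 0.25, b = 1, c = 0.5))
})

test_that("KS enrichment score behaves on constructed sets", {
  sig <- random_signature(500, seed = 91)
  ord <- names(sig)[order(-sig)]
  # top-k set: ES > 0, equal to the running-sum peak at position k
  k <- 25
  res <- ks_gsea(ord[1:k], sig, weight_exponent = 0, n_perm = 200, seed = 1)
  expect_gt(res$es, 0)
  expect_equal(res$es, 1 - (0), tolerance = 1e-12)  # peak at position k
  expect_equal(res$p, 1 / 201)
  expect_setequal(res$leading_edge, ord[1:k])
  # set = all genes -> ES = 0
  expect_equal(ks_gsea(names(sig), sig, n_perm = 10, seed = 1)$es, 0)
  # bottom set is negatively enriched
  res2 <- ks_gsea(rev(ord)[1:k], sig, weight_exponent = 0, n_perm = 200,
                  seed = 1)
  expect_lt(res2$es, 0)
  expect_error(ks_gsea(c("nope"), sig), "intersect")
  # determinism
  r1 <- ks_gsea(ord[10:40], sig, n_perm = 100, seed = 7)
  r2 <- ks_gsea(ord[10:40], sig, n_perm = 100, seed = 7)
  expect_identical(r1, r2)
})

test_that("KS ES with exponent 0 is invariant to monotone transforms and
           matches fgsea's weighted ES at exponent 1", {
  sig <- random_signature(400, seed = 92)
  set.seed(93)
  gs <- sample(names(sig), 30)
  e0 <- ks_gsea(gs, sig, weight_exponent = 0, n_perm = 10, seed = 1)$es
  e0b <- ks_gsea(gs, exp(sig), weight_exponent = 0, n_perm = 10,
                 seed = 1)$es
  e0c <- ks_gsea(gs, rank(sig), weight_exponent = 0, n_perm = 10,
                 seed = 1)$es
  expect_equal(e0, e0b, tolerance = 1e-12)
  expect_equal(e0, e0c, tolerance = 1e-12)
  skip_if_not_installed("fgsea")
  ref <- fgsea::calcGseaStat(sort(sig, decreasing = TRUE),
                             selectedStats = match(gs, names(sort(sig,
                                                                  decreasing = TRUE))),
                             gseaParam = 1, returnAllExtremes = FALSE)
  e1 <- ks_gsea(gs, sig, weight_exponent = 1, n_perm = 10, seed = 1)$es
  expect_equal(e1, unname(ref), tolerance = 1e-9)
})

test_that("KS permutation p-values are uniform under random gene sets", {
  sig <- random_signature(800, seed = 94)
  set.seed(95)
  ps <- vapply(1:200, function(i)
    ks_gsea(sample(names(sig), 40), sig, n_perm = 400, seed = 1000 + i)$p,
    numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("modulator and target evaluation rank along the right axes", {
  set.seed(96)
  nes <- matrix(rnorm(40 * 60), 40, 60,
                dimnames = list(sprintf("R%02d", 1:40),
                                sprintf("d%02d", 1:60)))
  # modulators forced to the most-negative NES of the target row
  target <- "R05"
  mods <- colnames(nes)[order(nes[target, ])][1:6]
  res <- evaluate_modulators(nes, target, mods, "inhibitor",
                             n_perm = 500, seed = 3)
  expect_equal(res$p, 1 / 501)
  expect_gt(res$es, 0)
  # reversing the direction flips the ES sign for the same data
  res_act <- evaluate_modulators(nes, target, mods, "activator",
                                 n_perm = 500, seed = 3)
  expect_equal(res_act$es, -res$es, tolerance = 1e-12)
  # random modulator sets give uniform p
  ps <- vapply(1:120, function(i) {
    set.seed(200 + i)
    evaluate_modulators(nes, target, sample(colnames(nes), 6),
                        n_perm = 200, seed = 300 + i)$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  # target evaluation mirrors along the regulator axis
  pert <- "d07"
  tg <- rownames(nes)[order(nes[, pert])][1:5]
  rest <- evaluate_targets(nes, pert, tg, "inhibitor", n_perm = 500,
                           seed = 4)
  expect_equal(rest$p, 1 / 501)
  # single-target set reduces to a rank test of one protein
  one <- evaluate_targets(nes, pert, tg[1], "inhibitor", n_perm = 500,
                          seed = 5)
  expect_lt(one$p, 0.05)
  expect_error(evaluate_modulators(nes, "nope", mods), "not tested")
})

test_that("drug-drug similarity is symmetric, bounded and sign-faithful", {
  a <- random_signature(2000, seed = 97)
  b <- random_signature(2000, seed = 98)
  s_ab <- drug_signature_similarity(a, b)
  s_ba <- drug_signature_similarity(b, a)
  expect_equal(s_ab$similarity, s_ba$similarity, tolerance = 1e-12)
  expect_lte(abs(s_ab$similarity), 1)
  expect_gt(drug_signature_similarity(a, a)$similarity, 0.9)
  expect_lt(drug_signature_similarity(a, -a)$similarity, -0.9)
  expect_equal(s_ab$distance, 1 - s_ab$similarity)
  expect_error(drug_signature_similarity(a, b, top_frac = 0.3), "0.25")
  expect_error(drug_signature_similarity(a[1:50], b[1:50]), "100")
})

test_that("sensitivity profiles correlate by Spearman over shared lines", {
  a <- c(l1 = 1, l2 = 2, l3 = 3, l4 = 4)
  expect_equal(sensitivity_correlation(a, log(a + 1)), 1)   # monotone
  expect_equal(sensitivity_correlation(a, rev(unname(a)) + 0 *
                                         setNames(a, names(a))), -1)
  b <- c(l1 = 2, l2 = 1, l3 = 4, l4 = 3)
  expect_equal(sensitivity_correlation(a, b), 0.6)
  expect_error(sensitivity_correlation(a[1:2], b), ">= 3")
})

test_that("gold standards rank compounds by matched correlation", {
  set.seed(99)
  genes <- sprintf("G%04d", 1:978)
  sil <- stats::setNames(rnorm(978), genes)
  comps <- list(match = sil + rnorm(978, 0, 0.4),
                near = sil + rnorm(978, 0, 2),
                noise1 = stats::setNames(rnorm(978), genes),
                noise2 = stats::setNames(rnorm(978), genes))
  comps$match <- stats::setNames(comps$match, genes)
  comps$near <- stats::setNames(comps$near, genes)
  gsd <- build_gold_standard(comps, list(TF1 = sil))
  tab <- gsd[["TF1"]]
  expect_equal(tab$compound[1], "match")
  expect_gt(tab$r[1], 0.9)
  expect_true(tab$significant[1])
  # ranking is a permutation of tested compounds
  expect_setequal(tab$compound, names(comps))
  # identical signature -> r = 1, ranked first
  gsd2 <- build_gold_standard(c(comps, list(exact = sil)),
                              list(TF1 = sil))
  expect_equal(gsd2[["TF1"]]$compound[1], "exact")
  expect_equal(gsd2[["TF1"]]$r[1], 1)
  # independent random signatures: positive-tail significance ~ p_cut / 2
  set.seed(100)
  rnd <- lapply(1:400, function(i) stats::setNames(rnorm(978), genes))
  names(rnd) <- paste0("c", 1:400)
  gsd3 <- build_gold_standard(rnd, list(TF1 = stats::setNames(rnorm(978),
                                                              genes)))
  expect_lt(abs(mean(gsd3[["TF1"]]$significant) - 0.025), 0.02)
  # zero-variance signatures are excluded with a warning
  expect_warning(build_gold_standard(c(comps,
                                       list(flat = stats::setNames(rep(1, 978), genes))),
                                     list(TF1 = sil)), "zero-variance")
})

test_that("AUROC helper matches brute-force pair counting", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(10:40, 1)
    score <- sample(rnorm(25), n, replace = TRUE)  # ties included
    pos <- runif(n) < 0.4
    if (!any(pos) || all(pos)) next
    expect_equal(netact:::.auroc(score, pos), oracle_auroc(score, pos),
                 tolerance = 1e-12)
  }
})

test_that("top-fraction overlap utility returns a Fisher test", {
  a <- random_signature(400, seed = 103)
  ft <- top_overlap_fisher(a, a, frac = 0.05)
  expect_lt(ft$p.value, 1e-10)
  b <- random_signature(400, seed = 104)
  expect_gt(top_overlap_fisher(a, b, frac = 0.05)$p.value, 0.001)
})
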