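test_that("rank transform is the probit of fractional and folded ranks", {
  sig <- c(a = 2.0, b = 0.0, c = -1.5)
  tr <- suppressWarnings(rank_transform(sig))
  expect_equal(unname(tr$t2), qnorm(c(3, 2, 1) / 4), tolerance = 1e-12)
  expect_equal(unname(tr$t2), c(0.674, 0, -0.674), tolerance = 1e-3)
  # |values| 2, 0, 1.5 -> magnitude ranks 3, 1, 2
  expect_equal(unname(tr$t1), qnorm(0.5 + c(3, 1, 2) / 8), tolerance = 1e-12)
  expect_equal(unname(tr$t1), c(1.150, 0.319, 0.674), tolerance = 1e-3)
  # negation flips t2, preserves t1
  trn <- suppressWarnings(rank_transform(-sig))
  expect_equal(trn$t2, -tr$t2)
  expect_equal(trn$t1, tr$t1)
  # monotone: larger statistic -> larger t2; larger |stat| -> larger t1
  sig2 <- random_signature(500, seed = 6)
  tr2 <- rank_transform(sig2)
  expect_equal(order(tr2$t2), order(sig2))
  expect_equal(order(tr2$t1), order(abs(sig2)))
  expect_true(all(is.finite(c(tr2$t1, tr2$t2))))
  suppressWarnings(expect_error(rank_transform(c(a = 1, b = 1, c = 1)),
                                "degenerate"))
})

test_that("regulon ES reduces correctly in the single-target limits", {
  tr <- mock_transformed(t2 = c(x = 0.674, y = -1), t1 = c(x = 0.9, y = 2))
  r1 <- regulon("r", "x", mode = 1, weight = 1)
  expect_equal(regulon_es(tr, r1, min_targets = 1)$es, 0.674)
  r0 <- regulon("r", "x", mode = 0, weight = 1)
  expect_equal(regulon_es(tr, r0, min_targets = 1)$es, 0.9)
  # 3 targets, modes (1, -1, 0), equal weights: (1 - 1 + 0.9) / 3
  tr3 <- mock_transformed(t2 = c(a = 1, b = 1, c = 0),
                          t1 = c(a = 0.5, b = 0.5, c = 0.9))
  r3 <- regulon("r", c("a", "b", "c"), mode = c(1, -1, 0),
                weight = c(1, 1, 1))
  expect_equal(regulon_es(tr3, r3, min_targets = 3)$es, 0.3)
  # below min_targets the cell is absent, not zero
  expect_null(regulon_es(tr3, r3, min_targets = 5))
})

test_that("regulon ES equals the brute-force oracle on random instances", {
  set.seed(31)
  genes <- sprintf("G%05d", 1:400)
  for (i in 1:200) {
    sig <- stats::setNames(rnorm(400), genes)
    tr <- rank_transform(sig)
    k <- sample(10:60, 1)
    tg <- sample(genes, k)
    mode <- runif(k, -1, 1)
    weight <- runif(k, 0.1, 1)
    r <- regulon(sprintf("r%d", i), tg, mode = mode, weight = weight)
    got <- regulon_es(tr, r)
    want <- oracle_es(tr$t2, tr$t1, r$targets, r$mode, r$weight)
    expect_equal(got$es, want, tolerance = 1e-12)
    # vectorized path agrees with the scalar path
    net <- interactome(list(r))
    m <- matrix(sig, ncol = 1, dimnames = list(genes, "s"))
    act <- infer_activity(m, net)
    expect_equal(unname(act$es[1, 1]), want, tolerance = 1e-12)
  }
})

test_that("analytic NES applies the effective-weight scaling", {
  expect_equal(nes_analytic(0.5, rep(1 / 25, 25))$nes, 2.5)
  expect_equal(nes_analytic(0, rep(0.25, 4))$nes, 0)
  expect_equal(nes_analytic(0, rep(0.25, 4))$p, 1)
  expect_equal(nes_analytic(1, c(0.5, 0.5))$nes, sqrt(2))
  expect_error(nes_analytic(1, c(0.5, 0.7)), "sum to 1")
})

test_that("empirical NES standardizes against the null ES distribution", {
  set.seed(8)
  genes <- sprintf("G%05d", 1:300)
  r <- regulon("r", sample(genes, 20), mode = rep(1, 20),
               weight = runif(20, 0.5, 1))
  nulls <- matrix(rnorm(300 * 200), 300, 200,
                  dimnames = list(genes, paste0("n", 1:200)))
  trn <- apply(nulls, 2, function(s)
    rank_transform(stats::setNames(s, genes)), simplify = FALSE)
  null_es <- vapply(trn, function(tn) regulon_es(tn, r)$es, numeric(1))
  mu <- mean(null_es); sdv <- sd(null_es)
  got <- nes_empirical(mu, r, trn)
  expect_equal(got$nes, 0, tolerance = 1e-12)
  expect_equal(got$p, 1, tolerance = 1e-12)
  got2 <- nes_empirical(mu + 1.96 * sdv, r, trn)
  expect_equal(got2$nes, 1.96, tolerance = 1e-10)
  expect_equal(got2$p, 0.05, tolerance = 1e-3)
  # matrix input path agrees
  got3 <- nes_empirical(mu + sdv, r, nulls)
  expect_equal(got3$nes, 1, tolerance = 1e-10)
})

test_that("analytic and empirical calibration agree on Gaussian nulls", {
  set.seed(41)
  genes <- sprintf("G%05d", 1:2000)
  net <- make_network(100, 30, 1900, seed = 42, mode_mix = c(0.5, 0.5, 0))
  sig <- matrix(rnorm(length(attr(net, "gene_universe")) * 5), ncol = 5,
                dimnames = list(attr(net, "gene_universe"), paste0("s", 1:5)))
  nulls <- matrix(rnorm(nrow(sig) * 1000), nrow(sig), 1000,
                  dimnames = list(rownames(sig), paste0("n", 1:1000)))
  a1 <- infer_activity(sig, net)
  a2 <- infer_activity(sig, net, nulls = nulls)
  expect_lt(median(abs(a1$nes - a2$nes)), 0.15)
})

test_that("the inferred activity matrix recovers planted perturbations", {
  net <- tiny_network(n = 12, k = 20, n_genes = 400, seed = 21)
  # a signature with one regulon's targets forced to the top ranks has the
  # largest positive NES for that regulator
  genes <- attr(net, "gene_universe")
  sig <- stats::setNames(rnorm(length(genes), 0, 1), genes)
  r <- net[["R003"]]
  sig[r$targets] <- r$mode * (10 + runif(length(r$targets)))
  act <- infer_activity(matrix(sig, ncol = 1,
                               dimnames = list(genes, "s1")), net)
  expect_equal(names(which.max(act$nes[, 1])), "R003")
  # single-sample mode: one signature in, one column out
  expect_equal(ncol(act$nes), 1L)
  expect_error(infer_activity(sig, interactome(list())), "empty")
})

test_that("type-I error of the full inference is calibrated on null data", {
  net <- make_network(40, 40, 1600, seed = 51)
  x <- simulate_cohort(net, 120, seed = 52)
  nulls <- generate_null_set(x, n = 400, group_size = 8, seed = 53)
  evalset <- generate_null_set(x, n = 150, group_size = 8, seed = 54)
  act <- infer_activity(evalset, net, nulls = nulls)
  expect_lt(abs(mean(abs(act$nes) > 1.96) - 0.05), 0.015)
})

test_that("pleiotropy adjustment shrinks shadow regulons only", {
  # disjoint regulons: matrix unchanged
  net <- tiny_network(n = 6, k = 15, n_genes = 300, seed = 61)
  ex <- simulate_perturbation_experiment(net,
                                         list(d1 = c(R001 = 3)),
                                         n_reps = 6, seed = 62)
  act <- infer_activity(ex$signatures, net)
  adj <- pleiotropy_adjust(act, net)
  expect_equal(adj$nes, act$nes)

  # identical regulons are shrunk identically (symmetry)
  genes <- sprintf("G%05d", 1:300)
  tg <- sample(genes, 20)
  twin <- interactome(list(
    regulon("A", tg, mode = rep(1, 20), weight = rep(1, 20)),
    regulon("B", tg, mode = rep(1, 20), weight = rep(1, 20))))
  sig <- stats::setNames(rnorm(300), genes)
  sig[tg] <- 5 + runif(20)
  acts <- infer_activity(matrix(sig, ncol = 1,
                                dimnames = list(genes, "s")), twin)
  adj2 <- pleiotropy_adjust(acts, twin)
  expect_equal(adj2$nes["A", 1], adj2$nes["B", 1])
  expect_lt(abs(adj2$nes["A", 1]), abs(acts$nes["A", 1]))
  expect_gt(adj2$nes["A", 1] * acts$nes["A", 1], -1e-12)  # no sign flip

  # planted regulator + 50%-overlapping shadow regulon, constructed so the
  # shadow's unique targets carry no signal
  set.seed(63)
  genes2 <- sprintf("G%05d", 1:600)
  planted_tg <- sample(genes2, 30)
  shadow_tg <- c(planted_tg[1:15], sample(setdiff(genes2, planted_tg), 15))
  net2 <- interactome(list(
    regulon("A", planted_tg, mode = rep(1, 30), weight = rep(1, 30)),
    regulon("B", shadow_tg, mode = rep(1, 30), weight = rep(1, 30))))
  sig2 <- stats::setNames(rnorm(600, 0, 0.5), genes2)
  sig2[planted_tg] <- 6 + runif(30)   # planted regulon fully activated
  sig2[shadow_tg[16:30]] <- 0         # shadow-unique targets mid-rank
  act2 <- infer_activity(matrix(sig2, ncol = 1,
                                dimnames = list(genes2, "s")), net2)
  expect_gte(abs(act2$nes["B", 1]), 1.96)  # shadow is dragged along
  adj3 <- pleiotropy_adjust(act2, net2)
  # the shadow's call weakens; the planted regulator's is untouched
  # because its unique targets keep it significant
  expect_lt(abs(adj3$nes["B", 1]), abs(act2$nes["B", 1]))
  expect_gt(abs(adj3$nes["A", 1]), 0.9 * abs(act2$nes["A", 1]))
})

test_that("network integration is the signed magnitude-weighted mean", {
  mk <- function(nes, name) {
    structure(list(nes = nes, p = 2 * pnorm(-abs(nes)),
                   es = nes, n_targets = rep(10L, nrow(nes)),
                   network = name, context = "t", calibration = "analytic",
                   min_targets = 10, transform = NULL),
              class = "netact_activity")
  }
  m1 <- matrix(c(2, 0.5), 2, 1, dimnames = list(c("r1", "r2"), "d1"))
  m2 <- matrix(c(-1, 0.5), 2, 1, dimnames = list(c("r1", "r2"), "d1"))
  int <- integrate_networks(list(mk(m1, "a"), mk(m2, "b")))
  expect_equal(int$nes["r1", "d1"], (2 * 2 + (-1) * 1) / (2 + 1))
  expect_equal(int$nes["r1", "d1"], 1.0)
  # identical copies: identity
  int2 <- integrate_networks(list(mk(m1, "a"), mk(m1, "b"), mk(m1, "c")))
  expect_equal(int2$nes, m1)
  # single matrix passes through
  expect_equal(integrate_networks(list(mk(m1, "a")))$nes, m1)
  # cell present in only one network passes through unchanged
  m3 <- matrix(3, 1, 1, dimnames = list("r3", "d1"))
  int3 <- integrate_networks(list(mk(m1, "a"), mk(m3, "b")))
  expect_equal(int3$nes["r3", "d1"], 3)
  expect_equal(int3$n_networks["r3", "d1"], 1)
  # all-zero contributions give 0
  mz <- matrix(0, 1, 1, dimnames = list("r1", "d1"))
  expect_equal(integrate_networks(list(mk(mz, "a"), mk(mz, "b")))$nes[1, 1],
               0)
  expect_error(integrate_networks(list()), ">= 1")
})

test_that("integration satisfies the weighted-mean bound on fuzzed inputs", {
  set.seed(71)
  for (i in 1:200) {
    k <- sample(1:4, 1)
    vals <- rnorm(k, 0, 3)
    nes <- (sum(vals * abs(vals))) / max(sum(abs(vals)),
                                         .Machine$double.xmin)
    mats <- lapply(seq_len(k), function(j)
      structure(list(nes = matrix(vals[j], 1, 1,
                                  dimnames = list("r", "d")),
                     p = matrix(1, 1, 1), es = NULL, n_targets = 1L,
                     network = paste0("n", j), context = "t",
                     calibration = "analytic", min_targets = 1,
                     transform = NULL), class = "netact_activity"))
    s <- integrate_networks(mats)$nes[1, 1]
    expect_equal(s, nes, tolerance = 1e-12)
    expect_lte(abs(s), max(abs(vals)) + 1e-12)
  }
})
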