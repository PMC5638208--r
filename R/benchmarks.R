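# Synthetic degradation and validation benchmarks: controlled analogues of
# the network-randomization, signature-noising and reciprocal-validation
# experiments used to characterize regulon-based activity inference.

#' IRS as a function of network randomization
#'
#' Generates a ground-truth network and a set of strong single-target
#' perturbation signatures, then infers activity against progressively
#' degree-preserving-randomized copies of the network (empirical null
#' calibration per copy) and reports the IRS at each randomization
#' fraction. An informative network should lose IRS monotonically as its
#' edges are rewired.
#'
#' @param fractions randomization fractions (default 0, 0.25, 0.5, 0.75, 1).
#' @param seed integer seed.
#' @param n_regulators,targets_per_regulator,n_genes network size (defaults
#'   match \code{\link{benchmark_recovery}}).
#' @param n_perturbed,strength,n_reps perturbation conditions: 10 compounds
#'   each shifting one regulator by +/-4 (a strongly bioactive compound
#'   regime) with 10 replicates per arm.
#' @param n_nulls,null_group_size empirical null settings (300 random
#'   two-group splits of an 80-sample baseline cohort, group size matching
#'   the replicate count).
#' @return named numeric vector: IRS per fraction.
#' @export
irs_randomization_curve <- function(fractions = c(0, 0.25, 0.5, 0.75, 1),
                                    seed = 1, n_regulators = 100,
                                    targets_per_regulator = 50,
                                    n_genes = 2000, n_perturbed = 10,
                                    strength = 4, n_reps = 10,
                                    n_nulls = 300, null_group_size = 10) {
  net <- make_network(n_regulators, targets_per_regulator, n_genes,
                      mode_mix = c(0.4, 0.4, 0.2), seed = .subseed(seed, 11))
  x <- simulate_cohort(net, 8 * null_group_size, seed = .subseed(seed, 12))
  nulls <- generate_null_set(x, n = n_nulls, group_size = null_group_size,
                             seed = .subseed(seed, 13))
  set.seed(.subseed(seed, 14))
  chosen <- sample(names(net), n_perturbed)
  perts <- stats::setNames(lapply(seq_along(chosen), function(i)
    stats::setNames(strength * (-1)^i, chosen[[i]])),
    sprintf("drug%02d", seq_along(chosen)))
  ex <- simulate_perturbation_experiment(net, perts, n_reps = n_reps,
                                         seed = .subseed(seed, 15))
  out <- stats::setNames(numeric(length(fractions)),
                         sprintf("%.2f", fractions))
  for (k in seq_along(fractions)) {
    net_k <- if (fractions[[k]] == 0) net
    else randomize_interactome(net, fractions[[k]],
                               seed = .subseed(seed, 20 + k))
    act <- infer_activity(ex$signatures, net_k, nulls = nulls)
    out[[k]] <- irs_score(act)
  }
  out
}

#' FDR-significant regulator count under signature shuffling
#'
#' Simulates one strongly bioactive compound perturbing many regulators
#' with graded strengths, then progressively shuffles random fractions of
#' the signature and counts how many regulators remain FDR-significant at
#' each noise level. Graded strengths make the count fall progressively
#' rather than collapse at once.
#'
#' @param fractions shuffle fractions (default 0, 0.2, ..., 1).
#' @param seed integer seed.
#' @param n_regulators,targets_per_regulator,n_genes network size (100
#'   regulators x 30 targets over a 3000-gene pool, so the perturbed
#'   regulons do not saturate the genome-wide ranking).
#' @param n_perturbed number of perturbed regulators (default 20) with
#'   strength magnitudes evenly spaced in \code{strength_range},
#'   alternating sign: graded bioactivity so detectability spans the whole
#'   noise grid.
#' @param strength_range magnitude range (default 0.75 to 6).
#' @param n_reps replicates per arm.
#' @param fdr_cut BH q-value threshold for counting (default 0.05).
#' @return named integer vector: significant-regulator count per fraction
#'   (analytic calibration: the count tracks how coherent regulon signal
#'   dissolves as gene labels are scrambled).
#' @export
shuffle_significance_curve <- function(fractions = seq(0, 1, by = 0.2),
                                       seed = 1, n_regulators = 100,
                                       targets_per_regulator = 30,
                                       n_genes = 3000, n_perturbed = 20,
                                       strength_range = c(0.75, 6),
                                       n_reps = 10, fdr_cut = 0.05) {
  net <- make_network(n_regulators, targets_per_regulator, n_genes,
                      mode_mix = c(0.4, 0.4, 0.2), seed = .subseed(seed, 31))
  set.seed(.subseed(seed, 34))
  chosen <- sample(names(net), n_perturbed)
  strengths <- seq(strength_range[[1]], strength_range[[2]],
                   length.out = n_perturbed) *
    rep_len(c(1, -1), n_perturbed)
  pert <- list(compound = stats::setNames(strengths, chosen))
  ex <- simulate_perturbation_experiment(net, pert, n_reps = n_reps,
                                         seed = .subseed(seed, 35))
  sig <- ex$signatures[, 1]
  out <- stats::setNames(integer(length(fractions)),
                         sprintf("%.2f", fractions))
  for (k in seq_along(fractions)) {
    s_k <- if (fractions[[k]] == 0) sig
    else degrade_signature(sig, "shuffle_fraction", fractions[[k]],
                           seed = .subseed(seed, 40 + k))
    act <- infer_activity(matrix(s_k, ncol = 1,
                                 dimnames = list(names(s_k), "compound")),
                          net)
    out[[k]] <- sum(bh_fdr(act$p[, 1]) < fdr_cut)
  }
  out
}

#' End-to-end reciprocal-validation benchmark
#'
#' Simulates matched compound and gene-silencing perturbations on a known
#' network, builds the gold standard by signature correlation, infers the
#' compound activity matrix, and runs the reciprocal enrichment validation
#' with the true and (optionally) a gene-permuted gold standard.
#'
#' @param seed integer seed.
#' @param n_gsd number of gold-standard genes (each with
#'   \code{inhibitors_per_gene} matched compounds at strength
#'   \code{-inhibitor_strength}).
#' @param inhibitors_per_gene matched compounds per gene (default 8: the
#'   NES > 1.96 recovery rule needs sets of several compounds, since even a
#'   perfectly ranked very small set cannot exceed the permutation-null
#'   spread by much).
#' @param n_decoys unmatched compounds perturbing other regulators.
#' @param inhibitor_strength activity drop induced by inhibitors and by
#'   the silencing assays (default 4).
#' @param n_reps replicates per arm.
#' @param noise_sd observation noise (default 2: biological latent
#'   variation then contributes less intra-regulon coherence, which keeps
#'   spurious signature correlations small).
#' @param p_cut gold-standard correlation cut (default 1e-4, a
#'   multiplicity-aware cut for genome-wide signatures; the iid-gene
#'   assumption of the correlation test is optimistic under regulon-block
#'   correlation, so the liberal 0.05 default of
#'   \code{\link{build_gold_standard}} would admit coherence artefacts).
#' @param randomize_gsd also evaluate a gold standard whose gene labels
#'   are randomly permuted (null control).
#' @return list(true = reciprocal_validation result, random = same for the
#'   permuted gold standard or NULL, gsd, activity).
#' @export
reciprocal_benchmark <- function(seed = 1, n_gsd = 15,
                                 inhibitors_per_gene = 8, n_decoys = 20,
                                 inhibitor_strength = 4, n_reps = 20,
                                 noise_sd = 2, p_cut = 1e-4,
                                 randomize_gsd = TRUE) {
  net <- make_network(60, 25, 3000, mode_mix = c(0.45, 0.45, 0.1),
                      seed = .subseed(seed, 51))
  set.seed(.subseed(seed, 52))
  gsd_genes <- sample(names(net), n_gsd)
  others <- setdiff(names(net), gsd_genes)
  perts <- list()
  for (i in seq_len(n_gsd)) for (j in seq_len(inhibitors_per_gene))
    perts[[sprintf("cmp_%02d_%d", i, j)]] <-
      stats::setNames(-inhibitor_strength, gsd_genes[[i]])
  for (d in seq_len(n_decoys))
    perts[[sprintf("decoy_%02d", d)]] <-
      stats::setNames(2.5 * (-1)^d, sample(others, 1))
  ex_cmp <- simulate_perturbation_experiment(net, perts, n_reps = n_reps,
                                             noise_sd = noise_sd,
                                             seed = .subseed(seed, 53))
  sil <- stats::setNames(lapply(gsd_genes, function(g)
    stats::setNames(-inhibitor_strength, g)), paste0("kd_", gsd_genes))
  ex_sil <- simulate_perturbation_experiment(net, sil, n_reps = n_reps,
                                             noise_sd = noise_sd,
                                             seed = .subseed(seed, 54))
  compound_sigs <- lapply(seq_len(ncol(ex_cmp$signatures)), function(j)
    ex_cmp$signatures[, j])
  names(compound_sigs) <- colnames(ex_cmp$signatures)
  silencing_sigs <- lapply(seq_len(ncol(ex_sil$signatures)), function(j)
    ex_sil$signatures[, j])
  names(silencing_sigs) <- gsd_genes
  gsd <- build_gold_standard(compound_sigs, silencing_sigs, p_cut = p_cut)
  act <- infer_activity(ex_cmp$signatures, net)
  integrated <- integrate_networks(list(act))
  true <- reciprocal_validation(integrated, gsd, seed = .subseed(seed, 55))
  random <- NULL
  if (randomize_gsd) {
    set.seed(.subseed(seed, 56))
    # derangement: no gene may keep its own compound set, or the control
    # would carry residual true signal through permutation fixed points
    repeat {
      perm <- sample(names(gsd))
      if (all(perm != names(gsd))) break
    }
    gsd_rand <- gsd
    names(gsd_rand) <- perm
    random <- reciprocal_validation(integrated, gsd_rand,
                                    seed = .subseed(seed, 57))
  }
  list(true = true, random = random, gsd = gsd, activity = integrated)
}
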