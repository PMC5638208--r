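# Downstream analytics: FDR, IRS, KS-based GSEA, modulator/target
# evaluation, drug-drug similarity, gold standards and reciprocal
# validation.

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR correction (wraps \code{p.adjust(method = "BH")} after
#' validating the input range).
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return q-values, order-equivariant with the input.
#' @export
bh_fdr <- function(p) {
  .check(is.numeric(p) && length(p) >= 1L, "p must be a numeric vector")
  .check(all(is.finite(p)) && all(p > 0) && all(p <= 1),
         "p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Interactome Reliability Score (IRS)
#'
#' Aggregate significance of the inferred activity changes in a set of
#' cells: restrict to cells that pass BH FDR at \code{fdr_cut}, then sum
#' \code{min(-log10 p, cap)}. This equals the area under the significant-
#' count curve N(t) = #\{i : -log10 p_i >= t\} integrated over t in
#' [0, cap]. Used both as a network-quality metric (across a whole
#' signature set) and as a per-compound bioactivity metric (one column).
#'
#' @param p p-values of the activity cells (a numeric vector, a
#'   \code{netact_activity} or \code{netact_integrated} object).
#' @param fdr_cut BH q-value cut (default 0.05).
#' @param cap per-cell contribution cap on the -log10 p scale (default 20).
#' @return non-negative scalar; 0 when nothing passes FDR.
#' @export
irs_score <- function(p, fdr_cut = 0.05, cap = 20) {
  if (inherits(p, "netact_activity") || inherits(p, "netact_integrated"))
    p <- p$p
  p <- as.vector(p)
  p <- p[!is.na(p)]
  .check(length(p) >= 1L, "no activity cells")
  p <- pmax(p, .Machine$double.xmin)
  q <- bh_fdr(p)
  keep <- q < fdr_cut
  if (!any(keep)) return(0)
  sum(pmin(-log10(p[keep]), cap))
}

#' Relative IRS across compared interactomes
#'
#' @param scores named numeric vector of IRS values.
#' @return scores divided by the largest score (percent-of-best scale in
#'   [0, 1]).
#' @export
relative_irs <- function(scores) {
  .check(length(scores) >= 1L && max(scores) > 0,
         "need at least one positive IRS")
  scores / max(scores)
}

# Weighted KS running-sum enrichment score of a gene set on a ranked
# statistic. O(k log k) in the set size: the running sum only changes at
# hit positions. Returns the signed maximum deviation and its peak index.
.ks_es <- function(stat, hits, weight_exponent = 1) {
  n <- length(stat)
  k <- length(hits)
  if (k == 0L) .fail("gene set does not intersect the ranking")
  if (k == n) return(list(es = 0, peak = n))
  ord <- order(stat, decreasing = TRUE)
  pos <- sort(match(match(hits, names(stat)), ord))
  w <- abs(stat[ord][pos])^weight_exponent
  if (sum(w) == 0) w <- rep(1, k)
  cw <- cumsum(w) / sum(w)
  miss <- 1 / (n - k)
  i <- seq_len(k)
  after <- cw - (pos - i) * miss          # value just after each hit
  before <- c(0, cw[-k]) - (pos - i) * miss  # value just before each hit
  hi <- max(after); lo <- min(before)
  if (hi >= -lo) list(es = hi, peak = pos[which.max(after)], ord = ord,
                      pos = pos)
  else list(es = lo, peak = pos[which.min(before)], ord = ord, pos = pos)
}

#' Gene-set enrichment by the weighted Kolmogorov-Smirnov statistic
#'
#' Classical GSEA running sum: genes are ranked by the statistic
#' (descending); walking down the ranking, set members add
#' \code{|stat|^weight_exponent} (normalized), non-members subtract
#' \code{1/(n - k)}; ES is the maximum signed deviation. Significance comes
#' from \code{n_perm} random gene sets of the same size (gene-label
#' permutation null): NES is the null-standardized ES and p the two-sided
#' permutation tail with the conventional +1 floor.
#'
#' @param gene_set character vector (must intersect the ranking).
#' @param ranked named numeric vector: per-gene ranking statistic.
#' @param weight_exponent 0 = classical KS (rank-only, invariant to
#'   monotone transforms), 1 = weighted (default).
#' @param n_perm number of random sets (default 1000).
#' @param seed integer seed.
#' @return object of class \code{"netact_enrichment"}: list(es, nes, p,
#'   leading_edge, n_permutations, seed).
#' @export
ks_gsea <- function(gene_set, ranked, weight_exponent = 1, n_perm = 1000,
                    seed = 1) {
  .check(is.numeric(ranked) && !is.null(names(ranked)),
         "ranked must be a named numeric vector")
  hits <- intersect(unique(gene_set), names(ranked))
  .check(length(hits) > 0L, "gene set does not intersect the ranking")
  obs <- .ks_es(ranked, hits, weight_exponent)
  k <- length(hits); n <- length(ranked)
  leading <- character(0)
  if (k < n) {
    in_peak <- if (obs$es >= 0) obs$pos <= obs$peak else obs$pos >= obs$peak
    leading <- names(ranked)[obs$ord][obs$pos[in_peak]]
  }
  set.seed(as.integer(seed))
  null_es <- vapply(seq_len(n_perm), function(i) {
    .ks_es(ranked, names(ranked)[sample.int(n, k)], weight_exponent)$es
  }, numeric(1))
  sdv <- stats::sd(null_es)
  nes <- if (sdv > 0) (obs$es - mean(null_es)) / sdv else 0
  p <- (1 + sum(abs(null_es) >= abs(obs$es))) / (n_perm + 1)
  structure(list(es = obs$es, nes = nes, p = p, leading_edge = leading,
                 n_permutations = n_perm, seed = as.integer(seed)),
            class = "netact_enrichment")
}

#' @export
print.netact_enrichment <- function(x, ...) {
  cat(sprintf("Enrichment: ES = %.3f, NES = %.2f, p = %.4g (%d permutations)\n",
              x$es, x$nes, x$p, x$n_permutations))
  invisible(x)
}

# Shared machinery for modulator/target evaluation: enrichment of a
# known set at the chosen end of a NES ranking.
.evaluate_enrichment <- function(values, known, direction, ...) {
  values <- values[!is.na(values)]
  known <- intersect(known, names(values))
  .check(length(known) > 0L, "no known item is present in the ranking")
  stat <- if (direction == "inhibitor") -values else values
  ks_gsea(known, stat, ...)
}

#' Are known modulators enriched among extreme activity calls?
#'
#' Ranks all perturbations by the target regulator's NES (most inactivating
#' first for \code{direction = "inhibitor"}, most activating first for
#' \code{"activator"}) and tests whether the known modulators concentrate
#' at the top of that ranking. The same machinery applies to
#' expression-based rankings for comparison (pass a matrix of per-gene
#' differential expression instead of activity).
#'
#' @param activity a \code{netact_activity}/\code{netact_integrated}, or a
#'   plain regulators x perturbations NES matrix.
#' @param target regulator (row) id.
#' @param known_modulators perturbation ids annotated as modulators of the
#'   target.
#' @param direction \code{"inhibitor"} or \code{"activator"}.
#' @param ... passed to \code{\link{ks_gsea}}.
#' @return a \code{netact_enrichment}.
#' @export
evaluate_modulators <- function(activity, target, known_modulators,
                                direction = c("inhibitor", "activator"),
                                ...) {
  direction <- match.arg(direction)
  m <- if (is.matrix(activity)) activity else activity$nes
  .check(target %in% rownames(m), "target '%s' not tested", target)
  .evaluate_enrichment(m[target, ], known_modulators, direction, ...)
}

#' Are a compound's established targets enriched among its activity calls?
#'
#' Mirror image of \code{\link{evaluate_modulators}} along the regulator
#' axis: ranks all regulators by their NES under one perturbation and tests
#' the known target set.
#'
#' @param activity as in \code{\link{evaluate_modulators}}.
#' @param perturbation column id.
#' @param known_targets regulator ids annotated as targets of the compound.
#' @param direction \code{"inhibitor"} or \code{"activator"}.
#' @param ... passed to \code{\link{ks_gsea}}.
#' @return a \code{netact_enrichment}.
#' @export
evaluate_targets <- function(activity, perturbation, known_targets,
                             direction = c("inhibitor", "activator"), ...) {
  direction <- match.arg(direction)
  m <- if (is.matrix(activity)) activity else activity$nes
  .check(perturbation %in% colnames(m), "perturbation '%s' not tested",
         perturbation)
  .evaluate_enrichment(m[, perturbation], known_targets, direction, ...)
}

#' Drug-drug signature similarity by mutual extreme-set enrichment
#'
#' Takes the \code{top_frac} most up- and most down-regulated features of
#' signature a and computes their KS enrichment on the ranking of b
#' (\code{dis_ab = (ES(U_a on b) - ES(D_a on b)) / 2}), and vice versa;
#' similarity is the average of the two directed scores, so it is symmetric
#' by construction and lies in [-1, 1]. \code{1 - similarity} serves as a
#' distance for downstream clustering.
#'
#' @param a,b named numeric signatures or activity columns on a shared
#'   universe of >= 100 features.
#' @param top_frac extreme fraction per tail, in (0, 0.25] (default 0.05).
#' @param weight_exponent passed to the KS running sum (default 1).
#' @return list(similarity, dis_ab, dis_ba, distance).
#' @export
drug_signature_similarity <- function(a, b, top_frac = 0.05,
                                      weight_exponent = 1) {
  .check(top_frac > 0 && top_frac <= 0.25, "top_frac must be in (0, 0.25]")
  shared <- intersect(names(a), names(b))
  .check(length(shared) >= 100L, "need >= 100 shared features")
  a <- a[shared]; b <- b[shared]
  .check(stats::sd(a) > 0 && stats::sd(b) > 0,
         "constant signature: similarity undefined")
  k <- max(1L, floor(top_frac * length(shared)))
  extremes <- function(x) {
    ord <- order(x, decreasing = TRUE)
    list(up = names(x)[ord[seq_len(k)]],
         down = names(x)[ord[length(x) - seq_len(k) + 1L]])
  }
  dis <- function(sets, target) {
    (.ks_es(target, sets$up, weight_exponent)$es -
       .ks_es(target, sets$down, weight_exponent)$es) / 2
  }
  dis_ab <- dis(extremes(a), b)
  dis_ba <- dis(extremes(b), a)
  sim <- (dis_ab + dis_ba) / 2
  list(similarity = sim, dis_ab = dis_ab, dis_ba = dis_ba,
       distance = 1 - sim)
}

#' Spearman correlation of drug-sensitivity profiles
#'
#' @param a,b named numeric potency profiles (e.g. -log GI50) over cell
#'   lines; >= 3 shared lines required.
#' @return Spearman rho over the shared cell lines.
#' @export
sensitivity_correlation <- function(a, b) {
  shared <- intersect(names(a), names(b))
  .check(length(shared) >= 3L, "need >= 3 shared cell lines, have %d",
         length(shared))
  stats::cor(a[shared], b[shared], method = "spearman")
}

#' Gold standard of compound-target couplings from matched signatures
#'
#' For each silenced gene, compounds are ranked by descending Pearson
#' correlation of their expression signature with the gene's silencing
#' signature; the significant (inhibitor) set holds compounds with r > 0
#' and correlation-test p < \code{p_cut} (two-sided t approximation with
#' n - 2 degrees of freedom, restricted to the positive tail: only a
#' compound that mimics the knock-down is an inhibitor candidate, so a
#' null input yields ~p_cut/2 significant calls).
#'
#' @param compound_sigs named list: compound -> signature.
#' @param silencing_sigs named list: gene -> silencing signature.
#' @param p_cut significance cut (default 0.05).
#' @return object of class \code{"netact_gold_standard"}: per-gene list of
#'   data.frames (compound, r, p, significant), ranked by r.
#' @export
build_gold_standard <- function(compound_sigs, silencing_sigs,
                                p_cut = 0.05) {
  .check(length(compound_sigs) >= 1L && length(silencing_sigs) >= 1L,
         "need compound and silencing signatures")
  const <- vapply(compound_sigs, function(s) stats::sd(s) == 0, logical(1))
  if (any(const)) {
    .warnf("%d zero-variance compound signature(s) excluded", sum(const))
    compound_sigs <- compound_sigs[!const]
  }
  out <- lapply(names(silencing_sigs), function(g) {
    sil <- silencing_sigs[[g]]
    if (stats::sd(sil) == 0) {
      .warnf("zero-variance silencing signature for '%s' excluded", g)
      return(NULL)
    }
    res <- lapply(names(compound_sigs), function(cp) {
      s <- compound_sigs[[cp]]
      shared <- intersect(names(s), names(sil))
      n <- length(shared)
      r <- stats::cor(s[shared], sil[shared])
      tt <- r * sqrt((n - 2) / (1 - r^2))
      data.frame(compound = cp, r = r,
                 p = 2 * stats::pt(-abs(tt), df = n - 2),
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    res <- res[order(-res$r), , drop = FALSE]
    res$significant <- res$r > 0 & res$p < p_cut
    rownames(res) <- NULL
    res
  })
  names(out) <- names(silencing_sigs)
  structure(Filter(Negate(is.null), out), class = "netact_gold_standard",
            p_cut = p_cut)
}

#' @export
print.netact_gold_standard <- function(x, ...) {
  nsig <- vapply(x, function(d) sum(d$significant), integer(1))
  cat(sprintf("Gold standard: %d genes, %d compounds tested, median %d significant inhibitor(s) per gene\n",
              length(x), if (length(x)) nrow(x[[1]]) else 0L,
              as.integer(stats::median(nsig))))
  invisible(x)
}

#' Reciprocal validation of activity predictions against a gold standard
#'
#' For each gold-standard gene that is also an inferred regulator, ranks
#' all compounds by the gene's activity score (most inactivating first) and
#' tests whether the gene's significant gold-standard inhibitors are
#' enriched at the top of that ranking. A gene is "recovered" when the
#' enrichment NES exceeds \code{nes_cut}; genes with an empty significant
#' set are untestable.
#'
#' @param activity a \code{netact_integrated}/\code{netact_activity} or NES
#'   matrix (regulators x compounds).
#' @param gsd a \code{netact_gold_standard}.
#' @param nes_cut recovery threshold (default 1.96).
#' @param n_perm,seed permutation settings for \code{\link{ks_gsea}}.
#' @param weight_exponent KS weighting (default 0, the classical rank-only
#'   statistic: with a handful of extreme activity calls per gene, the
#'   |stat|-weighted null is dominated by whether a random set catches one
#'   of them, which defeats the standardization).
#' @return list(per_gene = data.frame(gene, es, nes, p, recovered,
#'   n_inhibitors), recovered, testable, fraction).
#' @export
reciprocal_validation <- function(activity, gsd, nes_cut = 1.96,
                                  n_perm = 1000, seed = 1,
                                  weight_exponent = 0) {
  stopifnot(inherits(gsd, "netact_gold_standard"))
  m <- if (is.matrix(activity)) activity else activity$nes
  genes <- intersect(names(gsd), rownames(m))
  .check(length(genes) > 0L, "no gold-standard gene among the regulators")
  rows <- list()
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    sig_set <- gsd[[g]]$compound[gsd[[g]]$significant]
    sig_set <- intersect(sig_set, colnames(m))
    if (length(sig_set) == 0L) next  # untestable
    enr <- .evaluate_enrichment(m[g, ], sig_set, "inhibitor",
                                weight_exponent = weight_exponent,
                                n_perm = n_perm,
                                seed = .subseed(seed, i))
    rows[[g]] <- data.frame(gene = g, es = enr$es, nes = enr$nes, p = enr$p,
                            recovered = enr$nes > nes_cut,
                            n_inhibitors = length(sig_set),
                            stringsAsFactors = FALSE)
  }
  .check(length(rows) > 0L, "no testable gold-standard gene")
  per_gene <- do.call(rbind, rows)
  rownames(per_gene) <- NULL
  list(per_gene = per_gene, recovered = sum(per_gene$recovered),
       testable = nrow(per_gene),
       fraction = mean(per_gene$recovered))
}

#' Fisher's exact test for top-fraction overlap of two rankings
#'
#' Thin utility: dichotomizes both rankings at their top \code{frac} and
#' tests the 2x2 contingency of membership.
#'
#' @param a,b named numeric vectors over a shared universe.
#' @param frac top fraction (default 0.025).
#' @return \code{fisher.test} result on the shared universe.
#' @export
top_overlap_fisher <- function(a, b, frac = 0.025) {
  shared <- intersect(names(a), names(b))
  .check(length(shared) >= 40L, "need >= 40 shared features")
  k <- max(1L, floor(frac * length(shared)))
  top <- function(x) names(x[shared])[order(-x[shared])][seq_len(k)]
  ta <- shared %in% top(a); tb <- shared %in% top(b)
  stats::fisher.test(table(ta, tb))
}
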