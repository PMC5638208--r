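# Signature construction and preprocessing.
#
# All signatures are named numeric vectors on a signed z-score scale
# (positive = up in treatment); collections are genes x signatures matrices.

#' Per-sample z-score signatures
#'
#' Scales each gene to mean 0 / sd 1 across the samples of its scaling group
#' (all samples by default; per-plate when \code{group_by} is given, so a
#' sample's values depend only on its own plate). Every sample's scaled
#' column is a single-sample signature.
#'
#' @param x genes x samples matrix.
#' @param group_by optional character/factor of length \code{ncol(x)}
#'   assigning samples to scaling groups (e.g. plate or cell line).
#' @return genes x samples matrix of z-scores; zero-variance genes are set
#'   to 0 within their group with a warning.
#' @export
single_sample_zscores <- function(x, group_by = NULL) {
  .check(is.matrix(x), "x must be a matrix")
  if (is.null(group_by)) group_by <- rep("all", ncol(x))
  .check(length(group_by) == ncol(x), "group_by must match ncol(x)")
  out <- x
  for (g in unique(group_by)) {
    idx <- which(group_by == g)
    if (length(idx) < 3L)
      .fail("scaling group '%s' has %d sample(s); >= 3 required", g,
            length(idx))
    sub <- x[, idx, drop = FALSE]
    mu <- rowMeans(sub)
    sdv <- apply(sub, 1L, stats::sd)
    flat <- sdv == 0
    if (any(flat)) {
      .warnf("%d zero-variance gene(s) in group '%s' set to 0", sum(flat), g)
      sdv[flat] <- 1
    }
    z <- (sub - mu) / sdv
    z[flat, ] <- 0
    out[, idx] <- z
  }
  out
}

#' Two-group differential signature (Welch t)
#'
#' Per gene, the Welch t statistic comparing group A against group B is
#' converted to a signed z-score: \code{sign(meanA - meanB) *
#' qnorm(1 - p/2)} with p the two-sided t p-value, so that positive values
#' mean up in group A. Degenerate genes (zero variance in both groups) give
#' 0 when the means are equal and +/- \code{z_cap} otherwise.
#'
#' @param x genes x samples matrix.
#' @param groupA,groupB disjoint sample-id (or column-index) vectors, each
#'   of size >= 2.
#' @param z_cap clamp for infinite / overflowing statistics (default 12).
#' @return named numeric signature with attribute \code{"provenance"} =
#'   \code{"two_group_t"}.
#' @export
two_group_signature <- function(x, groupA, groupB, z_cap = 12) {
  .check(is.matrix(x), "x must be a matrix")
  a <- x[, groupA, drop = FALSE]; b <- x[, groupB, drop = FALSE]
  .check(ncol(a) >= 2L && ncol(b) >= 2L, "each group needs >= 2 samples")
  ca <- if (is.character(groupA)) groupA else colnames(x)[groupA]
  cb <- if (is.character(groupB)) groupB else colnames(x)[groupB]
  if (!is.null(ca) && !is.null(cb))
    .check(length(intersect(ca, cb)) == 0L, "groups must be disjoint")
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1L)
  vb <- rowSums((b - mb)^2) / (nb - 1L)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L))
  p <- 2 * stats::pt(-abs(tstat), df)
  z <- sign(ma - mb) * stats::qnorm(1 - p / 2)
  degen <- se2 == 0
  if (any(degen)) {
    eq <- degen & (ma == mb)
    z[eq] <- 0
    if (any(degen & !eq)) {
      .warnf("%d zero-variance gene(s) with unequal means clamped to +/-%g",
             sum(degen & !eq), z_cap)
      z[degen & !eq] <- sign(ma - mb)[degen & !eq] * z_cap
    }
  }
  z[is.infinite(z) | abs(z) > z_cap] <- sign(z[is.infinite(z) |
                                                 abs(z) > z_cap]) * z_cap
  z[is.na(z)] <- 0
  structure(z, provenance = "two_group_t")
}

#' Null signature set from random sample splits
#'
#' Draws n random disjoint splits of the samples into two groups of
#' \code{group_size} and computes a two-group signature per draw; emulates a
#' permutation null for perturbational signatures.
#'
#' @param x genes x samples matrix.
#' @param n number of null signatures (default 1000; a warning is issued
#'   below 100, where empirical calibration gets unreliable).
#' @param group_size samples per group; default
#'   \code{min(100, floor(ncol(x) / 2))}.
#' @param seed integer seed; the set is deterministic given the seed.
#' @return genes x n matrix with attributes \code{seed}, \code{scheme}.
#' @export
generate_null_set <- function(x, n = 1000, group_size = NULL, seed = 1) {
  .check(is.matrix(x), "x must be a matrix")
  if (is.null(group_size)) group_size <- min(100L, floor(ncol(x) / 2))
  .check(2L * group_size <= ncol(x),
         "need 2 * group_size = %d samples, have %d", 2L * group_size,
         ncol(x))
  .check(group_size >= 2L, "group_size must be >= 2")
  if (n < 100) .warnf("null set of size %d (< 100) is coarse for inference",
                      n)
  set.seed(as.integer(seed))
  out <- matrix(NA_real_, nrow(x), n,
                dimnames = list(rownames(x), paste0("null", seq_len(n))))
  for (i in seq_len(n)) {
    idx <- sample.int(ncol(x), 2L * group_size)
    out[, i] <- two_group_signature(x, idx[seq_len(group_size)],
                                    idx[group_size + seq_len(group_size)])
  }
  structure(out, seed = as.integer(seed),
            scheme = sprintf("random two-group splits (%d vs %d)",
                             group_size, group_size))
}

#' Stouffer combination of signatures
#'
#' Per gene, \code{z* = sum(z_i) / sqrt(k)} over the k signatures that
#' contain the gene (signatures need not share a universe; absent genes are
#' simply not counted).
#'
#' @param signatures non-empty list of named numeric signatures.
#' @return named numeric signature over the union of genes, with attribute
#'   \code{"provenance"} = \code{"stouffer"}.
#' @export
stouffer_combine <- function(signatures) {
  .check(is.list(signatures) && length(signatures) >= 1L,
         "need >= 1 signature")
  genes <- unique(unlist(lapply(signatures, names), use.names = FALSE))
  .check(length(genes) > 0L, "signatures carry no gene names")
  zsum <- stats::setNames(numeric(length(genes)), genes)
  k <- stats::setNames(integer(length(genes)), genes)
  for (s in signatures) {
    zsum[names(s)] <- zsum[names(s)] + s
    k[names(s)] <- k[names(s)] + 1L
  }
  structure(zsum / sqrt(k), provenance = "stouffer")
}

#' Knock-down efficiency check
#'
#' A knock-down signature is accepted when the silenced gene itself went
#' down: its two-sided p-value is below \code{p_max} and its statistic is
#' negative.
#'
#' @param signature named numeric signature (z scale).
#' @param silenced_gene gene id; must be present in the signature.
#' @param p_max p-value threshold (default 0.1).
#' @return logical.
#' @export
kd_efficiency_check <- function(signature, silenced_gene, p_max = 0.1) {
  .check(silenced_gene %in% names(signature),
         "silenced gene '%s' absent from signature", silenced_gene)
  z <- signature[[silenced_gene]]
  p <- 2 * stats::pnorm(-abs(z))
  z < 0 && p < p_max
}

#' Replicate-reproducibility filter
#'
#' Scores each sample by the mean Pearson correlation of its signature to
#' its replicates; the score is standardized against the background of that
#' sample's correlations to all non-replicate samples, and samples are kept
#' when the resulting z exceeds \code{z_keep}.
#'
#' @param x genes x samples signature matrix.
#' @param replicate_groups character/factor of length \code{ncol(x)}.
#' @param z_keep keep threshold on the background z (default 5).
#' @return data.frame (sample, group, score, z, keep); singleton groups get
#'   NA score and \code{keep = NA} ("unscorable").
#' @export
replicate_reproducibility <- function(x, replicate_groups, z_keep = 5) {
  .check(is.matrix(x) && length(replicate_groups) == ncol(x),
         "replicate_groups must match ncol(x)")
  cc <- stats::cor(x)
  n <- ncol(x)
  score <- z <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    reps <- which(replicate_groups == replicate_groups[[i]])
    reps <- setdiff(reps, i)
    if (length(reps) == 0L) next
    bg <- setdiff(seq_len(n), c(i, reps))
    score[[i]] <- mean(cc[i, reps])
    if (length(bg) >= 2L) {
      mu <- mean(cc[i, bg]); s <- stats::sd(cc[i, bg])
      z[[i]] <- if (s > 0) (score[[i]] - mu) / s else Inf
    }
  }
  data.frame(sample = if (is.null(colnames(x))) as.character(seq_len(n))
             else colnames(x),
             group = as.character(replicate_groups),
             score = score, z = z, keep = z > z_keep,
             stringsAsFactors = FALSE)
}

#' Controlled degradation of a signature
#'
#' Two noise models used for robustness experiments: permute the values of a
#' random fraction of genes among themselves (\code{"shuffle_fraction"}), or
#' add Gaussian noise with sd equal to \code{amount} times the signature's
#' sd to every gene (\code{"gaussian_sd_fraction"}).
#'
#' @param signature named numeric vector.
#' @param mode \code{"shuffle_fraction"} or \code{"gaussian_sd_fraction"}.
#' @param amount fraction in \code{[0, 1]} for shuffling; non-negative sd
#'   multiplier for Gaussian noise.
#' @param seed integer seed.
#' @return degraded signature (same genes, same order).
#' @export
degrade_signature <- function(signature,
                              mode = c("shuffle_fraction",
                                       "gaussian_sd_fraction"),
                              amount, seed = 1) {
  mode <- match.arg(mode)
  .check(is.numeric(amount) && length(amount) == 1L && amount >= 0,
         "amount must be a non-negative scalar")
  set.seed(as.integer(seed))
  out <- signature
  if (mode == "shuffle_fraction") {
    .check(amount <= 1, "shuffle fraction must be <= 1")
    k <- round(amount * length(signature))
    if (k >= 2L) {
      idx <- sample.int(length(signature), k)
      out[idx] <- out[sample(idx)]
    }
  } else {
    out <- out + stats::rnorm(length(out), 0, amount * stats::sd(signature))
  }
  out
}
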