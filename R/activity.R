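# Three-tail weighted regulon enrichment.
#
# A differential signature is converted to two rank scores per gene: a
# signed quantile score t2 (two-tail: where the gene sits from most down- to
# most up-regulated) and a magnitude quantile score t1 (one-tail: how
# extreme |statistic| is, direction ignored). A regulon's enrichment score
# is the confidence-weighted mean of mode * t2 + (1 - |mode|) * t1 over its
# targets, so fully signed targets contribute directionally, direction-
# unknown targets contribute through magnitude, and partial modes blend the
# two tails.

#' Rank-transform a signature for three-tail enrichment
#'
#' t2 = probit of the fractional rank of the signed statistic,
#' \code{qnorm(r / (n + 1))}; t1 = probit of the folded fractional rank of
#' the magnitude, \code{qnorm(0.5 + r' / (2 (n + 1)))}. Ties get average
#' ranks. Both scores are finite and monotone in the statistic
#' (respectively its magnitude).
#'
#' @param signature named numeric vector (>= 100 genes recommended; a
#'   warning is issued below).
#' @return object of class \code{"netact_transformed"}: list with named
#'   numeric vectors \code{t2}, \code{t1} and the signature \code{label}.
#' @export
rank_transform <- function(signature) {
  .check(is.numeric(signature) && !is.null(names(signature)),
         "signature must be a named numeric vector")
  .check(all(is.finite(signature)), "signature contains non-finite values")
  n <- length(signature)
  if (n < 100) .warnf("signature has only %d genes; ranks are coarse", n)
  if (length(unique(signature)) == 1L)
    .fail("all signature values equal: rank transform is degenerate")
  r2 <- rank(signature, ties.method = "average")
  r1 <- rank(abs(signature), ties.method = "average")
  structure(list(t2 = stats::qnorm(r2 / (n + 1)),
                 t1 = stats::qnorm(0.5 + r1 / (2 * (n + 1))),
                 label = attr(signature, "label")),
            class = "netact_transformed")
}

# Column-wise transform of a genes x signatures matrix -> list(t2, t1).
.rank_transform_matrix <- function(x) {
  n <- nrow(x)
  r2 <- apply(x, 2L, rank, ties.method = "average")
  r1 <- apply(abs(x), 2L, rank, ties.method = "average")
  list(t2 = matrix(stats::qnorm(r2 / (n + 1)), n, ncol(x),
                   dimnames = dimnames(x)),
       t1 = matrix(stats::qnorm(0.5 + r1 / (2 * (n + 1))), n, ncol(x),
                   dimnames = dimnames(x)))
}

#' Regulon enrichment score on a transformed signature
#'
#' \code{es = sum_i w_i (mode_i t2_i + (1 - |mode_i|) t1_i)} over the
#' regulon targets present in the signature, with the confidence weights
#' renormalized to sum 1 over the present targets, so the score is a
#' weighted mean of per-target rank scores.
#'
#' @param transformed a \code{netact_transformed}.
#' @param reg a \code{\link{regulon}}.
#' @param min_targets minimum present targets (default 10); below it the
#'   result is \code{NULL} (the cell is untestable, not zero).
#' @return list(es, n_targets_used, weights) where \code{weights} are the
#'   renormalized present-target weights, or \code{NULL}.
#' @export
regulon_es <- function(transformed, reg, min_targets = 10) {
  stopifnot(inherits(transformed, "netact_transformed"),
            inherits(reg, "netact_regulon"))
  present <- reg$targets %in% names(transformed$t2)
  if (sum(present) < min_targets) return(NULL)
  tg <- reg$targets[present]
  w <- reg$weight[present]; m <- reg$mode[present]
  w <- w / sum(w)
  es <- sum(w * (m * transformed$t2[tg] +
                   (1 - abs(m)) * transformed$t1[tg]))
  list(es = es, n_targets_used = length(tg), weights = w)
}

#' Analytic NES calibration
#'
#' Standardizes an enrichment score under the null that the transformed
#' per-target scores are iid standard normal: a weighted mean of k iid
#' N(0,1) variables with weights summing to 1 has sd
#' \code{sqrt(sum(w_i^2))}, so \code{nes = es / sqrt(sum(w_i^2))} with a
#' two-sided normal p-value. Fast path; exact for fully signed regulons.
#'
#' @param es enrichment score.
#' @param weights present-target weights summing to 1.
#' @return list(nes, p).
#' @export
nes_analytic <- function(es, weights) {
  .check(abs(sum(weights) - 1) < 1e-8, "weights must sum to 1")
  nes <- es / sqrt(sum(weights^2))
  list(nes = nes, p = 2 * stats::pnorm(-abs(nes)))
}

#' Empirical NES calibration against a null signature set
#'
#' The regulon's ES is computed on every rank-transformed null signature;
#' \code{nes = (es - mean_null) / sd_null} and the p-value is the two-sided
#' normal tail of the standardized score (a rank-based empirical p with 1000
#' nulls floors at 1e-3, too coarse for FDR over thousands of regulators).
#'
#' @param es observed enrichment score.
#' @param reg the \code{\link{regulon}}.
#' @param transformed_nulls list of \code{netact_transformed} null
#'   signatures (>= 100 recommended) or a genes x nulls statistic matrix.
#' @param min_targets passed to \code{\link{regulon_es}}.
#' @return list(nes, p).
#' @export
nes_empirical <- function(es, reg, transformed_nulls, min_targets = 10) {
  if (is.matrix(transformed_nulls)) {
    tr <- .rank_transform_matrix(transformed_nulls)
    null_es <- .es_matrix(interactome(list(reg)), tr$t2, tr$t1,
                          min_targets = min_targets)$es[1L, ]
  } else {
    if (length(transformed_nulls) < 100)
      .warnf("only %d null signatures; empirical calibration is coarse",
             length(transformed_nulls))
    null_es <- vapply(transformed_nulls, function(tn)
      regulon_es(tn, reg, min_targets = min_targets)$es, numeric(1))
  }
  mu <- mean(null_es); sdv <- stats::sd(null_es)
  .check(sdv > 0, "null ES distribution has zero spread")
  nes <- (es - mu) / sdv
  list(nes = nes, p = 2 * stats::pnorm(-abs(nes)))
}

# Vectorized ES for a whole interactome on transformed matrices.
# Returns list(es = regulators x signatures matrix, n_targets, denom,
# keep): regulons with < min_targets present targets are dropped.
.es_matrix <- function(net, t2, t1, min_targets = 10) {
  genes <- rownames(t2)
  gi <- stats::setNames(seq_along(genes), genes)
  rows <- integer(0); cols <- integer(0)
  vmode <- numeric(0); vmag <- numeric(0)
  n_targets <- integer(length(net)); denom <- numeric(length(net))
  keep <- logical(length(net))
  ri <- 0L
  for (k in seq_along(net)) {
    reg <- net[[k]]
    idx <- gi[reg$targets]
    present <- !is.na(idx)
    if (sum(present) < min_targets) next
    ri <- ri + 1L
    keep[k] <- TRUE
    w <- reg$weight[present]; m <- reg$mode[present]
    w <- w / sum(w)
    rows <- c(rows, rep.int(ri, sum(present)))
    cols <- c(cols, unname(idx[present]))
    vmode <- c(vmode, w * m)
    vmag <- c(vmag, w * (1 - abs(m)))
    n_targets[ri] <- sum(present)
    denom[ri] <- sqrt(sum(w^2))
  }
  if (ri == 0L) .fail("no regulon shares >= %d genes with the signatures",
                      min_targets)
  dims <- c(ri, length(genes))
  A <- Matrix::sparseMatrix(i = rows, j = cols, x = vmode, dims = dims)
  B <- Matrix::sparseMatrix(i = rows, j = cols, x = vmag, dims = dims)
  es <- as.matrix(A %*% t2 + B %*% t1)
  dimnames(es) <- list(names(net)[keep], colnames(t2))
  list(es = es, n_targets = n_targets[seq_len(ri)],
       denom = denom[seq_len(ri)], keep = keep)
}

#' Infer a protein-activity matrix from signatures and an interactome
#'
#' The central fitting function: converts each differential gene-expression
#' signature into per-regulator activity scores by three-tail weighted
#' regulon enrichment, calibrated either analytically or against an
#' empirical null signature set (recommended, and used automatically when
#' \code{nulls} is supplied). Works at the single-sample level: one
#' signature in, one activity column out.
#'
#' @param signatures named numeric vector (one signature) or genes x
#'   signatures matrix.
#' @param net a \code{netact_interactome}.
#' @param nulls optional genes x n null-signature matrix (see
#'   \code{\link{generate_null_set}}); enables empirical calibration.
#' @param min_targets minimum regulon targets present in the signature for
#'   a regulator to be testable (default 10).
#' @param pleiotropy apply shadow-regulon adjustment
#'   (\code{\link{pleiotropy_adjust}}) before returning (default FALSE).
#' @param ... passed to \code{pleiotropy_adjust}.
#' @return Object of class \code{"netact_activity"}: list with matrices
#'   \code{es}, \code{nes}, \code{p} (regulators x signatures), integer
#'   vector \code{n_targets}, the \code{network} and \code{context} labels,
#'   the \code{calibration} used, and the rank-transformed signatures.
#' @export
infer_activity <- function(signatures, net, nulls = NULL, min_targets = 10,
                           pleiotropy = FALSE, ...) {
  stopifnot(inherits(net, "netact_interactome"))
  .check(length(net) > 0L, "empty interactome")
  if (!is.matrix(signatures))
    signatures <- matrix(signatures, ncol = 1,
                         dimnames = list(names(signatures), "signature"))
  tr <- .rank_transform_matrix(signatures)
  fit <- .es_matrix(net, tr$t2, tr$t1, min_targets = min_targets)
  if (is.null(nulls)) {
    calibration <- "analytic"
    nes <- fit$es / fit$denom
  } else {
    calibration <- "empirical"
    if (ncol(nulls) < 100)
      .warnf("only %d null signatures; empirical calibration is coarse",
             ncol(nulls))
    trn <- .rank_transform_matrix(nulls)
    null_es <- .es_matrix(net, trn$t2, trn$t1,
                          min_targets = min_targets)$es
    mu <- rowMeans(null_es)
    sdv <- apply(null_es, 1L, stats::sd)
    .check(all(sdv > 0), "null ES with zero spread for some regulon")
    nes <- (fit$es - mu) / sdv
  }
  p <- 2 * stats::pnorm(-abs(nes))
  out <- structure(list(es = fit$es, nes = nes, p = p,
                        n_targets = stats::setNames(fit$n_targets,
                                                    rownames(fit$es)),
                        network = attr(net, "name"),
                        context = attr(net, "context"),
                        calibration = calibration,
                        min_targets = min_targets,
                        transform = tr),
                   class = "netact_activity")
  if (pleiotropy) out <- pleiotropy_adjust(out, net, ...)
  out
}

#' @export
print.netact_activity <- function(x, ...) {
  cat(sprintf("Activity matrix [%s/%s, %s calibration]: %d regulators x %d signatures\n",
              x$network, x$context, x$calibration, nrow(x$nes), ncol(x$nes)))
  cat(sprintf("  |NES| > 1.96 in %d / %d cells\n",
              sum(abs(x$nes) > 1.96), length(x$nes)))
  invisible(x)
}

#' @export
summary.netact_activity <- function(object, ...) {
  top <- order(-abs(object$nes))[seq_len(min(10L, length(object$nes)))]
  idx <- arrayInd(top, dim(object$nes))
  data.frame(regulator = rownames(object$nes)[idx[, 1]],
             signature = colnames(object$nes)[idx[, 2]],
             nes = object$nes[top], p = object$p[top],
             n_targets = object$n_targets[idx[, 1]],
             row.names = NULL)
}

#' @export
as.matrix.netact_activity <- function(x, ...) x$nes

#' @export
plot.netact_activity <- function(x, ...) {
  stats::heatmap(x$nes, scale = "none",
                 col = grDevices::hcl.colors(64, "Blue-Red"), ...)
  invisible(x)
}

#' Shadow-regulon (pleiotropy) adjustment
#'
#' Regulons overlap, so a strongly responding regulator can drag a
#' target-sharing "shadow" regulon into apparent significance. For every
#' signature and every ordered pair of significant regulators
#' (|NES| >= 1.96) sharing at least \code{overlap_min} targets, the
#' first regulator's ES is recomputed on its unique (non-shared) targets
#' with analytic calibration; if that unique-target NES loses significance,
#' its NES is shrunk toward the unique-target NES with weight
#' \code{penalty / (penalty + n_shared)}. The adjustment never flips a
#' sign (shrinkage is truncated at zero), and p-values are recomputed from
#' the adjusted NES.
#'
#' @param activity a \code{netact_activity} from \code{infer_activity}.
#' @param net the interactome it was fitted with.
#' @param overlap_min minimum shared targets for a pair to be examined
#'   (default 10).
#' @param penalty shrinkage half-weight in shared-target units (default
#'   20): the fewer shared targets, the milder the correction.
#' @param sig_cut significance threshold on |NES| (default 1.96).
#' @return the adjusted \code{netact_activity}.
#' @export
pleiotropy_adjust <- function(activity, net, overlap_min = 10, penalty = 20,
                              sig_cut = 1.96) {
  stopifnot(inherits(activity, "netact_activity"),
            inherits(net, "netact_interactome"))
  regs <- intersect(rownames(activity$nes), names(net))
  tr <- activity$transform
  targets <- lapply(net[regs], `[[`, "targets")
  nes <- activity$nes
  unique_nes <- function(r, other, col) {
    reg <- net[[r]]
    keep <- !(reg$targets %in% targets[[other]]) &
      reg$targets %in% rownames(tr$t2)
    if (!any(keep)) return(0)
    tg <- reg$targets[keep]
    w <- reg$weight[keep]
    m <- reg$mode[keep]
    w <- w / sum(w)
    es <- sum(w * (m * tr$t2[tg, col] + (1 - abs(m)) * tr$t1[tg, col]))
    es / sqrt(sum(w^2))
  }
  for (col in seq_len(ncol(nes))) {
    v <- nes[regs, col]
    sig <- regs[!is.na(v) & abs(v) >= sig_cut]
    if (length(sig) < 2L) next
    adjusted <- nes[, col]
    for (r in sig) {
      cand <- nes[r, col]
      for (o in setdiff(sig, r)) {
        n_shared <- length(intersect(targets[[r]], targets[[o]]))
        if (n_shared < overlap_min) next
        nu <- unique_nes(r, o, col)
        if (abs(nu) >= sig_cut) next  # unique targets carry the signal
        lambda <- penalty / (penalty + n_shared)
        val <- (1 - lambda) * nes[r, col] + lambda * nu
        if (val * nes[r, col] < 0) val <- 0  # never flip sign
        if (abs(val) < abs(cand)) cand <- val
      }
      adjusted[r] <- cand
    }
    nes[, col] <- adjusted
  }
  activity$nes <- nes
  activity$p <- 2 * stats::pnorm(-abs(nes))
  activity$pleiotropy <- list(overlap_min = overlap_min, penalty = penalty,
                              sig_cut = sig_cut)
  activity
}

#' Integrate activity matrices from several networks
#'
#' Cell-wise signed magnitude-weighted average over the networks where the
#' cell exists: \code{s* = sum_k s_k |s_k| / sum_k |s_k|} (0 when all
#' contributions are 0), so stronger calls dominate and
#' \code{|s*| <= max_k |s_k|} always. Cells tested in only one network pass
#' through unchanged.
#'
#' @param matrices non-empty list of \code{netact_activity} objects (NES on
#'   a common z-like scale).
#' @return object of class \code{"netact_integrated"}: list with the
#'   integrated \code{nes} matrix over the union of regulators and
#'   signatures, \code{p} (two-sided normal tail of the integrated score),
#'   \code{n_networks} (per-cell contributing count) and \code{networks}.
#' @export
integrate_networks <- function(matrices) {
  .check(is.list(matrices) && length(matrices) >= 1L,
         "need >= 1 activity matrix")
  stopifnot(all(vapply(matrices, inherits, logical(1), "netact_activity")))
  regs <- unique(unlist(lapply(matrices, function(m) rownames(m$nes))))
  perts <- unique(unlist(lapply(matrices, function(m) colnames(m$nes))))
  num <- den <- cnt <- matrix(0, length(regs), length(perts),
                              dimnames = list(regs, perts))
  for (m in matrices) {
    r <- rownames(m$nes); p <- colnames(m$nes)
    s <- m$nes
    num[r, p] <- num[r, p] + s * abs(s)
    den[r, p] <- den[r, p] + abs(s)
    cnt[r, p] <- cnt[r, p] + 1L
  }
  nes <- ifelse(den > 0, num / pmax(den, .Machine$double.xmin), 0)
  nes[cnt == 0] <- NA_real_
  structure(list(nes = nes, p = 2 * stats::pnorm(-abs(nes)),
                 n_networks = cnt,
                 networks = vapply(matrices, function(m) m$network,
                                   character(1))),
            class = "netact_integrated")
}

#' @export
print.netact_integrated <- function(x, ...) {
  cat(sprintf("Integrated activity over %d network(s) [%s]: %d regulators x %d signatures\n",
              length(x$networks), paste(x$networks, collapse = ", "),
              nrow(x$nes), ncol(x$nes)))
  invisible(x)
}

#' @export
as.matrix.netact_integrated <- function(x, ...) x$nes
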