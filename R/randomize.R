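#' Degree-preserving randomization of an interactome
#'
#' Rewires approximately a given fraction of regulator->target edges by
#' repeated double-edge swaps on the bipartite regulator/target multigraph:
#' two edges (r1, t1), (r2, t2) are replaced by (r1, t2), (r2, t1). Every
#' regulator keeps its out-degree and every target its in-degree exactly;
#' modes and weights travel with the regulator-side stub (r1 keeps its mode/
#' weight, now pointing at t2). Swaps that would create a duplicate edge or
#' a self-loop are rejected. Used to degrade a network controllably while
#' holding its degree structure fixed.
#'
#' @param x a \code{netact_interactome}.
#' @param fraction target fraction of edges to rewire, in \code{[0, 1]}.
#' @param seed integer seed; output is deterministic given the seed.
#' @param swap_factor attempted swaps = \code{ceiling(fraction * n_edges *
#'   swap_factor)} (default 3) so the realized rewired fraction approaches
#'   the request.
#' @return a \code{netact_interactome} with attribute
#'   \code{realized_fraction}: the fraction of original edges no longer
#'   present.
#' @export
randomize_interactome <- function(x, fraction, seed, swap_factor = 3) {
  stopifnot(inherits(x, "netact_interactome"))
  .check(.is_prob(fraction), "fraction must be in [0, 1]")
  edges <- interactome_edges(x)
  n <- nrow(edges)
  if (fraction == 0 || n < 2L) {
    out <- x
    attr(out, "realized_fraction") <- 0
    return(out)
  }
  set.seed(as.integer(seed))
  reg <- edges$regulator; tgt <- edges$target
  orig_tgt <- tgt
  key <- function(r, t) paste(r, t, sep = "\r")
  present <- new.env(hash = TRUE, parent = emptyenv())
  for (k in key(reg, tgt)) assign(k, TRUE, envir = present)
  rewired <- logical(n)
  n_target <- ceiling(fraction * n)
  attempts <- ceiling(fraction * n * swap_factor)
  for (it in seq_len(attempts)) {
    if (sum(rewired) >= n_target) break
    # draw the first edge among still-original ones so the realized
    # rewired fraction converges to the request
    intact <- which(!rewired)
    i <- intact[[sample.int(length(intact), 1L)]]
    j <- sample.int(n, 1L)
    if (i == j) next
    r1 <- reg[[i]]; t1 <- tgt[[i]]; r2 <- reg[[j]]; t2 <- tgt[[j]]
    if (t1 == t2 || r1 == t2 || r2 == t1) next
    k1 <- key(r1, t2); k2 <- key(r2, t1)
    if (exists(k1, envir = present, inherits = FALSE) ||
        exists(k2, envir = present, inherits = FALSE)) next
    rm(list = c(key(r1, t1), key(r2, t2)), envir = present)
    assign(k1, TRUE, envir = present); assign(k2, TRUE, envir = present)
    tgt[[i]] <- t2; tgt[[j]] <- t1
    rewired[[i]] <- tgt[[i]] != orig_tgt[[i]]
    rewired[[j]] <- tgt[[j]] != orig_tgt[[j]]
  }
  src <- if (length(x)) x[[1]]$source else "synthetic"
  df <- data.frame(regulator = reg, target = tgt, mode = edges$mode,
                   weight = edges$weight, stringsAsFactors = FALSE)
  regulons <- lapply(split(df, df$regulator), function(e)
    regulon(e$regulator[[1]], e$target, mode = e$mode, weight = e$weight,
            source = src))
  regulons <- regulons[names(x)]
  out <- interactome(regulons,
                     name = sprintf("%s_rand%.2f", attr(x, "name"), fraction),
                     context = attr(x, "context"))
  orig <- key(edges$regulator, edges$target)
  attr(out, "realized_fraction") <- mean(!(key(reg, tgt) %in% orig))
  out
}
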