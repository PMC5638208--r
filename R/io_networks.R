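#' Read an ARACNE adjacency file
#'
#' Supports the classic \code{.adj} dialect (one regulator per line:
#' \code{regulator<TAB>target<TAB>MI<TAB>target<TAB>MI...}, \code{>}-prefixed
#' header lines ignored) and a flat three-column TSV
#' (\code{regulator, target, MI}). Duplicate (regulator, target) pairs keep
#' the maximum MI with a warning; self-loops are dropped.
#'
#' @param path file path.
#' @param dialect \code{"adj"} or \code{"three_column"}.
#' @return data.frame with columns \code{regulator}, \code{target},
#'   \code{mi}.
#' @export
read_aracne_adjacency <- function(path, dialect = c("adj", "three_column")) {
  dialect <- match.arg(dialect)
  .check(file.exists(path), "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines) & !startsWith(lines, ">")]
  if (length(lines) == 0L) {
    .warnf("empty ARACNE file: %s", path)
    return(data.frame(regulator = character(), target = character(),
                      mi = numeric(), stringsAsFactors = FALSE))
  }
  parse_mi <- function(x, lineno) {
    mi <- suppressWarnings(as.numeric(x))
    if (anyNA(mi)) .fail("parse error at line %d of %s: non-numeric MI",
                         lineno, path)
    if (any(mi < 0)) .fail("negative MI at line %d of %s", lineno, path)
    mi
  }
  if (dialect == "adj") {
    rows <- lapply(seq_along(lines), function(i) {
      f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
      if (length(f) < 3L || length(f) %% 2L == 0L)
        .fail("parse error at line %d of %s: expected regulator + target/MI pairs",
              i, path)
      idx <- seq(2L, length(f), by = 2L)
      data.frame(regulator = f[[1]], target = f[idx],
                 mi = parse_mi(f[idx + 1L], i), stringsAsFactors = FALSE)
    })
    edges <- do.call(rbind, rows)
  } else {
    rows <- lapply(seq_along(lines), function(i) {
      f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
      if (length(f) != 3L)
        .fail("parse error at line %d of %s: expected 3 columns", i, path)
      data.frame(regulator = f[[1]], target = f[[2]],
                 mi = parse_mi(f[[3]], i), stringsAsFactors = FALSE)
    })
    edges <- do.call(rbind, rows)
  }
  self <- edges$regulator == edges$target
  if (any(self)) {
    .warnf("%d self-loop(s) removed from %s", sum(self), path)
    edges <- edges[!self, , drop = FALSE]
  }
  key <- paste(edges$regulator, edges$target, sep = "\r")
  if (anyDuplicated(key)) {
    .warnf("%d duplicate edge(s) in %s: keeping max MI",
           sum(duplicated(key)), path)
    edges <- edges[order(key, -edges$mi), , drop = FALSE]
    edges <- edges[!duplicated(paste(edges$regulator, edges$target,
                                     sep = "\r")), , drop = FALSE]
  }
  rownames(edges) <- NULL
  edges
}

#' Build regulons from an edge list and an expression matrix
#'
#' Turns a (regulator, target, MI) edge list into an interactome. The mode of
#' regulation of each edge is estimated as the Spearman rank correlation of
#' regulator and target expression across samples; the edge weight is its MI
#' max-normalized within the regulon.
#'
#' @param edges data.frame as returned by \code{\link{read_aracne_adjacency}}.
#' @param expression numeric matrix genes x samples (>= 3 samples).
#' @param min_targets regulons with fewer surviving targets are dropped with
#'   a warning (default 10).
#' @param name,context labels for the interactome.
#' @return a \code{netact_interactome} with source \code{"aracne"}.
#' @export
regulons_from_edges <- function(edges, expression, min_targets = 10,
                                name = "aracne", context = "generic") {
  .check(is.matrix(expression) && ncol(expression) >= 3L,
         "expression must be a matrix with >= 3 samples")
  genes <- rownames(expression)
  miss_r <- !(edges$regulator %in% genes)
  miss_t <- !(edges$target %in% genes)
  drop <- miss_r | miss_t
  if (any(drop)) {
    .warnf("%d edge(s) skipped: gene absent from expression matrix",
           sum(drop))
    edges <- edges[!drop, , drop = FALSE]
  }
  ranks <- t(apply(expression, 1L, rank))
  rvar <- apply(ranks, 1L, stats::var)
  regs <- split(edges, edges$regulator)
  regulons <- lapply(regs, function(e) {
    reg <- e$regulator[[1]]
    mode <- vapply(seq_len(nrow(e)), function(i) {
      tg <- e$target[[i]]
      if (rvar[reg] == 0 || rvar[tg] == 0) {
        .warnf("zero-variance gene in pair (%s, %s): mode set to 0", reg, tg)
        return(0)
      }
      stats::cor(ranks[reg, ], ranks[tg, ])
    }, numeric(1))
    mode <- pmin(1, pmax(-1, mode))
    if (nrow(e) < min_targets) return(NULL)
    regulon(reg, e$target, mode = mode, weight = e$mi, source = "aracne")
  })
  n_drop <- sum(vapply(regulons, is.null, logical(1)))
  if (n_drop > 0)
    .warnf("%d regulon(s) dropped (< %d targets)", n_drop, min_targets)
  interactome(regulons, name = name, context = context)
}

#' Read a STRING-style protein-link table
#'
#' Keeps links with combined score strictly greater than \code{min_score}
#' and converts each undirected link into two directed regulon memberships
#' (each endpoint becomes a member of the other's regulon). The direction of
#' regulation is unknown for protein-protein links, so all modes are 0; the
#' weight is the combined score. Scores on a 0-1000 scale are auto-detected
#' (any value > 1) and divided by 1000.
#'
#' @param path TSV with columns protein1, protein2, combined_score (header
#'   optional; whitespace- or tab-separated).
#' @param min_score strict lower bound on the kept combined score
#'   (default 0.7).
#' @param min_targets regulons with fewer members are dropped (default 10;
#'   set to 1 to keep all).
#' @param name,context labels.
#' @return a \code{netact_interactome} with source \code{"string"}.
#' @export
read_string_links <- function(path, min_score = 0.7, min_targets = 10,
                              name = "string", context = "generic") {
  .check(file.exists(path), "file not found: %s", path)
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           stringsAsFactors = FALSE)
  if (nrow(tab) > 0 && is.na(suppressWarnings(as.numeric(tab[1, 3]))))
    tab <- tab[-1, , drop = FALSE]  # header row
  .check(ncol(tab) >= 3L, "expected >= 3 columns (protein1 protein2 score)")
  p1 <- as.character(tab[[1]]); p2 <- as.character(tab[[2]])
  score <- suppressWarnings(as.numeric(tab[[3]]))
  .check(!anyNA(score), "non-numeric combined_score in %s", path)
  if (any(score > 1)) score <- score / 1000
  .check(all(score >= 0 & score <= 1),
         "combined score outside [0,1] after rescaling in %s", path)
  keep <- score > min_score
  p1 <- p1[keep]; p2 <- p2[keep]; score <- score[keep]
  # undirected -> both directions
  reg <- c(p1, p2); tgt <- c(p2, p1); w <- c(score, score)
  ok <- reg != tgt
  df <- unique(data.frame(reg = reg[ok], tgt = tgt[ok], w = w[ok],
                          stringsAsFactors = FALSE))
  regulons <- lapply(split(df, df$reg), function(e) {
    if (nrow(e) < min_targets) return(NULL)
    e <- e[!duplicated(e$tgt), , drop = FALSE]
    regulon(e$reg[[1]], e$tgt, mode = rep(0, nrow(e)), weight = e$w,
            source = "string")
  })
  interactome(regulons, name = name, context = context)
}

#' Read TF-target gene sets in GMT format
#'
#' Each GMT record is \code{TF<TAB>description<TAB>target...}; repeated
#' records for the same TF are merged by target union (all identified
#' targets across experiments form the regulon). Weights are 1. Modes are
#' the Spearman correlation of TF and target expression when an expression
#' matrix is supplied, 0 otherwise.
#'
#' @param path GMT file.
#' @param expression optional genes x samples matrix for mode estimation.
#' @param min_targets drop smaller regulons (default 10; use 1 to keep all).
#' @param name,context labels.
#' @return a \code{netact_interactome} with source \code{"chea"}.
#' @export
read_chea_sets <- function(path, expression = NULL, min_targets = 10,
                           name = "chea", context = "generic") {
  .check(file.exists(path), "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L)
      .fail("parse error at line %d of %s: expected TF, description, targets",
            i, path)
    tf <- f[[1]]; targets <- unique(f[-(1:2)])
    targets <- setdiff(targets[nzchar(targets)], tf)
    if (length(targets) == 0L) {
      .warnf("record for '%s' at line %d has no targets: skipped", tf, i)
      next
    }
    if (!is.null(sets[[tf]])) {
      .log("merging repeated record for TF '%s' (target union)", tf)
      sets[[tf]] <- union(sets[[tf]], targets)
    } else sets[[tf]] <- targets
  }
  if (!is.null(expression)) {
    ranks <- t(apply(expression, 1L, rank))
    rvar <- apply(ranks, 1L, stats::var)
  }
  regulons <- lapply(names(sets), function(tf) {
    targets <- sets[[tf]]
    if (length(targets) < min_targets) return(NULL)
    mode <- rep(0, length(targets))
    if (!is.null(expression) && tf %in% rownames(expression)) {
      present <- targets %in% rownames(expression)
      mode[present] <- vapply(targets[present], function(tg) {
        if (rvar[tf] == 0 || rvar[tg] == 0) 0
        else stats::cor(ranks[tf, ], ranks[tg, ])
      }, numeric(1))
      mode <- pmin(1, pmax(-1, mode))
    }
    regulon(tf, targets, mode = mode, weight = rep(1, length(targets)),
            source = "chea")
  })
  interactome(regulons, name = name, context = context)
}

#' Build regulons from gene knock-down signatures
#'
#' For each silenced gene g, the regulon is the set of genes responding to
#' its knock-down: genes with |z| >= \code{z_min} in the KD signature of g
#' (excluding g itself), capped at \code{max_targets} by decreasing |z|.
#' A gene whose expression falls when g is silenced is positively regulated
#' by g, so mode = -sign(z); weight = |z| max-normalized.
#'
#' @param kd_signatures named list: silenced gene -> named numeric signature
#'   (z-score scale).
#' @param z_min inclusion threshold on |z| (default 3).
#' @param max_targets regulon size cap (default 400).
#' @param min_targets drop regulons with fewer surviving targets
#'   (default 10).
#' @param name,context labels.
#' @return a \code{netact_interactome} with source \code{"kd"}.
#' @export
kd_regulons <- function(kd_signatures, z_min = 3.0, max_targets = 400,
                        min_targets = 10, name = "kd", context = "generic") {
  .check(is.list(kd_signatures) && !is.null(names(kd_signatures)),
         "kd_signatures must be a named list (silenced gene -> signature)")
  regulons <- lapply(names(kd_signatures), function(g) {
    z <- kd_signatures[[g]]
    .check(g %in% names(z), "silenced gene '%s' absent from its signature", g)
    z <- z[names(z) != g]
    z <- z[abs(z) >= z_min]
    if (length(z) > max_targets)
      z <- z[order(-abs(z))[seq_len(max_targets)]]
    if (length(z) < min_targets) {
      .warnf("KD regulon for '%s' dropped (%d < %d targets)", g,
             length(z), min_targets)
      return(NULL)
    }
    regulon(g, names(z), mode = -sign(z), weight = abs(z), source = "kd")
  })
  interactome(regulons, name = name, context = context)
}

#' Serialize / read an interactome as 4-column TSV
#'
#' The native on-disk format: header comment lines \code{# name=}/
#' \code{# context=}/\code{# source=} followed by a header row and one
#' (regulator, target, mode, weight) row per interaction, written at full
#' precision so that \code{read_regulons(write_regulons(x))} reproduces
#' \code{x}.
#'
#' @param x a \code{netact_interactome}.
#' @param path output/input file path.
#' @return \code{write_regulons}: the path, invisibly. \code{read_regulons}:
#'   a \code{netact_interactome}.
#' @export
write_regulons <- function(x, path) {
  stopifnot(inherits(x, "netact_interactome"))
  src <- if (length(x)) x[[1]]$source else "synthetic"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# name=%s", attr(x, "name")),
               sprintf("# context=%s", attr(x, "context")),
               sprintf("# source=%s", src),
               "regulator\ttarget\tmode\tweight"), con)
  edges <- interactome_edges(x)
  if (!is.null(edges))
    writeLines(sprintf("%s\t%s\t%.15g\t%.15g", edges$regulator, edges$target,
                       edges$mode, edges$weight), con)
  invisible(path)
}

#' @rdname write_regulons
#' @export
read_regulons <- function(path) {
  .check(file.exists(path), "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  meta <- lines[startsWith(lines, "#")]
  get_meta <- function(key, default) {
    m <- grep(sprintf("^# %s=", key), meta, value = TRUE)
    if (length(m)) sub(sprintf("^# %s=", key), "", m[[1]]) else default
  }
  name <- get_meta("name", "interactome")
  context <- get_meta("context", "generic")
  source <- get_meta("source", "synthetic")
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body)) {
    hdr <- strsplit(body[[1]], "\t", fixed = TRUE)[[1]]
    .check(identical(hdr, c("regulator", "target", "mode", "weight")),
           "missing or malformed header in %s", path)
    body <- body[-1]
  }
  if (length(body) == 0L) {
    .warnf("no interactions in %s: empty interactome", path)
    return(interactome(list(), name = name, context = context))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 4L)
  if (length(bad)) .fail("parse error in %s: row %d lacks 4 columns",
                         path, bad[[1]])
  df <- data.frame(regulator = vapply(f, `[[`, "", 1L),
                   target = vapply(f, `[[`, "", 2L),
                   mode = as.numeric(vapply(f, `[[`, "", 3L)),
                   weight = as.numeric(vapply(f, `[[`, "", 4L)),
                   stringsAsFactors = FALSE)
  .check(!anyNA(df$mode) && !anyNA(df$weight), "non-numeric mode/weight in %s",
         path)
  .check(all(abs(df$mode) <= 1), "mode outside [-1, 1] in %s", path)
  .check(all(df$weight >= 0), "negative weight in %s", path)
  regulons <- lapply(split(df, df$regulator), function(e)
    regulon(e$regulator[[1]], e$target, mode = e$mode, weight = e$weight,
            source = source))
  # preserve original regulator order
  regulons <- regulons[unique(df$regulator)]
  interactome(regulons, name = name, context = context)
}
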