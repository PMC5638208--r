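#' Construct a single regulon
#'
#' A regulon is the set of (direct or indirect) transcriptional targets of a
#' regulatory protein, each carrying a mode of regulation (MoR) and an
#' interaction-confidence weight. The MoR is a signed confidence in
#' \code{[-1, 1]}: its sign says whether the regulator activates (+) or
#' represses (-) the target, its magnitude how confident that sign is
#' (0 = direction unknown). Weights are non-negative interaction confidences
#' and are max-normalized to 1 within the regulon at construction.
#'
#' @param regulator character scalar, regulator gene identifier.
#' @param targets character vector of target gene identifiers (unique, and
#'   not containing the regulator itself).
#' @param mode numeric vector in \code{[-1, 1]}, one per target.
#' @param weight non-negative numeric vector, one per target; rescaled so the
#'   maximum is 1.
#' @param source one of \code{"aracne"}, \code{"chea"}, \code{"string"},
#'   \code{"kd"}, \code{"synthetic"}.
#' @return An object of class \code{"netact_regulon"}: a list with elements
#'   \code{regulator}, \code{targets}, \code{mode}, \code{weight},
#'   \code{source}.
#' @export
regulon <- function(regulator, targets, mode = rep(0, length(targets)),
                    weight = rep(1, length(targets)),
                    source = c("synthetic", "aracne", "chea", "string", "kd")) {
  source <- match.arg(source)
  .check(is.character(regulator) && length(regulator) == 1L,
         "regulator must be a single gene id")
  targets <- as.character(targets)
  .check(length(targets) >= 1L, "regulon '%s' is empty", regulator)
  .check(!anyDuplicated(targets), "duplicate targets in regulon '%s'",
         regulator)
  .check(!regulator %in% targets,
         "regulon '%s' contains its own regulator as a target", regulator)
  mode <- as.numeric(mode); weight <- as.numeric(weight)
  .check(length(mode) == length(targets) && length(weight) == length(targets),
         "mode/weight length mismatch in regulon '%s'", regulator)
  .check(all(is.finite(mode)) && all(abs(mode) <= 1),
         "regulon '%s': mode values must lie in [-1, 1]", regulator)
  .check(all(is.finite(weight)) && all(weight >= 0),
         "regulon '%s': weights must be non-negative", regulator)
  wmax <- max(weight)
  if (wmax > 0) weight <- weight / wmax else weight <- rep(1, length(weight))
  structure(list(regulator = regulator, targets = targets,
                 mode = mode, weight = weight, source = source),
            class = "netact_regulon")
}

#' @export
print.netact_regulon <- function(x, ...) {
  cat(sprintf("Regulon %s [%s]: %d targets (%d activated, %d repressed, %d unknown)\n",
              x$regulator, x$source, length(x$targets),
              sum(x$mode > 0), sum(x$mode < 0), sum(x$mode == 0)))
  invisible(x)
}

#' Assemble an interactome from regulons
#'
#' An interactome is a named collection of regulons from one source/context
#' (one regulatory-network model of a cellular context).
#'
#' @param regulons list of \code{\link{regulon}} objects with distinct
#'   regulators.
#' @param name short label for the network.
#' @param context tissue / cell-line label.
#' @return Object of class \code{"netact_interactome"}: a list of regulons
#'   keyed by regulator id with attributes \code{name}, \code{context} and
#'   \code{gene_universe} (regulators plus all targets).
#' @export
interactome <- function(regulons, name = "interactome", context = "generic") {
  .check(is.list(regulons), "regulons must be a list")
  regulons <- Filter(Negate(is.null), regulons)
  ids <- vapply(regulons, function(r) r$regulator, character(1))
  .check(!anyDuplicated(ids), "duplicate regulator ids in interactome")
  names(regulons) <- ids
  universe <- unique(c(ids, unlist(lapply(regulons, `[[`, "targets"),
                                   use.names = FALSE)))
  structure(regulons, class = "netact_interactome",
            name = name, context = context, gene_universe = universe)
}

#' @export
print.netact_interactome <- function(x, ...) {
  cnt <- interactome_counts(x)
  cat(sprintf("Interactome '%s' (context: %s)\n", attr(x, "name"),
              attr(x, "context")))
  cat(sprintf("  %d regulators, %d target genes, %d interactions\n",
              cnt["regulators"], cnt["targets"], cnt["interactions"]))
  invisible(x)
}

#' @export
summary.netact_interactome <- function(object, ...) {
  sizes <- vapply(object, function(r) length(r$targets), integer(1))
  out <- c(as.list(interactome_counts(object)),
           list(regulon_size = summary(sizes)))
  class(out) <- "summary.netact_interactome"
  out
}

#' @export
print.summary.netact_interactome <- function(x, ...) {
  cat(sprintf("%d regulators, %d target genes, %d interactions\n",
              x$regulators, x$targets, x$interactions))
  cat("Regulon sizes:\n"); print(x$regulon_size)
  invisible(x)
}

#' Regulator / target / interaction counts of an interactome
#'
#' @param x a \code{netact_interactome}.
#' @return named integer vector with \code{regulators}, \code{targets}
#'   (distinct target genes) and \code{interactions} (edges).
#' @export
interactome_counts <- function(x) {
  stopifnot(inherits(x, "netact_interactome"))
  tg <- unlist(lapply(x, `[[`, "targets"), use.names = FALSE)
  c(regulators = length(x), targets = length(unique(tg)),
    interactions = length(tg))
}

#' Flatten an interactome to an edge table
#'
#' @param x a \code{netact_interactome}.
#' @return data.frame with columns regulator, target, mode, weight.
#' @export
interactome_edges <- function(x) {
  stopifnot(inherits(x, "netact_interactome"))
  do.call(rbind, lapply(unname(x), function(r)
    data.frame(regulator = r$regulator, target = r$targets,
               mode = r$mode, weight = r$weight,
               stringsAsFactors = FALSE)))
}
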