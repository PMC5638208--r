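#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cor.test ecdf ks.test mad median pnorm pt qnorm
#'   quantile rnorm runif sd setNames t.test wilcox.test p.adjust fisher.test
#' @importFrom utils read.delim write.table head tail
NULL

# Validation helper: stop with a consistent message prefix.
.fail <- function(...) stop(sprintf(...), call. = FALSE)

.check <- function(cond, ...) if (!isTRUE(cond)) .fail(...)

# Logging goes to stderr so results stay pipeable on stdout.
.log <- function(..., level = "INFO") {
  message(sprintf("[%s] %s", level, sprintf(...)))
}

.warnf <- function(...) warning(sprintf(...), call. = FALSE)

.is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == floor(x) && x >= 0

.is_prob <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x <= 1

# Deterministic per-task seed derived from a user seed; kept below 2^31.
.subseed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 2011L + 7919L * as.integer(k) %% 1000003L
}
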