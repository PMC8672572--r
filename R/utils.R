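#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor median p.adjust pnorm runif rnorm rlnorm rexp rpois
#'   rbinom sd t.test quantile uniroot complete.cases setNames phyper ks.test
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic substream seed for item i under a master seed; stays within
# 32-bit integer range so set.seed() accepts it on any platform.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 69621) %% 2147483587)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == floor(x)
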