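#' @importFrom rlang %||% abort warn inform .data
#' @importFrom stats median mad quantile rnorm rbinom rlnorm rgamma runif
#'   setNames complete.cases
#' @importFrom utils head
NULL

# Derive a stream of child seeds from one user-facing seed so that per-site /
# per-chain draws are reproducible independently of evaluation order.
# Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 8191 + 11) %% 2147483629L)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Treatment levels used throughout the package
#' @keywords internal
TREATMENTS <- c("Control", "NPK")
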