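#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median rnorm rlnorm runif rbinom prcomp sd cor
#' @importFrom utils head
NULL

# Wide abundance tibbles have `sample_id` first, one column per feature.
# These helpers move between that representation and a plain numeric matrix.
abund_mat <- function(x) {
  stopifnot(is.data.frame(x), "sample_id" %in% names(x))
  m <- as.matrix(x[setdiff(names(x), "sample_id")])
  storage.mode(m) <- "double"
  rownames(m) <- x$sample_id
  m
}

mat_abund <- function(m) {
  out <- as_tibble(m, rownames = "sample_id")
  out
}

assert_scalar_count <- function(x, name, allow_zero = FALSE) {
  lo <- if (allow_zero) 0 else 1
  if (length(x) != 1 || is.na(x) || x < lo || x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, lo),
          class = "necmgs_config_error")
  }
  invisible(as.integer(x))
}

config_error <- function(msg) abort(msg, class = "necmgs_config_error")
input_error <- function(msg) abort(msg, class = "necmgs_input_error")

# Derive a stream-specific seed from a master seed so that independent
# stages do not share random streams; kept below 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 7919L * as.integer(offset)) %% 2147483629L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
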