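#' @keywords internal
"_PACKAGE"

#' @importFrom stats runif rnorm rbinom sd
#' @importFrom utils write.table head
#' @importFrom Rcpp evalCpp
#' @useDynLib gefdriver, .registration = TRUE
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Locale-independent lexicographic sort, so node order is reproducible
# across platforms.
sort_symbols <- function(x) sort(unique(as.character(x)), method = "radix")

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(ok, fmt, ...) if (!isTRUE(ok)) stop_(fmt, ...)

# Derive a 32-bit substream seed from a master seed and a stream index.
# Values stay below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + k * 10007) %% 2147483629 + 1)
}

# Glorot (Xavier) uniform initialization for a fan_in x fan_out matrix.
glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

relu <- function(x) x * (x > 0)
elu <- function(x) x * (x > 0) + (expm1(pmin(x, 0)))
elu_grad <- function(x) exp(pmin(x, 0))          # 1 for x > 0, exp(x) below
leaky_relu <- function(x, slope = 0.2) {
  neg <- x < 0
  x[neg] <- slope * x[neg]
  x
}
leaky_relu_grad <- function(x, slope) slope + (1 - slope) * (x > 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

identity_fn <- function(x) x
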