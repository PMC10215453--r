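# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero toward positive infinity ("round half up")
#'
#' Plain `round()` uses banker's rounding; gray-value quantization here
#' follows the half-up convention so that e.g. 127.5 becomes 128.
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_up <- function(x) floor(x + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# quantize continuous gray values to integer gray8 for classification
as_gray8_int <- function(x) clamp(round_half_up(x), 0, 255)

vnorm <- function(x) sqrt(sum(x^2))

vnormalize <- function(x) {
  n <- vnorm(x)
  if (n < .Machine$double.eps * 10) stop("cannot normalize a zero vector")
  x / n
}

# cross product of two 3-vectors (components in consistent order)
vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

is_point3 <- function(p) is.numeric(p) && length(p) == 3 && all(is.finite(p))

stop_if_not_point3 <- function(p, name) {
  if (!is_point3(p)) stop(sprintf("'%s' must be a finite numeric 3-vector", name))
}
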