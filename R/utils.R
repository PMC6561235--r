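#' Heaviside step function
#'
#' The unit step used for threshold fitting: 0 below zero, 1/2 at zero,
#' 1 above zero.
#'
#' @param x Numeric vector.
#' @return Numeric vector of the same length with values in \{0, 1/2, 1\}.
#' @examples
#' heaviside(c(-2, 0, 3))
#' @export
heaviside <- function(x) {
  stopifnot(is.numeric(x))
  out <- numeric(length(x))
  out[x > 0] <- 1
  out[x == 0] <- 0.5
  out[is.na(x)] <- NA_real_
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up false discovery rate control: sort the p-values
#' ascending, scale the i-th smallest by m/i, enforce monotonicity from the
#' largest rank downwards, cap at 1, and restore the input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04))
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    abort("`p` must contain p-values in [0, 1] with no missing values.")
  }
  m <- length(p)
  ord <- order(p)
  scaled <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# internal: assert a scalar condition with a readable message
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}
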