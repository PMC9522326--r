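# The class I/II/III rationale for assigning a single conformity coefficient
# d(x) per sample configuration.
#
# With r variants present in the sample, the average representation of a
# present variant is n/r. Counts above average (class II) receive a share of
# +d(x), counts below average (class III) a share of -d(x), and counts that
# are absent, exactly average, or fixed (class I) receive nothing. The shares
# g_i are proportional to x_i within class II and to 1/x_i within class III,
# so rarer below-average variants are pushed hardest.

#' Partition a sample configuration into conformity classes I/II/III
#'
#' @param x A sample configuration (nonnegative integer counts).
#' @param n Total sample size; defaults to `sum(x)`.
#'
#' @return An object of class `"class_partition"`: a list with `r` (number of
#'   variants present), `threshold` (`n / r`, the average representation,
#'   not necessarily an integer), and integer index vectors `I`, `II`, `III`.
#'   Class I holds counts in `{0, n/r, n}`, class II counts strictly above
#'   `n/r`, class III counts strictly between 0 and `n/r`. Class II is empty
#'   if and only if class III is empty.
#'
#' @examples
#' classify_configuration(c(3, 1, 0))            # n = 4: II = 1, III = 2, I = 3
#' classify_configuration(c(25, 20, 20, 10, 10, 10, 5, 0, 0, 0))
#' @export
classify_configuration <- function(x, n = sum(x)) {
  x <- check_configuration(x, n = n)
  if (n < 1L) {
    stop("`x` must contain at least one role model", call. = FALSE)
  }
  r <- sum(x > 0L)
  thr <- n / r
  idx <- seq_along(x)
  cls_II <- idx[x > thr & x < n]
  cls_III <- idx[x > 0L & x < thr]
  cls_I <- setdiff(idx, c(cls_II, cls_III))
  structure(
    list(x = x, n = as.integer(n), r = r, threshold = thr,
         I = cls_I, II = cls_II, III = cls_III),
    class = "class_partition"
  )
}

#' @export
print.class_partition <- function(x, ...) {
  cat("Sample configuration (", paste(x$x, collapse = ", "), "), n = ", x$n,
      "\n", sep = "")
  cat("  variants present r =", x$r, "; average representation n/r =",
      format(x$threshold), "\n")
  cat("  class I  (0, n/r or n):", paste(x$I, collapse = " "), "\n")
  cat("  class II (above avg):  ", paste(x$II, collapse = " "), "\n")
  cat("  class III (below avg): ", paste(x$III, collapse = " "), "\n")
  invisible(x)
}

#' Per-variant weights splitting a single coefficient d(x)
#'
#' Computes the weights `g_i(x)` that distribute one conformity coefficient
#' `d(x)` over the variants: `g_i = 0` in class I, `g_i = x_i / sum(x[II])`
#' in class II, and `g_i = -(1/x_i) / sum(1/x[III])` in class III. When both
#' classes are nonempty the class II weights sum to +1 and the class III
#' weights to -1, so `sum(g) = 0` and the induced coefficients
#' `D_i(x) = g_i(x) d(x)` sum to zero.
#'
#' @inheritParams classify_configuration
#' @return Numeric vector of weights, one per variant.
#' @examples
#' g_weights(c(2, 1, 0))  # (1, -1, 0): the single-coefficient n = 3 split
#' g_weights(c(2, 1, 1))  # (1, -1/2, -1/2)
#' @export
g_weights <- function(x, n = sum(x)) {
  cls <- classify_configuration(x, n = n)
  g <- numeric(length(cls$x))
  if (length(cls$II)) {
    g[cls$II] <- cls$x[cls$II] / sum(cls$x[cls$II])
    g[cls$III] <- -(1 / cls$x[cls$III]) / sum(1 / cls$x[cls$III])
  }
  g
}

#' Admissible range for the coefficient d(x) of one configuration
#'
#' The open interval of values of `d(x)` for which every adoption probability
#' `x_i/n + g_i(x) d(x)/n` stays in `[0, 1]`. The lower endpoint is
#' `-sum(x[II])` (the most-represented variant's probability reaches 0
#' first as anticonformity strengthens). The upper endpoint is the smaller
#' of two constraints: `sum(x[II]) * (n / max(x) - 1)` (the most-represented
#' variant's probability reaches 1) and
#' `min(x[III]^2) * sum(1 / x[III])` evaluated at the smallest class III
#' count (the rarest below-average variant's probability reaches 0, since
#' class III weights are inversely proportional to the counts). At every
#' configuration with a single class II member and a single class III
#' member -- which covers all the small-`n` named schemes -- the two upper
#' constraints coincide.
#'
#' @inheritParams classify_configuration
#' @return Numeric vector `c(lower, upper)`. When class II is empty the
#'   coefficient is inert (all weights vanish); the returned interval is
#'   `c(-Inf, Inf)` with attribute `inert = TRUE`.
#' @examples
#' d_bounds(c(3, 1, 0))  # (-3, 1)
#' d_bounds(c(2, 1, 0))  # (-2, 1)
#' d_bounds(c(2, 1, 1))  # (-2, 2)
#' @export
d_bounds <- function(x, n = sum(x)) {
  cls <- classify_configuration(x, n = n)
  if (!length(cls$II)) {
    return(structure(c(-Inf, Inf), inert = TRUE))
  }
  s2 <- sum(cls$x[cls$II])
  x3 <- cls$x[cls$III]
  upper_II <- s2 * (n / max(cls$x) - 1)
  upper_III <- min(x3)^2 * sum(1 / x3)
  structure(c(-s2, min(upper_II, upper_III)), inert = FALSE)
}

#' Tightest lower bound for a configuration-independent coefficient
#'
#' If a single constant `D` is used as `d(x)` for every sample configuration,
#' it must lie inside `d_bounds(x)` at every `x`. This returns the binding
#' (least negative) lower endpoint over all configurations of `n` into `m`
#' parts with nonempty class II. Anticonformity can be pushed further as `n`
#' grows: the bound is -2 at `n = 3` but -6 at `n = 15` (with `m = 3`).
#'
#' @inheritParams enumerate_configurations
#' @return A single number, the tightest lower bound.
#' @examples
#' uniform_d_lower_bound(3, 3)    # -2
#' uniform_d_lower_bound(15, 3)   # -6
#' @export
uniform_d_lower_bound <- function(n, m) {
  configs <- enumerate_configurations(n, m)
  lowers <- apply(configs, 1L, function(x) {
    b <- d_bounds(x, n = n)
    if (isTRUE(attr(b, "inert"))) -Inf else b[1L]
  })
  lowers <- lowers[is.finite(lowers)]
  if (!length(lowers)) {
    stop("no configuration of n = ", n, " into m = ", m,
         " parts has a nonempty class II", call. = FALSE)
  }
  max(lowers)
}
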