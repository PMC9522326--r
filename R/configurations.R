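# Role-model sample configurations and their multinomial probabilities.
#
# A sample configuration x = (x1, ..., xm) counts how many of the n sampled
# role models carry each of the m variants; a frequency vector p lies on the
# (m-1)-simplex. Both are plain numeric/integer vectors; configurations are
# handled in bulk as the rows of an integer matrix.

#' Enumerate all role-model sample configurations
#'
#' Lists every way a sample of `n` role models can be split among `m` variants,
#' i.e. all ordered compositions of `n` into `m` nonnegative parts. The number
#' of configurations is `choose(m - 1 + n, n)`.
#'
#' @param n Number of role models sampled by each offspring (positive integer).
#' @param m Number of trait variants (positive integer).
#'
#' @return An integer matrix with `m` columns; each row is one configuration.
#'   Rows are in lexicographic descending order, so `(n, 0, ..., 0)` comes
#'   first and `(0, ..., 0, n)` last. The order is deterministic and is the
#'   row order used by every scheme built for the same `(n, m)`.
#'
#' @examples
#' enumerate_configurations(3, 3)   # the 10 states for n = 3, m = 3
#' nrow(enumerate_configurations(4, 3)) == choose(6, 4)
#' @export
enumerate_configurations <- function(n, m) {
  n <- check_count(n, "n")
  m <- check_count(m, "m")
  rec <- function(n, m) {
    if (m == 1L) {
      return(matrix(n, nrow = 1L, ncol = 1L))
    }
    blocks <- lapply(seq.int(n, 0L), function(k) {
      cbind(k, rec(n - k, m - 1L))
    })
    do.call(rbind, blocks)
  }
  out <- rec(n, m)
  dimnames(out) <- NULL
  storage.mode(out) <- "integer"
  out
}

#' Multinomial probability of a sample configuration
#'
#' Probability of drawing the configuration `x` when `n` role models are
#' sampled independently from a population with variant frequencies `p`:
#' `n! / (x1! ... xm!) * p1^x1 * ... * pm^xm`, with the convention `0^0 = 1`
#' so that absent variants with zero count contribute a factor of 1.
#'
#' @param x Integer vector of counts (one sample configuration).
#' @param p Numeric frequency vector on the simplex, same length as `x`.
#'
#' @return A single probability.
#' @examples
#' multinomial_probability(c(1, 1, 1), c(1 / 3, 1 / 3, 1 / 3))  # 2/9
#' @export
multinomial_probability <- function(x, p) {
  x <- check_configuration(x)
  p <- check_simplex(p)
  if (length(x) != length(p)) {
    stop("`x` and `p` must have the same number of variants (length ",
         length(x), " vs ", length(p), ")", call. = FALSE)
  }
  multinomial_coefficient(x) * prod(p^x)
}

# Exact multinomial coefficient n!/(x1!...xm!) as a product of binomials,
# integer-valued at every intermediate step.
multinomial_coefficient <- function(x) {
  prod(choose(cumsum(x), x))
}

# Coefficients for all rows of a configuration matrix.
multinomial_coefficients <- function(configs) {
  apply(configs, 1L, multinomial_coefficient)
}

# P(x) for every row of `configs` at frequencies `p`, vectorised over rows.
# Relies on R's 0^0 == 1 for absent variants.
configuration_probabilities <- function(configs, mcoef, p) {
  pr <- mcoef
  for (j in seq_along(p)) {
    pr <- pr * p[j]^configs[, j]
  }
  pr
}

# ---- argument checks shared across the package ----

check_count <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) ||
      x < 1 || x != round(x)) {
    stop("`", name, "` must be a single positive integer", call. = FALSE)
  }
  as.integer(x)
}

check_configuration <- function(x, n = NULL) {
  if (!is.numeric(x) || length(x) < 1L || anyNA(x) ||
      any(x < 0) || any(x != round(x))) {
    stop("a sample configuration must be a vector of nonnegative integers",
         call. = FALSE)
  }
  x <- as.integer(round(x))
  if (!is.null(n) && sum(x) != n) {
    stop("configuration (", paste(x, collapse = ","), ") does not sum to n = ",
         n, call. = FALSE)
  }
  x
}

check_simplex <- function(p, m = NULL, tol = 1e-12) {
  if (!is.numeric(p) || length(p) < 1L || anyNA(p)) {
    stop("a frequency vector must be numeric with no missing values",
         call. = FALSE)
  }
  if (!is.null(m) && length(p) != m) {
    stop("frequency vector has length ", length(p), ", expected m = ", m,
         call. = FALSE)
  }
  if (any(p < -tol)) {
    stop("frequency vector has negative entries", call. = FALSE)
  }
  if (abs(sum(p) - 1) > max(tol, 1e-12)) {
    stop("frequency vector entries must sum to 1 (got ",
         format(sum(p), digits = 15), ")", call. = FALSE)
  }
  pmax(p, 0)
}

config_key <- function(x) paste(x, collapse = ",")
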