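# Conformity-coefficient schemes.
#
# A scheme attaches to every sample configuration x a coefficient vector
# D(x) = (D_1(x), ..., D_m(x)) giving the deviation (times n) of each
# variant's adoption probability from its sample frequency:
#   P(adopt variant i | x) = x_i/n + D_i(x)/n.
# Admissibility requires -x_i < D_i(x) < n - x_i (probabilities in [0, 1]),
# sum_i D_i(x) = 0 (probabilities sum to 1), D_i(x) = 0 whenever x_i = 0
# (absent variants are never invented), and full symmetry under relabelling
# of variants. Symmetry forces D = 0 at fixation samples (n, 0, ..., 0) and
# at all integer equal-split samples (k, k, 0, ...), (l, l, l, 0, ...), ...

BOUND_TOL <- 1e-12     # strict inequalities enforced up to this slack
BOUND_WARN <- 1e-9     # parameters this close to an endpoint draw a warning

new_conformity_scheme <- function(n, m, D, kind, parameters = list(),
                                  d_values = NULL) {
  configs <- enumerate_configurations(n, m)
  stopifnot(is.matrix(D), nrow(D) == nrow(configs), ncol(D) == m)
  structure(
    list(
      n = as.integer(n), m = as.integer(m),
      configs = configs,
      mcoef = multinomial_coefficients(configs),
      D = D,
      d_values = d_values,
      kind = kind,
      parameters = parameters,
      keys = apply(configs, 1L, config_key)
    ),
    class = "conformity_scheme"
  )
}

#' Build a conformity scheme from an explicit coefficient table
#'
#' Low-level constructor: supply the coefficient vectors `D(x)` yourself,
#' either as a matrix aligned with `enumerate_configurations(n, m)` or as a
#' function of one configuration. Use [single_coefficient_scheme()],
#' [two_coefficient_scheme_n4_m3()] or [classification_scheme()] for the
#' standard parameterisations.
#'
#' @param n,m Role-model sample size and number of variants.
#' @param D A numeric matrix (rows aligned with the enumeration order) or a
#'   function `function(x)` returning the length-`m` coefficient vector for
#'   configuration `x`.
#' @param validate If `TRUE` (default), check the scheme axioms with
#'   [validate_scheme()] and raise on any violation. Set to `FALSE` only to
#'   inspect a deliberately broken scheme.
#'
#' @return An object of class `"conformity_scheme"`.
#' @export
conformity_scheme <- function(n, m, D, validate = TRUE) {
  n <- check_count(n, "n")
  m <- check_count(m, "m")
  configs <- enumerate_configurations(n, m)
  if (is.function(D)) {
    D <- t(apply(configs, 1L, function(x) as.numeric(D(x))))
    if (ncol(D) != m) {
      stop("coefficient function must return vectors of length m = ", m,
           call. = FALSE)
    }
  }
  scheme <- new_conformity_scheme(n, m, D, kind = "explicit")
  if (validate) {
    stop_on_violations(scheme)
  }
  scheme
}

#' @export
print.conformity_scheme <- function(x, ...) {
  cat("Conformity scheme (", x$kind, "): n = ", x$n, " role models, m = ",
      x$m, " variants, ", nrow(x$configs), " configurations\n", sep = "")
  if (length(x$parameters)) {
    cat("  parameters:",
        paste(names(x$parameters), vapply(x$parameters, format, ""),
              sep = " = ", collapse = ", "), "\n")
  }
  nz <- which(rowSums(abs(x$D)) > BOUND_TOL)
  cat("  configurations with nonzero coefficients:", length(nz), "\n")
  for (i in utils::head(nz, 6L)) {
    cat("    D(", paste(x$configs[i, ], collapse = ","), ") = (",
        paste(format(x$D[i, ], digits = 4), collapse = ", "), ")\n", sep = "")
  }
  if (length(nz) > 6L) cat("    ...\n")
  invisible(x)
}

# Row index of configuration x in the scheme's enumeration.
config_index <- function(scheme, x) {
  x <- check_configuration(x, n = scheme$n)
  if (length(x) != scheme$m) {
    stop("configuration has ", length(x), " entries, scheme expects m = ",
         scheme$m, call. = FALSE)
  }
  i <- match(config_key(x), scheme$keys)
  if (is.na(i)) {
    stop("configuration (", paste(x, collapse = ","),
         ") is not a composition of n = ", scheme$n, call. = FALSE)
  }
  i
}

#' Coefficient vector of a scheme at one configuration
#'
#' @param scheme A `"conformity_scheme"`.
#' @param x A sample configuration.
#' @return The numeric vector `D(x)`.
#' @export
scheme_coefficients <- function(scheme, x) {
  scheme$D[config_index(scheme, x), ]
}

#' Adoption probabilities given a role-model sample
#'
#' The probability that an offspring who observed sample `x` adopts each
#' variant: `x_i/n + D_i(x)/n`. For any admissible scheme these are
#' probabilities (nonnegative, summing to one).
#'
#' @param x A sample configuration.
#' @param scheme A `"conformity_scheme"` for the matching `(n, m)`.
#' @return Numeric vector of `m` adoption probabilities.
#' @examples
#' sc <- single_coefficient_scheme(0.5)
#' adoption_probabilities(c(2, 1, 0), sc)  # (2/3 + 0.5/3, 1/3 - 0.5/3, 0)
#' @export
adoption_probabilities <- function(x, scheme) {
  i <- config_index(scheme, x)
  x <- scheme$configs[i, ]
  d <- scheme$D[i, ]
  bad <- which(d <= -x - BOUND_TOL | d >= scheme$n - x + BOUND_TOL)
  if (length(bad)) {
    stop("coefficient bound violated at configuration (",
         paste(x, collapse = ","), "), variant ", bad[1L],
         ": D = ", format(d[bad[1L]]), " outside (-x_i, n - x_i)",
         call. = FALSE)
  }
  pmin(pmax(x / scheme$n + d / scheme$n, 0), 1)
}

check_scalar_bound <- function(value, lower, upper, name) {
  if (length(value) != 1L || !is.finite(value)) {
    stop("`", name, "` must be a single finite number", call. = FALSE)
  }
  if (value <= lower + BOUND_TOL || value >= upper - BOUND_TOL) {
    stop("`", name, "` = ", format(value), " is outside the open interval (",
         lower, ", ", upper, ")", call. = FALSE)
  }
  if (value < lower + BOUND_WARN || value > upper - BOUND_WARN) {
    warning("`", name, "` = ", format(value),
            " is within 1e-9 of an admissibility endpoint", call. = FALSE)
  }
  value
}

#' Single-coefficient scheme for n = 3 role models
#'
#' With three role models the only sample types are fixation `(3, 0, ..., 0)`,
#' the even split `(1, 1, 1, 0, ..., 0)` and the majority type
#' `(2, 1, 0, ..., 0)`; symmetry forces the first two to carry zero
#' coefficients, so the whole scheme is determined by one number `D` with
#' `D(2, 1, 0, ...) = (D, -D, 0, ...)`. Admissibility requires `-2 < D < 1`.
#' `D > 0` is conformist, `D < 0` anticonformist, `D = 0` unbiased.
#'
#' @param D Conformity coefficient, in `(-2, 1)`.
#' @param m Number of variants (>= 2).
#' @return A `"conformity_scheme"` with `n = 3`.
#' @examples
#' single_coefficient_scheme(0.5)
#' scheme_coefficients(single_coefficient_scheme(0.5, m = 3), c(0, 2, 1))
#' @export
single_coefficient_scheme <- function(D, m = 3) {
  m <- check_count(m, "m")
  if (m < 2L) stop("`m` must be at least 2", call. = FALSE)
  D <- check_scalar_bound(D, -2, 1, "D")
  classification_scheme(3L, m, d = D, kind = "single",
                        parameters = list(D = D))
}

#' Two-coefficient scheme for n = 4 role models and m = 3 variants
#'
#' With four role models and three variants there are two sample types whose
#' coefficients are free: the strong majority `(3, 1, 0)` with
#' `D(3, 1, 0) = (D', -D', 0)` and the weak majority `(2, 1, 1)` with
#' `D(2, 1, 1) = (D, -D/2, -D/2)` (symmetry of the two singleton entries plus
#' the zero-sum constraint force the even split of `-D`). Fixation `(4, 0, 0)`
#' and the equal split `(2, 2, 0)` carry zero coefficients. Admissibility
#' requires `-3 < D' < 1` and `-2 < D < 2`. Opposite signs of `D'` and `D`
#' mix conformity and anticonformity in one scheme, which is what makes the
#' asymmetric interior equilibria of [interior_equilibria_n4_m3()] possible.
#'
#' @param D_prime Coefficient for the `(3, 1, 0)` sample type, in `(-3, 1)`.
#' @param D Coefficient for the `(2, 1, 1)` sample type, in `(-2, 2)`.
#' @return A `"conformity_scheme"` with `n = 4`, `m = 3`.
#' @examples
#' two_coefficient_scheme_n4_m3(-0.3, 0.9)
#' @export
two_coefficient_scheme_n4_m3 <- function(D_prime, D) {
  D_prime <- check_scalar_bound(D_prime, -3, 1, "D_prime")
  D <- check_scalar_bound(D, -2, 2, "D")
  classification_scheme(
    4L, 3L,
    d = c("3,1,0" = D_prime, "2,1,1" = D),
    kind = "n4m3",
    parameters = list(D_prime = D_prime, D = D)
  )
}

#' Scheme with one coefficient d(x) per sample-configuration type
#'
#' Builds a conformity scheme from a single coefficient `d(x)` per unordered
#' configuration type, split over variants by the class I/II/III weights of
#' [g_weights()]: `D_i(x) = g_i(x) d(x)`. Any such scheme satisfies the
#' axioms automatically provided each `d(x)` lies strictly inside
#' [d_bounds()]; `d(x) > 0` everywhere is pure conformity, `d(x) < 0`
#' everywhere pure anticonformity, and mixed signs are allowed.
#'
#' @param n,m Role-model sample size and number of variants.
#' @param d The coefficient assignment. One of: a single number (the same
#'   `d` at every configuration); a named numeric vector keyed by
#'   sorted-descending configuration type, e.g.
#'   `c("3,1,0" = -0.3, "2,1,1" = 0.9)` (types not named get `d = 0`); or a
#'   function of the sorted-descending counts returning one number.
#' @param kind,parameters Internal labelling, used by the wrappers.
#' @return A `"conformity_scheme"` whose `d_values` field records the
#'   per-configuration coefficient actually used (`NA` where the coefficient
#'   is inert because class II is empty).
#' @examples
#' # constant anticonformity, n = 15, m = 3 (admissible: bound is -6)
#' classification_scheme(15, 3, d = -5.9)
#' # state-dependent: each d(x) just above its own lower bound
#' classification_scheme(15, 3, d = function(x) d_bounds(x)[1] + 0.1)
#' @export
classification_scheme <- function(n, m, d, kind = "classification",
                                  parameters = list(d = d)) {
  n <- check_count(n, "n")
  m <- check_count(m, "m")
  configs <- enumerate_configurations(n, m)
  K <- nrow(configs)

  type_of <- function(x) config_key(sort(x, decreasing = TRUE))
  d_fun <-
    if (is.function(d)) {
      function(x) d(sort(x, decreasing = TRUE))
    } else if (is.numeric(d) && length(d) == 1L && is.null(names(d))) {
      function(x) d
    } else if (is.numeric(d) && !is.null(names(d))) {
      function(x) {
        v <- d[type_of(x)]
        if (is.na(v)) 0 else unname(v)
      }
    } else {
      stop("`d` must be a single number, a named numeric vector keyed by ",
           "configuration type, or a function", call. = FALSE)
    }

  D <- matrix(0, K, m)
  d_values <- rep(NA_real_, K)
  for (i in seq_len(K)) {
    x <- configs[i, ]
    b <- d_bounds(x, n = n)
    if (isTRUE(attr(b, "inert"))) next  # all weights zero; d irrelevant
    di <- d_fun(x)
    if (length(di) != 1L || !is.finite(di)) {
      stop("d(x) must be a single finite number at configuration (",
           paste(x, collapse = ","), ")", call. = FALSE)
    }
    if (di <= b[1L] - BOUND_TOL || di >= b[2L] + BOUND_TOL) {
      stop("d = ", format(di), " at configuration (",
           paste(x, collapse = ","), ") is outside its admissible interval (",
           format(b[1L]), ", ", format(b[2L]), ")", call. = FALSE)
    }
    if (di < b[1L] + BOUND_WARN || di > b[2L] - BOUND_WARN) {
      warning("d = ", format(di), " at configuration (",
              paste(x, collapse = ","),
              ") is within 1e-9 of an admissibility endpoint", call. = FALSE)
    }
    d_values[i] <- di
    D[i, ] <- g_weights(x, n = n) * di
  }
  new_conformity_scheme(n, m, D, kind = kind, parameters = parameters,
                        d_values = d_values)
}

#' Four-coefficient scheme for n = 5 role models and m = 3 variants
#'
#' With five role models and three variants, four unordered sample types carry
#' free coefficients. They are taken in lexicographic-descending order
#' `(4,1,0), (3,2,0), (3,1,1), (2,2,1)` and given the coefficients
#' `D_ppp, D_pp, D_p, D` respectively. Admissible ranges follow from
#' [d_bounds()]: `(-4, 1)`, `(-3, 2/3)`, `(-3, 2)`, `(-4, 6)`.
#'
#' @param D_ppp,D_pp,D_p,D Coefficients for the four sample types.
#' @return A `"conformity_scheme"` with `n = 5`, `m = 3`.
#' @export
four_coefficient_scheme_n5_m3 <- function(D_ppp, D_pp, D_p, D) {
  classification_scheme(
    5L, 3L,
    d = c("4,1,0" = D_ppp, "3,2,0" = D_pp, "3,1,1" = D_p, "2,2,1" = D),
    kind = "n5m3",
    parameters = list(D_ppp = D_ppp, D_pp = D_pp, D_p = D_p, D = D)
  )
}

# TRUE when every non-inert configuration is strictly conformist: class II
# coefficients positive, class III negative (equivalently d(x) > 0).
is_conformist_scheme <- function(scheme) {
  for (i in seq_len(nrow(scheme$configs))) {
    x <- scheme$configs[i, ]
    cls <- classify_configuration(x, n = scheme$n)
    if (!length(cls$II)) next
    if (any(scheme$D[i, cls$II] <= BOUND_TOL) ||
        any(scheme$D[i, cls$III] >= -BOUND_TOL)) {
      return(FALSE)
    }
  }
  TRUE
}

#' Check a scheme against the transmission axioms
#'
#' Audits every configuration for: the probability bounds
#' `-x_i < D_i(x) < n - x_i`; the zero-sum constraint `sum_i D_i(x) = 0`;
#' absent variants (`x_i = 0` implies `D_i(x) = 0`); symmetry under variant
#' relabelling (`D(sigma x) = sigma D(x)`, checked over all permutations for
#' `m <= 5`, over a generating set of the symmetric group otherwise); and the
#' forced zeros at
#' fixation and integer equal-split configurations.
#'
#' @param scheme A `"conformity_scheme"`.
#' @param tol Numeric tolerance for the equality checks.
#' @return A data frame of violations with columns `configuration`, `rule`
#'   and `detail`; zero rows means the scheme is valid.
#' @examples
#' nrow(validate_scheme(single_coefficient_scheme(0.5)))  # 0
#' @export
validate_scheme <- function(scheme, tol = BOUND_TOL) {
  stopifnot(inherits(scheme, "conformity_scheme"))
  configs <- scheme$configs
  D <- scheme$D
  n <- scheme$n
  m <- scheme$m
  out <- list()
  add <- function(i, rule, detail) {
    out[[length(out) + 1L]] <<- data.frame(
      configuration = config_key(configs[i, ]),
      rule = rule, detail = detail, stringsAsFactors = FALSE
    )
  }

  perms <- if (m <= 5L) {
    permutations_of(m)
  } else {
    # equivariance under a generating set of S_m implies it for the full group
    rbind(c(2L, 1L, seq_len(m)[-(1:2)]), c(seq_len(m)[-1L], 1L))
  }

  for (i in seq_len(nrow(configs))) {
    x <- configs[i, ]
    d <- D[i, ]
    bad <- which(d <= -x - tol | d >= n - x + tol)
    if (length(bad)) {
      add(i, "bound", paste0("variant ", bad[1L], ": D = ",
                             format(d[bad[1L]]), " outside (-", x[bad[1L]],
                             ", ", n - x[bad[1L]], ")"))
    }
    if (abs(sum(d)) > max(tol, 1e-10)) {
      add(i, "zero_sum", paste0("sum D_i = ", format(sum(d))))
    }
    if (any(x == 0L & abs(d) > tol)) {
      add(i, "absent_variant", "D_i != 0 for a variant absent from the sample")
    }
    ux <- sort(unique(x))
    for (v in ux) {
      dv <- d[x == v]
      if (max(dv) - min(dv) > 1e-10) {
        add(i, "symmetry", paste0("equal counts x_i = ", v,
                                  " carry unequal coefficients"))
        break
      }
    }
    if (length(unique(x[x > 0L])) == 1L && sum(x) %% sum(x > 0L) == 0L &&
        any(abs(d) > 1e-10)) {
      add(i, "forced_zero",
          "fixation/equal-split configuration has nonzero coefficients")
    }
  }

  # full relabelling equivariance D(sigma x) = sigma D(x)
  for (s in seq_len(nrow(perms))) {
    sigma <- perms[s, ]
    if (all(sigma == seq_len(m))) next
    permuted_keys <- apply(configs[, sigma, drop = FALSE], 1L, config_key)
    target <- match(permuted_keys, scheme$keys)
    mism <- which(rowSums(abs(D[target, , drop = FALSE] -
                                D[, sigma, drop = FALSE])) > 1e-10)
    for (i in utils::head(mism, 3L)) {
      add(i, "permutation",
          paste0("D(sigma x) != sigma D(x) for sigma = (",
                 paste(sigma, collapse = ","), ")"))
    }
  }

  if (length(out)) do.call(rbind, out) else
    data.frame(configuration = character(), rule = character(),
               detail = character(), stringsAsFactors = FALSE)
}

stop_on_violations <- function(scheme) {
  v <- validate_scheme(scheme)
  if (nrow(v)) {
    stop("scheme violates the transmission axioms (", nrow(v),
         " violation(s)); first: [", v$rule[1L], "] at (",
         v$configuration[1L], "): ", v$detail[1L], call. = FALSE)
  }
  invisible(scheme)
}

# All permutations of 1..m as rows (m! x m). Fine for m <= 5.
permutations_of <- function(m) {
  if (m == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(m - 1L)
  do.call(rbind, lapply(seq_len(m), function(k) {
    rest <- seq_len(m)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), m - 1L))
  }))
}
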