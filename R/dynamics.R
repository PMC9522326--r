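# One-generation frequency recursion and trajectory iteration.
#
# The offspring frequency of variant i is the expectation of the adoption
# probability over the multinomial distribution of role-model samples:
#   p'_i = p_i + (1/n) * sum_x D_i(x) P(x),
# where P(x) is the multinomial probability of sample x at frequencies p.
# The identity part comes from the multinomial mean, E[x_i]/n = p_i. The
# general engine evaluates the sum over the full configuration enumeration;
# closed forms are available for n = 3 (any m) and n = 4, m = 3.

#' One generation of transmission
#'
#' Applies the exact frequency recursion
#' `p'_i = p_i + (1/n) sum_x D_i(x) P(x)` over all role-model sample
#' configurations. The output is on the simplex for any admissible scheme:
#' the zero-sum constraint keeps `sum(p') = sum(p)` and the probability
#' bounds keep every entry in `[0, 1]`. An output off the simplex beyond
#' `1e-9` signals an inadmissible scheme and raises an error.
#'
#' @param p Frequency vector on the simplex (length `m`).
#' @param scheme A `"conformity_scheme"` with matching `m`.
#' @return The next-generation frequency vector.
#' @examples
#' sc <- single_coefficient_scheme(-0.5)
#' step_frequencies(c(0.5, 0.3, 0.2), sc)
#' @export
step_frequencies <- function(p, scheme) {
  stopifnot(inherits(scheme, "conformity_scheme"))
  p <- check_simplex(p, m = scheme$m)
  P <- configuration_probabilities(scheme$configs, scheme$mcoef, p)
  pp <- p + as.vector(crossprod(scheme$D, P)) / scheme$n
  if (abs(sum(pp) - 1) > 1e-9 || any(pp < -1e-9) || any(pp > 1 + 1e-9)) {
    stop("recursion output left the simplex; the scheme is inadmissible ",
         "(sum = ", format(sum(pp), digits = 15), ", min = ",
         format(min(pp)), ")", call. = FALSE)
  }
  # rounding noise only: true values are nonnegative sums of probabilities
  neg <- pp < 0
  if (any(neg)) {
    if (any(pp[neg] < -1e-12)) {
      stop("negative frequency beyond rounding noise (",
           format(min(pp)), ")", call. = FALSE)
    }
    pp[neg] <- 0
  }
  # symmetry: variants with exactly equal frequencies must stay exactly
  # equal (their column sums are permutations of one another, which float
  # summation order would otherwise break by an ulp -- and dynamics near an
  # unstable tie amplify an ulp exponentially)
  if (anyDuplicated(p)) {
    for (v in unique(p[duplicated(p)])) {
      grp <- which(p == v)
      pp[grp] <- mean(pp[grp])
    }
  }
  pp
}

#' Closed-form recursion for n = 3 role models
#'
#' With three role models and the single coefficient `D`, the recursion
#' collapses to `p'_i = p_i + D p_i (p_i - sum_j p_j^2)` for any number of
#' variants. Identical to [step_frequencies()] with
#' [single_coefficient_scheme()]; useful as a fast path and as an
#' independent cross-check of the general engine.
#'
#' @param p Frequency vector (length `m >= 2`).
#' @param D Conformity coefficient in `(-2, 1)`.
#' @return The next-generation frequency vector.
#' @export
step_closed_form_n3 <- function(p, D) {
  D <- check_scalar_bound(D, -2, 1, "D")
  p <- check_simplex(p)
  p + D * p * (p - sum(p^2))
}

#' Closed-form recursion for n = 4 role models and m = 3 variants
#'
#' The two-coefficient recursion, for `{i, j, k} = {1, 2, 3}`:
#' `p'_i = p_i + D' p_i (1 - p_i)(2 p_i - 1)
#'        + 3 p_i (p_j^2 p_k + p_j p_k^2)(D' - D/2) + 3 D p_i^2 p_j p_k`.
#' Identical to [step_frequencies()] with [two_coefficient_scheme_n4_m3()].
#'
#' @param p Frequency vector of length 3.
#' @param D_prime Coefficient for sample type `(3, 1, 0)`, in `(-3, 1)`.
#' @param D Coefficient for sample type `(2, 1, 1)`, in `(-2, 2)`.
#' @return The next-generation frequency vector.
#' @export
step_closed_form_n4_m3 <- function(p, D_prime, D) {
  D_prime <- check_scalar_bound(D_prime, -3, 1, "D_prime")
  D <- check_scalar_bound(D, -2, 2, "D")
  p <- check_simplex(p, m = 3L)
  jk <- list(c(2L, 3L), c(1L, 3L), c(1L, 2L))
  vapply(1:3, function(i) {
    pj <- p[jk[[i]][1L]]
    pk <- p[jk[[i]][2L]]
    pi_ <- p[i]
    pi_ + D_prime * pi_ * (1 - pi_) * (2 * pi_ - 1) +
      3 * pi_ * (pj^2 * pk + pj * pk^2) * (D_prime - D / 2) +
      3 * D * pi_^2 * pj * pk
  }, numeric(1))
}

#' Iterate the transmission recursion over many generations
#'
#' @param p0 Initial frequency vector.
#' @param scheme A `"conformity_scheme"`.
#' @param generations Number of generations to iterate (>= 1).
#' @param record `"all"` keeps every generation (default; suitable up to
#'   about 1e5 generations), `"thinned"` keeps every 100th generation plus
#'   the last 10,000.
#' @param classify If `TRUE` (default), attach the long-run classification
#'   from [classify_longrun()] when the recorded history is long enough
#'   (at least 200 generations); otherwise the classification is
#'   `"unclassified"`.
#' @param k_max Largest cycle period to test during classification.
#'
#' @return An object of class `"trajectory"`: a list with `history` (matrix,
#'   one row per recorded generation, including generation 0), `generation`
#'   (the recorded generation numbers), `generations`, `scheme`,
#'   `classification` and `summary` (see [classify_longrun()]).
#' @examples
#' tr <- iterate_frequencies(c(0.5, 0.3, 0.2), single_coefficient_scheme(-0.5),
#'                           generations = 500)
#' tr$classification
#' @export
iterate_frequencies <- function(p0, scheme, generations,
                                record = c("all", "thinned"),
                                classify = TRUE, k_max = 64L) {
  stopifnot(inherits(scheme, "conformity_scheme"))
  record <- match.arg(record)
  generations <- check_count(generations, "generations")
  p <- check_simplex(p0, m = scheme$m)

  keep <- if (record == "all") {
    seq.int(0L, generations)
  } else {
    sort(unique(c(0L, seq.int(0L, generations, by = 100L),
                  seq.int(max(0L, generations - 10000L), generations))))
  }
  history <- matrix(NA_real_, length(keep), scheme$m)
  pos <- 1L
  history[pos, ] <- p
  for (t in seq_len(generations)) {
    p <- tryCatch(
      step_frequencies(p, scheme),
      error = function(e) {
        stop("generation ", t, ": ", conditionMessage(e), call. = FALSE)
      }
    )
    if (t == keep[pos + 1L]) {
      pos <- pos + 1L
      history[pos, ] <- p
    }
  }
  colnames(history) <- paste0("p_", seq_len(scheme$m))

  traj <- structure(
    list(history = history, generation = keep, generations = generations,
         scheme = scheme, classification = "unclassified", summary = NULL),
    class = "trajectory"
  )
  if (classify && record == "all" && generations >= 200L) {
    cl <- classify_longrun(traj, k_max = min(as.integer(k_max),
                                             generations %/% 10L))
    traj$classification <- cl$classification
    traj$summary <- cl
  }
  traj
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Transmission trajectory: ", x$generations, " generations, m = ",
      ncol(x$history), " variants (", x$scheme$kind, " scheme, n = ",
      x$scheme$n, ")\n", sep = "")
  cat("  start:", format(x$history[1L, ], digits = 4), "\n")
  cat("  end:  ", format(x$history[nrow(x$history), ], digits = 4), "\n")
  cat("  long-run classification:", x$classification, "\n")
  if (!is.null(x$summary) && x$summary$classification == "cycle") {
    cat("  period:", x$summary$period, "\n")
  }
  invisible(x)
}
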