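# Asymptotic behaviour of trajectories: convergence to a fixed point, exact
# period-k cycles, or sustained aperiodic fluctuation. Pure conformity
# guarantees convergence (to 1/l on the l initially-maximal variants); strong
# anticonformity with many role models can overshoot the centre repeatedly,
# producing stable cycles or chaos.

#' Classify the long-run behaviour of a trajectory
#'
#' Decides among: `"fixed_point"` -- the sup-norm one-generation change is
#' below `1e-10` over the last 100 generations; `"cycle"` -- the smallest
#' period `k <= k_max` for which the trajectory repeats to within `1e-9`
#' (sup norm) over the last `10 k` generations; `"nonconvergent"` --
#' neither. "Exact" cycles are exact to machine precision of the
#' deterministic map, which is what the tolerance encodes.
#'
#' @param traj A `"trajectory"` from [iterate_frequencies()] (recorded with
#'   `record = "all"`), or a plain history matrix with one generation per row.
#' @param k_max Largest period tested; the trajectory must be at least
#'   `10 * k_max` generations long.
#' @param fixed_tol,cycle_tol Tolerances for the fixed-point and cycle tests.
#' @return A list with `classification`, `period` (`NA` unless a cycle),
#'   `cycle_points` (matrix of the k distinct phase points, for cycles),
#'   `final` (last recorded point), and `ergodic_mean` (mean over the last
#'   half of the trajectory).
#' @examples
#' sc <- classification_scheme(15, 3, d = -5.9)
#' tr <- iterate_frequencies(c(0.48, 0.501, 0.019), sc, 2000, classify = FALSE)
#' classify_longrun(tr)$period  # 2
#' @export
classify_longrun <- function(traj, k_max = 64L,
                             fixed_tol = 1e-10, cycle_tol = 1e-9) {
  H <- if (inherits(traj, "trajectory")) traj$history else as.matrix(traj)
  T_rec <- nrow(H) - 1L                     # transitions recorded
  k_max <- max(1L, as.integer(k_max))
  if (T_rec < 10L * k_max || T_rec < 100L) {
    stop("trajectory too short to classify: need at least max(100, 10*k_max)",
         " = ", max(100L, 10L * k_max), " generations, got ", T_rec,
         call. = FALSE)
  }

  last <- H[nrow(H), ]
  ergodic <- colMeans(H[(nrow(H) - T_rec %/% 2L):nrow(H), , drop = FALSE])

  diffs <- abs(H[(nrow(H) - 99L):nrow(H), , drop = FALSE] -
                 H[(nrow(H) - 100L):(nrow(H) - 1L), , drop = FALSE])
  if (max(diffs) < fixed_tol) {
    return(list(classification = "fixed_point", period = NA_integer_,
                cycle_points = NULL, final = last, ergodic_mean = ergodic))
  }

  for (k in seq_len(k_max)) {
    span <- 10L * k
    if (span + k > T_rec) break
    rows <- (nrow(H) - span + 1L):nrow(H)
    lagged <- rows - k
    if (max(abs(H[rows, , drop = FALSE] - H[lagged, , drop = FALSE])) <
        cycle_tol) {
      cls <- if (k == 1L) "fixed_point" else "cycle"
      cyc <- if (k > 1L) {
        pts <- H[(nrow(H) - k + 1L):nrow(H), , drop = FALSE]
        rownames(pts) <- paste0("phase_", seq_len(k))
        pts
      }
      return(list(classification = cls,
                  period = if (k > 1L) k else NA_integer_,
                  cycle_points = cyc, final = last, ergodic_mean = ergodic))
    }
  }
  list(classification = "nonconvergent", period = NA_integer_,
       cycle_points = NULL, final = last, ergodic_mean = ergodic)
}

#' Time-averaged frequencies over a trailing window
#'
#' @param traj A `"trajectory"` or history matrix.
#' @param window Number of trailing generations to average over.
#' @return A frequency vector (componentwise mean; on the simplex).
#' @examples
#' sc <- classification_scheme(15, 3, d = -5.9)
#' tr <- iterate_frequencies(c(0.48, 0.501, 0.019), sc, 2000, classify = FALSE)
#' ergodic_mean(tr, 1000)
#' @export
ergodic_mean <- function(traj, window) {
  H <- if (inherits(traj, "trajectory")) traj$history else as.matrix(traj)
  window <- check_count(window, "window")
  if (window > nrow(H)) {
    stop("window (", window, ") exceeds the recorded trajectory length (",
         nrow(H), ")", call. = FALSE)
  }
  colMeans(H[(nrow(H) - window + 1L):nrow(H), , drop = FALSE])
}

#' Predicted limit under pure conformity
#'
#' When every configuration's coefficient is strictly conformist
#' (`d(x) > 0` for all `x`), the population converges globally to the point
#' with the `l` initially-maximal variants at `1/l` and all others at 0,
#' where `l` is the number of variants tied (by exact floating-point
#' equality) at the initial maximum frequency. Symmetry preserves the tie in
#' every generation, so the prediction is exact, not approximate.
#'
#' @param p0 Initial frequency vector.
#' @param scheme A strictly conformist `"conformity_scheme"`.
#' @return The predicted limiting frequency vector.
#' @examples
#' sc <- single_coefficient_scheme(0.5)
#' max_frequency_limit(c(0.4, 0.35, 0.25), sc)  # (1, 0, 0)
#' max_frequency_limit(c(0.4, 0.4, 0.2), sc)    # (1/2, 1/2, 0)
#' @export
max_frequency_limit <- function(p0, scheme) {
  stopifnot(inherits(scheme, "conformity_scheme"))
  p0 <- check_simplex(p0, m = scheme$m)
  if (!is_conformist_scheme(scheme)) {
    stop("the limit prediction requires a strictly conformist scheme ",
         "(d(x) > 0 at every configuration)", call. = FALSE)
  }
  top <- which(p0 == max(p0))   # exact ties only (documented)
  out <- numeric(scheme$m)
  out[top] <- 1 / length(top)
  out
}

#' Divergence-rate diagnostic for sensitive dependence
#'
#' Largest-Lyapunov-style estimate: a twin trajectory offset by `delta`
#' inside the simplex is iterated alongside the reference, the log of the
#' separation growth is accumulated each generation, and the separation is
#' renormalised back to `delta` along its current direction. The mean log
#' growth rate over the post-transient generations is returned: positive
#' rates label sustained aperiodic trajectories as chaotic; contracting
#' regimes (fixed points, stable cycles) give negative rates.
#'
#' @param p0 Initial frequency vector.
#' @param scheme A `"conformity_scheme"`.
#' @param generations Generations to iterate (after `transient`, each
#'   contributes to the estimate).
#' @param delta Perturbation size.
#' @param transient Generations discarded before accumulating.
#' @return A list with `rate` (mean log separation growth per generation),
#'   `label` (`"expanding"` if positive, `"contracting"` otherwise),
#'   `generations` and `delta`.
#' @examples
#' sc <- classification_scheme(15, 3, d = -5.9)
#' sensitivity_diagnostic(c(0.48, 0.501, 0.019), sc, generations = 800)$label
#' @export
sensitivity_diagnostic <- function(p0, scheme, generations = 2000L,
                                   delta = 1e-9, transient = 200L) {
  stopifnot(inherits(scheme, "conformity_scheme"))
  generations <- check_count(generations, "generations")
  transient <- as.integer(transient)
  if (generations <= transient) {
    stop("`generations` must exceed `transient`", call. = FALSE)
  }
  p <- check_simplex(p0, m = scheme$m)
  u <- c(1, -1, rep(0, scheme$m - 2L))
  u <- u / sqrt(sum(u^2))
  q <- p + delta * u
  if (any(q < 0)) {            # start too close to a face: flip the offset
    q <- p - delta * u
  }
  q <- check_simplex(q, m = scheme$m)

  acc <- 0
  count <- 0L
  for (t in seq_len(generations)) {
    p <- step_frequencies(p, scheme)
    q <- step_frequencies(q, scheme)
    sep <- sqrt(sum((q - p)^2))
    if (sep == 0) {            # collapsed to identical orbits; reseed
      q <- check_simplex(pmax(p + delta * u, 0) /
                           sum(pmax(p + delta * u, 0)))
      next
    }
    if (t > transient) {
      acc <- acc + log(sep / delta)
      count <- count + 1L
    }
    # renormalise along the current separation direction, projected back
    # onto the zero-sum tangent space so the twin stays on the simplex
    w <- (q - p) * (delta / sep)
    w <- w - mean(w)
    q <- p + w
  }
  rate <- acc / count
  list(rate = rate, label = if (rate > 0) "expanding" else "contracting",
       generations = generations, delta = delta)
}
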