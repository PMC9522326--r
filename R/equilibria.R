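# Equilibria of the transmission recursion and their local stability.
#
# For any admissible symmetric scheme, every point with l variants at 1/l and
# the rest at 0 is an equilibrium: corners (l = 1), equal-split boundary
# points (1 < l < m) and the central polymorphism (l = m). Mixed-sign schemes
# can add asymmetric interior equilibria; with n = 4, m = 3 these have a
# closed form. Local stability is judged from the Jacobian of the map in
# simplex coordinates (the first m - 1 frequencies), with analytic
# cross-checks at the corners (sign of D_1(n-1, 1, 0, ...)) and at the
# central point (the aggregate statistic alpha).

STABILITY_TOL <- 1e-9

#' Catalogue of symmetric equilibria
#'
#' All points with `l` variants at frequency `1/l` and the remaining
#' `m - l` at 0, for `l = 1, ..., m` and every support set: `2^m - 1` points.
#' Each is a fixed point of [step_frequencies()] under any admissible scheme.
#'
#' @param m Number of variants.
#' @return A list with `points` (matrix, one equilibrium per row),
#'   `support_size` and `kind` (`"corner"`, `"boundary_equal_split"` or
#'   `"central"`).
#' @examples
#' symmetric_equilibria(3)  # 3 corners, 3 boundary points, 1 central
#' @export
symmetric_equilibria <- function(m) {
  m <- check_count(m, "m")
  pts <- list()
  sizes <- integer()
  for (l in seq_len(m)) {
    supports <- utils::combn(m, l)
    for (j in seq_len(ncol(supports))) {
      p <- numeric(m)
      p[supports[, j]] <- 1 / l
      pts[[length(pts) + 1L]] <- p
      sizes <- c(sizes, l)
    }
  }
  points <- do.call(rbind, pts)
  colnames(points) <- paste0("p_", seq_len(m))
  kind <- ifelse(sizes == 1L, "corner",
                 ifelse(sizes == m, "central", "boundary_equal_split"))
  list(points = points, support_size = sizes, kind = kind)
}

#' Asymmetric interior equilibria for n = 4, m = 3
#'
#' With the two-coefficient scheme, up to three interior equilibria exist at
#' `((-2D' - 3D)/(2D' - 3D), 2D'/(2D' - 3D), 2D'/(2D' - 3D))` and its
#' permutations. They are valid (all coordinates in `(0, 1)`) iff
#' `0 < D' < -(3/2) D` (with `D < 0`) or `-(3/2) D < D' < 0` (with `D > 0`),
#' i.e. only when the scheme mixes conformity and anticonformity. When valid
#' they are always unstable and lie on the separatrices between basins.
#'
#' @param D_prime,D Scheme coefficients (see [two_coefficient_scheme_n4_m3()]).
#' @return A list with `points` (3 x 3 matrix or `NULL` when the denominator
#'   `2D' - 3D` vanishes), `valid` (logical per point), `degenerate`, and the
#'   regime discriminants `two_dprime_plus_3d = 2D' + 3D` (existence, with
#'   the sign of `D'`) and `four_dprime_plus_3d = 4D' + 3D` (central-point
#'   stability boundary).
#' @examples
#' interior_equilibria_n4_m3(-0.3, 0.9)
#' @export
interior_equilibria_n4_m3 <- function(D_prime, D) {
  disc2 <- 2 * D_prime + 3 * D
  disc4 <- 4 * D_prime + 3 * D
  den <- 2 * D_prime - 3 * D
  if (abs(den) < 1e-12) {
    return(list(points = NULL, valid = logical(0), degenerate = TRUE,
                two_dprime_plus_3d = disc2, four_dprime_plus_3d = disc4))
  }
  a <- (-2 * D_prime - 3 * D) / den
  b <- 2 * D_prime / den
  points <- rbind(c(a, b, b), c(b, a, b), c(b, b, a))
  colnames(points) <- paste0("p_", 1:3)
  valid <- rep(a > 0 && a < 1 && b > 0 && b < 1, 3L)
  list(points = points, valid = valid, degenerate = FALSE,
       two_dprime_plus_3d = disc2, four_dprime_plus_3d = disc4)
}

#' Aggregate conformity statistic for central-point stability
#'
#' The central polymorphism `(1/m, ..., 1/m)` is locally stable iff
#' `|1 + (m/(m-1)) alpha| < 1`, where
#' `alpha = (1 / (n m^(n-1))) sum_x D_i(x) multicoef(x) x_i` (the same value
#' for every `i` by symmetry; computed for `i = 1`). Negative `alpha`
#' (net anticonformity around the centre) is stabilising.
#'
#' @param scheme A valid symmetric `"conformity_scheme"`.
#' @return An object of class `"central_stability"`: list with `alpha`,
#'   `multiplier` (the eigenvalue `1 + (m/(m-1)) alpha` of the linearised map
#'   at the centre) and `verdict` (`"stable"`, `"unstable"` or `"marginal"`).
#' @examples
#' alpha_statistic(single_coefficient_scheme(-0.5))  # alpha = 2D/9
#' @export
alpha_statistic <- function(scheme) {
  stopifnot(inherits(scheme, "conformity_scheme"))
  stop_on_violations(scheme)
  n <- scheme$n
  m <- scheme$m
  alpha <- sum(scheme$D[, 1L] * scheme$mcoef * scheme$configs[, 1L]) /
    (n * m^(n - 1))
  multiplier <- 1 + m / (m - 1) * alpha
  verdict <- if (abs(abs(multiplier) - 1) <= STABILITY_TOL) {
    "marginal"
  } else if (abs(multiplier) < 1) {
    "stable"
  } else {
    "unstable"
  }
  structure(list(alpha = alpha, multiplier = multiplier, verdict = verdict),
            class = "central_stability")
}

#' @export
print.central_stability <- function(x, ...) {
  cat("Central polymorphism stability: alpha =", format(x$alpha, digits = 6),
      "-> multiplier", format(x$multiplier, digits = 6), "->", x$verdict, "\n")
  invisible(x)
}

#' Local stability of the corner equilibria
#'
#' All `m` corners (fixation of one variant) are locally stable iff
#' `D_1(x) > 0` at the near-fixation sample `x = (n - 1, 1, 0, ..., 0)`:
#' a conformist response to a lone deviant pulls the population back.
#'
#' @param scheme A valid symmetric `"conformity_scheme"`.
#' @return A list with `D1` (the coefficient at the near-fixation sample)
#'   and `verdict`.
#' @export
corner_stability <- function(scheme) {
  stopifnot(inherits(scheme, "conformity_scheme"))
  x <- c(scheme$n - 1L, 1L, rep(0L, scheme$m - 2L))
  D1 <- scheme_coefficients(scheme, x)[1L]
  verdict <- if (abs(D1) <= STABILITY_TOL) {
    "marginal"
  } else if (D1 > 0) {
    "stable"
  } else {
    "unstable"
  }
  list(D1 = D1, verdict = verdict)
}

# Map in simplex coordinates: q holds the m-1 free frequencies, coordinate
# `drop` is 1 - sum(q); returns the free frequencies after one generation.
simplex_map <- function(q, scheme, drop = scheme$m) {
  p <- append(q, 1 - sum(q), after = drop - 1L)
  step_frequencies(p, scheme)[-drop]
}

#' Jacobian of the recursion in simplex coordinates
#'
#' Numerical Jacobian of the one-generation map restricted to `m - 1` free
#' frequencies (the remaining one is `1 - sum` of the others), by central
#' finite differences with step `h`; one-sided differences are used (and
#' flagged) within `h` of the simplex boundary. Dropping the constrained
#' coordinate removes the spurious unit eigenvalue along the constraint. The
#' dropped coordinate defaults to the largest entry of `p`, which leaves
#' room to perturb every free coordinate even at corners and boundary
#' points; the eigenvalues at a fixed point do not depend on this choice.
#'
#' @param p Frequency vector (an equilibrium, usually).
#' @param scheme A `"conformity_scheme"`.
#' @param h Finite-difference step.
#' @param drop Index of the coordinate eliminated by the constraint.
#' @return An `(m-1) x (m-1)` matrix with attribute `one_sided` (logical,
#'   per free coordinate).
#' @export
simplex_jacobian <- function(p, scheme, h = 1e-6, drop = which.max(p)) {
  stopifnot(inherits(scheme, "conformity_scheme"))
  p <- check_simplex(p, m = scheme$m)
  m <- scheme$m
  drop <- check_count(drop, "drop")
  if (drop > m) stop("`drop` must be a coordinate index", call. = FALSE)
  q <- p[-drop]
  p_drop <- p[drop]
  J <- matrix(NA_real_, m - 1L, m - 1L)
  one_sided <- logical(m - 1L)
  for (j in seq_len(m - 1L)) {
    can_down <- q[j] >= h          # lowering q_j raises the dropped entry
    can_up <- p_drop >= h          # raising q_j lowers the dropped entry
    if (can_down && can_up) {
      qp <- q; qp[j] <- qp[j] + h
      qm <- q; qm[j] <- qm[j] - h
      J[, j] <- (simplex_map(qp, scheme, drop) -
                   simplex_map(qm, scheme, drop)) / (2 * h)
    } else if (can_up) {
      qp <- q; qp[j] <- qp[j] + h
      J[, j] <- (simplex_map(qp, scheme, drop) -
                   simplex_map(q, scheme, drop)) / h
      one_sided[j] <- TRUE
    } else if (can_down) {
      qm <- q; qm[j] <- qm[j] - h
      J[, j] <- (simplex_map(q, scheme, drop) -
                   simplex_map(qm, scheme, drop)) / h
      one_sided[j] <- TRUE
    } else {
      stop("simplex too small for finite-difference step h = ", h,
           call. = FALSE)
    }
  }
  structure(J, one_sided = one_sided)
}

eigen_verdict <- function(moduli) {
  if (any(abs(moduli - 1) <= STABILITY_TOL)) {
    "marginal"
  } else if (all(moduli < 1)) {
    "stable"
  } else {
    "unstable"
  }
}

classify_point_kind <- function(p, tol = 1e-8) {
  m <- length(p)
  support <- which(p > tol)
  l <- length(support)
  equal_split <- all(abs(p[support] - 1 / l) < tol)
  if (l == 1L) {
    "corner"
  } else if (equal_split && l == m) {
    "central"
  } else if (equal_split) {
    "boundary_equal_split"
  } else {
    "interior_asymmetric"
  }
}

#' Stability report for one equilibrium point
#'
#' Verifies that `p` is a fixed point of the recursion (residual below
#' `residual_tol`), classifies its kind, computes the Jacobian eigenvalues in
#' simplex coordinates and issues a verdict: `"stable"` when every eigenvalue
#' modulus is below `1 - 1e-9`, `"marginal"` when any modulus is within
#' `1e-9` of 1, `"unstable"` otherwise. Analytic checks (corner coefficient
#' sign, central alpha condition) are attached where they apply.
#'
#' @param p A fixed point of the scheme's recursion.
#' @param scheme A `"conformity_scheme"`.
#' @param residual_tol Largest acceptable fixed-point residual (sup norm).
#' @return An object of class `"equilibrium_report"`.
#' @examples
#' sc <- two_coefficient_scheme_n4_m3(-0.3, 0.9)
#' equilibrium_report(c(0.5, 0.5, 0), sc)   # stable boundary point
#' @export
equilibrium_report <- function(p, scheme, residual_tol = 1e-10) {
  p <- check_simplex(p, m = scheme$m)
  residual <- max(abs(step_frequencies(p, scheme) - p))
  if (residual > residual_tol) {
    stop("point is not a fixed point (residual ", format(residual), ")",
         call. = FALSE)
  }
  J <- simplex_jacobian(p, scheme)
  ev <- eigen(J, only.values = TRUE)$values
  kind <- classify_point_kind(p)
  analytic <- list()
  if (kind == "corner") {
    analytic$corner <- corner_stability(scheme)
  } else if (kind == "central") {
    analytic$central <- alpha_statistic(scheme)
  }
  structure(
    list(point = p, kind = kind, residual = residual, jacobian = J,
         eigenvalues = ev, moduli = Mod(ev), verdict = eigen_verdict(Mod(ev)),
         analytic = analytic),
    class = "equilibrium_report"
  )
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat("Equilibrium (", x$kind, "): (",
      paste(format(x$point, digits = 6), collapse = ", "), ")\n", sep = "")
  cat("  eigenvalue moduli:", format(x$moduli, digits = 6), "\n")
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}

#' Locate fixed points of the recursion by Newton search
#'
#' Runs a damped Newton iteration on `F(q) = step(q) - q` in simplex
#' coordinates from each seed, drops seeds that fail to converge, removes
#' duplicates, and returns an [equilibrium_report()] for each distinct fixed
#' point found. The default seeds are the symmetric catalogue plus (for
#' `m = 3`) a triangular lattice with spacing 0.05, which covers the
#' equal-pair lines where asymmetric interior equilibria are found.
#'
#' @param scheme A `"conformity_scheme"`.
#' @param seeds Optional matrix of starting points (rows on the simplex).
#' @param lattice_spacing Spacing of the default `m = 3` seed lattice.
#' @param tol Convergence tolerance on the fixed-point residual (sup norm).
#' @param dedupe_tol Points closer than this (sup norm) are merged.
#' @param max_iter Newton iteration cap per seed.
#' @return A list of `"equilibrium_report"` objects, sorted by kind.
#' @examples
#' fps <- find_fixed_points(two_coefficient_scheme_n4_m3(-0.3, 0.9))
#' length(fps)  # 7 symmetric + 3 asymmetric interior
#' @export
find_fixed_points <- function(scheme, seeds = NULL, lattice_spacing = 0.05,
                              tol = 1e-12, dedupe_tol = 1e-8,
                              max_iter = 100L) {
  stopifnot(inherits(scheme, "conformity_scheme"))
  m <- scheme$m
  cat_pts <- symmetric_equilibria(m)$points
  if (is.null(seeds)) {
    seeds <- cat_pts
    if (m == 3L) {
      grid <- seq(lattice_spacing, 1 - lattice_spacing, by = lattice_spacing)
      lat <- expand.grid(p1 = grid, p2 = grid)
      lat <- lat[lat$p1 + lat$p2 < 1 - lattice_spacing / 2, ]
      seeds <- rbind(seeds, cbind(lat$p1, lat$p2, 1 - lat$p1 - lat$p2))
    }
  }

  found <- list()
  for (s in seq_len(nrow(seeds))) {
    q <- check_simplex(seeds[s, ], m = m)[-m]
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      p_full <- c(q, 1 - sum(q))
      if (any(p_full < -1e-12)) break
      Fq <- simplex_map(q, scheme, m) - q
      if (max(abs(Fq)) < tol) {
        converged <- TRUE
        break
      }
      JG <- tryCatch(
        simplex_jacobian(p_full, scheme, drop = m) - diag(m - 1L),
        error = function(e) NULL
      )
      delta <- if (is.null(JG)) NULL else {
        tryCatch(solve(JG, Fq), error = function(e) NULL)
      }
      if (is.null(delta)) break
      # damp: keep the full coordinate vector inside the closed simplex
      lambda <- 1
      repeat {
        q_new <- q - lambda * delta
        p_new <- c(q_new, 1 - sum(q_new))
        if (all(p_new >= -1e-12)) break
        lambda <- lambda / 2
        if (lambda < 1e-8) break
      }
      if (lambda < 1e-8) break
      q <- pmin(pmax(q - lambda * delta, 0), 1)
    }
    if (!converged) next
    p_fix <- pmax(c(q, 1 - sum(q)), 0)
    p_fix <- p_fix / sum(p_fix)
    dup <- any(vapply(found, function(g) max(abs(g - p_fix)) < dedupe_tol,
                      logical(1)))
    if (!dup) found[[length(found) + 1L]] <- p_fix
  }

  reports <- lapply(found, function(p) {
    tryCatch(equilibrium_report(p, scheme, residual_tol = 1e-8),
             error = function(e) NULL)
  })
  reports <- Filter(Negate(is.null), reports)
  kind_order <- c(corner = 1L, boundary_equal_split = 2L, central = 3L,
                  interior_asymmetric = 4L)
  reports[order(kind_order[vapply(reports, `[[`, "", "kind")])]
}
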