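test_that("the symmetric catalogue has 2^m - 1 equal-split points", {
  cat3 <- symmetric_equilibria(3)
  expect_equal(nrow(cat3$points), 7L)
  expect_equal(sum(cat3$kind == "corner"), 3L)
  expect_equal(sum(cat3$kind == "boundary_equal_split"), 3L)
  expect_equal(sum(cat3$kind == "central"), 1L)

  cat2 <- symmetric_equilibria(2)
  expect_setequal(apply(cat2$points, 1, paste, collapse = ","),
                  c("1,0", "0,1", "0.5,0.5"))
})

test_that("every catalogued point is fixed under seeded admissible schemes", {
  set.seed(61)
  for (rep in 1:20) {
    n <- sample(3:6, 1)
    m <- sample(2:4, 1)
    sc <- random_classification_scheme(n, m)
    pts <- symmetric_equilibria(m)$points
    for (i in seq_len(nrow(pts))) {
      expect_lt(max(abs(step_frequencies(pts[i, ], sc) - pts[i, ])), 1e-12)
    }
  }
})

test_that("interior equilibria for n = 4, m = 3 follow the closed form", {
  ie <- interior_equilibria_n4_m3(-0.3, 0.9)
  expect_false(ie$degenerate)
  expect_equal(ie$points[1, ], c(7 / 11, 2 / 11, 2 / 11),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(ie$valid))
  expect_equal(ie$two_dprime_plus_3d, 2.1)
  expect_equal(ie$four_dprime_plus_3d, 1.5)
  # each point is an exact fixed point of the closed-form recursion
  for (i in 1:3) {
    p <- ie$points[i, ]
    expect_lt(max(abs(step_closed_form_n4_m3(p, -0.3, 0.9) - p)), 1e-12)
  }

  # sign condition fails: coordinates leave (0, 1)
  ie_bad <- interior_equilibria_n4_m3(0.5, 0.5)
  expect_false(any(ie_bad$valid))

  # degenerate denominator 2D' - 3D = 0
  ie_deg <- interior_equilibria_n4_m3(0.75, 0.5)
  expect_true(ie_deg$degenerate)
  expect_null(ie_deg$points)

  # validity boundary: D' = -(3/2) D collapses onto a symmetric point
  ie_col <- interior_equilibria_n4_m3(-0.75, 0.5)
  expect_equal(ie_col$points[1, 1], 0, ignore_attr = TRUE)
})

test_that("alpha reduces to 2D/9 for the single-coefficient scheme", {
  for (D in c(-1.5, -0.5, 0.5)) {
    a <- alpha_statistic(single_coefficient_scheme(D))
    expect_equal(a$alpha, 2 * D / 9, tolerance = 1e-14)
    # centre stable exactly when D < 0 (multiplier 1 + D/3)
    expect_equal(a$multiplier, 1 + D / 3, tolerance = 1e-14)
    expect_equal(a$verdict, if (D < 0) "stable" else "unstable")
  }
  a0 <- alpha_statistic(classification_scheme(3, 3, d = 0))
  expect_equal(a0$alpha, 0)
  expect_equal(a0$verdict, "marginal")
})

test_that("alpha for the n = 4 scheme encodes the 4D' + 3D boundary", {
  for (par in list(c(-0.3, 0.9), c(-0.9, 0.4), c(0.5, -1.2))) {
    a <- alpha_statistic(two_coefficient_scheme_n4_m3(par[1], par[2]))
    expect_equal(a$alpha, (4 * par[1] + 3 * par[2]) / 27, tolerance = 1e-13)
    want <- if (4 * par[1] + 3 * par[2] < 0) "stable" else "unstable"
    expect_equal(a$verdict, want)
  }
})

test_that("corner stability is the sign of D_1 at near-fixation", {
  expect_equal(corner_stability(single_coefficient_scheme(0.5))$verdict,
               "stable")
  expect_equal(corner_stability(single_coefficient_scheme(-0.5))$verdict,
               "unstable")
  expect_equal(corner_stability(two_coefficient_scheme_n4_m3(-0.3, 0.9))$verdict,
               "unstable")
  expect_equal(corner_stability(two_coefficient_scheme_n4_m3(0.3, -0.9))$verdict,
               "stable")
})

test_that("the numerical Jacobian matches analytic multipliers", {
  # unbiased scheme: identity map, identity Jacobian
  J0 <- simplex_jacobian(rep(1 / 3, 3), classification_scheme(4, 3, d = 0))
  expect_equal(unclass(J0), diag(2), tolerance = 1e-9, ignore_attr = TRUE)

  # centre multiplier 1 + D/3 (double eigenvalue) for n = 3
  D <- -0.8
  J <- simplex_jacobian(rep(1 / 3, 3), single_coefficient_scheme(D))
  expect_equal(sort(Mod(eigen(J, only.values = TRUE)$values)),
               rep(abs(1 + D / 3), 2), tolerance = 1e-6)

  # corner multiplier 1 - alpha-free analytic: verdicts must agree
  set.seed(62)
  for (rep in 1:10) {
    sc <- random_classification_scheme(sample(3:5, 1), 3)
    r <- equilibrium_report(c(1, 0, 0), sc)
    cs <- corner_stability(sc)
    if (cs$verdict != "marginal" && r$verdict != "marginal") {
      expect_equal(r$verdict, cs$verdict)
    }
    rc <- equilibrium_report(rep(1 / 3, 3), sc)
    ca <- alpha_statistic(sc)
    if (ca$verdict != "marginal" && rc$verdict != "marginal") {
      expect_equal(rc$verdict, ca$verdict)
    }
  }
})

test_that("boundary stability window matches -(3/2)D < D' < 0", {
  grid <- expand.grid(D_prime = c(-1.4, -0.6, -0.2, 0.4),
                      D = c(-1.2, 0.5, 1.1))
  for (i in seq_len(nrow(grid))) {
    Dp <- grid$D_prime[i]
    D <- grid$D[i]
    sc <- two_coefficient_scheme_n4_m3(Dp, D)
    r <- equilibrium_report(c(0, 0.5, 0.5), sc)
    want <- if (Dp < 0 && Dp > -1.5 * D) "stable" else "unstable"
    if (abs(Dp + 1.5 * D) > 1e-3) {  # skip the marginal boundary itself
      expect_equal(r$verdict, want,
                   info = sprintf("D'=%g D=%g", Dp, D))
    }
  }
})

test_that("equilibrium reports reject non-fixed points", {
  sc <- single_coefficient_scheme(-0.5)
  expect_error(equilibrium_report(c(0.5, 0.3, 0.2), sc), "not a fixed point")
})

test_that("fixed-point search recovers the catalogue and nothing else", {
  # n = 3: only the 7 symmetric equilibria exist
  fps <- find_fixed_points(single_coefficient_scheme(-0.9))
  expect_equal(length(fps), 7L)
  kinds <- vapply(fps, `[[`, "", "kind")
  expect_equal(sum(kinds == "corner"), 3L)
  expect_equal(sum(kinds == "central"), 1L)

  # n = 4 with mixed signs: 7 symmetric + 3 asymmetric interior
  fps4 <- find_fixed_points(two_coefficient_scheme_n4_m3(-0.3, 0.9))
  expect_equal(length(fps4), 10L)
  kinds4 <- vapply(fps4, `[[`, "", "kind")
  expect_equal(sum(kinds4 == "interior_asymmetric"), 3L)
  ie <- interior_equilibria_n4_m3(-0.3, 0.9)
  found_interior <- t(vapply(fps4[kinds4 == "interior_asymmetric"],
                             `[[`, numeric(3), "point"))
  for (i in 1:3) {
    expect_true(any(apply(found_interior, 1, function(q) {
      max(abs(q - ie$points[i, ])) < 1e-6
    })))
  }
})
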