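test_that("class partition follows the n/r average-representation rule", {
  # worked sample of 100 role models across 7 of 10 variants
  x100 <- c(25, 20, 20, 10, 10, 10, 5, 0, 0, 0)
  cls <- classify_configuration(x100)
  expect_equal(cls$r, 7L)
  expect_equal(cls$II, 1:3)          # 25, 20, 20 above 100/7
  expect_equal(cls$III, 4:7)         # 10, 10, 10, 5 below 100/7
  expect_equal(cls$I, 8:10)

  # fixation: everything in class I
  cls_fix <- classify_configuration(c(4, 0, 0))
  expect_equal(cls_fix$I, 1:3)
  expect_length(cls_fix$II, 0)

  # n = 4, (3, 1, 0): threshold n/r = 2
  cls31 <- classify_configuration(c(3, 1, 0))
  expect_equal(cls31$II, 1L)
  expect_equal(cls31$III, 2L)
  expect_equal(cls31$I, 3L)

  # class II empty iff class III empty, over a full enumeration
  for (x in asplit(enumerate_configurations(6, 4), 1)) {
    cls <- classify_configuration(x)
    expect_equal(length(cls$II) == 0, length(cls$III) == 0)
  }
})

test_that("g-weights reproduce the worked n = 100 coefficients", {
  g <- g_weights(c(25, 20, 20, 10, 10, 10, 5, 0, 0, 0))
  expect_equal(g[1], 25 / 65)
  expect_equal(g[2], 20 / 65)
  expect_equal(g[4], -0.2)
  expect_equal(g[7], -0.4)
  expect_equal(g[8:10], rep(0, 3))
  # shares of +d and -d each sum to one
  expect_equal(sum(g[1:3]), 1)
  expect_equal(sum(g[4:7]), -1)
})

test_that("g-weights sum to +1 over class II and -1 over class III", {
  for (nm in list(c(4, 3), c(5, 3), c(6, 4))) {
    cfg <- enumerate_configurations(nm[1], nm[2])
    for (x in asplit(cfg, 1)) {
      cls <- classify_configuration(x)
      g <- g_weights(x)
      if (length(cls$II)) {
        expect_equal(sum(g[cls$II]), 1)
        expect_equal(sum(g[cls$III]), -1)
      } else {
        expect_equal(g, rep(0, length(x)))
      }
    }
  }
})

test_that("admissibility intervals for d(x) match the known endpoints", {
  expect_equal(as.numeric(d_bounds(c(3, 1, 0))), c(-3, 1))
  expect_equal(as.numeric(d_bounds(c(2, 1, 0))), c(-2, 1))
  expect_equal(as.numeric(d_bounds(c(2, 1, 1))), c(-2, 2))
  inert <- d_bounds(c(2, 2, 0))
  expect_true(attr(inert, "inert"))
  expect_equal(as.numeric(inert), c(-Inf, Inf))
})

test_that("d inside its bounds keeps adoption probabilities in [0, 1]", {
  set.seed(21)
  cfg <- enumerate_configurations(5, 3)
  for (x in asplit(cfg, 1)) {
    b <- d_bounds(x)
    if (isTRUE(attr(b, "inert"))) next
    g <- g_weights(x)
    for (d in seq(b[1] + 1e-6, b[2] - 1e-6, length.out = 9)) {
      pr <- x / 5 + g * d / 5
      expect_true(all(pr >= -1e-12 & pr <= 1 + 1e-12))
      expect_equal(sum(pr), 1)
    }
  }
})

test_that("uniform lower bound tightens with the sample size", {
  expect_equal(uniform_d_lower_bound(3, 3), -2)
  expect_equal(uniform_d_lower_bound(15, 3), -6)
  expect_equal(uniform_d_lower_bound(4, 3), -2)
})

test_that("adoption probabilities follow x/n + D/n", {
  sc <- single_coefficient_scheme(0.5)
  expect_equal(adoption_probabilities(c(2, 1, 0), sc),
               c(2 / 3 + 0.5 / 3, 1 / 3 - 0.5 / 3, 0))
  # even split: unbiased regardless of D
  expect_equal(adoption_probabilities(c(1, 1, 1), sc), rep(1 / 3, 3))
  # fixation sample: deterministic adoption
  expect_equal(adoption_probabilities(c(3, 0, 0), sc), c(1, 0, 0))
})

test_that("the n = 3 scheme matches its symmetry-derived table", {
  sc <- single_coefficient_scheme(0.5)
  expect_equal(scheme_coefficients(sc, c(2, 1, 0)), c(0.5, -0.5, 0))
  expect_equal(scheme_coefficients(sc, c(1, 2, 0)), c(-0.5, 0.5, 0))
  expect_equal(scheme_coefficients(sc, c(0, 2, 1)), c(0, 0.5, -0.5))
  expect_equal(scheme_coefficients(sc, c(3, 0, 0)), rep(0, 3))
  expect_equal(scheme_coefficients(sc, c(1, 1, 1)), rep(0, 3))
  expect_error(single_coefficient_scheme(1.2), "outside the open interval")
  expect_error(single_coefficient_scheme(-2), "outside the open interval")
})

test_that("the n = 4, m = 3 scheme satisfies its forced structure", {
  sc <- two_coefficient_scheme_n4_m3(-0.3, 0.9)
  expect_equal(scheme_coefficients(sc, c(3, 1, 0)), c(-0.3, 0.3, 0))
  expect_equal(scheme_coefficients(sc, c(2, 1, 1)), c(0.9, -0.45, -0.45))
  expect_equal(scheme_coefficients(sc, c(2, 2, 0)), rep(0, 3))
  expect_equal(scheme_coefficients(sc, c(4, 0, 0)), rep(0, 3))
  expect_equal(rowSums(sc$D), rep(0, 15))
  expect_error(two_coefficient_scheme_n4_m3(-3.5, 0), "outside the open")
  expect_error(two_coefficient_scheme_n4_m3(0.5, 2.5), "outside the open")
})

test_that("classification schemes reproduce the fixed-n parameterisations", {
  # n = 3: g(2,1,0) = (1, -1, 0), so constant d = D recovers the scheme
  sc3 <- single_coefficient_scheme(-1.2, m = 4)
  cl3 <- classification_scheme(3, 4, d = -1.2)
  expect_equal(sc3$D, cl3$D)
  # n = 4: per-type d-table recovers the two-coefficient scheme
  sc4 <- two_coefficient_scheme_n4_m3(0.4, -0.7)
  cl4 <- classification_scheme(4, 3, d = c("3,1,0" = 0.4, "2,1,1" = -0.7))
  expect_equal(sc4$D, cl4$D)
})

test_that("inadmissible d(x) is rejected with the offending configuration", {
  expect_error(classification_scheme(15, 3, d = -6.5),
               "outside its admissible interval")
  expect_error(classification_scheme(3, 3, d = 1.5), "2,1,0")
})

test_that("axiom validation passes constructed schemes and flags breakage", {
  expect_equal(nrow(validate_scheme(single_coefficient_scheme(0.5))), 0L)
  expect_equal(nrow(validate_scheme(two_coefficient_scheme_n4_m3(-0.3, 0.9))),
               0L)

  base <- single_coefficient_scheme(0.5)
  # bound violation: D_1(2,1,0) = 1.5 >= n - x_1 = 1
  broken <- base$D
  i210 <- which(apply(base$configs, 1, paste, collapse = ",") == "2,1,0")
  broken[i210, ] <- c(1.5, -1.5, 0)
  v <- validate_scheme(conformity_scheme(3, 3, broken, validate = FALSE))
  expect_true("bound" %in% v$rule)
  expect_true("2,1,0" %in% v$configuration[v$rule == "bound"])

  # zero-sum violation
  broken2 <- base$D
  broken2[i210, ] <- c(0.5, -0.4, 0)
  v2 <- validate_scheme(conformity_scheme(3, 3, broken2, validate = FALSE))
  expect_true("zero_sum" %in% v2$rule)
  expect_true("2,1,0" %in% v2$configuration[v2$rule == "zero_sum"])

  # absent-variant violation: nonzero coefficient where x_i = 0
  broken3 <- base$D
  broken3[i210, ] <- c(0.3, 0.2, -0.5)
  v3 <- validate_scheme(conformity_scheme(3, 3, broken3, validate = FALSE))
  expect_true("absent_variant" %in% v3$rule)

  # the validating constructor refuses the broken table outright
  expect_error(conformity_scheme(3, 3, broken), "axioms")
})

test_that("random classification schemes satisfy all axioms", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(3:6, 1)
    m <- sample(2:4, 1)
    sc <- random_classification_scheme(n, m)
    expect_equal(nrow(validate_scheme(sc)), 0L,
                 info = sprintf("n=%d m=%d rep=%d", n, m, rep))
  }
})

test_that("coefficients vanish at fixation and integer equal splits", {
  set.seed(41)
  sc <- random_classification_scheme(6, 4)
  for (x in list(c(6, 0, 0, 0), c(3, 3, 0, 0), c(2, 2, 2, 0),
                 c(0, 3, 0, 3), c(2, 0, 2, 2))) {
    expect_equal(scheme_coefficients(sc, x), rep(0, 4),
                 info = paste(x, collapse = ","))
  }
})

test_that("parameters near an admissibility endpoint warn but build", {
  w <- capture_warnings(sc <- single_coefficient_scheme(-2 + 1e-10))
  expect_true(any(grepl("endpoint", w)))
  expect_s3_class(sc, "conformity_scheme")
})
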