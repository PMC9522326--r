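# Shared fixtures and independent oracles for the test suite.

# Brute-force enumeration of compositions of n into m parts via expand.grid;
# independent of the package's recursive enumerator.
brute_force_configurations <- function(n, m) {
  grid <- as.matrix(expand.grid(rep(list(0:n), m)))
  grid <- grid[rowSums(grid) == n, , drop = FALSE]
  dimnames(grid) <- NULL
  grid
}

# One-generation recursion straight from its definition: the expectation of
# the adoption probabilities over the multinomial sample distribution,
# p'_i = sum_x P(A_i | x) P(x), with P(x) from stats::dmultinom. A different
# formula, enumeration and probability routine than the engine's
# p + crossprod(D, P)/n path.
oracle_step <- function(p, scheme) {
  grid <- brute_force_configurations(scheme$n, scheme$m)
  pp <- numeric(scheme$m)
  for (i in seq_len(nrow(grid))) {
    x <- grid[i, ]
    pp <- pp + adoption_probabilities(x, scheme) *
      stats::dmultinom(x, prob = p)
  }
  pp
}

# Interior Dirichlet(1) point, for property tests (assumes RNG already seeded).
rand_simplex <- function(m) {
  x <- stats::rexp(m)
  x / sum(x)
}

# The distinct unordered configuration types of (n, m), as sorted-descending
# key strings.
configuration_types <- function(n, m) {
  cfg <- enumerate_configurations(n, m)
  unique(apply(cfg, 1L, function(x) {
    paste(sort(x, decreasing = TRUE), collapse = ",")
  }))
}

# Random admissible classification scheme: one d per configuration type,
# drawn inside its admissibility interval. `sign` restricts the draw to
# strictly conformist (d > 0), strictly anticonformist (d < 0) or mixed.
# Draws d for a type from the interval of an arbitrary representative, which
# is the type's own interval (bounds are permutation-invariant). Assumes the
# RNG is already seeded.
random_classification_scheme <- function(n, m,
                                         sign = c("mixed", "conformist",
                                                  "anticonformist")) {
  sign <- match.arg(sign)
  types <- configuration_types(n, m)
  d <- vapply(types, function(key) {
    x <- as.integer(strsplit(key, ",")[[1]])
    b <- d_bounds(x, n = n)
    if (isTRUE(attr(b, "inert"))) return(0)
    u <- stats::runif(1, 0.2, 0.8)
    switch(sign,
           conformist = u * b[2L],
           anticonformist = u * b[1L],
           mixed = b[1L] + stats::runif(1, 0.15, 0.85) * (b[2L] - b[1L]))
  }, numeric(1))
  classification_scheme(n, m, d = d)
}

# Iterate in chunks until the trajectory has settled to a fixed point (or the
# generation cap is hit); returns the classification of the final chunk and
# the final point. Convergence under pure conformity can be slow when the
# initial top-two gap is tiny, so the cap is generous.
iterate_to_rest <- function(p0, scheme, chunk = 5000L, max_gens = 100000L) {
  p <- p0
  total <- 0L
  repeat {
    tr <- iterate_frequencies(p, scheme, chunk, classify = TRUE)
    total <- total + chunk
    if (tr$classification == "fixed_point" || total >= max_gens) {
      return(list(classification = tr$classification,
                  final = tr$history[nrow(tr$history), ],
                  generations = total))
    }
    p <- tr$history[nrow(tr$history), ]
  }
}
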