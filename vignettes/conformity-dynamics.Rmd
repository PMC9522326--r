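---
title: "Frequency dynamics under conformity and anticonformity with many variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency dynamics under conformity and anticonformity with many variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyconform)
```

## The model

A selectively neutral cultural trait has $m$ discrete variants
$A_1,\dots,A_m$ with population frequencies $p = (p_1,\dots,p_m)$ on the
$(m-1)$-simplex. Each offspring samples $n$ adult role models uniformly at
random and observes the sample configuration $x = (x_1,\dots,x_m)$,
$\sum_i x_i = n$, which occurs with multinomial probability

$$P(x) = \frac{n!}{x_1!\cdots x_m!}\,p_1^{x_1}\cdots p_m^{x_m}.$$

Transmission is frequency dependent: the probability of adopting $A_i$
after observing $x$ is

$$P(A_i \mid x) = \frac{x_i}{n} + \frac{D_i(x)}{n},$$

where the conformity coefficients $D_i(x)$ measure the deviation from
unbiased copying. Admissibility requires $-x_i < D_i(x) < n - x_i$ (each
adoption probability stays in $[0,1]$), $\sum_i D_i(x) = 0$ (they sum to
one), $D_i(x) = 0$ whenever $x_i = 0$ (variants absent from the sample are
never invented), and symmetry under relabelling of variants. Symmetry
forces $D(x) = 0$ at fixation samples $(n,0,\dots,0)$ and at every integer
equal split such as $(k,k,0,\dots)$ with $k = n/2$.

Averaging the adoption probabilities over samples gives the deterministic
one-generation recursion implemented by `step_frequencies()`:

$$p_i' = p_i + \frac{1}{n}\sum_x D_i(x)\,P(x).$$

Positive coefficients on over-represented variants are conformist (the
common become commoner); negative coefficients are anticonformist.

## One coefficient per sample configuration

With $n \ge 4$ there are many coefficient vectors, so the package supports
the class-based reduction to a single scalar $d(x)$ per unordered sample
type. With $r$ variants present in $x$, the average representation of a
present variant is $n/r$, and each count falls into class I (absent,
exactly average, or fixed), class II (above average) or class III (below
average). Then $D_i(x) = g_i(x)\,d(x)$ with

$$g_i(x) = \begin{cases}
0 & x_i \in \mathrm{I} \\
x_i \big/ \sum_{z \in \mathrm{II}} z & x_i \in \mathrm{II} \\
-\,x_i^{-1} \big/ \sum_{z \in \mathrm{III}} z^{-1} & x_i \in \mathrm{III},
\end{cases}$$

so the class II weights sum to $+1$, the class III weights to $-1$, and
within class III the rarest variants carry the largest (most negative)
share — a sample of 100 role models with counts
$(25, 20, 20, 10, 10, 10, 5)$ gives the 5-count variant weight $-0.4$,
double the $-0.2$ of each 10-count variant, while the 25-count variant
takes $25/65$ of the positive side:

```{r}
round(g_weights(c(25, 20, 20, 10, 10, 10, 5, 0, 0, 0)), 4)
```

The named small-sample schemes are special cases: `single_coefficient_scheme()`
($n = 3$, one coefficient $D \in (-2, 1)$), `two_coefficient_scheme_n4_m3()`
($n = 4$, $D' \in (-3,1)$ at type $(3,1,0)$ and $D \in (-2,2)$ at
$(2,1,1)$), and `four_coefficient_scheme_n5_m3()` ($n = 5$). For $n = 5$
the correspondence between the four printed coefficient labels and the four
sample types is not fixed by the sources available to us; this package
assigns them to the types $(4,1,0), (3,2,0), (3,1,1), (2,2,1)$ in
lexicographic-descending order. That convention is documented rather than
guaranteed, so $n = 5$ phase portraits should be treated qualitatively.

### Admissibility bounds for d(x)

`d_bounds()` returns the open interval of $d(x)$ values that keep every
adoption probability in $[0,1]$. The lower endpoint is
$-\sum_{z\in\mathrm{II}} z$: as anticonformity strengthens, the
most-represented variant's probability reaches 0 first. For the upper
endpoint this package uses the minimum of two constraints: the class II
constraint $\sum_{z\in\mathrm{II}} z\,(n/\max_i x_i - 1)$ (the leading
variant's probability reaches 1) **and** the class III constraint
$\min_{i\in\mathrm{III}} x_i^2 \sum_{z\in\mathrm{III}} z^{-1}$ (the rarest
below-average variant's probability reaches 0, because class III weights
are inversely proportional to counts). The class II constraint alone is
often quoted as the bound, but it is not sufficient: at $n = 5$,
$x = (2,2,1)$ it evaluates to 6, while $d = 2$ already drives the 1-count
variant's adoption probability to $1/5 - 2/5 < 0$; the class III
constraint (here 1) binds first. The two constraints coincide at every
configuration with a single class II member and a single class III member,
which covers all the named small-sample schemes, so the familiar endpoints
are unchanged:

```{r}
d_bounds(c(2, 1, 0))   # n = 3
d_bounds(c(3, 1, 0))   # n = 4
d_bounds(c(2, 1, 1))   # n = 4
```

For a configuration-independent coefficient $d(x) = D$, the binding lower
bound over all configurations is returned by `uniform_d_lower_bound()`;
it is $-2$ at $n = 3$ but widens to $-6$ at $n = 15$ (with $m = 3$), which
is what makes the strong-anticonformity regimes below possible.

## Equilibria and local stability

For any admissible symmetric scheme, every point with $l$ variants at
$1/l$ and the rest at 0 is an equilibrium (`symmetric_equilibria()`): $m$
corners, the equal-split boundary points, and the central polymorphism
$(1/m,\dots,1/m)$. Two analytic stability statistics are implemented:

* **Corners**: all $m$ corners are locally stable iff
  $D_1(n-1, 1, 0, \dots, 0) > 0$ (`corner_stability()`) — a conformist
  response to a lone deviant restores fixation.
* **Centre**: the central polymorphism is locally stable iff
  $\left|1 + \tfrac{m}{m-1}\alpha\right| < 1$, with
  $\alpha = \frac{1}{n\,m^{n-1}} \sum_x D_i(x)\,\binom{n}{x}\,x_i$
  (`alpha_statistic()`); for the $n=3$ scheme $\alpha = 2D/9$, so the
  centre is stable exactly under anticonformity ($D < 0$).

Mixed-sign schemes can add asymmetric interior equilibria. For $n = 4$,
$m = 3$ they have the closed form implemented by
`interior_equilibria_n4_m3()`, are valid only when $D'$ and $D$ have
opposite signs with $|D'| < \tfrac{3}{2}|D|$, and are always unstable —
they sit on the separatrices between basins of attraction:

```{r}
sc <- two_coefficient_scheme_n4_m3(-0.3, 0.9)
ie <- interior_equilibria_n4_m3(-0.3, 0.9)
ie$points[1, ]
equilibrium_report(ie$points[1, ], sc, residual_tol = 1e-8)$verdict
equilibrium_report(c(0.5, 0.5, 0), sc)$verdict
```

Numerical verdicts come from the Jacobian of the map restricted to the
simplex (`simplex_jacobian()`): central finite differences with step
$h = 10^{-6}$ on $m - 1$ free coordinates. The coordinate eliminated by
the constraint defaults to the largest entry of $p$, so the chart never
degenerates at corners or boundary points (one-sided differences are used,
and flagged, within $h$ of a face); eigenvalues at a fixed point do not
depend on the chart. An eigenvalue modulus within $10^{-9}$ of 1 is
reported as `"marginal"`, never silently as stable, because the analytic
stability conditions are strict inequalities. `find_fixed_points()` runs a
damped Newton search from the symmetric catalogue plus (for $m = 3$) a
triangular lattice with spacing 0.05, which covers the equal-pair lines
where asymmetric equilibria occur; the search is heuristic and reports what
it finds.

## Long-run behaviour

`classify_longrun()` labels a trajectory `"fixed_point"` when the sup-norm
one-generation change stays below $10^{-10}$ over the last 100
generations; otherwise `"cycle"` with the smallest period $k \le 64$ that
repeats to within $10^{-9}$ over the last $10k$ generations; otherwise
`"nonconvergent"`. "Exact" periodicity means machine precision of the
deterministic map, not rational exactness. Under pure conformity
($d(x) > 0$ everywhere) there is global convergence, and the limit is
known in advance: the $l$ variants that start tied at the maximum
frequency end at $1/l$ each and all others vanish
(`max_frequency_limit()`). Ties are detected by exact floating-point
equality — the tie is a symmetry property, preserved exactly by the map —
and the engine enforces that exactly-equal frequencies remain exactly
equal, since an unstable tie would otherwise be broken by an ulp of
floating-point summation noise and amplified exponentially.

Strong anticonformity with many role models behaves differently: a rare
variant can be favoured so strongly that it overshoots the centre, and the
overshoot can repeat forever. At $n = 15$, $m = 3$, constant
$d(x) = -5.9$ from $p_0 = (0.48, 0.501, 0.019)$ the trajectory settles on
an attracting two-generation cycle; with each $d(x)$ just above its own
lower bound the fluctuations become aperiodic:

```{r}
sc_cycle <- classification_scheme(15, 3, d = -5.9)
tr <- iterate_frequencies(c(0.48, 0.501, 0.019), sc_cycle, 10000)
tr$summary$period
round(tr$summary$cycle_points, 3)

sc_chaos <- classification_scheme(15, 3, d = function(x) d_bounds(x)[1] + 0.1)
tr2 <- iterate_frequencies(c(0.48, 0.501, 0.019), sc_chaos, 10000)
tr2$classification
round(ergodic_mean(tr2, 5000), 3)
```

The transient onto the $d = -5.9$ cycle decays by roughly a factor of 10
per 1,000 generations, so the lag-2 residual crosses the $10^{-9}$ cycle
tolerance only after about 6,000 generations; runs of 10,000 generations
(as above) classify cleanly.

`sensitivity_diagnostic()` supports the "chaotic" label with a
largest-Lyapunov-style estimate: a twin trajectory offset by
$\delta = 10^{-9}$ is iterated alongside the reference and renormalised to
separation $\delta$ each generation (the difference is projected onto the
zero-sum tangent space so both trajectories stay on the simplex). The mean
log growth rate is negative in fixed-point and cycle regimes and positive
in the aperiodic regime. It is a diagnostic, not a proof: the rate is
computed for any trajectory, and a positive value labels the run chaotic
in the same informal sense used when inspecting such figures.

## Numerical choices

* Multinomial coefficients are computed as products of binomials, exact in
  double precision throughout the supported range ($n \le 18$); all other
  arithmetic is double precision. No exact-rational mode is provided — the
  test suite uses `stats::dmultinom` and brute-force enumeration as
  independent oracles instead, and the closed forms for $n = 3$ and
  $n = 4, m = 3$ cross-check the general engine to $10^{-12}$.
* The engine precomputes the configuration enumeration, multinomial
  coefficients and coefficient table once per scheme; a step costs
  $O(Km)$ for $K = \binom{m-1+n}{n}$ configurations ($K = 136$ at
  $n = 15$, $m = 3$; 10,000 generations take well under a second).
* Strict admissibility inequalities are enforced with slack $10^{-12}$;
  parameters within $10^{-9}$ of an endpoint build with a warning, since
  regimes of interest sit deliberately close to the bounds.
* After a step, frequencies in $[-10^{-12}, 0)$ are snapped to 0 (rounding
  noise near an absorbing face: the exact value is a nonnegative sum of
  probabilities); anything more negative raises an error rather than
  masking an inadmissible scheme. A variant at exactly 0 stays exactly 0,
  because its coefficients vanish by the absent-variant axiom and its
  sample probabilities vanish identically.
* Scheme-axiom validation checks relabelling equivariance over all $m!$
  permutations for $m \le 5$ and over a generating set of the symmetric
  group for larger $m$ (equivariance under generators implies the full
  group).

## Problem sizes in the test suite

The convergence property tests iterate 200 seeded interior starts at
$n = 3$ (100 anticonformist draws $D \sim U(-1.9, -0.1)$, 100 conformist
draws $D \sim U(0.3, 0.9)$ — moderate conformity being the realistic
regime, and weak conformity merely slow, not different in outcome) and 20
strictly conformist state-dependent schemes with $n \le 6$, $m \le 4$ and
$d(x)$ drawn uniformly inside $(0.2, 0.8)$ of its admissible range. Runs
iterate in 5,000-generation chunks until the fixed-point criterion is met
(capped at $10^5$ generations), because the approach to a corner slows as
the initial top-two gap shrinks. Invariant properties (simplex
conservation, absorption of absent variants, permutation equivariance) are
checked over 500 random scheme/point cases at $n \le 6$, $m \le 4$.

## What the generated data do and do not show

All inputs are model parameters; there is no external data. Random
fixtures are Dirichlet(1) simplex points and coefficient draws inside the
admissibility intervals, under fixed seeds. Passing tests therefore
certify the mathematical behaviour of the deterministic recursion — not
that any real population conforms to it: real transmission involves finite
populations (drift), selection, content and demonstrator biases, network
structure in who is sampled, and time-varying coefficients, all outside
this model. The package is a tool for exploring the idealised dynamics and
for generating exact expectations against which such complications can be
compared.

## Known limitations

* The fixed-point search cannot certify completeness; for $n \ge 5$ there
  may be additional asymmetric equilibria it does not find from its seed
  lattice.
* Cycle detection is capped at period 64 and bounded by its tolerances; a
  cycle with an extremely slow transient would be reported nonconvergent
  at short run lengths.
* The divergence-rate diagnostic is a numerical estimate, not interval
  arithmetic; near a bifurcation its sign can be delicate.
* Enumeration is dense: cost grows as $\binom{m-1+n}{n}$, so very large
  $n$ and $m$ (say $n > 60$ at $m = 5$) become slow and memory-heavy.
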