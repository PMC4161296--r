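---
title: "Discovery times on broad-peak fitness landscapes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovery times on broad-peak fitness landscapes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakwalk)
```

## The model

We consider a haploid, asexually reproducing population of size $N$ evolving a
sequence of length $L$ over an alphabet of size $A$ (default `ACGT`, $A=4$).
The mutation rate is low enough that mutations arise and are resolved one at a
time (the sequential-fixation or origin–fixation regime), so the population is
effectively monomorphic and performs a walk on the sequence space: the graph
whose $A^L$ vertices are sequences and whose edges join sequences at Hamming
distance one.

One *event* is one proposed point mutation: a uniformly chosen position is
changed to a uniformly chosen different letter, i.e. a uniform draw among the
$L(A-1)$ neighbors. The proposal then fixes with the Moran probability
$$\rho(r, N) = \frac{1 - 1/r}{1 - 1/r^N},$$
where $r$ is the mutant-to-resident fitness ratio; $\rho = 1/N$ at $r = 1$.
The per-event acceptance probability is $\min(1, N\rho)$, which equals 1 on a
flat landscape — neutral evolution is a simple random walk on the Hamming
graph. All times reported by the package are in events (proposed mutations);
to convert to generations divide by $Nu$ with $u$ the per-sequence mutation
rate per generation.

A *broad peak* is the target set $\{s : d(s, s_0) \le w\}$ around a center
$s_0$, with radius $w = \lfloor cL \rfloor$ for a width fraction $c$. Its
volume, `ball_volume(L, w, A)` $= \sum_{i \le w} \binom{L}{i}(A-1)^i$, is
exponential in $L$ for fixed $c > 0$ — broad peaks are *huge* targets, which
makes the negative results below the more striking. Multi-peak landscapes take
a union of $m$ such balls; multiplicative-gradient landscapes assign fitness
$(1+\sigma)^{L-d}$ so that every step toward the center is favored.

### Discovery convention

Discovery is declared the first time a *target sequence is proposed*, whether
or not that mutant would ultimately fix. Rationale: the question is when the
function is first found; for neutral or advantageous targets, fixation after
discovery is fast and independent of $L$-scaling. The alternative
(discovery at fixation) is available via the `discovery = "fixation"` switch
in `selection_chain()` and the simulators. On neutral landscapes — every
quantitative check in the test suite — the two conventions coincide exactly.

## The one-dimensional projection

For a single centered ball target, the landscape is invariant under
permutations fixing the center, so the Hamming distance $k$ to the center is a
Markov chain — a birth–death chain on $\{0, \dots, L\}$. Per event, from
distance $k$:

* $p_{\mathrm{down}} = \dfrac{k}{L(A-1)}$ — a mismatched position reverts;
* $p_{\mathrm{up}} = \dfrac{L-k}{L}$ — a matched position mutates away;
* $p_{\mathrm{stay}} = \dfrac{k(A-2)}{L(A-1)}$ — wrong letter to another
  wrong letter (absent for $A = 2$).

`neutral_chain()` builds this chain; `selection_chain()` weights the moves by
$\min(1, N\rho)$ at the shell-to-shell fitness ratio and returns the residual
mass to $p_{\mathrm{stay}}$. The projection identity is verified empirically:
the full-space simulator and the chain simulator agree in distribution
(Kolmogorov–Smirnov test in the acceptance suite at $L=8$).

## Exact expected discovery times

Writing $H(k)$ for the expected number of events to reach the target from
distance $k$, the first-step recurrence
$$H(k) = 1 + p_{\mathrm{down}}H(k-1) + p_{\mathrm{stay}}H(k) +
p_{\mathrm{up}}H(k+1), \qquad H(k \le w) = 0,$$
is a tridiagonal linear system. Two implementations are provided and
cross-checked to $10^{-9}$ relative:

* `hitting_linear_solve()` eliminates the system from the reflecting boundary
  $k = L$ downward. These systems are spectacularly ill-conditioned — the
  condition number grows like $H$ itself, which exceeds $10^{100}$ in regimes
  we care about — so a textbook Thomas sweep or dense LU returns garbage past
  $H \sim 10^{16}$. The implementation instead uses the stochasticity
  identity $1 - p_{\mathrm{stay}} = p_{\mathrm{down}} + p_{\mathrm{up}}$ to
  make the elimination subtraction-free (the same device that makes the GTH
  algorithm for Markov steady states entrywise accurate); every operation
  combines non-negative quantities and full double precision survives up to
  overflow at $10^{308}$.
* `hitting_forward_sum()` evaluates the increment sequence
  $t_L = 1/p_{\mathrm{down}}(L)$,
  $t_k = (1 + p_{\mathrm{up}}(k)\, t_{k+1}) / p_{\mathrm{down}}(k)$, and
  $H(k) = \sum_{j=w+1}^{k} t_j$, entirely in log space with log-sum-exp, so
  values remain finite and self-consistent far beyond double overflow
  (e.g. $L = 1500$). Self-loops are real events; the recurrence conditions
  them out algebraically rather than simulating them.

The two routes share their algebra (the increment form is derived from the
recurrence), so their agreement is a check on the numerical machinery —
linear-scale elimination versus log-space evaluation — not an independent
derivation. Genuinely independent checks of $H$ are therefore also included:
the tail-sum identity $E[T] = \sum_{T \ge 0} P(T_{\mathrm{hit}} > T)$ against
the finite-horizon dynamic program (`success_within()`), and Monte-Carlo
means from both simulators.

`success_within(chain, start, T)` propagates the state distribution $T$ steps
and accumulates absorbed mass — exact, $O(TL)$, and the oracle for every
simulation-based experiment below.

## The dichotomy and its classifier

The neutral stationary measure over distance shells is
$\binom{L}{k}(A-1)^k$, maximal at the drift equilibrium
$k^* \approx L(1 - 1/A)$ ($3L/4$ for DNA). Below $k^*$ mutation pressure
pushes the walk outward; above, inward. Consequently:

* if the target boundary covers the equilibrium ($w \ge k^*$, i.e.
  $c > 1 - 1/A$), drift delivers the walk into the target and the expected
  discovery time is polynomial in $L$;
* if the boundary falls short by a macroscopic fraction of $L$, the walk must
  cross a region where $t_k$ grows geometrically (each state multiplies the
  time by $\approx p_{\mathrm{up}}/p_{\mathrm{down}} > 1$), and the time is
  exponential in $L$ — *regardless of how close the start is*: even from
  $w + 3$, three geometric factors of the barrier remain and the growth scan
  still fits a clean exponential.

`classify_time_scale()` implements the dichotomy as a drift-balance test that
works for arbitrary (including selection-weighted) chains: it computes the
chain's stationary mode $k^*$ from the detailed-balance ratios
$\pi_{k+1}/\pi_k = p_{\mathrm{up}}(k)/p_{\mathrm{down}}(k+1)$ and compares it
with $w$. The verdict is *polynomial* when $w \ge k^*$, *exponential* when
$k^* - w \ge \delta L$, and *critical* in the $\delta$-band between. We chose
this over a literal "scan for a $\delta L$-long run of states with
$p_{\mathrm{up}}/p_{\mathrm{down}} \ge 1+\delta$" because the mode comparison
flips exactly where the boundary crosses the drift equilibrium
(the transition the theory pinpoints), whereas run-length scans leave an
off-by-a-few indeterminate gap at every finite $L$. The margin defaults to
$\delta = 0.01$: at the desk scales we target ($L \le 200$) this leaves the
flip sharp while still refusing to call near-critical chains. Verdicts are
invariant to uniform time rescaling since only probability ratios enter.

`growth_scan()` quantifies the verdict: it computes $\log H$ across an
$L$-grid and fits both $\log H \sim a + bL$ (exponential rate $b$) and
$\log H \sim a' + b'\log L$ (polynomial degree $b'$). The default start state
is the drift equilibrium — the typical distance of a uniformly random
sequence; when the target covers the equilibrium (a typical start would be
*inside* the target) the worst-case start $k = L$ is used instead. Note the
width rule $w = \lfloor cL \rfloor$ makes the effective width fraction
oscillate with $L$ (at $c = 0.55$: between $0.533$ and $0.55$ on a step-10
grid), which puts a visible sawtooth on $\log H$ and caps the achievable
$R^2$ of either fit around $0.985$–$0.99$ on mixed grids; on grids where $cL$
is integral the log-linear fit is clean ($R^2 > 0.999$). The fitted
exponential can be projected to realistic gene lengths with
`extrapolate_scan()` — the standard "compute small, extrapolate large"
argument for infeasibility.

## Approximating rugged landscapes

Real landscapes are rugged. Two operators reduce a tabulated landscape (any
fitness table over an enumerable space, $A^L \le 10^6$) to the binary
broad-peak setting, given a fitness level $f^*$ that the sought function must
reach:

* **Threshold** (`approximate_threshold()`): target $= \{f \ge f^*\}$,
  everything else neutral. Appropriate when sub-threshold fitness differences
  are invisible to selection.
* **Plateau** (`approximate_plateau()`): target $= \{$sequences whose greedy
  adaptive ascent ends at a local maximum with $f \ge f^*\}$; the complement
  is lifted to the flat level $f_{\max}$, the highest sub-threshold local
  maximum. This upper-bounds the help a walker can get from sub-threshold
  hills, and its target (the whole upslope of every tall mountain range) is a
  superset of the threshold target — the more lenient approximation, suited
  to lower bounds on discovery time.

A *mountain range* is operationalized as a basin of greedy ascent: repeatedly
move to the strictly best improving neighbor, ties broken by the
deterministic neighbor order (by position, then alphabet). The underlying
notion of "the mountain range containing a sequence" is informal in pictures
of one-dimensional projections; connected components of level sets would be
an alternative reading, not implemented. With strict improvement, basins
partition the space and fitness plateaus are crossed only through the
tie-break order — irrelevant for generic noise-perturbed landscapes, where
ties have probability zero.

## The synthetic rugged generator

`generate_rugged()` draws Rough-Mount-Fuji landscapes: a linear slope of
strength $\theta$ toward an anchor plus i.i.d. $\mathcal N(0,
\sigma_{\mathrm{noise}}^2)$ roughness, shifted to be non-negative. It is the
stated world for testing the approximation operators: $\theta = 0$ gives a
pure random field whose strict-local-maximum density is $1/(L(A-1)+1)$;
$\sigma_{\mathrm{noise}} = 0$ gives a smooth cone with a single basin; mixed
settings interpolate. It does **not** emulate correlated epistasis, neutral
networks of exactly equal fitness, or empirically measured landscapes — a
green test establishes that the operators are correct on generic rugged
fields, not that any particular biological landscape is well-approximated.

## Simulators and experiments

The Monte-Carlo walkers are written in C++ (Rcpp) and draw from R's RNG, so a
single `set.seed()` (or the `seed` argument / `--seed` flag) makes every
experiment bit-for-bit reproducible; batch runs consume one sequential stream
rather than per-run substreams. The full-space walker keeps incremental
distances to all $m$ centers ($O(m)$ per event, no re-hashing); the projected
walker samples the birth–death chain directly and is distributionally
identical for centered ball targets.

* `parallel_experiment()` checks the independence product law
  $1 - (1-p)^t$ for $t$ searches against ensemble simulation, with $p$ exact
  from `success_within()`. Its moral: when $p$ is exponentially small,
  polynomially many parallel searches remain exponentially unlikely to
  succeed.
* `multi_target_experiment()` draws $m$ centers uniformly, starts walks from
  uniform non-target sequences (rejection sampling; it refuses degenerate
  regimes where targets cover more than half the space), and compares mean
  discovery times with the stationary-mass estimate
  $A^L / (m \cdot \mathrm{ball})$ — justified by the fast ($O(L\log L)$)
  mixing of the neutral walk, whose stationary distribution is uniform. The
  mixing-time factor is reported as an annotation, never folded into the
  estimate, since its constant is not pinned down. Space sizes and ball
  volumes use exact integer arithmetic throughout (a minimal big-integer
  module, since $A^L$ overflows doubles at $L \ge 27$); the estimate is kept
  as an exact rational plus a log-scale double.
* `regeneration_experiment()` models regeneration — e.g. gene duplication
  repeatedly producing starting sequences a *constant* $k_0$ mutations from
  the target — as independent budgeted restarts. We chose restarts over a
  continuous-time branching stream because the bound of interest counts
  searches, and restarts make the success count exactly binomial and hence
  directly testable. Per-attempt success within a polynomial budget decays
  only polynomially (about $L^{-k_0}$), so $\lceil 3/\hat p\rceil$ restarts
  give ensemble success $\ge 1 - e^{-3} \approx 0.95$ — while the *expected*
  time of any single search stays exponential. The ensemble stage draws
  search outcomes as Bernoulli trials at the DP-exact success probability,
  which is distributionally identical to simulating each search and much
  cheaper. Caveat at desk scale: for very small $L$ the polynomial budget is
  comparable to $A^L$, so whole-space mixing inflates per-attempt success
  above the asymptotic law (at $L = 8$, $T = 20L^2 = 1280$ against
  $4^8 = 65536$, the mixing route contributes $\approx T/A^L \approx 0.02$);
  clean $L^{-k_0}$ scaling needs $L \gtrsim 12$.

## Parameters that matter

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| $A$ | alphabet size | 4 | nucleotides; $A=2$ for exhaustive toy tests |
| $c$, $w$ | peak width fraction / radius | — | the dichotomy variable; $w = \lfloor cL\rfloor$ |
| $N$ | population size | 1 | neutral walk; enters only through $\min(1, N\rho)$ |
| $\sigma$ | per-step multiplicative advantage | 0 | gradient landscapes |
| $\delta$ | classifier margin (fraction of $L$) | 0.01 | sharp flip at desk scales, critical band at large $L$ |
| $k_0$ | regeneration start distance | 2 | smallest nontrivial constant offset |
| budget $T$ | events per search | $20L^2$ (regeneration) | a polynomial budget |
| runs | Monte-Carlo batch size | 200 | matches the scale of the numerical experiments it mirrors |

## Known limitations

* Sequential fixation only: no polymorphic populations, clonal interference,
  or recombination (recombination can change constants, not the
  exponential/polynomial class, and no mechanism is modeled here).
* Point mutations only: no indels, variable lengths, or codon structure.
* Enumeration-based operators (approximations, basins) are capped at
  $A^L \le 10^6$; the asymptotic machinery (chains, scans) has no such cap.
* The fixation model is pluggable but defaults to the Moran closed form; other
  update rules change $\rho$, not the framework.
* Exactness claims for linear-scale quantities hold up to double overflow;
  beyond that only log-scale values are reported.
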