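---
title: "Two-stage testing of union hypotheses by screening minimum p-values"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage testing of union hypotheses by screening minimum p-values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenmin)
```

## The problem

In exploratory mediation analysis — and, identically, in replicability
analysis across two studies — each of $m$ candidate variables carries a
*union* null hypothesis $H_i = H_{i1} \cup H_{i2}$: the candidate is
interesting only if **both** component nulls are false (the exposure moves
the mediator *and* the mediator moves the outcome; or the association
replicates in both studies). Given valid component p-values $p_{i1},
p_{i2}$, the maximum $\bar p_i = \max(p_{i1}, p_{i2})$ is a valid p-value
for $H_i$, so one-stage Bonferroni rejects when $\bar p_i \le \alpha/m$.
But when most pairs are double nulls, $\bar p_i$ is the maximum of two
uniforms — stochastically much larger than uniform — and the one-stage test
is badly conservative.

The two-stage remedy screens first on the minimum $\underline p_i =
\min(p_{i1}, p_{i2})$: with a screening threshold $c$, the selected set is
$S(c) = \{i : \underline p_i \le c\}$, and only survivors are tested,
rejecting $H_i$ when $\bar p_i \le \alpha/|S(c)|$. The package implements
this family of procedures and its finite-sample theory under a working
model in which all $2m$ p-values are independent, null p-values are
standard uniform, and nonnull p-values arise from a unit-variance Gaussian
test statistic with mean shift `snr`, one-sided:
$F(u) = \Phi(\mathrm{snr} - z_{1-u})$.

Pairs come in three types — $(0,0)$ double null, $(0,1)/(1,0)$ one false
component, $(1,1)$ both false — with counts $(m_0, m_1, m_2)$ held by
`mixture_model()`. Only $(1,1)$ pairs are non-null unions; rejecting a
type-$(0,0)$ or $(0,1)$ pair is a familywise error.

## Why the threshold matters

Conditional on selection, the maximum p-value of a one-false pair has the
distribution `cond_cdf_mixed()` (the double-null analogue is
`cond_cdf_doublenull()`). Writing $P_0(u, c)$ for the one-false conditional
CDF at the testing threshold $u$, screening is harmless exactly when
$P_0(u, c) \le u$. That holds asymptotically, but not for every finite
configuration: at low thresholds and weak signal the conditional law is
anticonservative,

```{r}
cond_cdf_mixed(0.05, c = 5e-4, snr = 0.5)  # > 0.05: inflated
cond_cdf_mixed(0.05, c = 5e-4, snr = 6)    # inflation gone at strong signal
```

Averaging over the randomness of $|S(c)|$ — a sum of three binomials,
computed exactly by `selection_size_pmf()` — gives the finite-sample bound
implemented in `fwer_bound()`, which is the *exact* familywise error rate
when every pair has exactly one false component ($\pi_1 = 1$). That
worst case is not hypothetical: with $m = 10$ one-false pairs, snr 2 and
the default threshold $c = \alpha/m$,

```{r}
fwer_bound(mixture_model(m1 = 10, snr = 2), c = 0.005, alpha = 0.05)
```

the error rate exceeds the nominal 0.05.

## Choosing the threshold

`oracle_threshold()` solves the constrained problem: maximise the
(mean-size approximated) power `approx_power()` subject to
`approx_fwer()` $\le \alpha$. Under the model's monotonicity the solution
is the *smallest* feasible threshold; the solver brackets the feasibility
boundary on a 400-point log-spaced grid in $[\alpha/(10m), \alpha]$ and
bisects to $10^{-10}$ (both knobs are arguments). A diagnostic attribute
reports whether the constraint was active. For large $m$ the boundary is
well approximated by the root of the calibration equation
$c \cdot E|S(c)| = \alpha$ (`approx_oracle_threshold()`), unique because
$c \, E|S(c)|$ is strictly increasing; when even $c = \alpha$ satisfies
the equation's left side below $\alpha$ the threshold is capped at
$\alpha$ and flagged — the testing level is the natural ceiling.

The data-dependent counterpart replaces $E|S(c)|$ by the observed
$|S(c)|$: `adaptive_threshold()` returns the largest grid value $\gamma
\in \{\alpha/m, \ldots, \alpha\}$ with $\gamma\,|S(\gamma)| \le \alpha$.
The grid form is canonical here (the continuous and grid solutions select
the same set). `adaptive_procedure()` then uses $\gamma$ for **both**
stages — selection and testing — which restores finite-sample control
because $P_0(c, c) \le c$ for every $c \in (0,1)$ and every snr, a
property the test suite asserts on a dense grid. Its reported adjusted
p-values $\min(|S(\gamma)|\,\bar p_i, 1)$ are a convenience for ranking;
the decision is the threshold comparison, and the two can disagree —
this is documented rather than hidden.

The same grid search with budget $k$ in place of $\alpha$ gives the
per-family error procedure `pfer_procedure()`: the expected number of
falsely rejected unions is bounded by $k$, and for a fixed threshold
`pfer_estimate()` returns the upward-biased estimate $|S(c)|\,c$. Grid
points $k/j$ above 1 are capped at 1 (a threshold cannot exceed 1; with a
lax budget the cap makes the procedure reject every selected pair, which
is the correct degenerate behaviour).

### Numerical choices and edge cases

* Ties at a threshold select/reject inclusively ($\le$), matching the
  procedure definitions; p-values exactly 0 or 1 are accepted as input.
* An empty selection returns all adjusted p-values 1 and no rejections —
  not an error.
* $\alpha/s$ inside $P_0$ is capped at 1; the non-integer exponent in the
  mean-size approximation is evaluated as
  $\exp(\hat E \log(1 - P_0))$ for stability near $P_0 \approx 0$.
* Expectations over $|S|$ are computed exactly from the convolution PMF,
  never by simulation.
* `power_exact()` must decide how the focal $(1,1)$ pair enters the size
  law it is averaged over. The default (`focal = "decomposed"`) counts the
  focal pair explicitly: $|S| = T + 1$ with $T$ the selection count of the
  other $m - 1$ pairs. This is exact at $m = 1$, where the alternative
  full-family accounting (`focal = "conditioned"`) would multiply by the
  selection probability once too often; at $m = 200$ the two differ by a
  few percent.
* Under unequal column shifts the oracle solver follows the misspecified
  single-snr convention; the default single value is the smaller shift
  (the conservative choice for selection probabilities), overridable via
  `oracle_snr`.

## The simulation harness and what it emulates

`sim_config()` + `estimate_error_rates()` reproduce the canonical study
design: independent (or equicorrelated) unit-variance Gaussian statistics,
mean-shifted for false components, one-sided p-values, the false column of
each one-false pair randomised per replicate. Compound symmetry with
correlation $\rho$ is applied *within* each column, columns independent —
the reading consistent with between-column independence being a structural
assumption of mediation p-values — with `cs_joint = TRUE` as a sensitivity
variant correlating all $2m$ statistics. All requested procedures are run
on the same replicate stream, so method comparisons are paired.

The generator emulates exactly what the theory assumes: Gaussian shifts, a
common snr per column, independence (or exchangeable correlation). Real
mediation p-values violate this in known ways — heterogeneous effect
sizes, dependence among mediators with arbitrary structure, conservative
component tests — so passing tests certify the procedures' operating
characteristics *under the working model*, not on any particular real
data set. The discussion of the metabolite walkthrough below is the
package's only contact with real data.

Default problem sizes were chosen to keep every Monte-Carlo comparison
identifiable at 3 standard errors: the worst-case error-rate study uses
$m = 200$, all pairs one-false, 20,000 replicates (`replicate_table1()`),
where the default-threshold procedure's estimated FWER exceeds 5% while
the adaptive and oracle variants stay at or below it; property checks use
$m \le 50$ with 2,000–10,000 replicates.

## The metabolite walkthrough

`navy_metabolites()` ships the 22 printed p-value pairs (of 149 screened
metabolites) from a case-control mediation analysis of fish intake and
colorectal adenoma risk. With $c = 0.05/149$, 13 metabolites pass the
screen; the smallest surviving maximum p-value (docosahexaenoate and
2-aminobutyrate, $8.3\times10^{-3}$) exceeds both the default testing
threshold $0.05/13$ and the adaptive threshold of the full family
($2.2\times10^{-3}$), so no mediator is declared at familywise level 0.05.
Under a per-family budget of $k = 1$ the full-family threshold is
$2.2\times10^{-2}$ and three of the printed metabolites fall under it.
Thresholds that require all 149 rows ($\gamma$, $c_1$) are supplied as
constants with the fixture, since only 22 rows are printed; everything
else is recomputed.

```{r}
navy <- navy_metabolites()
screen(navy, c = 0.05 / attr(navy, "m_total"))
sum(screenmin_adjust(navy, c = 0.05 / 149, alpha = 0.05)$rejected)
```

## Known limitations

* Independence of all $2m$ p-values underpins the exact theory; under
  positive dependence the harness shows control is retained (and becomes
  conservative), but the closed forms no longer apply.
* The theory layer models one common snr; two column-specific nonnull
  distributions would be a straightforward extension but are not
  implemented.
* Mixture parameters $(m_0, m_1, m_2, \mathrm{snr})$ are taken as known by
  the oracle; no estimation from data is provided — the adaptive threshold
  is the recommended practical surrogate precisely because it needs none
  of them.
* Only familywise and per-family error are controlled; a false-discovery-
  rate second stage is out of scope.
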