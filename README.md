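# screenmin

Two-stage familywise-error-rate (FWER) procedures for testing many **union
hypotheses** — hypotheses of the form H_i = H_i1 ∪ H_i2 that are false only
when *both* components are false. This is the inferential core of
exploratory high-dimensional mediation analysis (is variable M_i associated
with the exposure *and* with the outcome?) and of replicability analysis
across two studies (does the finding hold in *both*?). The intended users
are biostatisticians screening hundreds to tens of thousands of candidate
mediators, metabolites, or SNPs from a pair of component p-values per
candidate.

## The method

For each of m pairs let p̲_i = min(p_i1, p_i2) and p̄_i = max(p_i1, p_i2).
The intersection–union principle makes p̄_i a valid p-value for H_i, but
one-stage Bonferroni on the maxima is very conservative when most pairs are
double nulls. The two-stage procedure instead

1. **screens**: S(c) = { i : p̲_i ≤ c }, then
2. **tests** the survivors: reject H_i when p̄_i ≤ α/|S(c)|,
   i.e. adjusted p-value p*_i = min(|S(c)|·p̄_i, 1) for i ∈ S(c), else 1.

The package provides this procedure with a fixed threshold (default
c = α/m), plus the machinery showing that the threshold choice is not
innocuous in finite samples and what to use instead:

- **Exact finite-sample theory** under a Gaussian mean-shift model
  (`gaussian_p_cdf`, `mixture_model`): the conditional distribution of p̄
  after selection (`cond_cdf_mixed`, `cond_cdf_doublenull`), the exact
  distribution of |S(c)| (`selection_size_pmf`), a finite-sample FWER bound
  that is exact when every pair has one false component (`fwer_bound`), and
  exact/approximate power (`power_exact`, `approx_power`).
- **Oracle threshold** (`oracle_threshold`): the smallest c satisfying the
  approximate FWER constraint — which is also the power-maximising feasible
  choice — and its large-m surrogate, the root of c·E|S(c)| = α
  (`approx_oracle_threshold`).
- **Adaptive single threshold** (`adaptive_threshold`,
  `adaptive_procedure`): the largest γ ∈ {α/m, …, α} with γ·|S(γ)| ≤ α,
  used for both screening and testing; needs no knowledge of the p-value
  distribution and restores finite-sample FWER control.
- **Per-family error rate** (`pfer_estimate`, `pfer_procedure`): |S(c)|·c
  estimates E(V), and the budgeted threshold c_k bounds E(V) by k.
- **Monte-Carlo harness** (`sim_config`, `generate_table`,
  `estimate_error_rates`, `replicate_table1`) for type-I-error/power
  studies under independence or equicorrelated statistics.
- **Baseline** `bonferroni_maxp`, I/O (`read_pvalue_table`,
  `write_results`), a packaged 22-metabolite fixture
  (`navy_metabolites`), and a CLI (`inst/cli/screenmin.R`).

## Worked example

The packaged fixture holds the 22 printed metabolite p-value pairs (out of
149 screened) from a case-control mediation analysis of fish intake and
colorectal adenoma risk:

```r
library(screenmin)
navy <- navy_metabolites()
screen(navy, c = 0.05 / attr(navy, "m_total"))
#> screening at c = 0.0003356: |S| = 13 of 22 pairs selected

screenmin_adjust(navy, c = 0.05 / 149, alpha = 0.05)
#> screenmin_fixed: 13 of 22 pairs selected, 0 rejected
#>   c = 0.0003356
#>   alpha = 0.05
#>   test_threshold = 0.003846
```

Thirteen metabolites pass the default screen, but the smallest surviving
maximum p-value (8.3e-3, docosahexaenoate and 2-aminobutyrate) exceeds the
testing threshold 0.05/13 ≈ 3.8e-3 — no mediator is declared at familywise
level 0.05. The finite-sample theory shows why the default threshold still
needs care: with 10 pairs each having exactly one false component (snr 2),

```r
fwer_bound(mixture_model(m1 = 10, snr = 2), c = 0.005, alpha = 0.05)
#> [1] 0.05452084
```

the default procedure's *exact* FWER is 0.055 > α. The harness makes the
same point empirically, and shows the adaptive threshold repairing it:

```r
cfg <- sim_config(m1 = 200, snr1 = 3.1, reps = 5000, seed = 1,
                  methods = c("default", "adaptive", "bonferroni"))
estimate_error_rates(cfg)[, 1:3]
#>       method   fwer     fwer_se
#> 1    default 0.0524 0.003151325
#> 2   adaptive 0.0464 0.002974795
#> 3 bonferroni 0.0198 0.001970176
```

Here every union hypothesis is true, so `fwer` is the probability of any
false rejection: the default threshold overshoots 0.05, the adaptive
threshold stays below it, and one-stage Bonferroni is far more
conservative than either.

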