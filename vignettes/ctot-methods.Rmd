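---
title: "Cycle-to-threshold analysis of censored qPCR data: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cycle-to-threshold analysis of censored qPCR data: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctot)
```

## The problem

qPCR reports, for each reaction, the quantification cycle Cq at which
fluorescence crosses a fixed threshold; lower Cq means more starting
template. When the target is scarce — circulating microRNAs in serum are the
canonical case — some reactions never cross the threshold before the assay's
maximum quality cycle $C_1$ (commonly 32 or 40) and the instrument reports
"Undetermined". Under clean pre-PCR handling and reliable reactions, such an
observation is not missing at random: its true Cq is known to be at least
$C_1$. It is right-censored at a known point, exactly like administrative
censoring at the end of a follow-up study.

Common practice either deletes those samples (complete observations, CO),
refuses to analyze the target at all (CNA), or substitutes $C_1$ for the
missing value and runs a t-test (maximum cycle, MC). All three discard or
distort information. This package implements the alternative: treat
threshold crossing as an *event*, normalized cycle as *time*, and use exact
censored rank statistics built for small samples.

## Outcomes and normalization

For sample $i$ and a fixed target, let $Y_i$ be the reported Cq and
$Y_{ri}$ the Cq of a normalizer target from the same sample (assumed well
observed, $Y_{ri} < C_1$; the code refuses to proceed otherwise).
The analysis outcome is the pair $(\Delta Y_i, \varphi_i)$ with

$$\varphi_i = I(Y_i < C_1), \qquad
\Delta Y_i = \begin{cases} Y_i - Y_{ri}, & \varphi_i = 1\\
C_1 - Y_{ri}, & \varphi_i = 0,\end{cases}$$

so a censored observation carries a per-sample lower bound on its true
normalized value. Two conventions are fixed here and used everywhere:

* the boundary $Y_i = C_1$ counts as censored ($\varphi$ is the indicator of
  a *strict* inequality);
* an instrument-undetermined reaction is censored at $C_1$ even when
  $C_1$ is below the run length, since its true Cq is at least the run
  length.

Because normalizers differ between samples, censoring bounds are
observation-specific; all downstream machinery supports that (there is no
single global cutoff on the $\Delta Y$ scale). A sample lacking the target
record entirely is *missing*, not censored; it is excluded with a warning
and never enters the risk sets.

## The test

Let $d_1 < \dots < d_r$ be the distinct observed $\Delta Y$ values with
$\varphi = 1$ ("detection points"). At each $d$, $P_{dk}$ counts the group-$k$
samples whose value or censoring bound is $\geq d$ (still "at risk" of
detection), and $O_{dk}$ counts the group-$k$ detections at exactly $d$.
Censored observations tied with a detection point stay in the risk set at
that point (events precede censorings at equal values — the standard
survival convention; the choice only matters under exact ties).

Conditional on the margins, $O_{d1}$ is hypergeometric, with

$$E_{d1} = O_d \frac{P_{d1}}{P_d}, \qquad
V_{d1} = O_d \frac{P_{d1}}{P_d}\Big(1 - \frac{P_{d1}}{P_d}\Big)
\frac{P_d - O_d}{P_d - 1}$$

(and $V_{d1} = 0$ when $P_d \le 1$). The statistic is

$$U = \sum_d w_d\,(O_{d1} - E_{d1}), \qquad V = \sum_d w_d^2\, V_{d1},$$

with Fleming–Harrington weights $w_d = \hat S(d^-)^p (1-\hat S(d^-))^q$
computed from the pooled Kaplan–Meier left limit ($0^0 = 1$; $p = q = 0$
gives the plain log-rank test; $p>0$ stresses early, $q>0$ late detection
points). $U > 0$ means group 1 crosses the threshold in excess of
expectation: a higher crossing rate, lower $\Delta$Cq, more target. The
one-sided alternatives are named for the group-1 rate (`rate1_greater`,
`rate1_less`) to keep that direction unambiguous.

### Exact inference

With $n = n_1 + n_2$ samples, the null conditional distribution of $U$ is
obtained by permuting group labels. The pooled quantities (risk sets,
Kaplan–Meier limits, weights) are label-invariant, so $U$ for any labeling
equals a sum of fixed per-observation scores

$$c_i = \varphi_i\, w(y_i) - \sum_{d \le y_i} w_d \frac{O_d}{P_d},$$

over the samples assigned to group 1; the package verifies
$\sum_{i \in \text{group 1}} c_i = U$ as a tested invariant, and the test
suite additionally checks the whole machinery against a deliberately naive
oracle that rebuilds the risk table from scratch for every labeling.

The exact p-value enumerates all $\binom{n}{n_1}$ labelings (252 at the
default 5 + 5 design — instantaneous). Conventions:

* **two-sided exactness** counts labelings with $|T - \mu| \ge |T_{obs} -
  \mu|$ where $\mu$ is the permutation mean of $T$ — the standard
  exact-conditional convention, structurally keeping $p \le 1$, rather than
  doubling a one-sided tail;
* **floating-point ties**: comparisons use an absolute tolerance of
  $10^{-12} \max_i |c_i| \cdot n$ so mathematically tied statistics count as
  ties (the sums reuse the same floats, so true ties are at most a few ULP
  apart — far below this tolerance, while genuinely distinct sums sit far
  above it);
* the observed labeling is always counted, so $p \in (0, 1]$, and exact
  p-values are multiples of $1/\binom{n}{n_1}$.

Beyond a configurable enumeration limit (200,000 labelings) the test
switches to Monte Carlo resampling with $p = (1 + \#\text{extreme})/(B+1)$;
a normal approximation $Z = U/\sqrt{V}$ is also available for large
samples. Degenerate inputs — no detection points at all, or zero permutation
variance — return $p = 1$ with a reason flag instead of an error, because
simulation harnesses must count such replicates as non-rejections.

Because the statistic depends on the data only through ranks and the
censoring pattern, any strictly increasing transform of values and bounds
leaves the p-value unchanged (a tested invariant).

## Comparator strategies

`run_method()` / `compare_methods()` implement the strategies the test is
benchmarked against: MC (substitute the bound $C_1 - Y_{ri}$, then t-test),
CO (drop censored samples, then t-test), CNA (analyze only fully determined
targets), and BFD (t-test on the uncensored truth, available only in
simulation). On censoring-free data all of them coincide exactly — a tested
invariant.

The two-sample t-test is authored in closed form (Welch statistic with
Welch–Satterthwaite degrees of freedom, or the pooled Student form) and is
cross-checked against `stats::t.test` to $10^{-10}$ in the test suite. The
package default is Welch. The type-I-error study, however, runs the t-based
methods with the pooled form: under the null the two groups are iid normal
with a common variance, where the pooled test has exact size, whereas Welch
at $n = 5$ per group is conservative (true size about 0.043). Every study
report records which variant was used.

Degeneracy rules, chosen so every simulated replicate yields a decision: CO
with fewer than two complete observations left in a group is a flagged
non-rejection; CNA on a censored target is a "not analyzed" non-rejection,
tallied separately.

## Interpretable summaries

`ctot_summary()` reports per group the proportion of uncertain
quantifications, the Kaplan–Meier median of $\Delta Y$ (the smallest
detection point where the group survivor estimate reaches 0.5; reported as
not reached when censoring keeps it above 0.5 — no extrapolation), and a
threshold-crossing rate ratio. No estimator for that ratio is mandated by
the method itself; the package uses the O/E ratio
$(O_1/E_1)/(O_2/E_2)$ from the pooled unweighted risk table — closed-form,
stable at $n = 5$, requiring no proportionality fit — and labels it as such
in the output. It is undefined (flagged, `NA`) when a group has no expected
or observed detections. No confidence interval is attached: a defensible
one would need resampling theory out of proportion to this estimator's
role.

## The simulator

`simulate_replicate()` emulates the two-group experiment the method is
designed for. Per sample: a normalizer Cq from Normal(25, 0.45) (0.45 is a
standard deviation), a normalized outcome $\Delta Cq$ from one of three
location-scale families with location $\beta_0 + x\beta_1$ ($x \in \{0,1\}$
the group indicator) and dispersion $\sigma$, and a raw Cq
$= \Delta Cq + $ normalizer. The record is "determined" iff Cq $< C_1$
(default 40); the uncensored truth is retained for BFD. Defaults: $n = 5$
per group — the small-sample design typical of preclinical work.

The families, on the cycle scale:

| family | $\Delta$Cq distribution | $e^{\Delta Cq}$ distribution |
|---|---|---|
| `lognormal` | Normal($m$, $\sigma$) | log-normal |
| `weibull` | $m + \sigma G$, $G$ standard minimum-Gumbel | Weibull, shape $1/\sigma$ |
| `loglogistic` | Logistic($m$, $\sigma$) | log-logistic, scale parameter $\sigma$ |

The shape mappings (Weibull shape $p = 1/\sigma$, log-logistic
$\gamma = \sigma$) make $\sigma$ uniformly the scale of the cycle-scale
distribution across families. Draws are checked in the test suite against
closed-form moments and CDFs (Kolmogorov–Smirnov at $\alpha = 0.001$ under
fixed seeds).

Power scenarios draw $\beta_0 \sim$ Normal(10, 2.24) and $\beta_1 \sim$
Normal(1, 4.47) independently, 100 scenarios per family by default, with
$\sigma$ alternating 1, 2, 1, 2, … across scenario index (configurable to
all-1, all-2 or random; the alternation approximates an even split when no
assignment rule is otherwise specified). The null (type-I) design is the
fixed grid $\beta_1 = 0$, $\beta_0 \in \{5, 10\}$, $\sigma \in \{1, 2\}$.

What the simulator does *not* emulate: amplification-efficiency variation,
technical replicates, pre-PCR errors such as hemolysis, multi-normalizer
(geometric mean) normalization, or inter-plate effects. Passing tests
therefore certify the statistical machinery under idealized censoring at a
known cutoff — not robustness to assay artifacts upstream of the Cq values.

## The study harness

`run_power_study()` pools decisions over scenarios × replicates,
*restricted to replicates with at least one uncertain observation* (the
others are uninformative about censoring-handling and are identical across
methods anyway). Every drawn $\beta_1$ is nonzero almost surely, so a
correct decision is any two-sided rejection at $\alpha$. Reports include
per-method Wald 95% intervals $\hat p \pm 1.96\sqrt{\hat p(1-\hat p)/n}$ —
the interval form whose bounds match the published simulation tables — and
the fraction of kept replicates whose censoring is confined to one group.
`run_type1_study()` reports per-scenario rejection rates over all
replicates plus the pooled exact-test rate on the uncertain-observation
subset at its own (much smaller) realized $n$.

Determinism: every study is a pure function of its configuration and master
seed. Per-scenario seeds derive from the master seed by a fixed affine
counter scheme modulo $2^{31}-57$, so scenario subsets can be re-run
independently; identical configurations give bit-identical reports (tested).

Problem sizes: the bundled test suite runs the null design at its full
4 × 10,000 replicates, and the power comparison at 10 scenarios × 200
replicates per family — large enough that the method ordering
(BFD ≳ CTOT > CO, with CTOT close behind the full-data benchmark and far
ahead of deletion) is reproducible, while keeping the whole suite to a few
minutes. At 10 random scenarios the *magnitude* of the CTOT–CO gap varies
substantially between seeds, since it depends on how many drawn scenarios
produce heavy one-group censoring; at 100 scenarios per family the gap is
stable and large (tens of percentage points).

## Known limitations

* Exactly two groups; no stratification, trend tests, or regression
  adjustment.
* The normalizer must be well observed in every analyzed sample; there is
  no multi-normalizer averaging or efficiency correction.
* The rate-ratio summary is a score-based surrogate, not a fitted hazard
  ratio, and comes without an interval.
* Relative quantification only: absolute copy-number analysis via standard
  curves, and left-truncated concentration data, are out of scope.
* With very heavy censoring the exact test grows conservative (few
  detection points, coarse permutation atoms); this is visible in the
  type-I study's uncertain-observation subset, where the rejection rate
  sits at or below the nominal level.
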