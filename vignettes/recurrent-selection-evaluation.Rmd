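---
title: "Evaluating recurrent-selection strategies in half-sib maize trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating recurrent-selection strategies in half-sib maize trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recsel)
```

## The problem

Intrapopulation recurrent selection improves an outcrossing population —
here tropical maize — by cycles of progeny evaluation, selection of a top
fraction, and recombination. In the scheme this package models, each cycle
evaluates half-sib families (S0) in a lattice trial alongside a paired trial
of their selfed (S1) progenies, which exposes inbreeding depression. Five
strategies compete to nominate the families to recombine: three phenotypic
selection indexes (base, Smith–Hazel, Mulamba–Mock rank summation) and
REML/BLUP rankings of genotypic value for grain yield and for inbreeding
depression. The package implements the whole evaluation — simulation,
parameter estimation, model fitting, ranking, gain prediction, and agreement
analysis — so the strategies can be compared under controlled, repeatable
conditions.

## The trial model

A plot observation of trait $t$ for family $i$ in replicate $r$ and
incomplete block $b(r)$ is modelled as

$$ y = \mu + \tau_{g} + u_r + u_{b(r)} + g_i + \varepsilon, $$

with a fixed intercept $\mu$ and fixed ancestry-group effects $\tau_g$ (the
background populations from which the families derive), and independent
Gaussian random effects: replicate $u_r \sim N(0, \sigma^2_{rep})$, block
within replicate $u_{b(r)} \sim N(0, \sigma^2_{block})$, family
$g_i \sim N(0, \sigma^2_{fam})$, and plot residual
$\varepsilon \sim N(0, \sigma^2_e)$. Under the half-sib model
$\sigma^2_{fam} = \sigma^2_A/4$. The lattice is treated as blocks nested in
replicates with a random block effect; no lattice-specific inter-block
recovery beyond that term is attempted, because the selection statistics
all operate on plot or family means. Replicates are random by default, with
a fixed-replicate switch (`model_spec(fixed_terms = c("intercept", "rep"))`)
for sensitivity runs, since trial practice varies on this point.

## What the generator emulates — and what it does not

`simulate_trial()` reproduces the reference study conditions by default
(`default_study()`): 194 candidate progenies plus two checks in a
14 × 14 triple lattice (three replicates, 14 blocks of 14 plots), five
ancestry groups assigned cyclically, and ten traits on tropical-maize
scales — grain yield (GY) around 3950 kg/ha, ear weight around 4800 kg/ha,
flowering near 59 days, plant and ear height near 2.25 m and 1.0 m
(minimize-direction), ear number, diameter, length, and grain moisture.
The 20-plant row plots of such trials are abstracted to one value per plot
and trait: plant-to-plant variation is folded into the plot-error variance,
which is all the downstream statistics can see anyway.

The study that motivates these conditions does not report error variances,
genetic correlations, or heritabilities, so those are the package's own
calibration, chosen once to be realistic for tropical maize half-sib
trials: family-mean heritabilities near 0.5 for yield (e.g. GY:
$\sigma^2_{fam} = 9\times10^4$, $\sigma^2_e = 3.6\times10^5$, three
replicates), higher for flowering, moderate genetic correlations
(GY–EW 0.85, GY–NE 0.40, MF–FF 0.90, PH–EH 0.80), and small replicate and
block variances. Checks carry no family effect — they are controls, not
candidates, and are excluded from standardization, estimation, and
selection.

Inbreeding depression is generated multiplicatively: the S1 expected family
mean is $(1 - \delta_i/100)$ times the S0 expected family mean, with true
per-family depression $\delta_i \sim N(43, 8^2)$ percent for grain yield,
truncated to $(-100, 100)$. The multiplicative truth makes the depression
estimator exactly invertible on noise-free means, which anchors the
round-trip tests. One root seed expands into per-component substreams
(keyed by trait and design component), so adding a trait never perturbs the
draws of earlier traits and every table is bit-for-bit reproducible.

What the generator deliberately does **not** emulate: marker genotypes,
dominance or epistasis beyond the multiplicative depression shortcut,
spatial field trends, genotype-by-environment interaction (the reference
evaluation is single-location), and correlated residuals across traits
beyond what shared plots induce. Passing tests therefore certify the
estimators under an additive, Gaussian, single-location world — they say
nothing about robustness to non-additive genetic architecture or spatial
structure in real fields.

## Inbreeding depression as a trait

Per-family depression is $ID = 100(m_0 - m_1)/m_0$ from paired S0/S1 family
means. A design point worth making explicit: a single ID value per family
cannot support a family-plus-residual mixed model (the two variances are
confounded with one observation per level), so `id_table()` defaults to
pairing replicate $r$ of the S0 trial with replicate $r$ of the S1 trial,
giving one ID value per family and replicate. The pairing of replicate
numbers across the two fields is arbitrary but unbiased, and the resulting
replication makes the ID mixed model (family random effect + residual — no
plot term, since ID has no plot-level design of its own) identifiable.
Family-level values remain available with `level = "family"`. Negative ID
is retained, never clipped: an S1 above its S0 is residual heterosis, which
is information, not error.

## Genetic parameters, P and G

`anova_components()` uses the intra-block ANOVA (family mean squares
adjusted for replicates and blocks) with the method of moments:
$\hat\sigma^2_{fam} = (MS_{fam} - MS_{err})/k_1$, where $k_1$ is the
weighted average family size (equal to the replicate number $r$ when
balanced). Negative estimates are truncated to zero and flagged. The
effective replicate number of a family mean, `n_eff`, is the harmonic mean
of plots per family; family means are unweighted means over available
plots.

`estimate_PG()` builds the Smith–Hazel machinery on standardized,
direction-adjusted family means (each trait centred and scaled by the SD of
its family means over candidates; minimize-traits sign-flipped). Working on
this scale makes the base and Smith–Hazel indexes commensurable and handles
minimize-traits with a single convention stated once. $P$ is the empirical
covariance of family means. $G$'s diagonal comes from the ANOVA estimator;
off-diagonals subtract the plot-matched residual covariance over `n_eff`
from the family-mean covariance (the cross-trait analogue of the ANOVA
estimator). Residuals are matched by (generation, replicate, plot); a
derived trait like ID shares no physical plots with the field traits, so
its residual covariance with them is taken as zero. Replicate and block
variances are estimated but excluded from the family-mean phenotypic
variance by default — selection happens among entry means within one common
design, so those terms cancel from comparisons; the estimates are still
reported for diagnostics.

Conditioning: eigenvalues of $G$ (and $P$) below $10^{-6}$ times the
largest are raised to that floor and the matrix reassembled ("bending").
The Smith–Hazel equations need an invertible $P$; a $P$ still singular
after bending is an error that reports the offending eigenvalue. After
truncation, $0 \le G_{tt} \le P_{tt}$, so family-mean heritabilities
$h^2_t = G_{tt}/P_{tt}$ always lie in $[0, 1]$.

## EM-REML and Henderson's equations

`reml_fit()` estimates variance components by EM-REML. Each iteration
solves Henderson's mixed-model equations at the current components — the
coefficient matrix is $W'W$ with $\sigma^2_e/\sigma^2_k$ added to the
diagonal of random block $k$ — and updates
$\sigma^2_k \leftarrow (u_k'u_k + \sigma^2_e\,\mathrm{tr}\,C_{kk})/q_k$ and
$\sigma^2_e \leftarrow (y'y - \hat\beta'X'y - \hat u'Z'y)/(n - p)$, where
$C_{kk}$ is the corresponding block of the inverse coefficient matrix. The
restricted log-likelihood is computed from the same factorization
($-2\ell_R = (n-p-q)\log\sigma^2_e + \sum_k q_k\log\sigma^2_k + \log|M| +
y'Py$ up to a constant), stored per iteration, and must be non-decreasing —
a decrease beyond numerical noise raises a warning. Convergence is declared
at relative log-likelihood change below `1e-8` (default) and non-convergence
is always reported, never silent.

EM was chosen over average-information REML deliberately: at desk scale
(hundreds of families, a few thousand plots) its guaranteed monotonicity
and parameter-space safety outweigh its linear convergence rate. Components
are floored at $10^{-10}$ times the phenotypic variance; a family variance
that ends at the floor is reported as zero with all BLUPs zeroed and
flagged. Known components can be supplied to skip estimation entirely —
that is how the package's own tests compare the equations against direct
generalized-least-squares inversion.

The reported intercept is the fixed-effect estimate averaged over
ancestry-group effects weighted by group sizes, so one base mean $\hat\mu$
is added to every BLUP: predicted genotypic value $= \hat\mu + \hat g_i$,
and the value-minus-BLUP gap is constant across progenies by construction.
Report output rounds grain-yield values to whole kg/ha and depression to
one decimal, matching field-report precision; internal values are never
rounded.

## Indexes, selection, and gains

All three indexes operate on the family means of candidates. The base index
weights standardized means by the economic weights directly; Smith–Hazel
solves $Pb = Ga$ by a linear solve; rank summation sums weighted per-trait
ranks (rank 1 = best, average ranks on ties). Economic weights default to
2 for grain yield and 1 for inbreeding depression, all other traits 0 —
zero-weight traits are carried through reporting but exert no pressure.
All final rankings break ties deterministically by progeny identifier.

`select_top()` converts a fraction to $k = \max(1, \lfloor f N \rfloor)$:
20% of 194 candidates selects exactly 38, the reference intensity. Gains
come in two modes because field reports are often ambiguous about the
formula behind printed percentages: the raw differential $X_s - X_0$, and
the default heritability-adjusted $h^2 (X_s - X_0)$, the breeder's-equation
prediction of next-generation response, which on simulated data matches the
mean true family effect of the selected set (a property the test suite
verifies over 200 replicate trials). For BLUP strategies the gain is the
mean of the selected BLUPs — already shrunken, so no further adjustment —
relative to the fitted base mean. The aggregate "total" percent gain sums
absolute per-trait percentages by default (`total = "signed"` switches to
the signed sum), since a favourable minimize-trait response is negative on
the raw scale.

## Agreement among strategies

Three overlap measures are provided: plain coincidence $|S_p \cap S_q|/k$,
normalized coincidence (divide by the smaller set), and Jaccard (divide by
the union), with $J \le CI \le CI_{norm}$ always. The pairwise-matrix
output defaults to Jaccard alongside the plain-coincidence matrix; both are
written per $k$, plus the mean-pairwise agreement curve over the top-$k$
grid and the 0/1 progeny-by-strategy membership matrix that feeds overlap
heatmaps (rendering is left to the caller). Under independent uniform
rankings the expected coincidence at intensity $k$ among $N$ candidates is
$k/N$ (hypergeometric mean) — the calibration property the test suite
checks at $N = 194$.

## The pipeline

`run_pipeline()` chains the stages — data (simulated or from CSV), ID
trait, genetic parameters, the two REML/BLUP fits (grain yield with
replicate, block, and family random terms; ID with the family term only),
the three indexes, truncation to the selected fraction, gain prediction,
and coincidence analysis — writing every intermediate artifact plus a
manifest with MD5 checksums. A single root seed drives all randomness
through derived substreams, so identical configuration and seed give
identical checksums. Configurations are JSON, validated against the schema
in `inst/schema/` with unknown keys rejected. With fewer than two
strategies the coincidence stage is skipped with a logged notice. The
package is driven from R (or via the thin wrapper
`inst/scripts/recsel-run.R` for shell use); each stage is equally usable on
its own.

## Numerical choices and degenerate inputs

- Bending floor $10^{-6} \times \lambda_{max}$; component floor
  $10^{-10} \times \mathrm{var}(y)$; EM convergence `1e-8` relative
  log-likelihood change, 500 iterations maximum.
- A constant response collapses cleanly: intercept = the value, all
  components and BLUPs zero, with a warning.
- A zero $G$ matrix yields zero index weights and scores with a warning
  rather than an error (no heritable variation is an answer, not a crash).
- Non-positive-semi-definite correlation inputs are rejected with the
  smallest eigenvalue named; zero-SD traits with selection weight are
  rejected.
- Entries that do not fill the last incomplete block leave it short and
  mark the trial `unbalanced_blocks`.

## Problem sizes used by the test suite

The suite validates parameter recovery at 1000 families × 3 replicates
(ANOVA and EM-REML against generative truth within three standard errors),
oracle equivalence of the mixed-model equations against direct GLS on
twenty random instances of up to ~40 observations, Smith–Hazel solves
against brute-force inversion on fifty random positive-definite systems,
overlap-measure properties on a thousand random set pairs, and the
breeder's-equation consistency over 200 replicate trials of 100 families.
These sizes were chosen to give the Monte-Carlo checks resolving power at
interactive runtimes.

## Known limitations

- Family effects are independent (no pedigree or genomic relationship
  matrix); multi-trait REML is not implemented — the multi-trait machinery
  lives in $P$/$G$ estimation instead.
- The ID model ignores covariance between a family's S0 and S1 error terms
  across fields (they are separate trials, so independence is reasonable,
  but flanking-row competition effects are not modelled).
- Variance-component standard errors are not reported by the EM fitter;
  Monte-Carlo replication is the intended route to uncertainty here.
- Realized-gain comparison assumes the recombined-population trial is
  fairly compared against its base or checks in the same trial; no
  across-trial adjustment is attempted.
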