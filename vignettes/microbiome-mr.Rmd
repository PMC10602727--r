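---
title: "Bidirectional two-sample Mendelian randomization for microbiome exposures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bidirectional two-sample Mendelian randomization for microbiome exposures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microMR)
```

## The problem

Observational associations between gut-microbiome composition and disease
are confounded by diet, lifestyle, medication, and — for liver disease in
particular — by reverse causation through the gut–liver axis. Two-sample
Mendelian randomization (MR) sidesteps both problems by using germline
genetic variants as instrumental variables: alleles are assorted at
conception, so a variant that raises the abundance of a bacterial taxon is
not confounded by later environment, and the direction variant → taxon →
disease is fixed by biology. "Two-sample" means the variant–exposure and
variant–outcome associations come from different GWAS; only per-SNP summary
statistics (effect $\hat\gamma_j$, standard error $\sigma_{xj}$ for the
taxon; $\hat\Gamma_j$, $\sigma_{yj}$ for the disease) are required.

`microMR` implements the complete screen: instrument selection and quality
control, allele harmonization, five causal estimators, pleiotropy and
heterogeneity diagnostics with sequential outlier removal, per-rank
multiple-testing control across many taxa, the reverse-direction analysis,
and a summary-statistics simulator with known ground truth against which
every stage is validated.

## Instrument selection and quality control

For each taxon the candidate instruments pass through, in order:

1. **Association threshold** — `select_candidates()` keeps SNPs with
   $p < 10^{-5}$ (strict inequality). Microbiome GWAS rarely yield
   genome-wide significant hits per taxon, so the conventional relaxed
   ceiling is the default; the reverse direction uses the genome-wide
   $5\times10^{-8}$.
2. **LD clumping** — `clump()` greedily promotes the smallest-p SNP to
   index SNP and discards SNPs with $r^2 \ge 0.001$ within a 10,000 kb
   window, repeating on the remainder. Ties in $p$ are broken
   lexicographically by SNP id so output never depends on input order.
   The pairwise $r^2$ come from a user-supplied `ld_matrix` (long or square
   TSV); the package never computes LD from genotypes. Without an LD
   matrix, clumping degenerates to the window/identity rule with a warning.
3. **Confounder exclusion** — `exclude_confounder_snps()` removes SNPs on
   a static exclusion list (SNP id + annotated trait), the offline
   replacement for an interactive phenotype-lookup service.
4. **Instrument strength** — `filter_weak_instruments()` retains SNPs with
   $F \ge 10$ (inclusive). The default $F = (\hat\gamma/\sigma_x)^2$ is the
   single-instrument Wald form; the variance-explained form
   $F = R^2(N-2)/(1-R^2)$ with $R^2 = 2\,\mathrm{maf}(1-\mathrm{maf})\hat\gamma^2$
   is available (`f_method = "r2"`) and agrees with the Wald form to a
   fraction of a percent at GWAS scales, so which variant a study used is
   immaterial in practice.
5. **Harmonization** — `harmonize()` joins on SNP id (duplicate ids are a
   hard error, not a silent first match), aligns the outcome to the
   exposure's effect allele (sign-flipping $\hat\Gamma$ and replacing eaf
   by 1−eaf on swaps), attempts a strand-complement match before declaring
   alleles incompatible, and drops all palindromic (A/T, C/G) SNPs
   unconditionally. We deliberately do not rescue palindromic SNPs by
   allele-frequency matching: at microbiome effect sizes the frequency
   signal is weak and a wrong strand call silently flips a ratio estimate.
   Every input SNP not retained appears in the audit list with a reason.

## The five estimators

All estimators act on the harmonized per-SNP vectors. The per-SNP Wald
ratio is $\hat\beta_j = \hat\Gamma_j/\hat\gamma_j$ with first-order
standard error $\sigma_{yj}/|\hat\gamma_j|$ (exposure error ignored — the
standard no-measurement-error simplification; its consequences are
quantified below).

* **IVW** (`mr_ivw`): weighted regression of $\hat\Gamma$ on $\hat\gamma$
  through the origin, weights $1/\sigma_{yj}^2$:
  $\hat\beta = \sum w_j\hat\gamma_j\hat\Gamma_j / \sum w_j\hat\gamma_j^2$.
  The default multiplicative random-effects model inflates the
  fixed-effect variance by $\max(1, Q/(L-1))$, so heterogeneity widens but
  never narrows the interval; `model = "fe"` gives the fixed-effect SE.
  P-values are two-sided normal.
* **MR-Egger** (`mr_egger`): each SNP is oriented so $\hat\gamma_j \ge 0$,
  then $\hat\Gamma$ is regressed on $\hat\gamma$ **with** an intercept.
  The slope is the pleiotropy-adjusted effect; the intercept estimates
  average directional pleiotropy. SEs are the unscaled WLS errors times
  $\max(1, \sqrt{RSS/(L-2)})$ and tests use $t_{L-2}$ — at $L = 3$ a
  published $\beta/\mathrm{SE} = 1.93/0.864$ gives $p = 0.268$ only under
  $t_1$, which pins down the degrees-of-freedom convention.
* **Weighted median** (`mr_weighted_median`): the inverse-variance-weighted
  median of the ratio estimates, linearly interpolating the cumulative
  weight function $s_j = \sum_{k\le j} w'_k - w'_j/2$ at $1/2$; consistent
  while valid instruments carry more than half the weight.
* **Simple and weighted mode** (`mr_mode`): the argmax of a Gaussian
  kernel density over the ratio estimates, bandwidth
  $\phi \cdot 0.9\min(\mathrm{sd}, \mathrm{IQR}/1.349)L^{-1/5}$ with
  $\phi = 1$, evaluated on a fixed 512-point grid spanning the ratio range
  ± 3 bandwidths; consistent when the largest cluster of instruments is
  valid.

Bootstrap standard errors for the median and mode estimators come from a
seeded parametric bootstrap (redraw $\hat\gamma_j^* \sim N(\hat\gamma_j,
\sigma_{xj})$, $\hat\Gamma_j^* \sim N(\hat\Gamma_j, \sigma_{yj})$,
recompute; default `n_boot = 1000`); `n_boot = 0` skips the bootstrap for
large simulation studies. Mode p-values use $t_{L-1}$, weighted-median
p-values the normal. Estimates are reported on the log-odds scale and as
odds ratios with 95% intervals via `or_from_beta()`
($z = 1.96$).

```{r}
h <- harmonized_set(paste0("rs", 1:3), c(1, 2, 3), rep(0.05, 3),
                    c(0.4, 1.0, 1.5), c(0.1, 0.2, 0.3))
mr_ivw(h)
or_from_beta(0.778, 0.265)
```

## Pleiotropy and heterogeneity diagnostics

* **Cochran's Q** (`cochran_q`): weighted squared deviations about the
  fixed-effect IVW fit, $\chi^2_{L-1}$, flagged at $p < 0.05$.
* **Egger intercept** (`egger_intercept_test`): $t_{L-2}$ test of the
  intercept against zero.
* **Global residual test** (`presso_global`): the observed statistic is
  the weighted residual sum of squares about leave-one-out IVW fits; its
  null distribution is simulated parametrically (default 10,000 draws; the
  test suite uses 300–500 for speed). Empirical p-values use
  $(1+k)/(1+N)$ and so are never zero. Simulated draws are attached to SNP
  identity, making all results exactly equivariant under input reordering.
* **Outlier test** (`presso_outlier_test`): each SNP's observed weighted
  squared residual against its own simulated distribution, Bonferroni
  -adjusted by $L$.
* **Sequential removal** (`sequential_outlier_removal`): while the global
  test is significant at $\alpha = 0.05$, remove the SNP with the smallest
  outlier p (ties lexicographic) and re-run the global test on the
  remainder; outlier ranks are recomputed each iteration
  (`freeze_ranking = TRUE` ranks once on the initial set — both readings
  of the published procedure are available). The loop hard-stops, with a
  note, when fewer than four SNPs would remain, since the leave-one-out
  fits need at least three. A distortion test scales the before/after
  change in the IVW estimate by a bootstrap SE of the difference.
* **Leave-one-out** (`leave_one_out`): IVW excluding each SNP in turn,
  with a driver flag when any single exclusion changes the sign or moves
  the 95% interval across zero.

A caution established by the validation suite: when several pleiotropic
outliers share a sign, they drag the IVW fit itself, and the sequential
procedure then tends to remove one additional innocent SNP or to rank an
innocent SNP ahead of a genuine outlier. Exact recovery of a planted
outlier set is therefore only a well-posed expectation when the planted
effects are balanced; for directional plants the reliable guarantee — and
the one the suite asserts — is that the planted set is *contained* in the
removed set. Removing an extra SNP errs on the conservative side for
causal inference.

## The screen, thresholds, and the reverse direction

`run_forward()` takes a named list of exposure tables with taxonomic
ranks, one outcome table, and an `mr_config` (which requires an explicit
seed). Each taxon runs through the QC stack and sequential outlier
removal; taxa retaining fewer than three instruments are excluded with the
reason recorded, and any per-taxon error is quarantined rather than
aborting the screen. The per-rank significance threshold is
$\alpha/n$ where $n$ counts taxa *with a reported result* at that rank —
this operationalization of "effective number of independent taxa"
reproduces published thresholds exactly (e.g. $0.05/88 = 5.68\times
10^{-4}$ at genus rank) and avoids an eigenvalue computation that would
require the taxon correlation matrix. `run_reverse()` repeats the stages
with the disease as exposure at $p < 5\times10^{-8}$ and each identified
taxon as outcome, flagging `no_reverse_causality` when the reverse IVW
$p \ge 0.05$. `write_report()` emits the estimates table, diagnostics
table, and a manifest echoing the full configuration and per-stage SNP
accounting; outputs are byte-identical given the same inputs, config, and
seed.

## The synthetic-data generator

`simulate_mr_pair()` simulates directly at the summary-statistic level —
two-sample MR consumes nothing else, so individual-level genotypes would
add runtime without adding realism where it matters. Per SNP: maf ~
U(0.05, 0.5) (common variants, matching the usual maf > 0.05 filter); true
exposure effect $\gamma_j \sim N(0.08, 0.03^2)$ truncated positive
(effects reported for the trait-increasing allele); standard errors
$1/\sqrt{2N\,\mathrm{maf}(1-\mathrm{maf})}$ with defaults $N_{exp} =
18{,}340$ and $N_{out} = 24{,}510$, the scale of a microbiome GWAS
meta-analysis and a case-control liver-disease GWAS; observed effects
drawn about the truth; optional horizontal pleiotropy $\alpha_j$ on a
chosen fraction of SNPs (balanced or directional, scale `alpha_sd` = 0.1,
optionally correlated 0.5 with instrument strength to violate the InSIDE
assumption); outcome truth $\Gamma_j = \theta\gamma_j + \alpha_j$. Allele
pairs are drawn with a palindromic fraction of 0.2 — a deliberate
overweighting of the ~1/6 expected among random biallelic pairs so that
harmonization paths are exercised often. A truth sidecar records
$\gamma_j$, $\alpha_j$, and validity labels per SNP.
`simulate_multitaxon()` builds a panel of taxa over the five taxonomic
ranks with disjoint instrument sets, a shared outcome table, and —
for reverse-direction studies — direct (taxon-independent)
disease-associated SNPs at genome-wide significance, which are the
instruments a reverse analysis selects. `flip_fixture()` writes
allele-swapped and strand-complemented copies of a table to exercise
harmonization.

What the generator does **not** emulate: LD between instruments (clumping
is tested against hand-built LD matrices), winner's-curse from selecting
instruments in the same sample, case-control liability-scale effects,
sample overlap between the two GWAS, and non-normal effect distributions.
Passing tests therefore certify the algorithms under an idealized
sampling model, not robustness to those real-data complications.

## Attenuation: what "recovery" means under exposure noise

Because the ratio SE ignores exposure error, every summary-data MR
estimator carries regression-dilution bias when instruments are noisy. For
IVW the large-$L$ expectation is
$\theta \cdot \sum w_j\gamma_j^2 / \sum w_j(\gamma_j^2 + \sigma_{xj}^2)$
— about 2% attenuation at the generator's default instrument strength
(mean $F \approx 40$–50) — while MR-Egger attenuates on the *spread* of
$\gamma$, $\mathrm{var}_w(\gamma)/(\mathrm{var}_w(\gamma) + \sigma_x^2)$,
roughly 11–16% here because the spread is much smaller than the mean. The
estimator tests assert recovery against this closed-form attenuated
expectation (computed from the truth sidecar), not against bare $\theta$;
an acceptance check that demands the raw means sit within Monte-Carlo
error of $\theta$ fails for exactly this reason, and is retained in the
suite as a documented negative result. For the same reason the calibration
experiments for the Egger intercept test and Cochran's Q are run at
$\theta = 0$: at $\theta \ne 0$ attenuation leaks a genuine nonzero
intercept (and genuine heterogeneity) into the data-generating process, so
rejections there are not type-I errors.

## Numerical choices

* Empirical p-values are $(1+k)/(1+N)$, never zero, so downstream
  log-scale reporting is safe.
* The mode bandwidth falls back to the sd-based term when the IQR is zero
  but the sd is not; when both are zero (all ratios identical) the
  estimate is the common ratio.
* Zero exposure effects would make a ratio estimate infinite; such SNPs
  are excluded with a warning before any ratio-based estimator runs.
* Clumping and outlier-removal tie-breaks are lexicographic on SNP id;
  combined with mandatory seeds this makes every pipeline output
  reproducible byte-for-byte.
* Comparisons follow the conventions stated with each filter: strict
  `<` for p-value ceilings, inclusive `>=` for the F floor, `>` 0.05 for
  global-test termination.

## Problem sizes

The shipped test suite and acceptance script run simulation studies at
deliberately modest sizes chosen to estimate each property comfortably:
200 replicates of $L = 100$ for estimator recovery, 500 replicates for
test size, 1000 for Q calibration, 20 seeded runs for planted-outlier
recovery (500 null draws each), 100 replicates for the
pleiotropy-robustness ordering, and 10 reverse-direction screens. The
full-scale defaults (10,000 null draws, 1000 bootstrap resamples) remain
the package defaults.

## Limitations

Beyond the generator's idealizations listed above: the package consumes
precomputed LD; it does not query phenotype databases (confounder
exclusion is list-driven); binary-outcome effects are treated as log-odds
throughout without liability-scale conversion; and no multivariable or
robust-regression MR variants are provided — the five estimators and
diagnostics above are the deliberate scope.
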