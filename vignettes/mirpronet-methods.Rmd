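---
title: "Methods: models, parameters, and design decisions in mirpronet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design decisions in mirpronet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirpronet)
```

`mirpronet` implements an integrative miRNA–proteome workflow: differential
expression (DE) on a pooled two-library small-RNA design and a replicated
isobaric-tag proteome design, sequence-based miRNA target prediction in
3'UTRs, inverse-correlation network construction, and the wet-lab validation
statistics (comparative-CT qPCR, dual-luciferase ANOVA, rank correlation).
This vignette documents the statistical model behind each stage, every
parameter of the synthetic generator with the reason for its default, the
numerical choices, and the known limitations.

## 1. The study design being modeled

Two conditions are compared: an eyestalk-intact animal (`esi`) and an
eyestalk-ablated animal (`esa`). Eyestalk ablation removes the source of
gonad-inhibiting hormone and triggers ovarian maturation. Each condition
contributes one pooled small-RNA library (so miRNA DE must be inferred from
two count vectors without biological replicates) and a replicated
quantitative proteome (so protein DE can use per-protein t-tests, or, when
only published ratios are available, a fold-change rule). The integrative
hypothesis is repression: an edge between miRNA *m* and protein *p* is
plausible only if *m* has a predicted binding site in the 3'UTR of *p* **and**
the two moved in opposite directions after ablation.

## 2. miRNA differential expression: the conditional exact binomial test

With a single library per condition, the standard device is to condition on
the total count of a miRNA across both libraries. If miRNA *i* has counts
$(k_1, k_2)$ in libraries of total depth $(N_1, N_2)$, then under the null of
equal relative abundance,

$$ k_1 \mid (k_1 + k_2 = n) \;\sim\; \mathrm{Binomial}\!\left(n,\; \frac{N_1}{N_1+N_2}\right). $$

`binomial_test()` computes the two-sided p-value by the **minimum-likelihood
rule** (as in `stats::binom.test`): sum the probabilities of all outcomes no
more likely than the observed one, with a relative tolerance of $10^{-7}$ on
the likelihood comparison to absorb floating-point ties. The test suite
verifies this against an independent oracle that enumerates the full outcome
distribution; the maximum absolute disagreement over 1000 random instances is
at machine precision (~$10^{-15}$).

Fold changes are computed on TPM-normalized counts
(`count / library_total * 1e6`) with a pseudocount of 1 added to counts and
totals so that zero counts yield finite log fold changes. Two threshold
profiles are provided because published analyses often use different rules in
the methods and in the reported lists:

* `"methods"` (default): significant if $q < 0.01$ and $|\log_2 FC| > 1$,
  with $q$ from Benjamini–Hochberg (or optionally a Storey estimator with a
  fixed $\lambda = 0.5$, implemented from the definition
  $\hat\pi_0 = \#\{p > \lambda\}/((1-\lambda) m)$).
* `"results"`: significant if $p < 0.05$ and $FC \ge 2$ or $\le 0.5$.

Low-abundance miRNAs are removed before testing when the **pooled** count
across both libraries is at most `min_reads = 20`; the exact test has
essentially no power there and removing them improves the multiple-testing
budget.

## 3. Protein differential expression

`call_de_proteins()` has two modes matching the two forms protein data take:

* `mode = "fc"` takes a table of published ESA/ESI ratios and classifies
  them with a symmetric fold-change rule: up if $FC \ge 1.2$, down if
  $FC \le 1/1.2$. No p-values are computed; the result is flagged with a
  `passthrough_significance` attribute so downstream code knows significance
  was not re-derived.
* `mode = "replicates"` takes long-format log2 abundances with at least two
  replicates per condition, runs a Welch two-sample t-test per protein,
  adjusts by Benjamini–Hochberg, and reports $FC = 2^{\bar y_{esa} - \bar
  y_{esi}}$. Welch rather than pooled t because isobaric-tag channel
  variances need not be equal; the cost is power at tiny $n$ — at $n = 3$
  per group, a true $FC = 1.5$ with log2-scale noise sd 0.2 is detected at
  $p < 0.05$ only 65.5% of the time (Monte Carlo with 200,000 replicates;
  the pooled noncentral-t formula would claim 76.3%, which is wrong for
  Welch because the Satterthwaite degrees of freedom are themselves noisy).
  The test suite asserts the generator's empirical recall against this
  Monte-Carlo value, not the optimistic formula.

`de_direction_share()` is the small closed-form helper for summary
percentages (e.g. `de_direction_share(132, 163)` = 80.98).

## 4. The target scanner

`scan_pair()` aligns the **reversed** miRNA against the 3'UTR (miRNA–target
duplexes are antiparallel) by Smith–Waterman local dynamic programming with
Gotoh affine gaps, implemented in C++ for speed. The scoring scheme:

| feature | score |
| --- | --- |
| Watson–Crick pair (A:U, G:C) | +5 |
| G:U wobble | +1 |
| mismatch | −3 |
| gap open / extend | −9 / −4 |
| seed positions 2–8 of the miRNA | pair score ×2 |
| reporting threshold | 140 |

With the encoding A=0, C=1, G=2, U=3, a pair is Watson–Crick iff the codes
sum to 3 and a wobble iff they sum to 5, which keeps the inner loop
branch-light. A perfect site for an L-nt miRNA scores $5L + 35$: $5(L-7)$
from the non-seed positions plus $10 \cdot 7$ from the doubled seed — this
closed form is asserted in the tests for many lengths. The default threshold
of 140 therefore admits perfect sites only for $L \ge 21$ and forces shorter
or imperfect sites to earn their score.

Two implementation subtleties:

* **Seed weighting uses absolute miRNA positions.** A local alignment may
  begin in the middle of the miRNA, so the scanner reports `mirna_start` and
  both `score_alignment()` and the strict-seed filter take it as an offset;
  weighting seed positions relative to the alignment start would mis-score
  any hit that clips the miRNA 5' end.
* **Non-overlap selection.** Multiple sites per UTR are reported greedily by
  score with overlapping intervals suppressed, so two planted copies of a
  site are both found at full score.

The optional `strict_seed` filter additionally requires six contiguous
Watson–Crick pairs at miRNA positions 2–7 (no wobbles, no gaps), the
classical "conserved seed" rule.

Correctness is established against a brute-force enumerator that tries every
alignment up to a gap budget: the dynamic program is never below the
2-gap enumeration, and matches the enumeration exactly when the budget covers
the reported hit's gap count. (On random short pairs, about 7% of optima
need more than two gap columns, which is why the oracle's budget adapts.)

## 5. Network integration

`build_network()` keeps an edge (m, p) iff: *m* is a significant DE miRNA,
*p* is a significant DE protein, the scanner reports at least one site of
*m* in the UTR of *p*, and $\mathrm{sign}(\log_2 FC_m) = -\mathrm{sign}(\log_2 FC_p)$.
`build_network_from_pairs()` builds the same object from an already-curated
pair list (e.g. a published table), rejecting — with a warning and a
`rejected` attribute — any pair violating the inverse rule or with
non-positive fold changes. Invariants enforced on every network: bipartite,
no isolated nodes, all fold changes positive, and every edge
inverse-consistent. `edge_metrics()` scores a predicted edge set against a
truth set by precision and recall on the (miRNA, protein) pair identity.

## 6. Validation statistics

* `relative_activity()`: firefly/renilla ratios normalized so each plate's
  negative-control construct+treatment group means 1.
* `anova_tukey()`: one-way ANOVA followed by Tukey's HSD. Adjusted p-values
  are verified against a direct studentized-range computation,
  $P = \mathrm{ptukey}(|\bar y_i - \bar y_j| / \widehat{se},\, k,\, N-k)$
  with $\widehat{se} = \sqrt{MSE/2\,(1/n_i + 1/n_j)}$, to $10^{-8}$ over
  random unbalanced designs. Pairwise labels are reconstructed from
  `combn(levels, 2)` rather than by splitting `TukeyHSD` row names, because
  group names containing hyphens make the row names unparseable. The compact
  letter display uses the standard insert-and-absorb algorithm.
* `relative_expression()`: comparative-CT ($2^{-\Delta\Delta CT}$) with
  technical replicates averaged within biological replicates first, the
  time-0 group as calibrator (geometric mean RQ of 1 by construction), and
  Welch tests of each time point against the calibrator. One extra CT cycle
  relative to the reference halves RQ exactly — asserted in closed form.
* `spearman_pair()`: Spearman's $\rho$ with an **exact permutation p-value**
  for $n \le 8$ (all $n!$ permutations; at $n = 6$ a perfectly
  anti-monotone series gives $p = 2/720$) and the usual t-approximation for
  larger $n$. Exactness matters because published time courses typically
  have 5–7 points, where the approximation is poor.

## 7. The synthetic generator

`synth_config()` fully determines a study; `simulate_study()` materializes
sequences, counts, proteome, and the ground-truth edge list. All randomness
flows through a single seed: each stage draws from a sub-seed derived as
`(seed * 48271 + offset) mod (2^31 − 1)` so stages are independent and adding
a stage never perturbs another stage's draws. `noiseless = TRUE` replaces
every stochastic layer by its mean, giving exactly recoverable truth — the
pipeline achieves precision = recall = 1 there, which separates
statistical-power effects from implementation errors.

### Parameters and defaults

| parameter | default | rationale |
| --- | --- | --- |
| `seed` | 42 | arbitrary fixed default; any integer works |
| `n_mirnas`, `n_proteins` | 100, 200 | large enough for multiple-testing behavior to matter, small enough for seconds-scale runs |
| `mirna_length_range` | 21–23 | the canonical mature-miRNA length range; also ensures perfect planted sites ($5L+35 \ge 140$) clear the scanner threshold |
| `utr_length_range` | 200–1500 | typical invertebrate 3'UTR lengths; long enough that spurious 140-score sites are rare in random sequence |
| `n_de_mirnas`, `n_de_proteins` | 10, 15 | ~10% DE fraction, matching the sparse-signal regime of the design |
| `de_log2fc_range` | 1.5–3 | clears both threshold profiles ($|\log_2 FC| > 1$, $FC \ge 2$) so recall measures noise, not threshold geometry |
| `de_down_fraction` | 0.75 | ablation removes an inhibitory signal, so most regulatory miRNAs fall; the published pattern is a down-dominated miRNA layer and an up-dominated protein layer |
| `coupling_strength` | 0.3 | protein $\log_2 FC = -0.3 \times$ miRNA $\log_2 FC$: repression is real but buffered. The implied protein fold changes (≈1.4–1.9) sit in the range typical of iTRAQ ratio tables |
| `protein_fc_noise_sd` | 0.05 | log2-scale replicate noise. iTRAQ technical precision is a few percent CV; 0.05 (~3.5% CV) makes the planted fold changes detectable at $n = 3$ after BH correction (measured recall ≈ 0.93 at sd 0.05 vs ≈ 0.41 at sd 0.10), consistent with the generator representing a well-powered technical-replicate design |
| `nb_dispersion` | 0.05 | counts are Poisson with a per-miRNA gamma factor **shared between conditions**, i.e. marginally negative binomial but exactly binomial *conditionally* — this keeps the exact test calibrated (measured null rejection fraction 0.045 at $\alpha = 0.05$ over 100 simulated null studies) while still giving realistic overdispersion across miRNAs |
| `base_mean`, `base_mean_log_sd` | 150, 1 | log-normal baseline abundances spanning roughly 20–1000 counts, straddling the `min_reads = 20` filter |
| `n_replicates` | 3 | the usual minimal replicated proteome design |
| `timepoints_h` | 0–168 h | a week-long post-ablation qPCR time course |
| `ct_noise_sd` | 0.15 | ~0.15-cycle qPCR repeatability, standard for technical triplicates |
| `luciferase_repression` | 0.5 | a planted miRNA mimic halves wild-type reporter activity; mutant-site constructs are unaffected |
| `luciferase_noise_sd` | 0.05 | per-well ratio noise small enough that the 4-group ANOVA at $n = 3$ separates only the wild-type+mimic group |

### What the generator plants

DE miRNAs get log2 fold changes drawn from `de_log2fc_range` with the chosen
down fraction. Proteins are coupled round-robin to DE miRNAs with
opposite-sign fold changes, and each coupled protein's 3'UTR carries the full
reverse complement of its miRNA at a uniformly drawn, recorded position —
full complementarity, rather than a seed-plus-mismatch site, so that planted
truth is unambiguous at the default threshold and failures to recover it
indicate bugs or statistical noise, not scanner tuning. The time course
plants anti-monotone latent trajectories for a chosen (miRNA, target) pair
(miRNA decaying, target rising, both scaled by elapsed fraction of the
course), and the luciferase plate plants repression only in the
wild-type-construct/mimic-treatment cell.

## 8. Reproducibility machinery

`run_pipeline()` writes every stage artifact plus `manifest.json` containing
the full configuration, thresholds, a scanner-parameter fingerprint,
per-stage record counts, and MD5 digests of every artifact; identical
configurations produce byte-identical outputs (asserted in the tests).
`scripts/acceptance.R` recomputes the headline quantities from scratch with
all randomness derived from `--seed` and writes them as JSON.

## 9. Limitations

* The exact binomial test conditions away library-size uncertainty but
  cannot model **biological** variance with one pooled library per
  condition; its p-values measure sequencing-depth surprise, not
  population-level effect reliability. This is a property of the design, not
  the implementation.
* The scanner is a pure alignment score: no thermodynamic (free-energy)
  term, no site-accessibility or conservation filter, so it corresponds to a
  miRanda-class first-pass screen, not a modern ensemble predictor.
* The generator plants perfectly complementary sites and linear
  miRNA→protein coupling; it is built to validate the pipeline's recovery
  behavior, not to be a realistic transcriptome simulator. Spurious
  high-scoring sites in random UTR sequence can create extra true-ish edges
  only if they coincide with a DE-coupled pair, which is rare at the default
  threshold but not impossible at permissive thresholds.
* Storey's q-value uses a fixed $\lambda = 0.5$ rather than the spline
  estimator; with hundreds (not tens of thousands) of tests the spline is
  unstable anyway, but the two can differ.
* `relative_expression()` assumes amplification efficiency of exactly 2 per
  cycle (the comparative-CT assumption) and Welch tests on RQ values, which
  are only approximately normal.
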