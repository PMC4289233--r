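---
title: "Ratiometric co-expression: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ratiometric co-expression: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratiometrics)
library(dplyr)
```

## The model

Classical co-expression measures — the squared Pearson correlation (PE),
Spearman rank correlation (SP), and mutual information (MI) — score how
similarly two genes' expression trajectories move across samples. They are
at their best when between-sample variation is large, and they are nearly
blind to a different kind of relationship: two genes whose *relative*
expression is tightly held even though neither varies much in absolute
terms. In large panels of highly similar samples (hundreds of
lymphoblastoid lines, or many cells of one type), that second kind of
relationship is exactly what shared regulation should look like.

The ratiometric association (RA) measure targets it directly. For a gene
pair $(A, B)$ with per-sample values $a_i, b_i$, consider the two ratio
series $a_i/b_i$ and $b_i/a_i$ and their coefficients of variation

$$CV(A/B) = \frac{\mathrm{sd}(a_i/b_i)}{\overline{a_i/b_i}}, \qquad
  CV(B/A) = \frac{\mathrm{sd}(b_i/a_i)}{\overline{b_i/a_i}}.$$

If $A/B \approx c$ holds across samples, both CVs are small and — because
$B/A \approx 1/c$ — approximately equal. The stringency-of-fit statistic

$$\Delta_{CV} = \lvert CV(A/B) - CV(B/A) \rvert$$

is zero for an exact proportionality, invariant to gene order, and
well-suited as a *gate*: a pair follows a ratiometric profile when
$\Delta_{CV}$ falls strictly below a threshold (0.01 by default for bulk
data). Gated pairs are then ranked by their *stability*, the combined
magnitude of the two CVs — smaller is stronger. The sample means of the
ratios estimate the ratiometric constants $c$ and $d = 1/c$.

The package computes, for every unordered gene pair of a filtered
expression matrix, the full record: both ratio CVs, $\Delta_{CV}$, the
ratio means, Pearson $r$ and $R^2$, squared Spearman correlation, and a
binned mutual information — and builds the downstream comparisons on top:
rankings, stringency-sweep graphs, overlap partitions, enrichment scores,
permutation nulls, and the validating simulations.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `delta_cv_threshold` | 0.01 (bulk), 0.025 (single cell) | gate on $\Delta_{CV}$; strict `<` |
| `stability_rule` | `max` | how the two CVs collapse into one stability value (`max` is conservative; `mean` available) |
| `mi_bins` | 4 | equal-frequency bins per margin; the MI range is $[0, \log_2(\text{bins})]$, so 4 bins give the $[0,2]$-bit scale |
| `cv_ddof` | 1 | sample SD ($n-1$) in the ratio CVs |
| `min_used_fraction` | 0.95 | fraction of samples that must be positive in both genes for the ratio statistics to be evaluable |

Zeros deserve a note: ratios are undefined at zero, so samples with a zero
in either gene are excluded from the ratio statistics (but retained for
PE/SP/MI, which are defined there). A pair with too many zeros is flagged
`ra_evaluable = FALSE` rather than silently scored.

The MI estimator is a plug-in estimate on an equal-frequency
discretization. Ties receive average ranks; a tie group whose average rank
lands exactly on a bin boundary falls deterministically into the lower
bin. The bulk filter (`filter_by_expression()`) keeps genes with abundance
$\ge 1$ in $\ge 95\%$ of samples, both comparisons inclusive — so 3 of 4
samples passes a 0.75 fraction. The single-cell filter
(`filter_multi_batch()`) keeps genes expressed (abundance $\ge$ floor, 1
by default) in all but `allowed_misses` (1) cells of *every* batch.

## Stringency sweeps and graphs

Each method's statistic range is divided into 100 equal-width thresholds
from most to least stringent: $R^2$ from 1 to 0 for PE/SP, $I$ from
$\log_2(\text{bins})$ to 0 for MI, and for RA either $\Delta_{CV}$ from 0
to 1 over the evaluable pairs (`delta_cv` mode, the graph-growth reading)
or the stability of gate-passing pairs from 0 to its observed maximum
(`gated_cv` mode, the ranked-analysis reading). Both readings are
implemented because both genuinely occur in how such sweeps are described;
`delta_cv` is the default for inclusion profiles, `gated_cv` for recovery
curves and size-matched comparisons. Each step's graph keeps only genes
with degree $\ge 1$; graphs are nested by construction, which the tests
assert. Size-matching for overlap comparisons picks the most stringent
step whose vertex (or edge) count first reaches the target.

Ranking ties are broken by a secondary statistic (RA → $\Delta_{CV}$,
PE/SP → $|r|$, MI → $R^2$) and then by the lexicographic gene-id pair, so
all outputs are byte-stable across runs.

## Enrichment scoring

Gene-set inputs are GMT files; pair annotations are two-column lists;
ontologies are child→parent edge lists (two-column TSV or OBO `is_a`
stanzas) plus gene→term annotations. Undersized ontology terms are
aggregated upward: annotations are first propagated up the DAG (a term's
detected set includes its descendants'), terms reaching `min_size = 200`
detected genes become anchors, and every smaller term merges into its
nearest anchor ancestor, ties broken by fewest detected genes then
lexicographic id; terms with no qualifying ancestor go to the root and are
flagged. Enrichment itself is the standard one-sided hypergeometric tail
with Bonferroni correction (threshold $10^{-4}$) — no EASE-style variant.

The permutation null for within-pathway recovery draws random gene sets
matched to the pathway's size and expression profile: genes are stratified
into 10 equal-frequency bins of mean expression and each draw respects the
pathway's bin composition. Because the recovery curve depends only on the
already-built sweep and the gene set, permutations reuse the sweep rather
than recomputing pair statistics; each permuted curve is exactly what a
recomputation would give.

## Simulations and what the fixture does (and does not) show

`simulate_range_restriction()` draws $a_i = 2 b_i + u_i$ with
$u_i \sim N(0, 50)$ and $B \sim N(500, s)$ for $s = 0, 5, \dots, 125$,
i.e. $CV(B)$ from 0 to 25% of the mean — 10 datasets of 100 samples per
$s$. All stated normal parameters are read as standard deviations (the
$CV(B)$ range only works out that way). Draws with a non-positive value
are rejected and redrawn so ratios stay defined. The output reproduces the
defining contrast: the correlation statistics collapse as B's range
narrows while the ratio CV stays flat. Two honest caveats, reflected in
how the tests assert this: at $s = 0$, B is exactly constant and the
correlation is undefined (reported `NA`); and with 10 replicates the
per-$s$ means carry Monte-Carlo noise, so monotonicity is asserted up to
that resolution (no adjacent decrease beyond 3 pooled standard errors)
and flatness as the dispersion (sd/mean $<$ 10%) of the per-$s$ mean
$CV(A/B)$ — the expected ratio CV itself drifts upward by a few percent
across the sweep because $E[1/B^2]$ grows with $s$, a property of the
generative model rather than of the estimator.

`simulate_bivariate_normal()` draws pairs from a bivariate normal with
means 200, generative correlation 0.47, and equal SDs sweeping 10–80
(1000 runs of 1000 observations each). The sample correlation is constant
in SD — a property of the multivariate normal — while the fraction of runs
meeting the ratiometric definition ($\Delta_{CV} < 0.01$ *and* stability
$\le 0.135$; a `stability_only` flag drops the gate) collapses once the
SD-to-mean ratio makes the ratio CVs exceed the bound, around SD 26 here.
Draws are untruncated: rejecting non-positive values would truncate the
distribution and bias the sample correlation low at large SDs, breaking
the very constancy the experiment demonstrates; instead a run containing
a non-positive draw simply cannot meet the ratiometric definition (its
ratios are undefined). Non-positive draws are vanishingly rare below the
SD where the fraction reaches zero anyway.

`simulate_independent_null()` measures the false-positive gate rate on
independently expressed gene pairs. The abundance law is log-normal
(`meanlog = log(100)`, `sdlog = 0.5`) — a realistic FPKM-like dispersion,
chosen once since no canonical law exists for this null. Worth knowing:
two *independent* log-normal genes have symmetrically distributed ratio
CVs, so their $\Delta_{CV}$ concentrates near zero and a non-trivial
fraction passes the gate by chance. Those pairs carry large stability
values, which is exactly why ranked analyses use stability after the
gate.

`generate_fixture()` is the package's stand-in for a real homogeneous
panel: 200 samples; 50 planted ratiometric pairs
($a_i = c\,b_i(1+\varepsilon_i)$, 5% multiplicative noise, constants
log-uniform in $[0.2, 5]$); 50 wide-range correlated pairs (linear with an
offset across a wide abundance range); 50 two-regime pairs (an
uncorrelated low-expression bulk plus a small jointly-high sample
subgroup); 500 independent background genes with per-gene log-normal
dispersion ($\mathrm{sdlog} \in [0.2, 0.6]$); and, on request, two planted
modules — a *tight* pathway (genes proportional to one narrow-range base
profile; low expression CV, strongly ratiometric) and a *wide* pathway
(genes linearly tied to one wide-range profile; strongly correlated). The
fixture emulates the structure these methods discriminate on, not real
RNA-seq: there is no count noise model, no batch structure, no isoform
ambiguity, and the planted classes are cleanly separated. Passing tests
on the fixture demonstrate that the implementation ranks, gates, sweeps
and scores correctly and that the methods differ in the direction the
theory predicts — not that RA will recover any particular biology on a
real panel.

Problem sizes used throughout the tests were chosen to keep the full
suite under a minute while leaving every comparison well away from its
assertion boundary: oracle equivalence on $\le 20$-gene matrices, sweeps
and enrichment on the 800–830-gene fixture, and the two simulation
reproductions at their stated scales (8 × 1000 × 1000 and 26 × 10 × 100).

## Numerical and degenerate-input choices

- Ratio variance is computed from first and second moments with a clamp at
  zero before the square root; an exactly proportional pair reports CV 0.
- A constant vector is an error for the correlation statistics (undefined)
  and for MI (degenerate binning); `pair_measures()` converts those errors
  into `NA` fields so all-pairs tables never abort.
- `all_pairs()` processes gene blocks with matrix algebra (masked
  reciprocal products for ratio moments, indicator cross-products for the
  joint MI histograms); block size bounds memory, and results are
  independent of it — asserted in the tests against a per-pair loop.
- Stability ties in rankings, bin-boundary ties in the MI discretization,
  and ancestor ties in ontology aggregation all break deterministically
  (documented above), so identical inputs give identical bytes.

## Known limitations

- RA statistics require positive values; panels with heavy dropout leave
  many pairs non-evaluable under the default `min_used_fraction` — lower
  it (and widen the gate, e.g. 0.025) for single-cell data.
- The MI estimator is the plug-in estimate on a fixed discretization; it
  is the intended baseline, not a state-of-the-art MI estimator.
- The two-regime flag is a deliberate heuristic (drop in $R^2$ after
  removing the top decile by $a+b$), good for triage, not inference.
- Enrichment is plain hypergeometric/Bonferroni on user-supplied
  annotations; no annotation download, no GSEA-style statistics.
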