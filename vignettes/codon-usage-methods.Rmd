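---
title: "Methods: codon usage bias statistics in codonbias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon usage bias statistics in codonbias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonbias)
```

This vignette records the exact statistical definitions, conventions and
edge-case policies the package implements, so that results can be
reproduced and compared against other software without reading source
code.

## Scope and alphabet

All statistics operate on the 59 *informative* synonymous codons: the
61 sense codons minus AUG (Met) and UGG (Trp), whose amino acids admit
no synonym. Stop codons are excluded throughout. Codons are reported in
the RNA alphabet in fixed alphabetical order, so tabular outputs are
byte-stable. `count_codons()` reads in-frame triplets; under the default
`frame_policy = "strict"` a sequence whose length is not a multiple of
three is an error, while `"trim_tail"` drops the trailing partial codon.

## RSCU

For codon $i$ of an amino acid with family size $N_i$ and family total
$T$ observations,

$$\mathrm{RSCU}_i = \frac{x_i \, N_i}{T}.$$

When $T = 0$ the ratio is undefined and every codon of that family is
reported `NA` — never 0, which would falsely signal avoidance.
`classify_frequency()` bins RSCU as *high* (strictly $> 1.5$), *low*
(strictly $< 1.0$) and *mid* otherwise; a value of exactly 1.50 is mid.

## Third-position composition

`third_position_composition()` uses the codonW "could-have" convention:
X3s is the percentage of synonymous codons ending in base X among the
synonymous codons whose family *offers* an X-ending synonym. The
denominators therefore differ per base (e.g. the two-codon families
NAU/NAC offer C and U but not A or G endings). GC3s is the fraction of
G+C third positions among all 59-codon observations, on the same
could-have basis.

## Effective number of codons

Wright's ENc is assembled from per-family homozygosity
$\hat F = (n\sum_k p_k^2 - 1)/(n-1)$ with $n$ the family total and
$p_k$ within-family frequencies. Families with $n \le 1$ or
$\hat F \le 0$ are excluded. Class means $\bar F_d$ are taken over
degeneracy classes $d \in \{2, 3, 4, 6\}$ (9, 1, 5 and 3 families
respectively) and

$$\mathrm{ENc} = 2 + \frac{9}{\bar F_2} + \frac{1}{\bar F_3}
  + \frac{5}{\bar F_4} + \frac{3}{\bar F_6},$$

capped at 61. A missing 3-fold class (isoleucine absent) is imputed as
$(\bar F_2 + \bar F_4)/2$, the standard patch; any other missing class
makes ENc `NA` with a warning rather than an error, so one sparse gene
does not abort a batch — the warning still surfaces the problem.
Sequences this short are outside the statistic's intended regime
anyway. ENc below 35 conventionally flags strong bias
(`flag_strong_bias()`).

## CAI, CBI and Fop

`cai_weights()` derives relative adaptiveness $w_i = x_i / x_{\max}$
per family from a user-supplied highly-expressed reference, replacing
zero reference counts by 0.5 (Sharp–Li pseudo-count) so unseen codons
penalize rather than annihilate the geometric mean. `cai()` is the
geometric mean of weights over informative codons; codons absent from
the weight table are skipped and counted in an attribute. There is
deliberately *no default reference set*: CAI is only interpretable
relative to an explicit reference, and a silent default would invite
cross-species misuse.

Given an optimal-codon set, `cbi_fop()` computes
$\mathrm{Fop} = N_{opt}/N_{syn}$ and
$\mathrm{CBI} = (N_{opt} - N_{rand})/(N_{syn} - N_{rand})$ with
$N_{rand} = \sum_{f} T_f \, m_f / N_f$, the count expected under uniform
synonym choice ($m_f$ optimal codons among the $N_f$ synonyms of family
$f$). If every observed synonymous codon is optimal the 0/0 case is
defined as CBI = 1; any other degenerate denominator is `NA`.

## Optimal-codon screening

`preferred_codons()` contrasts mean RSCU between a high-bias and a
low-bias gene group. By default groups are the lowest and highest ENc
quartiles (`fraction = 0.25`, at least two genes per group enforced);
explicit group membership can be supplied instead. Codons with
$\Delta\mathrm{RSCU} = \overline{\mathrm{RSCU}}_{high-bias} -
\overline{\mathrm{RSCU}}_{low-bias} \ge 0.08$ are called preferred.
`optimal_codons()` intersects preferred codons with high-frequency
codons (RSCU > 1.5) in a profile of interest.

## Correspondence analysis

`correspondence_analysis()` performs classical CA on the genes × codons
RSCU matrix: with $P = N/\Sigma$, row masses $r$, column masses $c$,
the standardized residuals $S = (P - rc^\top)/\sqrt{rc^\top}$ are
decomposed by SVD; principal coordinates are the scaled singular
vectors and the inertia of axis $a$ is $d_a^2$. Conventions:

- `NA` cells (undefined RSCU) are imputed with their column mean before
  decomposition; the count of imputed cells is recorded on the result.
- A zero row or column margin is an error naming the offending gene or
  codon.
- The sign of each axis is fixed by making the dominant codon loading
  positive, so repeated runs and column permutations agree.
- The decomposition is validated in the test suite against a
  brute-force eigen oracle and against `MASS::corresp` (principal
  coordinates = standard coordinates × singular values) at $10^{-8}$.

`cluster_rscu()` clusters genes by Euclidean distance between RSCU
profiles (average linkage by default), sorting rows lexicographically
first so input order never changes the tree.

## Distance trees

`poisson_distance()` computes $d = -\ln(1 - p)$ from the proportion
$p$ of differing sites under *complete deletion*: alignment columns
containing `-`, `?` or `X` in any sequence are removed before
comparison. A pair with $p = 1$ is an error (saturated, distance
undefined). `neighbor_joining()` delegates tree construction to
`ape::nj` after sorting taxa by label (order invariance) and clamps
negative branch lengths to zero, recording how many were clamped.
`bootstrap_supports()` resamples alignment columns with replacement,
rebuilds the NJ tree per replicate (capping $p$ at $1 - 10^{-9}$ so
resampled saturated pairs stay finite), and annotates internal nodes
with percentage support via `ape::prop.clades`. The RNG seed is an
explicit argument; the caller's RNG state is saved and restored.

## Synthetic sequence generator

`codon_generate()` draws genes codon-by-codon. Amino acids are sampled
with weights defaulting to the pooled family totals of a 20-gene plant
XET (xyloglucan endotransglycosylase) family — a realistic plant
protein composition — and the synonym for an amino acid is drawn with
weight

$$w_{ij} \propto \left[b_{ij}\,(1 + 10^{-3}(N_i - \mathrm{rank}_j))\right]^{\kappa},
\qquad b_{ij} = \begin{cases} g & \text{third base G or C}\\
1 - g & \text{otherwise}\end{cases}$$

where $g$ is `gc3_bias` and $\kappa$ is `concentration`. $\kappa = 0$
gives uniform synonym use regardless of $g$ (ENc near 61);
$\kappa = \infty$ collapses each family to its single highest-weight
codon (ENc = 20, GC3s = 100 when $g = 1$). The tiny rank term breaks
ties deterministically at $\kappa = \infty$. `expected_gc3s()` returns
the analytic GC3s implied by the weights, which the generator matches
within 2 percentage points at 10,000 codons in the test suite. Each
gene is `AUG` + sampled codons + `UAA`, so generated FASTA round-trips
through `count_codons()` exactly. Defaults (20 genes of 225 codons)
mirror a typical small gene-family study.

## Problem sizes and validation

The test suite exercises single genes of 300 codons (the packaged
citrus XET count table), a 20-gene × 59-codon family table, generated
batches of up to 12 genes × 300 codons, a 10,000-codon convergence
check, CA oracles on 3×3 to 5×5 tables, 4-taxon additive-tree recovery,
and bootstrap runs of 25–1000 replicates. All published-table fixtures
are checksum-validated on load (`xet_fixture()`).

## Limitations

- ENc and the third-position statistics assume standard genetic code;
  alternative codes are not supported.
- CAI requires a biologically appropriate reference set; the package
  cannot validate that choice.
- The preference screen is a mean-difference heuristic, not a formal
  test; with few genes per group it is noisy, and the pipeline skips it
  below four genes.
- The generator models codon choice as i.i.d. given the amino acid; it
  does not model dicodon effects, GC gradients along genes, or amino
  acid composition differences between genes.
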