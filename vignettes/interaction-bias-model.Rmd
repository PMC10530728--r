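---
title: "Simulating interaction bias in microbiome data: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating interaction bias in microbiome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biasim)
```

## The measurement-bias model

Marker-gene sequencing measures relative, not absolute, abundances, and
measures them through a pipeline in which each step multiplies each
taxon's signal by an efficiency factor. Accumulated over the pipeline this
yields the multiplicative main-effect model: the expected observed
relative abundance of taxon $j$ in sample $i$ is

$$\log p_{ij} = \log \pi_{ij} + \gamma_j + \alpha_i,$$

with $\pi_{ij}$ the true relative abundance, $\gamma_j$ a taxon-specific
log bias, and $\alpha_i$ the per-sample normalization constant that makes
$\sum_j p_{ij} = 1$. The key property of this model is that *ratios*
between taxa are distorted by a constant factor
$e^{\gamma_j - \gamma_k}$ independent of the sample, which is why
log-ratio-based methods can in principle be made robust to it.

Mock-community evidence suggests the bias factor of a taxon can also
depend on the rest of the community. `biasim` adds an interaction term,

$$\log p_{ij} = \log \pi_{ij} + \gamma_j +
  \sum_{j' \ne j} \theta_{jj'}\, \pi_{ij'} + \alpha_i,$$

so the perturbation contributed by taxon $j'$ scales with its relative
abundance. Interaction coefficients are generated relative to the main
effects:

$$\theta_{jj'} = -\,\mathrm{sign}(\gamma_{j'})\,\phi\,
  \epsilon_{jj'}\,\lvert\gamma_j\rvert ,$$

with $\phi \ge 0$ a community-wide magnitude and $\epsilon_{jj'} \ge 0$ a
unit-mean error. Three consequences are built into the construction and
are enforced as invariants:

* **Sign opposition.** $\theta_{jj'}$ always opposes the sign of
  $\gamma_{j'}$: a taxon that is over-measured depresses the measured
  abundances of the others, as expected when a roughly fixed number of
  amplicons is sequenced. A taxon with $\gamma_{j'} = 0$ induces nothing
  ($\mathrm{sign}(0)$ is taken as 0).
* **Row scaling.** Row $j$ of $\theta$ scales with
  $\lvert\gamma_j\rvert$; a taxon with no main-effect bias receives no
  interaction bias either.
* **Asymmetry.** Nothing forces $\theta_{jj'} = \theta_{j'j}$, matching
  the asymmetry seen in mock-community estimates.

The aggregate interaction term
$\eta_{ij} = \sum_{j' \ne j} \theta_{jj'} \pi_{ij'}$ mixes contributions
of both signs weighted by small relative abundances, so across samples
(and across redraws of the bias structure, the package default) its mean
sits near zero while its variance grows with $\lvert\gamma_j\rvert$ at
fixed $\phi$ — `eta_diagnostics()` computes exactly these summaries.

## Calibrating $\phi$

Presence-based interaction estimates from seven-taxon mock communities
give a mean absolute interaction-to-main-effect ratio of 0.204. In a
presence model the interaction term is a constant whenever the taxon is
present, whereas here it is $\theta_{jj'} \pi_{ij'}$; with three equally
abundant taxa per sample ($\pi = 1/3$) the conversion is a division:
`phi_from_presence_ratios(0.204, 1/3)` $= 0.612$. Simulation grids scan
$\phi \in \{0, 0.612, 1, 2, 4\}$ — from no interaction bias through the
empirical estimate to well beyond it.

## Error-term scenarios

The half-scale errors $\epsilon_{jj'}/2$ are drawn from one of two
unit-mean-preserving laws: $N(0.5, 0.1^2)$, unimodal with modest spread,
or $\mathrm{Beta}(0.5, 0.5)$, bimodal at 0 and 1 with variance $0.125$.
Scenario `S-nondiff` uses the normal law everywhere; `S-diff-causal`
switches rows of trait-associated taxa to the beta law (trait-related
variation); `S-diff-half` switches a random half of all rows
(trait-unrelated variation). Normal draws are clamped at zero — the
clamped mass is about $3\times 10^{-7}$, preserving the stated
non-negative support with negligible distortion.

Each row of $\epsilon$ is drawn from its own seeded sub-stream keyed by
(bias seed, row index). This makes scenarios *couple*: switching from
`S-nondiff` to `S-diff-causal` redraws only the causal rows, so the
$\eta$ values at null taxa are bitwise identical between the two
scenarios under a shared seed — the property that makes FDR differences
between scenarios attributable to the causal taxa alone.

## The data generator

A replicate dataset chains:

1. **Community profile.** Mean relative abundances $\bar\pi$ (856 taxa by
   default) with Dirichlet overdispersion $\theta_{DM} = 0.02$, i.e.
   concentration $\bar\pi_j (1 - \theta_{DM})/\theta_{DM}$, so
   $\mathrm{Var}(\pi_j) = \bar\pi_j (1 - \bar\pi_j)\theta_{DM}$. The
   bundled profile is synthetic: a sorted, normalized log-normal tail
   (sdlog 2, giving the heavy tail and many rare taxa typical of
   upper-respiratory-tract communities) beneath five pinned leading
   abundances 0.105, 0.062, 0.054, 0.050, 0.049. A user-supplied profile
   file replaces it via the `pi_bar_file` configuration key.
2. **Causal taxa.** Scheme M1: 20 taxa sampled from those with mean
   abundance above 0.005, excluding the single most abundant taxon
   ("most prevalent" is read as largest mean abundance, the only notion
   computable from $\bar\pi$ alone). Scheme M2: the top five. With a
   confounder, 10 + 10 (M1) or 2 + 3 (M2) taxa are drawn from the causal
   and null pools.
3. **Traits.** Binary: exactly $n/2$ samples per group in random order;
   continuous: $U[-1, 1]$. A binary confounder (only with binary traits,
   mirroring the designs the harness targets) is Bernoulli(0.2) in the
   $T = 0$ group and Bernoulli(0.8) in the $T = 1$ group.
4. **Spike-in.** True abundances tilt the baseline by
   $e^{\beta_{j1} T_i + \beta_{j2} C_i}$ and renormalize; $\beta_{j1}$ is
   a common $\beta$ on causal taxa and zero elsewhere. Confounder effect
   sizes are nowhere standardized, so the default sets
   $\lvert\beta_{j2}\rvert = \beta$ with alternating signs across the
   confounder set (configurable).
5. **Bias.** $\gamma_j \sim N(0, 0.8^2)$ — putting ~95% of bias fold
   changes between 0.2 and 5 — then $\theta$, then the observed
   abundances $p_{ij}$ via the displayed formula, using the *post-spike*
   true abundances in the interaction term (the formula's
   $\pi_{ij'}$ is the true abundance, not the baseline).
6. **Counts.** Library sizes from $N(10^4, (10^4/3)^2)$ left-truncated at
   2000 (rejection sampling, acceptance $\approx 0.99$, rounded to
   integers because the multinomial needs them) and one multinomial draw
   per sample.

Every component uses a named sub-stream derived from the replicate seed
(`mix_seed()`), so a replicate is a pure function of (configuration,
seed), any component can be regenerated in isolation, and changing one
component's distribution never shifts another's draws. Biases are redrawn
each replicate by default — averaging performance over bias
configurations, consistent with redrawing the Dirichlet baseline — with a
`fixed_bias` mode holding them constant where a single bias configuration
is wanted (e.g. the $\eta$ diagnostics). When $\phi = 0$ the
$J \times J$ error matrix is skipped entirely; because $\epsilon$ owns a
dedicated sub-stream this is exactly equivalent to drawing and discarding
it, and the observed abundances reduce bitwise to the main-effect-only
model.

## The reference tests and the evaluation harness

The bundled methods `wilcox-alr-half` and `wilcox-alr-one` apply, in
order: a presence filter (taxon kept when observed with a non-zero count
in at least 20% of samples; 10% is the laxer alternative several external
methods default to), selection of the most abundant *null* taxon — known
in simulated data — as the additive-log-ratio reference, the alr
transform after adding a pseudocount of 0.5 or 1 to every count, a
two-sided Wilcoxon rank-sum test per remaining taxon against the binary
trait, and Benjamini–Hochberg adjustment with detection at
$q \le 0.20$. The generous nominal level reflects the small causal sets
(5 or 20 taxa). The reference taxon itself is not tested and is excluded
from all denominators. The Wilcoxon p-value uses exact enumeration when
the smaller group has at most 10 tie-free observations and the
tie-corrected, continuity-corrected normal approximation otherwise;
columns constant across samples return $p = 1$ by convention. How the
rank-sum variants would handle a continuous trait is not specified
anywhere we could anchor to, so they refuse it with an explicit error.

`run_grid()` scans (scenario, $\phi$, $\beta$) cells for any set of
registered methods, holding the community profile and the causal and
confounder sets fixed within a cell (drawn from the cell seed) so that
empirical FDR and sensitivity vary only through sampling noise. The false
discovery proportion of a replicate counts detections outside the set
$\{j : \beta_{j1} \ne 0\}$ — at $\beta = 0$ this set is empty, every
detection is false, and empirical FDR equals the probability of any
detection. An empty detection set contributes FDP 0 (the standard
convention making empirical FDR a mean of FDPs); sensitivity at
$\beta = 0$ is reported as missing rather than 0 to avoid averaging
artifacts. A failing method adapter marks the replicate failed for that
method and the grid continues.

## Problem sizes and what the checks do (and do not) show

Grid defaults are desk-scale: 200 replicates per cell (the reference
setting of 1000 is one configuration flag away), and package-level
verification runs the global-null FDR check with 500 replicates at
$J = 200$ taxa, $n = 100$ samples — sizes chosen so the whole suite
completes in about a minute while leaving Monte-Carlo error around the
nominal level at $\pm 2\sqrt{0.2 \cdot 0.8 / 500} \approx 0.036$.

The generator emulates the marginal features of a real
upper-respiratory-tract profile — heavy-tailed mean abundances, Dirichlet
overdispersion 0.02, realistic sequencing depths — but not taxon–taxon
*ecological* correlation (the Dirichlet forces weak negative
correlation), zero inflation beyond what the Dirichlet–multinomial
produces, phylogenetic structure, or longitudinal designs. Passing tests
therefore demonstrate correctness of the generative model and of the
analysis harness under these stated conditions, not performance claims
about real microbiome studies. Interaction biases in real communities
may also differ qualitatively from the mock-community-motivated model
(mock mixtures contain few taxa at equal proportions).

## Numerical and degenerate-case choices

* Row sums of abundance matrices are validated to $10^{-6}$ on input and
  held to $10^{-10}$ on output; the scalar-loop oracle for the observed
  abundance formula agrees with the vectorized path to $10^{-12}$.
* Pinned profile values are kept bitwise exact (no renormalizing
  division); the tail absorbs the remaining mass and, if its largest
  entry would exceed the smallest pinned value, is shrunk toward the
  uniform tail by a convex combination, which preserves both the total
  mass and the ordering.
* `sigma_gamma = 0`, `phi = 0`, `beta = 0` each degrade exactly: with all
  three zero the observed abundances equal the baseline bitwise.
* Reference-taxon ties break to the lowest column index; the M2 causal
  set ties break the same way through `order()`.
* Seeds are 31-bit integers derived by folding token strings into a
  multiplicative hash modulo the largest prime below $2^{31}$; collisions
  between distinct key paths are possible in principle but harmless (the
  affected sub-streams would merely share draws) and never observed in
  the suite.

## Session info

```{r}
sessionInfo()
```
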