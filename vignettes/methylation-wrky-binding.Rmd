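---
title: "How wrkymeth models methylation-dependent WRKY-DNA binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How wrkymeth models methylation-dependent WRKY-DNA binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wrkymeth)
```

## The scientific question

WRKY transcription factors bind the W-box element, core `TTGAC(C/T)`.
Cytosine methylation (5mC) on this element can repel binding, and the effect
is position-specific: in the orientation used throughout this package the
core reads `G1 G2 T3 C4 A5 A6` (the reverse complement of `TTGACC`), so the
only forward-strand cytosine sits at position 4 in a CHH context, while
positions 1 and 2 carry cytosines on the reverse strand. `wrkymeth`
implements three independent, mutually reinforcing analyses of how a
5-methyl group at these cytosines represses binding:

1. a genome-scale DAP/ampDAP signal-ratio analysis with per-motif-position
   correlation statistics,
2. a 1:1 binding-kinetics layer for Bio-Layer Interferometry (BLI)
   sensorgrams of methylated and unmethylated W-box duplexes, and
3. an atomic contact/clash analysis of the W-box C4 base against the
   conserved WRKY-domain tyrosine.

A synthetic-data module generates every input these analyses need, so the
whole pipeline is testable offline.

## 1. DAP/ampDAP methylation sensitivity

DAP-seq assays TF binding on native genomic DNA (methylation intact);
ampDAP-seq repeats the assay on PCR-amplified DNA (methylation erased). For
a bound region with read counts $d$ and $a$ and library sizes $D$ and $A$,
the package uses the normalized log ratio

$$\log_{10}\frac{(d + c)/D}{(a + c)/A},$$

with pseudocount $c = 1$ read keeping the ratio finite. A negative ratio at
a methylated region means methylation represses binding.

Three methylation summaries are computed, mirroring three levels of
resolution:

* **region level** — methylation density: the proportion of cytosines
  (both strands) in the region whose methylation probability is *strictly*
  greater than 0.5;
* **site level** — the count of such cytosines within the best PWM-scoring
  window of the region (the best TFBS, searched on both strands with
  log-odds scores, ties resolved toward the smaller offset and the forward
  strand);
* **position level** — for every motif position and strand, the Pearson
  correlation (two-sided) between the log ratio and the *continuous*
  methylation probability of the cytosine at that position, over regions
  whose best site carries a cytosine there.

The 0.5 threshold applies only to the density and count summaries; the
correlation uses the raw probability as a covariate. Cytosines with no
methylome record are treated as confidently unmethylated (probability 0),
the usual convention for thresholded bisulfite tracks; the run log records
this choice.

p-values are adjusted with the Benjamini-Hochberg step-up over all
(position, strand) tests of one run — the narrowest defensible family.
Reporting follows two masking rules: positions with fewer than ten
cytosines are flagged `insufficient_n` (too unreliable to display), and
positions with adjusted FDR above 5% are blanked (`blank_fdr`). Masking
annotates, it never alters the statistics. Zero-variance positions are
flagged `degenerate` rather than raising errors: every position is always
reported.

Reverse-strand best sites are strand-normalized, so position indices always
refer to the motif and genomic strands are translated accordingly; a
"reverse-strand cytosine at position 2" means the same chemical entity in
every region regardless of which genomic strand the site fell on.

## 2. BLI kinetics and the scenario registry

A sensorgram follows the 1:1 Langmuir model. During association at analyte
concentration $C$:

$$R(t) = R_{eq}\left(1 - e^{-(k_{on} C + k_{off}) t}\right),
\qquad R_{eq} = \frac{R_{max} C}{C + K_D},$$

and during dissociation $R(t) = R_0\, e^{-k_{off} t}$, with
$K_D = k_{off}/k_{on}$. The phase schedule defaults to baseline 120 s,
loading 300 s, baseline 120 s, association 300 s, dissociation 900 s,
sampled at 1 Hz; loading is treated as an immobilization offset removed by
reference subtraction, so simulated traces are already referenced.

The scenario registry (`bli_scenarios()`) anchors the ground truth to the
measured steady-state affinities of the AtWRKY40 DNA-binding domain for a
16-mer W-box duplex: 630 nM unmethylated, essentially unchanged for 5mC at
reverse-strand positions 1 or 2, 12 µM for 5mC at position 4, and 9.2 µM
for the triple-methylated duplex — i.e. no additive effect beyond position
4. Dissociation rates are not part of that measurement; the registry uses
$k_{off} = 0.126\,s^{-1}$ for the tight scenarios (a representative
fast-exchange TF-DNA value) and scales $k_{off}$ with $K_D$ at fixed
$k_{on} = 2\times10^5\,M^{-1}s^{-1}$ for the weak ones, so the registry
identity $K_D = k_{off}/k_{on}$ holds exactly everywhere. The `C4T_mutant`
scenario (20 µM) is marked illustrative: it encodes the qualitative
observation that position-4 methylation is almost as disruptive as the
C-to-T substitution that abolishes W-box function, not a measured number.

Two estimators are provided, and both are reported because they can differ
under noise:

* **steady state** (the anchor): $R_{eq}$ per concentration (tail mean of
  the final 5% of association, or a single-exponential plateau when the
  phase is short or far from equilibrium), then a least-squares fit of the
  binding hyperbola. Positivity is enforced by fitting $\log K_D$ and
  $\log R_{max}$; initialization is $R_{max} = 1.1 \max R_{eq}$,
  $K_D = \mathrm{median}(C)$. Fits are flagged when the data only bound
  $K_D$ from one side (all concentrations far below $K_D$, or a saturated
  flat curve).
* **kinetic**: global nonlinear least squares with $k_{on}$, $k_{off}$,
  $R_{max}$ shared across all concentrations, dissociation starting from
  the model's end-of-association response. Initialization: $k_{off}$ from a
  log-linear regression on early dissociation, per-curve $k_{obs}$ from
  single-exponential fits, $k_{on}$ from the slope of $k_{obs}$ versus
  $C$. Non-convergence is returned as a flagged result, never silently.

The default concentration ladder is $K_D \times \{0.2, 0.5, 1, 2, 5\}$ —
five concentrations spanning the informative range of both fits, matching a
five-concentration experimental design. A per-concentration diagnostic fit
is also available; note that at 1 Hz sampling the per-curve $k_{obs}$ of
the weak scenarios (about $3\,s^{-1}$) is faster than the sampling rate and
only the global and steady-state analyses remain reliable there.

## 3. Structural contacts and the 5-methyl clash

The structural layer analyses ensembles of atomic models (plain fixed-width
PDB, multi-model via `MODEL`/`ENDMDL`). Definitions, since "van der Waals
contact" has no universal number:

* **contact**: distance $\le r_i + r_j + 0.5$ Å (Bondi radii; C 1.70,
  N 1.55, O 1.52, P 1.80, S 1.80, H 1.20);
* **clash**: distance $< r_i + r_j - 0.4$ Å (MolProbity-style overlap).

Both thresholds are arguments. Hydrogens are not modelled; the methyl
carbon added by `methylate_cytosine()` uses a united-atom radius of 2.0 Å
to approximate CH3 bulk (configurable to 1.70 Å for explicit-hydrogen
work). In-silico methylation places a single `C5M` carbon in the base plane
at 1.50 Å from C5 along the external bisector of C4-C5-C6 — ideal
thymine-like pyrimidine geometry — and refuses to run twice on the same
residue. Ensemble support includes Kabsch superposition (SVD, proper
rotation enforced; protein backbone N/CA/C by default) and contact
persistence: the fraction of models in which two groups share at least one
contact (or clash).

The shipped geometry fixture is deliberately synthetic: an idealized planar
C·G pair built from regular hexagon/pentagon geometry plus a tyrosine ring
fragment whose nearest carbon sits at exactly the contact distance (sum of
radii + 0.2 Å) from the cytosine C5, along the direction the 5-methyl group
occupies. That placement makes the mechanism checkable as two sharp
properties: unmethylated, the base touches the tyrosine (persistence 1.0,
zero clashes); methylated, the C5M carbon lands 2.1 Å from the nearest ring
carbon and clashes in every model. Extra ensemble models are rigid-body
copies, so these properties are rotation/translation invariant by
construction. The fixture restates the mechanism's geometry; it is not a
refined experimental structure, and conclusions about real complexes
require user-supplied ensembles.

## The synthetic peak-set generator

`generate_methylome_peakset()` emulates the joint structure the genome-wide
analysis consumes. Choices, and what they do and do not capture:

* Each 160-bp region carries exactly one planted site *sampled from the PWM
  columns* (so realistic near-consensus variation, about 15% of sites carry
  a mismatch), at a random offset and strand. Real bound regions can carry
  several sites; the analysis only ever uses the best one.
* Methylation probabilities: background cytosines Beta(1, 10) (mostly
  unmethylated, as in a euchromatic methylome); planted-site cytosines from
  the bimodal mixture 0.5 Beta(0.5, 5) + 0.5 Beta(5, 0.5), so both
  methylation states occur and correlations are estimable. Real methylomes
  have context- and neighborhood-dependent structure that is not modelled.
* The planted signal is linear on the log scale:
  $\rho_i = \mathrm{baseline} - \sum_{j,s}\beta_{s,j}\, m_{s,j}
  + \varepsilon_i$, $\varepsilon_i \sim N(0, \sigma)$ with $\sigma = 0.2$
  by default; $\beta \ge 0$ encodes that methylation only represses in this
  generative model. Default planted effects 0.6 / 0.45 / 0.2 at positions
  4(+) / 2(-) / 1(-) reproduce the qualitative ordering strongest-at-4.
* Counts: ampDAP around a log-normal region baseline (mean 500 reads,
  sdlog 0.5), DAP scaled by $10^{\rho}$, both Poisson-realized
  (`count_noise = "poisson"`). The `"none"` mode skips count noise entirely
  so the computed log ratio equals the planted predictor to machine
  precision — that mode exists for exactness tests and diagnostics, not as
  a realistic condition.
* Fixed seed implies byte-identical output.

Because the planted sites are sampled (not forced to consensus), the
scanner occasionally prefers a different window; recovered correlations are
therefore slightly attenuated relative to the planted truth — as they would
be on real data with imperfect site calls. Passing tests on this generator
show that the statistics recover planted monotone effects with controlled
type-I error under the stated noise; they cannot show robustness to
chromatin, mapping or peak-calling artifacts, which the generator does not
emulate.

## Numerical choices and degenerate inputs

* Pseudocounts: 1 read (ratios), PWM pseudocount 1 split over the bases.
* Best-site ties are broken toward the smaller offset, then the forward
  strand; window scores are compared after rounding to 1e-9 so that
  mathematically equal windows tie regardless of summation order. `N` bases
  contribute zero log-odds (background).
* Correlations need at least 3 pairs to be attempted, 10 to be reported;
  zero variance is flagged, not thrown.
* Nonlinear fits run Levenberg-Marquardt on log-parameters (positivity by
  construction); the steady-state fit reports `saturated` when the response
  is flat in concentration (the $R_{max}/K_D$ split is unidentifiable) and
  `lower_bound_only` when $K_D$ lands far above the tested range.
* PDB round-trips preserve coordinates to the format's 1e-3 Å; superposition
  rejects collinear selections.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run entirely on generated data:
50 simulation replicates per kinetic scenario at 2% noise (a realistic
instrument noise floor), one 500-region planted peak set, 100 null peak
sets of 500 regions for the type-I rate, and the 3-model geometry fixture.
These sizes give stable medians and rates while keeping a full run in the
one-to-two-minute range; they are the package's chosen study conditions,
and all of them are function arguments.

## Known limitations

* The DAP layer starts from per-region counts; peak calling, alignment and
  motif discovery are out of scope (PWMs come from aligned sites or
  MEME-format files).
* The kinetic model is strict 1:1: no mass-transport limitation, drift,
  nonspecific binding, or heterogeneous-ligand models.
* The 16-mer duplex sequence attached to the scenario registry is a
  synthetic stand-in carrying the core in the stated orientation, not a
  promoter sequence.
* The structural layer analyses ensembles; it does not produce refined
  ones (no homology modelling, simulated annealing, or force fields).
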