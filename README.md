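# wrkymeth

Quantifying how single-cytosine DNA methylation represses WRKY
transcription-factor binding to W-box elements.

Plant WRKY transcription factors recognize the W-box core `TTGAC(C/T)`.
`wrkymeth` is for researchers in regulatory (epi)genomics who want to
measure, simulate or sanity-check the repressive effect of 5-methylcytosine
(5mC) on that interaction at three scales:

1. **Genome scale** — DAP-seq (native, methylated DNA) versus ampDAP-seq
   (amplified, methylation-free DNA). Per bound region the package computes
   the normalized signal ratio
   `log10( ((dap + 1)/D) / ((ampdap + 1)/A) )`, finds the best PWM-scoring
   binding site on either strand, and correlates the ratio with the
   methylation probability at every motif position (Pearson, two-sided,
   Benjamini-Hochberg adjusted), masking positions with fewer than ten
   cytosines or FDR above 5%.
2. **Molecule scale** — 1:1 Langmuir binding kinetics for Bio-Layer
   Interferometry: association
   `R(t) = R_eq (1 - exp(-(k_on C + k_off) t))` with
   `R_eq = R_max C / (C + K_D)`, dissociation `R0 exp(-k_off t)`, and both
   steady-state and global kinetic estimation of `K_D = k_off / k_on`. A
   scenario registry encodes the measured affinities of AtWRKY40 for a
   W-box duplex: 630 nM unmethylated, unchanged for 5mC at reverse-strand
   positions 1/2, 12 uM for 5mC at forward-strand position 4, 9.2 uM for
   the triple (no additive effect).
3. **Atom scale** — van der Waals contact and steric-clash analysis
   (Bondi radii; contact within +0.5 A of the radii sum, clash beyond
   0.4 A overlap) between the W-box C4 base and the conserved WRKY-domain
   tyrosine, with in-silico C5 methylation and multi-model PDB ensembles.

A synthetic-data module generates peak sets with planted per-position
methylation effects, noisy sensorgrams from the scenario registry, and an
idealized base-pair/tyrosine geometry fixture — so every analysis runs and
is tested without downloads.

Motif coordinates follow the displayed orientation `G1 G2 T3 C4 A5 A6`
(reverse complement of `TTGACC`): position 4 is the forward-strand cytosine
(CHH context); positions 1 and 2 carry reverse-strand cytosines.

## Worked example

Generate a synthetic peak set with planted repression at the three W-box
cytosines and run the full analysis:

```r
library(wrkymeth)

ps  <- generate_methylome_peakset(200, wbox_pwm(), wbox_effects(), seed = 11)
rep <- run_methylation_sensitivity(ps$regions, ps$genome, ps$counts,
                                   ps$track, wbox_pwm())
rep$effects[, c("position", "strand", "n_cytosines", "r", "q", "status")]
#>    position strand n_cytosines        r        q         status
#> 4         4      +         196 -0.56291 6.23e-17         tested
#> 7         1      -         165 -0.17518 4.27e-02         tested
#> 8         2      -         196 -0.45679 5.96e-11         tested
#> ...       (remaining positions: insufficient_n, fewer than 10 cytosines)
```

The planted effects (0.6 at position 4, 0.45 at position 2, 0.2 at
position 1, all repressive) come back as negative correlations with the
right ordering: strongest at the forward-strand C4, weakest at the
reverse-strand C1. The `status` column applies the display rules: only
positions with at least ten cytosines and FDR below 5% count as tested
findings.

Simulate a five-concentration BLI experiment from the unmethylated scenario
(2% noise) and recover its affinity both ways:

```r
set <- generate_sensorgram_set("unmethylated", noise_sd = 0.024, seed = 5)
req <- vapply(set, extract_req, numeric(1))
C   <- vapply(set, function(x) x$concentration_nM[1], numeric(1))
fit_steady_state(C, req)
#> steady-state 1:1 fit: K_D = 638.1 nM, R_max = 1.211 nm [ok]
fit_kinetic_global(set)
#> kinetic 1:1 fit: k_on = 2.008e+05 /M/s, k_off = 0.1263 /s, K_D = 629.2 nM
```

Both estimates sit within about 1% of the scenario's 630 nM ground truth.

Finally, the structural restatement of the mechanism on the shipped
fixture:

```r
fx   <- build_geometry_fixture(methylated = FALSE)
m    <- fx$models[[1]]
base <- select_atoms(m, chain = "A", resno = 4)   # the W-box C4 base
tyr  <- select_atoms(m, chain = "B")              # tyrosine ring + OH
vdw_contacts(m, base, tyr)
#>     atom_a       atom_b distance radii_sum gap classification
#> 5 A:DC4:C5 B:TYR154:CE1      3.6       3.4 0.2        contact

fxm <- build_geometry_fixture(methylated = TRUE)
detect_clashes(fxm$models[[1]],
               select_atoms(fxm$models[[1]], chain = "A", resno = 4),
               select_atoms(fxm$models[[1]], chain = "B"))
#>       atom_a       atom_b distance radii_sum   gap classification overlap
#> 9  A:DC4:C5M B:TYR154:CE1     2.10       3.7 -1.60          clash   1.60
#> 18 A:DC4:C5M  B:TYR154:CZ     3.04       3.7 -0.66          clash   0.66
#> 54 A:DC4:C5M B:TYR154:CD1     3.04       3.7 -0.66          clash   0.66
```

Unmethylated, the cytosine C5 touches the tyrosine ring at exactly van der
Waals distance; adding the 5-methyl carbon turns that contact into clashes
in every model of the ensemble.

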