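# iesplice

Detecting **immediate early splicing (IES)** — transient intron
retention that peaks ~30 minutes after cell stimulation and reverts by
150 minutes — from splice-junction read counts, and predicting what
each retained intron does to the encoded protein.

The package is aimed at transcriptomics analysts working with
short-time-course RNA-seq (typically chromatin-associated RNA at
0/30/150 min with biological duplicates) who have per-intron junction
counts and want a tested, reproducible path from counts to classified
events — without re-running an alignment-based splicing caller.

## What it computes

**Retention level.** For an intron with junction counts
`I_up` (exon–intron, 5' boundary), `I_down` (intron–exon, 3' boundary)
and `S` (spliced exon–exon):

```
PSI = ((I_up + I_down)/2) / ((I_up + I_down)/2 + S),   %IR = 100·PSI
```

the halving correcting the two-junction advantage of the retained form.

**Differential retention.** Replicates are pooled per condition into a
2×2 table of inclusion vs spliced reads and tested with a
likelihood-ratio test of equal binomial proportions (χ², 1 df);
q-values are Benjamini–Hochberg per comparison. An event is
significant when `|ΔPSI| > 0.15`, `q < 0.01` and it has ≥ 100 combined
junction reads.

**Trajectory.** `IES_UP`: significantly more retained at 30 min (in
0-vs-30 or 30-vs-150) with the 150-min residual at most half the
excursion (`reversion_max = 0.5`); `IES_DOWN` mirrored; significant
but non-reverting events are `NON_TRANSIENT`. Magnitudes
(max PSI change, signed earlier-minus-30) are binned at centres
−0.15…−0.65 in 0.05 steps; sample structure comes as a PCA over
significant events and a Δ-sorted heatmap matrix.

**Coding consequence.** Retaining an intron inside an ORF is
`CODING_INFRAME` (frame-preserving, no stop introduced; adds
length/3 residues), `LAST_INTRON_PTC` (novel stop in the ORF's last
intron — the NMD-escape case yielding an alternative C-terminus) or
`PTC`. Donor (−3..+6) and acceptor (−20..+3) splice-site windows are
extracted strand-aware and exported as FASTA; a trainable PWM scorer
is included.

**Synthetic data.** A seeded generator builds genome + GTF + junction
counts with planted transient trajectories, controlled intron
frame/stop classes and beta-binomial replicate noise, so the whole
pipeline is testable end to end against known truth.

## Worked example

```r
library(iesplice)
cfg <- pipeline_config(simulate = simulation_config(n_genes = 20, seed = 7))
bundle <- run_pipeline(cfg)
table(bundle$trajectory$class)
#>    IES_UP UNCHANGED
#>        19        81
```

Twenty simulated genes give 100 introns, 20 of them planted with a
transient trajectory (baseline PSI 0.1, +0.25 at 30 min, reverted at
150 min); 19 are recovered, none falsely. The calls:

```r
head(subset(bundle$trajectory, class == "IES_UP"),4)[,
     c("event_id","psi_t0","psi_t30","psi_t150","delta_max")]
#>    event_id psi_t0 psi_t30 psi_t150 delta_max
#> 7  TX002.I2 0.1402   0.397   0.0890    -0.308
#> 11 TX003.I1 0.1219   0.376   0.0969    -0.279
#> 13 TX003.I3 0.0908   0.274   0.0542    -0.220
#> 15 TX003.I5 0.0874   0.330   0.1220    -0.243
```

`delta_max` is the maximal PSI change (negative = retention up at
30 min); the magnitude histogram over the 19 events counts
`0 4 4 8 2 1 0 0 0 0 0` across bins −0.15…−0.65. Each event carries a
protein-level consequence:

```r
merge(subset(bundle$trajectory, class == "IES_UP")["event_id"],
      bundle$consequence)[1:4, c("event_id","category","frame_preserving")]
#>   event_id        category frame_preserving
#> 1 TX002.I2             PTC             TRUE
#> 2 TX003.I1             PTC            FALSE
#> 3 TX003.I3             PTC             TRUE
#> 4 TX003.I5 LAST_INTRON_PTC            FALSE
```

Most retained introns introduce a premature termination codon (here
via an in-frame stop or a frameshift); `LAST_INTRON_PTC` marks the
stop landing in the ORF's last intron. The packaged gel-shift probe
table reproduces its expected properties:

```r
load_probe_table()[, c("name","length","ends_with_AG")]
#>    name length ends_with_AG
#> 1 RPL10     30         TRUE
#> 2 eIF5A     30         TRUE
#> 3 TRAF4     30         TRUE
```

With `out_dir` set, `run_pipeline()` writes differential, trajectory
and consequence TSVs, the histogram, PCA coordinates, heatmap matrix,
a BED6 of transient retained introns, per-class gene lists, splice-site
window FASTA and a manifest with a config hash. A thin command-line
wrapper with `simulate`/`run`/`quantify`/`detect`/`classify`/`probes`
subcommands ships as `inst/scripts/ies-pipe.R`.

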