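---
title: "Detecting immediate early splicing from junction counts: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting immediate early splicing from junction counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iesplice)
```

## The problem

Stimulation of T cells triggers, within minutes, a transient wave of
alternative splicing dominated by intron retention: a set of introns —
many in transcripts encoding components of the translation machinery —
is retained more strongly 30 minutes after stimulation and returns to
baseline by 150 minutes, the splicing analogue of immediate early gene
induction ("immediate early splicing", IES). `iesplice` implements the
computational side of that analysis as a reusable pipeline: PSI
quantification from junction counts, differential testing with
multiple-testing correction and effect/coverage filters, trajectory
classification across the three time points, protein-coding consequence
prediction for each retained intron, and splice-site window extraction.
Because raw sequencing data are not needed for any of this, a seeded
generator produces genome, annotation and junction counts with planted
trajectories, and every stage is validated against that ground truth.

## Quantifying intron retention

For one intron in one sample the input is three junction read counts:
$I_{up}$ (reads crossing the exon–intron boundary at the 5' splice
site), $I_{down}$ (intron–exon reads at the 3' splice site) and $S$
(spliced exon–exon reads). A retained transcript presents two
exon–intron junctions where the spliced form presents one, so the
inclusion evidence is halved before forming the fraction:

$$\mathrm{PSI} \;=\; \frac{(I_{up}+I_{down})/2}{(I_{up}+I_{down})/2 + S},
\qquad \%IR = 100\cdot \mathrm{PSI}.$$

PSI is undefined when all three counts are zero; such replicates are
dropped from condition means, and an event with no reads in an entire
condition is untestable for comparisons involving it.

## Differential testing and filters

Replicates are pooled per condition into a 2×2 table of
inclusion-supporting reads ($I_{up}+I_{down}$) versus spliced reads
($S$), and equality of the two binomial proportions is tested with a
likelihood-ratio (G) test on 1 df. Two points deserve emphasis:

* **The table uses raw counts, not the halved effective inclusion.**
  At the read level the inclusion fraction is
  $p = 2\psi/(1+\psi)$, a strictly monotone function of PSI, so "equal
  inclusion fraction" and "equal PSI" are the same null hypothesis.
  Halving the inclusion count before a chi-squared test would shrink
  its sampling variance by the factor $1/(2-p)$ relative to what the
  test assumes and make the test conservative (empirically, a type-I
  rate of ~0.01 at nominal 0.05 for low-PSI events). The halved
  quantity is the right *estimator* normalisation and is used only
  there.
* **Pooling replaces a hierarchical replicate model.** The original
  tooling for this kind of analysis fits a hierarchical model over
  replicates; with duplicate samples there is little information to
  estimate replicate dispersion, and the pooled test is calibrated by
  construction under the generator's read model at $\rho = 0$. Its
  behaviour under overdispersion is checked empirically through the
  end-to-end false-discovery criterion rather than assumed.

P-values are adjusted per comparison with Benjamini–Hochberg
(`stats::p.adjust`). An event is *significant* in a comparison when
$|\Delta \mathrm{PSI}| > 0.15$, $q < 0.01$, and it carries at least 100
combined junction reads across the tested samples — the three filters
as stated, with the read filter inclusive (`>= 100`) and the effect
filter exclusive (`> 0.15`).

## Trajectory classification

An event is `IES_UP` when a qualifying comparison supports increased
retention at 30 min (0-vs-30 significant with rising PSI, or 30-vs-150
significant with falling PSI after the peak) *and* the excursion
reverts: the reversion ratio
$|\psi_{150}-\psi_0| / |\psi_{30}-\psi_0|$ must not exceed
`reversion_max`. "Returns towards baseline" is not quantified in the
source analysis; the default `reversion_max = 0.5` (the residual at 150
min is at most half the excursion) tolerates counting noise while
excluding sustained switches, and is exposed as a parameter.
`IES_DOWN` mirrors the rule for transiently *better*-spliced introns;
a significant but non-reverting event is `NON_TRANSIENT`; everything
else is `UNCHANGED`, and events with an undefined PSI at any time point
are reported `UNCLASSIFIABLE` rather than silently dropped.

The magnitude of a transient event is the larger-in-absolute-value of
the 0-vs-30 and 150-vs-30 PSI changes, signed as earlier-minus-30 so
that retention-up events are negative, and binned into centres
$-0.15, -0.20, \ldots, -0.65$. Bins are half-open on the magnitude
scale — a value on the shared edge (e.g. $-0.175$) belongs to the bin
of larger magnitude ($-0.20$) — which is the only convention consistent
with the intended edge assignment.

For sample-level structure, events significant between 0 and 30 min
enter a PCA with samples as observations and events as variables,
centred per event and decomposed on the covariance (PSI values share a
scale, so per-event standardisation would only amplify noisy events);
reported percent variances sum to 100. The heatmap export sorts events
by descending 0-to-30-min PSI gain. Intron lengths of the `IES_UP` and
`IES_DOWN` classes are compared with a two-sided Mann–Whitney U test
with tie correction.

## Coding consequence of retaining an intron

For each intron the classifier asks, in order: is the gene
protein-coding (`NONCODING_GENE` otherwise); is the intron inside the
ORF, i.e. are both flanking exons CDS-overlapping (`NONCODING_REGION`
otherwise); and what does inserting the intron sequence at its position
in the spliced CDS do to translation. A frame-preserving intron
(length divisible by 3) that introduces no stop codon is
`CODING_INFRAME`, adding length/3 residues. A novel stop — harboured
directly or reached in the shifted frame, searching through to the
annotated transcript 3' end — yields `LAST_INTRON_PTC` when the intron
is the last intron of the ORF (the case expected to escape
nonsense-mediated decay and produce an alternative C-terminus) and
`PTC` otherwise. The 50-nt exon-junction rule for NMD is deliberately
not used: the last-intron criterion *is* the decision rule here.

Numerical corner cases are handled explicitly: codons containing `N`
translate to `X`; a CDS whose length is not a multiple of 3, or with an
internal stop, is flagged malformed and the intron unclassifiable; a
frameshifted read-through that reaches the transcript end without a
stop is reported `PTC` with a no-stop sentinel; and an intron inserted
*inside* the annotated termination codon destroys it, so the
"no stop introduced" branch additionally requires the terminal codon to
be intact. Genes with several isoforms are classified per transcript;
a canonical summary uses the transcript with the longest CDS (ties
broken by smallest transcript id).

Splice-site windows span positions −3..+6 across the donor (3 exonic +
6 intronic bases) and −20..+3 across the acceptor (20 intronic + 3
exonic), strand-corrected to read 5'→3' on the transcript. The windows
are exported as FASTA for external maximum-entropy scoring; the
built-in scorer is a position weight matrix (log2 odds against a
uniform background, pseudocount 0.5 by default) trained from
user-supplied site sets — a deliberate stand-in, since maximum-entropy
parameter sets are external artifacts, and window extraction rather
than scoring is the part this pipeline owns.

## The synthetic-data generator

`simulate_genome_annotation()` builds one protein-coding transcript per
gene on its own contig (random strand), with a valid ATG…stop ORF split
across exons at random codon phases, and constructs each intron to
realise a planted coding class: in-frame stop-free introns have a
pyrimidine-only body (no stop codon is composable from C/T alone, in
any frame) behind canonical GT…AG ends; in-frame stop-carrying introns
add a TAA aligned to the landing frame; frameshift introns have length
≢ 0 (mod 3). The 3' UTR opens with TAA codons at offsets 0, 4 and 8 —
a stop in every frame — so frameshifted read-through always terminates
before the transcript end. Insertion points that would fuse an exonic
`TA` with the intron's leading `G` into a spurious TAG are excluded.

`simulate_junction_counts()` draws, per event and sample, a total
junction depth $n \sim \mathrm{Poisson}(\texttt{depth})$ and inclusion
reads from a beta-binomial with mean $p = 2\psi/(1+\psi)$ — the
read-level inclusion fraction implied by the true PSI, inverting the
estimator's halving so `estimate_psi` is unbiased at $\rho = 0$ — and
intra-class correlation `rho` for between-replicate overdispersion; at
$\rho = 0$ the model reduces exactly to binomial sampling. Inclusion
reads split evenly between the two intron boundaries. Every draw
derives from one master seed through fixed per-gene and per-event
substreams, so enlarging a simulation never perturbs the data of
earlier units.

Default parameters describe the regime the pipeline targets:
biological duplicates at three time points, ~200 junction reads per
event per sample, a low retention baseline (PSI 0.1), transient
excursions of 0.25 PSI (within the 0.15–0.30 band typical of these
events) with full reversion, mild overdispersion ($\rho = 0.02$), 20%
of introns transient, and a frame-class mix (10% in-frame stop-free,
30% in-frame with stop, 60% frameshift) echoing the observation that
most retained introns disrupt the frame or carry a stop. What the
generator does *not* emulate: intron-body coverage (the quantifier is
junction-only by design), positional read biases, overlapping genes,
alternative event types beyond retention, and library-size variation
between samples. Passing the recovery tests therefore demonstrates
correctness of the statistics under the stated count model, not
robustness to alignment artifacts in real libraries.

## Problem sizes and verification

The test suite and the acceptance script size their simulations to run
on a single CPU in minutes while keeping estimates stable: the
classifier is checked against a brute-force translation oracle on
1,000 random transcript fixtures (~2,500 introns, all categories,
both strands); calibration uses 2,000 null events at depth 200 with
duplicate samples (20 seeds for the zero-call check); recovery uses 20
seeds × 300 introns with 20% planted transient events at ΔPSI 0.3.
Worked examples with fixed expected numbers (a 96-nt stop-free intron
adding 32 residues; a 39-nt in-frame segment distinguishing two
isoform ORFs by 13 residues) ship as small synthetic fixtures
(`inst/extdata/synthetic_mirrors.*`) constructed to mirror the
biological cases they are named after.

## Known limitations

* The pooled G-test ignores replicate overdispersion; with more than a
  few replicates, or strong biological variability, a beta-binomial
  regression would be preferable. The FDR filter plus effect-size
  threshold keeps the empirical false-discovery proportion low in the
  tested regime, but nominal q-values are not exact under
  overdispersion.
* Junction-only quantification cannot distinguish intron retention
  from an overlapping unannotated exon; with alignment data,
  intron-body coverage should corroborate calls.
* Consequence classification trusts the annotation's CDS; on
  transcripts with annotation inconsistencies (internal stops,
  non-triplet CDS) it reports the inconsistency instead of guessing.
* The reversion criterion compares condition means; it does not model
  within-condition variance at 150 min.

## A minimal run

```{r example, eval = FALSE}
cfg <- pipeline_config(
  simulate = simulation_config(n_genes = 20, seed = 7),
  out_dir = "ies_out")
bundle <- run_pipeline(cfg)
table(bundle$trajectory$class)
head(bundle$consequence)
```
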