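---
title: "mirtap: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirtap: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mirtap` implements a complete two-library (control vs treatment) plant
small-RNA sequencing analysis: read cleaning and tag collapsing, genome
mapping and annotation-category accounting, known-miRNA matching, novel
miRNA discovery by hairpin qualification, TPM normalization with the
Audic–Claverie exact test and a five-way regulation classification, plant
miRNA target-site scoring, and stem-loop qPCR concordance. This vignette
explains the models and the choices behind them; the README shows the
worked example.

## The experimental design being modelled

The pipeline targets the classic unreplicated deep-sequencing design: one
sRNA library per condition (here called *control* and *treatment*, e.g. a
hormone treatment against water), each tens of millions of reads in a real
study. Because each condition is a single library, differential expression
cannot use a dispersion-estimating model (DESeq2/edgeR-style shrinkage
needs replicates); the appropriate tool is an exact conditional test on tag
counts under Poisson sampling, which is what the Audic–Claverie statistic
provides.

## Read cleaning and tag collapsing

Reads are inserts of 15–30 nt ligated to a 3′ adapter
(`UGGAAUUCUCGGGUGCCAAGG` by default). Cleaning (`trim_and_filter()`)
locates the adapter by seed-and-extend: the first 8 adapter bases with at
most 1 mismatch seed the match, and the full adapter prefix over the read
suffix must show at most `max_adapter_mismatch` (default 2) mismatches.
The leftmost acceptable match wins, which guarantees the returned insert
never contains the full adapter. Reads are rejected, with an auditable
tally, when no adapter is found (an insert longer than the read implies an
artifact for size-selected sRNA libraries), the insert contains `N`, falls
outside the length window, or is ≥ 80 % adenosine (polyA artifacts).

The length window defaults to 15–30 nt; both bounds are exposed because
published descriptions of this protocol quote both 14 and 15 nt lower
bounds, and the choice is a filter parameter, not a result. All sequence
handling is in the DNA alphabet (U→T at ingest). Collapsing
(`collapse_tags()`) reduces each library to unique tags with per-library
counts; count sums are conserved exactly.

## Annotation cascade

Tags are mapped to the genome (`map_tags()`) under a substitution-only
model (no indels — appropriate for 15–30 nt tags) on both strands, with 0–2
mismatches. Exact matching uses Biostrings `PDict` grouped by tag width;
the mismatch path scans per tag. Each tag is then assigned exactly one
category (`classify_tags()`) by the precedence

> known miRNA > rRNA > tRNA > snRNA > snoRNA > repeat > exon > intron >
> un-annotated,

with exon/intron split into sense/antisense by strand agreement.
Multimapping tags are classified once from their best alignment (fewest
mismatches, then category precedence, then longest feature overlap, then
lexicographic feature id) and their counts are not split, so the category
accounting partitions each library exactly — the property that makes the
per-class summary table internally consistent. The precedence order is a
design choice: class-defining databases (rRNA/tRNA/sn(o)RNA) outrank
positional annotation (repeat/exon/intron), and the known-miRNA match
outranks everything because miRNAs are reported as their own class.
Coordinates are 1-based closed throughout (the GFF3/Bioconductor
convention); percentages are printed to two decimals with round-half-even.

## Known-miRNA matching and expression counting

A tag is assigned to a known mature miRNA (`match_known()`) if some
end-shifted ungapped alignment (±2 nt shift, length difference ≤ 2 nt)
shows at most 2 substitutions over the overlap; the fewest-mismatch
assignment wins. Per-miRNA expression is counted with an end-tolerant rule
(`count_mirna_expression()`): a tag contributes iff it matches the mature
exactly over the core (mature positions 4..L−3) and accumulates at most 3
mismatching or overhanging nucleotides across the two terminal 3-nt
windows combined. The combined-budget reading (rather than 3 per end) is
the stricter of the two possible readings of "no more than three
mismatches on the end of 5′ and 3′" and is the documented default; the
budget is a parameter.

## Novel miRNA discovery

Un-annotated, genome-mapped tags are clustered (gap ≤ 10 nt, per strand)
and each cluster seeds candidate precursor windows
(`extract_precursor_windows()`): the symmetric window ±`flank` nt plus the
two asymmetric windows with the cluster at either window end. The default
flank is 150 nt, giving ~320 nt windows for a typical tag — this covers
the large majority of plant precursor lengths while keeping the fold
problem small; it is a tuning parameter, and larger flanks are supported
up to the 750 nt fold cap. Clusters lying within 60 nt of tags already
assigned to known matures are excluded from seeding, mirroring the
screening of candidate reads against known precursors: without this, the
star arm of a well-expressed known miRNA is faithfully re-discovered as a
"novel" hairpin.

Each window is folded and the candidate is evaluated against six
qualifications (`evaluate_hairpin()`), all of which must hold:

1. un-annotated genomic origin (from the cascade);
2. a stem-loop with the mature wholly on one arm — no mature base pairs
   with another mature base, and ≥ 80 % of the mature's paired bases lie
   on one side (a stray terminal base captured by a distant helix does not
   disqualify an otherwise clean duplex);
3. a coherent mature/miRNA* duplex with 2-nt 3′ overhangs — the star is
   derived arithmetically from the dominant antiparallel pairing register
   of the fold with the canonical 2-nt offset, must fit inside the window
   without touching the mature, and must capture at least half of the
   duplex positions;
4. no large internal loops or bulges, quantified as ≤ 4 duplex positions
   not pairing into the star and no asymmetric bulge > 2 nt (the common
   quantification in plant miRNA annotation criteria);
5. fold free energy ≤ −18 kcal/mol;
6. mature read support ≥ 5 (both libraries, under the end-tolerant
   counting rule).

Deriving the star from the dominant register, rather than requiring the
two duplex-end bases to be literally paired, is deliberate: minimum-energy
folds of windows embedded in genomic context routinely leave one or two
terminal duplex bases unpaired or captured by flanking helices even for
textbook hairpins, and annotation tools therefore judge duplex geometry on
the inferred register. With this operationalization every constructed
hairpin planted by the generator qualifies, while dinucleotide-shuffled
windows qualify in well under 5 % of cases — both properties are enforced
by the test suite.

Clusters whose total read support is below the support threshold are not
folded at all (they cannot satisfy qualification 6); this prefilter
changes no verdict and keeps folding cost proportional to the number of
plausible candidates.

## The folding backend

The built-in reference backend is a Zuker-style minimum-energy dynamic
program (O(n³), in C++ via Rcpp) over a deliberately small energy model:
pair energies GC −3, AU −2, GU −1 kcal/mol; hairpin loops +3; bulges and
interior loops +2 plus +1 per unpaired base (each side capped at 10 nt);
multiloops +3; nested structures only; minimum hairpin loop of 3 nt. The
loop penalties live *inside* the recursion — a pure maximum-pairing model
rewards isolated pairs and register shifts for free, which destroys duplex
geometry in exactly the cases that matter here. The traceback is
deterministic (stack > hairpin > smallest interior loop > multiloop), so
identical inputs give identical dot-bracket strings. The energies are
nominal kcal/mol; the −18 kcal/mol gate is applied to the whole-window
fold. An optional `"rnafold"` backend delegates to ViennaRNA's `RNAfold`
behind the same `fold_result` contract for users who want a full
thermodynamic model; everything in this package's tests and acceptance
runs uses the built-in backend so results are reproducible with no
external software.

## Differential expression

Counts are normalized to transcripts per million,
`TPM = count / total clean reads × 10⁶`, per library. miRNAs below 2 TPM
in *both* libraries are removed (the boundary is inclusive: reaching
2 TPM in one library retains the miRNA). Exact zeros are substituted by
0.01 TPM *only* for the fold-change computation and display; p-values are
always computed from the raw counts. The log₂ fold change is
`log2(TPM_treatment / TPM_control)` after substitution.

The Audic–Claverie point probability of observing `y` counts in the
second library given `x` in the first is

$$p(y\mid x) = \left(\frac{N_2}{N_1}\right)^{y}
\frac{(x+y)!}{x!\,y!\left(1+\frac{N_2}{N_1}\right)^{(x+y+1)}}$$

evaluated in log space via log-gamma, so it is overflow-safe at library
scale. This distribution is exactly a negative binomial with size `x+1`
and success probability `N1/(N1+N2)` — the package uses that identity only
as an independent cross-check in its tests. A useful exact identity worth
recording: `p(y|x; N1, N2) = (N1/N2) · p(x|y; N2, N1)`; plain symmetry
holds only for equal library depths. The reported p-value is the doubled
two-sided tail `min(1, 2·min(P(Y≤y|x), P(Y≥y|x)))`; one-sided variants
are available, since the choice of sidedness in unreplicated sRNA studies
is rarely stated. The doubled tail is slightly conservative on discrete
counts; at a null rate of ~100 reads per library its measured size is
just under the nominal 0.05, within ±0.01.

Each retained miRNA is then classified:

* `significantly_up` / `significantly_down`: |log₂FC| ≥ 1 **and** p < 0.05;
* `slightly_up` / `slightly_down`: 0.25 ≤ |log₂FC| < 1 (no p-value
  requirement — the slight tier is defined purely by fold change);
* `unobvious`: otherwise.

Library-exclusive miRNAs (raw count zero on one side) are flagged
`control_only` / `treatment_only`. No multiple-testing correction is
applied by default, matching the unreplicated design the package models;
`diff_expression(adjust = TRUE)` adds a Benjamini–Hochberg column without
affecting the classification.

## Target prediction

Plant miRNA targets are near-perfectly complementary, so scoring is
ungapped (`score_duplex()`): per miRNA position 5′→3′, a mismatch costs
1.0, a G:U wobble 0.5, a Watson–Crick match 0, and penalties at positions
2–13 are doubled; sites scoring ≤ 4.0 are reported. These constants are
the widely used plant target-prediction convention; every one of them is
a parameter because different tools ship slight variants. `predict_targets()`
slides each miRNA over every transcript window (C++ scan with early
termination) and is tested against exhaustive window enumeration; a
gene-level summary collapses transcript hits through a transcript→gene
map.

## qPCR concordance

Stem-loop qPCR relative expression uses ΔCt against the U6 snRNA internal
control, with replicates averaged on the Ct scale before differencing
(`delta_ct()`), ΔΔCt = ΔCt_treatment − ΔCt_control, and direction
sign(−ΔΔCt) (fewer cycles = more template). Concordance with sequencing
(`concordance_rate()`) is the percentage of miRNAs whose qPCR direction
matches the sign of the RNA-seq log₂FC; zero directions are excluded from
the denominator.

## The synthetic-data generator

Because the modelled study type rarely deposits raw libraries, every stage
is exercised on generated data with known ground truth
(`simulate_srna_experiment()`). The generator emulates, at desk scale:

* a random-background genome (default 500 kb, single chromosome) with
  planted rRNA/tRNA/snRNA/snoRNA/repeat/exon/intron features whose counts
  scale with genome size;
* planted hairpin loci: known (matures entered into the mature database),
  novel (not in the database — the discovery targets), and decoys
  (dinucleotide-shuffled precursors that receive reads but are not
  hairpins). Constructed precursors are near-perfect stems with the
  canonical 2-nt 3′ overhang geometry and an unpairable A/C loop;
* two libraries of 2×10⁵ reads: locus reads (Poisson counts around the
  planted expectation; negative binomial optional) with a small isomiR
  (±1 nt 3′ shift) and star-read fraction, plus background reads drawn
  from a finite pool of species (feature subwindows and intergenic
  windows) with log-normal abundances — a finite species pool is what
  makes tag collapsing behave like a real library;
* insert lengths with modes at 21 and 24 nt (defaults 22 %/45 %, the
  hallmark plant sRNA profile), enforced on the species pool by
  alternating proportional fitting of the category and length margins;
* a 5′-U preference (default probability 0.7) applied to planted matures
  and intergenic species;
* regulation tiers: planted |log₂FC| in 1–2.5 (strong), 0.3–0.9 (slight),
  and 0 (null), one third of loci each, with base abundances of ~30–300
  expected reads;
* reads as insert + 3′ adapter, per-base substitution errors at 0.001,
  constant high quality (no quality model is simulated).

What the generator does *not* emulate: realistic position-dependent error
profiles, ligation bias, isomiR biology beyond the 1-nt end shift,
multi-locus miRNA families, or genome repeat structure beyond the planted
repeat features. Passing the recovery suite therefore demonstrates that
the pipeline's logic is correct under its stated assumptions, not that
every real library will behave as cleanly.

All randomness flows from the single config seed, and identical configs
produce byte-identical FASTQ output.

## Problem sizes and numerical choices

The shipped test and acceptance workloads use a 500 kb genome, 80 planted
loci and 2×10⁵ reads per library — large enough that recovery and
calibration statistics are stable (recovery over 30 novel loci, tier
accuracy over ~24 strong loci, test size over 10⁴ null replicates), small
enough to run on a laptop in a few minutes. Ties in classification are
impossible by construction (strict inequalities at the thresholds are
stated explicitly); ties in best-alignment selection and candidate
ranking are broken deterministically (documented lexicographic orders),
so every pipeline output is reproducible bit-for-bit given the config.

## Known limitations

* The reference energy model is intentionally minimal; its −18 kcal/mol
  gate is calibrated to the same scale as the full nearest-neighbour
  model only approximately. For borderline precursors a thermodynamic
  backend will disagree occasionally.
* With a single library per condition, the exact test measures sampling
  variability only; biological replicate variance is out of reach by
  design, and "significant" should be read accordingly.
* Target prediction is ungapped; single-nucleotide bulge targets are not
  found.
* The discovery step reports one candidate (the dominant tag) per
  cluster; overlapping miRNAs on opposite strands of the same locus are
  collapsed to the better-supported one.
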