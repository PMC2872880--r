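---
title: "Scoring exonic variants for splice-modulating potential"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring exonic variants for splice-modulating potential}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(savscan)
```

## The problem

Exonic single-nucleotide variants can disrupt splicing without touching
the canonical splice sites: by destroying exonic splicing enhancers
(ESEs), creating exonic splicing silencers (ESSs), or creating an
ectopic splice site inside the exon that outcompetes the natural one.
Such splice-affecting variants (SAVs) — including translationally silent
ones — are routinely overlooked when variants are triaged only by their
protein-level consequence. `savscan` scores variants for the sequence-
and exon-level features that discriminate experimentally verified SAVs
from common, splicing-neutral polymorphisms, and provides the comparison
machinery to test a candidate cohort against a neutral background.

## The feature battery

**ESR changes.** For a variant at exon offset $v$ and a motif set of
k-mers (hexamers for most published collections, octamers for PESX-style
sets), every k-mer window containing $v$ — at most $k$, fewer near a
junction — is classified in the wild-type (ancestral) and derived
alleles as ESE, ESS or neutral. Each window falls into one of nine
ordered change categories over those three states; `ESE->ESS` and
`ESS->ESE` are the two *direct conversions*, the strongest single
indicator of splice disruption. Overlapping windows are counted
independently: one substitution can destroy five overlapping ESEs and
simultaneously create two ESSs, and the per-variant *combined extent*
(ESE losses + ESS gains, with direct conversions contributing to both)
captures that cumulative load. PWM (ESEFinder-style) sites are handled
by threshold crossing: a site is lost when the wild-type window scores
at or above the matrix threshold and the derived window does not; for
each lost site the variant's 1-based position within the motif is
recorded, since positional loss profiles are informative even when raw
loss counts are not.

**Neutral expectation.** The expected proportion of each change category
under no splicing selection is computed by permuting every base of all
$4^k$ k-mers to the three alternatives and viewing each mutated k-mer
from all $k$ containing windows — $4096 \times 3 \times 6 = 73{,}728$
permutations for hexamers — weighting each permutation by the empirical
proportion of that base substitution among polarised neutral variants.
The window factor is applied as a weight of $k$ per (k-mer, position,
base) triple rather than literal re-enumeration; a test asserts the two
are identical. K-mer background frequencies are uniform (each k-mer
counted once), not genome-weighted; this matches the enumeration over
the k-mer space itself rather than its genomic abundance. Observed
category counts are compared per category with a 2x2 chi-squared test
with Yates correction against the expected split; observed proportions
are normalised per classified window (the per-variant alternative is a
documented option the package does not default to).

**Regulatory constraint (RC).** Conservation at a variant is measured
against what its codon positions would show genome-wide. A 192-entry
matrix (64 codons x 3 positions) assigns each cell
$(1 - \Pr_{COD,i}) \times 10$, where $\Pr_{COD,i}$ is the genome-wide
proportion of fully conserved alignment columns for that codon position;
cells with no observations are flagged and error on use rather than
defaulting. The RC score of a window of $N$ ungapped columns
(reference plus at least two other species) is
$\mathrm{RC} = \sum_i S_i\,\delta_{c_i} / N$, with $S_i = 1$ for columns
identical across all rows and $\delta_{c_i}$ the matrix weight of the
reference codon position at column $i$. Variants are scored on the 11-bp
window covering all variant-containing hexamers, truncated at splice
junctions; windows with gaps or fewer than three species are returned
as `UNSCORED` values with reasons, never as numeric sentinels. Columns
whose codon extends beyond the exon are dropped from the window (the
matrix key would otherwise be undefined); batch statistics drop variants
with overlapping windows, keeping the first in coordinate order.

**Ectopic splice sites.** Splice-site strength is scored on the fixed
windows of the field's convention: 9 bp for 5' (donor) sites (3 exonic +
6 intronic) and 23 bp for 3' (acceptor) sites (20 intronic + 3 exonic).
$\Delta SS$ is the maximum, over all window placements containing the
variant (sliding 1 bp, clipped to available sequence), of the derived
minus wild-type score, taken over both sides:
$\Delta SS = \max(\Delta 5'SS, \Delta 3'SS)$. Placements may put the
putative junction inside the exon — that is precisely what an ectopic
site is. A variant is *ectopic-like* at $\Delta SS \ge 1$ (the
threshold is a parameter). Separately, the *best ectopic site* is the
highest-scoring variant-allele window among those the variant improves,
and is compared with the natural site of the same side scored with the
same backend; a side with no scorable window is an explicit absent
value. The scoring backend is pluggable: a position log-odds matrix
trained from true junction windows (pseudocount 0.5 per base, log base
2, uniform or empirical background), serialisable to a parameter file so
externally derived weight tables (e.g. converted maximum-entropy
models) drop in. The maximum-entropy model itself is not re-derived
here: the contribution is $\Delta SS$ and its use, not the site model.

**Exon definition.** Per-exon features: natural 5'/3' site scores
(flagged `NONCANONICAL` for non-GT/AG junctions), exon ESE/ESS densities
(labelled windows / total windows; windows never cross the exon
boundary), summed PWM density, and intron-flank densities on intronic
positions 3-102 from each junction (the GT/AG dinucleotides excluded;
exons with a flanking intron under 102 bp are excluded — hence the
102-bp minimum). Variant position is binned into six equal exon
sections with half-open intervals,
$\mathrm{section} = \lfloor 6\,v/L \rfloor + 1$ clamped to 6; sections 1
and 6 are "peripheral". Junction occupancy profiles report, per k-mer
start position across 100 bp of flanking intron and 50 bp of exon at
each junction, the fraction of exons whose k-mer there is ESE or ESS,
over exons of at least 100 bp with introns of at least 200 bp. The
exon-length model is implemented literally as
$fr(n) = p_{SNP} \times obs(n)$ with $p_{SNP} = 0.001$ over lengths
20-1000; a length-weighted mode $p_{SNP} \times n \times obs(n)$ is
available because only that form makes the probability of containing a
variant grow with exon length — the two are both exposed rather than
silently reconciled.

**Cohort statistics.** Test-vs-control comparisons use a stratified
bootstrap: draws from the control pool without replacement, matching the
test set's stratum counts exactly each iteration (consequence class
and/or junction-distance bins: 4-10, 11-25, 26-50, >50 exonic bases).
The observed statistic is compared with the null distribution via
$Z = (x - \mu)/\sigma$ and a normal two-sided P when the null passes a
Shapiro-Wilk test (P > 0.05), otherwise the empirical P
$(1 + \#\{\text{null at least as extreme}\})/(1 + B)$, doubled for
two-sidedness and capped at 1. The Shapiro-Wilk test is applied to a
deterministic subsample capped at 5000 draws because the test
degenerates at very large n. Exon-level features deduplicate to unique
exons before sampling. Significance uses a stringent $\alpha = 0.01$
with strict inequality. The auxiliary tests (Yates-corrected chi-squared,
two-sample Kolmogorov-Smirnov) call the standard R implementations.

## Conventions and edge cases

* Coordinates are 1-based inclusive in all I/O (VCF convention) and
  0-based offsets internally; round-trip identity is tested on both
  strands.
* Junction distance counts the exon edge base as distance 1; the
  inclusion filter "3 bp or less from a junction" therefore rejects
  distances 1-3 and keeps 4. The convention is exposed as a parameter.
* Alleles are polarised only when two outgroup bases are present, agree,
  and match one human allele; rejections are values with reason codes
  (`MISSING_ALIGNMENT`, `OUTGROUP_DISAGREE`, `NO_ALLELE_MATCH`), not
  errors. Unpolarised use treats the reference allele as wild type.
* Nonsense (stop-gain) variants and variants in first/last exons are
  excluded, matching how curated SAV cohorts are assembled.
* Soft-masked sequence is uppercased before classification; windows
  containing `N` are *unscorable* (skipped and tallied), not neutral —
  neutrality is a biological claim, an `N` is a data gap.
* Motif windows truncated by the exon boundary are dropped, not padded
  with intronic sequence: ESRs are exonic by definition.
* Multi-isoform positions resolve to the largest containing exon, ties
  broken by lowest transcript identifier.

## The synthetic data generator

`simulate_fixtures()` writes a complete, deterministic toy study:
a two-chromosome genome with 10 genes per chromosome (4 exons each,
both strands), internal exons of 102-240 bp with consensus GT-AG
junctions and introns of 250-400 bp (long enough for the 100-bp flank
and 23-bp acceptor analyses); BED12 exon models; a labelled hexamer set
of 400 ESEs and 200 ESSs (matching the roughly 2:1 enhancer:silencer
composition and double-digit-percent hexamer coverage of the large
published collections), an unlabeled 50-hexamer set and an octamer set;
four PWMs with thresholds; 4-species MAF alignments whose per-column
conservation follows the codon-position hierarchy (positions 1-2 ~0.95
and 0.97, third positions 0.60, third positions of CpG-context codons
TCG/ACG/CCG/GCG 0.30 — so the constraint matrix reproduces the
highest-scores-at-CpG-synonymous-sites structure); and three variant
cohorts with recorded ground truth: 40 SAV-like variants placed in
peripheral exon sections with a derived allele chosen to cause at least
2 combined ESE-loss/ESS-gain changes and an 11-bp window held fully
conserved in the alignments (variants in constrained sequence), 400
change-neutral controls placed uniformly, and 20 ectopic variants that
each complete a planted one-mismatch donor consensus inside an exon.
Cohort sizes keep the real studies' shape — tens of test variants
against an order-of-magnitude larger control pool — at a size where the
whole suite runs in minutes on one CPU.

What the generator does *not* emulate: linkage between variants, indels,
genome-scale hexamer composition, alternative isoform structure,
phylogenetically realistic substitution processes, or the biology that
makes real ESR motifs cluster. Passing tests on fixtures therefore
demonstrate that the implementation computes the intended quantities and
recovers planted effects — not that the features generalise to real
genomes, which requires the published motif sets, a reference genome and
real alignments supplied by the user (all accepted as drop-in files in
the documented formats).

## Numerical and design choices

* The log-odds splice backend with a degenerate training set has a
  closed form (tested): zero-count bases get large negative weights, so
  a variant creating a consensus dinucleotide can swing a window score
  by several bits — saturation the user should expect with small
  training sets.
* The neutral-model window factor, combined-extent double-counting of
  direct conversions, and per-window normalisation are each asserted
  against literal enumeration.
* Bootstrap reproducibility is bit-exact for a given seed; the RNG state
  of the caller is saved and restored.
* The bootstrap calibration suite runs 500 null simulations of 1000
  iterations each — scaled down from the production default of $10^5$
  iterations, which the `n_iter` argument restores.
* Batch size defaults to 200 variants (the interactive web-tool
  convention this framework descends from) and is overridable
  programmatically.

## Known limitations

RNA secondary-structure context is deliberately out of scope (it was
evaluated and found uninformative in the source analyses), as are
branch-point scoring, indels and multi-nucleotide variants, and
mRNA/EST evidence lookup for ectopic-like controls (the selection
function accepts a precomputed exclusion list instead). The
chi-squared comparison against expected proportions treats the expected
split as fixed, which is appropriate for the 73,728-permutation
expectation but approximate for small observed cohorts.
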