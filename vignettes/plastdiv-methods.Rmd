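---
title: "Methods and design notes for plastdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for plastdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records the statistical models, the algorithmic choices, and
the deliberate design decisions behind plastdiv, in the spirit of the
methods sections that accompany mature analysis packages. It states no
numbers that the package's own test suite or `scripts/acceptance.R` do not
themselves compute.

## Scope and shape

plastdiv analyses panels of closely related chloroplast genomes: the
quadripartite architecture, nucleotide diversity and its hotspots, pairwise
selection screening, repeat landscapes, and hotspot-derived barcode
markers. Sequences and alignments are held in two lightweight S3
containers (`plastome`, `plast_aln`) because genomes are not naturally
tabular; everything a user reads out — site classes, window profiles,
junction reports, Ka/Ks rows, repeat loci, marker statistics — is a tibble
that chains with the pipe, and fitted/structured objects carry
`tidy()`/`glance()` methods and ggplot2 `plot_*()` helpers. This hybrid
(Biostrings-like containers in, tibbles out) was chosen over a fully
data-frame-first design after judging that alignments-as-data-frames would
force constant repacking without adding analysis value.

## Coordinates

All internal coordinates are 1-based closed intervals on the forward
strand, the native convention of R, GFF3, and the IRanges ecosystem.
GenBank locations (`join`, `complement`) are converted on read; BED export
converts to 0-based half-open. Circular arithmetic wraps positions modulo
the genome length, and an interval may carry `end > length` to denote a
feature or region spanning the origin. A single convention applied
everywhere was preferred over the 0-based internal/1-based external split
common in Python tooling, which has no idiomatic footing in R.

## Quadripartite detection

The inverted-repeat pair is found by seed-and-extend: exact k-mer matches
(default k = 31) between the doubled sequence and its reverse complement
anchor candidate anti-diagonals, which are extended outward. Extension
walks through exact matches and crosses a short mismatch run (at most 5
positions) only when the run is immediately followed by 25 consecutive
exact matches and the overall mismatch fraction stays within
`max_mismatch_frac` (default 0.001; N counts as a mismatch). The anchor
requirement is what makes boundaries sharp: on a genome whose IRs are
identical — the usual case, since plastid copy-correction homogenises the
IRs — a random flank cannot supply a 25-base anchor, so the detected
boundary is the exact end of the repeat (up to bases that genuinely extend
it by chance, which are then part of the repeat by definition). The
longest pair wins; ties break to the smallest start coordinate. The longer
single-copy gap is the LSC; the copy clockwise of the LSC is IRa.
`min_ir` defaults to 10 kb, comfortably below real plastome IRs (~25 kb)
and above any incidental repeat.

Canonical orientation rotates the genome so the LSC starts at base 1. Two
further binary choices are fixed deterministically: the whole-genome strand
is the one with the lexicographically smaller LSC string (making
canonicalization an involution — a genome and its reverse complement map to
the same canonical form), and the SSC strand matches a reference record
when one is given (higher identity to the reference SSC), otherwise the
lexicographically smaller orientation. Feature coordinates are remapped
through every transform; a feature part straddling the SSC boundary during
an SSC flip is left in place with a warning rather than silently broken.

## Diversity statistics

Nucleotide diversity is the average per-site difference over all unordered
sequence pairs. The default treatment of gaps and missing data is complete
deletion within the analysed slice: any column containing `-` or `N`
(IUPAC ambiguity codes other than `N` are folded to `N`) is excluded for
all pairs. This matches the defaults of the desktop diversity software
used in comparative plastome work and makes site-class counts reproducible;
a pairwise-deletion mode is available behind an argument. The
parsimony-informative percentage uses the full gapped alignment length as
its denominator, again following the convention of published polymorphism
tables. Haplotypes are collapsed on the non-excluded columns, so indel
variation does not split haplotypes unless gaps are explicitly requested
as a fifth state; Hd carries the n/(n−1) small-sample correction.

Sliding windows (default 1 kb, step 100 bp; window count
`floor((L − window)/step) + 1`) compute π on each column slice with
window-local exclusion, in one vectorised pass via cumulative per-column
difference sums. Hotspots are maximal runs of consecutive windows with
π above the threshold (default 0.006), merged into intervals and labelled
with overlapping loci when an annotation table is supplied.

A caveat the simulator makes visible: when a region's background diversity
sits close to the hotspot threshold (the SSC default of 0.005 versus the
0.006 cutoff), Poisson noise in 1 kb windows pushes a nontrivial fraction
of plain-background windows over the line, so the detected interval set
contains spurious members alongside the true hotspots.
`scripts/acceptance.R` reports this count; users screening real panels
should treat the threshold as a ranking device and inspect window maxima,
not as a significance test.

## Pairwise Ka/Ks

Both estimators are implemented in the package against the standard
genetic code (appropriate for plastid CDS; the code table is centralised
should another be needed).

NG86: synonymous sites per codon by the 1/3-fraction rule with mutations
to stop codons disregarded (so S + N = 3 × codons); differences between
codons averaged over all minimal mutational pathways that avoid stop
codons (all pathways, if every one hits a stop), weighting permissible
paths equally; Jukes–Cantor correction of the two proportions, with
proportions ≥ 3/4 reported as `saturated`.

YN00-style: κ is estimated from positions that are fourfold degenerate in
both codons and positions nondegenerate in both, each via the K80 closed
form, combined by site-count weighting (falling back to κ = 1 with a
warning when variation is insufficient); site counting weights each
candidate mutation by κ (transitions) and by the observed codon frequency
of the target codon (with a flat prior so unseen codons stay reachable;
uniform frequencies and κ = 1 reduce the counts to NG86's); pathway
difference counts are split into transitions and transversions so Ks and
Ka each receive a K80-style correction; site counts and distances are
iterated until Ka and Ks move by less than 1e-8 (at most 100 rounds —
convergence is immediate here because the weights depend only on κ and the
codon frequencies, but the loop guards future weight schemes).

Pairs with Ks = 0 report ω as undefined (`Ks_zero`), never infinity, and
per-gene means average only pairs with status `ok`, counting the excluded
pairs separately. This keeps gene-level means finite; it can shift means
slightly relative to software that imputes large ω for Ks = 0 pairs. Genes
with mean ω above 0.5 (configurable) are flagged as candidates for relaxed
constraint or positive selection — a screening device, not a test;
site-model likelihood methods are out of scope. Frameshifted coding
sequences enter the screen after `truncate_cds_at_stop()`, which cuts at
the first induced stop.

## Repeat definitions

SSRs are maximal perfect tandem repeats of a primitive (not itself
periodic) 2–6 bp unit repeated at least three times; mononucleotide runs
are excluded, motifs are canonicalised to their smallest rotation, partial
trailing units are trimmed, and a run explainable at several unit lengths
is reported once at the smallest. LSRs are exact repeats of an 11–100 bp
unit with inter-copy spacers of at most 50 bp. Detection is seed-and-extend
over integer-encoded 11-mers; direct hits on nearby diagonals become
two-copy (spacer = offset − length) or tandem-array loci, and same-unit
copies are merged by greedy left-to-right chaining while spacers stay
within bound. Inverted hits are extended along anti-diagonals; an inverted
pair is a `hairpin` unless its arm is its own reverse complement, which is
reported as `palindromic`. Copies falling inside SSR loci are removed, and
both finders are verified against exhaustive brute-force scanners in the
test suite. Because IRb mirrors IRa exactly, region-level repeat
statistics count a single IR copy by default (`ir_policy = "ira_only"`).

Cross-genome polymorphism is classified by projecting each genome's loci
onto whole-alignment columns through that genome's gap pattern and merging
overlapping projections into homologous loci; a genome lacking the locus
scores copy number 0, and a locus is polymorphic when at least two
distinct per-genome values occur.

## Markers, consensus, primers, in-silico PCR

A marker is the ungapped sub-alignment of a 1 kb window centred on a
hotspot midpoint (symmetric placement was chosen as the neutral default;
the window is clipped at alignment edges and both windowed and ungapped
lengths are kept). Marker statistics delegate to the diversity module, and
concatenating markers refines the haplotype partition — the combined
haplotype count is the number of blocks in the common refinement, so
discrimination can only improve.

The consensus emits the modal base when its frequency reaches the
threshold (default 0.95) and otherwise the minimal IUPAC code covering all
bases above 1 − threshold; gaps never enter. Primer scanning minimises
window degeneracy subject to degeneracy ≤ 16, a fully conserved and
unambiguous 3′-terminal trinucleotide, and GC content in [0.3, 0.7];
between equal-degeneracy windows the one nearest the target wins.

In-silico PCR needs explicit stringency semantics, since published
analyses lean on external tools whose rules are undocumented. The package
defines: stringent = at most 1 total mismatch and none in the 3 terminal
3′ bases; relaxed = at most 3 total mismatches and at most 1 in the 5
terminal 3′ bases; a primer IUPAC code compatible with the template base
is no mismatch; success requires a passing forward/reverse pair with a
product between 0.5× and 2× the expected amplicon range (shortest product
reported). Stringent success implies relaxed success by construction, and
the test suite fuzzes this implication. Discriminatory power uses exact
full-length matching against a local database rather than a remote
similarity search, removing dependence on external database versions.

## The synthetic clade generator

The simulator is the package's ground-truth instrument. Defaults emulate a
small congeneric panel: 16 taxa; LSC 83,000 bp, IR 24,950 bp, SSC
18,300 bp (a ~151 kb genome); per-region substitution rates on the
expected-π scale, r_IR = 0.0006 < r_LSC = 0.003 < r_SSC = 0.005, applied
along a random coalescent tree rescaled to mean pairwise distance 1 so a
region's expected π equals its rate; a compact synthetic gene complement
(including an *accD*-like and a *ycf1*-like CDS, a 357 bp *trnH–psbA*
spacer, and an *rps19*-like gene overhanging 7 bp into IRa); two coding
hotspots carrying planted haplotype structure (4 and 6 classes by default,
defined by nested substitutions at 8 sites per class over clades of the
tree, with background substitution suppressed inside the planted interval
so the class count is exact truth); planted SSR/LSR loci with per-taxon
copy numbers drawn from stated ranges (IR repeats monomorphic so the IR
stays length-constant), flanked by guard bases that stop chance
continuation of the unit periodicity; and one single-base deletion
creating a frameshift in an *rpoA*-like gene. Mutations are applied to a
single-copy scaffold and the IR is mirrored afterwards, so IRa and IRb are
exact reverse complements in every genome. The true alignment is emitted
from the known homology — no aligner runs — with repeat blocks padded to
their widest version and the IRb block mirrored from the IRa columns.

What the generator does not emulate: rate heterogeneity beyond the
region/hotspot structure, realistic codon usage, structural rearrangement,
recombination, and alignment error (the emitted alignment is exact truth).
Passing tests therefore demonstrate the correctness of the statistics and
detectors, not robustness to misalignment or assembly artefacts.

For the selection module, `codon_simulate()` evolves codon pairs under a
symmetric 61-state substitution process with chosen ω and κ (stop codons
unreachable), scaled so the distance argument is expected substitutions
per codon; each lineage evolves half the distance from a uniform random
(or supplied) ancestor. The transition matrix comes from an eigen
decomposition of the symmetric rate matrix and is cached per parameter
set.

## Problem sizes and numerical choices

The test suite exercises full-scale objects where the defaults demand it
(151 kb × 16 alignments; 100 seeded clade replicates for the
rate-ordering property; 50 replicates per ω for estimator recovery at
1000 codons; 200 random strings per repeat-finder oracle; 10,000 fuzzed
in-silico PCR cases), and scaled-down fixtures (30/11/7 kb quadripartite
genomes with boundary guard bases) where boundary exactness, not scale, is
the property under test. Ties anywhere — longest-IR candidates, primer
windows, repeat chains, haplotype numbering — break deterministically by
coordinate or first-appearance order, and every stochastic path flows from
a single caller-supplied seed.
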