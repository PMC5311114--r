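---
title: "Methods: GATA zinc-finger regulon analysis with gzftools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GATA zinc-finger regulon analysis with gzftools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gzftools)
```

# The biological setting

Fungi growing on a preferred nitrogen source repress the machinery for
using poorer sources — nitrogen catabolite repression (NCR). The program is
wired through GATA zinc-finger transcription factors, which recognise
5'-GATAA-3'-like promoter elements through a DNA-interaction domain with a
characteristic spaced-cysteine arrangement,
Cys-X~2~-Cys-X~n~-Cys-X~2~-Cys. The canonical nitrogen-regulatory factors
carry n = 17; related families carry n = 18 (WC-2-like light-responsive
factors) or n = 19–20 (Ash1-like). In the oleaginous yeast *Yarrowia
lipolytica*, deleting the repressor-type GATA factor derepresses genes with
GATAA promoter sites, while carbon-responsive genes carry the distinct
element 5'-GYGGGG-3'; nitrogen quality, through these regulators, steers
carbon toward storage lipids.

gzftools implements the complete desk-side analysis chain for such a
system: find and classify candidate GATA factors in a proteome, cluster
their domains into families, count motif occurrences around transcription
start sites (TSS), and relate promoter motif content to
mutant-versus-wild-type expression responses. A synthetic-data module
generates inputs with known ground truth so every step can be verified
sharply.

# Domain scanning

`scan_zinc_fingers()` reports every position of a protein where four
cysteines occur in the arrangement C, two residues, C, n residues, C, two
residues, C, for n in {17, 18, 19, 20}. A hit of spacing n spans n + 8
residues; the cysteines sit at offsets 0, 3, n + 4 and n + 7 of the domain
substring. Overlapping hits are all reported — including several spacings
sharing a start — because selecting one domain per protein is a separate,
explicit stage (`best_domain()`, maximum global-alignment score against a
consensus, ties to the smallest start). Spacing maps to family via
`classify_spacing()`: 17 → canonical, 18 → WC-2-like, 19/20 → Ash1-like.

`matches_strict_retention()` implements the conserved-residue filter used
to retain genuine GATA domains:
C-X~2~-C-X~4~-T-(P/S)-(L/V)-W-R-(R/K)-X~7~-C-N-X-C followed by at least 25
further residues. Its implied inter-cysteine spacing is 17, so every strict
match is also a generic canonical hit — a property the tests enforce on
random and constructed sequences.

Decisions worth noting:

* The trailing X~25~ block is read as "at least 25 residues follow the
  fourth cysteine", not exactly 25; the block denotes a retained alignment
  region, and an exact reading would reject full-length proteins.
* The ambiguity code `X` in input proteins matches "any residue" positions
  but never a required conserved residue — the conservative treatment.
* Within-species deduplication (`dedup_within_species()`) collapses hits
  with byte-identical *domain substrings*, not identical full-length
  proteins: the domain is the unit entering the tree, so domain identity is
  the relevant redundancy. Representatives are chosen deterministically
  (smallest protein id, then smallest start).
* The scanner is pattern-only by design; no homology search (BLAST, HMM) is
  attempted, so candidate lists on real proteomes are as inclusive as the
  pattern and no more.

# Family clustering

Domains are compared by pairwise global (Needleman–Wunsch) alignment with
affine gaps, scored match +1, mismatch −1, gap open −2, gap extend −1 by
default (`align_params()`); a gap run of length L costs
gap_open + L·gap_extend. No published scoring scheme exists for this step,
so the defaults are the simplest symmetric choice and are configurable.
Pairwise distance is the p-distance: the fraction of mismatched residues
among gap-free columns. A multiple alignment would add nothing here — the
tree is a clustering aid over a distance matrix, and pairwise distances are
sufficient input for neighbor joining.

`nj_tree()` is the package's own neighbor-joining implementation, kept
in-house for two contractual details standard libraries do not promise:
deterministic tie-breaking (Q-minimal pairs resolve to the
lexicographically smallest pair of labels, internal nodes carrying the
smallest leaf label beneath them) and clamping of negative branch lengths
to zero with the deficit moved to the sibling branch, preserving the joined
pair's total length. On additive matrices neither device activates and the
algorithm returns the generating tree exactly; the tests verify recovery
(topology and path distances to 1e−9) on hundreds of random trees and
cross-check topologies against an independent reference implementation.
`assign_families()` labels unlabelled leaves by the nearest anchor in
path-length distance, ties to the smallest anchor id.

Maximum-likelihood tree search and bootstrap support are out of scope: the
tree's role is family grouping, not phylogenetic inference.

# Promoter motif counting

Motifs are IUPAC strings (GATAA is literal; GYGGGG matches GCGGGG and
GTGGGG). For each gene, windows [−d, 0) and [0, d) for d = 200, 400, …,
2000 bp are laid out in a gene-oriented frame with the TSS at 0 and
upstream negative — for a minus-strand gene, upstream is genomic rightward.
Both genome strands are scanned (the forward window sequence for the motif
and its reverse complement). Per window, the combined both-strand
occurrence count is categorised 0, 1, or 2-meaning-two-or-more; per-strand
categories are available through `category_matrix()` for users who read
the per-strand convention instead. The combined count is the default
because it is the simpler reading of "number of motifs on each strand …
from 0 to 2" and the switch preserves the alternative.

Edge rules, chosen for unambiguity:

* An occurrence belongs to a window iff its 5'-most base *in the gene
  frame* lies inside the window; occurrences straddling a window edge are
  therefore assigned to exactly one side. Counting uses one broad scan of
  ±(2000 + motif length) bp so straddling occurrences are never missed.
* Windows truncated by a contig edge are flagged `clipped`; the expression
  binning drops clipped genes by default rather than comparing unequal
  window widths.
* Overlapping occurrences all count (GATAA cannot overlap itself in phase;
  degenerate motifs can, and no non-overlap rule is imposed).
* Distances are genomic distances from the annotated TSS (GFF3 transcript
  5' end, or the BED start field per strand); transcript-relative
  coordinates for intron-containing genes are not attempted.

# Expression statistics

Fold changes are computed per gene as
log2((mean FPKM~numerator~ + ε) / (mean FPKM~denominator~ + ε)) with
ε = 0.1 FPKM by default — enough to keep ratios finite at zero expression
while shifting a 10-FPKM signal by under 2%. Replicates are aggregated as
the arithmetic mean of FPKM before the ratio (the natural operation on a
linear abundance scale); mean-of-ratios is available via
`aggregate = "mean_ratio"`. Per-gene differential-expression testing is
deliberately not re-implemented; upstream q-values can ride along as
columns.

`bin_by_motif_count()` averages the fold change within each
(window, category) cell — the motif-response profile. A positive mean means
higher expression in the contrast numerator (the mutant, in the intended
use). `category_effect_slope()` summarises a window's profile as the
weighted least-squares slope of bin mean on category, which on synthetic
data recovers the planted per-site effect.

`gene_set_shift_test()` compares a gene set's fold changes against the
*complement* of the set within the background, not the background including
the set — the inclusive comparison would correlate the two samples and
invalidate the null. The test is the two-sided Mann–Whitney U: exact for
tie-free samples with both groups ≤ 20, otherwise the normal approximation
with tie correction. The distribution-shift comparison in the motivating
analyses is unnamed; the rank-sum test is the standard nonparametric choice
and the exact-mode threshold is configurable.

`enrich()` scores a gene list against flat gene sets (no GO-DAG
propagation) with the upper-tail hypergeometric probability P(X ≥ k) —
one-sided, since only over-representation is reported — and applies
Bonferroni correction across the sets tested. The universe for the intended
use is all quantified genes; the pipeline defines "quantified" as mean
FPKM > 0, configurable. `top_n_genes()` defaults to n = 500 with
deterministic id tie-breaking.

# The synthetic-data generators

The generators define the conditions under which the machinery is tested,
and their defaults are fixed accordingly:

* **Genome**: one contig, genes on both strands with TSS-to-TSS spacing of
  at least 4200 bp so neighbouring ±2000 bp promoter windows never overlap,
  and a background guaranteed free of the configured motifs on both strands
  by iterative rescan-and-redraw rather than post-hoc subtraction. This
  makes planted-count recovery an exact, all-cells test instead of a
  statistical one.
* **Planted sites**: per gene, a count drawn from {0, 1, 2, 3} (uniform by
  default — the cap at 2 must actually be exercised), placed at uniform
  upstream offsets on a uniformly chosen genome strand, with a rescan
  verifying that exactly the planted occurrences (of every configured
  motif) exist in the gene's promoter region; collisions trigger a redraw.
* **Expression**: baseline log2 FPKM ~ Normal(5, 2) per gene (a realistic
  dynamic range for yeast RNA-seq), mutant samples shifted by
  β·min(count, 2) — the effect applies to the capped count, mirroring the
  0/1/2+ statistic under test — plus Normal(0, σ) replicate noise. The
  study-shaped preset (`simulate_regulon()`) uses 2000 genes, β = 0.5,
  σ = 0.5 and 4 replicates per strain: a regulon-sized effect against
  realistic biological noise at transcriptome scale.
* **Proteome**: cysteine-free random backgrounds (so planted domains are
  provably the only hits), planted domains of each spacing, and near-miss
  decoys — spacings 16 and 21, a mutated conserved threonine, and a
  too-short C-terminal tail — which pin down both directions of the
  scanner's decision boundary.

Every generator is a pure function of (parameters, seed); a master seed
fans out to per-component child seeds via a Lehmer-style derivation kept
inside R's 32-bit integer range. What the simulation does *not* model:
nucleotide composition bias, introns, overlapping promoters, FPKM
length-normalisation artifacts, or count-based noise (noise is Gaussian on
the log scale). Passing tests therefore demonstrate correctness of the
machinery under clean planted truth, not robustness to every property of
real RNA-seq.

# Numerical choices and degenerate inputs

* Coordinates are 0-based, end-exclusive everywhere (BED convention);
  GFF3's 1-based coordinates are converted on read.
* p-distance on an alignment with no gap-free column is an error, not 0 or
  NA — the quantity is undefined and silence would poison the matrix.
* Distance matrices must be symmetric to 1e−8; Q-tie detection in NJ uses
  a 1e−12 tolerance; final three-taxon branch lengths come from the closed
  form with plain clamping at zero.
* Empty bins in the motif-response profile carry n = 0 and an NA mean
  rather than erroring; the slope uses only non-empty bins and requires at
  least two.
* Bonferroni-corrected p-values are capped at 1; k = 0 enrichment rows are
  retained with fold enrichment 0.
* Problem sizes in the checked examples (500 oracle proteins, 10,000
  strict-pattern sequences, 200 random trees, 2000-gene fixtures, 1000 null
  simulations) are the package's standard verification scale, chosen to
  make binomial noise on the measured rates small relative to the margins
  being asserted.

# Known limitations

* The scanner classifies by spacing only; it does not predict function, and
  pattern-only detection on real proteomes will include non-GATA
  spaced-cysteine proteins that the strict filter is designed to remove.
* NJ family grouping has no support values; borderline leaves near family
  boundaries are assigned by nearest anchor without uncertainty.
* The shift test's exact mode requires tie-free data; heavily tied
  fold-change vectors fall back to the normal approximation regardless of
  sample size.
* The pipeline consumes FPKM tables as given — no normalisation is applied
  or checked beyond non-negativity.
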