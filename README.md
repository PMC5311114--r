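# gzftools

Regulatory-genomics toolkit for fungal GATA zinc-finger transcription
factors and their regulons, modelled on nitrogen catabolite repression (NCR)
in the oleaginous yeast *Yarrowia lipolytica*. It is aimed at yeast
regulatory genomicists who want the complete chain from raw sequence to
regulon statistics as small, testable, scriptable pieces:

1. **Domain scanning** — detect GATA-type DNA-interaction domains in protein
   sequences by their spaced-cysteine arrangement
   Cys-X<sub>2</sub>-Cys-X<sub>n</sub>-Cys-X<sub>2</sub>-Cys, with
   n = 17 (canonical GATA), 18 (WC-2-like) or 19–20 (Ash1-like), plus a
   strict retention pattern
   (Cys-X<sub>2</sub>-Cys-X<sub>4</sub>-Thr-(Pro/Ser)-(Leu/Val)-Trp-Arg-(Arg/Lys)-X<sub>7</sub>-Cys-Asn-X-Cys-X<sub>25</sub>)
   for high-confidence hits, best-domain selection and within-species
   deduplication.
2. **Family clustering** — pairwise global alignment of domain sequences,
   p-distances, and a neighbor-joining tree (Newick output) with
   nearest-anchor family assignment.
3. **Promoter motif counting** — occurrences of IUPAC motifs (canonical
   GATA site 5'-GATAA-3', carbon response element 5'-GYGGGG-3') on both DNA
   strands in windows of 200–2000 bp up- and downstream of each gene's
   transcription start site (TSS), categorised 0 / 1 / 2-or-more.
4. **Expression response** — log2 fold changes from FPKM tables
   (lfc = log2((mean FPKM<sub>num</sub> + ε)/(mean FPKM<sub>den</sub> + ε))), binning of
   mutant-vs-wild-type fold changes by capped promoter motif count,
   rank-sum (Mann–Whitney U) tests for fold-change distribution shifts in
   gene sets, and hypergeometric enrichment of top-N gene lists with
   Bonferroni correction
   (fold enrichment = (k/n)/(K/N), P(X ≥ k), p·m capped at 1).
5. **Synthetic data** — generators for motif-free genomes with planted
   promoter sites, FPKM tables whose mutant shift is β·min(sites, 2) plus
   noise, and proteomes with planted domains and near-miss decoys, all with
   machine-readable ground truth, so every statistic above can be tested
   against known answers.

All genomic coordinates are 0-based, end-exclusive (BED convention);
promoter windows live in a gene-oriented frame with the TSS at 0 and
upstream negative.

## Worked example

Simulate a small study-shaped data set (genes with 0–3 planted GATAA sites,
a repressor-deletion expression effect of 0.5 lfc units per capped site,
replicate noise 0.5), then recover the effect:

```r
library(gzftools)

fx  <- simulate_regulon(seed = 42, n_genes = 120)
wcm <- count_matrix(fx$sim$genome, fx$sim$genes, "GATAA")
lfc <- log2_fold_change(fx$expr, list(strain = "mutant"), list(strain = "WT"))
bins <- bin_by_motif_count(lfc, wcm)
subset(bins, interval == "[-2000,0)")
#>     interval  from to category  mean_delta  n
#> 28 [-2000,0) -2000  0        0 -0.06378265 32
#> 29 [-2000,0) -2000  0        1  0.50640212 24
#> 30 [-2000,0) -2000  0        2  0.99729778 64
category_effect_slope(bins, "[-2000,0)")
#> [1] 0.5276394
```

Genes with no upstream GATAA site are flat (mean lfc ≈ -0.06), genes with
one site shift by ≈ 0.51, genes with two or more by ≈ 1.0: the weighted
slope 0.53 recovers the planted per-site effect of 0.5 within the noise of
120 genes.

Domain scanning works the same way on proteins:

```r
p <- protein_record("gzf_like", paste0("C", "AA", "C", strrep("A", 18),
                                       "C", "AA", "C"))
scan_zinc_fingers(p)
#>   protein_id start end spacing_n family_class strict_pass tail_ok
#> 1   gzf_like     0  26        18  wc2_like_18       FALSE   FALSE
#>                   domain_seq
#> 1 CAACAAAAAAAAAAAAAAAAAACAAC
```

`run_pipeline()` (or `inst/scripts/gzf-pipeline.R` from a shell) chains all
stages — domain scan, tree, promoter scan, fold change, binning, shift
tests, enrichment — from a JSON configuration and writes TSV/FASTA/
Newick/BED artifacts plus a run manifest.

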