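# homoeolog

Comparison of paired homoeologous genomic regions in allopolyploid plant
genomes, modelled on the analysis of white clover (*Trifolium repens*), an
allotetraploid carrying two co-resident sub-genomes: **O** (closest to the
diploid *T. occidentale*) and **P'**. Given two annotated regions — one per
sub-genome — the package answers the questions a comparative BAC-sequencing
study asks:

* which genes are homoeologous (same putative function, conserved order),
  and which are sub-genome specific;
* how similar homoeologues are, exon by exon, intron by intron, and at the
  protein level;
* how long ago the sub-genomes diverged, from synonymous substitution
  rates;
* whether the regions are microsyntenic with reference genomes, and how
  good the synteny is;
* which haplotype belongs to which sub-genome.

It is aimed at researchers analysing homoeologous or duplicated genomic
segments at the scale of individual clones or regions rather than whole
genomes.

## The models at the core

**Ks/Ka under GY94.** For each homoeologue pair the spliced CDSs are
protein-aligned and back-mapped to codons, and divergence is estimated
under the Goldman–Yang codon model over the 61 sense codons. The
instantaneous rate of change between codons *i* and *j* differing at one
position is

    q_ij = pi_j                synonymous transversion
    q_ij = kappa * pi_j        synonymous transition
    q_ij = omega * pi_j        non-synonymous transversion
    q_ij = omega * kappa * pi_j  non-synonymous transition

with codon frequencies `pi` from F3x4 and `Q` scaled to one expected
substitution per codon per unit branch length *t*. `(t, kappa, omega)` are
estimated by maximum likelihood (`L = prod_c pi[a_c] P(t)[a_c, b_c]`), and

    Ks = t * rho_S / (3 * rho1_S),   Ka = t * (1 - rho_S) / (3 * (1 - rho1_S))

where `rho_S` is the synonymous share of substitution flow at the MLE and
`rho1_S` the same share at `omega = 1` (so `3 * rho1_S` is the number of
synonymous sites per codon). Nei–Gojobori (NG86) pathway counting with the
Jukes–Cantor correction is provided as an independent cross-check.

**Molecular clock.** With a per-lineage synonymous rate *r* (default
6.1e-9 substitutions per synonymous site per year, the legume estimate),
divergence time is `T = Ks / (2r)`; the median Ks across pairs is the
headline estimator.

**Microsynteny.** A region is syntenic with a reference segment when at
least 3 genes match at E <= 0.01; synteny quality defaults to the
symmetric `100 * 2S / (Nq + Nt)`.

## Worked example

Simulate a six-gene homoeologous pair whose generating median Ks is 0.05,
with one gene deleted from the P' sub-genome, then run the comparison:

```r
library(homoeolog)

p <- sim_params(n_genes = 6, target_ks = 0.05, target_gene_incidence = 4000,
                deletion_spec = list(genes = "g04", repeat_len = 32), seed = 42)
sim <- simulate_homoeolog_pair(p)
res <- run_compare(list(region_o = sim$region_o, region_p = sim$region_p))

res$pairs[, c("gene_o", "gene_p", "exon_identity", "intron_identity",
              "protein_identity", "Ks", "Ka")]
#>   gene_o gene_p exon_identity intron_identity protein_identity     Ks       Ka
#> 1  g01_O  g01_P          98.9              NA            100.0 0.0359 3.59e-06
#> 2  g02_O  g02_P          98.8              NA             96.2 0.0254 7.86e-03
#> 3  g03_O  g03_P          97.9            81.9             94.2 0.0608 8.14e-03
#> 4  g05_O  g05_P          97.8            82.1             95.1 0.0565 9.20e-03
#> 5  g06_O  g06_P         100.0              NA             97.9 0.0000 0.00e+00

res$clock$summary
#> clock estimate: Ks = 0.03591, r = 6.1e-09 /site/yr -> T = 2.9 Mya

res$comparison$unique_o
#> [1] "g04_O"
```

Each row is one homoeologue pair: per-element nucleotide identities (`NA`
intron identity marks single-exon genes), protein identity, and the GY94
`Ks`/`Ka`. The clock summary converts the median Ks into a divergence
time; the deleted gene `g04` surfaces as unique to the O sub-genome. On a
five-pair example the median estimate is noisy (here 2.9 Mya against a
generating expectation near 4 Mya); across a 100-gene run the recovered
median Ks lands within a few percent of the generating value.

The published per-clone and per-gene reference tables of the white clover
BAC study ship with the package:

```r
median_ks(na.omit(trifolium_homoeolog_stats()$Ks))
#> [1] 0.05085
divergence_time(0.05085)$T_mya_1dp
#> [1] 4.2
```

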