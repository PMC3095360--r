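---
title: "Methods: comparing homoeologous regions of an allopolyploid genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing homoeologous regions of an allopolyploid genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homoeolog)
```

# The problem

Allopolyploid genomes carry two (or more) diverged diploid complements in
one nucleus. In white clover (*Trifolium repens*) these are called the O
sub-genome (closest to the diploid *T. occidentale*) and the P' sub-genome.
When corresponding ("homoeologous") regions of the two sub-genomes are
sequenced — classically as BAC clones of tens of kilobases — the questions
are: which genes are retained in both copies, how similar the copies are at
every structural level, when the sub-genomes diverged, and how the regions
relate to sequenced reference genomes. This package implements that
comparison pipeline end to end, together with a simulator that generates
paired regions with known ground truth so that every stage can be validated
at desk scale.

All coordinates in the package are 1-based and closed (the GFF3
convention); conversions happen only inside alignment kernels. `N` bases
are legal in sequences but are scored as universal mismatches and never
count as identities, so assembly gaps cannot inflate conservation
statistics.

# Pairwise alignment and identity

Global (Needleman–Wunsch/Gotoh) and local (Smith–Waterman) alignments use
affine gap costs in the EMBOSS convention — a gap of length $L$ costs
$\mathrm{open} + (L-1)\,\mathrm{extend}$ — with the EMBOSS defaults used
for identity work: open 10, extend 0.5, DNA match $+5$ / mismatch $-4$,
BLOSUM62 for proteins. The dynamic programming itself is delegated to
`Biostrings::pairwiseAlignment` (its gap parameterisation is mapped onto
the EMBOSS one exactly); the optimal score is checked in the test suite
against an exhaustive enumeration over the full alignment space for
sequences up to length 7, for both modes. Traceback determinism is the
engine's; scores and identity values are tie-break independent, and the
symmetry of identity under sequence exchange is asserted by test.

Percent identity is identical columns over all alignment columns (gap
columns count in the denominator); protein similarity additionally counts
columns with a positive BLOSUM62 score, matching EMBOSS "similarity"
semantics. For DNA, similarity equals identity.

Conservation profiles in the VISTA style are computed from a global
alignment as percent identity in sliding windows along the first sequence
(defaults 100 bp window, 25 bp step; both configurable). Columns that are
gaps in the first sequence inherit the coordinate of the last non-gap
position; windows with no aligned columns are omitted rather than reported
as zero.

# Homoeologue pairing and per-element comparison

Candidate homoeologues are genes whose putative-function strings match
after lower-casing and whitespace collapsing; function strings are never
parsed beyond that. Because function labels can repeat, candidates are
weighted by protein identity and the final pairing is the longest chain of
candidates that preserves genomic order in both regions, with ties broken
by total protein identity (a quadratic chain dynamic programme, verified
against exhaustive search over all order-preserving matchings in tests).
Genes left unpaired inside the compared intervals are reported as unique
to their sub-genome — the signature of segmental deletions or insertions.

Within a pair, exons are compared element-wise from the 5' end of the
transcript (minus-strand genes are reverse-complemented first), introns
likewise; surplus elements of the gene with more exons are reported
unmatched and excluded from means rather than scored zero, and single-exon
genes have *missing* (not zero) intron identity. The spliced CDSs are
translated and globally aligned for protein identity and similarity.

Region summaries report length, gene count, gene incidence
(length / gene count) and "gene space" — the fraction of the region covered
by gene spans from first to last exon, introns included, with overlapping
spans merged before counting. Span semantics (rather than exon-only
coverage) is what reproduces published gene-space percentages of ~30–45%
given mean exon and intron lengths near 350 bp; exon-only coverage would
be far lower.

The overlap between two clones can be supplied manually, taken from the
span of the order-preserving pairing (`detect_overlap(method = "genes")`,
the default — linear cost and usable at any scale), or taken from the best
local alignment band (`method = "align"`), which is quadratic and
practical only for clone-sized inputs.

# Ks and Ka

## Codon alignments

CDS pairs are trimmed of trailing partial codons and terminal stops,
translated, protein-aligned, and back-mapped to codons; only columns that
are gap-free sense codons on both sides are kept. One internal stop codon
per CDS is tolerated (dropped with a warning) — more is an error. At least
10 clean codon pairs are required; below that no estimate is attempted.

## The GY94 estimator

The substitution model is Goldman–Yang over the 61 sense codons of the
standard code: single-nucleotide changes at rate $\pi_j$, multiplied by
$\kappa$ for transitions and $\omega$ for non-synonymous changes;
multi-nucleotide changes are instantaneous-rate zero. The matrix is scaled
so one unit of branch length $t$ is one expected substitution per codon.
Codon frequencies are F3x4 from the positional nucleotide composition of
both sequences pooled, floored at $10^{-6}$ and renormalised.

The pairwise likelihood $L = \prod_c \pi_{a_c} P(t)_{a_c b_c}$ is
maximised over $(\log t, \log\kappa, \log\omega)$ with bounded L-BFGS-B
(the log parameterisation enforces positivity); $P(t) = e^{Qt}$ is
computed by symmetric eigendecomposition of the reversible generator.
Start values are $t = 3\times$ codon p-distance, $\kappa = 2$,
$\omega = 0.4$; convergence tolerance is $\sim 2\times10^{-9}$ in
log-likelihood. If the optimizer reports failure, three deterministic
multiplicative perturbations of the start are tried and the best optimum
kept — deterministic restarts are used instead of random draws so that an
estimation never perturbs the caller's RNG stream. Identical sequences
short-circuit to $t = K_s = K_a = 0$. Alignments with nucleotide
p-distance above 0.75 are refused as saturated.

From the MLE, $K_s = t\rho_S / (3\rho_{1S})$ and
$K_a = t(1-\rho_S) / (3(1-\rho_{1S}))$, where $\rho_S$ is the synonymous
share of the substitution flow through $Q$ at the MLE and $\rho_{1S}$ the
same share at $\omega = 1$; $3\rho_{1S}$ is therefore the number of
synonymous sites per codon and `S_sites + N_sites = 3 n_codons` holds by
construction.

## The NG86 cross-check

Nei–Gojobori counting is implemented independently of the likelihood
machinery: per-codon site fractions from the three possible changes at
each position, difference counts averaged over minimal mutational
pathways, and the Jukes–Cantor correction
$d = -\tfrac34\log(1 - \tfrac43 p)$. Mutations creating stop codons count
as non-synonymous opportunity, and pathways passing through stops are
excluded from the average (when every pathway is blocked, all are used
with stop-passing steps counted non-synonymous) — the usual convention
ambiguity, fixed here and stated. $p_S$ or $p_N$ at or above 0.75 is a
saturation error. On simulated data with generating $K_s \le 0.1$ and
$\kappa = 1$, NG86 and GY94 agree within 0.02.

# Molecular-clock dating

With a per-lineage synonymous substitution rate $r$ (default
$6.1\times10^{-9}$ per site per year, the legume calibration), divergence
time is $T = K_s/(2r)$: synonymous divergence accumulates on both
lineages, hence the divisor 2 — the convention under which a median
$K_s = 0.05085$ dates to 4.2 Mya. The median across pairs is the headline
estimator (robust to the occasional saturated or misestimated pair); the
mean and standard deviation are reported alongside.

# Microsynteny

Query CDSs are matched against a reference gene set by local alignment,
one best hit per query, ties broken by smaller target ordinal. A region
pair is called syntenic when at least `min_genes = 3` queries match at
E-value at most `max_evalue = 0.01`. Synteny quality defaults to the
symmetric $100 \cdot 2S/(N_q + N_t)$; `S/N_q` and Jaccard-style
$S/(N_q+N_t-S)$ variants are selectable and the formula used is always
recorded in the output, because published quality percentages are not all
reproducible under any single simple formula (per-segment gene totals are
usually unprinted); only forced rows (full sharing, quality 100) anchor
tests.

Significance is an acknowledged approximation. The identity-oriented
EMBOSS penalties (open 10, extend 0.5) are unusable for search statistics:
with near-free extension, the optimal local score between *unrelated*
kilobase sequences grows roughly linearly with length (cheap gap chaining
of the longest common subsequence), and no E-value theory applies. The
search therefore uses BLAST-like scoring (open 10, extend 6) with gapped
Karlin–Altschul parameters calibrated empirically for exactly this scoring
— a moment-matched Gumbel fit to maximal local scores of seeded random
1 kb pairs gives $\lambda = 0.069$, $K = 0.0015$
(`synteny_search_params()`). Identical CDSs then score $E \approx 0$ and
random kilobase pairs stay well above 0.01. The exact positive root of the
ungapped moment equation ($\lambda = 0.1915$ for $+5/-4$ at equal base
frequencies) remains available through `ka_lambda_solve()` and is the
default of `alignment_params()`.

Order conservation is summarised as the longest-common-subsequence
fraction of the two gene orders (equivalently the longest increasing
subsequence of target positions in query order), and strand disagreements
are flagged per gene.

# Sub-genome assignment

Two complementary rules. By identity: among candidate haplotypes of one
locus, the unique best global identity to a *T. occidentale*-like
progenitor reference is designated O, the rest P'; a tie makes all calls
ambiguous. By diagnostic variants: the candidate is aligned to the
reference, its allele read at each diagnostic position (positions under an
alignment gap are excluded from both counts), and the sub-genome called by
majority vote with a required margin of 2 — single-variant margins are
within sequencing-error range, and loci typically carry several validated
diagnostic variants. Candidates covering fewer than half of the variant
positions are rejected rather than called. Only an O-progenitor-like
reference is supported: the other candidate progenitor is too diverged to
be informative.

# The simulator: what it emulates, and what it does not

`simulate_ancestor()` builds an ancestral region whose geometry matches
the observed structure of homoeologous white clover regions: mean exon
length 348 bp (clipped at 20), mean intron length 314 bp (clipped at 50),
1–5 exons per gene, and one gene per 9148 bp of region. CDSs are in-frame
with start and stop codons and no internal stops. `diverge_pair()` then
evolves the region along two independent branches:

* **Genic sequence** by sampling substitution paths from the scaled GY94
  chain (exponential waiting times). Because the chain lives on the 61
  sense codons, stop-creating changes are structurally impossible and
  every simulated CDS stays translatable. The generating branch length is
  derived from a target $K_s$ by inverting the $K_s$ definition
  (`genic_t_for_ks()`); the default target is 0.05, the observed median
  between the white clover sub-genomes. Realised per-gene synonymous and
  non-synonymous event counts are recorded as ground truth.
* **Introns and intergenic sequence** by a $\kappa$-weighted nucleotide
  substitution process plus geometric indels. Defaults: 0.10 expected
  substitutions per site between the sub-genomes and 0.02 indel events per
  site of mean length 5 — chosen once to make intergenic sequence visibly
  more diverged than exons (intergenic identity in the high 70s–80s
  percent under the default profile), as observed between real
  sub-genomes. Indels never hit coding sequence, reflecting the
  overwhelming frame conservation of real homoeologues.
* **Segmental deletion** (optional): a specified run of genes is excised
  from the P' copy between intergenic midpoints, and a short sequence
  repeat (default 32 bp, copied from the flank) is planted at the
  junction, mimicking the breakpoint signature of illegitimate
  recombination.
* **TE insertions** (optional): labelled random-sequence insertions into
  intergenic space of a named sub-genome, post-divergence — matching the
  observation that overlapping-region TEs are sub-genome specific.

`make_reference_set()` evolves orthologue CDS sets at larger divergence
with configurable retention, emulating draft reference genomes with
missing gene models.

All sampling for one operation flows from a single seeded RNG stream in
fixed order, so identical parameters give byte-identical FASTA and GFF3
output; reordering draws is a breaking change. `simulate_ancestor()` seeds
from `seed`, `diverge_pair()` from `seed + 1`.

What the simulator does **not** emulate: realistic TE sequence models
(insertions are labelled random sequence), recombination, gene conversion
between homoeologues, population polymorphism, codon-usage or GC bias
(ancestral codons are drawn uniformly from the 61), and alternative
splicing. Passing tests therefore demonstrate correct recovery of the
modelled divergence processes, not performance on every property of real
BAC data — in particular, real gene prediction errors and assembly gaps
are outside the simulator's scope and enter the pipeline only as `N`
handling and annotation validation.

# Problem sizes and numerical choices

The validation suite uses problem sizes chosen to exercise each claim
meaningfully at desk scale: GY94 recovery uses 20 replicates of 2000
codons at $t = 0.3$, $\kappa = 2$, $\omega = 0.2$ (recovered median $K_s$
within a few percent of realised truth; $\omega$ within a few percent of
0.2); the law-of-large-numbers check on the path sampler uses 10,000
codons; alignment enumeration covers 200 random pairs up to length 7; the
end-to-end run simulates 100 genes at the default geometry (~0.9 Mb per
sub-genome) with a three-gene deletion and recovers the generating median
$K_s$ within 20% and every deleted gene as sub-genome unique.

Other fixed numerical choices: pseudo-frequency floor $10^{-6}$ on codon
frequencies; transition-probability floor $10^{-300}$ inside the
likelihood; identities printed at 2 decimal places and $K_s$/$K_a$ at 4
(the table precision of the field's reports); tie-breaks — best synteny
hit at equal score goes to the smaller target ordinal, equal-identity
assignment calls go to ambiguous rather than arbitrary.

# Known limitations

* Ks/Ka is pairwise-only: no site- or branch-model tests, no
  likelihood-ratio tests of $\omega$.
* E-values are calibrated approximations, not BLAST statistics; they are
  meant to make the fixed 0.01 threshold behave sensibly, not to match any
  external search tool's numbers.
* The GY94 optimizer handles the boundary $t \to 0$ by short-circuiting
  exact-identity alignments; alignments with a single difference can sit
  near the boundary and carry wide implicit uncertainty (no standard
  errors are reported).
* Whole-genome anchoring, chained alignment (LAGAN-style), gene
  prediction and TE detection are out of scope: the pipeline consumes
  annotations, it does not create them.
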