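---
title: "Screening for hominoid-specific variants and exon-trapping inverted repeat pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for hominoid-specific variants and exon-trapping inverted repeat pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tailless)
```

## The problem

Hominoids (humans, great apes and gibbons) lost the external tail after the
split from Old World monkeys. A candidate genetic mechanism combines two
observations: (i) lineage-specific sequence changes can be found by comparing
hominoid genomes against tailed outgroup monkeys across a multi-species
alignment; and (ii) a pair of intronic repeats in *opposite* orientations
flanking an exon — such as an AluY/AluSx1 pair around *TBXT* exon 6 — can
base-pair in the pre-mRNA, loop the exon out, and cause exon skipping. If the
skipped exon's coding length is divisible by 3 the product is an in-frame
isoform (the TBXT^Δexon6^ analogue) rather than a frameshifted one. Mouse
crosses carrying an engineered exon-6-skipping allele then connect genotype
to tail phenotype with incomplete penetrance.

`tailless` re-implements this computational arm as a reusable toolkit:

1. **alignment I/O** — MAF blocks, reference-coordinate slicing, ingroup
   consensus;
2. **lineage screen** — hominoid-specific SNV/insertion/deletion calling over
   gene regions ± flank;
3. **effect triage** — coding-consequence classes, SIFT/PolyPhen damaging
   filter, and the three manual-triage false-positive categories;
4. **stem-pair scan** — exon-flanking inverted repeat pairs with stem
   identity, inner distance, trapped exons and frame prediction;
5. **cross statistics** — penetrance with exact intervals, Punnett
   expectations, chi-square goodness-of-fit;
6. **synthetic data** — seeded generators with ground-truth manifests so
   every stage is testable without genome downloads.

## Coordinates

All internal coordinates are 0-based half-open (the BED convention); MAF `s`
lines already use start+size in that convention. Printed genome-browser
coordinates are 1-based fully closed and must be converted at the boundary:

```{r coords}
iv <- interval_from_1based("chr17", 8439335, 8439554)
interval_width(iv)   # the 220-bp insRCS2 source segment
```

## The calling rules

With the six hominoid assemblies as the ingroup and pig-tailed macaque
(`macNem1`) plus marmoset (`calJac3`) as outgroups:

* **SNV** — every ingroup species carries the same base, no outgroup is
  gapped, and the shared base differs in *any* outgroup (`any-differs`).
* **Insertion** — every ingroup species carries sequence where at least one
  outgroup is gapped (`any-absent`); maximal runs of such columns with the
  same per-outgroup gap pattern merge into one call.
* **Deletion** — the whole ingroup is gapped where *both* outgroups carry
  bases; runs merge into one call anchored as a width-0 interval between the
  flanking reference bases, with the outgroup segment recorded (the deleted
  sequence has no reference coordinates).

The "any" readings deliberately admit outgroup-specific false positives; the
caller marks every call whose two outgroups disagree with
`ambiguous_outgroup = TRUE`, and stricter `both-differ`/`both-absent` rules
are available in `variant_call_config()`. Columns with `N` in any decisive
species yield no call — no imputation. A column where one outgroup is gapped
and the other carries a differing base satisfies both the insertion and the
SNV rule; the gap pattern wins, because a gapped outgroup contributes no
allele to compare. The consensus operation (`hominoid_consensus()`) is
defined as unanimity over a *complete* ingroup (else `N`): every calling
rule requires all six species to share the allele, so a majority consensus
would not represent the screen's notion of "the hominoid state". A majority
mode exists behind a flag for exploratory use.

Gene regions are expanded by `flank_bp = 10000` on each side before calling,
and a variant falling into two expanded regions is counted once globally and
once per gene. Default thresholds downstream: SIFT < 0.05 (strict) or
PolyPhen > 0.446 (strict) for SNVs; protein-altering indels always pass the
damaging filter.

```{r screen}
part <- species_partition()
plant <- random_planting(5000, n_snv = 6, n_ins = 3, n_del = 3, seed = 11)
sim <- simulate_alignment(5000, plant, partition = part, seed = 11)
genes <- data.frame(gene_id = "G1", chrom = "chrSim", start = 0L, end = 5000L)
res <- screen_genes(list(sim$block), genes, part)
unlist(res$summary[c("n_snv", "n_insertion", "n_deletion")])
```

## Consequence classes and triage

`classify_consequence()` is a minimal, transcript-level classifier (not a
re-implementation of the full VEP ontology). The representative transcript is
"the longest with the most exons": exon count is the primary key, spliced
length second, transcript id third for determinism. The splice region is
fixed at the 2 intronic bases flanking each junction (the canonical
donor/acceptor dinucleotides) and takes precedence over coding classes. CDS
SNVs are translated codon-wise, strand-aware, with the standard genetic code
(interior codons — alternative initiators are not forced to Met). Indel frame
logic is the affected CDS length modulo 3; a deletion spanning several exons
sums its deleted CDS length before the modulus. Because the screen uses the
hominoid genome as the reference allele, consequence classes test the
*removal* of a hominoid-specific insertion and the *re-insertion* of the
outgroup segment at a deletion anchor.

The three triage categories encode the screen's manual-inspection outcomes,
checked in order with first match winning: `outgroup_specific`,
`minor_transcript`, `shared_aa_in_tailed_species`; anything surviving is a
`candidate`. With no evidence tables supplied the function returns
`candidate` with evidence `"untested"` — it never throws.

## Stem pairs, identity and ranking

`find_inverted_pairs()` considers every pair of annotated repeats fully
contained in distinct introns of a transcript with *opposite* strand
annotations (RepeatMasker-style orientation, not sequence inference). For a
pair hosted by introns *i* < *j* (transcript order), the trapped exons are
*i*+1 … *j* — the exons an RNA stem formed by the pair would loop out.
Measurements:

* **Inner distance** — end of the upstream repeat to start of the downstream
  repeat, 0-based half-open, so abutting repeats are 0 bp apart. This is the
  only convention that yields 0 for abutting repeats; applied to the exemplar
  geometry it reproduces the printed 1,448 bp (proximal) and 4,188 bp
  (distal) separations.
* **Stem identity** — `pair_identity()` aligns the upstream sequence against
  the reverse complement of the downstream one and reports
  (matches, shorter length). The denominator choice reproduces "out of 297"
  for both exemplar pairs. Two alignment modes exist: the default gapped
  global alignment (match +1, mismatch −1, gap −2, via
  `Biostrings::pairwiseAlignment`) and a gapless best-offset mode. The
  *scanner's* default is gapless: the gapped optimum between two unrelated
  repeats of unequal length routinely exceeds 0.6 matches/shorter-length
  (the aligner gaps its way into the best corridor), which would swamp the
  default `min_identity_fraction = 0.6` with decoys, whereas ungapped
  identity of unrelated sequence stays near 0.25. A stem built as an exact
  reverse complement with *k* substitutions has gapless identity
  `L − k` of `L` by construction (69 substitutions in 297 bp → 228/297).
* **Frame** — skipping is in frame iff the trapped exons' summed CDS length
  is divisible by 3 (117 bp → in frame, the Δexon6 analogue; 117 + 200 bp →
  frameshift, the Δexon6–7 analogue). Trapped exons with no CDS are in frame
  and flagged.
* **Score** — `identity_fraction × exp(−inner_distance / λ)`, λ = 2,000 bp
  by default. The exponential decay is a configurable heuristic for the
  kinetic argument that a proximal stem can form on the nascent transcript
  before the distal partner is transcribed; it is *not* a free-energy
  model (no RNA secondary-structure prediction is attempted). Ties break by
  smaller distance, then genomic position.

```{r scan}
loc <- simulate_locus(
  exon_sizes = rep(120L, 8),
  intron_sizes = c(800L, 600L, 500L, 2000L, 1500L, 700L, 900L),
  pairs = data.frame(intron_up = c(5L, 5L), intron_down = c(6L, 7L),
                     length = 297L, substitutions = c(0L, 69L),
                     offset_up = c(20L, 1100L), offset_down = c(10L, 350L)),
  seed = 7)
cand <- find_inverted_pairs(loc$tx, loc$repeats, loc$genome)
cand[, c("up_family", "down_family", "trapped_exons", "inner_distance",
         "identity_matches", "frame", "score")]
```

## Cross statistics

"Affected" means any tail phenotype (`no_tail + short_tail + kinked_tail`);
long-tailed animals are unaffected. Penetrance intervals are exact
Clopper–Pearson (several printed cells sit at 0% or 100%, where the normal
approximation fails). Mendelian expectations are zygotic — computed before
any viability selection — so the chi-square statistic of `ratio_test()`
measures exactly the post-selection deviation (e.g. the absence of
homozygotes, or compound heterozygotes below their expected 50%). Runt/death
annotations are carried in a supplementary column and never enter phenotype
totals, mirroring how the printed tables count them inside the no-tail cells.

```{r cross}
f2 <- read_phenotype_table(system.file("extdata", "f2_intercross_counts.tsv",
                                       package = "tailless"))
ag <- aggregate_phenotypes(f2, "dexon6/+")
penetrance(ag[["affected"]], ag[["total"]])[c("estimate", "lower", "upper")]
ratio_test(c("dexon6/dexon6" = 0, "dexon6/+" = 63, "+/+" = 35),
           c("dexon6/dexon6" = 0.25, "dexon6/+" = 0.5, "+/+" = 0.25))
```

## What the generators emulate — and what they do not

`simulate_alignment()` plants hominoid-specific features into an otherwise
monomorphic 8-species alignment: the ingroup stays identical except where a
variant is planted, and optional background divergence mutates each outgroup
branch independently. This preserves the screen's central assumption — the
planted features are the only ingroup-shared signals — so with zero
background the screen must recover the truth set exactly, and with
background > 0 the calls form a superset. The generator does **not** model
phylogenetic substitution processes (no HKY/GTR, no rate variation), indel
length distributions, alignment error, or the patchy species coverage of
real whole-genome alignment tracks. Passing the recovery tests therefore
demonstrates the correctness of the calling logic, not robustness to
alignment artefacts in real Multiz tracks.

`simulate_locus()` writes the downstream repeat as the reverse complement of
the upstream one with a requested number of substitutions at uniformly drawn
positions (transitions and transversions are not distinguished), which
forces the gapless identity by construction. `simulate_cross()` draws
genotypes from the Punnett proportions and phenotypes from per-genotype
penetrance; it does not model viability selection, litter structure, or
parental phenotype effects.

All generators consume a single integer seed and are byte-reproducible;
random draws go through R's RNG under `withr::with_seed`, so a generator
call never perturbs the caller's RNG state.

## Numerical and design choices

* Problem sizes in the shipped tests: the at-scale recovery test uses a
  100-kb alignment with 200 planted variants of each class; oracle
  equivalence uses 10,000 random columns, all pairwise sequence lengths up
  to 12 bp against an exhaustive dynamic-programming aligner, and an
  exhaustive position × alternate-base sweep of a 90-bp toy CDS; the
  penetrance-coverage property uses 100 replicates of 10,000 offspring.
* Optimal global alignments need not be unique; co-optimal alignments can
  differ in match count. The alignment tests therefore assert the
  implementation's match count lies within the DP oracle's co-optimal
  [min, max] band. The 297/297 and 228/297 constructions have unique optima
  (a gap pair costs −4 and can never beat a −1 mismatch on equal-length
  stems), so those are exact.
* Species with multiple rows in one MAF block are rejected as a format
  error rather than silently merged; blocks with ingroup species missing
  yield no-calls at every column by default (`require_complete_ingroup`).
* Indel runs interrupted by any non-qualifying column split into separate
  variants — no gap-tolerant merging — and runs whose per-outgroup gap
  pattern changes split at the change point.
* Degenerate inputs: zero-overlap slices return an empty (0-column) block;
  `penetrance(0, 0)` returns `NA` rather than erroring; a transcript with
  fewer than 3 exons cannot trap an exon and scans to an empty table;
  `ratio_test` refuses expected proportions of zero.

## Known limitations

* The screen operates per alignment block; an indel run truncated by a
  block boundary is reported as two variants. Whether the original
  full-scale screen merged across block boundaries is not documented, and
  the headline full-genome counts (85,064 SNVs / 13,820 insertions / 5,533
  deletions over 140 genes) require the UCSC Multiz30way download, so they
  are out of desk-scale scope here.
* SIFT and PolyPhen are consumed as input annotations; the package never
  computes them.
* The stem-pair score is a ranking heuristic, not a thermodynamic model;
  no minimum-free-energy structure prediction is performed.
* The interfaces are R functions; orchestration for shell pipelines is a
  thin layer users can write over `run_screen()`/`run_scan()`.
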