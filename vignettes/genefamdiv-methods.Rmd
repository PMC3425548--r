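---
title: "Methods: analysing expressed multigene-family diversity"
author: "genefamdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing expressed multigene-family diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Xenobiotic-metabolising enzyme families such as cytochrome P450 2B (CYP2B)
occur in rodent genomes as several near-identical paralogous loci whose
transcripts can differ by only a handful of nucleotides. When hepatic cDNA
from such a family is cloned and Sanger-sequenced, the resulting clone set
mixes three sources of variation: divergence between paralogous loci,
allelic variation within a locus, and substitution noise introduced during
reverse transcription and PCR. `genefamdiv` implements the analysis chain a
molecular ecologist applies to such a clone set from animals sampled across
population-by-diet treatment groups:

1. ORF validation and translation (incomplete or interrupted clones are
   excluded, mirroring standard cloning practice);
2. dereplication of amino-acid variants at an identity threshold, to
   estimate how many distinct expressed variants (putative loci) the set
   contains;
3. a distance tree over the clones, and an unweighted UniFrac permutation
   test of whether treatment groups express different parts of the tree;
4. Nei–Gojobori synonymous/nonsynonymous accounting: global dN/dS, a
   codon-by-codon z-test of neutrality, and a per-site selection scan from
   parsimony ancestral states;
5. fingerprinting of the 13 substrate-recognition-site (SRS) residues known
   to alter CYP2B substrate specificity, their concordance with tree
   clades, and a Fisher test of nonsynonymous enrichment at SRS codons;
6. relative gene copy number from qPCR quantification cycles against a
   single-copy reference.

A seeded simulator (`family_model()` / `simulate_family()`) generates clone
sets with known locus structure so that every stage can be validated
against ground truth.

## The analysis entry point

```r
library(genefamdiv)
fam <- simulate_family(family_model(seed = 3))
fit <- gene_family_analysis(fam$clones, n_perm = 1000, seed = 5)
print(fit)
summary(fit)        # scalar summaries, serialisable with summary_json()
plot(fit)           # tree, treatment colours, fingerprint letters
write_genefam(fit, "results/")
```

`gene_family_analysis()` is the single fitting-style entry point; the
returned `genefam` object carries every stage result and has `print`,
`summary` and `plot` methods. All randomness (UniFrac permutations,
bootstrap resamples) flows from the `seed` argument; re-running with the
same input and configuration reproduces a byte-identical
`summary_json()`.

## Models and conventions

**Coding sequences.** A valid ORF begins with ATG, has length divisible by
3, contains exactly one stop codon at its end, and no ambiguity codes
(ambiguous bases are rejected rather than resolved, since silently
resolving them would corrupt substitution counts). A 1476-nt ORF therefore
translates to 491 residues. Codon coordinates are 1-based and all
codon-level analyses exclude the terminal stop. Raw p-distances, by
contrast, are computed over every aligned site of the input (including the
stop codon), as when a raw alignment is handed to a distance program.

**Percent identity with gaps.** Dereplication programs in this field
compute a global alignment and normalise matches by alignment length
including gap columns. The published scoring of those tools is not
specified, so the package pins its own: match +1, mismatch 0, linear gap
−1, and among maximal-score alignments the one with the fewest gap
columns. Under this scheme the score `S` and gap count `g` jointly
determine matches (`S + g`) and alignment length (`(m + n + g)/2`), so gap
*placement* cannot change the identity value — the quantity is fully
reproducible without specifying a traceback order. Normalisation is by
alignment length, not by the shorter sequence (the alternative reading),
which makes the measure symmetric and monotone in gap cost.

**Dereplication** is greedy centroid clustering in input order: each
sequence joins the first group whose representative exceeds the threshold,
else founds a new group. The threshold comparison is strict (`> 0.95`
implements ">95% similarity"). Greedy grouping is order-dependent by
nature; `order = "length_id"` offers a deterministic order-independent
variant. Exact-unique counts (`count_unique()`) are order-invariant.

**Trees.** Neighbor joining on Poisson-corrected amino-acid distances
(`d = -ln(1 - p)`) stands in for a maximum-likelihood search: downstream
analyses need a tree with branch lengths, not a specific ML topology, and
per-site substitution counting is conventionally run on NJ trees. Negative
NJ branch estimates are clamped to zero with the deficit moved to the
sister branch, because UniFrac requires non-negative lengths. Rooting is
on the midpoint of the outgroup's branch when an outgroup is supplied
(e.g. the human orthologue), else at the midpoint of the longest path.

**Ancestral states** use two-pass Fitch parsimony with a deterministic
top-down resolution (keep the parent state when admissible, otherwise the
lexicographically smallest member of the node's state set). This is a
declared surrogate for joint ML reconstruction, not claimed equivalent;
change counts are tie-invariant and equal the brute-force minimum, which
the tests verify exhaustively on small trees.

**UniFrac.** Unweighted (presence/absence) UniFrac between two treatment
groups is computed on the tree pruned to the two groups' leaves: the
fraction of spanned branch length unique to one group. Internally the
package classifies edges of the full tree by restricted descendant sets
(excluding edges above the union's most recent common ancestor), which is
algebraically identical to pruning but allows one edge–tip incidence
matrix to serve all permutations. The omnibus statistic is the mean of the
pairwise distances over all testable treatment pairs — the original
omnibus statistic of the Fast UniFrac service is not documented, so this
choice is pinned and stated. "Bootstrapped permutations" is interpreted as
label permutation with group sizes preserved (the standard UniFrac
significance test), not resampling with replacement. p-values follow the
add-one rule `p = (1 + #{null ≥ obs})/(1 + n_perm)` and are therefore
never zero; pairwise tests are Bonferroni-corrected by the number of pairs
actually tested (groups with fewer than two leaves are skipped with a
warning).

**Selection.** Nei–Gojobori (1986) counting: potential synonymous sites
per codon are the per-position fractions of synonymous single-nucleotide
changes (changes to stop excluded; `n = 3 - s`), observed differences are
averaged with equal weight over the minimal mutational pathways of each
codon pair (pathways through stop codons excluded; in the rare case all
are blocked, they are re-admitted with stop steps counted as
nonsynonymous), and proportions receive the Jukes–Cantor correction
`d = -(3/4) ln(1 - 4p/3)` (MEGA's default; raw proportions by flag).
Saturated proportions (`p ≥ 3/4`) yield `NA`, and ratios with `dS = 0`
are reported as undefined rather than infinite. The global ratio is mean
pairwise dN over mean pairwise dS; whether the published global ratio was
pairwise- or tree-based is not stated, so both modes exist
(`global_dnds(..., method)`) and the pairwise mode is the default. The
codon z-test bootstraps codon columns to estimate the standard error of
`dS - dN` and tests the purifying alternative one-tailed. The per-site
scan tallies changes over tree edges from the Fitch assignment and applies
a two-tailed binomial test of the nonsynonymous count against the
column's potential-site expectation `n_c/(n_c + s_c)`; pathway-averaged
tallies are rounded to integers for the test. Sites are classed at
`p < 0.1`, the conventional per-site threshold for this analysis
(configurable).

**SRS fingerprints.** Residue positions are defined on the ungapped
translated ORF, 1-based; the default positions are
114, 206, 209, 290, 294, 297, 298, 302, 363, 367, 477, 478, 480.
Fingerprint–clade concordance demands strict monophyly: a fingerprint
group interrupted even by a single noise-derived singleton scores 0, so
realistic noisy data sit below 1 by construction. The enrichment test is
Fisher's exact by full hypergeometric summation (all tables with
probability ≤ the observed one, the standard conditional two-sided rule),
with the cross-product odds ratio and a Haldane 0.5 correction applied
only when a cell is zero (flagged).

**Copy number.** `ratio = E^(Cq_ref − Cq_target)` with the amplification
efficiency `E` fixed at 2 by default (ideal doubling, the implicit
assumption when no standard curves are reported) and configurable per
primer set. Replicate scatter propagates to the ratio by the delta
method; replicate SD above 0.5 cycles raises a warning. Group comparisons
use Welch's t-test — the fractional degrees of freedom reported alongside
published copy-number contrasts identify the Welch form even when
labelled a Student's test.

## The simulator and its calibration

`family_model()` defaults describe the study-scale scenario: 4 loci (the
four major clades observed in woodrat CYP2B cDNA), 491 codons, 4
population-by-diet treatments, 3 animals per treatment, 8 clones per
animal (96 clones, near the 87 of the motivating dataset), and
treatment-biased expression in which one locus is expressed by all
treatments and each remaining locus is dominated by a different treatment
— the qualitative structure seen in the observed clade/treatment pie
charts.

Rates were calibrated once, forward from published summaries rather than
from any test outcome: `locus_divergence = 0.035` proposed substitutions
per site gives between-locus amino-acid divergence near 8% (safely above
the 5% dereplication threshold) and an overall mean nucleotide p-distance
near 0.03, matching the reported 0.031; `allele_divergence = 5e-4` and
`error_rate = 3e-4` give roughly one substitution per clone, so a
minority of clones recur as exact duplicates, as in the observed 87 → 62
unique parsing. `omega_background = 0.5` sits at the reported global
dN/dS of ~0.5, and `omega_srs = 5` elevates amino-acid change at SRS
codons.

The mutation mechanism proposes uniform single-nucleotide changes and
accepts them so that the nonsynonymous:synonymous acceptance *ratio*
equals ω: for ω ≤ 1 synonymous proposals are always accepted and
nonsynonymous ones with probability ω; for ω > 1 the thinning flips to
the synonymous side (probability 1/ω). A pure "accept nonsynonymous with
min(1, ω)" rule cannot push the realised nonsynonymous fraction above the
neutral expectation, which would make ω > 1 indistinguishable from ω = 1;
the flipped rule makes positive selection expressible and the realised
dN/dS track ω across the whole grid. Proposals that would create a stop
codon are re-drawn (not dropped), keeping the realised rate near nominal;
the start and stop codons are never mutated.

What the simulator does *not* emulate: indels, recombination and gene
conversion, codon-usage bias, pseudogenes, chromatogram-level error
profiles, and phylogenetic structure within a locus beyond star-like
allelic noise. Tests passing on synthetic data therefore demonstrate the
statistical machinery under the stated generative model, not robustness
to every feature of real cDNA clone sets.

## Numerical choices and degenerate inputs

- Alignment scoring ties: fewest gaps among score-optimal alignments;
  identity is invariant to residual placement ties (see above).
- NJ ties are resolved by `ape::nj`'s deterministic agglomeration order.
- Fitch top-down ties: lexicographically smallest state (counts are
  tie-invariant).
- p-values from permutation and bootstrap tests are seeded; results
  report the seed and replicate count used.
- Degenerate inputs are flagged, not silently coerced: alignments of
  identical sequences give `NA` dN/dS and z-statistics with an
  `undefined` flag; empty groups, zero-variance Welch inputs and
  all-zero enrichment tables raise errors or flagged `NA`s.
- Problem sizes in the test-suite simulations (replicate counts of
  50–1000, 100–300 codons for most property checks) were chosen to hold
  Monte-Carlo error well inside each asserted tolerance while keeping
  the default suite quick on a single CPU.

## Known limitations

- The parsimony-based site scan approximates an ML single-ancestor
  analysis; per-site calls near the significance boundary can differ
  from an ML implementation, which is why published per-site counts are
  checked only through reconstruction-independent quantities (invariant
  column counts) and distributional properties.
- No recombination screening is performed before the selection scan; a
  config option allows analysing user-supplied sub-alignments instead.
- Only unweighted UniFrac is tested; an abundance-weighted variant would
  require a different sampling model.
- Greedy dereplication counts can depend on input order near the
  threshold — consistent with the "3 to 4 variants" ambiguity such tools
  produce — and the package therefore exposes a deterministic pre-sort
  option rather than claiming a canonical count.
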