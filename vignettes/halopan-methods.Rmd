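---
title: "Methods behind halopan: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind halopan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halopan)
```

halopan implements the comparative-genomics toolchain used to study large
collections of haloarchaeal genomes: protein-family construction from
all-vs-all similarity searches, pangenome and core-genome analysis,
gene-tree-based classification of horizontal gene transfer, sliding-window
G+C changepoint analysis with family enrichment, proteome isoelectric-point
profiling, and phylogenetic profiling for annotation transfer. This
vignette explains each model, its assumptions, the tunable parameters and
their defaults, and the design choices made where the method left room.
Every empirical statement below is recomputed by the package's test suite
or by `scripts/acceptance.R`; nothing is quoted from elsewhere.

## Protein families from similarity graphs

Families are built in two stages. First, similarity edges are filtered to
remove spurious domain-level matches: an edge survives iff the alignment
covers at least 80% of *both* sequences (`min_bidir_coverage = 0.80`), the
shorter sequence is at least 75% of the length of the longer
(`min_length_ratio = 0.75`), and the E-value is at most `1e-10` for
clustering (homolog screens use the stricter `1e-20`). Self-edges are
dropped and reciprocal duplicates merged keeping the best E-value. The
filter is monotone: relaxing any threshold can only add edges.

Second, the filtered graph is clustered by Markov clustering (MCL),
implemented natively on a sparse column-stochastic matrix. Edge weights
default to `-log10(E-value)` capped at 200 (an E-value of zero maps to the
cap), the classical TRIBE-style convention; a bitscore transform is
available. Self-loops are set to each node's maximum incident weight,
which damps oscillation. Each iteration expands (squares the matrix),
inflates (raises entries to the `inflation` power, default 2.5, and
renormalizes columns), and prunes entries below `1e-5`; iteration stops
when the matrix changes by less than `1e-8` or after 100 iterations
(non-convergence returns the current clustering with a warning). Clusters
are the connected components of the limit matrix; proteins without
surviving edges become singleton families. The protein universe is sorted
before matrix construction, so results are reproducible run to run.

The inflation parameter trades granularity for cohesion. Because the
original selection of inflation 2.5 relied on manually curated families,
`benchmark_inflation()` reproduces the procedure generically: it clusters
at each grid value (default 1.4–8.0) and scores agreement with a curated
`FamilySet` by the adjusted Rand index restricted to curated proteins.
Whether cluster counts rise strictly monotonically with inflation is not
asserted anywhere — it is a diagnostic a user can tabulate, not a
guarantee of the algorithm.

## Pangenome structure

`build_matrix()` tabulates per-family, per-genome copy numbers. On top of
it:

* **Rarefaction** (`rarefy()`) draws, for each sample size $n$ from 0 to
  $N$ genomes, 10,000 uniform subsets and averages the number of families
  seen at least once. Alongside the Monte-Carlo curve it returns the exact
  expectation
  $E[U(n)] = \sum_f \left(1 - \binom{N-m_f}{n}\big/\binom{N}{n}\right)$,
  where $m_f$ is the number of genomes carrying family $f$. The closed
  form is itself validated against exhaustive enumeration of all
  $\binom{6}{n}$ subsets on a toy matrix, and the Monte-Carlo mean is
  required to sit within three standard errors of it. Sample sizes run 0
  to $N$ inclusive; the upper end is configurable. Singleton exclusion
  (`family_definition = "mcl_no_singletons"`) removes families with a
  single *member*, the reading under which a singleton is a one-protein
  cluster.
* **Core genome** (`core_families()`): families present in every column.
* **Genus-specific families** (`genus_specific_families()`): all member
  species belong to one genus, regardless of copy number or universality.
* **Markers** (`discover_markers()`): the strict triple — universal in the
  genus, absent outside it, single copy in every genus member. Markers are
  by construction a subset of the genus-specific families.
* **Per-genus reports** (`genus_report()`): 25th/50th/75th percentiles of
  genome statistics, using linear interpolation between closest ranks
  (`stats::quantile` type 7). The percentile convention of the original
  plotting tool is unknowable, so one convention is fixed and documented.

## Missed gene calls between conserved anchors

When two anchor families flank a gap where a target family is called in
most but not all species, `rescue_missed_genes()` scans the inter-anchor
sequence (anchors at most 5 kb apart) in all six reading frames for open
reading frames with start codons ATG/GTG/TTG (archaeal usage) and stops
TAA/TAG/TGA, whose encoded length is within ±20% of the target family's
median protein length. Candidates are scored by identity to family members
(equal lengths: positional identity; otherwise global alignment identity)
and reported above 30%. A `fixed_length` mode instead translates every
contiguous window of a given length (e.g. 117 nt), reproducing the
original fixed-window search as a special case; the ORF scan generalizes
it.

## Gene-tree classification of bacterial imports

Trees are unrooted and tips carry a domain tag — `H` (haloarchaea), `A`
(other archaea), `E` (bacteria) — as the first character of the label.
`test_monophyly()` asks whether some edge bipartitions the tips into
exactly the tagged set versus the rest; a single tagged tip (or its
complement) is trivially monophyletic. The implementation scans candidate
edges directly; the tests compare it against an independent exhaustive
edge scan on 500 random trees.

`classify_tree()` encodes "haloarchaea monophyletic and rooted among
bacteria" for unrooted trees: if H is not monophyletic the verdict is
`non_monophyly`; otherwise the tree is conceptually rooted on the
H-separating edge and the composition of the adjacent neighbor clades on
the non-H side is collected, expanding internal neighbors up to
`neighbor_depth` levels (default 1; tips encountered at any visited level
count). Under the strict `all_bacterial` rule (default) the verdict is
`basal_import` iff the collected tips include at least one `E` and no `A`;
the lenient `majority_bacterial` rule requires only a bacterial majority.
The strict rule is the conservative reading — it can only lower the
basal-import count — and since the original sister-group convention is not
recoverable, both are provided and neither is claimed to be "the" original
rule. Branch support values on input trees are ignored: no support
threshold enters the monophyly test.

Family extension (`extend_family()`) recruits pool proteins with at least
one edge to a member at E-value ≤ 1e-10 and identity ≥ 30%. Families
exceeding `max_family_size` (default 200) are flagged infeasible for tree
building; the original cutoff behind the excluded fraction is unstated, so
the size is a documented knob and flagged in outputs rather than silently
applied. `summarize_calls()` reports assessed counts and percentages
rounded to one decimal, dropping infeasible and untestable calls from the
denominator; it also accepts printed (assessed, basal) count pairs
directly so published tables can be recomputed without the underlying
trees.

Bootstrap clade support (`clade_support()`) counts, for each non-trivial
bipartition of a guide tree, the fraction of replicate trees containing
that bipartition, comparing bipartitions in canonical form (the side not
containing the alphabetically first tip). Replicates on a different tip
set are skipped; whether they still count in the denominator is a
configuration choice (`denominator = "used"` or `"all"`).

## G+C landscape

`gc_windows()` computes %G+C in 100 bp windows at 20 bp steps (both
configurable), never spanning contig boundaries and omitting each contig's
terminal sub-window residue. Windows with more than 10% ambiguous bases
are assigned the contig mean and flagged; *all* non-ACGT IUPAC codes count
as ambiguous (a conservative superset of `N`). For sub-threshold
ambiguity, the denominator excludes ambiguous positions so that a few `N`s
do not bias the composition — an interpretation, flagged as such, chosen
over a fixed denominator.

`segment_gc()` finds change-in-mean changepoints per contig. The original
analysis used a changepoint package followed by manual curation; here the
pipeline is fully automated and replaces curation with three knobs: a
penalty multiplier (default 2) on a BIC-style penalty
$\beta = \text{penalty} \cdot \hat\sigma^2 \log n \cdot \lceil w/s \rceil$,
a minimum segment length (10 windows), and a divergence threshold
(5 percentage points) defining which segments become divergent regions. No
numerical identity with any external changepoint implementation is
claimed. Two numerical points matter:

* Overlapping windows (step < window) are serially correlated, so the
  noise scale $\hat\sigma$ is estimated from differences at a lag of one
  full window (robust MAD estimate), and the penalty is scaled by the
  overlap factor $\lceil w/s \rceil$ — without this the segmenter badly
  over-splits real window series.
* Binary segmentation is greedy, so after splitting, each changepoint is
  re-optimized locally between its neighbors to a fixed point. An exact
  penalized dynamic-programming mode (`method = "exact"`, quadratic time)
  is available for short series and agrees with binary segmentation on
  clean jumps.

Divergent regions require no minimum length beyond the minimum segment
length; whether the original analysis imposed one is unstated.
`extract_region_features()` selects features whose midpoint falls in a
divergent region (an any-overlap mode is available), and `enrich()`
computes fold enrichment as the ratio of the family's frequency among
region features to its frequency among all features — the only reading of
"frequency" that makes fold enrichment well defined. Families with fewer
than 5 members are excluded and folds below 8 are not reported. No
chromosome/plasmid distinction is made anywhere (replicon-size
neutrality).

## Isoelectric points

`net_charge()` is the Henderson–Hasselbalch sum over ionizable groups:
basic groups contribute $1/(1+10^{pH-pK_a})$, acidic groups
$-1/(1+10^{pK_a-pH})$, termini once and side chains per occurrence. The
default pKa preset uses EMBOSS-style constants (N-terminus 8.6,
C-terminus 3.6; D 3.9, E 4.1, C 8.5, Y 10.1; H 6.5, K 10.8, R 12.5); the
table is swappable. The constants used by the original prediction
framework are not published, so per-protein numerical agreement with any
published pI is *not* claimed — only distributional properties are tested.
Cysteine counts as ionizable; B/Z/X contribute no charge.

Because the charge is strictly decreasing in pH, `isoelectric_point()`
bisects on [0, 14] to a default tolerance of 1e-4; an independent grid
scan at 1e-4 resolution (`isoelectric_point_grid()`) serves as the
reference, and the two agree to within 1e-3 on 1,000 random proteins in
the acceptance suite. pI depends only on composition, so it is invariant
under sequence permutation. `profile_proteome()` bins pIs into 100 equal
bins over [2.0, 13.0] (bin $k$ covers $[2+0.11k, 2+0.11(k+1))$, last bin
closed; out-of-range pIs are counted and logged), collects the high-pI set
at pI ≥ 7.5 (boundary inclusive), and tallies annotations by high-pI
instances. `pi_family_report()` applies the 60% rule, labelling a family
high/low/variable by the fraction of members above pI 7.5.

## Phylogenetic profiling

Profiles are binarized presence/absence vectors by default (a copy-number
mode exists; whether the original analysis binarized is unstated, and
binary is the default because Euclidean distance on copy numbers conflates
abundance with distribution). Distances are Euclidean, clustering is
agglomerative with average linkage (the original linkage is unstated;
average is the default and configurable), and the flat cut (`k` or height)
is a user parameter because the original clusters were interrogated
manually. `propose_annotations()` hypothesizes, for every cluster in which
at least 80% of annotated members share a category, that category for each
unannotated member, listing the supporting members. Functional categories
come from a user-supplied map from annotation text to category, since the
original category assignment was manual.

## Synthetic data and what it does (not) show

Every generator is a pure function of its parameters and seed, and ships a
truth bundle sufficient to score the corresponding pipeline stage:

* `gen_pangenome()` plants core, accessory and genus-private families with
  point-mutated members (default 12 genomes in 3 genera, 25 core, 60
  accessory with presence probability 0.4, 3 private families per genus,
  5% paralog probability, 5% per-site divergence) and emits a similarity
  table whose within-family edges pass the clustering thresholds while
  optional noise edges fall below them. Sequence evolution is i.i.d.
  substitution without indels — enough for threshold-based recruitment and
  clustering tests, and it keeps identities analytically predictable.
* `gen_genome()` draws bases i.i.d. at a local target G+C (default 62%
  background with a 5 kb 45% island in 50 kb), optionally sprinkling `N`s.
* `gen_proteome()` draws proteins from a D/E-enriched acidic mode and a
  K/R-enriched basic mode (default 80%/20%), emulating the acid-shifted
  proteome of a salt-in halophile with a basic minority mode; the
  compositions are strong enough that the high-pI fraction tracks the
  basic fraction within a few percentage points.
* `gen_gene_trees()` builds caterpillar scaffolds and attaches the
  haloarchaeal tips according to the scenario (one basal attachment inside
  the bacterial subtree; two attachments; nested in archaea; scattered),
  with optional random NNI noise applied after the truth verdict is
  recorded.
* `gen_missed_gene_case()` writes an anchorA–target–anchorB neighborhood
  into each genome and hides the target from the feature table of selected
  species; spacer sequence avoids start codons so the planted ORF is
  unambiguous.

These simulations establish correctness against planted truth under
idealized conditions: no alignment error, no domain-level chimerism, no
indels, no compositional heterogeneity beyond what is planted. Passing
them shows the algorithms do what they claim on their stated inputs — not
that real proteomes cluster perfectly or that real changepoints are
unambiguous. The published genome-scale totals (tens of thousands of
clusters from 80 proteomes and the associated counts) depend on those real
data and are deliberately not asserted anywhere in this package.

## Problem sizes in the routine checks

The test and acceptance runs use desk-scale problem sizes chosen to keep
the suite fast while leaving the statistics sharp: 60-node planted block
graphs and 10–12-genome pangenomes for clustering, a 6-genome matrix for
the exhaustive rarefaction oracle, 1,000 noise-free trees (250 per
scenario) plus 500 random trees for the classifier, 100 seeded
500-window series with planted 100-window (2 kb) shifts of 8 percentage
points at window noise σ = 3 for the segmenter, and 1,000 random proteins
of 50–500 residues for the pI cross-check.

## Workflow and interfaces

The package is organized as an analysis workflow: numbered drivers under
`analysis/` (simulate, cluster, pangenome, gene trees, G+C, pI, profiling)
are thin narrative scripts over the package functions and write their
tables under `results/`; the functions themselves, this vignette and those
scripts are the user interface, and no shell wrapper is provided beyond
them. `scripts/acceptance.R` recomputes the headline quantities from
scratch against the installed package.
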