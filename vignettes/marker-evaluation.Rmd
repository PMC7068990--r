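---
title: "Evaluating a two-part exon+intron barcoding marker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating a two-part exon+intron barcoding marker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcnbarcode)
```

## The setting

In recently radiated plant groups, plastid barcodes frequently carry too
little variation to tell close relatives apart. A low-copy nuclear
marker that pairs a slowly evolving exon with an adjacent intron
promises more resolution: the exon stays alignable across a whole
family, while the intron accumulates substitutions several times faster
and, crucially, insertions/deletions — so much so that no family-wide
intron alignment exists. This package evaluates such a marker the way a
barcoding study would: identity clustering against accepted taxonomy,
divergence and barcoding-gap statistics on the alignable exon,
best-hit species identification on the full exon+intron barcode, and
allele-level hybrid detection. Every component is exercised against a
simulator with planted truth, so the package's claims are testable
without any external data.

The record model is deliberately simple: a data frame with one row per
sequence (or per cloned allele), carrying taxonomy (species, genus,
subfamily, species group), provenance (the collection an accession came
from), and 0-based half-open region boundaries (`exon_end`,
`intron_end`). All coordinates in the package are 0-based half-open —
`[0, exon_end)` is the exon, `[exon_end, intron_end)` the intron, and
the remainder a short terminal exon remnant (14 bp by convention) that
is cut off before any analysis. IUPAC ambiguity codes are retained on
input (Sanger chromatogram double peaks produce them in real data) and
treated as missing everywhere downstream. Only the forward strand is
considered, since barcodes are amplified with fixed primer orientation.

## Alignment engines and their statistics

Two dynamic-programming kernels (C++, linear gap costs) back everything:

* **Banded global alignment** for identity computation. The band
  half-width defaults to `|len_a − len_b| + 32`: intron length
  differences dominate the offset between homologous barcodes, and 32
  extra diagonals absorb scattered indels. The band is widened
  automatically if it cannot cover the length difference. Identity is
  *matches / length of the shorter sequence* — the CD-HIT-EST
  convention, under which a clean terminal indel costs nothing. The
  denominator is configurable (`denominator = "alignment"`).
* **Word-seeded local alignment** for database search, emulating a
  megablast configuration appropriate for near-identical sequences:
  match +1, mismatch −2, linear gap cost, word size 28, E ≤ 10. Only
  subjects sharing at least one exact 28-mer with the query are
  aligned; short queries fall back to full DP against everything.

Scores are normalized with ungapped Karlin–Altschul statistics:
λ is always computed as the positive root of
Σᵢⱼ pᵢpⱼ e^{λ s(i,j)} = 1 (bisection to 1e−9; for +1/−2 and uniform
base frequencies this is 0.25·e^λ + 0.75·e^{−2λ} = 1, λ ≈ 1.333),
K defaults to 0.62. These constants are not published for the "linear
gap" megablast mode, so absolute bit-score magnitudes are not
reproducible against any particular BLAST build — but the species
identification rule below depends only on score *ordering*, which is
independent of K and, for integer raw scores, identical between raw and
bit scores. E-values use `E = K·m·n·e^{−λS}` with the summed database
length as n and no effective-length edge correction; the correction
would shift all E-values of a search equally and cannot change a
ranking.

## Distances and site statistics

Kimura 2-parameter distances use pairwise deletion: a site with a gap
or ambiguity code in either sequence of a pair is excluded for that
pair only. This is the common default for distance analyses in MEGA and
keeps rare indel columns from erasing whole comparisons; complete
deletion would also make distances depend on which other sequences
happen to be in the alignment. Saturated pairs (where `1 − 2P − Q` or
`1 − 2Q` is non-positive) raise an error from `k2p()` but are masked as
`NA` by `distance_matrix()`, keeping the matrix usable with explicit
masking rather than infinities.

Variable and parsimony-informative sites are counted model-free: a
column is variable with ≥ 2 distinct unambiguous bases, informative
when ≥ 2 bases each occur in ≥ 2 rows. Gaps are excluded from state
counts by default (the MEGA convention); a strict mode counts the gap
character as a fifth state, because published counts cannot be audited
without knowing which convention produced them.

## Clustering and taxonomic concordance

`greedy_cluster()` reproduces CD-HIT-EST's documented strategy:
sequences sorted longest-first (ties by id), each sequence joins the
*first* representative at or above the identity threshold, otherwise it
seeds a new cluster. First-fit, not best-fit — that is what the widely
used tool does, and emulating it makes cluster counts comparable with
studies that ran it. The length-sort plus deterministic tie-breaking
makes the output independent of input order. The default threshold of
0.98 reflects the empirical observation that identity clusters at ≈98%
track accepted taxonomic groups in the target family. No k-mer
prefilter is applied by default; the datasets this package targets are
hundreds of sequences, where the O(n²) identity computation in C++ is
cheap.

`cluster_purity()` labels each cluster `species_cluster` (one species),
`supported` (several species, but one species group or one genus),
`unsupported` (mixed groups) or `unknown` (species absent from the
taxonomy table), and aggregates per subfamily — the shape in which
clustering results are conventionally reported.

## Species identification

The reference database holds either the trimmed exon (≤ 264 bp) or the
concatenated exon+intron. Queries are one accession per species that
was sampled from ≥ 2 distinct provenances (the lexicographically
smallest record id, for determinism); restricting to multi-provenance
species guarantees a conspecific remains in the database after the
query itself is removed. Self-hit removal is by record id — without it
every query would trivially hit itself and the trial would measure
nothing.

The decision rule: let B be the best bit score among the hits. The
query is **correct** when every hit scoring B is conspecific,
**ambiguous** when the query species ties with others at B,
**no_hit** when nothing survives the seed and E-value filters,
**incorrect** otherwise. "Strictly lower score" is operationalized as
strict raw-score inequality with no epsilon: raw scores are integers,
and with fixed λ and K bit-score ties are exactly raw-score ties.
Group-level (genus/clade) success follows the single best-sorted hit.

## Barcoding-gap statistics

`gap_report()` partitions pairwise distances by taxonomic level
(intraspecific; congeneric = same species group; intergeneric = same
subfamily; interfamilial), reports quartiles per level, flags overlap
(`max(intra) ≥ min(inter)` — a true barcoding gap means no overlap) and
compares intra vs inter with a Wilcoxon rank-sum test implemented from
scratch: midranks for ties; exact two-sided p by full enumeration of
rank assignments when the smaller sample has ≤ 8 observations and no
ties; otherwise a normal approximation with tie-corrected variance and
continuity correction. The two-sided exact p is
P(|W − μ| ≥ |w − μ|), which coincides with the usual doubled-tail
definition for the symmetric tie-free null. Exhaustive enumeration at
8 vs 8 shows the continuity-corrected approximation stays within 0.011
of the exact value everywhere (worst case 0.0109 at W = 60), which is
as close as any normal approximation gets in that regime. The test is
two-sided by convention. One caveat is inherent to the design and
simply reported as such: pairwise distances sharing a sequence are
statistically dependent, so the Wilcoxon p-value is descriptive, not a
calibrated test of independent observations.

## Trees and hybrid assignment

`neighbor_joining()` is the standard Saitou–Nei agglomeration with
deterministic tie-breaking (lexicographically smallest pair of node
ids, an internal node being identified by its smallest leaf label).
Additive matrices are reconstructed exactly; negative branch lengths —
a well-known NJ artifact — are clamped to zero and counted in the
`"clamped"` attribute. Masked matrix entries are a hard error with
advice, not silently imputed. `bootstrap_support()` resamples alignment
columns with replacement, rebuilds the K2P matrix and tree per
replicate, and reports the percentage of successful replicates
containing each original bipartition; replicates whose resampled matrix
has masked pairs are skipped and counted. Distance-based NJ stands in
for likelihood tree inference deliberately: the scientific use of the
tree here is allele-to-genepool assignment, which is grounded in
identical alleles and clade support, not in likelihoods — a full ML
implementation would be out of proportion to that use.

`assign_alleles()` assigns each cloned allele to the genepool
containing its minimum-K2P reference (global alignment over
exon+intron, gaps excluded pairwise, consistent with the distance
module). The margin is the nearest-other-pool distance minus the
assigned-pool distance; exact ties go to the lexicographically first
pool with margin 0 and a tie flag. An individual whose alleles land in
≥ 2 pools is flagged `putative_hybrid`. Geographic co-occurrence
arguments that usually accompany hybrid diagnosis are outside this
package; only the allele-assignment signal is implemented.

## The simulator: a stated world

`sim_params()` defaults describe the world the package is designed for,
and they are fixed once, not tuned per test:

| Parameter | Default | Meaning |
| --- | --- | --- |
| `exon_length` | 264 bp | slow exon length (plus a 14-bp terminal remnant) |
| `intron_length_range` | 100–400 bp | root intron length, uniform |
| `exon_divergence_target` | 0.01 | expected interspecific exon K2P within a group |
| `intraspecific_divergence` | 0.004 | expected within-species K2P — deliberately overlapping the interspecific range |
| `group_divergence`, `subfamily_divergence` | 0.03, 0.08 | expected exon K2P between groups / subfamilies |
| `intron_rate_multiplier` | 5 | intron substitution rate relative to exon |
| `kappa` | 2 | transition:transversion odds per substitution event |
| `indel_rate` | 0.2/branch | intron indel probability (geometric lengths, mean 4) |
| `het_fraction` | 0.2 | accessions emitting two intron alleles differing by ≥ 1 indel |

Species evolve along a pure-birth tree per group, rescaled so the mean
pairwise path length equals the exon divergence target; accessions sit
on a within-species star. Substitutions are placed by per-branch
Poisson sampling with transition:transversion odds κ:1 per event rather
than exact matrix exponentiation — at the low divergences stated here
multiple hits at one site are rare and the expected pairwise K2P tracks
the branch-length sum closely, which the calibration tests verify to
within ±30% across seeds. Indels never touch the exon, matching the
empirical motivation (allelic differences confined to the intron) and
keeping the exon alignment trivially true. Hybrids receive one allele
near each of two parental species from different groups of one
subfamily.

What the simulator does **not** emulate — and hence what a green test
does not establish — includes: base-composition bias and rate
heterogeneity across sites, within-species genealogy (coalescent
structure), selection, paralogy/copy-number variation of the marker,
sequencing error other than the het-allele mechanism, and any
geographic structure. Conclusions about those phenomena require real
data.

## Numerical and degenerate-input conventions

* λ bisection tolerance 1e−9; a non-negative expected score per aligned
  pair is an error (no positive root exists).
* DP tie-breaking: diagonal > up > left in tracebacks; the local-DP hit
  is the first best cell in row-major order.
* Hit sorting: descending bit score, ties by subject id.
* Distances: saturation is masked in matrices, an error in scalar
  `k2p()`; zero comparable sites is always an error.
* Wilcoxon: all pooled values identical gives p = 1 by convention.
* Bootstrap on an all-identical alignment degenerates gracefully (every
  replicate is a star; no crash).
* Gap report with < 2 distances in a class leaves the p-value unset with
  a warning.
* Pipeline reports carry a provenance header (package version, seed,
  config hash excluding the output path) so reruns are byte-comparable.

## Known limitations

* Absolute bit scores/E-values are not comparable to any specific BLAST
  build (unpublished λ/K for the linear-gap mode); rankings are.
* Greedy clustering emulates the documented CD-HIT strategy, not its
  internal short-word statistics; counts on real data may differ
  slightly across tool versions, whose defaults also differ.
* How exon/intron boundaries were located in new sequences is a choice
  of this package (stored truth, or best local alignment against a
  reference exon); other reasonable mechanisms exist.
* The Wilcoxon p on distance sets inherits the dependence caveat above.
* NJ replaces ML tree inference by design (see above).
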