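---
title: "Methods: a profile-based census of KAT and KDAC families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a profile-based census of KAT and KDAC families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Lysine acetylation of histones (and many non-histone proteins) is written by
lysine acetyltransferases (KATs: MYST, GNAT, CBP, TAFII250 families) and
erased by lysine deacetylases (KDACs: the Zn-dependent HDA/RPD3 family, the
NAD-dependent SRT/sirtuin family, and the plant-lineage HDT/HD2 family).
Surveying these families across many sequenced genomes requires a chain of
standard but fiddly steps: sensitive family detection with explicit score
thresholds, validation of borderline hits, summaries of domain architecture
and subcellular targeting, and regulatory-region analysis. `katcensus`
implements that chain as tested, composable functions, and ships a
synthetic-data generator that plants known truth through every stage so the
chain can be verified end to end.

# Family detection model

## Profiles

Each family (or sub-class) is represented by a position-specific profile
built from a seed multiple alignment by `build_profile()`. Alignment columns
with at least 50% gap characters are excluded from the match states; this
keeps the profile length close to the core domain rather than to
alignment artifacts. For a retained column with residue counts $c_a$ over
$n$ non-gap rows, the emission probability is

$$ p_a = \frac{c_a + \tau\, q_a}{n + \tau} $$

with pseudocount mass $\tau$ (default 0.5) distributed according to the
background frequencies $q_a$ (a fixed Robinson–Robinson composition, so
results do not drift with the query proteome's composition). Scoring uses
natural-log odds $\log(p_a/q_a)$.

## Scoring

`score_protein()` computes the best local-alignment score of a sequence
against the profile by affine-gap dynamic programming (match, insert and
delete states; insertions emit at background, i.e. log-odds 0; adjacent
insert/delete transitions are disallowed; the empty alignment scores 0).
The default gap penalties, open 11 / extend 1 on the log-odds scale, follow
the common convention of BLOSUM62-based local search. They are deliberate
defaults, not estimates: the census operates far from the gap-penalty
sensitive regime because accepted hits are orders of magnitude above the
noise score distribution.

## E-values and the accept/review/reject zones

Profile search tools report E-values from an extreme-value law. We make
that explicit and self-contained: `calibrate_evalue()` scores `n_random`
(default 1000) i.i.d. background sequences of the proteome's median length
and fits a Gumbel location/scale $(\mu, \lambda)$ by the method of moments
($\lambda = \pi/(s\sqrt 6)$, $\mu = \bar x - \gamma/\lambda$). Then

$$ E(s) = D \left(1 - e^{-e^{-\lambda (s - \mu)}}\right) $$

for database size $D$ (the number of proteins searched). The tail is
evaluated as $D e^{-\lambda(s-\mu)}$ once the inner exponent is below
$10^{-12}$, so the astronomically small E-values of true family members are
computed accurately instead of underflowing through the double-exponential.

Hits are partitioned by two thresholds: E-values below $10^{-100}$ are
**accepted**; between $10^{-100}$ and $10^{-3}$ (inclusive) they enter a
**review** zone; above that they are **rejected**. A protein matching
several profiles is assigned to the family with the minimum E-value; exact
ties demote the hit to review. Review-zone hits are adjudicated
automatically by reciprocal best hit (`reciprocal_best_hit()`): the
candidate's best local alignment (BLOSUM62, gap 11/1, via `Biostrings`)
must land in the claimed family's reference set, and the reverse search
from that reference must rank the candidate first; any exact tie is treated
as ambiguous and the hit is excluded. By default family tabulations count
accepted plus RBH-confirmed review hits; `include_review = FALSE` gives the
stricter convention, since published counts rarely state which convention
was used.

## Family-size statistics

`compare_family_sizes()` compares per-species family sizes across
species-type groups with the Kruskal–Wallis rank-sum test (tie-corrected
$H$, chi-square approximation with $g-1$ degrees of freedom, via
`stats::kruskal.test`). Fully tied data short-circuit to $H = 0$, $p = 1$.
Each group must contain at least two species.

# Domain-architecture profiles

For each (family, species-type) group, `profile_group()` reports the
group's median protein length and, per domain, its prevalence and a binned
positional histogram:

* **Median**: the lower of the two middle order statistics for even group
  sizes, so the reported median is always an attained protein length (the
  bar in an architecture figure marks a real protein size).
* **Rescaling**: each 1-based domain interval $[s, e]$ in a protein of
  length $L$ is mapped to $[s, e] \cdot m / L$ on the group median $m$,
  preserving order and nesting.
* **Prevalence** is a per-protein predicate (a protein with three copies of
  a domain counts once); domains present in fewer than 5% of the group's
  proteins are dropped *after* prevalence is computed on the full group, so
  denominators are never post-filter sizes.
* **Positional frequency** over `bins` (default 100) equal bins of
  $[0, m]$: the per-protein variant (fraction of proteins with an
  overlapping copy; bounded above by prevalence, and the default display
  value) and the per-occurrence variant (every copy counts) are both
  computed, since either reading of a published histogram is defensible.

# Consensus subcellular localization

`consensus_localization()` is a pure function of the protein's leading
residue and the multiset of five predictor calls: proteins not starting
with methionine are *unpredicted* (a sequence-model artifact class, not a
biological call); `"none"` calls are discarded from the votes but the
majority bar stays absolute (3 of 5, not 3 of the non-none calls); a
compartment with ≥ 3 votes is a *single* call; otherwise the two most
frequent compartments become primary/secondary. Count ties are broken by a
fixed priority (nucleus > cytosol > mitochondrion > chloroplast >
secretory > other), a deterministic total order chosen because nuclear and
cytosolic calls dominate for these enzyme families. The whole rule is
checked against an exhaustive independent enumeration of all $6^5$ vote
patterns.

# Promoter elements

* **Extraction** (`extract_promoter()`): 2000 bp immediately upstream of
  the gene start on the coding strand — for minus-strand genes the region
  downstream of `end` in genome coordinates, reverse-complemented. Regions
  are truncated (and flagged) at scaffold ends, never discarded, and are
  not trimmed at upstream neighboring genes.
* **Scanning** (`scan_element()`): exact, non-overlapping matches by a
  greedy leftmost scan, which for exact patterns attains the maximum
  non-overlapping count (verified against a brute-force interval-scheduling
  oracle). Only the oriented promoter's forward strand is scanned; element
  libraries list strandless strings, and a user can scan the reverse
  complement explicitly if wanted.
* **Enrichment** (`enrich()`): per (species, family, element), the
  hypergeometric upper tail $P(X \ge k)$ with universe $N$ = all genes of
  the species with a non-empty promoter, $K$ = universe genes carrying ≥ 1
  match, family set size $n$, and $k$ carriers within it. The predicate is
  per-gene presence; occurrence counts are tracked and reported but do not
  enter the test. The cutoff is a raw $p < 0.05$ with no multiple-testing
  correction by default (Benjamini–Hochberg is available behind
  `adjust = "BH"`), matching common practice for exploratory promoter
  scans.
* **Conservation** (`conserve()`): an element is conserved for a family
  when enriched in ≥ 50% of the species examined; only species that
  possess the family count as examined, and the boundary is inclusive.

# The synthetic-data generator

`simulate_census()` emulates the structure of a multi-species census at
desk scale with planted, recoverable truth. The defaults are the package's
study conditions and are not tuned per analysis:

| Parameter | Default | Meaning |
|---|---|---|
| `n_species` | 12 | two per species-type division |
| `n_members` | 3 | planted members per family per species |
| `expansion` | HDA +2, HDT +2, CBP +1 | extra members in dicots/monocots, emulating the land-plant expansion of these families |
| `divergence` | 0.15 | per-site substitution rate of members from the family consensus |
| `seed_rows`, `seed_divergence` | 6, 0.08 | seed alignment depth and within-family divergence |
| `insertion_prob` / `background_prob` | 0.9 / 0.05 | element planting rate in target vs non-target promoters |
| `predictor_accuracy`, `none_prob` | 0.9, 0.03 | localization predictor behavior |
| `non_m_fraction` | 0.05 | background proteins lacking an initial methionine |
| `edge_fraction` | 0.05 | genes placed near scaffold ends to exercise promoter truncation |

Choices worth explaining:

* **Element strings are ≥ 7 bp.** In a uniform background, a 6-mer occurs
  by chance in roughly half of all 2000-bp promoters, which would
  contradict the generator's declared 5% background presence rate; the
  default library therefore uses extended forms of the classic elements
  (e.g. an extended G-box) so the declared rates hold.
* **The initial methionine of planted members is fixed.** Mutation applies
  to positions 2..L; start codons are conserved in real proteins, and an
  eroded leading M would conflate sequence divergence with the
  localization rule's missing-M exclusion. `mutate_family_member()` itself
  mutates every site per its contract; the generator composes it with a
  fixed `M`.
* **Genome layout**: one gene per 6000-bp segment with ≥ 2000 bp clearance
  on both sides (so promoters never collide), plus a small set of
  edge-proximal genes on short scaffolds with 1200 bp clearance to
  exercise truncation. Motif planting writes exact patterns into a shared
  non-overlapping slot grid on the oriented promoter, reverse-complementing
  for minus-strand genes.
* **Determinism**: one seed drives every draw in a fixed order; identical
  configurations produce byte-identical files.

What the generator does **not** emulate: tree-structured sequence
evolution (members are i.i.d. around a consensus, so phylogenetic signal
beyond family membership is absent), codon-level linkage between genome
and proteome, length variation by indels within families, compositional
heterogeneity across species, degenerate/PWM motifs, and overlapping gene
models. Passing the end-to-end tests therefore demonstrates that the
pipeline's logic is correct under its stated model, not that the detection
thresholds are optimal for any real clade.

# Numerical choices and problem sizes

* E-value tail switched to the first-order form below inner exponent
  $10^{-12}$; E-values clamped to $[0, D]$.
* Gumbel fits require ≥ 200 null scores and reject zero-variance score
  distributions.
* Exhaustive test oracles run at sizes where enumeration is exact:
  profiles ≤ 4 columns × sequences ≤ 6 residues for alignment scoring, all
  $(k, K, n, N)$ with $N \le 12$ for the hypergeometric tail, all $6^5$
  vote patterns for localization, 1000 random promoter/pattern pairs for
  scanning.
* The shipped analysis workflow and the acceptance checks use the default
  12-species bundle (~700 proteins, ~430 planted motif copies) and
  1000-replicate null/power simulations for the enrichment test; these
  sizes make every stage's behavior measurable in minutes on one core
  while keeping all statistical margins wide.

# Known limitations

* The Gumbel calibration is a stand-in for a full profile-HMM E-value
  machinery; absolute E-values are internally consistent but not
  comparable to HMMER's.
* Review-zone adjudication automates the reproducible part of manual
  curation (reciprocal best hit); genuinely ambiguous hits are excluded
  rather than resolved.
* The enrichment universe is "genes with a non-empty promoter"; other
  universes (all annotated genes, length-filtered promoters) change $N$
  and are easy to pass explicitly, but are not the default.
* Domain profiling consumes annotation tables; it does not call domains
  from sequence.
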