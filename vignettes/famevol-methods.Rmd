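---
title: "Methods: gene-family evolution analysis with famevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-family evolution analysis with famevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famevol)
```

famevol implements the computational core of a genome-wide gene-family
study of the kind routinely performed for plant transcription-factor
families (the packaged reference tables come from the trihelix/GT family of
Moso bamboo, 35 members): a census of family members and their protein
properties, detection of duplicate (paralogous) and cross-species
(orthologous) gene pairs, estimation of selective pressure and duplication
age from synonymous/nonsynonymous substitution rates, a neighbor-joining
phylogeny with bootstrap support and subfamily assignment, a promoter
cis-element census, and qPCR-based expression quantification. This
vignette explains each model, its assumptions, the tunable parameters, and
the design choices made where the underlying conventions are not uniquely
determined.

## Family census

Members of a family are recognized by a domain scan. Rather than a full
profile HMM, the package uses an ungapped log-odds position-specific score
matrix (PSSM) built from a seed alignment of the domain
(`build_domain_profile()`): column residue frequencies with a pseudocount
(default 0.5 per residue) are converted to log2 odds against a background
(default uniform). A protein is scanned by sliding the profile
(`scan_domain()`); windows at or above a bit-score threshold are kept and
reduced to a non-overlapping set greedily by score. The threshold is not a
constant: `calibrate_profile()` scores the best window of a large number of
background-random sequences and takes an extreme quantile (default
`fpr = 1e-3` over 200–1000 shuffles), which emulates the very stringent
E-value cutoffs used with database domain searches. The PSSM is a
deliberate simplification — it has no insert/delete states — so it suits
the well-conserved, fixed-length domain cores it is calibrated on, not
remote homology detection.

Per-protein characterization follows standard conventions:

* **Molecular weight** (`molecular_weight()`) is the sum of average
  (isotope-abundance-weighted) residue masses plus one water, 18.0153 Da —
  the default convention of the common web calculators. Units: daltons,
  reported to 2 decimals.
* **Isoelectric point** (`isoelectric_point()`) solves
  $\sum_i q_i(\mathrm{pH}) = 0$ for the Henderson–Hasselbalch charges of
  the two termini and the D, E, C, Y, H, K, R side chains, by bisection on
  pH $\in [0, 14]$ to $|q| < 10^{-4}$. The pKa set is a
  Bjellqvist-style table (N-terminus 9.69, C-terminus 2.34, D 3.65,
  E 4.25, C 8.3, Y 10.07, H 6.0, K 10.53, R 12.48) and is overridable,
  since published pKa tables differ and the original analyses rarely state
  which one they used. The statistic is composition-only: permuting a
  sequence cannot change it.
* **Census summaries** (`census_summary()`) report min/max/mean of ORF
  length, protein length, molecular weight and pI, plus the intronless
  count. Mean ORF and protein lengths are *truncated* (not rounded) to
  integers, matching the reporting convention of the reference tables this
  package reproduces (a mean of 1097.74 bp is reported as 1097 bp);
  molecular weight is rounded to 2 decimals.

## Homolog detection

Pairwise relationships are established on nucleotide coding sequences with
exact Smith–Waterman local alignment (match +2, mismatch −3, gap open 5,
gap extend 2 — BLASTN-like scoring) rather than a heuristic seeded search:
family-scale inputs are small enough that the exact optimum is affordable,
and it removes both an external binary and seeding artifacts. Two
thresholds, kept at their conventional values in `default_run_config()`,
define the relations:

* **Paralogs** (`find_paralogs()`): any two genes of one species whose
  optimal local alignment covers **more than 300 bp** with **identity
  ≥ 40%** (identity computed over aligned columns excluding gap columns,
  the BLAST convention). A gene may belong to several pairs.
* **Orthologs** (`find_orthologs()`): reciprocal best hits between two
  species, ranked by alignment score, with the same > 300 bp coverage
  requirement. Ties on the best score are broken lexicographically and
  flagged. RBH yields a partial matching — no gene appears twice.

Because exact alignment strictly dominates a heuristic search, on real
data this implementation can only find a superset of heuristically-derived
pair lists at the same thresholds.

## Ka/Ks, selection and duplication dating

The estimator is the classical Nei–Gojobori (1986) counting method
(`kaks_ng86()`), the historical default of DnaSP-style analyses:

1. **Codon-aware alignment** (`codon_align()`): both CDS are translated,
   globally aligned at the protein level (Needleman–Wunsch, BLOSUM62, gap
   open 10 / extend 1), and each amino-acid column is expanded back to its
   source codon, so gaps occur only as whole codons. Pre-aligned or
   indel-free sequences can bypass the aligner via `codon_alignment()`.
2. **Site counting**: each codon position contributes one site, split into
   synonymous and nonsynonymous fractions according to the three possible
   single-nucleotide changes; mutations creating stop codons are excluded
   from the denominator. Sites are averaged over the two sequences, so
   $N + S = 3 \times$ (ungapped codon columns) exactly.
3. **Difference counting**: for each differing codon pair, synonymous and
   nonsynonymous differences are averaged over all minimal substitution
   pathways ($k!$ orderings for $k$ differing positions), skipping
   pathways that pass through a stop codon (the standard convention); if
   every pathway is blocked, all pathways are used with stop transitions
   counted as nonsynonymous.
4. **Multiple-hit correction**: proportions $p_N = N_d/N$, $p_S = S_d/S$
   are Jukes–Cantor corrected, $d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$.
   A proportion at or above $3/4$ is flagged saturated and the
   corresponding rate is undefined.

The ratio $\omega = K_a/K_s$ classifies selection
(`classify_selection()`): $\omega > 1$ positive, $\omega < 1$ purifying,
$\omega = 1$ (within $10^{-9}$) neutral. Duplication events are dated as

$$T = \frac{K_s}{2\lambda}, \qquad \lambda = 6.5 \times 10^{-9}
\ \text{synonymous substitutions site}^{-1}\,\text{yr}^{-1},$$

the grass-lineage synonymous clock rate (`divergence_time()`, reported in
million years to 2 decimals). $\lambda$ is configurable; everything
downstream is linear in it.

**Sliding windows** (`sliding_window_kaks()`) recompute the estimator in
150-bp windows advanced by 9 bp over the ungapped codon columns. Both
defaults are divisible by 3, so windows are snapped to codon boundaries
(50 codons, step 3) with no information loss. Windows with saturated
proportions, no synonymous sites, or $K_s = 0$ yield an undefined ratio
rather than an arbitrary number.

**Ks age bands** (`group_ks()`): reports of this kind group duplicate
pairs into a few "waves" of duplication by similar Ks, but the grouping
rule is essentially never stated. famevol makes the rule explicit and
parameter-light: sort the Ks values and cut at the $k-1$ largest gaps
(equivalent to cutting a single-linkage dendrogram at $k$ clusters),
default $k = 3$, numbering bands by decreasing mean Ks. On the packaged
12-pair reference table this reproduces the published three groups
exactly (band means 97.46, 48.12 and 16.28 My). A fixed absolute gap
threshold was rejected: the critical gap in the reference data is 0.22,
so any threshold is either data-tuned or wrong, whereas "the k−1 largest
gaps" is scale-free and matches how such groups are described.

`selection_report()` assembles the per-pair table (ratio to 4 decimals,
dates to 2, matching the reference precision), band summaries, the count
of positively selected pairs and the count of pairs younger than a
species-divergence threshold (default 12 My, the age of the focal
species' speciation in the packaged study).

## Phylogeny and subfamily assignment

Protein distances (`protein_distance()`) are Poisson-corrected,
$d = -\ln(1 - p)$, with pairwise deletion of gap columns — the common
default for distance trees on protein alignments; a raw p-distance is
available by argument. Pairs with $p \ge 1 - e^{-20}$ are capped at
$d = 20$ and flagged. Trees are built with Saitou–Nei neighbor joining
(`neighbor_joining()`, via ape), with negative branch lengths clamped to
zero. Bootstrap support (`bootstrap_support()`) resamples alignment
columns with replacement, rebuilds the tree, and reports the percentage of
replicates containing each internal bipartition of the point-estimate
tree. The analysis convention is 1000 replicates; the package's tests use
30–100 to keep runtimes short, which does not change the estimator, only
the Monte Carlo resolution of the support values. A seed is mandatory —
there is no silently irreproducible resampling.

Subfamilies are assigned by anchored clades (`assign_subfamilies()`):
reference leaves of known subfamily (e.g. rice/Arabidopsis members) anchor
the tree, and each query leaf takes the subfamily of the smallest clade
containing it and at least one anchor, provided all anchors in that clade
agree; a mixed-anchor clade leaves the query unassigned with a diagnostic
instead of guessing. Unrooted trees are midpoint-rooted first — "smallest
clade" is otherwise ill-defined. Per-species composition percentages
(`subfamily_percentages()`) sum to 100 within each subfamily.

The MSA itself is an input: progressive alignment heuristics are not part
of this package's claims, and any aligned FASTA (or the indel-free output
of the simulator) is accepted.

## Promoter cis-element census

Promoters are the 2000 bp immediately upstream of the translation start on
the coding strand (`extract_promoters()`; minus-strand genes are
reverse-complemented, contig edges produce truncated promoters with a
flag). "Upstream only" is a deliberate reading: cis-regulatory element
censuses are promoter analyses, and scanning downstream sequence would
double-count gene bodies.

Elements are described by IUPAC consensus strings in an editable TSV
dictionary (`read_element_dictionary()`); the packaged dictionary covers
the hormone- (MeJA, SA, ABA, GA, IAA, ethylene), stress-, development- and
light-responsive elements commonly reported by plant promoter scanners.
The consensus strings are concise literature-style stand-ins, not the
proprietary position-weight matrices of online services — absolute counts
on real genomes will therefore differ from matrix-based scans, and the
package's quantitative surface is the *category-share arithmetic* on
whatever hits the dictionary produces, which is exact. `scan_elements()`
reports every match on both strands; a palindromic consensus matching the
same coordinates on both strands is counted once. Note that
reverse-complement element pairs (CGTCA/TGACG) are two names for the same
double-stranded site, so their counts mirror each other by construction.
`summarize_elements()` reports per-element counts and 2-decimal percentage
shares within each category and subcategory.

## Expression

**qPCR quantification** (`ddct()`) implements the 2^−ΔΔCt method with an
assumed amplification efficiency of 2 (no efficiency correction):
technical replicates are averaged first; ΔCt = Ct(target) − Ct(reference)
within each biological replicate and condition; ΔΔCt subtracts the same
replicate's calibrator ΔCt; the fold change is 2^−ΔΔCt. Means and standard
errors are taken across biological replicates only (technical replicates
measure pipetting, not biology). Pairing the calibrator within the
biological replicate makes the calibrator condition exactly 1 with zero
SE, and makes all folds invariant to any global Ct shift. Swapping the
calibrator rescales per-replicate folds exactly; the reported means
rescale exactly in the noise-free case and approximately otherwise (a mean
of ratios is not a ratio of means).

**Tissue profiles** (`tissue_profile()`) log-transform (`log2(x + 1)`),
z-score each gene row (constant rows become zero rows and are flagged
rather than NaN), and order genes by average-linkage hierarchical
clustering on Euclidean distances — a deterministic, heatmap-ready
ordering. **Tissue specificity** (`tissue_specificity()`) uses the tau
index on log-transformed values,
$\tau = \sum_i (1 - x_i/x_{\max}) / (n-1) \in [0, 1]$ (0 uniform, 1
single-tissue), with the top tissue reported and ties flagged. Tau is the
package's choice for quantifying the "tissue-specific expression" that
such studies describe qualitatively.

## Synthetic data with ground truth

Every stage is testable without downloads because the generators plant
known truth:

* `simulate_family()` / `simulate_two_species()` evolve coding sequences
  by an accept/reject single-substitution process: proposals creating
  stops are rejected, synonymous changes are always accepted,
  nonsynonymous ones with probability ω, until the count of accepted
  synonymous events per ancestral synonymous site reaches the target Ks.
  The *realized* event counts are recorded as truth, so estimator-recovery
  tests compare against what actually happened, not the target. This
  deliberately trades model elegance (no full codon-model CTMC, no
  indels, no rate heterogeneity among sites or lineages) for exactness of
  the truth record. Defaults: 500 codons; ortholog pairs split the target
  divergence evenly across the two species branches.
* `simulate_promoters()` plants consensus realizations at recorded
  non-overlapping positions on random backgrounds, and scrubs/rejects
  backgrounds until the scan count of every requested element equals the
  request exactly — planted coordinates are exhaustive truth.
* `simulate_ct()` builds Ct tables where the target's expected Ct is
  `base − log2(fold)` with Gaussian per-well noise (default sd 0.15
  cycles, a typical qPCR technical spread), 3 biological × 3 technical
  replicates; `simulate_tissue_matrix()` plants a dominant tissue per gene
  on a log-normal baseline.

What passing these tests shows — and does not show: the simulators match
the estimators' own model assumptions (that is the point: they verify the
implementations, including against independent brute-force oracles), so
recovery there does not certify behavior on real data with indels,
alignment error, rate heterogeneity, GC bias or PCR inhibition.

## Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open; on-disk tables are 1-based
  inclusive; conversion happens only at the I/O boundary.
* Sequences are upper-cased on read and RNA `U` is canonicalized to `T`.
* pI bisection: tolerance $|q| < 10^{-4}$, at most 200 halvings.
* NG86: saturated proportions (p ≥ 3/4) make the corresponding rate — and
  any ratio or date using it — undefined and flagged, never clamped.
* Zero Ks makes the ratio undefined (reported as such), not infinite.
* NJ tie-breaks are those of the underlying implementation; tests assert
  invariance of topology and total length under label permutation.
* All report precision (ratio 4 decimals, dates 2, percentages 2,
  truncated length means) mirrors the reference tables.
* Empty element-hit lists, all-zero expression rows, constant matrix rows
  and contig-edge promoters all produce defined, flagged results.

## Problem sizes used by the test and acceptance runs

Chosen as the package's own verification budget: NG86 oracle equivalence
on 50 seeded 300-codon pairs; NJ recovery on 50 random additive matrices
of 4–12 taxa; Ks recovery on 20 replicates of 500 codons at Ks 0.3,
ω 0.2; RBH recovery on 15 planted ortholog pairs plus decoys and 12
planted paralog pairs (Ks 0.1–1.3) plus decoys; promoter recovery on 14
planted element instances; ΔΔCt recovery on 20 replicates at true fold 4.
The pipeline demo uses 3 duplicate pairs of 150 codons with reduced
bootstrap (30–100 replicates) and null-calibration (100–200 shuffles)
settings.

## Known limitations

* NG86 is a counting method: no transition/transversion weighting, no
  codon-frequency bias, no ML (GY94-style) branch or site models.
* The PSSM domain scan is ungapped; it is not a profile-HMM replacement
  for remote homology.
* The element dictionary is consensus-based; PlantCARE-matrix parity on
  real genomes is out of scope by design.
* Tree inference is distance NJ only; likelihood/Bayesian methods and
  alignment construction are out of scope.
* qPCR quantification fixes amplification efficiency at 2.0.
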