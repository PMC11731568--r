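---
title: "Triangle keys: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triangle keys: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsrkeys)
```

## The model

A molecule with $n$ labeled points (C-alpha atoms of a protein chain, or
all heavy atoms of a cofactor or of a single amino acid) is represented
by the multiset of integer keys over all $\binom{n}{3}$ point triples.
For each triple:

1. **Vertex ordering.** The three vertices are ordered $(l_1, l_2, l_3)$
   by descending integer label; ties among equal labels are broken by
   descending distance to the triangle centroid, and residual ties by
   ascending input index.  Because the first two criteria are geometric
   and label-based, the ordering — and therefore every key — is
   invariant to rigid motion of the molecule and to the order in which
   atoms appear in the input file.  The input-index fallback only fires
   for triangles that are symmetric in both label and centroid distance
   (e.g. an equilateral triangle of one element), where every ordering
   yields the same key anyway.
2. **Geometry.** `MaxDist` is the longest of the three edges.  `Theta`
   is the angle at the midpoint of the $l_1$–$l_2$ edge between the
   median to $l_3$ and the half-edge towards $l_2$; an obtuse angle is
   replaced by its supplement, so $\theta \in (0^\circ, 90^\circ]$.
3. **Binning and encoding.** With $m$ labels, $n_\theta$ Theta bins and
   $n_d$ MaxDist bins, the key is the mixed radix integer
   $$\mathrm{key} = \big((l_1{-}1)m^2 + (l_2{-}1)m + (l_3{-}1)\big)
   n_\theta n_d + (\theta_{\mathrm{bin}}{-}1) n_d +
   (d_{\mathrm{bin}}{-}1),$$
   which is injective over the tuple space and inverted exactly by
   `decode_key()`.  Key integers are only meaningful relative to one
   `tsr_config()`; every key file records the configuration hash and bin
   boundaries in its header, and all pairwise comparisons refuse to mix
   hashes.  Key values from other implementations of triangle
   fingerprints are *not* reproduced: the comparable quantities are set
   relationships and counts, not absolute integers.

Two molecules are compared through their key-frequency vectors: the
**Generalized Jaccard** similarity
$\sum_k \min(f_a, f_b) / \sum_k \max(f_a, f_b)$ (frequency-aware; used
for proteins and cofactors) or the **Normalized Jaccard**
$|S_a \cap S_b| / |S_a \cup S_b|$ over the key supports (frequency-free;
used for single amino acids, whose small atom counts make frequencies
uninformative).  The Normalized variant is defined here as the plain set
Jaccard; the measure used is recorded as an attribute of every
similarity matrix.  Distances are $1 - s$; on multisets this is a true
metric, which the test suite checks on random triples.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| Theta bins | 30 equal bins over (0, 90] | degrees | upstream boundary tables are not published; equal-width bins are the neutral choice and are fully configurable, with the boundaries written into every output header |
| MaxDist bins, CA mode | 35 bins of 3 over (0, 105] | Angstrom | covers typical single-domain backbone spans; about twice the cofactor bin count |
| MaxDist bins, cofactor mode | 17 bins of 1 | Angstrom | chlorin-ring-scale resolution; the phytol tail exceeds the last boundary deliberately |
| MaxDist bins, amino-acid mode | 58 bins of 1 | Angstrom | generous upper range so every intra-residue distance falls below the last boundary |
| size-gap cutoff | off; 20 when enabled | Angstrom | drops triangles longer than the cutoff so that structures of unequal size are compared on shared-scale substructures |
| contact cutoff | 3.5 | Angstrom | conventional heavy-atom close-interaction threshold for binding-site contacts |
| jitter sigma (fixtures) | 0.05 | Angstrom | well below every bin width, so jittered copies of a template keep nearly identical keys |

Overflow policy: MaxDist beyond the last boundary falls in the last bin
(so tail-bearing cofactors remain keyable without widening the ring
scale); values at or below the first boundary fall in bin 1; a Theta of
exactly 90 degrees lands in the last Theta bin.

Vertex labels: CA mode numbers the 20 standard residues alphabetically
by three-letter code (ALA = 1 ... VAL = 20).  Cofactor and amino-acid
modes label by element: C = 1, N = 2, O = 3, S = 4, Mg = 5, P = 6,
Fe = 7; other elements must be added to `label_map` explicitly, and
unmapped atoms are dropped with a warning.  Element-level labeling is
the right granularity here because chemically equivalent atoms of a
pigment should contribute identical keys regardless of their ring
position.

The optional **grouping map** (`aa_grouping_map()`) merges residues with
similar structure and chemistry — (Asp,Glu), (Asn,Gln), (Ser,Thr),
(Lys,Arg), (Ile,Leu,Val), (Phe,Tyr,Trp) — to one label *before* vertex
ordering, which coarsens backbone keys and improves cluster recovery
when homologous chains differ in conservative substitutions.  The
membership table is configurable because published group definitions
vary; each group maps to its alphabetically first member.

The **size-gap filter** is implemented as a MaxDist cutoff on triangles
(default 20 Angstrom when enabled).  This is an interpretation: the
filter's intent is to stop large structures from accumulating long-range
triangles that small structures cannot have, and a longest-edge cutoff
is the simplest filter with exactly that effect.

## Numerical choices and degenerate inputs

* Triangles with coincident vertices (closest pair under $10^{-6}$
  Angstrom), or with the third vertex collinear with the $l_1$–$l_2$
  edge (zero-length median or $\theta < 10^{-9}$), are skipped with a
  warning; the key total then falls below $\binom{n}{3}$ by exactly the
  skipped count.
* Altloc resolution keeps the highest-occupancy conformer, ties going
  to the alphabetically first altloc code.  Multi-model files use model
  1.  Waters are flagged and excluded from key generation and residue
  contacts, but can be reported separately by the contact analysis
  (axial waters are chemically relevant to accessory-chlorophyll
  coordination).
* Hydrogens are recognised by the element field when present, else by an
  atom-name heuristic; experimental structures at the resolutions
  analysed here rarely contain any.
* UPGMA is delegated to `stats::hclust`, which is deterministic for
  tied merge candidates; heights are validated against a brute-force
  average-linkage oracle in the tests.  Classical MDS is Torgerson
  double-centering via `stats::cmdscale`; negative eigenvalues beyond
  numerical noise produce a warning that the input was not Euclidean.
* The flat cut used for scoring a dendrogram against class labels
  defaults to $k$ = the number of ground-truth classes, since no other
  cut rule is canonical.
* The two-group test is Welch's unequal-variance $t$ (the conservative
  default when only "t-test" is specified), annotated `*`/`**`/`***` at
  0.05/0.01/0.001.
* USR similarity uses the standard inverse scaled Manhattan score
  $1/(1 + \tfrac{1}{12}\sum|d_1 - d_2|)$; the third-moment descriptor is
  stored as the signed cube root of the third central moment so all
  twelve components share length units.  Population moments are used,
  with zero-variance distributions contributing 0 for both the sd and
  skew terms.
* RMSD correspondence defaults to atom-name matching (exact for
  chemically identical ligands and residues); `"order"` pairs by
  position, and a full permutation search is available up to 8 atoms as
  an oracle.  Only proper rotations are allowed, so a chiral set and its
  mirror image retain a positive RMSD.  Protein-level RMSD between
  non-identical sequences requires an external alignment tool; the
  clustering stage accepts any externally produced distance matrix in
  CSV instead.

## What the synthetic fixtures emulate

`make_toy_protein()` generates an ideal-helix C-alpha trace (rise
1.5 Angstrom, 100 degree turn, radius 2.3 Angstrom) with a repeating
GLY/ALA/TRP pattern; `make_toy_cofactor()` generates a near-planar
25-atom macrocycle (MG, four pyrrole nitrogens, twenty ring carbons)
with an optional 15-carbon tail named C6..C20 reaching beyond 20
Angstrom, so the tail filter, bin overflow and the size-gap cutoff are
all exercised.  Small deterministic ripples break the symmetry so no
triple is collinear and the $\binom{n}{3}$ invariant holds exactly.
`jitter_family()` plants families of Gaussian-perturbed copies for
clustering-recovery experiments.

These fixtures reproduce the *naming and topology* the selectors and
filters depend on, not chlorophyll chemistry: real pigments have
correlated (not isotropic) coordinate variation across species,
conformational substates, and crystallographic noise that scales with
resolution.  Passing the synthetic recovery tests therefore shows that
the pipeline is correct and discriminative under controlled noise; it
does not by itself quantify performance on experimental structures,
which additionally requires the accession-based workflow (fetching the
annotated photosystem I entries and keying the 40 annotated
chlorophylls via the packaged annotation table).

## Problem sizes used by the checks

The test suite and the acceptance script run entirely on generated
fixtures: helical traces of 4–25 residues, the 25/40-atom cofactor
fixture, 12-structure clustering problems (two families of six,
sigma = 0.05 Angstrom), a 4,500-tuple exhaustive encode/decode space,
and 1,000 random key-vector triples for the metric property.  These
sizes keep every oracle (brute-force UPGMA, pair-counting ARI,
permutation RMSD) exact while the whole suite completes in seconds.

## Known limitations

* Absolute key integers are configuration-relative and deliberately not
  comparable across implementations or configurations.
* Theta bin boundaries are equal-width by default; if the upstream
  boundary tables become available they can be supplied via
  `tsr_config(theta_bins = ...)` without code changes.
* mmCIF support is inherited from `bio3d::read.cif` and is less
  battle-tested than the PDB path; the fetcher retrieves PDB-format
  files only.
* Binding-site contact lists at 3.5 Angstrom approximate, but need not
  exactly match, manually curated interaction tables; discrepancies are
  reported rather than forced.
* The CA mode iterates all $\binom{n}{3}$ residue triples; full-length
  photosystem subunits (~750 residues) imply ~7e7 triangles and are
  compute-heavy in pure R — practical, but minutes rather than seconds.
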