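# tsrkeys

Alignment-free comparison of molecular 3D structures through integer
triangle-key fingerprints, with the photosystem I (PS I) electron-transfer
chain as the motivating application.

## The problem

The redox cofactors of PS I — the special-pair chlorophylls (P700), the
accessory (A<sub>-1</sub>) and primary-acceptor (A<sub>0</sub>)
chlorophylls, the phylloquinones (A<sub>1</sub>) and the connecting
chlorophylls (A<sub>C</sub>) — are chemically identical or near-identical
molecules whose distinct functions must come from subtle conformational
differences and from their protein environments.  Quantifying those
differences requires a structure comparison that (i) needs no alignment or
atom pre-matching, (ii) works equally for protein backbones, whole
pigments and single amino acids, and (iii) can point back from a
similarity score to the concrete substructures that cause it.

## The method

A molecule with *n* labeled points is decomposed into all C(*n*, 3)
triangles.  For each triangle the vertices are ordered by a deterministic
rule (label, then centroid distance, then input index), the longest edge
(`MaxDist`) and the midpoint angle (`Theta`, folded into (0°, 90°]) are
binned, and the tuple (l1, l2, l3, theta bin, dist bin) is packed into a
single integer:

    key = ((l1-1)·m² + (l2-1)·m + (l3-1)) · n_theta·n_dist
          + (theta_bin-1)·n_dist + (dist_bin-1)

The molecule becomes a key → frequency vector.  Three modes are provided:

* **CA** — one point per residue (C-alpha), residue-identity labels;
* **COFACTOR** — all heavy atoms of a pigment/ligand, element labels;
* **AA** — heavy atoms of one amino acid, element labels.

Structures are compared by the Generalized Jaccard similarity
Σ min(f_a, f_b) / Σ max(f_a, f_b) (or the frequency-free Normalized
Jaccard for amino acids); 1 − similarity is a metric.  Shared and
discriminating substructures are mined as *common* keys (present in every
member of a group) and *specific* keys (present in every member of one
group, absent from all contrast groups), and any key maps back to its
triangles through the triplet files.  Average-linkage clustering,
classical MDS and the adjusted Rand index score how well the fingerprints
recover functional classes; USR shape descriptors and Kabsch-superposition
RMSD are included as the standard baselines.

## Worked example

```r
library(tsrkeys)

# a 40-atom chlorophyll-like fixture: Mg + 4 N + 20 ring C + 15 tail C
model <- read_structure(make_toy_cofactor(with_tail = TRUE))
sel <- select_cofactor(model, list(pdb_id = "TOY", role = "P700_A",
                                   chain = "A", res_seq = 1011,
                                   res_name = "CLA"))
cfg  <- tsr_config("COFACTOR")       # element labels, 17 x 1 A, 30 theta bins
keys <- generate_keys(sel, cfg)
count_keys(keys$key_vector)
#> distinct    total
#>     1009     9880               # total = C(40,3): every triple keyed

# restrict to the chlorin ring by excluding tail carbons C6..C20
ring  <- filter_atoms(sel, atom_filter_preset("phytol_tail"))
rkeys <- generate_keys(ring, cfg)
count_keys(rkeys$key_vector)
#> distinct    total
#>      210     2300               # C(25,3)

generalized_jaccard(keys$key_vector, rkeys$key_vector)
#> [1] 0.2327935                   # tail triangles dominate the full set

head(keys$triplets[, c("v1", "v2", "v3", "maxdist", "theta", "key")], 3)
#>              v1            v2            v3  maxdist     theta    key
#> 1 A/CLA/1011/MG A/CLA/1011/NB A/CLA/1011/NA 2.899601 63.437428 104399
#> 2 A/CLA/1011/MG A/CLA/1011/NC A/CLA/1011/NA 4.100335  2.568532 104044
#> 3 A/CLA/1011/MG A/CLA/1011/ND A/CLA/1011/NA 2.898814 63.443468 104399
```

Each triplet row ties a key to the three atoms that formed it, so a
*specific* key found for one cofactor class can be inspected as a concrete
triangle of named atoms.

The packaged annotation table (`cofactor_annotations()`) lists chain,
residue number, residue name and axial ligand for the eight annotated
chlorophylls (P700/A<sub>-1</sub>/A<sub>0</sub>/A<sub>C</sub>, both
branches) of nine PS I structures (1JB0, 5OY0, 6HQB, 6JO6, 6KMW, 6KMX,
6PNJ, 7COY, 5ZJI); with network access `fetch_structure("1JB0")` +
`select_cofactor()` key the real pigments the same way.

A command-line interface is installed at `inst/scripts/tsr`
(subcommands `keygen`, `similarity`, `cluster`, `mds`, `keysets`, `usr`,
`rmsd`, `env`, `fixtures`, `fetch`).

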