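---
title: "Chromophore networks and energy-transfer paths in phycobilisomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromophore networks and energy-transfer paths in phycobilisomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbsnet)
```

## The analysis

Phycobilisomes (PBS) are the light-harvesting antennae of cyanobacteria and
red algae: a core of allophycocyanin (APC) cylinders with peripheral
phycocyanin (PC) rods, all of it chromophorylated with open-chain
tetrapyrroles (bilins, in cyanobacteria phycocyanobilin). Excitation
captured anywhere in the assembly migrates bilin-to-bilin and exits through
two terminal emitters in the core: the bilin of ApcD (feeding photosystem I)
and the bilin of the alpha-LCM domain of ApcE (feeding photosystem II), with
the ApcF bilin acting as the conserved bridge to alpha-LCM.

Because pairwise transfer rates fall off steeply with distance
(Förster-type, $\propto R^{-6}$), the structural question "where does the
energy go?" reduces, to first order, to a geometric one: which bilin pairs
are close, and which chains of short steps connect any given bilin to the
terminal emitters. `pbsnet` implements that analysis as a reusable pipeline
over atomic models:

1. **structure I/O** — read mmCIF/PDB, separate polymer chains from ligand
   groups, attach subunit roles (ApcA/ApcB/ApcD/ApcE/ApcF/ApcC, CpcA/CpcB,
   linkers) and core/rod region labels from a user-confirmed config;
2. **chromophore model** — extract bilins by chemical-component code,
   partition atoms into pyrrole rings A–D and methine bridges from the atom
   nomenclature, define the conjugated set, and compute distances under
   explicit metrics;
3. **EET network** — all-pairs distances, edges at or below a cutoff,
   shortest / k-shortest / bottleneck paths to the terminal emitters;
4. **microenvironment** — residue shells around each bilin with geometric
   π–π and cation–π classification, and aromatic censuses;
5. **array analysis** — rigid-body placements of whole PBS copies and
   inter-complex bilin contacts;
6. **synthetic fixtures** — a deterministic generator of toy assemblies
   with planted geometry, used throughout the test suite.

## Distance metrics

The literature rarely states which atom convention produced a printed
bilin–bilin distance. Three metrics are therefore first-class and every
report records which one was used:

* `min_conjugated_atom` (default): minimum heavy-atom distance between the
  two conjugated ring systems (rings A–D plus methine bridges). This is the
  default because transfer couples the conjugated π systems and the metric
  is insensitive to propionate/side-chain conformers.
* `min_any_atom`: minimum over all heavy atoms. Always ≤ the conjugated
  minimum (it minimises over a superset of pairs).
* `centroid`: conjugated-centroid to conjugated-centroid. The only one of
  the three that satisfies the triangle inequality; the min-atom metrics do
  not, which matters if you feed these distances to anything that assumes a
  metric space.

All distances are heavy-atom only (deposited cryo-EM models carry no
hydrogens) and use author residue numbering, the numbering in which
published residue callouts (Tyr88, Arg77, ...) are expressed.

## The path objective

"Most probable path" is not a single well-defined object when all one has
is geometry, so three objectives are implemented:

* **additive distance** — minimise the summed step length;
* **additive distance⁶** (default) — minimise $\sum_i d_i^6$, the
  Förster-motivated reading in which one long hop can cost more than many
  short ones. A direct hop of length $d$ beats a two-hop relay exactly when
  both relay hops exceed $d\cdot 2^{-1/6}$;
* **bottleneck** — minimise the longest single hop (minimax), the reading
  in which the weakest link limits the route.

All three are exposed (`eet_shortest_path()`, `eet_k_shortest_paths()`,
`eet_bottleneck_path()`) and the emitter report can be generated under any
of them; defaulting to distance⁶ reproduces nearest-neighbour stepping
while keeping the literal shortest-total reading available. Paths are
simple (loopless); no kinetic model, rate constant or directionality is
implied. Tie-breaking is everywhere deterministic: among equal-weight
optima the lexicographically smallest node-id sequence wins (for the
bottleneck objective: bottleneck, then total weight, then lexicographic).
The k-shortest enumeration is Yen's algorithm built on the same
deterministic subroutine, so its output is reproducible run to run.

The default edge cutoff is 40 Å — the permissive bound under which
bilin-pair transfer between stacked complexes is still entertained in the
array literature. It is a connectivity ceiling, not a physical rate
threshold; for path deduction within a core the results are insensitive to
anything above the typical ~20–30 Å nearest-neighbour spacing.

## Interaction geometry

π–π and cation–π assignments are purely geometric, with thresholds from
common structural-biology practice, configurable and echoed in every
record: parallel stacking at ring-centroid distance ≤ 5.5 Å and
interplanar angle < 30°; T-shaped at ≤ 6.0 Å and > 60°; cation–π when the
cationic-group centroid (Arg guanidinium heavy atoms or Lys NZ) is within
6.0 Å of a ring centroid. Ring planes are principal-plane fits (the
smallest-variance axis is the normal), since bilin pyrrole rings are
near-planar but not idealised; the interplanar angle is folded to [0°, 90°].
His is counted as aromatic; protonation is ignored. No energetic scoring is
attempted — a `pi_pi_parallel` label is a geometric statement only.

One documented discrepancy: the mutagenesis literature around the ApcF
bilin refers to the same residue both as Phe60 (text numbering) and F66
(one figure label); this package follows the text numbering (Phe60/Phe79)
in its deposited-model checks.

## The synthetic generator and what it does (not) show

`make_assembly()` builds assemblies from toy chromophores: four regular
pentagons named with bilin nomenclature (`NA`, `C1A`...`C4D`, bridges
`CHB`/`CHC`/`CHD`), ring centres 3 Å apart, ~12 Å span, under the
fictitious component code `TBL` so real chemistry is never shadowed. Each
toy bilin gets a parent chain holding one cysteine whose SG sits 1.9 Å from
ring A — a covalent-anchor mimic that also exercises the
nearest-polymer-chain parent assignment. Decoy residues (Tyr/Phe/Trp/His/
Arg/Lys/Ala) are idealised side-chain templates placed so the realised
minimum side-chain-to-target distance equals the requested one exactly;
requests below a 2.5 Å steric floor are rejected. Jitter, when requested,
displaces every atom by an independent uniform vector inside a ball of
radius `jitter`, which bounds every realised distance change by
2·`jitter` — a guarantee per-coordinate noise would not give.

`plant_path()` places a chromophore chain on a circular arc with
consecutive spacing `step` and all non-consecutive pairs beyond the
cutoff, and verifies that claim by enumeration on the re-read file. One
geometric fact shapes its interface: by the triangle inequality a
second-nearest neighbour can never be farther than `2*step`, so a planted
chain with strict non-consecutive separation exists only when
`cutoff < 2*step` (less the ~2.4 Å in-plane atom extent of the toys).
Requests like `step = 20, cutoff = 40` are therefore rejected as
infeasible rather than silently fudged; the packaged tests plant at
`step = 20, cutoff = 35`. The chromophores stand perpendicular to the arc
plane so that atom extent cannot create shortcut edges.

What passing these tests shows: the extraction, metrics, graph
construction, path algorithms and shell searches are correct on geometry
that is fully known. What it does not show: anything about real APC/PC
folds, bilin conformers (the toys are planar and symmetric), deposition
quirks (altlocs, insertion codes, microheterogeneity), or the biological
adequacy of a 40 Å cutoff. Deposited-model checks exist for exactly that
reason (`deposited_model_report()`), and run whenever the user supplies
local copies of the deposited PBS coordinate files plus a confirmed
annotation — the package ships an annotation *template*, not a derived
chain map, because depositions do not encode cylinder/layer/rod labels and
the mapping must be confirmed against each entry once.

## Numerical choices and degenerate inputs

* Alternate locations: highest occupancy wins, ties by file order. Only
  model 1 of a multi-model file is used unless another is requested.
* Assembly dimensions are sorted extents along the principal axes of the
  atom cloud; fewer than three non-collinear atoms is an error, and the
  extents are rigid-motion invariant to well below 1e-3 Å.
* Path optimality certificates use a 1e-9 relative tolerance when walking
  the shortest-path DAG, so floating-point ties collapse deterministically.
* Comparisons against values printed at fixed precision use round-half-up
  at the printed precision (`round_half_up()`): 4.6 Å "rounds to 5".
* Empty selections fail loudly (a Gly under the side-chain-only selection,
  a ring label absent from a degenerate chromophore), never silently.
* Problem sizes in the packaged tests: 100 random graphs of ≤ 8 nodes for
  the exhaustive path oracles, 100 planted-path seeds, 20-atom-pair
  brute-force distance checks, three-bilin reference fixtures — sizes at
  which every expected value can be recomputed from scratch in seconds.

## Known limitations

* Parent-subunit assignment is by heavy-atom proximity, not `struct_conn`
  records (these are inconsistently deposited); a bilin exactly between two
  chains could in principle be mis-assigned, though 1.9 Å thioether
  geometry makes this unlikely in practice.
* The auto-annotation draft (`auto_annotate()`) uses chain length and bilin
  count only; it cannot distinguish ApcA from ApcD, or ApcB from ApcF —
  that distinction requires sequence, which is out of scope, so the draft
  must be confirmed by the user.
* Rigid-body placements for array analysis are consumed, not derived: no
  density fitting is performed, so quantitative inter-complex distances are
  only as good as the supplied transforms.
* No exciton kinetics, transition dipoles, or spectra; the network is
  undirected and unweighted by energetics.
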