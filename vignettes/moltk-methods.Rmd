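---
title: "moltk: data model, algorithms and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{moltk: data model, algorithms and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moltk)
```

## Scope and intent

moltk covers the everyday operations of structural molecular modelling —
file I/O, selections, rigid-body motion, superposition, clash and contact
analysis — in plain R with no compiled code. It is deliberately *not* a
full MD-analysis stack: no force fields, no periodic boundary conditions,
no binary trajectory formats, no torsion-space manipulation. The design
premise is that a small, dependency-free toolkit with exactly specified
semantics is more useful for scripting and for embedding in other tools
than a large framework.

## The data model

A `Molecule` is a columnar atom table plus an ordered list of coordinate
frames, each an `n_atoms x 3` matrix in Ångström. Two conventions matter
everywhere:

* **Atom identity is the 1-based row index.** PDB serials are carried
  verbatim but never used as keys: real-world files repeat serials, leave
  gaps, and overflow the 5-column field. Selections, bond graphs,
  pairings and footprint results all speak row indices.
* **Value semantics.** R copies on modify, so every manipulation function
  returns the modified molecule and `get_frame()` is trivially a defensive
  copy; nothing mutates behind the caller's back. (An in-place API with a
  copy opt-out, natural in reference-semantics languages, would be
  unidiomatic here.)

Frames are indexed 1-based; negative indices count from the end
(`get_frame(mol, -1)` is the last frame), which keeps trajectory tail
access convenient without a length lookup.

Alt-loc conformers are kept, not deduplicated: the `alt_loc` column is
exposed so users can filter with `select_atoms(mol, list(alt_loc =
c("", "A")))` when they want a single conformer. Deduplicating silently
would hide occupancy-weighted detail that some analyses need.

## File formats

**PDB** parsing is strict fixed-column (v3.3): serial 7–11, name 13–16,
altLoc 17, resName 18–20, chainID 22, resSeq 23–26, iCode 27, x/y/z
31–38/39–46/47–54, occupancy 55–60, B-factor 61–66, element 77–78, charge
79–80. `MODEL`/`ENDMDL` blocks become frames; the first block defines the
topology and later blocks must match its atom count exactly (a mismatch is
an error, not a warning — trajectory frames that disagree on atom count
are almost always a concatenation bug upstream). Parsing tolerates CRLF
endings and trailing whitespace. Writing renders coordinates at 3 decimals
and occupancy/B-factor at 2; a coordinate that cannot fit the 8-column
field (≥ 10000 or ≤ −1000 Å) raises an error rather than corrupting the
column grid.

When the element column is blank, the element is inferred from the atom
name using the PDB justification convention: names starting in the first
column of the name field with a recognized two-letter prefix are
two-letter elements (`"CA  "` is calcium), otherwise the first alphabetic
character after stripping digits and primes wins (`" CA "` is a C-alpha
carbon, `"1HB "` is hydrogen). This reproduces the convention without a
chemistry perception engine.

Charges are stored as signed reals. The PDB `2+`/`1-` style is parsed on
read and re-rendered on write; non-integer charges are not representable
in the two-column field and render blank. `CONECT` records are ignored on
read and never written: bonds in this package always come from the
distance rule, which keeps the bond graph reproducible from coordinates
alone.

**PDBQT** is parsed as PDB except columns 67–76 hold the partial charge
and 78–79 the AutoDock atom type. Types are mapped to elements through a
bundled AutoDock-type table (`OA -> O`, `HD -> H`, ...); unmapped types
keep their verbatim string in the `autodock_type` column and fall back to
name-based element inference. Torsion-tree records
(`ROOT`/`BRANCH`/`ENDBRANCH`/`TORSDOF`) are preserved in `remarks` in
order. Writing PDBQT is out of scope.

**PYM** is the package's binary columnar container, built for fast,
lossless round trips: a 15-byte header (`PYM1` magic, version, atom and
frame counts, column flags), offset-indexed UTF-8 string columns, 64-bit
integer columns, IEEE-754 binary64 real columns, and contiguous
atom-major coordinate blocks, all little-endian. A columnar layout was
chosen because loading dominates high-throughput workloads and block
reads of homogeneous arrays are the fastest thing an interpreted reader
can do. Round trips are bit-exact — unlike PDB text, which truncates
coordinates at 3 decimals. The container is generalized to `n_frames ≥ 1`
(nothing in the layout forces a single frame). One layout note: the
element column is serialized as a seventh string column so that the
bit-exact round-trip guarantee covers the full atom table. R lacks a
native int64, so 64-bit integers are encoded as two 32-bit words; this is
exact for |x| < 2^53, far beyond any serial number.

## Bond perception

Atoms `i < j` are bonded iff

```
min_dist < d(i, j) <= r_cov(element_i) + r_cov(element_j) + tolerance
```

with single-bond covalent radii from the Cordero 2008 compilation
(H–Rn; the high-spin values are used for Mn/Fe/Co, the common choice in
cheminformatics toolkits). Defaults: `tolerance = 0.4 Å` — the
conventional perception slack, large enough to absorb thermal stretching,
small enough not to bridge 1–3 neighbours at typical geometries — and
`min_dist = 0.4 Å`, which suppresses spurious bonds between duplicated or
overlapping atoms (common in modelling intermediates). Unknown elements
get a 0.77 Å carbon-like fallback radius with a classed warning. There is
no valence capping: the rule is purely geometric, and anything more would
be chemistry perception beyond this package's scope. Bonds are computed on
one stated frame (default the first), never averaged.

Two code paths exist and are tested to agree exactly: a reference
all-pairs scan and a cell-list grid (`method = "grid"`) that only compares
atoms in adjacent cells of edge `2 * max(radius) + tolerance`. The grid
path is selected automatically above 400 atoms.

## Selections

Property criteria are per-column constraints combined by AND: value sets
for text/integer columns (matched exactly after whitespace trim,
case-sensitive — names are case-normalized upstream on read) and closed
intervals for real columns. A full boolean expression language is out of
scope; compose `select_atoms` results with the set algebra instead.

All spatial predicates use **closed balls** (`d ≤ cutoff`), stated once
here and applied uniformly — this makes "within 3 Å" inclusive in the
footprint, clash and near-selection operations, and it is what the
brute-force oracles in the test suite implement. Near-selection excludes
the seed selection by default (`include_sel = TRUE` keeps it); the
exclusion is a deliberate choice, since "atoms near my selection" almost
always means *other* atoms.

## Rigid-body manipulation

Euler rotations use the **extrinsic X-then-Y-then-Z** convention,
`R = Rz(az) Ry(ay) Rx(ax)`, with right-handed rotations about the fixed
axes; the convention is documented and pinned by closed-form quarter-turn
tests. Line rotations use the Rodrigues formula about the axis through
`p1` toward `p2`; an axis shorter than 1e-9 Å is rejected as degenerate.
Angles are radians in the API (the CLI accepts `--degrees`) — mixing
units silently is the classic rotation bug, so the library speaks one
unit only.

For atom-pivot rotations applied to all frames, the pivot is looked up
**per frame** (each frame rotates about the atom's position in that
frame); `pivot_frame` pins it to one frame when a common pivot is wanted.
Per-frame pivots were chosen because the atom, not a point in space, is
the user's stated pivot.

## Superposition and RMSD

`rmsd()` is the plain root-mean-square deviation over an explicit atom
pairing, with no fitting. `align_other_to_this()` performs Kabsch
superposition: center both paired sets, SVD of the cross-covariance,
determinant correction to exclude reflections (molecules are chiral — an
improper rotation can produce a smaller RMSD and a physically meaningless
pose). The transform is fitted on the paired atoms of the stated frames
but applied to *all* atoms and frames of the moving molecule, which is
what model-building workflows (align a domain, carry its ligands along)
need. With fewer than 3 non-collinear pairs the minimizer is not unique;
the SVD's minimizer is used as-is and the limitation is documented rather
than guessed around.

The pairing heuristic keys atoms on `(chain, resseq, insertion_code,
name)`; keys duplicated on either side are dropped entirely (both copies),
since guessing which duplicate corresponds would be silent error. It is
isolated in `pairing_heuristic()` so other schemes can be swapped in.

Minimum inter-molecule distance is defined as the minimum over cross
pairs — the definition consistent with clash detection — with
`mode = "centroid"` exposed for the center-to-center alternative.

## Contact footprints

For two disjoint domain selections A and B of a trajectory, each atom of A
counts the frames in which its minimum distance to B is ≤ cutoff (default
3.0 Å), and symmetrically; fractions are counts divided by `n_frames`, so
`fraction * n_frames` is always integral. Fractions are stored at
**atom** level because contact persistence is an atomic property; a
residue aggregation (`residue_contact_persistence`) is provided with
max-over-atoms as the default rule (a residue touches when any of its
atoms does) and mean as the alternative — the aggregation rule is a
documented choice, not a hidden constant.

`annotate_occupancy()` writes the fractions, rounded to the 2-decimal PDB
field precision, into the occupancy column of a single-frame copy — the
standard trick for coloring surfaces by a computed quantity in molecular
viewers. Occupancy holds the **fraction** 0.00–1.00 by default: PDB
occupancy is conventionally ≤ 1. `percent = TRUE` stores 0–100 instead
(the 6-column field renders `100.00` exactly) for viewers whose color
ramps expect percentages.

## Synthetic data

The generators state a small, fully analyzable world:

* `make_chain(n, spacing, chain)` — a collinear N/CA/C backbone at fixed
  spacing (default 1.5 Å, a typical covalent bond length, chosen so that
  consecutive atoms bond under the perception rule and the expected bond
  graph is a path graph known in advance).
* `make_two_domain_trajectory(schedule)` — two single-atom domains whose
  inter-domain gap follows the given per-frame schedule. Feeding the gap
  schedule directly makes every footprint expectation analytic: with
  cutoff c the residence fraction is exactly `mean(schedule <= c)`. The
  canonical fixture `c(2.0, 2.5, 2.9, 5.0)` with cutoff 3.0 forces
  fraction 0.75.
* `make_random_molecule(n, seed, ...)` — uniform coordinates in a 20 Å
  box, names/elements drawn from a small realistic alphabet (C/N/O/S/P/H
  plus an Fe HETATM case), occupancy/B-factor as multiples of 0.01 and
  integer charges so a PDB round trip is column-exact. Generators are
  pure: the seed is threaded explicitly and the session RNG stream is
  restored afterwards.

What the generators do **not** emulate: real protein geometry (sidechains,
secondary structure), element frequencies, correlated thermal motion, or
solvent. A green test therefore establishes that the *operations* are
correct against their definitions and oracles — not that any biological
conclusion drawn from a real trajectory is right.

## Numerical choices

* Closed-ball comparisons everywhere (`<=`), including the bond rule's
  upper bound; the lower bound is strict (`>`).
* PDB write precision: 3 decimals for coordinates, hence round trips are
  tested at 5e-4 Å (half an ulp of the text format); PYM round trips at
  exactly 0.
* Rotation identities (composition, inverse, distance preservation) are
  tested at 1e-9; closed-form quarter turns at 1e-12; Kabsch recovery of
  exact rigid motions at 1e-8.
* Ties and degenerate inputs: coincident atoms never bond (min_dist),
  empty selections are legal values but empty *required* selections are
  errors, zero-length rotation axes are errors, and a cutoff of 0 is
  rejected everywhere a cutoff is required.

## Known limitations

* The PDB writer emits no `TER` records and wraps serials above 99999
  modulo 100000 (the field is 5 columns); row order, not serials, is
  identity.
* Non-integer formal charges cannot round-trip through PDB text (the
  field has no decimal syntax); they survive PYM exactly.
* The grid spatial path is an acceleration of identical semantics, not an
  asymptotic guarantee: heavily clustered inputs can still degenerate to
  quadratic candidate sets.
* `pairing_heuristic` requires exact key equality; it will not pair
  renamed atoms or renumbered residues (sequence-alignment-driven pairing
  is deliberately out of scope).
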