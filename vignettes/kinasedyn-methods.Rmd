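---
title: "kinasedyn: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{kinasedyn: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinasedyn)
```

# The analysis scheme

Kinase regulation is conformational: the position of the activation
segment, the αC-helix and the lobe-lobe geometry decide whether the enzyme
is active. Some MAP kinase kinases adopt an unusual autoinhibited state in
which part of the activation segment folds into a protruding α-helix
(the activation segment helix, ASH), and the interesting dynamical
questions — does phosphorylation destabilise that helix? is the state
stabilised by dimerisation? — reduce to a small set of geometric
statistics over multi-replica, microsecond MD ensembles. `kinasedyn`
implements that statistic set as a tested package:

* a **cog apex angle** θ(ASH, hinge, αC) measuring ASH bending against the
  stable kinase core,
* **inter-subunit cog distances** for a dimer interface (N-lobe, ASH,
  αF-helix triad plus N-lobe sub-intervals),
* **RMSF/RMSD** with replica aggregation,
* a single **cross-system PCA** on a shared backbone selection,
* **contact detectors** (salt bridge, hydrophobic, hydrogen bond, water
  bridge, π-π) with frequency and replica-persistence summaries,
* **%SSE** helix occupancy per residue interval.

Angles are reported in degrees, distances/RMSF/RMSD in nm (coordinates are
kept in Å internally, the native PDB unit; conversion happens only at the
reporting boundary). Author (PDB) residue numbering is preserved
throughout, because every interval of interest is quoted in author
numbers; nothing is ever re-indexed.

# Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| ASH interval | 250–264 | residues | one angle ray; the autoinhibited helix |
| αC interval | 139–154 | residues | second ray; stable reference helix |
| hinge interval | 179–182 | residues | angle vertex between the lobes |
| equilibration cutoff | 250 | ns | initial stabilisation window excluded; the frame at exactly the cutoff is kept (boundary rule `time_ns >= cutoff`) |
| salt-bridge cutoff | 4.0 | Å | common tool default for N⁺–O⁻ contact |
| hydrophobic cutoff | 2.5 | Å (strict `<`) | side-chain atom criterion; hydrogens participate by default because a 2.5 Å heavy-atom pair would be a near-clash (flag to restrict) |
| H-bond | 3.5 Å, ≥110° | | donor–acceptor heavy distance plus donor–H–acceptor angle; the angular term is skipped when no hydrogens exist (configurable) |
| replica persistence | >30 | % frames (strict) | heatmap counts replicas above threshold |
| reporting spread | >20 | points (strict) | cross-system tables keep discriminating contacts only; 0 disables |
| PC retention | >9 | % variance (strict) | individual-contribution rule |

The angle uses *all* atoms of each interval (`atom_subset = "all"`). The
atom subset is configurable; no published convention pins it, so the
crystal-reference acceptance test (below) pins the default. The cog is
unweighted by construction — it is a centre of geometry, not of mass.

The interval-shift validation slides the ASH window inside itself:
negative shifts truncate the C-terminal end (250–264 → 250–259 at −5),
positive shifts the N-terminal end (→ 255–264 at +5), and the deviation
`angle(shifted) − angle(reference)` is reported per frame. On the crystal
geometry the N-truncated window sits 1–2° below the reference and the
C-window 1–2° above it, which is the package's sign convention.

# Numerical choices

* **Angle**: the cosine is clamped to [−1, 1] before `acos`; coincident
  cogs (ray norm < 1e-9 Å) raise a degenerate-geometry error rather than
  returning NaN.
* **Superposition**: Kabsch via SVD with the determinant sign correction;
  fewer than 3 fit atoms, or collinear fit atoms, raise an
  underdetermined-fit error. The test suite checks it against an
  independent Horn-quaternion implementation.
* **RMSF reference**: each replica's frames are superposed on the replica
  mean structure obtained by one re-fit iteration (fit to frame 1 →
  average → re-fit the originals to that mean). Tool defaults differ here
  and are rarely documented; the closed-form jitter test (RMSF → σ√3 for
  isotropic Gaussian displacement) is insensitive to the choice at large
  atom counts, which is why it can pin the implementation without pinning
  the convention.
* **PCA**: population (1/N) covariance normalisation, so the score
  variance of the fitting ensemble along PC *k* equals eigenvalue *k*
  exactly — an identity the tests assert numerically. No mass weighting.
  Frames are fitted to the pooled mean with the same one-iteration re-fit.
  Pooling all retained frames of all systems (rather than subsampling) is
  a deliberate choice; the planted-spectrum test is agnostic to it.
* **Quantiles**: linear interpolation between order statistics
  (`stats::quantile` type 7, the convention of the common plotting
  stacks). Whiskers reach the most extreme data point within 1.5·IQR of
  the quartiles; outliers are strictly beyond.
* **Boxplot pooling**: all frames of all replicas of a system are
  concatenated before summarising (pooled, not averaged-then-summarised).
* **Secondary structure**: the classic electrostatic H-bond energy with
  q₁q₂ = 0.084·332 ≈ 27.9 kcal·Å/mol and the −0.5 kcal/mol cutoff; amide
  hydrogens are reconstructed at 1.01 Å along the C(i−1)–N–CA bisector
  when absent; prolines and chain starts never donate. Helix pools the
  α (two consecutive i→i+4 turns) and 3₁₀ (two consecutive i→i+3 turns)
  patterns; strand uses the parallel/antiparallel bridge patterns. The
  upstream tool this mirrors does not publish its rule, so a transparent
  DSSP-style algorithm was adopted instead.

# The synthetic world

The original study's ~40 μs of trajectories were not deposited, so the
package ships generators that emulate the *geometry* of the phenomena —
never the physics — with exact, separately-returned ground truth:

* **Hinged pseudo-kinase** (`make_hinged_trajectory`): ideal-helix
  segments at the canonical residue numbers; the ASH body is rotated
  rigidly about an axis through the hinge cog so the measured apex angle
  equals a planted Ornstein–Uhlenbeck path frame by frame. Defaults
  (θ₀ = 40°, reversion 0.5 /ns, noise 2 °/√ns, 1500 frames at 1 ns)
  emulate sustained fluctuation around a shifted mean, the observed
  phenomenology of ASH bending; θ₀ sits in the middle of the reported
  per-system angle ranges.
* **Toy dimer** (`make_dimer_trajectory`): subunit B is subunit A rotated
  180° about the interface axis, so the zero-schedule dimer is exactly
  symmetric and static. The twist/translation axis passes through both
  N-lobe cogs while the ASH cogs sit at equal x on opposite sides of it.
  Consequently translation moves the N-lobe distance one-for-one, twist
  leaves it unchanged, and the ASH distance responds to translation only
  at second order — `sqrt(L² + d²) − L`, asserted in closed form rather
  than with a loose "unchanged" band, since exact invariance of a
  Euclidean distance under translation is geometrically impossible.
  This reproduces the core argument for using both metric families:
  distances see translation, angles see rotation.
* **Bernoulli contact pair** (`make_contact_trajectory`): a Lys/Glu pair
  toggled between 3.0 Å (inside the 4.0 Å cutoff) and 6.0 Å by seeded
  draws; a correct detector must reproduce the realized draw vector
  *exactly*, not just its frequency.
* **Jitter replicas** (`make_jitter_replicas`): isotropic Gaussian
  displacement of a rigid body, for which per-atom RMSF has the closed
  form σ√3 (0.0866 nm at σ = 0.5 Å).

All generators are bit-reproducible from (parameters, seed), and ground
truth travels in a side channel so no analysis can read it from the
trajectory.

What a green synthetic test does **not** establish: correctness on real
force-field ensembles (anharmonicity, correlated motions, solvent
effects), PBC/imaging artefacts (the package assumes whole, imaged
molecules), or the behaviour of the contact detectors on real rotamer
distributions. The crystal-reference tests cover real coordinates; see
limitations.

# Design decisions that were genuinely open

* **Frame→ns mapping is mandatory metadata.** Trajectory files do not
  carry a trustworthy clock and the upstream frame-saving stride is
  unstated, so `read_trajectory` refuses to guess.
* **Alternate locations / insertion codes**: highest-occupancy conformer
  kept; insertion codes rejected with a clear error (none occur in the
  intervals this scheme targets).
* **Salt-bridge atom sets** follow the common convention (Lys NZ, Arg
  NE/NH1/NH2, His ND1/NE2 vs Asp OD1/OD2, Glu OE1/OE2, phospho-Ser/Thr
  phosphate oxygens under both O1P/OP1 naming variants); His counts as a
  potential donor and the sets are configurable.
* **π-π criterion** (ring-centroid ≤ 5.5 Å with near-parallel ≤30° or
  T-shaped 60–90° plane angle) is the field's usual geometric definition;
  no criterion is published for the analysis this mirrors.
* **XTC is not read.** The xdrfile compression codec has no R
  implementation in the supported dependency set and hand-rolling it is
  out of proportion to its role; PDB (single/multi-model) and DCD are
  fully supported with round-trip tests.
* **Monomer reference angle** is the subunit-A crystal value; dimer
  reports use per-subunit references (the two published renderings of the
  subunit-B reference, 17.9° vs 17.34°, both lie inside the ±1° band the
  package tests against; the package reports its computed value and does
  not arbitrate).

# Verification layout

Every operation is tested against an independent oracle: brute-force
summation for cogs, the law of cosines for angles, Horn's quaternion
method for superposition, sort-based quantiles for boxplots, all-pairs
minima for contact detectors, an analytic spectrum for PCA, σ√3 for RMSF,
and biotite's P-SEA implementation (via the pre-installed Python stack)
for secondary structure. The P-SEA comparison runs on two *synthetic*
canonical structures built by the package's own peptide builder — a long
α-helix and a helix-loop-helix — because no real deposited structure can
be fetched in an offline environment; agreement is required at ≥85%
per residue, the same bar that would apply to real structures.

Three acceptance tests (the apex angle of each crystal subunit, 14.9° and
17.9° within ±1°, and the interval-shift signs) require the actual
crystal structure of the autoinhibited dimer (PDB 3alo). The entry cannot
be redistributed inside the package and cannot be downloaded where the
suite runs, so these tests fail with an explanatory message rather than
being skipped or faked; supplying `inst/extdata/3alo.pdb` activates them.
The ±1° tolerance reflects that published reference values were computed
from a prepared "frame 0" (capped termini, rebuilt loop), not the raw PDB
coordinates.

# Known limitations

* No trajectory imaging/PBC handling; inputs must be whole molecules.
* No mass-weighted variants of cog, RMSF or PCA (deliberate: the scheme
  is defined on geometry).
* DCD is read/written in native little-endian byte order only.
* The DSSP-style assigner labels only {helix, strand, other}; π-helices,
  bends and turns fold into "other".
* Interface energetics (ΔG of assembly/dissociation) are out of scope;
  the package measures geometry, not thermodynamics.
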