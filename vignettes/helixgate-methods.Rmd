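---
title: "Methods: helix twist, ligand engagement and ensemble analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: helix twist, ligand engagement and ensemble analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixgate)
```

# The scientific problem

Transporters of the APC (amino acid-polyamine-organocation) superfamily
carry their substrate in a pocket formed by the discontinuous middles of
transmembrane helices 1 and 6. In several members the break in TM1 is
not constitutive: the helix is continuous in the apo outward-open state
and unwinds at a conserved di-glycine (GAG-like) motif when the
substrate's carboxylate engages the exposed backbone amides. Molecular
dynamics is the natural instrument for watching this transition, and a
small set of quantitative summaries recurs across such studies:

* a **local helical twist map** that localises where and when the helix
  departs from ideal geometry,
* **ligand-engagement series** (hydrogen-bond occupancy, minimum
  ligand-helix distance) with a categorical **binding fate** per
  replica,
* per-residue **interaction fingerprints** averaged over replicates,
* **pooled PCA** of the ensemble, used for example to show that a
  flexible extracellular loop's flip-in/flip-out motion dominates the
  variance,
* **gromos-style RMSD clustering** with a cluster-median representative
  used to seed further simulations, and
* static-structure measurements (C-alpha RMSD between conformational
  states, binding-site shells, contact distances, sequence
  identity/similarity).

`helixgate` implements this analysis chain as plain R functions, and
pairs it with seeded synthetic-trajectory generators whose ground truth
is known exactly, so that every stage can be validated end to end
without gigabyte-scale trajectories.

# Local twist and the deviation map

The local twist at a C-alpha window follows the HELANAL idea of
measuring helix geometry from C-alpha atoms alone. For four consecutive
C-alphas $p_1 \dots p_4$ the two angle-bisector vectors

$$b_2 = (p_1 - p_2) + (p_3 - p_2), \qquad b_3 = (p_2 - p_3) + (p_4 - p_3)$$

are radial in an exact circular helix, so the angle between them equals
the per-residue rotation: $100^\circ$ for ideal alpha-helical geometry.
`local_twist()` returns $\theta = \arccos(\hat b_2 \cdot \hat b_3)$ in
degrees; `twist_map()` slides the window along a selection in every
frame, and the deviation is $\Delta\theta = \theta - \theta_{\rm ref}$
with $\theta_{\rm ref} = 100^\circ$ by default.

Numerical choices:

* **Window-to-residue assignment.** The angle from window
  $(i, i+1, i+2, i+3)$ is assigned to residue $i+1$, the residue whose
  bisector opens the angle. This is a convention, not a law; set
  `assign = "third"` to carry it on $i+2$. Either way the first and
  last residues of a selection carry no value.
* **Wrapping.** $\Delta\theta$ is wrapped into $(-180, 180]$. With a
  $100^\circ$ reference and $\theta \in [0, 180]$ wrapping never
  actually fires, but it keeps the quantity well defined for
  non-default references. Windows are never masked after large
  distortions: a broken helix simply reports its (large) deviation,
  which is the signal of interest.
* **Degeneracy.** Bisector norms below $10^{-6}$ Å (collinear or
  coincident points) raise an error rather than returning a silent
  angle; this tolerance is far below physical coordinate noise.
* **Integration.** `integrate_deviation()` uses the rectangle rule,
  $\sum_t |\Delta\theta| \, \Delta t$, reported in degree-microseconds.
  With uniformly sampled frames (the generators default to 50 ps) the
  rectangle rule *is* the per-frame sum the quantity is defined as;
  non-uniform frame times are rejected.

`build_helix_backbone()` provides an independent reference geometry: an
N-CA-C backbone built from standard bond lengths and angles with
repeating dihedrals ($\phi = -57.8^\circ$, $\psi = -47.0^\circ$,
$\omega = 180^\circ$). Its measured local twist is uniform at
$98.85^\circ$ — within about a degree of the canonical $100^\circ$ —
which is a useful reminder that "ideal alpha-helix" is itself a
convention with roughly a degree of slack depending on the chosen
internal coordinates.

```{r twist-demo}
spec <- helix_spec(30, n_frames = 200, noise_sigma = 0)
event <- unwind_event(10:12, 87, start_frame = 50, end_frame = 149)
traj <- generate_helix_trajectory(spec, list(event))
intd <- integrate_deviation(twist_map(traj))
intd
```

# The synthetic generators and what they do (not) emulate

The generators are first-class, tested code; their defaults are the
study conditions of every downstream check.

* **Helix generator** (`generate_helix_trajectory()`): a right-handed
  circular helix, radius 2.3 Å, rise 1.5 Å per residue, base twist
  100°/residue, frames every 50 ps. An `unwind_event()` is a square
  pulse in the inter-residue twist over a step span and frame window;
  transitions are instantaneous, which makes the time-integrated
  deviation analytically predictable (duration × |twist change|).
  Noise is isotropic Gaussian per atom per frame, applied after exact
  placement, so the expected RMSF is $\sigma\sqrt{3}$ in closed form.
* **Loop-flip generator**: a rigid helix core plus a terminal loop
  displaced by a fixed vector in state-1 frames — a two-state caricature
  of a flip-in/flip-out loop. With 50 core residues at $\sigma = 0.3$ Å
  and a 10-residue loop displaced 8 Å in half the frames, the flip
  accounts for $10 \times (8/2)^2 = 160$ Å² of coordinate variance
  against $\approx 16$ Å² of noise, so the first principal component is
  expected to carry roughly 90% of the variance.
* **Engagement generator**: a 3-heavy-atom rigid pseudo-ligand (donor
  N with an explicit hydrogen, central C, carboxylate-like O) driven by
  a per-frame schedule: hydrogen-bond geometry against a motif acceptor
  when `engaged`; more than 5 Å from the motif but inside the site when
  `disengaged_in_site`; beyond the escape radius when `escaped`. Motif
  residues carry a co-located backbone-carbonyl-like O pseudo-atom so
  chemistry-aware rules (which require N/O partners) see the motif as
  they would a real helix. An optional single-atom water bridges the
  donor and its partner on its own schedule.

What the generators deliberately do **not** emulate: real force-field
dynamics, correlated (non-isotropic) fluctuations, gradual unwinding
fronts, solvent, periodic boundaries, or rotameric side-chain detail.
Passing tests therefore demonstrate that the *measurement chain* is
correct and well calibrated on data whose answer is known — not that
any particular biological system behaves this way. That division of
labour is intentional: on real trajectories the same code measures
whatever the physics produced.

# Engagement, fates and fingerprints

Hydrogen bonds use the common geometric criterion: donor-acceptor
distance ≤ 3.5 Å and D-H···A angle ≥ 130° where a hydrogen is present,
distance-only otherwise (waters are modelled hydrogen-free). Occupancy
is the percentage of frames with at least one bond, and is monotone
under relaxed criteria by construction.

`classify_binding_fate()` judges the **trailing 20% of frames** — an
end-state taxonomy, because the scientific categories ("stayed bound",
"disengaged but stayed in the site", "diffused out") describe how a
replica ends, not its average. A replica is `bound` when terminal
occupancy is at least 50%; otherwise `diffused_out` when the median
terminal centre-of-mass distance from the site centre exceeds the
escape radius (default 10 Å, matching the usual binding-site shell),
else `disengaged_in_site`. All three thresholds are arguments; the
defaults are this package's decisions, since occupancy criteria of this
kind are rarely printed in papers.

Fingerprints type contacts per residue and frame as hydrogen bond, salt
bridge (opposite formal charges within 4.5 Å), pi-cation (cationic N
within 4.5 Å of an aromatic ring centroid, axial offset ≤ 30°),
hydrophobic (apolar carbons within 4.5 Å) and water bridge. Formal
charges, ring membership and apolar carbons come from a built-in
template table covering the standard amino acids plus ornithine- and
leucine-like ligands — deliberately avoiding a chemistry-toolkit
dependency at this scale. Replicate tables are aggregated as
within-replicate frequencies with across-replicate mean and *sample*
standard deviation.

# Superposition, PCA, clustering

`kabsch_superpose()` is the SVD closed form with the determinant
correction, so reflections are never returned; rank-deficient point
sets (collinear) are an error. RMSD between frames superposes each pair
on the analysis selection by default (`fit = FALSE` gives no-fit RMSD).

`pooled_pca()` concatenates replicas, superposes every frame on a
stated core selection against the **pooled** mean (two passes), and
eigendecomposes the flattened C-alpha covariance. Using the pooled
mean rather than per-replica means is what makes a between-state motion
visible as a single component. C-alpha-only is the default selection.
`classify_loop_state()` thresholds the chosen component's projections
at the midpoint of the two dominant density modes; a unimodal
projection density (no substantial second mode, or no clear dip between
modes) produces a warning and a single label rather than an arbitrary
split.

`cluster_gromos()` is the greedy neighbour algorithm: repeatedly take
the frame with the most neighbours within the cutoff (1 Å default),
assign and remove its neighbourhood. Ties break to the lowest frame
index for determinism. The representative of the most populated
cluster is its median member — minimal mean RMSD to the other members —
the frame one would use to seed follow-up simulations.

# Structure and sequence comparison

`ca_rmsd_pair()` matches C-alphas by (chain, residue number) and
reports post-fit RMSD with the matched count; `shell_residues()` gives
the heavy-atom distance shell around a ligand; `contact_distance()` is
a minimum heavy-atom distance (hydrogens always excluded);
`state_displacement()` superposes two conformational states on a stated
scaffold selection and reports per-atom displacements. Whole-chain and
scaffold-only superposition modes are both available because published
displacement numbers are sensitive to that choice.

`pairwise_identity_similarity()` delegates the global affine-gap
alignment to Biostrings (BLOSUM62, gap open 10 / extend 0.5 by
default). Identity is identical columns over the full alignment length
including gap columns; similarity counts positive substitution scores,
identities included. Because conventions differ between alignment
programs, the shorter-sequence denominators are attached as attributes
rather than silently preferred.

# Calibration of the validation suite

Problem sizes were chosen to exercise each estimator well inside its
asymptotic regime while staying desk-scale:

* The unwinding-recovery study uses 20 random events on a 30-residue
  helix over 400 frames: spans of 3-5 twist steps, event twist 80-90°,
  durations 50-90% of the run, coordinate noise $\sigma = 0.05$ Å. At
  this noise the per-window twist noise floor is
  $E|\Delta\theta_{\rm noise}| \approx 1.4^\circ$, which enters every
  raw integral over the non-event frames; the recovered integral is
  therefore compared with duration × |twist change| as an ensemble
  (median relative error, observed ≈ 4-5%), and individual events with
  the smallest twist change and shortest duration can deviate somewhat
  more. Location recovery (argmax of the integrated deviation inside
  the seeded span) is additionally verified at the much harsher
  $\sigma = 0.2$ Å.
* Reversibility is judged on the time-averaged $|\Delta\theta|$ after
  the event window, since per-frame values fluctuate with the noise
  floor; the post-event average returns below 2°.
* The fate classifier is checked against 30 random schedules (10 per
  terminal state).
* The pooled PCA check uses the loop-flip conditions above (3 × 1000
  frames); the null check (no flip) uses 600 frames on 105
  coordinates, enough that the top sample eigenvalue of isotropic
  noise stays below three times the mean.
* Gromos clustering is compared against an exhaustive brute-force
  oracle (independent superposition code) on fixtures of at most 12
  frames, where enumeration is trivially correct.

# Known limitations

* The twist map loops in R; for trajectories of $10^5$ frames a
  compiled kernel would be the next step.
* The fingerprint template table covers standard residues and the two
  ligand archetypes it ships with; exotic ligands need template rows
  (or a chemistry toolkit upstream).
* Trajectory input covers DCD, multi-model PDB and a plain-text
  fallback; compressed binary formats beyond DCD are out of scope.
* Cross-species structure comparison by residue-number intersection
  assumes a shared numbering; use the alignment route for remote
  homologues.
* `classify_loop_state()`'s mode finding assumes the two states are
  actually sampled; strongly imbalanced schedules (< ~5% minority)
  may be called unimodal.
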