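---
title: "Calibrated FEM forward modeling and combined EEG/MEG source localization: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated FEM forward modeling and combined EEG/MEG source localization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`emegfem` implements a complete presurgical source-imaging chain on
synthetic head phantoms: geometry-adapted hexahedral finite-element (FE)
forward modeling of EEG potentials and MEG fields, combined EEG/MEG
calibration of skull conductivity, sLORETA localization of averaged
epileptiform discharges at onset and peak latencies, and export of the
localized clusters as cuboid regions of interest (ROIs) sized for a zoomed
high-resolution MR acquisition. Closed-form multilayer-sphere and Sarvas
solutions serve as independent oracles for every forward computation, so
the whole chain is verifiable on one desk-scale machine without patient
data.

# The forward model

## Head model and meshing

The head is a labeled voxel volume (`labeled_grid`); for validation we use
concentric-sphere phantoms (`sphere_spec()`), rasterized with
`voxelize_sphere_model()`. A voxel centre exactly on a shell boundary is
assigned to the region outside that boundary; this tie-break is arbitrary
but deterministic and documented.

`build_hex_mesh()` creates one trilinear hexahedral element per
nonzero-label voxel with shared nodes deduplicated, then smooths the
staircase tissue interfaces: for each node, the up-to-8 incident voxels
(with missing neighbours forming a virtual background group) are grouped by
label, and if the smallest group is unique the node moves a fraction
`node_shift_factor` of the way toward that minority group's voxel-centre
centroid. Flat interfaces (tied groups) do not move, convex and concave
staircase corners round off, and the outer surface rounds toward the
interior at its corners. The default factor of 0.33 keeps all corner
Jacobians positive (asserted after shifting; the theoretical bound used by
geometry-adapted voxel meshers is just below 0.5). Total mesh volume is
conserved to well under 0.5% at the default factor.

Conductivity is a symmetric 3x3 tensor per element, stored packed as (xx,
xy, yy, xz, yz, zz) in S/m. `assign_conductivities()` writes isotropic
tissue values; the defaults follow the tabulated seven-tissue set (scalp
0.43, skull compacta 0.0033, skull spongiosa 0.0116, dura 0.1, CSF 1.79,
GM 0.33, WM 0.14 S/m). The white-matter reference of 0.14 S/m comes from
the effective-medium literature rather than an individual calibration and
is config-exposed everywhere it is used.

## Anisotropic white matter from diffusion tensors

`map_dti_conductivity()` implements the effective-medium conversion: the
conductivity tensor of a white-matter element shares the eigenvectors of
the local diffusion tensor. Two scalings are offered because the
literature uses both. The default, volume normalization, rescales the
diffusion eigenvalues by a common factor so their product equals
`iso_reference^3`; it preserves the diffusion eigenvalue ratios and keeps
the tensor volume tissue-typical. The alternative linear mode maps mean
diffusivity to `iso_reference`. Non-positive diffusion eigenvalues are
clamped to 1e-3 of the largest eigenvalue with a warning. Element tensors
are taken from the enclosing 8 voxel centres by arithmetic mean, which
degenerates to the element's own voxel when the diffusion grid coincides
with the mesh grid (the synthetic-phantom case).

## Assembly, sources, solver

`assemble_stiffness()` integrates `grad(phi_a) . sigma grad(phi_b)` with
8-point Gauss quadrature per hexahedron (Rcpp kernel; all coordinates
converted to metres internally so potentials are volts for ampere loads).
The matrix is symmetric with the constant vector in its null space; a
reference node near the volume centre is fixed during solves and solutions
are returned mean-zero, which is gauge-safe because all read-outs
(average-referenced electrodes, magnetic flux weights) annihilate
constants.

Dipole sources use the Venant approach (`venant_rhs()`): monopole loads on
the nodes sharing an element with the node nearest the dipole, found by
Tikhonov-regularized least squares matching the scaled spatial moments up
to second order (reference length 20 mm, regularization weight 1e-6). The
zeroth moment (total charge) is enforced exactly through a Lagrange
constraint rather than through the least-squares system, so charge is
conserved to machine precision; the first moment reproduces the dipole
moment to well under 1% on a 2 mm mesh.

Linear systems are solved by conjugate gradients preconditioned with a
smoothed-aggregation algebraic multigrid V-cycle built from geometric
2x2x2 lattice aggregates: piecewise-constant prolongators smoothed by one
damped-Jacobi step (weight 4/3 divided by a power-iteration estimate of
the largest eigenvalue of `D^-1 A`), damped-Jacobi pre/post smoothing
(2 sweeps, weight 0.7), and a dense Cholesky on the coarsest level (about
1200 unknowns, with a 1e-8 relative jitter because the Galerkin product can
be numerically semidefinite — this perturbs only the preconditioner).
Default relative residual tolerance is 1e-9 with a 500-iteration cap;
the realistic four-shell contrast (scalp/skull ratio ~130) converges in
15-25 iterations at any of the mesh sizes used here.

## Transfer matrices, MEG, leadfields

`eeg_transfer()` snaps electrodes to the nearest scalp-surface node
(tolerance 10 mm) and solves one system per electrode; rows are
average-referenced across sensors and mean-centred across nodes. Both
operations leave read-outs of charge-balanced loads unchanged, and make
transfer-matrix leadfields equal direct solves to solver tolerance (1e-8
verified on toy meshes).

MEG uses the two-term split: the primary field is the analytic
Biot-Savart term of the dipole; the secondary field integrates the volume
currents `-sigma grad(u)` with one Gauss point per element into per-coil
node-weight vectors, each solved once to form the MEG transfer matrix
(`meg_transfer()`). Axial gradiometers are two-coil differences along the
baseline (default 50 mm). Output units are uV per nA.m (EEG) and fT per
nA.m (MEG). On the 2 mm four-shell sphere phantom against the analytic
oracles, tangential dipoles up to eccentricity 0.8 give EEG RDM about
0.01 with |lnMAG| about 0.08 and MEG RDM about 0.004, and radial dipoles
are magnetically silent to better than 1%.

## Source space

`build_source_space()` lays an axis-aligned grid (seeded at the
gray-matter centroid) over GM and admits a candidate only if every element
containing its nearest FE node is GM-labeled — the strict node-neighbourhood
admissibility variant required by the Venant load construction; the laxer
element-only variant is a config switch because the admissibility
neighbourhood is not uniquely pinned down in practice.

# The analytic oracles

`eeg_sphere_potential()` evaluates the Legendre series for a dipole in a
concentric isotropic multilayer sphere in a coordinate-free form: with
`x` the cosine between dipole and electrode directions, the degree-n
angular factor is `n m_r P_n(x) + P_n'(x) (m.r_hat - x m_r)`, which avoids
any azimuth bookkeeping. The per-degree radial two-point boundary problem
is solved with per-layer scaled bases (`(r/R_j)^n` and `(R_{j-1}/r)^(n+1)`)
so the linear systems stay well conditioned to high degree. The
truncation error is bounded by `(b/r_electrode)^n_terms`; the default of
80 terms is below 1e-8 up to eccentricity 0.9. The implementation is
validated against the textbook homogeneous-sphere series, the equal-
conductivity reduction, and the zero-sum property of average reference.

`meg_sarvas()` is the closed-form field outside a spherically symmetric
conductor: conductivity-independent, exactly zero for radial moments, and
checked against plain Biot-Savart for the radial field component (volume
currents contribute no radial field outside the sphere).

`topography_error()` returns the relative difference measure
`||a/||a|| - b/||b||||` (shape) and `ln(||a||/||b||)` (magnitude).

# Skull-conductivity calibration

`calibrate_skull()` runs the three-step dipole-scanning strategy per
candidate skull conductivity: (1) the source position comes from an MEG
goodness-of-fit scan (`meg_dipole_scan()`), exploiting MEG's insensitivity
to skull conductivity — across a 40x conductivity range the scanned
position moves by less than one source-space spacing on the phantom;
(2) the orientation comes from an EEG vector fit at that fixed position
(`eeg_orientation_fit()`), supplying the quasi-radial component MEG cannot
see; (3) per-modality amplitudes are fitted at the fixed position and
orientation and the candidate is scored by the squared log-ratio
`log(A_eeg/A_meg)^2`. The magnitude comparison is the essential step: MEG
amplitudes are nearly conductivity-independent while EEG amplitudes vary
strongly (0.2x to 3.3x across the default candidate grid on the phantom),
so the ratio crosses unity at the reconciling conductivity and the goal
has a sharp minimum there. A goal formed from residual variances alone
(offered as the `"residual_variance"` option) is flat once per-modality
amplitudes are free — the shape of a topography carries far less skull
information than its magnitude — and fails under realistic noise; this is
why the amplitude ratio is the default.

The candidate grid is one-dimensional in skull-compacta conductivity (12
log-spaced values over 0.0005-0.02 S/m by default), with spongiosa tied to
compacta by a fixed ratio of 3.5, matching the convention of reporting the
calibrated pair (e.g. 0.0033/0.0116 S/m). The calibration latency defaults
to the maximum of the EEG global field power, emulating the use of the
somatosensory P20/N20 component, whose generator is focal, superficial and
mainly tangential.

# Inverse solution

`average_spikes()` aligns trials on their markers and averages; the noise
level of the average is estimated per channel from the pre-onset baseline.
`combine_emeg()` divides each channel of data and leadfield by that
channel's noise standard deviation — rendering EEG and MEG dimensionless
and unit-noise-variance, hence commensurable — and stacks them. Whitening
is diagonal (white noise per channel is what the phantom simulates; real
colored noise would call for a full covariance, which the interface
accepts upstream by pre-whitening).

`sloreta()` computes the Tikhonov minimum-norm estimate and standardizes
each node's 3-vector by the corresponding 3x3 diagonal block of the
resolution-derived variance, giving a nonnegative pseudo-F per node with
the defining property of exactly zero localization error for single
noiseless sources (verified exhaustively per modality and combined). The
regularization weight defaults to `trace(L L') / (n SNR^2)` with the SNR
estimated from the whitened topography (`||b||^2/n - 1`); a fixed lambda
is available. The 3x3 standardization blocks are inverted through a
ridge-stabilized adjugate (ridge 1e-10 of the block trace) — exact in the
limit because the minimum-norm coefficients lie in the block's row space,
and robust to the rank-2 blocks that spherical MEG produces.

`threshold_clusters()` keeps nodes at or above 85% of the F maximum
(config), groups them by source-space adjacency within 1.5x the grid
spacing, and discards clusters below `min_cluster_size`. The 5-node
default minimum was chosen for fine (~2 mm) source grids; it corresponds
to less volume than a single node of the coarse desk-scale grids used in
the test workloads, which therefore pass `min_cluster_size = 1`.
`roi_box()` centres an axis-aligned cuboid (default 160 x 82 x 28 mm, the
zoomed-acquisition volume) on a cluster peak.

# The synthetic phantom as study condition

The generator reproduces the structure of the study data, not its anatomy:

* Calibration input: a fixed tangential dipole driven by a unimodal
  waveform peaking at 20 ms (sd 4 ms), mimicking the somatosensory P20/N20;
  per-trial peak-amplitude SNR is configurable and averaging n trials
  raises it by sqrt(n).
* Epileptiform input: two dipolar foci with a 23 ms propagation delay —
  the onset focus fires a biphasic double-Gaussian spike template (main
  lobe sd 9 ms, rebound 0.4 at +16 ms, ~70 ms support, centred on its
  numerical maximum) 23 ms before the peak focus. Defaults: 10 discharges
  (matching the ten MEG-marked events of the motivating recordings), equal
  ~47 nA.m moments, per-trial SNR 5 per modality.
* Noise is white and Gaussian per channel. Real interictal noise is
  colored and correlated; diagonal whitening downstream makes the white
  approximation self-consistent for these desk-scale experiments, but
  passing tests say nothing about robustness to unmodeled noise color.

Problem sizes used by the test and validation workloads, chosen once as
desk-scale renderings of the study conditions: the forward-oracle suite
runs the four-shell sphere with radii 92/86/80/78 mm at 2 mm resolution
(~408k elements); calibration and inverse Monte-Carlo workloads use a
four-shell sphere with a deliberately thick (12 mm) skull band at 5 mm
voxels so the resistive compartment stays contiguous after rasterization —
at coarser-than-study resolutions a thin skull shell voxelizes with holes,
which short-circuits the EEG and silently destroys the calibration signal.
Source grids are 10 mm for scanning/localization statistics and 5 mm for
the onset/peak dissociation workload (the study's own source resolution is
2 mm); the dissociation workload also uses the full clinical montage (80
EEG electrodes, 275 axial gradiometers) because cluster-peak stability —
and hence containment in the fixed 28 mm ROI thickness — depends visibly
on sensor count.

# Numerical choices and limitations

* Determinism: every stochastic generator takes a seed and restores the
  caller's RNG state; pipeline reruns are bit-identical per stage.
* Electrode handling is nearest-surface-node collocation; sub-voxel
  electrode placement error is part of the measured forward error.
* MEG secondary-field quadrature uses one Gauss point per element;
  adequate at the validated resolutions, upgradeable per element.
* The multilayer EEG oracle assumes isotropic shells; anisotropic
  validation relies on the tensor-construction invariants (FA round-trip,
  volume normalization) rather than a closed form.
* The AMG is specialized to lattice meshes (geometric aggregation); it is
  not a general-matrix AMG.
* Sphere phantoms cannot probe errors specific to realistic geometry
  (thin CSF sheets, skull holes such as foramina, gyral folding); results
  here bound discretization and solver error, not anatomical model error.
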