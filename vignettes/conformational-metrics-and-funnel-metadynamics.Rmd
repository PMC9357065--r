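---
title: "Conformational metrics and funnel metadynamics for pLGICs: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational metrics and funnel metadynamics for pLGICs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(plgictools)
```

This vignette is the package's account of its methods: the structural
statistics it computes on pentameric ligand-gated ion channel (pLGIC)
models, the well-tempered funnel-metadynamics engine it provides at desk
scale, the parameters that matter and their defaults, what the synthetic
generators do and do not emulate, and the numerical choices made where the
design was genuinely open.

## Structure substrate and conventions

Structures are atom tibbles (`structure_model`) read from fixed-column PDB
via bio3d.  Policies applied on read: only the first MODEL block is kept
unless another is requested; alternate locations are collapsed to the
highest-occupancy conformer (ties to the first encountered), because every
metric here is a single-conformer statistic; waters are dropped by default
while HETATM ligands are retained and addressable by residue name;
hydrogens are kept but excluded wherever `heavy_only` selections apply.
Residue intervals are inclusive in author numbering.  All structure-side
lengths are Angstrom; the funnel module converts to nm at its boundary,
since binding-free-energy work conventionally reports nm and kJ/mol.

The subunit annotation maps chains to roles (two β2, two α1, one γ2 in the
synaptic receptor) and to the ECD/TMD partition.  The default ranges are
the β2-equivalent residues 10–217 (ECD) and 218–338 (TMD).  Chain-to-role
mapping is user-supplied, not inferred: deposited models do not carry a
reliable convention for which chain letter is which subunit.

## The twist dihedral

The ECD–TMD twist of a subunit is the signed dihedral of four centers of
mass: subunit ECD Cα COM, entire ECD Cα COM, entire TMD Cα COM, subunit
TMD Cα COM.  We use the IUPAC right-handed torsion (cis = 0°, range
(−180°, 180°]).  Because published twist values are reported as magnitudes
without a stated convention, the package fixes the sign internally: the
synthetic pentamer is laid out counterclockwise viewed from the
extracellular side, and `apply_ecd_twist(+θ)` rotates the ECD by the
right-hand rule about the axis from the TMD COM toward the ECD COM, which
makes the measured dihedral increase by exactly +θ.  A useful property that
falls out of the geometry: the torsion is invariant under reversal of the
four points and changes sign only under mirror reflection, and it is exactly
invariant under any global rigid motion — both are enforced by property
tests.

Reporting follows the β-mean convention: the arithmetic mean of the two β2
chains.  Angles sit far from the ±180° wrap in practice; if the two β
angles ever differ by more than 180° the implementation falls back to a
circular mean so the wrap cannot corrupt the average.

## ECD spread ("blooming")

The raw spread of a subunit is the distance between the subunit's ECD Cα
COM and the entire structure's ECD Cα COM; the reported value is the ratio
against the same chain's raw spread in a reference structure, so the
reference against itself is exactly 1.  Two readings of "the subunit's Cα
atoms" are computable; the package defaults to the ECD-only reading
(matching the ECD-spread framing) with `region = "subunit"` as a documented
switch for whole-subunit COMs.  Normalization is per chain rather than
against a chain-averaged reference — the per-chain ratio is the less lossy
choice and reduces to the averaged one on symmetric models.

## Cartesian PCA

Structure ensembles are superposed on a designated reference with the
Kabsch algorithm (SVD route, proper rotation enforced; an independent
quaternion implementation serves as the test oracle).  The Cα coordinates
of the region of interest (ECD, TMD or all) are stacked into
3N-dimensional vectors, mean-centered and decomposed without variable
scaling — coordinates share units, so correlation-scaling would distort the
modes.  Components are reported up to n−1 for n models; identical inputs
yield a `zero_variance` flag rather than NaN fractions.  Projections are
invariant to input order up to component sign, which is the usual PCA
indeterminacy.

## Pore-radius profile

A simplified sphere-fitting profiler in the spirit of HOLE: at each height
z along a user-supplied axis, the accessible radius is the largest sphere
centered in the plane at z that touches no atom's van der Waals surface,
`max over centers c of min over atoms (|c − x_i| − vdw_i)`.  The in-plane
center search uses a coarse 0.25 A grid (half-width 3 A) followed by
Nelder-Mead refinement; radii are capped at 10 A and flagged where the
optimum escapes the lining (or no atoms are near the plane), so open mouths
do not masquerade as measured radii.  The vdW table is fixed (C 1.70,
N 1.55, O 1.52, S 1.80, H 1.20, P 1.80 A) and overridable.  Automated axis
detection is out of scope; the inertial axis of a toy pore is close enough
to +z that the user-supplied axis remains the honest interface.

## Contacts and distances

Contact frequency is the fraction of frames in which a residue's minimum
heavy-atom distance to the ligand selection is at or below the cutoff.
The default cutoff is 4.0 A — the conventional heavy-atom contact radius —
as the analyses this mirrors do not print theirs.  Hydrogen-bond style
measurements use donor/acceptor heavy-atom pairs only; no hydrogen
placement is attempted.

## Funnel geometry and wall

The funnel apex is the mass-weighted heavy-atom COM of the residues
surrounding the ligand (seven in the published protocol); the axis points
toward the COM of the two loop C turn residues.  Defaults: cone half-angle
20°, cylinder radius 0.1 nm, cone-to-cylinder transition 2.5 nm, wall
stiffness 1000 kJ/mol/nm² (matching the positional-restraint stiffness of
the protocol; the wall constant itself is not printed anywhere, and any
stiff value gives the same confined statistics).  The allowed radius is
R(z) = r_cyl + (z_cc − z)·tan(cone angle) inside the cone and r_cyl
beyond; behind the apex the cone continues linearly and a half-harmonic
back wall at z = −0.2 nm prevents escape behind the binding site.  The
wall is half-harmonic in the radial excess, hence C¹ at the boundary —
verified by finite differences in the tests.  Whether the published apex
sits exactly at the site COM is not stated; apex = site COM is assumed.
The exported restraint spec (plain text, fixed ordering and formatting,
bit-exact for fixed inputs) lists geometry, both CV definitions and the
bias parameters, so an external engine can consume the same protocol.

## Well-tempered metadynamics at desk scale

The engine samples the two CVs directly — CV1 standing for the
ligand-COM–site distance and CV2 for the loop C projection — with
overdamped Langevin (Euler–Maruyama) dynamics on
U(s) = potential + V_bias(s, t) + wall.  This is a deliberate surrogate:
the package analyzes ensembles and simulates only in CV space; atomistic
force fields, thermostats and constraint solvers are out of scope.  The
CV2 definition in the published protocol (which loop C atoms enter the
projection) is not fully specified; the projection of the loop C COM is
assumed and recorded as such in the restraint spec.

Bias parameters follow the published protocol where printed: initial
Gaussian height w₀ = 2 kJ/mol, bias factor γ = 15, deposition at a fixed
pace.  Heights follow the well-tempered rule
w = w₀ exp(−V_bias(s, t)/((γ−1)kT)), so the first kernel anywhere has
height exactly w₀ and heights at a revisited point decay monotonically.
Values the protocol does not print were fixed once as follows:

- kernel widths σ = 0.05 nm per CV (common practice for nm-scale distance
  CVs), configurable;
- kT = 2.494 kJ/mol (300 K), configurable;
- friction 1 in the CV time unit, giving unit mobility and diffusion
  D = kT; timestep 2×10⁻⁵, so a single step displaces ~0.01 nm — small
  against both the kernel width and the landscape scale;
- deposition pace 500 steps, i.e. one kernel per ~0.22 nm of diffusive
  exploration.

For speed the per-step bias force is interpolated bilinearly from a grid
(0.01 CV-unit spacing) onto which each kernel is accumulated analytically —
the standard grid trick of metadynamics codes — while the height of every
new kernel is computed from the exact kernel sum, so the well-tempered
damping never sees interpolation error.  Trajectories are recorded at a
stride together with the instantaneous bias, and runs are bit-reproducible
for a fixed seed.  A sanity bound aborts diverging integrations with the
offending parameters named.

## Convergence, FES estimators, and the study conditions

Convergence is diagnosed by recrossings between the bound and unbound CV
basins, operationalized as at least 10 transitions (the minimal two-sided
sampling of both basins); runs below threshold complete but carry a
prominent non-convergence flag.

Two independent FES estimators are provided.  The final-bias estimator
uses F = −γ/(γ−1)·V_bias at the end of the run.  The reweighting
estimator assigns each sample the weight exp((V_bias(s_t, t) − c(t))/kT),
with the running offset c(t) computed from the accumulating bias via the
standard well-tempered relation (log-sum-exp on a coarse grid, linearly
interpolated between checkpoints every 20 kernels), then histograms the
weighted samples and takes F = −kT log(density).  The cited reweighting
algorithm's internal variant details are not reproduced in print, so the
running-offset form was chosen and the final-bias estimator kept as a
cross-check; both report min = 0, and agreement between them over the
thermally relevant region is itself a convergence diagnostic.

The reference study conditions used by the tests and the acceptance script
are a symmetric 2-D double well — quartic along CV1 (closed-form minima at
±0.5 and saddle, barrier 5 kT) and harmonic along CV2
(k = 100 kJ/mol/nm², thermal width ~0.16 nm) — with the protocol bias
parameters above.  Run length is chosen by the convergence criterion, not
by a fixed budget: 2×10⁷ steps gives ~1900 recrossings and, across seeds,
basin asymmetry ≤ 0.15 kT (tolerance 0.3 kT), barrier error ≤ 0.2 kT
(tolerance 1 kT), and estimator agreement within 1 kT pointwise over the
well regions (cells with analytic potential ≤ 2 kT); a 2×10⁶-step run
already recrosses hundreds of times but leaves residual basin asymmetry of
up to ~0.4 kT, which is why the longer protocol is the reference.  One run
takes under a minute on one CPU.

## Synthetic data: what it emulates and what it does not

The pseudo-pentamer places five chains at 72° spacing with one ECD and one
TMD blob of Cα atoms per chain, blob atoms arranged so each blob COM sits
exactly on its ring; twist and bloom operators are exact rigid/radial
inverses of the corresponding metrics, and Gaussian coordinate noise is
applied per Cartesian coordinate (isotropy).  This gives ground truth for
twist, spread, PCA, superposition and RMSD at the geometry level.  It does
not emulate real side chains, ligand topologies, membranes, or the
correlated (non-isotropic) fluctuations of real trajectories — so passing
recovery tests demonstrates correctness of the estimators, not robustness
to every pathology of experimental ensembles.  Likewise the double well is
a stand-in for the bound/unbound basins of a real binding funnel: it
validates the bias logic, convergence diagnosis and reweighting, not
force-field realism.

## Degenerate inputs and tie-breaks

Empty selections, missing residues, coincident COMs (degenerate twist axis
or spread reference), collinear superposition inputs and empty
trajectories raise errors naming the offending entity.  Pore heights
without nearby atoms return the capped radius with a flag rather than a
number that looks measured.  Alt-loc ties break to file order;
occupancies are clamped to [0, 1] on read.

## Known limitations

Torsion-space or mass-weighted PCA, HOLE file-format compatibility,
automated pore-axis detection, multiple-walker or adaptive-Gaussian
metadynamics, and atomistic MD are deliberately out of scope.  The
μs-scale twist and RMSD statistics of real receptor trajectories require a
cluster-scale engine; this package contributes the operators (twist,
spread, PCA, RMSD, contacts) and the restraint/CV export that such
pipelines consume.
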