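---
title: "Modeling subdural cortical stimulation with cortistim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling subdural cortical stimulation with cortistim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Subdural cortical stimulation (SuCS) places disc electrodes below the dura,
directly on the cortical surface, and drives them with brief current pulses.
`cortistim` models the two stages of the biophysics separately and couples
them one way:

1. **Volume conductor.** The head is a passive resistive medium; at the
   frequencies of a 100 µs pulse the quasi-static approximation holds, so the
   extracellular potential obeys ∇·(σ∇φ) = 0 with tissue-dependent (and in
   white matter, anisotropic) conductivity σ. A current-controlled contact is
   modeled as a floating equipotential body with prescribed net current,
   matching a clinical stimulator; the reduced symmetric positive-definite
   system of a first-order tetrahedral FEM is solved by sparse Cholesky
   factorization, with the relative residual checked against 1e-6.
2. **Compartmental neurons.** Layer 5 and layer 3 pyramidal cells are
   discretized into cylindrical compartments; each compartment's
   extracellular node is driven by `amplitude × φ_unit` during the pulse
   (there is no ephaptic feedback onto the field). Voltage integrates by
   backward Euler on the tree (Hines elimination, unconditionally stable);
   gating variables by exponential Euler.

Because the field problem is linear, one unit-amplitude (1 mA) solve per
polarity suffices: cathodal is the negated anodal field and bipolar is the
sum of the active (+1 mA) and return (−1 mA) solves. The excitation
threshold of each neuron is found by a doubling sweep plus bisection over
the amplitude, to 1 mA by default, with a 100 mA not-excitable cap; a
separate 20 mA "clinical" marker is applied at reporting time only.

## Geometry: what the slab is

The extruded slab is mirror-symmetric about the **stimulated gyrus**: the
electrode sits at x = 0 on a flat crown 8.5 mm wide, with a sulcal fold on
each side and an opposite crown beyond each fold; the cross-section is
constant along z. The cortical path (crown → lip → bank → sulcal bottom →
opposite bank → lip → opposite crown) covers one half of the symmetric
section, as in the half-cortex placement the geometry permits.

The crown width is the only printed dimension; everything else is
configuration with literature-typical defaults, recorded in
`slab_params()`: GM thickness 3.5 mm (precentral cortex is among the
thickest), sulcus half-width 0.8 mm, lip radius 3 mm, CSF/dura/skull/scalp
layers 1.2/0.5/4/4 mm, 70 mm extrusion (a 50 mm region of interest plus
10 mm margins so the grounded far boundaries stay out of the electrode near
field).

**Calibration.** The sulcal depth is solved from the requested
crown-to-crown path length (56.5 mm by default, giving a 19.7 mm central
sulcus). For this family of curves — straight crowns and banks joined by a
convex lip arc of radius r and a concave bottom arc of radius a — the path
length offset to depth δ is
`cf + c_opp + 2·wall + (π/2)(r−δ)·2 + π(a+δ)`, and the δ terms cancel
exactly: every cortical layer sees the same path length. One calibrated
length therefore yields the printed 57 somata per plane at 1 mm spacing for
both layers, and 57 × 51 = 2907 per layer over the 50 mm ROI.

**Asymmetric surrogate.** The MRI-derived full-head model is out of scope;
`build_asymmetric_geometry()` stands in for its one robust geometric
property — unequal banks around the stimulated gyrus. A smooth, invertible
depth-stretch, laterally masked to the fold on the cortical-path side and
ramped in below 1.5 mm depth, elongates that bank by the asymmetry factor
(arc-length ratio, exact for the straight bank) and fades out below the
sulcus so deep white matter is only rigidly shifted. At factor 1 the warp is
the identity and every slab test applies verbatim. Soma-depth rules on the
warped lip and bank are preserved only approximately (the placement tests
assert the 0.05 mm depth tolerance on the slab).

## Conductivity

Isotropic values (S/m): scalp 0.465, skull 0.01, dura 0.065, CSF 1.65, gray
matter 0.276, electrode 9.4e6, substrate 1e-10 (kept finite rather than
removing the body). White matter is transversely isotropic with fixed
eigenvalues 1.1 (longitudinal) and 0.13 (transverse) S/m about the fiber
direction: σ = S·diag(σL, σT, σT)·Sᵀ = σT·I + (σL−σT)·f fᵀ. In the slab the
fibers run along y (perpendicular to the skull); the surrogate carries that
field through the warp Jacobian, a geometry-derived stand-in for
diffusion-tensor eigenvectors. The isotropic-control arm sets WM to
0.126 S/m. Tensors are assigned per element from the tissue at its centroid
(nearest-label at the GM/WM interface).

## Meshing

No FEM/meshing stack exists in the R ecosystem this package targets, so the
mesher is deliberately simple and robust: a graded axis-aligned grid, each
hexahedral cell split into six tetrahedra along its main diagonal (Kuhn
subdivision, conforming because all cells share one orientation), elements
labeled by the tissue at their centroid. Grid planes coincide with tissue
interfaces, electrode tops/bottoms, and are refined around the fold, the
cortical layers and the GM/WM boundary. The structure gives O(1) point
location and exact FEM-consistent barycentric interpolation. The cost: the
split has a fixed handedness, so the discrete operator is not exactly
mirror-symmetric (measured threshold asymmetry up to ~8–14% at 1 mm
resolution), and curved interfaces are staircase to one cell.

## Neurons

The published cat-visual-cortex reconstructions behind the original models
are not printed anywhere we can reach, so the morphologies are stylized
parametric templates (`morphology_params()`), with SWC import available for
substituting real reconstructions. Both layers have an apical trunk with
obliques and a tuft, four basal dendrites, and an axon with initial
segment, myelinated internodes and nodes of Ranvier. Every neurite length is
multiplied by 1.6 (the 60% human-adaptation lengthening). The structural
distinctions that drive the results are preserved:

* **L5**: soma 0.6 mm above the GM/WM boundary; myelinated projection axon
  4.8 mm long, crossing into white matter and bent there toward the local
  fiber direction with a 0.5 mm radius (axons that run parallel to a
  vertical boundary segment are redirected toward the nearest white matter
  at the first point where that direction deviates from their course).
* **L3**: soma 1.8 mm above the boundary; axon 1.7 mm long, ending ~0.1 mm
  above the boundary — entirely within gray matter — with its distal half
  unmyelinated (superficial pyramidal intracortical axons are unmyelinated),
  carrying full membrane capacitance and moderate Na density.

Membrane parameters are configuration, not contract: the defaults
(`inst/extdata/membrane_default.json`, loaded by `membrane_parameters()`)
follow the standard published cortical pyramidal channel family — fast Na,
delayed-rectifier K, slow non-inactivating K, high-voltage-activated Ca and
Ca-dependent K with a calcium pool, q10 = 2.3 scaling from 23 °C to 37 °C —
with somatodendritic densities of tens of pS/µm², 3 S/cm² Na at the initial
segment and nodes, and 0.04 µF/cm² myelin capacitance. Leak reversal is
balanced per compartment at initialization so the resting state is an exact
fixed point. A node-density unmyelinated terminal was tried and rejected:
its Na window current overwhelms the leak (Rm = 30 kΩ·cm²) and self-ignites
milliseconds after the pulse, which is a model pathology, not physiology.

## Numerical choices

* dt = 5 µs through the pulse (≥ 20 steps across 100 µs), enlarged 5× after
  the pulse plus a 0.4 ms margin (backward Euler remains stable); 5 ms
  simulated per trial. Compartments ≤ 50 µm.
* Rate functions are saturated outside [−250, 150] mV: at 100 mA the
  extracellular forcing transiently polarizes compartments by volts, and the
  exponential rate expressions would otherwise overflow.
* AP detection: first upward crossing of 0 mV; ties resolve to the lowest
  compartment index. Initiation categories are zones: the unmyelinated
  terminal section (or last axonal compartment), the GM/WM boundary within
  `max(0.3 mm, mesh resolution)` (one element is the precision to which the
  discrete interface exists), the initial segment, the bent arc, the soma.
* Bisection assumes all-or-none monotone firing and raises an escalation
  error (reporting amplitudes) if the evaluated amplitudes contradict it.

## What the generator emulates — and what a green test does not establish

The synthetic world reproduces the *structure* of the published experiment:
geometry calibrated to the printed counts, printed conductivities, printed
pulse/cap/soma-depth/separation values, and the qualitative orderings
(anodal < cathodal minima under anisotropic WM; reversal under the
isotropic control; fraction-curve crossings; boundary-dominated L5 crown
initiation; bank asymmetry under the folded surrogate). It does not
reproduce the published absolute thresholds: those depend on unpublished
morphometry and channel parameters and a ~1.2M-element mesh. Three findings
could not be met at desk scale and are left red with analysis in the
decisions ledger: the L3-only fraction-curve crossing (too few cathodally
excitable L3 cells under the cap), the 1 mA bipolar/anodal agreement for L5
(a ~15% return-contact interference on a 12 mA minimum spans two reporting
bins; on the published ~7 mA minima it does not), and terminal-dominated L3
initiation (every configuration that achieves it destroys the
isotropic-control reversal; the initial segment wins in the defensible
configuration).

## Known limitations

* Staircase tissue interfaces and the fixed-handedness tetrahedral split
  (no body-fitted meshing); memory limits desk-scale meshes to ≥ ~0.9 mm.
* The surrogate is a warped slab, not anatomy: closed "hull" mode only
  re-tags the outer boundary (distant ground patch), and fiber streamlines
  are warp-derived, not measured.
* One-way coupling only; no synaptic/network (indirect) responses; no
  charge-balanced or train protocols.
* SWC round trips collapse the axonal subtypes (initial segment, internode,
  node, terminal) to SWC type 2; re-imported axons carry a generic kind.
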