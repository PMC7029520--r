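---
title: "Hybrid electro-neuro modelling of peripheral nerve stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid electro-neuro modelling of peripheral nerve stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

nervestim couples a quasi-static volume conductor of a multi-fascicular
peripheral nerve with a compartmental model of myelinated sensory axons to
predict which fascicles an implanted multichannel electrode can recruit
selectively. The pipeline has five stages — cross-section geometry,
electrode placement, extracellular potential solution, fiber-population
simulation, selectivity scoring — and every stage is driven by explicit
seeds, so a configuration reproduces its results bit for bit. This
vignette explains the model, its assumptions, the tunable parameters, the
numerical choices, and what the synthetic geometry does and does not
represent.

## The scientific problem

Restoring tactile and proprioceptive feedback after a leg amputation
requires stimulating the sensory fascicles of the sciatic nerve — a nerve
an order of magnitude larger than the arm nerves on which intraneural
stimulation was established. Electrode design questions (how many active
sites, intraneural TIME versus extraneural FINE, how many implants,
monopolar versus bipolar current delivery) are impractical to answer in
humans, so they are asked of a model: an anatomically plausible nerve in
which stimulation physics and axonal excitation are simulated end to end.
The quantity of merit is the percentage of fascicles an electrode can
recruit *selectively* — activating one fascicle while leaving the others
nearly silent — since each selectively addressable fascicle is a potential
independent channel of sensation.

## Nerve cross-sections

Two reference anatomies are built in: the proximal sciatic section
(elliptical envelope 18.7 x 8.8 mm, 37 fascicles) and the distal section
near the bifurcation (11.5 x 6.4 mm, about 58.2 mm^2, 31 fascicles).
`synthesize_cross_section()` draws fascicle equivalent diameters in three
size classes (small < 0.4 mm, medium 0.4-0.8 mm, big > 0.8 mm — the same
classes that later set the number of fiber populations), scales them so
the total fascicular area is 44% of the envelope (which puts the
whole-nerve fiber count at the reported scale, roughly 13 thousand
proximally at 240 fibers/mm^2), and packs them as near-circular ellipses
by seeded rejection sampling with a 50 um minimum gap and a 0.1 mm
clearance from the outline. Each fascicle carries a perineurium 3% of its
equivalent diameter thick; the rest of its lumen is endoneurium.

The envelope is an ellipse because only the section's bounding dimensions
and area are published; a segmented real cross-section can be supplied
instead as a plain-text contour file (`read_cross_section()`), one polygon
per block with a `NERVE` or `FASCICLE <id>` header and `x y` vertices in
mm. Validation rejects self-intersecting contours, fascicles that cross
the outline and overlapping fascicles, naming the offending fascicle.

What the generator does *not* emulate: the grouped, eccentric fascicle
clusters of real sciatic histology (our packing is spatially uniform),
inter-individual variability beyond the seed, and any paraneurial or
compressed state of the nerve. Scores computed on synthetic sections
therefore estimate the *statistical* behavior of an electrode design in a
nerve of this size and composition, not the outcome in a specific patient.

## Electrodes

`time_electrode()` builds a transversal intraneural shaft: 18 mm
(proximal) or 10 mm (distal) long, 20 um thick, 0.380-0.670 mm wide
(linear in the site count, 12 -> 0.380 mm, 24 -> 0.670 mm), with
circular 60-um active sites, half on each face, evenly pitched with the
opposite face shifted by half a pitch (end margins of a quarter pitch
make the two faces symmetric). `fine_electrode()` builds the
no-compression flat interface electrode: a rectangular frame of inner
opening 18.75 x 8.85 mm (proximal) or 10.9 x 7 mm (distal) with square
0.5 x 0.5 mm sites split evenly between the two long inner faces; the
distal frame admits at most 20 sites. Because the model is strictly
no-compression, a frame narrower than the nerve (the nominal distal case)
is expanded to circumscribe the nerve's bounding box. Two further
geometric choices follow from the premise that nerve and cuff have the
same dimensions: the frame extends 10 mm axially (the scale of implanted
cuffs — an axially short frame would let the stimulating current escape
around the walls instead of crossing the nerve), and the sliver between
the elliptical outline and the rectangular aperture is connective tissue
at epineurial conductivity rather than saline, since a saline-filled
corner void would shunt a large fraction of the drive current around the
nerve instead of through it, contradicting that premise.

`place_implants()` inserts TIME shafts parallel to the major axis.
Multiple implants (TIME only, up to four) are offset across the minor
axis at evenly spaced quantiles (thirds for two, quartiles for three,
fifths for four): the shaft length matches the major axis, so parallel
implants must be stacked across the minor one. Off-center shafts may
protrude slightly into the saline at the tips; placement requires at
least 60% of the shaft chord inside the outline.

## Volume conductor

The extracellular potential obeys the quasi-static equation
`div(sigma grad V) = 0` with tissue conductivities (S/m): epineurium
0.0826 (isotropic), endoneurium 0.0826 transverse / 0.571 longitudinal,
perineurium 0.00088, saline 2, polyimide substrate 6.67e-14. The domain
is the cross-section extruded along z, immersed in saline inside a
grounded cylinder (V = 0) of diameter `max(16 mm, nerve bounding box +
8 mm)` and half-length 15.4 mm; the published 16 mm bore is narrower than
the proximal nerve, so the bound is enlarged just enough to keep a 4 mm
saline margin.

Discretization is a cell-centered finite-volume scheme on a structured
grid: uniform in-plane spacing, graded axial spacing (fine near the
electrode plane, geometrically coarsening toward the ends). Two thin
structures are *not* resolved volumetrically:

* the perineurium (5-60 um) enters as a sheet resistance `t / sigma_p`
  on every grid face crossing a fascicle contour — the standard
  thin-layer (contact impedance) approximation;
* the 20-um electrode substrate enters as insulating "crack" faces along
  the shaft or frame plane. Grid axes are offset half a cell so these
  planes always fall between cell centers.

Each active site is a boundary current source: its reference current
(2 uA for TIME, 20 uA for FINE) is deposited in the grid cells adjacent
to the crack on the site's face. Laplace linearity turns one solution per
site (`solve_lead_field()`, Jacobi-preconditioned conjugate gradients,
relative residual 1e-7) into every amplitude, polarity and multi-site
configuration by scaling and superposition (`superpose_fields()`).
Potentials at arbitrary points come from trilinear interpolation
(`sample_potential()`); fiber compartments beyond the axial extent take
the grounded-boundary value 0.

Three solver profiles are built in: `fine` (0.1 mm in-plane — the
reference resolution), `coarse` (0.25 mm — the default for studies) and
`test` (0.45 mm — unit-test scale). Verification (see the test suite)
checks the solver against closed-form isotropic and anisotropic
point-source fields to within 10% at 0.5-4 mm, exact linearity, exact
cancellation of opposite-polarity superposition, and grid-refinement
stability of in-fascicle potentials to within 5%. At the coarse profile
the *far* field behind several perineurium sheaths converges more slowly
(10-20%); recruitment is governed by the near field within the
2-4 mm effective range, which is the regime the profile is chosen for.
The discrete source is smeared over one grid cell, so potentials within
half a cell of a site are effectively averaged over that cell — at
0.25 mm resolution, thresholds of fibers closer than ~0.1 mm to a site
inherit that smoothing.

## Myelinated fiber model

Axons follow the McIntyre-Richardson-Grill (MRG) double-cable
formulation: 21 nodes of Ranvier and 20 internodes, each internode built
as MYSA - FLUT - 6 x STIN, with an explicit periaxonal space under the
myelin. Nodal membrane carries fast Na+, persistent Na+, slow K+ and leak
conductances (3.0, 0.01, 0.08, 0.007 S/cm^2; reversal potentials +50,
-90, -90 mV; 36 C rate constants); internodal axolemma is passive; the
myelin sheath is an RC layer whose per-area constants scale with the
lamella count. Geometric and electrical parameters exist at nine
tabulated fiber diameters (5.7-16 um); a fiber's diameter is snapped to
the nearest tabulated value — interpolating the geometry between table
rows is deliberately not allowed, keeping every simulated fiber a
well-defined table entry. One deliberate departure from the original
table: the internode length is `L = 100 * D` exactly, matching the
population-model convention used for these nerves.

The extracellular potential profile is sampled at *all* compartments by
default. A `nodes_only` option samples only nodes of Ranvier and fills
internodal compartments by linear interpolation, for strict fidelity to
hybrid pipelines that export node potentials only; both options are
supported because the double-cable mechanism formally needs a potential
outside every compartment.

Integration is implicit Euler (1 us steps during the 50 us pulse, 5 us
afterwards, 2 ms window) on the coupled intracellular/periaxonal system,
solved per step as a 2x2-block tridiagonal system; gating variables use
an implicit update with tabulated rate constants. A fiber counts as
recruited when the action potential runs over its entire length —
operationally, the membrane potential crosses 0 mV at both terminal
nodes after stimulus onset.

Two behaviors of this model shape the threshold machinery:

* **Thresholds on a charge grid.** The stimulus sweep is 60 charges from
  0.5 to 60 nC (`seq(0.5, 60, length.out = 60)`) at fixed 50 us pulse
  width, i.e. site currents of 10-1200 uA. The threshold is the first
  grid charge that recruits.
* **Cathodal block.** Very close to a site, the raw response is not
  monotone: beyond a fiber-specific amplitude the flanking
  hyperpolarization blocks propagation. Recruitment curves are therefore
  *cumulative* (a fiber is counted recruited at and above its threshold
  charge, the recruitment-curve convention), and the threshold search is
  a cap-anchored bisection complemented by a bottom-up scan when the cap
  initiates but does not propagate. The bisection is validated against
  the exhaustive 60-point scan in the tests.

## Fiber populations

`populate_fibers()` fills each fascicle at 240 fibers per mm^2 of
endoneurial area (a 50x-reduced density that preserves potential
distributions and recruitment fractions while keeping populations
simulable; the density is a parameter). Counts are Poisson with a
minimum of one fiber per fascicle; positions are uniform in the
endoneurium; each fascicle is divided into 1, 3 or 5 Voronoi-clustered
populations according to its size class, emulating somatotopic grouping.
Diameters are drawn from a two-component Gaussian mixture (modes 7 and
12 um, SD 1.5 um, equal weights, truncated to 5.7-16 um) — the published
histogram behind the original populations is cited but not printed, so
the mixture is fully configurable — and snapped to the MRG table. Node
positions are shifted by a uniform offset in `[0, L)` per fiber.

## Selectivity and scoring

For a stimulation configuration (one cathodic site, or a signed pair
with equal current magnitudes) and fascicle `i` with recruited fraction
`mu_i` and recruited count `n_i` out of `m` fascicles:

* spatial selectivity: `Sel_i = mu_i - (1/(m-1)) * sum_{j != i} mu_j`
* functional selectivity: `Sel_s_i = n_i / sum_j n_j`

A fascicle is *selectively recruited* by a configuration if at some sweep
amplitude `Sel_i > 0.6` and `Sel_s_i > 0.9` (strict inequalities) with at
least one recruited fiber; requiring `n_i >= 1` excludes the vacuous
all-zero amplitude, where `Sel_s` is undefined. The electrode score is
`100 * |union of selective fascicles over all configurations| / m`. The
any-amplitude, any-configuration union is the reading of per-electrode
scoring adopted here, since no single amplitude is privileged in a
recruitment sweep. Reported scores are mean +/- SD over replicate fiber
population seeds; the anatomy is held fixed within a study, because lead
fields depend only on geometry and are shared across replicates.

The per-site *threshold charge* is the smallest sweep charge at which the
nearest fascicle (by contour distance, the site's own fascicle when
intrafascicular) reaches 10% recruitment — a perceptual-threshold
surrogate.

**Policies.** Monopolar stimulation drives each site cathodically.
Bipolar stimulation adds, for every anchor site, a pair with its nearest
opposite-face site and its nearest same-face site, each in anti-polarity
(cathodic anchor, anodic partner) and same-polarity patterns with equal
magnitudes; duplicate weight assignments (mutual same-polarity pairs) are
removed, and the bipolar policy always includes the monopolar
configurations, so its score cannot be lower. Multi-implant evaluation
unions the selective sets of all implants' sites, one configuration
active at a time; each implant's lead fields are solved with its own
substrate only (a parallel 20-um shaft a few millimetres away has a
negligible far-field effect), which keeps lead fields reusable across
implant counts.

**Effective range.** Fibers farther than 2 mm (TIME) or 4/3 mm
(proximal/distal FINE) from every active site of a configuration are not
simulated and count as non-recruited; a fascicle with at least one fiber
in range is implicated as a whole, so its recruitment fraction uses the
full fiber count. The tests verify on a five-fascicle nerve that the
filter leaves selective sets unchanged, and that no fiber beyond ~2 mm is
recruited by a TIME site even at the 60 nC cap.

## Problem sizes and reproducibility

Unit and property tests run on the `test` grid (0.45 mm) with reduced
fiber densities (40-120 /mm^2) and small sweeps; the scaled-down
reproduction studies in the test suite use two to three replicate seeds.
`scripts/acceptance.R` reruns the full study pipeline at the `coarse`
profile with three replicate fiber seeds per quantity (one per electrode
variant for the policy comparisons), 240 fibers/mm^2 for the
single-electrode TIME score and threshold runs, 120 fibers/mm^2 for the
FINE score and 60 fibers/mm^2 for the multi-implant, policy-comparison
and whole-population range runs — sizes at which a complete rerun stays
within a desk-scale compute budget. All randomness flows from explicit seeds through a derived-seed
helper, so identical configurations give identical outputs; lead-field
caches are stored in the package's serialized cache format
(`write_lead_fields()`).

## Known limitations

* The synthetic anatomies match published counts, dimensions and density
  statistics, not the spatial idiosyncrasies of a particular histological
  section; quantities that depend on where exactly sites land relative to
  fascicles (notably distal threshold charges) inherit that freedom.
* FINE is modelled without nerve compression, as in the underlying
  design; reshaping would change both geometry and selectivity.
* The paraneurium and capacitive/dispersive tissue properties are not
  modelled; the solution is purely quasi-static and resistive.
* Thresholds are single-pulse; no frequency encoding, receptor
  transduction or motor-fiber modelling.
* The coarse solver profile trades far-field accuracy (10-20% behind
  multiple perineurial sheaths) for speed; near-field quantities within
  the effective range converge at the few-percent level.
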