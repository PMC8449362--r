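---
title: "Synthetic cryo-ET analysis of platelet pseudopodia: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic cryo-ET analysis of platelet pseudopodia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package models

Activated platelets spread on a substrate and extend pseudopodia —
filopodia-like protrusions filled with bundled actin and studded with
adhesion receptors (dominated by the integrin family). Two questions about
these protrusions are quantitative and answerable from cryo-electron
tomograms:

1. **Actin polarity.** Each actin filament has a fast-growing barbed (+)
   end and a slow-growing pointed (−) end. What fraction of the filaments
   in a pseudopodium point their barbed end toward the protrusion tip?
   A purely protrusive bundle would be near 100% tip-ward; a mixed
   composition implies the bundle can also support acto-myosin
   contractility.
2. **Receptor architecture.** What do the membrane-attached densities on
   the pseudopodium surface look like — how tall are they above the
   membrane, and are they spatially organized?

`tomopod` re-implements the two in-situ analyses behind these questions as
parameter-recovery experiments: a synthetic tomogram generator produces
pseudopodium-like scenes with *known* ground truth, and the analysis
pipelines must recover that truth. All headline numbers the package
reports are therefore recoveries of generator parameters, not measurements
of real platelets.

# The synthetic scene generator

## Geometry

A scene is a 256 × 256 × 128-voxel volume at 1.1 nm/voxel (≈282 × 282 ×
141 nm). A capped membrane tube (cylinder of mid-surface radius 50 nm plus
a hemispherical tip cap, rendered as two Gaussian sheets 5 nm apart —
the bilayer leaflets) rests on a support film at z = 8 nm; z is the beam
axis, the tilt axis is y, and the tip points toward +x. Twenty actin
filaments (80–200 nm long) run inside the tube, nearly parallel to its
axis (≤12° in-plane deviation, ≤4° out-of-plane; spread protrusions are
thin and flat, so bundled actin runs nearly parallel to the support), at
least 10 nm apart.

Each filament's barbed end points tip-ward with probability
`tip_fraction`; the shipped `fig3b` configuration sets 0.74, the composition
the polarity experiment must recover. The stored trace point order is
randomized independently of polarity so that no downstream step can read
polarity from the digitization direction.

## The helical actin model

Actin is a 1-start helix with a rise of 27.6 Å and a left-handed twist of
166.7° per subunit (the handedness is the actin convention; the sign is
configurable). Subunits are rendered as five Gaussian lobes (σ 0.65 nm)
spaced along a 3.0-nm chevron tilted 55° away from the filament axis, at
1.8 nm radius, leaning toward the barbed end at the outer edge. The total
filament diameter is ≈8–9 nm.

The chevron is load-bearing, not cosmetic. The projected point pattern of
a 1-start helix of *isotropic* blobs is closed under axial flip combined
with an azimuthal phase shift — its 2D projection carries **no polarity
information at all**. Polarity in projection lives entirely in the
correlation between a subunit's internal axial and radial structure, which
is exactly what the tilted shape of the real actin monomer provides (and
why real 2D class averages look like arrowheads). The chevron parameters
were chosen once, by scanning for maximal plus/minus template
separability (cross-correlation of mirrored templates 0.85 versus 1.0 for
self) subject to two constraints: the axial autocorrelation must peak at
the 27.6 Å rise, and the diameter must stay near 8 nm.

## Imaging model

The composed density (filaments + membrane + receptors + support sheet)
passes a single-axis missing-wedge filter — Fourier coefficients whose
(k~x~, k~z~) direction lies more than 60° from the tilt-axis plane are
zeroed, mirroring a ±60° tilt series — followed by additive white
Gaussian noise. CTF effects are out of scope by design (the corresponding
corrections on real data are, too). The wedge filter is linear and
idempotent and never increases Fourier power; both properties are tested.

`noise_sigma` is the noise SD relative to the filament peak density
(relative to the membrane sheet amplitude in filament-free scenes, so
receptor brightness never rescales the noise). The default 0.3 was fixed
before the acceptance experiments were run, at the operating point where a
single 8-nm segment classifies correctly ≈90% of the time while roughly
half the filaments still fail the binomial confidence filter — the regime
the method is designed for, where single observations are unreliable and
class averaging plus per-filament aggregation carry the inference.

## Receptors

Receptor densities are bent two-lobe blobs attached to the outer leaflet:
a "legs" lobe (σ 1.5 nm) near the membrane and a laterally offset "head"
lobe (σ 2.0 nm), rendered at 1.0×/1.6× the membrane sheet amplitude
(protein contrast exceeds lipid contrast, and the receptors in the real
tomograms are visible protrusions). The head center is placed so that the
density along the normal falls to half its extracellular peak at exactly
`receptor_height` (default 12 nm) above the outer leaflet — the generator
self-consistently defines the quantity the measurement recovers. The
shipped `receptor_geometry` configuration places 50 receptors per scene in
the 50–70-nm height band above the support, at least 10 nm apart.

# The polarity pipeline

1. **Segments.** Trace polylines are resampled at 8-nm arc-length spacing
   with central-difference tangents; 32-voxel (35 nm) boxes are extracted
   at the nearest voxel, with the sub-voxel residual recorded. Boxes
   crossing the volume edge are rejected, never padded.
2. **Slab projection.** A soft raised-cosine cylindrical mask (radius
   6 nm, 2 nm taper) around the expected filament axis suppresses
   neighboring filaments; the central 11-nm slab is summed along z.
3. **In-plane alignment.** The image is rotated so the tangent maps to
   +x (the residual extraction offset is applied in the same resampling
   pass). Tangents within 5° of the beam axis are unusable: the filament
   axis cannot be resolved in projection.
4. **Pooled 2D classification.** All scenes' aligned images are
   classified together — class averages need hundreds of members to rise
   above the per-segment noise, and per-scene pools of ~330 segments
   cannot support 20 classes. The classifier alternates translational/180°
   alignment against current class averages with reassignment by
   normalized cross-correlation. Two design choices matter:
   * *kmeans++-style seeding on correlation distance.* From a random
     partition the iteration converges to polarity-mixed fixed points
     (the plus and minus projection manifolds are ≈0.86-correlated, so
     the mixture is stable). Farthest-point-biased seeding lets distinct
     phase/polarity modes nucleate separate classes.
   * *Flip augmentation.* Every image enters twice, once axially
     flipped. This makes the class landscape exactly symmetric under
     polarity; without it the landscape organizes around the majority
     orientation and vote accuracy becomes composition-dependent, which
     biases the resolved subset toward the majority (we measured
     recovered fractions of ~95% for a 74% composition before adopting
     it). A segment's two copies must agree for it to vote — a built-in
     mirror-consistency check.
5. **Class polarity labels.** Class averages are matched against slab
   projections of the helical model with barbed end toward +x ("plus")
   and their axial flips ("minus"), maximized over 12 azimuthal phases,
   three out-of-plane tilts (±4°, 0°), and integer shifts. The templates
   pass the same missing-wedge filter as the data. Classes are labeled by
   the winning orientation; classes with a score margin below 0.05 or
   fewer than 10 members are discarded and their members abstain. The
   180° in-plane rotation *is* part of the alignment search (the axis
   direction is ambiguous); the axial flip is *not* — it is exactly what
   classification must separate.
6. **Filament calls.** Per-filament votes are aggregated with an exact
   binomial test against chance (p = ½): a filament is resolved when
   P(X ≥ max(n₊, n₋)) ≤ α with at least `n_min` = 5 votes; ties are
   unresolved. The default α is 0.05; a stringent variant (α = 0.01) is
   reported alongside. The reference method defers its confidence
   definition to its own toolbox; the exact binomial tail is this
   package's transparent, testable substitute.
7. **Fractions.** A resolved filament counts tip-ward when its estimated
   barbed direction has positive dot product with the tip axis (a zero
   dot product counts cell-ward, conservatively, and is logged). Tip-ward
   fractions are computed over resolved filaments per tomogram —
   "total filament numbers" is interpreted as resolved filaments, so the
   two fractions sum to 100%; the unresolved share is reported
   separately. The aggregate is the mean ± SD across tomograms.

With 20 filaments per scene and roughly half resolving, the per-scene
binomial spread of the tip-ward fraction is ≈10 percentage points — the
same order as the spread reported for real pseudopodia, which is one
reason the desk-scale conditions were chosen this way.

# The receptor pipeline

1. **Normals.** Outward normals come from the negated gradient of a
   Gaussian-smoothed membrane mask at its boundary voxels; the mask is
   2× decimated first (membrane curvature radii are tens of nm).
   Surface points are then refined sub-voxel onto the 0.5-level of the
   smoothed mask — boundary-voxel centers sit up to half a voxel inside
   the true surface, which would otherwise bias every height downstream.
2. **Picking.** The volume is matched-filter smoothed (σ 1.5 nm); the
   density is sampled along each outward normal across the attach band
   (2–12 nm beyond the outer leaflet, which sits 2.5 nm past the
   segmented mid-surface). Each ray is scored by its residual against the
   median ray profile of the *height/tilt-eligible* surface population —
   the leaflet tail is common to all rays, and restricting the reference
   population keeps rays near the support film or the wedge-degraded tube
   top from corrupting the statistics. Candidates exceed
   median + 3 MAD of the eligible scores; they are then rejected with
   exactly one machine-readable reason: `height` (attachment outside
   50–70 nm above the support), `tilt` (normal more than 20° out of the
   x-y plane — the membrane must run parallel to the beam to be resolved),
   or `separation` (a stronger filter-passing pick within 8 nm; because
   suppression only ever comes from filter-passing picks, the filters and
   the dedup commute). Kept positions are refined to the score-weighted
   centroid of nearby candidates. On the default scenes this recovers
   ≥90% of placed receptors within 5 nm, with of order 5–10 false picks
   per scene — which is precisely what the classification stage is for.
3. **Averaging and classification.** Boxes are rotated normal-to-z and
   averaged; the in-plane angle about the normal is unconstrained and
   marginalized, giving a cylindrically smeared initial model (as in the
   corresponding real-data step). Two passes of FFT translational
   refinement against the running average remove the few-nm picking
   scatter. Alignment-free k = 2 classification by NCC separates
   receptor-bearing from junk boxes; the selected class maximizes mean
   intra-class correlation above a membership floor.
4. **Height.** The extracellular profile p(z) is the mean over a central
   6-nm disk; after subtracting the 25th-percentile extracellular
   pedestal (azimuthally smeared neighboring receptors), the height is
   the topmost z where p reaches 50% of its extracellular peak, minus the
   outer-leaflet position. The measurement is monotone non-increasing in
   the threshold level, which is tested.
5. **Spatial statistics.** Kept picks are compared against complete
   spatial randomness on the same surface: the observed mean
   nearest-neighbor distance versus `n_mc` uniform placements, two-sided,
   with the +1 Monte-Carlo correction. Under the uniform null the
   p-values are approximately uniform (tested by calibration).

**Rigid-body fitting.** `rigid_fit_score()` renders reference
(pseudo-)atom coordinates as Gaussians low-passed to a stated resolution,
scores an exhaustive coarse rotation grid by FFT translational
cross-correlation, and refines locally (Nelder–Mead on the rotation
vector). The deposited-map benchmark (docking the bent integrin ectodomain
into the published receptor map, reported correlation ≈0.72) requires
downloading the deposited volume and is not part of the default runs; the
test suite instead fits a synthetic bent-receptor reference into its own
rendered density.

# Numerical choices and degenerate inputs

* All tables are in nm; Ångström appears only where the field quotes it
  (helical rise, resolutions), converted at the boundary. Voxel (i,j,k)
  (1-based) sits at (i−1, j−1, k−1) · pixel size.
* MRC mode 2 with the pixel size in the header (Å); traces, segments,
  calls and picks travel as TSV or single-block STAR tables, so every
  stage is independently inspectable.
* Exact ties in classification assignment break toward the first
  candidate; empty classes are reseeded from the worst-fitting members;
  everything downstream of a seed is bit-reproducible, which is tested.
* A trace shorter than one spacing yields a single flagged segment; an
  arc length that is an exact multiple of the spacing includes the final
  point once; tangents at trace ends use one-sided differences.
* FSC uses one-Fourier-voxel shells under a soft spherical mask (raised
  cosine, 0.9 × half-box); thresholds 0.5 and 0.143 are both always
  reported, linearly interpolated between shells; a curve that never
  crosses is flagged "beyond Nyquist" rather than given a number.
* Filaments within 5° of the beam axis, boxes crossing the volume edge,
  empty vote lists, tomograms with zero resolved filaments, degenerate
  (near-spherical) membrane masks without a tip override, and `n_mc = 0`
  all fail loudly or are flagged — never silently imputed.

# Problem sizes

The shipped experiments are sized for a single CPU: the polarity
experiment classifies ≈9,400 segments (×2 with flip augmentation) from 28
scenes in one pooled run; the receptor experiment picks ≈50 receptors in
each of 5 scenes. The corresponding real-data analyses are two to three
orders of magnitude larger and use regularized-likelihood refinement; this
package's direct averaging and NCC classification are adequate because its
claims are parameter recoveries under its own generator, not resolution
claims.

# What passing tests do and do not show

The generator emulates the statistical structure the analyses rely on:
helical geometry with a polarity-encoding subunit asymmetry, a mixed
composition, membrane-attached receptors in a height band, the missing
wedge, and additive noise. It does **not** emulate CTF, dose damage,
alignment errors between tilts, filament curvature or branching, membrane
undulations, receptor conformational heterogeneity, or crowding by other
cytoplasmic material. Recovery of the generator's parameters therefore
shows the pipelines are correct and unbiased under these idealized
conditions; it does not certify accuracy on real tomograms, where the
listed effects degrade contrast in ways the generator deliberately leaves
out.

# Known limitations

* Reference-free 2D classification trades a little of the matched
  filter's per-image accuracy for model independence; on synthetic data
  its voted-segment accuracy sits slightly below the brute-force template
  oracle (the suite asserts it stays within 0.15). The filament-level
  binomial aggregation absorbs the difference.
* The polarity margin (0.05 NCC) and class floor (10 members) discard
  roughly half of all segments at the default noise; the unresolved
  fraction is a first-class output, not an error.
* Heights are only meaningful for receptors on membrane running parallel
  to the beam; the tilt filter enforces this and its 20° default is this
  package's explicit choice where the field's tooling leaves it implicit.
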