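---
title: "Quantifying protein recognition of lipid-droplet monolayers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protein recognition of lipid-droplet monolayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldbind)
```

## The problem

Lipid droplets (LDs) bud from the ER carrying a neutral-lipid core — wax
esters (WE) in jojoba seeds, triacylglycerols (TAG) in most oilseeds —
bounded by a phospholipid *monolayer*, while the ER itself presents a
standard *bilayer*. Cytoplasmic LD-associated proteins must tell these two
surfaces apart. The distinguishing physical features are subtle: monolayers
over a bulky core develop *packing defects* where acyl chains or core
lipids become solvent-exposed between headgroups, and amphipathic helices
with the right hydrophobic-face composition exploit them. `ldbind`
implements the trajectory-derived observables used to dissect this
recognition — per-residue contacts, penetration depths, defect areas and
helix hydrophobicity — together with a synthetic trajectory generator that
makes every stage testable by parameter recovery.

## Models and observables

### Contact numbers

For residue $i$ at frame $t$, over all protein-heavy/membrane-heavy atom
pairs:

$$C_i(t) = \sum_{j} \frac{1}{1 + e^{5\,(d_{ij}(t) - 4)}}, \qquad d \text{ in Å},$$

with pairs first restricted to $d \le 5$ Å. The sigmoid is a smoothed
native-contact count: ~1 at van der Waals contact, 0.5 at 4 Å, 0.0067 at
the 5 Å cutoff — so hard truncation at the prefilter changes each pair by
under 0.7%, which we accept. Distances use the minimum-image convention in
x and y only; the membrane normal (z) is not treated as periodic in
analysis. A residue is in a **bound conformation** when $C_i(t) > 25$
(strict inequality). Per-residue averages are taken **only over bound
frames** — a residue that never exceeds the threshold reports 0, so the
average is either 0 or above the threshold by construction. (The defensible
alternative — averaging over all frames after first binding — is not what
the bound-conformation definition implies, and we do not implement it.)
The cumulative sum of these averages over residue index is the standard
profile for locating binding regions along the sequence.

### Penetration depth

$\mathrm{depth}_i(t) = |z_{\mathrm{cog},i}(t) - z_{\mathrm{center}}(t)|$,
where the residue position is the heavy-atom center of geometry (a
CA-only mode is available) and the membrane center is the mean z of all
lipid heavy atoms, core included for filled monolayers; solvent is always
excluded. The absolute value folds the two leaflets together: the patch
is compositionally symmetric and a protein can associate with either face
through the periodic boundary. Depths are histogrammed in half-open 1 Å
bins from 0 to 60 Å (covering the 50 Å initial placement) and each
residue row is divided by its own maximum, $P_i(z)/P_i(\max)$.
Max-normalization, rather than unit-area normalization, is what makes
rows with very different occupancies visually and numerically comparable.

### Packing defects

Each leaflet surface is rasterized onto a square grid (default 1 Å
cells). The leaflet's lipid atoms plus all core atoms are assigned to
cells (minimum-image wrapped); the highest atom per cell (ties broken by
atom id) decides the label. A cell is a **defect** when its highest
lipid-chain or core atom lies below the glycerol plane, or when no atom
reaches above that plane at all — a single deep-defect rule, deliberately
simpler than the deep/shallow/chemical taxonomy of PackMem-style tools,
because only comparative defect areas are of interest here. Note the
first clause is logically contained in the second (if the *highest* atom
is below the plane, nothing is above it); we keep the rule as stated for
transparency. Components are 4-connected with periodic wrap. Pooled
component areas $A \ge a_\min$ (default 5 Å²) are summarized by the
maximum-likelihood size constant of the shifted exponential,
$\hat\lambda = \overline{A - a_\min}$; heavier defect-size tails give
larger $\hat\lambda$.

By default the classifier treats atoms as points. For bead-resolution
synthetic patches, whose lattice spacing (~6 Å at 100 lipids per 60×60 Å
leaflet) is far coarser than a 1 Å grid, we use the radius-aware mode
(`radius = 4`): each bead covers cells within 4 Å in-plane, a coarse van
der Waals footprint that makes an intact synthetic leaflet read as
covered while surfacing events still open defects.

### Amphipathic-helix analytics

Residues are projected on a helical wheel at 100°/residue (the ideal
α-helix periodicity; 18 residues = 5 exact turns). Hydrophobicity uses
the embedded Wimley–White water→POPC-interface scale (kcal/mol; negative
= favorable interface partitioning). Regional hydrophobicity is the plain
sum over a window; because the scale is additive, a point mutation
changes the sum by $\mathrm{WW}[\mathrm{new}]-\mathrm{WW}[\mathrm{wt}]$
regardless of context — which is why a published wild-type regional sum
can be adjusted to its mutant value without knowing the full sequence:

```{r}
ww_mutation_delta(c("I158F", "M161L"))
0.31 + ww_mutation_delta(c("I158F", "M161L"))
```

The hydrophobic moment is the Eisenberg-style vector sum of per-residue
hydrophobicities at wheel angles, computed on the *negated* WW scale so
the resultant points at the hydrophobic face and its magnitude is
invariant under the wheel phase. Backbone ϕ/ψ follow the IUPAC sign
convention; a residue is called helical when both angles are within a
circular tolerance (default 30°, boundary inclusive) of the canonical
(−57°, −47°), with Ramachandran region labels from a declared rectangle
set (allowed α: ϕ ∈ [−100, −30], ψ ∈ [−80, −5]; marginal: ±20°
dilation). The ideal-helix builder uses internal-coordinate (NeRF)
placement with standard bond geometry; round-tripping it through the
dihedral code recovers (−57, −47) to better than 1°, and the dihedral
implementation is cross-checked against an independent reference
implementation in the test suite.

## The synthetic generator

The generator produces the statistical structure the analyses assume —
not physics. Every random component draws from streams derived from one
master seed by fixed offsets, so runs are bit-reproducible and adding
frames does not reshuffle earlier jitter.

* **Membrane.** Bead lipids (head, glycerol, two tails of 8–12 chain
  beads at 1.4 Å spacing) on a jittered lattice, two mirrored leaflets.
  Headgroup counts per leaflet come from exact largest-remainder
  allocation of a composition table; built-ins reproduce a jojoba-like
  45:38:10:7 PC:PE:PI:PG membrane and a tobacco-leaf-like
  60:59:37:26:15:3 PC:PE:PA:PG:PI:PS membrane. Filled monolayers separate
  the leaflets by a 30 Å slab filled with WE chains (two acyl arms on an
  ester bead) or TAG chains (three arms on a glycerol bead).
* **Protein.** A rigid pseudo-protein: 60 residues on a planar serpentine,
  8 beads per residue — the mean heavy-atom count of an amino acid, so
  contact numbers land on the all-atom scale and the >25 threshold is
  meaningful. It starts with its centroid 50 Å above a monolayer center
  (40 Å for bilayers) in one of six canonical orientations (x-rotations
  0/90/180/270°, y-rotations ±90°), and descends by a mean-reverting
  height process.
* **Binding script.** At `bind_time` the listed binding residues ramp
  over 5 frames to `insertion_depth` (default 2 Å) below the head plane
  and are held with jitter; other residues stay above the head plane at a
  standoff growing with sequence distance from the binding set, so
  recovery tests can demand no false positives beyond ±3 neighbors. A
  `bounce` scenario touches the surface and retreats ≥ 20 Å instead.
* **Surfacing events.** Core molecules surface as a Poisson process
  (default 0.2 events/ns, exponential dwell, mean 2 ns): the molecule's
  top bead rises to the head-plane level and lipids are pushed out of a
  disc (default radius 8 Å), exposing core beads below the glycerol
  plane — the defect the classifier detects is the lipid-free annulus.
  The disc default was chosen from the classifier's 4 Å footprint
  geometry: a smaller disc is completely re-covered by the footprints of
  the displaced lipids.

What the generator does **not** emulate: energetics, lipid diffusion and
exchange, protein flexibility beyond the scripted insertion, curvature
(the patch is planar, as in published LD-mimic setups), solvent, and any
coupling between protein binding and defect formation. Passing recovery
tests therefore demonstrates that the *analysis* code measures what it
claims on data with known ground truth — not that real proteins behave
this way.

## Defaults and numerical choices

| Parameter | Default | Why |
|---|---|---|
| Contact kernel midpoint / steepness | 4 Å / 5 Å⁻¹ | smoothed native-contact form |
| Pair prefilter | 5 Å | kernel < 0.007 beyond it |
| Bound threshold | > 25, strict | bound-conformation definition |
| Depth bins | 1 Å, 0–60 Å | covers the 50 Å placement |
| Defect cell / footprint | 1 Å / 0 (4 Å for bead patches) | point rule; bead lattice needs a footprint |
| Defect area cutoff a_min | 5 Å² | excludes single-cell jitter noise |
| Helicity tolerance | 30° circular | "near (−57, −47)" made precise |
| Lipids per leaflet | 100 | patch size is a free parameter |
| Scenario length | 200 frames × 1 ns | ample for approach + bound statistics |

Ties in the defect "highest atom per cell" go to the smallest atom id;
degenerate inputs error early (empty leaflets, all-zero histogram rows,
empty membrane selections). Test problem sizes (50–120-frame scenarios,
60×60 Å patches) were chosen so the full suite exercises every stage in
under a minute on one CPU.

## Limitations

The defect classifier is a single-rule deep-defect scan: it reports
neither shallow (chemical) defects nor defect lifetimes. The contact
stage does not decompose contacts by lipid species. The generator's
scripted kinematics cannot probe binding thermodynamics or orientation
preference — six-orientation scenario grids enumerate starting poses, but
convergence to a preferred pose is outside a scripted model. For real
all-atom systems the role map must be extended to the force field's
residue names (`default_role_map()` rows are user-extensible), and
trajectory formats beyond multi-frame XYZ / multi-model PDB should be
converted externally.
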