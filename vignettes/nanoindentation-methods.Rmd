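---
title: "Quasi-static nanoindentation of a graphene/DPPC composite: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quasi-static nanoindentation of a graphene/DPPC composite: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The system and the question

`nanoindent` models a layered nanocomposite: two rectangular graphene flakes
with dipalmitoylphosphatidylcholine (DPPC) phospholipid molecules sandwiched
between them, pressed from above by a capped zigzag carbon-nanotube (CNT)
tip.  The questions it addresses are mechanical and electronic: how does the
adhesion between the sheets and the lipids evolve as the tip loads and
unloads the film, where in the graphene lattice does the mechanical stress
concentrate, and in which direction does charge flow between the tip, the
sheets and the lipids.

The composite's repeating unit (the *supercell*) is two 25.5 x 35.51
Angstrom flakes holding 618 carbon atoms in total, with two DPPC molecules
(C40H80NO8P, 130 atoms each) whose geometric centers sit 6.23 Angstrom from
each sheet plane; the film fragment is a 3 x 3 tiling, 7902 atoms.  The tip
is a (16,0) zigzag tube, radius $n a / 2\pi \approx 6.26$ Angstrom, with one
end closed by a hemispherical cap, initially 4.1 Angstrom above the upper
sheet.

# Coordinate and bookkeeping conventions

The indentation axis is `y`; sheets lie in the x-z plane.  The tip-edge
coordinate is measured relative to the *initial upper-sheet plane*, negative
above it: the tip starts at -4.1, and after three 0.5-Angstrom steps sits at
-2.6.  Positive coordinates mean the tip edge has passed below the initial
plane.  (Published figure captions for systems like this sometimes anchor
the zero at the tip edge instead; the plane-anchored convention is the one
under which the tabulated stroke coordinates are mutually consistent, so the
package uses it throughout.)

Atom indices are 0-based in all on-disk exports (bond files, stress maps);
the PDB writer converts to the format's 1-based serials.

# Structure generators

**Graphene flakes** crop an ideal honeycomb lattice (C-C bond 1.42 Angstrom)
to the requested rectangle with a half-open boundary and a 0.01-Angstrom
guard (the conventional lattice constant 2.46 rounds $\sqrt3 \times 1.42 =
2.4595$; without the guard a one-unit-wide request would admit an extra
lattice column).  Edges are unterminated carbon.  An ideal-lattice crop of
the stated flake holds 347 atoms; the study's supercell counts 309 per
sheet, below ideal-lattice density (its cell was relaxed with a
tight-binding model whose optimized vectors and vacancy structure are not
tabulated).  The supercell builder therefore accepts a per-sheet atom
budget, default 309, trimming the outermost atoms symmetrically, so the
default supercell reproduces the 618 + 260 = 878-atom composition exactly.

**DPPC** is generated from a deterministic internal-coordinate recipe:
choline and phosphate head, glycerol backbone, and two palmitoyl tails on
parallel all-anti zigzag lanes about 4 Angstrom apart, with standard bond
lengths (C-C 1.54, C-H 1.09, C-O 1.43, P-O 1.60, C-N 1.47 Angstrom).  Only
the element composition is treated as authoritative; the conformation is a
generic physically reasonable starting geometry, not an equilibrium
conformer, and the first conjugate-gradient relaxation reshapes it.  A
0.01-Angstrom seeded jitter breaks exact collinearities; the same seed gives
byte-identical coordinates.

**The capped tube** rolls the same honeycomb lattice into a cylinder and
continues it past one end, projecting the overhang onto a hemisphere of the
tube radius (arc length preserved along the meridian; crowded near-pole
sites are pruned by a 0.9-Angstrom minimum-distance filter).  The tip is
rigid in every protocol, so cap chemistry is cosmetic; what matters is that
it presents a smooth closed end to the film.

**Tiling** translates copies by the supercell's bounding-box extent plus a
1.42-Angstrom clearance per in-plane axis.  Exact-extent translation would
map boundary atoms of adjacent copies onto each other (the cropped flake is
mirror-symmetric), hence the clearance.  The fragment is an explicitly
finite structure; no periodic boundary conditions anywhere in the package.

# The molecular-mechanics engine

The energy is a compact AMBER-style sum: harmonic bonds $k(r-r_0)^2$ and
angles $k(\theta-\theta_0)^2$, cosine torsions $\tfrac{V}{2}(1+\cos(n\phi-
\gamma))$, and 12-6 Lennard-Jones with Lorentz-Berthelot combining, 1-2/1-3
exclusion, half-scaled 1-4 pairs, and plain truncation at 12 Angstrom (no
switching function).  Fixed-charge Coulomb with the same cutoff is available
but off by default: the mechanical and adhesion response of this system is
dominated by dispersion, and no reliable charge assignment for the
unterminated flakes exists.  Parameters are a small documented table with
GAFF-like magnitudes for C, H, N, O, P; carbon is typed `CA` (no bonded
hydrogen: graphitic and carbonyl) or `CT` (aliphatic).  This is deliberately
*not* a reproduction of any specific commercial AMBER parameterization, and
absolute energies are not comparable to published tables; all conclusions
the package draws are based on differences and orderings, which is also how
its tests are written.

Every term is split equally among its participating atoms (bond 1/2, angle
1/3, torsion 1/4, pair 1/2), giving a per-atom energy partition that sums
to the total exactly (asserted to 1e-8 relative in the tests).  This
partition is the $E_i$ entering the stress map.  The inner loop (pair list,
energies, analytic gradient) is C++ via Rcpp; analytic forces are verified
against central finite differences at 1e-5 kcal/mol/Angstrom.

# Relaxation

Geometry relaxation is Fletcher-Reeves conjugate gradients
($\beta = \lVert g_{new}\rVert^2 / \lVert g_{old}\rVert^2$) with an Armijo
backtracking line search (sufficient-decrease constant 1e-4, shrink 0.5,
warm-started trial step capped so no atom moves more than 0.5 Angstrom per
trial), direction reset to steepest descent every 3N iterations and whenever
the conjugate direction stops being a descent direction.  The stopping rule
is an RMS Cartesian gradient over the free atoms of 0.1 kcal/(mol Angstrom).
Accepted-step energies are non-increasing by construction, and frozen atoms'
coordinates are preserved bit-identically.  Near the tolerance the line
search can stall (steps of a few 1e-4 Angstrom); such relaxations are
flagged `converged = FALSE` and the protocol continues with a warning rather
than aborting — the flag is honest bookkeeping, not an error state.

# The indentation protocol

The tip is fully rigid (frozen) and advances in 0.5-Angstrom steps along the
axis; after every step the composite is relaxed, and the record stores the
total energy, the adhesion energy, and the per-layer maximum local stress.
A 3-Angstrom outer margin of both sheets is frozen — the film is finite, and
without the margin the whole composite would translate rigidly away from the
tip instead of deforming.  The forward stroke runs to a configured maximum
coordinate, the reverse stroke retraces to the start.

The adhesion energy is the decomposition
$E_{ADH} = E_{TOT} - E_{DPPC} - E_{UP} - E_{LOW}$
with each part evaluated in isolation at its current coordinates ($E_{TOT}$
is the composite's energy; the tip is excluded).  Since no bonds cross group
boundaries this equals the summed cross-group nonbonded interaction, and it
is negative when the parts bind.

Key points are reported as mechanism-tagged extrema per stroke — discrete
local minima/maxima of the total energy (plateaus flagged at their first
index), the step of maximum $|E_{ADH}|$, and the step of maximum MLS — with
letters assigned in stroke order.  Published accounts of such runs label
their key points by a narrative mix of criteria; a detector has to commit to
reproducible rules, and these are they.

# Local stress

The per-atom stress is the absolute change of the atom's energy volume
density against the pre-indentation reference:
$\sigma_i = |w_i - w_0|$, $w = E_i / V_i$, $V_i = \tfrac{4}{3}\pi r^3$ with
$r = 1.7$ Angstrom (20.579 cubic Angstrom).  Both $E_i$ and the reference
are evaluated over the composite subsystem in isolation, so the map reflects
deformation transmitted through the film rather than the tip's direct
interaction terms, and the reference state (the relaxed initial scene)
gives an identically zero map.  Converting the per-mole energy density to
pressure uses 1 kcal/mol/Angstrom^3 = 6.9477 GPa (4184 J per kcal over
Avogadro's number, per 1e-30 cubic meters); the maps are reported in GPa.
MLS (maximum local stress) is taken over graphene layers only, matching how
such maps are reported for this system; lipid atoms are mapped but excluded
from the layer maxima.

# Mulliken analysis

Charge bookkeeping uses standard Mulliken populations: density matrix
$P = \sum_k f_k c_k c_k^T$ from the occupied generalized eigenvectors of
$HC = SCE$ (solved by Cholesky reduction to a symmetric standard problem),
gross atomic population $GAP_A = \sum_{\mu \in A} (PS)_{\mu\mu}$, and charge
$q_A = Z_A - GAP_A$.  Orbitals fill aufbau, two electrons each; a partially
occupied degenerate frontier shell is split equally over its members, which
keeps the result deterministic and symmetry-respecting.

The electronic backend is a *toy tight-binding surrogate*, not a
self-consistent calculation: one orbital per heavy atom, element-wise onsite
energies, hoppings and overlaps decaying exponentially with distance
(reference bond 1.42 Angstrom, decay 0.45 Angstrom, cutoff 4 Angstrom).
$Z_A$ is the electron count each atom contributes to this minimal basis
(C/N/P 1, O 2) — using atomic numbers against a valence basis would make
even a neutral system appear charged.  The onsite ordering (carbon deepest)
is chosen so the composite reproduces the donor direction seen in
self-consistent reference calculations of this system: the lipids donate
charge to the sheets and the group charges sum to zero.  Group magnitudes
from this surrogate are qualitative; the per-atom machinery (`solve_electronic`,
`mulliken_charges`, `group_charges`) also accepts Hamiltonian/overlap/
occupation data from plain-text matrix files, so charges computed by an
external electronic-structure code can be re-analyzed with the same
bookkeeping.

# Problem sizes, defaults and what the tests show

The full published-scale protocol (7902-atom film, 50.62-Angstrom tip,
stroke to +17.4 Angstrom) is exposed through the same functions and
defaults, but the package's own analyses and acceptance checks run a
scaled-down study: one 878-atom supercell, a 12-Angstrom capped (16,0)
tube, forward stroke to +4.4 Angstrom (about 17 loading steps past the
tabulated point-A and point-E analogues) and full retraction — roughly five
minutes of compute.  On that system the package reproduces the qualitative
response reported for the full one: a total-energy minimum at tip-film vdW
contact before the repulsive rise, monotone MLS growth through the loading
regime with collapse on retraction, and adhesion that remains stronger after
full retraction than before indentation (the trough the tip leaves keeps
sheet and lipid in closer contact; the lipid rearrangements are not undone
by local minimization).

What passing these checks does *not* show: agreement with any specific
published energy or stress value (different force-field parameterization,
smaller film, shallower stroke), chemical realism of the DPPC conformer, or
electronic-structure accuracy of the surrogate charges.  Orderings and
conservation laws transfer; magnitudes do not.

Other numerical choices worth knowing: relaxations that hit the iteration
cap are flagged, warned about, and kept (quasi-static runs tolerate slightly
unconverged intermediate states; the stress reference state is given a
larger cap); degenerate torsions (collinear triples) contribute zero rather
than NaN; the flake/tile/cap builders are pure functions of their arguments
and seed, so every analysis in `analysis/` is re-runnable bit-identically.

# Known limitations

- The force field is a stand-in: no aromatic conjugation, no electrostatics
  by default, harmonic bonds that cannot break.  Deep indentation therefore
  strains bonds that a reactive model would rupture.
- The lipid conformer is synthetic; real DPPC in a confined film would
  start from a thermalized ensemble, not a single all-anti geometry.
- The film is finite with frozen margins; long-wavelength sheet modes are
  suppressed, and absolute MLS values scale with the chosen margin.
- The electronic surrogate is non-self-consistent; its group charges have
  the right sign structure and conservation, nothing more.
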