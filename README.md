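# ellipack

Ellipsoid-packing analysis of organic molecular crystals via persistent
homology.

Many organic crystals — polycyclic aromatics in particular — pack their
molecules the way identical ellipsoids pack densely in space, and the
densest packings of identical ellipsoids are exactly the affine images
of the densest sphere packings. `ellipack` exploits this: given a
crystal's unit cell and the fractional coordinates of its molecular
centroids, it

1. **identifies** whether the centroid arrangement is an affine
   transformation of one of the four basic cubic Bravais lattices —
   primitive (P), base-centered (C), body-centered (I), face-centered
   (F) — by topological data analysis,
2. **estimates** the radii of the identical ellipsoids packed at those
   centroids (an approximation of the intracrystalline molecular
   shape), and
3. **predicts** those radii directly from the single molecule's circular
   fingerprint (ECFP) with a small feedforward neural network.

It is aimed at crystal-structure-prediction and organic-semiconductor
workflows where a fast geometric proxy for molecular shape in the
crystal is useful.

## Method

The unit cell (a parallelepiped) is mapped by the affine transformation
*W* = α·*A*⁻¹ onto a cube of side α = 0.1 nm, where *A* is the cell
matrix. The boundary-completed centroid motif in the cube is analyzed by
persistent homology under a growing-ball (Čech) filtration: each
topological feature — connected component (*q* = 0), ring (*q* = 1),
cavity (*q* = 2) — contributes a (birth, death) pair of ball radii to the
persistence diagram *D*<sub>*q*</sub>. The crystal is assigned type Z if

&nbsp;&nbsp;&nbsp;&nbsp;min<sub>*q*=0,1,2</sub>
*d*<sub>B</sub>(*D*<sub>*q*</sub>(*P*<sub>M</sub>),
*D*<sub>*q*</sub>(*P*<sub>Z</sub>)) &lt; ε,&nbsp;&nbsp; ε = 0.001 nm,

where *d*<sub>B</sub> is the bottleneck distance and
*P*<sub>Z</sub> the reference motif of lattice Z (a strict
max-over-*q* mode is also provided). For an identified crystal the
packed ellipsoid {**v** : **v**ᵀ*Q***v** = 1} has
*Q* = *W*ᵀ*R*<sub>Z</sub>*W*, with *R*<sub>Z</sub> the diagonal form of
the reference ellipsoids that touch along nearest-neighbour directions
in the cube; the semi-axes are *r*<sub>*i*</sub> = 1/√λ<sub>*i*</sub>
with λ<sub>*i*</sub> the eigenvalues of *Q*, reported as
*r*₁ ≥ *r*₂ ≥ *r*₃ (nm), and the ellipsoid volume is
*V* = (4/3)π *r*₁ *r*₂ *r*₃. For a type-F crystal the four ellipsoids
per cell always fill π/√18 ≈ 0.74048 of it, whatever the affine map — a
strong end-to-end invariant used in testing.

The learning stage trains a one-hidden-layer network (64 tanh units,
linear 3-output) on (fingerprint → *r*₁, *r*₂, *r*₃) pairs by mini-batch
Adam (learning rate 0.001, batch 32), with 10 % of the training data
held out for early stopping, evaluated by k-fold cross validation.

All persistence machinery (exact Čech filtration via minimum enclosing
balls, Z/2 boundary-matrix reduction, exact bottleneck distance via
binary search + bipartite matching) is implemented in the package and
validated against independent oracles in the test suite.

## Worked example

```r
library(ellipack)

## a synthetic crystal: the F motif in a triclinic cell
cell <- cell_parameters(0.4, 0.5, 0.6, 80, 95, 100)   # nm, degrees
syn  <- generate_crystal("F", cell = cell)

a <- classify(syn$crystal)
print(a)
#> Lattice assignment: F  (epsilon = 0.001 nm, aggregate = min)
#> Aggregated bottleneck scores (nm):
#>        P        C        I        F
#> 0.007946 0.004588 0.002735 0.000000

sh <- estimate_ellipsoid(syn$crystal, a)
print(sh)
#> Ellipsoid (type F): r1 = 0.2195, r2 = 0.1719, r3 = 0.1361 nm; V = 0.02151 nm^3

ellipsoid_volume(sh, per_mole = TRUE)
#> [1] 12.952                      # cm^3/mol

4 * sh$volume_nm3 / abs(det(cell_matrix(cell)))
#> [1] 0.7404805                   # = pi/sqrt(18): F packs at 74.048 %
```

The scores say: the crystal's persistence diagrams coincide exactly
(distance 0) with the type-F reference and are two to eight thousandths
of a nanometre away from the other three — far above ε for them, so the
assignment is unambiguous. The estimated semi-axes are the planted
ground truth of the generator, and the packing fraction reproduces the
closest-packing constant.

Crystal I/O uses a plain CSV/JSON format (see `read_crystals()`), and
`inst/cli/ellipack` exposes `classify`, `estimate`, `simulate`, `train`
and `predict` subcommands for shell use.

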