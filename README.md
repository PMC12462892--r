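# hodgecube

Discrete de Rham–Hodge analysis of volumetric shapes on regular Cartesian
grids: Hodge and boundary-induced graph (BIG) Laplacians for sublevel-set
manifolds, Betti numbers from Laplacian kernels, spectral curves along
level-set filtrations, persistent Hodge/BIG Laplacians via discrete harmonic
extension, and element-specific topological feature vectors for
protein–ligand complexes.

## Who this is for

Researchers in structural bioinformatics and topological data analysis who
have data *on a manifold* — a signed-distance field, a density map, a
molecular surface — rather than a point cloud, and who want spectral
invariants (kernel dimensions = Betti numbers, first nonzero eigenvalues)
that track how topology and geometry change across a filtration.

## The method in brief

A solid `M = {x : f(x) <= c}` is discretized on a cubical complex.  Cells
are restricted to *normal* or *tangential* supports (a cell is kept iff one
of its primal, resp. dual-cell, vertices is inside `M`), giving restricted
incidence operators `D_k` with exact nilpotency.  Per degree `k = 0..3` the
package assembles

    L_k = t(D_k) S_{k+1} D_k + S_k D_{k-1} S_{k-1}^{-1} t(D_{k-1}) S_k

with boundary-adjusted diagonal Hodge stars `S_k` (fractional cut-cell
volumes), and its star-free BIG counterpart.  Under the normal condition
`dim ker L_{k,n} = beta_{3-k}(M)`; the nonzero spectrum splits into the
T/C/N singular families of the three normalized differentials.  Across a
nested family of isovalues, k-forms are carried forward by a discrete
harmonic extension `I_{l,p}`, giving p-persistent Laplacians whose kernels
count cohomology classes that survive from level `l` to `l+p`.  For
molecules, the level-set function is the FRI density
`rho(x) = -sum_i exp(-(||x-x_i||/(tau r_i))^2)`.

## Worked example

Four unit balls at the vertices of a regular tetrahedron (edge 3), swept
through their offset filtration:

```r
library(hodgecube)
four_ball <- sdf_primitive("four_ball_model", edge = 3, radius = 1)
sp <- (3 / (2 * sqrt(2))) / 8               # centers on lattice points
grid <- build_grid_complex(c(47, 47, 47), sp, origin = rep(-23 * sp, 3))
curves <- spectral_curves(four_ball, grid, seq(0.2, 0.85, length.out = 20),
                          variant = "big", eigenvalues = "T")
curves[c(1, 7, 8, 11, 14, 16, 20),
       c("isovalue", "beta0", "beta1", "beta2", "lambda1T")]
#>    isovalue beta0 beta1 beta2 lambda1T
#> 1    0.2000     4     0     0 0.043604
#> 7    0.4053     4     0     0 0.032678
#> 8    0.4395     1     3     0 0.002662
#> 11   0.5421     1     3     0 0.004436
#> 14   0.6447     1     0     1 0.005153
#> 16   0.7132     1     0     0 0.005279
#> 20   0.8500     1     0     0 0.005292
```

Reading the rows: the four components (`beta0 = 4`) merge into one at the
offset where the balls touch, and `lambda1T` — the Fiedler-like first
nonzero eigenvalue of the degree-3 BIG Laplacian — drops discontinuously at
that same isovalue.  The merged body is a thickened tetrahedron skeleton
with three independent tunnels (`beta1 = 3`); the tunnels fill and briefly
trap a central cavity (`beta2 = 1`), which then fills too, leaving a ball.
(Exact eigenvalues vary in the third digit with grid alignment; Betti
numbers are exact kernel dimensions.)

A two-line molecular example:

```r
st <- read_structures("complex_protein.pdb", "complex_ligand.mol2")
fv <- featurize_complex(st$protein, st$ligand, featurize_config(k = 5))
length(fv)   # 2160 = (5+1) x 9 isovalues x 40 element pairs
```

There is also a thin command-line front end (`inst/cli/phl.R`) with
subcommands `shapes`, `spectra`, `persist`, `featurize` and `selftest`, and
NRRD/CSV/JSON/Matrix-Market I/O throughout.

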