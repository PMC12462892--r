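---
title: "Persistent Hodge and BIG Laplacians on Cubical Grids: Methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Persistent Hodge and BIG Laplacians on Cubical Grids: Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hodgecube)
```

## The model

A solid region $M \subset \mathbb{R}^3$ is represented in Eulerian form as a
sublevel set $M = \{x : f(x) \le c\}$ of a level-set function $f$ sampled on
a regular Cartesian grid with spacing $\ell$.  The grid is treated as a
cubical cell complex — vertices, axis-aligned edges, faces and cubes — with
discrete differential $k$-forms stored as one value per $k$-cell and the
exterior derivative encoded by the signed incidence operators $D_k$
($D_{k+1} D_k = 0$ exactly, in integer arithmetic).

Boundary conditions are imposed by restriction to *supports*: under the
normal (Dirichlet-type) condition a cell is retained iff at least one of its
vertices lies inside or on the boundary of $M$; under the tangential
(Neumann-type) condition iff at least one corner of its *dual* cell — a
center of an incident cube — does.  Neither support contains the other in
general.  Restricted differentials $D_{k,\mathrm{bc}} = P_{k+1} D_k P_k^T$
retain exact nilpotency.

Two operator families are assembled per degree $k = 0..3$:

* the **Hodge Laplacian** $L_k = D_k^T S_{k+1} D_k +
  S_k D_{k-1} S_{k-1}^{-1} D_{k-1}^T S_k$, with diagonal Hodge stars $S_k$
  whose interior entries are the dual/primal volume ratio $\ell^{3-2k}$ and
  whose boundary entries use fractional cut-cell volumes (normal condition:
  fractional primal volume in the denominator; tangential: fractional dual
  volume in the numerator);
* the **BIG (boundary-induced graph) Laplacian**, the same formula with all
  stars replaced by the identity.  BIG spectra converge to Hodge spectra up
  to the scaling $\ell^{-2}$ under refinement.

The Hodge operator is stored in symmetrized form
$\bar L_k = S_k^{-1/2} L_k S_k^{-1/2}$, whose ordinary eigenvalues equal the
generalized eigenvalues of $(L_k, S_k)$; the diagonal transform is kept so
eigenvectors can be mapped back.

Under the normal condition the kernel dimension of the degree-$k$ operator
equals the Betti number $\beta_{3-k}$ of $M$: components from $L_{3,n}$,
tunnels from $L_{2,n}$, cavities from $L_{1,n}$.  The nonzero spectrum of
every $\bar L_k$ is the union of squared nonzero singular values of the
normalized differentials $\bar D_k$; across all degrees these fall into
three families — $N$ from $\bar D_0$, $C$ from $\bar D_1$, $T$ from
$\bar D_2$.  The $T$ label (gradients of *tangential* scalar fields)
attaches to $\bar D_2$ through the primal/dual duality: tangential 0-forms
live on the $\ell/2$-shifted dual grid, where their gradient corresponds to
the primal degree-2 differential.  Along a filtration we track
$(\beta_0, \beta_1, \beta_2)$ and the first nonzero eigenvalues
$\lambda_1^T, \lambda_1^C, \lambda_1^N$: discontinuities mark topological
transitions, the trends between them are geometric.

## Betti numbers: how zeros are counted

The zero eigenvalue count of a PSD operator is ambiguous in floating point,
so the package's default is exact: with $D_{k+1} D_k = 0$ the ranks add,
$\dim\ker L_k = N_k - \operatorname{rank} D_k -
\operatorname{rank} D_{k-1}$, and ranks of the restricted incidence
operators are computed over GF(46337) by sparse elimination (cubical
complexes embedded in $\mathbb{R}^3$ are torsion-free, so the finite-field
rank equals the real rank; a large prime sidesteps even 2-torsion concerns).
The ranks of $D_0$ and $D_2$ reduce to union-find on anchored graph
components, leaving one elimination per isovalue.  The numerical
alternative (`method = "eigen"`) counts eigenvalues below
$10^{-8} + 10^{-6}\hat\lambda_{\max}$, with $\hat\lambda_{\max}$ a
deterministic power-iteration estimate; eigenvalues within a decade of the
threshold raise an ambiguity flag.  The two methods are asserted equal on
every test shape.

Eigenvalues are computed densely below 2,000 unknowns and otherwise by
ARPACK in shift-invert mode (Cholesky factorization of $L + \sigma I$,
$\sigma = 10^{-8}\hat\lambda_{\max}$, fixed deterministic start vector).
$\lambda_1^N$ and $\lambda_1^T$ are the first nonzero eigenvalues of $L_0$
and $L_3$, whose kernel dimensions are known exactly from the rank path;
$\lambda_1^C$ is extracted from $L_2$, classifying each computed eigenpair
into the $C$ family (image of $D_1$, where $\|D_1^T v\| > \|D_2 v\|$) or
the $T$ family, and widening the eigenvalue window until a $C$ value
appears.

## Regularization of sub-resolution exterior slivers

A finding that shaped the implementation: applied verbatim, the
vertex-inclusion support rule produces *refinement-invariant* spurious
harmonic forms whenever the sublevel boundary has a shallow oblique crease
— for example where two offset spheres of a merging union intersect.  Near
the crease the exterior wedge is thinner than one grid cell, so isolated
outside lattice points become completely enclosed by kept cells; each such
stranded point (or chain of points along the crease) generates an exact
zero eigenvalue that reads as an extra tunnel or cavity.  The artifact is
localized at the lens rims, is absent for grid-aligned creases, and does
not shrink under refinement (the sub-cell wedge region is self-similar), so
it cannot be escaped by choosing a finer grid.

The package therefore regularizes the classification samples with
`close_slivers()`: any outside sample whose incident cubes all contain an
inside sample is pushed inside (to $c - 10^{-5}\ell$), iterated to a fixed
point.  This is an extension of the $\epsilon$-perturbation policy — it
declares features thinner than one cell unrepresentable and resolves them
inward — and it is monotone in the isovalue, so nested filtrations stay
nested.  Resolvable features are untouched: the ball, torus and genus-3
test fields are bitwise unchanged away from their transition isovalues.
With the regularization the four-ball trajectories below are clean step
functions; without it the merge window shows double-digit spurious
$\beta_1$ at every spacing we tried (0.13 down to 0.04).  It is on by
default (`regularize = TRUE`) and can be disabled to study the raw rule.

## Persistence

A strictly increasing isovalue sequence yields nested normal supports
$K_1 \subset \cdots \subset K_s$.  A $k$-form on $K_l$ is extended to
$K_{l+p}$ by the *discrete harmonic extension* $I_{l,p}$: identity on the
old cells, and $d\tilde\zeta$ on new cells, where the potential
$\tilde\zeta$ on new $(k{-}1)$-cells solves the difference-complex Laplace
system driven by the boundary codifferential of the input form
(minimum-norm least-squares with relative tolerance $10^{-10}$ when the
difference region carries topology; the solve is dense, which is intended —
the difference region is assumed small).  At $k = 0$ no lower-degree
potential exists; new vertex values are filled by the degree-0 Laplace
solve with Dirichlet data from the old vertices.  For the Hodge variant
the identity block is rescaled by the star ratio of the shared cells.

The $p$-persistent Laplacian on level-$l$ $k$-forms is
$\tilde d \tilde\delta + \delta_l d_l$ with
$\tilde\delta = \delta_{l+p} \circ I_{l,p}$ and $\tilde d$ its adjoint
under the level-$l$ and level-$(l+p)$ inner products
($\tilde D = S_{k,l}^{-1} I^T S_{k,l+p} D_{l+p}$; the BIG variant sets all
stars to the identity).  Persistent nilpotency
$D_l^k \tilde D^{k-1}_{l,p} = 0$ holds to machine precision.  Its kernel
dimension is the $p$-persistent Betti number; at degree 3 it matches exact
union-find persistent component counting on every tested filtration, and it
is non-increasing in $p$.  The *restriction* back to level $l$ is
implemented as the inner-product projection
$(I^T S I)^{-1} I^T S$, which satisfies $R \circ I = \mathrm{id}$ exactly;
the bare adjoint form $S^{-1} I^T S$ is not a left inverse once the
harmonic fill-in is nonzero.  One more discretization caveat: a form that
is co-exact only up to the moving boundary leaves an $O(h)$ fill-in; the
exact-zero extension property holds for potentials supported away from
$\partial K_l$.

## Synthetic study shapes

The demonstration fields are analytic: an exact ball SDF; an exact solid
torus (major radius 2, minor 0.6); a genus-3 handlebody (rounded box of
half-extents $(1.6, 1.0, 0.8)$ minus three $z$-parallel cylindrical tunnels
of radius 0.35 at $x \in \{-1, 0, 1\}$); and the four-ball model — unit
balls at the vertices of a regular tetrahedron of edge 3, combined by
pointwise minimum.  Offsetting by the isovalue is the filtration mechanism,
so no re-distancing is performed; the min-union is a valid level-set
function with the correct sign structure, not an exact distance.

The four-ball geometry forces the transition sequence: components merge at
offset $0.5$ (half the surface gap), the three tunnels of the resulting
thickened tetrahedron skeleton fill at $3/\sqrt3 - 1 \approx 0.732$, and
the central cavity fills at the circumradius $3\sqrt{3/8} - 1 \approx
0.837$.  The canonical study conditions, chosen from this geometry before
any spectra were computed, are a $47^3$ grid with spacing
$\ell = (3/(2\sqrt2))/8 \approx 0.133$ (placing the ball centers and
contact points on lattice points) and 20 evenly spaced isovalues in
$[0.2, 0.85]$.  Transitions register about one cell early because the
support rule dilates by up to a cell — e.g. the discrete merge occurs near
offset $0.42$ — but the plateau values $\beta_0: 4 \to 1$,
$\beta_1: 0 \to 3 \to 0$, $\beta_2: 0 \to 1 \to 0$ are exact, and
$\lambda_1^T$ drops discontinuously at the merge.

What these fields do *not* emulate: scanned-surface models with fine
geometric texture, noisy experimental density maps, and level sets whose
critical points cluster closer than the isovalue step.  Passing tests on
them validates operator assembly, kernel counting and persistence, not
robustness to measurement noise.

## Molecular featurization

For protein-ligand complexes the level-set function is the
flexibility-rigidity-index (FRI) density
$\rho(x,\tau) = -\sum_i \exp(-(\|x - x_i\|/(\tau r_i))^2)$ over a selected
atom set, with Bondi van der Waals radii and $\tau = 1$ by default ($\tau$
is deliberately configurable: it is a modeling scale, not a fitted
constant).  Selections follow the element-specific scheme: 40 pairs of a
protein element in $\{C,N,O,S\}$ (hydrogens ignored in proteins) with a
ligand element in $\{H,C,N,O,S,P,F,Cl,Br,I\}$; a pair keeps the protein
atoms of its element within 12 Å of *any* ligand atom plus all ligand atoms
of its element.  Per pair, the density is sampled on a grid of spacing
0.549 Å covering the selection's bounding box plus a margin
$\tau r_{\max}\sqrt{\ln(n/10^{-3})}$ that keeps $\rho$ above every isovalue
at the boundary; nine evenly spaced isovalues in $[-0.5, -0.001]$ define
the filtration.  The feature block per pair and isovalue is $\beta_0$ (the
kernel dimension of the BIG $L_{3,n}$) followed by its first $k$ nonzero
eigenvalues, zero-padded when a tiny manifold has fewer — giving
$(k{+}1) \times 9 \times 40$ features (2,160 at $k=5$, 3,960 at $k=10$).
Components smaller than 8 cubes trigger one automatic spacing halving, then
a logged warning.  Binding-affinity regression and sequence embeddings are
out of scope; the package stops at the feature matrix.

## Numerical choices and problem sizes

* Fractional cut-cell measures: exact linear interpolation on edges;
  deterministic dyadic midpoint subdivision of the bi/trilinear corner
  interpolant on faces, cubes and dual cells (depth 4 = 4,096 samples per
  cube; the depth is exposed).  Fractions are floored at $10^{-5}$ so star
  entries stay bounded.
* Exact ties $f = c$ are perturbed *inside* ($c - 10^{-5}\ell$), matching
  the closed sublevel convention.
* Grids are sized so the manifold stays at least one spacing from the grid
  boundary (a validator warns otherwise); the primal-normal vs.
  shifted-dual-tangential spectral equivalence holds under this condition
  and is tested at $10^{-8}$.
* Degenerate degrees (empty supports) propagate as empty operators and
  "no spectrum", never as errors.
* Default problem sizes: $47^3$ for the four-ball and torus Betti sweeps,
  $31^3$ for eigenvalue curves involving the degree-2 operator, $\le 21^3$
  for persistence examples (the harmonic-extension solve is dense).  These
  run in minutes on one CPU and are the sizes used by the shipped tests and
  the reproduction script.

## Known limitations

* The sliver regularization resolves sub-cell features inward by fiat;
  features genuinely at the grid scale die up to one cell early in the
  filtration.  Transition *isovalues* are therefore accurate only to
  $O(\ell)$, while plateau *values* are exact.
* Fractional volumes use interpolant subdivision, not exact polyhedral
  clipping of the trilinear isosurface.
* The composed extension $I_{l+p-1,1} \circ \cdots \circ I_{l,1}$ and the
  direct solve on the full difference complex need not coincide; the direct
  solve is canonical here and the composition is a cross-check only.
* Full-spectrum computation is dense-only; large grids expose only the
  smallest eigenvalues.

## A worked curve

```{r curves, eval = FALSE}
four_ball <- sdf_primitive("four_ball_model", edge = 3, radius = 1)
sp <- (3 / (2 * sqrt(2))) / 8
grid <- build_grid_complex(c(47, 47, 47), sp, origin = rep(-23 * sp, 3))
curves <- spectral_curves(four_ball, grid, seq(0.2, 0.85, length.out = 20),
                          variant = "big", eigenvalues = "T")
plot(curves)
```
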