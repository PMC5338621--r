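---
title: "Complete electrode model forward and inverse simulation on a synthetic neonatal head"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complete electrode model forward and inverse simulation on a synthetic neonatal head}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

cemfwd simulates electroencephalography (EEG) forward and inverse problems on
tetrahedral head meshes with finite-size electrodes. This vignette is the
package's account of the underlying science: the models, their assumptions,
the tunable parameters, the synthetic data generator, and the numerical and
design choices that were genuinely open.

## Forward model

The quasistatic electric potential $u$ in the head volume $\Omega$ obeys
$\nabla\cdot(\sigma\nabla u) = \nabla\cdot \vec j_p$, where $\vec j_p$ is the
primary (neural) current density and $\sigma$ the conductivity field,
piecewise constant per tissue compartment here.

**Complete electrode model (CEM).** Real electrodes cover a finite scalp
patch $e_\ell$ and contact the skin through an effective impedance
$\tilde Z_\ell = Z_\ell A_\ell$ ($Z_\ell$ the average contact impedance in
Ohm, $A_\ell$ the contact area). The boundary conditions are: no current
leaves the scalp outside the patches; the *net* current through each patch is
zero; and on each patch the potential jump $u - U_\ell$ is proportional to
the local normal current density. Current can therefore flow *along* the
contact (shunting), and the recorded voltage $U_\ell$ is the area average of
$u$ over the patch. The smaller $Z_\ell$, the stronger the shunting and the
flatter the potential under the electrode.

**Point electrode model (PEM).** The classical idealization: the voltage is
the potential at a single scalp point per electrode. It is the limit of the
CEM as the patch shrinks to a point.

**Discretization.** Linear (P1) nodal elements for $u$ give the block system
$$\begin{pmatrix} A & -B \\ -B^{\mathsf T} & C \end{pmatrix}
\begin{pmatrix} z \\ v \end{pmatrix} =
\begin{pmatrix} -Gx \\ 0 \end{pmatrix},$$
with $A$ = stiffness plus the impedance-weighted patch mass
$\sum_\ell \tfrac{1}{Z_\ell A_\ell}\int_{e_\ell}\psi_i\psi_j\,dS$,
$b_{i\ell} = \tfrac{1}{Z_\ell A_\ell}\int_{e_\ell}\psi_i\,dS$ and
$c_{\ell\ell} = 1/Z_\ell$. Patch surface integrals use the exact closed-form
P1 triangle mass ($\int\psi_i\psi_j\,dS = \text{area}\,(1+\delta_{ij})/12$).
The $1/(Z_\ell A_\ell)$ factor appears in both the mass term and $B$; writing
the electrode mass term without it would be dimensionally inconsistent with
$c_{\ell\ell} = 1/Z_\ell$, so the package includes it throughout.

The potential is grounded by replacing the row *and column* of one boundary
node with the identity. Symmetric grounding keeps $A$ symmetric positive
definite and is exact here because the right-hand side and the electrode
coupling both vanish at that node: the ground node is chosen
deterministically as the boundary node farthest from all electrode centers
(smallest index on ties), and sources live strictly inside the brain. CEM
and PEM share the same ground node so that model comparisons are not
contaminated by the reference choice; the average reference applied to all
outputs removes any residual dependence.

**Lead fields.** The referenced lead field is
$L = R\,(B^{\mathsf T}A^{-1}B - C)^{-1}B^{\mathsf T}A^{-1}G$ for the CEM and
$L = -R\,B'^{\mathsf T}A'^{-1}G$ for the PEM, with $R$ the average-reference
centering matrix. Three algebraically equivalent CEM routes are implemented
and cross-checked to $10^{-8}$: a sparse Cholesky transfer-matrix route
(`"schur"`), the same with Jacobi-preconditioned conjugate gradients
(`"transfer"`, relative tolerance $10^{-10}$, at most $10\sqrt N$
iterations), and a direct factorization of the full block system (`"block"`).
The PEM evaluates at the boundary node nearest each electrode center by
default (one unit entry per column of $B'$); a barycentric interpolation
mode exists for point placements that should not snap, e.g. the
patch-shrinking limit study.

## Whitney dipole sources

Sources are face-based synthetic dipoles: for an interior face $F$ shared by
two brain tetrahedra with opposite nodes $P_i$, $P_j$, the dipole sits at the
midpoint of $P_i P_j$ with unit moment $\hat q = (r_{P_j}-r_{P_i})/d$,
$d = \lVert r_{P_j}-r_{P_i}\rVert$. The associated Raviart–Thomas-type
basis function $\vec w$ is supported on the two tetrahedra, has continuous
normal flux across $F$, and is normalized so that $\int \vec w\,dV = \hat q$
— the physical dipole moment convention. Under that normalization the source
column is $g_{P_i} = +1/d$, $g_{P_j} = -1/d$ (two entries, zero sum), which
makes the right-hand side $-Gx$ the standard weak dipole load
$q\cdot\nabla\psi$. The package fixes the sign by the moment convention
because the homogeneous-sphere oracle checks the lead field's absolute sign;
an independent quadrature routine (`whitney_quadrature_column()`) rebuilds
each column and the moment integral from first principles and is compared
against the closed form in the tests.

Dipoles with an opposite node on the brain/CSF interface are excluded
(`exclude_surface_layers = 1`), the usual guard against material-discontinuity
outliers; deeper exclusion is configurable. On structured meshes two
different faces can carry the *same* opposite node pair; such dipoles are
exact duplicates (same position, moment and column) and the space keeps one
per unique pair.

**Eccentricity.** The relative norm of a dipole is its distance from the
head center divided by the *maximal admissible dipole radius*, so 0.98 means
"as superficial as the source space allows". The normalization reference was
an open choice (brain radius and skull radius are plausible alternatives);
tying it to the admissible set makes the most superficial band nonempty by
construction and is recorded in exported metadata.

## Minimum current estimation (IAS)

The inverse estimate minimizes
$f(x\mid y) = \lVert Lx - y\rVert_2^2 + \gamma\lVert x\rVert_1$ by the
iterative alternating sequential scheme: from $x_0 = (1,\dots,1)$, each step
solves the least-squares problem with the stacked matrix
$[L;\ \gamma^{1/2}D_{x}^{-1/2}]$, $D_x = \mathrm{diag}|x_k|$, for exactly
`n_iter` iterations (default 50). Three equivalent update routes are
implemented: the stacked QR as written, the normal equations, and a dual
(Woodbury) form $x = DL^{\mathsf T}(LDL^{\mathsf T}+\gamma I)^{-1}y$ that
costs one electrode-sized solve per iteration and is the default for
underdetermined problems. $|x_k|$ is floored at $10^{-12}$ of its maximum
inside the reweighting; the floor only matters once amplitudes collapse
toward zero and sits far below any recovered amplitude.

$\gamma$ follows the hierarchical-Bayes mapping
$\gamma = \nu^2\sqrt2/\theta_0$ with defaults $\nu = 0.001$, $\theta_0 = 1$
(so $\gamma = 1.41\times10^{-6}$); the gamma-prior shape $\beta = 3/2$ is
carried for provenance but does not enter the iteration. Because $\gamma$ is
an absolute number, the experiments normalize each data vector to unit
$\ell_2$ norm before inversion (`normalize_data = TRUE`), which makes
$\nu$ a *relative* noise level — the interpretation under which the printed
value is meaningful. No noise is added to synthetic data by default; $\nu$
enters only through $\gamma$.

The single-dipole summary is the $|x|$-weighted average of dipole positions
and unit moments. The averaged moment is deliberately not renormalized: the
angular difference is scale-invariant, and exported moments are flagged as
non-unit. IAS is not guaranteed monotone in $f$; the objective trace is
recorded per iteration instead of asserted.

## Comparison measures

RDM ($100\,\lVert u_1/\lVert u_1\rVert - u_2/\lVert u_2\rVert\rVert$,
topography mismatch, 0–200) and MAG
($100\,\lVert u_2\rVert/\lVert u_1\rVert - 100$) compare forward solutions;
PD (Euclidean distance, reported in mm), AD (angle in degrees, dot product
clamped before `acos`) and ND compare dipoles. ND is implemented literally
as $\lVert r_{\text{true}}\rVert - \lVert r_{\text{est}}\rVert$, under which
a *positive* value means the estimate lies deeper than the truth; because
that sign convention is easy to misread, the experiment tables also carry an
explicit `depth_bias = -ND` column. Box-plot summaries use type-7
(linearly interpolated) quartiles, the R default; the convention was
unspecified and is fixed here.

## The synthetic head and what it does (not) emulate

No real neonatal MRI mesh ships with the package; `build_sphere_head()`
generates a four-shell ball standing in for it:

| parameter | default | why |
|---|---|---|
| shell radii (m) | 0.038 / 0.042 / 0.046 / 0.050 | 50 mm scalp radius is a realistic 3-day-old head; 4 mm CSF, skull and scalp shells |
| conductivities (S/m) | scalp 0.33, skull 0.04, fontanel 0.30, CSF 1.79, brain 0.33 | the three tabulated tissue models (I open skull, II closed, III bone 0.10) |
| fontanels | one anterior cone (half-angle 0.45 rad) near the vertex, two lateral cones (0.2 rad) | unossified openings; the real geometry is unavailable, cones are the simplest solid-angle stand-in |
| electrodes | 74 centers, Fibonacci spiral over the upper 65 % of the sphere, 5 mm contact radius | 74-channel cap of 10 mm contacts; no published montage coordinates, so a deterministic quasi-uniform layout with a vertex "Fz-like" and 5th "C6-like" electrode |
| resolution `n` | 8 (`build_sphere_head`), 11 (`experiment_config`) | see below |
| `jitter` | 0.25 | see below |

The mesh is a spherified-cube lattice: a $2n^3$-cell cube grid split into six
tetrahedra per cell (conforming across cells) and mapped radially so that
three lattice shells land *exactly* on the CSF, skull and scalp interfaces;
labels follow centroid radius, and skull tetrahedra whose centroid direction
falls inside a fontanel cone are relabelled. Strictly interior brain nodes
receive a seeded uniform jitter of up to 0.25 of the local radial spacing.
The jitter exists because the raw lattice quantizes dipole radii: several
eccentricity bands ($\pm0.02$ of relative norm) would otherwise be empty and
the 5-level × 100-source sampling design infeasible. It also breaks the
worst grid anisotropy. Displacements this small cannot invert elements; the
constructor verifies positive volumes regardless.

Resolution defaults are convergence choices, not quoted values: the mesh
volume is within 2 % of the analytic ball volume from $n = 6$; the
homogeneous-sphere PEM solution agrees with the analytic dipole potential to
a median RDM of about 4 % at $n = 8$ and better at $n = 10$; and $n = 11$
(~64k tetrahedra) is the smallest resolution at which every eccentricity
band holds at least 100 admissible dipoles at tolerance 0.02, which the full
experiment design needs. The shipped tests run reduced configurations
($n = 5$–9, 8–10 sources per level, wider bands) so the suite completes in
minutes; the experiment functions accept the full design unchanged.

What the synthetic head does *not* emulate: realistic skull and fontanel
geometry (cones versus sutures), separate grey/white matter, tissue
anisotropy, a genuine 10–20 montage, or realistic mesh grading. Passing
tests therefore demonstrate the correctness and the qualitative behaviour of
the numerics (shunting monotonicity, CEM→PEM limits, open- vs closed-skull
contrasts), not absolute error levels of any particular MRI-derived head,
which depend on geometry the synthetic head does not carry.

## Test sources A and B

The two fixed 10 nAm sources used by the voltage-pattern experiment are
placed next to the C6-like (5th) electrode and under the Fz-like electrode
inside the anterior fontanel cone. Both are chosen among dipoles whose
moment is predominantly radial ($|\hat q\cdot\hat r| \ge 0.5$): a tangential
dipole peaks *away* from its overlying electrode, which would defeat the
purpose of the comparison (the local PEM outlier at the nearest electrode).
This orientation preference is a package design choice; the source
orientations were not published.

## Numerical choices and degenerate inputs

* Electrode patches are triangle sets selected by centroid distance; a
  triangle within capture distance of two centers is an *overlap error*
  naming the electrode pair, never a tie-break. Empty patches are errors.
* Forward solves verify a relative residual below $10^{-10}$ and fail
  loudly otherwise; the Schur route refuses nearly singular complements.
* Zero source vectors yield exact zero solutions; all-zero data yields a
  degenerate (flagged) zero inverse estimate; zero vectors are rejected by
  RDM/MAG and zero moments by AD.
* Meshes are validated on construction (positive volumes, single-owner
  boundary faces, outward orientation, face-count conservation
  $4T = 2F_{\text{int}} + F_{\text{bnd}}$).
* All randomness (node jitter, eccentricity sampling) flows through explicit
  integer seeds; identical configurations reproduce bitwise-identical
  tables.

## Known limitations

* The IAS position estimate is a weighted average over the whole source
  space; with the generating dipole excluded, its distance to the truth is
  of the order of the local source spacing and carries a systematic depth
  bias, so localization self-consistency should be judged against the
  source-space resolution (the validation suite bounds the median position
  error by twice the mean inter-dipole spacing), not against zero.
* Reconstructing CEM data through the PEM lead field (the model-mismatch
  design) is far more sensitive at desk scale than on a fine MRI-derived
  mesh: a few percent of topography mismatch dominates the tiny l1 penalty,
  the estimate spreads, and median position differences reach centimeters
  rather than millimeters. The mismatch *penalty* (PEM-based PD above
  matched-lead-field PD) is the robust, resolution-independent signature and
  is what the tests assert.
* Single-compartment isotropic conductivities only; no anisotropy, no
  boundary-element or finite-difference backends.
* The analytic oracle covers the homogeneous sphere; layered-sphere
  closed forms are not implemented, so multi-compartment accuracy is
  checked through invariants and limits rather than absolute values.
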