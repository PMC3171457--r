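---
title: "Exact derivatives under flexible constraints: model, kinematics, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact derivatives under flexible constraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexderiv)
```

## The model

A molecule of $N$ atoms has $3N-6$ internal coordinates: bond lengths
$b_k$, bond angles $\theta_k$ and dihedral angles $\phi_k$, each owned by
the atom $k$ they position. We split them into $M$ *unconstrained*
coordinates $u$ (here always principal dihedrals describing rotation around
single bonds) and $L = 3N-6-M$ *constrained* coordinates $d$. Flexible
constraints fix $d$ not to constants but to the minimizer of the potential
energy at each $u$:

$$ d = f(u), \qquad f(u) = \arg\min_d V(u, d). $$

$f$ exists locally by the implicit function theorem wherever the
constrained Hessian block is positive definite, but it has no closed form —
it is the output of a numerical minimization. The package's central object
is its Jacobian. Differentiating the stationarity identity
$\partial V/\partial d_I\,(u, f(u)) = 0$ with respect to $u_i$ gives

$$ H_{dd}\, J = -H_{du}, \qquad J_{Ii} = \frac{\partial f^I}{\partial u^i}, $$

with $H_{dd}$ and $H_{du}$ the constrained-constrained and
constrained-unconstrained blocks of the Hessian of $V$, evaluated **at the
minimum itself**. Because a true minimum makes $H_{dd}$ symmetric positive
definite, the system is solved by one Cholesky factorization plus $M$
triangular solves (`constrained_jacobian()`). The total derivative of any
observable restricted to the subspace follows by the chain rule
(`observable_total_derivative()`), and the hard-constraint limit ($d$
frozen, $J = 0$) reduces it to the plain partial derivative.

Two assumptions matter. First, the minimum is *local*: for molecular energy
surfaces a global search is not meaningful, so basins are selected by the
warm start `d0`, and `minimize_constrained()` certifies a posteriori that
the converged point is a minimum rather than a saddle (strict Cholesky,
smallest-eigenvalue report on failure). Second, the same coordinates stay
solvable across the region of interest; the package surfaces the condition
estimate of $H_{dd}$ and warns above $10^{12}$.

## Body-fixed kinematics

Observables of interest are often the atomic positions themselves, in a
frame fixed in the molecule: atom 1 at the origin, atom 2 on a positive
semi-axis, atom 3 in a coordinate plane. The default convention places atom
2 on $+z$ and atom 3 in the $xz$-plane with $x>0$; a second convention
(`"x-xy"`) is available and every consumer reads it from one place, so the
choice is a relabelling, not a branch. Gauge components are exact zeros by
construction, which the suite asserts as identities.

The partial derivatives $\partial x'_\beta/\partial q_k$ are purely
kinematic. A bond-length change translates every atom whose chain to the
origin passes through $k$ along the bond unit vector. An angle or dihedral
change rotates those atoms, so the derivative is the first-order term of
Rodrigues' rotation formula: the cross product of the rotation axis with
the lever arm from the fixed point (the bond-reference atom of $k$). For
bond angles the axis is the normal to the reference plane, oriented so that
a finite positive rotation increases the *measured* angle — the suite pins
this orientation with a self-consistency check rather than transcribing a
figure convention. For dihedrals the axis runs from the angle-reference
atom to the bond-reference atom, with the right-hand (cis = 0) sign
convention anchored by a planar test case.

Two branching patterns extend the mover sets beyond the chain rule.
Atoms attached to atom 2 that use atom 3 as angle reference co-rotate when
atom 3's bond angle changes; branch-start atoms positioned by a phase
dihedral co-rotate when the principal dihedral on their bond changes. Both
get the same cross-product formula with the same fixed point. Validation
enforces one structural consequence the derivation needs: atoms positioned
by the atom-2/atom-3 pattern must be terminal (they are hydrogens in real
SASMIC Z-matrices). If such an atom had children, the children's dihedral
reference (atom 1) would sit off the rotation axis and rigid co-rotation
would no longer preserve their torsion — the finite-difference motion
oracle confirms the rule breaks there, so such topologies are rejected
rather than silently mis-differentiated.

Everything on the analytic path is evaluated at the current geometry;
no finite difference enters it anywhere. Finite differences appear in this
package only as the *comparator* and in test oracles.

## The finite-difference comparator

`fd_derivative()` displaces one unconstrained coordinate, re-minimizes $d$
at the displaced point (warm-started from the undisplaced minimizer, which
reduces basin hops), and differences. The forward scheme is the default;
the central scheme is available because the validation study benefits from
its $\Delta^2$ convergence. Two failure modes are modelled explicitly:

* **Printed precision.** `truncate_precision()` rounds the minimized
  coordinates to a fixed number of decimals (half-to-even) before
  differencing, emulating output files with finite significant figures.
  For stiff coordinates (bonds, with force constants of order
  $600$ energy/Å$^2$ here) the minimizer barely moves, so small steps
  difference pure rounding noise, and the error-versus-$\Delta$ curve turns
  U-shaped with an interior optimum — the regime the exact method does not
  have.
* **Basin identity.** A large displacement can destroy the warm-start
  basin entirely; the endpoint minimizer then jumps to a different well.
  The comparator raises a basin-hop warning when any constrained coordinate
  moves more than `basin_hop_tol` (default 0.5 rad or Å) between endpoints;
  the suite exercises it on an engineered double well whose fold is crossed
  at a known displacement.

The normalized error metric averages $|FD - \text{exact}|$ over
conformations and divides by a per-coordinate normalizer. The normalizer is
kept in a single transcription point; the default is the maximum absolute
exact derivative over the conformations, which makes the metric invariant
under uniform rescaling of the compared values.

## Synthetic systems and what they do (not) show

**2D toy system.** $V(x,y) = \tfrac{a}{2}x^2 + c\,x^2 y +
\tfrac{k}{2}(y-y_0)^2 + q\,y^4$ with defaults $a=1$, $c=0.3$, $k=100$,
$y_0=1$, $q=0.5$, scanned over $x \in [-2, 2]$ at 11 points. The stiff
harmonic term dominates ($H_{yy} = k + 12qy^2 > 0$ everywhere), the
coupling makes the minimizer genuinely $x$-dependent, and the small quartic
keeps $f(x)$ implicit — there is no compact closed form to differentiate,
which is the situation the method exists for — while the Hessian entries
stay closed-form. These coefficients are this package's own calibration of
a stiff-plus-coupling toy landscape; all toy-system checks are
self-consistency checks (analytic route against extrapolated FD and against
a golden-section oracle), so nothing downstream depends on the particular
values.

**Synthetic force field.** All terms are direct functions of the internals:
harmonic bonds, angles and phase dihedrals, a cosine barrier on the
unconstrained dihedrals, and an optional adjacent-pair coupling inside the
constrained block (validated to keep $H_{dd}$ positive definite). The
equilibrium values of constrained coordinates depend on the nearest
unconstrained dihedral, e.g. $b_0(\phi) = b_{00} + c_b\cos\phi$. This
design has a deliberate property: the constrained minimizer sits exactly at
the equilibrium values for *any* positive-definite coupling, so the
constraint Jacobian has the closed form $J = \partial e/\partial u$ (e.g.
$-c_b\sin\phi$) — an independent analytic target the Hessian solve must
reproduce to $10^{-8}$, which is the package's parameter-recovery test.
Force-constant magnitudes (600/100/40 for bonds/angles/dihedrals) mirror
the stiffness ordering of real force fields so that the truncation
pathology appears on the right coordinates; the couplings
($c_b = 0.02$ Å, $c_\theta = 0.03$ rad, $c_\phi = 0.05$ rad) are small
enough to keep every scanned conformation positive definite.

**Molecule fixtures.** The methanol-like (6 atoms, one unconstrained
dihedral), NMA-like (12 atoms, three) and tri-glycine-like (26 atoms, six)
topologies follow SASMIC-style numbering with atom 1 a hydrogen, include
both branching special cases across the set, and keep principal dihedrals
over non-single (peptide-like) bonds in the constrained set. Geometries are
chemically plausible stand-ins built in code; they are not minimized
structures of any published force field, and no quantitative claim is tied
to their particular values. Conformations come from `scan_generator()`:
systematic grids for the small systems (the methanol scan is $-180^\circ$
to $180^\circ$ in $20^\circ$ steps, 19 conformations) and seeded uniform
sampling for the tri-glycine-like system, where a systematic grid would be
impractically large and the package substitutes a reproducible random scan
for a conformer-search procedure.

What passing tests show: the analytic machinery agrees with independent
oracles (matrix exponentials, BFS traversal, golden-section minimization,
Richardson-extrapolated FD with re-minimization) to the stated tolerances
on these landscapes. What they do not show: behaviour on rugged empirical
force fields with nonbonded Cartesian terms, where Hessian quality and
minimizer robustness, not the formulas, become the limiting factors.

## Numerical choices

* Tolerances: gradient $\infty$-norm $10^{-10}$ for analytic models,
  $10^{-8}$ for numeric-fallback derivatives; 500 iteration cap; all
  configurable.
* The Newton step reuses the analytic Hessian the Jacobian already needs,
  with a Levenberg shift until Cholesky succeeds and a backtracking line
  search. The acceptance test of the line search carries a few-ulp slack so
  that full Newton steps are not rejected once energy decreases fall below
  floating-point resolution; without it the iteration stalls around
  $10^{-9}$ residuals on well-conditioned problems.
* Numeric-fallback Hessians use central differences of the analytic
  gradient (step $10^{-5}$), symmetrized; this degrades the exactness
  guarantee to gradient-FD accuracy and is reported via
  `derivative_mode`.
* Degenerate geometries (collinear reference triplets, coincident bonded
  atoms) raise errors naming the atom rather than returning limits;
  the cross-product norm threshold is $10^{-10}$.
* Angles are degrees in all files and command-line surfaces, radians
  internally; indices are 1-based everywhere a user sees them. Dihedral
  arithmetic wraps to $(-\pi, \pi]$ (the boundary maps to $+\pi$).
* Problem sizes in the shipped validation: 100 random molecules with
  $N \le 10$ for the geometric-derivative sweep, 100 random quadratic
  potentials, 11 toy-system grid points, the 19-point methanol scan, and
  25 random tri-glycine starts — sizes at which every check runs in
  seconds to a couple of minutes on one core while exercising all code
  paths.

## Known limitations

* Ring closures and redundant internal-coordinate sets are out of scope;
  topologies are declared trees, not derived from connectivity.
* Second geometric derivatives $\partial^2 x'/\partial q\,\partial q$ are
  not provided (nothing in scope needs them).
* The synthetic force field has no nonbonded Cartesian terms, by design:
  keeping every term a direct function of the internals is what makes its
  Hessian closed-form and its Jacobian analytically recoverable.
* `f(u)` is only as well-defined as the basin structure: near folds where
  minima appear or disappear, the warm start decides which branch is
  followed, and the basin-hop warning is a diagnostic, not a cure.
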