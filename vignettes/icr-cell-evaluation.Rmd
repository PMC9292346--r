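---
title: "Electrostatic evaluation of ICR measuring cells: models, numerics and design choices"
author: "icrcell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electrostatic evaluation of ICR measuring cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(icrcell)
```

## The problem

In Fourier-transform ion cyclotron resonance (FT-ICR) mass spectrometry the
measuring device is a Penning trap ("ICR cell"): electrodes that superimpose
an electrostatic axial well on a homogeneous magnetic field $B$ along $z$.
An ion of mass $m$ and charge $q$ rotates at the pure cyclotron frequency
$\omega_c = qB/m$. The ideal trapping potential,

$$\varphi(x, y, z) \;=\; \alpha\!\left(z^2 - \tfrac{x^2 + y^2}{2}\right) + \chi,$$

is the simplest solution of the Laplace equation with a $z^2$ well; it
splits ion motion into three decoupled modes with the reduced cyclotron,
magnetron and axial frequencies

$$\omega_\pm = \frac{\omega_c}{2} \pm
  \sqrt{\Big(\frac{\omega_c}{2}\Big)^2 - \frac{q\alpha}{m}},
  \qquad \omega_z = \sqrt{2q\alpha/m},$$

obeying $2\omega_+\omega_- = \omega_z^2$ and
$\omega_c^2 = \omega_+^2 + \omega_-^2 + \omega_z^2$. Real electrode
assemblies only approximate the ideal field. Writing the azimuthally
averaged potential in even-order solid harmonics,

$$\bar\varphi(\rho, z) \simeq C + A_{20}\!\left(z^2 - \tfrac{\rho^2}{2}\right)
 + A_{40}\!\left(8z^4 - 24 z^2\rho^2 + 3\rho^4\right)
 + A_{60}\!\left(16 z^6 - 120 z^4 \rho^2 + 90 z^2 \rho^4 - 5\rho^6\right),$$

the higher coefficients $A_{40}, A_{60}$ make $\omega_+$ depend on position.
An excited ion cloud whose members see different $\omega_+$ shears into a
"comet" and eventually a rotating cylinder that induces no differential
signal. A rough but useful figure of merit is the comet-formation time

$$T_{\text{comet}} = \frac{2\pi}{\max_{\rho,z}\,\omega_+ - \min_{\rho,z}\,\omega_+},$$

with the extrema taken over the excited cloud's region. This package builds
the classical cell designs, computes their fields, extracts
$(A_{20}, A_{40}, A_{60})$ and $T_{\text{comet}}$, and models image-current
detection, so that the designs can be compared under one protocol.

## The evaluation protocol

`evaluate_trap()` runs, per design:

1. **Geometry** (`make_trap()`): electrode solids with applied voltages.
   Default dimensions keep the transverse size at 2.54 cm (1 in) and default
   voltages place each design at approximately the same dimensional
   $A_{20}$ as the cubic reference cell, so comet times are comparable.
2. **Field**: a closed-form series where one is exact (rectangular cells,
   closed cylinder, dynamically harmonized cell), otherwise the
   finite-difference Laplace solver (`solve_laplace()`).
3. **Azimuthal average** over the polar angle (the cyclotron motion averages
   the field the same way; for axisymmetric designs this is the identity).
4. **Least-squares fit** of the even-order basis above over the ion flight
   region $\rho \le 10$ mm, $|z| \le 10$ mm (`fit_harmonics()`).
   Dimensionless coefficients are normalized by
   $d^2 = \tfrac12\!\left(z_0^2 + \tfrac12 \rho_0^2\right)$ with per-design
   characteristic half-lengths; e.g. $A_{20}^{(n)} = A_{20} d^2$.
5. **Comet time** (`comet_time()`), with the default ion cloud: $B = 7$ T,
   $m/z = 500$, cloud radius 2 mm, excitation radius 6 mm, axial half-length
   8 mm. The $\omega_+$ extrema are searched on a dense
   $121 \times 161$ grid over
   $\rho \in [4, 8]$ mm, $z \in [-8, 8]$ mm; the search covers the full
   rectangle, not only the cloud boundary, because $\omega_+$ is a smooth
   function whose extrema may sit inside.

All stages are deterministic; rerunning a configuration reproduces rows
bit-exactly.

## Conventions and parameters

* SI units throughout: metres, volts, tesla, rad/s. $z$ is along $B$ and the
  origin is the trap centre.
* The near-centre expansion of the closed cylinder is reported as
  $V = V_{\text{trap}}\left[\gamma'' + (\alpha''/a^2)(z^2 - \rho^2/2)\right]$
  with $a = 2R$ the cell diameter. For $R = z_0$ this gives
  $\gamma'' = 0.2787$, $\alpha'' = 2.840$, consistent with the dimensionless
  $A_{20}^{(n)} \approx 0.52$–$0.53$ of the inch-sized cells at ~1 V.
* Characteristic lengths for $d$: half-edges for the rectangular cells (for
  the 7.62 × 2.54 × 2.54 cm cell, $\rho_0$ is the half-length of the longer
  transverse edge — the only choice under which its dimensionless $A_{20}$
  is mutually consistent with the cubic cell's at the same dimensional
  curvature); $(z_0, R)$ for all cylindrical, hyperbolic and harmonized
  designs.
* Physical constants: exact SI elementary charge and CODATA atomic mass
  unit, see `icr_constants()`.

## The numeric solver

`solve_laplace()` is red-black successive over-relaxation
($\omega = 1.9$) on uniform grids: axisymmetric $(\rho, z)$ with the
$1/\rho$ term (axis handled by symmetry) and Cartesian 3-D. The residual is
the maximum Gauss-Seidel displacement in volts (default target $10^{-8}$ V).
Electrode surfaces are rasterized by implicit-inequality nearest-node
snapping with zero-width inter-electrode gaps (the one design with
specified gaps, the trapping-ring cell, models them as open slits backed by
a grounded plate). Open designs are closed by a grounded box at 1.5 times
the electrode extent; for closed designs the grid boundary is the electrode
assembly itself.

Default problem sizes, chosen by grid-refinement studies
(`refine_study()`) as the point where the fitted $A_{20}$ drifts by well
under 1% between refinements: $257 \times 513$ nodes for axisymmetric
solves and 129 nodes across each transverse extent for 3-D solves. At these
sizes the solver agrees with the exact series solutions to better than
$10^{-3} V_{\text{trap}}$ away from electrode joints (pointwise convergence
is necessarily slow within ~1 mm of the joints, where the boundary data are
discontinuous). A full ten-design evaluation takes a few minutes on one
CPU; each axisymmetric design takes seconds.

## Per-design geometry notes

* **Hyperbolic cell** (Penning/Dehmelt; see Van Dyck et al.): electrode
  surfaces $2z^2 - \rho^2 = 2z_0^2$ (end caps) and
  $\rho^2 - 2z^2 = R^2$ (ring), truncated at $\rho \le 2R$.
* **Compensated hyperbolic cell** (Gabrielse 1983/1984): a compensation
  electrode in the asymptotic gap between the hyperbolae, modeled as the
  solid of revolution beyond spherical radius $r_c = 2R$ — Gabrielse showed
  the orthogonalization ratio is insensitive to the electrode's exact shape
  once it sits behind that radius. The quality factor
  $\gamma = (\partial A_2/\partial V_c)/(\partial A_4/\partial V_c)$
  crosses zero near $R/z_0 = 1.18$ for this electrode model (the idealized
  analysis gives 1.16).
* **Cuboid / cubic cells** (McIver; Comisarow & Marshall): exact double
  Fourier series. The 7.62 × 2.54 × 2.54 cm cell has its trapping plates
  along the short axis; the long edge is transverse.
* **Closed cylinder** (Comisarow & Marshall; Kofel et al.): exact
  modified-Bessel series. The printed form of such series is sometimes
  ambiguous about whether the axial wavenumber uses the half- or
  full-length; the package uses $\gamma_k = k\pi/(2z_0)$ (full length
  $2z_0$), the unique choice satisfying both boundary conditions, validated
  against an independent Bessel-J/cosh solution of the same problem.
* **Closed compensated cylinder** (Gabrielse & MacKintosh): compensation
  bands of length $\Delta z_c$ on the side wall adjacent to the end caps.
  The closed-form sensitivity `compensated_sensitivity()` was derived from
  this boundary-value problem; its default convention matches the regional
  fit (a pure Taylor variant is available), and it is validated against a
  finite-difference solver oracle, which is authoritative.
* **Open compensated cylinder** (Gabrielse, Haarsma & Rolston 1989): five
  coaxial cylinders; the long trapping cylinders screen the centre, so the
  box closes at their far ends.
* **Tolmachev-type and Brustkern-type compensated cells**: the published
  descriptions fix the segment lengths and voltages but not every axial
  placement; the package stacks the segments outward from the cell centre
  in the listed order as full axisymmetric rings. For the Brustkern-type
  cell the trapping-electrode length is taken equal to its inner-edge
  distance and the outer grounded cylinder is 1.5 times the
  trapping-plus-compensation length. These two designs are therefore
  indicative rather than exact reproductions.
* **Trapping-ring-electrode cell** (Weisbrod et al. 2008): five flat rings
  per end cap with stated voltages; the published width/gap expression is
  ambiguous in units, so widths and gaps are treated as relative and scaled
  to tile the end-cap radius (`ring_unit` parameter). Its metrics are
  flagged `reference = FALSE` and excluded from comparisons.
* **Dynamically harmonized cell / paracell** (Boldin & Nikolaev 2011):
  grounded leaf electrodes whose angular width shrinks as
  $1 - z^2/z_0^2$, trapping segments between them, and convex end caps on
  $2z^2 - \rho^2 = 2z_0^2 - R^2$.

## The paracell's averaged field is exactly quadratic

Two closed forms are implemented for the paracell: the azimuthally averaged
potential and a full 3-D approximation built from the slice-wise
harmonic-measure solution of the leaf pattern (as in Lioznov & Nikolaev).
A short argument shows the averaged form is *exact*: averaging the Laplace
equation over the polar angle annihilates the $\partial^2/\partial\theta^2$
term, so the true averaged potential solves the axisymmetric Laplace
problem with the averaged wall data
$\varphi_0[1 - \beta(1 - z^2/z_0^2)]$ — and

$$\hat\varphi(r, z) = \varphi_0\left[1 - \beta\Big(1 - \frac{z^2}{z_0^2}\Big)
 + \beta\,\frac{R^2 - r^2}{2 z_0^2}\right]$$

satisfies that problem *and* equals $\varphi_0$ exactly on the end-cap
surface: the end-cap shape is precisely an equipotential of this solution.
Consequently the exact averaged paracell field has $A_{40} = A_{60} = 0$
and an infinite comet time — dynamic harmonization is, in this averaged
picture, perfect. Any finite residual anharmonicity obtained for this cell
(by this package's 3-D solver, or by any grid-based field solver) is a
discretization artifact of rasterizing the leaves and end caps, shrinks
under refinement, and does not converge to a design property. For this
reason `evaluate_trap("paracell")` defaults to the numeric source — the
artifact-bearing route is the only one that yields a finite, comparable
comet time — while `source = "analytic"` documents the ideal behaviour
(`comet_time = Inf`). Reported paracell comet times should be read as
"longer than every statically compensated design at comparable numerical
fidelity", not as a converged physical constant.

## Detection model

Image-current detection uses the reciprocity principle: the charge induced
on an electrode by an ion at $\mathbf r$ is $Q = -q\,\phi_w(\mathbf r)$,
where $\phi_w$ is the weight potential (that electrode at 1 V, everything
else grounded). For a long cylinder the differential signal of a centred
orbit contains only odd harmonics of $\omega_+$ with amplitudes
$\propto 2\sin((2n{+}1)\alpha)/((2n{+}1)\pi)\,(\rho/R)^{2n+1}$; 120°
detection electrodes ($\alpha = \pi/3$) null the third harmonic
identically. With $p$ electrode pairs wired as two alternating ensembles
only orders $(2n{+}1)p$ survive — eight electrodes make $4\omega_+$ the
main harmonic, multiplying the detected frequency and hence the resolving
power. Off-centre (magnetron-shifted) orbits are handled only through
`reciprocity_charge()` on a solved weight field; no closed form is exposed
for the even harmonics they add.

## Synthetic fields, and what passing tests show

`synthetic_harmonic_field()` builds averaged potentials with prescribed
$(C, A_{20}, A_{40}, A_{60})$ — exact members of the fit basis. They
validate coefficient recovery (to $10^{-10}$ relative), scaling laws and
the comet-time definition, but contain none of the features that make real
fields hard: electrode-joint singularities, grid staircase error, series
truncation. Those are covered separately by the dual analytic/numeric
routes for the cylinder, cube and paracell. What no test here can show is
agreement with a *measured* cell: mechanical tolerances, patch potentials
and space charge are out of scope.

## Known limitations

* Space charge (ion-ion interaction), RF excitation dynamics, trajectory
  integration and peak coalescence are not modeled; the comet time is the
  standard rough dephasing estimate, not a transient simulation.
* The Tolmachev/Brustkern-type geometries involve documented placement
  assumptions (above).
* Tiny fitted residuals ($|A^{(n)}| \lesssim 10^{-4}$) of well-compensated
  designs are at the solver's discretization floor; comparisons between
  such designs reflect numerical fidelity as much as design quality.
* Weight-field and 3-D evaluations use trilinear interpolation; fits on
  numeric sources use the solver's own grid nodes inside the fit region
  rather than a fixed lattice, avoiding interpolation bias in the small
  coefficients.
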