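# icrcell

Electrostatic evaluation of FT-ICR measuring cells (Penning traps) in R.

In Fourier-transform ion cyclotron resonance mass spectrometry, ions are
confined in a magnetic field `B` by an electrostatic axial well and detected
through the image current they induce while orbiting at the reduced
cyclotron frequency. How well a cell performs is largely set by how close
its trapping field comes to the ideal harmonic form
`alpha * (z^2 - rho^2/2) + chi`. This package is for instrument builders and
simulation-minded spectrometrists who want the classical cell designs —
hyperbolic, cubic/cuboid, cylindrical, the compensated ("orthogonalized")
variants, and the dynamically harmonized cell — evaluated under one
protocol:

1. build the electrode geometry (`make_trap()`, 11 designs),
2. compute the trapping potential — exact series where available, otherwise
   a finite-difference Laplace solver (SOR) on axisymmetric or 3-D grids,
3. average azimuthally and fit the even-order harmonic model
   `C + A20 (z^2 - rho^2/2) + A40 (8z^4 - 24z^2 rho^2 + 3rho^4) + A60 (...)`
   by least squares over the 10 mm ion flight region,
4. convert the position dependence of the reduced cyclotron frequency
   `omega_+(rho, z)` into a comet-formation (cloud dephasing) time
   `T = 2*pi / (max omega_+ - min omega_+)`,
5. model image-current detection by reciprocity, including the 120-degree
   third-harmonic null and multielectrode frequency multiplication.

Dimensionless coefficients are normalized by
`d^2 = (z0^2 + rho0^2/2) / 2` (e.g. `A20n = A20 * d^2`).

## Worked example

```r
library(icrcell)

rows <- rbind(evaluate_trap("cubic"), evaluate_trap("cylindrical"))
rows[, c("kind", "source", "A20n", "A40n", "A60n", "comet_time_s")]
#>          kind   source      A20n       A40n         A60n comet_time_s
#> 1       cubic analytic 0.5200857 0.004622290 -0.002907936   0.02471440
#> 2 cylindrical analytic 0.5245885 0.009945133 -0.003611673   0.01421517
```

Both inch-sized cells sit at the same well depth (`A20n ~ 0.52`), but their
fourth-order residuals (`A40n` of 5e-3 and 1e-2) dephase a 2 mm ion cloud
excited to 6 mm radius within 25 ms and 14 ms respectively at `B = 7` T and
`m/z = 500` — this is why uncompensated cells broaden peaks at long
transients. A compensated or harmonized design buys orders of magnitude:

```r
evaluate_trap("hyperbolic_compensated")$comet_time_s
#> [1] 18.15998
```

The detection side: 120-degree electrodes null the third harmonic, and four
alternating pairs quadruple the detected frequency.

```r
cylinder_harmonics(0.5, detection_layout(pi/3), n_max = 3)$amplitudes
#> [1]  0.275664448  0.000000000 -0.003445806
multielectrode_harmonics(0.5, detection_layout(pi/16, n_pairs = 4))$orders[1]
#> [1] 4
```

A thin command-line front end is installed with the package
(`inst/cli/icr`): `icr list-traps`, `icr eval --trap cubic`,
`icr eval-all --out table.csv`, `icr detect --pairs 4 --rho-over-r 0.5`.

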