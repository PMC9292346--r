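## Independent oracles used across the test files.

## First n zeros of the Bessel function J0.
j0_zeros <- function(n) {
  z <- numeric(n)
  guess <- 2.404826
  for (i in seq_len(n)) {
    z[i] <- uniroot(function(x) besselJ(x, 0), c(guess - 1, guess + 1),
                    tol = 1e-14)$root
    guess <- z[i] + pi
  }
  z
}

## Independent closed-cylinder solution (end caps at vt, side grounded) built
## from Bessel-J radial modes and cosh axial profiles -- a different basis
## from the package's modified-Bessel series, so it serves as an oracle.
cyl_potential_jform <- function(rho, z, R, z0, vt = 1, nmax = 80) {
  xj <- j0_zeros(nmax)
  s <- 0
  for (j in seq_len(nmax)) {
    x <- xj[j]
    term <- 2 * vt / (x * besselJ(x, 1)) * besselJ(x * rho / R, 0) *
      exp(x * (abs(z) - z0) / R) * (1 + exp(-2 * x * abs(z) / R)) /
      (1 + exp(-2 * x * z0 / R))
    s <- s + term
  }
  s
}

## Boundary grid for a closed finite cylinder whose wall carries one
## segment pair: segment A (|phi| <= alpha) at 1 V, rest of wall and the end
## plates grounded. Used for reciprocity-detection oracle tests.
segment_cylinder_grid <- function(R = 0.0127, alpha = pi / 4, half_len = 4 * 0.0127,
                                  nx = 83, nzh = 60) {
  hx <- 1.02 * R / ((nx - 1) / 2)
  x <- seq(-(nx - 1) / 2, (nx - 1) / 2) * hx
  y <- x
  hz <- half_len / nzh
  z <- seq(-nzh, nzh) * hz
  dims <- c(length(x), length(y), length(z))
  gx <- rep(x, times = dims[2] * dims[3])
  gy <- rep(rep(y, each = dims[1]), times = dims[3])
  gz <- rep(z, each = dims[1] * dims[2])
  rho <- sqrt(gx^2 + gy^2)
  phi <- atan2(gy, gx)
  mask <- array(0L, dims)
  value <- array(0, dims)
  wall <- rho >= R
  segA <- wall & abs(phi) <= alpha
  mask[wall] <- 2L
  mask[segA] <- 1L
  value[segA] <- 1
  endz <- abs(gz) >= half_len
  mask[endz & mask == 0L] <- 3L
  boundary_grid(list(x = x, y = y, z = z), mask, value)
}

## Uniform all-Dirichlet box at a constant voltage (trivial solve fixture).
constant_box_grid <- function(v = 1, n = 17) {
  ax <- seq(0, 0.01, length.out = n)
  zax <- seq(-0.005, 0.005, length.out = n)
  mask <- matrix(0L, n, n)
  mask[n, ] <- 1L; mask[, 1] <- 1L; mask[, n] <- 1L
  value <- matrix(0, n, n)
  value[mask == 1L] <- v
  boundary_grid(list(rho = ax, z = zax), mask, value)
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected), tol * abs(expected))
}
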