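#' Detection-electrode layout
#'
#' Describes a ring of detection electrodes: `n_pairs = 1` is classical
#' dipolar detection; `n_pairs >= 2` are multielectrode layouts wired as two
#' alternating ensembles (frequency multiplication). With `2 * n_pairs`
#' detection electrodes of angular half-width `alpha`, geometric feasibility
#' requires `alpha <= pi / (2 * n_pairs)`.
#'
#' @param half_angle Electrode angular half-width `alpha` (rad).
#' @param n_pairs Electrode pairs per ring.
#' @param alternating Alternating-ensemble wiring flag (required for
#'   multielectrode layouts).
#' @return Object of class `detection_layout`.
#' @export
detection_layout <- function(half_angle, n_pairs = 1L, alternating = TRUE) {
  if (half_angle <= 0 || half_angle > pi / (2 * n_pairs)) {
    stop("half_angle must be in (0, pi/(2*n_pairs)]")
  }
  if (n_pairs < 1 || n_pairs != round(n_pairs)) stop("n_pairs must be a positive integer")
  structure(list(half_angle = half_angle, n_pairs = as.integer(n_pairs),
                 alternating = isTRUE(alternating)),
            class = "detection_layout")
}

.cyl_spectrum <- function(rho_over_R, alpha, p, n_max) {
  orders <- (2 * seq_len(n_max) - 1) * p
  s <- sin(orders * alpha)
  ## orders whose electrode-edge phase is an exact multiple of pi are nulled
  ## identically (e.g. the third harmonic at alpha = pi/3)
  s[abs(orders * alpha / pi - round(orders * alpha / pi)) < 1e-12] <- 0
  amps <- 2 * p * s / (orders * pi) * rho_over_R^orders
  structure(list(orders = orders, amplitudes = amps,
                 rho_over_R = rho_over_R, half_angle = alpha, n_pairs = p),
            class = "harmonic_spectrum")
}

#' Harmonic content of the dipolar detection signal in a long cylinder
#'
#' For an ion on a centred cyclotron orbit of radius `rho` in a cylinder of
#' radius `R`, the differential induced charge contains the reduced cyclotron
#' frequency and its odd harmonics only, with relative amplitudes
#' `2 sin((2n+1) alpha) / ((2n+1) pi) * (rho/R)^(2n+1)` (fractions of the ion
#' charge `q`). At `alpha = pi/3` (120-degree electrodes) the third harmonic
#' vanishes identically.
#'
#' @param rho_over_R Orbit radius over cylinder radius, in `[0, 1)`.
#' @param layout A [detection_layout()] with `n_pairs = 1`.
#' @param n_max Number of harmonics returned.
#' @return Object of class `harmonic_spectrum` with `orders` (multiples of
#'   `omega_+`) and `amplitudes`.
#' @export
cylinder_harmonics <- function(rho_over_R, layout, n_max = 10L) {
  stopifnot(inherits(layout, "detection_layout"))
  if (layout$n_pairs != 1L) stop("cylinder_harmonics is the dipolar (n_pairs = 1) case; use multielectrode_harmonics")
  if (rho_over_R < 0 || rho_over_R >= 1) stop("rho_over_R must be in [0, 1)")
  .cyl_spectrum(rho_over_R, layout$half_angle, 1L, n_max)
}

#' Harmonic content of multielectrode (frequency-multiplying) detection
#'
#' With `p = n_pairs` electrode pairs wired as two alternating ensembles and
#' a centred orbit, only harmonic orders `(2n+1) p` survive: `p = 2` gives
#' orders 2, 6, 10, ...; `p = 4` (eight electrodes) makes `4 omega_+` the
#' main harmonic. Amplitudes are
#' `2 p sin(k alpha) / (k pi) * (rho/R)^k` at order `k`.
#'
#' @inheritParams cylinder_harmonics
#' @param layout A [detection_layout()] with `n_pairs >= 2` and alternating
#'   wiring.
#' @export
multielectrode_harmonics <- function(rho_over_R, layout, n_max = 10L) {
  stopifnot(inherits(layout, "detection_layout"))
  if (layout$n_pairs < 2L) stop("multielectrode_harmonics needs n_pairs >= 2")
  if (!layout$alternating) stop("multielectrode detection requires alternating-ensemble wiring")
  if (rho_over_R < 0 || rho_over_R >= 1) stop("rho_over_R must be in [0, 1)")
  .cyl_spectrum(rho_over_R, layout$half_angle, layout$n_pairs, n_max)
}

#' Weight potential of one wall segment of an infinitely long cylinder
#'
#' Closed-form interior potential when a single wall segment of angular
#' half-width `alpha` (centred at polar angle 0) is held at 1 V and the rest
#' of the wall grounded:
#' `phi = alpha/pi + sum_n 2 sin(n alpha)/(n pi) (rho/R)^n cos(n phi)`.
#' This is the reciprocity weight field of one detection electrode far from
#' the cylinder ends.
#'
#' @param rho_over_R Radius fraction in `[0, 1)`.
#' @param phi Polar angle (rad), vectorized with `rho_over_R`.
#' @param alpha Segment half-width (rad).
#' @param n_max Series terms.
#' @return Weight potential (dimensionless, per volt).
#' @export
infinite_cylinder_segment_potential <- function(rho_over_R, phi, alpha,
                                                n_max = 400L) {
  if (any(rho_over_R < 0 | rho_over_R >= 1)) stop("rho_over_R must be in [0, 1)")
  n <- max(length(rho_over_R), length(phi))
  rho_over_R <- rep_len(rho_over_R, n); phi <- rep_len(phi, n)
  out <- rep(alpha / pi, n)
  for (k in seq_len(n_max)) {
    out <- out + 2 * sin(k * alpha) / (k * pi) * rho_over_R^k * cos(k * phi)
  }
  out
}

#' Induced charge by the reciprocity principle
#'
#' The charge induced on an electrode (set) by an ion of charge `q` equals
#' `-q` times the weight potential: the potential at the ion position when
#' that electrode is at 1 V and all others grounded. Differential detection
#' uses the difference of the two ensembles' weight fields. Superposition
#' gives the signal of multiple ions as the sum of their contributions.
#'
#' @param weight_field A `potential_grid` solved with the detection
#'   electrode(s) at 1 V, everything else grounded.
#' @param q Ion charge (C).
#' @param position Numeric matrix of positions (m): columns `(rho, z)` for
#'   axisymmetric grids, `(x, y, z)` for 3-D grids. A vector is treated as a
#'   single position.
#' @return Induced charge (C), one value per position.
#' @export
reciprocity_charge <- function(weight_field, q, position) {
  stopifnot(inherits(weight_field, "potential_grid"))
  if (is.null(dim(position))) position <- matrix(position, nrow = 1)
  ax <- weight_field$axes
  if (weight_field$type == "axisymmetric") {
    if (ncol(position) != 2) stop("axisymmetric grids need (rho, z) positions")
    ok <- position[, 1] >= min(ax$rho) & position[, 1] <= max(ax$rho) &
      position[, 2] >= min(ax$z) & position[, 2] <= max(ax$z)
    if (!all(ok)) stop("position outside grid")
    val <- .interp2(ax$rho, ax$z, weight_field$phi, position[, 1], position[, 2])
  } else {
    if (ncol(position) != 3) stop("3-D grids need (x, y, z) positions")
    ok <- position[, 1] >= min(ax$x) & position[, 1] <= max(ax$x) &
      position[, 2] >= min(ax$y) & position[, 2] <= max(ax$y) &
      position[, 3] >= min(ax$z) & position[, 3] <= max(ax$z)
    if (!all(ok)) stop("position outside grid")
    val <- .interp3(ax, weight_field$phi,
                    position[, 1], position[, 2], position[, 3])
  }
  -q * val
}

#' Synthesize a detection transient from a harmonic spectrum
#'
#' Sums cosines at `order * omega_plus` with the spectrum's relative
#' amplitudes and returns the time series together with its discrete-Fourier
#' magnitude spectrum. Induced-current amplitudes scale each order by its
#' angular frequency (`J = dQ/dt`).
#'
#' @param spectrum A `harmonic_spectrum`.
#' @param omega_plus Reduced cyclotron frequency (rad/s).
#' @param duration Transient length (s).
#' @param sample_rate Sampling rate (Hz); must exceed twice the highest
#'   harmonic frequency.
#' @param current Logical: return `dQ/dt` scaling (default) or raw charge.
#' @return List with `time`, `signal`, `freq`, `magnitude`.
#' @export
synthesize_transient <- function(spectrum, omega_plus, duration, sample_rate,
                                 current = TRUE) {
  stopifnot(inherits(spectrum, "harmonic_spectrum"))
  f_max <- max(spectrum$orders) * omega_plus / (2 * pi)
  if (sample_rate <= 2 * f_max) {
    stop("aliasing: sample_rate must exceed twice the highest harmonic frequency (",
         format(2 * f_max), " Hz)")
  }
  t <- seq(0, duration, by = 1 / sample_rate)
  sig <- numeric(length(t))
  for (i in seq_along(spectrum$orders)) {
    w <- spectrum$orders[i] * omega_plus
    amp <- spectrum$amplitudes[i] * if (current) w else 1
    sig <- sig + amp * if (current) -sin(w * t) else cos(w * t)
  }
  n <- length(t)
  mag <- Mod(stats::fft(sig))[seq_len(floor(n / 2))] / n * 2
  freq <- (seq_len(floor(n / 2)) - 1) * sample_rate / n
  list(time = t, signal = sig, freq = freq, magnitude = mag)
}

#' Write a transient as two-column text
#'
#' @param transient Output of [synthesize_transient()].
#' @param path File path.
#' @export
write_transient <- function(transient, path) {
  utils::write.table(data.frame(time_s = transient$time,
                                amplitude = transient$signal),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
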