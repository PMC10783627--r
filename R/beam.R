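#' Photostimulator beam model
#'
#' Divergence model of the stimulation beam: a straight-edge cone with
#' half-angle `asin(NA)` beyond the focal plane, where the spot has the
#' stated diameter. At distance `z` mm beyond focus the spot radius is
#' `spot_diameter / 2 + z * tan(asin(NA))`.
#'
#' @param spot_diameter Spot diameter at the platform in mm (default 5).
#' @param numerical_aperture Fiber numerical aperture, in (0, 1)
#'   (default 0.48).
#' @param total_power Total beam power in mW.
#' @param profile Irradiance profile: `"uniform_disc"` (default) or
#'   `"gaussian"`.
#' @return An object of class `beam_model`.
#' @export
beam_model <- function(spot_diameter = 5, numerical_aperture = 0.48,
                       total_power = 20,
                       profile = c("uniform_disc", "gaussian")) {
  profile <- match.arg(profile)
  if (spot_diameter <= 0) stop("spot_diameter must be > 0")
  if (numerical_aperture <= 0 || numerical_aperture >= 1) {
    stop("numerical_aperture must be in (0, 1)")
  }
  if (total_power < 0) stop("total_power must be >= 0")
  structure(list(spot_diameter = spot_diameter,
                 numerical_aperture = numerical_aperture,
                 total_power = total_power, profile = profile),
            class = "beam_model")
}

#' Paw-shaped aperture over the photodiode
#'
#' Planar region standing in for the paw (or the paw-shaped cut-out used to
#' calibrate delivery). Default is a 10 x 4 mm ellipse, a plausible mouse
#' hind-paw footprint; a half-plane shape is provided for geometry checks.
#'
#' @param shape `"ellipse"` (default) or `"halfplane"` (the region
#'   `x <= center[1]`).
#' @param width Ellipse full width (x extent) in mm.
#' @param height Ellipse full height (y extent) in mm.
#' @param center Aperture center offset in mm, `c(x, y)`.
#' @return An object of class `paw_aperture`.
#' @export
paw_aperture <- function(shape = c("ellipse", "halfplane"),
                         width = 10, height = 4, center = c(0, 0)) {
  shape <- match.arg(shape)
  if (shape == "ellipse" && (width <= 0 || height <= 0)) {
    stop("aperture must have positive area")
  }
  structure(list(shape = shape, width = width, height = height,
                 center = center),
            class = "paw_aperture")
}

#' Tester-jitter model for beam positioning
#'
#' Models positional instability of stimulus delivery: `"none"` for the
#' mounted stimulator, `"gaussian_iid"` or `"random_walk"` for handheld
#' aiming, with per-axis standard deviations in mm.
#'
#' @param kind `"none"`, `"gaussian_iid"` or `"random_walk"`.
#' @param sd_xy Lateral SD per sample in mm.
#' @param sd_z Axial SD per sample in mm.
#' @return An object of class `jitter_model`.
#' @export
jitter_model <- function(kind = c("none", "gaussian_iid", "random_walk"),
                         sd_xy = 0, sd_z = 0) {
  kind <- match.arg(kind)
  if (sd_xy < 0 || sd_z < 0) stop("jitter SDs must be >= 0")
  if (kind == "none" && (sd_xy != 0 || sd_z != 0)) {
    stop("kind = \"none\" requires zero SDs")
  }
  structure(list(kind = kind, sd_xy = sd_xy, sd_z = sd_z),
            class = "jitter_model")
}

#' Beam radius at axial distance z
#'
#' @param beam A [beam_model()].
#' @param z Distance beyond the focal plane in mm (>= 0).
#' @return Beam radius in mm.
#' @examples
#' beam_radius_at(beam_model(), 0)   # 2.5
#' beam_radius_at(beam_model(), 10)  # ~7.97
#' @export
beam_radius_at <- function(beam, z) {
  stopifnot(inherits(beam, "beam_model"))
  if (any(z < 0)) stop("z must be >= 0")
  beam$spot_diameter / 2 + z * tan(asin(beam$numerical_aperture))
}

point_in_aperture <- function(ap, x, y) {
  if (ap$shape == "halfplane") {
    x <= ap$center[1]
  } else {
    ((x - ap$center[1]) / (ap$width / 2))^2 +
      ((y - ap$center[2]) / (ap$height / 2))^2 <= 1
  }
}

#' On-target optical power for a displaced beam
#'
#' Fraction of the beam power falling on the aperture when the beam axis is
#' displaced by `offset = c(x, y, z)` mm from the aperture center (z measured
#' beyond the focal plane, enlarging the spot). For the uniform-disc profile
#' this is `total_power` times the overlap area of the beam disc with the
#' aperture divided by the disc area; for the Gaussian profile the irradiance
#' is weighted accordingly. Computed by midpoint-grid quadrature over the
#' beam disc (an even `grid_n` keeps symmetric configurations exact).
#'
#' @param beam A [beam_model()].
#' @param aperture A [paw_aperture()].
#' @param offset Numeric `c(x, y, z)` in mm.
#' @param grid_n Quadrature resolution per axis (default 120).
#' @return Power on target in mW.
#' @export
on_target_power <- function(beam, aperture, offset = c(0, 0, 0),
                            grid_n = 120) {
  stopifnot(inherits(beam, "beam_model"), inherits(aperture, "paw_aperture"))
  if (!all(is.finite(offset)) || length(offset) != 3L) {
    stop("offset must be finite c(x, y, z)")
  }
  r <- beam_radius_at(beam, offset[3])
  h <- 2 * r / grid_n
  g <- seq(-r + h / 2, r - h / 2, length.out = grid_n)
  gx <- rep(g, times = grid_n)
  gy <- rep(g, each = grid_n)
  in_disc <- gx^2 + gy^2 <= r^2
  if (beam$profile == "gaussian") {
    # 1/e^2 beam radius taken as the disc radius; truncated at the disc edge
    w <- exp(-2 * (gx^2 + gy^2) / r^2) * in_disc
  } else {
    w <- as.numeric(in_disc)
  }
  tot <- sum(w)
  if (tot == 0) return(0)
  inside <- point_in_aperture(aperture, gx + offset[1], gy + offset[2])
  beam$total_power * sum(w * inside) / tot
}

#' Simulate a delivered-power trace under positional jitter
#'
#' Emulates calibration of stimulus delivery against a photodiode under a
#' paw-shaped cut-out: per-sample beam offsets are drawn from the jitter
#' model, and the on-target power is evaluated at each offset. With
#' `kind = "none"` the trace is constant; larger jitter lowers the trace's
#' signal-to-noise ratio (see [snr_db()]).
#'
#' @param beam A [beam_model()].
#' @param aperture A [paw_aperture()].
#' @param jitter A [jitter_model()].
#' @param duration Trace duration in ms.
#' @param fs Sampling rate in Hz (default 100; positional drift is slow
#'   relative to the 1 kHz DAQ).
#' @param seed Integer seed; the trace is a deterministic function of the
#'   parameters and the seed.
#' @param grid_n Quadrature resolution passed to [on_target_power()].
#' @return A [signal_trace()] in mW.
#' @export
simulate_power_trace <- function(beam, aperture, jitter, duration = 10000,
                                 fs = 100, seed = 1, grid_n = 60) {
  stopifnot(inherits(jitter, "jitter_model"))
  if (duration <= 0) stop("duration must be > 0")
  n <- max(1L, as.integer(round(duration * fs / 1000)))
  with_seed(seed, {
    if (jitter$kind == "none") {
      dx <- dy <- dz <- rep(0, n)
    } else {
      dx <- stats::rnorm(n, 0, jitter$sd_xy)
      dy <- stats::rnorm(n, 0, jitter$sd_xy)
      dz <- stats::rnorm(n, 0, jitter$sd_z)
      if (jitter$kind == "random_walk") {
        dx <- cumsum(dx); dy <- cumsum(dy); dz <- cumsum(dz)
      }
    }
    vals <- vapply(seq_len(n), function(i) {
      on_target_power(beam, aperture,
                      c(dx[i], dy[i], pmax(0, dz[i])), grid_n = grid_n)
    }, numeric(1))
    signal_trace(vals, fs = fs, t0 = 0, units = "mW")
  })
}
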