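# Diastolic phenotyping from cine geometry: strain, strain rate, peak early
# diastolic strain rate, biplane left atrial volume and BSA indexing.

#' Compute myocardial strain curves from segment lengths
#'
#' Per segment, strain is the fractional length change relative to
#' end-diastole (phase 0): E(t) = (L(t) - L(0)) / L(0). The global curve is
#' the unweighted mean across segments.
#'
#' @param geom a `cine_geometry`.
#' @param direction one of "rr", "ll", "cc".
#' @return a `strain_curve`: list with `direction`, `values` (global curve,
#'   `values[1] == 0` exactly) and `segments` (segments x phases matrix).
#' @export
compute_strain <- function(geom, direction = c("rr", "ll", "cc")) {
  direction <- match.arg(direction)
  L <- geom$segment_lengths[[direction]]
  if (is.null(L)) stop("geometry has no segments for direction ", direction)
  L0 <- L[, 1]
  if (any(L0 <= 0)) stop("baseline segment lengths must be positive")
  E <- sweep(sweep(L, 1, L0, "-"), 1, L0, "/")
  structure(list(direction = direction, values = colMeans(E), segments = E),
            class = "strain_curve")
}

# Savitzky-Golay style slope of a local least-squares quadratic over `w`
# phases, periodic at the cycle boundary. w = 1 gives central differences.
sg_slope <- function(x, w, dt) {
  n <- length(x)
  if (w > n) stop("smoothing window larger than the series")
  if (w <= 1) {
    return((x[c(2:n, 1)] - x[c(n, 1:(n - 1))]) / (2 * dt))
  }
  h <- (w - 1L) %/% 2L
  k <- -h:h
  denom <- sum(k^2) * dt
  out <- numeric(n)
  for (j in k) {
    out <- out + j * x[((seq_len(n) - 1 + j) %% n) + 1]
  }
  out / denom
}

#' Differentiate a strain curve
#'
#' The strain rate is the slope of a local least-squares quadratic fitted
#' over `smooth_window` phases, with the cardiac cycle treated as periodic at
#' the boundary. `smooth_window = 1` reduces to central differences.
#'
#' @param sc a `strain_curve` (or plain numeric vector).
#' @param dt_s phase spacing in seconds (31 ms by default).
#' @param smooth_window odd window length >= 1.
#' @return a `strain_rate_curve`: list with `direction`, `values` (s^-1) and
#'   the smoothing descriptor.
#' @export
compute_strain_rate <- function(sc, dt_s = 0.031, smooth_window = 5) {
  if (dt_s <= 0) stop("dt_s must be positive")
  if (smooth_window < 1 || smooth_window %% 2 == 0)
    stop("smooth_window must be odd and >= 1")
  x <- if (inherits(sc, "strain_curve")) sc$values else as.numeric(sc)
  if (length(x) < 3) stop("need at least 3 phases")
  structure(list(direction = if (inherits(sc, "strain_curve")) sc$direction else NA,
                 values = sg_slope(x, smooth_window, dt_s),
                 dt_s = dt_s, smooth_window = smooth_window,
                 strain = x),
            class = "strain_rate_curve")
}

# Refine the magnitude of a local extremum of the recoil-signed strain rate:
# fit a quadratic to the central-difference derivative over up to 5 phases
# around the detected peak, take the vertex, and remove the O(dt^2) central-
# difference bias using the fitted curvature. Exact for a locally quadratic
# strain-rate peak at any sub-phase offset.
refine_peak <- function(strain, j, dt) {
  n <- length(strain)
  if (j < 2 || j > n - 1) return(NA_real_)
  r1 <- (strain[c(2:n, 1)] - strain[c(n, 1:(n - 1))]) / (2 * dt)
  idx <- (j - 1):(j + 1)
  if (idx[1] < 2 || idx[3] > n - 1) return(r1[j])
  y <- r1[idx]
  # refinement is only credible when the peak is resolved by the sampling:
  # both neighbours must carry at least half the centre value (true for any
  # smooth extremum wider than about one frame); otherwise the sampled value
  # is kept, which protects against step artefacts
  if (!all(is.finite(y)) || min(y[1], y[3]) < 0.5 * y[2]) return(y[2])
  # interpolating parabola through the three points
  b <- (y[3] - y[1]) / (2 * dt)
  cc <- (y[1] - 2 * y[2] + y[3]) / (2 * dt^2)
  if (!is.finite(cc) || cc >= 0) return(y[2])
  vx <- -b / (2 * cc)
  if (abs(vx) > dt) vx <- sign(vx) * dt
  vert <- y[2] + b * vx + cc * vx^2
  vert - (2 * cc) * dt^2 / 6
}

#' Detect the peak early diastolic strain rate
#'
#' Restricts to phases strictly after the phase of peak absolute strain,
#' finds local extrema of the recoil-signed strain rate (strain rate times
#' the negated sign of the strain peak, so recoil is positive), and returns
#' the magnitude of the largest extremum. The magnitude is refined by a
#' local quadratic fit of the unsmoothed derivative around the detected
#' phase, with a curvature-based correction for the finite-difference bias.
#' When no interior local extremum exists (including when peak strain falls
#' on the final phase) a flagged missing value is returned rather than an
#' error.
#'
#' @param src a `strain_rate_curve` from [compute_strain_rate()].
#' @param strain the matching `strain_curve` (optional when `src` carries its
#'   strain values).
#' @return positive peak magnitude in s^-1, or `NA` with attribute
#'   `reason` when no diastolic extremum exists.
#' @export
detect_pdsr <- function(src, strain = NULL) {
  E <- if (!is.null(strain)) {
    if (inherits(strain, "strain_curve")) strain$values else as.numeric(strain)
  } else src$strain
  r <- src$values
  n <- length(r)
  flagged <- function(reason) structure(NA_real_, reason = reason)
  ip <- which.max(abs(E))
  if (ip >= n - 1) return(flagged("no diastolic window"))
  w <- (ip + 1):(n - 1)                       # interior phases after peak |E|
  recoil_sign <- -sign(E[ip])
  if (recoil_sign == 0) recoil_sign <- 1
  rec <- recoil_sign * r
  loc <- w[rec[w] > rec[w - 1] & rec[w] >= rec[w + 1] & rec[w] > 0]
  if (!length(loc)) return(flagged("no local extremum in diastolic window"))
  j <- loc[which.max(rec[loc])]
  refined <- refine_peak(recoil_sign * E, j, src$dt_s)
  if (!is.finite(refined) || refined <= 0) refined <- rec[j]
  refined
}

#' Biplane area-length left atrial volume
#'
#' V = (8 / (3 * pi)) * A_2Ch * A_4Ch / L. For areas and length taken from an
#' ellipsoid with semi-axes a, b, c (A_2Ch = pi*a*c, A_4Ch = pi*b*c,
#' L = 2*c) this equals the ellipsoid volume (4/3)*pi*a*b*c exactly.
#'
#' @param a2,a4 atrial areas in the two- and four-chamber views (mm^2).
#' @param l longitudinal diameter averaged across the two views (mm).
#' @return volume in mm^3 (vectorized).
#' @export
biplane_la_volume <- function(a2, a4, l) {
  if (any(a2 <= 0) || any(a4 <= 0) || any(l <= 0))
    stop("areas and length must be positive")
  8 / (3 * pi) * a2 * a4 / l
}

#' Du Bois body surface area
#'
#' BSA = 0.20247 * weight^0.425 * height^0.725, weight in kg, height in m.
#'
#' @param weight_kg body weight in kilograms.
#' @param height_m height in metres.
#' @return body surface area in m^2 (vectorized).
#' @export
du_bois_bsa <- function(weight_kg, height_m) {
  if (any(weight_kg <= 0) || any(height_m <= 0))
    stop("weight and height must be positive")
  0.20247 * weight_kg^0.425 * height_m^0.725
}

#' Extract the three diastolic traits from cine geometry
#'
#' Derives global radial and longitudinal strain curves, differentiates them,
#' detects the peak early diastolic strain rates, computes the biplane left
#' atrial volume across phases, converts its maximum to millilitres and
#' indexes it to the Du Bois body surface area.
#'
#' @param geom a `cine_geometry`.
#' @param weight_kg,height_m anthropometrics for BSA indexing.
#' @param smooth_window strain-rate smoothing window (odd, >= 1).
#' @return a one-row data frame: subject_id, pdsr_rr, pdsr_ll (s^-1),
#'   lav_max (mL), lav_max_i (mL/m^2), bsa (m^2), and QC flag columns
#'   pdsr_rr_flag / pdsr_ll_flag (reason strings, NA when detection worked).
#' @export
extract_phenotypes <- function(geom, weight_kg, height_m, smooth_window = 5) {
  dt <- diff(geom$phase_times[1:2])
  out <- list(subject_id = geom$subject_id %||% NA_character_)
  for (dir in c("rr", "ll")) {
    sc <- compute_strain(geom, dir)
    src <- compute_strain_rate(sc, dt_s = dt, smooth_window = smooth_window)
    p <- detect_pdsr(src, sc)
    out[[paste0("pdsr_", dir)]] <- as.numeric(p)
    out[[paste0("pdsr_", dir, "_flag")]] <- attr(p, "reason") %||% NA_character_
  }
  vol <- biplane_la_volume(geom$atrial$a_2ch, geom$atrial$a_4ch, geom$atrial$l)
  bsa <- du_bois_bsa(weight_kg, height_m)
  out$lav_max <- max(vol) / 1000
  out$bsa <- bsa
  out$lav_max_i <- out$lav_max / bsa
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Extract diastolic traits for a cohort of cine geometries
#'
#' @param geometries list of `cine_geometry` objects.
#' @param anthro data frame with columns subject_id, weight (kg), height (m).
#' @param smooth_window strain-rate smoothing window.
#' @return data frame with one row per subject (see [extract_phenotypes()]).
#' @export
extract_phenotypes_cohort <- function(geometries, anthro, smooth_window = 5) {
  rows <- lapply(geometries, function(g) {
    i <- match(g$subject_id, anthro$subject_id)
    if (is.na(i)) stop("no anthropometrics for subject ", g$subject_id)
    extract_phenotypes(g, anthro$weight[i], anthro$height[i],
                       smooth_window = smooth_window)
  })
  do.call(rbind, rows)
}
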