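#' Hemoglobin molar extinction coefficients
#'
#' Base-10 molar extinction coefficients of oxy- and deoxyhemoglobin at the
#' two sensor wavelengths, in 1/(mM cm), taken from published compiled
#' tabulations of hemoglobin spectra in the NIR window. Rows are wavelengths,
#' columns are chromophores (`o2hb`, `hhb`). Override via
#' [optical_geometry()] when device-specific tables are available.
#'
#' @param wavelengths Wavelengths in nm; only 765 and 850 are tabulated here.
#' @return A 2 x 2 numeric matrix with dimnames.
#' @export
hb_extinction <- function(wavelengths = c(765, 850)) {
  tab <- rbind(
    `765` = c(o2hb = 0.586, hhb = 1.381),
    `850` = c(o2hb = 1.058, hhb = 0.691)
  )
  key <- as.character(wavelengths)
  if (!all(key %in% rownames(tab))) {
    stop("extinction coefficients tabulated only at 765 and 850 nm; ",
         "supply `extinction` explicitly for other wavelengths", call. = FALSE)
  }
  tab[key, , drop = FALSE]
}

#' Sensor geometry and tissue optical constants
#'
#' Describes the spatially-resolved-spectroscopy (SRS) sensor: two
#' wavelengths, three source-detector distances on one photodiode, the
#' extinction matrix, per-wavelength differential pathlength factors (DPF)
#' and reduced scattering coefficients. Defaults follow a compact
#' dual-wavelength (765/850 nm) continuous-wave muscle sensor with
#' 30/35/40 mm interoptode distances; scattering defaults are typical of
#' human musculature in this window (the DPF affects only the scaling of
#' relative chromophore units, never the saturation index).
#'
#' @param wavelengths Two wavelengths (nm).
#' @param distances Source-detector distances (mm), strictly increasing,
#'   at least two.
#' @param extinction 2 x 2 extinction matrix (rows = wavelengths, cols =
#'   o2hb, hhb) in 1/(mM cm); defaults to [hb_extinction()].
#' @param dpf Differential pathlength factor per wavelength (dimensionless).
#' @param mus_prime Reduced scattering coefficient per wavelength (1/cm).
#' @return An object of class `optical_geometry`.
#' @export
optical_geometry <- function(wavelengths = c(765, 850),
                             distances = c(30, 35, 40),
                             extinction = hb_extinction(wavelengths),
                             dpf = c(4.4, 4.2),
                             mus_prime = c(9.1, 8.3)) {
  if (length(wavelengths) != 2) stop("exactly 2 wavelengths required", call. = FALSE)
  if (length(distances) < 2 || any(diff(distances) <= 0)) {
    stop("`distances` must be >= 2 strictly increasing values (mm)", call. = FALSE)
  }
  extinction <- as.matrix(extinction)
  if (!all(dim(extinction) == c(2, 2)) ||
      abs(det(extinction)) < 1e-10) {
    stop("`extinction` must be a nonsingular 2 x 2 matrix", call. = FALSE)
  }
  if (any(dpf <= 0) || any(mus_prime <= 0)) {
    stop("`dpf` and `mus_prime` must be positive", call. = FALSE)
  }
  structure(
    list(wavelengths = wavelengths, distances = distances,
         extinction = extinction,
         dpf = rep_len(dpf, 2), mus_prime = rep_len(mus_prime, 2)),
    class = "optical_geometry"
  )
}

#' @export
print.optical_geometry <- function(x, ...) {
  cat(sprintf("<optical_geometry> %g/%g nm at %s mm\n",
              x$wavelengths[1], x$wavelengths[2],
              paste(x$distances, collapse = "/")))
  invisible(x)
}

#' Raw multi-distance dual-wavelength attenuation
#'
#' Container for optical-density traces indexed by wavelength and
#' source-detector distance: a numeric array of dimension
#' `time x wavelength x distance`.
#'
#' @param attenuation Array `[n_time, n_wavelength, n_distance]` in OD.
#' @param fs Sampling rate (Hz).
#' @param t0 Start time (s).
#' @param wavelengths,distances Channel coordinates (nm, mm).
#' @return An object of class `optical_recording`.
#' @export
optical_recording <- function(attenuation, fs, t0 = 0,
                              wavelengths = c(765, 850),
                              distances = c(30, 35, 40)) {
  attenuation <- as.array(attenuation)
  d <- dim(attenuation)
  if (length(d) != 3 || d[2] != length(wavelengths) || d[3] != length(distances)) {
    stop("`attenuation` must be [time x wavelength x distance]", call. = FALSE)
  }
  structure(
    list(attenuation = attenuation, fs = fs, t0 = t0,
         wavelengths = wavelengths, distances = distances),
    class = "optical_recording"
  )
}

#' @export
print.optical_recording <- function(x, ...) {
  cat(sprintf("<optical_recording> %d samples @ %g Hz, %d wavelengths x %d distances\n",
              dim(x$attenuation)[1], x$fs, length(x$wavelengths),
              length(x$distances)))
  invisible(x)
}

#' Oxy/deoxyhemoglobin traces and derived parameters
#'
#' Bundles the four relative chromophore channels and (optionally) the
#' absolute tissue saturation index. `thb = o2hb + hhb` and
#' `hbdiff = o2hb - hhb` are computed here so the identities hold exactly
#' at every sample.
#'
#' @param o2hb,hhb [time_series()] of oxy-/deoxyhemoglobin (uM relative, or
#'   s.d.u. after normalization), sharing rate and time base.
#' @param tsi Optional [time_series()] of tissue saturation index (%).
#' @return An object of class `chromophore_set` with elements `o2hb`,
#'   `hhb`, `thb`, `hbdiff`, `tsi`.
#' @export
chromophore_set <- function(o2hb, hhb, tsi = NULL) {
  stopifnot(inherits(o2hb, "time_series"), inherits(hhb, "time_series"))
  if (length(o2hb) != length(hhb) || o2hb$fs != hhb$fs) {
    stop("o2hb and hhb must share length and rate", call. = FALSE)
  }
  if (!is.null(tsi)) {
    bad <- tsi$values[is.finite(tsi$values)]
    if (any(bad < 0 | bad > 100)) {
      stop("tsi must lie within [0, 100] %", call. = FALSE)
    }
  }
  mk <- function(v, lab) time_series(v, o2hb$fs, o2hb$t0, o2hb$units, lab)
  structure(
    list(o2hb = o2hb, hhb = hhb,
         thb = mk(o2hb$values + hhb$values, "THb"),
         hbdiff = mk(o2hb$values - hhb$values, "Hbdiff"),
         tsi = tsi),
    class = "chromophore_set"
  )
}

# mm -> cm once, in one place
.dist_cm <- function(geometry) geometry$distances / 10

# OLS slope weights for attenuation-vs-distance regression (per time point)
.slope_weights <- function(rho_cm) {
  d <- rho_cm - mean(rho_cm)
  d / sum(d^2)
}

#' Forward optical model: chromophores to attenuation
#'
#' Twin of the SRS inversion in [srs_tsi()]. Absorption at each wavelength is
#' built from the extinction matrix, the spatial attenuation slope follows
#' the diffusion-approximation relation
#' `ln(10) dA/drho = sqrt(3 mu_a mu_s') + 2/rho_bar`, and attenuation is
#' linear in distance with that slope. An optional cardiac pulsatile
#' oxyhemoglobin component is added at the shortest distance through the
#' modified Beer-Lambert law (extinction x pathlength x DPF), which is where
#' a pulse-oximetry-style pulsatile term is usually strongest.
#'
#' @param o2hb,hhb [time_series()] of chromophore concentrations (uM). Must
#'   share length and rate.
#' @param geometry An [optical_geometry()].
#' @param o2hb_pulse Optional numeric vector (uM, same length) of pulsatile
#'   oxyhemoglobin added at the shortest distance only.
#' @param a0 Distance-independent attenuation offset per wavelength (OD);
#'   models source intensity / coupling and is annihilated by the spatial
#'   slope, so it never affects the saturation index.
#' @return An [optical_recording()].
#' @export
forward_attenuation <- function(o2hb, hhb, geometry = optical_geometry(),
                                o2hb_pulse = NULL, a0 = c(1, 1)) {
  if (length(o2hb) != length(hhb) || o2hb$fs != hhb$fs) {
    stop("o2hb and hhb traces must share length and rate", call. = FALSE)
  }
  n <- length(o2hb)
  rho <- .dist_cm(geometry)
  rho_bar <- mean(rho)
  conc_mM <- cbind(o2hb$values, hhb$values) / 1000  # uM -> mM
  A <- array(0, dim = c(n, 2, length(rho)))
  for (w in 1:2) {
    # base-e absorption coefficient (1/cm) from base-10 extinction
    mua <- log(10) * as.vector(conc_mM %*% geometry$extinction[w, ])
    if (any(mua < 0)) {
      stop("negative absorption: chromophore concentrations must be >= 0",
           call. = FALSE)
    }
    slope <- (sqrt(3 * mua * geometry$mus_prime[w]) + 2 / rho_bar) / log(10)
    for (j in seq_along(rho)) {
      A[, w, j] <- a0[w] + slope * rho[j]
    }
    if (!is.null(o2hb_pulse)) {
      A[, w, 1] <- A[, w, 1] +
        geometry$extinction[w, "o2hb"] * (o2hb_pulse / 1000) *
        rho[1] * geometry$dpf[w]
    }
  }
  optical_recording(A, o2hb$fs, o2hb$t0, geometry$wavelengths,
                    geometry$distances)
}

#' Tissue saturation index by spatially resolved spectroscopy
#'
#' Per time point and wavelength, the attenuation-vs-distance slope is
#' estimated by ordinary least squares over the source-detector distances;
#' the scattering-corrected, arbitrarily scaled absorption is
#' `k mu_a = (ln(10) dA/drho - 2/rho_bar)^2 / (3 mu_s')`; the 2 x 2
#' extinction system then yields `k [O2Hb]` and `k [HHb]`, and the unknown
#' scale `k` cancels in
#' `TSI = O2Hb / (O2Hb + HHb) x 100`.
#'
#' Samples where the slope term `ln(10) dA/drho - 2/rho_bar` is negative
#' (no real square root in the forward relation) or where the recovered
#' total hemoglobin is non-positive are flagged invalid and returned as
#' `NA` rather than clipped; the fraction of valid samples is attached as
#' attribute `"valid_fraction"`.
#'
#' @param rec An [optical_recording()] with >= 2 distances.
#' @param geometry An [optical_geometry()] matching the recording.
#' @return A [time_series()] of TSI (%) with attribute `valid_fraction`.
#' @export
srs_tsi <- function(rec, geometry = optical_geometry()) {
  if (length(rec$distances) < 2) {
    stop("SRS inversion needs >= 2 source-detector distances", call. = FALSE)
  }
  rho <- .dist_cm(geometry)
  rho_bar <- mean(rho)
  w8 <- .slope_weights(rho)
  n <- dim(rec$attenuation)[1]
  kmua <- matrix(NA_real_, n, 2)
  invalid <- rep(FALSE, n)
  for (w in 1:2) {
    slope <- as.vector(rec$attenuation[, w, ] %*% w8)     # OD / cm
    root <- log(10) * slope - 2 / rho_bar
    bad <- root < 0
    invalid <- invalid | bad
    root[bad] <- NA_real_
    kmua[, w] <- root^2 / (3 * geometry$mus_prime[w])
  }
  # k mu_a = ln(10) * E %*% (k c)  =>  solve for scaled concentrations
  kc <- t(solve(geometry$extinction, t(kmua / log(10))))
  tot <- kc[, 1] + kc[, 2]
  tsi <- ifelse(is.na(tot) | tot <= 0, NA_real_, 100 * kc[, 1] / tot)
  out <- time_series(tsi, rec$fs, rec$t0, units = "%", label = "TSI")
  attr(out, "valid_fraction") <- mean(!is.na(tsi))
  out
}

#' Relative chromophore changes by the modified Beer-Lambert law
#'
#' Attenuation changes at one source-detector distance, relative to the mean
#' over a reference window, are converted to concentration changes through
#' the extinction matrix and the effective pathlength `rho x DPF(lambda)`:
#' `dA(lambda) = [eps_o2hb, eps_hhb] . dC * rho * DPF(lambda)`. Total
#' hemoglobin and the hemoglobin difference follow by their defining
#' identities.
#'
#' @param rec An [optical_recording()].
#' @param geometry An [optical_geometry()].
#' @param distance Source-detector distance to use (mm); must be present in
#'   the recording. Defaults to the shortest.
#' @param reference Numeric `c(from, to)` window (s) whose mean attenuation
#'   defines the zero of the relative scale; must lie inside the recording.
#' @return A [chromophore_set()] in uM (relative), `tsi = NULL`.
#' @export
mbll_delta <- function(rec, geometry = optical_geometry(),
                       distance = min(rec$distances),
                       reference) {
  j <- match(distance, rec$distances)
  if (is.na(j)) {
    stop(sprintf("distance %g mm not present in recording", distance),
         call. = FALSE)
  }
  t <- rec$t0 + (seq_len(dim(rec$attenuation)[1]) - 1) / rec$fs
  eps <- 0.5 / rec$fs
  ref_idx <- which(t >= reference[1] - eps & t < reference[2] - eps)
  if (length(ref_idx) == 0 || reference[1] < rec$t0 - eps ||
      reference[2] > max(t) + 1 / rec$fs + eps) {
    stop("reference window outside recording", call. = FALSE)
  }
  rho_cm <- distance / 10
  dA <- sweep(rec$attenuation[, , j], 2,
              colMeans(rec$attenuation[ref_idx, , j, drop = FALSE]))
  # per-wavelength pathlength scaling folded into the system matrix
  M <- geometry$extinction * (rho_cm * geometry$dpf)
  dC_mM <- t(solve(M, t(dA)))
  o2hb <- time_series(1000 * dC_mM[, 1], rec$fs, rec$t0, "uM", "O2Hb")
  hhb <- time_series(1000 * dC_mM[, 2], rec$fs, rec$t0, "uM", "HHb")
  chromophore_set(o2hb, hhb)
}
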