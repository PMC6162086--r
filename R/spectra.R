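#' Uniform wavelength grid
#'
#' Defines the wavelength sampling used by all spectral integrals. The
#' default, 300--700 nm in 1 nm steps, spans the visual range of trichromatic
#' bees (UV through green/red) and makes trapezoidal discretisation error
#' negligible relative to the colour model itself.
#'
#' @param start,stop Grid bounds in nm (`start < stop`).
#' @param step Step size in nm (> 0).
#' @return An object of class `wl_grid` with elements `start`, `stop`,
#'   `step` and the vector of grid points `wl`.
#' @export
#' @examples
#' g <- wl_grid()
#' length(g$wl)  # 401 points
wl_grid <- function(start = 300, stop = 700, step = 1) {
  if (!is.numeric(start) || !is.numeric(stop) || !is.numeric(step)) {
    stop("grid bounds and step must be numeric", call. = FALSE)
  }
  if (start >= stop) stop("wavelength grid requires start < stop", call. = FALSE)
  if (step <= 0) stop("wavelength grid requires step > 0", call. = FALSE)
  wl <- seq(start, stop, by = step)
  structure(list(start = start, stop = stop, step = step, wl = wl),
            class = "wl_grid")
}

#' @export
print.wl_grid <- function(x, ...) {
  cat(sprintf("<wl_grid> %g-%g nm, step %g nm (%d points)\n",
              x$start, x$stop, x$step, length(x$wl)))
  invisible(x)
}

same_grid <- function(a, b) {
  length(a$wl) == length(b$wl) && isTRUE(all.equal(a$wl, b$wl))
}

#' Spectrum objects
#'
#' A spectrum is a vector of values sampled on a [wl_grid()]. Reflectance
#' spectra are dimensionless fractions (>= 0; values above 1 are only
#' admitted when flagged as calibrated against a white standard), illuminant
#' spectra are relative spectral photon flux (or energy) and must not be all
#' zero.
#'
#' @param values Numeric vector, one value per grid point.
#' @param grid A [wl_grid()].
#' @param calibrated For reflectance spectra: `TRUE` if measured as a ratio
#'   against a white standard, permitting values above 1.
#' @return An object of class `spectrum` with a `role` field.
#' @export
reflectance_spectrum <- function(values, grid = wl_grid(), calibrated = FALSE) {
  new_spectrum(values, grid, role = "reflectance", calibrated = calibrated)
}

#' @rdname reflectance_spectrum
#' @export
illuminant_spectrum <- function(values, grid = wl_grid()) {
  new_spectrum(values, grid, role = "illuminant")
}

new_spectrum <- function(values, grid, role, calibrated = FALSE) {
  stopifnot(inherits(grid, "wl_grid"))
  values <- as.numeric(values)
  if (length(values) != length(grid$wl)) {
    stop("spectrum length does not match grid (", length(values), " vs ",
         length(grid$wl), ")", call. = FALSE)
  }
  if (anyNA(values)) stop("spectrum contains NA values", call. = FALSE)
  if (any(values < 0)) stop(role, " spectrum has negative values", call. = FALSE)
  if (role == "reflectance" && !calibrated && any(values > 1 + 1e-9)) {
    stop("reflectance above 1 requires calibrated = TRUE", call. = FALSE)
  }
  if (role == "illuminant" && all(values == 0)) {
    stop("illuminant spectrum is identically zero", call. = FALSE)
  }
  structure(list(grid = grid, values = values, role = role,
                 calibrated = isTRUE(calibrated)),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum:%s> %g-%g nm, range [%.4g, %.4g]\n", x$role,
              x$grid$start, x$grid$stop, min(x$values), max(x$values)))
  invisible(x)
}

#' Resample a spectrum onto another grid
#'
#' Linear interpolation; wavelengths outside the source grid take the
#' nearest endpoint value. Resampling onto the spectrum's own grid is the
#' identity.
#'
#' @param spec A `spectrum`.
#' @param grid Target [wl_grid()].
#' @return A `spectrum` on `grid`.
#' @export
resample <- function(spec, grid) {
  stopifnot(inherits(spec, "spectrum"), inherits(grid, "wl_grid"))
  if (same_grid(spec$grid, grid)) return(spec)
  v <- stats::approx(spec$grid$wl, spec$values, xout = grid$wl, rule = 2)$y
  new_spectrum(v, grid, role = spec$role, calibrated = spec$calibrated)
}

#' Read and write spectrum CSV files
#'
#' The canonical on-disk format is a two-column CSV with header
#' `wavelength_nm,value`, one sample per row, `#` comment lines allowed.
#' Measured wavelengths must be strictly increasing; the spectrum is
#' resampled onto `grid` by linear interpolation, extending beyond the
#' measured range with the nearest endpoint value.
#'
#' @param path File path.
#' @param kind `"reflectance"` or `"illuminant"`.
#' @param grid Target [wl_grid()].
#' @param calibrated Passed to [reflectance_spectrum()].
#' @return A `spectrum`.
#' @export
read_spectrum <- function(path, kind = c("reflectance", "illuminant"),
                          grid = wl_grid(), calibrated = FALSE) {
  kind <- match.arg(kind)
  tab <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse spectrum file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  req <- c("wavelength_nm", "value")
  if (!all(req %in% names(tab))) {
    stop("spectrum file must have columns 'wavelength_nm' and 'value'",
         call. = FALSE)
  }
  if (nrow(tab) < 2) stop("spectrum file needs at least 2 rows", call. = FALSE)
  wl <- as.numeric(tab$wavelength_nm)
  if (anyNA(wl) || any(diff(wl) <= 0)) {
    stop("wavelengths must be numeric and strictly increasing", call. = FALSE)
  }
  v <- stats::approx(wl, as.numeric(tab$value), xout = grid$wl, rule = 2)$y
  if (kind == "reflectance") reflectance_spectrum(v, grid, calibrated = calibrated)
  else illuminant_spectrum(v, grid)
}

#' @rdname read_spectrum
#' @param spec Spectrum to write.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum"))
  utils::write.csv(
    data.frame(wavelength_nm = spec$grid$wl, value = spec$values),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Flat (spectrally constant) reflectance
#'
#' Convenience constructor for achromatic spectra such as the grey
#' experimental background, which reflects constantly across the UV and
#' visible range.
#'
#' @param level Reflectance fraction.
#' @param grid A [wl_grid()].
#' @export
flat_spectrum <- function(level = 0.30, grid = wl_grid()) {
  reflectance_spectrum(rep(level, length(grid$wl)), grid)
}

# ---- photoreceptor sensitivity templates -----------------------------------

#' Visual-pigment sensitivity template
#'
#' Generates a relative spectral sensitivity curve for a photoreceptor with
#' peak absorbance at `lambda_max`, using the A1 visual-pigment alpha-band
#' template of Govardovskii et al. (2000), which is parameterised on the
#' normalised abscissa x = lambda_max / lambda. The optional beta band (a
#' Gaussian UV shoulder) is off by default. The curve is normalised so the
#' grid point nearest `lambda_max` equals exactly 1.
#'
#' @param lambda_max Peak wavelength in nm; must lie on the grid range.
#' @param grid A [wl_grid()].
#' @param receptor_id Label, conventionally one of `"UV"`, `"blue"`,
#'   `"green"`.
#' @param beta_band Include the beta band?
#' @return An object of class `sensitivity` (also a `spectrum`-like list
#'   with `grid`, `values`, plus `receptor_id` and `lambda_max`).
#' @export
receptor_template <- function(lambda_max, grid = wl_grid(),
                              receptor_id = NA_character_, beta_band = FALSE) {
  if (lambda_max < grid$start || lambda_max > grid$stop) {
    stop("lambda_max ", lambda_max, " nm lies outside the grid", call. = FALSE)
  }
  v <- govardovskii_a1(grid$wl, lambda_max, beta_band = beta_band)
  i0 <- which.min(abs(grid$wl - lambda_max))
  v <- v / v[i0]
  v <- pmin(v, 1)  # guard against float dust above the peak sample
  structure(list(grid = grid, values = v, receptor_id = receptor_id,
                 lambda_max = lambda_max),
            class = "sensitivity")
}

# Govardovskii et al. (2000) A1 alpha band (+ optional beta band),
# evaluated at wavelengths wl (nm) for a pigment peaking at lmax (nm).
govardovskii_a1 <- function(wl, lmax, beta_band = FALSE) {
  x <- lmax / wl
  A <- 69.7; B <- 28; C <- -14.9; D <- 0.674
  b <- 0.922; cc <- 1.104
  a <- 0.8795 + 0.0459 * exp(-(lmax - 300)^2 / 11940)
  alpha <- 1 / (exp(A * (a - x)) + exp(B * (b - x)) + exp(C * (cc - x)) + D)
  if (!beta_band) return(alpha)
  lmb <- 189 + 0.315 * lmax
  bb <- -40.5 + 0.195 * lmax
  beta <- 0.26 * exp(-((wl - lmb) / bb)^2)
  alpha + beta
}

#' @export
print.sensitivity <- function(x, ...) {
  cat(sprintf("<sensitivity> %s, lambda_max %g nm\n",
              ifelse(is.na(x$receptor_id), "?", x$receptor_id), x$lambda_max))
  invisible(x)
}

#' Trichromatic receptor set
#'
#' Bundles the UV, blue and green photoreceptor sensitivities on a shared
#' grid. Defaults are the canonical bee maxima (~340, ~430, ~540 nm); they
#' are overridable because species-specific curves (e.g. measured
#' *Melipona quadrifasciata* sensitivities) can be substituted.
#'
#' @param uv,blue,green Either peak wavelengths in nm (template curves are
#'   generated) or `sensitivity` objects on `grid`.
#' @param grid A [wl_grid()].
#' @return Object of class `receptor_set` with elements `uv`, `blue`,
#'   `green`.
#' @export
receptor_set <- function(uv = 340, blue = 430, green = 540, grid = wl_grid()) {
  as_sens <- function(x, id) {
    if (inherits(x, "sensitivity")) {
      if (!same_grid(x$grid, grid)) stop("sensitivity grids differ", call. = FALSE)
      x$receptor_id <- id
      x
    } else {
      receptor_template(x, grid, receptor_id = id)
    }
  }
  rs <- list(uv = as_sens(uv, "UV"), blue = as_sens(blue, "blue"),
             green = as_sens(green, "green"))
  lm <- vapply(rs, `[[`, numeric(1), "lambda_max")
  if (!(lm[["uv"]] < lm[["blue"]] && lm[["blue"]] < lm[["green"]])) {
    stop("receptor maxima must be ordered UV < blue < green", call. = FALSE)
  }
  structure(rs, class = "receptor_set")
}

#' @export
print.receptor_set <- function(x, ...) {
  cat(sprintf("<receptor_set> UV %g / blue %g / green %g nm\n",
              x$uv$lambda_max, x$blue$lambda_max, x$green$lambda_max))
  invisible(x)
}

# ---- illuminant ------------------------------------------------------------

#' CIE D65 daylight illuminant
#'
#' Returns the CIE standard illuminant D65 resampled onto `grid`. The
#' bundled table covers 300--700 nm (energy basis, 100 at 560 nm); requests
#' outside that range are a domain error. Because photoreceptors count
#' photons, the default basis converts the energy table to relative photon
#' flux (energy x lambda, rescaled so 560 nm keeps its value).
#'
#' @param grid A [wl_grid()] within 300--700 nm.
#' @param basis `"photon"` (default) or `"energy"`.
#' @return An illuminant `spectrum`.
#' @export
d65_illuminant <- function(grid = wl_grid(), basis = c("photon", "energy")) {
  basis <- match.arg(basis)
  path <- system.file("extdata", "cie_d65_300_700_5nm.csv", package = "hexabee",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#")
  if (grid$start < min(tab$wavelength_nm) || grid$stop > max(tab$wavelength_nm)) {
    stop("grid extends outside the tabulated D65 range (",
         min(tab$wavelength_nm), "-", max(tab$wavelength_nm), " nm)",
         call. = FALSE)
  }
  v <- stats::approx(tab$wavelength_nm, tab$value, xout = grid$wl)$y
  if (basis == "photon") v <- v * grid$wl / 560
  illuminant_spectrum(v, grid)
}
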