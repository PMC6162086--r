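#' Photoreceptor quantum catch
#'
#' The quantum flux caught by receptor i viewing a surface of reflectance
#' I(lambda) under illuminant D(lambda):
#' Q_i = integral over 300-700 nm of S_i(lambda) I(lambda) D(lambda) dlambda,
#' evaluated by the trapezoidal rule on the shared grid.
#'
#' @param S A `sensitivity`.
#' @param refl Reflectance `spectrum`.
#' @param illum Illuminant `spectrum`.
#' @return Non-negative quantum flux (arbitrary units).
#' @export
quantum_catch <- function(S, refl, illum) {
  stopifnot(inherits(S, "sensitivity"), inherits(refl, "spectrum"),
            inherits(illum, "spectrum"))
  if (!same_grid(S$grid, refl$grid) || !same_grid(S$grid, illum$grid)) {
    stop("sensitivity, reflectance and illuminant must share one grid",
         call. = FALSE)
  }
  pracma::trapz(S$grid$wl, S$values * refl$values * illum$values)
}

#' Von Kries adaptation factor
#'
#' The sensitivity factor R that adapts each receptor to the background:
#' R = 1 / Q_i(background), so the adapted background catch is exactly
#' P = Q R = 1 and the background excitation E = 0.5.
#'
#' @inheritParams quantum_catch
#' @param background Background reflectance `spectrum`.
#' @return Scalar R (1/flux units).
#' @export
adaptation_factor <- function(S, background, illum) {
  qb <- quantum_catch(S, background, illum)
  if (qb <= .Machine$double.eps) {
    stop("degenerate background: zero quantum catch for receptor ",
         S$receptor_id, call. = FALSE)
  }
  1 / qb
}

#' Receptor excitation
#'
#' Michaelis-Menten style transduction of the adapted catch P into
#' excitation E = P / (P + 1), bounded in [0, 1) and monotone in P. The
#' adapted background (P = 1) sits at half-maximal excitation.
#'
#' @param P Adapted quantum catch(es), >= 0.
#' @return Excitation value(s) in [0, 1).
#' @export
excitation <- function(P) {
  if (any(P < 0)) stop("adapted catch P must be non-negative", call. = FALSE)
  P / (P + 1)
}

#' Full receptor response to a stimulus
#'
#' Runs the quantum-catch -> adaptation -> excitation chain for all three
#' receptors, returning every intermediate quantity of the model.
#'
#' @param receptors A [receptor_set()].
#' @param refl Stimulus reflectance `spectrum`.
#' @param background Background reflectance `spectrum`.
#' @param illum Illuminant `spectrum`.
#' @return A data.frame with one row per receptor and columns
#'   `receptor` (UV/blue/green), `Q` (stimulus catch), `Qb` (background
#'   catch), `q` (receptor-specific contrast Q/Qb), `R` (adaptation factor),
#'   `P` (adapted catch, = q) and `E` (excitation).
#' @export
receptor_excitations <- function(receptors, refl, background, illum) {
  stopifnot(inherits(receptors, "receptor_set"))
  rows <- lapply(receptors, function(S) {
    Q <- quantum_catch(S, refl, illum)
    R <- adaptation_factor(S, background, illum)
    P <- Q * R
    data.frame(receptor = S$receptor_id, Q = Q, Qb = 1 / R, q = P, R = R,
               P = P, E = excitation(P))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

excitation_triple <- function(receptors, refl, background, illum) {
  ex <- receptor_excitations(receptors, refl, background, illum)
  stats::setNames(ex$E, c("uv", "blue", "green"))
}

#' Colour-hexagon locus
#'
#' Maps an excitation triple onto the colour hexagon:
#' x = sin(60 deg) (E_green - E_uv), y = E_blue - (E_uv + E_green) / 2.
#' The adapted background (0.5, 0.5, 0.5) maps to the origin; the three
#' single-receptor vertices lie at distance 1.
#'
#' @param E Named numeric vector with elements `uv`, `blue`, `green`, each
#'   in [0, 1].
#' @return Named numeric `c(x, y)` in hexagon units.
#' @export
hexagon_locus <- function(E) {
  E <- E[c("uv", "blue", "green")]
  if (anyNA(E)) stop("E must have elements uv, blue, green", call. = FALSE)
  if (any(E < 0 | E > 1)) stop("excitations must lie in [0, 1]", call. = FALSE)
  c(x = sin(pi / 3) * (E[["green"]] - E[["uv"]]),
    y = E[["blue"]] - 0.5 * (E[["uv"]] + E[["green"]]))
}

#' Chromatic contrast between two loci
#'
#' Euclidean (perceptual) distance in hexagon units. With the default
#' second argument it is the contrast against the background, i.e. the
#' distance from the hexagon centre.
#'
#' @param a,b Hexagon loci (`c(x, y)`).
#' @return Distance in hexagon units.
#' @export
chromatic_contrast <- function(a, b = c(x = 0, y = 0)) {
  sqrt((a[["x"]] - b[["x"]])^2 + (a[["y"]] - b[["y"]])^2)
}

#' Spectral locus of monochromatic lights
#'
#' Computes the hexagon locus of monochromatic light at every grid
#' wavelength, for the given adaptation state. A monochromatic light at
#' wavelength lambda drives the receptors in proportion to
#' s_i = S_i(lambda) D(lambda) R_i; its hexagon position depends on its
#' intensity, which the hexagon does not normalise away. The spectral line
#' is therefore defined at the adaptation-matched intensity: each
#' monochromatic light is scaled so that its total adapted catch equals
#' that of the background (sum of P_i = 3, the background's own total),
#' i.e. P_i = 3 s_i / (s_uv + s_blue + s_green). This makes the curve
#' unique, independent of any spike-amplitude choice, bounded (E_i <=
#' 0.75), and shaped like the classic horseshoe with its ends near the UV
#' and green vertices. The "purple line" closing segment joining the long-
#' and short-wavelength ends is included by default so every hue direction
#' has a defined spectral-purity denominator.
#'
#' @inheritParams receptor_excitations
#' @param amplitude `NULL` (default) for the adaptation-matched
#'   construction, or a fixed spike intensity for exploration.
#' @param close Include the purple closing segment?
#' @return A data.frame (class `spectral_locus`) with columns `wavelength`,
#'   `x`, `y`, `E_uv`, `E_blue`, `E_green`, ordered 300 -> 700 nm;
#'   attribute `closed` records whether the purple line applies.
#' @export
spectral_locus <- function(receptors, background, illum,
                           amplitude = NULL, close = TRUE) {
  stopifnot(inherits(receptors, "receptor_set"))
  R <- vapply(receptors, adaptation_factor, numeric(1),
              background = background, illum = illum)
  wl <- receptors$uv$grid$wl
  D <- illum$values
  drives <- cbind(uv = receptors$uv$values * D * R[["uv"]],
                  blue = receptors$blue$values * D * R[["blue"]],
                  green = receptors$green$values * D * R[["green"]])
  sin60 <- sin(pi / 3)
  pts <- t(apply(drives, 1, function(s) {
    P <- if (is.null(amplitude)) 3 * s / sum(s) else amplitude * s / max(s)
    E <- excitation(P)
    c(x = sin60 * (E[[3]] - E[[1]]), y = E[[2]] - 0.5 * (E[[1]] + E[[3]]),
      E_uv = E[[1]], E_blue = E[[2]], E_green = E[[3]])
  }))
  out <- data.frame(wavelength = wl, x = pts[, "x"], y = pts[, "y"],
                    E_uv = pts[, "E_uv"], E_blue = pts[, "E_blue"],
                    E_green = pts[, "E_green"])
  attr(out, "closed") <- isTRUE(close)
  class(out) <- c("spectral_locus", class(out))
  out
}

# Nearest intersection of the ray from the origin through `locus` with the
# (optionally closed) spectral-locus polyline. Returns the ray parameter t
# such that the intersection point is t * unit(locus), plus the segment
# endpoints' wavelengths for dominant-wavelength interpolation.
ray_curve_intersection <- function(locus, curve, tol = 1e-12) {
  r <- sqrt(locus[["x"]]^2 + locus[["y"]]^2)
  u <- c(locus[["x"]], locus[["y"]]) / r
  p <- cbind(curve$x, curve$y)
  wlv <- curve$wavelength
  if (isTRUE(attr(curve, "closed"))) {
    p <- rbind(p, p[1, ])
    wlv <- c(wlv, NA_real_)  # purple segment carries no wavelength
  }
  best <- NULL
  for (k in seq_len(nrow(p) - 1)) {
    a <- p[k, ]; b <- p[k + 1, ]
    d <- b - a
    den <- u[1] * (-d[2]) - u[2] * (-d[1])
    if (abs(den) < tol) next  # segment parallel to the ray
    # solve t*u - s*d = a  for (t, s)
    t_par <- (a[1] * (-d[2]) - a[2] * (-d[1])) / den
    s_par <- (u[1] * a[2] - u[2] * a[1]) / den
    if (t_par > tol && s_par >= -tol && s_par <= 1 + tol) {
      if (is.null(best) || t_par < best$t) {
        wl_hit <- if (is.na(wlv[k]) || k + 1 > length(curve$wavelength)) NA_real_
                  else curve$wavelength[k] + s_par * (curve$wavelength[k + 1] - curve$wavelength[k])
        best <- list(t = t_par, wavelength = wl_hit)
      }
    }
  }
  if (is.null(best)) {
    stop("ray from background through the stimulus misses the spectral ",
         "locus; is the curve closed?", call. = FALSE)
  }
  best
}

#' Spectral purity
#'
#' The bee-subjective saturation of a stimulus: the ratio of its perceptual
#' distance from the background to the distance from the background to the
#' spectral line along the same hue direction,
#' SP = H(target - background) / H(spectral locus - background).
#' A stimulus on the spectral locus has SP = 1; the background itself is
#' assigned SP = 0 by convention (its hue direction is undefined).
#'
#' @param locus Stimulus hexagon locus (`c(x, y)`).
#' @param curve A [spectral_locus()].
#' @return SP in [0, 1] for loci inside the closed spectral locus.
#' @export
spectral_purity <- function(locus, curve) {
  r <- sqrt(locus[["x"]]^2 + locus[["y"]]^2)
  if (r == 0) return(0)
  hit <- ray_curve_intersection(locus, curve)
  r / hit$t
}

#' Dominant wavelength
#'
#' The wavelength of the spectral-locus point intersected by the ray from
#' the background through the stimulus locus (bee-subjective hue). `NA` for
#' the background itself and for hue directions that intersect the purple
#' closing segment.
#'
#' @inheritParams spectral_purity
#' @return Wavelength in nm, or `NA`.
#' @export
dominant_wavelength <- function(locus, curve) {
  r <- sqrt(locus[["x"]]^2 + locus[["y"]]^2)
  if (r == 0) return(NA_real_)
  ray_curve_intersection(locus, curve)$wavelength
}

#' Bee-subjective intensity
#'
#' The mean of the three receptor excitations,
#' (E_uv + E_blue + E_green) / 3; the adapted background scores 0.5.
#'
#' @param E Named excitation triple (`uv`, `blue`, `green`).
#' @return Intensity in [0, 1).
#' @export
intensity <- function(E) {
  E <- E[c("uv", "blue", "green")]
  if (anyNA(E)) stop("E must have elements uv, blue, green", call. = FALSE)
  mean(E)
}

#' Receiver-independent saturation and luminance
#'
#' Physical colour descriptors computed from the reflectance spectrum alone
#' (no photoreceptor sensitivities): luminance is the mean reflectance over
#' the grid, saturation is the Michelson spectral contrast
#' (Rmax - Rmin) / (Rmax + Rmin), which is invariant to rescaling the
#' spectrum by a positive constant. An all-zero spectrum has saturation 0
#' by convention.
#'
#' @param refl Reflectance `spectrum`.
#' @return Named numeric `c(saturation, luminance)`.
#' @export
physical_metrics <- function(refl) {
  stopifnot(inherits(refl, "spectrum"))
  v <- refl$values
  lum <- mean(v)
  sat <- if (max(v) + min(v) == 0) 0 else (max(v) - min(v)) / (max(v) + min(v))
  c(saturation = sat, luminance = lum)
}

#' Colour metrics for a set of stimuli
#'
#' Convenience wrapper running the full hexagon model for each stimulus
#' spectrum against one background and illuminant.
#'
#' @param spectra Named list of reflectance `spectrum` objects.
#' @param receptors A [receptor_set()].
#' @param background Background reflectance `spectrum`.
#' @param illum Illuminant `spectrum`; default D65 (photon basis) on the
#'   receptor grid.
#' @param curve Optional precomputed [spectral_locus()] (recomputed
#'   otherwise).
#' @return A data.frame with one row per stimulus: `stimulus_id`, `E_uv`,
#'   `E_blue`, `E_green`, `x`, `y`, `chromatic_contrast`, `spectral_purity`,
#'   `dominant_wavelength`, `intensity`, `physical_saturation`, `luminance`.
#' @export
colour_metrics <- function(spectra, receptors, background,
                           illum = d65_illuminant(receptors$uv$grid),
                           curve = NULL) {
  if (is.null(names(spectra)) || any(names(spectra) == "")) {
    stop("'spectra' must be a named list", call. = FALSE)
  }
  if (is.null(curve)) curve <- spectral_locus(receptors, background, illum)
  rows <- lapply(names(spectra), function(id) {
    E <- excitation_triple(receptors, spectra[[id]], background, illum)
    loc <- hexagon_locus(E)
    phys <- physical_metrics(spectra[[id]])
    data.frame(stimulus_id = id,
               E_uv = E[["uv"]], E_blue = E[["blue"]], E_green = E[["green"]],
               x = loc[["x"]], y = loc[["y"]],
               chromatic_contrast = chromatic_contrast(loc),
               spectral_purity = spectral_purity(loc, curve),
               dominant_wavelength = dominant_wavelength(loc, curve),
               intensity = intensity(E),
               physical_saturation = phys[["saturation"]],
               luminance = phys[["luminance"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
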