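test_that("quantum catch reduces to closed-form integrals", {
  g <- wl_grid()
  ones <- rep(1, length(g$wl))
  S <- receptor_template(540, g)
  S$values <- ones  # unit sensitivity for the analytic case
  refl1 <- reflectance_spectrum(ones, g, calibrated = TRUE)
  illum1 <- illuminant_spectrum(ones, g)
  expect_equal(quantum_catch(S, refl1, illum1), 400)

  refl0 <- reflectance_spectrum(rep(0, length(g$wl)), g)
  expect_equal(quantum_catch(S, refl0, illum1), 0)

  # boxcar sensitivity on [500, 600], I = 0.5, D = 2 -> 0.5 * 2 * 100
  S$values <- as.numeric(g$wl >= 500 & g$wl <= 600)
  reflh <- reflectance_spectrum(ones * 0.5, g)
  illum2 <- illuminant_spectrum(ones * 2, g)
  expect_equal(quantum_catch(S, reflh, illum2), 100, tolerance = 0.02)
})

test_that("mismatched grids are a shape error", {
  g1 <- wl_grid(); g2 <- wl_grid(300, 700, 2)
  S <- receptor_template(540, g1)
  expect_error(
    quantum_catch(S, flat_spectrum(0.3, g2), d65_illuminant(g1)),
    "share one grid")
})

test_that("adaptation makes the background the neutral point", {
  rs <- hx_receptors(); bg <- hx_background(); il <- hx_illum()
  ex <- receptor_excitations(rs, bg, bg, il)
  expect_equal(ex$q, rep(1, 3))
  expect_equal(ex$P, rep(1, 3))
  expect_equal(ex$E, rep(0.5, 3))
  E <- setNames(ex$E, c("uv", "blue", "green"))
  loc <- hexagon_locus(E)
  expect_equal(unname(loc), c(0, 0), tolerance = 1e-12)
  expect_equal(chromatic_contrast(loc), 0, tolerance = 1e-12)
  expect_equal(spectral_purity(loc, hx_curve()), 0, tolerance = 1e-9)
  expect_equal(intensity(E), 0.5)
})

test_that("reciprocal adaptation factor and degenerate background error", {
  g <- wl_grid()
  S <- receptor_template(540, g)
  S$values <- rep(1, length(g$wl))
  # background with catch exactly 2: flat level 2/400 under unit illuminant
  bg <- reflectance_spectrum(rep(2 / 400, length(g$wl)), g)
  il <- illuminant_spectrum(rep(1, length(g$wl)), g)
  expect_equal(adaptation_factor(S, bg, il), 0.5)
  bg0 <- reflectance_spectrum(rep(0, length(g$wl)), g)
  expect_error(adaptation_factor(S, bg0, il), "degenerate background")
})

test_that("excitation transform obeys its closed form", {
  expect_equal(excitation(1), 0.5)
  expect_equal(excitation(0), 0)
  expect_equal(excitation(3), 0.75)
  expect_error(excitation(-0.1), "non-negative")
  P <- seq(0, 50, by = 0.5)
  expect_true(all(diff(excitation(P)) > 0))
  expect_true(all(excitation(P) >= 0 & excitation(P) < 1))
})

test_that("hexagon vertices and distances behave geometrically", {
  expect_equal(unname(hexagon_locus(c(uv = 0.5, blue = 0.5, green = 0.5))),
               c(0, 0))
  expect_equal(unname(hexagon_locus(c(uv = 0, blue = 1, green = 0))), c(0, 1))
  expect_equal(unname(hexagon_locus(c(uv = 0, blue = 0, green = 1))),
               c(sin(pi / 3), -0.5))
  expect_equal(
    chromatic_contrast(hexagon_locus(c(uv = 0, blue = 1, green = 0))), 1)
  # metric properties on random triples
  set.seed(7)
  for (i in 1:25) {
    E3 <- matrix(runif(9), 3)
    l <- apply(E3, 1, function(e) hexagon_locus(c(uv = e[1], blue = e[2],
                                                  green = e[3])))
    d_ab <- chromatic_contrast(l[, 1], l[, 2])
    d_ba <- chromatic_contrast(l[, 2], l[, 1])
    expect_equal(d_ab, d_ba)
    expect_lte(d_ab,
               chromatic_contrast(l[, 1], l[, 3]) +
                 chromatic_contrast(l[, 3], l[, 2]) + 1e-12)
  }
})

test_that("the spectral locus is bounded, ordered and peaks at receptor maxima", {
  curve <- hx_curve()
  expect_true(all(sqrt(curve$x^2 + curve$y^2) <= 1))
  expect_true(all(diff(curve$wavelength) > 0))
  # monochromatic light at a receptor's lambda_max maximises that
  # receptor's excitation along the curve (numeric scan)
  rs <- hx_receptors()
  expect_equal(curve$wavelength[which.max(curve$E_uv)], rs$uv$lambda_max,
               tolerance = 6)
  expect_equal(curve$wavelength[which.max(curve$E_blue)], rs$blue$lambda_max,
               tolerance = 6)
  # green drive saturates over a long-wavelength plateau; the peak must at
  # least reach the green maximum region
  expect_gte(curve$wavelength[which.max(curve$E_green)], rs$green$lambda_max - 6)
})

test_that("the spectral locus is invariant to spike amplitude by construction", {
  rs <- hx_receptors(); bg <- hx_background()
  il <- hx_illum()
  il10 <- illuminant_spectrum(il$values * 10, hx_grid())
  c1 <- spectral_locus(rs, bg, il)
  c2 <- spectral_locus(rs, bg, il10)  # von Kries also cancels illuminant scale
  expect_equal(c1$x, c2$x, tolerance = 1e-10)
  expect_equal(c1$y, c2$y, tolerance = 1e-10)
})

test_that("spectral purity follows the ray geometry", {
  curve <- hx_curve()
  expect_equal(spectral_purity(c(x = 0, y = 0), curve), 0)
  # a point on the curve has SP 1; its midpoint to the origin has SP 0.5
  # tolerance allows the ray to clip a neighbouring segment of the
  # (non-convex) polyline fractionally before the vertex itself
  for (i in c(50, 130, 240, 330)) {
    pt <- c(x = curve$x[i], y = curve$y[i])
    expect_equal(spectral_purity(pt, curve), 1, tolerance = 1e-3)
    expect_equal(spectral_purity(pt / 2, curve), 0.5, tolerance = 1e-3)
  }
  # an open curve with a ray aimed at the gap is a geometry error
  open_curve <- curve[curve$wavelength >= 400, ]
  attr(open_curve, "closed") <- FALSE
  class(open_curve) <- class(curve)
  expect_error(spectral_purity(c(x = -0.4, y = -0.22), open_curve), "misses")
})

test_that("dominant wavelength is the hue direction's intersection", {
  curve <- hx_curve()
  pt <- c(x = curve$x[150], y = curve$y[150]) * 0.5
  expect_equal(dominant_wavelength(pt, curve), curve$wavelength[150],
               tolerance = 1.0)
  expect_true(is.na(dominant_wavelength(c(x = 0, y = 0), curve)))
})

test_that("intensity is the mean excitation", {
  expect_equal(intensity(c(uv = 0.5, blue = 0.5, green = 0.5)), 0.5)
  expect_equal(intensity(c(uv = 0, blue = 0, green = 0)), 0)
  expect_equal(intensity(c(uv = 0.2, blue = 0.4, green = 0.6)), 0.4)
})

test_that("physical saturation and luminance are receiver-independent", {
  g <- wl_grid()
  flat <- flat_spectrum(0.3, g)
  pm <- physical_metrics(flat)
  expect_equal(unname(pm["saturation"]), 0)
  expect_equal(unname(pm["luminance"]), 0.3)

  box <- reflectance_spectrum(as.numeric(g$wl >= 500 & g$wl <= 600), g)
  expect_equal(unname(physical_metrics(box)["saturation"]), 1)

  s <- reflectance_spectrum(0.1 + 0.2 * exp(-((g$wl - 450) / 50)^2), g)
  s2 <- reflectance_spectrum(s$values * 2.5, s$grid, calibrated = TRUE)
  expect_equal(physical_metrics(s)[["saturation"]],
               physical_metrics(s2)[["saturation"]])
  expect_equal(unname(physical_metrics(
    reflectance_spectrum(rep(0, length(g$wl)), g))["saturation"]), 0)
})

test_that("flat stimuli are achromatic with intensity k/(k+1)", {
  rs <- hx_receptors(); bg <- hx_background(); il <- hx_illum()
  for (lev in c(0.1, 0.3, 0.6)) {
    E <- hexabee:::excitation_triple(rs, flat_spectrum(lev, hx_grid()), bg, il)
    k <- lev / 0.30
    expect_equal(unname(E), rep(k / (k + 1), 3), tolerance = 1e-12)
    loc <- hexagon_locus(E)
    expect_equal(chromatic_contrast(loc), 0, tolerance = 1e-12)
  }
})

test_that("von Kries: illuminant scaling leaves the model invariant", {
  rs <- hx_receptors(); bg <- hx_background(); il <- hx_illum()
  s <- hx_setup()$stimuli$spectra[["blue_P+_I+"]]
  il_s <- illuminant_spectrum(il$values * 7.3, hx_grid())
  E1 <- hexabee:::excitation_triple(rs, s, bg, il)
  E2 <- hexabee:::excitation_triple(rs, s, bg, il_s)
  expect_equal(E1, E2, tolerance = 1e-10)
  expect_equal(spectral_purity(hexagon_locus(E1), hx_curve()),
               spectral_purity(hexagon_locus(E2),
                               spectral_locus(rs, bg, il_s)),
               tolerance = 1e-10)
  expect_equal(intensity(E1), intensity(E2), tolerance = 1e-10)
})

test_that("the model agrees with a brute-force path from the raw integrals", {
  # independent oracle: plain Riemann-trapezoid sums and the displayed
  # formula chain written out inline, no package colorimetry calls
  g <- hx_grid(); rs <- hx_receptors(); bg <- hx_background(); il <- hx_illum()
  s <- hx_setup()$stimuli$spectra[["yellow_P+_I+"]]
  wl <- g$wl
  trap <- function(v) sum((v[-1] + v[-length(v)]) / 2 * diff(wl))
  E_oracle <- vapply(list(rs$uv, rs$blue, rs$green), function(S) {
    Q <- trap(S$values * s$values * il$values)
    Qb <- trap(S$values * bg$values * il$values)
    P <- Q / Qb
    P / (P + 1)
  }, numeric(1))
  x_o <- sin(pi / 3) * (E_oracle[3] - E_oracle[1])
  y_o <- E_oracle[2] - 0.5 * (E_oracle[1] + E_oracle[3])
  E_pkg <- hexabee:::excitation_triple(rs, s, bg, il)
  loc <- hexagon_locus(E_pkg)
  expect_equal(unname(E_pkg), E_oracle, tolerance = 1e-10)
  expect_equal(unname(loc), c(x_o, y_o), tolerance = 1e-10)
  expect_equal(chromatic_contrast(loc), sqrt(x_o^2 + y_o^2), tolerance = 1e-10)
})

test_that("colour_metrics reports one tidy row per stimulus", {
  setup <- hx_setup()
  m <- setup$metrics
  expect_equal(nrow(m), 24)
  expect_true(all(c("stimulus_id", "E_uv", "x", "chromatic_contrast",
                    "spectral_purity", "intensity", "physical_saturation",
                    "luminance") %in% names(m)))
  expect_true(all(m$spectral_purity >= 0 & m$spectral_purity <= 1))
  expect_true(all(m$intensity > 0 & m$intensity < 1))
})
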