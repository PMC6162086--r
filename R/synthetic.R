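#' Synthetic pigment library
#'
#' Idealised reflectance spectra standing in for the artist pigments from
#' which dual-choice stimuli are pressed: chromatic pigments as smooth
#' Gaussian (blue) or long-pass sigmoid (yellow, red) reflectance shapes,
#' UV variants adding a 300-400 nm shoulder, and achromatic diluents
#' (UV-reflecting white, UV-absorbing white, grey, black) as flat or
#' step spectra. All values lie in [0, 1].
#'
#' @param grid A [wl_grid()].
#' @return Named list of reflectance `spectrum` objects with a `role`
#'   attribute (`"chromatic"`, `"white"`, `"grey"`, `"black"`).
#' @export
pigment_library <- function(grid = wl_grid()) {
  wl <- grid$wl
  gauss <- function(peak, width, high, base = 0.04) {
    base + (high - base) * exp(-((wl - peak) / width)^2)
  }
  longpass <- function(edge, width, high, low = 0.04) {
    low + (high - low) / (1 + exp(-(wl - edge) / width))
  }
  mk <- function(v, role) {
    s <- reflectance_spectrum(pmin(v, 1), grid)
    attr(s, "pigment_role") <- role
    s
  }
  list(
    blue = mk(gauss(450, 45, 0.65), "chromatic"),
    uv_blue = mk(pmin(gauss(450, 45, 0.65) + gauss(340, 30, 0.18, 0), 1), "chromatic"),
    yellow = mk(longpass(520, 15, 0.80), "chromatic"),
    uv_yellow = mk(pmin(longpass(520, 15, 0.80) + gauss(340, 30, 0.15, 0), 1), "chromatic"),
    red = mk(longpass(600, 12, 0.70, 0.03), "chromatic"),
    white_uv = mk(rep(0.90, length(wl)), "white"),
    white_nouv = mk(longpass(395, 12, 0.90, 0.06), "white"),
    grey = mk(rep(0.30, length(wl)), "grey"),
    # dark UV-absorbing grey: same spectral shape as the UV-absorbing white
    # at lower level, used to dim it without changing its bee-subjective hue
    slate_nouv = mk(longpass(395, 12, 0.25, 0.0167), "grey"),
    black = mk(rep(0.02, length(wl)), "black"))
}

#' Subtractive pigment mixing
#'
#' Mixes pigment reflectances by the weighted geometric mean,
#' R_mix(lambda) = prod_k R_k(lambda)^w_k, a one-parameter stand-in for
#' Kubelka-Munk mixing that is monotone in every component. Reflectances
#' are floored at 1e-4 before mixing and the result clipped to [1e-4, 1].
#'
#' @param recipe Named numeric weights (mass fractions), non-negative,
#'   summing to 1; names must match `pigments`.
#' @param pigments Named list of reflectance `spectrum` objects sharing one
#'   grid (e.g. [pigment_library()]).
#' @return A reflectance `spectrum`.
#' @export
mix_pigments <- function(recipe, pigments) {
  eps <- 1e-4
  if (any(recipe < 0)) stop("recipe weights must be non-negative", call. = FALSE)
  if (abs(sum(recipe) - 1) > 1e-8) stop("recipe weights must sum to 1", call. = FALSE)
  if (!all(names(recipe) %in% names(pigments))) {
    stop("recipe names unknown among pigments", call. = FALSE)
  }
  recipe <- recipe[recipe > 0]
  grid <- pigments[[names(recipe)[1]]]$grid
  logmix <- 0
  for (nm in names(recipe)) {
    p <- pigments[[nm]]
    if (!same_grid(p$grid, grid)) stop("pigment grids differ", call. = FALSE)
    logmix <- logmix + recipe[[nm]] * log(pmax(p$values, eps))
  }
  reflectance_spectrum(pmin(pmax(exp(logmix), eps), 1), grid)
}

# Dilution schedules tried in order when building a graded stimulus series;
# the first whose computed orderings certify is kept. Weights are the
# achromatic shares of each member: the P+ pair keeps a high chromatic
# share (lightly whitened at I+, lightly blackened at I-), the P- pair a
# low one (white at I+, grey at I-), which keeps spectral purity matched
# within each intensity pair while separating the two purity levels.
.series_schedules <- list(
  list(pp_w = 0.20, pp_b = 0.10, pm_w = 0.65, pm_g = 0.65,
       wh_b = 0.25, wh_s = 0.55),
  list(pp_w = 0.15, pp_b = 0.12, pm_w = 0.60, pm_g = 0.60,
       wh_b = 0.30, wh_s = 0.50),
  list(pp_w = 0.25, pp_b = 0.08, pm_w = 0.70, pm_g = 0.70,
       wh_b = 0.20, wh_s = 0.60))

#' Generate one category's graded stimulus series
#'
#' Builds the four stimuli of a colour category as pigment mixes crossing
#' two spectral-purity levels with two intensity levels (for white: UV
#' reflectance crossed with intensity). The series emulates the stimulus
#' *selection* of the dual-choice design: within each purity level the I+
#' and I- members are matched in spectral purity so that the intensity
#' axis is not confounded with saturation, and vice versa. The series is
#' self-validating under the hexagon model: it must certify
#' SP(P+) > SP(P-) at each intensity level, intensity(I+) > intensity(I-)
#' at each purity level, and SP matching within intensity pairs; recipe
#' weights are re-tried from a fixed ladder and an error is raised if no
#' schedule certifies.
#'
#' @param category One of [CATEGORIES].
#' @param pigments A [pigment_library()].
#' @param receptors,background,illum Viewing conditions for certification.
#' @param curve Optional precomputed [spectral_locus()].
#' @return Named list of 4 reflectance spectra; names are
#'   `<category>_<level>_<intensity>` (e.g. `"blue_P+_I+"`); attribute
#'   `levels` is the matching stimulus-table rows.
#' @export
make_stimulus_series <- function(category, pigments, receptors, background,
                                 illum, curve = NULL) {
  stopifnot(category %in% CATEGORIES)
  if (is.null(curve)) curve <- spectral_locus(receptors, background, illum)
  chrom <- switch(category,
                  "UV-blue" = "uv_blue", "blue" = "blue",
                  "UV-yellow" = "uv_yellow", "yellow" = "yellow",
                  "red" = "red", "white" = NA_character_)

  mixw <- function(w, diluent) {
    mix_pigments(stats::setNames(c(1 - w, w), c(chrom, diluent)), pigments)
  }
  build <- function(sch) {
    if (category == "white") {
      list("UV+_I+" = mix_pigments(c(white_uv = 1), pigments),
           "UV+_I-" = mix_pigments(stats::setNames(c(1 - sch$wh_b, sch$wh_b),
                                                   c("white_uv", "black")),
                                   pigments),
           "UV-_I+" = mix_pigments(c(white_nouv = 1), pigments),
           "UV-_I-" = mix_pigments(stats::setNames(c(1 - sch$wh_s, sch$wh_s),
                                                   c("white_nouv", "slate_nouv")),
                                   pigments))
    } else {
      list("P+_I+" = mixw(sch$pp_w, "white_uv"),
           "P+_I-" = mixw(sch$pp_b, "black"),
           "P-_I+" = mixw(sch$pm_w, "white_uv"),
           "P-_I-" = mixw(sch$pm_g, "grey"))
    }
  }

  certify <- function(sp) {
    m <- colour_metrics(sp, receptors, background, illum, curve = curve)
    sel <- function(lv) m[m$stimulus_id == lv, ]
    pn <- names(sp)
    # intensity ordering within each purity/UV level
    int_ok <- sel(pn[1])$intensity > sel(pn[2])$intensity &&
      sel(pn[3])$intensity > sel(pn[4])$intensity
    # saturation matched within each intensity pair (selection criterion)
    sp_match <- abs(sel(pn[1])$spectral_purity - sel(pn[2])$spectral_purity) <= 0.1 &&
      abs(sel(pn[3])$spectral_purity - sel(pn[4])$spectral_purity) <= 0.1
    if (category == "white") return(int_ok && sp_match)
    pur_ok <- sel("P+_I+")$spectral_purity > sel("P-_I+")$spectral_purity &&
      sel("P+_I-")$spectral_purity > sel("P-_I-")$spectral_purity
    int_ok && sp_match && pur_ok
  }

  for (sch in .series_schedules) {
    sp <- build(sch)
    if (certify(sp)) {
      names(sp) <- paste0(category, "_", names(sp))
      lv <- do.call(rbind, strsplit(sub("^.*_(UV.|P.)_(I.)$", "\\1;\\2",
                                        names(sp)), ";"))
      attr(sp, "levels") <- data.frame(id = names(sp), category = category,
                                       purity_level = lv[, 1],
                                       intensity_level = lv[, 2],
                                       stringsAsFactors = FALSE)
      return(sp)
    }
  }
  stop("could not generate a certified ", category, " series: purity/",
       "intensity orderings violated for all dilution schedules", call. = FALSE)
}

#' Default synthetic stimulus set
#'
#' Generates all six categories' graded series under one set of viewing
#' conditions and assembles them with [build_stimulus_set()].
#'
#' @inheritParams make_stimulus_series
#' @return List with `stimuli` (a `stimulus_set`), `metrics` (the
#'   [colour_metrics()] table for all 24 stimuli) and `curve` (the spectral
#'   locus used).
#' @export
default_stimulus_set <- function(receptors = receptor_set(),
                                 background = flat_spectrum(0.30, receptors$uv$grid),
                                 illum = d65_illuminant(receptors$uv$grid),
                                 pigments = pigment_library(receptors$uv$grid)) {
  curve <- spectral_locus(receptors, background, illum)
  spectra <- list()
  tabs <- list()
  for (cat in CATEGORIES) {
    s <- make_stimulus_series(cat, pigments, receptors, background, illum, curve)
    tabs[[cat]] <- attr(s, "levels")
    attr(s, "levels") <- NULL
    spectra <- c(spectra, s)
  }
  stimuli <- build_stimulus_set(do.call(rbind, tabs), spectra)
  metrics <- colour_metrics(stimuli$spectra, receptors, background, illum,
                            curve = curve)
  list(stimuli = stimuli, metrics = metrics, curve = curve)
}

#' Bee preference model
#'
#' Ground-truth choice model for simulated foragers. A stimulus's utility
#' is `beta_purity * SP + beta_intensity * intensity +
#' hue_effect[category]` (log-odds scale); in a dual test the probability
#' of choosing the canonically first stimulus (alphabetically first id,
#' independent of side) is `plogis(u_first - u_second + b_bee)` with a
#' per-bee intercept `b_bee ~ N(0, sigma_bee)`.
#'
#' @param beta_purity,beta_intensity Log-odds per unit predictor.
#' @param hue_effects Named log-odds per category (defaults all 0).
#' @param sigma_bee Random-intercept SD (>= 0).
#' @return Object of class `bee_preference_model`.
#' @export
bee_preference_model <- function(beta_purity = 0, beta_intensity = 0,
                                 hue_effects = NULL, sigma_bee = 0) {
  if (sigma_bee < 0) stop("sigma_bee must be >= 0", call. = FALSE)
  he <- stats::setNames(rep(0, length(CATEGORIES)), CATEGORIES)
  if (!is.null(hue_effects)) {
    if (!all(names(hue_effects) %in% CATEGORIES)) {
      stop("unknown categories in hue_effects", call. = FALSE)
    }
    he[names(hue_effects)] <- hue_effects
  }
  structure(list(beta_purity = beta_purity, beta_intensity = beta_intensity,
                 hue_effects = he, sigma_bee = sigma_bee),
            class = "bee_preference_model")
}

#' Preset preference models
#'
#' `helleri_model()` encodes a purity-driven chooser with a bluish hue bias
#' and a red penalty, qualitatively matching a *Partamona helleri*-like
#' pattern (purer stimuli preferred within categories, blue and
#' UV-absorbing white on top of the hue ranking, red least chosen).
#' `bicolor_model()` is the generalist null: no purity, intensity or hue
#' effect, only idiosyncratic per-bee variation, as observed for
#' *Melipona bicolor*-like choosers.
#' @export
helleri_model <- function() {
  bee_preference_model(
    beta_purity = 4, beta_intensity = 0,
    hue_effects = c("UV-blue" = 0.6, "blue" = 1.2, "UV-yellow" = 0,
                    "yellow" = 0, "red" = -2, "white" = 0.8),
    sigma_bee = 0.5)
}

#' @rdname helleri_model
#' @export
bicolor_model <- function() {
  bee_preference_model(sigma_bee = 0.5)
}

stimulus_utility <- function(model, metrics, stimuli) {
  u <- model$beta_purity * metrics$spectral_purity +
    model$beta_intensity * metrics$intensity +
    model$hue_effects[stimuli$table$category[match(metrics$stimulus_id,
                                                   stimuli$table$id)]]
  stats::setNames(as.numeric(u), metrics$stimulus_id)
}

#' Simulate forager choices
#'
#' Draws one choice per bee and scheduled dual test under a
#' [bee_preference_model()]. Fully reproducible: the same seed yields a
#' byte-identical choice table.
#'
#' @param model A [bee_preference_model()].
#' @param schedule A [generate_schedule()] result.
#' @param stimuli The matching `stimulus_set`.
#' @param metrics [colour_metrics()] for all scheduled stimuli.
#' @param n_bees Number of simulated bees.
#' @param seed Integer seed.
#' @param species Species label written into the records.
#' @return Choice-record data.frame (see [read_choice_table()]).
#' @export
simulate_bees <- function(model, schedule, stimuli, metrics, n_bees,
                          seed = 1L, species = "simulated") {
  stopifnot(inherits(model, "bee_preference_model"))
  miss <- setdiff(unique(c(schedule$stimulus_left, schedule$stimulus_right)),
                  metrics$stimulus_id)
  if (length(miss)) {
    stop("metrics missing for scheduled stimuli: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  u <- stimulus_utility(model, metrics, stimuli)
  first <- pmin(schedule$stimulus_left, schedule$stimulus_right)
  second <- pmax(schedule$stimulus_left, schedule$stimulus_right)
  du <- u[first] - u[second]
  withr::with_seed(seed, {
    recs <- lapply(seq_len(n_bees), function(b) {
      bi <- stats::rnorm(1, 0, model$sigma_bee)
      p_first <- stats::plogis(du + bi)
      pick_first <- stats::rbinom(length(du), 1, p_first) == 1
      data.frame(bee_id = sprintf("bee%02d", b), species = species,
                 test_index = schedule$test_index,
                 stimulus_left = schedule$stimulus_left,
                 stimulus_right = schedule$stimulus_right,
                 chosen = ifelse(pick_first, first, second),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, recs)
  })
}

#' Parameter-recovery experiment
#'
#' Repeatedly simulates choice data under a known preference model and
#' re-estimates the purity and intensity coefficients with a binomial GLMM
#' on per-choice predictor differences
#' (`chose_first ~ 0 + dSP + dI + (1 | bee)`), reporting bias, spread and
#' Wald 95% coverage of the estimates.
#'
#' @param true_model A [bee_preference_model()].
#' @param n_bees Bees per replicate.
#' @param n_reps Number of replicates.
#' @param seed Integer seed; replicate r uses `seed + r`.
#' @param setup Optional precomputed [default_stimulus_set()] result.
#' @param schedule_seed Seed for the fixed schedule used by all replicates.
#' @return List with `estimates` (per-rep data.frame: `beta_purity`,
#'   `se_purity`, `beta_intensity`, `converged`) and `summary` (mean, sd,
#'   bias and coverage for beta_purity, plus `n_failed`).
#' @export
recovery_experiment <- function(true_model, n_bees = 24, n_reps = 50,
                                seed = 1L, setup = NULL, schedule_seed = 100L) {
  if (is.null(setup)) setup <- default_stimulus_set()
  schedule <- generate_schedule(setup$stimuli, seed = schedule_seed)
  m <- setup$metrics
  first <- pmin(schedule$stimulus_left, schedule$stimulus_right)
  second <- pmax(schedule$stimulus_left, schedule$stimulus_right)
  dSP <- m$spectral_purity[match(first, m$stimulus_id)] -
    m$spectral_purity[match(second, m$stimulus_id)]
  dI <- m$intensity[match(first, m$stimulus_id)] -
    m$intensity[match(second, m$stimulus_id)]

  rows <- lapply(seq_len(n_reps), function(r) {
    recs <- simulate_bees(true_model, schedule, setup$stimuli, m, n_bees,
                          seed = seed + r)
    d <- data.frame(
      bee = factor(recs$bee_id),
      y = as.integer(recs$chosen == first[match(recs$test_index,
                                                schedule$test_index)]),
      dSP = dSP[match(recs$test_index, schedule$test_index)],
      dI = dI[match(recs$test_index, schedule$test_index)])
    fit <- tryCatch(fit_binomial_glmm(y ~ 0 + dSP + dI + (1 | bee), d),
                    error = function(e) NULL)
    if (is.null(fit)) {
      return(data.frame(beta_purity = NA_real_, se_purity = NA_real_,
                        beta_intensity = NA_real_, converged = FALSE))
    }
    data.frame(beta_purity = unname(fit$fixef["dSP"]),
               se_purity = sqrt(fit$vcov["dSP", "dSP"]),
               beta_intensity = unname(fit$fixef["dI"]),
               converged = fit$converged)
  })
  est <- do.call(rbind, rows)
  okv <- !is.na(est$beta_purity)
  cover <- mean(abs(est$beta_purity[okv] - true_model$beta_purity) <=
                  1.96 * est$se_purity[okv])
  list(estimates = est,
       summary = list(
         mean_beta_purity = mean(est$beta_purity, na.rm = TRUE),
         sd_beta_purity = stats::sd(est$beta_purity, na.rm = TRUE),
         bias_beta_purity = mean(est$beta_purity, na.rm = TRUE) -
           true_model$beta_purity,
         coverage_beta_purity = cover,
         n_failed = sum(!okv)))
}

#' Null calibration of the GLMM + Tukey pipeline
#'
#' Monte-Carlo estimate of the family-wise rejection rate of the
#' per-family binomial GLMM with Tukey all-pair comparisons when no
#' preference exists (all utilities equal; choices are fair coin flips).
#' Each replicate simulates the full 57-test schedule, tallies it and
#' analyses one family. Because the two counts of a dual test are
#' perfectly negatively coupled, per-bee stimulus counts violate the
#' model's independent-binomial assumption; this function quantifies the
#' resulting inflation of the family-wise error.
#'
#' @param n_reps Replicates.
#' @param n_bees Bees per replicate.
#' @param family Family analysed per replicate (a category or `"hue"`).
#' @param alpha Nominal family-wise level.
#' @param seed Integer seed; replicate r uses `seed + r`.
#' @param setup Optional precomputed [default_stimulus_set()].
#' @param schedule_seed Seed for the fixed schedule.
#' @return List with `rejection_rate`, `mc_se`, `n_reps`, `n_failed`.
#' @export
null_calibration <- function(n_reps = 500, n_bees = 20, family = "blue",
                             alpha = 0.05, seed = 1L, setup = NULL,
                             schedule_seed = 100L) {
  if (is.null(setup)) setup <- default_stimulus_set()
  schedule <- generate_schedule(setup$stimuli, seed = schedule_seed)
  null_model <- bee_preference_model()
  rej <- logical(n_reps)
  failed <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    recs <- simulate_bees(null_model, schedule, setup$stimuli, setup$metrics,
                          n_bees, seed = seed + r)
    res <- tryCatch({
      tally <- tally_choices(recs, schedule, setup$stimuli)
      fam <- family_choice_model(tally, family)
      any(fam$comparisons$p_adj < alpha)
    }, error = function(e) NA)
    if (is.na(res)) failed[r] <- TRUE else rej[r] <- res
  }
  ok <- !failed
  rate <- mean(rej[ok])
  list(rejection_rate = rate,
       mc_se = sqrt(rate * (1 - rate) / sum(ok)),
       n_reps = sum(ok), n_failed = sum(failed))
}
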