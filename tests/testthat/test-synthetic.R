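test_that("pigment mixing follows the weighted geometric mean", {
  pig <- pigment_library(hx_grid())
  # weight 1 on one pigment returns that pigment
  m1 <- mix_pigments(c(blue = 1), pig)
  expect_equal(m1$values, pig$blue$values)
  # 50:50 of white 1.0 and black 0.01: sqrt(0.01) = 0.1 everywhere
  g <- hx_grid()
  pig2 <- list(w = reflectance_spectrum(rep(1, 401), g, calibrated = TRUE),
               k = reflectance_spectrum(rep(0.01, 401), g))
  m2 <- mix_pigments(c(w = 0.5, k = 0.5), pig2)
  expect_equal(m2$values, rep(0.1, 401), tolerance = 1e-12)
  # adding white monotonically raises reflectance at every wavelength
  prev <- mix_pigments(c(blue = 1), pig)$values
  for (w in c(0.2, 0.4, 0.6, 0.8)) {
    cur <- mix_pigments(c(blue = 1 - w, white_uv = w), pig)$values
    expect_true(all(cur >= prev - 1e-12))
    prev <- cur
  }
  expect_error(mix_pigments(c(blue = 0.5, white_uv = 0.4), pig), "sum to 1")
  expect_error(mix_pigments(c(nosuch = 1), pig), "unknown")
})

test_that("stimulus series are certified by the hexagon model", {
  setup <- hx_setup()
  m <- setup$metrics
  get <- function(id, col) m[[col]][m$stimulus_id == id]
  for (cat in setdiff(CATEGORIES, "white")) {
    # purer member strictly purer at both intensity levels
    expect_gt(get(paste0(cat, "_P+_I+"), "spectral_purity"),
              get(paste0(cat, "_P-_I+"), "spectral_purity"))
    expect_gt(get(paste0(cat, "_P+_I-"), "spectral_purity"),
              get(paste0(cat, "_P-_I-"), "spectral_purity"))
    # more intense member strictly more intense at both purity levels
    expect_gt(get(paste0(cat, "_P+_I+"), "intensity"),
              get(paste0(cat, "_P+_I-"), "intensity"))
    expect_gt(get(paste0(cat, "_P-_I+"), "intensity"),
              get(paste0(cat, "_P-_I-"), "intensity"))
  }
  expect_gt(get("white_UV+_I+", "intensity"), get("white_UV+_I-", "intensity"))
  expect_gt(get("white_UV-_I+", "intensity"), get("white_UV-_I-", "intensity"))
  # the UV-reflecting white carries a larger UV excitation
  expect_gt(get("white_UV+_I+", "E_uv"), get("white_UV-_I+", "E_uv"))
})

test_that("red stimuli are near-achromatic to the bee, greys at the centre", {
  setup <- hx_setup()
  m <- setup$metrics
  red <- m[grepl("^red_", m$stimulus_id), ]
  nonred <- m[!grepl("^red_|^white_UV\\+", m$stimulus_id), ]
  expect_lt(max(red$chromatic_contrast), 0.2)
  # red loci are green-receptor dominated: x > 0
  expect_true(all(red$x > 0))
  # flat grey series: all four loci at the hexagon centre
  g <- hx_grid(); rs <- hx_receptors(); bg <- hx_background(); il <- hx_illum()
  for (lev in c(0.05, 0.15, 0.45, 0.9)) {
    E <- hexabee:::excitation_triple(rs, flat_spectrum(lev, g), bg, il)
    expect_lt(chromatic_contrast(hexagon_locus(E)), 1e-10)
  }
})

test_that("simulated choices are reproducible and respect the null model", {
  setup <- hx_setup()
  sch <- hx_schedule()
  a <- simulate_bees(bicolor_model(), sch, setup$stimuli, setup$metrics,
                     n_bees = 10, seed = 99)
  b <- simulate_bees(bicolor_model(), sch, setup$stimuli, setup$metrics,
                     n_bees = 10, seed = 99)
  expect_identical(a, b)
  # byte-identical CSVs from the same seed
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_choice_table(a, p1); write_choice_table(b, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))

  # all betas 0, sigma 0: pooled left-choice fraction is 0.5 within
  # binomial error (n = 40 bees x 57 tests = 2280 draws)
  nullm <- bee_preference_model()
  r0 <- simulate_bees(nullm, sch, setup$stimuli, setup$metrics,
                      n_bees = 40, seed = 7)
  frac_first <- mean(r0$chosen == pmin(r0$stimulus_left, r0$stimulus_right))
  expect_lt(abs(frac_first - 0.5), 3 * sqrt(0.25 / nrow(r0)))
})

test_that("choice frequencies match the logistic closed form", {
  # oracle: P(choose A) = plogis(beta_purity * (SP_A - SP_B)) when only
  # purity drives utility and sigma_bee = 0
  setup <- hx_setup()
  sch <- hx_schedule()
  m <- setup$metrics
  model <- bee_preference_model(beta_purity = 4)
  recs <- simulate_bees(model, sch, setup$stimuli, m, n_bees = 300, seed = 13)
  ct <- hexabee:::contrast_tests(sch, setup$stimuli, "purity")
  for (ti in ct$test_index[1:4]) {
    sub <- recs[recs$test_index == ti, ]
    plus <- ct$plus_stimulus[ct$test_index == ti]
    pair <- unique(c(sub$stimulus_left, sub$stimulus_right))
    minus <- setdiff(pair, plus)
    dsp <- m$spectral_purity[m$stimulus_id == plus] -
      m$spectral_purity[m$stimulus_id == minus]
    p_oracle <- plogis(4 * dsp)
    p_hat <- mean(sub$chosen == plus)
    expect_lt(abs(p_hat - p_oracle), 3 * sqrt(p_oracle * (1 - p_oracle) / 300))
  }
  # identical utilities (same stimulus metrics) give probability 1/2:
  # degenerate check via zero coefficients
  nullm <- bee_preference_model()
  u <- hexabee:::stimulus_utility(nullm, m, setup$stimuli)
  expect_true(all(u == 0))
})

test_that("parameter recovery is approximately unbiased at small scale", {
  setup <- hx_setup()
  truth <- bee_preference_model(beta_purity = 1, sigma_bee = 0.5)
  rec <- recovery_experiment(truth, n_bees = 24, n_reps = 8, seed = 500,
                             setup = setup)
  expect_equal(nrow(rec$estimates), 8)
  expect_equal(rec$summary$n_failed, 0)
  # loose sanity band at this replicate count; the acceptance suite runs
  # the full experiment
  expect_lt(abs(rec$summary$mean_beta_purity - 1), 0.6)
})

test_that("zero bee variance data yield near-zero estimated variance", {
  setup <- hx_setup()
  sch <- hx_schedule()
  truth <- bee_preference_model(beta_purity = 1, sigma_bee = 0)
  recs <- simulate_bees(truth, sch, setup$stimuli, setup$metrics,
                        n_bees = 48, seed = 77)
  first <- pmin(sch$stimulus_left, sch$stimulus_right)
  m <- setup$metrics
  d <- data.frame(
    bee = factor(recs$bee_id),
    y = as.integer(recs$chosen == first[match(recs$test_index, sch$test_index)]),
    dSP = (m$spectral_purity[match(first, m$stimulus_id)] -
             m$spectral_purity[match(pmax(sch$stimulus_left, sch$stimulus_right),
                                     m$stimulus_id)])[match(recs$test_index,
                                                            sch$test_index)])
  fit <- fit_binomial_glmm(y ~ 0 + dSP + (1 | bee), d)
  expect_lt(fit$sigma_bee, 0.25)
})

test_that("species-like parameterisations reproduce the qualitative pattern", {
  setup <- hx_setup()
  sch <- hx_schedule()
  m <- setup$metrics

  recs_h <- simulate_bees(helleri_model(), sch, setup$stimuli, m,
                          n_bees = 24, seed = 301, species = "P. helleri-like")
  th <- tally_choices(recs_h, sch, setup$stimuli)
  ps <- th$per_stimulus[th$per_stimulus$context == "within-category", ]
  cnt <- function(id) ps$n_chosen[ps$stimulus_id == id]
  for (cat in c("UV-blue", "blue", "UV-yellow", "yellow")) {
    expect_gt(cnt(paste0(cat, "_P+_I+")) + cnt(paste0(cat, "_P+_I-")),
              cnt(paste0(cat, "_P-_I+")) + cnt(paste0(cat, "_P-_I-")))
  }
  # red: purity nearly indistinguishable to the bee; difference much smaller
  red_diff <- (cnt("red_P+_I+") + cnt("red_P+_I-")) -
    (cnt("red_P-_I+") + cnt("red_P-_I-"))
  blue_diff <- (cnt("blue_P+_I+") + cnt("blue_P+_I-")) -
    (cnt("blue_P-_I+") + cnt("blue_P-_I-"))
  expect_lt(red_diff, blue_diff)

  # the null parameterisation shows no pooled purity preference
  recs_b <- simulate_bees(bicolor_model(), sch, setup$stimuli, m,
                          n_bees = 20, seed = 302, species = "M. bicolor-like")
  tb <- tally_choices(recs_b, sch, setup$stimuli)
  pb <- pooled_preference_test(tb, "purity", method = "wilcoxon")
  expect_gt(pb$p, 0.05)
})
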