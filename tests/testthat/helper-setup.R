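# Shared viewing conditions and synthetic stimulus set, built once per run.
# Everything is generated in code; no stored fixtures.

.hx <- new.env(parent = emptyenv())

hx_grid <- function() {
  if (is.null(.hx$grid)) .hx$grid <- wl_grid()
  .hx$grid
}

hx_receptors <- function() {
  if (is.null(.hx$receptors)) .hx$receptors <- receptor_set(grid = hx_grid())
  .hx$receptors
}

hx_background <- function() {
  if (is.null(.hx$background)) .hx$background <- flat_spectrum(0.30, hx_grid())
  .hx$background
}

hx_illum <- function() {
  if (is.null(.hx$illum)) .hx$illum <- d65_illuminant(hx_grid())
  .hx$illum
}

hx_curve <- function() {
  if (is.null(.hx$curve)) {
    .hx$curve <- spectral_locus(hx_receptors(), hx_background(), hx_illum())
  }
  .hx$curve
}

# full synthetic stimulus set + metrics (the heaviest shared object)
hx_setup <- function() {
  if (is.null(.hx$setup)) {
    .hx$setup <- default_stimulus_set(hx_receptors(), hx_background(),
                                      hx_illum())
  }
  .hx$setup
}

hx_schedule <- function() {
  if (is.null(.hx$schedule)) {
    .hx$schedule <- generate_schedule(hx_setup()$stimuli, seed = 100L)
  }
  .hx$schedule
}

# Brute-force two-sided exact Mann-Whitney p value by enumeration of all
# choose(n+m, n) group assignments of the pooled ranks. Independent of
# wilcox.test; assumes no ties.
enumerate_ranksum_p <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2  # U statistic of x
  combos <- utils::combn(n + m, n)
  ws <- apply(combos, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  mu <- n * m / 2
  # two-sided: probability of a U at least as extreme (in |U - mu|)
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}
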