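#' Shapiro-Wilk normality test
#'
#' Wrapper around [stats::shapiro.test()] returning the package's uniform
#' test-result structure. Requires 3 <= n <= 5000 and a non-constant sample.
#'
#' @param x Numeric sample.
#' @return List with `statistic` (`"W_shapiro"`), `value`, `p`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || length(x) > 5000) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("Shapiro-Wilk is undefined for a constant sample", call. = FALSE)
  }
  ht <- stats::shapiro.test(x)
  list(statistic = "W_shapiro", value = unname(ht$statistic), p = ht$p.value)
}

#' Student's t test
#'
#' Two-sided t test, paired or unpaired (classical equal-variance form for
#' the unpaired case, matching the textbook Student test).
#'
#' @param x,y Numeric samples.
#' @param paired Paired test?
#' @return List with `statistic` (`"t"`), `value`, `df`, `p`.
#' @export
students_t <- function(x, y, paired = FALSE) {
  if (length(x) < 2 || length(y) < 2) stop("need n >= 2 per sample", call. = FALSE)
  if (stats::sd(x) == 0 && stats::sd(y) == 0 && !paired) {
    stop("degenerate samples: zero variance in both", call. = FALSE)
  }
  if (paired && stats::sd(x - y) == 0 && all(x == y)) {
    # identical paired samples: t = 0, p = 1 by convention
    return(list(statistic = "t", value = 0, df = length(x) - 1, p = 1))
  }
  ht <- stats::t.test(x, y, paired = paired, var.equal = !paired)
  list(statistic = "t", value = unname(ht$statistic),
       df = unname(ht$parameter), p = ht$p.value)
}

#' Mann-Whitney U / Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test. The reported `W` follows the R convention
#' (number of pairs (x_i, y_j) with x_i > y_j, counting ties as 1/2, i.e.
#' the U statistic of the first sample); `U` is the smaller of the two
#' sample U statistics. The p value is exact (enumeration over rank
#' assignments, as computed by [stats::wilcox.test()]) for small untied
#' samples and a tie-corrected normal approximation with continuity
#' correction otherwise.
#'
#' @param x,y Numeric samples (n >= 1 each).
#' @param exact Force (`TRUE`) or suppress (`FALSE`) the exact p value;
#'   default `NULL` chooses exact for n, m < 50 without ties.
#' @return List with `statistic` (`"W_ranksum"`), `value` (= `W`), `W`,
#'   `U`, `p`.
#' @export
mann_whitney_u <- function(x, y, exact = NULL) {
  if (length(x) < 1 || length(y) < 1) stop("need n >= 1 per sample", call. = FALSE)
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  W <- unname(ht$statistic)
  U <- min(W, length(x) * length(y) - W)
  list(statistic = "W_ranksum", value = W, W = W, U = U, p = ht$p.value)
}

#' Fit a binomial mixed model to choice counts
#'
#' Binomial GLMM with a fixed effect for stimulus (or any formula supplied)
#' and a random intercept per bee, fitted by Laplace-approximation maximum
#' likelihood via [lme4::glmer()] with deterministic defaults, so repeated
#' fits of the same data are identical. AIC is reported for model
#' comparison.
#'
#' @param formula Model formula, e.g.
#'   `cbind(n_chosen, n_offered - n_chosen) ~ stimulus_id + (1 | bee_id)`.
#' @param data Data.frame (e.g. the `long` component of [tally_choices()]).
#' @return Object of class `glmm_fit`: list with `model` (the `glmerMod`),
#'   `fixef`, `vcov`, `sigma_bee` (random-intercept SD), `logLik`, `AIC`,
#'   `converged`.
#' @export
fit_binomial_glmm <- function(formula, data) {
  fit <- suppressMessages(suppressWarnings(
    lme4::glmer(formula, data = data, family = stats::binomial(),
                control = lme4::glmerControl(calc.derivs = TRUE))))
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  # a boundary (singular) fit is a converged solution with variance 0
  singular <- any(grepl("singular", msgs, ignore.case = TRUE))
  real_problems <- msgs[!grepl("singular", msgs, ignore.case = TRUE)]
  conv <- length(real_problems) == 0 && fit@optinfo$conv$opt == 0
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(model = fit,
                 singular = singular,
                 fixef = lme4::fixef(fit),
                 vcov = as.matrix(stats::vcov(fit)),
                 sigma_bee = vc$sdcor[1],
                 logLik = as.numeric(stats::logLik(fit)),
                 AIC = stats::AIC(fit),
                 converged = conv),
            class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("<glmm_fit> logLik %.2f, AIC %.2f, sigma_bee %.3f, %s\n",
              x$logLik, x$AIC, x$sigma_bee,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Tukey all-pair comparisons after a GLMM fit
#'
#' Single-step family-wise-adjusted contrasts among all levels of one fixed
#' factor, via the multivariate-normal method of [multcomp::glht()].
#' Refuses to run on an unconverged fit. The adjusted p values involve
#' quasi-Monte-Carlo integration of the multivariate normal; a fixed
#' internal seed makes them exactly reproducible across calls.
#'
#' @param fit A [fit_binomial_glmm()] result.
#' @param factor_name Name of the factor whose levels are compared.
#' @return Data.frame with `level_a`, `level_b`, `estimate` (log-odds
#'   difference a - b), `se`, `z`, `p_raw` (unadjusted), `p_adj`
#'   (family-wise).
#' @export
tukey_all_pairs <- function(fit, factor_name = "stimulus_id") {
  stopifnot(inherits(fit, "glmm_fit"))
  if (!fit$converged) {
    stop("refusing Tukey comparisons on an unconverged fit", call. = FALSE)
  }
  spec <- stats::setNames(list("Tukey"), factor_name)
  gh <- multcomp::glht(fit$model, linfct = do.call(multcomp::mcp, spec))
  # mvtnorm emits benign degenerate-interval notes for near-identical
  # contrasts; the fixed seed makes the quasi-MC adjustment reproducible
  sm <- withr::with_seed(1L, suppressWarnings(summary(gh)))
  lv <- strsplit(names(sm$test$coefficients), " - ", fixed = TRUE)
  data.frame(
    level_a = vapply(lv, `[`, character(1), 1),
    level_b = vapply(lv, `[`, character(1), 2),
    estimate = unname(sm$test$coefficients),
    se = unname(sm$test$sigma),
    z = unname(sm$test$tstat),
    p_raw = unname(2 * stats::pnorm(-abs(sm$test$tstat))),
    p_adj = unname(as.numeric(sm$test$pvalues)),
    stringsAsFactors = FALSE)
}

#' Per-family choice model for one category or the hue comparisons
#'
#' Convenience wrapper: selects the bee x stimulus counts for one family
#' (a colour category's within-category tests, or the hue comparisons),
#' fits `choices ~ stimulus + (1 | bee)` and runs the Tukey all-pair
#' comparisons.
#'
#' @param tally A [tally_choices()] result.
#' @param family A category name, or `"hue"` for the hue comparisons.
#' @return List with `fit` (`glmm_fit`) and `comparisons` (Tukey table).
#' @export
family_choice_model <- function(tally, family) {
  stopifnot(inherits(tally, "choice_tally"))
  d <- if (family == "hue") {
    tally$long[tally$long$context == "hue-comparison", ]
  } else {
    tally$long[tally$long$context == "within-category" &
               tally$long$category == family, ]
  }
  if (nrow(d) == 0) stop("no records for family '", family, "'", call. = FALSE)
  d$stimulus_id <- factor(d$stimulus_id)
  d$bee_id <- factor(d$bee_id)
  fit <- fit_binomial_glmm(
    cbind(n_chosen, n_offered - n_chosen) ~ stimulus_id + (1 | bee_id), d)
  cmp <- tukey_all_pairs(fit, "stimulus_id")
  list(fit = fit, comparisons = cmp)
}

#' Pooled preference test for spectral purity or intensity
#'
#' Compares total choices for the `+` level against the `-` level pooled
#' over categories, ignoring hue. The sampling unit is the dual test: the
#' purity contrast has 10 tests (2 per chromatic category), the intensity
#' contrast 12 (2 per category including white), each contributing the
#' count of bees that chose the `+` and the `-` stimulus. `method = "t"`
#' runs a paired t test across tests (df = number of tests - 1);
#' `method = "wilcoxon"` runs the unpaired rank-sum test on the two count
#' vectors (the convention under which near-complete separation of 10 vs
#' 10 counts yields W close to 100). `"auto"` picks the t test when the
#' paired differences pass Shapiro-Wilk at the 5% level, the rank-sum test
#' otherwise.
#'
#' @param tally A [tally_choices()] result.
#' @param parameter `"purity"` or `"intensity"`.
#' @param method `"auto"`, `"t"` or `"wilcoxon"`.
#' @return List with the chosen test's result (see [students_t()] /
#'   [mann_whitney_u()]) plus `parameter`, `method`, `n_tests`,
#'   `mean_plus`, `mean_minus`.
#' @export
pooled_preference_test <- function(tally, parameter = c("purity", "intensity"),
                                   method = c("auto", "t", "wilcoxon")) {
  parameter <- match.arg(parameter)
  method <- match.arg(method)
  pt <- tally$pooled[[parameter]]$per_test
  x <- pt$n_plus
  y <- pt$n_minus
  if (method == "auto") {
    d <- x - y
    method <- if (stats::sd(d) > 0 && shapiro_wilk(d)$p > 0.05) "t" else "wilcoxon"
  }
  res <- if (method == "t") students_t(x, y, paired = TRUE)
         else mann_whitney_u(x, y)
  c(res, list(parameter = parameter, method = method, n_tests = nrow(pt),
              mean_plus = mean(x), mean_minus = mean(y)))
}
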