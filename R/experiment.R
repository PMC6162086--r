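#' Colour categories of the dual-choice design
#'
#' Six categories of four stimuli each. In the five chromatic categories the
#' four members cross two levels of spectral purity (P+/P-) with two levels
#' of intensity (I+/I-); in the white category the purity axis is replaced
#' by UV reflectance (UV+/UV-).
#' @export
CATEGORIES <- c("UV-blue", "blue", "UV-yellow", "yellow", "red", "white")

#' Assemble and validate the stimulus set
#'
#' Builds the 24-stimulus set of the dual-choice design from a level table
#' and matching spectra, and tags the seven hue representatives: the most
#' intense, most spectrally pure member of each chromatic category (P+/I+)
#' plus both whites at full intensity (UV+/I+ and UV-/I+).
#'
#' @param table A data.frame with columns `id`, `category`, `purity_level`
#'   (`"P+"`/`"P-"`, or `"UV+"`/`"UV-"` for white) and `intensity_level`
#'   (`"I+"`/`"I-"`), one row per stimulus.
#' @param spectra Named list of reflectance `spectrum` objects, names
#'   matching `table$id`.
#' @return Object of class `stimulus_set`: list with the validated `table`
#'   (plus logical column `hue_representative`) and `spectra`.
#' @export
build_stimulus_set <- function(table, spectra) {
  req <- c("id", "category", "purity_level", "intensity_level")
  if (!all(req %in% names(table))) {
    stop("stimulus table needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(table$id)) stop("duplicate stimulus ids", call. = FALSE)
  if (!setequal(unique(table$category), CATEGORIES)) {
    stop("stimulus set must cover exactly the six colour categories",
         call. = FALSE)
  }
  cnt <- table(table$category)
  if (any(cnt != 4)) {
    bad <- names(cnt)[cnt != 4]
    stop("each category needs exactly 4 stimuli (violated by: ",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  }
  for (cat in CATEGORIES) {
    lv <- table[table$category == cat, ]
    want <- if (cat == "white") c("UV+", "UV-") else c("P+", "P-")
    combos <- paste(lv$purity_level, lv$intensity_level)
    expect <- as.vector(outer(want, c("I+", "I-"), paste))
    if (!setequal(combos, expect)) {
      stop("category '", cat, "' must cross levels {", paste(want, collapse = ","),
           "} x {I+,I-}", call. = FALSE)
    }
  }
  missing <- setdiff(table$id, names(spectra))
  if (length(missing)) {
    stop("missing spectra for stimuli: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  table$hue_representative <-
    (table$intensity_level == "I+") &
    (table$purity_level %in% c("P+", "UV+", "UV-"))
  stopifnot(sum(table$hue_representative) == 7)
  structure(list(table = table, spectra = spectra[table$id]),
            class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("<stimulus_set> %d stimuli, %d hue representatives\n",
              nrow(x$table), sum(x$table$hue_representative)))
  invisible(x)
}

#' Generate the 57-test semi-randomised dual-choice schedule
#'
#' All 6 within-category pairs for each of the six categories (36 tests)
#' plus all 21 pairs of the seven hue representatives. The order is
#' randomised under the constraint that no two consecutive tests come from
#' the same block (colour category, or the hue-comparison block), mirroring
#' the rule that tests within one colour category are never run back to
#' back. Left/right sides are randomised per test and counterbalanced to
#' within one test overall. `reversed = TRUE` emits the same order
#' back-to-front (used for part of the bees to cancel order effects);
#' reversing twice restores the original schedule.
#'
#' @param stimuli A [build_stimulus_set()] result.
#' @param seed Integer seed (the schedule is deterministic given the seed).
#' @param reversed Emit the order back-to-front?
#' @param max_restarts Restart budget for the no-consecutive constraint.
#' @return A data.frame (class `schedule`) with columns `test_index`,
#'   `context` (`"within-category"`/`"hue-comparison"`), `category`
#'   (`"hue"` for hue tests), `stimulus_left`, `stimulus_right`.
#' @export
generate_schedule <- function(stimuli, seed = 1L, reversed = FALSE,
                              max_restarts = 1000L) {
  stopifnot(inherits(stimuli, "stimulus_set"))
  tab <- stimuli$table
  pairs <- list()
  for (cat in CATEGORIES) {
    ids <- tab$id[tab$category == cat]
    cmb <- utils::combn(sort(ids), 2)
    for (k in seq_len(ncol(cmb))) {
      pairs[[length(pairs) + 1]] <- list(a = cmb[1, k], b = cmb[2, k],
                                         context = "within-category",
                                         block = cat)
    }
  }
  reps <- sort(tab$id[tab$hue_representative])
  cmb <- utils::combn(reps, 2)
  for (k in seq_len(ncol(cmb))) {
    pairs[[length(pairs) + 1]] <- list(a = cmb[1, k], b = cmb[2, k],
                                       context = "hue-comparison",
                                       block = "hue")
  }
  stopifnot(length(pairs) == 57)
  blocks <- vapply(pairs, `[[`, character(1), "block")

  withr::with_seed(seed, {
    ord <- order_without_adjacent(blocks, max_restarts)
    # side counterbalancing: swap left/right for exactly floor(n/2) tests
    n <- length(ord)
    swap <- sample(rep(c(TRUE, FALSE), c(n %/% 2, n - n %/% 2)))
  })

  pr <- pairs[ord]
  sw <- swap
  out <- data.frame(
    test_index = seq_along(pr),
    context = vapply(pr, `[[`, character(1), "context"),
    category = vapply(pr, `[[`, character(1), "block"),
    stimulus_left = ifelse(sw, vapply(pr, `[[`, character(1), "b"),
                           vapply(pr, `[[`, character(1), "a")),
    stimulus_right = ifelse(sw, vapply(pr, `[[`, character(1), "a"),
                            vapply(pr, `[[`, character(1), "b")),
    stringsAsFactors = FALSE)
  if (isTRUE(reversed)) {
    out <- out[rev(seq_len(nrow(out))), ]
    out$test_index <- seq_len(nrow(out))
    rownames(out) <- NULL
  }
  attr(out, "seed") <- seed
  attr(out, "reversed") <- isTRUE(reversed)
  class(out) <- c("schedule", class(out))
  out
}

# Random permutation of indices such that no two adjacent elements share a
# block label; sequential sampling with full restart on dead ends.
order_without_adjacent <- function(blocks, max_restarts) {
  n <- length(blocks)
  for (try in seq_len(max_restarts)) {
    remaining <- seq_len(n)
    ord <- integer(0)
    prev <- ""
    ok <- TRUE
    while (length(remaining)) {
      cand <- remaining[blocks[remaining] != prev]
      if (!length(cand)) { ok <- FALSE; break }
      pick <- if (length(cand) == 1) cand else sample(cand, 1)
      ord <- c(ord, pick)
      prev <- blocks[pick]
      remaining <- setdiff(remaining, pick)
    }
    if (ok) return(ord)
  }
  stop("could not order tests without consecutive same-category tests after ",
       max_restarts, " restarts", call. = FALSE)
}

#' Reverse a schedule
#'
#' @param schedule A `schedule`.
#' @return The same tests in back-to-front order, re-indexed 1..57.
#' @export
reverse_schedule <- function(schedule) {
  out <- schedule[rev(seq_len(nrow(schedule))), ]
  out$test_index <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "seed") <- attr(schedule, "seed")
  attr(out, "reversed") <- !isTRUE(attr(schedule, "reversed"))
  class(out) <- class(schedule)
  out
}

#' Read and write choice-record tables
#'
#' Canonical format: CSV with columns `bee_id`, `species`, `test_index`,
#' `stimulus_left`, `stimulus_right`, `chosen`. Files ending in `.xlsx` are
#' imported through the readxl package (mirroring raw data deposited as a
#' spreadsheet); CSV remains the round-trip format.
#'
#' @param path File path (`.csv` or `.xlsx`).
#' @return A data.frame of choice records.
#' @export
read_choice_table <- function(path) {
  if (grepl("\\.xlsx$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading .xlsx requires the readxl package", call. = FALSE)
    }
    tab <- as.data.frame(readxl::read_excel(path))
  } else {
    tab <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                    error = function(e) stop("cannot parse choice table '",
                                             path, "': ", conditionMessage(e),
                                             call. = FALSE))
  }
  req <- c("bee_id", "species", "test_index", "stimulus_left",
           "stimulus_right", "chosen")
  if (!all(req %in% names(tab))) {
    stop("choice table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(tab) == 0) stop("choice table is empty", call. = FALSE)
  tab[req]
}

#' @rdname read_choice_table
#' @param records Choice-record data.frame.
#' @export
write_choice_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname generate_schedule
#' @param path Output CSV path.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# Tests in which the two stimuli differ in one within-category level while
# the other level is held fixed; the basis of the pooled purity/intensity
# comparisons. For "purity" the white category is excluded (its purity axis
# is UV reflectance); for "intensity" all six categories contribute.
contrast_tests <- function(schedule, stimuli, parameter = c("purity", "intensity")) {
  parameter <- match.arg(parameter)
  tab <- stimuli$table
  lv <- function(id, col) tab[[col]][match(id, tab$id)]
  w <- schedule[schedule$context == "within-category", ]
  pl <- lv(w$stimulus_left, "purity_level");  pr <- lv(w$stimulus_right, "purity_level")
  il <- lv(w$stimulus_left, "intensity_level"); ir <- lv(w$stimulus_right, "intensity_level")
  if (parameter == "purity") {
    keep <- w$category != "white" & pl != pr & il == ir
    plus <- ifelse(lv(w$stimulus_left, "purity_level") == "P+",
                   w$stimulus_left, w$stimulus_right)
  } else {
    keep <- il != ir & pl == pr
    plus <- ifelse(lv(w$stimulus_left, "intensity_level") == "I+",
                   w$stimulus_left, w$stimulus_right)
  }
  data.frame(test_index = w$test_index[keep], plus_stimulus = plus[keep],
             stringsAsFactors = FALSE)
}

#' Tally choice records
#'
#' Aggregates per-bee binary choices into the counts behind the standard
#' figures and tests: per-stimulus choice counts by context with 95%
#' Clopper-Pearson binomial confidence intervals, per-test left/right
#' conservation totals, and the pooled purity (P+ vs P-) and intensity
#' (I+ vs I-) contrasts. Pooling follows the dual-test structure: the
#' purity contrast uses the 10 tests (2 per chromatic category) in which
#' purity differs at equal intensity; the intensity contrast uses the 12
#' tests in which intensity differs at equal purity/UV level.
#'
#' @param records Choice records (see [read_choice_table()]).
#' @param schedule The `schedule` the records refer to.
#' @param stimuli The [build_stimulus_set()] the schedule was built from.
#' @param conf_level Confidence level for the binomial intervals.
#' @return Object of class `choice_tally`: list with
#'   \describe{
#'     \item{per_stimulus}{stimulus x context counts `n_chosen`/`n_offered`
#'       with CI bounds.}
#'     \item{per_test}{per-test totals for the two sides.}
#'     \item{pooled}{for purity and intensity: per-test counts of choices
#'       for the `+` and `-` member (the sampling unit of the pooled
#'       two-sample tests) and per-bee totals.}
#'     \item{long}{bee x stimulus x context counts for mixed-model fitting.}
#'   }
#' @export
tally_choices <- function(records, schedule, stimuli, conf_level = 0.95) {
  req <- c("bee_id", "test_index", "chosen")
  if (!all(req %in% names(records))) {
    stop("records need columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(records[c("bee_id", "test_index")])) {
    stop("duplicate (bee, test) records", call. = FALSE)
  }
  m <- match(records$test_index, schedule$test_index)
  if (anyNA(m)) stop("records reference unknown test_index", call. = FALSE)
  left <- schedule$stimulus_left[m]
  right <- schedule$stimulus_right[m]
  ok <- records$chosen == left | records$chosen == right
  if (!all(ok)) {
    stop("chosen stimulus not offered in its test (first offending row ",
         which(!ok)[1], ")", call. = FALSE)
  }
  context <- schedule$context[m]

  # per-stimulus tallies by context
  offered <- rbind(
    data.frame(stimulus_id = left, context = context, chosen = records$chosen == left),
    data.frame(stimulus_id = right, context = context, chosen = records$chosen == right))
  agg <- stats::aggregate(chosen ~ stimulus_id + context, data = offered,
                          FUN = function(z) c(k = sum(z), n = length(z)))
  per_stim <- data.frame(stimulus_id = agg$stimulus_id, context = agg$context,
                         n_chosen = agg$chosen[, "k"], n_offered = agg$chosen[, "n"])
  ci <- t(mapply(function(k, n) {
    stats::binom.test(k, n, conf.level = conf_level)$conf.int
  }, per_stim$n_chosen, per_stim$n_offered))
  per_stim$ci_lower <- ci[, 1]
  per_stim$ci_upper <- ci[, 2]

  # per-test conservation totals
  per_test <- stats::aggregate(
    cbind(n_left = records$chosen == left, n_right = records$chosen == right),
    by = list(test_index = records$test_index), FUN = sum)
  per_test$n_bees <- per_test$n_left + per_test$n_right

  # pooled purity / intensity contrasts
  pooled <- lapply(c(purity = "purity", intensity = "intensity"), function(par) {
    ct <- contrast_tests(schedule, stimuli, par)
    sub <- records[records$test_index %in% ct$test_index, ]
    plus <- ct$plus_stimulus[match(sub$test_index, ct$test_index)]
    chose_plus <- sub$chosen == plus
    per_test_counts <- stats::aggregate(
      cbind(n_plus = chose_plus, n_minus = !chose_plus),
      by = list(test_index = sub$test_index), FUN = sum)
    per_bee <- stats::aggregate(
      cbind(n_plus = chose_plus, n_minus = !chose_plus),
      by = list(bee_id = sub$bee_id), FUN = sum)
    list(tests = ct, per_test = per_test_counts, per_bee = per_bee)
  })

  # bee x stimulus x context long table for GLMMs
  offered_b <- rbind(
    data.frame(bee_id = records$bee_id, stimulus_id = left, context = context,
               category = schedule$category[m], chosen = records$chosen == left),
    data.frame(bee_id = records$bee_id, stimulus_id = right, context = context,
               category = schedule$category[m], chosen = records$chosen == right))
  long <- stats::aggregate(chosen ~ bee_id + stimulus_id + context + category,
                           data = offered_b,
                           FUN = function(z) c(k = sum(z), n = length(z)))
  long <- data.frame(long[c("bee_id", "stimulus_id", "context", "category")],
                     n_chosen = long$chosen[, "k"], n_offered = long$chosen[, "n"])

  structure(list(per_stimulus = per_stim, per_test = per_test,
                 pooled = pooled, long = long,
                 conf_level = conf_level),
            class = "choice_tally")
}

#' @export
print.choice_tally <- function(x, ...) {
  cat(sprintf("<choice_tally> %d stimulus-context cells, %d tests\n",
              nrow(x$per_stimulus), nrow(x$per_test)))
  invisible(x)
}
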