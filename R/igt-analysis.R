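#' Proportional net score over a range of trials
#'
#' The net score is the number of choices from the good decks (C, D) minus
#' the number from the bad decks (A, B). Dividing by the number of trials in
#' the range gives the proportional net score, in \[-1, 1\], which is
#' comparable across task lengths (multiply by 100 to compare with classic
#' 100-trial net scores).
#'
#' @param log an `igt_log`.
#' @param trial_range inclusive 1-based interval `c(from, to)`; default the
#'   whole log.
#' @return proportional net score.
#' @export
net_score <- function(log, trial_range = c(1L, nrow(log))) {
  log <- as_igt_log(log)
  from <- as.integer(trial_range[1]); to <- as.integer(trial_range[2])
  if (is.na(from) || is.na(to) || from < 1L || to > nrow(log) || from > to)
    stop("`trial_range` must be a non-empty interval within the log",
         call. = FALSE)
  d <- log$deck[from:to]
  (sum(d %in% c("C", "D")) - sum(d %in% c("A", "B"))) / length(d)
}

#' Net score restricted to a stable window
#'
#' Convenience wrapper around [net_score()] for the operant practice of
#' scoring only post-stability trials (e.g. the final 40 trials of a
#' 200-trial session).
#'
#' @inheritParams net_score
#' @param window inclusive trial interval `c(from, to)`.
#' @export
stable_window_net_score <- function(log, window) net_score(log, window)

#' Blockwise deck-preference profiles
#'
#' Splits a trial log into consecutive blocks (default 20 trials) and
#' returns, per block, the proportion of choices allocated to each deck.
#'
#' @param log an `igt_log`.
#' @param block_size trials per block; the log length must be an exact
#'   multiple (partial final blocks are rejected).
#' @return data frame with columns `block`, `A`, `B`, `C`, `D`; each row
#'   sums to 1.
#' @export
block_profiles <- function(log, block_size = 20L) {
  log <- as_igt_log(log)
  block_size <- as.integer(block_size)
  if (is.na(block_size) || block_size <= 0L)
    stop("`block_size` must be a positive integer", call. = FALSE)
  n <- nrow(log)
  if (n %% block_size != 0L)
    stop("log length ", n, " is not a multiple of block_size ", block_size,
         " (partial final block)", call. = FALSE)
  blk <- rep(seq_len(n %/% block_size), each = block_size)
  prop <- t(vapply(split(log$deck, blk), function(d)
    table(factor(d, levels = c("A", "B", "C", "D"))) / length(d),
    numeric(4)))
  out <- data.frame(block = seq_len(nrow(prop)), prop)
  rownames(out) <- NULL
  out
}

#' Blockwise deck-switching proportions
#'
#' For each block, the fraction of eligible trials on which the chosen deck
#' differs from the immediately preceding trial. Trial 1 has no predecessor
#' and is ineligible; a comparison crossing a block boundary counts toward
#' the later block (denominators are `block_size - 1` for block 1 and
#' `block_size` thereafter).
#'
#' @inheritParams block_profiles
#' @return numeric vector of per-block switch proportions in \[0, 1\].
#' @export
switch_proportion <- function(log, block_size = 20L) {
  log <- as_igt_log(log)
  block_size <- as.integer(block_size)
  if (is.na(block_size) || block_size <= 0L)
    stop("`block_size` must be a positive integer", call. = FALSE)
  n <- nrow(log)
  if (n %% block_size != 0L)
    stop("log length ", n, " is not a multiple of block_size ", block_size,
         " (partial final block)", call. = FALSE)
  switched <- c(NA, log$deck[-1] != log$deck[-n])
  blk <- rep(seq_len(n %/% block_size), each = block_size)
  vapply(split(switched, blk),
         function(s) mean(s, na.rm = TRUE), numeric(1),
         USE.NAMES = FALSE)
}

#' Classify a net score against an impairment criterion
#'
#' Two published cut-offs for "impaired" performance, both strict
#' inequalities on the proportional net score: the original patient-normed
#' criterion (net < 0.10) and the stricter zero criterion (net < 0.00).
#'
#' @param net proportional net score(s) in \[-1, 1\].
#' @param criterion `"bechara_0.10"` or `"steingroever_0.00"`.
#' @return logical, `TRUE` where impaired.
#' @export
classify_impairment <- function(net,
                                criterion = c("bechara_0.10",
                                              "steingroever_0.00")) {
  criterion <- match.arg(criterion)
  if (any(!is.finite(net)) || any(net < -1) || any(net > 1))
    stop("`net` must lie in [-1, 1]", call. = FALSE)
  net < switch(criterion, bechara_0.10 = 0.10, steingroever_0.00 = 0.00)
}

#' Preference label for one block profile
#'
#' A block shows a strong preference for a single deck when that deck's
#' choice proportion is (a) at least 0.50 and (b) at least 0.25 greater than
#' every other deck's proportion. If no single deck qualifies, a pair of
#' decks is preferred when their proportions (a) sum to at least 0.75 and
#' (b) differ by less than 0.25. Otherwise the block has no strong
#' preference. The single-deck rule is tested first.
#'
#' @param proportions numeric vector of four deck proportions (named or in
#'   order A, B, C, D), summing to 1.
#' @return a preference label string: a deck (`"C"`), a pair (`"C+D"`, decks
#'   in alphabetical order), or `"none"`.
#' @export
block_preference <- function(proportions) {
  p <- as.numeric(proportions)
  if (length(p) != 4L || any(!is.finite(p)) || any(p < 0) ||
      abs(sum(p) - 1) > 1e-9)
    stop("`proportions` must be four non-negative values summing to 1",
         call. = FALSE)
  decks <- c("A", "B", "C", "D")
  for (i in 1:4)
    if (p[i] >= 0.50 && all(p[i] - p[-i] >= 0.25)) return(decks[i])
  pairs <- utils::combn(4, 2)
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    if (p[i1] + p[i2] >= 0.75 && abs(p[i1] - p[i2]) < 0.25)
      return(paste(decks[i1], decks[i2], sep = "+"))
  }
  "none"
}

#' Stability criterion over a sequence of block preference labels
#'
#' Behaviour is considered stable when the same non-`"none"` preference
#' label is maintained for `run_length` consecutive blocks (the reference
#' criterion uses 3 blocks of 20 trials, i.e. 60 trials). The reported
#' `first_stable_block` is the index of the *last* block of the earliest
#' qualifying run, so "stable by 100 trials" means `first_stable_block <= 5`
#' with 20-trial blocks. Once reached, the criterion locks: later label
#' changes do not revoke stability, but are counted in
#' `later_label_changes`.
#'
#' Decision classes: `"good"` if the stable preference involves only decks C
#' and/or D; `"bad-deck"` if it involves A or B; `"poor"` if the criterion
#' is never met.
#'
#' @param labels character vector of per-block preference labels, as
#'   produced by [block_preference()].
#' @param run_length number of consecutive identical blocks required.
#' @return an object of class `stability_result`: list with `labels`,
#'   `first_stable_block` (NA if never stable), `stable_preference` (NA if
#'   never stable), `decision_class`, `later_label_changes`.
#' @export
detect_stability <- function(labels, run_length = 3L) {
  if (length(labels) == 0L) stop("`labels` must be nonempty", call. = FALSE)
  run_length <- as.integer(run_length)
  if (is.na(run_length) || run_length < 1L)
    stop("`run_length` must be >= 1", call. = FALSE)
  labels <- as.character(labels)
  first <- NA_integer_; pref <- NA_character_
  run <- 0L
  for (i in seq_along(labels)) {
    run <- if (labels[i] != "none" && i > 1L &&
               labels[i] == labels[i - 1L]) run + 1L
           else if (labels[i] != "none") 1L else 0L
    if (run >= run_length) { first <- i; pref <- labels[i]; break }
  }
  later <- 0L
  if (!is.na(first) && first < length(labels))
    later <- sum(labels[(first + 1L):length(labels)] != pref)
  cls <- if (is.na(first)) "poor"
         else if (all(strsplit(pref, "+", fixed = TRUE)[[1]] %in% c("C", "D")))
           "good" else "bad-deck"
  structure(list(labels = labels, first_stable_block = first,
                 stable_preference = pref, decision_class = cls,
                 later_label_changes = later),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  if (is.na(x$first_stable_block)) {
    cat("Stability: criterion never met (class: poor)\n")
  } else {
    cat(sprintf("Stability: '%s' stable by block %d (class: %s)\n",
                x$stable_preference, x$first_stable_block,
                x$decision_class))
    if (x$later_label_changes > 0)
      cat("  note:", x$later_label_changes,
          "post-stability block(s) changed label\n")
  }
  invisible(x)
}

#' Apply the blockwise preference pipeline to one trial log
#'
#' Convenience composition: [block_profiles()] then [block_preference()] per
#' block then [detect_stability()].
#'
#' @inheritParams block_profiles
#' @param run_length consecutive identical blocks required for stability.
#' @return a `stability_result`.
#' @export
stability_analysis <- function(log, block_size = 20L, run_length = 3L) {
  prof <- block_profiles(log, block_size)
  labels <- apply(prof[, c("A", "B", "C", "D")], 1, block_preference)
  detect_stability(labels, run_length)
}

#' Cohort-level IGT summary
#'
#' Aggregates a set of equal-length trial logs: per epoch (first half,
#' second half, full task) the mean, SD, min, max and range of proportional
#' net scores and the proportion of participants impaired under both
#' criteria; plus the stability summary (cumulative proportion stable by
#' each block, and a histogram of stable preferences).
#'
#' @param logs list of `igt_log` objects of equal length.
#' @param block_size trials per block for the stability analysis.
#' @param run_length consecutive blocks required for stability.
#' @return list with elements `net_scores` (participant x epoch data frame),
#'   `epochs` (summary data frame), `stability` (per-participant data
#'   frame), `stable_by_block` (cumulative proportions), and
#'   `preference_histogram`.
#' @export
cohort_summary <- function(logs, block_size = 20L, run_length = 3L) {
  if (length(logs) < 1L) stop("need at least one log", call. = FALSE)
  logs <- lapply(logs, as_igt_log)
  lens <- vapply(logs, nrow, integer(1))
  if (length(unique(lens)) != 1L)
    stop("logs of unequal length: ",
         paste(which(lens != lens[1]), collapse = ", "), call. = FALSE)
  n <- lens[1]
  half <- n %/% 2L
  epochs <- list(first = c(1L, half), second = c(half + 1L, n),
                 full = c(1L, n))
  ids <- vapply(logs, function(l) as.character(l$participant_id[1]),
                character(1))
  nets <- data.frame(participant_id = ids)
  for (e in names(epochs))
    nets[[e]] <- vapply(logs, net_score, numeric(1),
                        trial_range = epochs[[e]])
  epoch_summary <- do.call(rbind, lapply(names(epochs), function(e) {
    x <- nets[[e]]
    data.frame(epoch = e,
               trials = paste(epochs[[e]], collapse = "-"),
               mean = mean(x),
               sd = if (length(x) > 1L) stats::sd(x) else 0,
               min = min(x), max = max(x), range = max(x) - min(x),
               prop_impaired_bechara =
                 mean(classify_impairment(x, "bechara_0.10")),
               prop_impaired_steingroever =
                 mean(classify_impairment(x, "steingroever_0.00")))
  }))
  stab <- lapply(logs, stability_analysis, block_size = block_size,
                 run_length = run_length)
  stab_df <- data.frame(
    participant_id = ids,
    first_stable_block = vapply(stab, function(s)
      s$first_stable_block, integer(1)),
    stable_preference = vapply(stab, function(s)
      s$stable_preference, character(1)),
    decision_class = vapply(stab, function(s)
      s$decision_class, character(1)),
    stringsAsFactors = FALSE)
  n_blocks <- n %/% block_size
  stable_by_block <- vapply(seq_len(n_blocks), function(b)
    mean(!is.na(stab_df$first_stable_block) &
           stab_df$first_stable_block <= b), numeric(1))
  pref <- table(ifelse(is.na(stab_df$stable_preference), "No Pref.",
                       stab_df$stable_preference)) / length(logs)
  list(net_scores = nets, epochs = epoch_summary, stability = stab_df,
       stable_by_block = stable_by_block,
       preference_histogram = pref)
}
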