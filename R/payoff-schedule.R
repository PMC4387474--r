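#' Construct an IGT payoff schedule
#'
#' A payoff schedule holds, for each of the four decks A--D, an ordered list
#' of card outcomes (a win amount and a loss amount per draw). The classic
#' four-deck task defines outcomes for 40 cards per deck; when a deck is drawn
#' from more often than that, the schedule cycles.
#'
#' @param decks named list with elements `A`, `B`, `C`, `D`; each element a
#'   data frame with numeric columns `win` and `loss` (both non-negative),
#'   one row per card position.
#' @param cycle_length number of cards defined per deck (all decks must have
#'   exactly this many rows). Default 40.
#' @return an object of class `payoff_schedule`.
#' @seealso [load_payoff_schedule()] for reading the packaged standard
#'   schedule or a CSV file, [draw_outcome()] for position lookup.
#' @export
payoff_schedule <- function(decks, cycle_length = 40L) {
  if (!is.list(decks) || !setequal(names(decks), c("A", "B", "C", "D")))
    stop("`decks` must be a named list with elements A, B, C, D", call. = FALSE)
  cycle_length <- as.integer(cycle_length)
  if (cycle_length < 1L) stop("`cycle_length` must be >= 1", call. = FALSE)
  decks <- decks[c("A", "B", "C", "D")]
  for (d in names(decks)) {
    dk <- decks[[d]]
    if (!is.data.frame(dk) || !all(c("win", "loss") %in% names(dk)))
      stop("deck ", d, " must be a data frame with columns win and loss",
           call. = FALSE)
    if (nrow(dk) != cycle_length)
      stop("deck ", d, " has ", nrow(dk), " cards; expected ", cycle_length,
           call. = FALSE)
    if (any(!is.finite(dk$win)) || any(!is.finite(dk$loss)) ||
        any(dk$win < 0) || any(dk$loss < 0))
      stop("deck ", d, ": win and loss must be finite and non-negative",
           call. = FALSE)
    decks[[d]] <- data.frame(win = as.numeric(dk$win),
                             loss = as.numeric(dk$loss))
  }
  structure(list(decks = decks, cycle_length = cycle_length),
            class = "payoff_schedule")
}

#' Load a payoff schedule from a file or packaged fixture
#'
#' Reads a schedule CSV with columns `deck`, `position`, `win`, `loss`
#' (positions 1..cycle_length per deck). The name `"bechara_standard"`
#' resolves to the packaged standard schedule: decks A and B win $100 on
#' every card and lose $250 net per 10 cards, decks C and D win $50 and gain
#' $250 net per 10 cards; A and C carry five smaller losses per 10 cards
#' while B and D carry one large loss.
#'
#' @param source path to a schedule CSV, or the fixture name
#'   `"bechara_standard"`.
#' @return a [payoff_schedule()].
#' @export
load_payoff_schedule <- function(source = "bechara_standard") {
  if (identical(source, "bechara_standard"))
    source <- system.file("extdata", "bechara_standard.csv",
                          package = "igtmatch", mustWork = TRUE)
  if (!file.exists(source))
    stop("schedule file not found: ", source, call. = FALSE)
  tab <- utils::read.csv(source, stringsAsFactors = FALSE)
  need <- c("deck", "position", "win", "loss")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("schedule file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!tab$deck %in% c("A", "B", "C", "D"))
  if (length(bad))
    stop("schedule file row ", bad[1] + 1L, ": unknown deck label '",
         tab$deck[bad[1]], "'", call. = FALSE)
  cyc <- max(tab$position)
  decks <- lapply(split(tab, tab$deck), function(dk) {
    if (!identical(sort(dk$position), seq_len(cyc)))
      stop("deck ", dk$deck[1], " does not cover positions 1..", cyc,
           " exactly once", call. = FALSE)
    dk <- dk[order(dk$position), ]
    data.frame(win = dk$win, loss = dk$loss)
  })
  payoff_schedule(decks, cycle_length = cyc)
}

#' Look up the outcome of the k-th draw from a deck
#'
#' The schedule repeats after `cycle_length` draws: draw k maps to card
#' position `((k - 1) %% cycle_length) + 1` of that deck. Draw counts are
#' per deck, i.e. k counts how many times this particular deck has been
#' chosen.
#'
#' @param schedule a [payoff_schedule()].
#' @param deck deck label, one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param draw_count 1-based per-deck draw index.
#' @return named numeric vector `c(win = , loss = )`.
#' @export
draw_outcome <- function(schedule, deck, draw_count) {
  stopifnot(inherits(schedule, "payoff_schedule"))
  if (length(deck) != 1L || !deck %in% names(schedule$decks))
    stop("unknown deck label: ", deck, call. = FALSE)
  draw_count <- as.integer(draw_count)
  if (length(draw_count) != 1L || is.na(draw_count) || draw_count < 1L)
    stop("`draw_count` must be a single integer >= 1", call. = FALSE)
  pos <- ((draw_count - 1L) %% schedule$cycle_length) + 1L
  dk <- schedule$decks[[deck]]
  c(win = dk$win[pos], loss = dk$loss[pos])
}

#' @export
print.payoff_schedule <- function(x, ...) {
  cat("IGT payoff schedule:", x$cycle_length, "cards per deck\n")
  net <- vapply(x$decks, function(d) sum(d$win) - sum(d$loss), numeric(1))
  nl <- vapply(x$decks, function(d) sum(d$loss > 0), numeric(1))
  for (d in names(x$decks))
    cat(sprintf("  deck %s: win $%g/card, %d losses/cycle, net %+g per cycle\n",
                d, x$decks[[d]]$win[1], nl[d], net[d]))
  invisible(x)
}
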