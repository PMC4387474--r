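#' Run one Iowa Gambling Task session against an agent policy
#'
#' Executes `n_trials` card selections. On each trial the policy is shown the
#' history so far and returns a deck label; the trial's win and loss are read
#' from the payoff schedule at that deck's current per-deck draw position
#' (cycling after `cycle_length` draws). The session starts with a $2000
#' loan; whenever the running balance falls below zero after a trial, a
#' further $2000 loan is added to the balance (and to the loan total).
#'
#' The whole session is deterministic given `(policy, seed)`: the RNG is
#' seeded once at session start and any stochastic policy draws from it.
#'
#' @param policy a function `function(history)` returning one of `"A"`,
#'   `"B"`, `"C"`, `"D"`. `history` is the data frame of completed trials
#'   (columns `trial`, `deck`, `win`, `loss`, `balance`), with zero rows on
#'   trial 1. Agents from [igt_agent()] satisfy this interface.
#' @param schedule a [payoff_schedule()]; default the packaged standard.
#' @param n_trials number of trials (the reference protocol uses 200).
#' @param seed integer seed for the session RNG.
#' @param participant_id identifier stored in the log.
#' @param loan size of each loan instalment (default $2000).
#' @param loan_mode `"add"` adds the loan to the negative balance;
#'   `"reset"` resets the displayed balance to zero on each loan event.
#' @return an `igt_log`: a data frame with columns `participant_id`, `trial`,
#'   `deck`, `win`, `loss`, `balance`, plus attributes `loans` (count of loan
#'   events, including the initial stake) and `loan_total`.
#' @export
run_igt_session <- function(policy, schedule = load_payoff_schedule(),
                            n_trials = 200L, seed = 1L,
                            participant_id = "sim", loan = 2000,
                            loan_mode = c("add", "reset")) {
  stopifnot(inherits(schedule, "payoff_schedule"), is.function(policy))
  loan_mode <- match.arg(loan_mode)
  n_trials <- as.integer(n_trials)
  if (n_trials < 1L) stop("`n_trials` must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))

  deck <- character(n_trials)
  win <- loss <- balance <- numeric(n_trials)
  draws <- c(A = 0L, B = 0L, C = 0L, D = 0L)
  bal <- loan
  loans <- 1L
  hist_template <- data.frame(trial = integer(), deck = character(),
                              win = numeric(), loss = numeric(),
                              balance = numeric(),
                              stringsAsFactors = FALSE)
  for (t in seq_len(n_trials)) {
    history <- if (t == 1L) hist_template else
      data.frame(trial = seq_len(t - 1L), deck = deck[seq_len(t - 1L)],
                 win = win[seq_len(t - 1L)], loss = loss[seq_len(t - 1L)],
                 balance = balance[seq_len(t - 1L)],
                 stringsAsFactors = FALSE)
    d <- policy(history)
    if (length(d) != 1L || !d %in% names(draws))
      stop("policy returned invalid deck '", paste(d, collapse = ","),
           "' on trial ", t, call. = FALSE)
    draws[d] <- draws[d] + 1L
    out <- draw_outcome(schedule, d, draws[d])
    bal <- bal + out["win"] - out["loss"]
    while (bal < 0) {
      loans <- loans + 1L
      bal <- if (loan_mode == "add") bal + loan else 0
    }
    deck[t] <- d
    win[t] <- out["win"]
    loss[t] <- out["loss"]
    balance[t] <- bal
  }
  log <- data.frame(participant_id = participant_id,
                    trial = seq_len(n_trials), deck = deck, win = win,
                    loss = loss, balance = balance,
                    stringsAsFactors = FALSE)
  attr(log, "loans") <- loans
  attr(log, "loan_total") <- loans * loan
  class(log) <- c("igt_log", "data.frame")
  log
}

#' Read or write an IGT trial log as CSV
#'
#' The CSV format has columns `participant_id, trial, deck, win, loss,
#' balance` with 1-based contiguous trial indices. `write_trial_log()`
#' followed by `read_trial_log()` is the identity on all fields.
#'
#' @param path file path.
#' @param log an `igt_log` (see [run_igt_session()]) or compatible data
#'   frame.
#' @return `read_trial_log()` returns an `igt_log`; `write_trial_log()`
#'   returns `path` invisibly.
#' @export
read_trial_log <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_igt_log(tab, source = path)
}

#' @rdname read_trial_log
#' @export
write_trial_log <- function(log, path) {
  log <- as_igt_log(log)
  utils::write.csv(as.data.frame(log)[, c("participant_id", "trial", "deck",
                                          "win", "loss", "balance")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate and coerce a data frame to an IGT trial log
#'
#' @param x data frame with the trial-log columns.
#' @param source label used in error messages.
#' @return an `igt_log`.
#' @export
as_igt_log <- function(x, source = "trial log") {
  need <- c("participant_id", "trial", "deck", "win", "loss", "balance")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop(source, " missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(x) == 0L) stop(source, " contains no trials", call. = FALSE)
  if (!identical(as.integer(x$trial), seq_len(nrow(x))))
    stop(source, ": trial indices must be contiguous 1..N", call. = FALSE)
  if (!all(x$deck %in% c("A", "B", "C", "D")))
    stop(source, ": deck labels must be A, B, C or D", call. = FALSE)
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  class(x) <- c("igt_log", "data.frame")
  x
}

#' @export
print.igt_log <- function(x, ...) {
  cat(sprintf("IGT trial log: participant %s, %d trials, final balance $%g\n",
              x$participant_id[1], nrow(x), x$balance[nrow(x)]))
  tab <- table(factor(x$deck, levels = c("A", "B", "C", "D")))
  cat("  deck counts:", paste(names(tab), tab, sep = "=", collapse = " "),
      "\n")
  if (!is.null(attr(x, "loans")))
    cat("  loans taken:", attr(x, "loans"),
        sprintf("($%g total)\n", attr(x, "loan_total")))
  invisible(x)
}
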