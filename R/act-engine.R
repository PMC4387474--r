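#' Arrange the events of one schedule stream
#'
#' Each component runs two independent streams (rewards and penalties), each
#' governed by a single variable-interval (VI) timer. Inter-arrangement
#' intervals are exponentially distributed; each arranged event is assigned
#' to deck 1 or deck 2 by sampling without replacement from the scheduled
#' per-deck counts (dependent scheduling), so exactly the scheduled counts
#' are arranged and the obtained deck ratio must equal the arranged ratio
#' once all events are collected. After an event is arranged the timer halts
#' until the event is collected by a press on its assigned deck.
#'
#' Variable-magnitude cells draw their amounts as a balanced shuffle of the
#' five-point [magnitude_set()] (each member used `count/5` times per deck),
#' so per-deck delivered totals equal `count * mean` exactly on full
#' delivery.
#'
#' @param spec a `component_spec` from [build_condition()].
#' @param stream `"reward"` or `"penalty"`.
#' @param seed optional integer seed; if `NULL`, draws from the current RNG
#'   stream (used internally by [run_component()]).
#' @param vi_mean mean inter-arrangement interval in seconds; default sized
#'   so the stream's events fit comfortably inside the component time limit
#'   (`0.6 * max_duration_s / total events`).
#' @return data frame with columns `interval` (timer seconds before the
#'   event arms), `deck`, `amount`; one row per scheduled event.
#' @export
arrange_schedule <- function(spec, stream = c("reward", "penalty"),
                             seed = NULL, vi_mean = NULL) {
  stopifnot(inherits(spec, "component_spec"))
  stream <- match.arg(stream)
  if (!is.null(seed)) set.seed(as.integer(seed))
  cell <- spec[[stream]]
  total <- sum(cell$count)
  if (is.null(vi_mean)) vi_mean <- 0.6 * spec$max_duration_s / total
  intervals <- stats::rexp(total, rate = 1 / vi_mean)
  decks <- sample(rep(1:2, times = cell$count))
  amounts <- numeric(total)
  for (d in 1:2) {
    k <- cell$count[d]
    amounts[decks == d] <- if (cell$variable[d]) {
      set <- magnitude_set(cell$mean[d])
      if (k %% length(set) != 0L)
        stop("variable count ", k, " is not a multiple of the magnitude ",
             "set size", call. = FALSE)
      sample(rep(set, each = k %/% length(set)))
    } else rep(cell$mean[d], k)
  }
  data.frame(interval = intervals, deck = decks, amount = amounts)
}

#' Run one ACT component against a continuous-time agent
#'
#' Simulates key presses in continuous time. The reward and penalty streams
#' run independently; each arms its next event when its VI timer elapses
#' (the timer only runs while no event of that stream is pending) and
#' delivers the armed event at the first press on the assigned deck. The
#' component ends when all scheduled events of both streams have been
#' delivered, or at the time limit (default 480 s), whichever comes first.
#' An armed event on a deck the agent never presses stalls its stream, which
#' is how exclusive preferences produce timeouts and missing late blocks.
#'
#' @param agent an agent from [act_agent()], or any list with elements
#'   `press_rate` (presses per second), `reset(spec)`, `choose()` (returns
#'   deck 1 or 2) and `notify(kind, deck, amount)`.
#' @param spec a `component_spec`.
#' @param seed integer seed covering schedule arrangement and agent choices.
#' @param vi_mean optional VI mean passed to [arrange_schedule()].
#' @return an `act_log`: data frame of events with columns `time`, `kind`
#'   (`"press"`, `"reward"`, `"penalty"`, `"component_end"`), `deck`,
#'   `amount` (NA for presses), with attributes `condition`, `component`,
#'   `varied`, `varied_dimension`, `termination_reason` (`"all_delivered"`
#'   or `"timeout"`), and `spec`.
#' @export
run_component <- function(agent, spec, seed = 1L, vi_mean = NULL) {
  stopifnot(inherits(spec, "component_spec"))
  set.seed(as.integer(seed))
  plans <- list(reward = arrange_schedule(spec, "reward", vi_mean = vi_mean),
                penalty = arrange_schedule(spec, "penalty",
                                           vi_mean = vi_mean))
  agent$reset(spec)
  max_t <- spec$max_duration_s
  # stream state: index of next event, time the current timer started
  idx <- c(reward = 1L, penalty = 1L)
  timer_start <- c(reward = 0, penalty = 0)
  n_ev <- vapply(plans, nrow, integer(1))

  cap <- max(64L, as.integer(ceiling(agent$press_rate * max_t * 1.3)) + 16L)
  ev_time <- numeric(cap); ev_kind <- character(cap)
  ev_deck <- integer(cap); ev_amount <- rep(NA_real_, cap)
  n_rec <- 0L
  rec <- function(time, kind, deck, amount) {
    n_rec <<- n_rec + 1L
    if (n_rec > length(ev_time)) {    # grow if the agent out-presses the cap
      ev_time <<- c(ev_time, numeric(cap)); ev_kind <<- c(ev_kind, character(cap))
      ev_deck <<- c(ev_deck, integer(cap)); ev_amount <<- c(ev_amount, rep(NA_real_, cap))
    }
    ev_time[n_rec] <<- time; ev_kind[n_rec] <<- kind
    ev_deck[n_rec] <<- deck; ev_amount[n_rec] <<- amount
  }

  t <- 0
  reason <- "timeout"
  end_t <- max_t
  if (all(n_ev == 0L)) { reason <- "all_delivered"; end_t <- 0 }
  while (reason == "timeout") {
    wait <- if (agent$press_rate > 0)
      stats::rexp(1, rate = agent$press_rate) else Inf
    if (t + wait > max_t) break
    t <- t + wait
    d <- agent$choose()
    rec(t, "press", d, NA_real_)
    for (s in c("reward", "penalty")) {
      i <- idx[[s]]
      if (i > n_ev[[s]]) next
      plan <- plans[[s]]
      armed <- timer_start[[s]] + plan$interval[i] <= t
      if (armed && plan$deck[i] == d) {
        rec(t, s, d, plan$amount[i])
        agent$notify(s, d, plan$amount[i])
        idx[[s]] <- i + 1L
        timer_start[[s]] <- t
      }
    }
    if (all(idx > n_ev)) { reason <- "all_delivered"; end_t <- t; break }
  }
  rec(end_t, "component_end", NA_integer_, NA_real_)
  log <- data.frame(time = ev_time[seq_len(n_rec)],
                    kind = ev_kind[seq_len(n_rec)],
                    deck = ev_deck[seq_len(n_rec)],
                    amount = ev_amount[seq_len(n_rec)],
                    stringsAsFactors = FALSE)
  attr(log, "condition") <- spec$condition
  attr(log, "component") <- spec$component
  attr(log, "varied") <- spec$varied
  attr(log, "varied_dimension") <- spec$varied_dimension
  attr(log, "termination_reason") <- reason
  attr(log, "spec") <- spec
  class(log) <- c("act_log", "data.frame")
  log
}

#' Run the four components of an ACT condition
#'
#' Components are presented in a seed-determined random order with the agent
#' reset between components (each component's contingencies must be learned
#' afresh).
#'
#' @inheritParams run_component
#' @param condition_id condition number 1--4.
#' @param config configuration list from [load_act_config()].
#' @return list of four `act_log`s, ordered by component number, with
#'   attribute `presentation_order` giving the order actually presented.
#' @export
run_act_session <- function(agent, condition_id, seed = 1L,
                            config = load_act_config(), vi_mean = NULL) {
  specs <- build_condition(condition_id, config)
  set.seed(as.integer(seed))
  order <- sample(4L)
  comp_seeds <- sample.int(.Machine$integer.max, 4L)
  logs <- vector("list", 4L)
  for (k in seq_len(4L)) {
    cmp <- order[k]
    logs[[cmp]] <- run_component(agent, specs[[cmp]], seed = comp_seeds[k],
                                 vi_mean = vi_mean)
  }
  attr(logs, "presentation_order") <- order
  attr(logs, "condition") <- condition_id
  logs
}

#' @export
print.act_log <- function(x, ...) {
  cat(sprintf("ACT event log: condition %d component %d (%s)\n",
              attr(x, "condition"), attr(x, "component"),
              attr(x, "termination_reason")))
  for (s in c("press", "reward", "penalty")) {
    sub <- x[x$kind == s, ]
    cat(sprintf("  %s: %d events (deck1 %d / deck2 %d)",
                s, nrow(sub), sum(sub$deck == 1), sum(sub$deck == 2)))
    if (s != "press") cat(sprintf(", $%g / $%g",
                                  sum(sub$amount[sub$deck == 1]),
                                  sum(sub$amount[sub$deck == 2])))
    cat("\n")
  }
  invisible(x)
}

#' Delivered net outcome per deck of one component
#'
#' Sum of delivered rewards minus delivered penalties, per deck. Equals the
#' configured net reward when the component ran to full delivery.
#'
#' @param log an `act_log`.
#' @return numeric length-2 vector (deck 1, deck 2).
#' @export
delivered_net <- function(log) {
  stopifnot(inherits(log, "act_log"))
  vapply(1:2, function(d)
    sum(log$amount[log$kind == "reward" & log$deck == d]) -
      sum(log$amount[log$kind == "penalty" & log$deck == d]), numeric(1))
}

#' Write or read ACT event logs as CSV
#'
#' Columns: `condition, component, time, kind, deck, amount,
#' termination_reason` (the last repeated per row for round-tripping).
#'
#' @param logs list of `act_log`s (e.g. from [run_act_session()]).
#' @param path file path.
#' @return `read_act_log()` returns a list of `act_log`s keyed by component;
#'   `write_act_log()` returns `path` invisibly.
#' @export
write_act_log <- function(logs, path) {
  if (inherits(logs, "act_log")) logs <- list(logs)
  rows <- do.call(rbind, lapply(logs, function(l)
    data.frame(condition = attr(l, "condition"),
               component = attr(l, "component"),
               time = l$time, kind = l$kind, deck = l$deck,
               amount = l$amount,
               varied = attr(l, "varied"),
               varied_dimension = attr(l, "varied_dimension"),
               termination_reason = attr(l, "termination_reason"),
               stringsAsFactors = FALSE)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_act_log
#' @export
read_act_log <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "component", "time", "kind", "deck", "amount",
            "varied", "varied_dimension", "termination_reason")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("event log missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  lapply(split(tab, tab$component), function(sub) {
    log <- data.frame(time = sub$time, kind = sub$kind, deck = sub$deck,
                      amount = sub$amount, stringsAsFactors = FALSE)
    attr(log, "condition") <- sub$condition[1]
    attr(log, "component") <- sub$component[1]
    attr(log, "varied") <- sub$varied[1]
    attr(log, "varied_dimension") <- sub$varied_dimension[1]
    attr(log, "termination_reason") <- sub$termination_reason[1]
    class(log) <- c("act_log", "data.frame")
    log
  })
}
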