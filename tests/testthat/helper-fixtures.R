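# Shared test fixtures: constructed logs and deterministic agents.

# Build an igt_log from a deck sequence alone (analysis functions only look
# at the deck column).
make_igt_log <- function(decks, id = "T") {
  as_igt_log(data.frame(participant_id = id, trial = seq_along(decks),
                        deck = decks, win = 0, loss = 0, balance = 0,
                        stringsAsFactors = FALSE))
}

# Deck sequence with a prescribed number of switches inside one block.
seq_with_switches <- function(n, k) {
  d <- rep("C", n)
  if (k > 0) for (i in seq_len(k)) d[i + 1] <- if (d[i] == "C") "D" else "C"
  # only the first k comparisons switch; rest constant
  for (i in (k + 2):n) d[i] <- d[k + 1]
  d
}

# Cooperative ACT agent: alternates decks deterministically, presses fast.
cooperative_agent <- function(press_rate = 2) {
  k <- 0L
  list(press_rate = press_rate,
       reset = function(spec = NULL) k <<- 0L,
       choose = function() { k <<- k + 1L; 1L + (k %% 2L) },
       notify = function(kind, deck, amount) invisible(NULL))
}

# Exclusive-preference ACT agent: never presses deck 1.
exclusive_agent <- function(press_rate = 2) {
  list(press_rate = press_rate,
       reset = function(spec = NULL) invisible(NULL),
       choose = function() 2L,
       notify = function(kind, deck, amount) invisible(NULL))
}

# Construct an act_log by hand for estimator tests.
fake_act_log <- function(press_time, press_deck, ev_time, ev_deck,
                         ev_amount = rep(50, length(ev_time)),
                         varied = "reward", dim = "frequency",
                         condition = 1L, component = 1L) {
  log <- rbind(
    data.frame(time = press_time, kind = "press", deck = press_deck,
               amount = NA_real_, stringsAsFactors = FALSE),
    data.frame(time = ev_time, kind = varied, deck = ev_deck,
               amount = ev_amount, stringsAsFactors = FALSE))
  log <- log[order(log$time), ]
  attr(log, "condition") <- condition
  attr(log, "component") <- component
  attr(log, "varied") <- varied
  attr(log, "varied_dimension") <- dim
  attr(log, "termination_reason") <- "all_delivered"
  class(log) <- c("act_log", "data.frame")
  log
}

# Random point on the 4-simplex in multiples of 1/20 (ties possible).
random_profile <- function() {
  x <- stats::rmultinom(1, 20, rep(0.25, 4))[, 1] / 20
  stats::setNames(as.numeric(x), c("A", "B", "C", "D"))
}

# Independent exhaustive implementation of the preference rules.
oracle_preference <- function(p) {
  decks <- c("A", "B", "C", "D")
  singles <- decks[vapply(1:4, function(i)
    p[i] >= 0.5 && all(p[i] - p[-i] >= 0.25), logical(1))]
  if (length(singles) >= 1) return(singles[1])
  for (i in 1:3) for (j in (i + 1):4)
    if (p[i] + p[j] >= 0.75 && abs(p[i] - p[j]) < 0.25)
      return(paste(decks[i], decks[j], sep = "+"))
  "none"
}

# Independent exhaustive window scan for the stability criterion.
oracle_stability <- function(labels, run_length = 3L) {
  n <- length(labels)
  if (n >= run_length)
    for (i in run_length:n) {
      w <- labels[(i - run_length + 1L):i]
      if (w[1] != "none" && all(w == w[1]))
        return(list(first = i, pref = w[1]))
    }
  list(first = NA_integer_, pref = NA_character_)
}

# Exhaustive pair-count Mann-Whitney U (with midrank tie handling).
oracle_u <- function(a, b) {
  gt <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  c(u_a = gt, u_b = length(a) * length(b) - gt)
}
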