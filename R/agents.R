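#' Parameter sets for named IGT agent archetypes
#'
#' Archetypes capture the phenomenology seen in individual learning
#' trajectories: fast learners, slow ("late") learners, agents that never
#' learn, random responders and perseverators. Stored as data so alternative
#' parameterizations are drop-in.
#'
#' @return data frame of archetype parameters.
#' @export
igt_archetypes <- function() {
  data.frame(
    archetype = c("learner", "late-learner", "non-learner", "random",
                  "perseverative", "ideal"),
    learning_rate = c(0.20, 0.03, 0.001, 0.2, 0.2, NA),
    inverse_temperature = c(0.25, 0.25, 0.05, 0, 0, NA),
    loss_weight = c(1, 1, 1, 1, 1, NA),
    exploration_floor = c(0.05, 0.05, 0.20, 0, 0, NA),
    stringsAsFactors = FALSE)
}

#' Construct an IGT agent policy
#'
#' A delta-rule/softmax bandit learner: after each trial the chosen deck's
#' expectancy is updated by `V <- V + alpha * (win - lambda * loss - V)`, and
#' the next deck is drawn from a softmax over expectancies,
#' `p(d) proportional to exp(beta * V_d)`, mixed with an exploration floor
#' (probability `epsilon` of a uniform choice). The returned policy
#' recomputes expectancies from the supplied history on every call, so it is
#' a pure function of (history, RNG state) and can be reused across
#' sessions.
#'
#' The `"ideal"` archetype is a deterministic reference policy: it cycles
#' through the available decks for the first 40 trials (one full schedule
#' cycle of exploration) and thereafter alternates between the good decks C
#' and D, so its net score over trials 41 onward is exactly 1.
#'
#' @param archetype optional name from [igt_archetypes()]; overrides the
#'   numeric parameters.
#' @param learning_rate delta-rule step size `alpha` in (0, 1].
#' @param inverse_temperature softmax `beta` (>= 0; 0 gives uniform choice).
#' @param loss_weight `lambda`, scaling of losses relative to wins in the
#'   value update.
#' @param exploration_floor probability of a uniform exploratory choice.
#' @param decks deck labels the agent is allowed to choose from.
#' @return a policy `function(history)` usable by [run_igt_session()], with
#'   the parameters attached as attribute `params`.
#' @export
igt_agent <- function(archetype = NULL, learning_rate = 0.2,
                      inverse_temperature = 0.25, loss_weight = 1,
                      exploration_floor = 0.05,
                      decks = c("A", "B", "C", "D")) {
  stopifnot(all(decks %in% c("A", "B", "C", "D")), length(decks) >= 1L)
  if (!is.null(archetype)) {
    tab <- igt_archetypes()
    if (!archetype %in% tab$archetype)
      stop("unknown archetype: ", archetype, call. = FALSE)
    if (archetype == "ideal") {
      good <- intersect(decks, c("C", "D"))
      if (length(good) == 0L)
        stop("ideal archetype needs access to deck C or D", call. = FALSE)
      policy <- function(history) {
        t <- nrow(history) + 1L
        if (t <= 40L) decks[(t - 1L) %% length(decks) + 1L]
        else good[(t - 1L) %% length(good) + 1L]
      }
      attr(policy, "params") <- list(archetype = "ideal", decks = decks)
      return(policy)
    }
    if (archetype == "perseverative") {
      policy <- function(history) {
        if (nrow(history) == 0L) sample(decks, 1L) else history$deck[1L]
      }
      attr(policy, "params") <- list(archetype = "perseverative",
                                     decks = decks)
      return(policy)
    }
    row <- tab[tab$archetype == archetype, ]
    learning_rate <- row$learning_rate
    inverse_temperature <- row$inverse_temperature
    loss_weight <- row$loss_weight
    exploration_floor <- row$exploration_floor
  }
  if (!is.finite(learning_rate) || learning_rate <= 0 || learning_rate > 1)
    stop("`learning_rate` must lie in (0, 1]", call. = FALSE)
  if (inverse_temperature < 0) stop("`inverse_temperature` must be >= 0",
                                    call. = FALSE)
  if (loss_weight < 0) stop("`loss_weight` must be >= 0", call. = FALSE)
  if (exploration_floor < 0 || exploration_floor > 1)
    stop("`exploration_floor` must be a probability", call. = FALSE)

  policy <- function(history) {
    V <- stats::setNames(numeric(length(decks)), decks)
    if (nrow(history) > 0L)
      for (i in seq_len(nrow(history))) {
        d <- history$deck[i]
        if (d %in% decks)
          V[d] <- V[d] + learning_rate *
            (history$win[i] - loss_weight * history$loss[i] - V[d])
      }
    z <- inverse_temperature * (V - max(V))
    p <- exp(z) / sum(exp(z))
    p <- (1 - exploration_floor) * p + exploration_floor / length(decks)
    sample(decks, 1L, prob = p)
  }
  attr(policy, "params") <- list(
    archetype = if (is.null(archetype)) NA_character_ else archetype,
    learning_rate = learning_rate,
    inverse_temperature = inverse_temperature, loss_weight = loss_weight,
    exploration_floor = exploration_floor, decks = decks)
  policy
}

#' Construct a matching-law ACT agent
#'
#' A continuous-time responder whose key presses arrive at `press_rate`
#' presses per second and are allocated between the decks according to the
#' generalized matching law applied to its running estimate of the obtained
#' reinforcer ratio: `log10(p1 / p2) = sensitivity * log10(r) + log_bias`,
#' where `r` is the ratio of varied-stream events (counts in frequency
#' conditions, delivered amounts in magnitude conditions) over the last
#' `estimate_window` obtained events, inverted for penalty streams so the
#' agent avoids the penalty-rich deck. Before any varied-stream event has
#' been obtained the allocation is 50/50; a side with no events in the
#' window is regularized by half an event-equivalent so the ratio stays
#' finite.
#'
#' @param sensitivity target matching sensitivity `a`.
#' @param log_bias log10 response bias toward deck 1.
#' @param press_rate presses per second (> 0). The default of 2/s reflects
#'   the low-effort key presses the task affords.
#' @param estimate_window number of most recent varied-stream events used in
#'   the obtained-ratio estimate (>= 1). The default of 20 spans a full
#'   component's varied-event budget, so the estimate converges on the
#'   cumulative obtained ratio as the component progresses.
#' @return an object of class `act_agent`: a list with elements
#'   `press_rate`, `reset(spec)`, `choose()`, `notify(kind, deck, amount)`
#'   and `params`, usable by [run_component()].
#' @export
act_agent <- function(sensitivity, log_bias = 0, press_rate = 2,
                      estimate_window = 20L) {
  if (!is.finite(press_rate) || press_rate <= 0)
    stop("`press_rate` must be > 0", call. = FALSE)
  estimate_window <- as.integer(estimate_window)
  if (is.na(estimate_window) || estimate_window < 1L)
    stop("`estimate_window` must be >= 1", call. = FALSE)

  varied <- "reward"; by_mag <- FALSE
  ev_deck <- integer(0); ev_amt <- numeric(0)

  reset <- function(spec = NULL) {
    if (!is.null(spec)) {
      varied <<- spec$varied
      by_mag <<- identical(spec$varied_dimension, "magnitude")
    }
    ev_deck <<- integer(0); ev_amt <<- numeric(0)
    invisible(NULL)
  }
  notify <- function(kind, deck, amount) {
    if (kind != varied) return(invisible(NULL))
    ev_deck <<- c(ev_deck, deck); ev_amt <<- c(ev_amt, amount)
    if (length(ev_deck) > estimate_window) {
      keep <- seq.int(length(ev_deck) - estimate_window + 1L,
                      length(ev_deck))
      ev_deck <<- ev_deck[keep]; ev_amt <<- ev_amt[keep]
    }
    invisible(NULL)
  }
  choose <- function() {
    if (length(ev_deck) == 0L) return(1L + (stats::runif(1) >= 0.5))
    s1 <- if (by_mag) sum(ev_amt[ev_deck == 1L]) else sum(ev_deck == 1L)
    s2 <- if (by_mag) sum(ev_amt[ev_deck == 2L]) else sum(ev_deck == 2L)
    if (varied == "penalty") { tmp <- s1; s1 <- s2; s2 <- tmp }
    if (s1 <= 0 || s2 <= 0) {
      h <- if (by_mag) 0.5 * mean(ev_amt) else 0.5
      s1 <- s1 + h; s2 <- s2 + h
    }
    lo <- sensitivity * log10(s1 / s2) + log_bias
    p1 <- 1 / (1 + 10^(-lo))
    if (stats::runif(1) < p1) 1L else 2L
  }
  structure(list(press_rate = press_rate, reset = reset, choose = choose,
                 notify = notify,
                 params = list(sensitivity = sensitivity,
                               log_bias = log_bias,
                               press_rate = press_rate,
                               estimate_window = estimate_window)),
            class = "act_agent")
}

#' Build a reproducible cohort of synthetic agents
#'
#' Draws `n` agents from a distribution specification and records every
#' drawn parameter (plus a per-agent seed) in a manifest, giving ground
#' truth for parameter-recovery tests.
#'
#' For IGT cohorts the distribution list is
#' `list(type = "igt", archetypes = c(learner = 0.6, "non-learner" = 0.4))`
#' (any archetypes from [igt_archetypes()], weights summing to 1), with
#' optional ranges `learning_rate`, `inverse_temperature`, `loss_weight`,
#' `exploration_floor` (length-2 `c(min, max)` vectors) from which learner
#' parameters are drawn uniformly; archetypes other than `"learner"` use
#' their fixed parameter sets.
#'
#' For ACT cohorts the distribution list is `list(type = "act", sensitivity = c(min,
#' max), log_bias = c(min, max), press_rate = c(min, max), estimate_window =
#' integer)`; scalar entries are treated as fixed values.
#'
#' @param n cohort size (>= 1).
#' @param param_distributions distribution specification (see Details).
#' @param seed integer seed; identical `(n, spec, seed)` give an identical
#'   manifest and identical agents.
#' @return list with `agents` (list of policies / `act_agent`s) and
#'   `manifest` (data frame: `participant_id`, `agent_seed`, and all drawn
#'   parameters).
#' @export
build_cohort <- function(n, param_distributions, seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be >= 1", call. = FALSE)
  spec <- param_distributions
  if (!is.list(spec) || is.null(spec$type) ||
      !spec$type %in% c("igt", "act"))
    stop("`param_distributions` must be a list with type 'igt' or 'act'",
         call. = FALSE)
  set.seed(as.integer(seed))
  agent_seed <- sample.int(.Machine$integer.max, n)
  rng_draw <- function(range, n) {
    if (length(range) == 1L) rep(range, n)
    else if (length(range) == 2L && range[2] >= range[1])
      stats::runif(n, range[1], range[2])
    else stop("parameter ranges must be c(min, max) or a single value",
              call. = FALSE)
  }
  if (spec$type == "igt") {
    w <- spec$archetypes
    if (is.null(w)) w <- c(learner = 1)
    known <- igt_archetypes()$archetype
    if (is.null(names(w)) || !all(names(w) %in% known))
      stop("archetype weights must be named after igt_archetypes()",
           call. = FALSE)
    arch <- sample(names(w), n, replace = TRUE, prob = w)
    lr <- rng_draw(spec$learning_rate %||% c(0.05, 0.35), n)
    beta <- rng_draw(spec$inverse_temperature %||% c(0.15, 0.35), n)
    lw <- rng_draw(spec$loss_weight %||% 1, n)
    ef <- rng_draw(spec$exploration_floor %||% c(0.02, 0.10), n)
    tab <- igt_archetypes()
    for (i in seq_len(n))
      if (arch[i] != "learner" && !arch[i] %in% c("ideal", "perseverative")) {
        row <- tab[tab$archetype == arch[i], ]
        lr[i] <- row$learning_rate; beta[i] <- row$inverse_temperature
        lw[i] <- row$loss_weight; ef[i] <- row$exploration_floor
      }
    manifest <- data.frame(
      participant_id = sprintf("P%03d", seq_len(n)),
      agent_seed = agent_seed, archetype = arch, learning_rate = lr,
      inverse_temperature = beta, loss_weight = lw,
      exploration_floor = ef, stringsAsFactors = FALSE)
    agents <- lapply(seq_len(n), function(i)
      if (arch[i] %in% c("ideal", "perseverative"))
        igt_agent(archetype = arch[i])
      else igt_agent(learning_rate = lr[i], inverse_temperature = beta[i],
                     loss_weight = lw[i], exploration_floor = ef[i]))
  } else {
    a <- rng_draw(spec$sensitivity %||% c(0.3, 1.2), n)
    b <- rng_draw(spec$log_bias %||% 0, n)
    pr <- rng_draw(spec$press_rate %||% 1, n)
    ew <- as.integer(round(rng_draw(spec$estimate_window %||% 12L, n)))
    manifest <- data.frame(
      participant_id = sprintf("P%03d", seq_len(n)),
      agent_seed = agent_seed, sensitivity = a, log_bias = b,
      press_rate = pr, estimate_window = ew, stringsAsFactors = FALSE)
    agents <- lapply(seq_len(n), function(i)
      act_agent(sensitivity = a[i], log_bias = b[i], press_rate = pr[i],
                estimate_window = ew[i]))
  }
  list(agents = agents, manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
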