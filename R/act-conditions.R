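#' Load an ACT condition configuration
#'
#' The Auckland Card Task (ACT) presents two decks under concurrent
#' variable-interval reward and penalty schedules. A configuration describes
#' four conditions (reward frequency, reward magnitude, penalty frequency,
#' penalty magnitude), each with four components giving per-deck arranged
#' probabilities, mean amounts and variable-magnitude flags. The packaged
#' default `"act_table4"` arranges net rewards of $100/$600, $200/$500,
#' $500/$200 and $600/$100 across the two decks in every condition.
#'
#' @param source a JSON config path or the packaged name `"act_table4"`.
#' @return the configuration list.
#' @export
load_act_config <- function(source = "act_table4") {
  if (identical(source, "act_table4"))
    source <- system.file("extdata", "act_table4.json",
                          package = "igtmatch", mustWork = TRUE)
  if (!file.exists(source))
    stop("no such config file: ", source, call. = FALSE)
  jsonlite::read_json(source, simplifyVector = TRUE,
                      simplifyDataFrame = FALSE)
}

#' Build the four component specifications of an ACT condition
#'
#' Converts arranged probabilities into concrete event counts: the varied
#' frequency dimension splits 20 events between the decks by the printed
#' probabilities (0.25/0.75 gives 5/15; 0.35/0.65 gives 7/13); a varied
#' magnitude dimension arranges 10 events per deck at the printed mean; the
#' constant reward dimension in penalty conditions arranges 5 events per
#' deck at $170, and the constant penalty dimension in reward conditions 5
#' per deck at $30. These counts make every component's per-deck net reward
#' (count x mean, rewards minus penalties) equal the configured values, and
#' every component's total net reward $700.
#'
#' @param condition_id condition number, 1--4.
#' @param config a configuration list from [load_act_config()].
#' @return list of four `component_spec` objects, each with fields
#'   `condition`, `component`, `varied` (`"reward"` or `"penalty"`),
#'   `varied_dimension` (`"frequency"` or `"magnitude"`), `max_duration_s`,
#'   and per stream (`reward`, `penalty`) `count`, `mean`, `variable`
#'   (length-2 vectors, deck 1 then deck 2), plus the configured `net`.
#' @export
build_condition <- function(condition_id, config = load_act_config()) {
  condition_id <- as.integer(condition_id)
  if (is.na(condition_id) || !condition_id %in% 1:4)
    stop("`condition_id` must be 1, 2, 3 or 4", call. = FALSE)
  cond <- NULL
  for (cc in config$conditions)
    if (cc$condition == condition_id) cond <- cc
  if (is.null(cond))
    stop("condition ", condition_id, " not present in config", call. = FALSE)
  varied_stream <- if (grepl("^reward", cond$varied)) "reward" else "penalty"
  varied_dim <- if (grepl("frequency$", cond$varied)) "frequency" else
    "magnitude"
  lapply(cond$components, function(cmp) {
    spec <- list(condition = condition_id, component = cmp$component,
                 varied = varied_stream, varied_dimension = varied_dim,
                 max_duration_s = config$max_duration_s,
                 net = as.numeric(cmp$net))
    for (stream in c("reward", "penalty")) {
      cell <- cmp[[stream]]
      prob <- as.numeric(cell$prob)
      is_varied <- stream == varied_stream
      count <- if (is_varied && varied_dim == "frequency") {
        # 20 events split by the arranged probabilities
        as.integer(round(20 * prob))
      } else if (is_varied) {
        c(10L, 10L)                       # varied magnitude: 10 per deck
      } else {
        c(5L, 5L)                         # constant dimension: 5 per deck
      }
      spec[[stream]] <- list(count = count, mean = as.numeric(cell$mean),
                             variable = as.logical(cell$variable))
    }
    got <- spec$reward$count * spec$reward$mean -
      spec$penalty$count * spec$penalty$mean
    if (!isTRUE(all.equal(got, spec$net)))
      stop("component ", cmp$component, " of condition ", condition_id,
           ": derived net reward (", paste(got, collapse = ", "),
           ") does not match configured net (",
           paste(spec$net, collapse = ", "), ")", call. = FALSE)
    class(spec) <- "component_spec"
    spec
  })
}

#' @export
print.component_spec <- function(x, ...) {
  cat(sprintf("ACT condition %d component %d (varied: %s %s)\n",
              x$condition, x$component, x$varied, x$varied_dimension))
  for (s in c("reward", "penalty"))
    cat(sprintf("  %s: counts %d/%d, means $%g/$%g%s\n", s,
                x[[s]]$count[1], x[[s]]$count[2], x[[s]]$mean[1],
                x[[s]]$mean[2],
                if (any(x[[s]]$variable)) " (variable)" else ""))
  cat(sprintf("  net reward: $%g / $%g\n", x$net[1], x$net[2]))
  invisible(x)
}

#' The multiset of amounts behind a variable-magnitude cell
#'
#' Variable magnitudes are drawn from a symmetric five-point set centred on
#' the mean, in $10 steps: \{mean-20, mean-10, mean, mean+10, mean+20\}.
#'
#' @param mean mean amount in dollars.
#' @param spread step size between adjacent set members (default $10).
#' @return numeric vector of five amounts.
#' @export
magnitude_set <- function(mean, spread = 10) {
  set <- mean + spread * (-2:2)
  if (any(set <= 0))
    stop("magnitude set around mean $", mean,
         " contains non-positive values", call. = FALSE)
  set
}

#' Sample one event amount
#'
#' Constant cells always deliver exactly the mean; variable cells draw
#' uniformly from [magnitude_set()].
#'
#' @param mean mean amount (> 0).
#' @param variable logical; is this a variable-magnitude cell?
#' @param spread passed to [magnitude_set()].
#' @return a single amount.
#' @export
sample_magnitude <- function(mean, variable = FALSE, spread = 10) {
  if (!is.finite(mean) || mean <= 0) stop("`mean` must be > 0", call. = FALSE)
  if (!variable) return(mean)
  sample(magnitude_set(mean, spread), 1L)
}
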