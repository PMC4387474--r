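#' Blockwise log response and reinforcer ratios for one condition
#'
#' Blocks are delimited by every `block_size`-th delivered event of the
#' condition's varied stream (rewards in the reward-frequency and
#' reward-magnitude conditions, penalties in the penalty conditions). For
#' each block and component, the log response ratio is computed from all
#' presses made during the block, and the log reinforcer ratio from all
#' varied-stream events delivered from the start of the component to the end
#' of the block. Frequency conditions use event counts; magnitude conditions
#' use delivered amounts. For penalty conditions the reinforcer ratio is
#' inverted (deck 2 over deck 1), so that appropriately avoiding the
#' penalty-rich deck yields positive sensitivity, matching the operant
#' convention for aversive schedules.
#'
#' A point is flagged invalid (not dropped) whenever either ratio has a zero
#' numerator or denominator; blocks whose delimiting event was never
#' delivered (component timeout) are missing entirely.
#'
#' @param logs list of four `act_log`s from one condition (see
#'   [run_act_session()]).
#' @param block_size varied-stream events per block (default 4).
#' @return data frame of ratio points with columns `condition`, `component`,
#'   `block`, `presses1`, `presses2`, `reinf1`, `reinf2`,
#'   `log_response_ratio`, `log_reinforcer_ratio`, `valid`.
#' @export
block_ratio_points <- function(logs, block_size = 4L) {
  stopifnot(length(logs) >= 1L)
  conds <- vapply(logs, function(l) as.integer(attr(l, "condition")),
                  integer(1))
  if (length(unique(conds)) != 1L)
    stop("logs come from mixed conditions: ",
         paste(unique(conds), collapse = ", "), call. = FALSE)
  block_size <- as.integer(block_size)
  if (is.na(block_size) || block_size < 1L)
    stop("`block_size` must be >= 1", call. = FALSE)
  out <- lapply(logs, function(log) {
    varied <- attr(log, "varied")
    by_mag <- identical(attr(log, "varied_dimension"), "magnitude")
    ev <- log[log$kind == varied, ]
    presses <- log[log$kind == "press", ]
    n_blocks <- nrow(ev) %/% block_size
    if (n_blocks == 0L) return(NULL)
    do.call(rbind, lapply(seq_len(n_blocks), function(b) {
      t_end <- ev$time[b * block_size]
      t_start <- if (b == 1L) -Inf else ev$time[(b - 1L) * block_size]
      in_block <- presses$time > t_start & presses$time <= t_end
      p1 <- sum(presses$deck[in_block] == 1)
      p2 <- sum(presses$deck[in_block] == 2)
      cum <- ev[ev$time <= t_end, ]
      r1 <- if (by_mag) sum(cum$amount[cum$deck == 1]) else
        sum(cum$deck == 1)
      r2 <- if (by_mag) sum(cum$amount[cum$deck == 2]) else
        sum(cum$deck == 2)
      if (varied == "penalty") { tmp <- r1; r1 <- r2; r2 <- tmp }
      valid <- p1 > 0 && p2 > 0 && r1 > 0 && r2 > 0
      data.frame(condition = attr(log, "condition"),
                 component = attr(log, "component"), block = b,
                 presses1 = p1, presses2 = p2, reinf1 = r1, reinf2 = r2,
                 log_response_ratio = if (valid) log10(p1 / p2) else
                   NA_real_,
                 log_reinforcer_ratio = if (valid) log10(r1 / r2) else
                   NA_real_,
                 valid = valid)
    }))
  })
  out <- do.call(rbind, out)
  if (is.null(out))                       # no block was ever completed
    out <- data.frame(condition = integer(0), component = integer(0),
                      block = integer(0), presses1 = integer(0),
                      presses2 = integer(0), reinf1 = numeric(0),
                      reinf2 = numeric(0), log_response_ratio = numeric(0),
                      log_reinforcer_ratio = numeric(0), valid = logical(0))
  rownames(out) <- NULL
  out
}

#' Fit the generalized matching law
#'
#' Ordinary least squares of log response ratio on log reinforcer ratio:
#' `log10(B1/B2) = a * log10(R1/R2) + log10(c)`. The slope `a` is the
#' sensitivity estimate and the intercept `log10(c)` the log bias. Only
#' points flagged valid enter the fit; invalid and missing points are
#' counted, not silently dropped. Fewer than two valid points (or valid
#' points with no spread in the reinforcer ratio) yield an undefined
#' estimate flagged in the result rather than an error.
#'
#' @param points ratio-point data frame from [block_ratio_points()], or any
#'   data frame with columns `log_response_ratio`, `log_reinforcer_ratio`
#'   and (optionally) `valid`.
#' @param points_offered total points that should have been available (used
#'   to report missing data); defaults to `nrow(points)`.
#' @param block block index the points belong to, or `"stable"`; carried
#'   into the result for bookkeeping.
#' @return an object of class `gml_fit` with elements `sensitivity`,
#'   `log_bias`, `r_squared`, `n_points`, `missing_points`, `block`,
#'   `defined`, and the fitted `points`.
#' @export
fit_gml <- function(points, points_offered = NULL, block = NA) {
  stopifnot(is.data.frame(points),
            all(c("log_response_ratio", "log_reinforcer_ratio") %in%
                  names(points)))
  if (is.null(points$valid))
    points$valid <- is.finite(points$log_response_ratio) &
      is.finite(points$log_reinforcer_ratio)
  if (is.null(points_offered)) points_offered <- nrow(points)
  ok <- points[points$valid, , drop = FALSE]
  n <- nrow(ok)
  res <- list(sensitivity = NA_real_, log_bias = NA_real_,
              r_squared = NA_real_, n_points = n,
              missing_points = points_offered - n, block = block,
              defined = FALSE, reason = "insufficient_points",
              points = points, fitted = NULL, residuals = NULL)
  class(res) <- "gml_fit"
  if (n < 2L) return(res)
  x <- ok$log_reinforcer_ratio
  y <- ok$log_response_ratio
  if (max(x) - min(x) < .Machine$double.eps^0.5) {
    res$reason <- "degenerate_x"   # no spread in the reinforcer ratio
    return(res)
  }
  res$reason <- NA_character_
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  res$sensitivity <- unname(cf[2])
  res$log_bias <- unname(cf[1])
  res$r_squared <- if (sum((y - mean(y))^2) == 0) 1 else
    1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  res$defined <- TRUE
  res$fitted <- unname(stats::fitted(fit))
  res$residuals <- unname(stats::residuals(fit))
  res
}

#' @export
print.gml_fit <- function(x, ...) {
  if (!x$defined) {
    cat(sprintf(
      "GML fit (block %s): undefined (%d valid point(s), %d missing)\n",
      as.character(x$block), x$n_points, x$missing_points))
  } else {
    cat(sprintf(
      "GML fit (block %s): sensitivity %.3f, log bias %.3f (R^2 %.3f, n=%d%s)\n",
      as.character(x$block), x$sensitivity, x$log_bias, x$r_squared,
      x$n_points,
      if (x$missing_points > 0)
        paste0(", ", x$missing_points, " missing") else ""))
  }
  invisible(x)
}

#' @export
coef.gml_fit <- function(object, ...) {
  c(log_bias = object$log_bias, sensitivity = object$sensitivity)
}

#' @export
residuals.gml_fit <- function(object, ...) object$residuals

#' @export
predict.gml_fit <- function(object, newdata = NULL, ...) {
  if (!object$defined) stop("undefined fit", call. = FALSE)
  x <- if (is.null(newdata)) {
    ok <- object$points[object$points$valid, , drop = FALSE]
    ok$log_reinforcer_ratio
  } else if (is.data.frame(newdata)) newdata$log_reinforcer_ratio
  else as.numeric(newdata)
  object$log_bias + object$sensitivity * x
}

#' @export
summary.gml_fit <- function(object, ...) {
  print(object)
  if (object$defined) {
    ok <- object$points[object$points$valid, , drop = FALSE]
    cat("Points (valid):\n")
    print(ok[, c("log_reinforcer_ratio", "log_response_ratio")],
          row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.gml_fit <- function(x, ...) {
  ok <- x$points[x$points$valid, , drop = FALSE]
  graphics::plot(ok$log_reinforcer_ratio, ok$log_response_ratio,
                 xlab = "log10 reinforcer ratio",
                 ylab = "log10 response ratio",
                 main = sprintf("Generalized matching law (a = %.2f)",
                                x$sensitivity), ...)
  if (x$defined) graphics::abline(x$log_bias, x$sensitivity)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Per-block GML fits for one participant and condition
#'
#' Fits the matching law separately for each block, across the four
#' components' block-k points. Blocks never reached (timeouts) count as
#' missing.
#'
#' @param points ratio points from [block_ratio_points()].
#' @param n_blocks total blocks the schedule offers (default 5: 20 varied
#'   events in blocks of 4).
#' @return list of `gml_fit` objects, one per block 1..`n_blocks`.
#' @export
gml_blocks <- function(points, n_blocks = 5L) {
  lapply(seq_len(n_blocks), function(b)
    fit_gml(points[points$block == b, , drop = FALSE],
            points_offered = 4L, block = b))
}

#' Cohort mean sensitivity per block
#'
#' Averages per-participant blockwise sensitivity estimates; participants
#' with undefined estimates for a block are excluded from that block's mean
#' and counted as missing.
#'
#' @param points_list list of per-participant ratio-point data frames (one
#'   condition).
#' @param n_blocks total blocks offered.
#' @return data frame with columns `block`, `mean_sensitivity`, `sem`, `n`,
#'   `missing`.
#' @export
blockwise_sensitivity <- function(points_list, n_blocks = 5L) {
  fits <- lapply(points_list, gml_blocks, n_blocks = n_blocks)
  do.call(rbind, lapply(seq_len(n_blocks), function(b) {
    a <- vapply(fits, function(f) f[[b]]$sensitivity, numeric(1))
    ok <- is.finite(a)
    data.frame(block = b,
               mean_sensitivity = if (any(ok)) mean(a[ok]) else NA_real_,
               sem = if (sum(ok) > 1)
                 stats::sd(a[ok]) / sqrt(sum(ok)) else NA_real_,
               n = sum(ok), missing = sum(!ok))
  }))
}

#' Stable sensitivity for one participant and condition
#'
#' Averages the per-block sensitivity estimates over the final blocks in
#' which group behaviour is stable: the last two blocks in condition 1 and
#' the last three blocks in conditions 2--4. Undefined blocks are skipped;
#' the estimate is undefined only if no designated block is defined.
#'
#' @param block_fits list of `gml_fit`s from [gml_blocks()].
#' @param condition_id condition number 1--4.
#' @return list with `sensitivity` (NA if undefined), `n_blocks_used`,
#'   `blocks` (the designated block indices).
#' @export
stable_sensitivity <- function(block_fits, condition_id) {
  condition_id <- as.integer(condition_id)
  if (!condition_id %in% 1:4)
    stop("`condition_id` must be 1..4", call. = FALSE)
  k <- if (condition_id == 1L) 2L else 3L
  n_blocks <- length(block_fits)
  idx <- seq.int(n_blocks - k + 1L, n_blocks)
  a <- vapply(block_fits[idx], function(f) f$sensitivity, numeric(1))
  ok <- is.finite(a)
  list(sensitivity = if (any(ok)) mean(a[ok]) else NA_real_,
       n_blocks_used = sum(ok), blocks = idx)
}

#' End-to-end sensitivity estimate for one session
#'
#' Composition: [block_ratio_points()], [gml_blocks()],
#' [stable_sensitivity()].
#'
#' @param logs list of four `act_log`s of one condition.
#' @param block_size varied events per block.
#' @return the [stable_sensitivity()] result, with the blockwise fits
#'   attached as attribute `block_fits`.
#' @export
session_sensitivity <- function(logs, block_size = 4L) {
  pts <- block_ratio_points(logs, block_size = block_size)
  spec <- attr(logs[[1]], "spec")
  total <- sum(spec[[spec$varied]]$count)
  fits <- gml_blocks(pts, n_blocks = total %/% block_size)
  out <- stable_sensitivity(fits, attr(logs[[1]], "condition"))
  attr(out, "block_fits") <- fits
  out
}
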