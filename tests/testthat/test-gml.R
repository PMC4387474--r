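test_that("ratio points match a hand count on a constructed log", {
  # 8 reward events: blocks of 4; block 2 has 30 deck-1 and 10 deck-2
  # presses; cumulative events at block 2 end are 6 deck-1, 2 deck-2
  ev_deck <- c(2, 1, 1, 2, 1, 1, 1, 1)          # cumulative 6/2 after 8
  log <- fake_act_log(
    press_time = c(seq(1, 34, length.out = 20),
                   seq(36, 75, length.out = 30),     # deck 1, block 2
                   seq(36.5, 74.5, length.out = 10)),# deck 2, block 2
    press_deck = c(rep(1:2, 10), rep(1, 30), rep(2, 10)),
    ev_time = seq(5, 75, by = 10), ev_deck = ev_deck)
  pts <- block_ratio_points(list(log), block_size = 4)
  expect_equal(nrow(pts), 2L)
  b2 <- pts[pts$block == 2, ]
  expect_equal(b2$presses1, 30)
  expect_equal(b2$presses2, 10)
  expect_equal(b2$log_response_ratio, log10(3))
  expect_equal(b2$log_reinforcer_ratio, log10(3))
  expect_true(b2$valid)
})

test_that("zero press or event counts flag the point invalid", {
  log <- fake_act_log(press_time = seq(1, 39, length.out = 10),
                      press_deck = rep(1, 10),
                      ev_time = seq(5, 35, by = 10),
                      ev_deck = c(1, 1, 2, 1))
  pts <- block_ratio_points(list(log), block_size = 4)
  expect_false(pts$valid[1])
  expect_true(is.na(pts$log_response_ratio[1]))

  log2 <- fake_act_log(press_time = seq(1, 39, length.out = 10),
                       press_deck = rep(1:2, 5),
                       ev_time = seq(5, 35, by = 10),
                       ev_deck = c(1, 1, 1, 1))   # no deck-2 events
  pts2 <- block_ratio_points(list(log2), block_size = 4)
  expect_false(pts2$valid[1])
})

test_that("penalty conditions invert the reinforcer ratio", {
  log <- fake_act_log(press_time = seq(1, 39, length.out = 12),
                      press_deck = rep(c(1, 2, 2), 4),
                      ev_time = seq(5, 35, by = 10),
                      ev_deck = c(1, 1, 1, 2),
                      varied = "penalty", condition = 3L)
  pts <- block_ratio_points(list(log), block_size = 4)
  # 3 penalties deck 1, 1 deck 2 -> inverted ratio 1/3
  expect_equal(pts$log_reinforcer_ratio[1], log10(1 / 3))
})

test_that("magnitude conditions use delivered amounts", {
  log <- fake_act_log(press_time = seq(1, 39, length.out = 12),
                      press_deck = rep(c(1, 2, 2), 4),
                      ev_time = seq(5, 35, by = 10),
                      ev_deck = c(1, 2, 1, 2),
                      ev_amount = c(25, 75, 35, 85),
                      dim = "magnitude", condition = 2L)
  pts <- block_ratio_points(list(log), block_size = 4)
  expect_equal(pts$log_reinforcer_ratio[1], log10(60 / 160))
})

test_that("mixed-condition logs are rejected", {
  l1 <- fake_act_log(1, 1, 2, 1, condition = 1L)
  l2 <- fake_act_log(1, 1, 2, 1, condition = 2L)
  expect_error(block_ratio_points(list(l1, l2)), "mixed")
})

test_that("the matching-law fit recovers exact lines to 1e-9", {
  x <- c(log10(5 / 15), log10(7 / 13), log10(13 / 7), log10(15 / 5))
  mk <- function(y) data.frame(log_response_ratio = y,
                               log_reinforcer_ratio = x, valid = TRUE)
  f1 <- fit_gml(mk(x))
  expect_equal(f1$sensitivity, 1, tolerance = 1e-9)
  expect_equal(f1$log_bias, 0, tolerance = 1e-9)
  expect_equal(f1$r_squared, 1, tolerance = 1e-9)
  f2 <- fit_gml(mk(0.5 * x))
  expect_equal(f2$sensitivity, 0.5, tolerance = 1e-9)
  f3 <- fit_gml(mk(0.8 * x + 0.1))
  expect_equal(f3$sensitivity, 0.8, tolerance = 1e-9)
  expect_equal(f3$log_bias, 0.1, tolerance = 1e-9)
  expect_equal(coef(f3), c(log_bias = 0.1, sensitivity = 0.8),
               tolerance = 1e-9)
  expect_equal(predict(f3, 0), 0.1, tolerance = 1e-9)
})

test_that("the fit agrees with closed-form simple regression on random sets", {
  set.seed(7)
  for (i in 1:1000) {
    n <- sample(3:12, 1)
    x <- stats::rnorm(n)
    y <- 0.7 * x + 0.05 + stats::rnorm(n, sd = 0.3)
    f <- fit_gml(data.frame(log_response_ratio = y,
                            log_reinforcer_ratio = x, valid = TRUE))
    b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    a0 <- mean(y) - b * mean(x)
    expect_equal(f$sensitivity, b, tolerance = 1e-9)
    expect_equal(f$log_bias, a0, tolerance = 1e-9)
  }
})

test_that("undefined and degenerate fits are flagged, not thrown", {
  pts <- data.frame(log_response_ratio = c(0.1, NA, NA, NA),
                    log_reinforcer_ratio = c(0.3, NA, NA, NA),
                    valid = c(TRUE, FALSE, FALSE, FALSE))
  f <- fit_gml(pts)
  expect_false(f$defined)
  expect_equal(f$n_points, 1L)
  expect_equal(f$missing_points, 3L)
  expect_equal(f$reason, "insufficient_points")

  deg <- data.frame(log_response_ratio = c(0.1, 0.2, 0.3),
                    log_reinforcer_ratio = rep(0.5, 3), valid = TRUE)
  f2 <- fit_gml(deg)
  expect_false(f2$defined)
  expect_equal(f2$reason, "degenerate_x")
})

test_that("relabeling the decks preserves sensitivity and negates bias", {
  set.seed(17)
  x <- stats::rnorm(6); y <- 1.1 * x + 0.2 + stats::rnorm(6, 0.02)
  f <- fit_gml(data.frame(log_response_ratio = y,
                          log_reinforcer_ratio = x, valid = TRUE))
  fsw <- fit_gml(data.frame(log_response_ratio = -y,
                            log_reinforcer_ratio = -x, valid = TRUE))
  expect_equal(fsw$sensitivity, f$sensitivity, tolerance = 1e-12)
  expect_equal(fsw$log_bias, -f$log_bias, tolerance = 1e-12)

  # end to end: physically swapping decks in a simulated component
  agent <- act_agent(sensitivity = 0.9, log_bias = 0.1)
  sess <- run_act_session(agent, 1, seed = 29)
  swap_log <- function(l) {
    l2 <- l
    l2$deck <- ifelse(l$deck == 1, 2L, ifelse(l$deck == 2, 1L, l$deck))
    l2
  }
  sw <- lapply(sess, swap_log)
  p1 <- block_ratio_points(sess); p2 <- block_ratio_points(sw)
  m <- merge(p1, p2, by = c("component", "block"))
  keep <- m$valid.x & m$valid.y
  expect_equal(m$log_response_ratio.y[keep],
               -m$log_response_ratio.x[keep])
  expect_equal(m$log_reinforcer_ratio.y[keep],
               -m$log_reinforcer_ratio.x[keep])
  fa <- fit_gml(p1[p1$block == 5, ]); fb <- fit_gml(p2[p2$block == 5, ])
  expect_equal(fb$sensitivity, fa$sensitivity, tolerance = 1e-9)
  expect_equal(fb$log_bias, -fa$log_bias, tolerance = 1e-9)
})

test_that("stable sensitivity averages the designated final blocks", {
  mkfit <- function(a) {
    f <- fit_gml(data.frame(log_response_ratio = a * c(-0.3, 0.3),
                            log_reinforcer_ratio = c(-0.3, 0.3),
                            valid = TRUE))
    f
  }
  undef <- fit_gml(data.frame(log_response_ratio = numeric(0),
                              log_reinforcer_ratio = numeric(0),
                              valid = logical(0)), points_offered = 4)
  # condition 1: mean of last two blocks
  fits <- list(mkfit(0.1), mkfit(0.2), mkfit(0.3), mkfit(0.9), mkfit(1.1))
  expect_equal(stable_sensitivity(fits, 1)$sensitivity, 1.0)
  expect_equal(stable_sensitivity(fits, 1)$blocks, 4:5)
  # condition 4: undefined middle block skipped
  fits2 <- list(mkfit(0), mkfit(0), mkfit(0.5), undef, mkfit(0.7))
  r <- stable_sensitivity(fits2, 4)
  expect_equal(r$sensitivity, 0.6)
  expect_equal(r$n_blocks_used, 2L)
  # all designated blocks undefined: flagged undefined
  fits3 <- list(mkfit(0.2), mkfit(0.2), undef, undef, undef)
  r3 <- stable_sensitivity(fits3, 2)
  expect_true(is.na(r3$sensitivity))
  expect_equal(r3$n_blocks_used, 0L)
})

test_that("identical agents give zero between-participant SEM", {
  pts <- lapply(1:3, function(i) {
    agent <- act_agent(sensitivity = 0.8)
    block_ratio_points(run_act_session(agent, 1, seed = 101))
  })
  bw <- blockwise_sensitivity(pts)
  expect_equal(nrow(bw), 5L)
  expect_equal(bw$sem[bw$n > 1], rep(0, sum(bw$n > 1)))
  expect_equal(bw$n + bw$missing, rep(3L, 5L))
})
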