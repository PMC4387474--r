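test_that("net score has the right scale, symmetry and additivity", {
  expect_equal(net_score(make_igt_log(rep("C", 100))), 1.0)
  expect_equal(net_score(make_igt_log(rep(c("A", "C"), 50))), 0.0)
  # 62 good / 38 bad choices over 100 trials: net = 0.62 - 0.38 = 0.24
  log <- make_igt_log(sample(c(rep("C", 40), rep("D", 22),
                               rep("A", 20), rep("B", 18))))
  expect_equal(net_score(log), 0.24)

  # additivity: net over full = mean of equal-epoch nets, exactly
  set.seed(5)
  for (i in 1:20) {
    lg <- make_igt_log(sample(c("A", "B", "C", "D"), 200, replace = TRUE))
    expect_equal(net_score(lg),
                 mean(c(net_score(lg, c(1, 100)),
                        net_score(lg, c(101, 200)))))
    expect_true(abs(net_score(lg)) <= 1)
  }
  expect_error(net_score(log, c(50, 20)), "interval")
  expect_error(net_score(log, c(1, 300)), "interval")
})

test_that("stable-window scoring restricts the net score to the window", {
  log <- make_igt_log(c(sample(c("A", "B", "C", "D"), 160, replace = TRUE),
                        rep("C", 40)))
  expect_equal(stable_window_net_score(log, c(161, 200)), 1.0)
  # 27 good / 13 bad in the final 40 trials -> (27-13)/40 = 0.35
  tail40 <- sample(c(rep("C", 20), rep("D", 7), rep("A", 13)))
  log2 <- make_igt_log(c(rep("B", 160), tail40))
  expect_equal(stable_window_net_score(log2, c(161, 200)), 0.35)
  expect_error(stable_window_net_score(log2, c(161, 201)), "interval")
})

test_that("block profiles partition trials and normalize within block", {
  expect_equal(unlist(block_profiles(make_igt_log(rep("D", 20)))[1, 2:5]),
               c(A = 0, B = 0, C = 0, D = 1))
  expect_equal(unlist(block_profiles(
    make_igt_log(c(rep("A", 10), rep("B", 10))))[1, 2:5]),
    c(A = 0.5, B = 0.5, C = 0, D = 0))
  prof <- block_profiles(make_igt_log(sample(c("A", "B", "C", "D"), 200,
                                             replace = TRUE)))
  expect_equal(nrow(prof), 10L)
  expect_equal(rowSums(prof[, 2:5]), rep(1, 10), tolerance = 1e-12)
  expect_error(block_profiles(make_igt_log(rep("A", 30))), "multiple")
  expect_error(block_profiles(make_igt_log(rep("A", 20)), 0), "positive")
})

test_that("switch proportions count deck changes against eligible trials", {
  expect_equal(switch_proportion(make_igt_log(rep("C", 60))), rep(0, 3))
  expect_equal(switch_proportion(make_igt_log(rep(c("A", "B"), 30))),
               c(1, 1, 1))
  # 5 changes among block 2's 20 comparisons -> 0.25
  blk2 <- seq_with_switches(20, 5)
  log <- make_igt_log(c(rep(blk2[1], 20), blk2))
  expect_equal(switch_proportion(log)[2], 0.25)

  # brute-force oracle on random logs
  set.seed(11)
  for (i in 1:20) {
    d <- sample(c("A", "B", "C", "D"), 80, replace = TRUE)
    got <- switch_proportion(make_igt_log(d), block_size = 20)
    manual <- vapply(1:4, function(b) {
      idx <- ((b - 1) * 20 + 1):(b * 20)
      idx <- idx[idx >= 2]
      mean(d[idx] != d[idx - 1])
    }, numeric(1))
    expect_equal(got, manual)
    expect_true(all(got >= 0 & got <= 1))
  }

  # a constant-deck log never switches, whatever the block partition
  const <- make_igt_log(rep("B", 120))
  for (bs in c(10, 20, 30, 40, 60))
    expect_true(all(switch_proportion(const, bs) == 0))
})

test_that("impairment criteria are strict inequalities on the stated cuts", {
  expect_true(classify_impairment(0.09, "bechara_0.10"))
  expect_false(classify_impairment(0.10, "bechara_0.10"))
  expect_true(classify_impairment(-0.01, "steingroever_0.00"))
  expect_false(classify_impairment(0.00, "steingroever_0.00"))
  expect_error(classify_impairment(0.5, "other"))
  expect_error(classify_impairment(1.2, "bechara_0.10"), "\\[-1, 1\\]")
})

test_that("preference rules label single decks, pairs, then none", {
  expect_equal(block_preference(c(0.10, 0.10, 0.60, 0.20)), "C")
  expect_equal(block_preference(c(0.05, 0.05, 0.45, 0.45)), "C+D")
  expect_equal(block_preference(c(0.25, 0.05, 0.40, 0.30)), "none")
  # single-deck rule wins when both rules are satisfied
  expect_equal(block_preference(c(0.75, 0.25, 0, 0)), "A")
  # p = 0.5/0.5 fails the single margin, falls through to the pair rule
  expect_equal(block_preference(c(0.5, 0.5, 0, 0)), "A+B")

  set.seed(21)
  for (i in 1:300) {
    p <- random_profile()
    expect_equal(block_preference(p), oracle_preference(p))
  }
  expect_error(block_preference(c(0.5, 0.5, 0.5, -0.5)), "summing")
})

test_that("stability detection matches an exhaustive window scan", {
  r <- detect_stability(rep("C", 10))
  expect_equal(r$first_stable_block, 3L)
  expect_equal(r$decision_class, "good")
  r2 <- detect_stability(rep("none", 10))
  expect_true(is.na(r2$first_stable_block))
  expect_equal(r2$decision_class, "poor")
  r3 <- detect_stability(rep("B+D", 5))
  expect_equal(r3$first_stable_block, 3L)
  expect_equal(r3$decision_class, "bad-deck")

  labs <- c("A", "B", "C", "C+D", "B+D", "none")
  set.seed(31)
  for (i in 1:300) {
    x <- sample(labs, sample(3:12, 1), replace = TRUE,
                prob = c(1, 1, 3, 2, 1, 3))
    got <- detect_stability(x)
    want <- oracle_stability(x)
    expect_equal(got$first_stable_block, want$first)
    expect_equal(got$stable_preference, want$pref)
    if (!is.na(got$first_stable_block))
      expect_gte(got$first_stable_block, 3L)
  }
  expect_error(detect_stability(character(0)), "nonempty")
})

test_that("stability locks at first attainment but reports later changes", {
  r <- detect_stability(c("C", "C", "C", "D", "C", "C"))
  expect_equal(r$first_stable_block, 3L)
  expect_equal(r$stable_preference, "C")
  expect_equal(r$later_label_changes, 1L)
})

test_that("permuting deck labels permutes preferences and flips the class", {
  set.seed(41)
  d <- c(sample(c("C", "D"), 60, TRUE, prob = c(0.8, 0.2)),
         sample(c("A", "B", "C", "D"), 40, TRUE))
  log <- make_igt_log(d)
  swap <- c(A = "C", B = "D", C = "A", D = "B")
  log_sw <- make_igt_log(unname(swap[d]))
  s1 <- stability_analysis(log)
  s2 <- stability_analysis(log_sw)
  relab <- function(lab) {
    if (lab == "none") return("none")
    parts <- sort(unname(swap[strsplit(lab, "+", fixed = TRUE)[[1]]]))
    paste(parts, collapse = "+")
  }
  expect_equal(vapply(s1$labels, relab, character(1), USE.NAMES = FALSE),
               s2$labels)
  expect_equal(s1$first_stable_block, s2$first_stable_block)
  if (s1$decision_class == "good") expect_equal(s2$decision_class,
                                                "bad-deck")
})

test_that("cohort summaries match a brute-force recount", {
  one <- cohort_summary(list(make_igt_log(rep("C", 200), id = "a")))
  expect_equal(one$epochs$mean, rep(1, 3))
  expect_equal(one$epochs$sd, rep(0, 3))
  expect_equal(one$epochs$prop_impaired_bechara, rep(0, 3))

  two <- cohort_summary(list(
    make_igt_log(c(rep("C", 120), rep("A", 80)), id = "a"),   # net 0.2
    make_igt_log(c(rep("C", 140), rep("A", 60)), id = "b")))  # net 0.4
  full <- two$epochs[two$epochs$epoch == "full", ]
  expect_equal(full$mean, 0.3)
  expect_equal(full$range, 0.2)

  expect_error(cohort_summary(list(make_igt_log(rep("C", 200)),
                                   make_igt_log(rep("C", 100)))),
               "unequal")

  # synthetic cohort: summary equals independent recomputation
  co <- build_cohort(6, list(type = "igt",
                             archetypes = c(learner = 0.7,
                                            "non-learner" = 0.3)),
                     seed = 3)
  logs <- lapply(1:6, function(i)
    run_igt_session(co$agents[[i]], n_trials = 200,
                    seed = co$manifest$agent_seed[i],
                    participant_id = co$manifest$participant_id[i]))
  sm <- cohort_summary(logs)
  nets <- vapply(logs, function(l)
    (sum(l$deck %in% c("C", "D")) - sum(l$deck %in% c("A", "B"))) / 200,
    numeric(1))
  expect_equal(sm$epochs$mean[sm$epochs$epoch == "full"], mean(nets))
  expect_equal(sm$epochs$prop_impaired_bechara[sm$epochs$epoch == "full"],
               mean(nets < 0.10))
  firsts <- vapply(logs, function(l)
    oracle_stability(apply(block_profiles(l)[, 2:5], 1,
                           block_preference))$first, integer(1))
  expect_equal(sm$stability$first_stable_block, firsts)
})
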