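test_that("the adjustment statistic anchors at stay and copy", {
  expect_equal(adjustment_s(40, 50, 45), 0.5)
  expect_equal(adjustment_s(40, 50, 40), 0)
  expect_equal(adjustment_s(40, 50, 50), 1)
  expect_error(adjustment_s(40, 40, 45),
               class = "beastsim_undefined_adjustment")
})

test_that("classification uses exact category boundaries", {
  expect_equal(as.character(classify_adjustment(c(-0.2, 0, 0.5, 1, 1.2))),
               c("contrarian", "stay", "compromise", "copy", "overshoot"))
  # s is a ratio of integers, so boundary equality is exact
  expect_equal(as.character(classify_adjustment(adjustment_s(37L, 52L, 52L))),
               "copy")
  expect_equal(as.character(classify_adjustment(adjustment_s(37L, 52L, 37L))),
               "stay")
})

test_that("adjustment is invariant to a common shift of all three estimates", {
  withr::with_seed(5, {
    for (i in 1:100) {
      E1 <- sample(20:80, 1)
      X <- E1 + sample(c(-20:-1, 1:20), 1)
      E2 <- sample(1:120, 1)
      k <- sample(1:50, 1)
      expect_equal(adjustment_s(E1 + k, X + k, E2 + k),
                   adjustment_s(E1, X, E2))
    }
  })
})

test_that("validity policies implement omit, include and clip", {
  rec <- tibble::tibble(s = c(-0.2, 0, 0.5, 1, 1.2))
  omit <- filter_valid(rec, "omit")
  expect_equal(omit$valid, c(FALSE, TRUE, TRUE, TRUE, FALSE))
  incl <- filter_valid(rec, "include")
  expect_true(all(incl$valid))
  clip <- filter_valid(rec, "clip")
  expect_equal(clip$s, c(0, 0, 0.5, 1, 1))
  expect_true(all(clip$valid))
  expect_equal(as.character(clip$category[1]), "stay")
  expect_error(filter_valid(rec, "drop"), class = "beastsim_invalid_argument")
})

test_that("participant summaries average valid rounds per condition", {
  rec <- records_from_s(s_peer = c(0, 0.5, 1, 0.5, 0.5),
                        s_adult = c(1.2, 0.4, 0.6, -0.1, 0.6))
  summ <- participant_summaries(rec)
  expect_equal(summ$S_peer, 0.5)
  expect_equal(summ$S_adult, mean(c(0.4, 0.6, 0.6)))
  expect_equal(summ$n_valid_peer, 5L)
  expect_equal(summ$n_valid_adult, 3L)

  all_bad <- records_from_s(s_peer = c(0.2, 0.4), s_adult = c(-0.5, 1.4))
  s2 <- participant_summaries(all_bad)
  expect_true(is.na(s2$S_adult))
  expect_equal(s2$n_valid_adult, 0L)
})

test_that("the predicted second estimate is the convex combination", {
  expect_equal(predicted_second_estimate(40, 50, 0.5), 45)
  expect_equal(predicted_second_estimate(40, 50, 0), 40)
  expect_equal(predicted_second_estimate(40, 50, 1), 50)
  expect_error(predicted_second_estimate(40, 50, 1.1),
               class = "beastsim_invalid_argument")
})

test_that("heuristic frequencies support both denominators", {
  rec4 <- tibble::tibble(s = c(0, 1, 0.5, 0.5),
                         category = classify_adjustment(c(0, 1, 0.5, 0.5)))
  f <- heuristic_frequencies(rec4, "all_rounds")
  expect_equal(f$proportion[f$category == "stay"], 0.25)
  expect_equal(f$proportion[f$category == "copy"], 0.25)
  expect_equal(f$proportion[f$category == "compromise"], 0.5)
  expect_equal(sum(f$proportion), 1)

  rec2 <- tibble::tibble(s = c(0, 1.2), category = classify_adjustment(c(0, 1.2)))
  fv <- heuristic_frequencies(rec2, "valid_rounds")
  expect_equal(fv$proportion[fv$category == "stay"], 1)
  fa <- heuristic_frequencies(rec2, "all_rounds")
  expect_equal(fa$proportion[fa$category == "stay"], 0.5)
  expect_equal(fa$proportion[fa$category == "overshoot"], 0.5)
  expect_error(heuristic_frequencies(rec2[0, ], "all_rounds"),
               class = "beastsim_invalid_argument")
})

test_that("deviation tables carry one first and one second row per trial", {
  trials <- tibble::tibble(participant_id = "p1", school = "s1",
                           condition = "peer", round = 1L,
                           E1 = 50L, X = 60L, E2 = 53L, true_count = 55L)
  dev <- deviation_table(trials)
  expect_equal(nrow(dev), 2)
  expect_equal(dev$deviation[dev$period == "first"], 5)
  expect_equal(dev$deviation[dev$period == "second"], 2)
  signed <- deviation_table(trials, signed = TRUE)
  expect_equal(signed$deviation, c(-5, -2))
})

test_that("recomputed adjustments recover the drawn heuristic for separated estimates", {
  # with |X - E1| >= 5 integer rounding cannot move a stay or copy off its anchor
  params <- agent_params()
  trials <- sim_small(n = 64, seed = 40)
  adj <- compute_adjustments(trials)
  sep <- adj[abs(adj$X - adj$E1) >= 5, ]
  expect_true(all(sep$s[sep$category == "stay"] == 0))
  expect_true(all(sep$s[sep$category == "copy"] == 1))
  # every defined trial lands in exactly one category
  expect_false(any(is.na(adj$category)))
  f <- heuristic_frequencies(adj, "all_rounds")
  expect_equal(sum(f$proportion), 1)
})
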