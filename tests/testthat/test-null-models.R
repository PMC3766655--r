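test_that("null model specs validate their parameters", {
  expect_error(null_model_spec(0, 0.2), "n_keys")
  expect_error(null_model_spec(10, 1.2), "q_space")
  expect_error(null_model_spec(10, 0.2, "random_text"), "random_text")
  expect_equal(random_text_spec(1946)$q_space, 1 / 1947)
  expect_equal(random_text_spec(13)$q_space, 1 / 14)
  expect_equal(random_text_spec(1)$q_space, 0.5)
})

test_that("length law is geometric, normalized, and correctly conditioned", {
  sp <- null_model_spec(13, 0.5)
  un <- null_length_pmf(sp, 2, conditional = FALSE)
  expect_equal(as.numeric(un), c(0.5, 0.25, 0.125))  # P(0), P(1), P(2)

  # conditional pmf + tail mass sums to 1 for a sweep of (q, l_max)
  for (q in c(0.05, 0.2, 1 / 14, 0.9)) {
    for (lm in c(1, 5, 60)) {
      p <- null_length_pmf(null_model_spec(5, q), lm)
      expect_lt(abs(sum(p) + attr(p, "tail") - 1), 1e-12)
    }
  }

  p <- null_length_pmf(null_model_spec(5, 0.2), 10)
  expect_equal(unname(p[1] / p[2]), 1 / 0.8)
})

test_that("block rank tables carry exact integer rank bookkeeping", {
  sp <- null_model_spec(2, 1 / 3, "random_text")
  b <- null_rank_blocks(sp, 2)
  expect_equal(b$rank_start, c(1, 3))
  expect_equal(b$rank_end, c(2, 6))
  expect_equal(b$word_probability, c((1 / 3) * (1 / 3), (1 / 3) * (1 / 9)))

  # rank_end(L) = sum_{j<=L} N^j exactly; probabilities strictly decreasing
  for (N in c(2, 5, 13)) {
    bb <- null_rank_blocks(null_model_spec(N, 0.2), 8)
    expect_equal(bb$rank_end, cumsum(N^(1:8)))
    expect_equal(bb$rank_start, c(1, utils::head(bb$rank_end, -1) + 1))
    expect_true(all(diff(bb$word_probability) < 0))
  }
  expect_error(null_rank_blocks(null_model_spec(1946, 0.2), 30),
               "capacity")
})

test_that("asymptotic slope matches its closed form and limits", {
  expect_equal(null_asymptotic_slope(null_model_spec(13, 1e-12)), -1,
               tolerance = 1e-9)
  expect_equal(null_asymptotic_slope(random_text_spec(2)),
               -log(3) / log(2))
  expect_equal(null_asymptotic_slope(null_model_spec(1946, 1 / 1947)),
               log(1946 / 1947) / log(1946) - 1)
  expect_lt(abs(null_asymptotic_slope(null_model_spec(1946, 1 / 1947)) + 1),
            1e-3)  # near-Zipf
  expect_error(null_asymptotic_slope(null_model_spec(1, 0.3)),
               "degenerate")
})

test_that("block-table fits converge to the closed-form slope as l_max grows", {
  for (N in c(2, 5, 13)) {
    sp <- null_model_spec(N, 0.2)
    target <- null_asymptotic_slope(sp)
    errs <- vapply(c(4, 8, 14), function(lm)
      abs(fit_null_blocks(sp, l_max = lm)$slope - target), numeric(1))
    expect_true(all(diff(errs) < 0))
  }
})

test_that("simulated typist matches the analytic length law", {
  sp <- null_model_spec(13, 1 / 14)
  lens <- simulate_monkey(sp, 1e5, seed = 21)
  # conditioned mean is 1/q; unconditioned mean is (1-q)/q
  se <- sqrt((1 - 1 / 14) / (1 / 14)^2 / 1e5)
  expect_lt(abs(mean(lens) - 14), 3 * se)
  lens0 <- simulate_monkey(sp, 1e5, seed = 21, include_empty = TRUE)
  expect_lt(abs(mean(lens0) - 13), 3 * se)

  expect_identical(simulate_monkey(sp, 1000, seed = 5),
                   simulate_monkey(sp, 1000, seed = 5))
})

test_that("distinct-input lengths respect the keyboard map and its cap", {
  sp <- null_model_spec(13, 1 / 14)
  expect_error(simulate_monkey(sp, 10, seed = 1,
                               length_metric = "distinct_inputs"),
               "input_map")
  lens <- simulate_monkey(sp, 2e4, seed = 8,
                          length_metric = "distinct_inputs",
                          input_map = mv_input_map("VC"))
  expect_true(all(lens >= 1 & lens <= 7))
  pc <- simulate_monkey(null_model_spec(11, 1 / 12), 2e4, seed = 8,
                        length_metric = "distinct_inputs",
                        input_map = mv_input_map("PC"))
  expect_true(all(pc <= 6))
})

test_that("monkey text generator agrees with the null model's statistics", {
  sp <- null_model_spec(5, 1 / 6)
  words <- gen_monkey_text(sp, 2e4, seed = 13)
  lens <- nchar(words)
  se <- sqrt((1 - sp$q_space) / sp$q_space^2 / 2e4)
  expect_lt(abs(mean(lens) - 1 / sp$q_space), 3 * se)
  expect_identical(words, gen_monkey_text(sp, 2e4, seed = 13))
  expect_false(identical(words[1:100],
                         gen_monkey_text(sp, 100, seed = 99)[1:100]))

  # whole-word rank-frequency slope approaches the closed form
  f <- fit_power_law(rank_frequency(build_vocabulary(
    gen_monkey_text(sp, 1e5, seed = 14))), min_count = 5)
  expect_lt(abs(f$slope - null_asymptotic_slope(sp)), 0.15)
})
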