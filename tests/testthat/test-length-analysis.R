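test_that("intervention pattern length counts changed inputs", {
  w <- "MV|D1111|VC:000+0-|B0"
  expect_equal(intervention_pattern_length(w), 2)
  expect_equal(intervention_pattern_length("MV|D1111|VC:+-+-+-|B1"), 7)
  expect_equal(intervention_pattern_length("MV|D1111|PC:+-+-+|B1"), 6)
  expect_equal(intervention_pattern_length("MV|D1111|VC:000000|B0"), 0)
  sw <- intervention_pattern_length("MV|D1111|SW>PC|B0")
  expect_equal(as.integer(sw), 1)
  expect_true(attr(sw, "switch"))
  expect_error(intervention_pattern_length("HD|D000000|Enone|Inone"),
               "MV scheme")

  lens <- intervention_pattern_lengths(c(w, "MV|D0000|PC:0000+|B1",
                                         "MV|D1111|SW>VC|B0"))
  expect_equal(as.integer(lens), c(2, 2))
  expect_equal(attr(lens, "mode"), c("VC", "PC"))
  with_sw <- intervention_pattern_lengths(c(w, "MV|D1111|SW>VC|B0"),
                                          include_switches = TRUE)
  expect_equal(as.integer(with_sw), c(2, 1))
})

test_that("length rank tables drop zeros and break ties toward smaller lengths", {
  t <- length_rank_table(c(1, 1, 1, 2, 2, 3))
  expect_equal(t$word, c("1", "2", "3"))
  expect_equal(t$frequency, c(3, 2, 1))

  expect_equal(length_rank_table(c(0, 0, 1))$word, "1")
  expect_equal(nrow(length_rank_table(c(0, 0))), 0)

  tie <- length_rank_table(c(2, 2, 5, 5))
  expect_equal(tie$word, c("2", "5"))
})

test_that("solution records count adjustments and completion status", {
  rows <- vent_fixture_rows()  # 3 adjust + 1 complete
  recs <- solution_lengths(rows)
  expect_equal(recs$n_interventions, 3)
  expect_true(recs$completed)

  # baseline exclusion for schema-conformant logs
  expect_equal(solution_lengths(rows, baseline_rows = 1)$n_interventions, 2)

  rows2 <- rows[rows$event_type != "complete", ]
  recs2 <- solution_lengths(rows2)
  expect_false(recs2$completed)
  expect_equal(recs2$n_interventions, 3)

  expect_equal(nrow(solution_lengths(rows[0, ])), 0)
})

test_that("solution filtering applies both exclusion rules and is idempotent", {
  recs <- data.frame(subject_id = "S", patient_id = sprintf("P%d", 1:4),
                     n_interventions = c(3, 3, 5, 0),
                     completed = TRUE, stringsAsFactors = FALSE)
  got <- filter_solutions(recs)
  expect_equal(got$n_interventions, c(3, 3))
  expect_identical(filter_solutions(got), got)

  keep <- data.frame(subject_id = "S", patient_id = sprintf("P%d", 1:3),
                     n_interventions = c(2, 2, 2), completed = TRUE,
                     stringsAsFactors = FALSE)
  expect_equal(nrow(filter_solutions(keep)), 3)
  lone <- keep[1, ]; lone$n_interventions <- 1
  expect_equal(nrow(filter_solutions(lone)), 0)
})

test_that("effective space frequency is the completion share of the keystroke stream", {
  recs <- data.frame(subject_id = "S", patient_id = sprintf("P%d", 1:20),
                     n_interventions = rep(4, 20), completed = TRUE,
                     stringsAsFactors = FALSE)
  expect_equal(effective_space_frequency(recs), 0.2)
  recs1 <- recs; recs1$n_interventions <- 1
  expect_equal(effective_space_frequency(recs1), 0.5)
  recs0 <- recs; recs0$completed <- FALSE
  expect_warning(q0 <- effective_space_frequency(recs0), "no completed")
  expect_equal(q0, 0)
  expect_error(effective_space_frequency(recs[0, ]), "no solution")
})

test_that("intervention-space enumeration reproduces the keyboard counts", {
  cs <- count_intervention_space()
  expect_equal(unname(cs$per_mode["VC"]), 1458)
  expect_equal(unname(cs$per_mode["PC"]), 486)
  expect_equal(cs$total, 1946)

  # enumeration equals the closed form 2 * 3^s for s = 1..8
  for (s in 1:8) {
    sp <- mode_spec("VC"); sp$n_settings <- s
    expect_equal(unname(count_intervention_space(list(sp),
                                                 n_mode_switches = 0)$total),
                 2 * 3^s)
  }

  expect_equal(keyboard_size(mode_spec("VC")), 14)
  expect_equal(keyboard_size(mode_spec("PC")), 12)
  one <- mode_spec("VC"); one$n_settings <- 1L
  expect_equal(keyboard_size(one), 4)
})

test_that("observed-vs-null comparison is a proper share comparison", {
  sp <- null_model_spec(13, 0.2)
  lens <- simulate_monkey(sp, 1e5, seed = 17)
  cmp <- observed_vs_null(length_rank_table(lens), sp)
  expect_lt(cmp$tv, 0.02)  # self-consistency at n = 1e5
  expect_lt(abs(sum(cmp$table$observed_share) - 1), 1e-12)
  expect_lt(abs(sum(cmp$table$null_share) + cmp$null_tail - 1), 1e-12)

  # a deterministic single length diverges maximally from a diffuse model
  det <- observed_vs_null(length_rank_table(rep(3, 50)), sp)
  expect_gt(det$tv, 0.5)
  expect_error(observed_vs_null(length_rank_table(integer(0)), sp),
               "empty")
})

test_that("goal-directed sessions diverge from the intermittent-silence null", {
  for (seed in c(1, 2, 3)) {
    cfg <- vent_sim_config(n_subjects = 6, n_patients_per_subject = 40,
                           solution_model = "powerlaw", seed = seed)
    rows <- gen_vent_sessions(cfg)
    path <- write_fixture(rows)
    res <- run_null_comparison(path, quiet = TRUE)
    expect_lt(res$fits$observed$slope, res$fits$null$slope)
  }
})
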