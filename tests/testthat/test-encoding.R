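test_that("MV derangement coding applies goal ranges with strict bounds", {
  d <- encode_mv_derangement(mv_row(spo2 = 88, ph = 7.50, map = 70,
                                    pplat = 32))
  expect_equal(unname(d$codes), c(0, 2, 1, 2))  # below, above, within, above

  d2 <- encode_mv_derangement(mv_row())
  expect_equal(unname(d2$codes), rep(1, 4))

  # boundary values fail strict goals
  expect_equal(unname(encode_mv_derangement(mv_row(spo2 = 90))$codes[1]), 0)
  expect_equal(unname(encode_mv_derangement(mv_row(pplat = 30))$codes[4]), 2)

  # per-patient pH lower bound override
  d3 <- encode_mv_derangement(mv_row(ph = 7.25, ph_lb = 7.20))
  expect_equal(unname(d3$codes[2]), 1)
  expect_error(encode_mv_derangement(mv_row(), goals = mv_goals()[1:3]),
               "goals")
})

test_that("MV intervention coding keeps direction only, handles switches", {
  prev <- mv_row(step_index = 0, fio2 = 0.4, rate = 12)
  curr <- mv_row(step_index = 1, fio2 = 0.6, rate = 10)
  i <- encode_mv_intervention(prev, curr)
  expect_equal(unname(i$mv_changes), c(0, 0, 0, 1, 0, -1))
  expect_equal(i$mv_bolus, 0)

  # magnitude is discarded
  curr_big <- mv_row(step_index = 1, fio2 = 0.99, rate = 2)
  expect_equal(encode_mv_intervention(prev, curr_big)$mv_changes,
               i$mv_changes)

  # mode change -> switch symbol with no change tuple
  sw <- encode_mv_intervention(prev, mv_row(mode = "PC", step_index = 1))
  expect_equal(sw$mv_mode, "switch_to_PC")
  expect_null(sw$mv_changes)

  # all-zero change with bolus is a valid non-empty intervention
  ib <- encode_mv_intervention(prev, mv_row(step_index = 1, fio2 = 0.4,
                                            bolus = 1))
  expect_true(all(ib$mv_changes == 0))
  expect_equal(ib$mv_bolus, 1)

  expect_error(encode_mv_intervention(prev, mv_row(patient_id = "P999",
                                                   step_index = 1)),
               "same subject")
  expect_error(encode_mv_intervention(curr, prev), "precede")
})

test_that("HD derangement coding covers all six elements", {
  cuts <- c(8000, 14000)
  prev <- list(patient_id = "D1", hgb = 9.8)
  curr <- list(patient_id = "D1", hgb = 9.0, ferritin = 150, tsat = 15,
               esa_dose = 10000)
  d <- encode_hd_derangement(prev, curr, tertile_cuts = cuts)
  expect_equal(unname(d$codes),
               c(0, 0, 0, 2, 0, 1))  # below/below/below, T2, falling, <=1

  curr2 <- list(hgb = 11, ferritin = 300, tsat = 25, esa_dose = 0)
  d2 <- encode_hd_derangement(list(hgb = 11), curr2, tertile_cuts = cuts)
  expect_equal(unname(d2$codes), c(1, 1, 1, 0, 1, 0))

  # distance bin >2 g/dL outside target
  d3 <- encode_hd_derangement(list(hgb = 14), list(hgb = 14.5,
                                                   ferritin = 300,
                                                   tsat = 25,
                                                   esa_dose = 0),
                              tertile_cuts = cuts)
  expect_equal(unname(d3$codes[6]), 3)

  # strict tsat bound; inclusive hgb band; first month flagged stable
  d4 <- encode_hd_derangement(NULL, list(hgb = 10, ferritin = 300,
                                         tsat = 20, esa_dose = 0),
                              tertile_cuts = cuts)
  expect_equal(unname(d4$codes[c(1, 3, 5)]), c(1, 0, 1))
  expect_true(attr(d4, "first_month"))
})

test_that("ESA ratio bins match the stated action categories exhaustively", {
  mk <- function(prev, curr)
    encode_hd_intervention(list(patient_id = "D1", esa_dose = prev,
                                iron_given = 0, iron_dose = 0),
                           list(patient_id = "D1", esa_dose = curr,
                                iron_given = 0, iron_dose = 0))$hd_esa_action
  expect_equal(mk(10000, 16000), "up_gt50")
  expect_equal(mk(10000, 13000), "up_25_50")
  expect_equal(mk(10000, 11000), "none")
  expect_equal(mk(0, 4000), "start")
  expect_equal(mk(4000, 0), "stop")
  expect_equal(mk(0, 0), "none")

  # oracle: exhaustive ratio sweep against the stated bins
  ratios <- seq(0.05, 2.5, by = 0.01)
  got <- vapply(ratios, function(r) mk(10000, 10000 * r), character(1))
  oracle <- ifelse(ratios > 1.5, "up_gt50",
            ifelse(ratios >= 1.25, "up_25_50",
            ifelse(ratios < 0.5, "down_gt50",
            ifelse(ratios <= 0.75, "down_25_50", "none"))))
  expect_equal(got, oracle)
})

test_that("iron actions distinguish start, stop, intensify", {
  mk <- function(pg, pd, cg, cd)
    encode_hd_intervention(list(patient_id = "D1", esa_dose = 0,
                                iron_given = pg, iron_dose = pd),
                           list(patient_id = "D1", esa_dose = 0,
                                iron_given = cg, iron_dose = cd))$hd_iron_action
  expect_equal(mk(0, 0, 1, 100), "start")
  expect_equal(mk(1, 100, 0, 0), "stop")
  expect_equal(mk(1, 100, 1, 150), "intensify")
  expect_equal(mk(1, 100, 1, 100), "none")
})

test_that("words render to the canonical grammar and round-trip", {
  d <- encode_mv_derangement(mv_row(spo2 = 88, ph = 7.50, map = 70,
                                    pplat = 32))
  i <- encode_mv_intervention(mv_row(step_index = 0, fio2 = 0.4, rate = 12),
                              mv_row(step_index = 1, fio2 = 0.6, rate = 10))
  w <- make_word(d, i)
  expect_equal(w$canonical, "MV|D0212|VC:000+0-|B0")
  rt <- parse_word(w$canonical)
  expect_equal(rt$derangement$codes, d$codes)
  expect_equal(rt$intervention$mv_changes, i$mv_changes)

  # scheme mismatch is a usage error
  hd_i <- structure(list(scheme = "HD", hd_esa_action = "none",
                         hd_iron_action = "none"),
                    class = "intervention_symbol")
  expect_error(make_word(d, hd_i), "scheme")
})

test_that("canonical grammar round-trips across both schemes' alphabets and is injective", {
  # every MV derangement code x a sample of interventions, plus switches
  mk_mv_d <- function(codes) structure(
    list(scheme = "MV", codes = stats::setNames(codes, c("spo2", "ph",
                                                         "map", "pplat"))),
    class = "derangement_symbol")
  mk_mv_i <- function(mode, changes, bolus) structure(
    list(scheme = "MV", mv_mode = mode,
         mv_changes = if (grepl("switch", mode)) NULL else changes,
         mv_bolus = bolus),
    class = "intervention_symbol")

  dgrid <- as.matrix(expand.grid(0:2, 0:2, 0:2, 0:2))
  vc_alpha <- carelex:::mv_alphabet("VC")
  pc_alpha <- carelex:::mv_alphabet("PC")

  # round trip: all 81 derangements against one intervention
  i0 <- mk_mv_i("VC", stats::setNames(c(0, 0, 0, 1, 0, -1),
                                      carelex:::VC_SETTINGS), 0)
  for (k in seq_len(nrow(dgrid))) {
    w <- make_word(mk_mv_d(dgrid[k, ]), i0)
    expect_equal(parse_word(w$canonical)$canonical, w$canonical)
  }

  # round trip: every VC and PC intervention and both switches
  d0 <- mk_mv_d(c(1, 1, 1, 1))
  canon_vc <- vapply(seq_len(nrow(vc_alpha)), function(k) {
    i <- mk_mv_i("VC",
                 stats::setNames(vc_alpha[k, carelex:::VC_SETTINGS],
                                 carelex:::VC_SETTINGS),
                 vc_alpha[k, "bolus"])
    w <- make_word(d0, i)$canonical
    rt <- parse_word(w)
    stopifnot(identical(rt$canonical, w))
    w
  }, character(1))
  canon_pc <- vapply(seq_len(nrow(pc_alpha)), function(k) {
    i <- mk_mv_i("PC",
                 stats::setNames(pc_alpha[k, carelex:::PC_SETTINGS],
                                 carelex:::PC_SETTINGS),
                 pc_alpha[k, "bolus"])
    w <- make_word(d0, i)$canonical
    rt <- parse_word(w)
    stopifnot(identical(rt$canonical, w))
    w
  }, character(1))
  for (m in c("switch_to_VC", "switch_to_PC")) {
    w <- make_word(d0, mk_mv_i(m, NULL, 0))$canonical
    expect_equal(parse_word(w)$canonical, w)
  }
  expect_equal(length(canon_vc), 1458)
  expect_equal(length(canon_pc), 486)
  expect_equal(anyDuplicated(c(canon_vc, canon_pc)), 0)

  # injectivity over the full VC cross product (81 x 1458)
  all_vc <- as.vector(outer(
    paste0("MV|D", apply(dgrid, 1, paste, collapse = "")),
    sub("^MV\\|D1111\\|", "", canon_vc), paste, sep = "|"))
  expect_equal(length(all_vc), 81 * 1458)
  expect_equal(anyDuplicated(all_vc), 0)

  # HD: every 6-code derangement x every action pair round-trips
  hd_codes <- expand.grid(0:2, 0:2, 0:1, 0:3, 0:2, 0:3)
  some_hd <- hd_codes[seq(1, nrow(hd_codes), by = 7), ]
  for (k in seq_len(nrow(some_hd))) {
    d <- structure(list(scheme = "HD",
                        codes = stats::setNames(unlist(some_hd[k, ]),
                                                c("hgb", "ferritin", "tsat",
                                                  "esa_tertile", "hgb_trend",
                                                  "hgb_dist"))),
                   class = "derangement_symbol")
    for (esa in carelex:::ESA_ACTIONS[c(1, 4, 7)]) {
      i <- structure(list(scheme = "HD", hd_esa_action = esa,
                          hd_iron_action = "intensify"),
                     class = "intervention_symbol")
      w <- make_word(d, i)$canonical
      expect_equal(parse_word(w)$canonical, w)
    }
  }
})

test_that("vocabulary counting conserves totals and ignores order", {
  v <- build_vocabulary(c("w1", "w2", "w1"))
  expect_equal(unname(v$counts[c("w1", "w2")]), c(2, 1))
  expect_equal(v$total_tokens, 3)
  v0 <- build_vocabulary(character(0))
  expect_equal(v0$total_tokens, 0)
  set.seed(1)
  toks <- sample(letters[1:5], 200, replace = TRUE)
  expect_equal(build_vocabulary(toks)$counts,
               build_vocabulary(rev(toks))$counts)
})

test_that("validate_dyads conserves row counts while dropping incomplete dyads", {
  rows <- vent_fixture_rows()
  v <- validate_dyads(rows)
  expect_equal(v$excluded, 0)
  expect_equal(nrow(v$clean), nrow(rows))

  rows$pplat[2] <- NA
  v2 <- validate_dyads(rows)
  expect_equal(v2$excluded, 1)
  expect_equal(nrow(v2$clean) + v2$excluded, nrow(rows))

  rows_all_na <- rows
  rows_all_na$spo2[rows_all_na$event_type == "adjust"] <- NA
  v3 <- validate_dyads(rows_all_na)
  expect_equal(sum(v3$clean$event_type == "adjust"), 0)
})

test_that("last_k_patients filters per subject by first appearance", {
  rows <- do.call(rbind, lapply(sprintf("P%03d", 1:30), function(p) {
    r <- vent_fixture_rows(); r$patient_id <- p; r
  }))
  got <- last_k_patients(rows, 25)
  expect_equal(sort(unique(got$patient_id)), sprintf("P%03d", 6:30))
  expect_warning(last_k_patients(rows, 40), "keeping all")

  # independent filtering across subjects
  rows2 <- rows; rows2$subject_id <- "S02"
  rows2 <- rows2[rows2$patient_id %in% sprintf("P%03d", 1:10), ]
  both <- rbind(rows, rows2)
  got2 <- suppressWarnings(last_k_patients(both, 25))
  expect_equal(sort(unique(got2$patient_id[got2$subject_id == "S02"])),
               sprintf("P%03d", 1:10))
})

test_that("encoding a log is deterministic and skips the baseline row", {
  rows <- vent_fixture_rows()
  w1 <- encode_vent_words(rows)
  w2 <- encode_vent_words(rows)
  expect_identical(w1, w2)
  expect_equal(nrow(w1), 2)  # 3 adjust rows -> 2 words
  expect_equal(w1$word[1], "MV|D1111|VC:000+0-|B0")
  expect_equal(w1$word[2], "MV|D1111|VC:-000+0|B1")
})

test_that("dialysis encoding pairs consecutive available months", {
  rows <- dialysis_fixture_rows()
  w <- encode_dialysis_words(rows)
  expect_equal(nrow(w), 4)  # 2 patients x (3 months - 1)
  expect_match(w$word, "^HD\\|D[0-9]{6}\\|E", all = TRUE)
  # D002 month 2: ESA start
  expect_match(w$word[w$patient_id == "D002" & w$month_index == 2],
               "Estart")
  # D001 month 1: ESA 10000 -> 16000 is up_gt50, iron start
  expect_match(w$word[w$patient_id == "D001" & w$month_index == 1],
               "Eup_gt50\\|Istart")
})
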