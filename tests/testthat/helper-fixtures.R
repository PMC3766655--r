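# Hand-built fixtures used across test files.

# One VC patient: baseline + 2 adjustments + completion.
vent_fixture_rows <- function() {
  data.frame(
    subject_id = "S01", patient_id = "P001", step_index = 0:3,
    event_type = c("adjust", "adjust", "adjust", "complete"),
    spo2 = c(88, 92, 95, NA), ph = c(7.50, 7.38, 7.40, NA),
    map = c(70, 72, 75, NA), pplat = c(32, 28, 26, NA),
    mode = "VC",
    fio2 = c(0.4, 0.6, 0.6, NA), peep = c(5, 5, 8, NA),
    rate = c(12, 10, 10, NA), tv = c(500, 500, 450, NA),
    flow = c(60, 60, 60, NA), pause = c(0.2, 0.2, 0.2, NA),
    pinsp = NA_real_, itime = NA_real_,
    bolus = c(0, 0, 1, NA), stringsAsFactors = FALSE)
}

write_fixture <- function(rows, writer = write_vent_log) {
  path <- tempfile(fileext = ".csv")
  writer(rows, path)
  path
}

dialysis_fixture_rows <- function() {
  data.frame(
    patient_id = rep(c("D001", "D002"), each = 3),
    month_index = rep(0:2, 2),
    hgb = c(9.8, 9.0, 10.5, 11.0, 11.0, 12.8),
    ferritin = c(150, 180, 220, 300, 320, 340),
    tsat = c(15, 18, 22, 25, 26, 27),
    esa_dose = c(10000, 16000, 16000, 0, 0, 4000),
    iron_given = c(0, 1, 1, 0, 0, 0),
    iron_dose = c(0, 100, 150, 0, 0, 0),
    stringsAsFactors = FALSE)
}

# A mid-list row for symbol construction in unit tests.
mv_row <- function(spo2 = 92, ph = 7.38, map = 72, pplat = 25,
                   mode = "VC", step_index = 0, bolus = 0, ...) {
  defaults <- list(subject_id = "S01", patient_id = "P001",
                   step_index = step_index, event_type = "adjust",
                   spo2 = spo2, ph = ph, map = map, pplat = pplat,
                   mode = mode, fio2 = 0.4, peep = 5, rate = 12,
                   tv = if (mode == "VC") 500 else NA_real_,
                   flow = if (mode == "VC") 60 else NA_real_,
                   pause = if (mode == "VC") 0.2 else NA_real_,
                   pinsp = if (mode == "PC") 20 else NA_real_,
                   itime = if (mode == "PC") 1 else NA_real_,
                   bolus = bolus)
  utils::modifyList(defaults, list(...))
}
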