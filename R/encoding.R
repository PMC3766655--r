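## Symbolic encoding of derangement/intervention dyads.
##
## State coding is uniformly ternary: below = 0, within = 1, above = 2.
## One-sided goals simply never emit their unbounded side.
##
## Canonical word grammar (stable across versions):
##   MV|D<4 digits>|<VC|PC|SW>VC|SW>PC>[:<signs>]|B<0|1>
##   HD|D<6 codes>|E<esa action>|I<iron action>
## where <signs> is one of -/0/+ per setting in the mode's setting order
## (VC: tv flow pause fio2 peep rate; PC: pinsp itime fio2 peep rate) and
## mode-switch symbols carry no sign string.

STATE_CODE <- c(below = 0L, within = 1L, above = 2L)
ESA_ACTIONS <- c("none", "start", "stop", "up_25_50", "up_gt50",
                 "down_25_50", "down_gt50")
IRON_ACTIONS <- c("none", "start", "stop", "intensify")

state_digit <- function(state) unname(STATE_CODE[state])
sign_char <- function(s) c("-", "0", "+")[s + 2L]

#' Encode a mechanical-ventilation derangement symbol
#'
#' Classifies the four goal variables of a session row (SpO2, pH, mean
#' arterial pressure, plateau pressure) against their goal ranges and
#' returns the 4-code derangement symbol.  Inequalities are honored
#' strictly as written: SpO2 = 90 with goal "> 90" codes \emph{below};
#' plateau pressure = 30 with goal "< 30" codes \emph{above}.
#'
#' @param row a single session row (list or 1-row data frame) with finite
#'   `spo2`, `ph`, `map`, `pplat`; an optional `ph_lb` overrides the pH
#'   lower bound for this patient.
#' @param goals named list of [goal_range()]s covering all four variables,
#'   e.g. [mv_goals()].
#' @return A `derangement_symbol` (scheme `"MV"`, 4 codes in
#'   below/within/above).
#' @export
encode_mv_derangement <- function(row, goals = mv_goals()) {
  need <- c("spo2", "ph", "map", "pplat")
  if (!all(need %in% names(goals)))
    stop("goals must cover: ", paste(need, collapse = ", "), call. = FALSE)
  vals <- vapply(need, function(v) as.numeric(row[[v]]), numeric(1))
  if (any(!is.finite(vals)))
    stop("physiologic values must be finite on adjust rows", call. = FALSE)
  g <- goals
  if (!is.null(row$ph_lb) && length(row$ph_lb) && is.finite(row$ph_lb))
    g$ph <- goal_range("ph", lower = as.numeric(row$ph_lb), upper = g$ph$upper)
  states <- vapply(need, function(v) classify_goal(g[[v]], vals[[v]]),
                   character(1))
  structure(list(scheme = "MV",
                 codes = stats::setNames(unname(STATE_CODE[states]), need)),
            class = "derangement_symbol")
}

#' Encode a mechanical-ventilation intervention symbol
#'
#' Compares two consecutive adjustment rows for the same patient.  If the
#' ventilation mode changed, the symbol is a mode switch (carrying no
#' per-setting change tuple).  Otherwise each of the mode's settings is
#' coded by the direction of its change only (-1/0/+1; the magnitude is
#' discarded), plus the fluid-bolus flag of the current row.
#'
#' @param prev,curr consecutive session rows for the same patient with
#'   `prev$step_index < curr$step_index`.
#' @return An `intervention_symbol` (scheme `"MV"`).
#' @export
encode_mv_intervention <- function(prev, curr) {
  if (!identical(as.character(prev$patient_id),
                 as.character(curr$patient_id)) ||
      !identical(as.character(prev$subject_id),
                 as.character(curr$subject_id)))
    stop("rows must belong to the same subject and patient", call. = FALSE)
  if (!(prev$step_index < curr$step_index))
    stop("'prev' must precede 'curr' in step order", call. = FALSE)
  bolus <- as.integer(curr$bolus)
  if (!identical(as.character(prev$mode), as.character(curr$mode))) {
    mv_mode <- paste0("switch_to_", curr$mode)
    return(structure(list(scheme = "MV", mv_mode = mv_mode,
                          mv_changes = NULL, mv_bolus = bolus),
                     class = "intervention_symbol"))
  }
  settings <- if (curr$mode == "VC") VC_SETTINGS else PC_SETTINGS
  changes <- vapply(settings, function(s)
    as.integer(sign(as.numeric(curr[[s]]) - as.numeric(prev[[s]]))),
    integer(1))
  structure(list(scheme = "MV", mv_mode = as.character(curr$mode),
                 mv_changes = changes, mv_bolus = bolus),
            class = "intervention_symbol")
}

#' ESA-dose tertile cut points
#'
#' Tertile boundaries over all positive ESA doses in a dataset
#' (population tertiles, recomputed per run).
#'
#' @param doses numeric vector of ESA doses (zeros ignored).
#' @return Numeric length-2 vector of cut points.
#' @export
esa_tertile_cuts <- function(doses) {
  pos <- doses[!is.na(doses) & doses > 0]
  if (!length(pos)) return(c(0, 0))
  unname(stats::quantile(pos, c(1, 2) / 3))
}

esa_tertile <- function(dose, cuts) {
  if (is.na(dose) || dose <= 0) return(0L)
  if (dose <= cuts[1]) 1L else if (dose <= cuts[2]) 2L else 3L
}

#' Encode a dialysis derangement symbol
#'
#' Six codes: hemoglobin state (below/within/above target), ferritin
#' state, iron saturation state (below / at-or-above 20\%), ESA dose
#' tertile (none/T1/T2/T3), hemoglobin trend versus the immediately
#' preceding available month (falling/stable/rising; stable when
#' |change| <= `stable_delta`), and the distance of hemoglobin from the
#' target range binned as in-range / <=1 / <=2 / >2 g/dL outside.
#'
#' @param prev the preceding available month's row, or `NULL` for a
#'   patient's first month (trend then codes stable, and the symbol
#'   carries attribute `first_month = TRUE`).
#' @param curr current month's row.
#' @param targets named list of [goal_range()]s, e.g. [hd_targets()].
#' @param tertile_cuts length-2 cut points from [esa_tertile_cuts()]
#'   computed over the whole dataset.
#' @param stable_delta hemoglobin change (g/dL per month) treated as
#'   stable; default 0.5.
#' @return A `derangement_symbol` (scheme `"HD"`, 6 codes).
#' @export
encode_hd_derangement <- function(prev, curr, targets = hd_targets(),
                                  tertile_cuts, stable_delta = 0.5) {
  hgb_state <- classify_goal(targets$hgb, as.numeric(curr$hgb))
  fer_state <- classify_goal(targets$ferritin, as.numeric(curr$ferritin))
  tsat_state <- classify_goal(targets$tsat, as.numeric(curr$tsat))
  tsat_code <- if (tsat_state == "below") 0L else 1L

  first_month <- is.null(prev)
  trend <- 1L
  if (!first_month) {
    d <- as.numeric(curr$hgb) - as.numeric(prev$hgb)
    trend <- if (d < -stable_delta) 0L else if (d > stable_delta) 2L else 1L
  }
  h <- as.numeric(curr$hgb)
  lo <- targets$hgb$lower; hi <- targets$hgb$upper
  dist <- max(lo - h, h - hi, 0)
  dist_bin <- if (dist == 0) 0L else if (dist <= 1) 1L else if (dist <= 2)
    2L else 3L

  codes <- c(hgb = state_digit(hgb_state), ferritin = state_digit(fer_state),
             tsat = tsat_code,
             esa_tertile = esa_tertile(as.numeric(curr$esa_dose),
                                       tertile_cuts),
             hgb_trend = trend, hgb_dist = dist_bin)
  structure(list(scheme = "HD", codes = codes),
            class = "derangement_symbol", first_month = first_month)
}

esa_action_from_doses <- function(prev_dose, curr_dose) {
  if (prev_dose <= 0 && curr_dose <= 0) return("none")
  if (prev_dose <= 0 && curr_dose > 0) return("start")
  if (prev_dose > 0 && curr_dose <= 0) return("stop")
  r <- curr_dose / prev_dose
  if (r > 1.5) "up_gt50"
  else if (r >= 1.25) "up_25_50"
  else if (r < 0.5) "down_gt50"
  else if (r <= 0.75) "down_25_50"
  else "none"
}

#' Encode a dialysis intervention symbol
#'
#' ESA action from the month-over-month dose ratio r: start (0 to >0),
#' stop (>0 to 0), increase by 25--50\% (1.25 <= r <= 1.5), increase by
#' >50\% (r > 1.5), decrease by 25--50\% (0.5 <= r <= 0.75), decrease by
#' >50\% (r < 0.5); sub-threshold changes (0.75 < r < 1.25) code as none.
#' Iron action: start, stop, intensify (dose increased while continuing),
#' else none.
#'
#' @param prev,curr consecutive available months for the same patient.
#' @return An `intervention_symbol` (scheme `"HD"`).
#' @export
encode_hd_intervention <- function(prev, curr) {
  if (!identical(as.character(prev$patient_id),
                 as.character(curr$patient_id)))
    stop("rows must belong to the same patient", call. = FALSE)
  esa <- esa_action_from_doses(as.numeric(prev$esa_dose),
                               as.numeric(curr$esa_dose))
  pg <- as.numeric(prev$iron_given) > 0
  cg <- as.numeric(curr$iron_given) > 0
  iron <- if (!pg && cg) "start"
  else if (pg && !cg) "stop"
  else if (pg && cg &&
           as.numeric(curr$iron_dose) > as.numeric(prev$iron_dose))
    "intensify"
  else "none"
  structure(list(scheme = "HD", hd_esa_action = esa, hd_iron_action = iron),
            class = "intervention_symbol")
}

canonical_derangement <- function(d) paste(d$codes, collapse = "")

canonical_intervention <- function(i) {
  if (i$scheme == "MV") {
    mode_part <- if (grepl("^switch_to_", i$mv_mode))
      paste0("SW>", sub("^switch_to_", "", i$mv_mode))
    else paste0(i$mv_mode, ":", paste(sign_char(i$mv_changes), collapse = ""))
    paste0(mode_part, "|B", i$mv_bolus)
  } else {
    paste0("E", i$hd_esa_action, "|I", i$hd_iron_action)
  }
}

#' Combine a derangement and an intervention symbol into a word
#'
#' The canonical rendering is injective over (derangement, intervention)
#' and [parse_word()] inverts it exactly.
#'
#' @param d a `derangement_symbol`.
#' @param i an `intervention_symbol` of the same scheme.
#' @return A `care_word`: list(derangement, intervention, canonical).
#' @examples
#' \dontrun{
#' make_word(d, i)$canonical   # e.g. "MV|D0212|VC:000+0-|B0"
#' }
#' @export
make_word <- function(d, i) {
  stopifnot(inherits(d, "derangement_symbol"),
            inherits(i, "intervention_symbol"))
  if (!identical(d$scheme, i$scheme))
    stop("derangement and intervention schemes differ", call. = FALSE)
  canonical <- paste0(d$scheme, "|D", canonical_derangement(d), "|",
                      canonical_intervention(i))
  structure(list(derangement = d, intervention = i, canonical = canonical),
            class = "care_word")
}

#' @export
print.care_word <- function(x, ...) {
  cat("<care_word> ", x$canonical, "\n", sep = "")
  invisible(x)
}

#' Parse a canonical word string
#'
#' Inverse of [make_word()]'s canonical rendering.
#'
#' @param canonical a canonical word string.
#' @return A `care_word` with `derangement` and `intervention` filled in.
#' @export
parse_word <- function(canonical) {
  parts <- strsplit(canonical, "|", fixed = TRUE)[[1]]
  scheme <- parts[1]
  if (!scheme %in% c("MV", "HD") || substr(parts[2], 1, 1) != "D")
    stop("not a canonical word: ", canonical, call. = FALSE)
  codes <- as.integer(strsplit(substring(parts[2], 2), "")[[1]])
  if (scheme == "MV") {
    if (length(codes) != 4) stop("MV derangement must have 4 codes")
    names(codes) <- c("spo2", "ph", "map", "pplat")
    d <- structure(list(scheme = "MV", codes = codes),
                   class = "derangement_symbol")
    mode_part <- parts[3]
    bolus <- as.integer(sub("^B", "", parts[4]))
    if (grepl("^SW>", mode_part)) {
      i <- structure(list(scheme = "MV",
                          mv_mode = paste0("switch_to_",
                                           sub("^SW>", "", mode_part)),
                          mv_changes = NULL, mv_bolus = bolus),
                     class = "intervention_symbol")
    } else {
      mode <- sub(":.*$", "", mode_part)
      signs <- strsplit(sub("^..:", "", mode_part), "")[[1]]
      changes <- c(`-` = -1L, `0` = 0L, `+` = 1L)[signs]
      names(changes) <- if (mode == "VC") VC_SETTINGS else PC_SETTINGS
      i <- structure(list(scheme = "MV", mv_mode = mode,
                          mv_changes = changes, mv_bolus = bolus),
                     class = "intervention_symbol")
    }
  } else {
    if (length(codes) != 6) stop("HD derangement must have 6 codes")
    names(codes) <- c("hgb", "ferritin", "tsat", "esa_tertile", "hgb_trend",
                      "hgb_dist")
    d <- structure(list(scheme = "HD", codes = codes),
                   class = "derangement_symbol")
    esa <- sub("^E", "", parts[3])
    iron <- sub("^I", "", parts[4])
    if (!esa %in% ESA_ACTIONS || !iron %in% IRON_ACTIONS)
      stop("unknown action in word: ", canonical, call. = FALSE)
    i <- structure(list(scheme = "HD", hd_esa_action = esa,
                        hd_iron_action = iron),
                   class = "intervention_symbol")
  }
  make_word(d, i)
}

#' Count word usage
#'
#' @param words character vector of canonical word strings, a list of
#'   `care_word`s, or a data frame with a `word` column.
#' @return A `vocabulary_counts`: list(counts = named positive integers,
#'   total_tokens).
#' @export
build_vocabulary <- function(words) {
  w <- if (is.data.frame(words)) as.character(words$word)
  else if (is.list(words))
    vapply(words, function(x) x$canonical, character(1))
  else as.character(words)
  counts <- table(w)
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(list(counts = counts, total_tokens = length(w)),
            class = "vocabulary_counts")
}

#' @export
print.vocabulary_counts <- function(x, ...) {
  cat("<vocabulary_counts> ", length(x$counts), " distinct words, ",
      x$total_tokens, " tokens\n", sep = "")
  invisible(x)
}

#' Drop incomplete dyads
#'
#' Removes adjustment rows with any missing physiologic value or any
#' missing mode-required setting (the analogue of the keystroke-error
#' exclusions in observed session logs).  Row counts are conserved:
#' clean + excluded = input.
#'
#' @param rows a vent-log data frame.
#' @return list(clean = data frame, excluded = integer count).
#' @export
validate_dyads <- function(rows) {
  if (!nrow(rows))
    return(list(clean = rows, excluded = 0L))
  adj <- rows$event_type == "adjust"
  bad <- rep(FALSE, nrow(rows))
  physio_na <- Reduce(`|`, lapply(MV_PHYSIO, function(v) !is.finite(rows[[v]])))
  bad[adj] <- physio_na[adj] | is.na(rows$bolus[adj]) |
    !(rows$mode[adj] %in% c("VC", "PC"))
  is_vc <- adj & !bad & rows$mode == "VC"
  if (any(is_vc)) {
    vc_na <- Reduce(`|`, lapply(VC_SETTINGS, function(v) is.na(rows[[v]])))
    bad[is_vc] <- vc_na[is_vc]
  }
  is_pc <- adj & !bad & rows$mode == "PC"
  if (any(is_pc)) {
    pc_na <- Reduce(`|`, lapply(PC_SETTINGS, function(v) is.na(rows[[v]])))
    bad[is_pc] <- pc_na[is_pc]
  }
  clean <- rows[!bad, , drop = FALSE]
  rownames(clean) <- NULL
  list(clean = clean, excluded = sum(bad))
}

#' Keep each subject's last k virtual patients
#'
#' Patients are ordered by first appearance within each subject; the k
#' most recent are kept.  Subjects with fewer than k patients keep all of
#' them, with a warning.
#'
#' @param rows a vent-log data frame.
#' @param k number of patients to keep per subject (>= 1).
#' @return Filtered data frame.
#' @export
last_k_patients <- function(rows, k) {
  stopifnot(k >= 1)
  keep <- rep(FALSE, nrow(rows))
  for (s in unique(rows$subject_id)) {
    idx <- rows$subject_id == s
    pats <- unique(rows$patient_id[idx])
    if (length(pats) < k)
      warning("subject ", s, " has only ", length(pats),
              " patients (< k = ", k, "); keeping all", call. = FALSE)
    last <- utils::tail(pats, k)
    keep[idx & rows$patient_id %in% last] <- TRUE
  }
  out <- rows[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Encode a ventilation log into words
#'
#' Full encoding pipeline for one log: drops incomplete dyads
#' ([validate_dyads()]), then within each (subject, patient) forms one
#' word per consecutive pair of adjustment rows — the derangement symbol
#' of the current row concatenated with the intervention inferred from
#' the setting changes since the previous row.  The first row of each
#' patient is the baseline and contributes no word.
#'
#' @param rows vent-log data frame (see [read_vent_log()]).
#' @param goals [mv_goals()]-style goal list.
#' @return Data frame (subject_id, patient_id, step_index, word) with
#'   attribute `"excluded"` = number of incomplete dyads dropped.
#' @export
encode_vent_words <- function(rows, goals = mv_goals()) {
  v <- validate_dyads(rows)
  rows <- v$clean
  rows <- rows[rows$event_type == "adjust", , drop = FALSE]
  rows <- rows[order(rows$subject_id, rows$patient_id, rows$step_index), ,
               drop = FALSE]
  out <- list()
  if (nrow(rows)) {
    key <- paste(rows$subject_id, rows$patient_id, sep = "\r")
    for (grp in split(seq_len(nrow(rows)), factor(key, unique(key)))) {
      if (length(grp) < 2) next
      g <- rows[grp, , drop = FALSE]
      words <- character(nrow(g) - 1L)
      for (j in 2:nrow(g)) {
        d <- encode_mv_derangement(g[j, ], goals)
        i <- encode_mv_intervention(g[j - 1L, ], g[j, ])
        words[j - 1L] <- make_word(d, i)$canonical
      }
      out[[length(out) + 1L]] <- data.frame(
        subject_id = g$subject_id[-1L], patient_id = g$patient_id[-1L],
        step_index = g$step_index[-1L], word = words,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out)
  else data.frame(subject_id = character(), patient_id = character(),
                  step_index = numeric(), word = character(),
                  stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "excluded") <- v$excluded
  res
}

#' Encode a dialysis log into words
#'
#' For each patient, every pair of consecutive \emph{available} months
#' yields one word: the derangement symbol of the current month (trend
#' computed against the preceding available month) concatenated with the
#' ESA/iron intervention inferred from the dose changes.  ESA tertiles
#' are population tertiles over all positive doses in `rows`.
#'
#' @param rows dialysis-log data frame (see [read_dialysis_log()]).
#' @param targets [hd_targets()]-style target list.
#' @param stable_delta hemoglobin stability threshold (g/dL per month).
#' @return Data frame (patient_id, month_index, word).
#' @export
encode_dialysis_words <- function(rows, targets = hd_targets(),
                                  stable_delta = 0.5) {
  rows <- rows[order(rows$patient_id, rows$month_index), , drop = FALSE]
  cuts <- esa_tertile_cuts(rows$esa_dose)
  out <- list()
  for (grp in split(seq_len(nrow(rows)),
                    factor(rows$patient_id, unique(rows$patient_id)))) {
    if (length(grp) < 2) next
    g <- rows[grp, , drop = FALSE]
    words <- character(nrow(g) - 1L)
    for (j in 2:nrow(g)) {
      d <- encode_hd_derangement(g[j - 1L, ], g[j, ], targets, cuts,
                                 stable_delta)
      i <- encode_hd_intervention(g[j - 1L, ], g[j, ])
      words[j - 1L] <- make_word(d, i)$canonical
    }
    out[[length(out) + 1L]] <- data.frame(
      patient_id = g$patient_id[-1L], month_index = g$month_index[-1L],
      word = words, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out)
  else data.frame(patient_id = character(), month_index = numeric(),
                  word = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
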