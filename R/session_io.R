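## File schemas for session logs.  CSV with header, UTF-8, '.' decimal;
## tab accepted as alternate delimiter (auto-detected from the header line).

VENT_COLUMNS <- c("subject_id", "patient_id", "step_index", "event_type",
                  "spo2", "ph", "map", "pplat", "mode",
                  "fio2", "peep", "rate", "tv", "flow", "pause",
                  "pinsp", "itime", "bolus")
VENT_NUMERIC <- c("step_index", "spo2", "ph", "map", "pplat", "fio2", "peep",
                  "rate", "tv", "flow", "pause", "pinsp", "itime", "bolus",
                  "ph_lb")
VC_SETTINGS <- c("tv", "flow", "pause", "fio2", "peep", "rate")
PC_SETTINGS <- c("pinsp", "itime", "fio2", "peep", "rate")
MV_PHYSIO <- c("spo2", "ph", "map", "pplat")

DIALYSIS_COLUMNS <- c("patient_id", "month_index", "hgb", "ferritin", "tsat",
                      "esa_dose", "iron_given", "iron_dose")
DIALYSIS_NUMERIC <- setdiff(DIALYSIS_COLUMNS, "patient_id")

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) && grepl("\t", header, fixed = TRUE)) "\t" else ","
}

read_log_table <- function(path, required, numeric_cols) {
  if (!file.exists(path))
    stop("log file not found: ", path, call. = FALSE)
  sep <- detect_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = TRUE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", fileEncoding = "UTF-8")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  ## line number in the file (header is line 1)
  raw$.line <- seq_len(nrow(raw)) + 1L
  for (cc in intersect(numeric_cols, names(raw))) {
    v <- raw[[cc]]
    num <- suppressWarnings(as.numeric(v))
    bad <- !is.na(v) & trimws(v) != "" & is.na(num)
    raw[[paste0(".bad_", cc)]] <- bad
    raw[[cc]] <- num
  }
  raw
}

take_rejects <- function(raw, bad, reason, rejected) {
  if (any(bad)) {
    rejected <- rbind(rejected,
                      data.frame(line = raw$.line[bad], reason = reason,
                                 stringsAsFactors = FALSE))
  }
  list(raw = raw[!bad, , drop = FALSE], rejected = rejected)
}

#' Read a mechanical-ventilation session log
#'
#' Reads a CSV/TSV log with one row per event (baseline, adjustment,
#' completion or abandonment) and validates it against the session schema:
#' numeric fields must parse, step indices must be strictly increasing
#' within each (subject, patient), and mode-specific settings may only be
#' present on rows of the matching ventilation mode.  Structurally invalid
#' rows are dropped (with line numbers and reasons attached as the
#' `"rejected"` attribute); rows that are merely incomplete (missing
#' values) are kept and handled later by [validate_dyads()].
#'
#' @param path path to a `vent_log.csv` / `.tsv` file.
#' @param quiet suppress the row-count message.
#' @return A data frame of accepted rows ordered by
#'   (subject_id, patient_id, step_index), with attribute `"rejected"`:
#'   a data frame of (line, reason).
#' @seealso [write_vent_log()], [validate_dyads()]
#' @export
read_vent_log <- function(path, quiet = FALSE) {
  raw <- read_log_table(path, VENT_COLUMNS, VENT_NUMERIC)
  rejected <- data.frame(line = integer(), reason = character(),
                         stringsAsFactors = FALSE)
  total <- nrow(raw)

  bad_event <- !(raw$event_type %in% c("adjust", "complete", "abandon"))
  r <- take_rejects(raw, bad_event, "unknown event_type", rejected)
  raw <- r$raw; rejected <- r$rejected

  bad_cols <- grep("^\\.bad_", names(raw), value = TRUE)
  for (bc in bad_cols) {
    field <- sub("^\\.bad_", "", bc)
    ## only physiologic/setting parse failures on adjust rows are fatal
    bad <- raw[[bc]] & raw$event_type == "adjust"
    r <- take_rejects(raw, bad, paste0("non-numeric value in '", field, "'"),
                      rejected)
    raw <- r$raw; rejected <- r$rejected
  }

  bad_mode <- raw$event_type == "adjust" & !(raw$mode %in% c("VC", "PC"))
  r <- take_rejects(raw, bad_mode, "mode must be VC or PC on adjust rows",
                    rejected)
  raw <- r$raw; rejected <- r$rejected

  ## mode-specific fields present iff mode matches
  adj <- raw$event_type == "adjust"
  vc_extra <- adj & raw$mode == "VC" &
    (!is.na(raw$pinsp) | !is.na(raw$itime))
  r <- take_rejects(raw, vc_extra, "PC-only setting present on VC row",
                    rejected)
  raw <- r$raw; rejected <- r$rejected
  adj <- raw$event_type == "adjust"
  pc_extra <- adj & raw$mode == "PC" &
    (!is.na(raw$tv) | !is.na(raw$flow) | !is.na(raw$pause))
  r <- take_rejects(raw, pc_extra, "VC-only setting present on PC row",
                    rejected)
  raw <- r$raw; rejected <- r$rejected

  bad_step <- is.na(raw$step_index) | raw$step_index < 0
  r <- take_rejects(raw, bad_step, "step_index missing or negative", rejected)
  raw <- r$raw; rejected <- r$rejected

  raw <- raw[order(raw$subject_id, raw$patient_id, raw$step_index), ,
             drop = FALSE]
  key <- paste(raw$subject_id, raw$patient_id, sep = "\r")
  dup <- unlist(tapply(raw$step_index, factor(key, unique(key)),
                       function(s) c(FALSE, diff(s) <= 0)), use.names = FALSE)
  r <- take_rejects(raw, dup, "step_index not strictly increasing", rejected)
  raw <- r$raw; rejected <- r$rejected

  keep <- intersect(c(VENT_COLUMNS, "ph_lb"), names(raw))
  out <- raw[, keep, drop = FALSE]
  rownames(out) <- NULL
  if (!quiet)
    msg(sprintf("read %d rows from %s: %d accepted, %d rejected",
                total, path, nrow(out), nrow(rejected)))
  attr(out, "rejected") <- rejected
  out
}

#' Write a mechanical-ventilation session log
#'
#' Inverse of [read_vent_log()]: writing then re-reading a valid event
#' table yields an identical table.
#'
#' @param rows data frame with the `vent_log` schema columns.
#' @param path output path; written as CSV, UTF-8.
#' @return `path`, invisibly.
#' @export
write_vent_log <- function(rows, path) {
  cols <- intersect(c(VENT_COLUMNS, "ph_lb"), names(rows))
  utils::write.csv(rows[, cols, drop = FALSE], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Read a dialysis anemia-management log
#'
#' One row per patient-month with hemoglobin (g/dL), ferritin (ng/mL),
#' iron saturation (percent), weekly ESA dose (0 = none) and iron
#' administration.  Months may be missing; gaps are reported but accepted
#' (downstream trend features use the immediately preceding available
#' month).  Rows with negative doses or non-increasing month indices are
#' rejected with reasons.
#'
#' @inheritParams read_vent_log
#' @return Data frame ordered by (patient_id, month_index) with attribute
#'   `"rejected"` as in [read_vent_log()].
#' @export
read_dialysis_log <- function(path, quiet = FALSE) {
  raw <- read_log_table(path, DIALYSIS_COLUMNS, DIALYSIS_NUMERIC)
  rejected <- data.frame(line = integer(), reason = character(),
                         stringsAsFactors = FALSE)
  total <- nrow(raw)

  for (cc in DIALYSIS_NUMERIC) {
    bad <- raw[[paste0(".bad_", cc)]]
    r <- take_rejects(raw, bad, paste0("non-numeric value in '", cc, "'"),
                      rejected)
    raw <- r$raw; rejected <- r$rejected
  }
  bad <- is.na(raw$month_index) | raw$month_index < 0
  r <- take_rejects(raw, bad, "month_index missing or negative", rejected)
  raw <- r$raw; rejected <- r$rejected
  bad <- (!is.na(raw$esa_dose) & raw$esa_dose < 0) |
    (!is.na(raw$iron_dose) & raw$iron_dose < 0)
  r <- take_rejects(raw, bad, "negative dose", rejected)
  raw <- r$raw; rejected <- r$rejected

  raw <- raw[order(raw$patient_id, raw$month_index), , drop = FALSE]
  dup <- unlist(tapply(raw$month_index,
                       factor(raw$patient_id, unique(raw$patient_id)),
                       function(s) c(FALSE, diff(s) <= 0)), use.names = FALSE)
  r <- take_rejects(raw, dup, "month_index not strictly increasing", rejected)
  raw <- r$raw; rejected <- r$rejected

  gaps <- sum(unlist(tapply(raw$month_index,
                            factor(raw$patient_id, unique(raw$patient_id)),
                            function(s) diff(s) > 1), use.names = FALSE))
  out <- raw[, DIALYSIS_COLUMNS, drop = FALSE]
  rownames(out) <- NULL
  if (!quiet) {
    msg(sprintf("read %d rows from %s: %d accepted, %d rejected",
                total, path, nrow(out), nrow(rejected)))
    if (gaps > 0)
      msg(sprintf("%d month gap(s) detected; trends will use the preceding available month", gaps))
  }
  attr(out, "rejected") <- rejected
  out
}

#' Write a dialysis anemia-management log
#'
#' @inheritParams write_vent_log
#' @return `path`, invisibly.
#' @export
write_dialysis_log <- function(rows, path) {
  utils::write.csv(rows[, DIALYSIS_COLUMNS, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Tokenize free text into a word stream
#'
#' Lower-cases the text, deletes apostrophes (so contractions stay one
#' token), replaces every other non-alphanumeric character (all Unicode
#' punctuation, dashes included) with a separator, and splits on
#' whitespace.  Tokens therefore contain only `[a-z0-9]`.
#'
#' @param raw a character scalar (or vector, concatenated in order).
#' @param source_label label carried on the output, e.g. the corpus name.
#' @return Character vector of tokens with attribute `"source_label"`.
#' @examples
#' tokenize_text("The cat, the cat.")    # "the" "cat" "the" "cat"
#' @export
tokenize_text <- function(raw, source_label = "") {
  stopifnot(is.character(raw))
  txt <- tolower(paste(raw, collapse = " "))
  txt <- gsub("['’]", "", txt)
  txt <- gsub("[^a-z0-9]+", " ", txt)
  tokens <- strsplit(trimws(txt), " +")[[1]]
  tokens <- tokens[nzchar(tokens)]
  attr(tokens, "source_label") <- source_label
  tokens
}

#' Write a rank-frequency table to TSV
#'
#' @param t a [rank_frequency()] table.
#' @param path output path (`rank_frequency.tsv` convention).
#' @return `path`, invisibly.
#' @export
write_rank_frequency <- function(t, path) {
  utils::write.table(as.data.frame(t)[, c("rank", "word", "frequency")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a table of power-law fits to TSV
#'
#' @param fits data frame with columns (group, slope, intercept, r, r2, n),
#'   e.g. the `summary` element of [fit_per_group()].
#' @param path output path (`fits.tsv` convention).
#' @return `path`, invisibly.
#' @export
write_fits <- function(fits, path) {
  utils::write.table(fits, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
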