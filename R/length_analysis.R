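#' Ventilation-mode keyboard specification
#'
#' @param mode `"VC"` (6 adjustable settings) or `"PC"` (5).
#' @return An object of class `mode_spec` with `mode`, `n_settings`,
#'   `has_bolus`.
#' @export
mode_spec <- function(mode = c("VC", "PC")) {
  mode <- match.arg(mode)
  structure(list(mode = mode, n_settings = if (mode == "VC") 6L else 5L,
                 has_bolus = TRUE),
            class = "mode_spec")
}

#' Intervention pattern length
#'
#' The number of inputs changed at one adjustment: nonzero setting-change
#' directions plus the bolus flag.  Ranges 0..7 in VC and 0..6 in PC.  A
#' mode switch counts as a single changed input (the mode) and is
#' returned as 1 with a `"switch"` attribute.
#'
#' @param i an `intervention_symbol` (MV scheme) or a canonical word /
#'   intervention string.
#' @return Integer length.
#' @seealso [intervention_pattern_lengths()] for the vectorized form.
#' @export
intervention_pattern_length <- function(i) {
  if (is.character(i)) i <- parse_word(i)$intervention
  if (inherits(i, "care_word")) i <- i$intervention
  stopifnot(inherits(i, "intervention_symbol"))
  if (!identical(i$scheme, "MV"))
    stop("intervention pattern length is defined for the MV scheme",
         call. = FALSE)
  if (grepl("^switch_to_", i$mv_mode))
    return(structure(1L, switch = TRUE))
  sum(i$mv_changes != 0L) + as.integer(i$mv_bolus != 0L)
}

#' Intervention pattern lengths of a word stream
#'
#' @param words character vector of canonical MV words.
#' @param include_switches count mode switches (as length 1)?  Default
#'   `FALSE`: a switch belongs to neither mode's keyboard and is excluded
#'   from per-mode length tables.
#' @return Integer vector (one element per non-excluded word) with
#'   attribute `"mode"` giving each word's mode.
#' @export
intervention_pattern_lengths <- function(words, include_switches = FALSE) {
  parts <- strsplit(words, "|", fixed = TRUE)
  mode_part <- vapply(parts, `[`, character(1), 3L)
  bolus <- as.integer(sub("^B", "", vapply(parts, `[`, character(1), 4L)))
  is_switch <- grepl("^SW>", mode_part)
  signs <- sub("^..:", "", mode_part)
  n_changes <- nchar(gsub("0", "", signs))
  len <- ifelse(is_switch, 1L, n_changes + (bolus != 0L))
  mode <- ifelse(is_switch, "switch", substr(mode_part, 1, 2))
  if (!include_switches) {
    len <- len[!is_switch]
    mode <- mode[!is_switch]
  }
  structure(as.integer(len), mode = mode)
}

#' Rank-frequency table of length values
#'
#' Lengths equal to 0 (nothing changed, no bolus) are dropped; the
#' remaining length values are ranked by frequency, ties going to the
#' smaller length.  The result re-uses the [rank_frequency()] container
#' with the stringified length as the word.
#'
#' @param lengths integer vector of observed lengths.
#' @return A `rank_frequency` table (possibly empty).
#' @export
length_rank_table <- function(lengths) {
  lengths <- lengths[lengths > 0]
  if (!length(lengths)) {
    out <- data.frame(rank = integer(), word = character(),
                      frequency = integer(), stringsAsFactors = FALSE)
    attr(out, "total_tokens") <- 0L
    class(out) <- c("rank_frequency", "data.frame")
    return(out)
  }
  counts <- table(lengths)
  vals <- as.integer(names(counts))
  n <- as.integer(counts)
  ord <- order(-n, vals)
  out <- data.frame(rank = seq_along(vals), word = as.character(vals[ord]),
                    frequency = n[ord], stringsAsFactors = FALSE)
  attr(out, "total_tokens") <- sum(n)
  class(out) <- c("rank_frequency", "data.frame")
  out
}

#' Solution lengths per virtual patient
#'
#' A "solution" is the sequence of interventions issued for one virtual
#' patient; its length is the number of adjustment events, and the
#' patient is completed iff a completion event exists ("non-solutions"
#' are abandoned or unfinished patients).
#'
#' @param rows vent-log data frame.
#' @param baseline_rows number of leading adjustment rows per patient to
#'   treat as baseline (not interventions).  The package's own log
#'   schema carries one baseline row per patient, so pipelines pass 1;
#'   the default 0 counts all adjustment events.
#' @return Data frame of class `solution_records`:
#'   (subject_id, patient_id, n_interventions, completed).
#' @export
solution_lengths <- function(rows, baseline_rows = 0) {
  key <- paste(rows$subject_id, rows$patient_id, sep = "\r")
  groups <- split(seq_len(nrow(rows)), factor(key, unique(key)))
  out <- lapply(groups, function(idx) {
    g <- rows[idx, , drop = FALSE]
    data.frame(subject_id = g$subject_id[1], patient_id = g$patient_id[1],
               n_interventions = max(0L, sum(g$event_type == "adjust") -
                                       as.integer(baseline_rows)),
               completed = any(g$event_type == "complete"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(res))
    res <- data.frame(subject_id = character(), patient_id = character(),
                      n_interventions = integer(), completed = logical(),
                      stringsAsFactors = FALSE)
  class(res) <- c("solution_records", "data.frame")
  res
}

#' Filter solution records for length analysis
#'
#' Keeps solutions of length >= 1 whose length value appears more than
#' once in total across records.  Idempotent.
#'
#' @param recs a [solution_lengths()] data frame.
#' @return Filtered data frame of the same shape.
#' @export
filter_solutions <- function(recs) {
  recs <- recs[recs$n_interventions >= 1, , drop = FALSE]
  counts <- table(recs$n_interventions)
  keep_vals <- as.integer(names(counts)[counts > 1])
  out <- recs[recs$n_interventions %in% keep_vals, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Effective space frequency
#'
#' The empirical probability of the "space" (completion) event in the
#' concatenated keystroke stream of interventions and completions:
#' completions / (interventions + completions).
#'
#' @param recs a [solution_lengths()] data frame.
#' @return A number in [0, 1]; 0 with a warning if nothing completed.
#' @export
effective_space_frequency <- function(recs) {
  if (!nrow(recs)) stop("no solution records", call. = FALSE)
  n_complete <- sum(recs$completed)
  denom <- sum(recs$n_interventions) + n_complete
  if (denom == 0) stop("no interventions or completions", call. = FALSE)
  if (n_complete == 0)
    warning("no completed patients; effective space frequency is 0",
            call. = FALSE)
  n_complete / denom
}

#' Enumerate the discrete intervention space
#'
#' Counts, by explicit enumeration, every distinct intervention pattern a
#' mode admits: each setting down/unchanged/up and the bolus given or
#' not, i.e. 2 * 3^n_settings patterns (the all-unchanged/no-bolus
#' pattern included), plus the mode switches.  For the standard VC (6
#' settings) and PC (5 settings) keyboards this yields
#' 1458 + 486 + 2 = 1946.
#'
#' @param specs list of [mode_spec()]s (default both modes).
#' @param n_mode_switches number of mode-change interventions (default 2).
#' @return list(per_mode = named counts, n_mode_switches, total).
#' @export
count_intervention_space <- function(specs = list(mode_spec("VC"),
                                                  mode_spec("PC")),
                                     n_mode_switches = 2L) {
  per_mode <- vapply(specs, function(sp) {
    grid <- expand.grid(c(rep(list(c(-1L, 0L, 1L)), sp$n_settings),
                          list(0:1)), KEEP.OUT.ATTRS = FALSE)
    if (anyDuplicated(grid)) stop("enumeration produced duplicates")
    nrow(grid)
  }, integer(1))
  names(per_mode) <- vapply(specs, `[[`, character(1), "mode")
  list(per_mode = per_mode, n_mode_switches = as.integer(n_mode_switches),
       total = sum(per_mode) + as.integer(n_mode_switches))
}

#' Size of a mode's conceptual keyboard
#'
#' Two change keys per setting, one bolus key, one space bar: 14 keys for
#' VC, 12 for PC.
#'
#' @param spec a [mode_spec()].
#' @return Integer key count (space bar included).
#' @export
keyboard_size <- function(spec) {
  stopifnot(inherits(spec, "mode_spec"))
  2L * spec$n_settings + 1L + 1L
}

#' Compare an observed length distribution with a null model
#'
#' Puts the observed rank-frequency table of lengths next to the
#' frequency shares a typing null model predicts: the model's length law
#' is computed analytically ([null_length_pmf()]) and its probabilities
#' sorted in decreasing order onto the same rank axis.  The total
#' variation distance is computed exactly on that axis (the observed
#' distribution is zero beyond its own support; the model's mass beyond
#' the tabulated ranks enters through its analytic tail), and the
#' largest absolute log share ratio is reported over the observed ranks.
#'
#' @param observed a non-empty `rank_frequency` table (of lengths).
#' @param spec a [null_model_spec()].
#' @param l_max largest model length tabulated (tail handled
#'   analytically).
#' @return An object of class `null_comparison`: list(table, tv,
#'   max_abs_log_diff, null_tail, spec) where `table` has one row per
#'   observed rank (rank, observed_share, null_share, log_ratio) and
#'   `null_tail` is the model mass beyond those ranks.
#' @export
observed_vs_null <- function(observed, spec, l_max = 10000) {
  if (!nrow(observed)) stop("observed table is empty", call. = FALSE)
  n <- nrow(observed)
  pmf <- null_length_pmf(spec, max(l_max, n))
  null_p <- sort(as.numeric(pmf), decreasing = TRUE)
  obs_share <- observed$frequency / sum(observed$frequency)
  head_null <- null_p[seq_len(n)]
  tv <- 0.5 * (sum(abs(obs_share - head_null)) +
                 sum(null_p[-seq_len(n)]) + attr(pmf, "tail"))
  tab <- data.frame(rank = observed$rank, observed_share = obs_share,
                    null_share = head_null,
                    log_ratio = log(obs_share) - log(head_null))
  structure(list(table = tab, tv = tv,
                 max_abs_log_diff = max(abs(tab$log_ratio)),
                 null_tail = 1 - sum(head_null), spec = spec),
            class = "null_comparison")
}

#' @export
print.null_comparison <- function(x, ...) {
  cat(sprintf("<null_comparison> vs %s (N = %g, q = %.4g): TV = %.4f, max |log ratio| = %.3f over %d ranks\n",
              x$spec$variant, x$spec$n_keys, x$spec$q_space, x$tv,
              x$max_abs_log_diff, nrow(x$table)))
  invisible(x)
}
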