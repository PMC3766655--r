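## Pipeline orchestration: read -> encode -> count -> rank -> fit, and
## the observed-versus-null length comparisons, each writing TSV tables
## plus a JSON manifest sufficient to reproduce the run.

write_manifest <- function(out_dir, inputs, config) {
  manifest <- list(
    package = "carelex",
    version = as.character(utils::packageVersion("carelex")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    inputs = inputs, config = config)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the word-usage (Zipf) pipeline
#'
#' Reads a session log (or text corpus), encodes it into words, builds
#' the population rank-frequency table, fits the Zipf-like power law,
#' and — for the ventilation scheme — fits each subject separately.
#' Writes `rank_frequency.tsv`, `fits.tsv` (population fit, per-subject
#' fits, and a mean/SD/range summary block) and `manifest.json` to
#' `out_dir`.
#'
#' @param input path to a `vent_log.csv`, `dialysis_log.csv`, or plain
#'   text file, depending on `scheme`.
#' @param scheme `"MV"`, `"HD"` or `"text"`.
#' @param out_dir output directory (created if needed); `NULL` writes
#'   nothing.
#' @param min_count smallest word frequency used in fits.
#' @param last_k if not `NULL`, keep only each subject's last `last_k`
#'   virtual patients (MV scheme).
#' @param goals goal ranges ([mv_goals()] / [hd_targets()] depending on
#'   scheme).
#' @param quiet suppress progress messages.
#' @return list(words, vocabulary, rank_table, fit, per_subject
#'   (or `NULL`), excluded), invisibly when writing.
#' @export
run_zipf_pipeline <- function(input, scheme = c("MV", "HD", "text"),
                              out_dir = NULL, min_count = 1,
                              last_k = NULL, goals = NULL, quiet = FALSE) {
  scheme <- match.arg(scheme)
  per_subject <- NULL
  excluded <- 0L
  if (scheme == "MV") {
    rows <- read_vent_log(input, quiet = quiet)
    if (!is.null(last_k)) rows <- last_k_patients(rows, last_k)
    words_df <- encode_vent_words(rows, goals = if (is.null(goals))
      mv_goals() else goals)
    excluded <- attr(words_df, "excluded")
    words <- words_df$word
    per_subject <- fit_per_group(words_df, min_count = min_count)
  } else if (scheme == "HD") {
    rows <- read_dialysis_log(input, quiet = quiet)
    words_df <- encode_dialysis_words(rows, targets = if (is.null(goals))
      hd_targets() else goals)
    words <- words_df$word
  } else {
    words <- tokenize_text(readLines(input, warn = FALSE, encoding = "UTF-8"),
                           source_label = basename(input))
  }
  if (!quiet)
    msg(sprintf("%s scheme: %d word tokens (%d dyads excluded)",
                scheme, length(words), excluded))
  vocab <- build_vocabulary(words)
  rf <- rank_frequency(vocab)
  fit <- fit_power_law(rf, min_count = min_count)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_rank_frequency(rf, file.path(out_dir, "rank_frequency.tsv"))
    fits_tab <- data.frame(group = "population", slope = fit$slope,
                           intercept = fit$intercept, r = fit$r,
                           r2 = fit$r2, n = fit$n_points,
                           stringsAsFactors = FALSE)
    if (!is.null(per_subject) && nrow(per_subject$summary)) {
      fits_tab <- rbind(fits_tab, per_subject$summary)
      st <- per_subject$stats
      fits_tab <- rbind(fits_tab, data.frame(
        group = c("mean", "sd", "min", "max"),
        slope = unname(st$slope[c("mean", "sd", "min", "max")]),
        intercept = NA, r = unname(st$r[c("mean", "sd", "min", "max")]),
        r2 = NA, n = NA, stringsAsFactors = FALSE))
    }
    write_fits(fits_tab, file.path(out_dir, "fits.tsv"))
    write_manifest(out_dir, inputs = list(input = input),
                   config = list(scheme = scheme, min_count = min_count,
                                 last_k = last_k))
  }
  res <- list(words = words, vocabulary = vocab, rank_table = rf,
              fit = fit, per_subject = per_subject, excluded = excluded)
  if (is.null(out_dir)) res else invisible(res)
}

#' Run the observed-versus-null length comparison
#'
#' From a ventilation log, computes per-mode intervention-pattern-length
#' rank tables and the solution-length rank table (solutions of length
#' >= 1 with total appearance count > 1), estimates the effective space
#' frequency, and compares the solution-length distribution against the
#' intermittent-silence model (1946-key keyboard, observed or supplied
#' q) and the random-text model (q = 1/1947).  Writes `lengths_rank.tsv`,
#' `solutions_rank.tsv`, `comparison.tsv` and `manifest.json`.
#'
#' @param input path to a vent log.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param space_q `"auto"` (use the observed effective space frequency)
#'   or a number in (0, 1).
#' @param baseline_rows leading baseline rows per patient excluded from
#'   intervention counts (the package's log schema has 1).
#' @param quiet suppress messages.
#' @return list(lengths (per-mode rank tables), solutions (records),
#'   solution_table, q_hat, comparisons (intermittent + random text),
#'   fits (observed and null log-log fits on the solution support)).
#' @export
run_null_comparison <- function(input, out_dir = NULL, space_q = "auto",
                                baseline_rows = 1, quiet = FALSE) {
  rows <- read_vent_log(input, quiet = quiet)
  words_df <- encode_vent_words(rows)
  lens <- intervention_pattern_lengths(words_df$word)
  mode <- attr(lens, "mode")
  length_tables <- list(VC = length_rank_table(lens[mode == "VC"]),
                        PC = length_rank_table(lens[mode == "PC"]))

  recs <- solution_lengths(rows, baseline_rows = baseline_rows)
  kept <- filter_solutions(recs)
  q_hat <- effective_space_frequency(recs)
  q_used <- if (identical(space_q, "auto")) q_hat else as.numeric(space_q)
  sol_table <- length_rank_table(kept$n_interventions)

  n_keys <- count_intervention_space()$total
  silence <- null_model_spec(n_keys, q_used)
  random <- random_text_spec(n_keys)
  comparisons <- list(
    intermittent_silence = observed_vs_null(sol_table, silence),
    random_text = observed_vs_null(sol_table, random))

  obs_fit <- fit_power_law(sol_table)
  null_fit <- null_share_fit(silence, nrow(sol_table))
  if (!quiet)
    msg(sprintf("q_hat = %.4f; observed slope %.3f vs intermittent-silence slope %.3f on %d ranks",
                q_hat, obs_fit$slope, null_fit$slope, nrow(sol_table)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    lt <- rbind(cbind(mode = "VC", as.data.frame(length_tables$VC)),
                cbind(mode = "PC", as.data.frame(length_tables$PC)))
    utils::write.table(lt, file.path(out_dir, "lengths_rank.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_rank_frequency(sol_table, file.path(out_dir,
                                              "solutions_rank.tsv"))
    comp <- rbind(
      cbind(model = "intermittent_silence",
            comparisons$intermittent_silence$table),
      cbind(model = "random_text", comparisons$random_text$table))
    utils::write.table(comp, file.path(out_dir, "comparison.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_manifest(out_dir, inputs = list(input = input),
                   config = list(space_q = space_q, q_hat = q_hat,
                                 n_keys = n_keys,
                                 baseline_rows = baseline_rows))
  }
  res <- list(lengths = length_tables, solutions = recs,
              solution_table = sol_table, q_hat = q_hat,
              comparisons = comparisons,
              fits = list(observed = obs_fit, null = null_fit))
  if (is.null(out_dir)) res else invisible(res)
}

## Log-log OLS fit of a null model's length-share curve on a finite rank
## support: model length probabilities sorted descending, truncated to
## n ranks, renormalized — the null-side counterpart of fitting the
## observed solution-length rank table.
null_share_fit <- function(spec, n_ranks, l_max = 10000) {
  pmf <- null_length_pmf(spec, max(l_max, n_ranks))
  p <- sort(as.numeric(pmf), decreasing = TRUE)[seq_len(n_ranks)]
  p <- p / sum(p)
  lnr <- log(seq_len(n_ranks)); lnp <- log(p)
  fit <- stats::lm.fit(cbind(1, lnr), lnp)
  structure(
    list(slope = unname(fit$coefficients[2]),
         intercept = unname(fit$coefficients[1]),
         r = stats::cor(lnr, lnp), r2 = stats::cor(lnr, lnp)^2,
         n_points = n_ranks, degenerate = FALSE,
         exponent = -unname(fit$coefficients[2]),
         beta = exp(unname(fit$coefficients[1])), min_count = 0,
         data = data.frame(rank = seq_len(n_ranks), frequency = p,
                           lnr = lnr, lnf = lnp)),
    class = "zipf_fit")
}
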