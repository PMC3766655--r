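#' Specify an intermittent-silence or random-text null model
#'
#' The generating picture is a typist striking keys uniformly at random:
#' `n_keys` non-space keys plus a space key hit with probability
#' `q_space`; the space terminates a word.  The `"random_text"` variant
#' is the special case where the space bar is just another key, so
#' `q_space = 1/(n_keys + 1)`.
#'
#' @param n_keys number of non-space keys (N >= 1; N >= 2 for
#'   rank-frequency asymptotics).
#' @param q_space probability of striking the space key, in (0, 1).
#' @param variant `"intermittent_silence"` or `"random_text"`.
#' @return An object of class `null_model_spec`.
#' @seealso [random_text_spec()], [null_length_pmf()],
#'   [null_rank_blocks()], [null_asymptotic_slope()], [simulate_monkey()]
#' @export
null_model_spec <- function(n_keys, q_space,
                            variant = c("intermittent_silence",
                                        "random_text")) {
  variant <- match.arg(variant)
  n_keys <- as.numeric(n_keys)
  if (n_keys < 1 || n_keys != round(n_keys))
    stop("n_keys must be a positive integer", call. = FALSE)
  if (!is.finite(q_space) || q_space <= 0 || q_space >= 1)
    stop("q_space must lie in (0, 1)", call. = FALSE)
  if (variant == "random_text" &&
      abs(q_space - 1 / (n_keys + 1)) > 1e-12)
    stop("random_text requires q_space = 1/(n_keys + 1)", call. = FALSE)
  structure(list(n_keys = n_keys, q_space = q_space, variant = variant),
            class = "null_model_spec")
}

#' @export
print.null_model_spec <- function(x, ...) {
  cat(sprintf("<null_model_spec> %s: N = %g keys, q = %.6g\n",
              x$variant, x$n_keys, x$q_space))
  invisible(x)
}

#' Random-text null model for a given keyboard
#'
#' All keys including the space bar equiprobable:
#' `q_space = 1/(n_keys + 1)`.  With the 1946-intervention keyboard this
#' gives q = 1/1947, approximately 5.1e-4.
#'
#' @param n_keys number of non-space keys.
#' @return A `null_model_spec` with `variant = "random_text"`.
#' @export
random_text_spec <- function(n_keys) {
  null_model_spec(n_keys, 1 / (n_keys + 1), "random_text")
}

#' Word-length distribution under a null model
#'
#' Keystroke word length is geometric: unconditionally
#' \eqn{P(L) = q (1-q)^L} for \eqn{L \ge 0}.  Zero-length words
#' (consecutive spaces) are excluded and the law renormalized, giving
#' \eqn{P(L \mid L \ge 1) = q (1-q)^{L-1}}.
#'
#' @param spec a [null_model_spec()].
#' @param l_max largest length tabulated (>= 1).
#' @param conditional if `FALSE`, return the unconditioned law over
#'   lengths 0..`l_max` instead.
#' @return Named numeric vector of probabilities with attribute
#'   `"tail"` = analytic mass beyond `l_max`.
#' @export
null_length_pmf <- function(spec, l_max, conditional = TRUE) {
  stopifnot(inherits(spec, "null_model_spec"), l_max >= 1)
  q <- spec$q_space
  if (conditional) {
    L <- seq_len(l_max)
    p <- q * (1 - q)^(L - 1)
    tail <- (1 - q)^l_max
  } else {
    L <- 0:l_max
    p <- q * (1 - q)^L
    tail <- (1 - q)^(l_max + 1)
  }
  structure(stats::setNames(p, L), tail = tail)
}

#' Blockwise rank-frequency table of a null model
#'
#' All \eqn{N^L} words of length L are equiprobable with probability
#' \eqn{q ((1-q)/N)^L}, so the rank-frequency curve is a staircase:
#' ranks are assigned blockwise by length, shorter (more probable) blocks
#' first.  Only block boundaries are stored; the table is never expanded
#' word by word, so huge alphabets (N = 1946) are handled exactly.
#'
#' @param spec a [null_model_spec()].
#' @param l_max number of length blocks to tabulate.  Rank bounds must
#'   stay exactly representable (below 2^53), otherwise a capacity error
#'   is raised.
#' @return A data frame of class `block_rank_table` with columns
#'   (length, rank_start, rank_end, word_probability).
#' @export
null_rank_blocks <- function(spec, l_max) {
  stopifnot(inherits(spec, "null_model_spec"), l_max >= 1)
  N <- spec$n_keys; q <- spec$q_space
  sizes <- N^seq_len(l_max)
  ends <- cumsum(sizes)
  if (any(!is.finite(ends)) || max(ends) >= 2^53)
    stop("capacity error: rank bounds exceed exact integer range; ",
         "reduce l_max", call. = FALSE)
  out <- data.frame(
    length = seq_len(l_max),
    rank_start = c(1, utils::head(ends, -1) + 1),
    rank_end = ends,
    word_probability = q * ((1 - q) / N)^seq_len(l_max))
  class(out) <- c("block_rank_table", "data.frame")
  out
}

#' Asymptotic log-log slope of a null model's rank-frequency curve
#'
#' In the large-rank limit the staircase rank-frequency curve of the
#' typing model has log-log slope \eqn{\ln(1-q)/\ln N - 1}.  For the
#' random-text variant (q = 1/(N+1)) this reduces to
#' \eqn{-\ln(N+1)/\ln N}; as q tends to 0 the slope tends to -1
#' (Zipf's law).
#'
#' @param spec a [null_model_spec()].
#' @return The slope (a negative real).
#' @export
null_asymptotic_slope <- function(spec) {
  stopifnot(inherits(spec, "null_model_spec"))
  if (spec$n_keys < 2)
    stop("asymptotic slope undefined for a degenerate 1-key alphabet",
         call. = FALSE)
  log(1 - spec$q_space) / log(spec$n_keys) - 1
}

#' Fit the staircase rank-frequency curve of a null model
#'
#' OLS of log word probability on log rank over log-spaced sample ranks
#' of the exact block table — the numerical counterpart of
#' [null_asymptotic_slope()].
#'
#' @param blocks a [null_rank_blocks()] table (or a spec, tabulated at
#'   `l_max`).
#' @param n_points number of log-spaced sample ranks.
#' @param l_max used when `blocks` is a spec.
#' @return A `zipf_fit` (frequencies are probabilities, not counts).
#' @export
fit_null_blocks <- function(blocks, n_points = 400, l_max = 12) {
  if (inherits(blocks, "null_model_spec"))
    blocks <- null_rank_blocks(blocks, l_max)
  rmax <- max(blocks$rank_end)
  ranks <- unique(floor(exp(seq(0, log(rmax), length.out = n_points))))
  bi <- findInterval(ranks, blocks$rank_start)
  p <- blocks$word_probability[bi]
  lnr <- log(ranks); lnp <- log(p)
  fit <- stats::lm.fit(cbind(1, lnr), lnp)
  structure(
    list(slope = unname(fit$coefficients[2]),
         intercept = unname(fit$coefficients[1]),
         r = stats::cor(lnr, lnp), r2 = stats::cor(lnr, lnp)^2,
         n_points = length(ranks), degenerate = FALSE,
         exponent = -unname(fit$coefficients[2]),
         beta = exp(unname(fit$coefficients[1])), min_count = 0,
         data = data.frame(rank = ranks, frequency = p, lnr = lnr,
                           lnf = lnp)),
    class = "zipf_fit")
}

#' Simulate the typing null model
#'
#' Draws word lengths from a seeded typist.  With
#' `length_metric = "keystrokes"` the length is the number of non-space
#' keystrokes before a space (by default conditioned on >= 1, matching
#' [null_length_pmf()]).  With `"distinct_inputs"` actual key sequences
#' are drawn and the length is the number of distinct mapped inputs
#' touched — e.g. the 12 volume-controlled setting-change keys map onto 6
#' settings and the bolus key onto a 7th input, capping lengths at 7.
#'
#' @param spec a [null_model_spec()].
#' @param n_words number of words to draw.
#' @param seed integer seed (reproducible; global RNG state untouched).
#' @param length_metric `"keystrokes"` or `"distinct_inputs"`.
#' @param input_map integer vector of length `n_keys` mapping each key to
#'   an input id; required for `"distinct_inputs"` (see [mv_input_map()]).
#' @param include_empty if `TRUE`, keep zero-length words (unconditioned
#'   geometric lengths).
#' @return Integer vector of word lengths.
#' @export
simulate_monkey <- function(spec, n_words, seed,
                            length_metric = c("keystrokes",
                                              "distinct_inputs"),
                            input_map = NULL, include_empty = FALSE) {
  stopifnot(inherits(spec, "null_model_spec"), n_words >= 1)
  length_metric <- match.arg(length_metric)
  q <- spec$q_space
  with_seed(seed, {
    lens <- stats::rgeom(n_words, q)
    if (!include_empty) lens <- lens + 1L
    if (length_metric == "keystrokes") return(as.integer(lens))
    if (is.null(input_map))
      stop("length_metric = 'distinct_inputs' requires an input_map",
           call. = FALSE)
    if (length(input_map) != spec$n_keys)
      stop("input_map must have one entry per non-space key",
           call. = FALSE)
    keys <- sample.int(spec$n_keys, sum(lens), replace = TRUE)
    word_id <- rep.int(seq_along(lens), lens)
    inputs <- input_map[keys]
    distinct <- integer(n_words)
    counted <- vapply(split(inputs, word_id),
                      function(x) length(unique(x)), integer(1))
    distinct[as.integer(names(counted))] <- counted
    as.integer(distinct)
  })
}

#' Key-to-input map for a ventilation-mode keyboard
#'
#' The conceptual keyboard for a mode has two change keys (up/down) per
#' setting plus one fluid-bolus key (space bar excluded).  Both keys of
#' a setting map to the same input, the bolus key to its own input, so
#' distinct-input word lengths cap at `n_settings + 1` (7 for VC, 6 for
#' PC).
#'
#' @param mode `"VC"` or `"PC"`.
#' @return Integer vector over the mode's non-space keys (13 for VC, 11
#'   for PC).
#' @export
mv_input_map <- function(mode = c("VC", "PC")) {
  mode <- match.arg(mode)
  n_settings <- if (mode == "VC") 6L else 5L
  c(rep(seq_len(n_settings), each = 2L), n_settings + 1L)
}
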