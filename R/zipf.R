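#' Rank-frequency table of a vocabulary
#'
#' Orders word counts so that \eqn{f_1 \ge f_2 \ge \dots \ge f_N} and
#' assigns ordinal ranks \eqn{r_i = i}.  Ties are broken by lexicographic
#' order of the word, making the table deterministic.
#'
#' @param v a [build_vocabulary()] result, a named count vector/table, or
#'   a character vector of tokens (counted first).
#' @return A data frame of class `rank_frequency` with columns
#'   (rank, word, frequency) and attribute `total_tokens`.
#' @examples
#' rank_frequency(c(a = 5, b = 3, c = 3, d = 1))
#' @export
rank_frequency <- function(v) {
  counts <- if (inherits(v, "vocabulary_counts")) v$counts
  else if (is.table(v)) stats::setNames(as.integer(v), names(v))
  else if (is.character(v)) build_vocabulary(v)$counts
  else if (!is.null(names(v))) stats::setNames(as.integer(v), names(v))
  else stop("cannot interpret 'v' as a vocabulary", call. = FALSE)
  if (!length(counts)) {
    out <- data.frame(rank = integer(), word = character(),
                      frequency = integer(), stringsAsFactors = FALSE)
  } else {
    if (any(counts < 1)) stop("counts must be positive", call. = FALSE)
    ord <- order(-counts, names(counts))
    out <- data.frame(rank = seq_along(counts), word = names(counts)[ord],
                      frequency = as.integer(counts[ord]),
                      stringsAsFactors = FALSE)
  }
  attr(out, "total_tokens") <- sum(out$frequency)
  class(out) <- c("rank_frequency", "data.frame")
  out
}

#' Fit a Zipf-like power law to a rank-frequency table
#'
#' Ordinary least squares of \eqn{\ln f_i} on \eqn{\ln r_i} (natural
#' logarithms), estimating the Zipf-like law
#' \eqn{f_i = \beta r_i^{-a}}: the slope estimates \eqn{-a} and the
#' intercept \eqn{\ln \beta}.  `min_count` restricts the fit to rows with
#' at least that frequency, since the singleton tail of a finite sample
#' flattens the empirical curve.
#'
#' If all qualifying frequencies are equal the regression is degenerate
#' (zero variance in the response); the fit is returned with slope 0,
#' r = 0 and `degenerate = TRUE` rather than an error.
#'
#' @param t a [rank_frequency()] table (or any data frame with `rank` and
#'   `frequency` columns; a named count vector is also accepted and ranked
#'   first).
#' @param min_count smallest frequency included in the fit (default 1 =
#'   all observed ranks).
#' @return An object of class `zipf_fit` with elements `slope`,
#'   `intercept`, `r` (Pearson correlation of the log-log points), `r2`,
#'   `n_points`, `degenerate`, `exponent` (= -slope), `beta`
#'   (= exp(intercept)) and the fitted points in `data`.
#' @seealso [fit_per_group()], [rank_frequency()]
#' @examples
#' rf <- rank_frequency(gen_zipf_tokens(100, 0.9, 5000, seed = 1))
#' fit <- fit_power_law(rf, min_count = 2)
#' coef(fit)
#' @export
fit_power_law <- function(t, min_count = 1) {
  if (!is.data.frame(t)) t <- rank_frequency(t)
  keep <- t$frequency >= min_count
  d <- t[keep, , drop = FALSE]
  if (nrow(d) < 2)
    stop("fit error: fewer than 2 ranks with frequency >= ", min_count,
         call. = FALSE)
  lnr <- log(d$rank)
  lnf <- log(d$frequency)
  degenerate <- stats::var(lnf) == 0
  if (degenerate) {
    slope <- 0; intercept <- mean(lnf); r <- 0
  } else {
    fit <- stats::lm.fit(cbind(1, lnr), lnf)
    intercept <- unname(fit$coefficients[1])
    slope <- unname(fit$coefficients[2])
    r <- stats::cor(lnr, lnf)
  }
  structure(
    list(slope = slope, intercept = intercept, r = r, r2 = r^2,
         n_points = nrow(d), degenerate = degenerate,
         exponent = -slope, beta = exp(intercept), min_count = min_count,
         data = data.frame(rank = d$rank, frequency = d$frequency,
                           lnr = lnr, lnf = lnf)),
    class = "zipf_fit")
}

#' @export
print.zipf_fit <- function(x, digits = 4, ...) {
  cat("Zipf-like power-law fit (OLS of ln f on ln r)\n")
  cat(sprintf("  slope: %.*f   intercept (ln beta): %.*f\n",
              digits, x$slope, digits, x$intercept))
  cat(sprintf("  r: %.*f   R-squared: %.*f   points: %d%s\n",
              digits, x$r, digits, x$r2, x$n_points,
              if (x$degenerate) "   [degenerate: constant frequencies]"
              else ""))
  invisible(x)
}

#' @export
summary.zipf_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.zipf_fit")
}

#' @export
print.summary.zipf_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  exponent a: %.4f   beta: %.4g\n", f$exponent, f$beta))
  cat(sprintf("  fitted law: f(r) = %.4g * r^%.4f\n", f$beta, f$slope))
  rng <- range(f$data$frequency)
  cat(sprintf("  frequency range: %d..%d over ranks 1..%d (min_count = %d)\n",
              rng[1], rng[2], max(f$data$rank), f$min_count))
  invisible(x)
}

#' @export
coef.zipf_fit <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept)
}

#' @rdname fit_power_law
#' @param object,x a `zipf_fit`.
#' @param newdata optional data frame with a `rank` column (or a numeric
#'   rank vector) at which to predict frequencies.
#' @param ... unused.
#' @export
predict.zipf_fit <- function(object, newdata = NULL, ...) {
  ranks <- if (is.null(newdata)) object$data$rank
  else if (is.data.frame(newdata)) newdata$rank
  else as.numeric(newdata)
  object$beta * ranks^object$slope
}

#' @export
residuals.zipf_fit <- function(object, ...) {
  object$data$lnf - (object$intercept + object$slope * object$data$lnr)
}

#' @rdname fit_power_law
#' @param nsim,seed as in [stats::simulate()]: draws `nsim` token streams
#'   of `n_tokens` tokens from the fitted law over the fitted ranks.
#' @param n_tokens tokens per simulated stream.
#' @export
simulate.zipf_fit <- function(object, nsim = 1, seed = NULL,
                              n_tokens = sum(object$data$frequency), ...) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  ranks <- object$data$rank
  p <- ranks^object$slope
  with_seed(seed, replicate(nsim, sample(paste0("r", ranks), n_tokens,
                                         replace = TRUE, prob = p),
                            simplify = FALSE))
}

#' @export
plot.zipf_fit <- function(x, main = "Rank-frequency (log-log)", ...) {
  plot(x$data$lnr, x$data$lnf, xlab = "ln rank", ylab = "ln frequency",
       main = main, ...)
  graphics::abline(x$intercept, x$slope, col = "red3")
  invisible(x)
}

#' Per-group power-law fits
#'
#' Builds an independent rank-frequency table and power-law fit for each
#' group (e.g. each subject), plus summary statistics of the slopes and
#' correlations across groups.  Groups that cannot be fitted (fewer than
#' two qualifying ranks) are excluded and listed with reasons.
#'
#' @param words data frame with a grouping column and a `word` column, or
#'   a list of token vectors named by group.
#' @param min_count as in [fit_power_law()].
#' @param group name of the grouping column (default `"subject_id"`).
#' @return An object of class `zipf_fit_group`: list(fits, summary,
#'   excluded, stats) where `summary` has one row per group
#'   (group, slope, intercept, r, r2, n) and `stats` holds mean/SD/range
#'   of slope and r across groups.
#' @export
fit_per_group <- function(words, min_count = 1, group = "subject_id") {
  streams <- if (is.data.frame(words))
    split(as.character(words$word), factor(words[[group]],
                                           unique(words[[group]])))
  else words
  fits <- list()
  excluded <- character()
  for (g in names(streams)) {
    w <- streams[[g]]
    if (length(unique(w)) < 2) {
      excluded[g] <- "fewer than 2 distinct words"
      next
    }
    rf <- rank_frequency(build_vocabulary(w))
    f <- tryCatch(fit_power_law(rf, min_count = min_count),
                  error = function(e) conditionMessage(e))
    if (is.character(f)) excluded[g] <- f else fits[[g]] <- f
  }
  summ <- if (length(fits)) data.frame(
    group = names(fits),
    slope = vapply(fits, `[[`, numeric(1), "slope"),
    intercept = vapply(fits, `[[`, numeric(1), "intercept"),
    r = vapply(fits, `[[`, numeric(1), "r"),
    r2 = vapply(fits, `[[`, numeric(1), "r2"),
    n = vapply(fits, `[[`, integer(1), "n_points"),
    stringsAsFactors = FALSE, row.names = NULL)
  else data.frame(group = character(), slope = numeric(),
                  intercept = numeric(), r = numeric(), r2 = numeric(),
                  n = integer(), stringsAsFactors = FALSE)
  stats_block <- list(
    slope = c(mean = mean(summ$slope), sd = stats::sd(summ$slope),
              min = suppressWarnings(min(summ$slope)),
              max = suppressWarnings(max(summ$slope))),
    r = c(mean = mean(summ$r), sd = stats::sd(summ$r),
          min = suppressWarnings(min(summ$r)),
          max = suppressWarnings(max(summ$r))))
  structure(list(fits = fits, summary = summ, excluded = excluded,
                 stats = stats_block),
            class = "zipf_fit_group")
}

#' @export
print.zipf_fit_group <- function(x, ...) {
  cat("Per-group Zipf fits:", length(x$fits), "groups fitted",
      if (length(x$excluded)) paste0("(", length(x$excluded), " excluded)")
      else "", "\n")
  if (nrow(x$summary)) {
    s <- x$stats
    cat(sprintf("  slope: mean %.3f, SD %.3f, range [%.3f, %.3f]\n",
                s$slope["mean"], s$slope["sd"], s$slope["min"],
                s$slope["max"]))
    cat(sprintf("  r:     mean %.3f, SD %.3f, range [%.3f, %.3f]\n",
                s$r["mean"], s$r["sd"], s$r["min"], s$r["max"]))
  }
  invisible(x)
}
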