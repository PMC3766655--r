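## Seeded synthetic-data generators.  These emulate the statistical
## structure the analysis assumes — heavy-tailed practitioner policies,
## per-patient completion events, goal-classified physiology — not the
## underlying physiology itself.  All generators are pure functions of
## (config, seed): randomness is drawn under with_seed() and the global
## RNG state is left untouched.

#' Sample tokens from a ground-truth Zipf source
#'
#' i.i.d. tokens with \eqn{P(\mathrm{rank}\ i) \propto i^{-a}} over a
#' vocabulary of `v` types — the reference source for fit-recovery
#' tests.
#'
#' @param v vocabulary size (>= 2).
#' @param a Zipf exponent (>= 0; 0 gives the uniform source).
#' @param n number of tokens.
#' @param seed integer seed.
#' @return Character vector of `n` tokens ("w00001" is rank 1).
#' @export
gen_zipf_tokens <- function(v, a, n, seed) {
  if (v < 2 || a < 0 || n < 1)
    stop("need v >= 2, a >= 0, n >= 1", call. = FALSE)
  p <- seq_len(v)^(-a)
  with_seed(seed,
            sample(sprintf("w%05d", seq_len(v)), n, replace = TRUE,
                   prob = p))
}

#' Generate words from the typing null model
#'
#' Draws whole words (strings over an `n_keys`-letter alphabet) whose
#' lengths follow the geometric law of the model, conditioned on length
#' >= 1.  Feeds both whole-word rank-frequency analysis and null-model
#' validation.
#'
#' @param spec a [null_model_spec()] with `n_keys` at most 62 (letters,
#'   capitals, digits).
#' @param n_words number of words.
#' @param seed integer seed.
#' @return Character vector of words.
#' @export
gen_monkey_text <- function(spec, n_words, seed) {
  stopifnot(inherits(spec, "null_model_spec"))
  alphabet <- c(letters, LETTERS, 0:9)
  if (spec$n_keys > length(alphabet))
    stop("gen_monkey_text supports at most 62 keys; use simulate_monkey ",
         "for larger alphabets", call. = FALSE)
  with_seed(seed, {
    lens <- stats::rgeom(n_words, spec$q_space) + 1L
    keys <- sample(alphabet[seq_len(spec$n_keys)], sum(lens),
                   replace = TRUE)
    wid <- factor(rep.int(seq_along(lens), lens),
                  levels = seq_along(lens))
    unname(vapply(split(keys, wid), paste, character(1), collapse = ""))
  })
}

## --- mechanical-ventilation session generator ------------------------

## Feasible MV derangement codes: one-sided goals never emit their
## unbounded side, so spo2 in {below, within}, ph in all three,
## map in {below, within}, pplat in {within, above}: 24 symbols.
mv_feasible_derangements <- function() {
  g <- expand.grid(spo2 = 0:1, ph = 0:2, map = 0:1, pplat = 1:2,
                   KEEP.OUT.ATTRS = FALSE)
  as.matrix(g)
}

## Intervention alphabet of a mode: every direction tuple x bolus flag,
## in a fixed enumeration order (2 * 3^n_settings items).
mv_alphabet <- function(mode) {
  s <- if (mode == "VC") length(VC_SETTINGS) else length(PC_SETTINGS)
  grid <- expand.grid(c(rep(list(c(-1L, 0L, 1L)), s), list(0:1)),
                      KEEP.OUT.ATTRS = FALSE)
  names(grid) <- c(if (mode == "VC") VC_SETTINGS else PC_SETTINGS, "bolus")
  as.matrix(grid)
}

#' Configuration for the ventilation session generator
#'
#' Defaults mirror the study conditions the analysis targets: 29
#' subjects each managing 100 virtual patients (analyses typically keep
#' the last 25 per subject), a Zipf policy exponent of 0.95, and a
#' per-step completion probability of 0.2 (hence geometric solution
#' lengths with mean 4 and an effective space frequency of 0.2).
#'
#' The practitioner policy is conditional-Zipf over habitual
#' repertoires: for each (derangement symbol, ventilation mode) there is
#' a shared preference ordering over `repertoire_size` recurring
#' intervention patterns, used with probability proportional to
#' preference-rank^(-`policy_exponent`).  Population word frequencies
#' are then a Zipf mixture concentrated on few recurring words, as
#' observed practice is.
#'
#' @param n_subjects number of subjects (virtual practitioners).
#' @param n_patients_per_subject virtual patients per subject.
#' @param policy_exponent Zipf exponent of the intervention policy (> 0).
#' @param p_complete_per_step per-intervention completion probability.
#' @param derangement_mix probability vector over the 24 feasible
#'   derangement symbols (rows of `mv_feasible_derangements()`);
#'   default weights each symbol by 0.5^(number of deranged variables).
#' @param repertoire_size number of habitual intervention patterns per
#'   (derangement symbol, mode) in the shared policy repertoire.
#' @param pc_fraction fraction of patients managed in pressure-controlled
#'   mode (the rest are volume-controlled; patients do not switch).
#' @param solution_model `"geometric"` (Bernoulli completion per step) or
#'   `"powerlaw"` (solution length drawn from a discrete power law with
#'   exponent `solution_exponent` — a completion hazard decaying with
#'   step, for goal-directed demonstrations).
#' @param solution_exponent exponent of the power-law solution-length
#'   option.
#' @param max_steps cap on interventions per patient; a patient still
#'   open at the cap is abandoned (a "non-solution").
#' @param seed integer seed.
#' @return A `vent_sim_config` list.
#' @export
vent_sim_config <- function(n_subjects = 29, n_patients_per_subject = 100,
                            policy_exponent = 0.95,
                            p_complete_per_step = 0.2,
                            derangement_mix = NULL, repertoire_size = 12,
                            pc_fraction = 0.25,
                            solution_model = c("geometric", "powerlaw"),
                            solution_exponent = 2, max_steps = 60,
                            seed = 1) {
  solution_model <- match.arg(solution_model)
  stopifnot(n_subjects >= 1, n_patients_per_subject >= 1,
            policy_exponent > 0, p_complete_per_step > 0,
            p_complete_per_step < 1, pc_fraction >= 0, pc_fraction <= 1,
            repertoire_size >= 2)
  n_sym <- nrow(mv_feasible_derangements())
  if (is.null(derangement_mix)) {
    deranged <- rowSums(cbind(mv_feasible_derangements()[, "spo2"] != 1,
                              mv_feasible_derangements()[, "ph"] != 1,
                              mv_feasible_derangements()[, "map"] != 1,
                              mv_feasible_derangements()[, "pplat"] != 1))
    derangement_mix <- 0.5^deranged
    derangement_mix <- derangement_mix / sum(derangement_mix)
  }
  if (length(derangement_mix) != n_sym || any(derangement_mix < 0))
    stop("derangement_mix must be a probability vector over the ", n_sym,
         " feasible derangement symbols", call. = FALSE)
  structure(list(n_subjects = n_subjects,
                 n_patients_per_subject = n_patients_per_subject,
                 policy_exponent = policy_exponent,
                 p_complete_per_step = p_complete_per_step,
                 derangement_mix = derangement_mix / sum(derangement_mix),
                 repertoire_size = repertoire_size,
                 pc_fraction = pc_fraction,
                 solution_model = solution_model,
                 solution_exponent = solution_exponent,
                 max_steps = max_steps, seed = seed),
            class = "vent_sim_config")
}

## Draw physiologic values consistent with given derangement codes.
## Margins keep values clear of the strict goal boundaries so encoding
## reproduces the intended codes exactly.
draw_physio <- function(codes) {
  n <- nrow(codes)
  spo2 <- ifelse(codes[, "spo2"] == 0, stats::runif(n, 80, 89.5),
                 stats::runif(n, 90.5, 99.5))
  ph <- c(7.10, 7.305, 7.455)[codes[, "ph"] + 1L] +
    stats::runif(n, 0.005, c(0.19, 0.135, 0.14)[codes[, "ph"] + 1L])
  map <- ifelse(codes[, "map"] == 0, stats::runif(n, 45, 64.5),
                stats::runif(n, 65.5, 95))
  pplat <- ifelse(codes[, "pplat"] == 1, stats::runif(n, 15, 29.5),
                  stats::runif(n, 30.5, 45))
  data.frame(spo2 = spo2, ph = ph, map = map, pplat = pplat)
}

## Apply one intervention's direction tuple to a settings vector.
## Multiplicative steps keep every setting positive and strictly
## monotone in the commanded direction; FiO2 contracts toward (0.21, 1)
## so it never leaves its physical range and never saturates.
apply_changes <- function(settings, dirs) {
  for (s in names(dirs)) {
    d <- dirs[[s]]
    if (d == 0L) next
    v <- settings[[s]]
    if (s == "fio2") {
      settings[[s]] <- if (d > 0) v + 0.15 * (0.995 - v)
      else v - 0.15 * (v - 0.215)
    } else {
      settings[[s]] <- if (d > 0) v * 1.12 else v / 1.12
    }
  }
  settings
}

#' Generate synthetic mechanical-ventilation sessions
#'
#' Emulates multi-subject simulator sessions: per virtual patient, a
#' baseline row, a sequence of adjustment rows, and a terminal
#' completion (or abandonment) row.  At each step a derangement symbol
#' is drawn from `derangement_mix` (physiologic values are then drawn
#' consistently with it) and the intervention pattern is drawn from the
#' conditional-Zipf policy over that symbol's habitual repertoire (see
#' [vent_sim_config()]).  Emitted setting values are consistent with
#' the drawn change directions, so encoding the output recovers the
#' generated words exactly.
#'
#' @param cfg a [vent_sim_config()].
#' @return A schema-valid vent-log data frame (see [read_vent_log()]).
#' @export
gen_vent_sessions <- function(cfg) {
  stopifnot(inherits(cfg, "vent_sim_config"))
  dmat <- mv_feasible_derangements()
  n_sym <- nrow(dmat)
  alpha <- list(VC = mv_alphabet("VC"), PC = mv_alphabet("PC"))

  with_seed(cfg$seed, {
    ## Habitual repertoires: per (mode, derangement symbol), a seeded
    ## preference order over repertoire_size distinct intervention
    ## patterns from the mode's alphabet, shared by all subjects.  The
    ## conditional policy is exactly Zipf(policy_exponent) over each
    ## repertoire.
    K <- cfg$repertoire_size
    pref <- list(
      VC = lapply(seq_len(n_sym), function(i)
        sample.int(nrow(alpha$VC), K)),
      PC = lapply(seq_len(n_sym), function(i)
        sample.int(nrow(alpha$PC), K)))
    cond_p <- seq_len(K)^(-cfg$policy_exponent)

    rows <- list()
    for (s in seq_len(cfg$n_subjects)) {
      sid <- sprintf("S%02d", s)
      for (p in seq_len(cfg$n_patients_per_subject)) {
        pid <- sprintf("P%03d", p)
        mode <- if (stats::runif(1) < cfg$pc_fraction) "PC" else "VC"
        if (cfg$solution_model == "geometric") {
          g <- stats::rgeom(1, cfg$p_complete_per_step)
          abandoned <- g > cfg$max_steps
          g <- min(g, cfg$max_steps)
        } else {
          lp <- seq_len(cfg$max_steps)^(-cfg$solution_exponent)
          g <- sample.int(cfg$max_steps, 1, prob = lp)
          abandoned <- FALSE
        }
        d_idx <- sample.int(n_sym, g + 1L, replace = TRUE,
                            prob = cfg$derangement_mix)
        physio <- draw_physio(dmat[d_idx, , drop = FALSE])
        item <- if (g > 0) {
          j <- sample.int(K, g, replace = TRUE, prob = cond_p)
          vapply(seq_len(g),
                 function(s2) pref[[mode]][[d_idx[s2 + 1L]]][j[s2]],
                 integer(1))
        } else integer(0)

        settings <- if (mode == "VC")
          list(tv = 500, flow = 60, pause = 0.2, fio2 = 0.5, peep = 5,
               rate = 15)
        else
          list(pinsp = 20, itime = 1.0, fio2 = 0.5, peep = 5, rate = 15)
        set_names <- names(settings)
        n_steps <- g + 1L
        smat <- matrix(NA_real_, n_steps, length(set_names),
                       dimnames = list(NULL, set_names))
        bolus <- integer(n_steps)
        smat[1L, ] <- unlist(settings)
        if (g > 0) for (j in seq_len(g)) {
          a_row <- alpha[[mode]][item[j], ]
          dirs <- a_row[set_names]
          settings <- apply_changes(settings, dirs)
          smat[j + 1L, ] <- unlist(settings)
          bolus[j + 1L] <- unname(a_row["bolus"])
        }

        base <- data.frame(
          subject_id = sid, patient_id = pid,
          step_index = 0:g,
          event_type = "adjust",
          spo2 = physio$spo2, ph = physio$ph, map = physio$map,
          pplat = physio$pplat, mode = mode,
          fio2 = smat[, "fio2"], peep = smat[, "peep"],
          rate = smat[, "rate"],
          tv = if (mode == "VC") smat[, "tv"] else NA_real_,
          flow = if (mode == "VC") smat[, "flow"] else NA_real_,
          pause = if (mode == "VC") smat[, "pause"] else NA_real_,
          pinsp = if (mode == "PC") smat[, "pinsp"] else NA_real_,
          itime = if (mode == "PC") smat[, "itime"] else NA_real_,
          bolus = bolus, stringsAsFactors = FALSE)
        terminal <- data.frame(
          subject_id = sid, patient_id = pid, step_index = g + 1L,
          event_type = if (abandoned) "abandon" else "complete",
          spo2 = NA_real_, ph = NA_real_, map = NA_real_,
          pplat = NA_real_, mode = mode, fio2 = NA_real_,
          peep = NA_real_, rate = NA_real_, tv = NA_real_,
          flow = NA_real_, pause = NA_real_, pinsp = NA_real_,
          itime = NA_real_, bolus = NA_real_, stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- rbind(base, terminal)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Configuration for the dialysis record generator
#'
#' Defaults emulate a medium-size dialysis unit: 30 patients followed
#' monthly for 3 years.
#'
#' @param n_patients number of patients.
#' @param n_months months of follow-up per patient (>= 2).
#' @param hgb_noise_sd monthly hemoglobin noise SD, g/dL.
#' @param esa_response_gain hemoglobin equilibrium gain, g/dL per unit
#'   log ESA dose.
#' @param seed integer seed.
#' @return An `hd_sim_config` list.
#' @export
hd_sim_config <- function(n_patients = 30, n_months = 36,
                          hgb_noise_sd = 0.5, esa_response_gain = 1.0,
                          seed = 1) {
  stopifnot(n_patients >= 1, n_months >= 2, hgb_noise_sd >= 0)
  structure(list(n_patients = n_patients, n_months = n_months,
                 hgb_noise_sd = hgb_noise_sd,
                 esa_response_gain = esa_response_gain, seed = seed),
            class = "hd_sim_config")
}

## Stochastic prescriber policy: action probabilities conditioned on the
## hemoglobin state, concentrated on a few habitual responses (most
## months: no change), with dose updates at exact ratio midpoints so the
## realized doses encode back to the intended action categories.
hd_esa_policy <- function(hgb, dose) {
  if (hgb < 10) {
    if (dose <= 0) c(start = 0.6, none = 0.4)
    else c(up_25_50 = 0.45, up_gt50 = 0.15, none = 0.40)
  } else if (hgb <= 12) {
    if (dose <= 0) c(none = 0.9, start = 0.1)
    else c(none = 0.8, up_25_50 = 0.07, down_25_50 = 0.1, stop = 0.03)
  } else {
    if (dose <= 0) c(none = 1)
    else c(down_25_50 = 0.4, down_gt50 = 0.15, stop = 0.15, none = 0.3)
  }
}

#' Generate synthetic dialysis anemia-management records
#'
#' Monthly hemoglobin mean-reverts toward an equilibrium set by the log
#' ESA dose, with Gaussian noise; ferritin and iron saturation respond
#' to iron administration.  A stochastic prescriber policy, concentrated
#' on a few habitual actions, maps each month's derangement to ESA and
#' iron actions using exact ratio-midpoint dose updates (so the encoded
#' intervention categories match the policy's intent).
#'
#' @param cfg an [hd_sim_config()].
#' @return A schema-valid dialysis-log data frame
#'   (see [read_dialysis_log()]).
#' @export
gen_dialysis_records <- function(cfg) {
  stopifnot(inherits(cfg, "hd_sim_config"))
  with_seed(cfg$seed, {
    rows <- list()
    for (p in seq_len(cfg$n_patients)) {
      pid <- sprintf("D%03d", p)
      hgb <- stats::rnorm(1, 10.5, 1.2)
      dose <- if (stats::runif(1) < 0.2) 0
      else round(exp(stats::rnorm(1, log(6000), 0.5)) / 500) * 500
      ferritin <- max(50, stats::rnorm(1, 300, 100))
      tsat <- max(8, stats::rnorm(1, 25, 6))
      iron_given <- as.integer(stats::runif(1) < 0.4)
      iron_dose <- if (iron_given) 100 else 0
      hgb_t <- numeric(cfg$n_months); fer_t <- numeric(cfg$n_months)
      tsat_t <- numeric(cfg$n_months); dose_t <- numeric(cfg$n_months)
      ig_t <- integer(cfg$n_months); id_t <- numeric(cfg$n_months)
      for (m in seq_len(cfg$n_months)) {
        hgb_t[m] <- hgb; fer_t[m] <- ferritin; tsat_t[m] <- tsat
        dose_t[m] <- dose; ig_t[m] <- iron_given; id_t[m] <- iron_dose
        ## prescriber reacts to this month's state
        pr <- hd_esa_policy(hgb, dose)
        act <- sample(names(pr), 1, prob = pr)
        dose <- switch(act,
                       none = dose, start = 4000, stop = 0,
                       up_25_50 = dose * 1.3, up_gt50 = dose * 1.7,
                       down_25_50 = dose * 0.7, down_gt50 = dose * 0.4)
        iron_low <- ferritin < 200 || tsat <= 20
        if (iron_low && !iron_given && stats::runif(1) < 0.5) {
          iron_given <- 1L; iron_dose <- 100
        } else if (iron_low && iron_given && stats::runif(1) < 0.3) {
          iron_dose <- iron_dose + 50
        } else if (ferritin > 500 && iron_given &&
                   stats::runif(1) < 0.6) {
          iron_given <- 0L; iron_dose <- 0
        }
        ## physiology responds over the following month
        h_eq <- 9 + cfg$esa_response_gain * log1p(dose / 1500)
        hgb <- hgb + 0.35 * (h_eq - hgb) +
          stats::rnorm(1, 0, cfg$hgb_noise_sd)
        hgb <- min(max(hgb, 5), 18)
        ferritin <- max(20, ferritin +
                          0.3 * (250 + 1.5 * iron_dose * iron_given -
                                   ferritin) + stats::rnorm(1, 0, 30))
        tsat <- max(3, tsat + 0.3 * (22 + 0.05 * iron_dose * iron_given -
                                       tsat) + stats::rnorm(1, 0, 3))
      }
      rows[[p]] <- data.frame(
        patient_id = pid, month_index = seq_len(cfg$n_months) - 1L,
        hgb = round(hgb_t, 2), ferritin = round(fer_t, 1),
        tsat = round(tsat_t, 1), esa_dose = round(dose_t, 1),
        iron_given = ig_t, iron_dose = id_t, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
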