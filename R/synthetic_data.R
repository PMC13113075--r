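## Synthetic generator for the nested repeated-measures design:
## animal -> growth phase -> available distress condition -> recording -> 3 samples,
## with animal- and recording-level random intercepts per trait and
## logistic (phase + condition driven) missing-not-at-random pitch.

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Default per-trait generator parameters
#'
#' Fixed effects (intercept, sex, phase, condition), random-effect standard
#' deviations (animal, recording, residual) and a log-scale flag for every
#' acoustic trait. Values are chosen so the generated descriptive statistics
#' qualitatively mirror the study system: pain raises intensity and the
#' second formant, cold lengthens calls, heat stress shortens calls and
#' raises pitch, growth phase shortens duration and shifts pitch
#' non-monotonically. They are illustrative defaults, not fits to any data.
#'
#' Positively skewed traits (energy, duration, pitch) are generated
#' log-normally: effects and standard deviations apply on the log scale.
#'
#' @return Named list (one element per trait) of parameter lists with fields
#'   `intercept`, `sex` (male minus female), `phase` (length 4, farrowing =
#'   0), `condition` (length 6, normal = 0), `interaction` (4 x 6 matrix or
#'   NULL), `sd_animal`, `sd_recording`, `sd_resid`, `log`.
#' @export
default_trait_params <- function() {
  lv <- voc_levels()
  p <- function(x) stats::setNames(x, lv$phase)
  k <- function(x) stats::setNames(x, lv$condition)
  list(
    energy = list(intercept = 0, sex = 0.05,
                  phase = p(c(0, 0.1, 0.15, 0.1)),
                  condition = k(c(0, 1.0, 0.3, 0.1, 0.2, 0.4)),
                  interaction = NULL,
                  sd_animal = 0.2, sd_recording = 0.2, sd_resid = 0.6,
                  log = TRUE),
    duration = list(intercept = log(0.50), sex = 0,
                    phase = p(c(0, -0.05, -0.15, -0.30)),
                    condition = k(c(0, 0.65, 0.27, 0.06, 0.84, -0.37)),
                    interaction = NULL,
                    sd_animal = 0.08, sd_recording = 0.10, sd_resid = 0.42,
                    log = TRUE),
    amp_max = list(intercept = 0.60, sex = 0.01,
                   phase = p(c(0, 0.02, 0.03, 0.02)),
                   condition = k(c(0, 0.15, 0.04, 0.02, 0.03, 0.06)),
                   interaction = NULL,
                   sd_animal = 0.04, sd_recording = 0.04, sd_resid = 0.12,
                   log = FALSE),
    amp_min = list(intercept = -0.60, sex = -0.01,
                   phase = p(c(0, -0.02, -0.03, -0.02)),
                   condition = k(c(0, -0.15, -0.04, -0.02, -0.03, -0.06)),
                   interaction = NULL,
                   sd_animal = 0.04, sd_recording = 0.04, sd_resid = 0.12,
                   log = FALSE),
    intensity = list(intercept = 72.8, sex = 0.5,
                     phase = p(c(0, 1.0, 1.5, 1.0)),
                     condition = k(c(0, 10.0, 0.3, 1.0, 1.6, 4.0)),
                     interaction = NULL,
                     sd_animal = 1.5, sd_recording = 1.5, sd_resid = 5.0,
                     log = FALSE),
    pitch = list(intercept = log(160), sex = -0.03,
                 phase = p(c(0, 0.15, 0.20, -0.12)),
                 condition = k(c(0, 0.45, 0.25, -0.10, -0.12, 0.60)),
                 interaction = NULL,
                 sd_animal = 0.10, sd_recording = 0.10, sd_resid = 0.55,
                 log = TRUE),
    f1 = list(intercept = 520, sex = 5,
              phase = p(c(0, -10, 15, 20)),
              condition = k(c(0, 60, -10, 5, -20, 25)),
              interaction = NULL,
              sd_animal = 20, sd_recording = 20, sd_resid = 80,
              log = FALSE),
    f2 = list(intercept = 1900, sex = 10,
              phase = p(c(0, -60, 60, 80)),
              condition = k(c(0, 375, -50, 25, -130, 90)),
              interaction = NULL,
              sd_animal = 45, sd_recording = 45, sd_resid = 230,
              log = FALSE),
    f3 = list(intercept = 2900, sex = 10,
              phase = p(c(0, -40, 40, 60)),
              condition = k(c(0, 120, -20, 10, -50, 40)),
              interaction = NULL,
              sd_animal = 50, sd_recording = 50, sd_resid = 250,
              log = FALSE),
    f4 = list(intercept = 4000, sex = 10,
              phase = p(c(0, -40, 40, 60)),
              condition = k(c(0, 80, -15, 10, -40, 30)),
              interaction = NULL,
              sd_animal = 60, sd_recording = 60, sd_resid = 300,
              log = FALSE)
  )
}

#' Default phase-to-condition availability map
#'
#' Which distress conditions occur in each growth phase: heat stress is
#' absent in farrowing and nursery, thirst is absent in farrowing, and cold
#' is absent in growing and finishing.
#'
#' @return Named list phase -> character vector of conditions.
#' @export
default_availability <- function() {
  list(
    farrowing = c("normal", "pain", "hunger", "cold"),
    nursery   = c("normal", "pain", "hunger", "thirst", "cold"),
    growing   = c("normal", "pain", "hunger", "thirst", "heat"),
    finishing = c("normal", "pain", "hunger", "thirst", "heat")
  )
}

#' Default pitch-missingness logits
#'
#' Logistic coefficients (intercept + phase + condition, reference farrowing
#' / normal) for the probability that a pitch value is missing. The defaults
#' emulate the study system's direction: missingness is near zero in
#' farrowing, rises steeply toward finishing, is elevated under heat stress,
#' hunger and pain, and is depressed under thirst and cold.
#'
#' @return List with `intercept`, `phase` (length 4), `condition` (length 6).
#' @export
default_missingness <- function() {
  lv <- voc_levels()
  list(intercept = -5,
       phase = stats::setNames(c(0, 1.0, 1.8, 3.3), lv$phase),
       condition = stats::setNames(c(0, 0.55, 1.0, -1.1, -1.2, 1.4),
                                   lv$condition))
}

#' Generator configuration
#'
#' Assembles and validates all distributional parameters of the synthetic
#' design.
#'
#' @param n_animals Number of animals (default 40).
#' @param sex_split Proportion female (default 0.5).
#' @param availability Named list phase -> conditions
#'   ([default_availability()]).
#' @param recordings_per_cell 60 s recordings per animal x phase x condition
#'   cell (default 1).
#' @param samples_per_recording 20 s samples per recording (default 3).
#' @param traits Per-trait parameter lists ([default_trait_params()]);
#'   entries supplied here override the defaults field-wise per trait.
#' @param missingness Pitch-missingness logits ([default_missingness()]).
#' @param dropout_rate Probability that a sample row is dropped from the
#'   design (default 0), emulating discarded samples in real collections.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A `voc_generator_config` list.
#' @export
generator_config <- function(n_animals = 40L, sex_split = 0.5,
                             availability = default_availability(),
                             recordings_per_cell = 1L,
                             samples_per_recording = 3L,
                             traits = list(),
                             missingness = default_missingness(),
                             dropout_rate = 0,
                             seed = 1L) {
  stopifnot(n_animals >= 1L, sex_split >= 0, sex_split <= 1,
            recordings_per_cell >= 1L, samples_per_recording >= 1L,
            dropout_rate >= 0, dropout_rate < 1)
  lv <- voc_levels()
  if (!setequal(names(availability), lv$phase))
    stop("config error: availability must name all four phases", call. = FALSE)
  for (ph in names(availability)) {
    if (length(availability[[ph]]) == 0L)
      stop("config error: empty condition availability for phase '", ph, "'",
           call. = FALSE)
    bad <- setdiff(availability[[ph]], lv$condition)
    if (length(bad) > 0L)
      stop("config error: unknown condition(s) in availability: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  base <- default_trait_params()
  for (tr in names(traits)) {
    if (!tr %in% names(base))
      stop("config error: unknown trait '", tr, "'", call. = FALSE)
    base[[tr]][names(traits[[tr]])] <- traits[[tr]]
  }
  for (tr in names(base)) {
    pp <- base[[tr]]
    if (any(c(pp$sd_animal, pp$sd_recording, pp$sd_resid) < 0))
      stop("config error: negative standard deviation for trait '", tr, "'",
           call. = FALSE)
    if (length(pp$phase) != 4L || length(pp$condition) != 6L)
      stop("config error: trait '", tr,
           "' needs 4 phase and 6 condition effects", call. = FALSE)
  }
  structure(list(n_animals = as.integer(n_animals), sex_split = sex_split,
                 availability = availability[lv$phase],
                 recordings_per_cell = as.integer(recordings_per_cell),
                 samples_per_recording = as.integer(samples_per_recording),
                 traits = base, missingness = missingness,
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "voc_generator_config")
}

#' Build the factor skeleton of a synthetic design
#'
#' Enumerates one recording block per animal x phase x available condition x
#' recording replicate, expanded to the configured samples per recording.
#' Animal sexes follow `sex_split`, randomized across animal ids under the
#' seed. If `dropout_rate > 0`, sample rows are dropped independently.
#'
#' @param cfg A [generator_config()].
#' @return Data frame of factor columns (no traits yet), in deterministic
#'   design order.
#' @export
build_design <- function(cfg) {
  stopifnot(inherits(cfg, "voc_generator_config"))
  lv <- voc_levels()
  n_f <- round(cfg$n_animals * cfg$sex_split)
  sexes <- .with_seed(cfg$seed, {
    sample(c(rep("female", n_f), rep("male", cfg$n_animals - n_f)))
  })
  rows <- vector("list", cfg$n_animals)
  for (a in seq_len(cfg$n_animals)) {
    blocks <- list()
    for (ph in lv$phase) {
      for (cond in intersect(lv$condition, cfg$availability[[ph]])) {
        for (r in seq_len(cfg$recordings_per_cell)) {
          rec_id <- sprintf("%s_%s_r%d", ph, cond, r)
          blocks[[length(blocks) + 1L]] <- data.frame(
            animal_id = sprintf("pig%02d", a), sex = sexes[a], phase = ph,
            condition = cond, recording_id = rec_id,
            sample_index = seq_len(cfg$samples_per_recording),
            stringsAsFactors = FALSE)
        }
      }
    }
    rows[[a]] <- do.call(rbind, blocks)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (cfg$dropout_rate > 0) {
    keep <- .with_seed(cfg$seed + 10L,
                       stats::runif(nrow(out)) >= cfg$dropout_rate)
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Simulate acoustic traits on a design skeleton
#'
#' For each trait: value = fixed linear predictor (intercept + sex + phase +
#' condition + optional interaction) + animal intercept N(0, sd_animal^2) +
#' recording intercept N(0, sd_recording^2) + residual N(0, sd_resid^2);
#' traits flagged `log` are simulated on the log scale and exponentiated.
#' All randomness is derived from `cfg$seed`; traits are drawn in canonical
#' order with a fixed draw order (animal effects, recording effects,
#' residuals), so identical seeds give bit-identical tables.
#'
#' @param skeleton Factor skeleton from [build_design()].
#' @param cfg A [generator_config()].
#' @return Data frame: skeleton plus all trait columns.
#' @export
simulate_traits <- function(skeleton, cfg) {
  stopifnot(inherits(cfg, "voc_generator_config"))
  lv <- voc_levels()
  missing_tr <- setdiff(lv$trait, names(cfg$traits))
  if (length(missing_tr) > 0L)
    stop("config error: no parameters for trait(s): ",
         paste(missing_tr, collapse = ", "), call. = FALSE)
  animals <- unique(skeleton$animal_id)
  recs <- unique(paste(skeleton$animal_id, skeleton$recording_id, sep = "\r"))
  rec_key <- paste(skeleton$animal_id, skeleton$recording_id, sep = "\r")
  out <- skeleton
  .with_seed(cfg$seed + 1L, {
    for (tr in lv$trait) {
      pp <- cfg$traits[[tr]]
      eta <- pp$intercept +
        pp$sex * (skeleton$sex == "male") +
        pp$phase[skeleton$phase] +
        pp$condition[skeleton$condition]
      if (!is.null(pp$interaction))
        eta <- eta + pp$interaction[cbind(match(skeleton$phase, lv$phase),
                                          match(skeleton$condition, lv$condition))]
      u_a <- stats::setNames(stats::rnorm(length(animals), 0, pp$sd_animal),
                             animals)
      u_r <- stats::setNames(stats::rnorm(length(recs), 0, pp$sd_recording),
                             recs)
      y <- as.numeric(eta) + u_a[skeleton$animal_id] + u_r[rec_key] +
        stats::rnorm(nrow(skeleton), 0, pp$sd_resid)
      out[[tr]] <- if (isTRUE(pp$log)) exp(y) else unname(y)
    }
  })
  for (tr in lv$trait) out[[tr]] <- unname(out[[tr]])
  out
}

#' Apply missing-not-at-random pitch missingness
#'
#' Each pitch value is independently set missing with probability
#' `plogis(intercept + phase coefficient + condition coefficient)`; other
#' traits are untouched. Missingness depends on the design factors only,
#' never on the latent pitch value.
#'
#' @param table Data frame with a `pitch` column and design factors.
#' @param cfg A [generator_config()].
#' @return The table with pitch values masked to `NA` where missing.
#' @export
apply_missingness <- function(table, cfg) {
  stopifnot(inherits(cfg, "voc_generator_config"))
  m <- cfg$missingness
  logit <- m$intercept + m$phase[as.character(table$phase)] +
    m$condition[as.character(table$condition)]
  p <- stats::plogis(as.numeric(logit))
  drop <- .with_seed(cfg$seed + 2L, stats::runif(nrow(table)) < p)
  table$pitch[drop] <- NA_real_
  table
}

#' Generate a complete synthetic feature table
#'
#' Convenience wrapper: [build_design()] then [simulate_traits()] then
#' [apply_missingness()], validated into a [voc_table()].
#'
#' @param cfg A [generator_config()].
#' @return A validated [voc_table()].
#' @export
generate_dataset <- function(cfg) {
  voc_table(apply_missingness(simulate_traits(build_design(cfg), cfg), cfg))
}

#' Canned scenario: strong individual signatures, weak distress signal
#'
#' Builds a generator configuration in which per-animal and per-recording
#' intercepts dominate while condition effects are scaled down — the regime
#' in which record-wise cross-validation inflates apparent performance
#' relative to subject-wise validation. Condition effects are multiplied by
#' `cond_scale`; animal and recording standard deviations are multiplied by
#' `signature_mult`. Formants are switched to log-normal generation with
#' equivalent relative variation so that inflated signature variances
#' cannot produce non-physical (non-positive) frequencies.
#'
#' @param n_animals Number of animals (default 20).
#' @param cond_scale Multiplier on all condition effects (default 0.15).
#' @param signature_mult Multiplier on animal/recording SDs (default 3).
#' @param seed Integer seed.
#' @return A [generator_config()].
#' @export
signature_scenario_config <- function(n_animals = 20L, cond_scale = 0.15,
                                      signature_mult = 3, seed = 1L) {
  tp <- default_trait_params()
  tr <- lapply(names(tp), function(nm) {
    p <- tp[[nm]]
    if (nm %in% c("f1", "f2", "f3", "f4")) {
      mu <- p$intercept
      list(log = TRUE, intercept = log(mu), sex = p$sex / mu,
           phase = p$phase / mu,
           condition = p$condition / mu * cond_scale,
           sd_animal = p$sd_animal / mu * signature_mult,
           sd_recording = p$sd_recording / mu * signature_mult,
           sd_resid = p$sd_resid / mu)
    } else {
      list(condition = p$condition * cond_scale,
           sd_animal = p$sd_animal * signature_mult,
           sd_recording = p$sd_recording * signature_mult)
    }
  })
  names(tr) <- names(tp)
  generator_config(n_animals = n_animals, traits = tr, seed = seed)
}
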