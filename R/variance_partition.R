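## Hierarchical variance partitioning: mixed-model fits (lme4), ICC,
## Nakagawa R2, drop-one delta-R2, interaction selection, BH-FDR, and a
## balanced one-way method-of-moments oracle.

.rhs_fixed <- function(fixed) {
  map <- c(sex = "sex", phase = "phase", distress = "condition",
           condition = "condition")
  unknown <- setdiff(fixed, names(map))
  if (length(unknown) > 0L)
    stop("unknown fixed-effect block(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  unname(map[fixed])
}

.rhs_random <- function(random) {
  random <- match.arg(random, c("animal", "animal_recording"))
  if (random == "animal") "(1 | animal_id)"
  else "(1 | animal_id) + (1 | animal_id:recording_id)"
}

#' Fit the trait-level linear mixed model
#'
#' Fits `trait ~ fixed factors + (1 | animal)` (optionally plus a recording
#' intercept nested in animal) by REML, on the observed cases for that trait
#' (trait-wise analysis). Skewed traits can be log-transformed before
#' modelling; by default duration and energy are.
#'
#' @param table A [voc_table()].
#' @param trait Trait column name.
#' @param fixed Character vector of fixed-effect blocks among
#'   `"sex"`, `"phase"`, `"distress"`.
#' @param random `"animal"` or `"animal_recording"`.
#' @param interaction If TRUE, adds the distress x phase interaction.
#' @param log_transform Log-transform the trait before fitting; default TRUE
#'   for duration and energy.
#' @param reml REML (default) or ML estimation.
#' @return A `voc_lmm`: list with the `lme4` fit, `components`
#'   (sigma2_animal, sigma2_recording, sigma2_resid), `fitted_fixed` (fixed
#'   -effect linear predictor on the analysis rows), `loglik`, `aic`, `n`,
#'   `rank_deficient` flag and the specification.
#' @export
fit_lmm <- function(table, trait, fixed = c("sex", "phase", "distress"),
                    random = "animal_recording", interaction = FALSE,
                    log_transform = NULL, reml = TRUE) {
  stopifnot(inherits(table, "voc_table"))
  if (!trait %in% attr(table, "trait_names"))
    stop("unknown trait: ", trait, call. = FALSE)
  if (is.null(log_transform)) log_transform <- trait %in% c("duration", "energy")
  dat <- as.data.frame(table)[!is.na(table[[trait]]), , drop = FALSE]
  if (length(unique(dat$animal_id)) < 2L)
    stop("trait observed in fewer than 2 animals", call. = FALSE)
  rhs <- .rhs_fixed(fixed)
  for (v in rhs) {
    if (length(unique(dat[[v]])) < 2L)
      stop("singular design: factor '", v, "' is constant on the analysis rows",
           call. = FALSE)
  }
  dat$.y <- if (log_transform) log(dat[[trait]]) else dat[[trait]]
  terms <- if (length(rhs) == 0L) "1" else rhs
  if (interaction) {
    if (!all(c("phase", "condition") %in% rhs))
      stop("interaction requires both phase and distress blocks", call. = FALSE)
    terms <- c(terms, "condition:phase")
  }
  fml <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + "), "+",
                                 .rhs_random(random)))
  rank_def <- FALSE
  fit <- withCallingHandlers(
    lme4::lmer(fml, data = dat, REML = reml,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE)),
    message = function(m) {
      if (grepl("rank deficient", conditionMessage(m))) rank_def <<- TRUE
      invokeRestart("muffleMessage")
    })
  conv <- fit@optinfo$conv$lme4
  if (!is.null(conv$messages) &&
      any(grepl("failed to converge", conv$messages)))
    stop("mixed model failed to converge for trait '", trait, "': ",
         paste(conv$messages, collapse = "; "), call. = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v) == 0L) NA_real_ else v
  }
  comp <- list(sigma2_animal = getv("animal_id"),
               sigma2_recording = getv("animal_id:recording_id"),
               sigma2_resid = getv("Residual"))
  structure(list(fit = fit, trait = trait, fixed = fixed, random = random,
                 interaction = interaction, log_transform = log_transform,
                 reml = reml, components = comp,
                 fitted_fixed = drop(stats::model.matrix(fit) %*% lme4::fixef(fit)),
                 loglik = as.numeric(stats::logLik(fit)),
                 aic = stats::AIC(fit), n = nrow(dat),
                 rank_deficient = rank_def, data = dat),
            class = "voc_lmm")
}

#' Intraclass correlation for animal identity
#'
#' Proportion of random variance attributable to stable between-animal
#' differences: sigma2_animal / (sigma2_animal + sigma2_resid), with
#' sigma2_recording added to the denominator when a recording-level
#' intercept is present.
#'
#' @param components List with `sigma2_animal`, `sigma2_recording` (may be
#'   `NA` or `NULL` when absent) and `sigma2_resid`, e.g. from
#'   [fit_lmm()]`$components`.
#' @return ICC in \[0, 1\].
#' @export
icc <- function(components) {
  s_a <- components$sigma2_animal
  s_r <- components$sigma2_recording
  s_e <- components$sigma2_resid
  if (is.null(s_r) || is.na(s_r)) s_r <- 0
  if (any(c(s_a, s_r, s_e) < 0)) stop("negative variance component",
                                      call. = FALSE)
  den <- s_a + s_r + s_e
  if (den <= 0) stop("undefined ICC: all variance components are zero",
                     call. = FALSE)
  s_a / den
}

#' Nakagawa marginal and conditional R2
#'
#' For a Gaussian LMM: R2m = var_f / (var_f + sum of random-effect variances
#' + residual variance) and R2c = (var_f + random variances) / same
#' denominator, where var_f is the population (n-denominator) variance of
#' the fitted fixed-effect linear predictor over the analysis rows.
#'
#' @param model A `voc_lmm` from [fit_lmm()].
#' @return List with `r2_marginal`, `r2_conditional`, `var_fixed`.
#' @export
nakagawa_r2 <- function(model) {
  stopifnot(inherits(model, "voc_lmm"))
  f <- model$fitted_fixed
  var_f <- mean((f - mean(f))^2)
  s_r <- model$components$sigma2_recording
  if (is.na(s_r)) s_r <- 0
  s_rand <- model$components$sigma2_animal + s_r
  den <- var_f + s_rand + model$components$sigma2_resid
  if (den <= 0) stop("degenerate model: zero total variance", call. = FALSE)
  list(r2_marginal = var_f / den,
       r2_conditional = (var_f + s_rand) / den,
       var_fixed = var_f)
}

#' Drop-one block contributions to marginal R2
#'
#' Refits the model with one fixed-effect block (sex, phase, distress)
#' removed at a time and reports delta-R2 = R2m(full) - R2m(reduced) per
#' block, clamped at zero with a flag (reduced and full fits are separate
#' optimizations, so tiny negative differences can occur). Block p-values
#' come from ML likelihood-ratio tests of the same comparisons.
#'
#' @param table A [voc_table()].
#' @param trait Trait name.
#' @param blocks Blocks to drop (default all three).
#' @param random,log_transform Passed to [fit_lmm()].
#' @param lrt Also compute ML likelihood-ratio p-values per block (default
#'   TRUE; set FALSE to skip the extra ML refits when only delta-R2 is
#'   needed).
#' @return Data frame: block, delta_r2, clamped, p_lrt; attribute
#'   `r2_full` holds the full-model Nakagawa R2.
#' @export
drop_one_delta_r2 <- function(table, trait,
                              blocks = c("sex", "phase", "distress"),
                              random = "animal_recording",
                              log_transform = NULL, lrt = TRUE) {
  bad <- setdiff(blocks, c("sex", "phase", "distress"))
  if (length(bad) > 0L)
    stop("unknown fixed-effect block(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  full <- fit_lmm(table, trait, fixed = c("sex", "phase", "distress"),
                  random = random, log_transform = log_transform)
  r2_full <- nakagawa_r2(full)
  full_ml <- if (lrt)
    fit_lmm(table, trait, fixed = c("sex", "phase", "distress"),
            random = random, log_transform = log_transform,
            reml = FALSE) else NULL
  out <- lapply(blocks, function(b) {
    keep <- setdiff(c("sex", "phase", "distress"), b)
    if (length(keep) == 0L)
      stop("cannot drop every block", call. = FALSE)
    red <- fit_lmm(table, trait, fixed = keep, random = random,
                   log_transform = log_transform)
    d <- r2_full$r2_marginal - nakagawa_r2(red)$r2_marginal
    p <- NA_real_
    if (lrt) {
      red_ml <- fit_lmm(table, trait, fixed = keep, random = random,
                        log_transform = log_transform, reml = FALSE)
      lrt_stat <- 2 * (full_ml$loglik - red_ml$loglik)
      df <- length(lme4::fixef(full_ml$fit)) - length(lme4::fixef(red_ml$fit))
      p <- stats::pchisq(max(lrt_stat, 0), df = max(df, 1L),
                         lower.tail = FALSE)
    }
    data.frame(block = b, delta_r2 = max(d, 0), clamped = d < 0, p_lrt = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "r2_full") <- r2_full
  res
}

#' Select the distress x growth-phase interaction
#'
#' Fits the additive and interaction models by ML and keeps the interaction
#' only if the likelihood-ratio test has p < 0.05 and the AIC decreases.
#' With structurally empty phase-condition cells (heat stress absent early)
#' the interaction is fitted on the estimable subset of contrasts and a
#' design warning is flagged.
#'
#' @param table A [voc_table()].
#' @param trait Trait name.
#' @param random,log_transform Passed to [fit_lmm()].
#' @param alpha LRT significance threshold (default 0.05).
#' @return List: `keep`, `p_lrt`, `lrt_stat`, `df`, `delta_aic`
#'   (interaction minus base), `design_warning`.
#' @export
select_interaction <- function(table, trait, random = "animal_recording",
                               log_transform = NULL, alpha = 0.05) {
  base <- fit_lmm(table, trait, random = random,
                  log_transform = log_transform, reml = FALSE)
  full <- fit_lmm(table, trait, random = random, interaction = TRUE,
                  log_transform = log_transform, reml = FALSE)
  stat <- max(2 * (full$loglik - base$loglik), 0)
  df <- length(lme4::fixef(full$fit)) - length(lme4::fixef(base$fit))
  p <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  if (stat == 0) p <- 1
  d_aic <- full$aic - base$aic
  list(keep = (p < alpha) && (d_aic < 0), p_lrt = p, lrt_stat = stat,
       df = df, delta_aic = d_aic, design_warning = full$rank_deficient)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate control across a family of tests.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values (same length/order).
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Method-of-moments variance components for balanced one-way data
#'
#' Closed-form one-way ANOVA estimators for a balanced animal grouping with
#' no fixed effects beyond the intercept: sigma2_resid = MS_within and
#' sigma2_animal = (MS_between - MS_within) / n0 (clamped at zero), where n0
#' is the common group size. Serves as an independent oracle for the REML
#' fit on balanced designs.
#'
#' @param table Data frame with `animal_id` and the trait column.
#' @param trait Trait column name.
#' @return List `sigma2_animal`, `sigma2_recording` (`NA`), `sigma2_resid`.
#' @export
mom_variance_oracle <- function(table, trait) {
  y <- table[[trait]]
  g <- factor(table$animal_id)
  if (anyNA(y)) stop("oracle requires complete data", call. = FALSE)
  sizes <- table(g)
  if (length(unique(as.integer(sizes))) != 1L)
    stop("oracle requires a balanced design (equal n per animal)",
         call. = FALSE)
  n0 <- as.integer(sizes[1]); a <- nlevels(g)
  gm <- tapply(y, g, mean)
  ms_b <- n0 * sum((gm - mean(y))^2) / (a - 1)
  ms_w <- sum((y - gm[g])^2) / (a * (n0 - 1))
  list(sigma2_animal = max((ms_b - ms_w) / n0, 0),
       sigma2_recording = NA_real_,
       sigma2_resid = ms_w)
}

#' Residual-based animal ICC
#'
#' Removes the fixed effects with an ordinary linear model, then computes
#' the animal ICC of the residuals from an intercept-only random-intercept
#' model. A simpler, assumption-light companion to the model-based ICC.
#'
#' @param table A [voc_table()].
#' @param trait Trait name.
#' @param fixed Fixed-effect blocks to remove first.
#' @param log_transform Passed through; default as in [fit_lmm()].
#' @return ICC of the residuals, in \[0, 1\].
#' @export
residual_icc <- function(table, trait, fixed = c("sex", "phase", "distress"),
                         log_transform = NULL) {
  if (is.null(log_transform)) log_transform <- trait %in% c("duration", "energy")
  dat <- as.data.frame(table)[!is.na(table[[trait]]), , drop = FALSE]
  dat$.y <- if (log_transform) log(dat[[trait]]) else dat[[trait]]
  fml <- stats::as.formula(paste(".y ~", paste(.rhs_fixed(fixed),
                                               collapse = " + ")))
  dat$.r <- stats::resid(stats::lm(fml, data = dat))
  fit <- suppressMessages(
    lme4::lmer(.r ~ 1 + (1 | animal_id), data = dat,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  s_a <- vc$vcov[vc$grp == "animal_id"]
  s_e <- vc$vcov[vc$grp == "Residual"]
  s_a / (s_a + s_e)
}

#' Full variance-partitioning table across traits
#'
#' For each trait: REML variance components, animal ICC, Nakagawa marginal
#' and conditional R2, the animal partial R2 (R2c - R2m), drop-one delta-R2
#' per block with ML LRT p-values, the distress x phase interaction decision,
#' and residual-based ICC. BH-FDR is applied across the whole family of
#' trait x block tests.
#'
#' @param table A [voc_table()].
#' @param traits Traits to analyse (default: intensity, duration, pitch, f2).
#' @param random Random-effect structure (default animal + recording).
#' @return List with `partition` (one row per trait) and `tests` (one row
#'   per trait x block with p and BH q).
#' @export
variance_partition <- function(table,
                               traits = c("intensity", "duration", "pitch", "f2"),
                               random = "animal_recording") {
  part <- list(); tests <- list()
  for (tr in traits) {
    m <- fit_lmm(table, tr, random = random)
    r2 <- nakagawa_r2(m)
    dd <- drop_one_delta_r2(table, tr, random = random)
    sel <- select_interaction(table, tr, random = random)
    part[[tr]] <- data.frame(
      trait = tr,
      sigma2_animal = m$components$sigma2_animal,
      sigma2_recording = m$components$sigma2_recording,
      sigma2_resid = m$components$sigma2_resid,
      icc = icc(m$components),
      icc_residual = residual_icc(table, tr),
      r2_marginal = r2$r2_marginal,
      r2_conditional = r2$r2_conditional,
      animal_partial_r2 = r2$r2_conditional - r2$r2_marginal,
      delta_r2_distress = dd$delta_r2[dd$block == "distress"],
      delta_r2_phase = dd$delta_r2[dd$block == "phase"],
      delta_r2_sex = dd$delta_r2[dd$block == "sex"],
      interaction_kept = sel$keep,
      interaction_p = sel$p_lrt,
      interaction_delta_aic = sel$delta_aic,
      stringsAsFactors = FALSE)
    tests[[tr]] <- data.frame(trait = tr, block = dd$block, p = dd$p_lrt,
                              stringsAsFactors = FALSE)
  }
  tests <- do.call(rbind, tests)
  tests$q <- bh_fdr(tests$p)
  rownames(tests) <- NULL
  part <- do.call(rbind, part)
  rownames(part) <- NULL
  list(partition = part, tests = tests)
}
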