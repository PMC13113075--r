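## Data model: one row per 20 s vocal sample, nested as
## animal -> growth phase -> distress condition -> 60 s recording -> sample.

#' Canonical factor levels of the experimental design
#'
#' Closed level sets for the design factors: four growth phases (ordered for
#' reporting, modelled as unordered), six distress conditions and two sexes.
#' The condition order fixes class order everywhere downstream (fold
#' stratification, confusion matrices, probability columns, argmax
#' tie-breaking).
#'
#' @return Named list with elements `phase`, `condition`, `sex`, `trait`.
#' @export
voc_levels <- function() {
  list(
    phase     = c("farrowing", "nursery", "growing", "finishing"),
    condition = c("normal", "pain", "hunger", "thirst", "cold", "heat"),
    sex       = c("female", "male"),
    trait     = c("energy", "duration", "amp_max", "amp_min", "intensity",
                  "pitch", "f1", "f2", "f3", "f4")
  )
}

.voc_factor_cols <- c("animal_id", "sex", "phase", "condition",
                      "recording_id", "sample_index")

#' @keywords internal
.canonical_columns <- function() c(.voc_factor_cols, voc_levels()$trait)

#' Construct a validated feature table
#'
#' Takes a data frame with the canonical columns and returns a validated
#' `voc_table`. Validation enforces the closed factor level sets, the sample
#' key uniqueness (animal, recording, sample index), `sample_index` in 1..3,
#' one sex per animal, positive durations, positive finite formants, and —
#' because only pitch may be missing in this data model — completeness of
#' every other trait.
#'
#' @param df Data frame containing the canonical columns.
#' @return A `voc_table`: a data frame with factor columns coerced to the
#'   canonical levels and a `trait_names` attribute.
#' @export
voc_table <- function(df) {
  lv <- voc_levels()
  need <- .canonical_columns()
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L)
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- as.data.frame(df)[, need]

  for (fc in c("sex", "phase", "condition")) {
    vals <- as.character(df[[fc]])
    bad <- which(!(vals %in% lv[[fc]]) | is.na(vals))
    if (length(bad) > 0L)
      stop("validation error: unknown ", fc, " level ",
           paste(unique(vals[bad]), collapse = ", "),
           " in row(s) ", paste(utils::head(bad, 10L), collapse = ", "),
           call. = FALSE)
    df[[fc]] <- factor(vals, levels = lv[[fc]])
  }
  df$animal_id <- factor(as.character(df$animal_id))
  df$recording_id <- factor(as.character(df$recording_id))
  df$sample_index <- as.integer(df$sample_index)
  if (any(is.na(df$sample_index)) || any(!df$sample_index %in% 1:3))
    stop("validation error: sample_index must be in {1,2,3}", call. = FALSE)

  key <- paste(df$animal_id, df$recording_id, df$sample_index, sep = "\r")
  if (anyDuplicated(key) > 0L)
    stop("integrity error: duplicated (animal_id, recording_id, sample_index) key",
         call. = FALSE)

  sex_per_animal <- tapply(as.character(df$sex), df$animal_id,
                           function(s) length(unique(s)))
  if (any(sex_per_animal > 1L))
    stop("integrity error: animal(s) with more than one sex: ",
         paste(names(sex_per_animal)[sex_per_animal > 1L], collapse = ", "),
         call. = FALSE)

  for (tr in lv$trait) {
    df[[tr]] <- as.numeric(df[[tr]])
    if (tr != "pitch" && anyNA(df[[tr]]))
      stop("validation error: trait '", tr,
           "' has missing values; only pitch may be missing", call. = FALSE)
  }
  if (any(df$duration <= 0, na.rm = TRUE))
    stop("validation error: duration must be positive", call. = FALSE)
  fmt <- as.matrix(df[, c("f1", "f2", "f3", "f4")])
  if (any(!is.finite(fmt)) || any(fmt <= 0))
    stop("validation error: formants must be finite and positive", call. = FALSE)

  structure(df, trait_names = lv$trait, class = c("voc_table", "data.frame"))
}

#' Read a feature table from CSV
#'
#' Reads an RFC-4180 CSV with a header row and validates it into a
#' [voc_table()]. Empty or `NA` pitch cells become the uniform missing value.
#' A schema mapping translates file-specific column names to the canonical
#' ones, absorbing dialect differences between feature exports.
#'
#' @param path Path to a CSV file.
#' @param schema Optional named character vector or list mapping canonical
#'   column names to the names used in the file, e.g.
#'   `c(pitch = "F0_Hz", animal_id = "PigID")`. Unmapped columns are assumed
#'   to carry canonical names already.
#' @return A validated [voc_table()].
#' @export
load_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         na.strings = c("", "NA"))
  if (!is.null(schema)) {
    schema <- unlist(schema)
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(raw))
        stop("schema error: mapped column '", src, "' (for '", canon,
             "') not found in file", call. = FALSE)
      names(raw)[names(raw) == src] <- canon
    }
  }
  voc_table(raw)
}

#' Write a feature table to CSV
#'
#' Deterministic column order (factors, then traits in canonical order);
#' missing pitch is written as an empty field. The written file round-trips
#' through [load_table()] to printed precision (15 significant digits).
#'
#' @param table A [voc_table()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(table, path) {
  stopifnot(inherits(table, "voc_table"))
  out <- as.data.frame(table)[, .canonical_columns(), drop = FALSE]
  for (nm in names(out)) if (is.factor(out[[nm]])) out[[nm]] <- as.character(out[[nm]])
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("I/O error writing '", path, "': ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Design completeness and missingness report
#'
#' Tabulates sample counts per growth phase x distress condition x sex cell
#' with pitch-missing counts and percentages, mirroring the descriptive
#' design table of the study, and flags phase-condition cells absent from
#' the realized design (heat stress does not occur in farrowing or nursery,
#' thirst does not occur in farrowing).
#'
#' @param table A [voc_table()].
#' @return List with `cells` (data frame: phase, condition, n_female, n_male,
#'   n_total, n_pitch_missing, pct_pitch_missing), `absent_cells` (data frame
#'   of phase-condition pairs with zero rows), `n_total`, `n_pitch_missing`,
#'   and `pct_pitch_missing` (overall, percent).
#' @export
validate_design <- function(table) {
  stopifnot(inherits(table, "voc_table"))
  lv <- voc_levels()
  grid <- expand.grid(phase = lv$phase, condition = lv$condition,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    sel <- table$phase == grid$phase[i] & table$condition == grid$condition[i]
    sub <- table[sel, , drop = FALSE]
    data.frame(phase = grid$phase[i], condition = grid$condition[i],
               n_female = sum(sub$sex == "female"),
               n_male = sum(sub$sex == "male"),
               n_total = nrow(sub),
               n_pitch_missing = sum(is.na(sub$pitch)),
               pct_pitch_missing = if (nrow(sub) > 0)
                 round(100 * sum(is.na(sub$pitch)) / nrow(sub), 1) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  absent <- cells[cells$n_total == 0L, c("phase", "condition")]
  list(cells = cells[cells$n_total > 0L, , drop = FALSE],
       absent_cells = absent,
       n_total = nrow(table),
       n_pitch_missing = sum(is.na(table$pitch)),
       pct_pitch_missing = round(100 * sum(is.na(table$pitch)) / nrow(table), 1))
}
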