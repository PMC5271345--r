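#' The cohort CSV schema
#'
#' Column names and types of the waiting-list cohort exchange format: one
#' row per patient, header required, comma-separated, UTF-8, booleans as
#' \code{true}/\code{false}, missing values as empty fields. Unit columns
#' accept \code{mg/dl}/\code{umol/l} (creatinine, bilirubin) and
#' \code{g/dl}/\code{g/l} (albumin).
#'
#' @return named character vector mapping column name to type
#'   (\code{"character"}, \code{"numeric"}, \code{"integer"},
#'   \code{"logical"}).
#' @export
cohort_schema <- function() {
  c(patient_id = "character", age_years = "numeric", sex = "character",
    weight_kg = "numeric", height_m = "numeric",
    dialysis_per_week = "integer", growth_failure = "logical",
    hu_status = "logical", standard_exception = "logical",
    indication = "character", retransplant = "logical",
    days_on_list = "integer", outcome = "character", died_90d = "logical",
    creatinine = "numeric", creatinine_unit = "character",
    bilirubin = "numeric", bilirubin_unit = "character",
    inr = "numeric", sodium_mmol_l = "numeric",
    albumin = "numeric", albumin_unit = "character", ptt_s = "numeric")
}

#' Read a cohort CSV
#'
#' Reads and validates a patient cohort against \code{\link{cohort_schema}}:
#' all columns present, unit tags normalised (\code{umol/l} spellings
#' unified), booleans parsed, duplicate patient identifiers rejected.
#'
#' @param path path to the cohort CSV.
#' @return a validated cohort data.frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  if (nrow(df) == 0) stop("cohort file is empty: ", path)
  schema <- cohort_schema()
  missing_cols <- setdiff(names(schema), names(df))
  if (length(missing_cols)) {
    stop("cohort CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in names(schema)) {
    df[[col]] <- switch(schema[[col]],
      numeric = as.numeric(df[[col]]),
      integer = as.integer(df[[col]]),
      logical = parse_bool(df[[col]], col),
      as.character(df[[col]]))
  }
  for (col in c("creatinine_unit", "bilirubin_unit", "albumin_unit")) {
    df[[col]] <- normalize_unit(df[[col]])
  }
  dup <- df$patient_id[duplicated(df$patient_id)]
  if (length(dup)) {
    stop("duplicate patient_id: ", paste(unique(dup), collapse = ", "))
  }
  bad_bmi_rows <- which(!is.na(df$weight_kg) & !is.na(df$height_m) &
                          df$height_m <= 0)
  if (length(bad_bmi_rows)) {
    stop("non-positive height_m at row(s): ",
         paste(bad_bmi_rows, collapse = ", "))
  }
  df
}

parse_bool <- function(x, col) {
  if (is.logical(x)) return(x)
  v <- tolower(as.character(x))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "1", "yes")] <- TRUE
  out[v %in% c("false", "f", "0", "no")] <- FALSE
  bad <- which(!is.na(v) & is.na(out))
  if (length(bad)) {
    stop(sprintf("column '%s': unparseable boolean at row(s) %s", col,
                 paste(bad, collapse = ", ")))
  }
  out
}

#' Write a table to CSV in the package dialect
#'
#' Comma-separated, header, UTF-8, booleans as \code{true}/\code{false},
#' missing values as empty fields. Byte-identical output for identical
#' input.
#'
#' @param rows data.frame to write.
#' @param path destination path.
#' @export
write_table <- function(rows, path) {
  out <- rows
  for (col in names(out)) {
    if (is.logical(out[[col]])) {
      out[[col]] <- ifelse(is.na(out[[col]]), NA,
                           ifelse(out[[col]], "true", "false"))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Run the full validation pipeline
#'
#' End-to-end seeded analysis: simulate (or load) a cohort, compute the
#' nine scores, build the sub-cohort AUROC matrix, run the two
#' multivariable model sets (set 1: clinical/laboratory covariates; set 2:
#' the clinical covariates retained by set 1 plus the nine scores), and
#' optionally summarise quality-assessment sheets. All artifacts are
#' written to the output directory; re-running with the same configuration
#' is deterministic.
#'
#' @param cohort_file path to a cohort CSV, or \code{NULL} to simulate.
#' @param spec a \code{\link{cohort_spec}} used when simulating (its seed
#'   governs all randomness).
#' @param out_dir output directory (created if absent).
#' @param qa_file optional assessments CSV (see
#'   \code{\link{read_assessments}}).
#' @param ci_method \code{"delong"} or \code{"bootstrap"}.
#' @param threshold AUROC acceptability threshold.
#' @param entry_alpha,removal_alpha forward-LR thresholds.
#' @param peld_max_age passed to \code{\link{score_cohort}}.
#' @return invisibly, a list with the scored cohort, the ROC matrix, the
#'   screen and the two \code{\link{forward_lr_select}} results (and the
#'   quality report when requested), plus the paths written.
#' @export
run_pipeline <- function(cohort_file = NULL, spec = cohort_spec(),
                         out_dir = "meldkit-output", qa_file = NULL,
                         ci_method = "delong", threshold = 0.700,
                         entry_alpha = 0.05, removal_alpha = 0.10,
                         peld_max_age = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- if (is.null(cohort_file)) {
    generate_cohort(spec)
  } else {
    read_cohort(cohort_file)
  }
  scored <- score_cohort(cohort, peld_max_age = peld_max_age)
  scored$bmi <- scored$weight_kg / scored$height_m^2
  scored$pediatric_lt16 <- scored$age_years < 16
  scored$pediatric_lt12 <- scored$age_years < 12
  write_table(scored, file.path(out_dir, "scores.csv"))

  roc <- auroc_matrix(scored, ci_method = ci_method, threshold = threshold)
  write_table(roc, file.path(out_dir, "roc.csv"))

  score_cols <- c("meld", "meso", "meld_na", "ukeld", "imeld", "refit_meld",
                  "refit_meld_na", "up_meld", "peld")
  clinical <- c("age_years", "creatinine", "bilirubin", "inr",
                "sodium_mmol_l", "ptt_s", "albumin", "dialysis_per_week",
                "weight_kg", "height_m", "bmi", "pediatric_lt16",
                "pediatric_lt12", "hu_status", "standard_exception",
                "days_on_list")
  outcome <- scored$died_90d
  screen1 <- univariable_screen(scored, outcome, clinical)
  cands1 <- resolve_collinearity(
    screen1,
    groups = list(c("weight_kg", "height_m", "bmi"),
                  c("age_years", "pediatric_lt16", "pediatric_lt12")))
  model1 <- forward_lr_select(scored, outcome, cands1,
                              entry_alpha = entry_alpha,
                              removal_alpha = removal_alpha)
  # set 2: clinical covariates retained by set 1, plus the scores
  screen2 <- univariable_screen(scored, outcome, score_cols)
  cands2 <- unique(c(model1$selected,
                     screen2$term[screen2$significant %in% TRUE]))
  model2 <- forward_lr_select(scored, outcome, cands2,
                              entry_alpha = entry_alpha,
                              removal_alpha = removal_alpha)

  reg <- list(
    model_set_1 = serialize_forward_lr(model1, screen1),
    model_set_2 = serialize_forward_lr(model2, screen2)
  )
  jsonlite::write_json(reg, file.path(out_dir, "regression.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  result <- list(scored = scored, roc = roc, screen = screen1,
                 model_set_1 = model1, model_set_2 = model2,
                 paths = file.path(out_dir, c("scores.csv", "roc.csv",
                                              "regression.json")))
  if (!is.null(qa_file)) {
    sheets <- read_assessments(qa_file)
    summaries <- lapply(sheets, summarize_model)
    report <- cohort_quality_report(summaries)
    jsonlite::write_json(
      list(mean_total = report$mean_total,
           percent_of_max = report$percent_of_max,
           category_item_means = as.list(report$category_item_means),
           ranking = report$ranking),
      file.path(out_dir, "qa_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    result$qa_report <- report
    result$paths <- c(result$paths, file.path(out_dir, "qa_report.json"))
  }
  log_lines <- c(
    sprintf("meldkit %s", as.character(utils::packageVersion("meldkit"))),
    sprintf("R %s", R.version.string),
    sprintf("seed %d", spec$seed),
    sprintf("cohort %s (n = %d)",
            if (is.null(cohort_file)) "simulated" else cohort_file,
            nrow(cohort)),
    sprintf("ci_method %s; threshold %.3f", ci_method, threshold))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(result)
}

serialize_forward_lr <- function(fit, screen) {
  list(selected = fit$selected,
       trace = fit$trace,
       terms = fit$model$terms,
       log_likelihood = fit$model$log_likelihood,
       n = fit$model$n, n_events = fit$model$n_events,
       univariable_screen = screen[, c("term", "p_value", "odds_ratio",
                                       "ci_low", "ci_high", "estimable",
                                       "significant")])
}
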