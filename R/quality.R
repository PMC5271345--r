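#' The 18-item quality-assessment taxonomy
#'
#' Fixed taxonomy of the 20-point quality-assessment instrument for
#' prognostic-model studies (Jacob et al. style): 18 subheadings in 5
#' categories. Each subheading is marked 0 or 1 per evaluator; the two
#' external-validity items are double-weighted, so each category has a
#' weighted maximum of 4 and the instrument totals 20 points.
#'
#' @return a data.frame with columns \code{item}, \code{category},
#'   \code{weight}, in fixed order.
#' @export
qa_items <- function() {
  data.frame(
    item = c(
      "inception_cohort_established", "inception_cohort_followed_up",
      "baseline_data_collected_prospectively",
      "candidate_prognostic_factors_clearly_defined",
      "multi_centre_population", "adequate_description",
      "continuous_variables", "sample_size_adequate",
      "collinearity_assessed", "missing_values",
      "assumptions_of_final_model_tested",
      "sensitivity_to_influential_observations",
      "model_validated_internal", "model_validated_external",
      "factors_available_in_clinical_practice",
      "final_model_described_sufficiently",
      "precision_of_predictions", "wide_generalisability"
    ),
    category = rep(c("internal_validity", "external_validity",
                     "statistical_validity", "evaluation_of_model",
                     "practicality"), times = c(4, 2, 4, 4, 4)),
    weight = rep(c(1, 2, 1, 1, 1), times = c(4, 2, 4, 4, 4)),
    stringsAsFactors = FALSE
  )
}

qa_categories <- c("internal_validity", "external_validity",
                   "statistical_validity", "evaluation_of_model",
                   "practicality")

#' Build an evaluator assessment sheet
#'
#' One evaluator's binary marks for one prognostic model over the 18 fixed
#' subheadings of \code{\link{qa_items}}.
#'
#' @param model_name name of the assessed prognostic model.
#' @param evaluator_id evaluator identifier.
#' @param marks named numeric/integer vector: exactly the 18 item keys,
#'   each 0 or 1.
#' @return a list of class \code{assessment_sheet}.
#' @export
assessment_sheet <- function(model_name, evaluator_id, marks) {
  items <- qa_items()$item
  if (!setequal(names(marks), items) || length(marks) != 18) {
    stop("marks must be named with exactly the 18 fixed item keys")
  }
  marks <- marks[items]
  if (!all(marks %in% c(0, 1))) stop("marks must be 0 or 1")
  structure(list(model_name = model_name, evaluator_id = evaluator_id,
                 marks = marks), class = "assessment_sheet")
}

#' Summarise evaluator sheets for one model
#'
#' Averages binary marks across evaluators per item, doubles the two
#' external-validity item means, forms category subtotals (each out of a
#' weighted maximum of 4) and the total out of 20. Averaging before or
#' after weighting is equivalent for linear means; weighting is applied to
#' the evaluator-averaged item mean.
#'
#' @param sheets list of \code{\link{assessment_sheet}} objects, all for
#'   the same model.
#' @return an object of class \code{quality_summary}: list with
#'   \code{model_name}, \code{item_means} (18 unweighted means),
#'   \code{weighted_item_scores}, \code{category_subtotals} (5 values),
#'   \code{total} (0--20), \code{n_evaluators}.
#' @examples
#' ones <- setNames(rep(1, 18), qa_items()$item)
#' sh <- lapply(1:3, function(i) assessment_sheet("MELD", paste0("E", i), ones))
#' summarize_model(sh)$total  # 20
#' @export
summarize_model <- function(sheets) {
  stopifnot(length(sheets) >= 1)
  models <- vapply(sheets, function(s) s$model_name, character(1))
  if (length(unique(models)) != 1) {
    stop("all sheets must assess the same model")
  }
  m <- do.call(rbind, lapply(sheets, function(s) s$marks))
  item_means <- colMeans(m)
  quality_summary_from_means(models[1], item_means,
                             n_evaluators = length(sheets))
}

#' Build a quality summary from per-item means
#'
#' Constructs a \code{quality_summary} directly from the 18 evaluator-
#' averaged item means (values in [0, 1]), e.g. when working from a
#' published summary table rather than raw sheets.
#'
#' @param model_name model name.
#' @param item_means named numeric vector over the 18 item keys,
#'   unweighted (external items on the 0--1 scale).
#' @param n_evaluators number of evaluators behind the means (for record).
#' @return a \code{quality_summary}.
#' @export
quality_summary_from_means <- function(model_name, item_means,
                                       n_evaluators = NA_integer_) {
  tax <- qa_items()
  if (!setequal(names(item_means), tax$item)) {
    stop("item_means must be named with the 18 fixed item keys")
  }
  item_means <- item_means[tax$item]
  if (any(item_means < 0 | item_means > 1)) {
    stop("item means must lie in [0, 1]")
  }
  weighted <- item_means * tax$weight
  subtotals <- vapply(qa_categories, function(cat) {
    sum(weighted[tax$category == cat])
  }, numeric(1))
  structure(list(model_name = model_name, item_means = item_means,
                 weighted_item_scores = weighted,
                 category_subtotals = subtotals,
                 total = sum(weighted), n_evaluators = n_evaluators),
            class = "quality_summary")
}

#' @export
print.quality_summary <- function(x, ...) {
  cat(sprintf("Quality assessment: %s — %.2f / 20 points\n",
              x$model_name, x$total))
  for (cat_ in qa_categories) {
    cat(sprintf("  %-22s %.2f / 4\n", cat_, x$category_subtotals[[cat_]]))
  }
  invisible(x)
}

#' Aggregate quality report over several models
#'
#' Mean total across models (with the percentage of the 20-point maximum),
#' per-category mean subtotals, per-item mean marks (unweighted, to expose
#' weak categories), and a ranking of models by total.
#'
#' @param summaries list of \code{quality_summary} objects.
#' @return a list of class \code{quality_report}: \code{mean_total},
#'   \code{percent_of_max}, \code{category_means} (weighted subtotal
#'   means), \code{category_item_means} (mean unweighted per-item mark by
#'   category), \code{ranking} (data.frame model/total, descending),
#'   \code{n_models}.
#' @export
cohort_quality_report <- function(summaries) {
  stopifnot(length(summaries) >= 1)
  totals <- vapply(summaries, function(s) s$total, numeric(1))
  models <- vapply(summaries, function(s) s$model_name, character(1))
  tax <- qa_items()
  sub <- do.call(rbind, lapply(summaries, function(s) s$category_subtotals))
  im <- do.call(rbind, lapply(summaries, function(s) s$item_means))
  cat_item_means <- vapply(qa_categories, function(cat) {
    mean(im[, tax$category == cat, drop = FALSE])
  }, numeric(1))
  ranking <- data.frame(model = models, total = totals)
  ranking <- ranking[order(-ranking$total), ]
  rownames(ranking) <- NULL
  structure(list(mean_total = mean(totals),
                 percent_of_max = mean(totals) / 20 * 100,
                 category_means = colMeans(sub),
                 category_item_means = cat_item_means,
                 ranking = ranking, n_models = length(summaries)),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("Quality report over %d models: mean %.2f / 20 (%.2f%%)\n",
              x$n_models, x$mean_total, x$percent_of_max))
  cat("Per-item category means (0-1):\n")
  for (cat_ in names(x$category_item_means)) {
    cat(sprintf("  %-22s %.2f\n", cat_, x$category_item_means[[cat_]]))
  }
  print(x$ranking, row.names = FALSE)
  invisible(x)
}

#' Radar (spider-web) data for a quality summary
#'
#' Normalises each category subtotal by its weighted maximum of 4, in the
#' fixed pentagon order (internal, external, statistical, evaluation,
#' practicality), for spider-web plotting.
#'
#' @param summary a \code{quality_summary}.
#' @return data.frame with columns \code{category} and \code{value}
#'   (proportions in [0, 1]).
#' @export
radar_export <- function(summary) {
  stopifnot(inherits(summary, "quality_summary"))
  data.frame(category = qa_categories,
             value = as.numeric(summary$category_subtotals[qa_categories]) / 4)
}

#' Read evaluator assessment sheets from CSV
#'
#' Expects columns \code{model}, \code{evaluator}, \code{item_key},
#' \code{mark} (0/1), one row per mark, 18 rows per (model, evaluator).
#'
#' @param path CSV path.
#' @return named list (by model) of lists of \code{assessment_sheet}s.
#' @export
read_assessments <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("model", "evaluator", "item_key", "mark")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("assessment CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- list()
  for (mod in unique(df$model)) {
    sub <- df[df$model == mod, ]
    sheets <- lapply(unique(sub$evaluator), function(ev) {
      rows <- sub[sub$evaluator == ev, ]
      assessment_sheet(mod, ev,
                       stats::setNames(rows$mark, rows$item_key))
    })
    out[[mod]] <- sheets
  }
  out
}

#' Published per-item quality means shipped with the package
#'
#' Loads the packaged fixture of published evaluator-averaged quality
#' marks for the nine score-development studies. External-validity cells
#' are stored as printed, i.e. already x2-weighted; \code{printed_total}
#' carries the totals as printed in the source table, which for some
#' models differ from the recomputed sum of their own cells (both are
#' retained deliberately).
#'
#' @return a data.frame: \code{item}, \code{category}, then one column per
#'   model; attribute \code{printed_totals} is the named vector of printed
#'   totals.
#' @export
table3_means <- function() {
  path <- system.file("extdata", "table3_means.csv", package = "meldkit")
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  totals <- df[df$item == "printed_total", -(1:2)]
  df <- df[df$item != "printed_total", ]
  attr(df, "printed_totals") <- unlist(totals)
  df
}

#' Quality summary from a published (weighted) table column
#'
#' Converts one model's column of the published per-item table (external
#' cells printed x2-weighted) into a \code{quality_summary} by unweighting
#' the external cells before the standard construction.
#'
#' @param model_name column name in \code{\link{table3_means}}.
#' @param table output of \code{\link{table3_means}} (loaded if omitted).
#' @return a \code{quality_summary}.
#' @export
quality_summary_from_table <- function(model_name, table = table3_means()) {
  if (!model_name %in% names(table)) {
    stop(sprintf("model '%s' not present in the table", model_name))
  }
  tax <- qa_items()
  vals <- table[[model_name]][match(tax$item, table$item)]
  means <- stats::setNames(vals / tax$weight, tax$item)
  quality_summary_from_means(model_name, means, n_evaluators = 3L)
}
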