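#' Area under the ROC curve (Mann-Whitney form)
#'
#' AUROC as the tie-aware Mann-Whitney statistic: over all event/non-event
#' pairs, the mean of 1 for a correctly ordered pair, 0.5 for a tied pair
#' and 0 otherwise. Orientation is fixed as higher score = event (death).
#' Computed in O(n log n) via midranks.
#'
#' @param scores numeric vector of prognostic scores.
#' @param events logical (or 0/1) event indicator of the same length.
#' @return the AUROC, a proportion in [0, 1].
#' @examples
#' auroc(c(1, 2, 3, 4), c(FALSE, TRUE, FALSE, TRUE))  # 0.75
#' @export
auroc <- function(scores, events) {
  ev <- check_roc_input(scores, events)
  r <- rank(scores, ties.method = "average")
  n1 <- sum(ev)
  n0 <- sum(!ev)
  (sum(r[ev]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

check_roc_input <- function(scores, events) {
  if (length(scores) != length(events)) {
    stop("scores and events must have equal length")
  }
  if (anyNA(scores) || anyNA(events)) {
    stop("scores and events must not contain missing values")
  }
  ev <- as.logical(events)
  if (all(ev) || !any(ev)) {
    stop("need at least one event and one non-event")
  }
  ev
}

#' ROC curve points
#'
#' Builds the empirical ROC curve with one operating point per distinct
#' threshold (thresholds descending, classification rule score >=
#' threshold), prepended with (0, 0). The trapezoidal area under the
#' returned curve equals \code{\link{auroc}} (midrank tie handling).
#'
#' @inheritParams auroc
#' @return an object of class \code{meld_roc}: a data.frame with columns
#'   \code{threshold}, \code{fpr}, \code{tpr}, plus attributes \code{auroc},
#'   \code{n}, \code{n_events}.
#' @examples
#' rc <- roc_curve(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
#' plot(rc)
#' @export
roc_curve <- function(scores, events) {
  ev <- check_roc_input(scores, events)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  e <- ev[ord]
  keep <- !duplicated(s)                 # last index of each tie group
  tp <- cumsum(e)
  fp <- cumsum(!e)
  grp_end <- c(which(keep)[-1] - 1L, length(s))
  thr <- s[keep]
  curve <- data.frame(
    threshold = c(Inf, thr),
    fpr = c(0, fp[grp_end] / sum(!ev)),
    tpr = c(0, tp[grp_end] / sum(ev))
  )
  structure(curve,
            auroc = auroc(scores, events),
            n = length(scores), n_events = sum(ev),
            class = c("meld_roc", "data.frame"))
}

#' @export
print.meld_roc <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, n = %d (%d events), AUROC = %.4f\n",
              nrow(x), attr(x, "n"), attr(x, "n_events"),
              attr(x, "auroc")))
  invisible(x)
}

#' @export
plot.meld_roc <- function(x, ...) {
  plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "1 - specificity", ylab = "Sensitivity", ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Confidence interval for an AUROC
#'
#' Two methods: \code{"delong"} computes the nonparametric structural-
#' components variance estimator and a normal-theory interval truncated to
#' [0, 1]; \code{"bootstrap"} takes the percentile interval over stratified
#' (event / non-event) resamples under a fixed seed.
#'
#' @inheritParams auroc
#' @param level confidence level (default 0.95).
#' @param method \code{"delong"} or \code{"bootstrap"}.
#' @param B number of bootstrap resamples.
#' @param seed seed for the bootstrap.
#' @return a list with \code{auroc}, \code{ci_low}, \code{ci_high},
#'   \code{se} (DeLong only), \code{method} and \code{level}.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(50), rnorm(50, 1))
#' auroc_ci(x, rep(c(FALSE, TRUE), each = 50))
#' @export
auroc_ci <- function(scores, events, level = 0.95, method = c("delong",
                                                              "bootstrap"),
                     B = 2000L, seed = 1L) {
  method <- match.arg(method)
  ev <- check_roc_input(scores, events)
  a <- auroc(scores, events)
  if (method == "delong") {
    if (sum(ev) < 2 || sum(!ev) < 2) {
      stop("DeLong interval needs at least 2 events and 2 non-events")
    }
    se <- delong_se(scores, ev)
    if (se == 0) {
      warning("degenerate DeLong variance; interval collapses to a point")
    }
    z <- stats::qnorm(1 - (1 - level) / 2)
    lo <- clamp(a - z * se, 0, 1)
    hi <- clamp(a + z * se, 0, 1)
    list(auroc = a, ci_low = lo, ci_high = hi, se = se,
         method = "delong", level = level)
  } else {
    i1 <- which(ev)
    i0 <- which(!ev)
    boots <- with_seed(seed, {
      vapply(seq_len(B), function(b) {
        idx <- c(sample(i1, length(i1), replace = TRUE),
                 sample(i0, length(i0), replace = TRUE))
        auroc(scores[idx], ev[idx])
      }, numeric(1))
    })
    qs <- stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                          names = FALSE, type = 7)
    list(auroc = a, ci_low = qs[1], ci_high = qs[2], se = NA_real_,
         method = "bootstrap", level = level)
  }
}

# DeLong structural components: V10 over events, V01 over non-events
delong_se <- function(scores, ev) {
  x <- scores[ev]
  y <- scores[!ev]
  m <- length(x)
  n <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  v10 <- (r_all[seq_len(m)] - rank(x, ties.method = "average")) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(y, ties.method = "average")) / m
  s10 <- if (m > 1) stats::var(v10) else 0
  s01 <- if (n > 1) stats::var(v01) else 0
  sqrt(s10 / m + s01 / n)
}

#' Sub-cohort AUROC matrix
#'
#' Computes, for each score and each sub-cohort, the AUROC for 90-day
#' mortality with its confidence interval and the clinical-usefulness flag
#' (strictly greater than the 0.700 threshold). Patients with a missing
#' score are dropped per score within subgroup (complete case). Subgroups
#' with fewer than 2 events or 2 non-events are flagged not estimable
#' rather than raising an error.
#'
#' @param scored a scored cohort (output of \code{\link{score_cohort}})
#'   containing the score columns and an outcome column.
#' @param score_cols character vector of score column names.
#' @param outcome_col name of the logical outcome column.
#' @param subgroups named list of logical vectors (length \code{nrow(scored)})
#'   selecting each sub-cohort, or \code{NULL} for the built-in set of
#'   \code{\link{default_subgroups}}.
#' @param ci_method passed to \code{\link{auroc_ci}}.
#' @param threshold acceptability threshold on the AUROC (strict).
#' @param pediatric_cutoff age (years, exclusive) defining the pediatric
#'   subgroup in the built-in set; 16 by default, 12 available.
#' @return a data.frame with one row per (subgroup, score): \code{subgroup},
#'   \code{score}, \code{n}, \code{n_events}, \code{auroc}, \code{ci_low},
#'   \code{ci_high}, \code{acceptable}, \code{estimable}.
#' @examples
#' sc <- score_cohort(generate_cohort(cohort_spec(n = 400, seed = 7)))
#' head(auroc_matrix(sc))
#' @export
auroc_matrix <- function(scored,
                         score_cols = c("meld", "meso", "meld_na", "ukeld",
                                        "imeld", "refit_meld",
                                        "refit_meld_na", "up_meld", "peld"),
                         outcome_col = "died_90d",
                         subgroups = NULL,
                         ci_method = "delong",
                         threshold = 0.700,
                         pediatric_cutoff = 16) {
  if (is.null(subgroups)) {
    subgroups <- default_subgroups(scored, pediatric_cutoff)
  }
  outcome <- as.logical(scored[[outcome_col]])
  rows <- list()
  for (g in names(subgroups)) {
    sel <- subgroups[[g]] & !is.na(outcome)
    for (s in score_cols) {
      x <- scored[[s]][sel]
      y <- outcome[sel]
      cc <- !is.na(x)
      x <- x[cc]
      y <- y[cc]
      estimable <- sum(y) >= 2 && sum(!y) >= 2
      if (estimable) {
        ci <- auroc_ci(x, y, method = ci_method)
        row <- data.frame(subgroup = g, score = s, n = length(x),
                          n_events = sum(y), auroc = ci$auroc,
                          ci_low = ci$ci_low, ci_high = ci$ci_high,
                          acceptable = ci$auroc > threshold,
                          estimable = TRUE)
      } else {
        row <- data.frame(subgroup = g, score = s, n = length(x),
                          n_events = sum(y), auroc = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          acceptable = NA, estimable = FALSE)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Built-in sub-cohort filters
#'
#' The standard validation sub-cohorts: all cases, children/adults,
#' first listing vs. listed for re-transplantation, and each major
#' indication group with its complement.
#'
#' @param cohort a cohort data.frame.
#' @param pediatric_cutoff age in years (exclusive) below which a patient
#'   counts as a child.
#' @return a named list of logical selection vectors.
#' @export
default_subgroups <- function(cohort, pediatric_cutoff = 16) {
  age <- cohort$age_years
  ind <- cohort$indication
  retx <- as.logical(cohort$retransplant)
  list(
    all_cases = rep(TRUE, nrow(cohort)),
    children = age < pediatric_cutoff,
    adults = age >= pediatric_cutoff,
    no_previous_tx = !retx,
    listed_for_retx = retx,
    no_cirrhosis = ind != "cirrhosis",
    cirrhosis = ind == "cirrhosis",
    no_cancer = ind != "cancers",
    cancer = ind == "cancers",
    no_metabolic = ind != "metabolic",
    metabolic = ind == "metabolic",
    no_acute_failure = ind != "acute_failure",
    acute_failure = ind == "acute_failure",
    no_cholestatic = ind != "cholestatic",
    cholestatic = ind == "cholestatic"
  )
}
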