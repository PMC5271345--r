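#' @name scores
#' @title MELD-family prognostic scores for end-stage liver disease
#'
#' @description
#' Vectorised calculators for nine published waiting-list prognostic scores,
#' each implementing its published variable-handling rules exactly: input
#' floors and caps, creatinine substitution under hemodialysis, and integer
#' rounding where the score is defined in points.
#'
#' The handling rules are:
#' \itemize{
#'   \item \strong{MELD}: creatinine, bilirubin (mg/dl) and INR floored at
#'     1.0; creatinine capped at 4.0 mg/dl and set to 4.0 under dialysis;
#'     \eqn{10(0.957\ln cr + 0.378\ln bili + 1.120\ln INR + 0.643)}, rounded
#'     to the nearest integer, maximum 40 points.
#'   \item \strong{MESO index}: integer MELD divided by serum sodium
#'     (mmol/l), times 10. No sodium clamp.
#'   \item \strong{MELD-Na}: \eqn{MELD - Na - 0.025 \cdot MELD \cdot
#'     (140 - Na) + 140} with sodium clamped to 125--140 mmol/l, rounded to
#'     the nearest integer.
#'   \item \strong{UKELD}: \eqn{1.485\ln cr + 3.13\ln bili + 5.395\ln INR -
#'     81.565\ln Na + 435} in SI units, creatinine clamped to 1--400 umol/l,
#'     sodium to 112--150 mmol/l, bilirubin (umol/l) and INR floored at 1.0.
#'   \item \strong{iMELD}: \eqn{MELD + 0.3 \cdot age - 0.7 \cdot Na + 100}.
#'     No sodium clamp.
#'   \item \strong{refitMELD}: \eqn{8.485\ln cr + 4.082\ln bili +
#'     10.671\ln INR + 7.432}, creatinine clamped to 0.8--3.0 mg/dl (3.0
#'     under dialysis), INR clamped to 1.0--3.0, bilirubin floored at 1.0.
#'   \item \strong{refitMELD-Na}: \eqn{6.792\ln cr + 4.258\ln bili +
#'     8.29\ln INR + 0.652(140-Na) - 0.194(140-Na) \cdot BiliCC + 6.327},
#'     sodium clamped to 125--140; creatinine/bilirubin/INR as refitMELD;
#'     BiliCC is the floored bilirubin additionally capped at 20 mg/dl,
#'     entered untransformed.
#'   \item \strong{upMELD}: \eqn{1.266\ln(1+cr) + 0.939\ln(1+bili) +
#'     1.658\ln(1+INR)}, all three floored at 1.0; creatinine capped at
#'     4.0 mg/dl with or without renal replacement therapy (dialysis does
#'     not alter creatinine for this score).
#'   \item \strong{PELD}: \eqn{10(0.436 \cdot [age<1y] - 0.687\ln alb +
#'     0.480\ln bili + 1.857\ln INR + 0.667 \cdot [growth failure])};
#'     growth failure forced to 0 above 219 months of age; unrounded, may
#'     be negative.
#' }
#'
#' Missing required inputs yield \code{NA} (complete-case; no imputation).
#'
#' @param creatinine serum creatinine, mg/dl unless stated otherwise.
#' @param bilirubin total bilirubin, mg/dl unless stated otherwise.
#' @param inr International Normalized Ratio.
#' @param sodium serum sodium, mmol/l.
#' @param dialysis logical: patient on hemodialysis.
#' @param age age at listing in years (fractional).
#' @param albumin serum albumin, g/dl.
#' @param growth_failure logical: height or weight at or below -2 SD of the
#'   sex/age reference.
#' @return numeric vector; \code{meld} and \code{meld_na} are integer-valued
#'   points, the others continuous.
#' @examples
#' meld(1.2, 2.5, 1.5)                    # 16
#' meld(10, 50, 12)                       # 40 (capped)
#' up_meld(1, 1, 1)                       # 2.678 (analytic floor)
#' peld(3.0, 3, 2, age = 0.5, growth_failure = TRUE)
NULL

#' @rdname scores
#' @export
meld <- function(creatinine, bilirubin, inr, dialysis = FALSE) {
  cr <- clamp(ifelse(rep_len(dialysis, length(creatinine)), 4.0, creatinine),
              1.0, 4.0)
  bi <- clamp(bilirubin, 1.0, NULL)
  ri <- clamp(inr, 1.0, NULL)
  raw <- 10 * (0.957 * log(cr) + 0.378 * log(bi) + 1.120 * log(ri) + 0.643)
  pmin(round_half_up(raw), 40)
}

#' @rdname scores
#' @export
meso <- function(creatinine, bilirubin, inr, sodium, dialysis = FALSE) {
  if (any(!is.na(sodium) & sodium <= 0)) stop("sodium must be positive")
  meld(creatinine, bilirubin, inr, dialysis) / sodium * 10
}

#' @rdname scores
#' @export
meld_na <- function(creatinine, bilirubin, inr, sodium, dialysis = FALSE) {
  m <- meld(creatinine, bilirubin, inr, dialysis)
  na <- clamp(sodium, 125, 140)
  round_half_up(m - na - 0.025 * m * (140 - na) + 140)
}

#' @rdname scores
#' @param creatinine_umoll,bilirubin_umoll creatinine and bilirubin in
#'   umol/l (UKELD works in SI units).
#' @export
ukeld <- function(creatinine_umoll, bilirubin_umoll, inr, sodium) {
  cr <- clamp(creatinine_umoll, 1, 400)
  bi <- clamp(bilirubin_umoll, 1.0, NULL)
  ri <- clamp(inr, 1.0, NULL)
  na <- clamp(sodium, 112, 150)
  1.485 * log(cr) + 3.13 * log(bi) + 5.395 * log(ri) - 81.565 * log(na) + 435
}

#' @rdname scores
#' @export
imeld <- function(creatinine, bilirubin, inr, sodium, age, dialysis = FALSE) {
  m <- meld(creatinine, bilirubin, inr, dialysis)
  m + 0.3 * age - 0.7 * sodium + 100
}

#' @rdname scores
#' @export
refit_meld <- function(creatinine, bilirubin, inr, dialysis = FALSE) {
  cr <- clamp(ifelse(rep_len(dialysis, length(creatinine)), 3.0, creatinine),
              0.8, 3.0)
  bi <- clamp(bilirubin, 1.0, NULL)
  ri <- clamp(inr, 1.0, 3.0)
  8.485 * log(cr) + 4.082 * log(bi) + 10.671 * log(ri) + 7.432
}

#' @rdname scores
#' @export
refit_meld_na <- function(creatinine, bilirubin, inr, sodium,
                          dialysis = FALSE) {
  cr <- clamp(ifelse(rep_len(dialysis, length(creatinine)), 3.0, creatinine),
              0.8, 3.0)
  bi <- clamp(bilirubin, 1.0, NULL)
  ri <- clamp(inr, 1.0, 3.0)
  na <- clamp(sodium, 125, 140)
  bili_cc <- clamp(bi, NULL, 20)
  6.792 * log(cr) + 4.258 * log(bi) + 8.29 * log(ri) +
    0.652 * (140 - na) - 0.194 * (140 - na) * bili_cc + 6.327
}

#' @rdname scores
#' @export
up_meld <- function(creatinine, bilirubin, inr) {
  cr <- clamp(creatinine, 1.0, 4.0)
  bi <- clamp(bilirubin, 1.0, NULL)
  ri <- clamp(inr, 1.0, NULL)
  1.266 * log(1 + cr) + 0.939 * log(1 + bi) + 1.658 * log(1 + ri)
}

#' @rdname scores
#' @export
peld <- function(albumin, bilirubin, inr, age, growth_failure = FALSE) {
  if (any(!is.na(albumin) & albumin <= 0)) stop("albumin must be positive")
  n <- max(length(albumin), length(bilirubin), length(inr), length(age),
           length(growth_failure))
  age <- rep_len(age, n)
  gf <- rep_len(as.logical(growth_failure), n)
  # growth failure is defined only up to 219 months of age
  gf <- gf & !is.na(age) & age <= 219 / 12
  10 * (0.436 * as.numeric(age < 1) - 0.687 * log(albumin) +
          0.480 * log(bilirubin) + 1.857 * log(inr) + 0.667 * as.numeric(gf))
}

#' Compute all nine scores for a cohort
#'
#' Applies every score calculator to a cohort data frame (the schema of
#' \code{\link{read_cohort}} / \code{\link{generate_cohort}}) and records,
#' per patient, which handling rules fired. Scores whose required inputs are
#' missing come back \code{NA} for that patient; no imputation is done.
#'
#' @param cohort a cohort data frame with the columns of
#'   \code{\link{cohort_schema}}.
#' @param peld_max_age upper age bound (years, exclusive) for PELD
#'   eligibility, or \code{NULL} (default) to compute PELD in all age groups.
#'   Set to 12 to mirror OPTN practice.
#' @return the input with nine score columns (\code{meld}, \code{meso},
#'   \code{meld_na}, \code{ukeld}, \code{imeld}, \code{refit_meld},
#'   \code{refit_meld_na}, \code{up_meld}, \code{peld}) and an
#'   \code{applied_rules} character column (semicolon-joined audit strings)
#'   appended.
#' @examples
#' coh <- generate_cohort(cohort_spec(n = 50, seed = 1))
#' sc <- score_cohort(coh)
#' summary(sc$meld)
#' @export
score_cohort <- function(cohort, peld_max_age = NULL) {
  labs <- lab_panel(
    creatinine = cohort$creatinine, bilirubin = cohort$bilirubin,
    inr = cohort$inr, sodium = cohort$sodium_mmol_l,
    albumin = cohort$albumin, ptt = cohort$ptt_s,
    creatinine_unit = cohort$creatinine_unit,
    bilirubin_unit = cohort$bilirubin_unit,
    albumin_unit = cohort$albumin_unit
  )
  dial <- on_dialysis(cohort)
  age <- cohort$age_years
  gf <- as.logical(cohort$growth_failure)

  out <- cohort
  out$meld <- meld(labs$creatinine_mgdl, labs$bilirubin_mgdl, labs$inr, dial)
  out$meso <- meso(labs$creatinine_mgdl, labs$bilirubin_mgdl, labs$inr,
                   labs$sodium, dial)
  out$meld_na <- meld_na(labs$creatinine_mgdl, labs$bilirubin_mgdl, labs$inr,
                         labs$sodium, dial)
  out$ukeld <- ukeld(labs$creatinine_umoll, labs$bilirubin_umoll, labs$inr,
                     labs$sodium)
  out$imeld <- imeld(labs$creatinine_mgdl, labs$bilirubin_mgdl, labs$inr,
                     labs$sodium, age, dial)
  out$refit_meld <- refit_meld(labs$creatinine_mgdl, labs$bilirubin_mgdl,
                               labs$inr, dial)
  out$refit_meld_na <- refit_meld_na(labs$creatinine_mgdl,
                                     labs$bilirubin_mgdl, labs$inr,
                                     labs$sodium, dial)
  out$up_meld <- up_meld(labs$creatinine_mgdl, labs$bilirubin_mgdl, labs$inr)
  out$peld <- peld(labs$albumin_gdl, labs$bilirubin_mgdl, labs$inr, age, gf)
  if (!is.null(peld_max_age)) {
    out$peld[is.na(age) | age >= peld_max_age] <- NA_real_
  }
  out$applied_rules <- applied_rules(labs, dial, age, gf)
  out
}

#' Score a single patient
#'
#' Single-patient wrapper around \code{\link{score_cohort}}; returns a list
#' with the nine scores and the audit trail of handling rules that fired.
#'
#' @param patient a one-row cohort data frame.
#' @inheritParams score_cohort
#' @return a list of class \code{score_panel}.
#' @export
score_panel <- function(patient, peld_max_age = NULL) {
  stopifnot(is.data.frame(patient), nrow(patient) == 1)
  sc <- score_cohort(patient, peld_max_age = peld_max_age)
  out <- as.list(sc[, c("meld", "meso", "meld_na", "ukeld", "imeld",
                        "refit_meld", "refit_meld_na", "up_meld", "peld")])
  out$applied_rules <- if (nzchar(sc$applied_rules)) {
    strsplit(sc$applied_rules, ";", fixed = TRUE)[[1]]
  } else character(0)
  class(out) <- "score_panel"
  out
}

#' @export
print.score_panel <- function(x, ...) {
  cat("Prognostic score panel\n")
  for (s in c("meld", "meso", "meld_na", "ukeld", "imeld", "refit_meld",
              "refit_meld_na", "up_meld", "peld")) {
    cat(sprintf("  %-13s %s\n", s,
                if (is.na(x[[s]])) "NA" else format(x[[s]], digits = 6)))
  }
  if (length(x$applied_rules)) {
    cat("Applied rules:", paste(x$applied_rules, collapse = "; "), "\n")
  }
  invisible(x)
}

# Dialysis flag: >= 1 session/week, unless an explicit on_dialysis column
# overrides it.
on_dialysis <- function(cohort) {
  if (!is.null(cohort$on_dialysis)) {
    return(as.logical(cohort$on_dialysis))
  }
  !is.na(cohort$dialysis_per_week) & cohort$dialysis_per_week >= 1
}

# Per-patient audit of which clamps/substitutions changed an input.
applied_rules <- function(labs, dial, age, gf) {
  n <- nrow(labs)
  rules <- vector("list", n)
  add <- function(cond, tag) {
    cond <- !is.na(cond) & cond
    for (i in which(cond)) rules[[i]] <<- c(rules[[i]], tag)
  }
  cr <- labs$creatinine_mgdl
  bi <- labs$bilirubin_mgdl
  ri <- labs$inr
  na <- labs$sodium
  add(dial, "creatinine_dialysis_substitution")
  add(!dial & cr < 1, "meld_creatinine_floor_1.0")
  add(!dial & cr > 4, "meld_creatinine_cap_4.0")
  add(bi < 1, "bilirubin_floor_1.0")
  add(ri < 1, "inr_floor_1.0")
  add(na < 125 | na > 140, "sodium_clamp_125_140")
  add(na < 112 | na > 150, "ukeld_sodium_clamp_112_150")
  add(labs$creatinine_umoll > 400, "ukeld_creatinine_cap_400")
  add(!dial & cr < 0.8, "refit_creatinine_floor_0.8")
  add(!dial & cr > 3, "refit_creatinine_cap_3.0")
  add(ri > 3, "refit_inr_cap_3.0")
  add(bi > 20, "bilicc_cap_20")
  add(gf & age > 219 / 12, "growth_failure_zeroed_over_219m")
  vapply(rules, function(r) paste(r, collapse = ";"), character(1))
}
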