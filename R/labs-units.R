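#' Convert a laboratory concentration between units
#'
#' Converts creatinine, bilirubin or albumin values between conventional and
#' SI units using standard clinical-chemistry factors: creatinine
#' 1 mg/dl = 88.42 umol/l, bilirubin 1 mg/dl = 17.104 umol/l, albumin
#' 1 g/dl = 10 g/l.
#'
#' @param value numeric vector of strictly positive concentrations (NA allowed,
#'   propagated).
#' @param from,to source and target unit. One of \code{"mg/dl"},
#'   \code{"umol/l"} for creatinine and bilirubin; \code{"g/dl"}, \code{"g/l"}
#'   for albumin. The spelling \code{"μmol/l"} is accepted as a synonym
#'   of \code{"umol/l"}.
#' @param analyte one of \code{"creatinine"}, \code{"bilirubin"},
#'   \code{"albumin"}.
#' @return numeric vector in the target unit. Same-unit conversion is the
#'   identity; round-trips are exact to within 1e-9 relative error.
#' @examples
#' convert_concentration(1, "mg/dl", "umol/l", "creatinine")   # 88.42
#' convert_concentration(70, "umol/l", "mg/dl", "creatinine")  # 0.7917
#' convert_concentration(31, "g/l", "g/dl", "albumin")         # 3.1
#' @export
convert_concentration <- function(value, from, to, analyte) {
  from <- normalize_unit(from)
  to <- normalize_unit(to)
  analyte <- match.arg(analyte, c("creatinine", "bilirubin", "albumin"))
  ok <- is.na(value) | value > 0
  if (!all(ok)) stop("concentration values must be strictly positive")
  units <- switch(analyte,
    creatinine = c(conventional = "mg/dl", si = "umol/l", factor = NA),
    bilirubin = c(conventional = "mg/dl", si = "umol/l", factor = NA),
    albumin = c(conventional = "g/dl", si = "g/l", factor = NA)
  )
  fac <- switch(analyte, creatinine = 88.42, bilirubin = 17.104, albumin = 10)
  conv <- units[["conventional"]]
  si <- units[["si"]]
  for (u in c(from, to)) {
    if (!u %in% c(conv, si)) {
      stop(sprintf("unsupported unit '%s' for analyte '%s'", u, analyte))
    }
  }
  if (from == to) return(value)
  if (from == conv) value * fac else value / fac
}

# Canonical spelling of unit tags; tolerant of the mu glyph and case.
normalize_unit <- function(u) {
  u <- tolower(trimws(u))
  u[u %in% c("μmol/l", "umol/l", "µmol/l")] <- "umol/l"
  u
}

#' Clamp a value to a closed interval
#'
#' The floor/cap primitive behind every published score handling rule:
#' values outside the stated range are set to the nearest bound. Either
#' bound may be absent.
#'
#' @param value numeric vector.
#' @param lower,upper bounds; \code{NULL} or \code{NA} means unbounded on
#'   that side.
#' @return clamped numeric vector; idempotent.
#' @examples
#' clamp(5.2, 1, 4)    # 4
#' clamp(0.4, 1, NULL) # 1
#' @export
clamp <- function(value, lower = NULL, upper = NULL) {
  lo <- if (is.null(lower) || all(is.na(lower))) -Inf else lower
  hi <- if (is.null(upper) || all(is.na(upper))) Inf else upper
  if (any(lo > hi)) stop("clamp: lower bound exceeds upper bound")
  pmin(pmax(value, lo), hi)
}

#' Assemble a laboratory panel in canonical units
#'
#' Normalises one or more patients' laboratory values to the canonical units
#' the score formulas use: creatinine and bilirubin are carried in both mg/dl
#' and umol/l, albumin in g/dl, sodium in mmol/l, PTT in seconds. Missing
#' values stay \code{NA} and propagate into the scores that need them.
#'
#' @param creatinine,bilirubin,albumin numeric vectors with their unit tags
#'   \code{creatinine_unit} (\code{"mg/dl"}/\code{"umol/l"}), etc.
#' @param inr dimensionless INR.
#' @param sodium serum sodium, mmol/l.
#' @param ptt partial thromboplastin time, seconds (optional covariate).
#' @param creatinine_unit,bilirubin_unit,albumin_unit unit tags (recycled).
#' @return a data.frame of class \code{lab_panel} with columns
#'   \code{creatinine_mgdl}, \code{creatinine_umoll}, \code{bilirubin_mgdl},
#'   \code{bilirubin_umoll}, \code{inr}, \code{sodium}, \code{albumin_gdl},
#'   \code{ptt}.
#' @export
lab_panel <- function(creatinine, bilirubin, inr, sodium,
                      albumin = NA_real_, ptt = NA_real_,
                      creatinine_unit = "mg/dl",
                      bilirubin_unit = "mg/dl",
                      albumin_unit = "g/dl") {
  n <- max(length(creatinine), length(bilirubin), length(inr), length(sodium),
           length(albumin), length(ptt))
  creatinine <- rep_len(creatinine, n)
  bilirubin <- rep_len(bilirubin, n)
  inr <- rep_len(inr, n)
  sodium <- rep_len(sodium, n)
  albumin <- rep_len(albumin, n)
  ptt <- rep_len(ptt, n)
  cu <- normalize_unit(rep_len(creatinine_unit, n))
  bu <- normalize_unit(rep_len(bilirubin_unit, n))
  au <- normalize_unit(rep_len(albumin_unit, n))

  to_both <- function(x, unit, analyte) {
    mgdl <- ifelse(unit == "mg/dl", x,
                   convert_concentration(x, "umol/l", "mg/dl", analyte))
    umoll <- ifelse(unit == "umol/l", x,
                    convert_concentration(x, "mg/dl", "umol/l", analyte))
    list(mgdl = mgdl, umoll = umoll)
  }
  cr <- to_both(creatinine, cu, "creatinine")
  bi <- to_both(bilirubin, bu, "bilirubin")
  alb <- ifelse(au == "g/dl", albumin,
                convert_concentration(albumin, "g/l", "g/dl", "albumin"))
  out <- data.frame(
    creatinine_mgdl = cr$mgdl, creatinine_umoll = cr$umoll,
    bilirubin_mgdl = bi$mgdl, bilirubin_umoll = bi$umoll,
    inr = inr, sodium = sodium, albumin_gdl = alb, ptt = ptt
  )
  class(out) <- c("lab_panel", "data.frame")
  out
}

# round half-up on the positive axis, as clinical calculators do
# (base round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)
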