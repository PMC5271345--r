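#' Specification for a synthetic waiting-list cohort
#'
#' Bundles the parameters of the synthetic cohort generator. The defaults
#' emulate a single-centre liver-transplant waiting list of 818 patients:
#' 28.4% pediatric (age < 16 years), 7.3% on hemodialysis, an indication mix
#' over the ten ELTR diagnosis groups, log-normal-like laboratory marginals
#' with SI-unit medians (creatinine 70 umol/l, bilirubin 66 umol/l, INR 1.4,
#' sodium 138 mmol/l, albumin 31 g/l, PTT 41 s) truncated to observed
#' ranges, and a 90-day waiting-list mortality of 9% generated through a
#' logistic link on a driver score (iMELD by default, slope 0.13 per point,
#' calibrated once so the driver's whole-cohort AUROC is about 0.80 at the
#' 9% event rate).
#'
#' @param n cohort size.
#' @param pediatric_fraction proportion of patients aged under 16 years.
#' @param dialysis_fraction proportion on hemodialysis.
#' @param indication_mix named numeric vector of 10 proportions over the
#'   ELTR diagnosis groups; must sum to 1.
#' @param lab_distributions list of per-analyte distribution parameters; see
#'   the default for the expected structure (log-normal \code{meanlog}/
#'   \code{sdlog} with truncation bounds, except sodium which is truncated
#'   normal).
#' @param mortality_link list with \code{slope}, \code{driver} (a score
#'   column name), \code{target} (marginal 90-day mortality) and optionally
#'   a fixed \code{intercept}. When \code{intercept} is \code{NULL} it is
#'   calibrated at generation time so the mean event probability equals
#'   \code{target}.
#' @param seed integer seed; all randomness in \code{\link{generate_cohort}}
#'   flows from it.
#' @return a list of class \code{cohort_spec}.
#' @seealso \code{\link{generate_cohort}}, \code{\link{calibrate_intercept}}
#' @export
cohort_spec <- function(n = 818,
                        pediatric_fraction = 0.284,
                        dialysis_fraction = 0.073,
                        indication_mix = default_indication_mix(),
                        lab_distributions = default_lab_distributions(),
                        mortality_link = list(intercept = NULL, slope = 0.13,
                                              driver = "imeld",
                                              target = 0.09),
                        seed = 1L) {
  if (n <= 0) stop("cohort size n must be positive")
  if (abs(sum(indication_mix) - 1) > 1e-9) {
    stop("indication_mix must sum to 1")
  }
  fr <- c(pediatric_fraction, dialysis_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  spec <- list(n = as.integer(n), pediatric_fraction = pediatric_fraction,
               dialysis_fraction = dialysis_fraction,
               indication_mix = indication_mix,
               lab_distributions = lab_distributions,
               mortality_link = mortality_link, seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  spec
}

#' Default indication mix over the ten ELTR diagnosis groups
#'
#' Group counts of the emulated waiting list, normalised to a proper
#' probability vector. The published group counts total 855 of 818
#' patients because categories overlap (re-transplant cases also carry a
#' diagnosis); a single categorical indication per patient requires
#' normalising.
#'
#' @return named numeric vector of 10 proportions summing to 1.
#' @export
default_indication_mix <- function() {
  counts <- c(acute_failure = 91, cholestatic = 74, congenital_biliary = 93,
              cirrhosis = 234, cancers = 112, metabolic = 70,
              budd_chiari = 10, benign_polycystic = 28,
              retransplantation = 138, other = 5)
  counts / sum(counts)
}

# Laboratory marginals: log-normal medians from the emulated cohort,
# truncated to its observed ranges; sodium is (truncated) normal.
default_lab_distributions <- function() {
  list(
    creatinine = list(dist = "lnorm", meanlog = log(70), sdlog = 0.80,
                      lower = 0.43, upper = 1100, unit = "umol/l"),
    bilirubin = list(dist = "lnorm", meanlog = log(66), sdlog = 1.30,
                     lower = 1.6, upper = 1710, unit = "umol/l"),
    inr = list(dist = "lnorm", meanlog = log(1.4), sdlog = 0.35,
               lower = 0.9, upper = 21.2),
    sodium = list(dist = "norm", mean = 138, sd = 4.5,
                  lower = 121, upper = 161),
    albumin = list(dist = "lnorm", meanlog = log(31), sdlog = 0.25,
                   lower = 3, upper = 53, unit = "g/l"),
    ptt = list(dist = "lnorm", meanlog = log(41), sdlog = 0.35,
               lower = 22, upper = 160)
  )
}

# inverse-CDF sampling from a truncated lognormal/normal marginal
rtrunc_marginal <- function(n, p) {
  if (p$dist == "lnorm") {
    lo <- stats::plnorm(p$lower, p$meanlog, p$sdlog)
    hi <- stats::plnorm(p$upper, p$meanlog, p$sdlog)
    stats::qlnorm(stats::runif(n, lo, hi), p$meanlog, p$sdlog)
  } else {
    lo <- stats::pnorm(p$lower, p$mean, p$sd)
    hi <- stats::pnorm(p$upper, p$mean, p$sd)
    stats::qnorm(stats::runif(n, lo, hi), p$mean, p$sd)
  }
}

#' Generate a synthetic waiting-list cohort
#'
#' Draws a fully synthetic cohort of liver-transplant waiting-list patients
#' with the marginal structure described in \code{\link{cohort_spec}} and a
#' score-linked 90-day mortality mechanism: each patient's event probability
#' is \code{plogis(intercept + slope * driver_score)} and the binary 90-day
#' death indicator is drawn from it. Laboratory marginals are independent
#' (no correlation structure is imposed). Output is reproducible: the same
#' spec and seed give identical cohorts.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return a data.frame following \code{\link{cohort_schema}}, one row per
#'   patient, with attribute \code{"mortality_intercept"} recording the
#'   intercept actually used.
#' @examples
#' coh <- generate_cohort(cohort_spec(n = 200, seed = 42))
#' mean(coh$died_90d)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n
    ped <- stats::runif(n) < spec$pediatric_fraction

    # ages: children are a mix of infants (log-uniform 0.02-2 y) and older
    # children (uniform 2-16); adults truncated normal on 16-73.6
    age <- numeric(n)
    npd <- sum(ped)
    if (npd > 0) {
      infant <- stats::runif(npd) < 0.4
      a <- numeric(npd)
      a[infant] <- exp(stats::runif(sum(infant), log(0.02), log(2)))
      a[!infant] <- stats::runif(sum(!infant), 2, 16)
      age[ped] <- a
    }
    age[!ped] <- rtrunc_marginal(n - npd, list(dist = "norm", mean = 50,
                                               sd = 11, lower = 16,
                                               upper = 73.6))

    sex <- ifelse(stats::runif(n) < 0.567, "male", "female")

    # anthropometrics: crude height-for-age curve for children, adult
    # heights normal; weight derived from a BMI marginal
    height <- numeric(n)
    height[ped] <- clamp(0.45 + 0.35 * log1p(2 * age[ped]) +
                           stats::rnorm(npd, 0, 0.05), 0.45, 1.85)
    height[!ped] <- rtrunc_marginal(n - npd, list(dist = "norm", mean = 1.70,
                                                  sd = 0.09, lower = 1.40,
                                                  upper = 2.00))
    bmi <- numeric(n)
    bmi[ped] <- rtrunc_marginal(npd, list(dist = "norm", mean = 17, sd = 2.5,
                                          lower = 10.5, upper = 30))
    bmi[!ped] <- rtrunc_marginal(n - npd, list(dist = "lnorm",
                                               meanlog = log(24),
                                               sdlog = 0.18, lower = 10.5,
                                               upper = 48.4))
    weight <- bmi * height^2

    dial <- stats::runif(n) < spec$dialysis_fraction
    dialysis_per_week <- ifelse(dial, sample(1:7, n, replace = TRUE,
                                             prob = c(1, 2, 6, 2, 1, 1, 1)),
                                0L)

    growth_failure <- ped & stats::runif(n) < 0.185
    hu_status <- stats::runif(n) < 0.203
    standard_exception <- stats::runif(n) < 0.256
    indication <- sample(names(spec$indication_mix), n, replace = TRUE,
                         prob = spec$indication_mix)
    retransplant <- indication == "retransplantation"

    ld <- spec$lab_distributions
    creatinine <- rtrunc_marginal(n, ld$creatinine)
    bilirubin <- rtrunc_marginal(n, ld$bilirubin)
    inr <- rtrunc_marginal(n, ld$inr)
    sodium <- rtrunc_marginal(n, ld$sodium)
    albumin <- rtrunc_marginal(n, ld$albumin)
    ptt <- rtrunc_marginal(n, ld$ptt)

    cohort <- data.frame(
      patient_id = sprintf("P%05d", seq_len(n)),
      age_years = age, sex = sex, weight_kg = weight, height_m = height,
      dialysis_per_week = as.integer(dialysis_per_week),
      growth_failure = growth_failure, hu_status = hu_status,
      standard_exception = standard_exception, indication = indication,
      retransplant = retransplant,
      days_on_list = 0L, outcome = "", died_90d = FALSE,
      creatinine = creatinine, creatinine_unit = "umol/l",
      bilirubin = bilirubin, bilirubin_unit = "umol/l",
      inr = inr, sodium_mmol_l = sodium,
      albumin = albumin, albumin_unit = "g/l", ptt_s = ptt,
      stringsAsFactors = FALSE
    )

    # 90-day mortality through a logistic link on the driver score
    link <- spec$mortality_link
    driver <- score_cohort(cohort)[[link$driver]]
    intercept <- link$intercept
    if (is.null(intercept)) {
      intercept <- intercept_for_target(driver, link$slope, link$target)
    }
    p_death <- stats::plogis(intercept + link$slope * driver)
    died_90d <- stats::runif(n) < p_death
    cohort$died_90d <- died_90d

    # waiting time: roughly exponential (median 91.5 d), but deaths within
    # 90 days must have left the list by day 90
    days <- round(stats::rexp(n, rate = log(2) / 91.5))
    days <- pmin(days, 2323)
    d90 <- which(died_90d)
    days[d90] <- round(stats::qexp(
      stats::runif(length(d90)) * stats::pexp(90, log(2) / 91.5),
      log(2) / 91.5))
    cohort$days_on_list <- as.integer(days)

    outcome <- character(n)
    outcome[died_90d] <- "died"
    surv <- which(!died_90d)
    outcome[surv] <- sample(c("transplanted", "died", "delisted"),
                            length(surv), replace = TRUE,
                            prob = c(0.762, 0.102, 0.136))
    cohort$outcome <- outcome

    attr(cohort, "mortality_intercept") <- intercept
    cohort
  })
}

# deterministic bisection: intercept a such that mean(plogis(a + s*x)) = t
intercept_for_target <- function(driver, slope, target) {
  x <- driver[!is.na(driver)]
  f <- function(a) mean(stats::plogis(a + slope * x)) - target
  lo <- -60; hi <- 60
  if (f(lo) > 0 || f(hi) < 0) stop("target mortality unattainable")
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Calibrate the mortality-link intercept for a target event rate
#'
#' Finds, by bisection, the logistic intercept for which the mean simulated
#' 90-day death probability over a large fixed-seed cohort equals the target
#' mortality to within 0.1 percentage points. With slope 0 this reduces to
#' the closed-form logit of the target.
#'
#' @param spec a \code{\link{cohort_spec}} fixing slope and driver score.
#' @param target_mortality target marginal event proportion in (0, 1).
#' @param n_calibration size of the calibration cohort.
#' @return the calibrated intercept (numeric scalar).
#' @examples
#' spec <- cohort_spec(mortality_link = list(intercept = NULL, slope = 0,
#'                                           driver = "imeld", target = 0.09))
#' calibrate_intercept(spec, 0.09)  # = qlogis(0.09)
#' @export
calibrate_intercept <- function(spec, target_mortality,
                                n_calibration = 5000L) {
  stopifnot(inherits(spec, "cohort_spec"),
            target_mortality > 0, target_mortality < 1)
  big <- spec
  big$n <- as.integer(n_calibration)
  big$mortality_link$intercept <- 0  # avoid recursive calibration
  coh <- generate_cohort(big)
  driver <- score_cohort(coh)[[spec$mortality_link$driver]]
  a <- intercept_for_target(driver, spec$mortality_link$slope,
                            target_mortality)
  achieved <- mean(stats::plogis(a + spec$mortality_link$slope *
                                   driver[!is.na(driver)]))
  if (abs(achieved - target_mortality) > 0.001) {
    stop("target mortality unattainable to within 0.1 percentage points")
  }
  a
}

# evaluate code under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
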