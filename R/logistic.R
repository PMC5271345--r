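#' Binary logistic regression with odds ratios
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares, deviance tolerance 1e-12, at most 100 iterations) returning
#' Wald standard errors, odds ratios with 95% Wald confidence intervals
#' and two-sided Wald p-values. Perfect separation is detected and raised
#' as an error naming the offending covariate.
#'
#' @param design data.frame of numeric/logical covariates (no intercept
#'   column; one is added).
#' @param outcome logical (or 0/1) event vector, same length as
#'   \code{nrow(design)}. Rows with any missing value are dropped
#'   (complete case).
#' @param level confidence level for the odds-ratio intervals.
#' @return an object of class \code{meld_logit}: list with \code{terms}
#'   (data.frame: term, coef, se, odds_ratio, ci_low, ci_high, p_value),
#'   \code{log_likelihood}, \code{n}, \code{n_events}, \code{fit} (the
#'   underlying \code{glm}).
#' @examples
#' coh <- score_cohort(generate_cohort(cohort_spec(n = 500, seed = 3)))
#' fit <- fit_logistic(coh[, "imeld", drop = FALSE], coh$died_90d)
#' summary(fit)
#' @export
fit_logistic <- function(design, outcome, level = 0.95) {
  stopifnot(is.data.frame(design))
  y <- as.numeric(as.logical(outcome))
  if (length(y) != nrow(design)) stop("design/outcome length mismatch")
  cc <- stats::complete.cases(design) & !is.na(y)
  design <- design[cc, , drop = FALSE]
  y <- y[cc]
  if (nrow(design) <= ncol(design) + 1) {
    stop("too few observations for the number of terms")
  }
  for (nm in names(design)) {
    v <- design[[nm]]
    if (is.logical(v)) design[[nm]] <- as.numeric(v)
    if (length(unique(design[[nm]])) < 2) {
      stop(sprintf("covariate '%s' is constant", nm))
    }
  }
  dat <- cbind(.y = y, design)
  sep_msg <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_msg <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (!fit$converged) stop("logistic fit did not converge in 100 iterations")
  cf <- stats::coef(fit)
  if (sep_msg && any(abs(cf[-1]) > 15, na.rm = TRUE)) {
    bad <- names(which.max(abs(cf[-1])))
    stop(sprintf("perfect separation detected for covariate '%s'", bad))
  }
  sm <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - level) / 2)
  terms <- data.frame(
    term = rownames(sm),
    coef = sm[, 1], se = sm[, 2],
    odds_ratio = exp(sm[, 1]),
    ci_low = exp(sm[, 1] - z * sm[, 2]),
    ci_high = exp(sm[, 1] + z * sm[, 2]),
    p_value = sm[, 4],
    row.names = NULL
  )
  structure(list(terms = terms,
                 log_likelihood = as.numeric(stats::logLik(fit)),
                 n = length(y), n_events = sum(y), level = level, fit = fit),
            class = "meld_logit")
}

#' @export
print.meld_logit <- function(x, digits = 4, ...) {
  cat(sprintf("Logistic regression: n = %d, events = %d, logLik = %.3f\n",
              x$n, x$n_events, x$log_likelihood))
  print(format(x$terms, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
summary.meld_logit <- function(object, ...) {
  object
}

#' @export
coef.meld_logit <- function(object, ...) {
  stats::setNames(object$terms$coef, object$terms$term)
}

#' @export
predict.meld_logit <- function(object, newdata = NULL, type = "response",
                               ...) {
  stats::predict(object$fit, newdata = newdata, type = type, ...)
}

#' @export
residuals.meld_logit <- function(object, ...) {
  stats::residuals(object$fit, ...)
}

#' Univariable screen of candidate risk factors
#'
#' Fits one single-covariate logistic regression per candidate and flags
#' which candidates are significant at the given level, for carry-forward
#' into multivariable modelling. Degenerate candidates (constant, or
#' perfectly separating the outcome) are flagged not estimable instead of
#' raising.
#'
#' @param data data.frame holding the candidate columns.
#' @param outcome logical event vector.
#' @param candidates character vector of column names.
#' @param alpha significance threshold (default 0.05).
#' @return a data.frame: \code{term}, \code{p_value}, \code{odds_ratio},
#'   \code{ci_low}, \code{ci_high}, \code{estimable}, \code{significant}.
#' @export
univariable_screen <- function(data, outcome, candidates, alpha = 0.05) {
  stopifnot(all(candidates %in% names(data)))
  rows <- lapply(candidates, function(nm) {
    res <- tryCatch(fit_logistic(data[, nm, drop = FALSE], outcome),
                    error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(term = nm, p_value = NA_real_, odds_ratio = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_, estimable = FALSE,
                 significant = FALSE,
                 reason = conditionMessage(res))
    } else {
      tr <- res$terms[res$terms$term != "(Intercept)", ]
      data.frame(term = nm, p_value = tr$p_value, odds_ratio = tr$odds_ratio,
                 ci_low = tr$ci_low, ci_high = tr$ci_high, estimable = TRUE,
                 significant = tr$p_value < alpha, reason = "")
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Resolve collinear candidate groups before multivariable modelling
#'
#' From each declared group of collinear variables, keeps only the member
#' with the smallest univariable p-value (ties broken by declaration
#' order), mirroring judgment-based collinearity exclusion rather than
#' automatic VIF screening. Non-grouped significant candidates pass
#' through unchanged, in stable order.
#'
#' @param screen output of \code{\link{univariable_screen}}.
#' @param groups list of character vectors declaring collinear sets, e.g.
#'   \code{list(c("weight_kg", "height_m", "bmi"), c("age_years",
#'   "pediatric_lt16", "pediatric_lt12"))}.
#' @param keep optional named override: for a group whose first member
#'   matches a name of \code{keep}, retain the named variable regardless of
#'   p-values.
#' @return character vector of retained candidate names (significant ones
#'   only).
#' @export
resolve_collinearity <- function(screen, groups = list(), keep = NULL) {
  sig <- screen$term[screen$significant %in% TRUE]
  grouped <- unlist(groups)
  retained <- sig[!sig %in% grouped]
  for (g in groups) {
    members <- g[g %in% sig]
    if (!length(members)) next
    if (!is.null(keep) && any(g %in% keep)) {
      choice <- intersect(keep, g)[1]
      if (!choice %in% sig) next
    } else {
      p <- screen$p_value[match(members, screen$term)]
      choice <- members[which.min(p)]   # which.min is first-of-ties
    }
    retained <- c(retained, choice)
  }
  retained[order(match(retained, screen$term))]
}

#' Forward likelihood-ratio stepwise logistic regression
#'
#' Starting from the intercept-only model, repeatedly enters the candidate
#' with the smallest likelihood-ratio test p-value below the entry
#' threshold; after each entry, removes any included term whose LR-based
#' removal p-value exceeds the removal threshold; stops when no candidate
#' qualifies. The full selection trace is recorded.
#'
#' @param data data.frame holding candidate columns.
#' @param outcome logical event vector.
#' @param candidates character vector of candidate column names (screened
#'   and collinearity-resolved).
#' @param entry_alpha LR p-value required for entry (default 0.05).
#' @param removal_alpha LR p-value beyond which an entered term is removed
#'   (default 0.10).
#' @return an object of class \code{forward_lr}: list with \code{model}
#'   (a \code{\link{fit_logistic}} result, intercept-only if nothing
#'   entered), \code{selected} (character), \code{trace} (data.frame:
#'   step, action, term, lr_statistic, p_value).
#' @examples
#' sc <- score_cohort(generate_cohort(cohort_spec(n = 600, seed = 11)))
#' sc$noise <- rnorm(nrow(sc))
#' forward_lr_select(sc, sc$died_90d, c("imeld", "noise"))
#' @export
forward_lr_select <- function(data, outcome, candidates,
                              entry_alpha = 0.05, removal_alpha = 0.10) {
  stopifnot(all(candidates %in% names(data)))
  y <- as.numeric(as.logical(outcome))
  # complete cases across all candidates so nested LR tests share data
  cc <- stats::complete.cases(data[, candidates, drop = FALSE]) & !is.na(y)
  data <- data[cc, , drop = FALSE]
  y <- y[cc]

  loglik <- function(terms) {
    if (!length(terms)) {
      p <- mean(y)
      return(sum(y * log(p) + (1 - y) * log(1 - p)))
    }
    fit_logistic(data[, terms, drop = FALSE], y)$log_likelihood
  }

  included <- character(0)
  ll_cur <- loglik(included)
  trace <- data.frame(step = integer(0), action = character(0),
                      term = character(0), lr_statistic = numeric(0),
                      p_value = numeric(0))
  step <- 0L
  repeat {
    pool <- setdiff(candidates, included)
    if (!length(pool)) break
    cand_stats <- vapply(pool, function(nm) {
      ll <- tryCatch(loglik(c(included, nm)), error = function(e) NA_real_)
      lr <- 2 * (ll - ll_cur)
      c(lr = lr, p = stats::pchisq(lr, df = 1, lower.tail = FALSE))
    }, numeric(2))
    p_enter <- cand_stats["p", ]
    if (all(is.na(p_enter)) || min(p_enter, na.rm = TRUE) >= entry_alpha) {
      break
    }
    best <- pool[which.min(p_enter)]
    step <- step + 1L
    included <- c(included, best)
    ll_cur <- loglik(included)
    trace <- rbind(trace, data.frame(
      step = step, action = "enter", term = best,
      lr_statistic = cand_stats["lr", best], p_value = p_enter[best]))
    # backward look: remove terms that no longer earn their keep
    repeat {
      if (length(included) < 2) break
      rem_stats <- vapply(included, function(nm) {
        ll <- loglik(setdiff(included, nm))
        lr <- 2 * (ll_cur - ll)
        c(lr = lr, p = stats::pchisq(lr, df = 1, lower.tail = FALSE))
      }, numeric(2))
      p_rem <- rem_stats["p", ]
      worst <- names(which.max(p_rem))
      if (p_rem[worst] <= removal_alpha) break
      step <- step + 1L
      included <- setdiff(included, worst)
      ll_cur <- loglik(included)
      trace <- rbind(trace, data.frame(
        step = step, action = "remove", term = worst,
        lr_statistic = rem_stats["lr", worst], p_value = p_rem[worst]))
    }
  }

  model <- if (length(included)) {
    fit_logistic(data[, included, drop = FALSE], y)
  } else {
    # intercept-only summary
    p <- mean(y)
    structure(list(
      terms = data.frame(term = "(Intercept)", coef = stats::qlogis(p),
                         se = sqrt(1 / (length(y) * p * (1 - p))),
                         odds_ratio = p / (1 - p),
                         ci_low = NA_real_, ci_high = NA_real_,
                         p_value = NA_real_),
      log_likelihood = loglik(character(0)), n = length(y),
      n_events = sum(y), level = 0.95, fit = NULL), class = "meld_logit")
  }
  rownames(trace) <- NULL
  structure(list(model = model, selected = included, trace = trace,
                 entry_alpha = entry_alpha, removal_alpha = removal_alpha),
            class = "forward_lr")
}

#' @export
print.forward_lr <- function(x, ...) {
  cat("Forward likelihood-ratio selection\n")
  if (nrow(x$trace)) {
    print(format(x$trace, digits = 4), row.names = FALSE)
  } else {
    cat("  (no candidate met the entry threshold)\n")
  }
  cat("Final model:\n")
  print(x$model)
  invisible(x)
}

#' @export
coef.forward_lr <- function(object, ...) coef(object$model)

#' Variance inflation factors for a covariate set
#'
#' Transparency report on multicollinearity: for each covariate, the VIF
#' \eqn{1 / (1 - R^2)} from a linear regression on the remaining
#' covariates. Reported for information only; collinearity decisions are
#' made through declared groups in \code{\link{resolve_collinearity}}.
#'
#' @param data data.frame of numeric covariates.
#' @param covariates character vector of column names (at least 2).
#' @return named numeric vector of VIFs.
#' @export
vif_report <- function(data, covariates) {
  stopifnot(length(covariates) >= 2, all(covariates %in% names(data)))
  X <- data[, covariates, drop = FALSE]
  X <- X[stats::complete.cases(X), , drop = FALSE]
  vapply(covariates, function(nm) {
    fit <- stats::lm(stats::reformulate(setdiff(covariates, nm),
                                        response = nm), data = X)
    r2 <- summary(fit)$r.squared
    1 / max(1 - r2, .Machine$double.eps)
  }, numeric(1))
}
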