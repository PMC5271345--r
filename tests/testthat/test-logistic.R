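test_that("intercept-only fit returns the logit of the event rate", {
  d <- data.frame(x = rep(c(0, 1), each = 50))
  y <- rep(c(TRUE, FALSE), 50)
  fit <- forward_lr_select(d, y, character(0))
  expect_equal(coef(fit)[["(Intercept)"]], 0, tolerance = 1e-9)
  expect_equal(fit$model$terms$odds_ratio[1], 1, tolerance = 1e-9)
})

test_that("a 2x2 design reproduces the closed-form odds ratio and SE", {
  # exposed: 10 events / 90 non-events; unexposed: 5 / 95
  a <- 10; b <- 90; c_ <- 5; d_ <- 95
  x <- rep(c(1, 1, 0, 0), c(a, b, c_, d_))
  y <- rep(c(TRUE, FALSE, TRUE, FALSE), c(a, b, c_, d_))
  fit <- fit_logistic(data.frame(exposed = x), y)
  tr <- fit$terms[fit$terms$term == "exposed", ]
  expect_equal(tr$odds_ratio, (a * d_) / (b * c_), tolerance = 1e-6)
  expect_equal(tr$odds_ratio, 2.111, tolerance = 1e-3)
  expect_equal(tr$se, sqrt(1 / a + 1 / b + 1 / c_ + 1 / d_),
               tolerance = 1e-6)
  expect_equal(tr$odds_ratio, exp(tr$coef), tolerance = 1e-9)
  expect_equal(tr$ci_low, exp(tr$coef - qnorm(0.975) * tr$se),
               tolerance = 1e-9)
})

test_that("degenerate designs raise informative errors", {
  y <- rep(c(TRUE, FALSE), 25)
  expect_error(fit_logistic(data.frame(k = rep(1, 50)), y), "constant")
  expect_error(fit_logistic(data.frame(copy = as.numeric(y)), y),
               "separation.*copy")
  expect_error(fit_logistic(data.frame(x = c(0.3, -0.2)), c(TRUE, FALSE)),
               "too few")
})

test_that("univariable screen separates signal from noise", {
  set.seed(33)
  sc <- score_cohort(generate_cohort(cohort_spec(n = 2000, seed = 51)))
  sc$noise <- rnorm(nrow(sc))
  scr <- univariable_screen(sc, sc$died_90d, c("imeld", "noise"))
  expect_true(scr$significant[scr$term == "imeld"])
  expect_gt(scr$odds_ratio[scr$term == "imeld"], 1)
  expect_true(all(scr$estimable))
  # type-I error control for the pure-noise covariate over repeated seeds
  rejections <- vapply(1:40, function(s) {
    coh <- score_cohort(generate_cohort(cohort_spec(n = 500,
                                                    seed = 3000 + s)))
    set.seed(s)
    coh$noise <- rnorm(nrow(coh))
    scr <- univariable_screen(coh, coh$died_90d, "noise")
    isTRUE(scr$significant[1])
  }, logical(1))
  expect_lte(mean(rejections), 0.15)
  # a covariate identical to the outcome flags separation, not an error
  sc$leak <- as.numeric(sc$died_90d)
  scr2 <- univariable_screen(sc, sc$died_90d, "leak")
  expect_false(scr2$estimable[1])
  expect_match(scr2$reason[1], "separation")
})

test_that("collinearity groups keep the most significant member", {
  screen <- data.frame(
    term = c("weight_kg", "height_m", "bmi", "sodium"),
    p_value = c(1e-4, 0.007, 0.001, 0.02),
    odds_ratio = 1, ci_low = 1, ci_high = 1,
    estimable = TRUE, significant = TRUE)
  kept <- resolve_collinearity(screen,
                               groups = list(c("weight_kg", "height_m",
                                               "bmi")))
  expect_identical(kept, c("weight_kg", "sodium"))
  # judgment override retains bmi as the anthropometric representative
  kept2 <- resolve_collinearity(screen,
                                groups = list(c("weight_kg", "height_m",
                                                "bmi")),
                                keep = "bmi")
  expect_identical(kept2, c("bmi", "sodium"))
  # a group with a single significant member keeps that member
  screen$significant <- screen$term == "height_m"
  expect_identical(resolve_collinearity(
    screen, groups = list(c("weight_kg", "height_m", "bmi"))), "height_m")
  # deterministic, declaration-ordered ties
  screen2 <- data.frame(term = c("a", "b", "c", "d"),
                        p_value = c(0.01, 0.01, 0.02, 0.03),
                        odds_ratio = 1, ci_low = 1, ci_high = 1,
                        estimable = TRUE, significant = TRUE)
  expect_identical(resolve_collinearity(screen2,
                                        groups = list(c("a", "b"),
                                                      c("c", "d"))),
                   c("a", "c"))
})

test_that("forward LR selection enters signal, skips noise and redundancy", {
  sc <- score_cohort(generate_cohort(cohort_spec(n = 1500, seed = 61)))
  set.seed(61)
  sc$noise <- rnorm(nrow(sc))
  sel <- forward_lr_select(sc, sc$died_90d, c("noise", "imeld"))
  expect_true("imeld" %in% sel$selected)
  expect_false("noise" %in% sel$selected)
  expect_true(all(sel$trace$p_value[sel$trace$action == "enter"] < 0.05))
  expect_true(all(sel$trace$lr_statistic >= 0))
  # an exact duplicate of an entered covariate is never entered
  sc$imeld_copy <- sc$imeld
  sel2 <- forward_lr_select(sc, sc$died_90d,
                            c("imeld", "imeld_copy", "noise"))
  expect_identical(sel2$selected, "imeld")
  # pure noise only: intercept-only model comes back
  sel3 <- forward_lr_select(sc, sc$died_90d, "noise")
  expect_length(sel3$selected, 0)
  expect_identical(sel3$model$terms$term, "(Intercept)")
})

test_that("selection is invariant to candidate order without LR ties", {
  sc <- score_cohort(generate_cohort(cohort_spec(n = 1200, seed = 71)))
  set.seed(71)
  sc$noise1 <- rnorm(nrow(sc))
  sc$noise2 <- rnorm(nrow(sc))
  cands <- c("imeld", "bilirubin", "noise1", "noise2")
  sc$bilirubin <- sc$bilirubin  # lab covariate with real signal
  s1 <- forward_lr_select(sc, sc$died_90d, cands)
  s2 <- forward_lr_select(sc, sc$died_90d, rev(cands))
  expect_setequal(s1$selected, s2$selected)
  expect_equal(s1$model$log_likelihood, s2$model$log_likelihood,
               tolerance = 1e-9)
})

test_that("LR statistics are monotone in model nesting", {
  sc <- score_cohort(generate_cohort(cohort_spec(n = 800, seed = 81)))
  f0 <- forward_lr_select(sc, sc$died_90d, character(0))
  f1 <- fit_logistic(sc[, "imeld", drop = FALSE], sc$died_90d)
  lr <- 2 * (f1$log_likelihood - f0$model$log_likelihood)
  expect_gte(lr, 0)
  p <- pchisq(lr, 1, lower.tail = FALSE)
  expect_gte(p, 0)
  expect_lte(p, 1)
})

test_that("vif_report flags aliased covariates and spares independent ones", {
  set.seed(91)
  d <- data.frame(x = rnorm(300))
  d$y <- rnorm(300)
  d$z <- d$x * 2 + rnorm(300, sd = 0.01)
  v <- vif_report(d, c("x", "y", "z"))
  expect_gt(v[["x"]], 100)
  expect_gt(v[["z"]], 100)
  expect_lt(v[["y"]], 2)
})

test_that("model methods expose coefficients, predictions and residuals", {
  sc <- score_cohort(generate_cohort(cohort_spec(n = 400, seed = 101)))
  fit <- fit_logistic(sc[, c("imeld", "inr"), drop = FALSE], sc$died_90d)
  expect_named(coef(fit), c("(Intercept)", "imeld", "inr"))
  pr <- predict(fit)
  expect_true(all(pr > 0 & pr < 1))
  expect_length(residuals(fit), fit$n)
  expect_output(print(fit), "Logistic regression")
})
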