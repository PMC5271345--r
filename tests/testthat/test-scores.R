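# Frozen expected values below were computed by hand arithmetic / the
# independent oracle transcriptions in helper-oracles.R.

test_that("MELD applies floors, cap, dialysis substitution and rounding", {
  expect_identical(meld(1, 1, 1), 6)           # 10 * 0.643 rounds to 6
  expect_identical(meld(1.2, 2.5, 1.5), 16)    # raw 16.18
  expect_identical(meld(10, 50, 12), 40)       # raw 62.3, capped
  expect_identical(meld(0.5, 2.5, 1.5, dialysis = TRUE), 28)  # cr -> 4.0
  expect_identical(meld(0.3, 0.2, 0.5), 6)     # all floored to 1.0
})

test_that("MESO divides the integer MELD by sodium", {
  expect_equal(meso(1, 1, 1, 140), 6 / 140 * 10, tolerance = 1e-12)
  expect_equal(meso(1.2, 2.5, 1.5, 140), 16 / 140 * 10, tolerance = 1e-12)
  expect_equal(meso(10, 50, 12, 121), 40 / 121 * 10, tolerance = 1e-12)
  expect_error(meso(1, 1, 1, -3), "sodium")
})

test_that("MELD-Na clamps sodium to 125-140 and is MELD at Na = 140", {
  expect_identical(meld_na(1.2, 2.5, 1.5, 140), 16)
  expect_identical(meld_na(1.2, 2.5, 1.5, 130), 22)
  expect_identical(meld_na(1.2, 2.5, 1.5, 120), 25)   # behaves as Na = 125
  expect_identical(meld_na(1.2, 2.5, 1.5, 120),
                   meld_na(1.2, 2.5, 1.5, 125))
  set.seed(31)
  labs <- random_labs(200)
  expect_identical(meld_na(labs$cr, labs$bi, labs$inr, rep(140, 200),
                           labs$dial),
                   meld(labs$cr, labs$bi, labs$inr, labs$dial))
})

test_that("UKELD works in SI units with its stated clamps", {
  expect_equal(ukeld(100, 50, 1.5, 135), 56.17, tolerance = 5e-3)
  expect_equal(ukeld(1, 1, 1, 150), 435 - 81.565 * log(150),
               tolerance = 1e-12)
  expect_equal(ukeld(500, 50, 1.5, 135), ukeld(400, 50, 1.5, 135))
  expect_equal(ukeld(100, 50, 1.5, 105), ukeld(100, 50, 1.5, 112))
})

test_that("iMELD adds age and sodium terms to the integer MELD", {
  expect_equal(imeld(1.2, 2.5, 1.5, 135, age = 50), 36.5)
  expect_equal(imeld(1, 1, 1, 140, age = 0), 8.0)
  expect_equal(imeld(10, 50, 12, 121, age = 70), 76.3)
})

test_that("refitMELD clamps creatinine 0.8-3 and INR 1-3", {
  expect_equal(refit_meld(0.8, 1, 1), 8.485 * log(0.8) + 7.432,
               tolerance = 1e-12)
  expect_equal(refit_meld(1.5, 3, 2), 22.75, tolerance = 5e-3)
  expect_equal(refit_meld(0.5, 1, 1, dialysis = TRUE),
               8.485 * log(3) + 7.432, tolerance = 1e-12)
  expect_equal(refit_meld(5, 2, 4), refit_meld(3, 2, 3))
})

test_that("refitMELD-Na handles sodium and the untransformed BiliCC cap", {
  expect_equal(refit_meld_na(1, 1, 1, 140), 6.327, tolerance = 1e-12)
  expect_equal(refit_meld_na(1, 25, 1, 130),
               4.258 * log(25) + 0.652 * 10 - 0.194 * 10 * 20 + 6.327,
               tolerance = 1e-12)
  expect_equal(refit_meld_na(1, 25, 1, 130), -12.247, tolerance = 5e-3)
  expect_equal(refit_meld_na(1, 1, 1, 120), refit_meld_na(1, 1, 1, 125))
})

test_that("upMELD floors all inputs, caps creatinine, ignores dialysis", {
  expect_equal(up_meld(1, 1, 1), (1.266 + 0.939 + 1.658) * log(2),
               tolerance = 1e-12)
  expect_equal(round(up_meld(1, 1, 1), 2), 2.68)
  expect_equal(up_meld(2, 5, 1.5),
               1.266 * log(3) + 0.939 * log(6) + 1.658 * log(2.5),
               tolerance = 1e-12)
  expect_equal(up_meld(8, 1, 1), up_meld(4, 1, 1))
})

test_that("PELD applies the age and growth-failure indicators", {
  expect_equal(peld(1, 1, 1, age = 5), 0)
  expect_equal(peld(3, 3, 2, age = 0.5, growth_failure = TRUE), 21.63,
               tolerance = 5e-3)
  # growth failure is zeroed above 219 months
  expect_equal(peld(3, 3, 2, age = 20, growth_failure = TRUE),
               peld(3, 3, 2, age = 20, growth_failure = FALSE))
  expect_lt(peld(3.5, 1, 1, age = 30), 0)   # may be negative
  expect_error(peld(-1, 1, 1, age = 5), "albumin")
})

test_that("every score matches its independent oracle on random labs", {
  set.seed(97)
  labs <- random_labs(1000)
  per_row <- function(f) {
    vapply(seq_len(nrow(labs)), function(i) f(labs[i, ]), numeric(1))
  }
  expect_identical(meld(labs$cr, labs$bi, labs$inr, labs$dial),
                   per_row(function(l) oracle_meld(l$cr, l$bi, l$inr,
                                                   l$dial)))
  expect_equal(meso(labs$cr, labs$bi, labs$inr, labs$na, labs$dial),
               per_row(function(l) oracle_meso(l$cr, l$bi, l$inr, l$na,
                                               l$dial)), tolerance = 1e-9)
  expect_identical(meld_na(labs$cr, labs$bi, labs$inr, labs$na, labs$dial),
                   per_row(function(l) oracle_meld_na(l$cr, l$bi, l$inr,
                                                      l$na, l$dial)))
  expect_equal(ukeld(labs$cr * 88.42, labs$bi * 17.104, labs$inr, labs$na),
               per_row(function(l) oracle_ukeld(l$cr * 88.42,
                                                l$bi * 17.104, l$inr,
                                                l$na)), tolerance = 1e-9)
  expect_equal(imeld(labs$cr, labs$bi, labs$inr, labs$na, labs$age,
                     labs$dial),
               per_row(function(l) oracle_imeld(l$cr, l$bi, l$inr, l$na,
                                                l$age, l$dial)),
               tolerance = 1e-9)
  expect_equal(refit_meld(labs$cr, labs$bi, labs$inr, labs$dial),
               per_row(function(l) oracle_refit_meld(l$cr, l$bi, l$inr,
                                                     l$dial)),
               tolerance = 1e-9)
  expect_equal(refit_meld_na(labs$cr, labs$bi, labs$inr, labs$na,
                             labs$dial),
               per_row(function(l) oracle_refit_meld_na(l$cr, l$bi, l$inr,
                                                        l$na, l$dial)),
               tolerance = 1e-9)
  expect_equal(up_meld(labs$cr, labs$bi, labs$inr),
               per_row(function(l) oracle_up_meld(l$cr, l$bi, l$inr)),
               tolerance = 1e-9)
  expect_equal(peld(labs$alb, labs$bi, labs$inr, labs$age, labs$dial),
               per_row(function(l) oracle_peld(l$alb, l$bi, l$inr, l$age,
                                               l$dial)), tolerance = 1e-9)
})

test_that("MELD stays within 6-40 over an exhaustive input grid", {
  grid <- expand.grid(cr = c(0.1, 0.5, 1, 2, 4, 8, 20),
                      bi = c(0.2, 1, 3, 10, 50, 200),
                      inr = c(0.5, 1, 1.5, 3, 8, 25),
                      dial = c(FALSE, TRUE))
  m <- meld(grid$cr, grid$bi, grid$inr, grid$dial)
  expect_true(all(m >= 6 & m <= 40))
  expect_true(all(m == round(m)))
})

test_that("scores are monotone in their inputs over the unclamped region", {
  bi_grid <- seq(1.1, 19, length.out = 25)
  inr_grid <- seq(1.05, 2.9, length.out = 25)
  cr_grid <- seq(1.05, 2.9, length.out = 25)
  na_grid <- seq(126, 139, length.out = 25)
  nondec <- function(x) all(diff(x) >= -1e-12)
  noninc <- function(x) all(diff(x) <= 1e-12)
  expect_true(nondec(meld(1.5, bi_grid, 1.5)))
  expect_true(nondec(meld(cr_grid, 2, 1.5)))
  expect_true(nondec(refit_meld(cr_grid, 2, 1.5)))
  expect_true(nondec(refit_meld(1.5, bi_grid, 1.5)))
  expect_true(nondec(up_meld(cr_grid, 2, 1.5)))
  expect_true(nondec(up_meld(1.5, 2, inr_grid)))
  expect_true(nondec(ukeld(100, 17.104 * bi_grid, 1.5, 135)))
  expect_true(noninc(ukeld(100, 50, 1.5, seq(113, 149, length.out = 25))))
  expect_true(noninc(meld_na(1.5, 2, 1.5, na_grid)))
  expect_true(noninc(imeld(1.5, 2, 1.5, na_grid, age = 40)))
  expect_true(noninc(refit_meld_na(1.5, 2, 1.5, na_grid)))
})

test_that("inputs beyond every stated bound behave as the bound", {
  expect_identical(meld(7, 2, 1.5), meld(4, 2, 1.5))
  expect_identical(meld(0.4, 2, 1.5), meld(1, 2, 1.5))
  expect_identical(meld(1.5, 0.3, 1.5), meld(1.5, 1, 1.5))
  expect_identical(meld(1.5, 2, 0.8), meld(1.5, 2, 1))
  expect_equal(refit_meld(0.4, 2, 1.5), refit_meld(0.8, 2, 1.5))
  expect_equal(refit_meld(1.5, 2, 5), refit_meld(1.5, 2, 3))
  # BiliCC caps at 20 only inside the interaction term: once bilirubin
  # exceeds 20, raising it further changes the score by the ln term alone
  expect_equal(refit_meld_na(1.5, 30, 1.5, 130) -
                 refit_meld_na(1.5, 25, 1.5, 130),
               4.258 * (log(30) - log(25)), tolerance = 1e-9)
  expect_equal(ukeld(450, 50, 1.5, 135), ukeld(400, 50, 1.5, 135))
  expect_equal(ukeld(0.5, 50, 1.5, 135), ukeld(1, 50, 1.5, 135))
  expect_equal(ukeld(100, 50, 1.5, 155), ukeld(100, 50, 1.5, 150))
  expect_equal(meld_na(1.5, 2, 1.5, 145), meld_na(1.5, 2, 1.5, 140))
  expect_equal(up_meld(9, 2, 1.5), up_meld(4, 2, 1.5))
})

test_that("analytic floors reproduce the observed minima at print precision", {
  expect_equal(round(up_meld(1, 1, 1), 2), 2.68)
  expect_equal(round(refit_meld(0.8, 1, 1), 1), 5.5)
  expect_identical(meld(1, 1, 1), 6)
})

test_that("score_cohort populates all nine scores with an audit trail", {
  coh <- generate_cohort(cohort_spec(n = 120, seed = 5))
  sc <- score_cohort(coh)
  for (s in c("meld", "meso", "meld_na", "ukeld", "imeld", "refit_meld",
              "refit_meld_na", "up_meld", "peld")) {
    expect_true(s %in% names(sc))
    expect_false(anyNA(sc[[s]]))
  }
  expect_type(sc$applied_rules, "character")
  # units: generated cohort carries SI labs; spot-check one patient by hand
  i <- 7
  expect_identical(sc$meld[i],
                   oracle_meld(coh$creatinine[i] / 88.42,
                               coh$bilirubin[i] / 17.104, coh$inr[i],
                               coh$dialysis_per_week[i] >= 1))
  # dialysis patients must carry the substitution audit tag
  d <- which(coh$dialysis_per_week >= 1)
  if (length(d)) {
    expect_true(all(grepl("dialysis_substitution", sc$applied_rules[d])))
  }
})

test_that("missing albumin blanks PELD only; Na = 140 makes MELD-Na = MELD", {
  coh <- generate_cohort(cohort_spec(n = 5, seed = 9))
  coh$albumin[2] <- NA
  coh$sodium_mmol_l[3] <- 140
  sc <- score_cohort(coh)
  expect_true(is.na(sc$peld[2]))
  expect_false(anyNA(sc$meld))
  expect_false(is.na(sc$ukeld[2]))
  expect_identical(sc$meld_na[3], sc$meld[3])
  pan <- score_panel(coh[2, ])
  expect_true(is.na(pan$peld))
  expect_false(is.na(pan$meld))
})

test_that("the PELD age restriction config blanks older patients", {
  coh <- generate_cohort(cohort_spec(n = 200, seed = 13))
  sc <- score_cohort(coh, peld_max_age = 12)
  expect_true(all(is.na(sc$peld[coh$age_years >= 12])))
  expect_false(anyNA(sc$peld[coh$age_years < 12]))
})
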