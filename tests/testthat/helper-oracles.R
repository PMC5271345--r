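# Independent oracles used across tests. These deliberately share no code
# with the package: formulas are transcribed literally with inline min/max,
# AUROC is brute-force over pairs, the 2x2 odds ratio is closed-form.

oracle_meld <- function(cr, bi, inr, dial = FALSE) {
  if (dial) cr <- 4
  cr <- min(max(cr, 1), 4)
  bi <- max(bi, 1)
  inr <- max(inr, 1)
  raw <- 10 * (0.957 * log(cr) + 0.378 * log(bi) + 1.120 * log(inr) + 0.643)
  min(floor(raw + 0.5), 40)
}

oracle_meso <- function(cr, bi, inr, na, dial = FALSE) {
  oracle_meld(cr, bi, inr, dial) / na * 10
}

oracle_meld_na <- function(cr, bi, inr, na, dial = FALSE) {
  m <- oracle_meld(cr, bi, inr, dial)
  na <- min(max(na, 125), 140)
  floor(m - na - 0.025 * m * (140 - na) + 140 + 0.5)
}

oracle_ukeld <- function(cr_si, bi_si, inr, na) {
  cr_si <- min(max(cr_si, 1), 400)
  bi_si <- max(bi_si, 1)
  inr <- max(inr, 1)
  na <- min(max(na, 112), 150)
  1.485 * log(cr_si) + 3.13 * log(bi_si) + 5.395 * log(inr) -
    81.565 * log(na) + 435
}

oracle_imeld <- function(cr, bi, inr, na, age, dial = FALSE) {
  oracle_meld(cr, bi, inr, dial) + 0.3 * age - 0.7 * na + 100
}

oracle_refit_meld <- function(cr, bi, inr, dial = FALSE) {
  if (dial) cr <- 3
  cr <- min(max(cr, 0.8), 3)
  bi <- max(bi, 1)
  inr <- min(max(inr, 1), 3)
  8.485 * log(cr) + 4.082 * log(bi) + 10.671 * log(inr) + 7.432
}

oracle_refit_meld_na <- function(cr, bi, inr, na, dial = FALSE) {
  if (dial) cr <- 3
  cr <- min(max(cr, 0.8), 3)
  bi <- max(bi, 1)
  inr <- min(max(inr, 1), 3)
  na <- min(max(na, 125), 140)
  bcc <- min(bi, 20)
  6.792 * log(cr) + 4.258 * log(bi) + 8.29 * log(inr) +
    0.652 * (140 - na) - 0.194 * (140 - na) * bcc + 6.327
}

oracle_up_meld <- function(cr, bi, inr) {
  cr <- min(max(cr, 1), 4)
  bi <- max(bi, 1)
  inr <- max(inr, 1)
  1.266 * log(1 + cr) + 0.939 * log(1 + bi) + 1.658 * log(1 + inr)
}

oracle_peld <- function(alb, bi, inr, age, gf) {
  if (age > 219 / 12) gf <- FALSE
  10 * (0.436 * (age < 1) - 0.687 * log(alb) + 0.480 * log(bi) +
          1.857 * log(inr) + 0.667 * gf)
}

# AUROC by exhaustive comparison of all event/non-event pairs
oracle_auroc <- function(scores, events) {
  ev <- as.logical(events)
  x <- scores[ev]
  y <- scores[!ev]
  total <- 0
  for (xi in x) total <- total + sum(xi > y) + 0.5 * sum(xi == y)
  total / (length(x) * length(y))
}

# random lab draws spanning (and exceeding) every clamp region
random_labs <- function(n) {
  data.frame(
    cr = exp(runif(n, log(0.2), log(12))),
    bi = exp(runif(n, log(0.3), log(60))),
    inr = exp(runif(n, log(0.8), log(15))),
    na = runif(n, 105, 165),
    alb = runif(n, 1, 5.5),
    age = runif(n, 0.05, 75),
    dial = runif(n) < 0.15
  )
}

# run code under a seed without disturbing the suite's RNG stream
with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
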