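# Dichotomized logistic DE, size factors, NB DE, BH, fold change.

test_that("dichotomization splits at the median, ties going low", {
  expect_equal(as.character(dichotomize(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  # odd length: the value equal to the median is low
  expect_equal(as.character(dichotomize(c(1, 5, 9))),
               c("low", "low", "high"))
  d <- dichotomize(c(3, 3, 3))
  expect_true(attr(d, "degenerate"))
  expect_error(dichotomize(7), "at least 2")
})

sim_logit_study <- function(n = 120, seed = 5, b_ge = 1.5) {
  set.seed(seed)
  counts <- matrix(rnbinom(3 * n, mu = 40, size = 5), nrow = 3,
                   dimnames = list(c("gA", "gB", "gC"), NULL))
  age <- pmax(rnorm(n, 50, 12), 1)
  sex <- ifelse(runif(n) < 0.6, "male", "female")
  race <- ifelse(runif(n) < 0.75, "white", "other")
  pmi <- runif(n, 5, 30)
  ge <- as.integer(dichotomize(counts["gA", ]) == "high")
  lp <- -0.5 + 0.01 * age - 0.3 * (sex == "male") +
    0.4 * (race == "white") + 0.02 * pmi + b_ge * ge
  samples <- data.frame(
    sample_id = sprintf("s%03d", 1:n),
    diagnosis = ifelse(runif(n) < plogis(lp), "case", "control"),
    age_at_death = age, sex = sex, race = race, pmi = pmi,
    stringsAsFactors = FALSE
  )
  expression_study(counts, samples)
}

test_that("logistic DE reports Wald z = beta/se and p = 2*pnorm(-|z|)", {
  st <- sim_logit_study()
  fit <- fit_logistic_de(st, "gA")
  expect_setequal(fit$term, c("(Intercept)", "age_at_death", "sex_male",
                              "race_white", "pmi", "ge_high"))
  expect_equal(fit$z, fit$beta / fit$se, tolerance = 1e-12)
  expect_equal(fit$p, 2 * pnorm(-abs(fit$z)), tolerance = 1e-12)
  # white-only variant drops the race term
  white <- st$samples$race == "white"
  fitw <- fit_logistic_de(st, "gA", include_race = FALSE, subset = white)
  expect_false("race_white" %in% fitw$term)
  expect_equal(attr(fitw, "n"), sum(white))
})

test_that("separation and degenerate predictors are explicit errors", {
  set.seed(17)
  n <- 60
  diagnosis <- rep(c("case", "control"), each = n / 2)
  counts <- rbind(gB = ifelse(diagnosis == "case", 100L, 1L),
                  gC = rep(7L, n))
  samples <- data.frame(
    sample_id = sprintf("s%02d", 1:n), diagnosis = diagnosis,
    age_at_death = runif(n, 30, 70), sex = sample(c("male", "female"), n, TRUE),
    race = sample(c("white", "other"), n, TRUE), pmi = runif(n, 5, 30),
    stringsAsFactors = FALSE
  )
  st <- expression_study(counts, samples)
  # GE identical to diagnosis: quasi-complete separation
  expect_error(fit_logistic_de(st, "gB"), "separation")
  expect_error(fit_logistic_de(st, "gC"), "dichotomized|constant")
})

test_that("logistic DE recovers known coefficients on simulated data", {
  hits <- 0L
  reps <- 40L
  for (r in seq_len(reps)) {
    st <- sim_logit_study(n = 200, seed = 1000 + r, b_ge = 1.2)
    fit <- tryCatch(fit_logistic_de(st, "gA"), error = function(e) NULL)
    if (is.null(fit)) next
    ge <- fit[fit$term == "ge_high", ]
    if (abs(ge$beta - 1.2) <= 2 * ge$se) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.9)
})

test_that("size factors follow median-of-ratios conventions", {
  cts <- matrix(c(10, 20, 30, 10, 20, 30, 10, 20, 30), nrow = 3)
  expect_equal(unname(size_factors(cts)), rep(1, 3))
  cts2 <- cbind(c(10, 20, 30), c(20, 40, 60))
  sf <- unname(size_factors(cts2))
  expect_equal(sf[2] / sf[1], 2)
  expect_equal(exp(mean(log(sf))), 1)     # normalized to geometric mean 1
  expect_equal(unname(size_factors(matrix(c(5, 7), ncol = 1))), 1)
  expect_error(size_factors(rbind(c(0, 5), c(3, 0))), "all-positive")
})

test_that("NB DE filters on total count and adjusts with BH", {
  set.seed(8)
  counts <- rbind(
    low = c(2, 3, 1, 2, 0, 1),            # total 9: excluded
    ten = c(2, 2, 2, 2, 1, 1),            # total 10: retained
    big = rnbinom(6, mu = 200, size = 10)
  )
  st <- expression_study(counts, data.frame(
    sample_id = paste0("s", 1:6),
    diagnosis = rep(c("case", "control"), each = 3)
  ))
  out <- nb_de(st, min_total = 10)
  expect_setequal(out$gene_id, c("ten", "big"))
  expect_true(all(out$p_adj >= out$p))
  expect_equal(out$p_adj, bh_adjust(out$p))
})

test_that("NB Wald statistic approaches the Poisson GLM in the limit", {
  # large counts generated from a Poisson: MoM dispersion collapses to the
  # floor and the NB fit must agree with a Poisson GLM oracle within 5%
  set.seed(13)
  n <- 400
  diagnosis <- rep(c("case", "control"), each = n / 2)
  mu <- ifelse(diagnosis == "case", 1020, 1000)
  k <- rpois(n, mu)
  st <- expression_study(matrix(k, 1, dimnames = list("g", NULL)),
                         data.frame(sample_id = paste0("s", 1:n),
                                    diagnosis = diagnosis))
  out <- nb_de(st, min_total = 10, sf = rep(1, n))
  pois <- glm(k ~ factor(diagnosis, levels = c("control", "case")),
              family = poisson())
  zp <- coef(summary(pois))[2, "z value"]
  znb <- qt(out$p / 2, df = n - 2, lower.tail = FALSE) * sign(out$lfc)
  expect_lt(abs(abs(znb) - abs(zp)) / abs(zp), 0.05)
})

test_that("a class of all zeros yields a clamped, flagged fold change", {
  counts <- rbind(g = c(25, 30, 28, 0, 0, 0),
                  stable = c(50, 55, 45, 52, 48, 50))
  st <- expression_study(counts, data.frame(
    sample_id = paste0("s", 1:6),
    diagnosis = rep(c("case", "control"), each = 3)
  ))
  out <- nb_de(st, min_total = 10)
  g <- out[out$gene_id == "g", ]
  expect_true(g$lfc_clamped)
  expect_equal(g$lfc, 30)
  expect_true(is.finite(g$p))
})

test_that("BH adjustment matches the brute-force step-up definition", {
  brute_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    sorted <- p[o]
    for (i in seq_len(m)) {
      adj[i] <- min(sorted[i:m] * m / (i:m), 1)
    }
    out <- numeric(m)
    out[o] <- adj
    out
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  set.seed(31)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
    expect_true(all(bh_adjust(p) >= p))
    expect_true(all(diff(bh_adjust(p)[order(p)]) >= -1e-12))
  }
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
})

test_that("fold change is 2^lfc", {
  expect_equal(fold_change(0), 1)
  expect_equal(round(fold_change(1.17), 2), 2.25)
  expect_equal(fold_change(-1), 0.5)
})
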