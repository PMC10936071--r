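# Feature assembly, LASSO-Cox fitting, risk scores and model evaluation.

# synthetic standardised feature matrix with one planted prognostic feature
planted_design <- function(n, p, beta, seed, censor_frac = 0.3) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  lp <- beta * x[, 1]
  t_event <- rexp(n, rate = 0.002 * exp(lp))
  t_cens <- rexp(n, rate = 0.002 * censor_frac / (1 - censor_frac))
  list(x = x, lp = lp,
       outcomes = data.frame(time = pmin(t_event, t_cens),
                             event = as.integer(t_event <= t_cens)))
}

test_that("feature tables are standardised on training rows only", {
  coh <- small_cohort()
  het <- small_het_table()
  ft <- assemble_feature_table(coh, "heterogeneity", heterogeneity = het)
  expect_identical(ncol(ft$x) + length(ft$dropped), 107L)
  tr <- ft$split == "train"
  expect_lt(max(abs(colMeans(ft$x[tr, ]))), 1e-9)
  expect_lt(max(abs(apply(ft$x[tr, ], 2, sd) - 1)), 1e-9)

  fc <- assemble_feature_table(coh, "conventional")
  fi <- assemble_feature_table(coh, "integrated", heterogeneity = het)
  expect_identical(ncol(fi$x) + length(fi$dropped), 32L + 107L)
  expect_false(any(duplicated(c(colnames(fc$x), colnames(ft$x)))))
  expect_setequal(c(colnames(fc$x), colnames(ft$x)), colnames(fi$x))
})

test_that("the LASSO-Cox fit selects a planted feature and shrinks it", {
  d <- planted_design(n = 250, p = 15, beta = 1.2, seed = 71)
  fit <- fit_ith_cox(d$x, d$outcomes, endpoint = "PFS", seed = 5)
  expect_s3_class(fit, "ith_cox")
  expect_true("f1" %in% names(coef(fit)))
  expect_gt(coef(fit)[["f1"]], 0)

  # unpenalised refit on the planted feature: classical Cox recovers beta,
  # and the penalised estimate is shrunk toward zero relative to it
  cox <- survival::coxph(survival::Surv(time, event) ~ x,
                         data = data.frame(d$outcomes, x = d$x[, 1]),
                         ties = "breslow")
  ci <- confint(cox)
  expect_gt(1.2, ci[1]); expect_lt(1.2, ci[2])
  expect_lte(coef(fit)[["f1"]], unname(coef(cox)) + 1e-9)
})

test_that("risk scores are sparse linear predictors", {
  d <- planted_design(n = 200, p = 10, beta = 1.5, seed = 72)
  fit <- fit_ith_cox(d$x, d$outcomes, seed = 2)
  sel <- names(coef(fit))
  x3 <- d$x[1:3, , drop = FALSE]
  expect_equal(unname(predict(fit, x3)),
               unname(drop(x3[, sel, drop = FALSE] %*% coef(fit))))
  expect_equal(unname(predict(fit, matrix(0, 2, 10,
    dimnames = list(NULL, colnames(d$x))))), c(0, 0))
  # appending an unselected column leaves scores unchanged
  x_extra <- cbind(x3, junk = c(9, 9, 9))
  expect_equal(predict(fit, x_extra), predict(fit, x3))
})

test_that("no test-set information enters the training artifacts", {
  coh <- small_cohort()
  het <- small_het_table()
  # the same cohort with the test patients removed entirely
  tr_idx <- which(coh$split == "train")
  coh_tr <- coh
  coh_tr$patients <- coh$patients[tr_idx]
  coh_tr$split <- coh$split[tr_idx]
  het_tr <- het[tr_idx, , drop = FALSE]

  f_full <- assemble_feature_table(coh, "conventional")
  f_tr <- assemble_feature_table(coh_tr, "conventional")
  expect_identical(f_full$center, f_tr$center)
  expect_identical(f_full$scale, f_tr$scale)

  out_full <- cohort_outcomes(coh, "PFS")
  fit_full <- fit_ith_cox(f_full, out_full, "PFS", seed = 3)
  fit_tr <- fit_ith_cox(f_tr, cohort_outcomes(coh_tr, "PFS"), "PFS", seed = 3)
  expect_identical(fit_full$coefficients, fit_tr$coefficients)
  expect_identical(fit_full$lambda, fit_tr$lambda)
  expect_identical(fit_full$risk_median, fit_tr$risk_median)
})

test_that("model methods (print/summary/residuals/simulate/plot) work", {
  d <- planted_design(n = 150, p = 8, beta = 1.5, seed = 73)
  fit <- fit_ith_cox(d$x, d$outcomes, seed = 4)
  expect_output(print(fit), "LASSO-Cox")
  expect_output(s <- summary(fit), "Selected")
  expect_true(is.list(s))
  r <- residuals(fit)
  expect_length(r, 150)
  expect_lt(abs(mean(r)), 0.1)  # martingale residuals are centred
  sim <- simulate(fit, nsim = 3, seed = 6)
  expect_identical(dim(sim), c(150L, 3L))
  expect_true(all(sim > 0))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("Harrell's C matches brute force and survival::concordance", {
  # perfect, reversed and random rankings
  t5 <- c(10, 20, 30, 40, 50); e5 <- rep(1, 5)
  sc <- 5:1
  expect_equal(concordance_index(sc, t5, e5, ci = FALSE)$c_index, 1)
  expect_equal(concordance_index(-sc, t5, e5, ci = FALSE)$c_index, 0)

  set.seed(81)
  n <- 400
  tt <- rexp(n); ee <- rbinom(n, 1, 0.7); ss <- rnorm(n)
  c_rand <- concordance_index(ss, tt, ee, ci = FALSE)$c_index
  expect_lt(abs(c_rand - 0.5), 0.05)

  # 6-patient worked set with censoring and a score tie
  sc6 <- c(2, 2, 1, 3, 0, 1.5); tm6 <- c(5, 8, 8, 3, 10, 6); ev6 <- c(1, 0, 1, 1, 0, 1)
  got <- concordance_index(sc6, tm6, ev6, n_boot = 200, seed = 2)
  expect_equal(got$c_index, brute_cindex(sc6, tm6, ev6))
  ref <- survival::concordance(survival::Surv(tm6, ev6) ~ sc6, reverse = TRUE)
  expect_equal(got$c_index, unname(ref$concordance))
  expect_lte(got$lower, got$c_index); expect_gte(got$upper, got$c_index)

  # antisymmetry without score ties
  s_nt <- rnorm(50); t_nt <- rexp(50); e_nt <- rbinom(50, 1, 0.6)
  expect_equal(concordance_index(-s_nt, t_nt, e_nt, ci = FALSE)$c_index,
               1 - concordance_index(s_nt, t_nt, e_nt, ci = FALSE)$c_index)
})

test_that("Kaplan-Meier and log-rank behave on worked examples", {
  # duplicated data split into two identical groups: log-rank statistic ~ 0
  tt <- c(3, 5, 7, 9, 11, 13); ee <- c(1, 1, 0, 1, 0, 1)
  km <- km_logrank(scores = rep(c(0, 1), each = 6),
                   time = c(tt, tt), event = c(ee, ee), threshold = 0.5)
  expect_lt(km$chisq, 1e-9)
  expect_gt(km$p, 0.99)

  # hand-computed product limit on 5 patients (censor at 4)
  t5 <- c(2, 4, 6, 8, 10); e5 <- c(1, 0, 1, 1, 1)
  sf <- survival::survfit(survival::Surv(t5, e5) ~ 1)
  hand <- c(4 / 5, 4 / 5, 4 / 5 * 2 / 3, 4 / 5 * 2 / 3 * 1 / 2, 0)
  expect_equal(summary(sf, times = t5)$surv, hand)

  # no censoring: survival beyond the last event is 0
  km2 <- km_logrank(rnorm(10), time = 1:10, event = rep(1, 10))
  expect_equal(min(km2$fit$surv), 0)
  expect_error(km_logrank(rep(1, 5), 1:5, rep(1, 5), threshold = 2), "empty")
})

test_that("time-dependent AUC reduces to binary AUC without censoring", {
  set.seed(91)
  n <- 120
  tt <- rexp(n, 0.01); ee <- rep(1, n); ss <- rnorm(n) + 0.01 * (200 - tt)
  h <- 80
  got <- time_dependent_auc(ss, tt, ee, h)
  expect_equal(unname(got), brute_binary_auc(ss, as.integer(tt <= h)))

  # perfectly separating score, no censoring
  ssp <- -tt
  expect_equal(unname(time_dependent_auc(ssp, tt, ee, h)), 1)

  # random score at n = 500: AUC ~ 0.5 (Monte-Carlo null over 10 replicates)
  n2 <- 500
  nulls <- vapply(1:10, function(b) {
    t2 <- rexp(n2, 0.01); e2 <- rbinom(n2, 1, 0.75); s2 <- rnorm(n2)
    unname(time_dependent_auc(s2, t2, e2, 60))
  }, numeric(1))
  expect_lt(abs(mean(nulls) - 0.5), 0.03)
  expect_lt(max(abs(nulls - 0.5)), 0.12)
  t2 <- rexp(n2, 0.01); e2 <- rbinom(n2, 1, 0.75); s2 <- rnorm(n2)
  expect_warning(time_dependent_auc(s2, t2, e2, max(t2) + 1), "beyond")
})

test_that("Cox hazard ratios recover a planted coefficient", {
  set.seed(95)
  n <- 500
  x <- rnorm(n)
  tt <- rexp(n, rate = 0.002 * exp(0.5 * x))
  cc <- runif(n, 0, 1500)
  d <- list(time = pmin(tt, cc), event = as.integer(tt <= cc))
  fit <- cox_hr(x, d$time, d$event)
  expect_lt(abs(fit$beta - 0.5), 0.1)
  expect_gt(fit$hr, 1)
  expect_lt(fit$p, 0.001)

  # reparameterisation: scaling the score by c rescales beta by 1/c
  fit2 <- cox_hr(2 * x, d$time, d$event)
  expect_equal(fit2$beta, fit$beta / 2, tolerance = 1e-6)

  # multivariate: adjusting for noise covariates keeps the estimate
  fit3 <- cox_hr(x, d$time, d$event,
                 covariates = data.frame(z1 = rnorm(n), z2 = rnorm(n)))
  expect_lt(abs(fit3$beta - 0.5), 0.12)
})

test_that("the null Cox CI covers 1 at nominal rate", {
  set.seed(97)
  cover <- vapply(1:200, function(b) {
    n <- 100
    x <- rnorm(n)
    tt <- rexp(n, 0.002)
    cc <- runif(n, 0, 1500)
    f <- cox_hr(x, pmin(tt, cc), as.integer(tt <= cc))
    f$lower <= 1 && f$upper >= 1
  }, logical(1))
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})
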