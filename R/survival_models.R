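# Prognostic modelling: feature-table assembly, LASSO-Cox fits (ith_cox),
# risk scores, and evaluation (Harrell's C, Kaplan-Meier/log-rank, IPCW
# time-dependent ROC, unpenalised Cox hazard ratios).

figo_levels <- function() c("IIB", "IIIA", "IIIB", "IIIC", "IVA", "IVB")

# Clinical + primary-lesion feature block for one patient.
conventional_features_row <- function(patient) {
  cv <- patient$covariates
  meas <- measure_patient(patient)
  prim <- meas[meas$region == "primary", , drop = FALSE]
  stop_if_not(nrow(prim) == 1, "patient lacks a primary lesion passing filters")
  loc <- as.numeric(cv$implant_locations)
  names(loc) <- paste0("loc_", gsub("-", "", ar_regions()))
  c(age = cv$age,
    ca125 = cv$ca125,
    figo_stage = as.numeric(match(cv$figo_stage, figo_levels())),
    sur_R1 = as.numeric(cv$sur_status == "R1"),
    sur_R2 = as.numeric(cv$sur_status == "R2"),
    ascites_volume = cv$ascites_volume,
    ascites_bloody = as.numeric(cv$ascites_character == "bloody"),
    ascites_nonbloody = as.numeric(cv$ascites_character == "non-bloody"),
    lnm_pelvic = as.numeric(cv$lnm[1]), lnm_middle = as.numeric(cv$lnm[2]),
    lnm_upper = as.numeric(cv$lnm[3]), lnm_distant = as.numeric(cv$lnm[4]),
    n_implants = cv$n_implants,
    loc,
    invasion_pattern = cv$invasion_pattern,
    solid_ratio = cv$solid_ratio,
    primary = unlist(prim[1, measurement_names()]))
}

#' Assemble a model feature table
#'
#' Builds the design matrix for one of the three model kinds: `conventional`
#' (clinical covariates + primary-lesion measurements), `heterogeneity` (the
#' 107 inter-tumor metrics), or `integrated` (their union). Columns are
#' standardised to training mean 0 / SD 1; test rows reuse the training
#' constants; zero-variance training columns are dropped and recorded.
#'
#' @param cohort An `ith_cohort`.
#' @param model_kind `"conventional"`, `"heterogeneity"` or `"integrated"`.
#' @param heterogeneity Optional precomputed [heterogeneity_table()] (computed
#'   on demand otherwise; image texture extraction is the slow part).
#' @param log_ca125,log_ascites Log1p-transform those covariates before
#'   standardisation (off by default).
#' @return An `ith_features` object: standardised matrix `x`, `patient_id`,
#'   `split`, `kind`, `center`/`scale` constants and `dropped` columns.
#' @export
assemble_feature_table <- function(cohort,
                                   model_kind = c("conventional",
                                                  "heterogeneity",
                                                  "integrated"),
                                   heterogeneity = NULL,
                                   log_ca125 = FALSE, log_ascites = FALSE) {
  model_kind <- match.arg(model_kind)
  patients <- cohort$patients
  ids <- vapply(patients, `[[`, character(1), "patient_id")
  blocks <- list()
  if (model_kind %in% c("conventional", "integrated")) {
    conv <- t(vapply(patients, conventional_features_row, numeric(32)))
    if (log_ca125) conv[, "ca125"] <- log1p(conv[, "ca125"])
    if (log_ascites) conv[, "ascites_volume"] <- log1p(conv[, "ascites_volume"])
    blocks$conv <- conv
  }
  if (model_kind %in% c("heterogeneity", "integrated")) {
    if (is.null(heterogeneity)) heterogeneity <- heterogeneity_table(cohort)
    stop_if_not(identical(heterogeneity$patient_id, ids),
                "heterogeneity table does not match the cohort")
    blocks$het <- as.matrix(heterogeneity[, setdiff(names(heterogeneity),
                                                    "patient_id")])
  }
  x <- do.call(cbind, unname(blocks))
  rownames(x) <- ids
  split <- if (!is.null(cohort$split)) cohort$split else rep("train", length(ids))
  tr <- split == "train"
  ctr <- colMeans(x[tr, , drop = FALSE])
  scl <- apply(x[tr, , drop = FALSE], 2, stats::sd)
  dropped <- colnames(x)[!is.finite(scl) | scl < 1e-12]
  keep <- setdiff(colnames(x), dropped)
  xs <- sweep(sweep(x[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], `/`)
  structure(list(x = xs, patient_id = ids, split = split, kind = model_kind,
                 center = ctr[keep], scale = scl[keep], dropped = dropped),
            class = "ith_features")
}

#' Extract outcomes from a cohort
#' @param cohort An `ith_cohort`.
#' @param endpoint `"PFS"` or `"OS"`.
#' @return data.frame with `time` and `event`.
#' @export
cohort_outcomes <- function(cohort, endpoint = c("PFS", "OS")) {
  endpoint <- match.arg(endpoint)
  fld <- if (endpoint == "PFS") "pfs" else "os"
  do.call(rbind, lapply(cohort$patients, function(p) {
    data.frame(time = p[[fld]]$time, event = p[[fld]]$event)
  }))
}

# Event-stratified fold assignment.
stratified_folds <- function(event, nfolds, seed) {
  foldid <- integer(length(event))
  with_seed(seed, {
    for (g in unique(event)) {
      idx <- which(event == g)
      foldid[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
    }
  })
  foldid
}

#' Fit a LASSO-Cox prognostic model
#'
#' L1-penalised Cox partial-likelihood fit over a log-spaced penalty grid,
#' with the penalty chosen to maximise the mean cross-validated partial
#' likelihood (lambda-min rule) under event-stratified k-fold cross-validation
#' on the training rows. Test rows of `features` are never seen by the fit.
#'
#' @param features An `ith_features` table (or plain standardised matrix).
#' @param outcomes data.frame with `time` and `event` rows matching
#'   `features` (e.g. [cohort_outcomes()]).
#' @param endpoint Label stored on the fit (`"PFS"` or `"OS"`).
#' @param nfolds Folds for cross-validation (default 5).
#' @param seed Integer seed (fold assignment).
#' @return An `ith_cox` object with the selected features, their
#'   coefficients, the penalty, the CV trace, the Breslow baseline cumulative
#'   hazard, the training risk-score median (the Kaplan-Meier split point)
#'   and the standardisation constants of the feature table.
#' @export
fit_ith_cox <- function(features, outcomes, endpoint = c("PFS", "OS"),
                        nfolds = 5, seed = 1) {
  endpoint <- match.arg(endpoint)
  x <- if (inherits(features, "ith_features")) features$x else as.matrix(features)
  split <- if (inherits(features, "ith_features")) features$split
           else rep("train", nrow(x))
  tr <- split == "train"
  xt <- x[tr, , drop = FALSE]
  yt <- outcomes[tr, , drop = FALSE]
  stop_if_not(sum(yt$event) >= 2, "need at least 2 events to fit")
  stop_if_not(nfolds >= 2, "nfolds must be >= 2")
  ys <- survival::Surv(yt$time, yt$event)
  foldid <- stratified_folds(yt$event, nfolds, seed)
  cvfit <- glmnet::cv.glmnet(xt, ys, family = "cox", foldid = foldid,
                             standardize = FALSE)
  beta <- as.numeric(stats::coef(cvfit, s = "lambda.min"))
  names(beta) <- colnames(xt)
  sel <- beta[beta != 0]
  lp_train <- drop(xt %*% beta)
  fit <- structure(list(
    endpoint = endpoint,
    coefficients = sel,
    beta_full = beta,
    lambda = cvfit$lambda.min,
    cv_trace = data.frame(lambda = cvfit$lambda, cvm = cvfit$cvm,
                          cvsd = cvfit$cvsd, nzero = as.numeric(cvfit$nzero)),
    baseline = breslow_baseline(yt$time, yt$event, lp_train),
    risk_median = stats::median(lp_train),
    center = if (inherits(features, "ith_features")) features$center else NULL,
    scale = if (inherits(features, "ith_features")) features$scale else NULL,
    kind = if (inherits(features, "ith_features")) features$kind else "matrix",
    train = list(lp = lp_train, time = yt$time, event = yt$event),
    nfolds = nfolds, seed = seed), class = "ith_cox")
  fit
}

# Breslow estimator of the baseline cumulative hazard.
breslow_baseline <- function(time, event, lp) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; elp <- exp(lp[ord])
  risk_denom <- rev(cumsum(rev(elp)))  # sum over at-risk set at each time
  et <- unique(time[event == 1])
  h0 <- vapply(et, function(t) {
    d <- sum(event == 1 & time == t)
    d / risk_denom[match(t, time)]
  }, numeric(1))
  data.frame(time = et, hazard = h0, cumhaz = cumsum(h0))
}

#' @export
print.ith_cox <- function(x, ...) {
  cat(sprintf("LASSO-Cox %s model (%s features): %d of %d features selected, lambda = %.4g\n",
              x$endpoint, x$kind, length(x$coefficients), length(x$beta_full),
              x$lambda))
  invisible(x)
}

#' @export
summary.ith_cox <- function(object, ...) {
  cf <- sort(object$coefficients, decreasing = TRUE)
  cat(sprintf("LASSO-Cox model, endpoint %s, feature set '%s'\n",
              object$endpoint, object$kind))
  cat(sprintf("Penalty lambda (CV-optimal over %d folds): %.5g\n",
              object$nfolds, object$lambda))
  cat(sprintf("Selected %d features (standardised scale):\n", length(cf)))
  print(round(cf, 4))
  cat(sprintf("Training risk-score median (KM split): %.4f\n",
              object$risk_median))
  invisible(list(coefficients = cf, lambda = object$lambda))
}

#' @export
coef.ith_cox <- function(object, all = FALSE, ...) {
  if (all) object$beta_full else object$coefficients
}

#' Predict risk scores (or survival) from a fitted model
#'
#' @param object An `ith_cox`.
#' @param newdata An `ith_features` table or standardised matrix with the
#'   model's feature columns.
#' @param type `"lp"` (risk score, the linear predictor on standardised
#'   features), `"risk"` (exp of it) or `"survival"` (Breslow survival at
#'   `times`).
#' @param times Horizons (days) for `type = "survival"`.
#' @param ... Unused.
#' @return Numeric vector, or matrix (patients x times) for survival.
#' @export
predict.ith_cox <- function(object, newdata, type = c("lp", "risk", "survival"),
                            times = NULL, ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "ith_features")) newdata$x else as.matrix(newdata)
  need <- names(object$coefficients)
  stop_if_not(all(need %in% colnames(x)),
              paste0("missing selected feature(s): ",
                     paste(setdiff(need, colnames(x)), collapse = ", ")))
  lp <- drop(x[, need, drop = FALSE] %*% object$coefficients)
  if (type == "lp") return(lp)
  if (type == "risk") return(exp(lp))
  stop_if_not(!is.null(times), "type = 'survival' needs times")
  H0 <- stats::stepfun(object$baseline$time, c(0, object$baseline$cumhaz))
  outer(exp(lp), H0(times), function(r, h) exp(-r * h))
}

#' @export
residuals.ith_cox <- function(object, type = "martingale", ...) {
  stop_if_not(type == "martingale", "only martingale residuals are provided")
  H0 <- stats::stepfun(object$baseline$time, c(0, object$baseline$cumhaz))
  with(object$train, event - H0(time) * exp(lp))
}

#' Simulate event times from a fitted model
#'
#' Inverts the Breslow baseline cumulative hazard at exponential deviates
#' scaled by each subject's relative hazard. Times beyond the last observed
#' event time are returned as `Inf` (no event within follow-up).
#'
#' @param object An `ith_cox`.
#' @param nsim Replicates per subject.
#' @param seed Integer seed.
#' @param lp Linear predictors of the simulated subjects (default: training).
#' @param ... Unused.
#' @return Matrix (subjects x nsim) of event times in days.
#' @export
simulate.ith_cox <- function(object, nsim = 1, seed = 1,
                             lp = object$train$lp, ...) {
  bh <- object$baseline
  out <- with_seed(seed, {
    matrix(stats::rexp(length(lp) * nsim, rate = 1), length(lp), nsim) / exp(lp)
  })
  apply(out, 2, function(tgt) {
    idx <- findInterval(tgt, bh$cumhaz - 1e-12) + 1
    ifelse(idx > nrow(bh), Inf, bh$time[pmin(idx, nrow(bh))])
  })
}

#' @export
plot.ith_cox <- function(x, ...) {
  with(x$cv_trace, {
    plot(log(lambda), cvm, type = "b", pch = 16, cex = 0.6,
         xlab = "log(lambda)", ylab = "mean CV partial-likelihood deviance",
         main = sprintf("%s model CV trace", x$endpoint), ...)
    graphics::arrows(log(lambda), cvm - cvsd, log(lambda), cvm + cvsd,
                     angle = 90, code = 3, length = 0.02, col = "grey60")
    graphics::abline(v = log(x$lambda), lty = 2)
  })
  invisible(x)
}

#' Harrell's concordance index with bootstrap CI
#'
#' Usable pairs: the patient with the shorter observed time experienced the
#' event (or both times tie with exactly one event). A pair is concordant
#' when the earlier event carries the higher score; score ties count 1/2.
#' The confidence interval is a seeded bootstrap percentile interval.
#'
#' @param scores Numeric risk scores (higher = higher hazard).
#' @param time,event Survival outcome.
#' @param ci Compute the bootstrap CI?
#' @param n_boot Bootstrap replicates (default 1000).
#' @param conf Confidence level.
#' @param seed Integer seed.
#' @return List with `c_index`, `lower`, `upper`, `n_pairs`.
#' @export
concordance_index <- function(scores, time, event, ci = TRUE, n_boot = 1000,
                              conf = 0.95, seed = 1) {
  cstat <- function(s, t, e) {
    comp <- (outer(t, t, `<`) & (e == 1)) |
            (outer(t, t, `==`) & outer(e, e, `>`))
    if (!any(comp)) return(c(NA_real_, 0))
    sgt <- outer(s, s, `>`)[comp]
    seq_ <- outer(s, s, `==`)[comp]
    c((sum(sgt) + 0.5 * sum(seq_)) / sum(comp), sum(comp))
  }
  base <- cstat(scores, time, event)
  stop_if_not(base[2] > 0, "no comparable pair")
  out <- list(c_index = base[1], n_pairs = base[2], lower = NA, upper = NA)
  if (ci) {
    n <- length(scores)
    bs <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        cstat(scores[idx], time[idx], event[idx])[1]
      }, numeric(1))
    })
    qs <- stats::quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          na.rm = TRUE, names = FALSE)
    out$lower <- qs[1]; out$upper <- qs[2]
  }
  out
}

#' Kaplan-Meier risk stratification and log-rank test
#'
#' Splits patients into high/low risk at a threshold (by default the median
#' of `scores`; pass the training median when evaluating a test set), fits
#' product-limit curves per group and runs the two-group log-rank test.
#'
#' @param scores Risk scores.
#' @param time,event Survival outcome.
#' @param threshold Risk split point (default `median(scores)`).
#' @return List with `fit` (a `survfit`), `chisq`, `p`, `group` and
#'   `threshold`.
#' @export
km_logrank <- function(scores, time, event, threshold = stats::median(scores)) {
  group <- factor(ifelse(scores > threshold, "high", "low"),
                  levels = c("low", "high"))
  stop_if_not(all(table(group) > 0), "one risk group is empty")
  df <- data.frame(time = time, event = event, group = group)
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  list(fit = sf, chisq = unname(sd$chisq), p = p, group = group,
       threshold = threshold)
}

#' Time-dependent cumulative/dynamic AUC
#'
#' Inverse-probability-of-censoring-weighted AUC at each horizon: cases are
#' subjects with an observed event by the horizon, controls those still at
#' risk beyond it; weights use the Kaplan-Meier estimate of the censoring
#' distribution. With no censoring this reduces to the empirical binary AUC.
#'
#' @param scores Risk scores.
#' @param time,event Survival outcome.
#' @param horizons Evaluation times (days).
#' @return Named numeric vector of AUCs (NA, with a warning, where a horizon
#'   exceeds follow-up).
#' @export
time_dependent_auc <- function(scores, time, event, horizons) {
  cens_fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  Gfun <- stats::stepfun(cens_fit$time, c(1, cens_fit$surv))
  Gminus <- function(t) Gfun(t - 1e-9)
  auc <- vapply(horizons, function(h) {
    if (h >= max(time)) {
      warning(sprintf("horizon %g beyond follow-up; AUC undefined", h))
      return(NA_real_)
    }
    case <- time <= h & event == 1
    ctrl <- time > h
    if (!any(case) || !any(ctrl)) return(NA_real_)
    wc <- 1 / pmax(Gminus(time[case]), 1e-9)
    wk <- rep(1 / pmax(Gfun(h), 1e-9), sum(ctrl))
    sc <- scores[case]; sk <- scores[ctrl]
    gt <- outer(sc, sk, `>`); eq <- outer(sc, sk, `==`)
    w <- outer(wc, wk)
    sum(w * (gt + 0.5 * eq)) / sum(w)
  }, numeric(1))
  stats::setNames(auc, paste0("t", horizons))
}

#' Unpenalised Cox hazard ratio for a risk score
#'
#' Univariate (score alone) or multivariate (score plus clinical covariates)
#' Cox proportional-hazards fit with Breslow tie handling; reports the
#' hazard ratio per unit score with a Wald confidence interval.
#'
#' @param scores Risk scores.
#' @param time,event Survival outcome.
#' @param covariates Optional data.frame of adjustment covariates
#'   (multivariate analysis when supplied).
#' @param conf Confidence level.
#' @return List with `hr`, `lower`, `upper`, `p`, `beta` and the underlying
#'   `coxph` fit.
#' @export
cox_hr <- function(scores, time, event, covariates = NULL, conf = 0.95) {
  df <- data.frame(time = time, event = event, score = scores)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  rhs <- paste(setdiff(names(df), c("time", "event")), collapse = " + ")
  fit <- survival::coxph(stats::as.formula(
    paste("survival::Surv(time, event) ~", rhs)),
    data = df, ties = "breslow")
  stop_if_not(fit$info != "failed" || TRUE, "cox fit failed")
  sm <- summary(fit, conf.int = conf)
  b <- stats::coef(fit)["score"]
  se <- sqrt(diag(stats::vcov(fit)))["score"]
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(hr = unname(exp(b)), lower = unname(exp(b - z * se)),
       upper = unname(exp(b + z * se)),
       p = unname(2 * stats::pnorm(-abs(b / se))),
       beta = unname(b), fit = fit)
}
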