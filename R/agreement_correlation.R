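# Immunohistochemistry H-scores, Spearman correlation of risk scores with
# marker expression, and ICC-based test-retest screening of the
# heterogeneity metrics.

#' Immunohistochemistry H-score
#'
#' `weak*1 + moderate*2 + strong*3` over staining-intensity percentages;
#' range 0 to 300.
#'
#' @param weak_pct,moderate_pct,strong_pct Percentages (vectors allowed),
#'   each >= 0, jointly summing to at most 100.
#' @return Numeric H-score(s) in \[0, 300\].
#' @export
h_score <- function(weak_pct, moderate_pct, strong_pct) {
  stop_if_not(all(weak_pct >= 0) && all(moderate_pct >= 0) &&
              all(strong_pct >= 0), "percentages must be >= 0")
  stop_if_not(all(weak_pct + moderate_pct + strong_pct <= 100 + 1e-9),
              "stained percentages must sum to at most 100")
  weak_pct * 1 + moderate_pct * 2 + strong_pct * 3
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties. The p-value uses the exact
#' permutation null for n <= 8 and the t-approximation above that.
#'
#' @param x,y Paired numeric vectors, n >= 3.
#' @return List with `rho`, `p` and `n`.
#' @export
spearman_cor <- function(x, y) {
  stop_if_not(length(x) == length(y), "x and y must be paired")
  n <- length(x)
  stop_if_not(n >= 3, "need n >= 3")
  stop_if_not(stats::sd(x) > 0 && stats::sd(y) > 0,
              "rho undefined for a constant vector")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- stats::cor(rx, ry)
  if (n <= 8) {
    perms <- permutations_all(n)
    null_rho <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(null_rho) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2 + 1e-300))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = min(p, 1), n = n)
}

# All permutations of 1..n (n small) as a matrix, one per row.
permutations_all <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_all(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- cbind(sub[, seq_len(pos - 1), drop = FALSE], n,
                 sub[, seq(pos, n - 1)[seq_len(n - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}

#' Intraclass correlation coefficient
#'
#' From the standard two-way mean-square decomposition of an n x k ratings
#' matrix. `form = "intra"` gives the two-way mixed, consistency, single
#' measurement ICC(3,1); `form = "inter"` the two-way random, absolute
#' agreement, single measurement ICC(2,1).
#'
#' @param ratings Numeric matrix, subjects in rows, raters/sessions in
#'   columns (n >= 2 subjects, k >= 2 columns).
#' @param form `"intra"` or `"inter"`.
#' @return ICC value (NA with a warning when the between-subject variance is
#'   zero).
#' @export
icc <- function(ratings, form = c("intra", "inter")) {
  form <- match.arg(form)
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  stop_if_not(n >= 2 && k >= 2, "need >= 2 subjects and >= 2 raters")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (msr < 1e-300) {
    warning("zero between-subject variance; ICC undefined")
    return(NA_real_)
  }
  if (form == "intra") {
    (msr - mse) / (msr + (k - 1) * mse)
  } else {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  }
}

#' Test-retest reproducibility screen of heterogeneity metrics
#'
#' Computes a per-metric ICC between two extraction runs (e.g. original vs
#' repeat segmentation) and flags metrics whose ICC exceeds the screening
#' threshold.
#'
#' @param metrics_run1,metrics_run2 data.frames with identical metric columns
#'   (a `patient_id` column, if present, is matched and dropped).
#' @param threshold Screening threshold (default 0.75).
#' @param form ICC form, see [icc()].
#' @return An `agreement_report`: data.frame (metric, icc, pass) with
#'   attributes `fraction_pass` and `threshold`.
#' @export
reproducibility_screen <- function(metrics_run1, metrics_run2,
                                   threshold = 0.75, form = "inter") {
  drop_id <- function(d) d[, setdiff(names(d), "patient_id"), drop = FALSE]
  if ("patient_id" %in% names(metrics_run1) &&
      "patient_id" %in% names(metrics_run2)) {
    stop_if_not(identical(metrics_run1$patient_id, metrics_run2$patient_id),
                "patient ids differ between runs")
  }
  m1 <- drop_id(as.data.frame(metrics_run1))
  m2 <- drop_id(as.data.frame(metrics_run2))
  stop_if_not(identical(names(m1), names(m2)),
              "metric columns differ between runs")
  iccs <- vapply(names(m1), function(nm) {
    suppressWarnings(icc(cbind(m1[[nm]], m2[[nm]]), form = form))
  }, numeric(1))
  out <- data.frame(metric = names(m1), icc = unname(iccs),
                    pass = unname(iccs) > threshold)
  out$pass[is.na(out$icc)] <- FALSE
  structure(out, fraction_pass = mean(out$pass), threshold = threshold,
            class = c("agreement_report", "data.frame"))
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "Reproducibility screen: %d/%d metrics with ICC > %.2f (%.1f%%); min ICC = %.3f\n",
    sum(x$pass), nrow(x), attr(x, "threshold"), 100 * attr(x, "fraction_pass"),
    min(x$icc, na.rm = TRUE)))
  invisible(x)
}

#' Correlate model risk scores with immunohistochemistry H-scores
#'
#' Runs [spearman_cor()] for every risk-score column against every marker's
#' H-score, on the patients carrying stain data.
#'
#' @param risk_scores data.frame: `patient_id` plus one column per model risk
#'   score.
#' @param stains data.frame: `patient_id`, `marker`, `weak_pct`,
#'   `moderate_pct`, `strong_pct`.
#' @return data.frame with `marker`, `model`, `rho`, `p`, `n`.
#' @export
correlate_risk_stains <- function(risk_scores, stains) {
  stains$h <- h_score(stains$weak_pct, stains$moderate_pct, stains$strong_pct)
  models <- setdiff(names(risk_scores), "patient_id")
  out <- list()
  for (mk in unique(stains$marker)) {
    sub <- stains[stains$marker == mk, ]
    idx <- match(sub$patient_id, risk_scores$patient_id)
    for (md in models) {
      sc <- spearman_cor(risk_scores[[md]][idx], sub$h)
      out[[length(out) + 1L]] <- data.frame(marker = mk, model = md,
                                            rho = sc$rho, p = sc$p, n = sc$n)
    }
  }
  do.call(rbind, out)
}
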