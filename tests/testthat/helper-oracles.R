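# Independent brute-force oracles and shared fixtures. These deliberately
# avoid the package's code paths (naive loops, sort-based quantiles) so they
# can certify the vectorised implementations.

# --- cross-lesion statistics, the naive way -------------------------------

brute_quantile <- function(x, p) {
  xs <- sort(x)
  h <- (length(xs) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

brute_stats <- function(x) {
  n <- length(x)
  s <- 0; for (v in x) s <- s + v
  m <- s / n
  css <- 0; uss <- 0; m2 <- 0; m3 <- 0; m4 <- 0
  for (v in x) {
    css <- css + (v - m)^2
    uss <- uss + v^2
    m2 <- m2 + (v - m)^2 / n
    m3 <- m3 + (v - m)^3 / n
    m4 <- m4 + (v - m)^4 / n
  }
  v_samp <- css / (n - 1)
  xs <- sort(x)
  med <- if (n %% 2 == 1) xs[(n + 1) / 2] else (xs[n / 2] + xs[n / 2 + 1]) / 2
  r4 <- signif(x, 4)
  best <- NULL; best_n <- 0
  for (u in sort(unique(r4))) {
    cnt <- sum(r4 == u)
    if (cnt > best_n) { best <- u; best_n <- cnt }
  }
  list(Mean = m, Median = med, Mode = best,
       R = (brute_quantile(x, 0.75) - brute_quantile(x, 0.25)) / 2,
       Std_dev = sqrt(v_samp), SM = sqrt(v_samp / n), Variance = v_samp,
       Range = max(x) - min(x),
       CV = if (m == 0) 0 else sqrt(v_samp) / abs(m),
       CSS = css, USS = uss,
       Kurtosis = if (m2 == 0) 0 else m4 / m2^2 - 3,
       Skewness = if (m2 == 0) 0 else m3 / m2^1.5)
}

# --- GLCM / Haralick ------------------------------------------------------

brute_glcm <- function(levels, mask) {
  G <- 8
  d <- dim(levels)
  counts <- matrix(0, G, G)
  idx <- which(mask != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      q <- idx[r, ] + c(dx, dy, dz)
      if (any(q < 1) || any(q > d)) next
      if (!mask[q[1], q[2], q[3]]) next
      a <- levels[idx[r, 1], idx[r, 2], idx[r, 3]]
      b <- levels[q[1], q[2], q[3]]
      counts[a, b] <- counts[a, b] + 1
    }
  }
  counts / sum(counts)
}

brute_haralick <- function(p) {
  G <- nrow(p)
  en <- 0; ent <- 0; con <- 0; hom <- 0
  for (i in 1:G) for (j in 1:G) {
    en <- en + p[i, j]^2
    if (p[i, j] > 0) ent <- ent - p[i, j] * log2(p[i, j])
    con <- con + (i - j)^2 * p[i, j]
    hom <- hom + p[i, j] / (1 + abs(i - j))
  }
  c(energy = en, entropy = ent, contrast = con, homogeneity = hom)
}

# --- zone counting by recursive flood fill --------------------------------

brute_zone_count <- function(levels, mask) {
  d <- dim(levels)
  seen <- array(FALSE, dim = d)
  nz <- 0
  idx <- which(mask != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    if (seen[v[1], v[2], v[3]]) next
    nz <- nz + 1
    g <- levels[v[1], v[2], v[3]]
    stack <- list(v)
    seen[v[1], v[2], v[3]] <- TRUE
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        q <- cur + c(dx, dy, dz)
        if (any(q < 1) || any(q > d)) next
        if (seen[q[1], q[2], q[3]] || !mask[q[1], q[2], q[3]]) next
        if (levels[q[1], q[2], q[3]] != g) next
        seen[q[1], q[2], q[3]] <- TRUE
        stack[[length(stack) + 1L]] <- q
      }
    }
  }
  nz
}

# --- survival oracles -----------------------------------------------------

brute_cindex <- function(s, t, e) {
  num <- 0; den <- 0
  n <- length(s)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    usable <- (t[i] < t[j] && e[i] == 1) || (t[i] == t[j] && e[i] == 1 && e[j] == 0)
    if (!usable) next
    den <- den + 1
    if (s[i] > s[j]) num <- num + 1
    else if (s[i] == s[j]) num <- num + 0.5
  }
  num / den
}

brute_binary_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# ICC from the aov() decomposition (independent of the package arithmetic).
aov_icc <- function(ratings, form) {
  n <- nrow(ratings); k <- ncol(ratings)
  df <- data.frame(y = as.vector(ratings),
                   subj = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  av <- summary(stats::aov(y ~ subj + rater, data = df))[[1]]
  msr <- av["subj", "Mean Sq"]; msc <- av["rater", "Mean Sq"]
  mse <- av["Residuals", "Mean Sq"]
  if (form == "intra") (msr - mse) / (msr + (k - 1) * mse)
  else (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# --- fixtures -------------------------------------------------------------

# A lesion with a hand-specified box mask and constant-plus-structure values.
box_lesion <- function(values, spacing = c(1, 1, 1), region = "primary",
                       id = "L1", suv = NULL) {
  mask <- array(TRUE, dim = dim(values))
  if (is.null(suv)) suv <- pmax(values / 10, 0)
  lesion_voi(id, region, voxel_grid(values, spacing),
             voxel_grid(suv, spacing), mask)
}

# Patient whose lesions are all bit-identical constant phantoms: every
# dispersion and texture heterogeneity metric must vanish.
clone_patient <- function(n_lesions = 3, diameter = 12) {
  regs <- c("primary", paste0("AR-", seq_len(n_lesions - 1) - 1))
  lesions <- lapply(seq_len(n_lesions), function(i) {
    l <- generate_lesion_phantom(regs[i], diameter,
      intensity = list(hu_mean = 40, suv_mean = 5, hu_sd = 0, suv_sd = 0),
      texture = list(corr_mm = 2), spacing = c(1, 1, 3.8), seed = 99,
      lesion_id = paste0("C_L", i))
    l
  })
  structure(list(patient_id = "C", lesions = lesions,
                 covariates = NULL, pfs = NULL, os = NULL,
                 stain_fractions = NULL, truth = NULL),
            class = "ith_patient")
}

# Small cached cohort shared across tests (built once per test run).
.fixture_env <- new.env()

small_cohort <- function() {
  if (is.null(.fixture_env$coh)) {
    cfg <- sim_config(n_train = 6, n_test = 3, lesion_diameter = c(8, 14))
    .fixture_env$coh <- simulate_cohort(cfg, seed = 42)
  }
  .fixture_env$coh
}

small_het_table <- function() {
  if (is.null(.fixture_env$het)) {
    .fixture_env$het <- heterogeneity_table(small_cohort(), seed = 11)
  }
  .fixture_env$het
}
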