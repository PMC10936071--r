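# CT-texture heterogeneity: discretization, GLCM/Haralick, subregions,
# dissimilarities, cSE, GLDZM, cluDev/cluDiss.

cube_gray <- function(values) {
  mask <- array(TRUE, dim = dim(values))
  discretize_ct(values, mask)
}

test_that("discretization maps the masked range onto 8 levels", {
  const <- array(7, dim = c(3, 3, 3))
  expect_warning(g <- cube_gray(const), "constant")
  expect_true(all(g$levels[g$mask] == 1L))
  expect_identical(g$G, 8L)

  v <- array(runif(4 * 4 * 4, 10, 60), dim = c(4, 4, 4))
  v[1, 1, 1] <- 10; v[4, 4, 4] <- 60
  g <- cube_gray(v)
  expect_identical(g$levels[1, 1, 1], 1L)
  expect_identical(g$levels[4, 4, 4], 8L)
  expect_true(all(g$levels[g$mask] >= 1 & g$levels[g$mask] <= 8))

  set.seed(3)
  big <- array(runif(22^3, 0, 100), dim = c(22, 22, 22))
  g <- cube_gray(big)
  counts <- tabulate(g$levels[g$mask], 8)
  chisq <- sum((counts - mean(counts))^2 / mean(counts))
  expect_lt(chisq, qchisq(0.999, df = 7))  # near-uniform occupancy
})

test_that("GLCM matches exhaustive pair enumeration and is a distribution", {
  # constant lesion: all mass at (1, 1)
  expect_warning(g <- cube_gray(array(5, dim = c(3, 3, 2))))
  p <- glcm(g)
  expect_equal(unclass(p)[1, 1], 1)
  expect_equal(sum(p), 1)

  # 2 x 2 x 1 checkerboard: hand enumeration over all distance-1 pairs
  lev <- array(c(1L, 2L, 2L, 1L), dim = c(2, 2, 1))
  gch <- list(levels = lev * 4L - 3L, mask = array(TRUE, dim = c(2, 2, 1)),
              G = 8L)
  class(gch) <- "gray_volume"
  # levels used: 1 and 5; expected counts: 4 bidirectional unlike pairs along
  # each in-plane axis (8), 2 bidirectional like pairs along each diagonal (4)
  p <- unclass(glcm(gch))
  expect_equal(p[1, 5], 4 / 12)
  expect_equal(p[5, 1], 4 / 12)
  expect_equal(p[1, 1], 2 / 12)
  expect_equal(p[5, 5], 2 / 12)
  expect_equal(sum(p), 1)

  set.seed(9)
  v <- array(runif(5 * 5 * 4, -50, 80), dim = c(5, 5, 4))
  mask <- array(runif(100) > 0.3, dim = c(5, 5, 4))
  g <- discretize_ct(v, mask)
  p <- unclass(glcm(g))
  expect_equal(p, t(p))
  expect_equal(sum(p), 1)
  expect_equal(p, brute_glcm(g$levels, mask), tolerance = 1e-12)
})

test_that("Haralick features match closed forms and the brute-force sums", {
  pt <- matrix(0, 8, 8); pt[1, 1] <- 1
  h <- haralick(pt)
  expect_equal(unname(h), c(1, 0, 0, 1))

  pu <- matrix(1 / 64, 8, 8)
  h <- haralick(pu)
  expect_equal(unname(h["entropy"]), 6)
  expect_equal(unname(h["energy"]), 1 / 64)

  set.seed(4)
  pr <- matrix(rexp(64), 8, 8); pr <- (pr + t(pr)); pr <- pr / sum(pr)
  expect_equal(haralick(pr), brute_haralick(pr), tolerance = 1e-12)
  expect_error(haralick(2 * pr), "normalized")
})

test_that("subregion clustering recovers planted compartments deterministically", {
  expect_warning(gc_ <- cube_gray(array(1, dim = c(4, 4, 3))))
  sub <- subregion_cluster(gc_, k = 3, seed = 5)
  expect_identical(sub$k, 1L)
  expect_equal(nrow(sub$signatures), 1)

  # two HU plateaus -> k = 2 recovers the compartments
  v <- array(0, dim = c(10, 6, 4)); v[6:10, , ] <- 100
  set.seed(2); v <- v + array(rnorm(length(v), sd = 1), dim = dim(v))
  g <- cube_gray(v)
  sub <- subregion_cluster(g, k = 2, seed = 7)
  truth <- as.integer(which(g$mask, arr.ind = TRUE)[, 1] >= 6)
  agree <- max(mean(sub$labels - 1 == truth), mean(2 - sub$labels == truth))
  expect_gte(agree, 0.95)

  sub2 <- subregion_cluster(g, k = 2, seed = 7)
  expect_identical(sub$labels, sub2$labels)
})

test_that("dissimilarity matrices are plain Euclidean distances", {
  sig <- rbind(c(0, 0), c(0, 0))
  expect_true(all(dissimilarity_matrix(sig) == 0))
  d <- dissimilarity_matrix(rbind(c(0, 0), c(3, 4)))
  expect_equal(d[1, 2], 5)
  set.seed(11)
  s <- matrix(rnorm(18), 6, 3)
  d <- dissimilarity_matrix(s)
  for (i in 1:6) for (j in 1:6) {
    expect_equal(d[i, j], sqrt(sum((s[i, ] - s[j, ])^2)), tolerance = 1e-12)
  }
  expect_error(dissimilarity_matrix(list(c(1, 2), c(1, 2, 3))), "dimension")
})

test_that("cluster site entropy bins pairwise dissimilarities", {
  expect_equal(cluster_site_entropy(matrix(0, 4, 4)), 0)

  # 10 distances filling each of the 10 bins exactly once -> log2(10) bits
  u <- seq(0.5, 9.5, by = 1)
  m <- matrix(0, 5, 5)
  m[upper.tri(m)] <- u
  m <- m + t(m)
  expect_equal(cluster_site_entropy(m, n_bins = 10), log2(10))

  set.seed(14)
  s <- matrix(rnorm(24), 8, 3)
  d <- dissimilarity_matrix(s)
  ud <- d[upper.tri(d)]
  bins <- pmin(floor(ud / max(ud) * 10) + 1, 10)
  p <- as.vector(table(bins)) / length(ud)
  expect_equal(cluster_site_entropy(d), -sum(p * log2(p)), tolerance = 1e-12)
})

test_that("GLDZM zones follow connected components and border distances", {
  expect_warning(g <- cube_gray(array(3, dim = c(4, 4, 4))))
  z <- gldzm(g)
  expect_identical(z$n_zones, 1)
  expect_equal(sum(z$z[1, ]), 1)  # the single zone sits at gray level 1

  # two disjoint plateaus of distinct levels -> 2 zones
  v <- array(0, dim = c(7, 3, 3)); v[5:7, , ] <- 100
  mask <- array(TRUE, dim = dim(v)); mask[4, , ] <- FALSE
  g2 <- discretize_ct(v, mask)
  expect_identical(gldzm(g2)$n_zones, 2)

  set.seed(21)
  v <- array(runif(5 * 5 * 3, 0, 40), dim = c(5, 5, 3))
  mask <- array(runif(75) > 0.25, dim = c(5, 5, 3))
  g3 <- discretize_ct(v, mask)
  expect_identical(gldzm(g3)$n_zones, brute_zone_count(g3$levels, mask))
})

test_that("cluDev and cluDiss summarise inter-lesion GLDZM distances", {
  a <- matrix(1 / 8, 8, 4) / 4
  expect_equal(unname(cluster_dev_diss(list(a, a, a))), c(0, 0))
  b <- a; b[1, 1] <- b[1, 1] + 0.3
  two <- cluster_dev_diss(list(a, b))
  expect_equal(unname(two["cluDev"]), 0)
  expect_equal(unname(two["cluDiss"]), 0.3)
  set.seed(31)
  vs <- lapply(1:4, function(i) matrix(runif(32), 8, 4))
  got <- cluster_dev_diss(vs)
  dd <- c()
  for (i in 1:3) for (j in (i + 1):4) {
    dd <- c(dd, sqrt(sum((as.vector(vs[[i]]) - as.vector(vs[[j]]))^2)))
  }
  expect_equal(unname(got["cluDiss"]), mean(dd), tolerance = 1e-12)
  expect_equal(unname(got["cluDev"]), sqrt(mean((dd - mean(dd))^2)),
               tolerance = 1e-12)
  expect_error(cluster_dev_diss(list(a)), "2 lesions")
})

test_that("texture metrics: 3 entries, zero for clones, reorder invariant", {
  p <- small_cohort()$patients[[2]]
  tx <- texture_heterogeneity(p, seed = 3)
  expect_identical(names(tx), c("cSE", "cluDev", "cluDiss"))
  expect_true(all(tx >= 0))
  expect_s3_class(attr(tx, "haralick"), "data.frame")

  cl <- clone_patient(4)
  txc <- texture_heterogeneity(cl, seed = 3)
  expect_identical(unname(as.vector(txc)), c(0, 0, 0))

  p_rev <- p; p_rev$lesions <- rev(p$lesions)
  tx_rev <- texture_heterogeneity(p_rev, seed = 3)
  expect_equal(as.vector(tx_rev), as.vector(tx), tolerance = 1e-12)
})

test_that("Haralick features are invariant under constant HU shifts", {
  p <- small_cohort()$patients[[3]]
  l <- p$lesions[[1]]
  g1 <- discretize_ct(l$ct$values, l$mask)
  g2 <- discretize_ct(l$ct$values + 120, l$mask)
  expect_identical(g1$levels, g2$levels)
  expect_equal(haralick(glcm(g1)), haralick(glcm(g2)))
})

test_that("planted between-lesion HU contrast raises cluDiss monotonically", {
  # 10-step sweep of the core-attenuation contrast between a patient's
  # lesions, averaged over 6 replicate phantoms per step
  sweep_pt <- function(delta, rep) {
    offs <- c(-delta, 0, delta)
    regs <- c("primary", "AR-1", "AR-2")
    lesions <- lapply(1:3, function(i) generate_lesion_phantom(regs[i], 11,
      intensity = list(hu_mean = 45, suv_mean = 5, hu_sd = 10, suv_sd = 1,
                       core_frac = 0.5, core_offset_hu = offs[i]),
      texture = list(corr_mm = 2.5), spacing = c(1, 1, 3.8),
      seed = 7000 + rep * 10 + i, lesion_id = paste0("L", i)))
    p <- structure(list(patient_id = "S", lesions = lesions),
                   class = "ith_patient")
    texture_heterogeneity(p, seed = 9)[["cluDiss"]]
  }
  deltas <- seq(0, 45, length.out = 10)
  mean_diss <- vapply(deltas, function(d) {
    mean(vapply(1:6, function(r) sweep_pt(d, r), numeric(1)))
  }, numeric(1))
  expect_gt(cor(deltas, mean_diss, method = "spearman"), 0.8)
  expect_gt(mean_diss[10], mean_diss[1])

  # the generator's between-lesion dispersion dial shows the same trend
  levels_ <- seq(0, 1.8, length.out = 5)
  dial <- vapply(seq_along(levels_), function(i) {
    cfg <- sim_config(n_train = 5, n_test = 0, lesion_diameter = c(9, 12),
                      lesions_per_patient = c(3, 3),
                      lesion_dispersion = levels_[i])
    coh <- simulate_cohort(cfg, seed = 500)
    mean(vapply(coh$patients, function(p) {
      texture_heterogeneity(p, seed = 9)[["cluDiss"]]
    }, numeric(1)))
  }, numeric(1))
  expect_gt(dial[5], dial[1])
})
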