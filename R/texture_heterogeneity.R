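# CT-texture inter-tumor heterogeneity: per-lesion GLCM/Haralick features and
# voxel subregion clustering feed a pooled dissimilarity structure (cluster
# site entropy, cSE); lesion-level grey level distance zone matrices feed the
# cluster standard deviation (cluDev) and cluster dissimilarity (cluDiss).

# The 13 unique 3-D direction offsets at Chebyshev distance 1.
offsets13 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, ]
  # keep one of each +/- pair
  keep <- g[, 3] > 0 | (g[, 3] == 0 & (g[, 2] > 0 | (g[, 2] == 0 & g[, 1] > 0)))
  unname(g[keep, , drop = FALSE])
}

offsets26 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  unname(g[rowSums(abs(g)) > 0, , drop = FALSE])
}

#' Discretize a CT sub-volume to 8 gray levels
#'
#' Masked HU values are linearly rescaled to integers 0-255 over the mask's
#' \[min, max\] range, then binned with width 32, giving levels 1-8 (G = 8).
#' A constant lesion maps entirely to level 1 with a warning.
#'
#' @param ct 3-D HU array.
#' @param mask Binary array, same shape, non-empty.
#' @return A `gray_volume`: list with `levels` (integer array, 0 outside the
#'   mask), `mask`, and `G = 8`.
#' @export
discretize_ct <- function(ct, mask) {
  msk <- mask != 0
  stop_if_not(sum(msk) >= 1, "mask is empty")
  x <- ct[msk]
  lev <- array(0L, dim = dim(ct))
  if (max(x) - min(x) < 1e-12) {
    warning("constant lesion: all voxels assigned gray level 1")
    lev[msk] <- 1L
  } else {
    g <- floor((x - min(x)) / (max(x) - min(x)) * 256)
    g[g > 255] <- 255
    lev[msk] <- as.integer(g %/% 32 + 1)
  }
  structure(list(levels = lev, mask = msk, G = 8L), class = "gray_volume")
}

#' 3-D gray-level co-occurrence matrix
#'
#' Co-occurrences are counted for the 13 unique direction offsets at distance
#' one voxel, both voxels inside the mask, symmetrised, merged over offsets
#' and normalised to sum 1.
#'
#' @param gray A `gray_volume` from [discretize_ct()].
#' @return G x G normalised symmetric matrix (class `glc_matrix`).
#' @export
glcm <- function(gray) {
  G <- gray$G
  lev <- gray$levels
  counts <- matrix(0, G, G)
  for (i in seq_len(nrow(offsets13()))) {
    off <- offsets13()[i, ]
    sh <- shift_array(lev, off)
    ok <- lev > 0 & sh > 0
    if (!any(ok)) next
    idx <- lev[ok] + (sh[ok] - 1L) * G
    counts <- counts + matrix(tabulate(idx, nbins = G * G), G, G)
  }
  counts <- counts + t(counts)  # symmetric pairs, both directions
  total <- sum(counts)
  stop_if_not(total > 0, "no valid voxel pair in mask (lesion too small)")
  structure(counts / total, class = c("glc_matrix", "matrix"))
}

#' Haralick features of a normalised co-occurrence matrix
#'
#' energy = sum p^2; entropy = -sum p log2 p (in bits, 0 log 0 = 0);
#' contrast = sum (i - j)^2 p(i, j); homogeneity = sum p(i, j) / (1 + |i - j|).
#'
#' @param p Normalised G x G matrix (entries >= 0, summing to 1).
#' @return Named numeric vector: energy, entropy, contrast, homogeneity.
#' @export
haralick <- function(p) {
  p <- unclass(p)
  stop_if_not(abs(sum(p) - 1) < 1e-8 && all(p >= 0),
              "p must be a normalized co-occurrence matrix")
  G <- nrow(p)
  i <- row(p); j <- col(p)
  nz <- p > 0
  c(energy = sum(p^2),
    entropy = -sum(p[nz] * log2(p[nz])),
    contrast = sum((i - j)^2 * p),
    homogeneity = sum(p / (1 + abs(i - j))))
}

#' Partition a lesion into voxel subregions
#'
#' Each masked voxel is described by (gray level, 3x3x3 local mean, 3x3x3
#' local SD), neighbourhoods restricted to the mask; features are standardised
#' over the lesion and clustered by k-means (10 restarts, seeded). Lesions
#' with fewer distinct feature vectors than `k` collapse to fewer subregions.
#'
#' @param gray A `gray_volume`.
#' @param k Number of subregions (default 3).
#' @param seed Integer seed.
#' @return List with `labels` (per masked voxel, mask order), `signatures`
#'   (k x 3 centroid matrix in standardised feature space) and `k` (effective).
#' @export
subregion_cluster <- function(gray, k = 3, seed = 1) {
  stop_if_not(k >= 1, "k must be >= 1")
  msk <- gray$mask
  lev <- gray$levels
  m_num <- array(as.numeric(msk), dim = dim(msk))
  offs <- rbind(c(0L, 0L, 0L), offsets26())
  s1 <- neighbourhood_sum(lev * m_num, offs)
  s2 <- neighbourhood_sum((lev * m_num)^2, offs)
  cnt <- neighbourhood_sum(m_num, offs)
  lm <- s1[msk] / cnt[msk]
  lv <- pmax(s2[msk] / cnt[msk] - lm^2, 0)
  feats <- cbind(level = lev[msk], local_mean = lm, local_sd = sqrt(lv))
  feats <- apply(feats, 2, function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s < 1e-12) rep(0, length(x)) else (x - mean(x)) / s
  })
  n <- nrow(feats)
  if (k > n) {
    warning("fewer voxels than k; k reduced")
    k <- n
  }
  ndistinct <- nrow(unique(feats))
  k_eff <- min(k, ndistinct)
  if (k_eff < 2) {
    return(list(labels = rep(1L, n), signatures = matrix(colMeans(feats), 1, 3),
                k = 1L))
  }
  km <- with_seed(seed, stats::kmeans(feats, centers = k_eff, nstart = 10,
                                      iter.max = 50))
  list(labels = km$cluster, signatures = unname(km$centers), k = k_eff)
}

#' Pairwise Euclidean dissimilarity matrix of subregion signatures
#'
#' @param signatures Matrix (rows = signatures, pooled across all lesions of
#'   the patient) or list of equal-length vectors.
#' @return Symmetric matrix of Euclidean distances with zero diagonal.
#' @export
dissimilarity_matrix <- function(signatures) {
  if (is.list(signatures) && !is.matrix(signatures)) {
    lens <- vapply(signatures, length, numeric(1))
    stop_if_not(length(unique(lens)) == 1, "signature dimensions differ")
    signatures <- do.call(rbind, signatures)
  }
  stop_if_not(nrow(signatures) >= 2, "need at least 2 signatures")
  as.matrix(stats::dist(signatures, method = "euclidean"))
}

#' Cluster site entropy
#'
#' Upper-triangle pairwise dissimilarities are binned into `n_bins`
#' equal-width bins over \[0, max\]; cSE is the Shannon entropy (bits) of the
#' bin frequencies. All-zero dissimilarities give cSE = 0.
#'
#' @param d Symmetric dissimilarity matrix.
#' @param n_bins Number of bins (default 10).
#' @return cSE in bits (>= 0).
#' @export
cluster_site_entropy <- function(d, n_bins = 10) {
  u <- d[upper.tri(d)]
  stop_if_not(length(u) >= 1, "need at least one off-diagonal entry")
  mx <- max(u)
  if (mx < 1e-12) return(0)
  bin <- pmin(floor(u / mx * n_bins) + 1L, n_bins)
  p <- tabulate(bin, nbins = n_bins)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Chebyshev distance of each masked voxel to the mask border (border = 1),
# by iterative relaxation over the 26-neighbourhood.
border_distance <- function(msk) {
  m_num <- array(as.numeric(msk), dim = dim(msk))
  nb <- neighbourhood_sum(m_num, offsets26())
  d <- array(Inf, dim = dim(msk))
  d[msk & nb < 26] <- 1  # adjacent to outside or to the array edge
  if (!any(is.finite(d[msk]))) d[msk] <- 1  # single-voxel degenerate case
  repeat {
    dn <- d
    for (i in seq_len(nrow(offsets26()))) {
      sh <- shift_array(ifelse(is.finite(d), d, 1e18), offsets26()[i, ])
      sh[sh == 0] <- 1e18  # zero-filled outside planes are not neighbours
      dn <- pmin(dn, sh + 1)
    }
    dn[!msk] <- Inf
    if (all(dn[msk] == d[msk])) break
    d <- dn
  }
  d
}

# 26-connected component labelling of a binary array (padded BFS).
label_components <- function(msk) {
  d <- dim(msk)
  pd <- d + 2L
  pad <- array(FALSE, dim = pd)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- msk
  lin_off <- offsets26() %*% c(1, pd[1], pd[1] * pd[2])
  lab <- array(0L, dim = pd)
  todo <- which(pad)
  next_lab <- 0L
  for (v in todo) {
    if (lab[v] > 0L) next
    next_lab <- next_lab + 1L
    frontier <- v
    lab[v] <- next_lab
    while (length(frontier)) {
      cand <- as.vector(outer(drop(lin_off), frontier, `+`))
      cand <- unique(cand[pad[cand] & lab[cand] == 0L])
      lab[cand] <- next_lab
      frontier <- cand
    }
  }
  out <- lab[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  array(out, dim = d)
}

#' Grey level distance zone matrix
#'
#' Zones are 26-connected components of equal gray level inside the mask;
#' each zone is indexed by its gray level and the minimum Chebyshev voxel
#' distance of its voxels to the mask border (border voxels have distance 1).
#' Zone distances are aggregated into 4 relative bands (quartiles of the
#' lesion's maximum border distance) so the matrix is comparable across
#' lesion sizes, and counts are normalised by the total zone count.
#'
#' @param gray A `gray_volume`.
#' @return List with `z` (G x 4 normalised zone-count matrix), `n_zones`, and
#'   `zones` (data.frame of gray level, zone size, zone distance).
#' @export
gldzm <- function(gray) {
  msk <- gray$mask
  stop_if_not(sum(msk) >= 1, "mask is empty")
  dist <- border_distance(msk)
  dmax <- max(dist[msk])
  G <- gray$G
  z <- matrix(0, G, 4)
  zone_tab <- list()
  for (g in sort(unique(gray$levels[msk]))) {
    sub <- gray$levels == g & msk
    lab <- label_components(sub)
    for (l in seq_len(max(lab))) {
      vox <- lab == l
      zd <- min(dist[vox])
      band <- min(max(ceiling(4 * zd / dmax), 1L), 4L)
      z[g, band] <- z[g, band] + 1
      zone_tab[[length(zone_tab) + 1L]] <- c(g, sum(vox), zd)
    }
  }
  n_zones <- sum(z)
  zones <- as.data.frame(do.call(rbind, zone_tab))
  names(zones) <- c("gray_level", "size", "distance")
  list(z = z / n_zones, n_zones = n_zones, zones = zones)
}

#' Cluster standard deviation and cluster dissimilarity
#'
#' The patient's lesions are compared through the Euclidean distances between
#' their flattened normalised GLDZM vectors (G x 4 bands). cluDiss is the mean
#' of the upper-triangle distances; cluDev is their population standard
#' deviation (0 when there is a single pair).
#'
#' @param gldzm_vectors List (one per lesion) of normalised GLDZM matrices or
#'   flattened vectors.
#' @return Named numeric `c(cluDev =, cluDiss =)`.
#' @export
cluster_dev_diss <- function(gldzm_vectors) {
  stop_if_not(length(gldzm_vectors) >= 2, "need at least 2 lesions")
  vecs <- do.call(rbind, lapply(gldzm_vectors, as.vector))
  d <- as.matrix(stats::dist(vecs))
  u <- d[upper.tri(d)]
  c(cluDev = sqrt(mean((u - mean(u))^2)), cluDiss = mean(u))
}

#' CT-texture inter-tumor heterogeneity metrics for one patient
#'
#' For every retained lesion: discretize the CT sub-volume, compute the GLCM
#' and its Haralick features (logged as an attribute), partition the lesion
#' into voxel subregions, and build its GLDZM. cSE is the entropy of the
#' pooled pairwise subregion-signature dissimilarities; cluDev/cluDiss
#' summarise the inter-lesion GLDZM dissimilarity matrix.
#'
#' @param patient An `ith_patient` (>= 2 lesions passing [filter_vois()]).
#' @param k Subregions per lesion (default 3).
#' @param seed Integer seed.
#' @param n_bins Bins for [cluster_site_entropy()].
#' @return Named numeric `c(cSE =, cluDev =, cluDiss =)`, with attribute
#'   `haralick`: per-lesion data.frame of the four Haralick features.
#' @export
texture_heterogeneity <- function(patient, k = 3, seed = 1, n_bins = 10) {
  lesions <- filter_vois(patient$lesions)
  stop_if_not(length(lesions) >= 2,
              "texture heterogeneity needs >= 2 lesions passing the VOI filter")
  sigs <- list()
  gvecs <- list()
  har <- matrix(0, length(lesions), 4)
  for (i in seq_along(lesions)) {
    les <- lesions[[i]]
    gray <- withCallingHandlers(
      discretize_ct(les$ct$values, les$mask),
      warning = function(w) invokeRestart("muffleWarning"))
    har[i, ] <- haralick(glcm(gray))
    # one shared clustering substream: identical lesions yield identical
    # subregions and the metrics stay invariant under lesion reordering
    sub <- subregion_cluster(gray, k = k, seed = substream_seed(seed, 401))
    sigs[[i]] <- sub$signatures
    gvecs[[i]] <- gldzm(gray)$z
  }
  pooled <- do.call(rbind, sigs)
  cse <- if (nrow(pooled) < 2) 0 else {
    cluster_site_entropy(dissimilarity_matrix(pooled), n_bins = n_bins)
  }
  out <- c(cSE = cse, cluster_dev_diss(gvecs))
  colnames(har) <- c("energy", "entropy", "contrast", "homogeneity")
  attr(out, "haralick") <- data.frame(
    lesion_id = vapply(lesions, `[[`, character(1), "lesion_id"), har)
  out
}
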