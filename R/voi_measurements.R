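# Conventional per-lesion measurements and VOI inclusion rules.
#
# Each retained VOI yields eight measurements: Pixel_number, Maj, Min, HU,
# SUVmax, SUVmean, SUVpeak, TLG.

#' Names of the eight conventional measurements, in canonical order
#' @return Character vector of length 8.
#' @export
measurement_names <- function() {
  c("Pixel_number", "Maj", "Min", "HU", "SUVmax", "SUVmean", "SUVpeak", "TLG")
}

#' Apply the VOI inclusion rules
#'
#' Removes lesions whose axis-aligned mask bounding box is not greater than
#' 5 mm in every dimension, then keeps, within each region code, only the
#' lesion with the largest voxel count.
#'
#' @param lesions List of `lesion_voi` objects.
#' @return Filtered list; zero length signals that the patient carries no
#'   usable VOI (an exclusion).
#' @export
filter_vois <- function(lesions) {
  keep <- vapply(lesions, function(l) {
    all(mask_bbox_mm(l$mask, l$ct$spacing) > 5)
  }, logical(1))
  lesions <- lesions[keep]
  if (length(lesions) == 0) return(lesions)
  regions <- vapply(lesions, `[[`, character(1), "region")
  sizes <- vapply(lesions, function(l) sum(l$mask), numeric(1))
  sel <- unlist(lapply(split(seq_along(lesions), regions), function(idx) {
    idx[which.max(sizes[idx])]
  }))
  lesions[sort(sel)]
}

# Physical extent (mm) of the mask bounding box along each axis.
mask_bbox_mm <- function(mask, spacing) {
  w <- which(mask != 0, arr.ind = TRUE)
  if (nrow(w) == 0) return(c(0, 0, 0))
  (apply(w, 2, max) - apply(w, 2, min) + 1) * spacing
}

#' Voxel count of a mask
#' @param mask Binary 3-D array with at least one voxel set.
#' @return Integer count of nonzero voxels.
#' @export
pixel_number <- function(mask) {
  n <- sum(mask != 0)
  stop_if_not(n >= 1, "mask is empty")
  n
}

#' Major and minor axis lengths of a masked region
#'
#' Principal axes of the masked voxel point cloud in physical mm, by
#' eigen-decomposition of the coordinate covariance; axis length is
#' `4 * sqrt(eigenvalue)` (the image-moment convention). `maj` is the largest
#' and `min` the smallest of the three axes.
#'
#' @param mask Binary 3-D array.
#' @param spacing Voxel spacing (mm).
#' @return Named numeric `c(maj =, min =)` in mm; a single-voxel mask gives
#'   `c(0, 0)` with a warning.
#' @export
axis_lengths <- function(mask, spacing) {
  w <- which(mask != 0, arr.ind = TRUE)
  if (nrow(w) < 2) {
    warning("degenerate mask (< 2 voxels); axis lengths set to 0")
    return(c(maj = 0, min = 0))
  }
  xyz <- sweep(w, 2, spacing, `*`)
  ev <- eigen(stats::cov(xyz) * (nrow(xyz) - 1) / nrow(xyz),
              symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  c(maj = 4 * sqrt(max(ev)), min = 4 * sqrt(min(ev)))
}

#' Peak standardized uptake value
#'
#' Maximum over masked voxels of the mean SUV within a 1 cm^3 sphere
#' (radius about 6.2 mm) centred on the voxel, the sphere restricted to
#' masked voxels.
#'
#' @param suv 3-D SUV array.
#' @param mask Binary array, same shape.
#' @param spacing Voxel spacing (mm).
#' @return SUVpeak (scalar).
#' @export
suv_peak <- function(suv, mask, spacing) {
  stop_if_not(sum(mask != 0) >= 1, "mask is empty")
  radius <- (3 * 1000 / (4 * pi))^(1 / 3)  # 1 cm^3 sphere, in mm
  offs <- sphere_offsets(spacing, radius)
  m <- array(as.numeric(mask != 0), dim = dim(mask))
  s <- suv * m
  num <- neighbourhood_sum(s, offs)
  den <- neighbourhood_sum(m, offs)
  vals <- num[mask != 0] / den[mask != 0]
  max(vals)
}

#' Total lesion glycolysis
#'
#' SUVmean times the metabolic volume (voxel count times voxel volume in mL),
#' which equals the masked SUV sum times the voxel volume.
#'
#' @inheritParams suv_peak
#' @return TLG in SUV*mL.
#' @export
tlg <- function(suv, mask, spacing) {
  stop_if_not(sum(mask != 0) >= 1, "mask is empty")
  sum(suv[mask != 0]) * prod(spacing) / 1000
}

#' Compute the eight conventional measurements of a lesion
#'
#' @param lesion A `lesion_voi` (expected to have passed [filter_vois()]).
#' @return Named numeric vector with the entries of [measurement_names()].
#' @export
measure_lesion <- function(lesion) {
  m <- lesion$mask
  sp <- lesion$ct$spacing
  ax <- axis_lengths(m, sp)
  suv_vox <- lesion$suv$values[m]
  c(Pixel_number = pixel_number(m),
    Maj = unname(ax["maj"]), Min = unname(ax["min"]),
    HU = mean(lesion$ct$values[m]),
    SUVmax = max(suv_vox),
    SUVmean = mean(suv_vox),
    SUVpeak = suv_peak(lesion$suv$values, m, sp),
    TLG = tlg(lesion$suv$values, m, sp))
}

#' Per-lesion measurement table for one patient
#'
#' Applies [filter_vois()] and measures every retained lesion.
#'
#' @param patient An `ith_patient`.
#' @return data.frame: one row per retained lesion with `lesion_id`, `region`
#'   and the 8 measurement columns.
#' @export
measure_patient <- function(patient) {
  lesions <- filter_vois(patient$lesions)
  stop_if_not(length(lesions) >= 1, "no lesion passes the VOI size filter")
  rows <- t(vapply(lesions, measure_lesion, numeric(8)))
  data.frame(lesion_id = vapply(lesions, `[[`, character(1), "lesion_id"),
             region = vapply(lesions, `[[`, character(1), "region"),
             rows, check.names = FALSE)
}
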