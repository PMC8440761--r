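# Percentile segmentations: thresholding the probability map at a level
# mapped from a percentile of the segmentation-uncertainty distribution.
# The mapping t = 1 - P/100 makes larger percentiles include more voxels
# (thresholding at eps >= 0.20 keeps every voxel with at least 20%
# membership probability, i.e. P = 80), so the three standard
# segmentations at P = 15.9, 50.0, 84.1 are nested mu-sigma, mu, mu+sigma
# volumes with the mu+sigma volume the largest.

#' Standard segmentation percentiles
#'
#' The three percentiles used to specify the characteristic Normal
#' distribution: `mu - sigma`, `mu`, `mu + sigma` of a Normal correspond to
#' its 15.9, 50.0 and 84.1 percentiles (100*pnorm(c(-1, 0, 1)) rounded to
#' one decimal, the conventional printed values).
#'
#' @return named numeric vector `c(low = 15.9, mid = 50, high = 84.1)`.
#' @export
standard_percentiles <- function() c(low = 15.9, mid = 50.0, high = 84.1)

#' Map a percentile to a probability threshold
#'
#' `t = 1 - P/100`: the P-th percentile segmentation keeps voxels whose
#' membership probability is at least `1 - P/100`, so masks grow with P.
#'
#' @param P percentile, strictly inside (0, 100).
#' @return threshold in (0, 1).
#' @export
percentile_to_threshold <- function(P) {
  if (any(!is.finite(P)) || any(P <= 0) || any(P >= 100))
    stop("percentile must lie strictly inside (0, 100)", call. = FALSE)
  (100 - P) / 100   # algebraically 1 - P/100; this form is exact for round P
}

#' Threshold a probability map at a percentile
#'
#' Inclusive comparison: `mask_v = 1` iff `eps_{v,i} >= t`, so ties belong
#' to the segmentation ("at least" the threshold probability).
#'
#' @param map a [probability_map].
#' @param class_i segmented class (default foreground).
#' @param P percentile in (0, 100).
#' @return object of class `percentile_segmentation`: `mask` (logical 3D
#'   array), `percentile`, `threshold`, `class_i`, `spacing`, `provenance`.
#' @export
threshold_map <- function(map, class_i = NULL, P = 50) {
  stopifnot(inherits(map, "probability_map"))
  class_i <- class_i %||% map$foreground
  t <- percentile_to_threshold(P)
  eps <- class_map(map, class_i)
  structure(list(mask = eps >= t, percentile = P, threshold = t,
                 class_i = class_i, spacing = map$spacing,
                 provenance = sprintf("probability_map[N=%s]",
                                      map$n_samples)),
            class = "percentile_segmentation")
}

#' @export
print.percentile_segmentation <- function(x, ...) {
  cat(sprintf("<percentile_segmentation> P = %.4g (t = %.4g), class %s, volume fraction %.4f\n",
              x$percentile, x$threshold, x$class_i, mean(x$mask)))
  invisible(x)
}

#' The three standard segmentations
#'
#' Percentile segmentations at P = 15.9, 50.0 and 84.1, which specify the
#' characteristic Normal distribution of a downstream physics quantity
#' (mean from the 50.0 percentile, standard deviation from the outer two).
#' The masks are nested: `low` is contained in `mid` is contained in `high`.
#'
#' @param map a [probability_map].
#' @param class_i segmented class (default foreground).
#' @return object of class `standard_segmentation_set` with fields `low`,
#'   `mid`, `high` ([threshold_map] results).
#' @export
standard_segmentations <- function(map, class_i = NULL) {
  p <- standard_percentiles()
  segs <- lapply(p, function(P) threshold_map(map, class_i, P))
  if (any(segs$low$mask & !segs$mid$mask) || any(segs$mid$mask & !segs$high$mask))
    stop("internal consistency error: standard segmentations are not nested",
         call. = FALSE)
  structure(segs, class = "standard_segmentation_set")
}

#' @export
print.standard_segmentation_set <- function(x, ...) {
  cat("<standard_segmentation_set>\n")
  for (nm in c("low", "mid", "high"))
    cat(sprintf("  %-4s P = %4.1f, volume fraction %.4f\n", nm,
                x[[nm]]$percentile, mean(x[[nm]]$mask)))
  invisible(x)
}

save_mask <- function(seg, path, format = NULL) {
  stopifnot(inherits(seg, "percentile_segmentation"))
  m <- array(as.integer(seg$mask), dim(seg$mask))
  switch(infer_format(path, format),
         npy  = write_npy(path, m, "uint8"),
         nrrd = write_nrrd(path, m, "uint8", spacing = seg$spacing),
         tiff = write_tiff_volume(path, m, bits = 8L))
  invisible(path)
}
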