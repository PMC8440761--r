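#' Segmentation sample stack
#'
#' Bundle of N co-registered label volumes over a common voxel grid -- the
#' raw evidence of segmentation uncertainty. Each sample assigns every voxel
#' an integer class label; any generator of plausible segmentations
#' (Monte-Carlo neural-network sampling, threshold jitter, manual
#' annotators) can feed this container.
#'
#' @param samples list of 3D integer arrays, all with identical dimensions,
#'   indexed `[x, y, z]`.
#' @param classes integer vector of admissible labels; inferred as the
#'   sorted union of observed labels when `NULL`.
#' @param spacing physical voxel size per axis `(x, y, z)`; scalar recycled.
#' @return an object of class `seg_sample_stack` with fields `samples`,
#'   `classes`, `spacing`.
#' @export
seg_sample_stack <- function(samples, classes = NULL, spacing = c(1, 1, 1)) {
  if (!is.list(samples) || length(samples) < 1)
    stop("need at least one segmentation sample", call. = FALSE)
  d1 <- dim(check_volume3d(samples[[1]], "sample 1"))
  for (k in seq_along(samples)) {
    dk <- dim(check_volume3d(samples[[k]], paste("sample", k)))
    if (!identical(dk, d1))
      stop(sprintf("sample %d has dimensions %s, expected %s", k,
                   paste(dk, collapse = "x"), paste(d1, collapse = "x")),
           call. = FALSE)
    if (!is_wholenumber(samples[[k]]))
      stop(sprintf("sample %d contains non-integer voxel values", k),
           call. = FALSE)
  }
  observed <- sort(unique(as.numeric(
    unlist(lapply(samples, function(s) unique(as.vector(s)))))))
  if (is.null(classes)) {
    classes <- observed
  } else {
    classes <- sort(unique(as.numeric(classes)))
    bad <- setdiff(observed, classes)
    if (length(bad))
      stop(sprintf("voxel label(s) %s outside declared class set {%s}",
                   paste(bad, collapse = ", "), paste(classes, collapse = ", ")),
           call. = FALSE)
  }
  structure(list(samples = samples, classes = classes,
                 spacing = check_spacing(spacing)),
            class = "seg_sample_stack")
}

#' @export
print.seg_sample_stack <- function(x, ...) {
  d <- dim(x$samples[[1]])
  cat(sprintf("<seg_sample_stack> N = %d samples, grid %dx%dx%d (x,y,z), classes {%s}\n",
              length(x$samples), d[1], d[2], d[3],
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Voxel-wise probability map
#'
#' The central object of the workflow: for each class i the per-voxel
#' probability eps_{v,i} that voxel v belongs to class i, estimated as the
#' mean over N segmentation samples. For a binary problem a single map for
#' the foreground class suffices; the complement class is implied as
#' `1 - eps`.
#'
#' @param eps either a single 3D array in `[0, 1]` (binary problem,
#'   foreground map) or a named list of such arrays, one per class, whose
#'   per-voxel values sum to 1.
#' @param classes class labels. For a single-array `eps` the default is
#'   `c(0, 1)` with the supplied map describing class 1 (the foreground).
#' @param n_samples number of samples the map was built from (`NA` if
#'   unknown, e.g. a map produced by an external model).
#' @param spacing physical voxel size per axis.
#' @return object of class `probability_map` with fields `eps` (named list
#'   of arrays), `classes`, `binary`, `foreground`, `n_samples`, `spacing`.
#' @export
probability_map <- function(eps, classes = NULL, n_samples = NA_integer_,
                            spacing = c(1, 1, 1)) {
  if (is.array(eps) && !is.list(eps)) {
    classes <- if (is.null(classes)) c(0, 1) else sort(as.numeric(classes))
    if (length(classes) != 2)
      stop("a single-array probability map implies exactly 2 classes", call. = FALSE)
    check_volume3d(eps, "probability map")
    check_unit_interval(eps)
    fg <- classes[2]
    maps <- stats::setNames(list(eps), as.character(fg))
    binary <- TRUE
  } else if (is.list(eps)) {
    if (is.null(names(eps)))
      stop("multi-class eps must be a named list (names = class labels)", call. = FALSE)
    classes <- sort(as.numeric(names(eps)))
    if (length(classes) < 2) stop("need at least 2 classes", call. = FALSE)
    d1 <- dim(check_volume3d(eps[[1]], "class map 1"))
    tot <- 0
    for (nm in names(eps)) {
      check_volume3d(eps[[nm]], paste("class map", nm))
      if (!identical(dim(eps[[nm]]), d1))
        stop("class maps have mismatched dimensions", call. = FALSE)
      check_unit_interval(eps[[nm]])
      tot <- tot + eps[[nm]]
    }
    if (max(abs(tot - 1)) > 1e-6)
      stop("per-voxel class probabilities do not sum to 1 (max deviation ",
           format(max(abs(tot - 1))), ")", call. = FALSE)
    maps <- eps[order(as.numeric(names(eps)))]
    fg <- classes[length(classes)]
    binary <- FALSE
  } else stop("eps must be a 3D array or a named list of 3D arrays", call. = FALSE)
  structure(list(eps = maps, classes = classes, binary = binary,
                 foreground = fg, n_samples = n_samples,
                 spacing = check_spacing(spacing)),
            class = "probability_map")
}

check_unit_interval <- function(x, tol = 0) {
  if (min(x) < -tol || max(x) > 1 + tol)
    stop(sprintf("probability values outside [0, 1]: %d offending voxels, range [%g, %g]",
                 sum(x < -tol | x > 1 + tol), min(x), max(x)), call. = FALSE)
  invisible(x)
}

#' @export
print.probability_map <- function(x, ...) {
  d <- dim(x$eps[[1]])
  cat(sprintf("<probability_map> grid %dx%dx%d (x,y,z), classes {%s}%s, N = %s\n",
              d[1], d[2], d[3], paste(x$classes, collapse = ", "),
              if (x$binary) sprintf(", binary (map stored for class %s)", x$foreground) else "",
              if (is.na(x$n_samples)) "?" else x$n_samples))
  invisible(x)
}

#' Per-class map lookup
#'
#' Returns the probability volume for one class; for a binary map the
#' complement class is reconstructed as `1 - eps`.
#'
#' @param map a [probability_map] object.
#' @param class_i class label; default the foreground class.
#' @return 3D array of probabilities.
#' @export
class_map <- function(map, class_i = NULL) {
  stopifnot(inherits(map, "probability_map"))
  class_i <- class_i %||% map$foreground
  if (!class_i %in% map$classes)
    stop(sprintf("unknown class %s (classes: %s)", class_i,
                 paste(map$classes, collapse = ", ")), call. = FALSE)
  key <- as.character(class_i)
  if (!is.null(map$eps[[key]])) return(map$eps[[key]])
  # binary map: only the foreground is stored
  1 - map$eps[[as.character(map$foreground)]]
}

#' Build a probability map from segmentation samples
#'
#' Per-voxel, per-class inclusion frequency over the sample ensemble:
#' `eps_{v,i} = (1/N) * sum_k [label_k(v) == i]`. Accumulation is in double
#' precision. For a binary class set only the foreground (larger-label)
#' map is materialised.
#'
#' @param stack a [seg_sample_stack].
#' @return a [probability_map] on the stack's grid with its class set.
#' @export
compute_probability_map <- function(stack) {
  stopifnot(inherits(stack, "seg_sample_stack"))
  N <- length(stack$samples)
  d <- dim(stack$samples[[1]])
  if (length(stack$classes) == 2) {
    fg <- stack$classes[2]
    acc <- array(0, d)
    for (s in stack$samples) acc <- acc + (s == fg)
    return(probability_map(acc / N, classes = stack$classes,
                           n_samples = N, spacing = stack$spacing))
  }
  maps <- lapply(stack$classes, function(ci) {
    acc <- array(0, d)
    for (s in stack$samples) acc <- acc + (s == ci)
    acc / N
  })
  names(maps) <- as.character(stack$classes)
  probability_map(maps, n_samples = N, spacing = stack$spacing)
}
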