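# Normalized Shannon-entropy uncertainty maps. A voxel whose class
# probabilities are uniform is maximally uncertain (H = 1 after dividing by
# log2(n_c)); a one-hot voxel is certain (H = 0). The 0*log2(0) terms are
# set to 0 by explicit masking so one-hot voxels are exactly zero.

xlog2x <- function(p) {
  out <- numeric(length(p))
  pos <- p > 0
  out[pos] <- p[pos] * log2(p[pos])
  dim(out) <- dim(p)
  out
}

#' Total Shannon-entropy uncertainty map
#'
#' Voxel-wise `H(eps_v) = -sum_i eps_{v,i} log2(eps_{v,i}) / log2(n_c)`,
#' normalized to `[0, 1]` by the number of classes. For a binary map the
#' complement class `1 - eps` is implied.
#'
#' @param map a [probability_map].
#' @param tol tolerance on per-voxel probability row sums.
#' @return object of class `uncertainty_map`: fields `H` (3D array in
#'   `[0,1]`), `kind`, `n_classes`, `spacing`.
#' @export
entropy_map <- function(map, tol = 1e-6) {
  stopifnot(inherits(map, "probability_map"))
  nc <- length(map$classes)
  if (nc < 2) stop("entropy normalizer log2(n_c) undefined for n_c < 2", call. = FALSE)
  if (map$binary) {
    e <- map$eps[[1]]
    H <- -(xlog2x(e) + xlog2x(1 - e))  # log2(2) = 1
  } else {
    tot <- Reduce(`+`, map$eps)
    if (max(abs(tot - 1)) > tol)
      stop("per-voxel probabilities do not sum to 1 (max deviation ",
           format(max(abs(tot - 1))), ")", call. = FALSE)
    H <- -Reduce(`+`, lapply(map$eps, xlog2x)) / log2(nc)
  }
  structure(list(H = pmin(pmax(H, 0), 1), kind = "total", n_classes = nc,
                 spacing = map$spacing),
            class = "uncertainty_map")
}

#' Per-class Shannon-entropy uncertainty map
#'
#' Voxel-wise `H(eps_{v,i}) = -eps_{v,i} log2(eps_{v,i}) / log2(n_c)`: the
#' contribution of one class to the total uncertainty, so per-class maps sum
#' to the total map over the full class set.
#'
#' @param map a [probability_map].
#' @param class_i the class to assess.
#' @return an `uncertainty_map` with `kind = "per_class"`.
#' @export
per_class_entropy_map <- function(map, class_i) {
  stopifnot(inherits(map, "probability_map"))
  nc <- length(map$classes)
  if (nc < 2) stop("entropy normalizer log2(n_c) undefined for n_c < 2", call. = FALSE)
  e <- class_map(map, class_i)
  H <- -xlog2x(e) / log2(nc)
  structure(list(H = H, kind = "per_class", class_i = class_i, n_classes = nc,
                 spacing = map$spacing),
            class = "uncertainty_map")
}

#' @export
print.uncertainty_map <- function(x, ...) {
  d <- dim(x$H)
  cat(sprintf("<uncertainty_map> %s%s, grid %dx%dx%d, mean H = %.4f, frac(H > 0.5) = %.4f\n",
              x$kind, if (x$kind == "per_class") paste0("(", x$class_i, ")") else "",
              d[1], d[2], d[3], mean(x$H), mean(x$H > 0.5)))
  invisible(x)
}

entropy_summary <- function(umap) {
  list(kind = umap$kind, n_classes = umap$n_classes,
       mean_entropy = mean(umap$H),
       fraction_above_0.5 = mean(umap$H > 0.5))
}
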