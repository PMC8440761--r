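# Synthetic scenes with analytically known probability maps. Each scene
# bundles a binary ground truth, a grayscale rendering, and (where
# available) a closed-form probability map, so the whole workflow --
# probability map, entropy, percentile segmentation, physics sweep,
# distribution fit -- can be verified end to end without external data.
#
# Under the threshold-jitter sampler the TRUE per-voxel inclusion
# probability equals the grayscale value g_v (a uniform threshold tau has
# P(tau <= g_v) = g_v), so the ensemble-mean probability map has a known
# target at every voxel.

synthetic_scene <- function(truth, grayscale, analytic_probmap, recipe,
                            spacing = c(1, 1, 1)) {
  structure(list(truth = truth, grayscale = grayscale,
                 analytic_probmap = analytic_probmap, recipe = recipe,
                 spacing = check_spacing(spacing)),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  d <- dim(x$truth)
  cat(sprintf("<synthetic_scene> %s, grid %dx%dx%d, truth volume fraction %.4f\n",
              x$recipe$generator, d[1], d[2], d[3], mean(x$truth)))
  invisible(x)
}

# run code under a scene-local RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

#' Planar two-phase interface with a blurred boundary
#'
#' Grayscale `g(x) = pnorm((x - x0) / w)` along the x axis: a standard
#' normal CDF profile, the canonical model of an interface blurred to width
#' `w`. The ground truth is the sharp step `x >= x0`. Under the
#' threshold-jitter sampler the analytic probability map equals `g`, so the
#' standard percentile segmentations sit at analytically known offsets
#' `x0 + w * qnorm(t)` from the interface.
#'
#' @param shape grid dimensions `(nx, ny, nz)`.
#' @param x0 interface position along x, in voxel units (0 < x0 < nx).
#' @param w blur width in voxels, > 0.
#' @param spacing per-axis voxel size.
#' @return a `synthetic_scene`.
#' @export
make_planar_interface <- function(shape, x0, w, spacing = c(1, 1, 1)) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 1))
    stop("shape must be 3 positive integers", call. = FALSE)
  if (!is.finite(w) || w <= 0) stop("blur width w must be > 0", call. = FALSE)
  if (x0 <= 0 || x0 >= shape[1])
    stop("interface position x0 must lie inside (0, nx)", call. = FALSE)
  x <- (seq_len(shape[1]) - 0.5)           # voxel centers
  gx <- pnorm((x - x0) / w)
  g <- array(rep(gx, times = shape[2] * shape[3]), shape)
  truth <- array(rep(x >= x0, times = shape[2] * shape[3]), shape)
  synthetic_scene(truth, g, g,
                  recipe = list(generator = "planar_interface", shape = shape,
                                x0 = x0, w = w),
                  spacing = spacing)
}

# separable periodic Gaussian smoothing via FFT
gaussian_smooth_3d <- function(vol, sigma) {
  d <- dim(vol)
  if (length(sigma) == 1) sigma <- rep(sigma, 3)
  kern1 <- function(n, s) {
    if (s <= 0) return(c(1, rep(0, n - 1)))
    x <- seq_len(n) - 1
    x <- pmin(x, n - x)                     # circular distance
    k <- exp(-x^2 / (2 * s^2))
    k / sum(k)
  }
  K <- outer(outer(kern1(d[1], sigma[1]), kern1(d[2], sigma[2])),
             kern1(d[3], sigma[3]))
  dim(K) <- d
  out <- Re(fft(fft(vol) * fft(K), inverse = TRUE)) / prod(d)
  dim(out) <- d
  out
}

#' Random blob microstructure from a thresholded Gaussian field
#'
#' White noise smoothed to correlation length `ell` and thresholded at its
#' empirical `(1 - phi)` quantile, giving a two-phase particle/pore
#' microstructure with volume fraction `phi`. The grayscale rendering is
#' the truth re-blurred (width 1 voxel) plus additive Gaussian noise of
#' amplitude `noise_amp` -- the knob emulating image quality: larger noise
#' stands for a blurrier, lower-contrast acquisition and widens every
#' downstream uncertainty.
#'
#' @param shape grid dimensions `(nx, ny, nz)`.
#' @param phi target volume fraction of the thresholded phase, in (0, 1).
#' @param ell correlation length in voxels, >= 1.
#' @param seed integer seed; the recipe fully determines the scene.
#' @param noise_amp grayscale noise amplitude (standard deviation).
#' @param blur_width grayscale blur width in voxels.
#' @param spacing per-axis voxel size.
#' @return a `synthetic_scene` (the analytic map is the clamped grayscale:
#'   exact for the threshold-jitter sampler).
#' @export
make_blob_microstructure <- function(shape, phi, ell, seed = 1,
                                     noise_amp = 0.05, blur_width = 1,
                                     spacing = c(1, 1, 1)) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 2))
    stop("shape must be 3 integers >= 2", call. = FALSE)
  if (phi <= 0 || phi >= 1) stop("phi must lie inside (0, 1)", call. = FALSE)
  if (ell < 1) stop("correlation length ell must be >= 1 voxel", call. = FALSE)
  with_seed(seed, {
    field <- array(rnorm(prod(shape)), shape)
    field <- gaussian_smooth_3d(field, ell)
    thr <- quantile(field, 1 - phi, names = FALSE)
    truth <- field >= thr
    achieved <- mean(truth)
    if (abs(achieved - phi) > 0.01)
      warning(sprintf("achieved volume fraction %.4f differs from target %.4f (tiny grid?)",
                      achieved, phi))
    g <- gaussian_smooth_3d(array(as.numeric(truth), shape), blur_width)
    g <- g + noise_amp * array(rnorm(prod(shape)), shape)
    g <- pmin(pmax(g, 0), 1)
    synthetic_scene(truth, g, g,
                    recipe = list(generator = "blob_microstructure",
                                  shape = shape, phi = phi, ell = ell,
                                  seed = seed, noise_amp = noise_amp,
                                  blur_width = blur_width),
                    spacing = spacing)
  })
}

#' Sample a segmentation ensemble from a synthetic scene
#'
#' Two samplers with closed-form per-voxel inclusion probabilities:
#' \describe{
#'   \item{threshold_jitter}{sample k binarizes the grayscale at a
#'     threshold `tau_k ~ U(0, 1)`; inclusion probability = grayscale
#'     value, so the ensemble probability map converges to the grayscale.}
#'   \item{noise_then_threshold}{sample k adds fresh Gaussian noise of
#'     amplitude `noise_amp` and thresholds at 0.5; inclusion probability =
#'     `pnorm((g - 0.5) / noise_amp)`.}
#' }
#'
#' @param scene a `synthetic_scene`.
#' @param N ensemble size, >= 1.
#' @param sampler `"threshold_jitter"` or `"noise_then_threshold"`.
#' @param seed integer seed.
#' @param noise_amp noise amplitude for `noise_then_threshold`.
#' @return a [seg_sample_stack] with classes `{0, 1}`.
#' @export
sample_segmentations <- function(scene, N,
                                 sampler = c("threshold_jitter",
                                             "noise_then_threshold"),
                                 seed = 1, noise_amp = 0.1) {
  stopifnot(inherits(scene, "synthetic_scene"))
  sampler <- match.arg(sampler)
  if (N < 1) stop("N must be >= 1", call. = FALSE)
  g <- scene$grayscale
  d <- dim(g)
  with_seed(seed, {
    samples <- vector("list", N)
    if (sampler == "threshold_jitter") {
      tau <- runif(N)
      for (k in seq_len(N))
        samples[[k]] <- array(as.integer(g >= tau[k]), d)
    } else {
      for (k in seq_len(N)) {
        noisy <- g + noise_amp * array(rnorm(prod(d)), d)
        samples[[k]] <- array(as.integer(noisy >= 0.5), d)
      }
    }
    seg_sample_stack(samples, classes = c(0, 1), spacing = scene$spacing)
  })
}

#' Analytic inclusion probability of a sampler
#'
#' The closed-form per-voxel probability map that [compute_probability_map]
#' converges to for the given scene and sampler.
#'
#' @inheritParams sample_segmentations
#' @return 3D array of probabilities.
#' @export
analytic_inclusion_probability <- function(scene,
                                           sampler = c("threshold_jitter",
                                                       "noise_then_threshold"),
                                           noise_amp = 0.1) {
  sampler <- match.arg(sampler)
  g <- scene$grayscale
  if (sampler == "threshold_jitter") pmin(pmax(g, 0), 1)
  else pnorm((g - 0.5) / noise_amp)
}

#' Exact percentile/quantity tables from known families
#'
#' `Q(P) = quantile_family(P / 100)`: fixtures whose characteristic fits
#' are known in closed form (a Normal table must be recovered exactly; a
#' beta table fitted as Normal must fail in the tails).
#'
#' @param family `"normal"`, `"beta"` or `"half_cauchy"`.
#' @param params named list of family parameters (`mean`/`sd`;
#'   `shape1`/`shape2` plus optional `lower`/`upper`; `location`/`scale`).
#' @param percentiles percentiles in (0, 100).
#' @return a [quantity_table].
#' @export
make_quantity_table <- function(family = c("normal", "beta", "half_cauchy"),
                                params, percentiles) {
  family <- match.arg(family)
  p <- percentiles / 100
  if (!length(percentiles))
    return(quantity_table(numeric(0), numeric(0), quantity = family))
  Q <- switch(family,
    normal = qnorm(p, params$mean, params$sd),
    beta = {
      lo <- params$lower %||% 0; up <- params$upper %||% 1
      lo + (up - lo) * qbeta(p, params$shape1, params$shape2)
    },
    half_cauchy = params$location + params$scale * tan(pi * p / 2))
  quantity_table(percentiles, Q, quantity = family)
}
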