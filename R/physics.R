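# Voxel-grid physics on percentile segmentations. Effective transport
# (electrical or thermal conduction) is computed by a cell-centered
# finite-volume discretization of Laplace's equation on the structured
# voxel grid: face conductances are harmonic means of the adjacent cell
# conductivities along the face normal (exact for series slabs and the
# standard treatment for discontinuous coefficients), a unit potential
# difference is imposed with Dirichlet conditions on the two boundary faces
# normal to the transport axis (applied at half-cell ghost distance, which
# makes the homogeneous medium exact), and the four remaining boundaries
# are zero-flux. The effective property is the area-averaged boundary flux
# divided by the imposed gradient. The non-transporting phase keeps a small
# conductivity (default 1e-6) rather than being carved out of the domain,
# which keeps the grid structured.

#' Two-phase conductivity field on a voxel grid
#'
#' @param mask logical/0-1 3D array marking the segmented phase.
#' @param k_in conductivity of `mask = 1` voxels; scalar (isotropic) or a
#'   length-3 axis-diagonal triple `(kx, ky, kz)`.
#' @param k_out conductivity of `mask = 0` voxels, same forms.
#' @param spacing per-axis voxel size.
#' @return object of class `conductivity_field`.
#' @export
conductivity_field <- function(mask, k_in = 1, k_out = 1e-6,
                               spacing = c(1, 1, 1)) {
  if (inherits(mask, "percentile_segmentation")) {
    spacing <- mask$spacing
    mask <- mask$mask
  }
  check_volume3d(mask, "mask")
  expand_k <- function(k, what) {
    k <- as.numeric(k)
    if (length(k) == 1) k <- rep(k, 3)
    if (length(k) != 3 || any(!is.finite(k)) || any(k <= 0))
      stop(what, " must be a positive scalar or length-3 triple", call. = FALSE)
    k
  }
  structure(list(mask = mask != 0, k_in = expand_k(k_in, "k_in"),
                 k_out = expand_k(k_out, "k_out"),
                 spacing = check_spacing(spacing)),
            class = "conductivity_field")
}

#' Volume fraction of a segmentation
#'
#' Fraction of voxels inside the segmented phase -- the physics quantity
#' that comes directly from segmentation with no solve.
#'
#' @param seg a `percentile_segmentation` or a logical/0-1 3D array.
#' @return object of class `physics_result` with `quantity =
#'   "volume_fraction"`.
#' @export
volume_fraction <- function(seg) {
  P <- NA_real_
  if (inherits(seg, "percentile_segmentation")) {
    P <- seg$percentile
    mask <- seg$mask
  } else mask <- check_volume3d(seg, "mask") != 0
  physics_result("volume_fraction", mean(mask), axis = NA_character_,
                 percentile = P)
}

physics_result <- function(quantity, value, axis, percentile = NA_real_,
                           solver_stats = list(iterations = 0L, residual = 0)) {
  structure(list(quantity = quantity, value = value, axis = axis,
                 percentile = percentile, solver_stats = solver_stats),
            class = "physics_result")
}

#' @export
print.physics_result <- function(x, ...) {
  cat(sprintf("<physics_result> %s = %.6g%s%s (%d CG iterations, residual %.2e)\n",
              x$quantity, x$value,
              if (!is.na(x$axis)) paste0(", axis ", x$axis) else "",
              if (!is.na(x$percentile)) sprintf(", P = %.4g", x$percentile) else "",
              x$solver_stats$iterations, x$solver_stats$residual))
  invisible(x)
}

# per-cell conductivity along one axis
cell_k <- function(field, a) {
  k <- array(field$k_out[a], dim(field$mask))
  k[field$mask] <- field$k_in[a]
  k
}

#' Effective transport property of a voxel conductivity field
#'
#' Solves the steady diffusion (Laplace) problem along `axis` with a unit
#' potential difference and returns boundary flux / imposed gradient,
#' normalized by the cross-sectional area so a homogeneous medium returns
#' its own conductivity exactly. The sparse SPD system is solved by
#' conjugate gradients with Jacobi (diagonal) preconditioning.
#'
#' @param field a [conductivity_field] (or a mask, converted with default
#'   unit / 1e-6 phase conductivities).
#' @param axis transport axis `"x"`, `"y"` or `"z"`.
#' @param rtol relative residual tolerance of the CG solve.
#' @param maxit iteration cap (default `50 * max(dim)` per the solver
#'   design; raise for extreme contrasts).
#' @param flux_rtol flux-conservation target: after the residual test the
#'   solve is polished at tighter tolerance until inflow and outflow agree
#'   to this relative imbalance (or the double-precision floor is hit).
#' @return `physics_result` with `quantity = "effective_conductivity"`;
#'   `solver_stats` carries iterations, final relative residual, the
#'   inflow/outflow imbalance and the Wiener (harmonic/arithmetic mean)
#'   bounds of the field.
#' @export
solve_effective_transport <- function(field, axis = "x", rtol = 1e-12,
                                      maxit = NULL, flux_rtol = 1e-8) {
  if (!inherits(field, "conductivity_field")) field <- conductivity_field(field)
  a <- axis_index(axis)
  d <- dim(field$mask); h <- field$spacing
  if (d[a] < 2) stop("need at least 2 voxels along the transport axis", call. = FALSE)
  n <- prod(d)
  maxit <- maxit %||% max(50L * max(d), 2000L)

  idx <- array(seq_len(n), d)
  ii <- list(); jj <- list(); gg <- list()
  diag_acc <- numeric(n)
  for (ax in 1:3) {
    if (d[ax] < 2) next
    k <- cell_k(field, ax)
    A_face <- prod(h[-ax])
    take <- function(arr, drop_last) {
      ind <- lapply(d, seq_len)
      ind[[ax]] <- if (drop_last) seq_len(d[ax] - 1) else 2:d[ax]
      do.call(`[`, c(list(arr), ind, list(drop = FALSE)))
    }
    kp <- take(k, TRUE); kq <- take(k, FALSE)
    g <- as.vector(A_face * (2 * kp * kq / (kp + kq)) / h[ax])
    p <- as.vector(take(idx, TRUE)); q <- as.vector(take(idx, FALSE))
    ii[[length(ii) + 1]] <- p; jj[[length(jj) + 1]] <- q
    gg[[length(gg) + 1]] <- g
    acc <- numeric(n)
    acc[p] <- acc[p] + g
    acc[q] <- acc[q] + g
    diag_acc <- diag_acc + acc
  }

  # Dirichlet faces at half-cell ghost distance along the transport axis
  bnd <- function(side) {
    ind <- lapply(d, seq_len)
    ind[[a]] <- if (side == "lo") 1L else d[a]
    as.vector(do.call(`[`, c(list(idx), ind, list(drop = FALSE))))
  }
  ka <- cell_k(field, a)
  A_face <- prod(h[-a])
  lo <- bnd("lo"); hi <- bnd("hi")
  g_lo <- 2 * A_face * ka[lo] / h[a]
  g_hi <- 2 * A_face * ka[hi] / h[a]
  diag_acc[lo] <- diag_acc[lo] + g_lo
  diag_acc[hi] <- diag_acc[hi] + g_hi
  b <- numeric(n)
  b[lo] <- b[lo] + g_lo * 1       # phi = 1 on the low face, 0 on the high

  iL <- unlist(ii); jL <- unlist(jj); gL <- unlist(gg)
  A <- sparseMatrix(i = c(iL, jL, seq_len(n)), j = c(jL, iL, seq_len(n)),
                    x = c(-gL, -gL, diag_acc), dims = c(n, n))

  sol <- pcg_solve(A, b, diag_acc, rtol = rtol, maxit = maxit)
  iterations <- sol$iterations
  fluxes <- function(phi) c(sum(g_lo * (1 - phi[lo])), sum(g_hi * phi[hi]))
  imb <- function(q) abs(q[1] - q[2]) / max(abs(q[1]), .Machine$double.xmin)
  qq <- fluxes(sol$x)
  rt <- rtol
  while (imb(qq) > flux_rtol && rt > 4e-16) {
    rt <- max(rt * 1e-2, 4e-16)
    sol <- pcg_solve(A, b, diag_acc, rtol = rt, maxit = maxit, x0 = sol$x,
                     best_effort = TRUE)
    iterations <- iterations + sol$iterations
    qq <- fluxes(sol$x)
    if (!sol$converged) break  # double-precision floor reached
  }
  phi <- sol$x
  sol$iterations <- iterations

  Q_in <- qq[1]
  Q_out <- qq[2]
  L <- d[a] * h[a]
  A_total <- prod(d[-a]) * A_face
  gradient <- 1 / L
  k_eff <- ((Q_in + Q_out) / 2) / A_total / gradient

  kvals <- as.vector(ka)
  stats <- list(iterations = sol$iterations, residual = sol$residual,
                flux_in = Q_in, flux_out = Q_out,
                flux_imbalance = abs(Q_in - Q_out) / max(abs(Q_in), .Machine$double.xmin),
                wiener_lower = 1 / mean(1 / kvals),
                wiener_upper = mean(kvals))
  physics_result("effective_conductivity", k_eff, axis = c("x", "y", "z")[a],
                 solver_stats = stats)
}

# Jacobi-preconditioned conjugate gradients for the SPD voxel system
pcg_solve <- function(A, b, diag_A, rtol = 1e-12, maxit = 1000L, x0 = NULL,
                      best_effort = FALSE) {
  n <- length(b)
  x <- x0 %||% numeric(n)
  r <- b - if (is.null(x0)) numeric(n) else as.vector(A %*% x)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(list(x = x, iterations = 0L, residual = 0,
                              converged = TRUE))
  res0 <- sqrt(sum(r^2)) / bnorm
  if (res0 <= rtol)
    return(list(x = x, iterations = 0L, residual = res0, converged = TRUE))
  Minv <- 1 / diag_A
  z <- Minv * r
  p <- z
  rz <- sum(r * z)
  hist <- numeric(0)
  for (it in seq_len(maxit)) {
    Ap <- as.vector(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    res <- sqrt(sum(r^2)) / bnorm
    hist[it] <- res
    if (res <= rtol)
      return(list(x = x, iterations = it, residual = res, converged = TRUE))
    # stagnation at the rounding floor: no progress over the last 30 steps
    if (best_effort && it > 30 && hist[it] >= 0.999 * hist[it - 30])
      return(list(x = x, iterations = it, residual = res, converged = FALSE))
    z <- Minv * r
    rz_new <- sum(r * z)
    beta <- rz_new / rz
    rz <- rz_new
    p <- z + beta * p
  }
  if (best_effort)
    return(list(x = x, iterations = maxit, residual = hist[maxit],
                converged = FALSE))
  cond <- structure(class = c("voxuq_convergence_error", "error", "condition"),
                    list(message = sprintf(
                      "CG did not reach rtol %g in %d iterations (final residual %g)",
                      rtol, maxit, hist[length(hist)]),
                      call = sys.call(-1), residual_history = hist))
  stop(cond)
}

#' Tortuosity of the transporting phase
#'
#' Porosity divided by the effective transport property of the pore network,
#' computed with unit conductivity in the pores and `k_solid` (default
#' 1e-6) in the blocking phase. An open domain gives tortuosity ~1; values
#' grow as transport paths wind.
#'
#' @param seg a `percentile_segmentation` or logical/0-1 3D array; voxels
#'   with `mask = 1` are treated as the transporting (pore) phase. If the
#'   segmentation marks the solid instead, pass `pore = "complement"`.
#' @param axis transport axis.
#' @param pore `"mask"` (default) or `"complement"`.
#' @param k_solid residual conductivity of the blocking phase.
#' @param spacing voxel spacing when `seg` is a bare array.
#' @param rtol,maxit CG controls, as in [solve_effective_transport].
#' @return `physics_result` with `quantity = "tortuosity"`; `solver_stats`
#'   additionally carries `porosity` and `k_eff`.
#' @export
tortuosity <- function(seg, axis = "x", pore = c("mask", "complement"),
                       k_solid = 1e-6, spacing = c(1, 1, 1),
                       rtol = 1e-12, maxit = NULL) {
  pore <- match.arg(pore)
  P <- NA_real_
  if (inherits(seg, "percentile_segmentation")) {
    P <- seg$percentile; spacing <- seg$spacing; mask <- seg$mask
  } else mask <- check_volume3d(seg, "mask") != 0
  pores <- if (pore == "mask") mask else !mask
  porosity <- mean(pores)
  if (porosity == 0)
    stop("tortuosity undefined: porosity is zero", call. = FALSE)
  field <- conductivity_field(pores, k_in = 1, k_out = k_solid,
                              spacing = spacing)
  tr <- solve_effective_transport(field, axis, rtol = rtol, maxit = maxit)
  stats <- tr$solver_stats
  stats$porosity <- porosity
  stats$k_eff <- tr$value
  physics_result("tortuosity", porosity / tr$value, axis = tr$axis,
                 percentile = P, solver_stats = stats)
}

#' Sweep physics quantities over percentile segmentations
#'
#' Thresholds the probability map at each percentile and evaluates each
#' requested quantity, producing the (percentile, value) table consumed by
#' the distribution-fitting stage. Deterministic given its inputs.
#'
#' @param map a [probability_map].
#' @param class_i segmented class (default foreground).
#' @param percentiles numeric vector of percentiles in (0, 100).
#' @param quantities subset of `"volume_fraction"`,
#'   `"effective_conductivity"`, `"tortuosity"`.
#' @param axis transport axis for solves.
#' @param k_in,k_out phase conductivities for `effective_conductivity`
#'   (segmented phase is the conductor).
#' @param pore phase interpretation for `tortuosity`, see [tortuosity].
#' @param rtol,maxit CG controls.
#' @return data.frame with columns `percentile`, `threshold`, `quantity`,
#'   `axis`, `value`, `iterations`, `residual`.
#' @export
run_physics_sweep <- function(map, class_i = NULL, percentiles,
                              quantities = "volume_fraction", axis = "x",
                              k_in = 1, k_out = 1e-6, pore = "mask",
                              rtol = 1e-12, maxit = NULL) {
  quantities <- match.arg(quantities,
                          c("volume_fraction", "effective_conductivity",
                            "tortuosity"), several.ok = TRUE)
  rows <- list()
  for (P in percentiles) {
    seg <- threshold_map(map, class_i, P)
    for (q in quantities) {
      res <- switch(q,
        volume_fraction = volume_fraction(seg),
        effective_conductivity = {
          r <- solve_effective_transport(
            conductivity_field(seg, k_in = k_in, k_out = k_out), axis,
            rtol = rtol, maxit = maxit)
          r$percentile <- P
          r
        },
        tortuosity = tortuosity(seg, axis, pore = pore, rtol = rtol,
                                maxit = maxit))
      rows[[length(rows) + 1]] <- data.frame(
        percentile = P, threshold = seg$threshold, quantity = q,
        axis = if (q == "volume_fraction") NA_character_ else res$axis,
        value = res$value,
        iterations = res$solver_stats$iterations,
        residual = res$solver_stats$residual,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(percentile = numeric(0), threshold = numeric(0),
                      quantity = character(0), axis = character(0),
                      value = numeric(0), iterations = integer(0),
                      residual = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
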