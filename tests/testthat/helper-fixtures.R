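# Fixtures and independent oracles, built in code at test time.

# random binary label stack on a small grid
random_stack <- function(N, d = c(4, 4, 4), seed = 1, classes = 0:1) {
  set.seed(seed)
  samples <- lapply(seq_len(N), function(k)
    array(sample(classes, prod(d), replace = TRUE), d))
  seg_sample_stack(samples, classes = classes)
}

# brute-force per-voxel, per-class sample mean with explicit nested loops
brute_force_probmap <- function(stack, class_i) {
  d <- dim(stack$samples[[1]])
  out <- array(0, d)
  N <- length(stack$samples)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    s <- 0
    for (n in seq_len(N)) s <- s + (stack$samples[[n]][i, j, k] == class_i)
    out[i, j, k] <- s / N
  }
  out
}

# spherical interface profile: eps = pnorm((R - r) / w), level 0.5 at r = R
sphere_profile_map <- function(n = 40, R = 12, w = 2) {
  cc <- (seq_len(n) - 0.5) - n / 2
  r <- sqrt(outer(outer(cc^2, cc^2, "+"), cc^2, "+"))
  arr <- pnorm((R - r) / w)
  dim(arr) <- c(n, n, n)
  arr
}

# dense direct finite-volume solve, written as an explicit scalar loop:
# an independent oracle for the sparse iterative path (same discretization,
# different implementation route, exact direct solve). Transport along x;
# permute the mask to probe other axes.
dense_keff <- function(mask, k_in = 1, k_out = 1e-6, spacing = c(1, 1, 1)) {
  axis <- 1
  d <- dim(mask); n <- prod(d); h <- spacing
  if (length(k_in) == 1) k_in <- rep(k_in, 3)
  if (length(k_out) == 1) k_out <- rep(k_out, 3)
  kf <- function(i, j, k, ax) if (mask[i, j, k]) k_in[ax] else k_out[ax]
  lin <- function(i, j, k) i + (j - 1) * d[1] + (k - 1) * d[1] * d[2]
  A <- matrix(0, n, n); b <- numeric(n)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    p <- lin(i, j, k)
    for (step in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                      c(0, 0, 1), c(0, 0, -1))) {
      ax <- which(step != 0)
      Af <- prod(h) / h[ax]
      ni <- i + step[1]; nj <- j + step[2]; nk <- k + step[3]
      inside <- ni >= 1 && ni <= d[1] && nj >= 1 && nj <= d[2] &&
        nk >= 1 && nk <= d[3]
      if (inside) {
        kp <- kf(i, j, k, ax); kq <- kf(ni, nj, nk, ax)
        g <- Af * (2 * kp * kq / (kp + kq)) / h[ax]
        A[p, p] <- A[p, p] + g
        A[p, lin(ni, nj, nk)] <- A[p, lin(ni, nj, nk)] - g
      } else if (ax == axis) {
        g <- 2 * Af * kf(i, j, k, ax) / h[ax]
        A[p, p] <- A[p, p] + g
        if (step[ax] < 0) b[p] <- b[p] + g  # phi = 1 on the low face
      }
    }
  }
  phi <- solve(A, b)
  Q <- 0
  for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    g <- 2 * (prod(h) / h[1]) * kf(1, j, k, 1) / h[1]
    Q <- Q + g * (1 - phi[lin(1, j, k)])
  }
  L <- d[axis] * h[axis]
  A_total <- prod(d[-axis]) * prod(h[-axis])
  Q / A_total * L
}

# winding pore channel: enters along x at low y, crosses, returns, so the
# transport path is ~2 traversals long
serpentine_mask <- function(d = c(6, 6, 3)) {
  m <- array(FALSE, d)
  m[, 1:2, ] <- TRUE
  m[(d[1] - 1):d[1], , ] <- TRUE
  m[, (d[2] - 1):d[2], ] <- TRUE
  m
}
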