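# Characteristic-distribution estimation. Each percentile segmentation P
# yields one physics value Q(P); interpreting Q(P) as the P/100 quantile of
# the unknown uncertainty distribution, the three standard segmentations
# specify a Normal: the 50.0-percentile value is the mean and half the
# spread between the 84.1 and 15.9 values is the standard deviation.
# When held-out percentile points fall off that CDF, alternative families
# (beta on a bounded support, half-Cauchy, or the empirical interpolant)
# are fitted by least-squares quantile matching.

#' Percentile/quantity table
#'
#' @param percentile percentiles in (0, 100), unique.
#' @param value physics quantity at each percentile.
#' @param quantity quantity name (metadata).
#' @return data.frame of class `quantity_table` with columns `percentile`,
#'   `value`, sorted by percentile.
#' @export
quantity_table <- function(percentile, value, quantity = "") {
  percentile <- as.numeric(percentile); value <- as.numeric(value)
  if (length(percentile) != length(value))
    stop("percentile and value lengths differ", call. = FALSE)
  if (length(percentile)) {
    if (any(percentile <= 0 | percentile >= 100))
      stop("percentiles must lie strictly inside (0, 100)", call. = FALSE)
    if (anyDuplicated(percentile))
      stop("percentiles must be unique", call. = FALSE)
  }
  o <- order(percentile)
  structure(data.frame(percentile = percentile[o], value = value[o]),
            quantity = quantity,
            class = c("quantity_table", "data.frame"))
}

as_quantity_table <- function(x) {
  if (inherits(x, "quantity_table")) return(x)
  if (is.data.frame(x) && all(c("percentile", "value") %in% names(x)))
    return(quantity_table(x$percentile, x$value))
  stop("expected a quantity_table or a data.frame with percentile/value columns",
       call. = FALSE)
}

table_lookup <- function(tab, P, tol = 1e-9) {
  i <- which(abs(tab$percentile - P) <= tol)
  if (length(i) != 1) return(NA_real_)
  tab$value[i]
}

characteristic_distribution <- function(family, params, diagnostics = list()) {
  structure(list(family = family, params = params, diagnostics = diagnostics),
            class = "characteristic_distribution")
}

#' @export
print.characteristic_distribution <- function(x, ...) {
  cat(sprintf("<characteristic_distribution> %s(%s)\n", x$family,
              paste(sprintf("%s = %.6g", names(x$params), unlist(x$params)),
                    collapse = ", ")))
  if (isTRUE(x$diagnostics$degenerate)) cat("  degenerate (sigma = 0)\n")
  if (isTRUE(x$diagnostics$decreasing))
    cat("  quantity decreases with percentile (|half-width| used)\n")
  invisible(x)
}

#' Characteristic Normal from the standard segmentations
#'
#' Mean = Q(50.0); sigma from the symmetric spread between the 84.1 and
#' 15.9 percentile values. Because the printed standard percentiles are
#' rounded (`qnorm(0.841) = 0.9986`, not exactly 1), the spread is divided
#' by the exact Normal quantile distance `2 * qnorm(0.841)` rather than by
#' 2, so a table whose values are exact Normal quantiles at the standard
#' percentiles recovers its sigma without bias. The raw symmetric
#' half-width `(Q(84.1) - Q(15.9)) / 2` and both one-sided half-widths are
#' kept in the diagnostics so asymmetry stays visible; a quantity that
#' decreases with percentile gives a negative half-width, which is flagged
#' and used in absolute value.
#'
#' @param table a [quantity_table] containing P = 15.9, 50.0, 84.1.
#' @param allow_nonmonotone proceed even when the table is non-monotone in
#'   percentile (see [check_monotonicity]); default errors.
#' @return a `characteristic_distribution` with `family = "normal"` and
#'   params `mean`, `sd`.
#' @export
fit_characteristic_normal <- function(table, allow_nonmonotone = FALSE) {
  table <- as_quantity_table(table)
  std <- standard_percentiles()
  q <- vapply(std, function(P) table_lookup(table, P), numeric(1))
  missing <- std[is.na(q)]
  if (length(missing))
    stop("table is missing standard percentile(s): ",
         paste(format(missing), collapse = ", "), call. = FALSE)
  if (nrow(table) >= 3 && !allow_nonmonotone) {
    rep <- check_monotonicity(table)
    if (!rep$monotone)
      stop("quantity table is non-monotone in percentile; fit the empirical ",
           "family or pass allow_nonmonotone = TRUE", call. = FALSE)
  }
  half <- (q[["high"]] - q[["low"]]) / 2
  # exact quantile distance between the rounded standard percentiles
  sigma <- abs(q[["high"]] - q[["low"]]) / (2 * qnorm(std[["high"]] / 100))
  characteristic_distribution(
    "normal", list(mean = q[["mid"]], sd = sigma),
    diagnostics = list(halfwidth_sym = half,
                       halfwidth_upper = q[["high"]] - q[["mid"]],
                       halfwidth_lower = q[["mid"]] - q[["low"]],
                       decreasing = half < 0,
                       degenerate = sigma == 0))
}

#' CDF and quantile function of a characteristic distribution
#'
#' Standard CDF/quantile of the fitted family; on the support interior the
#' two are mutual inverses. A degenerate Normal (sigma = 0) has a step CDF
#' at the mean.
#'
#' @param dist a `characteristic_distribution`.
#' @param q quantity values (for the CDF).
#' @param p probabilities strictly inside (0, 1) (for the quantile).
#' @return probabilities, resp. quantity values.
#' @export
characteristic_cdf <- function(dist, q) {
  stopifnot(inherits(dist, "characteristic_distribution"))
  pp <- dist$params
  switch(dist$family,
    normal = if (pp$sd == 0) as.numeric(q >= pp$mean)
             else pnorm(q, pp$mean, pp$sd),
    beta = pbeta((q - pp$lower) / (pp$upper - pp$lower), pp$shape1, pp$shape2),
    half_cauchy = ifelse(q < pp$location, 0,
                         2 / pi * atan((q - pp$location) / pp$scale)),
    empirical = {
      out <- approx(pp$x, pp$p, xout = q, rule = 2, ties = "ordered")$y
      out[q < min(pp$x)] <- 0
      out
    },
    stop("unknown family ", dist$family, call. = FALSE))
}

#' @rdname characteristic_cdf
#' @export
characteristic_quantile <- function(dist, p) {
  stopifnot(inherits(dist, "characteristic_distribution"))
  if (any(p <= 0 | p >= 1))
    stop("quantile probabilities must lie strictly inside (0, 1)", call. = FALSE)
  pp <- dist$params
  switch(dist$family,
    normal = if (pp$sd == 0) rep(pp$mean, length(p))
             else qnorm(p, pp$mean, pp$sd),
    beta = pp$lower + (pp$upper - pp$lower) * qbeta(p, pp$shape1, pp$shape2),
    half_cauchy = pp$location + pp$scale * tan(pi * p / 2),
    empirical = approx(pp$p, pp$x, xout = p, rule = 2, ties = "ordered")$y,
    stop("unknown family ", dist$family, call. = FALSE))
}

#' Assess a characteristic fit against held-out percentile points
#'
#' Percentile rows beyond the standard three were not used to specify the
#' characteristic Normal; if the fit is good they should fall on its CDF.
#' For each held-out row the discrepancy `|CDF(Q(P)) - P/100|` is reported;
#' large tail discrepancies signal a non-Normal quantity and the need for
#' more percentile segmentations.
#'
#' @param dist a `characteristic_distribution`.
#' @param table a [quantity_table] with percentiles beyond 15.9/50/84.1.
#' @param tolerance absolute CDF discrepancy for the pass flag.
#' @return list with `per_point` (data.frame percentile, value, cdf,
#'   discrepancy), `max`, `mean`, `pass`.
#' @export
assess_characteristic_fit <- function(dist, table, tolerance = 0.05) {
  table <- as_quantity_table(table)
  std <- standard_percentiles()
  held <- table[!vapply(table$percentile,
                        function(P) any(abs(std - P) <= 1e-9), logical(1)), ]
  if (!nrow(held))
    stop("no held-out rows: table contains only the standard percentiles",
         call. = FALSE)
  cdf <- characteristic_cdf(dist, held$value)
  disc <- abs(cdf - held$percentile / 100)
  list(per_point = data.frame(percentile = held$percentile,
                              value = held$value, cdf = cdf,
                              discrepancy = disc),
       max = max(disc), mean = mean(disc),
       pass = max(disc) <= tolerance, tolerance = tolerance)
}

#' Fit an alternative distribution family by quantile matching
#'
#' Least-squares match of the family quantile function to the table:
#' parameters minimize `sum_P (quantile(P/100) - Q(P))^2`, via Nelder-Mead
#' simplex from moment-based starts with 3 restarts (fixed restart seed).
#' The beta family lives on a finite support: supplied via `support`, or
#' defaulting to `[0, 1.1 * max(Q)]` (bounded-below quantities such as
#' permeability must not be assigned negative mass); with >= 6 rows and no
#' supplied support the bounds are estimated as free parameters. The
#' empirical family is the monotone linear interpolant of `(Q(P), P/100)`.
#'
#' @param table a [quantity_table] with at least 4 rows for parametric
#'   families.
#' @param family `"beta"`, `"half_cauchy"` or `"empirical"`.
#' @param support optional `c(lower, upper)` for the beta family.
#' @return a `characteristic_distribution`.
#' @export
fit_alternative <- function(table, family = c("beta", "half_cauchy", "empirical"),
                            support = NULL) {
  family <- match.arg(family)
  table <- as_quantity_table(table)
  P <- table$percentile / 100
  Q <- table$value

  if (family == "empirical") {
    rep <- check_monotonicity(table)
    if (!rep$monotone)
      stop("empirical family requires a monotone quantity table", call. = FALSE)
    x <- if (rep$direction == "decreasing") rev(Q) else Q
    p <- if (rep$direction == "decreasing") rev(P) else P
    return(characteristic_distribution("empirical", list(x = x, p = p),
                                       diagnostics = list(direction = rep$direction)))
  }
  if (nrow(table) < 4)
    stop(family, " fit needs at least 4 percentile rows, got ", nrow(table),
         call. = FALSE)

  obj_q <- switch(family,
    half_cauchy = function(par) {
      loc <- par[1]; sc <- exp(par[2])
      loc + sc * tan(pi * P / 2)
    },
    beta = NULL)

  old_seed <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(0)

  if (family == "half_cauchy") {
    span <- max(diff(range(Q)), 1e-12)
    start <- c(min(Q) - 0.05 * span, log(max(median(Q) - min(Q) + 0.05 * span,
                                             1e-12)))
    fn <- function(par) {
      r <- (par[1] + exp(par[2]) * tan(pi * P / 2)) - Q
      sum(r^2)
    }
    best <- multi_start_optim(fn, start, n_restarts = 3)
    params <- list(location = best$par[1], scale = exp(best$par[2]))
  } else {  # beta
    estimate_support <- is.null(support) && nrow(table) >= 6
    if (is.null(support)) support <- c(0, 1.1 * max(Q))
    if (support[1] >= support[2])
      stop("beta support must satisfy lower < upper", call. = FALSE)
    mom_ab <- function(lo, up) {
      y <- pmin(pmax((Q - lo) / (up - lo), 1e-6), 1 - 1e-6)
      m <- mean(y); v <- max(var(y), 1e-8)
      c(max(m * (m * (1 - m) / v - 1), 0.1),
        max((1 - m) * (m * (1 - m) / v - 1), 0.1))
    }
    if (estimate_support) {
      span <- max(diff(range(Q)), 1e-12)
      lo0 <- support[1]; up0 <- support[2]
      ab0 <- mom_ab(lo0, up0)
      start <- c(lo0, log(up0 - lo0), log(ab0))
      fn <- function(par) {
        lo <- par[1]; up <- lo + exp(par[2])
        a <- exp(par[3]); b <- exp(par[4])
        r <- (lo + (up - lo) * qbeta(P, a, b)) - Q
        sum(r^2)
      }
      best <- multi_start_optim(fn, start, n_restarts = 3)
      params <- list(shape1 = exp(best$par[3]), shape2 = exp(best$par[4]),
                     lower = best$par[1], upper = best$par[1] + exp(best$par[2]))
    } else {
      ab0 <- mom_ab(support[1], support[2])
      start <- log(ab0)
      fn <- function(par) {
        a <- exp(par[1]); b <- exp(par[2])
        r <- (support[1] + diff(support) * qbeta(P, a, b)) - Q
        sum(r^2)
      }
      best <- multi_start_optim(fn, start, n_restarts = 3)
      params <- list(shape1 = exp(best$par[1]), shape2 = exp(best$par[2]),
                     lower = support[1], upper = support[2])
    }
  }
  if (!is.finite(best$value))
    stop("quantile-matching optimizer failed; best iterate: ",
         paste(format(best$par), collapse = ", "), call. = FALSE)
  characteristic_distribution(family, params,
                              diagnostics = list(objective = best$value,
                                                 convergence = best$convergence))
}

multi_start_optim <- function(fn, start, n_restarts = 3) {
  best <- NULL
  for (r in seq_len(n_restarts)) {
    s <- if (r == 1) start else start + rnorm(length(start), sd = 0.25)
    fit <- tryCatch(optim(s, fn, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-12)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    # polish: restart the simplex at its own optimum
    fit <- optim(fit$par, fn, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed", call. = FALSE)
  best
}

#' Monotonicity check on a percentile/quantity table
#'
#' Nested percentile segmentations usually give quantities monotone in P;
#' non-monotone tables are a warning sign that the three standard
#' segmentations do not bound the quantity, so characteristic fitting
#' should only proceed with an explicit override. Additionally flags
#' interior rows escaping the `[Q(15.9), Q(84.1)]` band when both outer
#' standard percentiles are present.
#'
#' @param table a [quantity_table] with at least 3 rows.
#' @return list of class `monotonicity_report`: `monotone`, `direction`
#'   (`"increasing"`, `"decreasing"`, `"constant"` or `"none"`), `escapes`
#'   (percentiles of interior rows outside the standard band, `NULL` when
#'   the band is unavailable), `band`.
#' @export
check_monotonicity <- function(table) {
  table <- as_quantity_table(table)
  if (nrow(table) < 3)
    stop("monotonicity check needs at least 3 rows", call. = FALSE)
  dv <- diff(table$value)
  inc <- all(dv >= 0); dec <- all(dv <= 0)
  direction <- if (inc && dec) "constant" else if (inc) "increasing"
               else if (dec) "decreasing" else "none"
  q_lo <- table_lookup(table, 15.9)
  q_hi <- table_lookup(table, 84.1)
  escapes <- NULL; band <- NULL
  if (!is.na(q_lo) && !is.na(q_hi)) {
    band <- sort(c(q_lo, q_hi))
    interior <- table$percentile > 15.9 + 1e-9 & table$percentile < 84.1 - 1e-9
    out <- interior & (table$value < band[1] | table$value > band[2])
    escapes <- table$percentile[out]
  }
  structure(list(monotone = inc || dec, direction = direction,
                 escapes = escapes, band = band),
            class = "monotonicity_report")
}

#' @export
print.monotonicity_report <- function(x, ...) {
  cat(sprintf("<monotonicity_report> monotone: %s (%s)\n",
              x$monotone, x$direction))
  if (!is.null(x$escapes) && length(x$escapes))
    cat("  interior percentiles escaping the [Q(15.9), Q(84.1)] band:",
        paste(format(x$escapes), collapse = ", "), "\n")
  invisible(x)
}
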