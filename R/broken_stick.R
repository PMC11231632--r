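#' Broken-stick (linear-plateau) fit of transpiration against SWC
#'
#' Fits the stomatal-limitation model behind the critical soil water content
#' theta_c: transpiration is constant at `tr_max` for SWC at or above
#' `theta_c` and declines linearly below it,
#' `TR(s) = tr_max - b * (theta_c - s)` with `b >= 0`, continuous at the
#' breakpoint. For every candidate breakpoint on a grid over the observed
#' SWC range the remaining two parameters have an exact conditional
#' least-squares solution; the returned fit is the global SSE minimizer,
#' ties broken toward the larger breakpoint (earlier stomatal closure is the
#' conservative physiological reading). A fit is invalid when the minimizer
#' sits on the grid boundary or the decline slope vanishes (no identifiable
#' breakpoint), or when the data are insufficient (fewer than 6 points or
#' an SWC span under 10 percentage points).
#'
#' @param swc Soil water content, percent.
#' @param tr Transpiration response (whole-plant mmol s^-1 or normalized
#'   platform units; theta_c is invariant to the response scale).
#' @param grid_step Breakpoint grid resolution, SWC percentage points.
#' @param plateau_slope_zero If `TRUE` (default) the upper segment is a flat
#'   plateau; if `FALSE` it has a free slope (two-segment continuous fit).
#' @return Object of class `theta_fit`: list with `theta_c`, `tr_max`
#'   (plateau level at the breakpoint), `slope`, `sse`, `n_points`, `valid`,
#'   `boundary_flag` (`"none"`, `"at_min"`, `"at_max"`), `reason`.
#' @export
fit_broken_stick <- function(swc, tr, grid_step = 0.01,
                             plateau_slope_zero = TRUE) {
  ok <- is.finite(swc) & is.finite(tr)
  swc <- swc[ok]; tr <- tr[ok]
  n <- length(swc)
  invalid <- function(reason, flag = "none") {
    structure(list(theta_c = NA_real_, tr_max = NA_real_, slope = NA_real_,
                   sse = NA_real_, n_points = n, valid = FALSE,
                   boundary_flag = flag, reason = reason),
              class = "theta_fit")
  }
  if (n < 6) return(invalid("fewer than 6 points"))
  lo <- min(swc); hi <- max(swc)
  if (hi - lo < 10) return(invalid("SWC span below 10 percentage points"))

  grid <- seq(lo, hi, by = grid_step)
  if (grid[length(grid)] < hi) grid <- c(grid, hi)
  G <- length(grid)
  # hinge matrix: x[i, g] = max(0, c_g - s_i)
  X <- pmax(outer(-swc, grid, `+`), 0)  # arg order keeps the matrix dims
  if (plateau_slope_zero) {
    # tr = a - b * x, conditional LS in (a, b), constrained b >= 0
    sy <- sum(tr); syy <- sum(tr^2)
    sx <- colSums(X); sxx <- colSums(X^2); sxy <- colSums(X * tr)
    vx <- sxx - sx^2 / n
    cxy <- sxy - sx * sy / n
    b <- ifelse(vx > 0, -cxy / vx, 0)
    b <- pmax(0, b)
    a <- (sy + b * sx) / n
    sse <- syy - 2 * a * sy + n * a^2 + 2 * b * (sxy - a * sx) + b^2 * sxx
    tr_max <- a
  } else {
    fits <- vapply(seq_len(G), function(g) {
      up <- pmax(0, swc - grid[g])
      fm <- stats::lm.fit(cbind(1, -X[, g], up), tr)
      cf <- fm$coefficients
      if (is.na(cf[2]) || cf[2] < 0) {
        fm <- stats::lm.fit(cbind(1, up), tr)
        c(sum(fm$residuals^2), fm$coefficients[1], 0)
      } else {
        c(sum(fm$residuals^2), cf[1], cf[2])
      }
    }, numeric(3))
    sse <- fits[1, ]; tr_max <- fits[2, ]; b <- fits[3, ]
  }
  sse <- pmax(0, sse)
  best <- which(sse <= min(sse) + 1e-12)
  best <- best[length(best)]  # ties toward larger theta_c
  theta_hat <- grid[best]; tr_hat <- tr_max[best]; b_hat <- b[best]
  sse_hat <- sse[best]
  if (plateau_slope_zero && best > 1 && best < G) {
    # continuous polish of the breakpoint between the neighboring knots
    sse_at <- function(cc) {
      x <- pmax(cc - swc, 0)
      vx1 <- sum(x^2) - sum(x)^2 / n
      b1 <- if (vx1 > 0) max(0, -(sum(x * tr) - sum(x) * sum(tr) / n) / vx1) else 0
      a1 <- (sum(tr) + b1 * sum(x)) / n
      sum((tr - a1 + b1 * x)^2)
    }
    op <- stats::optimize(sse_at, c(grid[best - 1], grid[best + 1]),
                          tol = 1e-7)
    if (op$objective < sse_hat) {
      theta_hat <- op$minimum
      sse_hat <- op$objective
      x <- pmax(theta_hat - swc, 0)
      vx1 <- sum(x^2) - sum(x)^2 / n
      b_hat <- if (vx1 > 0) max(0, -(sum(x * tr) - sum(x) * sum(tr) / n) / vx1) else 0
      tr_hat <- (sum(tr) + b_hat * sum(x)) / n
    }
  }
  flat <- b_hat <= 1e-8
  flag <- if (flat || best == 1) "at_min" else if (best == G) "at_max" else "none"
  valid <- flag == "none"
  structure(list(
    theta_c = theta_hat, tr_max = tr_hat, slope = b_hat,
    sse = sse_hat, n_points = n, valid = valid,
    boundary_flag = flag,
    reason = if (valid) NA_character_ else "breakpoint at boundary or flat response"
  ), class = "theta_fit")
}

#' @export
print.theta_fit <- function(x, ...) {
  if (isTRUE(x$valid)) {
    cat(sprintf(
      "<theta_fit> theta_c = %.2f %% SWC, plateau = %.3f, slope = %.4f, sse = %.4g (n = %d)\n",
      x$theta_c, x$tr_max, x$slope, x$sse, x$n_points))
  } else {
    cat(sprintf("<theta_fit> invalid (%s), n = %d\n", x$reason, x$n_points))
  }
  invisible(x)
}

#' Per-line theta_c estimation from daily traits
#'
#' Pools (SWC, response) points across a line's replicates over the
#' pre-treatment and drought phases (clipped-SWC and missing-flagged days
#' excluded), fits the broken stick to the pooled points, and also fits
#' each replicate separately, reporting the replicate mean and standard
#' error of theta_c. The default response is demand-normalized solar-noon
#' transpiration per gram (`e_fit_norm`, paired with `swc_fit`): weight
#' normalization removes growth non-stationarity and demand normalization
#' removes day-to-day atmospheric variance, so its plateau estimates the
#' line's E_max at reference forcing. `tr_midday_mmol_s` gives the
#' whole-plant variant.
#'
#' @param daily A `daily_traits` table (one or more plants of one line).
#' @param response Column to use as the transpiration response.
#' @param phases Phases whose days contribute points.
#' @param grid_step Passed to [fit_broken_stick()].
#' @param dead_floor Days whose response has collapsed below this fraction
#'   of the observed maximum are excluded: after full stomatal closure the
#'   response saturates at zero (a second hinge) and no longer informs the
#'   linear decline, while the zero-floor of the rate estimator would bias
#'   such points upward.
#' @return List of class `theta_line`: `pooled` (a `theta_fit`),
#'   `per_replicate` (tibble `plant_id`, `theta_c`, `tr_max`, `slope`,
#'   `valid`), `theta_c_mean`, `theta_c_se`, `n_replicates`, `unfittable`.
#' @export
theta_by_line <- function(daily,
                          response = c("e_fit_norm", "e_midday_norm",
                                       "e_midday", "tr_midday_mmol_s"),
                          phases = c("pre", "drought"), grid_step = 0.01,
                          dead_floor = 0.05) {
  response <- match.arg(response)
  swc_col <- if (response == "e_fit_norm") "swc_fit" else "swc_midday"
  pts <- daily |>
    dplyr::filter(.data$phase %in% phases, !.data$flag_missing,
                  !.data$clipped, is.finite(.data[[swc_col]]),
                  is.finite(.data[[response]]))
  if (nrow(pts) > 0) {
    pts <- dplyr::filter(pts, .data[[response]] >=
                           dead_floor * max(pts[[response]]))
  }
  pooled <- fit_broken_stick(pts[[swc_col]], pts[[response]], grid_step)
  per_rep <- pts |>
    dplyr::group_by(.data$plant_id) |>
    dplyr::group_modify(function(g, key) {
      f <- fit_broken_stick(g[[swc_col]], g[[response]], grid_step)
      tibble::tibble(theta_c = f$theta_c, tr_max = f$tr_max,
                     slope = f$slope, valid = f$valid)
    }) |>
    dplyr::ungroup()
  th <- per_rep$theta_c[per_rep$valid]
  structure(list(
    pooled = pooled,
    per_replicate = per_rep,
    theta_c_mean = if (length(th)) mean(th) else NA_real_,
    theta_c_se = if (length(th) > 1) sd(th) / sqrt(length(th)) else NA_real_,
    n_replicates = nrow(per_rep),
    unfittable = !pooled$valid && length(th) == 0
  ), class = "theta_line")
}

#' Theta_c and plateau fits for every line of a cohort trait table
#'
#' @param daily `daily_traits` for several lines.
#' @inheritParams theta_by_line
#' @return Tibble: `line`, `theta_c`, `tr_max`, `slope`, `sse`, `n_points`,
#'   `valid`, `boundary_flag`, `theta_c_mean`, `theta_c_se`, `unfittable`.
#' @export
theta_by_cohort <- function(daily,
                            response = c("e_fit_norm", "e_midday_norm",
                                         "e_midday", "tr_midday_mmol_s"),
                            phases = c("pre", "drought"), grid_step = 0.01) {
  response <- match.arg(response)
  daily |>
    dplyr::group_by(.data$line) |>
    dplyr::group_modify(function(g, key) {
      fit <- theta_by_line(g, response, phases, grid_step)
      p <- fit$pooled
      tibble::tibble(theta_c = p$theta_c, tr_max = p$tr_max, slope = p$slope,
                     sse = p$sse, n_points = p$n_points, valid = p$valid,
                     boundary_flag = p$boundary_flag,
                     theta_c_mean = fit$theta_c_mean,
                     theta_c_se = fit$theta_c_se,
                     unfittable = fit$unfittable)
    }) |>
    dplyr::ungroup()
}
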