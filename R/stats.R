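#' Pearson correlation with degeneracy guards
#'
#' Sample Pearson correlation of paired per-line values; returns `NA` with a
#' warning when either argument has zero variance, and errors on fewer than
#' 3 complete pairs.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation coefficient in \[-1, 1\], or `NA` if undefined.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (var(x) == 0 || var(y) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  cor(x, y)
}

# Insert-and-absorb compact letter display. `sig` is a logical matrix
# (groups x groups) of significant pairwise differences. Returns a character
# vector of letter sets per group (in the given group order, assumed sorted
# by descending mean). Guarantees: two groups share a letter iff their pair
# is not significant.
.cld_insert_absorb <- function(sig) {
  g <- nrow(sig)
  cols <- list(seq_len(g))
  pairs <- which(sig & upper.tri(sig), arr.ind = TRUE)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    new_cols <- list()
    for (col in cols) {
      if (i %in% col && j %in% col) {
        new_cols <- c(new_cols, list(setdiff(col, i)), list(setdiff(col, j)))
      } else {
        new_cols <- c(new_cols, list(col))
      }
    }
    # absorb columns that are subsets of another
    keep <- rep(TRUE, length(new_cols))
    for (a in seq_along(new_cols)) {
      for (b in seq_along(new_cols)) {
        if (a != b && keep[a] &&
            all(new_cols[[a]] %in% new_cols[[b]]) &&
            (length(new_cols[[a]]) < length(new_cols[[b]]) || a > b)) {
          keep[a] <- FALSE
        }
      }
    }
    cols <- new_cols[keep]
  }
  ord <- order(vapply(cols, min, numeric(1)))
  cols <- cols[ord]
  letters_pool <- c(letters, paste0(rep(letters, each = 26), letters))
  out <- vapply(seq_len(g), function(i) {
    paste0(letters_pool[which(vapply(cols, function(col) i %in% col,
                                     logical(1)))], collapse = "")
  }, character(1))
  out
}

#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Fits a one-way ANOVA of `value` on `group`, performs all-pairs Tukey HSD
#' (Tukey-Kramer adjustment under unbalanced replication, via
#' [stats::TukeyHSD()]), and summarizes the pairwise decisions as a compact
#' letter display built by the insert-and-absorb algorithm: two groups share
#' at least one letter exactly when their Tukey-adjusted difference is not
#' significant at `alpha`.
#'
#' @param value Numeric response.
#' @param group Grouping factor/character (e.g. line).
#' @param alpha Significance level.
#' @return Tibble sorted by descending mean: `group`, `mean`, `se`, `n`,
#'   `letters`. Attributes: `"anova_f"`, `"anova_p"`, `"tukey"` (the adjusted
#'   p-value matrix), `"alpha"`, `"excluded"` (groups dropped for n < 2).
#' @export
anova_tukey_letters <- function(value, group, alpha = 0.05) {
  d <- tibble::tibble(value = value, group = as.character(group)) |>
    dplyr::filter(is.finite(.data$value))
  cnt <- table(d$group)
  excluded <- names(cnt)[cnt < 2]
  if (length(excluded)) {
    warning("groups with < 2 replicates excluded: ",
            paste(excluded, collapse = ", "))
    d <- dplyr::filter(d, !.data$group %in% excluded)
  }
  if (length(unique(d$group)) < 2) stop("need at least 2 groups with n >= 2")
  d$group <- factor(d$group)
  fit <- aov(value ~ group, data = d)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$group

  lv <- levels(d$group)
  g <- length(lv)
  pmat <- matrix(1, g, g, dimnames = list(lv, lv))
  pairs_lv <- utils::combn(lv, 2)
  expected <- paste0(pairs_lv[2, ], "-", pairs_lv[1, ])
  idx <- match(expected, rownames(tk))
  stopifnot(!anyNA(idx))
  for (k in seq_along(expected)) {
    a <- pairs_lv[1, k]; b <- pairs_lv[2, k]
    pmat[a, b] <- pmat[b, a] <- tk[idx[k], "p adj"]
  }

  sums <- d |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean = mean(.data$value),
                     se = sd(.data$value) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean))
  ord <- as.character(sums$group)
  sig <- pmat[ord, ord, drop = FALSE] < alpha
  sig[is.na(sig)] <- FALSE  # degenerate ANOVA (zero variance): nothing differs
  sums$letters <- .cld_insert_absorb(sig)
  sums$group <- as.character(sums$group)
  structure(sums,
            anova_f = an[["F value"]][1], anova_p = an[["Pr(>F)"]][1],
            tukey = pmat, alpha = alpha, excluded = excluded)
}

#' Classify drought-response strategy per line
#'
#' Rank-based rule over pre-treatment transpiration, drought transpiration
#' and the critical soil water content:
#' \itemize{
#'   \item dynamic: top-tertile pre-treatment DT, bottom-tertile drought DT,
#'     top-half theta_c (water-spending when watered, early curtailment);
#'   \item anisohydric: bottom-tertile pre-treatment DT, top-tertile drought
#'     DT, bottom-half theta_c (water-non-conserving, late curtailment);
#'   \item isohydric: all remaining lines.
#' }
#' With missing theta_c a line is classified on the DT ranks alone and
#' flagged low-confidence. Degenerate inputs (no rank separation) yield all
#' isohydric.
#'
#' @param metrics Tibble with `line`, `dt_pre`, `dt_drought` and optionally
#'   `theta_c` columns (e.g. from [build_metrics()]).
#' @return Tibble: `line`, `strategy`, `pre_tertile`, `drought_tertile`,
#'   `theta_half`, `low_confidence`.
#' @export
classify_strategy <- function(metrics) {
  stopifnot(all(c("line", "dt_pre", "dt_drought") %in% names(metrics)))
  n <- nrow(metrics)
  tertile <- function(x) {
    if (all(!is.finite(x)) || var(x[is.finite(x)]) == 0) {
      return(rep("mid", length(x)))
    }
    r <- rank(x, ties.method = "average")
    ifelse(r > 2 * n / 3, "top", ifelse(r <= n / 3, "bottom", "mid"))
  }
  half <- function(x) {
    if (all(!is.finite(x)) || var(x[is.finite(x)], na.rm = TRUE) == 0) {
      return(rep(NA_character_, length(x)))
    }
    r <- rank(x, ties.method = "average", na.last = "keep")
    ifelse(is.na(r), NA_character_, ifelse(r > n / 2, "top", "bottom"))
  }
  pre_t <- tertile(metrics$dt_pre)
  dr_t <- tertile(metrics$dt_drought)
  has_theta <- "theta_c" %in% names(metrics) && any(is.finite(metrics$theta_c))
  th_h <- if (has_theta) half(metrics$theta_c) else rep(NA_character_, n)
  low_conf <- is.na(th_h)

  dyn <- pre_t == "top" & dr_t == "bottom" & (is.na(th_h) | th_h == "top")
  ani <- pre_t == "bottom" & dr_t == "top" & (is.na(th_h) | th_h == "bottom")
  strategy <- ifelse(dyn, "dynamic", ifelse(ani, "anisohydric", "isohydric"))
  tibble::tibble(
    line = metrics$line, strategy = strategy,
    pre_tertile = pre_t, drought_tertile = dr_t, theta_half = th_h,
    low_confidence = low_conf
  )
}

#' Rank positions and rank shifts across phases
#'
#' Ranks lines within each phase by descending value (rank 1 = highest;
#' ties get average ranks) and reports the signed rank changes from
#' pre-treatment to drought and from drought to rewatering.
#'
#' @param metrics Tibble with `line`, `dt_pre`, `dt_drought`, `dt_rewater`.
#' @return Tibble: `line`, `rank_pre`, `rank_drought`, `rank_rewater`,
#'   `shift_pre_drought`, `shift_drought_rewater`.
#' @export
rank_shift_table <- function(metrics) {
  stopifnot(all(c("line", "dt_pre", "dt_drought", "dt_rewater") %in%
                  names(metrics)))
  rk <- function(x) rank(-x, ties.method = "average", na.last = "keep")
  r1 <- rk(metrics$dt_pre); r2 <- rk(metrics$dt_drought)
  r3 <- rk(metrics$dt_rewater)
  tibble::tibble(
    line = metrics$line,
    rank_pre = r1, rank_drought = r2, rank_rewater = r3,
    shift_pre_drought = r2 - r1,
    shift_drought_rewater = r3 - r2
  )
}

#' Cross-phase Pearson correlation matrix of line means
#'
#' @param metrics Tibble with per-line phase values (e.g. `dt_pre`,
#'   `dt_drought`, `dt_rewater`).
#' @param cols Columns to correlate.
#' @return Tibble of pairwise correlations: `var_x`, `var_y`, `r`, `n`.
#' @export
phase_correlations <- function(metrics,
                               cols = c("dt_pre", "dt_drought", "dt_rewater")) {
  stopifnot(all(cols %in% names(metrics)))
  pairs <- utils::combn(cols, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    x <- metrics[[pairs[1, k]]]; y <- metrics[[pairs[2, k]]]
    ok <- is.finite(x) & is.finite(y)
    tibble::tibble(var_x = pairs[1, k], var_y = pairs[2, k],
                   r = pearson_r(x[ok], y[ok]), n = sum(ok))
  })
}
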