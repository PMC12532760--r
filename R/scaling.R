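# Scaling screening: does the mean of a metric follow a smooth linear or
# power-law function of landscape side length, identically directed
# across classes?  The visual "smoothness" judgement of the original
# workflow is operationalised as an R-squared threshold (default 0.98)
# plus cross-class direction consistency; both are exposed.

#' Mean metric value per landscape extent
#'
#' Averages one metric for one class over all landscapes of each extent.
#' Zero-semantics metrics include their zeros; missing-semantics metrics
#' (LSI) exclude missing records from both numerator and denominator.
#' Extents with no defined value are omitted with a warning.
#'
#' @param records Metric records spanning at least three extents, with
#'   absence rules already applied.
#' @param metric One metric name.
#' @param class One class code.
#' @return Tibble with `side_km`, `mean_value`, `n_landscapes`.
#' @export
mean_metric_by_extent <- function(records, metric, class) {
  sub <- records[records$metric == metric & records$class == class, , drop = FALSE]
  lp_validate(length(unique(sub$extent_km)) >= 3L,
              "need records from at least three extents for ", metric,
              " / class ", class)
  n_extents <- length(unique(sub$extent_km))
  sub <- sub[!sub$missing, , drop = FALSE]
  out <- dplyr::summarise(
    dplyr::group_by(sub, side_km = .data$extent_km),
    mean_value = mean(.data$value), n_landscapes = dplyr::n(), .groups = "drop"
  )
  if (nrow(out) < n_extents) {
    warning("metric ", metric, " / class ", class, ": ",
            n_extents - nrow(out), " extent(s) had no defined value and were omitted")
  }
  dplyr::arrange(out, .data$side_km)
}

r_squared <- function(obs, fitted) {
  sst <- sum((obs - mean(obs))^2)
  if (sst < 1e-300) return(1)          # constant data: any intercept-only fit is exact
  1 - sum((obs - fitted)^2) / sst
}

slope_direction <- function(slope, tol = 1e-12) {
  if (abs(slope) < tol) "flat" else if (slope > 0) "increasing" else "decreasing"
}

#' Fit linear and power-law models of mean metric vs. side length
#'
#' The linear model is least squares of the mean on the side length; the
#' power model is least squares of `log(mean)` on `log(side)` (fitted and
#' scored in log space), with the exponent given by the slope.  The power
#' fit is skipped when any mean is non-positive.
#'
#' @param table Output of [mean_metric_by_extent()] (>= 3 points, distinct
#'   side lengths).
#' @return Tibble with one row per model: `model`, `intercept`
#'   (coefficient `a` in `a + b*L` resp. `a * L^b`), `slope` (slope resp.
#'   exponent `b`), `r2`, `direction`.
#' @export
fit_scaling <- function(table) {
  lp_validate(nrow(table) >= 3L, "need at least three extents to fit scaling")
  L <- table$side_km
  y <- table$mean_value
  lp_validate(length(unique(L)) == length(L) && length(unique(L)) > 1L,
              "degenerate side lengths")
  lin <- lm(y ~ L)
  out <- tibble::tibble(
    model = "linear",
    intercept = unname(coef(lin)[1]),
    slope = unname(coef(lin)[2]),
    r2 = r_squared(y, unname(lin$fitted.values)),
    direction = slope_direction(unname(coef(lin)[2]))
  )
  if (all(y > 0)) {
    pow <- lm(log(y) ~ log(L))
    out <- dplyr::bind_rows(out, tibble::tibble(
      model = "power",
      intercept = exp(unname(coef(pow)[1])),
      slope = unname(coef(pow)[2]),
      r2 = r_squared(log(y), unname(pow$fitted.values)),
      direction = slope_direction(unname(coef(pow)[2]))
    ))
  }
  out
}

#' Classify one metric as scale-predictable or not
#'
#' A metric is predictable iff, for every class, the better of its linear
#' and power fits reaches the R-squared threshold AND the fitted direction
#' of that best model is identical across classes.  Mixed directions
#' (e.g. a metric increasing with extent for one class and decreasing for
#' another) or a weak best fit make it unpredictable, with the failing
#' class and rule named.
#'
#' @param fits Tibble of per-class fits: columns `class`, `model`, `r2`,
#'   `direction` (stack of [fit_scaling()] outputs with a `class` column).
#' @param r2_threshold Minimum best-model R-squared (default 0.98).
#' @return List with `verdict` (`"predictable"`/`"unpredictable"`),
#'   `reason`, and `best` (per-class best model rows).
#' @export
classify_scale_invariant <- function(fits, r2_threshold = 0.98) {
  lp_validate(all(c("class", "model", "r2", "direction") %in% names(fits)),
              "fits needs columns class, model, r2, direction")
  fits <- dplyr::arrange(fits, .data$class, .data$model)  # order-invariant
  best <- dplyr::slice_max(dplyr::group_by(fits, .data$class),
                           order_by = .data$r2, n = 1L, with_ties = FALSE)
  best <- dplyr::ungroup(best)
  weak <- best[best$r2 < r2_threshold, , drop = FALSE]
  if (nrow(weak) > 0) {
    return(list(
      verdict = "unpredictable",
      reason = paste0("class ", weak$class[1], ": best R2 ",
                      signif(weak$r2[1], 4), " < ", r2_threshold),
      best = best
    ))
  }
  if (length(unique(best$direction)) > 1L) {
    return(list(
      verdict = "unpredictable",
      reason = paste0("mixed directions across classes: ",
                      paste(unique(best$direction), collapse = " vs ")),
      best = best
    ))
  }
  list(verdict = "predictable", reason = "all classes fit with one direction",
       best = best)
}

#' Fit scaling for every metric and class in a record set
#'
#' Convenience wrapper: applies [mean_metric_by_extent()] and
#' [fit_scaling()] to every metric/class pair and stacks the results.
#'
#' @param records Metric records spanning >= 3 extents (absence rules
#'   applied).
#' @return Tibble of fits with `metric` and `class` columns.
#' @export
fit_all_scaling <- function(records) {
  combos <- dplyr::distinct(records[, c("metric", "class")])
  out <- lapply(seq_len(nrow(combos)), function(i) {
    tab <- mean_metric_by_extent(records, combos$metric[i], combos$class[i])
    if (nrow(tab) < 3L) return(NULL)
    f <- fit_scaling(tab)
    f$metric <- combos$metric[i]
    f$class <- combos$class[i]
    f
  })
  dplyr::bind_rows(out)
}
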