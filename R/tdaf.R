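#' Time dispersion analysis of features (TDAF)
#'
#' Aggregates per-minute feature values across replicate plants into temporal
#' dispersion summaries: for every minute, the median, first and third
#' quartiles, minimum and maximum across the cohort, in temporal order.
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7, the common default of scientific stacks).
#'
#' @param features A tidy feature table from [epg_features()] (columns
#'   `plant_id`, `treatment`, `phase`, `minute`, `feature`, `value`, `units`).
#' @return An `epg_tdaf` tibble with columns `treatment`, `phase`, `feature`,
#'   `units`, `minute`, `n`, `median`, `q1`, `q3`, `min`, `max`, ordered by
#'   minute within each series.
#' @examples
#' feats <- tibble::tibble(
#'   plant_id = rep(c("p1", "p2", "p3"), 2), treatment = "t",
#'   phase = rep(c("before", "after"), each = 3), minute = 0L,
#'   feature = "abp:low", value = c(1, 2, 3, 2, 4, 6), units = "uV^2"
#' )
#' tdaf_aggregate(feats)
#' @export
tdaf_aggregate <- function(features) {
  required <- c("plant_id", "treatment", "phase", "minute", "feature", "value",
                "units")
  if (!is.data.frame(features) || !all(required %in% names(features))) {
    stop_electrome(sprintf("`features` must contain columns %s",
                           paste(required, collapse = ", ")),
                   "bad_features")
  }
  if (any(!is.finite(features$value))) {
    stop_electrome("feature values must be finite", "bad_features")
  }
  # replicate series within a (treatment, phase, feature) group must align:
  # every minute must carry the same replicate count
  counts <- features |>
    group_by(.data$treatment, .data$phase, .data$feature, .data$minute) |>
    summarise(n = dplyr::n(), .groups = "drop_last") |>
    summarise(k = dplyr::n_distinct(.data$n), .groups = "drop")
  if (any(counts$k > 1L)) {
    stop_electrome(
      "replicate feature series are misaligned: minutes differ in replicate count",
      "mismatched_series")
  }
  out <- features |>
    group_by(.data$treatment, .data$phase, .data$feature, .data$units,
             .data$minute) |>
    summarise(
      n = dplyr::n(),
      median = median(.data$value),
      q1 = quantile(.data$value, 0.25, type = 7, names = FALSE),
      q3 = quantile(.data$value, 0.75, type = 7, names = FALSE),
      min = min(.data$value),
      max = max(.data$value),
      .groups = "drop"
    ) |>
    arrange(.data$treatment, .data$phase, .data$feature, .data$minute)
  class(out) <- c("epg_tdaf", class(out))
  out
}

#' @method tidy epg_tdaf
#' @export
tidy.epg_tdaf <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "epg_tdaf")
  as_tibble(out)
}

#' One-row summary of a TDAF table
#' @param x An `epg_tdaf`.
#' @param ... Unused.
#' @return A one-row tibble with counts of features, treatments, phases,
#'   minutes and replicates.
#' @method glance epg_tdaf
#' @export
glance.epg_tdaf <- function(x, ...) {
  tibble(
    n_features = dplyr::n_distinct(x$feature),
    n_treatments = dplyr::n_distinct(x$treatment),
    n_phases = dplyr::n_distinct(x$phase),
    n_minutes = dplyr::n_distinct(x$minute),
    n_replicates = max(x$n)
  )
}

#' Plot TDAF summaries in the style of minute-by-minute electrome figures
#'
#' One panel per feature: the median line per phase with a shaded min--max
#' range (and optionally the interquartile range), before phase in green and
#' after phase in blue.
#'
#' @param object An `epg_tdaf` table.
#' @param features Optional character vector of features to plot.
#' @param ribbon `"range"` (min--max), `"iqr"`, or `"both"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot epg_tdaf
#' @export
autoplot.epg_tdaf <- function(object, features = NULL,
                              ribbon = c("both", "range", "iqr"), ...) {
  ribbon <- match.arg(ribbon)
  dat <- tidy(object)
  if (!is.null(features)) dat <- dat[dat$feature %in% features, ]
  dat$phase <- factor(dat$phase, levels = c("before", "after"))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$minute, group = .data$phase))
  if (ribbon %in% c("range", "both")) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$min, ymax = .data$max, fill = .data$phase),
      alpha = 0.2)
  }
  if (ribbon %in% c("iqr", "both")) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$q1, ymax = .data$q3, fill = .data$phase),
      alpha = 0.35)
  }
  p +
    ggplot2::geom_line(ggplot2::aes(y = .data$median, colour = .data$phase)) +
    ggplot2::scale_colour_manual(values = c(before = "#2e7d32", after = "#1565c0")) +
    ggplot2::scale_fill_manual(values = c(before = "#2e7d32", after = "#1565c0")) +
    ggplot2::facet_grid(feature ~ treatment, scales = "free_y") +
    ggplot2::labs(x = "minute", y = "feature value")
}

#' @rdname autoplot.epg_tdaf
#' @export
plot_tdaf <- function(object, features = NULL, ribbon = c("both", "range", "iqr"),
                      ...) {
  autoplot(object, features = features, ribbon = ribbon, ...)
}

#' Compare before/after phases of a TDAF table
#'
#' For every (treatment, feature): the pooled phase medians (median of the
#' per-minute medians), their after/before ratio, and an onset estimate -- the
#' first after-phase minute from which the per-minute median strictly exceeds
#' the before phase's pooled upper quartile (median of the per-minute q3) for
#' at least `onset_min_run` consecutive minutes, `NA` if no such run exists.
#' The onset rule is a simple threshold detector, configurable via
#' `onset_min_run`; it is a screening aid, not a changepoint model.
#'
#' @param tdaf An `epg_tdaf` table holding both phases.
#' @param before_label,after_label Phase labels (defaults `"before"`,
#'   `"after"`).
#' @param onset_min_run Minimum run length, in minutes, of supra-threshold
#'   medians (default 5).
#' @return An `epg_phase_comparison` tibble with columns `treatment`,
#'   `feature`, `band`, `median_before`, `median_after`, `after_before_ratio`
#'   and `onset_minute`.
#' @export
compare_phases <- function(tdaf, before_label = "before", after_label = "after",
                           onset_min_run = 5L) {
  if (!inherits(tdaf, "epg_tdaf")) {
    stop_electrome("`tdaf` must be an epg_tdaf table from tdaf_aggregate()",
                   "bad_tdaf")
  }
  check_number(onset_min_run, "onset_min_run", lower = 1)
  dat <- tidy(tdaf)
  groups <- distinct(dat, .data$treatment, .data$feature)
  rows <- pmap(groups, function(treatment, feature) {
    sub <- dat[dat$treatment == treatment & dat$feature == feature, ]
    b <- arrange(sub[sub$phase == before_label, ], .data$minute)
    a <- arrange(sub[sub$phase == after_label, ], .data$minute)
    if (nrow(b) == 0L || nrow(a) == 0L) {
      stop_electrome(sprintf(
        "feature `%s` (%s) lacks minutes in one phase: before n=%d, after n=%d",
        feature, treatment, nrow(b), nrow(a)), "empty_phase")
    }
    median_before <- median(b$median)
    median_after <- median(a$median)
    threshold <- median(b$q3)
    flag <- a$median > threshold
    onset <- NA_integer_
    if (any(flag)) {
      r <- rle(flag)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      hit <- which(r$values & r$lengths >= onset_min_run)
      if (length(hit) > 0L) onset <- as.integer(a$minute[starts[hit[1]]])
    }
    tibble(
      treatment = treatment, feature = feature,
      band = if (startsWith(feature, "abp:")) sub("^abp:", "", feature) else NA_character_,
      median_before = median_before, median_after = median_after,
      after_before_ratio = if (median_before > 0) median_after / median_before else NA_real_,
      onset_minute = onset
    )
  })
  out <- list_rbind(rows)
  attr(out, "onset_min_run") <- as.integer(onset_min_run)
  class(out) <- c("epg_phase_comparison", class(out))
  out
}

#' @method tidy epg_phase_comparison
#' @export
tidy.epg_phase_comparison <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "epg_phase_comparison")
  as_tibble(out)
}

#' One-row summary of a phase comparison
#' @param x An `epg_phase_comparison`.
#' @param ... Unused.
#' @return A one-row tibble: feature/treatment counts, number of detected
#'   onsets, and the onset rule's run length.
#' @method glance epg_phase_comparison
#' @export
glance.epg_phase_comparison <- function(x, ...) {
  tibble(
    n_features = dplyr::n_distinct(x$feature),
    n_treatments = dplyr::n_distinct(x$treatment),
    n_onsets_detected = sum(!is.na(x$onset_minute)),
    onset_min_run = attr(x, "onset_min_run") %||% NA_integer_
  )
}
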