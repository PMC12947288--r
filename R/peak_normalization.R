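#' Renormalize raw LC-MS peak areas to area percent
#'
#' Recalculates peak area percentages from raw areas while omitting every
#' peak that does not come from starting materials or products: injection
#' peaks and peaks from reagents, solvents and internal standards are
#' excluded from the denominator.  Each retained peak's percent is
#' `100 * raw_area / sum(retained raw areas)`, so retained percents sum to
#' 100.  If every retained raw area is zero (or no peak is retained) the
#' table is degenerate: all retained percents are 0.
#'
#' @param peaks data frame with columns `peak_class` (one of product,
#'   starting_material, reagent, solvent, internal_standard, injection,
#'   side_product, unknown) and `raw_area` (>= 0); other columns pass
#'   through.
#' @param retain peak classes kept in the denominator.  Default retains
#'   product, starting material, and side products (integrated side products
#'   belong in the denominator; omitting them is a known error source).
#'   `unknown` peaks are excluded by default.
#' @return list with `peaks` (retained rows plus an `area_pct` column),
#'   `product_pct` (summed percent of product peaks), and `degenerate`
#'   (TRUE when the retained total area is zero).
#' @export
#' @examples
#' tbl <- tibble::tibble(
#'   peak_class = c("product", "starting_material", "internal_standard"),
#'   raw_area = c(30, 50, 20)
#' )
#' normalize_areas(tbl)$product_pct  # 37.5
normalize_areas <- function(peaks, retain = RETAINED_PEAK_CLASSES) {
  peaks <- tibble::as_tibble(peaks)
  stopifnot(all(c("peak_class", "raw_area") %in% names(peaks)),
            nrow(peaks) >= 1)
  if (any(peaks$raw_area < 0, na.rm = TRUE)) {
    stop("raw_area must be >= 0", call. = FALSE)
  }
  bad <- setdiff(unique(peaks$peak_class), ALL_PEAK_CLASSES)
  if (length(bad) > 0) {
    stop("Unknown peak_class: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  kept <- peaks[peaks$peak_class %in% retain, , drop = FALSE]
  total <- sum(kept$raw_area)
  degenerate <- nrow(kept) == 0 || total == 0
  if (degenerate) {
    warning("No retained peak area; normalized percents set to 0", call. = FALSE)
    kept$area_pct <- rep(0, nrow(kept))
  } else {
    kept$area_pct <- 100 * kept$raw_area / total
  }
  list(
    peaks = kept,
    product_pct = sum(kept$area_pct[kept$peak_class == "product"]),
    degenerate = degenerate
  )
}

#' Collapse a reaction's sampling series to its outcome
#'
#' Each reaction is typically sampled at up to three time/temperature points;
#' the maximum normalized product percent across sampling points becomes the
#' reaction's outcome.  Ties at the maximum resolve to the earliest sampling
#' point (deterministic; favors the shorter reaction time).
#'
#' @param product_pcts numeric vector of per-sampling product area percents,
#'   in sampling order.
#' @param sampling_points optional character labels (e.g. "1h/25C") parallel
#'   to `product_pcts`.
#' @return list with `outcome_area_pct`, `argmax` (index of the winning
#'   sampling point), and `sampling_point` (its label, or NA).
#' @export
collapse_samples <- function(product_pcts, sampling_points = NULL) {
  stopifnot(length(product_pcts) >= 1, all(is.finite(product_pcts)))
  i <- which.max(product_pcts)  # first index at ties
  list(
    outcome_area_pct = product_pcts[[i]],
    argmax = i,
    sampling_point = if (is.null(sampling_points)) NA_character_ else sampling_points[[i]]
  )
}

#' Normalize a long-format peak table into per-reaction outcomes
#'
#' Convenience pipeline over [normalize_areas()] and [collapse_samples()]:
#' takes a long table of raw peaks (one row per peak per sampling) and
#' returns one outcome row per reaction.
#'
#' @param peak_table data frame with columns `reaction_id`, `sample_id`,
#'   `peak_class`, `raw_area`, and optionally `time` and `temperature`.
#' @param retain peak classes kept in the denominator; see [normalize_areas()].
#' @return tibble with one row per reaction: `reaction_id`,
#'   `outcome_area_pct`, `n_samples`, `sampling_profile` (label of the
#'   maximal sampling point), and `degenerate`.
#' @export
normalize_peak_table <- function(peak_table, retain = RETAINED_PEAK_CLASSES) {
  pt <- tibble::as_tibble(peak_table)
  stopifnot(all(c("reaction_id", "sample_id", "peak_class", "raw_area") %in% names(pt)))
  label <- if (all(c("time", "temperature") %in% names(pt))) {
    paste0(pt$time, "/", pt$temperature)
  } else {
    as.character(pt$sample_id)
  }
  pt$.label <- label

  per_sample <- pt |>
    dplyr::group_by(.data$reaction_id, .data$sample_id) |>
    dplyr::group_modify(function(df, key) {
      res <- suppressWarnings(normalize_areas(df, retain = retain))
      tibble::tibble(
        product_pct = res$product_pct,
        degenerate = res$degenerate,
        .label = df$.label[1]
      )
    }) |>
    dplyr::ungroup()

  per_sample |>
    dplyr::group_by(.data$reaction_id) |>
    dplyr::summarise(
      outcome_area_pct = collapse_samples(.data$product_pct)$outcome_area_pct,
      n_samples = dplyr::n(),
      sampling_profile = .data$.label[collapse_samples(.data$product_pct)$argmax],
      degenerate = any(.data$degenerate),
      .groups = "drop"
    )
}

#' Plate-inclusion filter
#'
#' A plate (by default, a transformation) is included iff at least one of its
#' reactions reached more than ten area percent normalized product — the
#' comparison is strict, so a maximum of exactly 10.0 is excluded.  Excluded
#' transformations are flagged, never deleted: they stay in storage but
#' contribute nothing to ranking.
#'
#' @param x an `hte_dataset` or records data frame.
#' @param threshold area-percent threshold, default 10.
#' @param by grouping for the filter: `"transformation"` (default) or the
#'   name of a column identifying physical plates (e.g. `"plate_id"`) when a
#'   transformation spans several plates.
#' @return tibble with one row per group: group id, `max_outcome`, and
#'   logical `included`.
#' @export
plate_filter <- function(x, threshold = 10, by = "transformation") {
  rec <- as_hte_records(x)
  group_col <- if (identical(by, "transformation")) "transformation_id" else by
  if (!group_col %in% names(rec)) {
    stop("Grouping column not found: ", group_col, call. = FALSE)
  }
  rec |>
    dplyr::group_by(.data[[group_col]]) |>
    dplyr::summarise(max_outcome = max(.data$outcome_area_pct), .groups = "drop") |>
    dplyr::mutate(included = .data$max_outcome > threshold)
}

# Record-level inclusion flags from plate_filter().
included_records <- function(rec, threshold = 10) {
  inc <- plate_filter(rec, threshold = threshold)
  rec$included <- inc$included[match(rec$transformation_id, inc$transformation_id)]
  rec
}

#' Relative yield from internal-standard ratios
#'
#' Secondary outcome metric: the ratio of product peak area to internal
#' standard area, scaled by the ratio of the actual weights dosed of internal
#' standard and limiting starting material.  Useful for comparing hits within
#' a transformation, but prone to weighing/integration outliers; it never
#' feeds the z-score ranking.
#'
#' @param product_area,internal_standard_area peak areas (>= 0).
#' @param internal_standard_weight,limiting_sm_weight dosed masses (> 0),
#'   same units.
#' @return unitless relative yield; `NA` with a warning when the internal
#'   standard area is zero.
#' @export
relative_yield <- function(product_area, internal_standard_area,
                           internal_standard_weight, limiting_sm_weight) {
  stopifnot(product_area >= 0, internal_standard_area >= 0,
            internal_standard_weight > 0, limiting_sm_weight > 0)
  if (any(internal_standard_area == 0)) {
    warning("Internal standard area is zero; relative yield undefined", call. = FALSE)
  }
  out <- (product_area / internal_standard_area) *
    (internal_standard_weight / limiting_sm_weight)
  out[internal_standard_area == 0] <- NA_real_
  out
}
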