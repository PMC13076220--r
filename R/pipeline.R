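# Per-site, per-group orchestration: metric tables, contrast subsetting,
# and the expansion/partitioning decomposition.

.resolution_levels <- c("taxon", "family", "genus", "species")

.metrics_columns <- c("site_id", "climate_zone", "land_use",
                      "functional_group", "n_samples", "taxon_richness",
                      "group_seac", "mean_taxon_seac", "dissimilarity",
                      "sd13C", "sd15N")

.empty_metrics <- function() {
  tibble::tibble(site_id = character(), climate_zone = character(),
                 land_use = character(), functional_group = character(),
                 n_samples = integer(), taxon_richness = integer(),
                 group_seac = numeric(), mean_taxon_seac = numeric(),
                 dissimilarity = numeric(), sd13C = numeric(),
                 sd15N = numeric())
}

.pooled_seac <- function(x, y) {
  fit <- fit_centroid_covariance(cbind(x, y))
  seac(standard_ellipse_area(fit$cov), fit$n)
}

#' Per-site, per-taxon niche metrics
#'
#' Computes the taxon-level ellipse statistics at one taxonomic resolution:
#' for every site x functional group x taxon (or family/genus/species) with
#' at least `threshold` samples, the corrected ellipse area and isotope
#' standard deviations. Records lacking the requested rank are excluded.
#'
#' @param records Annotated record tibble (must carry `functional_group`).
#' @param threshold Minimum samples per taxon per site; >= 3, default 5.
#' @param level Taxonomic resolution: `"taxon"` (high-rank group, default),
#'   `"family"`, `"genus"` or `"species"`.
#' @return Tibble with one row per qualifying site x group x taxon:
#'   `site_id`, `climate_zone`, `land_use`, `functional_group`, `taxon_unit`,
#'   `n_samples`, `seac`, `sd13C`, `sd15N`.
#' @export
compute_taxon_metrics <- function(records, threshold = 5,
                                  level = c("taxon", "family", "genus",
                                            "species")) {
  level <- match.arg(level)
  unit_col <- if (level == "taxon") "taxon" else level
  recs <- records[!is.na(records[[unit_col]]) &
                    nzchar(records[[unit_col]]), , drop = FALSE]
  if (nrow(recs) == 0)
    return(tibble::tibble(site_id = character(), climate_zone = character(),
                          land_use = character(),
                          functional_group = character(),
                          taxon_unit = character(), n_samples = integer(),
                          seac = numeric(), sd13C = numeric(),
                          sd15N = numeric()))
  recs$taxon_unit <- recs[[unit_col]]
  flt <- min_sample_filter(recs, c("site_id", "functional_group",
                                   "taxon_unit"), threshold)
  out <- flt$retained |>
    dplyr::group_by(.data$site_id, .data$climate_zone, .data$land_use,
                    .data$functional_group, .data$taxon_unit) |>
    dplyr::summarise(n_samples = dplyr::n(),
                     seac = .pooled_seac(.data$d13C, .data$d15N),
                     sd13C = sd(.data$d13C), sd15N = sd(.data$d15N),
                     .groups = "drop") |>
    dplyr::arrange(.data$site_id, .data$functional_group, .data$taxon_unit)
  attr(out, "exclusions") <- flt$excluded
  out
}

#' Per-site, per-functional-group niche metrics
#'
#' The pipeline's central table: for each site x functional group with at
#' least `threshold` pooled samples it reports the group's corrected
#' standard ellipse area (trophic diversity), the unweighted mean of
#' taxon-level SEAc across qualifying taxa (the niche-expansion indicator),
#' the mean pairwise distance between taxon centroids (the
#' niche-partitioning indicator), the isotope standard deviations, and the
#' number of taxa passing the per-taxon filter (`taxon_richness`). Results
#' are invariant to record order.
#'
#' Group-level SEAc pools all individual records of the group at a site.
#' Taxon centroids for the dissimilarity are computed for taxa with at least
#' `centroid_min` samples (default 2), independently of the stricter
#' per-taxon ellipse filter.
#'
#' @inheritParams compute_taxon_metrics
#' @param centroid_min Minimum samples per taxon for its centroid to enter
#'   the dissimilarity; >= 2.
#' @param taxon_threshold Minimum samples per taxon for taxon-level SEAc;
#'   defaults to `threshold`.
#' @return A tibble of site x group rows (see Details); the exclusion report
#'   is attached as `attr(, "exclusions")`.
#' @export
#' @seealso [compute_taxon_metrics()], [decomposition_table()]
compute_site_metrics <- function(records, threshold = 5,
                                 level = c("taxon", "family", "genus",
                                           "species"),
                                 centroid_min = 2,
                                 taxon_threshold = threshold) {
  level <- match.arg(level)
  if (centroid_min < 2)
    stop("centroid_min must be >= 2", call. = FALSE)
  unit_col <- if (level == "taxon") "taxon" else level
  if (nrow(records) == 0) return(.empty_metrics())
  recs <- records[!is.na(records[[unit_col]]) &
                    nzchar(records[[unit_col]]), , drop = FALSE]
  n_rank_dropped <- nrow(records) - nrow(recs)
  if (nrow(recs) == 0) return(.empty_metrics())
  recs$taxon_unit <- recs[[unit_col]]

  flt <- min_sample_filter(recs, c("site_id", "functional_group"), threshold)
  if (nrow(flt$retained) == 0) {
    out <- .empty_metrics()
    attr(out, "exclusions") <- flt$excluded
    return(out)
  }
  grp <- flt$retained |>
    dplyr::group_by(.data$site_id, .data$climate_zone, .data$land_use,
                    .data$functional_group) |>
    dplyr::summarise(n_samples = dplyr::n(),
                     group_seac = .pooled_seac(.data$d13C, .data$d15N),
                     sd13C = sd(.data$d13C), sd15N = sd(.data$d15N),
                     .groups = "drop")

  # taxon-level summaries at the requested resolution
  tax <- recs |>
    dplyr::group_by(.data$site_id, .data$functional_group,
                    .data$taxon_unit) |>
    dplyr::summarise(n_t = dplyr::n(),
                     cx = mean(.data$d13C), cy = mean(.data$d15N),
                     taxon_seac = if (dplyr::n() >= taxon_threshold)
                       .pooled_seac(.data$d13C, .data$d15N)
                     else NA_real_,
                     .groups = "drop")
  agg <- tax |>
    dplyr::group_by(.data$site_id, .data$functional_group) |>
    dplyr::summarise(
      taxon_richness = sum(!is.na(.data$taxon_seac)),
      mean_taxon_seac = if (any(!is.na(.data$taxon_seac)))
        mean(.data$taxon_seac, na.rm = TRUE) else NA_real_,
      dissimilarity = trophic_dissimilarity(
        cbind(.data$cx, .data$cy)[.data$n_t >= centroid_min, , drop = FALSE]),
      .groups = "drop")

  out <- dplyr::left_join(grp, agg,
                          by = c("site_id", "functional_group")) |>
    dplyr::select(dplyr::all_of(.metrics_columns)) |>
    dplyr::arrange(.data$site_id, .data$functional_group)
  attr(out, "exclusions") <- flt$excluded
  attr(out, "n_rank_dropped") <- n_rank_dropped
  out
}

#' Subset a metrics table to the strata used for the main contrasts
#'
#' The headline land-use and climate contrasts are estimated on the
#' temperate/tropical x woodland/agriculture subset, the strata with the
#' most robust sample sizes; all strata are retained at read time and only
#' excluded here.
#'
#' @param metrics A metrics table from [compute_site_metrics()].
#' @param climates Climate zones to keep.
#' @param land_uses Land-use types to keep.
#' @return The filtered table; per-stratum row counts are attached as
#'   `attr(, "stratum_counts")`. An empty result warns (it is not an error).
#' @export
subset_for_contrasts <- function(metrics,
                                 climates = c("temperate", "tropical"),
                                 land_uses = c("woodland", "agriculture")) {
  out <- metrics[metrics$climate_zone %in% climates &
                   metrics$land_use %in% land_uses, , drop = FALSE]
  if (nrow(out) == 0)
    warning("no rows left after stratum subsetting", call. = FALSE)
  attr(out, "stratum_counts") <-
    dplyr::count(out, .data$climate_zone, .data$land_use, name = "n")
  out
}

#' Analysis-ready table for the expansion/partitioning decomposition
#'
#' Pairs the (natural) log of group-level SEAc with the two mechanism
#' indicators: mean taxon-level SEAc (niche expansion) and between-taxon
#' centroid dissimilarity (niche partitioning). Rows with zero group SEAc
#' (degenerate, collinear point clouds) are excluded with a warning rather
#' than offset by an arbitrary constant; rows missing an indicator
#' contribute only to the relation(s) they inform.
#'
#' @param metrics A metrics table from [compute_site_metrics()].
#' @return Tibble with `log_group_seac`, `mean_taxon_seac`, `dissimilarity`
#'   and the identifying columns; counts of dropped rows in
#'   `attr(, "dropped")`. The log base is recorded in `attr(, "log_base")`.
#' @export
decomposition_table <- function(metrics) {
  zero <- !is.na(metrics$group_seac) & metrics$group_seac == 0
  if (any(zero))
    warning(sum(zero), " row(s) with degenerate (zero) group SEAc excluded",
            call. = FALSE)
  usable <- !is.na(metrics$group_seac) & metrics$group_seac > 0
  out <- metrics[usable, , drop = FALSE]
  out$log_group_seac <- log(out$group_seac)
  out <- out[, c("site_id", "climate_zone", "land_use", "functional_group",
                 "log_group_seac", "mean_taxon_seac", "dissimilarity")]
  attr(out, "dropped") <- list(
    zero_seac = sum(zero),
    missing_expansion = sum(is.na(out$mean_taxon_seac)),
    missing_partitioning = sum(is.na(out$dissimilarity)))
  attr(out, "log_base") <- "natural"
  out
}
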