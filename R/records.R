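# Record schema, delta notation, and tabular IO.

.canonical_columns <- c("record_id", "site_id", "climate_zone", "land_use",
                        "taxon", "family", "genus", "species", "d13C", "d15N")
.required_columns <- c("record_id", "site_id", "climate_zone", "land_use",
                       "taxon", "d13C", "d15N")

# plausibility windows (per mil); values outside warn but are retained
.d13C_range <- c(-60, 10)
.d15N_range <- c(-15, 30)

#' Convert isotope ratios to delta notation
#'
#' Delta values express the ratio R of the heavy to the light isotope of a
#' sample relative to an international standard (VPDB for 13C/12C,
#' atmospheric N2 for 15N/14N), in parts per thousand:
#' \eqn{\delta = (R_{sample}/R_{standard} - 1) \times 1000} (per mil).
#'
#' @param r_sample Isotope ratio(s) of the sample; non-negative.
#' @param r_standard Isotope ratio of the standard; strictly positive.
#' @return Delta value(s) in per mil.
#' @export
#' @examples
#' delta_from_ratios(0.0111248, 0.0112372)  # about -10 per mil vs VPDB
delta_from_ratios <- function(r_sample, r_standard) {
  if (!is.numeric(r_sample) || !is.numeric(r_standard))
    stop("isotope ratios must be numeric", call. = FALSE)
  if (any(!is.finite(r_standard)) || any(r_standard <= 0))
    stop("r_standard must be positive and finite", call. = FALSE)
  if (any(is.finite(r_sample) & r_sample < 0))
    stop("r_sample must be non-negative", call. = FALSE)
  (r_sample / r_standard - 1) * 1000
}

#' Read and validate a table of isotope records
#'
#' Reads a delimited table of sample-level paired d13C/d15N measurements,
#' validates it against the record schema, annotates each record with its
#' functional group, and attaches a read report counting rejected rows by
#' reason. Records missing either isotope value are always rejected; values
#' outside the plausibility windows (-60..10 per mil for d13C, -15..30 for
#' d15N) trigger a warning but are retained. `climate_zone` and `land_use`
#' must be members of their enumerations (see [schema_levels()]); grassland
#' and other land uses are retained here and only excluded later by
#' [subset_for_contrasts()].
#'
#' @param path Path to a UTF-8 CSV (or TSV for `.tsv`/`.txt`) file with one
#'   header row.
#' @param map A `group_map` used to annotate functional groups.
#' @param column_aliases Named character vector mapping file column names to
#'   canonical names (e.g. `c(siteID = "site_id", delta13C = "d13C")`).
#' @param strict If `TRUE` (default) a taxon absent from `map` is an error;
#'   if `FALSE` such records are dropped and counted in the report.
#' @return A tibble of validated records (canonical columns plus
#'   `functional_group`), with the report in `attr(, "read_report")`; see
#'   [read_report()].
#' @export
read_records <- function(path, map = default_group_map(),
                         column_aliases = NULL, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  reader <- if (grepl("\\.(tsv|txt)$", path)) readr::read_tsv else readr::read_csv
  raw <- reader(path, col_types = readr::cols(.default = readr::col_character()),
                progress = FALSE)
  if (!is.null(column_aliases)) {
    idx <- match(names(column_aliases), names(raw))
    names(raw)[idx[!is.na(idx)]] <- column_aliases[!is.na(idx)]
  }
  missing_cols <- setdiff(.required_columns, names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (opt in c("family", "genus", "species"))
    if (!opt %in% names(raw)) raw[[opt]] <- NA_character_
  raw <- raw[.canonical_columns]
  raw$d13C <- suppressWarnings(as.numeric(raw$d13C))
  raw$d15N <- suppressWarnings(as.numeric(raw$d15N))
  raw$taxon <- trimws(raw$taxon)

  n_read <- nrow(raw)
  reasons <- rep(NA_character_, n_read)
  bad_iso <- !is.finite(raw$d13C) | !is.finite(raw$d15N)
  reasons[bad_iso] <- "missing isotope value"
  bad_clim <- is.na(reasons) & !(raw$climate_zone %in% climate_levels)
  reasons[bad_clim] <- "invalid climate_zone"
  bad_lu <- is.na(reasons) & !(raw$land_use %in% land_use_levels)
  reasons[bad_lu] <- "invalid land_use"

  key <- tolower(raw$taxon)
  if (length(map$aliases)) {
    idx <- match(key, tolower(names(map$aliases)))
    key[!is.na(idx)] <- tolower(map$aliases[idx[!is.na(idx)]])
  }
  pos <- match(key, tolower(names(map$entries)))
  unmappable <- is.na(reasons) & is.na(pos)
  if (any(unmappable)) {
    if (strict)
      stop("taxon not in functional-group map: ",
           paste(unique(raw$taxon[unmappable]), collapse = ", "),
           call. = FALSE)
    reasons[unmappable] <- "unmappable taxon"
  }

  keep <- is.na(reasons)
  records <- raw[keep, , drop = FALSE]
  records$functional_group <- unname(map$entries[pos[keep]])

  out13 <- records$d13C < .d13C_range[1] | records$d13C > .d13C_range[2]
  out15 <- records$d15N < .d15N_range[1] | records$d15N > .d15N_range[2]
  if (any(out13 | out15))
    warning(sum(out13 | out15),
            " record(s) with isotope values outside the plausibility window",
            call. = FALSE)

  rejections <- tibble::tibble(reason = reasons[!keep])
  rejections <- dplyr::count(rejections, .data$reason, name = "n")
  report <- list(n_read = n_read, n_retained = nrow(records),
                 n_rejected = n_read - nrow(records),
                 rejections = rejections,
                 n_out_of_range = sum(out13 | out15))
  attr(records, "read_report") <- report
  records
}

#' Retrieve the read report attached by read_records
#'
#' @param records A tibble returned by [read_records()].
#' @return A list with `n_read`, `n_retained`, `n_rejected`, a `rejections`
#'   count table, and `n_out_of_range`.
#' @export
read_report <- function(records) {
  rep <- attr(records, "read_report")
  if (is.null(rep)) stop("no read report attached", call. = FALSE)
  rep
}

#' Write isotope records back to CSV
#'
#' Writes the canonical schema columns; the derived `functional_group`
#' annotation is dropped so that a read/write round trip reproduces the
#' retained input fields exactly.
#'
#' @param records A record tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  readr::write_csv(records[intersect(.canonical_columns, names(records))], path,
                   progress = FALSE)
  invisible(path)
}
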