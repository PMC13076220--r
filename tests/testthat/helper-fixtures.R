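# Shared fixtures built in code.

# a small well-formed record table
make_record_table <- function() {
  tibble::tibble(
    record_id = c("r1", "r2", "r3"),
    site_id = c("S1", "S1", "S2"),
    climate_zone = c("temperate", "temperate", "tropical"),
    land_use = c("woodland", "agriculture", "woodland"),
    taxon = c("Collembola", "Araneae", "Lumbricina"),
    family = c("Isotomidae", NA, NA),
    genus = c(NA_character_, NA, NA),
    species = c(NA_character_, NA, NA),
    d13C = c(-25.1, -24.3, -26.7),
    d15N = c(3.2, 6.1, 1.4))
}

write_record_csv <- function(tbl, path = tempfile(fileext = ".csv")) {
  readr::write_csv(tbl, path, progress = FALSE)
  path
}

# records for one site: n samples per taxon around given taxon centroids
make_site_records <- function(centroids, n_per_taxon, sd = 0.5,
                              site_id = "S1", group = "microbivore",
                              taxa = NULL, climate = "temperate",
                              land_use = "woodland") {
  if (is.null(taxa)) taxa <- group_taxa(group)[seq_len(nrow(centroids))]
  rows <- lapply(seq_len(nrow(centroids)), function(i) {
    n <- if (length(n_per_taxon) == 1) n_per_taxon else n_per_taxon[i]
    tibble::tibble(
      record_id = sprintf("%s_%s_%d", site_id, taxa[i], seq_len(n)),
      site_id = site_id, climate_zone = climate, land_use = land_use,
      taxon = taxa[i], family = NA_character_, genus = NA_character_,
      species = NA_character_,
      d13C = rnorm(n, centroids[i, 1], sd),
      d15N = rnorm(n, centroids[i, 2], sd),
      functional_group = group)
  })
  dplyr::bind_rows(rows)
}

# random rotation matrix
rotation2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

# bivariate normal draws with covariance sigma
rmvn2 <- function(n, mu, sigma) {
  z <- matrix(rnorm(2 * n), n, 2)
  sweep(z %*% chol(sigma), 2, mu, "+")
}
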