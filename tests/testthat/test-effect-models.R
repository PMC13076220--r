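# Mixed models, marginal-mean contrasts, covariate and decomposition models.

# deterministic balanced two-factor table: sites x (group, land use), with
# known additive log-scale effects and no noise
make_balanced_metrics <- function(n_sites = 8, noise_sd = 0,
                                  site_effect = NULL, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(site_id = sprintf("S%02d", seq_len(n_sites)),
                      functional_group = c("detritivore", "microbivore"),
                      land_use = c("woodland", "agriculture"),
                      stringsAsFactors = FALSE)
  grid$climate_zone <- "temperate"
  lu_eff <- c(woodland = 0, agriculture = 0.3)
  fg_eff <- c(detritivore = 0, microbivore = 0.5)
  se <- if (is.null(site_effect)) rep(0, n_sites)
        else rnorm(n_sites, 0, site_effect)
  names(se) <- sprintf("S%02d", seq_len(n_sites))
  grid$log_group_seac <- log(2) + lu_eff[grid$land_use] +
    fg_eff[grid$functional_group] + se[grid$site_id] +
    rnorm(nrow(grid), 0, noise_sd)
  grid$group_seac <- exp(grid$log_group_seac)
  tibble::as_tibble(grid)
}

test_that("with zero between-site variance the LMM reduces to OLS", {
  tbl <- make_balanced_metrics(noise_sd = 0.2, seed = 5)
  m <- fit_lmm(tbl, "log_group_seac",
               fixed = c("functional_group", "land_use"))
  ols <- lm(log_group_seac ~ functional_group * land_use,
            data = m$data)
  expect_equal(unname(lme4::fixef(m$fit)), unname(coef(ols)),
               tolerance = 1e-6)
})

test_that("the site random-intercept SD is recovered from simulated data", {
  strata <- tibble::tibble(climate_zone = "temperate",
                           land_use = c("woodland", "agriculture"),
                           n_sites = 100)
  cfg <- community_config(strata, site_sd = 0.5, seed = 42)
  sim <- generate_records(cfg)
  m <- fit_lmm(compute_site_metrics(sim$records), "log_group_seac",
               fixed = c("functional_group", "land_use"))
  vc <- as.data.frame(lme4::VarCorr(m$fit))
  site_sd_hat <- vc$sdcor[vc$grp == "site_id"]
  expect_equal(site_sd_hat, 0.5, tolerance = 0.2)
})

test_that("balanced-grid marginal-mean contrasts equal differences of cell means", {
  tbl <- make_balanced_metrics()
  m <- fit_lmm(tbl, "log_group_seac",
               fixed = c("functional_group", "land_use"))
  ct <- emm_contrast(m, "land_use")
  expect_identical(ct$contrast, "agriculture - woodland")
  expect_equal(ct$estimate, 0.3, tolerance = 1e-8)
  # back-transform contract
  expect_equal(ct$percent, (exp(ct$estimate) - 1) * 100)
  expect_equal(ct$percent_se, exp(ct$estimate) * ct$se * 100)
  expect_true(ct$lo <= ct$estimate && ct$estimate <= ct$hi)
  # per-group conditioning returns one contrast per group
  ctg <- emm_contrast(m, "land_use", by = "functional_group")
  expect_equal(nrow(ctg), 2)
  expect_equal(ctg$estimate, c(0.3, 0.3), tolerance = 1e-8)
})

test_that("a zero log-ratio back-transforms to a zero percent effect", {
  tbl <- make_balanced_metrics()
  tbl$log_group_seac <- log(2)  # no effects at all
  tbl$log_group_seac <- tbl$log_group_seac +
    rep(c(0, 0.5), length.out = nrow(tbl)) * 0  # keep constant
  tbl$log_group_seac[tbl$functional_group == "microbivore"] <- log(3)
  m <- fit_lmm(tbl, "log_group_seac",
               fixed = c("functional_group", "land_use"))
  ct <- emm_contrast(m, "land_use")
  expect_equal(ct$estimate, 0, tolerance = 1e-8)
  expect_equal(ct$percent, 0, tolerance = 1e-6)
})

test_that("a known multiplicative headline effect back-transforms correctly", {
  tbl <- make_balanced_metrics()
  shift <- log(1.321)
  tbl$log_group_seac <- tbl$log_group_seac - 0.3 *
    (tbl$land_use == "agriculture") + shift *
    (tbl$land_use == "agriculture")
  m <- fit_lmm(tbl, "log_group_seac",
               fixed = c("functional_group", "land_use"))
  ct <- emm_contrast(m, "land_use")
  expect_equal(ct$percent, 32.1, tolerance = 1e-6)
})

test_that("degenerate designs are rejected with informative errors", {
  tbl <- make_balanced_metrics(noise_sd = 0.1)
  expect_error(fit_lmm(tbl, "log_group_seac",
                       fixed = c("functional_group", "climate_zone")),
               "fewer than 2")
  tbl$n_samples <- 30  # constant covariate is aliased with the intercept
  expect_error(covariate_model(tbl, covariates = "n_samples",
                               fixed = c("functional_group", "land_use")),
               "aliased")
  expect_error(emm_contrast(fit_lmm(tbl, "log_group_seac",
                                    fixed = c("functional_group",
                                              "land_use")),
                            "climate_zone"),
               "not in the model")
})

test_that("rows with undefined (zero/missing) metrics are dropped and counted", {
  tbl <- make_balanced_metrics(noise_sd = 0.1)
  tbl$group_seac[1] <- 0
  tbl$group_seac[2] <- NA
  tbl$log_group_seac <- NULL
  m <- fit_lmm(tbl, "log_group_seac",
               fixed = c("functional_group", "land_use"))
  expect_equal(m$n_dropped, 2)
  expect_equal(nrow(m$data), nrow(tbl) - 2)
})

test_that("covariate model recovers a built-in richness effect and keeps the stratum effect", {
  set.seed(9)
  n_sites <- 120
  site_lu <- sample(c("woodland", "agriculture"), n_sites, replace = TRUE)
  site_cl <- sample(c("temperate", "tropical"), n_sites, replace = TRUE)
  tbl <- tibble::tibble(
    site_id = rep(sprintf("S%03d", 1:n_sites), each = 2),
    functional_group = rep(c("detritivore", "microbivore"), n_sites),
    land_use = rep(site_lu, each = 2),
    climate_zone = rep(site_cl, each = 2),
    taxon_richness = sample(2:8, 2 * n_sites, replace = TRUE),
    n_samples = sample(10:60, 2 * n_sites, replace = TRUE))
  site_eff <- rnorm(n_sites, 0, 0.2)
  tbl$log_group_seac <- 0.5 + 0.15 * tbl$taxon_richness +
    0.3 * (tbl$climate_zone == "tropical") +
    site_eff[as.integer(factor(tbl$site_id))] + rnorm(2 * n_sites, 0, 0.2)
  cm <- covariate_model(tbl, fixed = c("functional_group", "land_use",
                                       "climate_zone"),
                        covariates = c("n_samples", "taxon_richness"))
  rich <- cm$coefficients[cm$coefficients$term == "taxon_richness", ]
  expect_gt(rich$lo, 0)
  expect_lt(abs(rich$estimate - 0.15), 0.05)
  clim <- emm_contrast(cm$model, "climate_zone")
  expect_gt(clim$lo, 0)
  expect_equal(clim$estimate, 0.3, tolerance = 0.15)
})

test_that("decomposition models separate expansion-only from partitioning-only variation", {
  lib_e <- community_config(
    tibble::tibble(climate_zone = "temperate", land_use = "woodland",
                   n_sites = 60),
    site_sd = 0, site_expansion_sd = 0.6, seed = 21)
  d_e <- decomposition_table(
    compute_site_metrics(generate_records(lib_e)$records))
  dm_e <- decomposition_models(d_e)
  exp_slope <- dm_e$expansion$slopes[dm_e$expansion$slopes$group ==
                                       "pooled", ]
  expect_gt(exp_slope$lo, 0)

  lib_p <- community_config(
    tibble::tibble(climate_zone = "temperate", land_use = "woodland",
                   n_sites = 60),
    site_sd = 0, site_partitioning_sd = 0.6, seed = 22)
  d_p <- decomposition_table(
    compute_site_metrics(generate_records(lib_p)$records))
  dm_p <- decomposition_models(d_p)
  part_slope <- dm_p$partitioning$slopes[dm_p$partitioning$slopes$group ==
                                           "pooled", ]
  expect_gt(part_slope$lo, 0)
  expect_true(all(c("r2_marginal", "r2_conditional") %in%
                    names(dm_p$partitioning$r2)))
})

test_that("constant trophic diversity yields zero decomposition slopes", {
  tbl <- tibble::tibble(
    site_id = rep(sprintf("S%02d", 1:10), each = 2),
    functional_group = rep(c("detritivore", "microbivore"), 10),
    climate_zone = "temperate", land_use = "woodland",
    log_group_seac = log(2),
    mean_taxon_seac = runif(20, 1, 3),
    dissimilarity = runif(20, 0.5, 2))
  dm <- decomposition_models(tbl)
  expect_equal(dm$expansion$slopes$slope[1], 0, tolerance = 1e-8)
  expect_equal(dm$partitioning$slopes$slope[1], 0, tolerance = 1e-8)
})
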