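# Mixed-effects layer: LMMs on log niche metrics, marginal-mean contrasts
# back-transformed to percent effects, covariate models, and the
# decomposition relationship models.

.response_base <- c(log_group_seac = "group_seac",
                    log_taxon_seac = "seac",
                    log_dissimilarity = "dissimilarity")

.canonical_factor_levels <- list(
  functional_group = c("herbivore", "detritivore", "microbivore",
                       "predator", "mixed"),
  land_use = c("woodland", "agriculture", "grassland", "other"),
  climate_zone = c("subarctic", "temperate", "subtropical", "tropical"))

.prepare_factors <- function(data, factors) {
  for (f in factors) {
    lev <- .canonical_factor_levels[[f]]
    data[[f]] <- if (is.null(lev)) factor(data[[f]])
                 else factor(data[[f]], levels = intersect(lev,
                                                           unique(data[[f]])))
    data[[f]] <- droplevels(data[[f]])
    if (nlevels(data[[f]]) < 2)
      stop("factor '", f, "' has fewer than 2 observed levels",
           call. = FALSE)
  }
  data
}

.check_full_rank <- function(formula, data) {
  mm <- model.matrix(formula, data)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("singular fixed-effect design; aliased term(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Fit a random-intercept mixed model on a log niche metric
#'
#' Fits (by REML, via lme4) a linear mixed model with the natural log of a
#' niche metric as response, a site random intercept to absorb the
#' non-independence of multiple functional groups measured at the same
#' site, and optionally a taxon-identity random intercept nested within
#' functional group (for taxon-level responses). Rows with a non-finite
#' response (including zero or missing metrics, whose log is undefined) are
#' excluded and counted. A rank-deficient fixed-effect design is an error
#' naming the aliased terms.
#'
#' @param data A metrics table ([compute_site_metrics()],
#'   [compute_taxon_metrics()] or [decomposition_table()]).
#' @param response One of `"log_group_seac"`, `"log_taxon_seac"`,
#'   `"log_dissimilarity"`. The log is taken here from the corresponding
#'   raw column (`group_seac`, `seac`, `dissimilarity`) unless the log
#'   column is already present.
#' @param fixed Character vector of fixed-effect factors; each must have at
#'   least two observed levels.
#' @param interactions If `TRUE` (default) all interactions among `fixed`
#'   are included.
#' @param covariates Optional character vector of numeric covariate columns.
#' @param taxon_random If `TRUE`, adds a taxon-within-functional-group
#'   random intercept (requires a `taxon_unit` column).
#' @return An object of class `isoniche_lmm`: a list with the `lme4` fit
#'   (`$fit`), the model `$formula`, the analysis `$data`, and
#'   `$n_dropped`.
#' @export
fit_lmm <- function(data, response = "log_group_seac",
                    fixed = c("functional_group", "land_use",
                              "climate_zone"),
                    interactions = TRUE, covariates = NULL,
                    taxon_random = FALSE) {
  response <- match.arg(response, names(.response_base))
  if (!response %in% names(data)) {
    base_col <- .response_base[[response]]
    if (!base_col %in% names(data))
      stop("neither '", response, "' nor '", base_col,
           "' found in the data", call. = FALSE)
    data[[response]] <- ifelse(is.finite(data[[base_col]]) &
                                 data[[base_col]] > 0,
                               log(data[[base_col]]), NA_real_)
  }
  usable <- is.finite(data[[response]])
  if (!is.null(covariates))
    for (cv in covariates) usable <- usable & is.finite(data[[cv]])
  n_dropped <- sum(!usable)
  data <- data[usable, , drop = FALSE]
  if (length(unique(data$site_id)) < 2)
    stop("at least 2 sites are required", call. = FALSE)
  data <- .prepare_factors(data, fixed)

  fixed_rhs <- paste(fixed, collapse = if (interactions) " * " else " + ")
  if (!is.null(covariates))
    fixed_rhs <- paste(c(fixed_rhs, covariates), collapse = " + ")
  .check_full_rank(as.formula(paste("~", fixed_rhs)), data)

  ran <- "(1 | site_id)"
  if (taxon_random) {
    if (!"taxon_unit" %in% names(data))
      stop("taxon_random = TRUE requires a 'taxon_unit' column",
           call. = FALSE)
    ran <- paste(ran, "+ (1 | functional_group:taxon_unit)")
  }
  form <- as.formula(paste(response, "~", fixed_rhs, "+", ran))
  # boundary (zero-variance) fits are legitimate here; silence the message
  fit <- suppressMessages(
    lme4::lmer(form, data = data, REML = TRUE,
               control = lme4::lmerControl(calc.derivs = FALSE)))
  structure(list(fit = fit, formula = form, response = response,
                 fixed = fixed, data = data, n_dropped = n_dropped),
            class = "isoniche_lmm")
}

#' @export
print.isoniche_lmm <- function(x, ...) {
  cat("<isoniche_lmm> ", deparse(x$formula), "\n", sep = "")
  cat("  n = ", nrow(x$data), " rows (", x$n_dropped, " dropped), ",
      length(unique(x$data$site_id)), " sites\n", sep = "")
  vc <- as.data.frame(lme4::VarCorr(x$fit))
  cat("  random-effect SDs: ",
      paste(sprintf("%s = %.3f", vc$grp, vc$sdcor), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Marginal-mean contrasts back-transformed to percent effects
#'
#' Estimated marginal means are model predictions averaged over a balanced
#' grid of the remaining factors (equal weight per cell); contrasts between
#' the levels of `factor` are formed on the log scale (later minus earlier
#' enumeration level, e.g. agriculture minus woodland, tropical minus
#' temperate) with normal-approximation 95% confidence intervals, and
#' back-transformed to multiplicative percent effects:
#' \eqn{100(e^{\hat\beta} - 1)}, with delta-method standard error
#' \eqn{100\, e^{\hat\beta}\, SE}.
#'
#' @param object An `isoniche_lmm` fit.
#' @param factor Factor to contrast, e.g. `"land_use"` or `"climate_zone"`.
#' @param by Optional conditioning factor (e.g. `"functional_group"` for
#'   per-group effect sizes).
#' @param weights Cell weighting for the marginal means: `"equal"`
#'   (default) or `"proportional"`.
#' @return A tibble of class `effect_estimate` with `contrast`, the `by`
#'   column if any, `estimate` (log-response ratio), `se`, `lo`, `hi`
#'   (95% CI) and `percent`, `percent_se`.
#' @export
emm_contrast <- function(object, factor, by = NULL,
                         weights = c("equal", "proportional")) {
  stopifnot(inherits(object, "isoniche_lmm"))
  weights <- match.arg(weights)
  if (!factor %in% object$fixed)
    stop("factor '", factor, "' is not in the model", call. = FALSE)
  emm <- suppressMessages(
    emmeans::emmeans(object$fit, specs = factor, by = by,
                     data = object$data, lmer.df = "asymptotic",
                     weights = if (weights == "equal") "equal"
                               else "proportional"))
  ctr <- summary(emmeans::contrast(emm, method = "revpairwise"),
                 infer = FALSE)
  out <- tibble::tibble(contrast = as.character(ctr$contrast))
  if (!is.null(by)) out[[by]] <- as.character(ctr[[by]])
  out$estimate <- ctr$estimate
  out$se <- ctr$SE
  z <- qnorm(0.975)
  out$lo <- out$estimate - z * out$se
  out$hi <- out$estimate + z * out$se
  out$percent <- (exp(out$estimate) - 1) * 100
  out$percent_se <- exp(out$estimate) * out$se * 100
  class(out) <- c("effect_estimate", class(out))
  out
}

#' Covariate-adjusted model of log group SEAc
#'
#' Refits the main model with sampling number and taxon richness (a family
#' richness analogue at other resolutions) as numeric covariates, to check
#' whether stratum effects persist after adjustment for sampling effort and
#' richness.
#'
#' @inheritParams fit_lmm
#' @param covariates Covariate columns; default `c("n_samples",
#'   "taxon_richness")`.
#' @return A list with the `isoniche_lmm` (`$model`) and a tidy coefficient
#'   report (`$coefficients`: term, estimate, se, z, lo, hi).
#' @export
covariate_model <- function(data, response = "log_group_seac",
                            fixed = c("functional_group", "land_use",
                                      "climate_zone"),
                            covariates = c("n_samples", "taxon_richness"),
                            interactions = FALSE) {
  m <- fit_lmm(data, response = response, fixed = fixed,
               interactions = interactions, covariates = covariates)
  fe <- lme4::fixef(m$fit)
  se <- sqrt(diag(as.matrix(vcov(m$fit))))
  z <- qnorm(0.975)
  coefs <- tibble::tibble(term = names(fe), estimate = unname(fe),
                          se = unname(se),
                          zvalue = unname(fe / se),
                          lo = unname(fe - z * se),
                          hi = unname(fe + z * se))
  list(model = m, coefficients = coefs)
}

# Nakagawa-style variance explained for a lmer fit
.r2_lmm <- function(fit) {
  var_f <- var(as.vector(model.matrix(fit) %*% lme4::fixef(fit)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_re <- sum(vc$vcov[vc$grp != "Residual"])
  var_res <- vc$vcov[vc$grp == "Residual"]
  tot <- var_f + var_re + var_res
  c(r2_marginal = var_f / tot, r2_conditional = (var_f + var_re) / tot)
}

.slope_fit <- function(data, predictor) {
  keep <- is.finite(data[[predictor]]) & is.finite(data$log_group_seac)
  d <- data[keep, , drop = FALSE]
  if (nrow(d) < 3) stop("too few rows for the ", predictor, " relation",
                        call. = FALSE)
  form <- as.formula(paste("log_group_seac ~", predictor, "+ (1 | site_id)"))
  # a constant response (zero total variance) degenerates the mixed fit;
  # plain least squares then gives the exact zero slope directly
  fit <- if (var(d$log_group_seac) == 0)
    lm(as.formula(paste("log_group_seac ~", predictor)), data = d)
  else tryCatch(
    suppressMessages(
      lme4::lmer(form, data = d, REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE))),
    error = function(e) lm(as.formula(paste("log_group_seac ~", predictor)),
                           data = d))
  is_lmm <- inherits(fit, "merMod")
  b <- if (is_lmm) lme4::fixef(fit) else coef(fit)
  V <- suppressWarnings(as.matrix(vcov(fit)))
  z <- qnorm(0.975)
  slope <- unname(b[predictor])
  se <- sqrt(V[predictor, predictor])
  slopes <- tibble::tibble(group = "pooled", slope = slope, se = se,
                           lo = slope - z * se, hi = slope + z * se)
  # per-group slopes when several functional groups are present
  if ("functional_group" %in% names(d) &&
      length(unique(d$functional_group)) >= 2) {
    d$functional_group <- factor(d$functional_group)
    iform <- as.formula(paste("log_group_seac ~ functional_group *",
                              predictor, "+ (1 | site_id)"))
    ifit <- tryCatch(
      suppressMessages(
        lme4::lmer(iform, data = d, REML = TRUE,
                   control = lme4::lmerControl(calc.derivs = FALSE))),
      error = function(e) NULL)
    if (!is.null(ifit)) {
      tr <- summary(emmeans::emtrends(ifit, "functional_group",
                                      var = predictor, data = d,
                                      lmer.df = "asymptotic"))
      sl <- tr[[paste0(predictor, ".trend")]]
      slopes <- dplyr::bind_rows(slopes, tibble::tibble(
        group = as.character(tr$functional_group), slope = sl, se = tr$SE,
        lo = sl - z * tr$SE, hi = sl + z * tr$SE))
    }
  }
  r2 <- if (is_lmm) .r2_lmm(fit)
        else {
          rsq <- suppressWarnings(summary(fit)$r.squared)
          c(r2_marginal = rsq, r2_conditional = rsq)
        }
  list(fit = fit, slopes = slopes, r2 = r2, n = nrow(d))
}

#' Relationship models decomposing group trophic diversity
#'
#' Fits the two relations that separate the routes to high functional-group
#' trophic diversity: log group SEAc against mean taxon SEAc (niche
#' expansion) and against between-taxon centroid dissimilarity (niche
#' partitioning), each with a site random intercept, reporting pooled and
#' per-functional-group slopes with 95% CIs and marginal/conditional
#' variance explained.
#'
#' @param decomp A table from [decomposition_table()].
#' @return A list with elements `expansion` and `partitioning`, each
#'   holding `fit`, `slopes`, `r2` and `n`.
#' @export
decomposition_models <- function(decomp) {
  list(expansion = .slope_fit(decomp, "mean_taxon_seac"),
       partitioning = .slope_fit(decomp, "dissimilarity"))
}
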