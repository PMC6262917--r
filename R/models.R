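#' Fit the paired habitat-comparison mixed model
#'
#' Fits the per-site diversity response against habitat (broadleaf as the
#' reference level, a plantation indicator as the single fixed effect) with
#' random intercepts for the site pair nested in year and the site pair
#' nested in month. Integer-valued naive richness uses a Poisson GLMM (log
#' link, Laplace approximation); constrained effective numbers use a
#' Gaussian LMM fitted by REML.
#'
#' The repeated unit of the paired design is the site pair, so "site nested
#' in year / month" is encoded as pair-within-year and pair-within-month
#' random intercepts (`nesting = "pair"`). `nesting = "site"` instead uses
#' the individual site identifier, and `nesting = "none"` drops the random
#' terms entirely (plain (G)LM), which is useful for checks against ordinary
#' least squares.
#'
#' @param data data frame with columns `response`, `habitat`, `pair_id`,
#'   `year`, `month` (one row per site).
#' @param family `"gaussian"` or `"poisson"`; Poisson requires integer
#'   responses.
#' @param nesting `"pair"` (default), `"site"` (requires a `site_id`
#'   column) or `"none"`.
#' @param response_label stored label for reporting (e.g. "naive q=0").
#' @return object of class `diversity_model_fit`: a list with elements
#'   `coefficients` (data frame: term, estimate, se, t), `family`,
#'   `variance_components`, `residual_variance`, `marginal_r2`,
#'   `conditional_r2`, `singular`, `response_label`, and the underlying
#'   `model`.
#' @export
fit_diversity_model <- function(data, family = c("gaussian", "poisson"),
                                nesting = c("pair", "site", "none"),
                                response_label = "") {
  family <- match.arg(family)
  nesting <- match.arg(nesting)
  need <- c("response", "habitat", "pair_id", "year", "month")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("model data missing column(s): ", paste(missing_cols, collapse = ", "))
  y <- data$response
  if (anyNA(y)) stop("missing response values")
  if (family == "poisson" && any(y != round(y)))
    stop("poisson family requires integer responses; ",
         "use gaussian for effective numbers")
  d <- data
  d$habitat <- factor(as.character(d$habitat), levels = HABITATS)
  d$pair_id <- factor(d$pair_id)
  d$year <- factor(d$year)
  d$month <- factor(d$month)
  unit <- switch(nesting, pair = "pair_id", site = "site_id", none = NULL)
  if (identical(unit, "site_id")) {
    if (!"site_id" %in% names(d)) stop("nesting = 'site' requires a site_id column")
    d$site_id <- factor(d$site_id)
  }

  tiny <- (1e-8 * (max(abs(y)) + 1))^2
  if (family == "gaussian" && stats::var(y) <= tiny) {
    # constant response: no information about a habitat effect
    coefs <- data.frame(term = c("intercept", "plantation"),
                        estimate = c(mean(y), 0), se = c(0, 0),
                        t = c(NA_real_, NA_real_))
    out <- list(coefficients = coefs, family = family, nesting = nesting,
                variance_components = numeric(0), residual_variance = 0,
                fixed_variance = 0, marginal_r2 = NA_real_,
                conditional_r2 = NA_real_, singular = TRUE,
                response_label = response_label, model = NULL)
    class(out) <- "diversity_model_fit"
    return(out)
  }

  if (is.null(unit)) {
    fit <- if (family == "poisson")
      stats::glm(response ~ habitat, data = d, family = stats::poisson())
    else stats::lm(response ~ habitat, data = d)
    sm <- summary(fit)$coefficients
    coefs <- data.frame(term = c("intercept", "plantation"),
                        estimate = sm[, 1], se = sm[, 2], t = sm[, 1] / sm[, 2])
    rownames(coefs) <- NULL
    vc <- numeric(0)
    resid_var <- if (family == "gaussian") summary(fit)$sigma^2
      else log1p(1 / exp(sm[1, 1]))
    singular <- FALSE
  } else {
    form <- stats::as.formula(paste0(
      "response ~ habitat + (1 | year:", unit, ") + (1 | month:", unit, ")"))
    # convergence-gradient checks throw spurious warnings on the
    # near-degenerate responses this design produces; singularity is
    # reported through the `singular` flag instead
    fit <- if (family == "poisson")
      lme4::glmer(form, data = d, family = stats::poisson(),
                  control = lme4::glmerControl(
                    check.conv.singular = "ignore",
                    check.conv.grad = "ignore", check.conv.hess = "ignore"))
    else
      lme4::lmer(form, data = d, REML = TRUE,
                 control = lme4::lmerControl(
                   check.conv.singular = "ignore",
                   check.conv.grad = "ignore", check.conv.hess = "ignore"))
    b <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    coefs <- data.frame(term = c("intercept", "plantation"),
                        estimate = as.numeric(b), se = as.numeric(se),
                        t = as.numeric(b) / as.numeric(se))
    vc_tab <- as.data.frame(lme4::VarCorr(fit))
    ran <- vc_tab[vc_tab$grp != "Residual", , drop = FALSE]
    vc <- stats::setNames(ran$vcov, ran$grp)
    resid_var <- if (family == "gaussian")
      vc_tab$vcov[vc_tab$grp == "Residual"]
    else log1p(1 / exp(as.numeric(b[1])))  # log-normal approximation
    singular <- lme4::isSingular(fit)
  }

  # fixed-effect variance on the link scale: variance of the linear predictor
  X <- stats::model.matrix(~habitat, d)
  eta <- as.vector(X %*% coefs$estimate)
  var_fixed <- stats::var(eta) * (length(eta) - 1) / length(eta)
  denom <- var_fixed + sum(vc) + resid_var
  out <- list(
    coefficients = coefs, family = family, nesting = nesting,
    variance_components = vc, residual_variance = resid_var,
    fixed_variance = var_fixed,
    marginal_r2 = if (denom > 0) var_fixed / denom else NA_real_,
    conditional_r2 = if (denom > 0) (var_fixed + sum(vc)) / denom else NA_real_,
    singular = singular, response_label = response_label, model = fit)
  class(out) <- "diversity_model_fit"
  out
}

#' Marginal and conditional R-squared of a fitted habitat model
#'
#' Variance-components decomposition on the link scale: marginal
#' `= var_fixed / (var_fixed + sum(var_random) + var_residual)` and
#' conditional `= (var_fixed + sum(var_random))` over the same denominator.
#' For the Poisson GLMM the distribution-specific residual variance is the
#' log-normal approximation `log(1 + 1/lambda)` with `lambda` the
#' exponentiated fitted intercept.
#'
#' @param fit a `diversity_model_fit`.
#' @return named numeric vector `c(marginal, conditional)`.
#' @export
nakagawa_r2 <- function(fit) {
  stopifnot(inherits(fit, "diversity_model_fit"))
  denom <- fit$fixed_variance + sum(fit$variance_components) +
    fit$residual_variance
  if (!is.finite(denom) || denom <= 0)
    stop("zero total variance: R2 undefined")
  c(marginal = fit$marginal_r2, conditional = fit$conditional_r2)
}

#' Significance by the standard-error rule
#'
#' An effect is flagged "significant" when the interval estimate +/- 1 SE
#' excludes zero, i.e. `|estimate| > se`. This is the liberal rule used for
#' the habitat-comparison tables; it is not a conventional 95% test (under a
#' true null it fires roughly a third of the time).
#'
#' @param fit a `diversity_model_fit`, or a data frame with `estimate` and
#'   `se` columns.
#' @return logical vector, one flag per coefficient.
#' @export
significance_by_se <- function(fit) {
  coefs <- if (inherits(fit, "diversity_model_fit")) fit$coefficients else fit
  # an interval that exactly touches zero does not exclude it; the relative
  # tolerance keeps the boundary case off float noise
  abs(coefs$estimate) > coefs$se * (1 + 1e-9)
}

#' @export
print.diversity_model_fit <- function(x, ...) {
  cat("Habitat-comparison mixed model (", x$family, ")",
      if (nzchar(x$response_label)) paste0(" - ", x$response_label), "\n",
      sep = "")
  co <- x$coefficients
  co$significant <- significance_by_se(x)
  print(co, row.names = FALSE, digits = 3)
  cat(sprintf("marginal R2 = %.3f, conditional R2 = %.3f%s\n",
              x$marginal_r2, x$conditional_r2,
              if (isTRUE(x$singular)) " (singular fit)" else ""))
  invisible(x)
}

#' Fit the full habitat-comparison table
#'
#' Fits one model per constraint x order combination of a per-site
#' diversity table (Poisson for naive richness at `q = 0`, Gaussian
#' otherwise) plus one Gaussian model per constraint for redundancy, and
#' assembles the coefficient/R-squared summary.
#'
#' @param div long per-site diversity table from [site_diversity()].
#' @param red per-site redundancy table from [site_redundancy()]; `NULL` to
#'   skip the redundancy rows.
#' @param meta abundance metadata (site_id, pair_id, habitat, year, month).
#' @return data frame, one row per fitted model: `measure`, `constraint`,
#'   `q`, `family`, `intercept`, `intercept_se`, `plantation`,
#'   `plantation_se`, `t`, `marginal_r2`, `conditional_r2`, `significant`,
#'   `singular`.
#' @export
habitat_model_table <- function(div, red = NULL, meta) {
  rows <- list()
  fit_one <- function(vals, sites, fam, measure, cn, q) {
    md <- meta[match(sites, meta$site_id), ]
    md$response <- vals
    f <- fit_diversity_model(md, family = fam,
                             response_label = paste(measure, cn, "q =", q))
    co <- f$coefficients
    data.frame(measure = measure, constraint = cn, q = q, family = fam,
               intercept = co$estimate[1], intercept_se = co$se[1],
               plantation = co$estimate[2], plantation_se = co$se[2],
               t = co$t[2], marginal_r2 = f$marginal_r2,
               conditional_r2 = f$conditional_r2,
               significant = significance_by_se(f)[2],
               singular = f$singular)
  }
  for (cn in unique(div$constraint)) {
    for (qq in sort(unique(div$q))) {
      sub <- div[div$constraint == cn & div$q == qq, ]
      fam <- if (cn == "naive" && qq == 0 &&
                 all(sub$effective_number == round(sub$effective_number)))
        "poisson" else "gaussian"
      rows[[length(rows) + 1L]] <-
        fit_one(sub$effective_number, sub$site_id, fam, "diversity", cn, qq)
    }
  }
  if (!is.null(red)) {
    for (cn in unique(red$constraint)) {
      sub <- red[red$constraint == cn, ]
      rows[[length(rows) + 1L]] <-
        fit_one(sub$redundancy, sub$site_id, "gaussian", "redundancy", cn, 0)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
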