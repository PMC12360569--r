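#' Build case-level covariates for predictor modelling
#'
#' Constructs the binary design columns used to model predictors of a
#' target event among exposed cases: `male` (sex), `older` (decade age
#' class, see [assign_age_class()]), and one 0/1 flag per comorbidity term
#' set matched against the history table. Cases with unknown sex or age are
#' flagged `complete = FALSE` and are dropped by [fit_logistic()]
#' (complete-case analysis).
#'
#' @param reports A [case_data] object (typically already filtered to the
#'   exposed subpopulation of interest).
#' @param comorbidity_sets Named list of [term_set]s; names become column
#'   names.
#' @return A tibble with one row per case: `case_id`, `male`, `older`, the
#'   comorbidity flags, and `complete`.
#' @export
build_covariates <- function(reports, comorbidity_sets) {
  stopifnot(inherits(reports, "case_data"))
  demo <- reports$demo
  age_class <- assign_age_class(demo$age_group)
  out <- tibble(
    case_id = demo$case_id,
    male = as.integer(demo$sex == "male"),
    older = as.integer(age_class == "older")
  )
  for (nm in names(comorbidity_sets)) {
    pts <- term_set_terms(comorbidity_sets[[nm]])
    hit <- unique(reports$hist$case_id[reports$hist$pt_term %in% pts])
    out[[nm]] <- as.integer(out$case_id %in% hit)
  }
  out$complete <- demo$sex != "unknown" & age_class != "unknown"
  out
}

#' Drop degenerate covariates before model fitting
#'
#' Removes covariates that carry no information for a logistic fit: zero
#' variance overall, or no variation within either response class (e.g. a
#' comorbidity observed in no event case). Mirrors the "N.A." convention of
#' published predictor tables, where such covariates are reported as not
#' applicable rather than fitted.
#'
#' @param design Data frame / tibble of numeric covariates (no id column).
#' @param response Logical or 0/1 vector, same length as `nrow(design)`.
#' @return A list: `design` (reduced tibble) and `excluded` (tibble of
#'   `covariate`, `reason`). Errors if every covariate is degenerate.
#' @export
exclude_degenerate <- function(design, response) {
  design <- as_tibble(design)
  response <- as.logical(response)
  stopifnot(nrow(design) == length(response))
  excluded <- tibble(covariate = character(), reason = character())
  keep <- character()
  for (nm in names(design)) {
    x <- design[[nm]]
    if (length(unique(x)) < 2) {
      excluded <- bind_rows(excluded,
        tibble(covariate = nm, reason = "zero variance"))
    } else if (length(unique(x[response])) < 2) {
      excluded <- bind_rows(excluded,
        tibble(covariate = nm, reason = "no variation among event cases"))
    } else if (length(unique(x[!response])) < 2) {
      excluded <- bind_rows(excluded,
        tibble(covariate = nm, reason = "no variation among non-event cases"))
    } else {
      keep <- c(keep, nm)
    }
  }
  if (!length(keep)) abort("all covariates are degenerate; model not fit")
  list(design = design[keep], excluded = excluded)
}

#' Multivariable logistic regression with Wald inference
#'
#' Maximum-likelihood logistic regression (via iteratively reweighted least
#' squares) of a binary response on the covariate matrix, after dropping
#' degenerate covariates with [exclude_degenerate()] and restricting to
#' complete cases. Reports per-covariate odds ratios with two-sided Wald
#' 95% intervals and p-values. Non-convergence and (quasi-)separation are
#' flagged, never silently returned as estimates.
#'
#' @param design Tibble of 0/1 covariates, optionally with `case_id` and
#'   `complete` columns from [build_covariates()] (handled automatically).
#' @param response Logical / 0-1 vector aligned with `design` rows.
#' @return An object of class `pv_logistic`: list with `tidy`-able fit,
#'   `excluded` covariates, `converged`, `separation`, `n` used.
#' @export
#' @examples
#' set.seed(1)
#' x <- rbinom(500, 1, 0.4)
#' y <- rbinom(500, 1, plogis(-1 + 0.8 * x))
#' fit <- fit_logistic(tibble::tibble(x = x), y)
#' generics::tidy(fit)
fit_logistic <- function(design, response) {
  design <- as_tibble(design)
  response <- as.logical(response)
  stopifnot(nrow(design) == length(response))
  if ("complete" %in% names(design)) {
    keep <- design$complete
    design <- design[keep, setdiff(names(design), "complete")]
    response <- response[keep]
  }
  design$case_id <- NULL
  if (length(unique(response)) < 2) {
    abort("response is constant; model not estimable")
  }
  red <- exclude_degenerate(design, response)
  dat <- dplyr::bind_cols(tibble(.y = as.integer(response)), red$design)
  fit <- glm(.y ~ ., data = dat, family = binomial(),
             control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  separation <- any(abs(est[-1]) > 15) || any(se[-1] > 100)
  structure(list(
    coefficients = est, se = se, converged = fit$converged,
    separation = separation, excluded = red$excluded,
    n = nrow(dat), glm = fit
  ), class = "pv_logistic")
}

#' @export
print.pv_logistic <- function(x, ...) {
  cat("<pv_logistic> n = ", x$n,
      if (!x$converged) " [DID NOT CONVERGE]" else "",
      if (x$separation) " [possible separation]" else "", "\n", sep = "")
  print(tidy.pv_logistic(x))
  invisible(x)
}

#' Tidy a logistic predictor fit
#'
#' One row per model term with the coefficient, odds ratio, Wald 95%
#' interval and two-sided Wald p-value; excluded covariates are appended as
#' rows with `or = NA` and the exclusion reason, mirroring the "N.A."
#' presentation of published predictor tables.
#'
#' @param x A `pv_logistic` object.
#' @param ... Unused.
#' @return A tibble: `term`, `estimate`, `std.error`, `or`, `conf.low`,
#'   `conf.high`, `p.value`, `note`.
#' @export
tidy.pv_logistic <- function(x, ...) {
  z <- x$coefficients / x$se
  p <- 2 * pnorm(-abs(z))
  out <- tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    or = exp(unname(x$coefficients)),
    conf.low = exp(unname(x$coefficients) - Z975 * unname(x$se)),
    conf.high = exp(unname(x$coefficients) + Z975 * unname(x$se)),
    p.value = unname(p),
    note = NA_character_
  )
  if (nrow(x$excluded)) {
    out <- bind_rows(out, tibble(
      term = x$excluded$covariate, estimate = NA_real_, std.error = NA_real_,
      or = NA_real_, conf.low = NA_real_, conf.high = NA_real_,
      p.value = NA_real_, note = x$excluded$reason
    ))
  }
  out
}

#' Model-level summary of a logistic predictor fit
#' @param x A `pv_logistic` object.
#' @param ... Unused.
#' @return One-row tibble: `n`, `n_terms`, `converged`, `separation`,
#'   `deviance`, `aic`.
#' @export
glance.pv_logistic <- function(x, ...) {
  tibble(n = x$n, n_terms = length(x$coefficients) - 1L,
         converged = x$converged, separation = x$separation,
         deviance = x$glm$deviance, aic = x$glm$aic)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
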