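#' Configure an end-to-end analysis run
#'
#' Bundles every choice a full screening run needs: the input mode, term
#' sets, drug-class map, target (anchor) drug, partner classes, decision
#' thresholds and the time-to-onset window. Thresholds default to the
#' standard screening criteria: omega025 > 0, additive > 0, multiplicative
#' > 1, chi > 2, composite when at least 2 of 4 models flag.
#'
#' @param input Either `"simulate"` or a named list of the four table paths
#'   (`demo`, `drug`, `reac`, `hist`).
#' @param term_sets Named list of [term_set]s (needs at least the event
#'   sets named in `event_sets`); default [default_term_sets()].
#' @param class_map A [drug_class_map]; default [default_drug_class_map()].
#' @param target_drug Anchor drug for combination screening, predictor
#'   modelling and time-to-onset (default `"alteplase"`).
#' @param partner_classes Character vector of drug classes screened in
#'   combination with the target (defaults to every class in the map except
#'   the target's own class and `"other"`).
#' @param event_sets Names of the term sets treated as target events
#'   (default `c("ht", "ich")`).
#' @param comorbidity_sets Names of the term sets used as predictor
#'   covariates.
#' @param exclusion_history Optional term-set name: exposed cases with this
#'   history are dropped before analysis (e.g. an indication the study
#'   excludes). `NULL` disables the filter.
#' @param tto_window Analysis window in days for time-to-onset (default 20).
#' @param sim A [sim_config()] when `input = "simulate"`.
#' @param seed Integer seed recorded in the manifest and used for the
#'   simulator.
#' @return An `analysis_config` object.
#' @export
analysis_config <- function(input = "simulate",
                            term_sets = default_term_sets(),
                            class_map = default_drug_class_map(),
                            target_drug = "alteplase",
                            partner_classes = NULL,
                            event_sets = c("ht", "ich"),
                            comorbidity_sets = c("hypertension",
                                                 "diabetes_mellitus",
                                                 "heart_failure",
                                                 "convulsive_disorder",
                                                 "chronic_kidney_disease"),
                            exclusion_history = NULL,
                            tto_window = 20,
                            sim = NULL,
                            seed = 1L) {
  if (is.list(input)) {
    need <- c("demo", "drug", "reac", "hist")
    if (!all(need %in% names(input))) {
      abort("file input must name demo, drug, reac and hist paths")
    }
    for (p in unlist(input[need])) {
      if (!file.exists(p)) abort(sprintf("input table not found: %s", p))
    }
  } else if (!identical(input, "simulate")) {
    abort('input must be "simulate" or a named list of table paths')
  }
  missing_sets <- setdiff(c(event_sets, comorbidity_sets, exclusion_history),
                          names(term_sets))
  if (length(missing_sets)) {
    abort(sprintf("term set(s) not found: %s",
                  paste(missing_sets, collapse = ", ")))
  }
  if (identical(input, "simulate") && is.null(sim)) {
    abort("simulate mode needs a sim_config in `sim`")
  }
  if (tto_window <= 0) abort("tto_window must be positive")
  all_classes <- unique(class_map$table$class)
  target_class <- map_drug_class(target_drug, class_map)
  if (is.null(partner_classes)) {
    partner_classes <- setdiff(all_classes, c(target_class, "other"))
  }
  structure(list(
    input = input, term_sets = term_sets, class_map = class_map,
    target_drug = normalize_drug_name(target_drug),
    partner_classes = partner_classes, event_sets = event_sets,
    comorbidity_sets = comorbidity_sets,
    exclusion_history = exclusion_history,
    tto_window = tto_window, sim = sim, seed = as.integer(seed)
  ), class = "analysis_config")
}

#' Run the full screening pipeline
#'
#' Loads or simulates the report collection, applies the optional
#' history-based exclusion, then produces:
#'
#' 1. `ae_signals` — reporting odds ratio and information component per
#'    target + partner-class combination and event set, with the
#'    conjunction signal rule ([screen_ae_signals()]);
#' 2. `ddi_signals` — the four interaction statistics and two-of-four
#'    composite per partner class and event set ([screen_ddi_signals()]);
#' 3. `predictors` — tidied multivariable logistic fits of the covariates
#'    on each event among target-drug-exposed cases ([fit_logistic()]),
#'    `NULL` for an event when not estimable (reason recorded);
#' 4. `tto` — time-to-onset summary and outcome tabulation per event set
#'    among target-drug-exposed cases;
#' 5. `manifest` — seed, package version, row counts and configuration
#'    echoes sufficient to re-run the identical analysis.
#'
#' Identical config and seed give identical bundles.
#'
#' @param config An [analysis_config()].
#' @return A named list (`ae_signals`, `ddi_signals`, `predictors`, `tto`,
#'   `manifest`) of class `pv_analysis`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  if (identical(config$input, "simulate")) {
    sim <- config$sim
    sim$seed <- config$seed
    reports <- simulate_reports(sim)$reports
  } else {
    reports <- read_case_tables(config$input$demo, config$input$drug,
                                config$input$reac, config$input$hist,
                                col_map = config$input$col_map)
  }
  n_loaded <- n_cases(reports)
  if (!is.null(config$exclusion_history)) {
    reports <- exclude_by_history(
      reports, config$target_drug,
      config$term_sets[[config$exclusion_history]]
    )
  }

  events <- config$term_sets[config$event_sets]
  target <- config$target_drug
  partner_drugs <- lapply(config$partner_classes, drugs_in_class,
                          map = config$class_map)
  names(partner_drugs) <- config$partner_classes

  # combination exposure: on the target drug AND on the partner class
  combo_exposures <- lapply(partner_drugs, function(dn) {
    function(rep) intersect(exposed_cases(rep, target),
                            exposed_cases(rep, dn))
  })
  names(combo_exposures) <- config$partner_classes
  ae <- screen_ae_signals(reports, combo_exposures, events)

  ddi <- screen_ddi_signals(reports, target, partner_drugs, events)

  target_reports <- filter_cases(reports, exposed_cases(reports, target))
  covars <- build_covariates(target_reports,
                             config$term_sets[config$comorbidity_sets])
  predictors <- lapply(names(events), function(ev) {
    y <- match_event(target_reports, events[[ev]])$matched
    fit <- tryCatch(fit_logistic(covars, y), error = function(e) e)
    if (inherits(fit, "error")) {
      list(fit = NULL, tidy = NULL, reason = conditionMessage(fit))
    } else {
      list(fit = fit, tidy = tidy.pv_logistic(fit), reason = NULL)
    }
  })
  names(predictors) <- names(events)

  tto <- lapply(names(events), function(ev) {
    rec <- compute_tto(target_reports, target, events[[ev]]) %>%
      apply_window(config$tto_window)
    list(records = rec,
         summary = summarize_tto(rec),
         outcomes = tabulate_outcomes(target_reports, events[[ev]]))
  })
  names(tto) <- names(events)

  manifest <- list(
    package_version = as.character(utils::packageVersion("pvsignals")),
    seed = config$seed,
    input_mode = if (identical(config$input, "simulate")) "simulate"
      else "files",
    n_reports_loaded = n_loaded,
    n_reports_analyzed = n_cases(reports),
    n_target_exposed = n_cases(target_reports),
    target_drug = target,
    partner_classes = config$partner_classes,
    event_sets = config$event_sets,
    tto_window = config$tto_window
  )

  structure(list(ae_signals = ae, ddi_signals = ddi,
                 predictors = predictors, tto = tto, manifest = manifest),
            class = "pv_analysis")
}

#' @export
print.pv_analysis <- function(x, ...) {
  cat("<pv_analysis> ", x$manifest$n_reports_analyzed, " reports, target '",
      x$manifest$target_drug, "'\n", sep = "")
  cat("  AE signal rows: ", nrow(x$ae_signals),
      " | DDI rows: ", nrow(x$ddi_signals), "\n", sep = "")
  invisible(x)
}

#' Write an analysis bundle to delimited text
#'
#' Emits `ae_signals.csv`, `ddi_signals.csv`, one `predictors_<event>.csv`
#' per estimable event model, `tto_<event>.csv` day counts plus
#' `outcomes_<event>.csv`, and `manifest.yaml` into `dir`.
#'
#' @param bundle A `pv_analysis` from [run_full_analysis()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_analysis <- function(bundle, dir) {
  stopifnot(inherits(bundle, "pv_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  wr <- function(tab, name) {
    p <- file.path(dir, name)
    readr::write_csv(tab, p)
    paths <<- c(paths, p)
  }
  wr(bundle$ae_signals, "ae_signals.csv")
  wr(bundle$ddi_signals, "ddi_signals.csv")
  for (ev in names(bundle$predictors)) {
    td <- bundle$predictors[[ev]]$tidy
    if (!is.null(td)) wr(td, sprintf("predictors_%s.csv", ev))
  }
  for (ev in names(bundle$tto)) {
    s <- bundle$tto[[ev]]$summary
    wr(s$day_counts[[1]], sprintf("tto_%s.csv", ev))
    wr(bundle$tto[[ev]]$outcomes$counts, sprintf("outcomes_%s.csv", ev))
  }
  mp <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(bundle$manifest, mp)
  paths <- c(paths, mp)
  invisible(paths)
}
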