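#' Time-to-onset per case
#'
#' For each case, the whole-day difference between the earliest onset date
#' of a matching event and the earliest first-administration date of the
#' drug. Any missing date makes the value unknown (`NA`); a negative
#' difference (onset recorded before administration) is invalid and treated
#' as unknown with a message.
#'
#' @param reports A [case_data] object.
#' @param drug_name Drug whose first administration anchors the interval.
#' @param event_terms A [term_set] for the event.
#' @return A tibble with one row per case reporting the event (by any
#'   record): `case_id`, `days` (integer or `NA`).
#' @export
compute_tto <- function(reports, drug_name, event_terms) {
  stopifnot(inherits(reports, "case_data"))
  pts <- term_set_terms(event_terms)
  wanted <- normalize_drug_name(drug_name)

  ev <- reports$reac[reports$reac$pt_term %in% pts, ]
  if (!nrow(ev)) return(tibble(case_id = character(), days = integer()))
  onset <- ev %>%
    group_by(.data$case_id) %>%
    summarise(onset = suppressWarnings(min(.data$onset_date, na.rm = TRUE)),
              any_known_onset = any(!is.na(.data$onset_date)),
              .groups = "drop")
  onset$onset[!onset$any_known_onset] <- NA

  dr <- reports$drug[reports$drug$drug_name %in% wanted, ]
  admin <- dr %>%
    group_by(.data$case_id) %>%
    summarise(admin = suppressWarnings(min(.data$first_admin_date,
                                           na.rm = TRUE)),
              any_known_admin = any(!is.na(.data$first_admin_date)),
              .groups = "drop")
  admin$admin[!admin$any_known_admin] <- NA

  out <- onset[c("case_id", "onset")] %>%
    left_join(admin[c("case_id", "admin")], by = "case_id") %>%
    mutate(days = as.integer(.data$onset - .data$admin))
  neg <- !is.na(out$days) & out$days < 0
  if (any(neg)) {
    inform(sprintf("compute_tto: %d negative interval(s) treated as unknown",
                   sum(neg)))
    out$days[neg] <- NA_integer_
  }
  out[c("case_id", "days")]
}

#' Restrict time-to-onset records to an analysis window
#'
#' Known values greater than `window_days` are excluded (events after the
#' analysis period); day `window_days` itself is within the period and kept.
#' Unknown values are kept and stay unknown.
#'
#' @param records Tibble with a `days` column (from [compute_tto()]).
#' @param window_days Length of the analysis window in days (default 20).
#' @return The input tibble with a `status` column:
#'   `"known"` (in-window), `"unknown"`, or `"excluded"`.
#' @export
apply_window <- function(records, window_days = 20) {
  stopifnot("days" %in% names(records), window_days > 0)
  records %>%
    mutate(status = dplyr::case_when(
      is.na(.data$days) ~ "unknown",
      .data$days > window_days ~ "excluded",
      TRUE ~ "known"
    ))
}

#' Summarize a time-to-onset distribution
#'
#' Day-binned counts, median and mode over the known in-window values.
#' Records are first passed through [apply_window()] if they lack a
#' `status` column.
#'
#' @param records Tibble with `days` (and optionally `status`).
#' @param window_days Analysis window, used when `status` is absent.
#' @return A one-row tibble: `n_known`, `n_unknown`, `n_excluded`,
#'   `median_days`, `mode_days`, and `day_counts` (a list-column holding a
#'   tibble of `days`, `n` over known values). Median and mode are `NA`
#'   (with a message) when no known values remain.
#' @export
summarize_tto <- function(records, window_days = 20) {
  if (!"status" %in% names(records)) {
    records <- apply_window(records, window_days)
  }
  known <- records$days[records$status == "known"]
  counts <- tibble(days = as.integer(known)) %>%
    count(.data$days) %>%
    arrange(.data$days)
  if (!length(known)) inform("summarize_tto: no known values; median undefined")
  tibble(
    n_known = length(known),
    n_unknown = sum(records$status == "unknown"),
    n_excluded = sum(records$status == "excluded"),
    median_days = if (length(known)) median(known) else NA_real_,
    mode_days = if (length(known)) {
      counts$days[which.max(counts$n)]
    } else NA_integer_,
    day_counts = list(counts)
  )
}

#' Tabulate event outcomes
#'
#' Counts the six outcome categories for cases reporting the event, taking
#' each case's worst-informative record ordering (`death` > `after_effect` >
#' `no_recovery` > `remission` > `recovery`) when a case has several event
#' records with different outcomes. Aggregates `recovery + remission` as
#' recovered and `no_recovery + after_effect + death` as not recovered;
#' proportions are over known-outcome cases (unknowns excluded from the
#' denominator) and percentages are rounded to integers.
#'
#' @param reports A [case_data] object, or a character vector of outcome
#'   values (one per case; `NA` = unknown).
#' @param event_terms A [term_set]; ignored when `reports` is a vector.
#' @return A list with `counts` (tibble of `outcome`, `n` including
#'   `unknown`) and `summary` (one-row tibble: `n_known`, `n_unknown`,
#'   `recovered_n`, `recovered_pct`, `not_recovered_n`,
#'   `not_recovered_pct`). Percentages are `NA` (flagged via message) when
#'   all outcomes are unknown.
#' @export
tabulate_outcomes <- function(reports, event_terms = NULL) {
  severity <- c("death", "after_effect", "no_recovery", "remission",
                "recovery")
  if (inherits(reports, "case_data")) {
    if (is.null(event_terms)) abort("event_terms required with case_data input")
    pts <- term_set_terms(event_terms)
    ev <- reports$reac[reports$reac$pt_term %in% pts, ]
    per_case <- ev %>%
      group_by(.data$case_id) %>%
      summarise(outcome = {
        known <- .data$outcome[!is.na(.data$outcome)]
        if (length(known)) severity[min(match(known, severity))]
        else NA_character_
      }, .groups = "drop")
    outcomes <- per_case$outcome
  } else {
    outcomes <- as.character(reports)
    bad <- !is.na(outcomes) & !(outcomes %in% outcome_levels())
    if (any(bad)) abort("unrecognized outcome value(s)")
  }
  lv <- outcome_levels()
  counts <- tibble(
    outcome = c(lv, "unknown"),
    n = unname(c(vapply(lv, function(o) sum(outcomes == o, na.rm = TRUE),
                        integer(1)),
                 sum(is.na(outcomes))))
  )
  n_known <- sum(!is.na(outcomes))
  rec <- sum(outcomes %in% c("recovery", "remission"))
  not_rec <- sum(outcomes %in% c("no_recovery", "after_effect", "death"))
  if (n_known == 0) inform("tabulate_outcomes: all outcomes unknown")
  summary <- tibble(
    n_known = n_known, n_unknown = sum(is.na(outcomes)),
    recovered_n = rec,
    recovered_pct = if (n_known) round(100 * rec / n_known) else NA_real_,
    not_recovered_n = not_rec,
    not_recovered_pct = if (n_known) round(100 * not_rec / n_known)
      else NA_real_
  )
  list(counts = counts, summary = summary)
}

#' Bar chart of a time-to-onset distribution
#'
#' Histogram-style bar chart of day-binned time-to-onset counts, one panel
#' per event class when a `event_class` column is present.
#'
#' @param records Tibble with `days` (and optionally `status` and
#'   `event_class` columns); excluded/unknown records are dropped from the
#'   plot.
#' @param window_days Analysis window for on-the-fly status assignment.
#' @return A ggplot object.
#' @export
plot_tto <- function(records, window_days = 20) {
  if (!"status" %in% names(records)) {
    records <- apply_window(records, window_days)
  }
  dat <- records[records$status == "known", ]
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$days)) +
    ggplot2::geom_bar(fill = "grey30") +
    ggplot2::labs(x = "Time to onset (days)", y = "Number of cases") +
    ggplot2::theme_minimal()
  if ("event_class" %in% names(dat)) {
    p <- p + ggplot2::facet_wrap(~event_class, scales = "free_y")
  }
  p
}
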