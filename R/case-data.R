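#' Spontaneous-report case data
#'
#' A `case_data` object bundles the four linked tables of a spontaneous
#' adverse-event reporting database, keyed by a shared case identifier:
#'
#' * `demo` — one row per case: `case_id`, `sex`
#'   (`"male"`, `"female"`, `"unknown"`) and `age_group` (a decade label,
#'   `"under 10s"` through `"100s"`, or `NA` for unknown);
#' * `drug` — one row per reported drug exposure: `case_id`, `drug_name`
#'   (normalized), `role` (`"suspected"`, `"concomitant"`, `"interaction"`)
#'   and `first_admin_date` (`Date`, `NA` when unknown);
#' * `reac` — one row per adverse-event record: `case_id`, `pt_term`
#'   (preferred term), `onset_date` (`Date`, `NA` when unknown) and
#'   `outcome` (one of [outcome_levels()], `NA` when unknown);
#' * `hist` — one row per medical-history term: `case_id`, `pt_term`.
#'
#' All drug and event analysis in this package is case-level: a case counts
#' once for a drug or event however many rows mention it.
#'
#' @param demo,drug,reac,hist Data frames with the columns listed above.
#'   Extra columns are dropped; child rows whose `case_id` is absent from
#'   `demo` are kept (the case is then known only through its child rows)
#'   and a stub demo row is added for them.
#'
#' @return An object of class `case_data`: a named list of four tibbles.
#' @export
#' @examples
#' cd <- case_data(
#'   demo = data.frame(case_id = "c1", sex = "male", age_group = "70s"),
#'   drug = data.frame(case_id = "c1", drug_name = "alteplase",
#'                     role = "suspected",
#'                     first_admin_date = as.Date("2020-01-01")),
#'   reac = data.frame(case_id = "c1", pt_term = "placeholder event",
#'                     onset_date = as.Date("2020-01-02"),
#'                     outcome = "recovery"),
#'   hist = data.frame(case_id = character(), pt_term = character())
#' )
#' n_cases(cd)
case_data <- function(demo, drug, reac, hist) {
  demo <- as_tibble(demo)
  drug <- as_tibble(drug)
  reac <- as_tibble(reac)
  hist <- as_tibble(hist)

  need <- list(
    demo = c("case_id", "sex", "age_group"),
    drug = c("case_id", "drug_name", "role", "first_admin_date"),
    reac = c("case_id", "pt_term", "onset_date", "outcome"),
    hist = c("case_id", "pt_term")
  )
  tabs <- list(demo = demo, drug = drug, reac = reac, hist = hist)
  for (nm in names(need)) {
    missing_cols <- setdiff(need[[nm]], names(tabs[[nm]]))
    if (length(missing_cols)) {
      abort(sprintf("`%s` table is missing column(s): %s",
                    nm, paste(missing_cols, collapse = ", ")))
    }
    tabs[[nm]] <- tabs[[nm]][need[[nm]]]
    tabs[[nm]]$case_id <- as.character(tabs[[nm]]$case_id)
  }
  demo <- tabs$demo; drug <- tabs$drug; reac <- tabs$reac; hist <- tabs$hist

  # de-duplicate demographics: first row wins, conflicts warned
  if (anyDuplicated(demo$case_id)) {
    n_dup <- sum(duplicated(demo$case_id))
    warn(sprintf("%d duplicated case id(s) in demo table; keeping first row",
                 n_dup))
    demo <- demo[!duplicated(demo$case_id), ]
  }

  # stub demo rows for orphan child case ids
  orphans <- setdiff(
    unique(c(drug$case_id, reac$case_id, hist$case_id)), demo$case_id
  )
  if (length(orphans)) {
    demo <- bind_rows(demo, tibble(
      case_id = orphans, sex = "unknown", age_group = NA_character_
    ))
  }

  drug$role <- normalize_role(drug$role)
  drug$drug_name <- normalize_drug_name(drug$drug_name)
  drug$first_admin_date <- as.Date(drug$first_admin_date)
  reac$onset_date <- as.Date(reac$onset_date)
  bad_outcome <- !is.na(reac$outcome) & !(reac$outcome %in% outcome_levels())
  if (any(bad_outcome)) {
    warn(sprintf("%d outcome value(s) outside the six categories set to NA",
                 sum(bad_outcome)))
    reac$outcome[bad_outcome] <- NA_character_
  }
  sex <- tolower(trimws(demo$sex))
  sex[is.na(sex) | !(sex %in% c("male", "female"))] <- "unknown"
  demo$sex <- sex

  structure(list(demo = demo, drug = drug, reac = reac, hist = hist),
            class = "case_data")
}

#' The six reaction outcome categories
#'
#' Outcome levels used in the reaction table, ordered as usually tabulated.
#' `"unknown"` is represented by `NA` in the data; these six are the known
#' categories.
#'
#' @return Character vector of length 5 plus `after_effect`/`death` — the six
#'   categories: recovery, remission, no_recovery, after_effect, death,
#'   unknown is `NA`.
#' @export
outcome_levels <- function() {
  c("recovery", "remission", "no_recovery", "after_effect", "death")
}

#' @export
print.case_data <- function(x, ...) {
  cat("<case_data> ", n_cases(x), " cases\n", sep = "")
  cat("  drug rows: ", nrow(x$drug),
      " | reac rows: ", nrow(x$reac),
      " | hist rows: ", nrow(x$hist), "\n", sep = "")
  invisible(x)
}

#' Number of cases in a case_data object
#' @param x A [case_data] object.
#' @return Integer count of distinct cases.
#' @export
n_cases <- function(x) {
  stopifnot(inherits(x, "case_data"))
  nrow(x$demo)
}

normalize_role <- function(role) {
  role <- tolower(trimws(as.character(role)))
  role[!(role %in% c("suspected", "concomitant", "interaction"))] <-
    "suspected"
  role
}

#' Normalize a drug name for matching
#'
#' Case-folds, trims and collapses internal whitespace. Salt suffixes are
#' deliberately not stripped: distinct salts are distinct products in
#' reporting databases and class maps name them explicitly.
#'
#' @param x Character vector of drug names.
#' @return Normalized character vector.
#' @export
normalize_drug_name <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

#' Dichotomize decade age groups
#'
#' Reporting databases often record age only as a decade label. Cases in the
#' "under 10s" through "60s" decades are classed `"younger"`; "70s" through
#' "100s" are `"older"`; anything else (including `NA` and empty strings) is
#' `"unknown"`.
#'
#' @param age_group Character vector of decade labels.
#' @return Character vector in `{"younger", "older", "unknown"}`.
#' @export
#' @examples
#' assign_age_class(c("60s", "70s", "", NA))
assign_age_class <- function(age_group) {
  younger <- c("under 10s", "10s", "20s", "30s", "40s", "50s", "60s")
  older <- c("70s", "80s", "90s", "100s")
  x <- tolower(trimws(as.character(age_group)))
  out <- rep("unknown", length(x))
  out[x %in% younger] <- "younger"
  out[x %in% older] <- "older"
  out
}

#' Case-level event matching against a term set
#'
#' A case matches when any of its reaction preferred terms is in the term
#' set; duplicated or multiple matching rows still count the case once.
#'
#' @param reports A [case_data] object.
#' @param terms A [term_set] (or character vector of preferred terms).
#' @return A tibble with one row per case: `case_id`, `matched` (logical).
#' @export
match_event <- function(reports, terms) {
  stopifnot(inherits(reports, "case_data"))
  pts <- term_set_terms(terms)
  hit <- unique(reports$reac$case_id[reports$reac$pt_term %in% pts])
  tibble(case_id = reports$demo$case_id,
         matched = reports$demo$case_id %in% hit)
}

#' Case ids reporting an event in a term set
#' @inheritParams match_event
#' @return Character vector of case ids.
#' @export
event_cases <- function(reports, terms) {
  m <- match_event(reports, terms)
  m$case_id[m$matched]
}

#' Case ids exposed to any of the given drugs
#'
#' All three drug roles (suspected, concomitant, interaction) count as
#' exposure. Names are normalized before matching.
#'
#' @param reports A [case_data] object.
#' @param drug_names Character vector of drug names (any role counts).
#' @return Character vector of case ids.
#' @export
exposed_cases <- function(reports, drug_names) {
  stopifnot(inherits(reports, "case_data"))
  wanted <- normalize_drug_name(drug_names)
  unique(reports$drug$case_id[reports$drug$drug_name %in% wanted])
}

#' Exclude cases by drug exposure and history term
#'
#' Removes cases exposed to `drug_name` whose history contains any term in
#' `history_terms`. This mirrors pre-analysis cohort filters such as
#' dropping thrombolysis cases whose indication was myocardial infarction
#' rather than ischemic stroke.
#'
#' @param reports A [case_data] object.
#' @param drug_name Single drug name defining the exposed subpopulation.
#' @param history_terms A [term_set] or character vector of history
#'   preferred terms triggering exclusion.
#' @return A filtered [case_data]; the number of removed cases is reported
#'   via a message.
#' @export
exclude_by_history <- function(reports, drug_name, history_terms) {
  stopifnot(inherits(reports, "case_data"))
  pts <- term_set_terms(history_terms)
  exposed <- exposed_cases(reports, drug_name)
  flagged <- unique(reports$hist$case_id[reports$hist$pt_term %in% pts])
  drop <- intersect(exposed, flagged)
  inform(sprintf("exclude_by_history: removing %d case(s)", length(drop)))
  filter_cases(reports, setdiff(reports$demo$case_id, drop))
}

#' Subset a case_data object to given case ids
#' @param reports A [case_data] object.
#' @param case_ids Character vector of case ids to keep.
#' @return A [case_data] with only those cases.
#' @export
filter_cases <- function(reports, case_ids) {
  stopifnot(inherits(reports, "case_data"))
  structure(
    list(
      demo = reports$demo[reports$demo$case_id %in% case_ids, ],
      drug = reports$drug[reports$drug$case_id %in% case_ids, ],
      reac = reports$reac[reports$reac$case_id %in% case_ids, ],
      hist = reports$hist[reports$hist$case_id %in% case_ids, ]
    ),
    class = "case_data"
  )
}
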