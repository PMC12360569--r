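#' Read the four-table spontaneous-report layout
#'
#' Reads the demographic, drug, reaction and history tables from delimited
#' text (comma or tab separated, header row, UTF-8) and joins them by the
#' case identifier into a [case_data] object. Unparseable dates become `NA`
#' (unknown); per-table row counts and unknown-date counts are logged as
#' messages. When the same case id recurs in the demographic table the first
#' row wins with a warning.
#'
#' @param demo_path,drug_path,reac_path,hist_path Paths to the four tables.
#' @param col_map Optional named list remapping this package's canonical
#'   column names to the names used in the files, per table, e.g.
#'   `list(demo = c(case_id = "ID", sex = "SEX", age_group = "AGE"))`.
#' @param delim Field delimiter; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @return A [case_data] object.
#' @export
read_case_tables <- function(demo_path, drug_path, reac_path, hist_path,
                             col_map = NULL, delim = NULL) {
  paths <- c(demo = unname(demo_path), drug = unname(drug_path),
             reac = unname(reac_path), hist = unname(hist_path))
  for (p in paths) {
    if (!file.exists(p)) abort(sprintf("input table not found: %s", p))
  }
  canonical <- list(
    demo = c("case_id", "sex", "age_group"),
    drug = c("case_id", "drug_name", "role", "first_admin_date"),
    reac = c("case_id", "pt_term", "onset_date", "outcome"),
    hist = c("case_id", "pt_term")
  )
  tabs <- lapply(names(paths), function(nm) {
    tab <- read_delim_auto(paths[[nm]], delim)
    map <- col_map[[nm]]
    if (!is.null(map)) {
      for (canon in names(map)) {
        if (!map[[canon]] %in% names(tab)) {
          abort(sprintf("column '%s' not found in %s table", map[[canon]], nm))
        }
        names(tab)[names(tab) == map[[canon]]] <- canon
      }
    }
    if (!"case_id" %in% names(tab)) {
      abort(sprintf("%s table has no case id column", nm))
    }
    missing_cols <- setdiff(canonical[[nm]], names(tab))
    for (mc in missing_cols) tab[[mc]] <- NA_character_
    tab <- tab[canonical[[nm]]]
    inform(sprintf("read %s: %d rows", nm, nrow(tab)))
    tab
  })
  names(tabs) <- names(paths)

  tabs$drug$first_admin_date <- parse_report_date(
    tabs$drug$first_admin_date, "first_admin_date"
  )
  tabs$reac$onset_date <- parse_report_date(tabs$reac$onset_date, "onset_date")

  case_data(tabs$demo, tabs$drug, tabs$reac, tabs$hist)
}

read_delim_auto <- function(path, delim = NULL) {
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
}

# Day-level ISO dates only; year-month or other partial dates are unknown
# because time-to-onset needs day arithmetic.
parse_report_date <- function(x, what) {
  x <- as.character(x)
  out <- as.Date(rep(NA_real_, length(x)), origin = "1970-01-01")
  full <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[full] <- as.Date(x[full])
  n_unknown <- sum(is.na(out) & !is.na(x) & nzchar(x))
  if (n_unknown > 0) {
    inform(sprintf("%s: %d value(s) not day-level dates, set to unknown",
                   what, n_unknown))
  }
  out
}

#' Write a case_data object back to the four-table layout
#'
#' Writes four delimited files (`demo.csv`, `drug.csv`, `reac.csv`,
#' `hist.csv`) that [read_case_tables()] reads back to an identical object.
#'
#' @param reports A [case_data] object.
#' @param dir Output directory (created if needed).
#' @param delim Field delimiter (default comma).
#' @return Invisibly, the four file paths.
#' @export
write_case_tables <- function(reports, dir, delim = ",") {
  stopifnot(inherits(reports, "case_data"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("demo.csv", "drug.csv", "reac.csv", "hist.csv"))
  names(paths) <- c("demo", "drug", "reac", "hist")
  for (nm in names(paths)) {
    tab <- reports[[nm]]
    date_cols <- names(tab)[vapply(tab, inherits, logical(1), "Date")]
    for (dc in date_cols) tab[[dc]] <- format(tab[[dc]], "%Y-%m-%d")
    readr::write_delim(tab, paths[[nm]], delim = delim, na = "")
  }
  invisible(paths)
}
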