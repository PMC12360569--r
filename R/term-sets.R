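#' Term sets: named sets of preferred terms
#'
#' Adverse events and comorbidities are identified by matching reaction or
#' history preferred terms (PTs) against flat term sets. Matching is exact
#' string equality after normalization (case-fold, trim, collapse internal
#' whitespace) — no dictionary hierarchy is traversed, so the sets are
#' configuration, not code.
#'
#' @param name Term-set name.
#' @param pt_terms Non-empty character vector of preferred terms.
#' @return A `term_set` object.
#' @export
#' @examples
#' ts <- term_set("bleeding", c("Haemorrhage synthetic A", "Haemorrhage synthetic B"))
#' ts
term_set <- function(name, pt_terms) {
  pt_terms <- unique(normalize_pt(pt_terms))
  pt_terms <- pt_terms[nzchar(pt_terms)]
  if (!length(pt_terms)) abort("a term set must contain at least one term")
  structure(list(name = as.character(name), pt_terms = pt_terms),
            class = "term_set")
}

#' @export
print.term_set <- function(x, ...) {
  cat("<term_set> ", x$name, ": ", length(x$pt_terms), " PT(s)\n", sep = "")
  invisible(x)
}

normalize_pt <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

# accept term_set or bare character vector everywhere
term_set_terms <- function(terms) {
  if (inherits(terms, "term_set")) return(terms$pt_terms)
  normalize_pt(terms)
}

#' Read term sets from a YAML config
#'
#' The file maps set names to lists of preferred terms:
#' ```yaml
#' ht:
#'   - placeholder term 1
#'   - placeholder term 2
#' ```
#' The package ships a placeholder config (see
#' `system.file("extdata", "term_sets.yaml", package = "pvsignals")`)
#' whose PTs are synthetic stand-ins, since real dictionary term lists are
#' licensed; edit or replace it for production use.
#'
#' @param path Path to the YAML file.
#' @return Named list of [term_set] objects.
#' @export
read_term_sets <- function(path) {
  if (!file.exists(path)) abort(sprintf("term-set file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (!length(raw)) abort("term-set file is empty")
  out <- lapply(names(raw), function(nm) term_set(nm, unlist(raw[[nm]])))
  setNames(out, names(raw))
}

#' Built-in placeholder term sets
#'
#' Convenience loader for the synthetic placeholder term sets shipped with
#' the package: `ht` (3 PTs) and `ich` (9 PTs) for the two hemorrhage event
#' classes, plus five comorbidity sets (`hypertension`, `diabetes_mellitus`,
#' `heart_failure`, `convulsive_disorder`, `chronic_kidney_disease`). The
#' simulator emits these same placeholder PTs, so simulated data and default
#' term sets agree end to end.
#'
#' @return Named list of [term_set] objects.
#' @export
default_term_sets <- function() {
  read_term_sets(system.file("extdata", "term_sets.yaml",
                             package = "pvsignals"))
}

#' Drug-class map
#'
#' Maps normalized drug names to analysis classes (antiplatelet and
#' anticoagulant groups plus the thrombolytic itself); unmapped names
#' resolve to `"other"`.
#'
#' @param mapping Named list: class name -> character vector of drug names.
#' @return A `drug_class_map` object.
#' @export
drug_class_map <- function(mapping) {
  if (!length(mapping) || is.null(names(mapping))) {
    abort("mapping must be a named list of class -> drug names")
  }
  flat <- tibble(
    class = rep(names(mapping), lengths(mapping)),
    drug_name = normalize_drug_name(unlist(mapping, use.names = FALSE))
  )
  dup <- flat$drug_name[duplicated(flat$drug_name)]
  if (length(dup)) {
    abort(sprintf("drug name(s) mapped to more than one class: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  structure(list(table = flat), class = "drug_class_map")
}

#' @export
print.drug_class_map <- function(x, ...) {
  cat("<drug_class_map> ", nrow(x$table), " drug(s), ",
      length(unique(x$table$class)), " class(es)\n", sep = "")
  invisible(x)
}

#' Read a drug-class map from YAML
#' @param path Path to a YAML file mapping class names to drug-name lists.
#' @return A [drug_class_map].
#' @export
read_drug_class_map <- function(path) {
  if (!file.exists(path)) abort(sprintf("class-map file not found: %s", path))
  drug_class_map(yaml::read_yaml(path))
}

#' Built-in drug-class map
#'
#' The antiplatelet / anticoagulant grouping used throughout the package:
#' aspirin; P2Y12 inhibitors (clopidogrel sulfate, ticagrelor, ticlopidine
#' hydrochloride, prasugrel hydrochloride); cilostazol; ozagrel sodium;
#' other antiplatelets; DOACs; warfarin potassium; heparin group; argatroban;
#' and alteplase itself. Salt names are kept verbatim.
#'
#' @return A [drug_class_map].
#' @export
default_drug_class_map <- function() {
  read_drug_class_map(system.file("extdata", "drug_classes.yaml",
                                  package = "pvsignals"))
}

#' Map drug names to classes
#'
#' @param drug_name Character vector of drug names (normalized internally).
#' @param map A [drug_class_map]; defaults to [default_drug_class_map()].
#' @return Character vector of class labels; unmapped names give `"other"`.
#' @export
#' @examples
#' map_drug_class(c("Clopidogrel sulfate", "acetaminophen"))
map_drug_class <- function(drug_name, map = default_drug_class_map()) {
  stopifnot(inherits(map, "drug_class_map"))
  idx <- match(normalize_drug_name(drug_name), map$table$drug_name)
  out <- map$table$class[idx]
  out[is.na(idx)] <- "other"
  out
}

#' Drug names belonging to a class
#' @param class Class label.
#' @param map A [drug_class_map].
#' @return Character vector of member drug names.
#' @export
drugs_in_class <- function(class, map = default_drug_class_map()) {
  stopifnot(inherits(map, "drug_class_map"))
  map$table$drug_name[map$table$class == class]
}
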