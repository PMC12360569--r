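test_that("four-table fixture loads with correct per-case bookkeeping", {
  cd <- fixture_case_data()
  expect_s3_class(cd, "case_data")
  expect_equal(n_cases(cd), 3)
  expect_equal(nrow(cd$drug), 5)
  expect_equal(nrow(cd$reac), 4)
  # role labels survive, including "interaction"
  expect_setequal(unique(cd$drug$role),
                  c("suspected", "concomitant", "interaction"))
  expect_equal(cd$drug$role[cd$drug$case_id == "c2" &
                              cd$drug$drug_name == "warfarin potassium"],
               "interaction")
  # drug names are normalized (case-folded)
  expect_true("aspirin" %in% cd$drug$drug_name)
  expect_false("Aspirin" %in% cd$drug$drug_name)
})

test_that("empty tables give an empty collection", {
  cd <- case_data(
    demo = data.frame(case_id = character(), sex = character(),
                      age_group = character()),
    drug = data.frame(case_id = character(), drug_name = character(),
                      role = character(),
                      first_admin_date = as.Date(character())),
    reac = data.frame(case_id = character(), pt_term = character(),
                      onset_date = as.Date(character()),
                      outcome = character()),
    hist = data.frame(case_id = character(), pt_term = character())
  )
  expect_equal(n_cases(cd), 0)
})

test_that("round trip through the four-table text layout is lossless", {
  cd <- fixture_case_data()
  dir <- withr::local_tempdir()
  suppressMessages(paths <- write_case_tables(cd, dir))
  cd2 <- suppressMessages(read_case_tables(paths["demo"], paths["drug"],
                                           paths["reac"], paths["hist"]))
  for (nm in c("demo", "drug", "reac", "hist")) {
    expect_equal(as.data.frame(cd2[[nm]]), as.data.frame(cd[[nm]]),
                 ignore_attr = TRUE)
  }
})

test_that("reader rejects a missing id column and warns on duplicate demo rows", {
  dir <- withr::local_tempdir()
  suppressMessages(paths <- write_case_tables(fixture_case_data(), dir))
  bad <- file.path(dir, "bad_demo.csv")
  writeLines(c("ident,sex,age_group", "c1,male,60s"), bad)
  expect_error(
    suppressMessages(read_case_tables(bad, paths["drug"], paths["reac"],
                                      paths["hist"])),
    "case id"
  )
  # duplicate conflicting demographics: first row wins with a warning
  expect_warning(
    cd <- case_data(
      demo = data.frame(case_id = c("c1", "c1"), sex = c("male", "female"),
                        age_group = c("60s", "70s")),
      drug = fixture_case_data()$drug[0, ],
      reac = fixture_case_data()$reac[0, ],
      hist = fixture_case_data()$hist[0, ]
    ),
    "duplicated"
  )
  expect_equal(cd$demo$sex[cd$demo$case_id == "c1"], "male")
})

test_that("partial or malformed dates are read as unknown", {
  dir <- withr::local_tempdir()
  writeLines(c("case_id,sex,age_group", "c1,male,60s"),
             file.path(dir, "demo.csv"))
  writeLines(c("case_id,drug_name,role,first_admin_date",
               "c1,alteplase,suspected,2020-01",
               "c1,aspirin,suspected,garbage",
               "c1,heparin sodium,suspected,2020-01-15"),
             file.path(dir, "drug.csv"))
  writeLines(c("case_id,pt_term,onset_date,outcome",
               "c1,target event a,2020-01-16,recovery"),
             file.path(dir, "reac.csv"))
  writeLines("case_id,pt_term", file.path(dir, "hist.csv"))
  cd <- suppressMessages(read_case_tables(
    file.path(dir, "demo.csv"), file.path(dir, "drug.csv"),
    file.path(dir, "reac.csv"), file.path(dir, "hist.csv")
  ))
  expect_equal(sum(is.na(cd$drug$first_admin_date)), 2)
  expect_equal(sum(!is.na(cd$drug$first_admin_date)), 1)
})

test_that("age classes partition every decade label", {
  labels <- c("under 10s", "10s", "20s", "30s", "40s", "50s", "60s",
              "70s", "80s", "90s", "100s")
  classes <- assign_age_class(labels)
  expect_equal(classes[labels == "60s"], "younger")
  expect_equal(classes[labels == "70s"], "older")
  expect_true(all(classes %in% c("younger", "older")))
  expect_equal(sum(classes == "younger"), 7)
  expect_equal(sum(classes == "older"), 4)
  expect_equal(assign_age_class(c("", NA, "not an age")),
               rep("unknown", 3))
})

test_that("event matching is case-level and idempotent under duplicate rows", {
  cd <- fixture_case_data()
  terms <- fixture_event_terms()
  m <- match_event(cd, terms)
  expect_equal(m$matched, c(TRUE, TRUE, FALSE))
  # c1 has two matching PTs but counts once
  expect_equal(sum(m$case_id == "c1"), 1)
  # duplicating an event row changes nothing
  cd2 <- cd
  cd2$reac <- dplyr::bind_rows(cd$reac, cd$reac[1, ])
  expect_equal(match_event(cd2, terms), m)
  # no events at all
  cd3 <- cd
  cd3$reac <- cd$reac[0, ]
  expect_false(any(match_event(cd3, terms)$matched))
})

test_that("drug class mapping is deterministic with 'other' fallback", {
  expect_equal(map_drug_class("clopidogrel sulfate"), "P2Y12")
  expect_equal(map_drug_class("heparin calcium"), "heparin")
  expect_equal(map_drug_class("Warfarin  Potassium"), "warfarin")
  expect_equal(map_drug_class("acetaminophen"), "other")
  expect_error(
    drug_class_map(list(a = "drug x", b = "drug x")),
    "more than one class"
  )
})

test_that("term sets load from YAML and reject empty sets", {
  sets <- default_term_sets()
  expect_true(all(c("ht", "ich") %in% names(sets)))
  expect_length(sets$ht$pt_terms, 3)
  expect_length(sets$ich$pt_terms, 9)
  expect_error(term_set("empty", character()), "at least one")
})

test_that("history-based exclusion removes only exposed flagged cases", {
  cd <- fixture_case_data()
  # c1 is alteplase-exposed with the flagged history term; c2 exposed without
  out <- suppressMessages(
    exclude_by_history(cd, "alteplase", "hypertension placeholder 1")
  )
  expect_setequal(out$demo$case_id, c("c2", "c3"))
  # an unexposed case with the term is untouched
  out2 <- suppressMessages(
    exclude_by_history(cd, "warfarin potassium", "hypertension placeholder 1")
  )
  expect_equal(n_cases(out2), 3)
})
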