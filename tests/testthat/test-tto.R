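tto_fixture <- function(admin, onset) {
  case_data(
    demo = data.frame(case_id = "c1", sex = "male", age_group = "50s"),
    drug = data.frame(case_id = "c1", drug_name = "alteplase",
                      role = "suspected",
                      first_admin_date = as.Date(admin)),
    reac = data.frame(case_id = "c1", pt_term = "target event a",
                      onset_date = as.Date(onset),
                      outcome = "recovery"),
    hist = data.frame(case_id = character(), pt_term = character())
  )
}

test_that("time-to-onset is the day difference with unknown as the sink state", {
  terms <- "target event a"
  expect_equal(compute_tto(tto_fixture("2020-01-01", "2020-01-02"),
                           "alteplase", terms)$days, 1L)
  expect_equal(compute_tto(tto_fixture("2020-01-01", "2020-01-01"),
                           "alteplase", terms)$days, 0L)
  expect_true(is.na(compute_tto(tto_fixture("2020-01-01", NA),
                                "alteplase", terms)$days))
  expect_true(is.na(compute_tto(tto_fixture(NA, "2020-01-02"),
                                "alteplase", terms)$days))
  # onset before administration is invalid -> unknown, with a message
  expect_message(
    d <- compute_tto(tto_fixture("2020-01-10", "2020-01-02"),
                     "alteplase", terms)$days,
    "negative"
  )
  expect_true(is.na(d))
})

test_that("earliest event onset and earliest administration anchor the interval", {
  cd <- case_data(
    demo = data.frame(case_id = "c1", sex = "male", age_group = "50s"),
    drug = data.frame(case_id = c("c1", "c1"), drug_name = "alteplase",
                      role = "suspected",
                      first_admin_date = as.Date(c("2020-01-05",
                                                   "2020-01-01"))),
    reac = data.frame(case_id = c("c1", "c1"),
                      pt_term = c("target event a", "target event b"),
                      onset_date = as.Date(c("2020-01-09", "2020-01-03")),
                      outcome = NA_character_),
    hist = data.frame(case_id = character(), pt_term = character())
  )
  expect_equal(
    compute_tto(cd, "alteplase",
                c("target event a", "target event b"))$days, 2L)
})

test_that("shifting all dates by a constant leaves time-to-onset unchanged", {
  base <- compute_tto(tto_fixture("2020-01-01", "2020-01-04"),
                      "alteplase", "target event a")$days
  for (k in c(-30, 7, 365)) {
    shifted <- compute_tto(
      tto_fixture(as.Date("2020-01-01") + k, as.Date("2020-01-04") + k),
      "alteplase", "target event a")$days
    expect_equal(shifted, base)
  }
})

test_that("the analysis window keeps day 20, excludes later days, keeps unknowns", {
  rec <- tibble::tibble(case_id = as.character(1:4),
                        days = c(20L, 36L, 3L, NA))
  w <- apply_window(rec, 20)
  expect_equal(w$status, c("known", "excluded", "known", "unknown"))
  # partition: kept + excluded + unknown = input size
  expect_equal(sum(table(w$status)), nrow(rec))
})

test_that("published time-to-onset distributions give the published medians", {
  ht <- summarize_tto(tibble::tibble(days = published_tto_days("HT")))
  expect_equal(ht$n_known, 308)
  expect_equal(ht$n_unknown, 28)
  expect_equal(ht$median_days, 1)
  expect_equal(ht$mode_days, 1L)

  ich <- summarize_tto(tibble::tibble(days = published_tto_days("ICH")))
  expect_equal(ich$n_known, 185)
  expect_equal(ich$median_days, 0)
  expect_equal(ich$mode_days, 0L)

  # medians do not depend on where the 4-20-day bin mass sits
  ht_alt <- c(rep(0L, 62), rep(1L, 197), rep(2L, 24), rep(3L, 8),
              rep(20L, 17))
  expect_equal(summarize_tto(tibble::tibble(days = ht_alt))$median_days, 1)

  single <- summarize_tto(tibble::tibble(days = 5L))
  expect_equal(single$median_days, 5)
  empty <- suppressMessages(
    summarize_tto(tibble::tibble(days = NA_integer_)))
  expect_true(is.na(empty$median_days))
  expect_equal(empty$n_unknown, 1)
})

test_that("outcome tabulation reproduces the published recovery shares", {
  ht <- tabulate_outcomes(published_outcomes("HT"))
  expect_equal(ht$summary$n_known, 307)
  expect_equal(ht$summary$recovered_n, 94)
  expect_equal(ht$summary$recovered_pct, 31)
  expect_equal(ht$summary$not_recovered_n, 213)
  expect_equal(ht$summary$not_recovered_pct, 69)

  ich <- tabulate_outcomes(published_outcomes("ICH"))
  expect_equal(ich$summary$n_known, 187)
  expect_equal(ich$summary$recovered_pct, 17)
  expect_equal(ich$summary$not_recovered_pct, 83)

  all_unknown <- suppressMessages(
    tabulate_outcomes(rep(NA_character_, 5)))
  expect_true(is.na(all_unknown$summary$recovered_pct))
  expect_equal(all_unknown$counts$n[all_unknown$counts$outcome == "unknown"],
               5)
})

test_that("case-level outcome tabulation takes the most severe event record", {
  cd <- fixture_case_data()
  # c1 has recovery + death records for the target event -> counted as death
  out <- tabulate_outcomes(cd, fixture_event_terms())
  expect_equal(out$counts$n[out$counts$outcome == "death"], 1)
  expect_equal(out$counts$n[out$counts$outcome == "recovery"], 0)
  expect_equal(out$counts$n[out$counts$outcome == "no_recovery"], 1)
  expect_equal(sum(out$counts$n), 2)  # two cases report the event
})

test_that("the time-to-onset plot builds from records", {
  rec <- tibble::tibble(days = c(0L, 1L, 1L, 2L, NA))
  p <- plot_tto(rec)
  expect_s3_class(p, "ggplot")
})
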