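make_pair_data <- function(strata_sizes, strata_events) {
  # strata order: 11, 10, 01, 00
  n <- sum(strata_sizes)
  ids <- sprintf("p%03d", seq_len(n))
  stratum <- rep(c("11", "10", "01", "00"), strata_sizes)
  event <- unlist(mapply(function(k, tot) c(rep(TRUE, k), rep(FALSE, tot - k)),
                         strata_events, strata_sizes, SIMPLIFY = FALSE))
  on_a <- stratum %in% c("11", "10")
  on_b <- stratum %in% c("11", "01")
  drug <- data.frame(
    case_id = c(ids[on_a], ids[on_b]),
    drug_name = c(rep("drug a", sum(on_a)), rep("drug b", sum(on_b))),
    role = "suspected", first_admin_date = as.Date("2021-01-01")
  )
  reac <- data.frame(
    case_id = ids,
    pt_term = ifelse(event, "target event a", "other event"),
    onset_date = as.Date("2021-01-02"), outcome = NA_character_
  )
  case_data(
    demo = data.frame(case_id = ids, sex = "male", age_group = "40s"),
    drug = drug, reac = reac,
    hist = data.frame(case_id = character(), pt_term = character())
  )
}

test_that("4x2 tables partition reports into exposure strata", {
  cd <- make_pair_data(c(2, 2, 2, 2), c(1, 1, 0, 0))
  tab <- build_contingency_4x2(cd, "drug a", "drug b", "target event a")
  expect_equal(
    unlist(tab[c("n11_total", "n10_total", "n01_total", "n00_total")]),
    c(n11_total = 2, n10_total = 2, n01_total = 2, n00_total = 2)
  )
  expect_equal(
    unlist(tab[c("n11_event", "n10_event", "n01_event", "n00_event")]),
    c(n11_event = 1, n10_event = 1, n01_event = 0, n00_event = 0)
  )
  # strata partition all reports; a both-drug case is only in stratum 11
  expect_equal(tab$n11_total + tab$n10_total + tab$n01_total + tab$n00_total,
               n_cases(cd))
  rates <- stratum_rates(tab)
  expect_equal(unlist(rates), c(p11 = 0.5, p10 = 0.5, p01 = 0, p00 = 0))
  # empty input
  empty <- filter_cases(cd, character())
  tab0 <- build_contingency_4x2(empty, "drug a", "drug b", "target event a")
  expect_true(all(unlist(tab0) == 0))
  expect_true(is.na(stratum_rates(tab0)$p00))
})

test_that("expected count follows the harmonic no-interaction model", {
  # equal rates: no single-drug effect, g111 = p
  eq <- expected_count(tibble::tibble(p10 = 0.2, p01 = 0.2, p00 = 0.2), 50)
  expect_equal(eq$g111, 0.2, tolerance = 1e-12)
  expect_equal(eq$e111, 10, tolerance = 1e-12)
  # hand evaluation: 1/(1-g) = 1/0.8 + 1/0.7 - 1/0.9
  ec <- expected_count(tibble::tibble(p10 = 0.2, p01 = 0.3, p00 = 0.1), 100)
  expect_equal(ec$g111, 1 - 1 / (1 / 0.8 + 1 / 0.7 - 1 / 0.9),
               tolerance = 1e-12)
  expect_equal(ec$e111, 36.20, tolerance = 0.005)
  # harmonic sum beyond the probability cap is clamped below 1
  hi <- expected_count(tibble::tibble(p10 = 0.9, p01 = 0.9, p00 = 0), 10)
  expect_true(hi$g111 < 1 && hi$g111 >= 0.9)
  # degenerate rate -> non-evaluable
  expect_true(is.na(
    expected_count(tibble::tibble(p10 = 1, p01 = 0.2, p00 = 0.1), 10)$e111
  ))
  expect_true(is.na(
    expected_count(tibble::tibble(p10 = NA_real_, p01 = 0.2, p00 = 0.1),
                   10)$e111
  ))
})

test_that("omega shrinkage and chi statistics match hand evaluation", {
  o <- omega_shrinkage(4, 4)
  expect_equal(o$omega, 0)
  expect_equal(o$omega025, -1.959964 / (log(2) * 2), tolerance = 1e-9)
  expect_false(o$flag)
  # n111 = 0 is non-evaluable and never a signal
  o0 <- omega_shrinkage(0, 5)
  expect_false(o0$evaluable)
  expect_false(o0$flag)

  ch <- chi_square_interaction(10.5, 10)
  expect_equal(ch$chi, 0)
  expect_false(chi_square_interaction(5, 0)$evaluable)
})

test_that("additive and multiplicative statistics detect exact departures", {
  exact_add <- stratum_tbl(0.30, 0.20, 0.15, 0.05)
  a0 <- additive_interaction(exact_add)
  expect_equal(a0$am, 0, tolerance = 1e-12)
  expect_false(a0$flag)
  a1 <- additive_interaction(stratum_tbl(0.40, 0.20, 0.15, 0.05))
  expect_equal(a1$am, 0.10, tolerance = 1e-12)
  expect_true(a1$flag)

  m0 <- multiplicative_interaction(stratum_tbl(0.04, 0.02, 0.02, 0.01))
  expect_equal(m0$mm, 1, tolerance = 1e-12)
  expect_false(m0$flag)
  m1 <- multiplicative_interaction(stratum_tbl(0.08, 0.02, 0.02, 0.01))
  expect_equal(m1$mm, 2, tolerance = 1e-12)
  expect_true(m1$flag)
  # zero denominator -> non-evaluable
  expect_false(
    multiplicative_interaction(stratum_tbl(0.1, 0, 0.02, 0.01))$evaluable
  )
  expect_false(
    additive_interaction(stratum_tbl(0.1, NA_real_, 0.02, 0.01))$evaluable
  )
})

test_that("omega025 and chi are strictly increasing in the observed count", {
  for (e111 in c(1, 10, 80)) {
    om <- vapply(1:500, function(n) omega_shrinkage(n, e111)$omega025,
                 numeric(1))
    ch <- vapply(1:500, function(n) chi_square_interaction(n, e111)$chi,
                 numeric(1))
    expect_true(all(diff(om) > 0))
    expect_true(all(diff(ch) > 0))
  }
})

test_that("omega and chi agree in sign with the observed-expected contrast", {
  set.seed(7)
  for (i in 1:100) {
    n111 <- sample(1:300, 1)
    e111 <- runif(1, 0.5, 300)
    if (n111 + 0.5 < e111 + 0.5) {
      expect_lt(omega_shrinkage(n111, e111)$omega, 0)
    }
    if (n111 < e111 + 0.5) {
      expect_lt(chi_square_interaction(n111, e111)$chi, 0)
    }
  }
})

test_that("composite verdict requires at least two of four flags", {
  mk <- function(om, am, mm, ch) {
    tibble::tibble(omega_flag = om, am_flag = am, mm_flag = mm, chi_flag = ch)
  }
  # a lone additive flag is not a composite signal
  expect_false(evaluate_ddi_signal(mk(FALSE, TRUE, FALSE, FALSE)))
  expect_true(evaluate_ddi_signal(mk(TRUE, TRUE, FALSE, FALSE)))
  expect_false(evaluate_ddi_signal(mk(FALSE, FALSE, FALSE, FALSE)))
  # non-evaluable (NA) models count as not flagged
  expect_false(evaluate_ddi_signal(mk(NA, TRUE, NA, FALSE)))
  expect_true(evaluate_ddi_signal(mk(NA, TRUE, TRUE, NA)))
})

test_that("published drug-pair statistics are reproduced from printed counts", {
  tab <- published_ddi_table()
  for (i in seq_len(nrow(tab))) {
    om <- omega_shrinkage(tab$n111[i], tab$e111[i])$omega025
    ch <- chi_square_interaction(tab$n111[i], tab$e111[i])$chi
    if (tab$exact[i]) {
      expect_equal(round(om, 2), tab$omega025[i],
                   info = paste(tab$pair[i], tab$event[i]))
      expect_equal(round(ch, 2), tab$chi[i],
                   info = paste(tab$pair[i], tab$event[i]))
    } else {
      # printed expected counts are rounded to 2 dp, which limits these rows
      expect_lt(abs(om - tab$omega025[i]), 0.015)
      expect_lt(abs(ch - tab$chi[i]), 0.015)
    }
  }
})

test_that("ddi_statistics composes the four models end to end", {
  cd <- make_pair_data(c(50, 100, 100, 750), c(20, 20, 15, 38))
  tab <- build_contingency_4x2(cd, "drug a", "drug b", "target event a")
  res <- ddi_statistics(tab)
  rates <- stratum_rates(tab)
  expect_equal(res$am, rates$p11 - rates$p10 - rates$p01 + rates$p00)
  expect_equal(res$mm, rates$p11 * rates$p00 / (rates$p10 * rates$p01))
  expect_equal(res$e111,
               expected_count(rates, tab$n11_total)$e111)
  expect_equal(res$signal, evaluate_ddi_signal(res))
  # supplying a published expected count bypasses the internal model
  res2 <- ddi_statistics(tab, e111 = 10)
  expect_equal(res2$e111, 10)
  expect_equal(res2$chi, (tab$n11_event - 10 - 0.5) / sqrt(10))
})
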