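#' Build a 4x2 contingency table for drug-drug interaction screening
#'
#' Partitions the report collection into four exposure strata for a drug
#' pair — both drugs (`11`), drug 1 only (`10`), drug 2 only (`01`),
#' neither (`00`) — and counts, per stratum, the reports with the target
#' event (`n_ij1`) and all reports (`n_ij+`). The observed count in the
#' both-drugs stratum is `n111 = n_111` with denominator `n11plus = n_11+`;
#' the expected count `E111` is filled in later by [expected_count()].
#'
#' @param reports A [case_data] object.
#' @param drug1,drug2 Character vectors of drug names (or functions of the
#'   [case_data] returning case ids) defining the two exposures; they must
#'   be distinct.
#' @param event_terms A [term_set] for the target event.
#' @return A one-row tibble of class `contingency_4x2` with columns
#'   `n11_event`, `n11_total`, `n10_event`, `n10_total`, `n01_event`,
#'   `n01_total`, `n00_event`, `n00_total`.
#' @export
build_contingency_4x2 <- function(reports, drug1, drug2, event_terms) {
  stopifnot(inherits(reports, "case_data"))
  ids1 <- if (is.function(drug1)) as.character(drug1(reports)) else
    exposed_cases(reports, drug1)
  ids2 <- if (is.function(drug2)) as.character(drug2(reports)) else
    exposed_cases(reports, drug2)
  if (identical(sort(ids1), sort(ids2)) && length(ids1)) {
    warn("drug1 and drug2 expose exactly the same cases")
  }
  ids <- reports$demo$case_id
  e1 <- ids %in% ids1
  e2 <- ids %in% ids2
  y <- ids %in% event_cases(reports, event_terms)
  stratum <- dplyr::case_when(
    e1 & e2 ~ "11", e1 & !e2 ~ "10", !e1 & e2 ~ "01", TRUE ~ "00"
  )
  out <- tibble(
    n11_event = sum(y[stratum == "11"]), n11_total = sum(stratum == "11"),
    n10_event = sum(y[stratum == "10"]), n10_total = sum(stratum == "10"),
    n01_event = sum(y[stratum == "01"]), n01_total = sum(stratum == "01"),
    n00_event = sum(y[stratum == "00"]), n00_total = sum(stratum == "00")
  )
  class(out) <- c("contingency_4x2", class(out))
  out
}

#' Per-stratum event reporting proportions
#'
#' `p_ij = n_ij1 / n_ij+` for the four exposure strata of a drug pair.
#' A stratum with no reports leaves its proportion `NA`; the additive and
#' multiplicative models are then non-evaluable.
#'
#' @param table A `contingency_4x2` from [build_contingency_4x2()].
#' @return A one-row tibble with `p11`, `p10`, `p01`, `p00`.
#' @export
stratum_rates <- function(table) {
  stopifnot(is.data.frame(table), nrow(table) == 1)
  rate <- function(ev, tot) if (tot > 0) ev / tot else NA_real_
  tibble(
    p11 = rate(table$n11_event, table$n11_total),
    p10 = rate(table$n10_event, table$n10_total),
    p01 = rate(table$n01_event, table$n01_total),
    p00 = rate(table$n00_event, table$n00_total)
  )
}

#' Expected event count in the both-drugs stratum
#'
#' Under the no-interaction reference model of the omega shrinkage
#' methodology, the expected event probability `g111` for reports on both
#' drugs satisfies
#' `1/(1 - g111) = 1/(1 - p10) + 1/(1 - p01) - 1/(1 - p00)`,
#' clamped into `[max(p10, p01), 1)` so it is a valid probability no
#' smaller than either single-exposure risk. The expected count is
#' `E111 = g111 * n11plus`.
#'
#' @param rates A one-row tibble from [stratum_rates()] (needs `p10`, `p01`,
#'   `p00`).
#' @param n11plus Number of reports in the both-drugs stratum.
#' @return A list with `g111` and `e111`; both `NA` when any required rate
#'   is undefined or equal to 1.
#' @export
#' @examples
#' expected_count(tibble::tibble(p10 = 0.2, p01 = 0.3, p00 = 0.1), 100)
expected_count <- function(rates, n11plus) {
  p10 <- rates$p10; p01 <- rates$p01; p00 <- rates$p00
  if (anyNA(c(p10, p01, p00)) || any(c(p10, p01, p00) >= 1)) {
    return(list(g111 = NA_real_, e111 = NA_real_))
  }
  inv <- 1 / (1 - p10) + 1 / (1 - p01) - 1 / (1 - p00)
  # inv >= 1 whenever p00 <= min(p10, p01); the clamp guards the general case
  g <- if (inv <= 0) 1 else 1 - 1 / inv
  g <- min(max(g, p10, p01), 1 - .Machine$double.eps)
  list(g111 = g, e111 = g * n11plus)
}

#' Omega shrinkage measure for a drug pair
#'
#' `Omega = log2((n111 + 0.5) / (E111 + 0.5))`, a shrinkage-regularized
#' observed-to-expected log ratio for the both-drugs stratum, with lower
#' credibility bound `Omega025 = Omega - 1.959964 / (ln(2) * sqrt(n111))`.
#' `Omega025 > 0` flags an interaction signal. With `n111 = 0` the bound is
#' undefined and the pair is non-evaluable (such pairs are excluded from
#' screening).
#'
#' @param n111 Observed target-event count among reports on both drugs.
#' @param e111 Expected count from [expected_count()] (or supplied
#'   externally).
#' @return A one-row tibble: `omega`, `omega025`, `evaluable`, `flag`.
#' @export
#' @examples
#' omega_shrinkage(72, 79.17)
omega_shrinkage <- function(n111, e111) {
  if (is.na(n111) || is.na(e111) || n111 < 1) {
    return(tibble(omega = NA_real_, omega025 = NA_real_,
                  evaluable = FALSE, flag = FALSE))
  }
  omega <- log2((n111 + 0.5) / (e111 + 0.5))
  omega025 <- omega - Z975 / (log(2) * sqrt(n111))
  tibble(omega = omega, omega025 = omega025,
         evaluable = TRUE, flag = omega025 > 0)
}

#' Additive interaction statistic
#'
#' Departure from risk additivity: `AM = p11 - p10 - p01 + p00`. Under no
#' interaction the excess risk of the pair equals the sum of the single-drug
#' excess risks and AM is 0; `AM > 0` flags a signal. A point estimate with
#' no interval.
#'
#' @param rates One-row tibble from [stratum_rates()].
#' @return One-row tibble: `am`, `evaluable`, `flag`.
#' @export
additive_interaction <- function(rates) {
  ps <- c(rates$p11, rates$p10, rates$p01, rates$p00)
  if (anyNA(ps)) {
    return(tibble(am = NA_real_, evaluable = FALSE, flag = FALSE))
  }
  am <- ps[1] - ps[2] - ps[3] + ps[4]
  tibble(am = am, evaluable = TRUE, flag = am > 0)
}

#' Multiplicative interaction statistic
#'
#' Departure from relative-risk multiplicativity:
#' `MM = (p11 * p00) / (p10 * p01)`. Under no interaction the relative risk
#' of the combination equals the product of the single-drug relative risks
#' and MM is 1; `MM > 1` flags a signal.
#'
#' @param rates One-row tibble from [stratum_rates()].
#' @return One-row tibble: `mm`, `evaluable`, `flag`.
#' @export
multiplicative_interaction <- function(rates) {
  ps <- c(rates$p11, rates$p10, rates$p01, rates$p00)
  if (anyNA(ps) || rates$p10 <= 0 || rates$p01 <= 0) {
    return(tibble(mm = NA_real_, evaluable = FALSE, flag = FALSE))
  }
  mm <- (rates$p11 * rates$p00) / (rates$p10 * rates$p01)
  tibble(mm = mm, evaluable = TRUE, flag = mm > 1)
}

#' Chi-square interaction statistic
#'
#' A continuity-corrected standardized residual of the observed both-drugs
#' event count against its expectation:
#' `chi = (n111 - E111 - 0.5) / sqrt(E111)`, flagged when `chi > 2`.
#'
#' @inheritParams omega_shrinkage
#' @return One-row tibble: `chi`, `evaluable`, `flag`.
#' @export
#' @examples
#' chi_square_interaction(16, 13.99)
chi_square_interaction <- function(n111, e111) {
  if (is.na(n111) || is.na(e111) || e111 <= 0) {
    return(tibble(chi = NA_real_, evaluable = FALSE, flag = FALSE))
  }
  chi <- (n111 - e111 - 0.5) / sqrt(e111)
  tibble(chi = chi, evaluable = TRUE, flag = chi > 2)
}

#' All four interaction statistics and the composite verdict for one pair
#'
#' Convenience wrapper: computes stratum rates, the expected count, the
#' four interaction statistics and the two-of-four composite rule from a
#' 4x2 table. `e111` may be supplied directly (for example from a published
#' table) to bypass [expected_count()].
#'
#' @param table A `contingency_4x2`.
#' @param e111 Optional externally supplied expected count.
#' @return One-row tibble of class `ddi_result`: stratum counts, `e111`,
#'   `omega`, `omega025`, `am`, `mm`, `chi`, per-model flags
#'   (`omega_flag`, `am_flag`, `mm_flag`, `chi_flag`), evaluability flags
#'   and `signal` (composite).
#' @export
ddi_statistics <- function(table, e111 = NULL) {
  rates <- stratum_rates(table)
  n111 <- table$n11_event
  if (is.null(e111)) {
    e111 <- expected_count(rates, table$n11_total)$e111
  }
  r_om <- omega_shrinkage(n111, e111)
  r_am <- additive_interaction(rates)
  r_mm <- multiplicative_interaction(rates)
  r_ch <- chi_square_interaction(n111, e111)
  res <- tibble(
    n11_total = table$n11_total, n111 = n111, e111 = e111,
    omega = r_om$omega, omega025 = r_om$omega025, omega_flag = r_om$flag,
    omega_evaluable = r_om$evaluable,
    am = r_am$am, am_flag = r_am$flag, am_evaluable = r_am$evaluable,
    mm = r_mm$mm, mm_flag = r_mm$flag, mm_evaluable = r_mm$evaluable,
    chi = r_ch$chi, chi_flag = r_ch$flag, chi_evaluable = r_ch$evaluable
  )
  res$signal <- evaluate_ddi_signal(res)
  class(res) <- c("ddi_result", class(res))
  res
}

#' Composite two-of-four interaction verdict
#'
#' A drug pair is a positive interaction signal when at least two of the
#' four models flag it. Non-evaluable models count as not flagged, so a
#' pair with one evaluable flagging model is never positive.
#'
#' @param result A one-row `ddi_result` tibble (or any data frame with the
#'   four `*_flag` columns).
#' @return Single logical.
#' @export
evaluate_ddi_signal <- function(result) {
  flags <- c(result$omega_flag, result$am_flag,
             result$mm_flag, result$chi_flag)
  sum(flags, na.rm = TRUE) >= 2
}

#' Screen drug pairs for interaction signals
#'
#' For one anchor drug (typically the thrombolytic) against each partner
#' exposure, builds the 4x2 table and computes all four interaction
#' statistics plus the composite verdict, mirroring the usual published
#' layout (one row per partner). Pairs with `n111 = 0` are excluded from
#' evaluation (reported with `evaluable` columns FALSE).
#'
#' @param reports A [case_data] object.
#' @param drug1 Character vector of drug names (or function) for the anchor
#'   exposure.
#' @param partners Named list of partner exposures (drug-name vectors or
#'   functions).
#' @param event_sets Named list of [term_set]s.
#' @return Tibble, one row per partner x event set.
#' @export
screen_ddi_signals <- function(reports, drug1, partners, event_sets) {
  grid <- tidyr::expand_grid(
    partner = names(partners), event = names(event_sets)
  )
  purrr::pmap_dfr(grid, function(partner, event) {
    tab <- build_contingency_4x2(reports, drug1, partners[[partner]],
                                 event_sets[[event]])
    res <- ddi_statistics(tab)
    dplyr::bind_cols(tibble(partner = partner, event = event), res)
  })
}
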