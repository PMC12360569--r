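# two-sided 97.5% normal quantile, fixed for bit-stable results
Z975 <- 1.959964

#' Build a 2x2 contingency table for adverse-event signal detection
#'
#' Cross-tabulates case-level drug exposure against case-level event
#' occurrence over the whole report collection passed in. Each case falls in
#' exactly one cell:
#'
#' |                  | target event | other events |
#' |------------------|--------------|--------------|
#' | exposed          | `n11`        | `n10`        |
#' | not exposed      | `n01`        | `n00`        |
#'
#' @param reports A [case_data] object (the denominator population; the
#'   caller chooses the scope).
#' @param exposure Either a character vector of drug names (any role counts
#'   as exposure) or a function taking the [case_data] and returning the
#'   exposed case ids.
#' @param event_terms A [term_set] (or character vector of PTs) defining the
#'   target event.
#' @return A one-row tibble of class `contingency_2x2` with integer columns
#'   `n11`, `n10`, `n01`, `n00`.
#' @export
build_contingency_2x2 <- function(reports, exposure, event_terms) {
  stopifnot(inherits(reports, "case_data"))
  if (n_cases(reports) == 0) abort("no reports in scope")
  exposed <- if (is.function(exposure)) {
    as.character(exposure(reports))
  } else {
    exposed_cases(reports, exposure)
  }
  ev <- event_cases(reports, event_terms)
  ids <- reports$demo$case_id
  e <- ids %in% exposed
  y <- ids %in% ev
  out <- tibble(
    n11 = sum(e & y), n10 = sum(e & !y),
    n01 = sum(!e & y), n00 = sum(!e & !y)
  )
  class(out) <- c("contingency_2x2", class(out))
  out
}

as_2x2 <- function(table) {
  if (is.data.frame(table)) {
    stopifnot(all(c("n11", "n10", "n01", "n00") %in% names(table)),
              nrow(table) == 1)
    lapply(table[c("n11", "n10", "n01", "n00")], as.numeric)
  } else {
    stopifnot(is.numeric(table), length(table) == 4)
    setNames(as.list(as.numeric(table)), c("n11", "n10", "n01", "n00"))
  }
}

#' Reporting odds ratio with 95% confidence interval
#'
#' The reporting odds ratio (ROR) compares the odds of the target event
#' among reports mentioning the target drug with the odds among all other
#' reports: `ROR = (n11 * n00) / (n10 * n01)`. The 95% CI is
#' `exp(log(ROR) +/- z * sqrt(1/n11 + 1/n10 + 1/n01 + 1/n00))` with
#' `z = 1.959964`. With any zero cell the statistic is undefined and the
#' estimate is returned non-evaluable (no continuity correction by default;
#' set `correction = TRUE` for a Haldane 0.5 correction).
#'
#' A non-evaluable estimate never contributes a positive signal.
#'
#' @param table A `contingency_2x2` (from [build_contingency_2x2()]) or a
#'   numeric vector `c(n11, n10, n01, n00)`.
#' @param correction Add 0.5 to every cell when any cell is zero
#'   (default `FALSE`).
#' @return A one-row tibble: `statistic` (`"ROR"`), `estimate`, `conf.low`,
#'   `conf.high`, `evaluable`, `signal` (lower CI bound > 1).
#' @export
#' @examples
#' compute_ror(c(10, 90, 100, 9900))
compute_ror <- function(table, correction = FALSE) {
  n <- as_2x2(table)
  cells <- c(n$n11, n$n10, n$n01, n$n00)
  if (any(cells == 0) && correction) cells <- cells + 0.5
  if (any(cells == 0)) {
    return(tibble(statistic = "ROR", estimate = NA_real_,
                  conf.low = NA_real_, conf.high = NA_real_,
                  evaluable = FALSE, signal = FALSE))
  }
  ror <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  lo <- exp(log(ror) - Z975 * se)
  hi <- exp(log(ror) + Z975 * se)
  tibble(statistic = "ROR", estimate = ror, conf.low = lo, conf.high = hi,
         evaluable = TRUE, signal = lo > 1)
}

#' Bayesian information component (BCPNN) with 95% credibility interval
#'
#' The information component (IC) of the Bayesian confidence propagation
#' neural network measures the log2 disproportion between the observed and
#' expected joint reporting probability of a drug-event pair, shrunk toward
#' zero by prior pseudo-counts so that sparse cells do not explode:
#'
#' \deqn{E(IC) = \log_2 \frac{(n_{11}+\gamma_{11})(n_{++}+\alpha)(n_{++}+\beta)}
#'   {(n_{++}+\gamma)(n_{1+}+\alpha_1)(n_{+1}+\beta_1)}}
#'
#' with the standard three-term variance
#'
#' \deqn{V(IC) = \frac{1}{\ln^2 2}\left[
#'   \frac{n_{++}-n_{11}+\gamma-\gamma_{11}}{(n_{11}+\gamma_{11})(1+n_{++}+\gamma)} +
#'   \frac{n_{++}-n_{1+}+\alpha-\alpha_1}{(n_{1+}+\alpha_1)(1+n_{++}+\alpha)} +
#'   \frac{n_{++}-n_{+1}+\beta-\beta_1}{(n_{+1}+\beta_1)(1+n_{++}+\beta)}\right]}
#'
#' and interval `E(IC) +/- 2 sqrt(V(IC))`. The default priors are
#' `gamma11 = 1`, `alpha1 = beta1 = 1`, `alpha = beta = 2`, with `gamma`
#' recomputed per table as
#' `gamma11 * (n++ + alpha)(n++ + beta) / ((n1+ + alpha1)(n+1 + beta1))`
#' so that E(IC) is zero under independence. Thanks to the pseudo-counts the
#' IC is defined even when `n11 = 0`.
#'
#' @inheritParams compute_ror
#' @param priors Named list overriding `gamma11`, `alpha1`, `beta1`,
#'   `alpha`, `beta`.
#' @return A one-row tibble: `statistic` (`"IC"`), `estimate` (bits),
#'   `conf.low`, `conf.high`, `evaluable`, `signal` (lower bound > 0).
#' @export
#' @examples
#' compute_ic(c(10, 10, 20, 960))
compute_ic <- function(table, priors = list()) {
  n <- as_2x2(table)
  p <- utils::modifyList(
    list(gamma11 = 1, alpha1 = 1, beta1 = 1, alpha = 2, beta = 2), priors
  )
  n11 <- n$n11
  n1p <- n$n11 + n$n10
  np1 <- n$n11 + n$n01
  npp <- n$n11 + n$n10 + n$n01 + n$n00
  if (npp <= 0) abort("IC requires a non-empty table")
  gamma <- p$gamma11 * (npp + p$alpha) * (npp + p$beta) /
    ((n1p + p$alpha1) * (np1 + p$beta1))
  eic <- log2(
    (n11 + p$gamma11) * (npp + p$alpha) * (npp + p$beta) /
      ((npp + gamma) * (n1p + p$alpha1) * (np1 + p$beta1))
  )
  vic <- (1 / log(2))^2 * (
    (npp - n11 + gamma - p$gamma11) / ((n11 + p$gamma11) * (1 + npp + gamma)) +
    (npp - n1p + p$alpha - p$alpha1) / ((n1p + p$alpha1) * (1 + npp + p$alpha)) +
    (npp - np1 + p$beta - p$beta1) / ((np1 + p$beta1) * (1 + npp + p$beta))
  )
  lo <- eic - 2 * sqrt(vic)
  hi <- eic + 2 * sqrt(vic)
  tibble(statistic = "IC", estimate = eic, conf.low = lo, conf.high = hi,
         evaluable = TRUE, signal = lo > 0)
}

#' Conjunction rule for an adverse-event signal
#'
#' A drug-event pair is a positive adverse-event signal only when both
#' indices agree: the ROR is evaluable with its 95% CI lower bound above 1,
#' and the IC 95% interval lower bound is above 0.
#'
#' @param ror,ic One-row tibbles from [compute_ror()] and [compute_ic()]
#'   for the same table.
#' @return Single logical.
#' @export
evaluate_ae_signal <- function(ror, ic) {
  stopifnot(ror$statistic == "ROR", ic$statistic == "IC")
  isTRUE(ror$evaluable) && isTRUE(ror$conf.low > 1) &&
    isTRUE(ic$evaluable) && isTRUE(ic$conf.low > 0)
}

#' Screen drug classes for adverse-event signals
#'
#' Runs [build_contingency_2x2()], [compute_ror()] and [compute_ic()] for
#' each exposure (typically a combination such as thrombolytic + one
#' partner class) against each event term set, and applies the conjunction
#' signal rule. Estimates are reported at full precision; round to 2
#' decimals for presentation.
#'
#' @param reports A [case_data] object.
#' @param exposures Named list; each element is a character vector of drug
#'   names (the case must be exposed to at least one of them) or a function
#'   of the [case_data] returning exposed case ids.
#' @param event_sets Named list of [term_set]s.
#' @return A tibble with one row per exposure x event set: counts, ROR and
#'   IC with intervals, and `signal`.
#' @export
screen_ae_signals <- function(reports, exposures, event_sets) {
  stopifnot(length(exposures) > 0, length(event_sets) > 0)
  grid <- tidyr::expand_grid(
    exposure = names(exposures), event = names(event_sets)
  )
  purrr::pmap_dfr(grid, function(exposure, event) {
    tab <- build_contingency_2x2(reports, exposures[[exposure]],
                                 event_sets[[event]])
    r_ror <- compute_ror(tab)
    r_ic <- compute_ic(tab)
    tibble(
      exposure = exposure, event = event,
      n11 = tab$n11, n10 = tab$n10, n01 = tab$n01, n00 = tab$n00,
      ror = r_ror$estimate, ror_low = r_ror$conf.low,
      ror_high = r_ror$conf.high,
      ic = r_ic$estimate, ic_low = r_ic$conf.low, ic_high = r_ic$conf.high,
      signal = evaluate_ae_signal(r_ror, r_ic)
    )
  })
}
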