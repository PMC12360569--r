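#' Configure the spontaneous-report simulator
#'
#' Builds a validated configuration for [simulate_reports()]. Each simulated
#' report independently samples drug exposures from per-drug marginal
#' probabilities, then a Bernoulli target event whose probability is the
#' baseline times the relative reporting rate of every exposed drug, with an
#' optional planted interaction for one drug pair:
#'
#' * `additive_excess`: the both-drugs event probability is
#'   `p00 + (p10 - p00) + (p01 - p00) + magnitude`, i.e. risk-additive when
#'   `magnitude = 0`;
#' * `multiplicative_factor`: it is
#'   `p00 * (p10/p00) * (p01/p00) * magnitude`, i.e. relative-risk
#'   multiplicative when `magnitude = 1`.
#'
#' These are exactly the null structures of the additive and multiplicative
#' interaction statistics, so a non-null magnitude is a true planted
#' interaction that those statistics should recover. When drugs outside the
#' interaction pair are exposed their relative rates multiply on top of the
#' pair-stratum probability. Probabilities are clamped to `[0, 1]`.
#'
#' @param n_reports Number of reports to simulate.
#' @param drugs Tibble/data frame with columns `name` and `p_exposure`, or a
#'   named numeric vector of exposure probabilities.
#' @param baseline_event_prob Event probability with no exposures. Default
#'   0.001, the rare-event regime typical of a single preferred term in a
#'   large spontaneous-report database.
#' @param rr Named numeric vector of per-drug relative reporting rates
#'   (>= 0); drugs not named have rate 1.
#' @param interaction `NULL`, or a list with `drug_a`, `drug_b`,
#'   `mode` (`"additive_excess"` or `"multiplicative_factor"`) and
#'   `magnitude`.
#' @param missing_date_prob Probability that an administration or onset date
#'   is missing (applied independently to each). Default 0.2.
#' @param outcome_probs Named probability vector over [outcome_levels()]
#'   plus `"unknown"`; must sum to 1.
#' @param tto_mean Mean of the geometric (non-negative integer) day count
#'   from first administration to event onset. Default 2 days.
#' @param event_pt Preferred term recorded for simulated target events;
#'   defaults to the first placeholder term of the built-in `ht` set so that
#'   simulated data matches [default_term_sets()] out of the box.
#' @param seed Integer seed; the same config and seed give byte-identical
#'   datasets.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(n_reports,
                       drugs,
                       baseline_event_prob = 0.001,
                       rr = NULL,
                       interaction = NULL,
                       missing_date_prob = 0.2,
                       outcome_probs = c(recovery = 0.08, remission = 0.22,
                                         no_recovery = 0.22,
                                         after_effect = 0.19, death = 0.2,
                                         unknown = 0.09),
                       tto_mean = 2,
                       event_pt = "haemorrhagic transformation placeholder 1",
                       seed = 1L) {
  if (is.numeric(drugs) && !is.null(names(drugs))) {
    drugs <- tibble(name = names(drugs), p_exposure = unname(drugs))
  }
  drugs <- as_tibble(drugs)
  stopifnot(all(c("name", "p_exposure") %in% names(drugs)))
  drugs$name <- normalize_drug_name(drugs$name)
  if (anyDuplicated(drugs$name)) abort("duplicate drug names in config")
  check_prob <- function(p, what) {
    if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
      abort(sprintf("%s must be in [0, 1]", what))
    }
  }
  check_prob(drugs$p_exposure, "exposure probabilities")
  check_prob(baseline_event_prob, "baseline_event_prob")
  check_prob(missing_date_prob, "missing_date_prob")
  rr_full <- setNames(rep(1, nrow(drugs)), drugs$name)
  if (!is.null(rr)) {
    names(rr) <- normalize_drug_name(names(rr))
    unknown <- setdiff(names(rr), drugs$name)
    if (length(unknown)) {
      abort(sprintf("rr names not in drug list: %s",
                    paste(unknown, collapse = ", ")))
    }
    if (any(rr < 0)) abort("relative reporting rates must be >= 0")
    rr_full[names(rr)] <- rr
  }
  if (!is.null(interaction)) {
    need <- c("drug_a", "drug_b", "mode", "magnitude")
    if (!all(need %in% names(interaction))) {
      abort("interaction needs drug_a, drug_b, mode, magnitude")
    }
    interaction$drug_a <- normalize_drug_name(interaction$drug_a)
    interaction$drug_b <- normalize_drug_name(interaction$drug_b)
    if (!all(c(interaction$drug_a, interaction$drug_b) %in% drugs$name)) {
      abort("interaction drugs must be in the drug list")
    }
    if (!interaction$mode %in% c("additive_excess", "multiplicative_factor")) {
      abort("interaction mode must be additive_excess or multiplicative_factor")
    }
  }
  allowed <- c(outcome_levels(), "unknown")
  if (!all(names(outcome_probs) %in% allowed) ||
      abs(sum(outcome_probs) - 1) > 1e-8) {
    abort("outcome_probs must be named over the outcome categories and sum to 1")
  }
  if (tto_mean < 0) abort("tto_mean must be non-negative")
  structure(
    list(n_reports = as.integer(n_reports), drugs = drugs,
         baseline_event_prob = baseline_event_prob, rr = rr_full,
         interaction = interaction, missing_date_prob = missing_date_prob,
         outcome_probs = outcome_probs, tto_mean = tto_mean,
         event_pt = normalize_pt(event_pt), seed = as.integer(seed)),
    class = "sim_config"
  )
}

# planted pair-stratum event probabilities implied by a config
planted_stratum_probs <- function(config) {
  p00 <- config$baseline_event_prob
  if (is.null(config$interaction)) {
    return(tibble(p00 = p00, p10 = NA_real_, p01 = NA_real_, p11 = NA_real_))
  }
  ia <- config$interaction
  p10 <- min(p00 * config$rr[[ia$drug_a]], 1)
  p01 <- min(p00 * config$rr[[ia$drug_b]], 1)
  p11 <- switch(ia$mode,
    additive_excess = p00 + (p10 - p00) + (p01 - p00) + ia$magnitude,
    multiplicative_factor = if (p00 > 0) {
      p00 * (p10 / p00) * (p01 / p00) * ia$magnitude
    } else 0
  )
  tibble(p00 = p00, p10 = p10, p01 = p01, p11 = min(max(p11, 0), 1))
}

#' Simulate a spontaneous-report dataset with planted structure
#'
#' Draws `n_reports` independent reports under a [sim_config()]: drug
#' exposures, a Bernoulli target event per the planted stratum
#' probabilities, an index administration date, a geometric time-to-onset
#' for events, independent date missingness, demographic attributes, and an
#' outcome category per event record. Reports without the target event get
#' one background reaction record so every report carries at least one
#' adverse event, as in real spontaneous-report tables.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements
#'   * `reports`: a [case_data] object;
#'   * `truth`: a `sim_truth` list with the planted stratum probabilities
#'     (`p00`, `p10`, `p01`, `p11` for the interaction pair when one is
#'     configured), realized per-drug and pair exposure counts, realized
#'     stratum event counts, the interaction magnitude, and the count of
#'     reports whose event probability had to be clamped.
#' @export
simulate_reports <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_reports
  set.seed(config$seed)

  drugs <- config$drugs
  expo <- matrix(runif(n * nrow(drugs)) < rep(drugs$p_exposure, each = n),
                 nrow = n)
  colnames(expo) <- drugs$name

  ia <- config$interaction
  planted <- planted_stratum_probs(config)
  # per-report event probability
  log_rr <- log(pmax(config$rr, .Machine$double.xmin))
  if (is.null(ia)) {
    p <- config$baseline_event_prob *
      exp(expo %*% log_rr[drugs$name])[, 1]
  } else {
    pair <- c(ia$drug_a, ia$drug_b)
    others <- setdiff(drugs$name, pair)
    r_other <- if (length(others)) {
      exp(expo[, others, drop = FALSE] %*% log_rr[others])[, 1]
    } else rep(1, n)
    ea <- expo[, ia$drug_a]; eb <- expo[, ia$drug_b]
    p_pair <- ifelse(ea & eb, planted$p11,
              ifelse(ea, planted$p10,
              ifelse(eb, planted$p01, planted$p00)))
    p <- p_pair * r_other
  }
  n_clamped <- sum(p > 1 | p < 0)
  if (n_clamped > 0) {
    inform(sprintf("simulate_reports: clamped %d event probabilit(ies) to [0, 1]",
                   n_clamped))
  }
  p <- pmin(pmax(p, 0), 1)
  event <- runif(n) < p

  case_id <- sprintf("sim%07d", seq_len(n))
  sex <- sample(c("male", "female", "unknown"), n, replace = TRUE,
                prob = c(0.48, 0.48, 0.04))
  decades <- c("under 10s", "10s", "20s", "30s", "40s", "50s", "60s",
               "70s", "80s", "90s", "100s")
  age_group <- sample(c(decades, NA_character_), n, replace = TRUE,
                      prob = c(rep(0.085, 11), 0.065))
  demo <- tibble(case_id = case_id, sex = sex, age_group = age_group)

  # drug rows: one per exposed drug, index date per report
  index_date <- as.Date("2020-01-01") + sample.int(365, n, replace = TRUE) - 1
  which_expo <- which(expo, arr.ind = TRUE)
  admin_date <- index_date[which_expo[, 1]]
  admin_date[runif(nrow(which_expo)) < config$missing_date_prob] <- NA
  drug_tab <- tibble(
    case_id = case_id[which_expo[, 1]],
    drug_name = drugs$name[which_expo[, 2]],
    role = sample(c("suspected", "concomitant", "interaction"),
                  nrow(which_expo), replace = TRUE, prob = c(0.6, 0.3, 0.1)),
    first_admin_date = admin_date
  )
  drug_tab <- drug_tab[order(drug_tab$case_id, drug_tab$drug_name), ]

  # reaction rows: target event where drawn, one background PT otherwise
  ev_idx <- which(event)
  tto <- if (config$tto_mean > 0) {
    rgeom(length(ev_idx), prob = 1 / (1 + config$tto_mean))
  } else rep(0L, length(ev_idx))
  onset <- index_date[ev_idx] + tto
  onset[runif(length(ev_idx)) < config$missing_date_prob] <- NA
  draw_outcome <- function(k) {
    o <- sample(names(config$outcome_probs), k, replace = TRUE,
                prob = config$outcome_probs)
    o[o == "unknown"] <- NA_character_
    o
  }
  reac_event <- tibble(
    case_id = case_id[ev_idx], pt_term = config$event_pt,
    onset_date = onset, outcome = draw_outcome(length(ev_idx))
  )
  bg_idx <- which(!event)
  reac_bg <- tibble(
    case_id = case_id[bg_idx],
    pt_term = "background adverse event placeholder",
    onset_date = as.Date(ifelse(runif(length(bg_idx)) < config$missing_date_prob,
                                NA, index_date[bg_idx]),
                         origin = "1970-01-01"),
    outcome = draw_outcome(length(bg_idx))
  )
  reac <- bind_rows(reac_event, reac_bg)
  reac <- reac[order(reac$case_id), ]

  hist_tab <- tibble(case_id = character(), pt_term = character())

  reports <- case_data(demo, drug_tab, reac, hist_tab)

  truth <- structure(list(
    planted = planted,
    magnitude = if (is.null(ia)) NA_real_ else ia$magnitude,
    mode = if (is.null(ia)) NA_character_ else ia$mode,
    exposure_counts = setNames(colSums(expo), drugs$name),
    pair_counts = if (is.null(ia)) NULL else {
      ea <- expo[, ia$drug_a]; eb <- expo[, ia$drug_b]
      c(n11 = sum(ea & eb), n10 = sum(ea & !eb),
        n01 = sum(!ea & eb), n00 = sum(!ea & !eb))
    },
    stratum_event_counts = if (is.null(ia)) NULL else {
      ea <- expo[, ia$drug_a]; eb <- expo[, ia$drug_b]
      c(n111 = sum(event[ea & eb]), n101 = sum(event[ea & !eb]),
        n011 = sum(event[!ea & eb]), n001 = sum(event[!ea & !eb]))
    },
    n_events = sum(event), n_clamped = n_clamped
  ), class = "sim_truth")

  list(reports = reports, truth = truth)
}

#' Detection-rate experiment over simulation replicates
#'
#' Repeats [simulate_reports()] `n_replicates` times (seeds
#' `config$seed + 0:(n_replicates - 1)`), runs the four drug-drug
#' interaction statistics and the composite rule on the configured
#' interaction pair each time, and tabulates per-model positive rates with
#' Monte-Carlo standard errors. Used to study operating characteristics,
#' e.g. that the omega shrinkage model is the most conservative of the four
#' under a null interaction.
#'
#' @param config A [sim_config()] with a configured `interaction` pair (use
#'   `magnitude = 0` additive or `magnitude = 1` multiplicative for a null).
#' @param n_replicates Number of simulation replicates (>= 1).
#' @param event_terms Term set identifying the simulated target event;
#'   defaults to the config's `event_pt`.
#' @return A tibble with one row per model (`omega`, `additive`,
#'   `multiplicative`, `chi`, `composite`): `positives`, `evaluable`
#'   (replicates where the model could be computed), `rate`
#'   (positives / evaluable) and `mc_se`; plus attribute `"replicates"`, a
#'   tibble of per-replicate statistics.
#' @export
recovery_experiment <- function(config, n_replicates,
                                event_terms = NULL) {
  stopifnot(inherits(config, "sim_config"), n_replicates >= 1)
  if (is.null(config$interaction)) {
    abort("recovery_experiment needs a configured interaction pair")
  }
  if (is.null(event_terms)) event_terms <- term_set("target", config$event_pt)
  ia <- config$interaction
  reps <- purrr::map_dfr(seq_len(n_replicates), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    sim <- simulate_reports(cfg)
    tab <- build_contingency_4x2(sim$reports, ia$drug_a, ia$drug_b,
                                 event_terms)
    res <- ddi_statistics(tab)
    dplyr::bind_cols(tibble(replicate = i), res)
  })
  rate_row <- function(model, flag, evaluable) {
    k <- sum(flag & evaluable)
    m <- sum(evaluable)
    r <- if (m > 0) k / m else NA_real_
    tibble(model = model, positives = k, evaluable = m, rate = r,
           mc_se = if (m > 0) sqrt(r * (1 - r) / m) else NA_real_)
  }
  out <- bind_rows(
    rate_row("omega", reps$omega_flag, reps$omega_evaluable),
    rate_row("additive", reps$am_flag, reps$am_evaluable),
    rate_row("multiplicative", reps$mm_flag, reps$mm_evaluable),
    rate_row("chi", reps$chi_flag, reps$chi_evaluable),
    rate_row("composite", reps$signal, rep(TRUE, nrow(reps)))
  )
  attr(out, "replicates") <- reps
  out
}
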