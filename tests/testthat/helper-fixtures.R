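# Fixtures built in code: a small hand-written four-table dataset and the
# published drug-pair screening table used as a golden suite.

# 3 cases, 5 drug rows, 4 event rows, 2 history rows
fixture_case_data <- function() {
  case_data(
    demo = data.frame(
      case_id = c("c1", "c2", "c3"),
      sex = c("male", "female", "unknown"),
      age_group = c("60s", "70s", NA)
    ),
    drug = data.frame(
      case_id = c("c1", "c1", "c2", "c2", "c3"),
      drug_name = c("alteplase", "Aspirin", "alteplase",
                    "warfarin potassium", "aspirin"),
      role = c("suspected", "concomitant", "suspected", "interaction",
               "suspected"),
      first_admin_date = as.Date(c("2020-01-01", "2020-01-01", "2020-02-01",
                                   NA, "2020-03-01"))
    ),
    reac = data.frame(
      case_id = c("c1", "c1", "c2", "c3"),
      pt_term = c("target event a", "target event b", "target event a",
                  "some other event"),
      onset_date = as.Date(c("2020-01-02", "2020-01-05", NA, "2020-03-02")),
      outcome = c("recovery", "death", "no_recovery", NA)
    ),
    hist = data.frame(
      case_id = c("c1", "c2"),
      pt_term = c("hypertension placeholder 1", "old history term")
    )
  )
}

fixture_event_terms <- function() {
  term_set("target", c("target event a", "target event b"))
}

# published drug-pair screening table: observed and expected counts with the
# printed omega025 and chi values; `exact` marks rows whose printed inputs
# carry enough precision to reproduce the printed statistic at 2 dp
published_ddi_table <- function() {
  tibble::tribble(
    ~pair,         ~event, ~n111, ~e111,   ~omega025, ~chi,   ~exact,
    "aspirin",      "HT",   72,    79.17,  -0.47,     -0.86,  TRUE,
    "P2Y12",        "HT",   37,    40.23,  -0.58,     -0.59,  TRUE,
    "cilostazol",   "HT",   10,    19.99,  -1.86,     -2.35,  TRUE,
    "ozagrel",      "HT",   14,    14.53,  -0.81,     -0.27,  TRUE,
    "others",       "HT",   3,     5.37,   -2.38,     -1.23,  FALSE,
    "DOAC",         "HT",   10,    16.70,  -1.61,     -1.76,  TRUE,
    "warfarin",     "HT",   104,   101.24, -0.24,     0.22,   TRUE,
    "heparin",      "HT",   92,    113.31, -0.59,     -2.05,  TRUE,
    "argatroban",   "HT",   19,    25.57,  -1.07,     -1.40,  TRUE,
    "aspirin",      "ICH",  53,    55.24,  -0.45,     -0.37,  TRUE,
    "P2Y12",        "ICH",  30,    28.37,  -0.44,     0.21,   TRUE,
    "cilostazol",   "ICH",  16,    13.99,  -0.52,     0.40,   TRUE,
    "ozagrel",      "ICH",  8,     11.23,  -1.47,     -1.11,  FALSE,
    "others",       "ICH",  4,     3.63,   -1.29,     -0.07,  TRUE,
    "DOAC",         "ICH",  13,    14.35,  -0.92,     -0.49,  TRUE,
    "warfarin",     "ICH",  49,    77.26,  -1.06,     -3.27,  TRUE,
    "heparin",      "ICH",  53,    81.05,  -1.00,     -3.17,  TRUE,
    "argatroban",   "ICH",  8,     18.42,  -2.15,     -2.54,  TRUE
  )
}

# published time-to-onset distributions; the 4-20 day bin is placed at day 4,
# which cannot move the median (it sits in the day 0/1 mass)
published_tto_days <- function(event = c("HT", "ICH")) {
  event <- match.arg(event)
  if (event == "HT") {
    c(rep(0L, 62), rep(1L, 197), rep(2L, 24), rep(3L, 8), rep(4L, 17),
      rep(NA_integer_, 28))
  } else {
    c(rep(0L, 103), rep(1L, 72), rep(2L, 6), rep(3L, 2), rep(4L, 2),
      rep(NA_integer_, 45))
  }
}

published_outcomes <- function(event = c("HT", "ICH")) {
  event <- match.arg(event)
  if (event == "HT") {
    c(rep("recovery", 24), rep("remission", 70), rep("no_recovery", 69),
      rep("after_effect", 59), rep("death", 85), rep(NA_character_, 29))
  } else {
    c(rep("recovery", 11), rep("remission", 20), rep("no_recovery", 28),
      rep("after_effect", 74), rep("death", 54), rep(NA_character_, 45))
  }
}

# random small report collection for oracle-equivalence checks
random_case_data <- function(n, p_expo = 0.3, p_event = 0.3) {
  ids <- sprintf("r%04d", seq_len(n))
  exposed <- runif(n) < p_expo
  event <- runif(n) < p_event
  drug <- data.frame(
    case_id = c(ids[exposed], ids),
    drug_name = c(rep("drug x", sum(exposed)), rep("filler drug", n)),
    role = "suspected",
    first_admin_date = as.Date("2021-06-01")
  )
  reac <- data.frame(
    case_id = ids,
    pt_term = ifelse(event, "target event a", "some other event"),
    onset_date = as.Date("2021-06-02"),
    outcome = NA_character_
  )
  demo <- data.frame(case_id = ids, sex = "female", age_group = "50s")
  hist <- data.frame(case_id = character(), pt_term = character())
  list(reports = case_data(demo, drug, reac, hist),
       exposed = exposed, event = event)
}

stratum_tbl <- function(p11, p10, p01, p00) {
  tibble::tibble(p11 = p11, p10 = p10, p01 = p01, p00 = p00)
}
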