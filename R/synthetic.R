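default_unit_alphabet <- function() {
  c("KIPI", "KIBE", "KIB1", "KIB2", "KIB3", "KIB4", "KII2", "KIN3",
    "FRY4", "FRH1", "FRGS", "HNSO", "MEM1")
}

default_unit_weights <- function(alphabet) {
  w <- stats::setNames(rep(1, length(alphabet)), alphabet)
  common <- c(KIBE = 6, KIB1 = 4, KIB3 = 3, KIPI = 3, KIB4 = 2)
  w[names(common)[names(common) %in% alphabet]] <-
    common[names(common) %in% alphabet]
  w
}

#' Default transfer bias matrix
#'
#' Multiplicative weights applied to the choice of the next unit given the
#' current one. The default concentrates outgoing mass from the intensive
#' care unit (KIPI) onto the wards (KIBE, KIB1, KII2), reflecting the
#' stabilise-then-transfer-to-ward pattern typical of paediatric diabetes
#' admissions.
#'
#' @param alphabet Character vector of unit codes.
#' @return A square numeric matrix with unit codes as dimnames.
#' @export
default_transition_bias <- function(alphabet = default_unit_alphabet()) {
  m <- matrix(1, length(alphabet), length(alphabet),
              dimnames = list(alphabet, alphabet))
  bump <- function(from, to, f) {
    if (from %in% alphabet && to %in% alphabet) m[from, to] <<- f
  }
  bump("KIPI", "KIBE", 12)
  bump("KIPI", "KIB1", 8)
  bump("KIPI", "KII2", 4)
  bump("KIPI", "KIB3", 3)
  m
}

#' Specification of a synthetic cohort
#'
#' Bundles the distributions from which [generate_cohort()] draws a
#' spreadsheet-shaped cohort of hospital stay records. The defaults emulate
#' the scale and structure of a nine-year single-centre paediatric diabetes
#' cohort: 298 patients, a geometric-like number of cases per patient
#' (mean about 4.06, so roughly 1200 cases), and a records-per-case
#' distribution under which about 13% of case graphs have more than one
#' vertex, most of those being a single relocation.
#'
#' @param n_patients Number of patients (default 298).
#' @param cases_geom_p Success probability of the geometric cases-per-patient
#'   law: a patient has `1 + Geom(p)` cases, capped at `max_cases`. The
#'   default 0.246 gives mean ~ 4.06 cases per patient.
#' @param max_cases Cap on cases per patient (default 15).
#' @param records_per_case Named probability vector over record counts
#'   (names "1", "2", ...). Default puts 0.870 on single-record cases, 0.105
#'   on two records, and 0.025 on three to five.
#' @param revisit_prob Probability that a record from the third onwards
#'   returns to an already-visited unit, closing a directed cycle
#'   (default 0.03).
#' @param home_unit_prob Probability that a case starts on the patient's home
#'   ward (one unit drawn per patient). Models the observed stickiness of a
#'   homogeneous-diagnosis cohort to one specialised ward (default 0.8).
#' @param unit_alphabet Unit codes to draw from.
#' @param unit_weights Named sampling weights over `unit_alphabet`.
#' @param transition_bias Square multiplier matrix over the alphabet applied
#'   to next-unit choice; see [default_transition_bias()]. `NULL` disables
#'   biasing.
#' @param stay_duration_probs Probability vector over stay durations 0, 1,
#'   ... days (default geometric-shaped over 0--14, mean about 2 days).
#' @param gap_probs Probability vector over the 0, 1, ... day gap between a
#'   discharge and the next acquisition within a case (default mostly
#'   contiguous).
#' @param start_window Two `Date`s bounding case start dates
#'   (default 2005--2013).
#' @return A `cohort_spec` list, validated.
#' @export
cohort_spec <- function(n_patients = 298L,
                        cases_geom_p = 0.246,
                        max_cases = 15L,
                        records_per_case = c("1" = 0.870, "2" = 0.105,
                                             "3" = 0.013, "4" = 0.008,
                                             "5" = 0.004),
                        revisit_prob = 0.03,
                        home_unit_prob = 0.8,
                        unit_alphabet = default_unit_alphabet(),
                        unit_weights = default_unit_weights(unit_alphabet),
                        transition_bias = default_transition_bias(unit_alphabet),
                        stay_duration_probs = stats::dgeom(0:14, 0.35),
                        gap_probs = c(0.8, 0.1, 0.05, 0.05),
                        start_window = as.Date(c("2005-01-01", "2013-12-31"))) {
  stopifnot(
    n_patients >= 1,
    cases_geom_p > 0, cases_geom_p <= 1,
    length(unit_alphabet) >= 2, !anyDuplicated(unit_alphabet),
    all(records_per_case >= 0), sum(records_per_case) > 0,
    revisit_prob >= 0, revisit_prob <= 1,
    home_unit_prob >= 0, home_unit_prob <= 1,
    all(stay_duration_probs >= 0), sum(stay_duration_probs) > 0,
    all(gap_probs >= 0), sum(gap_probs) > 0,
    length(start_window) == 2, start_window[1] <= start_window[2]
  )
  if (is.null(names(records_per_case))) {
    names(records_per_case) <- seq_along(records_per_case)
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      cases_geom_p = cases_geom_p,
      max_cases = as.integer(max_cases),
      records_per_case = records_per_case / sum(records_per_case),
      revisit_prob = revisit_prob,
      home_unit_prob = home_unit_prob,
      unit_alphabet = unit_alphabet,
      unit_weights = unit_weights[unit_alphabet],
      transition_bias = transition_bias,
      stay_duration_probs = stay_duration_probs / sum(stay_duration_probs),
      gap_probs = gap_probs / sum(gap_probs),
      start_window = start_window
    ),
    class = "cohort_spec"
  )
}

sample_units <- function(spec, k, home_unit = NULL) {
  # one unit sequence; consecutive units always differ, a revisit (possible
  # from the third record on) returns to an earlier, non-current unit
  seq_u <- character(k)
  seq_u[1] <- if (!is.null(home_unit) && stats::runif(1) < spec$home_unit_prob) {
    home_unit
  } else {
    sample(spec$unit_alphabet, 1, prob = spec$unit_weights)
  }
  revisited <- FALSE
  if (k > 1) {
    for (j in 2:k) {
      cur <- seq_u[j - 1]
      earlier <- setdiff(unique(seq_u[seq_len(j - 1)]), cur)
      fresh <- setdiff(spec$unit_alphabet, unique(seq_u[seq_len(j - 1)]))
      go_back <- length(earlier) > 0 &&
        (length(fresh) == 0 || stats::runif(1) < spec$revisit_prob)
      pool <- if (go_back) earlier else fresh
      w <- spec$unit_weights[pool]
      if (!is.null(spec$transition_bias)) {
        w <- w * spec$transition_bias[cur, pool]
      }
      seq_u[j] <- if (length(pool) == 1) pool else sample(pool, 1, prob = w)
      revisited <- revisited || go_back
    }
  }
  list(units = seq_u, revisited = revisited)
}

#' Generate a synthetic cohort of stay records
#'
#' Draws a full spreadsheet-shaped cohort from a [cohort_spec()], together
#' with per-case ground-truth labels for recovery testing. Within a case,
#' stays never overlap: each acquisition date is at or after the previous
#' outgoing date. The intended structural category of each case graph follows
#' from the planted unit sequence by construction: one record gives an empty
#' graph, distinct units along the sequence a linear path (`linear_2` for one
#' relocation), and any revisit of an earlier unit a directed cycle.
#' Identical spec and seed give byte-identical output.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; all randomness is drawn under it.
#' @return A list of two tibbles: `records` (a valid stay-record table that
#'   round-trips through [write_stay_records()] / [read_stay_records()]) and
#'   `ground_truth` (`patient_id`, `case_id`, `category`, `n_records`,
#'   `units` -- the planted visit sequence, comma-separated).
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(n_patients = 10), seed = 1)
#' coh$ground_truth
generate_cohort <- function(spec = cohort_spec(), seed) {
  stopifnot(inherits(spec, "cohort_spec"), is.numeric(seed))
  withr::with_seed(as.integer(seed), {
    n_case_total <- 0L
    rec_counts <- as.integer(names(spec$records_per_case))
    max_days <- (length(spec$stay_duration_probs) +
                   length(spec$gap_probs)) * max(rec_counts)
    start_max <- spec$start_window[2] - max_days
    records <- vector("list", spec$n_patients)
    truth <- vector("list", spec$n_patients)

    for (p in seq_len(spec$n_patients)) {
      pid <- sprintf("PAT%05d", p)
      home_unit <- sample(spec$unit_alphabet, 1, prob = spec$unit_weights)
      n_cases <- min(1L + stats::rgeom(1, spec$cases_geom_p), spec$max_cases)
      precs <- vector("list", n_cases)
      ptruth <- vector("list", n_cases)
      for (cs in seq_len(n_cases)) {
        n_case_total <- n_case_total + 1L
        cid <- sprintf("FAL%05d", n_case_total)
        k <- sample(rec_counts, 1, prob = spec$records_per_case)
        su <- sample_units(spec, k, home_unit)
        durs <- sample(seq_along(spec$stay_duration_probs) - 1L, k,
                       replace = TRUE, prob = spec$stay_duration_probs)
        gaps <- sample(seq_along(spec$gap_probs) - 1L, k,
                       replace = TRUE, prob = spec$gap_probs)
        acq <- out <- as.Date(rep(NA, k))
        acq[1] <- spec$start_window[1] +
          floor(stats::runif(1) * (as.numeric(start_max - spec$start_window[1]) + 1))
        out[1] <- acq[1] + durs[1]
        if (k > 1) {
          for (j in 2:k) {
            acq[j] <- out[j - 1] + gaps[j]
            out[j] <- acq[j] + durs[j]
          }
        }
        precs[[cs]] <- tibble::tibble(
          patient_id = pid, case_id = cid, unit_code = su$units,
          acquisition_date = acq, outgoing_date = out
        )
        category <- if (k == 1) {
          "empty"
        } else if (su$revisited) {
          "cyclic"
        } else if (k == 2) "linear_2" else "linear_long"
        ptruth[[cs]] <- tibble::tibble(
          patient_id = pid, case_id = cid,
          category = factor(category, levels = cycle_categories),
          n_records = k,
          units = paste(su$units, collapse = ",")
        )
      }
      records[[p]] <- purrr::list_rbind(precs)
      truth[[p]] <- purrr::list_rbind(ptruth)
    }
    list(
      records = purrr::list_rbind(records),
      ground_truth = purrr::list_rbind(truth)
    )
  })
}

#' Worked-example stay records
#'
#' A small fixture of seven cases for one patient, matching the worked
#' examples used throughout the documentation: case FAL00002 carries the
#' authentic two-row stay pair (FRY4 one day, FRH1 six days, so the single
#' transition has weight 6); case FAL00009 visits KIB3, FRH1 and FRGS with
#' stay durations chosen so its two edge weights are 3 and 12; the remaining
#' cases realise the documented vertex sets. All dates outside FAL00002 are
#' synthetic but date-consistent.
#'
#' @return A stay-record tibble of 11 rows across 7 cases for patient
#'   PAT00001.
#' @export
#' @examples
#' worked_example_records() |> build_case_cycles() |> classify_cycles()
worked_example_records <- function() {
  d <- function(x) as.Date(x, format = "%d.%m.%Y")
  tibble::tribble(
    ~patient_id, ~case_id, ~unit_code, ~acquisition_date, ~outgoing_date,
    "PAT00001", "FAL00001", "KIBE", d("12.10.2005"), d("15.10.2005"),
    "PAT00001", "FAL00002", "FRY4", d("03.11.2005"), d("04.11.2005"),
    "PAT00001", "FAL00002", "FRH1", d("04.11.2005"), d("10.11.2005"),
    "PAT00001", "FAL00004", "KIB3", d("20.01.2006"), d("24.01.2006"),
    "PAT00001", "FAL00007", "KIN3", d("14.03.2006"), d("14.03.2006"),
    "PAT00001", "FAL00009", "KIB3", d("05.06.2006"), d("06.06.2006"),
    "PAT00001", "FAL00009", "FRH1", d("06.06.2006"), d("09.06.2006"),
    "PAT00001", "FAL00009", "FRGS", d("09.06.2006"), d("23.06.2006"),
    "PAT00001", "FAL00013", "HNSO", d("11.09.2006"), d("13.09.2006"),
    "PAT00001", "FAL00013", "KIB3", d("13.09.2006"), d("17.09.2006"),
    "PAT00001", "FAL00015", "MEM1", d("02.02.2007"), d("05.02.2007")
  )
}
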