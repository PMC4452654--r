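# build a stay-record tibble for one case from a unit sequence and durations
mk_case_records <- function(units, durations, patient = "P1", case = "C1",
                            start = as.Date("2005-11-03"), gaps = 0L) {
  k <- length(units)
  stopifnot(length(durations) == k)
  gaps <- rep_len(gaps, k)
  acq <- out <- as.Date(rep(NA, k))
  acq[1] <- start
  out[1] <- acq[1] + durations[1]
  if (k > 1) {
    for (j in 2:k) {
      acq[j] <- out[j - 1] + gaps[j]
      out[j] <- acq[j] + durations[j]
    }
  }
  tibble::tibble(
    patient_id = patient, case_id = case, unit_code = units,
    acquisition_date = acq, outgoing_date = out
  )
}

# treatment_cycle for a directed path v1 -> v2 -> ... -> vn
path_graph <- function(n, labels = paste0("U", seq_len(n))) {
  treatment_cycle(data.frame(from = labels[-n], to = labels[-1]))
}

# treatment_cycle for a directed cycle on n vertices
cycle_graph <- function(n, labels = paste0("U", seq_len(n))) {
  treatment_cycle(data.frame(from = labels, to = labels[c(2:n, 1)]))
}

# random simple digraph (no self-loops) on n labelled vertices
random_digraph <- function(n, p = 0.3) {
  pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- stats::runif(nrow(pairs)) < p
  lab <- paste0("U", seq_len(n))
  treatment_cycle(
    data.frame(from = lab[pairs$from[keep]], to = lab[pairs$to[keep]]),
    vertices = lab
  )
}
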