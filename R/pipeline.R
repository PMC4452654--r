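#' Configuration of a full pipeline run
#'
#' Exactly one of `input` (a stay-record CSV) and `synthetic` (a
#' [cohort_spec()]) must be given.
#'
#' @param input Path to a stay-record CSV, or `NULL`.
#' @param synthetic A [cohort_spec()], or `NULL`.
#' @param outdir Output directory (created if missing).
#' @param col_map,date_format,delim Passed to [read_stay_records()].
#' @param analyses Which stages to run after graph building; any subset of
#'   `"classify"`, `"indices"`, `"frequencies"`, `"extremal"`.
#' @param population Build graphs for individual `"cases"`, `"joined"`
#'   per-patient unions, or `"both"` (default).
#' @param export_graphml Also write one GraphML file per non-empty case graph
#'   (default `FALSE`; the combined edge-list TSV is always written).
#' @param seed Seed for synthetic generation (required with `synthetic`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, synthetic = NULL, outdir,
                            col_map = stay_record_columns(),
                            date_format = "%d.%m.%Y", delim = NULL,
                            analyses = c("classify", "indices",
                                         "frequencies", "extremal"),
                            population = c("both", "cases", "joined"),
                            export_graphml = FALSE,
                            seed = NULL) {
  if (is.null(input) == is.null(synthetic)) {
    stop("Set exactly one of `input` and `synthetic`", call. = FALSE)
  }
  if (!is.null(synthetic)) {
    stopifnot(inherits(synthetic, "cohort_spec"))
    if (is.null(seed)) stop("`seed` is required with a synthetic spec",
                            call. = FALSE)
  }
  analyses <- match.arg(analyses, several.ok = TRUE)
  structure(
    list(input = input, synthetic = synthetic, outdir = outdir,
         col_map = col_map, date_format = date_format, delim = delim,
         analyses = analyses, population = match.arg(population),
         export_graphml = export_graphml, seed = seed),
    class = "pipeline_config"
  )
}

#' Run the full treatment-cycle pipeline
#'
#' Reads (or generates) the stay records, builds per-case and joined
#' per-patient treatment cycles, then runs the configured analyses and writes
#' a report bundle to `outdir`:
#' `records_normalized.csv`, `case_edges.tsv` / `joined_edges.tsv`,
#' `classification_cases.tsv` / `classification_joined.tsv`,
#' `cohort_summary.csv`, `indices_cases.csv` / `indices_joined.csv`,
#' `extremal.json`, `unit_frequencies.csv`, `transition_frequencies.csv`,
#' and `run_log.txt` with stage counts and all validation warnings. The
#' summary invariants are re-verified at report time. With zero valid
#' records the run aborts.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`records`, `cases`,
#'   `case_cycles`, `joined_cycles`, `summary`, `indices`, `frequencies`,
#'   `extremal`, `log`, `paths`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$outdir, ...)
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  warnings_seen <- character()
  records <- withCallingHandlers(
    {
      if (!is.null(config$input)) {
        read_stay_records(config$input, col_map = config$col_map,
                          date_format = config$date_format,
                          delim = config$delim)
      } else {
        generate_cohort(config$synthetic, seed = config$seed)$records
      }
    },
    warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  if (nrow(records) == 0) stop("No valid stay records in input", call. = FALSE)
  probs <- stay_record_problems(records)
  note("records: %d valid, %d rejected", nrow(records), nrow(probs))
  for (w in warnings_seen) note("warning: %s", w)
  write_stay_records(records, out("records_normalized.csv"))
  if (nrow(probs) > 0) {
    readr::write_csv(probs, out("rejected_rows.csv"), progress = FALSE)
  }

  cases <- group_into_cases(records)
  note("cases: %d (%d patients); %d with overlapping stays",
       nrow(cases), dplyr::n_distinct(cases$patient_id),
       sum(cases$n_overlaps > 0))

  case_cycles <- build_case_cycles(cases)
  joined_cycles <- join_patient_cycles(case_cycles)
  note("graphs: %d case cycles, %d joined cycles",
       nrow(case_cycles), nrow(joined_cycles))
  write_cycle_edges(case_cycles, out("case_edges.tsv"))
  write_cycle_edges(joined_cycles, out("joined_edges.tsv"))
  if (isTRUE(config$export_graphml)) {
    gml_dir <- out("graphml")
    dir.create(gml_dir, showWarnings = FALSE)
    for (cy in case_cycles$cycle) {
      if (igraph::ecount(cy$graph) > 0) {
        write_cycle_graphml(cy, file.path(
          gml_dir, paste0(cy$patient_id, "_", cy$case_ids[[1]], ".graphml")
        ))
      }
    }
  }

  pops <- switch(config$population,
                 both = c("cases", "joined"),
                 config$population)
  res <- list(records = records, cases = cases,
              case_cycles = case_cycles, joined_cycles = joined_cycles,
              log = NULL, paths = config$outdir)

  if ("classify" %in% config$analyses) {
    case_cycles <- classify_cycles(case_cycles)
    joined_cycles <- classify_cycles(joined_cycles)
    res$case_cycles <- case_cycles
    res$joined_cycles <- joined_cycles
    res$summary <- summarize_cohort(case_cycles, joined_cycles)
    readr::write_csv(res$summary, out("cohort_summary.csv"), progress = FALSE)
    drop_cols <- c("records", "cycle")
    if ("cases" %in% pops) {
      readr::write_tsv(case_cycles[setdiff(names(case_cycles), drop_cols)],
                       out("classification_cases.tsv"), progress = FALSE)
    }
    if ("joined" %in% pops) {
      readr::write_tsv(joined_cycles[setdiff(names(joined_cycles), drop_cols)],
                       out("classification_joined.tsv"), progress = FALSE)
    }
    note("summary: %s", paste(sprintf(
      "%s %d/%d multi-vertex", res$summary$population,
      res$summary$n_multi_vertex, res$summary$n_graphs), collapse = "; "))
  }

  if ("indices" %in% config$analyses) {
    res$indices <- list()
    if ("cases" %in% pops) {
      res$indices$cases <- graph_indices(case_cycles)
      readr::write_csv(
        res$indices$cases[setdiff(names(res$indices$cases), "cycle")],
        out("indices_cases.csv"), progress = FALSE)
    }
    if ("joined" %in% pops) {
      res$indices$joined <- graph_indices(joined_cycles)
      readr::write_csv(
        res$indices$joined[setdiff(names(res$indices$joined), "cycle")],
        out("indices_joined.csv"), progress = FALSE)
    }
    note("indices computed for: %s", paste(pops, collapse = ", "))
  }

  if ("extremal" %in% config$analyses) {
    idx_tbl <- res$indices$cases %||% graph_indices(case_cycles)
    nonempty <- sum(idx_tbl$n_edges >= 1)
    if (nonempty == 0) {
      note("extremal: skipped, all case graphs empty")
    } else {
      res$extremal <- list(
        wiener = find_extremal(idx_tbl, "wiener"),
        randic_directed = find_extremal(idx_tbl, "randic_directed")
      )
      jsonlite::write_json(
        purrr::map(res$extremal,
                   ~ .x[setdiff(names(.x), c("cycle", "records"))]),
        out("extremal.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
      )
      note("extremal: over %d non-empty case graphs", nonempty)
    }
  }

  if ("frequencies" %in% config$analyses) {
    classified <- if ("category" %in% names(case_cycles)) {
      case_cycles
    } else {
      classify_cycles(case_cycles)
    }
    res$frequencies <- list(
      units_cyclic = withCallingHandlers(
        unit_frequencies(classified, categories = "cyclic"),
        warning = function(w) {
          note("warning: %s", conditionMessage(w))
          invokeRestart("muffleWarning")
        }
      ),
      transitions = transition_frequencies(cases)
    )
    readr::write_csv(res$frequencies$units_cyclic,
                     out("unit_frequencies.csv"), progress = FALSE)
    readr::write_csv(res$frequencies$transitions,
                     out("transition_frequencies.csv"), progress = FALSE)
    note("frequencies: %d distinct transitions",
         nrow(res$frequencies$transitions))
  }

  res$log <- log_lines
  writeLines(log_lines, out("run_log.txt"))
  invisible(res)
}
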