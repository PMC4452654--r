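#' Default column mapping for stay-record spreadsheets
#'
#' Maps the internal field names to the column headers found in the source
#' spreadsheet. The defaults are the headers used by the hospital export this
#' package was designed around; override any entry to read other exports.
#'
#' @param patient_id,case_id,unit_code,acquisition_date,outgoing_date
#'   Column names in the source file.
#' @return A named character vector of length five.
#' @export
#' @examples
#' stay_record_columns(patient_id = "pid")
stay_record_columns <- function(patient_id = "Patient ID",
                                case_id = "Case",
                                unit_code = "Nursing term",
                                acquisition_date = "Acquisition Date OE",
                                outgoing_date = "Outgoing Date pfl. OE") {
  c(
    patient_id = patient_id,
    case_id = case_id,
    unit_code = unit_code,
    acquisition_date = acquisition_date,
    outgoing_date = outgoing_date
  )
}

#' Read and validate a stay-record spreadsheet
#'
#' Reads a delimited text file of hospital stay records -- one row per stay of
#' a patient on a nursing organizational unit -- validates every row, and
#' returns the valid rows as a typed tibble in file order. A stay record
#' carries a patient identifier, a case (treatment episode) identifier, a unit
#' code, and the acquisition (admission to the unit) and outgoing (departure)
#' dates.
#'
#' Rows that violate the record invariants (empty identifiers or unit code,
#' unparseable dates, outgoing date before acquisition date) are dropped from
#' the result but never silently: they are collected with their row numbers
#' and reasons, attached as the `"problems"` attribute (see
#' [stay_record_problems()]), and summarised in a warning. A missing mapped
#' column is a fatal error.
#'
#' @param file Path to a delimited text file with a header row, or a
#'   data frame already holding the five mapped columns as character.
#' @param col_map Named character vector mapping internal field names to file
#'   column headers; see [stay_record_columns()].
#' @param date_format Date format string for both date columns
#'   (default `"%d.%m.%Y"`, i.e. `DD.MM.YYYY`).
#' @param delim Field delimiter. `NULL` (default) autodetects `","` vs `";"`
#'   from the header line.
#' @return A tibble with columns `patient_id`, `case_id`, `unit_code`
#'   (character), `acquisition_date`, `outgoing_date` (`Date`) and `.row`
#'   (source row number), carrying rejected rows in `attr(, "problems")`.
#' @seealso [group_into_cases()], [write_stay_records()]
#' @export
read_stay_records <- function(file,
                              col_map = stay_record_columns(),
                              date_format = "%d.%m.%Y",
                              delim = NULL) {
  needed <- c("patient_id", "case_id", "unit_code",
              "acquisition_date", "outgoing_date")
  if (!all(needed %in% names(col_map))) {
    stop("`col_map` must name all of: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (is.data.frame(file)) {
    raw <- tibble::as_tibble(file)
  } else {
    if (is.null(delim)) {
      header <- readLines(file, n = 1L)
      delim <- if (lengths(regmatches(header, gregexpr(";", header))) >
                   lengths(regmatches(header, gregexpr(",", header)))) ";" else ","
    }
    raw <- readr::read_delim(
      file, delim = delim, col_types = readr::cols(.default = readr::col_character()),
      trim_ws = TRUE, progress = FALSE, show_col_types = FALSE
    )
  }
  missing_cols <- setdiff(unname(col_map[needed]), names(raw))
  if (length(missing_cols) > 0) {
    stop("Input is missing mapped column(s): ",
         paste0("'", missing_cols, "'", collapse = ", "), call. = FALSE)
  }

  rec <- tibble::tibble(
    patient_id = trimws(as.character(raw[[col_map[["patient_id"]]]])),
    case_id = trimws(as.character(raw[[col_map[["case_id"]]]])),
    unit_code = trimws(as.character(raw[[col_map[["unit_code"]]]])),
    acq_raw = trimws(as.character(raw[[col_map[["acquisition_date"]]]])),
    out_raw = trimws(as.character(raw[[col_map[["outgoing_date"]]]])),
    .row = seq_len(nrow(raw))
  )
  rec$acquisition_date <- as.Date(rec$acq_raw, format = date_format)
  rec$outgoing_date <- as.Date(rec$out_raw, format = date_format)

  problem <- dplyr::case_when(
    is.na(rec$patient_id) | rec$patient_id == "" ~ "empty patient_id",
    is.na(rec$case_id) | rec$case_id == "" ~ "empty case_id",
    is.na(rec$unit_code) | rec$unit_code == "" ~ "empty unit_code",
    is.na(rec$acquisition_date) ~ "unparseable acquisition_date",
    is.na(rec$outgoing_date) ~ "unparseable outgoing_date",
    rec$outgoing_date < rec$acquisition_date ~
      "outgoing_date before acquisition_date",
    .default = NA_character_
  )

  problems <- tibble::tibble(
    row = rec$.row[!is.na(problem)],
    reason = problem[!is.na(problem)],
    patient_id = rec$patient_id[!is.na(problem)],
    case_id = rec$case_id[!is.na(problem)]
  )
  out <- rec[is.na(problem),
             c("patient_id", "case_id", "unit_code",
               "acquisition_date", "outgoing_date", ".row")]

  dup <- duplicated(out[c("patient_id", "case_id", "unit_code",
                          "acquisition_date", "outgoing_date")])
  if (any(dup)) {
    warning(sum(dup), " duplicated identical row(s) kept (possible re-admissions)",
            call. = FALSE)
  }
  if (nrow(problems) > 0) {
    warning(nrow(problems), " invalid row(s) rejected; see stay_record_problems()",
            call. = FALSE)
  }
  attr(out, "problems") <- problems
  out
}

#' Rejected rows from the last read
#'
#' @param records A tibble returned by [read_stay_records()].
#' @return A tibble with columns `row`, `reason`, `patient_id`, `case_id`
#'   (zero rows if the whole file validated).
#' @export
stay_record_problems <- function(records) {
  p <- attr(records, "problems")
  if (is.null(p)) {
    p <- tibble::tibble(row = integer(), reason = character(),
                        patient_id = character(), case_id = character())
  }
  p
}

#' Write stay records as normalized CSV
#'
#' Writes the five record columns with ISO-8601 (`YYYY-MM-DD`) dates so the
#' file round-trips exactly through
#' `read_stay_records(file, date_format = "%Y-%m-%d")`.
#'
#' @param records A stay-record tibble.
#' @param file Output path.
#' @param col_map Column headers to write, as in [stay_record_columns()].
#' @return `records`, invisibly.
#' @export
write_stay_records <- function(records, file, col_map = stay_record_columns()) {
  out <- tibble::tibble(
    !!col_map[["patient_id"]] := records$patient_id,
    !!col_map[["case_id"]] := records$case_id,
    !!col_map[["unit_code"]] := records$unit_code,
    !!col_map[["acquisition_date"]] := format(records$acquisition_date, "%Y-%m-%d"),
    !!col_map[["outgoing_date"]] := format(records$outgoing_date, "%Y-%m-%d")
  )
  readr::write_csv(out, file, progress = FALSE)
  invisible(records)
}

#' Group stay records into cases
#'
#' A case is one treatment episode of one patient; a patient may have several
#' cases and each case yields its own treatment-cycle graph. Records within a
#' case are put in temporal order: by acquisition date, ties broken by
#' outgoing date, remaining ties by original file order (stable). Overlapping
#' stays (next acquisition before previous outgoing) are tolerated but counted
#' in the `n_overlaps` column so they can be audited.
#'
#' @param records A validated stay-record tibble from [read_stay_records()]
#'   (a bare data frame with the five record columns also works).
#' @return A tibble with one row per `(patient_id, case_id)` pair: columns
#'   `patient_id`, `case_id`, `first_acquisition`, `n_records`, `n_overlaps`
#'   and a list-column `records` of temporally ordered record tibbles.
#'   Grouping partitions the input: `sum(n_records) == nrow(records)`.
#' @export
#' @examples
#' worked_example_records() |> group_into_cases()
group_into_cases <- function(records) {
  records <- tibble::as_tibble(records)
  if (!".row" %in% names(records)) records$.row <- seq_len(nrow(records))
  if (nrow(records) == 0) {
    return(tibble::tibble(
      patient_id = character(), case_id = character(),
      first_acquisition = as.Date(character()), n_records = integer(),
      n_overlaps = integer(), records = list()
    ))
  }
  records |>
    dplyr::arrange(.data$acquisition_date, .data$outgoing_date, .data$.row) |>
    tidyr::nest(records = -c("patient_id", "case_id")) |>
    dplyr::mutate(
      first_acquisition = purrr::map_vec(.data$records, ~ min(.x$acquisition_date)),
      n_records = purrr::map_int(.data$records, nrow),
      n_overlaps = purrr::map_int(.data$records, function(r) {
        if (nrow(r) < 2) return(0L)
        sum(r$acquisition_date[-1] < r$outgoing_date[-nrow(r)])
      })
    ) |>
    dplyr::arrange(.data$first_acquisition, .data$patient_id, .data$case_id) |>
    dplyr::select("patient_id", "case_id", "first_acquisition",
                  "n_records", "n_overlaps", "records")
}
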