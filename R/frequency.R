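#' Unit occurrence frequencies across a set of graphs
#'
#' Counts, per nursing organizational unit, in how many graphs of the
#' filtered set the unit appears as a vertex (each graph contributes at most
#' once per unit). The default filter keeps the cyclic graphs, the subset
#' where repeated returns to a unit make the occupancy question most
#' interesting.
#'
#' @param classified_tbl A classified cycle tibble ([classify_cycles()]
#'   output); an unclassified one is classified on the fly.
#' @param categories Structural categories to keep (`NULL` keeps all graphs).
#' @param min_count Drop units occurring fewer than this many times
#'   (default 1 keeps everything; 2 reproduces a "# > 1" style table).
#' @return A tibble `unit`, `n`, sorted by descending count, ties broken
#'   lexicographically; zero rows (with a warning) if no graph passes the
#'   filter.
#' @export
unit_frequencies <- function(classified_tbl, categories = "cyclic",
                             min_count = 1L) {
  if (!"category" %in% names(classified_tbl)) {
    classified_tbl <- classify_cycles(classified_tbl)
  }
  keep <- if (is.null(categories)) {
    classified_tbl
  } else {
    classified_tbl[classified_tbl$category %in% categories, ]
  }
  if (nrow(keep) == 0) {
    warning("No graphs match the category filter; returning an empty table",
            call. = FALSE)
    return(tibble::tibble(unit = character(), n = integer()))
  }
  tibble::tibble(unit = unlist(purrr::map(keep$cycle, cycle_units))) |>
    dplyr::count(.data$unit) |>
    dplyr::filter(.data$n >= min_count) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$unit)
}

#' Transfer frequencies across a cohort
#'
#' Counts every occurrence of a directed transfer (relocation) between two
#' differing units over all consecutive record pairs of all cases -- at
#' record level, so a transfer repeated within or across cases counts each
#' time, unlike the per-graph edges which collapse repeats. The total count
#' equals the number of consecutive differing-unit record pairs in the
#' cohort.
#'
#' @param records A stay-record tibble, or the case tibble from
#'   [group_into_cases()].
#' @return A tibble `rank`, `n`, `from`, `to`, sorted by descending count,
#'   ties broken lexicographically; tied counts share a rank (min rank).
#' @export
#' @examples
#' worked_example_records() |> transition_frequencies()
transition_frequencies <- function(records) {
  cases <- if ("records" %in% names(records)) records else group_into_cases(records)
  pairs <- purrr::map(cases$records, function(r) {
    n <- nrow(r)
    if (n < 2) return(NULL)
    u <- r$unit_code
    keep <- u[-n] != u[-1]
    if (!any(keep)) return(NULL)
    tibble::tibble(from = u[-n][keep], to = u[-1][keep])
  }) |> purrr::list_rbind()
  if (nrow(pairs) == 0) {
    return(tibble::tibble(rank = integer(), n = integer(),
                          from = character(), to = character()))
  }
  pairs |>
    dplyr::count(.data$from, .data$to) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$from, .data$to) |>
    dplyr::mutate(rank = dplyr::min_rank(dplyr::desc(.data$n)), .before = 1)
}
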