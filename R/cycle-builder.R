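#' Stay duration in whole days
#'
#' Length of a stay on one unit: outgoing date minus acquisition date. A
#' same-day admission and discharge has duration 0.
#'
#' @param records A stay-record tibble (or any data frame with
#'   `acquisition_date` and `outgoing_date` as `Date`).
#' @return Integer vector of day counts, one per row.
#' @export
stay_duration <- function(records) {
  as.integer(records$outgoing_date - records$acquisition_date)
}

#' Weight of a transition edge
#'
#' The label of a directed edge between two consecutive stays is the absolute
#' difference of the two stay durations plus one day, so every edge weight is
#' a positive whole number of days. Two equal-length stays give weight 1.
#'
#' @param start_duration,target_duration Stay durations in days of the start
#'   and target unit (vectors recycle).
#' @return Integer vector of weights, all `>= 1`.
#' @export
#' @examples
#' edge_weight(1, 6) # 6
edge_weight <- function(start_duration, target_duration) {
  as.integer(abs(target_duration - start_duration) + 1L)
}

new_treatment_cycle <- function(graph, patient_id, case_ids, first_acquisition) {
  structure(
    list(
      graph = graph,
      patient_id = patient_id,
      case_ids = case_ids,
      first_acquisition = first_acquisition
    ),
    class = "treatment_cycle"
  )
}

#' Build the treatment cycle of one case
#'
#' A treatment cycle is a directed graph whose vertices are the distinct
#' nursing organizational units visited during one case and whose edges are
#' the relocations between consecutive, differing units, labelled by
#' [edge_weight()]. One vertex per distinct unit code (so revisiting a unit
#' closes a directed cycle); consecutive records on the same unit are a
#' continued stay and add no edge (no self-loops). A repeated identical
#' directed transition does not duplicate the edge: its `multiplicity`
#' attribute is incremented and the weight of the first occurrence kept.
#' A single-record case yields one vertex and no edges -- an "empty" graph.
#'
#' @param case_records Temporally ordered record tibble of a single case
#'   (one element of the `records` list-column of [group_into_cases()]).
#' @param patient_id,case_id Provenance identifiers; taken from the records
#'   when omitted.
#' @return A `treatment_cycle` object; see [tidy.treatment_cycle()] and
#'   [glance.treatment_cycle()] for tabular views.
#' @export
build_case_cycle <- function(case_records, patient_id = NULL, case_id = NULL) {
  if (nrow(case_records) == 0) {
    stop("A case must contain at least one stay record", call. = FALSE)
  }
  patient_id <- patient_id %||% case_records$patient_id[[1]]
  case_id <- case_id %||% case_records$case_id[[1]]

  units <- case_records$unit_code
  durs <- stay_duration(case_records)
  vertices <- unique(units)

  n <- nrow(case_records)
  edges <- tibble::tibble(from = character(), to = character(),
                          weight = integer(), multiplicity = integer())
  if (n >= 2) {
    keep <- units[-n] != units[-1]
    if (any(keep)) {
      raw <- tibble::tibble(
        from = units[-n][keep],
        to = units[-1][keep],
        weight = edge_weight(durs[-n][keep], durs[-1][keep])
      )
      edges <- raw |>
        dplyr::mutate(.ord = dplyr::row_number()) |>
        dplyr::summarise(
          weight = .data$weight[which.min(.data$.ord)],
          multiplicity = dplyr::n(),
          .ord = min(.data$.ord),
          .by = c("from", "to")
        ) |>
        dplyr::arrange(.data$.ord) |>
        dplyr::select("from", "to", "weight", "multiplicity")
    }
  }
  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = vertices)
  )
  new_treatment_cycle(g, patient_id, case_id,
                      min(case_records$acquisition_date))
}

#' Build the treatment cycles of a whole cohort
#'
#' The main entry point from records to graphs: groups records into cases
#' (unless already grouped) and builds one treatment cycle per case.
#'
#' @param records A stay-record tibble, or the case tibble from
#'   [group_into_cases()].
#' @return The case tibble with a list-column `cycle` of `treatment_cycle`
#'   objects.
#' @export
#' @examples
#' worked_example_records() |> build_case_cycles()
build_case_cycles <- function(records) {
  cases <- if ("records" %in% names(records)) records else group_into_cases(records)
  cases |>
    dplyr::mutate(cycle = purrr::pmap(
      list(.data$records, .data$patient_id, .data$case_id),
      build_case_cycle
    ))
}

#' Join the treatment cycles of one patient
#'
#' The joined treatment cycle is the graph-theoretical union of several case
#' graphs of one patient: vertices are merged by unit code, directed edges are
#' unioned, edge multiplicities are summed, and the weight of an edge present
#' in several cases is taken from the earliest contributing case (cases are
#' processed in the order given). The union of vertex-disjoint case graphs is
#' a disconnected joined graph.
#'
#' @param cycles List of `treatment_cycle` objects of a single patient.
#' @param patient_id The patient; taken from the first cycle when omitted.
#' @return A single `treatment_cycle` whose `case_ids` lists all contributing
#'   cases.
#' @export
join_cycles <- function(cycles, patient_id = NULL) {
  stopifnot(length(cycles) >= 1)
  pids <- unique(purrr::map_chr(cycles, "patient_id"))
  patient_id <- patient_id %||% pids[[1]]
  if (!identical(pids, patient_id)) {
    stop("join_cycles() got cycles of more than one patient: ",
         paste(pids, collapse = ", "), call. = FALSE)
  }
  vertices <- unique(unlist(purrr::map(cycles, ~ igraph::V(.x$graph)$name)))
  all_edges <- purrr::map(cycles, tidy) |>
    purrr::list_rbind(names_to = ".case_ord")
  edges <- if (nrow(all_edges) == 0) {
    all_edges[c("from", "to", "weight", "multiplicity")]
  } else {
    all_edges |>
    dplyr::summarise(
      weight = .data$weight[which.min(.data$.case_ord)],
      multiplicity = sum(.data$multiplicity),
      .ord = min(.data$.case_ord),
      .by = c("from", "to")
    ) |>
    dplyr::arrange(.data$.ord) |>
    dplyr::select("from", "to", "weight", "multiplicity")
  }
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = vertices))
  new_treatment_cycle(
    g, patient_id,
    unlist(purrr::map(cycles, "case_ids")),
    min(as.Date(purrr::map_vec(cycles, "first_acquisition")))
  )
}

#' Join case cycles patient-wise across a cohort
#'
#' @param cycle_tbl The tibble from [build_case_cycles()]. Cases are joined in
#'   order of first acquisition date, so merged edge weights come from the
#'   chronologically earliest case.
#' @return A tibble with one row per patient: `patient_id`, `n_cases`, and a
#'   list-column `cycle` of joined `treatment_cycle` objects.
#' @export
join_patient_cycles <- function(cycle_tbl) {
  cycle_tbl |>
    dplyr::arrange(.data$first_acquisition, .data$case_id) |>
    dplyr::summarise(
      n_cases = dplyr::n(),
      cycle = list(join_cycles(.data$cycle, .data$patient_id[[1]])),
      .by = "patient_id"
    )
}

#' @export
print.treatment_cycle <- function(x, ...) {
  cat(sprintf(
    "<treatment_cycle> patient %s, case(s) %s: |V| = %d, |E| = %d\n",
    x$patient_id, paste(x$case_ids, collapse = "+"),
    igraph::vcount(x$graph), igraph::ecount(x$graph)
  ))
  ed <- tidy(x)
  if (nrow(ed) > 0) {
    cat(paste0(
      "  ", ed$from, " -> ", ed$to, "  (", ed$weight, " d",
      ifelse(ed$multiplicity > 1, paste0(", x", ed$multiplicity), ""), ")",
      collapse = "\n"
    ), "\n")
  }
  invisible(x)
}

#' Tidy a treatment cycle into its edge list
#'
#' @param x A `treatment_cycle`.
#' @param ... Unused.
#' @return A tibble with one row per directed edge: `from`, `to`, `weight`
#'   (days), `multiplicity` (occurrence count).
#' @method tidy treatment_cycle
#' @export
tidy.treatment_cycle <- function(x, ...) {
  if (igraph::ecount(x$graph) == 0) {
    return(tibble::tibble(from = character(), to = character(),
                          weight = integer(), multiplicity = integer()))
  }
  el <- igraph::as_data_frame(x$graph, what = "edges")
  tibble::tibble(
    from = el$from, to = el$to,
    weight = as.integer(el$weight),
    multiplicity = as.integer(el$multiplicity)
  )
}

#' One-row summary of a treatment cycle
#'
#' @param x A `treatment_cycle`.
#' @param ... Unused.
#' @return A one-row tibble: `patient_id`, `case_id` (cases joined by `+`),
#'   `n_vertices`, `n_edges`, `units` (comma-separated vertex labels).
#' @method glance treatment_cycle
#' @export
glance.treatment_cycle <- function(x, ...) {
  tibble::tibble(
    patient_id = x$patient_id,
    case_id = paste(x$case_ids, collapse = "+"),
    n_vertices = igraph::vcount(x$graph),
    n_edges = igraph::ecount(x$graph),
    units = paste(sort(igraph::V(x$graph)$name), collapse = ",")
  )
}

#' Unit codes (vertex labels) of a treatment cycle
#'
#' @param cycle A `treatment_cycle`.
#' @return Character vector of distinct unit codes, in first-visit order.
#' @export
cycle_units <- function(cycle) {
  igraph::V(cycle$graph)$name
}

#' Plot a treatment cycle
#'
#' Draws the directed graph with unit codes as node labels and day weights on
#' the edges, using a deterministic circular layout.
#'
#' @param object A `treatment_cycle`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot treatment_cycle
#' @export
autoplot.treatment_cycle <- function(object, ...) {
  g <- object$graph
  n <- igraph::vcount(g)
  ang <- if (n == 1) 0 else seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  nodes <- tibble::tibble(
    unit = igraph::V(g)$name,
    x = cos(ang), y = sin(ang)
  )
  p <- ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::coord_equal(xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4)) +
    ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("Patient %s, case %s", object$patient_id,
                                  paste(object$case_ids, collapse = "+")))
  ed <- tidy(object)
  if (nrow(ed) > 0) {
    ed <- ed |>
      dplyr::left_join(nodes, by = c(from = "unit")) |>
      dplyr::left_join(nodes, by = c(to = "unit"), suffix = c("", "end")) |>
      dplyr::mutate(
        # pull arrow tips off the node centres
        dx = .data$xend - .data$x, dy = .data$yend - .data$y,
        len = sqrt(.data$dx^2 + .data$dy^2),
        x0 = .data$x + 0.12 * .data$dx / .data$len,
        y0 = .data$y + 0.12 * .data$dy / .data$len,
        x1 = .data$xend - 0.12 * .data$dx / .data$len,
        y1 = .data$yend - 0.12 * .data$dy / .data$len
      )
    p <- p +
      ggplot2::geom_segment(
        data = ed,
        ggplot2::aes(x = .data$x0, y = .data$y0,
                     xend = .data$x1, yend = .data$y1),
        arrow = grid::arrow(length = grid::unit(8, "pt"), type = "closed"),
        colour = "grey40"
      ) +
      ggplot2::geom_label(
        data = ed,
        ggplot2::aes(x = (.data$x0 + .data$x1) / 2,
                     y = (.data$y0 + .data$y1) / 2,
                     label = .data$weight),
        size = 3, label.size = 0
      )
  }
  p + ggplot2::geom_label(ggplot2::aes(label = .data$unit), fontface = "bold")
}

#' Export the edges of many cycles as one TSV
#'
#' @param cycle_tbl A tibble with a `cycle` list-column (from
#'   [build_case_cycles()] or [join_patient_cycles()]).
#' @param file Output path (tab-separated).
#' @return The combined edge tibble, invisibly.
#' @export
write_cycle_edges <- function(cycle_tbl, file) {
  edges <- cycle_tbl$cycle |>
    purrr::map(function(cy) {
      ed <- tidy(cy)
      if (nrow(ed) == 0) return(NULL)
      dplyr::mutate(ed,
                    patient_id = cy$patient_id,
                    case_id = paste(cy$case_ids, collapse = "+"),
                    .before = 1)
    }) |>
    purrr::list_rbind()
  readr::write_tsv(edges, file, progress = FALSE)
  invisible(edges)
}

#' Export one treatment cycle as GraphML
#'
#' Vertex labels (unit codes) and edge attributes (weight in days,
#' multiplicity) are written as GraphML attributes.
#'
#' @param cycle A `treatment_cycle`.
#' @param file Output path.
#' @return `cycle`, invisibly.
#' @export
write_cycle_graphml <- function(cycle, file) {
  igraph::write_graph(cycle$graph, file, format = "graphml")
  invisible(cycle)
}

#' Construct a treatment cycle from an edge list
#'
#' Programmatic constructor for a directed, labelled graph that did not come
#' from stay records -- useful for composing examples and reference graphs.
#'
#' @param edges Data frame with columns `from`, `to` (unit codes) and
#'   optionally `weight` (default 1) and `multiplicity` (default 1), or
#'   `NULL` for an edgeless graph.
#' @param vertices Character vector of vertex labels; defaults to the units
#'   appearing in `edges`, and must cover them when given.
#' @param patient_id,case_id Provenance labels.
#' @return A `treatment_cycle`.
#' @export
#' @examples
#' treatment_cycle(data.frame(from = c("A", "B"), to = c("B", "A")))
treatment_cycle <- function(edges = NULL, vertices = NULL,
                            patient_id = "synthetic", case_id = "synthetic") {
  if (is.null(edges)) {
    edges <- tibble::tibble(from = character(), to = character())
  }
  edges <- tibble::as_tibble(edges)
  if (!"weight" %in% names(edges)) edges$weight <- rep(1L, nrow(edges))
  if (!"multiplicity" %in% names(edges)) edges$multiplicity <- rep(1L, nrow(edges))
  stopifnot(all(edges$weight >= 1), all(edges$from != edges$to))
  units <- unique(c(edges$from, edges$to))
  vertices <- vertices %||% units
  if (length(setdiff(units, vertices)) > 0) {
    stop("`vertices` must cover every unit in `edges`", call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = vertices))
  new_treatment_cycle(g, patient_id, case_id, as.Date("2000-01-01"))
}
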