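#' Shortest-path distance between two units
#'
#' Hop count of the shortest path; edge day-weights are labels, not lengths,
#' and are ignored. Unreachable pairs are reported as `Inf`.
#'
#' @param cycle A `treatment_cycle`.
#' @param from,to Unit codes (vertex labels) present in the graph.
#' @param mode `"undirected"` (default) walks the underlying undirected
#'   graph; `"directed"` respects edge direction.
#' @return A single nonnegative number, or `Inf` when unreachable.
#' @export
shortest_path_distance <- function(cycle, from, to,
                                   mode = c("undirected", "directed")) {
  mode <- match.arg(mode)
  vs <- igraph::V(cycle$graph)$name
  if (!from %in% vs || !to %in% vs) {
    stop("Vertex not in graph: ", setdiff(c(from, to), vs)[[1]], call. = FALSE)
  }
  igraph::distances(
    cycle$graph, v = from, to = to,
    mode = if (mode == "directed") "out" else "all",
    weights = NA
  )[1, 1]
}

#' Wiener index of a treatment cycle
#'
#' Half the sum of shortest-path distances over all ordered vertex pairs,
#' computed on the underlying undirected graph with unit edge lengths. On a
#' disconnected graph only reachable pairs are summed and the result carries
#' `attr(, "disconnected") = TRUE`. A distance-based index: the more stretched
#' out (less compact) the transfer pattern, the larger the value.
#'
#' @param cycle A `treatment_cycle`.
#' @return A nonnegative number with a logical `"disconnected"` attribute.
#' @export
#' @examples
#' wiener_index(build_case_cycle(worked_example_records()[1:2, ])) # 1
wiener_index <- function(cycle) {
  d <- igraph::distances(cycle$graph, mode = "all", weights = NA)
  finite <- is.finite(d)
  w <- sum(d[finite]) / 2
  attr(w, "disconnected") <- any(!finite)
  w
}

#' Randic connectivity index from a degree assignment
#'
#' The elementary summation behind every Randic variant: over each edge, the
#' inverse square root of the product of its endpoint degrees. An edge whose
#' degree product is zero (possible for in-/out-degree variants at the
#' endpoints of a path) contributes 0 rather than being undefined.
#'
#' @param degrees Named numeric vector, one nonnegative degree per vertex.
#' @param edges Two-column data frame (`from`, `to`) of edges over the same
#'   vertices.
#' @return A nonnegative number.
#' @export
randic_index <- function(degrees, edges) {
  if (nrow(edges) == 0) return(0)
  prod <- degrees[edges[[1]]] * degrees[edges[[2]]]
  sum(ifelse(prod > 0, 1 / sqrt(prod), 0))
}

randic_parts <- function(cycle) {
  g <- cycle$graph
  ed <- igraph::as_data_frame(g, what = "edges")[, c("from", "to")]
  gu <- igraph::as_undirected(g, mode = "collapse")
  edu <- igraph::as_data_frame(gu, what = "edges")[, c("from", "to")]
  list(
    undirected = randic_index(igraph::degree(gu), edu),
    r_in = randic_index(igraph::degree(g, mode = "in"), ed),
    r_out = randic_index(igraph::degree(g, mode = "out"), ed)
  )
}

#' Directed Randic index
#'
#' The Randic index adapted to directed graphs: the mean of [randic_index()]
#' evaluated over the directed edge set with in-degrees and with out-degrees,
#' `(R_in + R_out) / 2`. High values flag patients with many, evenly spread
#' transfer points; a directed cycle on `n` units scores exactly `n`.
#'
#' @param cycle A `treatment_cycle`.
#' @return A nonnegative number.
#' @export
randic_directed <- function(cycle) {
  p <- randic_parts(cycle)
  (p$r_in + p$r_out) / 2
}

#' Index table for a cohort of cycles
#'
#' Computes, per graph: vertex and edge counts, the Wiener index (with its
#' disconnection flag), the undirected Randic index, and the in-, out- and
#' directed Randic variants.
#'
#' @param cycle_tbl A tibble with a `cycle` list-column.
#' @return `cycle_tbl` (minus bulky list-columns other than `cycle`) with
#'   columns `n_vertices`, `n_edges`, `wiener`, `wiener_disconnected`,
#'   `randic_undirected`, `randic_in`, `randic_out`, `randic_directed`.
#' @export
#' @examples
#' worked_example_records() |> build_case_cycles() |> graph_indices()
graph_indices <- function(cycle_tbl) {
  idx <- purrr::map(cycle_tbl$cycle, function(cy) {
    w <- wiener_index(cy)
    p <- randic_parts(cy)
    tibble::tibble(
      n_vertices = as.integer(igraph::vcount(cy$graph)),
      n_edges = as.integer(igraph::ecount(cy$graph)),
      wiener = as.numeric(w),
      wiener_disconnected = attr(w, "disconnected"),
      randic_undirected = p$undirected,
      randic_in = p$r_in,
      randic_out = p$r_out,
      randic_directed = (p$r_in + p$r_out) / 2
    )
  }) |> purrr::list_rbind()
  keep <- setdiff(names(cycle_tbl), c("records", names(idx)))
  dplyr::bind_cols(cycle_tbl[keep], idx)
}

#' Extremal graphs under an index
#'
#' Finds the graphs attaining the minimum and the maximum of a structural
#' index across a cohort, after discarding empty graphs (every index is
#' trivially 0 there). All ties are reported; within each extreme rows keep
#' the cohort (provenance) order, so the first row is the representative.
#'
#' @param cycle_tbl A tibble with a `cycle` list-column; index columns are
#'   computed via [graph_indices()] if absent.
#' @param index One of `"wiener"`, `"randic_undirected"`, `"randic_in"`,
#'   `"randic_out"`, `"randic_directed"`.
#' @return A tibble of the tied extremal rows with a leading `extreme` column
#'   (`"min"`/`"max"`) and the index value in `value`.
#' @export
find_extremal <- function(cycle_tbl, index = c("wiener", "randic_undirected",
                                               "randic_in", "randic_out",
                                               "randic_directed")) {
  index <- match.arg(index)
  tbl <- if (!index %in% names(cycle_tbl)) graph_indices(cycle_tbl) else cycle_tbl
  tbl <- tbl[tbl$n_edges >= 1L, ]
  if (nrow(tbl) == 0) {
    stop("No non-empty graphs to rank: every cycle has |E| = 0", call. = FALSE)
  }
  vals <- tbl[[index]]
  dplyr::bind_rows(
    dplyr::mutate(tbl[vals == min(vals), ], extreme = "min", .before = 1),
    dplyr::mutate(tbl[vals == max(vals), ], extreme = "max", .before = 1)
  ) |>
    dplyr::mutate(value = .data[[index]])
}
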