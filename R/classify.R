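cycle_categories <- c("empty", "linear_2", "linear_long", "cyclic", "other")

#' Classify the structure of one treatment cycle
#'
#' Assigns each graph to exactly one structural category:
#' \describe{
#'   \item{`empty`}{no edges -- the case had no relocation.}
#'   \item{`cyclic`}{contains a directed cycle: the patient returned to a unit
#'     already visited, so some walk starts and terminates on the same unit.}
#'   \item{`linear_2` / `linear_long`}{a directed path: a unique start vertex
#'     with one outgoing edge, a unique end vertex with one incoming edge,
#'     intermediate vertices with exactly one of each, and the graph weakly
#'     connected. `linear_2` has two vertices (a single relocation),
#'     `linear_long` more.}
#'   \item{`other`}{acyclic but not a path (branching, or a disconnected
#'     union).}
#' }
#' Connectivity is weak connectivity of the underlying undirected graph; a
#' graph with an isolated vertex is disconnected.
#'
#' @param cycle A `treatment_cycle`.
#' @return A one-row tibble: `category` (factor over the five categories),
#'   `is_weakly_connected`, `n_weak_components`, `n_vertices`, `n_edges`.
#' @export
classify_cycle <- function(cycle) {
  g <- cycle$graph
  nv <- igraph::vcount(g)
  ne <- igraph::ecount(g)
  comp <- igraph::components(g, mode = "weak")
  connected <- comp$no == 1L

  if (ne == 0L) {
    cat <- "empty"
  } else if (!igraph::is_dag(g)) {
    cat <- "cyclic"
  } else {
    indeg <- igraph::degree(g, mode = "in")
    outdeg <- igraph::degree(g, mode = "out")
    is_path <- connected &&
      ne == nv - 1L &&
      sum(indeg == 0L) == 1L && sum(outdeg == 0L) == 1L &&
      all(indeg <= 1L) && all(outdeg <= 1L)
    cat <- if (!is_path) "other" else if (nv == 2L) "linear_2" else "linear_long"
  }
  tibble::tibble(
    category = factor(cat, levels = cycle_categories),
    is_weakly_connected = connected,
    n_weak_components = comp$no,
    n_vertices = as.integer(nv),
    n_edges = as.integer(ne)
  )
}

#' Classify every cycle in a cohort tibble
#'
#' @param cycle_tbl A tibble with a `cycle` list-column (from
#'   [build_case_cycles()] or [join_patient_cycles()]).
#' @return `cycle_tbl` with the [classify_cycle()] columns appended.
#' @export
#' @examples
#' worked_example_records() |> build_case_cycles() |> classify_cycles()
classify_cycles <- function(cycle_tbl) {
  dplyr::bind_cols(
    cycle_tbl,
    purrr::list_rbind(purrr::map(cycle_tbl$cycle, classify_cycle))
  )
}

count_population <- function(classified, population) {
  multi <- classified[classified$n_vertices > 1L, ]
  named <- table(factor(multi$category, levels = cycle_categories))
  s <- tibble::tibble(
    population = population,
    n_graphs = nrow(classified),
    n_multi_vertex = nrow(multi),
    n_connected = sum(multi$is_weakly_connected),
    n_disconnected = sum(!multi$is_weakly_connected),
    n_linear_2 = as.integer(named[["linear_2"]]),
    n_linear_long = as.integer(named[["linear_long"]]),
    n_cyclic = as.integer(named[["cyclic"]])
  )
  # `other` absorbs every |V|>1 graph outside the three named shapes,
  # including edgeless disconnected unions, so the categories partition
  s$n_other <- s$n_multi_vertex - s$n_linear_2 - s$n_linear_long - s$n_cyclic
  s
}

#' Cohort-level structural summary
#'
#' Tabulates, separately for the individual case graphs and the joined
#' per-patient graphs: the number of graphs, how many have more than one
#' vertex, connectivity among those, and the structural category counts.
#' Two invariants are enforced: connected + disconnected graphs equal the
#' multi-vertex count, and the four category counts partition it.
#'
#' @param case_cycles Classified case tibble ([classify_cycles()] output);
#'   an unclassified cycle tibble is classified on the fly.
#' @param joined_cycles Optional classified joined-cycle tibble; computed from
#'   `case_cycles` via [join_patient_cycles()] when `NULL`.
#' @return A `cohort_summary` tibble with one row per population.
#' @export
summarize_cohort <- function(case_cycles, joined_cycles = NULL) {
  ensure_classified <- function(tbl) {
    if (!"category" %in% names(tbl)) classify_cycles(tbl) else tbl
  }
  case_cycles <- ensure_classified(case_cycles)
  if (is.null(joined_cycles)) {
    joined_cycles <- join_patient_cycles(case_cycles)
  }
  joined_cycles <- ensure_classified(joined_cycles)

  out <- dplyr::bind_rows(
    count_population(case_cycles, "cases"),
    count_population(joined_cycles, "joined")
  )
  stopifnot(
    out$n_connected + out$n_disconnected == out$n_multi_vertex,
    out$n_linear_2 + out$n_linear_long + out$n_cyclic + out$n_other ==
      out$n_multi_vertex
  )
  class(out) <- c("cohort_summary", class(out))
  out
}

#' Long-format view of a cohort summary
#'
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @return A tibble with columns `population`, `measure`, `n`.
#' @method tidy cohort_summary
#' @export
tidy.cohort_summary <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"population",
                      names_to = "measure", values_to = "n")
}

#' Plot a cohort summary
#'
#' Side-by-side bars of the structural category counts among multi-vertex
#' graphs, per population.
#'
#' @param object A `cohort_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cohort_summary
#' @export
autoplot.cohort_summary <- function(object, ...) {
  dat <- tidy(object) |>
    dplyr::filter(.data$measure %in%
                    c("n_linear_2", "n_linear_long", "n_cyclic", "n_other")) |>
    dplyr::mutate(measure = sub("^n_", "", .data$measure))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$measure, y = .data$n,
                                    fill = .data$population)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "structural category", y = "graphs",
                  fill = "population") +
    ggplot2::theme_minimal()
}
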