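test_that("hop distances respect direction and report unreachability", {
  p3 <- path_graph(3, c("A", "B", "C"))
  expect_equal(shortest_path_distance(p3, "A", "C"), 2)
  expect_equal(shortest_path_distance(p3, "C", "A", mode = "directed"), Inf)
  expect_equal(shortest_path_distance(p3, "B", "B"), 0)
  expect_error(shortest_path_distance(p3, "A", "Z"), "not in graph")
})

test_that("Wiener index matches the path closed form and the BFS oracle", {
  expect_equal(as.numeric(wiener_index(treatment_cycle(vertices = "A"))), 0)
  expect_equal(as.numeric(wiener_index(path_graph(2))), 1)
  for (n in 2:10) {
    p <- path_graph(n)
    expect_equal(as.numeric(wiener_index(p)), n * (n^2 - 1) / 6)
    ed <- tidy(p)[c("from", "to")]
    expect_equal(as.numeric(wiener_index(p)),
                 oracle_wiener(ed, cycle_units(p)))
  }
})

test_that("Wiener on random graphs equals the all-pairs BFS oracle", {
  withr::local_seed(5)
  for (i in 1:40) {
    g <- random_digraph(sample(2:7, 1), stats::runif(1, 0.1, 0.6))
    w <- wiener_index(g)
    expect_equal(as.numeric(w),
                 oracle_wiener(tidy(g)[c("from", "to")], cycle_units(g)))
  }
})

test_that("Wiener flags disconnection and grows under a pendant vertex", {
  two <- treatment_cycle(data.frame(from = "A", to = "B"),
                         vertices = c("A", "B", "C"))
  w <- wiener_index(two)
  expect_true(attr(w, "disconnected"))
  expect_equal(as.numeric(w), 1)

  withr::local_seed(8)
  for (i in 1:20) {
    n <- sample(2:7, 1)
    g <- random_digraph(n, 0.6)
    if (attr(wiener_index(g), "disconnected")) next
    ed <- tidy(g)[c("from", "to")]
    grown <- treatment_cycle(
      rbind(ed, data.frame(from = paste0("U", sample(n, 1)), to = "PENDANT"))
    )
    expect_gt(as.numeric(wiener_index(grown)), as.numeric(wiener_index(g)))
  }
})

test_that("Randic index matches the path closed form (n-3)/2 + sqrt(2)", {
  one_edge <- path_graph(2)
  expect_equal(
    randic_index(igraph::degree(igraph::as_undirected(one_edge$graph)),
                 tidy(one_edge)[c("from", "to")]),
    1
  )
  for (n in 3:10) {
    p <- path_graph(n)
    gu <- igraph::as_undirected(p$graph)
    got <- randic_index(igraph::degree(gu), tidy(p)[c("from", "to")])
    expect_equal(got, (n - 3) / 2 + sqrt(2))
  }
})

test_that("in-degree Randic of the directed 2-cycle is 2 and zero-degree edges drop", {
  c2 <- cycle_graph(2)
  ed <- tidy(c2)[c("from", "to")]
  expect_equal(randic_index(igraph::degree(c2$graph, mode = "in"), ed), 2)

  # on a path the start has in-degree 0, the end out-degree 0: those edges
  # contribute nothing to the respective variant
  p3 <- path_graph(3, c("A", "B", "C"))
  ed3 <- tidy(p3)[c("from", "to")]
  k_in <- igraph::degree(p3$graph, mode = "in")    # A:0 B:1 C:1
  expect_equal(randic_index(k_in, ed3), 1)         # only (B,C) counts
  expect_equal(randic_index(k_in, ed3), oracle_randic(k_in, ed3))
})

test_that("the directed Randic index is the mean of the in and out variants", {
  withr::local_seed(13)
  for (i in 1:300) {
    g <- random_digraph(sample(2:8, 1), stats::runif(1, 0.05, 0.7))
    ed <- tidy(g)[c("from", "to")]
    # exact identity when both sides use the same summation
    r_in <- randic_index(igraph::degree(g$graph, mode = "in"), ed)
    r_out <- randic_index(igraph::degree(g$graph, mode = "out"), ed)
    expect_identical(randic_directed(g), (r_in + r_out) / 2)
    # and agreement with the naive term-by-term oracle
    expect_equal(r_in, oracle_randic(igraph::degree(g$graph, mode = "in"), ed))
    expect_equal(r_out, oracle_randic(igraph::degree(g$graph, mode = "out"), ed))
  }
  expect_equal(randic_directed(treatment_cycle(vertices = "A")), 0)
})

test_that("a directed cycle on n units has directed Randic index n", {
  for (n in 2:10) {
    expect_equal(randic_directed(cycle_graph(n)), n)
  }
})

test_that("indices are invariant under vertex relabelling", {
  withr::local_seed(21)
  for (i in 1:20) {
    g <- random_digraph(sample(3:7, 1), 0.4)
    ed <- tidy(g)[c("from", "to")]
    perm <- sample(cycle_units(g))
    names(perm) <- cycle_units(g)
    ed2 <- data.frame(from = unname(perm[ed$from]), to = unname(perm[ed$to]))
    g2 <- treatment_cycle(ed2, vertices = unname(perm))
    expect_equal(randic_directed(g2), randic_directed(g))
    expect_equal(as.numeric(wiener_index(g2)), as.numeric(wiener_index(g)))
  }
})

test_that("graph_indices tabulates every variant per graph", {
  idx <- worked_example_records() |> build_case_cycles() |> graph_indices()
  expect_equal(nrow(idx), 7)
  expect_true(all(c("wiener", "randic_in", "randic_out",
                    "randic_directed") %in% names(idx)))
  expect_equal(idx$randic_directed, (idx$randic_in + idx$randic_out) / 2)
  expect_true(all(idx$wiener >= 0))
  f9 <- idx[idx$case_id == "FAL00009", ]
  expect_equal(f9$wiener, 4)  # path on 3 vertices: 1+1+2
})

test_that("extremal search finds the shortest and longest path", {
  tbl <- tibble::tibble(
    patient_id = "P", case_id = c("a", "b", "c"),
    cycle = list(path_graph(2), path_graph(5), path_graph(3))
  )
  ex <- find_extremal(tbl, "wiener")
  expect_equal(ex$case_id[ex$extreme == "min"], "a")   # W = 1
  expect_equal(ex$case_id[ex$extreme == "max"], "b")   # W = 5*24/6 = 20
  expect_equal(ex$value[ex$extreme == "max"], 20)

  single <- find_extremal(tbl[2, ], "wiener")
  expect_equal(single$case_id, c("b", "b"))            # min and max coincide

  empty_tbl <- tibble::tibble(patient_id = "P", case_id = "z",
                              cycle = list(treatment_cycle(vertices = "A")))
  expect_error(find_extremal(empty_tbl, "wiener"), "non-empty")
})
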