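test_that("stay durations and edge weights follow the day arithmetic", {
  rec <- mk_case_records(c("FRY4", "FRH1"), c(1, 6))
  expect_equal(stay_duration(rec), c(1L, 6L))
  expect_equal(edge_weight(1, 6), 6L)        # |6-1|+1
  expect_equal(edge_weight(4, 4), 1L)        # equal stays
  expect_equal(edge_weight(12, 3), 10L)      # |3-12|+1
  same_day <- mk_case_records("KIN3", 0)
  expect_equal(stay_duration(same_day), 0L)
})

test_that("a two-stay case builds the single-transition graph", {
  cy <- build_case_cycle(mk_case_records(c("FRY4", "FRH1"), c(1, 6),
                                         patient = "PAT00001",
                                         case = "FAL00002"))
  g <- glance(cy)
  expect_equal(g$n_vertices, 2)
  expect_equal(g$n_edges, 1)
  ed <- tidy(cy)
  expect_equal(ed$from, "FRY4")
  expect_equal(ed$to, "FRH1")
  expect_equal(ed$weight, 6L)
})

test_that("single-record cases yield empty graphs and empty cases error", {
  cy <- build_case_cycle(mk_case_records("KIBE", 2))
  expect_equal(glance(cy)$n_vertices, 1)
  expect_equal(glance(cy)$n_edges, 0)
  expect_error(build_case_cycle(mk_case_records("A", 1)[0, ]), "at least one")
})

test_that("a unit revisit maps to the same vertex and closes a cycle", {
  cy <- build_case_cycle(mk_case_records(c("A", "B", "A"), c(1, 2, 3)))
  expect_setequal(cycle_units(cy), c("A", "B"))
  ed <- tidy(cy)
  expect_equal(nrow(ed), 2)
  expect_true(all(c("A", "B") %in% ed$from))
  expect_false(igraph::is_dag(cy$graph))
})

test_that("consecutive same-unit records add no self-loop", {
  cy <- build_case_cycle(mk_case_records(c("A", "A", "B"), c(1, 1, 2)))
  ed <- tidy(cy)
  expect_equal(nrow(ed), 1)
  expect_equal(ed$from, "A")
})

test_that("repeated transitions collapse to one edge with multiplicity", {
  cy <- build_case_cycle(
    mk_case_records(c("A", "B", "A", "B"), c(1, 3, 1, 9))
  )
  ed <- tidy(cy)
  ab <- ed[ed$from == "A" & ed$to == "B", ]
  expect_equal(ab$multiplicity, 2L)
  expect_equal(ab$weight, 3L)  # first occurrence: |3-1|+1
})

test_that("case graphs satisfy the structural invariants on random walks", {
  withr::local_seed(42)
  for (i in 1:50) {
    k <- sample(1:6, 1)
    units <- sample(LETTERS[1:4], k, replace = TRUE)
    cy <- build_case_cycle(mk_case_records(units, sample(0:14, k, replace = TRUE)))
    g <- glance(cy)
    expect_lte(g$n_edges, k - 1)                         # |E| <= records - 1
    expect_equal(g$n_vertices, length(unique(units)))    # one vertex per unit
    if (g$n_edges > 0) expect_true(all(tidy(cy)$weight >= 1))
    if (g$n_vertices > 1) {
      expect_equal(igraph::components(cy$graph, mode = "weak")$no, 1)
    }
  }
})

test_that("joining merges shared units and sums multiplicities", {
  a <- build_case_cycle(mk_case_records(c("FRY4", "FRH1"), c(1, 6),
                                        case = "FAL00002"))
  b <- build_case_cycle(mk_case_records(c("KIB3", "FRH1", "FRGS"), c(1, 3, 14),
                                        case = "FAL00009",
                                        start = as.Date("2006-06-05")))
  j <- join_cycles(list(a, b))
  expect_equal(glance(j)$n_vertices, 4)  # FRH1 shared
  expect_equal(glance(j)$n_edges, 3)
  expect_setequal(cycle_units(j), c("FRY4", "FRH1", "KIB3", "FRGS"))

  # identity on a single graph
  expect_equal(tidy(join_cycles(list(a))), tidy(a))

  # disjoint graphs give a disconnected union
  c2 <- build_case_cycle(mk_case_records(c("X", "Y"), c(1, 1), case = "C9"))
  dj <- join_cycles(list(a, c2))
  expect_equal(igraph::components(dj$graph, mode = "weak")$no, 2)

  # mixed patients refuse to join
  other <- build_case_cycle(mk_case_records(c("A", "B"), c(1, 1),
                                            patient = "P2"))
  expect_error(join_cycles(list(a, other)), "more than one patient")
})

test_that("joining is idempotent and order-insensitive on sets", {
  a <- build_case_cycle(mk_case_records(c("A", "B", "C"), c(1, 2, 3)))
  b <- build_case_cycle(mk_case_records(c("B", "D"), c(2, 5), case = "C2"))
  ab <- join_cycles(list(a, b))
  ba <- join_cycles(list(b, a))
  expect_setequal(cycle_units(ab), cycle_units(ba))
  eab <- dplyr::arrange(tidy(ab), from, to)
  eba <- dplyr::arrange(tidy(ba), from, to)
  expect_equal(eab[c("from", "to", "multiplicity")],
               eba[c("from", "to", "multiplicity")])
  again <- join_cycles(list(ab))
  expect_equal(dplyr::arrange(tidy(again), from, to), eab)
})

test_that("merged edge weights come from the earliest contributing case", {
  early <- build_case_cycle(mk_case_records(c("A", "B"), c(1, 3), case = "C1"))
  late <- build_case_cycle(mk_case_records(c("A", "B"), c(1, 9), case = "C2",
                                           start = as.Date("2007-01-01")))
  tbl <- tibble::tibble(
    patient_id = "P1", case_id = c("C2", "C1"),
    first_acquisition = c(late$first_acquisition, early$first_acquisition),
    cycle = list(late, early)
  )
  j <- join_patient_cycles(tbl)$cycle[[1]]
  ed <- tidy(j)
  expect_equal(ed$weight, 3L)        # from C1, the earlier case
  expect_equal(ed$multiplicity, 2L)  # summed
})

test_that("edge-list and GraphML exports carry labels and weights", {
  cyc <- build_case_cycles(worked_example_records())
  f <- withr::local_tempfile(fileext = ".tsv")
  edges <- write_cycle_edges(cyc, f)
  expect_true(file.exists(f))
  expect_equal(nrow(edges), 4)  # FAL00002 (1) + FAL00009 (2) + FAL00013 (1)
  expect_true(all(c("patient_id", "case_id", "from", "to", "weight") %in%
                    names(edges)))

  g <- withr::local_tempfile(fileext = ".graphml")
  write_cycle_graphml(cyc$cycle[[which(cyc$case_id == "FAL00009")]], g)
  reread <- igraph::read_graph(g, format = "graphml")
  expect_equal(sort(igraph::V(reread)$name), c("FRGS", "FRH1", "KIB3"))
  expect_setequal(igraph::E(reread)$weight, c(3, 12))
})
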