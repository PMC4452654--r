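# Independent oracles, deliberately naive: plain R, no igraph.

# directed-cycle detection by colouring DFS over an edge list
oracle_has_directed_cycle <- function(edges, vertices) {
  colour <- stats::setNames(rep(0L, length(vertices)), vertices)
  adj <- split(edges$to, factor(edges$from, levels = vertices))
  found <- FALSE
  visit <- function(v) {
    if (found) return()
    colour[[v]] <<- 1L
    for (w in adj[[v]]) {
      if (colour[[w]] == 1L) {
        found <<- TRUE
        return()
      }
      if (colour[[w]] == 0L) visit(w)
    }
    colour[[v]] <<- 2L
  }
  for (v in vertices) if (colour[[v]] == 0L) visit(v)
  found
}

# undirected BFS hop distances from one vertex over an edge list
oracle_bfs_dist <- function(edges, vertices, start) {
  nbr <- stats::setNames(vector("list", length(vertices)), vertices)
  for (i in seq_len(nrow(edges))) {
    nbr[[edges$from[i]]] <- c(nbr[[edges$from[i]]], edges$to[i])
    nbr[[edges$to[i]]] <- c(nbr[[edges$to[i]]], edges$from[i])
  }
  dist <- stats::setNames(rep(Inf, length(vertices)), vertices)
  dist[[start]] <- 0
  frontier <- start
  while (length(frontier) > 0) {
    nxt <- character()
    for (v in frontier) {
      for (w in unique(nbr[[v]])) {
        if (is.infinite(dist[[w]])) {
          dist[[w]] <- dist[[v]] + 1
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  dist
}

# Wiener index by summing BFS distances over reachable unordered pairs
oracle_wiener <- function(edges, vertices) {
  total <- 0
  for (v in vertices) {
    d <- oracle_bfs_dist(edges, vertices, v)
    total <- total + sum(d[is.finite(d)])
  }
  total / 2
}

# path check straight from the degree conditions: unique start with one
# outgoing edge, unique end with one incoming, intermediates one of each,
# one weak component
oracle_is_directed_path <- function(edges, vertices) {
  if (nrow(edges) == 0) return(FALSE)
  indeg <- table(factor(edges$to, levels = vertices))
  outdeg <- table(factor(edges$from, levels = vertices))
  d <- oracle_bfs_dist(edges, vertices, vertices[[1]])
  all(is.finite(d)) &&
    nrow(edges) == length(vertices) - 1 &&
    sum(indeg == 0) == 1 && sum(outdeg == 0) == 1 &&
    all(indeg <= 1) && all(outdeg <= 1)
}

# direct Randic summation over an edge list given a degree lookup
oracle_randic <- function(degrees, edges) {
  tot <- 0
  for (i in seq_len(nrow(edges))) {
    p <- degrees[[edges$from[i]]] * degrees[[edges$to[i]]]
    if (p > 0) tot <- tot + 1 / sqrt(p)
  }
  tot
}

# every simple digraph (no self-loops) on n labelled vertices, as edge tibbles
all_digraphs <- function(n) {
  lab <- paste0("U", seq_len(n))
  pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
  pairs <- pairs[pairs$from != pairs$to, ]
  m <- nrow(pairs)
  lapply(seq_len(2^m) - 1L, function(mask) {
    keep <- bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) > 0
    data.frame(from = lab[pairs$from[keep]], to = lab[pairs$to[keep]])
  })
}
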