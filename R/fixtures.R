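#' The budding-yeast cell-cycle network
#'
#' The classical 11-node, 34-edge Boolean model of the budding-yeast cell
#' cycle (Li, Long, Lu, Ouyang & Tang, PNAS 2004): 15 activating edges, 14
#' inhibiting edges and 5 self-degradation loops on the nodes without an
#' inhibitor (Cln3, Cln1-2, Swi5, Cdc20/Cdc14, Mcm1/SFF).  Node order: 1 Cln3,
#' 2 MBF, 3 SBF, 4 Cln1-2, 5 Cdh1, 6 Swi5, 7 Cdc20/Cdc14, 8 Clb5-6, 9 Sic1,
#' 10 Clb1-2, 11 Mcm1/SFF.  Under the strong-inhibition update this network
#' has exactly seven singleton attractors; the biological G1 rest state
#' `00001000100` (Cdh1 and Sic1 on) is the one with the dominant basin.
#'
#' The wiring is defined in code here; the same matrix ships as
#' `extdata/budding_yeast_cell_cycle.tsv` for the file-based interface.
#'
#' @return A [signed_network()] with node labels.
#' @examples
#' net <- yeast_cell_cycle_network()
#' enumerate_singleton_attractors(net)
#' @export
yeast_cell_cycle_network <- function() {
  labels <- c("Cln3", "MBF", "SBF", "Cln1.2", "Cdh1", "Swi5", "Cdc20.Cdc14",
              "Clb5.6", "Sic1", "Clb1.2", "Mcm1.SFF")
  activation <- matrix(c(   # source, target
    1, 2,   1, 3,   2, 8,   3, 4,   6, 9,
    7, 5,   7, 6,   7, 9,   8, 10,  8, 11,
    10, 7,  10, 11, 11, 6,  11, 7,  11, 10), ncol = 2L, byrow = TRUE)
  inhibition <- matrix(c(
    4, 5,   4, 9,   5, 10,  7, 8,   7, 10,
    8, 5,   8, 9,   9, 8,   9, 10,  10, 2,
    10, 3,  10, 5,  10, 6,  10, 9,
    1, 1,   4, 4,   6, 6,   7, 7,   11, 11), ncol = 2L, byrow = TRUE)
  a <- matrix(0L, 11L, 11L)
  a[activation[, c(2L, 1L)]] <- 1L
  a[inhibition[, c(2L, 1L)]] <- -1L
  signed_network(a, labels)
}

#' Classical network fixtures
#'
#' A `network_fixture` bundles a named network with an optionally known
#' singleton-attractor count, so enumeration results can be cross-checked
#' against published figures.
#'
#' `classical_network_fixtures()` returns the fixtures shipped with the
#' package.  Currently that is the budding-yeast cell-cycle network (expected
#' count 7).  The other classical benchmark networks (cancer cell, Arabidopsis
#' thaliana, T-helper cell, T-cell receptor) require adjacency matrices from
#' their supplementary sources that are not redistributed here; the registry
#' accepts them as additional fixtures once such files are available.
#'
#' @param name fixture name.
#' @param network a [signed_network()].
#' @param expected_attractor_count known singleton-attractor count, or `NULL`.
#' @param source free-text provenance note.
#' @return `network_fixture()`: an object of class `network_fixture`;
#'   `classical_network_fixtures()`: a named list of them.
#' @examples
#' fx <- classical_network_fixtures()$budding_yeast
#' fx$expected_attractor_count
#' @export
network_fixture <- function(name, network, expected_attractor_count = NULL,
                            source = NULL) {
  stopifnot(inherits(network, "signed_network"))
  if (!is.null(expected_attractor_count)) {
    expected_attractor_count <- as.integer(expected_attractor_count)
    stopifnot(expected_attractor_count >= 0L)
  }
  structure(list(name = name, network = network,
                 expected_attractor_count = expected_attractor_count,
                 source = source),
            class = "network_fixture")
}

#' @export
print.network_fixture <- function(x, ...) {
  cat("Fixture '", x$name, "': ", n_nodes(x$network), " nodes, ",
      n_edges(x$network), " edges", sep = "")
  if (!is.null(x$expected_attractor_count)) {
    cat(", expected singleton attractors:", x$expected_attractor_count)
  }
  cat("\n")
  if (!is.null(x$source)) cat("  source:", x$source, "\n")
  invisible(x)
}

#' @rdname network_fixture
#' @export
classical_network_fixtures <- function() {
  list(
    budding_yeast = network_fixture(
      "budding_yeast",
      yeast_cell_cycle_network(),
      expected_attractor_count = 7L,
      source = paste("Budding-yeast cell-cycle Boolean model",
                     "(Li et al., PNAS 101:4781, 2004); wiring transcribed",
                     "from the published figure and cross-validated against",
                     "its known fixed points")
    )
  )
}

#' Check a fixture's expected attractor count
#'
#' Runs [enumerate_singleton_attractors()] on the fixture's network and
#' compares with the recorded expectation.
#'
#' @param fixture a [network_fixture()].
#' @return `TRUE` invisibly on success; an error if the count disagrees.
#' @export
check_fixture <- function(fixture) {
  stopifnot(inherits(fixture, "network_fixture"))
  if (is.null(fixture$expected_attractor_count)) {
    return(invisible(TRUE))
  }
  got <- length(enumerate_singleton_attractors(fixture$network)$bitstrings)
  if (got != fixture$expected_attractor_count) {
    stop("fixture '", fixture$name, "': found ", got,
         " singleton attractors, expected ", fixture$expected_attractor_count)
  }
  invisible(TRUE)
}
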