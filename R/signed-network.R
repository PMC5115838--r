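#' Signed regulatory networks
#'
#' A `signed_network` stores the wiring of a Boolean gene regulatory network as
#' an N x N integer sign matrix `a` with entries in `{-1, 0, +1}`.  The
#' orientation convention, used by every function and file format in this
#' package, is that `a[i, j]` is the effect of source node `j` on target node
#' `i`: `+1` an activating edge, `-1` an inhibiting edge, `0` no edge.
#' Self-edges (`a[i, i] != 0`) are allowed; a `-1` on the diagonal is the usual
#' self-degradation loop of cell-cycle models.
#'
#' Under the strong-inhibition (dominant inhibition) model only the sign of an
#' interaction matters, so the network stores signs rather than weights; the
#' inhibition strength enters only through the `gamma` argument of
#' [threshold_step()].
#'
#' @param a square integer matrix with entries in `{-1, 0, 1}`; `a[i, j]` is
#'   the effect of node `j` on node `i`.
#' @param labels optional character vector of node names (length N).
#' @return An object of class `signed_network` with elements `a` (integer
#'   matrix) and `labels`.
#' @examples
#' # two mutually inhibiting genes
#' net <- signed_network(matrix(c(0, -1, -1, 0), 2, 2))
#' n_nodes(net)
#' n_edges(net)
#' @seealso [regulatory_decomposition()], [read_network()]
#' @export
signed_network <- function(a, labels = NULL) {
  if (!is.matrix(a)) {
    a <- as.matrix(a)
  }
  if (nrow(a) != ncol(a)) {
    stop("adjacency matrix must be square, got ", nrow(a), " x ", ncol(a))
  }
  if (nrow(a) < 1L) stop("network must have at least one node")
  storage.mode(a) <- "integer"
  bad <- which(!(a %in% c(-1L, 0L, 1L)))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(a))
    stop("invalid entry ", a[bad[1L]], " at row ", rc[1L], ", column ", rc[2L],
         ": entries must be -1, 0 or +1")
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(a)) {
      stop("labels must have length ", nrow(a), ", got ", length(labels))
    }
    if (anyDuplicated(labels)) stop("node labels must be unique")
  }
  dimnames(a) <- NULL
  structure(list(a = a, labels = labels), class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  cat("Signed Boolean regulatory network\n")
  cat("  nodes:", n_nodes(x), "  edges:", n_edges(x),
      sprintf("(%d activating, %d inhibiting)\n",
              sum(x$a == 1L), sum(x$a == -1L)))
  if (!is.null(x$labels)) {
    cat("  labels:", paste(x$labels, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of nodes / edges of a network
#'
#' @param net a [signed_network()].
#' @return `n_nodes()`: the node count N; `n_edges()`: the number of nonzero
#'   entries of the sign matrix (self-edges included).
#' @export
n_nodes <- function(net) nrow(net$a)

#' @rdname n_nodes
#' @export
n_edges <- function(net) sum(net$a != 0L)

#' Split a sign matrix into putative stimulatory and inhibitory edges
#'
#' Decomposes the sign matrix into two binary matrices: `g[i, j] = 1` iff node
#' `j` activates node `i`, and `r[i, j] = 1` iff node `j` inhibits node `i`.
#' By construction `g` and `r` never overlap (a regulator cannot both activate
#' and inhibit the same target).  The decomposition also caches per-node
#' adjacency lists used by the propagation engine.
#'
#' @param x a [signed_network()] or a raw sign matrix.
#' @return An object of class `regulatory_decomposition` with logical matrices
#'   `g` and `r`, the diagonal indicators `g_self`/`r_self`, and per-node
#'   regulator index lists (`act_in`, `inh_in`, `inh_out`, external edges
#'   only).
#' @examples
#' net <- yeast_cell_cycle_network()
#' dec <- regulatory_decomposition(net)
#' sum(dec$g) + sum(dec$r) == n_edges(net)
#' @export
regulatory_decomposition <- function(x) {
  if (inherits(x, "regulatory_decomposition")) return(x)
  net <- if (inherits(x, "signed_network")) x else signed_network(x)
  a <- net$a
  n <- nrow(a)
  g <- a == 1L
  r <- a == -1L
  g_off <- g; diag(g_off) <- FALSE
  r_off <- r; diag(r_off) <- FALSE
  structure(list(
    n = n,
    g = g,
    r = r,
    g_self = diag(g),
    r_self = diag(r),
    # external (j != i) regulator lists; hot path of the search
    act_in  = lapply(seq_len(n), function(i) which(g_off[i, ])),
    inh_in  = lapply(seq_len(n), function(i) which(r_off[i, ])),
    inh_out = lapply(seq_len(n), function(i) which(r_off[, i])),
    labels = net$labels
  ), class = "regulatory_decomposition")
}

#' @export
print.regulatory_decomposition <- function(x, ...) {
  cat("Regulatory decomposition:", x$n, "nodes,",
      sum(x$g), "stimulatory and", sum(x$r), "inhibitory edges\n")
  invisible(x)
}

# Recover the sign matrix from a decomposition (round-trip inverse).
#' @rdname regulatory_decomposition
#' @param dec a `regulatory_decomposition`.
#' @export
sign_matrix <- function(dec) {
  dec <- regulatory_decomposition(dec)
  m <- matrix(0L, dec$n, dec$n)
  m[dec$g] <- 1L
  m[dec$r] <- -1L
  m
}

as_decomposition <- function(x) {
  if (inherits(x, "regulatory_decomposition")) x else regulatory_decomposition(x)
}

#' Parse and format Boolean network states
#'
#' States are written as bitstrings with node 1 leftmost, e.g. `"00001000100"`
#' for the 11-node state with nodes 5 and 9 active.  Partial states (used
#' during the search) mark undetermined nodes with `"?"`; numerically they are
#' `NA` entries.
#'
#' @param x a bitstring, or a numeric/integer/logical vector over `{0, 1}`
#'   (possibly with `NA` for undetermined nodes).
#' @param n expected length (optional; checked when supplied).
#' @return `parse_state()`: an integer vector over `{0, 1, NA}`;
#'   `format_state()`: a single bitstring, `"?"` for `NA`.
#' @examples
#' parse_state("01?")
#' format_state(c(0L, 1L, NA))
#' @export
parse_state <- function(x, n = NULL) {
  if (is.character(x)) {
    if (length(x) != 1L) stop("expected a single bitstring")
    ch <- strsplit(x, "")[[1L]]
    s <- rep(NA_integer_, length(ch))
    s[ch == "0"] <- 0L
    s[ch == "1"] <- 1L
    bad <- !(ch %in% c("0", "1", "?", "-"))
    if (any(bad)) {
      stop("invalid character '", ch[which(bad)[1L]], "' in state bitstring")
    }
  } else {
    s <- as.integer(x)
    if (any(!(s %in% c(0L, 1L)) & !is.na(s))) {
      stop("state entries must be 0, 1 or NA")
    }
  }
  if (!is.null(n) && length(s) != n) {
    stop("state has length ", length(s), ", expected ", n)
  }
  s
}

#' @rdname parse_state
#' @param s state vector.
#' @export
format_state <- function(s) {
  ch <- as.character(as.integer(s))
  ch[is.na(ch)] <- "?"
  paste(ch, collapse = "")
}

# number of undetermined nodes of a partial state
l0 <- function(s) sum(is.na(s))

# all 2^n states as an integer matrix, row k+1 = binary expansion of k,
# node 1 = most significant bit (leftmost in bitstrings)
all_states <- function(n) {
  k <- 0:(2^n - 1)
  m <- outer(k, 2^((n - 1):0), function(a, b) (a %/% b) %% 2)
  storage.mode(m) <- "integer"
  m
}

state_index <- function(m, n) as.vector(m %*% 2^((n - 1):0)) + 1
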