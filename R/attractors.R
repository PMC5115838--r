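#' Inhibitory connectivity of a node
#'
#' Counts the inhibitory edges a node takes part in: its inhibitory in-degree
#' plus its inhibitory out-degree, with a self-inhibition loop counted once.
#' This is the branching heuristic of the attractor search: fixing the value
#' of a node with many inhibitory connections lets the propagation rules
#' determine many neighbours at once.
#'
#' @param x a [signed_network()] or [regulatory_decomposition()].
#' @param i node index (1-based); `NULL` returns the degree of every node.
#' @return Integer vector of inhibitory degrees.
#' @examples
#' inhibitory_degree(yeast_cell_cycle_network())
#' @export
inhibitory_degree <- function(x, i = NULL) {
  dec <- as_decomposition(x)
  deg <- rowSums(dec$r) + colSums(dec$r) - dec$r_self
  deg <- as.integer(deg)
  if (is.null(i)) return(deg)
  if (!is.numeric(i) || length(i) != 1L || i < 1L || i > dec$n) {
    stop("node index out of range 1..", dec$n)
  }
  deg[[i]]
}

#' Choose the next branching node
#'
#' Among the still-undetermined nodes of a partial state, returns the one with
#' the largest [inhibitory_degree()]; ties are broken by the smallest node
#' index.
#'
#' @inheritParams inhibitory_degree
#' @param partial partial state (bitstring with `?`, or vector with `NA`).
#' @return A node index.
#' @export
select_branch_node <- function(x, partial) {
  dec <- as_decomposition(x)
  s <- parse_state(partial, dec$n)
  open <- which(is.na(s))
  if (!length(open)) stop("no undetermined node to branch on")
  deg <- inhibitory_degree(dec)
  open[which.max(deg[open])]
}

# ---------------------------------------------------------------------------
# propagation engine
#
# Partial states are integer vectors over {0, 1, NA}.  Rules fire only on
# entailed premises: a sum condition "no active regulator in J" holds iff
# every node of J is determined and 0 (vacuously if J is empty); an existence
# condition requires a determined node.  Each sweep visits every node; sweeps
# repeat until a full pass determines nothing new, or a rule's conclusion
# conflicts with an already-determined value (a contradiction, which is a
# normal outcome that prunes the search, not an error).
# ---------------------------------------------------------------------------

new_propagation <- function(status, state, fired, passes) {
  structure(list(status = status, state = state,
                 fired = fired, passes = passes),
            class = "sibnet_propagation")
}

#' @export
print.sibnet_propagation <- function(x, ...) {
  cat("Propagation outcome:", x$status, "\n")
  if (x$status == "consistent") {
    cat("  state:", format_state(x$state), " (", l0(x$state),
        "undetermined )\n")
  }
  if (nrow(x$fired)) {
    cat("  fired:", paste(sprintf("%s@%d", x$fired$rule, x$fired$node),
                          collapse = " "), "\n")
  }
  invisible(x)
}

# shared driver for the two rule sets; per_node(i) applies every rule
# attached to node i via the assign_val closure
run_propagation <- function(n, s, per_node) {
  fired_rule <- character()
  fired_node <- integer()
  contra <- FALSE
  changed <- TRUE
  passes <- 0L

  assign_val <- function(j, v, rule) {
    if (contra) return(invisible(NULL))
    cur <- s[j]
    if (is.na(cur)) {
      s[j] <<- v
      changed <<- TRUE
      fired_rule[length(fired_rule) + 1L] <<- rule
      fired_node[length(fired_node) + 1L] <<- j
    } else if (cur != v) {
      contra <<- TRUE
      fired_rule[length(fired_rule) + 1L] <<- rule
      fired_node[length(fired_node) + 1L] <<- j
    }
    invisible(NULL)
  }
  contradict <- function(i, rule) {
    contra <<- TRUE
    fired_rule[length(fired_rule) + 1L] <<- rule
    fired_node[length(fired_node) + 1L] <<- i
    invisible(NULL)
  }

  while (changed && !contra) {
    changed <- FALSE
    passes <- passes + 1L
    for (i in seq_len(n)) {
      per_node(i, function() s, assign_val, contradict)
      if (contra) break
    }
  }
  new_propagation(if (contra) "contradiction" else "consistent",
                  if (contra) NULL else s,
                  data.frame(rule = fired_rule, node = fired_node,
                             stringsAsFactors = FALSE),
                  passes)
}

#' Constraint propagation for the fixed-point search
#'
#' Applies the seven fixed-point rules to a partial state until no rule can
#' determine another node (a fixpoint) or a contradiction appears.  Writing
#' `In(i)`/`Act(i)` for the external inhibitors/activators of node i, the
#' rules are: an active node switches off every node it inhibits (rule 1) and
#' every node that inhibits it (rule 2); an active self-inhibited node whose
#' other activators are all off forces its last candidate activator on
#' (rule 3); an inactive node with no active inhibitor and all other
#' activators off forces its last candidate activator off (rule 4); a
#' self-inhibited node with no active activator must be off (rule 5); a
#' self-activated node with no active inhibitor must be on (rule 6); and a
#' node with an active activator and no active inhibitor must be on (rule 7).
#'
#' All premises use entailment semantics: "no active regulator" requires every
#' regulator in question to be determined and equal to 0 (vacuously true when
#' there is none), and existence premises require a determined node.
#'
#' @inheritParams select_branch_node
#' @return An object of class `sibnet_propagation`: `status`
#'   (`"consistent"`/`"contradiction"`), `state` (the more determined partial
#'   state, `NULL` on contradiction), `fired` (data frame of (rule, node)
#'   firings, for tracing) and `passes` (number of full sweeps).
#' @examples
#' net <- yeast_cell_cycle_network()
#' propagate(net, strrep("?", 11))   # determines node 1 = 0, nothing else
#' @export
propagate <- function(x, partial) {
  dec <- as_decomposition(x)
  s <- parse_state(partial, dec$n)
  g_self <- dec$g_self; r_self <- dec$r_self
  act_in <- dec$act_in; inh_in <- dec$inh_in; inh_out <- dec$inh_out

  per_node <- function(i, get_s, assign_val, contradict) {
    s <- get_s()
    acts <- act_in[[i]]; inhs <- inh_in[[i]]
    sa <- s[acts]; si_ <- s[inhs]
    act_on <- any(sa == 1L, na.rm = TRUE)
    inh_on <- any(si_ == 1L, na.rm = TRUE)
    act_open <- acts[is.na(sa)]
    inh_open <- inhs[is.na(si_)]
    nae <- !act_on && length(act_open) == 0L   # all activators entailed off
    nie <- !inh_on && length(inh_open) == 0L   # all inhibitors entailed off

    if (r_self[i] && nae) assign_val(i, 0L, "5")
    if (g_self[i] && nie) assign_val(i, 1L, "6")
    if (nie && act_on)    assign_val(i, 1L, "7")

    v <- get_s()[i]
    if (!is.na(v) && v == 1L) {
      for (j in inh_out[[i]]) assign_val(j, 0L, "1")
      for (j in inhs)         assign_val(j, 0L, "2")
      if (r_self[i] && !act_on && length(act_open) == 1L) {
        assign_val(act_open, 1L, "3")
      }
    } else if (!is.na(v) && v == 0L) {
      if (nie && !act_on && length(act_open) == 1L) {
        assign_val(act_open, 0L, "4")
      }
    }
  }
  run_propagation(dec$n, s, per_node)
}

# ---------------------------------------------------------------------------
# branch-and-propagate enumeration
# ---------------------------------------------------------------------------

new_search_stats <- function(nodes_expanded, propagation_passes,
                             contradictions, found) {
  structure(list(nodes_expanded = nodes_expanded,
                 propagation_passes = propagation_passes,
                 contradictions = contradictions,
                 found = found),
            class = "sibnet_search_stats")
}

#' @export
print.sibnet_search_stats <- function(x, ...) {
  cat("Search effort: ", x$nodes_expanded, " branchings, ",
      x$propagation_passes, " propagation passes, ",
      x$contradictions, " contradictions, ",
      x$found, " states found\n", sep = "")
  invisible(x)
}

# depth-first branch-and-propagate over partial states; propagate_fn maps a
# partial state to a sibnet_propagation, verify_fn checks a complete leaf.
# Branch value 1 is explored before 0.  Stops early (capped = TRUE) once
# max_solutions leaves have been accepted.
branch_enumerate <- function(dec, propagate_fn, verify_fn,
                             max_solutions = Inf) {
  n <- dec$n
  nodes_expanded <- 0L
  passes <- 0L
  contradictions <- 0L
  sols <- character()
  capped <- FALSE

  root <- propagate_fn(rep(NA_integer_, n))
  passes <- passes + root$passes
  if (root$status == "contradiction") {
    contradictions <- contradictions + 1L
  } else {
    stack <- list(root$state)
    deg <- inhibitory_degree(dec)
    while (length(stack)) {
      s <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      open <- which(is.na(s))
      if (!length(open)) {
        if (verify_fn(s)) {
          sols[length(sols) + 1L] <- format_state(s)
          if (length(sols) >= max_solutions) { capped <- TRUE; break }
        }
        next
      }
      i0 <- open[which.max(deg[open])]
      nodes_expanded <- nodes_expanded + 1L
      for (v in c(0L, 1L)) {       # pushed 0 first so value 1 is explored first
        child <- s
        child[i0] <- v
        out <- propagate_fn(child)
        passes <- passes + out$passes
        if (out$status == "contradiction") {
          contradictions <- contradictions + 1L
        } else {
          stack[[length(stack) + 1L]] <- out$state
        }
      }
    }
  }
  sols <- sort(unique(sols))
  list(states = sols,
       stats = new_search_stats(nodes_expanded, passes, contradictions,
                                length(sols)),
       capped = capped)
}

state_matrix <- function(bitstrings, n) {
  if (!length(bitstrings)) return(matrix(integer(), 0L, n))
  do.call(rbind, lapply(bitstrings, parse_state, n = n))
}

#' Enumerate all singleton attractors of a network
#'
#' Finds every fixed point of the synchronous strong-inhibition dynamics by
#' depth-first branch-and-propagate: starting from the fully undetermined
#' state, the seven fixed-point rules ([propagate()]) are run to fixpoint;
#' then the search repeatedly branches on the undetermined node with the most
#' inhibitory connections ([select_branch_node()]), trying value 1 before 0,
#' propagating after each assignment and pruning contradictory branches.
#' Complete, contradiction-free leaves are verified against the fixed-point
#' condition before being reported, so the result is exactly the set of
#' singleton attractors — the same set [brute_force_singleton_attractors()]
#' finds by scanning all \eqn{2^N} states — usually at a small fraction of the
#' cost.
#'
#' @param net a [signed_network()] (or decomposition).
#' @param max_attractors cap on the number of reported attractors; when hit,
#'   the search stops early and the result is flagged `capped` (sparse
#'   networks can have astronomically many fixed points — an empty network has
#'   \eqn{2^N}).
#' @return An object of class `attractor_set`: `bitstrings` (sorted), `states`
#'   (0/1 matrix, one row per attractor), `stats` (search-effort counters) and
#'   `capped`.
#' @examples
#' res <- enumerate_singleton_attractors(yeast_cell_cycle_network())
#' res$bitstrings    # the seven fixed points of the cell-cycle network
#' @export
enumerate_singleton_attractors <- function(net, max_attractors = 1e6) {
  dec <- as_decomposition(net)
  out <- branch_enumerate(
    dec,
    propagate_fn = function(s) propagate(dec, s),
    verify_fn = function(s) is_singleton_attractor(dec, s),
    max_solutions = max_attractors
  )
  structure(list(bitstrings = out$states,
                 states = state_matrix(out$states, dec$n),
                 stats = out$stats,
                 capped = out$capped,
                 labels = dec$labels),
            class = "attractor_set")
}

#' @export
print.attractor_set <- function(x, ...) {
  cat("Singleton attractors:", length(x$bitstrings),
      if (x$capped) "(capped)" else "", "\n")
  show <- utils::head(x$bitstrings, 20L)
  for (b in show) cat(" ", b, "\n")
  if (length(x$bitstrings) > 20L) {
    cat("  ... and", length(x$bitstrings) - 20L, "more\n")
  }
  print(x$stats)
  invisible(x)
}

#' @export
summary.attractor_set <- function(object, ...) {
  cat("Attractor set with", length(object$bitstrings), "fixed point(s)\n")
  if (length(object$bitstrings)) {
    act <- rowSums(object$states)
    cat("  active nodes per attractor: min", min(act), "median",
        stats::median(act), "max", max(act), "\n")
  }
  print(object$stats)
  invisible(object)
}

#' Brute-force enumeration of singleton attractors
#'
#' Scans all \eqn{2^N} states with the vectorised strong-inhibition update and
#' keeps the fixed points.  This is the testing oracle for
#' [enumerate_singleton_attractors()]; it refuses networks above `max_nodes`
#' because the scan is exponential in N.
#'
#' @inheritParams enumerate_singleton_attractors
#' @param max_nodes refuse networks larger than this (default 24).
#' @return An `attractor_set` (with trivial search stats).
#' @export
brute_force_singleton_attractors <- function(net, max_nodes = 24L) {
  dec <- as_decomposition(net)
  if (dec$n > max_nodes) {
    stop("brute force over 2^", dec$n, " states refused (max_nodes = ",
         max_nodes, "); raise max_nodes explicitly if you really mean it")
  }
  chunk <- 2L^min(dec$n, 16L)
  total <- 2^dec$n
  hits <- character()
  for (lo in seq(0, total - 1, by = chunk)) {
    k <- lo:(min(lo + chunk, total) - 1)
    S <- outer(k, 2^((dec$n - 1):0), function(a, b) (a %/% b) %% 2)
    storage.mode(S) <- "integer"
    nxt <- si_step_matrix(dec, S)
    fp <- which(rowSums(nxt != S) == 0L)
    if (length(fp)) {
      hits <- c(hits, apply(S[fp, , drop = FALSE], 1L, paste, collapse = ""))
    }
  }
  hits <- sort(unique(hits))
  structure(list(bitstrings = hits,
                 states = state_matrix(hits, dec$n),
                 stats = new_search_stats(0L, 0L, 0L, length(hits)),
                 capped = FALSE,
                 labels = dec$labels),
            class = "attractor_set")
}
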