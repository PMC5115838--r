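#' Constraint propagation for the pre-image search
#'
#' Applies the pre-image rules for a fixed target state to a partial input
#' state, to fixpoint or contradiction.  For a target bit equal to 1 at node
#' i: every external inhibitor of i must be off (rule 1.1); a self-inhibited
#' node whose other activators are all off forces its last candidate activator
#' on (rule 1.2); a node with no self-edge, no active inhibitor and all
#' activators off must itself be on (rule 1.3); such a node known to be off
#' forces its last candidate activator on (rule 1.4); and a self-inhibited
#' node with every activator off is impossible — contradiction (rule 1.5).
#' For a target bit equal to 0: with no active inhibitor every activator of i
#' must be off (rule 2.1) and, with no self-edge, node i itself must be off
#' (rule 2.2); a self-activated node whose other inhibitors are all off forces
#' its last candidate inhibitor on (rules 2.3); the same conclusion follows
#' whenever the activation part is already entailed — self-activation or some
#' determined active activator (rule 2.4, which subsumes 2.3); and a
#' self-activated node with every external inhibitor off is impossible —
#' contradiction (rule 2.5).
#'
#' Premises use the same entailment semantics as [propagate()].  The rule set
#' need not determine everything determinable: branching plus leaf
#' verification in [enumerate_preimages()] guarantee a complete and exact
#' enumeration regardless.
#'
#' @inheritParams select_branch_node
#' @param target the target state (fully determined bitstring or 0/1 vector):
#'   the state the sought inputs must map to in one synchronous step.
#' @return A `sibnet_propagation` object, as for [propagate()].
#' @examples
#' net <- yeast_cell_cycle_network()
#' propagate_preimage(net, "00001000100", strrep("?", 11))
#' @export
propagate_preimage <- function(x, target, partial) {
  dec <- as_decomposition(x)
  tg <- parse_state(target, dec$n)
  if (anyNA(tg)) stop("target state must be fully determined")
  s <- parse_state(partial, dec$n)
  g_self <- dec$g_self; r_self <- dec$r_self
  act_in <- dec$act_in; inh_in <- dec$inh_in

  per_node <- function(i, get_s, assign_val, contradict) {
    s <- get_s()
    acts <- act_in[[i]]; inhs <- inh_in[[i]]
    sa <- s[acts]; si_ <- s[inhs]
    act_on <- any(sa == 1L, na.rm = TRUE)
    inh_on <- any(si_ == 1L, na.rm = TRUE)
    act_open <- acts[is.na(sa)]
    inh_open <- inhs[is.na(si_)]
    nae <- !act_on && length(act_open) == 0L
    nie <- !inh_on && length(inh_open) == 0L

    if (tg[i] == 1L) {
      for (j in inhs) assign_val(j, 0L, "1.1")
      if (r_self[i] && nae) { contradict(i, "1.5"); return(invisible(NULL)) }
      if (r_self[i] && nie && !act_on && length(act_open) == 1L) {
        assign_val(act_open, 1L, "1.2")
      }
      if (!g_self[i] && !r_self[i] && nie && nae) assign_val(i, 1L, "1.3")
      v <- get_s()[i]
      if (!g_self[i] && !is.na(v) && v == 0L && nie &&
          !act_on && length(act_open) == 1L) {
        assign_val(act_open, 1L, "1.4")
      }
    } else {
      if (inh_on) return(invisible(NULL))   # target bit already explained
      if (g_self[i] && nie) { contradict(i, "2.5"); return(invisible(NULL)) }
      if (nie) {
        for (j in acts) assign_val(j, 0L, "2.1")
        if (!g_self[i] && !r_self[i]) assign_val(i, 0L, "2.2")
      }
      if (length(inh_open) == 1L) {
        if (g_self[i]) assign_val(inh_open, 1L, "2.3")
        if (g_self[i] || act_on) assign_val(inh_open, 1L, "2.4")
      }
    }
  }
  run_propagation(dec$n, s, per_node)
}

#' Enumerate all pre-images of a target state
#'
#' Finds every state that maps to `target` in one synchronous
#' strong-inhibition step, with the same depth-first branch-and-propagate
#' skeleton as [enumerate_singleton_attractors()] but driven by the pre-image
#' rules ([propagate_preimage()]).  Complete leaves are verified by one
#' forward step before being reported.  A target with no pre-image (a
#' Garden-of-Eden state) yields an empty set.
#'
#' @inheritParams enumerate_singleton_attractors
#' @param target target state (bitstring or 0/1 vector).
#' @param max_preimages cap on the number of reported pre-images.
#' @return An object of class `preimage_set`: `bitstrings`, `states`, `target`,
#'   `stats`, `capped`.
#' @examples
#' net <- yeast_cell_cycle_network()
#' enumerate_preimages(net, "00001000100")$bitstrings   # three pre-images
#' @export
enumerate_preimages <- function(net, target, max_preimages = 1e6) {
  dec <- as_decomposition(net)
  tg <- parse_state(target, dec$n)
  if (anyNA(tg)) stop("target state must be fully determined")
  out <- branch_enumerate(
    dec,
    propagate_fn = function(s) propagate_preimage(dec, tg, s),
    verify_fn = function(s) identical(strong_inhibition_step(dec, s), tg),
    max_solutions = max_preimages
  )
  structure(list(bitstrings = out$states,
                 states = state_matrix(out$states, dec$n),
                 target = format_state(tg),
                 stats = out$stats,
                 capped = out$capped,
                 labels = dec$labels),
            class = "preimage_set")
}

#' @export
print.preimage_set <- function(x, ...) {
  cat("Pre-images of", x$target, ":", length(x$bitstrings),
      if (x$capped) "(capped)" else "", "\n")
  for (b in utils::head(x$bitstrings, 20L)) cat(" ", b, "\n")
  if (length(x$bitstrings) > 20L) {
    cat("  ... and", length(x$bitstrings) - 20L, "more\n")
  }
  print(x$stats)
  invisible(x)
}

#' Brute-force enumeration of pre-images
#'
#' Scans all \eqn{2^N} input states and keeps those whose successor equals the
#' target.  Testing oracle for [enumerate_preimages()].
#'
#' @inheritParams enumerate_preimages
#' @param max_nodes refuse networks larger than this (default 24).
#' @return A `preimage_set`.
#' @export
brute_force_preimages <- function(net, target, max_nodes = 24L) {
  dec <- as_decomposition(net)
  tg <- parse_state(target, dec$n)
  if (anyNA(tg)) stop("target state must be fully determined")
  if (dec$n > max_nodes) {
    stop("brute force over 2^", dec$n, " states refused (max_nodes = ",
         max_nodes, ")")
  }
  chunk <- 2L^min(dec$n, 16L)
  total <- 2^dec$n
  hits <- character()
  for (lo in seq(0, total - 1, by = chunk)) {
    k <- lo:(min(lo + chunk, total) - 1)
    S <- outer(k, 2^((dec$n - 1):0), function(a, b) (a %/% b) %% 2)
    storage.mode(S) <- "integer"
    nxt <- si_step_matrix(dec, S)
    ok <- which(rowSums(nxt != rep(tg, each = nrow(nxt))) == 0L)
    if (length(ok)) {
      hits <- c(hits, apply(S[ok, , drop = FALSE], 1L, paste, collapse = ""))
    }
  }
  hits <- sort(unique(hits))
  structure(list(bitstrings = hits,
                 states = state_matrix(hits, dec$n),
                 target = format_state(tg),
                 stats = new_search_stats(0L, 0L, 0L, length(hits)),
                 capped = FALSE,
                 labels = dec$labels),
            class = "preimage_set")
}

#' Reconstruct the basin of attraction of a fixed point
#'
#' Builds the full basin of a singleton attractor by iterated pre-imaging:
#' layer 0 is the attractor itself, layer d+1 collects the pre-images of
#' layer-d states not seen before, and the reverse breadth-first closure stops
#' when a layer comes up empty.  A state sits in layer d exactly when its
#' shortest forward path to the attractor takes d synchronous steps.
#'
#' @inheritParams enumerate_preimages
#' @param attractor a singleton attractor of the network (checked; an error
#'   otherwise).
#' @param max_layers optional cap on the number of reverse layers.
#' @return An object of class `sibnet_basin`: `layers` (list of character
#'   vectors of bitstrings, layer 0 first), `attractor`, `size` (total number
#'   of basin states) and `truncated` (`TRUE` if `max_layers` stopped the
#'   closure early).
#' @examples
#' b <- compute_basin(yeast_cell_cycle_network(), "00110000000")
#' b$size
#' lengths(b$layers)
#' @export
compute_basin <- function(net, attractor, max_layers = Inf) {
  dec <- as_decomposition(net)
  a <- parse_state(attractor, dec$n)
  if (!is_singleton_attractor(dec, a)) {
    stop("state ", format_state(a), " is not a singleton attractor")
  }
  akey <- format_state(a)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  assign(akey, TRUE, envir = seen)
  layers <- list(akey)
  frontier <- akey
  truncated <- FALSE
  d <- 0L
  while (length(frontier)) {
    if (d >= max_layers) { truncated <- TRUE; break }
    nxt <- character()
    for (b in frontier) {
      pre <- enumerate_preimages(dec, b)$bitstrings
      for (p in pre) {
        if (is.null(get0(p, envir = seen))) {
          assign(p, TRUE, envir = seen)
          nxt[length(nxt) + 1L] <- p
        }
      }
    }
    if (!length(nxt)) break
    nxt <- sort(nxt)
    layers[[length(layers) + 1L]] <- nxt
    frontier <- nxt
    d <- d + 1L
  }
  structure(list(layers = layers, attractor = akey,
                 size = sum(lengths(layers)), truncated = truncated),
            class = "sibnet_basin")
}

#' @export
print.sibnet_basin <- function(x, ...) {
  cat("Basin of attraction of", x$attractor, ":", x$size, "state(s) in",
      length(x$layers) - 1L, "reverse layer(s)",
      if (x$truncated) "(truncated)" else "", "\n")
  cat("  layer sizes:", paste(lengths(x$layers), collapse = " "), "\n")
  invisible(x)
}
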