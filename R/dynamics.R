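#' Synchronous threshold update
#'
#' One synchronous step of the weighted threshold model.  Each node sums its
#' inputs (activating edges contribute `+1` per active regulator, off-diagonal
#' inhibiting edges `-gamma`, a diagonal `-1` contributes `-1`) and switches to
#' 1 on a positive sum, to 0 on a negative sum, and keeps its current value
#' when the sum is exactly zero.
#'
#' The dominant-inhibition limit `gamma = Inf` makes any single active
#' inhibitor decisive; [strong_inhibition_step()] is the logical form of that
#' limit.
#'
#' @param net a [signed_network()].
#' @param state Boolean state (bitstring or 0/1 vector of length N).
#' @param gamma inhibition weight, a number `>= 1` or `Inf`.
#' @return The next state as an integer 0/1 vector.
#' @examples
#' net <- signed_network(matrix(c(0, -1, -1, 0), 2, 2))
#' threshold_step(net, c(1, 1), gamma = 2)   # mutual inhibition shuts both off
#' @export
threshold_step <- function(net, state, gamma = Inf) {
  if (!inherits(net, "signed_network")) net <- signed_network(net)
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 1) {
    stop("gamma must be a single number >= 1")
  }
  s <- parse_state(state, n_nodes(net))
  if (anyNA(s)) stop("threshold_step requires a fully determined state")
  a <- net$a
  pos <- as.vector((a == 1L) %*% s)
  off <- a == -1L; diag(off) <- FALSE
  neg_off <- as.vector(off %*% s)
  neg_diag <- as.integer(diag(a) == -1L) * s
  if (is.infinite(gamma)) {
    total <- pos - neg_diag
    total[neg_off > 0] <- -1          # any active inhibitor dominates
  } else {
    total <- pos - gamma * neg_off - neg_diag
  }
  ifelse(total > 0, 1L, ifelse(total < 0, 0L, s))
}

#' Synchronous strong-inhibition update
#'
#' One step of the strong-inhibition Boolean model.  Node i switches on iff
#' none of its inhibitors is active and its activation part holds: some
#' external activator is active, or the node sustains itself (it is on and not
#' self-inhibited, or it is off and self-activated).  Equivalently, with `g`
#' and `r` the stimulatory/inhibitory indicator matrices,
#' \deqn{S_i(t+1) = \Big(\bigvee_{j \ne i} S_j g_{ij} \vee S_i \bar r_{ii}
#'   \vee \bar S_i g_{ii}\Big) \wedge \bigwedge_{j \ne i} \overline{S_j r_{ij}}.}
#' Any single active inhibitor therefore forces the target off, regardless of
#' how many activators are on.
#'
#' @param x a [signed_network()] or [regulatory_decomposition()].
#' @param state Boolean state (bitstring or 0/1 vector).
#' @return The next state, an integer 0/1 vector.
#' @examples
#' net <- yeast_cell_cycle_network()
#' format_state(strong_inhibition_step(net, "00001100000"))
#' @export
strong_inhibition_step <- function(x, state) {
  dec <- as_decomposition(x)
  s <- parse_state(state, dec$n)
  if (anyNA(s)) stop("strong_inhibition_step requires a fully determined state")
  drop(si_step_matrix(dec, matrix(s, nrow = 1L)))
}

# vectorised update: S is a (#states x n) 0/1 matrix, returns the successor
# of every row in one pass of dense linear algebra
si_step_matrix <- function(dec, S) {
  g_off <- dec$g; diag(g_off) <- FALSE
  r_off <- dec$r; diag(r_off) <- FALSE
  act <- S %*% t(g_off)                      # count of active activators
  inh <- S %*% t(r_off)                      # count of active inhibitors
  keep <- sweep(S == 1L, 2L, !dec$r_self, "&") |   # S_i and not r_ii
          sweep(S == 0L, 2L, dec$g_self, "&")      # not S_i and g_ii
  out <- ((act > 0) | keep) & (inh == 0)
  m <- matrix(0L, nrow(S), ncol(S))
  m[out] <- 1L
  m
}

#' Test a state for being a singleton attractor (fixed point)
#'
#' @inheritParams strong_inhibition_step
#' @return `TRUE` iff the state is its own successor under
#'   [strong_inhibition_step()].
#' @examples
#' is_singleton_attractor(yeast_cell_cycle_network(), "00110000000")
#' @export
is_singleton_attractor <- function(x, state) {
  dec <- as_decomposition(x)
  s <- parse_state(state, dec$n)
  if (anyNA(s)) stop("is_singleton_attractor requires a fully determined state")
  identical(strong_inhibition_step(dec, s), s)
}

#' Simulate a synchronous trajectory
#'
#' Iterates [strong_inhibition_step()] from a start state until the orbit
#' revisits a state (a fixed point or a cycle) or the step budget runs out.
#'
#' @inheritParams strong_inhibition_step
#' @param start start state.
#' @param max_steps maximum number of update steps.
#' @return An object of class `sibnet_trajectory`: `states` (matrix, one row
#'   per visited state, starting at `start`), `status` (`"fixed_point"`,
#'   `"cycle"` or `"max_steps"`), `period` (cycle length, `NA` if the budget
#'   ran out) and `transient` (steps before entering the recurrent part).
#' @examples
#' tr <- trajectory(yeast_cell_cycle_network(), "01110000000")
#' tr$status
#' @export
trajectory <- function(x, start, max_steps = 1000L) {
  dec <- as_decomposition(x)
  s <- parse_state(start, dec$n)
  if (anyNA(s)) stop("trajectory requires a fully determined start state")
  if (max_steps < 1L) stop("max_steps must be positive")
  seen <- new.env(hash = TRUE, parent = emptyenv())
  states <- matrix(NA_integer_, max_steps + 1L, dec$n)
  states[1L, ] <- s
  assign(format_state(s), 1L, envir = seen)
  status <- "max_steps"; period <- NA_integer_; transient <- NA_integer_
  steps <- 1L
  for (t in seq_len(max_steps)) {
    s <- strong_inhibition_step(dec, s)
    key <- format_state(s)
    prev <- get0(key, envir = seen)
    if (!is.null(prev)) {
      period <- (t + 1L) - prev
      transient <- prev - 1L
      status <- if (period == 1L) "fixed_point" else "cycle"
      steps <- t
      states[t + 1L, ] <- s
      break
    }
    states[t + 1L, ] <- s
    assign(key, t + 1L, envir = seen)
    steps <- t
  }
  structure(list(states = states[seq_len(steps + 1L), , drop = FALSE],
                 status = status, period = period, transient = transient),
            class = "sibnet_trajectory")
}

#' @export
print.sibnet_trajectory <- function(x, ...) {
  n <- nrow(x$states)
  cat("Synchronous trajectory,", n - 1L, "step(s):\n")
  show <- min(n, 12L)
  for (k in seq_len(show)) cat(" ", format_state(x$states[k, ]), "\n")
  if (n > show) cat("  ...\n")
  cat("  status:", x$status,
      if (!is.na(x$period) && x$status == "cycle") paste0("(period ", x$period, ")"),
      "\n")
  invisible(x)
}
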