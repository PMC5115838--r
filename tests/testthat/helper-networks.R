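# small networks and oracles shared across the suite

mutual_inhibition_net <- function() {
  signed_network(matrix(c(0L, -1L, -1L, 0L), 2L, 2L))
}

empty_net <- function(n) signed_network(matrix(0L, n, n))

yeast_net <- function() yeast_cell_cycle_network()

# the seven fixed points of the budding-yeast cell-cycle network under the
# strong-inhibition update (frozen from the brute-force oracle)
YEAST_ATTRACTORS <- sort(c(
  "00001000100", "01001000100", "01000000100", "00000000100",
  "00001000000", "00110000000", "00000000000"))

# random signed network drawn outside the ensemble machinery, so generator
# and search can be tested against each other independently
rand_net <- function(n, k_avg, r_inh, seed) {
  set.seed(seed)
  p <- min(1, k_avg / n)
  edge <- matrix(runif(n * n) < p, n, n)
  a <- matrix(0L, n, n)
  a[edge] <- ifelse(runif(sum(edge)) < r_inh, -1L, 1L)
  signed_network(a)
}

rand_net_noself <- function(n, k_avg, r_inh, seed) {
  net <- rand_net(n, k_avg, r_inh, seed)
  a <- net$a
  diag(a) <- 0L
  signed_network(a)
}

# successor index (1-based) of every state of a small network
successor_indices <- function(net) {
  dec <- regulatory_decomposition(net)
  S <- sibnet:::all_states(dec$n)
  nxt <- sibnet:::si_step_matrix(dec, S)
  sibnet:::state_index(nxt, dec$n)
}

random_full_state <- function(n) sample(0:1, n, replace = TRUE)
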