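#' Random signed-network ensemble configuration
#'
#' Describes an Erdos--Renyi-style ensemble of signed regulatory networks:
#' every ordered node pair (i, j), self-pairs included, independently carries
#' an edge with probability `p = k_avg / N`; each edge is inhibitory (`-1`)
#' with probability `r` and activating (`+1`) otherwise.  Biological
#' regulatory networks typically have average degree around 2--4 with
#' inhibition in the minority, which motivates the conventional operating
#' point `k_avg = 3`, `r = 0.4`.
#'
#' @param N node count.
#' @param k_avg average degree \eqn{\langle k \rangle}; must satisfy
#'   `k_avg / N <= 1`.
#' @param r probability that an edge is inhibitory, in `[0, 1]`.
#' @param M number of sample networks.
#' @param seed root seed; each sample gets its own stream derived
#'   deterministically from `(seed, sample index)`, so samples are
#'   reproducible individually and under any execution order.
#' @return An object of class `ensemble_config`.
#' @examples
#' cfg <- ensemble_config(N = 12, k_avg = 3, r = 0.4, M = 10, seed = 1)
#' sample_network(cfg, 1)
#' @export
ensemble_config <- function(N, k_avg = 3, r = 0.4, M = 1L, seed = 1L) {
  if (N < 1L) stop("N must be positive")
  if (k_avg <= 0) stop("k_avg must be positive")
  p <- k_avg / N
  if (p > 1) stop("k_avg / N = ", signif(p, 4), " exceeds 1; reduce k_avg")
  if (r < 0 || r > 1) stop("r must lie in [0, 1]")
  if (M < 1L) stop("M must be at least 1")
  structure(list(N = as.integer(N), k_avg = k_avg, r = r, p = p,
                 M = as.integer(M), seed = as.integer(seed)),
            class = "ensemble_config")
}

#' @export
print.ensemble_config <- function(x, ...) {
  cat(sprintf(
    "Random-network ensemble: N = %d, <k> = %g (p = %.4g), r = %g, M = %d, seed = %d\n",
    x$N, x$k_avg, x$p, x$r, x$M, x$seed))
  invisible(x)
}

# Lehmer-step derivation of one sub-stream seed per (root seed, index);
# stays below 2^31 and within exact double arithmetic.
per_sample_seed <- function(seed, index) {
  m <- 2147483647
  f <- function(x) (x * 48271) %% m
  f((f(abs(as.numeric(seed)) %% m) + as.numeric(index)) %% m)
}

# evaluate expr under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Draw one sample network from an ensemble
#'
#' @param cfg an [ensemble_config()].
#' @param index sample index in `1..M` (determines the RNG sub-stream).
#' @return A [signed_network()].
#' @export
sample_network <- function(cfg, index = 1L) {
  stopifnot(inherits(cfg, "ensemble_config"))
  if (index < 1L) stop("sample index must be positive")
  n <- cfg$N
  with_seed(per_sample_seed(cfg$seed, index), {
    edge <- matrix(stats::runif(n * n) < cfg$p, n, n)
    sgn <- matrix(ifelse(stats::runif(n * n) < cfg$r, -1L, 1L), n, n)
    a <- matrix(0L, n, n)
    a[edge] <- sgn[edge]
    signed_network(a)
  })
}

#' Run an attractor-enumeration experiment over a random ensemble
#'
#' Draws `cfg$M` networks, enumerates the singleton attractors of each, and
#' records the attractor count (NS) together with hardware-independent search
#' effort (branchings) and wall-clock seconds per sample.  Samples whose
#' attractor count hits `max_attractors` are flagged `capped` (and excluded
#' from the aggregate statistics), never silently dropped.
#'
#' @inheritParams sample_network
#' @param max_attractors per-sample cap passed to
#'   [enumerate_singleton_attractors()].
#' @param verbose print one line per sample.
#' @return An object of class `sibnet_ensemble`: `records` (data frame with
#'   columns `sample`, `ns`, `nodes_expanded`, `seconds`, `capped`),
#'   aggregates `avS`, `MinS`, `MaxS`, `avT` (over uncapped samples), `n_capped`
#'   and the `config`.
#' @examples
#' res <- run_ensemble(ensemble_config(N = 10, k_avg = 3, r = 0.4, M = 5, seed = 7))
#' res$avS
#' @export
run_ensemble <- function(cfg, max_attractors = 1e6, verbose = FALSE) {
  stopifnot(inherits(cfg, "ensemble_config"))
  rec <- data.frame(sample = seq_len(cfg$M), ns = NA_real_,
                    nodes_expanded = NA_real_, seconds = NA_real_,
                    capped = FALSE)
  for (m in seq_len(cfg$M)) {
    net <- sample_network(cfg, m)
    t0 <- proc.time()[["elapsed"]]
    res <- enumerate_singleton_attractors(net, max_attractors = max_attractors)
    rec$seconds[m] <- proc.time()[["elapsed"]] - t0
    rec$ns[m] <- length(res$bitstrings)
    rec$nodes_expanded[m] <- res$stats$nodes_expanded
    rec$capped[m] <- res$capped
    if (verbose) {
      message(sprintf("sample %d: NS = %d, branchings = %d%s",
                      m, rec$ns[m], rec$nodes_expanded[m],
                      if (res$capped) " [capped]" else ""))
    }
  }
  ok <- !rec$capped
  structure(list(records = rec,
                 avS = mean(rec$ns[ok]),
                 MinS = if (any(ok)) min(rec$ns[ok]) else NA_real_,
                 MaxS = if (any(ok)) max(rec$ns[ok]) else NA_real_,
                 avT = mean(rec$seconds[ok]),
                 n_capped = sum(rec$capped),
                 config = cfg),
            class = "sibnet_ensemble")
}

#' @export
print.sibnet_ensemble <- function(x, ...) {
  print(x$config)
  cat(sprintf("  NS: av %.3f  min %g  max %g   (avT %.4fs",
              x$avS, x$MinS, x$MaxS, x$avT))
  if (x$n_capped) cat(";", x$n_capped, "sample(s) capped")
  cat(")\n")
  invisible(x)
}

#' Plot search effort against attractor count for an ensemble
#'
#' Scatter of branchings (search effort) versus the number of singleton
#' attractors NS across the samples of one ensemble, on log axes.  Their
#' near-linear relation is the hardware-free analogue of computation time
#' growing proportionally to the number of attractors.
#'
#' @param x a `sibnet_ensemble`.
#' @param ... passed to [plot()].
#' @export
plot.sibnet_ensemble <- function(x, ...) {
  r <- x$records[!x$records$capped, ]
  graphics::plot(pmax(r$ns, 1), pmax(r$nodes_expanded, 1), log = "xy",
                 xlab = "singleton attractors (NS)",
                 ylab = "search effort (branchings)",
                 main = sprintf("N = %d, <k> = %g, r = %g",
                                x$config$N, x$config$k_avg, x$config$r), ...)
  invisible(x)
}
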