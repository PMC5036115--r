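# Shared fixtures, built in code.

# the seven-node example topology used throughout
tree7 <- function() example_tree7()

# cached noiseless benchmark dataset (m = 20 grid)
.fixture_env <- new.env(parent = emptyenv())
noiseless_sim <- function(seed = 3) {
  key <- paste0("sim", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- simulate_pathway(sim_spec(seed = seed,
                                                     noise_level = 0))
  .fixture_env[[key]]
}

# relative root-mean-square error between two rate-curve matrices
rel_rms <- function(K, Kt) sqrt(mean((K - Kt)^2)) / sqrt(mean(Kt^2))

# brute-force tree check for small digraphs: in-degrees, undirected cycle
# by edge-subset enumeration, directed reachability by path powers
brute_force_is_tree <- function(nodes, edges, root) {
  n <- length(nodes)
  if (!nrow(edges)) return(n == 1L)
  idx <- stats::setNames(seq_len(n), nodes)
  indeg <- tabulate(idx[edges[, 2L]], n)
  if (indeg[idx[[root]]] != 0L || any(indeg[-idx[[root]]] != 1L))
    return(FALSE)
  # undirected cycle <=> some subset of >= 3 edges forms a closed chain;
  # equivalently the undirected graph has as many independent cycles as
  # edges - nodes + components > 0
  A <- matrix(0L, n, n)
  for (r in seq_len(nrow(edges))) {
    A[idx[[edges[r, 1L]]], idx[[edges[r, 2L]]]] <- 1L
    A[idx[[edges[r, 2L]]], idx[[edges[r, 1L]]]] <- 1L
  }
  comp <- 0L
  seen <- rep(FALSE, n)
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- comp + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[1L]; stack <- stack[-1L]
      if (seen[v]) next
      seen[v] <- TRUE
      stack <- c(stack, which(A[v, ] > 0 & !seen))
    }
  }
  if (nrow(edges) - n + comp > 0L) return(FALSE)   # undirected cycle
  # directed reachability from root
  D <- matrix(0, n, n)
  for (r in seq_len(nrow(edges)))
    D[idx[[edges[r, 1L]]], idx[[edges[r, 2L]]]] <- 1
  reach <- diag(n)
  for (k in seq_len(n)) reach <- (reach %*% (D + diag(n)) > 0) * 1
  all(reach[idx[[root]], ] > 0)
}
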