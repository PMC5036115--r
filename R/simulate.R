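# ---- Synthetic-data generator for benchmark studies ------------------------

#' Specify a synthetic benchmark dataset
#'
#' The generator emulates the study conditions of the benchmark: random
#' rooted tree (or cyclic) networks the size of the seven-node example,
#' quadratic-in-time catalytic rates with coefficients drawn so the rate
#' curves stay non-negative over the grid, trajectories from the linear
#' mass-balance ODE, and multiplicative uniform noise of +/-10% by default.
#' Coefficient ranges are chosen so the solutions stay on the scale of the
#' motivating metabolite data (concentrations of order 0.1–10).
#'
#' @param n_nodes number of metabolites (default 7).
#' @param topology `"tree"` or `"cyclic"`.
#' @param times measurement grid; default 20 points on `[0, 10]`. The
#'   `tomato` preset (`times = 5:9`) mimics five daily measurements on
#'   days 5–9.
#' @param noise_level half-width of the relative uniform noise
#'   (default 0.10; 0 for noiseless data).
#' @param alpha_range,beta_range,gamma_range uniform sampling intervals for
#'   the quadratic rate coefficients (units: per day^3, per day^2, per day).
#' @param b1_range uniform interval for the influx (concentration per day).
#' @param x0_root_range,x0_other_range uniform intervals for initial
#'   concentrations of root and non-root nodes.
#' @param seed integer seed; the dataset is bit-reproducible given the seed.
#' @return object of class `"sim_spec"`.
#' @export
sim_spec <- function(n_nodes = 7L, topology = c("tree", "cyclic"),
                     times = seq(0, 10, length.out = 20L),
                     noise_level = 0.10,
                     alpha_range = c(-0.02, 0.02),
                     beta_range = c(-0.1, 0.1),
                     gamma_range = c(0.1, 1.0),
                     b1_range = c(0.5, 2.0),
                     x0_root_range = c(1, 5),
                     x0_other_range = c(0.1, 0.5),
                     seed = 1L) {
  topology <- match.arg(topology)
  stopifnot(n_nodes >= 1L, noise_level >= 0, all(diff(times) > 0))
  structure(list(n_nodes = as.integer(n_nodes), topology = topology,
                 times = times, noise_level = noise_level,
                 alpha_range = alpha_range, beta_range = beta_range,
                 gamma_range = gamma_range, b1_range = b1_range,
                 x0_root_range = x0_root_range,
                 x0_other_range = x0_other_range,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Five-point "tomato-like" preset
#'
#' The sparse-sampling preset: daily measurements on days 5 to 9, the
#' sampling scheme of the motivating tomato seedling data.
#'
#' @param ... overrides passed to [sim_spec()].
#' @return a [sim_spec()] object with `times = 5:9`.
#' @export
sim_spec_tomato <- function(...) {
  args <- list(...)
  args$times <- if (!is.null(args$times)) args$times else 5:9
  do.call(sim_spec, args)
}

#' Sample a random rooted directed tree
#'
#' Each non-root node picks a parent uniformly among the nodes created
#' before it, giving exactly `n_nodes - 1` edges directed away from the
#' root.
#'
#' @param n_nodes number of nodes (>= 1).
#' @param seed optional RNG seed.
#' @return a [metnet()] object passing [validate_tree()].
#' @export
random_tree <- function(n_nodes, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_nodes >= 1L)
  nodes <- paste0("X", seq_len(n_nodes))
  if (n_nodes == 1L)
    return(metnet(NULL, nodes = nodes, influx = nodes))
  parents <- vapply(2:n_nodes, function(i)
    if (i == 2L) 1L else sample.int(i - 1L, 1L), integer(1L))
  metnet(cbind(nodes[parents], nodes[2:n_nodes]), nodes = nodes,
         influx = nodes[1L])
}

#' Sample a random non-tree (cyclic) network
#'
#' A random rooted tree plus at least one extra edge between already
#' connected nodes, which closes an undirected cycle; the extra edges run
#' from lower to higher node index so the directed graph stays acyclic and
#' the trajectories remain well-behaved.
#'
#' @param n_nodes number of nodes (>= 3).
#' @param seed optional RNG seed.
#' @param extra_edges how many cycle-closing edges to add (default 1).
#' @return a [metnet()] object failing [validate_tree()].
#' @export
random_cyclic <- function(n_nodes, seed = NULL, extra_edges = 1L) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_nodes >= 3L)
  tr <- random_tree(n_nodes)
  nodes <- tr$nodes
  have <- paste(tr$edges$parent, tr$edges$child)
  cand <- list()
  for (i in seq_len(n_nodes - 1L)) for (j in (i + 1L):n_nodes) {
    p <- paste0("X", i); ch <- paste0("X", j)
    if (!(paste(p, ch) %in% have)) cand[[length(cand) + 1L]] <- c(p, ch)
  }
  pick <- sample(seq_along(cand), min(extra_edges, length(cand)))
  metnet(rbind(as.matrix(tr$edges), do.call(rbind, cand[pick])),
         nodes = nodes, influx = nodes[1L])
}

#' Sample quadratic rate coefficients for a network
#'
#' Per-edge coefficients are drawn uniformly from the ranges in `spec` and
#' rejection-sampled until the rate curve is non-negative over the whole
#' time grid; the influx is drawn from `b1_range`.
#'
#' @param network a [metnet()] object.
#' @param spec a [sim_spec()] object.
#' @param max_tries rejection-sampling cap per edge (default 1000).
#' @return a [rate_set()] object.
#' @export
sample_rates <- function(network, spec, max_tries = 1000L) {
  draw_poly <- function() {
    for (i in seq_len(max_tries)) {
      r <- c(stats::runif(1, spec$alpha_range[1], spec$alpha_range[2]),
             stats::runif(1, spec$beta_range[1], spec$beta_range[2]),
             stats::runif(1, spec$gamma_range[1], spec$gamma_range[2]))
      if (min(eval_rate(r, spec$times)) >= 0) return(r)
    }
    stop("could not sample a non-negative rate curve in ", max_tries,
         " draws; widen gamma_range")
  }
  rates <- lapply(edge_ids(network), function(id) draw_poly())
  names(rates) <- edge_ids(network)
  decay <- lapply(network$decay, function(v) draw_poly())
  names(decay) <- network$decay
  rate_set(rates, b1 = stats::runif(1, spec$b1_range[1], spec$b1_range[2]),
           decay = decay)
}

#' Generate a synthetic benchmark dataset
#'
#' Draws a network and ground-truth rates, integrates the clean
#' trajectories, evaluates the exact derivatives from the ODE right-hand
#' side (not by differencing), and adds multiplicative uniform noise.
#' Sub-seeds for topology, rates and noise are derived from `spec$seed`, so
#' the dataset is reproducible bit-for-bit.
#'
#' @param spec a [sim_spec()] object.
#' @return list of class `"sim_dataset"`: `network`, `rates` (truth),
#'   `clean` and `noisy` ([ts_data()]), `deriv_exact`
#'   (a `"deriv_estimate"`), `x0`, `spec`.
#' @export
simulate_pathway <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  sub <- sample.int(.Machine$integer.max - 1L, 3L)
  net <- if (spec$topology == "tree") random_tree(spec$n_nodes, sub[1L])
  else random_cyclic(spec$n_nodes, sub[1L])
  set.seed(sub[2L])
  rates <- sample_rates(net, spec)
  x0 <- stats::setNames(c(
    stats::runif(1, spec$x0_root_range[1], spec$x0_root_range[2]),
    stats::runif(spec$n_nodes - 1L, spec$x0_other_range[1],
                 spec$x0_other_range[2])), net$nodes)
  clean <- model_trajectories(net, rates, x0, spec$times)
  # exact derivatives from the right-hand side at each grid point
  Xd <- vapply(seq_along(spec$times), function(k) {
    sm <- build_system_matrix(net, rates, spec$times[k])
    drop(sm$A %*% clean[, k]) + sm$b
  }, numeric(spec$n_nodes))
  Xd <- matrix(Xd, nrow = spec$n_nodes,
               dimnames = list(net$nodes, NULL))
  set.seed(sub[3L])
  u <- matrix(stats::runif(length(clean), -spec$noise_level,
                           spec$noise_level), nrow(clean))
  noisy <- clean * (1 + u)
  structure(list(
    network = net, rates = rates,
    clean = ts_data(spec$times, clean, net$nodes),
    noisy = ts_data(spec$times, noisy, net$nodes),
    deriv_exact = structure(list(times = spec$times, Xdot = Xd,
                                 method = "exact", smoothers = NULL),
                            class = "deriv_estimate"),
    x0 = x0, spec = spec), class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Synthetic dataset:", x$spec$topology, "network with",
      x$spec$n_nodes, "nodes,", length(x$spec$times), "time points, noise",
      x$spec$noise_level, "\n")
  invisible(x)
}
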