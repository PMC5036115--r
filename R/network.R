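#' Construct a metabolic network
#'
#' A network is a directed graph whose nodes are metabolites and whose edges
#' carry first-order catalytic rates \eqn{k_{ij} \ge 0}: a directed edge
#' \eqn{i \to j} means metabolite \eqn{i} is enzymatically converted to
#' \eqn{j}. One node (the root) receives a constant influx \eqn{b_1} from the
#' surrounding larger network. Optionally, nodes may be allowed to decay
#' without constraint, i.e. lose mass to an implicit, unobserved sink; such
#' decay terms break the balanced tree property (see
#' [structural_identifiability()]).
#'
#' @param edges a two-column matrix or data frame of directed edges
#'   (parent, child), as character node identifiers.
#' @param nodes optional character vector fixing the node set and its order;
#'   defaults to the nodes in order of first appearance in `edges`
#'   (root first when inferable).
#' @param influx identifier of the influx (root) node; defaults to the unique
#'   node with in-degree zero.
#' @param decay character vector of nodes allowed to decay to an implicit
#'   sink (default none).
#' @return an object of class `"metnet"` with fields `nodes`, `edges`
#'   (data frame with columns `parent`, `child`), `influx`, `decay`.
#' @examples
#' net <- metnet(cbind(c("X1", "X1"), c("X2", "X3")))
#' validate_tree(net)$is_tree
#' @export
metnet <- function(edges, nodes = NULL, influx = NULL, decay = character()) {
  if (is.null(edges) || length(edges) == 0L) {
    ed <- data.frame(parent = character(), child = character(),
                     stringsAsFactors = FALSE)
  } else {
    em <- as.matrix(edges)
    if (ncol(em) != 2L)
      stop("`edges` must have two columns (parent, child)")
    ed <- data.frame(parent = as.character(em[, 1L]),
                     child  = as.character(em[, 2L]),
                     stringsAsFactors = FALSE)
  }
  if (is.null(nodes)) nodes <- unique(c(ed$parent, ed$child))
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("node identifiers must be unique")
  bad <- setdiff(c(ed$parent, ed$child), nodes)
  if (length(bad))
    stop("edge endpoint(s) not in node set: ", paste(bad, collapse = ", "))
  if (any(ed$parent == ed$child)) stop("self-loop edges are not allowed")
  if (is.null(influx)) {
    indeg <- table(factor(ed$child, levels = nodes))
    roots <- nodes[indeg == 0L]
    if (length(roots) != 1L)
      stop("influx node not given and not inferable (need exactly one ",
           "in-degree-0 node, found ", length(roots), ")")
    influx <- roots
  }
  influx <- as.character(influx)
  if (length(influx) != 1L || !(influx %in% nodes))
    stop("the influx term is restricted to a single root node present in ",
         "the node set")
  decay <- as.character(decay)
  if (length(setdiff(decay, nodes)))
    stop("decay node(s) not in node set")
  # put the root first so default orderings start at the influx
  nodes <- c(influx, setdiff(nodes, influx))
  structure(list(nodes = nodes, edges = ed, influx = influx, decay = decay),
            class = "metnet")
}

#' @export
print.metnet <- function(x, ...) {
  cat("Metabolic network:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges; influx at", x$influx, "\n")
  if (nrow(x$edges))
    cat("  edges:", paste(edge_ids(x), collapse = ", "), "\n")
  if (length(x$decay))
    cat("  unconstrained decay at:", paste(x$decay, collapse = ", "), "\n")
  vt <- validate_tree(x)
  cat(if (vt$is_tree) "  tree topology" else paste0("  not a tree (", vt$reason, ")"),
      "\n")
  invisible(x)
}

#' Edge identifiers of a network
#'
#' @param network a [metnet()] object.
#' @return character vector `"parent->child"`, in the network's edge order.
#' @export
edge_ids <- function(network) {
  if (!nrow(network$edges)) return(character())
  paste0(network$edges$parent, "->", network$edges$child)
}

#' Check the tree property of a network
#'
#' A network is a tree when (i) no undirected cycle exists — no closed chain
#' of edges regardless of their directions; (ii) every non-root node has
#' exactly one incoming edge and the root none; and (iii) every node is
#' reachable from the root following edge directions. Networks with
#' unconstrained decay terms are not balanced trees: their parameter count
#' exceeds the number of observed states, which destroys the one-parameter-
#' per-node structure that the point-wise solve relies on.
#'
#' @param network a [metnet()] object.
#' @return a list with elements `is_tree` (logical), `order` (root-first
#'   breadth-first topological node order, `NULL` when not a tree), `reason`
#'   (`NULL`, or why the check failed) and `cycle` (node sequence of an
#'   undirected cycle when one exists, else `NULL`).
#' @export
validate_tree <- function(network) {
  stopifnot(inherits(network, "metnet"))
  nodes <- network$nodes
  ed <- network$edges
  n <- length(nodes)
  fail <- function(reason, cycle = NULL)
    list(is_tree = FALSE, order = NULL, reason = reason, cycle = cycle)

  cyc <- find_undirected_cycle(nodes, ed)
  if (!is.null(cyc))
    return(fail("contains an undirected cycle", cyc))
  indeg <- table(factor(ed$child, levels = nodes))
  if (indeg[[network$influx]] != 0L)
    return(fail("root has an incoming edge"))
  off <- nodes[nodes != network$influx & indeg != 1L]
  if (length(off))
    return(fail(paste0("node(s) without exactly one parent: ",
                       paste(off, collapse = ", "))))
  ord <- bfs_order(network)
  if (length(ord) != n)
    return(fail("not all nodes reachable from the root"))
  if (length(network$decay))
    return(fail(paste0("unconstrained decay at ",
                       paste(network$decay, collapse = ", "),
                       " (flux to an implicit sink unbalances the tree)")))
  list(is_tree = TRUE, order = ord, reason = NULL, cycle = NULL)
}

# Breadth-first order from the root along edge directions; children are
# visited parent by parent so that edges sorted by (parent position, child
# position) yield consecutive child positions — the ordering that makes the
# point-wise design matrix upper triangular.
bfs_order <- function(network) {
  ed <- network$edges
  ord <- character(0)
  queue <- network$influx
  seen <- network$influx
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    ord <- c(ord, v)
    kids <- setdiff(ed$child[ed$parent == v], seen)
    seen <- c(seen, kids)
    queue <- c(queue, kids)
  }
  ord
}

# First undirected cycle found by incremental union-find; returns the node
# sequence of the cycle (closed chain), or NULL.
find_undirected_cycle <- function(nodes, ed) {
  n <- length(nodes)
  idx <- seq_len(n)
  names(idx) <- nodes
  parent <- idx
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  adj <- vector("list", n)  # undirected adjacency of edges added so far
  for (r in seq_len(nrow(ed))) {
    u <- idx[[ed$parent[r]]]; v <- idx[[ed$child[r]]]
    if (find(u) == find(v)) {
      # path u..v in the current forest closes the cycle with this edge
      prev <- rep(NA_integer_, n)
      queue <- u; prev[u] <- u
      while (length(queue)) {
        w <- queue[1L]; queue <- queue[-1L]
        for (x in adj[[w]]) if (is.na(prev[x])) { prev[x] <- w; queue <- c(queue, x) }
      }
      path <- v
      while (path[1L] != u) path <- c(prev[path[1L]], path)
      return(nodes[c(path, u)])
    }
    parent[find(u)] <- find(v)
    adj[[u]] <- c(adj[[u]], v); adj[[v]] <- c(adj[[v]], u)
  }
  NULL
}

#' Bundle constant or quadratic-in-time rates with the influx
#'
#' Each edge rate is either a non-negative constant or a quadratic
#' polynomial in time, \eqn{k_{ij}(t) = \alpha t^2 + \beta t + \gamma},
#' stored as `c(alpha, beta, gamma)`. Decay rates (when the network declares
#' decay nodes) follow the same convention.
#'
#' @param rates named list, one entry per edge id (`"parent->child"`), each a
#'   numeric scalar (constant rate) or length-3 vector `c(alpha, beta,
#'   gamma)`.
#' @param b1 non-negative influx into the root, in concentration per time.
#' @param decay named list of decay rates per decaying node (same formats).
#' @return an object of class `"rateset"`.
#' @export
rate_set <- function(rates, b1, decay = list()) {
  stopifnot(is.numeric(b1), length(b1) == 1L, is.finite(b1))
  ok <- vapply(rates, function(r) is.numeric(r) && length(r) %in% c(1L, 3L),
               logical(1L))
  if (length(rates) && !all(ok))
    stop("each rate must be a scalar or c(alpha, beta, gamma)")
  structure(list(rates = rates, b1 = b1, decay = decay), class = "rateset")
}

#' Evaluate a rate specification at given times
#'
#' @param r numeric scalar (constant rate) or `c(alpha, beta, gamma)`.
#' @param t numeric vector of times.
#' @return numeric vector `k(t)`.
#' @export
eval_rate <- function(r, t) {
  if (length(r) == 1L) rep(r, length(t))
  else r[1L] * t^2 + r[2L] * t + r[3L]
}

#' Evaluate all rate curves of a rate set on a time grid
#'
#' @param network a [metnet()] object.
#' @param rates a [rate_set()] object.
#' @param times numeric vector of times.
#' @return matrix (edges + decay terms) x times; row names are edge ids,
#'   decay rows are named `"decay:<node>"`.
#' @export
rate_curves <- function(network, rates, times) {
  ids <- edge_ids(network)
  dn <- if (length(network$decay)) paste0("decay:", network$decay) else character()
  K <- matrix(0, length(ids) + length(dn), length(times),
              dimnames = list(c(ids, dn), NULL))
  for (id in ids) {
    r <- rates$rates[[id]]
    if (is.null(r)) stop("missing rate for edge ", id)
    K[id, ] <- eval_rate(r, times)
  }
  for (v in network$decay) {
    r <- rates$decay[[v]]
    if (is.null(r)) stop("missing decay rate for node ", v)
    K[paste0("decay:", v), ] <- eval_rate(r, times)
  }
  K
}

#' Build the mass-balance system matrices
#'
#' Builds the matrix `A` of the linear mass-balance model
#' \eqn{\dot X = A X + b}: off-diagonals \eqn{A_{ij} = k_{ji}}, diagonals
#' \eqn{A_{ii} = -\sum_{j \ne i} k_{ij}}, so every column of `A` sums to zero
#' (flux out of one node enters another) unless the node decays. `b` is zero
#' except for the influx \eqn{b_1} at the root, and `A_tilde = [A | b]` is
#' the extension acting on the state vector with an appended 1.
#'
#' @param network a [metnet()] object.
#' @param rates a [rate_set()] object; time-varying rates require `t`.
#' @param t evaluation time (scalar), required when any rate is a polynomial.
#' @return list with `A` (n x n), `b` (length n), `A_tilde` (n x (n+1)).
#' @export
build_system_matrix <- function(network, rates, t = NULL) {
  nodes <- network$nodes
  n <- length(nodes)
  poly <- any(vapply(c(rates$rates, rates$decay), length, 1L) == 3L)
  if (poly && is.null(t))
    stop("time-varying rates require an evaluation time `t`")
  if (is.null(t)) t <- 0
  K <- rate_curves(network, rates, t)
  if (any(K < 0))
    stop("negative evaluated rate(s): ",
         paste(rownames(K)[K[, 1L] < 0], collapse = ", "))
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  ed <- network$edges
  for (r in seq_len(nrow(ed))) {
    k <- K[r, 1L]
    A[ed$child[r], ed$parent[r]] <- A[ed$child[r], ed$parent[r]] + k
    A[ed$parent[r], ed$parent[r]] <- A[ed$parent[r], ed$parent[r]] - k
  }
  for (v in network$decay)
    A[v, v] <- A[v, v] - K[paste0("decay:", v), 1L]
  b <- stats::setNames(numeric(n), nodes)
  b[network$influx] <- rates$b1
  list(A = A, b = b, A_tilde = cbind(A, b1 = unname(b)))
}

#' Parameter ordering for the point-wise design matrix
#'
#' Influx first, then edges sorted by the breadth-first topological position
#' of (parent, child), then decay terms. On a balanced tree this ordering
#' makes the point-wise design matrix upper triangular.
#'
#' @param network a [metnet()] object.
#' @return character vector of parameter names (`"b1"`, edge ids,
#'   `"decay:<node>"`).
#' @export
param_order <- function(network) {
  ord <- bfs_order(network)
  pos <- stats::setNames(seq_along(ord), ord)
  ed <- network$edges
  if (nrow(ed)) {
    o <- order(pos[ed$parent], pos[ed$child])
    ids <- edge_ids(network)[o]
  } else ids <- character()
  c("b1", ids,
    if (length(network$decay)) paste0("decay:", network$decay) else character())
}

#' Point-wise design matrix exchanging states and parameters
#'
#' At a single time point the mass-balance equations are linear in the
#' parameter vector \eqn{\theta = (b_1, k_{ij}, \ldots)}: row \eqn{i}
#' expresses \eqn{\dot X_i} as a linear form in \eqn{\theta} with
#' coefficients built from the concentrations. On a tree with \eqn{n} nodes
#' there are exactly \eqn{n} parameters (one influx plus \eqn{n-1} edges),
#' and under the ordering of [param_order()] (rows in breadth-first node
#' order) the matrix is upper triangular with determinant equal to the
#' product of its diagonal entries — nonzero whenever all concentrations
#' are, which is the structural-identifiability certificate.
#'
#' @param network a [metnet()] object.
#' @param x named (or network-ordered) concentration vector at one time.
#' @param require_tree error when the network is not a balanced tree
#'   (default TRUE); with FALSE a rectangular design is returned for
#'   non-tree networks.
#' @param eps relative threshold below which a concentration is treated as
#'   zero and a singularity error is raised (default `1e-9 * max|x|`).
#' @return matrix with rows in breadth-first node order and columns named by
#'   [param_order()].
#' @export
pointwise_design_matrix <- function(network, x, require_tree = TRUE,
                                    eps = 1e-9) {
  nodes <- network$nodes
  n <- length(nodes)
  if (is.null(names(x))) names(x) <- nodes else x <- x[nodes]
  if (anyNA(x)) stop("concentration vector does not cover all nodes")
  vt <- validate_tree(network)
  if (require_tree && !vt$is_tree)
    stop("structural identifiability requires a balanced tree network: ",
         vt$reason)
  rord <- if (!is.null(vt$order)) vt$order else bfs_order(network)
  if (length(rord) != n) rord <- nodes
  thr <- eps * max(abs(x))
  if (any(abs(x) <= thr))
    stop("singular design: concentration(s) of ",
         paste(names(x)[abs(x) <= thr], collapse = ", "),
         " numerically zero at this time point")
  pars <- param_order(network)
  B <- matrix(0, n, length(pars), dimnames = list(rord, pars))
  B[network$influx, "b1"] <- 1
  ed <- network$edges
  ids <- edge_ids(network)
  for (r in seq_len(nrow(ed))) {
    p <- ed$parent[r]; ch <- ed$child[r]
    B[p, ids[r]] <- B[p, ids[r]] - x[[p]]
    B[ch, ids[r]] <- B[ch, ids[r]] + x[[p]]
  }
  for (v in network$decay)
    B[v, paste0("decay:", v)] <- -x[[v]]
  B
}

#' Read a network from JSON or a 2-column edge-list file
#'
#' JSON files carry keys `nodes` (list), `edges` (list of `[parent, child]`
#' pairs), `influx_node`, and optionally `decay`. Tab-separated files carry
#' two columns (parent, child) without header; the root is inferred as the
#' unique in-degree-0 node.
#'
#' @param path file path (`.json`, else treated as TSV edge list).
#' @return a [metnet()] object.
#' @export
read_network <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    edges <- j$edges
    if (is.list(edges) && !is.data.frame(edges))
      edges <- do.call(rbind, edges)
    metnet(edges, nodes = j$nodes, influx = j$influx_node,
           decay = if (!is.null(j$decay)) j$decay else character())
  } else {
    ed <- utils::read.table(path, sep = "\t", header = FALSE,
                            colClasses = "character")
    metnet(ed[, 1:2])
  }
}

#' Write a network to JSON
#'
#' @param network a [metnet()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  jsonlite::write_json(
    list(nodes = network$nodes,
         edges = unname(as.matrix(network$edges)),
         influx_node = network$influx,
         decay = network$decay),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' The seven-node example tree
#'
#' The bundled example topology used throughout the documentation: a root
#' feeding two intermediates, each feeding two terminal products — the shape
#' of a putative quercetin glycosylation pathway in tomato seedlings.
#'
#' @return a [metnet()] object with 7 nodes and 6 edges.
#' @examples
#' example_tree7()
#' @export
example_tree7 <- function() {
  metnet(cbind(c("X1", "X1", "X2", "X2", "X3", "X3"),
               c("X2", "X3", "X4", "X5", "X6", "X7")))
}
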