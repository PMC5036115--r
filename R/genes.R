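# ---- Candidate-gene ranking and MCMC validation ----------------------------

#' Expression table container
#'
#' @param times numeric time grid (matching, or resampled to, the
#'   metabolite grid).
#' @param E numeric matrix genes x times.
#' @param genes gene identifiers; defaults to `rownames(E)`.
#' @param dispersion optional per-gene replicate dispersion used by the
#'   weighted ranking.
#' @return object of class `"expr_table"`.
#' @export
expr_table <- function(times, E, genes = rownames(E), dispersion = NULL) {
  E <- as.matrix(E)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(E)))
  stopifnot(length(genes) == nrow(E), length(times) == ncol(E),
            length(times) >= 2L, all(is.finite(E)))
  if (anyDuplicated(genes)) stop("duplicate gene identifiers")
  rownames(E) <- genes
  structure(list(times = as.numeric(times), E = E, genes = as.character(genes),
                 dispersion = dispersion), class = "expr_table")
}

#' Standardise a series to zero mean and unit variance
#'
#' @param x numeric vector (length >= 2).
#' @return z-scored vector; errors on zero-variance input (callers flag and
#'   exclude such series rather than silently zeroing them).
#' @export
standardize <- function(x) {
  stopifnot(length(x) >= 2L)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("zero-variance series cannot be standardised")
  (x - mean(x)) / s
}

#' Rank candidate genes against estimated rate dynamics
#'
#' Computes the correlation between each standardised gene expression
#' series and each standardised fitted rate curve (sampled at the
#' expression time points); a gene's score is its best correlation over
#' edges and genes are ranked by descending score. Zero-variance genes are
#' flagged and excluded. With `weighting = "dispersion"` correlations are
#' multiplied by `1 / (1 + dispersion)` (rescaled to a maximum of one) so
#' precisely measured genes are favoured.
#'
#' @param fit a [fit_kinetics()] object (the reference rates).
#' @param expr an [expr_table()].
#' @param method correlation type, `"pearson"` (default) or `"spearman"`.
#' @param weighting `"none"` or `"dispersion"`.
#' @return object of class `"gene_ranking"`: data frame `ranking` (gene,
#'   best_edge, score, rank), full `correlations` matrix (genes x edges),
#'   `excluded` genes.
#' @export
rank_genes <- function(fit, expr, method = c("pearson", "spearman"),
                       weighting = c("none", "dispersion")) {
  method <- match.arg(method)
  weighting <- match.arg(weighting)
  stopifnot(inherits(fit, "kinfit"), inherits(expr, "expr_table"))
  tt <- expr$times
  K <- rate_curves(fit$network, fit$rates, tt)
  K <- K[!grepl("^decay:", rownames(K)), , drop = FALSE]
  kz <- t(apply(K, 1L, function(k) {
    s <- stats::sd(k)
    if (s == 0) rep(0, length(k)) else (k - mean(k)) / s
  }))
  keep <- apply(expr$E, 1L, function(e) stats::sd(e) > 0)
  excluded <- expr$genes[!keep]
  E <- expr$E[keep, , drop = FALSE]
  cors <- matrix(NA_real_, nrow(E), nrow(K),
                 dimnames = list(rownames(E), rownames(K)))
  for (g in seq_len(nrow(E)))
    for (e in seq_len(nrow(K)))
      cors[g, e] <- stats::cor(E[g, ], kz[e, ], method = method)
  score <- apply(cors, 1L, max)
  if (weighting == "dispersion") {
    if (is.null(expr$dispersion))
      stop("dispersion weighting requested but no dispersion given")
    w <- 1 / (1 + expr$dispersion[keep])
    w <- w / max(w)
    score <- score * w
  }
  ord <- order(score, decreasing = TRUE)
  ranking <- data.frame(
    gene = rownames(E)[ord],
    best_edge = colnames(cors)[apply(cors, 1L, which.max)][ord],
    score = score[ord],
    rank = seq_along(ord),
    row.names = NULL)
  structure(list(ranking = ranking, correlations = cors,
                 excluded = excluded, method = method,
                 weighting = weighting),
            class = "gene_ranking")
}

#' @export
print.gene_ranking <- function(x, n = 10L, ...) {
  cat("Gene ranking (", x$method, " correlation, top ", n, " of ",
      nrow(x$ranking), ")\n", sep = "")
  print(utils::head(x$ranking, n), row.names = FALSE)
  if (length(x$excluded))
    cat("Excluded (zero variance):", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Synthetic expression panel with planted enzymes
#'
#' Test-fixture generator for the selection procedure: one planted gene per
#' edge whose series is the standardised true rate curve plus Gaussian
#' noise, and `n_decoys` decoy genes that are standardised smooth random
#' curves on the same grid (cubic splines through random control points,
#' giving decoys several shape degrees of freedom so that chance matches
#' with a rate curve are rare rather than generic).
#'
#' @param network a [metnet()] object.
#' @param rates the ground-truth [rate_set()].
#' @param times expression time grid.
#' @param n_decoys number of decoy genes (default 200).
#' @param noise Gaussian noise standard deviation added to planted genes
#'   (default 0.05; 0 gives correlation 1 with the true rates).
#' @param seed optional RNG seed.
#' @param standardized if TRUE (default) each series is a standardised
#'   shape mapped onto a positive, microarray-like intensity scale (a
#'   random affine transform, which leaves all correlations unchanged);
#'   FALSE keeps the raw rate curves as expression values, useful as an
#'   oracle assignment whose residual sits at the simulator's noise floor.
#' @return an [expr_table()]; planted genes are named `"GT_<edge>"`, with
#'   attribute `planted` listing them.
#' @export
synthesize_expression <- function(network, rates, times, n_decoys = 200L,
                                  noise = 0.05, seed = NULL,
                                  standardized = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  ids <- edge_ids(network)
  # planted genes track their enzyme's activity: the rate curve in
  # arbitrary positive units (random per-gene scale) plus relative noise --
  # transcript abundance proportional to catalytic capacity
  planted <- t(vapply(ids, function(id) {
    k <- eval_rate(rates$rates[[id]], times)
    if (!standardized) return(k + stats::rnorm(length(times), 0, noise))
    # noise on the standardised scale (relative to the curve's sd), so the
    # planted correlation is ~1 - noise^2/2 regardless of how flat k is
    y <- k + stats::sd(k) * stats::rnorm(length(times), 0, noise)
    kbar <- max(mean(k), 1e-8)
    stats::runif(1, 0.5, 2) * pmax(y / kbar, 0.01)
  }, numeric(length(times))))
  rownames(planted) <- paste0("GT_", gsub("->", "_", ids))
  # decoys: positive smooth random intensity curves (cubic splines through
  # random positive control points, so their shapes have several degrees of
  # freedom and chance matches with a rate curve are rare, not generic)
  ctrl <- seq(min(times), max(times), length.out = 5L)
  decoys <- matrix(0, 0L, length(times))
  if (n_decoys > 0L) {
    decoys <- t(vapply(seq_len(n_decoys), function(i) {
      y <- stats::spline(ctrl, stats::runif(length(ctrl), 0.2, 2),
                         xout = times)$y
      if (stats::sd(y) == 0) y <- y + stats::rnorm(length(times), 0, 1e-3)
      if (standardized) stats::runif(1, 0.5, 2) * pmax(y, 0.01)
      else standardize(y)
    }, numeric(length(times))))
    rownames(decoys) <- paste0("decoy_", seq_len(n_decoys))
  }
  tab <- expr_table(times, rbind(planted, decoys))
  attr(tab, "planted") <- rownames(planted)
  tab
}

# Precomputed state for the MCMC residual: RK4 stage grid, all expression
# curves linearly interpolated onto it, and the network index arrays
# (decay pseudo-edges dropped: substituted models carry no decay flux).
.mcmc_context <- function(network, data, Emat, b1, n_sub = 2L) {
  sg <- .stage_grid(data$times, n_sub)
  i <- findInterval(sg$stage, data$times, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(data$times) - 1L)
  w <- (sg$stage - data$times[i]) / (data$times[i + 1L] - data$times[i])
  Estage <- Emat[, i, drop = FALSE] * rep(1 - w, each = nrow(Emat)) +
    Emat[, i + 1L, drop = FALSE] * rep(w, each = nrow(Emat))
  idx <- .edge_index(network)
  nE <- nrow(network$edges)
  list(sg = sg, parent = idx$parent[seq_len(nE)],
       child = idx$child[seq_len(nE)], root = idx$root, Estage = Estage,
       X = data$X, x0 = data$X[, 1L], b1 = b1, n_sub = as.integer(n_sub))
}

#' Validate a gene ranking by MCMC substitution into the kinetic model
#'
#' Takes two rank windows of the gene ranking (by default ranks 1–10 and
#' 11–20) and, for each set, runs independent Metropolis chains over the
#' assignment of the set's genes to the network's edges together with one
#' positive scale factor per edge. Each state's residual is the trajectory
#' objective with every rate curve \eqn{k_{ij}(t)} replaced by the clipped,
#' scaled expression curve of the assigned gene. The per-chain minimum
#' residuals of the two sets are compared by a Welch two-sample t-test
#' (means) and an F-test (variances): significantly smaller residuals for
#' the top-ranked set support the ranking.
#'
#' @param fit the reference [fit_kinetics()] object (also supplies the
#'   network and the estimated influx).
#' @param data the metabolite [ts_data()] used for the residuals.
#' @param expr the [expr_table()].
#' @param ranking a [rank_genes()] object.
#' @param setA,setB rank windows (default `1:10` and `11:20`); the sets
#'   must be disjoint and at least as large as the number of edges.
#' @param iterations number of independent chains per set (default 200).
#' @param samples Metropolis steps per chain (default 1000).
#' @param seed RNG seed.
#' @param scale_sd log-normal step size for scale proposals (default 0.2).
#' @return object of class `"mcmc_validation"`: per-iteration minimum
#'   residuals `residA`, `residB`, `mean_test` and `var_test` (htest
#'   objects), and the settings.
#' @export
mcmc_validate <- function(fit, data, expr, ranking, setA = 1:10,
                          setB = 11:20, iterations = 200L, samples = 1000L,
                          seed = 1L, scale_sd = 0.2) {
  stopifnot(inherits(ranking, "gene_ranking"))
  identical_sets <- setequal(setA, setB)
  if (!identical_sets && length(intersect(setA, setB)))
    stop("setA and setB must be disjoint rank windows (or identical, as ",
         "a null-case diagnostic)")
  network <- fit$network
  nE <- nrow(network$edges)
  if (length(setA) < nE || length(setB) < nE)
    stop("each gene set must cover the network's ", nE, " edges")
  data <- ts_data(data$times, data$X[network$nodes, , drop = FALSE],
                  network$nodes)
  genesA <- ranking$ranking$gene[ranking$ranking$rank %in% setA]
  genesB <- ranking$ranking$gene[ranking$ranking$rank %in% setB]
  tt <- data$times
  Emat <- t(vapply(expr$genes, function(g)
    stats::approx(expr$times, expr$E[g, ], xout = tt, rule = 2L)$y,
    numeric(length(tt))))
  rownames(Emat) <- expr$genes
  ctx <- .mcmc_context(network, data, Emat,
                       b1 = max(0, fit$coefficients[["b1"]]), n_sub = 2L)
  Kref <- rate_curves(network, fit$rates, tt)
  Kref <- Kref[!grepl("^decay:", rownames(Kref)), , drop = FALSE]
  init_scale <- function(gene, e) {
    y <- pmax(Emat[gene, ], 0)
    denom <- sum(y^2)
    if (denom == 0) return(1e-3)
    max(1e-3, sum(Kref[e, ] * y) / denom)
  }
  # least-squares reference scale for every gene x edge pair
  Eplus <- pmax(Emat, 0)
  Sinit <- (Eplus %*% t(Kref)) / pmax(rowSums(Eplus^2), 1e-9)
  Sinit <- pmax(Sinit, 1e-3)
  run_set <- function(genes, seed0) {
    set.seed(seed0)
    mins <- numeric(iterations)
    gidx <- match(genes, rownames(Emat)) - 1L
    for (it in seq_len(iterations)) {
      assign <- sample(gidx, nE, replace = length(gidx) < nE)
      scales <- vapply(seq_len(nE), function(e)
        init_scale(expr$genes[assign[e] + 1L], e), numeric(1L))
      mins[it] <- metropolis_chain(ctx$Estage, gidx, assign, scales, Sinit,
                                   ctx$parent, ctx$child, ctx$X, ctx$x0,
                                   ctx$sg$h, ctx$n_sub, ctx$root, ctx$b1,
                                   as.integer(samples), scale_sd, 0.4)
    }
    mins
  }
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 2L)
  residA <- run_set(genesA, seeds[1L])
  residB <- run_set(genesB, seeds[2L])
  mean_test <- stats::t.test(residA, residB)
  var_test <- stats::var.test(residA, residB)
  structure(list(residA = residA, residB = residB,
                 mean_test = mean_test, var_test = var_test,
                 setA = setA, setB = setB, iterations = iterations,
                 samples = samples, seed = seed),
            class = "mcmc_validation")
}

#' @export
print.mcmc_validation <- function(x, ...) {
  cat("MCMC ranking validation:", x$iterations, "chains x", x$samples,
      "steps per set\n")
  cat("  mean residual set A (ranks ", min(x$setA), "-", max(x$setA), "): ",
      signif(mean(x$residA), 4), "\n", sep = "")
  cat("  mean residual set B (ranks ", min(x$setB), "-", max(x$setB), "): ",
      signif(mean(x$residB), 4), "\n", sep = "")
  cat("  mean test P =", format.pval(x$mean_test$p.value, digits = 3),
      " variance test P =", format.pval(x$var_test$p.value, digits = 3),
      "\n")
  invisible(x)
}

#' Read / write gene-expression tables
#'
#' Same dialect as [read_timeseries()]: first column gene identifier,
#' header row of numeric times.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return an [expr_table()].
#' @export
read_expression <- function(path, sep = "\t") {
  ts <- read_timeseries(path, sep)
  expr_table(ts$times, ts$X, ts$labels)
}

#' @rdname read_expression
#' @param expr an [expr_table()] to write.
#' @export
write_expression <- function(expr, path, sep = "\t") {
  write_timeseries(ts_data(expr$times, expr$E, expr$genes), path, sep)
}
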