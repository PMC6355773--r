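#' Markov Cluster (MCL) graph clustering
#'
#' In-house implementation of the MCL algorithm on a weighted
#' undirected graph.  The adjacency matrix (optionally with self-loops
#' added, weight equal to the node's maximum incident edge weight) is
#' column-normalized to a stochastic flow matrix, then expansion
#' (matrix power) and inflation (elementwise power followed by column
#' renormalization) alternate until the flow changes by less than
#' \code{tol} or \code{max_iter} iterations are reached.  Clusters are
#' the connected components of the support of the limiting flow matrix
#' (the attractor interpretation).  The procedure is deterministic.
#'
#' @param network an [build_overlap_network()] result, or a symmetric
#'   non-negative weight matrix with dimnames.
#' @param inflation inflation exponent (> 1 for contraction; must be
#'   positive).
#' @param expansion integer matrix-power exponent (>= 2).
#' @param max_iter maximum number of expansion/inflation rounds.
#' @param tol convergence threshold on the maximum entrywise change.
#' @param self_loops add self-loops before normalization (canonical
#'   MCL regularisation).
#' @return named integer vector of cluster ids (contiguous from 1, in
#'   order of first node), class \code{cluster_assignment}, with
#'   attributes \code{n_clusters}, \code{iterations}, \code{converged}
#'   and \code{stochastic_dev} (largest deviation of any column sum
#'   from 1 observed after an inflation step).
#' @export
mcl_cluster <- function(network, inflation = 2.0, expansion = 2L,
                        max_iter = 100L, tol = 1e-6, self_loops = TRUE) {
  if (inflation <= 0) stop("inflation must be positive")
  if (expansion < 2L) stop("expansion must be at least 2")
  adj <- if (inherits(network, "overlap_network")) {
    .network_adjacency(network)
  } else {
    as.matrix(network)
  }
  n <- nrow(adj)
  if (n == 0L) stop("empty graph")
  if (any(adj < 0)) stop("edge weights must be non-negative")
  if (max(abs(adj - t(adj))) > 1e-8) stop("adjacency must be symmetric")
  if (is.null(rownames(adj))) rownames(adj) <- colnames(adj) <-
      paste0("n", seq_len(n))
  if (self_loops) {
    loop <- apply(adj, 1, max)
    loop[loop == 0] <- 1
    diag(adj) <- loop
  } else if (any(colSums(adj) == 0)) {
    # keep isolated nodes well-defined even without regularisation
    iso <- colSums(adj) == 0
    diag(adj)[iso] <- 1
  }
  m <- sweep(adj, 2, colSums(adj), "/")
  dev_max <- 0
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    mexp <- m
    for (e in seq_len(expansion - 1L)) mexp <- mexp %*% m
    minf <- mexp^inflation
    minf[minf < 1e-12] <- 0
    cs <- colSums(minf)
    cs[cs == 0] <- 1
    minf <- sweep(minf, 2, cs, "/")
    dev_max <- max(dev_max, max(abs(colSums(minf) - 1)))
    delta <- max(abs(minf - m))
    m <- minf
    if (delta < tol) { converged <- TRUE; break }
  }
  support <- (m > tol) | t(m > tol)
  comp <- .components(support)
  structure(comp, class = "cluster_assignment",
            n_clusters = max(comp), iterations = it,
            converged = converged, stochastic_dev = dev_max)
}

# adjacency matrix (weight = shared gene count) from an overlap network
.network_adjacency <- function(network) {
  nm <- names(network$nodes)
  adj <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  e <- network$edges
  for (j in seq_len(nrow(e))) {
    adj[e$node_a[j], e$node_b[j]] <- e$shared_genes[j]
    adj[e$node_b[j], e$node_a[j]] <- e$shared_genes[j]
  }
  adj
}

# connected components of a logical adjacency matrix by breadth-first
# search; ids contiguous from 1 in order of first node
.components <- function(support) {
  n <- nrow(support)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(support[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  stats::setNames(comp, rownames(support))
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("MCL clustering: ", attr(x, "n_clusters"), " cluster(s), ",
      attr(x, "iterations"), " iteration(s)",
      if (isTRUE(attr(x, "converged"))) ", converged" else
        " (not converged)", "\n", sep = "")
  print(split(names(x), unclass(x)))
  invisible(x)
}
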