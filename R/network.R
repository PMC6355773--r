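#' Hypergeometric gene-set overlap test
#'
#' Upper-tail probability of observing at least the given overlap when
#' \code{|b|} genes are sampled without replacement from a universe
#' containing \code{|a|} marked genes: \eqn{P(X \ge k)} with
#' \eqn{X \sim} Hypergeometric(\code{universe_size}, \code{|a|},
#' \code{|b|}).
#'
#' @param set_a,set_b character vectors of gene identifiers.
#' @param universe_size number of genes in the measured universe.
#' @return one-sided p-value.
#' @export
overlap_test <- function(set_a, set_b, universe_size) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (length(set_a) > universe_size || length(set_b) > universe_size)
    stop("a gene set is larger than the universe")
  k <- length(intersect(set_a, set_b))
  stats::phyper(k - 1, length(set_a), universe_size - length(set_a),
                length(set_b), lower.tail = FALSE)
}

#' Build the signature-overlap network
#'
#' Every non-empty up set and down set of each signature becomes a node
#' (named \code{<signature>.up} / \code{<signature>.down}).  All node
#' pairs are tested for overlap with [overlap_test()]; p-values are
#' Benjamini-Hochberg adjusted across all pairs, and edges are kept
#' where \code{q <= q_threshold} and at least one gene is shared.  Edge
#' weight is the shared-gene count.
#'
#' @param signatures list of [gene_signature()] objects.
#' @param universe_size number of genes on the derivation platform.
#' @param q_threshold FDR threshold for keeping an edge.
#' @return object of class \code{overlap_network}: \code{nodes} (named
#'   list of gene sets), \code{edges} (data.frame: \code{node_a},
#'   \code{node_b}, \code{shared_genes}, \code{overlap_p},
#'   \code{overlap_q}), \code{universe_size}, \code{q_threshold}.
#' @export
build_overlap_network <- function(signatures, universe_size,
                                  q_threshold = 0.05) {
  if (inherits(signatures, "gene_signature")) signatures <- list(signatures)
  nodes <- list()
  for (sig in signatures) {
    if (length(sig$up))
      nodes[[paste0(sig$name, ".up")]] <- sig$up
    if (length(sig$down))
      nodes[[paste0(sig$name, ".down")]] <- sig$down
  }
  if (length(nodes) < 2L)
    stop("need at least 2 non-empty gene sets to build a network")
  nm <- names(nodes)
  pairs <- utils::combn(length(nodes), 2)
  shared <- integer(ncol(pairs))
  pv <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- nodes[[pairs[1, j]]]
    b <- nodes[[pairs[2, j]]]
    shared[j] <- length(intersect(a, b))
    pv[j] <- overlap_test(a, b, universe_size)
  }
  qv <- bh_adjust(pv)
  keep <- qv <= q_threshold & shared >= 1L
  edges <- data.frame(node_a = nm[pairs[1, keep]],
                      node_b = nm[pairs[2, keep]],
                      shared_genes = shared[keep],
                      overlap_p = pv[keep], overlap_q = qv[keep],
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges,
                 universe_size = universe_size,
                 q_threshold = q_threshold),
            class = "overlap_network")
}

#' @export
print.overlap_network <- function(x, ...) {
  cat("Signature overlap network: ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges (q <= ", x$q_threshold, ", universe ",
      x$universe_size, ")\n", sep = "")
  if (nrow(x$edges)) print(utils::head(x$edges, 10), row.names = FALSE)
  invisible(x)
}

#' Write an overlap network as a tab-delimited edge list
#'
#' @param network an [build_overlap_network()] result.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_edge_list <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
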