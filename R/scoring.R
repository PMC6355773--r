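# per-gene robust rescaling: map the central q-range of each gene to
# [-1, +1].  fit/apply are split so cross-validation can learn the
# transform on training samples only.
.rescale_fit <- function(expr, q = 0.95) {
  if (q <= 0 || q >= 1) stop("rescaling quantile q must lie in (0, 1)")
  lo <- (1 - q) / 2
  if (anyNA(expr)) {
    qs <- t(apply(expr, 1, stats::quantile, probs = c(lo, 1 - lo),
                  na.rm = TRUE, names = FALSE))
    return(list(qlo = qs[, 1], qhi = qs[, 2], q = q))
  }
  # complete rows: type-7 quantiles from one row-wise sort, avoiding a
  # quantile() call per gene
  n <- ncol(expr)
  o <- order(rep.int(seq_len(nrow(expr)), n), expr, method = "radix")
  srt <- matrix(expr[o], nrow(expr), n, byrow = TRUE)
  qt <- function(p) {
    h <- (n - 1) * p + 1
    f <- floor(h)
    srt[, f] + (h - f) * (srt[, min(f + 1, n)] - srt[, f])
  }
  list(qlo = qt(lo), qhi = qt(1 - lo), q = q)
}

.rescale_apply <- function(expr, fit) {
  rng <- fit$qhi - fit$qlo
  const <- rng <= 0 | !is.finite(rng)
  rng[const] <- 1
  out <- 2 * (expr - fit$qlo) / rng - 1
  out[const, ] <- 0
  attr(out, "constant_genes") <- rownames(expr)[const]
  out
}

#' Rescale an expression dataset for cross-cohort comparability
#'
#' Per gene, a linear transform maps the central \code{q} quantile
#' range to \eqn{[-1, +1]}: for the default \code{q = 0.95} the 2.5th
#' and 97.5th percentiles map to -1 and +1.  This robust rescaling puts
#' expression values from different platforms on a common scale before
#' signature scoring.  Genes with zero central range map to all zeros
#' with a warning.
#'
#' @param expr expression matrix (genes x samples, log2).
#' @param q central quantile span in (0, 1).
#' @return rescaled matrix of the same shape.
#' @export
rescale_dataset <- function(expr, q = 0.95) {
  if (ncol(expr) < 3L) stop("rescaling needs at least 3 samples")
  fit <- .rescale_fit(expr, q)
  out <- .rescale_apply(expr, fit)
  cg <- attr(out, "constant_genes")
  if (length(cg))
    warning(length(cg), " constant gene(s) rescaled to zero (e.g. ",
            cg[1], ")")
  dimnames(out) <- dimnames(expr)
  attr(out, "dataset_id") <- attr(expr, "dataset_id")
  out
}

#' Score a gene signature in a (rescaled) expression matrix
#'
#' The score of a sample is the mean over signature genes present in
#' the matrix of weight times rescaled expression, with weight +1 for
#' up genes and -1 for down genes.  Signature genes absent from the
#' matrix are dropped and counted.
#'
#' @param expr rescaled expression matrix (see [rescale_dataset()]).
#' @param sig a [gene_signature()].
#' @return named numeric vector of per-sample scores (class
#'   \code{score_vector}) with attributes \code{signature},
#'   \code{n_genes_used} and \code{n_genes_missing}.
#' @export
signature_score <- function(expr, sig) {
  stopifnot(inherits(sig, "gene_signature"))
  w <- weights.gene_signature(sig)
  present <- names(w)[names(w) %in% rownames(expr)]
  if (!length(present))
    stop("no genes of signature '", sig$name, "' present in the matrix")
  sub <- expr[present, , drop = FALSE] * w[present]
  sc <- colMeans(sub, na.rm = TRUE)
  structure(sc, class = "score_vector", signature = sig$name,
            n_genes_used = length(present),
            n_genes_missing = length(w) - length(present))
}

#' @export
print.score_vector <- function(x, ...) {
  cat("Signature scores for '", attr(x, "signature"), "' (",
      length(x), " samples; ", attr(x, "n_genes_used"), " genes used, ",
      attr(x, "n_genes_missing"), " missing)\n", sep = "")
  print(unclass(stats::setNames(as.vector(x), names(x))), ...)
  invisible(x)
}

#' Split samples into score tertiles
#'
#' Empirical tertile cut points (type-7 quantiles); samples exactly on
#' a boundary go to the lower group, so ties break deterministically.
#' If all scores are equal the grouping is degenerate: every sample is
#' labelled \code{mid} and the result carries
#' \code{attr(, "degenerate") = TRUE}.
#'
#' @param scores numeric scores (>= 3 non-missing).
#' @return factor with levels \code{low}, \code{mid}, \code{high}
#'   (missing scores give \code{NA}).
#' @export
tertile_groups <- function(scores) {
  ok <- !is.na(scores)
  if (sum(ok) < 3L) stop("tertile grouping needs at least 3 scores")
  qs <- stats::quantile(scores[ok], probs = c(1, 2) / 3, names = FALSE)
  if (qs[1] == qs[2] && all(scores[ok] == scores[ok][1])) {
    out <- factor(rep("mid", length(scores)),
                  levels = c("low", "mid", "high"))
    out[!ok] <- NA
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  lab <- ifelse(scores <= qs[1], "low",
                ifelse(scores <= qs[2], "mid", "high"))
  factor(lab, levels = c("low", "mid", "high"))
}
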