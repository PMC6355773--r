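#' Fit an RPPA-guided gene expression signature
#'
#' The top-level fitting function: given matched expression and RPPA
#' data, derives a directional gene signature that predicts the high/low
#' activation status of one protein marker, choosing the FDR and
#' fold-change selection thresholds by nested k-fold cross-validation
#' maximising the AUC (see [nested_cv_derive()] for the procedure).
#'
#' @param expr expression matrix (genes x samples, log2), e.g. from
#'   [read_expression_matrix()].
#' @param rppa RPPA table (samples x markers) from [rppa_table()], or a
#'   named per-sample numeric vector of marker values.
#' @param marker marker column name when \code{rppa} is a table.
#' @param grid threshold grid (see [default_grid()]).
#' @param k number of folds for both cross-validation loops.
#' @param dichotomize_method \code{"median"} or
#'   \code{"tertile_extremes"}.
#' @param rescale_q quantile span for the per-gene rescaling used when
#'   scoring (default 0.95: central 95\% range maps to [-1, 1]).
#' @param seed integer seed for the fold shuffles.
#' @return object of class \code{rppa_signature} with components
#'   \code{signature} (the final [gene_signature()]), \code{cv} (the
#'   [nested_cv_derive()] result), \code{marker}, \code{rescale_q},
#'   \code{call}.
#' @seealso [predict.rppa_signature()] to score new cohorts,
#'   [build_overlap_network()] and [pooled_analysis()] for downstream
#'   analyses.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_samples = 80, n_genes = 300,
#'                                      planted_up = 15, planted_down = 15,
#'                                      effect_size = 2, seed = 7))
#' fit <- rppa_signature(cohort$expr, cohort$rppa, marker = "pAKT",
#'                       k = 5, seed = 7)
#' fit
#' head(coef(fit))
#' sc <- predict(fit, cohort$expr)
#' @export
rppa_signature <- function(expr, rppa, marker = colnames(rppa)[1],
                           grid = default_grid(), k = 10L,
                           dichotomize_method = "median",
                           rescale_q = 0.95, seed = 1L) {
  values <- if (is.matrix(rppa) || is.data.frame(rppa)) {
    if (!marker %in% colnames(rppa))
      stop("marker '", marker, "' not found in the RPPA table")
    stats::setNames(as.matrix(rppa)[, marker], rownames(rppa))
  } else {
    rppa
  }
  cv <- nested_cv_derive(expr, values, grid = grid, k = k,
                         dichotomize_method = dichotomize_method,
                         seed = seed, rescale_q = rescale_q,
                         marker = marker)
  structure(list(signature = cv$signature, cv = cv, marker = marker,
                 rescale_q = rescale_q, call = match.call()),
            class = "rppa_signature")
}

#' @export
print.rppa_signature <- function(x, ...) {
  cat("RPPA-guided gene signature for marker '", x$marker, "'\n", sep = "")
  print(x$signature)
  cat(sprintf("  thresholds chosen by nested %d-fold CV\n", x$cv$k))
  invisible(x)
}

#' Summarise a fitted RPPA signature
#'
#' @param object an \code{rppa_signature} fit.
#' @param ... unused.
#' @return list of class \code{summary.rppa_signature} with the final
#'   signature, the chosen thresholds, the outer-CV AUC and the per
#'   outer-fold inner-CV AUC surface over the grid.
#' @export
summary.rppa_signature <- function(object, ...) {
  cv <- object$cv
  grid_tab <- cbind(cv$grid,
                    mean_inner_auc = rowMeans(cv$inner_auc),
                    times_chosen = tabulate(cv$chosen_per_fold,
                                            nbins = nrow(cv$grid)))
  structure(list(marker = object$marker, signature = object$signature,
                 chosen = cv$chosen, outer_auc = cv$outer_auc,
                 outer_auc_p = cv$outer_auc_p, grid = grid_tab,
                 empty_flag = cv$empty_flag, k = cv$k),
            class = "summary.rppa_signature")
}

#' @export
print.summary.rppa_signature <- function(x, ...) {
  cat("RPPA-guided signature: marker '", x$marker, "'\n", sep = "")
  cat(sprintf("  outer-CV AUC %.3f (p = %.3g), %d up / %d down genes\n",
              x$outer_auc, x$outer_auc_p, length(x$signature$up),
              length(x$signature$down)))
  cat(sprintf("  chosen: FDR <= %g, |log2 FC| >= %g\n",
              x$chosen$fdr_max, x$chosen$fc_min))
  cat("Grid (inner-CV mean AUC, times chosen across outer folds):\n")
  print(x$grid, row.names = FALSE)
  invisible(x)
}

#' Signature gene weights of a fit
#'
#' @param object an \code{rppa_signature} fit.
#' @param ... unused.
#' @return named numeric vector: +1 for up genes, -1 for down genes.
#' @export
coef.rppa_signature <- function(object, ...) {
  weights.gene_signature(object$signature)
}

#' Score a new cohort with a fitted signature
#'
#' The new expression matrix is rescaled per gene (central
#' \code{rescale_q} range to [-1, 1]) and each sample receives the
#' sign-weighted mean expression of the signature genes.
#'
#' @param object an \code{rppa_signature} fit.
#' @param newdata expression matrix (genes x samples, log2).
#' @param rescale logical; rescale \code{newdata} first (set to
#'   \code{FALSE} if it is already rescaled).
#' @param ... unused.
#' @return a \code{score_vector} (named numeric, one score per sample).
#' @export
predict.rppa_signature <- function(object, newdata, rescale = TRUE, ...) {
  if (length(object$signature) == 0L)
    stop("cannot score with an empty signature")
  m <- if (rescale) rescale_dataset(newdata, object$rescale_q) else newdata
  signature_score(m, object$signature)
}

#' Plot the cross-validation AUC surface of a fit
#'
#' Displays the inner-CV mean AUC (averaged over outer folds) as an
#' image over the FDR x fold-change grid, marking the chosen point.
#'
#' @param x an \code{rppa_signature} fit.
#' @param ... passed to [graphics::image()].
#' @export
plot.rppa_signature <- function(x, ...) {
  cv <- x$cv
  fdr <- sort(unique(cv$grid$fdr_max))
  fc <- sort(unique(cv$grid$fc_min))
  z <- matrix(NA_real_, length(fdr), length(fc))
  m <- rowMeans(cv$inner_auc)
  for (i in seq_len(nrow(cv$grid)))
    z[match(cv$grid$fdr_max[i], fdr), match(cv$grid$fc_min[i], fc)] <- m[i]
  graphics::image(seq_along(fdr), seq_along(fc), z, axes = FALSE,
                  xlab = "max FDR", ylab = "min |log2 FC|",
                  main = paste0("Inner-CV AUC, marker ", x$marker), ...)
  graphics::axis(1, at = seq_along(fdr), labels = fdr)
  graphics::axis(2, at = seq_along(fc), labels = fc)
  graphics::points(match(cv$chosen$fdr_max, fdr),
                   match(cv$chosen$fc_min, fc), pch = 4, cex = 2, lwd = 2)
  invisible(x)
}
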