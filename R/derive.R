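#' Dichotomize an RPPA marker into high/low activation classes
#'
#' \code{median}: samples strictly above the median are \code{high},
#' the rest \code{low}; nothing is excluded.  \code{tertile_extremes}:
#' the top third of ranks is \code{high}, the bottom third \code{low},
#' the middle third \code{excluded}.  Missing values are \code{NA}.
#'
#' @param values per-sample marker values (>= 4 non-missing).
#' @param method \code{"median"} or \code{"tertile_extremes"}.
#' @return factor with levels \code{low}, \code{excluded}, \code{high},
#'   same length and names as \code{values}.
#' @export
dichotomize_rppa <- function(values, method = c("median", "tertile_extremes")) {
  method <- match.arg(method)
  ok <- !is.na(values)
  if (sum(ok) < 4L) stop("dichotomization needs at least 4 non-missing values")
  v <- values[ok]
  if (length(unique(v)) < 2L)
    stop("all marker values identical; no high/low split possible")
  lab <- rep(NA_character_, length(values))
  if (method == "median") {
    med <- stats::median(v)
    lab[ok] <- ifelse(values[ok] > med, "high", "low")
  } else {
    r <- rank(v)
    n <- length(v)
    cls <- ifelse(r <= n / 3, "low", ifelse(r > 2 * n / 3, "high", "excluded"))
    lab[ok] <- cls
  }
  out <- factor(lab, levels = c("low", "excluded", "high"))
  names(out) <- names(values)
  out
}

#' Per-gene Welch differential expression between activation classes
#'
#' For every gene, a Welch two-sample t-test of log2 expression in
#' \code{high} versus \code{low} samples; \code{log2_fc} is the mean
#' difference high minus low; q-values are Benjamini-Hochberg over all
#' tested genes.  Missing expression values are handled complete-case
#' per gene.  A gene with identical values in both classes gets
#' \code{t = 0, p = 1}; a gene with fewer than 2 usable values in a
#' class is not tested (\code{p = NA}).
#'
#' @param expr expression matrix, genes x samples (log2).
#' @param labels per-sample factor with levels including \code{low} and
#'   \code{high} (others and \code{NA} are dropped); length
#'   \code{ncol(expr)}.
#' @return data.frame of class \code{de_result}: \code{gene},
#'   \code{mean_high}, \code{mean_low}, \code{log2_fc},
#'   \code{t_statistic}, \code{df}, \code{p_value}, \code{q_value}.
#' @export
differential_expression <- function(expr, labels) {
  if (length(labels) != ncol(expr))
    stop("labels length must equal the number of samples")
  hi <- !is.na(labels) & labels == "high"
  lo <- !is.na(labels) & labels == "low"
  if (sum(hi) < 2L || sum(lo) < 2L)
    stop("need at least 2 samples per class (have ", sum(hi), " high, ",
         sum(lo), " low)")
  st <- function(cols) {
    x <- expr[, cols, drop = FALSE]
    n <- rowSums(!is.na(x))
    m <- rowMeans(x, na.rm = TRUE)
    v <- rowSums((x - m)^2, na.rm = TRUE) / pmax(n - 1, 1)
    list(n = n, m = m, v = v)
  }
  a <- st(hi)
  b <- st(lo)
  fc <- a$m - b$m
  se2 <- a$v / a$n + b$v / b$n
  tt <- fc / sqrt(se2)
  df <- se2^2 / (a$v^2 / (a$n^2 * (a$n - 1)) + b$v^2 / (b$n^2 * (b$n - 1)))
  p <- 2 * stats::pt(-abs(tt), df)
  zero <- is.finite(fc) & se2 == 0
  tt[zero & fc == 0] <- 0
  p[zero & fc == 0] <- 1
  p[zero & fc != 0] <- 0
  untest <- a$n < 2 | b$n < 2
  tt[untest] <- NA_real_
  p[untest] <- NA_real_
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- bh_adjust(p[!is.na(p)])
  structure(data.frame(gene = rownames(expr), mean_high = a$m,
                       mean_low = b$m, log2_fc = fc, t_statistic = tt,
                       df = df, p_value = p, q_value = q,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("de_result", "data.frame"))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Step-up q-values controlling the false discovery rate:
#' \eqn{q_{(i)} = \min_{j \ge i} m \, p_{(j)} / j}, capped at 1, with
#' the original order restored.
#'
#' @param p_values numeric vector of p-values in [0, 1] (\code{NA}
#'   allowed and propagated).
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Select a directional signature from differential-expression results
#'
#' Up genes satisfy \code{q <= fdr_max} and \code{log2_fc >= fc_min};
#' down genes satisfy \code{q <= fdr_max} and \code{log2_fc <= -fc_min}.
#' An empty signature is a legal result.
#'
#' @param de a [differential_expression()] result.
#' @param fdr_max maximum Benjamini-Hochberg q-value.
#' @param fc_min minimum absolute log2 fold change.
#' @param name signature name.
#' @return a [gene_signature()] carrying the thresholds.
#' @export
select_signature <- function(de, fdr_max, fc_min, name = "signature") {
  ok <- !is.na(de$q_value) & de$q_value <= fdr_max
  gene_signature(name,
                 up = de$gene[ok & de$log2_fc >= fc_min],
                 down = de$gene[ok & de$log2_fc <= -fc_min],
                 fdr_max = fdr_max, fc_min = fc_min)
}

#' AUC and Mann-Whitney p-value of scores against high/low labels
#'
#' The AUC is the probability that a random \code{high} sample scores
#' above a random \code{low} sample, counting ties as 1/2 — i.e. the
#' Mann-Whitney U statistic divided by the number of cross-class pairs.
#' The p-value uses the tie-corrected normal approximation of the U
#' test (two-sided).
#'
#' @param scores numeric scores.
#' @param labels factor/character with classes \code{high} and
#'   \code{low}, both non-empty.
#' @return list with \code{auc} and \code{p_value}.
#' @export
auc_mann_whitney <- function(scores, labels) {
  keep <- !is.na(scores) & labels %in% c("high", "low")
  scores <- scores[keep]
  labels <- as.character(labels[keep])
  n1 <- sum(labels == "high")
  n0 <- sum(labels == "low")
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be non-empty (", n1, " high, ", n0, " low)")
  r <- rank(scores)
  u <- sum(r[labels == "high"]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n0)
  nn <- n1 + n0
  ties <- table(scores)
  s2 <- (n1 * n0 / 12) * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
  p <- if (s2 <= 0) 1 else 2 * stats::pnorm(-abs(u - n1 * n0 / 2) / sqrt(s2))
  list(auc = auc, p_value = min(p, 1))
}

#' Default FDR x fold-change threshold grid
#'
#' @return data.frame with columns \code{fdr_max} and \code{fc_min}.
#' @export
default_grid <- function() {
  expand.grid(fdr_max = c(0.001, 0.01, 0.05, 0.1),
              fc_min = c(0.5, 1.0, 1.5, 2.0), KEEP.OUT.ATTRS = FALSE)
}

# stratified fold assignment: within each class, shuffled indices are
# dealt round-robin into k folds
.stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    ix <- sample(which(labels == cl))
    fold[ix] <- rep_len(seq_len(k), length(ix))
  }
  fold
}

# grid preference order for ties: smaller fdr_max, then larger fc_min
.grid_order <- function(grid) order(grid$fdr_max, -grid$fc_min)

#' Derive a signature by nested cross-validated threshold selection
#'
#' The marker is dichotomized into high/low activation classes.  An
#' outer stratified k-fold split assesses the whole procedure: within
#' each outer training set, an inner k-fold cross-validation computes
#' the mean AUC of the signature selected at every (FDR, fold-change)
#' grid point (differential expression and the rescaling transform are
#' fit on the inner training samples only; inner validation samples are
#' scored with the sign-weighted signature score).  The best grid point
#' is refit on the outer training set and evaluated on the held-out
#' fold; the outer AUC pools scores and labels across all outer test
#' folds.  The final signature is selected on all samples at the grid
#' point chosen most often across outer folds (ties prefer the smaller
#' FDR, then the larger fold change).
#'
#' @param expr expression matrix (genes x samples, log2).
#' @param rppa_values per-sample marker values, aligned with
#'   \code{colnames(expr)} (named vectors are matched by name).
#' @param grid data.frame with columns \code{fdr_max}, \code{fc_min}.
#' @param k folds for both the outer and inner loops.
#' @param dichotomize_method passed to [dichotomize_rppa()].
#' @param seed integer seed for the fold shuffles.
#' @param rescale_q quantile span for [rescale_dataset()]-style
#'   rescaling inside the cross-validation.
#' @param marker name used for the resulting signature.
#' @return list of class \code{cv_result}: \code{grid},
#'   \code{inner_auc} (grid x outer-fold matrix of inner-CV mean AUC),
#'   \code{chosen_per_fold}, \code{chosen} (row of \code{grid}),
#'   \code{outer_auc}, \code{outer_auc_p}, \code{signature} (final
#'   [gene_signature()]), \code{empty_flag}, \code{labels} and
#'   \code{outer_fold} (per-sample fold assignment).
#' @export
nested_cv_derive <- function(expr, rppa_values, grid = default_grid(),
                             k = 10L, dichotomize_method = "median",
                             seed = 1L, rescale_q = 0.95,
                             marker = "marker") {
  if (!nrow(grid)) stop("empty threshold grid")
  if (!is.null(names(rppa_values)) && !is.null(colnames(expr))) {
    miss <- setdiff(colnames(expr), names(rppa_values))
    if (length(miss))
      stop("no marker value for sample(s): ",
           paste(utils::head(miss, 3), collapse = ", "))
    rppa_values <- rppa_values[colnames(expr)]
  }
  lab_all <- dichotomize_rppa(rppa_values, dichotomize_method)
  use <- !is.na(lab_all) & lab_all != "excluded"
  expr <- expr[, use, drop = FALSE]
  labels <- factor(as.character(lab_all[use]), levels = c("low", "high"))
  if (min(table(labels)) < k)
    stop("need at least k = ", k, " samples per class after dichotomization")

  set.seed(seed)
  outer_fold <- .stratified_folds(labels, k)
  ngrid <- nrow(grid)
  inner_auc <- matrix(NA_real_, ngrid, k)
  chosen_per_fold <- integer(k)
  pooled_scores <- numeric(0)
  pooled_labels <- character(0)
  any_nonempty <- FALSE
  pref <- .grid_order(grid)

  eval_grid_on_split <- function(tr_idx, va_idx) {
    de <- differential_expression(expr[, tr_idx, drop = FALSE],
                                  labels[tr_idx])
    sigs <- lapply(seq_len(ngrid), function(gi)
      select_signature(de, grid$fdr_max[gi], grid$fc_min[gi]))
    used <- unique(unlist(lapply(sigs, function(s) c(s$up, s$down)),
                          use.names = FALSE))
    if (!length(used)) return(rep(0.5, ngrid))
    any_nonempty <<- TRUE
    # the rescaling transform is only needed for candidate signature
    # genes; fitting it on that subset (training samples only) keeps
    # the validation fold untouched
    rfit <- .rescale_fit(expr[used, tr_idx, drop = FALSE], rescale_q)
    va <- .rescale_apply(expr[used, va_idx, drop = FALSE], rfit)
    rownames(va) <- used
    vapply(seq_len(ngrid), function(gi) {
      if (length(sigs[[gi]]) == 0L) return(0.5)
      sc <- signature_score(va, sigs[[gi]])
      auc_mann_whitney(as.vector(sc), labels[va_idx])$auc
    }, numeric(1))
  }

  for (f in seq_len(k)) {
    tr <- which(outer_fold != f)
    te <- which(outer_fold == f)
    inner_fold <- .stratified_folds(labels[tr], k)
    acc <- matrix(NA_real_, ngrid, k)
    for (j in seq_len(k)) {
      itr <- tr[inner_fold != j]
      iva <- tr[inner_fold == j]
      acc[, j] <- eval_grid_on_split(itr, iva)
    }
    mean_auc <- rowMeans(acc)
    inner_auc[, f] <- mean_auc
    best <- pref[which.max(mean_auc[pref])]
    # which.max on the preference-ordered vector resolves ties by the
    # parsimony rule (smaller fdr_max, then larger fc_min)
    chosen_per_fold[f] <- best

    de_tr <- differential_expression(expr[, tr, drop = FALSE], labels[tr])
    sig_tr <- select_signature(de_tr, grid$fdr_max[best], grid$fc_min[best],
                               name = marker)
    sc <- if (length(sig_tr) > 0L) {
      used <- c(sig_tr$up, sig_tr$down)
      rfit <- .rescale_fit(expr[used, tr, drop = FALSE], rescale_q)
      te_resc <- .rescale_apply(expr[used, te, drop = FALSE], rfit)
      rownames(te_resc) <- used
      as.vector(signature_score(te_resc, sig_tr))
    } else rep(0, length(te))
    pooled_scores <- c(pooled_scores, sc)
    pooled_labels <- c(pooled_labels, as.character(labels[te]))
  }

  outer <- auc_mann_whitney(pooled_scores, pooled_labels)
  tab <- tabulate(chosen_per_fold, nbins = ngrid)
  cand <- which(tab == max(tab))
  final_gi <- pref[pref %in% cand][1]
  de_all <- differential_expression(expr, labels)
  final <- select_signature(de_all, grid$fdr_max[final_gi],
                            grid$fc_min[final_gi], name = marker)
  empty_flag <- !any_nonempty || length(final) == 0L
  if (!any_nonempty) {
    warning("every grid point gave an empty signature on every inner ",
            "split; returning an empty signature with AUC 0.5")
    outer <- list(auc = 0.5, p_value = 1)
  }
  final$cv_auc <- outer$auc
  final$cv_auc_p <- outer$p_value
  structure(list(grid = grid, inner_auc = inner_auc,
                 chosen_per_fold = chosen_per_fold,
                 chosen = grid[final_gi, , drop = FALSE],
                 outer_auc = outer$auc, outer_auc_p = outer$p_value,
                 signature = final, empty_flag = empty_flag,
                 labels = stats::setNames(labels, colnames(expr)),
                 outer_fold = stats::setNames(outer_fold, colnames(expr)),
                 k = k, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Nested cross-validated signature derivation (k = ", x$k, ")\n",
      sep = "")
  cat(sprintf("  chosen thresholds: FDR <= %g, |log2 FC| >= %g\n",
              x$chosen$fdr_max, x$chosen$fc_min))
  cat(sprintf("  outer-CV AUC: %.3f (p = %.3g)\n", x$outer_auc,
              x$outer_auc_p))
  print(x$signature)
  if (x$empty_flag) cat("  [flag] empty signature\n")
  invisible(x)
}
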