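# container for the association battery results
.assoc_result <- function(test, statistic, p_value, group_sizes,
                          flag = NA_character_) {
  structure(list(test = test, statistic = statistic, p_value = p_value,
                 group_sizes = group_sizes, flag = flag),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(x$test, ": statistic = ", format(x$statistic, digits = 4),
      ", p = ", format(x$p_value, digits = 3),
      " (n = ", paste(x$group_sizes, collapse = "/"), ")",
      if (!is.na(x$flag)) paste0(" [", x$flag, "]"), "\n", sep = "")
  invisible(x)
}

#' Kruskal-Wallis rank test of scores across groups
#'
#' Tie-corrected H statistic with a chi-squared reference on k - 1
#' degrees of freedom.  If every value is identical across all groups
#' the test is degenerate: H = 0, p = 1, flagged.
#'
#' @param scores numeric values.
#' @param group_labels group membership, same length.
#' @return an \code{assoc_result}.
#' @export
kruskal_wallis <- function(scores, group_labels) {
  keep <- !is.na(scores) & !is.na(group_labels)
  scores <- scores[keep]
  g <- factor(group_labels[keep])
  g <- droplevels(g)
  if (nlevels(g) < 2L) stop("Kruskal-Wallis needs at least 2 groups")
  sizes <- as.vector(table(g))
  if (length(unique(scores)) == 1L)
    return(.assoc_result("kruskal_wallis", 0, 1, sizes, "degenerate"))
  kt <- stats::kruskal.test(scores, g)
  .assoc_result("kruskal_wallis", unname(kt$statistic), kt$p.value, sizes)
}

#' Mann-Whitney (Wilcoxon rank-sum) test between two score vectors
#'
#' Two-sided.  Exact when the smaller group has at most 8 observations
#' and there are no ties; otherwise the tie- and continuity-corrected
#' normal approximation.
#'
#' @param scores_a,scores_b numeric vectors, both non-empty after
#'   removing missing values.
#' @return an \code{assoc_result} (statistic is the rank-sum U of the
#'   first group).
#' @export
mann_whitney <- function(scores_a, scores_b) {
  scores_a <- scores_a[!is.na(scores_a)]
  scores_b <- scores_b[!is.na(scores_b)]
  if (!length(scores_a) || !length(scores_b))
    stop("both groups must be non-empty")
  ties <- anyDuplicated(c(scores_a, scores_b)) > 0
  exact <- min(length(scores_a), length(scores_b)) <= 8 && !ties
  wt <- suppressWarnings(stats::wilcox.test(scores_a, scores_b,
                                            exact = exact, correct = TRUE))
  .assoc_result("mann_whitney", unname(wt$statistic),
                min(wt$p.value, 1), c(length(scores_a), length(scores_b)))
}

#' Association of signature scores with mutation status
#'
#' Mann-Whitney comparison of scores in mutated versus wild-type
#' samples (a sample is mutated regardless of its mutation count).
#' For PIK3CA with \code{by_exon = TRUE}, three contrasts are computed
#' against the same wild-type reference: exon 9 carriers, exon 20
#' carriers, and carriers of any other exon.  A contrast with fewer
#' than \code{min_n} samples on either side is flagged as skipped
#' rather than computed.
#'
#' @param scores named per-sample scores (names matched against
#'   \code{clinical$sample_id}).
#' @param clinical a [clinical_table()] with \code{pik3ca_status} /
#'   \code{p53_status}.
#' @param gene \code{"PIK3CA"} or \code{"P53"}.
#' @param by_exon analyze PIK3CA by exon class.
#' @param min_n minimum class size per side.
#' @return named list of \code{assoc_result} objects (contrast names
#'   \code{mut}, and with \code{by_exon}: \code{exon9}, \code{exon20},
#'   \code{other_exon}).
#' @export
mutation_association <- function(scores, clinical,
                                 gene = c("PIK3CA", "P53"),
                                 by_exon = FALSE, min_n = 10L) {
  gene <- match.arg(gene)
  col <- if (gene == "PIK3CA") "pik3ca_status" else "p53_status"
  if (is.null(clinical[[col]]))
    stop("clinical table lacks column ", col)
  idx <- match(clinical$sample_id, names(scores))
  sc <- as.vector(scores)[idx]
  status <- clinical[[col]]
  keep <- !is.na(sc) & !is.na(status)
  sc <- sc[keep]
  status <- status[keep]
  wt_scores <- sc[status == "wt"]

  one <- function(mut_scores, label) {
    if (length(mut_scores) < min_n || length(wt_scores) < min_n)
      return(.assoc_result("mann_whitney", NA_real_, NA_real_,
                           c(length(mut_scores), length(wt_scores)),
                           "skipped: class below minimum size"))
    mann_whitney(mut_scores, wt_scores)
  }
  res <- list(mut = one(sc[status != "wt"], "mut"))
  if (by_exon) {
    if (gene != "PIK3CA") stop("by_exon is only defined for PIK3CA")
    for (cl in c("exon9", "exon20", "other_exon"))
      res[[cl]] <- one(sc[status == cl], cl)
  }
  res
}
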