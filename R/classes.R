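#' Construct a validated expression matrix
#'
#' An expression matrix is a plain numeric matrix of log2 expression
#' values with genes as rows and samples as columns, carrying its gene
#' and sample identifiers as dimnames and a dataset identifier as an
#' attribute.  Missing values are allowed and propagated as \code{NA}.
#'
#' @param values numeric matrix, genes x samples, log2 scale.
#' @param gene_ids character vector of unique gene identifiers.
#' @param sample_ids character vector of unique sample identifiers.
#' @param dataset_id single string naming the dataset.
#' @return numeric matrix with dimnames set and attribute
#'   \code{dataset_id}.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              dataset_id = "dataset") {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (nrow(values) == 0L || ncol(values) == 0L) stop("empty expression matrix")
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene and sample identifiers are required")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values))
    stop("gene_ids length does not match number of rows")
  if (length(sample_ids) != ncol(values))
    stop("sample_ids length does not match number of columns")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)])[1:min(3, sum(duplicated(gene_ids)))],
               collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (any(is.infinite(values)))
    stop("non-finite expression values (Inf) present; flag them as NA instead")
  dimnames(values) <- list(gene_ids, sample_ids)
  attr(values, "dataset_id") <- as.character(dataset_id)[1]
  values
}

#' Construct a validated RPPA table
#'
#' Continuous protein abundances per sample, one column per marker
#' (e.g. \code{pAKT}, \code{p-mTOR}).  Stored samples x markers.
#'
#' @param values numeric matrix or data.frame, samples x markers.
#' @param sample_ids unique sample identifiers.
#' @param marker_ids marker names.
#' @return numeric matrix with dimnames \code{list(sample_ids, marker_ids)}.
#' @export
rppa_table <- function(values, sample_ids = rownames(values),
                       marker_ids = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("RPPA values must be numeric")
  sample_ids <- as.character(sample_ids)
  marker_ids <- as.character(marker_ids)
  if (length(sample_ids) != nrow(values) || length(marker_ids) != ncol(values))
    stop("identifier lengths do not match RPPA matrix dimensions")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers in RPPA table: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  dimnames(values) <- list(sample_ids, marker_ids)
  values
}

#' Construct a validated clinical table
#'
#' Per-sample clinical covariates.  Recognised columns: \code{sample_id},
#' \code{subtype} (LumA/LumB/other), \code{age} (years), \code{size}
#' (mm), \code{grade} (1-3), \code{nodal_status} (0/1), \code{rfs_time}
#' (months), \code{rfs_event} (0/1), \code{endocrine_only} (0/1),
#' \code{pik3ca_status} (wt/exon9/exon20/other_exon), \code{p53_status}
#' (wt/mut).  Any field may be missing; validation only rejects values
#' outside their domain.
#'
#' @param df data.frame with at least a \code{sample_id} column.
#' @return the validated data.frame (row names cleared).
#' @export
clinical_table <- function(df) {
  df <- as.data.frame(df)
  if (is.null(df$sample_id)) stop("clinical table requires a sample_id column")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in clinical table: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  chk_dom <- function(col, dom) {
    v <- df[[col]]
    if (!is.null(v)) {
      bad <- !is.na(v) & !(v %in% dom)
      if (any(bad))
        stop("invalid ", col, " for sample ",
             df$sample_id[which(bad)[1]], ": ", v[which(bad)[1]])
    }
  }
  chk_dom("subtype", c("LumA", "LumB", "other"))
  chk_dom("grade", 1:3)
  chk_dom("nodal_status", 0:1)
  chk_dom("rfs_event", 0:1)
  chk_dom("endocrine_only", 0:1)
  chk_dom("pik3ca_status", c("wt", "exon9", "exon20", "other_exon"))
  chk_dom("p53_status", c("wt", "mut"))
  if (!is.null(df$rfs_time) && any(df$rfs_time < 0, na.rm = TRUE))
    stop("negative rfs_time for sample ",
         df$sample_id[which(df$rfs_time < 0)[1]])
  rownames(df) <- NULL
  df
}

#' Construct a gene signature
#'
#' A directional gene set: up-regulated genes carry weight +1 and
#' down-regulated genes weight -1.  Derivation metadata (chosen FDR and
#' fold-change thresholds, cross-validated AUC and its p-value) is kept
#' alongside.
#'
#' @param name signature name.
#' @param up character vector of up-regulated genes.
#' @param down character vector of down-regulated genes.
#' @param fdr_max,fc_min thresholds the signature was selected at
#'   (log2 units for \code{fc_min}); \code{NA} if not derived here.
#' @param cv_auc,cv_auc_p cross-validated AUC in [0, 1] and its
#'   Mann-Whitney p-value; \code{NA} if not assessed.
#' @return object of class \code{gene_signature}.
#' @export
gene_signature <- function(name, up = character(), down = character(),
                           fdr_max = NA_real_, fc_min = NA_real_,
                           cv_auc = NA_real_, cv_auc_p = NA_real_) {
  up <- unique(as.character(up))
  down <- unique(as.character(down))
  both <- intersect(up, down)
  if (length(both))
    stop("signature '", name, "': genes in both up and down sets: ",
         paste(utils::head(both, 5), collapse = ", "))
  if (!is.na(cv_auc) && (cv_auc < 0 || cv_auc > 1))
    stop("cv_auc must lie in [0, 1]")
  structure(list(name = as.character(name)[1], up = up, down = down,
                 fdr_max = fdr_max, fc_min = fc_min,
                 cv_auc = cv_auc, cv_auc_p = cv_auc_p),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("Gene signature '", x$name, "': ", length(x$up), " up, ",
      length(x$down), " down\n", sep = "")
  if (!is.na(x$fdr_max) || !is.na(x$fc_min))
    cat(sprintf("  thresholds: FDR <= %s, |log2 FC| >= %s\n",
                format(x$fdr_max), format(x$fc_min)))
  if (!is.na(x$cv_auc))
    cat(sprintf("  cross-validated AUC: %.3f (p = %.3g)\n",
                x$cv_auc, x$cv_auc_p))
  invisible(x)
}

#' Signature gene weights
#'
#' @param object a \code{gene_signature}.
#' @param ... unused.
#' @return named numeric vector, +1 for up genes, -1 for down genes.
#' @export
weights.gene_signature <- function(object, ...) {
  c(stats::setNames(rep(1, length(object$up)), object$up),
    stats::setNames(rep(-1, length(object$down)), object$down))
}

#' Number of genes in a signature
#' @param x a \code{gene_signature}.
#' @export
length.gene_signature <- function(x) length(x$up) + length(x$down)
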