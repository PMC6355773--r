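#' Read a tab-delimited expression matrix
#'
#' Expects genes as rows: first column gene identifier, header row of
#' sample identifiers, tab-delimited UTF-8 as in common GEO/TCGA matrix
#' exports.  Non-numeric cells (e.g. \code{"NA"}) become missing values.
#' Duplicate gene rows are collapsed by keeping the row with the highest
#' overall mean expression (most-informative-probe convention); a
#' message reports the number collapsed.
#'
#' @param path file path.
#' @param dataset_id dataset identifier stored on the result.
#' @return validated expression matrix (see [expression_matrix()]).
#' @export
read_expression_matrix <- function(path, dataset_id = basename(path)) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    stop("malformed expression file '", path,
         "': need a gene column plus at least one sample column")
  genes <- as.character(raw[[1]])
  vals <- raw[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(!is.na(v) & is.na(vn) & v != "NA" & v != "")
      if (length(bad))
        message("non-numeric cell(s) in column '", names(vals)[j],
                "' (e.g. row ", bad[1], ": '", v[bad[1]],
                "') treated as missing")
      v <- vn
    }
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  if (nrow(m) == 0L) stop("empty expression matrix in '", path, "'")
  if (anyDuplicated(genes)) {
    means <- rowMeans(m, na.rm = TRUE)
    keep <- unlist(lapply(split(seq_along(genes), genes),
                          function(ix) ix[which.max(means[ix])]),
                   use.names = FALSE)
    keep <- sort(keep)
    message(sum(duplicated(genes)),
            " duplicate gene row(s) collapsed by highest mean expression")
    m <- m[keep, , drop = FALSE]
    genes <- genes[keep]
  }
  expression_matrix(m, gene_ids = genes, sample_ids = colnames(m),
                    dataset_id = dataset_id)
}

#' Read an RPPA protein table
#'
#' Tab-delimited, samples as rows: first column sample identifier,
#' header of marker names, continuous values.
#'
#' @param path file path.
#' @return samples x markers numeric matrix (see [rppa_table()]).
#' @export
read_rppa_table <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    stop("malformed RPPA file '", path, "'")
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rppa_table(m, sample_ids = ids, marker_ids = colnames(m))
}

#' Read a clinical covariate table
#'
#' Tab-delimited with header; must contain a \code{sample_id} column.
#'
#' @param path file path.
#' @return validated data.frame (see [clinical_table()]).
#' @export
read_clinical_table <- function(path) {
  clinical_table(utils::read.delim(path, header = TRUE, sep = "\t",
                                   check.names = FALSE,
                                   stringsAsFactors = FALSE))
}

#' Read gene signatures from a GMT-style file
#'
#' Each line is \code{name <TAB> description <TAB> gene1 <TAB> gene2 ...}.
#' Lines whose names end in \code{_up} / \code{_down} and share a base
#' name are merged into one directional signature; a line without a
#' suffix becomes an up-only signature.  Duplicate genes within a set
#' are dropped with a warning; a gene in both the up and the down set of
#' one signature is an error.
#'
#' @param path file path.
#' @return named list of [gene_signature()] objects.
#' @export
read_signature_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L)
      stop("malformed GMT line (need name + description): '", ln, "'")
    nm <- f[1]
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicate gene(s) within set '", nm, "' dropped: ",
              paste(unique(genes[duplicated(genes)]), collapse = ", "))
      genes <- unique(genes)
    }
    if (grepl("_up$", nm)) {
      base <- sub("_up$", "", nm); dir <- "up"
    } else if (grepl("_down$", nm)) {
      base <- sub("_down$", "", nm); dir <- "down"
    } else {
      base <- nm; dir <- "up"
    }
    if (is.null(sets[[base]]))
      sets[[base]] <- list(up = character(), down = character())
    sets[[base]][[dir]] <- union(sets[[base]][[dir]], genes)
  }
  out <- lapply(names(sets), function(nm)
    gene_signature(nm, up = sets[[nm]]$up, down = sets[[nm]]$down))
  stats::setNames(out, names(sets))
}

#' Write gene signatures to a GMT-style file
#'
#' Emits an \code{<name>_up} line for each non-empty up set and an
#' \code{<name>_down} line for each non-empty down set, so that
#' \code{read_signature_file(write_signature_file(x))} round-trips.
#'
#' @param signatures list of [gene_signature()] objects.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_signature_file <- function(signatures, path) {
  if (inherits(signatures, "gene_signature")) signatures <- list(signatures)
  lines <- character()
  for (sig in signatures) {
    if (length(sig$up))
      lines <- c(lines, paste(c(paste0(sig$name, "_up"), "up", sig$up),
                              collapse = "\t"))
    if (length(sig$down))
      lines <- c(lines, paste(c(paste0(sig$name, "_down"), "down", sig$down),
                              collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a table as tab-delimited text
#'
#' Convenience writer used for simulated cohorts: expression matrices
#' are written genes-as-rows with a leading \code{gene_id} column, RPPA
#' tables samples-as-rows with a leading \code{sample_id} column.
#'
#' @param x matrix or data.frame.
#' @param path output path.
#' @param id_col name of the leading identifier column.
#' @return \code{path}, invisibly.
#' @export
write_tsv_matrix <- function(x, path, id_col = "id") {
  df <- data.frame(rownames(x), as.data.frame(x, check.names = FALSE),
                   check.names = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
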