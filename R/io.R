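## Readers and writers for the plain-text formats the pipeline consumes
## and emits: association pair TSVs, expression tables, FASTA sequence
## files, and score matrices.

normalize_ids <- function(x, uppercase = FALSE) {
  x <- trimws(x)
  if (uppercase) toupper(x) else x
}

#' Read a protein-disease association TSV
#'
#' Expects a header line and at least a protein-ID and a disease-ID
#' column (matched by name, else taken as the first two columns).
#' Duplicate pairs collapse to a single association.  Optional PTM
#' type/site columns are ignored except that `require_site` filters out
#' rows whose site column is empty, mirroring PTM-database exports that
#' carry site annotations for only some records.
#'
#' @param path TSV file path.
#' @param protein_col,disease_col column names (or integer positions).
#' @param require_site drop rows with an empty `site_col` value.
#' @param site_col site column name; only used with `require_site`.
#' @param uppercase normalize IDs to upper case.
#' @return binary association matrix; read/duplicate counts are
#'   reported via `message()` and attached as attribute `provenance`.
#' @export
read_association_tsv <- function(path, protein_col = "protein",
                                 disease_col = "disease",
                                 require_site = FALSE, site_col = "site",
                                 uppercase = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0) stop("empty association file: ", path, call. = FALSE)
  pick <- function(col, fallback) {
    if (is.numeric(col)) return(col)
    if (col %in% names(df)) which(names(df) == col)[1] else fallback
  }
  pc <- pick(protein_col, 1L); dc <- pick(disease_col, 2L)
  if (max(pc, dc) > ncol(df))
    stop("association file lacks protein/disease columns", call. = FALSE)
  prot <- normalize_ids(df[[pc]], uppercase)
  dis <- normalize_ids(df[[dc]], uppercase)
  keep <- nzchar(prot) & nzchar(dis)
  n_read <- nrow(df)
  if (require_site) {
    sc <- pick(site_col, NA_integer_)
    if (is.na(sc)) stop("site column not found", call. = FALSE)
    keep <- keep & nzchar(trimws(df[[sc]]))
  }
  prot <- prot[keep]; dis <- dis[keep]
  dup <- duplicated(paste0(prot, "\r", dis))
  prot_u <- prot[!dup]; dis_u <- dis[!dup]
  a <- matrix(0, length(unique(prot_u)), length(unique(dis_u)),
              dimnames = list(unique(prot_u), unique(dis_u)))
  a[cbind(prot_u, dis_u)] <- 1
  message(sprintf("read %d rows: %d associations (%d duplicates dropped), %d proteins, %d diseases",
                  n_read, sum(a), sum(dup), nrow(a), ncol(a)))
  structure(as_association(a),
            provenance = list(rows_read = n_read, duplicates = sum(dup),
                              filtered = n_read - length(prot) - 0L))
}

#' Write associations as a pair-per-row TSV
#'
#' @param assoc binary association matrix.
#' @param path output path.
#' @export
write_association_tsv <- function(assoc, path) {
  assoc <- as_association(assoc)
  idx <- which(assoc == 1, arr.ind = TRUE)
  df <- data.frame(protein = rownames(assoc)[idx[, 1]],
                   disease = colnames(assoc)[idx[, 2]])
  df <- df[order(df$protein, df$disease), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a sample x protein expression TSV
#'
#' Parses a numeric table with one label column into an
#' [expression_dataset()].  Non-numeric cells are rejected with their
#' coordinates.  When the file stores proteins in rows, pass
#' `orientation = "proteins"` and it is transposed (the label row is
#' then named `label_column`).
#'
#' @param path TSV file path with sample IDs in the first column.
#' @param label_column name of the subtype label column (default
#'   `"label"`).
#' @param orientation `"samples"` (rows are samples, default) or
#'   `"proteins"`.
#' @param scale apply [robust_scale()] after parsing.
#' @param assoc_proteins optional association-protein vocabulary used to
#'   compute the shared index (an overlap report is printed).
#' @param disease_key disease term this dataset maps to.
#' @param uppercase normalize protein IDs to upper case before matching.
#' @return an [expression_dataset()].
#' @export
read_expression_tsv <- function(path, label_column = "label",
                                orientation = c("samples", "proteins"),
                                scale = FALSE, assoc_proteins = NULL,
                                disease_key = NA_character_,
                                uppercase = FALSE) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1,
                          colClasses = "character")
  if (orientation == "proteins") df <- as.data.frame(t(df))
  if (!label_column %in% names(df))
    stop("label column '", label_column, "' not found", call. = FALSE)
  labels <- df[[label_column]]
  df[[label_column]] <- NULL
  x <- suppressWarnings(
    matrix(as.numeric(as.matrix(df)), nrow(df), ncol(df),
           dimnames = list(rownames(df), names(df))))
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at sample '%s', protein '%s'",
                 rownames(x)[bad[1]], colnames(x)[bad[2]]), call. = FALSE)
  }
  if (scale) x <- robust_scale(x)
  colnames(x) <- normalize_ids(colnames(x), uppercase)
  shared <- character()
  if (!is.null(assoc_proteins)) {
    shared <- intersect(colnames(x), normalize_ids(assoc_proteins, uppercase))
    message(sprintf("%d proteins, %d shared with the association data",
                    ncol(x), length(shared)))
  }
  expression_dataset(x, labels, shared = shared, disease_key = disease_key)
}

#' Write an expression dataset as TSV
#'
#' @param expr an [expression_dataset()].
#' @param path output path.
#' @export
write_expression_tsv <- function(expr, path) {
  stopifnot(inherits(expr, "expression_dataset"))
  df <- data.frame(sample = expr$sample_ids,
                   label = as.character(expr$labels),
                   expr$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a multi-record FASTA file
#'
#' Wrapped lines are concatenated; the record ID is the first
#' whitespace-delimited token of the header.
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1)
  seqs
}

#' Write sequences as FASTA
#'
#' @param sequences named character vector.
#' @param path output path.
#' @param width line-wrap width (default 60).
#' @export
write_fasta <- function(sequences, path, width = 60) {
  stopifnot(!is.null(names(sequences)))
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(sequences)) {
    writeLines(paste0(">", names(sequences)[i]), con)
    s <- sequences[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Write / read a potentiality score matrix as TSV
#'
#' Proteins in rows (first column `protein`), diseases in columns.
#'
#' @param scores numeric protein x disease matrix with dimnames.
#' @param path file path.
#' @return `read_scores_tsv` returns the numeric matrix.
#' @export
write_scores_tsv <- function(scores, path) {
  df <- data.frame(protein = rownames(scores), scores, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores_tsv
#' @export
read_scores_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
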