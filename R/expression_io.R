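#' Read a tab-delimited gene expression matrix
#'
#' Parses the tab-delimited dialect used throughout the package: a header row
#' of sample identifiers, then one row per gene consisting of the gene
#' identifier followed by one numeric value per sample. Values are assumed
#' already normalized upstream; the reader validates, it never transforms.
#'
#' @param source path to a file, or a character scalar containing the
#'   tab-delimited text itself (recognized by embedded newlines).
#' @return numeric matrix (genes x samples) with gene IDs as rownames and
#'   sample IDs as colnames.
#' @details Hard errors are raised for duplicate gene IDs (naming the ID),
#'   non-numeric cells (naming row and column), ragged rows, and missing
#'   values. Both LF and CRLF line endings are accepted.
#' @seealso [write_expression_matrix()], [validate_expression_matrix()]
#' @export
#' @examples
#' m <- read_expression_matrix("g\ts1\ts2\ts3\nA\t1\t2\t3\nB\t3\t2\t1\n")
#' dim(m)
read_expression_matrix <- function(source) {
  lines <- read_text_lines(source)
  if (length(lines) < 2L) {
    stop("expression input needs a header row and at least one gene row",
         call. = FALSE)
  }
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  sample_ids <- header[-1L]
  if (length(sample_ids) < 1L) stop("no sample columns in header", call. = FALSE)
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ID: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nfield <- lengths(body)
  if (any(nfield != length(sample_ids) + 1L)) {
    bad <- which(nfield != length(sample_ids) + 1L)[1L]
    stop(sprintf("ragged row %d: expected %d fields, found %d",
                 bad + 1L, length(sample_ids) + 1L, nfield[bad]), call. = FALSE)
  }
  gene_ids <- vapply(body, `[[`, character(1L), 1L)
  if (any(!nzchar(gene_ids))) stop("empty gene ID", call. = FALSE)
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ID: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  vals <- matrix(NA_real_, nrow = length(gene_ids), ncol = length(sample_ids),
                 dimnames = list(gene_ids, sample_ids))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1L]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1L]
      stop(sprintf("non-numeric value '%s' at gene '%s' (row %d), sample '%s' (column %d)",
                   body[[i]][j + 1L], gene_ids[i], i + 1L, sample_ids[j], j + 1L),
           call. = FALSE)
    }
    vals[i, ] <- v
  }
  validate_expression_matrix(vals, for_association = FALSE)
  vals
}

#' Validate an expression matrix
#'
#' Checks the structural invariants every downstream step relies on: a
#' numeric matrix with unique, non-empty gene rownames, unique sample
#' colnames, and only finite values (matrices with NA/NaN/Inf are rejected
#' rather than imputed, because the association estimators assume complete
#' profiles). When `for_association = TRUE` additionally requires at least 2
#' genes and 3 samples.
#'
#' @param m numeric matrix, genes in rows.
#' @param for_association require dimensions usable for pairwise association.
#' @return `m`, invisibly.
#' @export
validate_expression_matrix <- function(m, for_association = TRUE) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("expression data must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(m)) || any(!nzchar(rownames(m)))) {
    stop("gene IDs (rownames) must be present and non-empty", call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) {
    stop("duplicate gene ID: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(colnames(m)) && anyDuplicated(colnames(m))) {
    stop("duplicate sample ID", call. = FALSE)
  }
  if (!all(is.finite(m))) {
    stop("expression matrix contains missing or non-finite values; ",
         "complete profiles are required", call. = FALSE)
  }
  if (for_association && (nrow(m) < 2L || ncol(m) < 3L)) {
    stop("association computation needs >= 2 genes and >= 3 samples",
         call. = FALSE)
  }
  invisible(m)
}

#' Write an expression matrix in the tab-delimited dialect
#'
#' Full-precision output (15 significant digits) so that a write/read
#' round trip reproduces the matrix exactly.
#'
#' @param m numeric matrix with gene rownames and sample colnames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  validate_expression_matrix(m, for_association = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(m)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], format(m[i, ], digits = 15, trim = TRUE,
                                   scientific = FALSE)), collapse = "\t")
  }, character(1L))
  writeLines(body, con)
  invisible(path)
}

#' Read a gene list (one ID per line)
#'
#' Blank lines are ignored; duplicates are dropped with a warning, keeping
#' first occurrence order. An empty list is a hard error.
#'
#' @inheritParams read_expression_matrix
#' @return character vector of unique gene IDs.
#' @export
#' @examples
#' read_gene_list("NANOG\nPOU5F1\nSOX2\nPHC1")
read_gene_list <- function(source) {
  ids <- trimws(read_text_lines(source))
  ids <- ids[nzchar(ids)]
  if (length(ids) == 0L) stop("empty gene list", call. = FALSE)
  if (anyDuplicated(ids)) {
    warning("dropping duplicated gene IDs: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
    ids <- ids[!duplicated(ids)]
  }
  ids
}

# Accepts a file path or literal text (detected by an embedded newline, or by
# the path not existing as a file). Normalizes CRLF to LF.
read_text_lines <- function(source) {
  if (!is.character(source) || length(source) != 1L) {
    stop("'source' must be a single path or text string", call. = FALSE)
  }
  if (grepl("\n", source, fixed = TRUE) || !file.exists(source)) {
    if (!grepl("\n", source, fixed = TRUE) && !file.exists(source)) {
      stop("file not found: ", source, call. = FALSE)
    }
    txt <- source
  } else {
    txt <- paste(readLines(source, warn = FALSE), collapse = "\n")
  }
  txt <- gsub("\r\n", "\n", txt, fixed = TRUE)
  txt <- gsub("\r", "\n", txt, fixed = TRUE)
  strsplit(txt, "\n", fixed = TRUE)[[1L]]
}
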