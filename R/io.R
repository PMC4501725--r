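#' Read and write FASTA sequence files
#'
#' Wrappers around Biostrings with the package's conventions: ids are the
#' first whitespace-delimited word of the header, duplicate ids are an
#' error, output is wrapped at 60 columns, and CRLF input parses like LF.
#'
#' @param path File path.
#' @param type `"AA"` or `"DNA"`.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::readAAStringSet(path)
         else Biostrings::readDNAStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  abort_if(anyDuplicated(names(seqs)) > 0, "duplicate sequence ids in ", path,
           class = "parse_error")
  seqs
}

#' @param seqs Named character vector of sequences.
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  abort_if(is.null(names(seqs)) || anyDuplicated(names(seqs)) > 0,
           "sequences need unique names", class = "invalid_input")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = 60)
    writeLines(substring(s, starts, pmin(starts + 59, nchar(s))), con)
  }
  invisible(path)
}

# strict TSV reader: header + rectangular rows, no quoting, UTF-8
read_tsv_strict <- function(path, required = NULL) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("\r$", "", lines)
  abort_if(length(lines) < 1, "empty file: ", path, class = "parse_error")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  ncol <- length(header)
  for (i in seq_along(cells)[-1]) {
    abort_if(length(cells[[i]]) != ncol,
             "ragged row at line ", i, " of ", path, " (", length(cells[[i]]),
             " fields, expected ", ncol, ")", class = "parse_error")
  }
  body <- cells[-1]
  df <- as.data.frame(
    setNames(lapply(seq_len(ncol), function(j)
      vapply(body, `[[`, character(1), j)), header),
    stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(required))
    abort_if(!all(required %in% names(df)),
             "missing column(s) in ", path, ": ",
             paste(setdiff(required, names(df)), collapse = ", "),
             class = "parse_error")
  df
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a contig x sample count matrix from TSV
#'
#' First column `contig_id`, one column per sample, non-negative integer
#' entries; violations are reported with their line number.
#'
#' @param counts_path Counts TSV.
#' @param samples_path Sample sheet TSV (`sample_id`, `hpo`, `infected`).
#' @return A [count_table()].
#' @export
read_counts <- function(counts_path, samples_path) {
  df <- read_tsv_strict(counts_path, required = "contig_id")
  abort_if(anyDuplicated(df$contig_id) > 0, "duplicate contig ids in ",
           counts_path, class = "parse_error")
  samp_cols <- setdiff(names(df), "contig_id")
  mat <- matrix(NA_real_, nrow(df), length(samp_cols),
                dimnames = list(df$contig_id, samp_cols))
  for (j in seq_along(samp_cols)) {
    v <- suppressWarnings(as.numeric(df[[samp_cols[j]]]))
    bad <- which(!is.finite(v) | v < 0 | v != round(v))
    abort_if(length(bad) > 0,
             "non-count value in column ", samp_cols[j], " at line ",
             bad[1] + 1L, " of ", counts_path, class = "parse_error")
    mat[, j] <- v
  }
  ss <- read_sample_sheet(samples_path)
  count_table(mat, ss)
}

#' @param x A `count_table`.
#' @param path Output TSV path.
#' @rdname read_counts
#' @export
write_counts <- function(x, path) {
  df <- data.frame(contig_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a sample sheet (sample_id, hpo, infected)
#' @param path TSV path.
#' @return data.frame with typed columns.
#' @export
read_sample_sheet <- function(path) {
  df <- read_tsv_strict(path, required = c("sample_id", "hpo", "infected"))
  df$hpo <- as.numeric(df$hpo)
  abort_if(anyNA(df$hpo), "non-numeric hpo in ", path, class = "parse_error")
  df$infected <- toupper(df$infected) %in% c("TRUE", "1", "YES")
  df
}

#' Read a qPCR Ct table (individual_id, gene, replicate, ct)
#' @param path TSV path.
#' @return data.frame with typed columns.
#' @export
read_ct_table <- function(path) {
  df <- read_tsv_strict(path, required = c("individual_id", "gene", "ct"))
  df$ct <- as.numeric(df$ct)
  abort_if(anyNA(df$ct) || any(df$ct <= 0), "invalid Ct value in ", path,
           class = "parse_error")
  if ("replicate" %in% names(df)) df$replicate <- as.integer(df$replicate)
  df
}

#' Read a gene table (gene_id, chromosome)
#' @param path TSV path.
#' @return data.frame.
#' @export
read_gene_table <- function(path) {
  df <- read_tsv_strict(path, required = c("gene_id", "chromosome"))
  abort_if(anyDuplicated(df$gene_id) > 0, "duplicate gene ids in ", path,
           class = "parse_error")
  df
}
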