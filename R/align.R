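#' Protein scoring scheme
#'
#' Substitution matrix plus affine gap penalties and Karlin-Altschul
#' parameters.  Defaults follow the de facto protein-search standard:
#' BLOSUM62 with gap open 11 and gap extend 1 (a gap of length k costs
#' `11 + k`), and the published ungapped BLOSUM62 constants
#' `lambda = 0.3176`, `K = 0.134` for the E-value
#' `E = K * m * n * exp(-lambda * S)`.
#'
#' @param matrix Either the string `"BLOSUM62"` or a numeric substitution
#'   matrix with matching row/column names (residue letters).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param lambda,K Karlin-Altschul parameters for significance.
#' @return A list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                           lambda = 0.3176, K = 0.134) {
  if (is.character(matrix)) {
    abort_if(matrix != "BLOSUM62", "only BLOSUM62 is built in",
             class = "invalid_input")
    e <- new.env()
    data("BLOSUM62", package = "Biostrings", envir = e)
    matrix <- e$BLOSUM62
  }
  abort_if(!is.matrix(matrix) || is.null(rownames(matrix)) ||
             !identical(rownames(matrix), colnames(matrix)),
           "substitution matrix needs identical row/column names",
           class = "invalid_input")
  abort_if(gap_open < 0 || gap_extend < 0, "gap penalties must be >= 0",
           class = "invalid_input")
  structure(list(sub = matrix, gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K),
            class = "scoring_scheme")
}

# residues -> 0-based codes into scoring$sub; unknowns map to "X" when present
encode_residues <- function(seq, scoring) {
  letters <- rownames(scoring$sub)
  x <- strsplit(toupper(seq), "")[[1]]
  idx <- match(x, letters)
  if (anyNA(idx)) {
    abort_if(!"X" %in% letters,
             "unknown residue(s) and no 'X' in the substitution matrix: ",
             paste(unique(x[is.na(idx)]), collapse = ", "),
             class = "invalid_input")
    idx[is.na(idx)] <- match("X", letters)
  }
  as.integer(idx - 1L)
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * S)` for a raw score `S` in a search of a
#' query of length `m` against a database of total length `n`.
#'
#' @param score Raw alignment score(s).
#' @param m Query length.
#' @param n Database (total subject) length.
#' @param scoring A [scoring_scheme()] supplying `lambda` and `K`.
#' @return E-value(s), strictly decreasing in `score`.
#' @export
karlin_evalue <- function(score, m, n, scoring = scoring_scheme()) {
  abort_if(m <= 0 || n <= 0, "search-space dimensions must be positive",
           class = "invalid_input")
  scoring$K * m * n * exp(-scoring$lambda * score)
}

alignment_result <- function(score, aligned_a, aligned_b, evalue = NA_real_) {
  achars <- strsplit(aligned_a, "")[[1]]
  bchars <- strsplit(aligned_b, "")[[1]]
  both <- achars != "-" & bchars != "-"
  identities <- sum(both & achars == bchars)
  cols <- sum(both)
  structure(list(score = score, aligned_a = aligned_a, aligned_b = aligned_b,
                 identities = identities, aligned_columns = cols,
                 percent_identity = if (cols > 0) 100 * identities / cols
                                    else NA_real_,
                 evalue = evalue),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> score %.1f, identity %.1f%% (%d/%d)%s\n",
              x$score, x$percent_identity, x$identities, x$aligned_columns,
              if (!is.na(x$evalue)) sprintf(", E = %.3g", x$evalue) else ""))
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  invisible(x)
}

aligned_strings <- function(seq, pos) {
  chars <- strsplit(seq, "")[[1]]
  paste(ifelse(pos == 0, "-", chars[pmax(pos, 1)]), collapse = "")
}

#' Global (Needleman-Wunsch) protein alignment with affine gaps
#'
#' Optimal global alignment under the Gotoh three-state recursion.  Percent
#' identity is computed over columns where neither row is a gap.
#'
#' @param a,b Protein sequences (non-empty strings).
#' @param scoring A [scoring_scheme()].
#' @return An `alignment_result`: `score`, aligned strings, `identities`,
#'   `aligned_columns`, `percent_identity` (and `evalue = NA`, which is a
#'   local-search notion).
#' @examples
#' global_align("ACDE", "ACDD")$percent_identity
#' @export
global_align <- function(a, b, scoring = scoring_scheme()) {
  abort_if(!nzchar(a) || !nzchar(b), "sequences must be non-empty",
           class = "invalid_input")
  res <- affine_global_cpp(encode_residues(a, scoring),
                           encode_residues(b, scoring),
                           scoring$sub, scoring$gap_open, scoring$gap_extend)
  alignment_result(res$score,
                   aligned_strings(a, res$a_pos),
                   aligned_strings(b, res$b_pos))
}

#' Local (Smith-Waterman) protein alignment with affine gaps
#'
#' @inheritParams global_align
#' @param m,n Optional query/database lengths for the E-value; default to the
#'   two sequence lengths.
#' @return An `alignment_result` for the best-scoring local pair, with a
#'   Karlin-Altschul `evalue`.
#' @export
local_align <- function(a, b, scoring = scoring_scheme(),
                        m = nchar(a), n = nchar(b)) {
  abort_if(!nzchar(a) || !nzchar(b), "sequences must be non-empty",
           class = "invalid_input")
  res <- affine_local_cpp(encode_residues(a, scoring),
                          encode_residues(b, scoring),
                          scoring$sub, scoring$gap_open, scoring$gap_extend)
  alignment_result(res$score,
                   aligned_strings(a, res$a_pos),
                   aligned_strings(b, res$b_pos),
                   evalue = karlin_evalue(res$score, m, n, scoring))
}

#' Rank reference proteins by local-alignment significance
#'
#' Smith-Waterman search of `query` against every target, with
#' Karlin-Altschul E-values over the whole database
#' (`n` = summed target length).  Hits passing `evalue_threshold` are
#' returned sorted by ascending E-value, then descending score, then target
#' id (lexicographic), so the order is deterministic.
#'
#' @param query Protein sequence.
#' @param targets Named character vector of target protein sequences.
#' @param scoring A [scoring_scheme()].
#' @param evalue_threshold Keep hits with `evalue < evalue_threshold`.
#' @return data.frame (`target_id`, `score`, `evalue`), possibly empty.
#' @export
local_search <- function(query, targets, scoring = scoring_scheme(),
                         evalue_threshold = 1e-9) {
  abort_if(!nzchar(query), "query must be non-empty", class = "invalid_input")
  abort_if(length(targets) == 0, "target set is empty", class = "invalid_input")
  abort_if(is.null(names(targets)) || anyDuplicated(names(targets)) > 0,
           "targets must have unique names", class = "invalid_input")
  enc_t <- lapply(targets, encode_residues, scoring = scoring)
  scores <- affine_local_scores_cpp(encode_residues(query, scoring), enc_t,
                                    scoring$sub, scoring$gap_open,
                                    scoring$gap_extend)
  db_len <- sum(nchar(targets))
  ev <- karlin_evalue(scores, nchar(query), db_len, scoring)
  hits <- data.frame(target_id = names(targets), score = scores, evalue = ev,
                     stringsAsFactors = FALSE)
  hits <- hits[hits$evalue < evalue_threshold, , drop = FALSE]
  hits <- hits[order(hits$evalue, -hits$score, hits$target_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Six-frame translations of a nucleotide sequence
#'
#' Translates all three forward and three reverse-complement frames with the
#' standard genetic code; each frame is truncated to its longest stop-free
#' stretch (internal stops end a candidate peptide).  Frames are labelled
#' 1, 2, 3, -1, -2, -3.
#'
#' @param dna Nucleotide sequence (string).
#' @return data.frame (`frame`, `peptide`) keeping frames with at least one
#'   residue.
#' @export
six_frame_peptides <- function(dna) {
  n <- nchar(dna)
  if (n < 3) return(data.frame(frame = integer(0), peptide = character(0)))
  gc_tab <- Biostrings::GENETIC_CODE
  fwd <- toupper(dna)
  rc <- chartr("ACGTUN", "TGCAAN",
               paste(rev(strsplit(fwd, "", fixed = TRUE)[[1]]),
                     collapse = ""))
  one <- function(s, off) {
    len <- nchar(s) - off
    len <- len - (len %% 3)
    if (len < 3) return(NA_character_)
    starts <- seq.int(off + 1L, off + len, by = 3L)
    aa <- unname(gc_tab[substring(s, starts, starts + 2L)])
    aa[is.na(aa)] <- "X"  # ambiguous codons
    parts <- strsplit(paste(aa, collapse = ""), "*", fixed = TRUE)[[1]]
    parts <- parts[nzchar(parts)]
    if (length(parts) == 0) return(NA_character_)
    parts[which.max(nchar(parts))]
  }
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  peps <- c(vapply(0:2, function(o) one(fwd, o), character(1)),
            vapply(0:2, function(o) one(rc, o), character(1)))
  keep <- !is.na(peps)
  data.frame(frame = frames[keep], peptide = peps[keep],
             stringsAsFactors = FALSE)
}

#' Assign transcript contigs to chromosomes by best protein hit
#'
#' Each contig is translated in six frames; every frame's longest stop-free
#' peptide is searched against the reference proteins by Smith-Waterman, and
#' the single best hit (highest score; ties broken by smaller E-value, then
#' lexicographically smallest gene id) decides the chromosome.  Contigs whose
#' best hit does not reach `evalue_threshold`, or that are shorter than one
#' codon, are labelled `"unassigned"`.
#'
#' @param contigs Named character vector of contig nucleotide sequences.
#' @param ref_proteins Named character vector of reference protein sequences
#'   (names = gene ids).
#' @param gene_chromosomes Named character vector mapping gene id to
#'   chromosome label.
#' @param scoring A [scoring_scheme()].
#' @param evalue_threshold Significance threshold (default the conventional
#'   1e-9 homology cutoff).
#' @return data.frame of class `chrom_assignment`
#'   (`contig_id`, `chromosome`, `gene_id`, `frame`, `score`, `evalue`).
#' @export
assign_chromosomes <- function(contigs, ref_proteins, gene_chromosomes,
                               scoring = scoring_scheme(),
                               evalue_threshold = 1e-9) {
  abort_if(length(contigs) == 0, "no contigs given", class = "invalid_input")
  abort_if(length(ref_proteins) == 0, "reference set is empty",
           class = "invalid_input")
  abort_if(!all(names(ref_proteins) %in% names(gene_chromosomes)),
           "every reference gene needs a chromosome label",
           class = "invalid_input")
  enc_t <- lapply(ref_proteins, encode_residues, scoring = scoring)
  db_len <- sum(nchar(ref_proteins))
  gene_ids <- names(ref_proteins)

  out <- vector("list", length(contigs))
  for (ci in seq_along(contigs)) {
    frames <- six_frame_peptides(contigs[[ci]])
    if (nrow(frames) == 0) {
      warning("contig ", names(contigs)[ci],
              " is shorter than one codon in every frame; unassigned")
      out[[ci]] <- data.frame(contig_id = names(contigs)[ci],
                              chromosome = "unassigned", gene_id = NA_character_,
                              frame = NA_integer_, score = NA_real_,
                              evalue = NA_real_, stringsAsFactors = FALSE)
      next
    }
    best <- NULL
    for (fi in seq_len(nrow(frames))) {
      pep <- frames$peptide[fi]
      scores <- affine_local_scores_cpp(encode_residues(pep, scoring), enc_t,
                                        scoring$sub, scoring$gap_open,
                                        scoring$gap_extend)
      ev <- karlin_evalue(scores, nchar(pep), db_len, scoring)
      ord <- order(-scores, ev, gene_ids)
      top <- ord[1]
      cand <- list(gene = gene_ids[top], score = scores[top],
                   evalue = ev[top], frame = frames$frame[fi])
      if (is.null(best) || cand$score > best$score ||
          (cand$score == best$score && cand$evalue < best$evalue) ||
          (cand$score == best$score && cand$evalue == best$evalue &&
           cand$gene < best$gene)) best <- cand
    }
    assigned <- best$evalue < evalue_threshold
    out[[ci]] <- data.frame(
      contig_id = names(contigs)[ci],
      chromosome = if (assigned) unname(gene_chromosomes[best$gene])
                   else "unassigned",
      gene_id = if (assigned) best$gene else NA_character_,
      frame = best$frame, score = best$score, evalue = best$evalue,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("chrom_assignment", "data.frame")
  res
}
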