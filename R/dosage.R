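#' Construct a validated count table
#'
#' A contig x sample matrix of non-negative integer counts plus per-sample
#' metadata (hours post-oviposition and infection status).
#'
#' @param counts Integer matrix, rows = contigs, columns = samples (both
#'   named).
#' @param samples data.frame with columns `sample_id`, `hpo`, `infected`
#'   covering every column of `counts`.
#' @return List of class `count_table` with elements `counts` and `samples`.
#' @export
count_table <- function(counts, samples) {
  abort_if(!is.matrix(counts) || is.null(rownames(counts)) ||
             is.null(colnames(counts)),
           "counts must be a matrix with row and column names",
           class = "invalid_input")
  abort_if(any(counts < 0) || any(!is.finite(counts)) ||
             any(counts != round(counts)),
           "counts must be non-negative integers", class = "invalid_input")
  abort_if(anyDuplicated(colnames(counts)) > 0 ||
             anyDuplicated(rownames(counts)) > 0,
           "contig and sample ids must be unique", class = "invalid_input")
  abort_if(!all(c("sample_id", "hpo", "infected") %in% names(samples)),
           "samples needs columns sample_id, hpo, infected",
           class = "invalid_input")
  abort_if(!setequal(samples$sample_id, colnames(counts)) ||
             anyDuplicated(samples$sample_id) > 0,
           "sample metadata must cover every column exactly once",
           class = "invalid_input")
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(counts = counts, samples = samples), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d contigs x %d samples; hpo: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(sort(unique(x$samples$hpo)), collapse = ", ")))
  invisible(x)
}

#' Counts-per-million normalization
#'
#' Scales every sample (column) so it sums to one million.  Ratio-based
#' downstream analyses are insensitive to the choice of within-sample scale,
#' which is why plain CPM suffices here; composition effects across samples
#' are handled by median-centering in [compute_ratios()].
#'
#' @param x A `count_table` or a counts matrix.
#' @return Numeric matrix of CPM values (columns sum to 1e6).
#' @export
normalize_cpm <- function(x) {
  counts <- if (inherits(x, "count_table")) x$counts else x
  totals <- colSums(counts)
  bad <- colnames(counts)[totals <= 0]
  abort_if(length(bad) > 0, "sample(s) with zero total counts: ",
           paste(bad, collapse = ", "), class = "degenerate_sample")
  sweep(counts, 2, totals, "/") * 1e6
}

#' Per-contig infected/uninfected log2 expression ratios
#'
#' For each contig, `M = log2((mean_inf + pc) / (mean_uninf + pc))` and
#' `A = 0.5 * log2((mean_inf + pc) * (mean_uninf + pc))`, where means are
#' taken over the two sample groups on the normalized (CPM) scale and `pc` is
#' a pseudocount.  Contigs whose group means are both below `min_abundance`
#' are dropped (their M would be noise-dominated) and reported via the
#' `"dropped"` attribute.
#'
#' Per-sample normalization introduces a compositional offset whenever a
#' large gene class shifts en bloc: extra Z-derived reads in a
#' compensation-failed library depress the apparent abundance of every other
#' gene.  `center = "autosomes"` (the default) therefore subtracts the
#' median M of autosome-labelled contigs - the invariant set of a Z-dosage
#' analysis - from every M; `"global"` uses the median over all contigs
#' (adequate only when the shifted class is a small fraction of the
#' transcriptome), and `"none"` leaves M raw.  `TRUE`/`FALSE` are accepted
#' as aliases.  Without chromosome labels, `"autosomes"` falls back to the
#' global median.
#'
#' @param normalized Matrix of normalized abundances (e.g. from
#'   [normalize_cpm()]).
#' @param infected,uninfected Character vectors of sample ids for the two
#'   groups.
#' @param chromosomes Optional named character vector (contig id ->
#'   chromosome label) used to fill the `chromosome` column; contigs without
#'   a label get `NA`.
#' @param pseudocount Positive pseudocount on the normalized scale.
#' @param min_abundance Abundance filter (same scale); a contig is kept if
#'   either group mean reaches it.
#' @param center `"autosomes"`, `"global"` or `"none"` (or `TRUE`/`FALSE`).
#' @return data.frame of class `ratio_table`
#'   (`contig_id`, `chromosome`, `M`, `A`), with dropped contig ids in
#'   `attr(, "dropped")`.
#' @export
compute_ratios <- function(normalized, infected, uninfected,
                           chromosomes = NULL, pseudocount = 0.5,
                           min_abundance = 1, center = "autosomes") {
  abort_if(length(infected) == 0 || length(uninfected) == 0,
           "both sample groups must be non-empty", class = "invalid_design")
  abort_if(pseudocount <= 0, "pseudocount must be > 0",
           class = "invalid_design")
  abort_if(!all(c(infected, uninfected) %in% colnames(normalized)),
           "unknown sample id(s) in group definitions",
           class = "invalid_input")
  mi <- rowMeans(normalized[, infected, drop = FALSE])
  mu <- rowMeans(normalized[, uninfected, drop = FALSE])
  keep <- mi >= min_abundance | mu >= min_abundance
  dropped <- rownames(normalized)[!keep]
  mi <- mi[keep]; mu <- mu[keep]
  M <- log2((mi + pseudocount) / (mu + pseudocount))
  A <- 0.5 * log2((mi + pseudocount) * (mu + pseudocount))
  ids <- rownames(normalized)[keep]
  chrom <- if (is.null(chromosomes)) rep(NA_character_, length(ids))
           else unname(chromosomes[ids])
  if (isTRUE(center)) center <- "autosomes"
  if (isFALSE(center)) center <- "none"
  center <- match.arg(center, c("autosomes", "global", "none"))
  if (center != "none" && length(M) > 0) {
    auto <- !is.na(chrom) & !chrom %in% c("Z", "unassigned")
    M <- M - if (center == "autosomes" && any(auto)) median(M[auto])
             else median(M)
  }
  res <- data.frame(contig_id = ids, chromosome = chrom, M = M, A = A,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "dropped") <- dropped
  class(res) <- c("ratio_table", "data.frame")
  res
}

#' Per-chromosome summary of expression ratios
#'
#' Median and quartiles (linear-interpolation, i.e. type-7 quantiles) of M
#' per chromosome: the numbers behind a box-and-whisker view of the ratio
#' distributions.  The Z chromosome is listed first, then autosomes by label.
#' Contigs with `NA` or `"unassigned"` chromosome are excluded.
#'
#' @param ratios A `ratio_table` from [compute_ratios()] with chromosome
#'   labels.
#' @return data.frame (`chromosome`, `n`, `q25`, `median`, `q75`).
#' @export
summarize_by_chromosome <- function(ratios) {
  keep <- !is.na(ratios$chromosome) & ratios$chromosome != "unassigned"
  if (any(!keep))
    message(sum(!keep), " contig(s) without chromosome label excluded")
  r <- ratios[keep, , drop = FALSE]
  abort_if(nrow(r) == 0, "no labelled contigs to summarize",
           class = "invalid_input")
  chroms <- unique(r$chromosome)
  chroms <- c(intersect("Z", chroms), sort(setdiff(chroms, "Z")))
  rows <- lapply(chroms, function(ch) {
    m <- r$M[r$chromosome == ch]
    q <- quantile(m, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(chromosome = ch, n = length(m), q25 = q[1], median = q[2],
               q75 = q[3], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Permutation test for a Z-specific ratio shift
#'
#' Observed statistic: `median(M[Z]) - median(M[autosomes])`.  Chromosome
#' labels are permuted across contigs `n_permutations` times and the
#' one-sided (Z up) p-value is
#' `(1 + #{permuted shift >= observed}) / (1 + n_permutations)`.
#'
#' @param ratios A `ratio_table` with chromosome labels.
#' @param n_permutations Number of label permutations (>= 100).
#' @param seed Optional seed.
#' @return List of class `z_shift_test`: `shift`, `p_value`,
#'   `n_permutations`, `n_z`, `n_autosomal`.
#' @export
z_shift_test <- function(ratios, n_permutations = 999, seed = NULL) {
  abort_if(n_permutations < 100, "n_permutations must be >= 100",
           class = "invalid_design")
  keep <- !is.na(ratios$chromosome) & ratios$chromosome != "unassigned"
  r <- ratios[keep, , drop = FALSE]
  abort_if(length(unique(r$chromosome)) < 2,
           "need at least two chromosomes", class = "invalid_input")
  is_z <- r$chromosome == "Z"
  abort_if(sum(is_z) < 5, "fewer than 5 Z-linked contigs",
           class = "insufficient_data")
  M <- r$M
  n <- length(M)
  nz <- sum(is_z)
  obs <- median(M[is_z]) - median(M[!is_z])
  perm <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      idx <- sample.int(n, nz)
      zm <- logical(n); zm[idx] <- TRUE
      median(M[zm]) - median(M[!zm])
    }, numeric(1))
  })
  p <- (1 + sum(perm >= obs)) / (1 + n_permutations)
  structure(list(shift = obs, p_value = p, n_permutations = n_permutations,
                 n_z = nz, n_autosomal = n - nz),
            class = "z_shift_test")
}

#' @export
print.z_shift_test <- function(x, ...) {
  cat(sprintf(paste0("<z_shift_test> shift (median Z - median A) = %.4f; ",
                     "one-sided p = %.4g (%d permutations; %d Z / %d A ",
                     "contigs)\n"),
              x$shift, x$p_value, x$n_permutations, x$n_z, x$n_autosomal))
  invisible(x)
}

#' Infected vs uninfected abundance of one contig over development
#'
#' Normalizes the full table to CPM and reports, per timepoint, the mean
#' abundance of the target contig in infected and uninfected samples and
#' their ratio.
#'
#' @param x A `count_table`.
#' @param target Contig id.
#' @param pseudocount Added to both means before the ratio (guards empty
#'   libraries; 0 gives the raw ratio).
#' @return data.frame (`hpo`, `infected`, `uninfected`, `ratio`) ordered by
#'   hpo.
#' @export
timecourse_profile <- function(x, target, pseudocount = 0) {
  abort_if(!inherits(x, "count_table"), "x must be a count_table",
           class = "invalid_input")
  abort_if(!target %in% rownames(x$counts), "contig not found: ", target,
           class = "not_found")
  cpm <- normalize_cpm(x)
  tps <- sort(unique(x$samples$hpo))
  rows <- lapply(tps, function(t) {
    inf_ids <- x$samples$sample_id[x$samples$hpo == t & x$samples$infected]
    un_ids <- x$samples$sample_id[x$samples$hpo == t & !x$samples$infected]
    vi <- if (length(inf_ids)) mean(cpm[target, inf_ids]) else NA_real_
    vu <- if (length(un_ids)) mean(cpm[target, un_ids]) else NA_real_
    data.frame(hpo = t, infected = vi, uninfected = vu,
               ratio = (vi + pseudocount) / (vu + pseudocount))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
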