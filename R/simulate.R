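#' Simulate a reference gene-model set and transcript contigs
#'
#' Generates `n_chromosomes * genes_per_chromosome` protein-coding gene models
#' with chromosome labels (a synthetic stand-in for a reference set of gene
#' models with known chromosomal locations), plus one transcript contig per
#' gene.  Contigs are the CDSs with random point substitutions at
#' `design$mutation_rate`, so homology-based chromosome assignment is
#' non-trivial but recoverable.  Exactly one Z-linked gene is flagged as
#' Masc-like; it is the target of the infection-specific knockdown.
#'
#' @param design A [sim_design()].
#' @return A list of class `ref_simulation` with elements
#'   `genes` (data.frame: gene_id, chromosome, is_masc, base_expr, protein,
#'   cds), `contigs` (named character vector of nucleotide sequences),
#'   `truth` (data.frame: contig_id, gene_id, chromosome) and `design`.
#' @examples
#' ref <- simulate_reference(sim_design(n_chromosomes = 2,
#'                                      genes_per_chromosome = 3))
#' ref$genes[, c("gene_id", "chromosome", "is_masc")]
#' @export
simulate_reference <- function(design) {
  abort_if(!inherits(design, "sim_design"), "design must be a sim_design",
           class = "invalid_design")
  gc_tab <- Biostrings::GENETIC_CODE
  codons_by_aa <- split(names(gc_tab), gc_tab)
  aas <- setdiff(unique(gc_tab), "*")
  stops <- codons_by_aa[["*"]]

  n_genes <- design$n_chromosomes * design$genes_per_chromosome
  with_seed(design$seed, {
    chrom <- rep(design$chromosomes, each = design$genes_per_chromosome)
    gene_id <- sprintf("gene_%04d", seq_len(n_genes))
    base_expr <- rlnorm(n_genes, meanlog = log(50), sdlog = 1)
    # codon matrix for vectorized synonymous-codon sampling
    aa_names <- names(codons_by_aa)
    ncod <- lengths(codons_by_aa)
    codon_mat <- t(vapply(codons_by_aa, function(cs) cs[((0:7) %% length(cs)) + 1],
                          character(8)))
    protein <- character(n_genes)
    cds <- character(n_genes)
    for (i in seq_len(n_genes)) {
      aa <- c("M", sample(aas, design$protein_length - 1L, replace = TRUE))
      protein[i] <- paste(aa, collapse = "")
      ai <- match(aa, aa_names)
      pick <- 1L + floor(runif(length(aa)) * ncod[ai])
      cods <- codon_mat[cbind(ai, pick)]
      cds[i] <- paste0(paste(cods, collapse = ""),
                       stops[sample.int(length(stops), 1L)])
    }
    genes <- data.frame(gene_id = gene_id, chromosome = chrom,
                        is_masc = FALSE, base_expr = base_expr,
                        protein = protein, cds = cds,
                        stringsAsFactors = FALSE)
    genes$is_masc[match("Z", genes$chromosome)] <- TRUE

    contigs <- vapply(cds, mutate_dna, character(1),
                      rate = design$mutation_rate, USE.NAMES = FALSE)
    names(contigs) <- paste0("ctg_", gene_id)
    truth <- data.frame(contig_id = names(contigs), gene_id = gene_id,
                        chromosome = chrom, stringsAsFactors = FALSE)
    structure(list(genes = genes, contigs = contigs, truth = truth,
                   design = design),
              class = "ref_simulation")
  })
}

# random point substitutions; consumes RNG
mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  bases <- c("A", "C", "G", "T")
  x <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(x)) < rate)
  for (i in hit) x[i] <- sample(setdiff(bases, x[i]), 1L)
  paste(x, collapse = "")
}

#' Masc expression multiplier over early embryogenesis
#'
#' A unimodal piecewise-linear profile of relative Masc mRNA abundance with
#' its maximum at 6 hpo followed by rapid decay, the qualitative shape seen in
#' uninfected embryo pools by RT-qPCR.  Infected pools are the same curve
#' multiplied by the knockdown `d`, so infection lowers Masc at every
#' timepoint when `d < 1`.  The knot values are free parameters of the
#' synthetic world (only the peak position and rapid decay are constrained).
#'
#' @param timepoint Hours post-oviposition (vectorised), `>= 0`.
#' @param infected Logical; apply the knockdown?
#' @param d Knockdown multiplier in `(0, 1]`.
#' @param knots Named numeric: profile values at 0, 6, 12 and 18 hpo
#'   (constant beyond the last knot).
#' @return Numeric multiplier(s).
#' @examples
#' masc_profile(c(0, 6, 12, 18))
#' masc_profile(6, infected = TRUE, d = 0.2)
#' @export
masc_profile <- function(timepoint, infected = FALSE, d = 1,
                         knots = c(`0` = 0.4, `6` = 1, `12` = 0.3,
                                   `18` = 0.1)) {
  abort_if(any(!is.finite(timepoint)) || any(timepoint < 0),
           "timepoint must be finite and >= 0 hpo", class = "invalid_design")
  abort_if(!is.numeric(d) || d <= 0 || d > 1, "d must lie in (0, 1]",
           class = "invalid_design")
  tk <- as.numeric(names(knots))
  y <- approx(tk, knots, xout = pmin(timepoint, max(tk)), rule = 2)$y
  if (infected) y <- y * d
  y
}

#' Simulate one pooled-RNA count column
#'
#' Draws negative-binomial counts for a single mixed-sex embryo pool.  The
#' expected count of gene *g* is
#' `library_size * base_g * dose_g * profile_g / denom`, with
#' `denom = sum(base_g * baseline_profile_g)` the uninfected, fully
#' compensated composition at the same timepoint:
#' autosomal genes have pool dose 1; Z-linked genes have dose
#' `male_fraction * m + (1 - male_fraction)` where the per-male Z dose `m` is
#' 1 in compensated (uninfected) pools and `f` under compensation failure
#' (infected); the Masc-like gene is further multiplied by
#' [masc_profile()].  Because the scaling denominator is the baseline
#' composition, an uninfected library totals `library_size` in expectation,
#' per-gene infected/uninfected expectation ratios equal the dose model
#' exactly, and failed compensation adds excess Z-derived reads on top of
#' `library_size`, exactly as extra transcription would.
#'
#' @param design A [sim_design()].
#' @param ref A [simulate_reference()] result.
#' @param infected Logical: is this pool from infected mothers?
#' @param timepoint hpo; must be one of `design$timepoints`.
#' @param f,male_fraction Optional per-call overrides of the design values
#'   (e.g. to ramp failure in over development).
#' @param seed Optional seed for this column alone.
#' @return A list with `counts` (named integer vector over contigs),
#'   `expected` (the NB means) and `truth` (list: f, male_fraction, d,
#'   infected, timepoint used).
#' @examples
#' des <- sim_design(n_chromosomes = 2, genes_per_chromosome = 5,
#'                   dispersion = 0, library_size = 1e4)
#' ref <- simulate_reference(des)
#' simulate_pool_counts(des, ref, infected = TRUE, timepoint = 48,
#'                      seed = 1)$truth$f
#' @export
simulate_pool_counts <- function(design, ref, infected, timepoint,
                                 f = design$f,
                                 male_fraction = design$male_fraction,
                                 seed = NULL) {
  abort_if(!inherits(ref, "ref_simulation"), "ref must be a ref_simulation",
           class = "invalid_design")
  abort_if(nrow(ref$genes) == 0, "gene set is empty", class = "invalid_design")
  abort_if(!timepoint %in% design$timepoints,
           "timepoint is not in design$timepoints", class = "invalid_design")
  abort_if(f < 1 || f > 2, "f must lie in [1, 2]", class = "invalid_design")
  abort_if(male_fraction < 0 || male_fraction > 1,
           "male_fraction must lie in [0, 1]", class = "invalid_design")

  genes <- ref$genes
  male_dose <- if (infected) f else 1
  dose <- ifelse(genes$chromosome == "Z",
                 male_fraction * male_dose + (1 - male_fraction), 1)
  prof <- ifelse(genes$is_masc,
                 masc_profile(timepoint, infected = infected, d = design$d), 1)
  prof_base <- ifelse(genes$is_masc, masc_profile(timepoint), 1)
  mu <- design$library_size * genes$base_expr * dose * prof /
    sum(genes$base_expr * prof_base)
  counts <- with_seed(seed, {
    if (design$dispersion == 0) rpois(length(mu), mu)
    else rnbinom(length(mu), mu = mu, size = 1 / design$dispersion)
  })
  names(counts) <- ref$truth$contig_id
  names(mu) <- ref$truth$contig_id
  list(counts = counts, expected = mu,
       truth = list(f = f, male_fraction = male_fraction, d = design$d,
                    infected = infected, timepoint = timepoint))
}

#' Simulate a full infected-vs-uninfected time-course experiment
#'
#' One library per condition per timepoint (matching a design with single
#' pooled libraries).  With `f_schedule = "ramp"` the compensation-failure
#' factor grows linearly from 1 at the first timepoint to `design$f` at the
#' last, emulating failure that becomes detectable only as development
#' proceeds; `"constant"` applies `design$f` throughout.
#'
#' @param design A [sim_design()].
#' @param ref A [simulate_reference()] result (defaults to simulating one).
#' @param f_schedule `"constant"` or `"ramp"`.
#' @param seed Seed for the count draws (default `design$seed`).
#' @return A [count_table()] whose samples are
#'   `hpo<TT>_<inf|uninf>`, with the per-sample truth attached as
#'   attribute `"truth"`.
#' @export
simulate_experiment <- function(design, ref = simulate_reference(design),
                                f_schedule = c("constant", "ramp"),
                                seed = design$seed) {
  f_schedule <- match.arg(f_schedule)
  tps <- design$timepoints
  f_at <- function(t) {
    if (f_schedule == "constant" || length(tps) == 1L) return(design$f)
    1 + (design$f - 1) * (t - min(tps)) / (max(tps) - min(tps))
  }
  grid <- expand.grid(infected = c(FALSE, TRUE), hpo = tps,
                      KEEP.OUT.ATTRS = FALSE)
  with_seed(seed, {
    cols <- vector("list", nrow(grid))
    truth <- vector("list", nrow(grid))
    for (k in seq_len(nrow(grid))) {
      inf <- grid$infected[k]; t <- grid$hpo[k]
      sim <- simulate_pool_counts(design, ref, infected = inf, timepoint = t,
                                  f = if (inf) f_at(t) else 1)
      cols[[k]] <- sim$counts
      truth[[k]] <- sim$truth
    }
    counts <- do.call(cbind, cols)
    ids <- sprintf("hpo%02d_%s", grid$hpo, ifelse(grid$infected, "inf", "uninf"))
    colnames(counts) <- ids
    samples <- data.frame(sample_id = ids, hpo = grid$hpo,
                          infected = grid$infected, stringsAsFactors = FALSE)
    ct <- count_table(counts, samples)
    attr(ct, "truth") <- truth
    ct
  })
}

#' Simulate qPCR cycle thresholds for one individual
#'
#' Models molecular sexing with two Z-linked genes (Tpi, kettin) and an
#' autosomal normalizer (EF1a).  The template dose is the gene copy number: 2
#' for Z genes in ZZ males, 1 in WZ females, and 2 for the autosomal gene in
#' both sexes.  `Ct = base_ct - log(dose) / log(1 + efficiency) + noise`, so
#' at perfect efficiency each missing copy delays Ct by exactly one cycle.
#' Technical replicates (default 3, standard qPCR practice) share nothing but
#' the dose.
#'
#' @param sex `"WZ"` (female) or `"ZZ"` (male).
#' @param efficiency Amplification efficiency in `(0, 1]` (1 = perfect
#'   doubling each cycle).
#' @param noise_sd Gaussian per-well Ct noise, in cycles.
#' @param n_replicates Technical replicates per gene.
#' @param base_ct Named baseline Ct (cycles) at dose 2 for each gene;
#'   arbitrary, cancels in all dose ratios.
#' @param individual_id Identifier written into the table.
#' @param seed Optional seed.
#' @return A data.frame (`individual_id`, `gene`, `replicate`, `ct`).
#' @examples
#' simulate_qpcr("WZ", noise_sd = 0, n_replicates = 1)
#' @export
simulate_qpcr <- function(sex = c("WZ", "ZZ"), efficiency = 1,
                          noise_sd = 0.15, n_replicates = 3L,
                          base_ct = c(Tpi = 20, kettin = 20, EF1a = 20),
                          individual_id = "ind1", seed = NULL) {
  sex <- match.arg(sex)
  abort_if(!is.numeric(efficiency) || efficiency <= 0 || efficiency > 1,
           "efficiency must lie in (0, 1]", class = "invalid_design")
  abort_if(noise_sd < 0, "noise_sd must be >= 0", class = "invalid_design")
  genes <- c("Tpi", "kettin", "EF1a")
  abort_if(!all(genes %in% names(base_ct)),
           "base_ct must name Tpi, kettin and EF1a", class = "invalid_design")
  dose <- c(Tpi = if (sex == "ZZ") 2 else 1,
            kettin = if (sex == "ZZ") 2 else 1,
            EF1a = 2)
  with_seed(seed, {
    rows <- expand.grid(gene = genes, replicate = seq_len(n_replicates),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    ct <- base_ct[rows$gene] - log(dose[rows$gene]) / log(1 + efficiency) +
      rnorm(nrow(rows), 0, noise_sd)
    data.frame(individual_id = individual_id, gene = rows$gene,
               replicate = rows$replicate, ct = as.numeric(ct),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a sexing cohort
#'
#' @param n Number of individuals; the first `ceiling(n/2)` are ZZ males and
#'   the rest WZ females (order is immaterial downstream).
#' @param seed Seed.
#' @inheritParams simulate_qpcr
#' @return List with `ct` (stacked Ct table) and `truth`
#'   (data.frame individual_id, sex).
#' @export
simulate_qpcr_cohort <- function(n = 200L, efficiency = 1, noise_sd = 0.15,
                                 n_replicates = 3L, seed = NULL) {
  abort_if(n < 1, "n must be >= 1", class = "invalid_design")
  sexes <- rep(c("ZZ", "WZ"), c(ceiling(n / 2), floor(n / 2)))
  ids <- sprintf("ind_%03d", seq_len(n))
  with_seed(seed, {
    tabs <- lapply(seq_len(n), function(i)
      simulate_qpcr(sexes[i], efficiency = efficiency, noise_sd = noise_sd,
                    n_replicates = n_replicates, individual_id = ids[i]))
    list(ct = do.call(rbind, tabs),
         truth = data.frame(individual_id = ids, sex = sexes,
                            stringsAsFactors = FALSE))
  })
}

#' Evolve a gap-free protein alignment down a tree
#'
#' Sites are independent; along a branch of length `b` (expected
#' substitutions per site) each site changes with probability
#' `(19/20) * (1 - exp(-20 b / 19))` (the 20-state symmetric model), and a
#' changed site takes one of the 19 other residues uniformly.  The root
#' sequence is uniform over the 20 canonical amino acids.
#'
#' @param tree An `ape::phylo` tree with non-negative branch lengths.
#' @param seq_length Number of alignment columns.
#' @param seed Optional seed.
#' @return Named character vector of aligned (gap-free) sequences, one per
#'   tip.
#' @examples
#' tr <- ape::read.tree(text = "((A:0.1,B:0.1):0.5,(C:0.1,D:0.1):0.5);")
#' evolve_alignment(tr, 20, seed = 1)
#' @export
evolve_alignment <- function(tree, seq_length, seed = NULL) {
  abort_if(!inherits(tree, "phylo"), "tree must be an ape phylo object",
           class = "invalid_tree")
  abort_if(length(tree$tip.label) < 1, "tree has no leaves",
           class = "invalid_tree")
  abort_if(is.null(tree$edge.length) || any(tree$edge.length < 0) ||
             any(!is.finite(tree$edge.length)),
           "tree must have finite non-negative branch lengths",
           class = "invalid_tree")
  abort_if(seq_length < 1, "seq_length must be >= 1", class = "invalid_tree")

  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
           "F", "P", "S", "T", "W", "Y", "V")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  with_seed(seed, {
    seqs <- vector("list", ntip + tree$Nnode)
    seqs[[root]] <- sample(aas, seq_length, replace = TRUE)
    # preorder: parents are assigned before children
    ord <- ape::reorder.phylo(tree, "cladewise")
    for (k in seq_len(nrow(ord$edge))) {
      par <- ord$edge[k, 1]; chd <- ord$edge[k, 2]
      b <- ord$edge.length[k]
      s <- seqs[[par]]
      p_change <- (19 / 20) * (1 - exp(-20 * b / 19))
      hit <- which(runif(seq_length) < p_change)
      for (i in hit) s[i] <- sample(setdiff(aas, s[i]), 1L)
      seqs[[chd]] <- s
    }
    out <- vapply(seqs[seq_len(ntip)], paste, character(1), collapse = "")
    names(out) <- tree$tip.label
    out
  })
}
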