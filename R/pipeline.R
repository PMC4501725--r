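#' Write every simulated pipeline input to a directory
#'
#' Materializes a [sim_design()] world on disk: reference proteins and CDSs
#' (FASTA), the gene table (TSV), transcript contigs (FASTA), the count
#' matrix and sample sheet for a full infected-vs-uninfected time course
#' (TSV), a qPCR sexing cohort (TSV) and the ground truth (TSV).
#'
#' @param design A [sim_design()].
#' @param outdir Output directory (created if needed).
#' @param f_schedule Passed to [simulate_experiment()]; the default `"ramp"`
#'   makes compensation failure grow over development, so the Z shift is
#'   absent at the first timepoint and full-strength at the last.
#' @param n_individuals Size of the qPCR cohort.
#' @return Named list of file paths (invisibly the same list).
#' @export
simulate_inputs <- function(design, outdir, f_schedule = "ramp",
                            n_individuals = 40L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ref <- simulate_reference(design)
  expt <- simulate_experiment(design, ref, f_schedule = f_schedule,
                              seed = design$seed + 1L)
  cohort <- simulate_qpcr_cohort(n_individuals, seed = design$seed + 2L)

  p <- function(f) file.path(outdir, f)
  paths <- list(
    reference_proteins = p("reference_proteins.fasta"),
    reference_cds = p("reference_cds.fasta"),
    gene_table = p("gene_table.tsv"),
    contigs = p("contigs.fasta"),
    counts = p("counts.tsv"),
    samples = p("samples.tsv"),
    ct_table = p("ct_table.tsv"),
    ground_truth = p("ground_truth.tsv"))
  write_fasta(setNames(ref$genes$protein, ref$genes$gene_id),
              paths$reference_proteins)
  write_fasta(setNames(ref$genes$cds, ref$genes$gene_id), paths$reference_cds)
  write_tsv(ref$genes[, c("gene_id", "chromosome", "is_masc")],
            paths$gene_table)
  write_fasta(ref$contigs, paths$contigs)
  write_counts(expt, paths$counts)
  write_tsv(expt$samples, paths$samples)
  write_tsv(cohort$ct, paths$ct_table)
  truth <- merge(ref$truth,
                 data.frame(gene_id = ref$genes$gene_id,
                            is_masc = ref$genes$is_masc), by = "gene_id")
  write_tsv(truth[order(truth$contig_id),
                  c("contig_id", "gene_id", "chromosome", "is_masc")],
            paths$ground_truth)
  invisible(paths)
}

default_pipeline_params <- function() {
  list(evalue_threshold = 1e-9, pseudocount = 0.5, min_abundance = 1,
       center = "autosomes", n_permutations = 999,
       sex_low = 0.70, sex_high = 0.75,
       efficiency = 1, calibrator_tpi = 0, calibrator_kettin = 0,
       bootstrap_replicates = 100)
}

#' Run the full analysis pipeline on files
#'
#' Orchestrates every stage: chromosome assignment of contigs, per-timepoint
#' infected/uninfected ratio tables, per-chromosome summaries, Z-shift
#' permutation tests with Benjamini-Hochberg correction across timepoints,
#' molecular sexing, and (if an aligned domain block is supplied) the NJ +
#' bootstrap tree.  All outputs are written as TSV/newick plus a JSON run
#' manifest recording the seed and parameters; a rerun with the same config
#' and seed is byte-identical.
#'
#' @param config Either a list or a path to a JSON file with elements
#'   `paths` (reference_proteins, gene_table, contigs, counts, samples,
#'   ct_table; optionally `msa`, an aligned FASTA of domain sequences),
#'   optional `params` (see [default_pipeline_params()] for names and
#'   defaults) and `seed`.
#' @param outdir Output directory.
#' @param verbose Emit one progress line per stage.
#' @return Named list of results (assignments, per-timepoint ratio tables and
#'   summaries, z-shift table, sex calls, tree, manifest path), invisibly.
#' @export
run_full <- function(config, outdir, verbose = TRUE) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  abort_if(is.null(config$paths), "config needs a 'paths' element",
           class = "invalid_input")
  params <- utils::modifyList(default_pipeline_params(),
                              config$params %||% list())
  seed <- as.integer(config$seed %||% 1L)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(stage, ...) if (verbose)
    message(sprintf("[%s] %s", stage, sprintf(...)))
  paths <- config$paths
  for (nm in c("reference_proteins", "gene_table", "contigs", "counts",
               "samples", "ct_table"))
    abort_if(is.null(paths[[nm]]) || !file.exists(paths[[nm]]),
             "missing input path: ", nm, class = "invalid_input")

  ref_prot <- read_fasta(paths$reference_proteins, "AA")
  gene_tab <- read_gene_table(paths$gene_table)
  contigs <- read_fasta(paths$contigs, "DNA")
  counts <- read_counts(paths$counts, paths$samples)
  ct_tab <- read_ct_table(paths$ct_table)
  say("input", "%d reference proteins, %d contigs, %d samples, %d Ct rows",
      length(ref_prot), length(contigs), ncol(counts$counts), nrow(ct_tab))

  chrom_map <- setNames(gene_tab$chromosome, gene_tab$gene_id)
  assign <- assign_chromosomes(contigs, ref_prot, chrom_map,
                               evalue_threshold = params$evalue_threshold)
  say("assign", "%d/%d contigs assigned",
      sum(assign$chromosome != "unassigned"), nrow(assign))
  write_tsv(assign, file.path(outdir, "assignments.tsv"))
  contig_chrom <- setNames(assign$chromosome, assign$contig_id)
  contig_chrom[contig_chrom == "unassigned"] <- NA_character_

  cpm <- normalize_cpm(counts)
  tps <- sort(unique(counts$samples$hpo))
  ratio_tables <- list()
  summaries <- list()
  zres <- list()
  for (k in seq_along(tps)) {
    t <- tps[k]
    inf_ids <- counts$samples$sample_id[counts$samples$hpo == t &
                                          counts$samples$infected]
    un_ids <- counts$samples$sample_id[counts$samples$hpo == t &
                                         !counts$samples$infected]
    if (length(inf_ids) == 0 || length(un_ids) == 0) next
    rt <- compute_ratios(cpm, inf_ids, un_ids, chromosomes = contig_chrom,
                         pseudocount = params$pseudocount,
                         min_abundance = params$min_abundance,
                         center = params$center)
    key <- sprintf("hpo%02d", t)
    ratio_tables[[key]] <- rt
    summaries[[key]] <- summarize_by_chromosome(rt)
    zres[[key]] <- z_shift_test(rt, n_permutations = params$n_permutations,
                                seed = seed + k)
    write_tsv(rt, file.path(outdir, sprintf("ratios_%s.tsv", key)))
    write_tsv(summaries[[key]],
              file.path(outdir, sprintf("chrom_summary_%s.tsv", key)))
    say("dosage", "%s: shift %.3f, p = %.4g", key, zres[[key]]$shift,
        zres[[key]]$p_value)
  }
  ztab <- data.frame(
    hpo = tps[seq_along(zres)],
    shift = vapply(zres, `[[`, numeric(1), "shift"),
    p_value = vapply(zres, `[[`, numeric(1), "p_value"),
    stringsAsFactors = FALSE)
  ztab$p_adj_bh <- p.adjust(ztab$p_value, method = "BH")
  write_tsv(ztab, file.path(outdir, "z_shift_tests.tsv"))

  calls <- sex_calls(ct_tab, efficiency = params$efficiency,
                     calibrator = c(Tpi = params$calibrator_tpi,
                                    kettin = params$calibrator_kettin),
                     thresholds = c(low = params$sex_low,
                                    high = params$sex_high))
  say("sexing", "%d individuals: %s", nrow(calls),
      paste(names(table(calls$call)), table(calls$call), collapse = ", ",
            sep = "="))
  write_tsv(calls, file.path(outdir, "sex_calls.tsv"))

  tree <- NULL
  if (!is.null(paths$msa) && nzchar(paths$msa)) {
    msa <- read_fasta(paths$msa, "AA")
    tree <- bootstrap_tree(msa, n_replicates = params$bootstrap_replicates,
                           seed = seed + 1000L)
    write_newick(tree, file.path(outdir, "masc_tree.nwk"))
    say("phylo", "%d taxa, %d bootstrap replicates", length(msa),
        params$bootstrap_replicates)
  }

  manifest <- list(
    package = "mascdose",
    version = as.character(utils::packageVersion("mascdose")),
    seed = seed, params = params, inputs = paths,
    outputs = sort(list.files(outdir, pattern = "\\.(tsv|nwk)$")))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(assignments = assign, ratios = ratio_tables,
                 summaries = summaries, z_shift = ztab, sex_calls = calls,
                 tree = tree, manifest = manifest_path))
}
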