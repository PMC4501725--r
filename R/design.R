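#' Simulation design for mixed-sex embryo-pool transcriptomes
#'
#' Collects every parameter of the synthetic world: a WZ/ZZ karyotype with one
#' Z chromosome, pooled RNA from 25-50 embryos of mixed sex, a Z-dose model in
#' which males (ZZ) carry two Z copies that are transcriptionally compensated
#' down to the single-copy female (WZ) output, a compensation-failure factor
#' `f` that lifts infected-male Z output back towards two-copy levels, and a
#' Masc-specific knockdown `d` applied to infected pools.
#'
#' @param n_chromosomes Number of chromosomes; the first is the Z, the rest are
#'   autosomes `A1`, `A2`, ... Default 28, the karyotype of *Bombyx mori*,
#'   whose gene models anchor the chromosome assignment.
#' @param genes_per_chromosome Genes simulated per chromosome.
#' @param male_fraction Proportion of pool RNA contributed by ZZ (male)
#'   individuals, in `[0, 1]`. Pools are mixed-sex; 0.5 reflects an
#'   unperturbed primary sex ratio at oviposition.
#' @param f Compensation-failure factor in `[1, 2]`: effective Z dose of an
#'   infected male. 1 = full compensation (male Z output equals the female
#'   single-copy output), 2 = no compensation (both Z copies fully expressed).
#' @param d Masc knockdown in `(0, 1]`: multiplier on Masc expression in
#'   infected pools. 1 = no knockdown.
#' @param dispersion Negative-binomial dispersion (variance `mu + dispersion *
#'   mu^2`); 0 degenerates to Poisson.
#' @param library_size Expected total read count of an uninfected (baseline)
#'   library.
#' @param timepoints Hours post-oviposition (hpo) at which pools are sampled.
#' @param mutation_rate Per-nucleotide substitution rate applied to reference
#'   CDSs when deriving transcript contigs, so that homology assignment is
#'   non-trivial.
#' @param protein_length Length (residues) of each simulated reference protein.
#' @param seed Integer seed; every downstream simulation is reproducible from
#'   the design.
#'
#' @return An object of class `sim_design` (a validated list).
#' @examples
#' d <- sim_design(n_chromosomes = 2, genes_per_chromosome = 3)
#' d$chromosomes
#' @export
sim_design <- function(n_chromosomes = 28L,
                       genes_per_chromosome = 50L,
                       male_fraction = 0.5,
                       f = 2,
                       d = 0.2,
                       dispersion = 0.05,
                       library_size = 1e6,
                       timepoints = c(0, 12, 24, 36, 48),
                       mutation_rate = 0.02,
                       protein_length = 120L,
                       seed = 1L) {
  abort_if(!is.numeric(n_chromosomes) || n_chromosomes < 1,
           "n_chromosomes must be a positive integer", class = "invalid_design")
  abort_if(!is.numeric(genes_per_chromosome) || genes_per_chromosome < 1,
           "genes_per_chromosome must be a positive integer",
           class = "invalid_design")
  abort_if(!is.numeric(male_fraction) || male_fraction < 0 || male_fraction > 1,
           "male_fraction must lie in [0, 1]", class = "invalid_design")
  abort_if(!is.numeric(f) || f < 1 || f > 2,
           "f must lie in [1, 2]", class = "invalid_design")
  abort_if(!is.numeric(d) || d <= 0 || d > 1,
           "d must lie in (0, 1]", class = "invalid_design")
  abort_if(!is.numeric(dispersion) || dispersion < 0 || !is.finite(dispersion),
           "dispersion must be finite and >= 0", class = "invalid_design")
  abort_if(!is.numeric(library_size) || library_size <= 0 ||
             !is.finite(library_size),
           "library_size must be finite and positive", class = "invalid_design")
  abort_if(length(timepoints) < 1 || any(!is.finite(timepoints)) ||
             any(timepoints < 0),
           "timepoints must be finite and >= 0 hpo", class = "invalid_design")
  abort_if(!is.numeric(mutation_rate) || mutation_rate < 0 || mutation_rate >= 1,
           "mutation_rate must lie in [0, 1)", class = "invalid_design")
  abort_if(!is.numeric(protein_length) || protein_length < 10,
           "protein_length must be >= 10", class = "invalid_design")

  chroms <- c("Z", if (n_chromosomes > 1)
    paste0("A", seq_len(n_chromosomes - 1)))
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    genes_per_chromosome = as.integer(genes_per_chromosome),
    chromosomes = chroms,
    male_fraction = male_fraction,
    f = f,
    d = d,
    dispersion = dispersion,
    library_size = library_size,
    timepoints = as.numeric(timepoints),
    mutation_rate = mutation_rate,
    protein_length = as.integer(protein_length),
    seed = as.integer(seed)
  ), class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat("<sim_design>\n")
  cat(sprintf("  karyotype: %d chromosomes (%d genes each), Z + %d autosomes\n",
              x$n_chromosomes, x$genes_per_chromosome, x$n_chromosomes - 1L))
  cat(sprintf("  pool: male_fraction = %.2f; failure f = %.2f; Masc d = %.2f\n",
              x$male_fraction, x$f, x$d))
  cat(sprintf("  counts: library %.3g, NB dispersion %.3g\n",
              x$library_size, x$dispersion))
  cat(sprintf("  timepoints (hpo): %s; seed %d\n",
              paste(x$timepoints, collapse = ", "), x$seed))
  invisible(x)
}
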