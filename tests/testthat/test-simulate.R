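tiny_design <- function(...) {
  sim_design(n_chromosomes = 2, genes_per_chromosome = 3, protein_length = 30,
             library_size = 1e5, dispersion = 0, mutation_rate = 0, ...)
}

test_that("simulate_reference is seeded, counted and labelled correctly", {
  des <- tiny_design()
  r1 <- simulate_reference(des)
  r2 <- simulate_reference(des)
  expect_identical(r1, r2)  # byte-identical under the same seed

  expect_equal(nrow(r1$genes), 6)
  expect_equal(length(r1$contigs), 6)
  expect_setequal(unique(r1$genes$chromosome), c("Z", "A1"))
  expect_equal(sum(r1$genes$is_masc), 1)
  expect_equal(r1$genes$chromosome[r1$genes$is_masc], "Z")

  r3 <- simulate_reference(tiny_design(seed = 99))
  expect_false(identical(r1$genes$protein, r3$genes$protein))
})

test_that("CDSs translate to their protein and contigs mirror the CDS", {
  ref <- simulate_reference(tiny_design())
  for (i in seq_len(nrow(ref$genes))) {
    cds <- ref$genes$cds[i]
    expect_equal(nchar(cds), 3 * nchar(ref$genes$protein[i]) + 3)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_equal(sub("\\*$", "", aa), ref$genes$protein[i])
    expect_false(grepl("\\*.", aa))  # no internal stops
  }
  # mutation rate 0: contig == CDS
  expect_identical(unname(ref$contigs), ref$genes$cds)
  # mutation rate > 0 changes roughly that fraction of bases
  refm <- simulate_reference(sim_design(n_chromosomes = 2,
                                        genes_per_chromosome = 10,
                                        protein_length = 60,
                                        mutation_rate = 0.1))
  diffs <- mapply(function(a, b) {
    mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, refm$contigs, refm$genes$cds)
  expect_gt(mean(diffs), 0.05)
  expect_lt(mean(diffs), 0.15)
})

test_that("masc_profile peaks at 6 hpo and scales by d when infected", {
  tp <- c(0, 6, 12, 18)
  un <- masc_profile(tp)
  expect_equal(tp[which.max(un)], 6)
  expect_true(all(diff(un[tp >= 6]) < 0))  # rapid decline after the peak
  expect_equal(masc_profile(tp, infected = TRUE, d = 1), un)
  expect_equal(masc_profile(6, infected = TRUE, d = 0.2),
               0.2 * masc_profile(6))
  expect_true(all(masc_profile(tp, infected = TRUE, d = 0.5) < un))
  expect_error(masc_profile(6, infected = TRUE, d = 0),
               class = "invalid_design")
  expect_error(masc_profile(-1), class = "invalid_design")
})

test_that("pool count expectations follow the Z-dose model", {
  des <- tiny_design(d = 1)
  ref <- simulate_reference(des)
  z <- ref$genes$chromosome == "Z" & !ref$genes$is_masc
  a <- ref$genes$chromosome != "Z"

  # null case: f irrelevant when set to 1 -> identical expectations
  inf1 <- simulate_pool_counts(des, ref, TRUE, 48, f = 1, seed = 1)
  un1 <- simulate_pool_counts(des, ref, FALSE, 48, seed = 1)
  expect_equal(inf1$expected, un1$expected)

  # f = 2, half males: Z expectation ratio 1.5, autosomes 1.0
  inf2 <- simulate_pool_counts(des, ref, TRUE, 48, f = 2, seed = 1)
  expect_equal(unname(inf2$expected[z] / un1$expected[z]),
               rep(1.5, sum(z)))
  expect_equal(unname(inf2$expected[a] / un1$expected[a]), rep(1, sum(a)))

  # all-female pool shows no shift
  inf3 <- simulate_pool_counts(des, ref, TRUE, 48, f = 2, male_fraction = 0,
                               seed = 1)
  expect_equal(inf3$expected, un1$expected)

  # baseline (uninfected) library totals library_size in expectation
  expect_equal(sum(un1$expected), des$library_size, tolerance = 1e-12)

  expect_error(simulate_pool_counts(des, ref, TRUE, 7), # not a design timepoint
               class = "invalid_design")
})

test_that("empirical Z count ratio converges to the dose-model closed form", {
  # male_fraction * f + 1 - male_fraction, within 2% at library >= 1e6
  world <- quick_ref(28, 50, library_size = 4e6, dispersion = 0,
                     male_fraction = 0.5, seed = 3)
  inf <- simulate_pool_counts(world$design, world$ref, TRUE, 48, f = 2,
                              seed = 11)
  un <- simulate_pool_counts(world$design, world$ref, FALSE, 48, seed = 12)
  z <- world$ref$truth$chromosome == "Z"
  ratio <- sum(inf$counts[z]) / sum(un$counts[z])
  expect_lt(abs(ratio - 1.5) / 1.5, 0.02)
  ratio_a <- sum(inf$counts[!z]) / sum(un$counts[!z])
  expect_lt(abs(ratio_a - 1), 0.02)
})

test_that("negative-binomial noise honours the dispersion parameter", {
  world <- quick_ref(2, 200, dispersion = 0.2, library_size = 1e6, seed = 4)
  sim <- simulate_pool_counts(world$design, world$ref, FALSE, 48, seed = 9)
  mu <- sim$expected
  big <- mu > 500  # dispersion dominates Poisson noise here
  pearson <- (sim$counts[big] - mu[big])^2 / (mu[big] + 0.2 * mu[big]^2)
  expect_lt(abs(mean(pearson) - 1), 0.35)
})

test_that("simulate_experiment assembles a deterministic count_table", {
  des <- tiny_design()
  e1 <- simulate_experiment(des)
  e2 <- simulate_experiment(des)
  expect_identical(e1$counts, e2$counts)
  expect_equal(ncol(e1$counts), 2 * length(des$timepoints))
  expect_true(all(c("sample_id", "hpo", "infected") %in% names(e1$samples)))
  # ramp schedule: infected truth f grows from 1 to design f
  er <- simulate_experiment(des, f_schedule = "ramp")
  truth <- attr(er, "truth")
  fs <- vapply(truth, function(t) if (t$infected) t$f else NA_real_,
               numeric(1))
  fs <- fs[!is.na(fs)]
  expect_equal(min(fs), 1)
  expect_equal(max(fs), des$f)
  expect_true(all(diff(fs) >= 0))
})

test_that("simulate_qpcr reproduces copy-number arithmetic", {
  wz <- simulate_qpcr("WZ", efficiency = 1, noise_sd = 0, n_replicates = 1)
  zz <- simulate_qpcr("ZZ", efficiency = 1, noise_sd = 0, n_replicates = 1)
  ct <- function(tab, g) tab$ct[tab$gene == g]
  # one missing Z copy = one extra cycle at perfect efficiency
  expect_equal(ct(wz, "Tpi") - ct(zz, "Tpi"), 1)
  expect_equal(ct(wz, "kettin") - ct(zz, "kettin"), 1)
  # autosomal normalizer identical in both sexes
  expect_equal(ct(wz, "EF1a"), ct(zz, "EF1a"))
  # seeded determinism
  expect_identical(simulate_qpcr("WZ", seed = 7), simulate_qpcr("WZ", seed = 7))
  expect_error(simulate_qpcr("WZ", efficiency = 0), class = "invalid_design")
  expect_error(simulate_qpcr("WZ", efficiency = 1.5), class = "invalid_design")
})

test_that("evolve_alignment respects branch lengths and seeding", {
  tr0 <- ape::read.tree(text = "((A:0,B:0):0,(C:0,D:0):0);")
  aln0 <- evolve_alignment(tr0, 40, seed = 1)
  expect_equal(length(unique(aln0)), 1)  # zero branch lengths: identical

  tr <- ape::read.tree(text = "((A:0.1,B:0.1):0.6,(C:0.1,D:0.1):0.1);")
  aln <- evolve_alignment(tr, 250, seed = 2)
  expect_equal(unname(nchar(aln)), rep(250, 4))
  expect_identical(evolve_alignment(tr, 250, seed = 2), aln)
  # NJ on p-distances recovers the generating split across the long branch
  nj <- neighbor_joining(p_distance(aln))
  expect_true("C,D" %in% phylo_splits(nj))

  expect_error(evolve_alignment(tr, 0), class = "invalid_tree")
  trneg <- tr; trneg$edge.length[1] <- -0.1
  expect_error(evolve_alignment(trneg, 10), class = "invalid_tree")
})
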