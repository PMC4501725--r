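mat <- function(...) {
  m <- rbind(...)
  rownames(m) <- paste0("c", seq_len(nrow(m)))
  m
}

test_that("count_table validates counts and metadata", {
  m <- mat(c(1, 2), c(3, 4))
  colnames(m) <- c("s1", "s2")
  ss <- data.frame(sample_id = c("s1", "s2"), hpo = c(0, 0),
                   infected = c(TRUE, FALSE))
  expect_s3_class(count_table(m, ss), "count_table")
  m2 <- m; m2[1, 1] <- -1
  expect_error(count_table(m2, ss), class = "invalid_input")
  m3 <- m; m3[1, 1] <- 1.5
  expect_error(count_table(m3, ss), class = "invalid_input")
  expect_error(count_table(m, ss[1, ]), class = "invalid_input")
})

test_that("CPM normalization is exact and flags degenerate samples", {
  m <- mat(c(1, 0), c(1, 0), c(2, 0))
  colnames(m) <- c("s1", "s2")
  expect_error(normalize_cpm(m), class = "degenerate_sample")
  expect_error(normalize_cpm(m), "s2")  # names the offender

  m2 <- m[, 1, drop = FALSE]
  cpm <- normalize_cpm(m2)
  expect_equal(unname(cpm[, 1]), c(250000, 250000, 500000))
  # doubling a sample's counts leaves its normalized column unchanged
  expect_equal(normalize_cpm(m2 * 2), cpm)
  # column sums are 1e6 for random tables
  set.seed(3)
  for (k in 1:25) {
    r <- matrix(rpois(60, 20) + 1, 10, 6,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
    expect_equal(unname(colSums(normalize_cpm(r))), rep(1e6, 6))
  }
})

test_that("compute_ratios has the documented closed forms", {
  m <- mat(c(10, 10), c(80, 80), c(300, 100))
  colnames(m) <- c("inf", "uninf")
  rt <- compute_ratios(m, "inf", "uninf", center = FALSE)
  expect_equal(rt$M[rt$contig_id %in% c("c1", "c2")], c(0, 0),
               tolerance = 0.1)  # equal means -> M ~ 0 (pseudocount only)
  # 3x ratio with vanishing pseudocount -> log2 3
  rt2 <- compute_ratios(m, "inf", "uninf", pseudocount = 1e-9,
                        center = FALSE)
  expect_equal(rt2$M[rt2$contig_id == "c3"], log2(3), tolerance = 1e-6)
  # A is the mean log2 abundance
  expect_equal(rt2$A[rt2$contig_id == "c3"], 0.5 * log2(300 * 100),
               tolerance = 1e-6)

  # label swap negates every M (centering included)
  big <- mat(c(10, 20), c(30, 30), c(50, 40), c(9, 12), c(100, 50))
  colnames(big) <- c("inf", "uninf")
  f <- compute_ratios(big, "inf", "uninf")
  r <- compute_ratios(big, "uninf", "inf")
  expect_equal(f$M, -r$M)

  # min_abundance drops doubly-low contigs and reports them
  low <- mat(c(0.2, 0.3), c(10, 10))
  colnames(low) <- c("inf", "uninf")
  rl <- compute_ratios(low, "inf", "uninf", min_abundance = 1)
  expect_equal(rl$contig_id, "c2")
  expect_equal(attr(rl, "dropped"), "c1")

  expect_error(compute_ratios(m, character(0), "uninf"),
               class = "invalid_design")
  expect_error(compute_ratios(m, "inf", "uninf", pseudocount = 0),
               class = "invalid_design")
})

test_that("raw-count scaling cancels out of M", {
  world <- quick_ref(3, 30, seed = 8, dispersion = 0.05, library_size = 2e5)
  inf <- simulate_pool_counts(world$design, world$ref, TRUE, 48, seed = 1)
  un <- simulate_pool_counts(world$design, world$ref, FALSE, 48, seed = 2)
  chroms <- setNames(world$ref$truth$chromosome, world$ref$truth$contig_id)
  m1 <- cbind(inf = inf$counts, uninf = un$counts)
  m2 <- cbind(inf = inf$counts * 7, uninf = un$counts)  # rescaled library
  r1 <- compute_ratios(normalize_cpm(m1), "inf", "uninf", chromosomes = chroms)
  r2 <- compute_ratios(normalize_cpm(m2), "inf", "uninf", chromosomes = chroms)
  expect_equal(r1$M, r2$M)
})

test_that("summarize_by_chromosome uses type-7 quantiles, Z first", {
  rt <- data.frame(contig_id = paste0("c", 1:8),
                   chromosome = c(rep("A1", 5), rep("Z", 3)),
                   M = c(1, 2, 3, 4, 5, 0, 0, 0), A = 0)
  class(rt) <- c("ratio_table", "data.frame")
  s <- summarize_by_chromosome(rt)
  expect_equal(s$chromosome, c("Z", "A1"))
  a1 <- s[s$chromosome == "A1", ]
  expect_equal(c(a1$q25, a1$median, a1$q75), c(2, 3, 4))
  z <- s[s$chromosome == "Z", ]
  expect_equal(c(z$q25, z$median, z$q75), c(0, 0, 0))
  expect_true(all(s$q25 <= s$median & s$median <= s$q75))
})

test_that("z_shift_test: null returns p ~ 1, errors are classed", {
  rt <- data.frame(contig_id = paste0("c", 1:30),
                   chromosome = rep(c("Z", "A1", "A2"), each = 10),
                   M = rep(0.7, 30), A = 0)
  z <- z_shift_test(rt, n_permutations = 199, seed = 1)
  expect_equal(z$shift, 0)
  expect_equal(z$p_value, 1)

  expect_error(z_shift_test(rt[rt$chromosome == "Z", ], seed = 1),
               class = "invalid_input")  # one chromosome only
  rt2 <- rt[c(1:3, 11:30), ]             # 3 Z contigs
  expect_error(z_shift_test(rt2, seed = 1), class = "insufficient_data")
  expect_error(z_shift_test(rt, n_permutations = 10), class = "invalid_design")
})

test_that("z-shift detects failed compensation and stays calibrated", {
  world <- quick_ref(5, 40, seed = 21)   # 40 Z + 160 autosomal genes
  rt <- quick_ratio_table(world, f = 2, seed = 100)
  z <- z_shift_test(rt, n_permutations = 499, seed = 1)
  expect_equal(z$shift, log2(1.5), tolerance = 0.25)
  expect_lt(z$p_value, 0.01)

  # swapping labels negates the observed shift
  world2 <- world
  rt_sw <- rt
  rt_sw$M <- -rt_sw$M
  z_sw <- z_shift_test(rt_sw, n_permutations = 499, seed = 1)
  expect_equal(z_sw$shift, -z$shift)

  # f = 1 null: p-values approximately uniform (KS at alpha = 0.01)
  pvals <- vapply(1:120, function(r) {
    rtn <- quick_ratio_table(world, f = 1, seed = 2000 + r)
    z_shift_test(rtn, n_permutations = 199, seed = r)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("parameter recovery: 2^(Z median M) estimates the pooled dose", {
  # male_fraction 0.4, f 1.6 -> pooled Z dose 1.24; three libraries per
  # condition, so group means tame the per-gene NB noise
  world <- quick_ref(4, 150, male_fraction = 0.4, f = 1.6, seed = 31,
                     dispersion = 0.05, library_size = 1e6)
  cols <- list()
  for (r in 1:3) {
    cols[[paste0("inf", r)]] <-
      simulate_pool_counts(world$design, world$ref, TRUE, 48, f = 1.6,
                           seed = 700 + r)$counts
    cols[[paste0("un", r)]] <-
      simulate_pool_counts(world$design, world$ref, FALSE, 48,
                           seed = 800 + r)$counts
  }
  m <- do.call(cbind, cols)
  rt <- compute_ratios(normalize_cpm(m), paste0("inf", 1:3), paste0("un", 1:3),
                       chromosomes = setNames(world$ref$truth$chromosome,
                                              world$ref$truth$contig_id))
  est <- 2^median(rt$M[rt$chromosome == "Z"])
  truth <- 0.4 * 1.6 + 0.6
  expect_lt(abs(est - truth) / truth, 0.05)
})

test_that("timecourse_profile tracks the Masc knockdown", {
  # all-female pools isolate the Masc knockdown from the Z-dose shift
  des <- sim_design(n_chromosomes = 2, genes_per_chromosome = 10,
                    protein_length = 20, mutation_rate = 0, dispersion = 0,
                    library_size = 2e6, d = 0.2, male_fraction = 0,
                    timepoints = c(0, 6, 12, 18), seed = 6)
  ref <- simulate_reference(des)
  expt <- simulate_experiment(des, ref, f_schedule = "constant")
  masc_ctg <- ref$truth$contig_id[ref$genes$is_masc]
  prof <- timecourse_profile(expt, masc_ctg)
  # uninfected profile peaks at 6 hpo
  expect_equal(prof$hpo[which.max(prof$uninfected)], 6)
  # knockdown recovered at every timepoint (Poisson noise only)
  expect_equal(prof$ratio, rep(0.2, 4), tolerance = 0.15)

  # d = 1: ratio ~ 1 everywhere... up to the Z-dose shift of an f=2 pool,
  # so use f = 1 via an all-female pool
  des1 <- sim_design(n_chromosomes = 2, genes_per_chromosome = 10,
                     protein_length = 20, mutation_rate = 0, dispersion = 0,
                     library_size = 2e6, d = 1, male_fraction = 0,
                     timepoints = c(0, 6, 12, 18), seed = 6)
  ref1 <- simulate_reference(des1)
  expt1 <- simulate_experiment(des1, ref1, f_schedule = "constant")
  prof1 <- timecourse_profile(expt1, ref1$truth$contig_id[ref1$genes$is_masc])
  expect_equal(prof1$ratio, rep(1, 4), tolerance = 0.1)

  expect_error(timecourse_profile(expt, "nope"), class = "not_found")
})
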