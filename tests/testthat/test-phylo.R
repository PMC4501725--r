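test_that("extract_domain uses 1-based inclusive coordinates", {
  prot <- paste(rep(c("A", "C", "D", "E"), 50), collapse = "")  # 200 aa
  dom <- extract_domain(prot)
  expect_equal(nchar(dom), 72)
  expect_equal(dom, substr(prot, 51, 122))
  expect_equal(extract_domain(prot, 1, nchar(prot)), prot)
  short <- substr(prot, 1, 71)
  expect_error(extract_domain(short), class = "out_of_range")
})

test_that("p_distance counts mismatches over comparable columns", {
  expect_equal(unname(p_distance(c(a = "AAAA", b = "AAAA"))["a", "b"]), 0)
  expect_equal(unname(p_distance(c(a = "AAAA", b = "AAAT"))["a", "b"]), 0.25)
  # gap columns are excluded from the denominator
  expect_equal(unname(p_distance(c(a = "A-AA", b = "ATAA"))["a", "b"]), 0)
  d <- p_distance(c(x = "ARND", y = "ARNC", z = "DRNA"))
  expect_true(isSymmetric(d))
  expect_equal(unname(diag(d)), c(0, 0, 0))
  expect_error(p_distance(c(a = "A---", b = "-AAA")),
               class = "incomparable_pair")
  expect_error(p_distance(c(a = "AA")), class = "invalid_input")
  # poisson correction is -log(1 - p)
  expect_equal(unname(p_distance(c(a = "AAAA", b = "AAAT"),
                                 correction = "poisson")["a", "b"]),
               -log(0.75))
})

test_that("neighbor_joining solves the 3-taxon closed form", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("a", "b", "c"))
  # three-point formulas: la = (dab + dac - dbc)/2 = 1, lb = 2, lc = 3
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[c("a", "b", "c")], c(a = 1, b = 2, c = 3))
  expect_error(neighbor_joining(d[1:2, 1:2]), class = "insufficient_taxa")
  bad <- d; bad[1, 2] <- 99
  expect_error(neighbor_joining(bad), class = "invalid_input")
})

test_that("NJ recovers the 4-taxon additive tree exactly", {
  tr0 <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):1);")
  d <- ape::cophenetic.phylo(tr0)
  tr <- neighbor_joining(d)
  expect_true("C,D" %in% phylo_splits(tr))  # the AB|CD split
  got <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_equal(got, d, tolerance = 1e-12)
  # least-squares oracle over all 3 topologies agrees
  rss <- vapply(all_topologies(4), function(tp)
    topo_ls_rss(tp$edges, d[sort(rownames(d)), sort(colnames(d))]),
    numeric(1))
  best <- all_topologies(4)[[which.min(rss)]]
  expect_identical(topo_splits(best$edges, sort(rownames(d))),
                   phylo_splits(tr))
})

test_that("NJ is consistent on random additive matrices (5 taxa, LS oracle)", {
  for (s in 1:20) {
    am <- random_additive_matrix(5, seed = 400 + s)
    tr <- neighbor_joining(am$d)
    got <- ape::cophenetic.phylo(tr)[rownames(am$d), colnames(am$d)]
    expect_equal(got, am$d, tolerance = 1e-9)
    labs <- sort(rownames(am$d))
    dd <- am$d[labs, labs]
    rss <- vapply(all_topologies(5), function(tp) topo_ls_rss(tp$edges, dd),
                  numeric(1))
    best <- all_topologies(5)[[which.min(rss)]]
    expect_identical(topo_splits(best$edges, labs), phylo_splits(tr))
  }
})

test_that("bootstrap supports: perfect signal, determinism, range", {
  # every column separates {A,B} from {C,D}: support must be 100
  msa <- c(A = "AAAAAAAAAA", B = "AAAAAAAAAA",
           C = "CCCCCCCCCC", D = "CCCCCCCCCC")
  tr <- bootstrap_tree(msa, n_replicates = 50, seed = 1)
  sup <- attr(tr, "support")
  expect_equal(nrow(sup), 1)
  expect_equal(sup$support, 100)

  aln <- evolve_alignment(
    ape::read.tree(text = "((A:0.1,B:0.1):0.5,(C:0.1,D:0.1):0.1);"),
    150, seed = 5)
  t1 <- bootstrap_tree(aln, n_replicates = 40, seed = 9)
  t2 <- bootstrap_tree(aln, n_replicates = 40, seed = 9)
  expect_identical(write_newick(t1), write_newick(t2))
  s <- attr(t1, "support")$support
  expect_true(all(s >= 0 & s <= 100))

  expect_error(bootstrap_tree(msa[1:3], 10), class = "insufficient_taxa")
  expect_error(bootstrap_tree(c(A = "A", B = "A", C = "C", D = "C"), 10),
               class = "insufficient_data")
})

test_that("newick round trips preserve topology, lengths and supports", {
  s <- "(A:1,B:2,(C:3,D:4):1);"
  tr <- read_newick(s)
  expect_equal(length(tr$tip.label), 4)
  expect_equal(tr$Nnode, 2)  # basal trifurcation + one internal edge
  expect_equal(write_newick(tr), s)

  # 50 random trees: write/read preserves splits and branch lengths
  set.seed(13)
  for (k in 1:50) {
    n <- sample(4:10, 1)
    tr0 <- ape::unroot(ape::rtree(n))
    tr0$edge.length <- round(runif(nrow(tr0$edge), 0.01, 2), 6)
    tr1 <- read_newick(write_newick(tr0))
    expect_identical(phylo_splits(tr1), phylo_splits(tr0))
    d0 <- ape::cophenetic.phylo(tr0)
    d1 <- ape::cophenetic.phylo(tr1)[rownames(d0), colnames(d0)]
    expect_equal(d1, d0, tolerance = 1e-9)
  }

  # supports survive the round trip as node labels
  msa <- c(A = "AAAAAAAAAA", B = "AAAAAAAAAA",
           C = "CCCCCCCCCC", D = "CCCCCCCCCC")
  bt <- bootstrap_tree(msa, n_replicates = 20, seed = 2)
  rt <- read_newick(write_newick(bt))
  expect_true("100" %in% rt$node.label)

  # malformed strings: classed errors naming a position
  expect_error(read_newick("(A,B))C;"), class = "parse_error")
  expect_error(read_newick("((A,B),C"), class = "parse_error")
  err <- tryCatch(read_newick("(A,B))C;"), error = function(e) conditionMessage(e))
  expect_match(err, "position")
})
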