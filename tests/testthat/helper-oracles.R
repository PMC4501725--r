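# Independent oracles used by the unit and acceptance tests.  Everything here
# is deliberately brute-force and shares no code with the package internals.

# score an explicit alignment (moves: M = both, X = residue of a vs gap,
# Y = residue of b vs gap) under affine gap costs: a maximal gap run of
# length k costs gap_open + k * gap_extend, and switching gap sides reopens.
oracle_move_score <- function(a, b, moves, scoring) {
  i <- 0L; j <- 0L; s <- 0
  run <- ""
  for (mv in moves) {
    if (mv == "M") {
      i <- i + 1L; j <- j + 1L
      s <- s + scoring$sub[substr(a, i, i), substr(b, j, j)]
      run <- ""
    } else {
      if (mv != run) s <- s - scoring$gap_open
      s <- s - scoring$gap_extend
      run <- mv
      if (mv == "X") i <- i + 1L else j <- j + 1L
    }
  }
  s
}

# exhaustive enumeration of every global alignment
oracle_global_score <- function(a, b, scoring) {
  na <- nchar(a); nb <- nchar(b)
  best <- -Inf
  rec <- function(i, j, moves) {
    if (i == na && j == nb) {
      best <<- max(best, oracle_move_score(a, b, moves, scoring))
      return(invisible(NULL))
    }
    if (i < na && j < nb) rec(i + 1L, j + 1L, c(moves, "M"))
    if (i < na) rec(i + 1L, j, c(moves, "X"))
    if (j < nb) rec(i, j + 1L, c(moves, "Y"))
  }
  rec(0L, 0L, character(0))
  best
}

# a local alignment is a global alignment of some substring pair (or empty)
oracle_local_score <- function(a, b, scoring) {
  best <- 0
  for (i1 in seq_len(nchar(a))) for (i2 in i1:nchar(a))
    for (j1 in seq_len(nchar(b))) for (j2 in j1:nchar(b))
      best <- max(best, oracle_global_score(substr(a, i1, i2),
                                            substr(b, j1, j2), scoring))
  best
}

random_peptide <- function(len, alphabet = c("A", "C", "D", "E")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# ---- exhaustive unrooted topologies and least-squares fits -----------------

# all unrooted binary topologies on n labelled tips, as (node1, node2) edge
# matrices; tips are 1..n, internals n+1, n+2, ...
all_topologies <- function(n) {
  base <- list(edges = rbind(c(1L, n + 1L), c(2L, n + 1L), c(3L, n + 1L)),
               next_id = n + 2L)
  trees <- list(base)
  if (n < 4) return(trees)
  for (k in 4:n) {
    out <- list()
    for (tr in trees) {
      for (e in seq_len(nrow(tr$edges))) {
        ed <- tr$edges
        v <- tr$next_id
        b <- ed[e, 2]
        ed[e, 2] <- v
        ed <- rbind(ed, c(v, b), c(as.integer(k), v))
        out[[length(out) + 1L]] <- list(edges = ed, next_id = v + 1L)
      }
    }
    trees <- out
  }
  trees
}

# edge indices on the path between two tips (BFS over the edge list)
topo_path <- function(edges, from, to) {
  nmax <- max(edges)
  prev_edge <- rep(NA_integer_, nmax)
  prev_node <- rep(NA_integer_, nmax)
  seen <- rep(FALSE, nmax)
  seen[from] <- TRUE
  queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (v == to) break
    for (e in seq_len(nrow(edges))) {
      w <- if (edges[e, 1] == v) edges[e, 2]
           else if (edges[e, 2] == v) edges[e, 1] else next
      if (!seen[w]) {
        seen[w] <- TRUE
        prev_edge[w] <- e; prev_node[w] <- v
        queue <- c(queue, w)
      }
    }
  }
  path <- integer(0)
  v <- to
  while (v != from) { path <- c(path, prev_edge[v]); v <- prev_node[v] }
  path
}

# least-squares branch fit of a topology to a distance matrix; returns RSS
topo_ls_rss <- function(edges, d) {
  n <- nrow(d)
  pairs <- t(combn(n, 2))
  A <- matrix(0, nrow(pairs), nrow(edges))
  y <- numeric(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    A[r, topo_path(edges, pairs[r, 1], pairs[r, 2])] <- 1
    y[r] <- d[pairs[r, 1], pairs[r, 2]]
  }
  fit <- qr.solve(qr(A), y)
  sum((A %*% fit - y)^2)
}

# non-trivial bipartitions of a topology edge list, as canonical keys over
# tip labels
topo_splits <- function(edges, labels) {
  n <- length(labels)
  keys <- character(0)
  for (e in seq_len(nrow(edges))) {
    if (edges[e, 1] <= n || edges[e, 2] <= n) next  # pendant edge
    sub <- edges[-e, , drop = FALSE]
    # component containing edges[e, 1]
    comp <- edges[e, 1]
    repeat {
      grow <- unique(c(sub[sub[, 1] %in% comp, 2], sub[sub[, 2] %in% comp, 1]))
      add <- setdiff(grow, comp)
      if (!length(add)) break
      comp <- c(comp, add)
    }
    clade <- sort(labels[comp[comp <= n]])
    keys <- c(keys, canonical_split(clade, labels))
  }
  sort(keys)
}

canonical_split <- function(clade, labels) {
  all_sorted <- sort(labels)
  side <- if (all_sorted[1] %in% clade) setdiff(all_sorted, clade)
          else sort(clade)
  paste(side, collapse = ",")
}

# non-trivial bipartitions of an ape phylo tree (independent of the package's
# internal split code)
phylo_splits <- function(tree) {
  n <- length(tree$tip.label)
  parts <- ape::prop.part(tree)
  keys <- character(0)
  for (p in parts) {
    if (length(p) < 2 || length(p) > n - 2) next
    keys <- c(keys, canonical_split(sort(tree$tip.label[p]), tree$tip.label))
  }
  sort(unique(keys))
}

# random additive (tree-metric) matrix: random unrooted topology with
# uniform branch lengths well away from zero
random_additive_matrix <- function(n, seed) {
  set.seed(seed)
  tr <- ape::unroot(ape::rtree(n, br = NULL))
  tr$edge.length <- runif(nrow(tr$edge), 0.2, 1.5)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# ---- fast simulated dosage datasets ---------------------------------------

# reference world with short proteins (sequence content is irrelevant to the
# count model); reused across count replicates
quick_ref <- function(n_chromosomes, genes_per_chromosome, seed = 1,
                      d = 1, f = 2, male_fraction = 0.5, dispersion = 0.05,
                      library_size = 1e6) {
  des <- sim_design(n_chromosomes = n_chromosomes,
                    genes_per_chromosome = genes_per_chromosome,
                    male_fraction = male_fraction, f = f, d = d,
                    dispersion = dispersion, library_size = library_size,
                    protein_length = 10, mutation_rate = 0, seed = seed)
  list(design = des, ref = simulate_reference(des))
}

# one infected-vs-uninfected ratio table at 48 hpo from a quick_ref world
quick_ratio_table <- function(world, f, seed, center = TRUE) {
  inf <- simulate_pool_counts(world$design, world$ref, infected = TRUE,
                              timepoint = 48, f = f, seed = seed)
  un <- simulate_pool_counts(world$design, world$ref, infected = FALSE,
                             timepoint = 48, seed = seed + 5e8)
  counts <- cbind(inf = inf$counts, uninf = un$counts)
  cpm <- normalize_cpm(counts)
  compute_ratios(cpm, "inf", "uninf",
                 chromosomes = setNames(world$ref$truth$chromosome,
                                        world$ref$truth$contig_id),
                 center = center)
}
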