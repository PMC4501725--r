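#' Extract the zinc-finger domain window from a protein
#'
#' 1-based inclusive coordinates; the default window (residues 51-122, 72
#' residues) is the tandem CCCH zinc-finger block used to relate Masc family
#' members across species.
#'
#' @param protein Protein sequence (string), length `>= window_end`.
#' @param window_start,window_end 1-based inclusive bounds.
#' @return The subsequence.
#' @examples
#' nchar(extract_domain(paste(rep("A", 200), collapse = "")))  # 72
#' @export
extract_domain <- function(protein, window_start = 51, window_end = 122) {
  abort_if(window_start < 1 || window_end < window_start,
           "need 1 <= window_start <= window_end", class = "out_of_range")
  abort_if(nchar(protein) < window_end,
           "protein has ", nchar(protein), " residues; window ends at ",
           window_end, class = "out_of_range")
  substr(protein, window_start, window_end)
}

msa_char_matrix <- function(msa) {
  abort_if(length(msa) < 2, "need at least 2 taxa", class = "invalid_input")
  abort_if(is.null(names(msa)) || anyDuplicated(names(msa)) > 0,
           "alignment rows need unique names", class = "invalid_input")
  lens <- nchar(msa)
  abort_if(length(unique(lens)) != 1, "alignment rows differ in length",
           class = "invalid_input")
  m <- do.call(rbind, strsplit(toupper(msa), ""))
  rownames(m) <- names(msa)
  m
}

p_distance_mat <- function(cm, correction = "none") {
  n <- nrow(cm)
  d <- matrix(0, n, n, dimnames = list(rownames(cm), rownames(cm)))
  ok <- cm != "-"
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- ok[i, ] & ok[j, ]
      abort_if(!any(comp), "no comparable columns between ", rownames(cm)[i],
               " and ", rownames(cm)[j], class = "incomparable_pair")
      p <- sum(cm[i, comp] != cm[j, comp]) / sum(comp)
      if (correction == "poisson") {
        abort_if(p >= 1, "Poisson correction undefined at p = 1 for pair ",
                 rownames(cm)[i], "/", rownames(cm)[j],
                 class = "incomparable_pair")
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Pairwise p-distances of an aligned protein block
#'
#' `d(i, j)` is the proportion of mismatches over columns where neither row
#' is a gap (`-`).  The uncorrected p-distance is the default; a Poisson
#' correction `-log(1 - p)` for multiple hits is available.
#'
#' @param msa Named character vector of equal-length aligned sequences.
#' @param correction `"none"` or `"poisson"`.
#' @return Symmetric numeric matrix with zero diagonal.
#' @examples
#' p_distance(c(a = "AAAA", b = "AAAT"))["a", "b"]  # 0.25
#' @export
p_distance <- function(msa, correction = c("none", "poisson")) {
  correction <- match.arg(correction)
  p_distance_mat(msa_char_matrix(msa), correction)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration on the Q criterion.  Determinism rules: ties in
#' Q are broken by the smallest (row, column) index pair; negative branch
#' length estimates are clamped to zero with the deficit moved to the sister
#' branch so the joined distance is preserved.  On additive distance
#' matrices the tree's path lengths reproduce the input exactly.
#'
#' @param d Symmetric distance matrix (or `dist`) with labels, `>= 3` taxa.
#' @return An unrooted `ape::phylo` tree (basal trifurcation).
#' @examples
#' d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
#'             dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
#' neighbor_joining(d)
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  abort_if(!is.matrix(d) || is.null(rownames(d)),
           "d must be a labelled matrix or dist", class = "invalid_input")
  n <- nrow(d)
  abort_if(n < 3, "need at least 3 taxa", class = "insufficient_taxa")
  abort_if(any(!is.finite(d)) || any(d < 0) || any(abs(d - t(d)) > 1e-12) ||
             any(abs(diag(d)) > 1e-12),
           "d must be symmetric, non-negative, with zero diagonal",
           class = "invalid_input")
  labels <- rownames(d)

  active <- seq_len(n)            # node ids of current rows
  next_id <- n + 1L
  edges <- list()
  D <- d
  while (length(active) > 3) {
    r <- nrow(D)
    Rs <- rowSums(D)
    Q <- (r - 2) * D - outer(Rs, Rs, `+`)
    diag(Q) <- Inf
    hits <- which(Q == min(Q), arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    li <- D[i, j] / 2 + (Rs[i] - Rs[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- D[i, j]; li <- 0 }
    if (lj < 0) { li <- D[i, j]; lj <- 0 }
    u <- next_id; next_id <- next_id + 1L
    edges[[length(edges) + 1L]] <- c(u, active[i], li)
    edges[[length(edges) + 1L]] <- c(u, active[j], lj)
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    active <- c(active[keep], u)
  }
  # resolve the final three nodes around one internal vertex
  u <- next_id
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  ls <- pmax(c(l1, l2, l3), 0)
  for (k in 1:3)
    edges[[length(edges) + 1L]] <- c(u, active[k], ls[k])

  edge_mat <- do.call(rbind, edges)
  build_phylo(edge_mat, labels, n_tips = n, root_id = u)
}

# Convert an (parent, child, length) edge list over arbitrary node ids into
# an ape phylo object rooted (for numbering only) at root_id.
build_phylo <- function(edge_mat, labels, n_tips, root_id) {
  # adjacency by node id
  nodes <- sort(unique(as.integer(edge_mat[, 1:2])))
  adj <- lapply(setNames(vector("list", length(nodes)), nodes), identity)
  for (k in seq_len(nrow(edge_mat))) {
    a <- as.character(edge_mat[k, 1]); b <- as.character(edge_mat[k, 2])
    adj[[a]] <- c(adj[[a]], k)
    adj[[b]] <- c(adj[[b]], k)
  }
  new_id <- integer(max(nodes))
  new_id[seq_len(n_tips)] <- seq_len(n_tips)
  next_internal <- n_tips + 1L

  parent <- integer(0); child <- integer(0); elen <- numeric(0)
  # iterative DFS
  stack <- list(list(node = root_id, from_edge = NA_integer_))
  while (length(stack) > 0) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    if (node > n_tips) {
      new_id[node] <- next_internal
      next_internal <- next_internal + 1L
    }
    ks <- adj[[as.character(node)]]
    ks <- ks[is.na(top$from_edge) | ks != top$from_edge]
    # push in reverse so traversal is in edge-creation order
    for (k in rev(ks)) {
      other <- as.integer(edge_mat[k, 1:2])
      other <- other[other != node]
      parent <- c(parent, node); child <- c(child, other)
      elen <- c(elen, edge_mat[k, 3])
      stack[[length(stack) + 1L]] <- list(node = other, from_edge = k)
    }
  }
  edge <- cbind(new_id[parent], new_id[child])
  stopifnot(all(edge > 0L))
  tree <- list(edge = edge, edge.length = elen, tip.label = labels,
               Nnode = max(new_id) - n_tips)
  class(tree) <- "phylo"
  attr(tree, "order") <- NULL
  ape::reorder.phylo(tree, "cladewise")
}

# canonical bipartition keys for every internal edge of an unrooted tree
tree_splits <- function(tree) {
  n <- length(tree$tip.label)
  all_labels <- sort(tree$tip.label)
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- tree$tip.label[i]
  post <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(post$edge))) {
    par <- post$edge[k, 1]; chd <- post$edge[k, 2]
    desc[[par]] <- c(desc[[par]], desc[[chd]])
  }
  keys <- character(0)
  nodes <- integer(0)
  for (k in seq_len(nrow(tree$edge))) {
    chd <- tree$edge[k, 2]
    if (chd <= n) next
    clade <- sort(desc[[chd]])
    side <- if (all_labels[1] %in% clade) setdiff(all_labels, clade) else clade
    if (length(side) < 2 || length(side) > n - 2) next
    keys <- c(keys, paste(side, collapse = "\r"))
    nodes <- c(nodes, chd)
  }
  list(keys = keys, nodes = nodes)
}

#' Neighbor-joining tree with column-resampling bootstrap supports
#'
#' Builds the NJ tree from the full alignment, then resamples alignment
#' columns with replacement `n_replicates` times, rebuilds the tree each
#' time, and reports for every internal split of the full-data tree the
#' percentage of replicate trees containing it.  Supports are stored as node
#' labels of the returned tree (the ape convention, so they survive newick
#' round trips).
#'
#' @param msa Named character vector of aligned sequences, `>= 4` taxa,
#'   `>= 2` columns.
#' @param n_replicates Bootstrap replicates (`>= 1`; 1000 is the
#'   conventional choice).
#' @param seed Optional seed.
#' @param correction Distance correction, see [p_distance()].
#' @return An `ape::phylo` tree whose `node.label` holds bootstrap
#'   percentages (empty at the basal trifurcation), with a `support` table
#'   (`split`, `support`) attached as an attribute.
#' @export
bootstrap_tree <- function(msa, n_replicates = 1000, seed = NULL,
                           correction = c("none", "poisson")) {
  correction <- match.arg(correction)
  abort_if(length(msa) < 4, "need at least 4 taxa", class = "insufficient_taxa")
  cm <- msa_char_matrix(msa)
  abort_if(ncol(cm) < 2, "alignment has fewer than 2 columns",
           class = "insufficient_data")
  abort_if(n_replicates < 1, "n_replicates must be >= 1",
           class = "invalid_design")
  full <- neighbor_joining(p_distance_mat(cm, correction))
  sp <- tree_splits(full)
  counts <- setNames(numeric(length(sp$keys)), sp$keys)
  with_seed(seed, {
    for (b in seq_len(n_replicates)) {
      idx <- sample.int(ncol(cm), ncol(cm), replace = TRUE)
      rt <- neighbor_joining(p_distance_mat(cm[, idx, drop = FALSE],
                                            correction))
      rk <- tree_splits(rt)$keys
      hit <- sp$keys %in% rk
      counts[hit] <- counts[hit] + 1
    }
  })
  support <- 100 * counts / n_replicates
  n <- length(full$tip.label)
  labs <- rep("", full$Nnode)
  labs[sp$nodes - n] <- format(support, trim = TRUE, digits = 4)
  full$node.label <- labs
  attr(full, "support") <- data.frame(
    split = gsub("\r", ",", sp$keys), support = unname(support),
    stringsAsFactors = FALSE)
  full
}

#' Write / read trees in newick format
#'
#' Thin, validated wrappers around ape's newick serializer.  `read_newick`
#' pre-checks bracket balance and reports the 1-based character position of
#' the first imbalance before handing off to the parser.
#'
#' @param tree An `ape::phylo` object.
#' @param path Optional file path; if `NULL`, `write_newick` returns the
#'   string.
#' @return `write_newick`: the newick string (invisibly when writing to a
#'   file). `read_newick`: an `ape::phylo` tree.
#' @export
write_newick <- function(tree, path = NULL) {
  abort_if(!inherits(tree, "phylo"), "tree must be an ape phylo object",
           class = "invalid_input")
  s <- ape::write.tree(tree)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' @param x A newick string, or a path to a file containing one.
#' @rdname write_newick
#' @export
read_newick <- function(x) {
  s <- if (length(x) == 1 && !grepl("(", x, fixed = TRUE) && file.exists(x))
    paste(readLines(x, warn = FALSE), collapse = "") else x
  chars <- strsplit(s, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    abort_if(depth < 0, "unbalanced ')' at position ", i, class = "parse_error")
  }
  abort_if(depth != 0, "unclosed '(' (", depth, " open) at position ",
           length(chars), class = "parse_error")
  abort_if(!grepl(";\\s*$", s), "newick string must end with ';' at position ",
           nchar(s), class = "parse_error")
  tr <- tryCatch(ape::read.tree(text = s), error = function(e) NULL,
                 warning = function(w) NULL)
  abort_if(is.null(tr), "newick parse failed", class = "parse_error")
  tr
}
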