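# Independent oracles and small fixture builders used across the suite.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
NT4 <- c("A", "C", "G", "T")

random_protein <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_dna <- function(n) paste(sample(NT4, n, replace = TRUE), collapse = "")

# ---- quadratic affine-gap Smith-Waterman oracle (Gotoh) ------------------
# Independent of Biostrings: plain R dynamic programming over three
# matrices; gap of length k costs gap_open + k * gap_extend.
sw_oracle <- function(a, b, mat, gap_open, gap_extend) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (vertical)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a (horizontal)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                             X[i, j + 1] - gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                             Y[i + 1, j] - gap_extend)
      s <- mat[av[i], bv[j]]
      M[i + 1, j + 1] <- max(0,
                             s + max(M[i, j], X[i, j], Y[i, j]))
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# ---- brute-force Robinson-Foulds oracle ----------------------------------
# Enumerates non-trivial bipartitions by deleting each internal edge and
# flood-filling the resulting components over the tree's edge list.
tree_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  edges <- tree$edge
  keys <- character(0)
  adj <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
  for (e in seq_len(nrow(edges))) {
    u <- edges[e, 1]; v <- edges[e, 2]
    # flood fill from v without crossing edge (u, v)
    seen <- v
    queue <- v
    while (length(queue) > 0) {
      x <- queue[1]; queue <- queue[-1]
      for (y in adj[[as.character(x)]]) {
        if (y %in% seen) next
        if ((x == u && y == v) || (x == v && y == u)) next
        if (x == v && y == u) next
        seen <- c(seen, y)
        queue <- c(queue, y)
      }
    }
    seen <- setdiff(seen, u)
    side <- sort(tree$tip.label[seen[seen <= ntip]])
    if (length(side) < 2 || length(side) > ntip - 2) next
    anchor <- min(tree$tip.label)
    if (!(anchor %in% side)) {
      side <- sort(setdiff(tree$tip.label, side))
    }
    keys <- c(keys, paste(side, collapse = "|"))
  }
  unique(keys)
}

rf_oracle <- function(t1, t2) {
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# ---- misc ----------------------------------------------------------------
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

random_additive_tree <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.1, 2)
  tr
}

write_temp_fasta <- function(lines) {
  tf <- tempfile(fileext = ".fasta")
  writeLines(lines, tf)
  tf
}

small_sim_config <- function(seed = 1, ...) {
  args <- list(seed = seed, n_hosts = 3, host_len = 20000, n_clades = 3,
               genomes_per_clade = 4, genome_len = 12000, n_core_genes = 5,
               n_flexible_genes = 4, n_reads = 300, read_len = 120)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}
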