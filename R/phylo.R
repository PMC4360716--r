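# Distance-based tree inference with bootstrap support, support-based
# collapsing, outgroup rooting, clade delineation, Robinson-Foulds
# distance, and the leaf-permutation concordance test.
#
# Trees are ape "phylo" objects; integer bootstrap supports (0-100) ride
# on internal nodes as node labels, which is also how they are serialised
# to Newick.

#' Pairwise p-distance matrix of an alignment
#'
#' `d(i, j)` is the fraction of mismatching columns among the columns
#' where both rows are non-gap.  Pairs with no shared columns get
#' distance 1 and are listed in attribute `no_overlap`.
#'
#' @param msa An `msa` with at least two rows.
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(msa) {
  if (length(msa) < 2) abort("need at least two rows")
  m <- as.matrix.msa(msa)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  flagged <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(both)) {
        D[i, j] <- D[j, i] <- 1
        flagged <- c(flagged, paste(rownames(m)[c(i, j)], collapse = "|"))
      } else {
        D[i, j] <- D[j, i] <- mean(m[i, both] != m[j, both])
      }
    }
  }
  attr(D, "no_overlap") <- flagged
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (Saitou & Nei) on a symmetric distance
#' matrix; negative branch lengths are clamped to zero.
#'
#' @param D Symmetric matrix with zero diagonal and at least 3 taxa.
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3) abort("neighbor joining needs at least 3 taxa")
  if (max(abs(D - t(D))) > 1e-9 || any(diag(D) != 0)) {
    abort("distance matrix must be symmetric with zero diagonal")
  }
  tr <- ape::nj(D)
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

msa_tree <- function(msa) neighbor_joining(p_distance_matrix(msa))

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement `n_reps` times, rebuilds
#' the NJ tree for each replicate, and labels each internal edge of the
#' full-data tree with the percentage of replicate trees containing the
#' same bipartition.  Deterministic under `seed`.
#'
#' @param msa An `msa`.
#' @param n_reps Number of bootstrap replicates (> 0).
#' @param seed Integer seed.
#' @return The NJ tree with integer supports in `$node.label`.
#' @export
bootstrap_support <- function(msa, n_reps = 100, seed = 1) {
  if (n_reps <= 0) abort("n_reps must be positive")
  base <- msa_tree(msa)
  m <- as.matrix.msa(msa)
  set.seed(seed)
  reps <- purrr::map(seq_len(n_reps), function(i) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    sub <- new_msa(setNames(apply(m[, cols, drop = FALSE], 1, paste,
                                  collapse = ""), rownames(m)))
    msa_tree(sub)
  })
  counts <- ape::prop.clades(base, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  base$node.label <- as.character(as.integer(round(100 * counts / n_reps)))
  base
}

node_supports <- function(tree) {
  if (is.null(tree$node.label)) abort("tree has no support values")
  suppressWarnings(as.numeric(tree$node.label))
}

#' Collapse poorly supported branches
#'
#' Contracts internal edges whose bootstrap support is strictly below
#' `threshold` into polytomies; edges with support equal to or above the
#' threshold are kept.  Implementation note: low-support internal edge
#' lengths are zeroed and zero-length dichotomies collapsed, so retained
#' edge lengths shorter than 1e-8 are raised to 1e-8 first.
#'
#' @param tree A `phylo` with supports in `$node.label`.
#' @param threshold Support threshold (support `< threshold` collapses).
#' @return A `phylo`, possibly multifurcating; leaf set unchanged.
#' @export
collapse_low_support <- function(tree, threshold = 50) {
  sup <- node_supports(tree)
  ntip <- length(tree$tip.label)
  if (is.null(tree$edge.length)) tree$edge.length <- rep(1, nrow(tree$edge))
  el <- pmax(tree$edge.length, 1e-8)
  is_int <- tree$edge[, 2] > ntip
  child_node <- tree$edge[is_int, 2] - ntip
  low <- !is.na(sup[child_node]) & sup[child_node] < threshold
  el[which(is_int)[low]] <- 0
  tree$edge.length <- el
  ape::di2multi(tree, tol = 1e-9)
}

#' Root a tree with an outgroup
#'
#' Places the root on the edge separating the outgroup from the ingroup,
#' at the midpoint of that edge.  The outgroup must be monophyletic in
#' the unrooted tree.
#'
#' @param tree An unrooted `phylo`.
#' @param outgroup_ids Tip labels of the outgroup.
#' @return A rooted `phylo`.
#' @export
root_with_outgroup <- function(tree, outgroup_ids) {
  missing_tips <- setdiff(outgroup_ids, tree$tip.label)
  if (length(missing_tips) > 0) {
    abort(paste0("outgroup tips not in tree: ",
                 paste(missing_tips, collapse = ", ")))
  }
  if (length(outgroup_ids) < length(tree$tip.label) &&
      !ape::is.monophyletic(tree, outgroup_ids)) {
    abort(paste0("outgroup is not monophyletic: ",
                 paste(outgroup_ids, collapse = ", ")))
  }
  rt <- ape::root(tree, outgroup = outgroup_ids, resolve.root = TRUE,
                  edgelabel = TRUE)
  if (!is.null(rt$edge.length)) {
    ntip <- length(rt$tip.label)
    root_node <- ntip + 1L
    kids <- which(rt$edge[, 1] == root_node)
    if (length(kids) == 2) {
      total <- sum(rt$edge.length[kids])
      rt$edge.length[kids] <- total / 2
    }
  }
  rt
}

#' Delineate supported clades of query leaves
#'
#' Finds the maximal rooted subtrees whose support is at least
#' `min_support`, whose leaves all belong to `query_ids`, and which
#' contain at least two leaves.  Remaining query leaves are reported as
#' unassigned.  Clade ids are assigned in preorder, so they are
#' deterministic for a given tree.
#'
#' @param rooted_tree A rooted `phylo` with supports in `$node.label`.
#' @param query_ids Tip labels eligible for clade membership.
#' @param min_support Minimum bootstrap support.
#' @return A tibble with columns `leaf` and `clade_id`
#'   (`"clade_01" ...` or `"unassigned"`).
#' @export
delineate_clades <- function(rooted_tree, query_ids, min_support = 80) {
  sup <- node_supports(rooted_tree)
  ntip <- length(rooted_tree$tip.label)
  tips_under <- function(node) {
    if (node <= ntip) return(rooted_tree$tip.label[node])
    kids <- rooted_tree$edge[rooted_tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_under))
  }
  assigned <- character(0)
  clades <- list()
  preorder <- function(node) {
    if (node <= ntip) return(invisible())
    tips <- tips_under(node)
    s <- sup[node - ntip]
    if (node != ntip + 1L && !is.na(s) && s >= min_support &&
        length(tips) >= 2 && all(tips %in% query_ids) &&
        !any(tips %in% assigned)) {
      clades[[length(clades) + 1]] <<- tips
      assigned <<- c(assigned, tips)
      return(invisible())  # maximal: do not descend
    }
    kids <- rooted_tree$edge[rooted_tree$edge[, 1] == node, 2]
    for (k in kids) preorder(k)
    invisible()
  }
  preorder(ntip + 1L)
  out <- purrr::imap(clades, function(tips, i) {
    tibble(leaf = tips, clade_id = sprintf("clade_%02d", i))
  }) |> bind_rows()
  if (nrow(out) == 0) out <- tibble(leaf = character(0),
                                    clade_id = character(0))
  left_out <- setdiff(intersect(query_ids, rooted_tree$tip.label),
                      out$leaf)
  bind_rows(out, tibble(leaf = left_out, clade_id = "unassigned")) |>
    arrange(.data$clade_id, .data$leaf)
}

#' Robinson-Foulds distance between two trees
#'
#' The symmetric-difference count of non-trivial bipartitions of the
#' unrooted topologies.  Trees with different leaf sets are restricted to
#' the common leaves first (recorded in attribute `n_common`).
#'
#' @param t1,t2 `phylo` trees.
#' @return Integer RF distance with attribute `n_common`.
#' @export
rf_distance <- function(t1, t2) {
  common <- intersect(t1$tip.label, t2$tip.label)
  if (length(common) < 4) abort("need at least 4 common leaves")
  p1 <- ape::unroot(ape::keep.tip(t1, common))
  p2 <- ape::unroot(ape::keep.tip(t2, common))
  d <- as.integer(phangorn::RF.dist(p1, p2, check.labels = TRUE))
  attr(d, "n_common") <- length(common)
  d
}

#' Leaf-permutation test of tree concordance
#'
#' Tests whether two tree topologies are more similar than expected for
#' random leaf labellings: the null distribution is the RF distance
#' between `t1` and `t2` with `t2`'s leaf labels uniformly permuted.
#' Reports the empirical p-value
#' `(1 + #(null <= observed)) / (n_perm + 1)` (bounded below by
#' `1/(n_perm+1)`), the lower-tail normal-approximation p-value from the
#' null mean and standard deviation, and a tie-randomized empirical
#' p-value `(1 + #(null < observed) + U * #(null == observed)) /
#' (n_perm + 1)` with `U` uniform on `[0, 1]`.  The RF statistic is
#' discrete with heavy ties, so `p_empirical` is conservative
#' (super-uniform) under the null while `p_randomized` is exactly
#' uniform; the latter is the quantity to use for calibration checks.
#'
#' @param t1,t2 `phylo` trees with at least 4 common leaves.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return An object of class `rf_permutation` with fields
#'   `observed_rf`, `null_mean`, `null_sd`, `p_empirical`, `p_normal`,
#'   `n_perm`, `seed`, `n_common`.
#' @export
rf_permutation_test <- function(t1, t2, n_perm = 1000, seed = 1) {
  common <- intersect(t1$tip.label, t2$tip.label)
  if (length(common) < 4) abort("need at least 4 common leaves")
  p1 <- ape::unroot(ape::keep.tip(t1, common))
  p2 <- ape::unroot(ape::keep.tip(t2, common))
  obs <- as.integer(phangorn::RF.dist(p1, p2, check.labels = TRUE))
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    perm <- p2
    perm$tip.label <- sample(perm$tip.label)
    phangorn::RF.dist(p1, perm, check.labels = TRUE)
  }, 0)
  mu <- mean(null)
  sdev <- sd(null)
  z <- if (sdev > 0) (obs - mu) / sdev else ifelse(obs < mu, -Inf,
                                                   ifelse(obs > mu, Inf, 0))
  p_rand <- (1 + sum(null < obs) + runif(1) * sum(null == obs)) /
    (n_perm + 1)
  structure(list(observed_rf = obs, null_mean = mu, null_sd = sdev,
                 p_empirical = (1 + sum(null <= obs)) / (n_perm + 1),
                 p_normal = pnorm(z), p_randomized = p_rand,
                 n_perm = n_perm, seed = seed,
                 n_common = length(common)),
            class = "rf_permutation")
}

#' @export
print.rf_permutation <- function(x, ...) {
  cat("RF leaf-permutation concordance test\n")
  cat(sprintf("  observed RF = %d on %d common leaves\n", x$observed_rf,
              x$n_common))
  cat(sprintf("  null mean %.2f (sd %.2f) over %d permutations\n",
              x$null_mean, x$null_sd, x$n_perm))
  cat(sprintf("  p (empirical) = %.4g ; p (normal approx.) = %.4g\n",
              x$p_empirical, x$p_normal))
  invisible(x)
}

#' @rdname rf_permutation_test
#' @param x An `rf_permutation` object.
#' @param ... Unused.
#' @export
tidy.rf_permutation <- function(x, ...) {
  tibble(observed_rf = x$observed_rf, null_mean = x$null_mean,
         null_sd = x$null_sd, p_empirical = x$p_empirical,
         p_normal = x$p_normal, p_randomized = x$p_randomized,
         n_perm = x$n_perm, n_common = x$n_common)
}

#' @rdname rf_permutation_test
#' @export
glance.rf_permutation <- function(x, ...) tidy.rf_permutation(x)

#' Read / write Newick trees with integer supports as node labels
#'
#' @param path File path.
#' @param tree A `phylo`.
#' @return `read_newick()` returns a `phylo`; `write_newick()` returns
#'   `path` invisibly.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, path)
  invisible(path)
}
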