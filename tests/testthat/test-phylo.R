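test_that("p-distances count mismatches over shared non-gap columns", {
  m <- new_msa(c(a = "AAAA", b = "AAAT"))
  D <- p_distance_matrix(m)
  expect_equal(D["a", "b"], 0.25)
  expect_equal(D["a", "a"], 0)

  disjoint <- new_msa(c(a = "AA--", b = "--TT"))
  D2 <- p_distance_matrix(disjoint)
  expect_equal(D2["a", "b"], 1)
  expect_equal(attr(D2, "no_overlap"), "a|b")
})

test_that("neighbor joining recovers additive trees exactly", {
  # all three quartet topologies
  for (nwk in c("((A:1,B:2):1,(C:3,D:4):0);",
                "((A:1,C:2):1,(B:3,D:4):0);",
                "((A:1,D:2):1,(B:3,C:4):0);")) {
    tr <- ape::read.tree(text = nwk)
    D <- ape::cophenetic.phylo(tr)
    nj <- neighbor_joining(D)
    expect_equal(rf_distance(nj, tr), 0, ignore_attr = TRUE)
    expect_equal(ape::cophenetic.phylo(nj)[rownames(D), colnames(D)], D,
                 tolerance = 1e-9)
  }
  expect_error(neighbor_joining(matrix(0, 2, 2)), "at least 3")
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 3), 2, 2)), "at least 3")

  # label-permutation invariance
  tr <- random_additive_tree(6)
  D <- ape::cophenetic.phylo(tr)
  perm <- sample(rownames(D))
  expect_equal(rf_distance(neighbor_joining(D),
                           neighbor_joining(D[perm, perm])), 0,
               ignore_attr = TRUE)
})

test_that("NJ on random additive matrices is exact (property sweep)", {
  set.seed(14)
  for (i in 1:25) {
    tr <- random_additive_tree(sample(4:12, 1))
    D <- ape::cophenetic.phylo(tr)
    nj <- neighbor_joining(D)
    expect_equal(rf_distance(nj, tr), 0, ignore_attr = TRUE)
    expect_lt(max(abs(ape::cophenetic.phylo(nj)[rownames(D), colnames(D)] -
                        D)), 1e-9)
  }
})

clean_msa <- function() {
  # homoplasy-free signal: blocks of identical columns per split
  new_msa(c(s1 = paste0(strrep("A", 40), strrep("C", 20)),
            s2 = paste0(strrep("A", 40), strrep("C", 18), "GG"),
            s3 = paste0(strrep("G", 40), strrep("C", 20)),
            s4 = paste0(strrep("G", 40), strrep("C", 18), "TT"),
            s5 = strrep("T", 60),
            s6 = paste0(strrep("T", 58), "AC")))
}

test_that("bootstrap supports are deterministic and saturate on clean signal", {
  m <- clean_msa()
  b1 <- bootstrap_support(m, n_reps = 60, seed = 2)
  b2 <- bootstrap_support(m, n_reps = 60, seed = 2)
  expect_identical(ape::write.tree(b1), ape::write.tree(b2))
  expect_true(all(as.numeric(b1$node.label) == 100))
  expect_error(bootstrap_support(m, n_reps = 0), "positive")
})

test_that("low-support collapsing contracts exactly the weak edges", {
  b <- bootstrap_support(clean_msa(), n_reps = 50, seed = 1)
  expect_equal(collapse_low_support(b, 50)$Nnode, b$Nnode)

  tr <- ape::read.tree(text = "((A:1,B:1)x:1,(C:1,D:1)y:1);")
  tr <- ape::unroot(tr)
  tr$node.label <- c("", "49")
  star <- collapse_low_support(tr, 50)
  expect_equal(star$Nnode, 1)                 # star tree
  tr$node.label <- c("", "50")
  expect_equal(collapse_low_support(tr, 50)$Nnode, 2)  # exactly 50 retained

  # leaf set never changes; bipartitions only shrink
  set.seed(4)
  for (i in 1:10) {
    t0 <- ape::rtree(8, rooted = FALSE)
    t0$node.label <- as.character(sample(0:100, t0$Nnode, replace = TRUE))
    cl <- collapse_low_support(t0, 70)
    expect_setequal(cl$tip.label, t0$tip.label)
    expect_true(all(tree_bipartitions(cl) %in% tree_bipartitions(t0)))
  }
})

test_that("outgroup rooting places the root on the separating edge midpoint", {
  tr <- ape::read.tree(text = "((A:1,B:1):2,(C:1,D:1):4);")
  tr <- ape::unroot(tr)
  rt <- root_with_outgroup(tr, c("A", "B"))
  expect_true(ape::is.rooted(rt))
  root_edges <- rt$edge.length[rt$edge[, 1] == length(rt$tip.label) + 1L]
  # the original separating edge (2 + 4 after unrooting) is split evenly
  expect_equal(root_edges, c(3, 3), tolerance = 1e-9)

  expect_error(root_with_outgroup(tr, c("A", "C")), "monophyletic")
  single <- root_with_outgroup(tr, "C")
  expect_true(ape::is.rooted(single))
})

test_that("clade delineation respects support, query membership and maximality", {
  # rooted tree with labelled supports
  tr <- ape::read.tree(text = "(((a1,a2)95,(a3,a4)99)90,((b1,b2)85,o1)40)root;")
  qs <- c("a1", "a2", "a3", "a4", "b1", "b2")
  cl <- delineate_clades(tr, qs, min_support = 80)
  # the maximal supported all-query subtree wins over its nested children
  a_clades <- cl$clade_id[cl$leaf %in% c("a1", "a2", "a3", "a4")]
  expect_equal(length(unique(a_clades)), 1)
  expect_false(unique(a_clades) == "unassigned")
  b_clades <- cl$clade_id[cl$leaf %in% c("b1", "b2")]
  expect_equal(length(unique(b_clades)), 1)
  expect_false("o1" %in% cl$leaf)

  lowtr <- tr
  lowtr$node.label <- rep("10", lowtr$Nnode)
  all_un <- delineate_clades(lowtr, qs, min_support = 80)
  expect_true(all(all_un$clade_id == "unassigned"))
})

test_that("RF distance counts bipartition differences like the brute-force oracle", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(rf_distance(t1, t1), 0, ignore_attr = TRUE)
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(rf_distance(t1, t2), 2, ignore_attr = TRUE)

  set.seed(31)
  for (i in 1:30) {
    n <- sample(4:9, 1)
    x <- ape::rtree(n, rooted = FALSE)
    y <- ape::rtree(n, rooted = FALSE)
    y$tip.label <- sample(x$tip.label)
    d <- rf_distance(x, y)
    expect_equal(as.integer(d), rf_oracle(x, y))
    expect_lte(as.integer(d), 2 * (n - 3))
    expect_equal(as.integer(rf_distance(y, x)), as.integer(d))
  }
  expect_error(rf_distance(ape::rtree(3), ape::rtree(3)), "4 common")
})

test_that("the leaf-permutation test bounds, seeds and summaries behave", {
  set.seed(2)
  t1 <- ape::rtree(12, rooted = FALSE)
  res <- rf_permutation_test(t1, t1, n_perm = 199, seed = 7)
  expect_equal(res$observed_rf, 0)
  expect_lte(res$p_empirical, (1 + 0) / 200 + 1e-12)
  expect_gte(res$p_empirical, 1 / 200)

  res2 <- rf_permutation_test(t1, t1, n_perm = 199, seed = 7)
  expect_identical(tidy(res), tidy(res2))

  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("observed_rf", "null_mean", "null_sd", "p_empirical",
                     "p_normal", "p_randomized", "n_perm", "n_common"))
  expect_identical(glance(res), td)
})

test_that("Monte-Carlo null moments are stable across permutation depth", {
  set.seed(3)
  t1 <- ape::rtree(10, rooted = FALSE)
  t2 <- ape::rtree(10, rooted = FALSE)
  t2$tip.label <- sample(t1$tip.label)
  small <- rf_permutation_test(t1, t2, n_perm = 200, seed = 1)
  big <- rf_permutation_test(t1, t2, n_perm = 2000, seed = 2)
  expect_lt(abs(small$null_mean - big$null_mean),
            3 * small$null_sd / sqrt(200) + 3 * big$null_sd / sqrt(2000))
})

test_that("Newick round trip preserves topology and supports", {
  b <- bootstrap_support(clean_msa(), n_reps = 30, seed = 9)
  tf <- tempfile(fileext = ".nwk")
  write_newick(b, tf)
  back <- read_newick(tf)
  expect_equal(rf_distance(back, b), 0, ignore_attr = TRUE)
  expect_setequal(back$node.label, b$node.label)
})
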