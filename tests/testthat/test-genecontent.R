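sch <- scoring_scheme("protein")

make_gene_set <- function(contig, fams, catalogue) {
  tibble::tibble(contig_id = contig, start = 0L, end = 3L,
                 strand = "+",
                 gene_id = paste0(contig, "_", fams),
                 protein = unname(catalogue[fams]),
                 annotation = fams)
}

test_that("shared gene counting and proportions follow the thresholds", {
  set.seed(12)
  catalogue <- setNames(vapply(1:8, function(i) random_protein(150), ""),
                        paste0("f", 1:8))
  a <- setNames(catalogue[c("f1", "f2", "f3", "f4")], paste0("a", 1:4))
  b <- setNames(catalogue[c("f1", "f2", "f5", "f6", "f7")], paste0("b", 1:5))
  expect_equal(shared_gene_count(a, a, sch), 4)     # all self-hit
  expect_equal(shared_gene_count(a, b, sch), 2)
  none <- setNames(vapply(1:3, function(i) random_protein(150), ""),
                   paste0("n", 1:3))
  expect_equal(shared_gene_count(a, none, sch), 0)

  expect_equal(sharing_proportion(4, 10, 8), 0.5)
  expect_equal(sharing_proportion(0, 3, 9), 0)
  expect_error(sharing_proportion(1, 0, 5), "at least one gene")
})

test_that("the sharing matrix is symmetric with unit diagonal and clade signal", {
  set.seed(13)
  catalogue <- setNames(vapply(1:10, function(i) random_protein(140), ""),
                        paste0("f", 1:10))
  # two 'clades' of two contigs: clade I uses f1-f5, clade II f6-f10
  gc <- dplyr::bind_rows(
    make_gene_set("c1", paste0("f", 1:5), catalogue),
    make_gene_set("c2", paste0("f", 1:5), catalogue),
    make_gene_set("c3", paste0("f", 6:10), catalogue),
    make_gene_set("c4", paste0("f", 6:10), catalogue))
  sm <- sharing_matrix(gc, sch)
  expect_equal(sm$proportions, t(sm$proportions))
  expect_equal(unname(diag(sm$proportions)), rep(1, 4))
  expect_true(all(sm$proportions >= 0 & sm$proportions <= 1))
  expect_equal(sm$proportions["c1", "c2"], 1)
  expect_equal(sm$proportions["c1", "c3"], 0)

  expect_s3_class(cluster_contigs(sm), "phylo")
  # two perfect blocks separate at height 1
  h <- stats::hclust(stats::as.dist(1 - sm$proportions), "complete")
  expect_equal(sort(unique(round(h$height, 9))), c(0, 1))

  td <- tidy(sm)
  expect_true(all(c("contig_a", "contig_b", "shared", "proportion") %in%
                    names(td)))
  expect_s3_class(autoplot(sm), "ggplot")
})

test_that("sharing is invariant to contig input order", {
  set.seed(14)
  catalogue <- setNames(vapply(1:6, function(i) random_protein(130), ""),
                        paste0("f", 1:6))
  gc <- dplyr::bind_rows(
    make_gene_set("x", paste0("f", 1:4), catalogue),
    make_gene_set("y", paste0("f", 2:5), catalogue),
    make_gene_set("z", paste0("f", 3:6), catalogue))
  sm1 <- sharing_matrix(gc, sch)
  sm2 <- sharing_matrix(gc[sample(nrow(gc)), ], sch)
  expect_equal(sm1$proportions, sm2$proportions)
})

test_that("duplicate contigs collapse to one representative", {
  seqs <- c(s4m = "ACGTACGTAA", s8m = "ACGTACGTAA", other = "GGGGCCCCAA")
  res <- exclude_duplicates(seqs)
  expect_equal(length(res$kept), 2)
  expect_equal(res$removed$duplicate_id, "s8m")
  expect_equal(res$removed$kept_id, "s4m")

  res2 <- exclude_duplicates(c(a = "AC", b = "GT"))
  expect_equal(length(res2$kept), 2)

  res3 <- exclude_duplicates(c(a = "AAAA", b = "AAAA", c = "AAAA"))
  expect_equal(length(res3$kept), 1)
  expect_equal(nrow(res3$removed), 2)
})

test_that("novelty classes apply reference-over-group precedence", {
  set.seed(15)
  ref_gene <- random_protein(150)
  shared_gene <- random_protein(150)
  unique_gene <- random_protein(150)
  catalogue <- c(ref = ref_gene, shr = shared_gene, unq = unique_gene,
                 shr2 = shared_gene)
  gc <- dplyr::bind_rows(
    tibble::tibble(contig_id = "c1", start = 0L, end = 3L, strand = "+",
                   gene_id = c("c1_ref", "c1_shr", "c1_unq"),
                   protein = c(ref_gene, shared_gene, unique_gene),
                   annotation = NA_character_),
    tibble::tibble(contig_id = "c2", start = 0L, end = 3L, strand = "+",
                   gene_id = "c2_shr", protein = shared_gene,
                   annotation = NA_character_))
  res <- classify_novelty(gc, c(nr1 = ref_gene), sch)
  cls <- setNames(res$genes$class, res$genes$gene_id)
  expect_equal(unname(cls["c1_ref"]), "affiliated_reference")
  expect_equal(unname(cls["c1_shr"]), "group_only")
  expect_equal(unname(cls["c1_unq"]), "unique")
  fr <- res$by_contig
  expect_equal(rowSums(fr[, c("affiliated_reference", "group_only",
                              "unique")]),
               rep(1, nrow(fr)), ignore_attr = TRUE)

  # removing the reference sends reference genes to the remaining classes
  res0 <- classify_novelty(gc, character(0), sch)
  cls0 <- setNames(res0$genes$class, res0$genes$gene_id)
  expect_true(cls0[["c1_ref"]] %in% c("group_only", "unique"))
  expect_equal(unname(cls0["c1_shr"]), "group_only")
})

test_that("synteny blocks recover self-identity and embedded cassettes", {
  set.seed(16)
  a <- random_dna(3000)
  self <- synteny_blocks(a, a, window = 500)
  expect_equal(nrow(self), 1)
  expect_equal(self$a_start, 0L)
  expect_equal(self$a_end, 3000L)
  expect_equal(self$identity, 1)

  b <- random_dna(3000)
  expect_equal(nrow(synteny_blocks(a, b, window = 500)), 0)

  cassette <- random_dna(1500)
  x <- paste0(random_dna(600), cassette, random_dna(500))
  y <- paste0(random_dna(200), cassette, random_dna(900))
  bl <- synteny_blocks(x, y, window = 500)
  expect_gte(nrow(bl), 1)
  main <- bl[which.max(bl$a_end - bl$a_start), ]
  expect_lt(abs(main$a_start - 600), 500)
  expect_lt(abs(main$b_start - 200), 500)
  expect_gt(main$identity, 0.9)
})

test_that("within-clade sharing exceeds between-clade sharing on synthetic data", {
  cfg <- small_sim_config(seed = 21)
  sim <- make_phage_clades(cfg, make_hosts(cfg))
  sm <- sharing_matrix(sim$gene_calls)
  cl <- setNames(sim$truth$clade_id, sim$truth$genome_id)
  same <- outer(cl[sm$contig_ids], cl[sm$contig_ids], `==`)
  off <- upper.tri(sm$proportions)
  expect_gt(mean(sm$proportions[off & same]),
            mean(sm$proportions[off & !same]))
})
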