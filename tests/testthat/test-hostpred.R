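test_that("tetranucleotide profiles count overlapping windows and skip N", {
  p <- tetra_profile("AAAAA", "x")
  expect_equal(unname(p$freqs["AAAA"]), 1)
  expect_equal(sum(p$freqs), 1)

  q <- tetra_profile("ACGTACGT", "y")
  expect_equal(unname(q$freqs[c("ACGT", "CGTA", "GTAC", "TACG")]),
               c(0.4, 0.2, 0.2, 0.2))

  n <- tetra_profile("ACGNACGT", "z")     # windows spanning N excluded
  expect_equal(sum(n$counts), 1)
  expect_equal(sum(n$freqs), 1)

  expect_error(tetra_profile("ACG"), "shorter")
  expect_error(tetra_profile("NNNNNN"), "ambiguous")
})

test_that("tetranucleotide distance is a Euclidean metric", {
  p <- tetra_profile("AAAAACGTTT", "p")
  expect_equal(tetra_distance(p, p), 0)

  e1 <- tetra_profile("AAAA", "e1")       # unit mass on AAAA
  e2 <- tetra_profile("CCCC", "e2")       # unit mass on CCCC
  expect_equal(tetra_distance(e1, e2), sqrt(2))

  q <- tetra_profile("ACGTACGTGG", "q")
  r <- tetra_profile("TTTTACGCAT", "r")
  expect_equal(tetra_distance(p, q), tetra_distance(q, p))
  expect_lte(tetra_distance(p, r),
             tetra_distance(p, q) + tetra_distance(q, r))
  expect_gte(tetra_distance(p, q), 0)
})

test_that("host tiers follow the calibrated distance thresholds strictly", {
  expect_equal(host_tier(2e-4)$tier, "high_95")
  expect_equal(host_tier(2e-4)$stated_accuracy, 95)
  t47 <- host_tier(4.7e-4)
  expect_equal(t47$tier, "moderate_84")
  expect_equal(t47$stated_accuracy, 84)
  expect_equal(host_tier(5e-3)$tier, "none")
  # strict 'below': boundaries fall into the next tier
  expect_equal(host_tier(4e-4)$tier, "moderate_84")
  expect_equal(host_tier(1e-3)$tier, "none")
  expect_error(host_tier(-1), "non-negative")
  # step function: accuracy non-increasing with distance
  acc <- vapply(c(0, 3e-4, 5e-4, 2e-3),
                function(d) host_tier(d)$stated_accuracy %||% 0, 0)
  acc[is.na(acc)] <- 0
  expect_true(all(diff(acc) <= 0))
})

test_that("host prediction picks the argmin host with deterministic ties", {
  set.seed(22)
  hosts <- Biostrings::DNAStringSet(c(hb = random_dna(3000),
                                      ha = random_dna(3000)))
  contig <- as.character(hosts[["ha"]])
  call <- predict_host(contig, hosts, contig_id = "c")
  expect_equal(call$best_host_id, "ha")
  expect_equal(call$distance, 0)
  expect_equal(call$tier, "high_95")

  # exact tie (identical hosts) resolved alphabetically
  twins <- Biostrings::DNAStringSet(c(zeta = contig, alpha = contig))
  tie <- predict_host(contig, twins, contig_id = "c")
  expect_equal(tie$best_host_id, "alpha")

  single <- predict_host(random_dna(500),
                         Biostrings::DNAStringSet(c(only = random_dna(500))),
                         contig_id = "c")
  expect_equal(single$best_host_id, "only")
  expect_true(single$tier %in% c("high_95", "moderate_84", "none"))
  expect_error(predict_host("ACGT", Biostrings::DNAStringSet()), "at least one")
})

test_that("amelioration drives contigs toward their true host signature", {
  cfg <- small_sim_config(seed = 33, amelioration_w = 0.8)
  hosts <- make_hosts(cfg)
  sim <- make_phage_clades(cfg, hosts)
  profs <- lapply(seq_along(hosts), function(i)
    tetra_profile(hosts[[i]], names(hosts)[i]))
  calls <- purrr::map(names(sim$genomes), function(g) {
    predict_host(sim$genomes[[g]], hosts, contig_id = g,
                 host_profiles = profs)
  }) |> dplyr::bind_rows()
  j <- dplyr::inner_join(calls, sim$truth, by = c(contig_id = "genome_id"))
  expect_gte(mean(j$best_host_id == j$host_id), 0.8)
  expect_gt(mean(j$best_host_id == j$host_id), 1 / length(hosts))
})

test_that("spacer matching applies the stringent coverage and identity filters", {
  set.seed(23)
  contig <- random_dna(2000)
  spacer <- substring(contig, 501, 533)
  hit <- match_spacer(spacer, contig, spacer_id = "s", contig_id = "c")
  expect_true(hit$passes)
  expect_true(hit$exact)
  expect_equal(hit$identity, 1)
  expect_equal(hit$coverage, 1)

  # reverse-strand spacers still match
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(spacer)))
  expect_true(match_spacer(rc, contig)$passes)

  # 25-nt spacer with 2 mismatches: 92% identity, passes but not exact
  sp25 <- substring(contig, 801, 825)
  v <- strsplit(sp25, "")[[1]]
  for (i in c(10, 15)) v[i] <- setdiff(c("A", "C", "G", "T"), v[i])[1]
  mm <- match_spacer(paste(v, collapse = ""), contig)
  expect_true(mm$passes)
  expect_false(mm$exact)
  expect_equal(mm$identity, 23 / 25, tolerance = 0.02)

  # only 20 of 30 nt present in the contig: coverage fails
  sp30 <- paste0(substring(contig, 1201, 1220), "GGGGGGGGGG")
  part <- match_spacer(sp30, substring(contig, 1100, 1400))
  expect_lte(part$coverage, 0.8)
  expect_false(part$passes)
  expect_error(match_spacer("ACGTACGT", contig), "15")
})

test_that("unmutated synthetic spacers all pass as exact matches", {
  cfg <- small_sim_config(seed = 8, spacer_mut = 0)
  sim <- make_phage_clades(cfg, make_hosts(cfg))
  sp <- make_spacers(sim$genomes[1:3], cfg, n_per_genome = 2)
  res <- purrr::imap(as.character(sp), function(s, sid) {
    src <- strsplit(sid, "|", fixed = TRUE)[[1]][2]
    match_spacer(s, sim$genomes[[src]], spacer_id = sid, contig_id = src)
  }) |> dplyr::bind_rows()
  expect_true(all(res$passes))
  expect_true(all(res$exact))
})

test_that("microbial genome search ranks the prophage-bearing host first", {
  set.seed(24)
  contig_prots <- setNames(vapply(1:3, function(i) random_protein(120), ""),
                           paste0("p", 1:3))
  # genome A carries a near-identical copy of p1; genome B is unrelated
  microbial <- c(genomeA_1 = contig_prots[["p1"]],
                 genomeA_2 = random_protein(120),
                 genomeB_1 = random_protein(120),
                 genomeB_2 = random_protein(120))
  res <- search_microbial_genomes(contig_prots, microbial)
  expect_equal(res$by_genome$genome_id[1], "genomeA")
  expect_equal(res$by_genome$max_identity[1], 1)
  expect_equal(unique(res$hits$query_id), "p1")

  nothing <- search_microbial_genomes(contig_prots,
                                      c(x_1 = random_protein(100)))
  expect_equal(nrow(nothing$hits), 0)
  expect_equal(nrow(nothing$by_genome), 0)
  expect_error(search_microbial_genomes(character(0), microbial), "empty")
})
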