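test_that("subsampling is uniform, deterministic and flagged", {
  reads <- Biostrings::DNAStringSet(setNames(rep("ACGT", 100),
                                             paste0("r", 1:100)))
  all_back <- subsample_reads(reads, 200, seed = 1)
  expect_equal(length(all_back), 100)
  expect_false(attr(all_back, "subsampled"))

  s1 <- subsample_reads(reads, 40, seed = 5)
  s2 <- subsample_reads(reads, 40, seed = 5)
  expect_identical(names(s1), names(s2))
  expect_true(attr(s1, "subsampled"))

  # inclusion frequency approximates the sampling fraction
  set.seed(3)
  big <- Biostrings::DNAStringSet(setNames(rep("ACGT", 10000),
                                           paste0("r", 1:10000)))
  inc <- names(subsample_reads(big, 5000, seed = 9))
  f <- mean(paste0("r", 1:10000) %in% inc)
  expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / 10000) + 1e-9)
})

test_that("coverage windows reproduce the worked example and tile exactly", {
  w <- coverage_windows(30000, 30)
  expect_equal(nrow(w), 30)
  expect_equal(unique(w$end - w$start), 1000)

  set.seed(4)
  for (L in c(30, 31, 97, sample(100:100000, 10))) {
    w <- coverage_windows(L, 30)
    expect_equal(w$start[1], 0)
    expect_equal(w$end[30], L)
    expect_equal(w$start[-1], w$end[-30])          # no gap, no overlap
    expect_true(all(w$end > w$start))
  }
  expect_error(coverage_windows(10, 30), "shorter")
})

test_that("presence calls apply the >= 100 distinct-read rule", {
  cfg <- recruit_config()
  mk <- function(n) tibble::tibble(read_id = paste0("r", seq_len(n)),
                                   contig_id = "c", bit_score = 60,
                                   evalue = 1e-6, identity = 1,
                                   s_start = 0L, frame_read = NA_integer_,
                                   frame_contig = NA_integer_)
  expect_false(presence_call(mk(99), "c", cfg))
  expect_true(presence_call(mk(100), "c", cfg))
  expect_false(presence_call(mk(0), "c", cfg))
  # duplicated read ids count once
  dup <- dplyr::bind_rows(mk(60), mk(60))
  expect_false(presence_call(dup, "c", cfg))
})

test_that("error-free reads recruit to their own contig at identity 1 (nucleotide)", {
  set.seed(17)
  contig <- Biostrings::DNAStringSet(c(src = random_dna(4000)))
  cfg <- sim_config(seed = 2, n_reads = 25, read_len = 120, read_error = 0)
  reads <- make_reads(contig, cfg)
  rcfg <- recruit_config(mode = "nucleotide", presence_min_reads = 5,
                         seed = 1)
  hits <- recruit_reads(reads, contig, rcfg)
  expect_equal(sort(unique(hits$read_id)), sort(names(reads)))
  expect_equal(unique(hits$identity), 1)
  expect_true(presence_call(hits, "src", rcfg))

  # unrelated genome: nothing recruits
  other <- Biostrings::DNAStringSet(c(bg = random_dna(4000)))
  none <- recruit_reads(make_reads(other, cfg), contig, rcfg)
  expect_equal(nrow(none), 0)
})

test_that("translated recruitment finds the best frame pair at identity 1", {
  set.seed(18)
  contig <- Biostrings::DNAStringSet(c(src = random_dna(1500)))
  cfg <- sim_config(seed = 3, n_reads = 6, read_len = 150, read_error = 0)
  reads <- make_reads(contig, cfg)
  rcfg <- recruit_config(mode = "translated", presence_min_reads = 2,
                         seed = 1)
  hits <- recruit_reads(reads, contig, rcfg)
  expect_gt(nrow(hits), 0)
  expect_equal(unique(hits$identity), 1)
  expect_true(all(hits$bit_score > 50))
  # window assignment uses nucleotide coordinates
  expect_true(all(hits$s_start >= 0 & hits$s_start < 1500))
})

test_that("coverage profiles count reads by window of alignment start", {
  cfg <- recruit_config(n_windows = 30)
  hits <- tibble::tibble(read_id = paste0("r", 1:90), contig_id = "c",
                         bit_score = 60, evalue = 1e-6, identity = 1,
                         s_start = rep(c(10L, 15000L, 29990L), each = 30),
                         frame_read = NA_integer_,
                         frame_contig = NA_integer_)
  cp <- coverage_profile(hits, "c", 30000, cfg, read_len = 100)
  expect_equal(sum(cp$windows$count), 90)
  expect_equal(cp$windows$count[1], 30)
  expect_equal(cp$windows$count[16], 30)
  expect_equal(cp$windows$count[30], 30)
  expect_equal(cp$normalized_coverage, 90 * 100 / 30000)

  empty <- coverage_profile(hits[0, ], "c", 30000, cfg, read_len = 100)
  expect_equal(sum(empty$windows$count), 0)
  expect_equal(empty$normalized_coverage, 0)

  expect_s3_class(autoplot(cp), "ggplot")
  expect_equal(nrow(tidy(cp)), 30)

  # near-uniform starts spread evenly over windows
  set.seed(6)
  u <- hits[rep(1, 3000), ]
  u$read_id <- paste0("u", 1:3000)
  u$s_start <- sample(0:29999, 3000, replace = TRUE)
  cpu <- coverage_profile(u, "c", 30000, cfg)
  expect_lt(max(cpu$windows$count) / max(1, min(cpu$windows$count)), 2)
})

test_that("the Welch comparison matches the closed form and its conventions", {
  same <- env_comparison(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  g1 <- c(2.1, 2.5, 2.3); g2 <- c(3.1, 3.3, 3.0)
  res <- env_comparison(g1, g2)
  # closed-form Welch statistic
  se <- sqrt(var(g1) / 3 + var(g2) / 3)
  expect_equal(res$t, (mean(g1) - mean(g2)) / se, tolerance = 1e-12)
  df <- se^4 / ((var(g1) / 3)^2 / 2 + (var(g2) / 3)^2 / 2)
  expect_equal(res$df, df, tolerance = 1e-12)
  expect_equal(res$p, 2 * stats::pt(-abs(res$t), df), tolerance = 1e-12)

  flipped <- env_comparison(g2, g1)
  expect_equal(flipped$t, -res$t)
  expect_equal(flipped$p, res$p)

  const_eq <- env_comparison(c(1, 1), c(1, 1))
  expect_equal(const_eq$p, 1)
  const_ne <- env_comparison(c(1, 1), c(2, 2))
  expect_equal(const_ne$p, 0)
  expect_true(attr(const_ne, "degenerate"))
  expect_error(env_comparison(1, c(1, 2)), "n >= 2")
})

test_that("a two-environment design separates clade coverages", {
  set.seed(19)
  gA <- Biostrings::DNAStringSet(c(cladeA = random_dna(3000)))
  gB <- Biostrings::DNAStringSet(c(cladeB = random_dna(3000)))
  both <- c(gA, gB)
  rcfg <- recruit_config(mode = "nucleotide", presence_min_reads = 1,
                         seed = 1)
  cov_for <- function(abund, seed) {
    cfg <- sim_config(seed = seed, n_reads = 24, read_len = 120,
                      read_error = 0)
    reads <- make_reads(both, cfg, abundances = abund)
    hits <- recruit_reads(reads, both, rcfg)
    vapply(names(both), function(cid) {
      coverage_profile(hits, cid, 3000, rcfg, read_len = 120)$normalized_coverage
    }, 0)
  }
  env1 <- vapply(1:3, function(s) cov_for(c(cladeA = 0.9, cladeB = 0.1), s),
                 c(cladeA = 0, cladeB = 0))
  env2 <- vapply(4:6, function(s) cov_for(c(cladeA = 0.1, cladeB = 0.9), s),
                 c(cladeA = 0, cladeB = 0))
  resA <- env_comparison(env1["cladeA", ], env2["cladeA", ])
  resB <- env_comparison(env1["cladeB", ], env2["cladeB", ])
  expect_lt(resA$p, 0.01)
  expect_gt(resA$t, 0)
  expect_lt(resB$p, 0.01)
  expect_lt(resB$t, 0)
})
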