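# End-to-end orchestration on simulated (or user-supplied) data, and
# validation of the packaged contig summary table.

#' Summarise a contig table
#'
#' Derived counts of a contig summary table (see [read_contig_table()]):
#' totals per dataset class, contigs above a length cutoff, marker and
#' host-hint counts, and clade representation.
#'
#' @param tb A contig table tibble.
#' @param long_cutoff Length cutoff (bp) for the "long contig" count.
#' @return A tibble with columns `quantity` and `value`.
#' @export
contig_table_summary <- function(tb, long_cutoff = 25000) {
  has_marker <- function(mk) {
    sum(purrr::map_lgl(tb$markers,
                       function(m) any(startsWith(m, mk))))
  }
  tibble(
    quantity = c("n_contigs", "n_hiseq", "n_454", "n_long",
                 "n_phoh", "n_crispr_host", "n_tetra_host",
                 "n_clades_present", "n_g23", "n_g20", "n_g17"),
    value = c(nrow(tb),
              sum(grepl("HiSeq", tb$dataset)),
              sum(grepl("454", tb$dataset)),
              sum(tb$length > long_cutoff),
              sum(tb$phoh),
              sum(!is.na(tb$crispr_host)),
              sum(!is.na(tb$tetra_host)),
              dplyr::n_distinct(tb$clade),
              has_marker("g23"), has_marker("g20"), has_marker("g17"))
  )
}

#' Validate a pipeline's contig table against the packaged fixture
#'
#' Recomputes the summary counts from the fixture and compares them with
#' the expected values from the published study description (40 contigs:
#' 32 from HiSeq viromes and 8 from 454 viromes; 12 contigs longer than
#' 25 kb; 3 CRISPR and 3 tetranucleotide host hints; 4 clades with
#' assembled contigs).
#'
#' @param tb Contig table (defaults to the packaged fixture).
#' @param expected Named numeric vector of expected counts; any quantity
#'   not listed is reported but not asserted.
#' @return A tibble `quantity`, `value`, `expected`, `match`; attribute
#'   `ok` is `TRUE` when every asserted quantity matches.
#' @export
validate_against_fixture <- function(tb = read_contig_table(),
                                     expected = c(n_contigs = 40,
                                                  n_hiseq = 32,
                                                  n_454 = 8,
                                                  n_long = 12,
                                                  n_crispr_host = 3,
                                                  n_tetra_host = 3,
                                                  n_clades_present = 4)) {
  if (nrow(tb) == 0) abort("empty contig table")
  s <- contig_table_summary(tb)
  s$expected <- unname(expected[s$quantity])
  s$match <- is.na(s$expected) | s$value == s$expected
  attr(s, "ok") <- all(s$match)
  s
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the stages end to end: simulate, marker screening, marker
#' phylogeny with bootstrap and clade delineation, gene-content sharing
#' and clustering, tree concordance (RF leaf-permutation test), read
#' recruitment with presence calls and a coverage profile, host
#' prediction (tetranucleotide tiers and CRISPR spacers), and group-wise
#' dN/dS of the major capsid protein.  Deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param outdir Optional directory; when given, all tables are written
#'   as TSV plus a JSON summary.
#' @param n_boot Bootstrap replicates for the marker tree.
#' @param clade_min_support Minimum support for clade delineation.
#' @param n_perm Permutations for the concordance test.
#' @param recruit_n_reads Reads subsampled for the recruitment stage.
#' @param recruit_contigs How many contigs (one per clade, by default
#'   the first of each) to recruit against.
#' @param run_recruit Set `FALSE` to skip the recruitment stage (it is
#'   the slowest); skipping emits a warning and leaves the rest intact.
#' @return A list of class `viroclade_report` with elements `truth`,
#'   `marker_calls`, `marker_tree`, `clades`, `clade_ari_input`,
#'   `sharing`, `cluster_tree`, `concordance`, `recruit_hits`,
#'   `presence`, `coverage`, `host_calls`, `spacer_matches`, `dnds`,
#'   `seed`.
#' @export
run_pipeline <- function(cfg = sim_config(), outdir = NULL, n_boot = 100,
                         clade_min_support = 80, n_perm = 1000,
                         recruit_n_reads = 60, recruit_contigs = NULL,
                         run_recruit = TRUE) {
  hosts <- make_hosts(cfg)
  sim <- make_phage_clades(cfg, hosts)
  genomes <- sim$genomes
  contig_lengths <- setNames(Biostrings::width(genomes), names(genomes))

  # --- marker screening ---
  # the clade reference proteins are colinear by construction (the
  # generator introduces no indels inside genes), so the reference
  # alignment is the identity alignment of the equal-length references
  ref_msa <- new_msa(setNames(as.character(sim$marker_refs$g23),
                              names(sim$marker_refs$g23)))
  W <- msa_ncol(ref_msa)
  mcfg <- marker_screen_config(
    refsets = sim$marker_refs,
    min_contig_len = min(10000, cfg$genome_len),
    n_domain_cols = c(10, min(50, W)),
    c_domain_cols = c(max(1, W - 49), W - 9))
  marker_calls <- screen_markers(sim$gene_calls, mcfg, contig_lengths,
                                 reference_msa = ref_msa)

  # --- marker phylogeny and clades ---
  # the tree holds the screened query proteins plus the marker reference
  # set and distant references; clades are delineated among queries and
  # designated references, so the distant references bound them
  g23 <- marker_calls |> filter(.data$marker == "g23")
  g23_prot <- sim$gene_calls |>
    filter(.data$gene_id %in% g23$gene_id) |>
    (\(d) setNames(d$protein, d$contig_id))()
  tree_seqs <- c(g23_prot,
                 setNames(as.character(sim$marker_refs$g23),
                          names(sim$marker_refs$g23)),
                 setNames(as.character(sim$distant_refs$g23),
                          names(sim$distant_refs$g23)))
  marker_msa <- progressive_msa(tree_seqs)
  marker_tree <- bootstrap_support(marker_msa, n_reps = n_boot,
                                   seed = child_seed(cfg$seed, "boot"))
  rooted <- phangorn::midpoint(marker_tree, node.labels = "support")
  clades <- delineate_clades(
    rooted, c(names(genomes), names(sim$marker_refs$g23)),
    min_support = clade_min_support) |>
    filter(.data$leaf %in% names(genomes))

  # --- gene content and concordance ---
  sharing <- sharing_matrix(sim$gene_calls)
  cluster_tree <- cluster_contigs(sharing)
  concordance <- rf_permutation_test(marker_tree, cluster_tree,
                                     n_perm = n_perm,
                                     seed = child_seed(cfg$seed, "perm"))

  # --- read recruitment ---
  recruit_hits <- NULL; presence <- NULL; coverage <- NULL
  if (run_recruit) {
    reads <- make_reads(genomes, cfg)
    rcfg <- recruit_config(subsample_n = recruit_n_reads,
                           presence_min_reads = 5, mode = "nucleotide",
                           seed = child_seed(cfg$seed, "recruit"))
    sub <- subsample_reads(reads, recruit_n_reads, seed = rcfg$seed)
    targets <- recruit_contigs %||%
      (sim$truth |> group_by(.data$clade_id) |> dplyr::slice(1) |>
         pull(.data$genome_id))
    recruit_hits <- recruit_reads(sub, genomes[targets], rcfg)
    presence <- tibble(
      contig_id = targets,
      n_reads = purrr::map_int(targets, function(cid) {
        recruit_hits |> filter(.data$contig_id == cid) |>
          distinct(.data$read_id) |> nrow()
      }),
      present = purrr::map_lgl(targets, function(cid) {
        presence_call(recruit_hits, cid, rcfg)
      }))
    coverage <- coverage_profile(recruit_hits, targets[1],
                                 contig_lengths[targets[1]], rcfg,
                                 read_len = cfg$read_len)
  } else {
    warn("recruitment stage skipped")
  }

  # --- host prediction ---
  host_profiles <- lapply(seq_along(hosts), function(i)
    tetra_profile(hosts[[i]], id = names(hosts)[i]))
  host_calls <- purrr::map(names(genomes), function(gid) {
    predict_host(genomes[[gid]], hosts, contig_id = gid,
                 host_profiles = host_profiles)
  }) |> bind_rows()
  spacers <- make_spacers(genomes, cfg, n_per_genome = 1)
  spacer_matches <- purrr::imap(as.character(spacers), function(sp, sid) {
    src <- strsplit(sid, "|", fixed = TRUE)[[1]][2]
    match_spacer(sp, genomes[[src]], spacer_id = sid, contig_id = src)
  }) |> bind_rows()

  # --- selection on the major capsid protein ---
  g23_nt <- sim$gene_calls |>
    filter(.data$annotation == "g23") |>
    (\(d) setNames(substring(as.character(genomes[d$contig_id]),
                             d$start + 1, d$end), d$contig_id))()
  grp <- sim$truth |> filter(.data$clade_id == "clade_1") |>
    pull(.data$genome_id)
  dnds <- group_dnds(g23_nt, grp)

  report <- structure(
    list(truth = sim$truth, marker_calls = marker_calls,
         marker_tree = marker_tree, clades = clades, sharing = sharing,
         cluster_tree = cluster_tree, concordance = concordance,
         recruit_hits = recruit_hits, presence = presence,
         coverage = coverage, host_calls = host_calls,
         spacer_matches = spacer_matches, dnds = dnds, seed = cfg$seed),
    class = "viroclade_report")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' @export
print.viroclade_report <- function(x, ...) {
  cat("<viroclade_report> seed ", x$seed, "\n", sep = "")
  cat("  genomes: ", nrow(x$truth), " in ",
      dplyr::n_distinct(x$truth$clade_id), " true clades; delineated: ",
      dplyr::n_distinct(x$clades$clade_id[x$clades$clade_id != "unassigned"]),
      "\n", sep = "")
  cat("  concordance: observed RF ", x$concordance$observed_rf,
      " vs null mean ", sprintf("%.1f", x$concordance$null_mean),
      " (p_emp ", sprintf("%.4g", x$concordance$p_empirical), ")\n",
      sep = "")
  invisible(x)
}

write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_tsv_strict(report$truth, p("truth.tsv"))
  write_tsv_strict(report$marker_calls, p("marker_calls.tsv"))
  write_newick(report$marker_tree, p("marker_tree.nwk"))
  write_tsv_strict(report$clades, p("clades.tsv"))
  write_tsv_strict(tidy(report$sharing), p("sharing.tsv"))
  write_newick(report$cluster_tree, p("cluster_tree.nwk"))
  write_tsv_strict(tidy(report$concordance), p("concordance.tsv"))
  if (!is.null(report$recruit_hits)) {
    write_tsv_strict(report$recruit_hits, p("recruit_hits.tsv"))
    write_tsv_strict(report$presence, p("presence.tsv"))
    write_tsv_strict(tidy(report$coverage), p("coverage.tsv"))
  }
  write_tsv_strict(report$host_calls, p("host_calls.tsv"))
  write_tsv_strict(report$spacer_matches, p("spacer_matches.tsv"))
  write_tsv_strict(report$dnds, p("dnds.tsv"))
  summary <- list(
    seed = report$seed,
    n_genomes = nrow(report$truth),
    n_true_clades = dplyr::n_distinct(report$truth$clade_id),
    n_delineated_clades = dplyr::n_distinct(
      report$clades$clade_id[report$clades$clade_id != "unassigned"]),
    concordance = as.list(tidy(report$concordance)))
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(outdir)
}
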