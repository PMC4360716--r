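# Synthetic virome generator: clade-structured phage genomes sharing a
# core-gene backbone, host-ameliorated nucleotide composition, reads at
# controlled divergence/error, and CRISPR spacers excised from the genomes.
#
# Everything is deterministic under the global seed: each sub-generator
# derives a child seed by a labelled integer hash so modules can be run
# independently yet reproducibly.

BASES <- c("A", "C", "G", "T")
SENSE_CODONS <- {
  all3 <- as.vector(outer(as.vector(outer(BASES, BASES, paste0)), BASES,
                          paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

#' Configuration of the synthetic virome study
#'
#' Collects every knob of the generator: host genomes (order-`host_order`
#' Markov composition), clade structure (number of clades, genomes per
#' clade, within- and between-clade divergence as per-site substitution
#' probabilities with a uniform Jukes-Cantor-like kernel), gene content
#' (core genes, including the labelled markers g23/g20/g17/phoH, plus a
#' pool of flexible genes), amelioration weight (probability that a
#' genome base is drawn from the host Markov chain rather than a uniform
#' background), and read/spacer parameters.
#'
#' @param seed Global integer seed; all randomness derives from it.
#' @param n_hosts,host_len,host_order Host genome count, length (bp) and
#'   Markov order of their composition model.
#' @param n_clades,genomes_per_clade,genome_len Clade structure and phage
#'   genome length (bp).
#' @param n_core_genes Number of core genes (>= 4; the first four are the
#'   markers g23, g20, g17, phoH).
#' @param n_flexible_genes Size of the flexible gene pool; each clade
#'   carries a random half of the pool.
#' @param within_clade_div,between_clade_div Per-site substitution
#'   probabilities applied leaf-from-clade-ancestor and
#'   clade-ancestor-from-root respectively.
#' @param amelioration_w Weight in `[0, 1]` of the host chain in genome
#'   base composition.
#' @param read_len,n_reads,read_error Read simulation parameters.
#' @param spacer_len,spacer_mut CRISPR spacer length and per-base mutation
#'   rate.
#' @return A validated `sim_config` object (a named list).
#' @export
sim_config <- function(seed = 1L, n_hosts = 5, host_len = 200000,
                       host_order = 3, n_clades = 3, genomes_per_clade = 4,
                       genome_len = 30000, n_core_genes = 8,
                       n_flexible_genes = 6, within_clade_div = 0.05,
                       between_clade_div = 0.5, amelioration_w = 0.7,
                       read_len = 150, n_reads = 2000, read_error = 0.01,
                       spacer_len = 33, spacer_mut = 0.02) {
  cfg <- list(seed = as.integer(seed), n_hosts = n_hosts,
              host_len = host_len, host_order = host_order,
              n_clades = n_clades, genomes_per_clade = genomes_per_clade,
              genome_len = genome_len, n_core_genes = n_core_genes,
              n_flexible_genes = n_flexible_genes,
              within_clade_div = within_clade_div,
              between_clade_div = between_clade_div,
              amelioration_w = amelioration_w, read_len = read_len,
              n_reads = n_reads, read_error = read_error,
              spacer_len = spacer_len, spacer_mut = spacer_mut)
  rates <- c(cfg$within_clade_div, cfg$between_clade_div,
             cfg$amelioration_w, cfg$read_error, cfg$spacer_mut)
  if (any(rates < 0 | rates > 1)) abort("all rates must lie in [0, 1]")
  if (cfg$within_clade_div > cfg$between_clade_div) {
    abort("within_clade_div must not exceed between_clade_div")
  }
  lens <- c(cfg$host_len, cfg$genome_len, cfg$read_len, cfg$spacer_len)
  if (any(lens <= 0)) abort("lengths must be positive")
  structure(cfg, class = "sim_config")
}

# labelled child seed, always < 2^31
child_seed <- function(seed, label) {
  m <- 2147483629
  h <- 0
  for (code in utf8ToInt(label)) h <- (h * 131 + code) %% m
  as.integer((h + (abs(as.numeric(seed)) %% m) * 48271) %% m)
}

# transition matrix of a random order-k Markov chain (rows: 4^k contexts)
markov_chain <- function(k, seed) {
  set.seed(seed)
  p <- matrix(stats::rgamma(4^k * 4, shape = 1), ncol = 4)
  p / rowSums(p)
}

# sample n bases: with prob w from the chain, else uniform background
markov_mix_sample <- function(n, trans, k, w = 1) {
  cum <- t(apply(trans, 1, cumsum))
  n_ctx <- nrow(trans)
  u <- runif(n)
  from_chain <- runif(n) <= w
  out <- integer(n)
  ctx <- 0L
  for (i in seq_len(n)) {
    b <- if (i > k && from_chain[i]) {
      1L + sum(u[i] > cum[ctx + 1L, 1:3])
    } else {
      1L + (floor(u[i] * 4) %% 4)
    }
    out[i] <- b
    ctx <- as.integer((ctx * 4L + (b - 1L)) %% n_ctx)
  }
  paste(BASES[out], collapse = "")
}

#' Generate host genomes with distinct compositional signatures
#'
#' Each host genome is sampled from its own order-`host_order` Markov
#' chain (a distinct random transition table per host), so host
#' tetranucleotide profiles are well separated.  Deterministic under
#' `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A [Biostrings::DNAStringSet] of `n_hosts` genomes named
#'   `host_1 ... host_n`.
#' @export
make_hosts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  seqs <- vapply(seq_len(cfg$n_hosts), function(h) {
    trans <- markov_chain(cfg$host_order,
                          child_seed(cfg$seed, paste0("host_chain_", h)))
    set.seed(child_seed(cfg$seed, paste0("host_seq_", h)))
    markov_mix_sample(cfg$host_len, trans, cfg$host_order, w = 1)
  }, "")
  Biostrings::DNAStringSet(setNames(seqs, paste0("host_", seq_len(cfg$n_hosts))))
}

# per-site substitution with uniform kernel to the other three bases
mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  v <- strsplit(s, "")[[1]]
  hit <- which(runif(length(v)) < rate)
  if (length(hit) > 0) {
    repl <- vapply(v[hit], function(b) sample(setdiff(BASES, b), 1), "")
    v[hit] <- repl
  }
  paste(v, collapse = "")
}

# force a gene region into a clean ORF: ATG start, no in-frame stops
repair_gene <- function(s) {
  n <- nchar(s)
  stopifnot(n %% 3 == 0)
  codons <- substring(s, seq(1, n, 3), seq(3, n, 3))
  codons[1] <- "ATG"
  bad <- codons %in% c("TAA", "TAG", "TGA")
  codons[bad] <- paste0(substring(codons[bad], 1, 2), "C")
  paste(codons, collapse = "")
}

random_gene <- function(n_codons) {
  body <- paste(sample(SENSE_CODONS, n_codons - 1, replace = TRUE),
                collapse = "")
  paste0("ATG", body)
}

# gene family catalogue: name, class, length in codons (incl. start)
gene_catalogue <- function(cfg) {
  marker_len <- c(g23 = 300, g20 = 250, g17 = 250, phoH = 200)
  core_names <- c(names(marker_len),
                  if (cfg$n_core_genes > 4)
                    sprintf("core_%02d", 5:cfg$n_core_genes))
  core_len <- c(marker_len,
                setNames(rep(150, max(0, cfg$n_core_genes - 4)),
                         setdiff(core_names, names(marker_len))))
  flex_names <- sprintf("flex_%02d", seq_len(cfg$n_flexible_genes))
  tibble(
    family = c(core_names, flex_names, "private"),
    class = c(rep("core", length(core_names)),
              rep("flexible", length(flex_names)), "unique"),
    len_codons = c(unname(core_len[core_names]),
                   rep(120, length(flex_names)), 100)
  )
}

#' Generate clade-structured phage genomes with known truth
#'
#' Builds, for each host with assigned clades, an ancestral set of gene
#' family sequences whose bases are drawn with probability
#' `amelioration_w` from that host's Markov chain and otherwise from a
#' uniform background; derives clade ancestors at `between_clade_div` and
#' leaf genomes at `within_clade_div` (per-site substitution, uniform
#' kernel, no indels inside genes so gene coordinates are exact).  Each
#' clade carries all core genes (g23, g20, g17, phoH, ...) plus a
#' clade-specific half of the flexible pool; every leaf genome additionally
#' carries one private gene.  Genes keep their order within a clade.
#'
#' @param cfg A [sim_config()]; `n_core_genes` must be >= 4 so the marker
#'   genes exist.
#' @param hosts Host genomes from [make_hosts()] (used for host ids; the
#'   composition chains are re-derived from `cfg$seed`).
#' @return A list with `genomes` ([Biostrings::DNAStringSet]),
#'   `gene_calls` (gene-call tibble with `annotation` = family name),
#'   `truth` (tibble: `genome_id`, `clade_id`, `host_id`),
#'   `marker_refs` (list mapping marker label to an
#'   [Biostrings::AAStringSet] of per-clade ancestral reference proteins,
#'   the synthetic analogue of the known marker reference set), and
#'   `distant_refs` (same structure, per-host root proteins standing in
#'   for distant relatives outside the group of interest).
#' @export
make_phage_clades <- function(cfg, hosts) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_core_genes < 4) {
    abort("n_core_genes must be >= 4 (marker genes g23/g20/g17/phoH)")
  }
  cat_tb <- gene_catalogue(cfg)
  host_ids <- names(hosts)
  clade_host <- host_ids[((seq_len(cfg$n_clades) - 1) %% cfg$n_hosts) + 1]

  # ancestral gene family sequences per host actually used
  root_genes <- list()
  for (h in unique(clade_host)) {
    trans <- markov_chain(cfg$host_order,
                          child_seed(cfg$seed, paste0("host_chain_",
                                                      match(h, host_ids))))
    set.seed(child_seed(cfg$seed, paste0("root_genes_", h)))
    fam <- setNames(vapply(seq_len(nrow(cat_tb)), function(i) {
      repair_gene(markov_mix_sample(3 * cat_tb$len_codons[i], trans,
                                    cfg$host_order, w = cfg$amelioration_w))
    }, ""), cat_tb$family)
    root_genes[[h]] <- fam
  }

  genomes <- character(0)
  calls <- list()
  truth <- list()
  clade_anc_markers <- list()
  for (cl in seq_len(cfg$n_clades)) {
    h <- clade_host[cl]
    clade_id <- paste0("clade_", cl)
    set.seed(child_seed(cfg$seed, paste0("clade_", cl)))
    flex_pool <- cat_tb$family[cat_tb$class == "flexible"]
    flex_pick <- sort(sample(flex_pool, max(1L, ceiling(length(flex_pool) / 2))))
    families <- c(cat_tb$family[cat_tb$class == "core"], flex_pick, "private")
    anc <- vapply(families, function(f) {
      repair_gene(mutate_seq(root_genes[[h]][[f]], cfg$between_clade_div))
    }, "")
    clade_anc_markers[[paste0("clade_", cl)]] <-
      vapply(c("g23", "g20", "g17", "phoH"),
             function(mk) translate_nt(anc[[mk]]), "")
    gene_nt <- sum(nchar(anc)) + 3 * length(anc)       # incl. stop codons
    spare <- cfg$genome_len - gene_nt
    n_gap <- length(anc) + 1
    if (spare < n_gap * 10) {
      abort("genome_len too small for the configured gene content")
    }
    gap_len <- diff(floor(seq(0, spare, length.out = n_gap + 1)))
    trans <- markov_chain(cfg$host_order,
                          child_seed(cfg$seed, paste0("host_chain_",
                                                      match(h, host_ids))))
    stops <- vapply(seq_along(anc), function(i)
      sample(c("TAA", "TAG", "TGA"), 1), "")
    gaps <- vapply(gap_len, function(L) {
      if (L == 0) "" else
        markov_mix_sample(L, trans, cfg$host_order, w = cfg$amelioration_w)
    }, "")
    # genome layout (identical for every genome of the clade)
    gene_starts <- integer(length(anc))
    pos <- 0L
    for (i in seq_along(anc)) {
      pos <- pos + nchar(gaps[i])
      gene_starts[i] <- pos
      pos <- pos + nchar(anc[i]) + 3L
    }
    assemble <- function(slot_seqs) {
      pieces <- character(0)
      for (i in seq_along(slot_seqs)) {
        pieces <- c(pieces, gaps[i], slot_seqs[i], stops[i])
      }
      paste(c(pieces, gaps[length(gaps)]), collapse = "")
    }
    gene_ends <- gene_starts + nchar(anc)
    repair_genome <- function(genome) {
      for (i in seq_along(anc)) {
        region <- substring(genome, gene_starts[i] + 1, gene_ends[i])
        substring(genome, gene_starts[i] + 1, gene_ends[i]) <-
          repair_gene(region)
        substring(genome, gene_ends[i] + 1, gene_ends[i] + 3) <- stops[i]
      }
      genome
    }

    # within-clade structure: two subgroups descending from intermediate
    # ancestors (half the within-clade divergence on each level), with
    # one flexible-gene slot swapped between the subgroups so gene
    # content carries the same within-clade signal as the sequences
    n_g <- cfg$genomes_per_clade
    subgroup <- rep(1L, n_g)
    fam_by_subgroup <- list(families, families)
    sub_anc <- list(anc, anc)
    structured <- cfg$within_clade_div > 0 && n_g >= 4
    if (structured) {
      subgroup[seq(n_g %/% 2 + 1, n_g)] <- 2L
      alt_pool <- setdiff(flex_pool, flex_pick)
      flex_slots <- which(families %in% flex_pool)
      if (length(alt_pool) > 0 && length(flex_slots) > 0) {
        swap_slot <- flex_slots[length(flex_slots)]
        alt_family <- alt_pool[1]
        fam_b <- families
        fam_b[swap_slot] <- alt_family
        anc_b <- anc
        anc_b[swap_slot] <-
          repair_gene(mutate_seq(root_genes[[h]][[alt_family]],
                                 cfg$between_clade_div))
        fam_by_subgroup[[2]] <- fam_b
        sub_anc[[2]] <- anc_b
      }
      half <- cfg$within_clade_div / 2
      sub_anc <- lapply(sub_anc, function(slots) {
        g <- repair_genome(mutate_seq(assemble(slots), half))
        g
      })
    } else {
      sub_anc <- lapply(sub_anc, assemble)
    }

    leaf_rate <- if (structured) cfg$within_clade_div / 2 else
      cfg$within_clade_div
    priv_slot <- which(families == "private")
    for (g in seq_len(n_g)) {
      gid <- sprintf("clade%d_genome%02d", cl, g)
      set.seed(child_seed(cfg$seed, paste0("leaf_", gid)))
      sg <- subgroup[g]
      genome <- sub_anc[[sg]]
      if (cfg$within_clade_div > 0) {
        genome <- repair_genome(mutate_seq(genome, leaf_rate))
        # per-genome private gene (same slot length in every genome)
        substring(genome, gene_starts[priv_slot] + 1,
                  gene_ends[priv_slot]) <-
          random_gene(cat_tb$len_codons[cat_tb$family == "private"])
      }
      fams <- fam_by_subgroup[[sg]]
      tb <- tibble(
        contig_id = gid, start = gene_starts, end = gene_ends,
        strand = "+", gene_id = sprintf("%s_%s", gid, fams),
        protein = translate_nt(substring(genome, gene_starts + 1,
                                         gene_ends)),
        annotation = fams)
      genomes[gid] <- genome
      calls[[gid]] <- tb
      truth[[gid]] <- tibble(genome_id = gid, clade_id = clade_id,
                             host_id = h,
                             subgroup = if (structured) sg else NA_integer_)
    }
  }

  markers <- c("g23", "g20", "g17", "phoH")
  marker_refs <- lapply(markers, function(mk) {
    refs <- vapply(names(clade_anc_markers),
                   function(cl) clade_anc_markers[[cl]][[mk]], "")
    Biostrings::AAStringSet(setNames(refs, paste0("ref_", mk, "_",
                                                  names(clade_anc_markers))))
  })
  names(marker_refs) <- markers
  distant_refs <- lapply(markers, function(mk) {
    refs <- vapply(unique(clade_host), function(h) {
      translate_nt(root_genes[[h]][[mk]])
    }, "")
    Biostrings::AAStringSet(setNames(refs, paste0("dist_", mk, "_",
                                                  unique(clade_host))))
  })
  names(distant_refs) <- markers

  list(genomes = Biostrings::DNAStringSet(genomes),
       gene_calls = bind_rows(calls),
       truth = bind_rows(truth),
       marker_refs = marker_refs,
       distant_refs = distant_refs)
}

#' Simulate shotgun reads from phage genomes
#'
#' Draws `n_reads` reads of `read_len` bp from the genomes, with genome
#' choice proportional to `abundance * length`, uniform start positions,
#' random strand and independent per-base substitution errors at
#' `read_error`.  Read ids encode the true origin as
#' `r<idx>|<genome>|<start>|<strand>`.
#'
#' @param genomes A [Biostrings::DNAStringSet].
#' @param cfg A [sim_config()].
#' @param abundances Named numeric vector over `names(genomes)` summing
#'   to 1; defaults to uniform.
#' @return A [Biostrings::QualityScaledDNAStringSet] (all qualities
#'   phred 40).
#' @export
make_reads <- function(genomes, cfg, abundances = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  L <- Biostrings::width(genomes)
  if (cfg$read_len > min(L)) {
    abort("read_len exceeds the shortest genome")
  }
  ab <- abundances %||%
    setNames(rep(1 / length(genomes), length(genomes)), names(genomes))
  if (abs(sum(ab) - 1) > 1e-8) abort("abundances must sum to 1")
  ab <- ab[names(genomes)]
  if (anyNA(ab)) abort("abundances must be named by genome id")
  set.seed(child_seed(cfg$seed, "reads"))
  w <- ab * L
  origin <- sample.int(length(genomes), cfg$n_reads, replace = TRUE,
                       prob = w / sum(w))
  starts <- floor(runif(cfg$n_reads) * (L[origin] - cfg$read_len + 1))
  strands <- sample(c("+", "-"), cfg$n_reads, replace = TRUE)
  gseq <- as.character(genomes)
  reads <- substring(gseq[origin], starts + 1, starts + cfg$read_len)
  flip <- strands == "-"
  if (any(flip)) {
    reads[flip] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(reads[flip])))
  }
  if (cfg$read_error > 0) {
    reads <- vapply(reads, function(s) mutate_seq(s, cfg$read_error), "",
                    USE.NAMES = FALSE)
  }
  ids <- sprintf("r%06d|%s|%d|%s", seq_len(cfg$n_reads),
                 names(genomes)[origin], starts, strands)
  x <- Biostrings::DNAStringSet(setNames(reads, ids))
  q <- Biostrings::PhredQuality(rep(strrep("I", cfg$read_len), length(x)))
  Biostrings::QualityScaledDNAStringSet(x, q)
}

#' Excise mutated CRISPR spacers from phage genomes
#'
#' Cuts `n_per_genome` windows of `spacer_len` bp at random positions from
#' each genome and mutates each base independently at `spacer_mut`.
#' Spacer ids encode the source genome and realised mutation count as
#' `spacer|<genome>|<idx>|mut=<k>`.
#'
#' @param phage_genomes A [Biostrings::DNAStringSet].
#' @param cfg A [sim_config()] (`spacer_len` must be shorter than every
#'   genome).
#' @param n_per_genome Spacers excised per genome.
#' @return A [Biostrings::DNAStringSet] of spacers.
#' @export
make_spacers <- function(phage_genomes, cfg, n_per_genome = 3) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$spacer_len >= min(Biostrings::width(phage_genomes))) {
    abort("spacer_len must be shorter than every genome")
  }
  set.seed(child_seed(cfg$seed, "spacers"))
  out <- character(0)
  for (gid in names(phage_genomes)) {
    s <- as.character(phage_genomes[[gid]])
    for (i in seq_len(n_per_genome)) {
      pos <- floor(runif(1) * (nchar(s) - cfg$spacer_len + 1))
      sp <- substring(s, pos + 1, pos + cfg$spacer_len)
      mut <- mutate_seq(sp, cfg$spacer_mut)
      k <- sum(strsplit(sp, "")[[1]] != strsplit(mut, "")[[1]])
      out[sprintf("spacer|%s|%d|mut=%d", gid, i, k)] <- mut
    }
  }
  Biostrings::DNAStringSet(out)
}

#' Run the full generator and write all study inputs to disk
#'
#' Writes hosts, phage genomes, gene calls (GFF3 + protein FASTA), reads
#' (FASTQ), spacers, marker reference sets, the truth table and the
#' abundance table under one output directory.  Byte-identical output for
#' identical configurations.
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory (created if missing).
#' @param abundances Optional abundances passed to [make_reads()].
#' @return Invisibly, a list with all in-memory objects plus `paths`.
#' @export
simulate_virome <- function(cfg, outdir, abundances = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hosts <- make_hosts(cfg)
  sim <- make_phage_clades(cfg, hosts)
  reads <- make_reads(sim$genomes, cfg, abundances)
  spacers <- make_spacers(sim$genomes, cfg)
  p <- function(f) file.path(outdir, f)
  write_fasta(hosts, p("hosts.fasta"))
  write_fasta(sim$genomes, p("genomes.fasta"))
  write_gene_calls(sim$gene_calls, p("genes.gff3"))
  prot <- sim$gene_calls$protein
  write_fasta(Biostrings::AAStringSet(setNames(prot, sim$gene_calls$gene_id)),
              p("proteins.fasta"))
  write_fastq(reads, p("reads.fastq"))
  write_fasta(spacers, p("spacers.fasta"))
  for (mk in names(sim$marker_refs)) {
    write_fasta(sim$marker_refs[[mk]], p(paste0("ref_", mk, ".fasta")))
    write_fasta(sim$distant_refs[[mk]], p(paste0("distant_", mk, ".fasta")))
  }
  write_tsv_strict(sim$truth, p("truth.tsv"))
  ab <- abundances %||% setNames(rep(1 / length(sim$genomes),
                                     length(sim$genomes)), names(sim$genomes))
  write_tsv_strict(tibble(genome_id = names(ab), abundance = unname(ab)),
                   p("abundances.tsv"))
  invisible(list(hosts = hosts, genomes = sim$genomes,
                 gene_calls = sim$gene_calls, truth = sim$truth,
                 marker_refs = sim$marker_refs, reads = reads,
                 spacers = spacers,
                 paths = setNames(file.path(outdir, list.files(outdir)),
                                  list.files(outdir))))
}
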