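# Composition-based host prediction (tetranucleotide frequency
# signatures with calibrated distance tiers), CRISPR-spacer matching with
# stringent coverage/identity filters, and protein-level search against
# microbial genomes.

#' Tetranucleotide frequency profile of a sequence
#'
#' Overlapping 4-mer counts on the given strand only; windows containing
#' an ambiguous base (N) match no canonical 4-mer and are excluded, so
#' frequencies always sum to 1 over the counted windows.
#'
#' @param seq A nucleotide sequence (string, XString or single-element
#'   set) of length >= 4.
#' @param id Sequence id recorded in the profile.
#' @return A `tetra_profile` object: list with `sequence_id`, `counts`
#'   (named integer vector of the 256 4-mers in lexicographic order) and
#'   `freqs`.
#' @export
tetra_profile <- function(seq, id = NULL) {
  if (methods::is(seq, "XStringSet")) {
    id <- id %||% names(seq)[1]
    seq <- seq[[1]]
  }
  s <- Biostrings::DNAString(toupper(as.character(seq)))
  if (length(s) < 4) abort("sequence shorter than 4 bases")
  counts <- Biostrings::oligonucleotideFrequency(s, width = 4)
  total <- sum(counts)
  if (total == 0) abort("no valid 4-mer window (all windows ambiguous)")
  structure(list(sequence_id = id %||% "seq", counts = counts,
                 freqs = counts / total),
            class = "tetra_profile")
}

#' @export
print.tetra_profile <- function(x, ...) {
  cat("<tetra_profile> ", x$sequence_id, " (", sum(x$counts),
      " windows)\n", sep = "")
  invisible(x)
}

#' Euclidean distance between two tetranucleotide profiles
#'
#' @param p1,p2 `tetra_profile` objects.
#' @return The L2 distance between the frequency vectors.
#' @export
tetra_distance <- function(p1, p2) {
  sqrt(sum((p1$freqs - p2$freqs)^2))
}

#' Confidence tier of a composition-based host call
#'
#' Distance tiers calibrated on known virus-host pairs: below 4e-4 the
#' host family prediction is stated to be 95% accurate (`high_95`);
#' from 4e-4 up to (excluding) 1e-3, 84% accurate (`moderate_84`);
#' beyond that no prediction is made.  The thresholds are strict "below"
#' boundaries: a distance of exactly 4e-4 falls in the moderate tier and
#' exactly 1e-3 in `none`.
#'
#' @param distance Non-negative tetranucleotide distance.
#' @param high,moderate Tier boundaries.
#' @return List with `tier` (`"high_95"`, `"moderate_84"` or `"none"`)
#'   and `stated_accuracy` (95, 84 or `NA`).
#' @export
host_tier <- function(distance, high = 4e-4, moderate = 1e-3) {
  if (distance < 0) abort("distance must be non-negative")
  if (distance < high) {
    list(tier = "high_95", stated_accuracy = 95)
  } else if (distance < moderate) {
    list(tier = "moderate_84", stated_accuracy = 84)
  } else {
    list(tier = "none", stated_accuracy = NA_real_)
  }
}

#' Predict the host of a contig by composition
#'
#' Computes the tetranucleotide profile of the contig and of every
#' candidate host genome, picks the host at minimum Euclidean distance
#' (ties broken by alphabetical host id), and attaches the confidence
#' tier.
#'
#' @param contig A nucleotide sequence (named, or supply `contig_id`).
#' @param host_genomes A named [Biostrings::DNAStringSet].
#' @param contig_id Optional contig id for the output.
#' @param host_profiles Optional precomputed list of `tetra_profile`s for
#'   the hosts (avoids recomputation across many contigs).
#' @return One-row tibble: `contig_id`, `best_host_id`, `distance`,
#'   `tier`, `stated_accuracy`.
#' @export
predict_host <- function(contig, host_genomes, contig_id = NULL,
                         host_profiles = NULL) {
  if (length(host_genomes) == 0) abort("need at least one host genome")
  pc <- tetra_profile(contig, id = contig_id)
  hp <- host_profiles %||%
    lapply(seq_along(host_genomes),
           function(i) tetra_profile(host_genomes[[i]],
                                     id = names(host_genomes)[i]))
  d <- vapply(hp, function(p) tetra_distance(pc, p), 0)
  ids <- vapply(hp, function(p) p$sequence_id, "")
  ord <- order(d, ids)
  best <- ord[1]
  tr <- host_tier(d[best])
  tibble(contig_id = pc$sequence_id, best_host_id = ids[best],
         distance = d[best], tier = tr$tier,
         stated_accuracy = tr$stated_accuracy)
}

#' Match a CRISPR spacer against a contig
#'
#' Best local nucleotide alignment of the spacer (both strands) against
#' the contig.  The hit is significant (`passes`) when it covers more
#' than 80% of the spacer with more than 90% nucleotide identity;
#' `exact` flags full-length perfect matches (the only ones that can be
#' fully trusted on such short sequences).
#'
#' @param spacer A short nucleotide sequence (>= 15 bp).
#' @param contig The contig sequence.
#' @param scheme_nuc Nucleotide [scoring_scheme()].
#' @param spacer_id,contig_id Ids for the output.
#' @param min_coverage,min_identity Significance thresholds (strict
#'   "more than").
#' @return One-row tibble: `spacer_id`, `contig_id`, `coverage`,
#'   `identity`, `exact`, `passes`.
#' @export
match_spacer <- function(spacer, contig,
                         scheme_nuc = scoring_scheme("nucleotide"),
                         spacer_id = "spacer", contig_id = "contig",
                         min_coverage = 0.8, min_identity = 0.9) {
  sp <- toupper(as.character(spacer))
  if (nchar(sp) < 15) abort("spacer shorter than 15 bp")
  ctg <- as.character(contig)
  sp_rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(sp)))
  hits <- bind_rows(
    local_align(sp, ctg, scheme_nuc, query_id = spacer_id,
                subject_id = contig_id),
    local_align(sp_rc, ctg, scheme_nuc, query_id = spacer_id,
                subject_id = contig_id))
  best <- hits |> arrange(dplyr::desc(.data$bit_score)) |> dplyr::slice(1)
  aligned_spacer_pos <- sum(strsplit(best$aligned_query, "")[[1]] != "-")
  coverage <- aligned_spacer_pos / nchar(sp)
  identity <- best$identity
  tibble(spacer_id = spacer_id, contig_id = contig_id,
         coverage = coverage, identity = identity,
         exact = coverage == 1 && identity == 1,
         passes = coverage > min_coverage & identity > min_identity)
}

#' Match many spacers against many contigs
#'
#' @param spacers Named [Biostrings::DNAStringSet] of spacers.
#' @param contigs Named [Biostrings::DNAStringSet] of contigs.
#' @param scheme_nuc Nucleotide [scoring_scheme()].
#' @return Row-bound [match_spacer()] results for every spacer/contig
#'   pair.
#' @export
match_spacers <- function(spacers, contigs,
                          scheme_nuc = scoring_scheme("nucleotide")) {
  grid <- tidyr::expand_grid(spacer = names(spacers),
                             contig = names(contigs))
  purrr::pmap(grid, function(spacer, contig) {
    match_spacer(spacers[[spacer]], contigs[[contig]], scheme_nuc,
                 spacer_id = spacer, contig_id = contig)
  }) |> bind_rows()
}

#' Protein-level search of contig genes against microbial genomes
#'
#' Best qualifying hit per contig protein against a set of microbial
#' proteins, plus a per-genome summary of the maximum amino-acid
#' identity (genomes are identified by the prefix of the protein id up
#' to the last `_`, or supply `genome_of`).
#'
#' @param contig_proteins Named protein set.
#' @param microbial_proteins Named protein set.
#' @param scheme Protein [scoring_scheme()].
#' @param min_bit,max_evalue Hit qualification thresholds.
#' @param genome_of Optional named character vector mapping microbial
#'   protein id to genome id.
#' @return List with `hits` (best qualifying hit per contig protein) and
#'   `by_genome` (tibble `genome_id`, `max_identity`, `n_hits` sorted by
#'   identity).
#' @export
search_microbial_genomes <- function(contig_proteins, microbial_proteins,
                                     scheme = scoring_scheme("protein"),
                                     min_bit = 50, max_evalue = 0.001,
                                     genome_of = NULL) {
  qp <- as_stringset(contig_proteins, type = "AA")
  mp <- as_stringset(microbial_proteins, type = "AA")
  if (length(qp) == 0 || length(mp) == 0) abort("empty protein set")
  all_hits <- purrr::map(names(mp), function(mid) {
    msubj <- as.character(mp[[mid]])
    raw <- local_scores(qp, msubj, scheme)
    ok <- qualifies(raw, scheme, m = Biostrings::width(qp),
                    n = nchar(msubj), min_bit, max_evalue)
    if (!any(ok)) return(NULL)
    local_align_many(qp[ok], msubj, scheme, subject_id = mid)
  }) |> bind_rows() |>
    (\(d) if (nrow(d) == 0) empty_hit_table() else d)() |>
    filter_hits(min_bit, max_evalue)
  if (nrow(all_hits) == 0) {
    return(list(hits = all_hits,
                by_genome = tibble(genome_id = character(0),
                                   max_identity = numeric(0),
                                   n_hits = integer(0))))
  }
  best <- all_hits |>
    arrange(.data$query_id, dplyr::desc(.data$bit_score), .data$subject_id) |>
    group_by(.data$query_id) |> dplyr::slice(1) |> ungroup()
  gmap <- genome_of %||%
    setNames(sub("_[^_]*$", "", names(mp)), names(mp))
  by_genome <- all_hits |>
    mutate(genome_id = unname(gmap[.data$subject_id])) |>
    group_by(.data$genome_id) |>
    summarise(max_identity = max(.data$identity), n_hits = n()) |>
    arrange(dplyr::desc(.data$max_identity))
  list(hits = best, by_genome = by_genome)
}
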