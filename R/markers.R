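# Marker-gene screening: assign g23/g20/g17/phoH labels to predicted genes
# by best reference hit, then apply the contig-selection rules (contig
# length, and for the major capsid protein the presence of both the
# N-terminal and C-terminal domain regions of the reference alignment).

#' Configuration for marker screening
#'
#' @param refsets Named list mapping marker label (e.g. `"g23"`) to an
#'   [Biostrings::AAStringSet] of reference proteins.
#' @param min_bit,max_evalue Hit qualification thresholds (bit score
#'   strictly above, E-value strictly below).
#' @param min_contig_len Minimum contig length (bp) for a passing call.
#' @param n_domain_cols,c_domain_cols 1-based inclusive column ranges of
#'   the N- and C-terminal domains in the reference major-capsid-protein
#'   alignment.  Defaults are the published coordinates 122-162 and
#'   735-766.
#' @param min_domain_cov Fraction of in-range columns that must be
#'   non-gap for a domain to count as present.
#' @return A `marker_screen_config` object.
#' @export
marker_screen_config <- function(refsets, min_bit = 50, max_evalue = 0.001,
                                 min_contig_len = 10000,
                                 n_domain_cols = c(122, 162),
                                 c_domain_cols = c(735, 766),
                                 min_domain_cov = 0.8) {
  stopifnot(is.list(refsets), length(refsets) > 0, !is.null(names(refsets)))
  if (any(vapply(refsets, length, 0L) == 0)) abort("empty marker refset")
  stopifnot(min_bit > 0, max_evalue > 0, min_contig_len > 0,
            min_domain_cov > 0, min_domain_cov <= 1)
  structure(list(refsets = refsets, min_bit = min_bit,
                 max_evalue = max_evalue, min_contig_len = min_contig_len,
                 n_domain_cols = n_domain_cols, c_domain_cols = c_domain_cols,
                 min_domain_cov = min_domain_cov),
            class = "marker_screen_config")
}

#' Screen predicted genes for marker-gene identity
#'
#' Each gene is assigned at most one marker label: the refset giving the
#' best qualifying bit score (`bit > min_bit`, `E < max_evalue`); ties go
#' to the label whose best reference id sorts first.  A call `passes`
#' when its contig is at least `min_contig_len` bp and, for the major
#' capsid protein (`g23`) when a reference alignment is supplied, both
#' domain regions are present (see [check_domains()]).
#'
#' @param gene_calls Gene-call tibble with `protein` translations.
#' @param cfg A [marker_screen_config()].
#' @param contig_lengths Named integer vector of contig lengths (bp).
#' @param scheme Protein [scoring_scheme()].
#' @param reference_msa Optional `msa` of reference g23 proteins used for
#'   the domain check; when `NULL` the domain flags default to `TRUE`.
#' @return A tibble with one row per marker-labelled gene: `gene_id`,
#'   `contig_id`, `marker`, `bit_score`, `evalue`, `identity`,
#'   `ref_id`, `n_present`, `c_present`, `passes`.
#' @export
screen_markers <- function(gene_calls, cfg, contig_lengths,
                           scheme = scoring_scheme("protein"),
                           reference_msa = NULL) {
  stopifnot(inherits(cfg, "marker_screen_config"))
  genes <- gene_calls |> filter(!is.na(.data$protein))
  if (nrow(genes) == 0) return(empty_marker_table())
  prot <- Biostrings::AAStringSet(setNames(genes$protein, genes$gene_id))

  # score-only pass over every (gene, reference) pair, then full
  # alignments only for each gene's best qualifying reference
  scored <- purrr::imap(cfg$refsets, function(refs, label) {
    purrr::map(names(refs), function(rid) {
      rseq <- as.character(refs[[rid]])
      raw <- local_scores(prot, rseq, scheme)
      ka <- bit_and_evalue(raw, scheme, m = Biostrings::width(prot),
                           n = nchar(rseq))
      tibble(query_id = names(prot), subject_id = rid, marker = label,
             raw_score = raw, bit_score = ka$bit_score,
             evalue = ka$evalue)
    }) |> bind_rows()
  }) |> bind_rows()
  best_ref <- scored |>
    filter(.data$bit_score > cfg$min_bit, .data$evalue < cfg$max_evalue) |>
    arrange(.data$query_id, dplyr::desc(.data$bit_score), .data$subject_id) |>
    group_by(.data$query_id) |>
    dplyr::slice(1) |>
    ungroup()
  if (nrow(best_ref) == 0) return(empty_marker_table())
  ref_seqs <- unlist(lapply(cfg$refsets, function(r)
    setNames(as.character(r), names(r))), use.names = TRUE)
  names(ref_seqs) <- sub("^[^.]*\\.", "", names(ref_seqs))
  best <- best_ref |>
    group_by(.data$subject_id) |>
    (\(d) dplyr::group_split(d))() |>
    purrr::map(function(grp) {
      full <- local_align_many(prot[grp$query_id],
                               ref_seqs[[grp$subject_id[1]]], scheme,
                               subject_id = grp$subject_id[1])
      full$marker <- grp$marker[1]
      full
    }) |> bind_rows()

  out <- best |>
    select(gene_id = "query_id", marker = "marker",
           bit_score = "bit_score", evalue = "evalue",
           identity = "identity", ref_id = "subject_id") |>
    left_join(genes |> select("gene_id", "contig_id", "protein"),
              by = "gene_id")

  dom <- tibble(gene_id = out$gene_id, n_present = TRUE, c_present = TRUE)
  if (!is.null(reference_msa)) {
    g23 <- out |> filter(.data$marker == "g23")
    if (nrow(g23) > 0) {
      flags <- check_domains(setNames(g23$protein, g23$gene_id),
                             reference_msa, cfg)
      dom <- dom |>
        dplyr::rows_update(flags |> rename(gene_id = "id"), by = "gene_id")
    }
  }
  clen <- contig_lengths[out$contig_id]
  out |>
    left_join(dom, by = "gene_id") |>
    mutate(contig_length = as.integer(unname(clen)),
           passes = .data$contig_length >= cfg$min_contig_len &
             (.data$marker != "g23" |
                (.data$n_present & .data$c_present))) |>
    select(-"protein")
}

empty_marker_table <- function() {
  tibble(gene_id = character(0), marker = character(0),
         bit_score = numeric(0), evalue = numeric(0), identity = numeric(0),
         ref_id = character(0), contig_id = character(0),
         n_present = logical(0), c_present = logical(0),
         contig_length = integer(0), passes = logical(0))
}

#' Check presence of the N- and C-terminal domain regions
#'
#' Aligns candidate proteins into the reference alignment's column space
#' (see [align_to_reference()]) and declares a domain present when at
#' least `min_domain_cov` of the columns in its range are non-gap in the
#' candidate row.  Ranges are 1-based inclusive reference-MSA columns.
#'
#' @param candidates Named character vector (or AAStringSet) of candidate
#'   proteins.
#' @param reference_msa The reference `msa`.
#' @param cfg A [marker_screen_config()] carrying the column ranges.
#' @return A tibble with columns `id`, `n_present`, `c_present`.
#' @export
check_domains <- function(candidates, reference_msa, cfg) {
  nc <- msa_ncol(reference_msa)
  rng <- list(n = cfg$n_domain_cols, c = cfg$c_domain_cols)
  for (r in rng) {
    if (r[1] < 1 || r[2] > nc || r[1] > r[2]) {
      abort("domain column range outside the reference alignment")
    }
  }
  placed <- align_to_reference(candidates, reference_msa)
  m <- as.matrix.msa(placed)
  cov <- function(range) {
    cols <- m[, range[1]:range[2], drop = FALSE]
    rowMeans(cols != "-") >= cfg$min_domain_cov
  }
  tibble(id = names(placed),
         n_present = unname(cov(rng$n)),
         c_present = unname(cov(rng$c)))
}

#' Relative mean length difference between two groups
#'
#' `mean(a) / mean(b) - 1`: e.g. 0.15 means group A sequences are on
#' average 15 percent longer than group B.
#'
#' @param group_a_lengths,group_b_lengths Non-empty numeric vectors.
#' @return A single number.
#' @export
marker_length_ratio <- function(group_a_lengths, group_b_lengths) {
  if (length(group_a_lengths) == 0 || length(group_b_lengths) == 0) {
    abort("both groups must be non-empty")
  }
  mean(group_a_lengths) / mean(group_b_lengths) - 1
}
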