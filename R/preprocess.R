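# Elementary read preprocessing: 3'-end quality trimming, exact duplicate
# removal, and a naive ORF finder used when gene calls are not supplied.

#' Quality-trim reads from the 3' end
#'
#' Removes the trailing run of bases whose phred score is below `cutoff`
#' (3'-only trimming); reads shorter than `min_len` after trimming are
#' dropped.
#'
#' @param reads A [Biostrings::QualityScaledDNAStringSet].
#' @param cutoff Phred cutoff; trailing bases with quality `< cutoff` are
#'   removed.
#' @param min_len Minimum retained length; shorter results are discarded.
#' @return A [Biostrings::QualityScaledDNAStringSet] of the surviving,
#'   trimmed reads (possibly empty).
#' @export
quality_trim <- function(reads, cutoff = 30, min_len = 50) {
  if (!methods::is(reads, "QualityScaledDNAStringSet")) {
    abort("quality_trim() needs reads with quality scores (FASTQ input)")
  }
  quals <- phred_scores(reads)
  keep_len <- vapply(quals, function(q) {
    ok <- which(q >= cutoff)
    if (length(ok) == 0) 0L else max(ok)
  }, integer(1))
  sel <- keep_len >= min_len
  if (!any(sel)) {
    return(reads[0])
  }
  Biostrings::subseq(reads[sel], start = 1L, end = keep_len[sel])
}

#' Remove exact full-length duplicate sequences
#'
#' Among records with byte-identical sequence, the record with the
#' lexicographically smallest id is kept.  Prefix/containment duplicates
#' are not considered duplicates.
#'
#' @param records A named [Biostrings::XStringSet] or named character
#'   vector.
#' @return A list with `kept` (string set in original order, duplicates
#'   dropped) and `removed` (tibble with columns `duplicate_id`,
#'   `kept_id`).
#' @export
dedupe_exact <- function(records) {
  x <- as_stringset(records)
  s <- as.character(x)
  ids <- names(x)
  keeper <- vapply(split(ids, s), function(g) min(g), "")
  kept_ids <- unname(keeper[s])
  removed <- tibble(duplicate_id = ids[ids != kept_ids],
                    kept_id = kept_ids[ids != kept_ids]) |>
    arrange(.data$duplicate_id)
  list(kept = x[ids == kept_ids], removed = removed)
}

GENETIC_CODE_STOPS <- c("TAA", "TAG", "TGA")

translate_nt <- function(nt) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(nt),
                                     if.fuzzy.codon = "X", no.init.codon = TRUE))
}

#' Find open reading frames on both strands
#'
#' Reports every maximal ATG-to-stop ORF of at least `min_len_aa` codons
#' in all six frames, using the standard genetic code.  Coordinates are
#' 0-based half-open on the forward strand and span start codon through the
#' last sense codon; the stop codon is excluded, so the protein length is
#' exactly `(end - start) / 3`.
#'
#' @param contig A [Biostrings::DNAString], single-element set, or string.
#' @param contig_id Id recorded in the output (defaults to the sequence
#'   name or `"contig"`).
#' @param min_len_aa Minimum protein length in residues.
#' @return A gene-call tibble (see [read_gene_calls()]) ordered by `start`;
#'   `protein` excludes the stop codon.
#' @export
find_orfs <- function(contig, contig_id = NULL, min_len_aa = 60) {
  if (methods::is(contig, "XStringSet")) {
    contig_id <- contig_id %||% names(contig)[1]
    contig <- contig[[1]]
  }
  s <- toupper(as.character(contig))
  contig_id <- contig_id %||% "contig"
  L <- nchar(s)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

  scan_strand <- function(seqstr, strand) {
    out <- list()
    for (frame in 0:2) {
      n_cod <- (nchar(seqstr) - frame) %/% 3
      if (n_cod < 1) next
      codons <- substring(seqstr, frame + 1 + 3 * (seq_len(n_cod) - 1),
                          frame + 3 * seq_len(n_cod))
      is_start <- codons == "ATG"
      is_stop <- codons %in% GENETIC_CODE_STOPS
      # maximal ORFs: for each stop, the earliest ATG after the previous stop
      prev_stop <- 0L
      i <- 1L
      while (i <= n_cod) {
        if (is_stop[i]) {
          starts <- which(is_start[(prev_stop + 1L):(i - 1L)]) + prev_stop
          if (length(starts) > 0) {
            st <- starts[1]
            len_aa <- i - st  # codons before the stop
            if (len_aa >= min_len_aa) {
              from <- frame + 3L * (st - 1L)        # 0-based
              to <- frame + 3L * (i - 1L)           # stop codon excluded
              out[[length(out) + 1L]] <- c(from, to)
            }
          }
          prev_stop <- i
        }
        i <- i + 1L
      }
    }
    if (length(out) == 0) return(NULL)
    m <- do.call(rbind, out)
    if (strand == "+") {
      tibble(start = m[, 1], end = m[, 2], strand = "+")
    } else {
      # map reverse-complement coordinates back onto the forward axis
      tibble(start = L - m[, 2], end = L - m[, 1], strand = "-")
    }
  }

  fwd <- scan_strand(s, "+")
  rev <- scan_strand(rc, "-")
  tb <- bind_rows(fwd, rev)
  if (is.null(tb) || nrow(tb) == 0) {
    return(tibble(contig_id = character(0), start = integer(0),
                  end = integer(0), strand = character(0),
                  gene_id = character(0), protein = character(0),
                  annotation = character(0)))
  }
  tb <- tb |> arrange(.data$start, .data$end, .data$strand)
  nt <- vapply(seq_len(nrow(tb)), function(i) {
    sub <- substring(s, tb$start[i] + 1, tb$end[i])
    if (tb$strand[i] == "-") {
      sub <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub)))
    }
    sub
  }, "")
  prot <- translate_nt(nt)
  tibble(
    contig_id = contig_id,
    start = as.integer(tb$start), end = as.integer(tb$end),
    strand = tb$strand,
    gene_id = sprintf("%s_orf%03d", contig_id, seq_len(nrow(tb))),
    protein = prot,
    annotation = NA_character_
  )
}
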