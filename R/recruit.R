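# Read recruitment to contigs: translated (tblastx-like best-frame-pair)
# or nucleotide local alignment, presence calls, windowed coverage
# profiles, and the freshwater-vs-seawater style group comparison.

#' Configuration for read recruitment
#'
#' @param subsample_n Reads subsampled per virome before recruitment.
#' @param min_bit,max_evalue Hit qualification thresholds.
#' @param plot_min_identity Identity filter applied at plot time
#'   (amino-acid identity in translated mode).
#' @param presence_min_reads Minimum distinct recruited reads for a
#'   presence call.
#' @param n_windows Number of coverage windows tiling each contig.
#' @param mode `"translated"` (best frame-pair protein alignment) or
#'   `"nucleotide"`.
#' @param seed Integer seed for subsampling.
#' @return A `recruit_config` object.
#' @export
recruit_config <- function(subsample_n = 2500000, min_bit = 50,
                           max_evalue = 0.001, plot_min_identity = 0.60,
                           presence_min_reads = 100, n_windows = 30,
                           mode = c("translated", "nucleotide"), seed = 1) {
  mode <- match.arg(mode)
  stopifnot(subsample_n > 0, min_bit > 0, max_evalue > 0,
            presence_min_reads > 0, n_windows >= 1)
  structure(list(subsample_n = subsample_n, min_bit = min_bit,
                 max_evalue = max_evalue,
                 plot_min_identity = plot_min_identity,
                 presence_min_reads = presence_min_reads,
                 n_windows = n_windows, mode = mode, seed = seed),
            class = "recruit_config")
}

#' Uniformly subsample reads without replacement
#'
#' @param reads A [Biostrings::XStringSet] (or quality-scaled set).
#' @param n Target sample size; when `length(reads) <= n` all reads are
#'   returned and attribute `subsampled` is `FALSE`.
#' @param seed Integer seed.
#' @return The sampled read set with logical attribute `subsampled`.
#' @export
subsample_reads <- function(reads, n, seed = 1) {
  if (length(reads) <= n) {
    attr(reads, "subsampled") <- FALSE
    return(reads)
  }
  set.seed(seed)
  out <- reads[sort(sample.int(length(reads), n))]
  attr(out, "subsampled") <- TRUE
  out
}

six_frames <- function(nt) {
  # returns character vector of 6 protein translations (frames f1..f3,r1..r3)
  s <- as.character(nt)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  frames <- c(lapply(0:2, function(f) substring(s, f + 1)),
              lapply(0:2, function(f) substring(rc, f + 1)))
  vapply(frames, function(x) {
    trimmed <- substring(x, 1, 3 * (nchar(x) %/% 3))
    if (nchar(trimmed) < 3) "" else translate_nt(trimmed)
  }, "")
}

#' Recruit reads to contigs
#'
#' In translated mode each read/contig pair is scored by the best local
#' protein alignment over all 6 x 6 frame combinations (stop codons are
#' ordinary `*` residues and score accordingly); in nucleotide mode by
#' direct local nucleotide alignment of both read strands.  One best hit
#' per read per contig passing the bit-score and E-value thresholds is
#' reported; `s_start` is the hit start in contig nucleotide coordinates.
#'
#' @param reads A named nucleotide read set.
#' @param contigs A named [Biostrings::DNAStringSet].
#' @param cfg A [recruit_config()].
#' @param scheme Optional [scoring_scheme()] override (protein scheme for
#'   translated mode, nucleotide otherwise).
#' @return A hit tibble: `read_id`, `contig_id`, `bit_score`, `evalue`,
#'   `identity`, `s_start` (0-based nucleotide position on the contig),
#'   `frame_read`, `frame_contig` (`NA` in nucleotide mode).
#' @export
recruit_reads <- function(reads, contigs, cfg = recruit_config(),
                          scheme = NULL) {
  reads <- Biostrings::DNAStringSet(setNames(as.character(reads),
                                             names(reads)))
  out <- list()
  if (cfg$mode == "translated") {
    scheme <- scheme %||% scoring_scheme("protein")
    read_frames <- lapply(seq_along(reads),
                          function(i) six_frames(reads[[i]]))
    for (cid in names(contigs)) {
      ctg <- contigs[[cid]]
      ctg_frames <- six_frames(ctg)
      Lnt <- length(ctg)
      # score-only sweep over all 6x6 frame pairs to find each read's
      # best combination, then full alignments for qualifying reads only
      best_raw <- rep(-Inf, length(reads))
      best_fr <- best_fc <- rep(NA_integer_, length(reads))
      for (fc in seq_len(6)) {
        prot_ctg <- ctg_frames[fc]
        if (nchar(prot_ctg) < 10) next
        for (fr in seq_len(6)) {
          qs <- vapply(read_frames, `[[`, "", fr)
          ok <- nchar(qs) >= 5
          if (!any(ok)) next
          raw <- rep(-Inf, length(reads))
          raw[ok] <- local_scores(
            Biostrings::AAStringSet(setNames(qs[ok], names(reads)[ok])),
            prot_ctg, scheme)
          upd <- raw > best_raw
          best_raw[upd] <- raw[upd]
          best_fr[upd] <- fr
          best_fc[upd] <- fc
        }
      }
      cand <- which(is.finite(best_raw))
      if (length(cand) == 0) next
      qlen <- vapply(cand, function(i) nchar(read_frames[[i]][best_fr[i]]),
                     0)
      okc <- qualifies(pmax(best_raw[cand], 0), scheme, m = qlen,
                       n = nchar(ctg_frames)[best_fc[cand]],
                       cfg$min_bit, cfg$max_evalue)
      if (!any(okc)) next
      best <- purrr::map(cand[okc], function(i) {
        h <- local_align(read_frames[[i]][best_fr[i]],
                         ctg_frames[best_fc[i]], scheme,
                         query_id = names(reads)[i], subject_id = cid)
        h$frame_read <- best_fr[i]
        h$frame_contig <- best_fc[i]
        h
      }) |> bind_rows() |>
        filter_hits(cfg$min_bit, cfg$max_evalue)
      if (nrow(best) == 0) next
      # protein position on a contig frame -> nucleotide position
      fwd <- best$frame_contig <= 3
      off <- ((best$frame_contig - 1) %% 3)
      nt_start <- ifelse(fwd, off + 3 * best$s_start,
                         Lnt - (off + 3 * best$s_end))
      out[[cid]] <- tibble(read_id = best$query_id, contig_id = cid,
                           bit_score = best$bit_score,
                           evalue = best$evalue, identity = best$identity,
                           s_start = as.integer(pmax(0, nt_start)),
                           frame_read = best$frame_read,
                           frame_contig = best$frame_contig)
    }
  } else {
    scheme <- scheme %||% scoring_scheme("nucleotide")
    rc <- Biostrings::reverseComplement(reads)
    for (cid in names(contigs)) {
      ctg <- as.character(contigs[[cid]])
      raw_f <- local_scores(reads, ctg, scheme)
      raw_r <- local_scores(rc, ctg, scheme)
      raw <- pmax(raw_f, raw_r)
      fwd <- raw_f >= raw_r
      ok <- qualifies(raw, scheme, m = Biostrings::width(reads),
                      n = nchar(ctg), cfg$min_bit, cfg$max_evalue)
      if (!any(ok)) next
      both <- bind_rows(
        if (any(ok & fwd)) local_align_many(reads[ok & fwd], ctg, scheme,
                                            subject_id = cid),
        if (any(ok & !fwd)) local_align_many(rc[ok & !fwd], ctg, scheme,
                                             subject_id = cid)) |>
        filter_hits(cfg$min_bit, cfg$max_evalue)
      if (nrow(both) == 0) next
      out[[cid]] <- tibble(read_id = both$query_id, contig_id = cid,
                           bit_score = both$bit_score,
                           evalue = both$evalue, identity = both$identity,
                           s_start = both$s_start,
                           frame_read = NA_integer_,
                           frame_contig = NA_integer_)
    }
  }
  if (length(out) == 0) {
    return(tibble(read_id = character(0), contig_id = character(0),
                  bit_score = numeric(0), evalue = numeric(0),
                  identity = numeric(0), s_start = integer(0),
                  frame_read = integer(0), frame_contig = integer(0)))
  }
  bind_rows(out)
}

#' Presence call for a contig in a virome
#'
#' A contig is called present when at least `presence_min_reads` distinct
#' reads are recruited to it (bit-score/E-value thresholds only; the
#' plot-time identity filter is not applied here).
#'
#' @param hit_table Output of [recruit_reads()].
#' @param contig_id Contig to test.
#' @param cfg A [recruit_config()].
#' @return Logical.
#' @export
presence_call <- function(hit_table, contig_id, cfg = recruit_config()) {
  n <- hit_table |> filter(.data$contig_id == !!contig_id) |>
    distinct(.data$read_id) |> nrow()
  n >= cfg$presence_min_reads
}

#' Window boundaries tiling a contig
#'
#' Window `i` (0-based) spans `[floor(i*L/n), floor((i+1)*L/n))`; the
#' windows tile `[0, L)` exactly.
#'
#' @param L Contig length (>= number of windows).
#' @param n_windows Number of windows.
#' @return Tibble with `window` (1-based), `start`, `end`.
#' @export
coverage_windows <- function(L, n_windows = 30) {
  if (L < n_windows) abort("contig shorter than the number of windows")
  bounds <- floor((0:n_windows) * L / n_windows)
  tibble(window = seq_len(n_windows), start = as.integer(bounds[-length(bounds)]),
         end = as.integer(bounds[-1]))
}

#' Windowed coverage profile of a contig
#'
#' Assigns each recruited read to the window containing its alignment
#' start and reports raw per-window counts plus the normalised coverage
#' (total aligned bp divided by contig length, approximating aligned bp
#' by read span on the contig).
#'
#' @param hit_table Output of [recruit_reads()].
#' @param contig_id Contig id.
#' @param contig_len Contig length in bp.
#' @param cfg A [recruit_config()].
#' @param read_len Nominal read length (bp) used for the aligned-bp
#'   estimate; defaults to 100.
#' @return A `coverage_profile` object: list with `contig_id`, `windows`
#'   (tibble `window`, `start`, `end`, `count`), `n_reads`,
#'   `normalized_coverage`.
#' @export
coverage_profile <- function(hit_table, contig_id, contig_len,
                             cfg = recruit_config(), read_len = NULL) {
  win <- coverage_windows(contig_len, cfg$n_windows)
  hits <- hit_table |> filter(.data$contig_id == !!contig_id)
  idx <- findInterval(hits$s_start, win$start)
  idx[idx < 1] <- 1; idx[idx > cfg$n_windows] <- cfg$n_windows
  counts <- tabulate(idx, nbins = cfg$n_windows)
  aligned_bp <- nrow(hits) * (read_len %||% 100)
  structure(list(contig_id = contig_id,
                 windows = win |> mutate(count = counts),
                 n_reads = nrow(hits),
                 normalized_coverage = aligned_bp / contig_len),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat("<coverage_profile> ", x$contig_id, ": ", x$n_reads, " reads, ",
      "normalised coverage ", sprintf("%.3f", x$normalized_coverage),
      "\n", sep = "")
  invisible(x)
}

#' @rdname coverage_profile
#' @param x,object A `coverage_profile`.
#' @param ... Unused.
#' @export
tidy.coverage_profile <- function(x, ...) {
  x$windows |> mutate(contig_id = x$contig_id, .before = 1)
}

#' @rdname coverage_profile
#' @export
autoplot.coverage_profile <- function(object, ...) {
  ggplot2::ggplot(object$windows,
                  ggplot2::aes(.data$start, log10(.data$count + 1))) +
    ggplot2::geom_step() +
    ggplot2::labs(x = paste0("position on ", object$contig_id, " (bp)"),
                  y = "log10(reads + 1)") +
    ggplot2::theme_minimal()
}

#' Compare contig coverage between two groups of viromes
#'
#' Welch two-sample t-test on per-virome coverage values.  Degenerate
#' inputs follow fixed conventions: both groups constant and equal means
#' gives p = 1; constant groups with different means give p = 0 with
#' attribute `degenerate = TRUE`.
#'
#' @param coverages_group1,coverages_group2 Numeric vectors (n >= 2
#'   each).
#' @return Tibble with `t`, `p`, `df`, `mean1`, `mean2`.
#' @export
env_comparison <- function(coverages_group1, coverages_group2) {
  g1 <- coverages_group1; g2 <- coverages_group2
  if (length(g1) < 2 || length(g2) < 2) abort("each group needs n >= 2")
  if (sd(g1) == 0 && sd(g2) == 0) {
    if (mean(g1) == mean(g2)) {
      return(tibble(t = 0, p = 1, df = NA_real_, mean1 = mean(g1),
                    mean2 = mean(g2)))
    }
    out <- tibble(t = sign(mean(g1) - mean(g2)) * Inf, p = 0,
                  df = NA_real_, mean1 = mean(g1), mean2 = mean(g2))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  tt <- t.test(g1, g2, var.equal = FALSE)
  tibble(t = unname(tt$statistic), p = tt$p.value,
         df = unname(tt$parameter), mean1 = mean(g1), mean2 = mean(g2))
}
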