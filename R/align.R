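# Pairwise and multiple alignment with BLAST-like score statistics.
#
# local_align() is an exact affine-gap Smith-Waterman (Biostrings dynamic
# programming); bit scores and E-values follow the Karlin-Altschul
# formulas S' = (lambda*S - ln K)/ln 2, E = m*n*2^-S'.  The search space is
# per pair (m x n), not database-wide.

#' Scoring scheme for pairwise alignment
#'
#' Bundles the substitution matrix, affine gap penalties and
#' Karlin-Altschul constants used for raw-score, bit-score and E-value
#' computation.  Protein defaults are BLOSUM62 with gap open 11 / extend 1
#' and the standard gapped constants lambda = 0.267, K = 0.041; nucleotide
#' defaults are match +2 / mismatch -3, gap open 5 / extend 2, lambda =
#' 0.625, K = 0.41.
#'
#' @param type `"protein"` or `"nucleotide"`.
#' @param gap_open,gap_extend Non-negative gap penalties.
#' @param lambda,K Karlin-Altschul constants (> 0).
#' @param match,mismatch Nucleotide match/mismatch scores (ignored for
#'   protein).
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(type = c("protein", "nucleotide"),
                           gap_open = NULL, gap_extend = NULL,
                           lambda = NULL, K = NULL,
                           match = 2, mismatch = -3) {
  type <- match.arg(type)
  if (type == "protein") {
    gap_open <- gap_open %||% 11
    gap_extend <- gap_extend %||% 1
    lambda <- lambda %||% 0.267
    K <- K %||% 0.041
    mat <- get_blosum62()
  } else {
    gap_open <- gap_open %||% 5
    gap_extend <- gap_extend %||% 2
    lambda <- lambda %||% 0.625
    K <- K %||% 0.41
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                    mismatch = mismatch,
                                                    baseOnly = FALSE)
  }
  stopifnot(gap_open >= 0, gap_extend >= 0, lambda > 0, K > 0)
  structure(list(type = type, matrix = mat, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K),
            class = "scoring_scheme")
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Bit score and E-value from a raw alignment score
#'
#' Karlin-Altschul statistics: `bit = (lambda * S - log(K)) / log(2)` and
#' `E = m * n * 2^-bit`.  E is strictly decreasing in S and exactly linear
#' in both sequence lengths.
#'
#' @param raw_score Non-negative raw alignment score.
#' @param scheme A [scoring_scheme()].
#' @param m,n Query and subject lengths defining the search space.
#' @return A list with `bit_score` and `evalue`.
#' @export
bit_and_evalue <- function(raw_score, scheme, m, n) {
  stopifnot(raw_score >= 0, m > 0, n > 0)
  bit <- (scheme$lambda * raw_score - log(scheme$K)) / log(2)
  list(bit_score = bit, evalue = m * n * 2^(-bit))
}

empty_hit_table <- function() {
  tibble(query_id = character(0), subject_id = character(0),
         raw_score = numeric(0), bit_score = numeric(0), evalue = numeric(0),
         identity = numeric(0), q_start = integer(0), q_end = integer(0),
         s_start = integer(0), s_end = integer(0),
         aligned_query = character(0), aligned_subject = character(0))
}

aln_identity <- function(aq, as_) {
  qs <- strsplit(aq, "")
  ss <- strsplit(as_, "")
  unname(purrr::map2_dbl(qs, ss, function(q, s) {
    cols <- !(q == "-" & s == "-")
    if (!any(cols)) return(0)
    sum(q[cols] == s[cols] & q[cols] != "-") / sum(cols)
  }))
}

#' Optimal local alignment of many queries against one subject
#'
#' Exact Smith-Waterman local alignment with affine gap penalties,
#' vectorised over queries.  Raw scores below zero (no positive-scoring
#' local alignment exists) are reported as score 0 with an empty alignment.
#'
#' @param queries A named [Biostrings::XStringSet] (or named character
#'   vector) of query sequences.
#' @param subject A single subject sequence (string or XString).
#' @param scheme A [scoring_scheme()] matching the molecule type.
#' @param subject_id Id used in the output table.
#' @return A hit tibble with one row per query: `query_id`, `subject_id`,
#'   `raw_score`, `bit_score`, `evalue`, `identity`, `q_start`, `q_end`,
#'   `s_start`, `s_end` (0-based half-open), `aligned_query`,
#'   `aligned_subject`.
#' @export
local_align_many <- function(queries, subject, scheme,
                             subject_id = "subject") {
  qs <- as_stringset(queries,
                     type = if (scheme$type == "protein") "AA" else "DNA")
  subj <- as.character(subject)
  if (length(qs) == 0) return(empty_hit_table())
  if (nchar(subj) == 0 || any(Biostrings::width(qs) == 0)) {
    abort("empty sequence passed to local alignment")
  }
  pa <- Biostrings::pairwiseAlignment(
    qs, if (scheme$type == "protein") Biostrings::AAString(subj) else
      Biostrings::DNAString(subj),
    type = "local", substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend
  )
  raw <- Biostrings::score(pa)
  aq <- unname(as.character(Biostrings::alignedPattern(pa)))
  as_ <- unname(as.character(Biostrings::alignedSubject(pa)))
  qst <- Biostrings::start(Biostrings::pattern(pa)) - 1L
  qen <- Biostrings::end(Biostrings::pattern(pa))
  sst <- Biostrings::start(Biostrings::subject(pa)) - 1L
  sen <- Biostrings::end(Biostrings::subject(pa))
  ident <- aln_identity(aq, as_)
  neg <- raw < 0
  raw[neg] <- 0
  aq[neg] <- ""; as_[neg] <- ""; ident[neg] <- 0
  qst[neg] <- 0L; qen[neg] <- 0L; sst[neg] <- 0L; sen[neg] <- 0L
  ka <- bit_and_evalue(raw, scheme, m = Biostrings::width(qs),
                       n = nchar(subj))
  tibble(
    query_id = names(qs), subject_id = subject_id,
    raw_score = as.numeric(raw), bit_score = ka$bit_score,
    evalue = ka$evalue, identity = ident,
    q_start = qst, q_end = qen, s_start = sst, s_end = sen,
    aligned_query = aq, aligned_subject = as_
  )
}

#' Optimal local alignment scores of many queries against one subject
#'
#' Score-only variant of [local_align_many()] (no traceback), an order of
#' magnitude faster; used as a prefilter before full alignments are
#' computed for qualifying pairs.
#'
#' @inheritParams local_align_many
#' @return Named numeric vector of raw Smith-Waterman scores (negative
#'   optima clamped to 0).
#' @export
local_scores <- function(queries, subject, scheme) {
  qs <- as_stringset(queries,
                     type = if (scheme$type == "protein") "AA" else "DNA")
  subj <- if (scheme$type == "protein") {
    Biostrings::AAString(as.character(subject))
  } else {
    Biostrings::DNAString(as.character(subject))
  }
  s <- Biostrings::pairwiseAlignment(
    qs, subj, type = "local", substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
    scoreOnly = TRUE)
  setNames(pmax(as.numeric(s), 0), names(qs))
}

# logical vector: does each query have a qualifying hit against subject?
qualifies <- function(raw, scheme, m, n, min_bit, max_evalue) {
  ka <- bit_and_evalue(raw, scheme, m, n)
  ka$bit_score > min_bit & ka$evalue < max_evalue
}

#' Optimal local alignment of two sequences
#'
#' @param a,b Sequences (strings or XString objects); `a` is the query.
#' @param scheme A [scoring_scheme()].
#' @param query_id,subject_id Ids used in the output row.
#' @return A one-row hit tibble (see [local_align_many()]).
#' @export
local_align <- function(a, b, scheme, query_id = "query",
                        subject_id = "subject") {
  qs <- setNames(as.character(a), query_id)
  local_align_many(qs, as.character(b), scheme, subject_id = subject_id)
}

#' Apply bit-score and E-value thresholds to a hit table
#'
#' @param hits A hit tibble.
#' @param min_bit Minimum bit score (exclusive: `bit_score > min_bit`).
#' @param max_evalue Maximum E-value (exclusive: `evalue < max_evalue`).
#' @return The qualifying rows.
#' @export
filter_hits <- function(hits, min_bit = 50, max_evalue = 0.001) {
  hits |> filter(.data$bit_score > min_bit, .data$evalue < max_evalue)
}

# ---- MSA ----------------------------------------------------------------

#' Multiple sequence alignment container
#'
#' A light container for an aligned set of sequences: a named character
#' vector of equal-length gapped rows, class `msa`.  Ungapping any row
#' reproduces its input sequence.
#'
#' @param rows Named character vector of gapped sequences (equal lengths).
#' @return An `msa` object.
#' @export
new_msa <- function(rows) {
  stopifnot(is.character(rows), !is.null(names(rows)))
  if (length(unique(nchar(rows))) > 1) {
    abort("all MSA rows must have equal length")
  }
  structure(rows, class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("<msa> ", length(x), " sequences x ", msa_ncol(x), " columns\n",
      sep = "")
  invisible(x)
}

#' Number of columns of an MSA
#' @param msa An `msa` object.
#' @return Integer column count.
#' @export
msa_ncol <- function(msa) if (length(msa) == 0) 0L else nchar(msa[[1]])

#' MSA as a character matrix (rows x columns)
#' @param x An `msa` object.
#' @param ... Unused.
#' @return Character matrix with one row per sequence.
#' @export
as.matrix.msa <- function(x, ...) {
  m <- do.call(rbind, strsplit(unclass(x), ""))
  rownames(m) <- names(x)
  m
}

#' Read / write aligned FASTA
#'
#' @param path File path.
#' @param msa An `msa` object.
#' @param type `"DNA"` or `"AA"` (reading only; gaps allowed).
#' @return `read_msa()` returns an `msa`; `write_msa()` returns `path`
#'   invisibly.
#' @export
read_msa <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  x <- tryCatch(
    if (type == "DNA") Biostrings::readDNAStringSet(path) else
      Biostrings::readAAStringSet(path),
    error = function(e) abort(paste0("aligned FASTA parse error: ",
                                     conditionMessage(e))))
  names(x) <- sub("\\s.*$", "", names(x))
  new_msa(setNames(toupper(as.character(x)), names(x)))
}

#' @rdname read_msa
#' @export
write_msa <- function(msa, path) {
  writeLines(paste0(">", names(msa), "\n", unclass(msa)), path)
  invisible(path)
}

run_mafft <- function(args, input, input2 = NULL) {
  if (Sys.which("mafft") == "") {
    abort("mafft executable not found on PATH")
  }
  fin <- tempfile(fileext = ".fasta")
  on.exit(unlink(fin), add = TRUE)
  write_fasta(input, fin)
  files <- fin
  if (!is.null(input2)) {
    fin2 <- tempfile(fileext = ".fasta")
    on.exit(unlink(fin2), add = TRUE)
    write_fasta(input2, fin2)
    files <- c(fin, fin2)
  }
  out <- suppressWarnings(
    system2("mafft", c("--quiet", "--anysymbol", args, files), stdout = TRUE,
            stderr = FALSE))
  if (!is.null(attr(out, "status")) && attr(out, "status") != 0) {
    abort("mafft failed")
  }
  tf <- tempfile(fileext = ".fasta")
  on.exit(unlink(tf), add = TRUE)
  writeLines(out, tf)
  read_msa(tf, type = "AA")  # alphabet-agnostic: AA container accepts both
}

#' Progressive multiple sequence alignment
#'
#' Guide-tree progressive alignment.  A single sequence is returned
#' unchanged; two sequences are aligned by exact global Needleman-Wunsch
#' (so the result equals the optimal pairwise global alignment); three or
#' more sequences are aligned with the progressive aligner `mafft`
#' (deterministic).  Row order always equals input order.
#'
#' @param seqs Named [Biostrings::XStringSet] or named character vector.
#' @param scheme A [scoring_scheme()] used for the two-sequence exact case.
#' @return An `msa` object.
#' @export
progressive_msa <- function(seqs, scheme = scoring_scheme("protein")) {
  x <- as_stringset(seqs,
                    type = if (scheme$type == "protein") "AA" else "DNA")
  if (length(x) == 0) abort("progressive_msa() needs at least one sequence")
  if (length(x) == 1) {
    return(new_msa(setNames(as.character(x), names(x))))
  }
  if (length(x) == 2) {
    pa <- Biostrings::pairwiseAlignment(
      x[[1]], x[[2]], type = "global",
      substitutionMatrix = scheme$matrix,
      gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
    rows <- setNames(c(as.character(Biostrings::alignedPattern(pa)),
                       as.character(Biostrings::alignedSubject(pa))),
                     names(x))
    return(new_msa(rows))
  }
  res <- run_mafft(character(0), x)
  new_msa(unclass(res)[names(x)])
}

#' Align candidate sequences into a reference MSA's column space
#'
#' Adds candidates to an existing reference alignment while keeping the
#' reference column count fixed (candidate-specific insertions are
#' discarded), so candidate rows can be read off in reference column
#' coordinates.  Backed by `mafft --add --keeplength`.
#'
#' @param candidates Named sequences to place.
#' @param reference_msa An `msa` (the reference alignment).
#' @return An `msa` containing only the candidate rows, with exactly
#'   `msa_ncol(reference_msa)` columns.
#' @export
align_to_reference <- function(candidates, reference_msa) {
  cand <- as_stringset(candidates)
  full <- run_mafft(c("--keeplength", "--add"), cand,
                    input2 = setNames(unclass(reference_msa),
                                      names(reference_msa)))
  rows <- unclass(full)[names(cand)]
  if (anyNA(names(rows))) abort("mafft --add dropped a candidate row")
  new_msa(rows)
}

#' Trim an MSA to a column range
#'
#' @param msa An `msa`.
#' @param start_col,end_col 0-based half-open column range.
#' @return The column slice as an `msa`; rows that become all-gap are kept
#'   and listed in attribute `all_gap_rows`.
#' @export
trim_msa <- function(msa, start_col, end_col) {
  nc <- msa_ncol(msa)
  if (!(start_col >= 0 && start_col < end_col && end_col <= nc)) {
    abort(paste0("column range [", start_col, ",", end_col,
                 ") out of bounds for MSA with ", nc, " columns"))
  }
  rows <- substring(unclass(msa), start_col + 1, end_col)
  out <- new_msa(setNames(rows, names(msa)))
  attr(out, "all_gap_rows") <- names(msa)[grepl("^-*$", rows)]
  out
}

#' Per-column conservation and consensus of an MSA
#'
#' Consensus is the modal non-gap residue (ties broken alphabetically);
#' conservation is the modal count divided by the non-gap count.  An
#' all-gap column scores 0 with consensus `"-"`.
#'
#' @param msa An `msa` with at least two rows.
#' @return A tibble with columns `column` (1-based), `consensus`,
#'   `conservation`.
#' @export
conservation_and_consensus <- function(msa) {
  if (length(msa) < 2) abort("need at least two rows")
  m <- as.matrix.msa(msa)
  res <- apply(m, 2, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0) return(list(cons = "-", score = 0))
    tb <- sort(table(col), decreasing = TRUE)
    top <- max(tb)
    cons <- sort(names(tb)[tb == top])[1]
    list(cons = cons, score = top / length(col))
  })
  tibble(column = seq_along(res),
         consensus = vapply(res, `[[`, "", "cons"),
         conservation = vapply(res, function(r) as.numeric(r$score), 0))
}

#' Ungap an MSA row
#' @param row Gapped sequence string(s).
#' @return The string(s) with `-` removed.
#' @export
ungap <- function(row) gsub("-", "", row)

#' Write a hit table in 12-column tab-separated format
#'
#' The classic tabular dialect (query, subject, % identity, alignment
#' length, mismatches, gap opens, q. start, q. end, s. start, s. end,
#' evalue, bit score) with 1-based inclusive coordinates in this format
#' only.
#'
#' @param hits A hit tibble from [local_align_many()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  gaps_opened <- function(a) {
    vapply(gregexpr("-+", a), function(g) sum(g[1] != -1), 0L)
  }
  aln_len <- nchar(hits$aligned_query)
  matches <- round(hits$identity * aln_len)
  gapcols <- vapply(strsplit(hits$aligned_query, ""), function(x) sum(x == "-"),
                    0L) +
    vapply(strsplit(hits$aligned_subject, ""), function(x) sum(x == "-"), 0L)
  out <- tibble(
    query = hits$query_id, subject = hits$subject_id,
    pident = sprintf("%.2f", 100 * hits$identity),
    length = aln_len,
    mismatch = aln_len - gapcols - matches,
    gapopen = gaps_opened(hits$aligned_query) +
      gaps_opened(hits$aligned_subject),
    qstart = hits$q_start + 1L, qend = hits$q_end,
    sstart = hits$s_start + 1L, send = hits$s_end,
    evalue = hits$evalue, bitscore = hits$bit_score
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
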