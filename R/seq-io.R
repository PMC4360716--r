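# FASTA/FASTQ/TSV readers and writers shared by every stage.
#
# Sequence sets are Biostrings containers; ids must be unique within a file
# and sequences are uppercased on read.  GFF3 is 1-based inclusive on disk
# and converted to 0-based half-open coordinates at this boundary.

#' Read a FASTA file
#'
#' Reads nucleotide or protein FASTA into a \pkg{Biostrings} string set.
#' Sequences are uppercased; record order is preserved; duplicate ids are an
#' error (ids must be unique within a file).
#'
#' @param path Path to a FASTA file.
#' @param type `"DNA"` or `"AA"`, selecting the container class.
#' @return A [Biostrings::DNAStringSet] or [Biostrings::AAStringSet] named
#'   by record id (first whitespace-delimited token of the header).
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- tryCatch(
    if (type == "DNA") Biostrings::readDNAStringSet(path) else
      Biostrings::readAAStringSet(path),
    error = function(e) abort(paste0("FASTA parse error in ", path, ": ",
                                     conditionMessage(e)))
  )
  if (length(x) == 0) abort(paste0("empty FASTA file: ", path))
  names(x) <- sub("\\s.*$", "", names(x))
  dup <- unique(names(x)[duplicated(names(x))])
  if (length(dup) > 0) {
    abort(paste0("duplicate sequence id(s) in ", path, ": ",
                 paste(dup, collapse = ", ")))
  }
  toupper_set(x, type)
}

toupper_set <- function(x, type) {
  s <- toupper(as.character(x))
  out <- if (type == "DNA") Biostrings::DNAStringSet(s) else
    Biostrings::AAStringSet(s)
  names(out) <- names(x)
  out
}

#' Write sequences to FASTA
#'
#' @param x A named [Biostrings::XStringSet] or named character vector.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70) {
  x <- as_stringset(x)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

as_stringset <- function(x, type = NULL) {
  if (methods::is(x, "XStringSet")) return(x)
  if (is.character(x)) {
    if (length(x) == 0) {
      return(if (identical(type, "DNA")) Biostrings::DNAStringSet() else
        Biostrings::AAStringSet())
    }
    if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == "")) {
      abort("character sequences must be named")
    }
    guess <- type %||%
      if (all(grepl("^[ACGTNacgtn-]*$", x))) "DNA" else "AA"
    return(if (guess == "DNA") Biostrings::DNAStringSet(x) else
      Biostrings::AAStringSet(x))
  }
  abort("expected an XStringSet or named character vector")
}

#' Read a FASTQ file (phred+33)
#'
#' @param path Path to a 4-line-per-record FASTQ file.
#' @return A [Biostrings::QualityScaledDNAStringSet] with per-base phred
#'   scores; ids unique; a truncated or length-mismatched record is an error.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  if (length(lines) == 0) abort(paste0("empty FASTQ file: ", path))
  if (length(lines) %% 4 != 0) {
    abort(paste0("truncated FASTQ record at line ", length(lines), " of ", path))
  }
  hdr <- lines[seq(1, length(lines), by = 4)]
  seq <- toupper(lines[seq(2, length(lines), by = 4)])
  qul <- lines[seq(4, length(lines), by = 4)]
  bad_hdr <- which(!startsWith(hdr, "@"))
  if (length(bad_hdr) > 0) {
    abort(paste0("malformed FASTQ header at line ", (bad_hdr[1] - 1) * 4 + 1))
  }
  mism <- which(nchar(seq) != nchar(qul))
  if (length(mism) > 0) {
    abort(paste0("sequence/quality length mismatch at record ", mism[1],
                 " (line ", (mism[1] - 1) * 4 + 2, ")"))
  }
  ids <- sub("\\s.*$", "", substring(hdr, 2))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(paste0("duplicate read id(s): ", paste(dup, collapse = ", ")))
  }
  x <- Biostrings::DNAStringSet(seq)
  names(x) <- ids
  q <- Biostrings::PhredQuality(qul)
  Biostrings::QualityScaledDNAStringSet(x, q)
}

#' Write reads to FASTQ (phred+33)
#'
#' @param x A [Biostrings::QualityScaledDNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path) {
  stopifnot(methods::is(x, "QualityScaledDNAStringSet"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", names(x), "\n", as.character(x), "\n+\n",
                    as.character(Biostrings::quality(x))), con)
  invisible(path)
}

#' Per-base phred scores of a quality-scaled read set
#'
#' @param x A [Biostrings::QualityScaledDNAStringSet].
#' @return A list of integer vectors, one per read.
#' @export
phred_scores <- function(x) {
  as(Biostrings::quality(x), "IntegerList") |> as.list()
}

# ---- TSV ----------------------------------------------------------------

#' Read / write tab-separated tables
#'
#' Thin wrappers over \pkg{readr} fixing the dialect used throughout the
#' package: tab separator, header row, UTF-8, `.` decimal mark.
#'
#' @param path File path.
#' @param x A data frame.
#' @param col_types Optional readr column specification.
#' @return `read_tsv_strict()` returns a tibble; `write_tsv_strict()`
#'   returns `path` invisibly.
#' @export
read_tsv_strict <- function(path, col_types = NULL) {
  readr::read_tsv(path, col_types = col_types, progress = FALSE,
                  show_col_types = FALSE)
}

#' @rdname read_tsv_strict
#' @export
write_tsv_strict <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read the packaged contig summary table
#'
#' Parses the published summary of Far-T4 contigs assembled from freshwater
#' viromes (packaged at `inst/extdata/table1_far_t4_contigs.tsv`) into one
#' row per contig.  The `markers` column holds the marker-gene labels
#' carried by the contig as a list-column of character vectors (a
#' `"(partial)"` qualifier is kept attached to its label).
#'
#' @param path Path to the TSV; defaults to the packaged fixture.
#' @return A tibble with columns `dataset`, `sequence_id`, `length`
#'   (bp), `clade`, `markers` (list), `phoh` (logical), `crispr_host`,
#'   `tetra_host` (NA when absent).
#' @export
read_contig_table <- function(path = system.file("extdata",
                                                 "table1_far_t4_contigs.tsv",
                                                 package = "viroclade")) {
  expected <- c("dataset", "sequence_id", "length", "clade", "markers",
                "phoh", "crispr_host", "tetra_host")
  tb <- readr::read_tsv(path, col_types = readr::cols(
    dataset = "c", sequence_id = "c", length = "i", clade = "c",
    markers = "c", phoh = "c", crispr_host = "c", tetra_host = "c"
  ), progress = FALSE, show_col_types = FALSE)
  if (!identical(names(tb), expected)) {
    abort(paste0("contig table schema mismatch; expected columns: ",
                 paste(expected, collapse = ", ")))
  }
  if (nrow(tb) == 0) abort("empty contig table")
  if (any(tb$length <= 0)) abort("contig lengths must be positive")
  tb |>
    mutate(
      markers = purrr::map(.data$markers, function(m) {
        if (is.na(m) || m == "") character(0) else trimws(strsplit(m, ";")[[1]])
      }),
      phoh = !is.na(.data$phoh) & .data$phoh == "+"
    )
}

# ---- GFF3 ---------------------------------------------------------------

#' Read gene calls from GFF3 (+ optional protein FASTA)
#'
#' Reads CDS features from a GFF3 file into the package's gene-call table.
#' On disk coordinates are 1-based inclusive (GFF3); in memory they are
#' 0-based half-open.  Protein translations are attached by matching the
#' GFF3 `ID` attribute against names of `proteins`.
#'
#' @param path Path to a GFF3 file with CDS features carrying `ID=` tags.
#' @param proteins Optional [Biostrings::AAStringSet] of translations named
#'   by gene id.
#' @return A gene-call tibble with columns `contig_id`, `start`, `end`
#'   (0-based half-open), `strand`, `gene_id`, `protein`, `annotation`.
#' @export
read_gene_calls <- function(path, proteins = NULL) {
  g <- ape::read.gff(path)
  g <- g[g$type == "CDS", , drop = FALSE]
  att <- function(field) {
    m <- regmatches(g$attributes,
                    regexec(paste0("(?:^|;)", field, "=([^;]+)"), g$attributes))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
  }
  ids <- att("ID")
  if (anyNA(ids)) abort("GFF3 CDS feature without an ID attribute")
  ann <- att("annotation")
  tb <- tibble(
    contig_id = as.character(g$seqid),
    start = as.integer(g$start) - 1L,
    end = as.integer(g$end),
    strand = as.character(g$strand),
    gene_id = ids,
    protein = NA_character_,
    annotation = ann
  )
  if (!is.null(proteins)) {
    p <- as.character(proteins)
    tb$protein <- unname(p[tb$gene_id])
  }
  validate_gene_calls(tb)
}

validate_gene_calls <- function(tb) {
  stopifnot(all(c("contig_id", "start", "end", "strand", "gene_id") %in%
                  names(tb)))
  if (any(tb$start < 0 | tb$start >= tb$end)) {
    abort("gene-call coordinates must satisfy 0 <= start < end")
  }
  if (!all(tb$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  dup <- tb |> count(.data$contig_id, .data$gene_id) |> filter(n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicate gene id(s) on contig ", dup$contig_id[1], ": ",
                 dup$gene_id[1]))
  }
  tb
}

#' Write gene calls to GFF3
#'
#' Inverse of [read_gene_calls()]: converts 0-based half-open coordinates
#' back to the 1-based inclusive GFF3 convention.
#'
#' @param gene_calls A gene-call tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_calls <- function(gene_calls, path) {
  tb <- validate_gene_calls(gene_calls)
  ann <- if ("annotation" %in% names(tb)) tb$annotation else NA_character_
  attr_col <- paste0("ID=", tb$gene_id,
                     ifelse(is.na(ann), "", paste0(";annotation=", ann)))
  lines <- paste(tb$contig_id, "viroclade", "CDS", tb$start + 1L, tb$end,
                 ".", tb$strand, "0", attr_col, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
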