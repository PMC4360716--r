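# All-vs-all protein comparison of contigs: shared-gene counts and
# proportions, hierarchical clustering of the sharing matrix, gene novelty
# classes, duplicate-contig exclusion, and nucleotide synteny blocks.

qualifying_hit_exists <- function(query_prots, subject_prots, scheme,
                                  min_bit, max_evalue) {
  # for each query protein: any qualifying hit among subject proteins?
  # (score-only alignments; the bit/E thresholds only need raw scores)
  found <- rep(FALSE, length(query_prots))
  for (sp in subject_prots) {
    todo <- which(!found)
    if (length(todo) == 0) break
    raw <- local_scores(query_prots[todo], sp, scheme)
    ok <- qualifies(raw, scheme, m = Biostrings::width(query_prots[todo]),
                    n = nchar(sp), min_bit, max_evalue)
    found[todo][ok] <- TRUE
  }
  found
}

# symmetric gene-vs-gene qualifying-hit matrix over all proteins
# (raw local score and m*n search space are both symmetric, so only the
# upper triangle is computed)
gene_hit_adjacency <- function(prots, scheme, min_bit, max_evalue) {
  n <- length(prots)
  adj <- matrix(FALSE, n, n, dimnames = list(names(prots), names(prots)))
  for (j in seq_len(n)) {
    idx <- seq_len(j)
    raw <- local_scores(prots[idx], as.character(prots[[j]]), scheme)
    ok <- qualifies(raw, scheme, m = Biostrings::width(prots[idx]),
                    n = Biostrings::width(prots)[j], min_bit, max_evalue)
    adj[idx, j] <- ok
    adj[j, idx] <- ok
  }
  adj
}

#' Count genes shared between two contigs
#'
#' A gene is shared when it has at least one local-alignment hit in the
#' other contig's gene set with bit score above `min_bit` and E-value
#' below `max_evalue`.  The count is taken over the genes of the contig
#' with the smaller gene complement.
#'
#' @param genes_a,genes_b Named protein vectors (or AAStringSets) of the
#'   two contigs' genes.
#' @param scheme Protein [scoring_scheme()].
#' @param min_bit,max_evalue Hit qualification thresholds.
#' @return Integer count.
#' @export
shared_gene_count <- function(genes_a, genes_b,
                              scheme = scoring_scheme("protein"),
                              min_bit = 50, max_evalue = 0.001) {
  a <- as_stringset(genes_a, type = "AA")
  b <- as_stringset(genes_b, type = "AA")
  if (length(a) <= length(b)) {
    sum(qualifying_hit_exists(a, as.character(b), scheme, min_bit,
                              max_evalue))
  } else {
    sum(qualifying_hit_exists(b, as.character(a), scheme, min_bit,
                              max_evalue))
  }
}

#' Proportion of shared genes
#'
#' Shared-gene count normalised by the gene complement of the contig with
#' fewer genes.
#'
#' @param count Shared-gene count.
#' @param n_genes_a,n_genes_b Gene counts of the two contigs (> 0).
#' @return A proportion in `[0, 1]`.
#' @export
sharing_proportion <- function(count, n_genes_a, n_genes_b) {
  if (n_genes_a == 0 || n_genes_b == 0) {
    abort("both contigs must have at least one gene")
  }
  count / min(n_genes_a, n_genes_b)
}

#' Pairwise gene-sharing matrix over contigs
#'
#' Runs the all-vs-all shared-gene comparison for every pair of contigs
#' and assembles the symmetric matrices of shared counts and sharing
#' proportions.
#'
#' @param gene_calls Gene-call tibble with `contig_id`, `gene_id`,
#'   `protein`.
#' @param scheme Protein [scoring_scheme()].
#' @param min_bit,max_evalue Hit qualification thresholds.
#' @return A `sharing_matrix` object: list with `contig_ids`,
#'   `proportions` (symmetric, diagonal from self-comparison), `counts`
#'   and `n_genes`.
#' @export
sharing_matrix <- function(gene_calls, scheme = scoring_scheme("protein"),
                           min_bit = 50, max_evalue = 0.001) {
  prots <- Biostrings::AAStringSet(setNames(gene_calls$protein,
                                            gene_calls$gene_id))
  contig_of <- setNames(gene_calls$contig_id, gene_calls$gene_id)
  ids <- sort(unique(gene_calls$contig_id))
  n <- length(ids)
  if (n < 2) abort("need at least two contigs")
  adj <- gene_hit_adjacency(prots, scheme, min_bit, max_evalue)
  gene_idx <- split(seq_along(prots), contig_of[names(prots)])
  n_genes <- vapply(gene_idx[ids], length, 0L)
  counts <- matrix(0L, n, n, dimnames = list(ids, ids))
  P <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      gi <- gene_idx[[ids[i]]]
      gj <- gene_idx[[ids[j]]]
      # count over the genes of the contig with the smaller complement
      cnt <- if (length(gi) <= length(gj)) {
        sum(apply(adj[gi, gj, drop = FALSE], 1, any))
      } else {
        sum(apply(adj[gj, gi, drop = FALSE], 1, any))
      }
      counts[i, j] <- counts[j, i] <- cnt
      P[i, j] <- P[j, i] <- sharing_proportion(cnt, length(gi), length(gj))
    }
  }
  structure(list(contig_ids = ids, proportions = P, counts = counts,
                 n_genes = n_genes),
            class = "sharing_matrix")
}

#' @export
print.sharing_matrix <- function(x, ...) {
  cat("<sharing_matrix> ", length(x$contig_ids), " contigs; mean sharing ",
      sprintf("%.3f", mean(x$proportions[upper.tri(x$proportions)])), "\n",
      sep = "")
  invisible(x)
}

#' Tidy a sharing matrix into long form
#'
#' @param x A `sharing_matrix`.
#' @param ... Unused.
#' @return Tibble with `contig_a`, `contig_b`, `shared`, `proportion`
#'   (upper triangle including diagonal).
#' @export
tidy.sharing_matrix <- function(x, ...) {
  idx <- which(upper.tri(x$proportions, diag = TRUE), arr.ind = TRUE)
  tibble(contig_a = x$contig_ids[idx[, 1]], contig_b = x$contig_ids[idx[, 2]],
         shared = x$counts[idx], proportion = x$proportions[idx])
}

#' Heatmap of a gene-sharing matrix
#'
#' @param object A `sharing_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sharing_matrix <- function(object, ...) {
  ord <- stats::order.dendrogram(stats::as.dendrogram(
    sharing_hclust(object)))
  ids <- object$contig_ids[ord]
  long <- tidyr::expand_grid(contig_a = ids, contig_b = ids) |>
    mutate(proportion = object$proportions[cbind(.data$contig_a,
                                                 .data$contig_b)],
           contig_a = factor(.data$contig_a, levels = ids),
           contig_b = factor(.data$contig_b, levels = ids))
  ggplot2::ggplot(long, ggplot2::aes(.data$contig_a, .data$contig_b,
                                     fill = .data$proportion)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "shared\nproportion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1))
}

sharing_hclust <- function(sm) {
  d <- as.dist(1 - sm$proportions)
  hclust(d, method = "complete")
}

#' Exclude duplicate contigs
#'
#' Collapses byte-identical contig sequences (e.g. the same genome
#' assembled independently from two samples) to a single representative,
#' keeping the lexicographically smallest id.
#'
#' @param contigs Named [Biostrings::DNAStringSet] or character vector.
#' @return List with `kept` and `removed` (see [dedupe_exact()]).
#' @export
exclude_duplicates <- function(contigs) dedupe_exact(contigs)

#' Hierarchical clustering of contigs by gene sharing
#'
#' Agglomerative clustering with complete linkage on the dissimilarity
#' `1 - P`, returned as a tree over contigs.
#'
#' @param sm A `sharing_matrix`.
#' @return A `phylo` tree (topology from the dendrogram).
#' @export
cluster_contigs <- function(sm) {
  if (length(sm$contig_ids) < 2) abort("need at least two contigs")
  ape::as.phylo(sharing_hclust(sm))
}

#' Classify gene novelty against a reference database and the contig group
#'
#' Each gene is classified with precedence `affiliated_reference` (a
#' qualifying hit in the reference protein set) over `group_only` (a
#' qualifying hit in another contig of the group; self-contig hits never
#' count) over `unique`.
#'
#' @param gene_calls Gene-call tibble (`contig_id`, `gene_id`,
#'   `protein`).
#' @param reference_db Named protein set standing in for the reference
#'   database (may be empty).
#' @param scheme Protein [scoring_scheme()].
#' @param min_bit,max_evalue Hit qualification thresholds.
#' @return List with `genes` (tibble `gene_id`, `contig_id`, `class`)
#'   and `by_contig` (tibble of per-contig class fractions, summing
#'   to 1).
#' @export
classify_novelty <- function(gene_calls, reference_db,
                             scheme = scoring_scheme("protein"),
                             min_bit = 50, max_evalue = 0.001) {
  prot <- Biostrings::AAStringSet(setNames(gene_calls$protein,
                                           gene_calls$gene_id))
  ref <- as.character(as_stringset(reference_db, type = "AA"))
  in_ref <- if (length(ref) > 0) {
    qualifying_hit_exists(prot, ref, scheme, min_bit, max_evalue)
  } else rep(FALSE, length(prot))
  in_group <- rep(FALSE, length(prot))
  if (any(!in_ref) && dplyr::n_distinct(gene_calls$contig_id) > 1) {
    adj <- gene_hit_adjacency(prot, scheme, min_bit, max_evalue)
    same_contig <- outer(gene_calls$contig_id, gene_calls$contig_id, `==`)
    adj[same_contig] <- FALSE   # self-contig hits never count
    in_group <- apply(adj, 1, any) & !in_ref
  }
  cls <- ifelse(in_ref, "affiliated_reference",
                ifelse(in_group, "group_only", "unique"))
  genes <- tibble(gene_id = gene_calls$gene_id,
                  contig_id = gene_calls$contig_id, class = cls)
  by_contig <- genes |>
    count(.data$contig_id, .data$class) |>
    group_by(.data$contig_id) |>
    mutate(fraction = n / sum(n)) |>
    ungroup() |>
    select(-"n") |>
    tidyr::pivot_wider(names_from = "class", values_from = "fraction",
                       values_fill = 0)
  for (col in c("affiliated_reference", "group_only", "unique")) {
    if (!col %in% names(by_contig)) by_contig[[col]] <- 0
  }
  list(genes = genes,
       by_contig = by_contig |>
         select("contig_id", "affiliated_reference", "group_only", "unique"))
}

#' Nucleotide synteny blocks between two contigs
#'
#' Finds qualifying local nucleotide similarities between two contigs and
#' reports them as coordinate blocks.  Contig A is tiled into
#' `window` bp pieces, each piece locally aligned to contig B, and
#' qualifying window hits that are collinear and adjacent on both contigs
#' are chained into maximal blocks.
#'
#' @param contig_a,contig_b Nucleotide sequences (strings or XString).
#' @param scheme_nuc Nucleotide [scoring_scheme()].
#' @param min_bit Bit-score threshold for a window hit.
#' @param window Tile width in bp.
#' @return Tibble sorted by `a_start`: `a_start`, `a_end`, `b_start`,
#'   `b_end` (0-based half-open), `identity`.
#' @export
synteny_blocks <- function(contig_a, contig_b,
                           scheme_nuc = scoring_scheme("nucleotide"),
                           min_bit = 50, window = 500) {
  a <- as.character(contig_a)
  b <- as.character(contig_b)
  starts <- seq(0, max(0, nchar(a) - 1), by = window)
  tiles <- substring(a, starts + 1, pmin(starts + window, nchar(a)))
  keep <- nchar(tiles) >= 50
  starts <- starts[keep]; tiles <- tiles[keep]
  if (length(tiles) == 0) return(empty_synteny())
  named_tiles <- setNames(tiles, sprintf("w%06d", starts))
  raw <- local_scores(named_tiles, b, scheme_nuc)
  pre <- bit_and_evalue(raw, scheme_nuc, m = nchar(tiles),
                        n = nchar(b))$bit_score > min_bit
  if (!any(pre)) return(empty_synteny())
  hits <- local_align_many(named_tiles[pre], b, scheme_nuc) |>
    filter(.data$bit_score > min_bit)
  if (nrow(hits) == 0) return(empty_synteny())
  hits <- hits |>
    mutate(a_start = as.integer(sub("w", "", .data$query_id)) +
             .data$q_start,
           a_end = as.integer(sub("w", "", .data$query_id)) + .data$q_end,
           b_start = .data$s_start, b_end = .data$s_end,
           len = .data$a_end - .data$a_start) |>
    arrange(.data$a_start)
  # chain collinear, near-adjacent window hits
  blocks <- list()
  cur <- hits[1, ]
  cur_matches <- cur$identity * cur$len
  if (nrow(hits) > 1) {
    for (i in 2:nrow(hits)) {
      h <- hits[i, ]
      if (abs(h$a_start - cur$a_end) <= 10 &&
          abs(h$b_start - cur$b_end) <= 10) {
        cur$a_end <- h$a_end
        cur$b_end <- h$b_end
        cur_matches <- cur_matches + h$identity * h$len
      } else {
        cur$identity <- cur_matches / (cur$a_end - cur$a_start)
        blocks[[length(blocks) + 1]] <- cur
        cur <- h
        cur_matches <- h$identity * h$len
      }
    }
  }
  cur$identity <- cur_matches / (cur$a_end - cur$a_start)
  blocks[[length(blocks) + 1]] <- cur
  bind_rows(blocks) |>
    select("a_start", "a_end", "b_start", "b_end", "identity") |>
    arrange(.data$a_start)
}

empty_synteny <- function() {
  tibble(a_start = integer(0), a_end = integer(0), b_start = integer(0),
         b_end = integer(0), identity = numeric(0))
}
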