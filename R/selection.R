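# Nei-Gojobori (1986) counting estimator of dN/dS on codon sequences,
# with Jukes-Cantor correction and group-wise summaries for a designated
# set of sequences vs the rest.

codon_env <- new.env(parent = emptyenv())

genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

is_stop <- function(codon) codon %in% c("TAA", "TAG", "TGA")

# fraction of synonymous sites per sense codon (mutations to stop codons
# are skipped in the numerator; each position contributes denominator 3,
# so S + N = 3 per codon)
syn_site_table <- function() {
  if (!is.null(codon_env$syn_sites)) return(codon_env$syn_sites)
  gc <- genetic_code()
  sense <- names(gc)[!is_stop(names(gc))]
  s <- vapply(sense, function(cod) {
    aa <- gc[[cod]]
    tot <- 0
    for (pos in 1:3) {
      for (b in setdiff(BASES, substring(cod, pos, pos))) {
        alt <- cod
        substring(alt, pos, pos) <- b
        if (is_stop(alt)) next
        if (gc[[alt]] == aa) tot <- tot + 1 / 3
      }
    }
    tot
  }, 0)
  codon_env$syn_sites <- s
  s
}

split_codons <- function(s) {
  n <- nchar(s)
  substring(s, seq(1, n, 3), seq(3, n, 3))
}

# (syn, nonsyn) differences between two codons, averaging equally over
# all substitution orderings; pathways through stop codons are excluded
# (all-blocked pairs fall back to including them)
codon_diff_counts <- function(c1, c2) {
  gc <- genetic_code()
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(pos)
  if (k == 0) return(c(syn = 0, nonsyn = 0))
  paths <- function(allow_stops) {
    perms <- if (k == 1) list(pos) else
      if (k == 2) list(pos, rev(pos)) else
        lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2),
                    c(3,2,1)), function(o) pos[o])
    out <- list()
    for (ord in perms) {
      cur <- c1
      steps <- c(syn = 0, nonsyn = 0)
      valid <- TRUE
      for (p in ord) {
        nxt <- cur
        substring(nxt, p, p) <- substring(c2, p, p)
        if (is_stop(nxt) && !allow_stops) { valid <- FALSE; break }
        if (!is_stop(cur) && !is_stop(nxt) && gc[[cur]] == gc[[nxt]]) {
          steps["syn"] <- steps["syn"] + 1
        } else {
          steps["nonsyn"] <- steps["nonsyn"] + 1
        }
        cur <- nxt
      }
      if (valid) out[[length(out) + 1]] <- steps
    }
    out
  }
  valid <- paths(allow_stops = FALSE)
  if (length(valid) == 0) valid <- paths(allow_stops = TRUE)
  Reduce(`+`, valid) / length(valid)
}

validate_codon_seq <- function(s, label) {
  s <- toupper(as.character(s))
  if (nchar(s) %% 3 != 0) {
    abort(paste0(label, ": length is not a multiple of 3"))
  }
  if (any(is_stop(split_codons(s)))) {
    abort(paste0(label, ": internal stop codon"))
  }
  s
}

jc_correct <- function(p) {
  ifelse(p < 0.75, -3 / 4 * log(1 - 4 * p / 3), NaN)
}

#' Nei-Gojobori (1986) dN/dS for a codon sequence pair
#'
#' Counts synonymous (S) and nonsynonymous (N) sites per codon (averaged
#' over both sequences; mutations to stop codons are not counted as
#' synonymous opportunities), observed synonymous/nonsynonymous
#' differences with equal-weight pathway averaging for multi-position
#' codon differences (pathways through stop codons excluded), applies the
#' Jukes-Cantor correction `d = -3/4 ln(1 - 4p/3)`, and reports
#' `omega = dN/dS`.
#'
#' @param codon_seq_a,codon_seq_b In-frame nucleotide sequences of equal
#'   length (multiple of 3, no internal stop codons).
#' @param label Pair label carried into the output.
#' @return One-row tibble: `label`, `n_codons`, `S`, `N`, `Sd`, `Nd`,
#'   `pS`, `pN`, `dS`, `dN`, `omega` (`NA` when undefined) and
#'   `undefined` (`NA`, `"identical"` for 0/0 or `"dS_zero"` when
#'   `dN > 0` with `dS = 0`).
#' @export
ng86_pair <- function(codon_seq_a, codon_seq_b, label = "pair") {
  a <- validate_codon_seq(codon_seq_a, "codon_seq_a")
  b <- validate_codon_seq(codon_seq_b, "codon_seq_b")
  if (nchar(a) != nchar(b)) abort("sequences must have equal length")
  ca <- split_codons(a)
  cb <- split_codons(b)
  syn_tab <- syn_site_table()
  S <- (sum(syn_tab[ca]) + sum(syn_tab[cb])) / 2
  N <- 3 * length(ca) - S
  d <- purrr::map2(ca, cb, codon_diff_counts)
  Sd <- sum(vapply(d, `[[`, 0, "syn"))
  Nd <- sum(vapply(d, `[[`, 0, "nonsyn"))
  pS <- Sd / S
  pN <- Nd / N
  dS <- jc_correct(pS)
  dN <- jc_correct(pN)
  undefined <- NA_character_
  omega <- NA_real_
  if (Sd == 0 && Nd == 0) {
    undefined <- "identical"
  } else if (Nd == 0) {
    omega <- 0          # no nonsynonymous change observed
  } else if (is.nan(dS)) {
    undefined <- "dS_saturated"
  } else if (dS == 0) {
    undefined <- "dS_zero"
  } else if (is.nan(dN)) {
    undefined <- "dN_saturated"
  } else {
    omega <- dN / dS
  }
  tibble(label = label, n_codons = length(ca), S = S, N = N, Sd = Sd,
         Nd = Nd, pS = pS, pN = pN, dS = dS, dN = dN, omega = omega,
         undefined = undefined)
}

#' Group-wise mean pairwise dN/dS
#'
#' Computes [ng86_pair()] for every within-partition pair of a codon
#' alignment and reports the mean omega of the designated group and of
#' the rest (pairs with undefined omega are excluded and counted).
#'
#' @param codon_msa An `msa` of in-frame, gap-free codon sequences (or a
#'   named character vector).
#' @param group_ids Sequence ids forming the designated group; both the
#'   group and its complement must have >= 2 sequences.
#' @return A tibble with one row per partition: `partition`
#'   (`"group"`/`"rest"`), `n_seqs`, `n_pairs`, `n_defined`,
#'   `omega_mean` (`NA` when no pair is defined).
#' @export
group_dnds <- function(codon_msa, group_ids) {
  seqs <- if (inherits(codon_msa, "msa")) unclass(codon_msa) else codon_msa
  stopifnot(!is.null(names(seqs)))
  grp <- intersect(names(seqs), group_ids)
  rest <- setdiff(names(seqs), group_ids)
  if (length(grp) < 2 || length(rest) < 2) {
    abort("both partitions need at least 2 sequences")
  }
  summarise_partition <- function(ids, partition) {
    pairs <- utils::combn(sort(ids), 2, simplify = FALSE)
    res <- purrr::map(pairs, function(p) {
      ng86_pair(seqs[[p[1]]], seqs[[p[2]]],
                label = paste(p, collapse = "|"))
    }) |> bind_rows()
    ok <- !is.na(res$omega)
    tibble(partition = partition, n_seqs = length(ids),
           n_pairs = nrow(res), n_defined = sum(ok),
           omega_mean = if (any(ok)) mean(res$omega[ok]) else NA_real_)
  }
  bind_rows(summarise_partition(grp, "group"),
            summarise_partition(rest, "rest"))
}

#' Simulate a codon sequence pair under a simple substitution regime
#'
#' Generates a random ancestral sense-codon sequence and applies `n_subs`
#' accepted single-base substitutions to an evolving copy.  Under
#' `"neutral"` any substitution not creating a stop codon is accepted
#' (so omega should scatter around 1); under `"synonymous"` only
#' synonymous substitutions are accepted (so omega is exactly 0).
#'
#' @param n_codons Number of codons.
#' @param n_subs Number of accepted substitutions.
#' @param mode `"neutral"` or `"synonymous"`.
#' @param seed Integer seed.
#' @return List with `ancestor` and `derived` codon sequences.
#' @export
simulate_codon_pair <- function(n_codons = 200, n_subs = 30,
                                mode = c("neutral", "synonymous"),
                                seed = 1) {
  mode <- match.arg(mode)
  gc <- genetic_code()
  set.seed(seed)
  anc <- paste(sample(SENSE_CODONS, n_codons, replace = TRUE),
               collapse = "")
  cur <- anc
  done <- 0
  guard <- 0
  while (done < n_subs && guard < n_subs * 1000) {
    guard <- guard + 1
    pos <- sample.int(nchar(cur), 1)
    old <- substring(cur, pos, pos)
    new <- sample(setdiff(BASES, old), 1)
    cand <- cur
    substring(cand, pos, pos) <- new
    cod_i <- (pos - 1) %/% 3 + 1
    cod_old <- split_codons(cur)[cod_i]
    cod_new <- split_codons(cand)[cod_i]
    if (is_stop(cod_new)) next
    if (mode == "synonymous" && gc[[cod_old]] != gc[[cod_new]]) next
    cur <- cand
    done <- done + 1
  }
  list(ancestor = anc, derived = cur)
}
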