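# Pairwise sequence comparison primitives. Protein pairs get an exact local
# (Smith-Waterman) alignment under BLOSUM62 11/1 via Biostrings, with
# Karlin-Altschul E-values computed from the raw score; whole genomes get an
# exact global (Needleman-Wunsch) alignment computed in linear space by the
# compiled divide-and-conquer kernel, since the DP matrix of two ~50 kb
# genomes does not fit a quadratic-memory aligner.

# BLOSUM62 with ambiguity code X scored 0 against everything, cached.
the <- new.env(parent = emptyenv())

scoring_matrix <- function(name = "BLOSUM62") {
  if (!identical(name, "BLOSUM62")) {
    abort(paste0("unknown scoring matrix: ", name))
  }
  if (is.null(the$blosum62x)) {
    m <- get_blosum62()
    m["X", ] <- 0L
    m[, "X"] <- 0L
    the$blosum62x <- m
  }
  the$blosum62x
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Protein alignment with score, E-value and percent identity
#'
#' The raw score is an exact local (Smith--Waterman) alignment under the
#' configured scoring scheme; the E-value uses the Karlin--Altschul formula
#' `E = K * m * n * exp(-lambda * S)` with `m`, `n` the sequence lengths
#' (pairwise search space) or `m * fixed_db_size` under the `fixed_db`
#' policy, and the bit score is `(lambda * S - ln K) / ln 2`. Percent
#' identity is taken over the columns of a full-length global alignment of
#' the pair (gap columns included in the length), the way a
#' multiple-aligner-style identity behaves: a short, locally similar stretch
#' between otherwise unrelated proteins does not inflate it. The comparison
#' is symmetric: swapping the arguments changes nothing.
#'
#' @param a,b Amino-acid strings (non-empty).
#' @param params A [scoring_params()].
#' @return One-row tibble: `raw_score`, `bit_score`, `evalue`,
#'   `pct_identity`, `aln_length`, `n_identical`.
#' @examples
#' align_proteins("MKVLAAGHK", "MKVLAAGHK")
#' @export
align_proteins <- function(a, b, params = scoring_params()) {
  assert_that(is.character(a) && length(a) == 1 && nchar(a) > 0,
              "sequence a must be a non-empty string")
  assert_that(is.character(b) && length(b) == 1 && nchar(b) > 0,
              "sequence b must be a non-empty string")
  mat <- scoring_matrix(params$matrix_name)
  loc <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = mat,
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    type = "local"
  )
  glo <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = mat,
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    type = "global"
  )
  alignment_result(Biostrings::score(loc), Biostrings::nmatch(glo),
                   nchar(as.character(Biostrings::alignedPattern(glo))),
                   nchar(a), nchar(b), params)
}

alignment_result <- function(raw_score, n_identical, aln_length, m, n, params) {
  raw_score <- unname(raw_score)
  n_identical <- unname(n_identical)
  aln_length <- unname(aln_length)
  space <- if (params$search_space_policy == "fixed_db") {
    as.numeric(m) * params$fixed_db_size
  } else {
    as.numeric(m) * n
  }
  evalue <- params$ka_K * space * exp(-params$ka_lambda * raw_score)
  tibble(
    raw_score = raw_score,
    bit_score = (params$ka_lambda * raw_score - log(params$ka_K)) / log(2),
    evalue = evalue,
    pct_identity = ifelse(aln_length > 0, 100 * n_identical / aln_length, 0),
    aln_length = aln_length,
    n_identical = n_identical
  )
}

# all-vs-all protein comparison; one row per unordered pair (i < j).
# Vectorized over patterns per subject to keep the Biostrings call count low.
all_vs_all_similarity <- function(proteins, params = scoring_params()) {
  assert_that(all(c("gene_id", "aa_seq") %in% names(proteins)),
              "proteins needs columns gene_id, aa_seq")
  assert_that(!anyDuplicated(proteins$gene_id), "duplicate gene_id")
  n <- nrow(proteins)
  if (n < 2) {
    return(tibble(query = character(), subject = character(),
                  raw_score = numeric(), bit_score = numeric(),
                  evalue = numeric(), pct_identity = numeric(),
                  aln_length = integer(), n_identical = integer()))
  }
  set <- Biostrings::AAStringSet(setNames(proteins$aa_seq, proteins$gene_id))
  mat <- scoring_matrix(params$matrix_name)
  out <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    idx <- (i + 1):n
    loc <- Biostrings::pairwiseAlignment(
      set[idx], set[[i]],
      substitutionMatrix = mat, gapOpening = params$gap_open,
      gapExtension = params$gap_extend, type = "local"
    )
    glo <- Biostrings::pairwiseAlignment(
      set[idx], set[[i]],
      substitutionMatrix = mat, gapOpening = params$gap_open,
      gapExtension = params$gap_extend, type = "global"
    )
    res <- alignment_result(
      Biostrings::score(loc), Biostrings::nmatch(glo),
      nchar(as.character(Biostrings::alignedPattern(glo))),
      nchar(proteins$aa_seq[idx]), nchar(proteins$aa_seq[i]), params
    )
    out[[i]] <- bind_cols(
      tibble(query = proteins$gene_id[i], subject = proteins$gene_id[idx]),
      res
    )
  }
  bind_rows(out)
}

#' Whole-sequence nucleotide identity
#'
#' Exact global (Needleman--Wunsch) alignment with match +1, mismatch -1 and
#' gap -2 per gap position, computed in linear space; identity is 100 times
#' the identical columns over the alignment length (gap columns included),
#' reported to two decimals (half-up). For equal-length inputs whose optimal
#' alignment is gapless this reduces to Hamming identity.
#'
#' @param a,b Nucleotide strings (non-empty).
#' @param match,mismatch,gap Scoring scheme (integers).
#' @return Percent identity in `[0, 100]`, two decimals.
#' @examples
#' nucleotide_identity("ACGTACGT", "ACGAACGT") # 87.50
#' @export
nucleotide_identity <- function(a, b, match = 1L, mismatch = -1L, gap = -2L) {
  assert_that(is.character(a) && length(a) == 1 && nchar(a) > 0,
              "sequence a must be a non-empty string")
  assert_that(is.character(b) && length(b) == 1 && nchar(b) > 0,
              "sequence b must be a non-empty string")
  st <- .nw_align_stats(toupper(a), toupper(b), match, mismatch, gap)
  round_half_up(100 * st$n_identical / st$aln_length, 2)
}

#' Global alignment statistics
#'
#' The column statistics (score, length, identical/mismatch/gap columns) of
#' one optimal global alignment under a linear gap penalty. Backbone of
#' [nucleotide_identity()]; exposed for callers who need the raw counts.
#'
#' @inheritParams nucleotide_identity
#' @return One-row tibble: `score`, `aln_length`, `n_identical`,
#'   `n_mismatch`, `n_gap`.
#' @export
global_alignment_stats <- function(a, b, match = 1L, mismatch = -1L, gap = -2L) {
  st <- .nw_align_stats(toupper(a), toupper(b), match, mismatch, gap)
  as_tibble(st[c("score", "aln_length", "n_identical", "n_mismatch", "n_gap")])
}
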