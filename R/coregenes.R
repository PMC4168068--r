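# Core-genome counting between genome pairs: a reference protein is "core"
# with respect to a comparison genome when its best raw alignment score
# against any comparison protein reaches the score threshold (best-hit,
# unidirectional — no reciprocal-best refinement). Percentages of the
# reference's proteome drive the conventional >= 40% grouping rule.

#' Count core proteins of a reference genome in a comparison genome
#'
#' @param reference,comparison `phage_genome` objects (or protein tibbles
#'   with `gene_id`, `aa_seq`), both non-empty.
#' @param score Thresholds, a [core_score_params()].
#' @param params A [scoring_params()].
#' @return Integer: number of reference proteins whose best raw score against
#'   any comparison protein is `>= score$score_threshold` (each reference
#'   protein counted at most once).
#' @export
core_gene_count <- function(reference, comparison,
                            score = core_score_params(),
                            params = scoring_params()) {
  ref <- as_protein_tbl(reference)
  cmp <- as_protein_tbl(comparison)
  assert_that(nrow(ref) > 0 && nrow(cmp) > 0, "empty proteome")
  sum(best_scores(ref, cmp, params) >= score$score_threshold)
}

as_protein_tbl <- function(x) {
  if (inherits(x, "phage_genome")) {
    select(genes(x), "gene_id", "aa_seq")
  } else {
    assert_that(all(c("gene_id", "aa_seq") %in% names(x)),
                "need gene_id and aa_seq columns")
    as_tibble(x)[, c("gene_id", "aa_seq")]
  }
}

# best local raw score of each reference protein vs the whole comparison set
best_scores <- function(ref, cmp, params) {
  mat <- scoring_matrix(params$matrix_name)
  set <- Biostrings::AAStringSet(ref$aa_seq)
  best <- rep(-Inf, nrow(ref))
  for (j in seq_len(nrow(cmp))) {
    sc <- Biostrings::pairwiseAlignment(
      set, Biostrings::AAString(cmp$aa_seq[j]),
      substitutionMatrix = mat, gapOpening = params$gap_open,
      gapExtension = params$gap_extend, type = "local", scoreOnly = TRUE
    )
    best <- pmax(best, sc)
  }
  best
}

#' Core-genome count and percentage matrix
#'
#' For every ordered (reference, comparison) pair, the number of reference
#' proteins with a comparison hit at or above the score threshold and that
#' count as a percentage of the reference's proteome (two decimals, half-up;
#' diagonal exactly 100). The matrix is not symmetric because reference
#' totals differ.
#'
#' @param genomes List of at least two `phage_genome` objects.
#' @inheritParams core_gene_count
#' @return Object of class `core_genes_matrix`: list with `names`, `counts`
#'   (reference x comparison), `percentages`, `totals`.
#' @export
core_percentage_matrix <- function(genomes, score = core_score_params(),
                                   params = scoring_params()) {
  assert_that(length(genomes) >= 2, "need at least two genomes")
  nm <- map_chr(genomes, function(g) g$name)
  tbls <- lapply(genomes, as_protein_tbl)
  n <- length(genomes)
  counts <- matrix(0L, n, n, dimnames = list(reference = nm, comparison = nm))
  totals <- map_int(tbls, nrow)
  for (r in seq_len(n)) {
    for (c in seq_len(n)) {
      counts[r, c] <- if (r == c) totals[r] else {
        sum(best_scores(tbls[[r]], tbls[[c]], params) >= score$score_threshold)
      }
    }
  }
  new_core_genes_matrix(nm, counts, totals)
}

#' Assemble a core-genes matrix from planted counts
#'
#' Builds the same `core_genes_matrix` object from already-known core-gene
#' counts and proteome totals, for exercising the percentage and grouping
#' arithmetic directly.
#'
#' @param counts Square integer matrix (reference rows x comparison columns)
#'   with genome names as dimnames.
#' @param totals Integer vector of proteome sizes per genome.
#' @return A `core_genes_matrix`.
#' @export
core_matrix_from_counts <- function(counts, totals) {
  nm <- rownames(counts)
  assert_that(!is.null(nm) && identical(nm, colnames(counts)),
              "counts needs identical row and column names")
  new_core_genes_matrix(nm, counts, as.integer(totals))
}

new_core_genes_matrix <- function(nm, counts, totals) {
  percentages <- round_half_up(100 * sweep(counts, 1, totals, "/"), 2)
  diag(percentages) <- 100
  structure(
    list(names = nm, counts = counts, percentages = percentages,
         totals = setNames(as.integer(totals), nm)),
    class = "core_genes_matrix"
  )
}

#' @export
print.core_genes_matrix <- function(x, ...) {
  cat("<core_genes_matrix> ", length(x$names), " genomes\n", sep = "")
  cells <- matrix(sprintf("%d (%.2f%%)", x$counts, x$percentages),
                  nrow = length(x$names),
                  dimnames = list(sprintf("%s (%d gp)", x$names, x$totals),
                                  x$names))
  print(cells, quote = FALSE)
  invisible(x)
}

#' @export
tidy.core_genes_matrix <- function(x, ...) {
  tidyr::expand_grid(reference = x$names, comparison = x$names) |>
    mutate(
      count = as.vector(t(x$counts)),
      percentage = as.vector(t(x$percentages)),
      reference_total = x$totals[.data$reference]
    )
}

#' @export
glance.core_genes_matrix <- function(x, ...) {
  off <- x$percentages[row(x$percentages) != col(x$percentages)]
  tibble(n_genomes = length(x$names),
         min_pct = min(off), max_pct = max(off),
         n_pairs_over_40 = sum(off >= 40) / 2)
}

#' @export
autoplot.core_genes_matrix <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$comparison, y = .data$reference,
                               fill = .data$percentage)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%d\n(%.2f%%)", .data$count, .data$percentage)
    ), size = 2.6) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 100)) +
    ggplot2::labs(x = "comparison genome", y = "reference genome",
                  fill = "% core") +
    ggplot2::theme_minimal()
}

#' Group genomes by the core-percentage rule
#'
#' Links two genomes when either directed core percentage reaches the cutoff
#' (40% by convention) and returns the connected components — the standard
#' family-level grouping heuristic for phages.
#'
#' @param m A `core_genes_matrix`.
#' @param cutoff_pct Grouping cutoff (default 40; `>=` applies).
#' @return List of character vectors, one per group, each sorted; groups
#'   ordered by their first member.
#' @export
group_by_core_threshold <- function(m, cutoff_pct = 40) {
  stopifnot(inherits(m, "core_genes_matrix"))
  p <- m$percentages
  adj <- (p >= cutoff_pct) | (t(p) >= cutoff_pct)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "max")
  comp <- igraph::components(g)$membership
  groups <- split(m$names, comp)
  groups <- lapply(groups, sort)
  groups <- groups[order(map_chr(groups, 1))]
  unname(groups)
}
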