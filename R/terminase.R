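# Distance-based phylogeny of large terminase proteins and the pham-overlay
# inference of DNA packaging strategy. The distance is a p-distance
# (1 - fractional identity from pairwise local alignment); the tree is for
# pham-consistency checking, not for branch-length inference under a
# substitution model.

#' Pairwise p-distance matrix of proteins
#'
#' `d[i, j] = 1 - pct_identity(i, j) / 100` from [align_proteins()];
#' symmetric with a zero diagonal.
#'
#' @param proteins Tibble with columns `name`, `aa_seq` (>= 3 rows).
#' @param params A [scoring_params()].
#' @return Symmetric numeric matrix with `name` dimnames.
#' @export
terminase_distances <- function(proteins, params = scoring_params()) {
  assert_that(all(c("name", "aa_seq") %in% names(proteins)),
              "proteins needs columns name, aa_seq")
  n <- nrow(proteins)
  assert_that(n >= 3, "need at least three proteins")
  d <- matrix(0, n, n, dimnames = list(proteins$name, proteins$name))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- align_proteins(proteins$aa_seq[i], proteins$aa_seq[j], params)
      d[i, j] <- d[j, i] <- 1 - r$pct_identity / 100
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou--Nei neighbor joining: iteratively joins the pair minimizing the
#' Q-criterion, with branch lengths from the standard formulas. Negative
#' branch lengths are clamped to zero with the deficit transferred to the
#' sister branch so leaf-to-leaf path lengths are preserved; ties on the
#' Q-matrix are broken by the smallest `(i, j)` index pair, making the result
#' deterministic. On an additive matrix the tree reproduces every pairwise
#' distance exactly.
#'
#' @param d Symmetric distance matrix with taxon dimnames, zero diagonal
#'   and at least three taxa.
#' @return An unrooted `ape::phylo` tree (root trifurcation).
#' @export
neighbor_joining <- function(d) {
  assert_that(is.matrix(d) && nrow(d) == ncol(d), "d must be square")
  assert_that(isTRUE(all.equal(d, t(d), tolerance = 1e-8)),
              "distance matrix must be symmetric")
  n <- nrow(d)
  assert_that(n >= 3, "need at least three taxa")
  taxa <- rownames(d) %||% paste0("t", seq_len(n))
  # newick fragment per active node
  labs <- taxa
  D <- d
  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    # smallest (i, j), i < j, among minima
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    vi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    cl <- clamp_pair(vi, vj)
    new_lab <- sprintf("(%s:%.10f,%s:%.10f)", labs[i], cl[1], labs[j], cl[2])
    # distances from the new node to the others
    others <- setdiff(seq_len(m), c(i, j))
    dnew <- 0.5 * (D[i, others] + D[j, others] - D[i, j])
    D <- rbind(cbind(D[others, others, drop = FALSE], dnew),
               c(dnew, 0))
    labs <- c(labs[others], new_lab)
    rownames(D) <- colnames(D) <- NULL
  }
  # final three nodes joined at the root trifurcation
  va <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  vb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  vc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  v <- pmax(c(va, vb, vc), 0)
  nwk <- sprintf("(%s:%.10f,%s:%.10f,%s:%.10f);",
                 labs[1], v[1], labs[2], v[2], labs[3], v[3])
  ape::read.tree(text = nwk)
}

# clamp a negative branch of a joined pair to zero, moving the deficit to the
# sister so the path through the new node keeps its length
clamp_pair <- function(vi, vj) {
  if (vi < 0) { vj <- vj + vi; vi <- 0 }
  if (vj < 0) { vi <- max(vi + vj, 0); vj <- 0 }
  c(vi, vj)
}

#' Write a tree as Newick
#'
#' @param tree An `ape::phylo`.
#' @param path Output path.
#' @param digits Branch-length precision (default 6).
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path, digits = 6) {
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}

#' Infer DNA packaging strategy from terminase phams
#'
#' A phage's packaging strategy is taken from the experimentally characterized
#' phages whose large terminase falls in the same pham: if exactly one
#' strategy occurs among those pham-mates, it is assigned with the mate as
#' evidence; an orpham terminase, or a pham with no characterized member,
#' yields `"undetermined"`; conflicting strategies within one pham violate
#' the expected consistency and raise an error naming the pham.
#'
#' @param p A `pham_partition` covering the terminase genes.
#' @param terminase_ids Tibble `phage`, `gene_id`: the designated large
#'   terminase gene of every phage (exactly one per phage).
#' @param known Tibble `phage`, `strategy` for experimentally characterized
#'   phages; strategies are one of `"headful_circularly_permuted"`,
#'   `"cohesive_ends_3prime"`, `"long_direct_terminal_repeats"`.
#' @return Tibble: `phage`, `terminase_gene`, `pham_id`, `strategy`,
#'   `evidence`.
#' @export
infer_packaging <- function(p, terminase_ids, known) {
  assert_that(all(c("phage", "gene_id") %in% names(terminase_ids)),
              "terminase_ids needs columns phage, gene_id")
  assert_that(!anyDuplicated(terminase_ids$phage),
              "each phage must have exactly one terminase gene")
  strategies <- c("headful_circularly_permuted", "cohesive_ends_3prime",
                  "long_direct_terminal_repeats")
  if (nrow(known) > 0) {
    assert_that(all(known$strategy %in% strategies),
                "unknown packaging strategy in `known`")
  }
  tm <- terminase_ids |>
    left_join(as_tibble(p)[, c("gene_id", "pham_id", "pham_size")],
              by = "gene_id")
  assert_that(!anyNA(tm$pham_id),
              "terminase gene absent from the pham partition")
  tm <- left_join(tm, known, by = "phage")
  out <- vector("list", nrow(tm))
  for (k in seq_len(nrow(tm))) {
    row <- tm[k, ]
    in_pham <- filter(tm, .data$pham_id == row$pham_id, !is.na(.data$strategy))
    mates <- filter(in_pham, .data$phage != row$phage)
    strats <- unique(mates$strategy)
    if (length(unique(in_pham$strategy)) > 1) {
      abort(paste0("conflicting packaging strategies in pham ", row$pham_id,
                   ": ", paste(strats, collapse = " vs ")))
    }
    if (row$pham_size == 1) {
      call <- "undetermined"; ev <- "orpham"
    } else if (length(strats) == 1) {
      call <- strats; ev <- paste(sort(mates$phage), collapse = ",")
    } else {
      call <- "undetermined"; ev <- "no_characterized_pham_member"
    }
    out[[k]] <- tibble(phage = row$phage, terminase_gene = row$gene_id,
                       pham_id = row$pham_id, strategy = call, evidence = ev)
  }
  bind_rows(out)
}
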