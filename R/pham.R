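# Pham clustering: all-vs-all protein similarity edges filtered by the dual
# threshold, then single-linkage grouping (connected components). A pham with
# one member is an orpham. Pham ids are dense integers assigned so that the
# component containing the lexicographically smallest gene_id gets the
# smallest id, making partitions reproducible regardless of input order.

#' Build the protein similarity graph
#'
#' All-vs-all local alignment of a protein set (one comparison per unordered
#' pair), with each pair flagged as passing when its E-value is strictly
#' below `thresholds$evalue_max` OR its percent identity is strictly above
#' `thresholds$identity_min_pct`. Self-comparisons are excluded.
#'
#' @param proteins Tibble with columns `gene_id`, `aa_seq` (a `phage` column,
#'   if present, is carried along; see [cohort_proteins()]).
#' @param thresholds A [pham_thresholds()].
#' @param params A [scoring_params()].
#' @return Edge tibble: `protein_a`, `protein_b`, `raw_score`, `evalue`,
#'   `pct_identity`, `aln_length`, `passes`.
#' @export
build_similarity_graph <- function(proteins,
                                   thresholds = pham_thresholds(),
                                   params = scoring_params()) {
  edges <- all_vs_all_similarity(proteins, params)
  edges |>
    rename(protein_a = "query", protein_b = "subject") |>
    mutate(passes = .data$evalue < thresholds$evalue_max |
             .data$pct_identity > thresholds$identity_min_pct) |>
    select("protein_a", "protein_b", "raw_score", "evalue",
           "pct_identity", "aln_length", "passes")
}

#' Cluster proteins into phams
#'
#' Single-linkage clustering: phams are the connected components of the graph
#' whose edges pass the dual threshold, so membership only requires a passing
#' comparison with at least one other member. Proteins with no passing edge
#' form size-1 phams (orphams). Identical duplicate sequences remain distinct
#' members.
#'
#' @param edges Edge tibble from [build_similarity_graph()] (needs
#'   `protein_a`, `protein_b`, `passes`).
#' @param proteins Tibble of all proteins (`gene_id`, optionally `phage`);
#'   proteins without edges still get a pham.
#' @return A `pham_partition`: tibble with columns `gene_id`, `phage`,
#'   `pham_id`, `pham_size`, `is_orpham`, carrying the edge table as an
#'   attribute for later re-clustering.
#' @export
cluster_phams <- function(edges, proteins) {
  assert_that(all(c("gene_id") %in% names(proteins)), "proteins needs gene_id")
  assert_that(!anyDuplicated(proteins$gene_id), "duplicate gene_id")
  ids <- proteins$gene_id
  unknown <- setdiff(c(edges$protein_a, edges$protein_b), ids)
  if (length(unknown) > 0) {
    abort(paste0("edges reference unknown proteins: ",
                 paste(unknown, collapse = ", ")))
  }
  pass <- filter(edges, .data$passes)
  g <- igraph::graph_from_data_frame(
    pass[, c("protein_a", "protein_b")], directed = FALSE,
    vertices = data.frame(name = ids)
  )
  comp <- igraph::components(g)$membership[ids]
  # deterministic dense ids: order components by their smallest gene_id
  smallest <- tapply(ids, comp, function(x) min(sort(x)))
  rank <- rank(smallest, ties.method = "first")
  pham_id <- as.integer(rank[as.character(comp)])
  phage <- if ("phage" %in% names(proteins)) proteins$phage else
    infer_phage_from_id(ids)
  out <- tibble(gene_id = ids, phage = phage, pham_id = pham_id) |>
    group_by(.data$pham_id) |>
    mutate(pham_size = n()) |>
    ungroup() |>
    mutate(is_orpham = .data$pham_size == 1L) |>
    arrange(.data$pham_id, .data$gene_id)
  structure(out, edges = edges,
            class = c("pham_partition", class(out)))
}

# gene ids follow the "<phage>_gp<N>" convention; fall back to the id itself
infer_phage_from_id <- function(ids) {
  out <- sub("_gp[0-9]+$", "", ids)
  ifelse(out == ids, ids, out)
}

#' @export
print.pham_partition <- function(x, ...) {
  s <- pham_summary(x)
  cat("<pham_partition> ", s$n_proteins, " proteins in ", s$n_phams,
      " phams (", s$n_orphams, " orphams)\n", sep = "")
  NextMethod()
}

#' @export
tidy.pham_partition <- function(x, ...) {
  as_tibble(unclass_partition(x))
}

#' @export
glance.pham_partition <- function(x, ...) pham_summary(x)

unclass_partition <- function(x) {
  class(x) <- setdiff(class(x), "pham_partition")
  attr(x, "edges") <- NULL
  x
}

#' Summarize a pham partition
#'
#' Counts of phams, multi-member phams, proteins covered by them and orphams,
#' with the corresponding percentages to one decimal (half-up).
#'
#' @param p A `pham_partition` (or any tibble with `gene_id` and `pham_id`).
#' @return One-row tibble: `n_proteins`, `n_phams`, `n_multimember_phams`,
#'   `n_proteins_in_multimember`, `n_orphams`, `pct_multimember_phams`,
#'   `pct_proteins_in_multimember`, `pct_orphams`.
#' @export
pham_summary <- function(p) {
  sizes <- table(p$pham_id)
  n_proteins <- nrow(p)
  n_phams <- length(sizes)
  n_multi <- sum(sizes >= 2)
  n_in_multi <- sum(sizes[sizes >= 2])
  n_orph <- sum(sizes == 1)
  tibble(
    n_proteins = n_proteins,
    n_phams = n_phams,
    n_multimember_phams = n_multi,
    n_proteins_in_multimember = n_in_multi,
    n_orphams = n_orph,
    pct_multimember_phams = pct(n_multi, n_phams),
    pct_proteins_in_multimember = pct(n_in_multi, n_proteins),
    pct_orphams = pct(n_orph, n_proteins)
  )
}

#' Construct a partition from planted pham sizes
#'
#' Builds a synthetic `pham_partition`-shaped tibble with the given pham
#' sizes, for exercising summary arithmetic on known counts.
#'
#' @param sizes Integer vector of pham sizes (each >= 1).
#' @return Tibble with `gene_id`, `phage`, `pham_id`, `pham_size`,
#'   `is_orpham`.
#' @export
partition_from_sizes <- function(sizes) {
  assert_that(all(sizes >= 1), "pham sizes must be >= 1")
  pham_id <- rep(seq_along(sizes), sizes)
  tibble(
    gene_id = sprintf("g%07d", seq_along(pham_id)),
    phage = "synthetic",
    pham_id = pham_id,
    pham_size = rep(as.integer(sizes), sizes),
    is_orpham = rep(sizes == 1L, sizes)
  )
}

#' Classify each phage's genes by pham sharing
#'
#' For every phage in `focal_group`, classifies each gene into exactly one of
#' three categories: shared with a phage outside the focal group (its pham
#' has a member from another host's phage), focal-group-only (pham size >= 2
#' but members only within the focal group), or orpham.
#'
#' @param p A `pham_partition` whose `phage` column is populated.
#' @param focal_group Character vector of phage names to report rows for.
#' @return Tibble: `phage`, `n_shared_outside`, `n_focal_only`, `n_orphams`,
#'   `n_genes` (the three categories sum to `n_genes`).
#' @export
shared_pham_table <- function(p, focal_group) {
  known <- unique(p$phage)
  missing <- setdiff(focal_group, known)
  if (length(missing) > 0) {
    abort(paste0("focal phages absent from partition: ",
                 paste(missing, collapse = ", ")))
  }
  pham_outside <- as_tibble(p) |>
    group_by(.data$pham_id) |>
    summarise(has_outside = any(!.data$phage %in% focal_group),
              .groups = "drop")
  as_tibble(p) |>
    filter(.data$phage %in% focal_group) |>
    left_join(pham_outside, by = "pham_id") |>
    mutate(category = dplyr::case_when(
      has_outside ~ "shared_outside",
      pham_size >= 2 ~ "focal_only",
      TRUE ~ "orpham"
    )) |>
    group_by(phage = .data$phage) |>
    summarise(
      n_shared_outside = sum(.data$category == "shared_outside"),
      n_focal_only = sum(.data$category == "focal_only"),
      n_orphams = sum(.data$category == "orpham"),
      n_genes = n(),
      .groups = "drop"
    ) |>
    arrange(match(.data$phage, focal_group))
}

#' Re-cluster after removing one genome
#'
#' Drops the victim phage's proteins, re-clusters the remaining similarity
#' graph from scratch, and reports which surviving proteins become orphams —
#' the "would be orphams if X were not isolated" question.
#'
#' @param p A `pham_partition` built by [cluster_phams()] (so it carries its
#'   edge table).
#' @param victim Phage name to remove.
#' @return List with `partition` (the re-clustered remainder),
#'   `newly_orphamed` (gene ids that were in multi-member phams but are now
#'   orphams), `summary_before`, `summary_after`.
#' @export
remove_genome_recount <- function(p, victim) {
  assert_that(victim %in% p$phage, paste0("unknown victim phage: ", victim))
  edges <- attr(p, "edges")
  assert_that(!is.null(edges), "partition carries no edge table")
  keep_tbl <- filter(as_tibble(p), .data$phage != victim)
  gone <- setdiff(p$gene_id, keep_tbl$gene_id)
  edges2 <- filter(edges, !.data$protein_a %in% gone,
                   !.data$protein_b %in% gone)
  p2 <- cluster_phams(edges2, keep_tbl[, c("gene_id", "phage")])
  was_multi <- filter(as_tibble(p), !.data$is_orpham)$gene_id
  now_orph <- filter(as_tibble(p2), .data$is_orpham)$gene_id
  list(
    partition = p2,
    newly_orphamed = sort(intersect(was_multi, now_orph)),
    summary_before = pham_summary(p),
    summary_after = pham_summary(p2)
  )
}

#' Phamily circle layout for one pham
#'
#' Lays the cohort's phages on a circle (in the given order) and links every
#' pair of member genes of the chosen pham, the data behind a phamily-circle
#' diagram.
#'
#' @param p A `pham_partition`.
#' @param pham_id Pham to draw.
#' @param genome_order Character vector giving the circular phage order;
#'   defaults to sorted unique phages in `p`.
#' @return List with `members` (tibble `phage`, `gene_id`, `theta` position)
#'   and `links` (tibble `from`, `to`; `k` members yield `k*(k-1)/2` rows).
#' @export
pham_circle <- function(p, pham_id, genome_order = NULL) {
  assert_that(pham_id %in% p$pham_id, paste0("unknown pham: ", pham_id))
  pid <- pham_id
  genome_order <- genome_order %||% sort(unique(p$phage))
  mem <- filter(as_tibble(p), .data$pham_id == pid) |>
    arrange(match(.data$phage, genome_order), .data$gene_id)
  pos <- match(mem$phage, genome_order)
  members <- tibble(phage = mem$phage, gene_id = mem$gene_id,
                    theta = 2 * pi * (pos - 1) / length(genome_order))
  links <- if (nrow(mem) < 2) {
    tibble(from = character(), to = character())
  } else {
    pairs <- utils::combn(mem$gene_id, 2)
    tibble(from = pairs[1, ], to = pairs[2, ])
  }
  list(members = members, links = links)
}

#' Fraction of phams with a conserved-domain annotation
#'
#' @param p A `pham_partition`.
#' @param domains Tibble mapping `gene_id` to domain hits (any extra columns
#'   ignored); may be empty.
#' @return Percentage of phams with at least one annotated member, one
#'   decimal (half-up).
#' @export
pham_domain_coverage <- function(p, domains) {
  n_phams <- length(unique(p$pham_id))
  if (is.null(domains) || nrow(domains) == 0) return(0.0)
  annotated <- unique(domains$gene_id)
  n_hit <- as_tibble(p) |>
    filter(.data$gene_id %in% annotated) |>
    pull("pham_id") |>
    unique() |>
    length()
  pct(n_hit, n_phams)
}

#' Genome map data for plotting
#'
#' Gene boxes (start, end, strand, pham id/size) per phage, the data behind
#' a color-coded linear genome map.
#'
#' @param p A `pham_partition`.
#' @param genomes List of `phage_genome` objects covering the partition.
#' @return Tibble: `phage`, `gene_id`, `start`, `end`, `strand`, `pham_id`,
#'   `pham_size`, `is_orpham`.
#' @export
genome_map_data <- function(p, genomes) {
  coords <- bind_rows(lapply(genomes, function(g) {
    select(genes(g), "phage", "gene_id", "start", "end", "strand")
  }))
  inner_join(coords,
             as_tibble(p)[, c("gene_id", "pham_id", "pham_size", "is_orpham")],
             by = "gene_id")
}

#' @export
autoplot.pham_partition <- function(object, genomes, ...) {
  d <- genome_map_data(object, genomes)
  d$ymin <- as.integer(factor(d$phage)) - 0.35
  d$ymax <- d$ymin + 0.7
  ggplot2::ggplot(d) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start, xmax = .data$end,
      ymin = .data$ymin, ymax = .data$ymax,
      fill = factor(ifelse(.data$is_orpham, NA, .data$pham_id))
    ), colour = "grey20", linewidth = 0.2, show.legend = FALSE) +
    ggplot2::scale_y_continuous(
      breaks = seq_along(unique(d$phage)), labels = levels(factor(d$phage))
    ) +
    ggplot2::labs(x = "position (bp)", y = NULL) +
    ggplot2::theme_minimal()
}
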