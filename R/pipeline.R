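# End-to-end orchestration: genome stats -> all-vs-all similarity -> pham
# clustering and summaries -> core-genome matrix and grouping -> terminase
# tree and packaging calls (when terminases are designated) -> morphology
# summaries and TMP/tail matching (when measurements are supplied). Every
# table defined by the module interfaces is written to the output directory,
# plus a manifest echoing the configuration and seed.

#' Pipeline configuration
#'
#' @param genomes_dir Directory of single-record GenBank files (`*.gb`,
#'   `*.gbk`, `*.gbff`), or `NULL` when `genomes` are passed to
#'   [run_pipeline()] directly.
#' @param domains_tsv Optional TSV `gene_id`, `domain` of conserved-domain
#'   hits.
#' @param measurements_tsv Optional TSV `phage`, `feature`, `value_nm`.
#' @param known_packaging_tsv Optional TSV `phage`, `strategy`.
#' @param terminase_tsv Optional TSV `phage`, `gene_id` designating large
#'   terminase genes.
#' @param thresholds,scoring,core Parameter objects (see
#'   [pham_thresholds()], [scoring_params()], [core_score_params()]).
#' @param core_group_cutoff Grouping cutoff percentage (default 40).
#' @param focal_group Phage names treated as the focal cohort for the
#'   shared-pham table; defaults to all genomes.
#' @param out_dir Output directory (created if needed).
#' @param seed Seed recorded in the manifest and used by any stochastic step.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(genomes_dir = NULL, domains_tsv = NULL,
                            measurements_tsv = NULL,
                            known_packaging_tsv = NULL,
                            terminase_tsv = NULL,
                            thresholds = pham_thresholds(),
                            scoring = scoring_params(),
                            core = core_score_params(),
                            core_group_cutoff = 40,
                            focal_group = NULL,
                            out_dir = "phamily_out",
                            seed = 1L) {
  for (p in c(genomes_dir, domains_tsv, measurements_tsv,
              known_packaging_tsv, terminase_tsv)) {
    assert_that(is.null(p) || file.exists(p), paste0("path not found: ", p))
  }
  structure(
    list(genomes_dir = genomes_dir, domains_tsv = domains_tsv,
         measurements_tsv = measurements_tsv,
         known_packaging_tsv = known_packaging_tsv,
         terminase_tsv = terminase_tsv, thresholds = thresholds,
         scoring = scoring, core = core,
         core_group_cutoff = core_group_cutoff, focal_group = focal_group,
         out_dir = out_dir, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the comparative-genomics pipeline
#'
#' @param config A [pipeline_config()].
#' @param genomes Optional list of `phage_genome` objects; when `NULL` they
#'   are read from `config$genomes_dir`.
#' @return Invisibly, a list with every stage result (`stats`, `edges`,
#'   `partition`, `pham_summary`, `shared_phams`, `core_matrix`, `groups`,
#'   and, when inputs allow, `tree`, `packaging`, `morphology`); all tables
#'   are also written under `config$out_dir` together with `manifest.json`.
#' @export
run_pipeline <- function(config, genomes = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  if (is.null(genomes)) {
    genomes <- stage("read_genomes", {
      paths <- list.files(config$genomes_dir,
                          pattern = "\\.(gb|gbk|gbff)$", full.names = TRUE)
      assert_that(length(paths) >= 2, "need at least two genomes")
      lapply(sort(paths), read_genbank)
    })
  }
  assert_that(length(genomes) >= 2, "need at least two genomes")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  stats <- stage("genome_stats", cohort_stats(genomes))
  readr::write_tsv(stats, out("genome_stats.tsv"))

  proteins <- cohort_proteins(genomes)
  edges <- stage("similarity",
                 build_similarity_graph(proteins, config$thresholds,
                                        config$scoring))
  readr::write_tsv(edges, out("similarity_edges.tsv"))

  partition <- stage("pham_clustering", cluster_phams(edges, proteins))
  readr::write_tsv(tidy(partition), out("pham_partition.tsv"))
  summ <- pham_summary(partition)
  jsonlite::write_json(as.list(summ), out("pham_summary.json"),
                       auto_unbox = TRUE, digits = NA)

  focal <- config$focal_group %||% map_chr(genomes, function(g) g$name)
  shared <- stage("shared_phams", shared_pham_table(partition, focal))
  readr::write_tsv(shared, out("shared_pham_table.tsv"))

  cg <- stage("core_genes",
              core_percentage_matrix(genomes, config$core, config$scoring))
  readr::write_tsv(tidy(cg), out("core_genes_matrix.tsv"))
  groups <- group_by_core_threshold(cg, config$core_group_cutoff)
  jsonlite::write_json(groups, out("core_groups.json"))

  if (!is.null(config$domains_tsv)) {
    domains <- readr::read_tsv(config$domains_tsv, show_col_types = FALSE)
    cov <- pham_domain_coverage(partition, domains)
    jsonlite::write_json(list(pct_phams_with_domain = cov),
                         out("domain_coverage.json"), auto_unbox = TRUE,
                         digits = NA)
  }

  tree <- NULL; packaging <- NULL
  if (!is.null(config$terminase_tsv)) {
    terminases <- readr::read_tsv(config$terminase_tsv,
                                  show_col_types = FALSE)
    aa <- proteins |>
      filter(.data$gene_id %in% terminases$gene_id) |>
      rename(name = "phage")
    if (nrow(aa) >= 3) {
      d <- stage("terminase_distances",
                 terminase_distances(aa, config$scoring))
      tree <- stage("neighbor_joining", neighbor_joining(d))
      write_tree_newick(tree, out("terminase_tree.nwk"))
    }
    known <- if (!is.null(config$known_packaging_tsv)) {
      readr::read_tsv(config$known_packaging_tsv, show_col_types = FALSE)
    } else {
      tibble(phage = character(), strategy = character())
    }
    packaging <- stage("packaging",
                       infer_packaging(partition, terminases, known))
    readr::write_tsv(packaging, out("packaging_calls.tsv"))
  }

  morph <- NULL
  if (!is.null(config$measurements_tsv)) {
    meas <- readr::read_tsv(config$measurements_tsv, show_col_types = FALSE)
    morph <- stage("morphology", morphology_summary(meas))
    readr::write_tsv(morph, out("morphology_summary.tsv"))
  }

  manifest <- list(
    package = "phamily",
    version = as.character(utils::packageVersion("phamily")),
    seed = config$seed,
    thresholds = unclass(config$thresholds),
    scoring = unclass(config$scoring)[c("matrix_name", "gap_open",
                                        "gap_extend", "ka_lambda", "ka_K",
                                        "search_space_policy")],
    core_score_threshold = config$core$score_threshold,
    core_group_cutoff = config$core_group_cutoff,
    focal_group = focal,
    genomes = map_chr(genomes, function(g) g$name),
    outputs = list.files(config$out_dir)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")

  invisible(list(stats = stats, edges = edges, partition = partition,
                 pham_summary = summ, shared_phams = shared,
                 core_matrix = cg, groups = groups, tree = tree,
                 packaging = packaging, morphology = morph,
                 manifest = manifest))
}
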