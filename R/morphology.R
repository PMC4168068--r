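# Electron-micrograph morphology: replicate summaries (mean +/- sample sd),
# morphotype classification, and the tape-measure-protein (TMP) gene length
# vs tail length rank matching that identifies co-isolated phages.

#' Summarize structural measurements
#'
#' Mean and sample (n-1) standard deviation per phage and feature, one
#' decimal (half-up) — the "mean ± sd" cells of a structure table.
#'
#' @param measurements Tibble with columns `phage`, `feature`, `value_nm`
#'   (one row per replicate; values in nm, > 0). Every `(phage, feature)`
#'   group needs at least two replicates, otherwise the sd is undefined and
#'   an error is raised.
#' @return Tibble: `phage`, `feature`, `mean_nm`, `sd_nm`, `n`.
#' @export
morphology_summary <- function(measurements) {
  assert_that(all(c("phage", "feature", "value_nm") %in% names(measurements)),
              "measurements needs columns phage, feature, value_nm")
  assert_that(all(measurements$value_nm > 0), "measurements must be positive")
  out <- measurements |>
    group_by(.data$phage, .data$feature) |>
    summarise(mean_nm = round_half_up(mean(.data$value_nm), 1),
              sd_nm = round_half_up(sd(.data$value_nm), 1),
              n = n(), .groups = "drop")
  if (any(out$n < 2)) {
    bad <- filter(out, .data$n < 2)
    abort(paste0("sd undefined with fewer than 2 replicates: ",
                 paste(bad$phage, bad$feature, sep = "/", collapse = ", ")))
  }
  out
}

#' Classify phage morphotype
#'
#' A contractile tail sheath marks a myovirus. Siphoviruses split by capsid
#' aspect ratio (height / width): above the elongation cutoff they are
#' elongated, otherwise round; phages lacking capsid measurements cannot be
#' placed in either siphovirus group.
#'
#' @param features Tibble with columns `phage`, `contractile_sheath`
#'   (logical), `capsid_height`, `capsid_width` (nm; may be `NA`).
#' @param elongation_cutoff Aspect-ratio cutoff separating elongated from
#'   round capsids (default 1.2; published elongated phages sit at >= 1.47
#'   and round ones at <= 1.11, so the boundary is uncontested).
#' @return Tibble: `phage`, `morphotype`, `aspect_ratio`.
#' @export
classify_morphotype <- function(features, elongation_cutoff = 1.2) {
  assert_that(all(c("phage", "contractile_sheath") %in% names(features)),
              "features needs columns phage, contractile_sheath")
  features |>
    mutate(
      aspect_ratio = ifelse(
        is.na(.data$capsid_height) | is.na(.data$capsid_width),
        NA_real_, .data$capsid_height / .data$capsid_width
      ),
      morphotype = dplyr::case_when(
        contractile_sheath ~ "myovirus",
        is.na(aspect_ratio) ~ "siphovirus_unclassified",
        aspect_ratio > elongation_cutoff ~ "siphovirus_elongated",
        TRUE ~ "siphovirus_round"
      )
    ) |>
    select("phage", "morphotype", "aspect_ratio")
}

#' Match co-isolated phages to genomes by TMP gene and tail length
#'
#' When one sample contains several phages, genomes are matched to imaged
#' particles by rank order: the longest tape-measure-protein gene goes with
#' the longest tail, and so on — the positive TMP-length/tail-length
#' correlation. Ratios between consecutive ranked pairs are reported for both
#' scales (two decimals, half-up) so the correspondence can be eyeballed.
#'
#' @param tmp_lengths Tibble `genome`, `tmp_bp` (all distinct).
#' @param tail_lengths Tibble `image`, `tail_nm` (all distinct; same number
#'   of rows as `tmp_lengths`).
#' @return Object of class `tmp_tail_match`: list with `assignments`
#'   (tibble `genome`, `image`, `tmp_bp`, `tail_nm`, `rank`) and `ratios`
#'   (tibble `rank_pair`, `tmp_ratio`, `tail_ratio`).
#' @export
match_coisolated <- function(tmp_lengths, tail_lengths) {
  assert_that(all(c("genome", "tmp_bp") %in% names(tmp_lengths)),
              "tmp_lengths needs columns genome, tmp_bp")
  assert_that(all(c("image", "tail_nm") %in% names(tail_lengths)),
              "tail_lengths needs columns image, tail_nm")
  assert_that(nrow(tmp_lengths) == nrow(tail_lengths),
              "need equal numbers of genomes and imaged phages")
  if (anyDuplicated(tmp_lengths$tmp_bp) || anyDuplicated(tail_lengths$tail_nm)) {
    abort("tied lengths make the rank assignment ambiguous")
  }
  g <- arrange(as_tibble(tmp_lengths), dplyr::desc(.data$tmp_bp))
  t <- arrange(as_tibble(tail_lengths), dplyr::desc(.data$tail_nm))
  k <- nrow(g)
  assignments <- tibble(genome = g$genome, image = t$image,
                        tmp_bp = g$tmp_bp, tail_nm = t$tail_nm,
                        rank = seq_len(k))
  ratios <- if (k < 2) {
    tibble(rank_pair = character(), tmp_ratio = numeric(),
           tail_ratio = numeric())
  } else {
    tibble(
      rank_pair = paste(seq_len(k - 1), 2:k, sep = "/"),
      tmp_ratio = round_half_up(g$tmp_bp[-k] / g$tmp_bp[-1], 2),
      tail_ratio = round_half_up(t$tail_nm[-k] / t$tail_nm[-1], 2)
    )
  }
  structure(list(assignments = assignments, ratios = ratios),
            class = "tmp_tail_match")
}

#' @export
print.tmp_tail_match <- function(x, ...) {
  cat("<tmp_tail_match>\n")
  print(x$assignments)
  if (nrow(x$ratios)) print(x$ratios)
  invisible(x)
}

#' @export
tidy.tmp_tail_match <- function(x, ...) x$assignments
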