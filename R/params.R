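#' Protein alignment scoring parameters
#'
#' Parameters for exact local (Smith--Waterman) protein alignment and its
#' Karlin--Altschul E-value. Defaults are the gapped BLOSUM62 11/1 scheme with
#' the published gapped constants (lambda = 0.267, K = 0.041), so raw scores
#' live on the familiar BLASTP scale while remaining fully deterministic.
#'
#' @param matrix_name Substitution matrix name; only `"BLOSUM62"` ships.
#' @param gap_open Gap opening penalty (positive; a gap of length k costs
#'   `gap_open + k * gap_extend`).
#' @param gap_extend Gap extension penalty (positive, per residue).
#' @param ka_lambda,ka_K Karlin--Altschul gapped constants used for bit scores
#'   and E-values.
#' @param search_space_policy `"pairwise_mn"` (E-value search space is the
#'   product of the two sequence lengths; proteins are compared pairwise, not
#'   against a database) or `"fixed_db"` (uses `m * fixed_db_size`, for
#'   replaying database-style E-values).
#' @param fixed_db_size Effective database size, required for `"fixed_db"`.
#' @return A list of class `scoring_params`.
#' @examples
#' scoring_params()
#' @export
scoring_params <- function(matrix_name = "BLOSUM62",
                           gap_open = 11L,
                           gap_extend = 1L,
                           ka_lambda = 0.267,
                           ka_K = 0.041,
                           search_space_policy = c("pairwise_mn", "fixed_db"),
                           fixed_db_size = NULL) {
  search_space_policy <- match.arg(search_space_policy)
  assert_that(gap_open > 0 && gap_extend > 0, "gap penalties must be positive")
  assert_that(ka_lambda > 0 && ka_K > 0, "Karlin-Altschul constants must be positive")
  if (search_space_policy == "fixed_db") {
    assert_that(is.numeric(fixed_db_size) && fixed_db_size > 0,
                "fixed_db policy requires a positive fixed_db_size")
  }
  structure(
    list(matrix_name = matrix_name, gap_open = as.integer(gap_open),
         gap_extend = as.integer(gap_extend), ka_lambda = ka_lambda,
         ka_K = ka_K, search_space_policy = search_space_policy,
         fixed_db_size = fixed_db_size),
    class = "scoring_params"
  )
}

#' Pham membership thresholds
#'
#' The dual cutoff that admits a protein pair into the similarity graph used
#' for pham clustering: a pair is linked when its E-value is strictly below
#' `evalue_max` OR its percent identity is strictly above `identity_min_pct`.
#' Boundary values fail on purpose: an E-value of exactly 1e-50 or an identity
#' of exactly 32.5 does not link a pair.
#'
#' @param evalue_max E-value ceiling (strict `<`). Default `1e-50`.
#' @param identity_min_pct Percent identity floor (strict `>`). Default 32.5.
#' @return A list of class `pham_thresholds`.
#' @export
pham_thresholds <- function(evalue_max = 1e-50, identity_min_pct = 32.5) {
  assert_that(evalue_max > 0, "evalue_max must be positive")
  assert_that(identity_min_pct >= 0 && identity_min_pct <= 100,
              "identity_min_pct must be in [0, 100]")
  structure(list(evalue_max = evalue_max, identity_min_pct = identity_min_pct),
            class = "pham_thresholds")
}

#' Core-gene score threshold
#'
#' A reference protein counts as a core gene of a comparison genome when its
#' best raw alignment score against any comparison protein reaches
#' `score_threshold`. The default of 75 is the conventional raw-score floor
#' for core-genome counting; whether such floors are raw or bit scores is not
#' universally stated, so the value is exposed as a parameter.
#'
#' @param score_threshold Positive raw-score floor (best hit must be `>=`).
#' @return A list of class `core_score_params`.
#' @export
core_score_params <- function(score_threshold = 75) {
  assert_that(score_threshold > 0, "score_threshold must be positive")
  structure(list(score_threshold = score_threshold), class = "core_score_params")
}
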