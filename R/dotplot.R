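#' Exact-word dotplot of two sequences
#'
#' Enumerates every pair of positions `(i, j)` (0-based) where the word of
#' length `word_size` starting at `i` in `a` equals the word starting at `j`
#' in `b` — the classic word-match dotplot used to eyeball phage genome
#' relatedness. For nucleotide sequences, matches against the
#' reverse-complement of the `b` word are reported too, tagged separately.
#'
#' @param a,b Sequences (character scalars).
#' @param word_size Word length (>= 1).
#' @param alphabet `"nt"` (default; reverse-complement words also indexed)
#'   or `"aa"`.
#' @return A tibble of class `dotplot_matrix` with columns `i`, `j` (0-based
#'   word start positions) and `strand` (`"forward"` or `"reverse"`), plus
#'   attributes `word_size`, `len_a`, `len_b`, `alphabet`. A `word_size`
#'   longer than either sequence yields an empty matrix with a warning.
#' @examples
#' dotplot("ACGTACGT", "ACGT", word_size = 4)
#' @export
dotplot <- function(a, b, word_size = 10L, alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  assert_that(word_size >= 1, "word_size must be >= 1")
  a <- toupper(a); b <- toupper(b)
  la <- nchar(a); lb <- nchar(b)
  empty <- tibble(i = integer(), j = integer(), strand = character())
  if (word_size > la || word_size > lb) {
    warn("word_size exceeds a sequence length; empty dotplot")
    return(new_dotplot(empty, word_size, la, lb, alphabet))
  }
  words_of <- function(s, len) {
    substring(s, 1:(len - word_size + 1), word_size:len)
  }
  wa <- words_of(a, la)
  wb <- words_of(b, lb)
  hits_join <- function(wb_words, strand) {
    ia <- split(seq_along(wa) - 1L, wa)
    jb <- split(seq_along(wb_words) - 1L, wb_words)
    shared <- intersect(names(ia), names(jb))
    if (length(shared) == 0) return(empty)
    bind_rows(lapply(shared, function(w) {
      tidyr::expand_grid(i = ia[[w]], j = jb[[w]])
    })) |> mutate(strand = strand)
  }
  hits <- hits_join(wb, "forward")
  if (alphabet == "nt") {
    wb_rc <- map_chr(wb, revcomp)
    hits <- bind_rows(hits, hits_join(wb_rc, "reverse"))
  }
  hits <- arrange(hits, .data$i, .data$j, .data$strand)
  new_dotplot(hits, word_size, la, lb, alphabet)
}

new_dotplot <- function(hits, word_size, la, lb, alphabet) {
  structure(hits, word_size = word_size, len_a = la, len_b = lb,
            alphabet = alphabet,
            class = c("dotplot_matrix", class(hits)))
}

#' @describeIn dotplot Plot a dotplot as points in sequence coordinates.
#' @param object A `dotplot_matrix`.
#' @param ... Unused.
#' @export
autoplot.dotplot_matrix <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$i, y = .data$j,
                               colour = .data$strand)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::scale_colour_manual(values = c(forward = "black",
                                            reverse = "red3")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "sequence A (bp)", y = "sequence B (bp)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
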