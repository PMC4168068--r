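#' Construct an annotated phage genome
#'
#' A `phage_genome` bundles a nucleotide sequence with its ordered CDS records.
#' Gene coordinates are 0-based half-open on the forward strand of `sequence`;
#' all file I/O converts to and from 1-based inclusive coordinates at the
#' boundary. Genomes are linear; a gene spanning the sequence end is rejected.
#'
#' @param name Phage name.
#' @param sequence Nucleotide sequence (character scalar, ACGT).
#' @param genes Tibble with columns `gene_id`, `start`, `end`, `strand`
#'   (`"forward"`/`"reverse"`), and optionally `nt_seq`, `aa_seq`, `product`.
#'   Missing `nt_seq`/`aa_seq` are filled from `sequence` using `code`.
#' @param host,accession Optional metadata.
#' @param code Genetic code table used for translation (default `"11"`,
#'   bacterial).
#' @param check_translation When a gene carries both `nt_seq` and `aa_seq`,
#'   verify that translating `nt_seq` (minus the terminal stop) reproduces
#'   `aa_seq`; mismatch is an error unless this is `FALSE`.
#' @return An object of class `phage_genome`.
#' @examples
#' g <- phage_genome(
#'   "toy", "ATGGCCTAA",
#'   tibble::tibble(gene_id = "toy_gp1", start = 0L, end = 9L, strand = "forward")
#' )
#' genes(g)
#' @export
phage_genome <- function(name, sequence, genes, host = NA_character_,
                         accession = NA_character_, code = "11",
                         check_translation = TRUE) {
  assert_that(is.character(name) && length(name) == 1, "name must be a string")
  assert_that(is.character(sequence) && length(sequence) == 1,
              "sequence must be a single string")
  sequence <- toupper(sequence)
  genes <- as_tibble(genes)
  if (nrow(genes) > 0) {
    assert_that(all(c("gene_id", "start", "end", "strand") %in% names(genes)),
                "genes needs columns gene_id, start, end, strand")
  }
  L <- nchar(sequence)
  if (nrow(genes) > 0) {
    assert_that(!anyDuplicated(genes$gene_id), "duplicate gene_id")
    assert_that(all(genes$strand %in% c("forward", "reverse")),
                "strand must be 'forward' or 'reverse'")
    bad <- genes$start < 0 | genes$start >= genes$end | genes$end > L
    if (any(bad)) {
      abort(paste0("gene coordinates outside [0, genome length): ",
                   paste(genes$gene_id[bad], collapse = ", ")))
    }
    if (!"product" %in% names(genes)) genes$product <- NA_character_
    if (!"nt_seq" %in% names(genes)) genes$nt_seq <- NA_character_
    if (!"aa_seq" %in% names(genes)) genes$aa_seq <- NA_character_
    slice_nt <- function(start, end, strand) {
      s <- substr(sequence, start + 1, end)
      if (strand == "reverse") revcomp(s) else s
    }
    for (i in seq_len(nrow(genes))) {
      if (is.na(genes$nt_seq[i])) {
        genes$nt_seq[i] <- slice_nt(genes$start[i], genes$end[i], genes$strand[i])
      }
      if (is.na(genes$aa_seq[i])) {
        genes$aa_seq[i] <- translate_cds(genes$nt_seq[i], code)
      } else if (check_translation) {
        tr <- translate_cds(genes$nt_seq[i], code, allow_internal_stop = TRUE)
        if (tr != genes$aa_seq[i]) {
          abort(paste0("translation of nt_seq does not match aa_seq for gene ",
                       genes$gene_id[i],
                       " (set check_translation = FALSE to override)"))
        }
      }
      assert_that(nchar(genes$aa_seq[i]) > 0,
                  paste0("empty protein for gene ", genes$gene_id[i]))
    }
    genes$length_bp <- genes$end - genes$start
    genes <- genes[, c("gene_id", "start", "end", "strand", "nt_seq",
                       "aa_seq", "product", "length_bp")]
    genes <- arrange(genes, .data$start)
  } else {
    genes <- tibble(gene_id = character(), start = integer(), end = integer(),
                    strand = character(), nt_seq = character(),
                    aa_seq = character(), product = character(),
                    length_bp = integer())
  }
  gc_n <- sum(Biostrings::letterFrequency(Biostrings::DNAString(sequence),
                                          c("G", "C")))
  structure(
    list(name = name, host = host, accession = accession, sequence = sequence,
         genes = genes, gc_fraction = if (L > 0) gc_n / L else NA_real_,
         code = code),
    class = "phage_genome"
  )
}

#' @export
print.phage_genome <- function(x, ...) {
  cat("<phage_genome> ", x$name,
      if (!is.na(x$accession)) paste0(" [", x$accession, "]") else "", "\n",
      "  ", nchar(x$sequence), " bp, ", nrow(x$genes), " genes, GC ",
      round_half_up(100 * x$gc_fraction, 2), "%\n", sep = "")
  invisible(x)
}

#' Gene table of a genome
#'
#' @param g A `phage_genome`.
#' @return Tibble of gene records with a `phage` column prepended.
#' @export
genes <- function(g) {
  stopifnot(inherits(g, "phage_genome"))
  bind_cols(tibble(phage = rep(g$name, nrow(g$genes))), g$genes)
}

#' @export
as_tibble.phage_genome <- function(x, ...) genes(x)

#' Protein table of a cohort
#'
#' Flattens a list of genomes into the `(gene_id, phage, aa_seq)` table that
#' the similarity and clustering stages consume.
#'
#' @param genomes List of `phage_genome` objects.
#' @return Tibble with columns `gene_id`, `phage`, `aa_seq`.
#' @export
cohort_proteins <- function(genomes) {
  assert_that(length(genomes) > 0, "empty cohort")
  out <- bind_rows(lapply(genomes, function(g) {
    select(genes(g), "gene_id", "phage", "aa_seq")
  }))
  assert_that(!anyDuplicated(out$gene_id), "duplicate gene_id across cohort")
  out
}

#' Per-genome descriptive statistics
#'
#' Genome length, gene counts by strand and GC percent (two decimals,
#' half-up), the standard first table of a phage genome report.
#'
#' @param g A `phage_genome`.
#' @return One-row tibble: `phage`, `accession`, `length_bp`, `n_genes`,
#'   `n_forward`, `n_reverse`, `gc_percent`.
#' @export
genome_stats <- function(g) {
  stopifnot(inherits(g, "phage_genome"))
  tibble(
    phage = g$name,
    accession = g$accession,
    length_bp = nchar(g$sequence),
    n_genes = nrow(g$genes),
    n_forward = sum(g$genes$strand == "forward"),
    n_reverse = sum(g$genes$strand == "reverse"),
    gc_percent = round_half_up(100 * g$gc_fraction, 2)
  )
}

#' Cohort-level statistics table
#'
#' @param genomes List of `phage_genome` objects.
#' @return Tibble with one `genome_stats()` row per genome.
#' @export
cohort_stats <- function(genomes) {
  bind_rows(lapply(genomes, genome_stats))
}

#' Mean and spread of GC content across a cohort
#'
#' Arithmetic mean and sample (n-1) standard deviation of the per-genome GC
#' percentages, both to two decimals (half-up).
#'
#' @param genomes List of at least two `phage_genome` objects, or a numeric
#'   vector of GC percentages.
#' @return Tibble with columns `mean_gc_percent`, `sd_gc_percent`, `n`.
#' @export
cohort_gc_summary <- function(genomes) {
  gc <- if (is.numeric(genomes)) {
    genomes
  } else {
    map_dbl(genomes, function(g) round_half_up(100 * g$gc_fraction, 2))
  }
  assert_that(length(gc) >= 2, "need at least two genomes")
  tibble(
    mean_gc_percent = round_half_up(mean(gc), 2),
    sd_gc_percent = round_half_up(sd(gc), 2),
    n = length(gc)
  )
}
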