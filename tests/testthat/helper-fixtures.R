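# Small fixtures built in code.

# a tiny annotated genome: two forward genes, one reverse gene
toy_genome <- function(name = "toy") {
  # gene1: ATG GCC TAA at 2..11 forward; gene2 reverse at 15..24;
  # gene3 forward at 28..37
  g1 <- "ATGGCCTAA"
  g2 <- "ATGAAATGA"               # coding strand of the reverse gene
  g3 <- "ATGTGTTAA"
  seqn <- paste0("GC", g1, "ACGTA", revcomp_str(g2), "CGT", g3, "AT")
  genes <- tibble::tibble(
    gene_id = paste0(name, "_gp", 1:3),
    start = c(2L, 16L, 28L),
    end = c(11L, 25L, 37L),
    strand = c("forward", "reverse", "forward"),
    product = c("terminase", "hypothetical protein", "tail fiber")
  )
  phamily::phage_genome(name, seqn, genes, host = "synthetic-host",
                        accession = "SYN000001")
}

revcomp_str <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# proteins with two planted families and one singleton:
# fam A = p1,p2 (near-identical), fam B = p3,p4, singleton p5
planted_proteins <- function() {
  base_a <- paste0("MKLVNSTEWQRAGHD", "PLIKEWQRTYASDFGH", "NMKLVCTSRQP")
  base_b <- "MTTSGAQRWEEPLNKHGFDSACVYILMRQPWEN"
  tibble::tibble(
    gene_id = c("pha_gp1", "phb_gp1", "pha_gp2", "phb_gp2", "phc_gp1"),
    phage = c("pha", "phb", "pha", "phb", "phc"),
    aa_seq = c(base_a,
               sub("PLIKE", "PLLKE", base_a),
               base_b,
               sub("QRWEE", "QRWDE", base_b),
               "MWYYHHRRNNDDCCEEQQGGIILLKKFFPPSSTT")
  )
}
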