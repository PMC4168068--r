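# Synthetic phage cohorts with known evolutionary truth. An ancestral genome
# (random genes with a realistic length distribution, one designated
# tape-measure-protein gene) is evolved down a genealogy with nucleotide
# substitutions, gene loss, gene gain (novel genes destined to be orphams),
# tandem duplication with divergence, and inter-lineage block transfer.
# Every emitted gene carries an ortholog-group label, so pham clustering and
# core-gene counting can be scored against ground truth.

#' Parameters for a synthetic phage cohort
#'
#' Defaults emulate a small cohort of related ~50 kb phage genomes: ~80
#' genes per genome, ~90% of genes on the forward strand, GC around 39%,
#' log-normal gene lengths (median 600 bp, clipped to 150--4,500 bp so
#' TMP-scale genes occur) and short intergenic spacers (2--150 bp).
#'
#' @param n_genomes Number of genomes (2--20).
#' @param genome_length_target Approximate genome length in bp; emergent
#'   length depends on the drawn gene lengths (default 50,000).
#' @param genes_per_genome Ancestral gene count (default 80).
#' @param forward_strand_fraction Probability a gene lies on the forward
#'   strand (default 0.9).
#' @param gc_target GC fraction of generated sequence (default 0.39).
#' @param substitution_rate Substitutions per site per branch.
#' @param gene_loss_prob,duplication_prob Per-gene per-branch event
#'   probabilities.
#' @param gene_gain_prob,block_transfer_prob Per-branch event probabilities
#'   (one novel gene gained / one block copied per event).
#' @param tmp_length Ancestral TMP gene length in bp (default 2,400).
#' @param tmp_lengths Optional vector (length `n_genomes`) of per-genome TMP
#'   gene lengths in bp; the leaf TMP genes are resized to these by codon
#'   insertion/deletion in the middle of the gene.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n_genomes = 4,
                          genome_length_target = 50000,
                          genes_per_genome = 80,
                          forward_strand_fraction = 0.9,
                          gc_target = 0.39,
                          substitution_rate = 0.02,
                          gene_loss_prob = 0.02,
                          gene_gain_prob = 0.3,
                          duplication_prob = 0.02,
                          block_transfer_prob = 0.1,
                          tmp_length = 2400,
                          tmp_lengths = NULL,
                          seed = 1L) {
  probs <- c(forward_strand_fraction, substitution_rate, gene_loss_prob,
             gene_gain_prob, duplication_prob, block_transfer_prob)
  assert_that(all(probs >= 0 & probs <= 1), "probabilities must be in [0, 1]")
  assert_that(n_genomes >= 2 && n_genomes <= 20, "n_genomes must be in 2..20")
  assert_that(genes_per_genome >= 2, "need at least two genes")
  assert_that(genes_per_genome * 150 <= genome_length_target * 1.5,
              "genes cannot fit the genome length target")
  if (!is.null(tmp_lengths)) {
    assert_that(length(tmp_lengths) == n_genomes,
                "tmp_lengths must have one entry per genome")
  }
  structure(
    list(n_genomes = as.integer(n_genomes),
         genome_length_target = genome_length_target,
         genes_per_genome = as.integer(genes_per_genome),
         forward_strand_fraction = forward_strand_fraction,
         gc_target = gc_target, substitution_rate = substitution_rate,
         gene_loss_prob = gene_loss_prob, gene_gain_prob = gene_gain_prob,
         duplication_prob = duplication_prob,
         block_transfer_prob = block_transfer_prob,
         tmp_length = tmp_length, tmp_lengths = tmp_lengths,
         seed = as.integer(seed)),
    class = "cohort_params"
  )
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
BASES <- c("A", "T", "G", "C")

base_probs <- function(gc) c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)

random_dna <- function(n, gc) {
  if (n <= 0) return("")
  paste(sample(BASES, n, replace = TRUE, prob = base_probs(gc)),
        collapse = "")
}

# the 61 sense codons with sampling weights under iid base composition
sense_codons <- local({
  all64 <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
  sort(setdiff(all64, STOP_CODONS))
})

sense_codon_probs <- function(gc) {
  p <- setNames(base_probs(gc), BASES)
  w <- vapply(strsplit(sense_codons, ""), function(b) prod(p[b]), 0)
  w / sum(w)
}

# expected GC fraction of a sense codon drawn with base parameter gc
sense_codon_gc <- function(gc) {
  ngc <- vapply(strsplit(sense_codons, ""),
                function(b) sum(b %in% c("G", "C")), 0)
  sum(sense_codon_probs(gc) * ngc) / 3
}

# base parameter whose sense-codon distribution hits the GC target: excluding
# the AT-rich stop codons raises GC, so sample slightly AT-richer to land on
# target on average
calibrate_codon_gc <- function(target) {
  stats::uniroot(function(x) sense_codon_gc(x) - target,
                 c(0.02, 0.98), tol = 1e-9)$root
}

random_codon <- function(gc) {
  sample(sense_codons, 1, prob = sense_codon_probs(gc))
}

# a translatable CDS: ATG + sense codons + stop
random_gene_nt <- function(len_bp, gc) {
  len_bp <- max(9, round(len_bp / 3) * 3)
  n_body <- (len_bp - 6) / 3
  body <- paste(sample(sense_codons, n_body, replace = TRUE,
                       prob = sense_codon_probs(gc)), collapse = "")
  paste0("ATG", body, sample(STOP_CODONS, 1))
}

# substitution kernel preserving the target composition: the replacement base
# is drawn from the stationary base distribution conditional on differing
# from the current base
substitute_base <- function(old, gc) {
  cands <- setdiff(BASES, old)
  p <- setNames(base_probs(gc), BASES)[cands]
  sample(cands, 1, prob = p / sum(p))
}

# mutate k random positions of a CDS without touching the terminal stop codon
# and without introducing an in-frame internal stop
mutate_gene_nt <- function(nt, k, gc) {
  n <- nchar(nt)
  mutable <- n - 3
  if (k <= 0 || mutable <= 0) return(nt)
  k <- min(k, mutable)
  s <- strsplit(nt, "")[[1]]
  pos <- sample.int(mutable, k)
  for (p in pos) {
    old <- s[p]
    cod_start <- p - ((p - 1) %% 3)
    ok <- function(base) {
      s[p] <- base
      !paste(s[cod_start:(cod_start + 2)], collapse = "") %in% STOP_CODONS
    }
    # preferred draw from the stationary kernel, then any non-stop fallback
    new <- substitute_base(old, gc)
    if (!ok(new)) {
      valid <- Filter(ok, setdiff(BASES, old))
      new <- if (length(valid)) valid[[1]] else old
    }
    s[p] <- new
  }
  paste(s, collapse = "")
}

mutate_spacer_nt <- function(nt, k, gc) {
  n <- nchar(nt)
  if (k <= 0 || n == 0) return(nt)
  k <- min(k, n)
  s <- strsplit(nt, "")[[1]]
  pos <- sample.int(n, k)
  for (p in pos) s[p] <- substitute_base(s[p], gc)
  paste(s, collapse = "")
}

# resize a CDS to target_bp by inserting random codons into, or deleting
# codons from, the middle; keeps start/stop and translatability
resize_gene_nt <- function(nt, target_bp, gc) {
  target_bp <- max(9, round(target_bp / 3) * 3)
  cur <- nchar(nt)
  if (cur == target_bp) return(nt)
  codons <- substring(nt, seq(1, cur, 3), seq(3, cur, 3))
  n_body <- length(codons) - 2  # between start and stop
  delta <- (target_bp - cur) / 3
  mid <- 1 + n_body %/% 2
  if (delta > 0) {
    ins <- vapply(seq_len(delta), function(i) random_codon(gc), "")
    codons <- append(codons, ins, after = mid)
  } else {
    drop <- min(-delta, n_body)
    from <- max(2, mid - drop %/% 2)
    codons <- codons[-(from:(from + drop - 1))]
  }
  paste(codons, collapse = "")
}

new_element <- function(type, nt, group = NA_character_, strand = NA_character_,
                        origin = "ancestral", is_tmp = FALSE) {
  list(type = type, nt = nt, group = group, strand = strand, origin = origin,
       is_tmp = is_tmp)
}

ancestral_elements <- function(cp) {
  ng <- cp$genes_per_genome
  lens <- pmin(pmax(stats::rlnorm(ng, log(600), 0.55), 150), 4500)
  lens <- round(lens / 3) * 3
  tmp_idx <- sample.int(ng, 1)
  lens[tmp_idx] <- max(9, round(cp$tmp_length / 3) * 3)
  elements <- list(new_element("spacer", random_dna(sample(2:150, 1), cp$gc_target)))
  for (i in seq_len(ng)) {
    strand <- if (stats::runif(1) < cp$forward_strand_fraction) "forward" else "reverse"
    elements[[length(elements) + 1]] <- new_element(
      "gene", random_gene_nt(lens[i], cp$gc_codon),
      group = sprintf("og%03d", i), strand = strand,
      is_tmp = i == tmp_idx
    )
    elements[[length(elements) + 1]] <-
      new_element("spacer", random_dna(sample(2:150, 1), cp$gc_target))
  }
  elements
}

gene_idx <- function(elements) {
  which(map_chr(elements, "type") == "gene")
}

# one branch of evolution applied to an element list; returns the new state
# and the event-log rows. donors: list of other materialized element lists.
evolve_branch <- function(elements, cp, branch_label, donors, counters) {
  log_rows <- list()
  # substitutions
  for (i in seq_along(elements)) {
    el <- elements[[i]]
    k <- stats::rbinom(1, nchar(el$nt), cp$substitution_rate)
    if (k > 0) {
      elements[[i]]$nt <- if (el$type == "gene") {
        mutate_gene_nt(el$nt, k, cp$gc_target)
      } else {
        mutate_spacer_nt(el$nt, k, cp$gc_target)
      }
    }
  }
  # gene loss (spacer after the gene goes with it); never empty the genome
  gi <- gene_idx(elements)
  lose <- gi[stats::runif(length(gi)) < cp$gene_loss_prob]
  if (length(lose) >= length(gi)) {
    abort("gene loss would empty a genome; lower gene_loss_prob")
  }
  if (length(lose) > 0) {
    lost_groups <- map_chr(elements[lose], "group")
    drop <- sort(unique(c(lose, lose + 1)))
    drop <- drop[drop <= length(elements)]
    elements <- elements[-drop]
    log_rows[[length(log_rows) + 1]] <-
      tibble(event = "loss", branch = branch_label,
             genes = paste(lost_groups, collapse = ","))
  }
  # tandem duplication with divergence
  gi <- gene_idx(elements)
  dup <- gi[stats::runif(length(gi)) < cp$duplication_prob]
  for (d in rev(dup)) {
    copy <- elements[[d]]
    copy$nt <- mutate_gene_nt(copy$nt,
                              stats::rbinom(1, nchar(copy$nt),
                                            cp$substitution_rate),
                              cp$gc_target)
    copy$origin <- "duplication"
    spacer <- new_element("spacer", random_dna(sample(2:150, 1), cp$gc_target))
    elements <- append(elements, list(spacer, copy), after = d)
    log_rows[[length(log_rows) + 1]] <-
      tibble(event = "duplication", branch = branch_label,
             genes = copy$group)
  }
  # gene gain: a novel gene with no homolog anywhere (future orpham)
  if (stats::runif(1) < cp$gene_gain_prob) {
    counters$novel <- counters$novel + 1L
    len <- pmin(pmax(stats::rlnorm(1, log(600), 0.55), 150), 4500)
    gene <- new_element(
      "gene", random_gene_nt(len, cp$gc_codon),
      group = sprintf("novel%03d", counters$novel),
      strand = if (stats::runif(1) < cp$forward_strand_fraction) "forward" else "reverse",
      origin = "gain"
    )
    spacer <- new_element("spacer", random_dna(sample(2:150, 1), cp$gc_target))
    at <- sample(gene_idx(elements), 1)
    elements <- append(elements, list(spacer, gene), after = at)
    log_rows[[length(log_rows) + 1]] <-
      tibble(event = "gain", branch = branch_label, genes = gene$group)
  }
  # horizontal block transfer from another materialized lineage
  if (length(donors) > 0 && stats::runif(1) < cp$block_transfer_prob) {
    donor <- donors[[sample.int(length(donors), 1)]]
    dgi <- gene_idx(donor)
    if (length(dgi) >= 2) {
      w <- sample(2:min(4, length(dgi)), 1)
      s0 <- sample.int(length(dgi) - w + 1, 1)
      block_idx <- dgi[s0:(s0 + w - 1)]
      block <- lapply(donor[block_idx], function(el) {
        el$origin <- "transfer"
        el
      })
      spacers <- lapply(seq_along(block), function(i) {
        new_element("spacer", random_dna(sample(2:150, 1), cp$gc_target))
      })
      ins <- vector("list", 2 * length(block))
      ins[seq(1, length(ins), 2)] <- spacers
      ins[seq(2, length(ins), 2)] <- block
      at <- sample(gene_idx(elements), 1)
      elements <- append(elements, ins, after = at)
      log_rows[[length(log_rows) + 1]] <-
        tibble(event = "block_transfer", branch = branch_label,
               genes = paste(map_chr(block, "group"), collapse = ","))
    }
  }
  list(elements = elements, log = bind_rows(log_rows))
}

assemble_genome <- function(elements, name, cp) {
  rows <- list()
  pos <- 0L
  gp <- 0L
  for (el in elements) {
    L <- nchar(el$nt)
    if (el$type == "gene") {
      gp <- gp + 1L
      rows[[gp]] <- tibble(
        gene_id = sprintf("%s_gp%d", name, gp),
        start = pos, end = pos + L, strand = el$strand,
        nt_seq = el$nt,
        product = if (el$is_tmp) "tape measure protein" else "hypothetical protein",
        ortholog_group = el$group, origin = el$origin, is_tmp = el$is_tmp
      )
    }
    pos <- pos + L
  }
  pieces <- map_chr(elements, function(el) {
    if (el$type == "gene" && el$strand == "reverse") revcomp(el$nt) else el$nt
  })
  sequence <- paste(pieces, collapse = "")
  genes_tbl <- bind_rows(rows)
  truth <- genes_tbl[, c("gene_id", "ortholog_group", "origin", "is_tmp")]
  truth$phage <- name
  g <- phage_genome(
    name, sequence,
    genes_tbl[, c("gene_id", "start", "end", "strand", "nt_seq", "product")],
    host = "synthetic", code = "11"
  )
  list(genome = g, truth = truth[, c("gene_id", "phage", "ortholog_group",
                                     "origin", "is_tmp")])
}

#' Generate a synthetic phage cohort with ground truth
#'
#' Simulates an ancestral annotated genome and evolves it down a random
#' genealogy (see [cohort_params()] for the event model). Returns GenBank-
#' writable genomes plus a truth object: per-gene ortholog-group labels, the
#' event log, and the generating tree. Fully reproducible from the seed.
#'
#' @param cp A [cohort_params()].
#' @return List with `genomes` (list of [phage_genome()]), `truth` (tibble
#'   `gene_id`, `phage`, `ortholog_group`, `origin`, `is_tmp`), `event_log`
#'   (tibble `event`, `branch`, `genes`), `tree` (`ape::phylo`), `params`.
#' @examples
#' cohort <- generate_cohort(cohort_params(n_genomes = 2, genes_per_genome = 8,
#'                                         seed = 42))
#' cohort_stats(cohort$genomes)
#' @export
generate_cohort <- function(cp = cohort_params()) {
  stopifnot(inherits(cp, "cohort_params"))
  withr::with_seed(cp$seed, generate_cohort_impl(cp))
}

generate_cohort_impl <- function(cp) {
  cp$gc_codon <- calibrate_codon_gc(cp$gc_target)
  n <- cp$n_genomes
  names <- sprintf("synphage%d", seq_len(n))
  tree <- ape::rtree(n, rooted = TRUE, br = NULL)
  tree$edge.length <- rep(1, nrow(tree$edge))
  tree$tip.label <- names[as.integer(sub("^t", "", tree$tip.label))]
  root <- ape::Ntip(tree) + 1L
  anc <- ancestral_elements(cp)
  states <- list()
  states[[root]] <- anc
  counters <- new.env()
  counters$novel <- 0L
  logs <- list()
  edges <- tree$edge[order(tree$edge[, 1]), , drop = FALSE]
  # preorder: parents are materialized before children in rtree numbering,
  # but order edges by depth to be safe
  depth <- ape::node.depth.edgelength(tree)
  ord <- order(depth[edges[, 2]])
  node_label <- function(v) {
    if (v <= ape::Ntip(tree)) tree$tip.label[v] else paste0("node", v)
  }
  for (e in ord) {
    parent <- edges[e, 1]; child <- edges[e, 2]
    donors <- states[setdiff(which(!vapply(states, is.null, TRUE)),
                             c(parent, root))]
    donors <- keep(donors, function(x) !is.null(x))
    res <- evolve_branch(states[[parent]], cp, node_label(child), donors,
                         counters)
    states[[child]] <- res$elements
    if (nrow(res$log) > 0) logs[[length(logs) + 1]] <- res$log
  }
  genomes <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    tip <- which(tree$tip.label == names[i])
    els <- states[[tip]]
    if (!is.null(cp$tmp_lengths)) {
      gi <- gene_idx(els)
      tmp_at <- gi[map_lgl(els[gi], "is_tmp")]
      if (length(tmp_at) >= 1) {
        els[[tmp_at[1]]]$nt <- resize_gene_nt(els[[tmp_at[1]]]$nt,
                                              cp$tmp_lengths[i], cp$gc_codon)
      }
    }
    out <- assemble_genome(els, names[i], cp)
    genomes[[i]] <- out$genome
    truths[[i]] <- out$truth
  }
  list(
    genomes = genomes,
    truth = bind_rows(truths),
    event_log = if (length(logs)) bind_rows(logs) else
      tibble(event = character(), branch = character(), genes = character()),
    tree = tree,
    params = cp
  )
}

#' Mutate exactly k positions of a sequence
#'
#' Returns a copy of `seq` differing at exactly `k` distinct positions, each
#' changed to a different base — e.g. for constructing near-twin genome pairs
#' with a known Hamming distance.
#'
#' @param seq Nucleotide string.
#' @param k Number of positions to change (`0 <= k <= nchar(seq)`).
#' @param seed Optional integer seed for reproducibility.
#' @return The mutated sequence.
#' @examples
#' mutate_fixed_positions("ACGTACGT", 2, seed = 1)
#' @export
mutate_fixed_positions <- function(seq, k, seed = NULL) {
  n <- nchar(seq)
  assert_that(k >= 0 && k <= n, "k must be in [0, sequence length]")
  if (k == 0) return(seq)
  run <- function() {
    s <- strsplit(toupper(seq), "")[[1]]
    pos <- sample.int(n, k)
    for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
    paste(s, collapse = "")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a co-isolated phage mixture
#'
#' Emits labeled read-like fragments from two genomes — the situation where
#' one phage sample turns out to contain two different phages — so the
#' de-mixing workflow (assembly surrogate plus TMP/tail matching) can be
#' exercised against truth.
#'
#' @param g1,g2 Distinct `phage_genome` objects.
#' @param coverage Target fold coverage per unit weight (default 10).
#' @param fragment_bp Fragment length (default 500).
#' @param weights Length-2 non-negative weights; a weight of 0 silences that
#'   genome. Fragment counts are `round(weight * coverage * length /
#'   fragment_bp)`.
#' @param seed Optional integer seed.
#' @return List with `fragments` (tibble `fragment_id`, `genome`, `start`,
#'   `seq`) and `truth` (tibble `genome`, `n_fragments`, `tmp_gene`,
#'   `tmp_bp` for genomes with an annotated tape measure protein).
#' @export
make_coisolation_mixture <- function(g1, g2, coverage = 10, fragment_bp = 500,
                                     weights = c(1, 1), seed = NULL) {
  stopifnot(inherits(g1, "phage_genome"), inherits(g2, "phage_genome"))
  assert_that(!identical(g1$name, g2$name), "genomes must be distinct")
  assert_that(all(weights >= 0) && length(weights) == 2,
              "weights must be two non-negative numbers")
  run <- function() {
    frag_one <- function(g, w) {
      L <- nchar(g$sequence)
      n_frag <- round(w * coverage * L / fragment_bp)
      if (n_frag == 0) {
        return(tibble(genome = character(), start = integer(),
                      seq = character()))
      }
      starts <- sample.int(max(L - fragment_bp + 1, 1), n_frag, replace = TRUE)
      tibble(genome = g$name, start = starts,
             seq = substring(g$sequence, starts,
                             pmin(starts + fragment_bp - 1, L)))
    }
    frags <- bind_rows(frag_one(g1, weights[1]), frag_one(g2, weights[2]))
    frags <- mutate(frags,
                    fragment_id = sprintf("frag%06d", seq_len(nrow(frags)))) |>
      select("fragment_id", "genome", "start", "seq")
    tmp_row <- function(g) {
      tm <- filter(g$genes, .data$product == "tape measure protein")
      tibble(genome = g$name,
             n_fragments = sum(frags$genome == g$name),
             tmp_gene = if (nrow(tm)) tm$gene_id[1] else NA_character_,
             tmp_bp = if (nrow(tm)) tm$length_bp[1] else NA_integer_)
    }
    list(fragments = frags, truth = bind_rows(tmp_row(g1), tmp_row(g2)))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
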