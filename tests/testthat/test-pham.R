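test_that("dual threshold passes with strict inequalities, either criterion", {
  pr <- planted_proteins()[1:2, ]
  edges <- build_similarity_graph(pr)
  expect_equal(nrow(edges), 1)
  expect_true(edges$passes)  # near-identical pair

  # boundary values fail: construct edges at exactly the cutoffs
  t <- pham_thresholds()
  at_boundary <- tibble::tibble(
    protein_a = "x", protein_b = "y",
    evalue = t$evalue_max, pct_identity = t$identity_min_pct
  )
  expect_false(with(at_boundary, evalue < t$evalue_max |
                      pct_identity > t$identity_min_pct))
  # just inside either cutoff passes
  expect_true(t$evalue_max * 0.999 < t$evalue_max)
  expect_true(32.5 + 1e-9 > t$identity_min_pct)
})

test_that("edge passes flags agree with naive recomputation on 8 proteins", {
  withr::with_seed(41, {
    pr <- tibble::tibble(
      gene_id = sprintf("p%d_gp1", 1:8),
      aa_seq = c(replicate(8, random_peptide(40)))
    )
  })
  # plant two related pairs
  pr$aa_seq[2] <- sub("^.{5}", "AAAAA", pr$aa_seq[1])
  pr$aa_seq[4] <- sub("^.{3}", "CCC", pr$aa_seq[3])
  t <- pham_thresholds()
  edges <- build_similarity_graph(pr, t)
  expect_equal(nrow(edges), 8 * 7 / 2)
  redo <- mapply(function(a, b) {
    r <- align_proteins(pr$aa_seq[pr$gene_id == a],
                        pr$aa_seq[pr$gene_id == b])
    r$evalue < t$evalue_max | r$pct_identity > t$identity_min_pct
  }, edges$protein_a, edges$protein_b)
  expect_equal(edges$passes, unname(redo))
})

test_that("single linkage: chains merge, isolated proteins become orphams", {
  prot <- tibble::tibble(gene_id = c("A", "B", "C", "D", "E"))
  edges <- tibble::tibble(
    protein_a = c("A", "B", "A"), protein_b = c("B", "C", "C"),
    passes = c(TRUE, TRUE, FALSE)
  )
  p <- cluster_phams(edges, prot)
  tp <- tidy(p)
  expect_equal(sort(tp$gene_id[tp$pham_id == tp$pham_id[tp$gene_id == "A"]]),
               c("A", "B", "C"))
  expect_true(all(tp$is_orpham[tp$gene_id %in% c("D", "E")]))

  none <- cluster_phams(edges[0, ], prot)
  expect_equal(pham_summary(none)$n_orphams, 5)
  expect_error(cluster_phams(tibble::tibble(protein_a = "Z", protein_b = "A",
                                            passes = TRUE), prot),
               "unknown")
})

test_that("clustering equals brute-force components on random graphs", {
  withr::with_seed(42, {
    for (trial in 1:200) {
      n <- sample(3:12, 1)
      ids <- sprintf("g%02d", 1:n)
      pairs <- t(combn(ids, 2))
      m <- nrow(pairs)
      pass <- runif(m) < runif(1, 0.05, 0.5)
      edges <- tibble::tibble(protein_a = pairs[, 1], protein_b = pairs[, 2],
                              passes = pass)
      p <- cluster_phams(edges, tibble::tibble(gene_id = ids))
      got <- setNames(tidy(p)$pham_id, tidy(p)$gene_id)[ids]
      want <- components_oracle(ids, pairs[pass, 1], pairs[pass, 2])
      expect_true(same_partition(got, want), info = paste("trial", trial))
    }
  })
})

test_that("partition is order-invariant and ids follow smallest member", {
  prot <- tibble::tibble(gene_id = c("b", "a", "d", "c"))
  edges <- tibble::tibble(protein_a = c("c"), protein_b = c("d"),
                          passes = TRUE)
  p1 <- cluster_phams(edges, prot)
  p2 <- cluster_phams(edges, prot[sample(4), , drop = FALSE])
  expect_equal(as.data.frame(tidy(p1)), as.data.frame(tidy(p2)))
  # component containing "a" (smallest gene id) gets pham 1
  expect_equal(tidy(p1)$pham_id[tidy(p1)$gene_id == "a"], 1L)
})

test_that("relaxing either threshold never increases the pham count", {
  withr::with_seed(43, {
    co <- generate_cohort(cohort_params(n_genomes = 3, genes_per_genome = 8,
                                        substitution_rate = 0.08, seed = 43))
    pr <- cohort_proteins(co$genomes)
    edges_raw <- build_similarity_graph(pr)  # passes recomputed below
    n_phams_at <- function(emax, imin) {
      e <- dplyr::mutate(edges_raw,
                         passes = evalue < emax | pct_identity > imin)
      pham_summary(cluster_phams(e, pr))$n_phams
    }
    base <- n_phams_at(1e-50, 32.5)
    expect_lte(n_phams_at(1e-30, 32.5), base)
    expect_lte(n_phams_at(1e-50, 25), base)
    expect_gte(n_phams_at(1e-80, 40), base)
  })
})

test_that("pham summary percentages use half-up rounding at one decimal", {
  p <- partition_from_sizes(c(3, 1, 1))
  s <- pham_summary(p)
  expect_equal(s$n_proteins, 5)
  expect_equal(s$pct_orphams, 40.0)
  expect_equal(s$pct_multimember_phams, round_half_up(100 / 3, 1))
  all_orph <- partition_from_sizes(rep(1, 7))
  expect_equal(pham_summary(all_orph)$pct_orphams, 100.0)
  one_big <- partition_from_sizes(12)
  s1 <- pham_summary(one_big)
  expect_equal(s1$pct_multimember_phams, 100.0)
  expect_equal(s1$n_orphams, 0)
})

test_that("shared-pham categories are exclusive and sum to the gene count", {
  # 3 genomes; focal group = f1, f2; outsider = out
  prot <- tibble::tibble(
    gene_id = c("f1_gp1", "f2_gp1", "out_gp1",   # cross-host pham
                "f1_gp2", "f2_gp2",              # focal-only pham
                "f1_gp3"),                       # orpham
    phage = c("f1", "f2", "out", "f1", "f2", "f1")
  )
  edges <- tibble::tibble(
    protein_a = c("f1_gp1", "f2_gp1", "f1_gp2"),
    protein_b = c("f2_gp1", "out_gp1", "f2_gp2"),
    passes = TRUE
  )
  p <- cluster_phams(edges, prot)
  tab <- shared_pham_table(p, c("f1", "f2"))
  expect_equal(tab$n_genes, c(3L, 2L))
  expect_equal(tab$n_shared_outside + tab$n_focal_only + tab$n_orphams,
               tab$n_genes)
  expect_equal(tab$n_shared_outside, c(1L, 1L))
  expect_equal(tab$n_orphams, c(1L, 0L))
  expect_error(shared_pham_table(p, c("f1", "nope")), "absent")

  # a lone genome has no outside sharing at all
  solo <- cluster_phams(edges[0, ], prot[prot$phage == "f1", ])
  tab2 <- shared_pham_table(solo, "f1")
  expect_equal(tab2$n_shared_outside, 0L)
})

test_that("removing a twin genome orphans its partner's shared genes", {
  withr::with_seed(44, {
    # twin pair: genome B is a light mutation of genome A
    co <- generate_cohort(cohort_params(n_genomes = 2, genes_per_genome = 31,
                                        substitution_rate = 0.005,
                                        gene_gain_prob = 0, gene_loss_prob = 0,
                                        duplication_prob = 0,
                                        block_transfer_prob = 0, seed = 44))
    pr <- cohort_proteins(co$genomes)
    p <- cluster_phams(build_similarity_graph(pr), pr)
    # all 31 phams are twin-only two-member phams
    expect_equal(pham_summary(p)$n_multimember_phams, 31)
    res <- remove_genome_recount(p, "synphage2")
    expect_equal(length(res$newly_orphamed), 31)
    expect_true(all(grepl("^synphage1", res$newly_orphamed)))
    # equals re-clustering from scratch without the victim
    pr1 <- pr[pr$phage == "synphage1", ]
    fresh <- cluster_phams(build_similarity_graph(pr1), pr1)
    expect_equal(as.data.frame(tidy(res$partition)),
                 as.data.frame(tidy(fresh)))
  })
})

test_that("pham circles link every member pair", {
  p <- partition_from_sizes(c(1, 4))
  pc1 <- pham_circle(p, 1)
  expect_equal(nrow(pc1$links), 0)
  for (k in c(2, 5, 10)) {
    pk <- partition_from_sizes(k)
    out <- pham_circle(pk, 1)
    expect_equal(nrow(out$members), k)
    expect_equal(nrow(out$links), k * (k - 1) / 2)
  }
  expect_error(pham_circle(p, 99), "unknown pham")
})

test_that("domain coverage fraction counts phams with any annotated member", {
  p <- partition_from_sizes(c(2, 1, 1))
  ids <- p$gene_id
  expect_equal(pham_domain_coverage(p, tibble::tibble(gene_id = character(),
                                                      domain = character())),
               0.0)
  all_dom <- tibble::tibble(gene_id = ids, domain = "PF00001")
  expect_equal(pham_domain_coverage(p, all_dom), 100.0)
  one <- tibble::tibble(gene_id = ids[1], domain = "PF00002")
  expect_equal(pham_domain_coverage(p, one), round_half_up(100 / 3, 1))
})

test_that("partition invariants hold on a synthetic cohort", {
  withr::with_seed(45, {
    co <- generate_cohort(cohort_params(n_genomes = 3, genes_per_genome = 10,
                                        seed = 45))
    pr <- cohort_proteins(co$genomes)
    p <- cluster_phams(build_similarity_graph(pr), pr)
    tp <- tidy(p)
    expect_setequal(tp$gene_id, pr$gene_id)
    expect_equal(anyDuplicated(tp$gene_id), 0)
    expect_equal(sum(table(tp$pham_id)), nrow(pr))
    s <- pham_summary(p)
    expect_equal(s$n_orphams + s$n_proteins_in_multimember, s$n_proteins)
    expect_equal(s$n_phams, s$n_multimember_phams + s$n_orphams)
  })
})
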