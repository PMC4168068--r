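test_that("p-distances are symmetric, zero on identity, near one when unrelated", {
  withr::with_seed(61, {
    s <- random_peptide(60)
    pr <- tibble::tibble(
      name = c("A", "B", "C"),
      aa_seq = c(s, s, random_peptide(60))
    )
    d <- terminase_distances(pr)
    expect_equal(d["A", "B"], 0)
    expect_equal(d, t(d))
    expect_gt(d["A", "C"], 0.7)
    r <- align_proteins(pr$aa_seq[1], pr$aa_seq[3])
    expect_equal(d["A", "C"], 1 - r$pct_identity / 100)
  })
  expect_error(terminase_distances(tibble::tibble(name = c("A", "B"),
                                                  aa_seq = c("MK", "MR"))),
               "three")
})

test_that("three-taxon NJ solves the closed-form branch lengths", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("A", "B", "C")], c(A = 1, B = 1, C = 3))
})

test_that("NJ recovers random additive trees exactly", {
  withr::with_seed(62, {
    for (trial in 1:25) {
      n <- sample(4:8, 1)
      true_tree <- ape::rtree(n)
      d <- ape::cophenetic.phylo(true_tree)
      d <- d[order(rownames(d)), order(colnames(d))]
      tr <- neighbor_joining(d)
      # leaf-to-leaf path lengths reproduce the matrix
      got <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
      expect_equal(got, d, tolerance = 1e-8, info = paste("trial", trial))
      # topology agrees with the independent ape implementation
      expect_equal(ape::dist.topo(ape::unroot(tr), ape::nj(d)), 0,
                   ignore_attr = TRUE)
    }
  })
})

test_that("NJ is input-order invariant and handles star matrices", {
  withr::with_seed(63, {
    true_tree <- ape::rtree(6)
    d <- ape::cophenetic.phylo(true_tree)
    perm <- sample(6)
    t1 <- neighbor_joining(d)
    t2 <- neighbor_joining(d[perm, perm])
    expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
                 ignore_attr = TRUE)
  })
  star <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(star) <- 0
  tr <- neighbor_joining(star)
  internal <- tr$edge[, 2] > ape::Ntip(tr)
  expect_true(all(tr$edge.length[internal] < 1e-8))
  expect_true(all(tr$edge.length >= 0))
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric|square")
})

test_that("negative branch estimates are clamped, preserving path length", {
  # a matrix known to push one NJ branch negative
  d <- matrix(c(0, 1, 6, 6,
                1, 0, 7, 7,
                6, 7, 0, 2,
                6, 7, 2, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(d)
  expect_true(all(tr$edge.length >= 0))
})

packaging_fixture <- function() {
  # phams: {J1.ter, J2.ter, P40.ter, SPP1.ter} ; {Pl23.ter, SLT.ter} ;
  # {Emery.ter} orpham
  prot <- tibble::tibble(
    gene_id = c("J1_gp2", "J2_gp2", "P40_gp2", "SPP1_gp2",
                "Pl23_gp2", "SLT_gp2", "Emery_gp3"),
    phage = c("J1", "J2", "P40", "SPP1", "Pl23", "SLT", "Emery")
  )
  edges <- tibble::tibble(
    protein_a = c("J1_gp2", "J2_gp2", "P40_gp2", "Pl23_gp2"),
    protein_b = c("J2_gp2", "P40_gp2", "SPP1_gp2", "SLT_gp2"),
    passes = TRUE
  )
  p <- cluster_phams(edges, prot)
  term <- tibble::tibble(phage = prot$phage, gene_id = prot$gene_id)
  list(p = p, term = term)
}

test_that("packaging strategy is inherited from characterized pham-mates", {
  fx <- packaging_fixture()
  known <- tibble::tibble(
    phage = c("P40", "SPP1", "SLT"),
    strategy = c("headful_circularly_permuted", "headful_circularly_permuted",
                 "cohesive_ends_3prime")
  )
  calls <- infer_packaging(fx$p, fx$term, known)
  get <- function(ph) calls[calls$phage == ph, ]
  expect_equal(get("J1")$strategy, "headful_circularly_permuted")
  expect_true(grepl("P40|SPP1", get("J1")$evidence))
  expect_equal(get("Pl23")$strategy, "cohesive_ends_3prime")
  expect_equal(get("Pl23")$evidence, "SLT")
  expect_equal(get("Emery")$strategy, "undetermined")
  expect_equal(get("Emery")$evidence, "orpham")
  # determinate calls always carry a characterized mate as evidence
  det <- calls[calls$strategy != "undetermined", ]
  expect_true(all(det$evidence %in% c("P40", "SPP1", "SLT") |
                    grepl(",", det$evidence)))
})

test_that("conflicting strategies within one pham raise a consistency error", {
  fx <- packaging_fixture()
  known <- tibble::tibble(
    phage = c("P40", "SPP1"),
    strategy = c("headful_circularly_permuted", "cohesive_ends_3prime")
  )
  expect_error(infer_packaging(fx$p, fx$term, known), "conflicting")
})

test_that("uncharacterized phams and unknown strategies are handled", {
  fx <- packaging_fixture()
  none <- tibble::tibble(phage = character(), strategy = character())
  calls <- infer_packaging(fx$p, fx$term, none)
  expect_true(all(calls$strategy == "undetermined"))
  bad <- tibble::tibble(phage = "P40", strategy = "sideways")
  expect_error(infer_packaging(fx$p, fx$term, bad), "unknown packaging")
})
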