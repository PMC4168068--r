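# Independent oracles implemented naively in R, kept deliberately separate
# from the package's code paths.

# exhaustive Smith-Waterman raw score under a substitution matrix with
# affine-ish gap cost: a gap of length k costs open + k * extend
sw_oracle_score <- function(a, b, mat, open = 11, extend = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  m <- length(av); n <- length(bv)
  M <- matrix(0, m + 1, n + 1)      # best ending in a match/mismatch
  X <- matrix(-Inf, m + 1, n + 1)   # gap in b (consumes a)
  Y <- matrix(-Inf, m + 1, n + 1)   # gap in a (consumes b)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      s <- mat[av[i - 1], bv[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend)
      Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend)
      best <- max(best, M[i, j], X[i, j], Y[i, j])
    }
  }
  best
}

# quadratic Needleman-Wunsch with linear gap penalty; returns score and the
# column stats of one optimal alignment (diagonal-preferring traceback)
nw_oracle <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  m <- length(av); n <- length(bv)
  S <- matrix(0, m + 1, n + 1)
  S[, 1] <- gap * (0:m)
  S[1, ] <- gap * (0:n)
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      s <- if (av[i - 1] == bv[j - 1]) match else mismatch
      S[i, j] <- max(S[i - 1, j - 1] + s, S[i - 1, j] + gap, S[i, j - 1] + gap)
    }
  }
  i <- m + 1; j <- n + 1
  nid <- nmis <- ngap <- 0
  while (i > 1 || j > 1) {
    s <- if (i > 1 && j > 1 && av[i - 1] == bv[j - 1]) match else mismatch
    if (i > 1 && j > 1 && S[i, j] == S[i - 1, j - 1] + s) {
      if (av[i - 1] == bv[j - 1]) nid <- nid + 1 else nmis <- nmis + 1
      i <- i - 1; j <- j - 1
    } else if (i > 1 && S[i, j] == S[i - 1, j] + gap) {
      ngap <- ngap + 1; i <- i - 1
    } else {
      ngap <- ngap + 1; j <- j - 1
    }
  }
  list(score = S[m + 1, n + 1], n_identical = nid, n_mismatch = nmis,
       n_gap = ngap, aln_length = nid + nmis + ngap)
}

# brute-force connected components by repeated reachability expansion
components_oracle <- function(ids, edge_a, edge_b) {
  comp <- setNames(seq_along(ids), ids)
  repeat {
    changed <- FALSE
    for (k in seq_along(edge_a)) {
      ca <- comp[edge_a[k]]; cb <- comp[edge_b[k]]
      if (ca != cb) {
        comp[comp == max(ca, cb)] <- min(ca, cb)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# partitions are equal as set partitions (labels ignored)
same_partition <- function(f1, f2) {
  identical(
    unname(split(names(f1), f1)[order(sapply(split(names(f1), f1), min))]),
    unname(split(names(f2), f2)[order(sapply(split(names(f2), f2), min))])
  )
}

random_peptide <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, TRUE),
        collapse = "")
}

random_dna_str <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
}

# brute-force dotplot by double loop
dotplot_oracle <- function(a, b, w) {
  rc <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
                                                 collapse = ""))
  hits <- list()
  for (i in 0:(nchar(a) - w)) {
    wa <- substr(a, i + 1, i + w)
    for (j in 0:(nchar(b) - w)) {
      wb <- substr(b, j + 1, j + w)
      if (wa == wb) hits[[length(hits) + 1]] <- c(i, j, 0)
      if (wa == rc(wb)) hits[[length(hits) + 1]] <- c(i, j, 1)
    }
  }
  if (!length(hits)) return(data.frame(i = integer(), j = integer(),
                                       rev = integer()))
  m <- do.call(rbind, hits)
  data.frame(i = m[, 1], j = m[, 2], rev = m[, 3])
}

blosum62_oracle <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}
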