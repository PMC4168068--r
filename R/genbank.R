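# GenBank flat-file I/O. Single-record files only: one LOCUS, a FEATURES
# table whose CDS entries become genes, and an ORIGIN sequence block.
# Locations support `a..b`, `join(...)` (spliced) and `complement(...)`.
# GenBank coordinates are 1-based inclusive; they are converted to the
# internal 0-based half-open convention on read and back on write.

#' Read a single-record GenBank flat file
#'
#' Every CDS feature becomes a gene. A `/translation` qualifier is used
#' verbatim (and checked against re-translation of the spliced nucleotide
#' sequence); without one the CDS is translated with the configured genetic
#' code. `complement()` locations become reverse-strand genes.
#'
#' @param path Path to a GenBank flat file with one LOCUS record.
#' @param code Genetic code table (default `"11"`).
#' @param check_translation Error when a `/translation` disagrees with
#'   re-translation of the CDS (default `TRUE`).
#' @return A [phage_genome()].
#' @export
read_genbank <- function(path, code = "11", check_translation = TRUE) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) == 0) abort(paste0("not a GenBank record (no LOCUS line): ", path))
  if (length(locus_i) > 1) abort("multi-record GenBank files are not supported")
  name <- strsplit(trimws(sub("^LOCUS", "", lines[locus_i])), "\\s+")[[1]][1]
  acc <- NA_character_
  acc_i <- grep("^ACCESSION", lines)
  if (length(acc_i)) {
    acc <- strsplit(trimws(sub("^ACCESSION", "", lines[acc_i[1]])), "\\s+")[[1]][1]
    if (identical(acc, ".") || is.na(acc) || acc == "") acc <- NA_character_
  }

  origin_i <- grep("^ORIGIN", lines)
  if (length(origin_i) != 1) abort(paste0("malformed record: expected one ORIGIN line in ", path))
  end_i <- grep("^//", lines)
  end_i <- end_i[end_i > origin_i][1]
  if (is.na(end_i)) abort("malformed record: missing terminating // line")
  seq_lines <- lines[(origin_i + 1):(end_i - 1)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0) abort("malformed record: empty ORIGIN sequence")

  feat_i <- grep("^FEATURES", lines)
  genes_tbl <- NULL
  host <- NA_character_
  if (length(feat_i) == 1) {
    feat_lines <- lines[(feat_i + 1):(origin_i - 1)]
    feats <- parse_feature_table(feat_lines)
    host <- feats$host
    genes_tbl <- build_genes_from_features(feats$features, sequence, name, code,
                                           check_translation)
  }
  if (is.null(genes_tbl)) {
    genes_tbl <- tibble(gene_id = character(), start = integer(),
                        end = integer(), strand = character())
  }
  phage_genome(name, sequence, genes_tbl, host = host, accession = acc,
               code = code, check_translation = check_translation)
}

# split the FEATURES block into features, each with key, location, qualifiers
parse_feature_table <- function(feat_lines) {
  # feature keys start at column 6; continuations/qualifiers at column 22
  starts <- grep("^ {5}\\S", feat_lines)
  features <- list()
  host <- NA_character_
  for (k in seq_along(starts)) {
    from <- starts[k]
    to <- if (k < length(starts)) starts[k + 1] - 1 else length(feat_lines)
    block <- feat_lines[from:to]
    key <- strsplit(trimws(block[1]), "\\s+")[[1]][1]
    rest <- sub("^ {5}\\S+\\s*", "", block[1])
    body <- c(rest, trimws(block[-1]))
    # location = leading lines up to the first qualifier
    qual_start <- grep("^/", body)[1]
    loc_lines <- if (is.na(qual_start)) body else body[seq_len(qual_start - 1)]
    location <- gsub("\\s", "", paste(loc_lines, collapse = ""))
    quals <- list()
    if (!is.na(qual_start)) {
      qlines <- body[qual_start:length(body)]
      # merge continuation lines into their qualifier
      idx <- cumsum(grepl("^/", qlines))
      for (q in split(qlines, idx)) {
        qtext <- paste(q, collapse = " ")
        m <- regmatches(qtext, regexec('^/([A-Za-z_0-9]+)(?:=(.*))?$', qtext,
                                       perl = TRUE))[[1]]
        if (length(m) < 2) next
        qname <- m[2]
        qval <- if (length(m) >= 3) gsub('^"|"$', "", m[3]) else TRUE
        if (identical(qname, "translation")) qval <- gsub("\\s", "", qval)
        quals[[qname]] <- qval
      }
    }
    if (key == "source" && !is.null(quals$host)) host <- quals$host
    if (key == "source" && is.na(host) && !is.null(quals$lab_host)) host <- quals$lab_host
    features[[length(features) + 1]] <- list(key = key, location = location,
                                             qualifiers = quals)
  }
  list(features = features, host = host)
}

parse_location <- function(loc) {
  complement <- FALSE
  x <- loc
  if (grepl("^complement\\(", x)) {
    complement <- TRUE
    x <- sub("^complement\\((.*)\\)$", "\\1", x)
  }
  if (grepl("^join\\(", x)) {
    x <- sub("^join\\((.*)\\)$", "\\1", x)
  }
  parts <- strsplit(x, ",")[[1]]
  iv <- lapply(parts, function(p) {
    p <- gsub("[<>]", "", p)
    m <- regmatches(p, regexec("^(\\d+)\\.\\.(\\d+)$", p))[[1]]
    if (length(m) != 3) abort(paste0("cannot parse location segment: ", p,
                                     " (in ", loc, ")"))
    c(as.integer(m[2]), as.integer(m[3]))
  })
  list(intervals = iv, complement = complement)
}

build_genes_from_features <- function(features, sequence, name, code,
                                      check_translation) {
  cds <- keep(features, function(f) f$key == "CDS")
  if (length(cds) == 0) {
    return(tibble(gene_id = character(), start = integer(), end = integer(),
                  strand = character()))
  }
  rows <- vector("list", length(cds))
  for (i in seq_along(cds)) {
    f <- cds[[i]]
    loc <- parse_location(f$location)
    segs <- loc$intervals
    lo <- min(map_int(segs, 1))
    hi <- max(map_int(segs, 2))
    if (lo < 1 || hi > nchar(sequence)) {
      abort(paste0("CDS location outside sequence: ", f$location))
    }
    # spliced nucleotide sequence, 1-based inclusive segments
    nt <- paste(map_chr(segs, function(s) substr(sequence, s[1], s[2])),
                collapse = "")
    if (loc$complement) nt <- revcomp(nt)
    aa <- f$qualifiers$translation
    if (is.null(aa)) {
      aa <- tryCatch(translate_cds(nt, code), error = function(e) {
        abort(paste0("CDS at ", f$location,
                     " lacks /translation and cannot be translated: ",
                     conditionMessage(e)))
      })
    }
    gid <- f$qualifiers$locus_tag %||% f$qualifiers$gene %||%
      paste0(name, "_gp", i)
    rows[[i]] <- tibble(
      gene_id = gid,
      start = lo - 1L,            # GenBank 1-based inclusive -> 0-based half-open
      end = hi,
      strand = if (loc$complement) "reverse" else "forward",
      nt_seq = nt,
      aa_seq = aa,
      product = f$qualifiers$product %||% NA_character_
    )
  }
  bind_rows(rows)
}

#' Write a genome as a single-record GenBank flat file
#'
#' Inverse of [read_genbank()]: emits LOCUS/ACCESSION headers, a `source`
#' feature, one CDS per gene (with `/locus_tag`, `/product`, `/translation`)
#' and the ORIGIN block. Coordinates are converted back to 1-based inclusive.
#'
#' @param g A `phage_genome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(g, path) {
  stopifnot(inherits(g, "phage_genome"))
  L <- nchar(g$sequence)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w(sprintf("LOCUS       %-17s %d bp    DNA     linear   PHG", g$name, L))
  w(sprintf("DEFINITION  %s, complete genome.", g$name))
  w(sprintf("ACCESSION   %s", if (is.na(g$accession)) "." else g$accession))
  w("FEATURES             Location/Qualifiers")
  w(sprintf("     source          1..%d", L))
  if (!is.na(g$host)) w(sprintf('                     /host="%s"', g$host))
  for (i in seq_len(nrow(g$genes))) {
    gn <- g$genes[i, ]
    loc <- sprintf("%d..%d", gn$start + 1L, gn$end)
    if (gn$strand == "reverse") loc <- sprintf("complement(%s)", loc)
    w(sprintf("     CDS             %s", loc))
    w(sprintf('                     /locus_tag="%s"', gn$gene_id))
    if (!is.na(gn$product)) w(sprintf('                     /product="%s"', gn$product))
    tr <- paste0('/translation="', gn$aa_seq, '"')
    from <- seq(1, nchar(tr), by = 58)
    for (p in from) {
      w(paste0("                     ", substr(tr, p, min(p + 57, nchar(tr)))))
    }
  }
  w("ORIGIN")
  pos <- seq(1, L, by = 60)
  for (p in pos) {
    chunk <- substr(g$sequence, p, min(p + 59, L))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    w(sprintf("%9d %s", p, tolower(paste(groups, collapse = " "))))
  }
  w("//")
  invisible(path)
}
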