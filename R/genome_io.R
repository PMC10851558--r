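#' An annotated genome and its ordered gene features
#'
#' Constructs a `GenomeRecord`, the normalized gene model shared by all
#' downstream stages. Coordinates are 0-based half-open throughout the
#' package; GenBank I/O converts at the boundary.
#'
#' @param genome_id Accession or other identifier.
#' @param sequence Nucleotide sequence as a single character string over
#'   `A,C,G,T,N` (case-insensitive; stored upper case).
#' @param genes A data.frame with columns `gene_id`, `name`, `kind`
#'   (one of `CDS`, `tRNA`, `rRNA`, `ncRNA`, `tmRNA`), `start`, `end`
#'   (0-based half-open), `strand` (`+`/`-`), `pseudo` (logical) and
#'   optionally `translation`. Rows are re-sorted by `start`.
#' @param organism Organism name (free text).
#' @param circular Is the replicon circular? Origin-spanning features on a
#'   circular record are represented with `end > nchar(sequence)` and are
#'   extracted with wrap-around.
#' @return An object of class `GenomeRecord`.
#' @export
GenomeRecord <- function(genome_id, sequence, genes, organism = "",
                         circular = TRUE) {
  sequence <- toupper(as.character(sequence))
  stopifnot(is.character(genome_id), length(genome_id) == 1L,
            nchar(sequence) > 0L, is.data.frame(genes))
  need <- c("gene_id", "kind", "start", "end", "strand")
  miss <- setdiff(need, names(genes))
  if (length(miss))
    stop("genes table is missing columns: ", paste(miss, collapse = ", "))
  if (!"name" %in% names(genes)) genes$name <- ""
  if (!"pseudo" %in% names(genes)) genes$pseudo <- FALSE
  if (!"translation" %in% names(genes)) genes$translation <- ""
  genes <- genes[order(genes$start, genes$end, genes$gene_id),
                 c("gene_id", "name", "kind", "start", "end", "strand",
                   "pseudo", "translation"), drop = FALSE]
  rownames(genes) <- NULL
  g <- structure(list(genome_id = genome_id, organism = organism,
                      circular = isTRUE(circular), sequence = sequence,
                      genes = genes),
                 class = "GenomeRecord")
  validate_genome(g)
  g
}

GENE_KINDS <- c("CDS", "tRNA", "rRNA", "ncRNA", "tmRNA")

#' Validate GenomeRecord invariants
#'
#' Checks coordinate sanity (0 <= start < end; end may exceed the sequence
#' length only for origin-spanning features on a circular record), gene_id
#' uniqueness and sort order. Called by the constructor; exported for use
#' after manual edits.
#'
#' @param g A `GenomeRecord`.
#' @return `g`, invisibly; errors on violation.
#' @export
validate_genome <- function(g) {
  stopifnot(inherits(g, "GenomeRecord"))
  L <- nchar(g$sequence)
  gn <- g$genes
  if (nrow(gn)) {
    if (any(gn$start < 0L) || any(gn$start >= gn$end))
      stop("gene coordinates violate 0 <= start < end")
    lim <- if (g$circular) gn$start + L else L
    if (any(gn$end > lim))
      stop("gene end beyond sequence length: ",
           paste(gn$gene_id[gn$end > lim], collapse = ", "))
    if (anyDuplicated(gn$gene_id))
      stop("duplicate gene_id: ",
           paste(unique(gn$gene_id[duplicated(gn$gene_id)]), collapse = ", "))
    if (is.unsorted(gn$start))
      stop("genes not sorted by start")
    bad <- !gn$kind %in% GENE_KINDS
    if (any(bad))
      stop("unknown gene kind: ", paste(unique(gn$kind[bad]), collapse = ", "))
    if (!all(gn$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'")
  }
  invisible(g)
}

#' @export
print.GenomeRecord <- function(x, ...) {
  cat(sprintf("GenomeRecord %s (%s): %s bp, %d genes%s\n",
              x$genome_id, if (x$circular) "circular" else "linear",
              format(nchar(x$sequence), big.mark = ","), nrow(x$genes),
              if (nchar(x$organism)) paste0(" [", x$organism, "]") else ""))
  invisible(x)
}

## -- sequence extraction ------------------------------------------------

#' Extract gene nucleotide sequences (strand-aware, origin-wrapping)
#'
#' @param g A `GenomeRecord`.
#' @param gene_ids Genes to extract; default all.
#' @return Named character vector of nucleotide sequences on the coding
#'   strand (minus-strand genes are reverse-complemented).
#' @export
gene_sequence <- function(g, gene_ids = NULL) {
  gn <- g$genes
  if (!is.null(gene_ids)) {
    idx <- match(gene_ids, gn$gene_id)
    if (anyNA(idx)) stop("unknown gene_id: ",
                         paste(gene_ids[is.na(idx)], collapse = ", "))
    gn <- gn[idx, , drop = FALSE]
  }
  L <- nchar(g$sequence)
  out <- character(nrow(gn))
  for (i in seq_len(nrow(gn))) {
    s <- gn$start[i]; e <- gn$end[i]
    seq <- if (e <= L) substr(g$sequence, s + 1L, e)
           else paste0(substr(g$sequence, s + 1L, L),   # wraps the origin
                       substr(g$sequence, 1L, e - L))
    if (gn$strand[i] == "-") seq <- revcomp(seq)
    out[i] <- seq
  }
  names(out) <- gn$gene_id
  out
}

#' Reverse-complement a nucleotide string
#' @param seq Character vector of nucleotide strings.
#' @return Reverse-complemented strings.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

## -- GenBank flat file I/O ----------------------------------------------
## No installed package parses local GenBank flat files, so the parser is
## implemented here. It handles single-contig records, join() locations
## (including origin wrap on circular records), /pseudo and /translation.

#' Read a single-contig GenBank flat file
#'
#' Converts 1-based inclusive GenBank coordinates to the package's 0-based
#' half-open convention. Features of unknown kind (other than the structural
#' `source`/`gene` features) are dropped with a warning; pseudogenes are
#' retained and flagged. A feature whose `join()` location spans the origin
#' of a circular record becomes a single gene with `end > genome length`.
#'
#' @param path Path to a GenBank flat file containing exactly one record.
#' @return A `GenomeRecord`.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) > 1L) {
    ids <- vapply(strsplit(lines[locus_i], "[[:space:]]+"), `[`, "", 2L)
    stop("multi-record GenBank file; records: ", paste(ids, collapse = ", "))
  }
  if (length(locus_i) == 0L) stop("not a GenBank file (no LOCUS line)")
  locus <- strsplit(lines[locus_i], "[[:space:]]+")[[1]]
  locus_name <- locus[2]
  circular <- any(grepl("circular", lines[locus_i], ignore.case = TRUE))

  ver_i <- grep("^VERSION", lines)
  genome_id <- if (length(ver_i))
    strsplit(lines[ver_i[1]], "[[:space:]]+")[[1]][2] else locus_name
  if (is.na(genome_id) || !nzchar(genome_id)) genome_id <- locus_name

  org_i <- grep("^  ORGANISM", lines)
  organism <- if (length(org_i))
    sub("^  ORGANISM[[:space:]]+", "", lines[org_i[1]]) else ""

  ## sequence
  ori_i <- grep("^ORIGIN", lines)
  if (!length(ori_i)) stop("missing ORIGIN sequence in ", path)
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[end_i > ori_i[1]][1] else length(lines) + 1L
  seq_lines <- lines[(ori_i[1] + 1L):(end_i - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) stop("missing ORIGIN sequence in ", path)
  L <- nchar(sequence)

  ## features
  feat_i <- grep("^FEATURES", lines)
  feats <- list()
  if (length(feat_i)) {
    block <- lines[(feat_i[1] + 1L):(ori_i[1] - 1L)]
    is_new <- grepl("^ {5}\\S", block)
    idx <- cumsum(is_new)
    for (k in seq_len(max(idx, 0))) {
      fl <- block[idx == k]
      key <- sub("^ {5}(\\S+).*", "\\1", fl[1])
      body <- sub("^ {5}\\S+\\s*", "", fl[1])
      rest <- sub("^\\s+", "", fl[-1])
      ## location may continue until first qualifier line
      qual_start <- which(grepl("^/", rest))[1]
      loc <- paste0(body, paste(rest[seq_len(
        if (is.na(qual_start)) length(rest) else qual_start - 1L)],
        collapse = ""))
      quals <- if (is.na(qual_start)) character(0) else
        rest[qual_start:length(rest)]
      feats[[length(feats) + 1L]] <- list(key = key, loc = loc, quals = quals)
    }
  }

  qual_value <- function(quals, name) {
    ## joins continuation lines of a multi-line qualifier value
    hits <- grep(paste0("^/", name, "(=|$)"), quals)
    if (!length(hits)) return(NA_character_)
    i <- hits[1]
    val <- sub(paste0("^/", name, "=?"), "", quals[i])
    j <- i + 1L
    while (j <= length(quals) && !grepl("^/", quals[j])) {
      val <- paste0(val, if (grepl("^/translation", quals[i])) "" else " ",
                    quals[j])
      j <- j + 1L
    }
    gsub("\"", "", val)
  }

  rows <- list(); dropped <- character(0); counter <- 0L
  for (f in feats) {
    if (f$key %in% c("source", "gene")) next
    if (!f$key %in% GENE_KINDS) { dropped <- c(dropped, f$key); next }
    loc <- gsub("[<>]", "", gsub("\\s", "", f$loc))
    strand <- if (grepl("complement", loc)) "-" else "+"
    loc <- gsub("complement\\(|join\\(|order\\(|\\)", "", loc)
    spans <- strsplit(loc, ",")[[1]]
    mat <- t(vapply(spans, function(s) {
      p <- as.integer(strsplit(s, "\\.\\.")[[1]])
      if (length(p) == 1L) p <- c(p, p)
      p
    }, integer(2)))
    start1 <- mat[1, 1]; end1 <- mat[nrow(mat), 2]
    if (nrow(mat) > 1L && circular && mat[nrow(mat), 1] < mat[1, 2]) {
      ## origin-spanning join: second span restarts at base 1
      start <- start1 - 1L; end <- L + end1
    } else {
      start <- min(mat) - 1L; end <- max(mat)
    }
    counter <- counter + 1L
    lt <- qual_value(f$quals, "locus_tag")
    gname <- qual_value(f$quals, "gene")
    tr <- qual_value(f$quals, "translation")
    pseudo <- any(grepl("^/pseudo(gene)?", f$quals))
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = if (!is.na(lt)) lt else if (!is.na(gname)) gname
                else sprintf("%s_%04d", f$key, counter),
      name = if (!is.na(gname)) gname else "",
      kind = f$key, start = start, end = end, strand = strand,
      pseudo = pseudo,
      translation = if (!is.na(tr)) gsub("\\s", "", tr) else "",
      stringsAsFactors = FALSE)
  }
  if (length(dropped))
    warning("dropped features of unknown kind: ",
            paste(unique(dropped), collapse = ", "))
  genes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), name = character(0),
               kind = character(0), start = integer(0), end = integer(0),
               strand = character(0), pseudo = logical(0),
               translation = character(0))
  ## locus tags can repeat across feature kinds in rare annotations
  if (anyDuplicated(genes$gene_id))
    genes$gene_id <- make.unique(genes$gene_id, sep = "_")
  GenomeRecord(genome_id, sequence, genes, organism, circular)
}

#' Write a GenomeRecord as a GenBank flat file
#'
#' @param g A `GenomeRecord`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(g, path) {
  L <- nchar(g$sequence)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("LOCUS       %s%17d bp    DNA     %s   BCT",
                     g$genome_id, L,
                     if (g$circular) "circular" else "linear "), con)
  writeLines(sprintf("DEFINITION  %s.", g$organism), con)
  writeLines(sprintf("VERSION     %s", g$genome_id), con)
  writeLines(sprintf("SOURCE      %s", g$organism), con)
  writeLines(sprintf("  ORGANISM  %s", g$organism), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", L), con)
  fmt_loc <- function(start, end, strand) {
    loc <- if (end <= L) sprintf("%d..%d", start + 1L, end)
           else sprintf("join(%d..%d,1..%d)", start + 1L, L, end - L)
    if (strand == "-") sprintf("complement(%s)", loc) else loc
  }
  for (i in seq_len(nrow(g$genes))) {
    gn <- g$genes[i, ]
    writeLines(sprintf("     %-16s%s", gn$kind,
                       fmt_loc(gn$start, gn$end, gn$strand)), con)
    writeLines(sprintf("                     /locus_tag=\"%s\"", gn$gene_id),
               con)
    if (nzchar(gn$name))
      writeLines(sprintf("                     /gene=\"%s\"", gn$name), con)
    if (gn$pseudo)
      writeLines("                     /pseudo", con)
    if (nzchar(gn$translation))
      writeLines(sprintf("                     /translation=\"%s\"",
                         gn$translation), con)
  }
  writeLines("ORIGIN", con)
  pos <- seq(1L, L, by = 60L)
  for (p in pos) {
    chunk <- substr(g$sequence, p, min(p + 59L, L))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, paste(tens, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

## -- FASTA I/O (via Biostrings) -----------------------------------------

#' Read a FASTA file into a named character vector
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write named sequences as FASTA (70-column wrap)
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 70L)
  invisible(path)
}

## -- proteome extraction ------------------------------------------------

#' Translate all protein-coding genes of a genome
#'
#' Translation uses the bacterial/plastid genetic code (transl_table 11);
#' the trailing stop is removed. A CDS whose length is not a codon multiple
#' is truncated to the codon boundary with a warning. A CDS containing an
#' internal stop is truncated at that stop and reported as a split-gene
#' candidate, mirroring how fragmented genes betray themselves on
#' translation.
#'
#' @param g A `GenomeRecord` with at least one non-pseudo CDS.
#' @param table Genetic code id (default `"11"`).
#' @param include_pseudo Include pseudogenes? Default `FALSE`.
#' @return A list with `proteome` (named character vector of amino-acid
#'   sequences) and `split_candidates` (gene ids with internal stops).
#' @export
extract_proteome <- function(g, table = "11", include_pseudo = FALSE) {
  gn <- g$genes
  keep <- gn$kind == "CDS" & (include_pseudo | !gn$pseudo)
  if (!any(keep)) stop("genome ", g$genome_id, " has no eligible CDS")
  ids <- gn$gene_id[keep]
  nts <- gene_sequence(g, ids)
  code <- Biostrings::getGeneticCode(table)
  bad_len <- nchar(nts) %% 3L != 0L
  if (any(bad_len)) {
    warning("CDS length not divisible by 3, truncating: ",
            paste(ids[bad_len], collapse = ", "))
    nts[bad_len] <- substr(nts[bad_len], 1L,
                           nchar(nts[bad_len]) - nchar(nts[bad_len]) %% 3L)
  }
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(nts), genetic.code = code,
    if.fuzzy.codon = "solve", no.init.codon = FALSE))
  aa <- sub("\\*$", "", aa)            # trailing stop
  internal <- grepl("\\*", aa)
  aa[internal] <- sub("\\*.*$", "", aa[internal])
  keep2 <- nzchar(aa)
  list(proteome = setNames(aa[keep2], ids[keep2]),
       split_candidates = ids[internal])
}

#' Tabulate the genes of a genome
#'
#' One row per gene: id, kind, coordinates, strand, length, %GC and pseudo
#' flag. The table is written/read as TSV by [write_gene_table()].
#'
#' @param g A `GenomeRecord`.
#' @return A data.frame with columns `gene_id`, `kind`, `start`, `end`,
#'   `strand`, `length`, `gc_percent`, `pseudo`.
#' @export
gene_table <- function(g) {
  gn <- g$genes
  if (!nrow(gn)) {
    warning("genome ", g$genome_id, " has no annotated genes")
    return(data.frame(gene_id = character(0), kind = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), length = integer(0),
                      gc_percent = numeric(0), pseudo = logical(0)))
  }
  seqs <- gene_sequence(g)
  data.frame(gene_id = gn$gene_id, kind = gn$kind, start = gn$start,
             end = gn$end, strand = gn$strand, length = gn$end - gn$start,
             gc_percent = gc_percent(seqs), pseudo = gn$pseudo,
             row.names = NULL)
}

#' Write a gene table as TSV
#' @param tab Output of [gene_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Count genes by kind
#' @param g A `GenomeRecord`.
#' @param include_pseudo Count pseudogenes? Default `FALSE` (annotation
#'   summaries in this field conventionally exclude them).
#' @return Named integer vector over the five gene kinds plus `total`.
#' @export
gene_kind_counts <- function(g, include_pseudo = FALSE) {
  gn <- g$genes
  if (!include_pseudo) gn <- gn[!gn$pseudo, , drop = FALSE]
  counts <- vapply(GENE_KINDS, function(k) sum(gn$kind == k), integer(1))
  c(counts, total = sum(counts))
}
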