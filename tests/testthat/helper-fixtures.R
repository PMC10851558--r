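## Programmatic fixtures shared across test files.

## A linear toy genome: genes laid down left to right with fixed spacers.
## `genes` is a data.frame with columns name, seq (coding-strand
## nucleotides) and optionally strand / kind / pseudo.
toy_genome <- function(genome_id, genes, spacer = 10L, circular = TRUE,
                       spacer_base = "T") {
  pos <- 0L; rows <- list(); chunks <- character(0)
  for (i in seq_len(nrow(genes))) {
    sp <- strrep(spacer_base, spacer)
    chunks <- c(chunks, sp); pos <- pos + nchar(sp)
    strand <- if ("strand" %in% names(genes)) genes$strand[i] else "+"
    rows[[i]] <- data.frame(
      gene_id = paste0(genome_id, "_", genes$name[i]),
      name = genes$name[i],
      kind = if ("kind" %in% names(genes)) genes$kind[i] else "CDS",
      start = pos, end = pos + nchar(genes$seq[i]), strand = strand,
      pseudo = if ("pseudo" %in% names(genes)) genes$pseudo[i] else FALSE,
      translation = "")
    chunks <- c(chunks, if (strand == "-") generosion::revcomp(genes$seq[i])
                        else genes$seq[i])
    pos <- pos + nchar(genes$seq[i])
  }
  GenomeRecord(genome_id, paste(chunks, collapse = ""),
               do.call(rbind, rows), circular = circular)
}

## Random valid ORF at roughly 50% GC (uniform sense codons).
random_orf <- function(n_codons) {
  codons <- as.vector(outer(outer(c("A", "C", "G", "T"),
                                  c("A", "C", "G", "T"), paste0),
                            c("A", "C", "G", "T"), paste0))
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste0("ATG", paste(sample(sense, n_codons - 2L, replace = TRUE),
                      collapse = ""), "TAA")
}

## Minimal GeneArray constructed directly, for operations that only read
## rows/cells (syntenic blocks, strand deviations, presence matrix).
toy_array <- function(rows, cells, genome_ids) {
  structure(list(genome_ids = genome_ids, rows = rows, cells = cells),
            class = "GeneArray")
}

## A small cached simulation shared by expensive tests within one run.
.sim_cache <- new.env(parent = emptyenv())
small_simulation <- function() {
  if (is.null(.sim_cache$res)) {
    cfg <- sim_config(seed = 5, n_descendants = 3, n_ancestor_genes = 40,
                      gene_length_mean = 450, gene_length_sd = 120)
    anc <- generate_ancestor(cfg)
    red <- simulate_reduction(anc, cfg)
    proteomes <- lapply(red$genomes,
                        function(g) extract_proteome(g)$proteome)
    assignments <- lapply(names(red$genomes), function(gid)
      reciprocal_best_hits(proteomes[[gid]], anc$proteome))
    names(assignments) <- names(red$genomes)
    arr <- build_array(red$genomes, assignments, proteomes)
    .sim_cache$res <- list(cfg = cfg, anc = anc, red = red,
                           proteomes = proteomes,
                           assignments = assignments, array = arr)
  }
  .sim_cache$res
}
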