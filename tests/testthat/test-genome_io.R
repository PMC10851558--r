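test_that("GenBank coordinates convert to 0-based half-open", {
  gb <- c(
    "LOCUS       TOY       30 bp    DNA     circular BCT",
    "DEFINITION  toy.",
    "VERSION     TOY.1",
    "FEATURES             Location/Qualifiers",
    "     source          1..30",
    "     CDS             1..9",
    "                     /locus_tag=\"t1\"",
    "     CDS             complement(13..21)",
    "                     /locus_tag=\"t2\"",
    "                     /pseudo",
    "ORIGIN",
    "        1 atgaaataac ccatgaaatt tacgtacgta",
    "//")
  tf <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, tf)
  g <- read_genbank(tf)
  expect_equal(g$genome_id, "TOY.1")
  expect_true(g$circular)
  expect_equal(nchar(g$sequence), 30)
  expect_equal(g$genes$start, c(0L, 12L))
  expect_equal(g$genes$end, c(9L, 21L))
  expect_equal(g$genes$strand, c("+", "-"))
  expect_equal(g$genes$pseudo, c(FALSE, TRUE))
})

test_that("pseudogenes are excluded from PCG statistics by default", {
  g <- toy_genome("P", data.frame(
    name = c("a", "b"),
    seq = c("ATGAAATAA", "ATGGGGTAA"),
    pseudo = c(FALSE, TRUE)))
  counts <- gene_kind_counts(g)
  expect_equal(unname(counts["CDS"]), 1L)
  expect_equal(unname(gene_kind_counts(g, include_pseudo = TRUE)["CDS"]), 2L)
  stats <- pcg_gc_stats(list(g))
  expect_equal(nrow(stats$per_gene), 1L)
  prot <- extract_proteome(g)
  expect_named(prot$proteome, "P_a")
})

test_that("malformed GenBank input is rejected with useful errors", {
  tf <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS  A 5 bp", "ORIGIN", "  1 acgta", "//",
               "LOCUS  B 5 bp", "ORIGIN", "  1 acgta", "//"), tf)
  expect_error(read_genbank(tf), "multi-record.*A.*B")
  tf2 <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS  A 5 bp", "FEATURES", "     CDS   1..3", "//"), tf2)
  expect_error(read_genbank(tf2), "ORIGIN")
})

test_that("origin-spanning features wrap and extract correctly", {
  seq <- strrep("ACGT", 25)                      # 100 bp
  gn <- data.frame(gene_id = "w1", name = "", kind = "CDS", start = 90L,
                   end = 106L, strand = "+", pseudo = FALSE,
                   translation = "")
  g <- GenomeRecord("W", seq, gn, circular = TRUE)
  got <- unname(gene_sequence(g, "w1"))
  manual <- paste0(substr(seq, 91, 100), substr(seq, 1, 6))
  expect_equal(got, manual)
  ## survives a GenBank round trip as a join() location
  tf <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, tf)
  g2 <- read_genbank(tf)
  expect_equal(g2$genes$start, 90L)
  expect_equal(g2$genes$end, 106L)
  expect_match(readLines(tf), "join\\(91\\.\\.100,1\\.\\.6\\)", all = FALSE)
})

test_that("read-write-read round trip preserves a simulated genome", {
  set.seed(7)
  cfg <- sim_config(seed = 7, n_descendants = 1, n_ancestor_genes = 15,
                    gene_length_mean = 300, gene_length_sd = 60)
  g <- simulate_reduction(generate_ancestor(cfg), cfg)$genomes[[1]]
  tf <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, tf)
  g2 <- read_genbank(tf)
  expect_identical(g2$sequence, g$sequence)
  expect_identical(g2$genes$start, g$genes$start)
  expect_identical(g2$genes$end, g$genes$end)
  expect_identical(g2$genes$strand, g$genes$strand)
  expect_identical(g2$genes$gene_id, g$genes$gene_id)
  tf2 <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g2, tf2)
  expect_identical(readLines(tf), readLines(tf2))
})

test_that("translation follows the bacterial code with strand awareness", {
  g <- toy_genome("T", data.frame(
    name = c("p", "m"),
    seq = c("ATGAAATAA", "ATGAAAATGTAA"),
    strand = c("+", "-")))
  ## the minus-strand gene is stored reverse-complemented on the genome;
  ## extraction must recover the coding strand
  expect_equal(substr(g$sequence, g$genes$start[2] + 1, g$genes$end[2]),
               "TTACATTTTCAT")
  prot <- extract_proteome(g)$proteome
  expect_equal(unname(prot["T_p"]), "MK")
  expect_equal(unname(prot["T_m"]), "MKM")
})

test_that("internal stops are truncated and reported as split candidates", {
  g <- toy_genome("S", data.frame(name = "s1", seq = "ATGTAAAAATAA"))
  res <- extract_proteome(g)
  expect_equal(unname(res$proteome["S_s1"]), "M")
  expect_equal(res$split_candidates, "S_s1")
})

test_that("gene tables have one row per gene and consistent kind counts", {
  g <- toy_genome("G", data.frame(
    name = c("a", "b", "t"),
    seq = c("ATGAAATAA", "ATGGGCTAA", strrep("AC", 38)),
    kind = c("CDS", "CDS", "tRNA")))
  tab <- gene_table(g)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$length, tab$end - tab$start)
  counts <- gene_kind_counts(g)
  kinds <- c("CDS", "tRNA", "rRNA", "ncRNA", "tmRNA")
  expect_equal(sum(counts[kinds]), unname(counts["total"]))
  empty <- GenomeRecord("E", "ACGT", g$genes[0, ])
  expect_warning(et <- gene_table(empty), "no annotated genes")
  expect_equal(nrow(et), 0L)
})

test_that("FASTA I/O round trips with 70-column wrap", {
  seqs <- c(a = strrep("ACGT", 50), b = "ATGAAATAA")
  tf <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, tf)
  expect_lte(max(nchar(readLines(tf))), 70L)
  expect_identical(read_fasta(tf), seqs)
})
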