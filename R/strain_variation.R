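## Variant filtering and allele-frequency analytics: detection of multiple
## co-resident endosymbiont genotypes within single hosts, shared-variant
## reports across populations, and coding-effect annotation.

PILEUP_COLS <- c("position", "ref", "A", "C", "G", "T", "ins", "del",
                 "mean_qual")

#' Read a per-site allele-count (pileup-style) TSV
#'
#' Expected header: `position ref A C G T ins del mean_qual`, positions
#' 0-based.
#'
#' @param path TSV path.
#' @return Validated data.frame.
#' @export
read_pileup <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  miss <- setdiff(PILEUP_COLS, names(d))
  if (length(miss))
    stop("pileup is missing columns: ", paste(miss, collapse = ", "))
  num <- c("position", "A", "C", "G", "T", "ins", "del", "mean_qual")
  for (cn in num) {
    v <- suppressWarnings(as.numeric(d[[cn]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop("malformed pileup row at line ", bad + 1L, " (column ", cn, ")")
    }
    d[[cn]] <- v
  }
  d
}

#' Call variants from a per-site allele-count table
#'
#' A site is emitted iff its depth (sum of all allele counts at the site)
#' is at least `min_depth`, its mean base quality at least `min_qual`, and
#' some non-reference allele frequency at least `min_freq` — all three
#' thresholds inclusive, matching a x100 coverage / Q20 / 20% filter at
#' the defaults. Multi-allelic sites emit one record per alternate allele
#' passing the frequency filter.
#'
#' @param pileup Data frame as returned by [read_pileup()].
#' @param min_depth Minimum site depth (default 100).
#' @param min_qual Minimum mean base quality (default 20).
#' @param min_freq Minimum alternate-allele frequency (default 0.20).
#' @param population Population label stored on the records.
#' @return Data frame of `VariantSite` rows: `population, position,
#'   ref_allele, alt_allele, depth, alt_count, frequency,
#'   mean_base_quality`.
#' @export
call_variants <- function(pileup, min_depth = 100, min_qual = 20,
                          min_freq = 0.20, population = "") {
  alleles <- c("A", "C", "G", "T", "ins", "del")
  depth <- rowSums(pileup[, alleles])
  out <- list()
  keep_site <- depth >= min_depth & pileup$mean_qual >= min_qual
  for (al in alleles) {
    cnt <- pileup[[al]]
    is_alt <- al != pileup$ref
    freq <- ifelse(depth > 0, cnt / depth, 0)
    sel <- keep_site & is_alt & cnt > 0 & freq >= min_freq
    if (any(sel))
      out[[al]] <- data.frame(
        population = population,
        position = pileup$position[sel],
        ref_allele = pileup$ref[sel],
        alt_allele = al,
        depth = depth[sel],
        alt_count = cnt[sel],
        frequency = freq[sel],
        mean_base_quality = pileup$mean_qual[sel])
  }
  if (!length(out))
    return(data.frame(population = character(0), position = numeric(0),
                      ref_allele = character(0), alt_allele = character(0),
                      depth = numeric(0), alt_count = numeric(0),
                      frequency = numeric(0), mean_base_quality = numeric(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$position, res$alt_allele), ]
  rownames(res) <- NULL
  res
}

#' Read variant sites from a VCF with AD/DP fields
#'
#' Alternative ingestion route producing the same `VariantSite` table
#' that [call_variants()] emits; the VCF QUAL column stands in for the
#' mean base quality. Positions are converted to 0-based.
#'
#' @param path VCF path (vcfR is used for parsing).
#' @param population Population label.
#' @return Data frame of `VariantSite` rows.
#' @export
read_vcf_sites <- function(path, population = "") {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ad <- vcfR::extract.gt(v, element = "AD")[, 1]
  out <- list()
  for (i in seq_len(nrow(fix))) {
    counts <- as.numeric(strsplit(ad[i], ",")[[1]])
    alts <- strsplit(fix[i, "ALT"], ",")[[1]]
    depth <- sum(counts)
    for (k in seq_along(alts)) {
      out[[length(out) + 1L]] <- data.frame(
        population = population,
        position = as.numeric(fix[i, "POS"]) - 1,
        ref_allele = fix[i, "REF"],
        alt_allele = alts[k],
        depth = depth,
        alt_count = counts[k + 1L],
        frequency = counts[k + 1L] / depth,
        mean_base_quality = suppressWarnings(as.numeric(fix[i, "QUAL"])))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Flag variable sites (evidence of multiple co-resident strains)
#'
#' A site is variable when its alternate-allele frequency lies in
#' `[low, high]` (inclusive); fixed-like differences near 0 or 1 are not.
#'
#' @param sites `VariantSite` data frame.
#' @param low,high Frequency window (defaults 0.20 and 0.80).
#' @return `sites` with an added logical `variable` column.
#' @export
classify_variable_sites <- function(sites, low = 0.20, high = 0.80) {
  sites$variable <- sites$frequency >= low & sites$frequency <= high
  sites
}

#' Shared-variant (Venn) report across populations
#'
#' Variants are keyed by `position + ref + alt`. Counts are reported for
#' every population subset; a variant is "shared" when present in at
#' least two populations.
#'
#' @param site_sets Named list of `VariantSite` data frames, one per
#'   population.
#' @return List with `subset_counts` (named by `&`-joined population
#'   subsets), `per_population` (total per population), `n_union`,
#'   `n_shared`.
#' @export
shared_variants <- function(site_sets) {
  if (length(site_sets) < 2L) stop("need at least two populations")
  keys <- lapply(site_sets, function(s)
    unique(paste(s$position, s$ref_allele, s$alt_allele, sep = ":")))
  all_keys <- unique(unlist(keys))
  member <- vapply(keys, function(k) all_keys %in% k,
                   logical(length(all_keys)))
  if (length(all_keys) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL,
                                                               names(keys)))
  sig <- apply(member, 1, function(m)
    paste(names(site_sets)[m], collapse = "&"))
  subset_counts <- table(sig)
  list(subset_counts = as.list(subset_counts),
       per_population = vapply(keys, length, integer(1)),
       n_union = length(all_keys),
       n_shared = sum(rowSums(member) >= 2L))
}

#' Annotate the coding effect of variant sites
#'
#' SNVs inside a CDS are classified by re-translating the affected codon
#' (strand-aware, bacterial code): synonymous, missense or stop_gained.
#' Indels whose length change is not a codon multiple are frameshift;
#' in-frame indels are reported as missense (they alter the protein
#' without shifting the frame). Sites outside annotated genes are
#' intergenic.
#'
#' @param sites `VariantSite` data frame (alleles `A/C/G/T` for SNVs,
#'   `ins`/`del` or sequence strings for indels).
#' @param genome A `GenomeRecord`.
#' @return `sites` with added columns `gene_id`, `effect`, `aa_change`.
#' @export
annotate_effect <- function(sites, genome) {
  L <- nchar(genome$sequence)
  if (any(sites$position >= L))
    stop("variant position beyond genome length")
  gn <- genome$genes
  code <- Biostrings::getGeneticCode("11")
  sites$gene_id <- NA_character_
  sites$effect <- "intergenic"
  sites$aa_change <- NA_character_
  for (i in seq_len(nrow(sites))) {
    pos <- sites$position[i]
    hit <- which(gn$start <= pos & pos < gn$end)
    if (!length(hit)) next
    hit <- hit[1]
    sites$gene_id[i] <- gn$gene_id[hit]
    if (gn$kind[hit] != "CDS") { sites$effect[i] <- "intergenic"; next }
    ref <- sites$ref_allele[i]; alt <- sites$alt_allele[i]
    is_indel <- alt %in% c("ins", "del") || nchar(ref) != nchar(alt) ||
      nchar(alt) > 1L
    if (is_indel) {
      shift <- if (alt == "ins") 1L else if (alt == "del") 1L
        else abs(nchar(alt) - nchar(ref))
      sites$effect[i] <- if (shift %% 3L != 0L) "frameshift" else "missense"
      next
    }
    ## SNV: locate the codon within the coding sequence
    nt <- gene_sequence(genome, gn$gene_id[hit])
    off <- if (gn$strand[hit] == "+") pos - gn$start[hit]
           else gn$end[hit] - 1L - pos
    base <- if (gn$strand[hit] == "+") alt else
      chartr("ACGT", "TGCA", alt)
    codon_i <- off %/% 3L
    within <- off %% 3L
    codon <- substr(nt, codon_i * 3L + 1L, codon_i * 3L + 3L)
    if (nchar(codon) < 3L) { sites$effect[i] <- "intergenic"; next }
    new_codon <- codon
    substr(new_codon, within + 1L, within + 1L) <- base
    aa_old <- unname(code[codon]); aa_new <- unname(code[new_codon])
    if (is.na(aa_old) || is.na(aa_new)) next
    sites$effect[i] <-
      if (aa_new == aa_old) "synonymous"
      else if (aa_new == "*") "stop_gained"
      else "missense"
    sites$aa_change[i] <- sprintf("%s%d%s", aa_old, codon_i + 1L, aa_new)
  }
  sites
}

#' Distribution of genic variants across conservation quadrants
#'
#' Counts effect-annotated genic sites per quadrant of their host gene;
#' intergenic sites are excluded and genes without a quadrant are counted
#' as `unclassified`.
#'
#' @param sites Effect-annotated `VariantSite` data frame (from
#'   [annotate_effect()]).
#' @param gene_quadrants Named character vector mapping gene ids to
#'   `"Q1".."Q4"`.
#' @return Named integer vector `Q1..Q4, unclassified`.
#' @export
snp_quadrant_distribution <- function(sites, gene_quadrants) {
  genic <- sites[!is.na(sites$gene_id) & sites$effect != "intergenic", ]
  q <- gene_quadrants[genic$gene_id]
  q[is.na(q)] <- "unclassified"
  counts <- table(factor(q, levels = c("Q1", "Q2", "Q3", "Q4",
                                       "unclassified")))
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}
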