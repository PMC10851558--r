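## Synthetic genome-reduction simulator. Generates an ancestor genome
## (standing in for the free-living relative), reduced descendants with a
## complete ground-truth ledger (AT-biased substitution, gene loss,
## splitting, duplication, strand flips, short inversions, intergenic
## decay), two-strain read pileups at known mixing frequencies, and
## overdispersed expression counts with known tiers.

#' Simulation configuration
#'
#' Defaults describe a mild-erosion scenario: ten descendants of a
#' 150-gene ancestor, AT-biased substitution (80% of substitutions create
#' A or T), gamma-distributed per-gene erosion intensity, gene loss
#' logistic in eroded gene %GC around a 26% tipping point, occasional
#' splits, duplications, strand flips and short inversions, and decaying
#' intergenic spacers.
#'
#' @param seed Master seed; every draw is reproducible from it.
#' @param n_descendants Number of descendant genomes.
#' @param n_ancestor_genes Genes in the ancestor.
#' @param gene_length_mean,gene_length_sd Gene length distribution in bp
#'   (codon-rounded, minimum 90 bp).
#' @param intergenic_mean Mean ancestral intergenic spacer (bp).
#' @param ancestor_gc Target ancestor %GC.
#' @param at_bias Probability that a substitution writes A or T.
#' @param erosion_shape,erosion_mean Gamma shape and mean of the per-gene
#'   substitution rate (expected substitutions per site).
#' @param loss_max,loss_midpoint_gc,loss_scale Loss probability is
#'   `loss_max * weight * plogis((loss_midpoint_gc - gc) / loss_scale)`,
#'   echoing the observation that low-GC genes are purged around a ~26%
#'   tipping point.
#' @param protected_fraction,protected_weight Fraction of genes in the
#'   protected category (e.g. translation machinery) and their loss-weight
#'   multiplier.
#' @param split_prob,dup_prob Per-gene probabilities of a split (planted
#'   internal stop, re-annotated as two fragments) and a tandem
#'   duplication.
#' @param inversion_rate Expected number of inversions per descendant.
#' @param inversion_len_range Inversion length range in genes.
#' @param strand_flip_prob Per-gene probability of an isolated strand
#'   flip.
#' @param intergenic_decay Fractional shrinkage of spacers per descendant.
#' @return List of class `SimulationConfig`.
#' @export
sim_config <- function(seed = 1L, n_descendants = 10L,
                       n_ancestor_genes = 150L,
                       gene_length_mean = 900, gene_length_sd = 300,
                       intergenic_mean = 120, ancestor_gc = 50,
                       at_bias = 0.8, erosion_shape = 2,
                       erosion_mean = 0.08, loss_max = 0.25,
                       loss_midpoint_gc = 26, loss_scale = 4,
                       protected_fraction = 0.4, protected_weight = 0.1,
                       split_prob = 0.03, dup_prob = 0.02,
                       inversion_rate = 0.1,
                       inversion_len_range = c(2L, 6L),
                       strand_flip_prob = 0.002,
                       intergenic_decay = 0.3) {
  cfg <- as.list(environment())
  probs <- c(cfg$at_bias, cfg$loss_max, cfg$protected_fraction,
             cfg$protected_weight, cfg$split_prob, cfg$dup_prob,
             cfg$strand_flip_prob, cfg$intergenic_decay)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$erosion_mean < 0 || cfg$inversion_rate < 0)
    stop("rates must be non-negative")
  structure(cfg, class = "SimulationConfig")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

## per-base G+C probability whose induced sense-codon distribution hits
## the target gene %GC (stop codons are AT-rich, so the naive probability
## undershoots slightly)
.solve_base_gc <- function(target_gc) {
  codons <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                  paste0), c("A", "C", "G", "T"), paste0))
  sense <- setdiff(codons, STOP_CODONS)
  gc_count <- vapply(strsplit(sense, ""), function(b)
    sum(b %in% c("G", "C")), numeric(1))
  expected <- function(p) {
    bp <- c(A = (1 - p) / 2, C = p / 2, G = p / 2, T = (1 - p) / 2)
    pr <- vapply(strsplit(sense, ""), function(b) prod(bp[b]), numeric(1))
    pr <- pr / sum(pr)
    sum(pr * gc_count / 3) - target_gc / 100
  }
  stats::uniroot(expected, c(1e-4, 1 - 1e-4))$root
}

.sense_codon_probs <- function(p) {
  codons <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                  paste0), c("A", "C", "G", "T"), paste0))
  sense <- setdiff(codons, STOP_CODONS)
  bp <- c(A = (1 - p) / 2, C = p / 2, G = p / 2, T = (1 - p) / 2)
  pr <- vapply(strsplit(sense, ""), function(b) prod(bp[b]), numeric(1))
  list(codons = sense, probs = pr / sum(pr))
}

.random_bases <- function(n, gc) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate a synthetic ancestor genome and proteome
#'
#' Every gene is a valid ORF (ATG start, no internal stop, TAA stop) at
#' the configured %GC; genes carry stable names shared with their
#' descendant copies, as orthologs in annotated genomes do.
#'
#' @param cfg A `SimulationConfig`.
#' @return List with `genome` (a `GenomeRecord`) and `proteome`.
#' @export
generate_ancestor <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_ancestor_genes
  p <- .solve_base_gc(cfg$ancestor_gc)
  cp <- .sense_codon_probs(p)
  lens <- pmax(30L, round(stats::rnorm(n, cfg$gene_length_mean / 3,
                                       cfg$gene_length_sd / 3)))
  strands <- sample(c("+", "-"), n, replace = TRUE, prob = c(0.75, 0.25))
  gene_seqs <- vapply(lens, function(k) {
    paste0("ATG", paste(sample(cp$codons, k - 2L, replace = TRUE,
                               prob = cp$probs), collapse = ""), "TAA")
  }, character(1))
  spacer_lens <- stats::rpois(n, cfg$intergenic_mean)
  spacers <- vapply(spacer_lens, .random_bases, character(1),
                    gc = cfg$ancestor_gc / 100)
  pos <- 0L; rows <- vector("list", n)
  chunks <- character(2L * n)
  for (i in seq_len(n)) {
    chunks[2L * i - 1L] <- spacers[i]
    pos <- pos + nchar(spacers[i])
    glen <- nchar(gene_seqs[i])
    rows[[i]] <- data.frame(
      gene_id = sprintf("ANC_%04d", i), name = sprintf("gene%04d", i),
      kind = "CDS", start = pos, end = pos + glen, strand = strands[i],
      pseudo = FALSE, translation = "", stringsAsFactors = FALSE)
    chunks[2L * i] <- if (strands[i] == "-") revcomp(gene_seqs[i])
                      else gene_seqs[i]
    pos <- pos + glen
  }
  genome <- GenomeRecord("ANC", paste(chunks, collapse = ""),
                         do.call(rbind, rows),
                         organism = "synthetic free-living ancestor",
                         circular = TRUE)
  list(genome = genome,
       proteome = extract_proteome(genome)$proteome)
}

.mutate_orf <- function(seq, q, at_bias) {
  ## substitute with probability q per site, AT-biased, preserving the
  ## start/stop codons and rejecting substitutions that create an
  ## in-frame internal stop (the generator plants stops only on purpose)
  b <- strsplit(seq, "")[[1]]
  n <- length(b)
  core <- 4:(n - 3)
  hit <- core[stats::runif(length(core)) < q]
  if (length(hit)) {
    new <- ifelse(stats::runif(length(hit)) < at_bias,
                  sample(c("A", "T"), length(hit), replace = TRUE),
                  sample(c("G", "C"), length(hit), replace = TRUE))
    b[hit] <- new
    codon_start <- seq(4L, n - 6L, by = 3L)
    cods <- paste0(b[codon_start], b[codon_start + 1L], b[codon_start + 2L])
    bad <- which(cods %in% STOP_CODONS)
    orig <- strsplit(seq, "")[[1]]
    for (k in bad) {
      ix <- codon_start[k] + 0:2
      b[ix] <- orig[ix]
    }
  }
  paste(b, collapse = "")
}

.mutate_plain <- function(seq, q, at_bias) {
  if (!nzchar(seq)) return(seq)
  b <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(b)) < q)
  if (length(hit))
    b[hit] <- ifelse(stats::runif(length(hit)) < at_bias,
                     sample(c("A", "T"), length(hit), replace = TRUE),
                     sample(c("G", "C"), length(hit), replace = TRUE))
  paste(b, collapse = "")
}

#' Simulate reduced descendant genomes with a ground-truth ledger
#'
#' Applies, per descendant and in order: AT-biased substitution at a
#' gamma-distributed per-gene rate (one latent intensity couples %GC
#' erosion and identity decay), gene loss logistic in eroded %GC, gene
#' splitting by a planted internal stop, tandem duplication, isolated
#' strand flips, short inversions, and intergenic decay. Gene order is
#' otherwise preserved.
#'
#' @param ancestor Output of [generate_ancestor()].
#' @param cfg The `SimulationConfig` (the same used for the ancestor).
#' @return List with `genomes` (descendant `GenomeRecord`s) and `truth`
#'   (ledger: per-descendant lost/split/duplicated/inverted/flipped genes
#'   and a per-gene table of substitution counts, identity to ancestor
#'   and final %GC; plus the protected-category assignment).
#' @export
simulate_reduction <- function(ancestor, cfg) {
  set.seed(cfg$seed + 1000L)
  anc <- ancestor$genome
  n <- nrow(anc$genes)
  anc_seqs <- gene_sequence(anc)     # coding-strand sequences
  gene_ids <- anc$genes$gene_id
  protected <- stats::runif(n) < cfg$protected_fraction
  names(protected) <- gene_ids
  spacer_len0 <- stats::rpois(n, cfg$intergenic_mean)

  genomes <- list(); per_desc <- list()
  for (d in seq_len(cfg$n_descendants)) {
    did <- sprintf("D%02d", d)
    rates <- stats::rgamma(n, shape = cfg$erosion_shape,
                           rate = cfg$erosion_shape / max(cfg$erosion_mean,
                                                          1e-12))
    if (cfg$erosion_mean == 0) rates[] <- 0
    q <- 1 - exp(-rates)
    entries <- list()   # one per surviving gene copy, in order
    lost <- character(0); splits <- list(); dups <- character(0)
    flips <- character(0)
    pg <- vector("list", n)
    for (i in seq_len(n)) {
      seq0 <- anc_seqs[[i]]
      seq1 <- if (q[i] > 0) .mutate_orf(seq0, q[i], cfg$at_bias) else seq0
      b0 <- strsplit(seq0, "")[[1]]; b1 <- strsplit(seq1, "")[[1]]
      subs <- sum(b0 != b1)
      ident <- 100 * mean(b0 == b1)
      gcv <- gc_percent(seq1)
      pg[[i]] <- data.frame(gene_id = gene_ids[i], subs = subs,
                            identity = ident, gc = gcv,
                            protected = protected[i])
      w <- if (protected[i]) cfg$protected_weight else 1
      p_loss <- cfg$loss_max * w *
        stats::plogis((cfg$loss_midpoint_gc - gcv) / cfg$loss_scale)
      if (stats::runif(1) < p_loss) { lost <- c(lost, gene_ids[i]); next }
      strand <- anc$genes$strand[i]
      if (stats::runif(1) < cfg$strand_flip_prob) {
        strand <- if (strand == "+") "-" else "+"
        flips <- c(flips, gene_ids[i])
      }
      name <- anc$genes$name[i]
      if (stats::runif(1) < cfg$split_prob && nchar(seq1) >= 60L) {
        ncod <- nchar(seq1) / 3
        k <- floor(ncod / 3) + sample.int(max(1L, floor(ncod / 3)), 1L)
        f1 <- paste0(substr(seq1, 1L, 3L * (k - 1L)), "TAA")
        f2 <- substr(seq1, 3L * k + 1L, nchar(seq1))
        ids <- paste0(did, "_", gene_ids[i], c("_f1", "_f2"))
        splits[[gene_ids[i]]] <- ids
        entries[[length(entries) + 1L]] <- list(id = ids[1], name = name,
                                                seq = f1, strand = strand,
                                                spacer = spacer_len0[i])
        entries[[length(entries) + 1L]] <- list(id = ids[2], name = name,
                                                seq = f2, strand = strand,
                                                spacer = 0L)
      } else {
        entries[[length(entries) + 1L]] <- list(
          id = paste0(did, "_", gene_ids[i]), name = name, seq = seq1,
          strand = strand, spacer = spacer_len0[i])
        if (stats::runif(1) < cfg$dup_prob) {
          dups <- c(dups, gene_ids[i])
          entries[[length(entries) + 1L]] <- list(
            id = paste0(did, "_", gene_ids[i], "_d2"), name = name,
            seq = seq1, strand = strand, spacer = 5L)
        }
      }
    }
    ## short inversions: reverse a run of entries and flip strands
    inv <- list()
    n_inv <- stats::rpois(1, cfg$inversion_rate)
    if (n_inv > 0 && length(entries) > cfg$inversion_len_range[2] + 2L) {
      for (v in seq_len(n_inv)) {
        len <- sample(seq(cfg$inversion_len_range[1],
                          cfg$inversion_len_range[2]), 1L)
        st <- sample.int(length(entries) - len, 1L)
        seg <- st:(st + len - 1L)
        entries[seg] <- rev(entries[seg])
        for (s in seg)
          entries[[s]]$strand <- if (entries[[s]]$strand == "+") "-" else "+"
        inv[[length(inv) + 1L]] <- data.frame(
          start = st, length = len,
          gene_ids = paste(vapply(entries[seg], `[[`, "", "id"),
                           collapse = ";"))
      }
    }
    ## rebuild the genome sequence with decayed spacers
    pos <- 0L; rows <- list(); chunks <- character(0)
    for (e in entries) {
      sp_len <- round(e$spacer * (1 - cfg$intergenic_decay))
      sp <- .mutate_plain(.random_bases(sp_len, cfg$ancestor_gc / 100),
                          mean(q), cfg$at_bias)
      chunks <- c(chunks, sp)
      pos <- pos + nchar(sp)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = e$id, name = e$name, kind = "CDS", start = pos,
        end = pos + nchar(e$seq), strand = e$strand, pseudo = FALSE,
        translation = "", stringsAsFactors = FALSE)
      chunks <- c(chunks, if (e$strand == "-") revcomp(e$seq) else e$seq)
      pos <- pos + nchar(e$seq)
    }
    if (!length(rows)) {   # every gene lost: an empty replicon remains
      chunks <- .random_bases(max(1L, cfg$intergenic_mean), cfg$ancestor_gc / 100)
      rows <- list(anc$genes[0, ])
    }
    genomes[[did]] <- GenomeRecord(did, paste(chunks, collapse = ""),
                                   do.call(rbind, rows),
                                   organism = "synthetic descendant",
                                   circular = TRUE)
    per_desc[[did]] <- list(
      lost = lost, splits = splits, duplicated = dups, flipped = flips,
      inversions = if (length(inv)) do.call(rbind, inv) else NULL,
      per_gene = do.call(rbind, pg))
  }
  list(genomes = genomes,
       truth = list(per_descendant = per_desc, protected = protected,
                    ancestor_gene_ids = gene_ids))
}

#' Pan/core genome implied by the simulation truth ledger
#'
#' @param truth Truth ledger from [simulate_reduction()].
#' @return List with `pan` and `core` counts (ancestral gene families
#'   retained in at least one / in every descendant).
#' @export
truth_pan_core <- function(truth) {
  ids <- truth$ancestor_gene_ids
  lost <- lapply(truth$per_descendant, `[[`, "lost")
  present <- vapply(ids, function(g)
    vapply(lost, function(l) !(g %in% l), logical(1)),
    logical(length(lost)))
  if (is.null(dim(present))) present <- matrix(present, nrow = length(lost))
  list(pan = sum(colSums(present) >= 1L),
       core = sum(colSums(present) == length(lost)))
}

#' Simulate a strain-mixture read pileup
#'
#' Per-site allele counts are multinomial draws from the mixture of
#' strain genotypes with a uniform sequencing-error component; site depth
#' is Poisson around the target coverage.
#'
#' @param genome A `GenomeRecord` (the mapping reference).
#' @param strains List of `list(variants = data.frame(position, alt),
#'   frequency)`; frequencies must sum to 1, positions 0-based.
#' @param depth Mean coverage.
#' @param error_rate Per-base sequencing error probability.
#' @param seed Seed.
#' @param n_invariant Number of non-variant reference positions to
#'   include in the table.
#' @return List with `pileup` (data.frame in the pileup TSV layout) and
#'   `truth` (planted alternate frequency per variant site).
#' @export
simulate_pileup <- function(genome, strains, depth = 1000,
                            error_rate = 0.001, seed = 1L,
                            n_invariant = 100L) {
  set.seed(seed)
  freqs <- vapply(strains, `[[`, numeric(1), "frequency")
  if (abs(sum(freqs) - 1) > 1e-8) stop("strain frequencies must sum to 1")
  L <- nchar(genome$sequence)
  for (s in strains) {
    v <- s$variants
    if (is.null(v) || !nrow(v)) next
    if (any(v$position < 0 | v$position >= L))
      stop("variant outside genome bounds")
    if (anyDuplicated(v$position)) {
      dd <- v[v$position %in% v$position[duplicated(v$position)], ]
      if (any(tapply(dd$alt, dd$position, function(a)
        length(unique(a)) > 1L)))
        stop("conflicting variants at one position within a strain")
    }
  }
  var_pos <- sort(unique(unlist(lapply(strains, function(s)
    s$variants$position))))
  inv_pool <- setdiff(seq_len(L) - 1L, var_pos)
  inv_pos <- sort(sample(inv_pool, min(n_invariant, length(inv_pool))))
  positions <- sort(c(var_pos, inv_pos))
  bases <- c("A", "C", "G", "T")
  ref <- substring(genome$sequence, positions + 1L, positions + 1L)
  counts <- matrix(0L, length(positions), 4L,
                   dimnames = list(NULL, bases))
  truth_freq <- numeric(length(positions))
  truth_alt <- rep(NA_character_, length(positions))
  for (i in seq_along(positions)) {
    p <- stats::setNames(numeric(4), bases)
    for (s in strains) {
      v <- s$variants
      j <- if (!is.null(v) && nrow(v)) match(positions[i], v$position)
           else NA_integer_
      b <- if (!is.na(j)) v$alt[j] else ref[i]
      p[b] <- p[b] + s$frequency
      if (!is.na(j) && b != ref[i]) {
        truth_freq[i] <- truth_freq[i] + s$frequency
        truth_alt[i] <- b
      }
    }
    p <- p * (1 - error_rate) + (1 - p) * error_rate / 3
    p <- p / sum(p)
    counts[i, ] <- stats::rmultinom(1, stats::rpois(1, depth), p)
  }
  pileup <- data.frame(position = positions, ref = ref,
                       A = counts[, "A"], C = counts[, "C"],
                       G = counts[, "G"], T = counts[, "T"],
                       ins = 0L, del = 0L,
                       mean_qual = pmax(25, round(stats::rnorm(
                         length(positions), 30, 1), 1)))
  truth <- data.frame(position = positions, ref = ref,
                      alt = truth_alt, planted_freq = truth_freq)
  truth <- truth[!is.na(truth$alt), ]
  rownames(truth) <- NULL
  list(pileup = pileup, truth = truth)
}

#' Simulate overdispersed expression counts with known tiers
#'
#' Genes are assigned expression tiers; counts are negative-binomial
#' around tier-specific means calibrated on the logCPM scale against the
#' supplied total library size (the library includes host reads, so
#' endosymbiont genes occupy only a small fraction of it, as in whole-body
#' RNA-seq).
#'
#' @param gene_ids Character vector of gene ids.
#' @param n_samples Number of samples.
#' @param library_size Total library size per sample (reads).
#' @param dispersion Negative-binomial dispersion (`size = 1/dispersion`).
#' @param tier_fractions Named fractions for `low`, `mid`, `high`
#'   (sum to 1).
#' @param tier_logcpm Planted mean logCPM per tier.
#' @param seed Seed.
#' @return List with `table` (an `ExpressionTable` whose `lib_sizes` are
#'   the supplied totals) and `truth` (planted tier and mean logCPM per
#'   gene).
#' @export
simulate_counts <- function(gene_ids, n_samples = 2L, library_size = 5e7,
                            dispersion = 0.05,
                            tier_fractions = c(low = 0.6, mid = 0.3,
                                               high = 0.1),
                            tier_logcpm = c(low = 7, mid = 10, high = 12),
                            seed = 1L) {
  set.seed(seed)
  if (abs(sum(tier_fractions) - 1) > 1e-8)
    stop("tier fractions must sum to 1")
  n <- length(gene_ids)
  tiers <- sample(names(tier_fractions), n, replace = TRUE,
                  prob = tier_fractions)
  mu_cpm <- 2 ^ tier_logcpm[tiers]
  mu <- mu_cpm / 1e6 * library_size
  counts <- matrix(0L, n, n_samples,
                   dimnames = list(gene_ids,
                                   sprintf("S%02d", seq_len(n_samples))))
  for (j in seq_len(n_samples))
    counts[, j] <- stats::rnbinom(n, mu = mu,
                                  size = if (dispersion > 0)
                                    1 / dispersion else 1e8)
  list(table = ExpressionTable(counts,
                               lib_sizes = rep(library_size, n_samples)),
       truth = data.frame(gene_id = gene_ids, tier = tiers,
                          planted_logcpm = unname(tier_logcpm[tiers])))
}

#' Plant a linear %GC-identity coupling (regression ground truth)
#'
#' Generates a per-gene table where homolog identity is exactly linear in
#' gene %GC and relative length plus Gaussian noise, for testing that the
#' regression recovers a known generative slope.
#'
#' @param n Number of genes.
#' @param slope Identity change per %GC unit.
#' @param intercept Intercept.
#' @param len_coef Identity change per relative-length unit.
#' @param gc_mean,gc_sd %GC distribution.
#' @param len_mean,len_sd Relative-length distribution.
#' @param noise_sd Residual SD.
#' @param seed Seed.
#' @return List with `table` (data.frame `gene_id, gc, relative_length,
#'   identity`) and `truth` (the generative coefficients).
#' @export
simulate_identity_table <- function(n = 200L, slope = 3.12,
                                    intercept = -30, len_coef = 0.05,
                                    gc_mean = 26, gc_sd = 5,
                                    len_mean = 96, len_sd = 12,
                                    noise_sd = 5, seed = 1L) {
  set.seed(seed)
  gc <- stats::rnorm(n, gc_mean, gc_sd)
  rel <- stats::rnorm(n, len_mean, len_sd)
  identity <- intercept + slope * gc + len_coef * rel +
    stats::rnorm(n, 0, noise_sd)
  list(table = data.frame(gene_id = sprintf("g%04d", seq_len(n)), gc = gc,
                          relative_length = rel, identity = identity),
       truth = list(slope = slope, intercept = intercept,
                    len_coef = len_coef, noise_sd = noise_sd))
}

#' Rearrange a reference order to plant known synteny breaks
#'
#' Cuts the reference gene order into `k + 1` segments (each at least
#' `min_segment` genes) and rearranges the segments so that a collinear
#' array scanned against the new order contains exactly `k`
#' discontinuities, i.e. `k + 1` syntenic blocks by construction.
#'
#' @param ref_ids Reference gene ids in original (collinear) order.
#' @param k Number of breaks to plant.
#' @param min_segment Minimum segment length (default 3).
#' @return Character vector: the rearranged reference order.
#' @export
plant_synteny_breaks <- function(ref_ids, k, min_segment = 3L) {
  n <- length(ref_ids)
  if (k == 0L) return(ref_ids)
  if ((k + 1L) * min_segment > n) stop("too many breaks for this order")
  cuts <- round(seq(0, n, length.out = k + 2L))
  segs <- lapply(seq_len(k + 1L), function(j)
    ref_ids[(cuts[j] + 1L):cuts[j + 1L]])
  ## segments are laid down in reverse order; with segments of >= 3 genes
  ## no two array-consecutive segments remain reference-adjacent
  unlist(rev(segs), use.names = FALSE)
}
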