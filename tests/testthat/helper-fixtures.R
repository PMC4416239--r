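# Shared fixtures and independent oracles. Oracles are deliberately written
# as brute-force re-derivations (enumeration, linear-space products,
# quadratic scans), independent of the package's code paths.

.fixture_env <- new.env(parent = emptyenv())

# One full synthetic study, simulated once per test run and shared.
shared_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    cfg <- simulation_config(seed = 101L)
    sim <- simulate_panel(cfg)
    panel <- read_population_vcf(sim$vcf)
    popmap <- read_population_map(sim$popmap)
    catalog <- build_catalog(panel, popmap = popmap)
    truth <- sim$truth[sim$truth$class != "non_rra", , drop = FALSE]
    .fixture_env$sim <- list(cfg = cfg, sim = sim, panel = panel,
                             popmap = popmap, catalog = catalog,
                             truth = truth)
  }
  .fixture_env$sim
}

locus_key <- function(d) paste(d$chrom, d$pos)

# Write a small multi-sample VCF from a genotype-code matrix
# (0/1/2/NA per locus x sample).
write_toy_vcf <- function(records, codes, path,
                          sample_ids = sprintf("S%02d", seq_len(ncol(codes)))) {
  gt <- matrix("1/1", nrow = nrow(codes), ncol = ncol(codes))
  gt[codes == 0L] <- "0/0"
  gt[codes == 1L] <- "0/1"
  gt[is.na(codes)] <- "./."
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample_ids), collapse = "\t"))
  body <- vapply(seq_len(nrow(records)), function(i) {
    paste(c(records$chrom[i], records$pos[i], ".", records$ref[i],
            records$alt[i], ".", "PASS", ".", "GT", gt[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

# Write a SAM file from explicit alignment rows (for filter-contract tests).
write_toy_sam <- function(reads, contigs, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs))
  body <- vapply(seq_len(nrow(reads)), function(i) {
    paste(reads$qname[i], reads$flag[i], reads$chrom[i], reads$pos[i],
          reads$mapq[i], reads$cigar[i], "*", 0L, 0L, reads$seq[i],
          reads$qual[i], sep = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

# Oracle: RRA class by scanning the genotype vector for reference-carrying
# genotypes (codes 0 and 1 carry the reference allele; NA does not count).
oracle_classify <- function(codes) {
  codes <- codes[!is.na(codes)]
  has_homref <- any(codes == 0L)
  has_het <- any(codes == 1L)
  if (!has_homref && !has_het) return("A")
  if (!has_homref) return("B")
  if (has_het) return("C")
  "U"
}

# Oracle: exact two-sided Fisher p by explicit enumeration of all tables
# with the observed margins, with probabilities from binomial coefficients.
# Ties in "at least as extreme" use the customary 1e-7 relative tolerance.
oracle_fisher <- function(a, b, c, d) {
  n <- a + b + c + d
  if (n == 0) return(1)
  m <- a + b
  k <- a + c
  support <- max(0, k - (n - m)):min(k, m)
  logp <- lchoose(m, support) + lchoose(n - m, k - support) - lchoose(n, k)
  probs <- exp(logp)
  p_obs <- probs[match(a, support)]
  min(sum(probs[probs <= p_obs * (1 + 1e-7)]), 1)
}

# Oracle: per-read probabilities multiplied in linear space (no logs).
oracle_likelihoods_linear <- function(support, qual, type) {
  e <- 10^(-qual / 10)
  mism <- if (type == "SNV") e / 3 else e
  p_ref <- ifelse(support == "ref", 1 - e, mism)
  p_alt <- ifelse(support == "alt", 1 - e, mism)
  c(ref_ref = prod(p_ref),
    ref_alt = prod(p_ref / 2 + p_alt / 2),
    alt_alt = prod(p_alt))
}

# Oracle: quadratic interval scan (0-based half-open query vs track).
oracle_overlap <- function(q_chrom, q_start, q_end, track) {
  hits <- character()
  for (j in seq_len(nrow(track))) {
    if (track$chrom[j] == q_chrom &&
        track$start[j] < q_end && q_start < track$end[j]) {
      hits <- c(hits, track$name[j])
    }
  }
  sort(unique(hits))
}

# Pileup column built directly from planted observations (no SAM round trip).
make_column <- function(support, qual, type = "SNV") {
  col <- data.frame(qname = sprintf("r%03d", seq_along(support)),
                    support = support, base_quality = qual,
                    mapping_quality = rep(60L, length(support)),
                    stringsAsFactors = FALSE)
  attr(col, "type") <- type
  class(col) <- c("pileup_column", "data.frame")
  col
}
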