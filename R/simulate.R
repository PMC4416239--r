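## synthetic_data: generate every input the pipeline consumes at toy scale
## with planted ground truth — a population panel VCF emulating the 1000
## Genomes phase-1 structure (1092 individuals, four macro populations),
## aligned reads with planted genotypes, and annotation tracks with planted
## overlaps. All randomness flows from the single seed in the config.

#' Simulation configuration
#'
#' Defaults emulate the study conditions of the source panel: 1092 samples
#' split across the four macro populations (AFR/AMR/ASN/EUR at the phase-1
#' proportions), class-B loci carrying 1-10 heterozygotes, class-C loci with
#' 1-3 hom-ref plus 1-5 het carriers (reference AF well below the 1%
#' threshold), non-RRA loci at reference AF >= 0.05, and sequencing at 40x
#' with uniform Q30 bases.
#'
#' @param n_samples number of panel samples.
#' @param pop_sizes named integer vector of per-population sample counts;
#'   must sum to `n_samples`.
#' @param n_loci named integer vector: planted locus counts per class
#'   (A, B, C, non_rra).
#' @param type_fractions named numeric vector over SNV/INS/DEL; must sum
#'   to 1.
#' @param b_het_range,c_homref_range,c_het_range planted genotype-count
#'   ranges for class B and C loci.
#' @param af_threshold catalog AF threshold the planted classes must respect.
#' @param read_depth,base_quality,read_length read-simulation parameters.
#' @param n_somatic number of somatic RRA loci planted in a tumor/normal
#'   pair.
#' @param contig_lengths named integer vector of reference contig lengths.
#' @param seed master seed; fully determines every simulated artifact.
#' @return list of class `rra_sim_config`.
#' @export
simulation_config <- function(n_samples = 1092L,
                              pop_sizes = c(AFR = 246L, AMR = 181L,
                                            ASN = 286L, EUR = 379L),
                              n_loci = c(A = 20L, B = 40L, C = 10L,
                                         non_rra = 30L),
                              type_fractions = c(SNV = 0.7, INS = 0.15,
                                                 DEL = 0.15),
                              b_het_range = c(1L, 10L),
                              c_homref_range = c(1L, 3L),
                              c_het_range = c(1L, 5L),
                              af_threshold = 0.01,
                              read_depth = 40L,
                              base_quality = 30L,
                              read_length = 100L,
                              n_somatic = 3L,
                              contig_lengths = c(chr1 = 30000L,
                                                 chr2 = 20000L),
                              seed = 1L) {
  if (sum(pop_sizes) != n_samples) {
    stop("pop_sizes must sum to n_samples")
  }
  if (abs(sum(type_fractions) - 1) > 1e-9) {
    stop("type_fractions must sum to 1")
  }
  if (n_loci[["B"]] > 0 && (n_samples < 1L || b_het_range[2] < 1L)) {
    stop("class B loci need at least one sample and one heterozygote")
  }
  if (n_loci[["C"]] > 0 && n_samples < c_homref_range[2] + c_het_range[2]) {
    stop("class C loci need more samples than planted carriers")
  }
  worst_c <- (2 * c_homref_range[2] + c_het_range[2]) / (2 * n_samples)
  worst_b <- b_het_range[2] / (2 * n_samples)
  if (max(worst_c, worst_b) >= af_threshold) {
    stop("planted carrier ranges violate the AF threshold: infeasible config")
  }
  structure(list(
    n_samples = as.integer(n_samples), pop_sizes = pop_sizes,
    n_loci = n_loci, type_fractions = type_fractions,
    b_het_range = b_het_range, c_homref_range = c_homref_range,
    c_het_range = c_het_range, af_threshold = af_threshold,
    read_depth = as.integer(read_depth),
    base_quality = as.integer(base_quality),
    read_length = as.integer(read_length),
    n_somatic = as.integer(n_somatic),
    contig_lengths = contig_lengths, seed = as.integer(seed)
  ), class = "rra_sim_config")
}

#' Simulate a random reference genome
#'
#' @param config an `rra_sim_config` (contig lengths and seed).
#' @return `Biostrings::DNAStringSet`, one contig per `contig_lengths` entry.
#' @export
simulate_reference <- function(config) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  seqs <- vapply(config$contig_lengths, function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
  ref <- Biostrings::DNAStringSet(seqs)
  names(ref) <- names(config$contig_lengths)
  ref
}

## Deterministic locus positions: a grid with 300 bp spacing, 500 bp margins,
## so read windows and 100 bp context windows never interfere.
.locus_grid <- function(contig_lengths) {
  do.call(rbind, lapply(names(contig_lengths), function(chrom) {
    pos <- seq(500L, contig_lengths[[chrom]] - 500L, by = 300L)
    data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
  }))
}

## Alleles at a position, consistent with the reference sequence.
.draw_alleles <- function(reference, chrom, pos, type) {
  base_at <- function(p) as.character(Biostrings::subseq(reference[[chrom]],
                                                         start = p, width = 1))
  ref_base <- base_at(pos)
  if (type == "SNV") {
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref_base), 1)
    return(c(ref_base, alt))
  }
  len <- sample(1:3, 1)
  if (type == "INS") {
    ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
    return(c(ref_base, paste0(ref_base, ins)))
  }
  del <- as.character(Biostrings::subseq(reference[[chrom]], start = pos,
                                         width = len + 1L))
  c(del, ref_base)
}

#' Simulate a population panel with planted RRA classes
#'
#' Draws loci on a fixed grid over the reference, plants genotype vectors
#' realizing each locus's class (A: no reference-carrying genotype; B: 1-10
#' heterozygotes; C: both hom-ref and het carriers; non-RRA: reference AF
#' >= 0.05 under approximate Hardy-Weinberg counts), and writes the panel
#' VCF, the sample-to-population map, the reference FASTA and a truth table.
#'
#' @param config an `rra_sim_config`.
#' @param dir output directory (created if needed).
#' @return list: `vcf`, `popmap`, `fasta`, `truth_tsv` (paths), `reference`
#'   (DNAStringSet), `popmap_vec` (named vector), `truth` (data.frame: chrom,
#'   pos, ref, alt, type, class, n_homref, n_het, n_homalt, ref_af, pops).
#' @export
simulate_panel <- function(config, dir = tempfile("rra_sim_")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reference <- simulate_reference(config)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 1L)

  n <- config$n_samples
  sample_ids <- sprintf("S%04d", seq_len(n))
  popmap <- rep(names(config$pop_sizes), config$pop_sizes)
  names(popmap) <- sample_ids

  classes <- rep(names(config$n_loci), config$n_loci)
  n_total <- length(classes)
  grid <- .locus_grid(config$contig_lengths)
  if (n_total > nrow(grid)) stop("too many loci for the configured contigs")
  sel <- sort(sample.int(nrow(grid), n_total))
  loci <- grid[sel, , drop = FALSE]
  loci$class <- sample(classes)   # shuffle classes over positions
  loci$type <- sample(names(config$type_fractions), n_total, replace = TRUE,
                      prob = config$type_fractions)

  gt_mat <- matrix("1/1", nrow = n_total, ncol = n)
  truth <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    al <- .draw_alleles(reference, loci$chrom[i], loci$pos[i], loci$type[i])
    cls <- loci$class[i]
    n_homref <- 0L; n_het <- 0L
    if (cls == "B") {
      n_het <- sample(config$b_het_range[1]:config$b_het_range[2], 1)
    } else if (cls == "C") {
      n_homref <- sample(config$c_homref_range[1]:config$c_homref_range[2], 1)
      n_het <- sample(config$c_het_range[1]:config$c_het_range[2], 1)
    } else if (cls == "non_rra") {
      af <- stats::runif(1, 0.1, 0.9)
      n_homref <- max(1L, round(af^2 * n))
      n_het <- round(2 * af * (1 - af) * n)
    }
    carriers <- sample.int(n, n_homref + n_het)
    if (n_homref > 0L) gt_mat[i, carriers[seq_len(n_homref)]] <- "0/0"
    if (n_het > 0L) gt_mat[i, carriers[n_homref + seq_len(n_het)]] <- "0/1"
    ref_af <- (2 * n_homref + n_het) / (2 * n)
    pops <- sort(unique(popmap[carriers]))
    truth[[i]] <- data.frame(
      chrom = loci$chrom[i], pos = loci$pos[i],
      ref = al[1], alt = al[2], type = loci$type[i],
      class = ifelse(cls == "non_rra", "non_rra", cls),
      n_homref = n_homref, n_het = n_het,
      n_homalt = n - n_homref - n_het,
      ref_af = ref_af,
      pops = paste(pops, collapse = ","),
      stringsAsFactors = FALSE
    )
  }
  truth <- do.call(rbind, truth)

  fasta <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(reference, fasta)
  popmap_path <- file.path(dir, "popmap.tsv")
  writeLines(c("sample_id\tpopulation",
               paste(sample_ids, popmap, sep = "\t")), popmap_path)
  truth_tsv <- file.path(dir, "truth.tsv")
  utils::write.table(truth, truth_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  vcf <- file.path(dir, "panel.vcf")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=rrascan_simulate_panel",
    sprintf("##contig=<ID=%s,length=%d>", names(config$contig_lengths),
            config$contig_lengths),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  )
  body <- vapply(seq_len(n_total), function(i) {
    paste(c(truth$chrom[i], truth$pos[i], ".", truth$ref[i], truth$alt[i],
            ".", "PASS", ".", "GT", gt_mat[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), vcf)

  list(vcf = vcf, popmap = popmap_path, fasta = fasta, truth_tsv = truth_tsv,
       reference = reference, popmap_vec = popmap, truth = truth,
       config = config, dir = dir)
}

#' Simulate aligned reads carrying planted genotypes
#'
#' Generates `depth` spanning reads per locus: homozygous genotypes emit one
#' allele only; heterozygotes draw each read's allele as a fair coin
#' (binomial(depth, 0.5)). Reads have fixed length, uniform base quality, and
#' valid CIGARs (`<n>M` for SNV-allele and reference reads, with an I or D op
#' at the event for indel-allele reads). Output is a coordinate-sorted SAM
#' file.
#'
#' @param reference `DNAStringSet` (or FASTA path).
#' @param genotypes data.frame: chrom, pos, ref, alt, type, gt — one row per
#'   locus, gt in "0/0", "0/1", "1/1" (0 = the `ref` allele).
#' @param path output SAM path.
#' @param depth,base_quality,read_length simulation parameters.
#' @param seed integer seed (byte-identical output under the same seed).
#' @param sample_id read-group sample name.
#' @return `path`, invisibly.
#' @export
simulate_reads <- function(reference, genotypes, path, depth = 40L,
                           base_quality = 30L, read_length = 100L,
                           seed = 1L, sample_id = "sample") {
  if (is.character(reference)) reference <- read_fasta(reference)
  bad <- !genotypes$chrom %in% names(reference)
  if (any(bad)) stop("locus outside reference: ", genotypes$chrom[bad][1])
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  qual_str <- strrep(intToUtf8(base_quality + 33L), read_length)
  recs <- vector("list", nrow(genotypes))
  for (i in seq_len(nrow(genotypes))) {
    g <- genotypes[i, ]
    if (g$pos + nchar(g$ref) + 10L > length(reference[[g$chrom]]) ||
        g$pos <= read_length) {
      stop("locus too close to a contig edge for spanning reads: ",
           g$chrom, ":", g$pos)
    }
    n_ref <- switch(g$gt,
                    "0/0" = depth,
                    "1/1" = 0L,
                    "0/1" = stats::rbinom(1, depth, 0.5),
                    stop("unsupported planted genotype: ", g$gt))
    is_ref <- c(rep(TRUE, n_ref), rep(FALSE, depth - n_ref))
    event_len <- abs(nchar(g$alt) - nchar(g$ref))
    # leftmost start such that the event plus 5 bp flank is inside the read
    min_start <- g$pos - read_length + nchar(g$ref) + 5L + event_len
    starts <- sample(seq.int(max(1L, min_start), g$pos - 5L), depth,
                     replace = TRUE)
    for (r in seq_len(depth)) {
      st <- starts[r]
      left <- as.character(Biostrings::subseq(reference[[g$chrom]],
                                              start = st, end = g$pos))
      if (is_ref[r]) {
        # the reference allele IS the reference genome: a plain genomic read
        seq_r <- as.character(Biostrings::subseq(reference[[g$chrom]],
                                                 start = st,
                                                 width = read_length))
        cigar <- paste0(read_length, "M")
      } else if (g$type == "SNV") {
        seq_r <- as.character(Biostrings::subseq(reference[[g$chrom]],
                                                 start = st,
                                                 width = read_length))
        substr(seq_r, g$pos - st + 1L, g$pos - st + 1L) <- g$alt
        cigar <- paste0(read_length, "M")
      } else if (g$type == "INS") {
        ins <- substr(g$alt, 2, nchar(g$alt))
        lead_len <- nchar(left)
        tail_len <- read_length - lead_len - nchar(ins)
        seq_r <- paste0(left, ins, as.character(Biostrings::subseq(
          reference[[g$chrom]], start = g$pos + 1L, width = tail_len)))
        cigar <- sprintf("%dM%dI%dM", lead_len, nchar(ins), tail_len)
      } else { # DEL: alt is the anchor base, ref spans the deleted bases
        dlen <- nchar(g$ref) - 1L
        lead_len <- nchar(left)
        tail_len <- read_length - lead_len
        seq_r <- paste0(left, as.character(Biostrings::subseq(
          reference[[g$chrom]], start = g$pos + 1L + dlen,
          width = tail_len)))
        cigar <- sprintf("%dM%dD%dM", lead_len, dlen, tail_len)
      }
      recs[[i]] <- c(recs[[i]], paste(
        sprintf("rd_%s_%d_%d", gsub("[^A-Za-z0-9]", "", g$chrom), g$pos, r),
        0L, g$chrom, st, 60L, cigar, "*", 0L, 0L, seq_r, qual_str,
        sep = "\t"))
    }
  }
  body <- unlist(recs)
  # coordinate sort: contig order as in the reference, then leftmost position
  f <- strsplit(body, "\t")
  chrom <- vapply(f, `[`, character(1), 3L)
  posn <- as.integer(vapply(f, `[`, character(1), 4L))
  body <- body[order(match(chrom, names(reference)), posn)]
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(reference),
                   Biostrings::width(reference)),
           sprintf("@RG\tID:%s\tSM:%s", sample_id, sample_id))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Simulate annotation tracks with planted overlaps
#'
#' Builds toy GENCODE-like and ENCODE-like interval tracks, a per-base GERP
#' RS bedGraph, a gene model, GAD/OMIM/RegulomeDB/consequence tables and a
#' uniform mappability track, each planted over a recorded subset of catalog
#' loci so round-trip tests can check the annotator against truth.
#'
#' @param truth locus table (chrom, pos, ref, alt, type), e.g. the RRA rows
#'   of [simulate_panel()]'s truth.
#' @param config an `rra_sim_config` (seed, contig lengths).
#' @return list of data.frames — gencode, encode, gene_model (interval
#'   tracks), gerp, mappability (score tracks), gad, omim, regdb,
#'   consequence (tables) — plus `planted`: per-locus truth columns (biotype,
#'   encode_elements, gerp_rs, gerp_pass, gene, gad_classes, omim,
#'   regdb_score, consequence).
#' @export
simulate_tracks <- function(truth, config) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 2L)
  n <- nrow(truth)
  spans <- vcf_span(truth$pos, truth$ref,
                    vapply(strsplit(truth$alt, ","), `[`, character(1), 1L))
  biotypes <- c("protein_coding", "lincRNA", "antisense",
                "processed_transcript", "pseudogene")
  planted_bio <- sample(c(biotypes, NA), n, replace = TRUE,
                        prob = c(rep(0.5 / 5, 5), 0.5))
  gencode <- data.frame(
    chrom = truth$chrom[!is.na(planted_bio)],
    start = spans$start[!is.na(planted_bio)] - 20L,
    end = spans$end[!is.na(planted_bio)] + 20L,
    name = planted_bio[!is.na(planted_bio)],
    stringsAsFactors = FALSE
  )
  elements <- c("TFP", "DHS", "enhancer")
  enc_flags <- matrix(stats::runif(n * 3) < 0.3, nrow = n,
                      dimnames = list(NULL, elements))
  enc_rows <- which(enc_flags, arr.ind = TRUE)
  encode <- data.frame(
    chrom = truth$chrom[enc_rows[, 1]],
    start = spans$start[enc_rows[, 1]] - 10L,
    end = spans$end[enc_rows[, 1]] + 10L,
    name = elements[enc_rows[, 2]],
    stringsAsFactors = FALSE
  )
  encode <- encode[order(encode$chrom, encode$start, encode$name), ,
                   drop = FALSE]
  rownames(encode) <- NULL

  # per-base GERP RS over each affected span (plus one flank base): roughly
  # a third pass (RS 2.5), a third sit exactly at the cutoff (RS 2.0, which
  # must fail the strict rule), a third clearly fail (RS 0.5)
  rs_value <- sample(c(2.5, 2.0, 0.5), n, replace = TRUE)
  gerp <- data.frame(
    chrom = truth$chrom,
    start = spans$start - 1L,
    end = spans$end + 1L,
    score = rs_value,
    stringsAsFactors = FALSE
  )
  gerp_pass <- rs_value > 2

  gene <- sprintf("GENE%03d", seq_len(n))
  has_gene <- planted_bio %in% "protein_coding"
  gene[!has_gene] <- NA
  gene_model <- data.frame(
    chrom = truth$chrom[has_gene],
    start = spans$start[has_gene] - 50L,
    end = spans$end[has_gene] + 50L,
    name = gene[has_gene],
    stringsAsFactors = FALSE
  )
  gad_classes_all <- c("CANCER", "IMMUNE", "CARDIOVASCULAR", "PSYCH",
                       "METABOLIC", "NEUROLOGICAL")
  gad_rows <- list()
  gad_planted <- rep("", n)
  for (i in which(has_gene)) {
    k <- sample(0:2, 1)
    if (k > 0) {
      cls <- sample(gad_classes_all, k)
      gad_rows[[length(gad_rows) + 1L]] <- data.frame(
        gene_id = gene[i], disease_class = cls, association = "Y",
        stringsAsFactors = FALSE)
      gad_planted[i] <- paste(sort(cls), collapse = ",")
    }
    # a negative-association record that must be ignored
    gad_rows[[length(gad_rows) + 1L]] <- data.frame(
      gene_id = gene[i], disease_class = "AGING", association = "N",
      stringsAsFactors = FALSE)
  }
  gad <- if (length(gad_rows)) do.call(rbind, gad_rows) else
    data.frame(gene_id = character(), disease_class = character(),
               association = character())
  omim_genes <- gene[has_gene & stats::runif(n) < 0.3]
  omim <- data.frame(gene_id = omim_genes[!is.na(omim_genes)],
                     stringsAsFactors = FALSE)
  regdb_score <- sample(1:6, n, replace = TRUE)
  regdb <- data.frame(chrom = truth$chrom, pos = truth$pos,
                      score = regdb_score, stringsAsFactors = FALSE)
  consequences <- c("missense", "nonsense", "frameshift", "splicing",
                    "synonymous", "non_exonic")
  cons <- ifelse(has_gene, sample(consequences, n, replace = TRUE),
                 "non_exonic")
  alt1 <- vapply(strsplit(truth$alt, ","), `[`, character(1), 1L)
  consequence <- data.frame(chrom = truth$chrom, pos = truth$pos,
                            ref = truth$ref, alt = alt1,
                            consequence = cons, stringsAsFactors = FALSE)
  mappability <- data.frame(
    chrom = names(config$contig_lengths),
    start = 0L,
    end = unname(config$contig_lengths),
    score = 1.0,
    stringsAsFactors = FALSE
  )
  planted <- data.frame(
    chrom = truth$chrom, pos = truth$pos,
    biotype = ifelse(is.na(planted_bio), "", planted_bio),
    encode_elements = apply(enc_flags, 1, function(f)
      paste(sort(elements[f]), collapse = ",")),
    gerp_rs = rs_value, gerp_pass = gerp_pass,
    gene = ifelse(is.na(gene), "", gene),
    gad_classes = gad_planted,
    omim = gene %in% omim$gene_id & !is.na(gene),
    regdb_score = regdb_score,
    consequence = cons,
    stringsAsFactors = FALSE
  )
  list(gencode = gencode, encode = encode, gene_model = gene_model,
       gerp = gerp, mappability = mappability, gad = gad, omim = omim,
       regdb = regdb, consequence = consequence, planted = planted)
}
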