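## genotyper: forced-allele diploid genotyping at catalog loci from aligned
## reads. Genotype likelihoods are computed only over the supplied ref/alt
## allele pair and a record is emitted at every site (no allele discovery),
## so loci where the reference allele is the rare one are never skipped.

## ---- CIGAR walking -------------------------------------------------------

## Expand a CIGAR string into (length, op) pairs.
.parse_cigar <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  list(len = lens, op = ops)
}

## Aligned base (and its quality) of one read at a 1-based reference
## position. Returns NULL when the position is not covered by an aligned
## (M/=/X) base.
.read_base_at <- function(read_pos, cigar, seq, qual, target) {
  cg <- .parse_cigar(cigar)
  rpos <- read_pos        # next reference position to consume
  qpos <- 1L              # next query position to consume
  for (k in seq_along(cg$op)) {
    op <- cg$op[k]; len <- cg$len[k]
    if (op %in% c("M", "=", "X")) {
      if (target >= rpos && target < rpos + len) {
        off <- qpos + (target - rpos)
        return(list(base = substr(seq, off, off),
                    qual = utf8ToInt(substr(qual, off, off)) - 33L))
      }
      rpos <- rpos + len; qpos <- qpos + len
    } else if (op %in% c("D", "N")) {
      if (target >= rpos && target < rpos + len) return(NULL)
      rpos <- rpos + len
    } else if (op %in% c("I", "S")) {
      qpos <- qpos + len
    }
  }
  NULL
}

## Indel support of one read at a locus. For an insertion of `event_len`
## bases after `pos`, a read supports "alt" when its CIGAR carries an I op of
## that length at the junction after pos, and "ref" when it aligns straight
## through pos and pos+1. For a deletion of `event_len` bases starting at
## pos+1, "alt" means a D op spanning exactly that range; "ref" means aligned
## bases across the span. Reads that do not span the event are uninformative
## (NULL). The observation quality is the minimum base quality over the event
## plus one flanking base on each side (within the read).
.read_indel_support <- function(read_pos, cigar, seq, qual, pos, type,
                                event_len) {
  cg <- .parse_cigar(cigar)
  rpos <- read_pos
  qpos <- 1L
  anchor_q <- NA_integer_   # query offset of the aligned base at `pos`
  ins_here <- 0L            # length of I op at the junction after pos
  del_here <- 0L            # length of D op starting at pos+1
  aligned_through <- FALSE  # read aligns M across the event span
  last_ref_end <- rpos - 1L
  for (k in seq_along(cg$op)) {
    op <- cg$op[k]; len <- cg$len[k]
    if (op %in% c("M", "=", "X")) {
      if (pos >= rpos && pos < rpos + len) anchor_q <- qpos + (pos - rpos)
      if (type == "DEL") {
        if (pos >= rpos && pos + event_len < rpos + len) aligned_through <- TRUE
      } else {
        # insertion: ref support = M covering both pos and pos + 1
        if (pos >= rpos && pos + 1L < rpos + len) aligned_through <- TRUE
      }
      rpos <- rpos + len; qpos <- qpos + len
      last_ref_end <- rpos - 1L
    } else if (op == "I") {
      if (rpos == pos + 1L) ins_here <- len
      qpos <- qpos + len
    } else if (op %in% c("D", "N")) {
      if (op == "D" && rpos == pos + 1L) del_here <- len
      rpos <- rpos + len
    } else if (op == "S") {
      qpos <- qpos + len
    }
  }
  if (is.na(anchor_q)) return(NULL)
  qual_at <- function(off) {
    off <- off[off >= 1L & off <= nchar(qual)]
    if (!length(off)) return(NA_integer_)
    min(vapply(off, function(o) utf8ToInt(substr(qual, o, o)) - 33L,
               integer(1)))
  }
  if (type == "INS") {
    if (ins_here == event_len) {
      return(list(support = "alt",
                  qual = qual_at(seq.int(anchor_q, anchor_q + event_len + 1L))))
    }
    if (ins_here == 0L && aligned_through) {
      return(list(support = "ref", qual = qual_at(c(anchor_q, anchor_q + 1L))))
    }
    if (ins_here > 0L) {
      return(list(support = "other",
                  qual = qual_at(seq.int(anchor_q, anchor_q + ins_here + 1L))))
    }
    return(NULL)  # does not span the junction
  }
  # DEL
  if (del_here == event_len) {
    return(list(support = "alt", qual = qual_at(c(anchor_q, anchor_q + 1L))))
  }
  if (del_here == 0L && aligned_through) {
    return(list(support = "ref",
                qual = qual_at(seq.int(anchor_q, anchor_q + event_len + 1L))))
  }
  if (del_here > 0L) {
    return(list(support = "other", qual = qual_at(c(anchor_q, anchor_q + 1L))))
  }
  NULL
}

## ---- pileup --------------------------------------------------------------

#' Pileup of read observations at a forced-allele locus
#'
#' Collects, for every read overlapping the locus, which candidate allele it
#' supports (`ref`, `alt` or `other`) together with the observation's base
#' quality and the read's mapping quality. SNV support comes from the aligned
#' base at POS; insertion/deletion support from the CIGAR at the event
#' junction (reads not spanning the event are uninformative and excluded).
#' Unmapped reads, secondary/supplementary alignments, duplicates, reads
#' below `min_mapping_quality` and observations below `min_base_quality` are
#' excluded. When both mates of a pair overlap the locus the observation with
#' the higher base quality is kept once.
#'
#' @param reads data.frame of alignments from [read_sam()].
#' @param chrom,pos locus (1-based VCF position).
#' @param ref,alt the forced allele pair (VCF representation).
#' @param min_base_quality,min_mapping_quality Phred filters (defaults 13/20).
#' @return data.frame of class `pileup_column`: qname, support, base_quality,
#'   mapping_quality, with attributes `locus` and `type`; `depth` =
#'   `nrow(...)`.
#' @export
pileup <- function(reads, chrom, pos, ref, alt,
                   min_base_quality = 13L, min_mapping_quality = 20L) {
  type <- classify_variant_type(ref, alt)
  event_len <- abs(nchar(alt) - nchar(ref))
  r <- reads[!is.na(reads$pos) &
             reads$chrom == chrom &
             !bitwAnd(reads$flag, 4L) &          # unmapped
             !bitwAnd(reads$flag, 256L) &        # secondary
             !bitwAnd(reads$flag, 1024L) &       # duplicate
             !bitwAnd(reads$flag, 2048L) &       # supplementary
             reads$mapq >= min_mapping_quality, , drop = FALSE]
  obs <- list()
  for (i in seq_len(nrow(r))) {
    if (type == "SNV") {
      hit <- .read_base_at(r$pos[i], r$cigar[i], r$seq[i], r$qual[i], pos)
      if (is.null(hit)) next
      support <- if (toupper(hit$base) == toupper(ref)) "ref"
                 else if (toupper(hit$base) == toupper(alt)) "alt"
                 else "other"
      q <- hit$qual
    } else {
      hit <- .read_indel_support(r$pos[i], r$cigar[i], r$seq[i], r$qual[i],
                                 pos, type, event_len)
      if (is.null(hit) || is.na(hit$qual)) next
      support <- hit$support
      q <- hit$qual
    }
    if (q < min_base_quality) next
    obs[[length(obs) + 1L]] <- data.frame(
      qname = r$qname[i], support = support, base_quality = q,
      mapping_quality = r$mapq[i], stringsAsFactors = FALSE)
  }
  col <- if (length(obs)) do.call(rbind, obs) else
    data.frame(qname = character(), support = character(),
               base_quality = integer(), mapping_quality = integer(),
               stringsAsFactors = FALSE)
  if (nrow(col) && anyDuplicated(col$qname)) {
    # overlapping mate pairs: keep the higher-quality observation once
    col <- col[order(col$qname, -col$base_quality), , drop = FALSE]
    col <- col[!duplicated(col$qname), , drop = FALSE]
    rownames(col) <- NULL
  }
  attr(col, "locus") <- list(chrom = chrom, pos = pos, ref = ref, alt = alt)
  attr(col, "type") <- type
  class(col) <- c("pileup_column", "data.frame")
  col
}

## ---- likelihood model ----------------------------------------------------

#' Diploid genotype log10-likelihoods from a pileup column
#'
#' Per read with error probability e = 10^(-Q/10): P(obs | allele) = 1 - e
#' when the read supports that allele, otherwise e/3 for SNVs (three
#' alternative bases) or e for indels (binary event). For a diploid genotype
#' g = a1/a2, P(obs | g) = P(obs | a1)/2 + P(obs | a2)/2, and the genotype
#' log10-likelihood is the sum over reads.
#'
#' @param column a `pileup_column`, or a data.frame with columns `support`
#'   and `base_quality`.
#' @param type variant type ("SNV", "INS", "DEL"); taken from the column
#'   attribute when present.
#' @return named numeric vector of log10-likelihoods: ref_ref, ref_alt,
#'   alt_alt. Zero observations return a no-call (all NA).
#' @export
genotype_likelihoods <- function(column, type = attr(column, "type")) {
  if (is.null(type)) stop("variant type required")
  if (nrow(column) == 0L) {
    return(c(ref_ref = NA_real_, ref_alt = NA_real_, alt_alt = NA_real_))
  }
  e <- 10^(-column$base_quality / 10)
  mism <- if (type == "SNV") e / 3 else e
  p_ref <- ifelse(column$support == "ref", 1 - e, mism)
  p_alt <- ifelse(column$support == "alt", 1 - e, mism)
  c(ref_ref = sum(log10(p_ref)),
    ref_alt = sum(log10(p_ref / 2 + p_alt / 2)),
    alt_alt = sum(log10(p_alt)))
}

#' Call a genotype from log10-likelihoods with a theta-based diploid prior
#'
#' Posterior(g) is proportional to prior(g) x L(g) with the standard
#' heterozygosity prior: P(ref/ref) = 1 - 3 theta / 2, P(ref/alt) = theta,
#' P(alt/alt) = theta / 2. The call is the posterior argmax (exact posterior
#' ties break toward the heterozygote). `genotype_quality` is the Phred of
#' 1 - max normalized posterior. `site_qual` mirrors VCF QUAL under
#' emit-all-sites semantics: for non-hom-ref calls the Phred of the hom-ref
#' posterior (confidence a non-reference allele segregates); for hom-ref
#' calls the Phred of 1 minus the hom-ref posterior (confidence the site is
#' hom-ref).
#'
#' @param likelihoods log10-likelihood triple from [genotype_likelihoods()].
#' @param prior_heterozygosity theta (default 0.001).
#' @param allele_depths optional (ref, alt) depths to carry through.
#' @return list: genotype ("ref/ref", "ref/alt", "alt/alt" or NA for a
#'   no-call), gt (VCF string "0/0", "0/1", "1/1" or "./."),
#'   genotype_quality, site_qual, posteriors, log10_likelihoods,
#'   allele_depths.
#' @export
call_genotype <- function(likelihoods, prior_heterozygosity = 0.001,
                          allele_depths = c(0L, 0L)) {
  theta <- prior_heterozygosity
  if (any(is.na(likelihoods))) {
    return(list(genotype = NA_character_, gt = "./.",
                genotype_quality = 0, site_qual = 0,
                posteriors = c(ref_ref = NA, ref_alt = NA, alt_alt = NA),
                log10_likelihoods = likelihoods,
                allele_depths = allele_depths))
  }
  prior <- c(ref_ref = 1 - 3 * theta / 2, ref_alt = theta, alt_alt = theta / 2)
  logpost <- log10(prior) + likelihoods
  post <- 10^(logpost - max(logpost))
  post <- post / sum(post)
  best <- which(post == max(post))
  best <- if (length(best) > 1L && 2L %in% best) 2L else best[1L]
  genotype <- c("ref/ref", "ref/alt", "alt/alt")[best]
  gt <- c("0/0", "0/1", "1/1")[best]
  phred <- function(p) min(-10 * log10(max(p, 1e-300)), 3000)
  gq <- phred(1 - post[best])
  site_qual <- if (best == 1L) phred(1 - post[1L]) else phred(post[1L])
  list(genotype = genotype, gt = gt,
       genotype_quality = unname(gq), site_qual = unname(site_qual),
       posteriors = post, log10_likelihoods = likelihoods,
       allele_depths = allele_depths)
}

#' Forced-allele genotyping of every catalog locus in one sample
#'
#' Emits exactly one record per catalog locus, including no-calls at loci
#' with zero usable coverage (emit-all-sites semantics).
#'
#' @param reads alignments: a data.frame from [read_sam()] or a SAM/BAM path.
#' @param catalog an `rra_catalog` (needs chrom, pos, ref, alt1, type).
#' @param sample_id sample name for the output.
#' @param min_base_quality,min_mapping_quality pileup filters.
#' @param prior_heterozygosity theta for [call_genotype()].
#' @return data.frame: sample_id, chrom, pos, ref, alt, type, gt, genotype,
#'   ref_depth, alt_depth, depth, gq, qual, pl_ref_ref, pl_ref_alt,
#'   pl_alt_alt (log10-likelihoods).
#' @export
genotype_targets <- function(reads, catalog, sample_id = "sample",
                             min_base_quality = 13L,
                             min_mapping_quality = 20L,
                             prior_heterozygosity = 0.001) {
  if (is.character(reads)) reads <- read_sam(reads)
  n <- nrow(catalog)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    col <- pileup(reads, catalog$chrom[i], catalog$pos[i],
                  catalog$ref[i], catalog$alt1[i],
                  min_base_quality = min_base_quality,
                  min_mapping_quality = min_mapping_quality)
    ll <- genotype_likelihoods(col)
    ad <- c(sum(col$support == "ref"), sum(col$support == "alt"))
    call <- call_genotype(ll, prior_heterozygosity, allele_depths = ad)
    out[[i]] <- data.frame(
      sample_id = sample_id,
      chrom = catalog$chrom[i], pos = catalog$pos[i],
      ref = catalog$ref[i], alt = catalog$alt1[i], type = catalog$type[i],
      gt = call$gt, genotype = call$genotype,
      ref_depth = ad[1], alt_depth = ad[2], depth = nrow(col),
      gq = call$genotype_quality, qual = call$site_qual,
      pl_ref_ref = unname(ll[1]), pl_ref_alt = unname(ll[2]),
      pl_alt_alt = unname(ll[3]),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write genotype calls as a single-sample VCF
#'
#' @param calls data.frame from [genotype_targets()] (or a filtered subset).
#' @param path output file.
#' @param info optional character vector of per-record INFO strings.
#' @param header_extra optional extra `##` header lines.
#' @export
write_genotype_vcf <- function(calls, path, info = NULL,
                               header_extra = character()) {
  sample_id <- if (nrow(calls)) calls$sample_id[1] else "sample"
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=rrascan",
    '##INFO=<ID=RRA_CLASS,Number=1,Type=String,Description="RRA class of the locus">',
    '##INFO=<ID=ZYG,Number=1,Type=String,Description="Zygosity of the reference allele in this sample">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=2,Type=Integer,Description="Allele depths: ref,alt">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Filtered depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    '##FORMAT=<ID=PL,Number=3,Type=Integer,Description="Phred-scaled genotype likelihoods: ref/ref, ref/alt, alt/alt">',
    header_extra,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_id), collapse = "\t")
  )
  if (is.null(info)) info <- rep(".", nrow(calls))
  pl <- function(x) {
    x <- -10 * x
    x <- round(x - min(x))
    paste(pmin(x, 9999), collapse = ",")
  }
  pls <- vapply(seq_len(nrow(calls)), function(i) {
    v <- c(calls$pl_ref_ref[i], calls$pl_ref_alt[i], calls$pl_alt_alt[i])
    if (any(is.na(v))) "." else pl(v)
  }, character(1))
  fmt <- sprintf("%s:%d,%d:%d:%d:%s", calls$gt, calls$ref_depth,
                 calls$alt_depth, calls$depth, round(calls$gq), pls)
  body <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt,
                sprintf("%.2f", calls$qual), "PASS", info, "GT:AD:DP:GQ:PL",
                fmt, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
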