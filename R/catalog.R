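## rra_catalog: build, classify and compare the catalog of rare reference
## allele (RRA) loci from a multi-sample population VCF.
##
## A locus is an RRA locus when the reference assembly's allele segregates at
## a population frequency below a threshold (default 1%). Genotypes enter as
## 0/1/2 non-reference dosage codes (0 = hom-ref, 1 = het, 2 = hom-alt).

#' Reference allele frequency from 0/1/2 genotype codes
#'
#' @param codes integer vector of per-sample dosage codes (NA = missing).
#'   Missing genotypes are excluded from numerator and denominator.
#' @return reference AF in \[0, 1\]: called reference alleles over called
#'   alleles.
#' @export
#' @examples
#' compute_ref_af(c(1, 1, rep(2, 10)))  # 2 ref alleles of 24
compute_ref_af <- function(codes) {
  codes <- codes[!is.na(codes)]
  if (length(codes) == 0L) stop("all genotypes missing: reference AF undefined")
  n_homref <- sum(codes == 0L)
  n_het <- sum(codes == 1L)
  (2 * n_homref + n_het) / (2 * length(codes))
}

#' Classify a ref/alt allele pair as SNV, INS or DEL
#'
#' @param ref,alt non-empty allele strings (vectorized).
#' @return character vector in {"SNV","INS","DEL"}. Equal-length multi-base
#'   substitutions (MNVs) are unsupported and raise an error.
#' @export
classify_variant_type <- function(ref, alt) {
  if (any(!nzchar(ref)) || any(!nzchar(alt))) stop("empty allele string")
  lr <- nchar(ref)
  la <- nchar(alt)
  bad <- lr == la & lr > 1L
  if (any(bad)) {
    stop("unsupported variant: equal-length multi-base substitution (MNV) at ",
         "entry ", which(bad)[1])
  }
  ifelse(lr == la, "SNV", ifelse(la > lr, "INS", "DEL"))
}

#' Classify an RRA locus from its genotype codes
#'
#' Class A: the reference allele is never observed. Class B: observed only in
#' heterozygotes. Class C: at least one hom-ref and at least one het. Class U
#' (unclassified): hom-ref present but no het — a configuration outside the
#' three published classes.
#'
#' @param codes integer vector of 0/1/2 dosage codes (NA = missing; missing
#'   genotypes do not participate).
#' @return one of "A", "B", "C", "U".
#' @export
classify_rra <- function(codes) {
  codes <- codes[!is.na(codes)]
  n_homref <- sum(codes == 0L)
  n_het <- sum(codes == 1L)
  if (n_homref == 0L && n_het == 0L) return("A")
  if (n_homref == 0L) return("B")
  if (n_het > 0L) return("C")
  "U"
}

#' Population-sharing category of reference-allele carriers
#'
#' @param codes 0/1/2 dosage codes, one per sample.
#' @param sample_ids sample names aligned with `codes`.
#' @param popmap named character vector mapping sample id to population label
#'   (see [read_population_map()]); must cover every sample.
#' @return list with `pops` (sorted character vector of populations holding at
#'   least one reference-allele carrier) and `category`: "None" (no carriers),
#'   a single population label (private), or "Two Pop"/"Three Pop"/"Four Pop".
#' @export
population_presence <- function(codes, sample_ids, popmap) {
  miss <- setdiff(sample_ids, names(popmap))
  if (length(miss)) {
    stop("samples without population label: ", paste(utils::head(miss), collapse = ", "))
  }
  carrier <- !is.na(codes) & codes <= 1L
  pops <- sort(unique(unname(popmap[sample_ids[carrier]])))
  category <- if (length(pops) == 0L) "None"
  else if (length(pops) == 1L) pops
  else paste(c("Two", "Three", "Four")[min(length(pops), 4L) - 1L], "Pop")
  list(pops = pops, category = category)
}

#' Build the rare-reference-allele catalog from a population VCF
#'
#' Computes the reference AF of every usable record, keeps loci with AF
#' strictly below `af_threshold`, classifies each by genotype configuration,
#' and (optionally) attaches the population-sharing summary.
#'
#' @param panel either a path to a multi-sample VCF or the list returned by
#'   [read_population_vcf()].
#' @param af_threshold retain loci with reference AF strictly below this
#'   value (default 0.01).
#' @param popmap optional named vector from [read_population_map()].
#' @return data.frame of class `rra_catalog`, ordered by (chrom in input
#'   order, pos, ref, alt): chrom, pos, ref, alt (full ALT list), alt1 (first
#'   ALT, the forced alternative allele used downstream), type, ref_af,
#'   n_homref, n_het, n_homalt, n_missing, class, pop_presence.
#' @export
build_catalog <- function(panel, af_threshold = 0.01, popmap = NULL) {
  if (is.character(panel)) panel <- read_population_vcf(panel)
  rec <- panel$records
  codes <- panel$gt_codes
  n <- nrow(rec)
  if (n == 0L) return(.empty_catalog())

  alt1 <- vapply(strsplit(rec$alt, ","), `[`, character(1), 1L)
  type <- rep(NA_character_, n)
  usable <- rep(TRUE, n)
  for (i in seq_len(n)) {
    type[i] <- tryCatch(classify_variant_type(rec$ref[i], alt1[i]),
                        error = function(e) NA_character_)
    if (is.na(type[i])) usable[i] <- FALSE
  }
  n_allmiss <- 0L
  af <- rep(NA_real_, n)
  for (i in which(usable)) {
    af[i] <- tryCatch(compute_ref_af(codes[i, ]), error = function(e) NA_real_)
    if (is.na(af[i])) {
      usable[i] <- FALSE
      n_allmiss <- n_allmiss + 1L
    }
  }
  n_bad <- sum(!usable) - n_allmiss
  if (n_bad > 0) message(n_bad, " record(s) skipped (unsupported alleles)")
  if (n_allmiss > 0) message(n_allmiss, " record(s) skipped (all genotypes missing)")

  keep <- usable & af < af_threshold
  idx <- which(keep)
  if (length(idx) == 0L) return(.empty_catalog())

  cls <- character(length(idx))
  pop <- character(length(idx))
  nh <- nhet <- nha <- nmiss <- integer(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    ci <- codes[i, ]
    nh[k] <- sum(ci == 0L, na.rm = TRUE)
    nhet[k] <- sum(ci == 1L, na.rm = TRUE)
    nha[k] <- sum(ci == 2L, na.rm = TRUE)
    nmiss[k] <- sum(is.na(ci))
    cls[k] <- classify_rra(ci)
    pop[k] <- if (is.null(popmap)) NA_character_ else
      population_presence(ci, panel$sample_ids, popmap)$category
  }
  out <- data.frame(
    chrom = rec$chrom[idx], pos = rec$pos[idx],
    ref = rec$ref[idx], alt = rec$alt[idx], alt1 = alt1[idx],
    type = type[idx], ref_af = af[idx],
    n_homref = nh, n_het = nhet, n_homalt = nha, n_missing = nmiss,
    class = cls, pop_presence = pop,
    stringsAsFactors = FALSE
  )
  chrom_order <- match(out$chrom, unique(rec$chrom))
  out <- out[order(chrom_order, out$pos, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rra_catalog", "data.frame")
  out
}

.empty_catalog <- function() {
  out <- data.frame(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), alt1 = character(), type = character(),
    ref_af = numeric(), n_homref = integer(), n_het = integer(),
    n_homalt = integer(), n_missing = integer(), class = character(),
    pop_presence = character(), stringsAsFactors = FALSE
  )
  class(out) <- c("rra_catalog", "data.frame")
  out
}

#' @export
print.rra_catalog <- function(x, ...) {
  cat("RRA catalog:", nrow(x), "loci\n")
  if (nrow(x)) {
    cat("  classes:", paste(names(table(x$class)), table(x$class),
                            sep = "=", collapse = " "), "\n")
    cat("  types:  ", paste(names(table(x$type)), table(x$type),
                            sep = "=", collapse = " "), "\n")
  }
  NextMethod()
  invisible(x)
}

#' Affected reference spans of catalog loci as a BED-style data.frame
#'
#' SNV: the POS base; DEL: the deleted span (anchor base excluded); INS: the
#' base after POS (insertion point). Used to target the forced-allele
#' genotyper and the annotator.
#'
#' @param catalog an `rra_catalog`.
#' @return data.frame: chrom, start, end (0-based half-open), name
#'   ("chrom:pos:ref:alt").
#' @export
catalog_spans <- function(catalog) {
  if (nrow(catalog) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character()))
  }
  sp <- vcf_span(catalog$pos, catalog$ref, catalog$alt1)
  data.frame(chrom = catalog$chrom, start = sp$start, end = sp$end,
             name = paste(catalog$chrom, catalog$pos, catalog$ref,
                          catalog$alt1, sep = ":"),
             stringsAsFactors = FALSE)
}

#' Cross-panel allele-frequency concordance
#'
#' Intersects the catalog with an external panel's AF table (keyed by chrom,
#' pos, ref, alt) and counts, per threshold, how many shared loci also have
#' an external reference AF below that threshold.
#'
#' @param catalog an `rra_catalog`.
#' @param other data.frame with columns chrom, pos, ref, alt, ref_af.
#' @param thresholds numeric vector of AF cutoffs.
#' @return list: `n_shared`, and `below` — named integer vector per threshold.
#' @export
compare_panels <- function(catalog, other, thresholds = c(0.01, 0.03, 0.05)) {
  key <- function(d, alt) paste(d$chrom, d$pos, d$ref, alt, sep = ":")
  k_cat <- key(catalog, catalog$alt1)
  k_oth <- key(other, other$alt)
  m <- match(k_cat, k_oth)
  shared <- !is.na(m)
  oaf <- other$ref_af[m[shared]]
  below <- vapply(thresholds, function(t) sum(oaf < t), integer(1))
  names(below) <- as.character(thresholds)
  list(n_shared = sum(shared), below = below)
}

#' Compare catalog reference alleles against a newer assembly
#'
#' Given a coordinate remap table and the new assembly's FASTA, marks each
#' locus "updated" (the new assembly's bases at the remapped coordinates
#' differ from the catalog reference allele), "unchanged", or "unmappable"
#' (no remapped coordinate, or remapped span outside the new sequence).
#'
#' @param catalog an `rra_catalog`.
#' @param remap data.frame from [read_remap_table()].
#' @param new_fasta path to the new assembly FASTA, or a `DNAStringSet`.
#' @return list: `status` character vector per locus and `tally` — a
#'   type x status contingency table.
#' @export
compare_reference_alleles <- function(catalog, remap, new_fasta) {
  if (is.character(new_fasta)) new_fasta <- read_fasta(new_fasta)
  key <- paste(remap$old_chrom, remap$old_pos, sep = ":")
  m <- match(paste(catalog$chrom, catalog$pos, sep = ":"), key)
  status <- character(nrow(catalog))
  for (i in seq_len(nrow(catalog))) {
    j <- m[i]
    if (is.na(j) || is.na(remap$new_pos[j]) || remap$new_chrom[j] == "-") {
      status[i] <- "unmappable"
      next
    }
    chrom <- remap$new_chrom[j]
    pos <- remap$new_pos[j]
    len <- nchar(catalog$ref[i])
    if (!chrom %in% names(new_fasta) ||
        pos < 1L || pos + len - 1L > length(new_fasta[[chrom]])) {
      status[i] <- "unmappable"
      next
    }
    new_base <- as.character(Biostrings::subseq(new_fasta[[chrom]],
                                                start = pos, width = len))
    status[i] <- if (toupper(new_base) == toupper(catalog$ref[i]))
      "unchanged" else "updated"
  }
  tally <- table(factor(catalog$type, levels = c("SNV", "INS", "DEL")),
                 factor(status, levels = c("updated", "unchanged", "unmappable")))
  list(status = status, tally = tally)
}
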