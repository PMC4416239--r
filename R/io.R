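## io_formats: readers/writers for the standard formats the pipeline touches.
## All coordinate conversion between VCF (1-based) and the internal 0-based
## half-open convention happens in this file and nowhere else.

#' Convert a 1-based VCF position to a 0-based half-open interval
#'
#' The affected reference span depends on the variant type: an SNV covers the
#' POS base, a deletion covers the deleted bases (excluding the VCF anchor
#' base), and an insertion is anchored at the insertion point, represented
#' here as the single base after POS.
#'
#' @param pos 1-based VCF position (integer vector).
#' @param ref,alt reference and alternative allele strings.
#' @return data.frame with columns `start`, `end` (0-based half-open).
#' @export
vcf_span <- function(pos, ref, alt) {
  type <- classify_variant_type(ref, alt)
  start <- ifelse(type == "SNV", pos - 1L,
           ifelse(type == "DEL", pos, pos))
  end <- ifelse(type == "SNV", pos,
         ifelse(type == "DEL", pos - 1L + nchar(ref), pos + 1L))
  data.frame(start = as.integer(start), end = as.integer(end))
}

## internal: 0-based half-open data.frame -> GRanges (1-based closed)
.df_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

## internal: GRanges -> 0-based half-open data.frame
.granges_to_df <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Read a multi-sample VCF into panel records and a genotype-code matrix
#'
#' Parses the GT field of every sample into a 0/1/2 dosage code counting
#' non-reference alleles (0 = hom-ref, 1 = het, 2 = hom-alt, NA = missing),
#' the encoding used to classify rare-reference-allele loci. Any
#' non-reference allele counts toward the alternative dosage, so multi-allelic
#' genotypes such as 1/2 code as 2.
#'
#' @param path VCF file (plain text or gzipped).
#' @param haploid how to treat single-allele GT values: `"missing"` (default)
#'   or `"one_allele"` (count the one allele; dosage 0 or 1 from half a
#'   diploid genotype).
#' @return list with `records` (data.frame: chrom, pos, id, ref, alt —
#'   comma-joined ALT list), `gt_codes` (integer matrix, loci x samples),
#'   `sample_ids`, and `n_skipped` (malformed/structural records dropped).
#' @export
read_population_vcf <- function(path, haploid = c("missing", "one_allele")) {
  haploid <- match.arg(haploid)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (is.null(v@gt) || ncol(v@gt) < 2 || !"FORMAT" %in% colnames(v@gt)) {
    stop("VCF has no FORMAT/genotype columns; GT fields are required")
  }
  has_gt <- vapply(strsplit(v@gt[, "FORMAT"], ":"),
                   function(x) "GT" %in% x, logical(1))
  if (!all(has_gt)) stop("every VCF record must carry a GT field")
  gt <- vcfR::extract.gt(v, element = "GT")
  keep <- !grepl("[<>\\[\\]]", fix$ALT) & !is.na(fix$ALT) & fix$ALT != "."
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    message(n_skipped, " structural/symbolic or ALT-less records skipped")
  }
  records <- data.frame(
    chrom = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    id = fix$ID[keep],
    ref = fix$REF[keep],
    alt = fix$ALT[keep],
    stringsAsFactors = FALSE
  )
  gt <- gt[keep, , drop = FALSE]
  codes <- gt_to_codes(gt, haploid = haploid)
  list(records = records, gt_codes = codes,
       sample_ids = colnames(gt), n_skipped = n_skipped)
}

#' Convert GT strings to 0/1/2 non-reference dosage codes
#'
#' @param gt character matrix (or vector) of GT strings ("0/0", "0|1", ...).
#' @param haploid see [read_population_vcf()].
#' @return integer matrix/vector of codes; NA for missing genotypes.
#' @export
gt_to_codes <- function(gt, haploid = c("missing", "one_allele")) {
  haploid <- match.arg(haploid)
  u <- unique(as.vector(gt))
  code1 <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_integer_)
    if (length(alleles) == 1L && haploid == "missing") return(NA_integer_)
    sum(alleles != "0")
  }
  lut <- vapply(u, code1, integer(1))
  out <- lut[match(as.vector(gt), u)]
  if (is.matrix(gt)) {
    out <- matrix(out, nrow = nrow(gt), dimnames = dimnames(gt))
  } else {
    out <- unname(out)
  }
  out
}

#' Read a two-column sample-to-population table
#'
#' @param path TSV with columns `sample_id`, `population` (header optional if
#'   exactly two columns).
#' @return named character vector: population label keyed by sample id.
#' @export
read_population_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "population") %in% names(df))) {
    if (ncol(df) == 2) {
      df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                              col.names = c("sample_id", "population"))
    } else {
      stop("population map needs columns sample_id, population")
    }
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in population map")
  stats::setNames(df$population, df$sample_id)
}

#' Write an RRA catalog as a VCF with RRA INFO keys
#'
#' INFO carries RRA_CLASS, RRA_AF, RRA_COUNTS (homref,het,homalt,missing) and
#' RRA_POPS (population-sharing summary).
#'
#' @param catalog data.frame from [build_catalog()].
#' @param path output file.
#' @param header_extra optional character vector of extra `##` header lines
#'   (e.g. provenance written by the command-line driver).
#' @export
write_catalog_vcf <- function(catalog, path, header_extra = character()) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=rrascan",
    '##INFO=<ID=RRA_CLASS,Number=1,Type=String,Description="RRA class: A (reference allele never observed), B (only heterozygous), C (het and hom), U (hom-ref without het)">',
    '##INFO=<ID=RRA_AF,Number=1,Type=Float,Description="Reference allele frequency in the source panel">',
    '##INFO=<ID=RRA_COUNTS,Number=4,Type=Integer,Description="Genotype counts: homref,het,homalt,missing">',
    '##INFO=<ID=RRA_POPS,Number=1,Type=String,Description="Population-sharing summary of reference-allele carriers">',
    '##INFO=<ID=RRA_TYPE,Number=1,Type=String,Description="Variant type: SNV, INS or DEL">',
    header_extra,
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  )
  pops <- if ("pop_presence" %in% names(catalog)) catalog$pop_presence else "."
  pops <- gsub(" ", "_", pops)
  info <- sprintf(
    "RRA_CLASS=%s;RRA_AF=%.6g;RRA_COUNTS=%d,%d,%d,%d;RRA_POPS=%s;RRA_TYPE=%s",
    catalog$class, catalog$ref_af, catalog$n_homref, catalog$n_het,
    catalog$n_homalt, catalog$n_missing, pops, catalog$type
  )
  body <- paste(catalog$chrom, catalog$pos, ".", catalog$ref, catalog$alt,
                ".", "PASS", info, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a catalog VCF written by [write_catalog_vcf()]
#'
#' @param path catalog VCF file.
#' @return catalog data.frame (same columns as [build_catalog()] output,
#'   minus any column absent from the INFO field).
#' @export
read_catalog_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  grab <- function(key) {
    m <- regmatches(fix$INFO, regexpr(paste0(key, "=[^;]+"), fix$INFO))
    sub(paste0(key, "="), "", m)
  }
  counts <- do.call(rbind, strsplit(grab("RRA_COUNTS"), ","))
  out <- data.frame(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    type = grab("RRA_TYPE"),
    ref_af = as.numeric(grab("RRA_AF")),
    n_homref = as.integer(counts[, 1]),
    n_het = as.integer(counts[, 2]),
    n_homalt = as.integer(counts[, 3]),
    n_missing = as.integer(counts[, 4]),
    class = grab("RRA_CLASS"),
    pop_presence = gsub("_", " ", grab("RRA_POPS")),
    stringsAsFactors = FALSE
  )
  out$alt1 <- vapply(strsplit(out$alt, ","), `[`, character(1), 1L)
  class(out) <- c("rra_catalog", "data.frame")
  out
}

#' Read a BED file into a 0-based half-open interval data.frame
#'
#' @param path BED file (3+ columns; column 4 kept as `name` if present).
#' @param sorted if `TRUE` (default) intervals are sorted by (chrom, start);
#'   unsorted input is sorted with a warning.
#' @return data.frame: chrom, start, end (0-based half-open), name (optional).
#' @export
read_bed <- function(path, sorted = TRUE) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- .granges_to_df(gr)
  nm <- gr$name
  if (!is.null(nm)) df$name <- nm
  if (sorted) {
    o <- order(df$chrom, df$start, df$end)
    if (!identical(o, seq_len(nrow(df))) && nrow(df) > 1) {
      warning("unsorted BED input; sorting internally")
      df <- df[o, , drop = FALSE]
      rownames(df) <- NULL
    }
  }
  df
}

#' Write a 0-based half-open interval data.frame to BED
#'
#' @param df data.frame with chrom, start, end and optionally name.
#' @param path output file.
#' @export
write_bed <- function(df, path) {
  cols <- list(df$chrom, df$start, df$end)
  if (!is.null(df$name)) cols <- c(cols, list(df$name))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read a bedGraph track of per-interval scores
#'
#' @param path bedGraph file.
#' @return data.frame: chrom, start, end (0-based half-open), score.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- .granges_to_df(gr)
  df$score <- gr$score
  df
}

#' Write a score track as bedGraph
#' @param df data.frame with chrom, start, end, score (0-based half-open).
#' @param path output file.
#' @export
write_bedgraph <- function(df, path) {
  writeLines(paste(df$chrom, df$start, df$end, df$score, sep = "\t"), path)
  invisible(path)
}

#' Read a FASTA file as a DNAStringSet keyed by the first header token
#' @param path FASTA file.
#' @return `Biostrings::DNAStringSet` with names truncated at whitespace.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Read aligned reads from SAM or BAM into a data.frame
#'
#' SAM text input is converted in place (via Rsamtools) before scanning.
#'
#' @param path SAM or BAM file.
#' @return data.frame: qname, flag, chrom, pos (1-based leftmost), mapq,
#'   cigar, seq, qual (Phred+33 string).
#' @export
read_sam <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = TRUE)
  }
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual")
    )
  )[[1]]
  data.frame(
    qname = res$qname,
    flag = res$flag,
    chrom = as.character(res$rname),
    pos = res$pos,
    mapq = res$mapq,
    cigar = res$cigar,
    seq = as.character(res$seq),
    qual = as.character(res$qual),
    stringsAsFactors = FALSE
  )
}

#' Read a TSV table and check a required schema
#'
#' @param path tab-delimited file with a header row.
#' @param required character vector of column names that must be present.
#' @return data.frame.
#' @export
read_tsv_table <- function(path, required = character()) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          comment.char = "#")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("table ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df
}

#' Read a coordinate remap table (old assembly to new assembly)
#'
#' @param path 4-column TSV: old_chrom, old_pos, new_chrom, new_pos, where
#'   unmapped loci carry "-" in the new columns.
#' @return data.frame with new_pos as integer (NA when unmapped).
#' @export
read_remap_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("old_chrom", "old_pos", "new_chrom", "new_pos")
  if (!all(need %in% names(df))) {
    stop("remap table needs columns: ", paste(need, collapse = ", "))
  }
  df$new_pos <- suppressWarnings(as.integer(df$new_pos))
  df$old_pos <- as.integer(df$old_pos)
  df
}
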