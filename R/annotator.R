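## annotator: attach genomic-feature, conservation, regulatory and phenotype
## annotations to RRA loci and apply the threshold rules (GERP RS > 2,
## RegulomeDB score <= 3, positively-associated GAD classes).

## Overlap between catalog affected spans and an interval track, via
## GenomicRanges. Insertions use stricter semantics: the insertion point (the
## base after POS) must fall strictly inside the feature, i.e. both flanking
## bases belong to it.
.span_overlaps <- function(catalog, track) {
  if (nrow(track) == 0L || nrow(catalog) == 0L) {
    return(data.frame(locus = integer(), feature = integer()))
  }
  spans <- catalog_spans(catalog)
  ins <- catalog$type == "INS"
  # for insertions, widen to both flanking bases and require full containment
  spans$start[ins] <- spans$start[ins] - 1L
  q <- .df_to_granges(spans)
  s <- .df_to_granges(track)
  hits_any <- GenomicRanges::findOverlaps(q, s)
  hits_within <- GenomicRanges::findOverlaps(q, s, type = "within")
  qh_any <- S4Vectors::queryHits(hits_any)
  use <- ifelse(ins[S4Vectors::queryHits(hits_any)], FALSE, TRUE)
  df_any <- data.frame(locus = qh_any[use],
                       feature = S4Vectors::subjectHits(hits_any)[use])
  qh_w <- S4Vectors::queryHits(hits_within)
  use_w <- ins[qh_w]
  df_ins <- data.frame(locus = qh_w[use_w],
                       feature = S4Vectors::subjectHits(hits_within)[use_w])
  rbind(df_any, df_ins)
}

#' Feature labels overlapping each catalog locus
#'
#' A locus overlaps a feature when its affected reference span (SNV: the POS
#' base; DEL: the deleted span; INS: the insertion point, strictly inside the
#' feature) intersects the feature interval.
#'
#' @param catalog an `rra_catalog`.
#' @param track interval data.frame: chrom, start, end (0-based half-open),
#'   name (feature label). Unsorted tracks are handled.
#' @return list (one element per locus) of sorted unique feature labels.
#' @export
overlap_features <- function(catalog, track) {
  out <- rep(list(character()), nrow(catalog))
  if (is.null(track) || nrow(track) == 0L) return(out)
  if (is.null(track$name)) track$name <- "feature"
  ov <- .span_overlaps(catalog, track)
  if (nrow(ov)) {
    sp <- split(track$name[ov$feature], ov$locus)
    for (k in names(sp)) out[[as.integer(k)]] <- sort(unique(sp[[k]]))
  }
  out
}

#' GERP conservation filter
#'
#' SNVs and insertions pass when the RS score at the locus position (the VCF
#' POS base) is strictly greater than `cutoff`; deletions pass when any
#' deleted base (anchor excluded) has RS strictly greater than `cutoff`.
#' Positions absent from the track fail with a warning.
#'
#' @param catalog an `rra_catalog`.
#' @param rs_track per-base score data.frame: chrom, start, end, score
#'   (bedGraph semantics, from [read_bedgraph()]).
#' @param cutoff RS threshold (default 2; strict inequality).
#' @return logical vector, one per locus.
#' @export
gerp_filter <- function(catalog, rs_track, cutoff = 2) {
  n <- nrow(catalog)
  out <- logical(n)
  n_absent <- 0L
  for (i in seq_len(n)) {
    if (catalog$type[i] == "DEL") {
      span_start <- catalog$pos[i]                       # 0-based, anchor excluded
      span_end <- catalog$pos[i] - 1L + nchar(catalog$ref[i])
    } else {
      span_start <- catalog$pos[i] - 1L                  # the POS base
      span_end <- catalog$pos[i]
    }
    t <- rs_track[rs_track$chrom == catalog$chrom[i] &
                  rs_track$end > span_start & rs_track$start < span_end, ,
                  drop = FALSE]
    covered <- if (nrow(t))
      sum(pmin(t$end, span_end) - pmax(t$start, span_start)) else 0L
    if (covered < span_end - span_start) n_absent <- n_absent + 1L
    out[i] <- nrow(t) > 0 && any(t$score > cutoff)
  }
  if (n_absent > 0L) {
    warning(n_absent, " locus/loci with bases absent from the RS track ",
            "(treated as not passing)")
  }
  out
}

#' Join gene-level phenotype and locus-level regulatory tables
#'
#' Genes are assigned by overlap of the affected span with the gene model;
#' GAD disease classes are the union over overlapped genes of classes with a
#' positive (Y) association; OMIM is true when any overlapped gene appears in
#' the OMIM table; the RegulomeDB score is joined by (chrom, pos) and
#' `regdb_tf_binding` flags scores <= 3 (likely TF-binding impact).
#'
#' @param catalog an `rra_catalog`.
#' @param gene_model data.frame: chrom, start, end, name (gene id).
#' @param gad_table data.frame: gene_id, disease_class, association ("Y"/"N";
#'   records without a Y flag are ignored).
#' @param omim_table data.frame with a gene_id column.
#' @param regdb_table data.frame: chrom, pos (1-based), score (integer).
#' @return data.frame: genes, gad_classes (comma-joined, "" if none), omim,
#'   regulomedb_score (NA if absent), regdb_tf_binding.
#' @export
join_phenotypes <- function(catalog, gene_model, gad_table = NULL,
                            omim_table = NULL, regdb_table = NULL) {
  n <- nrow(catalog)
  genes <- overlap_features(catalog, gene_model)
  gad <- character(n)
  omim <- logical(n)
  if (!is.null(gad_table) && nrow(gad_table)) {
    gad_pos <- gad_table[toupper(gad_table$association) == "Y", , drop = FALSE]
    gad <- vapply(genes, function(g) {
      cls <- sort(unique(gad_pos$disease_class[gad_pos$gene_id %in% g]))
      paste(cls, collapse = ",")
    }, character(1))
  }
  if (!is.null(omim_table) && nrow(omim_table)) {
    omim <- vapply(genes, function(g) any(g %in% omim_table$gene_id),
                   logical(1))
  }
  score <- rep(NA_integer_, n)
  if (!is.null(regdb_table) && nrow(regdb_table)) {
    m <- match(paste(catalog$chrom, catalog$pos),
               paste(regdb_table$chrom, regdb_table$pos))
    score <- as.integer(regdb_table$score[m])
  }
  data.frame(
    genes = vapply(genes, paste, character(1), collapse = ","),
    gad_classes = gad,
    omim = omim,
    regulomedb_score = score,
    regdb_tf_binding = !is.na(score) & score <= 3L,
    stringsAsFactors = FALSE
  )
}

#' Annotate an RRA catalog
#'
#' One call assembling the full annotation record per locus: GENCODE-style
#' biotype overlaps, ENCODE-style regulatory element overlaps (TFP / DHS /
#' enhancer), the GERP pass flag, the consumed consequence class, and the
#' phenotype/regulatory joins.
#'
#' @param catalog an `rra_catalog`.
#' @param gencode,encode interval tracks (chrom, start, end, name) or NULL.
#' @param gerp per-base RS track or NULL.
#' @param gene_model,gad_table,omim_table,regdb_table see
#'   [join_phenotypes()]; any may be NULL.
#' @param consequence_table precomputed consequence classes (e.g. VEP
#'   output): data.frame chrom, pos, ref, alt, consequence; loci absent from
#'   the table get "none".
#' @return the catalog with annotation columns appended: gencode_biotypes,
#'   encode_elements, n_encode_elements, gerp_pass, consequence, genes,
#'   gad_classes, omim, regulomedb_score, regdb_tf_binding.
#' @export
annotate_catalog <- function(catalog, gencode = NULL, encode = NULL,
                             gerp = NULL, gene_model = NULL,
                             gad_table = NULL, omim_table = NULL,
                             regdb_table = NULL, consequence_table = NULL) {
  n <- nrow(catalog)
  join <- function(x) vapply(x, paste, character(1), collapse = ",")
  bio <- overlap_features(catalog, gencode)
  enc <- overlap_features(catalog, encode)
  out <- as.data.frame(catalog)
  out$gencode_biotypes <- join(bio)
  out$encode_elements <- join(enc)
  out$n_encode_elements <- lengths(enc)
  out$gerp_pass <- if (is.null(gerp)) NA else
    suppressWarnings(gerp_filter(catalog, gerp))
  cons <- rep("none", n)
  if (!is.null(consequence_table) && nrow(consequence_table)) {
    m <- match(paste(catalog$chrom, catalog$pos, catalog$ref, catalog$alt1),
               paste(consequence_table$chrom, consequence_table$pos,
                     consequence_table$ref, consequence_table$alt))
    cons[!is.na(m)] <- consequence_table$consequence[m[!is.na(m)]]
  }
  out$consequence <- cons
  if (!is.null(gene_model)) {
    out <- cbind(out, join_phenotypes(catalog, gene_model, gad_table,
                                      omim_table, regdb_table))
  }
  class(out) <- c("rra_annotated", "data.frame")
  out
}

#' Cross-tabulate an annotated catalog
#'
#' Counts loci by variant type and RRA class for each annotation category:
#' Total, Intergenic (no biotype overlap), Gencode (any biotype), Functional
#' (missense/nonsense/frameshift/splicing consequence), Pseudogenes,
#' Non-coding RNA, and Encode elements. Categories other than Total and
#' Intergenic are not mutually exclusive (a locus may carry several
#' biotypes), so category rows need not sum to the totals; the Total row
#' always conserves the catalog size.
#'
#' @param annotated output of [annotate_catalog()].
#' @param nc_biotypes biotype labels counted as non-coding RNA.
#' @return 3-dimensional table: category x class x type.
#' @export
summarize_catalog <- function(annotated,
                              nc_biotypes = c("lincRNA", "antisense",
                                              "processed_transcript",
                                              "miRNA", "snoRNA", "snRNA")) {
  classes <- c("A", "B", "C", "U")
  types <- c("SNV", "INS", "DEL")
  cats <- c("Total", "Intergenic", "Gencode", "Functional", "Pseudogenes",
            "Non coding RNA", "Encode Elements")
  has <- function(col, what) {
    vapply(strsplit(col, ","), function(x) any(x %in% what), logical(1))
  }
  in_gencode <- nzchar(annotated$gencode_biotypes)
  flags <- list(
    "Total" = rep(TRUE, nrow(annotated)),
    "Intergenic" = !in_gencode,
    "Gencode" = in_gencode,
    "Functional" = annotated$consequence %in%
      c("missense", "nonsense", "frameshift", "splicing"),
    "Pseudogenes" = has(annotated$gencode_biotypes,
                        c("pseudogene", "processed_pseudogene")),
    "Non coding RNA" = has(annotated$gencode_biotypes, nc_biotypes),
    "Encode Elements" = annotated$n_encode_elements > 0
  )
  arr <- array(
    0L, dim = c(length(cats), length(classes), length(types)),
    dimnames = list(category = cats, class = classes, type = types)
  )
  for (cat_i in seq_along(cats)) {
    sub <- annotated[flags[[cats[cat_i]]], , drop = FALSE]
    if (!nrow(sub)) next
    tab <- table(factor(sub$class, levels = classes),
                 factor(sub$type, levels = types))
    arr[cat_i, , ] <- as.integer(tab)
  }
  as.table(arr)
}

#' Write an annotated catalog as a TSV report
#'
#' Column layout mirrors a per-locus variant report: coordinates, alleles,
#' type, class, biotypes, consequence, conservation flag, phenotype and
#' regulatory joins.
#'
#' @param annotated output of [annotate_catalog()].
#' @param path output file.
#' @param header_extra optional `#`-prefixed provenance lines.
#' @export
write_annotation_tsv <- function(annotated, path, header_extra = character()) {
  cols <- intersect(
    c("chrom", "pos", "ref", "alt", "type", "class", "ref_af",
      "gencode_biotypes", "encode_elements", "consequence", "gerp_pass",
      "genes", "gad_classes", "omim", "regulomedb_score", "regdb_tf_binding"),
    names(annotated)
  )
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_extra)) writeLines(header_extra, con)
  utils::write.table(annotated[, cols, drop = FALSE], con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
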