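## variant_caller: turn per-locus genotype calls into germline RRA variant
## calls and somatic RRA calls (tumor/normal pairs, Fisher exact test).

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact p-value under the hypergeometric null with fixed margins, using the
#' probability-ordering definition of "at least as extreme": the p-value sums
#' the probabilities of all tables whose probability does not exceed that of
#' the observed table (with the customary relative tie tolerance of 1e-7).
#' One-sided alternatives sum the corresponding hypergeometric tail. The
#' all-zero table returns p = 1 by convention.
#'
#' @param a,b,c,d the four non-negative counts, row-wise:
#'   \[\[a, b\], \[c, d\]\]. `a` may also be a 2x2 matrix.
#' @param alternative "two.sided" (default), "less" or "greater" (tail of
#'   `a`, the top-left count).
#' @return the exact p-value.
#' @export
#' @examples
#' fisher_exact_2x2(5, 5, 5, 5)   # identical margins: p = 1
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL,
                             alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (is.matrix(a)) {
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  n <- a + b + c + d
  if (n == 0) {
    message("all-zero table: p = 1 by convention")
    return(1)
  }
  m <- a + b        # row 1 total (white balls)
  k <- a + c        # column 1 total (balls drawn)
  lo <- max(0, k - (n - m))
  hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n - m, k)
  p_obs <- stats::dhyper(a, m, n - m, k)
  p <- switch(alternative,
    two.sided = sum(probs[probs <= p_obs * (1 + 1e-7)]),
    less = stats::phyper(a, m, n - m, k),
    greater = stats::phyper(a - 1, m, n - m, k, lower.tail = FALSE)
  )
  min(p, 1)
}

#' Filter genotype calls down to germline RRA variant calls
#'
#' Retains calls whose site quality passes `min_qual` and whose genotype
#' contains at least one reference allele (heterozygous or homozygous
#' reference) — at RRA loci these are the calls standard pipelines miss.
#' No-calls and homozygous-alternative calls are dropped.
#'
#' @param calls data.frame from [genotype_targets()].
#' @param min_qual minimum site quality (default 30, error rate below 0.1%).
#' @return the retained subset with a `zygosity` column ("heterozygous" or
#'   "homozygous_ref"). Records are never modified, only filtered/annotated.
#' @export
germline_filter <- function(calls, min_qual = 30) {
  keep <- !is.na(calls$genotype) &
    calls$qual >= min_qual &
    calls$gt %in% c("0/0", "0/1")
  out <- calls[keep, , drop = FALSE]
  out$zygosity <- ifelse(out$gt == "0/1", "heterozygous", "homozygous_ref")
  rownames(out) <- NULL
  out
}

#' Compare a matched normal/tumor call pair at one RRA locus
#'
#' A locus is a somatic RRA candidate when the normal genotype contains no
#' reference allele (homozygous alternative) while the tumor genotype
#' contains at least one. Candidates are tested with a Fisher exact test on
#' the post-filter allele depths \[\[normal_ref, normal_alt\],
#' \[tumor_ref, tumor_alt\]\]; the verdict is `somatic_rra` when
#' p < `alpha`, otherwise `rejected`.
#'
#' @param normal_call,tumor_call single-row call data.frames (same locus)
#'   from [genotype_targets()].
#' @param alpha significance threshold (default 0.01).
#' @param min_qual site-quality threshold both calls must meet (default 30).
#' @param alternative sidedness of the Fisher test (default two-sided).
#' @return one-row data.frame: chrom, pos, ref, alt, type, normal_gt,
#'   tumor_gt, normal_ref_depth, normal_alt_depth, tumor_ref_depth,
#'   tumor_alt_depth, fisher_p, verdict, reason.
#' @export
somatic_compare <- function(normal_call, tumor_call, alpha = 0.01,
                            min_qual = 30, alternative = "two.sided") {
  if (normal_call$chrom != tumor_call$chrom ||
      normal_call$pos != tumor_call$pos ||
      normal_call$ref != tumor_call$ref ||
      normal_call$alt != tumor_call$alt) {
    stop("normal and tumor calls refer to different loci")
  }
  res <- data.frame(
    chrom = normal_call$chrom, pos = normal_call$pos,
    ref = normal_call$ref, alt = normal_call$alt, type = normal_call$type,
    normal_gt = normal_call$gt, tumor_gt = tumor_call$gt,
    normal_ref_depth = normal_call$ref_depth,
    normal_alt_depth = normal_call$alt_depth,
    tumor_ref_depth = tumor_call$ref_depth,
    tumor_alt_depth = tumor_call$alt_depth,
    fisher_p = NA_real_, verdict = "rejected", reason = "",
    stringsAsFactors = FALSE
  )
  if (is.na(normal_call$genotype) || is.na(tumor_call$genotype)) {
    res$reason <- "no_call"
    return(res)
  }
  if (normal_call$qual < min_qual || tumor_call$qual < min_qual) {
    res$reason <- "low_quality"
    return(res)
  }
  if (normal_call$gt != "1/1") {
    res$reason <- "reference_allele_in_normal"
    return(res)
  }
  if (!tumor_call$gt %in% c("0/0", "0/1")) {
    res$reason <- "no_reference_allele_in_tumor"
    return(res)
  }
  res$fisher_p <- fisher_exact_2x2(
    normal_call$ref_depth, normal_call$alt_depth,
    tumor_call$ref_depth, tumor_call$alt_depth,
    alternative = alternative
  )
  if (res$fisher_p < alpha) {
    res$verdict <- "somatic_rra"
    res$reason <- "significant"
  } else {
    res$reason <- "fisher_not_significant"
  }
  res
}

#' Germline RRA calling over one or more samples
#'
#' For each sample: force-genotype every catalog locus, apply the germline
#' filter, attach the catalog class, and (optionally) write a per-sample VCF.
#'
#' @param alignments named list of per-sample alignments (paths or read
#'   data.frames); names are sample ids.
#' @param catalog an `rra_catalog`.
#' @param min_qual germline site-quality threshold (default 30).
#' @param out_dir if non-NULL, one VCF per sample is written here.
#' @param ... passed to [genotype_targets()].
#' @return named list of per-sample filtered call data.frames (with
#'   `rra_class` column).
#' @export
run_germline <- function(alignments, catalog, min_qual = 30, out_dir = NULL,
                         ...) {
  if (is.null(names(alignments)) || any(!nzchar(names(alignments)))) {
    stop("alignments must be a named list (sample ids)")
  }
  lapply(stats::setNames(names(alignments), names(alignments)), function(sid) {
    calls <- genotype_targets(alignments[[sid]], catalog, sample_id = sid, ...)
    kept <- germline_filter(calls, min_qual = min_qual)
    kept$rra_class <- catalog$class[match(
      paste(kept$chrom, kept$pos, kept$ref, kept$alt),
      paste(catalog$chrom, catalog$pos, catalog$ref, catalog$alt1))]
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      info <- sprintf("RRA_CLASS=%s;ZYG=%s", kept$rra_class, kept$zygosity)
      write_genotype_vcf(kept, file.path(out_dir, paste0(sid, ".rra.vcf")),
                         info = info)
    }
    kept
  })
}

#' Somatic RRA calling over matched tumor/normal pairs
#'
#' For each pair: force-genotype both samples at every catalog locus, run
#' [somatic_compare()] per locus, and keep `somatic_rra` verdicts. Optionally
#' writes one tab-delimited file per pair.
#'
#' @param pairs named list; each element is `list(normal = , tumor = )`
#'   (paths or read data.frames). Elements lacking either member are an
#'   error.
#' @param catalog an `rra_catalog`.
#' @param alpha Fisher significance threshold (default 0.01).
#' @param min_qual site-quality threshold (default 30).
#' @param out_dir if non-NULL, one TSV per pair is written here.
#' @param ... passed to [genotype_targets()].
#' @return named list of per-pair data.frames of `somatic_rra` calls (with
#'   `rra_class`).
#' @export
run_somatic <- function(pairs, catalog, alpha = 0.01, min_qual = 30,
                        out_dir = NULL, ...) {
  if (is.null(names(pairs)) || any(!nzchar(names(pairs)))) {
    stop("pairs must be a named list")
  }
  lapply(stats::setNames(names(pairs), names(pairs)), function(pid) {
    pair <- pairs[[pid]]
    if (!all(c("normal", "tumor") %in% names(pair))) {
      stop("pair '", pid, "' must have 'normal' and 'tumor' members")
    }
    nc <- genotype_targets(pair$normal, catalog,
                           sample_id = paste0(pid, "_normal"), ...)
    tc <- genotype_targets(pair$tumor, catalog,
                           sample_id = paste0(pid, "_tumor"), ...)
    rows <- lapply(seq_len(nrow(catalog)), function(i) {
      somatic_compare(nc[i, ], tc[i, ], alpha = alpha, min_qual = min_qual)
    })
    res <- do.call(rbind, rows)
    res$rra_class <- catalog$class
    hits <- res[res$verdict == "somatic_rra", , drop = FALSE]
    rownames(hits) <- NULL
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      out <- data.frame(
        chrom = hits$chrom, pos = hits$pos, ref = hits$ref, alt = hits$alt,
        type = hits$type, rra_class = hits$rra_class,
        normal_AD = paste(hits$normal_ref_depth, hits$normal_alt_depth,
                          sep = ","),
        tumor_AD = paste(hits$tumor_ref_depth, hits$tumor_alt_depth,
                         sep = ","),
        fisher_p = signif(hits$fisher_p, 6),
        stringsAsFactors = FALSE
      )
      utils::write.table(out, file.path(out_dir, paste0(pid, ".somatic.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    hits
  })
}
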