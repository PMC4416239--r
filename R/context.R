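## context_metrics: GC content and mean mappability of the window around each
## RRA locus, plus randomly sampled background windows. Used to check whether
## rare-reference-allele loci sit in unusually hard-to-sequence regions.

#' Window around a locus
#'
#' Returns a window of exactly `size` bases centered on the locus base
#' (0-based center = pos - 1). For even sizes the extra base goes to the left.
#' Windows truncated at contig boundaries are flagged `clamped`.
#'
#' @param chrom contig name.
#' @param pos 1-based locus position.
#' @param size window width in bases (default 100).
#' @param contig_length optional contig length for boundary clamping; if
#'   missing no clamping is applied (the caller guarantees bounds).
#' @return data.frame: chrom, start, end (0-based half-open), clamped.
#' @export
window_around <- function(chrom, pos, size = 100L, contig_length = NULL) {
  center <- pos - 1L
  start <- center - size %/% 2L
  end <- start + size
  clamped <- rep(FALSE, length(pos))
  if (!is.null(contig_length)) {
    clamped <- start < 0L | end > contig_length
    start <- pmax(start, 0L)
    end <- pmin(end, contig_length)
  } else if (any(start < 0L)) {
    clamped <- clamped | start < 0L
    start <- pmax(start, 0L)
  }
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             clamped = clamped, stringsAsFactors = FALSE)
}

#' GC fraction of a sequence
#'
#' (G + C) / (A + C + G + T), case-insensitive. N and other ambiguity codes
#' are excluded from the denominator by default (set `count_n = TRUE` to
#' divide by the full length, the bedtools-nuc convention). All-N sequences
#' return NA.
#'
#' @param sequence character vector of DNA strings.
#' @param count_n include non-ACGT bases in the denominator.
#' @return numeric vector of GC fractions.
#' @export
gc_content <- function(sequence, count_n = FALSE) {
  if (any(!nzchar(sequence))) stop("empty sequence")
  s <- Biostrings::DNAStringSet(toupper(sequence))
  freq <- Biostrings::letterFrequency(s, letters = c("A", "C", "G", "T"))
  gc <- freq[, "G"] + freq[, "C"]
  denom <- if (count_n) Biostrings::width(s) else rowSums(freq)
  out <- ifelse(denom > 0, gc / denom, NA_real_)
  unname(out)
}

#' Mean per-base score of a track over an interval
#'
#' Arithmetic mean of per-base scores over a 0-based half-open interval.
#' Bases absent from the track contribute 0 and trigger a warning, so sparse
#' tracks degrade gracefully rather than silently shrinking the denominator.
#'
#' @param track data.frame: chrom, start, end, score (bedGraph semantics,
#'   e.g. from [read_bedgraph()]).
#' @param chrom,start,end the query interval (0-based half-open).
#' @return mean score over all `end - start` bases.
#' @export
mean_mappability <- function(track, chrom, start, end) {
  width <- end - start
  if (width <= 0) stop("empty interval")
  t <- track[track$chrom == chrom & track$end > start & track$start < end, ,
             drop = FALSE]
  covered <- 0L
  total <- 0
  if (nrow(t)) {
    ov_start <- pmax(t$start, start)
    ov_end <- pmin(t$end, end)
    w <- ov_end - ov_start
    covered <- sum(w)
    total <- sum(w * t$score)
  }
  if (covered < width) {
    warning(sprintf("%d of %d bases absent from track (contribute 0)",
                    width - covered, width))
  }
  total / width
}

#' Sample random background windows from a genome
#'
#' Windows are sampled uniformly over all valid (non-clamped) start positions
#' across contigs, so per-contig counts are proportional to contig length.
#'
#' @param fasta path to a FASTA file or a `DNAStringSet`.
#' @param n number of windows.
#' @param size window width (default 100).
#' @param seed integer seed; the same seed reproduces the same windows.
#' @return data.frame: chrom, start, end (0-based half-open).
#' @export
sample_background <- function(fasta, n, size = 100L, seed = 1L) {
  stopifnot(n > 0)
  if (is.character(fasta)) fasta <- read_fasta(fasta)
  lens <- Biostrings::width(fasta)
  valid <- lens - size + 1L
  if (all(valid <= 0L)) stop("every contig is shorter than the window size")
  valid[valid < 0L] <- 0L
  total <- sum(as.numeric(valid))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  u <- sort(sample.int(total, n, replace = TRUE))
  cum <- cumsum(as.numeric(valid))
  ci <- findInterval(u - 1, cum) + 1L
  offset <- u - c(0, cum)[ci] - 1L
  out <- data.frame(chrom = names(fasta)[ci],
                    start = as.integer(offset),
                    end = as.integer(offset + size),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Per-window GC and mappability metrics
#'
#' Computes [gc_content()] and [mean_mappability()] for each of a set of
#' windows (catalog loci via [window_around()], or background windows from
#' [sample_background()]).
#'
#' @param windows data.frame: chrom, start, end (0-based half-open).
#' @param fasta path to FASTA or `DNAStringSet`.
#' @param mappability optional track data.frame (chrom, start, end, score);
#'   if NULL the mappability column is NA.
#' @return the input windows with `gc_fraction` and `mean_mappability` added.
#' @export
window_metrics <- function(windows, fasta, mappability = NULL) {
  if (is.character(fasta)) fasta <- read_fasta(fasta)
  missing_contig <- setdiff(unique(windows$chrom), names(fasta))
  if (length(missing_contig)) {
    stop("contig(s) absent from FASTA: ", paste(missing_contig, collapse = ", "))
  }
  seqs <- vapply(seq_len(nrow(windows)), function(i) {
    as.character(Biostrings::subseq(fasta[[windows$chrom[i]]],
                                    start = windows$start[i] + 1L,
                                    end = windows$end[i]))
  }, character(1))
  windows$gc_fraction <- gc_content(seqs)
  windows$mean_mappability <- if (is.null(mappability)) NA_real_ else
    vapply(seq_len(nrow(windows)), function(i) {
      suppressWarnings(mean_mappability(mappability, windows$chrom[i],
                                        windows$start[i], windows$end[i]))
    }, numeric(1))
  windows
}
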