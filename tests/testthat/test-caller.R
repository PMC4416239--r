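# variant_caller: Fisher exact test, germline filtering, somatic comparison
# and the run_* drivers.

test_that("Fisher exact test matches its enumeration oracle on examples", {
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)
  expect_equal(fisher_exact_2x2(0, 1, 1, 0), 1)  # both tables equally extreme
  expect_equal(fisher_exact_2x2(0, 30, 15, 15), oracle_fisher(0, 30, 15, 15),
               tolerance = 1e-12)
  expect_message(p0 <- fisher_exact_2x2(0, 0, 0, 0), "convention")
  expect_equal(p0, 1)
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("Fisher p-values agree with stats::fisher.test", {
  set.seed(11)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 8), 2, 2)
    expect_equal(fisher_exact_2x2(tab),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
  # one-sided tails
  tab <- matrix(c(2, 10, 12, 4), 2, 2, byrow = TRUE)
  expect_equal(fisher_exact_2x2(tab, alternative = "less"),
               stats::fisher.test(tab, alternative = "less")$p.value,
               tolerance = 1e-9)
  expect_equal(fisher_exact_2x2(tab, alternative = "greater"),
               stats::fisher.test(tab, alternative = "greater")$p.value,
               tolerance = 1e-9)
})

test_that("Fisher p is invariant under row swap and transpose symmetries", {
  set.seed(21)
  for (i in 1:30) {
    x <- rpois(4, 6)
    p <- fisher_exact_2x2(x[1], x[2], x[3], x[4])
    expect_equal(fisher_exact_2x2(x[2], x[1], x[4], x[3]), p)
    expect_equal(fisher_exact_2x2(x[3], x[4], x[1], x[2]), p)
  }
})

test_that("germline filter keeps high-quality reference-carrying calls", {
  calls <- data.frame(
    sample_id = "s", chrom = "chr1", pos = c(100L, 200L, 300L, 400L),
    ref = "A", alt = "G", type = "SNV",
    gt = c("1/1", "0/1", "0/0", "./."),
    genotype = c("alt/alt", "ref/alt", "ref/ref", NA),
    ref_depth = c(0L, 20L, 38L, 0L), alt_depth = c(40L, 20L, 2L, 0L),
    depth = c(40L, 40L, 40L, 0L), gq = 99,
    qual = c(90, 45, 10, 0),
    pl_ref_ref = 0, pl_ref_alt = 0, pl_alt_alt = 0,
    stringsAsFactors = FALSE
  )
  kept <- germline_filter(calls, min_qual = 30)
  # hom-alt dropped (no reference allele), hom-ref dropped (quality),
  # no-call dropped; the Q45 het stays
  expect_equal(kept$pos, 200L)
  expect_equal(kept$zygosity, "heterozygous")
  # germline output is an unmodified subset of the input calls
  expect_identical(kept[, names(calls)],
                   calls[calls$pos == 200L, , drop = FALSE],
                   ignore_attr = "row.names")
})

test_that("somatic comparison demands ref-free normal and ref-carrying tumor", {
  mk <- function(gt, genotype, ref_d, alt_d, qual = 90, pos = 500L) {
    data.frame(sample_id = "x", chrom = "chr1", pos = pos, ref = "A",
               alt = "G", type = "SNV", gt = gt, genotype = genotype,
               ref_depth = ref_d, alt_depth = alt_d, depth = ref_d + alt_d,
               gq = 99, qual = qual, pl_ref_ref = 0, pl_ref_alt = 0,
               pl_alt_alt = 0, stringsAsFactors = FALSE)
  }
  normal_hom <- mk("1/1", "alt/alt", 0L, 40L)
  tumor_het <- mk("0/1", "ref/alt", 18L, 22L)
  res <- somatic_compare(normal_hom, tumor_het)
  expect_equal(res$verdict, "somatic_rra")
  expect_equal(res$fisher_p, oracle_fisher(0, 40, 18, 22), tolerance = 1e-12)
  # a reference allele in the normal rejects the locus regardless of tumor
  expect_equal(somatic_compare(mk("0/1", "ref/alt", 20L, 20L),
                               tumor_het)$reason,
               "reference_allele_in_normal")
  # a hom-alt tumor carries no reference allele
  expect_equal(somatic_compare(normal_hom,
                               mk("1/1", "alt/alt", 0L, 40L))$reason,
               "no_reference_allele_in_tumor")
  # no-call in either member rejects with its own reason
  expect_equal(somatic_compare(normal_hom, mk("./.", NA, 0L, 0L))$reason,
               "no_call")
  # low-quality calls never reach the Fisher test
  expect_equal(somatic_compare(mk("1/1", "alt/alt", 0L, 40L, qual = 5),
                               tumor_het)$reason, "low_quality")
  # mismatched loci are a hard error
  expect_error(somatic_compare(normal_hom,
                               mk("0/1", "ref/alt", 18L, 22L, pos = 501L)),
               "different loci")
})

test_that("insignificant Fisher tables reject the candidate", {
  mk <- function(gt, genotype, ref_d, alt_d) {
    data.frame(sample_id = "x", chrom = "chr1", pos = 500L, ref = "A",
               alt = "G", type = "SNV", gt = gt, genotype = genotype,
               ref_depth = ref_d, alt_depth = alt_d, depth = ref_d + alt_d,
               gq = 99, qual = 90, pl_ref_ref = 0, pl_ref_alt = 0,
               pl_alt_alt = 0, stringsAsFactors = FALSE)
  }
  # 1 ref read of 4 in the tumor vs 0 of 4 in the normal: p = 1
  res <- somatic_compare(mk("1/1", "alt/alt", 0L, 4L),
                         mk("0/1", "ref/alt", 1L, 3L))
  expect_equal(res$verdict, "rejected")
  expect_equal(res$reason, "fisher_not_significant")
})

test_that("run_germline recovers planted reference-carrying loci per sample", {
  fx <- shared_sim()
  catalog <- fx$catalog
  gl <- data.frame(chrom = catalog$chrom, pos = catalog$pos,
                   ref = catalog$ref, alt = catalog$alt1,
                   type = catalog$type, gt = "1/1", stringsAsFactors = FALSE)
  set.seed(31)
  planted <- sort(sample(nrow(gl), 7))
  gl$gt[planted] <- rep(c("0/1", "0/0"), length.out = 7)
  sam <- withr::local_tempfile(fileext = ".sam")
  simulate_reads(fx$sim$reference, gl, sam, depth = 40L, seed = 33L)
  out_dir <- withr::local_tempdir()
  res <- run_germline(list(g1 = sam), catalog, out_dir = out_dir)
  expect_equal(nrow(res$g1), 7)
  expect_setequal(locus_key(res$g1), locus_key(gl[planted, ]))
  expect_equal(sort(unique(res$g1$zygosity)),
               c("heterozygous", "homozygous_ref"))
  expect_true(all(res$g1$rra_class %in% c("A", "B", "C")))
  # the per-sample VCF is written and round-trips the same loci
  vcf_path <- file.path(out_dir, "g1.rra.vcf")
  expect_true(file.exists(vcf_path))
  lines <- readLines(vcf_path)
  expect_equal(sum(!startsWith(lines, "#")), 7)
  expect_error(run_germline(list(sam), catalog), "named")
})

test_that("run_somatic finds planted pairs and is silent on identical pairs", {
  fx <- shared_sim()
  catalog <- fx$catalog
  base <- data.frame(chrom = catalog$chrom, pos = catalog$pos,
                     ref = catalog$ref, alt = catalog$alt1,
                     type = catalog$type, gt = "1/1",
                     stringsAsFactors = FALSE)
  set.seed(41)
  som <- sort(sample(which(catalog$class %in% c("A", "B")), 3))
  tum <- base
  tum$gt[som] <- "0/1"
  samN <- withr::local_tempfile(fileext = ".sam")
  samT <- withr::local_tempfile(fileext = ".sam")
  simulate_reads(fx$sim$reference, base, samN, depth = 40L, seed = 51L)
  simulate_reads(fx$sim$reference, tum, samT, depth = 40L, seed = 52L)
  out_dir <- withr::local_tempdir()
  res <- run_somatic(list(p1 = list(normal = samN, tumor = samT)), catalog,
                     out_dir = out_dir)
  expect_equal(nrow(res$p1), 3)
  expect_setequal(locus_key(res$p1), locus_key(catalog[som, ]))
  expect_true(all(res$p1$fisher_p < 0.01))
  tsv <- read_tsv_table(file.path(out_dir, "p1.somatic.tsv"),
                        c("chrom", "pos", "fisher_p"))
  expect_equal(nrow(tsv), 3)
  # identical tumor and normal alignments: no somatic calls
  null <- run_somatic(list(p0 = list(normal = samN, tumor = samN)), catalog)
  expect_equal(nrow(null$p0), 0)
  expect_error(run_somatic(list(p = list(normal = samN)), catalog),
               "tumor")
})
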