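# annotator: feature overlap semantics, the GERP rule, phenotype joins and
# the catalog cross-tabulation.

toy_catalog <- function(df) {
  df$alt1 <- df$alt
  class(df) <- c("rra_catalog", "data.frame")
  df
}

test_that("feature overlap uses the affected reference span", {
  catalog <- toy_catalog(data.frame(
    chrom = c("chr1", "chr1", "chr2"),
    pos = c(150L, 300L, 100L),
    ref = c("A", "ATT", "A"), alt = c("G", "A", "G"),
    type = c("SNV", "DEL", "SNV"),
    class = "A", stringsAsFactors = FALSE
  ))
  track <- data.frame(chrom = "chr1",
                      start = c(100L, 301L), end = c(200L, 302L),
                      name = c("lincRNA", "exonic"), stringsAsFactors = FALSE)
  ov <- overlap_features(catalog, track)
  expect_equal(ov[[1]], "lincRNA")
  # deletion at pos 300 (ref ATT) affects bases [300, 302): hits "exonic"
  expect_equal(ov[[2]], "exonic")
  # chromosome absent from the track: empty set
  expect_equal(ov[[3]], character(0))
})

test_that("a locus can overlap all three regulatory elements", {
  catalog <- toy_catalog(data.frame(chrom = "chr1", pos = 500L, ref = "A",
                                    alt = "G", type = "SNV", class = "B",
                                    stringsAsFactors = FALSE))
  track <- data.frame(chrom = "chr1", start = c(450L, 490L, 499L),
                      end = c(550L, 510L, 500L),
                      name = c("TFP", "DHS", "enhancer"),
                      stringsAsFactors = FALSE)
  expect_equal(overlap_features(catalog, track)[[1]],
               c("DHS", "TFP", "enhancer"))
})

test_that("insertion points must fall strictly inside a feature", {
  # insertion after POS 200: affected junction between bases 200 and 201
  catalog <- toy_catalog(data.frame(chrom = "chr1", pos = 200L, ref = "A",
                                    alt = "ATG", type = "INS", class = "A",
                                    stringsAsFactors = FALSE))
  inside <- data.frame(chrom = "chr1", start = 150L, end = 250L,
                       name = "gene", stringsAsFactors = FALSE)
  expect_equal(overlap_features(catalog, inside)[[1]], "gene")
  # feature ending exactly at the junction: not strictly inside
  left_edge <- data.frame(chrom = "chr1", start = 150L, end = 200L,
                          name = "gene", stringsAsFactors = FALSE)
  expect_equal(overlap_features(catalog, left_edge)[[1]], character(0))
  # feature starting at the junction: the POS base is outside
  right_edge <- data.frame(chrom = "chr1", start = 200L, end = 250L,
                           name = "gene", stringsAsFactors = FALSE)
  expect_equal(overlap_features(catalog, right_edge)[[1]], character(0))
})

test_that("overlap agrees with a quadratic brute-force scan", {
  set.seed(19)
  n_iv <- 600
  track <- data.frame(
    chrom = sample(c("chr1", "chr2"), n_iv, replace = TRUE),
    start = sample(0:5000, n_iv, replace = TRUE),
    name = sample(c("pc", "linc", "anti", "pseudo"), n_iv, replace = TRUE),
    stringsAsFactors = FALSE
  )
  track$end <- track$start + sample(1:200, n_iv, replace = TRUE)
  catalog <- toy_catalog(data.frame(
    chrom = sample(c("chr1", "chr2"), 60, replace = TRUE),
    pos = sample(50:5000, 60),
    ref = sample(c("A", "AT", "ATT"), 60, replace = TRUE),
    alt = "A", type = NA_character_, class = "A", stringsAsFactors = FALSE
  ))
  catalog$alt1 <- catalog$alt
  # make SNVs where ref length is 1 (A/A is not a variant; use G)
  catalog$alt[catalog$ref == "A"] <- "G"
  catalog$alt1 <- catalog$alt
  catalog$type <- classify_variant_type(catalog$ref, catalog$alt1)
  ov <- overlap_features(catalog, track)
  spans <- catalog_spans(catalog)
  for (i in seq_len(nrow(catalog))) {
    expect_equal(ov[[i]], oracle_overlap(spans$chrom[i], spans$start[i],
                                         spans$end[i], track),
                 info = paste("locus", i))
  }
})

test_that("GERP rule: strict threshold for SNVs, any-base rule for deletions", {
  catalog <- toy_catalog(data.frame(
    chrom = "chr1", pos = c(100L, 200L, 300L),
    ref = c("A", "A", "ATTG"), alt = c("G", "G", "A"),
    type = c("SNV", "SNV", "DEL"), class = "A", stringsAsFactors = FALSE
  ))
  rs <- data.frame(
    chrom = "chr1",
    start = c(99L, 199L, 300L, 301L, 302L),
    end = c(100L, 200L, 301L, 302L, 303L),
    score = c(2.5, 2.0, 1.0, 2.3, 0.1)
  )
  res <- gerp_filter(catalog, rs)
  expect_true(res[1])    # RS 2.5 > 2
  expect_false(res[2])   # RS exactly 2.0 fails the strict rule
  expect_true(res[3])    # deletion span [300,303): one base at 2.3 passes
  # position absent from the track: fails with a warning
  absent <- toy_catalog(data.frame(chrom = "chr1", pos = 900L, ref = "A",
                                   alt = "G", type = "SNV", class = "A",
                                   stringsAsFactors = FALSE))
  expect_warning(r <- gerp_filter(absent, rs), "absent")
  expect_false(r)
})

test_that("phenotype joins honor GAD Y-flags and the RegulomeDB cutoff", {
  catalog <- toy_catalog(data.frame(
    chrom = "chr1", pos = c(100L, 200L, 300L),
    ref = "A", alt = "G", type = "SNV", class = "A", stringsAsFactors = FALSE
  ))
  genes <- data.frame(chrom = "chr1", start = c(50L, 150L),
                      end = c(120L, 220L), name = c("G1", "G2"),
                      stringsAsFactors = FALSE)
  gad <- data.frame(
    gene_id = c("G1", "G1", "G1", "G2"),
    disease_class = c("CANCER", "IMMUNE", "METABOLIC", "PSYCH"),
    association = c("Y", "Y", "N", "Y"), stringsAsFactors = FALSE
  )
  omim <- data.frame(gene_id = "G2", stringsAsFactors = FALSE)
  regdb <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L),
                      score = c(3L, 4L, 1L), stringsAsFactors = FALSE)
  ph <- join_phenotypes(catalog, genes, gad, omim, regdb)
  expect_equal(ph$gad_classes, c("CANCER,IMMUNE", "PSYCH", ""))
  expect_equal(ph$omim, c(FALSE, TRUE, FALSE))
  # score 3 passes the <= 3 rule; 4 does not; 1 does
  expect_equal(ph$regdb_tf_binding, c(TRUE, FALSE, TRUE))
  # intergenic locus: no gene, no classes, no OMIM
  expect_equal(ph$genes[3], "")
})

test_that("annotation preserves the locus set and matches planted truth", {
  fx <- shared_sim()
  tracks <- simulate_tracks(fx$truth, fx$cfg)
  ann <- annotate_catalog(fx$catalog, gencode = tracks$gencode,
                          encode = tracks$encode, gerp = tracks$gerp,
                          gene_model = tracks$gene_model,
                          gad_table = tracks$gad, omim_table = tracks$omim,
                          regdb_table = tracks$regdb,
                          consequence_table = tracks$consequence)
  expect_equal(locus_key(ann), locus_key(fx$catalog))
  pl <- tracks$planted[match(locus_key(ann), locus_key(tracks$planted)), ]
  expect_equal(ann$gencode_biotypes, pl$biotype)
  expect_equal(ann$encode_elements, pl$encode_elements)
  expect_equal(ann$gerp_pass, pl$gerp_pass)
  expect_equal(ann$gad_classes, pl$gad_classes)
  expect_equal(ann$omim, pl$omim)
  expect_equal(ann$consequence, pl$consequence)
  expect_equal(ann$regulomedb_score, pl$regdb_score)
})

test_that("catalog summary conserves totals and class partitions", {
  fx <- shared_sim()
  tracks <- simulate_tracks(fx$truth, fx$cfg)
  ann <- annotate_catalog(fx$catalog, gencode = tracks$gencode,
                          encode = tracks$encode,
                          consequence_table = tracks$consequence)
  s <- summarize_catalog(ann)
  expect_equal(sum(s["Total", , ]), nrow(fx$catalog))
  # Total splits into Gencode + Intergenic
  expect_equal(s["Total", , ], s["Gencode", , ] + s["Intergenic", , ])
  # class columns sum to the catalog's class totals
  for (cl in c("A", "B", "C")) {
    expect_equal(sum(s["Total", cl, ]), sum(fx$catalog$class == cl))
  }
  # empty catalog: all zeros
  empty <- ann[0, , drop = FALSE]
  expect_true(all(summarize_catalog(empty) == 0))
})

test_that("empty tracks leave all annotations empty", {
  fx <- shared_sim()
  ann <- annotate_catalog(fx$catalog)
  expect_true(all(ann$gencode_biotypes == ""))
  expect_true(all(ann$encode_elements == ""))
  expect_true(all(ann$consequence == "none"))
  expect_true(all(is.na(ann$gerp_pass)))
})
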