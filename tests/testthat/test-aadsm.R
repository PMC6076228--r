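make_record <- function(chrom = "1", pos = 100L, ref = "A", alt = "G",
                        var_type = "SNV", gene = "GA",
                        consequence = "missense", zygosity = "het",
                        allele_freq = NA_real_, hgmd = "absent",
                        near_splice = FALSE, end = NA_integer_) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             var_type = var_type, gene = gene, consequence = consequence,
             zygosity = zygosity, allele_freq = allele_freq, hgmd = hgmd,
             near_splice = near_splice, end = end, stringsAsFactors = FALSE)
}

test_that("frequency, consequence and panel filters apply with rescues", {
  recs <- rbind(
    make_record(pos = 1L, allele_freq = 0.20),                  # common -> drop
    make_record(pos = 2L, allele_freq = 0.02, hgmd = "DM"),     # rescued
    make_record(pos = 3L, allele_freq = 0.02, hgmd = "DM?"),    # rescued
    make_record(pos = 4L, consequence = "synonymous"),          # drop
    make_record(pos = 5L, consequence = "synonymous",
                near_splice = TRUE),                            # kept
    make_record(pos = 6L, allele_freq = 0.001))                 # rare -> kept
  kept <- filter_variants(recs)
  expect_equal(kept$pos, c(2L, 3L, 5L, 6L))

  # panel manifest: exons +/- 10 bp
  panel <- data.frame(chrom = "1", start = 100L, end = 200L)
  recs2 <- rbind(make_record(pos = 95L),   # within flank
                 make_record(pos = 89L),   # outside
                 make_record(pos = 150L))  # inside
  expect_equal(filter_variants(recs2, panel = panel)$pos, c(95L, 150L))
  # CNVs overlap by span
  cnv <- make_record(pos = 10L, var_type = "CNV_DEL", end = 1000L,
                     alt = "<DEL>", consequence = "other")
  expect_equal(nrow(filter_variants(cnv, panel = panel)), 1L)
})

test_that("filtering is idempotent", {
  set.seed(9)
  recs <- do.call(rbind, lapply(1:60, function(i) {
    make_record(pos = i * 10L,
                allele_freq = sample(c(NA, 0.001, 0.02, 0.3), 1),
                consequence = sample(CONSEQUENCES <- c("missense",
                  "synonymous", "nonsense", "other"), 1),
                hgmd = sample(c("absent", "DM", "DP"), 1))
  }))
  once <- filter_variants(recs)
  twice <- filter_variants(once)
  expect_identical(once, twice)
})

test_that("phenotype-driven gene list ranks without excluding", {
  db <- make_tiny_db()
  gl <- phenotype_gene_list(c("t1", "t2", "t3"), db)
  expect_equal(gl$gene[1], "GA")
  expect_equal(gl$score[1], 3L)
  expect_equal(gl$score[gl$gene == "GB"], 0L)
  expect_equal(nrow(gl), 2L)  # zero-score genes retained

  gl0 <- phenotype_gene_list(character(), db)
  expect_true(all(gl0$score == 0L))

  expect_warning(gl2 <- phenotype_gene_list(c("t1", "nope"), db), "nope")
  expect_equal(gl2$score[gl2$gene == "GA"], 1L)

  empty_db <- make_tiny_db()
  empty_db$phenotype_gene <- empty_db$phenotype_gene[0, ]
  expect_error(phenotype_gene_list("t1", empty_db), "empty")
})

test_that("variant scores sum their evidence components", {
  # novel nonsense, curated DM, ensemble damaging
  s1 <- score_variant(make_record(consequence = "nonsense", hgmd = "DM"),
                      mpps_class = "damaging")
  expect_equal(unlist(s1[c("freq_pts", "consequence_pts", "hgmd_pts",
                           "mpps_pts")]),
               c(freq_pts = 4, consequence_pts = 4, hgmd_pts = 4,
                 mpps_pts = 2))
  expect_equal(s1$total, 14)

  # low-frequency missense, nothing else
  s2 <- score_variant(make_record(allele_freq = 0.008))
  expect_equal(s2$total, 3)
  expect_equal(s2$freq_pts, 1)
  expect_equal(s2$consequence_pts, 2)

  # whole-gene deletion scores as a CNV type regardless of curated class
  s3 <- score_variant(make_record(var_type = "CNV_DEL", alt = "<DEL>",
                                  consequence = "other"))
  expect_equal(s3$type_pts, 4)
  expect_equal(s3$consequence_pts, 0)
  s3b <- score_variant(make_record(var_type = "CNV_DEL", alt = "<DEL>",
                                   consequence = "other", hgmd = "DM"))
  expect_equal(s3b$type_pts, 4)

  # total is always the component sum
  set.seed(12)
  for (i in 1:30) {
    r <- make_record(allele_freq = sample(c(NA, runif(1)), 1),
                     var_type = sample(c("SNV", "CNV_DUP"), 1),
                     consequence = sample(c("missense", "nonsense",
                                            "synonymous", "frameshift"), 1),
                     hgmd = sample(c("absent", "DM", "DM?", "DP"), 1))
    s <- score_variant(r, sample(c(NA, "damaging", "benign"), 1))
    expect_equal(s$total, s$freq_pts + s$type_pts + s$consequence_pts +
                   s$hgmd_pts + s$mpps_pts)
  }
})

test_that("disease ranking follows the combination formula", {
  db <- make_tiny_db()
  # causal nonsense DM in GA; D01 (AD, terms t1-t3 all matched) must lead
  sv <- mendeldx:::score_variants(rbind(
    make_record(gene = "GA", consequence = "nonsense", hgmd = "DM"),
    make_record(pos = 200L, gene = "GB", allele_freq = 0.008)))
  ranked <- rank_diseases(sv, db, terms = c("t1", "t2", "t3", "t4"))
  expect_equal(ranked$disease_id[1], "D01")
  # hand check: support 12 (4+4+4), full phenotype match, AD consistent
  expect_equal(ranked$variant_support[1], 12)
  expect_equal(ranked$phenotype_match[1], 1)
  expect_true(ranked$inheritance_consistent[1])
  expect_equal(ranked$total[1], 12 * 2 + 2)
  # D02: GB support 3, match 1 (t4 of 1 term), AR with one het -> not
  # consistent: 3 * 2 + 0 = 6
  d02 <- ranked[ranked$disease_id == "D02", ]
  expect_equal(d02$total, 6)
  expect_false(d02$inheritance_consistent)

  # identical totals tie-break by disease id: D01 vs D03 share gene GA and
  # both miss all phenotype terms here
  ranked2 <- rank_diseases(sv[sv$gene == "GA", ], db, terms = character())
  expect_equal(ranked2$total[1], ranked2$total[2])
  expect_equal(ranked2$disease_id, c("D01", "D03"))
})

test_that("AR consistency needs two het hits or one hom/hemi hit", {
  db <- make_tiny_db()
  one_het <- mendeldx:::score_variants(
    make_record(gene = "GB", consequence = "nonsense"))
  expect_false(rank_diseases(one_het, db)$inheritance_consistent[
    rank_diseases(one_het, db)$disease_id == "D02"])
  two_het <- mendeldx:::score_variants(rbind(
    make_record(gene = "GB", pos = 1L, consequence = "nonsense"),
    make_record(gene = "GB", pos = 2L, consequence = "missense")))
  expect_true(rank_diseases(two_het, db)$inheritance_consistent[1])
  hom <- mendeldx:::score_variants(
    make_record(gene = "GB", zygosity = "hom", consequence = "nonsense"))
  expect_true(rank_diseases(hom, db)$inheritance_consistent[1])
})

test_that("disease ranking is invariant to variant order", {
  db <- build_gene_phenotype_db(n_genes = 40, n_diseases = 25, seed = 4)
  p <- simulate_patient(db, n_background = 40, seed = 5)
  ann <- annotation_db(freq_table = p$freq_table, hgmd_table = p$hgmd_table)
  v <- annotate(p$variants, ann)
  sv <- mendeldx:::score_variants(filter_variants(v))
  r1 <- rank_diseases(sv, db, p$terms)
  set.seed(6)
  perm <- sample(nrow(sv))
  r2 <- rank_diseases(sv[perm, ], db, p$terms)
  expect_equal(r1, r2)
})

test_that("no surviving variants still yields a (empty-list) report", {
  db <- make_tiny_db()
  common_only <- make_record(allele_freq = 0.4)
  rep <- diagnose(common_only, "t1", db, patient_id = "none",
                  out_dir = withr::local_tempdir(), timestamp = "T0")
  expect_equal(nrow(rep$diseases), 0L)
  expect_equal(nrow(rep$variants), 0L)
  expect_true(file.exists(rep$paths[["html"]]))
})

test_that("reports include every ranked disease and round-trip via JSON", {
  db <- build_gene_phenotype_db(n_genes = 40, n_diseases = 25, seed = 14)
  p <- simulate_patient(db, n_background = 30, seed = 15)
  ann <- annotation_db(freq_table = p$freq_table, hgmd_table = p$hgmd_table)
  dir <- withr::local_tempdir()
  rep <- diagnose(p$variants, p$terms, db, annot = ann, patient_id = "pt1",
                  out_dir = dir, timestamp = "2026-01-01T00:00:00")
  html <- paste(readLines(rep$paths[["html"]]), collapse = "\n")
  for (nm in rep$diseases$name) expect_true(grepl(nm, html, fixed = TRUE))
  # every surviving variant appears exactly once
  expect_equal(nrow(rep$variants),
               nrow(filter_variants(annotate(p$variants, ann))))
  expect_equal(anyDuplicated(with(rep$variants,
                                  paste(chrom, pos, ref, alt))), 0L)

  back <- read_report(rep$paths[["json"]])
  expect_equal(back$patient_id, "pt1")
  expect_equal(back$diseases$disease_id, rep$diseases$disease_id)
  expect_equal(back$diseases$total, rep$diseases$total)
  expect_equal(back$variants$score_total, rep$variants$score_total)
  expect_equal(back$provenance$timestamp, "2026-01-01T00:00:00")

  # deterministic given a timestamp override
  dir2 <- withr::local_tempdir()
  rep2 <- diagnose(p$variants, p$terms, db, annot = ann, patient_id = "pt1",
                   out_dir = dir2, timestamp = "2026-01-01T00:00:00")
  expect_identical(readLines(rep$paths[["json"]]),
                   readLines(rep2$paths[["json"]]))
})

test_that("a batch of patients produces one report pair each", {
  db <- build_gene_phenotype_db(n_genes = 40, n_diseases = 25, seed = 20)
  dir <- withr::local_tempdir()
  n_pat <- 20
  for (k in seq_len(n_pat)) {
    p <- simulate_patient(db, n_background = 10, seed = 20 + k)
    ann <- annotation_db(freq_table = p$freq_table, hgmd_table = p$hgmd_table)
    diagnose(p$variants, p$terms, db, annot = ann,
             patient_id = sprintf("P%03d", k), out_dir = dir,
             timestamp = "T0")
  }
  expect_equal(length(list.files(dir, pattern = "\\.json$")), n_pat)
  expect_equal(length(list.files(dir, pattern = "\\.html$")), n_pat)
})
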