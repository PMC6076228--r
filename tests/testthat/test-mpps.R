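test_that("raw scores map to categories per the threshold table", {
  expect_equal(map_raw_to_category("SIFT", NA), "unclassified")
  expect_equal(map_raw_to_category("SIFT", 0.01), "damaging")
  expect_equal(map_raw_to_category("SIFT", 0.96), "benign")
  # between the midpoint and the benign cut-off: softened, not benign
  expect_equal(map_raw_to_category("SIFT", 0.80), "possibly_benign")
  expect_equal(map_raw_to_category("SIFT", 0.30), "possibly_damaging")
  expect_equal(map_raw_to_category("CADD", c(25, 5, 18, 12)),
               c("damaging", "benign", "possibly_damaging", "possibly_benign"))
  expect_error(map_raw_to_category("NotATool", 1), "unknown tool")
})

test_that("category points follow the 10/5/0/-5/-10 scale", {
  expect_equal(category_points("damaging"), 10L)
  expect_equal(category_points("possibly_damaging"), 5L)
  expect_equal(category_points("unclassified"), 0L)
  expect_equal(category_points("possibly_benign"), -5L)
  expect_equal(category_points("benign"), -10L)
  expect_error(category_points("meh"), "invalid category")
})

test_that("simulated raw scores invert to their generating category", {
  for (tl in mpps_tools()) {
    for (cat in c("damaging", "possibly_damaging", "possibly_benign", "benign")) {
      expect_equal(map_raw_to_category(tl, raw_for(tl, cat)), cat,
                   label = paste(tl, cat))
    }
  }
})

test_that("region weights count correct predictions per class", {
  # 10 pathogenic variants in one bin; SIFT correct on 9
  n <- 10
  truth <- data.frame(chrom = "1", pos = seq_len(n) * 100L,
                      ref = "A", alt = "G",
                      label = "pathogenic", stringsAsFactors = FALSE)
  truth <- rbind(truth,
                 data.frame(chrom = "1", pos = 5000L + seq_len(n) * 100L,
                            ref = "A", alt = "G", label = "neutral",
                            stringsAsFactors = FALSE))
  prof <- truth[, 1:4]
  prof$SIFT <- c(rep(raw_for("SIFT", "damaging"), 9),
                 raw_for("SIFT", "benign"),
                 rep(raw_for("SIFT", "benign"), 10))
  w <- suppressWarnings(fit_region_weights(truth, prof))
  g <- w[w$region == "genome" & w$tool == "SIFT", ]
  expect_equal(g$w_dmg, 0.9)
  expect_equal(g$w_ben, 1.0)
  expect_equal(g$n_dmg, 10L)

  # bins below min_n emit no region row: lookups fall back to genome-wide
  expect_equal(unique(w$region), "genome")
  rw <- mendeldx:::region_weights(w, "7:3")
  expect_equal(rw$w_dmg[rw$tool == "SIFT"], 0.9)
})

test_that("weight fitting validates inputs and handles one-class truth", {
  expect_error(fit_region_weights(NULL, NULL), "empty")
  truth <- data.frame(chrom = "1", pos = 1:4 * 100L, ref = "A", alt = "G",
                      label = "pathogenic", stringsAsFactors = FALSE)
  prof <- truth[, 1:4]
  prof$SIFT <- raw_for("SIFT", "damaging")
  expect_warning(w <- fit_region_weights(truth, prof), "single class")
  expect_equal(w$w_ben[w$tool == "SIFT" & w$region == "genome"], 0.5)
  expect_equal(w$w_dmg[w$tool == "SIFT" & w$region == "genome"], 1.0)
})

test_that("weight fitting is deterministic for a fixed seed", {
  truth <- simulate_truth_set(150, 150, seed = 5)
  prof <- simulate_tool_profiles(truth, tool_accuracy_spec(), seed = 6)
  w1 <- fit_region_weights(truth, prof, seed = 3, subsample = 0.8)
  w2 <- fit_region_weights(truth, prof, seed = 3, subsample = 0.8)
  expect_identical(as.data.frame(w1), as.data.frame(w2))
})

test_that("trio selection ranks by weight with alphabetical tie-break", {
  w <- make_weights(
    w_dmg = c(SIFT = 0.99, CADD = 0.98, DANN = 0.97, LRT = 0.96,
              FATHMM = 0.95, VEST3 = 0.94),
    w_ben = c(MetaSVM = 0.99, MetaLR = 0.98, PROVEAN = 0.97))
  tr1 <- select_trios(w, round = 1)
  expect_equal(tr1$dmg_tools, c("SIFT", "CADD", "DANN"))
  expect_equal(tr1$ben_tools, c("MetaSVM", "MetaLR", "PROVEAN"))
  tr2 <- select_trios(w, round = 2)
  expect_equal(tr2$dmg_tools, c("LRT", "FATHMM", "VEST3"))
  # remaining tools tie at 0.5: alphabetical (byte) order decides
  rest <- sort(setdiff(setdiff(mpps_tools(), mpps_tools(TRUE)),
                       c("SIFT", "CADD", "DANN", "LRT", "FATHMM", "VEST3")),
               method = "radix")
  tr3 <- select_trios(w, round = 3)
  expect_equal(tr3$dmg_tools, rest[1:3])
  expect_error(select_trios(w, round = 6), "exhausts")
  # conservation scores are not trio candidates by default
  for (r in 1:5) {
    tr <- select_trios(w, round = r)
    expect_false(any(mpps_tools(TRUE) %in% c(tr$dmg_tools, tr$ben_tools)))
  }
})

test_that("trio scores are weight-normalized category points", {
  # all three damaging with equal weights
  w <- make_weights(default = 0.8)
  prof <- make_profile(SIFT = "damaging", CADD = "damaging", DANN = "damaging")
  expect_equal(trio_score(prof, c("SIFT", "CADD", "DANN"), w, "dmg"), 10)
  # hand arithmetic: weights (1, .5, .5), categories (damaging, benign,
  # unclassified) -> (10*1 - 10*.5 + 0*.5) / 2 = 2.5
  w2 <- make_weights(w_dmg = c(SIFT = 1, CADD = 0.5, DANN = 0.5))
  prof2 <- make_profile(SIFT = "damaging", CADD = "benign")
  expect_equal(trio_score(prof2, c("SIFT", "CADD", "DANN"), w2, "dmg"), 2.5)
  # all benign, any positive weights
  w3 <- make_weights(w_ben = c(SIFT = 0.9, CADD = 0.2, DANN = 0.4))
  prof3 <- make_profile(SIFT = "benign", CADD = "benign", DANN = "benign")
  expect_equal(trio_score(prof3, c("SIFT", "CADD", "DANN"), w3, "ben"), -10)
  # all-zero weights: defined as 0
  w4 <- make_weights(w_dmg = c(SIFT = 0, CADD = 0, DANN = 0))
  expect_equal(trio_score(prof3, c("SIFT", "CADD", "DANN"), w4, "dmg"), 0)
})

test_that("trio_score matches a brute-force oracle on random instances", {
  set.seed(77)
  tools <- setdiff(mpps_tools(), mpps_tools(TRUE))
  cats <- c("damaging", "possibly_damaging", "unclassified",
            "possibly_benign", "benign")
  for (i in 1:300) {
    trio <- sample(tools, 3)
    w <- runif(3)
    cat_i <- sample(cats, 3, replace = TRUE)
    # independent oracle: explicit loop over the definition
    num <- 0; den <- 0
    pts_tab <- c(damaging = 10, possibly_damaging = 5, unclassified = 0,
                 possibly_benign = -5, benign = -10)
    for (k in 1:3) {
      num <- num + w[k] * pts_tab[[cat_i[k]]]
      den <- den + w[k]
    }
    expected <- if (den == 0) 0 else num / den

    wt <- make_weights(w_dmg = setNames(w, trio))
    args <- setNames(as.list(cat_i[cat_i != "unclassified"]),
                     trio[cat_i != "unclassified"])
    prof <- if (length(args)) do.call(make_profile, args) else
      make_profile(SIFT = "damaging")[, 1:4]
    expect_equal(trio_score(prof, trio, wt, "dmg"), expected,
                 tolerance = 1e-12)
  }
})

test_that("upgrading a trio member toward damaging never lowers the score", {
  set.seed(78)
  ladder <- c("benign", "possibly_benign", "unclassified",
              "possibly_damaging", "damaging")
  tools <- c("SIFT", "CADD", "DANN")
  for (i in 1:50) {
    w <- make_weights(w_dmg = setNames(runif(3, 0.05, 1), tools))
    cat_i <- sample(ladder, 3, replace = TRUE)
    base_args <- setNames(as.list(cat_i), tools)
    base <- trio_score(do.call(make_profile, base_args), tools, w, "dmg")
    k <- sample(3, 1)
    pos <- match(cat_i[k], ladder)
    if (pos == length(ladder)) next
    up <- cat_i; up[k] <- ladder[pos + 1]
    upscore <- trio_score(do.call(make_profile, setNames(as.list(up), tools)),
                          tools, w, "dmg")
    expect_gte(upscore, base - 1e-12)
  }
})

test_that("conservation bonus adds one at conserved positions, clamped", {
  expect_equal(conservation_bonus(5, gerp = 4, phylop = 2.5), 6)
  expect_equal(conservation_bonus(5, gerp = 1, phylop = 2.5), 5)
  expect_equal(conservation_bonus(5, gerp = NA, phylop = 2.5), 5)
  expect_equal(conservation_bonus(10, gerp = 4, phylop = 2.5), 10)
  expect_equal(conservation_bonus(-3, gerp = 4, phylop = 2.5), -2)
})

test_that("classification agrees at round 1 under unanimity", {
  w <- make_weights(default = 0.9)
  res <- classify_variant(uniform_profile("damaging"), w)
  expect_equal(res$classification, "damaging")
  expect_equal(res$round_used, 1L)
  expect_false(res$mis_classified)
  expect_equal(res$score_dmg, 10)
  expect_equal(res$score_ben, 10)

  res_b <- classify_variant(uniform_profile("benign"), w)
  expect_equal(res_b$classification, "benign")
  expect_false(res_b$mis_classified)
  expect_true(res_b$score_dmg <= -1 && res_b$score_ben <= -1)
})

test_that("persistent trio disagreement reports mis-classified with fallback", {
  # weights descending in byte order on the damaging side and ascending on
  # the benign side; the two rankings are exact reverses, so round-r trios
  # are byte-order ranks 3(r-1)+1..3r from opposite ends
  tools <- setdiff(mpps_tools(), mpps_tools(TRUE))
  st <- sort(tools, method = "radix")
  wd <- setNames(seq(0.95, 0.50, length.out = 15), st)
  wb <- setNames(seq(0.50, 0.95, length.out = 15), st)
  w <- make_weights(w_dmg = wd, w_ben = wb)
  # damaging-rank top 6 say damaging, bottom 6 say benign, middle 3 silent:
  # rounds 1/2 disagree, round 3 is indeterminate, rounds 4/5 disagree with
  # the sides swapped -> never an agreement
  args <- c(setNames(as.list(rep("damaging", 6)), st[1:6]),
            setNames(as.list(rep("benign", 6)), st[10:15]))
  prof <- do.call(make_profile, args)
  res <- classify_variant(prof, w)
  expect_true(res$mis_classified)
  expect_equal(res$round_used, 5L)
  # fallback from the round-1 scores (+10 damaging side, -10 benign side):
  # zero mean falls to the conservative side
  expect_equal(res$score_dmg, 10)
  expect_equal(res$score_ben, -10)
  expect_equal(res$classification, "benign")

  # all predictors absent: scores 0 at every round, still classified
  empty_prof <- make_profile(SIFT = "damaging")[, 1:4]
  res0 <- classify_variant(empty_prof, w)
  expect_true(res0$mis_classified)
  expect_equal(res0$score_dmg, 0)
  expect_equal(res0$classification, "benign")
})

test_that("batch prediction is a bijection and matches the scalar path", {
  truth <- simulate_truth_set(80, 80, seed = 21)
  prof <- simulate_tool_profiles(truth, tool_accuracy_spec(
    sensitivity = 0.9, specificity = 0.85, missing_rate = 0.3,
    possibly_rate = 0.2), seed = 22)
  w <- fit_region_weights(truth, prof, min_n = 20)
  res <- predict_batch(prof, w)
  expect_equal(nrow(res), nrow(prof))
  for (i in c(1, 17, 53, 160)) {
    single <- classify_variant(prof[i, , drop = FALSE], w)
    expect_equal(res$MPPS_CLASS[i], single$classification)
    expect_equal(res$MPPS_SCORE_DMG[i], single$score_dmg)
    expect_equal(res$MPPS_SCORE_BEN[i], single$score_ben)
    expect_equal(res$MPPS_MISCLASS[i], single$mis_classified)
    expect_equal(res$MPPS_ROUND[i], single$round_used)
  }
  # empty batch
  expect_equal(nrow(predict_batch(prof[0, ], w)), 0L)
  # agreed classifications have same-sign scores
  ok <- !res$MPPS_MISCLASS
  expect_true(all(sign(res$MPPS_SCORE_DMG[ok]) == sign(res$MPPS_SCORE_BEN[ok])))
  expect_true(all(abs(res$MPPS_SCORE_DMG) <= 10 + 1e-9))
})

test_that("the mpps S3 surface fits, prints, predicts and serializes", {
  truth <- simulate_truth_set(120, 120, seed = 30)
  prof <- simulate_tool_profiles(truth, tool_accuracy_spec(), seed = 31)
  fit <- mpps(truth, prof)
  expect_s3_class(fit, "mpps")
  expect_output(print(fit), "round-1 damaging trio")
  expect_output(print(summary(fit)), "Genome-wide predictor weights")
  expect_s3_class(coef(fit), "mpps_weights")
  res <- predict(fit, prof)
  expect_equal(nrow(res), nrow(prof))

  path <- file.path(withr::local_tempdir(), "w.tsv")
  write_region_weights(coef(fit), path)
  back <- read_region_weights(path)
  expect_equal(back$w_dmg, coef(fit)$w_dmg, tolerance = 1e-9)
  expect_equal(attr(back, "bin_size"), 1e7)
  res2 <- predict_batch(prof, back)
  expect_equal(res2$MPPS_CLASS, res$MPPS_CLASS)
})

test_that("MPPS results serialize to TSV and VCF INFO keys", {
  truth <- simulate_truth_set(30, 30, seed = 41)
  prof <- simulate_tool_profiles(truth, tool_accuracy_spec(), seed = 42)
  w <- suppressWarnings(fit_region_weights(truth, prof))
  res <- predict_batch(prof, w)
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "res.tsv"); vcf <- file.path(dir, "res.vcf")
  write_mpps_tsv(prof, res, tsv)
  tab <- read.delim(tsv, check.names = FALSE)
  expect_equal(nrow(tab), 60L)
  expect_true(all(c("MPPS_CLASS", "MPPS_SCORE_DMG") %in% names(tab)))
  write_mpps_vcf(prof, res, vcf)
  back <- read_vcf(vcf)
  expect_equal(mendeldx:::parse_info(back$info, "MPPS_CLASS"), res$MPPS_CLASS)
})
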