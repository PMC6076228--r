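#' The 17 deleteriousness predictors combined by MPPS
#'
#' Canonical names of the predictors whose precomputed raw scores MPPS
#' ensembles: 8 functional prediction scores (Polyphen2_HDIV,
#' Polyphen2_HVAR, MutationTaster, SIFT, LRT, FATHMM, MutationAssessor,
#' M-CAP), 7 further scores (PROVEAN, VEST3, MetaSVM, MetaLR, fathmm-MKL,
#' CADD, DANN) and 2 conservation scores (GERP++, phyloP100way). By
#' default the two conservation scores are reserved for the conservation
#' bonus and excluded from predictor trios.
#'
#' @param conservation if `TRUE`, return only the 2 conservation scores;
#'   if `FALSE` (default), all 17.
#' @return character vector of tool names.
#' @export
mpps_tools <- function(conservation = FALSE) {
  tools <- c("Polyphen2_HDIV", "Polyphen2_HVAR", "MutationTaster", "SIFT",
             "LRT", "FATHMM", "MutationAssessor", "M-CAP", "PROVEAN",
             "VEST3", "MetaSVM", "MetaLR", "fathmm-MKL", "CADD", "DANN",
             "GERP++", "phyloP100way")
  if (conservation) tools[16:17] else tools
}

CATEGORIES <- c("damaging", "possibly_damaging", "unclassified",
                "possibly_benign", "benign")

#' Default per-tool category thresholds
#'
#' Raw predictor scores are mapped to five ordered categories
#' (damaging, possibly damaging, unclassified, possibly benign, benign)
#' via two cut-offs per tool: scores at or past the damaging cut-off are
#' `damaging`, at or past the benign cut-off `benign`, and scores in
#' between are split at the midpoint into the two "possibly" categories.
#' `direction` records whether larger (`higher`) or smaller (`lower`)
#' raw scores indicate damage. Cut-offs follow each tool's published
#' recommendation where one exists (e.g. SIFT 0.05, PolyPhen-2 HDIV
#' 0.957/0.452, CADD phred 20, M-CAP 0.025, PROVEAN -2.5); all are
#' user-overridable.
#'
#' @return `data.frame` with columns `tool`, `direction`, `dmg`, `ben`.
#' @export
mpps_thresholds <- function() {
  data.frame(
    tool = mpps_tools(),
    direction = c("higher", "higher", "higher", "lower", "lower", "lower",
                  "higher", "higher", "lower", "higher", "higher", "higher",
                  "higher", "higher", "higher", "higher", "higher"),
    dmg = c(0.957, 0.909, 0.90, 0.05, 0.001, -1.5, 3.5, 0.025, -2.5,
            0.80, 0.50, 0.75, 0.90, 20, 0.98, 4.0, 2.7),
    ben = c(0.452, 0.446, 0.10, 0.95, 0.50, 1.5, 1.9, 0.005, 0.0,
            0.30, -0.50, 0.25, 0.30, 10, 0.50, 2.0, 1.0),
    stringsAsFactors = FALSE
  )
}

#' Map a raw predictor score to a category
#'
#' Deterministic mapping per the threshold table; an absent (NA) raw score
#' is `unclassified`.
#'
#' @param tool canonical tool name (see [mpps_tools()]).
#' @param raw numeric vector of raw scores (NA = no prediction).
#' @param thresholds threshold table, default [mpps_thresholds()].
#' @return character vector of categories.
#' @export
#' @examples
#' map_raw_to_category("SIFT", c(0.01, 0.8, NA))
map_raw_to_category <- function(tool, raw, thresholds = mpps_thresholds()) {
  i <- match(tool, thresholds$tool)
  if (is.na(i)) stop("unknown tool name: ", tool)
  d <- thresholds$dmg[i]; b <- thresholds$ben[i]
  m <- (d + b) / 2
  raw <- as.numeric(raw)
  if (thresholds$direction[i] == "lower") {
    out <- ifelse(raw <= d, "damaging",
           ifelse(raw >= b, "benign",
           ifelse(raw <= m, "possibly_damaging", "possibly_benign")))
  } else {
    out <- ifelse(raw >= d, "damaging",
           ifelse(raw <= b, "benign",
           ifelse(raw >= m, "possibly_damaging", "possibly_benign")))
  }
  out[is.na(raw)] <- "unclassified"
  out
}

#' Points awarded to a prediction category
#'
#' The categorical scale underlying MPPS scores: damaging 10, possibly
#' damaging 5, unclassified 0, possibly benign -5, benign -10.
#'
#' @param category character vector of categories.
#' @return integer vector of points.
#' @export
category_points <- function(category) {
  pts <- c(damaging = 10L, possibly_damaging = 5L, unclassified = 0L,
           possibly_benign = -5L, benign = -10L)
  bad <- setdiff(unique(category), names(pts))
  if (length(bad)) stop("invalid category: ", paste(bad, collapse = ", "))
  unname(pts[category])
}

# Category matrix (variants x tools) from a profile table holding raw-score
# columns. Tools with no column are all-unclassified.
categorize_profiles <- function(profiles, tools = mpps_tools(),
                                thresholds = mpps_thresholds()) {
  n <- nrow(profiles)
  out <- matrix("unclassified", nrow = n, ncol = length(tools),
                dimnames = list(NULL, tools))
  for (tl in intersect(tools, names(profiles))) {
    out[, tl] <- map_raw_to_category(tl, profiles[[tl]], thresholds)
  }
  out
}

#' Genomic bin id for region-wise predictor weights
#'
#' Variants are binned into fixed-size windows keyed by
#' `chrom:floor((pos-1)/bin_size)`; the pooled genome-wide bin is
#' `"genome"`.
#'
#' @param chrom,pos chromosome labels and 1-based positions.
#' @param bin_size bin width in bp (default 10 Mb).
#' @return character vector of region ids.
#' @export
region_of <- function(chrom, pos, bin_size = 1e7) {
  paste0(norm_chrom(chrom), ":", (as.numeric(pos) - 1) %/% bin_size)
}

side_call <- function(categories, side) {
  if (side == "dmg") {
    categories %in% c("damaging", "possibly_damaging")
  } else {
    categories %in% c("benign", "possibly_benign")
  }
}

#' Fit per-region predictor weights from a labeled truth set
#'
#' The weight of a predictor in a region is its fraction of correct
#' predictions there, computed separately on the two truth classes:
#' `w_dmg` is the fraction of truth-pathogenic variants with a prediction
#' in the region that the tool calls on the damaging side (damaging or
#' possibly damaging), `w_ben` the analogue on truth-neutral variants and
#' the benign side. Regions with fewer than `min_n` backing variants for
#' either class fall back to the pooled genome-wide row, which is always
#' present.
#'
#' @param truth `data.frame` with columns `chrom,pos,ref,alt,label`
#'   (label `pathogenic` or `neutral`); keys must be unique.
#' @param profiles annotated variant table containing raw-score columns
#'   for (a subset of) the 17 tools, covering every truth variant.
#' @param bin_size region width in bp (default 10 Mb).
#' @param min_n minimum truth variants per class for a region-specific
#'   row (default 50).
#' @param seed optional; only consulted when `subsample < 1`.
#' @param subsample fraction of truth variants to sample (without
#'   replacement) before fitting; default 1 uses all.
#' @param thresholds category threshold table.
#' @return a `data.frame` of class `mpps_weights` with columns
#'   `region, tool, w_dmg, w_ben, n_dmg, n_ben`; attribute `bin_size`.
#' @export
fit_region_weights <- function(truth, profiles, bin_size = 1e7, min_n = 50,
                               seed = NULL, subsample = 1,
                               thresholds = mpps_thresholds()) {
  if (is.null(truth) || !nrow(truth)) stop("truth set is empty")
  stopifnot_cols(truth, c("chrom", "pos", "ref", "alt", "label"), "truth")
  bad <- setdiff(unique(truth$label), c("pathogenic", "neutral"))
  if (length(bad)) stop("invalid truth label(s): ", paste(bad, collapse = ", "))
  tkey <- variant_key(truth$chrom, truth$pos, truth$ref, truth$alt)
  if (anyDuplicated(tkey)) stop("duplicate keys in truth set")
  pkey <- variant_key(profiles$chrom, profiles$pos, profiles$ref, profiles$alt)
  idx <- match(tkey, pkey)
  if (anyNA(idx)) {
    stop("truth variant without a prediction profile: ", tkey[which(is.na(idx))[1]])
  }
  if (subsample < 1) {
    keep <- with_seed(seed, sort(sample(length(tkey),
                                        max(1, round(subsample * length(tkey))))))
    truth <- truth[keep, , drop = FALSE]
    idx <- idx[keep]
  }
  prof <- profiles[idx, , drop = FALSE]
  tools <- mpps_tools()
  cats <- categorize_profiles(prof, tools, thresholds)
  region <- region_of(truth$chrom, truth$pos, bin_size)
  is_path <- truth$label == "pathogenic"

  one_class <- !any(is_path) || all(is_path)
  if (one_class) {
    warning("truth set contains a single class; weights for the missing ",
            "class set to the uninformative prior 0.5")
  }

  weight_rows <- function(sel, reg_label) {
    # sel: logical row selector for this region
    vapply(tools, function(tl) {
      cat_t <- cats[sel, tl]
      lp <- is_path[sel]
      has <- cat_t != "unclassified"
      n_d <- sum(lp & has); n_b <- sum(!lp & has)
      w_d <- if (n_d > 0) sum(lp & has & side_call(cat_t, "dmg")) / n_d else 0.5
      w_b <- if (n_b > 0) sum(!lp & has & side_call(cat_t, "ben")) / n_b else 0.5
      c(w_d, w_b, n_d, n_b)
    }, numeric(4))
  }

  build <- function(sel, reg_label) {
    m <- weight_rows(sel, reg_label)
    data.frame(region = reg_label, tool = tools, w_dmg = m[1, ],
               w_ben = m[2, ], n_dmg = as.integer(m[3, ]),
               n_ben = as.integer(m[4, ]), stringsAsFactors = FALSE,
               row.names = NULL)
  }

  out <- build(rep(TRUE, nrow(truth)), "genome")
  for (reg in sort(unique(region))) {
    sel <- region == reg
    if (sum(is_path & sel) >= min_n && sum(!is_path & sel) >= min_n) {
      out <- rbind(out, build(sel, reg))
    }
  }
  rownames(out) <- NULL
  structure(out, bin_size = bin_size, min_n = min_n,
            class = c("mpps_weights", "data.frame"))
}

# Per-tool weights for one region, falling back to the genome-wide row.
region_weights <- function(weights, region) {
  g <- weights[weights$region == "genome", , drop = FALSE]
  r <- weights[weights$region == region, , drop = FALSE]
  if (nrow(r)) {
    i <- match(g$tool, r$tool)
    hit <- !is.na(i)
    g[hit, c("w_dmg", "w_ben", "n_dmg", "n_ben")] <-
      r[i[hit], c("w_dmg", "w_ben", "n_dmg", "n_ben")]
  }
  g
}

#' Write / read a region weight table as headered TSV
#'
#' @param weights an `mpps_weights` table from [fit_region_weights()].
#' @param path TSV path. A `#bin_size=` comment line preserves the bin
#'   width.
#' @return `write_region_weights`: the path, invisibly;
#'   `read_region_weights`: the weight table.
#' @export
write_region_weights <- function(weights, path) {
  write_atomic(function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines(sprintf("#bin_size=%d\t#min_n=%d",
                       as.integer(attr(weights, "bin_size") %||% 1e7),
                       as.integer(attr(weights, "min_n") %||% 50)), con)
    write.table(weights, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }, path)
}

#' @rdname write_region_weights
#' @export
read_region_weights <- function(path) {
  first <- readLines(path, n = 1)
  bin_size <- 1e7; min_n <- 50
  if (startsWith(first, "#bin_size=")) {
    parts <- strsplit(first, "\t", fixed = TRUE)[[1]]
    bin_size <- as.numeric(sub("#bin_size=", "", parts[1]))
    if (length(parts) > 1) min_n <- as.integer(sub("#min_n=", "", parts[2]))
  }
  w <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                  check.names = FALSE)
  stopifnot_cols(w, c("region", "tool", "w_dmg", "w_ben"), "weight table")
  if (!"genome" %in% w$region) stop("weight table lacks the genome-wide fallback row")
  structure(w, bin_size = bin_size, min_n = min_n,
            class = c("mpps_weights", "data.frame"))
}

#' Select the predictor trios for a round
#'
#' Ranks candidate predictors by their regional weight — `w_dmg` for the
#' damaging side, `w_ben` for the benign side — descending, ties broken
#' alphabetically by tool name, and returns the 3 tools at ranks
#' `3(round-1)+1 ... 3*round` on each side. Round 1 is therefore the 3
#' most reliable tools per side; later rounds walk down the ranking in
#' non-overlapping triples. The two conservation scores are excluded from
#' candidacy unless `include_conservation = TRUE`.
#'
#' @param weights `mpps_weights` table.
#' @param region region id ([region_of()]); unknown regions use the
#'   genome-wide fallback.
#' @param round integer >= 1; errors when the ranked list is exhausted
#'   (round > 5 with the 15 default candidates).
#' @param include_conservation allow GERP++/phyloP100way in trios.
#' @return list with `round`, `dmg_tools`, `ben_tools` (3 names each).
#' @export
select_trios <- function(weights, region = "genome", round = 1,
                         include_conservation = FALSE) {
  if (round < 1) stop("round must be >= 1")
  candidates <- mpps_tools()
  if (!include_conservation) {
    candidates <- setdiff(candidates, mpps_tools(conservation = TRUE))
  }
  rw <- region_weights(weights, region)
  rw <- rw[rw$tool %in% candidates, , drop = FALSE]
  idx <- (3 * (round - 1) + 1):(3 * round)
  if (max(idx) > nrow(rw)) {
    stop("round ", round, " exhausts the ranked predictor list (",
         nrow(rw), " candidates)")
  }
  # ties broken by tool name in C (byte) order, independent of locale
  rank_side <- function(w) {
    rw$tool[order(-w, match(rw$tool, sort(rw$tool, method = "radix")))]
  }
  list(round = as.integer(round),
       dmg_tools = rank_side(rw$w_dmg)[idx],
       ben_tools = rank_side(rw$w_ben)[idx])
}

#' Weighted trio score for one variant
#'
#' The score of a trio is the weight-normalized sum of the member tools'
#' category points: `sum(w_i * p_i) / sum(w_i)`, which stays in
#' \[-10, 10\] for any non-negative weights; if all three weights are zero
#' the score is 0. Absent predictions contribute 0 points but keep their
#' weight in the denominator.
#'
#' @param profile one-row annotated variant (raw-score columns) or a named
#'   numeric vector of raw scores.
#' @param trio 3 canonical tool names.
#' @param weights `mpps_weights` table.
#' @param side `"dmg"` (use `w_dmg`) or `"ben"` (use `w_ben`).
#' @param region region id for the weight lookup.
#' @param thresholds category threshold table.
#' @return a single score in \[-10, 10\].
#' @export
trio_score <- function(profile, trio, weights, side = c("dmg", "ben"),
                       region = "genome", thresholds = mpps_thresholds()) {
  side <- match.arg(side)
  if (length(trio) != 3L || anyDuplicated(trio)) {
    stop("trio must be 3 distinct tool names")
  }
  bad <- setdiff(trio, mpps_tools())
  if (length(bad)) stop("unknown tool name: ", paste(bad, collapse = ", "))
  if (is.numeric(profile)) profile <- as.data.frame(as.list(profile), check.names = FALSE)
  raw <- vapply(trio, function(tl) {
    if (tl %in% names(profile)) as.numeric(profile[[tl]][1]) else NA_real_
  }, numeric(1))
  pts <- category_points(vapply(trio, function(tl) {
    map_raw_to_category(tl, raw[[tl]], thresholds)
  }, ""))
  rw <- region_weights(weights, region)
  w <- rw[[if (side == "dmg") "w_dmg" else "w_ben"]][match(trio, rw$tool)]
  weighted_points(pts, w)
}

# Core arithmetic shared by trio_score and the batch classifier.
weighted_points <- function(points, w) {
  sw <- sum(w)
  if (sw == 0) 0 else sum(w * points) / sw
}

#' Conservation bonus
#'
#' A trio score gets +1 (clamped at +10) when the variant sits at a
#' conserved position, i.e. both conservation scores reach their
#' thresholds; an absent conservation score on either side means not
#' conserved.
#'
#' @param score trio score(s) in \[-10, 10\].
#' @param gerp,phylop raw GERP++ / phyloP100way scores (NA = absent).
#' @param gerp_threshold,phylop_threshold conservation cut-offs
#'   (defaults 2.0 and 1.6).
#' @return adjusted score(s).
#' @export
#' @examples
#' conservation_bonus(5, gerp = 4.1, phylop = 2.5)   # 6
#' conservation_bonus(10, gerp = 4.1, phylop = 2.5)  # clamped at 10
conservation_bonus <- function(score, gerp, phylop, gerp_threshold = 2.0,
                               phylop_threshold = 1.6) {
  conserved <- !is.na(gerp) & !is.na(phylop) &
    gerp >= gerp_threshold & phylop >= phylop_threshold
  ifelse(conserved, pmin(score + 1, 10), score)
}

is_conserved <- function(profile, gerp_threshold = 2.0, phylop_threshold = 1.6) {
  g <- if ("GERP++" %in% names(profile)) as.numeric(profile[["GERP++"]]) else NA_real_
  p <- if ("phyloP100way" %in% names(profile)) as.numeric(profile[["phyloP100way"]]) else NA_real_
  !is.na(g) & !is.na(p) & g >= gerp_threshold & p >= phylop_threshold
}

#' Classify one variant with the iterative trio-agreement protocol
#'
#' For rounds r = 1, 2, ...: select the round-r damaging and benign trios,
#' compute both weighted trio scores, add the conservation bonus to each,
#' and read each side's verdict from its score sign (score >= +1 is a
#' damaging verdict, <= -1 benign, anything in (-1, 1) indeterminate). If
#' the two sides agree the classification is reported with
#' `mis_classified = FALSE` and the round recorded. If no round agrees
#' before the ranked predictor list is exhausted, the variant is reported
#' mis-classified, and a fallback classification is still emitted from
#' the sign of the mean of the two round-1 scores (positive mean:
#' damaging; otherwise benign), so every variant receives a result.
#'
#' @param profile one-row annotated variant with raw-score columns.
#' @param weights `mpps_weights` table.
#' @param region region id; defaults to the variant's bin when `profile`
#'   has `chrom`/`pos`, else the genome-wide row.
#' @param thresholds category threshold table.
#' @param gerp_threshold,phylop_threshold conservation cut-offs.
#' @param max_rounds cap on agreement rounds (default 5, exhausting the 15
#'   candidate predictors).
#' @param include_conservation allow conservation scores in trios.
#' @return list: `score_dmg`, `score_ben` (from the agreeing round, or
#'   round 1 for mis-classified variants), `classification`
#'   (`"damaging"`/`"benign"`), `mis_classified`, `round_used`,
#'   `dmg_tools`, `ben_tools`, `conserved`.
#' @export
classify_variant <- function(profile, weights, region = NULL,
                             thresholds = mpps_thresholds(),
                             gerp_threshold = 2.0, phylop_threshold = 1.6,
                             max_rounds = 5, include_conservation = FALSE) {
  if (is.null(region)) {
    region <- if (all(c("chrom", "pos") %in% names(profile))) {
      region_of(profile$chrom[1], profile$pos[1],
                attr(weights, "bin_size") %||% 1e7)
    } else "genome"
  }
  conserved <- is_conserved(profile, gerp_threshold, phylop_threshold)
  verdict <- function(s) {
    if (s >= 1) "damaging" else if (s <= -1) "benign" else NA_character_
  }
  round1 <- NULL
  n_cand <- length(mpps_tools()) - if (include_conservation) 0L else 2L
  max_rounds <- min(max_rounds, n_cand %/% 3L)
  for (r in seq_len(max_rounds)) {
    tr <- select_trios(weights, region, r, include_conservation)
    s_d <- trio_score(profile, tr$dmg_tools, weights, "dmg", region, thresholds)
    s_b <- trio_score(profile, tr$ben_tools, weights, "ben", region, thresholds)
    if (conserved) {
      s_d <- min(s_d + 1, 10)
      s_b <- min(s_b + 1, 10)
    }
    if (r == 1L) round1 <- list(s_d = s_d, s_b = s_b, tr = tr)
    v_d <- verdict(s_d); v_b <- verdict(s_b)
    if (!is.na(v_d) && !is.na(v_b) && v_d == v_b) {
      return(list(score_dmg = s_d, score_ben = s_b, classification = v_d,
                  mis_classified = FALSE, round_used = r,
                  dmg_tools = tr$dmg_tools, ben_tools = tr$ben_tools,
                  conserved = conserved))
    }
  }
  mean1 <- (round1$s_d + round1$s_b) / 2
  list(score_dmg = round1$s_d, score_ben = round1$s_b,
       classification = if (mean1 > 0) "damaging" else "benign",
       mis_classified = TRUE, round_used = as.integer(max_rounds),
       dmg_tools = round1$tr$dmg_tools, ben_tools = round1$tr$ben_tools,
       conserved = conserved)
}

#' Classify a batch of variants
#'
#' Runs [classify_variant()] on every row of an annotated variant table.
#' Exactly one result row is emitted per input variant in input order —
#' mis-classified variants included — so the Prediction Coverage of the
#' batch is 100% by construction.
#'
#' @inheritParams classify_variant
#' @param variants annotated variant table with raw-score columns; rows
#'   may cover any subset of the 17 tools (including none).
#' @param weights `mpps_weights` table.
#' @return `data.frame` with columns `MPPS_SCORE_DMG`, `MPPS_SCORE_BEN`,
#'   `MPPS_CLASS`, `MPPS_MISCLASS`, `MPPS_ROUND`, `MPPS_CONSERVED`, one
#'   row per input variant.
#' @export
predict_batch <- function(variants, weights, thresholds = mpps_thresholds(),
                          gerp_threshold = 2.0, phylop_threshold = 1.6,
                          max_rounds = 5, include_conservation = FALSE) {
  n <- nrow(variants)
  out <- data.frame(MPPS_SCORE_DMG = numeric(n), MPPS_SCORE_BEN = numeric(n),
                    MPPS_CLASS = character(n), MPPS_MISCLASS = logical(n),
                    MPPS_ROUND = integer(n), MPPS_CONSERVED = logical(n),
                    stringsAsFactors = FALSE)
  if (!n) return(out)
  bin_size <- attr(weights, "bin_size") %||% 1e7
  has_pos <- all(c("chrom", "pos") %in% names(variants))
  regions <- if (has_pos) region_of(variants$chrom, variants$pos, bin_size) else
    rep("genome", n)

  # group by region: trio selection and weight lookup are per-region,
  # scoring is vectorized within each group
  tools <- mpps_tools()
  cats <- categorize_profiles(variants, tools, thresholds)
  pts <- matrix(category_points(cats), nrow = n,
                dimnames = list(NULL, tools))
  conserved <- is_conserved(variants, gerp_threshold, phylop_threshold)
  n_cand <- length(tools) - if (include_conservation) 0L else 2L
  max_rounds <- min(max_rounds, n_cand %/% 3L)

  for (reg in unique(regions)) {
    rows <- which(regions == reg)
    rw <- region_weights(weights, reg)
    undecided <- rows
    r1_sd <- r1_sb <- numeric(length(rows))
    names(r1_sd) <- names(r1_sb) <- as.character(rows)
    for (r in seq_len(max_rounds)) {
      tr <- select_trios(weights, reg, r, include_conservation)
      w_d <- rw$w_dmg[match(tr$dmg_tools, rw$tool)]
      w_b <- rw$w_ben[match(tr$ben_tools, rw$tool)]
      sw_d <- sum(w_d); sw_b <- sum(w_b)
      s_d <- if (sw_d == 0) rep(0, length(rows)) else
        as.numeric(pts[rows, tr$dmg_tools, drop = FALSE] %*% w_d / sw_d)
      s_b <- if (sw_b == 0) rep(0, length(rows)) else
        as.numeric(pts[rows, tr$ben_tools, drop = FALSE] %*% w_b / sw_b)
      s_d <- ifelse(conserved[rows], pmin(s_d + 1, 10), s_d)
      s_b <- ifelse(conserved[rows], pmin(s_b + 1, 10), s_b)
      if (r == 1L) { r1_sd[] <- s_d; r1_sb[] <- s_b }
      v_d <- ifelse(s_d >= 1, "damaging", ifelse(s_d <= -1, "benign", NA))
      v_b <- ifelse(s_b >= 1, "damaging", ifelse(s_b <= -1, "benign", NA))
      agree <- !is.na(v_d) & !is.na(v_b) & v_d == v_b &
        rows %in% undecided
      hit <- rows[agree]
      if (length(hit)) {
        out$MPPS_SCORE_DMG[hit] <- s_d[agree]
        out$MPPS_SCORE_BEN[hit] <- s_b[agree]
        out$MPPS_CLASS[hit] <- v_d[agree]
        out$MPPS_MISCLASS[hit] <- FALSE
        out$MPPS_ROUND[hit] <- r
        undecided <- setdiff(undecided, hit)
      }
      if (!length(undecided)) break
    }
    if (length(undecided)) {
      i <- match(as.character(undecided), names(r1_sd))
      mean1 <- (r1_sd[i] + r1_sb[i]) / 2
      out$MPPS_SCORE_DMG[undecided] <- r1_sd[i]
      out$MPPS_SCORE_BEN[undecided] <- r1_sb[i]
      out$MPPS_CLASS[undecided] <- ifelse(mean1 > 0, "damaging", "benign")
      out$MPPS_MISCLASS[undecided] <- TRUE
      out$MPPS_ROUND[undecided] <- max_rounds
    }
    out$MPPS_CONSERVED[rows] <- conserved[rows]
  }
  out
}

#' Write MPPS results as TSV or as VCF INFO keys
#'
#' @param variants the classified variant table.
#' @param results the matching [predict_batch()] output.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_mpps_tsv <- function(variants, results, path) {
  stopifnot(nrow(variants) == nrow(results))
  keep <- intersect(c("chrom", "pos", "ref", "alt", "gene"), names(variants))
  out <- cbind(variants[, keep, drop = FALSE], results)
  write_atomic(function(tmp) {
    write.table(out, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  }, path)
}

#' @rdname write_mpps_tsv
#' @export
write_mpps_vcf <- function(variants, results, path) {
  stopifnot(nrow(variants) == nrow(results))
  v <- variants
  v$MPPS_SCORE_DMG <- round(results$MPPS_SCORE_DMG, 4)
  v$MPPS_SCORE_BEN <- round(results$MPPS_SCORE_BEN, 4)
  v$MPPS_CLASS <- results$MPPS_CLASS
  v$MPPS_MISCLASS <- as.integer(results$MPPS_MISCLASS)
  v$MPPS_ROUND <- results$MPPS_ROUND
  write_vcf(v, path)
}
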