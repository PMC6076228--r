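#' Accuracy and Prediction Coverage of one method on a truth set
#'
#' Calls on the damaging side (damaging / possibly damaging) count as
#' pathogenic predictions, calls on the benign side as neutral
#' predictions, and unclassified as no prediction. Accuracy denominators
#' are by default the variants for which the method emitted a prediction,
#' keeping accuracy separate from coverage; Prediction Coverage is the
#' number of predicted variants (correctly or incorrectly) divided by the
#' total number of variants evaluated, as a percentage.
#'
#' @param categories character vector of prediction categories (one per
#'   truth variant, in truth order).
#' @param truth_labels character vector, `"pathogenic"` / `"neutral"`.
#' @param method method name for the output row.
#' @param denominator `"predicted"` (default) or `"all"` — whether
#'   accuracy percentages divide by predicted variants or all variants of
#'   the class.
#' @return one-row `data.frame`: `method`, `pct_correct_pathogenic`,
#'   `pct_correct_neutral`, `prediction_coverage` (percentages, half-up
#'   to 2 decimals; `NA` when a class has no predicted variants), plus
#'   backing counts. A truth set with zero variants of a class reports
#'   that accuracy as `NA`, not 0.
#' @export
tool_accuracy <- function(categories, truth_labels, method = "method",
                          denominator = c("predicted", "all")) {
  denominator <- match.arg(denominator)
  if (!length(truth_labels)) stop("truth set is empty")
  stopifnot(length(categories) == length(truth_labels))
  is_path <- truth_labels == "pathogenic"
  has <- categories != "unclassified"
  call_dmg <- side_call(categories, "dmg")
  call_ben <- side_call(categories, "ben")

  n_path_all <- sum(is_path); n_neut_all <- sum(!is_path)
  n_path_pred <- sum(is_path & has); n_neut_pred <- sum(!is_path & has)
  n_path_corr <- sum(is_path & call_dmg)
  n_neut_corr <- sum(!is_path & call_ben)

  den_path <- if (denominator == "predicted") n_path_pred else n_path_all
  den_neut <- if (denominator == "predicted") n_neut_pred else n_neut_all
  pct <- function(num, den) {
    if (den == 0) NA_real_ else round_half_up(100 * num / den, 2)
  }
  data.frame(
    method = method,
    pct_correct_pathogenic = pct(n_path_corr, den_path),
    pct_correct_neutral = pct(n_neut_corr, den_neut),
    prediction_coverage = round_half_up(100 * sum(has) / length(has), 2),
    n_pathogenic = n_path_all, n_neutral = n_neut_all,
    n_pathogenic_predicted = n_path_pred, n_neutral_predicted = n_neut_pred,
    n_pathogenic_correct = n_path_corr, n_neutral_correct = n_neut_corr,
    stringsAsFactors = FALSE
  )
}

#' Benchmark the 17 predictors and the MPPS ensemble
#'
#' Splits the truth set into a fitting and an evaluation half (by seed),
#' fits MPPS region weights on the fitting half, then computes
#' [tool_accuracy()] rows for every individual predictor and for MPPS on
#' the evaluation half. MPPS emits a classification for every variant, so
#' its Prediction Coverage is 100 by construction (still computed, not
#' assigned). Resubstitution (fit and evaluate on the full set) must be
#' requested explicitly.
#'
#' @inheritParams fit_region_weights
#' @param split fraction of truth variants used for fitting (default
#'   0.5); the rest are evaluated.
#' @param allow_resubstitution if `TRUE`, fit and evaluate on the full
#'   truth set; otherwise `split` must lie strictly in (0, 1) so the two
#'   halves are disjoint.
#' @param denominator passed to [tool_accuracy()].
#' @param ... further arguments to [mpps()].
#' @return `data.frame`, one row per predictor plus one `MPPS` row.
#' @export
benchmark_all <- function(profiles, truth, bin_size = 1e7, min_n = 50,
                          seed = NULL, split = 0.5,
                          allow_resubstitution = FALSE,
                          thresholds = mpps_thresholds(),
                          denominator = "predicted", ...) {
  if (!allow_resubstitution && (split <= 0 || split >= 1)) {
    stop("fit and evaluation splits overlap; use allow_resubstitution = TRUE ",
         "to fit and evaluate on the full truth set")
  }
  n <- nrow(truth)
  if (allow_resubstitution) {
    fit_idx <- eval_idx <- seq_len(n)
  } else {
    fit_idx <- with_seed(seed, sort(sample(n, max(1, round(split * n)))))
    eval_idx <- setdiff(seq_len(n), fit_idx)
  }
  fit <- mpps(truth[fit_idx, , drop = FALSE], profiles,
              bin_size = bin_size, min_n = min_n, thresholds = thresholds, ...)

  ekey <- variant_key(truth$chrom[eval_idx], truth$pos[eval_idx],
                      truth$ref[eval_idx], truth$alt[eval_idx])
  pkey <- variant_key(profiles$chrom, profiles$pos, profiles$ref, profiles$alt)
  eprof <- profiles[match(ekey, pkey), , drop = FALSE]
  elab <- truth$label[eval_idx]

  cats <- categorize_profiles(eprof, mpps_tools(), thresholds)
  rows <- lapply(mpps_tools(), function(tl) {
    tool_accuracy(cats[, tl], elab, method = tl, denominator = denominator)
  })
  res <- predict(fit, eprof)
  mpps_cat <- ifelse(res$MPPS_CLASS == "damaging", "damaging", "benign")
  rows <- c(rows, list(tool_accuracy(mpps_cat, elab, method = "MPPS",
                                     denominator = denominator)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genotype concordance between two call sets
#'
#' Compares genotypes at the loci present in both maps. Genotypes are
#' compared as unordered allele pairs (`"A/G"` equals `"G/A"`); the
#' concordance percentage is rounded half-up to 2 decimals.
#'
#' @param calls_a,calls_b `data.frame`s with columns `locus` and
#'   `genotype`, or named vectors (names = loci, values = genotypes).
#' @return list of class `concordance` with `n_compared`, `n_concordant`,
#'   `pct`.
#' @export
#' @examples
#' a <- c(l1 = "A/G", l2 = "C/C", l3 = "T/A")
#' b <- c(l1 = "G/A", l2 = "C/T", l3 = "A/T")
#' genotype_concordance(a, b)
genotype_concordance <- function(calls_a, calls_b) {
  as_map <- function(x) {
    if (is.data.frame(x)) {
      stopifnot_cols(x, c("locus", "genotype"), "genotype map")
      list(locus = as.character(x$locus), gt = as.character(x$genotype))
    } else {
      list(locus = names(x), gt = as.character(x))
    }
  }
  a <- as_map(calls_a); b <- as_map(calls_b)
  i <- match(a$locus, b$locus)
  shared <- !is.na(i)
  n <- sum(shared)
  if (n == 0) stop("no shared loci between the two call sets")
  norm_gt <- function(g) {
    vapply(strsplit(g, "[/|]"), function(al) paste(sort(al), collapse = "/"), "")
  }
  ga <- a$gt[shared]
  gb <- b$gt[i[shared]]
  # allele order must not matter; normalize only where the raw strings differ
  diff <- which(ga != gb)
  n_conc <- (n - length(diff)) +
    if (length(diff)) sum(norm_gt(ga[diff]) == norm_gt(gb[diff])) else 0L
  structure(list(n_compared = n, n_concordant = n_conc,
                 pct = round_half_up(100 * n_conc / n, 2)),
            class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("genotype concordance: %.2f%% (%s/%s)\n", x$pct,
              format(x$n_concordant, big.mark = ","),
              format(x$n_compared, big.mark = ",")))
  invisible(x)
}
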