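#' Fit an MPPS ensemble classifier
#'
#' Fits the region-wise predictor weights of the MPPS ensemble from a
#' labeled truth set and returns a classifier object. Fitting estimates,
#' for each genomic bin and each of the 17 deleteriousness predictors,
#' the fraction of correct predictions on pathogenic and on neutral truth
#' variants ([fit_region_weights()]); prediction then runs the iterative
#' trio-agreement protocol with conservation bonus ([predict.mpps()]).
#'
#' @inheritParams fit_region_weights
#' @param gerp_threshold,phylop_threshold conservation cut-offs used at
#'   prediction time.
#' @param include_conservation allow the two conservation scores in
#'   predictor trios (default `FALSE`: they only drive the bonus).
#' @param max_rounds cap on trio-agreement rounds.
#' @return an object of class `"mpps"` with components `weights`
#'   (the `mpps_weights` table), `thresholds`, `bin_size`, `min_n`,
#'   `n_pathogenic`, `n_neutral`, the prediction options, and `call`.
#' @export
#' @examples
#' sim <- simulate_truth_set(300, 300, seed = 1)
#' prof <- simulate_tool_profiles(sim, tool_accuracy_spec(), seed = 2)
#' fit <- mpps(sim, prof)
#' fit
#' head(predict(fit, prof))
mpps <- function(truth, profiles, bin_size = 1e7, min_n = 50,
                 thresholds = mpps_thresholds(), seed = NULL, subsample = 1,
                 gerp_threshold = 2.0, phylop_threshold = 1.6,
                 include_conservation = FALSE, max_rounds = 5) {
  weights <- fit_region_weights(truth, profiles, bin_size = bin_size,
                                min_n = min_n, seed = seed,
                                subsample = subsample, thresholds = thresholds)
  structure(list(
    weights = weights,
    thresholds = thresholds,
    bin_size = bin_size,
    min_n = min_n,
    n_pathogenic = sum(truth$label == "pathogenic"),
    n_neutral = sum(truth$label == "neutral"),
    gerp_threshold = gerp_threshold,
    phylop_threshold = phylop_threshold,
    include_conservation = include_conservation,
    max_rounds = max_rounds,
    call = match.call()
  ), class = "mpps")
}

#' @export
print.mpps <- function(x, ...) {
  cat("MPPS ensemble pathogenicity classifier\n")
  cat("  predictors:", length(mpps_tools()),
      if (x$include_conservation) "(conservation scores in trios)" else
        "(15 in trios + 2 conservation)", "\n")
  cat(sprintf("  trained on %d pathogenic / %d neutral variants\n",
              x$n_pathogenic, x$n_neutral))
  n_reg <- length(setdiff(unique(x$weights$region), "genome"))
  cat(sprintf("  region bins: %d specific (%.0f Mb) + genome-wide fallback\n",
              n_reg, x$bin_size / 1e6))
  tr <- select_trios(x$weights, "genome", 1, x$include_conservation)
  cat("  round-1 damaging trio:", paste(tr$dmg_tools, collapse = ", "), "\n")
  cat("  round-1 benign trio:  ", paste(tr$ben_tools, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.mpps <- function(object, ...) {
  g <- object$weights[object$weights$region == "genome", ]
  g <- g[order(-(g$w_dmg + g$w_ben) / 2, g$tool), ]
  rownames(g) <- NULL
  structure(list(genome_weights = g,
                 n_regions = length(setdiff(unique(object$weights$region),
                                            "genome")),
                 n_pathogenic = object$n_pathogenic,
                 n_neutral = object$n_neutral),
            class = "summary.mpps")
}

#' @export
print.summary.mpps <- function(x, ...) {
  cat("Genome-wide predictor weights (fraction correct per truth class):\n")
  print(x$genome_weights, digits = 3)
  cat(sprintf("\n%d region-specific bins; truth: %d pathogenic, %d neutral\n",
              x$n_regions, x$n_pathogenic, x$n_neutral))
  invisible(x)
}

#' @export
coef.mpps <- function(object, ...) object$weights

#' Classify variants with a fitted MPPS ensemble
#'
#' @param object a fitted [mpps()] classifier.
#' @param newdata annotated variant table with raw-score columns for (a
#'   subset of) the 17 predictors.
#' @param ... unused.
#' @return the [predict_batch()] result: one row per variant with MPPS
#'   scores, classification, mis-classification flag and round used.
#' @export
predict.mpps <- function(object, newdata, ...) {
  predict_batch(newdata, object$weights, thresholds = object$thresholds,
                gerp_threshold = object$gerp_threshold,
                phylop_threshold = object$phylop_threshold,
                max_rounds = object$max_rounds,
                include_conservation = object$include_conservation)
}
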