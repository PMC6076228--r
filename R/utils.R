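`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Percentages in reports are rounded half-up (so 99.795 prints as 99.80),
#' unlike [round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(99.795, 2)
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Evaluate `code` under set.seed(seed) without disturbing the caller's RNG
# stream. seed = NULL evaluates as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Variant key shared by every join in the package. Chromosome labels are
# normalized by stripping a leading "chr".
variant_key <- function(chrom, pos, ref, alt) {
  paste(norm_chrom(chrom), pos, ref, alt, sep = "|")
}

norm_chrom <- function(chrom) sub("^chr", "", as.character(chrom))

# Atomic write: serialize to a sibling temp file, then rename into place.
write_atomic <- function(lines_or_fun, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  if (is.function(lines_or_fun)) lines_or_fun(tmp) else writeLines(lines_or_fun, tmp)
  if (!file.rename(tmp, path)) stop("could not write ", path)
  invisible(path)
}

stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, " is missing required column(s): ", paste(miss, collapse = ", "))
  }
  invisible(df)
}
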