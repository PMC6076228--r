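html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

html_table <- function(df) {
  if (is.null(df) || !nrow(df)) return("<p><em>none</em></p>")
  head_row <- paste0("<tr>", paste0("<th>", html_escape(names(df)), "</th>",
                                    collapse = ""), "</tr>")
  body <- apply(df, 1, function(r) {
    paste0("<tr>", paste0("<td>", html_escape(as.character(r)), "</td>",
                          collapse = ""), "</tr>")
  })
  paste0("<table border='1' cellpadding='4' cellspacing='0'>\n", head_row,
         "\n", paste(body, collapse = "\n"), "\n</table>")
}

#' Generate a diagnosis report (JSON + HTML)
#'
#' Writes one machine-readable JSON report and one human-readable HTML
#' page for a patient: input phenotype terms, ranked candidate diseases,
#' ranked variants with score components, and provenance (package
#' version, configuration hash, timestamp). Output is deterministic for
#' fixed inputs when `timestamp` is supplied.
#'
#' @param patient_id identifier used for the file stem.
#' @param terms patient phenotype terms.
#' @param diseases ranked disease table from [rank_diseases()].
#' @param variants scored variant table (every variant surviving the
#'   filters, each exactly once).
#' @param out_dir output directory (created if needed).
#' @param config an [aadsm_config()] list, recorded in provenance.
#' @param timestamp override for the provenance timestamp (any string);
#'   default is the current time.
#' @return list of class `diagnosis_report` with the report content and
#'   `paths` (json, html), invisibly.
#' @export
generate_report <- function(patient_id, terms, diseases, variants, out_dir,
                            config = aadsm_config(), timestamp = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create report directory: ", out_dir)
  }
  if (file.access(out_dir, 2) != 0) stop("report directory not writable: ", out_dir)
  report <- list(
    patient_id = patient_id,
    phenotype_terms = as.character(terms),
    diseases = diseases,
    variants = variants,
    provenance = list(
      package = "mendeldx",
      version = as.character(utils::packageVersion("mendeldx")),
      config_hash = config_hash(config),
      timestamp = timestamp %||% format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
  )
  json_path <- file.path(out_dir, paste0(patient_id, ".json"))
  html_path <- file.path(out_dir, paste0(patient_id, ".html"))
  write_atomic(function(tmp) {
    jsonlite::write_json(report, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }, json_path)

  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset='utf-8'>",
    sprintf("<title>Diagnosis report %s</title></head><body>",
            html_escape(patient_id)),
    sprintf("<h1>Diagnosis report: %s</h1>", html_escape(patient_id)),
    "<h2>Phenotype terms</h2>",
    sprintf("<p>%s</p>", if (length(terms))
      paste(html_escape(terms), collapse = ", ") else "<em>none provided</em>"),
    "<h2>Ranked candidate diseases</h2>",
    html_table(diseases),
    "<h2>Ranked variants</h2>",
    html_table(variants),
    "<h2>Provenance</h2>",
    sprintf("<p>%s %s | config %s | %s</p>",
            report$provenance$package, report$provenance$version,
            report$provenance$config_hash, report$provenance$timestamp),
    "</body></html>"
  )
  write_atomic(html, html_path)
  report$paths <- c(json = json_path, html = html_path)
  class(report) <- "diagnosis_report"
  invisible(report)
}

#' Read a JSON diagnosis report back
#'
#' @param path path to a `.json` report written by [generate_report()].
#' @return the report as a list (tables as data.frames).
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
}

#' @export
print.diagnosis_report <- function(x, ...) {
  cat("Diagnosis report for", x$patient_id, "\n")
  cat("  phenotype terms:", length(x$phenotype_terms), "\n")
  nd <- if (is.null(x$diseases)) 0 else nrow(x$diseases)
  cat("  candidate diseases:", nd, "\n")
  if (nd) {
    top <- x$diseases[1, ]
    cat(sprintf("  top: %s (%s, gene %s, score %.2f)\n", top$disease_id,
                top$name, top$gene, top$total))
  }
  nv <- if (is.null(x$variants)) 0 else nrow(x$variants)
  cat("  reported variants:", nv, "\n")
  invisible(x)
}

#' Run the full automated diagnosis pipeline for one patient
#'
#' Wires the three AADSM steps end to end: annotate the variants against
#' the annotation database, optionally classify SNVs with a fitted MPPS
#' ensemble, filter, score, build the phenotype-driven gene list, rank
#' candidate diseases and (optionally) write the report pair.
#'
#' @param variants variant table or path to a VCF file.
#' @param terms phenotype term vector or path to a term file.
#' @param db a `gene_phenotype_db` or directory for
#'   [read_gene_phenotype_db()].
#' @param annot an [annotation_db()] (optional; variants may already
#'   carry `allele_freq`/`hgmd` columns).
#' @param mpps_fit optional fitted [mpps()] classifier.
#' @param config an [aadsm_config()] list.
#' @param panel optional panel manifest for [filter_variants()].
#' @param patient_id report identifier.
#' @param out_dir if non-`NULL`, write the JSON/HTML report pair there.
#' @param timestamp provenance timestamp override.
#' @return a `diagnosis_report` list (see [generate_report()]); when
#'   `out_dir` is `NULL` the `paths` element is absent.
#' @export
diagnose <- function(variants, terms, db, annot = NULL, mpps_fit = NULL,
                     config = aadsm_config(), panel = NULL,
                     patient_id = "patient", out_dir = NULL,
                     timestamp = NULL) {
  if (is.character(variants)) variants <- read_vcf(variants)
  if (is.character(terms) && length(terms) == 1 && file.exists(terms)) {
    terms <- read_phenotype_terms(terms)
  }
  if (is.character(db)) db <- read_gene_phenotype_db(db)
  if (!is.null(annot)) variants <- annotate(variants, annot)
  if (is.null(variants$hgmd)) variants$hgmd <- "absent"

  if (!is.null(mpps_fit)) {
    res <- predict(mpps_fit, variants)
    tool_cols <- intersect(mpps_tools(), names(variants))
    has_profile <- if (length(tool_cols)) {
      rowSums(!is.na(variants[, tool_cols, drop = FALSE])) > 0
    } else rep(FALSE, nrow(variants))
    # the ensemble scores nonsynonymous SNVs with at least one raw score;
    # other records carry no MPPS evidence into the variant score
    variants$MPPS_CLASS <- ifelse(variants$var_type == "SNV" & has_profile,
                                  res$MPPS_CLASS, NA_character_)
  }
  kept <- filter_variants(variants, config, panel)
  scored <- score_variants(kept, config = config)
  scored <- scored[order(-scored$score_total), , drop = FALSE]
  rownames(scored) <- NULL
  gene_list <- phenotype_gene_list(terms, db)
  diseases <- rank_diseases(scored, db, terms, config)

  report_cols <- intersect(
    c("chrom", "pos", "ref", "alt", "var_type", "gene", "consequence",
      "zygosity", "allele_freq", "hgmd", "MPPS_CLASS", "freq_pts",
      "type_pts", "consequence_pts", "hgmd_pts", "mpps_pts", "score_total"),
    names(scored))
  var_report <- scored[, report_cols, drop = FALSE]

  if (!is.null(out_dir)) {
    rep <- generate_report(patient_id, terms, diseases, var_report, out_dir,
                           config, timestamp)
  } else {
    rep <- structure(list(patient_id = patient_id,
                          phenotype_terms = as.character(terms),
                          diseases = diseases, variants = var_report,
                          provenance = list(package = "mendeldx")),
                     class = "diagnosis_report")
  }
  rep$gene_list <- gene_list
  rep
}
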