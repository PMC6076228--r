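#' Default AADSM configuration
#'
#' Tunable parameters of the diagnosis pipeline. `freq_cutoff` is the
#' population allele frequency at or above which a variant is considered
#' common and removed (unless rescued by a curated `DM`/`DM?` class);
#' `splice_window` keeps synonymous variants within that many bp of a
#' splice site; `flank` is the intronic flank retained around panel
#' exons; `max_rank` caps the number of diseases reported.
#'
#' @param freq_cutoff common-variant threshold (default 0.01).
#' @param splice_window bp window rescuing synonymous variants (default 2).
#' @param flank exon flank in bp (default 10).
#' @param max_rank maximum diseases in a report (default 100).
#' @param freq_pts,conseq_pts,hgmd_pts,mpps_pts scoring tables, see
#'   [score_variant()].
#' @return a named list.
#' @export
aadsm_config <- function(freq_cutoff = 0.01, splice_window = 2, flank = 10,
                         max_rank = 100,
                         freq_pts = c(absent = 4, rare = 2, low = 1, common = -6),
                         conseq_pts = c(nonsense = 4, frameshift = 4,
                                        splicing = 4, inframe_indel = 3,
                                        missense = 2, other = 0,
                                        synonymous = -4, cnv = 4),
                         mpps_pts = c(damaging = 2, benign = -2, none = 0),
                         hgmd_pts = c(DM = 4, `DM?` = 2, DP = 1, DFP = 1,
                                      absent = 0)) {
  list(freq_cutoff = freq_cutoff, splice_window = splice_window,
       flank = flank, max_rank = max_rank, freq_pts = freq_pts,
       conseq_pts = conseq_pts, hgmd_pts = hgmd_pts, mpps_pts = mpps_pts)
}

#' Filter annotated variants
#'
#' The first AADSM step. Removes:
#' * common variants — `allele_freq >= freq_cutoff` — unless rescued by a
#'   curated `DM` / `DM?` class;
#' * synonymous variants, unless flagged within `splice_window` bp of a
#'   splice site (logical column `near_splice`);
#' * variants outside panel exons +/- `flank` bp, when a panel manifest
#'   is supplied.
#'
#' Input order is preserved and the operation is idempotent.
#'
#' @param records annotated variant table (needs `allele_freq`, `hgmd`,
#'   `consequence`; see [annotate()]).
#' @param config an [aadsm_config()] list.
#' @param panel optional manifest `data.frame` with columns
#'   `chrom,start,end` (exon intervals).
#' @return the surviving records.
#' @export
filter_variants <- function(records, config = aadsm_config(), panel = NULL) {
  if (!nrow(records)) return(records)
  af <- records$allele_freq %||% rep(NA_real_, nrow(records))
  hgmd <- records$hgmd %||% rep("absent", nrow(records))
  rescued <- hgmd %in% c("DM", "DM?")
  common <- !is.na(af) & af >= config$freq_cutoff & !rescued

  near_splice <- records$near_splice %||% rep(FALSE, nrow(records))
  near_splice[is.na(near_splice)] <- FALSE
  syn_drop <- records$consequence %in% "synonymous" & !near_splice

  off_panel <- rep(FALSE, nrow(records))
  if (!is.null(panel) && nrow(panel)) {
    stopifnot_cols(panel, c("chrom", "start", "end"), "panel manifest")
    pch <- norm_chrom(panel$chrom)
    lo <- panel$start - config$flank
    hi <- panel$end + config$flank
    vch <- norm_chrom(records$chrom)
    vend <- ifelse(is.na(records$end), records$pos, records$end)
    off_panel <- !mapply(function(ch, p1, p2) {
      any(pch == ch & lo <= p2 & hi >= p1)
    }, vch, records$pos, vend)
  }
  out <- records[!(common | syn_drop | off_panel), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Phenotype-driven gene ranking
#'
#' Scores every gene in the database by the number of the patient's
#' phenotype terms that link to it. Genes with no matching term are kept
#' at the bottom of the ranking (score 0) — phenotype evidence ranks
#' genes, it never excludes them. Terms absent from the database raise a
#' warning, not an error.
#'
#' @param terms character vector of patient phenotype terms.
#' @param db a `gene_phenotype_db`.
#' @return `data.frame` with columns `gene`, `score`, sorted by score
#'   descending then gene name.
#' @export
phenotype_gene_list <- function(terms, db) {
  stopifnot(inherits(db, "gene_phenotype_db"))
  pg <- db$phenotype_gene
  if (is.null(pg) || !nrow(pg)) stop("gene-phenotype database is empty")
  all_genes <- sort(unique(c(pg$gene, db$gene_disease$gene)))
  terms <- unique(terms)
  unknown <- setdiff(terms, unique(pg$term))
  if (length(unknown)) {
    warning("phenotype term(s) not in database: ",
            paste(unknown, collapse = ", "))
  }
  hits <- pg[pg$term %in% terms, , drop = FALSE]
  score <- table(factor(hits$gene, levels = all_genes))
  out <- data.frame(gene = all_genes, score = as.integer(score),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score one annotated variant
#'
#' The AADSM variant score sums four evidence components plus the
#' ensemble call:
#' * frequency: absent from population databases or AF < 1e-4 -> 4;
#'   < 0.005 -> 2; < freq_cutoff -> 1; common -> -6;
#' * type: whole-gene / multi-exon copy-number events -> 4 (regardless of
#'   curated class), other types -> 0;
#' * consequence (SNV/indel): nonsense, frameshift, splicing -> 4;
#'   in-frame indel -> 3; missense -> 2; other -> 0; synonymous -> -4;
#' * curated class: DM -> 4, DM? -> 2, DP/DFP -> 1, absent -> 0;
#' * ensemble: MPPS damaging -> 2, benign -> -2, no call -> 0.
#'
#' All magnitudes are configurable via [aadsm_config()].
#'
#' @param record one-row annotated variant.
#' @param mpps_class optional MPPS classification for the variant
#'   (`"damaging"`, `"benign"` or `NA`).
#' @param config an [aadsm_config()] list.
#' @return list of class `variant_score`: `freq_pts`, `type_pts`,
#'   `consequence_pts`, `hgmd_pts`, `mpps_pts`, `total`.
#' @export
score_variant <- function(record, mpps_class = NA_character_,
                          config = aadsm_config()) {
  af <- record$allele_freq %||% NA_real_
  af <- af[1]
  fp <- config$freq_pts
  freq_pts <- if (is.na(af) || af < 1e-4) fp[["absent"]]
    else if (af < 0.005) fp[["rare"]]
    else if (af < config$freq_cutoff) fp[["low"]]
    else fp[["common"]]

  vt <- (record$var_type %||% "SNV")[1]
  is_cnv <- vt %in% c("CNV_DEL", "CNV_DUP")
  type_pts <- if (is_cnv) config$conseq_pts[["cnv"]] else 0

  cq <- (record$consequence %||% "other")[1]
  consequence_pts <- if (is_cnv) 0 else
    unname(config$conseq_pts[cq] %||% 0)
  if (is.na(consequence_pts)) consequence_pts <- 0

  hg <- (record$hgmd %||% "absent")[1]
  hgmd_pts <- unname(config$hgmd_pts[hg])
  if (is.na(hgmd_pts)) hgmd_pts <- 0

  mp <- mpps_class[1]
  mpps_pts <- if (is.na(mp) || !mp %in% c("damaging", "benign")) {
    config$mpps_pts[["none"]]
  } else config$mpps_pts[[mp]]

  structure(list(freq_pts = freq_pts, type_pts = type_pts,
                 consequence_pts = consequence_pts, hgmd_pts = hgmd_pts,
                 mpps_pts = mpps_pts,
                 total = freq_pts + type_pts + consequence_pts +
                   hgmd_pts + mpps_pts),
            class = "variant_score")
}

# Vectorized scoring: appends score component columns and `score_total`.
score_variants <- function(records, mpps_class = NULL,
                           config = aadsm_config()) {
  n <- nrow(records)
  if (is.null(mpps_class)) mpps_class <- records$MPPS_CLASS %||%
      rep(NA_character_, n)
  comp <- matrix(0, nrow = n, ncol = 5,
                 dimnames = list(NULL, c("freq_pts", "type_pts",
                                         "consequence_pts", "hgmd_pts",
                                         "mpps_pts")))
  for (i in seq_len(n)) {
    s <- score_variant(records[i, , drop = FALSE], mpps_class[i], config)
    comp[i, ] <- c(s$freq_pts, s$type_pts, s$consequence_pts, s$hgmd_pts,
                   s$mpps_pts)
  }
  out <- cbind(records, as.data.frame(comp))
  out$score_total <- rowSums(comp)
  out
}

#' Rank candidate diseases for a patient
#'
#' The third AADSM step. Every disease with at least one scored variant
#' in one of its genes becomes a candidate and receives:
#' * `phenotype_match` — the fraction of the disease's phenotype terms
#'   present in the patient's terms (0 when the disease has no terms);
#' * `variant_support` — the best variant score total in the disease's
#'   genes;
#' * `inheritance_consistent` — for autosomal recessive diseases, two
#'   heterozygous hits or one homozygous/hemizygous hit in a disease
#'   gene; other modes need one supporting variant;
#' * `total = variant_support * (1 + phenotype_match) +
#'   2 * inheritance_consistent`.
#'
#' Sorted by total descending, ties broken by disease id ascending.
#'
#' @param scored_variants output of the scoring step (needs `gene`,
#'   `score_total`, `zygosity`).
#' @param db a `gene_phenotype_db`.
#' @param terms the patient's phenotype terms.
#' @param config an [aadsm_config()] list (uses `max_rank`).
#' @return `data.frame`: `disease_id`, `name`, `gene`, `phenotype_match`,
#'   `variant_support`, `inheritance_consistent`, `total`, `rank`.
#' @export
rank_diseases <- function(scored_variants, db, terms = character(),
                          config = aadsm_config()) {
  stopifnot(inherits(db, "gene_phenotype_db"))
  empty <- data.frame(disease_id = character(), name = character(),
                      gene = character(), phenotype_match = numeric(),
                      variant_support = numeric(),
                      inheritance_consistent = logical(), total = numeric(),
                      rank = integer(), stringsAsFactors = FALSE)
  if (is.null(scored_variants) || !nrow(scored_variants)) return(empty)
  sv <- scored_variants[!is.na(scored_variants$gene), , drop = FALSE]
  if (!nrow(sv)) return(empty)

  gd <- db$gene_disease[db$gene_disease$gene %in% sv$gene, , drop = FALSE]
  if (!nrow(gd)) return(empty)
  meta <- db$disease_meta
  terms <- unique(terms)

  rows <- lapply(unique(gd$disease_id), function(did) {
    mi <- match(did, meta$disease_id)
    dgenes <- db$gene_disease$gene[db$gene_disease$disease_id == did]
    hits <- sv[sv$gene %in% dgenes, , drop = FALSE]
    best <- which.max(hits$score_total)
    dterms <- if (is.na(mi) || is.na(meta$terms[mi]) || !nzchar(meta$terms[mi]))
      character() else strsplit(meta$terms[mi], ";")[[1]]
    pmatch <- if (!length(dterms)) 0 else
      length(intersect(terms, dterms)) / length(dterms)
    inh <- if (is.na(mi)) "unknown" else meta$inheritance[mi]
    consistent <- if (identical(inh, "AR")) {
      per_gene <- vapply(unique(hits$gene), function(g) {
        z <- hits$zygosity[hits$gene == g]
        sum(z == "het") >= 2 || any(z %in% c("hom", "hemi"))
      }, logical(1))
      any(per_gene)
    } else nrow(hits) >= 1
    data.frame(disease_id = did,
               name = if (is.na(mi)) NA_character_ else meta$name[mi],
               gene = hits$gene[best],
               phenotype_match = pmatch,
               variant_support = hits$score_total[best],
               inheritance_consistent = consistent,
               total = hits$score_total[best] * (1 + pmatch) +
                 2 * as.numeric(consistent),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$total, out$disease_id), , drop = FALSE]
  out <- head(out, config$max_rank)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
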