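#' Synthetic genome specification
#'
#' 22 autosomes plus X as integer intervals (approximate GRCh37 lengths).
#' Positions only — no operation in the toolkit needs nucleotide context,
#' so no sequence is simulated.
#'
#' @return `data.frame` with columns `chrom`, `length`.
#' @export
default_genome <- function() {
  data.frame(
    chrom = c(as.character(1:22), "X"),
    length = c(249250621, 243199373, 198022430, 191154276, 180915260,
               171115067, 159138663, 146364022, 141213431, 135534747,
               135006516, 133851895, 115169878, 107349540, 102531392,
               90354753, 81195210, 78077248, 59128983, 63025520,
               48129895, 51304566, 155270560),
    stringsAsFactors = FALSE
  )
}

BASES <- c("A", "C", "G", "T")

#' Simulate a labeled pathogenicity truth set
#'
#' Places `n_pathogenic + n_neutral` SNVs uniformly over the synthetic
#' genome (chromosome drawn proportionally to length, position uniform,
#' distinct ref/alt bases, unique keys) and labels them.
#'
#' @param n_pathogenic,n_neutral non-negative counts.
#' @param genome genome specification ([default_genome()]).
#' @param seed RNG seed; same seed, same set.
#' @return `data.frame` with columns `chrom,pos,ref,alt,label`.
#' @export
simulate_truth_set <- function(n_pathogenic, n_neutral,
                               genome = default_genome(), seed = NULL) {
  stopifnot(n_pathogenic >= 0, n_neutral >= 0)
  n <- n_pathogenic + n_neutral
  if (n == 0) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), label = character(),
                      stringsAsFactors = FALSE))
  }
  with_seed(seed, {
    draw <- function(k) {
      ci <- sample(nrow(genome), k, replace = TRUE, prob = genome$length)
      pos <- floor(runif(k, 1, genome$length[ci] + 1))
      ref <- sample(BASES, k, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1), "")
      data.frame(chrom = genome$chrom[ci], pos = as.integer(pos), ref = ref,
                 alt = unname(alt), stringsAsFactors = FALSE)
    }
    v <- draw(n)
    # resample any colliding keys until unique
    repeat {
      dup <- duplicated(variant_key(v$chrom, v$pos, v$ref, v$alt))
      if (!any(dup)) break
      v[dup, ] <- draw(sum(dup))
    }
    v$label <- c(rep("pathogenic", n_pathogenic), rep("neutral", n_neutral))
    rownames(v) <- NULL
    v
  })
}

#' Per-tool accuracy specification for profile simulation
#'
#' One row per predictor (optionally per region) giving the probability a
#' pathogenic variant is called on the damaging side (`sensitivity`), the
#' probability a neutral variant is called on the benign side
#' (`specificity`), the fraction of predictions withheld
#' (`missing_rate`) and the fraction of calls softened to the
#' "possibly" categories (`possibly_rate`). A `region` column may be
#' added for region-dependent behaviour; rows with `region = "genome"`
#' (or no region column) apply everywhere not covered by a specific row.
#'
#' @param tools predictor names (default all 17).
#' @param sensitivity,specificity,missing_rate,possibly_rate rates in
#'   \[0,1\], recycled across tools.
#' @return `data.frame` of class `tool_accuracy_spec`.
#' @export
tool_accuracy_spec <- function(tools = mpps_tools(), sensitivity = 0.85,
                               specificity = 0.85, missing_rate = 0,
                               possibly_rate = 0) {
  spec <- data.frame(tool = tools,
                     region = "genome",
                     sensitivity = rep_len(sensitivity, length(tools)),
                     specificity = rep_len(specificity, length(tools)),
                     missing_rate = rep_len(missing_rate, length(tools)),
                     possibly_rate = rep_len(possibly_rate, length(tools)),
                     stringsAsFactors = FALSE)
  rates <- as.matrix(spec[, 3:6])
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  class(spec) <- c("tool_accuracy_spec", "data.frame")
  spec
}

# Representative raw score inside each category's threshold band, chosen
# so that map_raw_to_category() inverts the simulation exactly.
category_representative <- function(tool, category,
                                    thresholds = mpps_thresholds()) {
  i <- match(tool, thresholds$tool)
  if (is.na(i)) stop("unknown tool name: ", tool)
  d <- thresholds$dmg[i]; b <- thresholds$ben[i]
  m <- (d + b) / 2
  span <- abs(d - b)
  s <- if (thresholds$direction[i] == "lower") -1 else 1
  reps <- c(damaging = d + s * span / 4,
            possibly_damaging = (d + m) / 2,
            possibly_benign = (m + b) / 2,
            benign = b - s * span / 4,
            unclassified = NA_real_)
  unname(reps[category])
}

#' Simulate per-tool prediction profiles for a truth set
#'
#' For every variant and every predictor in the spec, draws a prediction:
#' withheld with probability `missing_rate`; otherwise on the correct
#' side with probability `sensitivity` (pathogenic variants) or
#' `specificity` (neutral variants); softened to the adjacent
#' "possibly" category with probability `possibly_rate`. Raw scores are
#' back-computed as the midpoint of the matching category band so that
#' [map_raw_to_category()] recovers the simulated category exactly.
#'
#' @param truth truth set from [simulate_truth_set()] (needs
#'   `chrom,pos,ref,alt,label`).
#' @param spec a [tool_accuracy_spec()]; must cover all 17 tools.
#' @param bin_size region width used to match per-region spec rows.
#' @param seed RNG seed.
#' @param thresholds category threshold table.
#' @return `data.frame` with `chrom,pos,ref,alt` plus one numeric
#'   raw-score column per tool (NA = withheld).
#' @export
simulate_tool_profiles <- function(truth, spec = tool_accuracy_spec(),
                                   bin_size = 1e7, seed = NULL,
                                   thresholds = mpps_thresholds()) {
  stopifnot(inherits(spec, "data.frame"))
  missing_tools <- setdiff(mpps_tools(), spec$tool)
  if (length(missing_tools)) {
    stop("spec does not cover tool(s): ", paste(missing_tools, collapse = ", "))
  }
  n <- nrow(truth)
  out <- truth[, c("chrom", "pos", "ref", "alt"), drop = FALSE]
  if (!n) {
    for (tl in unique(spec$tool)) out[[tl]] <- numeric(0)
    return(out)
  }
  is_path <- truth$label == "pathogenic"
  regions <- region_of(truth$chrom, truth$pos, bin_size)
  with_seed(seed, {
    for (tl in unique(spec$tool)) {
      srows <- spec[spec$tool == tl, , drop = FALSE]
      gi <- which(srows$region %in% c("genome", NA))[1]
      ri <- match(regions, srows$region)
      ri[is.na(ri)] <- gi
      sens <- srows$sensitivity[ri]
      spcf <- srows$specificity[ri]
      miss <- srows$missing_rate[ri]
      poss <- srows$possibly_rate[ri]

      withheld <- runif(n) < miss
      correct <- runif(n) < ifelse(is_path, sens, spcf)
      dmg_side <- ifelse(is_path, correct, !correct)
      soften <- runif(n) < poss
      cat <- ifelse(dmg_side,
                    ifelse(soften, "possibly_damaging", "damaging"),
                    ifelse(soften, "possibly_benign", "benign"))
      cat[withheld] <- "unclassified"
      out[[tl]] <- category_representative(tl, cat, thresholds)
    }
    out
  })
}

#' Build a synthetic gene–phenotype–disease database
#'
#' Generates a controlled-vocabulary phenotype/gene/disease database with
#' known structure: diseases are assigned to the 19 clinical categories
#' proportionally to the built-in category counts, each disease gets 1–2
#' causal genes, an inheritance mode (autosomal dominant, autosomal
#' recessive or X-linked) and a phenotype term set; X-linked diseases
#' draw their genes from X-chromosome genes. The phenotype-to-gene map is
#' derived from disease membership.
#'
#' @param n_genes number of genes in the pool.
#' @param n_diseases number of diseases (>= 1).
#' @param category_table categories with relative disease counts
#'   (default [load_disease_category_table()]).
#' @param terms_per_disease phenotype terms per disease.
#' @param seed RNG seed.
#' @return object of class `gene_phenotype_db`: list with data.frames
#'   `phenotype_gene` (term, gene), `gene_disease` (gene, disease_id),
#'   `disease_meta` (disease_id, name, category, inheritance, terms —
#'   semicolon-joined) and `genes` (gene, chrom, start, end).
#' @export
build_gene_phenotype_db <- function(n_genes = 300, n_diseases = 150,
                                    category_table = load_disease_category_table(),
                                    terms_per_disease = 5, seed = NULL) {
  stopifnot(n_diseases >= 1, n_genes >= 2)
  with_seed(seed, {
    genome <- default_genome()
    ci <- sample(nrow(genome), n_genes, replace = TRUE,
                 prob = c(rep(1, 22), 2))  # upweight X so XL genes exist
    start <- floor(runif(n_genes, 1, genome$length[ci] - 2e5))
    genes <- data.frame(gene = sprintf("G%04d", seq_len(n_genes)),
                        chrom = genome$chrom[ci],
                        start = as.integer(start),
                        end = as.integer(start + 2e5),
                        stringsAsFactors = FALSE)
    if (!any(genes$chrom == "X")) genes$chrom[1] <- "X"

    vocab <- sprintf("HP:%07d",
                     seq_len(max(30, ceiling(n_diseases * terms_per_disease / 3))))
    categories <- sample(category_table$category, n_diseases, replace = TRUE,
                         prob = category_table$n_diseases)
    inheritance <- sample(c("AD", "AR", "XL"), n_diseases, replace = TRUE,
                          prob = c(0.40, 0.45, 0.15))
    x_genes <- genes$gene[genes$chrom == "X"]

    meta <- vector("list", n_diseases)
    gd <- vector("list", n_diseases)
    for (k in seq_len(n_diseases)) {
      id <- sprintf("D%04d", k)
      pool <- if (inheritance[k] == "XL") x_genes else genes$gene
      dg <- sample(pool, min(sample(1:2, 1), length(pool)))
      terms <- sample(vocab, terms_per_disease)
      meta[[k]] <- data.frame(disease_id = id,
                              name = paste0("Synthetic disease ", id),
                              category = categories[k],
                              inheritance = inheritance[k],
                              terms = paste(terms, collapse = ";"),
                              stringsAsFactors = FALSE)
      gd[[k]] <- data.frame(gene = dg, disease_id = id,
                            stringsAsFactors = FALSE)
    }
    disease_meta <- do.call(rbind, meta)
    gene_disease <- do.call(rbind, gd)

    pg <- lapply(seq_len(n_diseases), function(k) {
      expand.grid(term = strsplit(disease_meta$terms[k], ";")[[1]],
                  gene = gene_disease$gene[gene_disease$disease_id ==
                                             disease_meta$disease_id[k]],
                  stringsAsFactors = FALSE)
    })
    pg <- unique(do.call(rbind, pg))
    phenotype_gene <- data.frame(term = pg$term, gene = pg$gene,
                                 stringsAsFactors = FALSE)
    structure(list(phenotype_gene = phenotype_gene,
                   gene_disease = gene_disease,
                   disease_meta = disease_meta,
                   genes = genes),
              class = "gene_phenotype_db")
  })
}

#' @export
print.gene_phenotype_db <- function(x, ...) {
  cat(sprintf("gene-phenotype database: %d diseases, %d genes, %d phenotype links\n",
              nrow(x$disease_meta), nrow(x$genes), nrow(x$phenotype_gene)))
  invisible(x)
}

#' Write / read a gene–phenotype database as three headered TSVs
#'
#' Files `phenotype_gene.tsv`, `gene_disease.tsv`, `disease_meta.tsv`
#' (plus `genes.tsv` when gene intervals are available) under `dir`.
#'
#' @param db a `gene_phenotype_db`.
#' @param dir directory (created if needed).
#' @return `write_gene_phenotype_db`: `dir`, invisibly;
#'   `read_gene_phenotype_db`: the database.
#' @export
write_gene_phenotype_db <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) {
    write_atomic(function(tmp) {
      write.table(d, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
    }, file.path(dir, f))
  }
  wt(db$phenotype_gene, "phenotype_gene.tsv")
  wt(db$gene_disease, "gene_disease.tsv")
  wt(db$disease_meta, "disease_meta.tsv")
  if (!is.null(db$genes)) wt(db$genes, "genes.tsv")
  invisible(dir)
}

#' @rdname write_gene_phenotype_db
#' @export
read_gene_phenotype_db <- function(dir) {
  rd <- function(f, required = TRUE) {
    p <- file.path(dir, f)
    if (!file.exists(p)) {
      if (required) stop("missing database file: ", p) else return(NULL)
    }
    read.delim(p, stringsAsFactors = FALSE, check.names = FALSE)
  }
  db <- list(phenotype_gene = rd("phenotype_gene.tsv"),
             gene_disease = rd("gene_disease.tsv"),
             disease_meta = rd("disease_meta.tsv"),
             genes = rd("genes.tsv", required = FALSE))
  orphan <- setdiff(db$gene_disease$disease_id, db$disease_meta$disease_id)
  if (length(orphan)) {
    stop("gene_disease references unknown disease id(s): ",
         paste(head(orphan, 3), collapse = ", "))
  }
  structure(db, class = "gene_phenotype_db")
}

#' Simulate one patient with an implanted causal variant
#'
#' Implants the causal variant(s) of one database disease, honoring its
#' inheritance mode: autosomal dominant — one heterozygous hit; autosomal
#' recessive — either two heterozygous hits or one homozygous hit (drawn
#' at random); X-linked — one hemizygous hit. The causal variant is a
#' nonsense SNV absent from population databases and carries a curated
#' `DM` class. `n_background` common benign variants (allele frequency
#' drawn uniformly in \[0.01, 0.5\], so the default frequency filter
#' removes them) are added, and the patient's phenotype terms are the
#' disease's terms with `phenotype_noise["drop"]` terms removed and
#' `phenotype_noise["add"]` unrelated terms added.
#'
#' @param db a `gene_phenotype_db`.
#' @param disease_id disease to implant; `NULL` picks one at random.
#' @param n_background number of background variants.
#' @param phenotype_noise named vector `c(drop = 0, add = 0)`.
#' @param seed RNG seed.
#' @return list of class `sim_patient`: `variants` (VCF-ready table),
#'   `terms`, `truth` (implanted disease id, gene, causal keys),
#'   `freq_table` and `hgmd_table` (annotation stand-ins consistent with
#'   the simulation).
#' @export
simulate_patient <- function(db, disease_id = NULL, n_background = 200,
                             phenotype_noise = c(drop = 0, add = 0),
                             seed = NULL) {
  stopifnot(inherits(db, "gene_phenotype_db"))
  with_seed(seed, {
    meta <- db$disease_meta
    if (is.null(disease_id)) disease_id <- sample(meta$disease_id, 1)
    di <- match(disease_id, meta$disease_id)
    if (is.na(di)) stop("disease not in database: ", disease_id)
    genes <- db$gene_disease$gene[db$gene_disease$disease_id == disease_id]
    gene <- sample(genes, 1)
    gi <- match(gene, db$genes$gene)
    gchrom <- db$genes$chrom[gi]; gstart <- db$genes$start[gi]
    gend <- db$genes$end[gi]
    inh <- meta$inheritance[di]

    n_causal <- if (inh == "AR" && runif(1) < 0.5) 2L else 1L
    zyg <- if (inh == "AR" && n_causal == 1L) "hom" else
           if (inh == "XL") "hemi" else "het"
    cpos <- sort(sample(seq(gstart, gend), n_causal))
    cref <- sample(BASES, n_causal, replace = TRUE)
    calt <- vapply(cref, function(r) sample(setdiff(BASES, r), 1), "")
    causal <- data.frame(chrom = gchrom, pos = as.integer(cpos), ref = cref,
                         alt = unname(calt), var_type = "SNV", gene = gene,
                         consequence = "nonsense", zygosity = zyg,
                         allele_freq = NA_real_, end = NA_integer_,
                         stringsAsFactors = FALSE)

    bg <- simulate_truth_set(0, n_background)[, c("chrom", "pos", "ref", "alt")]
    background <- NULL
    if (n_background > 0) {
      background <- data.frame(
        bg, var_type = "SNV", gene = NA_character_,
        consequence = sample(c("missense", "synonymous", "other"),
                             n_background, replace = TRUE),
        zygosity = "het",
        allele_freq = round(runif(n_background, 0.01, 0.5), 4),
        end = NA_integer_, stringsAsFactors = FALSE)
      # annotate background with nearest gene when inside a gene interval
      hit <- mapply(function(ch, p) {
        j <- which(db$genes$chrom == ch & db$genes$start <= p & db$genes$end >= p)
        if (length(j)) db$genes$gene[j[1]] else NA_character_
      }, background$chrom, background$pos)
      background$gene <- unname(hit)
    }
    variants <- rbind(causal, background)
    rownames(variants) <- NULL

    dterms <- strsplit(meta$terms[di], ";")[[1]]
    n_drop <- min(phenotype_noise[["drop"]] %||% 0, length(dterms) - 1)
    terms <- if (n_drop > 0) {
      dterms[-sample(length(dterms), n_drop)]
    } else dterms
    n_add <- phenotype_noise[["add"]] %||% 0
    if (n_add > 0) {
      vocab <- setdiff(unique(db$phenotype_gene$term), dterms)
      terms <- c(terms, sample(vocab, min(n_add, length(vocab))))
    }

    freq_table <- variants[!is.na(variants$allele_freq),
                           c("chrom", "pos", "ref", "alt", "allele_freq")]
    hgmd_table <- data.frame(causal[, c("chrom", "pos", "ref", "alt")],
                             class = "DM", stringsAsFactors = FALSE)
    structure(list(
      variants = variants, terms = terms,
      truth = list(disease_id = disease_id, gene = gene,
                   causal_keys = variant_key(causal$chrom, causal$pos,
                                             causal$ref, causal$alt)),
      freq_table = freq_table, hgmd_table = hgmd_table),
      class = "sim_patient")
  })
}

#' Write a simulated patient to disk
#'
#' Emits `<id>.vcf` (the variant calls) and `<id>.phenotypes.txt` (one
#' term per line) plus `<id>.freq.tsv` / `<id>.hgmd.tsv` annotation
#' stand-ins, in the dialects consumed by [read_vcf()] and
#' [read_annotation_db()].
#'
#' @param patient a `sim_patient`.
#' @param dir output directory.
#' @param id patient identifier used as file stem.
#' @return named character vector of the written paths, invisibly.
#' @export
write_patient <- function(patient, dir, id = "patient") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, paste0(id, ".vcf")),
    phenotypes = file.path(dir, paste0(id, ".phenotypes.txt")),
    freq = file.path(dir, paste0(id, ".freq.tsv")),
    hgmd = file.path(dir, paste0(id, ".hgmd.tsv"))
  )
  write_vcf(patient$variants, paths[["vcf"]])
  write_atomic(patient$terms, paths[["phenotypes"]])
  wt <- function(d, p) write_atomic(function(tmp) {
    write.table(d, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  }, p)
  wt(patient$freq_table, paths[["freq"]])
  wt(patient$hgmd_table, paths[["hgmd"]])
  invisible(paths)
}
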