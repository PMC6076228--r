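#' Variant record constants
#'
#' Controlled vocabularies for variant records: variant types, functional
#' consequences and zygosity states.
#' @name variant-vocab
#' @keywords internal
NULL

VAR_TYPES <- c("SNV", "INDEL", "CNV_DEL", "CNV_DUP")
CONSEQUENCES <- c("missense", "nonsense", "frameshift", "inframe_indel",
                  "splicing", "synonymous", "other")
ZYGOSITIES <- c("het", "hom", "hemi", "unknown")

infer_var_type <- function(ref, alt) {
  ifelse(alt == "<DEL>", "CNV_DEL",
  ifelse(alt == "<DUP>", "CNV_DUP",
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV", "INDEL")))
}

parse_info <- function(info, key) {
  m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, "")
}

gt_to_zygosity <- function(gt) {
  gt <- sub(":.*", "", gt)
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(a) {
    a <- a[a != "."]
    if (!length(a)) return("unknown")
    if (length(a) == 1L) return(if (a == "0") "unknown" else "hemi")
    nonref <- sum(a != "0")
    if (nonref == 0L) "unknown" else if (nonref == length(a)) "hom" else "het"
  }, "")
}

#' Read variants from a VCF file
#'
#' Parses a VCF v4.x file into a variant table with one row per ALT allele
#' per data line, in file order. Multi-allelic lines are split. Symbolic
#' structural alleles `<DEL>` / `<DUP>` become copy-number records
#' (`CNV_DEL` / `CNV_DUP`); the `END` INFO key is carried along so
#' whole-gene events keep their span. Coordinates stay 1-based as in VCF.
#'
#' Recognized INFO keys: `GENE` (gene symbol), `CONSEQ` (functional
#' consequence, see [variant-vocab]), `AF` (allele frequency), `END`
#' (CNV end), `ZYG` (zygosity override when no genotype column is present),
#' `PROBAND` and `DISEASE` (sample metadata used by fixtures). Zygosity is
#' derived from the first sample's GT when present.
#'
#' @param path path to an uncompressed VCF file.
#' @return a `data.frame` with columns `chrom` (label, `chr` prefix
#'   stripped), `pos` (integer, 1-based), `ref`, `alt`, `var_type`, `gene`,
#'   `consequence`, `zygosity`, `allele_freq`, `end`, `info` (raw INFO
#'   string).
#' @export
#' @seealso [write_vcf()] for the inverse, [annotate()] to attach database
#'   annotations.
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !startsWith(lines[1], "##fileformat=VCF")) {
    stop("not a VCF file (missing ##fileformat header): ", path)
  }
  hdr <- grep("^#CHROM\t", lines)
  if (!length(hdr)) stop("not a VCF file (missing #CHROM column header): ", path)
  data_idx <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in data_idx) {
    if (length(strsplit(lines[i], "\t", fixed = TRUE)[[1]]) < 8L) {
      stop("unparseable VCF data line ", i, " in ", path,
           " (fewer than 8 tab-separated fields)")
    }
  }
  if (!length(data_idx)) {
    return(empty_variant_table())
  }

  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- if (ncol(v@gt) >= 2L) v@gt[, 2L] else rep(NA_character_, nrow(fix))
  if (is.null(dim(v@gt)) || !nrow(fix)) gt <- rep(NA_character_, nrow(fix))

  pos <- suppressWarnings(as.integer(fix$POS))
  if (anyNA(pos)) {
    bad <- data_idx[which(is.na(pos))[1]]
    stop("unparseable VCF data line ", bad, " in ", path, " (bad POS)")
  }
  info <- fix$INFO
  info[is.na(info)] <- ""

  out <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    zyg <- if (!is.na(gt[i])) gt_to_zygosity(gt[i]) else {
      z <- parse_info(info[i], "ZYG")
      if (!is.na(z) && z %in% ZYGOSITIES) z else "unknown"
    }
    data.frame(
      chrom = norm_chrom(fix$CHROM[i]),
      pos = pos[i],
      ref = fix$REF[i],
      alt = alts,
      var_type = infer_var_type(fix$REF[i], alts),
      gene = parse_info(info[i], "GENE"),
      consequence = parse_info(info[i], "CONSEQ"),
      zygosity = zyg,
      allele_freq = suppressWarnings(as.numeric(parse_info(info[i], "AF"))),
      end = suppressWarnings(as.integer(parse_info(info[i], "END"))),
      info = info[i],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  out$consequence[is.na(out$consequence)] <- "other"
  rownames(out) <- NULL
  out
}

empty_variant_table <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), var_type = character(), gene = character(),
             consequence = character(), zygosity = character(),
             allele_freq = numeric(), end = integer(), info = character(),
             stringsAsFactors = FALSE)
}

#' Write a variant table to a VCF file
#'
#' Serializes a variant table (as produced by [read_vcf()] or
#' [simulate_patient()]) to plain-text VCF v4.2. Gene, consequence,
#' zygosity, allele frequency and CNV end coordinates are written as INFO
#' keys so that [read_vcf()] round-trips them. Extra columns named
#' `MPPS_*` (from [predict.mpps()] results merged onto the table) are also
#' emitted as INFO keys.
#'
#' @param variants variant `data.frame` with at least `chrom,pos,ref,alt`.
#' @param path output file path (written atomically).
#' @return the path, invisibly.
#' @export
write_vcf <- function(variants, path) {
  stopifnot_cols(variants, c("chrom", "pos", "ref", "alt"), "variant table")
  info_keys <- list(
    GENE = variants$gene, CONSEQ = variants$consequence,
    AF = variants$allele_freq, END = variants$end,
    ZYG = variants$zygosity,
    PROBAND = variants$proband, DISEASE = variants$disease,
    MPPS_SCORE_DMG = variants$MPPS_SCORE_DMG,
    MPPS_SCORE_BEN = variants$MPPS_SCORE_BEN,
    MPPS_CLASS = variants$MPPS_CLASS,
    MPPS_MISCLASS = variants$MPPS_MISCLASS,
    MPPS_ROUND = variants$MPPS_ROUND
  )
  info_keys <- Filter(Negate(is.null), info_keys)
  n <- nrow(variants)
  info <- rep("", n)
  for (key in names(info_keys)) {
    val <- info_keys[[key]]
    keep <- !is.na(val)
    piece <- paste0(key, "=", val)
    info[keep] <- ifelse(nzchar(info[keep]), paste0(info[keep], ";", piece[keep]),
                         piece[keep])
  }
  info[!nzchar(info)] <- "."
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=mendeldx",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CONSEQ,Number=1,Type=String,Description=\"Functional consequence\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Population allele frequency\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of CNV\">",
    "##INFO=<ID=ZYG,Number=1,Type=String,Description=\"Zygosity\">",
    "##INFO=<ID=PROBAND,Number=1,Type=String,Description=\"Proband id\">",
    "##INFO=<ID=DISEASE,Number=1,Type=String,Description=\"Disease name\">",
    "##INFO=<ID=MPPS_SCORE_DMG,Number=1,Type=Float,Description=\"MPPS damaging-trio score\">",
    "##INFO=<ID=MPPS_SCORE_BEN,Number=1,Type=Float,Description=\"MPPS benign-trio score\">",
    "##INFO=<ID=MPPS_CLASS,Number=1,Type=String,Description=\"MPPS classification\">",
    "##INFO=<ID=MPPS_MISCLASS,Number=1,Type=Integer,Description=\"1 if no trio round agreed\">",
    "##INFO=<ID=MPPS_ROUND,Number=1,Type=Integer,Description=\"Trio-agreement round used\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  rows <- paste(variants$chrom, variants$pos, ".", variants$ref, variants$alt,
                ".", "PASS", info, sep = "\t")
  write_atomic(c(hdr, rows), path)
}

#' Assemble an annotation database
#'
#' Bundles the three lookup tables used by [annotate()]: population allele
#' frequencies, curated pathogenicity classes (HGMD-style: `DM` disease
#' mutation, `DM?` probable, `DP`/`DFP` associated polymorphisms) and raw
#' scores for the 17 deleteriousness predictors. All tables are keyed by
#' `(chrom, pos, ref, alt)`; chromosome labels are normalized by stripping
#' `chr`.
#'
#' @param freq_table `data.frame` with columns `chrom,pos,ref,alt,allele_freq`
#'   or `NULL`.
#' @param hgmd_table `data.frame` with columns `chrom,pos,ref,alt,class`
#'   (class in `DM, DM?, DP, DFP`) or `NULL`.
#' @param tool_table `data.frame` with columns `chrom,pos,ref,alt` plus one
#'   numeric column per predictor (names must be canonical, see
#'   [mpps_tools()]), or `NULL`.
#' @return an object of class `annotation_db`.
#' @export
annotation_db <- function(freq_table = NULL, hgmd_table = NULL,
                          tool_table = NULL) {
  check_key <- function(tab, what) {
    if (is.null(tab)) return(NULL)
    stopifnot_cols(tab, c("chrom", "pos", "ref", "alt"), what)
    tab$chrom <- norm_chrom(tab$chrom)
    key <- variant_key(tab$chrom, tab$pos, tab$ref, tab$alt)
    if (anyDuplicated(key)) {
      stop("duplicate variant keys in ", what, ": ",
           key[duplicated(key)][1])
    }
    tab
  }
  freq_table <- check_key(freq_table, "freq_table")
  hgmd_table <- check_key(hgmd_table, "hgmd_table")
  tool_table <- check_key(tool_table, "tool_table")
  if (!is.null(freq_table)) stopifnot_cols(freq_table, "allele_freq", "freq_table")
  if (!is.null(hgmd_table)) {
    stopifnot_cols(hgmd_table, "class", "hgmd_table")
    bad <- setdiff(unique(hgmd_table$class), c("DM", "DM?", "DP", "DFP"))
    if (length(bad)) stop("unknown HGMD class: ", paste(bad, collapse = ", "))
  }
  if (!is.null(tool_table)) {
    tool_cols <- setdiff(names(tool_table), c("chrom", "pos", "ref", "alt"))
    unknown <- setdiff(tool_cols, mpps_tools())
    if (length(unknown)) {
      stop("tool_table has non-canonical tool column(s): ",
           paste(unknown, collapse = ", "))
    }
    for (tc in tool_cols) {
      if (!is.numeric(tool_table[[tc]])) {
        raw <- suppressWarnings(as.numeric(tool_table[[tc]]))
        bad <- which(is.na(raw) & !is.na(tool_table[[tc]]) &
                       tool_table[[tc]] != "" & tool_table[[tc]] != ".")
        if (length(bad)) {
          stop("non-numeric raw score for tool ", tc, " at variant ",
               variant_key(tool_table$chrom[bad[1]], tool_table$pos[bad[1]],
                           tool_table$ref[bad[1]], tool_table$alt[bad[1]]))
        }
        tool_table[[tc]] <- raw
      }
    }
  }
  structure(list(freq_table = freq_table, hgmd_table = hgmd_table,
                 tool_table = tool_table),
            class = "annotation_db")
}

#' Read an annotation database from headered TSV files
#'
#' @param freq,hgmd,tools paths to headered TSV files (any may be `NULL`).
#'   Column layouts as in [annotation_db()].
#' @return an `annotation_db` object.
#' @export
read_annotation_db <- function(freq = NULL, hgmd = NULL, tools = NULL) {
  rd <- function(p) {
    if (is.null(p)) return(NULL)
    read.delim(p, stringsAsFactors = FALSE, check.names = FALSE,
               na.strings = c("NA", ".", ""))
  }
  annotation_db(rd(freq), rd(hgmd), rd(tools))
}

#' Annotate variants against an annotation database
#'
#' Left join: every input record is kept in order and gains an
#' `allele_freq` (NA when absent from the frequency table), an `hgmd`
#' class (`"absent"` when unknown) and one raw-score column per predictor
#' present in the database's tool table (NA where the predictor has no
#' score, i.e. an unclassified prediction).
#'
#' @param records variant `data.frame` (see [read_vcf()]).
#' @param db an [annotation_db()] object.
#' @return the input with annotation columns appended; same row count and
#'   order.
#' @export
annotate <- function(records, db) {
  stopifnot(inherits(db, "annotation_db"))
  stopifnot_cols(records, c("chrom", "pos", "ref", "alt"), "records")
  key <- variant_key(records$chrom, records$pos, records$ref, records$alt)
  out <- records
  if (!is.null(db$freq_table)) {
    i <- match(key, variant_key(db$freq_table$chrom, db$freq_table$pos,
                                db$freq_table$ref, db$freq_table$alt))
    out$allele_freq <- db$freq_table$allele_freq[i]
  } else if (is.null(out$allele_freq)) {
    out$allele_freq <- NA_real_
  }
  if (!is.null(db$hgmd_table)) {
    i <- match(key, variant_key(db$hgmd_table$chrom, db$hgmd_table$pos,
                                db$hgmd_table$ref, db$hgmd_table$alt))
    out$hgmd <- ifelse(is.na(i), "absent", db$hgmd_table$class[i])
  } else {
    out$hgmd <- "absent"
  }
  tool_cols <- character()
  if (!is.null(db$tool_table)) {
    tool_cols <- intersect(mpps_tools(), names(db$tool_table))
    i <- match(key, variant_key(db$tool_table$chrom, db$tool_table$pos,
                                db$tool_table$ref, db$tool_table$alt))
    for (tc in tool_cols) out[[tc]] <- db$tool_table[[tc]][i]
  }
  out
}

# 19 clinical categories of the diagnosable Mendelian diseases, with the
# number of diseases per category (sums to 4,413).
DISEASE_CATEGORIES <- data.frame(
  category = c(
    "Neuromuscular system disease", "Metabolic disease",
    "Growth and development abnormal", "Eye disease", "Bone disease",
    "Mental retardation and related syndromes", "Skin disease",
    "Circulatory system diseases", "Immune and infectious diseases",
    "Deafness and related syndromes", "Blood disease",
    "Endocrine system diseases", "Urinary system disease",
    "Reproductive system diseases", "Digestive system diseases",
    "Psychiatric and behavioral abnormal", "Cancer and Tumor Syndrome",
    "Respiratory system diseases", "Oral disease"),
  n_diseases = c(870L, 547L, 522L, 344L, 299L, 241L, 238L, 224L, 203L,
                 173L, 169L, 146L, 111L, 73L, 72L, 51L, 48L, 47L, 35L),
  stringsAsFactors = FALSE
)

#' Disease clinical-category table
#'
#' The built-in table of 19 clinical categories covering the 4,413
#' Mendelian diseases diagnosable on the targeted panel, with the number
#' of diseases per category. A user-supplied headered TSV with columns
#' `category` and `n_diseases` may be given instead.
#'
#' @param path optional path to a headered TSV; `NULL` (default) returns
#'   the built-in table.
#' @return `data.frame` with columns `category`, `n_diseases`.
#' @export
#' @examples
#' tab <- load_disease_category_table()
#' nrow(tab)            # 19
#' sum(tab$n_diseases)  # 4413
load_disease_category_table <- function(path = NULL) {
  if (is.null(path)) return(DISEASE_CATEGORIES)
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot_cols(tab, c("category", "n_diseases"), "category table")
  if (anyDuplicated(tab$category)) {
    stop("duplicate category name(s): ",
         paste(unique(tab$category[duplicated(tab$category)]), collapse = ", "))
  }
  if (nrow(tab) && any(tab$n_diseases < 0)) stop("negative disease counts")
  tab
}

#' Load the nine-proband validation fixture
#'
#' Ships the 9 probands with known, independently validated mutations used
#' to check concordance of panel sequencing: 11 mutation records in total
#' (two probands are compound heterozygous and contribute two records
#' each; whole-gene and multi-exon copy-number events contribute one
#' record each). Gene symbols, diseases and coding-level mutation
#' descriptions are the published ones; genomic coordinates in the VCF are
#' synthetic placeholders on the correct chromosomes, since the published
#' table reports mutations at the coding (HGVS c.) level only.
#'
#' @return a list with `variants` (the 11 records, with `proband` and
#'   `disease` columns) and `probands` (one row per proband: id, disease,
#'   gene, n_records).
#' @export
load_proband_fixture <- function() {
  path <- system.file("extdata", "table1_probands_synthetic_coords.vcf",
                      package = "mendeldx", mustWork = TRUE)
  v <- read_vcf(path)
  v$proband <- parse_info(v$info, "PROBAND")
  v$disease <- gsub("_", " ", parse_info(v$info, "DISEASE"))
  probands <- do.call(rbind, lapply(split(v, v$proband), function(d) {
    data.frame(proband = d$proband[1], disease = d$disease[1],
               gene = d$gene[1], n_records = nrow(d),
               stringsAsFactors = FALSE)
  }))
  probands <- probands[order(probands$proband), ]
  rownames(probands) <- NULL
  list(variants = v, probands = probands)
}

#' Read a phenotype term list
#'
#' One term per line; blank lines and `#` comments ignored.
#'
#' @param path path to a plain-text file.
#' @return character vector of terms.
#' @export
read_phenotype_terms <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}
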