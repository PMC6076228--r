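# Shared fixture builders. Everything is generated in code; no data files.

# Weight table with chosen per-tool weights (defaults 0.5), genome-wide
# fallback only unless `region` rows are supplied too.
make_weights <- function(w_dmg = numeric(), w_ben = w_dmg,
                         default = 0.5, regions = NULL) {
  tools <- mpps_tools()
  wd <- setNames(rep(default, length(tools)), tools)
  wb <- wd
  wd[names(w_dmg)] <- w_dmg
  wb[names(w_ben)] <- w_ben
  out <- data.frame(region = "genome", tool = tools, w_dmg = unname(wd),
                    w_ben = unname(wb), n_dmg = 100L, n_ben = 100L,
                    stringsAsFactors = FALSE)
  if (!is.null(regions)) out <- rbind(out, regions)
  structure(out, bin_size = 1e7, min_n = 50,
            class = c("mpps_weights", "data.frame"))
}

# Raw score guaranteed to map to `category` for `tool`.
raw_for <- function(tool, category) {
  mendeldx:::category_representative(tool, category)
}

# One-row profile assigning a category per named tool; others absent.
make_profile <- function(...) {
  cats <- list(...)
  prof <- data.frame(chrom = "1", pos = 500L, ref = "A", alt = "G",
                     stringsAsFactors = FALSE)
  for (tl in names(cats)) prof[[tl]] <- raw_for(tl, cats[[tl]])
  prof
}

# Profile with every non-conservation tool at the same category.
uniform_profile <- function(category, tools = setdiff(mpps_tools(),
                                                      mpps_tools(TRUE))) {
  args <- setNames(as.list(rep(category, length(tools))), tools)
  do.call(make_profile, args)
}

# Minimal VCF text written to a temp file; returns the path.
write_test_vcf <- function(body) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               body), path)
  path
}

# Tiny hand-built gene-phenotype database with fully known structure.
make_tiny_db <- function() {
  structure(list(
    phenotype_gene = data.frame(
      term = c("t1", "t2", "t3", "t4"),
      gene = c("GA", "GA", "GA", "GB"),
      stringsAsFactors = FALSE),
    gene_disease = data.frame(
      gene = c("GA", "GB", "GA"),
      disease_id = c("D01", "D02", "D03"),
      stringsAsFactors = FALSE),
    disease_meta = data.frame(
      disease_id = c("D01", "D02", "D03"),
      name = c("disease one", "disease two", "disease three"),
      category = "Eye disease",
      inheritance = c("AD", "AR", "AD"),
      terms = c("t1;t2;t3", "t4", "t9"),
      stringsAsFactors = FALSE),
    genes = data.frame(gene = c("GA", "GB"), chrom = c("1", "2"),
                       start = c(1000L, 1000L), end = c(200000L, 200000L),
                       stringsAsFactors = FALSE)),
    class = "gene_phenotype_db")
}
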