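#' @import methods
#' @importFrom stats setNames
NULL

GT_LEVELS <- c("hom_ref", "het", "hom_alt", "missing")
CLINVAR_LEVELS <- c("NR", "B", "LB", "LP", "P")
CONSEQUENCE_LEVELS <- c("missense", "synonymous")

# ---------------------------------------------------------------------------
# VariantSet: a per-alt-allele variant table plus a member x variant genotype
# matrix. This is the pipeline's canonical genotype carrier; functional
# annotations (gene, consequence, MAFs, ClinVar) arrive via side-car tables.
# ---------------------------------------------------------------------------

#' Construct a VariantSet
#'
#' A `fvn_variant_set` bundles a per-variant annotation table (one row per
#' alt allele per site) with a genotype matrix over pedigree members.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt` and
#'   optionally `gene`, `rsid`, `cdna_change`, `protein_change`,
#'   `consequence`, `maf_gnomad3`, `maf_1000g`, `qual`, `clinvar`, `novel`.
#'   Missing optional columns are added as `NA`. ClinVar categories are a
#'   semicolon-joined subset of `NR;B;LB;LP;P`.
#' @param geno character matrix, rows aligned with `variants`, one column per
#'   pedigree member, values in `hom_ref`, `het`, `hom_alt`, `missing`.
#' @return an object of class `fvn_variant_set` with elements `variants`
#'   (data.frame, including a `key` column `chrom:pos:ref:alt`) and `geno`.
#' @export
variant_set <- function(variants, geno) {
  stopifnot(is.data.frame(variants), is.matrix(geno))
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stopf("variants table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  opt <- c(gene = NA_character_, rsid = NA_character_,
           cdna_change = NA_character_, protein_change = NA_character_,
           consequence = NA_character_, clinvar = "NR")
  nr <- nrow(variants)
  for (nm in names(opt)) {
    if (is.null(variants[[nm]])) variants[[nm]] <- rep(opt[[nm]], nr)
  }
  for (nm in c("maf_gnomad3", "maf_1000g", "qual")) {
    if (is.null(variants[[nm]])) variants[[nm]] <- rep(NA_real_, nr)
  }
  if (is.null(variants$novel)) variants$novel <- rep(FALSE, nr)
  if (any(variants$pos < 1)) stopf("variant positions must be >= 1")
  for (nm in c("maf_gnomad3", "maf_1000g")) {
    bad <- !is.na(variants[[nm]]) &
      (variants[[nm]] < 0 | variants[[nm]] > 1)
    if (any(bad)) stopf("%s outside [0,1] for %s", nm,
                        variants$gene[bad][1])
  }
  if (nrow(variants) != nrow(geno)) {
    stopf("geno rows (%d) do not match variants rows (%d)",
          nrow(geno), nrow(variants))
  }
  bad_gt <- !(geno %in% GT_LEVELS)
  if (any(bad_gt)) stopf("invalid genotype value(s): %s",
                         paste(unique(geno[bad_gt]), collapse = ", "))
  variants$key <- variant_key(variants$chrom, variants$pos,
                              variants$ref, variants$alt)
  rownames(variants) <- NULL
  rownames(geno) <- variants$key
  structure(list(variants = variants, geno = geno),
            class = "fvn_variant_set")
}

#' @export
`[.fvn_variant_set` <- function(x, i, ...) {
  variant_set(x$variants[i, , drop = FALSE],
              x$geno[i, , drop = FALSE])
}

#' @export
print.fvn_variant_set <- function(x, ...) {
  cat(sprintf("<fvn_variant_set> %d variant(s) x %d member(s)\n",
              nrow(x$variants), ncol(x$geno)))
  invisible(x)
}

#' Number of variants in a VariantSet
#' @param x a `fvn_variant_set`
#' @export
n_variants <- function(x) nrow(x$variants)

#' ClinVar categories of each variant as a list of character sets
#' @param x a `fvn_variant_set`
#' @return list of character vectors (subset of NR/B/LB/LP/P) per variant
#' @export
clinvar_sets <- function(x) {
  lapply(x$variants$clinvar, function(cv) {
    s <- split_set(cv)
    if (length(s) == 0) "NR" else s
  })
}

# ---------------------------------------------------------------------------
# Pedigree
# ---------------------------------------------------------------------------

#' Read a 6-column PED pedigree file
#'
#' Whitespace-delimited columns: family id, member id, father id, mother id,
#' sex (1 male / 2 female / 0 unknown), affection status (2 affected,
#' 1 unaffected, 0 or -9 unknown). Unknown status is treated as unaffected
#' with a warning; `0` parent references mean "absent".
#'
#' @param path path to the PED file
#' @return a `fvn_pedigree` data.frame with columns `id`, `father`, `mother`,
#'   `sex`, `affected`
#' @export
read_ped <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0) stopf("PED file '%s' is empty", path)
  rows <- strsplit(trimws(lines), "\\s+")
  nc <- vapply(rows, length, integer(1))
  if (any(nc < 6)) {
    stopf("PED file '%s': line %d has %d columns (6 required)",
          path, which(nc < 6)[1], nc[nc < 6][1])
  }
  m <- do.call(rbind, lapply(rows, function(r) r[1:6]))
  ids <- m[, 2]
  if (anyDuplicated(ids)) {
    stopf("PED file '%s': duplicate member id(s): %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  status <- m[, 6]
  unknown <- status %in% c("0", "-9")
  if (any(unknown)) {
    warnf("PED: unknown affection status for %s; treated as unaffected",
          paste(ids[unknown], collapse = ", "))
  }
  ped <- data.frame(
    id = ids,
    father = ifelse(m[, 3] %in% c("0", "-9"), NA_character_, m[, 3]),
    mother = ifelse(m[, 4] %in% c("0", "-9"), NA_character_, m[, 4]),
    sex = ifelse(m[, 5] == "1", "male",
                 ifelse(m[, 5] == "2", "female", NA_character_)),
    affected = status == "2",
    stringsAsFactors = FALSE
  )
  unresolved <- setdiff(stats::na.omit(c(ped$father, ped$mother)), ped$id)
  if (length(unresolved)) {
    warnf("PED: parent id(s) not present as members: %s",
          paste(unresolved, collapse = ", "))
  }
  class(ped) <- c("fvn_pedigree", "data.frame")
  ped
}

#' Ids of affected pedigree members
#' @param pedigree a `fvn_pedigree`
#' @export
affected_ids <- function(pedigree) pedigree$id[pedigree$affected]

# ---------------------------------------------------------------------------
# Gene panel
# ---------------------------------------------------------------------------

#' Read a candidate gene panel (one symbol per line)
#'
#' Lines starting with `#` are comments. Symbols are uppercased and
#' deduplicated.
#'
#' @param path path to the panel file
#' @return a `fvn_gene_panel` character vector of unique uppercase symbols
#' @export
read_panel <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stopf("gene panel '%s' contains no symbols", path)
  structure(unique(toupper(lines)), class = "fvn_gene_panel")
}

# ---------------------------------------------------------------------------
# VCF
# ---------------------------------------------------------------------------

parse_gt <- function(gt, alt_index, sample, key) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return("missing")
  toks <- strsplit(gt, "[/|]")[[1]]
  if (any(toks == ".")) return("missing")
  alleles <- suppressWarnings(as.integer(toks))
  if (any(is.na(alleles)) || length(alleles) == 0) {
    warnf("unparsable genotype '%s' for %s at %s; set to missing",
          gt, sample, key)
    return("missing")
  }
  n_alt <- sum(alleles == alt_index)
  if (n_alt == 0) "hom_ref" else if (n_alt == 1) "het" else "hom_alt"
}

#' Read a multi-sample VCF into a VariantSet
#'
#' Multiallelic sites are split into one record per alt allele; genotypes are
#' recoded per member relative to that alt allele (unphased). Gene,
#' consequence, population MAFs and ClinVar arrive through `annotations`
#' (see [read_annotation_tables()]) joined on `chrom:pos:ref:alt`.
#'
#' @param path path to a VCF 4.x file (uncompressed or bgzipped)
#' @param pedigree a `fvn_pedigree`; every member id must have a sample
#'   column in the VCF
#' @param annotations optional `fvn_annotations` store whose variant table
#'   supplies gene/consequence/MAF/ClinVar fields
#' @return a `fvn_variant_set`, records sorted by (chrom, pos, alt)
#' @export
read_vcf <- function(path, pedigree, annotations = NULL) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  samples <- colnames(vcf)
  miss <- setdiff(pedigree$id, samples)
  if (length(miss)) {
    stopf("VCF '%s' lacks sample column(s) for pedigree member(s): %s",
          path, paste(miss, collapse = ", "))
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  n_sites <- length(rr)
  if (n_sites == 0) {
    ids <- pedigree$id
    return(variant_set(
      data.frame(chrom = character(0), pos = integer(0),
                 ref = character(0), alt = character(0),
                 stringsAsFactors = FALSE),
      matrix(character(0), nrow = 0, ncol = length(ids),
             dimnames = list(NULL, ids))
    ))
  }
  gt <- VariantAnnotation::geno(vcf)$GT[, pedigree$id, drop = FALSE]
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(rr$REF)
  alt_list <- lapply(seq_len(n_sites), function(i) {
    as.character(rr$ALT[[i]])
  })
  qual <- rr$QUAL
  ids <- names(rr)
  rows <- list(); genos <- list()
  for (i in seq_len(n_sites)) {
    alts <- alt_list[[i]]
    rsid <- if (!is.null(ids) && grepl("^rs", ids[i])) ids[i]
            else NA_character_
    for (k in seq_along(alts)) {
      key <- variant_key(chrom[i], pos[i], ref[i], alts[k])
      g <- vapply(pedigree$id, function(s)
        parse_gt(gt[i, s], k, s, key), character(1))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom[i], pos = pos[i], ref = ref[i], alt = alts[k],
        rsid = rsid, qual = if (is.na(qual[i])) NA_real_ else qual[i],
        stringsAsFactors = FALSE)
      genos[[length(genos) + 1L]] <- g
    }
  }
  variants <- do.call(rbind, rows)
  geno <- do.call(rbind, genos)
  colnames(geno) <- pedigree$id
  if (!is.null(annotations)) {
    variants <- join_variant_annotations(variants, annotations)
  }
  ord <- variant_order(variants)
  variant_set(variants[ord, , drop = FALSE], geno[ord, , drop = FALSE])
}

join_variant_annotations <- function(variants, annotations) {
  av <- annotations$variants
  if (is.null(av)) return(variants)
  key <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  idx <- match(key, av$key)
  unmatched <- key[is.na(idx)]
  if (length(unmatched)) {
    warnf("no annotation for %d variant record(s): %s", length(unmatched),
          paste(utils::head(unmatched, 5), collapse = ", "))
  }
  for (nm in c("gene", "cdna_change", "protein_change", "consequence",
               "clinvar")) {
    if (!is.null(av[[nm]])) variants[[nm]] <- av[[nm]][idx]
  }
  for (nm in c("maf_gnomad3", "maf_1000g")) {
    if (!is.null(av[[nm]])) variants[[nm]] <- as.numeric(av[[nm]][idx])
  }
  if (!is.null(av$novel)) variants$novel <- isTRUE_vec(av$novel[idx])
  if (!is.null(av$rsid)) {
    has <- !is.na(av$rsid[idx]) & nzchar(av$rsid[idx]) & av$rsid[idx] != "-"
    variants$rsid <- ifelse(has, av$rsid[idx], variants$rsid)
  }
  variants
}

isTRUE_vec <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

#' Write a VariantSet to a VCF 4.2 file
#'
#' One line per record (split multiallelics are written as separate
#' biallelic lines); genotypes are encoded unphased (`0/0`, `0/1`, `1/1`,
#' `./.`).
#'
#' @param x a `fvn_variant_set`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_vcf <- function(x, path) {
  v <- x$variants
  members <- colnames(x$geno)
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
               missing = "./.")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=famvarnet",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", members), collapse = "\t")
  ), con)
  for (i in seq_len(nrow(v))) {
    gts <- gt_code[x$geno[i, members]]
    line <- paste(c(
      v$chrom[i], v$pos[i],
      if (is.na(v$rsid[i])) "." else v$rsid[i],
      v$ref[i], v$alt[i],
      if (is.na(v$qual[i])) "." else format(v$qual[i], trim = TRUE),
      "PASS", ".", "GT", gts), collapse = "\t")
    writeLines(line, con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Annotation tables
# ---------------------------------------------------------------------------

#' Read side-car annotation tables into a joined store
#'
#' Two TSV dialects are understood. The *variant* table is keyed by
#' `chrom, pos, ref, alt` and carries `gene`, `consequence`
#' (missense/synonymous), `rsid`, `cdna_change`, `protein_change`,
#' `maf_gnomad3`, `maf_1000g`, `clinvar` (semicolon-joined categories) and
#' `novel`. The *regulatory* table is keyed by `rsid` (or
#' `gene`+`protein_change` when no rsid exists) and carries
#' `region_features`, `splicing`, `eqtl`, `sqtl` as semicolon-joined sets.
#'
#' Duplicate keys with identical values are collapsed; duplicate keys with
#' conflicting values are fatal.
#'
#' @param variant_tsv path to the variant annotation TSV (or `NULL`)
#' @param regulatory_tsv path to the regulatory/QTL TSV (or `NULL`)
#' @return a `fvn_annotations` list with elements `variants`, `regulatory`
#' @export
read_annotation_tables <- function(variant_tsv = NULL, regulatory_tsv = NULL) {
  store <- list(variants = NULL, regulatory = NULL)
  if (!is.null(variant_tsv)) {
    av <- read_tsv(variant_tsv)
    need <- c("chrom", "pos", "ref", "alt")
    miss <- setdiff(need, names(av))
    if (length(miss)) stopf("variant annotation table lacks: %s",
                            paste(miss, collapse = ", "))
    av$key <- variant_key(av$chrom, av$pos, av$ref, av$alt)
    av <- dedupe_keyed(av, "key", "variant annotation")
    store$variants <- av
  }
  if (!is.null(regulatory_tsv)) {
    rg <- read_tsv(regulatory_tsv)
    if (is.null(rg$rsid)) stopf("regulatory table lacks 'rsid' column")
    rg$rkey <- ifelse(!is.na(rg$rsid) & nzchar(rg$rsid) & rg$rsid != "-",
                      rg$rsid,
                      paste(rg$gene, rg$protein_change, sep = ":"))
    rg <- dedupe_keyed(rg, "rkey", "regulatory annotation")
    store$regulatory <- rg
  }
  structure(store, class = "fvn_annotations")
}

dedupe_keyed <- function(df, keycol, what) {
  if (!anyDuplicated(df[[keycol]])) return(df)
  split_rows <- split(seq_len(nrow(df)), df[[keycol]])
  offenders <- character(0)
  keep <- integer(0)
  for (k in names(split_rows)) {
    idx <- split_rows[[k]]
    block <- df[idx, setdiff(names(df), keycol), drop = FALSE]
    if (nrow(unique(block)) > 1) offenders <- c(offenders, k)
    keep <- c(keep, idx[1])
  }
  if (length(offenders)) {
    stopf("%s table: conflicting duplicate values for key(s): %s",
          what, paste(offenders, collapse = ", "))
  }
  df[sort(keep), , drop = FALSE]
}

#' Look up regulatory/QTL evidence for a variant
#'
#' @param annotations a `fvn_annotations` store
#' @param rsid dbSNP id (preferred key), or `NA`
#' @param gene,protein_change fallback key for variants without an rsid
#' @return list with character-set elements `region_features`, `splicing`,
#'   `eqtl`, `sqtl` (all empty when the variant is absent from the table)
#' @export
lookup_regulatory <- function(annotations, rsid = NA,
                              gene = NA, protein_change = NA) {
  empty <- list(region_features = character(0), splicing = character(0),
                eqtl = character(0), sqtl = character(0))
  rg <- annotations$regulatory
  if (is.null(rg)) return(empty)
  rkey <- if (!is.na(rsid) && nzchar(rsid) && rsid != "-") rsid else
    paste(gene, protein_change, sep = ":")
  i <- match(rkey, rg$rkey)
  if (is.na(i)) return(empty)
  list(region_features = split_set(rg$region_features[i]),
       splicing = split_set(rg$splicing[i]),
       eqtl = split_set(rg$eqtl[i]),
       sqtl = split_set(rg$sqtl[i]))
}
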