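# Low-frequency filtering and segregation structure across the family.

#' Apply the panel / frequency / quality / segregation filter
#'
#' Keeps records whose gene is on the candidate panel, whose call quality
#' exceeds `qual_min`, whose minor allele frequency is strictly below
#' `maf_max` in *both* population databases (a variant absent from a
#' database passes that database's test: novel and unreported variants are
#' by construction rare), and -- when `require_het_in_affected` -- that are
#' heterozygous in at least one affected pedigree member. Homozygous-alt
#' genotypes alone do not satisfy the heterozygosity requirement, though
#' such members still count as carriers downstream.
#'
#' @param x a `fvn_variant_set`
#' @param panel a `fvn_gene_panel` (or character vector of symbols)
#' @param pedigree a `fvn_pedigree`; must contain at least one affected
#'   member when `require_het_in_affected` is `TRUE`
#' @param maf_max exclusive MAF upper bound, in (0, 1]; default 0.04
#' @param qual_min exclusive lower bound on call quality; default 30
#' @param require_het_in_affected require a het genotype in >= 1 affected
#'   member; default `TRUE`
#' @return the filtered `fvn_variant_set`, sorted by (chrom, pos, alt)
#' @export
apply_frequency_filter <- function(x, panel, pedigree, maf_max = 0.04,
                                   qual_min = 30,
                                   require_het_in_affected = TRUE) {
  if (!is.numeric(maf_max) || maf_max <= 0 || maf_max > 1) {
    stopf("maf_max must be in (0, 1], got %s", format(maf_max))
  }
  aff <- affected_ids(pedigree)
  if (require_het_in_affected && length(aff) == 0) {
    stopf("pedigree has no affected members")
  }
  v <- x$variants
  panel_syms <- toupper(as.character(panel))
  in_panel <- !is.na(v$gene) & toupper(v$gene) %in% panel_syms
  qual_ok <- !is.na(v$qual) & v$qual > qual_min
  maf_ok <- (is.na(v$maf_gnomad3) | v$maf_gnomad3 < maf_max) &
            (is.na(v$maf_1000g)   | v$maf_1000g   < maf_max)
  keep <- in_panel & qual_ok & maf_ok
  if (require_het_in_affected) {
    het_aff <- apply(x$geno[, aff, drop = FALSE] == "het", 1, any)
    keep <- keep & het_aff
  }
  x[which(keep)]
}

#' Partition a variant set by consequence
#'
#' @param x a `fvn_variant_set` whose records all carry a known consequence
#' @return list with `fvn_variant_set` elements `missense` and `synonymous`,
#'   input order preserved within each class
#' @export
split_by_consequence <- function(x) {
  cons <- x$variants$consequence
  bad <- is.na(cons) | !(cons %in% CONSEQUENCE_LEVELS)
  if (any(bad)) {
    stopf("unknown consequence '%s' for variant %s",
          cons[bad][1], x$variants$key[bad][1])
  }
  list(missense = x[which(cons == "missense")],
       synonymous = x[which(cons == "synonymous")])
}

#' Build the carrier matrix for a variant set
#'
#' A member is a carrier of a variant when its genotype is `het` or
#' `hom_alt`. Missing genotypes are not carriers.
#'
#' @param x a `fvn_variant_set`
#' @param pedigree a `fvn_pedigree`
#' @return a `fvn_carrier_matrix`: list with `variants` (the annotation
#'   table), `carriers` (named list, variant key -> member ids),
#'   `affected_carriers` (same, restricted to affected members) and
#'   `zygosity` (the genotype matrix)
#' @export
carrier_matrix <- function(x, pedigree) {
  stopifnot(all(colnames(x$geno) %in% pedigree$id))
  aff <- affected_ids(pedigree)
  is_carrier <- x$geno == "het" | x$geno == "hom_alt"
  members <- colnames(x$geno)
  carriers <- lapply(seq_len(nrow(is_carrier)), function(i) {
    members[is_carrier[i, ]]
  })
  names(carriers) <- x$variants$key
  affected_carriers <- lapply(carriers, function(cc) intersect(cc, aff))
  structure(list(variants = x$variants, carriers = carriers,
                 affected_carriers = affected_carriers,
                 zygosity = x$geno, pedigree = pedigree),
            class = "fvn_carrier_matrix")
}

#' Count variants carried per affected member
#'
#' Typically applied to a carrier matrix built on the missense partition to
#' summarize per-patient mutational burden.
#'
#' @param matrix a `fvn_carrier_matrix`
#' @param pedigree a `fvn_pedigree`
#' @param members member ids to count for; default all affected
#' @return named integer vector, member id -> number of carried variants
#' @export
count_carried_per_member <- function(matrix, pedigree,
                                     members = affected_ids(pedigree)) {
  unknown <- setdiff(members, pedigree$id)
  if (length(unknown)) {
    stopf("member(s) not in pedigree: %s", paste(unknown, collapse = ", "))
  }
  counts <- vapply(members, function(m) {
    sum(vapply(matrix$carriers, function(cc) m %in% cc, logical(1)))
  }, integer(1))
  stats::setNames(as.integer(counts), members)
}

#' Variants carried by every affected member
#'
#' Set intersection of the carrier sets over all affected members.
#'
#' @param matrix a `fvn_carrier_matrix`
#' @param pedigree a `fvn_pedigree`
#' @return character vector of variant keys, in genomic order
#' @export
shared_in_affected <- function(matrix, pedigree) {
  aff <- affected_ids(pedigree)
  if (length(aff) == 0) return(character(0))
  shared <- vapply(matrix$affected_carriers, function(cc) {
    all(aff %in% cc)
  }, logical(1))
  keys <- names(shared)[shared]
  v <- matrix$variants[match(keys, matrix$variants$key), , drop = FALSE]
  keys[variant_order(v)]
}

#' Detect linkage / compound-heterozygous groups
#'
#' Groups of two or more same-gene variants all carried by at least one
#' member. Without phase information true linkage (same haplotype) cannot
#' be distinguished from compound heterozygosity (opposite haplotypes), so
#' both are reported as one group kind. For each gene, each member's
#' maximal co-carried variant set of size >= 2 is a candidate group;
#' identical sets are merged, listing all supporting members.
#'
#' @param x a `fvn_variant_set` (may span both the low-frequency set and
#'   supplementary frequent variants)
#' @param matrix a `fvn_carrier_matrix` built on `x`
#' @return data.frame with columns `gene`, `variants` (semicolon-joined
#'   keys), `n_variants`, `members` (semicolon-joined ids), `kind`
#' @export
linkage_groups <- function(x, matrix) {
  v <- x$variants
  out <- list()
  for (g in sort(unique(stats::na.omit(v$gene)))) {
    keys <- v$key[!is.na(v$gene) & v$gene == g]
    if (length(keys) < 2) next
    members <- colnames(matrix$zygosity)
    carried <- lapply(members, function(m) {
      keys[vapply(keys, function(k) m %in% matrix$carriers[[k]],
                  logical(1))]
    })
    names(carried) <- members
    carried <- carried[vapply(carried, length, integer(1)) >= 2]
    if (length(carried) == 0) next
    sets <- vapply(carried, function(kk) {
      vv <- v[match(kk, v$key), , drop = FALSE]
      paste(kk[variant_order(vv)], collapse = ";")
    }, character(1))
    for (s in unique(sets)) {
      supp <- sort(names(sets)[sets == s])
      out[[length(out) + 1L]] <- data.frame(
        gene = g, variants = s,
        n_variants = length(split_set(s)),
        members = paste(supp, collapse = ";"),
        kind = "linked_or_compound_het",
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(gene = character(0), variants = character(0),
                      n_variants = integer(0), members = character(0),
                      kind = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$gene, -res$n_variants, res$variants), , drop = FALSE]
}
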