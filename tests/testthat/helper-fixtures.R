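# In-code builders for small test objects.

toy_pedigree <- function(ids = c("A1", "A2", "U1"),
                         affected = c(TRUE, TRUE, FALSE)) {
  ped <- data.frame(id = ids, father = NA_character_,
                    mother = NA_character_, sex = NA_character_,
                    affected = affected, stringsAsFactors = FALSE)
  class(ped) <- c("fvn_pedigree", "data.frame")
  ped
}

# n variants on one chromosome; geno is a character matrix or a default of
# all hom_ref
toy_variant_set <- function(n = 3, members = c("A1", "A2", "U1"),
                            gene = paste0("G", seq_len(n)),
                            consequence = rep("missense", n),
                            maf = rep(0.001, n), qual = rep(90, n),
                            geno = NULL, clinvar = rep("NR", n)) {
  v <- data.frame(chrom = "chr1", pos = 1000L + seq_len(n),
                  ref = "A", alt = "G", gene = gene,
                  rsid = sprintf("rs%d", seq_len(n)),
                  cdna_change = NA_character_,
                  protein_change = sprintf("p.X%d", seq_len(n)),
                  consequence = consequence,
                  maf_gnomad3 = maf, maf_1000g = maf, qual = qual,
                  clinvar = clinvar, novel = FALSE,
                  stringsAsFactors = FALSE)
  if (is.null(geno)) {
    geno <- matrix("hom_ref", n, length(members),
                   dimnames = list(NULL, members))
  }
  variant_set(v, geno)
}

# cached fixture bundle (loading parses the VCF once per test file)
fixture_bundle <- local({
  fx <- NULL
  function() {
    if (is.null(fx)) fx <<- load_paper_fixture()
    fx
  }
})

fixture_gene_key <- function(fx, gene, protein_change = NULL) {
  v <- fx$variants$variants
  hit <- !is.na(v$gene) & v$gene == gene
  if (!is.null(protein_change)) hit <- hit & v$protein_change == protein_change
  v$key[hit]
}

# uniform random prediction matrix over the standard 15 tools
random_prediction_matrix <- function(n, seed) {
  set.seed(seed)
  tools <- prediction_tools()
  m <- matrix(round(stats::runif(n * length(tools)), 4), nrow = n,
              dimnames = list(sprintf("v%03d", seq_len(n)), tools))
  cutoffs <- data.frame(tool = tools, damaging_min = 0.5,
                        neutral_max = 0.25)
  prediction_matrix(m, cutoffs)
}
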