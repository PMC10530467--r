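# Packaged study fixture: the printed family data (variant table, pedigree,
# carriers, ClinVar, QTL features) transcribed to standard formats, plus a
# predictor-score encoding consistent with the reported consensus counts, a
# mini interaction edge database and a term database. Predictor raw scores
# and interaction channel scores are synthetic values consistent with the
# published categories and tier statements (the printed panels are not
# machine-readable); they are labelled as such here and in the data files.

#' Paths of the packaged study fixture files
#' @return named list of file paths under the installed package
#' @export
fixture_paths <- function() {
  dir <- system.file("extdata", "fixture", package = "famvarnet",
                     mustWork = TRUE)
  list(
    ped = file.path(dir, "family.ped"),
    vcf = file.path(dir, "family.vcf"),
    panel = file.path(dir, "panel.txt"),
    variants = file.path(dir, "variants.tsv"),
    regulatory = file.path(dir, "regulatory.tsv"),
    scores = file.path(dir, "scores.tsv"),
    cutoffs = file.path(dir, "cutoffs.tsv"),
    edge_db = file.path(dir, "edge_db.tsv"),
    terms = file.path(dir, "terms.gmt"),
    config = file.path(dir, "config.json"))
}

#' Load the packaged study fixture
#'
#' Returns the complete input bundle for a pipeline run: the six-member,
#' three-generation pedigree (three affected), the 22 low-frequency
#' variant records plus frequent/supplementary and distractor records,
#' regulatory/QTL annotations, the 15-tool prediction matrix with pinned
#' cutoffs, the mini interaction and term databases, and the run
#' configuration (thresholds, manual includes, network-eligible genes,
#' per-patient extra includes).
#'
#' @return a list with elements `pedigree`, `panel`, `annotations`,
#'   `variants` (a `fvn_variant_set` with annotations joined), `pm`
#'   (`fvn_prediction_matrix`), `edge_db`, `term_db`, `background`,
#'   `config`, `paths`
#' @export
load_paper_fixture <- function() {
  p <- fixture_paths()
  ped <- read_ped(p$ped)
  panel <- read_panel(p$panel)
  ann <- read_annotation_tables(variant_tsv = p$variants,
                                regulatory_tsv = p$regulatory)
  vs <- read_vcf(p$vcf, ped, annotations = ann)
  pm <- read_prediction_matrix(p$scores, p$cutoffs)
  edge_db <- read_edge_db(p$edge_db)
  term_db <- read_term_db(p$terms)
  cfg <- jsonlite::read_json(p$config, simplifyVector = TRUE)
  background <- sort(unique(toupper(c(
    as.character(panel), unlist(term_db$genes),
    cfg$manual_includes))))
  list(pedigree = ped, panel = panel, annotations = ann, variants = vs,
       pm = pm, edge_db = edge_db, term_db = term_db,
       background = background, config = cfg, paths = p)
}
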