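# Multi-tool deleteriousness consensus, REVEL ranking and rule-based
# prioritization with eQTL/sQTL and ClinVar evidence joins.

#' Default ordered tool list for the prediction matrix
#'
#' Fourteen fixed predictors plus one configurable slot (default `CADD`).
#' All scores are expected on a common "higher = more damaging" [0, 1]
#' orientation; tools whose native scale differs (e.g. SIFT, where low
#' means damaging) must be inverted/min-max mapped at ingestion.
#' @param extra name of the fifteenth, configurable tool slot
#' @export
prediction_tools <- function(extra = "CADD") {
  c("ClinPred", "DANNCoding", "MetaSVM", "REVEL", "VEST4", "FATHMM-XF",
    "MetaLR", "PhD-SNPg", "LRT", "MutationAssessor", "MutationTaster",
    "PROVEAN", "PolyPhen-2", "SIFT", extra)
}

#' Construct a prediction matrix
#'
#' @param scores numeric matrix, variants (rows, named by variant key) x
#'   tools (columns); `NA` means the tool produced no score
#' @param cutoffs data.frame with columns `tool`, `damaging_min`,
#'   `neutral_max`; per tool, `damaging_min >= neutral_max` is required
#' @return a `fvn_prediction_matrix` list with `scores`, `cutoffs`, `tools`
#' @export
prediction_matrix <- function(scores, cutoffs) {
  stopifnot(is.matrix(scores), is.numeric(scores),
            is.data.frame(cutoffs))
  miss <- setdiff(c("tool", "damaging_min", "neutral_max"), names(cutoffs))
  if (length(miss)) stopf("cutoffs lack column(s): %s",
                          paste(miss, collapse = ", "))
  scored_tools <- colnames(scores)[colSums(!is.na(scores)) > 0]
  no_cut <- setdiff(scored_tools, cutoffs$tool)
  if (length(no_cut)) stopf("no cutoffs defined for tool(s): %s",
                            paste(no_cut, collapse = ", "))
  bad <- cutoffs$damaging_min < cutoffs$neutral_max
  if (any(bad)) stopf("damaging_min < neutral_max for tool(s): %s",
                      paste(cutoffs$tool[bad], collapse = ", "))
  structure(list(scores = scores, cutoffs = cutoffs,
                 tools = colnames(scores)),
            class = "fvn_prediction_matrix")
}

#' Read a prediction score matrix and cutoff table from TSV
#'
#' The score TSV has a `key` column (variant key) followed by one numeric
#' column per tool; the cutoff TSV has columns `tool`, `damaging_min`,
#' `neutral_max`.
#' @param scores_tsv,cutoffs_tsv file paths
#' @return a `fvn_prediction_matrix`
#' @export
read_prediction_matrix <- function(scores_tsv, cutoffs_tsv) {
  sc <- read_tsv(scores_tsv)
  if (is.null(sc$key)) stopf("score table lacks 'key' column")
  keys <- sc$key
  m <- as.matrix(sc[, setdiff(names(sc), "key"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- keys
  prediction_matrix(m, read_tsv(cutoffs_tsv))
}

#' Categorize prediction scores as neutral / moderate / damaging
#'
#' Per tool: `score >= damaging_min` is damaging, `score <= neutral_max`
#' neutral, in between moderate; absent scores are `missing`. Scores
#' outside [0, 1] are fatal (all tools are ingested on a common [0, 1]
#' orientation).
#'
#' @param pm a `fvn_prediction_matrix`
#' @return character matrix of categories, same shape as `pm$scores`
#' @export
categorize_scores <- function(pm) {
  s <- pm$scores
  out_of_range <- which(!is.na(s) & (s < 0 | s > 1), arr.ind = TRUE)
  if (nrow(out_of_range)) {
    i <- out_of_range[1, ]
    stopf("score %.3f outside [0,1] for tool %s, variant %s",
          s[i[1], i[2]], colnames(s)[i[2]], rownames(s)[i[1]])
  }
  cats <- matrix("missing", nrow(s), ncol(s), dimnames = dimnames(s))
  for (tool in colnames(s)) {
    ci <- match(tool, pm$cutoffs$tool)
    if (is.na(ci)) next  # tool with no scores anywhere
    dmin <- pm$cutoffs$damaging_min[ci]
    nmax <- pm$cutoffs$neutral_max[ci]
    x <- s[, tool]
    cats[, tool] <- ifelse(is.na(x), "missing",
                    ifelse(x >= dmin, "damaging",
                    ifelse(x <= nmax, "neutral", "moderate")))
  }
  cats
}

#' Count damaging votes per variant
#'
#' @param categories category matrix from [categorize_scores()]
#' @param variant optional single variant key; when given, returns a scalar
#' @return named integer vector (or scalar) of damaging-tool counts;
#'   missing tools contribute zero
#' @export
damaging_vote_count <- function(categories, variant = NULL) {
  votes <- as.integer(rowSums(categories == "damaging"))
  names(votes) <- rownames(categories)
  if (!is.null(variant)) {
    if (!variant %in% names(votes)) stopf("unknown variant '%s'", variant)
    return(votes[[variant]])
  }
  votes
}

#' Rank missense variants by REVEL score
#'
#' Descending REVEL order; ties broken by damaging votes (descending) then
#' gene symbol (ascending). Variants lacking a REVEL score are placed after
#' all ranked variants in input order with `NA` rank. Quartiles are
#' assigned over the ranked variants by rank position
#' (`ceiling(4 * rank / n_ranked)`).
#'
#' @param pm a `fvn_prediction_matrix` containing a `REVEL` column
#' @param x a missense-only `fvn_variant_set` (non-missense input is fatal)
#' @return decision data.frame with columns `key`, `gene`,
#'   `protein_change`, `consequence`, `revel_score`, `rank`, `quartile`,
#'   `damaging_votes`
#' @export
rank_by_revel <- function(pm, x) {
  v <- x$variants
  if (any(is.na(v$consequence) | v$consequence != "missense")) {
    stopf("rank_by_revel expects missense variants only (offender: %s)",
          v$key[which(is.na(v$consequence) | v$consequence != "missense")[1]])
  }
  votes <- damaging_vote_count(categorize_scores(pm))
  revel <- pm$scores[match(v$key, rownames(pm$scores)), "REVEL"]
  dv <- as.integer(votes[v$key])
  dv[is.na(dv)] <- 0L
  d <- data.frame(key = v$key, gene = v$gene,
                  protein_change = v$protein_change,
                  consequence = v$consequence,
                  revel_score = as.numeric(revel),
                  damaging_votes = dv,
                  stringsAsFactors = FALSE)
  has <- !is.na(d$revel_score)
  ranked <- d[has, , drop = FALSE]
  ord <- order(-ranked$revel_score, -ranked$damaging_votes, ranked$gene)
  ranked <- ranked[ord, , drop = FALSE]
  ranked$rank <- seq_len(nrow(ranked))
  ranked$quartile <- if (nrow(ranked)) {
    as.integer(ceiling(4 * ranked$rank / nrow(ranked)))
  } else integer(0)
  unranked <- d[!has, , drop = FALSE]
  if (nrow(unranked)) {
    unranked$rank <- NA_integer_
    unranked$quartile <- NA_integer_
  }
  res <- rbind(ranked, unranked)
  rownames(res) <- NULL
  res
}

clinvar_nonreported <- function(cv_string) {
  length(setdiff(split_set(cv_string), "NR")) == 0
}

#' Apply the prioritization rules
#'
#' Two evidence flags mirror the study's highlighting conventions:
#' `flag_plus` marks variants detected in at least `affected_min` affected
#' subjects and damaging by at least `votes_min` tools; `flag_star` marks
#' variants damaging by at least `votes_min` tools and supported by
#' eQTL/sQTL or ClinVar evidence (`clinvar_star` controls whether any
#' reported category counts, or only LP/P).
#'
#' The status rule is configurable:
#' * `"low_evidence_exclusion"` (default): a variant is *not* prioritized
#'   only when it has fewer than `votes_min` damaging votes *and* no
#'   functional correlates (no QTL genes and no LP/P ClinVar category) --
#'   i.e. the low-evidence exclusion applied in the source workflow.
#' * `"flags_only"`: prioritized iff `flag_plus` or `flag_star`.
#'
#' Variants whose gene is in `manual_includes` get status
#' `manual_include` regardless of flags (a manual include absent from the
#' input is fatal).
#'
#' @param decisions decision data.frame from [rank_by_revel()] (rows may be
#'   appended for manual-include variants, with `NA` votes)
#' @param annotations `fvn_annotations` store supplying eQTL/sQTL sets
#'   (may be `NULL`: no QTL evidence)
#' @param x the `fvn_variant_set` the decisions refer to (supplies rsid and
#'   ClinVar categories)
#' @param affected_carriers named integer vector, variant key -> number of
#'   affected carriers
#' @param manual_includes character vector of gene symbols to force-include
#' @param votes_min minimum damaging votes, default 4
#' @param affected_min minimum affected carriers for `flag_plus`, default 2
#' @param status_rule see Details
#' @param clinvar_star `"any"` (default; any non-NR category supports
#'   `flag_star`) or `"pathogenic"` (LP/P only)
#' @return the decision data.frame with added columns `affected_carriers`,
#'   `has_qtl`, `clinvar`, `flag_plus`, `flag_star`, `status`, `reason`
#' @export
prioritize <- function(decisions, annotations, x, affected_carriers,
                       manual_includes = character(0),
                       votes_min = 4, affected_min = 2,
                       status_rule = c("low_evidence_exclusion",
                                       "flags_only"),
                       clinvar_star = c("any", "pathogenic")) {
  status_rule <- match.arg(status_rule)
  clinvar_star <- match.arg(clinvar_star)
  d <- decisions
  miss_mi <- setdiff(toupper(manual_includes), toupper(d$gene))
  if (length(miss_mi)) {
    stopf("manual include(s) not found among input variants: %s",
          paste(miss_mi, collapse = ", "))
  }
  vi <- match(d$key, x$variants$key)
  rsid <- x$variants$rsid[vi]
  cv <- x$variants$clinvar[vi]
  cv[is.na(cv)] <- "NR"
  d$affected_carriers <- as.integer(affected_carriers[d$key])
  d$affected_carriers[is.na(d$affected_carriers)] <- 0L
  qtl <- vapply(seq_len(nrow(d)), function(i) {
    reg <- lookup_regulatory(annotations %||% list(regulatory = NULL),
                             rsid = rsid[i], gene = d$gene[i],
                             protein_change = d$protein_change[i])
    length(union(reg$eqtl, reg$sqtl)) > 0
  }, logical(1))
  d$has_qtl <- qtl
  d$clinvar <- cv
  cv_reported <- !vapply(cv, clinvar_nonreported, logical(1))
  cv_pathogenic <- vapply(cv, function(s) {
    length(intersect(split_set(s), c("LP", "P"))) > 0
  }, logical(1))
  votes <- ifelse(is.na(d$damaging_votes), 0L, d$damaging_votes)
  star_cv <- if (clinvar_star == "any") cv_reported else cv_pathogenic
  d$flag_plus <- d$affected_carriers >= affected_min & votes >= votes_min
  d$flag_star <- votes >= votes_min & (d$has_qtl | star_cv)
  is_manual <- toupper(d$gene) %in% toupper(manual_includes)
  prio <- switch(status_rule,
    flags_only = d$flag_plus | d$flag_star,
    low_evidence_exclusion = votes >= votes_min | d$has_qtl | cv_pathogenic)
  d$status <- ifelse(is_manual, "manual_include",
                     ifelse(prio, "prioritized", "not_prioritized"))
  d$reason <- ifelse(is_manual, "manual_include",
              ifelse(d$flag_plus & d$flag_star, "plus_and_star",
              ifelse(d$flag_plus, "plus",
              ifelse(d$flag_star, "star",
              ifelse(prio & votes >= votes_min, "votes_ge_min",
              ifelse(prio & d$has_qtl, "qtl_evidence",
              ifelse(prio, "clinvar_pathogenic",
                     "low_votes_no_evidence")))))))
  d
}

#' Export the heatmap matrices (probability and category panels)
#'
#' Writes two bit-stable TSVs with rows in rank order (unranked rows last)
#' and one column per tool, plus the evidence flag columns: `plus`, `star`
#' and `delta` (variant prioritized but excluded from network analysis).
#'
#' @param pm a `fvn_prediction_matrix`
#' @param decisions finalized decisions from [prioritize()]
#' @param scores_out,categories_out output TSV paths
#' @param network_eligible optional character vector of gene symbols
#'   entering network analysis (used for the `delta` flag)
#' @return invisible character vector of the two paths
#' @export
export_heatmap_matrix <- function(pm, decisions, scores_out, categories_out,
                                  network_eligible = NULL) {
  d <- decisions[order(is.na(decisions$rank), decisions$rank), ,
                 drop = FALSE]
  cats <- categorize_scores(pm)
  idx <- match(d$key, rownames(pm$scores))
  flag <- data.frame(
    key = d$key, gene = d$gene, rank = d$rank,
    plus = ifelse(isTRUE_vec(d$flag_plus), "+", ""),
    star = ifelse(isTRUE_vec(d$flag_star), "*", ""),
    delta = if (is.null(network_eligible)) rep("", nrow(d)) else
      ifelse(d$status %in% c("prioritized", "manual_include") &
               !(toupper(d$gene) %in% toupper(network_eligible)),
             "D", ""),
    stringsAsFactors = FALSE)
  sc <- as.data.frame(pm$scores[idx, , drop = FALSE])
  ct <- as.data.frame(cats[idx, , drop = FALSE])
  rownames(sc) <- rownames(ct) <- NULL
  write_tsv(cbind(flag, sc), scores_out)
  write_tsv(cbind(flag, ct), categories_out)
  invisible(c(scores_out, categories_out))
}
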