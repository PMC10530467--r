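# Per-patient protein interaction networks from channelized evidence, with
# prior-corrected noisy-OR score combination, confidence tiers and
# hypergeometric term enrichment (BH FDR).

EVIDENCE_CHANNELS <- c("neighborhood", "fusion", "cooccurrence",
                       "experimental", "database", "coexpression",
                       "textmining")

#' Default tier lower bounds for combined confidence scores
#' @export
default_tier_bounds <- function() {
  c(low = 0.15, medium = 0.4, high = 0.7, highest = 0.9)
}

#' Read an interaction edge database (long TSV)
#'
#' Columns: `protein_a`, `protein_b`, `channel`, `score`. Pairs are
#' normalized lexicographically; unknown channels are fatal.
#'
#' @param path TSV path
#' @return a `fvn_edge_db` data.frame
#' @export
read_edge_db <- function(path) {
  db <- read_tsv(path)
  miss <- setdiff(c("protein_a", "protein_b", "channel", "score"),
                  names(db))
  if (length(miss)) stopf("edge db lacks column(s): %s",
                          paste(miss, collapse = ", "))
  bad <- !(db$channel %in% EVIDENCE_CHANNELS)
  if (any(bad)) stopf("unknown evidence channel(s): %s",
                      paste(unique(db$channel[bad]), collapse = ", "))
  a <- pmin(toupper(db$protein_a), toupper(db$protein_b))
  b <- pmax(toupper(db$protein_a), toupper(db$protein_b))
  db$protein_a <- a
  db$protein_b <- b
  class(db) <- c("fvn_edge_db", "data.frame")
  db
}

#' Combine per-channel evidence scores into one confidence score
#'
#' STRING-style prior-corrected noisy-OR: each channel score is corrected
#' for the prior, `s' = (s - p) / (1 - p)`; the corrected scores are
#' combined as `u = 1 - prod(1 - s')`; the prior is added back,
#' `combined = u * (1 - p) + p`. With a single channel the combination
#' returns that channel's score exactly; with no channels it returns `p`.
#' Channels scoring below the prior carry no information beyond it and are
#' dropped with a warning.
#'
#' @param scores named (or unnamed) numeric vector of channel scores in
#'   [0, 1]
#' @param prior random-expectation prior probability `p` in [0, 1);
#'   default 0.041
#' @return combined confidence score in [p, 1)
#' @export
combine_channel_scores <- function(scores, prior = 0.041) {
  stopifnot(is.numeric(prior), prior >= 0, prior < 1)
  if (length(scores) && any(scores < 0 | scores > 1)) {
    stopf("channel score(s) outside [0,1]: %s",
          paste(format(scores[scores < 0 | scores > 1]), collapse = ", "))
  }
  low <- scores < prior
  if (any(low)) {
    warnf("dropping %d channel(s) scoring below the prior %.3f",
          sum(low), prior)
    scores <- scores[!low]
  }
  if (length(scores) == 0) return(prior)
  s_corr <- (scores - prior) / (1 - prior)
  u <- 1 - prod(1 - s_corr)
  u * (1 - prior) + prior
}

#' Classify a combined confidence score into a tier
#'
#' Half-open bins with the given lower bounds: scores below the lowest
#' bound map to `below_low`; a score exactly at a bound belongs to that
#' tier.
#'
#' @param score numeric vector of combined scores in [0, 1]
#' @param bounds named increasing numeric vector of tier lower bounds;
#'   default `c(low = 0.15, medium = 0.4, high = 0.7, highest = 0.9)`
#' @return character vector of tier labels
#' @export
classify_tier <- function(score, bounds = default_tier_bounds()) {
  stopifnot(!is.unsorted(bounds), all(score >= 0 & score <= 1))
  labels <- c("below_low", names(bounds))
  idx <- findInterval(score, bounds) + 1L
  labels[idx]
}

#' Build per-patient protein node sets
#'
#' For each affected patient: the genes of network-eligible prioritized
#' variants the patient carries, plus any per-patient extra includes
#' (e.g. frequent functional variants added manually to the analysis).
#'
#' @param decisions finalized decisions from [prioritize()]
#' @param matrix a `fvn_carrier_matrix` over (at least) the decision
#'   variants
#' @param pedigree a `fvn_pedigree`
#' @param network_eligible character vector of gene symbols admitted to
#'   network analysis; every symbol must appear among the decisions
#' @param extra_includes named list, patient id -> character vector of
#'   extra gene symbols
#' @return named list, affected patient id -> sorted character node set
#' @export
build_patient_sets <- function(decisions, matrix, pedigree,
                               network_eligible,
                               extra_includes = list()) {
  aff <- affected_ids(pedigree)
  dec_genes <- toupper(stats::na.omit(decisions$gene))
  miss <- setdiff(toupper(network_eligible), dec_genes)
  if (length(miss)) {
    stopf("network-eligible gene(s) absent from decisions: %s",
          paste(miss, collapse = ", "))
  }
  keep <- decisions$status == "prioritized" &
    toupper(decisions$gene) %in% toupper(network_eligible)
  eligible <- decisions[keep, , drop = FALSE]
  out <- lapply(aff, function(p) {
    carried <- vapply(eligible$key, function(k) {
      cc <- matrix$carriers[[k]]
      !is.null(cc) && p %in% cc
    }, logical(1))
    nodes <- unique(toupper(eligible$gene[carried]))
    extra <- toupper(extra_includes[[p]] %||% character(0))
    sort(union(nodes, extra))
  })
  stats::setNames(out, aff)
}

#' Build a patient's interaction network from an edge database
#'
#' Edges are created only between node pairs present in the edge database;
#' per-channel scores are combined by [combine_channel_scores()] and
#' tiered by [classify_tier()]. Edge order is deterministic
#' (lexicographic by pair).
#'
#' @param patient patient/member id (metadata only)
#' @param nodes character vector of gene symbols
#' @param edge_db a `fvn_edge_db`
#' @param prior noisy-OR prior, default 0.041
#' @param tier_bounds tier lower bounds, see [classify_tier()]
#' @return a `fvn_patient_network` list with `patient`, `nodes`, `edges`
#'   (data.frame: `protein_a`, `protein_b`, one column per channel,
#'   `combined_score`, `tier`)
#' @export
build_patient_network <- function(patient, nodes, edge_db,
                                  prior = 0.041,
                                  tier_bounds = default_tier_bounds()) {
  nodes <- sort(unique(toupper(nodes)))
  channels <- sort(unique(edge_db$channel))
  edges <- list()
  if (length(nodes) >= 2) {
    pairs <- utils::combn(nodes, 2)
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      rows <- edge_db$protein_a == a & edge_db$protein_b == b
      if (!any(rows)) next
      sc <- stats::setNames(edge_db$score[rows], edge_db$channel[rows])
      combined <- combine_channel_scores(sc, prior = prior)
      rec <- as.list(stats::setNames(rep(NA_real_, length(channels)),
                                     channels))
      rec[names(sc)] <- as.numeric(sc)
      edges[[length(edges) + 1L]] <- c(
        list(protein_a = a, protein_b = b), rec,
        list(combined_score = combined,
             tier = classify_tier(combined, tier_bounds)))
    }
  }
  edges_df <- if (length(edges)) {
    do.call(rbind, lapply(edges, function(e)
      as.data.frame(e, stringsAsFactors = FALSE)))
  } else {
    cols <- c("protein_a", "protein_b", channels, "combined_score", "tier")
    stats::setNames(
      data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
  }
  structure(list(patient = patient, nodes = nodes, edges = edges_df,
                 prior = prior),
            class = "fvn_patient_network")
}

#' @export
print.fvn_patient_network <- function(x, ...) {
  cat(sprintf("<fvn_patient_network> %s: %d node(s), %d edge(s)\n",
              x$patient, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read a term annotation database (GMT-style)
#'
#' Tab-separated lines: `term_id`, `category:label`, then one gene symbol
#' per field. Example description field: `GO-BP:acute-phase response`.
#'
#' @param path GMT file path
#' @return a `fvn_term_db` data.frame with columns `term_id`, `category`,
#'   `label` and list-column `genes`
#' @export
read_term_db <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stopf("malformed GMT line: %s", l)
    desc <- strsplit(f[2], ":", fixed = TRUE)[[1]]
    list(term_id = f[1],
         category = desc[1],
         label = paste(desc[-1], collapse = ":"),
         genes = unique(toupper(f[-(1:2)])))
  })
  db <- data.frame(term_id = vapply(recs, `[[`, "", "term_id"),
                   category = vapply(recs, `[[`, "", "category"),
                   label = vapply(recs, `[[`, "", "label"),
                   stringsAsFactors = FALSE)
  db$genes <- lapply(recs, `[[`, "genes")
  class(db) <- c("fvn_term_db", "data.frame")
  db
}

#' Hypergeometric term enrichment with BH FDR
#'
#' Upper-tail hypergeometric test per term: with `N` background genes, `K`
#' term genes, `n` query genes and `k` overlapping genes,
#' `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. FDR is
#' Benjamini-Hochberg, adjusted within each term category.
#'
#' @param nodes character vector of query gene symbols; every node must be
#'   in the background
#' @param term_db a `fvn_term_db`
#' @param background character vector of background gene symbols
#' @return data.frame sorted by FDR: `term_id`, `category`, `label`,
#'   `k`, `n`, `K`, `N`, `p_value`, `fdr`
#' @export
enrich_terms <- function(nodes, term_db, background) {
  nodes <- unique(toupper(nodes))
  background <- unique(toupper(background))
  outside <- setdiff(nodes, background)
  if (length(outside)) {
    stopf("query gene(s) absent from declared background: %s",
          paste(outside, collapse = ", "))
  }
  N <- length(background)
  n <- length(nodes)
  res <- data.frame(term_id = term_db$term_id,
                    category = term_db$category,
                    label = term_db$label,
                    stringsAsFactors = FALSE)
  res$K <- vapply(term_db$genes, function(g)
    length(intersect(g, background)), integer(1))
  res$k <- vapply(term_db$genes, function(g)
    length(intersect(intersect(g, background), nodes)), integer(1))
  res$n <- n
  res$N <- N
  res$p_value <- stats::phyper(res$k - 1, res$K, res$N - res$K, res$n,
                               lower.tail = FALSE)
  res$fdr <- NA_real_
  for (cat in unique(res$category)) {
    idx <- res$category == cat
    res$fdr[idx] <- stats::p.adjust(res$p_value[idx], method = "BH")
  }
  res <- res[, c("term_id", "category", "label", "k", "n", "K", "N",
                 "p_value", "fdr")]
  res[order(res$fdr, res$p_value, res$term_id), , drop = FALSE]
}

#' Write a patient network as TSV (+ SIF triple)
#'
#' @param net a `fvn_patient_network`
#' @param tsv_out edge-list TSV path
#' @param sif_out optional SIF path (`protein_a  tier  protein_b`)
#' @return invisible `tsv_out`
#' @export
write_patient_network <- function(net, tsv_out, sif_out = NULL) {
  write_tsv(net$edges, tsv_out)
  if (!is.null(sif_out)) {
    sif <- net$edges[, c("protein_a", "tier", "protein_b")]
    utils::write.table(sif, sif_out, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(tsv_out)
}
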