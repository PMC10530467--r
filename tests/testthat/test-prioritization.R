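test_that("categorize_scores applies boundary conventions per tool", {
  tools <- prediction_tools()
  m <- matrix(NA_real_, 1, length(tools),
              dimnames = list("v1", tools))
  m[1, "REVEL"] <- 0.5    # exactly at damaging_min -> damaging
  m[1, "SIFT"] <- 0.25    # exactly at neutral_max -> neutral
  m[1, "LRT"] <- 0.3      # in between -> moderate
  m[1, "CADD"] <- 0.9
  pm <- prediction_matrix(m, data.frame(tool = tools, damaging_min = 0.5,
                                        neutral_max = 0.25))
  cats <- categorize_scores(pm)
  expect_equal(unname(cats[1, c("REVEL", "SIFT", "LRT", "CADD",
                                "ClinPred")]),
               c("damaging", "neutral", "moderate", "damaging",
                 "missing"))
})

test_that("categorize_scores rejects out-of-range scores naming the cell", {
  pm <- random_prediction_matrix(2, seed = 1)
  pm$scores[2, "SIFT"] <- 1.2
  expect_error(categorize_scores(pm), "SIFT.*v002")
})

test_that("categorization equals an independent per-cell oracle", {
  for (seed in c(11, 12, 13)) {
    pm <- random_prediction_matrix(10, seed = seed)
    cats <- categorize_scores(pm)
    for (i in seq_len(nrow(pm$scores))) {
      for (j in seq_len(ncol(pm$scores))) {
        s <- pm$scores[i, j]
        cut <- pm$cutoffs[pm$cutoffs$tool == colnames(pm$scores)[j], ]
        want <- if (is.na(s)) "missing"
          else if (s >= cut$damaging_min) "damaging"
          else if (s <= cut$neutral_max) "neutral"
          else "moderate"
        expect_identical(cats[i, j], want)
      }
    }
  }
})

test_that("damaging_vote_count counts damaging tools only", {
  tools <- prediction_tools()
  m <- matrix(0.9, 1, 15, dimnames = list("v1", tools))
  pm <- prediction_matrix(m, data.frame(tool = tools, damaging_min = 0.5,
                                        neutral_max = 0.25))
  expect_equal(damaging_vote_count(categorize_scores(pm), "v1"), 15L)
  m[] <- NA_real_
  pm2 <- prediction_matrix(m, pm$cutoffs)
  expect_equal(damaging_vote_count(categorize_scores(pm2), "v1"), 0L)
  # fixture: UGT1A3 Val246Leu is damaging by exactly two tools
  fx <- fixture_bundle()
  votes <- damaging_vote_count(categorize_scores(fx$pm))
  expect_equal(unname(votes[fixture_gene_key(fx, "UGT1A3")]), 2L)
})

test_that("rank_by_revel orders, tie-breaks, and assigns quartiles", {
  fx <- fixture_bundle()
  filt <- apply_frequency_filter(fx$variants, fx$panel, fx$pedigree)
  mis <- split_by_consequence(filt)$missense
  d <- rank_by_revel(fx$pm, mis)
  # bijection onto 1..n for REVEL-scored variants
  expect_setequal(d$rank[!is.na(d$revel_score)], 1:16)
  # quartile sizes 4/4/4/4 over 16 ranked variants
  expect_equal(as.integer(table(d$quartile)), rep(4L, 4))
  # KLK13 His109Tyr and NQO1 Arg139Trp fall in the last quartile
  expect_equal(d$quartile[d$gene == "KLK13"], 4L)
  expect_equal(d$quartile[d$gene == "NQO1"], 4L)
  # top-5 for predicted deleteriousness
  expect_setequal(d$gene[d$rank <= 5],
                  c("CRP", "F2", "SERPINA1", "VWF", "THBS1"))
  expect_error(rank_by_revel(fx$pm, filt), "missense")
})

test_that("rank_by_revel tie-break and absent-REVEL placement", {
  tools <- prediction_tools()
  m <- matrix(0.1, 3, 15,
              dimnames = list(c("chr1:1001:A:G", "chr1:1002:A:G",
                                "chr1:1003:A:G"), tools))
  m[1, "REVEL"] <- 0.6
  m[2, "REVEL"] <- 0.6
  m[2, c("SIFT", "LRT", "CADD", "MetaLR", "VEST4")] <- 0.9  # 5 votes
  m[3, "REVEL"] <- NA  # unscored
  pm <- prediction_matrix(m, data.frame(tool = tools, damaging_min = 0.5,
                                        neutral_max = 0.25))
  vs <- toy_variant_set(n = 3, gene = c("AAA", "BBB", "CCC"))
  d <- rank_by_revel(pm, vs)
  # equal REVEL: higher vote count ranks first despite later gene symbol
  expect_equal(d$gene[which(d$rank == 1)], "BBB")
  expect_equal(d$gene[which(d$rank == 2)], "AAA")
  # absent REVEL: placed last, NA rank, still vote-counted
  expect_true(is.na(d$rank[d$gene == "CCC"]))
  expect_equal(d$gene[nrow(d)], "CCC")
})

fixture_decisions <- function(fx = fixture_bundle(),
                              status_rule = "low_evidence_exclusion") {
  filt <- apply_frequency_filter(fx$variants, fx$panel, fx$pedigree)
  mis <- split_by_consequence(filt)$missense
  d <- rank_by_revel(fx$pm, mis)
  cm <- carrier_matrix(fx$variants, fx$pedigree)
  n_aff <- vapply(cm$affected_carriers, length, integer(1))
  prioritize(d, fx$annotations, fx$variants, affected_carriers = n_aff,
             votes_min = 4, affected_min = 2, status_rule = status_rule)
}

test_that("flag invariants hold for every decision after prioritize", {
  d <- fixture_decisions()
  votes <- ifelse(is.na(d$damaging_votes), 0L, d$damaging_votes)
  expect_identical(d$flag_plus,
                   d$affected_carriers >= 2 & votes >= 4)
  cv_reported <- vapply(d$clinvar, function(s)
    any(strsplit(s, ";")[[1]] != "NR"), logical(1))
  expect_identical(d$flag_star,
                   unname(votes >= 4 & (d$has_qtl | cv_reported)))
})

test_that("prioritize reproduces the reported decision pattern", {
  d <- fixture_decisions()
  expect_equal(sum(d$status == "prioritized"), 12)
  expect_setequal(d$gene[d$status == "not_prioritized"],
                  c("UGT1A3", "JAK2", "SAA2", "PSG8"))
  # under the literal flags-only rule the three single-affected-carrier,
  # evidence-free variants drop out
  d2 <- fixture_decisions(status_rule = "flags_only")
  expect_equal(sum(d2$status == "prioritized"), 9)
  expect_setequal(setdiff(d$key[d$status == "prioritized"],
                          d2$key[d2$status == "prioritized"]),
                  c(fixture_gene_key(fixture_bundle(), "ARID4A"),
                    fixture_gene_key(fixture_bundle(), "NCOA1")))
})

test_that("low-evidence variants are not prioritized; manual includes are checked", {
  vs <- toy_variant_set(n = 1, gene = "GX")
  d <- data.frame(key = vs$variants$key, gene = "GX",
                  protein_change = "p.X1", consequence = "missense",
                  revel_score = 0.4, damaging_votes = 3L, rank = 1L,
                  quartile = 1L, stringsAsFactors = FALSE)
  out <- prioritize(d, NULL, vs,
                    affected_carriers = c(1L), votes_min = 4)
  expect_equal(out$status, "not_prioritized")
  expect_equal(out$reason, "low_votes_no_evidence")
  expect_error(
    prioritize(d, NULL, vs, affected_carriers = c(1L),
               manual_includes = "NOTHERE"),
    "NOTHERE")
})

test_that("prioritize is idempotent and order-independent", {
  fx <- fixture_bundle()
  d <- fixture_decisions(fx)
  set.seed(42)
  perm <- sample(nrow(d))
  filt <- apply_frequency_filter(fx$variants, fx$panel, fx$pedigree)
  mis <- split_by_consequence(filt)$missense
  base <- rank_by_revel(fx$pm, mis)
  cm <- carrier_matrix(fx$variants, fx$pedigree)
  n_aff <- vapply(cm$affected_carriers, length, integer(1))
  d_perm <- prioritize(base[perm, ], fx$annotations, fx$variants,
                       affected_carriers = n_aff)
  expect_equal(d_perm$status[match(d$key, d_perm$key)], d$status)
  # idempotent: re-running on its own output changes nothing
  d_again <- prioritize(d[, names(base)], fx$annotations, fx$variants,
                        affected_carriers = n_aff)
  expect_equal(d_again$status, d$status)
})

test_that("planted strong variants are always prioritized (100 seeds)", {
  vs <- toy_variant_set(n = 4, gene = c("P1", "P2", "W1", "W2"))
  for (seed in 1:100) {
    set.seed(seed)
    votes <- c(sample(10:15, 2, replace = TRUE),   # planted strong
               sample(0:3, 2, replace = TRUE))     # weak background
    d <- data.frame(key = vs$variants$key, gene = vs$variants$gene,
                    protein_change = vs$variants$protein_change,
                    consequence = "missense",
                    revel_score = round(stats::runif(4), 3),
                    damaging_votes = as.integer(votes),
                    rank = 1:4, quartile = c(1L, 2L, 3L, 4L),
                    stringsAsFactors = FALSE)
    ac <- stats::setNames(c(3L, 3L, sample(0:1, 2, replace = TRUE)),
                          vs$variants$key)
    for (rule in c("low_evidence_exclusion", "flags_only")) {
      out <- prioritize(d, NULL, vs, affected_carriers = ac,
                        status_rule = rule)
      expect_equal(out$status[out$gene %in% c("P1", "P2")],
                   rep("prioritized", 2))
    }
  }
})

test_that("export_heatmap_matrix writes rank-ordered, deterministic panels", {
  fx <- fixture_bundle()
  d <- fixture_decisions(fx)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  export_heatmap_matrix(fx$pm, d, f1, f2,
                        network_eligible = fx$config$network_eligible)
  sc <- read.delim(f1, check.names = FALSE)
  expect_equal(nrow(sc), 16)
  expect_equal(sc$rank, 1:16)
  expect_length(intersect(prediction_tools(), names(sc)), 15)
  ct <- read.delim(f2, check.names = FALSE)
  expect_true(all(unlist(ct[prediction_tools()]) %in%
                    c("neutral", "moderate", "damaging", "missing")))
  # prioritized-but-network-excluded variants carry the delta mark
  expect_setequal(ct$gene[ct$delta == "D"],
                  c("ARID4A", "PEAR1", "KLK13", "NQO1", "NCOA1"))
  # byte-identical on re-export
  f3 <- withr::local_tempfile(fileext = ".tsv")
  f4 <- withr::local_tempfile(fileext = ".tsv")
  export_heatmap_matrix(fx$pm, d, f3, f4,
                        network_eligible = fx$config$network_eligible)
  expect_identical(readLines(f1), readLines(f3))
  expect_identical(readLines(f2), readLines(f4))

  # empty decisions -> header-only files
  f5 <- withr::local_tempfile(fileext = ".tsv")
  f6 <- withr::local_tempfile(fileext = ".tsv")
  export_heatmap_matrix(fx$pm, d[integer(0), ], f5, f6)
  expect_length(readLines(f5), 1)
})
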