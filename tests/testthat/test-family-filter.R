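ped3 <- toy_pedigree()  # A1, A2 affected; U1 unaffected

test_that("frequency filter applies every clause with strict bounds", {
  geno <- matrix("hom_ref", 6, 3, dimnames = list(NULL, ped3$id))
  geno[, "A1"] <- "het"
  vs <- toy_variant_set(n = 6, gene = rep("G1", 6), geno = geno,
                        maf = c(0.04, 0.039, NA, 0.001, 0.001, 0.001),
                        qual = c(90, 90, 90, 30, 90, 90))
  vs$variants$maf_1000g[5] <- 0.5          # fails the 1000G arm
  panel <- structure("G1", class = "fvn_gene_panel")
  kept <- apply_frequency_filter(vs, panel, ped3)
  # row1: MAF == 0.04 excluded (strict <); row4: qual == 30 excluded
  # (strict >); row5: 1000G >= 0.04 excluded; row3: absent MAF passes
  expect_setequal(kept$variants$pos, vs$variants$pos[c(2, 3, 6)])

  # panel membership
  vs2 <- toy_variant_set(n = 1, gene = "NOTPANEL",
                         geno = matrix("het", 1, 3,
                                       dimnames = list(NULL, ped3$id)))
  expect_equal(n_variants(apply_frequency_filter(vs2, panel, ped3)), 0)
})

test_that("het-in-affected requirement: hom_alt or unaffected-only fail", {
  geno <- matrix("hom_ref", 3, 3, dimnames = list(NULL, ped3$id))
  geno[1, "U1"] <- "het"       # only unaffected carries
  geno[2, "A1"] <- "hom_alt"   # affected carries, but not het
  geno[3, "A2"] <- "het"
  vs <- toy_variant_set(n = 3, gene = rep("G1", 3), geno = geno)
  panel <- structure("G1", class = "fvn_gene_panel")
  kept <- apply_frequency_filter(vs, panel, ped3)
  expect_equal(kept$variants$pos, vs$variants$pos[3])
  relaxed <- apply_frequency_filter(vs, panel, ped3,
                                    require_het_in_affected = FALSE)
  expect_equal(n_variants(relaxed), 3)
})

test_that("filter argument validation", {
  vs <- toy_variant_set(n = 1)
  panel <- structure("G1", class = "fvn_gene_panel")
  expect_error(apply_frequency_filter(vs, panel, ped3, maf_max = 0),
               "maf_max")
  expect_error(apply_frequency_filter(vs, panel, ped3, maf_max = 1.5),
               "maf_max")
  no_aff <- toy_pedigree(affected = c(FALSE, FALSE, FALSE))
  expect_error(apply_frequency_filter(vs, panel, no_aff), "no affected")
})

test_that("filter is monotone in maf_max", {
  fx <- fixture_bundle()
  grid <- c(0.5, 0.1, 0.04, 0.01, 0.001, 1e-05)
  counts <- vapply(grid, function(mm) {
    n_variants(apply_frequency_filter(fx$variants, fx$panel,
                                      fx$pedigree, maf_max = mm))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("split_by_consequence partitions and rejects unknown classes", {
  vs <- toy_variant_set(n = 5, consequence = rep("missense", 5))
  parts <- split_by_consequence(vs)
  expect_equal(n_variants(parts$missense), 5)
  expect_equal(n_variants(parts$synonymous), 0)

  empty <- vs[integer(0)]
  parts0 <- split_by_consequence(empty)
  expect_equal(n_variants(parts0$missense), 0)
  expect_equal(n_variants(parts0$synonymous), 0)

  bad <- toy_variant_set(n = 1, consequence = "stop_gained")
  expect_error(split_by_consequence(bad), "stop_gained")
})

test_that("carrier_matrix lists het and hom_alt members", {
  fx <- fixture_bundle()
  cm <- carrier_matrix(fx$variants, fx$pedigree)
  crp <- fixture_gene_key(fx, "CRP")
  expect_setequal(cm$carriers[[crp]],
                  c("I1", "II2", "II3", "III1", "III2"))
  # hom_alt member counts as carrier (IL1A homozygous in III2)
  il1a <- fixture_gene_key(fx, "IL1A")
  expect_true("III2" %in% cm$carriers[[il1a]])
  # all-hom_ref variant -> empty carrier set
  vs0 <- toy_variant_set(n = 1)
  cm0 <- carrier_matrix(vs0, ped3)
  expect_length(cm0$carriers[[1]], 0)
})

test_that("count_carried_per_member counts and validates members", {
  geno <- matrix("hom_ref", 2, 3, dimnames = list(NULL, ped3$id))
  geno[, "A1"] <- "het"; geno[2, "A2"] <- "hom_alt"
  vs <- toy_variant_set(n = 2, geno = geno)
  cm <- carrier_matrix(vs, ped3)
  expect_equal(count_carried_per_member(cm, ped3),
               c(A1 = 2L, A2 = 1L))
  expect_error(count_carried_per_member(cm, ped3, members = "ZZ"),
               "not in pedigree")
  cm_empty <- carrier_matrix(vs[integer(0)], ped3)
  expect_equal(unname(count_carried_per_member(cm_empty, ped3)),
               c(0L, 0L))
})

test_that("shared_in_affected is the intersection over affected carriers", {
  # intersection of one == that member's carrier list
  ped1 <- toy_pedigree(ids = c("A1", "U1"), affected = c(TRUE, FALSE))
  geno <- matrix(c("het", "hom_ref", "het", "het", "hom_ref", "het"),
                 nrow = 3, dimnames = list(NULL, c("A1", "U1")))
  vs <- toy_variant_set(n = 3, members = c("A1", "U1"), geno = geno)
  cm <- carrier_matrix(vs, ped1)
  expect_setequal(shared_in_affected(cm, ped1),
                  vs$variants$key[c(1, 3)])  # A1 carries rows 1 and 3
  # disjoint carriers -> empty
  geno2 <- matrix("hom_ref", 2, 3, dimnames = list(NULL, ped3$id))
  geno2[1, "A1"] <- "het"; geno2[2, "A2"] <- "het"
  vs2 <- toy_variant_set(n = 2, geno = geno2)
  expect_length(shared_in_affected(carrier_matrix(vs2, ped3), ped3), 0)
})

test_that("shared_in_affected subset invariant holds exhaustively on fixture", {
  fx <- fixture_bundle()
  cm <- carrier_matrix(fx$variants, fx$pedigree)
  shared <- shared_in_affected(cm, fx$pedigree)
  for (m in affected_ids(fx$pedigree)) {
    carried <- names(cm$carriers)[vapply(cm$carriers, function(cc)
      m %in% cc, logical(1))]
    expect_true(all(shared %in% carried))
  }
})

test_that("linkage_groups finds co-carried same-gene variant sets", {
  fx <- fixture_bundle()
  cm <- carrier_matrix(fx$variants, fx$pedigree)
  gr <- linkage_groups(fx$variants, cm)
  vwf <- gr[gr$gene == "VWF", ]
  expect_equal(nrow(vwf), 1)
  expect_equal(vwf$members, "II3")
  expect_equal(vwf$n_variants, 2)
  # THBS1 Asp901Glu linked with Thr523Ala and Asn700Ser in II2/III2
  thbs1 <- gr[gr$gene == "THBS1" & gr$n_variants == 3, ]
  expect_setequal(strsplit(thbs1$members, ";")[[1]], c("II2", "III2"))

  # single variant per gene -> no groups
  vs1 <- toy_variant_set(n = 2, gene = c("GA", "GB"),
                         geno = matrix("het", 2, 3,
                                       dimnames = list(NULL, ped3$id)))
  expect_equal(nrow(linkage_groups(vs1, carrier_matrix(vs1, ped3))), 0)

  # three co-carried variants in one gene -> one group of size 3
  geno3 <- matrix("hom_ref", 3, 3, dimnames = list(NULL, ped3$id))
  geno3[, "A1"] <- "het"
  vs3 <- toy_variant_set(n = 3, gene = rep("GX", 3), geno = geno3)
  gr3 <- linkage_groups(vs3, carrier_matrix(vs3, ped3))
  expect_equal(nrow(gr3), 1)
  expect_equal(gr3$n_variants, 3)
  expect_equal(gr3$members, "A1")
})

test_that("linkage_groups agrees with a brute-force co-carriage oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 8
    genes <- sample(c("GA", "GB", "GC"), n, replace = TRUE)
    geno <- matrix(sample(c("hom_ref", "het", "hom_alt"), n * 3,
                          replace = TRUE, prob = c(0.5, 0.4, 0.1)),
                   nrow = n, dimnames = list(NULL, ped3$id))
    vs <- toy_variant_set(n = n, gene = genes, geno = geno)
    cm <- carrier_matrix(vs, ped3)
    gr <- linkage_groups(vs, cm)
    # oracle: per member and gene, enumerate carried variants directly
    expected <- character(0)
    for (m in ped3$id) {
      for (g in unique(genes)) {
        idx <- which(genes == g & geno[, m] %in% c("het", "hom_alt"))
        if (length(idx) >= 2) {
          expected <- c(expected, paste(
            g, paste(sort(vs$variants$key[idx]), collapse = ";"),
            m, sep = "|"))
        }
      }
    }
    got <- character(0)
    for (i in seq_len(nrow(gr))) {
      ks <- paste(sort(strsplit(gr$variants[i], ";")[[1]]), collapse = ";")
      for (m in strsplit(gr$members[i], ";")[[1]]) {
        got <- c(got, paste(gr$gene[i], ks, m, sep = "|"))
      }
    }
    expect_setequal(got, unique(expected))
  }
})
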