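# Synthetic family generator: pedigrees, panel-restricted variant tables
# with planted segregation structure, correlated predictor scores and
# channelized interaction evidence, with a ground-truth manifest.

#' Simulation configuration for the synthetic family generator
#'
#' Defaults emulate the structure of the study family: six sequenced
#' members over three generations, three of them affected, a candidate
#' panel restricted variant set with a mixed MAF spectrum (a point mass of
#' very rare variants plus a uniform tail up to 0.3), a small fraction of
#' planted shared-in-affected variants, two planted compound-heterozygous
#' gene pairs, strongly correlated predictor tools and beta-distributed
#' per-channel interaction evidence.
#'
#' @param seed integer seed; makes every output reproducible
#' @param n_members total sequenced members (>= 4)
#' @param n_affected affected members (<= n_members - 1)
#' @param n_panel_genes genes on the candidate panel
#' @param n_variants variant records to simulate
#' @param p_rare probability a variant draws from the very-rare point mass
#' @param maf_tail_max upper bound of the uniform MAF tail
#' @param p_shared_in_affected fraction of variants planted as
#'   shared-in-affected (het in every affected member)
#' @param n_compound_het_genes genes planted with a co-carried variant pair
#' @param predictor_correlation in [0, 1]; weight of the latent "true
#'   deleteriousness" driving all 15 tool scores (1 = tools identical,
#'   0 = independent noise)
#' @param channel_score_distribution named list of beta shape pairs per
#'   evidence channel
#' @param prior interaction prior used when scaling channel scores
#' @return a `fvn_sim_config` list
#' @export
simulation_config <- function(seed = 1L,
                              n_members = 6L,
                              n_affected = 3L,
                              n_panel_genes = 25L,
                              n_variants = 60L,
                              p_rare = 0.3,
                              maf_tail_max = 0.3,
                              p_shared_in_affected = 0.1,
                              n_compound_het_genes = 2L,
                              predictor_correlation = 0.8,
                              channel_score_distribution = list(
                                neighborhood = c(1, 8),
                                fusion = c(1, 12),
                                cooccurrence = c(1, 10),
                                experimental = c(2, 2),
                                database = c(2, 2),
                                coexpression = c(2, 5)),
                              prior = 0.041) {
  stopifnot(n_members >= 4, n_affected >= 1, n_affected < n_members,
            p_shared_in_affected >= 0, p_shared_in_affected <= 1,
            predictor_correlation >= 0, predictor_correlation <= 1,
            p_rare >= 0, p_rare <= 1)
  structure(as.list(environment()), class = "fvn_sim_config")
}

sim_pedigree <- function(n_members, n_affected) {
  # Three-generation template: two founders, a sibship in generation II,
  # one generation-III child (the propositus analogue).
  n_mid <- n_members - 3L
  ids <- c("I1", "I2", paste0("II", seq_len(n_mid)), "III1")
  father <- c(NA, NA, rep("I1", n_mid), "II1")
  mother <- c(NA, NA, rep("I2", n_mid), NA)
  affected <- rep(FALSE, n_members)
  # affected: the propositus analogue plus the tail of the sibship
  affected[n_members] <- TRUE
  if (n_affected > 1) {
    extra <- seq(n_members - 1L, by = -1L, length.out = n_affected - 1L)
    affected[extra] <- TRUE
  }
  ped <- data.frame(id = ids, father = father, mother = mother,
                    sex = NA_character_, affected = affected,
                    stringsAsFactors = FALSE)
  class(ped) <- c("fvn_pedigree", "data.frame")
  ped
}

sample_genotype_hwe <- function(maf, n) {
  p <- maf
  probs <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  sample(c("hom_ref", "het", "hom_alt"), n, replace = TRUE, prob = probs)
}

#' Generate a synthetic family dataset with planted ground truth
#'
#' Produces a pedigree, a panel-restricted variant set with genotypes
#' (planted shared-in-affected variants are het in every affected member;
#' planted compound-het gene pairs are co-carried by one affected member;
#' no other variant is carried by all affected members), per-variant
#' population MAFs and qualities, a 15-tool prediction score matrix driven
#' by a latent deleteriousness with configurable correlation, a
#' channelized interaction edge database and a small term database. When
#' `dir` is given, all standard-format files plus a JSON ground-truth
#' manifest are written there (byte-reproducible for a fixed seed).
#'
#' @param config a `fvn_sim_config`
#' @param dir optional output directory (created if needed)
#' @return invisible list: `pedigree`, `variants` (a `fvn_variant_set`),
#'   `panel`, `annotations` (variant annotation data.frame), `pm`
#'   (`fvn_prediction_matrix`), `edge_db`, `term_db`, `manifest`, and
#'   `paths` when `dir` was given
#' @export
generate_family <- function(config = simulation_config(), dir = NULL) {
  stopifnot(inherits(config, "fvn_sim_config"))
  set.seed(config$seed)
  n_shared <- round(config$p_shared_in_affected * config$n_variants)
  n_planted <- n_shared + 2L * config$n_compound_het_genes
  if (n_planted > config$n_variants) {
    stopf("infeasible config: %d planted variants exceed n_variants = %d",
          n_planted, config$n_variants)
  }
  if (config$n_compound_het_genes > config$n_panel_genes) {
    stopf("infeasible config: more compound-het genes than panel genes")
  }
  ped <- sim_pedigree(config$n_members, config$n_affected)
  aff <- affected_ids(ped)
  genes <- sprintf("GENE%03d", seq_len(config$n_panel_genes))

  nv <- config$n_variants
  gene_of <- sample(genes, nv, replace = TRUE)
  # planted compound-het pairs occupy the tail slots, shared the head slots
  shared_idx <- seq_len(n_shared)
  ch_genes <- sample(genes, config$n_compound_het_genes)
  ch_idx <- list()
  slot <- n_shared
  for (g in ch_genes) {
    idx <- slot + 1:2
    gene_of[idx] <- g
    ch_idx[[g]] <- idx
    slot <- slot + 2L
  }
  chrom_of_gene <- stats::setNames(
    paste0("chr", (seq_along(genes) - 1L) %% 22L + 1L), genes)
  bases <- c("A", "C", "G", "T")
  chrom <- chrom_of_gene[gene_of]
  pos <- 10000L + 50L * seq_len(nv) +
    1000000L * match(gene_of, genes)
  ref <- sample(bases, nv, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  consequence <- sample(c("missense", "synonymous"), nv, replace = TRUE,
                        prob = c(0.7, 0.3))
  rare <- stats::runif(nv) < config$p_rare
  maf <- ifelse(rare, 10^stats::runif(nv, -6, -4),
                stats::runif(nv, 0, config$maf_tail_max))
  maf_1000g <- pmin(1, maf * stats::runif(nv, 0.8, 1.2))
  qual <- round(stats::runif(nv, 35, 99), 1)

  # planted variants must survive the panel/MAF/quality filter and be
  # missense so segregation analysis sees them
  planted_all <- c(shared_idx, unlist(ch_idx, use.names = FALSE))
  if (length(planted_all)) {
    maf[planted_all] <- 10^stats::runif(length(planted_all), -6, -3)
    maf_1000g[planted_all] <- maf[planted_all]
    consequence[planted_all] <- "missense"
    qual[planted_all] <- round(stats::runif(length(planted_all), 60, 99), 1)
  }

  geno <- matrix("hom_ref", nrow = nv, ncol = config$n_members,
                 dimnames = list(NULL, ped$id))
  for (i in seq_len(nv)) {
    geno[i, ] <- sample_genotype_hwe(maf[i], config$n_members)
  }
  # planted shared-in-affected: het in every affected member
  for (i in shared_idx) geno[i, aff] <- "het"
  # planted compound hets: both variants het in one affected member
  ch_member <- stats::setNames(sample(aff, length(ch_idx), replace = TRUE),
                               names(ch_idx))
  for (g in names(ch_idx)) geno[ch_idx[[g]], ch_member[[g]]] <- "het"
  # no accidental shared-in-affected: knock one affected down to hom_ref
  for (i in setdiff(seq_len(nv), shared_idx)) {
    if (all(geno[i, aff] %in% c("het", "hom_alt"))) {
      geno[i, aff[1]] <- "hom_ref"
    }
  }

  variants <- data.frame(
    chrom = unname(chrom), pos = pos, ref = unname(ref), alt = unname(alt),
    gene = gene_of,
    rsid = sprintf("rs9%06d", seq_len(nv)),
    cdna_change = sprintf("c.%dN > N", seq_len(nv)),
    protein_change = ifelse(consequence == "missense",
                            sprintf("p.Xaa%dXaa", seq_len(nv)),
                            sprintf("p.Xaa%d=", seq_len(nv))),
    consequence = consequence,
    maf_gnomad3 = signif(maf, 6), maf_1000g = signif(maf_1000g, 6),
    qual = qual, clinvar = "NR", novel = FALSE,
    stringsAsFactors = FALSE)
  vs <- variant_set(variants, geno)

  # latent deleteriousness drives all tools through noisy monotone maps
  tools <- prediction_tools()
  mis <- vs$variants$consequence == "missense"
  keys_mis <- vs$variants$key[mis]
  d_latent <- stats::runif(sum(mis))
  rho <- config$predictor_correlation
  scores <- matrix(NA_real_, nrow = sum(mis), ncol = length(tools),
                   dimnames = list(keys_mis, tools))
  for (j in seq_along(tools)) {
    noise <- stats::runif(sum(mis))
    scores[, j] <- pmin(1, pmax(0, rho * d_latent + (1 - rho) * noise))
  }
  cutoffs <- data.frame(tool = tools, damaging_min = 0.5,
                        neutral_max = 0.25, stringsAsFactors = FALSE)
  pm <- prediction_matrix(scores, cutoffs)

  # channelized interaction evidence over a subset of panel genes
  hub <- genes[seq_len(min(12L, length(genes)))]
  pairs <- utils::combn(hub, 2)
  edges <- list()
  for (j in seq_len(ncol(pairs))) {
    if (stats::runif(1) > 0.3) next
    for (ch in names(config$channel_score_distribution)) {
      if (stats::runif(1) > 0.5) next
      sh <- config$channel_score_distribution[[ch]]
      s <- config$prior +
        (1 - config$prior) * stats::rbeta(1, sh[1], sh[2])
      edges[[length(edges) + 1L]] <- data.frame(
        protein_a = pairs[1, j], protein_b = pairs[2, j],
        channel = ch, score = round(s, 4), stringsAsFactors = FALSE)
    }
  }
  edge_db <- if (length(edges)) do.call(rbind, edges) else
    data.frame(protein_a = character(0), protein_b = character(0),
               channel = character(0), score = numeric(0))
  class(edge_db) <- c("fvn_edge_db", "data.frame")

  term_db <- data.frame(
    term_id = c("SYN:0001", "SYN:0002", "SYN:0003"),
    category = c("GO-BP", "GO-CC", "keyword"),
    label = c("synthetic process A", "synthetic compartment B",
              "synthetic keyword C"),
    stringsAsFactors = FALSE)
  term_db$genes <- list(genes[1:6], genes[4:10], genes[8:14])
  class(term_db) <- c("fvn_term_db", "data.frame")

  # variant_set() sorts nothing; read_vcf sorts by (chrom,pos,alt). Keys:
  manifest <- list(
    seed = config$seed,
    n_members = config$n_members,
    n_affected = config$n_affected,
    affected = aff,
    n_variants = nv,
    planted_shared = as.list(vs$variants$key[shared_idx]),
    compound_het = lapply(names(ch_idx), function(g) {
      list(gene = g, member = unname(ch_member[[g]]),
           keys = as.list(vs$variants$key[ch_idx[[g]]]))
    })
  )

  out <- list(pedigree = ped, variants = vs,
              panel = structure(genes, class = "fvn_gene_panel"),
              annotations = variants, pm = pm, edge_db = edge_db,
              term_db = term_db, manifest = manifest)
  if (!is.null(dir)) {
    out$paths <- write_family_bundle(out, dir)
  }
  invisible(out)
}

write_family_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- list(
    ped = file.path(dir, "family.ped"),
    vcf = file.path(dir, "family.vcf"),
    panel = file.path(dir, "panel.txt"),
    variants = file.path(dir, "variants.tsv"),
    scores = file.path(dir, "scores.tsv"),
    cutoffs = file.path(dir, "cutoffs.tsv"),
    edge_db = file.path(dir, "edge_db.tsv"),
    terms = file.path(dir, "terms.gmt"),
    manifest = file.path(dir, "manifest.json"))
  ped <- bundle$pedigree
  ped_out <- data.frame(
    fid = "FAM1", id = ped$id,
    father = ifelse(is.na(ped$father), "0", ped$father),
    mother = ifelse(is.na(ped$mother), "0", ped$mother),
    sex = ifelse(is.na(ped$sex), "0", ifelse(ped$sex == "male", "1", "2")),
    status = ifelse(ped$affected, "2", "1"))
  utils::write.table(ped_out, p$ped, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_vcf(bundle$variants, p$vcf)
  writeLines(as.character(bundle$panel), p$panel)
  ann <- bundle$annotations
  ann$maf_gnomad3 <- format(ann$maf_gnomad3, trim = TRUE, digits = 6)
  ann$maf_1000g <- format(ann$maf_1000g, trim = TRUE, digits = 6)
  write_tsv(ann, p$variants)
  sc <- data.frame(key = rownames(bundle$pm$scores),
                   round(bundle$pm$scores, 6), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(sc, p$scores)
  write_tsv(bundle$pm$cutoffs, p$cutoffs)
  write_tsv(as.data.frame(bundle$edge_db), p$edge_db)
  gmt <- vapply(seq_len(nrow(bundle$term_db)), function(i) {
    paste(c(bundle$term_db$term_id[i],
            paste0(bundle$term_db$category[i], ":",
                   bundle$term_db$label[i]),
            bundle$term_db$genes[[i]]), collapse = "\t")
  }, character(1))
  writeLines(gmt, p$terms)
  jsonlite::write_json(bundle$manifest, p$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  p
}
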