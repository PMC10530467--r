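# Orchestration: one reproducible run of filter -> segregation ->
# categorize/rank -> prioritize -> per-patient networks -> enrichment.

#' Build a run configuration
#'
#' @param paths named list of input files: `vcf`, `ped`, `panel`,
#'   `variants` (variant annotation TSV), `regulatory`, `scores`,
#'   `cutoffs`, `edge_db`, `terms`
#' @param out_dir output directory (created if needed)
#' @param maf_max,qual_min,votes_min,affected_min,prior thresholds
#' @param tier_bounds named tier lower bounds (see [classify_tier()])
#' @param manual_includes gene symbols force-included in prioritization
#' @param network_eligible prioritized gene symbols admitted to network
#'   analysis
#' @param extra_includes named list patient -> extra node symbols
#' @param status_rule,clinvar_star see [prioritize()]
#' @param background optional enrichment background symbols (default:
#'   panel plus term-database genes plus manual includes)
#' @param seed integer recorded in the summary (the pipeline itself is
#'   deterministic)
#' @return a `fvn_run_config` list
#' @export
run_config <- function(paths, out_dir,
                       maf_max = 0.04, qual_min = 30,
                       votes_min = 4, affected_min = 2,
                       prior = 0.041,
                       tier_bounds = default_tier_bounds(),
                       manual_includes = character(0),
                       network_eligible = character(0),
                       extra_includes = list(),
                       status_rule = "low_evidence_exclusion",
                       clinvar_star = "any",
                       background = NULL,
                       seed = 1L) {
  stopifnot(maf_max > 0, maf_max <= 1, prior >= 0, prior < 1)
  core <- c("vcf", "ped", "panel", "variants", "scores", "cutoffs")
  miss <- setdiff(core, names(paths))
  if (length(miss)) stopf("run config lacks path(s): %s",
                          paste(miss, collapse = ", "))
  absent <- core[!vapply(paths[core], file.exists, logical(1))]
  if (length(absent)) {
    stopf("input file(s) not found: %s",
          paste(unlist(paths[absent]), collapse = ", "))
  }
  structure(as.list(environment()), class = "fvn_run_config")
}

#' Read a run configuration from JSON
#'
#' The JSON object mirrors the arguments of [run_config()]; `paths` and
#' `out_dir` are required.
#' @param path JSON file path
#' @return a `fvn_run_config`
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$paths) || is.null(cfg$out_dir)) {
    stopf("run config JSON must define 'paths' and 'out_dir'")
  }
  args <- cfg[intersect(names(cfg), names(formals(run_config)))]
  if (!is.null(args$extra_includes)) {
    args$extra_includes <- lapply(as.list(args$extra_includes), unlist)
  }
  if (!is.null(args$tier_bounds)) args$tier_bounds <- unlist(args$tier_bounds)
  do.call(run_config, args)
}

#' A ready-made run configuration for the packaged study fixture
#' @param out_dir output directory
#' @param ... overrides passed on to [run_config()]
#' @export
fixture_run_config <- function(out_dir, ...) {
  p <- fixture_paths()
  fcfg <- jsonlite::read_json(p$config, simplifyVector = TRUE)
  args <- list(paths = p, out_dir = out_dir,
               maf_max = fcfg$maf_max, qual_min = fcfg$qual_min,
               votes_min = fcfg$votes_min,
               affected_min = fcfg$affected_min, prior = fcfg$prior,
               tier_bounds = unlist(fcfg$tier_bounds),
               manual_includes = fcfg$manual_includes,
               network_eligible = fcfg$network_eligible,
               extra_includes = lapply(as.list(fcfg$extra_includes),
                                       unlist))
  override <- list(...)
  args[names(override)] <- override
  do.call(run_config, args)
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full pipeline
#'
#' Executes filter -> segregation -> categorize/rank -> prioritize ->
#' per-patient networks -> enrichment, writes all stage outputs under
#' `config$out_dir` (decisions TSV, heatmap TSV pair, per-patient edge
#' lists and enrichment TSVs, `summary.json`, `run.log`) and returns the
#' summary. Running twice with the same config yields identical outputs.
#'
#' @param config a `fvn_run_config`
#' @return the summary list, invisibly
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "fvn_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c("famvarnet pipeline run",
                 sprintf("package version: %s",
                         as.character(utils::packageVersion("famvarnet"))),
                 sprintf("seed: %d", as.integer(config$seed)),
                 sprintf("thresholds: maf_max=%g qual_min=%g votes_min=%d affected_min=%d prior=%g",
                         config$maf_max, config$qual_min,
                         config$votes_min, config$affected_min,
                         config$prior))

  inputs <- pipeline_stage("load", {
    ped <- read_ped(config$paths$ped)
    panel <- read_panel(config$paths$panel)
    ann <- read_annotation_tables(
      variant_tsv = config$paths$variants,
      regulatory_tsv = config$paths$regulatory)
    vs <- read_vcf(config$paths$vcf, ped, annotations = ann)
    pm <- read_prediction_matrix(config$paths$scores,
                                 config$paths$cutoffs)
    list(ped = ped, panel = panel, ann = ann, vs = vs, pm = pm)
  })
  ped <- inputs$ped; vs <- inputs$vs

  filtered <- pipeline_stage("filter", {
    apply_frequency_filter(vs, inputs$panel, ped,
                           maf_max = config$maf_max,
                           qual_min = config$qual_min)
  })
  parts <- pipeline_stage("segregation", split_by_consequence(filtered))
  cm_all <- carrier_matrix(vs, ped)
  cm_mis <- carrier_matrix(parts$missense, ped)
  shared_mis <- shared_in_affected(cm_mis, ped)
  per_member <- count_carried_per_member(cm_mis, ped)
  groups <- linkage_groups(vs, cm_all)

  decisions <- pipeline_stage("rank", {
    d <- rank_by_revel(inputs$pm, parts$missense)
    # manual includes: frequent functional variants outside the
    # low-frequency set join the decision table unranked
    for (g in setdiff(toupper(config$manual_includes), toupper(d$gene))) {
      cand <- vs$variants[!is.na(vs$variants$gene) &
                            toupper(vs$variants$gene) == g &
                            vs$variants$consequence == "missense", ,
                          drop = FALSE]
      if (nrow(cand) == 0) {
        stopf("manual include '%s' has no missense record in the input", g)
      }
      cand <- cand[variant_order(cand)[1], , drop = FALSE]
      d <- rbind(d, data.frame(
        key = cand$key, gene = cand$gene,
        protein_change = cand$protein_change,
        consequence = cand$consequence,
        revel_score = NA_real_, damaging_votes = NA_integer_,
        rank = NA_integer_, quartile = NA_integer_,
        stringsAsFactors = FALSE))
    }
    d
  })

  decisions <- pipeline_stage("prioritize", {
    n_aff <- vapply(cm_all$affected_carriers, length, integer(1))
    prioritize(decisions, inputs$ann, vs,
               affected_carriers = n_aff,
               manual_includes = config$manual_includes,
               votes_min = config$votes_min,
               affected_min = config$affected_min,
               status_rule = config$status_rule,
               clinvar_star = config$clinvar_star)
  })

  out <- function(f) file.path(config$out_dir, f)
  write_tsv(decisions, out("decisions.tsv"))
  export_heatmap_matrix(inputs$pm, decisions,
                        out("heatmap_scores.tsv"),
                        out("heatmap_categories.tsv"),
                        network_eligible = config$network_eligible)
  write_tsv(groups, out("linkage_groups.tsv"))

  networks <- list(); enrichments <- list(); node_sets <- list()
  if (length(config$network_eligible)) {
    pipeline_stage("network", {
      for (nm in c("edge_db", "terms")) {
        f <- config$paths[[nm]]
        if (is.null(f) || !file.exists(f)) {
          stopf("%s file not found (%s)", nm, f %||% "<unset>")
        }
      }
      edge_db <- read_edge_db(config$paths$edge_db)
      term_db <- read_term_db(config$paths$terms)
      background <- config$background %||% sort(unique(toupper(c(
        as.character(inputs$panel), unlist(term_db$genes),
        config$manual_includes))))
      node_sets <- build_patient_sets(decisions, cm_all, ped,
                                       config$network_eligible,
                                       config$extra_includes)
      for (p in names(node_sets)) {
        net <- build_patient_network(p, node_sets[[p]], edge_db,
                                     prior = config$prior,
                                     tier_bounds = config$tier_bounds)
        networks[[p]] <- net
        write_patient_network(net, out(sprintf("network_%s.tsv", p)),
                              out(sprintf("network_%s.sif", p)))
        enr <- enrich_terms(node_sets[[p]], term_db, background)
        enrichments[[p]] <- enr
        write_tsv(enr, out(sprintf("enrichment_%s.tsv", p)))
      }
    })
  }

  summary <- list(
    seed = as.integer(config$seed),
    thresholds = list(maf_max = config$maf_max,
                      qual_min = config$qual_min,
                      votes_min = config$votes_min,
                      affected_min = config$affected_min,
                      prior = config$prior),
    n_members = nrow(ped),
    n_affected = sum(ped$affected),
    n_input_records = n_variants(vs),
    n_filtered = n_variants(filtered),
    n_missense = n_variants(parts$missense),
    n_synonymous = n_variants(parts$synonymous),
    n_maf_lt_0.001 = sum(!is.na(filtered$variants$maf_gnomad3) &
                           filtered$variants$maf_gnomad3 < 0.001),
    missense_per_affected = as.list(per_member),
    n_shared_missense = length(shared_mis),
    shared_missense = as.list(shared_mis),
    n_linkage_groups = nrow(groups),
    n_prioritized = sum(decisions$status == "prioritized"),
    n_manual_include = sum(decisions$status == "manual_include"),
    prioritized_shared = as.list(
      intersect(decisions$key[decisions$status == "prioritized"],
                shared_mis)),
    node_set_sizes = lapply(node_sets, length),
    node_sets = lapply(node_sets, as.list))
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  writeLines(c(log_lines,
               sprintf("filtered: %d of %d records", summary$n_filtered,
                       summary$n_input_records),
               sprintf("prioritized: %d missense variants",
                       summary$n_prioritized)),
             out("run.log"))
  invisible(summary)
}
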