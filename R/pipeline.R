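write_fasta <- function(proteins, path) {
  seqinr::write.fasta(as.list(proteins$sequence), proteins$accession, path,
                      as.string = TRUE, nbchar = 60)
}

read_fasta_proteins <- function(path) {
  fa <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                           seqonly = FALSE)
  tibble(accession = names(fa),
         sequence = toupper(vapply(fa, function(s) as.character(s[[1]]),
                                   character(1), USE.NAMES = FALSE)))
}

#' Write a synthetic cohort to a directory of standard text formats
#'
#' CSV event/clinical/peak/HLA/rank tables, TSV expression matrices and a
#' FASTA protein file — the same formats the pipeline readers consume.
#'
#' @param cohort A `"synthetic_cohort"`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  catalog <- cohort$mutation_catalog |>
    mutate(protein_change = sprintf("p.%s%d%s", .data$wt_aa, .data$position,
                                    .data$mut_aa)) |>
    select("gene", "accession", "protein_change", "source")
  readr::write_csv(cohort$cell_events, p("cell_events.csv"))
  readr::write_csv(cohort$truth, p("truth_labels.csv"))
  readr::write_csv(catalog, p("mutation_catalog.csv"))
  write_fasta(cohort$proteins, p("proteins.fasta"))
  readr::write_csv(cohort$peptide_peaks, p("peptide_peaks.csv"))
  readr::write_csv(cohort$hla_types, p("hla_types.csv"))
  readr::write_csv(cohort$planted_ranks, p("planted_ranks.csv"))
  readr::write_csv(cohort$mhc_quant, p("mhc_quant.csv"))
  readr::write_tsv(cohort$mrna, p("expression_mrna.tsv"))
  readr::write_tsv(cohort$protein, p("expression_protein.tsv"))
  readr::write_csv(cohort$clinical, p("clinical.csv"))
  readr::write_csv(cohort$planted_signature, p("planted_signature.csv"))
  invisible(list.files(dir, full.names = TRUE))
}

read_expression_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Pipeline configuration
#'
#' Collects the synthetic-cohort configuration and every stage parameter —
#' all of the method's thresholds surfaced as named defaults: arcsinh
#' cofactor 5, k = 500 clusters, 29-residue windows via the neoantigen
#' module, binder tiers 2/1 (MHC-I) and 10/5 (MHC-II), dual-level signature
#' threshold 0.05, Cox screening threshold 0.2, and the 1.96 Z-ratio cutoff.
#'
#' @param sim A [sim_config()].
#' @param k Clusters for [cluster_events()]. The default here is 50, scaled
#'   to the synthetic cohorts' cell counts; set 500 for full-scale data.
#' @param cofactor Arcsinh cofactor.
#' @param target_fraction,outlier_quantile Downsampling parameters.
#' @param tier Neoantigen tier mode, `"potential"` or `"high"`.
#' @param p_threshold Signature derivation threshold.
#' @param screen_p Cox univariable screening threshold.
#' @param retention_quantile Scaffold-graph edge retention quantile.
#' @param zratio_cutoff Z-ratio significance cutoff.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(sim = sim_config(), k = 50, cofactor = 5,
                            target_fraction = 0.2, outlier_quantile = 0.01,
                            tier = "potential", p_threshold = 0.05,
                            screen_p = 0.2, retention_quantile = 0.9,
                            zratio_cutoff = 1.96) {
  stopifnot(inherits(sim, "sim_config"))
  if (!tier %in% c("potential", "high")) abort("invalid `tier`")
  structure(list(sim = sim, k = k, cofactor = cofactor,
                 target_fraction = target_fraction,
                 outlier_quantile = outlier_quantile, tier = tier,
                 p_threshold = p_threshold, screen_p = screen_p,
                 retention_quantile = retention_quantile,
                 zratio_cutoff = zratio_cutoff),
            class = "pipeline_config")
}

#' Run the full pipeline end to end
#'
#' simulate -> subtype -> neoantigen -> signature -> outcomes, writing every
#' stage's outputs as plain-text tables under `out_dir` plus a
#' `manifest.json` recording the configuration, package version, and an md5
#' hash of every written file. The manifest carries no timestamps, so two
#' runs with the same configuration produce byte-identical outputs.
#'
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(out_dir, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)

  # stage 1: simulate
  cohort <- simulate_cohort(config$sim)
  write_cohort(cohort, p("cohort"))

  # stage 2: cytometry subtyping
  ev <- arcsinh_transform(cohort$cell_events, cofactor = config$cofactor)
  down <- density_downsample(ev, target_fraction = config$target_fraction,
                             outlier_quantile = config$outlier_quantile,
                             seed = config$sim$seed)
  scaffold <- cluster_events(down, k = min(config$k, nrow(down)),
                             full_events = ev, seed = config$sim$seed)
  scaffold <- assign_phenotypes(scaffold, strict = FALSE)
  graph <- build_scaffold_graph(scaffold,
                                retention_quantile = config$retention_quantile)
  subtypes <- subtype_samples(scaffold$fractions,
                              scaffold$nodes[, c("node_id", "phenotype")])
  act <- intersect(time_panel()$marker[time_panel()$role == "activation"],
                   marker_cols(ev))
  act_summary <- ev |>
    group_by(.data$sample_id) |>
    summarise(across(dplyr::all_of(act), stats::median), .groups = "drop")
  zr <- z_ratio(act_summary,
                subtypes$sample_id[subtypes$subtype == "I"],
                subtypes$sample_id[subtypes$subtype == "II"],
                cutoff = config$zratio_cutoff)
  readr::write_csv(scaffold$nodes, p("nodes.csv"))
  readr::write_csv(scaffold$fractions, p("node_fractions.csv"))
  readr::write_csv(graph$edges, p("graph_edges.csv"))
  readr::write_csv(subtypes, p("subtypes.csv"))
  readr::write_csv(zr, p("z_ratios.csv"))

  # stage 3: neoantigen calling and quantification
  predictor <- toy_rank_predictor(cohort$planted_ranks)
  peaks <- quantify_abundance(cohort$peptide_peaks)
  calls <- call_neoantigens(peaks, cohort$hla_types, cohort$mutation_catalog,
                            cohort$proteins, predictor, tier = config$tier)
  abundance <- average_neoantigen_abundance(calls,
                                            samples = subtypes$sample_id)
  mhc <- mhc_protein_expression(cohort$mhc_quant)
  conc <- concordance_analysis(calls, mhc$per_locus, subtypes)
  readr::write_csv(calls, p("neoantigen_calls.csv"))
  readr::write_csv(abundance, p("neoantigen_abundance.csv"))
  readr::write_csv(mhc$totals, p("mhc_totals.csv"))

  # stage 4: dual-level signature
  groups <- rename(subtypes, group = "subtype")
  mrna_stats <- differential_features(cohort$mrna, groups)
  prot_stats <- differential_features(cohort$protein, groups)
  signature <- derive_signature(mrna_stats, prot_stats, cohort$mrna, groups,
                                p_threshold = config$p_threshold)
  sig_calls <- classify_samples(signature, cohort$mrna)
  readr::write_csv(tidy(signature), p("signature_genes.csv"))
  readr::write_csv(sig_calls, p("signature_calls.csv"))

  # stage 5: outcomes
  surv <- survival_compare(cohort$clinical,
                           tibble(patient_id = sig_calls$sample_id,
                                  group = sig_calls$label))
  fisher <- fisher_response(sig_calls, cohort$clinical)
  clin <- cohort$clinical
  clin$signature <- sig_calls$label[match(clin$patient_id,
                                          sig_calls$sample_id)]
  cox <- cox_model(clin, c("signature", "age", "asbestos", "histology",
                           "stage"), screen_p = config$screen_p)
  readr::write_csv(surv$km, p("km_curves.csv"))
  readr::write_csv(tidy(cox), p("cox_fits.csv"))
  stats_out <- list(
    logrank = list(statistic = surv$statistic, p_value = surv$p_value),
    fisher = list(odds_ratio = fisher$odds_ratio, p_value = fisher$p_value),
    concordance_chisq = list(statistic = conc$statistic,
                             p_value = conc$p_value),
    signature_size = nrow(signature$genes),
    realized_nodes = nrow(scaffold$nodes)
  )
  jsonlite::write_json(stats_out, p("outcome_stats.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  manifest <- list(
    package = "timeatlas",
    version = as.character(utils::packageVersion("timeatlas")),
    seed = config$sim$seed,
    config = unclass(config$sim),
    parameters = unclass(config)[setdiff(names(unclass(config)), "sim")],
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files))
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
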