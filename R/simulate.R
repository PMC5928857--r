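#' Configuration for a synthetic immunoproteogenomic cohort
#'
#' Bundles and validates every knob of the synthetic-cohort generator. The
#' generator plants known structure — two latent immunologic subtypes driving
#' cell-composition shifts, neopeptide abundance shifts, a dual-level gene
#' signature, and survival/response differences — so each pipeline stage can be
#' scored against ground truth.
#'
#' @param n_samples Number of tumor samples / patients.
#' @param subtype_fraction Fraction of samples assigned to subtype I.
#' @param n_phenotypes Number of cellular phenotypes (fixed at the 15 built-in
#'   definitions; see [time_phenotypes()]).
#' @param n_markers Number of panel markers (fixed at the 35-marker panel).
#' @param cells_per_sample Cells simulated per sample.
#' @param dirichlet_concentration Concentration of the Dirichlet prior on
#'   per-sample phenotype mixtures; larger = less sample-to-sample variability.
#' @param activation_shift Subtype separation, in noise-SD units, applied both
#'   to phenotype mixture weights and to activation-marker means. 0 = no
#'   planted cytometry signal.
#' @param n_genes Genes in the paired mRNA/protein expression matrices.
#' @param n_signature_genes Number of planted dual-level signature genes.
#' @param signature_effect Between-subtype mean difference of planted signature
#'   genes, in SD units, at both expression levels.
#' @param mrna_protein_corr Per-gene correlation between mRNA and protein
#'   noise, in `[-1, 1]`.
#' @param n_mutations_per_patient Missense mutations carried per patient
#'   (drawn from a shared cohort-level catalog three times that size).
#' @param detect_prob Probability that a carried mutation's peptide is detected
#'   by mass spectrometry.
#' @param abundance_shift Log-scale increase of detected neopeptide peak
#'   intensity (and, at half strength, MHC protein expression) in subtype-I
#'   samples.
#' @param hazard_ratio Hazard multiplier for subtype-II patients in the
#'   exponential survival model.
#' @param response_prob_good,response_prob_bad Probability of objective
#'   response (CR/PR) for subtype-I and subtype-II patients.
#' @param seed Integer seed; fully determines the generated cohort.
#' @return A validated list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(n_samples = 12, seed = 7)
#' @export
sim_config <- function(n_samples = 12,
                       subtype_fraction = 0.5,
                       n_phenotypes = 15,
                       n_markers = 35,
                       cells_per_sample = 600,
                       dirichlet_concentration = 50,
                       activation_shift = 3,
                       n_genes = 1000,
                       n_signature_genes = 137,
                       signature_effect = 3,
                       mrna_protein_corr = 0.7,
                       n_mutations_per_patient = 25,
                       detect_prob = 0.6,
                       abundance_shift = 2,
                       hazard_ratio = 1.74,
                       response_prob_good = 0.8,
                       response_prob_bad = 0.1,
                       seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples),
    subtype_fraction = subtype_fraction,
    n_phenotypes = as.integer(n_phenotypes),
    n_markers = as.integer(n_markers),
    cells_per_sample = as.integer(cells_per_sample),
    dirichlet_concentration = dirichlet_concentration,
    activation_shift = activation_shift,
    n_genes = as.integer(n_genes),
    n_signature_genes = as.integer(n_signature_genes),
    signature_effect = signature_effect,
    mrna_protein_corr = mrna_protein_corr,
    n_mutations_per_patient = as.integer(n_mutations_per_patient),
    detect_prob = detect_prob,
    abundance_shift = abundance_shift,
    hazard_ratio = hazard_ratio,
    response_prob_good = response_prob_good,
    response_prob_bad = response_prob_bad,
    seed = as.integer(seed)
  )
  counts <- c("n_samples", "n_phenotypes", "n_markers", "cells_per_sample",
              "n_genes", "n_signature_genes", "n_mutations_per_patient")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1L)
      abort(sprintf("`%s` must be a count >= 1", nm))
  }
  probs <- c("subtype_fraction", "detect_prob", "response_prob_good",
             "response_prob_bad")
  for (nm in probs) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      abort(sprintf("`%s` must be in [0, 1]", nm))
  }
  if (abs(cfg$mrna_protein_corr) > 1)
    abort("`mrna_protein_corr` must be in [-1, 1]")
  if (cfg$dirichlet_concentration <= 0)
    abort("`dirichlet_concentration` must be positive")
  if (cfg$hazard_ratio <= 0) abort("`hazard_ratio` must be positive")
  if (cfg$n_phenotypes != 15L)
    abort("`n_phenotypes` is fixed at the 15 built-in phenotype definitions")
  if (cfg$n_markers != 35L)
    abort("`n_markers` is fixed at the 35-marker built-in panel")
  if (cfg$n_signature_genes >= cfg$n_genes)
    abort("`n_signature_genes` must be smaller than `n_genes`")
  if (is.na(cfg$seed)) abort("`seed` must be an integer")
  structure(cfg, class = "sim_config")
}

# Deterministic subtype assignment for a config: subtype I for a seeded random
# subset of round(n * fraction) samples.
subtype_truth <- function(config) {
  n <- config$n_samples
  n1 <- round(n * config$subtype_fraction)
  ids <- sample_ids(n)
  with_seed(config$seed, {
    pick <- sample.int(n, n1)
    tibble(sample_id = ids,
           subtype = ifelse(seq_len(n) %in% pick, "I", "II"))
  })
}

# arcsinh-scale template matrix (phenotype x marker): gate markers hi/lo,
# other lineage markers lo, non-gated activation markers at a mid baseline.
phenotype_templates <- function() {
  panel <- time_panel()
  defs <- time_phenotypes()
  phenos <- unique(defs$phenotype)
  tmpl <- matrix(NA_real_, length(phenos), nrow(panel),
                 dimnames = list(phenos, panel$marker))
  tmpl[, panel$marker[panel$role == "lineage"]] <- 0.4
  tmpl[, panel$marker[panel$role == "activation"]] <- 0.8
  for (i in seq_len(nrow(defs))) {
    tmpl[defs$phenotype[i], defs$marker[i]] <-
      if (defs$sign[i] > 0) 3.0 else 0.4
  }
  tmpl
}

#' Simulate single-cell mass-cytometry events for a cohort
#'
#' Draws, for each sample, a Dirichlet mixture over the 15 built-in cellular
#' phenotypes and then cells from Gaussian hi/lo marker archetypes on the
#' arcsinh scale. Subtype I tilts the mixture toward exhausted CD8 T cells,
#' pDCs and cancer cells and away from Tregs/TAM/neutrophils/CAFs, and shifts
#' activation-marker means, both proportionally to `activation_shift`. Values
#' are returned on the raw intensity scale (inverse arcsinh, cofactor 5,
#' clamped at zero) so the standard preprocessing applies.
#'
#' @param config A [sim_config()].
#' @return A list with `events` (tibble: `sample_id`, `cell_id`, 35 marker
#'   columns, untransformed), `truth` (tibble: `sample_id`, `subtype`) and
#'   `cell_truth` (tibble: `sample_id`, `cell_id`, `phenotype`).
#' @export
generate_cell_events <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$cells_per_sample < config$n_phenotypes)
    abort("insufficient cells: `cells_per_sample` < `n_phenotypes`")
  truth <- subtype_truth(config)
  tmpl <- phenotype_templates()
  phenos <- rownames(tmpl)
  markers <- colnames(tmpl)
  tilt_w <- phenotype_tilt()[phenos]
  tilt_a <- activation_tilt()
  noise_sd <- 0.4
  cofactor <- 5

  with_seed(config$seed + 1L, {
    per_sample <- purrr::map2(truth$sample_id, truth$subtype, function(sid, st) {
      dir <- if (st == "I") 1 else -1
      alpha <- config$dirichlet_concentration / length(phenos) *
        exp(0.35 * config$activation_shift * tilt_w * dir)
      w <- rdirichlet1(alpha)
      counts <- as.vector(stats::rmultinom(1, config$cells_per_sample, w))
      pheno_of_cell <- rep(phenos, counts)
      z <- tmpl[pheno_of_cell, , drop = FALSE] +
        matrix(stats::rnorm(length(pheno_of_cell) * length(markers),
                            sd = noise_sd),
               length(pheno_of_cell), length(markers))
      act <- names(tilt_a)
      shift <- config$activation_shift * noise_sd / 2 * dir
      z[, act] <- sweep(z[, act, drop = FALSE], 2, tilt_a * shift, "+")
      raw <- pmax(cofactor * sinh(z), 0)
      out <- as_tibble(raw)
      out$sample_id <- sid
      out$cell_id <- sprintf("%s_c%05d", sid, seq_along(pheno_of_cell))
      out$.phenotype <- pheno_of_cell
      out
    })
    all <- bind_rows(per_sample)
    cell_truth <- all[, c("sample_id", "cell_id", ".phenotype")]
    names(cell_truth)[3] <- "phenotype"
    events <- all[, c("sample_id", "cell_id", markers)]
    events <- new_cell_events(events, transformed = FALSE)
    list(events = events, truth = truth, cell_truth = cell_truth)
  })
}

# ---- peptidome -------------------------------------------------------------

hla_allele_pool <- function() {
  list(
    "HLA-A"    = c("HLA-A*01:01", "HLA-A*02:01", "HLA-A*03:01",
                   "HLA-A*26:01", "HLA-A*30:02"),
    "HLA-B"    = c("HLA-B*07:02", "HLA-B*08:01", "HLA-B*18:01",
                   "HLA-B*35:01", "HLA-B*44:02"),
    "HLA-C"    = c("HLA-C*04:01", "HLA-C*05:01", "HLA-C*07:01",
                   "HLA-C*07:02"),
    "HLA-DRB1" = c("HLA-DRB1*03:01", "HLA-DRB1*07:01", "HLA-DRB1*08:01",
                   "HLA-DRB1*13:01", "HLA-DRB1*15:01"),
    "HLA-DRB3" = c("HLA-DRB3*01:01", "HLA-DRB3*02:02"),
    "HLA-DRB4" = c("HLA-DRB4*01:01", "HLA-DRB4*01:03"),
    "HLA-DRB5" = c("HLA-DRB5*01:01", "HLA-DRB5*02:02"),
    "HLA-DQA1" = c("HLA-DQA1*01:02", "HLA-DQA1*03:01", "HLA-DQA1*05:01"),
    "HLA-DQB1" = c("HLA-DQB1*02:01", "HLA-DQB1*03:01", "HLA-DQB1*06:02"),
    "HLA-DPA1" = c("HLA-DPA1*01:03", "HLA-DPA1*02:01"),
    "HLA-DPB1" = c("HLA-DPB1*01:01", "HLA-DPB1*04:01", "HLA-DPB1*04:02")
  )
}

class_i_loci <- function() c("HLA-A", "HLA-B", "HLA-C")
class_ii_loci <- function() c("HLA-DRB1", "HLA-DRB3", "HLA-DRB4", "HLA-DRB5",
                              "HLA-DQA1", "HLA-DQB1", "HLA-DPA1", "HLA-DPB1")

#' Simulate the mutation catalog, proteome and detected neopeptide peaks
#'
#' Builds a cohort-level catalog of missense mutations on random protein
#' sequences, assigns each patient a subset of carried mutations, samples
#' Bernoulli detection and log-normal peak abundances (mean shifted by
#' `abundance_shift` on the log scale for subtype-I samples), types each
#' patient at 11 HLA loci, and plants true MHC binders: for a binder mutation
#' one mutation-spanning candidate peptide receives a percentile rank below 1
#' on one designated allele, while all background (peptide, allele) ranks sit
#' above every binding threshold so the planted call set is unambiguous.
#' MHC-locus protein expression (iFOT) is simulated with half the abundance
#' shift, higher in subtype I.
#'
#' @param config A [sim_config()].
#' @param truth Tibble `sample_id`, `subtype` covering all samples (as from
#'   [generate_cell_events()]).
#' @return A list: `mutation_catalog`, `proteins` (tibble with `accession`,
#'   `gene`, `sequence`), `peptide_peaks`, `hla_types`, `planted_ranks`,
#'   `binder_truth` (mutation x class truth with binding allele),
#'   `call_truth` (expected neoantigen calls at `detect_prob = 1`),
#'   `mhc_quant` (per-sample per-locus iFOT).
#' @export
generate_peptidome <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  ids <- sample_ids(config$n_samples)
  if (!setequal(truth$sample_id, ids))
    abort("`truth` must cover exactly the config's sample identifiers")
  n_cat <- config$n_mutations_per_patient * 3L
  pool <- hla_allele_pool()

  with_seed(config$seed + 2L, {
    # proteins: one mutation per protein
    lens <- sample(40:120, n_cat, replace = TRUE)
    seqs <- vapply(lens, function(L)
      paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = ""),
      character(1))
    proteins <- tibble(
      accession = sprintf("P%04d", seq_len(n_cat)),
      gene = sprintf("GENE%04d", seq_len(n_cat)),
      sequence = seqs
    )
    pos <- vapply(lens, function(L) sample.int(L, 1), integer(1))
    wt <- substring(seqs, pos, pos)
    mut <- vapply(wt, function(a) sample(setdiff(AA_ALPHABET, a), 1),
                  character(1), USE.NAMES = FALSE)
    catalog <- tibble(
      gene = proteins$gene,
      accession = proteins$accession,
      position = pos,
      wt_aa = wt,
      mut_aa = mut,
      source = sample(c("cohortA", "cohortB", "public_db"), n_cat,
                      replace = TRUE)
    )

    # windows and one detected peptide per mutation (shared across patients)
    windows <- purrr::map(seq_len(n_cat), function(i) {
      make_peptide_window(proteins$sequence[i], catalog[i, ])
    })
    detected <- purrr::map_chr(windows, function(w) {
      L <- min(sample(9:18, 1), nchar(w$sequence))
      lo <- max(1, w$mutation_offset - L + 1)
      hi <- min(w$mutation_offset, nchar(w$sequence) - L + 1)
      start <- if (hi <= lo) lo else sample(lo:hi, 1)
      substr(w$sequence, start, start + L - 1)
    })

    # HLA typing: two alleles per locus (possibly homozygous), DRB3/4/5 0-1
    hla_types <- purrr::map_dfr(ids, function(pid) {
      purrr::map_dfr(names(pool), function(locus) {
        k <- if (locus %in% c("HLA-DRB3", "HLA-DRB4", "HLA-DRB5"))
          sample(0:1, 1) else 2
        if (k == 0) return(tibble())
        tibble(patient_id = pid, locus = locus,
               allele = sample(pool[[locus]], k, replace = TRUE))
      })
    })
    hla_types <- distinct(hla_types)

    # planted binders: per mutation x class, binder w.p. 0.7 on one allele
    binder_truth <- purrr::map_dfr(c("I", "II"), function(cls) {
      is_binder <- stats::runif(n_cat) < 0.7
      loci <- if (cls == "I") class_i_loci() else "HLA-DRB1"
      allele <- vapply(seq_len(n_cat), function(i)
        sample(unlist(pool[loci], use.names = FALSE), 1), character(1))
      tibble(accession = catalog$accession, position = catalog$position,
             mut_aa = catalog$mut_aa, mhc_class = cls,
             is_binder = is_binder, binding_allele = allele)
    })
    planted_ranks <- purrr::map_dfr(seq_len(nrow(binder_truth)), function(j) {
      row <- binder_truth[j, ]
      if (!row$is_binder) return(tibble())
      i <- match(row$accession, catalog$accession)
      cands <- enumerate_candidates(windows[[i]], row$mhc_class)
      # plant on a candidate contained in the detected peptide when possible,
      # so detection and binding concern the same peptide region
      inside <- cands$sequence[vapply(cands$sequence, grepl, logical(1),
                                      x = detected[i], fixed = TRUE)]
      seqs <- if (length(inside)) inside else cands$sequence
      tibble(peptide = sample(seqs, 1), allele = row$binding_allele,
             rank = stats::runif(1, 0.2, 1.0))
    })

    # per-patient carried mutations, detection, abundance
    peaks <- purrr::map_dfr(ids, function(pid) {
      st <- truth$subtype[truth$sample_id == pid]
      carried <- sort(sample.int(n_cat, config$n_mutations_per_patient))
      det <- carried[stats::runif(length(carried)) < config$detect_prob]
      if (!length(det)) return(tibble())
      tibble(
        peptide = detected[det],
        sample_id = pid,
        accession = catalog$accession[det],
        position = catalog$position[det],
        auc = stats::rlnorm(length(det),
                            meanlog = 9 + (st == "I") * config$abundance_shift,
                            sdlog = 1)
      )
    })

    # expected calls at the generator's detection outcome
    call_truth <- inner_join(
      peaks, filter(binder_truth, .data$is_binder),
      by = c("accession", "position"),
      relationship = "many-to-many"
    )
    call_truth <- inner_join(
      call_truth,
      rename(hla_types, sample_id = "patient_id"),
      by = c("sample_id", binding_allele = "allele")
    )
    call_truth <- distinct(select(call_truth, "sample_id", "accession",
                                  "position", "mhc_class", "auc",
                                  "binding_allele"))

    # MHC protein expression, subtype-I-elevated
    loci <- names(pool)
    mhc_quant <- purrr::map_dfr(ids, function(pid) {
      st <- truth$subtype[truth$sample_id == pid]
      tibble(sample_id = pid, locus = loci,
             ifot = stats::rlnorm(length(loci),
                                  meanlog = log(300) +
                                    (st == "I") * config$abundance_shift / 2,
                                  sdlog = 0.6))
    })

    list(mutation_catalog = catalog, proteins = proteins,
         peptide_peaks = select(peaks, "peptide", "sample_id", "auc"),
         peak_parents = select(peaks, "peptide", "sample_id", "accession",
                               "position"),
         hla_types = hla_types, planted_ranks = planted_ranks,
         binder_truth = binder_truth, call_truth = call_truth,
         mhc_quant = mhc_quant)
  })
}

#' Simulate paired mRNA and protein expression with a planted signature
#'
#' Non-signature genes are null at both levels. Planted signature genes are
#' shifted between subtypes by `signature_effect` SD units in a random but
#' concordant direction at both levels. Each gene's mRNA and protein values
#' share a latent component giving per-gene correlation `mrna_protein_corr`;
#' at correlation 1 the two levels are numerically identical.
#'
#' @param config A [sim_config()].
#' @param truth Tibble `sample_id`, `subtype`.
#' @return A list: `mrna` and `protein` (tibbles, `gene` + one column per
#'   sample), `planted_signature` (tibble `gene`, `direction` with
#'   `"up_in_I"`/`"down_in_I"`).
#' @export
generate_expression_cohort <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  ids <- truth$sample_id
  n <- length(ids)
  genes <- sprintf("G%05d", seq_len(config$n_genes))
  with_seed(config$seed + 3L, {
    sig_idx <- sort(sample.int(config$n_genes, config$n_signature_genes))
    dir_sign <- sample(c(-1, 1), config$n_signature_genes, replace = TRUE)
    rho <- config$mrna_protein_corr
    u <- matrix(stats::rnorm(config$n_genes * n), config$n_genes, n)
    e1 <- matrix(stats::rnorm(config$n_genes * n), config$n_genes, n)
    e2 <- matrix(stats::rnorm(config$n_genes * n), config$n_genes, n)
    a <- sqrt(abs(rho))
    b <- sqrt(1 - abs(rho))
    mrna <- a * u + b * e1
    protein <- if (rho >= 0) a * u + b * e2 else -a * u + b * e2
    mu <- matrix(0, config$n_genes, n)
    stI <- truth$subtype == "I"
    mu[sig_idx, stI] <- dir_sign * config$signature_effect / 2
    mu[sig_idx, !stI] <- -dir_sign * config$signature_effect / 2
    mrna <- mrna + mu
    protein <- protein + mu
    colnames(mrna) <- colnames(protein) <- ids
    list(
      mrna = bind_cols(tibble(gene = genes), as_tibble(mrna)),
      protein = bind_cols(tibble(gene = genes), as_tibble(protein)),
      planted_signature = tibble(
        gene = genes[sig_idx],
        direction = ifelse(dir_sign > 0, "up_in_I", "down_in_I")
      )
    )
  })
}

#' Simulate survival and immunotherapy response outcomes
#'
#' Exponential overall survival (baseline median 18 months) with the hazard
#' multiplied by `hazard_ratio` for subtype-II patients; independent uniform
#' censoring on \[0, 60\] months. Objective response is Bernoulli with
#' subtype-specific probability; responders split CR:PR = 3:1 and
#' non-responders PD:SD = 4:1 into mRECIST categories.
#'
#' @param config A [sim_config()].
#' @param truth Tibble `sample_id`, `subtype`.
#' @return A tibble: `patient_id`, `time_months`, `event`, `age`, `asbestos`,
#'   `histology`, `stage`, `response`.
#' @export
generate_outcomes <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(truth)
  with_seed(config$seed + 4L, {
    rate <- log(2) / 18 * ifelse(truth$subtype == "II", config$hazard_ratio, 1)
    t_true <- stats::rexp(n, rate)
    cens <- stats::runif(n, 0, 60)
    responder <- stats::runif(n) < ifelse(truth$subtype == "I",
                                          config$response_prob_good,
                                          config$response_prob_bad)
    response <- ifelse(
      responder,
      sample(c("CR", "PR"), n, replace = TRUE, prob = c(3, 1)),
      sample(c("PD", "SD"), n, replace = TRUE, prob = c(4, 1))
    )
    tibble(
      patient_id = truth$sample_id,
      time_months = pmin(t_true, cens),
      event = as.integer(t_true <= cens),
      age = round(stats::rnorm(n, 65, 8)),
      asbestos = stats::rbinom(n, 1, 0.6),
      histology = sample(c("epithelial", "nonepithelial"), n, TRUE,
                         prob = c(0.7, 0.3)),
      stage = sample(1:4, n, TRUE, prob = c(0.1, 0.3, 0.4, 0.2)),
      response = response
    )
  })
}

#' Simulate a complete synthetic cohort
#'
#' Runs every generator under one configuration: cell events, mutation catalog
#' and neopeptide peaks, HLA types and planted binder ranks, paired expression
#' matrices with a planted signature, and clinical outcomes. All components
#' share one sample-identifier set and the planted subtype labels.
#'
#' @param config A [sim_config()].
#' @return A list of class `"synthetic_cohort"`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_samples = 6, cells_per_sample = 100,
#'                                      n_genes = 50, n_signature_genes = 10,
#'                                      seed = 1))
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cells <- generate_cell_events(config)
  pept <- generate_peptidome(config, cells$truth)
  expr <- generate_expression_cohort(config, cells$truth)
  clin <- generate_outcomes(config, cells$truth)
  structure(
    c(list(config = config, truth = cells$truth,
           cell_events = cells$events, cell_truth = cells$cell_truth,
           clinical = clin),
      pept, expr),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>\n")
  cat("  samples:   ", x$config$n_samples,
      sprintf(" (subtype I: %d)", sum(x$truth$subtype == "I")), "\n", sep = "")
  cat("  cells:     ", nrow(x$cell_events), "\n", sep = "")
  cat("  mutations: ", nrow(x$mutation_catalog), " in catalog\n", sep = "")
  cat("  peaks:     ", nrow(x$peptide_peaks), " detected\n", sep = "")
  cat("  genes:     ", x$config$n_genes,
      sprintf(" (planted signature: %d)", nrow(x$planted_signature)),
      "\n", sep = "")
  invisible(x)
}
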