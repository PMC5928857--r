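#' Build a missense-mutation reference database from source catalogs
#'
#' Parses protein-change notation (e.g. `"p.N645K"`), drops non-missense and
#' malformed rows with a logged count, and collapses duplicate mutations
#' (same protein, position and substitution) across sources, keeping every
#' source tag.
#'
#' @param sources A tibble, or list of tibbles, with columns `gene`,
#'   `protein_change` and `source`, plus optionally `accession` (defaults to
#'   the gene symbol).
#' @return A tibble `gene`, `accession`, `position`, `wt_aa`, `mut_aa`,
#'   `source` (semicolon-collapsed tags), one row per distinct mutation.
#' @examples
#' build_mutation_db(tibble::tibble(gene = "BAP1",
#'                                  protein_change = "p.N645K",
#'                                  source = "cohortA"))
#' @export
build_mutation_db <- function(sources) {
  if (is.data.frame(sources)) sources <- list(sources)
  raw <- bind_rows(sources)
  if (!all(c("gene", "protein_change", "source") %in% names(raw)))
    abort("sources need columns `gene`, `protein_change`, `source`")
  if (!"accession" %in% names(raw)) raw$accession <- raw$gene
  m <- stringr::str_match(raw$protein_change,
                          "^p\\.([A-Za-z])(\\d+)([A-Za-z])$")
  wt <- toupper(m[, 2])
  mut <- toupper(m[, 4])
  ok <- !is.na(m[, 1]) & wt %in% AA_ALPHABET & mut %in% AA_ALPHABET & wt != mut
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    inform(sprintf("dropped %d non-missense or malformed rows", n_dropped))
  parsed <- tibble(
    gene = raw$gene[ok], accession = raw$accession[ok],
    position = as.integer(m[ok, 3]), wt_aa = wt[ok], mut_aa = mut[ok],
    source = raw$source[ok]
  )
  parsed |>
    group_by(.data$gene, .data$accession, .data$position,
             .data$wt_aa, .data$mut_aa) |>
    summarise(source = paste(sort(unique(.data$source)), collapse = ";"),
              .groups = "drop") |>
    arrange(.data$accession, .data$position)
}

#' Extract the 29-residue mutant peptide window around a missense site
#'
#' Takes the residues 14 positions either side of the mutation (a 29-mer with
#' the point-mutation site at the middle), clipped at the protein termini,
#' with the mutant residue substituted. The reference residue at the mutation
#' position must match `wt_aa`.
#'
#' @param protein_seq Reference protein sequence (single string).
#' @param mutation One-row data frame (or list) with `position`, `wt_aa`,
#'   `mut_aa`, and optionally `gene`/`accession`.
#' @param flank Residues kept either side of the mutation, default 14.
#' @return A list of class `"peptide_window"`: `sequence`, `mutation_offset`
#'   (1-based index of the mutant residue within the window), `mutation`.
#' @export
make_peptide_window <- function(protein_seq, mutation, flank = 14) {
  pos <- as.integer(mutation$position)
  if (pos < 1 || pos > nchar(protein_seq))
    abort("mutation position outside the protein")
  ref <- substr(protein_seq, pos, pos)
  if (ref != mutation$wt_aa)
    abort(sprintf(
      "reference inconsistency: protein has %s at position %d, expected %s",
      ref, pos, mutation$wt_aa))
  start <- as.integer(max(1, pos - flank))
  end <- as.integer(min(nchar(protein_seq), pos + flank))
  window <- substr(protein_seq, start, end)
  offset <- pos - start + 1L
  substr(window, offset, offset) <- mutation$mut_aa
  structure(list(sequence = window, mutation_offset = offset,
                 mutation = as.list(mutation)[c("gene", "accession",
                                                "position", "wt_aa",
                                                "mut_aa")]),
            class = "peptide_window")
}

#' Enumerate candidate MHC-binding peptides from a mutant window
#'
#' All substrings of the class-appropriate lengths (8-14-mers for MHC class I,
#' 15-mers for class II) that span the mutated residue, each emitted once per
#' (sequence, length). A full 29-mer with a centered mutation yields 77
#' class-I and 15 class-II candidates.
#'
#' @param window A `"peptide_window"`.
#' @param mhc_class `"I"` or `"II"`.
#' @return A tibble `sequence`, `length`, `mhc_class`, `mut_offset`
#'   (mutation position within the candidate), `wt_aa`, `mut_aa`; empty with a
#'   warning if the window is shorter than the minimum candidate length.
#' @export
enumerate_candidates <- function(window, mhc_class = c("I", "II")) {
  mhc_class <- match.arg(mhc_class)
  lengths <- if (mhc_class == "I") 8:14 else 15L
  W <- nchar(window$sequence)
  off <- window$mutation_offset
  if (W < min(lengths)) {
    warn("window shorter than the minimum candidate length; no candidates")
    return(tibble(sequence = character(), length = integer(),
                  mhc_class = character(), mut_offset = integer(),
                  wt_aa = character(), mut_aa = character()))
  }
  out <- purrr::map_dfr(lengths[lengths <= W], function(L) {
    starts <- max(1L, off - L + 1L):min(off, W - L + 1L)
    tibble(sequence = substring(window$sequence, starts, starts + L - 1L),
           length = L, mhc_class = mhc_class,
           mut_offset = off - starts + 1L)
  })
  out$wt_aa <- window$mutation$wt_aa
  out$mut_aa <- window$mutation$mut_aa
  distinct(out, .data$sequence, .data$length, .keep_all = TRUE)
}

#' Deterministic toy percentile-rank predictor
#'
#' A stand-in for an external epitope-prediction service with the same seam:
#' `f(peptides, alleles) -> percentile ranks`. Background ranks come from a
#' deterministic string hash of `(peptide, allele)` mapped onto
#' `(background_floor, 100]`; optional planted `(peptide, allele, rank)` rows
#' override the hash, which is how the synthetic generator plants true binders
#' below the binding thresholds while keeping everything else above them.
#'
#' @param planted Optional tibble `peptide`, `allele`, `rank`.
#' @param background_floor Lower bound of background ranks, default 10 (above
#'   every binding threshold, so only planted pairs can be binders).
#' @return A vectorized function `(peptides, alleles) -> ranks in (0, 100]`.
#' @export
toy_rank_predictor <- function(planted = NULL, background_floor = 10) {
  stopifnot(background_floor >= 0, background_floor < 100)
  key <- if (!is.null(planted)) paste(planted$peptide, planted$allele) else
    character()
  function(peptides, alleles) {
    r <- background_floor +
      string_hash_unit(paste(peptides, "|", alleles)) * (100 - background_floor)
    if (length(key)) {
      hit <- match(paste(peptides, alleles), key)
      r[!is.na(hit)] <- planted$rank[hit[!is.na(hit)]]
    }
    r
  }
}

#' Predict mutant and wild-type percentile ranks for candidate peptides
#'
#' Crosses candidates with alleles, builds each candidate's wild-type
#' counterpart by reverting the mutated residue, and attaches both percentile
#' ranks from the supplied predictor.
#'
#' @param candidates Candidate tibble from [enumerate_candidates()].
#' @param alleles Character vector of HLA alleles.
#' @param predictor A function `(peptides, alleles) -> ranks in (0, 100]`,
#'   e.g. [toy_rank_predictor()].
#' @return The candidates crossed with alleles, plus `wt_sequence`,
#'   `mut_rank`, `wt_rank`.
#' @export
predict_ranks <- function(candidates, alleles, predictor) {
  if (!nrow(candidates) || !length(alleles))
    return(mutate(candidates[0, ], allele = character(),
                  wt_sequence = character(), mut_rank = numeric(),
                  wt_rank = numeric()))
  wt_seq <- candidates$sequence
  substr(wt_seq, candidates$mut_offset, candidates$mut_offset) <-
    candidates$wt_aa
  out <- tidyr::crossing(bind_cols(candidates, tibble(wt_sequence = wt_seq)),
                         tibble(allele = alleles))
  out$mut_rank <- predictor(out$sequence, out$allele)
  out$wt_rank <- predictor(out$wt_sequence, out$allele)
  bad <- !is.finite(out$mut_rank) | !is.finite(out$wt_rank) |
    out$mut_rank <= 0 | out$mut_rank > 100 | out$wt_rank <= 0 |
    out$wt_rank > 100
  if (any(bad))
    abort(paste0("predictor failed on peptide(s): ",
                 paste(utils::head(unique(out$sequence[bad]), 5),
                       collapse = ", ")))
  out
}

#' Tier a candidate peptide from its mutant and wild-type ranks
#'
#' Nested rule on IEDB-style percentile ranks (lower = stronger binding).
#' MHC-I: a potential binder has mutant rank <= 2 and wild-type rank > 2;
#' among potential binders, mutant rank <= 1 is `high`, otherwise
#' `intermediate`. MHC-II uses thresholds 10 (potential) and 5 (high).
#' Anything else is `non_binder`; boundaries follow the <= / > wording
#' exactly, so e.g. mutant rank 2.0 with wild-type rank 2.0 is a non-binder
#' for class I.
#'
#' @param mut_rank,wt_rank Percentile ranks in `(0, 100]` (vectorized).
#' @param mhc_class `"I"` or `"II"` (scalar or vector).
#' @return Character vector: `"non_binder"`, `"intermediate"` or `"high"`.
#' @examples
#' classify_binder(0.5, 3, "I")   # high
#' classify_binder(1.5, 3, "I")   # intermediate
#' classify_binder(0.5, 1.5, "I") # non_binder: wild type also binds
#' @export
classify_binder <- function(mut_rank, wt_rank, mhc_class) {
  n <- max(length(mut_rank), length(wt_rank), length(mhc_class))
  mut_rank <- rep_len(mut_rank, n)
  wt_rank <- rep_len(wt_rank, n)
  mhc_class <- rep_len(mhc_class, n)
  if (any(mut_rank <= 0 | mut_rank > 100 | wt_rank <= 0 | wt_rank > 100))
    abort("percentile ranks must lie in (0, 100]")
  if (!all(mhc_class %in% c("I", "II"))) abort("`mhc_class` must be I or II")
  pot_thr <- ifelse(mhc_class == "I", 2, 10)
  high_thr <- ifelse(mhc_class == "I", 1, 5)
  potential <- mut_rank <= pot_thr & wt_rank > pot_thr
  ifelse(!potential, "non_binder",
         ifelse(mut_rank <= high_thr, "high", "intermediate"))
}

#' Trapezoidal area under an extracted-ion chromatogram
#'
#' @param time,intensity Numeric vectors (>= 2 points); negative intensities
#'   error, unsorted times are sorted with a warning.
#' @return The trapezoidal integral.
#' @examples
#' auc_trapezoid(c(0, 1, 2), c(0, 4, 0)) # 4
#' @export
auc_trapezoid <- function(time, intensity) {
  stopifnot(length(time) == length(intensity))
  if (length(time) < 2) abort("need at least 2 chromatogram points")
  if (any(intensity < 0)) abort("negative intensity in chromatogram")
  if (is.unsorted(time)) {
    warn("chromatogram times unsorted; sorting")
    o <- order(time)
    time <- time[o]
    intensity <- intensity[o]
  }
  sum(diff(time) * (utils::head(intensity, -1) + utils::tail(intensity, -1)) / 2)
}

#' Quantify detected peptide peaks
#'
#' Accepts either precomputed AUC rows (`peptide`, `sample_id`, `auc`) or long
#' chromatogram rows (`peptide`, `sample_id`, `time`, `intensity`), which are
#' integrated by [auc_trapezoid()] per (peptide, sample).
#'
#' @param peaks A tibble in either of the two layouts.
#' @return A tibble `peptide`, `sample_id`, `auc`.
#' @export
quantify_abundance <- function(peaks) {
  if ("auc" %in% names(peaks)) {
    if (any(peaks$auc < 0)) abort("negative AUC")
    return(select(peaks, "peptide", "sample_id", "auc"))
  }
  if (!all(c("time", "intensity") %in% names(peaks)))
    abort("peaks need either `auc` or `time` + `intensity` columns")
  peaks |>
    group_by(.data$peptide, .data$sample_id) |>
    summarise(auc = auc_trapezoid(.data$time, .data$intensity),
              .groups = "drop")
}

#' Fraction-of-total (iFOT) normalization of peak areas within each sample
#'
#' Each peak's AUC is divided by the summed AUC of all peaks in that sample
#' and multiplied by `scale` (default 1e5), so iFOT values in a sample sum to
#' the scale factor.
#'
#' @param peak_aucs Tibble `peptide`, `sample_id`, `auc`.
#' @param scale Scale factor, default `1e5`.
#' @return The input with an `ifot` column.
#' @export
ifot_normalize <- function(peak_aucs, scale = 1e5) {
  peak_aucs |>
    group_by(.data$sample_id) |>
    mutate(ifot = .data$auc / sum(.data$auc) * scale) |>
    ungroup()
}

patient_class_alleles <- function(hla_types, patient, mhc_class) {
  loci <- if (mhc_class == "I") class_i_loci() else class_ii_loci()
  unique(hla_types$allele[hla_types$patient_id == patient &
                            hla_types$locus %in% loci])
}

#' Call neoantigens from detected peptide peaks and patient HLA types
#'
#' A detected mutated peptide is first assigned to its parent mutation: its
#' sequence must occur within the mutation's 29-residue mutant window at a
#' position spanning the mutated residue (unmatched peptides are logged as
#' unassigned). For each (mutation, MHC class, sample), the mutation becomes a
#' neoantigen call iff at least one mutation-spanning candidate peptide of
#' legal class length from the window is tiered `intermediate` or `high`
#' (configurable to `high` only) on at least one of the patient's typed
#' alleles of that class. Each call carries the best tier, the supporting
#' alleles, and the detected peptide's AUC — attributed once per mutation, not
#' per sub-peptide, so the average-abundance metric does not double count.
#'
#' @param peaks Tibble `peptide`, `sample_id`, `auc` (see
#'   [quantify_abundance()]).
#' @param hla_types Tibble `patient_id`, `locus`, `allele`; patient ids must
#'   match sample ids.
#' @param mutation_db Missense-mutation tibble (see [build_mutation_db()]).
#' @param proteins Tibble `accession`, `sequence` of reference proteins.
#' @param predictor Percentile-rank predictor function (see
#'   [toy_rank_predictor()]).
#' @param tier `"potential"` (intermediate + high, default) or `"high"`.
#' @return A tibble of calls: `sample_id`, `gene`, `accession`, `position`,
#'   `wt_aa`, `mut_aa`, `peptide`, `auc`, `mhc_class`, `best_tier`,
#'   `alleles` (semicolon-separated supporting alleles).
#' @export
call_neoantigens <- function(peaks, hla_types, mutation_db, proteins,
                             predictor, tier = c("potential", "high")) {
  tier <- match.arg(tier)
  windows <- purrr::map(seq_len(nrow(mutation_db)), function(i) {
    seq <- proteins$sequence[match(mutation_db$accession[i],
                                   proteins$accession)]
    if (is.na(seq)) return(NULL)
    make_peptide_window(seq, mutation_db[i, ])
  })

  # peptide -> mutation assignment: occurrence in a window spanning the site
  match_mutations <- function(pep) {
    which(vapply(windows, function(w) {
      if (is.null(w)) return(FALSE)
      hits <- gregexpr(pep, w$sequence, fixed = TRUE)[[1]]
      if (hits[1] == -1) return(FALSE)
      any(hits <= w$mutation_offset &
            hits + nchar(pep) - 1 >= w$mutation_offset)
    }, logical(1)))
  }

  uniq_pep <- unique(peaks$peptide)
  assign_map <- purrr::map(uniq_pep, match_mutations)
  names(assign_map) <- uniq_pep
  unassigned <- uniq_pep[lengths(assign_map) == 0]
  if (length(unassigned))
    inform(sprintf("%d detected peptide(s) unassigned to any mutation window",
                   length(unassigned)))

  # tier candidates per mutation x class x allele (cached across samples)
  tier_cache <- new.env(parent = emptyenv())
  best_tier_for <- function(mut_i, cls, alleles) {
    if (!length(alleles)) return(NULL)
    key <- paste(mut_i, cls, paste(sort(alleles), collapse = ","))
    if (!is.null(tier_cache[[key]])) return(tier_cache[[key]])
    cands <- enumerate_candidates(windows[[mut_i]], cls)
    res <- if (!nrow(cands)) {
      list(best = "non_binder", alleles = character())
    } else {
      ranked <- predict_ranks(cands, alleles, predictor)
      ranked$tier <- classify_binder(ranked$mut_rank, ranked$wt_rank, cls)
      keep <- if (tier == "high") ranked$tier == "high" else
        ranked$tier != "non_binder"
      if (!any(keep)) {
        list(best = "non_binder", alleles = character())
      } else {
        best <- if (any(ranked$tier[keep] == "high")) "high" else "intermediate"
        list(best = best, alleles = sort(unique(ranked$allele[keep])))
      }
    }
    tier_cache[[key]] <- res
    res
  }

  calls <- purrr::map_dfr(seq_len(nrow(peaks)), function(r) {
    pep <- peaks$peptide[r]
    sid <- peaks$sample_id[r]
    muts <- assign_map[[pep]]
    if (!length(muts)) return(tibble())
    purrr::map_dfr(muts, function(mi) {
      purrr::map_dfr(c("I", "II"), function(cls) {
        alle <- patient_class_alleles(hla_types, sid, cls)
        res <- best_tier_for(mi, cls, alle)
        if (is.null(res) || res$best == "non_binder") return(tibble())
        tibble(sample_id = sid,
               gene = mutation_db$gene[mi],
               accession = mutation_db$accession[mi],
               position = mutation_db$position[mi],
               wt_aa = mutation_db$wt_aa[mi],
               mut_aa = mutation_db$mut_aa[mi],
               peptide = pep, auc = peaks$auc[r],
               mhc_class = cls, best_tier = res$best,
               alleles = paste(res$alleles, collapse = ";"))
      })
    })
  })
  if (!nrow(calls)) return(calls)
  # one call per (mutation, class, sample): keep the highest-AUC peak
  calls |>
    group_by(.data$sample_id, .data$accession, .data$position,
             .data$mut_aa, .data$mhc_class) |>
    arrange(dplyr::desc(.data$auc), .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    arrange(.data$sample_id, .data$accession, .data$position, .data$mhc_class)
}

#' Average neoantigen abundance per sample and MHC class
#'
#' The sum of the AUC values of a sample's neoantigen calls divided by the
#' number of calls, per MHC class. Samples with zero calls for a class are
#' reported as missing with a warning.
#'
#' @param calls Neoantigen-call tibble from [call_neoantigens()].
#' @param samples Optional sample ids to report (defaults to those in
#'   `calls`); samples without calls get `NA`.
#' @return A tibble `sample_id`, `mhc_class`, `n_neoantigens`, `mean_auc`.
#' @export
average_neoantigen_abundance <- function(calls, samples = NULL) {
  samples <- samples %||% unique(calls$sample_id)
  out <- calls |>
    group_by(.data$sample_id, .data$mhc_class) |>
    summarise(n_neoantigens = n(), mean_auc = mean(.data$auc),
              .groups = "drop") |>
    tidyr::complete(sample_id = samples, mhc_class = c("I", "II"),
                    fill = list(n_neoantigens = 0L, mean_auc = NA_real_))
  if (any(out$n_neoantigens == 0))
    warn("some sample/class combinations have zero neoantigen calls; mean AUC reported as NA")
  out
}

#' Per-locus and per-class MHC protein expression
#'
#' Collects iFOT protein quantification for the classical MHC loci: class I =
#' HLA-A, -B, -C; class II = HLA-DRB1/B3/B4/B5, -DQA1, -DQB1, -DPA1, -DPB1.
#' Unknown locus symbols are ignored with a log message; loci absent for a
#' sample count as 0.
#'
#' @param quant Tibble `sample_id`, `locus` (gene symbol), `ifot`.
#' @return A list: `per_locus` (`sample_id`, `locus`, `mhc_class`, `ifot`)
#'   and `totals` (`sample_id`, `mhc_class`, `total_ifot`).
#' @export
mhc_protein_expression <- function(quant) {
  known <- c(class_i_loci(), class_ii_loci())
  unknown <- setdiff(unique(quant$locus), known)
  if (length(unknown))
    inform(sprintf("ignoring %d non-MHC locus symbol(s)", length(unknown)))
  per_locus <- quant |>
    filter(.data$locus %in% known) |>
    mutate(mhc_class = ifelse(.data$locus %in% class_i_loci(), "I", "II")) |>
    tidyr::complete(sample_id = unique(quant$sample_id), locus = known,
                    fill = list(ifot = 0)) |>
    mutate(mhc_class = ifelse(.data$locus %in% class_i_loci(), "I", "II")) |>
    select("sample_id", "locus", "mhc_class", "ifot")
  totals <- per_locus |>
    group_by(.data$sample_id, .data$mhc_class) |>
    summarise(total_ifot = sum(.data$ifot), .groups = "drop")
  list(per_locus = per_locus, totals = totals)
}

allele_locus <- function(allele) sub("\\*.*$", "", allele)

#' Neoantigen abundance vs MHC expression concordance analysis
#'
#' Pairs every neoantigen call with the expression of the MHC locus of each
#' supporting allele, splits abundance and expression at the cohort medians,
#' and tests whether high-abundance/high-expression pairs are enriched in one
#' subtype with a two-tailed chi-square test on the 2x2 table
#' (subtype x high/high vs other).
#'
#' @param calls Neoantigen-call tibble.
#' @param mhc_expression `per_locus` tibble from [mhc_protein_expression()].
#' @param subtypes Tibble `sample_id`, `subtype`.
#' @param split_quantile Quantile for the high/low splits, default 0.5
#'   (median).
#' @return A list of class `"concordance_result"`: `pairs` (one row per
#'   call-locus pair with `high_abundance`, `high_expression`, `high_high`),
#'   `table` (2x2 counts), `statistic`, `p_value`.
#' @export
concordance_analysis <- function(calls, mhc_expression, subtypes,
                                 split_quantile = 0.5) {
  if (any(table(subtypes$subtype) < 2) || length(unique(subtypes$subtype)) < 2)
    abort("need at least 2 samples per subtype")
  pairs <- calls |>
    tidyr::separate_longer_delim("alleles", ";") |>
    rename(allele = "alleles") |>
    mutate(locus = allele_locus(.data$allele)) |>
    inner_join(mhc_expression, by = c("sample_id", "locus", "mhc_class")) |>
    inner_join(subtypes, by = "sample_id")
  if (!nrow(pairs)) abort("no call-locus pairs to analyze")
  a_cut <- stats::quantile(pairs$auc, split_quantile, names = FALSE)
  e_cut <- stats::quantile(pairs$ifot, split_quantile, names = FALSE)
  pairs <- pairs |>
    mutate(high_abundance = .data$auc > a_cut,
           high_expression = .data$ifot > e_cut,
           high_high = .data$high_abundance & .data$high_expression)
  tab <- table(factor(pairs$subtype, levels = c("I", "II")),
               factor(pairs$high_high, levels = c(TRUE, FALSE),
                      labels = c("high_high", "other")))
  test <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(pairs = pairs, table = tab,
                 statistic = unname(test$statistic),
                 p_value = test$p.value),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("<concordance_result>\n")
  print(x$table)
  cat(sprintf("chi-square = %.4g, p = %.4g\n", x$statistic, x$p_value))
  invisible(x)
}
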