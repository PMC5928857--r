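test_that("mutation database parsing, deduplication and filtering", {
  src1 <- tibble::tibble(gene = c("BAP1", "NF2", "SETD2"),
                         protein_change = c("p.N645K", "p.E166V", "p.L10L"),
                         source = "cohortA")
  src2 <- tibble::tibble(gene = c("BAP1", "TP53"),
                         protein_change = c("p.N645K", "bad_string"),
                         source = "cohortB")
  expect_message(db <- build_mutation_db(list(src1, src2)), "dropped 2")
  expect_identical(nrow(db), 2L)
  bap1 <- db[db$gene == "BAP1", ]
  expect_identical(bap1$wt_aa, "N")
  expect_identical(bap1$position, 645L)
  expect_identical(bap1$mut_aa, "K")
  expect_identical(bap1$source, "cohortA;cohortB")
})

test_that("peptide windows are centered, clipped and substituted", {
  prot <- paste(rep(c("A", "C", "D", "E", "G"), 12), collapse = "") # 60-mer
  mut <- list(gene = "g", accession = "p", position = 15L,
              wt_aa = substr(prot, 15, 15), mut_aa = "W")
  w <- make_peptide_window(prot, mut)
  expect_identical(nchar(w$sequence), 29L)
  expect_identical(w$mutation_offset, 15L)
  expect_identical(substr(w$sequence, 15, 15), "W")
  # flanks equal the reference
  expect_identical(substr(w$sequence, 1, 14), substr(prot, 1, 14))
  expect_identical(substr(w$sequence, 16, 29), substr(prot, 16, 29))

  mut5 <- list(gene = "g", accession = "p", position = 5L,
               wt_aa = substr(prot, 5, 5), mut_aa = "W")
  w5 <- make_peptide_window(prot, mut5)
  expect_identical(nchar(w5$sequence), 19L) # residues 1..19
  expect_identical(w5$mutation_offset, 5L)

  bad <- list(gene = "g", accession = "p", position = 15L,
              wt_aa = "W", mut_aa = "Y")
  expect_error(make_peptide_window(prot, bad), "reference inconsistency")
})

test_that("candidate enumeration matches brute force, incl. clipped windows", {
  # distinct residues avoid duplicate-sequence collapse
  w29 <- make_peptide_window(
    paste(c(AA_29 <- strsplit("ACDEFGHIKLMNPQRSTVWYACDEFGHIK", "")[[1]]),
          collapse = ""),
    list(gene = "g", accession = "p", position = 15L,
         wt_aa = "R", mut_aa = "W"))
  expect_identical(nrow(enumerate_candidates(w29, "I")), 77L)
  expect_identical(nrow(enumerate_candidates(w29, "II")), 15L)
  cands_i <- enumerate_candidates(w29, "I")
  expect_identical(sum(cands_i$length == 8), 8L)
  # mutation present in every candidate at the recorded offset
  expect_true(all(substr(cands_i$sequence, cands_i$mut_offset,
                         cands_i$mut_offset) == "W"))

  # clipped window, 8-mers: 5 candidates
  w19 <- structure(list(sequence = "ACDEFGHIKLMNPQRSTVW",
                        mutation_offset = 5L,
                        mutation = list(gene = "g", accession = "p",
                                        position = 5L, wt_aa = "Y",
                                        mut_aa = "F")),
                   class = "peptide_window")
  e8 <- dplyr::filter(enumerate_candidates(w19, "I"), length == 8)
  expect_identical(nrow(e8), 5L)

  # a window below the minimum length yields nothing, with a warning
  tiny <- structure(list(sequence = "ACDEFG", mutation_offset = 3L,
                         mutation = list(gene = "g", accession = "p",
                                         position = 3L, wt_aa = "D",
                                         mut_aa = "E")),
                    class = "peptide_window")
  expect_warning(none <- enumerate_candidates(tiny, "I"), "shorter")
  expect_identical(nrow(none), 0L)

  # property: equality with the brute-force oracle on random windows
  set.seed(6)
  for (i in 1:60) {
    L <- sample(6:29, 1)
    seq <- paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
    off <- sample.int(L, 1)
    wr <- structure(list(sequence = seq, mutation_offset = off,
                         mutation = list(gene = "g", accession = "p",
                                         position = off,
                                         wt_aa = "A", mut_aa = "C")),
                    class = "peptide_window")
    for (cls in c("I", "II")) {
      lens <- if (cls == "I") 8:14 else 15L
      got <- suppressWarnings(enumerate_candidates(wr, cls))
      expect_setequal(paste(got$sequence, got$length),
                      oracle_enumerate(seq, off, lens))
    }
  }
})

test_that("binder tiers follow the nested percentile-rank rules exactly", {
  expect_identical(classify_binder(0.5, 3.0, "I"), "high")
  expect_identical(classify_binder(1.5, 3.0, "I"), "intermediate")
  expect_identical(classify_binder(0.5, 1.5, "I"), "non_binder")
  expect_identical(classify_binder(4, 12, "II"), "high")
  expect_identical(classify_binder(8, 12, "II"), "intermediate")
  expect_identical(classify_binder(4, 8, "II"), "non_binder")
  # boundaries per the <= / > wording
  expect_identical(classify_binder(2.0, 2.0, "I"), "non_binder")
  expect_identical(classify_binder(2.0, 2.0001, "I"), "intermediate")
  expect_identical(classify_binder(1.0, 2.5, "I"), "high")
  expect_identical(classify_binder(10, 10, "II"), "non_binder")
  expect_identical(classify_binder(5.0, 10.5, "II"), "high")
  expect_error(classify_binder(0, 50, "I"), "\\(0, 100\\]")
  expect_error(classify_binder(50, 101, "I"), "\\(0, 100\\]")
  expect_error(classify_binder(1, 50, "III"), "I or II")

  # tier lattice: lowering the mutant rank never demotes the tier
  lvl <- c(non_binder = 0, intermediate = 1, high = 2)
  set.seed(7)
  for (i in 1:200) {
    wt <- runif(1, 0.01, 100)
    cls <- sample(c("I", "II"), 1)
    m <- sort(runif(2, 0.01, 100), decreasing = TRUE)
    t_hi <- lvl[classify_binder(m[1], wt, cls)]
    t_lo <- lvl[classify_binder(m[2], wt, cls)]
    expect_gte(t_lo, t_hi)
  }
})

test_that("rank prediction reverts the wild type and honours planting", {
  w <- make_peptide_window("ACDEFGHIKLMNPQRSTVWY",
                           list(gene = "g", accession = "p", position = 10L,
                                wt_aa = "L", mut_aa = "W"))
  cands <- enumerate_candidates(w, "I")
  planted <- tibble::tibble(peptide = cands$sequence[1],
                            allele = "HLA-A*02:01", rank = 0.4)
  pred <- toy_rank_predictor(planted)
  ranked <- predict_ranks(cands, c("HLA-A*02:01", "HLA-B*07:02"), pred)
  # WT reversion reproduces the reference: re-substituting the mutant
  # residue at the recorded offset recovers the mutant candidate
  expect_true(all(substr(ranked$wt_sequence, ranked$mut_offset,
                         ranked$mut_offset) == "L"))
  back <- ranked$wt_sequence
  substr(back, ranked$mut_offset, ranked$mut_offset) <- "W"
  expect_identical(back, ranked$sequence)
  # planted pair gets its rank; everything else sits above the floor
  hit <- ranked$sequence == planted$peptide & ranked$allele == planted$allele
  expect_equal(ranked$mut_rank[hit], 0.4)
  expect_true(all(ranked$mut_rank[!hit] > 10))
  expect_true(all(ranked$wt_rank > 10))
  # determinism
  ranked2 <- predict_ranks(cands, c("HLA-A*02:01", "HLA-B*07:02"), pred)
  expect_identical(ranked, ranked2)
  expect_error(predict_ranks(cands, "HLA-A*02:01",
                             function(p, a) rep(NA_real_, length(p))),
               "predictor failed")
})

test_that("chromatogram AUC matches analytic integrals", {
  expect_equal(auc_trapezoid(c(0, 3), c(2, 2)), 6)
  expect_equal(auc_trapezoid(c(0, 1, 2), c(0, 4, 0)), 4)
  expect_warning(a <- auc_trapezoid(c(2, 0, 1), c(0, 0, 4)), "unsorted")
  expect_equal(a, 4)
  expect_error(auc_trapezoid(c(0, 1), c(-1, 2)), "negative")
  expect_error(auc_trapezoid(1, 2), "at least 2")
  # piecewise-linear analytic oracle
  set.seed(8)
  for (i in 1:20) {
    tt <- sort(runif(6, 0, 10))
    y <- runif(6, 0, 5)
    analytic <- sum(vapply(seq_len(5), function(j) {
      (tt[j + 1] - tt[j]) * (y[j] + y[j + 1]) / 2
    }, numeric(1)))
    expect_equal(auc_trapezoid(tt, y), analytic, tolerance = 1e-12)
  }
  long <- tibble::tibble(peptide = rep("PEP", 3), sample_id = "s1",
                         time = c(0, 1, 2), intensity = c(0, 4, 0))
  expect_equal(quantify_abundance(long)$auc, 4)
})

test_that("iFOT normalization sums to the scale factor per sample", {
  pk <- tibble::tibble(peptide = c("A", "B"), sample_id = "s1",
                       auc = c(1, 3))
  out <- ifot_normalize(pk)
  expect_equal(out$ifot, c(2.5e4, 7.5e4))
  set.seed(9)
  pk2 <- tibble::tibble(peptide = sprintf("P%d", 1:30),
                        sample_id = rep(c("a", "b", "c"), 10),
                        auc = rlnorm(30))
  sums <- tapply(ifot_normalize(pk2)$ifot, pk2$sample_id, sum)
  expect_equal(as.vector(sums), rep(1e5, 3), tolerance = 1e-6)
})

test_that("neoantigen calls recover the planted ground truth exactly", {
  co <- tiny_cohort(seed = 101)
  pred <- toy_rank_predictor(co$planted_ranks)
  peaks <- quantify_abundance(co$peptide_peaks)
  calls <- call_neoantigens(peaks, co$hla_types, co$mutation_catalog,
                            co$proteins, pred)
  key <- function(d) sort(paste(d$sample_id, d$accession, d$position,
                                d$mhc_class))
  expect_identical(key(calls), key(co$call_truth))
  expect_true(all(calls$best_tier != "non_binder"))
  # supporting alleles belong to the patient's typing
  for (r in sample.int(nrow(calls), min(10, nrow(calls)))) {
    alle <- strsplit(calls$alleles[r], ";")[[1]]
    typed <- co$hla_types$allele[co$hla_types$patient_id == calls$sample_id[r]]
    expect_true(all(alle %in% typed))
  }
})

test_that("calls respect allele restriction monotonically", {
  co <- tiny_cohort(seed = 111)
  pred <- toy_rank_predictor(co$planted_ranks)
  peaks <- quantify_abundance(co$peptide_peaks)
  full <- call_neoantigens(peaks, co$hla_types, co$mutation_catalog,
                           co$proteins, pred)
  # drop all class-II typing: class-II calls vanish, class-I unchanged
  hla_i <- dplyr::filter(co$hla_types,
                         locus %in% c("HLA-A", "HLA-B", "HLA-C"))
  sub <- call_neoantigens(peaks, hla_i, co$mutation_catalog,
                          co$proteins, pred)
  expect_identical(sum(sub$mhc_class == "II"), 0L)
  key <- function(d) paste(d$sample_id, d$accession, d$position, d$mhc_class)
  expect_true(all(key(sub) %in% key(full)))
  # replacing the typing with binder-free alleles kills every call
  none <- dplyr::mutate(co$hla_types, allele = "HLA-A*99:99")
  expect_identical(nrow(call_neoantigens(peaks, none, co$mutation_catalog,
                                         co$proteins, pred)), 0L)
})

test_that("average abundance is the AUC mean and scales linearly", {
  calls <- tibble::tibble(sample_id = "s1", mhc_class = "I",
                          auc = c(2, 4, 6))
  out <- suppressWarnings(average_neoantigen_abundance(calls, samples = "s1"))
  expect_equal(out$mean_auc[out$mhc_class == "I"], 4)
  expect_identical(out$n_neoantigens[out$mhc_class == "I"], 3L)
  expect_warning(miss <- average_neoantigen_abundance(calls,
                                                      samples = c("s1", "s2")),
                 "zero neoantigen calls")
  expect_true(is.na(miss$mean_auc[miss$sample_id == "s2" &
                                    miss$mhc_class == "I"]))
  scaled <- dplyr::mutate(calls, auc = auc * 7)
  expect_equal(
    suppressWarnings(average_neoantigen_abundance(scaled, "s1"))$mean_auc[1],
    4 * 7)
})

test_that("MHC expression totals sum the class loci", {
  q <- tibble::tibble(sample_id = "s1", locus = "HLA-A", ifot = 12)
  out <- mhc_protein_expression(q)
  expect_equal(out$totals$total_ifot[out$totals$mhc_class == "I"], 12)
  expect_equal(out$totals$total_ifot[out$totals$mhc_class == "II"], 0)
  set.seed(10)
  loci <- c("HLA-A", "HLA-B", "HLA-C", "HLA-DRB1", "HLA-DQB1", "RPL13")
  q2 <- tibble::tibble(sample_id = "s2", locus = loci, ifot = runif(6, 1, 9))
  expect_message(out2 <- mhc_protein_expression(q2), "non-MHC")
  tot_i <- sum(q2$ifot[q2$locus %in% c("HLA-A", "HLA-B", "HLA-C")])
  expect_equal(out2$totals$total_ifot[out2$totals$sample_id == "s2" &
                                        out2$totals$mhc_class == "I"], tot_i)
})

test_that("concordance chi-square matches the textbook 2x2 formula", {
  co <- tiny_cohort(seed = 121)
  pred <- toy_rank_predictor(co$planted_ranks)
  calls <- call_neoantigens(quantify_abundance(co$peptide_peaks),
                            co$hla_types, co$mutation_catalog, co$proteins,
                            pred)
  mhc <- mhc_protein_expression(co$mhc_quant)
  res <- concordance_analysis(calls, mhc$per_locus, co$truth)
  expect_equal(res$statistic, oracle_chisq_2x2(res$table), tolerance = 1e-9)
  expect_identical(sum(res$table), nrow(res$pairs))
  expect_error(concordance_analysis(calls, mhc$per_locus,
                                    co$truth[1:2, ]), "2 samples")
})
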