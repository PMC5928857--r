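expr_matrix <- function(expr) {
  x <- as.matrix(expr[, setdiff(names(expr), "gene"), drop = FALSE])
  rownames(x) <- toupper(expr$gene)
  x
}

#' Per-gene differential expression between two groups
#'
#' Two-sample, two-tailed Welch t test per gene (unequal variances; robust at
#' the small per-group sizes this design targets). Raw p values are reported
#' with a Benjamini-Hochberg column alongside. Genes with zero variance in
#' both groups get `statistic = NA`, `p_value = 1` and a `degenerate` flag.
#'
#' @param expr Expression tibble: `gene` column plus one column per sample.
#' @param groups Tibble `sample_id`, `group` with exactly two groups and at
#'   least two samples each; the difference is first group minus second,
#'   groups ordered by factor level or alphabetically (so subtype `"I"`
#'   minus `"II"`), independent of row order.
#' @return A tibble `gene`, `mean_diff`, `statistic`, `df`, `p_value`,
#'   `p_adj`, `degenerate`.
#' @export
differential_features <- function(expr, groups) {
  x <- expr_matrix(expr)
  lev <- if (is.factor(groups$group)) levels(groups$group) else
    sort(unique(groups$group))
  if (length(lev) != 2) abort("`groups` must contain exactly two groups")
  ga <- groups$sample_id[groups$group == lev[1]]
  gb <- groups$sample_id[groups$group == lev[2]]
  if (length(ga) < 2 || length(gb) < 2)
    abort("need at least 2 samples per group")
  if (!all(c(ga, gb) %in% colnames(x)))
    abort("group samples missing from the expression matrix")
  xa <- x[, ga, drop = FALSE]
  xb <- x[, gb, drop = FALSE]
  na <- length(ga)
  nb <- length(gb)
  ma <- rowMeans(xa)
  mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  stat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
  degen <- se2 == 0
  stat[degen] <- NA_real_
  df[degen] <- NA_real_
  p[degen] <- 1
  tibble(gene = rownames(x), mean_diff = unname(ma - mb),
         statistic = unname(stat), df = unname(df), p_value = unname(p),
         p_adj = stats::p.adjust(p, "BH"), degenerate = unname(degen))
}

#' Derive the dual-level TiME signature
#'
#' Signature genes are those differentially expressed between the two
#' subtypes at **both** the mRNA and the protein level (`p_value <
#' p_threshold` in each) with, by default, a concordant direction of change.
#' Per-subtype centroids are the subtype means of the standardized (per-gene
#' z-scored) mRNA expression over the signature genes; subtype I is the
#' good-TiME centroid.
#'
#' @param mrna_stats,protein_stats Results of [differential_features()] on the
#'   mRNA and protein matrices with the same group ordering (subtype I
#'   first).
#' @param mrna The mRNA expression tibble used to build centroids.
#' @param groups Tibble `sample_id`, `group` (subtype `"I"`/`"II"`).
#' @param p_threshold Per-level significance threshold, default 0.05.
#' @param require_concordance Drop genes whose mRNA and protein changes
#'   disagree in sign (default `TRUE`).
#' @return A list of class `"time_signature"`: `genes` (gene, direction, both
#'   levels' statistics), `centroids` (gene, good, bad), `metadata`.
#' @export
derive_signature <- function(mrna_stats, protein_stats, mrna, groups,
                             p_threshold = 0.05, require_concordance = TRUE) {
  joined <- inner_join(mrna_stats, protein_stats, by = "gene",
                       suffix = c("_mrna", "_protein"))
  if (!nrow(joined)) abort("no signature genes: empty gene intersection")
  keep <- joined$p_value_mrna < p_threshold &
    joined$p_value_protein < p_threshold
  if (require_concordance)
    keep <- keep & sign(joined$mean_diff_mrna) == sign(joined$mean_diff_protein) &
      joined$mean_diff_mrna != 0
  sig <- joined[keep, , drop = FALSE]
  if (!nrow(sig)) abort("no signature genes at this threshold")
  genes <- sig |>
    mutate(direction = ifelse(.data$mean_diff_mrna > 0, "up_in_I",
                              "down_in_I")) |>
    select("gene", "direction", "mean_diff_mrna", "statistic_mrna",
           "p_value_mrna", "mean_diff_protein", "statistic_protein",
           "p_value_protein")

  x <- expr_matrix(mrna)[genes$gene, , drop = FALSE]
  z <- t(scale(t(x)))
  lev <- if (is.factor(groups$group)) levels(groups$group) else
    sort(unique(groups$group))
  good <- groups$sample_id[groups$group == lev[1]]
  bad <- groups$sample_id[groups$group == lev[2]]
  centroids <- tibble(
    gene = genes$gene,
    good = rowMeans(z[, good, drop = FALSE]),
    bad = rowMeans(z[, bad, drop = FALSE])
  )
  structure(list(
    genes = genes, centroids = centroids,
    metadata = list(p_threshold = p_threshold,
                    require_concordance = require_concordance,
                    n_good = length(good), n_bad = length(bad),
                    n_candidates = nrow(joined))
  ), class = "time_signature")
}

#' @export
print.time_signature <- function(x, ...) {
  cat("<time_signature> ", nrow(x$genes), " genes (",
      sum(x$genes$direction == "up_in_I"), " up in good-TiME), p < ",
      x$metadata$p_threshold, " at both levels\n", sep = "")
  invisible(x)
}

#' Classify samples as good- or bad-TiME with the signature
#'
#' Nearest-centroid classification: each sample's expression over the
#' available signature genes is standardized per gene across the cohort and
#' correlated (Pearson) with the good and bad centroids. The label is the
#' nearer centroid, ties going to bad-TiME (the conservative call); the
#' continuous score is `cor(good) - cor(bad)`.
#'
#' @param signature A `"time_signature"`.
#' @param expr Expression tibble (`gene` + sample columns); any platform on a
#'   comparable gene universe.
#' @param min_coverage Minimum fraction of signature genes that must be
#'   present, default 0.5.
#' @param alias Optional two-column tibble (`from`, `to`) mapping the
#'   cohort's gene symbols onto the signature's (e.g. mouse to human).
#' @return A tibble `sample_id`, `label` (`"good_TiME"`/`"bad_TiME"`),
#'   `score`, `cor_good`, `cor_bad`.
#' @export
classify_samples <- function(signature, expr, min_coverage = 0.5,
                             alias = NULL) {
  x <- expr_matrix(expr)
  if (!is.null(alias)) {
    hit <- match(rownames(x), toupper(alias$from))
    rownames(x)[!is.na(hit)] <- toupper(alias$to[hit[!is.na(hit)]])
  }
  sig_genes <- signature$centroids$gene
  avail <- intersect(sig_genes, rownames(x))
  if (length(avail) < min_coverage * length(sig_genes)) {
    missing <- setdiff(sig_genes, rownames(x))
    abort(paste0("signature coverage below ", min_coverage, "; missing e.g. ",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  z <- t(scale(t(x[avail, , drop = FALSE])))
  z[!is.finite(z)] <- 0
  cg <- signature$centroids$good[match(avail, sig_genes)]
  cb <- signature$centroids$bad[match(avail, sig_genes)]
  cor_safe <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
    stats::cor(a, b)
  }
  cor_good <- unname(apply(z, 2, cor_safe, b = cg))
  cor_bad <- unname(apply(z, 2, cor_safe, b = cb))
  tibble(sample_id = colnames(z),
         label = ifelse(cor_good > cor_bad, "good_TiME", "bad_TiME"),
         score = cor_good - cor_bad,
         cor_good = cor_good, cor_bad = cor_bad)
}

#' ROC area under the curve from scores and a binary outcome
#'
#' Computed as the Mann-Whitney U statistic divided by `n1 * n0`, with ties
#' counted one half: the probability that a random positive outscores a random
#' negative.
#'
#' @param scores Numeric scores (higher = more positive-like).
#' @param outcome Logical/0-1 outcome; both classes must be present.
#' @return The AUC in `[0, 1]`.
#' @export
evaluate_auc <- function(scores, outcome) {
  outcome <- as.logical(outcome)
  stopifnot(length(scores) == length(outcome))
  n1 <- sum(outcome)
  n0 <- sum(!outcome)
  if (n1 == 0 || n0 == 0) abort("both outcome classes must be present")
  r <- rank(scores)
  (sum(r[outcome]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy time_signature
#' @export
tidy.time_signature <- function(x, ...) {
  left_join(x$genes, x$centroids, by = "gene")
}

#' @method glance time_signature
#' @export
glance.time_signature <- function(x, ...) {
  tibble(n_genes = nrow(x$genes),
         n_up_in_good = sum(x$genes$direction == "up_in_I"),
         n_candidates = x$metadata$n_candidates,
         p_threshold = x$metadata$p_threshold,
         require_concordance = x$metadata$require_concordance)
}
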