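make_events <- function(x, sample_id = "s1") {
  n <- nrow(x)
  tb <- tibble::as_tibble(x)
  tb$sample_id <- rep_len(sample_id, n)
  tb$cell_id <- paste0(tb$sample_id, "_c", seq_len(n))
  tb[, c("sample_id", "cell_id", colnames(x))]
}

test_that("arcsinh transform matches the closed form and guards reuse", {
  ev <- make_events(cbind(m1 = c(0, 5, 10), m2 = c(1, 2, 3)))
  tr <- arcsinh_transform(ev, cofactor = 5)
  expect_equal(tr$m1, asinh(c(0, 1, 2)))
  expect_equal(tr$m1[1], 0)
  expect_error(arcsinh_transform(tr), "twice")
  expect_error(arcsinh_transform(ev, cofactor = 0), "positive")
  # strict monotonicity on random values
  x <- sort(runif(50, 0, 100))
  trx <- arcsinh_transform(make_events(cbind(m = x, m2 = 0)))$m
  expect_true(all(diff(trx) > 0))
})

test_that("downsampling keeps everything at target 1 and enriches rare cells", {
  set.seed(1)
  x <- cbind(m1 = rnorm(300), m2 = rnorm(300))
  ev <- arcsinh_transform(make_events(abs(x)))
  kept <- density_downsample(ev, target_fraction = 1, outlier_quantile = 0)
  expect_identical(nrow(kept), nrow(ev))

  # 99:1 two-blob mixture: the minority fraction must increase
  enriched <- vapply(1:10, function(s) {
    set.seed(s)
    n_maj <- 495; n_min <- 5
    blob <- rbind(cbind(rnorm(n_maj, 0, 0.3), rnorm(n_maj, 0, 0.3)),
                  cbind(rnorm(n_min, 6, 0.3), rnorm(n_min, 6, 0.3)))
    colnames(blob) <- c("m1", "m2")
    ev2 <- make_events(blob)
    attr(ev2, "transformed") <- TRUE
    is_min <- c(rep(FALSE, n_maj), rep(TRUE, n_min))
    down <- density_downsample(ev2, target_fraction = 0.1,
                               outlier_quantile = 0, seed = s)
    kept_min <- mean(down$cell_id %in% ev2$cell_id[is_min])
    kept_min > n_min / (n_maj + n_min)
  }, logical(1))
  expect_true(all(enriched))
})

test_that("downsampling of a sample ignores the other samples and row order", {
  set.seed(2)
  x <- cbind(m1 = rnorm(200), m2 = rnorm(200))
  colnames(x) <- c("m1", "m2")
  ev <- make_events(x, sample_id = rep(c("a", "b"), each = 100))
  attr(ev, "transformed") <- TRUE
  perm <- ev[sample(nrow(ev)), ]
  attr(perm, "transformed") <- TRUE
  d1 <- density_downsample(ev, target_fraction = 0.3, seed = 9)
  d2 <- density_downsample(perm, target_fraction = 0.3, seed = 9)
  expect_setequal(d1$cell_id[d1$sample_id == "a"],
                  d2$cell_id[d2$sample_id == "a"])
  # fewer cells than k: keep all, with a warning
  small <- make_events(cbind(m1 = rnorm(5), m2 = rnorm(5)))
  attr(small, "transformed") <- TRUE
  expect_warning(keep <- density_downsample(small, k = 15), "keeping all")
  expect_identical(nrow(keep), 5L)
})

test_that("clustering recovers separated blobs and conserves fractions", {
  set.seed(3)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
  lab <- rep(1:3, each = 60)
  x <- centers[lab, ] + matrix(rnorm(360, sd = 0.3), ncol = 2)
  colnames(x) <- c("m1", "m2")
  ev <- make_events(x, sample_id = rep(c("a", "b"), 90))
  attr(ev, "transformed") <- TRUE
  sc <- cluster_events(ev, k = 3, seed = 1)
  expect_equal(adjusted_rand_index(sc$assignment$node_id, lab), 1)
  sums <- tapply(sc$fractions$fraction, sc$fractions$sample_id, sum)
  expect_equal(as.vector(sums), rep(1, 2), tolerance = 1e-9)
  # cross-check ARI implementation against mclust on the same partition
  expect_equal(adjusted_rand_index(sc$assignment$node_id, lab),
               mclust::adjustedRandIndex(sc$assignment$node_id, lab))

  one <- cluster_events(ev, k = 1)
  expect_identical(nrow(one$nodes), 1L)
  expect_equal(one$fractions$fraction, rep(1, 2))
  expect_error(cluster_events(ev, k = 1000), "exceeds")
})

test_that("phenotype assignment labels archetype nodes exactly", {
  tmpl <- timeatlas:::phenotype_templates()
  defs <- time_phenotypes()
  markers <- colnames(tmpl)
  # duplicate one archetype to exercise the zero-distance rule
  dup <- tmpl[c(seq_len(nrow(tmpl)), 4), ]
  nodes <- tibble::as_tibble(dup)
  nodes <- dplyr::bind_cols(
    tibble::tibble(node_id = sprintf("N%04d", seq_len(nrow(dup))),
                   n_cells = 10L), nodes)
  sc <- structure(list(nodes = nodes, markers = markers),
                  class = "scaffold_nodes")
  out <- assign_phenotypes(sc, defs)
  expect_identical(out$nodes$phenotype[seq_len(nrow(tmpl))], rownames(tmpl))
  expect_identical(out$nodes$phenotype[nrow(dup)], rownames(tmpl)[4])
  expect_identical(sum(out$nodes$landmark), 15L)
})

test_that("phenotype assignment recovers generated cell identities", {
  cfg <- sim_config(n_samples = 8, cells_per_sample = 250,
                    activation_shift = 3, seed = 13)
  ce <- generate_cell_events(cfg)
  ev <- arcsinh_transform(ce$events)
  sc <- assign_phenotypes(cluster_events(ev, k = 60, seed = 13),
                          strict = FALSE)
  joined <- dplyr::inner_join(sc$assignment, ce$cell_truth,
                              by = c("sample_id", "cell_id"))
  joined <- dplyr::inner_join(joined,
                              sc$nodes[, c("node_id", "phenotype")],
                              by = "node_id")
  expect_gt(mean(joined$phenotype.x == joined$phenotype.y,
                 na.rm = TRUE), 0.9)
})

test_that("scaffold graph weights equal the cosine oracle", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_warning(z <- cosine_similarity(c(0, 0), c(1, 2)), "zero-norm")
  expect_equal(z, 0)
  set.seed(4)
  for (i in 1:20) {
    u <- rnorm(10); v <- rnorm(10)
    expect_equal(cosine_similarity(u, v),
                 sum(u * v) / sqrt(sum(u^2) * sum(v^2)), tolerance = 1e-12)
  }
  nodes <- tibble::tibble(node_id = c("N0001", "N0002", "N0003"),
                          n_cells = 5L, m1 = c(1, 2, 0), m2 = c(0, 0, 3))
  sc <- structure(list(nodes = nodes, markers = c("m1", "m2")),
                  class = "scaffold_nodes")
  g <- build_scaffold_graph(sc, retention_quantile = 0)
  w <- g$edges$weight[g$edges$from == "N0001" & g$edges$to == "N0002"]
  expect_equal(w, 1)
  expect_true(all(g$edges$weight >= -1 & g$edges$weight <= 1))
  expect_true(all(g$edges$from != g$edges$to))
})

test_that("subtyping splits duplicated blocks and is row-order stable", {
  set.seed(5)
  base1 <- runif(30); base2 <- runif(30)
  prof <- rbind(
    t(replicate(4, base1 + rnorm(30, sd = 0.01))),
    t(replicate(4, base2 + rnorm(30, sd = 0.01)))
  )
  fr <- tibble::tibble(
    sample_id = rep(sprintf("s%02d", 1:8), each = 30),
    node_id = rep(sprintf("N%04d", 1:30), 8),
    fraction = as.vector(t(prof / rowSums(prof)))
  )
  st <- suppressWarnings(subtype_samples(fr))
  expect_equal(length(unique(st$subtype[1:4])), 1)
  expect_equal(length(unique(st$subtype[5:8])), 1)
  expect_false(st$subtype[1] == st$subtype[5])

  # orientation is content-based: permuting rows must not flip labels
  phen <- tibble::tibble(node_id = sprintf("N%04d", 1:30),
                         phenotype = c(rep("exhausted_CD8_T", 3),
                                       rep("other", 27)))
  st1 <- subtype_samples(fr, phen)
  st2 <- subtype_samples(fr[sample(nrow(fr)), ], phen)
  expect_identical(st1, st2)

  degenerate <- tibble::tibble(sample_id = rep(sprintf("s%d", 1:4), each = 2),
                               node_id = rep(c("N1", "N2"), 4),
                               fraction = 0.5)
  expect_error(subtype_samples(degenerate), "degenerate")
})

test_that("paired node comparison matches the textbook paired t test", {
  phen <- tibble::tibble(node_id = sprintf("N%d", 1:5), phenotype = "ph")
  fa <- tibble::tibble(node_id = sprintf("N%d", 1:5),
                       fraction = c(0.10, 0.15, 0.22, 0.08, 0.05))
  fb <- tibble::tibble(node_id = sprintf("N%d", 1:5),
                       fraction = c(0.07, 0.16, 0.18, 0.03, 0.02))
  res <- compare_nodes(fa, fb, phen)
  d <- fa$fraction - fb$fraction
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(abs(t_hand), 4, lower.tail = FALSE),
               tolerance = 1e-12)
  # antisymmetry and the identical-groups null
  swapped <- compare_nodes(fb, fa, phen)
  expect_equal(swapped$statistic, -res$statistic)
  expect_equal(swapped$p_value, res$p_value)
  same <- compare_nodes(fa, fa, phen)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # a single-pair phenotype is flagged
  one <- compare_nodes(fa[1, ], fb[1, ], phen[1, ])
  expect_true(one$insufficient_pairs)
  expect_true(is.na(one$statistic))
})

test_that("Z ratios follow the two-feature closed form and invariances", {
  d <- tibble::tibble(sample_id = sprintf("s%d", 1:6),
                      m1 = c(5, 6, 7, 1, 2, 3),
                      m2 = c(1, 2, 3, 5, 6, 7))
  a <- sprintf("s%d", 1:3); b <- sprintf("s%d", 4:6)
  zr <- z_ratio(d, a, b)
  # d = (+c, -c) so the ratios are +-1/sqrt(2)
  expect_equal(zr$z_ratio, c(1, -1) / sqrt(2), tolerance = 1e-12)
  expect_false(any(zr$significant))
  # group swap negates
  expect_equal(z_ratio(d, b, a)$z_ratio, -zr$z_ratio)
  # affine rescaling of a raw feature leaves z-scores unchanged
  d2 <- dplyr::mutate(d, m1 = 100 * m1 - 7)
  expect_equal(z_ratio(d2, a, b)$z_ratio, zr$z_ratio, tolerance = 1e-9)
  # degenerate comparison errors
  d3 <- tibble::tibble(sample_id = d$sample_id, m1 = d$m1, m2 = d$m1)
  expect_error(z_ratio(d3, a, b), "degenerate")
})
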