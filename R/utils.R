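#' @keywords internal
"_PACKAGE"

#' @importFrom rlang %||% .data abort warn inform
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join bind_rows bind_cols across n distinct pull rename
#'   row_number
#' @importFrom tibble tibble as_tibble
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# One Dirichlet draw via normalized gammas.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) g <- g + 1e-12
  g / sum(g)
}

#' Cosine similarity between two numeric vectors
#'
#' Defined as `sum(x * y) / (|x| * |y|)`. If either vector has zero norm the
#' similarity is defined as 0 (with a warning), so degenerate all-zero nodes
#' never poison a similarity graph.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A scalar in `[-1, 1]`.
#' @export
cosine_similarity <- function(x, y) {
  stopifnot(length(x) == length(y))
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    warn("zero-norm vector in cosine similarity; returning 0")
    return(0)
  }
  min(1, max(-1, sum(x * y) / (nx * ny)))
}

#' Adjusted Rand index between two labelings
#'
#' Used to score recovery of planted subtype labels: 1 means identical
#' partitions up to label permutation, 0 is the chance level.
#'
#' @param a,b Vectors of cluster labels over the same items.
#' @return A scalar, at most 1.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Deterministic string hash onto (0, 1]: polynomial rolling hash mod a prime.
# Reproducible across platforms; no external digest dependency.
string_hash_unit <- function(s) {
  p <- 1048573     # prime < 2^20, keeps arithmetic exact in doubles
  mod <- 2147483629 # prime < 2^31
  h <- vapply(s, function(one) {
    codes <- utf8ToInt(one)
    acc <- 7
    for (cc in codes) acc <- (acc * p + cc) %% mod
    acc
  }, numeric(1), USE.NAMES = FALSE)
  (h + 1) / (mod + 1)
}

# Amino-acid alphabet (20 canonical residues).
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

sample_ids <- function(n) sprintf("MPM.%03d", seq_len(n))
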