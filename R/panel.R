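#' The built-in 35-marker mass-cytometry panel
#'
#' A panel of 35 metal-conjugated antibody targets split into lineage markers
#' (used for gating, clustering and phenotype assignment) and activation /
#' checkpoint markers (used for differential activation statistics only,
#' following SPADE practice of clustering on lineage markers).
#'
#' @return A tibble with columns `marker` and `role`
#'   (`"lineage"` or `"activation"`).
#' @export
time_panel <- function() {
  lineage <- c("CD45", "CD3", "CD4", "CD8", "CD25", "FOXP3", "CD127",
               "HLA_DR", "CD14", "CD11c", "CD11b", "CD68", "CD123",
               "CD15", "CD56", "PanCK", "CD200", "Vimentin", "CD24",
               "CD326")
  activation <- c("PD1", "CTLA4", "PD_L1", "ICOS", "CD38", "CXCR4",
                  "CD40", "CD86", "CD27", "CD28", "TIM3", "LAG3",
                  "CD69", "GranzymeB", "Ki67")
  tibble(
    marker = c(lineage, activation),
    role = c(rep("lineage", length(lineage)),
             rep("activation", length(activation)))
  )
}

#' The 15 built-in cellular phenotype definitions
#'
#' Gating-style definitions of the 15 major cellular phenotypes used to anchor
#' the landmark nodes of the scaffold map: T-cell subsets (including partially
#' exhausted PD-1+CTLA-4+CD8+ T cells), myeloid populations, NK cells,
#' neutrophils, cancer cells and stromal populations. Each row is one
#' (phenotype, marker, sign) gate requirement; `+1` requires the marker high,
#' `-1` requires it low.
#'
#' @return A tibble with columns `phenotype`, `marker`, `sign`.
#' @export
time_phenotypes <- function() {
  g <- function(phenotype, pos = character(), neg = character()) {
    tibble(
      phenotype = phenotype,
      marker = c(pos, neg),
      sign = c(rep(1L, length(pos)), rep(-1L, length(neg)))
    )
  }
  bind_rows(
    g("CD4_T",            c("CD45", "CD3", "CD4")),
    g("Treg",             c("CD45", "CD3", "CD4", "CD25", "FOXP3"), "CD127"),
    g("CD8_T",            c("CD45", "CD3", "CD8")),
    g("exhausted_CD8_T",  c("CD45", "CD3", "CD8", "PD1", "CTLA4")),
    g("monocyte",         c("CD45", "HLA_DR", "CD14", "CD11c"), "CD3"),
    g("TAM",              c("CD45", "HLA_DR", "CD68", "CD11b"),
                          c("CD3", "CD11c", "CD123")),
    g("pDC",              c("CD45", "HLA_DR", "CD123"),
                          c("CD3", "CD11c", "CD68")),
    g("cDC",              c("CD45", "HLA_DR", "CD11c"), c("CD3", "CD14")),
    g("neutrophil",       c("CD45", "CD15"), c("CD3", "HLA_DR", "CD56")),
    g("NK",               c("CD45", "CD56"), c("CD3", "HLA_DR", "CD15")),
    g("cancer",           "PanCK", "CD45"),
    g("cancer_stem",      c("CD24", "CD326"),
                          c("CD45", "PanCK", "CD200", "Vimentin")),
    g("CAF",              "Vimentin", c("CD45", "PanCK", "CD200")),
    g("mesothelial",      "CD200", c("CD45", "PanCK", "Vimentin")),
    g("stromal",          character(),
                          c("CD45", "PanCK", "CD200", "Vimentin", "CD24", "CD326"))
  )
}

# Subtype-I-enriched ("good") and subtype-II-enriched ("bad") phenotypes:
# encodes the directionality of the two immunologic subtypes (exhausted CD8 and
# activated pDC up in subtype I; Tregs, neutrophils, suppressive myeloid and
# fibroblasts up in subtype II).
phenotype_tilt <- function() {
  c(CD4_T = 0, Treg = -1, CD8_T = 0, exhausted_CD8_T = 1, monocyte = 0,
    TAM = -1, pDC = 1, cDC = -1, neutrophil = -1, NK = 0, cancer = 1,
    cancer_stem = 0, CAF = -1, mesothelial = 0, stromal = 0)
}

# Activation markers shifted up in subtype I (stimulatory) vs subtype II
# (inhibitory / suppressive axis).
activation_tilt <- function() {
  c(PD1 = 1, CTLA4 = 1, PD_L1 = -1, ICOS = -1, CD38 = 1, CXCR4 = -1,
    CD40 = 1, CD86 = 1, CD27 = 1, CD28 = 1, TIM3 = -1, LAG3 = -1,
    CD69 = 1, GranzymeB = 1, Ki67 = 0)
}
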