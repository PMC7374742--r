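#' Candidate-table fixture: 22 top-bottleneck proteins
#'
#' The published cytoHubba candidate table for the curcumin-rewired
#' interactome: the 22 proteins (21 seed proteins plus the connector RB1)
#' occupying the 10 best distinct bottleneck score levels, with their
#' betweenness, harmonic closeness, clustering coefficient and degree.
#' Bottleneck, clustering coefficient and degree are transcribed for every
#' row; a block of betweenness/closeness cells whose printed digits run
#' together in the source table is carried with `ambiguous = TRUE` and
#' should not be asserted on.
#'
#' @return A data frame with columns `name`, `bottleneck`, `betweenness`,
#'   `closeness`, `clustering_coefficient`, `degree`, `role`, `ambiguous`.
#' @export
table1_fixture <- function() {
  df <- data.frame(
    name = c("CREBBP", "TP53", "RELA", "MAPK1", "NFKB1", "CYP1A1", "SRC",
             "BRCA1", "EDN1", "ATR", "RB1", "SP1", "CASP8", "STAT1",
             "CREB1", "AKT1", "IL8", "CDH1", "KRAS", "SYK", "CCR5", "HDAC3"),
    bottleneck = c(52L, 22L, 14L, 13L, 11L, 10L, 9L, 9L, 9L, 9L, 7L, 7L,
                   6L, 6L, 6L, 5L, 5L, 5L, 5L, 5L, 5L, 5L),
    betweenness = c(13223.35, 7640.317, 4458.032, 4779.75, 3211.738,
                    4831.488, 2899.138, 1537.711, 684.0157, 647.5952,
                    2625.42, 391.5314, 2299.261, 1012.291, 597.4255,
                    2328.794, 2227.319, 1162.138, 917.6512, 796.2624,
                    669.6932, 471.1578),
    closeness = c(155.8333, 148.4167, 149.0833, 146.5, 144.8333, 110.8667,
                  135.6667, 128.1, 123.8333, 124.0667, 142.8333, 130.6667,
                  123.3667, 130.1667, 121.6667, 137.4167, 121.1667, 113.0,
                  120.8333, 123.6667, 108.3667, 124.3333),
    clustering_coefficient = c(0.15837, 0.17639, 0.20863, 0.18316, 0.22304,
                               0.43137, 0.17424, 0.38413, 0.29412, 0.38391,
                               0.29445, 0.34762, 0.41521, 0.36594, 0.30882,
                               0.17094, 0.40582, 0.34848, 0.25692, 0.24265,
                               0.42222, 0.35263),
    degree = c(50L, 38L, 51L, 47L, 44L, 18L, 33L, 36L, 18L, 30L, 38L, 21L,
               9L, 24L, 17L, 27L, 4L, 12L, 23L, 17L, 10L, 20L))
  df$role <- ifelse(df$name == "RB1", "connector", "seed")
  # betweenness/closeness digits for this block run together in print and
  # cannot be segmented with certainty; never assert on these cells
  df$ambiguous <- df$name %in% c("BRCA1", "EDN1", "ATR", "RB1", "SP1", "CDH1")
  df
}

table2_terms <- function() {
  list(
    `KEGG:04137` = list("Mitophagy",
      c("KRAS", "RELA", "SP1", "SRC", "TP53")),
    `R-HSA:10906` = list("Intrinsic pathway for apoptosis",
      c("AKT1", "CASP8", "TP53")),
    `KEGG:05167` = list("Kaposi's sarcoma-associated herpes virus infection",
      c("AKT1", "CASP8", "CCR5", "CREB1", "CREBBP", "CXCL8", "KRAS", "MAPK1",
        "NFKB1", "RB1", "RELA", "SRC", "STAT1", "SYK", "TP53")),
    `KEGG:04210` = list("Apoptosis",
      c("AKT1", "CASP8", "KRAS", "MAPK1", "NFKB1", "RELA", "TP53")),
    `KEGG:04926` = list("Relaxin signalling pathway",
      c("AKT1", "CREB1", "EDN1", "KRAS", "MAPK1", "NFKB1", "RELA", "SRC")),
    `KEGG:05161` = list("Hepatitis B",
      c("AKT1", "CASP8", "CREB1", "CREBBP", "CXCL8", "KRAS", "MAPK1",
        "NFKB1", "RB1", "RELA", "SRC", "STAT1", "TP53")),
    `KEGG:05218` = list("Melanoma",
      c("AKT1", "CDH1", "KRAS", "MAPK1", "RB1", "TP53")),
    `KEGG:04919` = list("Thyroid hormone signalling pathway",
      c("AKT1", "CREBBP", "HDAC3", "KRAS", "MAPK1", "SRC", "STAT1", "TP53")),
    `R-HSA:8940973` = list("RUNX2 regulates osteoblast differentiation",
      c("HDAC3", "MAPK1", "RB1", "SRC")),
    `KEGG:05203` = list("Viral carcinogenesis",
      c("CASP8", "CCR5", "CREB1", "CREBBP", "HDAC3", "KRAS", "MAPK1",
        "NFKB1", "RB1", "RELA", "SRC", "SYK", "TP53")),
    `KEGG:04066` = list("HIF-1 signalling pathway",
      c("AKT1", "CREBBP", "EDN1", "MAPK1", "NFKB1", "RELA")),
    `KEGG:05165` = list("Human papilloma virus infection",
      c("AKT1", "ATR", "CASP8", "CREB1", "CREBBP", "HDAC3", "KRAS", "MAPK1",
        "NFKB1", "RB1", "RELA", "STAT1", "TP53")),
    `KEGG:05212` = list("Pancreatic cancer",
      c("AKT1", "KRAS", "MAPK1", "NFKB1", "RB1", "RELA", "STAT1", "TP53")),
    `R-HSA:8878166` = list("Transcriptional regulation by RUNX2",
      c("AKT1", "HDAC3", "MAPK1", "RB1", "SRC", "STAT1")),
    `KEGG:05215` = list("Prostate cancer",
      c("AKT1", "CREB1", "CREBBP", "KRAS", "MAPK1", "NFKB1", "RB1", "RELA",
        "TP53")),
    `KEGG:04062` = list("Chemokine signalling pathway",
      c("AKT1", "CCR5", "CXCL8", "KRAS", "MAPK1", "NFKB1", "RELA", "SRC",
        "STAT1")),
    `KEGG:05152` = list("Tuberculosis",
      c("AKT1", "CASP8", "CREB1", "CREBBP", "MAPK1", "NFKB1", "RELA", "SRC",
        "STAT1", "SYK")))
}

#' Functional-group fixture: 17 enriched pathway groups
#'
#' The published ClueGO grouping of enriched KEGG/Reactome pathways for the
#' 22 candidate proteins: 17 groups (ids 0 to 16, one pathway each) with
#' their associated genes. Table-of-record note: these lists use CXCL8 as
#' the gene symbol (the candidate table prints the IL8 alias), and neither
#' BRCA1 nor CYP1A1 appears in any group.
#'
#' @return A list of 17 groups, each a list with `group_id`, `term_id`,
#'   `term_name`, `member_terms`, `associated_genes` (sorted).
#' @export
table2_fixture <- function() {
  terms <- table2_terms()
  lapply(seq_along(terms), function(i) {
    list(group_id = i - 1L,
         term_id = names(terms)[i],
         term_name = terms[[i]][[1]],
         member_terms = names(terms)[i],
         associated_genes = sort(terms[[i]][[2]]))
  })
}

#' @rdname table2_fixture
#' @return `table2_annotation()` returns the same 17 pathways as an
#'   [annotation_set] (universe = union of all listed genes).
#' @export
table2_annotation <- function() {
  terms <- table2_terms()
  annotation_set(lapply(terms, `[[`, 2),
                 term_names = stats::setNames(vapply(terms, `[[`, "", 1),
                                              names(terms)))
}

#' The Huang-Ferrell MAPK cascade model
#'
#' In-code transcription of the curated BioModels entry BIOMD0000000009
#' (Huang & Ferrell's ultrasensitive MAPK cascade) as elementary
#' mass-action steps: three kinase tiers (MAPKKK, MAPKK, MAPK/Erk2), each
#' (de)phosphorylation an enzyme-substrate binding equilibrium
#' (a = 1000/(uM s), d = 150/s) followed by irreversible catalysis
#' (k = 150/s). Initial concentrations (uM): MAPKKK 3e-3, MAPKK 1.2,
#' MAPK 1.2, activating enzyme E1 3e-5, deactivator E2 3e-4, MAPKK
#' phosphatase 3e-4, MAPK phosphatase 0.12. The same model ships as an SBML
#' file at `system.file("extdata", "BIOMD0000000009_mapk_cascade.xml",
#' package = "netpharm")`.
#'
#' @return A [kinetic_model] with 22 species and 10 reversible binding plus
#'   10 catalytic reactions.
#' @export
mapk_cascade_model <- function() {
  species <- c(
    MKKK = 3e-3, MKKK_P = 0, MKK = 1.2, MKK_P = 0, MKK_PP = 0,
    MAPK = 1.2, MAPK_P = 0, MAPK_PP = 0,
    E1 = 3e-5, E2 = 3e-4, KKPase = 3e-4, KPase = 0.12,
    E1_KKK = 0, E2_KKKP = 0, KKKP_KK = 0, KKPase_KKP = 0, KKKP_KKP = 0,
    KKPase_KKPP = 0, KKPP_K = 0, KPase_KP = 0, KKPP_KP = 0, KPase_KPP = 0)
  step <- function(id, sub, enz, cx, prod) {
    list(
      list(id = paste0("bind_", id),
           reactants = stats::setNames(c(1L, 1L), c(sub, enz)),
           products = stats::setNames(1L, cx), rate = 1000, reverse_rate = 150),
      list(id = paste0("cat_", id),
           reactants = stats::setNames(1L, cx),
           products = stats::setNames(c(1L, 1L), c(prod, enz)), rate = 150))
  }
  reactions <- c(
    step("1", "MKKK", "E1", "E1_KKK", "MKKK_P"),
    step("2", "MKKK_P", "E2", "E2_KKKP", "MKKK"),
    step("3", "MKK", "MKKK_P", "KKKP_KK", "MKK_P"),
    step("4", "MKK_P", "KKPase", "KKPase_KKP", "MKK"),
    step("5", "MKK_P", "MKKK_P", "KKKP_KKP", "MKK_PP"),
    step("6", "MKK_PP", "KKPase", "KKPase_KKPP", "MKK_P"),
    step("7", "MAPK", "MKK_PP", "KKPP_K", "MAPK_P"),
    step("8", "MAPK_P", "KPase", "KPase_KP", "MAPK"),
    step("9", "MAPK_P", "MKK_PP", "KKPP_KP", "MAPK_PP"),
    step("10", "MAPK_PP", "KPase", "KPase_KPP", "MAPK_P"))
  kinetic_model(species, reactions)
}

#' Export an in-package fixture in its pipeline file format
#'
#' `"table1"` writes the candidate table as a metrics CSV (the
#' [write_metrics_csv()] layout); `"table2"` writes the 17 pathway groups
#' as a GMT file; `"mapk_sbml"` writes the MAPK cascade as SBML level 2.
#'
#' @param which one of `"table1"`, `"table2"`, `"mapk_sbml"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_fixture <- function(which = c("table1", "table2", "mapk_sbml"), path) {
  which <- match.arg(which)
  switch(which,
    table1 = write_metrics_csv(table1_fixture(), path),
    table2 = write_gmt(table2_annotation(), path),
    mapk_sbml = write_sbml(mapk_cascade_model(), path,
                           model_id = "MAPK_cascade"))
  invisible(path)
}
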