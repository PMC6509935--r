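# The built-in FA-CHKREC model: 25 nodes coupling the FA/BRCA interstrand-
# crosslink repair pathway, the G2/M DNA-damage checkpoint and the
# checkpoint-recovery (CHKREC) machinery.  The rules below are stored fully
# parenthesized so grouping never has to be re-derived from typography; two
# rules (CDK1-AurA, CycB-CDK1) are line-wrapped in common transcriptions and
# their canonical grouping — standard precedence NOT > AND > OR applied to
# the printed strings — is fixed here once:
#   CDK1-AurA:  CycB-CDK1 ∨ CDC25 ∨ (¬(p21 ∧ PP2A-B55) ∧ ¬(WEE1 ∨ MYT1 ∨ ATM ∨ ATR))
#   CycB-CDK1:  CycB-CDK1 ∨ ((CDC25 ∧ PLK1 ∧ CDK1-AurA) ∧ ¬p21)
# FANCD2I's self-negation is kept exactly as published even though it forces
# an active FANCD2I to oscillate.

fa_chkrec_lines <- c(
    "ICL <- ICL & !(NUC1 | NUC2)",
    "FAcore <- ICL & !((RNF4 & PLK1) | (FAcore & !ATR))",
    "FANCD2I <- FAcore & (ATM | ATR) & !FANCD2I",
    "NUC1 <- (ICL & FANCD2I) | (DSB & PARP-1)",
    "RNF4 <- ICL & !FAcore",
    "NUC2 <- ICL & RNF4 & PLK1 & !(R-DSB | NUC1)",
    "DSB <- (DSB | (ICL & NUC2)) & !(NHEJ | NUC1)",
    "PARP-1 <- (DSB | R-DSB) & gH2AX & !KU-53BP1",
    "R-DSB <- (R-DSB | ((ICL | DSB) & NUC1)) & !HRR",
    "HRR <- gH2AX & R-DSB & ATM & !(PLK1 & CycB-CDK1)",
    "KU-53BP1 <- DSB & !PARP-1",
    "NHEJ <- KU-53BP1 & DSB & ATM & !(PLK1 & CycB-CDK1)",
    "gH2AX <- (DSB | R-DSB) & (ATM | ATR | gH2AX | KU-53BP1) & !(WIP1 & PP2A-B55)",
    "ATR <- (ICL | ATM) & !(WIP1 | (PLK1 & KU-53BP1))",
    "ATM <- (ATR | DSB | R-DSB | NUC1 | FAcore) & !(WIP1 | PP2A-B55 | (PLK1 & KU-53BP1))",
    "MYT1 <- (ATM | ATR) & !(CDC25 | CycB-CDK1 | PLK1)",
    "WEE1 <- (ATM | ATR | PP2A-B55) & !(CDC25 | CycB-CDK1 | PLK1)",
    "p53 <- (ATM | ATR) & !(WIP1 & (PLK1 | CDK1-AurA))",
    "p21 <- p53",
    "PP2A-B55 <- (ATM | ATR) & !CycB-CDK1",
    "WIP1 <- p53",
    "CDK1-AurA <- CycB-CDK1 | CDC25 | (!(p21 & PP2A-B55) & !(WEE1 | MYT1 | ATM | ATR))",
    "PLK1 <- CycB-CDK1 | (ICL & ATR & !FAcore) | (CDK1-AurA & !(MYT1 | WEE1 | ATR | ATM))",
    "CDC25 <- CycB-CDK1 | (PLK1 & (CycB-CDK1 | CDK1-AurA) & !((WEE1 | MYT1) & (PP2A-B55 | ATM | ATR)))",
    "CycB-CDK1 <- CycB-CDK1 | ((CDC25 & PLK1 & CDK1-AurA) & !p21)")

fa_chkrec_categories <- c(
    ICL = "DNA_damage", DSB = "DNA_damage", "R-DSB" = "DNA_damage",
    FAcore = "DNA_repair", FANCD2I = "DNA_repair", NUC1 = "DNA_repair",
    RNF4 = "DNA_repair", NUC2 = "DNA_repair", "PARP-1" = "DNA_repair",
    HRR = "DNA_repair", "KU-53BP1" = "DNA_repair", NHEJ = "DNA_repair",
    gH2AX = "DNA_repair",
    ATR = "checkpoint", ATM = "checkpoint", MYT1 = "checkpoint",
    WEE1 = "checkpoint", p53 = "checkpoint", p21 = "checkpoint",
    "PP2A-B55" = "checkpoint",
    WIP1 = "CHKREC", "CDK1-AurA" = "CHKREC", PLK1 = "CHKREC",
    CDC25 = "CHKREC", "CycB-CDK1" = "CHKREC")

#' The built-in FA-CHKREC Boolean network
#'
#' Returns the 25-node logical model coupling interstrand-crosslink (ICL)
#' detection and repair by the FA/BRCA pathway, double-strand-break
#' signalling, the ATM/ATR-p53-p21-WEE1-MYT1 G2/M checkpoint, and the
#' checkpoint-recovery kinases and phosphatases (WIP1, PLK1, Aurora A/CDK1,
#' CDC25, Cyclin B/CDK1).  Node order is fixed (ICL first, CycB-CDK1 last)
#' and defines the state encoding.
#'
#' @return a [BooleanNetwork] with node annotations (functional category,
#'   see [nodeCategories()]) and the inferred-interaction table
#'   ([novelInteractions()]) in its metadata.
#' @examples
#' net <- faChkrecNetwork()
#' length(nodes(net))  # 25
#' @export
faChkrecNetwork <- function() {
    net <- parseRules(fa_chkrec_lines, dialect = "unicode")
    net@metadata <- list(
        name = "FA-CHKREC",
        categories = fa_chkrec_categories[net@nodes],
        novelInteractions = novelInteractions())
    validObject(net)
    net
}

#' Functional category of each FA-CHKREC node
#'
#' Nodes group into four functional categories: DNA damage lesions
#' (`DNA_damage`: ICL, DSB, R-DSB), DNA repair machinery (`DNA_repair`),
#' G2/M checkpoint components (`checkpoint`) and checkpoint-recovery
#' components (`CHKREC`).
#'
#' @return named character vector over all 25 nodes.
#' @examples
#' nodeCategories()[["WIP1"]]  # "CHKREC"
#' @export
nodeCategories <- function() fa_chkrec_categories

#' Inferred (previously unreported) regulatory interactions of the model
#'
#' The model contains interactions that had not been described
#' experimentally but are required for it to reproduce the known dynamical
#' behaviour; they implement (1) an alternative, RNF4/PLK1-driven
#' ICL-unhooking route through the NUC2 endonucleases, (2) inactivation of
#' the DNA-repair nodes (HRR, NHEJ) by the mitotic kinases, and (3)
#' inactivation of checkpoint kinases by CHKREC components and KU-53BP1.
#' Twelve edges are directly supported by the accompanying text; three more
#' (the wild-type guards of the alternative unhooking route) are inferred
#' from the circuit description and flagged with lower confidence.  The list
#' is configuration, not hard-coded truth: pass any subset to
#' [removeInteractions()] to ablate it.
#'
#' @return data.frame with columns `source`, `target`,
#'   `sign` (`"positive"`/`"negative"`) and `confidence`
#'   (`"text"`/`"inferred"`).  Every row corresponds to a literal occurrence
#'   of the source inside the target's update rule.
#' @export
novelInteractions <- function() {
    df <- rbind(
        data.frame(source = c("RNF4", "PLK1"), target = "NUC2",
                   sign = "positive", confidence = "text"),
        data.frame(source = c("PLK1", "CycB-CDK1"), target = "HRR",
                   sign = "negative", confidence = "text"),
        data.frame(source = c("PLK1", "CycB-CDK1"), target = "NHEJ",
                   sign = "negative", confidence = "text"),
        data.frame(source = c("PLK1", "KU-53BP1"), target = "ATM",
                   sign = "negative", confidence = "text"),
        data.frame(source = c("PLK1", "KU-53BP1"), target = "ATR",
                   sign = "negative", confidence = "text"),
        data.frame(source = "CycB-CDK1", target = c("MYT1", "WEE1"),
                   sign = "negative", confidence = "text"),
        # wild-type guards of the alternative unhooking route
        data.frame(source = c("R-DSB", "NUC1"), target = "NUC2",
                   sign = "negative", confidence = "inferred"),
        data.frame(source = "FAcore", target = "RNF4",
                   sign = "negative", confidence = "inferred"))
    rownames(df) <- NULL
    df
}
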