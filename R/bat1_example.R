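#' The BAT1 disambiguation example
#'
#' A self-contained reconstruction of the classic BAT1 ambiguity case from
#' abstract PubMed 8081366: the mention "BAT1" carries three candidate
#' EntrezGene identifiers (7919, 10212, 11136 — three distinct genes that
#' all carry "BAT1" among their synonyms), and the abstract's entity
#' context ("human major histocompatibility complex", "MHC", "6p21.3",
#' "BAT1", "TNFB") points to 7919, whose Symbol is BAT1 and whose map
#' location 6p21.3 both occur verbatim in the context. The gene metadata
#' for 7919 (Symbol BAT1, chromosome 6, map location 6p21.3, description
#' "HLA-B associated transcript 1") is the documented EntrezGene record;
#' the records for 10212 (DDX39, 19p13.12) and 11136 (SLC7A9, 19q13.11)
#' are reconstructed from public EntrezGene metadata of the same era.
#'
#' @return List with `candidates` (a candidate set for the mention
#'   "BAT1"), `context` (doc_id + normalized entity strings),
#'   `gene_info` (metadata data frame for the three candidates) and
#'   `doc_id`.
#' @export
#' @examples
#' ex <- bat1_example()
#' disambiguate(ex$candidates, ex$context, ex$gene_info)$gene_id  # "7919"
bat1_example <- function() {
  gene_info <- data.frame(
    gene_id = c("7919", "10212", "11136"),
    symbol = c("BAT1", "DDX39", "SLC7A9"),
    chromosome = c("6", "19", "19"),
    map_location = c("6p21.3", "19p13.12", "19q13.11"),
    description = c(
      "HLA-B associated transcript 1",
      "DEAD (Asp-Glu-Ala-Asp) box polypeptide 39",
      "solute carrier family 7 (cystine transporter), member 9"),
    stringsAsFactors = FALSE)
  rownames(gene_info) <- gene_info$gene_id
  mention <- data.frame(doc_id = "8081366", start = 0L, end = 4L,
                        text = "BAT1", stringsAsFactors = FALSE)
  candidates <- data.frame(
    gene_id = c("7919", "10212", "11136"),
    matched_synonym = "bat1", method = "exact", score = 1,
    stringsAsFactors = FALSE)
  context <- list(
    doc_id = "8081366",
    entities = normalize_term(c("human major histocompatibility complex",
                                "MHC", "6p21.3", "BAT1", "TNFB")))
  list(candidates = list(mention = mention, candidates = candidates),
       context = context, gene_info = gene_info, doc_id = "8081366")
}
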