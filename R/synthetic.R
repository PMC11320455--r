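#' Synthetic base proviral plasmid (C1 stand-in)
#'
#' Generates a 5,575-bp circular scAAV proviral plasmid with the documented
#' architecture: a 2,052-bp ITR-to-ITR insert (mITR, U6 promoter, mi405
#' hairpin, human collagen-intron stuffer, full-length ITR) inside a 3,523-bp
#' backbone carrying KanR, the pMB1 bacterial origin and the F1 phage origin.
#' All sequences (including the ITRs) are random synthetic stand-ins; the
#' published sequences are not redistributed.
#'
#' @param seed Integer seed (fixed default so the shipped construct is stable).
#' @return A [plasmid_construct()] named `"C1"`.
#' @export
synthetic_c1 <- function(seed = 101L) {
  feats <- data.frame(
    label = c("mITR", "U6", "mi405", "collagen_stuffer", "ITR",
               "KanR", "pMB1_Ori", "F1_Ori"),
    role = c("mITR", "promoter", "miRNA", "stuffer", "ITR",
              "resistance", "ori", "ori"),
    start = c(0L, 128L, 377L, 465L, 1907L, 2252L, 3368L, 4368L),
    end   = c(128L, 377L, 465L, 1907L, 2052L, 3068L, 3968L, 4822L),
    strand = c("+", "+", "+", "+", "+", "-", "+", "+"),
    origin = c("viral", "human", "synthetic", "human", "viral",
               "bacterial", "bacterial", "phage"),
    stringsAsFactors = FALSE)
  with_seed(seed, plasmid_construct("C1", random_dna(5575L), feats))
}

#' Synthetic helper references for a packaging run
#'
#' Random stand-ins for the RepCap plasmid, the adenovirus helper plasmid, and
#' a small host-cell decoy (in place of a full human assembly) with a gene
#' annotation table for the gene-overlap operation.
#'
#' @param seed Integer seed.
#' @param repcap_length,phelper_length,host_length Sequence lengths in bp.
#' @param n_genes Number of non-overlapping decoy genes to annotate.
#' @return `list(repcap =, phelper =, host = list(sequence =, genes =))`;
#'   `genes` is a `data.frame(gene_id, start, end)` in 0-based half-open
#'   coordinates.
#' @export
synthetic_reference_panel <- function(seed = 202L, repcap_length = 4400L,
                                      phelper_length = 6000L,
                                      host_length = 20000L, n_genes = 8L) {
  with_seed(seed, {
    repcap <- random_dna(repcap_length)
    phelper <- random_dna(phelper_length)
    host <- random_dna(host_length)
    span <- host_length %/% n_genes
    gs <- (seq_len(n_genes) - 1L) * span
    width <- pmax(200L, as.integer(floor(stats::runif(n_genes, 0.3, 0.8) * span)))
    genes <- data.frame(gene_id = sprintf("gene%02d", seq_len(n_genes)),
                        start = gs, end = pmin(gs + width, host_length),
                        stringsAsFactors = FALSE)
    list(repcap = repcap, phelper = phelper,
         host = list(sequence = host, genes = genes))
  })
}
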