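# small fixture builders shared across test files

# 500-bp proviral plasmid: 200-bp ITR-to-ITR insert + 300-bp backbone
tiny_proviral <- function(seed = 11L) {
  feats <- data.frame(
    label = c("mITR", "U6", "mi405", "ITR", "KanR"),
    role = c("mITR", "promoter", "miRNA", "ITR", "resistance"),
    start = c(0L, 30L, 90L, 170L, 220L),
    end = c(30L, 80L, 120L, 200L, 420L),
    strand = "+",
    origin = c("viral", "human", "synthetic", "viral", "bacterial"),
    stringsAsFactors = FALSE)
  provpack:::with_seed(seed, plasmid_construct("tiny", provpack:::random_dna(500L), feats))
}

# construct whose backbone is 70% human / 30% bacterial by base count
composition_construct <- function(seed = 12L) {
  feats <- data.frame(
    label = c("mITR", "ITR", "human_arm"),
    role = c("mITR", "ITR", "ACTB_intron_arm"),
    start = c(0L, 240L, 300L),
    end = c(60L, 300L, 1000L),
    strand = "+",
    origin = c("viral", "viral", "human"),
    stringsAsFactors = FALSE)
  provpack:::with_seed(seed, plasmid_construct("comp", provpack:::random_dna(1300L), feats))
}

tiny_panel <- function(seed = 13L) {
  synthetic_reference_panel(seed, repcap_length = 1500L,
                            phelper_length = 1500L, host_length = 3000L,
                            n_genes = 3L)
}

# expected category of a construct-derived read from its source interval:
# majority of its bases inside/outside the ITR-to-ITR insert interval
interval_truth <- function(truth, s, e, construct) {
  ie <- insert_interval(construct)[2L]
  L <- length(construct)
  f <- function(x) (x %/% L) * ie + pmin(x %% L, ie)  # insert bases in [0, x)
  nin <- f(e) - f(s)
  out <- truth$category
  ci <- truth$source_ref == "construct"
  w <- (e - s)[ci]
  out[ci] <- ifelse(2L * nin[ci] > w, "insert",
             ifelse(2L * nin[ci] < w, "backbone", "ambiguous"))
  out
}
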