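#' Per-sample reference set for read classification
#'
#' Mirrors the concatenated-reference mapping strategy used for packaged-
#' genome sequencing: the proviral construct (partitioned into the ITR-to-ITR
#' insert and the backbone), the RepCap and helper plasmids, and a host decoy
#' used as fallback for reads that hit nothing else. Classification is
#' alignment-free: reads are scored by exact k-mer seed matches on both
#' strands.
#'
#' @param construct Proviral [plasmid_construct()].
#' @param repcap,phelper,host DNA strings (`host` may also be the `host`
#'   element of [synthetic_reference_panel()]).
#' @param k Seed length (odd, >= 11; default 31).
#' @return An object of class `reference_set` with a prebuilt k-mer index.
#' @export
reference_set <- function(construct, repcap, phelper, host, k = 31L) {
  k <- as.integer(k)
  if (k < 11L) stop("seed length k must be >= 11", call. = FALSE)
  if (k %% 2L == 0L) stop("seed length k must be odd", call. = FALSE)
  ins <- validate_proviral(construct)
  if (is.list(host)) host <- host$sequence
  rs <- structure(list(construct = construct, insert_interval = ins,
                       refs = list(repcap = assert_dna(repcap, "repcap"),
                                   phelper = assert_dna(phelper, "phelper"),
                                   host = assert_dna(host, "host")),
                       k = k),
                  class = "reference_set")
  rs$index <- build_kmer_index(rs)
  rs
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> construct %s (insert %d bp / backbone %d bp), k=%d, %d indexed k-mers\n",
              x$construct$name, x$insert_interval[2L],
              nchar(x$construct$sequence) - x$insert_interval[2L],
              x$k, length(x$index$kmer)))
  invisible(x)
}

.CAT_BITS <- c(insert = 1L, backbone = 2L, repcap = 4L, phelper = 8L, host = 16L)

# k-mer -> category bitmask over both strands; construct k-mers are labelled
# insert/backbone by the majority of their k bases (k odd, no ties)
build_kmer_index <- function(rs) {
  k <- rs$k
  L <- nchar(rs$construct$sequence)
  ie <- rs$insert_interval[2L]
  dbl <- paste0(rs$construct$sequence, substr(rs$construct$sequence, 1L, k - 1L))
  km <- kmers_of(dbl, k)  # one per circular start position, length L
  in_ins <- as.integer(((seq_len(nchar(dbl)) - 1L) %% L) < ie)
  cs <- cumsum(in_ins)
  ins_bases <- cs[seq_len(L) + k - 1L] - c(0L, cs)[seq_len(L)]
  bit <- ifelse(ins_bases * 2L > k, .CAT_BITS[["insert"]], .CAT_BITS[["backbone"]])

  kmer <- c(km, revcomp(km))
  bits <- c(bit, bit)
  for (nm in c("repcap", "phelper", "host")) {
    km2 <- kmers_of(rs$refs[[nm]], k)
    kmer <- c(kmer, km2, revcomp(km2))
    bits <- c(bits, rep(.CAT_BITS[[nm]], 2L * length(km2)))
  }
  merged <- tapply(bits, kmer, function(b) Reduce(bitwOr, b))
  list(kmer = names(merged), bits = as.integer(merged))
}

#' Classify reads against a reference set
#'
#' For each read, the matched bases per category are the read positions
#' covered by exact k-mer seed hits (both strands) to that category; insert
#' versus backbone is decided by the construct coordinate of the hit, so a
#' junction-spanning read goes to the category with the majority of matched
#' bases. The category is the argmax over insert/backbone/repcap/phelper; an
#' exact tie gives `ambiguous`; a read with no hits falls back to the host
#' decoy, and `unassigned` if the host misses too. Reads shorter than `k`
#' are `unassigned` (with a warning).
#'
#' @param reads Character vector (or `DNAStringSet`) of reads; names are used
#'   as read ids.
#' @param refs A [reference_set()].
#' @param chunk_size Reads per processing block (memory/speed trade-off).
#' @return `data.frame(read_id, category, tie_flag, mb_insert, mb_backbone,
#'   mb_repcap, mb_phelper, mb_host)`.
#' @export
classify_reads <- function(reads, refs, chunk_size = 10000L) {
  stopifnot(inherits(refs, "reference_set"))
  if (methods::is(reads, "XStringSet")) {
    nm <- names(reads)
    reads <- as.character(reads)
    names(reads) <- nm
  }
  n <- length(reads)
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%07d", seq_len(n))
  out <- vector("list", ceiling(n / chunk_size))
  short_count <- 0L
  for (ci in seq_along(out)) {
    sel <- ((ci - 1L) * chunk_size + 1L):min(ci * chunk_size, n)
    block <- classify_block(unname(reads[sel]), ids[sel], refs)
    short_count <- short_count + attr(block, "n_short")
    out[[ci]] <- block
  }
  if (short_count > 0L)
    warning(short_count, " read(s) shorter than k were left unassigned")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

classify_block <- function(seqs, ids, refs) {
  k <- refs$k
  idx <- refs$index
  n <- length(seqs)
  mb <- matrix(0L, n, 5L, dimnames = list(NULL, names(.CAT_BITS)))
  w <- nchar(seqs)
  n_short <- sum(w < k)
  for (L in unique(w[w >= k])) {
    rows <- which(w == L)
    m <- L - k + 1L
    Q <- matrix("", length(rows), m)
    for (s in seq_len(m)) Q[, s] <- substr(seqs[rows], s, s + k - 1L)
    bits <- idx$bits[match(Q, idx$kmer)]
    bits[is.na(bits)] <- 0L
    bits <- matrix(bits, length(rows), m)
    for (cat in names(.CAT_BITS)) {
      H <- bitwAnd(bits, .CAT_BITS[[cat]]) > 0L
      if (!any(H)) next
      CS <- matrix(as.integer(H), length(rows), m)
      if (m > 1L) for (j in 2:m) CS[, j] <- CS[, j - 1L] + CS[, j]
      covered <- integer(length(rows))
      for (p in seq_len(L)) {
        hi <- CS[, min(p, m)]
        lo <- if (p - k >= 1L) CS[, p - k] else 0L
        covered <- covered + as.integer((hi - lo) > 0L)
      }
      mb[rows, cat] <- covered
    }
  }

  primary <- mb[, c("insert", "backbone", "repcap", "phelper"), drop = FALSE]
  arg <- max.col(primary, ties.method = "first")
  best <- primary[cbind(seq_len(n), arg)]
  n_top <- rowSums(primary == best)
  category <- colnames(primary)[arg]
  tie <- best > 0L & n_top > 1L
  category[tie] <- "ambiguous"
  none <- best == 0L
  category[none & mb[, "host"] > 0L] <- "host"
  category[none & mb[, "host"] == 0L] <- "unassigned"
  category[w < k] <- "unassigned"
  res <- data.frame(read_id = ids, category = category, tie_flag = tie,
                    mb_insert = mb[, "insert"], mb_backbone = mb[, "backbone"],
                    mb_repcap = mb[, "repcap"], mb_phelper = mb[, "phelper"],
                    mb_host = mb[, "host"], stringsAsFactors = FALSE)
  attr(res, "n_short") <- n_short
  res
}

#' Classify a single read
#'
#' @param read A single read (character).
#' @param refs A [reference_set()].
#' @return One-row `data.frame` as in [classify_reads()].
#' @export
classify_read <- function(read, refs) {
  classify_reads(stats::setNames(read, "read"), refs)
}

#' Reconcile the mate classifications of read pairs
#'
#' Mates are classified independently; a pair keeps the shared category, an
#' `unassigned` mate defers to the other, and any other disagreement makes the
#' pair `ambiguous`.
#'
#' @param a1,a2 [classify_reads()] results for mate 1 and mate 2 (same order).
#' @return `data.frame(read_id, category, category_m1, category_m2)`.
#' @export
reconcile_pairs <- function(a1, a2) {
  stopifnot(nrow(a1) == nrow(a2))
  c1 <- a1$category
  c2 <- a2$category
  category <- ifelse(c1 == c2, c1,
              ifelse(c1 == "unassigned", c2,
              ifelse(c2 == "unassigned", c1, "ambiguous")))
  data.frame(read_id = sub("/[12]$", "", a1$read_id), category = category,
             category_m1 = c1, category_m2 = c2, stringsAsFactors = FALSE)
}

#' Per-sample classification summary (the sequencing-table computation)
#'
#' Computes the per-category percentages and the derived ratios from raw
#' category counts. "Unique mapped reads" is the number of unambiguously
#' assigned reads (insert + backbone + other); ambiguous and unassigned reads
#' are excluded from the denominator and reported separately. Percentages are
#' rounded half-up to 2 decimals for presentation (exact values retained);
#' ratios are reported both exact and rounded to the nearest integer, with an
#' infinity sentinel when the denominator count is zero.
#'
#' @param counts Named counts with `insert`, `backbone` and either `other` or
#'   any of `repcap`, `phelper`, `host`.
#' @param sample Sample name.
#' @param ambiguous,unassigned Excluded read counts (bookkeeping only).
#' @return An object of class `classification_summary`.
#' @export
classification_summary <- function(counts, sample = "sample",
                                   ambiguous = 0L, unassigned = 0L) {
  counts <- counts[!is.na(counts)]
  get0n <- function(nm) if (nm %in% names(counts)) as.numeric(counts[[nm]]) else 0
  insert <- get0n("insert")
  backbone <- get0n("backbone")
  other <- if ("other" %in% names(counts)) as.numeric(counts[["other"]])
           else get0n("repcap") + get0n("phelper") + get0n("host")
  unique_mapped <- insert + backbone + other
  if (unique_mapped <= 0)
    stop("summary undefined: zero unique mapped reads", call. = FALSE)
  pct <- function(x) round_half_up(100 * x / unique_mapped, 2L)
  ratio <- function(num, den) if (den > 0) num / den else Inf
  structure(list(
    sample = sample,
    unique_mapped = unique_mapped,
    counts = c(insert = insert, backbone = backbone, other = other),
    insert_pct = pct(insert), backbone_pct = pct(backbone), other_pct = pct(other),
    insert_backbone_ratio = ratio(insert, backbone),
    insert_other_ratio = ratio(insert, other),
    insert_backbone_ratio_int = round_half_up(ratio(insert, backbone), 0L),
    insert_other_ratio_int = round_half_up(ratio(insert, other), 0L),
    ambiguous = ambiguous, unassigned = unassigned),
    class = "classification_summary")
}

#' @export
print.classification_summary <- function(x, ...) {
  cat(sprintf("<classification_summary> %s\n", x$sample))
  cat(sprintf("  unique mapped reads: %s\n",
              format(x$unique_mapped, big.mark = ",", scientific = FALSE)))
  cat(sprintf("  insert   %10.0f  %6.2f%%\n", x$counts["insert"], x$insert_pct))
  cat(sprintf("  backbone %10.0f  %6.2f%%\n", x$counts["backbone"], x$backbone_pct))
  cat(sprintf("  other    %10.0f  %6.2f%%\n", x$counts["other"], x$other_pct))
  cat(sprintf("  insert:backbone = %s:1   insert:other = %s:1\n",
              format(x$insert_backbone_ratio_int),
              format(x$insert_other_ratio_int)))
  invisible(x)
}

#' Summarize read assignments for one sample
#'
#' @param assignments A [classify_reads()] or [reconcile_pairs()] result.
#' @param sample Sample name.
#' @return A [classification_summary()].
#' @export
summarize_assignments <- function(assignments, sample = "sample") {
  stopifnot(nrow(assignments) >= 1L)
  tab <- table(assignments$category)
  cnt <- function(nm) if (nm %in% names(tab)) as.integer(tab[[nm]]) else 0L
  classification_summary(
    c(insert = cnt("insert"), backbone = cnt("backbone"),
      repcap = cnt("repcap"), phelper = cnt("phelper"), host = cnt("host")),
    sample = sample, ambiguous = cnt("ambiguous"), unassigned = cnt("unassigned"))
}

#' Assign host-aligned reads to genes by minimum overlap
#'
#' A read counts toward every gene it overlaps by at least `min_overlap` bases
#' (15 bp by default, introns included since gene intervals span them).
#'
#' @param reads `data.frame(start, end)` of aligned read intervals (0-based
#'   half-open) on the host coordinate system; an optional `chrom` column is
#'   honoured.
#' @param genes `data.frame(gene_id, start, end)` (same conventions).
#' @param min_overlap Minimum overlap in bases.
#' @return `data.frame(gene_id, count)` (all genes, zero counts included).
#' @export
assign_reads_to_genes <- function(reads, genes, min_overlap = 15L) {
  if (nrow(genes) == 0L)
    return(data.frame(gene_id = character(), count = integer(),
                      stringsAsFactors = FALSE))
  check_iv <- function(d, what) {
    if (any(d$start >= d$end))
      stop("malformed ", what, " interval (start >= end)", call. = FALSE)
  }
  if (nrow(reads)) check_iv(reads, "read")
  check_iv(genes, "gene")
  rchrom <- if ("chrom" %in% names(reads)) reads$chrom else rep("host", nrow(reads))
  gchrom <- if ("chrom" %in% names(genes)) genes$chrom else rep("host", nrow(genes))
  counts <- integer(nrow(genes))
  if (nrow(reads)) {
    gr_r <- GenomicRanges::GRanges(rchrom, IRanges::IRanges(reads$start + 1L, reads$end))
    gr_g <- GenomicRanges::GRanges(gchrom, IRanges::IRanges(genes$start + 1L, genes$end))
    hits <- IRanges::findOverlaps(gr_r, gr_g, minoverlap = min_overlap)
    counts <- tabulate(S4Vectors::subjectHits(hits), nbins = nrow(genes))
  }
  data.frame(gene_id = genes$gene_id, count = counts, stringsAsFactors = FALSE)
}
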