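#' Statistical model of a packaged AAV prep
#'
#' Describes the population of DNase-resistant genomes in a vector prep:
#' correctly packaged (possibly truncated) insert genomes, cross-packaged
#' ITR-flanked backbone genomes, and "other" contaminants from the RepCap
#' plasmid, the helper plasmid and host-cell DNA.
#'
#' Truncation is modeled as one-sided shortening of an insert genome at a
#' breakpoint drawn from a hotspot mixture (two sites flanking the miRNA
#' hairpin by default); the retained segment runs from the breakpoint to the
#' ITR-side end, which removes the upstream U6 promoter.
#'
#' @param construct Proviral [plasmid_construct()].
#' @param repcap,phelper DNA strings (stand-in plasmid sequences).
#' @param host Host decoy: DNA string or the `host` element of
#'   [synthetic_reference_panel()].
#' @param category_probs Named probabilities for
#'   `insert`, `backbone`, `repcap`, `phelper`, `host`; must sum to 1. The
#'   default mirrors a first-generation AAV2 prep (95.65% insert, 1.90%
#'   backbone, 2.45% other split across its three sources).
#' @param truncation_hotspots `data.frame(position, weight)` of breakpoint
#'   sites on the insert (construct coordinates). Default: two sites flanking
#'   the mi405 feature at +/- 15 bp, equal weights.
#' @param total_truncation_prob Fraction of insert genomes that are truncated
#'   (default 0.5: roughly half of packaged genomes).
#' @param error_rate Per-base substitution probability applied when reads are
#'   emitted.
#' @return An object of class `prep_model`.
#' @export
prep_model <- function(construct, repcap, phelper, host,
                       category_probs = c(insert = 0.9565, backbone = 0.0190,
                                          repcap = 0.0100, phelper = 0.0080,
                                          host = 0.0065),
                       truncation_hotspots = NULL,
                       total_truncation_prob = 0.5,
                       error_rate = 0.001) {
  ins <- validate_proviral(construct)
  if (is.list(host)) host <- host$sequence
  cats <- c("insert", "backbone", "repcap", "phelper", "host")
  if (!setequal(names(category_probs), cats))
    stop("category_probs must be named: ", paste(cats, collapse = ", "),
         call. = FALSE)
  category_probs <- category_probs[cats]
  if (any(category_probs < 0 | category_probs > 1))
    stop("category probabilities must lie in [0, 1]", call. = FALSE)
  if (abs(sum(category_probs) - 1) > 1e-9)
    stop("category_probs must sum to 1", call. = FALSE)
  if (is.null(truncation_hotspots)) {
    mi <- tryCatch(get_feature(construct, label = "mi405"), error = function(e) NULL)
    if (is.null(mi)) mi <- get_feature(construct, role = "miRNA")
    truncation_hotspots <- data.frame(position = c(mi$start - 15L, mi$end + 15L),
                                      weight = c(0.5, 0.5))
  }
  if (any(truncation_hotspots$position <= ins[1L]) ||
      any(truncation_hotspots$position >= ins[2L]))
    stop("truncation hotspot positions must lie inside the insert interval",
         call. = FALSE)
  stopifnot(total_truncation_prob >= 0, total_truncation_prob <= 1,
            error_rate >= 0, error_rate < 1)
  structure(list(construct = construct,
                 refs = list(repcap = assert_dna(repcap, "repcap"),
                             phelper = assert_dna(phelper, "phelper"),
                             host = assert_dna(host, "host")),
                 category_probs = category_probs,
                 truncation_hotspots = truncation_hotspots,
                 total_truncation_prob = total_truncation_prob,
                 error_rate = error_rate),
            class = "prep_model")
}

#' @export
print.prep_model <- function(x, ...) {
  cat("<prep_model> on", x$construct$name, "\n")
  cat("  category probs:",
      paste(sprintf("%s=%.4f", names(x$category_probs), x$category_probs),
            collapse = " "), "\n")
  cat(sprintf("  truncation: p=%.2f at hotspot(s) %s\n", x$total_truncation_prob,
              paste(x$truncation_hotspots$position, collapse = ", ")))
  cat(sprintf("  substitution error rate: %g\n", x$error_rate))
  invisible(x)
}

#' Simulate a population of packaged genomes
#'
#' Draws genome categories from the model's multinomial, assigns each genome a
#' source interval (insert genomes span the full ITR-to-ITR insert unless
#' truncated; backbone genomes span the ITR-flanked backbone arc including any
#' stuffer arms; repcap/phelper/host genomes are uniform sub-fragments), and
#' records everything in a ground-truth table. Fixing `seed` makes the output
#' bit-reproducible.
#'
#' Intervals on the circular construct are reported in "unrolled" coordinates:
#' `end` may exceed the plasmid length when a genome crosses the rotation
#' origin (backbone genomes do, by construction).
#'
#' @param model A [prep_model()].
#' @param n_genomes Number of capsid contents to draw (>= 1).
#' @param seed Integer seed or `NULL`.
#' @param keep_sequences Materialize the genome sequences (memory-hungry for
#'   large `n_genomes`; reads can be emitted without it).
#' @return An object of class `packaged_prep`: `list(truth =, model =,
#'   sequences =)`. `truth` has columns `genome_id`, `category`, `source_ref`,
#'   `start`, `end`, `strand`, `breakpoint`.
#' @export
simulate_prep <- function(model, n_genomes, seed = NULL, keep_sequences = FALSE) {
  stopifnot(inherits(model, "prep_model"), n_genomes >= 1L)
  with_seed(seed, {
    p <- model$category_probs
    cats <- sample(names(p), n_genomes, replace = TRUE, prob = p)
    strand <- sample(c("+", "-"), n_genomes, replace = TRUE)
    L <- nchar(model$construct$sequence)
    ins <- insert_interval(model$construct)
    itr <- get_feature(model$construct, role = "ITR")
    mitr <- get_feature(model$construct, role = "mITR")

    start <- integer(n_genomes)
    end <- integer(n_genomes)
    src <- rep("construct", n_genomes)
    bp <- rep(NA_integer_, n_genomes)

    i_ins <- which(cats == "insert")
    start[i_ins] <- ins[1L]
    end[i_ins] <- ins[2L]
    if (length(i_ins)) {
      tr <- i_ins[stats::runif(length(i_ins)) < model$total_truncation_prob]
      if (length(tr)) {
        hs <- model$truncation_hotspots
        pick <- sample.int(nrow(hs), length(tr), replace = TRUE, prob = hs$weight)
        bp[tr] <- hs$position[pick]
        start[tr] <- bp[tr]  # retained segment runs breakpoint -> ITR end
      }
    }

    i_bb <- which(cats == "backbone")
    start[i_bb] <- itr$start
    end[i_bb] <- L + mitr$end  # crosses the rotation origin; both ITRs flank

    for (cat in c("repcap", "phelper", "host")) {
      idx <- which(cats == cat)
      if (!length(idx)) next
      ref <- model$refs[[cat]]
      n <- length(idx)
      maxlen <- min(nchar(ref), 2300L)
      len <- as.integer(floor(stats::runif(n, min(500L, maxlen), maxlen + 1L)))
      s <- as.integer(floor(stats::runif(n) * (nchar(ref) - len + 1L)))
      start[idx] <- s
      end[idx] <- s + len
      src[idx] <- cat
    }

    truth <- data.frame(genome_id = sprintf("g%07d", seq_len(n_genomes)),
                        category = cats, source_ref = src,
                        start = start, end = end, strand = strand,
                        breakpoint = bp, stringsAsFactors = FALSE)
    seqs <- if (keep_sequences) genome_sequences(model, truth) else NULL
    structure(list(truth = truth, model = model, sequences = seqs),
              class = "packaged_prep")
  })
}

#' @export
print.packaged_prep <- function(x, ...) {
  cat(sprintf("<packaged_prep> %d genomes on %s\n",
              nrow(x$truth), x$model$construct$name))
  print(round(prop.table(table(x$truth$category)), 4))
  invisible(x)
}

# forward-strand genome sequences for a slice of the truth table
genome_sequences <- function(model, truth) {
  out <- character(nrow(truth))
  for (ref in unique(truth$source_ref)) {
    idx <- truth$source_ref == ref
    s <- if (ref == "construct") model$construct$sequence else model$refs[[ref]]
    big <- paste0(s, s)  # tolerate origin-crossing intervals
    out[idx] <- substring(big, truth$start[idx] + 1L, truth$end[idx])
  }
  stats::setNames(out, truth$genome_id)
}

# uniform substitution errors; returns the mutated vector
apply_errors <- function(seqs, rate) {
  if (rate <= 0 || !length(seqs)) return(seqs)
  w <- nchar(seqs)
  nerr <- stats::rbinom(length(seqs), w, rate)
  for (i in which(nerr > 0L)) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    pos <- sample.int(w[i], nerr[i])
    ch[pos] <- vapply(ch[pos], function(b)
      sample(setdiff(.DNA_ALPHABET, b), 1L), character(1), USE.NAMES = FALSE)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Emit short sequencing reads from a simulated prep
#'
#' Fragments are placed uniformly on each genome (`depth` fragments per
#' genome); paired mode emits a 2 x `read_len` pair from the fragment ends with
#' random fragment orientation. Genomes (or fragments) shorter than `read_len`
#' emit full-length reads. Read names encode the ground truth
#' (`id:fragment/mate cat=... ref=... s=... e=...`, 0-based half-open span on
#' the source reference, unrolled coordinates for origin-crossing genomes).
#'
#' @param prep A [simulate_prep()] result.
#' @param read_len Read length (default 150, the 2 x 150 PE layout).
#' @param paired Emit mate pairs?
#' @param depth Fragments per genome.
#' @param frag_len Fragment length range (uniform draw, clipped to the genome).
#' @param error_rate Per-base substitution rate; defaults to the model's.
#' @param seed Integer seed or `NULL`.
#' @return `list(r1 =, r2 =, truth =)`: named character vectors of reads (`r2`
#'   is `NULL` when unpaired) and a per-fragment truth table with mate spans.
#' @export
emit_short_reads <- function(prep, read_len = 150L, paired = TRUE, depth = 1L,
                             frag_len = c(250L, 450L), error_rate = NULL,
                             seed = NULL) {
  stopifnot(inherits(prep, "packaged_prep"), read_len >= 1L, depth >= 1L)
  if (is.null(error_rate)) error_rate <- prep$model$error_rate
  model <- prep$model
  with_seed(seed, {
    truth <- prep$truth[rep(seq_len(nrow(prep$truth)), each = depth), ]
    nf <- nrow(truth)
    fragn <- rep(seq_len(depth), times = nrow(prep$truth))
    glen <- truth$end - truth$start
    flen <- pmin(glen, as.integer(floor(stats::runif(nf, frag_len[1L], frag_len[2L] + 1L))))
    flen <- pmax(flen, pmin(glen, read_len))
    fstart <- as.integer(floor(stats::runif(nf) * (glen - flen + 1L)))
    a <- truth$start + fstart
    b <- a + flen

    frag <- character(nf)
    for (ref in unique(truth$source_ref)) {
      idx <- truth$source_ref == ref
      s <- if (ref == "construct") model$construct$sequence else model$refs[[ref]]
      big <- paste0(s, s)
      frag[idx] <- substring(big, a[idx] + 1L, b[idx])
    }

    l1 <- pmin(read_len, flen)
    fwd <- substr(frag, 1L, read_len)
    rev_ <- revcomp(substring(frag, pmax(1L, flen - read_len + 1L), flen))
    flip <- stats::runif(nf) < 0.5
    r1 <- ifelse(flip, rev_, fwd)
    s1 <- ifelse(flip, b - l1, a)
    e1 <- ifelse(flip, b, a + l1)

    base <- sprintf("%s:f%d", truth$genome_id, fragn)
    out_truth <- data.frame(fragment_id = base, category = truth$category,
                            source_ref = truth$source_ref,
                            s1 = s1, e1 = e1, stringsAsFactors = FALSE)
    r1 <- apply_errors(r1, error_rate)
    names(r1) <- sprintf("%s/1 cat=%s ref=%s s=%d e=%d",
                         base, truth$category, truth$source_ref, s1, e1)
    r2 <- NULL
    if (paired) {
      r2 <- ifelse(flip, fwd, rev_)
      s2 <- ifelse(flip, a, b - l1)
      e2 <- ifelse(flip, a + l1, b)
      r2 <- apply_errors(r2, error_rate)
      names(r2) <- sprintf("%s/2 cat=%s ref=%s s=%d e=%d",
                           base, truth$category, truth$source_ref, s2, e2)
      out_truth$s2 <- s2
      out_truth$e2 <- e2
    }
    list(r1 = r1, r2 = r2, truth = out_truth)
  })
}

#' Emit one long read per packaged genome
#'
#' Each read is the full packaged molecule (so truncated genomes yield
#' correspondingly shorter reads), on the genome's strand, with uniform
#' substitution errors. Names carry the ground truth.
#'
#' @param prep A [simulate_prep()] result.
#' @param error_rate Per-base substitution rate; defaults to the model's.
#' @param seed Integer seed or `NULL`.
#' @return Named character vector of reads.
#' @export
emit_long_reads <- function(prep, error_rate = NULL, seed = NULL) {
  stopifnot(inherits(prep, "packaged_prep"))
  if (is.null(error_rate)) error_rate <- prep$model$error_rate
  with_seed(seed, {
    truth <- prep$truth
    seqs <- if (!is.null(prep$sequences)) unname(prep$sequences)
            else unname(genome_sequences(prep$model, truth))
    neg <- truth$strand == "-"
    seqs[neg] <- revcomp(seqs[neg])
    seqs <- apply_errors(seqs, error_rate)
    names(seqs) <- sprintf("%s cat=%s ref=%s s=%d e=%d strand=%s",
                           truth$genome_id, truth$category, truth$source_ref,
                           truth$start, truth$end, truth$strand)
    seqs
  })
}

#' Parse ground truth out of simulated read names
#'
#' @param headers Read names produced by [emit_short_reads()] or
#'   [emit_long_reads()] (FASTA/FASTQ headers survive a round trip).
#' @return `data.frame(read_id, category, source_ref, start, end)`.
#' @export
read_truth_from_names <- function(headers) {
  grab <- function(key) sub(paste0(".*", key, "=(\\S+).*"), "\\1", headers)
  data.frame(read_id = sub(" .*", "", headers),
             category = grab("cat"), source_ref = grab("ref"),
             start = as.integer(grab("s")), end = as.integer(grab("e")),
             stringsAsFactors = FALSE)
}

#' Write simulated reads to FASTQ / FASTA
#'
#' @param reads Named character vector of reads.
#' @param path Output path.
#' @param quality_char Constant base quality for FASTQ output.
#' @name reads_io
NULL

#' @rdname reads_io
#' @export
write_reads_fastq <- function(reads, path, quality_char = "I") {
  x <- Biostrings::DNAStringSet(unname(reads))
  names(x) <- names(reads)
  q <- Biostrings::BStringSet(strrep(quality_char, nchar(reads)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' @rdname reads_io
#' @export
write_reads_fasta <- function(reads, path) {
  x <- Biostrings::DNAStringSet(unname(reads))
  names(x) <- names(reads)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a truth table written alongside simulated reads
#'
#' @param truth Truth `data.frame`.
#' @param path TSV path.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
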