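#' Align long reads to the construct by seed-and-diagonal voting
#'
#' Packaged-genome long reads are contiguous (possibly truncated) copies of
#' the circular construct with substitution errors, so a handful of exact
#' k-mer anchors plus majority voting on the alignment diagonal recovers the
#' aligned interval exactly. Both strands are tried; the interval is reported
#' in unrolled circular coordinates (`ref_end` may exceed the plasmid length
#' for origin-crossing molecules).
#'
#' @param reads Character vector (or `DNAStringSet`) of long reads.
#' @param construct Proviral [plasmid_construct()].
#' @param k Anchor seed length.
#' @param n_anchors Number of anchor positions spread along each read.
#' @return `data.frame(read_id, width, aligned, strand, ref_start, ref_end)`
#'   (0-based half-open).
#' @export
align_long_reads <- function(reads, construct, k = 21L, n_anchors = 12L) {
  if (methods::is(reads, "XStringSet")) {
    nm <- names(reads)
    reads <- as.character(reads)
    names(reads) <- nm
  }
  n <- length(reads)
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%07d", seq_len(n))
  ids <- sub(" .*", "", ids)
  L <- nchar(construct$sequence)
  dbl <- paste0(construct$sequence, construct$sequence)
  km <- kmers_of(dbl, k)
  keep <- !duplicated(km)
  env <- list2env(stats::setNames(as.list(which(keep) - 1L), km[keep]),
                  hash = TRUE, size = sum(keep) * 2L)
  rc_cache <- revcomp(reads)

  w <- nchar(reads)
  strand <- rep(NA_character_, n)
  ref_start <- rep(NA_integer_, n)
  aligned <- rep(FALSE, n)
  diag_of <- function(x, wi) {
    qs <- unique(as.integer(round(seq(1L, wi - k + 1L,
                                      length.out = min(n_anchors, wi - k + 1L)))))
    kq <- substring(x, qs, qs + k - 1L)
    p0 <- unlist(mget(kq, envir = env, ifnotfound = NA), use.names = FALSE)
    int_mode((p0 - (qs - 1L)) %% L)
  }
  for (i in seq_len(n)) {
    if (w[i] < k) next
    d <- diag_of(reads[i], w[i])
    if (!is.na(d)) {
      strand[i] <- "+"
    } else {
      d <- diag_of(rc_cache[i], w[i])
      if (!is.na(d)) strand[i] <- "-"
    }
    if (!is.na(d)) {
      ref_start[i] <- d
      aligned[i] <- TRUE
    }
  }
  data.frame(read_id = ids, width = w, aligned = aligned, strand = strand,
             ref_start = ref_start, ref_end = ref_start + w,
             stringsAsFactors = FALSE)
}

#' Locate truncation breakpoints from long-read alignments
#'
#' A breakpoint is a read end that falls strictly inside the profiled
#' reference interval, at least `min_anchor` bases away from the interval
#' termini (so natural full-length ends are not called). Reads that cannot be
#' anchored (too short or no seed hit) are skipped and counted.
#'
#' @param reads Long reads (character / `DNAStringSet`) or a pre-computed
#'   alignment `data.frame` with `ref_start`/`ref_end` columns (e.g. from
#'   [align_long_reads()] or [read_paf_intervals()]).
#' @param construct Proviral [plasmid_construct()].
#' @param interval Profiled interval `c(start, end)`; defaults to the
#'   ITR-to-ITR insert.
#' @param min_anchor Minimum distance (bp) from the interval termini.
#' @param k Anchor seed length for the internal aligner.
#' @return `list(alignments =, breakpoints = data.frame(read_id, position),
#'   n_skipped =, n_aligned =)`.
#' @export
locate_breakpoints <- function(reads, construct, interval = NULL,
                               min_anchor = 10L, k = 21L) {
  aln <- if (is.data.frame(reads)) normalize_alignments(reads)
         else align_long_reads(reads, construct, k = k)
  if (is.null(interval)) interval <- insert_interval(construct)
  lo <- interval[1L]
  hi <- interval[2L]
  L <- nchar(construct$sequence)
  ok <- aln$aligned & aln$width >= min_anchor
  n_skipped <- sum(!ok)
  cand <- rbind(
    data.frame(read_id = aln$read_id[ok], position = aln$ref_start[ok] %% L),
    data.frame(read_id = aln$read_id[ok], position = aln$ref_end[ok] %% L))
  keep <- cand$position - lo >= min_anchor & hi - cand$position >= min_anchor
  bp <- cand[keep, , drop = FALSE]
  rownames(bp) <- NULL
  list(alignments = aln, breakpoints = bp,
       n_skipped = n_skipped, n_aligned = sum(ok))
}

normalize_alignments <- function(df) {
  stopifnot(all(c("ref_start", "ref_end") %in% names(df)))
  if (is.null(df$read_id)) df$read_id <- sprintf("read%07d", seq_len(nrow(df)))
  if (is.null(df$width)) df$width <- df$ref_end - df$ref_start
  if (is.null(df$aligned)) df$aligned <- TRUE
  if (is.null(df$strand)) df$strand <- "+"
  df
}

#' Call truncation hotspots from per-position read-end counts
#'
#' Sites are formed greedily: the most frequent end position absorbs all ends
#' within `merge_window` bases (so a site spans at most `2 * merge_window + 1`
#' bases and dense uniform ends cannot chain into one giant cluster), then the
#' next peak is taken, and so on. Sites with frequency above `threshold` are
#' returned, sorted by frequency (descending).
#'
#' @param end_counts `data.frame(position, count)` or a named count vector.
#' @param total_reads Denominator for frequencies (>= 1).
#' @param threshold Minimum frequency (exclusive); default 0.01.
#' @param merge_window Merge radius in bp (default 5).
#' @return `data.frame(position, count, frequency)`.
#' @export
call_hotspots <- function(end_counts, total_reads, threshold = 0.01,
                          merge_window = 5L) {
  stopifnot(total_reads >= 1L)
  if (!is.data.frame(end_counts)) {
    end_counts <- data.frame(position = as.integer(names(end_counts)),
                             count = as.integer(end_counts))
  }
  if (nrow(end_counts) == 0L)
    return(data.frame(position = integer(), count = integer(),
                      frequency = numeric()))
  d <- end_counts[order(end_counts$position), , drop = FALSE]
  pos <- integer(0)
  cnt <- integer(0)
  while (nrow(d)) {
    i <- which.max(d$count)  # ties -> smallest position (d is sorted)
    near <- abs(d$position - d$position[i]) <= merge_window
    pos <- c(pos, d$position[i])
    cnt <- c(cnt, sum(d$count[near]))
    d <- d[!near, , drop = FALSE]
  }
  res <- data.frame(position = as.integer(pos), count = as.integer(cnt),
                    frequency = cnt / total_reads)
  res <- res[res$frequency > threshold, , drop = FALSE]
  res <- res[order(-res$frequency), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Fraction of genomes that lost a promoter (or any feature) to truncation
#'
#' @param reads Long reads or alignment `data.frame` (see
#'   [locate_breakpoints()]).
#' @param construct Proviral [plasmid_construct()].
#' @param feature Feature label (or role) whose full coverage is required;
#'   default the U6 promoter.
#' @param k Anchor seed length for the internal aligner.
#' @return Fraction of aligned reads whose span does not fully cover the
#'   feature interval.
#' @export
promoter_loss_fraction <- function(reads, construct, feature = "U6", k = 21L) {
  aln <- if (is.data.frame(reads)) normalize_alignments(reads)
         else align_long_reads(reads, construct, k = k)
  aln <- aln[aln$aligned, , drop = FALSE]
  if (nrow(aln) == 0L)
    stop("no aligned reads: promoter-loss fraction undefined", call. = FALSE)
  f <- tryCatch(get_feature(construct, label = feature),
                error = function(e) get_feature(construct, role = feature))
  L <- nchar(construct$sequence)
  covers <- (aln$ref_start <= f$start & aln$ref_end >= f$end) |
            (aln$ref_start <= f$start + L & aln$ref_end >= f$end + L)
  mean(!covers)
}

#' Truncation profile of an AAV prep from long reads
#'
#' Combines breakpoint location, hotspot calling, promoter-loss and per-site
#' truncation fractions into one report over the insert coordinate.
#'
#' @param reads Long reads (character / `DNAStringSet`) or alignments.
#' @param construct Proviral [plasmid_construct()].
#' @param promoter Feature whose loss is quantified (default `"U6"`).
#' @param site_features Feature labels for per-site truncation fractions
#'   (e.g. the miRNA hairpin and the insulator sites).
#' @param threshold Hotspot frequency threshold.
#' @param min_anchor,k See [locate_breakpoints()].
#' @return An object of class `truncation_profile`: per-position end counts,
#'   hotspot calls, `fraction_truncated`, `fraction_missing_promoter`,
#'   per-site fractions, and `total_reads`.
#' @export
truncation_profile <- function(reads, construct, promoter = "U6",
                               site_features = c("mi405"), threshold = 0.01,
                               min_anchor = 10L, k = 21L) {
  lb <- locate_breakpoints(reads, construct, min_anchor = min_anchor, k = k)
  total <- lb$n_aligned
  if (total == 0L) stop("no aligned reads to profile", call. = FALSE)
  bp <- lb$breakpoints
  ends <- as.data.frame(table(bp$position), stringsAsFactors = FALSE)
  ends <- data.frame(position = as.integer(ends$Var1), count = ends$Freq)
  ends$frequency <- ends$count / total
  hot <- call_hotspots(ends[, c("position", "count")], total, threshold)
  site_fractions <- vapply(site_features, function(lab) {
    f <- tryCatch(get_feature(construct, label = lab), error = function(e) NULL)
    if (is.null(f)) return(NA_real_)
    sum(bp$position >= f$start & bp$position < f$end) / total
  }, numeric(1))
  aligned <- lb$alignments[lb$alignments$aligned, , drop = FALSE]
  structure(list(
    end_counts = ends, hotspots = hot,
    fraction_truncated = length(unique(bp$read_id)) / total,
    fraction_missing_promoter =
      promoter_loss_fraction(aligned, construct, feature = promoter),
    site_fractions = site_fractions,
    total_reads = total, n_skipped = lb$n_skipped),
    class = "truncation_profile")
}

#' @export
print.truncation_profile <- function(x, ...) {
  cat(sprintf("<truncation_profile> %d aligned reads (%d skipped)\n",
              x$total_reads, x$n_skipped))
  cat(sprintf("  truncated: %.1f%%   promoter lost: %.1f%%\n",
              100 * x$fraction_truncated, 100 * x$fraction_missing_promoter))
  if (nrow(x$hotspots)) {
    cat("  hotspots:\n")
    print(transform(x$hotspots, frequency = sprintf("%.2f%%", 100 * frequency)),
          row.names = FALSE)
  } else cat("  hotspots: none above threshold\n")
  if (length(x$site_fractions)) {
    cat("  per-site truncation fractions:\n")
    for (nm in names(x$site_fractions))
      cat(sprintf("    %-10s %.2f%%\n", nm, 100 * x$site_fractions[[nm]]))
  }
  invisible(x)
}

#' Origin composition of cross-packaged backbone genomes
#'
#' Tallies aligned bases falling in the plasmid backbone by the origin of the
#' underlying feature annotation (unannotated backbone bases count as
#' bacterial vector sequence; ITR bases belong to the insert interval and are
#' excluded). Origins `bacterial` and `phage` are pooled, `human` stands
#' alone, and everything else (e.g. synthetic stop cassettes) is `other`.
#'
#' @param reads Backbone-classified long reads (character / `DNAStringSet`) or
#'   alignment `data.frame` with `ref_start`/`ref_end`.
#' @param construct Proviral [plasmid_construct()].
#' @param k Anchor seed length for the internal aligner.
#' @return An object of class `composition_report`: `fractions`
#'   (`bacterial_phage`, `human`, `other`), `base_tally`, per-feature base
#'   tallies, reads used/excluded.
#' @export
composition <- function(reads, construct, k = 21L) {
  aln <- if (is.data.frame(reads)) normalize_alignments(reads)
         else align_long_reads(reads, construct, k = k)
  aln <- aln[aln$aligned, , drop = FALSE]
  if (nrow(aln) == 0L)
    stop("no aligned backbone bases: composition undefined", call. = FALSE)
  L <- nchar(construct$sequence)
  ie <- insert_interval(construct)[2L]
  omap <- base_origin_map(construct)
  grp <- ifelse(omap %in% c("bacterial", "phage"), "bacterial_phage",
         ifelse(omap == "human", "human", "other"))
  grp[seq_len(ie)] <- "excluded"  # insert interval (incl. ITRs)
  grp2 <- rep(grp, 2L)

  tally_interval <- function(indic) {
    cs <- c(0L, cumsum(indic))
    cs[pmin(aln$ref_end, 2L * L) + 1L] - cs[pmin(aln$ref_start, 2L * L) + 1L]
  }
  groups <- c("bacterial_phage", "human", "other")
  per_read <- vapply(groups, function(g) tally_interval(grp2 == g),
                     numeric(nrow(aln)))
  per_read <- matrix(per_read, nrow = nrow(aln),
                     dimnames = list(NULL, groups))
  used <- rowSums(per_read) > 0
  n_excluded <- sum(!used)
  tally <- colSums(per_read[used, , drop = FALSE])
  if (sum(tally) == 0)
    stop("no aligned backbone bases: composition undefined", call. = FALSE)

  f <- construct$features
  bb_feats <- f[f$start >= ie, , drop = FALSE]
  feat_tally <- vapply(seq_len(nrow(bb_feats)), function(i) {
    indic <- logical(L)
    indic[(bb_feats$start[i] + 1L):bb_feats$end[i]] <- TRUE
    sum(tally_interval(rep(indic, 2L))[used])
  }, numeric(1))
  names(feat_tally) <- bb_feats$label

  structure(list(fractions = tally / sum(tally), base_tally = tally,
                 feature_tally = feat_tally,
                 n_reads_used = sum(used), n_reads_excluded = n_excluded),
            class = "composition_report")
}

#' @export
print.composition_report <- function(x, ...) {
  cat(sprintf("<composition_report> %d backbone reads (%d excluded)\n",
              x$n_reads_used, x$n_reads_excluded))
  for (nm in names(x$fractions))
    cat(sprintf("  %-16s %6.1f%%  (%.0f bases)\n", nm,
                100 * x$fractions[[nm]], x$base_tally[[nm]]))
  invisible(x)
}

#' Read target intervals from a PAF alignment file
#'
#' Ingestion path for externally aligned long reads (e.g. minimap2/pbmm2 CCS
#' alignments): extracts query name, strand and target interval so the
#' profiling operations can run on real data.
#'
#' @param path PAF file path.
#' @return `data.frame(read_id, strand, ref_start, ref_end, aligned, width)`.
#' @export
read_paf_intervals <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  normalize_alignments(data.frame(
    read_id = d$V1, strand = d$V5,
    ref_start = as.integer(d$V8), ref_end = as.integer(d$V9),
    width = as.integer(d$V9) - as.integer(d$V8), aligned = TRUE,
    stringsAsFactors = FALSE))
}
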