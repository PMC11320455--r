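#' Mutate ATG start codons to ATT
#'
#' Every ATG on the forward strand (and, with `strands = "both"`, every ATG on
#' the reverse strand, i.e. every CAT on the forward strand) is destroyed by
#' mutating the third codon position G to T. Replacement is applied iteratively
#' until a fixpoint is reached, so the result is guaranteed start-codon free on
#' the requested strand(s). Sequence length is preserved.
#'
#' @param seq DNA string over A/C/G/T.
#' @param strands `"forward"` (default; the orientation in which a cassette is
#'   synthesized) or `"both"` (ITRs flank both ends and can drive transcription
#'   in either direction).
#' @return `list(sequence =, count =)` where `count` is the number of point
#'   substitutions made.
#' @examples
#' scrub_atg("ATGATG")   # "ATTATT", 2 substitutions
#' scrub_atg("CATCAT")   # unchanged on the forward strand
#' @export
scrub_atg <- function(seq, strands = c("forward", "both")) {
  strands <- match.arg(strands)
  if (nzchar(seq)) seq <- assert_dna(seq, "seq")
  total <- 0L
  repeat {
    changed <- FALSE
    hits <- gregexpr("ATG", seq, fixed = TRUE)[[1L]]
    if (hits[1L] != -1L) {
      ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
      ch[hits + 2L] <- "T"
      seq <- paste(ch, collapse = "")
      total <- total + length(hits)
      changed <- TRUE
    }
    if (strands == "both") {
      hits <- gregexpr("CAT", seq, fixed = TRUE)[[1L]]
      if (hits[1L] != -1L) {
        ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
        ch[hits] <- "A"  # third base of the minus-strand ATG
        seq <- paste(ch, collapse = "")
        total <- total + length(hits)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(sequence = seq, count = total)
}

#' Check that a cassette carries TAG stops in all three reading frames
#'
#' @param seq DNA string (a stop cassette candidate).
#' @return `TRUE` iff TAG occurs at offsets covering all three residue classes
#'   mod 3; `FALSE` for the empty string.
#' @examples
#' verify_three_frame_stops("TAGGTAGGTAG")  # TRUE  (offsets 0, 4, 8)
#' verify_three_frame_stops("TAGTAGTAG")    # FALSE (all offsets = 0 mod 3)
#' @export
verify_three_frame_stops <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) return(FALSE)
  if (!nzchar(seq)) return(FALSE)
  hits <- gregexpr("TAG", toupper(seq), fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(FALSE)
  length(unique((hits - 1L) %% 3L)) == 3L
}

#' Scan for translatable open reading frames
#'
#' Reports every ORF that begins with ATG and ends at the first in-frame stop
#' codon (TAA/TAG/TGA), with length at least `min_aa` codons (ATG included,
#' stop excluded). ORFs without an in-frame stop are not reported. Coordinates
#' are 0-based half-open on the forward strand; minus-strand ORFs (with
#' `strands = "both"`) are mapped back to forward coordinates.
#'
#' @param seq DNA string.
#' @param min_aa Minimum ORF length in amino acids (>= 1).
#' @param strands `"forward"` or `"both"`.
#' @return `data.frame(start, end, strand, length_aa)`.
#' @export
scan_orfs <- function(seq, min_aa = 1L, strands = c("forward", "both")) {
  strands <- match.arg(strands)
  stopifnot(min_aa >= 1L)
  if (nzchar(seq)) seq <- assert_dna(seq, "seq")
  res <- orf_scan_fwd(seq)
  if (strands == "both" && nzchar(seq)) {
    L <- nchar(seq)
    rc <- orf_scan_fwd(revcomp(seq))
    if (nrow(rc)) {
      rc <- data.frame(start = L - rc$end, end = L - rc$start,
                       strand = "-", length_aa = rc$length_aa)
      res <- rbind(res, rc)
    }
  }
  res <- res[res$length_aa >= min_aa, , drop = FALSE]
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

orf_scan_fwd <- function(seq) {
  out <- data.frame(start = integer(), end = integer(),
                    strand = character(), length_aa = integer(),
                    stringsAsFactors = FALSE)
  if (!nzchar(seq)) return(out)
  starts <- gregexpr("ATG", seq, fixed = TRUE)[[1L]]
  if (starts[1L] == -1L) return(out)
  L <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  for (s in starts) {
    p <- s
    while (p + 2L <= L) {
      codon <- substr(seq, p, p + 2L)
      if (p > s && codon %in% stops) {
        out <- rbind(out, data.frame(start = s - 1L, end = p + 2L,
                                     strand = "+", length_aa = (p - s) %/% 3L,
                                     stringsAsFactors = FALSE))
        break
      }
      p <- p + 3L
    }
  }
  out
}

#' Design specification for the insulated stuffer edit series
#'
#' Bundles the raw material for [build_series()]: four 80-bp CTCF-binding
#' sites (insulators), a stop cassette with TAG codons in all three reading
#' frames, two human beta-actin intron arm sequences for the plasmid backbone,
#' and the AAV packaging-capacity limits.
#'
#' @param ctcf_sites `data.frame(site_id, sequence, placement)`; each sequence
#'   must be exactly 80 bp and placements must include `outside_mITR`,
#'   `outside_ITR`, `flanking_mITR`, `flanking_ITR`.
#' @param stop_cassette_sequence Stop cassette; must pass
#'   [verify_three_frame_stops()]. Default `"TAGGTAGGTAG"` (11 bp, TAG at
#'   offsets 0/4/8).
#' @param intron_arm_sequences List of two DNA strings: the arm placed next to
#'   the mITR and the arm placed next to the ITR. They are ATG-scrubbed during
#'   [build_series()].
#' @param capacity_limits Named numeric, packaging capacity in bp:
#'   `c(sc = 2300, ss = 4700)`.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(ctcf_sites, stop_cassette_sequence = "TAGGTAGGTAG",
                        intron_arm_sequences,
                        capacity_limits = c(sc = 2300, ss = 4700)) {
  stopifnot(is.data.frame(ctcf_sites),
            all(c("site_id", "sequence", "placement") %in% names(ctcf_sites)))
  if (!all(nchar(ctcf_sites$sequence) == 80L))
    stop("every CTCF site sequence must be exactly 80 bp", call. = FALSE)
  need <- c("outside_mITR", "outside_ITR", "flanking_mITR", "flanking_ITR")
  if (!all(need %in% ctcf_sites$placement))
    stop("ctcf_sites must cover placements: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!verify_three_frame_stops(stop_cassette_sequence))
    stop("stop_cassette_sequence must carry TAG stops in all three frames",
         call. = FALSE)
  stopifnot(length(intron_arm_sequences) == 2L,
            all(c("sc", "ss") %in% names(capacity_limits)))
  structure(list(ctcf_sites = ctcf_sites,
                 stop_cassette_sequence = assert_dna(stop_cassette_sequence),
                 intron_arm_sequences = lapply(intron_arm_sequences, assert_dna),
                 capacity_limits = capacity_limits),
            class = "design_spec")
}

#' Default design specification with synthetic stand-in sequences
#'
#' The published CTCF 80-mers (HERC2, TBC1D2B, ERCC4, and an lncRNA-derived
#' site) and the exact beta-actin intron arms live in supplementary material
#' that is not redistributed here, so this generator produces synthetic
#' stand-ins of the documented sizes: four random 80-bp sites and intron arms
#' of 2,700 bp (mITR side) and 2,402 bp (ITR side).
#'
#' @param seed Integer seed for the stand-in sequences (fixed default so the
#'   shipped series is reproducible).
#' @param arm_lengths Lengths of the two backbone intron arms.
#' @return A [design_spec()].
#' @export
default_design_spec <- function(seed = 20240626L, arm_lengths = c(2700L, 2402L)) {
  with_seed(seed, {
    sites <- data.frame(
      site_id = c("CTCF4", "CTCF11", "CTCF8", "CTCF10"),
      sequence = vapply(1:4, function(i) random_dna(80L), character(1)),
      placement = c("outside_mITR", "outside_ITR", "flanking_mITR", "flanking_ITR"),
      stringsAsFactors = FALSE)
    arms <- list(mITR_arm = random_dna(arm_lengths[1L]),
                 ITR_arm = random_dna(arm_lengths[2L]))
    design_spec(ctcf_sites = sites, intron_arm_sequences = arms)
  })
}

ctcf_seq <- function(spec, placement) {
  spec$ctcf_sites$sequence[spec$ctcf_sites$placement == placement][1L]
}

ctcf_id <- function(spec, placement) {
  spec$ctcf_sites$site_id[spec$ctcf_sites$placement == placement][1L]
}

#' Build the C2..C5 edit series from a base proviral plasmid
#'
#' Starting from the base construct (C1), the series sequentially adds:
#' \describe{
#'   \item{C2}{stop cassette + CTCF site + ATG-scrubbed 2,700-bp intron arm in
#'     the backbone adjacent to the mITR;}
#'   \item{C3}{stop cassette + CTCF site + ATG-scrubbed 2,402-bp intron arm in
#'     the backbone adjacent to the full-length ITR;}
#'   \item{C4}{stop cassette + CTCF site inside the proviral genome adjacent to
#'     the mITR;}
#'   \item{C5}{CTCF site + stop cassette inside the proviral genome adjacent to
#'     the ITR.}
#' }
#' Stop cassettes always sit between the ITR and the CTCF site. Intron arms are
#' scrubbed with [scrub_atg()] before insertion, so re-scrubbing any arm in the
#' output makes zero substitutions. ITR sequences are never modified.
#'
#' @param c1 Base proviral [plasmid_construct()] (one mITR + one ITR).
#' @param spec A [design_spec()].
#' @return Named list of constructs `C2`, `C3`, `C4`, `C5`.
#' @export
build_series <- function(c1, spec = default_design_spec()) {
  validate_proviral(c1)
  stops <- spec$stop_cassette_sequence
  arm1 <- scrub_atg(spec$intron_arm_sequences[[1L]])$sequence
  arm2 <- scrub_atg(spec$intron_arm_sequences[[2L]])$sequence

  # C2: backbone side of the mITR; element order on the circle:
  # [... arm, CTCF, stops, mITR ...]
  c2 <- insert_element(c1, stops, anchor = feature_label_for(c1, "mITR"),
                       side = "before", label = "stops_mITR_backbone",
                       role = "stop_cassette", origin = "synthetic")
  c2 <- insert_element(c2, ctcf_seq(spec, "outside_mITR"),
                       anchor = "stops_mITR_backbone", side = "before",
                       label = ctcf_id(spec, "outside_mITR"),
                       role = "CTCF_site", origin = "human")
  c2 <- insert_element(c2, arm1, anchor = ctcf_id(spec, "outside_mITR"),
                       side = "before", label = "ACTB_intron_arm_mITR",
                       role = "ACTB_intron_arm", origin = "human")
  c2$name <- "C2"

  # C3: backbone side of the full ITR: [... ITR, stops, CTCF, arm ...]
  c3 <- insert_element(c2, stops, anchor = feature_label_for(c2, "ITR"),
                       side = "after", label = "stops_ITR_backbone",
                       role = "stop_cassette", origin = "synthetic")
  c3 <- insert_element(c3, ctcf_seq(spec, "outside_ITR"),
                       anchor = "stops_ITR_backbone", side = "after",
                       label = ctcf_id(spec, "outside_ITR"),
                       role = "CTCF_site", origin = "human")
  c3 <- insert_element(c3, arm2, anchor = ctcf_id(spec, "outside_ITR"),
                       side = "after", label = "ACTB_intron_arm_ITR",
                       role = "ACTB_intron_arm", origin = "human")
  c3$name <- "C3"

  # C4: inside the proviral genome, next to the mITR: [mITR, stops, CTCF, ...]
  c4 <- insert_element(c3, stops, anchor = feature_label_for(c3, "mITR"),
                       side = "after", label = "stops_mITR_insert",
                       role = "stop_cassette", origin = "synthetic")
  c4 <- insert_element(c4, ctcf_seq(spec, "flanking_mITR"),
                       anchor = "stops_mITR_insert", side = "after",
                       label = ctcf_id(spec, "flanking_mITR"),
                       role = "CTCF_site", origin = "human")
  c4$name <- "C4"

  # C5: inside the proviral genome, next to the ITR: [..., CTCF, stops, ITR]
  c5 <- insert_element(c4, stops, anchor = feature_label_for(c4, "ITR"),
                       side = "before", label = "stops_ITR_insert",
                       role = "stop_cassette", origin = "synthetic")
  c5 <- insert_element(c5, ctcf_seq(spec, "flanking_ITR"),
                       anchor = "stops_ITR_insert", side = "before",
                       label = ctcf_id(spec, "flanking_ITR"),
                       role = "CTCF_site", origin = "human")
  c5$name <- "C5"

  list(C2 = c2, C3 = c3, C4 = c4, C5 = c5)
}

feature_label_for <- function(construct, role) {
  get_feature(construct, role = role)$label
}

#' Packaging-capacity check for the protective backbone arms
#'
#' A cross-packaged genome is anchored at an ITR and extends into the plasmid
#' backbone. The protective "arm" on each side is the contiguous run of
#' non-bacterial, non-phage backbone sequence (stop cassette, CTCF site, human
#' intron arm) adjacent to that ITR, measured outward on the circle and capped
#' at the full backbone arc. When both arms exceed the packaging capacity,
#' contaminating genomes that fit in a capsid cannot reach bacterial sequence.
#'
#' @param construct A proviral [plasmid_construct()].
#' @param mode `"sc"` (self-complementary, 2,300 bp) or `"ss"` (single-
#'   stranded, 4,700 bp).
#' @param limits Named capacity limits in bp.
#' @return `list(mode, limit, arm_lengths = c(mITR =, ITR =),
#'   arms_exceed_capacity)`.
#' @export
check_capacity <- function(construct, mode = c("sc", "ss"),
                           limits = c(sc = 2300, ss = 4700)) {
  mode <- match.arg(mode)
  ins <- validate_proviral(construct)
  L <- nchar(construct$sequence)
  limit <- unname(limits[[mode]])
  arc <- L - ins[2L]
  if (arc == 0L) {
    arms <- c(mITR = 0L, ITR = 0L)
  } else {
    omap <- base_origin_map(construct)
    protective <- !(omap %in% c("bacterial", "phage"))
    bb <- protective[(ins[2L] + 1L):L]  # backbone positions, ITR -> mITR order
    run_from <- function(v) {
      r <- rle(v)
      if (r$values[1L]) r$lengths[1L] else 0L
    }
    arms <- c(mITR = run_from(rev(bb)), ITR = run_from(bb))
  }
  list(mode = mode, limit = limit, arm_lengths = arms,
       arms_exceed_capacity = all(arms > limit))
}
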