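#' Annotated circular plasmid constructs
#'
#' A `plasmid_construct` holds an uppercase A/C/G/T sequence together with a
#' feature table (0-based, half-open coordinates) and a topology flag. Circular
#' constructs carrying an mITR feature are rotation-normalized so the mITR
#' starts at offset 0; features may not wrap the origin after normalization.
#'
#' @param name Construct name.
#' @param sequence DNA string (A/C/G/T only; ambiguity codes are rejected).
#' @param features `data.frame` with columns `label`, `role`, `start`, `end`,
#'   `strand`, `origin`. `start`/`end` are 0-based half-open offsets; `origin`
#'   is one of `bacterial`, `phage`, `human`, `viral`, `synthetic` (or `NA`).
#' @param topology `"circular"` or `"linear"`.
#' @param normalize Rotate circular constructs so the mITR starts at offset 0.
#'
#' @return An object of class `plasmid_construct`.
#' @export
plasmid_construct <- function(name, sequence, features = empty_features(),
                              topology = c("circular", "linear"),
                              normalize = TRUE) {
  topology <- match.arg(topology)
  sequence <- assert_dna(sequence, "sequence")
  L <- nchar(sequence)
  if (L < 1L) stop("sequence must have length >= 1", call. = FALSE)
  features <- validate_features(features, L)

  x <- structure(list(name = as.character(name), sequence = sequence,
                      features = features, topology = topology),
                 class = "plasmid_construct")
  if (normalize && topology == "circular" && any(features$role == "mITR")) {
    x <- rotate_construct(x, features$start[features$role == "mITR"][1L])
  }
  check_itr_pair(x$features)
  x
}

empty_features <- function() {
  data.frame(label = character(), role = character(),
             start = integer(), end = integer(),
             strand = character(), origin = character(),
             stringsAsFactors = FALSE)
}

validate_features <- function(features, L) {
  needed <- c("label", "role", "start", "end")
  if (!is.data.frame(features) || !all(needed %in% names(features)))
    stop("features must be a data.frame with columns label, role, start, end",
         call. = FALSE)
  if (is.null(features$strand)) features$strand <- rep("+", nrow(features))
  if (is.null(features$origin)) features$origin <- rep(NA_character_, nrow(features))
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (nrow(features)) {
    if (any(features$start >= features$end))
      stop("feature intervals must satisfy start < end", call. = FALSE)
    if (any(features$start < 0L) || any(features$end > L))
      stop("feature intervals must lie within [0, length)", call. = FALSE)
    if (!all(features$strand %in% c("+", "-")))
      stop("feature strand must be '+' or '-'", call. = FALSE)
    if (anyDuplicated(features$label))
      stop("feature labels must be unique", call. = FALSE)
  }
  rownames(features) <- NULL
  features[, c("label", "role", "start", "end", "strand", "origin")]
}

check_itr_pair <- function(features) {
  n_itr <- sum(features$role == "ITR")
  n_mitr <- sum(features$role == "mITR")
  if (n_itr > 1L || n_mitr > 1L)
    stop("at most one feature each of role 'ITR' and 'mITR' is allowed", call. = FALSE)
  if (n_itr == 1L && n_mitr == 1L) {
    a <- features[features$role == "mITR", ]
    b <- features[features$role == "ITR", ]
    if (a$start < b$end && b$start < a$end)
      stop("ITR and mITR features must not overlap", call. = FALSE)
  }
  invisible(TRUE)
}

# rotate a circular construct so position `offset` becomes position 0
rotate_construct <- function(x, offset) {
  stopifnot(inherits(x, "plasmid_construct"))
  L <- nchar(x$sequence)
  offset <- as.integer(offset %% L)
  if (offset == 0L) return(x)
  if (x$topology != "circular")
    stop("only circular constructs can be rotated", call. = FALSE)
  x$sequence <- paste0(substr(x$sequence, offset + 1L, L),
                       substr(x$sequence, 1L, offset))
  if (nrow(x$features)) {
    w <- x$features$end - x$features$start
    s <- (x$features$start - offset) %% L
    if (any(s + w > L))
      stop("a feature would wrap the origin after rotation; wrap-around features are forbidden",
           call. = FALSE)
    x$features$start <- as.integer(s)
    x$features$end <- as.integer(s + w)
    x$features <- x$features[order(x$features$start), , drop = FALSE]
    rownames(x$features) <- NULL
  }
  x
}

#' @export
print.plasmid_construct <- function(x, ...) {
  cat(sprintf("<plasmid_construct> %s: %d bp, %s, %d features\n",
              x$name, nchar(x$sequence), x$topology, nrow(x$features)))
  if (nrow(x$features)) print(x$features, row.names = FALSE)
  invisible(x)
}

#' @export
length.plasmid_construct <- function(x) nchar(x$sequence)

#' Look up a feature by label or role
#'
#' @param construct A [plasmid_construct()].
#' @param label,role Exactly one of the two must be given; the match must be
#'   unique.
#' @return One-row `data.frame` (the feature).
#' @export
get_feature <- function(construct, label = NULL, role = NULL) {
  stopifnot(inherits(construct, "plasmid_construct"))
  f <- construct$features
  if (!is.null(label)) hit <- f[f$label == label, , drop = FALSE]
  else if (!is.null(role)) hit <- f[f$role == role, , drop = FALSE]
  else stop("give either label= or role=", call. = FALSE)
  what <- if (!is.null(label)) label else role
  if (nrow(hit) == 0L) stop("feature not found: ", what, call. = FALSE)
  if (nrow(hit) > 1L) stop("feature lookup is ambiguous: ", what, call. = FALSE)
  hit
}

#' ITR-to-ITR insert interval of a proviral construct
#'
#' The insert runs from the outer edge of the mITR (offset 0 after rotation
#' normalization) to the outer edge of the full-length ITR; both ITR sequences
#' count as insert. The complement of this interval on the circle is the
#' plasmid backbone.
#'
#' @param construct A normalized circular [plasmid_construct()] with one mITR
#'   and one ITR feature.
#' @return Integer vector `c(start, end)`, 0-based half-open.
#' @export
insert_interval <- function(construct) {
  mitr <- get_feature(construct, role = "mITR")
  itr <- get_feature(construct, role = "ITR")
  if (mitr$start != 0L)
    stop("construct is not rotation-normalized (mITR must start at offset 0)", call. = FALSE)
  c(0L, itr$end)
}

validate_proviral <- function(construct) {
  stopifnot(inherits(construct, "plasmid_construct"))
  if (construct$topology != "circular")
    stop("a proviral construct must be circular", call. = FALSE)
  if (sum(construct$features$role == "ITR") != 1L ||
      sum(construct$features$role == "mITR") != 1L)
    stop("a proviral construct needs exactly one ITR and one mITR feature", call. = FALSE)
  invisible(insert_interval(construct))
}

# per-base origin labels (length L). Unannotated backbone bases default to
# "bacterial" (vector sequence); unannotated insert bases to "synthetic".
base_origin_map <- function(construct) {
  L <- nchar(construct$sequence)
  map <- rep(NA_character_, L)
  f <- construct$features
  for (i in seq_len(nrow(f))) {
    o <- f$origin[i]
    if (!is.na(o)) map[(f$start[i] + 1L):f$end[i]] <- o
  }
  ins <- tryCatch(insert_interval(construct), error = function(e) NULL)
  if (!is.null(ins)) {
    idx_ins <- seq_len(L) <= ins[2]
    map[is.na(map) & idx_ins] <- "synthetic"
    map[is.na(map) & !idx_ins] <- "bacterial"
  } else {
    map[is.na(map)] <- "bacterial"
  }
  map
}

#' Insert a sequence element at a feature-anchored position
#'
#' Splices `element_seq` into the construct immediately before or after the
#' anchor feature, shifts all downstream feature coordinates, annotates the
#' inserted element, and re-normalizes the rotation. ITR/mITR sequences are
#' never modified. Inserting an empty string returns the construct unchanged.
#'
#' @param construct A [plasmid_construct()].
#' @param element_seq DNA string to insert (may be `""`).
#' @param anchor Label of an existing, unique feature.
#' @param side `"before"` or `"after"` the anchor.
#' @param label,role,strand,origin Annotation for the inserted element.
#' @return The edited [plasmid_construct()].
#' @export
insert_element <- function(construct, element_seq, anchor,
                           side = c("after", "before"),
                           label = NULL, role = "inserted",
                           strand = "+", origin = "synthetic") {
  side <- match.arg(side)
  stopifnot(inherits(construct, "plasmid_construct"))
  element_seq <- assert_dna0(element_seq, "element_seq")
  len <- nchar(element_seq)
  if (len == 0L) return(construct)
  hit <- get_feature(construct, label = anchor)
  point <- if (side == "before") hit$start else hit$end

  f <- construct$features
  splits <- f$start < point & f$end > point
  if (any(splits))
    stop("insertion point would split feature(s): ",
         paste(f$label[splits], collapse = ", "), call. = FALSE)

  L <- nchar(construct$sequence)
  seq2 <- paste0(substr(construct$sequence, 1L, point), element_seq,
                 substr(construct$sequence, point + 1L, L))
  shift <- f$start >= point
  f$start[shift] <- f$start[shift] + len
  f$end[f$end > point] <- f$end[f$end > point] + len

  if (is.null(label)) label <- paste0(role, "_", nrow(f) + 1L)
  f <- rbind(f, data.frame(label = label, role = role,
                           start = point, end = point + len,
                           strand = strand, origin = origin,
                           stringsAsFactors = FALSE))
  plasmid_construct(construct$name, seq2, f, construct$topology)
}

# like assert_dna but permits the empty string
assert_dna0 <- function(seq, what) {
  if (identical(seq, "")) return(seq)
  assert_dna(seq, what)
}

#' Read/write constructs as FASTA plus a feature TSV
#'
#' The TSV carries columns `label`, `role`, `start`, `end`, `strand`, `origin`
#' with 0-based half-open coordinates.
#'
#' @param construct A [plasmid_construct()].
#' @param fasta,tsv File paths.
#' @param topology Topology to assume when reading.
#' @name construct_io
NULL

#' @rdname construct_io
#' @export
write_construct <- function(construct, fasta, tsv) {
  s <- Biostrings::DNAStringSet(construct$sequence)
  names(s) <- construct$name
  Biostrings::writeXStringSet(s, fasta)
  utils::write.table(construct$features, tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(construct)
}

#' @rdname construct_io
#' @export
read_construct <- function(fasta, tsv, topology = "circular") {
  s <- Biostrings::readDNAStringSet(fasta)
  feats <- utils::read.delim(tsv, stringsAsFactors = FALSE)
  plasmid_construct(names(s)[1L], as.character(s[[1L]]), feats, topology)
}

#' Write a construct as a minimal GenBank flat file
#'
#' Features are emitted as `misc_feature` entries (1-based inclusive spans)
#' with `/label` and a `role=...; origin=...` `/note`.
#'
#' @param construct A [plasmid_construct()].
#' @param path Output file path.
#' @export
write_genbank <- function(construct, path) {
  L <- nchar(construct$sequence)
  topo <- if (construct$topology == "circular") "circular" else "linear"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %-17s %d bp    DNA     %-8s SYN",
                     construct$name, L, topo), con)
  writeLines(sprintf("DEFINITION  %s", construct$name), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  f <- construct$features
  for (i in seq_len(nrow(f))) {
    loc <- sprintf("%d..%d", f$start[i] + 1L, f$end[i])
    if (f$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     misc_feature    %s", loc), con)
    writeLines(sprintf("                     /label=\"%s\"", f$label[i]), con)
    writeLines(sprintf("                     /note=\"role=%s; origin=%s\"",
                       f$role[i],
                       ifelse(is.na(f$origin[i]), "NA", f$origin[i])), con)
  }
  writeLines("ORIGIN", con)
  for (s in seq(1L, L, by = 60L)) {
    chunk <- substr(construct$sequence, s, min(s + 59L, L))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", s, tolower(paste(blocks, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(construct)
}

#' Read a construct from a (minimal) GenBank flat file
#'
#' Understands the subset written by [write_genbank()]: `LOCUS` topology,
#' `misc_feature` spans with `/label` and `role=...; origin=...` notes, and the
#' `ORIGIN` sequence block.
#'
#' @param path GenBank file path.
#' @return A [plasmid_construct()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  locus <- lines[grepl("^LOCUS", lines)][1L]
  name <- strsplit(trimws(sub("^LOCUS", "", locus)), "[[:space:]]+")[[1L]][1L]
  topology <- if (grepl("circular", locus)) "circular" else "linear"

  ori_at <- which(grepl("^ORIGIN", lines))[1L]
  seq_lines <- lines[(ori_at + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^acgtnACGTN]", "", paste(seq_lines, collapse = "")))

  feats <- empty_features()
  i <- which(grepl("^FEATURES", lines))[1L] + 1L
  while (i < ori_at) {
    ln <- lines[i]
    if (grepl("^     \\S", ln)) {
      loc <- trimws(sub("^     \\S+", "", ln))
      strand <- if (grepl("complement", loc)) "-" else "+"
      nums <- as.integer(strsplit(gsub("[^0-9.]", "", loc), "\\.\\.")[[1L]])
      lab <- role <- origin <- NA_character_
      j <- i + 1L
      while (j < ori_at && grepl("^                     /", lines[j])) {
        q <- trimws(lines[j])
        if (grepl("^/label=", q)) lab <- gsub("^/label=\"|\"$", "", q)
        if (grepl("^/note=", q)) {
          note <- gsub("^/note=\"|\"$", "", q)
          role <- sub(".*role=([^;\"]+).*", "\\1", note)
          origin <- sub(".*origin=([^;\"]+).*", "\\1", note)
        }
        j <- j + 1L
      }
      if (identical(origin, "NA")) origin <- NA_character_
      feats <- rbind(feats, data.frame(
        label = lab, role = trimws(role), start = nums[1L] - 1L, end = nums[2L],
        strand = strand, origin = trimws(origin), stringsAsFactors = FALSE))
      i <- j
    } else i <- i + 1L
  }
  plasmid_construct(name, sequence, feats, topology)
}
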