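test_that("scrub_atg destroys start codons by G->T and counts substitutions", {
  expect_equal(scrub_atg("CATCAT"), list(sequence = "CATCAT", count = 0L))
  expect_equal(scrub_atg("ATGATG"), list(sequence = "ATTATT", count = 2L))
  expect_equal(scrub_atg("GGATGG"), list(sequence = "GGATTG", count = 1L))
  expect_error(scrub_atg("ATGN"), "ambiguity")
})

test_that("scrub_atg is idempotent and leaves no forward ATG on random input", {
  set.seed(401)
  for (i in 1:200) {
    s <- provpack:::random_dna(sample(10:300, 1))
    r1 <- scrub_atg(s)
    expect_false(grepl("ATG", r1$sequence, fixed = TRUE))
    expect_equal(nchar(r1$sequence), nchar(s))
    r2 <- scrub_atg(r1$sequence)
    expect_identical(r2$sequence, r1$sequence)
    expect_equal(r2$count, 0L)
    # every change is a single-base G->T substitution
    a <- strsplit(s, "")[[1]]; b <- strsplit(r1$sequence, "")[[1]]
    diff <- which(a != b)
    expect_true(all(a[diff] == "G" & b[diff] == "T"))
    expect_equal(length(diff), r1$count)
  }
})

test_that("scrub_atg strands='both' also clears reverse-strand start codons", {
  set.seed(402)
  for (i in 1:50) {
    s <- provpack:::random_dna(sample(10:200, 1))
    r <- scrub_atg(s, strands = "both")
    expect_false(grepl("ATG", r$sequence, fixed = TRUE))
    expect_false(grepl("CAT", r$sequence, fixed = TRUE))
  }
})

test_that("three-frame stop verification covers all residue classes mod 3", {
  expect_true(verify_three_frame_stops("TAGGTAGGTAG"))   # offsets 0, 4, 8
  expect_false(verify_three_frame_stops("TAGTAGTAG"))    # all offsets = 0 mod 3
  expect_false(verify_three_frame_stops(""))
  expect_false(verify_three_frame_stops("AAAA"))
  # brute-force offset scan agrees on random cassettes
  set.seed(403)
  for (i in 1:100) {
    s <- provpack:::random_dna(sample(3:60, 1))
    hits <- which(vapply(seq_len(nchar(s) - 2), function(p)
      substr(s, p, p + 2) == "TAG", logical(1)))
    expect_equal(verify_three_frame_stops(s),
                 length(unique((hits - 1) %% 3)) == 3)
  }
})

test_that("scan_orfs reports ATG..stop spans and respects min_aa", {
  expect_equal(scan_orfs("ATGAAATAG", min_aa = 2),
               data.frame(start = 0L, end = 9L, strand = "+", length_aa = 2L))
  expect_equal(nrow(scan_orfs("CCCCCC")), 0L)
  expect_equal(nrow(scan_orfs("ATGAAATAG", min_aa = 3)), 0L)
  # an ORF without an in-frame stop is not reported
  expect_equal(nrow(scan_orfs("ATGAAAAAA")), 0L)
  # scrubbed output has no forward ORFs at all
  set.seed(404)
  for (i in 1:25) {
    s <- scrub_atg(provpack:::random_dna(300))$sequence
    expect_equal(nrow(scan_orfs(s, min_aa = 1)), 0L)
  }
  # minus-strand ORF is found and mapped back to forward coordinates
  both <- scan_orfs(provpack:::revcomp("ATGAAATAG"), min_aa = 2, strands = "both")
  expect_equal(both$strand, "-")
  expect_equal(c(both$start, both$end), c(0L, 9L))
})

test_that("the edit series adds stop cassettes, insulators and scrubbed arms", {
  c1 <- synthetic_c1()
  expect_equal(length(c1), 5575L)
  spec <- default_design_spec()
  series <- build_series(c1, spec)
  lens <- vapply(series, length, integer(1))
  expect_equal(unname(lens),
               5575L + cumsum(c(11L + 80L + 2700L, 11L + 80L + 2402L, 91L, 91L)))
  expect_true(all(diff(c(5575L, lens)) > 0))

  # CTCF/arm feature counts grow as 2, 4, 5, 6 along the series
  n_ca <- vapply(series, function(x)
    sum(x$features$role %in% c("CTCF_site", "ACTB_intron_arm")), integer(1))
  expect_equal(unname(n_ca), c(2L, 4L, 5L, 6L))

  # ITR sequences byte-identical to the input ITRs
  for (role in c("ITR", "mITR")) {
    f0 <- get_feature(c1, role = role)
    s0 <- substr(c1$sequence, f0$start + 1, f0$end)
    for (x in series) {
      f <- get_feature(x, role = role)
      expect_identical(substr(x$sequence, f$start + 1, f$end), s0)
    }
  }

  # every intron arm in the output is already ATG-free (re-scrub count 0)
  c5 <- series$C5
  for (lab in c("ACTB_intron_arm_mITR", "ACTB_intron_arm_ITR")) {
    f <- get_feature(c5, label = lab)
    expect_gte(f$end - f$start, 2402L)
    expect_equal(scrub_atg(substr(c5$sequence, f$start + 1, f$end))$count, 0L)
  }

  # all four stop cassettes carry stops in all three frames
  stops <- c5$features[c5$features$role == "stop_cassette", ]
  expect_equal(nrow(stops), 4L)
  for (i in seq_len(4)) {
    expect_true(verify_three_frame_stops(
      substr(c5$sequence, stops$start[i] + 1, stops$end[i])))
  }

  # insert-side additions total ~180 bp (two cassettes + two 80-bp sites)
  expect_equal(insert_interval(c5)[2] - insert_interval(c1)[2], 182L)
})

test_that("capacity check measures protective arms and compares to the limit", {
  c1 <- synthetic_c1()
  series <- build_series(c1, default_design_spec())
  r5 <- check_capacity(series$C5, "sc")
  expect_equal(unname(r5$arm_lengths), c(11L + 80L + 2700L, 11L + 80L + 2402L))
  expect_true(r5$arms_exceed_capacity)
  expect_false(check_capacity(series$C5, "ss")$arms_exceed_capacity)
  r1 <- check_capacity(c1, "ss")
  expect_equal(unname(r1$arm_lengths), c(0L, 0L))
  expect_false(r1$arms_exceed_capacity)
  # degenerate construct: ITRs adjacent, no backbone
  f <- data.frame(label = c("m", "i"), role = c("mITR", "ITR"),
                  start = c(0L, 30L), end = c(30L, 60L), strand = "+",
                  origin = "viral")
  deg <- plasmid_construct("deg", strrep("ACGT", 15), f)
  rd <- check_capacity(deg, "sc")
  expect_equal(unname(rd$arm_lengths), c(0L, 0L))
  expect_false(rd$arms_exceed_capacity)
})

test_that("capacity arms agree with a brute-force walk on rotated constructs", {
  brute_arms <- function(x) {
    L <- length(x); ie <- insert_interval(x)[2]
    origin <- rep(NA_character_, L)
    f <- x$features
    for (i in seq_len(nrow(f)))
      origin[(f$start[i] + 1):f$end[i]] <- f$origin[i]
    origin[is.na(origin) & seq_len(L) > ie] <- "bacterial"
    walk <- function(pos_seq) {
      n <- 0L
      for (p in pos_seq) {
        if (origin[p] %in% c("bacterial", "phage")) break
        n <- n + 1L
      }
      n
    }
    if (ie == L) return(c(0L, 0L))
    c(walk(L:(ie + 1)), walk((ie + 1):L))
  }
  series <- build_series(synthetic_c1(), default_design_spec())
  set.seed(405)
  for (x in list(synthetic_c1(), series$C2, series$C5)) {
    # rotation offsets that do not land strictly inside a feature
    f <- x$features
    inside <- unlist(mapply(function(s, e) seq(s + 1L, e - 1L),
                            f$start, f$end, SIMPLIFY = FALSE))
    allowed <- setdiff(seq_len(length(x) - 1L), inside)
    for (r in sample(allowed, 3)) {
      rot <- provpack:::rotate_construct(x, r)
      renorm <- plasmid_construct(rot$name, rot$sequence, rot$features)
      expect_equal(unname(check_capacity(renorm, "sc")$arm_lengths),
                   brute_arms(renorm))
    }
  }
})

test_that("design_spec validates its raw material", {
  sites <- data.frame(site_id = paste0("s", 1:4),
                      sequence = vapply(1:4, function(i)
                        provpack:::with_seed(i, provpack:::random_dna(80)), ""),
                      placement = c("outside_mITR", "outside_ITR",
                                    "flanking_mITR", "flanking_ITR"))
  arms <- list(a = strrep("AC", 50), b = strrep("GT", 50))
  expect_s3_class(design_spec(sites, intron_arm_sequences = arms), "design_spec")
  bad <- sites; bad$sequence[1] <- "ACGT"
  expect_error(design_spec(bad, intron_arm_sequences = arms), "80 bp")
  expect_error(design_spec(sites, stop_cassette_sequence = "TAGTAGTAG",
                           intron_arm_sequences = arms), "three frames")
})
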