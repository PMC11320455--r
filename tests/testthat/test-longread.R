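lr_fixture <- function(n = 400, seed = 61, error_rate = 0,
                       total_truncation_prob = 0.5) {
  x <- tiny_proviral(); panel <- tiny_panel()
  m <- prep_model(x, panel$repcap, panel$phelper, panel$host,
                  error_rate = error_rate,
                  total_truncation_prob = total_truncation_prob)
  prep <- simulate_prep(m, n, seed = seed)
  reads <- emit_long_reads(prep, seed = seed + 1)
  list(construct = x, model = m, prep = prep, reads = reads)
}

test_that("the seed aligner recovers exact intervals on both strands", {
  fx <- lr_fixture(200)
  aln <- align_long_reads(fx$reads, fx$construct, k = 15)
  tt <- fx$prep$truth
  cons <- tt$source_ref == "construct"
  expect_true(all(aln$aligned[cons]))
  expect_equal(aln$ref_start[cons] %% length(fx$construct),
               tt$start[cons] %% length(fx$construct))
  expect_equal(aln$ref_end[cons] - aln$ref_start[cons],
               tt$end[cons] - tt$start[cons])
  expect_identical(aln$strand[cons], tt$strand[cons])
})

test_that("breakpoints equal planted truncation positions; full reads have none", {
  fx <- lr_fixture(400)
  ins <- fx$reads[fx$prep$truth$category == "insert"]
  lb <- locate_breakpoints(ins, fx$construct, k = 15)
  tt <- fx$prep$truth[fx$prep$truth$category == "insert", ]
  planted <- tt[!is.na(tt$breakpoint), c("genome_id", "breakpoint")]
  got <- lb$breakpoints[order(lb$breakpoints$read_id), ]
  expect_equal(got$read_id, sort(planted$genome_id))
  expect_equal(got$position,
               planted$breakpoint[order(planted$genome_id)])
  # untruncated genomes contribute no breakpoints at all
  full <- setdiff(tt$genome_id, planted$genome_id)
  expect_length(intersect(full, lb$breakpoints$read_id), 0)
})

test_that("reads without a usable anchor are skipped and counted", {
  fx <- lr_fixture(50)
  cons <- which(fx$prep$truth$source_ref == "construct")[1:5]
  reads <- c(fx$reads[cons], junk = strrep("A", 80), tiny = "ACGTA")
  lb <- locate_breakpoints(reads, fx$construct, k = 15)
  expect_equal(lb$n_skipped, 2L)
  expect_equal(lb$n_aligned, 5L)
})

test_that("hotspot calling merges nearby ends and applies the threshold", {
  # a site at 0.11% frequency is not a hotspot at the 1% threshold
  ends <- data.frame(position = 500L, count = 2217L)
  expect_equal(nrow(call_hotspots(ends, 2050198L, threshold = 0.01)), 0L)
  hs <- call_hotspots(ends, 2050198L, threshold = 0.001)
  expect_equal(round(100 * hs$frequency, 2), 0.11)
  # ends within +/-5 bp merge into one site at the modal position
  ends2 <- data.frame(position = c(98L, 100L, 103L, 300L),
                      count = c(5L, 50L, 5L, 40L))
  hs2 <- call_hotspots(ends2, 100L, threshold = 0.01)
  expect_equal(hs2$position, c(100L, 300L))
  expect_equal(hs2$count, c(60L, 40L))
  # hotspot calls are monotone non-increasing in the threshold
  set.seed(601)
  ends3 <- data.frame(position = sample(1000, 50), count = rpois(50, 20) + 1L)
  ths <- c(0, 0.005, 0.01, 0.02, 0.1)
  ncalls <- vapply(ths, function(t) nrow(call_hotspots(ends3, 2000L, t)), 1L)
  expect_true(all(diff(ncalls) <= 0))
})

test_that("uniform random ends produce no 1% hotspots on a long reference", {
  set.seed(602)
  pos <- sample(2000L, 5000L, replace = TRUE)
  tab <- as.data.frame(table(pos), stringsAsFactors = FALSE)
  ends <- data.frame(position = as.integer(tab$pos), count = tab$Freq)
  expect_equal(nrow(call_hotspots(ends, 5000L, threshold = 0.01)), 0L)
})

test_that("planted hotspots and promoter loss are recovered from long reads", {
  fx <- lr_fixture(4000, error_rate = 0.001)
  ins <- fx$reads[fx$prep$truth$category == "insert"]
  tp <- truncation_profile(ins, fx$construct, k = 15)
  expect_setequal(tp$hotspots$position, fx$model$truncation_hotspots$position)
  n <- tp$total_reads
  expect_lt(abs(tp$fraction_truncated - 0.5), 3 * sqrt(0.25 / n))
  # both hotspots sit between U6 start and the ITR, so every truncation
  # removes the promoter
  expect_equal(tp$fraction_missing_promoter, tp$fraction_truncated)
  # per-site fraction for the hairpin: planted breakpoints flank it, never hit it
  expect_equal(unname(tp$site_fractions["mi405"]), 0)
})

test_that("promoter_loss_fraction is 0 for full reads and errors on empty input", {
  fx <- lr_fixture(100, total_truncation_prob = 0)
  ins <- fx$reads[fx$prep$truth$category == "insert"]
  expect_equal(promoter_loss_fraction(ins, fx$construct, k = 15), 0)
  expect_error(promoter_loss_fraction(character(0), fx$construct), "no aligned")
})

test_that("origin composition: all-bacterial backbone gives fraction 1", {
  fx <- lr_fixture(800)
  bb <- fx$reads[fx$prep$truth$category == "backbone"]
  expect_gt(length(bb), 5)
  comp <- composition(bb, fx$construct, k = 15)
  expect_equal(unname(comp$fractions["bacterial_phage"]), 1)
  expect_equal(sum(comp$fractions), 1)
  expect_error(composition(character(0), fx$construct), "composition undefined")
})

test_that("composition recovers a planted 70/30 human/bacterial backbone", {
  x <- composition_construct()
  panel <- tiny_panel()
  m <- prep_model(x, panel$repcap, panel$phelper, panel$host,
                  category_probs = c(insert = 0, backbone = 1, repcap = 0,
                                     phelper = 0, host = 0),
                  truncation_hotspots = data.frame(position = 150L, weight = 1),
                  error_rate = 0.001)
  prep <- simulate_prep(m, 300, seed = 71)
  reads <- emit_long_reads(prep, seed = 72)
  comp <- composition(reads, x, k = 15)
  q <- 700 / 1000
  tol <- 3 * sqrt(q * (1 - q) / comp$n_reads_used) + 1e-9
  expect_lt(abs(comp$fractions[["human"]] - q), tol)
  expect_lt(abs(comp$fractions[["bacterial_phage"]] - (1 - q)), tol)
  # invariant to read order and reverse-complementation
  shuf <- sample(reads)
  expect_equal(composition(shuf, x, k = 15)$fractions, comp$fractions)
  rc <- stats::setNames(provpack:::revcomp(reads), names(reads))
  expect_equal(composition(rc, x, k = 15)$fractions, comp$fractions)
})

test_that("precomputed alignment intervals (PAF-style) drive the profiler", {
  fx <- lr_fixture(200)
  aln <- align_long_reads(fx$reads, fx$construct, k = 15)
  paf <- tempfile(fileext = ".paf")
  ok <- aln[aln$aligned, ]
  write.table(data.frame(ok$read_id, ok$width, 0L, ok$width, ok$strand,
                         "construct", length(fx$construct) * 2L,
                         ok$ref_start, ok$ref_end, ok$width, ok$width, 60L),
              paf, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  ingested <- read_paf_intervals(paf)
  lb1 <- locate_breakpoints(ingested, fx$construct)
  lb2 <- locate_breakpoints(fx$reads, fx$construct, k = 15)
  expect_equal(lb1$breakpoints[order(lb1$breakpoints$read_id), ],
               lb2$breakpoints[order(lb2$breakpoints$read_id), ],
               ignore_attr = TRUE)
})
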