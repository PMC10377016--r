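test_that("overlap counting matches the exhaustive all-pairs oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    frags <- random_fragments(300)
    wins <- random_windows(30)
    fast <- count_fragments_in_windows(frags, wins)
    expect_identical(unname(as.numeric(fast)), brute_force_counts(frags, wins))
  }
})

test_that("counting respects half-open intervals and empty input", {
  win <- data.frame(gene_id = "w1", chrom = "chr1", start = 200, end = 300)
  abut <- data.frame(chrom = "chr1", start = 100, end = 200)
  expect_equal(unname(count_fragments_in_windows(abut, win)), 0L)
  touch <- data.frame(chrom = "chr1", start = 100, end = 201)
  expect_equal(unname(count_fragments_in_windows(touch, win)), 1L)

  none <- data.frame(chrom = character(0), start = integer(0),
                     end = integer(0))
  expect_equal(unname(count_fragments_in_windows(none, win)), 0L)

  other <- data.frame(chrom = "chr2", start = 250, end = 260)
  expect_warning(n <- count_fragments_in_windows(other, win), "chr1")
  expect_equal(unname(n), 0L)
})

test_that("counting is order-independent and monotone", {
  set.seed(11)
  frags <- random_fragments(500)
  wins <- random_windows(20)
  base <- count_fragments_in_windows(frags, wins)

  perm <- frags[sample(nrow(frags)), ]
  expect_equal(count_fragments_in_windows(perm, wins), base)
  wperm <- sample(nrow(wins))
  expect_equal(count_fragments_in_windows(frags, wins[wperm, ])[order(wperm)],
               base)

  # adding a fragment never decreases any count
  more <- rbind(frags, data.frame(chrom = "chr1", start = 0, end = 10000))
  expect_true(all(count_fragments_in_windows(more, wins) >= base))
  # widening a window never decreases its count
  wider <- wins; wider$start <- wider$start - 500; wider$end <- wider$end + 500
  expect_true(all(count_fragments_in_windows(frags, wider) >= base))
})

test_that("midpoint counting only admits fragments whose centre falls inside", {
  win <- data.frame(gene_id = "w1", chrom = "chr1", start = 200, end = 300)
  # overlaps by its tail but midpoint (150) outside
  f <- data.frame(chrom = "chr1", start = 90, end = 210)
  expect_equal(unname(count_fragments_in_windows(f, win, method = "any")), 1L)
  expect_equal(unname(count_fragments_in_windows(f, win, method = "midpoint")), 0L)
})

test_that("RPM normalization scales by library size and inverts", {
  expect_equal(to_rpm(5, 1e6), 5)
  expect_equal(to_rpm(0, 123), 0)
  set.seed(2)
  counts <- rpois(100, 40); lib <- 3.7e6
  expect_equal(to_rpm(counts, lib) * lib / 1e6, counts, tolerance = 1e-12)
  expect_error(to_rpm(1, 0), "positive")
  expect_error(to_rpm(1, -5), "positive")
})

test_that("input normalization follows the ratio-with-pseudocount rule", {
  expect_equal(as.numeric(input_normalize(2, 1, pseudocount = 0)), 2)
  expect_equal(as.numeric(input_normalize(2, 0, pseudocount = 0.1)), 20)
  expect_equal(as.numeric(input_normalize(0, 3, pseudocount = 0)), 0)

  # zero input with zero pseudocount is missing, not infinite
  q <- input_normalize(c(2, 1), c(0, 1), pseudocount = 0)
  expect_true(is.na(q[1]))
  expect_equal(attr(q, "reason")[1], "zero_input")

  # the input-coverage quality gate marks cells missing
  q2 <- input_normalize(c(2, 2), c(1, 1), input_raw = c(3, 10),
                        min_input_raw = 5)
  expect_true(is.na(q2[1]) && !is.na(q2[2]))
  expect_equal(attr(q2, "reason")[1], "inadequate_input")
  expect_error(input_normalize(1, 1, pseudocount = -1), ">= 0")
})

test_that("signal matrix reproduces hand-computed Q values", {
  rec <- toy_records(c("tRNA-Gly-GCC-1-1", "tRNA-Ala-AGC-1-1"),
                     start = c(1000L, 9000L), gene_len = 72L)
  # windows: [536,1536) and [8536,9536)
  chip <- data.frame(
    chrom = "chr1",
    start = c(600, 700, 1500, 8600, 20000),
    end = c(800, 900, 1700, 8800, 20200))   # 3 in w1, 1 in w2, 1 outside
  input <- data.frame(
    chrom = "chr1",
    start = c(600, 1000, 8600, 8700, 8800, 30000),
    end = c(800, 1200, 8800, 8900, 9000, 30200))  # 2 in w1, 3 in w2
  cohort <- list(
    sheet = data.frame(sample_id = "s1", condition = "primary",
                       chip = NA, input = NA),
    chip = list(s1 = fragment_source("s1", chip)),
    input = list(s1 = fragment_source("s1_input", input)))
  m <- build_signal_matrix(cohort, rec, pseudocount = 0.5, min_input_raw = 2)
  # chip library 5, input library 6
  q1 <- (3e6 / 5) / (2e6 / 6 + 0.5)
  q2 <- (1e6 / 5) / (3e6 / 6 + 0.5)
  expect_equal(m["tRNA-Gly-GCC-1-1", "s1"], q1)
  expect_equal(m["tRNA-Ala-AGC-1-1", "s1"], q2)
  expect_equal(attr(m, "library_sizes")$chip_library, 5)

  # Q values invariant under duplicating the whole library
  dup <- list(sheet = cohort$sheet,
              chip = list(s1 = fragment_source("s1", rbind(chip, chip))),
              input = list(s1 = fragment_source("s1", rbind(input, input))))
  m2 <- build_signal_matrix(dup, rec, pseudocount = 0.5, min_input_raw = 2)
  expect_equal(unname(m2[, 1]), unname(m[, 1]), tolerance = 1e-12)
})

test_that("signal matrix handles empty libraries, ordering and pairing", {
  rec <- toy_records(c("tRNA-Gly-GCC-1-1", "tRNA-Ala-AGC-1-1"),
                     start = c(9000L, 1000L))  # deliberately unsorted
  emptyf <- data.frame(chrom = character(0), start = integer(0),
                       end = integer(0))
  somef <- data.frame(chrom = "chr1", start = 1000, end = 1200)
  cohort <- list(
    sheet = data.frame(sample_id = c("m1", "p1"),
                       condition = c("metastatic", "primary"),
                       chip = NA, input = NA),
    chip = list(p1 = fragment_source("p1", emptyf),
                m1 = fragment_source("m1", somef)),
    input = list(p1 = fragment_source("p1", somef),
                 m1 = fragment_source("m1", somef)))
  m <- build_signal_matrix(cohort, rec, min_input_raw = 1)
  # primary column first, rows in genomic order
  expect_equal(colnames(m), c("p1", "m1"))
  expect_equal(rownames(m), c("tRNA-Ala-AGC-1-1", "tRNA-Gly-GCC-1-1"))
  # zero-fragment chip library -> whole column missing with a reason
  expect_true(all(is.na(m[, "p1"])))
  expect_true(all(attr(m, "missing_reason")[, "p1"] == "empty_library"))

  broken <- cohort; broken$chip$m1 <- NULL
  expect_error(build_signal_matrix(broken, rec), "pairing")
})

test_that("fragments are reconstructed from SAM in both read modes", {
  sam <- write_toy_sam()
  src <- read_fragments(sam, sample_id = "t", format = "sam",
                        read_mode = "paired_fragment")
  # two usable templates; unmapped/secondary/duplicate records dropped
  expect_equal(src$library_size, 2)
  expect_equal(src$fragments$start, c(999, 4999))
  expect_equal(src$fragments$end, c(1199, 5300))

  dup <- read_fragments(sam, format = "sam", keep_duplicates = TRUE)
  expect_equal(dup$library_size, 3)

  single <- read_fragments(write_toy_sam_single(), format = "sam",
                           read_mode = "single_end_extended",
                           fragment_length = 200)
  expect_equal(single$fragments$start, c(1000, 1850))
  expect_equal(single$fragments$end, c(1200, 2050))
})

test_that("fragment BED files round-trip through the reader", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t300", "chr2\t0\t200\tname\t0\t+"), path)
  src <- read_fragments(path, sample_id = "b")
  expect_equal(src$fragments$start, c(100, 0))
  expect_equal(src$library_size, 2)
  expect_error(fragment_source("x", src$fragments, library_size = 1),
               "smaller")

  empty <- tempfile(fileext = ".bed"); file.create(empty)
  expect_equal(read_fragments(empty)$library_size, 0)
})
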