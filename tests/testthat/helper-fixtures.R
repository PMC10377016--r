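# Fixtures are built in code at test time; nothing is read from disk that a
# test did not itself write.

# Write a BED6 of toy genes and load it through the public reader.
toy_records <- function(gene_id, chrom = "chr1", start = NULL,
                        spacing = 3000L, gene_len = 72L) {
  n <- length(gene_id)
  if (is.null(start)) start <- 1000L + (seq_len(n) - 1L) * spacing
  chrom <- rep_len(chrom, n)
  bed <- data.frame(chrom, start, start + gene_len, gene_id, 0L, "+")
  path <- tempfile(fileext = ".bed")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  load_gene_table(path, format = "bed")
}

# Random full signal matrix with parseable gtRNAdb-style rownames.
random_signal_matrix <- function(n_iso = 4, fam_per_iso = 2, members = 3,
                                 n_samples = 5, seed = 1) {
  set.seed(seed)
  cfg <- synthetic_config(seed = seed, n_isotypes = n_iso,
                          n_families = n_iso * fam_per_iso,
                          members_per_family = members)
  rec <- make_annotation(cfg)
  m <- matrix(rlnorm(nrow(rec) * n_samples), nrow(rec), n_samples,
              dimnames = list(rec$gene_id, sprintf("S_%02d", 1:n_samples)))
  m
}

# Exhaustive all-pairs overlap oracle: >= 1 bp intersection, half-open.
brute_force_counts <- function(frags, windows) {
  vapply(seq_len(nrow(windows)), function(i) {
    sum(frags$chrom == windows$chrom[i] &
          frags$start < windows$end[i] &
          frags$end > windows$start[i])
  }, numeric(1))
}

random_fragments <- function(n, chroms = c("chr1", "chr2"),
                             max_pos = 10000, min_len = 1, max_len = 300) {
  start <- floor(runif(n, 0, max_pos))
  len <- floor(runif(n, min_len, max_len + 1))
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len, stringsAsFactors = FALSE)
}

random_windows <- function(n, chroms = c("chr1", "chr2"),
                           max_pos = 10000, width = 1000) {
  start <- floor(runif(n, 0, max_pos))
  data.frame(gene_id = sprintf("w%03d", seq_len(n)),
             chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + width, stringsAsFactors = FALSE)
}

# Independent Spearman oracle: average ranks, then Pearson on the ranks.
rank_pearson <- function(x, y) {
  ok <- complete.cases(x, y)
  cor(rank(x[ok]), rank(y[ok]))
}

# Minimal SAM with paired and single-end alignments on a toy chromosome.
write_toy_sam <- function(path = tempfile(fileext = ".sam")) {
  lines <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr1\tLN:100000",
    # proper pair: fragment chr1:[999,1199) (0-based), TLEN 200
    "r1\t99\tchr1\t1000\t60\t50M\t=\t1150\t200\t*\t*",
    "r1\t147\tchr1\t1150\t60\t50M\t=\t1000\t-200\t*\t*",
    # second pair: fragment chr1:[4999,5300)
    "r2\t99\tchr1\t5000\t60\t50M\t=\t5251\t301\t*\t*",
    "r2\t147\tchr1\t5251\t60\t50M\t=\t5000\t-301\t*\t*",
    # unmapped read: always dropped
    "r3\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",
    # secondary alignment: dropped
    "r4\t355\tchr1\t7000\t60\t50M\t=\t7100\t150\t*\t*",
    # duplicate-flagged pair: dropped by default
    "r5\t1123\tchr1\t9000\t60\t50M\t=\t9100\t150\t*\t*",
    "r5\t1171\tchr1\t9100\t60\t50M\t=\t9000\t-150\t*\t*"
  )
  writeLines(lines, path)
  path
}

write_toy_sam_single <- function(path = tempfile(fileext = ".sam")) {
  lines <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr1\tLN:100000",
    "s1\t0\tchr1\t1001\t60\t50M\t*\t0\t0\t*\t*",   # + strand, start 1000
    "s2\t16\tchr1\t2001\t60\t50M\t*\t0\t0\t*\t*"   # - strand, aln end 2050
  )
  writeLines(lines, path)
  path
}
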