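#' Construct a fragment source
#'
#' A fragment source is a sample's set of sequenced DNA fragments reduced to
#' genomic intervals (0-based half-open), plus the library size used for
#' per-million normalization. By default the library size is the number of
#' fragments surviving filters; it may be overridden for reproducibility.
#'
#' @param sample_id sample identifier.
#' @param fragments data.frame with columns `chrom`, `start`, `end`.
#' @param library_size total usable fragments; defaults to `nrow(fragments)`.
#' @return object of class `fragment_source`.
#' @export
fragment_source <- function(sample_id, fragments, library_size = NULL) {
  stopifnot(is.data.frame(fragments),
            all(c("chrom", "start", "end") %in% names(fragments)))
  if (is.null(library_size)) library_size <- nrow(fragments)
  if (library_size < nrow(fragments)) {
    stop("library_size (", library_size, ") smaller than the number of ",
         "fragments (", nrow(fragments), ")")
  }
  structure(list(sample_id = sample_id,
                 fragments = fragments[c("chrom", "start", "end")],
                 library_size = as.numeric(library_size)),
            class = "fragment_source")
}

#' @export
print.fragment_source <- function(x, ...) {
  cat("<fragment_source> ", x$sample_id, ": ", nrow(x$fragments),
      " fragments, library size ", x$library_size, "\n", sep = "")
  invisible(x)
}

# SAM -> filtered fragment intervals via Rsamtools. Drops unmapped,
# secondary, supplementary and (by default) duplicate-flagged records.
.fragments_from_sam <- function(path, read_mode, fragment_length,
                                keep_duplicates) {
  bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                          indexDestination = TRUE)
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE,
    isDuplicate = if (keep_duplicates) NA else FALSE
  )
  param <- Rsamtools::ScanBamParam(
    flag = flag,
    what = c("rname", "pos", "strand", "qwidth", "isize")
  )
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  chrom <- as.character(rec$rname)
  pos0 <- rec$pos - 1L  # SAM POS is 1-based
  if (read_mode == "paired_fragment") {
    sel <- !is.na(rec$isize) & rec$isize > 0L
    data.frame(chrom = chrom[sel],
               start = pos0[sel],
               end = pos0[sel] + rec$isize[sel],
               stringsAsFactors = FALSE)
  } else {
    minus <- as.character(rec$strand) == "-"
    aln_end <- pos0 + rec$qwidth
    start <- ifelse(minus, pmax(aln_end - fragment_length, 0L), pos0)
    end <- ifelse(minus, aln_end, pos0 + fragment_length)
    data.frame(chrom = chrom, start = as.integer(start),
               end = as.integer(end), stringsAsFactors = FALSE)
  }
}

.fragments_from_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "[ \t]+")
  short <- which(lengths(f) < 3L)
  if (length(short)) {
    stop("unparseable fragment BED row at line ", short[1], " of ", path)
  }
  data.frame(chrom = vapply(f, `[[`, character(1), 1L),
             start = as.integer(vapply(f, `[[`, character(1), 2L)),
             end = as.integer(vapply(f, `[[`, character(1), 3L)),
             stringsAsFactors = FALSE)
}

#' Read aligned fragments from SAM/BAM or fragment BED
#'
#' For paired-end alignments (`read_mode = "paired_fragment"`) each template
#' is reduced to the mate-to-mate fragment interval, taken from the leftmost
#' mate's position and TLEN. For single-end alignments
#' (`read_mode = "single_end_extended"`) each read is extended to
#' `fragment_length` bp in its strand direction. Fragment BED files are taken
#' as-is (0-based half-open intervals). Unmapped, secondary, supplementary
#' and duplicate-flagged alignments are dropped.
#'
#' @param path input file (`.sam`/`.bam` or `.bed`).
#' @param sample_id sample identifier (defaults to the file name).
#' @param format `"auto"`, `"sam"` or `"bed"`.
#' @param read_mode fragment reconstruction mode for alignments.
#' @param fragment_length extension length for single-end reads (bp).
#' @param keep_duplicates keep duplicate-flagged alignments.
#' @param library_size optional override of the computed library size.
#' @return a [fragment_source()].
#' @export
read_fragments <- function(path, sample_id = basename(path),
                           format = c("auto", "sam", "bed"),
                           read_mode = c("paired_fragment",
                                         "single_end_extended"),
                           fragment_length = 200L,
                           keep_duplicates = FALSE,
                           library_size = NULL) {
  format <- match.arg(format)
  read_mode <- match.arg(read_mode)
  if (format == "auto") {
    format <- if (grepl("\\.(sam|bam)$", path, ignore.case = TRUE)) "sam"
              else "bed"
  }
  frags <- if (format == "sam") {
    .fragments_from_sam(path, read_mode, fragment_length, keep_duplicates)
  } else {
    .fragments_from_bed(path)
  }
  fragment_source(sample_id, frags, library_size)
}

.as_granges <- function(df) {
  # internal 0-based half-open -> GRanges 1-based closed
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

#' Count fragments overlapping quantification windows
#'
#' A fragment is counted in every window it intersects by at least 1 bp
#' (`method = "any"`); with `method = "midpoint"` only the fragment midpoint
#' must fall inside the window. Counts are independent of fragment and
#' window input order, and a fragment overlapping several windows
#' contributes to each of them.
#'
#' @param source a [fragment_source()] or a fragment data.frame.
#' @param windows window data.frame from [gene_windows()].
#' @param method overlap rule.
#' @return integer vector of counts, named by `windows$gene_id` when present.
#' @export
count_fragments_in_windows <- function(source, windows,
                                       method = c("any", "midpoint")) {
  method <- match.arg(method)
  frags <- if (inherits(source, "fragment_source")) source$fragments
           else source
  missing_chrom <- setdiff(unique(windows$chrom), unique(frags$chrom))
  if (length(missing_chrom) && nrow(frags) > 0L) {
    warning("no fragments on chromosome(s): ",
            paste(missing_chrom, collapse = ", "), "; counts set to 0")
  }
  if (method == "midpoint") {
    mid <- floor((frags$start + frags$end) / 2)
    frags <- data.frame(chrom = frags$chrom, start = mid, end = mid + 1L)
  }
  n <- suppressWarnings(
    GenomicRanges::countOverlaps(.as_granges(windows), .as_granges(frags),
                                 minoverlap = 1L))
  n <- as.integer(n)
  if (!is.null(windows$gene_id)) names(n) <- windows$gene_id
  n
}

#' Reads-per-million normalization
#'
#' @param counts numeric vector of raw fragment counts.
#' @param library_size total usable fragments in the library (> 0).
#' @return `counts * 1e6 / library_size`.
#' @export
to_rpm <- function(counts, library_size) {
  if (!is.numeric(library_size) || length(library_size) != 1L ||
      is.na(library_size) || library_size <= 0) {
    stop("library_size must be a single positive number")
  }
  counts * 1e6 / library_size
}

#' Input normalization of ChIP signal
#'
#' The per-window quantification value ("Q-value") is the ratio of ChIP RPM
#' to matched input RPM, with a pseudocount in the denominator:
#' `Q = chip_rpm / (input_rpm + pseudocount)`. Cells whose raw input
#' coverage falls below `min_input_raw` fragments are flagged missing with
#' reason `"inadequate_input"` (the grey cells of a heat map); with a zero
#' pseudocount a zero input yields a missing cell with reason
#' `"zero_input"`.
#'
#' @param chip_rpm,input_rpm RPM-normalized values.
#' @param pseudocount denominator pseudocount in RPM units (>= 0);
#'   default 0.5.
#' @param input_raw optional raw input fragment counts for the quality gate.
#' @param min_input_raw minimum raw input fragments for an adequate cell.
#' @return numeric vector of Q values with `NA` for missing cells and a
#'   `"reason"` character attribute recording why each missing cell is
#'   missing.
#' @export
input_normalize <- function(chip_rpm, input_rpm, pseudocount = 0.5,
                            input_raw = NULL, min_input_raw = 5L) {
  if (!is.numeric(pseudocount) || pseudocount < 0) {
    stop("pseudocount must be >= 0")
  }
  q <- chip_rpm / (input_rpm + pseudocount)
  reason <- rep(NA_character_, length(q))
  if (pseudocount == 0) {
    zero <- input_rpm == 0
    q[zero] <- NA_real_
    reason[zero] <- "zero_input"
  }
  if (!is.null(input_raw)) {
    low <- input_raw < min_input_raw
    q[low] <- NA_real_
    reason[low] <- "inadequate_input"
  }
  attr(q, "reason") <- reason
  q
}

.resolve_sources <- function(samples) {
  # Accept either a cohort list (sheet + in-memory sources) or a sample
  # sheet whose chip/input columns are file paths.
  if (is.list(samples) && !is.data.frame(samples) &&
      all(c("sheet", "chip", "input") %in% names(samples))) {
    return(samples)
  }
  sheet <- samples
  stopifnot(is.data.frame(sheet),
            all(c("sample_id", "condition", "chip", "input") %in% names(sheet)))
  chip <- list(); input <- list()
  for (i in seq_len(nrow(sheet))) {
    id <- sheet$sample_id[i]
    if (is.na(sheet$chip[i]) || is.na(sheet$input[i])) {
      stop("sample ", id, " lacks a chip/input pairing")
    }
    chip[[id]] <- read_fragments(sheet$chip[i], sample_id = id)
    input[[id]] <- read_fragments(sheet$input[i],
                                  sample_id = paste0(id, "_input"))
  }
  list(sheet = sheet, chip = chip, input = input)
}

#' Build the gene-by-sample signal matrix
#'
#' Runs the full window quantification for a cohort: fragments are counted
#' in the +/- `flank` bp window around each gene centre for the ChIP and the
#' matched input library, both are RPM-normalized, and the ChIP value is
#' divided by the input value ([input_normalize()]). Rows are ordered by
#' genomic position and columns primary-then-metastatic (then other),
#' preserving the sheet's order within each condition.
#'
#' @param samples either a sample sheet data.frame (`sample_id`, `condition`,
#'   `chip`, `input`; the last two being file paths) or a cohort list with
#'   elements `sheet`, `chip` and `input`, the latter two named lists of
#'   [fragment_source()] objects (as returned by [simulate_chip_cohort()]).
#' @param genes gene records data.frame.
#' @param flank window half-width in bp.
#' @param pseudocount,min_input_raw see [input_normalize()].
#' @param method overlap counting rule, see [count_fragments_in_windows()].
#' @param chrom_lengths optional chromosome lengths for window clipping.
#' @return numeric matrix (genes x samples) of Q values with attributes
#'   `missing_reason` (character matrix), `library_sizes` (data.frame),
#'   `stage = "input_normalized"` and `params`.
#' @export
build_signal_matrix <- function(samples, genes, flank = 500L,
                                pseudocount = 0.5, min_input_raw = 5L,
                                method = "any", chrom_lengths = NULL) {
  src <- .resolve_sources(samples)
  sheet <- src$sheet
  cond <- factor(sheet$condition,
                 levels = c("primary", "metastatic",
                            setdiff(unique(sheet$condition),
                                    c("primary", "metastatic"))))
  sheet <- sheet[order(cond), , drop = FALSE]
  if (anyDuplicated(sheet$sample_id)) stop("duplicate sample_ids in sheet")

  ord <- order(genes$chrom, genes$start)
  genes <- genes[ord, , drop = FALSE]
  windows <- gene_windows(genes, flank = flank, chrom_lengths = chrom_lengths)

  n_g <- nrow(genes); n_s <- nrow(sheet)
  q <- matrix(NA_real_, n_g, n_s,
              dimnames = list(genes$gene_id, sheet$sample_id))
  reason <- matrix(NA_character_, n_g, n_s,
                   dimnames = dimnames(q))
  lib <- data.frame(sample_id = sheet$sample_id,
                    chip_library = NA_real_, input_library = NA_real_)

  for (j in seq_len(n_s)) {
    id <- sheet$sample_id[j]
    chip <- src$chip[[id]]; input <- src$input[[id]]
    if (is.null(chip) || is.null(input)) {
      stop("sample ", id, " lacks a chip/input pairing")
    }
    if (is.data.frame(chip)) chip <- fragment_source(id, chip)
    if (is.data.frame(input)) input <- fragment_source(id, input)
    lib$chip_library[j] <- chip$library_size
    lib$input_library[j] <- input$library_size
    if (chip$library_size == 0 || input$library_size == 0) {
      reason[, j] <- "empty_library"
      next
    }
    chip_n <- suppressWarnings(
      count_fragments_in_windows(chip, windows, method = method))
    input_n <- suppressWarnings(
      count_fragments_in_windows(input, windows, method = method))
    qj <- input_normalize(to_rpm(chip_n, chip$library_size),
                          to_rpm(input_n, input$library_size),
                          pseudocount = pseudocount,
                          input_raw = input_n,
                          min_input_raw = min_input_raw)
    q[, j] <- as.numeric(qj)
    reason[, j] <- attr(qj, "reason")
  }
  structure(q,
            missing_reason = reason,
            library_sizes = lib,
            stage = "input_normalized",
            params = list(flank = flank, pseudocount = pseudocount,
                          min_input_raw = min_input_raw, method = method))
}

#' Write a signal matrix with its missing-reason sidecar
#'
#' @param mat signal matrix from [build_signal_matrix()].
#' @param path output path; a `<path>.reasons.tsv` sidecar listing missing
#'   cells and their reason codes is written alongside.
#' @export
write_signal_matrix <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  reason <- attr(mat, "missing_reason")
  if (!is.null(reason)) {
    idx <- which(!is.na(reason), arr.ind = TRUE)
    side <- data.frame(gene_id = rownames(reason)[idx[, 1]],
                       sample_id = colnames(reason)[idx[, 2]],
                       reason = reason[idx])
    utils::write.table(side, paste0(path, ".reasons.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
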