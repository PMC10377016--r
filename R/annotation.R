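# Levels of the tRNA gene family hierarchy, ordered finest to coarsest.
FAMILY_LEVELS <- c("gene", "isodecoder", "isoacceptor", "isotype")

#' Parse gtRNAdb-style tRNA gene names
#'
#' tRNA genes are conventionally named `tRNA-<Isotype>-<Anticodon>-<Fam>-<Copy>`,
#' e.g. `tRNA-iMet-CAT-1-5`: the amino-acid isotype, the three-letter
#' DNA-alphabet anticodon (`NNN` when undetermined), the isodecoder family
#' number, and the gene copy number within that family. The four components
#' encode the full gene -> isodecoder -> isoacceptor -> isotype hierarchy.
#'
#' @param name character vector of gene names.
#' @return A data.frame with one row per name and columns `isotype`,
#'   `anticodon`, `isodecoder_family` (integer), `gene_copy` (integer).
#'   Parsing then re-serializing with [serialize_gene_name()] reproduces the
#'   input exactly.
#' @examples
#' parse_gene_name("tRNA-iMet-CAT-1-5")
#' @export
parse_gene_name <- function(name) {
  stopifnot(is.character(name))
  parts <- strsplit(name, "-", fixed = TRUE)
  out <- lapply(seq_along(name), function(i) {
    p <- parts[[i]]
    nm <- name[i]
    if (length(p) != 5L || p[1] != "tRNA") {
      stop("malformed tRNA gene name '", nm,
           "': expected tRNA-<Isotype>-<Anticodon>-<Fam>-<Copy>", call. = FALSE)
    }
    if (!grepl("^[A-Za-z]{1,4}$", p[2])) {
      stop("malformed tRNA gene name '", nm, "': bad isotype token '",
           p[2], "'", call. = FALSE)
    }
    if (!grepl("^[ACGT]{3}$", p[3]) && p[3] != "NNN") {
      stop("malformed tRNA gene name '", nm, "': bad anticodon token '",
           p[3], "' (expected three of A/C/G/T, or NNN)", call. = FALSE)
    }
    if (!grepl("^[0-9]+$", p[4]) || as.integer(p[4]) < 1L) {
      stop("malformed tRNA gene name '", nm,
           "': bad isodecoder family token '", p[4], "'", call. = FALSE)
    }
    if (!grepl("^[0-9]+$", p[5]) || as.integer(p[5]) < 1L) {
      stop("malformed tRNA gene name '", nm, "': bad gene copy token '",
           p[5], "'", call. = FALSE)
    }
    list(p[2], p[3], as.integer(p[4]), as.integer(p[5]))
  })
  data.frame(
    isotype = vapply(out, `[[`, character(1), 1L),
    anticodon = vapply(out, `[[`, character(1), 2L),
    isodecoder_family = vapply(out, `[[`, integer(1), 3L),
    gene_copy = vapply(out, `[[`, integer(1), 4L),
    stringsAsFactors = FALSE
  )
}

#' Serialize parsed name components back to a gtRNAdb-style name
#'
#' Inverse of [parse_gene_name()].
#'
#' @param isotype,anticodon character vectors.
#' @param isodecoder_family,gene_copy integer vectors.
#' @return character vector of names.
#' @export
serialize_gene_name <- function(isotype, anticodon, isodecoder_family, gene_copy) {
  paste("tRNA", isotype, anticodon, isodecoder_family, gene_copy, sep = "-")
}

# Lenient vectorized parse used by table readers: rows whose names do not
# follow the convention (nmt-tRNAs, tRNA-like predictions) get NA components
# and are left for filter_gene_set() to drop.
.parse_lenient <- function(name) {
  ok <- grepl("^tRNA-[A-Za-z]{1,4}-([ACGT]{3}|NNN)-[0-9]+-[0-9]+$", name)
  res <- data.frame(
    isotype = rep(NA_character_, length(name)),
    anticodon = rep(NA_character_, length(name)),
    isodecoder_family = rep(NA_integer_, length(name)),
    gene_copy = rep(NA_integer_, length(name)),
    stringsAsFactors = FALSE
  )
  if (any(ok)) res[ok, ] <- parse_gene_name(name[ok])
  res
}

.new_gene_records <- function(gene_id, chrom, start, end, strand,
                              high_confidence = NA) {
  comp <- .parse_lenient(gene_id)
  high_confidence <- rep_len(high_confidence, length(gene_id))
  bad <- start >= end
  if (any(bad)) {
    stop("invalid coordinates (start >= end) for: ",
         paste(gene_id[bad], collapse = ", "))
  }
  data.frame(
    gene_id = gene_id, chrom = chrom,
    start = as.integer(start), end = as.integer(end),
    strand = strand,
    isotype = comp$isotype, anticodon = comp$anticodon,
    isodecoder_family = comp$isodecoder_family, gene_copy = comp$gene_copy,
    high_confidence = high_confidence,
    stringsAsFactors = FALSE
  )
}

#' Load a tRNA gene annotation table
#'
#' Reads either a BED6 file or a tab-separated UCSC Table Browser export of
#' the tRNA gene track. Coordinates are stored 0-based half-open internally.
#' BED starts are 0-based by definition; UCSC browser table `chromStart` is
#' also 0-based, but a `one_based_start` flag is provided for tables exported
#' through 1-based tools, in which case starts are decremented on read.
#'
#' @param path file path.
#' @param format `"bed"` or `"ucsc_table"`.
#' @param one_based_start logical; treat the start column as 1-based and
#'   decrement it (only meaningful for `format = "ucsc_table"`).
#' @return data.frame of gene records (one per row) with columns `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, parsed name components and
#'   `high_confidence` (NA until [filter_gene_set()] is applied).
#' @export
load_gene_table <- function(path, format = c("bed", "ucsc_table"),
                            one_based_start = FALSE) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  is_header <- startsWith(lines, "#")
  body <- lines[!is_header]
  if (length(body) == 0L) {
    return(.new_gene_records(character(0), character(0), integer(0),
                             integer(0), character(0)))
  }
  header <- if (any(is_header)) sub("^#", "", lines[which(is_header)[1]]) else NULL
  fields <- strsplit(body, "\t")
  # BED may be space-separated in toy files
  if (format == "bed" && all(lengths(fields) == 1L)) {
    fields <- strsplit(body, "[ \t]+")
  }
  line_no <- which(!is_header)

  if (format == "bed") {
    idx <- list(chrom = 1L, start = 2L, end = 3L, name = 4L, strand = 6L)
  } else {
    cols <- if (!is.null(header)) strsplit(header, "\t")[[1]] else character(0)
    pick <- function(candidates, default) {
      hit <- which(cols %in% candidates)
      if (length(hit)) hit[1] else default
    }
    idx <- list(
      chrom = pick(c("chrom", "#chrom"), 1L),
      start = pick(c("chromStart", "txStart", "start"), 2L),
      end = pick(c("chromEnd", "txEnd", "end"), 3L),
      name = pick(c("name", "gene_id"), 4L),
      strand = pick("strand", 6L)
    )
  }

  get <- function(f, j, i) {
    if (length(f) < j) {
      stop("unparseable annotation row at line ", line_no[i], " of ", path,
           ": expected at least ", j, " columns", call. = FALSE)
    }
    f[j]
  }
  n <- length(fields)
  chrom <- character(n); start <- integer(n); end <- integer(n)
  nm <- character(n); strand <- character(n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    chrom[i] <- get(f, idx$chrom, i)
    s <- suppressWarnings(as.integer(get(f, idx$start, i)))
    e <- suppressWarnings(as.integer(get(f, idx$end, i)))
    if (is.na(s) || is.na(e)) {
      stop("unparseable coordinates at line ", line_no[i], " of ", path,
           call. = FALSE)
    }
    start[i] <- s; end[i] <- e
    nm[i] <- get(f, idx$name, i)
    strand[i] <- if (length(f) >= idx$strand) f[idx$strand] else "+"
  }
  if (one_based_start) start <- start - 1L
  if (!any(grepl("^chr", chrom))) {
    warning("chromosome names do not use the UCSC 'chr' prefix; ",
            "make sure fragment sources use the same naming style")
  }
  .new_gene_records(nm, chrom, start, end, strand)
}

#' Filter a tRNA gene set to the high-confidence analysis set
#'
#' Retains genes present in a supplied high-confidence id set (e.g. the
#' gtRNAdb curated set) or in an explicit exception list, then removes genes
#' matching drop patterns: by default nuclear-encoded mitochondrial tRNAs
#' (`nmt-` prefix), tRNA-like predictions, and genes on unplaced or alternate
#' contigs. Counts removed per reason are reported via `message()` and
#' attached as the `"removed"` attribute.
#'
#' The high-confidence set and any exceptions are inputs, not constants:
#' database versions drift, and studies may deliberately retain individual
#' genes (e.g. a selenocysteine gene) that fall outside the curated set.
#'
#' @param records gene records data.frame.
#' @param high_confidence_ids character vector of gene ids to keep.
#' @param keep_exceptions character vector of ids kept regardless.
#' @param drop_patterns named character vector of regular expressions; a gene
#'   is dropped when its id or chromosome matches any of them.
#' @return filtered records with `high_confidence` filled in.
#' @export
filter_gene_set <- function(records, high_confidence_ids,
                            keep_exceptions = character(0),
                            drop_patterns = c(
                              nmt = "^nmt-",
                              trna_like = "tRNA-like",
                              unplaced = "^chrUn|_alt$|_random$|_hap[0-9]*$"
                            )) {
  keep <- records$gene_id %in% high_confidence_ids |
    records$gene_id %in% keep_exceptions
  removed <- data.frame(reason = "not_high_confidence",
                        n = sum(!keep), stringsAsFactors = FALSE)
  out <- records[keep, , drop = FALSE]
  for (nm in names(drop_patterns)) {
    pat <- drop_patterns[[nm]]
    hit <- grepl(pat, out$gene_id) | grepl(pat, out$chrom)
    removed <- rbind(removed, data.frame(reason = nm, n = sum(hit)))
    out <- out[!hit, , drop = FALSE]
  }
  out$high_confidence <- out$gene_id %in% high_confidence_ids
  for (i in seq_len(nrow(removed))) {
    if (removed$n[i] > 0) {
      message("filter_gene_set: removed ", removed$n[i],
              " gene(s): ", removed$reason[i])
    }
  }
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

#' Quantification windows centred on tRNA genes
#'
#' Builds the fixed window around each gene in which ChIP signal is counted:
#' `flank` bp either side of the gene centre, `[centre - flank, centre +
#' flank)` in 0-based half-open coordinates (2 kb of flank-inclusive sequence
#' at the default `flank = 500` gives a 1000 bp window). Windows are clipped
#' at position 0 and, when chromosome lengths are supplied, at the chromosome
#' end; clipped windows are flagged. Strand is ignored: ChIP fragment
#' coverage is unstranded.
#'
#' @param records gene records.
#' @param flank half-width in bp (> 0); default 500.
#' @param chrom_lengths optional named integer vector of chromosome lengths.
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `clipped`.
#' @export
gene_windows <- function(records, flank = 500L, chrom_lengths = NULL) {
  if (!is.numeric(flank) || length(flank) != 1L || flank <= 0) {
    stop("flank must be a single positive number of base pairs")
  }
  centre <- floor((records$start + records$end) / 2)
  start <- centre - flank
  end <- centre + flank
  clipped <- start < 0
  start <- pmax(start, 0)
  if (!is.null(chrom_lengths)) {
    len <- unname(chrom_lengths[records$chrom])
    over <- !is.na(len) & end > len
    clipped <- clipped | over
    end <- ifelse(over, len, end)
  }
  data.frame(gene_id = records$gene_id, chrom = records$chrom,
             start = as.integer(start), end = as.integer(end),
             clipped = clipped, stringsAsFactors = FALSE)
}

#' Family keys at a hierarchy level
#'
#' @param records gene records (parsed components required).
#' @param level one of `"gene"`, `"isodecoder"`, `"isoacceptor"`, `"isotype"`.
#' @return character vector of group keys, one per record.
#' @export
family_key <- function(records, level = FAMILY_LEVELS) {
  level <- match.arg(level)
  if (anyNA(records$isotype)) {
    stop("unparsed gene names in record set: ",
         paste(records$gene_id[is.na(records$isotype)], collapse = ", "))
  }
  switch(level,
    gene = records$gene_id,
    isodecoder = paste(records$isotype, records$anticodon,
                       records$isodecoder_family, sep = "-"),
    isoacceptor = paste(records$isotype, records$anticodon, sep = "-"),
    isotype = records$isotype
  )
}

#' Partition gene records by family level
#'
#' At every level the groups are disjoint and jointly cover the record set,
#' and each group at a finer level is contained in exactly one group at any
#' coarser level (gene < isodecoder < isoacceptor < isotype).
#'
#' @inheritParams family_key
#' @return named list mapping group key to member gene ids.
#' @export
group_by_level <- function(records, level = FAMILY_LEVELS) {
  level <- match.arg(level)
  keys <- family_key(records, level)
  split(records$gene_id, factor(keys, levels = unique(keys)))
}

#' Family sizes at a hierarchy level
#'
#' @inheritParams family_key
#' @return named integer vector of member counts per group.
#' @export
family_sizes <- function(records, level = FAMILY_LEVELS) {
  level <- match.arg(level)
  groups <- group_by_level(records, level)
  vapply(groups, length, integer(1))
}

#' Write gene records as BED6
#'
#' @param records gene records.
#' @param path output path.
#' @export
write_gene_bed <- function(records, path) {
  bed <- data.frame(records$chrom, records$start, records$end,
                    records$gene_id, 0L,
                    ifelse(is.na(records$strand), ".", records$strand))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export the gene-to-family map
#'
#' Writes (or returns) a table of each gene's key at the three super-gene
#' levels of the hierarchy.
#'
#' @param records gene records.
#' @param path optional output path (tab-separated).
#' @return the map data.frame, invisibly when written to a file.
#' @export
export_family_map <- function(records, path = NULL) {
  map <- data.frame(
    gene_id = records$gene_id,
    isodecoder_key = family_key(records, "isodecoder"),
    isoacceptor_key = family_key(records, "isoacceptor"),
    isotype_key = family_key(records, "isotype"),
    stringsAsFactors = FALSE
  )
  if (is.null(path)) return(map)
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(map)
}
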