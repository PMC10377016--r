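#' Aggregate a signal matrix to a family level
#'
#' Sums member-gene Q values within each family at the requested level of
#' the hierarchy (the family total is the sum, not the mean, of its members'
#' values; a mean is available for family-size sensitivity analyses). With
#' no missing cells, each sample's total is identical at every level.
#'
#' Missing cells are handled by policy: `"omit"` (default) excludes missing
#' members from the sum and records the per-cell effective member count;
#' `"propagate"` marks a family cell missing as soon as any member is.
#' Under `"omit"` a cell whose members are all missing is still missing.
#'
#' @param mat signal matrix (genes x samples) with gtRNAdb-style rownames.
#' @param level target level, one of `"gene"`, `"isodecoder"`,
#'   `"isoacceptor"`, `"isotype"`.
#' @param missing_policy `"omit"` or `"propagate"`.
#' @param stat `"sum"` (default) or `"mean"`.
#' @return numeric matrix (families x samples) with attributes `level`,
#'   `member_count` (integer vector) and `effective_n` (matrix of members
#'   actually summed per cell).
#' @export
aggregate_signal <- function(mat, level = c("isoacceptor", "gene",
                                            "isodecoder", "isotype"),
                             missing_policy = c("omit", "propagate"),
                             stat = c("sum", "mean")) {
  level <- match.arg(level)
  missing_policy <- match.arg(missing_policy)
  stat <- match.arg(stat)
  ids <- rownames(mat)
  if (is.null(ids)) stop("signal matrix must have gene_id rownames")
  gene_style <- grepl("^tRNA-[A-Za-z]{1,4}-([ACGT]{3}|NNN)-[0-9]+-[0-9]+$",
                      ids)
  dec_style <- grepl("^[A-Za-z]{1,4}-([ACGT]{3}|NNN)-[0-9]+$", ids)
  acc_style <- grepl("^[A-Za-z]{1,4}-([ACGT]{3}|NNN)$", ids)
  if (all(gene_style)) {
    comp <- parse_gene_name(ids)
    rec <- data.frame(gene_id = ids, comp, stringsAsFactors = FALSE)
    keys <- family_key(rec, level)
  } else if (all(dec_style)) {
    # rows are already isodecoder families; only coarser levels make sense
    if (!level %in% c("isodecoder", "isoacceptor", "isotype")) {
      stop("cannot disaggregate an isodecoder-level matrix to level '",
           level, "'")
    }
    keys <- switch(level,
                   isodecoder = ids,
                   isoacceptor = sub("-[0-9]+$", "", ids),
                   isotype = sub("-.*$", "", ids))
  } else if (all(acc_style)) {
    if (!level %in% c("isoacceptor", "isotype")) {
      stop("cannot disaggregate an isoacceptor-level matrix to level '",
           level, "'")
    }
    keys <- if (level == "isotype") sub("-.*$", "", ids) else ids
  } else {
    bad <- ids[!(gene_style | dec_style | acc_style)]
    stop("gene ids not parseable into the family hierarchy: ",
         paste(bad, collapse = ", "))
  }
  fkeys <- factor(keys, levels = unique(keys))

  present <- !is.na(mat)
  n_eff <- rowsum(present + 0L, fkeys)
  sums <- rowsum(ifelse(present, mat, 0), fkeys)
  if (missing_policy == "omit") {
    sums[n_eff == 0L] <- NA_real_
  } else {
    member_n <- as.integer(table(fkeys)[rownames(sums)])
    sums[n_eff < member_n] <- NA_real_
  }
  if (stat == "mean") {
    denom <- if (missing_policy == "omit") n_eff
             else matrix(as.integer(table(fkeys)[rownames(sums)]),
                         nrow(sums), ncol(sums))
    sums <- sums / ifelse(denom == 0L, NA_integer_, denom)
  }
  structure(sums,
            level = level,
            member_count = as.integer(table(fkeys)[rownames(sums)]),
            effective_n = n_eff,
            missing_policy = missing_policy,
            stat = stat)
}

#' Proportional distribution of signal across families
#'
#' For each sample, each family's share of the sample's total signal; shares
#' sum to 1 per sample before averaging over the requested sample group.
#' Used, at the isotype level, to compare how the overall signal budget is
#' apportioned between amino-acid families in different tumour groups.
#'
#' @param agg aggregated matrix from [aggregate_signal()] (or any
#'   families x samples matrix).
#' @param samples optional character vector of sample ids to average over;
#'   default all columns.
#' @return named numeric vector of mean shares, summing to 1.
#' @export
proportional_distribution <- function(agg, samples = NULL) {
  if (!is.null(samples)) agg <- agg[, samples, drop = FALSE]
  totals <- colSums(agg, na.rm = TRUE)
  empty <- totals == 0 | colSums(!is.na(agg)) == 0
  if (any(empty)) {
    warning("excluding sample(s) with no usable signal: ",
            paste(colnames(agg)[empty], collapse = ", "))
    agg <- agg[, !empty, drop = FALSE]
    totals <- totals[!empty]
  }
  if (ncol(agg) == 0L) stop("no usable samples")
  shares <- sweep(ifelse(is.na(agg), 0, agg), 2, totals, "/")
  rowMeans(shares)
}
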