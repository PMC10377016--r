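#' Spearman rank correlation on pairwise-complete observations
#'
#' Average ranks are used for ties. At least three complete pairs are
#' required; when either vector is constant over the complete pairs the
#' coefficient is undefined and `NA` is returned.
#'
#' @param x,y numeric vectors of equal length; `NA`s removed pairwise.
#' @return Spearman's rho, with the number of complete pairs attached as
#'   attribute `"n"`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3L) {
    stop("spearman_rho needs at least 3 complete pairs (got ", sum(ok), ")")
  }
  xs <- x[ok]; ys <- y[ok]
  rho <- if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    NA_real_
  } else {
    r <- suppressWarnings(stats::cor(xs, ys, method = "spearman"))
    if (is.na(r)) NA_real_ else r  # zero rank variance under total ties
  }
  attr(rho, "n") <- sum(ok)
  rho
}

#' Pairwise sample correlations across the family hierarchy
#'
#' For each requested pair of samples, computes Spearman's rho between their
#' signal profiles at each hierarchy level, after aggregating the matrix to
#' that level. Family-level buffering shows up as rho increasing from the
#' gene level through isoacceptor to isotype.
#'
#' @param mat signal matrix (genes x samples, gtRNAdb-style rownames).
#' @param pairs two-column matrix/data.frame of sample ids; default all
#'   unordered pairs of columns.
#' @param levels hierarchy levels to evaluate.
#' @param missing_policy passed to [aggregate_signal()].
#' @return data.frame `sample_a`, `sample_b`, `level`, `rho`, `n`.
#' @export
correlation_hierarchy <- function(mat, pairs = NULL,
                                  levels = c("gene", "isoacceptor", "isotype"),
                                  missing_policy = "omit") {
  stopifnot(all(levels %in% FAMILY_LEVELS))
  if (is.null(pairs)) {
    cb <- utils::combn(colnames(mat), 2)
    pairs <- data.frame(sample_a = cb[1, ], sample_b = cb[2, ],
                        stringsAsFactors = FALSE)
  } else {
    pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
    names(pairs)[1:2] <- c("sample_a", "sample_b")
  }
  bad <- setdiff(unique(c(pairs$sample_a, pairs$sample_b)), colnames(mat))
  if (length(bad)) stop("unknown sample id(s): ", paste(bad, collapse = ", "))

  agg <- lapply(levels, function(lv) {
    if (lv == "gene") mat
    else aggregate_signal(mat, level = lv, missing_policy = missing_policy)
  })
  names(agg) <- levels

  out <- do.call(rbind, lapply(levels, function(lv) {
    m <- agg[[lv]]
    rho <- numeric(nrow(pairs)); n <- integer(nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      r <- spearman_rho(m[, pairs$sample_a[i]], m[, pairs$sample_b[i]])
      rho[i] <- as.numeric(r); n[i] <- attr(r, "n")
    }
    data.frame(sample_a = pairs$sample_a, sample_b = pairs$sample_b,
               level = lv, rho = rho, n = n, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-sample total signal and fold range
#'
#' Totals are taken over non-missing cells. The fold range is the ratio of
#' the strongest sample's total to the weakest's; when the weakest total is
#' zero the fold is infinite (with a warning).
#'
#' @param mat signal matrix.
#' @return list with `totals` (named numeric) and `fold` (max/min ratio).
#' @export
sample_totals <- function(mat) {
  usable <- colSums(!is.na(mat))
  if (any(usable == 0L)) {
    stop("sample(s) with no non-missing cells: ",
         paste(colnames(mat)[usable == 0L], collapse = ", "))
  }
  totals <- colSums(mat, na.rm = TRUE)
  if (min(totals) == 0) {
    warning("weakest sample has zero total signal; fold range is infinite")
    fold <- Inf
  } else {
    fold <- max(totals) / min(totals)
  }
  list(totals = totals, fold = fold)
}

#' Classify gene loci as active or inactive
#'
#' The notion of an "active" locus is operationalized by one of three rules:
#' `per_sample_median` (default) marks a cell active when its value is at or
#' above that sample's median across genes — by construction roughly half
#' the loci come out active in every sample, with cells equal to the median
#' counting as active; `global_quantile` thresholds every cell at the q-th
#' quantile of all non-missing values; `fixed_threshold` applies an absolute
#' cutoff tau (>= 0). Missing cells stay undefined.
#'
#' @param mat signal matrix.
#' @param rule classification rule.
#' @param q quantile in (0,1) for `global_quantile`.
#' @param tau threshold (>= 0) for `fixed_threshold`.
#' @return logical matrix of the same shape with the rule recorded in the
#'   `"rule"` attribute.
#' @export
classify_activity <- function(mat, rule = c("per_sample_median",
                                            "global_quantile",
                                            "fixed_threshold"),
                              q = 0.5, tau = NULL) {
  rule <- match.arg(rule)
  act <- switch(rule,
    per_sample_median = {
      med <- apply(mat, 2, stats::median, na.rm = TRUE)
      sweep(mat, 2, med, ">=")
    },
    global_quantile = {
      if (!is.numeric(q) || q <= 0 || q >= 1) stop("q must be in (0,1)")
      mat >= stats::quantile(mat, q, na.rm = TRUE)
    },
    fixed_threshold = {
      if (is.null(tau) || !is.numeric(tau) || tau < 0) {
        stop("tau must be a number >= 0")
      }
      mat >= tau
    }
  )
  structure(act, rule = rule)
}

#' Mean signal profile per sample group
#'
#' @param mat signal matrix.
#' @param groups named character vector or factor mapping sample id to
#'   group label.
#' @return list with `mean` (units x groups matrix of row means over
#'   non-missing cells) and `n` (effective sample counts per cell).
#' @export
group_average_profile <- function(mat, groups) {
  groups <- groups[colnames(mat)]
  if (anyNA(groups)) stop("groups must label every sample in the matrix")
  labs <- unique(as.character(groups))
  mean_m <- matrix(NA_real_, nrow(mat), length(labs),
                   dimnames = list(rownames(mat), labs))
  n_m <- matrix(0L, nrow(mat), length(labs), dimnames = dimnames(mean_m))
  for (g in labs) {
    sub <- mat[, as.character(groups) == g, drop = FALSE]
    n_m[, g] <- rowSums(!is.na(sub))
    mean_m[, g] <- rowMeans(sub, na.rm = TRUE)
    mean_m[n_m[, g] == 0L, g] <- NA_real_
  }
  list(mean = mean_m, n = n_m)
}

#' Per-unit two-group comparison by Student's t-test
#'
#' Compares each row (gene or family) between two sample groups with the
#' equal-variance two-sample t-test (Welch's correction available via
#' `var_equal = FALSE`). Units with fewer than two non-missing values in
#' either group are reported missing with a reason; units where both groups
#' are constant and equal get t = 0, p = 1. Benjamini-Hochberg adjusted
#' p-values are reported alongside the raw ones — with hundreds of loci
#' tested simultaneously the raw p-values alone overstate significance.
#'
#' @param mat signal matrix (units x samples).
#' @param groups named vector/factor mapping sample id to one of exactly two
#'   group labels.
#' @param var_equal pooled-variance (Student) t-test when `TRUE` (default).
#' @param adjust `"benjamini_hochberg"` (default) or `"none"`.
#' @return data.frame `unit`, `mean_a`, `mean_b`, `n_a`, `n_b`, `t`, `p`,
#'   `q` (adjusted p, `NA` when `adjust = "none"`), `reason`; group labels
#'   are stored in the `"groups"` attribute (a maps to the first label).
#' @export
compare_groups <- function(mat, groups, var_equal = TRUE,
                           adjust = c("benjamini_hochberg", "none")) {
  adjust <- match.arg(adjust)
  groups <- groups[colnames(mat)]
  if (anyNA(groups)) stop("groups must label every sample in the matrix")
  labs <- unique(as.character(groups))
  if (length(labs) != 2L) stop("compare_groups requires exactly two groups")
  a_cols <- as.character(groups) == labs[1]

  n <- nrow(mat)
  res <- data.frame(unit = rownames(mat),
                    mean_a = NA_real_, mean_b = NA_real_,
                    n_a = NA_integer_, n_b = NA_integer_,
                    t = NA_real_, p = NA_real_, q = NA_real_,
                    reason = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    a <- mat[i, a_cols]; a <- a[!is.na(a)]
    b <- mat[i, !a_cols]; b <- b[!is.na(b)]
    res$n_a[i] <- length(a); res$n_b[i] <- length(b)
    if (length(a)) res$mean_a[i] <- mean(a)
    if (length(b)) res$mean_b[i] <- mean(b)
    if (length(a) < 2L || length(b) < 2L) {
      res$reason[i] <- "insufficient_n"
      next
    }
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (mean(a) == mean(b)) {
        res$t[i] <- 0; res$p[i] <- 1
      } else {
        res$t[i] <- sign(mean(a) - mean(b)) * Inf; res$p[i] <- 0
        res$reason[i] <- "degenerate_variance"
      }
      next
    }
    tt <- stats::t.test(a, b, var.equal = var_equal)
    res$t[i] <- unname(tt$statistic)
    res$p[i] <- tt$p.value
  }
  if (adjust == "benjamini_hochberg") {
    res$q <- stats::p.adjust(res$p, method = "BH")
  }
  attr(res, "groups") <- labs
  res
}
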