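#' Configuration for the synthetic cohort generator
#'
#' Defaults define a scaled-down study: 12 tumour samples (9 primary, 3
#' metastatic), a toy genome of 10 isotypes x 4 isoacceptor families x 5
#' member genes (40 families, 200 genes), conserved family activity budgets
#' with heterogeneous member selection, matched flat input tracks, and a
#' survival cohort of 500 patients whose hazard depends on one chosen unit.
#'
#' Family budgets are log-normal around hierarchical means (isotype
#' component sd `isotype_log_sd`, within-isotype family component sd
#' `family_log_sd`) with an independent between-sample jitter of sd
#' `sigma_budget`; each sample partitions every family's budget over its
#' member genes with a symmetric Dirichlet of concentration `alpha_sel`
#' (values below 1 concentrate the budget on few members, i.e. heterogeneous
#' gene selection).
#'
#' @param seed integer seed driving every draw.
#' @param ... overrides of any default field (unknown names are an error).
#' @return validated config list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # cohort
    n_primary = 9L, n_metastatic = 3L,
    # toy genome / hierarchy
    n_isotypes = 10L, n_families = 40L, members_per_family = 5L,
    gene_length = 72L, gene_spacing = 3000L, flank = 500L,
    # generative structure
    isotype_log_sd = 0.3, family_log_sd = 0.12,
    sigma_budget = 0.15, alpha_sel = 0.3,
    mean_gene_frags = 150, background_chip_per_kb = 0.5,
    input_per_kb = 20, fragment_length = 200L,
    met_budget_shift = NULL,  # optional named per-family multiplier
    # survival cohort
    n_patients = 500L, beta_true = 0.6, baseline_hazard = 0.3,
    censoring_fraction = 0.3, horizon = 5
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown synthetic_config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  with(cfg, {
    stopifnot(n_primary + n_metastatic > 0, n_isotypes > 0, n_families > 0,
              members_per_family > 0, n_families %% n_isotypes == 0,
              sigma_budget >= 0, alpha_sel > 0, mean_gene_frags > 0,
              n_patients > 0, baseline_hazard > 0,
              censoring_fraction >= 0, censoring_fraction < 1, horizon > 0)
  })
  structure(cfg, class = "synthetic_config")
}

# standard amino-acid isotype labels for toy annotations
.ISOTYPES <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly",
               "His", "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser",
               "Thr", "Trp", "Tyr", "Val", "iMet", "SeC")

#' Generate a toy tRNA gene annotation
#'
#' Places `n_families` isoacceptor families (split evenly over
#' `n_isotypes` isotypes, one toy chromosome per isotype) with
#' `members_per_family` member genes each, spaced so that quantification
#' windows never overlap. Members are split over two isodecoder families so
#' all four hierarchy levels are distinct. Names follow the gtRNAdb
#' convention and round-trip through [parse_gene_name()].
#'
#' @param config a [synthetic_config()].
#' @return gene records data.frame with a `chrom_lengths` attribute.
#' @export
make_annotation <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$gene_spacing < 2L * config$flank) {
    stop("gene_spacing shorter than the window width; windows would ",
         "overlap - increase gene_spacing (or use longer chromosomes)")
  }
  fam_per_iso <- config$n_families %/% config$n_isotypes
  isotypes <- .ISOTYPES[seq_len(config$n_isotypes)]
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))

  rows <- list(); k <- 0L
  for (i in seq_along(isotypes)) {
    chrom <- paste0("chr", i)
    pos <- 2L * config$flank  # keep the first window clear of position 0
    for (f in seq_len(fam_per_iso)) {
      k <- k + 1L
      anticodon <- codons[k]
      m <- config$members_per_family
      n1 <- ceiling(m / 2)
      fam_no <- rep(c(1L, 2L), c(n1, m - n1))
      copy_no <- c(seq_len(n1), seq_len(m - n1))
      if (m == 1L) { fam_no <- 1L; copy_no <- 1L }
      for (g in seq_len(m)) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = serialize_gene_name(isotypes[i], anticodon,
                                        fam_no[g], copy_no[g]),
          chrom = chrom, start = pos,
          end = pos + config$gene_length,
          strand = if (g %% 2L == 0L) "-" else "+",
          stringsAsFactors = FALSE
        )
        pos <- pos + config$gene_spacing
      }
    }
  }
  df <- do.call(rbind, rows)
  rec <- .new_gene_records(df$gene_id, df$chrom, df$start, df$end, df$strand,
                           high_confidence = TRUE)
  lens <- tapply(rec$end, rec$chrom, max) + 2L * config$flank + 1000L
  attr(rec, "chrom_lengths") <- stats::setNames(as.integer(lens), names(lens))
  rec
}

.rdirichlet1 <- function(k, alpha) {
  g <- stats::rgamma(k, shape = alpha)
  s <- sum(g)
  if (!is.finite(s) || s <= 0) return(rep(1 / k, k))
  g / s
}

.uniform_fragments <- function(n, chrom, lo, hi, frag_len) {
  # fragment start uniform on [lo, hi - frag_len); intervals 0-based half-open
  if (n == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  start <- lo + floor(stats::runif(n, 0, pmax(hi - lo - frag_len, 1)))
  data.frame(chrom = rep(chrom, n), start = as.integer(start),
             end = as.integer(start + frag_len), stringsAsFactors = FALSE)
}

#' Simulate a ChIP cohort over a toy annotation
#'
#' For each sample s and family f the activity budget is
#' `A[f,s] = exp(m_iso + b_fam + N(0, sigma_budget))`, conserved across
#' samples up to the jitter term; each sample independently partitions the
#' budget over member genes with Dirichlet(`alpha_sel`) weights, so which
#' members carry the family's activity varies from sample to sample. Gene
#' fragment counts are Poisson with rate `A * w * members_per_family *
#' mean_gene_frags`, fragments are placed uniformly within the gene's
#' quantification window, genome-wide background fragments are added, and a
#' matched input track is drawn as a flat Poisson field. All draws come from
#' the seeded generator, so a fixed config reproduces the cohort exactly.
#'
#' @param config a [synthetic_config()].
#' @param records annotation from [make_annotation()] (rebuilt from the
#'   config when omitted).
#' @param out_dir optional directory; when given, writes `genes.bed`,
#'   per-sample `*_chip.bed` / `*_input.bed` fragment files, `samples.tsv`
#'   and the ground-truth tables.
#' @return cohort list: `sheet` (sample sheet), `records`, `chip` and
#'   `input` (named lists of [fragment_source()]), and `truth` with the
#'   hidden parameters (`budgets`, `weights`, `rates` matrices and the
#'   family/isotype assignment).
#' @export
simulate_chip_cohort <- function(config, records = make_annotation(config),
                                 out_dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)

  n_s <- config$n_primary + config$n_metastatic
  condition <- rep(c("primary", "metastatic"),
                   c(config$n_primary, config$n_metastatic))
  sample_id <- ifelse(condition == "primary",
                      sprintf("P_%03d", seq_len(n_s)),
                      sprintf("M_%03d", seq_len(n_s)))

  fam_key <- family_key(records, "isoacceptor")
  iso_key <- family_key(records, "isotype")
  fams <- unique(fam_key)
  iso_of_fam <- iso_key[match(fams, fam_key)]
  isos <- unique(iso_of_fam)
  windows <- gene_windows(records, flank = config$flank,
                          chrom_lengths = attr(records, "chrom_lengths"))
  chrom_lengths <- attr(records, "chrom_lengths")
  frag_len <- config$fragment_length

  m_iso <- stats::setNames(stats::rnorm(length(isos), 0,
                                        config$isotype_log_sd), isos)
  b_fam <- stats::setNames(stats::rnorm(length(fams), 0,
                                        config$family_log_sd), fams)

  budgets <- matrix(NA_real_, length(fams), n_s,
                    dimnames = list(fams, sample_id))
  weights <- matrix(NA_real_, nrow(records), n_s,
                    dimnames = list(records$gene_id, sample_id))
  rates <- weights
  chip <- list(); input <- list()
  gene_of_fam <- split(seq_len(nrow(records)),
                       factor(fam_key, levels = fams))

  for (j in seq_len(n_s)) {
    A <- exp(m_iso[iso_of_fam] + b_fam +
               stats::rnorm(length(fams), 0, config$sigma_budget))
    if (condition[j] == "metastatic" && !is.null(config$met_budget_shift)) {
      shift <- config$met_budget_shift[fams]
      shift[is.na(shift)] <- 1
      A <- A * shift
    }
    budgets[, j] <- A
    w <- numeric(nrow(records))
    for (f in seq_along(fams)) {
      idx <- gene_of_fam[[f]]
      w[idx] <- .rdirichlet1(length(idx), config$alpha_sel)
    }
    weights[, j] <- w
    lam <- A[match(fam_key, fams)] * w *
      config$members_per_family * config$mean_gene_frags
    rates[, j] <- lam

    counts <- stats::rpois(nrow(records), lam)
    gi <- rep(seq_len(nrow(records)), counts)
    if (length(gi)) {
      lo <- windows$start[gi]; hi <- windows$end[gi]
      start <- lo + floor(stats::runif(length(gi), 0,
                                       pmax(hi - lo - frag_len, 1)))
      sig <- data.frame(chrom = windows$chrom[gi],
                        start = as.integer(start),
                        end = as.integer(start + frag_len),
                        stringsAsFactors = FALSE)
    } else {
      sig <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), stringsAsFactors = FALSE)
    }
    bg <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
      L <- chrom_lengths[[ch]]
      .uniform_fragments(stats::rpois(1, config$background_chip_per_kb *
                                        L / 1000), ch, 0L, L, frag_len)
    }))
    inp <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
      L <- chrom_lengths[[ch]]
      .uniform_fragments(stats::rpois(1, config$input_per_kb * L / 1000),
                         ch, 0L, L, frag_len)
    }))
    chip_df <- rbind(sig, bg)
    chip[[sample_id[j]]] <- fragment_source(sample_id[j], chip_df)
    input[[sample_id[j]]] <- fragment_source(paste0(sample_id[j], "_input"),
                                             inp)
  }

  sheet <- data.frame(sample_id = sample_id, condition = condition,
                      chip = NA_character_, input = NA_character_,
                      stringsAsFactors = FALSE)
  truth <- list(budgets = budgets, weights = weights, rates = rates,
                m_iso = m_iso, b_fam = b_fam,
                fam_of_gene = fam_key, iso_of_fam = iso_of_fam)
  cohort <- list(sheet = sheet, records = records, chip = chip,
                 input = input, truth = truth)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_gene_bed(records, file.path(out_dir, "genes.bed"))
    wb <- function(df, path) utils::write.table(
      df, path, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
    for (id in sample_id) {
      cp <- file.path(out_dir, paste0(id, "_chip.bed"))
      ip <- file.path(out_dir, paste0(id, "_input.bed"))
      wb(chip[[id]]$fragments, cp)
      wb(input[[id]]$fragments, ip)
      sheet$chip[sheet$sample_id == id] <- cp
      sheet$input[sheet$sample_id == id] <- ip
    }
    # the written sheet uses paths relative to its own directory
    rel <- sheet
    rel$chip <- basename(rel$chip); rel$input <- basename(rel$input)
    utils::write.table(rel, file.path(out_dir, "samples.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(family = fams, budgets),
                       file.path(out_dir, "truth_budgets.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(gene_id = records$gene_id, rates),
                       file.path(out_dir, "truth_rates.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cohort$sheet <- sheet
  }
  cohort
}

# expected censoring probability P(T > min(U, h)), U ~ Unif(0, cmax)
.censor_prob <- function(cmax, rate, horizon) {
  h <- min(cmax, horizon)
  # integral over u in [0, h] of exp(-r u) du / cmax, plus mass with u > h
  mean((1 - exp(-rate * h)) / (rate * cmax) +
         pmax(0, 1 - h / cmax) * exp(-rate * horizon))
}

#' Generate expression covariates for a synthetic patient cohort
#'
#' Independent log-normal expression values for `n_units` units across the
#' config's patients; a convenience input for survival simulations and
#' hazard screens.
#'
#' @param config a [synthetic_config()].
#' @param n_units number of units (genes or families).
#' @param log_sd log-scale standard deviation.
#' @return units x patients matrix with dimnames.
#' @export
simulate_expression_matrix <- function(config, n_units = 20L, log_sd = 0.5) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n_p <- config$n_patients
  m <- matrix(exp(stats::rnorm(n_units * n_p, 0, log_sd)), n_units, n_p)
  dimnames(m) <- list(sprintf("unit_%02d", seq_len(n_units)),
                      sprintf("patient_%04d", seq_len(n_p)))
  m
}

#' Simulate a survival cohort with a known hazard coefficient
#'
#' Each patient's hazard is `h0 * exp(beta_true * z)` with `z` the
#' standardized expression of `effect_unit`; event times are exponential.
#' Censoring is the minimum of an independent Uniform(0, c_max) time and the
#' administrative horizon, with `c_max` calibrated so that the expected
#' censoring fraction matches the config's target; when the target is below
#' the floor imposed by the horizon, a warning reports the achieved value.
#'
#' @param config a [synthetic_config()].
#' @param expression units x patients matrix (e.g.
#'   [simulate_expression_matrix()]).
#' @param effect_unit rowname of the unit that carries the effect.
#' @return list `surv` (a [survival_table()], time unit years) and `truth`
#'   (`beta_true`, `z`, `rates`, `c_max`, `expected_censoring`).
#' @export
simulate_survival_cohort <- function(config, expression,
                                     effect_unit = rownames(expression)[1]) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!effect_unit %in% rownames(expression)) {
    stop("effect_unit '", effect_unit, "' not present in expression matrix")
  }
  set.seed(config$seed)
  x <- expression[effect_unit, ]
  z <- (x - mean(x)) / stats::sd(x)
  rate <- config$baseline_hazard * exp(config$beta_true * z)
  n <- length(z)
  t_event <- stats::rexp(n, rate)

  target <- config$censoring_fraction
  h <- config$horizon
  floor_cens <- mean(exp(-rate * h))  # censoring from the horizon alone
  if (target <= floor_cens) {
    warning(sprintf(
      "target censoring fraction %.2f unattainable below the %.2f imposed ",
      target, floor_cens), "by the horizon; using horizon-only censoring")
    c_max <- Inf
    C <- rep(h, n)
    expected <- floor_cens
  } else {
    f <- function(cm) .censor_prob(cm, rate, h) - target
    c_max <- stats::uniroot(f, lower = 1e-6, upper = 1e6, tol = 1e-10)$root
    C <- pmin(stats::runif(n, 0, c_max), h)
    expected <- .censor_prob(c_max, rate, h)
  }
  time <- pmin(t_event, C)
  event <- as.integer(t_event <= C)
  time <- pmax(time, 1e-9)
  surv <- survival_table(colnames(expression), time, event,
                         time_unit = "years")
  list(surv = surv,
       truth = list(beta_true = config$beta_true, z = z, rates = rate,
                    c_max = c_max, expected_censoring = expected))
}
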