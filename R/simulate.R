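#' Configuration for a synthetic glioma-like cohort
#'
#' Bundles every knob of the synthetic-cohort generator: cohort size, gene
#' panel, planted proportional-hazards effects, expression-outlier process,
#' exponential baseline hazard, administrative censoring horizon and grade
#' mix. The defaults describe a lower-grade-glioma-like cohort: 275 samples,
#' 61 iron-regulatory genes, roughly 79% of patients alive (censored) at the
#' end of follow-up, and an approximately even split of grade II and III
#' tumors.
#'
#' @param n_samples number of patients (>= 2).
#' @param n_genes number of genes; ignored when `gene_names` is given.
#' @param gene_names character vector of gene symbols; defaults to the
#'   shipped 61-gene iron panel (recycled/truncated to `n_genes`).
#' @param planted_effects named numeric vector, gene -> log hazard ratio per
#'   unit of expression (the generator draws expression on the z scale).
#'   Unnamed empty vector means a null cohort.
#' @param outlier_fraction probability in \[0,1) that a given (gene, sample)
#'   cell is an expression outlier.
#' @param outlier_shift magnitude, in z units, added (with random sign) to
#'   outlier cells.
#' @param baseline_hazard exponential event rate, events per month (> 0).
#' @param censor_time administrative censoring horizon in months; events
#'   after this time are observed as censored at `censor_time`.
#' @param grade_probs named probabilities over grades II, III, IV; must sum
#'   to 1.
#' @param grade_hazard optional named multipliers on the hazard per grade
#'   (default: grade does not affect hazard).
#' @param aberrant_hazard optional named numeric vector, gene -> hazard
#'   multiplier applied to samples whose generated expression of that gene
#'   lies beyond |2| (i.e. the sample is aberrant in the gene at the
#'   default threshold). This plants a signal on the aberrance state
#'   itself — both expression tails raise hazard — which is the
#'   data-generating process an any-aberrant survival split is designed to
#'   detect, as opposed to `planted_effects`, whose signed linear link
#'   makes one tail protective.
#' @param idh1_prob probability that a sample carries an IDH1 mutation flag.
#' @param seed integer seed; one seed drives all stages through derived
#'   sub-streams, so a config + seed pair fully determines the cohort.
#'
#' @return an object of class `sim_config`.
#' @seealso [simulate_cohort()], [cohort_preset()]
#' @export
sim_config <- function(n_samples = 275,
                       n_genes = 61,
                       gene_names = NULL,
                       planted_effects = numeric(0),
                       outlier_fraction = 0.01,
                       outlier_shift = 4,
                       baseline_hazard = log(2) / 90,
                       censor_time = 30,
                       grade_probs = c(II = 0.491, III = 0.509, IV = 0),
                       grade_hazard = NULL,
                       aberrant_hazard = NULL,
                       idh1_prob = 0.77,
                       seed = 1L) {
  if (!is_count(n_samples) || n_samples < 2)
    stopf("n_samples must be an integer >= 2 (got %s)", format(n_samples))
  if (is.null(gene_names)) {
    if (!is_count(n_genes) || n_genes < 1)
      stopf("n_genes must be a positive integer (got %s)", format(n_genes))
    pool <- iron_panel("iron61")
    gene_names <- if (n_genes <= length(pool)) pool[seq_len(n_genes)] else
      c(pool, sprintf("GENE%03d", seq_len(n_genes - length(pool))))
  }
  gene_names <- as.character(gene_names)
  if (anyDuplicated(gene_names))
    stopf("duplicate gene names: %s",
          paste(unique(gene_names[duplicated(gene_names)]), collapse = ", "))
  if (length(planted_effects)) {
    if (is.null(names(planted_effects)) || any(!nzchar(names(planted_effects))))
      stopf("planted_effects must be a named numeric vector (gene -> log HR)")
    missing <- setdiff(names(planted_effects), gene_names)
    if (length(missing))
      stopf("planted_effects name genes absent from the cohort: %s",
            paste(missing, collapse = ", "))
  }
  if (!is.numeric(outlier_fraction) || outlier_fraction < 0 ||
      outlier_fraction >= 1)
    stopf("outlier_fraction must lie in [0, 1)")
  if (!is.numeric(baseline_hazard) || baseline_hazard <= 0)
    stopf("baseline_hazard must be > 0")
  if (!is.numeric(censor_time) || censor_time < 0)
    stopf("censor_time must be >= 0 (Inf allowed)")
  grade_probs <- grade_probs[c("II", "III", "IV")]
  grade_probs[is.na(grade_probs)] <- 0
  names(grade_probs) <- c("II", "III", "IV")
  if (abs(sum(grade_probs) - 1) > 1e-8)
    stopf("grade_probs must sum to 1 (got %.6f)", sum(grade_probs))
  if (!is.null(grade_hazard)) {
    if (is.null(names(grade_hazard)) ||
        !all(names(grade_hazard) %in% c("II", "III", "IV")))
      stopf("grade_hazard must be named with grades II/III/IV")
    if (any(grade_hazard <= 0)) stopf("grade_hazard multipliers must be > 0")
  }
  if (!is.null(aberrant_hazard)) {
    if (is.null(names(aberrant_hazard)) || any(!nzchar(names(aberrant_hazard))))
      stopf("aberrant_hazard must be a named numeric vector (gene -> multiplier)")
    missing <- setdiff(names(aberrant_hazard), gene_names)
    if (length(missing))
      stopf("aberrant_hazard names genes absent from the cohort: %s",
            paste(missing, collapse = ", "))
    if (any(aberrant_hazard <= 0))
      stopf("aberrant_hazard multipliers must be > 0")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = length(gene_names),
                 gene_names = gene_names,
                 planted_effects = planted_effects,
                 outlier_fraction = outlier_fraction,
                 outlier_shift = outlier_shift,
                 baseline_hazard = baseline_hazard,
                 censor_time = censor_time,
                 grade_probs = grade_probs,
                 grade_hazard = grade_hazard,
                 aberrant_hazard = aberrant_hazard,
                 idh1_prob = idh1_prob,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Preset synthetic-cohort configurations
#'
#' `"lgg"` emulates the structure of a TCGA lower-grade-glioma cohort:
#' 275 samples, ~79% administratively censored, grades II and III in roughly
#' equal proportion, most tumors IDH1-mutated. `"gbm"` emulates a
#' glioblastoma cohort: 135 samples, ~77% deceased by end of follow-up,
#' all grade IV, IDH1 mutation rare.
#'
#' @param cohort `"lgg"` or `"gbm"`.
#' @param ... overrides passed on to [sim_config()].
#' @return a `sim_config`.
#' @export
cohort_preset <- function(cohort = c("lgg", "gbm"), ...) {
  cohort <- match.arg(cohort)
  args <- list(...)
  base <- if (cohort == "lgg") {
    list(n_samples = 275, baseline_hazard = log(2) / 90, censor_time = 30,
         grade_probs = c(II = 0.491, III = 0.509, IV = 0), idh1_prob = 0.77)
  } else {
    list(n_samples = 135, baseline_hazard = log(2) / 13, censor_time = 28,
         grade_probs = c(II = 0, III = 0, IV = 1), idh1_prob = 0.055)
  }
  base[names(args)] <- args
  do.call(sim_config, base)
}

#' Simulate a gene-expression matrix with planted outliers
#'
#' Draws per-gene expression standard normal across samples, then turns a
#' random subset of cells into outliers by adding `outlier_shift` z units
#' with random sign. Because the background is standard normal, downstream
#' z-scoring approximately preserves the outlier calls (large
#' `outlier_fraction` distorts the per-gene scale, see the methods
#' vignette).
#'
#' @param config a [sim_config()].
#' @return list with `expression` (genes x samples numeric matrix) and
#'   `outlier_mask` (logical matrix of the same shape, TRUE where a shift
#'   was planted).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$n_genes
  n <- config$n_samples
  sample_ids <- sprintf("S%04d", seq_len(n))
  expr <- with_seed(stage_seed(config$seed, "expression"), {
    matrix(stats::rnorm(g * n), nrow = g, ncol = n)
  })
  mask <- matrix(FALSE, g, n)
  if (config$outlier_fraction > 0) {
    shift <- with_seed(stage_seed(config$seed, "outlier"), {
      m <- matrix(stats::runif(g * n) < config$outlier_fraction, g, n)
      s <- matrix(sample(c(-1, 1), g * n, replace = TRUE), g, n)
      list(mask = m, sign = s)
    })
    mask <- shift$mask
    expr <- expr + ifelse(mask, shift$sign * config$outlier_shift, 0)
  }
  dimnames(expr) <- dimnames(mask) <- list(config$gene_names, sample_ids)
  list(expression = expr, outlier_mask = mask)
}

#' Simulate right-censored survival under proportional hazards
#'
#' Event times are exponential with per-sample rate
#' `baseline_hazard * exp(sum_g beta_g x_g) * grade multiplier`; the
#' observed time is the minimum of the event time and the administrative
#' censoring horizon, and the event flag records whether death occurred
#' before the horizon. Grade and the IDH1 flag are drawn independently of
#' expression unless `grade_hazard` is set.
#'
#' @param expr genes x samples expression matrix (from
#'   [simulate_expression()] or compatible).
#' @param config a [sim_config()]; every gene in `planted_effects` must be a
#'   row of `expr`.
#' @return list with `clinical` (data.frame: sample_id, os_months, event,
#'   grade, idh1_mutated, dfs_months) and `truth` (list: true_betas,
#'   true_event_times).
#' @export
simulate_survival <- function(expr, config) {
  stopifnot(inherits(config, "sim_config"), is.matrix(expr))
  n <- ncol(expr)
  betas <- stats::setNames(numeric(nrow(expr)), rownames(expr))
  if (length(config$planted_effects)) {
    missing <- setdiff(names(config$planted_effects), rownames(expr))
    if (length(missing))
      stopf("planted effect gene(s) absent from expression matrix: %s",
            paste(missing, collapse = ", "))
    betas[names(config$planted_effects)] <- config$planted_effects
  }
  grades <- with_seed(stage_seed(config$seed, "grade"), {
    factor(sample(names(config$grade_probs), n, replace = TRUE,
                  prob = config$grade_probs), levels = c("II", "III", "IV"))
  })
  mult <- rep(1, n)
  if (!is.null(config$grade_hazard)) {
    m <- config$grade_hazard[as.character(grades)]
    mult <- ifelse(is.na(m), 1, m)
  }
  if (!is.null(config$aberrant_hazard)) {
    missing <- setdiff(names(config$aberrant_hazard), rownames(expr))
    if (length(missing))
      stopf("aberrant hazard gene(s) absent from expression matrix: %s",
            paste(missing, collapse = ", "))
    for (g in names(config$aberrant_hazard))
      mult <- mult * ifelse(abs(expr[g, ]) > 2, config$aberrant_hazard[[g]], 1)
  }
  eta <- as.numeric(crossprod(expr, betas))
  rate <- config$baseline_hazard * exp(eta) * mult
  true_t <- with_seed(stage_seed(config$seed, "survival"),
                      stats::rexp(n, rate = rate))
  idh1 <- with_seed(stage_seed(config$seed, "idh1"),
                    stats::runif(n) < config$idh1_prob)
  observed <- pmin(true_t, config$censor_time)
  event <- true_t <= config$censor_time
  clinical <- data.frame(
    sample_id = colnames(expr),
    os_months = observed,
    event = event,
    grade = grades,
    idh1_mutated = idh1,
    dfs_months = NA_real_,
    stringsAsFactors = FALSE
  )
  list(clinical = clinical,
       truth = list(true_betas = betas, true_event_times = true_t))
}

#' Simulate a full cohort (expression + clinical + ground truth)
#'
#' @param config a [sim_config()].
#' @return list with `expression`, `clinical`, and `truth` (true_betas,
#'   outlier_mask, true_event_times).
#' @export
simulate_cohort <- function(config) {
  ex <- simulate_expression(config)
  sv <- simulate_survival(ex$expression, config)
  list(expression = ex$expression,
       clinical = sv$clinical,
       truth = list(true_betas = sv$truth$true_betas,
                    outlier_mask = ex$outlier_mask,
                    true_event_times = sv$truth$true_event_times))
}

#' Write a simulated cohort in the TSV dialects the readers consume
#'
#' Expression goes out as a `Hugo_Symbol`-keyed genes x samples table,
#' clinical as one row per sample, and the ground truth (true event times
#' and planted betas) as a sidecar for downstream validation — so pipeline
#' tests can round-trip through files.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, named paths of the files written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             truth = file.path(dir, "ground_truth.tsv"))
  expr_df <- data.frame(Hugo_Symbol = rownames(cohort$expression),
                        cohort$expression, check.names = FALSE,
                        stringsAsFactors = FALSE)
  utils::write.table(expr_df, paths[["expression"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$clinical, paths[["clinical"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  truth_df <- data.frame(sample_id = cohort$clinical$sample_id,
                         true_event_time = cohort$truth$true_event_times,
                         stringsAsFactors = FALSE)
  utils::write.table(truth_df, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
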