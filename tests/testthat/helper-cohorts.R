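# Shared fixture builders. Everything is generated in code; no stored data.

# Small cohort with optional planted effects, LGG-like censoring by default.
make_cohort <- function(n = 100, betas = numeric(0), seed = 1,
                        n_genes = 8, censor_time = 30,
                        baseline_hazard = log(2) / 90, ...) {
  pool <- iron_panel("iron61")
  genes <- unique(c(names(betas), pool))[seq_len(n_genes)]
  cfg <- sim_config(n_samples = n, gene_names = genes,
                    planted_effects = betas, censor_time = censor_time,
                    baseline_hazard = baseline_hazard, seed = seed, ...)
  simulate_cohort(cfg)
}

# Hand-built clinical table.
clin_table <- function(os, event, grade = NULL, id = NULL) {
  n <- length(os)
  data.frame(
    sample_id = if (is.null(id)) sprintf("S%04d", seq_len(n)) else id,
    os_months = os,
    event = event,
    grade = if (is.null(grade)) factor(rep(NA_character_, n),
                                       levels = c("II", "III", "IV"))
            else factor(grade, levels = c("II", "III", "IV")),
    idh1_mutated = NA,
    dfs_months = NA_real_,
    stringsAsFactors = FALSE
  )
}

# Random small survival data for oracle cross-checks.
random_surv <- function(n, seed, censor_frac = 0.3) {
  set.seed(seed)
  tm <- rexp(n, 0.05)
  ev <- runif(n) > censor_frac
  list(time = round(tm, 3), event = ev)
}
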