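#' Pipeline configuration
#'
#' Bundles every tunable cutoff of the pipeline.  Defaults are the
#' method's standard operating point: efficacious drugs are called at
#' \eqn{z \ge 1.65} (one-sided p of about 0.05 under a standard normal
#' null), a protein is a candidate MOA protein at Fisher p < 0.05, disease
#' pairs are significant at q < 0.05, the comorbidity-enrichment weight
#' coefficient is \eqn{\alpha = 0.025} with an enrichment score threshold
#' of 0.01 over the top 100 comorbidities, benchmark "easy pairs" are
#' excluded above a 0.9 efficacious-drug overlap, and permutation nulls
#' use 100 runs.
#'
#' @param z_cutoff z-score at or above which a drug counts as efficacious.
#' @param moa_p_cutoff Fisher p-value below which a protein is a candidate
#'   MOA protein for a disease.
#' @param pair_q_cutoff q-value below which a disease pair (or pathway
#'   family member) is called significant.
#' @param alpha Coefficient of the comorbidity-enrichment weight
#'   `min(1, -alpha * ln p)`.
#' @param top_k_comorbid Number of top-ranked comorbidities pooled when
#'   scoring comorbidity-enriched proteins.
#' @param enrich_score_cutoff Normalised enrichment score above which a
#'   protein is flagged enriched.
#' @param easy_pair_cutoff Efficacious-drug overlap
#'   \eqn{|A \cap B| / \sqrt{|A||B|}} above which (strictly) a pair is
#'   excluded from benchmarking as trivially implied.
#' @param n_permutations Number of permutation-null runs.
#' @param rng_seed Integer seed governing all randomness.
#' @return A named list of class `comoa_config`.
#' @examples
#' cfg <- comoaConfig(rng_seed = 7)
#' cfg$z_cutoff
#' @export
comoaConfig <- function(z_cutoff = 1.65,
                        moa_p_cutoff = 0.05,
                        pair_q_cutoff = 0.05,
                        alpha = 0.025,
                        top_k_comorbid = 100L,
                        enrich_score_cutoff = 0.01,
                        easy_pair_cutoff = 0.9,
                        n_permutations = 100L,
                        rng_seed = 1L) {
  cfg <- list(
    z_cutoff = as.numeric(z_cutoff),
    moa_p_cutoff = as.numeric(moa_p_cutoff),
    pair_q_cutoff = as.numeric(pair_q_cutoff),
    alpha = as.numeric(alpha),
    top_k_comorbid = as.integer(top_k_comorbid),
    enrich_score_cutoff = as.numeric(enrich_score_cutoff),
    easy_pair_cutoff = as.numeric(easy_pair_cutoff),
    n_permutations = as.integer(n_permutations),
    rng_seed = as.integer(rng_seed)
  )
  for (nm in c("moa_p_cutoff", "pair_q_cutoff")) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] <= 0 || cfg[[nm]] >= 1) {
      stop(sprintf("'%s' must be a probability in (0, 1)", nm))
    }
  }
  for (nm in c("alpha", "enrich_score_cutoff", "easy_pair_cutoff")) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] <= 0) {
      stop(sprintf("'%s' must be positive", nm))
    }
  }
  if (cfg$top_k_comorbid < 1L) stop("'top_k_comorbid' must be >= 1")
  if (cfg$n_permutations < 1L) stop("'n_permutations' must be >= 1")
  if (!is.finite(cfg$z_cutoff)) stop("'z_cutoff' must be finite")
  class(cfg) <- "comoa_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys fall back to the
#' [comoaConfig()] defaults.
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [comoaConfig()].
#' @return A `comoa_config` list.
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(comoaConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(comoaConfig, vals)
}

#' @export
print.comoa_config <- function(x, ...) {
  cat("comoa pipeline configuration\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
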