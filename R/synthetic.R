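# Seeded synthetic-world generator with planted ground truth.  Emulates
# the upstream predictors' outputs (probe-drug indication scores and
# drug-target maps) plus claims-style clinical counts, so that every
# pipeline stage is testable without external data.

#' Synthetic-world generator parameters
#'
#' Defaults define the standard study conditions of the package's own
#' test bed: 300 probe drugs, a 2000-protein universe, 40 diseases each
#' with a planted 25-protein mode-of-action module, signal effect size
#' `delta = 3` against unit Gaussian score noise, and 8 planted comorbid
#' pairs sharing half their modules.  Each drug is dedicated round-robin
#' to one disease and draws `module_target_frac` of its
#' `targets_per_drug` targets from that disease's module — emulating a
#' drug library developed against disease-relevant targets.  Clinical
#' counts come from binomial draws over a one-million-patient cohort with
#' per-disease prevalence uniform in (0.01, 0.05); planted pairs co-occur
#' at `rr_planted` times independence, all other pairs at independence.
#'
#' @param n_drugs,n_proteins,n_diseases World dimensions.
#' @param module_size Planted module size per disease.
#' @param targets_per_drug Predicted targets per drug.
#' @param module_target_frac Fraction of a drug's targets drawn from its
#'   dedicated disease's module.
#' @param delta Score effect size: raw score of drug d for disease D is
#'   `delta * |targets(d) ∩ module(D)| / |targets(d)|` plus noise.
#' @param noise_sd Gaussian score noise standard deviation.
#' @param n_planted_pairs Number of planted comorbid disease pairs.
#' @param sharing_frac Fraction of the module shared within a planted
#'   pair (exact by construction).
#' @param n_tot Clinical cohort size.
#' @param rr_planted Co-occurrence relative risk planted for comorbid
#'   pairs (1 = independence).
#' @param prevalence_range Range of per-disease prevalence.
#' @param n_tissues,tissues_per_disease,tissue_coverage Tissue table
#'   shape: number of tissue names, related tissues per disease, and the
#'   probability that a (protein, tissue) record exists.
#' @param n_decoy_pathways Decoy gene sets added to the GMT collection
#'   beside the planted modules.
#' @return Named list of parameters for [generateWorld()].
#' @export
worldParams <- function(n_drugs = 300L, n_proteins = 2000L, n_diseases = 40L,
                        module_size = 25L, targets_per_drug = 25L,
                        module_target_frac = 0.8, delta = 3, noise_sd = 1,
                        n_planted_pairs = 8L, sharing_frac = 0.5,
                        n_tot = 1e6, rr_planted = 5,
                        prevalence_range = c(0.01, 0.05),
                        n_tissues = 8L, tissues_per_disease = 2L,
                        tissue_coverage = 0.5,
                        n_decoy_pathways = 20L) {
  as.list(environment())
}

#' Generate a synthetic world with planted ground truth
#'
#' Deterministic function of `params` and `seed`.  Construction: (i)
#' every disease gets a planted protein module; planted pairs share an
#' exact `sharing_frac` fraction of module proteins; (ii) every drug gets
#' a target set biased toward its dedicated disease's module; (iii) the
#' raw score of drug d for disease D is
#' `delta * |targets(d) ∩ module(D)| / |targets(d)|` plus Gaussian noise,
#' so drugs hitting the module score high; (iv) clinical counts are
#' binomial draws in which planted pairs co-occur at `rr_planted` times
#' independence (capped at `min(n_a, n_b)`) and all other pairs at
#' independence; (v) the GMT collection contains each planted module as a
#' pathway plus random decoys.  The tissue table is uniform-random levels
#' (mostly detected) and is deliberately unrealistic — it exists to
#' exercise the filter, not to model histology.
#'
#' @param params Parameter list from [worldParams()].
#' @param seed Integer seed.
#' @return A [SyntheticWorld-class].
#' @export
generateWorld <- function(params = worldParams(), seed = 1L) {
  p <- params
  if (p$module_size > p$n_proteins) stop("module size exceeds protein count")
  if (p$n_diseases < 2) stop("need at least 2 diseases")
  if (2 * p$n_planted_pairs > p$n_diseases) {
    stop("too many planted pairs for the number of diseases")
  }
  withr::with_seed(as.integer(seed), {
    proteins <- sprintf("P%04d", seq_len(p$n_proteins))
    diseases <- sprintf("D%02d", seq_len(p$n_diseases))
    drugs <- sprintf("drug%03d", seq_len(p$n_drugs))

    # (i) planted modules; planted pairs (D1,D2), (D3,D4), ... share an
    # exact round(sharing_frac * module_size) proteins
    modules <- stats::setNames(vector("list", p$n_diseases), diseases)
    plantedPairs <- data.frame(
      disease_a = diseases[2 * seq_len(p$n_planted_pairs) - 1],
      disease_b = diseases[2 * seq_len(p$n_planted_pairs)],
      stringsAsFactors = FALSE
    )
    nShare <- round(p$sharing_frac * p$module_size)
    paired <- character(0)
    for (k in seq_len(p$n_planted_pairs)) {
      a <- plantedPairs$disease_a[k]
      b <- plantedPairs$disease_b[k]
      modA <- sample(proteins, p$module_size)
      fresh <- sample(setdiff(proteins, modA), p$module_size - nShare)
      modules[[a]] <- modA
      modules[[b]] <- c(sample(modA, nShare), fresh)
      paired <- c(paired, a, b)
    }
    for (d in setdiff(diseases, paired)) {
      modules[[d]] <- sample(proteins, p$module_size)
    }

    # (ii) drug target sets: round-robin dedication to a disease
    dedicated <- diseases[((seq_len(p$n_drugs) - 1) %% p$n_diseases) + 1]
    nMod <- round(p$module_target_frac * p$targets_per_drug)
    nMod <- min(nMod, p$module_size)
    targets <- stats::setNames(vector("list", p$n_drugs), drugs)
    for (i in seq_len(p$n_drugs)) {
      mod <- modules[[dedicated[i]]]
      fromMod <- sample(mod, nMod)
      fromRest <- sample(setdiff(proteins, fromMod),
                         p$targets_per_drug - nMod)
      targets[[i]] <- c(fromMod, fromRest)
    }

    # (iii) raw scores
    scores <- matrix(0, nrow = p$n_drugs, ncol = p$n_diseases,
                     dimnames = list(drugs, diseases))
    for (j in seq_len(p$n_diseases)) {
      overlap <- vapply(targets, function(tg) {
        length(intersect(tg, modules[[j]]))
      }, integer(1))
      scores[, j] <- p$delta * overlap / p$targets_per_drug +
        stats::rnorm(p$n_drugs, 0, p$noise_sd)
    }

    # (iv) clinical counts for every unordered disease pair
    prev <- stats::runif(p$n_diseases, p$prevalence_range[1],
                         p$prevalence_range[2])
    names(prev) <- diseases
    nA <- stats::setNames(
      stats::rbinom(p$n_diseases, p$n_tot, prev), diseases
    )
    nA <- pmax(nA, 1L)
    pairKey <- paste(plantedPairs$disease_a, plantedPairs$disease_b)
    iIdx <- rep.int(seq_len(p$n_diseases - 1L), (p$n_diseases - 1L):1L)
    jIdx <- sequence((p$n_diseases - 1L):1L, from = 2:p$n_diseases)
    da <- diseases[iIdx]
    db <- diseases[jIdx]
    rr <- ifelse(paste(da, db) %in% pairKey, p$rr_planted, 1)
    qab <- pmin(rr * (nA[da] / p$n_tot) * (nA[db] / p$n_tot),
                pmin(nA[da], nA[db]) / p$n_tot)
    nAB <- stats::rbinom(length(qab), p$n_tot, qab)
    nAB <- pmin(nAB, pmin(nA[da], nA[db]))
    clinical <- data.frame(
      disease_a = da, disease_b = db,
      n_a = as.numeric(nA[da]), n_b = as.numeric(nA[db]),
      n_ab = as.numeric(nAB), stringsAsFactors = FALSE
    )

    # tissue table + disease-tissue map
    tissues <- sprintf("tissue_%02d", seq_len(p$n_tissues))
    tissueMap <- stats::setNames(lapply(seq_len(p$n_diseases), function(i) {
      sample(tissues, p$tissues_per_disease)
    }), diseases)
    rec <- expand.grid(protein = proteins, tissue = tissues,
                       stringsAsFactors = FALSE)
    keep <- stats::runif(nrow(rec)) < p$tissue_coverage
    rec <- rec[keep, , drop = FALSE]
    rec$level <- sample(TISSUE_LEVELS, nrow(rec), replace = TRUE,
                        prob = c(0.1, 0.3, 0.4, 0.2))
    rec$reliability <- sample(c("approved", "supported", "uncertain"),
                              nrow(rec), replace = TRUE,
                              prob = c(0.8, 0.1, 0.1))
    rownames(rec) <- NULL

    # (v) GMT: planted modules + decoys
    gmt <- modules
    names(gmt) <- paste0("module_", diseases)
    decoys <- stats::setNames(lapply(seq_len(p$n_decoy_pathways), function(i) {
      sample(proteins, p$module_size)
    }), sprintf("decoy_%02d", seq_len(p$n_decoy_pathways)))
    gmt <- c(gmt, decoys)
    attr(gmt, "descriptions") <- stats::setNames(
      c(paste("planted module of", diseases),
        rep("random decoy set", p$n_decoy_pathways)),
      names(gmt)
    )

    new("SyntheticWorld",
        scores = scores, targets = targets, universe = proteins,
        tissue = rec, tissueMap = tissueMap, clinical = clinical,
        nTot = p$n_tot, gmt = gmt,
        truth = list(modules = modules, plantedPairs = plantedPairs),
        params = p, seed = as.integer(seed))
  })
}

#' Evaluate pipeline outputs against the planted truth
#'
#' Recovery report for outputs computed on a [SyntheticWorld-class]:
#' pooled MOA recall and precision of the inferred MOA sets against the
#' planted modules; AUROC of the J-score separating planted comorbid
#' pairs from all other pairs; and, when pathway over-representation
#' results are given, the rank of each planted module pathway.
#'
#' @param truth The `truth` list of a [SyntheticWorld-class] (or the
#'   world itself).
#' @param profiles Optional [MoaProfileSet-class].
#' @param result Optional [ComorbidityResult-class] from [allPairs()].
#' @param pathways Optional data.frame from [pathwayOra()].
#' @return List with any of `moaRecall`, `moaPrecision` (fractions in
#'   `[0, 1]`), `comorbidityAuroc`, `pathwayRanks` (named integer
#'   vector).
#' @export
truthEval <- function(truth, profiles = NULL, result = NULL,
                      pathways = NULL) {
  if (is(truth, "SyntheticWorld")) truth <- truth@truth
  out <- list()
  if (!is.null(profiles)) {
    sets <- moaSets(profiles)
    miss <- setdiff(names(truth$modules), names(sets))
    if (length(miss)) stop("profiles lack planted diseases: ",
                           paste(head(miss, 5), collapse = ", "))
    tp <- sum(vapply(names(truth$modules), function(d) {
      length(intersect(sets[[d]], truth$modules[[d]]))
    }, numeric(1)))
    nPlanted <- sum(lengths(truth$modules))
    nCalled <- sum(lengths(sets[names(truth$modules)]))
    out$moaRecall <- tp / nPlanted
    out$moaPrecision <- if (nCalled > 0) tp / nCalled else NA_real_
  }
  if (!is.null(result)) {
    e <- edgeTable(result)
    key <- paste(pmin(e$diseaseA, e$diseaseB), pmax(e$diseaseA, e$diseaseB))
    pKey <- paste(pmin(truth$plantedPairs$disease_a, truth$plantedPairs$disease_b),
                  pmax(truth$plantedPairs$disease_a, truth$plantedPairs$disease_b))
    if (!all(pKey %in% key)) stop("edge table does not cover the planted pairs")
    planted <- key %in% pKey
    out$comorbidityAuroc <- aucRoc(e$jScore, planted)
  }
  if (!is.null(pathways)) {
    ranks <- match(paste0("module_", names(truth$modules)), pathways$pathway)
    names(ranks) <- names(truth$modules)
    out$pathwayRanks <- ranks
  }
  out
}
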