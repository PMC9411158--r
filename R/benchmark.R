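# Benchmarking against clinical co-occurrence: log relative risk and phi
# score of claims counts, Table-style evaluation metrics (recall,
# precision, correlations, AUROC, AUPRC), easy-pair exclusion, and the
# two permutation null models.

#' Log relative risk of clinical co-occurrence
#'
#' \eqn{\ln\frac{n_{AB}/n_{tot}}{(n_A/n_{tot})(n_B/n_{tot})}}: the log of
#' the probability that the two diseases co-occur in one individual
#' relative to independence.  Natural log; the base affects only the
#' scale, never the sign, and comorbidity labels are sign-based.
#' `n_ab = 0` is undefined (the record is excluded upstream).
#'
#' @param n_a,n_b Patients with disease A / B (>= 1, vectorised).
#' @param n_ab Patients with both (>= 1).
#' @param n_tot Total cohort size.
#' @return Log relative risks.
#' @export
logRR <- function(n_a, n_b, n_ab, n_tot) {
  r <- suppressWarnings(cbind(n_a, n_b, n_ab, n_tot))
  dimnames(r) <- NULL
  storage.mode(r) <- "double"
  n_a <- r[, 1]; n_b <- r[, 2]; n_ab <- r[, 3]; n_tot <- r[, 4]
  if (any(n_ab < 1)) stop("log RR undefined for n_ab = 0; exclude the record")
  if (any(n_a < 1) || any(n_b < 1)) stop("marginal counts must be >= 1")
  if (any(n_tot < pmax(n_a, n_b))) stop("n_tot must be >= max(n_a, n_b)")
  log((n_ab / n_tot) / ((n_a / n_tot) * (n_b / n_tot)))
}

#' Phi score of clinical co-occurrence
#'
#' Pearson correlation of the two binary disease indicators over the
#' cohort:
#' \eqn{(n_{AB} n_{tot} - n_A n_B)/\sqrt{n_A n_B (n_{tot}-n_A)(n_{tot}-n_B)}}.
#' Its sign always agrees with the sign of the log relative risk.
#'
#' @param n_a,n_b Patients with disease A / B, strictly between 0 and
#'   `n_tot`.
#' @param n_ab Patients with both.
#' @param n_tot Total cohort size.
#' @return Phi scores in `[-1, 1]`.
#' @export
phiScore <- function(n_a, n_b, n_ab, n_tot) {
  r <- suppressWarnings(cbind(n_a, n_b, n_ab, n_tot))
  dimnames(r) <- NULL
  storage.mode(r) <- "double"  # integer inputs would overflow the products
  n_a <- r[, 1]; n_b <- r[, 2]; n_ab <- r[, 3]; n_tot <- r[, 4]
  if (any(n_a <= 0 | n_a >= n_tot) || any(n_b <= 0 | n_b >= n_tot)) {
    stop("phi undefined for degenerate margins (n in {0, n_tot})")
  }
  (n_ab * n_tot - n_a * n_b) /
    sqrt(n_a * n_b * (n_tot - n_a) * (n_tot - n_b))
}

#' AUROC by the rank statistic with tie correction
#'
#' Equals the probability that a random positive outranks a random
#' negative, ties counted half (Mann-Whitney).
#'
#' @param score Numeric prediction scores.
#' @param label Logical (or 0/1) true labels.
#' @return AUROC in `[0, 1]`.
#' @export
aucRoc <- function(score, label) {
  label <- as.logical(label)
  nPos <- sum(label)
  nNeg <- sum(!label)
  if (nPos == 0 || nNeg == 0) stop("AUROC needs both classes")
  r <- rank(score, ties.method = "average")
  (sum(r[label]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' AUPRC by step-wise precision-recall summation
#'
#' Ranks by score descending (tied scores processed as one block) and
#' sums precision times the recall increment at each block.
#'
#' @param score Numeric prediction scores.
#' @param label Logical (or 0/1) true labels.
#' @return AUPRC in `[0, 1]`.
#' @export
aucPr <- function(score, label) {
  label <- as.logical(label)
  nPos <- sum(label)
  if (nPos == 0) stop("AUPRC needs at least one positive")
  o <- order(score, decreasing = TRUE)
  s <- score[o]
  l <- label[o]
  # block boundaries at distinct score values
  newBlock <- c(TRUE, s[-1] != s[-length(s)])
  blockId <- cumsum(newBlock)
  tpBlock <- tapply(l, blockId, sum)
  nBlock <- tapply(l, blockId, length)
  tp <- cumsum(tpBlock)
  nSeen <- cumsum(nBlock)
  prec <- tp / nSeen
  rec <- tp / nPos
  dRec <- diff(c(0, rec))
  sum(prec * dRec)
}

#' Benchmark predicted comorbidity against clinical co-occurrence
#'
#' Joins the predicted edge table with the clinical table on the
#' unordered disease pair (pairs missing from either side are dropped),
#' excludes records with `n_ab = 0` (log RR undefined, warned) and easy
#' pairs (efficacious-drug overlap strictly above the cutoff, when
#' `effDrugs` are supplied), then computes: truth label `log RR > 0`,
#' predicted positive `q < pair_q_cutoff`; recall and precision in
#' percent; Pearson correlations (with two-sided p) of the J-score with
#' log RR and with phi; AUROC (rank statistic, tie-corrected) and AUPRC
#' (step-wise) using the J-score as the continuous ranking variable.
#'
#' @param result A [ComorbidityResult-class] (or its edge data.frame).
#' @param clinical Clinical co-occurrence data.frame (`disease_a`,
#'   `disease_b`, `n_a`, `n_b`, `n_ab`).
#' @param nTot Total cohort size.
#' @param config A [comoaConfig()].
#' @param effDrugs Optional named list disease -> efficacious drug ids for
#'   easy-pair exclusion (e.g. [effDrugs()] of the profile set).
#' @return List of class `comoa_benchmark`: `cc_logRR`, `cc_logRR_p`,
#'   `cc_phi`, `cc_phi_p`, `recall`, `precision` (percent), `auroc`,
#'   `auprc`, `n_pairs_used`, `n_excluded_easy`, `n_excluded_zero_nab`.
#' @export
evaluateComorbidity <- function(result, clinical, nTot,
                                config = comoaConfig(), effDrugs = NULL) {
  edges <- if (is(result, "ComorbidityResult")) edgeTable(result) else result
  if (!nrow(clinical)) stop("no overlapping pairs: clinical table is empty")
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  edges$.key <- key(edges$diseaseA, edges$diseaseB)
  clinical$.key <- key(clinical$disease_a, clinical$disease_b)
  m <- merge(edges, clinical, by = ".key")
  if (!nrow(m)) stop("no overlapping pairs between predictions and clinical table")
  nZero <- sum(m$n_ab == 0)
  if (nZero) {
    warning(sprintf("%d pair(s) with n_ab = 0 excluded (log RR undefined)", nZero))
    m <- m[m$n_ab > 0, , drop = FALSE]
  }
  nEasy <- 0L
  if (!is.null(effDrugs)) {
    es <- vapply(seq_len(nrow(m)), function(i) {
      eA <- effDrugs[[m$diseaseA[i]]]
      eB <- effDrugs[[m$diseaseB[i]]]
      if (is.null(eA) || is.null(eB) || !length(eA) || !length(eB)) {
        warning(sprintf("pair (%s, %s): empty efficacious drug set, retained",
                        m$diseaseA[i], m$diseaseB[i]))
        return(0)
      }
      easyPairScore(eA, eB)
    }, numeric(1))
    drop <- es > config$easy_pair_cutoff
    nEasy <- sum(drop)
    m <- m[!drop, , drop = FALSE]
  }
  if (nrow(m) < 10) stop("fewer than 10 usable pairs after exclusions")
  lrr <- logRR(m$n_a, m$n_b, m$n_ab, nTot)
  phi <- phiScore(m$n_a, m$n_b, m$n_ab, nTot)
  label <- lrr > 0
  pred <- m$q < config$pair_q_cutoff
  if (!any(label)) stop("no true positives: benchmark metrics undefined")
  corL <- tryCatch(pearsonWithP(m$jScore, lrr),
                   error = function(e) list(estimate = NA_real_, p.value = NA_real_))
  corP <- tryCatch(pearsonWithP(m$jScore, phi),
                   error = function(e) list(estimate = NA_real_, p.value = NA_real_))
  auroc <- if (all(label)) NA_real_ else aucRoc(m$jScore, label)
  res <- list(
    cc_logRR = corL$estimate, cc_logRR_p = corL$p.value,
    cc_phi = corP$estimate, cc_phi_p = corP$p.value,
    recall = 100 * sum(label & pred) / sum(label),
    precision = if (any(pred)) 100 * sum(label & pred) / sum(pred) else NA_real_,
    auroc = auroc,
    auprc = aucPr(m$jScore, label),
    n_pairs_used = nrow(m),
    n_excluded_easy = as.integer(nEasy),
    n_excluded_zero_nab = as.integer(nZero)
  )
  class(res) <- "comoa_benchmark"
  res
}

#' @export
print.comoa_benchmark <- function(x, ...) {
  cat("comorbidity benchmark on", x$n_pairs_used, "pairs",
      sprintf("(%d easy, %d zero-overlap excluded)\n",
              x$n_excluded_easy, x$n_excluded_zero_nab))
  cat(sprintf("  c.c. J vs log(RR): %.4f (p = %.3g)\n", x$cc_logRR, x$cc_logRR_p))
  cat(sprintf("  c.c. J vs phi:     %.4f (p = %.3g)\n", x$cc_phi, x$cc_phi_p))
  cat(sprintf("  recall %.1f%%  precision %.1f%%  AUROC %.3f  AUPRC %.3f\n",
              x$recall, x$precision, x$auroc, x$auprc))
  invisible(x)
}

#' Permute drug-protein relations
#'
#' A uniform random bijection of the drugs reassigns whole target sets
#' among drugs: drug i receives drug sigma(i)'s target set, so the
#' multiset of target sets is preserved exactly.
#'
#' @param targets Named list drug -> character vector of protein ids.
#' @param seed Integer seed (deterministic result).
#' @return Permuted target map with the same drug names.
#' @export
permuteDrugProtein <- function(targets, seed) {
  if (length(targets) < 2) stop("need at least 2 drugs to permute")
  withr::with_seed(seed, {
    perm <- sample(length(targets))
  })
  stats::setNames(targets[perm], names(targets))
}

#' Permute drug-disease relations
#'
#' A uniform random bijection of the drugs reassigns whole score rows:
#' drug i receives drug sigma(i)'s indication score row, destroying the
#' drug-to-disease mapping while preserving the multiset of rows.
#'
#' @param scores Drug-by-indication numeric matrix.
#' @param seed Integer seed (deterministic result).
#' @return Permuted score matrix with the same drug rownames.
#' @export
permuteDrugDisease <- function(scores, seed) {
  if (nrow(scores) < 2) stop("need at least 2 drugs to permute")
  withr::with_seed(seed, {
    perm <- sample(nrow(scores))
  })
  out <- scores[perm, , drop = FALSE]
  rownames(out) <- rownames(scores)
  out
}

# profiles -> pairs -> benchmark, as a named metric vector (NA where a
# metric is undefined, e.g. constant J under a permuted world)
pipelineMetrics <- function(world, config = comoaConfig()) {
  profiles <- suppressWarnings(inferMoaProfiles(world, config))
  result <- allPairs(profiles, config = config)
  bench <- suppressWarnings(tryCatch(
    evaluateComorbidity(result, clinicalTable(world), world@nTot, config,
                        effDrugs = effDrugs(profiles)),
    error = function(e) NULL
  ))
  metrics <- c("cc_logRR", "cc_phi", "recall", "precision", "auroc", "auprc")
  if (is.null(bench)) {
    return(stats::setNames(rep(NA_real_, length(metrics)), metrics))
  }
  vapply(metrics, function(mn) as.numeric(bench[[mn]]), numeric(1))
}

#' Permutation null models for the full pipeline
#'
#' Runs the pipeline (profiles, all pairs, benchmark against the world's
#' clinical table) once on the observed inputs and `n_permutations` times
#' on permuted inputs (seeds `seed + 1 ... seed + n`), permuting either
#' the drug-protein target map or the drug-disease score rows.  For each
#' metric reports the observed value, the null mean and sd, the z-score
#' `(observed - mean) / sd`, and a one-sided upper-tail normal p-value.
#' Null runs in which a metric is undefined (e.g. a constant J-score
#' vector) contribute NA and are dropped from that metric's mean/sd;
#' `nDefined` records how many runs remained.
#'
#' @param world A [MoaWorld-class] with a non-empty clinical table.
#' @param config A [comoaConfig()]; `n_permutations` and `rng_seed` are
#'   honoured.
#' @param which `"drug_protein"` or `"drug_disease"`.
#' @param seed Base seed (default `config$rng_seed`).
#' @return data.frame with one row per metric: `metric`, `observed`,
#'   `nullMean`, `nullSd`, `z`, `p`, `nDefined`.
#' @export
permutationTest <- function(world, config = comoaConfig(),
                            which = c("drug_protein", "drug_disease"),
                            seed = config$rng_seed) {
  which <- match.arg(which)
  observed <- pipelineMetrics(world, config)
  n <- config$n_permutations
  null <- matrix(NA_real_, nrow = n, ncol = length(observed),
                 dimnames = list(NULL, names(observed)))
  for (i in seq_len(n)) {
    w <- world
    if (which == "drug_protein") {
      w@targets <- permuteDrugProtein(targetMap(world), seed + i)
    } else {
      w@scores <- permuteDrugDisease(scoreMatrix(world), seed + i)
    }
    null[i, ] <- pipelineMetrics(w, config)
  }
  summaries <- lapply(names(observed), function(mn) {
    v <- null[, mn]
    nd <- sum(!is.na(v))
    mu <- if (nd) mean(v, na.rm = TRUE) else NA_real_
    sdv <- if (nd > 1) stats::sd(v, na.rm = TRUE) else NA_real_
    z <- if (!is.na(sdv) && sdv > 0 && !is.na(observed[[mn]])) {
      (observed[[mn]] - mu) / sdv
    } else NA_real_
    data.frame(metric = mn, observed = observed[[mn]],
               nullMean = mu, nullSd = sdv, z = z,
               p = if (is.na(z)) NA_real_ else normalRightTail(z),
               nDefined = nd, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, summaries)
  rownames(out) <- NULL
  out
}

#' Write permutation summaries
#'
#' TSV with columns `metric`, `observed`, `mean`, `sd`, `z`, `p`.
#'
#' @param summaries data.frame from [permutationTest()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writePermutationTable <- function(summaries, path) {
  out <- data.table::data.table(
    metric = summaries$metric,
    observed = fmtNum(summaries$observed),
    mean = fmtNum(summaries$nullMean),
    sd = fmtNum(summaries$nullSd),
    z = fmtNum(summaries$z),
    p = fmtNum(summaries$p)
  )
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
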