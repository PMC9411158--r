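# Comorbidity-enrichment of MOA proteins: p-value-weighted frequency of a
# protein across a disease's top comorbidities, the exponential
# score-to-p conversion, and pathway over-representation on the top
# proteins.

#' Per-comorbidity enrichment weight of a protein
#'
#' `min(1, -alpha * ln p)`: the contribution of one comorbid disease in
#' which the protein is an MOA protein with association p-value `p`.  The
#' logarithm is natural: the weight saturates at 1 exactly when
#' `p = exp(-1/alpha)` (about 4.2e-18 at the default alpha = 0.025).
#' Non-positive p is clamped to 1e-320 before the log.
#'
#' @param p Association p-value(s) in `(0, 1]`.
#' @param alpha Positive weight coefficient.
#' @return Weights in `[0, 1]`.
#' @export
comoaWeight <- function(p, alpha = 0.025) {
  if (alpha <= 0) stop("alpha must be positive")
  if (any(p > 1)) stop("p-values must not exceed 1")
  pmin(1, -alpha * log(clampP(p)))
}

#' Convert an enrichment weight back to a p-value
#'
#' \eqn{e^{-w/\alpha}} on the *unnormalized* total weight: a single
#' saturated contribution (w = 1) maps to `exp(-1/alpha)`, about 4.2e-18
#' at the default alpha.
#'
#' @param totalWeight Non-negative unnormalized weight sum(s).
#' @param alpha Positive weight coefficient.
#' @return Implied p-values in `(0, 1]`.
#' @export
scoreToP <- function(totalWeight, alpha = 0.025) {
  if (alpha <= 0) stop("alpha must be positive")
  if (any(totalWeight < 0)) stop("total weight must be non-negative")
  exp(-totalWeight / alpha)
}

#' Comorbidity-enriched MOA proteins of a focal disease
#'
#' Pools the focal disease's top `k = min(top_k_comorbid, #significant)`
#' comorbidities (ranked by q ascending, J descending, partner id
#' ascending).  For each protein in the focal MOA set, sums over the
#' pooled comorbid diseases that share the protein the weight
#' `min(1, -alpha * ln p)`, where p is the *comorbid* disease's MOA
#' p-value for that protein; the score is this total divided by k, so a
#' score of 0.01 at k = 100 means one saturated-weight comorbidity in a
#' hundred.  Proteins with score strictly above the enrichment cutoff are
#' flagged enriched.
#'
#' @param focal Focal disease id.
#' @param result A [ComorbidityResult-class] from [allPairs()].
#' @param profiles The [MoaProfileSet-class] the result was computed from.
#' @param config A [comoaConfig()].
#' @return data.frame with columns `protein`, `totalWeight`, `score`,
#'   `impliedP`, `enriched`, sorted by score descending; attribute
#'   `kUsed` records k.  Zero rows (with a warning) when the focal
#'   disease has no significant comorbidity.
#' @export
comoaEnrich <- function(focal, result, profiles, config = comoaConfig()) {
  stopifnot(is(profiles, "MoaProfileSet"))
  sets <- moaSets(profiles)
  if (!focal %in% names(sets)) stop("unknown focal disease: ", focal)
  ranked <- rankComorbidities(result, focal, onlySignificant = TRUE)
  if (nrow(ranked) == 0) {
    warning(sprintf("'%s' has no significant comorbidity", focal))
    out <- data.frame(protein = character(0), totalWeight = numeric(0),
                      score = numeric(0), impliedP = numeric(0),
                      enriched = logical(0), stringsAsFactors = FALSE)
    attr(out, "kUsed") <- 0L
    return(out)
  }
  k <- min(config$top_k_comorbid, nrow(ranked))
  top <- ranked$partner[seq_len(k)]
  focalSet <- sets[[focal]]
  a <- associations(profiles)
  a <- a[a$disease %in% top & a$protein %in% focalSet, , drop = FALSE]
  # only count diseases that carry the protein in their MOA set
  inMoa <- mapply(function(d, pr) pr %in% sets[[d]], a$disease, a$protein)
  a <- a[as.logical(inMoa), , drop = FALSE]
  w <- if (nrow(a)) comoaWeight(a$p, config$alpha) else numeric(0)
  tw <- rep(0, length(focalSet))
  names(tw) <- focalSet
  if (nrow(a)) {
    agg <- tapply(w, a$protein, sum)
    tw[names(agg)] <- agg
  }
  score <- tw / k
  out <- data.frame(
    protein = focalSet, totalWeight = unname(tw), score = unname(score),
    impliedP = scoreToP(unname(tw), config$alpha),
    enriched = unname(score) > config$enrich_score_cutoff,
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$score, out$protein), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "kUsed") <- as.integer(k)
  out
}

#' Pathway over-representation of a protein set
#'
#' One-sided hypergeometric test of the query against each pathway over
#' the protein universe:
#' `p = hypergeomRightTail(|query & set|, |set & universe|, |query|, Nt)`.
#' q-values are computed across the collection; pathways with p < 0.05
#' are flagged significant.
#'
#' @param query Character vector of protein ids (non-empty, within the
#'   universe); typically the top (up to 100) comorbidity-enriched MOA
#'   proteins.
#' @param collection Named list of pathway gene sets (as from
#'   [readGmt()]).
#' @param universe Character vector, the protein universe.
#' @param pCutoff Significance flag threshold (default 0.05).
#' @return data.frame with columns `pathway`, `description`, `overlap`,
#'   `setSize`, `p`, `q`, `significant`, sorted by p ascending.
#' @export
pathwayOra <- function(query, collection, universe, pCutoff = 0.05) {
  query <- unique(query)
  if (!length(query)) stop("empty query set")
  bad <- setdiff(query, universe)
  if (length(bad)) {
    stop("query proteins outside the universe: ",
         paste(head(bad, 5), collapse = ", "))
  }
  if (!length(collection)) {
    return(data.frame(pathway = character(0), description = character(0),
                      overlap = integer(0), setSize = integer(0),
                      p = numeric(0), q = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  }
  descs <- attr(collection, "descriptions")
  Nt <- length(universe)
  setsU <- lapply(collection, intersect, universe)
  K <- lengths(setsU)
  ov <- vapply(setsU, function(s) length(intersect(query, s)), integer(1))
  p <- hypergeomRightTail(ov, K, length(query), Nt)
  q <- qvalues(p)
  out <- data.frame(
    pathway = names(collection),
    description = if (is.null(descs)) NA_character_ else unname(descs[names(collection)]),
    overlap = as.integer(ov), setSize = as.integer(K),
    p = p, q = q, significant = p < pCutoff,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an enrichment table
#'
#' TSV with columns `protein`, `total_weight`, `score`, `implied_p`,
#' `enriched_flag`.
#'
#' @param enrich data.frame from [comoaEnrich()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeEnrichTable <- function(enrich, path) {
  out <- data.table::data.table(
    protein = enrich$protein,
    total_weight = fmtNum(enrich$totalWeight),
    score = fmtNum(enrich$score),
    implied_p = fmtNum(enrich$impliedP),
    enriched_flag = as.integer(enrich$enriched)
  )
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Write a pathway over-representation table
#'
#' TSV with columns `pathway`, `description`, `overlap`, `p`, `q`.
#'
#' @param ora data.frame from [pathwayOra()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writePathwayTable <- function(ora, path) {
  out <- data.table::data.table(
    pathway = ora$pathway, description = ora$description,
    overlap = ora$overlap, p = fmtNum(ora$p), q = fmtNum(ora$q)
  )
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
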