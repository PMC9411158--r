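# Disease-pair comorbidity scoring: Jaccard overlap of MOA protein sets
# with one-sided hypergeometric significance, FDR control across the full
# pair family, gene-set query mode and easy-pair scoring.

#' Jaccard comorbidity score of two MOA protein sets
#'
#' \eqn{J = N_s / (N_{D1} + N_{D2} - N_s)}; defined as 0 when both sets
#' are empty.
#'
#' @param Ns Shared protein count(s), `0 <= Ns <= min(ND1, ND2)`.
#' @param ND1,ND2 MOA set sizes of the two diseases.
#' @return J-scores in `[0, 1]`.
#' @export
jscore <- function(Ns, ND1, ND2) {
  r <- suppressWarnings(cbind(Ns, ND1, ND2))
  dimnames(r) <- NULL
  Ns <- r[, 1]; ND1 <- r[, 2]; ND2 <- r[, 3]
  if (any(r < 0)) stop("set sizes and overlaps must be non-negative")
  if (any(Ns > pmin(ND1, ND2))) stop("overlap exceeds the smaller set")
  denom <- ND1 + ND2 - Ns
  j <- ifelse(denom > 0, Ns / denom, 0)
  j
}

#' One-sided significance of an MOA overlap
#'
#' Probability of an overlap at least `Ns` when a set of size `ND2` is
#' drawn at random from the `Nt`-protein universe against a fixed set of
#' size `ND1`: `hypergeomRightTail(Ns, ND1, ND2, Nt)`.  Pairs in which
#' either profile is empty return 1 (no evidence).
#'
#' @param Ns Shared protein count(s).
#' @param ND1,ND2 MOA set sizes.
#' @param Nt Protein universe size, `>= max(ND1, ND2)`.
#' @return One-sided p-values in `(0, 1]`.
#' @export
pairPValue <- function(Ns, ND1, ND2, Nt) {
  r <- suppressWarnings(cbind(Ns, ND1, ND2, Nt))
  dimnames(r) <- NULL
  Ns <- r[, 1]; ND1 <- r[, 2]; ND2 <- r[, 3]; Nt <- r[, 4]
  p <- rep(1, length(Ns))
  live <- ND1 > 0 & ND2 > 0
  if (any(live)) {
    p[live] <- hypergeomRightTail(Ns[live], ND1[live], ND2[live], Nt[live])
  }
  p
}

# overlap counts for all unordered pairs of sets, as a pair-indexed vector
# (pair k of i<j in lexicographic index order)
pairOverlaps <- function(sets, nPairs, n) {
  allProt <- unique(unlist(sets, use.names = FALSE))
  Ns <- integer(nPairs)
  if (length(allProt) == 0) return(Ns)
  m <- Matrix::sparseMatrix(
    i = match(unlist(sets, use.names = FALSE), allProt),
    j = rep.int(seq_along(sets), lengths(sets)),
    x = 1, dims = c(length(allProt), length(sets))
  )
  ov <- Matrix::crossprod(m)
  ovT <- as(Matrix::triu(ov, 1), "TsparseMatrix")
  if (length(ovT@x)) {
    i <- ovT@i + 1L
    j <- ovT@j + 1L
    k <- (i - 1) * (2 * n - i) / 2 + (j - i)
    Ns[k] <- as.integer(ovT@x)
  }
  Ns
}

#' Score all disease pairs for comorbidity
#'
#' Enumerates every unordered pair of diseases (self-pairs excluded),
#' computes the shared-MOA count, J-score and one-sided hypergeometric
#' p-value, and controls the FDR once across the full pair family.
#' Pairs involving an empty profile carry J = 0 and p = 1.
#'
#' @param profiles A [MoaProfileSet-class], or a named list
#'   disease -> character vector of MOA proteins.
#' @param Nt Protein universe size (defaults to the profile set's
#'   universe).
#' @param config A [comoaConfig()]; `pair_q_cutoff` sets the significance
#'   flag.
#' @return A [ComorbidityResult-class] with `n(n-1)/2` edges.
#' @export
allPairs <- function(profiles, Nt = NULL, config = comoaConfig()) {
  if (is(profiles, "MoaProfileSet")) {
    if (is.null(Nt)) Nt <- length(profiles@universe)
    sets <- moaSets(profiles)
  } else {
    sets <- profiles
    if (is.null(Nt)) stop("Nt required when profiles is a plain list")
  }
  if (length(sets) < 2) stop("need at least 2 disease profiles")
  ids <- sort(names(sets))
  sets <- sets[ids]
  n <- length(ids)
  nPairs <- n * (n - 1) / 2
  iIdx <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  jIdx <- sequence((n - 1L):1L, from = 2:n)
  sizes <- lengths(sets)
  Ns <- pairOverlaps(sets, nPairs, n)
  sA <- sizes[iIdx]
  sB <- sizes[jIdx]
  j <- jscore(Ns, sA, sB)
  p <- pairPValue(Ns, sA, sB, Nt)
  q <- qvalues(p)
  edges <- data.frame(
    diseaseA = ids[iIdx], diseaseB = ids[jIdx],
    nShared = Ns, jScore = j, p = p, q = q,
    significant = q < config$pair_q_cutoff,
    stringsAsFactors = FALSE
  )
  new("ComorbidityResult", edges = edges, diseases = ids,
      universeSize = as.integer(Nt))
}

#' Rank diseases against a pathogenic gene set
#'
#' Treats the query gene set as a pseudo-disease and scores it against
#' every profile with the same J-score / hypergeometric machinery;
#' q-values are computed across the n per-disease tests and the result is
#' ranked by (q ascending, J descending, disease id ascending).
#'
#' @param genes Character vector of query protein ids.
#' @param profiles A [MoaProfileSet-class].
#' @param Nt Protein universe size (defaults to the profile universe).
#' @param config A [comoaConfig()].
#' @return A [ComorbidityResult-class]; `diseaseA` is the literal
#'   `"query"`, `diseaseB` the disease, rows ranked.
#' @export
genesetQuery <- function(genes, profiles, Nt = NULL, config = comoaConfig()) {
  stopifnot(is(profiles, "MoaProfileSet"))
  if (is.null(Nt)) Nt <- length(profiles@universe)
  genes <- intersect(unique(genes), profiles@universe)
  if (!length(genes)) stop("query gene set has empty intersection with the universe")
  sets <- moaSets(profiles)
  ids <- names(sets)
  Ns <- vapply(sets, function(s) length(intersect(genes, s)), integer(1))
  nd <- lengths(sets)
  nq <- length(genes)
  j <- jscore(Ns, nq, nd)
  p <- pairPValue(Ns, nq, nd, Nt)
  q <- qvalues(p)
  edges <- data.frame(
    diseaseA = "query", diseaseB = ids,
    nShared = as.integer(Ns), jScore = j, p = p, q = q,
    significant = q < config$pair_q_cutoff,
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$q, -edges$jScore, edges$diseaseB), ]
  rownames(edges) <- NULL
  new("ComorbidityResult", edges = edges, diseases = ids,
      universeSize = as.integer(Nt))
}

#' Efficacious-drug overlap of a disease pair
#'
#' \eqn{|A \cap B| / \sqrt{|A| |B|}} of the two diseases' efficacious
#' drug sets.  Benchmarking drops pairs with score strictly above the
#' configured cutoff as "easy pairs": their comorbidity is trivially
#' implied by sharing the same efficacious drugs.
#'
#' @param effA,effB Character vectors of efficacious drug ids (non-empty).
#' @return Overlap score in `[0, 1]`.
#' @export
easyPairScore <- function(effA, effB) {
  if (length(effA) == 0 || length(effB) == 0) {
    stop("easy-pair score undefined for an empty efficacious drug set")
  }
  length(intersect(effA, effB)) / sqrt(length(unique(effA)) * length(unique(effB)))
}

#' Rank a disease's comorbidities
#'
#' The canonical ranking rule used for the top-k comorbidities consumed
#' by enrichment: q ascending, tie-break J descending, then partner id
#' ascending.
#'
#' @param result A [ComorbidityResult-class].
#' @param disease Focal disease id.
#' @param onlySignificant Keep only edges flagged significant.
#' @return data.frame of the focal disease's edges with a `partner`
#'   column, ranked.
#' @export
rankComorbidities <- function(result, disease, onlySignificant = TRUE) {
  e <- edgeTable(result)
  sel <- e$diseaseA == disease | e$diseaseB == disease
  e <- e[sel, , drop = FALSE]
  e$partner <- ifelse(e$diseaseA == disease, e$diseaseB, e$diseaseA)
  if (onlySignificant) e <- e[e$significant, , drop = FALSE]
  e <- e[order(e$q, -e$jScore, e$partner), , drop = FALSE]
  rownames(e) <- NULL
  e
}
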