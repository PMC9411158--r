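# MOA inference: raw indication scores -> z-scores -> efficacious/rest drug
# partition -> per-protein relative risk + one-sided Fisher p -> tissue
# filter -> per-disease MOA protein profile.

#' Standardise raw indication scores to z-scores
#'
#' \eqn{z = (raw - \bar{raw}) / \sigma} with \eqn{\sigma} the *population*
#' standard deviation over the full drug library (divide by N): the probe
#' library is the whole population of drugs being ranked, not a sample
#' from one.
#'
#' @param raw Numeric vector of raw scores over drugs (length >= 2).
#' @return z-scores with mean 0 and population sd 1.
#' @export
standardizeScores <- function(raw) {
  if (length(raw) < 2) stop("need at least 2 drugs to standardise")
  if (anyNA(raw)) stop("missing raw scores")
  mu <- mean(raw)
  sdp <- sqrt(mean((raw - mu)^2))
  if (sdp == 0) stop("zero variance: all raw scores equal, indication unusable")
  (raw - mu) / sdp
}

#' Partition drugs into efficacious and rest by z cutoff
#'
#' Membership is `z >= cutoff`: the boundary is inclusive, so a drug
#' exactly at the cutoff counts as efficacious.
#'
#' @param z Named numeric vector of z-scores (names = drug ids).
#' @param cutoff Finite z threshold.
#' @return List with `efficacious` and `rest` (character vectors of drug
#'   ids, disjoint, jointly all drugs).
#' @export
partitionDrugs <- function(z, cutoff) {
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  if (is.null(names(z))) stop("z-scores must be named by drug id")
  eff <- z >= cutoff
  list(efficacious = names(z)[eff], rest = names(z)[!eff])
}

#' Relative risk of a protein being targeted by efficacious drugs
#'
#' \eqn{RR = (n_{1T}/N_1) / (n_{2T}/N_2)}: the probability that an
#' efficacious drug binds the protein relative to the background
#' probability that a non-efficacious drug does.  When no drug at all is
#' predicted to bind the protein the RR is defined as 0; when only
#' efficacious drugs bind it (zero denominator) it is `Inf`.
#'
#' @param n1t Number of efficacious drugs binding the protein
#'   (vectorised).
#' @param N1 Number of efficacious drugs (>= 1).
#' @param n2t Number of non-efficacious drugs binding the protein.
#' @param N2 Number of non-efficacious drugs (>= 1).
#' @return Non-negative relative risks (possibly `Inf`).
#' @export
relativeRisk <- function(n1t, N1, n2t, N2) {
  if (any(N1 < 1)) {
    stop("no predicted efficacious drugs (N1 = 0); skip the indication upstream")
  }
  if (any(N2 < 1)) stop("empty background partition (N2 = 0)")
  if (any(n1t < 0) || any(n2t < 0) || any(n1t > N1) || any(n2t > N2)) {
    stop("counts must satisfy 0 <= n1t <= N1 and 0 <= n2t <= N2")
  }
  rr <- (n1t / N1) / (n2t / N2)
  rr[n1t == 0 & n2t == 0] <- 0
  rr[n1t > 0 & n2t == 0] <- Inf
  rr
}

#' One-sided significance of a disease-protein association
#'
#' Right-tail Fisher exact test on the 2x2 table of (binds protein,
#' efficacious) counts: `fisherRightTail(n1t, N1 - n1t, n2t, N2 - n2t)`.
#' A protein is a candidate MOA protein when this p-value is below the
#' configured MOA cutoff.
#'
#' @inheritParams relativeRisk
#' @return One-sided p-values.
#' @export
moaPValue <- function(n1t, N1, n2t, N2) {
  fisherRightTail(n1t, N1 - n1t, n2t, N2 - n2t)
}

#' Tissue-expression filter for candidate MOA proteins
#'
#' A candidate is removed iff it has at least one expression record in the
#' disease-related tissues AND every such record has level "not detected"
#' AND none of them has reliability "uncertain".  Candidates with no
#' records in the related tissues are retained (absence of evidence is not
#' "not detected"), and an empty tissue set makes the filter a no-op.
#'
#' @param candidates Character vector of protein ids.
#' @param expr Tissue-expression data.frame (`protein`, `tissue`, `level`,
#'   `reliability`).
#' @param tissues Character vector of disease-related tissue names.
#' @return The retained subset of `candidates` (order preserved).
#' @export
tissueFilter <- function(candidates, expr, tissues) {
  if (length(tissues) == 0 || length(candidates) == 0 || nrow(expr) == 0) {
    return(candidates)
  }
  rel <- expr[expr$protein %in% candidates & expr$tissue %in% tissues, ,
              drop = FALSE]
  if (!nrow(rel)) return(candidates)
  allND <- tapply(rel$level == "not detected", rel$protein, all)
  anyUnc <- tapply(rel$reliability == "uncertain", rel$protein, any)
  drop <- names(allND)[allND & !anyUnc[names(allND)]]
  candidates[!candidates %in% drop]
}

# sparse drug x protein incidence matrix over the universe
targetIncidence <- function(targets, drugs, universe) {
  di <- rep.int(match(names(targets), drugs), lengths(targets))
  pi <- match(unlist(targets, use.names = FALSE), universe)
  Matrix::sparseMatrix(i = di, j = pi, x = 1,
                       dims = c(length(drugs), length(universe)),
                       dimnames = list(drugs, universe))
}

#' Infer MOA protein profiles for every indication
#'
#' For each indication: standardise the raw scores, partition drugs at
#' the z cutoff, count per-protein binding drugs in each partition,
#' compute relative risk and one-sided Fisher p, apply the tissue filter,
#' and keep as the MOA set the surviving proteins with p below the MOA
#' cutoff.  q-values are computed per disease across the p-values of all
#' universe proteins (proteins bound by no drug contribute p = 1) and are
#' stored for ranking only: MOA membership uses the raw p-value.
#' Indications with zero score variance or an empty efficacious partition
#' yield empty profiles with a warning.
#'
#' @param world A [MoaWorld-class].
#' @param config A [comoaConfig()].
#' @return A [MoaProfileSet-class].
#' @export
inferMoaProfiles <- function(world, config = comoaConfig()) {
  stopifnot(is(world, "MoaWorld"))
  sc <- scoreMatrix(world)
  universe <- proteinUniverse(world)
  drugs <- rownames(sc)
  inc <- targetIncidence(targetMap(world), drugs, universe)
  nT <- Matrix::colSums(inc)           # drugs binding each protein
  bound <- which(nT > 0)
  nUni <- length(universe)
  diseases <- colnames(sc)
  moaSets <- stats::setNames(vector("list", length(diseases)), diseases)
  eff <- stats::setNames(vector("list", length(diseases)), diseases)
  assocList <- vector("list", length(diseases))
  for (ix in seq_along(diseases)) {
    d <- diseases[ix]
    raw <- sc[, ix]
    moaSets[[d]] <- character(0)
    eff[[d]] <- character(0)
    if (length(unique(raw)) == 1) {
      warning(sprintf("indication '%s': zero score variance, empty profile", d))
      next
    }
    z <- standardizeScores(raw)
    names(z) <- drugs
    part <- partitionDrugs(z, config$z_cutoff)
    N1 <- length(part$efficacious)
    N2 <- length(part$rest)
    if (N1 == 0) {
      warning(sprintf("indication '%s': no efficacious drugs, empty profile", d))
      next
    }
    eff[[d]] <- part$efficacious
    if (N2 == 0) {
      warning(sprintf("indication '%s': every drug efficacious, empty profile", d))
      next
    }
    if (length(bound) == 0) next  # no drug binds anything: empty profile
    n1t <- Matrix::colSums(inc[match(part$efficacious, drugs), , drop = FALSE])
    n2t <- nT - n1t
    rr <- relativeRisk(n1t[bound], N1, n2t[bound], N2)
    p <- moaPValue(n1t[bound], N1, n2t[bound], N2)
    # q across all universe proteins for this disease; unbound proteins
    # are tests with p = 1
    pAll <- rep(1, nUni)
    pAll[bound] <- p
    qAll <- qvalues(pAll)
    cand <- universe[bound][p < config$moa_p_cutoff]
    kept <- tissueFilter(cand, world@tissue,
                         world@tissueMap[[d]] %||% character(0))
    moaSets[[d]] <- kept
    assocList[[ix]] <- data.frame(
      disease = d, protein = universe[bound],
      n1t = as.integer(n1t[bound]), n2t = as.integer(n2t[bound]),
      rr = rr, p = p, q = qAll[bound],
      passedTissueFilter = !(universe[bound] %in% setdiff(cand, kept)),
      stringsAsFactors = FALSE
    )
  }
  assoc <- if (length(assocList)) do.call(rbind, assocList) else emptyAssociationTable()
  if (is.null(assoc)) assoc <- emptyAssociationTable()
  rownames(assoc) <- NULL
  new("MoaProfileSet", associations = assoc, moaSets = moaSets,
      effDrugs = eff, universe = universe)
}

#' Write a MOA association table
#'
#' TSV with columns `disease`, `protein`, `n1t`, `n2t`, `rr` ("inf" for
#' infinite), `p`, `q`, `passed_tissue_filter` (0/1).
#'
#' @param profiles A [MoaProfileSet-class].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeMoaTable <- function(profiles, path) {
  a <- associations(profiles)
  out <- data.table::data.table(
    disease = a$disease, protein = a$protein,
    n1t = a$n1t, n2t = a$n2t,
    rr = ifelse(is.infinite(a$rr), "inf", fmtNum(a$rr)),
    p = fmtNum(a$p), q = fmtNum(a$q),
    passed_tissue_filter = as.integer(a$passedTissueFilter)
  )
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
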