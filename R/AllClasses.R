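#' @include comoa-package.R
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' World of pipeline inputs
#'
#' Container for everything the pipeline consumes: the drug-by-indication
#' raw score matrix, the drug-to-protein target map, the protein universe,
#' an optional tissue-expression table with a disease-to-tissue map, an
#' optional clinical co-occurrence table, and an optional pathway
#' collection.
#'
#' @slot scores Numeric matrix, drugs in rows (rownames = drug ids),
#'   indications in columns (colnames = disease ids); no missing cells.
#' @slot targets Named list, one entry per drug, each a character vector of
#'   protein ids (possibly empty); every drug is a row of `scores` and every
#'   protein is in `universe`.
#' @slot universe Character vector of unique protein identifiers; its
#'   length is the population size of every hypergeometric test.
#' @slot tissue data.frame with columns `protein`, `tissue`, `level`
#'   (one of "not detected", "low", "medium", "high") and `reliability`;
#'   may have zero rows (no tissue filtering).
#' @slot tissueMap Named list disease -> character vector of tissue names.
#' @slot clinical data.frame with columns `disease_a`, `disease_b`, `n_a`,
#'   `n_b`, `n_ab`; may have zero rows.
#' @slot nTot Numeric scalar, total cohort size shared by all clinical
#'   records (a single cohort, so it lives here and not per row).
#' @slot gmt Named list of pathway gene sets (character vectors) with a
#'   `descriptions` attribute; may be empty.
#' @export
setClass("MoaWorld", representation(
  scores = "matrix",
  targets = "list",
  universe = "character",
  tissue = "data.frame",
  tissueMap = "list",
  clinical = "data.frame",
  nTot = "numeric",
  gmt = "list"
))

setValidity("MoaWorld", function(object) {
  msg <- character(0)
  sc <- object@scores
  if (!is.numeric(sc)) msg <- c(msg, "scores must be a numeric matrix")
  if (anyNA(sc)) msg <- c(msg, "scores contains missing cells")
  if (is.null(rownames(sc)) || is.null(colnames(sc))) {
    msg <- c(msg, "scores must have drug rownames and indication colnames")
  } else {
    if (anyDuplicated(rownames(sc))) msg <- c(msg, "duplicate drug ids")
    if (anyDuplicated(colnames(sc))) msg <- c(msg, "duplicate indication ids")
  }
  if (anyDuplicated(object@universe)) {
    msg <- c(msg, "protein universe contains duplicate identifiers")
  }
  if (length(object@targets)) {
    if (is.null(names(object@targets))) {
      msg <- c(msg, "target map must be named by drug id")
    } else {
      badDrug <- setdiff(names(object@targets), rownames(sc))
      if (length(badDrug)) {
        msg <- c(msg, paste0("target-map drugs absent from score matrix: ",
                             paste(head(badDrug, 5), collapse = ", ")))
      }
      badProt <- setdiff(unique(unlist(object@targets, use.names = FALSE)),
                         object@universe)
      if (length(badProt)) {
        msg <- c(msg, paste0("target-map proteins absent from universe: ",
                             paste(head(badProt, 5), collapse = ", ")))
      }
    }
  }
  if (nrow(object@clinical)) {
    cl <- object@clinical
    need <- c("disease_a", "disease_b", "n_a", "n_b", "n_ab")
    if (!all(need %in% names(cl))) {
      msg <- c(msg, "clinical table lacks required columns")
    } else {
      if (any(cl$n_ab > pmin(cl$n_a, cl$n_b))) {
        msg <- c(msg, "clinical counts violate n_ab <= min(n_a, n_b)")
      }
      if (length(object@nTot) == 1 && any(pmax(cl$n_a, cl$n_b) > object@nTot)) {
        msg <- c(msg, "clinical counts exceed n_tot")
      }
    }
  }
  if (length(object@nTot) > 1 || (length(object@nTot) == 1 && object@nTot <= 0)) {
    msg <- c(msg, "nTot must be a single positive number")
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic world with planted ground truth
#'
#' A [MoaWorld-class] produced by [generateWorld()], carrying in addition
#' the planted truth (per-disease protein modules and the list of planted
#' comorbid pairs), the generator parameters, and the seed.
#'
#' @slot truth List with elements `modules` (named list disease -> planted
#'   protein module) and `plantedPairs` (data.frame `disease_a`,
#'   `disease_b`).
#' @slot params Named list of generator parameters (see [worldParams()]).
#' @slot seed Integer seed the bundle is a deterministic function of.
#' @export
setClass("SyntheticWorld", contains = "MoaWorld", representation(
  truth = "list",
  params = "list",
  seed = "integer"
))

#' Per-disease MOA protein profiles
#'
#' Result of [inferMoaProfiles()]: for every disease the set of significant
#' mode-of-action proteins plus the full per-protein association table
#' retained for ranking.
#'
#' @slot associations data.frame with columns `disease`, `protein`, `n1t`,
#'   `n2t`, `rr`, `p`, `q`, `passedTissueFilter`; one row per
#'   (disease, protein) with at least one binding drug.
#' @slot moaSets Named list disease -> character vector of MOA proteins
#'   (p below the MOA cutoff and surviving the tissue filter).
#' @slot effDrugs Named list disease -> character vector of efficacious
#'   drug ids (the z >= cutoff partition), kept for easy-pair scoring.
#' @slot universe Character vector, the protein universe the profiles were
#'   inferred against.
#' @export
setClass("MoaProfileSet", representation(
  associations = "data.frame",
  moaSets = "list",
  effDrugs = "list",
  universe = "character"
))

setValidity("MoaProfileSet", function(object) {
  msg <- character(0)
  if (is.null(names(object@moaSets))) {
    if (length(object@moaSets)) msg <- c(msg, "moaSets must be named by disease")
  } else {
    extra <- setdiff(unique(unlist(object@moaSets, use.names = FALSE)),
                     object@universe)
    if (length(extra)) {
      msg <- c(msg, paste0("MOA proteins outside the universe: ",
                           paste(head(extra, 5), collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Disease-pair comorbidity scores
#'
#' Result of [allPairs()] or [genesetQuery()]: one row per unordered
#' disease pair with the shared-MOA count, J-score, one-sided
#' hypergeometric p-value and q-value.
#'
#' @slot edges data.frame with columns `diseaseA`, `diseaseB`
#'   (lexicographically `diseaseA < diseaseB` for all-pairs results),
#'   `nShared`, `jScore`, `p`, `q`, `significant`.
#' @slot diseases Character vector of all disease ids covered.
#' @slot universeSize Integer, population size used in the pair tests.
#' @export
setClass("ComorbidityResult", representation(
  edges = "data.frame",
  diseases = "character",
  universeSize = "integer"
))

# ---- constructors ----------------------------------------------------------

#' Construct a MoaWorld from in-memory pieces
#'
#' @param scores Drug-by-indication numeric matrix with dimnames.
#' @param targets Named list drug -> character vector of protein ids.
#' @param universe Character vector of protein identifiers.
#' @param tissue Optional tissue-expression data.frame
#'   (`protein`, `tissue`, `level`, `reliability`).
#' @param tissueMap Optional named list disease -> tissue names.
#' @param clinical Optional clinical co-occurrence data.frame.
#' @param nTot Cohort size for the clinical table.
#' @param gmt Optional named list of pathway gene sets.
#' @return A [MoaWorld-class] object (validity-checked).
#' @export
moaWorld <- function(scores, targets, universe,
                     tissue = emptyTissueTable(),
                     tissueMap = list(),
                     clinical = emptyClinicalTable(),
                     nTot = 1,
                     gmt = list()) {
  new("MoaWorld", scores = scores, targets = targets,
      universe = as.character(universe), tissue = as.data.frame(tissue),
      tissueMap = tissueMap, clinical = as.data.frame(clinical),
      nTot = as.numeric(nTot), gmt = gmt)
}

#' Construct a MoaProfileSet from plain MOA sets
#'
#' Convenience constructor used when profiles come from somewhere other
#' than [inferMoaProfiles()] (e.g. externally curated gene sets, or empty
#' placeholder profiles for pair enumeration).
#'
#' @param moaSets Named list disease -> character vector of MOA proteins.
#' @param universe Character vector of protein identifiers.
#' @param effDrugs Optional named list disease -> efficacious drug ids.
#' @param associations Optional full association table.
#' @return A [MoaProfileSet-class] object.
#' @export
moaProfileSet <- function(moaSets, universe, effDrugs = list(),
                          associations = emptyAssociationTable()) {
  new("MoaProfileSet", associations = as.data.frame(associations),
      moaSets = moaSets, effDrugs = effDrugs,
      universe = as.character(universe))
}

emptyTissueTable <- function() {
  data.frame(protein = character(0), tissue = character(0),
             level = character(0), reliability = character(0),
             stringsAsFactors = FALSE)
}

emptyClinicalTable <- function() {
  data.frame(disease_a = character(0), disease_b = character(0),
             n_a = integer(0), n_b = integer(0), n_ab = integer(0),
             stringsAsFactors = FALSE)
}

emptyAssociationTable <- function() {
  data.frame(disease = character(0), protein = character(0),
             n1t = integer(0), n2t = integer(0), rr = numeric(0),
             p = numeric(0), q = numeric(0),
             passedTissueFilter = logical(0), stringsAsFactors = FALSE)
}

# ---- accessors -------------------------------------------------------------

#' @rdname MoaWorld-class
#' @param object,x A `MoaWorld`.
#' @export
setGeneric("scoreMatrix", function(object) standardGeneric("scoreMatrix"))

#' @rdname MoaWorld-class
#' @export
setMethod("scoreMatrix", "MoaWorld", function(object) object@scores)

#' @rdname MoaWorld-class
#' @export
setGeneric("targetMap", function(object) standardGeneric("targetMap"))

#' @rdname MoaWorld-class
#' @export
setMethod("targetMap", "MoaWorld", function(object) object@targets)

#' @rdname MoaWorld-class
#' @export
setGeneric("proteinUniverse", function(object) standardGeneric("proteinUniverse"))

#' @rdname MoaWorld-class
#' @export
setMethod("proteinUniverse", "MoaWorld", function(object) object@universe)

#' @rdname MoaWorld-class
#' @export
setGeneric("clinicalTable", function(object) standardGeneric("clinicalTable"))

#' @rdname MoaWorld-class
#' @export
setMethod("clinicalTable", "MoaWorld", function(object) object@clinical)

#' @rdname MoaProfileSet-class
#' @param object A `MoaProfileSet`.
#' @export
setGeneric("moaSets", function(object) standardGeneric("moaSets"))

#' @rdname MoaProfileSet-class
#' @export
setMethod("moaSets", "MoaProfileSet", function(object) object@moaSets)

#' @rdname MoaProfileSet-class
#' @export
setGeneric("effDrugs", function(object) standardGeneric("effDrugs"))

#' @rdname MoaProfileSet-class
#' @export
setMethod("effDrugs", "MoaProfileSet", function(object) object@effDrugs)

#' @rdname MoaProfileSet-class
#' @export
setGeneric("associations", function(object) standardGeneric("associations"))

#' @rdname MoaProfileSet-class
#' @export
setMethod("associations", "MoaProfileSet", function(object) object@associations)

#' @rdname ComorbidityResult-class
#' @param object A `ComorbidityResult`.
#' @export
setGeneric("edgeTable", function(object) standardGeneric("edgeTable"))

#' @rdname ComorbidityResult-class
#' @export
setMethod("edgeTable", "ComorbidityResult", function(object) object@edges)

# ---- show ------------------------------------------------------------------

setMethod("show", "MoaWorld", function(object) {
  cat(class(object), "with",
      nrow(object@scores), "drugs x", ncol(object@scores), "indications;",
      length(object@universe), "proteins in universe\n")
  cat("  target map:", sum(lengths(object@targets) > 0), "drugs with targets;",
      "tissue records:", nrow(object@tissue), ";",
      "clinical pairs:", nrow(object@clinical), ";",
      "pathways:", length(object@gmt), "\n")
  if (is(object, "SyntheticWorld")) {
    cat("  planted:", length(object@truth$modules), "modules,",
        nrow(object@truth$plantedPairs), "comorbid pairs (seed",
        object@seed, ")\n")
  }
})

setMethod("show", "MoaProfileSet", function(object) {
  sizes <- lengths(object@moaSets)
  cat("MoaProfileSet:", length(sizes), "diseases, universe of",
      length(object@universe), "proteins\n")
  if (length(sizes)) {
    cat(sprintf("  MOA set sizes: min %d / median %s / max %d; %d empty\n",
                min(sizes), format(stats::median(sizes)), max(sizes),
                sum(sizes == 0)))
  }
})

setMethod("show", "ComorbidityResult", function(object) {
  cat("ComorbidityResult:", nrow(object@edges), "pairs over",
      length(object@diseases), "diseases;",
      sum(object@edges$significant), "significant\n")
})
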