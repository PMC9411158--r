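# Readers and writers for every external file the tool touches.
# Dialect: tab-separated, UTF-8, header row required (except one-per-line
# lists and GMT); missing values are an error, never silently dropped.

stopIfMissing <- function(path, what) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    stop(sprintf("cannot load %s: file not found: %s", what, path))
  }
}

#' Read a drug-by-indication raw score matrix
#'
#' Layout: TSV, first column = drug id, remaining header fields =
#' indication ids, cells = raw scores.  Any non-numeric or missing cell is
#' a parse error reporting the offending row.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix with drug rownames and indication colnames.
#' @export
readScoreMatrix <- function(path) {
  stopIfMissing(path, "score matrix")
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1), data.table = TRUE)
  if (ncol(dt) < 2) stop("score matrix needs a drug column plus indications")
  drugs <- dt[[1]]
  if (anyDuplicated(drugs)) stop("duplicate drug ids in score matrix")
  m <- as.matrix(dt[, -1])
  if (!is.numeric(m)) {
    bad <- which(apply(m, 1, function(r) anyNA(suppressWarnings(as.numeric(r)))))
    stop(sprintf("malformed numeric cell in score matrix at data row %d",
                 bad[1]))
  }
  if (anyNA(m)) {
    stop(sprintf("missing score cell at data row %d",
                 which(rowSums(is.na(m)) > 0)[1]))
  }
  rownames(m) <- drugs
  if (anyDuplicated(colnames(m))) stop("duplicate indication ids in score matrix")
  m
}

#' Read a drug-to-protein target map
#'
#' Layout: TSV with header, two columns `drug`, `protein`, one pair per
#' row.  Drugs with no targets simply have no rows; use `drugs` to include
#' them with empty target sets.
#'
#' @param path Path to the TSV file.
#' @param drugs Optional character vector of all drug ids; drugs absent
#'   from the file get empty target sets.
#' @return Named list drug -> character vector of protein ids.
#' @export
readTargetMap <- function(path, drugs = NULL) {
  stopIfMissing(path, "target map")
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  if (!all(c("drug", "protein") %in% names(dt))) {
    stop("target map must have columns 'drug' and 'protein'")
  }
  if (anyNA(dt$drug) || anyNA(dt$protein) ||
      any(dt$drug == "") || any(dt$protein == "")) {
    stop("empty field in target map")
  }
  tm <- split(dt$protein, dt$drug)
  tm <- lapply(tm, unique)
  if (!is.null(drugs)) {
    out <- stats::setNames(vector("list", length(drugs)), drugs)
    for (d in drugs) out[[d]] <- character(0)
    out[names(tm)[names(tm) %in% drugs]] <- tm[names(tm) %in% drugs]
    extra <- setdiff(names(tm), drugs)
    if (length(extra)) {
      stop("target map references unknown drugs: ",
           paste(head(extra, 5), collapse = ", "))
    }
    return(out)
  }
  tm
}

#' Read a protein universe file
#'
#' One identifier per line, blank lines ignored; duplicates are an error
#' because the universe size is the population of every test.
#'
#' @param path Path to the text file.
#' @return Character vector of protein identifiers.
#' @export
readProteinUniverse <- function(path) {
  stopIfMissing(path, "protein universe")
  ids <- readLines(path, warn = FALSE)
  ids <- trimws(ids)
  ids <- ids[nzchar(ids)]
  if (!length(ids)) stop("protein universe file is empty")
  if (anyDuplicated(ids)) stop("duplicate identifiers in protein universe")
  ids
}

TISSUE_LEVELS <- c("not detected", "low", "medium", "high")

#' Read a tissue-expression table
#'
#' Column layout of the Human Protein Atlas normal-tissue file: `protein`,
#' `tissue`, `level` (one of "not detected", "low", "medium", "high") and
#' `reliability`.  A (protein, tissue) pair may repeat (multiple cell
#' types).
#'
#' @param path Path to the TSV file.
#' @return data.frame with the four columns above.
#' @export
readTissueTable <- function(path) {
  stopIfMissing(path, "tissue-expression table")
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  need <- c("protein", "tissue", "level", "reliability")
  if (!all(need %in% names(dt))) {
    stop("tissue table must have columns: ", paste(need, collapse = ", "))
  }
  bad <- which(!dt$level %in% TISSUE_LEVELS)
  if (length(bad)) {
    stop(sprintf("unknown expression level '%s' at data row %d",
                 dt$level[bad[1]], bad[1]))
  }
  as.data.frame(dt[, need, with = FALSE])
}

#' Read a disease-to-tissue map
#'
#' TSV with header, columns `disease`, `tissue`, one pair per row.
#'
#' @param path Path to the TSV file.
#' @return Named list disease -> character vector of tissue names.
#' @export
readDiseaseTissueMap <- function(path) {
  stopIfMissing(path, "disease-tissue map")
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  if (!all(c("disease", "tissue") %in% names(dt))) {
    stop("disease-tissue map must have columns 'disease' and 'tissue'")
  }
  lapply(split(dt$tissue, dt$disease), unique)
}

#' Read a clinical co-occurrence table
#'
#' TSV with header, columns `disease_a`, `disease_b`, `n_a`, `n_b`,
#' `n_ab`: per-disease patient counts and the both-diseases count.  The
#' total cohort size is a single shared number and lives in the pipeline
#' configuration, not per row.
#'
#' @param path Path to the TSV file.
#' @param nTot Total cohort size; counts are validated against it.
#' @return data.frame with the five columns above (counts numeric).
#' @export
readClinicalTable <- function(path, nTot = NULL) {
  stopIfMissing(path, "clinical co-occurrence table")
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("disease_a", "disease_b", "n_a", "n_b", "n_ab")
  if (!all(need %in% names(dt))) {
    stop("clinical table must have columns: ", paste(need, collapse = ", "))
  }
  for (cc in c("n_a", "n_b", "n_ab")) {
    v <- suppressWarnings(as.numeric(dt[[cc]]))
    if (anyNA(v)) {
      stop(sprintf("malformed numeric cell in column '%s' at data row %d",
                   cc, which(is.na(v))[1]))
    }
    data.table::set(dt, j = cc, value = v)
  }
  if (any(dt$n_ab > pmin(dt$n_a, dt$n_b))) {
    stop("clinical counts violate n_ab <= min(n_a, n_b)")
  }
  if (!is.null(nTot) && any(pmax(dt$n_a, dt$n_b) > nTot)) {
    stop("clinical counts exceed the configured cohort size")
  }
  as.data.frame(dt[, need, with = FALSE])
}

#' Read a GMT pathway collection
#'
#' Standard GMT: `name TAB description TAB gene1 TAB gene2 ...`.  A line
#' with fewer than three fields (i.e. no genes) is a parse error naming
#' the line.
#'
#' @param path Path to the GMT file.
#' @return Named list pathway -> character vector of gene ids, with a
#'   `descriptions` attribute (named character vector).
#' @export
readGmt <- function(path) {
  stopIfMissing(path, "GMT collection")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop(sprintf("GMT parse error at line %d: %d field(s), need name, description and at least one gene",
                 which(nf < 3)[1], nf[which(nf < 3)[1]]))
  }
  ids <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(ids)) stop("duplicate pathway ids in GMT")
  descs <- stats::setNames(vapply(fields, `[[`, character(1), 2), ids)
  sets <- stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])), ids)
  attr(sets, "descriptions") <- descs
  sets
}

#' Write a GMT pathway collection
#'
#' @param gmt Named list of gene sets (optionally with a `descriptions`
#'   attribute).
#' @param path Output path.
#' @export
writeGmt <- function(gmt, path) {
  descs <- attr(gmt, "descriptions")
  if (is.null(descs)) descs <- stats::setNames(rep("na", length(gmt)), names(gmt))
  lines <- vapply(names(gmt), function(id) {
    paste(c(id, descs[[id]], gmt[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Read a pathogenic gene list
#'
#' One identifier per line, blank lines ignored, duplicates collapsed.
#' Identifiers absent from the universe are reported (message) but do not
#' fail the load; an empty usable set is an error.
#'
#' @param path Path to the text file.
#' @param universe Optional protein universe to check identifiers against.
#' @return Character vector of de-duplicated identifiers (restricted to
#'   the universe when one is given), with attribute `nUnknown` = number
#'   of identifiers not found in the universe.
#' @export
readGeneList <- function(path, universe = NULL) {
  stopIfMissing(path, "gene list")
  ids <- trimws(readLines(path, warn = FALSE))
  ids <- unique(ids[nzchar(ids)])
  if (!length(ids)) stop("no usable identifiers in gene list")
  nUnknown <- 0L
  if (!is.null(universe)) {
    unknown <- setdiff(ids, universe)
    nUnknown <- length(unknown)
    if (nUnknown > 0) {
      message(sprintf("%d identifier(s) in gene list not in the protein universe",
                      nUnknown))
    }
    ids <- intersect(ids, universe)
    if (!length(ids)) stop("no usable identifiers in gene list (none in universe)")
  }
  attr(ids, "nUnknown") <- nUnknown
  ids
}

# full-precision numeric rendering: round-trips to >= 15 significant digits
fmtNum <- function(x) sprintf("%.15g", x)

#' Write a comorbidity edge table
#'
#' TSV with header `disease_a, disease_b, n_shared, j_score, p_value,
#' q_value`, rows sorted by (q ascending, J descending, pair id
#' ascending), numbers at full precision so that rewriting and reloading
#' reproduces values to at least 12 significant digits.
#'
#' @param edges data.frame as in [edgeTable()] (columns `diseaseA`,
#'   `diseaseB`, `nShared`, `jScore`, `p`, `q`), or a
#'   [ComorbidityResult-class].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeEdgeTable <- function(edges, path) {
  if (is(edges, "ComorbidityResult")) edges <- edgeTable(edges)
  dt <- data.table::as.data.table(edges)
  out <- data.table::data.table(
    disease_a = dt$diseaseA, disease_b = dt$diseaseB,
    n_shared = dt$nShared, j_score = dt$jScore,
    p_value = dt$p, q_value = dt$q
  )
  data.table::setorder(out, q_value, -j_score, disease_a, disease_b)
  for (cc in c("j_score", "p_value", "q_value")) {
    data.table::set(out, j = cc, value = fmtNum(out[[cc]]))
  }
  ok <- tryCatch({
    data.table::fwrite(out, path, sep = "\t", quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write edge table to ", path)
  invisible(path)
}

#' Read back a comorbidity edge table written by [writeEdgeTable()]
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns `diseaseA`, `diseaseB`, `nShared`,
#'   `jScore`, `p`, `q`.
#' @export
readEdgeTable <- function(path) {
  stopIfMissing(path, "edge table")
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1:2))
  need <- c("disease_a", "disease_b", "n_shared", "j_score", "p_value", "q_value")
  if (!all(need %in% names(dt))) stop("edge table lacks required columns")
  data.frame(diseaseA = dt$disease_a, diseaseB = dt$disease_b,
             nShared = as.integer(dt$n_shared), jScore = as.numeric(dt$j_score),
             p = as.numeric(dt$p_value), q = as.numeric(dt$q_value),
             stringsAsFactors = FALSE)
}

#' Load a complete input world from files
#'
#' @param paths Named list of file paths: required `scores`, `targets`,
#'   `universe`; optional `tissue`, `tissueMap`, `clinical`, `gmt`.
#' @param config A [comoaConfig()]; unused fields are ignored here.
#' @param nTot Cohort size for the clinical table.
#' @return A validated [MoaWorld-class].
#' @export
loadWorld <- function(paths, config = comoaConfig(), nTot = 1) {
  need <- c("scores", "targets", "universe")
  miss <- setdiff(need, names(paths))
  if (length(miss)) stop("missing input paths: ", paste(miss, collapse = ", "))
  scores <- readScoreMatrix(paths$scores)
  universe <- readProteinUniverse(paths$universe)
  targets <- readTargetMap(paths$targets, drugs = rownames(scores))
  tissue <- if (!is.null(paths$tissue)) readTissueTable(paths$tissue) else emptyTissueTable()
  tissueMap <- if (!is.null(paths$tissueMap)) readDiseaseTissueMap(paths$tissueMap) else list()
  clinical <- if (!is.null(paths$clinical)) readClinicalTable(paths$clinical, nTot) else emptyClinicalTable()
  gmt <- if (!is.null(paths$gmt)) readGmt(paths$gmt) else list()
  moaWorld(scores = scores, targets = targets, universe = universe,
           tissue = tissue, tissueMap = tissueMap, clinical = clinical,
           nTot = nTot, gmt = gmt)
}

#' Write a world's input files to a directory
#'
#' Emits the standard file layout consumed by [loadWorld()]: `scores.tsv`,
#' `targets.tsv`, `universe.txt`, `tissue.tsv`, `tissue_map.tsv`,
#' `clinical.tsv`, `pathways.gmt`; for a [SyntheticWorld-class] also
#' `truth.json`.
#'
#' @param world A [MoaWorld-class].
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named list of the written paths.
#' @export
writeWorld <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    scores = file.path(dir, "scores.tsv"),
    targets = file.path(dir, "targets.tsv"),
    universe = file.path(dir, "universe.txt"),
    tissue = file.path(dir, "tissue.tsv"),
    tissueMap = file.path(dir, "tissue_map.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    gmt = file.path(dir, "pathways.gmt")
  )
  sc <- scoreMatrix(world)
  scDt <- data.table::data.table(drug = rownames(sc))
  for (j in seq_len(ncol(sc))) {
    data.table::set(scDt, j = colnames(sc)[j], value = fmtNum(sc[, j]))
  }
  data.table::fwrite(scDt, paths$scores, sep = "\t", quote = FALSE)
  tm <- targetMap(world)
  tmDt <- data.table::data.table(
    drug = rep(names(tm), lengths(tm)),
    protein = unlist(tm, use.names = FALSE)
  )
  data.table::fwrite(tmDt, paths$targets, sep = "\t", quote = FALSE)
  writeLines(proteinUniverse(world), paths$universe)
  data.table::fwrite(world@tissue, paths$tissue, sep = "\t", quote = FALSE)
  tmap <- world@tissueMap
  data.table::fwrite(data.table::data.table(
    disease = rep(names(tmap), lengths(tmap)),
    tissue = unlist(tmap, use.names = FALSE)
  ), paths$tissueMap, sep = "\t", quote = FALSE)
  data.table::fwrite(clinicalTable(world), paths$clinical, sep = "\t", quote = FALSE)
  writeGmt(world@gmt, paths$gmt)
  if (is(world, "SyntheticWorld")) {
    paths$truth <- file.path(dir, "truth.json")
    jsonlite::write_json(
      list(modules = world@truth$modules,
           plantedPairs = world@truth$plantedPairs,
           params = world@params, seed = world@seed, nTot = world@nTot),
      paths$truth, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(paths)
}
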