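# Disease-disease network characterisation: degree, closeness (reachable
# count over summed hop distances, within the node's component),
# betweenness (equal-split shortest-path counting), and the
# giant-component curve over a grid of J-score cutoffs.

buildDiseaseGraph <- function(edges, diseases, jCutoff, qCutoff) {
  keep <- edges$q < qCutoff & edges$jScore >= jCutoff
  igraph::graph_from_data_frame(
    edges[keep, c("diseaseA", "diseaseB"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = diseases, stringsAsFactors = FALSE)
  )
}

giantFraction <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0) return(0)
  max(igraph::components(g)$csize) / n
}

#' Characterise the disease-disease network
#'
#' Builds the graph whose edges are the pairs with `q < pair_q_cutoff`
#' and `J >= jCutoff`, then reports per-node degree, closeness and
#' betweenness plus the giant-component fraction, and the
#' giant-component curve over a grid of J-score cutoffs (the q filter and
#' the J cutoff are applied conjunctively).
#'
#' Closeness is (number of other reachable nodes) / (sum of shortest hop
#' distances to them), i.e. the reciprocal of the mean shortest distance
#' within the node's component (0 for isolated nodes).  Betweenness uses
#' standard equal-split counting over equally short paths.  All paths are
#' unweighted (every edge has length 1).
#'
#' @param result A [ComorbidityResult-class] (or plain edge data.frame
#'   plus `diseases`).
#' @param jCutoffGrid Numeric grid of J-score cutoffs for the
#'   giant-component curve.
#' @param config A [comoaConfig()]; supplies the q cutoff.
#' @param jCutoff J-score cutoff for the per-node metrics (default: the
#'   smallest grid value).
#' @param diseases Required when `result` is a plain data.frame.
#' @return List with `nodes` (data.frame: `disease`, `degree`,
#'   `closeness`, `betweenness`), `giantFraction`, and `curve`
#'   (data.frame: `jCutoff`, `fraction`, non-increasing in the cutoff).
#' @export
networkReport <- function(result, jCutoffGrid = seq(0, 0.9, by = 0.05),
                          config = comoaConfig(), jCutoff = min(jCutoffGrid),
                          diseases = NULL) {
  if (is(result, "ComorbidityResult")) {
    edges <- edgeTable(result)
    diseases <- result@diseases
  } else {
    edges <- result
    if (is.null(diseases)) stop("'diseases' required with a plain edge table")
  }
  g <- buildDiseaseGraph(edges, diseases, jCutoff, config$pair_q_cutoff)
  n <- igraph::vcount(g)
  deg <- igraph::degree(g)
  clo <- rep(0, n)
  if (n > 1 && igraph::ecount(g) > 0) {
    d <- igraph::distances(g)
    diag(d) <- Inf
    reach <- is.finite(d)
    nr <- rowSums(reach)
    sd_ <- rowSums(ifelse(reach, d, 0))
    clo <- ifelse(nr > 0, nr / sd_, 0)
  }
  btw <- if (igraph::ecount(g) > 0) igraph::betweenness(g, directed = FALSE) else rep(0, n)
  nodes <- data.frame(
    disease = igraph::V(g)$name,
    degree = as.integer(deg),
    closeness = as.numeric(clo),
    betweenness = as.numeric(btw),
    stringsAsFactors = FALSE
  )
  rownames(nodes) <- NULL
  curve <- data.frame(
    jCutoff = jCutoffGrid,
    fraction = vapply(jCutoffGrid, function(ct) {
      giantFraction(buildDiseaseGraph(edges, diseases, ct, config$pair_q_cutoff))
    }, numeric(1))
  )
  list(nodes = nodes, giantFraction = giantFraction(g), curve = curve)
}

#' Write a network report as JSON
#'
#' @param report A list as returned by [networkReport()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeNetworkReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
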