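#' @import methods
NULL

#' Single network layer
#'
#' A `Layer` holds one intra-layer graph: the directed gene regulatory
#' network (GRN), or the undirected protein-protein interaction (PPI) or
#' metabolic layer. Nodes are string identifiers; edges are stored as a
#' two-column character matrix. Undirected edges are stored canonically
#' (endpoint pairs sorted), self-loops are forbidden, and no duplicate
#' edges are allowed.
#'
#' @slot name layer label, e.g. `"grn"`.
#' @slot directed single logical.
#' @slot nodes character vector of node ids (may include isolated nodes).
#' @slot edges two-column character matrix of edges.
#' @export
setClass("Layer",
  representation(name = "character", directed = "logical",
                 nodes = "character", edges = "matrix"),
  validity = function(object) {
    msg <- character(0)
    e <- object@edges
    if (!is.character(e) || ncol(e) != 2L)
      return("edges must be a two-column character matrix")
    if (anyDuplicated(object@nodes))
      msg <- c(msg, "duplicate node ids")
    if (nrow(e)) {
      if (!all(e %in% object@nodes))
        msg <- c(msg, "edge endpoint not in node set")
      if (any(e[, 1L] == e[, 2L]))
        msg <- c(msg, "self-loop present")
      key <- if (object@directed) paste(e[, 1L], e[, 2L], sep = "\r")
             else .edgeKey(e[, 1L], e[, 2L])
      if (anyDuplicated(key))
        msg <- c(msg, "duplicate edge present")
      if (!object@directed && any(e[, 1L] > e[, 2L]))
        msg <- c(msg, "undirected edges must be stored canonically")
    }
    if (length(msg)) msg else TRUE
  })

#' One-to-one gene/protein interdependency map
#'
#' Bidirectional couplings between protein-coding genes in the GRN and
#' their protein products in the PPI layer: a partial one-to-one matching,
#' so each gene appears in at most one pair and so does each protein.
#'
#' @slot gene,protein parallel character vectors, one entry per pair.
#' @export
setClass("InterdependencyMap",
  representation(gene = "character", protein = "character"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@gene) != length(object@protein))
      msg <- c(msg, "gene and protein vectors differ in length")
    if (anyDuplicated(object@gene))
      msg <- c(msg, "a gene appears in more than one pair")
    if (anyDuplicated(object@protein))
      msg <- c(msg, "a protein appears in more than one pair")
    if (length(msg)) msg else TRUE
  })

#' Many-to-many protein-to-metabolite support map
#'
#' Directed support links from PPI proteins to metabolites. A metabolite's
#' support degree k_s is the number of distinct proteins sustaining it.
#'
#' @slot protein,metabolite parallel character vectors, one entry per link.
#' @export
setClass("SupportMap",
  representation(protein = "character", metabolite = "character"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@protein) != length(object@metabolite))
      msg <- c(msg, "protein and metabolite vectors differ in length")
    if (length(object@protein) &&
        anyDuplicated(paste(object@protein, object@metabolite, sep = "\r")))
      msg <- c(msg, "duplicate support link")
    if (length(msg)) msg else TRUE
  })

#' Three-layer molecular network
#'
#' The central container: a directed GRN, an undirected PPI layer and an
#' undirected metabolic layer, tied together by a one-to-one
#' gene/protein interdependency map and a many-to-many protein-to-metabolite
#' support map. All simulation and theory operate on this object.
#'
#' Use [MultilayerNetwork()] to construct one (it validates the instance),
#' and [validateNetwork()] to obtain the full violation report.
#'
#' @slot grn,ppi,met [Layer-class] objects.
#' @slot gp [InterdependencyMap-class].
#' @slot pm [SupportMap-class].
#' @export
setClass("MultilayerNetwork",
  representation(grn = "Layer", ppi = "Layer", met = "Layer",
                 gp = "InterdependencyMap", pm = "SupportMap"))

#' Empirical degree distributions of a multilayer network
#'
#' Inputs to the generating-function machinery: the joint in/out degree
#' pmf of the GRN, the degree pmfs of the PPI and metabolic layers, and
#' the support-degree pmf (including metabolites with k_s = 0).
#'
#' @slot grnJoint data.frame with integer columns `kIn`, `kOut` and a
#'   numeric `prob` column summing to one.
#' @slot ppi,met,support numeric pmf vectors; element `i` is the
#'   probability of degree `i - 1`.
#' @export
setClass("DegreeDistributions",
  representation(grnJoint = "data.frame", ppi = "numeric",
                 met = "numeric", support = "numeric"),
  validity = function(object) {
    msg <- character(0)
    ok1 <- function(p) length(p) && all(p >= 0) && abs(sum(p) - 1) < 1e-12
    if (!ok1(object@grnJoint$prob)) msg <- c(msg, "grnJoint pmf must sum to 1")
    if (!ok1(object@ppi)) msg <- c(msg, "ppi pmf must sum to 1")
    if (!ok1(object@met)) msg <- c(msg, "met pmf must sum to 1")
    if (!ok1(object@support)) msg <- c(msg, "support pmf must sum to 1")
    if (length(msg)) msg else TRUE
  })

#' Degree-distribution generating function
#'
#' Wraps a pmf over non-negative integer degrees and exposes the
#' generating function G(x) = sum_k P(k) x^k and the branching
#' (excess-degree) function H(x) = G'(x)/G'(1), the core objects of
#' configuration-model percolation.
#'
#' @slot pmf numeric vector; element `i` is P(degree = i - 1).
#' @export
setClass("GeneratingFunction",
  representation(pmf = "numeric"),
  validity = function(object) {
    p <- object@pmf
    if (!length(p) || any(p < 0) || any(!is.finite(p)))
      return("pmf must be non-negative and finite")
    if (abs(sum(p) - 1) > 1e-12)
      return("pmf must sum to 1 (within 1e-12)")
    TRUE
  })

#' Perturbation configuration
#'
#' Describes one perturbation experiment: either an explicit seed gene set
#' or a random removal fraction 1 - p, plus the metabolite failure
#' threshold f_P2M, the process mode, GRN propagation rule, the
#' target-failure fraction f, the interdependency-link retention and an
#' RNG seed. Construct with [perturbationConfig()].
#'
#' @slot seeds character vector of seed genes, or `NA_character_` when a
#'   fraction is used.
#' @slot fraction removal fraction 1 - p in `[0, 1]`, or `NA_real_`.
#' @slot fP2M metabolite support-failure threshold in `[0, 1]`.
#' @slot mode `"coupled"`, `"uncoupled"` or `"merged"`.
#' @slot grnPropagation `"one_hop"` or `"recursive"`.
#' @slot targetFraction fraction f of a failing gene's out-neighbours that
#'   fail, in `(0, 1]`.
#' @slot couplingRetention fraction of gene-protein pairs retained.
#' @slot seed integer RNG seed or `NA_integer_`.
#' @export
setClass("PerturbationConfig",
  representation(seeds = "character", fraction = "numeric", fP2M = "numeric",
                 mode = "character", grnPropagation = "character",
                 targetFraction = "numeric", couplingRetention = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character(0)
    hasSeeds <- !(length(object@seeds) == 1L && is.na(object@seeds[1L]))
    hasFrac <- !is.na(object@fraction)
    if (hasSeeds == hasFrac)
      msg <- c(msg, "exactly one of seeds / fraction must be given")
    if (hasFrac && (object@fraction < 0 || object@fraction > 1))
      msg <- c(msg, "fraction must lie in [0, 1]")
    if (object@fP2M < 0 || object@fP2M > 1)
      msg <- c(msg, "fP2M must lie in [0, 1]")
    if (!object@mode %in% c("coupled", "uncoupled", "merged"))
      msg <- c(msg, "unknown mode")
    if (!object@grnPropagation %in% c("one_hop", "recursive"))
      msg <- c(msg, "unknown grnPropagation")
    if (object@targetFraction <= 0 || object@targetFraction > 1)
      msg <- c(msg, "targetFraction must lie in (0, 1]")
    if (object@couplingRetention < 0 || object@couplingRetention > 1)
      msg <- c(msg, "couplingRetention must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Result of one cascading-failure run
#'
#' Per-node failure rounds (0 means the node stayed functional; round
#' indices start at 1, one index per full GRN/PPI pass) and final
#' functional fractions per layer. Metabolite failures are resolved once,
#' after the GRN/PPI cascade converges, and carry the final round index.
#'
#' @slot geneRounds,proteinRounds,metRounds named integer vectors.
#' @slot fsG,fsP,fsM final functional fractions (NA where a mode does not
#'   define them).
#' @slot rounds number of cascade rounds (>= 1).
#' @slot mode the process mode that produced the result.
#' @slot lccTies diagnostic: whether any largest-component computation
#'   during the run ended in a tie (the inclusive rule keeps all tied
#'   components, which can make outcomes non-monotone in the seed set).
#' @export
setClass("CascadeResult",
  representation(geneRounds = "integer", proteinRounds = "integer",
                 metRounds = "integer", fsG = "numeric", fsP = "numeric",
                 fsM = "numeric", rounds = "integer", mode = "character",
                 lccTies = "logical"))

#' Robustness curve
#'
#' Mean final functional fractions per layer over a grid of gene survival
#' probabilities p, with Monte-Carlo standard errors, plus the robustness
#' integral R (trapezoidal area under the mean curve) per layer.
#'
#' @slot curve data.frame with columns `p`, `fsG`, `fsP`, `fsM`,
#'   `seG`, `seP`, `seM`.
#' @slot replicates number of independent removal draws per p.
#' @slot R named numeric: robustness integral per layer.
#' @slot repR data.frame of per-replicate integrals (columns G, P, M).
#' @export
setClass("RobustnessCurve",
  representation(curve = "data.frame", replicates = "integer",
                 R = "numeric", repR = "data.frame"))

#' Analytical cascade fixed point
#'
#' Sequences of remaining (psi', phi') and functional (psi, phi) network
#' sizes for the GRN/PPI cascade recursion, the fixed points, and the
#' predicted final functional fractions.
#'
#' @slot p initial gene survival probability.
#' @slot qG,qP coupling strengths.
#' @slot psiPrime,psi,phiPrime,phi numeric sequences over cascade stages.
#' @slot fsG,fsP predicted final functional fractions.
#' @slot converged logical; @slot iterations stages used.
#' @export
setClass("TheoryResult",
  representation(p = "numeric", qG = "numeric", qP = "numeric",
                 psiPrime = "numeric", psi = "numeric",
                 phiPrime = "numeric", phi = "numeric",
                 fsG = "numeric", fsP = "numeric",
                 converged = "logical", iterations = "integer"))

#' Rewiring specification
#'
#' Names a null-model randomization: the target component (`ppi`, `met`,
#' `grn_inout`, `gp_links`, `pm_links`), the mode (`neutral`,
#' `assortative`, `disassortative`), the number of attempted steps and a
#' seed. Construct with [rewireSpec()].
#'
#' @slot target,mode character scalars.
#' @slot nSteps integer >= 0 (ignored for interlayer targets).
#' @slot seed integer.
#' @export
setClass("RewireSpec",
  representation(target = "character", mode = "character",
                 nSteps = "integer", seed = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (!object@target %in% c("ppi", "met", "grn_inout", "gp_links", "pm_links"))
      msg <- c(msg, "unknown target")
    if (!object@mode %in% c("neutral", "assortative", "disassortative"))
      msg <- c(msg, "unknown mode")
    if (!is.na(object@nSteps) && object@nSteps < 0L)
      msg <- c(msg, "nSteps must be >= 0")  # NA means the 10x|E| default
    if (length(msg)) msg else TRUE
  })
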