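#' @include engine.R
NULL

#' Build a perturbation configuration
#'
#' Exactly one of `seeds` (explicit target genes; an empty character
#' vector is a valid, empty perturbation) or `fraction` (the fraction
#' 1 - p of genes to remove uniformly at random) must be given.
#'
#' @param seeds character vector of seed gene ids, or `NULL`.
#' @param fraction removal fraction 1 - p in `[0, 1]`, or `NULL`.
#' @param fP2M metabolite failure threshold: a metabolite with k_s > 0
#'   supports fails once at least `ceiling(fP2M * k_s)` of them have
#'   failed. Default 1 (a metabolite fails when all supports fail).
#' @param mode `"coupled"` (full cascade), `"uncoupled"` (PPI-only
#'   control) or `"merged"` (GRN+PPI union control).
#' @param grnPropagation `"one_hop"` (default; only genes failed by
#'   perturbation or protein loss drag down their targets) or
#'   `"recursive"` (target failure iterates within a round).
#' @param targetFraction fraction f of a failing gene's out-neighbours
#'   that fail (each retained independently with probability 1 - f when
#'   f < 1).
#' @param couplingRetention fraction of gene-protein interdependency
#'   links kept; the severed complement is drawn uniformly per run. Seed
#'   genes always take their own protein down.
#' @param seed RNG seed (used for fraction sampling, f < 1 thinning and
#'   link severing), or `NULL`.
#' @return a [PerturbationConfig-class].
#' @export
perturbationConfig <- function(seeds = NULL, fraction = NULL, fP2M = 1,
                               mode = c("coupled", "uncoupled", "merged"),
                               grnPropagation = c("one_hop", "recursive"),
                               targetFraction = 1, couplingRetention = 1,
                               seed = NULL) {
  mode <- match.arg(mode)
  grnPropagation <- match.arg(grnPropagation)
  new("PerturbationConfig",
      seeds = if (is.null(seeds)) NA_character_ else as.character(seeds),
      fraction = if (is.null(fraction)) NA_real_ else as.numeric(fraction),
      fP2M = fP2M, mode = mode, grnPropagation = grnPropagation,
      targetFraction = targetFraction, couplingRetention = couplingRetention,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

.cfgSeeds <- function(cfg) {
  if (length(cfg@seeds) == 1L && is.na(cfg@seeds[1L])) NULL else cfg@seeds
}

#' Run the cascading-failure process
#'
#' Simulates a gene perturbation on a multilayer network. One round is a
#' full pass: (i) newly failed genes drag down their regulatory targets
#' and genes left with no remaining regulatory links fail; (ii) proteins
#' paired to the genes that failed this round fail; (iii) proteins
#' disconnected from the largest PPI component(s) fail; (iv) genes paired
#' to those proteins fail and propagate next round. Rounds repeat until a
#' fixed point, after which the metabolic layer is resolved once:
#' metabolites losing at least `ceiling(fP2M * k_s)` of their k_s > 0
#' supports fail, then metabolites outside the surviving metabolic
#' largest component(s) fail. With p = 1 and no seeds, GRN isolates,
#' non-LCC proteins and non-LCC metabolites are already non-functional.
#'
#' In `"uncoupled"` mode the seed genes' partner proteins are deleted
#' from the isolated PPI network directly; in `"merged"` mode the seeds
#' are deleted from the contracted union of GRN and PPI edges. Both
#' controls report a single functional fraction in `fsP`.
#'
#' @param net a [MultilayerNetwork-class].
#' @param cfg a [PerturbationConfig-class].
#' @return a [CascadeResult-class].
#' @examples
#' t1 <- toyFixture("T1")
#' finalFractions(runCascade(t1, perturbationConfig(seeds = "g1")))
#' @export
runCascade <- function(net, cfg = perturbationConfig(seeds = character(0))) {
  stopifnot(is(net, "MultilayerNetwork"), is(cfg, "PerturbationConfig"))
  validObject(cfg)
  eng <- .buildEngine(net)
  .runCascadeEngine(net, eng, cfg)
}

# split out so repeated callers can reuse the engine
.runCascadeEngine <- function(net, eng, cfg) {
  seeds <- .cfgSeeds(cfg)
  seedVal <- if (is.na(cfg@seed)) NULL else cfg@seed
  emptyRounds <- stats::setNames(integer(0), character(0))
  .withSeed(seedVal, {
    if (is.null(seeds)) {
      nRemove <- round(cfg@fraction * eng$nG)
      seedIdx <- if (nRemove > 0L) sample.int(eng$nG, nRemove) else integer(0)
    } else {
      seedIdx <- match(seeds, eng$genes)
      if (anyNA(seedIdx))
        stop("unknown seed gene id: ", seeds[is.na(seedIdx)][1L], call. = FALSE)
    }
    if (cfg@mode == "uncoupled") {
      rem <- eng$partner[seedIdx]
      rem <- rem[!is.na(rem)]
      new("CascadeResult", geneRounds = emptyRounds,
          proteinRounds = emptyRounds, metRounds = emptyRounds,
          fsG = NA_real_, fsP = .runUncoupledEngine(eng, rem),
          fsM = NA_real_, rounds = 1L, mode = "uncoupled",
          lccTies = FALSE)
    } else if (cfg@mode == "merged") {
      new("CascadeResult", geneRounds = emptyRounds,
          proteinRounds = emptyRounds, metRounds = emptyRounds,
          fsG = NA_real_, fsP = runMerged(net, seeds = eng$genes[seedIdx]),
          fsM = NA_real_, rounds = 1L, mode = "merged",
          lccTies = FALSE)
    } else {
      r <- .runEngine(eng, seedIdx, fP2M = cfg@fP2M,
                      grnPropagation = cfg@grnPropagation,
                      targetFraction = cfg@targetFraction,
                      couplingRetention = cfg@couplingRetention)
      new("CascadeResult",
          geneRounds = stats::setNames(r$gRounds, eng$genes),
          proteinRounds = stats::setNames(r$pRounds, eng$proteins),
          metRounds = stats::setNames(r$mRounds, eng$mets),
          fsG = r$fsG, fsP = r$fsP, fsM = r$fsM,
          rounds = r$rounds, mode = "coupled", lccTies = r$lccTies)
    }
  })
}

#' @rdname cascadeAccessors
#' @name cascadeAccessors
#' @aliases finalFractions failedNodes nRounds
#' @param x a [CascadeResult-class].
#' @param layer which layer's failed nodes to return.
#' @param round restrict to nodes that failed in this round (default all).
NULL

#' @rdname cascadeAccessors
setMethod("finalFractions", "CascadeResult", function(x) {
  c(fsG = x@fsG, fsP = x@fsP, fsM = x@fsM)
})

#' @rdname cascadeAccessors
setMethod("failedNodes", "CascadeResult", function(x, layer, round = NULL) {
  layer <- match.arg(layer, c("gene", "protein", "metabolite"))
  r <- switch(layer, gene = x@geneRounds, protein = x@proteinRounds,
              metabolite = x@metRounds)
  sel <- if (is.null(round)) r > 0L else r == round
  names(r)[sel]
})

#' @rdname cascadeAccessors
setMethod("nRounds", "CascadeResult", function(x) x@rounds)

setMethod("show", "CascadeResult", function(object) {
  cat(sprintf("CascadeResult (%s mode, %d round%s)\n", object@mode,
              object@rounds, if (object@rounds == 1L) "" else "s"))
  f <- finalFractions(object)
  cat(sprintf("  functional fractions: fsG = %s, fsP = %s, fsM = %s\n",
              format(f[1L], digits = 4), format(f[2L], digits = 4),
              format(f[3L], digits = 4)))
})

#' Uncoupled PPI control
#'
#' Removes the given proteins from the isolated PPI network and returns
#' the fraction of proteins left in the largest connected component(s).
#'
#' @param ppi an undirected [Layer-class].
#' @param removed character vector of protein ids to delete.
#' @return functional fraction in `[0, 1]`.
#' @export
runUncoupled <- function(ppi, removed = character(0)) {
  idx <- match(removed, ppi@nodes)
  if (anyNA(idx)) stop("unknown protein id: ", removed[is.na(idx)][1L],
                       call. = FALSE)
  alive <- setdiff(seq_along(ppi@nodes), idx)
  ig <- .layerIgraph(ppi)
  length(.lccKeep(ig, alive)) / length(ppi@nodes)
}

#' Merged-network control
#'
#' Builds (once per call) the undirected union of GRN edges (direction
#' dropped), PPI edges and gene-protein pairs contracted into single
#' nodes, deletes the seeds' contracted nodes, and returns the
#' largest-component fraction over merged nodes.
#'
#' @param net a [MultilayerNetwork-class].
#' @param seeds character vector of seed gene ids.
#' @return functional fraction in `[0, 1]`.
#' @export
runMerged <- function(net, seeds = character(0)) {
  genes <- net@grn@nodes; proteins <- net@ppi@nodes
  if (!all(seeds %in% genes))
    stop("unknown seed gene id: ", setdiff(seeds, genes)[1L], call. = FALSE)
  # contracted node label per gene/protein
  partner <- stats::setNames(rep(NA_character_, length(genes)), genes)
  partner[net@gp@gene] <- net@gp@protein
  lab <- function(g) ifelse(is.na(partner[g]), paste0("g|", g),
                            paste0("m|", g))
  gLab <- stats::setNames(lab(genes), genes)
  pLab <- stats::setNames(paste0("p|", proteins), proteins)
  pLab[net@gp@protein] <- gLab[net@gp@gene]
  edges <- rbind(
    cbind(gLab[net@grn@edges[, 1L]], gLab[net@grn@edges[, 2L]]),
    cbind(pLab[net@ppi@edges[, 1L]], pLab[net@ppi@edges[, 2L]]))
  mergedNodes <- unique(c(gLab, pLab))
  ml <- Layer("merged", edges, directed = FALSE, nodes = mergedNodes)
  keepNodes <- setdiff(mergedNodes, gLab[seeds])
  length(largestComponent(ml, keepNodes)) / length(mergedNodes)
}

#' Robustness curve over a survival-probability grid
#'
#' For each p in `pGrid`, removes a uniform random 1 - p fraction of
#' genes (`round((1 - p) * n)` genes, without replacement), runs the
#' coupled cascade, and averages the final functional fractions over
#' `replicates` independent draws. The robustness integral R is the
#' trapezoidal area under each mean curve over the grid.
#'
#' @param net a [MultilayerNetwork-class].
#' @param pGrid increasing grid of survival probabilities in `[0, 1]`.
#' @param replicates independent removal draws per p (>= 1).
#' @param fP2M metabolite failure threshold.
#' @param seed RNG seed; replicate draws use derived substreams, so
#'   results are reproducible and extending the grid never perturbs
#'   earlier draws.
#' @param grnPropagation,targetFraction,couplingRetention passed to the
#'   cascade (see [perturbationConfig()]).
#' @return a [RobustnessCurve-class].
#' @export
robustnessCurve <- function(net, pGrid = seq(0, 1, by = 0.05),
                            replicates = 30L, fP2M = 1, seed = 1L,
                            grnPropagation = "one_hop", targetFraction = 1,
                            couplingRetention = 1) {
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  stopifnot(all(pGrid >= 0 & pGrid <= 1))
  eng <- .buildEngine(net)
  nG <- eng$nG
  res <- array(NA_real_, dim = c(length(pGrid), replicates, 3L))
  for (i in seq_along(pGrid)) {
    p <- pGrid[i]
    nRemove <- round((1 - p) * nG)
    for (r in seq_len(replicates)) {
      .withSeed(.deriveSeed(seed, i * 1000L + r), {
        seedIdx <- if (nRemove > 0L) sample.int(nG, nRemove) else integer(0)
        out <- .runEngine(eng, seedIdx, fP2M = fP2M,
                          grnPropagation = grnPropagation,
                          targetFraction = targetFraction,
                          couplingRetention = couplingRetention)
        res[i, r, ] <- c(out$fsG, out$fsP, out$fsM)
      })
    }
  }
  mn <- apply(res, c(1L, 3L), mean)
  se <- apply(res, c(1L, 3L), stats::sd) / sqrt(replicates)
  curve <- data.frame(p = pGrid, fsG = mn[, 1L], fsP = mn[, 2L],
                      fsM = mn[, 3L], seG = se[, 1L], seP = se[, 2L],
                      seM = se[, 3L])
  repR <- data.frame(G = apply(res[, , 1L, drop = FALSE], 2L,
                               function(y) .trapz(pGrid, y)),
                     P = apply(res[, , 2L, drop = FALSE], 2L,
                               function(y) .trapz(pGrid, y)),
                     M = apply(res[, , 3L, drop = FALSE], 2L,
                               function(y) .trapz(pGrid, y)))
  new("RobustnessCurve", curve = curve, replicates = as.integer(replicates),
      R = c(G = .trapz(pGrid, mn[, 1L]), P = .trapz(pGrid, mn[, 2L]),
            M = .trapz(pGrid, mn[, 3L])),
      repR = repR)
}

setMethod("show", "RobustnessCurve", function(object) {
  cat(sprintf("RobustnessCurve: %d p values x %d replicates\n",
              nrow(object@curve), object@replicates))
  cat("  R:", paste(names(object@R),
                    format(object@R, digits = 4), sep = " = ",
                    collapse = ", "), "\n")
})

#' Plot a robustness curve
#'
#' Base-graphics view of the mean functional fractions per layer vs p.
#'
#' @param x a [RobustnessCurve-class].
#' @param ... passed to [graphics::matplot()].
#' @export
plotRobustnessCurve <- function(x, ...) {
  graphics::matplot(x@curve$p, x@curve[, c("fsG", "fsP", "fsM")],
                    type = "b", pch = c(1, 2, 3), lty = 1,
                    xlab = "gene survival probability p",
                    ylab = "final functional fraction", ...)
  graphics::legend("topleft", c("GRN", "PPI", "metabolic"),
                   pch = c(1, 2, 3), col = 1:3, bty = "n")
}
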