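#' @include netmodel.R
NULL

#' @rdname RewireSpec-class
#' @param target one of `"ppi"`, `"met"`, `"grn_inout"`, `"gp_links"`,
#'   `"pm_links"`.
#' @param mode `"neutral"`, `"assortative"` or `"disassortative"`.
#' @param nSteps attempted steps (default 10 x the number of edges of
#'   the target, resolved when the spec is applied).
#' @param seed RNG seed.
#' @export
rewireSpec <- function(target, mode = "neutral", nSteps = NA_integer_,
                       seed = 1L) {
  new("RewireSpec", target = target, mode = mode,
      nSteps = as.integer(nSteps), seed = as.integer(seed))
}

setMethod("show", "RewireSpec", function(object) {
  cat(sprintf("RewireSpec: %s / %s, %s steps, seed %d\n", object@target,
              object@mode,
              if (is.na(object@nSteps)) "10x|E|" else object@nSteps,
              object@seed))
})

#' Degree-preserving double-edge swaps
#'
#' Repeatedly picks two edges (A,B), (C,D) with four distinct endpoints
#' and rewires them: `neutral` chooses one of the two alternative
#' pairings at random; `assortative` connects the highest-degree node of
#' the four to the next highest (and the remaining two together);
#' `disassortative` connects the highest to the lowest. Steps that would
#' create a self-loop or multi-edge are rejected, so the degree sequence
#' is preserved exactly. Since degrees never change, every accepted
#' assortative (disassortative) step weakly increases (decreases) the
#' edge degree-degree correlation.
#'
#' @param layer an undirected [Layer-class] with at least 2 edges.
#' @param mode rewiring mode.
#' @param nSteps attempted swaps (default `10 * |E|`).
#' @param seed RNG seed.
#' @return the rewired [Layer-class].
#' @export
doubleEdgeSwap <- function(layer,
                           mode = c("neutral", "assortative", "disassortative"),
                           nSteps = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (isDirected(layer)) stop("doubleEdgeSwap needs an undirected layer",
                              call. = FALSE)
  nodes <- layer@nodes
  e <- cbind(match(layer@edges[, 1L], nodes), match(layer@edges[, 2L], nodes))
  m <- nrow(e)
  if (m < 2L) stop("layer too small to rewire", call. = FALSE)
  if (is.null(nSteps)) nSteps <- 10L * m
  if (nSteps == 0L) return(layer)
  deg <- tabulate(as.vector(e), nbins = length(nodes))
  has <- new.env(hash = TRUE, parent = emptyenv())
  key <- function(a, b) paste(min(a, b), max(a, b))
  for (i in seq_len(m)) assign(key(e[i, 1L], e[i, 2L]), TRUE, envir = has)
  .withSeed(seed, {
    picks <- matrix(sample.int(m, 2L * nSteps, replace = TRUE), ncol = 2L)
    coins <- stats::runif(nSteps)
    for (s in seq_len(nSteps)) {
      i <- picks[s, 1L]; j <- picks[s, 2L]
      if (i == j) next
      four <- c(e[i, ], e[j, ])
      if (anyDuplicated(four)) next
      if (mode == "neutral") {
        newPairs <- if (coins[s] < 0.5)
          rbind(four[c(1L, 3L)], four[c(2L, 4L)])
        else
          rbind(four[c(1L, 4L)], four[c(2L, 3L)])
      } else {
        ord <- order(-deg[four], four)  # degree desc, id tie-break
        newPairs <- if (mode == "assortative")
          rbind(four[ord[c(1L, 2L)]], four[ord[c(3L, 4L)]])
        else
          rbind(four[ord[c(1L, 4L)]], four[ord[c(2L, 3L)]])
      }
      k1 <- key(newPairs[1L, 1L], newPairs[1L, 2L])
      k2 <- key(newPairs[2L, 1L], newPairs[2L, 2L])
      oldK1 <- key(e[i, 1L], e[i, 2L]); oldK2 <- key(e[j, 1L], e[j, 2L])
      if (k1 == oldK1 && k2 == oldK2) next
      if (k1 == k2) next
      if ((exists(k1, envir = has) && k1 != oldK1 && k1 != oldK2) ||
          (exists(k2, envir = has) && k2 != oldK1 && k2 != oldK2)) next
      rm(list = c(oldK1, oldK2), envir = has)
      assign(k1, TRUE, envir = has); assign(k2, TRUE, envir = has)
      e[i, ] <- newPairs[1L, ]; e[j, ] <- newPairs[2L, ]
    }
  })
  Layer(layer@name, cbind(nodes[e[, 1L]], nodes[e[, 2L]]),
        directed = FALSE, nodes = nodes)
}

#' In/out-degree correlation rewiring of a directed layer
#'
#' Repeatedly picks two genes and swaps their entire out-neighbour sets,
#' which preserves both the in-degree and out-degree marginal
#' distributions exactly while changing the joint. A step is accepted in
#' `assortative` (`disassortative`) mode only if it increases
#' (decreases) the Pearson correlation between per-node in- and
#' out-degrees; `neutral` always accepts. Steps that would create a
#' self-loop are rejected.
#'
#' @param grn a directed [Layer-class].
#' @param mode rewiring mode.
#' @param nSteps attempted swaps (default `10 * |E|`).
#' @param seed RNG seed.
#' @return the rewired [Layer-class].
#' @export
grnInOutRewire <- function(grn,
                           mode = c("neutral", "assortative", "disassortative"),
                           nSteps = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (!isDirected(grn)) stop("grnInOutRewire needs a directed layer",
                             call. = FALSE)
  nodes <- grn@nodes
  n <- length(nodes)
  src <- match(grn@edges[, 1L], nodes); tgt <- match(grn@edges[, 2L], nodes)
  out <- unname(split(tgt, factor(src, levels = seq_len(n))))
  kIn <- tabulate(tgt, nbins = n)
  kOut <- lengths(out)
  if (is.null(nSteps)) nSteps <- 10L * length(src)
  .withSeed(seed, {
    for (s in seq_len(nSteps)) {
      uv <- sample.int(n, 2L)
      u <- uv[1L]; v <- uv[2L]
      if (u %in% out[[v]] || v %in% out[[u]]) next  # would create a self-loop
      if (mode != "neutral") {
        # corr moves with (kIn_u - kIn_v) * (kOut_v - kOut_u)
        delta <- (kIn[u] - kIn[v]) * (kOut[v] - kOut[u])
        if (mode == "assortative" && delta <= 0) next
        if (mode == "disassortative" && delta >= 0) next
      }
      tmp <- out[[u]]; out[[u]] <- out[[v]]; out[[v]] <- tmp
      tmpK <- kOut[u]; kOut[u] <- kOut[v]; kOut[v] <- tmpK
    }
  })
  newSrc <- rep(seq_len(n), lengths(out))
  newTgt <- unlist(out, use.names = FALSE)
  Layer(grn@name, cbind(nodes[newSrc], nodes[newTgt]), directed = TRUE,
        nodes = nodes)
}

#' Rewire an interlayer map
#'
#' For a one-to-one [InterdependencyMap-class]: `neutral` re-matches the
#' same genes to the same proteins uniformly at random; `assortative`
#' matches both sides by descending degree rank (ties broken by id);
#' `disassortative` matches descending against ascending ranks. For a
#' many-to-many [SupportMap-class] the endpoint stubs are reshuffled the
#' same way while preserving each node's link count; conflicting
#' (duplicate) links under the rank matchings are repaired by local stub
#' swaps.
#'
#' @param map an [InterdependencyMap-class] or [SupportMap-class].
#' @param mode rewiring mode.
#' @param degreesA named degrees for the first side (genes / proteins).
#' @param degreesB named degrees for the second side (proteins /
#'   metabolites).
#' @param seed RNG seed.
#' @return a rewired map of the same class.
#' @export
interlayerRewire <- function(map,
                             mode = c("neutral", "assortative",
                                      "disassortative"),
                             degreesA = NULL, degreesB = NULL, seed = 1L) {
  mode <- match.arg(mode)
  a <- if (is(map, "InterdependencyMap")) map@gene else map@protein
  b <- if (is(map, "InterdependencyMap")) map@protein else map@metabolite
  if (!length(a)) stop("empty map", call. = FALSE)
  if (mode != "neutral" && (is.null(degreesA) || is.null(degreesB)))
    stop("assortative/disassortative rewiring needs degreesA and degreesB",
         call. = FALSE)
  ordA <- if (mode == "neutral") NULL
          else order(-as.numeric(degreesA[a]), a)
  .withSeed(seed, {
    if (mode == "neutral") {
      newB <- sample(b)
    } else {
      ordB <- if (mode == "assortative") order(-as.numeric(degreesB[b]), b)
              else order(as.numeric(degreesB[b]), b)
      newB <- character(length(b))
      newB[ordA] <- b[ordB]
    }
    if (is(map, "InterdependencyMap")) {
      InterdependencyMap(a, newB)
    } else {
      # SupportMap: repair duplicate links one at a time by swapping the
      # conflicting stub with a random partner (a transposition, so every
      # node's link count is untouched)
      keyOf <- function(x, y) paste(x, y, sep = "\r")
      for (pass in seq_len(200L * length(newB))) {
        dup <- which(duplicated(keyOf(a, newB)))
        if (!length(dup)) break
        i <- dup[1L]
        j <- sample.int(length(newB), 1L)
        tmp <- newB[i]; newB[i] <- newB[j]; newB[j] <- tmp
      }
      if (anyDuplicated(keyOf(a, newB)))
        stop("could not repair duplicate support links after rewiring",
             call. = FALSE)
      SupportMap(a, newB)
    }
  })
}

#' Inject edge noise
#'
#' Removes `floor(removeFraction * |E|)` uniformly chosen edges and adds
#' `floor(addFraction * |E|)` uniformly chosen absent pairs (no
#' self-loops or duplicates), emulating false-negative/false-positive
#' interaction calls.
#'
#' @param layer a [Layer-class].
#' @param addFraction,removeFraction fractions in `[0, 0.5]` of the
#'   original edge count.
#' @param seed RNG seed.
#' @return the perturbed [Layer-class].
#' @export
injectNoise <- function(layer, addFraction = 0, removeFraction = 0,
                        seed = 1L) {
  stopifnot(addFraction >= 0, addFraction <= 0.5,
            removeFraction >= 0, removeFraction <= 0.5)
  nodes <- layer@nodes
  e <- layer@edges
  m0 <- nrow(e)
  nRemove <- floor(removeFraction * m0)
  nAdd <- floor(addFraction * m0)
  n <- length(nodes)
  maxEdges <- if (layer@directed) n * (n - 1) else n * (n - 1) / 2
  if (m0 - nRemove + nAdd > maxEdges)
    stop("graph too dense to add the requested edges", call. = FALSE)
  .withSeed(seed, {
    if (nRemove > 0L) e <- e[-sample.int(m0, nRemove), , drop = FALSE]
    if (nAdd > 0L) {
      have <- new.env(hash = TRUE, parent = emptyenv())
      mk <- function(x, y) if (layer@directed) paste(x, y, sep = "\r")
                           else .edgeKey(x, y)
      for (i in seq_len(nrow(e))) assign(mk(e[i, 1L], e[i, 2L]), TRUE, have)
      added <- 0L
      while (added < nAdd) {
        cand <- nodes[sample.int(n, 2L)]
        k <- mk(cand[1L], cand[2L])
        if (exists(k, envir = have)) next
        assign(k, TRUE, have)
        e <- rbind(e, cand)
        added <- added + 1L
      }
    }
  })
  Layer(layer@name, e, directed = layer@directed, nodes = nodes)
}

#' Apply a rewiring specification to a network
#'
#' @param net a [MultilayerNetwork-class].
#' @param spec a [RewireSpec-class].
#' @return the rewired [MultilayerNetwork-class].
#' @export
applyRewire <- function(net, spec) {
  stopifnot(is(spec, "RewireSpec"))
  validObject(spec)
  nSteps <- if (is.na(spec@nSteps)) NULL else spec@nSteps
  undirDeg <- function(l) {
    d <- tabulate(factor(c(l@edges[, 1L], l@edges[, 2L]), levels = l@nodes),
                  nbins = length(l@nodes))
    stats::setNames(d, l@nodes)
  }
  grnTotDeg <- function(l) {
    d <- tabulate(factor(c(l@edges[, 1L], l@edges[, 2L]), levels = l@nodes),
                  nbins = length(l@nodes))
    stats::setNames(d, l@nodes)
  }
  switch(spec@target,
    ppi = MultilayerNetwork(net@grn,
                            doubleEdgeSwap(net@ppi, spec@mode, nSteps,
                                           spec@seed),
                            net@met, net@gp, net@pm),
    met = MultilayerNetwork(net@grn, net@ppi,
                            doubleEdgeSwap(net@met, spec@mode, nSteps,
                                           spec@seed),
                            net@gp, net@pm),
    grn_inout = MultilayerNetwork(grnInOutRewire(net@grn, spec@mode, nSteps,
                                                 spec@seed),
                                  net@ppi, net@met, net@gp, net@pm),
    gp_links = MultilayerNetwork(net@grn, net@ppi, net@met,
                                 interlayerRewire(net@gp, spec@mode,
                                                  grnTotDeg(net@grn),
                                                  undirDeg(net@ppi),
                                                  spec@seed),
                                 net@pm),
    pm_links = MultilayerNetwork(net@grn, net@ppi, net@met, net@gp,
                                 interlayerRewire(net@pm, spec@mode,
                                                  undirDeg(net@ppi),
                                                  undirDeg(net@met),
                                                  spec@seed)))
}

#' Robustness comparison against randomized null models
#'
#' Computes per-layer robustness integrals R for the real network and
#' for each rewired version, with Monte-Carlo standard errors from the
#' per-replicate integrals, and reports Delta R = R(real) - R(random).
#'
#' @param net a [MultilayerNetwork-class].
#' @param specs list of [RewireSpec-class] objects.
#' @param pGrid survival-probability grid.
#' @param replicates removal draws per p.
#' @param fP2M metabolite threshold.
#' @param seed RNG seed for the removal draws.
#' @return data.frame with one row per spec and layer: `target`, `mode`,
#'   `layer`, `Rreal`, `Rrand`, `deltaR`, `se`.
#' @export
compareRobustness <- function(net, specs, pGrid = seq(0, 1, by = 0.1),
                              replicates = 10L, fP2M = 1, seed = 1L) {
  real <- robustnessCurve(net, pGrid, replicates, fP2M, seed)
  rows <- list()
  for (spec in specs) {
    rnet <- applyRewire(net, spec)
    rand <- robustnessCurve(rnet, pGrid, replicates, fP2M, seed)
    for (layer in c("G", "P", "M")) {
      seReal <- stats::sd(real@repR[[layer]]) / sqrt(replicates)
      seRand <- stats::sd(rand@repR[[layer]]) / sqrt(replicates)
      rows[[length(rows) + 1L]] <- data.frame(
        target = spec@target, mode = spec@mode, layer = layer,
        Rreal = real@R[[layer]], Rrand = rand@R[[layer]],
        deltaR = real@R[[layer]] - rand@R[[layer]],
        se = sqrt(seReal^2 + seRand^2))
    }
  }
  do.call(rbind, rows)
}
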