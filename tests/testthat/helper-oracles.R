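# Independent oracles and small fixtures shared across the test files.
# These deliberately avoid the package's engine code paths: set/loop
# implementations whose correctness is obvious by inspection.

# small ER multilayer used by many property tests
smallEr <- function(seed, nG = 40, nP = 40, nM = 15, cG = 2, cP = 3,
                    cM = 2.5, qG = 0.8, qP = 0.8, cS = 2) {
  generateERMultilayer(erBenchmarkSpec(nG = nG, nP = nP, nM = nM, cG = cG,
                                       cP = cP, cM = cM, qG = qG, qP = qP,
                                       cS = cS, seed = seed))
}

# brute-force connected components by label propagation over an edge list
bruteComponents <- function(nodes, edges) {
  comp <- stats::setNames(seq_along(nodes), nodes)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1L]; b <- edges[i, 2L]
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[a] <- m; comp[b] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(nodes, comp[nodes])
}

bruteLargest <- function(nodes, edges) {
  if (!length(nodes)) return(character(0))
  keep <- edges[edges[, 1L] %in% nodes & edges[, 2L] %in% nodes, ,
                drop = FALSE]
  comps <- bruteComponents(nodes, keep)
  sizes <- lengths(comps)
  sort(unlist(comps[sizes == max(sizes)], use.names = FALSE))
}

# Slow reference implementation of the full coupled cascade, written with
# named sets and per-round loops; deterministic (f = 1, full coupling).
naiveCascade <- function(net, seeds, fP2M = 1) {
  grnE <- layerEdges(grnLayer(net)); genes <- layerNodes(grnLayer(net))
  ppiE <- layerEdges(ppiLayer(net)); prots <- layerNodes(ppiLayer(net))
  metE <- layerEdges(metLayer(net)); mets <- layerNodes(metLayer(net))
  gp <- geneProteinMap(net); pm <- proteinMetaboliteMap(net)
  pOfG <- stats::setNames(gp@protein, gp@gene)
  gOfP <- stats::setNames(gp@gene, gp@protein)
  aliveG <- stats::setNames(rep(TRUE, length(genes)), genes)
  aliveP <- stats::setNames(rep(TRUE, length(prots)), prots)
  seeds <- intersect(seeds, genes)
  aliveG[seeds] <- FALSE
  sources <- seeds
  first <- TRUE
  repeat {
    newG <- if (first) seeds else character(0)
    tg <- unique(grnE[grnE[, 1L] %in% sources, 2L])
    tg <- tg[aliveG[tg]]
    aliveG[tg] <- FALSE; newG <- c(newG, tg)
    av <- names(aliveG)[aliveG]
    keepE <- grnE[grnE[, 1L] %in% av & grnE[, 2L] %in% av, , drop = FALSE]
    deg <- table(factor(c(keepE[, 1L], keepE[, 2L]), levels = av))
    iso <- av[deg == 0L]
    aliveG[iso] <- FALSE; newG <- c(newG, iso)
    pk <- pOfG[newG]; pk <- pk[!is.na(pk)]; pk <- pk[aliveP[pk]]
    aliveP[pk] <- FALSE
    av <- names(aliveP)[aliveP]
    keep <- bruteLargest(av, ppiE)
    dropP <- setdiff(av, keep)
    aliveP[dropP] <- FALSE
    fb <- gOfP[dropP]; fb <- fb[!is.na(fb)]; fb <- fb[aliveG[fb]]
    aliveG[fb] <- FALSE
    sources <- fb
    first <- FALSE
    if (!(length(newG) || length(pk) || length(dropP) || length(fb))) break
  }
  ks <- table(factor(pm@metabolite, levels = mets))
  failedSup <- table(factor(pm@metabolite[!aliveP[pm@protein]],
                            levels = mets))
  aliveM <- !(ks > 0L & failedSup >= ceiling(fP2M * ks - 1e-9))
  keepM <- bruteLargest(mets[aliveM], metE)
  aliveM <- stats::setNames(mets %in% keepM, mets)
  c(fsG = mean(aliveG), fsP = mean(aliveP), fsM = mean(aliveM))
}

# step-wise average precision computed the obvious way
apOracle <- function(ranked, positives) {
  hits <- 0; s <- 0
  for (i in seq_along(ranked)) {
    if (ranked[i] %in% positives) {
      hits <- hits + 1
      s <- s + hits / i
    }
  }
  s / length(positives)
}

# exact one-sided Mann-Whitney p-value for "x shifted below y" by full
# enumeration of the group assignments; feasible for n + m <= 12. The
# statistic matches R's W = #\{x_i > y_j\} (+ 0.5 per tie); small W
# supports the alternative.
mannWhitneyEnum <- function(x, y) {
  nx <- length(x)
  all <- c(x, y)
  wOf <- function(xs, ys) sum(outer(xs, ys, ">")) +
    0.5 * sum(outer(xs, ys, "=="))
  wObs <- wOf(x, y)
  combs <- utils::combn(length(all), nx)
  w <- apply(combs, 2L, function(ix) wOf(all[ix], all[-ix]))
  mean(w <= wObs)
}

expect_setsEqual <- function(a, b) {
  testthat::expect_identical(sort(unique(a)), sort(unique(b)))
}
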