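#' @include cascade.R
NULL

#' Single-gene influence scores
#'
#' Runs one deterministic single-gene cascade per eligible gene (genes
#' with a protein partner; all others are excluded, so coupled and
#' uncoupled scores are comparable) and scores each gene by the PPI
#' damage it causes: influence = 1 - fsP. The uncoupled score deletes
#' only the partner protein from the isolated PPI network. The
#' second-round column counts genes plus proteins whose failure carries
#' round index 2 in the coupled cascade.
#'
#' @param net a [MultilayerNetwork-class].
#' @param mode restrict the (potentially expensive) coupled pass:
#'   `"both"` (default), `"coupled"`, `"uncoupled"`.
#' @param fP2M metabolite threshold (only affects the reported fsM-based
#'   columns, not the scores).
#' @param grnPropagation passed to the cascade.
#' @return data.frame with columns `gene`, `influence`,
#'   `uncoupledInfluence`, `outDegree`, `secondRound` (NA for columns the
#'   chosen mode does not compute).
#' @export
influenceScores <- function(net, mode = c("both", "coupled", "uncoupled"),
                            fP2M = 1, grnPropagation = "one_hop") {
  mode <- match.arg(mode)
  eng <- .buildEngine(net)
  eligible <- which(!is.na(eng$partner))
  gene <- eng$genes[eligible]
  n <- length(eligible)
  coup <- rep(NA_real_, n); unc <- rep(NA_real_, n)
  second <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    g <- eligible[i]
    if (mode != "uncoupled") {
      r <- .runEngine(eng, g, fP2M = fP2M, grnPropagation = grnPropagation)
      coup[i] <- 1 - r$fsP
      second[i] <- sum(r$gRounds == 2L) + sum(r$pRounds == 2L)
    }
    if (mode != "coupled")
      unc[i] <- 1 - .runUncoupledEngine(eng, eng$partner[g])
  }
  data.frame(gene = gene, influence = coup, uncoupledInfluence = unc,
             outDegree = eng$outDeg[eligible], secondRound = second,
             stringsAsFactors = FALSE)
}

#' Genes/proteins failing in the second cascade round
#'
#' @param net a [MultilayerNetwork-class].
#' @param genes eligible gene ids to perturb one at a time.
#' @param fP2M metabolite threshold.
#' @return named integer vector of second-round failure counts.
#' @export
secondRoundCounts <- function(net, genes, fP2M = 1) {
  eng <- .buildEngine(net)
  idx <- match(genes, eng$genes)
  if (anyNA(idx)) stop("unknown gene id: ", genes[is.na(idx)][1L],
                       call. = FALSE)
  out <- vapply(idx, function(g) {
    r <- .runEngine(eng, g, fP2M = fP2M)
    sum(r$gRounds == 2L) + sum(r$pRounds == 2L)
  }, integer(1L))
  stats::setNames(out, genes)
}

# average precision of one ranking (ids in rank order) against a positive set
.averagePrecision <- function(ranked, positives) {
  hit <- ranked %in% positives
  if (!any(hit)) return(0)
  prec <- cumsum(hit) / seq_along(hit)
  sum(prec[hit]) / length(positives)
}

# one tie-shuffled rank order of names(scores), descending score
.shuffledRanking <- function(scores) {
  jitter <- stats::runif(length(scores))
  names(scores)[order(-scores, jitter)]
}

#' Precision-recall curve and average precision score
#'
#' Ranks genes by descending score, resolving ties by uniform random
#' shuffles within tie groups (`tieShuffles` draws), accumulates
#' precision and recall along the ranking, and averages the precision at
#' each recall level and the average precision score (APS; the sum of
#' precision at each positive hit divided by the number of positives)
#' over shuffles. A band of APS values from uniformly random rankings is
#' returned as the chance baseline.
#'
#' @param scores named numeric vector (names are gene ids).
#' @param positives character vector of positive gene ids; ids not in
#'   `scores` are dropped with a warning.
#' @param tieShuffles,randomBaselines number of tie shuffles / random
#'   rankings.
#' @param seed RNG seed.
#' @return list with `recall` (grid i/|positives|), `precision` (mean
#'   precision at each recall level), `aps`, `tieShuffles`, and
#'   `baselineAps` (vector over random rankings).
#' @export
prCurve <- function(scores, positives, tieShuffles = 100L,
                    randomBaselines = 100L, seed = 1L) {
  if (is.null(names(scores))) stop("scores must be named", call. = FALSE)
  drop <- setdiff(positives, names(scores))
  if (length(drop)) {
    warning(length(drop), " positive id(s) not among scored genes; dropped")
    positives <- setdiff(positives, drop)
  }
  if (!length(positives)) stop("empty positive set", call. = FALSE)
  nPos <- length(positives)
  .withSeed(seed, {
    precMat <- matrix(NA_real_, tieShuffles, nPos)
    aps <- numeric(tieShuffles)
    for (s in seq_len(tieShuffles)) {
      ranked <- .shuffledRanking(scores)
      hit <- ranked %in% positives
      prec <- cumsum(hit) / seq_along(hit)
      precMat[s, ] <- prec[hit]
      aps[s] <- sum(prec[hit]) / nPos
    }
    base <- vapply(seq_len(randomBaselines), function(b) {
      .averagePrecision(sample(names(scores)), positives)
    }, numeric(1L))
    list(recall = seq_len(nPos) / nPos,
         precision = colMeans(precMat),
         aps = mean(aps), tieShuffles = tieShuffles,
         baselineAps = base)
  })
}

#' Positive-gene density among top-ranked genes
#'
#' For each cutoff n, the fraction of positives among the top n genes of
#' a ranking, averaged over uniform tie shuffles, returned for the score
#' ranking and for a comparator ranking (e.g. out-degree).
#'
#' @param scores named numeric vector.
#' @param positives character vector of positive ids.
#' @param comparator named numeric vector for the second ranking
#'   (default: the same names ranked by `scores`' names order is
#'   meaningless, so supply e.g. out-degrees); `NULL` omits it.
#' @param shuffles tie shuffles.
#' @param seed RNG seed.
#' @return data.frame with columns `n`, `density`, and `comparatorDensity`
#'   when a comparator is given.
#' @export
densityVsRank <- function(scores, positives, comparator = NULL,
                          shuffles = 100L, seed = 1L) {
  if (is.null(names(scores))) stop("scores must be named", call. = FALSE)
  densOf <- function(sc) {
    acc <- numeric(length(sc))
    for (s in seq_len(shuffles)) {
      ranked <- .shuffledRanking(sc)
      acc <- acc + cumsum(ranked %in% positives)
    }
    acc / shuffles / seq_along(sc)
  }
  .withSeed(seed, {
    out <- data.frame(n = seq_along(scores), density = densOf(scores))
    if (!is.null(comparator)) out$comparatorDensity <- densOf(comparator)
    out
  })
}

#' Hypergeometric overlap test
#'
#' Upper-tail probability of observing an overlap at least as large as
#' `|top n genes ∩ gene set|` when the gene set is drawn uniformly from
#' the universe.
#'
#' @param topGenes character vector (e.g. top 500 influential genes).
#' @param geneSet character vector.
#' @param universe character vector of all candidate genes.
#' @return list with `overlap`, `expected` and `p`.
#' @export
hypergeometricOverlap <- function(topGenes, geneSet, universe) {
  if (!length(universe)) stop("empty universe", call. = FALSE)
  topGenes <- intersect(topGenes, universe)
  geneSet <- intersect(geneSet, universe)
  k <- length(intersect(topGenes, geneSet))
  N <- length(universe); K <- length(geneSet); n <- length(topGenes)
  list(overlap = k, expected = n * K / N,
       p = stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE))
}

# greedy degree bins: walk the sorted distinct degree values, closing a
# bin once it holds >= minBin distinct values; a short final bin is
# merged into its predecessor
.degreeBins <- function(degrees, minBin = 30L) {
  vals <- sort(unique(degrees))
  if (!length(vals)) stop("no degrees to bin", call. = FALSE)
  nBins <- max(1L, length(vals) %/% minBin)
  binOfVal <- pmin(ceiling(seq_along(vals) / minBin), nBins)
  binOfVal[match(degrees, vals)]
}

#' Degree-matched empirical overlap test
#'
#' Compares the observed overlap between `geneSet` and `topGenes` with a
#' null distribution of overlaps from degree-matched random gene sets:
#' degrees are binned greedily so that each bin spans at least `minBin`
#' distinct degree values, and each gene in the set is replaced by a
#' uniform draw from its bin (without replacement within a bin). The
#' empirical p-value uses the +1 correction,
#' p = (1 + #\{null >= observed\}) / (nSets + 1).
#'
#' @param geneSet character vector to randomize.
#' @param topGenes reference set the overlap is measured against.
#' @param degrees named integer/numeric vector over the universe (e.g.
#'   GRN total degree).
#' @param nSets number of random sets (> 0).
#' @param minBin minimum distinct degree values per bin.
#' @param seed RNG seed.
#' @return list with `overlap`, `null` (vector) and `p`.
#' @export
degreeMatchedNullOverlap <- function(geneSet, topGenes, degrees,
                                     nSets = 10000L, minBin = 30L,
                                     seed = 1L) {
  if (nSets < 1L) stop("nSets must be >= 1", call. = FALSE)
  if (is.null(names(degrees))) stop("degrees must be named", call. = FALSE)
  universe <- names(degrees)
  geneSet <- intersect(geneSet, universe)
  if (!length(geneSet)) stop("gene set is empty within the universe",
                             call. = FALSE)
  bins <- .degreeBins(degrees, minBin)
  names(bins) <- universe
  byBin <- split(universe, bins)
  setBinCount <- table(bins[geneSet])
  obs <- length(intersect(geneSet, topGenes))
  .withSeed(seed, {
    null <- vapply(seq_len(nSets), function(s) {
      draw <- unlist(lapply(names(setBinCount), function(b) {
        pool <- byBin[[b]]
        sample(pool, min(setBinCount[[b]], length(pool)))
      }), use.names = FALSE)
      length(intersect(draw, topGenes))
    }, numeric(1L))
    list(overlap = obs, null = null,
         p = (1 + sum(null >= obs)) / (nSets + 1))
  })
}

#' Targeted vs degree-matched random metabolic damage
#'
#' For each combination of perturbed fraction `ps` and threshold `fP2M`,
#' draws `reps` targeted perturbations (a uniform fraction ps of the
#' disease genes) and `reps` degree-matched random control sets of the
#' same size (resampled within greedy degree bins; `matchDegree` chooses
#' GRN total degree or out-degree), runs the coupled cascade for each,
#' and tests targeted < random damage on the final metabolic fraction
#' with a one-sided Mann-Whitney test.
#'
#' @param net a [MultilayerNetwork-class].
#' @param diseaseGenes character vector of GRN gene ids.
#' @param psGrid perturbed fractions in `(0, 1]`.
#' @param fP2MGrid thresholds in `[0, 1]`.
#' @param reps draws per condition.
#' @param matchDegree `"total"` or `"out"`.
#' @param minBin degree-bin width (distinct values).
#' @param seed RNG seed.
#' @return data.frame with one row per condition: `ps`, `fP2M`,
#'   `targetedMean`, `randomMean`, `p` (Mann-Whitney, alternative
#'   targeted < random).
#' @export
targetedDamage <- function(net, diseaseGenes, psGrid = 1,
                           fP2MGrid = 1, reps = 1000L,
                           matchDegree = c("total", "out"), minBin = 30L,
                           seed = 1L) {
  matchDegree <- match.arg(matchDegree)
  if (!length(diseaseGenes)) stop("empty gene set", call. = FALSE)
  eng <- .buildEngine(net)
  dIdx <- match(diseaseGenes, eng$genes)
  if (anyNA(dIdx)) stop("unknown gene id: ", diseaseGenes[is.na(dIdx)][1L],
                        call. = FALSE)
  deg <- if (matchDegree == "total") eng$degG else eng$outDeg
  bins <- .degreeBins(deg, minBin)
  byBin <- split(seq_len(eng$nG), bins)
  setBinCount <- table(bins[dIdx])
  drawMatched <- function() {
    unlist(lapply(names(setBinCount), function(b) {
      pool <- byBin[[b]]
      pool[sample.int(length(pool), min(setBinCount[[b]], length(pool)))]
    }), use.names = FALSE)
  }
  rows <- list()
  cond <- 0L
  for (ps in psGrid) for (f2 in fP2MGrid) {
    cond <- cond + 1L
    nSeed <- max(1L, round(ps * length(dIdx)))
    tVals <- numeric(reps); rVals <- numeric(reps)
    for (r in seq_len(reps)) {
      .withSeed(.deriveSeed(seed, cond * 100000L + r), {
        tSeed <- dIdx[sample.int(length(dIdx), nSeed)]
        ctrl <- drawMatched()
        rSeed <- ctrl[sample.int(length(ctrl), min(nSeed, length(ctrl)))]
        tVals[r] <- .runEngine(eng, tSeed, fP2M = f2)$fsM
        rVals[r] <- .runEngine(eng, rSeed, fP2M = f2)$fsM
      })
    }
    # ties are expected (identical fsM values across draws); the normal
    # approximation with tie correction is the intended path there
    p <- suppressWarnings(stats::wilcox.test(tVals, rVals,
                                             alternative = "less")$p.value)
    rows[[length(rows) + 1L]] <- data.frame(
      ps = ps, fP2M = f2, targetedMean = mean(tVals),
      randomMean = mean(rVals), p = p)
  }
  do.call(rbind, rows)
}
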