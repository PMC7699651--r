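#' @include netmodel.R
NULL

#' Default Erdos-Renyi benchmark specification
#'
#' The canonical three-layer synthetic benchmark: ER layers of 5000 genes
#' (directed, mean in = out degree 2), 5000 proteins (mean degree 8) and
#' 1000 metabolites (mean degree 4), coupling strengths qG = qP = 0.8
#' realized as a random one-to-one matching, and Poisson(3) support
#' degrees. All fields can be overridden.
#'
#' @param nG,nP,nM layer sizes.
#' @param cG,cP,cM mean degrees.
#' @param qG,qP coupling strengths in `[0, 1]`.
#' @param cS mean support degree.
#' @param seed RNG seed.
#' @return named list understood by [generateERMultilayer()].
#' @export
erBenchmarkSpec <- function(nG = 5000L, nP = 5000L, nM = 1000L,
                            cG = 2, cP = 8, cM = 4, qG = 0.8, qP = 0.8,
                            cS = 3, seed = 1L) {
  stopifnot(nG >= 1L, nP >= 1L, nM >= 1L, cG >= 0, cP >= 0, cM >= 0, cS >= 0)
  .assertScalar01(qG, "qG"); .assertScalar01(qP, "qP")
  list(nG = as.integer(nG), nP = as.integer(nP), nM = as.integer(nM),
       cG = cG, cP = cP, cM = cM, qG = qG, qP = qP, cS = cS,
       seed = as.integer(seed))
}

# sample m distinct ordered (directed) or unordered (undirected) pairs
# among n nodes, uniformly, as a 2-column integer matrix
.samplePairs <- function(n, m, directed) {
  nPairs <- if (directed) as.double(n) * (n - 1) else as.double(n) * (n - 1) / 2
  m <- min(m, nPairs)
  idx <- sample(nPairs, m)
  if (directed) {
    i <- floor((idx - 1) / (n - 1)) + 1
    j <- (idx - 1) %% (n - 1) + 1
    j <- ifelse(j >= i, j + 1, j)  # skip the diagonal
  } else {
    # map linear index over the strict lower triangle, column-major
    i <- ceiling((sqrt(8 * idx + 1) - 1) / 2) + 1
    j <- idx - (i - 1) * (i - 2) / 2
  }
  cbind(as.integer(i), as.integer(j))
}

#' Generate a three-layer Erdos-Renyi multilayer network
#'
#' GRN: directed G(n, cG/n) over ordered pairs (in- and out-degrees
#' independently ~ Poisson(cG)); PPI and metabolic layers: undirected ER.
#' The gene-protein map is a uniform one-to-one matching covering
#' `round(qG * nG)` genes and `round(qP * nP)` proteins (reconciled to
#' the smaller count). Each metabolite draws k_s ~ Poisson(cS) and
#' attaches to that many distinct uniform proteins. Same seed, same
#' network.
#'
#' @param spec a list from [erBenchmarkSpec()].
#' @param seed overrides `spec$seed` when given.
#' @return a [MultilayerNetwork-class].
#' @export
generateERMultilayer <- function(spec = erBenchmarkSpec(), seed = NULL) {
  if (is.null(seed)) seed <- spec$seed
  .withSeed(seed, {
    nG <- spec$nG; nP <- spec$nP; nM <- spec$nM
    genes <- sprintf("g%d", seq_len(nG))
    prots <- sprintf("p%d", seq_len(nP))
    mets <- sprintf("m%d", seq_len(nM))
    mk <- function(n, c, directed, ids, name) {
      nPairs <- if (directed) as.double(n) * (n - 1)
                else as.double(n) * (n - 1) / 2
      prob <- if (directed) c / n else c / (n - 1)
      m <- stats::rbinom(1L, size = min(nPairs, .Machine$integer.max),
                         prob = min(1, prob))
      e <- .samplePairs(n, m, directed)
      Layer(name, cbind(ids[e[, 1L]], ids[e[, 2L]]), directed = directed,
            nodes = ids)
    }
    grn <- mk(nG, spec$cG, TRUE, genes, "grn")
    ppi <- mk(nP, spec$cP, FALSE, prots, "ppi")
    met <- mk(nM, spec$cM, FALSE, mets, "met")
    nPairs <- min(round(spec$qG * nG), round(spec$qP * nP))
    gp <- InterdependencyMap(sample(genes, nPairs), sample(prots, nPairs))
    ks <- pmin(stats::rpois(nM, spec$cS), nP)
    pmP <- character(0); pmM <- character(0)
    for (i in which(ks > 0L)) {
      pmP <- c(pmP, sample(prots, ks[i]))
      pmM <- c(pmM, rep(mets[i], ks[i]))
    }
    MultilayerNetwork(grn, ppi, met, gp = gp,
                      pm = SupportMap(pmP, pmM))
  })
}

#' Hand-traceable toy fixtures
#'
#' `"T1"`: 4 genes (g1->g2, g1->g3, g4->g3), 5 proteins
#' (p1-p2, p2-p3, p3-p4, p4-p5, p2-p4), pairs g1:p1 .. g4:p4, metabolites
#' m1-m2-m3 with supports p2,p4 -> m1; p3 -> m2; p5 -> m3. Every cascade
#' quantity on T1 can be traced by hand. `"T2"` extends T1 with the pair
#' g5:p5 and the edge g5->g2, creating a genuine second-round failure
#' chain (losing p5 kills g5, whose target g2 falls one round later).
#'
#' @param name `"T1"` or `"T2"`.
#' @return a [MultilayerNetwork-class].
#' @export
toyFixture <- function(name = c("T1", "T2")) {
  name <- match.arg(name)
  grnE <- rbind(c("g1", "g2"), c("g1", "g3"), c("g4", "g3"))
  gpG <- c("g1", "g2", "g3", "g4")
  gpP <- c("p1", "p2", "p3", "p4")
  if (name == "T2") {
    grnE <- rbind(grnE, c("g5", "g2"))
    gpG <- c(gpG, "g5")
    gpP <- c(gpP, "p5")
  }
  grn <- Layer("grn", grnE, directed = TRUE)
  ppi <- Layer("ppi", rbind(c("p1", "p2"), c("p2", "p3"), c("p3", "p4"),
                            c("p4", "p5"), c("p2", "p4")), directed = FALSE)
  met <- Layer("met", rbind(c("m1", "m2"), c("m2", "m3")), directed = FALSE)
  MultilayerNetwork(grn, ppi, met,
                    gp = InterdependencyMap(gpG, gpP),
                    pm = SupportMap(c("p2", "p4", "p3", "p5"),
                                    c("m1", "m1", "m2", "m3")))
}

#' Planted positive gene sets
#'
#' Test stand-ins for curated essential/cancer gene lists. With
#' `placement = "high_coupling"` the k eligible genes maximizing
#' out-degree x paired-protein PPI degree are returned (these dominate
#' the coupled cascade); `"random"` draws k eligible genes uniformly.
#' Only genes with a protein partner are eligible.
#'
#' @param net a [MultilayerNetwork-class].
#' @param k set size.
#' @param placement `"high_coupling"` or `"random"`.
#' @param seed RNG seed (used for `"random"` and to break score ties).
#' @return character vector of gene ids.
#' @export
generatePlantedPositives <- function(net, k,
                                     placement = c("high_coupling", "random"),
                                     seed = 1L) {
  placement <- match.arg(placement)
  eligible <- net@gp@gene
  if (k > length(eligible)) stop("k exceeds the number of eligible genes",
                                 call. = FALSE)
  if (placement == "random")
    return(.withSeed(seed, sample(eligible, k)))
  outDeg <- tabulate(factor(net@grn@edges[, 1L], levels = net@grn@nodes),
                     nbins = length(net@grn@nodes))
  names(outDeg) <- net@grn@nodes
  pDeg <- tabulate(factor(c(net@ppi@edges[, 1L], net@ppi@edges[, 2L]),
                          levels = net@ppi@nodes),
                   nbins = length(net@ppi@nodes))
  names(pDeg) <- net@ppi@nodes
  score <- outDeg[eligible] * pDeg[net@gp@protein]
  ord <- order(-score, eligible)  # deterministic tie-break by id
  eligible[ord[seq_len(k)]]
}

#' Planted disease gene set
#'
#' Test stand-in for a GWAS-derived disease gene list: the genes whose
#' paired proteins support the given target metabolites. Perturbing the
#' full set knocks out every support with a paired gene, so the target
#' metabolites fail whenever enough of their supports are gene-paired.
#'
#' @param net a [MultilayerNetwork-class].
#' @param targetMetabolites character vector of metabolite ids.
#' @param seed unused randomness hook kept for interface symmetry.
#' @return character vector of gene ids (empty for empty targets).
#' @export
generatePlantedDiseaseSet <- function(net, targetMetabolites, seed = 1L) {
  if (!length(targetMetabolites)) return(character(0))
  bad <- setdiff(targetMetabolites, net@met@nodes)
  if (length(bad)) stop("unknown metabolite id: ", bad[1L], call. = FALSE)
  sup <- net@pm@protein[net@pm@metabolite %in% targetMetabolites]
  genes <- net@gp@gene[match(unique(sup), net@gp@protein)]
  genes <- sort(unique(genes[!is.na(genes)]))
  if (!length(genes))
    stop("no paired genes support the target metabolites", call. = FALSE)
  genes
}
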