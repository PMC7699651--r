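#' @include netmodel.R
NULL

# Internal integer-indexed simulation engine. Built once per network and
# reused across runs (robustness curves, influence scores, damage scans);
# all hot-path state is plain vectors plus two igraph objects for the
# undirected LCC steps.
.buildEngine <- function(net) {
  grn <- net@grn; ppi <- net@ppi; met <- net@met
  genes <- grn@nodes; proteins <- ppi@nodes; mets <- met@nodes
  nG <- length(genes); nP <- length(proteins); nM <- length(mets)
  ge <- grn@edges
  src <- match(ge[, 1L], genes); tgt <- match(ge[, 2L], genes)
  outAdj <- unname(split(tgt, factor(src, levels = seq_len(nG))))
  inAdj <- unname(split(src, factor(tgt, levels = seq_len(nG))))
  partner <- rep(NA_integer_, nG)
  geneOf <- rep(NA_integer_, nP)
  if (length(net@gp@gene)) {
    gi <- match(net@gp@gene, genes); pi <- match(net@gp@protein, proteins)
    partner[gi] <- pi
    geneOf[pi] <- gi
  }
  supProt <- match(net@pm@protein, proteins)
  supMet <- match(net@pm@metabolite, mets)
  list(nG = nG, nP = nP, nM = nM,
       genes = genes, proteins = proteins, mets = mets,
       outAdj = outAdj, inAdj = inAdj,
       degG = lengths(outAdj) + lengths(inAdj),
       outDeg = lengths(outAdj),
       ppiIg = .layerIgraph(ppi), metIg = .layerIgraph(met),
       partner = partner, geneOf = geneOf,
       supProt = supProt, supMet = supMet,
       ks = tabulate(supMet, nbins = nM))
}

# indices (into aliveIdx's values) of nodes in all maximum-size
# components; attr "tie" flags several components sharing the maximum
# (the inclusive rule keeps them all)
.lccKeep <- function(ig, aliveIdx) {
  if (!length(aliveIdx)) return(structure(integer(0), tie = FALSE))
  sub <- igraph::induced_subgraph(ig, aliveIdx)
  cm <- igraph::components(sub)
  top <- which(cm$csize == max(cm$csize))
  structure(aliveIdx[cm$membership %in% top], tie = length(top) > 1L)
}

# One coupled cascade. seedIdx: integer gene indices perturbed at t = 1.
# Uses the current RNG stream (callers wrap in .withSeed as needed).
.runEngine <- function(eng, seedIdx, fP2M = 1,
                       grnPropagation = c("one_hop", "recursive"),
                       targetFraction = 1, couplingRetention = 1) {
  grnPropagation <- match.arg(grnPropagation)
  nG <- eng$nG; nP <- eng$nP; nM <- eng$nM
  aliveG <- rep(TRUE, nG); aliveP <- rep(TRUE, nP)
  gRounds <- integer(nG); pRounds <- integer(nP)
  curDeg <- eng$degG
  pairActive <- !is.na(eng$partner)
  if (couplingRetention < 1) {
    paired <- which(pairActive)
    nSever <- round((1 - couplingRetention) * length(paired))
    if (nSever > 0L)
      pairActive[paired[sample.int(length(paired), nSever)]] <- FALSE
  }
  seedIdx <- unique(as.integer(seedIdx))
  isSeed <- rep(FALSE, nG); isSeed[seedIdx] <- TRUE

  killGene <- function(idx) {
    idx <- idx[aliveG[idx]]
    if (length(idx)) {
      aliveG[idx] <<- FALSE
      nb <- c(unlist(eng$outAdj[idx], use.names = FALSE),
              unlist(eng$inAdj[idx], use.names = FALSE))
      if (length(nb)) curDeg <<- curDeg - tabulate(nb, nbins = nG)
    }
    idx
  }

  sources <- integer(0)
  tieSeen <- FALSE
  t <- 0L
  repeat {
    t <- t + 1L
    newGene <- integer(0)
    if (t == 1L && length(seedIdx)) {
      s <- killGene(seedIdx)
      gRounds[s] <- 1L
      newGene <- s
      sources <- s
    }
    # (i) GRN step: failing genes drag down (a fraction of) their targets;
    # in recursive mode target failure iterates to a fixed point.
    prop <- sources
    repeat {
      if (length(prop)) {
        cand <- unlist(lapply(prop, function(g) {
          nb <- eng$outAdj[[g]]
          nb <- nb[aliveG[nb]]
          if (targetFraction < 1 && length(nb))
            nb <- nb[stats::runif(length(nb)) < targetFraction]
          nb
        }), use.names = FALSE)
        cand <- unique(cand)
      } else cand <- integer(0)
      killed <- killGene(cand)
      if (length(killed)) {
        gRounds[killed] <- t
        newGene <- c(newGene, killed)
      }
      if (grnPropagation != "recursive" || !length(killed)) break
      prop <- killed
    }
    # genes left with zero remaining regulatory degree are non-functional
    iso <- which(aliveG & curDeg == 0L)
    if (length(iso)) {
      killGene(iso)
      gRounds[iso] <- t
      newGene <- c(newGene, iso)
    }
    # (ii) proteins paired to genes that failed this round
    act <- pairActive[newGene] | isSeed[newGene]
    pk <- eng$partner[newGene[act]]
    pk <- pk[!is.na(pk)]
    pk <- unique(pk[aliveP[pk]])
    if (length(pk)) {
      aliveP[pk] <- FALSE
      pRounds[pk] <- t
    }
    # (iii) proteins disconnected from the PPI largest component(s) fail
    ap <- which(aliveP)
    keep <- .lccKeep(eng$ppiIg, ap)
    tieSeen <- tieSeen || attr(keep, "tie")
    dropP <- if (length(ap)) ap[!ap %in% keep] else integer(0)
    if (length(dropP)) {
      aliveP[dropP] <- FALSE
      pRounds[dropP] <- t
    }
    # (iv) genes paired to disconnection-failed proteins fail and seed the
    # next round's GRN step
    fb <- eng$geneOf[dropP]
    fb <- fb[!is.na(fb)]
    fb <- fb[pairActive[fb] & aliveG[fb]]
    fb <- killGene(fb)
    if (length(fb)) gRounds[fb] <- t
    sources <- fb
    if (!(length(newGene) || length(pk) || length(dropP) || length(fb))) {
      t <- t - 1L
      break
    }
    if (t > nG + nP + 2L) break # unreachable; guards against cycles
  }
  rounds <- max(1L, t)

  # metabolic stage: applied once after GRN/PPI convergence (no feedback)
  if (length(eng$supMet)) {
    failedSup <- tabulate(eng$supMet[!aliveP[eng$supProt]], nbins = nM)
  } else failedSup <- integer(nM)
  thr <- .ceilFrac(fP2M, eng$ks)
  aliveM <- !(eng$ks > 0L & failedSup >= thr)
  am <- which(aliveM)
  keepM <- .lccKeep(eng$metIg, am)
  tieSeen <- tieSeen || attr(keepM, "tie")
  if (length(am)) aliveM[am[!am %in% keepM]] <- FALSE
  mRounds <- integer(nM)
  mRounds[!aliveM] <- rounds

  list(aliveG = aliveG, aliveP = aliveP, aliveM = aliveM,
       gRounds = gRounds, pRounds = pRounds, mRounds = mRounds,
       rounds = rounds, lccTies = tieSeen,
       fsG = sum(aliveG) / nG, fsP = sum(aliveP) / nP,
       fsM = sum(aliveM) / nM)
}

# PPI-only control: delete the given proteins, keep the largest
# component(s). Returns the functional fraction.
.runUncoupledEngine <- function(eng, removedIdx) {
  alive <- rep(TRUE, eng$nP)
  alive[removedIdx] <- FALSE
  keep <- .lccKeep(eng$ppiIg, which(alive))
  length(keep) / eng$nP
}
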