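#' @include netmodel.R
NULL

#' Generating functions
#'
#' `GeneratingFunction(pmf)` wraps a degree pmf (element `i` =
#' P(degree = i - 1)). `gfEval` evaluates G(x) = sum_k P(k) x^k and
#' `gfBranch` the branching (excess-degree) function
#' H(x) = G'(x)/G'(1).
#'
#' @param pmf non-negative numeric vector summing to one.
#' @param gf a [GeneratingFunction-class].
#' @param x evaluation points in `[0, 1]` (vectorized).
#' @return `GeneratingFunction()`: the object; `gfEval`/`gfBranch`:
#'   numeric values.
#' @examples
#' gf <- GeneratingFunction(c(0, 0, 1))   # all nodes have degree 2
#' gfEval(gf, 0.5)                        # 0.25
#' @name gfEval
#' @export
GeneratingFunction <- function(pmf) {
  new("GeneratingFunction", pmf = as.numeric(pmf))
}

#' Truncated, renormalized Poisson degree pmf
#'
#' Convenience builder for ER-style layers: `dpois(0:kMax, lambda)`
#' renormalized to sum to one.
#'
#' @param lambda mean degree.
#' @param kMax truncation degree (default covers the mass to ~1e-16).
#' @export
poissonPmf <- function(lambda, kMax = max(30L, ceiling(lambda + 12 * sqrt(lambda + 1)))) {
  p <- stats::dpois(0:kMax, lambda)
  p / sum(p)
}

#' @rdname gfEval
setMethod("gfEval", "GeneratingFunction", function(gf, x) {
  k <- seq_along(gf@pmf) - 1L
  vapply(x, function(xx) sum(gf@pmf * xx^k), numeric(1L))
})

#' @rdname gfEval
setMethod("gfBranch", "GeneratingFunction", function(gf, x) {
  k <- seq_along(gf@pmf) - 1L
  mu <- sum(k * gf@pmf)
  if (mu == 0) stop("degenerate pmf: mean degree is zero", call. = FALSE)
  vapply(x, function(xx) sum(k * gf@pmf * xx^pmax(k - 1L, 0L) * (k > 0L)) / mu,
         numeric(1L))
})

setMethod("show", "GeneratingFunction", function(object) {
  k <- seq_along(object@pmf) - 1L
  cat(sprintf("GeneratingFunction over degrees 0..%d (mean %.4g)\n",
              max(k), sum(k * object@pmf)))
})

.checkJoint <- function(joint) {
  stopifnot(is.data.frame(joint),
            all(c("kIn", "kOut", "prob") %in% names(joint)))
  if (abs(sum(joint$prob) - 1) > 1e-9)
    stop("joint pmf must sum to 1", call. = FALSE)
  invisible(joint)
}

#' Gene-layer percolation quantities
#'
#' For a random removal of a 1 - p fraction of genes in a directed
#' regulatory network with joint in/out degree pmf P(k_in, k_out):
#'
#' * `rS(p, joint)` is the fraction of genes that are neither perturbed
#'   nor the target of a perturbed regulator,
#'   sum P(k_in, k_out) p^(k_in + 1).
#' * `remainingJoint(joint, rS)` is the degree pmf of the remaining
#'   network under binomial thinning of both margins at rate rS
#'   (in/out independence assumed).
#' * `fsGene(p, joint)` is the functional fraction after the isolates of
#'   the remaining network fail: rS * (1 - sum P(i, j) (1 - rS)^(i + j)).
#' * `hGene(p, joint)` is the functional fraction per remaining node,
#'   rS / p * (1 - P^(rS)(0, 0)); undefined at p = 0.
#'
#' @param p gene survival probability in `[0, 1]` (`(0, 1]` for
#'   `hGene`).
#' @param joint data.frame with columns `kIn`, `kOut`, `prob` (see
#'   [degreeDistributions()]).
#' @param rs thinning rate in `[0, 1]`.
#' @return numeric scalar (`rS`, `fsGene`, `hGene`) or a joint pmf
#'   data.frame (`remainingJoint`).
#' @export
rS <- function(p, joint) {
  .assertScalar01(p, "p")
  .checkJoint(joint)
  p * sum(joint$prob * p^joint$kIn)
}

# P^(rs)(0,0): probability a remaining gene keeps no in- or out-links
.p00 <- function(joint, rs) {
  sum(joint$prob * (1 - rs)^(joint$kIn + joint$kOut))
}

#' @rdname rS
#' @export
remainingJoint <- function(joint, rs) {
  .assertScalar01(rs, "rs")
  .checkJoint(joint)
  pieces <- lapply(seq_len(nrow(joint)), function(r) {
    i <- joint$kIn[r]; j <- joint$kOut[r]; pr <- joint$prob[r]
    ki <- 0:i; kj <- 0:j
    grid <- expand.grid(kIn = ki, kOut = kj)
    grid$prob <- pr * stats::dbinom(grid$kIn, i, rs) *
      stats::dbinom(grid$kOut, j, rs)
    grid
  })
  all <- do.call(rbind, pieces)
  agg <- stats::aggregate(prob ~ kIn + kOut, data = all, FUN = sum)
  agg <- agg[agg$prob > 0, , drop = FALSE]
  agg <- agg[order(agg$kIn, agg$kOut), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' @rdname rS
#' @export
fsGene <- function(p, joint) {
  rs <- rS(p, joint)
  rs * (1 - .p00(joint, rs))
}

#' @rdname rS
#' @export
hGene <- function(p, joint) {
  if (p <= 0) stop("hGene is undefined at p = 0", call. = FALSE)
  rs <- rS(p, joint)
  rs / p * (1 - .p00(joint, rs))
}

# internal, total-function version used inside the cascade recursion
.hGeneSafe <- function(p, joint) {
  if (p <= 0) return(0)
  hGene(p, joint)
}

#' Giant-component fraction under random node removal
#'
#' Solves the configuration-model self-consistency
#' `x_c = H(p x_c + 1 - p)` for the smallest root (fixed-point iteration
#' from 0; bisection fallback) and returns
#' `h(p) = 1 - G(p x_c + 1 - p)`, the probability that a surviving node
#' belongs to the giant component when each node survives independently
#' with probability p. Below the percolation threshold
#' (`p * H'(1) <= 1`) the result is exactly 0.
#'
#' @param gf a [GeneratingFunction-class] (or bare pmf vector).
#' @param p node survival probability.
#' @param tol fixed-point tolerance.
#' @param maxIter iteration cap before the bisection fallback.
#' @return fraction in `[0, 1]`; attribute `"xc"` carries the root.
#' @export
giantFraction <- function(gf, p, tol = 1e-12, maxIter = 1e5) {
  if (!is(gf, "GeneratingFunction")) gf <- GeneratingFunction(gf)
  .assertScalar01(p, "p")
  k <- seq_along(gf@pmf) - 1L
  mu <- sum(k * gf@pmf)
  if (mu == 0 || p == 0) return(structure(0, xc = 1))
  hp1 <- sum(k * (k - 1L) * gf@pmf) / mu
  if (p * hp1 <= 1) return(structure(0, xc = 1))
  f <- function(x) gfBranch(gf, p * x + 1 - p)
  x <- 0
  for (it in seq_len(maxIter)) {
    xn <- f(x)
    if (abs(xn - x) < tol) {
      x <- xn
      break
    }
    x <- xn
  }
  if (abs(f(x) - x) > sqrt(tol)) {
    # monotone iteration stalled; bisect g(x) = x - H(px + 1 - p) on
    # [x, 1 - eps] for the smallest sign change
    g <- function(z) z - f(z)
    lo <- x; hi <- 1 - 1e-9
    if (g(lo) * g(hi) > 0)
      stop(sprintf("giantFraction did not converge (residual %.3e)",
                   abs(f(x) - x)), call. = FALSE)
    x <- stats::uniroot(g, c(lo, hi), tol = tol)$root
  }
  structure(max(0, 1 - gfEval(gf, p * x + 1 - p)), xc = x)
}

#' Analytical GRN/PPI cascade fixed point
#'
#' Iterates the remaining-size recursion for two partially interdependent
#' layers: `psi'_n = p (1 - qG (1 - hPPI(phi'_{n-1})))` and
#' `phi'_n = 1 - qP (1 - hGene(psi'_n) p)`, starting from `psi'_1 = p`,
#' until successive psi' differ by less than `tol`. The functional sizes
#' are `psi_n = psi'_n hGene(psi'_n)` and `phi_n = phi'_n hPPI(phi'_n)`;
#' the fixed-point values are the predicted final functional fractions of
#' the gene and protein layers.
#'
#' @param p initial gene survival probability.
#' @param qG fraction of genes depending on a protein; `qP` the converse.
#' @param qP see `qG`.
#' @param joint GRN joint degree pmf (data.frame `kIn`, `kOut`, `prob`).
#' @param ppiGf PPI degree [GeneratingFunction-class] (or pmf vector).
#' @param tol convergence tolerance on psi'.
#' @param maxIter stage cap.
#' @return a [TheoryResult-class].
#' @export
cascadeTheory <- function(p, qG, qP, joint, ppiGf, tol = 1e-9,
                          maxIter = 1e4) {
  .assertScalar01(p, "p"); .assertScalar01(qG, "qG"); .assertScalar01(qP, "qP")
  .checkJoint(joint)
  if (!is(ppiGf, "GeneratingFunction")) ppiGf <- GeneratingFunction(ppiGf)
  hP <- function(pp) as.numeric(giantFraction(ppiGf, pp))
  psiP <- p
  phiP <- 1 - qP * (1 - .hGeneSafe(psiP, joint) * p)
  psiSeq <- psiP; phiSeq <- phiP
  converged <- FALSE
  for (n in seq_len(maxIter)) {
    psiN <- p * (1 - qG * (1 - hP(phiP)))
    phiN <- 1 - qP * (1 - .hGeneSafe(psiN, joint) * p)
    psiSeq <- c(psiSeq, psiN); phiSeq <- c(phiSeq, phiN)
    if (abs(psiN - psiP) < tol) {
      psiP <- psiN; phiP <- phiN
      converged <- TRUE
      break
    }
    psiP <- psiN; phiP <- phiN
  }
  if (!converged)
    stop(sprintf("cascade recursion did not converge in %d stages", maxIter),
         call. = FALSE)
  psiFun <- vapply(psiSeq, function(x) x * .hGeneSafe(x, joint), numeric(1L))
  phiFun <- vapply(phiSeq, hP, numeric(1L)) * phiSeq
  new("TheoryResult", p = p, qG = qG, qP = qP,
      psiPrime = psiSeq, psi = psiFun, phiPrime = phiSeq, phi = phiFun,
      fsG = psiFun[length(psiFun)], fsP = phiFun[length(phiFun)],
      converged = converged, iterations = length(psiSeq))
}

setMethod("show", "TheoryResult", function(object) {
  cat(sprintf(
    "TheoryResult: p = %.3g, qG = %.3g, qP = %.3g (%d stages)\n",
    object@p, object@qG, object@qP, object@iterations))
  cat(sprintf("  fsG = %.6g, fsP = %.6g\n", object@fsG, object@fsP))
})

#' Metabolic-layer percolation
#'
#' Given the final functional PPI fraction `phiM`, computes the
#' probability omega that a metabolite loses at least
#' `ceiling(fP2M * k_s)` of its k_s supports,
#' `omega = sum_{k_s >= 1} P_D(k_s) * Binom-tail(k_s, 1 - phiM)`,
#' the remaining fraction `rMeta = 1 - omega`, and the final functional
#' metabolic fraction `fsM = rMeta * h_Meta(rMeta)` via the metabolic
#' layer's giant component. Metabolites with no supports (k_s = 0) never
#' fail through support loss; their weight is what the coupling strength
#' q_Meta removes from omega.
#'
#' @param phiM final functional PPI fraction in `[0, 1]`.
#' @param supportGf support-degree pmf (vector or
#'   [GeneratingFunction-class]); the full pmf including k_s = 0 mass
#'   unless `qMeta` is supplied, in which case it is read as the pmf
#'   conditional on k_s >= 1 and scaled by `qMeta`.
#' @param metGf metabolic-layer degree pmf or generating function.
#' @param fP2M failure threshold in `[0, 1]`.
#' @param qMeta optional explicit coupling strength (see `supportGf`).
#' @return list with elements `omega`, `rMeta`, `fsM`, `xc`.
#' @export
metabolicTheory <- function(phiM, supportGf, metGf, fP2M = 1, qMeta = NULL) {
  .assertScalar01(phiM, "phiM"); .assertScalar01(fP2M, "fP2M")
  pmfD <- if (is(supportGf, "GeneratingFunction")) supportGf@pmf
          else as.numeric(supportGf)
  ks <- seq_along(pmfD) - 1L
  tail <- vapply(ks, function(k) {
    if (k == 0L) return(0)
    lmin <- .ceilFrac(fP2M, k)
    stats::pbinom(lmin - 1L, k, 1 - phiM, lower.tail = FALSE)
  }, numeric(1L))
  if (is.null(qMeta)) {
    omega <- sum(pmfD * tail)
  } else {
    .assertScalar01(qMeta, "qMeta")
    omega <- qMeta * sum(pmfD * tail)
  }
  rMeta <- 1 - omega
  h <- giantFraction(metGf, rMeta)
  list(omega = omega, rMeta = rMeta, fsM = rMeta * as.numeric(h),
       xc = attr(h, "xc"))
}

#' Coupling strengths between layers
#'
#' `method = "naive"` reads the equivalent coupling strengths off the
#' interlayer maps: qG = fraction of GRN genes with a protein partner,
#' qP = fraction of PPI proteins with a gene partner, qMeta = fraction of
#' metabolites with at least one support. `method = "calibrated"` fits
#' (qG, qP) by least squares between the analytical curves and a
#' supplied simulated curve (data.frame with columns `p`, `fsP` and
#' optionally `fsG`), by grid search followed by bounded local
#' refinement; qMeta is always the naive fraction.
#'
#' @param net a [MultilayerNetwork-class].
#' @param method `"naive"` or `"calibrated"`.
#' @param simCurve simulated curve for calibration.
#' @param gridStep coarse grid spacing for the calibration search.
#' @return list with elements `qG`, `qP`, `qMeta` (and `objective` for
#'   the calibrated method).
#' @export
couplingStrengths <- function(net, method = c("naive", "calibrated"),
                              simCurve = NULL, gridStep = 0.1) {
  method <- match.arg(method)
  nG <- length(net@grn@nodes); nP <- length(net@ppi@nodes)
  ks <- supportDegrees(net)
  naive <- list(qG = length(net@gp@gene) / nG,
                qP = length(net@gp@protein) / nP,
                qMeta = mean(ks > 0L))
  if (method == "naive") return(naive)
  if (is.null(simCurve) || !all(c("p", "fsP") %in% names(simCurve)))
    stop("calibration requires simCurve with columns p and fsP",
         call. = FALSE)
  dd <- degreeDistributions(net)
  ppiGf <- GeneratingFunction(dd@ppi)
  useG <- "fsG" %in% names(simCurve)
  obj <- function(q) {
    qg <- q[1L]; qp <- q[2L]
    err <- 0
    for (i in seq_len(nrow(simCurve))) {
      th <- cascadeTheory(simCurve$p[i], qg, qp, dd@grnJoint, ppiGf)
      err <- err + (th@fsP - simCurve$fsP[i])^2
      if (useG) err <- err + (th@fsG - simCurve$fsG[i])^2
    }
    err
  }
  grid <- expand.grid(qG = seq(0, 1, by = gridStep),
                      qP = seq(0, 1, by = gridStep))
  vals <- apply(grid, 1L, obj)
  best <- as.numeric(grid[which.min(vals), ])
  fit <- stats::optim(best, obj, method = "L-BFGS-B", lower = 0, upper = 1,
                      control = list(factr = 1e9))
  list(qG = fit$par[1L], qP = fit$par[2L], qMeta = naive$qMeta,
       objective = fit$value)
}

#' Analytical robustness curve
#'
#' Runs the full theory pipeline for each p: the GRN/PPI cascade fixed
#' point (via [cascadeTheory()]) followed by the metabolic stage (via
#' [metabolicTheory()]), using degree distributions and coupling
#' strengths measured on `net` (or supplied directly).
#'
#' @param net a [MultilayerNetwork-class], or `NULL` when `dists` and
#'   `couplings` are given.
#' @param pGrid survival-probability grid.
#' @param fP2M metabolite failure threshold.
#' @param coupling `"naive"` or a list with `qG`, `qP`, `qMeta`.
#' @param dists optional [DegreeDistributions-class].
#' @return data.frame with columns `p`, `fsG`, `fsP`, `fsM`.
#' @export
theoryCurve <- function(net = NULL, pGrid = seq(0, 1, by = 0.05), fP2M = 1,
                        coupling = "naive", dists = NULL) {
  if (is.null(dists)) dists <- degreeDistributions(net)
  q <- if (is.list(coupling)) coupling
       else couplingStrengths(net, method = coupling)
  ppiGf <- GeneratingFunction(dists@ppi)
  metGf <- GeneratingFunction(dists@met)
  # support pmf conditional on ks >= 1, weighted by qMeta
  supPmf <- dists@support
  out <- lapply(pGrid, function(p) {
    th <- cascadeTheory(p, q$qG, q$qP, dists@grnJoint, ppiGf)
    met <- metabolicTheory(th@fsP, supPmf, metGf, fP2M = fP2M)
    c(p = p, fsG = th@fsG, fsP = th@fsP, fsM = met$fsM)
  })
  as.data.frame(do.call(rbind, out))
}

#' Correlation between two robustness curves
#'
#' Concatenates the per-layer, per-p functional fractions of two curves
#' (matched on `p`) and returns the Pearson correlation, the agreement
#' statistic used to compare theory against simulation.
#'
#' @param curveA,curveB data.frames with columns `p` and at least one of
#'   `fsG`, `fsP`, `fsM`.
#' @param layers layer columns to include.
#' @return Pearson correlation coefficient.
#' @export
theoryVsSim <- function(curveA, curveB, layers = c("fsG", "fsP", "fsM")) {
  layers <- intersect(layers, intersect(names(curveA), names(curveB)))
  m <- merge(curveA[, c("p", layers)], curveB[, c("p", layers)],
             by = "p", suffixes = c(".a", ".b"))
  if (nrow(m) < 3L) stop("need at least 3 matching grid points", call. = FALSE)
  a <- unlist(m[, paste0(layers, ".a")], use.names = FALSE)
  b <- unlist(m[, paste0(layers, ".b")], use.names = FALSE)
  ok <- is.finite(a) & is.finite(b)
  stats::cor(a[ok], b[ok])
}
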