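# joint pmf with independent Poisson margins, truncated + renormalized
poissonJoint <- function(cIn, cOut = cIn, kMax = 30L) {
  g <- expand.grid(kIn = 0:kMax, kOut = 0:kMax)
  g$prob <- stats::dpois(g$kIn, cIn) * stats::dpois(g$kOut, cOut)
  g$prob <- g$prob / sum(g$prob)
  g
}

test_that("rS matches the Poisson closed form and its limits", {
  joint <- poissonJoint(2)
  expect_equal(rS(1, joint), 1, tolerance = 1e-12)
  expect_equal(rS(0, joint), 0, tolerance = 1e-12)
  for (p in c(0.2, 0.5, 0.8))
    expect_equal(rS(p, joint), p * exp(2 * (p - 1)), tolerance = 1e-6)
  # truncated-sum oracle at in-degree Poisson(2), p = 0.5
  oracle <- 0.5 * sum(stats::dpois(0:100, 2) * 0.5^(0:100))
  expect_equal(rS(0.5, joint), oracle, tolerance = 1e-6)
})

test_that("remainingJoint performs exact binomial thinning", {
  j <- data.frame(kIn = 1L, kOut = 1L, prob = 1)
  thin <- remainingJoint(j, 0.5)
  expect_equal(nrow(thin), 4L)
  expect_equal(thin$prob, rep(0.25, 4L))
  expect_equal(remainingJoint(j, 1), j[, c("kIn", "kOut", "prob")],
               ignore_attr = TRUE)
  thin0 <- remainingJoint(j, 0)
  expect_equal(thin0$prob[thin0$kIn == 0 & thin0$kOut == 0], 1)
})

test_that("the isolate-corrected functional size agrees across both routes", {
  set.seed(8)
  for (i in 1:5) {
    # random sparse joint pmf
    j <- expand.grid(kIn = 0:4, kOut = 0:4)
    j$prob <- stats::rexp(nrow(j))
    j$prob <- j$prob / sum(j$prob)
    for (p in c(0.3, 0.7, 1)) {
      rs <- rS(p, j)
      viaThinning <- remainingJoint(j, rs)
      p00 <- viaThinning$prob[viaThinning$kIn == 0 & viaThinning$kOut == 0]
      expect_equal(fsGene(p, j), rs * (1 - p00), tolerance = 1e-10)
      expect_equal(hGene(p, j), fsGene(p, j) / p, tolerance = 1e-12)
    }
  }
  expect_error(hGene(0, poissonJoint(2)), "p = 0")
})

test_that("fsGene matches a Monte-Carlo perturbation of a large ER regulatory layer", {
  # simulation oracle: perturb each gene independently w.p. 1 - p, remove
  # the targets of perturbed genes, fail the isolates of the remainder.
  # The formula assumes a locally tree-like layer with independent edge
  # survival, so the oracle runs on a 2000-node sparse directed ER graph
  # (on a 4-node toy the neighbour-survival correlations it neglects are
  # large and the comparison is not meaningful).
  set.seed(5)
  n <- 2000L; cg <- 2
  m <- stats::rbinom(1L, n * (n - 1L), cg / n)
  idx <- sample(n * (n - 1L), m)
  i <- floor((idx - 1) / (n - 1)) + 1
  j <- (idx - 1) %% (n - 1) + 1
  j <- ifelse(j >= i, j + 1, j)
  tab <- as.data.frame(table(kin = tabulate(j, n), kout = tabulate(i, n)))
  tab <- tab[tab$Freq > 0, ]
  joint <- data.frame(kIn = as.integer(as.character(tab$kin)),
                      kOut = as.integer(as.character(tab$kout)),
                      prob = tab$Freq / n)
  p <- 0.75
  reps <- 200L
  fs <- replicate(reps, {
    kept <- stats::runif(n) < p
    kept[unique(j[!kept[i]])] <- FALSE
    aliveE <- kept[i] & kept[j]
    deg <- tabulate(c(i[aliveE], j[aliveE]), n)
    sum(kept & deg > 0L) / n
  })
  se <- stats::sd(fs) / sqrt(reps)
  expect_lt(abs(fsGene(p, joint) - mean(fs)), 3 * se + 3e-3)
})

test_that("giantFraction solves the Poisson self-consistency equation", {
  gf <- GeneratingFunction(poissonPmf(4))
  u <- stats::uniroot(function(u) u - exp(4 * (u - 1)), c(0, 0.999),
                      tol = 1e-14)$root
  expect_equal(as.numeric(giantFraction(gf, 1)), 1 - u, tolerance = 1e-9)
  # subcritical: effective mean degree 0.8
  expect_identical(as.numeric(giantFraction(gf, 0.2)), 0)
  expect_identical(as.numeric(giantFraction(GeneratingFunction(1), 0.9)), 0)
})

test_that("fixed-point solver agrees with a bisection oracle on random pmfs", {
  set.seed(21)
  for (i in 1:100) {
    if (i %% 2 == 0) {
      gf <- GeneratingFunction(poissonPmf(stats::runif(1, 0.5, 8)))
    } else {
      q <- stats::runif(1, 0.2, 0.7)   # geometric-ish
      pmf <- q * (1 - q)^(0:40)
      gf <- GeneratingFunction(pmf / sum(pmf))
    }
    p <- stats::runif(1)
    h <- giantFraction(gf, p)
    g <- function(x) x - gfBranch(gf, p * x + 1 - p)
    k <- seq_along(gf@pmf) - 1L
    mu <- sum(k * gf@pmf)
    crit <- p * sum(k * (k - 1L) * gf@pmf) / mu
    if (crit <= 1) {
      expect_identical(as.numeric(h), 0)
    } else {
      xBis <- stats::uniroot(g, c(0, 1 - 1e-10), tol = 1e-13)$root
      expect_equal(attr(h, "xc"), xBis, tolerance = 1e-9)
    }
  }
})

test_that("the coupled recursion decouples exactly at qG = qP = 0", {
  joint <- poissonJoint(2)
  gf <- GeneratingFunction(poissonPmf(8))
  for (p in c(0.2, 0.5, 0.9)) {
    th <- cascadeTheory(p, 0, 0, joint, gf)
    expect_true(all(abs(th@psiPrime - p) < 1e-15))
    expect_true(all(abs(th@phiPrime - 1) < 1e-15))
    expect_equal(th@fsG, fsGene(p, joint), tolerance = 1e-14)
    expect_equal(th@fsP, as.numeric(giantFraction(gf, 1)), tolerance = 1e-14)
  }
})

test_that("the recursion is monotone, bounded and baseline-consistent", {
  joint <- poissonJoint(2)
  gf <- GeneratingFunction(poissonPmf(8))
  th <- cascadeTheory(1, 0.8, 0.8, joint, gf)
  expect_true(all(diff(th@psiPrime) <= 1e-12))
  expect_true(all(th@psiPrime >= 0 & th@psiPrime <= 1))
  expect_true(all(th@phiPrime >= 0 & th@phiPrime <= 1))
  expect_gt(th@fsG, 0.9)  # baseline: almost all genes functional
  # fs curves monotone in p
  ps <- seq(0.05, 1, by = 0.05)
  fsg <- vapply(ps, function(p) cascadeTheory(p, 0.8, 0.8, joint, gf)@fsG,
                numeric(1L))
  expect_true(all(diff(fsg) >= -1e-9))
})

test_that("metabolic percolation matches hand-computed binomial tails", {
  met <- poissonPmf(4)
  # no protein failure: omega = 0, metabolic giant intact
  m1 <- metabolicTheory(1, c(0, 0.5, 0.5), met, fP2M = 0.7)
  expect_equal(m1$omega, 0)
  expect_equal(m1$rMeta, 1)
  # worked case: all support degree 2, fP2M = 0.5, phi = 0.9
  m2 <- metabolicTheory(0.9, c(0, 0, 1), met, fP2M = 0.5, qMeta = 1)
  expect_equal(m2$omega, 2 * 0.1 * 0.9 + 0.1^2, tolerance = 1e-12)
  # fP2M = 1 reduces to the all-supports-fail closed form
  pmfD <- c(0.2, 0.3, 0.5)
  phi <- 0.8
  m3 <- metabolicTheory(phi, pmfD, met, fP2M = 1)
  expect_equal(m3$omega, 0.3 * (1 - phi) + 0.5 * (1 - phi)^2,
               tolerance = 1e-12)
  expect_true(m3$fsM >= 0 && m3$fsM <= 1)
})

test_that("naive coupling strengths count interlayer coverage", {
  q <- couplingStrengths(toyFixture("T1"))
  expect_equal(q$qG, 1)
  expect_equal(q$qP, 4 / 5)
  expect_equal(q$qMeta, 1)
  full <- smallEr(5, qG = 1, qP = 1, nG = 20, nP = 20)
  qf <- couplingStrengths(full)
  expect_equal(qf$qG, 1)
  expect_equal(qf$qP, 1)
})

test_that("calibration on a decoupled simulated curve drives qP to zero", {
  # With no interdependency links the protein curve is flat at the giant
  # fraction, which pins qP ~ 0. qG is then structurally unidentifiable:
  # its only effect enters through the (near-zero) non-giant protein
  # fraction, so no value of qG changes the fit and it is not asserted.
  net <- smallEr(15, nG = 400, nP = 400, nM = 50, cG = 2, cP = 8,
                 qG = 0, qP = 0, cS = 2)
  rc <- robustnessCurve(net, pGrid = seq(0.2, 1, by = 0.2), replicates = 5,
                        seed = 2)
  cal <- couplingStrengths(net, "calibrated", simCurve = rc@curve,
                           gridStep = 0.25)
  expect_lt(cal$qP, 0.1)
  expect_error(couplingStrengths(net, "calibrated"), "simCurve")
})

test_that("theoryVsSim concatenates layers and handles degenerate curves", {
  a <- data.frame(p = c(0.2, 0.5, 0.8), fsG = c(0.1, 0.4, 0.8),
                  fsP = c(0.2, 0.5, 0.9), fsM = c(0.1, 0.3, 0.7))
  expect_equal(theoryVsSim(a, a), 1)
  b <- a
  b[, 2:4] <- 1 - b[, 2:4]
  expect_equal(theoryVsSim(a, b), -1)
  expect_error(theoryVsSim(a[1:2, ], a[1:2, ]), "at least 3")
})
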