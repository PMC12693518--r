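nullTable <- function(alpha, nPerGroup, nGroups = 2L) {
  n <- nPerGroup * nGroups
  m <- t(vapply(seq_len(n), function(i) {
    g <- rgamma(length(alpha), alpha); g / sum(g)
  }, numeric(length(alpha))))
  colnames(m) <- names(alpha)
  closeComposition(CompositionTable(m, group = rep(paste0("g", seq_len(nGroups)),
                                                   each = nPerGroup)))
}

test_that("closure places compositions strictly inside the simplex", {
  out <- closeComposition(rbind(c(0, 0.5, 0.5)), pseudocount = 1e-6)
  expect_true(all(out > 0))
  expect_equal(sum(out), 1)

  ## an already-interior row changes by at most pseudocount * D
  x <- rbind(c(0.2, 0.3, 0.5))
  expect_equal(closeComposition(x), x, tolerance = 3e-6)

  expect_error(closeComposition(rbind(c(0, 0, 0))), "all-zero")
  expect_error(closeComposition(rbind(c(-0.1, 1.1, 0))), "nonnegative")
})

test_that("Dirichlet regression recovers simulated concentrations", {
  ## single group, n = 500: concentration estimates within 10% of truth
  alpha <- c(a = 4, b = 12, c = 8)
  tab <- closeComposition(
    simulateReplicates(alpha / sum(alpha), precision = sum(alpha), n = 500,
                       seed = 3))
  fit <- fitDirichlet(tab, model = "intercept")
  ahat <- exp(fit$coefficients[1, ])
  expect_true(fit$converged)
  expect_lt(max(abs(ahat - alpha) / alpha), 0.10)

  ## intercept-only expected composition equals the closed sample mean
  expect_lt(max(abs(fit$fitted[1, ] - colMeans(proportions(tab)))), 1e-2)

  ## the optimum never falls below the moment-matched start
  start <- log(pmax(colMeans(proportions(tab)), 1e-6))
  ll0 <- -bermass:::.dirichletNegLL(start, matrix(1, nrow(proportions(tab))),
                                    log(proportions(tab)), 3)
  expect_gte(fit$logLik, ll0)
})

test_that("group coefficients vanish for identical groups and the LRT is
          null-calibrated at moderate n", {
  ## duplicated data in two groups: group effects ~ 0, stat ~ 0, p ~ 1
  set.seed(6)
  m <- t(vapply(1:6, function(i) {
    g <- rgamma(3, c(5, 10, 3)); g / sum(g)
  }, numeric(3)))
  colnames(m) <- c("a", "b", "c")
  tab <- closeComposition(CompositionTable(rbind(m, m),
                                           group = rep(c("x", "y"), each = 6)))
  full <- fitDirichlet(tab, "group")
  null <- fitDirichlet(tab, "intercept")
  expect_lt(max(abs(full$coefficients[2, ])), 1e-2)
  lrt <- lrtGlobal(full, null)
  expect_lt(lrt$statistic, 0.01)
  expect_gt(lrt$p.value, 0.99)
  expect_equal(lrt$df, 3L)   # D * (G - 1)

  ## null rejection rate near nominal once n is moderate
  set.seed(30)
  rej <- 0L; nsim <- 150L
  for (i in seq_len(nsim)) {
    tb <- nullTable(c(a = 5, b = 10, c = 3), nPerGroup = 25L)
    p <- lrtGlobal(fitDirichlet(tb, "group"),
                   fitDirichlet(tb, "intercept"))$p.value
    rej <- rej + (p < 0.05)
  }
  expect_gte(rej / nsim, 0.005)
  expect_lte(rej / nsim, 0.10)
})

test_that("the LRT has power against separated groups and a bootstrap p-value
          is available", {
  set.seed(8)
  m1 <- t(vapply(1:8, function(i) {
    g <- rgamma(3, c(20, 5, 5)); g / sum(g)
  }, numeric(3)))
  m2 <- t(vapply(1:8, function(i) {
    g <- rgamma(3, c(5, 20, 5)); g / sum(g)
  }, numeric(3)))
  colnames(m1) <- colnames(m2) <- c("a", "b", "c")
  tab <- closeComposition(CompositionTable(rbind(m1, m2),
                                           group = rep(c("x", "y"), each = 8)))
  full <- fitDirichlet(tab, "group")
  null <- fitDirichlet(tab, "intercept")
  expect_lt(lrtGlobal(full, null)$p.value, 1e-6)

  pb <- lrtGlobal(full, null, table = tab, pvalue = "bootstrap", nBoot = 49L,
                  seed = 1)
  expect_lt(pb$p.value, 0.05)
  expect_match(pb$method, "bootstrap")

  expect_error(lrtGlobal(null, full), "nested")
})

test_that("per-component beta regression is near-nominal under the null and
          covers a simulated effect", {
  ## null rejection rate
  set.seed(10)
  ps <- c()
  for (i in 1:80) {
    tb <- nullTable(c(a = 6, b = 10, c = 4), nPerGroup = 6L)
    ps <- c(ps, betaComponentTests(tb)$p)
  }
  expect_gt(mean(ps < 0.05), 0.01)
  expect_lt(mean(ps < 0.05), 0.12)

  ## estimate of a logit-mean shift covered by its 95% Wald interval
  set.seed(20)
  delta <- 0.8; phi <- 60; cov <- 0L; nsim <- 120L
  for (i in seq_len(nsim)) {
    mu1 <- 0.3; mu2 <- plogis(qlogis(0.3) + delta)
    y <- c(rbeta(6, mu1 * phi, (1 - mu1) * phi),
           rbeta(6, mu2 * phi, (1 - mu2) * phi))
    tb <- closeComposition(CompositionTable(cbind(a = y, b = 1 - y),
                                            group = rep(c("x", "y"), each = 6)))
    bt <- betaComponentTests(tb)
    cov <- cov + (bt$estimate[1] - 1.96 * bt$se[1] <= delta &&
                    delta <= bt$estimate[1] + 1.96 * bt$se[1])
  }
  expect_gte(cov / nsim, 0.85)

  ## a constant class yields a degenerate-fit NA row, not an error
  tb <- closeComposition(CompositionTable(
    cbind(a = rep(0.3, 8), b = rep(0.7, 8)),
    group = rep(c("x", "y"), each = 4)))
  bt <- betaComponentTests(tb)
  expect_true(all(is.na(bt$p)))

  ## with a single testable class, BH over m = 1 gives q = p
  set.seed(2)
  y <- rbeta(12, 3, 7)
  tb1 <- CompositionTable(cbind(a = y, b = rep(0.5, 12)),
                          group = rep(c("x", "y"), each = 6))
  bt1 <- betaComponentTests(tb1)
  expect_true(is.na(bt1$p[2]))
  expect_equal(bt1$q[1], bt1$p[1])
})

test_that("BH adjustment agrees with a brute-force step-up evaluation", {
  bruteBH <- function(p) {
    m <- length(p); o <- order(p); q <- numeric(m)
    for (i in seq_len(m)) {
      j <- which(o == i)   # rank of p[i]
      q[i] <- min(1, min(m * p[o][j:m] / (j:m)))
    }
    q
  }
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  expect_equal(bhAdjust(0.2), 0.2)

  set.seed(14)
  for (i in 1:20) {
    p <- runif(sample(1:12, 1))
    q <- bhAdjust(p)
    expect_equal(q, bruteBH(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    ## (re-adjusting q is not asserted: step-up is not an idempotent map)
  }
  expect_error(bhAdjust(c(0.1, 1.2)), "input error")
  expect_error(bhAdjust(c(-0.1)), "input error")
})
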