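test_that("enumerateModels yields all downward-closed term sets", {
  expect_length(enumerateModels("A"), 2L)
  m2 <- enumerateModels(c("A", "B"))
  expect_length(m2, 5L)
  m3f <- enumerateModels(c("A", "B", "C"), forceMainEffects = TRUE)
  expect_length(m3f, 9L)
  # every emitted model respects the hierarchy principle
  hier <- function(m) all(vapply(m, function(t) {
    f <- strsplit(t, ":")[[1]]
    if (length(f) == 1) return(TRUE)
    subs <- unlist(lapply(seq_len(length(f) - 1), function(k)
      apply(combn(f, k), 2, paste, collapse = ":")))
    all(subs %in% m)
  }, logical(1)))
  expect_true(all(vapply(m3f, hier, logical(1))))
  # only the saturated forced model carries the three-way term
  expect_identical(sum(vapply(m3f, function(m) "A:B:C" %in% m, logical(1))), 1L)
  # deterministic order: by size then label
  expect_identical(attr(m2[[1]], "label"), "1")
  expect_identical(lengths(m2), c(0L, 1L, 1L, 2L, 3L))
})

test_that("loglinDeviance matches the closed-form G-squared", {
  o <- c(3, 1, 1, 3)
  e <- rep(2, 4)
  expect_equal(loglinDeviance(o, e), 2 * (2 * 3 * log(1.5) + 2 * log(0.5)),
               tolerance = 1e-12)
  expect_equal(loglinDeviance(o, o), 0)                     # saturated
  expect_equal(loglinDeviance(c(0, 4), c(1, 3)), loglinDeviance(c(4, 0), c(3, 1)))
  perm <- sample(4)
  expect_equal(loglinDeviance(o[perm], e[perm]), loglinDeviance(o, e))
})

test_that("cell aggregation preserves the Poisson likelihood", {
  fr <- simulateCountFrame(c(0.5, 0.2, 0.05, 0.1), n = 400, seed = 2)
  cl <- loglinearCells(fr, "y", c("deMet01", "ChronoAge"))
  expect_identical(sum(cl$n_records), 400L)
  expect_equal(sum(cl$y), sum(fr$y))
  f1 <- glm(y ~ deMet01 * ChronoAge, poisson, fr)
  f2 <- glm(y ~ deMet01 * ChronoAge + offset(offset), poisson, cl)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
})

test_that("a single candidate model gives probability one and 0% RJ rate", {
  cells <- data.frame(A = factor(0:1), y = c(30, 50), offset = 0)
  fit <- rjmcmc(cells, enumerateModels("A")[2],
                mcmcSettings(nIter = 500, burnIn = 100, seed = 3))
  expect_equal(modelProbabilities(fit)$post_prob, 1)
  expect_equal(unname(fit@acceptance["rj_pct"]), 0)
  expect_gt(unname(fit@acceptance["mh_pct"]), 0)
})

test_that("chains are exactly reproducible under a fixed seed", {
  cells <- data.frame(A = factor(c(0, 0, 1, 1)), B = factor(c(0, 1, 0, 1)),
                      y = c(40, 42, 39, 45), offset = 0)
  s <- mcmcSettings(nIter = 800, burnIn = 200, seed = 17)
  f1 <- rjmcmc(cells, enumerateModels(c("A", "B")), s)
  f2 <- rjmcmc(cells, enumerateModels(c("A", "B")), s)
  expect_identical(f1@draws, f2@draws)
  expect_identical(posteriorSummary(f1), posteriorSummary(f2))
  f3 <- rjmcmc(cells, enumerateModels(c("A", "B")),
               mcmcSettings(nIter = 800, burnIn = 200, seed = 18))
  expect_false(identical(f1@draws$g, f3@draws$g))
})

test_that("hierarchy-violating candidates are rejected up front", {
  cells <- data.frame(A = factor(c(0, 0, 1, 1)), B = factor(c(0, 1, 0, 1)),
                      y = c(40, 42, 39, 45))
  expect_error(rjmcmc(cells, list(c("A:B")), mcmcSettings(nIter = 200,
               burnIn = 50)), "hierarchy")
})

test_that("posterior model probabilities track the enumeration oracle", {
  set.seed(51)
  cells <- data.frame(A = factor(c(0, 0, 1, 1)), B = factor(c(0, 1, 0, 1)),
                      y = rpois(4, 2000), offset = 0)
  models <- enumerateModels(c("A", "B"))[4:5]  # independence vs saturated
  fit <- rjmcmc(cells, models,
                mcmcSettings(nIter = 4000, burnIn = 1000, seed = 52))
  pIndep <- modelProbabilities(fit)$post_prob[1]
  expect_gt(pIndep, 0.5)
  oracle <- oracleModelProbs(cells, models)
  se <- indicatorSE(fit@draws$model == 1L)
  expect_lt(abs(pIndep - oracle[1]), 3 * se)
})

test_that("hpdInterval implements the Chen-Shao sweep", {
  expect_equal(hpdInterval(rep(2, 150)), c(2, 2))
  set.seed(6)
  z <- rnorm(1e6)
  h <- hpdInterval(z)
  expect_equal(h[1], -1.96, tolerance = 0.02)
  expect_equal(h[2], 1.96, tolerance = 0.02)
  # for symmetric samples HPD ~ equal-tail interval
  et <- quantile(z, c(0.025, 0.975))
  expect_equal(unname(h), unname(et), tolerance = 0.03)
  expect_error(hpdInterval(rnorm(50)), "at least 100")
  # skewed draws: HPD is shorter than the equal-tail interval
  x <- rexp(1e5)
  expect_lt(diff(hpdInterval(x)), diff(quantile(x, c(0.025, 0.975))))
})

test_that("bayesian p-value flags misfit and stays calibrated", {
  # strong planted interaction, independence-only candidate -> tiny p_B
  set.seed(31)
  mu <- c(400, 100, 100, 400)
  cells <- data.frame(A = factor(c(0, 0, 1, 1)), B = factor(c(0, 1, 0, 1)),
                      y = rpois(4, mu), offset = 0)
  fitBad <- rjmcmc(cells, enumerateModels(c("A", "B"))[4],
                   mcmcSettings(nIter = 2000, burnIn = 500, seed = 32))
  pBad <- bayesianPValue(fitBad, seed = 33)
  expect_lt(pBad, 0.05)
  # data generated from the fitted model -> p_B well inside (0, 1)
  inWindow <- 0L
  for (r in 1:8) {
    cellsOk <- data.frame(A = cells$A, B = cells$B,
                          y = rpois(4, c(250, 250, 250, 250)), offset = 0)
    fitOk <- rjmcmc(cellsOk, enumerateModels(c("A", "B"))[4],
                    mcmcSettings(nIter = 1500, burnIn = 500, seed = 40 + r))
    pOk <- bayesianPValue(fitOk, maxDraws = 500, seed = 40 + r)
    expect_true(pOk >= 0 && pOk <= 1)
    if (pOk > 0.2 && pOk < 0.8) inWindow <- inWindow + 1L
  }
  expect_gte(inWindow, 6L)
  # saturated fit reproduces the data essentially exactly -> p_B near 1
  fitSat <- rjmcmc(cells, enumerateModels(c("A", "B"))[5],
                   mcmcSettings(nIter = 1500, burnIn = 500, seed = 34))
  expect_gt(bayesianPValue(fitSat, seed = 35), 0.3)
})

test_that("variance ranking identifies the dominant term", {
  fr <- simulateCountFrame(c(1, 0.05, 0.4, 0), n = 3000, seed = 61)
  cl <- loglinearCells(fr, "y", c("deMet01", "ChronoAge"))
  fit <- rjmcmc(cl, enumerateModels(c("deMet01", "ChronoAge"))[4],
                mcmcSettings(nIter = 1500, burnIn = 500, seed = 62))
  rk <- rankTermsByVariance(fit)
  expect_identical(rk$term[rk$rank == 1], "ChronoAge")  # planted dominant
  expect_setequal(rk$rank, seq_len(nrow(rk)))           # a permutation
  # single-term model: that term is ranked first
  fit1 <- rjmcmc(cl, enumerateModels(c("deMet01", "ChronoAge"))[2:3][1],
                 mcmcSettings(nIter = 800, burnIn = 200, seed = 63))
  rk1 <- rankTermsByVariance(fit1)
  expect_identical(nrow(rk1), 1L)
  expect_identical(rk1$rank, 1L)
})
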