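paperTab <- matrix(c(6598, 5798, 5799, 6597), 2,
                   dimnames = list(c("BF", "NBF"),
                                   c("methylated", "unmethylated")))

test_that("phi coefficient matches closed forms and the published table", {
  expect_equal(round(phiCoefficient(paperTab), 3), 0.064)
  expect_equal(phiCoefficient(matrix(c(10, 0, 0, 10), 2)), 1.0)
  expect_equal(phiCoefficient(matrix(c(3, 1, 1, 3), 2)), 0.5)  # 8/sqrt(256)
  expect_error(phiCoefficient(matrix(c(1, 1, 0, 0), 2)), "zero margin")
})

test_that("pearsonChi2 agrees with brute-force summation and N*phi^2", {
  flat <- matrix(c(5, 10, 5, 10), 2)          # O = E exactly
  r <- pearsonChi2(flat)
  expect_equal(r$chi2, 0)
  expect_true(all(r$residuals == 0))
  r2 <- pearsonChi2(matrix(c(3, 1, 1, 3), 2))
  expect_equal(r2$chi2, 2.0)                  # N*phi^2 = 8 * 0.25
  set.seed(4)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 40) + 1, 2)
    r <- pearsonChi2(tab)
    expect_equal(r$chi2, chi2BruteForce(tab), tolerance = 1e-12)
    expect_equal(r$chi2, sum(tab) * r$phi^2, tolerance = 1e-12)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(r$chi2, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(r$residuals, unname(ref$residuals) + 0 * r$residuals,
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  # the published counts give chi2 ~ 103, consistent with the reported
  # p < 2.22e-16
  rp <- pearsonChi2(paperTab)
  expect_equal(rp$chi2, chi2BruteForce(paperTab), tolerance = 1e-10)
  expect_equal(rp$chi2, sum(paperTab) * rp$phi^2, tolerance = 1e-10)
  expect_lt(rp$p_value, 2.22e-16)
})

test_that("CMH test matches mantelhaen.test and is order-invariant", {
  # odds ratio exactly 1 and O = E in every stratum -> statistic 0
  null3 <- array(c(2, 2, 2, 2, 6, 3, 6, 3), c(2, 2, 2))
  expect_equal(cmhTest(null3)$statistic, 0)
  set.seed(9)
  for (i in 1:10) {
    tab <- array(rpois(12, 15) + 1, c(2, 2, 3))
    for (corr in c(TRUE, FALSE)) {
      r <- cmhTest(tab, correct = corr)
      ref <- mantelhaen.test(tab, correct = corr, exact = FALSE)
      expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(r$p_value, ref$p.value, tolerance = 1e-10)
    }
    perm <- tab[, , c(3, 1, 2)]
    expect_equal(cmhTest(perm)$statistic, cmhTest(tab)$statistic,
                 tolerance = 1e-12)
  }
  # single stratum reduces to the continuity-corrected 2x2 chi-square up to
  # the hypergeometric (n-1)/n variance factor
  t2 <- matrix(c(12, 5, 7, 14), 2)
  n2 <- sum(t2)
  expect_equal(cmhTest(t2, correct = TRUE)$statistic,
               unname(chisq.test(t2, correct = TRUE)$statistic) *
                 (n2 - 1) / n2,
               tolerance = 1e-10)
  degen <- array(c(0, 0, 0, 0, 3, 1, 2, 4), c(2, 2, 2))
  expect_warning(r <- cmhTest(degen), "zero margin")
})

test_that("kendallTauB matches the spec worked examples", {
  expect_equal(kendallTauB(c(0, 1, 1, 0), c(0, 1, 1, 0)), 1.0)
  expect_equal(kendallTauB(c(0, 0, 1, 1), c(1, 1, 0, 0)), -1.0)
  expect_equal(kendallTauB(c(0, 1, 1, 0, 1), c(0, 1, 0, 0, 1)), 2 / 3)
  expect_error(kendallTauB(c(1, 1, 1), c(0, 1, 0)), "constant")
  expect_error(kendallTauB(1, c(1, 2)), "equal length")
})

test_that("kendallTauB equals pair enumeration on short binary vectors", {
  # exhaustive over lengths 2..5 here; the full sweep up to length 8 runs
  # in the acceptance suite
  for (n in 2:5) {
    codes <- 0:(2^n - 1)
    vecs <- lapply(codes, function(k) as.integer(intToBits(k)[1:n]))
    ok <- vapply(vecs, function(v) length(unique(v)) == 2L, logical(1))
    vecs <- vecs[ok]
    for (i in seq_along(vecs)) for (j in seq(i, length(vecs))) {
      expect_equal(kendallTauB(vecs[[i]], vecs[[j]]),
                   tauBruteForce(vecs[[i]], vecs[[j]]), tolerance = 1e-12)
    }
  }
})

test_that("pairwiseConcordance composes per-pair tau-b with genotype tags", {
  set.seed(11)
  st <- matrix(sample(c(1L, 4L), 40 * 4, TRUE), 40, 4)
  st[, 2] <- st[, 1]                        # duplicated accession
  st[, 4] <- ifelse(st[, 3] == 1L, 4L, 1L)  # anti-correlated pair
  meta <- toyMeta(4, genotype = c("A", "A", "B", "B"))
  epi <- epiFromStates(st, meta)
  pc <- pairwiseConcordance(epi, meta)
  me <- assay(epi, "methylated")
  expect_equal(pc$tau["acc1", "acc2"], 1.0)
  expect_equal(pc$tau["acc3", "acc4"], -1.0)
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(pc$tau[i, j], kendallTauB(me[, i], me[, j]))
  expect_true(all(pc$tau == t(pc$tau), na.rm = TRUE))
  expect_identical(pc$pairs$within_genotype,
                   c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE))
  # constant profiles are flagged as missing
  stc <- cbind(rep(1L, 10), rep(1L, 10), sample(c(1L, 4L), 10, TRUE))
  pcc <- pairwiseConcordance(epiFromStates(stc))
  expect_true(is.na(pcc$tau[1, 2]))
})

test_that("perfectlyAssociatedBands finds exactly the separating bands", {
  grp <- setNames(factor(c("BF", "BF", "NBF", "NBF"),
                         levels = c("NBF", "BF")), paste0("acc", 1:4))
  st <- rbind(c(4L, 3L, 1L, 1L),   # perfect, methylated in BF
              c(1L, 1L, 2L, 4L),   # perfect complement
              c(4L, 1L, 1L, 1L),   # one accession off
              c(1L, 1L, 1L, 1L))
  epi <- epiFromStates(st)
  hits <- perfectlyAssociatedBands(epi, grp)
  expect_identical(hits$band, c("a1", "a2"))
  expect_identical(hits$direction,
                   c("methylated_in_BF", "demethylated_in_BF"))
  # sweep oracle: a band is reported iff group separation is total
  me <- assay(epi, "methylated")
  oracle <- vapply(seq_len(nrow(me)), function(b) {
    bf <- me[b, grp == "BF"]; nbf <- me[b, grp == "NBF"]
    (all(bf == 1) && all(nbf == 0)) || (all(bf == 0) && all(nbf == 1))
  }, logical(1))
  expect_identical(sort(hits$band), sort(rownames(me)[oracle]))
  # none present -> empty result
  none <- perfectlyAssociatedBands(epiFromStates(st[3:4, , drop = FALSE]), grp)
  expect_identical(nrow(none), 0L)
})

test_that("buildContingency2x2 tallies cells with BF column first", {
  grp <- setNames(factor(c("BF", "NBF"), levels = c("NBF", "BF")),
                  c("acc1", "acc2"))
  st <- cbind(c(1L, 4L, 2L), c(1L, 1L, 3L))
  tab <- buildContingency2x2(epiFromStates(st), grp)
  expect_identical(colnames(tab), c("BF", "NBF"))
  expect_identical(as.vector(tab), c(2L, 1L, 1L, 2L))
  expect_identical(sum(tab), 6L)  # bands x accessions
  allde <- buildContingency2x2(epiFromStates(cbind(1L, 1L)), grp)
  expect_identical(as.vector(allde["methylated", ]), c(0L, 0L))
})
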