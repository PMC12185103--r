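# helper: synthetic readings table
mkReadings <- function(values, group = "sham") {
  do.call(rbind, lapply(seq_len(nrow(values)), function(s) {
    do.call(rbind, lapply(colnames(values), function(rg) {
      data.frame(subject = rownames(values)[s], group = group, region = rg,
                 hemisphere = c("L", "R"), reading_index = 1:2,
                 od = values[s, rg])
    }))
  }))
}

test_that("replicate averaging collapses readings and flags missing cells", {
  r <- data.frame(
    subject = "s1", group = "sham", region = "dCA1",
    hemisphere = "L", reading_index = 1:3, od = c(1, 2, 3)
  )
  tab <- averageReplicates(r)
  expect_equal(unname(tab@values["s1", "dCA1"]), 2)
  single <- averageReplicates(data.frame(
    subject = "s1", group = "sham", region = "dCA1", od = 0.7
  ))
  expect_equal(unname(single@values[1, 1]), 0.7)
  expect_message(
    two <- averageReplicates(data.frame(
      subject = c("s1", "s1", "s2"), group = "sham",
      region = c("dCA1", "dCA2", "dCA1"), od = c(1, 2, 3)
    )),
    "missing"
  )
  expect_true(is.na(two@values["s2", "dCA2"]))
})

test_that("standards normalisation divides by the batch slope", {
  stds <- data.frame(batch = "b1", thickness_um = c(20, 40, 60, 80),
                     od = 0.01 * c(20, 40, 60, 80))
  raw <- data.frame(batch = "b1", od = 0.5)
  expect_equal(normalizeToStandards(raw, stds)$activity, 50)
  # degenerate standards
  flat <- data.frame(batch = "b1", thickness_um = rep(40, 4), od = 1:4)
  expect_error(normalizeToStandards(raw, flat), "degenerate")
  zero <- data.frame(batch = "b1", thickness_um = c(20, 40, 60, 80),
                     od = rep(0.3, 4))
  expect_error(normalizeToStandards(raw, zero), "zero-slope")
  # common rescaling leaves Pearson correlations unchanged
  set.seed(15)
  v <- matrix(rnorm(8 * 14), 8, dimnames = list(paste0("s", 1:8),
                                                canonicalRegions))
  tabA <- RegionTable(v, rep("sham", 8))
  tabB <- RegionTable(v / 0.01, rep("sham", 8))
  eA <- correlationMatrix(tabA, "sham")
  eB <- correlationMatrix(tabB, "sham")
  expect_equal(eA$r, eB$r)
})

test_that("the canonical 14-region panel yields 91 unordered pairs", {
  set.seed(16)
  v <- matrix(rnorm(8 * 14), 8, dimnames = list(paste0("s", 1:8),
                                                canonicalRegions))
  edges <- correlationMatrix(RegionTable(v, rep("sham", 8)), "sham")
  expect_equal(nrow(edges), choose(14, 2))
  expect_equal(nrow(edges), 91)
  expect_true(all(abs(edges$r) <= 1))
  # a duplicated region correlates perfectly with its twin
  v2 <- cbind(v[, 1:13], dup = v[, 1])
  colnames(v2) <- c(canonicalRegions[1:13], "RSDdup")
  e2 <- correlationMatrix(RegionTable(v2, rep("sham", 8)), "sham")
  dup <- e2[e2$region1 == "RSD" & e2$region2 == "RSDdup", ]
  expect_equal(dup$r, 1)
})

test_that("correlations estimate a known covariance within sampling error", {
  skip_if_not_installed("MASS")
  set.seed(17)
  Sigma <- diag(4)
  Sigma[1, 2] <- Sigma[2, 1] <- 0.6
  Sigma[3, 4] <- Sigma[4, 3] <- -0.4
  # average the estimate over replicates of n = 200 draws so the check is
  # on estimator accuracy rather than one draw's sampling noise
  reps <- replicate(20, {
    x <- MASS::mvrnorm(200, rep(0, 4), Sigma)
    colnames(x) <- c("dCA1", "dCA2", "dCA3", "dDG")
    e <- correlationMatrix(RegionTable(x, rep("g", 200)), "g")
    c(e$r[e$region1 == "dCA1" & e$region2 == "dCA2"],
      e$r[e$region1 == "dCA3" & e$region2 == "dDG"])
  })
  expect_lt(abs(mean(reps[1, ]) - 0.6), 0.1)
  expect_lt(abs(mean(reps[2, ]) + 0.4), 0.1)
})

test_that("BH selection is correct at the edges and monotone in q", {
  expect_false(any(fdrSelect(rep(1, 91))))
  expect_true(fdrSelect(c(1e-6, runif(90, 0.5, 1)))[1])
  set.seed(18)
  p <- runif(91)
  for (q in c(0.001, 0.01, 0.05)) {
    expect_true(all(fdrSelect(p, q = q) | !fdrSelect(p, q = q / 2)))
  }
})

test_that("Fisher z comparison matches its closed form", {
  expect_equal(fisherZCompare(0.5, 10, 0.5, 20)$z, 0)
  fz <- fisherZCompare(0.9, 8, 0, 8)
  expect_equal(fz$z, atanh(0.9) / sqrt(2 / 5), tolerance = 1e-4)
  expect_equal(fz$z, 2.328, tolerance = 1e-3)
  expect_error(fisherZCompare(1, 8, 0.5, 8), "atanh")
})

test_that("pooled proportion test handles equality and bad counts", {
  expect_equal(proportionTest(5, 10, 10, 20)$z, 0)
  pt <- proportionTest(15, 91, 7, 91)
  expect_gt(pt$z, 0)
  manual <- local({
    pp <- 22 / 182
    (15 / 91 - 7 / 91) / sqrt(pp * (1 - pp) * (2 / 91))
  })
  expect_equal(pt$z, manual)
  expect_error(proportionTest(12, 10, 1, 10), "0 <= k <= n")
})

test_that("graphs carry nested significance tiers", {
  set.seed(19)
  v <- matrix(rnorm(8 * 14), 8, dimnames = list(paste0("s", 1:8),
                                                canonicalRegions))
  v[, "dCA1"] <- v[, "dCA2"] + rnorm(8, sd = 0.05)  # one strong edge
  edges <- correlationMatrix(RegionTable(v, rep("sham", 8)), "sham")
  g <- buildGraph(edges)
  expect_equal(sort(igraph::V(g)$name), sort(canonicalRegions))
  expect_true(all(edges$p[edges$sig_fdr] < 0.05))      # FDR tier is nested
  tiers <- igraph::E(g)$tier
  expect_true(all(tiers %in% c("fdr", "p05")))
  expect_true("fdr" %in% tiers)
  # empty significant set still yields all nodes
  pEmpty <- edges; pEmpty$sig_p05 <- FALSE
  g0 <- buildGraph(pEmpty)
  expect_equal(igraph::ecount(g0), 0)
  expect_equal(igraph::vcount(g0), 14)
})

test_that("group comparison tables align pairs and propagate Fisher z", {
  set.seed(20)
  v1 <- matrix(rnorm(8 * 5), 8)
  v2 <- matrix(rnorm(8 * 5), 8)
  colnames(v1) <- colnames(v2) <- c("RSD", "RSG", "RE", "CEA", "BMA")
  eA <- correlationMatrix(RegionTable(v1, rep("sham", 8)), "sham")
  eB <- correlationMatrix(RegionTable(v2, rep("lesion", 8)), "lesion")
  cmp <- compareGroups(eA, eB)
  expect_equal(nrow(cmp), choose(5, 2))
  k <- which(!is.na(cmp$fisher_z))[1]
  direct <- fisherZCompare(eA$r[k], eA$n[k], eB$r[k], eB$n[k])
  expect_equal(cmp$fisher_z[k], direct$z)
})
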