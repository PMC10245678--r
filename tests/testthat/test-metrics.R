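test_that("identical models pair every residue at distance zero", {
  m <- genStructure(c(10L, 6L), seed = 3)
  corr <- matchResidues(m, m)
  expect_identical(nrow(corr@pairs), 16L)
  expect_true(all(corr@pairs$dist == 0))
  expect_identical(nrow(corr@unmatchedRef), 0L)
})

test_that("a rigid 5 A shift with a 3 A cutoff leaves nothing paired", {
  m <- ca_model(cbind(3.8 * (1:10), 0, 0))
  a <- atomTable(m); a$y <- a$y + 5
  corr <- matchResidues(AtomicModel(a), m, cutoff = 3)
  expect_identical(nrow(corr@pairs), 0L)
})

test_that("pairing matches brute-force mutual nearest neighbours and is symmetric", {
  set.seed(17)
  for (rep in 1:5) {
    ref_xyz <- matrix(runif(30 * 3, 0, 40), 30)
    pred_xyz <- ref_xyz[sample(30, 25), ] + matrix(rnorm(75, 0, 0.8), 25)
    pred <- ca_model(pred_xyz); ref <- ca_model(ref_xyz)
    corr <- matchResidues(pred, ref)
    ## brute force: mutual nearest neighbour under the cutoff
    expected <- 0L
    for (i in 1:25) {
      d <- sqrt(colSums((t(ref_xyz) - pred_xyz[i, ])^2))
      j <- which.min(d)
      dp <- sqrt(colSums((t(pred_xyz) - ref_xyz[j, ])^2))
      if (which.min(dp) == i && d[j] <= 3) expected <- expected + 1L
    }
    expect_identical(nrow(corr@pairs), expected)
    ## one-to-one
    expect_identical(anyDuplicated(corr@pairs$pred_row), 0L)
    expect_identical(anyDuplicated(corr@pairs$ref_row), 0L)
    ## symmetry of the pair count
    expect_identical(nrow(matchResidues(ref, pred)@pairs), nrow(corr@pairs))
  }
})

test_that("RMSD is zero on self, exact on a rigid translation", {
  m <- genStructure(20L, seed = 5)
  expect_identical(rmsdMetrics(matchResidues(m, m), "CA"), 0)
  a <- atomTable(m)
  a$x <- a$x + 1 / sqrt(3); a$y <- a$y + 1 / sqrt(3); a$z <- a$z + 1 / sqrt(3)
  corr <- matchResidues(AtomicModel(a), m)
  expect_equal(rmsdMetrics(corr, "CA"), 1, tolerance = 1e-12)
  expect_equal(rmsdMetrics(corr, c("CA", "C", "O", "N")), 1,
               tolerance = 1e-12)
})

test_that("Gaussian jitter of sigma per axis gives RMSD near sigma * sqrt(3)", {
  m <- genStructure(125L, seed = 6)  # 500 backbone atoms
  sigma <- 0.3
  p <- perturbModel(m, sigmaXyz = sigma, seed = 7)
  corr <- matchResidues(p, m)
  r <- rmsdMetrics(corr, c("CA", "C", "O", "N"))
  ## chi_3 mean-square is exactly 3 sigma^2; 4 sigma tolerance on the rms
  expect_equal(r, sigma * sqrt(3), tolerance = 0.05)
})

test_that("classification metrics count identity errors and omissions correctly", {
  m <- genStructure(10L, seed = 9)
  expect_equal(classificationMetrics(matchResidues(m, m))[
    c("recall", "precision", "aa_accuracy", "completeness")],
    list(recall = 1, precision = 1, aa_accuracy = 1, completeness = 1))

  ## one of ten identities wrong
  rt <- residueTable(m)
  wrong <- densid:::set_residue_fields(
    m, rt$chain[1], 1L,
    res_name = ifelse(rt$res_name[1] == "ALA", "GLY", "ALA"))
  cm <- classificationMetrics(matchResidues(wrong, m))
  expect_equal(cm$recall, 1.0)
  expect_equal(cm$aa_accuracy, 0.9)
  expect_equal(cm$completeness, 0.9)

  ## two of ten residues missing, rest exact
  sub <- AtomicModel(atomTable(m)[atomTable(m)$res_idx <= 8, ])
  cm2 <- classificationMetrics(matchResidues(sub, m))
  expect_equal(cm2$recall, 0.8)
  expect_equal(cm2$precision, 1.0)
  expect_equal(cm2$completeness, 0.8)
})

test_that("ratio metrics stay in [0,1] with completeness <= recall on random cases", {
  set.seed(23)
  for (rep in 1:20) {
    ref <- genStructure(sample(10:40, 1), seed = rep)
    pred <- perturbModel(ref, sigmaXyz = runif(1, 0, 2),
                         identityErrorRate = runif(1), seed = rep + 100)
    ## randomly drop some residues
    a <- atomTable(pred)
    drop <- sample(unique(a$res_idx), sample(0:5, 1))
    pred <- AtomicModel(a[!(a$res_idx %in% drop), ])
    cm <- classificationMetrics(matchResidues(pred, ref))
    v <- unlist(cm[c("recall", "precision", "completeness")])
    expect_true(all(v >= 0 & v <= 1))
    expect_lte(cm$completeness, cm$recall + 1e-12)
    if (!is.na(cm$aa_accuracy))
      expect_true(cm$aa_accuracy >= 0 && cm$aa_accuracy <= 1)
  }
})

## --- Q-score ---------------------------------------------------------------

test_that("Q-score is near 1 for a map rendered with the scoring sigma", {
  m <- ca_model(matrix(c(10, 10, 10), 1))
  map <- renderMap(m, voxel = 0.4, sigma = 0.6, boxPad = 5)
  q <- qscore(m, map, sigma = 0.6, rMax = 2.0)
  expect_gt(q$model_q, 0.99)
})

test_that("Q-score on pure noise is near zero and edge atoms are skipped", {
  set.seed(3)
  map <- DensityMap(array(rnorm(40^3), c(40, 40, 40)), voxelSize = 1,
                    origin = c(0, 0, 0))
  xyz <- matrix(runif(100 * 3, 8, 32), 100)
  q <- qscore(ca_model(xyz), map)
  expect_lt(abs(mean(q$atom_q$q, na.rm = TRUE)), 0.15)

  edge <- ca_model(matrix(c(0.5, 20, 20), 1))
  expect_warning(qe <- qscore(edge, map), "skipped")
  expect_identical(qe$n_skipped, 1L)
})

test_that("Q-score is invariant to affine rescaling of map values", {
  m <- genStructure(5L, seed = 2)
  map <- renderMap(m, voxel = 0.5, sigma = 0.8, boxPad = 4)
  q1 <- qscore(m, map, sigma = 0.8)
  map2 <- DensityMap(3.7 * map@grid + 11, voxelSize = voxelSize(map),
                     origin = mapOrigin(map))
  q2 <- qscore(m, map2, sigma = 0.8)
  expect_equal(q1$atom_q$q, q2$atom_q$q, tolerance = 1e-9)
  ## per-residue q is the mean over the residue's atoms
  r1 <- q1$residue_q$q[1]
  expect_equal(r1, mean(q1$atom_q$q[q1$atom_q$res_idx == 1], na.rm = TRUE))
})

## --- FSC -------------------------------------------------------------------

test_that("FSC of a map with itself is 1 and with its negation is -1", {
  m <- genStructure(8L, seed = 4)
  map <- renderMap(m, voxel = 1, sigma = 1.2, boxPad = 4)
  f1 <- fsc(map, map)
  expect_true(all(abs(f1$curve$fsc - 1) < 1e-9))
  neg <- DensityMap(-map@grid, voxelSize = voxelSize(map),
                    origin = mapOrigin(map))
  f2 <- fsc(map, neg)
  expect_true(all(abs(f2$curve$fsc + 1) < 1e-9))
  expect_error(fsc(map, DensityMap(array(0, c(4, 4, 4)))), "grid")
})

test_that("adding independent noise depresses FSC at high frequency", {
  m <- genStructure(30L, seed = 12)
  map <- renderMap(m, voxel = 1, sigma = 1.0, boxPad = 6)
  noisy <- DensityMap(
    map@grid + densid:::with_seed(5, array(rnorm(length(map@grid), 0,
                                                 0.3 * sd(map@grid)),
                                           dim(map@grid))),
    voxelSize = voxelSize(map), origin = mapOrigin(map))
  f <- fsc(map, noisy)
  cv <- f$curve
  lo <- mean(cv$fsc[cv$freq <= quantile(cv$freq, 0.2)])
  hi <- mean(cv$fsc[cv$freq >= quantile(cv$freq, 0.8)])
  expect_gt(lo, hi)
  expect_gt(lo, 0.9)
  ## the 0.5 crossing, when present, lies inside the frequency range
  if (!is.na(f$crossing_0.5)) {
    expect_gt(f$crossing_0.5, 0)
    expect_lte(f$crossing_0.5, max(cv$freq))
  }
})
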