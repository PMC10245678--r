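test_that("a one-node one-hot profile scores a single match in closed form", {
  h <- buildProfile(onehot_profile("M"))
  ## only path: enter node 1 (prob 1/L = 1), emit M with odds 1/0.05
  expect_equal(forwardScore(h, "M"), log2(1 / 0.05), tolerance = 1e-9)
  ## a sequence the profile cannot emit anywhere scores -Inf-free via flanks?
  ## emission is one-hot, so "A" has no valid path: score is -Inf guarded
  expect_true(forwardScore(h, "MA") >= forwardScore(h, "A"))
})

test_that("a uniform-emission profile has zero log-odds per matched residue", {
  uni <- ResidueProfile("U", matrix(0.05, 3, 20), rep(0.8, 3))
  h <- buildProfile(uni)
  ## every match emission equals background: paths contribute only
  ## transition mass, so the all-match global path has odds ratio built
  ## purely from entry/transition probabilities (<= 1): score <= 0
  expect_lte(viterbiAlign(h, "AAA")$bits, 0)
})

test_that("Forward and Viterbi agree with exhaustive path enumeration", {
  set.seed(31)
  seqs <- c("M", "MK", "KVAM", "AWY", "MKV")
  for (rep in 1:12) {
    L <- sample(1:3, 1)
    rp <- random_profile(L)
    h <- buildProfile(rp, d = runif(1, 0.2, 0.8), mmin = runif(1, 0, 0.6))
    for (s in seqs) {
      oracle <- enumerate_paths(h, s)
      expect_equal(forwardScore(h, s), oracle$forward, tolerance = 1e-9)
      expect_equal(viterbiAlign(h, s)$bits, oracle$viterbi,
                   tolerance = 1e-9)
    }
  }
})

test_that("an exact one-hot match aligns all-M with node i on position i", {
  h <- buildProfile(onehot_profile("MKVAW"))
  v <- viterbiAlign(h, "MKVAW")
  expect_identical(v$alignment$state, rep("M", 5))
  expect_identical(v$alignment$node, 1:5)
  expect_identical(v$alignment$pos, 1:5)
})

test_that("one extra residue produces exactly one insert state", {
  h <- buildProfile(onehot_profile("MKVAW"))
  v <- viterbiAlign(h, "MKQVAW")  # Q inserted after node 2
  expect_identical(sum(v$alignment$state == "I"), 1L)
  expect_identical(sum(v$alignment$state == "M"), 5L)
})

test_that("Viterbi never exceeds Forward on random profile/sequence pairs", {
  set.seed(77)
  for (rep in 1:200) {
    h <- buildProfile(random_profile(sample(1:8, 1)),
                      d = runif(1, 0.2, 0.8), mmin = runif(1, 0, 0.6))
    s <- paste(sample(AA20, sample(1:12, 1), replace = TRUE),
               collapse = "")
    expect_lte(viterbiAlign(h, s)$bits, forwardScore(h, s) + 1e-9)
  }
})

test_that("alignment paths are monotone in node and position", {
  set.seed(5)
  for (rep in 1:50) {
    h <- buildProfile(random_profile(sample(2:10, 1)))
    s <- paste(sample(AA20, sample(2:15, 1), replace = TRUE), collapse = "")
    a <- viterbiAlign(h, s)$alignment
    md <- a$node[a$state != "I"]
    expect_true(all(diff(md) > 0) || length(md) < 2)
    mi <- a$pos[a$state != "D"]
    expect_true(all(diff(mi) > 0) || length(mi) < 2)
  }
})

test_that("empty sequences and invalid letters are rejected; X scores as background", {
  h <- buildProfile(onehot_profile("MK"))
  expect_error(forwardScore(h, ""), "empty")
  expect_error(forwardScore(h, "M1K"), "invalid")
  ## an X contributes zero log-odds wherever it lands
  expect_equal(forwardScore(h, "X"),
               forwardScore(buildProfile(onehot_profile("WW")), "X"))
})

test_that("calibration is deterministic, positive-scale, and fits the tail", {
  h <- buildProfile(random_profile(15), mmin = 0.3)
  c1 <- calibrate(h, n = 300, len = 60, seed = 9)
  c2 <- calibrate(h, n = 300, len = 60, seed = 9)
  expect_identical(c1@mu, c2@mu)
  expect_identical(c1@lambda, c2@lambda)
  expect_gt(c1@lambda, 0)
  ## goodness of fit: empirical survival at the fitted quantiles matches
  ## the Gumbel prediction within binomial error at n = 1000
  cal <- calibrate(h, n = 1000, len = 60, seed = 10)
  scores <- densid:::with_seed(123, {
    lt <- densid:::hmm_log_tables(h)
    seqs <- lapply(rep(60, 1000), function(l)
      as.integer(sample.int(20, l, replace = TRUE) - 1L))
    densid:::c_forward_batch(lt$mlod, lt$ilod, lt$ltr, seqs)
  })
  for (p_target in c(0.5, 0.1)) {
    s <- quantile(scores, 1 - p_target)
    pred <- gumbelSurvival(cal, s)
    se <- sqrt(p_target * (1 - p_target) / 1000)
    expect_lt(abs(mean(scores > s) - pred), 5 * se + 0.01)
  }
  ## far tail: the extreme-value approximation stays within a small factor
  s <- quantile(scores, 0.98)
  expect_lt(abs(log(gumbelSurvival(cal, s) / 0.02)), log(4))
  expect_error(calibrate(h, n = 50), "n >= 100")
})

test_that("database search ranks the true consensus first among decoys", {
  seq <- densid:::with_seed(21, densid:::random_aa_seq(80))
  h <- buildProfile(genProfile(seq, eta = 0.3, seed = 22, chainId = "q"))
  db <- genProteome(setNames(seq, "self"), nDecoys = 99, seed = 23)
  cal <- calibrate(h, n = 200, len = 80, seed = 24)
  hits <- searchDb(h, db, cal, eMax = 1e6)
  expect_identical(hits$target_id[1], "true_self")
  ## E-values are monotone decreasing in bit score
  expect_true(all(diff(order(hits$bit_score, decreasing = TRUE)) ==
                    diff(order(hits$e_value))))
  ## eMax = 0 filters everything
  expect_identical(nrow(searchDb(h, db, cal, eMax = 0)), 0L)
})

test_that("duplicating every database entry doubles every E-value", {
  seq <- densid:::with_seed(31, densid:::random_aa_seq(40))
  h <- buildProfile(genProfile(seq, eta = 0.2, seed = 32))
  db <- genProteome(seq, nDecoys = 20, seed = 33)
  db2 <- c(db, db)
  names(db2) <- make.unique(names(db2))
  cal <- calibrate(h, n = 200, len = 40, seed = 34)
  h1 <- searchDb(h, db, cal, eMax = Inf)
  h2 <- searchDb(h, db2, cal, eMax = Inf)
  e1 <- setNames(h1$e_value, h1$target_id)
  e2 <- setNames(h2$e_value, h2$target_id)
  expect_equal(unname(e2[names(e1)]), unname(2 * e1), tolerance = 1e-12)
})

test_that("aggregateHits groups chains by best-hit target and sums scores", {
  mk <- function(target, bits, ev) {
    data.frame(query_chain = "x", target_id = target, bit_score = bits,
               e_value = ev, stringsAsFactors = FALSE)
  }
  out <- aggregateHits(list(A = mk("T", 10, 1e-3), B = mk("T", 8, 1e-2),
                            C = mk("T", 5, 0.5)))
  expect_identical(nrow(out), 1L)
  expect_identical(out$k, 3L)
  expect_equal(out$combined_bits, 23)
  expect_equal(out$e_best, 1e-3)
  expect_equal(out$e_worst, 0.5)

  out2 <- aggregateHits(list(A = mk("T1", 10, 1e-3), B = mk("T2", 8, 1e-2)))
  expect_identical(nrow(out2), 2L)
  expect_identical(out2$k, c(1L, 1L))
  expect_identical(out2$target_id, c("T1", "T2"))  # sorted by combined
})

test_that("cross-referencing pseudo-symmetric copies rescues weak individual hits", {
  ## three copies of one protein, each with a noisy profile whose single
  ## hit would fail a strict E-value cut, but all agreeing on the target
  seq <- densid:::with_seed(41, densid:::random_aa_seq(30))
  db <- genProteome(setNames(seq, "sym"), nDecoys = 50, seed = 42)
  hits <- list()
  for (k in 1:3) {
    ## a short very noisy fragment of the common sequence per copy
    h <- buildProfile(genProfile(substr(seq, 1, 10), eta = 0.85,
                                 seed = 42 + k,
                                 chainId = paste0("c", k)))
    cal <- calibrate(h, n = 150, len = 300, seed = 52 + k)
    hits[[paste0("c", k)]] <- searchDb(h, db, cal, eMax = 1e6)
  }
  strict <- 1e-3
  weak <- all(vapply(hits, function(h)
    h$e_value[h$target_id == "true_sym"][1] > strict, logical(1)))
  expect_true(weak)  # every copy is individually unconvincing
  cons <- aggregateHits(hits)
  expect_identical(cons$target_id[1], "true_sym")
  expect_identical(cons$k[1], 3L)
})
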