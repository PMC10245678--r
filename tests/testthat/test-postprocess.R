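test_that("small systems clamp the neighbour count to n - 1", {
  m <- ca_model(cbind(c(0, 4, 8), 0, 0))
  g <- buildResidueGraph(m, k = 20)
  expect_true(all(lengths(g@neighbors) == 2L))
  expect_error(buildResidueGraph(ca_model(cbind(0, 0, 0))), "at least 2")
})

test_that("a 100-residue helix gives out-degree exactly 20", {
  m <- genStructure(100L, seed = 8)
  g <- buildResidueGraph(m, k = 20)
  expect_true(all(lengths(g@neighbors) == 20L))
  ## no self-edges, no duplicates
  for (i in seq_along(g@neighbors)) {
    nb <- g@neighbors[[i]]
    expect_false(i %in% nb)
    expect_identical(anyDuplicated(nb), 0L)
  }
})

test_that("neighbour lists match the brute-force all-pairs oracle", {
  set.seed(13)
  for (n in c(10, 50, 200)) {
    xyz <- matrix(runif(n * 3, 0, 30), n)
    m <- ca_model(xyz)
    for (k in c(3, 20)) {
      g <- buildResidueGraph(m, k = k)
      expect_identical(g@neighbors, brute_knn(xyz, k))
    }
  }
})

## --- sequence assignment ---------------------------------------------------

fake_hit <- function(chain, target, ali) {
  h <- data.frame(query_chain = chain, target_id = target,
                  bit_score = 10, e_value = 1e-5,
                  stringsAsFactors = FALSE)
  h$alignment <- list(ali)
  h
}

test_that("an all-M alignment mutates the chain to the target letters in order", {
  m <- ca_model(cbind(c(0, 4, 8), 0, 0), res_name = "GLY")
  db <- Biostrings::AAStringSet(c(t1 = "MKV"))
  ali <- data.frame(node = 1:3, pos = 1:3, state = "M")
  res <- assignAndMutate(m, list(onehot_profile("GGG")),
                         list(A = fake_hit("A", "t1", ali)), db)
  rt <- residueTable(res$model)
  expect_identical(rt$res_name, c("MET", "LYS", "VAL"))
  expect_identical(rt$seq_pos, 1:3)
  expect_identical(res$assignment$chains$target_id, "t1")
})

test_that("delete-state residues keep their argmax identity with seq_pos unset", {
  m <- ca_model(cbind(c(0, 4, 8), 0, 0), res_name = "GLY")
  db <- Biostrings::AAStringSet(c(t1 = "MV"))
  ali <- data.frame(node = c(1, 2, 3), pos = c(1, NA, 2),
                    state = c("M", "D", "M"))
  rp <- onehot_profile("WWW")  # argmax identity TRP everywhere
  res <- assignAndMutate(m, list(rp), list(A = fake_hit("A", "t1", ali)), db)
  rt <- residueTable(res$model)
  expect_identical(rt$res_name, c("MET", "TRP", "VAL"))
  expect_identical(rt$seq_pos, c(1L, NA_integer_, 2L))
  ## matched positions strictly increase
  sp <- rt$seq_pos[!is.na(rt$seq_pos)]
  expect_true(all(diff(sp) > 0))
})

test_that("chains without hits are left unchanged and UNK mode works", {
  m <- ca_model(cbind(c(0, 4), 0, 0), res_name = "GLY")
  db <- Biostrings::AAStringSet(c(t1 = "MV"))
  res <- assignAndMutate(m, list(onehot_profile("WW")), list(), db)
  expect_identical(residueTable(res$model)$res_name, c("GLY", "GLY"))
  expect_identical(nrow(res$assignment$chains), 0L)

  ali <- data.frame(node = 1, pos = 1, state = "M")
  res2 <- assignAndMutate(m, list(onehot_profile("WW")),
                          list(A = fake_hit("A", "t1", ali)), db,
                          unmatchedAsUnk = TRUE)
  expect_identical(residueTable(res2$model)$res_name, c("MET", "UNK"))
})

test_that("alignments beyond the chain length are rejected", {
  m <- ca_model(cbind(c(0, 4), 0, 0))
  db <- Biostrings::AAStringSet(c(t1 = "MKV"))
  ali <- data.frame(node = 1:3, pos = 1:3, state = "M")
  expect_error(
    assignAndMutate(m, list(onehot_profile("AA")),
                    list(A = fake_hit("A", "t1", ali)), db),
    "beyond chain length")
})

## --- chain connection ------------------------------------------------------

two_fragment_model <- function(gap_xyz = 3.8) {
  xyz1 <- cbind(seq(0, by = 3.8, length.out = 10), 0, 0)
  xyz2 <- cbind(seq(max(xyz1[, 1]) + gap_xyz, by = 3.8,
                    length.out = 10), 0, 0)
  AtomicModel(rbind(atomTable(ca_model(xyz1, chain = "A")),
                    atomTable(ca_model(xyz2, chain = "B"))))
}

two_fragment_assignment <- function(tgt = "t1") {
  list(chains = data.frame(chain = c("A", "B"),
                           target_id = c(tgt, tgt),
                           stringsAsFactors = FALSE),
       residues = data.frame(chain = rep(c("A", "B"), each = 10),
                             res_idx = rep(1:10, 2),
                             seq_pos = c(1:10, 11:20),
                             stringsAsFactors = FALSE))
}

test_that("adjacent fragments of one target merge into a single chain", {
  m <- two_fragment_model(3.8)
  out <- connectChains(m, two_fragment_assignment())
  expect_identical(unname(chainLengths(out)), 20L)
  expect_identical(chainIds(out), "A")
  ## residue order preserved: x increases along the merged chain
  rt <- residueTable(out)
  expect_true(all(diff(rt$ax) > 0))
})

test_that("distant termini and distinct targets are never merged", {
  m <- two_fragment_model(50)
  out <- connectChains(m, two_fragment_assignment())
  expect_identical(length(chainIds(out)), 2L)

  m2 <- two_fragment_model(3.8)
  asn <- two_fragment_assignment()
  asn$chains$target_id <- c("t1", "t2")
  out2 <- connectChains(m2, asn)
  expect_identical(length(chainIds(out2)), 2L)
})

test_that("the gap rule scales the allowed distance by g + 1", {
  ## gap of 2 unbuilt residues: termini 11 A apart is <= 3.8 * 3
  m <- two_fragment_model(11)
  asn <- two_fragment_assignment()
  asn$residues$seq_pos <- c(1:10, 13:22)
  out <- connectChains(m, asn)
  expect_identical(unname(chainLengths(out)), 20L)
  ## same geometry but gap 0: 11 A > 3.8, no merge
  out0 <- connectChains(m, two_fragment_assignment())
  expect_identical(length(chainIds(out0)), 2L)
  ## overlapping ranges never merge
  asn_bad <- two_fragment_assignment()
  asn_bad$residues$seq_pos <- c(1:10, 5:14)
  expect_identical(length(chainIds(connectChains(m, asn_bad))), 2L)
})

test_that("residue counts are conserved by assignment and connection", {
  m <- two_fragment_model(3.8)
  n0 <- nResidues(m)
  out <- connectChains(m, two_fragment_assignment())
  expect_identical(nResidues(out), n0)
})

## --- pruning ---------------------------------------------------------------

test_that("chains shorter than four residues are pruned, longer ones kept", {
  chains <- lapply(1:10, function(n) {
    atomTable(ca_model(cbind(seq_len(n) * 3.8, n * 10, 0),
                       chain = sprintf("c%02d", n)))
  })
  m <- AtomicModel(do.call(rbind, chains))
  out <- pruneChains(m)
  expect_identical(unname(chainLengths(out)), 4:10)
  ## minLen = 1 is the identity
  expect_identical(chainLengths(pruneChains(m, minLen = 1)),
                   chainLengths(m))
  ## pruning everything yields a valid empty model
  expect_identical(nResidues(pruneChains(m, minLen = 99)), 0L)
})

test_that("two short fragments that connect into one long chain survive pruning", {
  xyz1 <- cbind(c(0, 3.8), 0, 0)
  xyz2 <- cbind(c(7.6, 11.4), 0, 0)
  m <- AtomicModel(rbind(atomTable(ca_model(xyz1, chain = "A")),
                         atomTable(ca_model(xyz2, chain = "B"))))
  asn <- list(chains = data.frame(chain = c("A", "B"), target_id = "t",
                                  stringsAsFactors = FALSE),
              residues = data.frame(chain = rep(c("A", "B"), each = 2),
                                    res_idx = rep(1:2, 2),
                                    seq_pos = 1:4,
                                    stringsAsFactors = FALSE))
  merged <- connectChains(m, asn)
  expect_identical(unname(chainLengths(merged)), 4L)
  expect_identical(unname(chainLengths(pruneChains(merged))), 4L)
  ## without connection both fragments would have been pruned
  expect_identical(nResidues(pruneChains(m)), 0L)
})
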