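## Shared fixture builders. Everything is generated in code; no binary data.

AA20 <- densid:::AA_ALPHABET

## One-hot residue profile for an exact sequence, confidence constant.
onehot_profile <- function(seq, conf = 0.9, chain = "A") {
  genProfile(seq, eta = 0, confRange = c(conf, conf), seed = 1,
             chainId = chain)
}

## Random valid ResidueProfile (Dirichlet-ish rows via normalized gammas).
random_profile <- function(L, chain = "A") {
  P <- matrix(stats::rgamma(L * 20, shape = 0.5), L, 20)
  P <- P / rowSums(P)
  ResidueProfile(chain, P, stats::runif(L))
}

## Minimal single-residue atom table.
ala_atoms <- function(chain = "A", score = 0.8) {
  data.frame(chain = chain, res_idx = 1L, res_name = "ALA",
             seq_pos = NA_integer_,
             atom = c("N", "CA", "C", "O"),
             x = c(0, 1.458, 2.009, 1.383),
             y = c(0, 0, 1.42, 2.34), z = c(0, 0, 0, 0.2),
             score = score, stringsAsFactors = FALSE)
}

## Model with CA-only residues at given coordinates (n x 3), one chain.
ca_model <- function(xyz, chain = "A", res_name = "ALA", score = NA_real_) {
  n <- nrow(xyz)
  AtomicModel(data.frame(
    chain = chain, res_idx = seq_len(n),
    res_name = rep_len(res_name, n), seq_pos = NA_integer_, atom = "CA",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    score = rep_len(score, n), stringsAsFactors = FALSE))
}
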