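# Shared fixtures and independent oracles. Heavy simulations elsewhere in
# the suite are scaled down relative to the module contracts where noted,
# to keep the default run within budget; the acceptance tests keep the
# stated sizes.

JTT <- jtt_model()
UNIF <- uniform_model()

row_str <- function(aln, tx) paste(aln$mat[tx, ], collapse = "")

# simulate one pair of sequences separated by total distance t
simulate_pair <- function(t, n, model, seed) {
  set.seed(seed)
  root <- sample.int(20L, n, replace = TRUE, prob = model$pi)
  P <- transition_matrix(model, t)
  child <- integer(n)
  for (i in unique(root)) {
    ii <- root == i
    child[ii] <- sample.int(20L, sum(ii), replace = TRUE, prob = P[i, ])
  }
  list(a = paste(AA_ALPHABET[root], collapse = ""),
       b = paste(AA_ALPHABET[child], collapse = ""))
}

# Poisson-model closed-form distance: the independent oracle for the
# uniform control model (20 states, equal rates)
poisson_distance <- function(p) -(19 / 20) * log(1 - 20 * p / 19)

rand_additive_tree <- function(n, seed) {
  set.seed(seed)
  ape::rtree(n, br = function(k) stats::runif(k, 0.05, 1))
}

# invert the full-length dilution of a region/full-length rate ratio:
# if a region of length Ls inside a protein of length L evolves at
# multiplier m in one clade, that clade's expected region ratio is
# r = m*L / (m*Ls + (L - Ls)); solving for m gives the estimator below.
invert_dilution <- function(r, L, Ls) r * (L - Ls) / (L - r * Ls)

aln_from_rows <- function(...) {
  rows <- list(...)
  as_alignment(seq_records(names(rows), unlist(rows)))
}
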