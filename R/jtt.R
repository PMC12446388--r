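#' Build a reversible amino-acid substitution model
#'
#' Assembles a time-reversible continuous-time Markov model from symmetric
#' exchangeabilities \eqn{S} and equilibrium frequencies \eqn{\pi}:
#' \eqn{Q_{ij} = S_{ij}\pi_j} for \eqn{i \ne j}, diagonal set so rows sum
#' to zero, and the whole matrix scaled so the expected substitution rate
#' at equilibrium, \eqn{-\sum_i \pi_i Q_{ii}}, equals 1. Branch lengths are
#' then in expected substitutions per site. The eigendecomposition of the
#' symmetrized rate matrix is cached on the model so that transition
#' matrices \eqn{P(t) = e^{Qt}} are cheap and numerically stable.
#'
#' @param S symmetric non-negative 20x20 exchangeability matrix, zero
#'   diagonal, rows/cols in `ARNDCQEGHILKMFPSTWYV` order.
#' @param pi equilibrium frequency vector (length 20, positive, sums to 1).
#' @return An object of class `subst_model` with elements `alphabet`, `S`,
#'   `pi`, `Q` and cached spectral factors.
#' @export
build_model <- function(S, pi) {
  k <- length(AA_ALPHABET)
  S <- unname(as.matrix(S))
  pi <- unname(as.numeric(pi))
  if (!all(dim(S) == k) || length(pi) != k) stop("S must be 20x20, pi length 20")
  if (any(pi <= 0)) stop("pi entries must be > 0 (reversibility undefined)")
  if (abs(sum(pi) - 1) > 1e-8) pi <- pi / sum(pi)
  if (max(abs(S - t(S))) > 1e-8 || any(S < 0)) {
    stop("S must be symmetric and non-negative")
  }
  diag(S) <- 0
  Q <- S * rep(pi, each = k)        # Q_ij = S_ij * pi_j
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))          # expected rate at equilibrium
  if (mu <= 0) stop("degenerate model: zero substitution rate")
  Q <- Q / mu
  # symmetrize: B = D^{1/2} Q D^{-1/2} with D = diag(pi); B symmetric
  d <- sqrt(pi)
  B <- Q * (d %o% (1 / d))
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  U <- eig$vectors / d              # row-scaled: D^{-1/2} V
  W <- t(eig$vectors * d)           # V' D^{1/2}
  structure(list(alphabet = AA_ALPHABET, S = S, pi = pi, Q = Q,
                 eigenvalues = eig$values, U = U, W = W),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat("subst_model: 20-state reversible amino-acid model,",
      "expected rate 1\n")
  invisible(x)
}

#' Load the packaged JTT model
#'
#' Reads the embedded plain-text table of the published JTT
#' (Jones-Taylor-Thornton) replacement model — lower-triangle
#' exchangeabilities and equilibrium frequencies in canonical
#' `ARNDCQEGHILKMFPSTWYV` order — and builds the normalized model.
#'
#' @param path optional path to an alternative model file in the same
#'   layout; defaults to the packaged JTT table.
#' @return A `subst_model`.
#' @export
jtt_model <- function(path = trpa1evo_extdata("jtt_model.txt")) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines[!startsWith(trimws(lines), "#")])
  lines <- lines[nzchar(lines)]
  # line 1: alphabet; lines 2..20: lower triangle rows 2..20; last: frequencies
  alpha <- strsplit(lines[1L], "[[:space:]]+")[[1L]]
  if (!identical(alpha, AA_ALPHABET)) {
    stop("model file alphabet must be ", paste(AA_ALPHABET, collapse = ""))
  }
  S <- matrix(0, 20L, 20L)
  for (i in 2:20) {
    row <- as.numeric(strsplit(lines[i], "[[:space:]]+")[[1L]])
    if (length(row) != i - 1L) stop("bad lower-triangle row ", i)
    S[i, seq_len(i - 1L)] <- row
  }
  S <- S + t(S)
  pi <- as.numeric(strsplit(lines[21L], "[[:space:]]+")[[1L]])
  build_model(S, pi)
}

#' Uniform (Poisson-style) control model
#'
#' All exchangeabilities equal and frequencies uniform; the ML distance
#' under this model has the closed form
#' \eqn{\hat t = -\frac{19}{20}\ln(1 - \frac{20p}{19})} for observed
#' difference fraction \eqn{p}, which the tests use as an independent
#' oracle for the numeric optimizer.
#'
#' @return A `subst_model`.
#' @export
uniform_model <- function() {
  S <- matrix(1, 20L, 20L); diag(S) <- 0
  build_model(S, rep(1 / 20, 20L))
}

#' Transition probability matrix
#'
#' \eqn{P(t) = e^{Qt}} computed from the cached spectral factors of the
#' reversible rate matrix. Tiny negative entries from roundoff are clipped
#' to zero and rows renormalized.
#'
#' @param model a `subst_model`.
#' @param t branch length in expected substitutions per site (finite,
#'   `>= 0`).
#' @return A 20x20 row-stochastic matrix.
#' @export
transition_matrix <- function(model, t) {
  if (!is.finite(t) || t < 0) stop("t must be finite and >= 0")
  P <- model$U %*% (exp(model$eigenvalues * t) * model$W)
  P[P < 0] <- 0
  P / rowSums(P)
}

.aa_index <- function(chars) match(chars, AA_ALPHABET)

# 20x20 count matrix of aligned residue pairs over comparable columns
# (both standard amino acids); gaps and 'X' are excluded.
pair_count_matrix <- function(a, b) {
  if (length(a) == 1L) a <- strsplit(a, "", fixed = TRUE)[[1L]]
  if (length(b) == 1L) b <- strsplit(b, "", fixed = TRUE)[[1L]]
  if (length(a) != length(b)) stop("sequences must have equal length")
  ia <- .aa_index(a); ib <- .aa_index(b)
  ok <- !is.na(ia) & !is.na(ib)
  N <- matrix(0, 20L, 20L)
  if (any(ok)) {
    tab <- table(factor(ia[ok], levels = 1:20), factor(ib[ok], levels = 1:20))
    N <- unclass(tab)
  }
  N
}

#' Maximum-likelihood pairwise distance
#'
#' Estimates the evolutionary distance \eqn{\hat t} between two aligned
#' residue strings by maximizing
#' \eqn{\ell(t) = \sum_{\mathrm{columns}} \log(\pi_a P_{ab}(t))}
#' over comparable columns (both residues standard amino acids), using
#' bounded scalar optimization on \eqn{[0, t_{max}]}. Identical sequences
#' give \eqn{\hat t = 0}; an estimate at the upper bound is flagged
#' saturated.
#'
#' @param a,b gapped residue strings (or character vectors) of equal length.
#' @param model a `subst_model`.
#' @param t_max upper optimization bound defining saturation (default 20).
#' @param tol absolute optimizer tolerance on `t` (default 1e-6).
#' @return List with `t_hat`, `log_likelihood`, `n_sites`, `saturated`.
#' @export
pairwise_ml_distance <- function(a, b, model, t_max = 20, tol = 1e-6) {
  N <- pair_count_matrix(a, b)
  n <- sum(N)
  if (n == 0L) stop("no comparable columns: distance undefined")
  logpi <- sum(rowSums(N) * log(model$pi))
  nll <- function(t) {
    P <- transition_matrix(model, t)
    lp <- suppressWarnings(log(P))
    lp[N == 0] <- 0
    -(logpi + sum(N * lp))
  }
  n_diff <- n - sum(diag(N))
  if (n_diff == 0L) {
    return(list(t_hat = 0, log_likelihood = -nll(0), n_sites = n,
                saturated = FALSE))
  }
  opt <- optimize(nll, c(0, t_max), tol = tol)
  t_hat <- opt$minimum
  # optimize() never returns exact endpoints; check the boundary explicitly
  if (nll(t_max) <= opt$objective) t_hat <- t_max
  list(t_hat = t_hat, log_likelihood = -nll(t_hat), n_sites = n,
       saturated = t_hat >= t_max - tol)
}

#' All pairwise ML distances of an alignment
#'
#' Computes the symmetric matrix of pairwise ML distances under the model.
#' With `deletion = "complete"` (the classical MEGA-style default, used by
#' the pipeline) columns containing any gap or `X` are removed once for the
#' whole alignment; with `"pairwise"` each pair uses all of its own
#' comparable columns.
#'
#' @param aln an [aa_alignment].
#' @param model a `subst_model`.
#' @param deletion `"complete"` or `"pairwise"`.
#' @param allow_saturated keep saturated estimates (at `t_max`) instead of
#'   erroring.
#' @param t_max,tol passed to [pairwise_ml_distance].
#' @return A `dist_matrix`: list with `taxa`, `values` (symmetric, zero
#'   diagonal), `support` (comparable-column counts) and `saturated`
#'   (logical matrix).
#' @export
distance_matrix <- function(aln, model, deletion = c("complete", "pairwise"),
                            allow_saturated = FALSE, t_max = 20, tol = 1e-6) {
  deletion <- match.arg(deletion)
  mat <- aln$mat
  if (deletion == "complete") {
    keep <- colSums(!matrix(mat %in% AA_ALPHABET, nrow(mat))) == 0L
    mat <- mat[, keep, drop = FALSE]
    if (!ncol(mat)) stop("complete deletion removed every column")
  }
  tx <- rownames(mat)
  k <- length(tx)
  V <- matrix(0, k, k, dimnames = list(tx, tx))
  Sup <- matrix(0L, k, k, dimnames = list(tx, tx))
  Sat <- matrix(FALSE, k, k, dimnames = list(tx, tx))
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      est <- tryCatch(
        pairwise_ml_distance(mat[i, ], mat[j, ], model,
                             t_max = t_max, tol = tol),
        error = function(e) stop("pair (", tx[i], ", ", tx[j], "): ",
                                 conditionMessage(e)))
      if (est$saturated && !allow_saturated) {
        stop("saturated distance for pair (", tx[i], ", ", tx[j],
             "); pass allow_saturated = TRUE to keep it")
      }
      V[i, j] <- V[j, i] <- est$t_hat
      Sup[i, j] <- Sup[j, i] <- est$n_sites
      Sat[i, j] <- Sat[j, i] <- est$saturated
    }
  }
  structure(list(taxa = tx, values = V, support = Sup, saturated = Sat,
                 deletion = deletion),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("dist_matrix: %d taxa, %s deletion\n",
              length(x$taxa), x$deletion))
  print(round(x$values, 4))
  invisible(x)
}

#' Write a distance matrix
#'
#' `write_dist_phylip` emits the PHYLIP square layout; `write_dist_long`
#' a tab-separated long table (`taxon_a`, `taxon_b`, `distance`,
#' `n_sites`) with a `#` metadata header.
#'
#' @param d a `dist_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dist_phylip <- function(d, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%5d", length(d$taxa)), con)
  for (i in seq_along(d$taxa)) {
    writeLines(paste(c(sprintf("%-10s", d$taxa[i]),
                       sprintf("%.8f", d$values[i, ])), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_dist_phylip
#' @export
write_dist_long <- function(d, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# pairwise ML distances; deletion=%s", d$deletion), con)
  writeLines("taxon_a\ttaxon_b\tdistance\tn_sites", con)
  for (i in seq_len(length(d$taxa) - 1L)) {
    for (j in seq.int(i + 1L, length(d$taxa))) {
      writeLines(sprintf("%s\t%s\t%.8f\t%d", d$taxa[i], d$taxa[j],
                         d$values[i, j], d$support[i, j]), con)
    }
  }
  invisible(path)
}
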