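#' Read / write Newick trees
#'
#' Thin wrappers around `ape` that normalize error reporting. Trees are
#' `ape::phylo` objects throughout the package; branch lengths are expected
#' substitutions per site.
#'
#' @param path file path.
#' @return `read_newick` returns an `ape::phylo`; `write_newick` returns
#'   `path` invisibly. Round-trips preserve topology and branch lengths to
#'   at least 10 significant digits.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close) {
    stop("Newick parse error: unbalanced parentheses in ", path)
  }
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("Newick parse error: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error: no tree in ", path)
  tr
}

#' @rdname read_newick
#' @param tree an `ape::phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 15)
  invisible(path)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining, deterministic given the matrix:
#' ties in the Q criterion are broken by the smallest (row, column) index
#' pair of the current matrix, and negative intermediate branch lengths are
#' clamped to zero with the deficit transferred to the sibling branch
#' (clamp count recorded in `attr(tree, "n_clamped")`). Exact on additive
#' matrices.
#'
#' @param d a `dist_matrix` (from [distance_matrix]) or a labeled symmetric
#'   numeric matrix; at least 3 taxa, all finite.
#' @param allow_saturated proceed even if `d` carries saturated pairs.
#' @return An unrooted `ape::phylo`.
#' @export
neighbor_joining <- function(d, allow_saturated = FALSE) {
  if (inherits(d, "dist_matrix")) {
    if (!allow_saturated && any(d$saturated)) {
      stop("distance matrix contains saturated pairs; ",
           "pass allow_saturated = TRUE to proceed")
    }
    D <- d$values
  } else {
    D <- as.matrix(d)
  }
  if (is.null(rownames(D))) stop("distance matrix must be labeled")
  if (nrow(D) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (any(!is.finite(D))) stop("distance matrix must be finite")
  labs <- rownames(D)
  # working newick fragments per active node
  frag <- labs
  n_clamped <- 0L
  clamp2 <- function(bi, bj) {
    if (bi < 0) { bj <- bj + bi; bi <- 0; n_clamped <<- n_clamped + 1L }
    if (bj < 0) { bi <- bi + bj; bj <- 0; n_clamped <<- n_clamped + 1L }
    c(max(bi, 0), max(bj, 0))
  }
  while (nrow(D) > 3L) {
    r <- nrow(D)
    u <- rowSums(D)
    Qc <- (r - 2) * D - outer(u, u, `+`)
    diag(Qc) <- Inf
    # smallest Q with deterministic (row, column) tie-break
    best <- which(Qc == min(Qc), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1L, ]
    i <- best[1L]; j <- best[2L]
    bi <- D[i, j] / 2 + (u[i] - u[j]) / (2 * (r - 2))
    bj <- D[i, j] - bi
    b <- clamp2(bi, bj)
    newfrag <- sprintf("(%s:%.17g,%s:%.17g)", frag[i], b[1L], frag[j], b[2L])
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    frag <- c(frag[keep], newfrag)
    rownames(D2) <- colnames(D2) <- seq_len(r - 1L)
    D <- D2
  }
  # resolve the final star of three
  ba <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  bb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  bc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  neg <- c(ba, bb, bc) < 0
  if (any(neg)) { n_clamped <- n_clamped + sum(neg) }
  ba <- max(ba, 0); bb <- max(bb, 0); bc <- max(bc, 0)
  nwk <- sprintf("(%s:%.17g,%s:%.17g,%s:%.17g);",
                 frag[1L], ba, frag[2L], bb, frag[3L], bc)
  tr <- ape::read.tree(text = nwk)
  attr(tr, "n_clamped") <- n_clamped
  tr
}

# --- pruning machinery -----------------------------------------------------

# Compress an alignment into site patterns keyed to a tree's tip order.
# Returns list(idx = ntip x npat integer matrix (NA = gap/X), w = weights).
site_patterns <- function(aln, tip_labels) {
  miss <- setdiff(tip_labels, taxa(aln))
  if (length(miss)) {
    stop("alignment lacks tree taxa: ", paste(miss, collapse = ", "))
  }
  mat <- aln$mat[tip_labels, , drop = FALSE]
  idx <- matrix(.aa_index(mat), nrow = nrow(mat))
  key <- apply(idx, 2L, paste, collapse = ",")
  first <- !duplicated(key)
  w <- as.vector(table(factor(key, levels = key[first])))
  list(idx = idx[, first, drop = FALSE], w = w)
}

# Tip conditional-likelihood matrices (20 x npat), one per tip row of idx.
tip_conditionals <- function(idx) {
  npat <- ncol(idx)
  lapply(seq_len(nrow(idx)), function(i) {
    L <- matrix(0, 20L, npat)
    known <- !is.na(idx[i, ])
    L[cbind(idx[i, known], which(known))] <- 1
    L[, !known] <- 1
    L
  })
}

# Postorder conditional likelihoods for every node.
# scale = TRUE tracks per-pattern log-scalers (needed for exact logLik);
# scale = FALSE rescales without tracking (argmax-safe only).
down_pass <- function(tree, model, tips, scale = TRUE) {
  ntip <- length(tree$tip.label)
  nn <- max(tree$edge)
  L <- vector("list", nn)
  L[seq_len(ntip)] <- tips
  logsc <- rep(0, ncol(tips[[1L]]))
  ord <- seq_len(nrow(tree$edge))   # tree assumed in postorder
  for (e in ord) {
    par <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    P <- transition_matrix(model, tree$edge.length[e])
    contrib <- P %*% L[[ch]]
    L[[par]] <- if (is.null(L[[par]])) contrib else L[[par]] * contrib
  }
  # rescale internal nodes (after the fact is enough at these tree sizes)
  root <- ntip + 1L
  if (scale) {
    sc <- apply(L[[root]], 2L, max)
    sc[sc == 0] <- 1
    L[[root]] <- sweep(L[[root]], 2L, sc, `/`)
    logsc <- log(sc)
  }
  list(L = L, logsc = logsc)
}

#' Tree log-likelihood by Felsenstein pruning
#'
#' Computes the log-likelihood of an alignment on a tree under the model,
#' summing per-site likelihoods over compressed site patterns, with the
#' stationary distribution as the root prior. By time-reversibility the
#' value is independent of root placement. Columns where a taxon has a gap
#' or `X` treat that taxon's state as missing.
#'
#' @param tree an `ape::phylo` whose tip labels match the alignment taxa.
#' @param aln an [aa_alignment].
#' @param model a `subst_model`.
#' @return The log-likelihood (a scalar).
#' @export
tree_log_likelihood <- function(tree, aln, model) {
  tree <- ape::reorder.phylo(tree, "postorder")
  pat <- site_patterns(aln, tree$tip.label)
  tips <- tip_conditionals(pat$idx)
  dp <- down_pass(tree, model, tips, scale = TRUE)
  root <- length(tree$tip.label) + 1L
  site <- colSums(model$pi * dp$L[[root]])
  sum(pat$w * (log(site) + dp$logsc))
}

# Preorder "up" conditionals along the path from the root to node `target`.
# U[v]_j = P(data outside subtree(v) | state j at v), with pi folded in at
# the root. Only ancestors of `target` (and target itself) are computed.
up_to_node <- function(tree, model, L, target) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  npat <- ncol(L[[root]])
  parent_of <- integer(max(tree$edge))
  elen_of <- numeric(max(tree$edge))
  parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
  elen_of[tree$edge[, 2L]] <- tree$edge.length
  path <- target
  while (path[1L] != root) path <- c(parent_of[path[1L]], path)
  U <- matrix(model$pi, 20L, npat)
  for (k in seq_along(path)[-1L]) {
    p <- path[k - 1L]; v <- path[k]
    sibs <- tree$edge[tree$edge[, 1L] == p, 2L]
    sibs <- sibs[sibs != v]
    acc <- U
    for (s in sibs) {
      acc <- acc * (transition_matrix(model, elen_of[s]) %*% L[[s]])
    }
    U <- crossprod(transition_matrix(model, elen_of[v]), acc)
    U <- U / max(U)
  }
  U
}

# Single-branch ML length given the flanking conditionals.
# Safeguarded Newton on the log-likelihood derivative, using analytic
# dP/dt = U diag(lambda e^{lambda t}) W from the cached spectral factors;
# falls back to Brent if the iteration misbehaves. Bounded on [0, t_max].
opt_branch <- function(Fmat, G, w, model, t0, t_max) {
  ev <- model$eigenvalues
  t <- min(max(t0, 1e-6), t_max - 1e-6)
  lo <- 0; hi <- t_max
  ok <- FALSE
  for (it in seq_len(25L)) {
    E <- exp(ev * t)
    P <- model$U %*% (E * model$W)
    s <- colSums(Fmat * (P %*% G))
    if (any(s <= 0) || any(!is.finite(s))) break
    s1 <- colSums(Fmat * ((model$U %*% ((ev * E) * model$W)) %*% G))
    s2 <- colSums(Fmat * ((model$U %*% ((ev * ev * E) * model$W)) %*% G))
    g <- sum(w * s1 / s)                       # d loglik / dt
    h <- sum(w * (s2 * s - s1 * s1) / (s * s)) # d2 loglik / dt2
    if (g > 0) lo <- t else hi <- t
    if (abs(g) < 1e-9 * sum(w)) { ok <- TRUE; break }
    tn <- if (is.finite(h) && h < 0) t - g / h else (lo + hi) / 2
    if (!is.finite(tn) || tn <= lo || tn >= hi) tn <- (lo + hi) / 2
    if (abs(tn - t) < 1e-9) { t <- tn; ok <- TRUE; break }
    t <- tn
  }
  if (!ok && (hi - lo) > 1e-7) {
    negll <- function(tt) {
      site <- colSums(Fmat * (transition_matrix(model, tt) %*% G))
      -sum(w * log(site))
    }
    opt <- optimize(negll, c(0, t_max), tol = 1e-7)
    t <- opt$minimum
    if (negll(0) <= opt$objective) t <- 0
  }
  max(min(t, t_max), 0)
}

#' Maximum-likelihood branch lengths on a fixed topology
#'
#' Round-robin bounded scalar optimization of each branch length (Brent's
#' method on `[0, t_max]`), holding the others fixed, repeated until the
#' total log-likelihood improves by less than `tol_ll` or `max_sweeps` is
#' reached. The log-likelihood is non-decreasing across sweeps. If the
#' sweep cap is hit without convergence the returned tree carries
#' `attr(, "converged") = FALSE` (a warning flag, not an error).
#'
#' @param tree starting `ape::phylo` with branch lengths.
#' @param aln an [aa_alignment] whose taxa match the tree tips.
#' @param model a `subst_model`.
#' @param max_sweeps sweep cap (default 50).
#' @param tol_ll convergence tolerance on the total log-likelihood.
#' @param t_max upper bound per branch.
#' @return The tree with optimized `edge.length`; attributes `logLik`,
#'   `converged`, `n_sweeps`.
#' @export
optimize_branch_lengths <- function(tree, aln, model, max_sweeps = 50L,
                                    tol_ll = 1e-6, t_max = 20) {
  orig <- tree
  tree <- ape::reorder.phylo(tree, "postorder")
  pat <- site_patterns(aln, tree$tip.label)
  tips <- tip_conditionals(pat$idx)
  w <- pat$w
  ntip <- length(tree$tip.label)
  nn <- max(tree$edge)
  root <- ntip + 1L
  parent_of <- integer(nn)
  parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
  kids <- lapply(seq_len(nn), function(v) tree$edge[tree$edge[, 1L] == v, 2L])
  elen <- numeric(nn)                       # branch length above each node
  elen[tree$edge[, 2L]] <- tree$edge.length
  L <- vector("list", nn)
  L[seq_len(ntip)] <- tips
  node_partial <- function(v) {
    acc <- NULL
    for (ch in kids[[v]]) {
      contrib <- transition_matrix(model, elen[ch]) %*% L[[ch]]
      acc <- if (is.null(acc)) contrib else acc * contrib
    }
    acc
  }
  # initial postorder fill (tree$edge is postorder: children precede parents)
  for (v in unique(tree$edge[, 1L])) L[[v]] <- node_partial(v)
  refresh_up <- function(v) {
    repeat {
      L[[v]] <<- node_partial(v)
      if (v == root) break
      v <- parent_of[v]
    }
  }
  loglik_now <- function() sum(w * log(colSums(model$pi * L[[root]])))
  ll_prev <- loglik_now()
  converged <- FALSE
  sweep_i <- 0L
  for (sweep_i in seq_len(max_sweeps)) {
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
      U <- up_to_node(tree, model, L, p)
      Fmat <- U
      for (s in kids[[p]][kids[[p]] != ch]) {
        Fmat <- Fmat * (transition_matrix(model, elen[s]) %*% L[[s]])
      }
      G <- L[[ch]]
      cand <- opt_branch(Fmat, G, w, model, elen[ch], t_max)
      tree$edge.length[e] <- cand
      elen[ch] <- cand
      refresh_up(p)
    }
    ll <- loglik_now()
    if (ll < ll_prev - 1e-9) {
      warning("log-likelihood decreased during a sweep; keeping result")
    }
    if (abs(ll - ll_prev) < tol_ll) { converged <- TRUE; ll_prev <- ll; break }
    ll_prev <- ll
  }
  # hand lengths back in the caller's edge order (reorder permutes rows)
  key <- paste(tree$edge[, 1L], tree$edge[, 2L])
  orig$edge.length <- tree$edge.length[
    match(paste(orig$edge[, 1L], orig$edge[, 2L]), key)]
  attr(orig, "converged") <- converged
  attr(orig, "logLik") <- ll_prev
  attr(orig, "n_sweeps") <- sweep_i
  orig
}

#' Patristic distance matrix
#'
#' Sums of branch lengths along the unique tree path between every pair of
#' tips.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @return A `dist_matrix` whose `values` are the patristic distances.
#' @export
patristic_matrix <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  V <- ape::cophenetic.phylo(tree)
  V <- V[tree$tip.label, tree$tip.label]
  structure(list(taxa = tree$tip.label, values = V,
                 support = matrix(NA_integer_, nrow(V), ncol(V),
                                  dimnames = dimnames(V)),
                 saturated = matrix(FALSE, nrow(V), ncol(V),
                                    dimnames = dimnames(V)),
                 deletion = "none"),
            class = "dist_matrix")
}

#' Root-to-tip path lengths
#'
#' @param tree a *rooted* `ape::phylo` with branch lengths; unrooted input
#'   is an error (midpoint-root first, see [midpoint_root]).
#' @return Named numeric vector: taxon to root-to-tip path length.
#' @export
root_to_tip <- function(tree) {
  if (!ape::is.rooted(tree)) {
    stop("tree is unrooted; root it first (e.g. midpoint_root(tree))")
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  d <- ape::node.depth.edgelength(tree)
  setNames(d[seq_along(tree$tip.label)], tree$tip.label)
}

#' Midpoint rooting
#'
#' Roots the tree at the midpoint of the longest tip-to-tip path
#' (delegates to `phangorn::midpoint`).
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @return A rooted `ape::phylo`.
#' @export
midpoint_root <- function(tree) phangorn::midpoint(tree)

#' Root at an outgroup taxon
#' @param tree an `ape::phylo`.
#' @param outgroup tip label to use as outgroup.
#' @return A rooted `ape::phylo`.
#' @export
outgroup_root <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label) stop("outgroup not in tree: ", outgroup)
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}
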