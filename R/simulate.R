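#' Simulation configuration
#'
#' Describes a clade-structured protein-evolution simulation: a rooted
#' tree (or a random-tree recipe), a sequence length, a domain map on the
#' (gap-free) simulated reference, per-(clade, region) rate multipliers,
#' an optional planted diagnostic column, and a mandatory seed.
#'
#' Rate multipliers act on branches: a multiplier entry
#' `list(taxa = <tip set>, region = <region name>, multiplier = r)` scales
#' the branch length by `r` at sites inside `region`, on every branch whose
#' descendant tips all lie inside `taxa` (i.e. the subtree spanned by the
#' clade). All other branch/site combinations evolve at rate 1.
#'
#' @param seq_length number of simulated sites.
#' @param seed integer seed (mandatory; all randomness derives from it).
#' @param tree optional rooted `ape::phylo` with branch lengths; if `NULL`,
#'   a random topology with `n_taxa` tips is drawn with branch lengths
#'   uniform in `branch_range`.
#' @param n_taxa number of tips for the random-tree recipe.
#' @param branch_range branch-length range for the recipe (expected
#'   substitutions per site).
#' @param domain_map optional [domain_map] used to resolve region names;
#'   defaults to a single `full_length` region.
#' @param rate_multipliers list of multiplier entries (see above).
#' @param planted_column optional
#'   `list(position = <reference position>, residues = <named vector:
#'   taxon or group pattern -> residue letter>)`; the column is overwritten
#'   after simulation.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seq_length, seed, tree = NULL, n_taxa = NULL,
                       branch_range = c(0.02, 0.3), domain_map = NULL,
                       rate_multipliers = list(), planted_column = NULL) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  for (m in rate_multipliers) {
    if (!is.numeric(m$multiplier) || m$multiplier <= 0) {
      stop("rate multipliers must be > 0")
    }
  }
  if (!is.null(planted_column)) {
    if (planted_column$position < 1L || planted_column$position > seq_length) {
      stop("planted position outside sequence length")
    }
  }
  if (is.null(tree) && is.null(n_taxa)) stop("give a tree or n_taxa")
  structure(list(seq_length = as.integer(seq_length),
                 seed = as.integer(seed), tree = tree,
                 n_taxa = if (is.null(n_taxa)) NULL else as.integer(n_taxa),
                 branch_range = branch_range, domain_map = domain_map,
                 rate_multipliers = rate_multipliers,
                 planted_column = planted_column),
            class = "sim_config")
}

# descendant tip labels per node
node_descendants <- function(tree) {
  ntip <- length(tree$tip.label)
  tre <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", max(tre$edge))
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(tre$edge))) {
    p <- tre$edge[e, 1L]; ch <- tre$edge[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

#' Simulate a protein alignment along a tree
#'
#' Draws the root sequence from the model's stationary distribution, then
#' evolves it down the tree: each branch applies \eqn{P(r t)} per site,
#' where \eqn{r} is the site's region multiplier on branches inside the
#' configured clade subtree and 1 otherwise. A configured planted column
#' is overwritten last. Deterministic per seed; alignments are gap-free.
#'
#' @param config a [sim_config].
#' @param model a `subst_model` (packaged JTT by default).
#' @return A `sim_dataset`: list with `alignment`, `tree` (rooted, with
#'   true branch lengths), `domain_map`, and `truth` (multipliers, planted
#'   column, seed).
#' @export
simulate_alignment <- function(config, model = jtt_model()) {
  set.seed(config$seed)
  tree <- config$tree
  if (is.null(tree)) {
    tree <- ape::rtree(config$n_taxa,
                       br = function(n) stats::runif(n, config$branch_range[1L],
                                                     config$branch_range[2L]))
  }
  if (!ape::is.rooted(tree)) stop("simulation tree must be rooted")
  nsites <- config$seq_length
  # per-site region id (0 = background), resolved once
  site_region <- rep(0L, nsites)
  region_names <- character(0)
  mults <- config$rate_multipliers
  if (length(mults)) {
    if (is.null(config$domain_map)) stop("rate multipliers need a domain map")
    region_names <- unique(vapply(mults, `[[`, "", "region"))
    for (k in seq_along(region_names)) {
      iv <- config$domain_map$regions[[region_names[k]]]
      if (is.null(iv)) stop("multiplier region not in domain map: ",
                            region_names[k])
      for (r in seq_len(nrow(iv))) {
        site_region[seq.int(iv[r, "start"], min(iv[r, "end"], nsites))] <- k
      }
    }
  }
  desc <- node_descendants(tree)
  ntip <- length(tree$tip.label)
  nn <- max(tree$edge)
  # per-edge, per-region-slot multiplier
  edge_mult <- matrix(1, nrow(tree$edge), length(region_names) + 1L)
  for (m in mults) {
    k <- match(m$region, region_names) + 1L
    inside <- vapply(tree$edge[, 2L],
                     function(ch) all(desc[[ch]] %in% m$taxa), logical(1L))
    edge_mult[inside, k] <- edge_mult[inside, k] * m$multiplier
  }
  states <- matrix(NA_integer_, nn, nsites)
  root <- ntip + 1L
  states[root, ] <- sample.int(20L, nsites, replace = TRUE, prob = model$pi)
  tre <- ape::reorder.phylo(tree, "cladewise")   # parents before children
  eord <- seq_len(nrow(tre$edge))
  for (e in eord) {
    p <- tre$edge[e, 1L]; ch <- tre$edge[e, 2L]; t <- tre$edge.length[e]
    em <- edge_mult[match(paste(tre$edge[e, 1L], tre$edge[e, 2L]),
                          paste(tree$edge[, 1L], tree$edge[, 2L])), ]
    site_mult <- em[site_region + 1L]
    child <- integer(nsites)
    for (r in unique(site_mult)) {
      P <- transition_matrix(model, r * t)
      sel <- which(site_mult == r)
      par_states <- states[p, sel]
      for (i in unique(par_states)) {
        ii <- sel[par_states == i]
        child[ii] <- sample.int(20L, length(ii), replace = TRUE, prob = P[i, ])
      }
    }
    states[ch, ] <- child
  }
  rows <- matrix(AA_ALPHABET[states[seq_len(ntip), , drop = FALSE]], ntip)
  rownames(rows) <- tree$tip.label
  planted <- config$planted_column
  if (!is.null(planted)) {
    for (tx in tree$tip.label) {
      res <- planted$residues[[tx]]
      if (!is.null(res)) rows[tx, planted$position] <- res
    }
  }
  aln <- structure(list(mat = rows,
                        description = setNames(rep("", ntip),
                                               tree$tip.label)),
                   class = "aa_alignment")
  structure(list(alignment = aln, tree = tree,
                 domain_map = config$domain_map,
                 truth = list(rate_multipliers = mults,
                              planted_column = planted,
                              seed = config$seed)),
            class = "sim_dataset")
}

# clade-structured tree: one rooted subtree per group joined on a backbone
clade_tree <- function(group_taxa, subtree_branch = c(0.02, 0.15),
                       backbone_branch = c(0.04, 0.12)) {
  sub <- lapply(names(group_taxa), function(g) {
    tx <- group_taxa[[g]]
    if (length(tx) == 1L) {
      sprintf("%s:%.6f", tx, stats::runif(1, subtree_branch[1L],
                                          subtree_branch[2L]))
    } else {
      tr <- ape::rtree(length(tx),
                       br = function(n) stats::runif(n, subtree_branch[1L],
                                                     subtree_branch[2L]))
      tr$tip.label <- tx[as.integer(factor(tr$tip.label,
                                           levels = paste0("t", seq_along(tx))))]
      sub("; *$", "", ape::write.tree(tr))
    }
  })
  bb <- function() stats::runif(1, backbone_branch[1L], backbone_branch[2L])
  while (length(sub) > 1L) {
    merged <- sprintf("(%s:%.6f,%s:%.6f)", sub[[1L]], bb(), sub[[2L]], bb())
    sub <- c(list(merged), sub[-(1:2)])
  }
  ape::read.tree(text = paste0(sub[[1L]], ";"))
}

#' Marine-mammal style test fixture
#'
#' Simulates the data structure of the marine-vs-terrestrial comparison:
#' 16 taxa in 4 labeled clade groups (ids 14-17, mimicking the
#' Sirenia / Proboscidea / Afroinsectiphilia / Cetacea grouping), three
#' equal-length regions (`sensor`, `middle`, `pore`) plus `full_length`,
#' with the `sensor` region evolving at an elevated multiplier (default
#' x3) in the designated "aquatic" group (group 14) and rate 1 elsewhere.
#'
#' @param seed integer seed.
#' @param sensor_multiplier rate multiplier of the aquatic clade's sensor
#'   region (1 gives the null fixture).
#' @param region_length sites per region (total length = 3x this).
#' @param taxa_per_group taxa in each of the 4 groups.
#' @param model a `subst_model`.
#' @return A `sim_dataset` with additional elements `clade_groups`,
#'   `aquatic_group` (14) and truth recording the multiplier.
#' @export
make_marine_fixture <- function(seed, sensor_multiplier = 3,
                                region_length = 300L, taxa_per_group = 4L,
                                model = jtt_model()) {
  set.seed(seed)
  gdef <- list(`14` = "sirenia", `15` = "proboscidea",
               `16` = "afroinsectiphilia", `17` = "cetacea")
  group_taxa <- lapply(gdef, function(nm) paste0(nm, "_", seq_len(taxa_per_group)))
  tree <- clade_tree(group_taxa)
  L <- as.integer(region_length)
  dmap <- domain_map(reference_taxon = group_taxa[[1L]][1L],
                     reference_length = 3L * L,
                     regions = list(sensor = c(1L, L),
                                    middle = c(L + 1L, 2L * L),
                                    pore = c(2L * L + 1L, 3L * L)))
  mults <- if (sensor_multiplier != 1) {
    list(list(taxa = group_taxa[[1L]], region = "sensor",
              multiplier = sensor_multiplier))
  } else list()
  cfg <- sim_config(seq_length = 3L * L, seed = seed + 1L, tree = tree,
                    domain_map = dmap, rate_multipliers = mults)
  ds <- simulate_alignment(cfg, model)
  ds$clade_groups <- clade_group_table(
    taxon_id = unlist(group_taxa, use.names = FALSE),
    group_id = rep(as.integer(names(gdef)), lengths(group_taxa)),
    group_name = rep(c("Sirenia", "Proboscidea", "Afroinsectiphilia",
                       "Cetacea"), lengths(group_taxa)),
    superorder = rep(c("Afrotheria", "Afrotheria", "Afrotheria",
                       "Laurasiatheria"), lengths(group_taxa)))
  ds$aquatic_group <- 14L
  ds$truth$sensor_multiplier <- sensor_multiplier
  ds
}

#' Residue-scan test fixture
#'
#' Simulates the diagnostic-residue pattern at the S5 position: four clade
#' groups with a planted column carrying valine (V) in the
#' lagomorph-, squirrel- and primate-like groups and glycine (G) in the
#' myomorph-like group, plus thermal labels (`cold` for the G group,
#' `insensitive` for the V groups). The reference taxon is named
#' `human_TRPA1` and sits in the primate-like group.
#'
#' @param seed integer seed.
#' @param seq_length simulated length (default 120).
#' @param position planted diagnostic position on the gap-free reference
#'   (default 80; stands in for human residue 878 at fixture scale).
#' @param taxa_per_group taxa per group.
#' @param model a `subst_model`.
#' @return A `sim_dataset` with `clade_groups`, `thermal_labels`, and
#'   truth recording the planted residues and position.
#' @export
make_residue_fixture <- function(seed, seq_length = 120L, position = 80L,
                                 taxa_per_group = 3L, model = jtt_model()) {
  set.seed(seed)
  gdef <- data.frame(
    group_id = c(23L, 24L, 25L, 26L),
    group_name = c("Sciuromorpha_like", "Lagomorpha", "Myomorpha",
                   "Primates"),
    residue = c("V", "V", "G", "V"),
    thermal = c("insensitive", "insensitive", "cold", "insensitive"),
    stringsAsFactors = FALSE)
  stem <- c("sciuromorpha", "lagomorpha", "myomorpha", "primates")
  group_taxa <- lapply(seq_len(4L), function(k) {
    tx <- paste0(stem[k], "_", seq_len(taxa_per_group))
    if (gdef$group_id[k] == 26L) tx[1L] <- "human_TRPA1"
    tx
  })
  names(group_taxa) <- as.character(gdef$group_id)
  tree <- clade_tree(group_taxa)
  planted_res <- setNames(rep(gdef$residue, lengths(group_taxa)),
                          unlist(group_taxa, use.names = FALSE))
  dmap <- domain_map(reference_taxon = "human_TRPA1",
                     reference_length = as.integer(seq_length),
                     regions = list(S5 = c(max(1L, position - 10L),
                                           min(seq_length, position + 15L))))
  cfg <- sim_config(seq_length = seq_length, seed = seed + 1L, tree = tree,
                    domain_map = dmap,
                    planted_column = list(position = as.integer(position),
                                          residues = as.list(planted_res)))
  ds <- simulate_alignment(cfg, model)
  ds$clade_groups <- clade_group_table(
    taxon_id = unlist(group_taxa, use.names = FALSE),
    group_id = rep(gdef$group_id, lengths(group_taxa)),
    group_name = rep(gdef$group_name, lengths(group_taxa)),
    superorder = "Euarchontoglires")
  ds$thermal_labels <- setNames(gdef$thermal, as.character(gdef$group_id))
  ds$truth$planted_residues <- planted_res
  ds$truth$position <- as.integer(position)
  ds
}

#' Write a simulated dataset to a directory
#'
#' Emits aligned FASTA, Newick, the clade table and a truth table, each
#' with a `#`-style seed header where the format allows one.
#'
#' @param ds a `sim_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(ds$alignment, file.path(dir, "alignment.fasta"))
  write_newick(ds$tree, file.path(dir, "tree.nwk"))
  if (!is.null(ds$clade_groups)) {
    con <- file(file.path(dir, "clade_groups.tsv"), "w")
    writeLines(sprintf("# seed=%d", ds$truth$seed), con)
    close(con)
    suppressWarnings(
      write.table(as.data.frame(ds$clade_groups),
                  file.path(dir, "clade_groups.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE, append = TRUE))
  }
  con <- file(file.path(dir, "truth.tsv"), "w")
  writeLines(sprintf("# seed=%d", ds$truth$seed), con)
  for (m in ds$truth$rate_multipliers) {
    writeLines(sprintf("multiplier\t%s\t%g\t%s", m$region, m$multiplier,
                       paste(m$taxa, collapse = ",")), con)
  }
  if (!is.null(ds$truth$planted_column)) {
    writeLines(sprintf("planted_position\t%d", ds$truth$planted_column$position),
               con)
  }
  close(con)
  invisible(dir)
}
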