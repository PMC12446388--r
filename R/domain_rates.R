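#' Map ungapped reference positions to alignment columns
#'
#' Anchors reference-protein coordinates (e.g. human TRPA1 residue
#' numbering) onto a multiple alignment: the k-th non-gap character of the
#' reference row maps to its alignment column; reference gap columns are
#' skipped. The map is strictly increasing and has one entry per ungapped
#' reference residue.
#'
#' @param aln an [aa_alignment].
#' @param reference_taxon taxon id of the reference row.
#' @return Integer vector `map` with `map[pos]` = alignment column of
#'   ungapped reference position `pos`.
#' @export
map_reference_columns <- function(aln, reference_taxon) {
  if (!reference_taxon %in% taxa(aln)) {
    stop("reference taxon not in alignment: ", reference_taxon)
  }
  ref <- aln$mat[reference_taxon, ]
  which(ref != GAP_CHAR)
}

#' Slice an alignment to a named region
#'
#' Maps the region's reference intervals through [map_reference_columns]
#' and concatenates the corresponding column ranges (all taxa retained).
#' Columns that are all-gap after slicing are dropped; their count is kept
#' in `attr(, "n_dropped_allgap")`.
#'
#' @param aln an [aa_alignment] containing the reference taxon.
#' @param dmap a [domain_map].
#' @param region_name a region present in `dmap$regions`.
#' @return The sliced [aa_alignment].
#' @export
slice_region <- function(aln, dmap, region_name) {
  if (!region_name %in% names(dmap$regions)) {
    stop("region not in domain map: ", region_name)
  }
  iv <- dmap$regions[[region_name]]
  cmap <- map_reference_columns(aln, dmap$reference_taxon)
  if (any(iv[, "end"] > length(cmap))) {
    stop("region '", region_name, "' extends beyond the ungapped reference ",
         "length (", length(cmap), ")")
  }
  cols <- unlist(lapply(seq_len(nrow(iv)), function(r) {
    cmap[seq.int(iv[r, "start"], iv[r, "end"])]
  }), use.names = FALSE)
  subset_columns(aln, cols, drop_all_gap = TRUE)
}

#' Per-clade-group distance summary
#'
#' Summarizes phylogenetic distances for the members of one clade group on
#' a tree, under one of two schemes: `root_to_tip` (each member's path
#' length from the root; the tree must be rooted — midpoint rooting is the
#' pipeline default) or `mean_pairwise_within_group` (each member's mean
#' patristic distance to the other group members; undefined for singleton
#' groups). The standard deviation uses the n-1 denominator and is `NA`
#' for a single-member group.
#'
#' @param tree an `ape::phylo` with branch lengths (rooted for
#'   `root_to_tip`).
#' @param clade_groups a `clade_group_table`.
#' @param group_id integer group to summarize.
#' @param scheme `"root_to_tip"` or `"mean_pairwise_within_group"`.
#' @return List with `group_id`, `scheme`, `distances` (named per-taxon
#'   vector), `mean`, `sd` (`NA` when n = 1), `n`.
#' @export
group_distance_summary <- function(tree, clade_groups, group_id,
                                   scheme = c("root_to_tip",
                                              "mean_pairwise_within_group")) {
  scheme <- match.arg(scheme)
  members <- intersect(tree$tip.label,
                       clade_groups$taxon_id[clade_groups$group_id == group_id])
  if (!length(members)) stop("no members of group ", group_id, " in tree")
  if (scheme == "root_to_tip") {
    d <- root_to_tip(tree)[members]
  } else {
    if (length(members) < 2L) {
      stop("mean_pairwise_within_group undefined for singleton group ",
           group_id)
    }
    V <- patristic_matrix(tree)$values[members, members, drop = FALSE]
    d <- rowSums(V) / (length(members) - 1L)
  }
  list(group_id = as.integer(group_id), scheme = scheme, distances = d,
       mean = mean(d), sd = if (length(d) > 1L) sd(d) else NA_real_,
       n = length(d))
}

#' Default pipeline configuration
#'
#' @param regions regions to analyze besides `full_length` (which is always
#'   included and is the ratio denominator).
#' @param scheme distance scheme, see [group_distance_summary].
#' @param deletion gap-deletion scheme for ML distances, see
#'   [distance_matrix].
#' @param rooting `"midpoint"` or `"outgroup"`.
#' @param outgroup outgroup tip label (required if `rooting = "outgroup"`).
#' @param shared_topology reuse the full-length tree topology for every
#'   region (branch lengths still re-optimized per region) instead of
#'   rebuilding each region's tree independently.
#' @param allow_saturated tolerate saturated pairwise distances.
#' @return A named list of options.
#' @export
rate_config <- function(regions = NULL,
                        scheme = c("root_to_tip",
                                   "mean_pairwise_within_group"),
                        deletion = c("complete", "pairwise"),
                        rooting = c("midpoint", "outgroup"),
                        outgroup = NULL,
                        shared_topology = FALSE,
                        allow_saturated = FALSE) {
  list(regions = regions, scheme = match.arg(scheme),
       deletion = match.arg(deletion), rooting = match.arg(rooting),
       outgroup = outgroup, shared_topology = isTRUE(shared_topology),
       allow_saturated = isTRUE(allow_saturated))
}

# region -> fitted, rooted tree (NJ topology + ML branch lengths)
fit_region_tree <- function(aln_region, model, config, topology = NULL) {
  D <- distance_matrix(aln_region, model, deletion = config$deletion,
                       allow_saturated = config$allow_saturated)
  tre <- if (is.null(topology)) {
    neighbor_joining(D, allow_saturated = config$allow_saturated)
  } else topology
  tre <- optimize_branch_lengths(tre, aln_region, model)
  rooted <- if (config$rooting == "outgroup") {
    outgroup_root(tre, config$outgroup)
  } else midpoint_root(tre)
  list(tree = rooted, unrooted = tre, distances = D)
}

#' Region / full-length rate-ratio report
#'
#' The pipeline's central statistic. For each configured region (always
#' including `full_length`): slice the alignment, estimate all pairwise ML
#' distances under the model, build a neighbor-joining topology, fit ML
#' branch lengths by Felsenstein pruning, root the tree, and summarize
#' per-clade-group phylogenetic distances. Each group's regional mean is
#' finally expressed as a ratio to the same group's full-length mean, so
#' the `full_length` rows have ratio exactly 1. Elevated ratios in a region
#' are read as an elevated relative substitution rate (relaxed selection)
#' for that group in that region.
#'
#' @param aln an [aa_alignment] containing the domain map's reference
#'   taxon.
#' @param dmap a [domain_map] (regions must include `full_length`).
#' @param clade_groups a `clade_group_table` covering the alignment taxa.
#' @param model a `subst_model` (the packaged JTT model by default).
#' @param config a [rate_config].
#' @return A `rate_ratio_report`: data.frame with columns `group_id`,
#'   `group_name`, `region`, `n`, `mean`, `sd`, `ratio`, plus attributes
#'   `metadata` (scheme strings) and `trees` (per-region rooted trees).
#' @export
rate_ratio_report <- function(aln, dmap, clade_groups, model = jtt_model(),
                              config = rate_config()) {
  regions <- unique(c("full_length",
                      config$regions %||% setdiff(names(dmap$regions),
                                                  "full_length")))
  miss <- setdiff(regions, names(dmap$regions))
  if (length(miss)) stop("regions not in domain map: ",
                         paste(miss, collapse = ", "))
  unknown <- setdiff(taxa(aln), clade_groups$taxon_id)
  if (length(unknown)) stop("taxa missing from clade table: ",
                            paste(unknown, collapse = ", "))
  groups <- sort(unique(clade_groups$group_id[clade_groups$taxon_id %in%
                                                taxa(aln)]))
  fits <- list()
  topology <- NULL
  for (rg in regions) {
    sl <- tryCatch(slice_region(aln, dmap, rg),
                   error = function(e) stop("region '", rg, "': ",
                                            conditionMessage(e)))
    fit <- tryCatch(fit_region_tree(sl, model, config, topology = topology),
                    error = function(e) stop("region '", rg, "': ",
                                             conditionMessage(e)))
    fits[[rg]] <- fit
    if (config$shared_topology && rg == "full_length") {
      topology <- fit$unrooted
    }
  }
  summaries <- lapply(regions, function(rg) {
    lapply(groups, function(g) {
      tryCatch(group_distance_summary(fits[[rg]]$tree, clade_groups, g,
                                      scheme = config$scheme),
               error = function(e) stop("region '", rg, "', group ", g, ": ",
                                        conditionMessage(e)))
    })
  })
  names(summaries) <- regions
  full_means <- vapply(summaries$full_length, `[[`, 0, "mean")
  names(full_means) <- groups
  rows <- do.call(rbind, lapply(regions, function(rg) {
    do.call(rbind, lapply(seq_along(groups), function(k) {
      s <- summaries[[rg]][[k]]
      g <- groups[k]
      gname <- clade_groups$group_name[match(g, clade_groups$group_id)]
      ratio <- if (rg == "full_length") 1 else s$mean / full_means[[as.character(g)]]
      data.frame(group_id = g, group_name = gname, region = rg, n = s$n,
                 mean = s$mean, sd = s$sd, ratio = ratio,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(rows) <- NULL
  structure(rows,
            class = c("rate_ratio_report", "data.frame"),
            metadata = list(scheme = config$scheme,
                            deletion = config$deletion,
                            rooting = config$rooting,
                            topology = if (config$shared_topology)
                              "shared-full-length" else "per-region NJ + ML branch lengths"),
            trees = lapply(fits, `[[`, "tree"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a rate-ratio report
#'
#' Tab-separated table with a `#` metadata comment header recording the
#' distance scheme, deletion scheme, rooting and topology strategy.
#'
#' @param report a `rate_ratio_report`.
#' @param path output path.
#' @param extra named character vector of extra metadata lines.
#' @return `path`, invisibly.
#' @export
write_rate_report <- function(report, path, extra = NULL) {
  md <- attr(report, "metadata")
  con <- file(path, "w"); on.exit(close(con))
  hdr <- c(sprintf("# scheme=%s", md$scheme),
           sprintf("# deletion=%s", md$deletion),
           sprintf("# rooting=%s", md$rooting),
           sprintf("# topology=%s", md$topology))
  if (!is.null(extra)) hdr <- c(hdr, sprintf("# %s=%s", names(extra), extra))
  writeLines(hdr, con)
  writeLines(paste(c("group_id", "group_name", "region", "n", "mean", "sd",
                     "ratio"), collapse = "\t"), con)
  for (i in seq_len(nrow(report))) {
    writeLines(paste(c(report$group_id[i], report$group_name[i],
                       report$region[i], report$n[i],
                       sprintf("%.6f", report$mean[i]),
                       ifelse(is.na(report$sd[i]), "NA",
                              sprintf("%.6f", report$sd[i])),
                       sprintf("%.6f", report$ratio[i])),
                     collapse = "\t"), con)
  }
  invisible(path)
}
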