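#' Call the residue at a reference-anchored position for every taxon
#'
#' Locates the alignment column homologous to an ungapped position of the
#' reference protein (human TRPA1 residue 878 by default — the S5 position
#' whose valine/glycine state tracks TRPA1 cold sensitivity in
#' Euarchontoglires) and reports each taxon's residue there, classified as
#' `V`, `G`, `other`, or `gap`.
#'
#' @param aln an [aa_alignment].
#' @param reference_taxon taxon id of the reference row.
#' @param position 1-based position on the ungapped reference (default
#'   878).
#' @return A `residue_calls` data.frame with columns `taxon_id`,
#'   `reference_position`, `alignment_column`, `residue`, `call_class`.
#' @export
call_reference_residue <- function(aln, reference_taxon, position = 878L) {
  cmap <- map_reference_columns(aln, reference_taxon)
  position <- as.integer(position)
  if (position < 1L || position > length(cmap)) {
    stop("position ", position, " outside ungapped reference length (",
         length(cmap), ")")
  }
  col <- cmap[position]
  res <- aln$mat[, col]
  cls <- ifelse(res == "V", "V",
                ifelse(res == "G", "G",
                       ifelse(res == GAP_CHAR, "gap", "other")))
  structure(data.frame(taxon_id = taxa(aln),
                       reference_position = position,
                       alignment_column = col,
                       residue = unname(res),
                       call_class = unname(cls),
                       stringsAsFactors = FALSE),
            class = c("residue_calls", "data.frame"))
}

#' Tabulate residue calls by clade group
#'
#' Counts `V` / `G` / `other` / `gap` calls per clade group and attaches
#' the curated thermal-sensitivity label (`unknown` for unlabeled groups).
#' Groups are ordered by `group_id`.
#'
#' @param calls a `residue_calls` table from [call_reference_residue].
#' @param clade_groups a `clade_group_table` covering every called taxon.
#' @param thermal optional named label vector from [load_thermal_labels].
#' @return A `residue_by_clade` data.frame with columns `group_id`,
#'   `group_name`, `n_V`, `n_G`, `n_other`, `n_gap`, `n_total`,
#'   `thermal_label`.
#' @export
tabulate_by_clade <- function(calls, clade_groups, thermal = NULL) {
  if (nrow(calls) == 0L) {
    out <- data.frame(group_id = integer(), group_name = character(),
                      n_V = integer(), n_G = integer(), n_other = integer(),
                      n_gap = integer(), n_total = integer(),
                      thermal_label = character(), stringsAsFactors = FALSE)
    return(structure(out, class = c("residue_by_clade", "data.frame")))
  }
  m <- match(calls$taxon_id, clade_groups$taxon_id)
  if (anyNA(m)) {
    stop("taxa missing from clade table: ",
         paste(calls$taxon_id[is.na(m)], collapse = ", "))
  }
  gid <- clade_groups$group_id[m]
  groups <- sort(unique(gid))
  out <- do.call(rbind, lapply(groups, function(g) {
    cls <- calls$call_class[gid == g]
    lab <- if (!is.null(thermal) && as.character(g) %in% names(thermal)) {
      thermal[[as.character(g)]]
    } else "unknown"
    data.frame(group_id = g,
               group_name = clade_groups$group_name[
                 match(g, clade_groups$group_id)],
               n_V = sum(cls == "V"), n_G = sum(cls == "G"),
               n_other = sum(cls == "other"), n_gap = sum(cls == "gap"),
               n_total = length(cls), thermal_label = lab,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  structure(out, class = c("residue_by_clade", "data.frame"))
}

#' Extract a display region (e.g. the S5 helix) from an alignment
#'
#' Convenience wrapper over [slice_region] for reporting the alignment
#' block around the diagnostic residue.
#'
#' @param aln an [aa_alignment].
#' @param dmap a [domain_map] containing the region.
#' @param region region name (default `"S5"`).
#' @return The sliced [aa_alignment].
#' @export
extract_region_alignment <- function(aln, dmap, region = "S5") {
  slice_region(aln, dmap, region)
}
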