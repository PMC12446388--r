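N_CLADE_GROUPS <- 26L
THERMAL_LEVELS <- c("heat", "cold", "insensitive", "unknown")

#' Load a clade-group membership table
#'
#' Reads a tab-separated table with header columns `taxon_id`, `group_id`,
#' `group_name`, `superorder` assigning each taxon to one of the 26
#' taxonomic clade groups (class to infraorder) used to pool species in the
#' comparative analysis. The packaged default
#' (`system.file("extdata", "clade_groups.tsv", package = "trpa1evo")`)
#' carries one or more representative taxa for each of the 26 groups.
#'
#' @param path path to a tab-separated table.
#' @return A `clade_group_table`: a data.frame with the four columns above.
#' @export
load_clade_groups <- function(path) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("taxon_id", "group_id", "group_name", "superorder")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("clade table lacks columns: ",
                         paste(miss, collapse = ", "))
  tab <- tab[, need]
  tab$group_id <- as.integer(tab$group_id)
  if (any(is.na(tab$group_id)) ||
      any(tab$group_id < 1L | tab$group_id > N_CLADE_GROUPS)) {
    stop("group_id must be an integer in 1..", N_CLADE_GROUPS)
  }
  dup <- tab$taxon_id[duplicated(tab$taxon_id)]
  if (length(dup)) {
    stop("taxon assigned to more than one group: ",
         paste(unique(dup), collapse = ", "))
  }
  structure(tab, class = c("clade_group_table", "data.frame"))
}

#' @rdname load_clade_groups
#' @param taxon_id,group_id,group_name,superorder column vectors.
#' @export
clade_group_table <- function(taxon_id, group_id, group_name,
                              superorder = "") {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  write.table(data.frame(taxon_id = taxon_id, group_id = group_id,
                         group_name = group_name,
                         superorder = rep_len(superorder, length(taxon_id))),
              tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  load_clade_groups(tmp)
}

#' Load thermal-sensitivity labels per clade group
#'
#' Tab-separated table with columns `group_id`, `label`; labels are one of
#' `heat`, `cold`, `insensitive`, `unknown` (curated from published
#' electrophysiology). Groups absent from the table are `unknown`.
#'
#' @param path path to the table.
#' @param clade_groups optional `clade_group_table`; if given, every labeled
#'   group_id must exist there.
#' @return Named character vector: `group_id` (as names) to label.
#' @export
load_thermal_labels <- function(path, clade_groups = NULL) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("group_id", "label") %in% names(tab))) {
    stop("thermal label table needs columns group_id, label")
  }
  if (!all(tab$label %in% THERMAL_LEVELS)) {
    stop("labels must be one of: ", paste(THERMAL_LEVELS, collapse = ", "))
  }
  if (!is.null(clade_groups)) {
    bad <- setdiff(tab$group_id, clade_groups$group_id)
    if (length(bad)) stop("labeled group_id not in clade table: ",
                          paste(bad, collapse = ", "))
  }
  setNames(tab$label, as.character(tab$group_id))
}

#' Load a domain map
#'
#' The domain map names regions of the reference protein (human TRPA1 by
#' convention) as 1-based inclusive intervals on the *ungapped* reference
#' sequence. The config is a flat `key: value` text format (a YAML subset):
#'
#' ```
#' reference: human_TRPA1
#' reference_length: 1119
#' region full_length: 1-1119
#' region ARD1_9: 1-445
#' ard ARD1: 1-33
#' ```
#'
#' `region` keys define analysis regions (values are comma-separated
#' `start-end` intervals, non-overlapping and sorted within a region);
#' `ard` keys form the ankyrin-repeat sub-annotation. `full_length` is
#' derived as `1-reference_length` when absent.
#'
#' @param path path to the config file.
#' @return A `domain_map`: list with `reference_taxon`, `reference_length`,
#'   `regions` (named list of 2-column start/end matrices) and `ard`
#'   (named list, same shape).
#' @export
load_domain_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  if (any(lengths(kv) != 3L)) {
    stop("domain map: lines must be 'key: value'")
  }
  keys <- trimws(vapply(kv, `[`, "", 2L))
  vals <- trimws(vapply(kv, `[`, "", 3L))
  ref <- vals[keys == "reference"]
  if (!length(ref)) stop("domain map lacks a 'reference' entry")
  ref_len <- vals[keys == "reference_length"]
  ref_len <- if (length(ref_len)) as.integer(ref_len[1L]) else NA_integer_
  parse_intervals <- function(v, name) {
    parts <- trimws(strsplit(v, ",", fixed = TRUE)[[1L]])
    m <- regmatches(parts, regexec("^([0-9]+)\\s*-\\s*([0-9]+)$", parts))
    if (any(lengths(m) != 3L)) {
      stop("domain map region '", name, "': intervals must be start-end")
    }
    iv <- cbind(start = as.integer(vapply(m, `[`, "", 2L)),
                end   = as.integer(vapply(m, `[`, "", 3L)))
    if (any(iv[, "end"] < iv[, "start"]) || any(iv[, "start"] < 1L)) {
      stop("domain map region '", name, "': end < start or start < 1")
    }
    if (nrow(iv) > 1L) {
      o <- order(iv[, "start"])
      if (!identical(o, seq_len(nrow(iv)))) {
        stop("domain map region '", name, "': intervals must be sorted")
      }
      if (any(iv[-1L, "start"] <= iv[-nrow(iv), "end"])) {
        stop("domain map region '", name, "': overlapping intervals")
      }
    }
    iv
  }
  pick <- function(prefix) {
    sel <- startsWith(keys, paste0(prefix, " "))
    nm <- trimws(sub(paste0("^", prefix, " "), "", keys[sel]))
    setNames(Map(parse_intervals, vals[sel], nm), nm)
  }
  regions <- pick("region")
  ard <- pick("ard")
  if (!is.na(ref_len)) {
    too_far <- vapply(c(regions, ard), function(iv) any(iv[, "end"] > ref_len),
                      logical(1L))
    if (any(too_far)) {
      stop("domain map: intervals beyond reference length in: ",
           paste(names(c(regions, ard))[too_far], collapse = ", "))
    }
    if (!"full_length" %in% names(regions)) {
      regions$full_length <- cbind(start = 1L, end = ref_len)
    }
  } else if (!"full_length" %in% names(regions)) {
    stop("domain map: give reference_length or an explicit full_length region")
  }
  structure(list(reference_taxon = ref[1L],
                 reference_length = if (is.na(ref_len))
                   max(regions$full_length[, "end"]) else ref_len,
                 regions = regions, ard = ard),
            class = "domain_map")
}

#' @export
print.domain_map <- function(x, ...) {
  cat(sprintf("domain_map on '%s' (length %d): %d regions, %d ARD entries\n",
              x$reference_taxon, x$reference_length,
              length(x$regions), length(x$ard)))
  invisible(x)
}

#' Build a domain map in code
#'
#' @param reference_taxon taxon id of the reference sequence.
#' @param reference_length ungapped reference length.
#' @param regions named list; each element a 2-column matrix or a numeric
#'   `c(start, end)` pair (or an n x 2 matrix of intervals).
#' @param ard optional named list like `regions` for the ARD sub-annotation.
#' @return A `domain_map`.
#' @export
domain_map <- function(reference_taxon, reference_length, regions,
                       ard = list()) {
  norm <- function(x) {
    if (is.matrix(x)) {
      m <- cbind(start = as.integer(x[, 1L]), end = as.integer(x[, 2L]))
    } else {
      m <- cbind(start = as.integer(x[1L]), end = as.integer(x[2L]))
    }
    m
  }
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  con <- file(tmp, "w")
  writeLines(c(paste0("reference: ", reference_taxon),
               paste0("reference_length: ", as.integer(reference_length))),
             con)
  fmt <- function(prefix, lst) {
    for (nm in names(lst)) {
      m <- norm(lst[[nm]])
      writeLines(paste0(prefix, " ", nm, ": ",
                        paste(sprintf("%d-%d", m[, 1L], m[, 2L]),
                              collapse = ",")), con)
    }
  }
  fmt("region", regions)
  fmt("ard", ard)
  close(con)
  load_domain_map(tmp)
}

#' Read the climate fixture table
#'
#' Tab-separated columns `park`, `month`, `mean_daily_min`, `cold_nights`,
#' `mean_daily_max`, `hot_days`, temperatures in degrees Celsius; months are
#' `Nov` or `Dec`. The packaged fixture transcribes the 30-year November and
#' December records of the three southern-African national parks used to
#' pick the experimental temperature range.
#'
#' @param path path to the table.
#' @return A `climate_table` data.frame.
#' @export
read_climate_table <- function(path) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("park", "month", "mean_daily_min", "cold_nights",
            "mean_daily_max", "hot_days")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("climate table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (!all(tab$month %in% c("Nov", "Dec"))) {
    stop("climate table months must be Nov or Dec")
  }
  num <- tab[, need[3:6]]
  if (!all(vapply(num, is.numeric, logical(1L))) ||
      any(!is.finite(as.matrix(num)))) {
    stop("climate table temperatures must be finite numbers")
  }
  structure(tab[, need], class = c("climate_table", "data.frame"))
}

#' Path to a packaged fixture
#' @param name file name under `inst/extdata`.
#' @return Absolute path.
#' @export
trpa1evo_extdata <- function(name) {
  p <- system.file("extdata", name, package = "trpa1evo", mustWork = FALSE)
  if (!nzchar(p)) stop("no packaged file named ", name)
  p
}
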