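round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Column averages of the climate fixture
#'
#' Arithmetic mean of each temperature column over all rows, rounded
#' half-up to one decimal — the "Average Temperature" row of the packaged
#' November/December park-climate table.
#'
#' @param table a `climate_table` from [read_climate_table].
#' @return Named numeric vector over `mean_daily_min`, `cold_nights`,
#'   `mean_daily_max`, `hot_days` (degrees Celsius, one decimal).
#' @export
climate_summary <- function(table) {
  if (nrow(table) < 1L) stop("climate table is empty")
  cols <- c("mean_daily_min", "cold_nights", "mean_daily_max", "hot_days")
  vapply(table[cols], function(v) round_half_up(mean(v), 1L), numeric(1L))
}

config_hash <- function(obj) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(obj), collapse = ""), tmp)
  unname(tools::md5sum(tmp))
}

provenance_lines <- function(config, seed = NA) {
  c(sprintf("# config_hash=%s", config_hash(config)),
    sprintf("# seed=%s", ifelse(is.na(seed), "NA", seed)),
    sprintf("# scheme=%s deletion=%s rooting=%s",
            config$scheme %||% "NA", config$deletion %||% "NA",
            config$rooting %||% "NA"))
}

#' Run the domain-rate analysis end to end
#'
#' Slices every configured region, estimates ML distances under the JTT
#' model, builds and fits per-region trees, summarizes per-clade-group
#' distances and writes the region/full-length rate-ratio report, the
#' per-region Newick trees and a log file to `out_dir`.
#'
#' @param aln an [aa_alignment] (or a path to an aligned FASTA).
#' @param clade_groups a `clade_group_table` (or a path).
#' @param dmap a [domain_map] (or a path to its config file).
#' @param out_dir output directory.
#' @param model a `subst_model`.
#' @param config a [rate_config].
#' @return The `rate_ratio_report`, invisibly; artifacts on disk.
#' @export
run_domain_rates <- function(aln, clade_groups, dmap, out_dir,
                             model = jtt_model(), config = rate_config()) {
  if (is.character(aln)) aln <- read_alignment(aln)
  if (is.character(clade_groups)) clade_groups <- load_clade_groups(clade_groups)
  if (is.character(dmap)) dmap <- load_domain_map(dmap)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  report <- rate_ratio_report(aln, dmap, clade_groups, model, config)
  write_rate_report(report, file.path(out_dir, "rate_ratios.tsv"),
                    extra = c(config_hash = config_hash(config)))
  trees <- attr(report, "trees")
  for (rg in names(trees)) {
    write_newick(trees[[rg]], file.path(out_dir, paste0("tree_", rg, ".nwk")))
  }
  writeLines(c(provenance_lines(config),
               sprintf("# regions=%s", paste(unique(report$region),
                                             collapse = ",")),
               sprintf("# elapsed_s=%.2f",
                       as.numeric(difftime(Sys.time(), t0, units = "secs")))),
             file.path(out_dir, "run.log"))
  invisible(report)
}

#' Run the residue scan end to end
#'
#' Calls the residue at the reference-anchored position for every taxon,
#' tabulates calls per clade group with thermal labels, writes both tables
#' and an aligned-FASTA dump of the display region (if present in the
#' domain map) to `out_dir`.
#'
#' @param aln an [aa_alignment] (or path).
#' @param clade_groups a `clade_group_table` (or path).
#' @param dmap a [domain_map] (or path); its reference taxon anchors the
#'   scan.
#' @param out_dir output directory.
#' @param position ungapped reference position (default 878).
#' @param thermal optional thermal label vector (or path).
#' @param region display region to dump (default `"S5"`; skipped if absent
#'   from the map).
#' @return The `residue_by_clade` table, invisibly; artifacts on disk.
#' @export
run_residue_scan <- function(aln, clade_groups, dmap, out_dir,
                             position = 878L, thermal = NULL,
                             region = "S5") {
  if (is.character(aln)) aln <- read_alignment(aln)
  if (is.character(clade_groups)) clade_groups <- load_clade_groups(clade_groups)
  if (is.character(dmap)) dmap <- load_domain_map(dmap)
  if (is.character(thermal) && length(thermal) == 1L &&
      is.null(names(thermal)) && file.exists(thermal)) {
    thermal <- load_thermal_labels(thermal)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  calls <- call_reference_residue(aln, dmap$reference_taxon, position)
  tab <- tabulate_by_clade(calls, clade_groups, thermal)
  cfg <- list(position = position, reference = dmap$reference_taxon)
  for (out in list(list(df = calls, f = "residue_calls.tsv"),
                   list(df = tab, f = "residue_by_clade.tsv"))) {
    con <- file(file.path(out_dir, out$f), "w")
    writeLines(provenance_lines(cfg), con)
    close(con)
    suppressWarnings(write.table(as.data.frame(out$df),
                                 file.path(out_dir, out$f), sep = "\t",
                                 quote = FALSE, row.names = FALSE,
                                 append = TRUE))
  }
  if (region %in% names(dmap$regions)) {
    write_fasta(extract_region_alignment(aln, dmap, region),
                file.path(out_dir, paste0(region, "_slice.fasta")))
  }
  invisible(tab)
}

# ---- command-line interface ----------------------------------------------

parse_cli_args <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i < length(args) && !startsWith(args[i + 1L], "--")) {
        opts[[key]] <- args[i + 1L]; i <- i + 2L
      } else {
        opts[[key]] <- TRUE; i <- i + 1L
      }
    } else {
      opts[["_positional"]] <- c(opts[["_positional"]], a); i <- i + 1L
    }
  }
  opts
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (`--fixture marine|residue|null --seed N --out
#' dir`), `domain-rates` (`--alignment msa.fasta --groups groups.tsv
#' --domains domains.yaml [--regions a,b] [--scheme root_to_tip]
#' [--deletion complete] [--rooting midpoint] --out dir`), `residue-scan`
#' (`--alignment ... --groups ... --domains ... [--position 878]
#' [--thermal labels.tsv] --out dir`) and `climate` (`--table
#' table1.tsv`).
#'
#' @param args character vector of command-line arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status 0 on success, invisibly; stage-tagged errors
#'   otherwise.
#' @export
trpa1evo_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    stop("usage: trpa1evo <simulate|domain-rates|residue-scan|climate> ...")
  }
  cmd <- args[1L]
  opts <- parse_cli_args(args[-1L])
  need <- function(key) {
    v <- opts[[key]]
    if (is.null(v)) stop(sprintf("[%s] missing required option --%s", cmd, key))
    v
  }
  switch(cmd,
    "simulate" = {
      seed <- as.integer(need("seed"))
      fixture <- opts[["fixture"]] %||% "marine"
      ds <- switch(fixture,
                   marine = make_marine_fixture(seed),
                   null = make_marine_fixture(seed, sensor_multiplier = 1),
                   residue = make_residue_fixture(seed),
                   stop("[simulate] unknown fixture: ", fixture))
      write_fixture(ds, need("out"))
      message(sprintf("[simulate] wrote %s fixture (seed %d) to %s",
                      fixture, seed, opts[["out"]]))
    },
    "domain-rates" = {
      cfg <- rate_config(
        regions = if (!is.null(opts[["regions"]]))
          strsplit(opts[["regions"]], ",", fixed = TRUE)[[1L]] else NULL,
        scheme = opts[["scheme"]] %||% "root_to_tip",
        deletion = opts[["deletion"]] %||% "complete",
        rooting = opts[["rooting"]] %||% "midpoint",
        outgroup = opts[["outgroup"]],
        shared_topology = isTRUE(opts[["shared-topology"]]),
        allow_saturated = isTRUE(opts[["allow-saturated"]]))
      run_domain_rates(need("alignment"), need("groups"), need("domains"),
                       need("out"), config = cfg)
      message("[domain-rates] report written to ", opts[["out"]])
    },
    "residue-scan" = {
      run_residue_scan(need("alignment"), need("groups"), need("domains"),
                       need("out"),
                       position = as.integer(opts[["position"]] %||% 878L),
                       thermal = opts[["thermal"]])
      message("[residue-scan] tables written to ", opts[["out"]])
    },
    "climate" = {
      avg <- climate_summary(read_climate_table(need("table")))
      cat(paste(names(avg), sprintf("%.1f", avg), sep = "\t"), sep = "\n")
    },
    stop("unknown subcommand: ", cmd))
  invisible(0L)
}
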