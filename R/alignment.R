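#' @importFrom stats optimize sd setNames median
#' @importFrom utils read.delim write.table head
NULL

#' The 20 amino acids in canonical `ARNDCQEGHILKMFPSTWYV` order
#' @export
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
GAP_CHAR <- "-"
VALID_RESIDUE_CHARS <- c(AA_ALPHABET, GAP_CHAR, "X")

#' Sequence records
#'
#' A set of protein sequence records: taxon identifiers, free-text
#' descriptions and residue strings over the 20 amino-acid letters plus the
#' gap character `-` and the unknown character `X`. Residues are uppercased
#' on read; taxon identifiers must be unique.
#'
#' @param taxon_id character vector of unique, non-empty labels.
#' @param residues character vector of residue strings (no whitespace).
#' @param description optional character vector of free-text descriptions.
#' @return An object of class `seq_records`: a data.frame with columns
#'   `taxon_id`, `description`, `residues`.
#' @export
seq_records <- function(taxon_id, residues, description = "") {
  taxon_id <- as.character(taxon_id)
  residues <- toupper(as.character(residues))
  if (length(taxon_id) != length(residues)) {
    stop("taxon_id and residues must have the same length")
  }
  if (any(!nzchar(taxon_id))) stop("taxon_id entries must be non-empty")
  dup <- taxon_id[duplicated(taxon_id)]
  if (length(dup)) {
    stop("duplicate taxon_id: ", paste(unique(dup), collapse = ", "))
  }
  if (any(grepl("[[:space:]]", residues))) {
    stop("residues must not contain whitespace")
  }
  bad <- !grepl(sprintf("^[%s-]*$", paste(c(AA_ALPHABET, "X"), collapse = "")),
                residues)
  if (any(bad)) {
    stop("invalid residue characters in: ",
         paste(taxon_id[bad], collapse = ", "))
  }
  structure(
    data.frame(taxon_id = taxon_id,
               description = rep_len(as.character(description), length(taxon_id)),
               residues = residues,
               stringsAsFactors = FALSE),
    class = c("seq_records", "data.frame"))
}

#' Read a FASTA file
#'
#' Parses a (possibly wrapped) FASTA file of amino-acid sequences. Malformed
#' input is rejected with an error that names the offending line.
#'
#' @param path path to a FASTA file.
#' @return A [seq_records] object, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) stop("empty FASTA file: ", path)
  first <- nonblank[1L]
  if (!startsWith(lines[first], ">")) {
    stop(sprintf("malformed FASTA at line %d (expected '>' header): %s",
                 first, path))
  }
  hdr_idx <- which(startsWith(lines, ">"))
  ids <- character(length(hdr_idx))
  desc <- character(length(hdr_idx))
  seqs <- character(length(hdr_idx))
  bounds <- c(hdr_idx, length(lines) + 1L)
  for (k in seq_along(hdr_idx)) {
    h <- sub("^>", "", lines[hdr_idx[k]])
    id <- sub("[[:space:]].*$", "", h)
    if (!nzchar(id)) {
      stop(sprintf("malformed FASTA header at line %d: empty taxon id",
                   hdr_idx[k]))
    }
    ids[k] <- id
    desc[k] <- trimws(sub("^[^[:space:]]*[[:space:]]?", "", h))
    body <- lines[seq.int(hdr_idx[k] + 1L, bounds[k + 1L] - 1L)]
    body <- body[seq_len(max(0L, length(body)))]
    seqs[k] <- gsub("[[:space:]]", "", paste(body, collapse = ""))
  }
  if (anyDuplicated(ids)) {
    d <- ids[duplicated(ids)][1L]
    at <- hdr_idx[ids == d][2L]
    stop(sprintf("duplicate taxon id '%s' at line %d", d, at))
  }
  seq_records(ids, seqs, desc)
}

#' Write sequence records to FASTA
#'
#' Writes FASTA wrapped at 60 columns.
#'
#' @param records a [seq_records] object or an [aa_alignment].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "aa_alignment")) records <- as_seq_records(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- if (nzchar(records$description[i])) {
      paste(records$taxon_id[i], records$description[i])
    } else records$taxon_id[i]
    writeLines(paste0(">", hdr), con)
    s <- records$residues[i]
    starts <- seq.int(1L, max(1L, nchar(s)), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}

#' Amino-acid multiple alignment
#'
#' An alignment is stored as a character matrix of single residues with
#' taxa as rownames; all rows have equal length, there are at least two
#' rows, and no column is entirely gaps.
#'
#' @param records a [seq_records] object with equal-length residue strings.
#' @return An object of class `aa_alignment`.
#' @export
as_alignment <- function(records) {
  lens <- nchar(records$residues)
  if (length(unique(lens)) != 1L) {
    bad <- records$taxon_id[lens != stats::median(lens)]
    stop("alignment rows have unequal lengths; offending taxa: ",
         paste(bad, collapse = ", "))
  }
  if (nrow(records) < 2L) stop("an alignment needs at least 2 rows")
  mat <- do.call(rbind, strsplit(records$residues, "", fixed = TRUE))
  rownames(mat) <- records$taxon_id
  if (ncol(mat) > 0L && any(colSums(mat != GAP_CHAR) == 0L)) {
    stop("alignment contains all-gap columns")
  }
  structure(list(mat = mat,
                 description = setNames(records$description,
                                        records$taxon_id)),
            class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("aa_alignment: %d taxa x %d columns\n",
              nrow(x$mat), ncol(x$mat)))
  show <- head(rownames(x$mat), 6L)
  for (t in show) {
    s <- paste(x$mat[t, seq_len(min(50L, ncol(x$mat)))], collapse = "")
    cat(sprintf("  %-20s %s%s\n", t, s, if (ncol(x$mat) > 50) "..." else ""))
  }
  if (nrow(x$mat) > 6L) cat(sprintf("  ... and %d more\n", nrow(x$mat) - 6L))
  invisible(x)
}

#' @rdname as_alignment
#' @param x an `aa_alignment`.
#' @export
as_seq_records <- function(x) {
  stopifnot(inherits(x, "aa_alignment"))
  seq_records(rownames(x$mat),
              apply(x$mat, 1L, paste, collapse = ""),
              description = unname(x$description[rownames(x$mat)]))
}

#' Number of taxa / columns of an alignment
#' @param x an `aa_alignment`.
#' @export
n_taxa <- function(x) nrow(x$mat)

#' @rdname n_taxa
#' @export
n_cols <- function(x) ncol(x$mat)

#' @rdname n_taxa
#' @export
taxa <- function(x) rownames(x$mat)

#' Read an aligned FASTA file
#'
#' Like [read_fasta] but enforces alignment invariants (equal row lengths,
#' at least two rows, no all-gap column).
#'
#' @inheritParams read_fasta
#' @return An [aa_alignment].
#' @export
read_alignment <- function(path) as_alignment(read_fasta(path))

#' Subset an alignment to a set of columns (internal helper)
#' @noRd
subset_columns <- function(aln, cols, drop_all_gap = TRUE) {
  mat <- aln$mat[, cols, drop = FALSE]
  n_dropped <- 0L
  if (drop_all_gap && ncol(mat)) {
    keep <- colSums(mat != GAP_CHAR) > 0L
    n_dropped <- sum(!keep)
    mat <- mat[, keep, drop = FALSE]
  }
  out <- structure(list(mat = mat, description = aln$description),
                   class = "aa_alignment")
  attr(out, "n_dropped_allgap") <- n_dropped
  out
}
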