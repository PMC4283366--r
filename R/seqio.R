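# Symbol classes used throughout: '-' gap, '?' missing, any IUPAC letter
# outside ACGT (including N) ambiguous.
.IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
.ALLOWED <- c("A", "C", "G", "T", .IUPAC_AMBIG, "-", "?")

#' Construct an alignment object
#'
#' An alignment is stored as an upper-case character matrix (rows =
#' sequences, columns = sites) with sequence identifiers as row names, plus
#' an optional specimen metadata table.
#'
#' @param x named character vector of equal-length residue strings, or a
#'   character matrix with one row per sequence, or a data frame with
#'   columns `id` and `residues` (as returned by [read_fasta()]).
#' @param meta optional metadata data frame with an `id` column (see
#'   [read_metadata()]); joined onto the sequences, erroring on ids without
#'   a metadata row.
#' @return an object of class `aln`: a list with elements `ids`, `mat`
#'   (character matrix) and `meta` (data frame or `NULL`).
#' @examples
#' as_alignment(c(s1 = "ACGT", s2 = "AC-T"))
#' @export
as_alignment <- function(x, meta = NULL) {
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "residues") %in% names(x)))
    x <- stats::setNames(x$residues, x$id)
  }
  if (is.matrix(x)) {
    mat <- toupper(x)
    ids <- rownames(mat)
  } else {
    ids <- names(x)
    if (is.null(ids) || any(!nzchar(ids))) {
      stop("every sequence must carry a non-empty id", call. = FALSE)
    }
    res <- toupper(as.character(x))
    if (any(!nzchar(res))) stop("empty residue string", call. = FALSE)
    lens <- nchar(res)
    if (length(unique(lens)) != 1L) {
      stop("sequences have unequal lengths (", paste(unique(lens), collapse = ", "),
           "); input must be aligned", call. = FALSE)
    }
    mat <- matrix(unlist(strsplit(res, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(res), byrow = TRUE)
    rownames(mat) <- ids
  }
  if (any(duplicated(ids))) {
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (ncol(mat) == 0L) stop("alignment has zero columns", call. = FALSE)
  bad <- setdiff(unique(as.vector(mat)), .ALLOWED)
  if (length(bad)) {
    stop("disallowed residue symbol(s): ", paste(bad, collapse = " "), call. = FALSE)
  }
  if (!is.null(meta)) meta <- .join_meta(ids, meta)
  structure(list(ids = ids, mat = mat, meta = meta), class = "aln")
}

#' @export
print.aln <- function(x, ...) {
  cat("<alignment> ", length(x$ids), " sequences x ", ncol(x$mat), " columns\n",
      sep = "")
  invisible(x)
}

#' Number of sequences / columns in an alignment
#' @param aln an `aln` object.
#' @return integer count.
#' @export
n_sequences <- function(aln) length(aln$ids)

#' @rdname n_sequences
#' @export
n_sites <- function(aln) ncol(aln$mat)

#' Read sequences from a FASTA file
#'
#' The first whitespace-delimited token of each header becomes the record
#' id. Residues are upper-cased and line wraps joined; record order is
#' preserved.
#'
#' @param path path to a FASTA file.
#' @return data frame with columns `id` and `residues`, one row per entry.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(trimws(lines) != "")
  if (!length(nonblank)) stop("empty FASTA file: ", path, call. = FALSE)
  first <- nonblank[1L]
  if (!startsWith(lines[first], ">")) {
    stop("malformed FASTA: sequence data before any header at line ", first,
         " of ", path, call. = FALSE)
  }
  seqs <- seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                             forceDNAtolower = FALSE, set.attributes = FALSE)
  ids <- names(seqs)
  if (any(duplicated(ids))) {
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  data.frame(id = ids, residues = toupper(unlist(seqs, use.names = FALSE)),
             stringsAsFactors = FALSE)
}

#' Write an alignment (or record table) to FASTA
#'
#' @param x an `aln` object or a data frame with `id` and `residues`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "aln")) {
    ids <- x$ids
    res <- apply(x$mat, 1L, paste, collapse = "")
  } else {
    ids <- x$id
    res <- x$residues
  }
  writeLines(paste0(">", ids, "\n", res), path)
  invisible(path)
}

#' Read a specimen metadata table
#'
#' Reads a delimited table (TSV or CSV, sniffed from the header line) with
#' a mandatory `id` column and optional `taxon`, `locality_code`, `lot` and
#' `lineage` columns; missing optional fields become empty strings.
#'
#' @param path path to the table.
#' @return data frame keyed by `id` with the four optional columns always
#'   present.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, strip.white = TRUE,
                          colClasses = "character")
  if (!"id" %in% names(df)) stop("metadata table must have an 'id' column",
                                 call. = FALSE)
  if (any(duplicated(df$id))) {
    stop("duplicate metadata id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "), call. = FALSE)
  }
  for (col in c("taxon", "locality_code", "lot", "lineage")) {
    if (!col %in% names(df)) df[[col]] <- ""
    df[[col]][is.na(df[[col]])] <- ""
  }
  df[, c("id", "taxon", "locality_code", "lot", "lineage")]
}

.join_meta <- function(ids, meta) {
  missing <- setdiff(ids, meta$id)
  if (length(missing)) {
    stop("sequence id(s) absent from metadata table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  meta[match(ids, meta$id), , drop = FALSE]
}

# Per-column exclusion class flags for an alignment matrix.
.column_flags <- function(mat) {
  list(gap       = apply(mat == "-", 2L, any),
       missing   = apply(mat == "?", 2L, any),
       ambiguous = apply(matrix(mat %in% .IUPAC_AMBIG, nrow(mat)), 2L, any))
}

#' Filter alignment columns by symbol class
#'
#' Complete-deletion column filtering: a column is dropped when any
#' sequence carries a symbol of an excluded class ('-' gap, '?' missing,
#' any non-ACGT IUPAC letter ambiguous). Retained columns keep their
#' original order. The report records, per excluded column, a single
#' reason: the highest-priority excluded class present in it
#' (gap > missing > ambiguous).
#'
#' @param aln an `aln` object.
#' @param exclude subset of `c("gap", "missing", "ambiguous")`.
#' @return list with elements `aln` (the filtered alignment) and `report`
#'   (class `column_filter_report`: `n_input_columns`, `n_excluded`,
#'   `n_retained`, `excluded_reasons` — a named character vector keyed by
#'   original column index).
#' @export
filter_columns <- function(aln, exclude = c("gap", "missing", "ambiguous")) {
  stopifnot(inherits(aln, "aln"))
  exclude <- match.arg(exclude, c("gap", "missing", "ambiguous"),
                       several.ok = TRUE)
  flags <- .column_flags(aln$mat)
  reason <- rep(NA_character_, ncol(aln$mat))
  for (cls in c("ambiguous", "missing", "gap")) {  # ascending priority
    if (cls %in% exclude) reason[flags[[cls]]] <- cls
  }
  drop <- !is.na(reason)
  if (all(drop)) {
    stop("all ", length(drop), " columns excluded; nothing left to analyse",
         call. = FALSE)
  }
  kept <- aln$mat[, !drop, drop = FALSE]
  out <- structure(list(ids = aln$ids, mat = kept, meta = aln$meta),
                   class = "aln")
  reasons <- reason[drop]
  names(reasons) <- as.character(which(drop))
  report <- structure(list(n_input_columns = ncol(aln$mat),
                           n_excluded = sum(drop),
                           n_retained = ncol(kept),
                           excluded_reasons = reasons),
                      class = "column_filter_report")
  list(aln = out, report = report)
}

#' @export
print.column_filter_report <- function(x, ...) {
  cat("column filter: ", x$n_input_columns, " columns in, ",
      x$n_excluded, " excluded, ", x$n_retained, " retained\n", sep = "")
  if (x$n_excluded) {
    tab <- table(x$excluded_reasons)
    cat("  reasons:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
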