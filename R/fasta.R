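#' Read protein sequences from a FASTA file
#'
#' Reads plain (ungapped) protein FASTA into a tibble with one row per
#' record. Residues are upper-cased on ingest; only the 20 standard amino
#' acids plus `X` (unknown) are accepted. `*` (stop) and any other character
#' are rejected with the offending position, since they indicate an upstream
#' parsing fault rather than a valid database protein.
#'
#' @param path Path to a FASTA file.
#' @param gapped Logical; if `TRUE`, the gap character `-` is also accepted
#'   (use [read_alignment()] for aligned FASTA, which additionally checks
#'   that all rows share one column count).
#' @return A tibble with columns `id` (first whitespace-delimited token of
#'   the header), `description` (remainder of the header, possibly empty)
#'   and `residues`.
#' @seealso [write_fasta()], [read_alignment()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a first", "ACDE", ">b", "WY"), f)
#' read_fasta(f)
read_fasta <- function(path, gapped = FALSE) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  allowed <- if (gapped) c(AA_OK, GAP) else AA_OK
  validate_fasta_chars(path, allowed)  # Biostrings silently drops bad codes
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) {
      abort(sprintf("could not parse FASTA file %s: %s", path, conditionMessage(e)))
    }
  )
  if (length(set) == 0L) abort(sprintf("empty FASTA file: %s", path))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate FASTA id(s): %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  residues <- toupper(as.character(set))
  for (i in seq_along(residues)) {
    cc <- chars(residues[[i]])
    if (length(cc) == 0L) abort(sprintf("record '%s' has an empty sequence", ids[[i]]))
    bad <- which(!cc %in% allowed)
    if (length(bad)) {
      abort(sprintf("invalid character '%s' at position %d of record '%s'",
                    cc[bad[1]], bad[1], ids[[i]]))
    }
  }
  tibble(id = ids, description = desc, residues = unname(residues))
}

# scan the raw text so an offending character is reported with its
# residue position and record id
validate_fasta_chars <- function(path, allowed) {
  lines <- readLines(path, warn = FALSE)
  seq_id <- NA_character_
  pos <- 0L
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      seq_id <- sub("\\s.*$", "", sub("^>", "", ln))
      pos <- 0L
      next
    }
    cc <- chars(toupper(trimws(ln)))
    bad <- which(!cc %in% allowed)
    if (length(bad)) {
      abort(sprintf("invalid character '%s' at position %d of record '%s'",
                    cc[bad[1]], pos + bad[1], seq_id))
    }
    pos <- pos + length(cc)
  }
  invisible(TRUE)
}

#' Read an aligned FASTA file
#'
#' Like [read_fasta()] but accepts the gap character `-` and checks that all
#' rows share one column count. Ungapping any row reproduces the source
#' protein sequence.
#'
#' @inheritParams read_fasta
#' @return A tibble with columns `id`, `description`, `residues` (gapped).
#' @export
read_alignment <- function(path) {
  aln <- read_fasta(path, gapped = TRUE)
  check_alignment(aln, "alignment")
  aln
}

#' Write protein records to FASTA
#'
#' @param records A tibble with columns `id` and `residues` (and optionally
#'   `description`), a named character vector, or a single string.
#' @param path Output path.
#' @param width Line-wrap width in residues (default 60, a common
#'   convention; the read/write round trip is identical up to this wrapping).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  records <- as_protein_tbl(records, "records")
  nm <- records$id
  if (!is.null(records$description)) {
    has_desc <- !is.na(records$description) & nzchar(records$description)
    nm[has_desc] <- paste(records$id[has_desc], records$description[has_desc])
  }
  set <- Biostrings::AAStringSet(setNames(records$residues, nm))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Remove gap characters from a gapped sequence
#'
#' @param x Character vector of (possibly gapped) sequences.
#' @return Character vector with all `-` removed.
#' @export
ungap <- function(x) gsub(GAP, "", x, fixed = TRUE)
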