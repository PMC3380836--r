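# The 20 standard amino acids, alphabetical one-letter codes.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Residues acceptable in a ProteinRecord: the 20 standard letters plus X
# (unknown). '*' (stop) and other letters are rejected on ingest.
AA_OK <- c(AA20, "X")

GAP <- "-"

# split a string into single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Normalise sequence input: accepts a tibble/data.frame with `id` and
# `residues` columns, a named character vector, or a single unnamed string
# (given id "seq1"). Returns a tibble(id, residues).
as_protein_tbl <- function(seqs, arg = "seqs") {
  if (is.data.frame(seqs)) {
    if (!all(c("id", "residues") %in% names(seqs))) {
      abort(sprintf("`%s` must have columns `id` and `residues`", arg))
    }
    return(as_tibble(seqs[, intersect(c("id", "description", "residues"), names(seqs))]))
  }
  if (is.character(seqs)) {
    ids <- names(seqs)
    if (is.null(ids)) {
      ids <- if (length(seqs) == 1L) "seq1" else paste0("seq", seq_along(seqs))
    }
    return(tibble(id = ids, residues = unname(seqs)))
  }
  abort(sprintf("`%s` must be a data frame or character vector of sequences", arg))
}

# Validate that rows of an alignment tibble share one column count.
check_alignment <- function(aln, arg = "alignment") {
  aln <- as_protein_tbl(aln, arg)
  widths <- nchar(aln$residues)
  if (nrow(aln) == 0L) abort(sprintf("`%s` has no rows", arg))
  if (length(unique(widths)) != 1L) {
    abort(sprintf("`%s` rows differ in length (%s)", arg,
                  paste(unique(widths), collapse = ", ")))
  }
  aln
}

# character matrix (rows = sequences, columns = alignment columns)
alignment_matrix <- function(aln) {
  aln <- check_alignment(aln)
  m <- do.call(rbind, strsplit(aln$residues, "", fixed = TRUE))
  rownames(m) <- aln$id
  m
}
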