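#' Parse a Prosite-dialect motif pattern
#'
#' Parses the pattern dialect used for C2H2 zinc-finger motifs: residue
#' letters (`C`), bracketed residue sets (`[FWsgat]`, where lowercase
#' members are "exceptional" rarely observed residues), wildcards `x`,
#' `x(n)` and `x(n,m)`, with `-` separating elements. Exceptional residues
#' are allowed during scanning exactly like uppercase members; the case
#' distinction is kept for rendering and reporting only. Prosite's `{...}`
#' exclusion classes and the `<`, `>` anchors are outside the dialect and
#' rejected with a clear message.
#'
#' @param text Pattern string, e.g. `"C-x(2)-C-x(3)-[FWsgat]-x(8)-H-x(3,4)-H"`.
#' @return An object of class `prosite_pattern`: a tibble of elements with
#'   columns `kind` (`"set"` or `"wildcard"`), `major`/`exceptional`
#'   (list-columns of residue letters), `min_rep`, `max_rep`; attributes
#'   `source` (the input text), `min_span` and `max_span` (summed repeat
#'   bounds).
#' @seealso [scan_pattern()], [render_pattern()], [ovol_patterns()]
#' @export
#' @examples
#' p <- parse_pattern("C-x(2,4)-C-x(3)-[LIVMFYWC]-x(8)-H-x(3,5)-H")
#' attr(p, "min_span") # 21
#' attr(p, "max_span") # 25
parse_pattern <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (grepl("[{}<>]", text)) {
    abort(paste0("pattern '", text, "' uses Prosite features ({...}, <, >) ",
                 "outside the supported dialect"))
  }
  tokens <- strsplit(text, "-", fixed = TRUE)[[1]]
  if (length(tokens) == 0L || !nzchar(text)) abort("empty pattern")
  # character offset of each token within the source, for error messages
  offsets <- cumsum(c(1L, nchar(tokens) + 1L))[seq_along(tokens)]

  parse_token <- function(tok, off) {
    if (tok == "") {
      abort(sprintf("empty pattern element at offset %d in '%s'", off, text))
    }
    if (tok == "x") {
      return(list(kind = "wildcard", major = character(), exceptional = character(),
                  min_rep = 1L, max_rep = 1L, bracketed = FALSE))
    }
    m <- regmatches(tok, regexec("^x\\((\\d+)(,(\\d+))?\\)$", tok))[[1]]
    if (length(m)) {
      lo <- as.integer(m[2])
      hi <- if (nzchar(m[4])) as.integer(m[4]) else lo
      if (lo < 1L || hi < lo) {
        abort(sprintf("invalid repeat bounds '%s' at offset %d in '%s'", tok, off, text))
      }
      return(list(kind = "wildcard", major = character(), exceptional = character(),
                  min_rep = lo, max_rep = hi, bracketed = FALSE))
    }
    if (grepl("^\\[[A-Za-z]*\\]$", tok)) {
      members <- chars(substr(tok, 2, nchar(tok) - 1))
      if (length(members) == 0L) {
        abort(sprintf("empty residue set at offset %d in '%s'", off, text))
      }
      up <- members[members == toupper(members)]
      lo <- toupper(members[members != toupper(members)])
      bad <- setdiff(c(up, lo), AA20)
      if (length(bad)) {
        abort(sprintf("unknown residue(s) %s at offset %d in '%s'",
                      paste(bad, collapse = ","), off, text))
      }
      return(list(kind = "set", major = up, exceptional = lo,
                  min_rep = 1L, max_rep = 1L, bracketed = TRUE))
    }
    if (nchar(tok) == 1L && tok %in% AA20) {
      return(list(kind = "set", major = tok, exceptional = character(),
                  min_rep = 1L, max_rep = 1L, bracketed = FALSE))
    }
    abort(sprintf("malformed pattern element '%s' at offset %d in '%s'", tok, off, text))
  }

  parsed <- Map(parse_token, tokens, offsets)
  elements <- tibble(
    kind = vapply(parsed, `[[`, "", "kind"),
    major = lapply(parsed, `[[`, "major"),
    exceptional = lapply(parsed, `[[`, "exceptional"),
    min_rep = vapply(parsed, `[[`, 1L, "min_rep"),
    max_rep = vapply(parsed, `[[`, 1L, "max_rep"),
    bracketed = vapply(parsed, `[[`, TRUE, "bracketed")
  )
  structure(elements,
            source = text,
            min_span = sum(elements$min_rep),
            max_span = sum(elements$max_rep),
            class = c("prosite_pattern", class(elements)))
}

#' Render a parsed pattern back to its text form
#'
#' `parse_pattern(render_pattern(p))` is a fixed point for every pattern in
#' the supported dialect.
#'
#' @param pattern A `prosite_pattern`.
#' @return The pattern string.
#' @export
render_pattern <- function(pattern) {
  stopifnot(inherits(pattern, "prosite_pattern"))
  toks <- vapply(seq_len(nrow(pattern)), function(i) {
    if (pattern$kind[i] == "wildcard") {
      lo <- pattern$min_rep[i]; hi <- pattern$max_rep[i]
      if (lo == 1L && hi == 1L) return("x")
      if (lo == hi) return(sprintf("x(%d)", lo))
      return(sprintf("x(%d,%d)", lo, hi))
    }
    maj <- pattern$major[[i]]; exc <- tolower(pattern$exceptional[[i]])
    if (length(maj) == 1L && length(exc) == 0L && !pattern$bracketed[i]) return(maj)
    paste0("[", paste0(c(maj, exc), collapse = ""), "]")
  }, "")
  paste(toks, collapse = "-")
}

#' @export
print.prosite_pattern <- function(x, ...) {
  cat("<prosite_pattern> ", render_pattern(x), "\n", sep = "")
  cat("  elements: ", nrow(x),
      "  span: ", attr(x, "min_span"),
      if (attr(x, "max_span") != attr(x, "min_span"))
        paste0("-", attr(x, "max_span")) else "",
      " aa\n", sep = "")
  invisible(x)
}

# coerce a pattern argument: accept text or parsed pattern
as_pattern <- function(pattern) {
  if (inherits(pattern, "prosite_pattern")) pattern else parse_pattern(pattern)
}
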