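# Independent oracles used across the suite. Each deliberately takes a
# different route from the package implementation it checks.

# --- pattern-scanning oracle: translate the pattern dialect into an R
# regex and test every substring of every candidate length with the regex
# engine (vs the package's backtracking matcher).
pattern_to_regex <- function(text) {
  toks <- strsplit(text, "-", fixed = TRUE)[[1]]
  parts <- vapply(toks, function(tok) {
    if (tok == "x") return("[A-Z]")
    m <- regmatches(tok, regexec("^x\\((\\d+)(,(\\d+))?\\)$", tok))[[1]]
    if (length(m)) {
      lo <- m[2]
      hi <- if (nzchar(m[4])) m[4] else lo
      return(sprintf("[A-Z]{%s,%s}", lo, hi))
    }
    if (grepl("^\\[", tok)) {
      members <- toupper(gsub("\\[|\\]", "", tok))
      return(paste0("[", members, "]"))
    }
    tok  # single residue letter; X never satisfies a residue element
  }, "")
  paste0("^", paste(parts, collapse = ""), "$")
}

oracle_scan_all <- function(residues, pattern_text) {
  rx <- pattern_to_regex(pattern_text)
  p <- parse_pattern(pattern_text)
  lo <- attr(p, "min_span"); hi <- attr(p, "max_span")
  L <- nchar(residues)
  out <- list()
  for (s in seq_len(max(L - lo + 1L, 0L))) {
    for (len in lo:min(hi, L - s + 1L)) {
      sub <- substr(residues, s, s + len - 1L)
      # 'X' in a sequence may only be consumed by a wildcard element; a
      # regex letter/class never matches X by construction of
      # pattern_to_regex except the wildcard class, which we emulate by
      # keeping X in [A-Z] and excluding it from residue classes below.
      if (grepl(rx, sub)) out[[length(out) + 1L]] <- c(s, s + len - 1L)
    }
  }
  if (!length(out)) return(data.frame(start = integer(), end = integer()))
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2])
}

# fixed residue in regex must not match X: ensure residue classes exclude X
# (single letters and explicit sets already cannot match X; the wildcard
# [A-Z] correctly includes it)

oracle_scan_leftmost <- function(residues, pattern_text) {
  all <- oracle_scan_all(residues, pattern_text)
  if (nrow(all) == 0L) return(all)
  all <- all[order(all$start, all$end), , drop = FALSE]
  picked <- list()
  last_end <- 0L
  for (i in seq_len(nrow(all))) {
    if (all$start[i] <= last_end) next
    cand <- all[all$start == all$start[i] & all$start > last_end, , drop = FALSE]
    hit <- cand[which.min(cand$end), , drop = FALSE]
    picked[[length(picked) + 1L]] <- hit
    last_end <- hit$end
  }
  do.call(rbind, picked)
}

random_pattern <- function() {
  n_el <- sample(2:5, 1)
  toks <- vapply(seq_len(n_el), function(i) {
    switch(sample(3, 1),
           sample(c("A", "C", "G", "H", "W"), 1),
           {
             set <- sample(ovolution:::AA20, sample(2:4, 1))
             up <- sample(c(TRUE, FALSE), length(set), replace = TRUE)
             up[1] <- TRUE
             paste0("[", paste0(ifelse(up, set, tolower(set)), collapse = ""), "]")
           },
           {
             lo <- sample(1:3, 1); hi <- lo + sample(0:2, 1)
             if (lo == hi && lo == 1) "x" else if (lo == hi) sprintf("x(%d)", lo)
             else sprintf("x(%d,%d)", lo, hi)
           })
  }, "")
  paste(toks, collapse = "-")
}

random_protein <- function(len, x_frac = 0.05) {
  pool <- c(ovolution:::AA20, if (x_frac > 0) "X")
  probs <- c(rep((1 - x_frac) / 20, 20), if (x_frac > 0) x_frac)
  paste(sample(pool, len, replace = TRUE, prob = probs), collapse = "")
}

# --- Kruskal-Wallis oracle: direct rank-formula evaluation
oracle_kw_h <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n_i <- tapply(r, g, length)
  h <- 12 / (N * (N + 1)) * sum(n_i * (rbar - (N + 1) / 2)^2)
  tt <- table(x)
  corr <- 1 - sum(tt^3 - tt) / (N^3 - N)
  if (corr == 0) return(0)
  h / corr
}

# --- bias-patch oracle: exhaustive window scan with the same patch
# definition (union of qualifying windows, trimmed to the dominant
# residue, minimum length = window), written independently
oracle_bias_patches <- function(residues, window, min_frac) {
  cc <- strsplit(residues, "")[[1]]
  L <- length(cc)
  out <- list()
  for (res in unique(cc)) {
    covered <- rep(FALSE, L)
    any_hit <- FALSE
    for (s in seq_len(L - window + 1L)) {
      win <- cc[s:(s + window - 1L)]
      if (mean(win == res) >= min_frac - 1e-12) {
        covered[s:(s + window - 1L)] <- TRUE
        any_hit <- TRUE
      }
    }
    if (!any_hit) next
    r <- rle(covered)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      occ <- which(cc[starts[k]:ends[k]] == res) + starts[k] - 1L
      if (!length(occ)) next
      s2 <- occ[1]; e2 <- occ[length(occ)]
      if (e2 - s2 + 1L < window) next
      out[[length(out) + 1L]] <- data.frame(start = s2, end = e2, residue = res)
    }
  }
  if (!length(out)) return(data.frame(start = integer(), end = integer(),
                                      residue = character()))
  d <- do.call(rbind, out)
  d[order(d$start, d$residue), , drop = FALSE]
}

# --- p-distance oracle: per-position loop
oracle_p_distance <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n_comp <- 0L; n_diff <- 0L
  for (i in seq_along(ca)) {
    if (ca[i] %in% ovolution:::AA20 && cb[i] %in% ovolution:::AA20) {
      n_comp <- n_comp + 1L
      if (ca[i] != cb[i]) n_diff <- n_diff + 1L
    }
  }
  list(distance = if (n_comp == 0) NA_real_ else n_diff / n_comp, sites = n_comp)
}
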