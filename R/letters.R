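# Compact letter display for pairwise LSD decisions (insert-and-absorb).
# Invariant: two groups share a letter iff their pairwise difference is not
# significant; letters run 'a' upward from the smallest mean.

lsd_letters <- function(means, sig) {
  k <- length(means)
  ord <- order(means)
  cols <- list(seq_len(k))
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    if (!sig[i, j]) next
    new_cols <- list()
    for (col in cols) {
      if (i %in% col && j %in% col) {
        new_cols <- c(new_cols, list(setdiff(col, i)), list(setdiff(col, j)))
      } else new_cols <- c(new_cols, list(col))
    }
    cols <- absorb_columns(new_cols)
  }
  # safety: every non-significant pair must share a column
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    if (sig[i, j]) next
    if (!any(vapply(cols, function(col) i %in% col && j %in% col, logical(1))))
      cols <- absorb_columns(c(cols, list(c(i, j))))
  }
  col_rank <- vapply(cols, function(col) min(match(col, ord)), numeric(1))
  cols <- cols[order(col_rank)]
  out <- vapply(seq_len(k), function(g) {
    paste(letters[which(vapply(cols, function(col) g %in% col, logical(1)))],
          collapse = "")
  }, character(1))
  setNames(out, names(means) %||% as.character(seq_len(k)))
}

absorb_columns <- function(cols) {
  cols <- unique(lapply(cols, sort))
  cols <- cols[lengths(cols) > 0L]
  keep <- rep(TRUE, length(cols))
  for (a in seq_along(cols)) for (b in seq_along(cols)) {
    if (a != b && keep[a] && keep[b] &&
        all(cols[[a]] %in% cols[[b]]) &&
        length(cols[[a]]) < length(cols[[b]]))
      keep[a] <- FALSE
  }
  # drop exact duplicates that survive the subset test
  cols <- cols[keep]
  cols[!duplicated(lapply(cols, paste, collapse = ","))]
}
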