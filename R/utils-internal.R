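## Internal helpers for canonical unordered pairs and ids.

## Canonicalize unordered pairs: returns a 2-column character matrix with
## each row sorted. Identifiers must not contain tabs (ids are tab-joined).
canonicalPairs <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  cbind(a, b, deparse.level = 0L)
}

pairIds <- function(m) {
  if (nrow(m) == 0L) return(character(0))
  paste(m[, 1L], m[, 2L], sep = "\t")
}

idsToPairs <- function(ids) {
  if (length(ids) == 0L)
    return(matrix(character(0), ncol = 2L))
  parts <- strsplit(ids, "\t", fixed = TRUE)
  cbind(vapply(parts, `[[`, character(1), 1L),
        vapply(parts, `[[`, character(1), 2L), deparse.level = 0L)
}

## Sort pair matrix rows by id for a stable order.
sortPairs <- function(m) {
  if (nrow(m) <= 1L) return(m)
  m[order(pairIds(m)), , drop = FALSE]
}

checkNoTabs <- function(x, what) {
  if (any(grepl("\t", x, fixed = TRUE)))
    stop(what, " identifiers must not contain tab characters", call. = FALSE)
  invisible(x)
}

emptyPairMatrix <- function() matrix(character(0), ncol = 2L)

## All unordered pairs of a character vector, canonical order.
allPairs <- function(x) {
  x <- sort(unique(x))
  n <- length(x)
  if (n < 2L) return(emptyPairMatrix())
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  cbind(x[idx[, 1L]], x[idx[, 2L]], deparse.level = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
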