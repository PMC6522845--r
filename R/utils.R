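# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Byte-order (C locale) sort so output ordering is identical across platforms.
sort_c <- function(x) sort(x, method = "radix")

order_c <- function(...) order(..., method = "radix")

# One string key per row of a sparse binary matrix: the comma-joined sorted
# column names of the row support.  Rows are equal iff keys are equal.
profile_keys <- function(M) {
  tM <- methods::as(methods::as(Matrix::t(M), "CsparseMatrix"), "generalMatrix")
  p <- tM@p
  idx <- tM@i
  cn <- rownames(M) # unused; keys built from column index space of M
  labs <- colnames(M)
  vapply(seq_len(ncol(tM)), function(j) {
    if (p[j + 1L] == p[j]) {
      ""
    } else {
      paste(sort_c(labs[idx[(p[j] + 1L):p[j + 1L]] + 1L]), collapse = "|")
    }
  }, character(1))
}

# Rand index between two labelled partitions of the same item set.
rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    if (length(common) != length(a) || length(common) != length(b)) {
      stop("partitions cover different item sets")
    }
    b <- b[names(a)]
  }
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2L) {
    return(1)
  }
  tab <- table(a, b)
  s_ij <- sum(choose(tab, 2))
  s_a <- sum(choose(rowSums(tab), 2))
  s_b <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  (total + 2 * s_ij - s_a - s_b) / total
}

# Zero-padded sequential ids: prefix_fn("M", 12) -> M01 ... M12.
seq_ids <- function(prefix, n) {
  if (n == 0L) {
    return(character(0))
  }
  sprintf("%s%0*d", prefix, max(2L, nchar(as.character(n))), seq_len(n))
}

stop_data <- function(...) stop(..., call. = FALSE)
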