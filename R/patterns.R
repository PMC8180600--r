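#' Attribute-pattern bit-string utilities
#'
#' Attribute patterns are binary K-vectors (1 = attribute mastered).
#' Throughout the package they are serialized as bit-strings in attribute
#' order, e.g. `"10110"`, and pattern spaces are kept in lexicographic
#' bit-string order (equivalently, binary counting with the first attribute
#' as the most significant bit).
#'
#' @param pattern binary integer vector, or a matrix with one pattern per row.
#' @return `pattern_to_string()` returns a character vector of bit-strings;
#'   `string_to_pattern()` returns an integer matrix with one pattern per row.
#' @examples
#' pattern_to_string(c(1, 0, 1))
#' string_to_pattern(c("00", "11"))
#' @export
pattern_to_string <- function(pattern) {
  if (is.matrix(pattern)) {
    apply(pattern, 1L, function(r) paste(as.integer(r), collapse = ""))
  } else {
    paste(as.integer(pattern), collapse = "")
  }
}

#' @rdname pattern_to_string
#' @param x character vector of bit-strings of equal length.
#' @export
string_to_pattern <- function(x) {
  k <- unique(nchar(x))
  if (length(k) != 1L) stop("bit-strings must have equal length")
  m <- t(vapply(strsplit(x, "", fixed = TRUE),
                function(b) as.integer(b), integer(k)))
  if (any(is.na(m)) || any(m != 0L & m != 1L)) {
    stop("bit-strings must contain only 0 and 1")
  }
  m
}

# All 2^K patterns, lexicographic order (first attribute = MSB).
all_binary_patterns <- function(K) {
  L <- 2L^K
  m <- matrix(0L, L, K)
  for (k in seq_len(K)) {
    m[, k] <- rep(rep(c(0L, 1L), each = 2L^(K - k)), length.out = L)
  }
  m
}

# 1-based index of each row of `patmat[, cols]` read as a binary number with
# the first column as the most significant bit. cols may be empty (all 1s).
config_index <- function(patmat, cols) {
  if (length(cols) == 0L) return(rep(1L, nrow(patmat)))
  sub <- patmat[, cols, drop = FALSE]
  w <- 2L^(rev(seq_along(cols)) - 1L)
  as.integer(sub %*% w) + 1L
}

assert_binary_matrix <- function(m, what = "matrix") {
  if (!is.matrix(m)) stop(what, " must be a matrix")
  if (anyNA(m)) stop(what, " contains missing values")
  if (!all(m == 0 | m == 1)) stop(what, " contains values outside {0, 1}")
  invisible(m)
}
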