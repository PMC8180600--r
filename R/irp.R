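#' Ideal response of an attribute pattern to one item
#'
#' The error-free (no slip, no guess) response under a condensation rule:
#' conjunctive DINA scores 1 iff all attributes required by the item are
#' mastered, prod_k pattern_k^q_k; disjunctive DINO scores 1 iff at least one
#' required attribute is mastered, 1 - prod_k (1 - pattern_k)^q_k. The rules
#' coincide for single-attribute items.
#'
#' @param pattern binary K-vector of attribute masteries.
#' @param q_row binary K-vector, the item's Q-matrix row.
#' @param rule `"DINA"` or `"DINO"`.
#' @return 0 or 1.
#' @examples
#' ideal_response(c(0, 1), c(1, 1), "DINA")  # 0
#' ideal_response(c(0, 1), c(1, 1), "DINO")  # 1
#' @export
ideal_response <- function(pattern, q_row, rule = c("DINA", "DINO")) {
  rule <- match.arg(rule)
  if (length(pattern) != length(q_row)) {
    stop("pattern and q_row lengths differ (", length(pattern), " vs ",
         length(q_row), ")")
  }
  req <- which(q_row == 1)
  if (rule == "DINA") {
    as.integer(all(pattern[req] == 1))
  } else {
    as.integer(any(pattern[req] == 1))
  }
}

#' Build the ideal-response-pattern (IRP) training dataset
#'
#' One row per admissible attribute pattern: the pattern together with its
#' ideal response vector over all items under the chosen condensation rule.
#' This complete (no latent variable) dataset is the supervised training set
#' for the Bayesian network: counting its frequencies yields the IRP prior
#' CPTs. Each pattern appears once (unit case weight) by default; `weight`
#' scales the prior strength globally.
#'
#' @param Q a [qmatrix()].
#' @param space a [enumerate_patterns()] pattern space with K matching Q.
#' @param rule `"DINA"` or `"DINO"`.
#' @param weight positive case weight per row (default 1).
#' @return object of class `irp_dataset`: `patterns` (L x K), `responses`
#'   (L x J), `rule`, `weights`.
#' @export
build_irp_dataset <- function(Q, space, rule = c("DINA", "DINO"), weight = 1) {
  rule <- match.arg(rule)
  stopifnot(inherits(Q, "qmatrix"), inherits(space, "pattern_space"))
  if (ncol(Q$entries) != space$K) stop("Q-matrix and pattern space K differ")
  if (weight <= 0) stop("weight must be positive")
  pats <- space$patterns
  J <- nrow(Q$entries)
  resp <- matrix(0L, nrow(pats), J, dimnames = list(space$labels, Q$item_ids))
  for (j in seq_len(J)) {
    req <- which(Q$entries[j, ] == 1L)
    resp[, j] <- if (rule == "DINA") {
      as.integer(rowSums(pats[, req, drop = FALSE]) == length(req))
    } else {
      as.integer(rowSums(pats[, req, drop = FALSE]) > 0L)
    }
  }
  structure(list(patterns = pats, responses = resp, rule = rule,
                 weights = rep(weight, nrow(pats))),
            class = "irp_dataset")
}

#' Write an IRP dataset as CSV
#'
#' Same CSV dialect as response data, with a leading `pattern` bit-string
#' column and a `weight` column.
#'
#' @param irp an [build_irp_dataset()] result.
#' @param path output path.
#' @export
write_irp_dataset <- function(irp, path) {
  df <- data.frame(pattern = pattern_to_string(irp$patterns),
                   irp$responses, weight = irp$weights, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
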