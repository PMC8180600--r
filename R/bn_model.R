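#' Bayesian-network structure from a Q-matrix
#'
#' Attribute (latent) nodes get their parents from the optional prerequisite
#' hierarchy (roots when absent); each item (observed) node's parents are
#' exactly the attributes its Q-matrix row requires. Item nodes have no
#' children, so the graph is a two-layer DAG and inference can enumerate the
#' attribute-pattern space exactly.
#'
#' @param Q a [qmatrix()].
#' @param hierarchy optional [hierarchy_dag()]; its node labels must be
#'   Q-matrix attribute ids.
#' @return object of class `bn_structure`: `attribute_ids`, `item_ids`,
#'   `attr_parents` and `item_parents` (lists of integer attribute indices),
#'   `hierarchy`.
#' @export
structure_from_q <- function(Q, hierarchy = NULL) {
  stopifnot(inherits(Q, "qmatrix"))
  K <- ncol(Q$entries)
  atts <- Q$attribute_ids
  attr_parents <- rep(list(integer(0)), K)
  names(attr_parents) <- atts
  if (!is.null(hierarchy)) {
    stopifnot(inherits(hierarchy, "hierarchy_dag"))
    bad <- setdiff(hierarchy$attributes, atts)
    if (length(bad) > 0L) {
      stop("hierarchy node(s) not among Q-matrix attributes: ",
           paste(bad, collapse = ", "))
    }
    e <- hierarchy$edges
    for (i in seq_len(nrow(e))) {
      ch <- match(e[i, "child"], atts)
      pa <- match(e[i, "parent"], atts)
      attr_parents[[ch]] <- sort(unique(c(attr_parents[[ch]], pa)))
    }
  }
  item_parents <- lapply(seq_len(nrow(Q$entries)),
                         function(j) which(Q$entries[j, ] == 1L))
  names(item_parents) <- Q$item_ids
  structure(list(attribute_ids = atts, item_ids = Q$item_ids,
                 attr_parents = attr_parents, item_parents = item_parents,
                 hierarchy = hierarchy),
            class = "bn_structure")
}

#' @export
print.bn_structure <- function(x, ...) {
  cat("BN structure:", length(x$attribute_ids), "attribute nodes,",
      length(x$item_ids), "item nodes\n")
  invisible(x)
}

# Topological order of attribute indices under attr_parents.
attr_topological_order <- function(structure) {
  K <- length(structure$attribute_ids)
  placed <- logical(K)
  order <- integer(0)
  while (length(order) < K) {
    ready <- which(!placed & vapply(structure$attr_parents,
                                    function(p) all(placed[p]), logical(1)))
    if (length(ready) == 0L) stop("attribute graph contains a cycle")
    order <- c(order, ready)
    placed[ready] <- TRUE
  }
  order
}

#' Learn CPTs from complete data by counting
#'
#' Every node (attributes and items) is observed in the data, so each CPT row
#' is a smoothed relative frequency:
#' `P(node = v | pa) = (count(v, pa) + smoothing) / (count(pa) + 2 * smoothing)`.
#' The raw counts plus smoothing are stored as a Dirichlet prior-count table
#' of identical shape for downstream MAP estimation. A parent configuration
#' with zero count and zero smoothing is left uniform and flagged via a
#' message.
#'
#' Parent configurations are ordered by the bit-string convention: parents in
#' attribute order, first parent the most significant bit.
#'
#' @param data an `irp_dataset`, or a list with binary matrices `profiles`
#'   (N x K) and `responses` (N x J) (complete data), optionally `weights`.
#' @param structure a [structure_from_q()] BN structure.
#' @param smoothing non-negative pseudo-count added to every cell.
#' @return object of class `cpt_set`.
#' @export
count_cpts <- function(data, structure, smoothing = 0) {
  stopifnot(inherits(structure, "bn_structure"))
  if (smoothing < 0) stop("smoothing must be >= 0")
  if (inherits(data, "irp_dataset")) {
    pats <- data$patterns; resp <- data$responses; w <- data$weights
  } else {
    pats <- data$profiles; resp <- data$responses
    w <- if (is.null(data$weights)) rep(1, nrow(pats)) else data$weights
  }
  if (nrow(pats) != nrow(resp)) stop("profiles and responses row counts differ")
  K <- length(structure$attribute_ids)
  J <- length(structure$item_ids)
  if (ncol(pats) != K || ncol(resp) != J) stop("data does not match structure")

  count_node <- function(values, parents) {
    ncfg <- 2L^length(parents)
    cfg <- config_index(pats, parents)
    agg <- rowsum(cbind(w * (values == 1L), w), cfg)
    n1 <- numeric(ncfg); ntot <- numeric(ncfg)
    idx <- as.integer(rownames(agg))
    n1[idx] <- agg[, 1L]
    ntot[idx] <- agg[, 2L]
    prior1 <- n1 + smoothing
    prior0 <- (ntot - n1) + smoothing
    p1 <- ifelse(prior1 + prior0 > 0, prior1 / (prior1 + prior0), 0.5)
    empty <- which(prior1 + prior0 == 0)
    if (length(empty) > 0L) {
      message("CPT row(s) with zero count and zero smoothing left uniform: ",
              length(empty), " configuration(s)")
    }
    list(parents = parents, p1 = p1, prior1 = prior1, prior0 = prior0)
  }

  attr_cpts <- lapply(seq_len(K), function(k)
    count_node(pats[, k], structure$attr_parents[[k]]))
  names(attr_cpts) <- structure$attribute_ids
  item_cpts <- lapply(seq_len(J), function(j)
    count_node(resp[, j], structure$item_parents[[j]]))
  names(item_cpts) <- structure$item_ids
  new_cpt_set(structure, attr_cpts, item_cpts)
}

new_cpt_set <- function(structure, attr_cpts, item_cpts) {
  x <- structure(list(structure = structure, attr = attr_cpts,
                      item = item_cpts),
                 class = "cpt_set")
  validate_cpt_set(x)
  x
}

validate_cpt_set <- function(cpts) {
  for (nd in c(cpts$attr, cpts$item)) {
    if (any(nd$p1 < -1e-12 | nd$p1 > 1 + 1e-12)) stop("CPT probability outside [0, 1]")
    # rows are (p1, 1 - p1): row sums are 1 by construction
    if (any(nd$prior1 < 0) || any(nd$prior0 < 0)) stop("negative prior count")
  }
  invisible(cpts)
}

#' @export
print.cpt_set <- function(x, ...) {
  cat("CPT set:", length(x$attr), "attribute nodes,", length(x$item),
      "item nodes\n")
  invisible(x)
}

# Per-pattern quantities used by all inference: log prior probability of each
# admissible pattern under the attribute CPTs, and the L x J matrix of item
# success probabilities per pattern. Logs are clamped at log(1e-300) so that
# matrix products never produce NaN; exact zeros are preserved in the
# scalar-path functions (pattern_likelihood, posterior_over_patterns).
cpt_pattern_matrices <- function(cpts, space) {
  pats <- space$patterns
  L <- nrow(pats)
  K <- ncol(pats)
  lp <- numeric(L)
  for (k in seq_len(K)) {
    nd <- cpts$attr[[k]]
    cfg <- config_index(pats, nd$parents)
    pk <- nd$p1[cfg]
    lp <- lp + ifelse(pats[, k] == 1L, log(pk), log1p(-pk))
  }
  J <- length(cpts$item)
  P <- matrix(0, L, J)
  for (j in seq_len(J)) {
    nd <- cpts$item[[j]]
    cfg <- config_index(pats, nd$parents)
    P[, j] <- nd$p1[cfg]
  }
  list(log_prior = lp, P = P)
}

clamp_log <- function(x) pmax(x, log(1e-300))

# Batch posterior over patterns for a whole response matrix.
# Returns W (N x L, rows sum to 1), loglik (sum over examinees of the log
# marginal), and ll_il for reuse.
batch_posterior <- function(cpts, X, space) {
  mats <- cpt_pattern_matrices(cpts, space)
  l1 <- clamp_log(log(mats$P))
  l0 <- clamp_log(log1p(-mats$P))
  lpri <- clamp_log(mats$log_prior)
  # ll[i, l] = log prior_l + sum_j x_ij l1[l,j] + (1-x_ij) l0[l,j]
  ll <- X %*% t(l1 - l0)
  ll <- sweep(ll, 2L, rowSums(l0) + lpri, "+")
  m <- apply(ll, 1L, max)
  W <- exp(ll - m)
  s <- rowSums(W)
  list(W = W / s, loglik = sum(log(s) + m))
}

#' Joint probability of one attribute pattern and one response vector
#'
#' The BN joint factorizes as the product of each attribute's CPT entry given
#' its hierarchy parents and each item's CPT entry given the attributes it
#' requires. Exact zeros are preserved.
#'
#' @param cpts a [count_cpts()] CPT set.
#' @param pattern binary K-vector.
#' @param response binary J-vector.
#' @return the joint probability.
#' @export
pattern_likelihood <- function(cpts, pattern, response) {
  K <- length(cpts$attr); J <- length(cpts$item)
  if (length(pattern) != K) stop("pattern length != number of attributes")
  if (length(response) != J) stop("response length != number of items")
  pm <- matrix(as.integer(pattern), 1L)
  pr <- 1
  for (k in seq_len(K)) {
    nd <- cpts$attr[[k]]
    p <- nd$p1[config_index(pm, nd$parents)]
    pr <- pr * if (pattern[k] == 1) p else 1 - p
  }
  for (j in seq_len(J)) {
    nd <- cpts$item[[j]]
    p <- nd$p1[config_index(pm, nd$parents)]
    pr <- pr * if (response[j] == 1) p else 1 - p
  }
  pr
}

#' Posterior distribution over attribute patterns for one examinee
#'
#' Belief updating by exact enumeration: the joint probability of each
#' admissible pattern with the observed response vector, normalized. With a
#' hierarchy, inadmissible patterns are excluded (posterior mass exactly 0).
#'
#' @param cpts a [count_cpts()] CPT set.
#' @param response binary J-vector.
#' @param space the admissible [enumerate_patterns()] space.
#' @return object of class `pattern_posterior`: `prob` (named by pattern
#'   bit-string, sums to 1), `patterns`.
#' @export
posterior_over_patterns <- function(cpts, response, space) {
  pats <- space$patterns
  lik <- vapply(seq_len(nrow(pats)), function(l)
    pattern_likelihood(cpts, pats[l, ], response), numeric(1))
  if (all(lik == 0)) {
    stop("all patterns have zero likelihood for response ",
         paste(as.integer(response), collapse = ""))
  }
  structure(list(prob = stats::setNames(lik / sum(lik), space$labels),
                 patterns = pats),
            class = "pattern_posterior")
}

#' MAP attribute-pattern classification
#'
#' The posterior-mode pattern; ties broken by the lexicographically smallest
#' bit-string.
#'
#' @param posterior a [posterior_over_patterns()] result.
#' @return binary K-vector.
#' @export
classify_map <- function(posterior) {
  stopifnot(inherits(posterior, "pattern_posterior"))
  posterior$patterns[which.max(posterior$prob), ]
}

#' Batch MAP classification of a response matrix
#'
#' [classify_map()] applied to every examinee's posterior at once.
#'
#' @param cpts a [count_cpts()] CPT set.
#' @param data a [response_data()] or binary matrix.
#' @param space admissible pattern space.
#' @return N x K binary matrix of MAP patterns.
#' @export
classify_responses <- function(cpts, data, space) {
  X <- if (inherits(data, "response_data")) data$responses else data
  bp <- batch_posterior(cpts, X, space)
  space$patterns[max.col(bp$W, ties.method = "first"), , drop = FALSE]
}

#' Marginal log-likelihood of response data under a BN
#'
#' Sum over examinees of the log of the pattern-marginalized joint:
#' `sum_i log sum_l P(pattern_l, x_i)`.
#'
#' @param cpts a [count_cpts()] CPT set.
#' @param data a [response_data()] or binary matrix.
#' @param space admissible pattern space.
#' @return scalar log-likelihood.
#' @export
data_loglik <- function(cpts, data, space) {
  X <- if (inherits(data, "response_data")) data$responses else data
  batch_posterior(cpts, X, space)$loglik
}

#' Forward (ancestral) sampling from a BN
#'
#' Samples attributes in topological order given their hierarchy parents,
#' then items given the sampled attributes; returns the true profiles
#' alongside the responses.
#'
#' @param cpts a [count_cpts()] CPT set.
#' @param structure the matching [structure_from_q()] structure.
#' @param n number of examinees.
#' @param seed integer seed.
#' @return list with `profiles` (n x K) and `responses` ([response_data()]).
#' @export
forward_sample <- function(cpts, structure, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- length(structure$attribute_ids)
  J <- length(structure$item_ids)
  prof <- matrix(0L, n, K, dimnames = list(NULL, structure$attribute_ids))
  for (k in attr_topological_order(structure)) {
    nd <- cpts$attr[[k]]
    cfg <- config_index(prof, nd$parents)
    prof[, k] <- as.integer(stats::runif(n) < nd$p1[cfg])
  }
  resp <- matrix(0L, n, J, dimnames = list(NULL, structure$item_ids))
  for (j in seq_len(J)) {
    nd <- cpts$item[[j]]
    cfg <- config_index(prof, nd$parents)
    resp[, j] <- as.integer(stats::runif(n) < nd$p1[cfg])
  }
  list(profiles = prof, responses = response_data(resp, item_ids = structure$item_ids))
}

#' Serialize a CPT set to JSON
#'
#' Node -> parent-config-ordered probability rows plus prior counts; parent
#' configurations follow the bit-string convention (first parent most
#' significant).
#'
#' @param cpts a `cpt_set`.
#' @param path output path.
#' @export
write_cpts <- function(cpts, path) {
  enc <- function(nd, ids) list(
    parents = ids[nd$parents],
    prob = cbind(`1` = nd$p1, `0` = 1 - nd$p1),
    prior = cbind(`1` = nd$prior1, `0` = nd$prior0))
  out <- list(
    attributes = lapply(cpts$attr, enc, ids = cpts$structure$attribute_ids),
    items = lapply(cpts$item, enc, ids = cpts$structure$attribute_ids))
  jsonlite::write_json(out, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
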