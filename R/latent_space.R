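#' Enumerate the admissible attribute-pattern space
#'
#' Without a hierarchy the space is all 2^K binary mastery patterns. With a
#' prerequisite hierarchy a pattern is admissible only if every mastered
#' attribute has all its (transitive) hierarchy ancestors mastered, so the
#' space shrinks below 2^K. Patterns are kept in lexicographic bit-string
#' order.
#'
#' @param K number of attributes (>= 1).
#' @param hierarchy optional [hierarchy_dag()] over the K attributes.
#' @param attribute_ids attribute labels; default `A1..AK`. Hierarchy node
#'   labels must be a subset.
#' @return object of class `pattern_space`: list with `patterns` (L x K
#'   integer matrix), `K`, `hierarchy`, `labels` (bit-strings).
#' @examples
#' enumerate_patterns(2)$patterns
#' h <- hierarchy_dag(rbind(c("A1", "A2"), c("A2", "A3")))
#' pattern_to_string(enumerate_patterns(3, h)$patterns)  # 000 100 110 111
#' @export
enumerate_patterns <- function(K, hierarchy = NULL, attribute_ids = NULL) {
  if (K < 1L) stop("K must be >= 1")
  if (is.null(attribute_ids)) attribute_ids <- paste0("A", seq_len(K))
  m <- all_binary_patterns(K)
  colnames(m) <- attribute_ids
  if (!is.null(hierarchy)) {
    stopifnot(inherits(hierarchy, "hierarchy_dag"))
    if (!all(hierarchy$attributes %in% attribute_ids)) {
      stop("hierarchy attribute(s) not in the pattern space: ",
           paste(setdiff(hierarchy$attributes, attribute_ids), collapse = ", "))
    }
    h <- hierarchy
    h$attributes <- attribute_ids
    anc <- ancestor_matrix(h, attribute_ids)
    ok <- apply(m, 1L, function(p) {
      mastered <- which(p == 1L)
      all(vapply(mastered, function(k) all(p[anc[, k]] == 1L), logical(1)))
    })
    m <- m[ok, , drop = FALSE]
  }
  structure(list(patterns = m, K = K, hierarchy = hierarchy,
                 labels = pattern_to_string(m)),
            class = "pattern_space")
}

#' @export
print.pattern_space <- function(x, ...) {
  cat("pattern space: K =", x$K, ",", nrow(x$patterns), "admissible patterns",
      if (!is.null(x$hierarchy)) "(hierarchy-restricted)" else "", "\n")
  invisible(x)
}

#' Sample attribute profiles uniformly over a pattern space
#'
#' Each admissible pattern has probability 1/|space| (1/2^K without a
#' hierarchy).
#'
#' @param n number of profiles to draw.
#' @param space a [enumerate_patterns()] pattern space.
#' @param seed integer seed.
#' @return n x K integer matrix of profiles.
#' @export
sample_uniform <- function(n, space, seed = NULL) {
  stopifnot(inherits(space, "pattern_space"))
  L <- nrow(space$patterns)
  if (L == 0L) stop("empty pattern space")
  if (n < 1L) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(L, n, replace = TRUE)
  space$patterns[idx, , drop = FALSE]
}

#' Specification of the thresholded multivariate-normal profile sampler
#'
#' Latent scores theta_i ~ MVN(0, Sigma) with unit variances and
#' compound-symmetry correlation `rho`; attribute k is mastered iff
#' theta_ik >= qnorm(k / (K + 1)), so the marginal mastery probability of
#' attribute k is 1 - k / (K + 1).
#'
#' @param K number of attributes.
#' @param rho common latent correlation, -1 < rho < 1 (and Sigma must be
#'   positive definite, i.e. rho > -1 / (K - 1)).
#' @return object of class `mvn_sampler_spec` with `K`, `rho`, `thresholds`,
#'   `sigma`.
#' @export
mvn_sampler_spec <- function(K, rho = 0.5) {
  if (rho <= -1 || rho >= 1) stop("rho must be in (-1, 1)")
  sigma <- matrix(rho, K, K)
  diag(sigma) <- 1
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("covariance matrix not positive definite")
  structure(list(K = K, rho = rho,
                 thresholds = stats::qnorm(seq_len(K) / (K + 1)),
                 sigma = sigma),
            class = "mvn_sampler_spec")
}

#' Sample correlated attribute profiles via a thresholded MVN
#'
#' @param n number of profiles.
#' @param spec a [mvn_sampler_spec()].
#' @param seed integer seed.
#' @return n x K integer matrix of profiles.
#' @export
sample_mvnorm <- function(n, spec, seed = NULL) {
  stopifnot(inherits(spec, "mvn_sampler_spec"))
  if (n < 1L) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  R <- chol(spec$sigma)
  theta <- matrix(stats::rnorm(n * spec$K), n, spec$K) %*% R
  alpha <- matrix(0L, n, spec$K,
                  dimnames = list(NULL, paste0("A", seq_len(spec$K))))
  for (k in seq_len(spec$K)) {
    alpha[, k] <- as.integer(theta[, k] >= spec$thresholds[k])
  }
  alpha
}
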