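#' Fitting options
#'
#' @param max_iter maximum EM iterations.
#' @param tol relative log-posterior convergence tolerance.
#' @param smoothing pseudo-count added to IRP counts when building prior CPTs
#'   (strictly positive priors are required for refinement: raw IRP counting
#'   yields 0/1 item CPTs that are absorbing in the E-step).
#' @param max_cg maximum conjugate-gradient iterations; each iteration costs
#'   roughly three objective/gradient evaluations, so the default keeps the
#'   total near 2000 evaluations.
#' @param seed seed for random initialization of the plain EM/GD baselines.
#' @param fallback_gain_factor the DINA->DINO fallback fires when the relative
#'   log-likelihood gain over the prior-only model is below
#'   `fallback_gain_factor * tol`.
#' @param fallback_violation_frac ... or when the fraction of item-CPT
#'   comparable parent-config pairs violating monotonicity exceeds this.
#' @return list of class `fit_options`.
#' @export
fit_options <- function(max_iter = 500L, tol = 1e-6, smoothing = 0.01,
                        max_cg = 600L, seed = NULL,
                        fallback_gain_factor = 10,
                        fallback_violation_frac = 0.5) {
  if (tol <= 0) stop("tol must be > 0")
  if (max_iter < 0L) stop("max_iter must be >= 0")
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 smoothing = smoothing, max_cg = as.integer(max_cg),
                 seed = seed, fallback_gain_factor = fallback_gain_factor,
                 fallback_violation_frac = fallback_violation_frac),
            class = "fit_options")
}

# Pattern space matching a BN structure (hierarchy-restricted when present).
space_for_structure <- function(structure) {
  enumerate_patterns(length(structure$attribute_ids), structure$hierarchy,
                     attribute_ids = structure$attribute_ids)
}

# Dirichlet log-prior term: sum over nodes/configs of
# prior1 * log(p) + prior0 * log(1 - p). Prior counts act as Dirichlet
# exponents so that the MAP update is (prior + expected count), normalized.
log_prior_term <- function(cpts, prior) {
  s <- 0
  for (grp in c("attr", "item")) {
    for (i in seq_along(cpts[[grp]])) {
      p <- cpts[[grp]][[i]]$p1
      pr <- prior[[grp]][[i]]
      s <- s + sum(pr$prior1 * clamp_log(log(p)) +
                   pr$prior0 * clamp_log(log1p(-p)))
    }
  }
  s
}

# Precompute, per node, the parent-config index of every pattern in `space`.
node_config_map <- function(structure, space) {
  pats <- space$patterns
  list(
    attr = lapply(structure$attr_parents, function(pa) config_index(pats, pa)),
    item = lapply(structure$item_parents, function(pa) config_index(pats, pa)))
}

# Expected sufficient statistics given posterior weights W (N x L):
# for each node, expected counts of (value = 1, config) and (config).
expected_counts <- function(W, X, space, structure, cfgmap) {
  pats <- space$patterns
  m <- colSums(W)                       # expected pattern occupancy, length L
  N1 <- crossprod(W, X)                 # L x J expected correct counts
  agg <- function(v, cfg, ncfg) {
    out <- numeric(ncfg)
    a <- rowsum(v, cfg)
    out[as.integer(rownames(a))] <- a
    out
  }
  attr_counts <- lapply(seq_along(structure$attr_parents), function(k) {
    cfg <- cfgmap$attr[[k]]
    ncfg <- 2L^length(structure$attr_parents[[k]])
    e1 <- agg(m * (pats[, k] == 1L), cfg, ncfg)
    etot <- agg(m, cfg, ncfg)
    list(e1 = e1, e0 = etot - e1)
  })
  item_counts <- lapply(seq_along(structure$item_parents), function(j) {
    cfg <- cfgmap$item[[j]]
    ncfg <- 2L^length(structure$item_parents[[j]])
    e1 <- agg(N1[, j], cfg, ncfg)
    etot <- agg(m, cfg, ncfg)
    list(e1 = e1, e0 = etot - e1)
  })
  list(attr = attr_counts, item = item_counts)
}

# Replace every node's p1 with new values (same shapes).
set_probs <- function(cpts, probs) {
  for (grp in c("attr", "item")) {
    for (i in seq_along(cpts[[grp]])) cpts[[grp]][[i]]$p1 <- probs[[grp]][[i]]
  }
  cpts
}

get_probs <- function(cpts) {
  list(attr = lapply(cpts$attr, `[[`, "p1"),
       item = lapply(cpts$item, `[[`, "p1"))
}

new_fit_result <- function(cpts, log_posterior, loglik, iterations, converged,
                           prior_source = "none", fallback_used = FALSE,
                           method = NA_character_) {
  structure(list(cpts = cpts, log_posterior = log_posterior, loglik = loglik,
                 iterations = iterations, converged = converged,
                 prior_source = prior_source, fallback_used = fallback_used,
                 method = method),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("BN fit (%s, prior %s): loglik %.4f, %d iteration(s), %s%s\n",
              x$method, x$prior_source, x$loglik, x$iterations,
              if (x$converged) "converged" else "not converged",
              if (x$fallback_used) ", DINO fallback" else ""))
  invisible(x)
}

check_positive_init <- function(init) {
  for (nd in c(init$attr, init$item)) {
    if (any(nd$p1 <= 0 | nd$p1 >= 1)) {
      stop("initial CPT rows must be strictly positive (got a 0/1 entry); ",
           "use a positive smoothing pseudo-count")
    }
  }
}

#' EM estimation of BN CPTs with a Dirichlet prior
#'
#' Dirichlet-MAP EM for the latent-attribute BN. The E-step computes each
#' examinee's posterior over admissible attribute patterns under the current
#' CPTs; expected counts for every node / parent-configuration cell
#' accumulate the posterior-weighted occurrences. The M-step sets each CPT
#' row to (prior count + expected count), normalized, where the prior counts
#' are taken from `init`'s prior-count table (the IRP counts, for the
#' IRP-prior pipeline). Iterates until the relative log-posterior change
#' drops below `opts$tol`; the log-posterior is asserted non-decreasing at
#' every iteration.
#'
#' @param data a [response_data()].
#' @param structure a [structure_from_q()] BN structure.
#' @param init a `cpt_set` with strictly positive rows; its prior-count table
#'   defines the Dirichlet prior.
#' @param opts a [fit_options()].
#' @return a `fit_result`.
#' @export
em_fit <- function(data, structure, init, opts = fit_options()) {
  check_positive_init(init)
  X <- if (inherits(data, "response_data")) data$responses else data
  space <- space_for_structure(structure)
  cfgmap <- node_config_map(structure, space)
  cpts <- init
  bp <- batch_posterior(cpts, X, space)
  lp <- bp$loglik + log_prior_term(cpts, init)
  if (opts$max_iter == 0L) {
    return(new_fit_result(cpts, lp, bp$loglik, 0L, TRUE, method = "EM"))
  }
  converged <- FALSE
  iter <- 0L
  while (iter < opts$max_iter) {
    iter <- iter + 1L
    ec <- expected_counts(bp$W, X, space, structure, cfgmap)
    probs <- get_probs(cpts)
    for (grp in c("attr", "item")) {
      for (i in seq_along(probs[[grp]])) {
        a1 <- init[[grp]][[i]]$prior1 + ec[[grp]][[i]]$e1
        a0 <- init[[grp]][[i]]$prior0 + ec[[grp]][[i]]$e0
        probs[[grp]][[i]] <- ifelse(a1 + a0 > 0, a1 / (a1 + a0),
                                    probs[[grp]][[i]])
      }
    }
    cpts <- set_probs(cpts, probs)
    bp <- batch_posterior(cpts, X, space)
    lp_new <- bp$loglik + log_prior_term(cpts, init)
    if (lp_new < lp - 1e-8 * max(1, abs(lp))) {
      stop(sprintf("internal error: EM log-posterior decreased (%.10g -> %.10g)",
                   lp, lp_new))
    }
    if (abs(lp_new - lp) < opts$tol * abs(lp)) {
      lp <- lp_new
      converged <- TRUE
      break
    }
    lp <- lp_new
  }
  new_fit_result(cpts, lp, bp$loglik, iter, converged, method = "EM")
}

#' Conjugate-gradient estimation of BN CPTs with a Dirichlet prior
#'
#' Minimizes the negative log-posterior (marginal log-likelihood plus the
#' Dirichlet prior terms from `init`'s count table) over all CPT rows,
#' reparameterized per row on the unconstrained scale (logit of the
#' success/mastery probability). Uses Polak-Ribiere nonlinear conjugate
#' gradient ([stats::optim()] `method = "CG", type = 2`) with the analytic
#' gradient: for a row with logit eta and probability p, the gradient of the
#' log-posterior is `(e1 + prior1) (1 - p) - (e0 + prior0) p` where e1/e0 are
#' the E-step expected counts at the current point. Returns the best point
#' found; the final log-posterior is never below `init`'s.
#'
#' @inheritParams em_fit
#' @return a `fit_result`.
#' @export
gd_fit <- function(data, structure, init, opts = fit_options()) {
  check_positive_init(init)
  X <- if (inherits(data, "response_data")) data$responses else data
  space <- space_for_structure(structure)
  cfgmap <- node_config_map(structure, space)

  probs0 <- get_probs(cpts <- init)
  lens <- list(attr = lengths(probs0$attr), item = lengths(probs0$item))
  flatten <- function(probs) stats::qlogis(unlist(c(probs$attr, probs$item),
                                                  use.names = FALSE))
  unflatten <- function(theta) {
    p <- stats::plogis(theta)
    off <- 0L
    out <- list(attr = vector("list", length(lens$attr)),
                item = vector("list", length(lens$item)))
    for (grp in c("attr", "item")) {
      for (i in seq_along(lens[[grp]])) {
        n <- lens[[grp]][[i]]
        out[[grp]][[i]] <- p[off + seq_len(n)]
        off <- off + n
      }
    }
    out
  }

  # optim evaluates fn and gr back to back at the same point; cache the
  # E-step there so each CG iteration runs one posterior pass, not two
  cache <- new.env(parent = emptyenv())
  posterior_at <- function(theta) {
    if (!is.null(cache$theta) && identical(cache$theta, theta)) {
      return(cache$bp)
    }
    bp <- batch_posterior(set_probs(init, unflatten(theta)), X, space)
    cache$theta <- theta
    cache$bp <- bp
    bp
  }

  neg_log_post <- function(theta) {
    cp <- set_probs(init, unflatten(theta))
    -(posterior_at(theta)$loglik + log_prior_term(cp, init))
  }
  neg_grad <- function(theta) {
    probs <- unflatten(theta)
    bp <- posterior_at(theta)
    ec <- expected_counts(bp$W, X, space, structure, cfgmap)
    g <- numeric(0)
    for (grp in c("attr", "item")) {
      for (i in seq_along(probs[[grp]])) {
        p <- probs[[grp]][[i]]
        a1 <- ec[[grp]][[i]]$e1 + init[[grp]][[i]]$prior1
        a0 <- ec[[grp]][[i]]$e0 + init[[grp]][[i]]$prior0
        g <- c(g, a1 * (1 - p) - a0 * p)
      }
    }
    if (any(!is.finite(g))) {
      stop("non-finite gradient in gd_fit (max |theta| = ",
           format(max(abs(theta))), ")")
    }
    -g
  }

  theta0 <- flatten(probs0)
  bp0 <- batch_posterior(init, X, space)
  lp0 <- bp0$loglik + log_prior_term(init, init)
  if (opts$max_cg == 0L) {
    return(new_fit_result(init, lp0, bp0$loglik, 0L, TRUE, method = "GD"))
  }
  res <- stats::optim(theta0, fn = neg_log_post, gr = neg_grad, method = "CG",
                      control = list(type = 2, maxit = opts$max_cg,
                                     reltol = opts$tol))
  if (-res$value >= lp0) {
    cpts <- set_probs(init, unflatten(res$par))
    lp <- -res$value
  } else {                              # CG failed to improve: keep init
    cpts <- init
    lp <- lp0
  }
  ll <- batch_posterior(cpts, X, space)$loglik
  new_fit_result(cpts, lp, ll, res$counts[["gradient"]],
                 res$convergence == 0L, method = "GD")
}

# Fraction of item-CPT comparable parent-config pairs (configs ordered
# componentwise, differing in one mastered parent) where mastering more
# parents lowers the success probability by more than eps. The epsilon keeps
# sampling noise on exactly-tied rows (conjunctive generators tie all
# non-complete configurations) from counting as violations.
monotonicity_violation_fraction <- function(cpts, structure, eps = 0.01) {
  viol <- 0L
  total <- 0L
  for (j in seq_along(cpts$item)) {
    np <- length(structure$item_parents[[j]])
    if (np == 0L) next
    pairs <- covering_pairs(np)
    p <- cpts$item[[j]]$p1
    viol <- viol + sum(p[pairs[, 1L]] > p[pairs[, 2L]] + eps)
    total <- total + nrow(pairs)
  }
  if (total == 0L) 0 else viol / total
}

# Covering pairs (lower, upper) of the 2^K config lattice, 1-based bit-string
# indices: upper = lower with exactly one extra mastered parent.
covering_pairs <- function(K) {
  cfgs <- all_binary_patterns(K)
  lower <- integer(0); upper <- integer(0)
  for (i in seq_len(nrow(cfgs))) {
    for (k in which(cfgs[i, ] == 0L)) {
      up <- cfgs[i, ]
      up[k] <- 1L
      lower <- c(lower, i)
      upper <- c(upper, config_index(matrix(up, 1L), seq_len(K)))
    }
  }
  cbind(lower, upper)
}

#' Fit a BN with an ideal-response-pattern prior
#'
#' The combined pipeline: build the IRP dataset under the first condensation
#' rule (DINA by default), count smoothed CPTs from it as the informative
#' Dirichlet prior and starting point, and refine on the observed responses
#' by EM or conjugate gradient. If the refinement looks trapped in a poor
#' local optimum -- relative log-likelihood gain over the prior-only model
#' below `fallback_gain_factor * tol`, or more than
#' `fallback_violation_frac` of the comparable item-CPT pairs violating
#' monotonicity -- the fit is repeated with the next rule (DINO) and the fit
#' with the higher final log-likelihood is returned, with the fallback flag
#' set.
#'
#' @param data a [response_data()].
#' @param Q a [qmatrix()].
#' @param hierarchy optional [hierarchy_dag()].
#' @param rule_sequence condensation rules to try, in order.
#' @param method `"EM"` or `"GD"`.
#' @param opts a [fit_options()].
#' @return a `fit_result` with `prior_source` naming the rule used.
#' @export
fit_with_irp_prior <- function(data, Q, hierarchy = NULL,
                               rule_sequence = c("DINA", "DINO"),
                               method = c("EM", "GD"),
                               opts = fit_options()) {
  method <- match.arg(method)
  structure <- structure_from_q(Q, hierarchy)
  space <- space_for_structure(structure)
  fit_one <- function(rule) {
    irp <- build_irp_dataset(Q, space, rule)
    init <- count_cpts(irp, structure, smoothing = opts$smoothing)
    fit <- if (method == "EM") em_fit(data, structure, init, opts)
           else gd_fit(data, structure, init, opts)
    fit$prior_source <- paste0(rule, "_IRP")
    ll0 <- data_loglik(init, data, space)
    rel_gain <- (fit$loglik - ll0) / abs(ll0)
    viol <- monotonicity_violation_fraction(fit$cpts, structure)
    fit$trapped <- rel_gain < opts$fallback_gain_factor * opts$tol ||
      viol > opts$fallback_violation_frac
    fit
  }
  fit <- fit_one(rule_sequence[1L])
  if (length(rule_sequence) > 1L && isTRUE(fit$trapped)) {
    alt <- fit_one(rule_sequence[2L])
    if (alt$loglik > fit$loglik) fit <- alt
    fit$fallback_used <- TRUE
  }
  fit$method <- method
  fit
}

#' Fit a BN from a random start with flat unit priors
#'
#' The plain EM / conjugate-gradient baselines: every CPT row is initialized
#' from a uniform draw (seeded) with unit uniform Dirichlet prior counts.
#' These baselines are not monotonicity-protected and routinely land in poor
#' local optima -- which is the phenomenon the IRP prior exists to fix.
#'
#' @param data a [response_data()].
#' @param structure a [structure_from_q()] BN structure.
#' @param method `"EM"` or `"GD"`.
#' @param opts a [fit_options()]; `opts$seed` seeds the initialization.
#' @return a `fit_result`.
#' @export
fit_plain <- function(data, structure, method = c("EM", "GD"),
                      opts = fit_options()) {
  method <- match.arg(method)
  if (!is.null(opts$seed)) set.seed(opts$seed)
  rand_node <- function(parents) {
    ncfg <- 2L^length(parents)
    # keep away from the boundary so logits stay finite
    p <- stats::runif(ncfg, 0.01, 0.99)
    list(parents = parents, p1 = p, prior1 = rep(1, ncfg),
         prior0 = rep(1, ncfg))
  }
  attr_cpts <- lapply(structure$attr_parents, rand_node)
  item_cpts <- lapply(structure$item_parents, rand_node)
  init <- new_cpt_set(structure, attr_cpts, item_cpts)
  fit <- if (method == "EM") em_fit(data, structure, init, opts)
         else gd_fit(data, structure, init, opts)
  fit$prior_source <- "none"
  fit
}
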