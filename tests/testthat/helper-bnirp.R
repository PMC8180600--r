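# Shared fixtures and independent oracles, built in code.

toy_space <- function() enumerate_patterns(2, attribute_ids = c("A1", "A2"))

# Raw-count CPTs of the 2-item/2-attribute worked example (Table-3 analogue).
toy_cpts <- function(smoothing = 0) {
  Q <- qmatrix_toy2()
  irp <- build_irp_dataset(Q, toy_space(), "DINA")
  count_cpts(irp, structure_from_q(Q), smoothing = smoothing)
}

# Random strictly-positive CPT set for a structure (test-local).
random_cpts <- function(structure, seed) {
  set.seed(seed)
  rn <- function(parents) {
    ncfg <- 2L^length(parents)
    list(parents = parents, p1 = runif(ncfg, 0.05, 0.95),
         prior1 = rep(1, ncfg), prior0 = rep(1, ncfg))
  }
  bnirp:::new_cpt_set(structure,
                      lapply(structure$attr_parents, rn),
                      lapply(structure$item_parents, rn))
}

# Random small Q-matrix (every row nonzero), test-local.
random_qmatrix <- function(J, K, seed) {
  set.seed(seed)
  repeat {
    m <- matrix(rbinom(J * K, 1, 0.5), J, K)
    if (all(rowSums(m) >= 1)) return(qmatrix(m))
  }
}

# Independent brute-force joint probability of (pattern, response) from the
# raw CPT lists: explicit scalar loops, no shared code path with
# batch_posterior / cpt_pattern_matrices.
oracle_joint <- function(cpts, pattern, response, structure) {
  pr <- 1
  for (k in seq_along(cpts$attr)) {
    pa <- structure$attr_parents[[k]]
    idx <- 1L
    if (length(pa) > 0L) {
      bits <- pattern[pa]
      idx <- sum(bits * 2^(rev(seq_along(pa)) - 1)) + 1L
    }
    p <- cpts$attr[[k]]$p1[idx]
    pr <- pr * (if (pattern[k] == 1) p else 1 - p)
  }
  for (j in seq_along(cpts$item)) {
    pa <- structure$item_parents[[j]]
    bits <- pattern[pa]
    idx <- sum(bits * 2^(rev(seq_along(pa)) - 1)) + 1L
    p <- cpts$item[[j]]$p1[idx]
    pr <- pr * (if (response[j] == 1) p else 1 - p)
  }
  pr
}

oracle_posterior <- function(cpts, response, space, structure) {
  lik <- sapply(seq_len(nrow(space$patterns)), function(l)
    oracle_joint(cpts, space$patterns[l, ], response, structure))
  lik / sum(lik)
}

oracle_loglik <- function(cpts, X, space, structure) {
  sum(apply(X, 1L, function(x) {
    log(sum(sapply(seq_len(nrow(space$patterns)), function(l)
      oracle_joint(cpts, space$patterns[l, ], x, structure))))
  }))
}
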