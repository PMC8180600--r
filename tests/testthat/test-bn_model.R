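test_that("structure_from_q maps Q rows and hierarchy edges to parent sets", {
  Q <- qmatrix_sim30()
  st <- structure_from_q(Q)
  expect_equal(unname(st$item_parents[["I21"]]), 1:3)   # I21 requires A1,A2,A3
  expect_true(all(lengths(st$attr_parents) == 0L))      # roots without hierarchy

  st1 <- structure_from_q(qmatrix(matrix(1, 1, 1)))
  expect_equal(length(st1$attribute_ids), 1L)
  expect_equal(unname(st1$item_parents[[1]]), 1L)

  h <- hierarchy_dag(rbind(c("A1", "A2")), attributes = paste0("A", 1:5))
  st2 <- structure_from_q(Q, h)
  expect_equal(unname(st2$attr_parents[["A2"]]), 1L)
  hbad <- hierarchy_dag(rbind(c("A1", "A9")))
  expect_error(structure_from_q(Q, hbad), "not among")
})

test_that("counting on the toy IRP data reproduces the worked CPTs exactly", {
  cp <- toy_cpts(smoothing = 0)
  expect_equal(cp$attr$A1$p1, 0.5)               # 2/4
  expect_equal(cp$attr$A2$p1, 0.5)
  # item 1 | (A1,A2) configs 00,01,10,11
  expect_equal(cp$item$Item1$p1, c(0, 0, 0, 1))
  # item 2 requires A2 only, so its CPT conditions on A2: configs 0,1. The
  # worked table's four-row display P(Item2|A1,A2) is its redundant
  # expansion, checked entry-by-entry:
  expect_equal(cp$item$Item2$p1, c(0, 1))
  for (a1 in 0:1) for (a2 in 0:1) {
    cfg <- bnirp:::config_index(matrix(c(a1, a2), 1), cp$item$Item2$parents)
    expect_equal(cp$item$Item2$p1[cfg], a2)   # = the four-row table entries
  }
  # prior counts carry the raw counts
  expect_equal(cp$item$Item1$prior1, c(0, 0, 0, 1))
  expect_equal(cp$item$Item1$prior0, c(1, 1, 1, 0))

  cps <- toy_cpts(smoothing = 0.01)
  expect_equal(cps$item$Item1$p1[4], 1.01 / 1.02)
})

test_that("degenerate and unseen-configuration counting behaves as documented", {
  Q <- qmatrix_toy2()
  st <- structure_from_q(Q)
  dat <- list(profiles = rbind(c(1L, 1L), c(1L, 1L)),
              responses = rbind(c(1L, 1L), c(1L, 1L)))
  expect_message(cp <- count_cpts(dat, st, smoothing = 0), "left uniform")
  expect_equal(cp$attr$A1$p1, 1)                 # all-identical rows: 0/1 CPTs
  expect_equal(cp$item$Item1$p1[4], 1)
  expect_equal(cp$item$Item1$p1[1], 0.5)         # unseen config left uniform
})

test_that("pattern likelihood is the exact product of CPT entries", {
  # flat CPTs: 0.5^4
  st <- structure_from_q(qmatrix_toy2())
  flat <- random_cpts(st, seed = 1)
  for (g in c("attr", "item")) for (i in 1:2) flat[[g]][[i]]$p1[] <- 0.5
  expect_equal(pattern_likelihood(flat, c(0, 1), c(1, 0)), 0.0625)

  cp <- toy_cpts()
  expect_equal(pattern_likelihood(cp, c(1, 1), c(1, 1)), 0.25)  # .5*.5*1*1
  expect_equal(pattern_likelihood(cp, c(1, 0), c(1, 1)), 0)
  expect_error(pattern_likelihood(cp, c(1, 0, 1), c(1, 1)), "pattern length")
})

test_that("posterior over patterns: flat uniformity and noiseless identification", {
  st <- structure_from_q(qmatrix_toy2())
  sp <- toy_space()
  flat <- random_cpts(st, seed = 2)
  for (g in c("attr", "item")) for (i in 1:2) flat[[g]][[i]]$p1[] <- 0.5
  po <- posterior_over_patterns(flat, c(1, 0), sp)
  expect_equal(unname(po$prob), rep(0.25, 4))

  cp <- toy_cpts()
  expect_equal(unname(posterior_over_patterns(cp, c(0, 1), sp)$prob),
               c(0, 1, 0, 0))
  expect_equal(unname(posterior_over_patterns(cp, c(1, 1), sp)$prob),
               c(0, 0, 0, 1))
  # response unreachable under deterministic CPTs
  expect_error(posterior_over_patterns(cp, c(1, 0), sp), "zero likelihood.*10")
})

test_that("MAP classification breaks ties toward the smaller bit-string", {
  sp <- toy_space()
  po <- structure(list(prob = setNames(c(0.5, 0, 0, 0.5), sp$labels),
                       patterns = sp$patterns),
                  class = "pattern_posterior")
  expect_equal(unname(classify_map(po)), c(0L, 0L))
  po$prob <- setNames(c(0, 1, 0, 0), sp$labels)
  expect_equal(unname(classify_map(po)), c(0L, 1L))
})

test_that("noiseless DINA data is classified perfectly on the 30x5 design", {
  Q <- qmatrix_sim30()
  st <- structure_from_q(Q)
  sp <- enumerate_patterns(5)
  irp <- build_irp_dataset(Q, sp, "DINA")
  cp <- count_cpts(irp, st, smoothing = 0.001)
  pred <- bnirp:::classify_responses(cp, irp$responses, sp)
  expect_equal(unname(pred), unname(sp$patterns))
})

test_that("posterior and marginal log-likelihood match brute-force enumeration", {
  set.seed(33)
  for (rep in 1:6) {
    K <- sample(2:4, 1)
    J <- sample(3:5, 1)
    Q <- random_qmatrix(J, K, seed = 100 + rep)
    h <- if (rep %% 2 == 0) hierarchy_dag(rbind(c("A1", "A2"))) else NULL
    st <- structure_from_q(Q, h)
    sp <- bnirp:::space_for_structure(st)
    cp <- random_cpts(st, seed = 200 + rep)
    X <- matrix(rbinom(4 * J, 1, 0.5), 4, J)
    for (i in 1:4) {
      po <- posterior_over_patterns(cp, X[i, ], sp)
      expect_equal(unname(po$prob), oracle_posterior(cp, X[i, ], sp, st),
                   tolerance = 1e-10)
    }
    expect_equal(data_loglik(cp, X, sp), oracle_loglik(cp, X, sp, st),
                 tolerance = 1e-10)
  }
})

test_that("log-likelihood closed forms and monotonicity in examinees", {
  st <- structure_from_q(qmatrix_toy2())
  sp <- toy_space()
  flat <- random_cpts(st, seed = 3)
  for (g in c("attr", "item")) for (i in 1:2) flat[[g]][[i]]$p1[] <- 0.5
  expect_equal(data_loglik(flat, matrix(c(1L, 0L), 1), sp), log(0.25))
  x1 <- matrix(rbinom(10, 1, 0.5), 5, 2)
  expect_lte(data_loglik(flat, rbind(x1, c(1L, 1L)), sp),
             data_loglik(flat, x1, sp))
})

test_that("with a hierarchy, inadmissible patterns get exactly zero posterior", {
  Q <- random_qmatrix(4, 3, seed = 9)
  h <- hierarchy_dag(rbind(c("A1", "A2"), c("A2", "A3")))
  st <- structure_from_q(Q, h)
  sp_full <- enumerate_patterns(3)
  sp <- bnirp:::space_for_structure(st)
  expect_equal(sp$labels, c("000", "100", "110", "111"))
  cp <- random_cpts(st, seed = 10)
  po <- posterior_over_patterns(cp, c(1, 0, 1, 1), sp)
  expect_equal(sum(po$prob), 1)
  expect_false(any(c("001", "010", "011", "101") %in% names(po$prob)))
})

test_that("forward sampling is seeded, matches CPT frequencies, and closes the loop", {
  Q <- qmatrix_toy2()
  st <- structure_from_q(Q)
  cp <- toy_cpts()  # deterministic 0/1 item CPTs
  s1 <- forward_sample(cp, st, 50, seed = 5)
  s2 <- forward_sample(cp, st, 50, seed = 5)
  expect_identical(s1$responses$responses, s2$responses$responses)
  # deterministic CPTs: every sampled row reproduces its pattern's IRP row
  irp <- build_irp_dataset(Q, toy_space(), "DINA")
  idx <- match(pattern_to_string(s1$profiles), rownames(irp$responses))
  expect_equal(unname(s1$responses$responses), unname(irp$responses[idx, ]))

  # empirical frequency vs CPT entry at n = 1e5, and counting recovery
  st2 <- structure_from_q(random_qmatrix(6, 3, seed = 11))
  cp2 <- random_cpts(st2, seed = 12)
  fs <- forward_sample(cp2, st2, 1e5, seed = 13)
  refit <- count_cpts(list(profiles = fs$profiles,
                           responses = fs$responses$responses), st2)
  for (g in c("attr", "item")) {
    for (i in seq_along(cp2[[g]])) {
      expect_lt(max(abs(refit[[g]][[i]]$p1 - cp2[[g]][[i]]$p1)), 0.02)
    }
  }
})

test_that("CPT sets serialize to JSON with both columns and prior counts", {
  tmp <- withr::local_tempfile(fileext = ".json")
  write_cpts(toy_cpts(0.01), tmp)
  x <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_named(x, c("attributes", "items"))
  p <- x$items$Item1$prob
  expect_equal(rowSums(p), rep(1, 4))
})
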