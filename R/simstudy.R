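#' Classification accuracy report
#'
#' Compares predicted attribute patterns with the truth. PCR (pattern
#' classification rate) is the proportion of examinees whose whole predicted
#' pattern equals the true one; AACR (average attribute classification rate)
#' is the per-attribute agreement proportion averaged over attributes. PCR <=
#' AACR always.
#'
#' @param true_patterns,predicted_patterns N x K binary matrices.
#' @return object of class `classification_report` with `pcr`, `aacr`,
#'   `per_attribute` (length K), `true`, `predicted`.
#' @export
score <- function(true_patterns, predicted_patterns) {
  true_patterns <- as.matrix(true_patterns)
  predicted_patterns <- as.matrix(predicted_patterns)
  if (!all(dim(true_patterns) == dim(predicted_patterns))) {
    stop("true and predicted pattern matrices have different dimensions")
  }
  agree <- true_patterns == predicted_patterns
  per_attribute <- colMeans(agree)
  rep <- structure(list(pcr = mean(rowSums(!agree) == 0L),
                        aacr = mean(per_attribute),
                        per_attribute = as.numeric(per_attribute),
                        true = true_patterns, predicted = predicted_patterns),
                   class = "classification_report")
  stopifnot(rep$pcr <= rep$aacr + 1e-12)
  rep
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("PCR = %.4f, AACR = %.4f (N = %d, K = %d)\n",
              x$pcr, x$aacr, nrow(x$true), ncol(x$true)))
  invisible(x)
}

# Fit + classify one simulated dataset with one named method.
# Returns the N x K predicted pattern matrix.
analyze_with_method <- function(method, data, Q, structure, space, opts,
                                seed = NULL) {
  switch(method,
    EM = {
      o <- opts; o$seed <- seed
      classify_responses(fit_plain(data, structure, "EM", o)$cpts, data, space)
    },
    GD = {
      o <- opts; o$seed <- seed
      classify_responses(fit_plain(data, structure, "GD", o)$cpts, data, space)
    },
    IRP = {
      irp <- build_irp_dataset(Q, space, "DINA")
      cpts <- count_cpts(irp, structure, smoothing = opts$smoothing)
      classify_responses(cpts, data, space)
    },
    IRP_EM = classify_responses(
      fit_with_irp_prior(data, Q, structure$hierarchy, method = "EM",
                         opts = opts)$cpts, data, space),
    IRP_GD = classify_responses(
      fit_with_irp_prior(data, Q, structure$hierarchy, method = "GD",
                         opts = opts)$cpts, data, space),
    GDINA = {
      fit <- fit_gdina_em(data, Q, space, opts)
      classify_gdina(fit, data, space)
    },
    stop("unknown method: ", method))
}

aggregate_replicates <- function(reps, methods, replications) {
  out <- lapply(methods, function(m) {
    vals <- do.call(rbind, lapply(reps, function(r) r[[m]]))
    data.frame(method = m,
               pcr_mean = mean(vals[, "pcr"]),
               pcr_sd = if (nrow(vals) > 1L) stats::sd(vals[, "pcr"]) else 0,
               aacr_mean = mean(vals[, "aacr"]),
               aacr_sd = if (nrow(vals) > 1L) stats::sd(vals[, "aacr"]) else 0,
               replications = nrow(vals))
  })
  summary <- do.call(rbind, out)
  rownames(summary) <- NULL
  if (replications == 1L) {
    message("single replication: dispersion reported as 0")
  }
  replicates <- lapply(stats::setNames(methods, methods), function(m)
    do.call(rbind, lapply(reps, function(r) r[[m]])))
  structure(list(summary = summary, replicates = replicates),
            class = "condition_result")
}

#' @export
print.condition_result <- function(x, ...) {
  print(x$summary, ...)
  invisible(x)
}

#' Run one simulation condition
#'
#' Per replication r (seeded with `base_seed + r`): draw true attribute
#' profiles (uniform over the admissible space, or thresholded MVN with
#' rho = 0.5), redraw monotone G-DINA item parameters under the guess/slip
#' setting, simulate responses, fit every requested method, classify by MAP
#' pattern, and score against the truth. Means and dispersions (sample SD
#' across replications) are aggregated per method. The condition aborts if
#' more than 10 percent of replications fail.
#'
#' @param config a [run_config()].
#' @param Q a [qmatrix()].
#' @param hierarchy optional [hierarchy_dag()].
#' @param opts a [fit_options()].
#' @param rho latent correlation of the mvnorm profile generator.
#' @return a `condition_result`: `summary` data.frame (method, pcr_mean,
#'   pcr_sd, aacr_mean, aacr_sd, replications) and per-replication
#'   `replicates`.
#' @export
run_condition <- function(config, Q, hierarchy = NULL, opts = fit_options(),
                          rho = 0.5) {
  stopifnot(inherits(config, "run_config"), inherits(Q, "qmatrix"))
  structure <- structure_from_q(Q, hierarchy)
  space <- space_for_structure(structure)
  K <- ncol(Q$entries)
  mvn <- if (config$distribution == "mvnorm") mvn_sampler_spec(K, rho)
  reps <- vector("list", config$replications)
  failures <- 0L
  for (r in seq_len(config$replications)) {
    seed <- config$base_seed + r
    res <- tryCatch({
      set.seed(seed)
      profiles <- if (config$distribution == "uniform") {
        sample_uniform(config$n, space)
      } else {
        sample_mvnorm(config$n, mvn)
      }
      params <- gen_item_params(Q, config$gs_setting)
      data <- simulate_gdina(profiles, params)
      out <- list()
      for (m in config$methods) {
        pred <- analyze_with_method(m, data, Q, structure, space, opts,
                                    seed = seed)
        rep <- score(profiles, pred)
        out[[m]] <- c(pcr = rep$pcr, aacr = rep$aacr)
      }
      out
    }, error = function(e) {
      warning("replication ", r, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) failures <- failures + 1L else reps[[r]] <- res
  }
  if (failures > 0.1 * config$replications) {
    stop("condition aborted: ", failures, " of ", config$replications,
         " replications failed")
  }
  aggregate_replicates(Filter(Negate(is.null), reps), config$methods,
                       config$replications)
}

#' Run a BN-generated simulation condition
#'
#' The empirical-pattern generator: a BN is fitted to `source_data` with the
#' IRP-EM pipeline, then used to forward-sample `replications` datasets of
#' `n` examinees with known profiles, each analyzed with the requested
#' methods and scored. (The source study analyzed such data with IRP-GD and
#' G-DINA only, to avoid overrating the IRP-EM method that built the
#' generator.)
#'
#' @param source_data a [response_data()] used to estimate the generating BN.
#' @param Q a [qmatrix()].
#' @param hierarchy optional [hierarchy_dag()].
#' @param n examinees per generated replication.
#' @param replications number of generated datasets.
#' @param methods methods to analyze with (default `c("IRP_GD", "GDINA")`).
#' @param seed integer; replication r uses `seed + r`.
#' @param opts a [fit_options()].
#' @return a `condition_result`.
#' @export
run_bn_generated_condition <- function(source_data, Q, hierarchy = NULL, n,
                                       replications,
                                       methods = c("IRP_GD", "GDINA"),
                                       seed = 1L, opts = fit_options()) {
  structure <- structure_from_q(Q, hierarchy)
  space <- space_for_structure(structure)
  gen_fit <- fit_with_irp_prior(source_data, Q, hierarchy, method = "EM",
                                opts = opts)
  reps <- vector("list", replications)
  for (r in seq_len(replications)) {
    fs <- forward_sample(gen_fit$cpts, structure, n, seed = seed + r)
    out <- list()
    for (m in methods) {
      pred <- analyze_with_method(m, fs$responses, Q, structure, space, opts,
                                  seed = seed + r)
      rep <- score(fs$profiles, pred)
      out[[m]] <- c(pcr = rep$pcr, aacr = rep$aacr)
    }
    reps[[r]] <- out
  }
  res <- aggregate_replicates(reps, methods, replications)
  res$generator_fit <- gen_fit
  res
}
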