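#' Construct a Q-matrix
#'
#' A Q-matrix is the J x K binary item-by-attribute requirement matrix of a
#' cognitively diagnostic test: `entries[j, k] = 1` iff item j requires
#' attribute k. Every item must require at least one attribute.
#'
#' @param entries binary matrix, J items x K attributes.
#' @param item_ids,attribute_ids optional label vectors; taken from dimnames
#'   when absent, else generated (`I1..IJ`, `A1..AK`).
#' @return an object of class `qmatrix`: a list with `entries`, `item_ids`,
#'   `attribute_ids`.
#' @export
qmatrix <- function(entries, item_ids = NULL, attribute_ids = NULL) {
  entries <- as.matrix(entries)
  if (nrow(entries) < 1L || ncol(entries) < 1L) {
    stop("Q-matrix must have at least one item and one attribute")
  }
  assert_binary_matrix(entries, "Q-matrix")
  storage.mode(entries) <- "integer"
  if (is.null(item_ids)) {
    item_ids <- rownames(entries)
    if (is.null(item_ids)) item_ids <- paste0("I", seq_len(nrow(entries)))
  }
  if (is.null(attribute_ids)) {
    attribute_ids <- colnames(entries)
    if (is.null(attribute_ids)) attribute_ids <- paste0("A", seq_len(ncol(entries)))
  }
  zero <- which(rowSums(entries) == 0L)
  if (length(zero) > 0L) {
    stop("item(s) with all-zero Q-matrix row: ",
         paste(item_ids[zero], collapse = ", "))
  }
  dimnames(entries) <- list(item_ids, attribute_ids)
  structure(list(entries = entries, item_ids = item_ids,
                 attribute_ids = attribute_ids),
            class = "qmatrix")
}

#' @export
print.qmatrix <- function(x, ...) {
  cat("Q-matrix:", nrow(x$entries), "items x", ncol(x$entries), "attributes\n")
  print(x$entries, ...)
  invisible(x)
}

#' Read / write a Q-matrix CSV
#'
#' The CSV dialect is fixed: comma-separated, UTF-8, header row of attribute
#' ids, first column item ids.
#'
#' @param path file path.
#' @return `read_qmatrix()` returns a validated [qmatrix()].
#' @export
read_qmatrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("Q-matrix CSV needs an item-id column and >= 1 attribute column")
  item_ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cell in Q-matrix CSV: ", path)
  q <- qmatrix(m, item_ids = item_ids, attribute_ids = colnames(df)[-1L])
  message(sprintf("read Q-matrix: J=%d items, K=%d attributes", nrow(q$entries), ncol(q$entries)))
  q
}

#' @rdname read_qmatrix
#' @param q a [qmatrix()].
#' @export
write_qmatrix <- function(q, path) {
  df <- data.frame(item = q$item_ids, q$entries, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct an attribute-hierarchy DAG
#'
#' Directed prerequisite edges parent -> child: a child attribute can be
#' mastered only if all its (transitive) parents are mastered. Must be
#' acyclic.
#'
#' @param edges two-column character matrix or data.frame (parent, child);
#'   may have zero rows.
#' @param attributes optional full attribute label set (superset of the edge
#'   labels); defaults to the labels appearing in `edges`.
#' @return object of class `hierarchy_dag` with `edges` (character matrix)
#'   and `attributes`.
#' @export
hierarchy_dag <- function(edges, attributes = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(character(0), 0L, 2L)
  }
  if (ncol(edges) != 2L) stop("edges must have two columns (parent, child)")
  storage.mode(edges) <- "character"
  colnames(edges) <- c("parent", "child")
  labs <- unique(c(edges))
  if (is.null(attributes)) attributes <- labs
  if (!all(labs %in% attributes)) {
    stop("hierarchy node(s) not among attributes: ",
         paste(setdiff(labs, attributes), collapse = ", "))
  }
  h <- structure(list(edges = edges, attributes = attributes),
                 class = "hierarchy_dag")
  topological_order(h)  # errors on a cycle
  h
}

# Kahn topological sort of the attributes; error if cyclic.
topological_order <- function(hierarchy) {
  atts <- hierarchy$attributes
  e <- hierarchy$edges
  indeg <- stats::setNames(integer(length(atts)), atts)
  if (nrow(e) > 0L) {
    tab <- table(e[, "child"])
    indeg[names(tab)] <- as.integer(tab)
  }
  order <- character(0)
  queue <- atts[indeg == 0L]
  indeg_left <- indeg
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    if (nrow(e) > 0L) {
      for (ch in e[e[, "parent"] == v, "child"]) {
        indeg_left[ch] <- indeg_left[ch] - 1L
        if (indeg_left[ch] == 0L) queue <- c(queue, ch)
      }
    }
  }
  if (length(order) != length(atts)) stop("hierarchy contains a cycle")
  order
}

# K x K logical: anc[a, k] TRUE iff attribute a is a (transitive) hierarchy
# ancestor of attribute k. Attribute order = `attributes`.
ancestor_matrix <- function(hierarchy, attributes) {
  K <- length(attributes)
  anc <- matrix(FALSE, K, K, dimnames = list(attributes, attributes))
  e <- hierarchy$edges
  if (nrow(e) > 0L) {
    for (i in seq_len(nrow(e))) anc[e[i, 1L], e[i, 2L]] <- TRUE
    for (m in seq_len(K)) {          # Floyd-Warshall style closure
      anc <- anc | (anc %*% anc > 0)
    }
  }
  anc
}

#' Read / write a hierarchy DAG as a JSON edge list
#'
#' JSON format: `{"attributes": [...], "edges": [["parent","child"], ...]}`.
#'
#' @param path file path.
#' @return `read_hierarchy()` returns a [hierarchy_dag()].
#' @export
read_hierarchy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- x$edges
  if (is.list(edges)) edges <- do.call(rbind, edges)
  hierarchy_dag(edges, attributes = x$attributes)
}

#' @rdname read_hierarchy
#' @param hierarchy a [hierarchy_dag()].
#' @export
write_hierarchy <- function(hierarchy, path) {
  jsonlite::write_json(
    list(attributes = hierarchy$attributes,
         edges = apply(hierarchy$edges, 1L, identity, simplify = FALSE)),
    path, auto_unbox = FALSE)
  invisible(path)
}

#' Construct a response-data object
#'
#' Dichotomous responses of N examinees to J items (1 = correct). Missing
#' responses are not supported.
#'
#' @param responses binary matrix, N x J.
#' @param examinee_ids,item_ids optional labels.
#' @return object of class `response_data`.
#' @export
response_data <- function(responses, examinee_ids = NULL, item_ids = NULL) {
  responses <- as.matrix(responses)
  if (nrow(responses) < 1L) stop("response matrix has no examinees")
  assert_binary_matrix(responses, "response matrix")
  storage.mode(responses) <- "integer"
  if (is.null(item_ids)) {
    item_ids <- colnames(responses)
    if (is.null(item_ids)) item_ids <- paste0("I", seq_len(ncol(responses)))
  }
  if (is.null(examinee_ids)) examinee_ids <- paste0("E", seq_len(nrow(responses)))
  dimnames(responses) <- list(examinee_ids, item_ids)
  structure(list(responses = responses, examinee_ids = examinee_ids,
                 item_ids = item_ids),
            class = "response_data")
}

#' Read / write response data CSV
#'
#' CSV with a header of item ids; one row per examinee; entries in {0, 1}.
#'
#' @param path file path.
#' @return `read_responses()` returns a validated [response_data()].
#' @export
read_responses <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("response CSV has no data rows: ", path)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric cell in response CSV: ", path)
  response_data(m, item_ids = colnames(df))
}

#' @rdname read_responses
#' @param data a [response_data()].
#' @export
write_responses <- function(data, path) {
  utils::write.csv(as.data.frame(data$responses), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulation run configuration
#'
#' @param condition condition name.
#' @param distribution attribute-profile generator, `"uniform"` or `"mvnorm"`.
#' @param gs_setting guess/slip level, `"flat"` (g = s = 0.2 on all items) or
#'   `"mixed"` (three 10-item blocks at 0.3 / 0.2 / 0.1).
#' @param n examinees per replication.
#' @param replications number of replications (>= 1).
#' @param base_seed integer; replication r uses seed `base_seed + r`.
#' @param methods subset of `c("EM","GD","IRP","IRP_EM","IRP_GD","GDINA")`.
#' @return object of class `run_config`.
#' @export
run_config <- function(condition = "condition", distribution = "uniform",
                       gs_setting = "flat", n = 1000L, replications = 30L,
                       base_seed = 1L,
                       methods = c("IRP_EM", "IRP_GD", "GDINA")) {
  distribution <- match.arg(distribution, c("uniform", "mvnorm"))
  gs_setting <- match.arg(gs_setting, c("flat", "mixed"))
  if (replications < 1L) stop("replications must be >= 1")
  if (n < 1L) stop("n must be >= 1")
  allowed <- c("EM", "GD", "IRP", "IRP_EM", "IRP_GD", "GDINA")
  if (!all(methods %in% allowed)) {
    stop("unknown method(s): ", paste(setdiff(methods, allowed), collapse = ", "))
  }
  structure(list(condition = condition, distribution = distribution,
                 gs_setting = gs_setting, n = as.integer(n),
                 replications = as.integer(replications),
                 base_seed = as.integer(base_seed), methods = methods),
            class = "run_config")
}

#' Read a run configuration from YAML (or JSON)
#'
#' @param path `.yaml`/`.yml` or `.json` file with the fields of
#'   [run_config()].
#' @return a validated [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(run_config, x[intersect(names(x), names(formals(run_config)))])
}

#' Write a classification report to disk
#'
#' Writes a per-examinee CSV (true pattern, predicted MAP pattern, exact
#' match flag) to `path` and a JSON summary (PCR, AACR, per-attribute rates)
#' alongside it (same stem, `_summary.json` suffix).
#'
#' @param report a `classification_report` from [score()].
#' @param path CSV output path.
#' @return invisibly, the JSON summary path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "classification_report"))
  df <- data.frame(
    examinee = seq_len(nrow(report$true)),
    true = pattern_to_string(report$true),
    predicted = pattern_to_string(report$predicted),
    exact = as.integer(rowSums(report$true != report$predicted) == 0L))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jpath <- paste0(sub("\\.[^.]*$", "", path), "_summary.json")
  jsonlite::write_json(
    list(pcr = report$pcr, aacr = report$aacr,
         per_attribute = report$per_attribute,
         n = nrow(report$true), k = ncol(report$true)),
    jpath, auto_unbox = TRUE, digits = NA)
  invisible(jpath)
}

#' @rdname write_report
#' @return `read_report_summary()` returns the parsed JSON summary list.
#' @export
read_report_summary <- function(path) {
  jpath <- paste0(sub("\\.[^.]*$", "", path), "_summary.json")
  jsonlite::read_json(jpath, simplifyVector = TRUE)
}
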