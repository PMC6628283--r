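#' Number of distinct values in a vector
#'
#' The "pivot table" count: how many fuzzy sets a variable could have at most
#' if every observed value kept its own set.
#'
#' @param values Non-empty vector.
#' @return Number of distinct values.
#' @export
unique_value_count <- function(values) {
  if (length(values) == 0) rlang::abort("`values` must be non-empty")
  length(unique(values))
}

#' Recommended number of clusters for a variable
#'
#' Implements the pivot-table sizing rule: use the distinct-value count `u`
#' directly when `u <= 20`; above 20 take the square root of `u`, rounded
#' half away from zero, to keep the fuzzy-set (and hence rule) count
#' manageable. The result is never below the minimum of two clusters.
#'
#' @param values Non-empty vector of raw values for one variable.
#' @return A cluster count `>= 2` and `<= 20` (the square root is capped at
#'   the 20-set ceiling the rule exists to enforce).
#' @examples
#' optimal_cluster_count(rep(1:10, 3))   # 10 distinct codes -> 10
#' optimal_cluster_count(seq_len(110))   # 110 -> round(sqrt(110)) = 10
#' @export
optimal_cluster_count <- function(values) {
  u <- unique_value_count(values)
  k <- if (u <= 20) u else round_half_up(sqrt(u))
  min(20L, max(2L, as.integer(k)))
}

# round half away from zero (R's round() is banker's rounding)
round_half_up <- function(x) trunc(x + sign(x) * 0.5)

#' Cluster one variable's values
#'
#' Partitions a single numeric variable into `k` groups, either by
#' agglomerative hierarchical clustering with Ward linkage on the 1-D
#' Euclidean distances (the default for datasets up to ~10,000 rows) or by
#' k-means (recommended for larger data). Cluster labels are canonicalised so
#' that cluster minima increase with the label; identical values always share
#' a cluster. When the variable has fewer than `k` distinct values, `k` is
#' reduced to that count with a warning.
#'
#' @param values Non-empty numeric vector.
#' @param k Requested number of clusters (`>= 2`).
#' @param method `"ward"` or `"kmeans"`.
#' @param seed Integer seed controlling the k-means restarts.
#' @return An object of class `fz_clusters`: the canonical labels (one per
#'   value) and a `summaries` tibble with per-cluster `min`, `max`, `n`.
#' @export
cluster_variable <- function(values, k, method = c("ward", "kmeans"),
                             seed = 1L, variable = "x") {
  method <- match.arg(method)
  if (length(values) == 0) rlang::abort("`values` must be non-empty")
  if (!is.numeric(values)) rlang::abort("`values` must be numeric")
  if (k < 2) rlang::abort("`k` must be at least 2")
  k <- as.integer(k)
  u <- unique_value_count(values)
  if (u < k) {
    rlang::warn(sprintf(
      "variable '%s' has only %d distinct value(s); reducing k from %d",
      variable, u, k))
    k <- max(u, 1L)
  }
  if (k == 1L) {
    labels <- rep(1L, length(values))
  } else if (method == "ward") {
    hc <- stats::hclust(stats::dist(values), method = "ward.D2")
    labels <- stats::cutree(hc, k = k)
  } else {
    labels <- withr::with_seed(seed, {
      stats::kmeans(values, centers = k, nstart = 10)$cluster
    })
  }
  canonicalise_clusters(values, labels, method, variable)
}

# relabel clusters so minima are ascending; build per-cluster summaries
canonicalise_clusters <- function(values, labels, method, variable) {
  mins <- tapply(values, labels, min)
  ord <- order(mins)
  relabel <- integer(length(ord))
  relabel[as.integer(names(mins))[ord]] <- seq_along(ord)
  labels <- relabel[labels]
  summaries <- tibble::tibble(
    cluster = seq_along(ord),
    min = as.numeric(tapply(values, labels, min)),
    max = as.numeric(tapply(values, labels, max)),
    n = as.integer(tapply(values, labels, length))
  )
  structure(
    list(variable = variable, method = method, k = nrow(summaries),
         labels = as.integer(labels), summaries = summaries),
    class = "fz_clusters"
  )
}

# nominal variables: each observed code is its own singleton cluster
cluster_nominal <- function(values, variable = "x") {
  codes <- sort(unique(values))
  labels <- match(values, codes)
  canonicalise_clusters(values, labels, "nominal", variable)
}

#' @export
print.fz_clusters <- function(x, ...) {
  cat(sprintf("<fz_clusters> '%s' via %s: %d cluster(s) over %d value(s)\n",
              x$variable, x$method, x$k, length(x$labels)))
  print(x$summaries)
  invisible(x)
}

#' Membership functions from a fitted clustering
#'
#' Turns per-cluster minima and maxima into a fuzzy variable. For cluster
#' `i` with raw-data extremes `(m_i, M_i)`, the plateau breakpoints are
#' `b = m_i` and `c = M_i`; the set is triangular (peak `b`) when
#' `m_i == M_i` and trapezoidal otherwise. The feet, which the clustering
#' alone does not determine, are placed at the neighbouring cluster's nearest
#' extreme (`a_i = M_{i-1}`, `d_i = m_{i+1}`; the outermost feet coincide
#' with the plateau), so that the family forms a Ruspini partition: degrees
#' sum to exactly 1 across the variable's range.
#'
#' @param cm An [cluster_variable()] result.
#' @return An [fz_variable()] with one membership function per cluster.
#' @export
mfs_from_cluster_model <- function(cm) {
  stopifnot(inherits(cm, "fz_clusters"))
  s <- cm$summaries
  K <- nrow(s)
  if (K == 0) rlang::abort("empty cluster model")
  mfs <- lapply(seq_len(K), function(i) {
    b <- s$min[i]; c_ <- s$max[i]
    a <- if (i == 1) b else s$max[i - 1]
    d <- if (i == K) c_ else s$min[i + 1]
    label <- paste0("MF", i)
    if (b == c_) fz_trimf(a, b, d, label = label)
    else fz_trapmf(a, b, c_, d, label = label)
  })
  lo <- s$min[1]; hi <- s$max[K]
  if (!(lo < hi)) {
    rlang::abort(sprintf("variable '%s' is constant over the training rows",
                         cm$variable))
  }
  fz_variable(cm$variable, lo, hi, mfs)
}

#' Extract the unique-row rule base
#'
#' Reduces a table of cluster indices (one row per training observation, one
#' column per clustered variable) to its sorted unique rows; each surviving
#' row becomes one IF-THEN rule with weight 1 and the AND connector.
#' Contradictory rows — identical antecedents with different consequents —
#' are both kept by default (they are distinct rows) with a warning;
#' `resolve_contradictions = TRUE` keeps only the majority consequent,
#' breaking ties toward the lower consequent index.
#'
#' @param clustered Data frame of positive integer cluster indices.
#' @param n_outputs Number of trailing columns holding output clusters.
#' @param resolve_contradictions Collapse contradictory antecedents?
#' @return A list of [fz_rule()] objects.
#' @export
extract_rule_base <- function(clustered, n_outputs = 1L,
                              resolve_contradictions = FALSE) {
  clustered <- as.data.frame(clustered)
  if (nrow(clustered) == 0) rlang::abort("`clustered` must be non-empty")
  n_outputs <- as.integer(n_outputs)
  n_inputs <- ncol(clustered) - n_outputs
  if (n_inputs < 1) rlang::abort("need at least one input column")

  uniq <- dplyr::distinct(clustered)
  uniq <- dplyr::arrange(uniq, dplyr::across(dplyr::everything()))

  ant_cols <- seq_len(n_inputs)
  key <- do.call(paste, c(uniq[ant_cols], sep = "\r"))
  dup_ant <- key %in% key[duplicated(key)]
  if (any(dup_ant)) {
    rlang::warn(sprintf(
      "%d antecedent pattern(s) map to more than one consequent (contradictory rules)",
      length(unique(key[dup_ant]))))
    if (resolve_contradictions) {
      counts <- dplyr::count(clustered, dplyr::across(dplyr::everything()))
      counts$..key <- do.call(paste, c(counts[ant_cols], sep = "\r"))
      counts <- dplyr::arrange(
        counts, .data$..key, dplyr::desc(.data$n),
        dplyr::across(dplyr::all_of(names(clustered)[-ant_cols]))
      )
      keep <- counts[!duplicated(counts$..key), names(clustered), drop = FALSE]
      uniq <- dplyr::arrange(keep, dplyr::across(dplyr::everything()))
    }
  }
  lapply(seq_len(nrow(uniq)), function(i) {
    fz_rule(
      antecedent = as.integer(unlist(uniq[i, ant_cols])),
      consequent = as.integer(unlist(uniq[i, n_inputs + seq_len(n_outputs)]))
    )
  })
}

#' All feature subsets of a given size
#'
#' Enumerates the `choose(n, k)` unordered k-subsets of the feature indices
#' `1..n`, each sorted ascending, in lexicographic order — e.g. 36 pairs and
#' 84 triples from nine candidate features.
#'
#' @param n Number of available features.
#' @param k Subset size, `1 <= k <= n`.
#' @return A list of integer vectors.
#' @export
enumerate_feature_subsets <- function(n, k) {
  n <- as.integer(n); k <- as.integer(k)
  if (k < 1 || k > n) rlang::abort("`k` must satisfy 1 <= k <= n")
  m <- utils::combn(n, k)
  lapply(seq_len(ncol(m)), function(j) m[, j])
}

#' Build a fuzzy knowledge base from training data
#'
#' The induction step: clusters every selected input column and the outcome
#' column on the training rows, converts each clustering into membership
#' functions ([mfs_from_cluster_model()]), maps each training row to its
#' vector of cluster indices, extracts the unique-row rule base and assembles
#' the Mamdani system (min/max operators, centroid defuzzification). Each
#' output membership function is tagged with a class code — the most frequent
#' raw outcome value inside its cluster — used by [predict.fz_kb()].
#'
#' @param data Data frame of training rows.
#' @param outcome Name of the class column.
#' @param features Character vector of input column names (default: all
#'   non-outcome columns).
#' @param k_inputs Integer cluster counts, one per feature (recycled if
#'   length 1). Default: [optimal_cluster_count()] per feature.
#' @param k_output Cluster count for the outcome (default its
#'   [optimal_cluster_count()], i.e. 2 for a binary class).
#' @param method `"ward"`, `"kmeans"` or `"auto"` (ward up to 10,000 rows,
#'   k-means beyond).
#' @param nominal Character vector of feature names to treat as nominal codes
#'   (one singleton cluster per code, no distance-based clustering).
#' @param seed Integer seed (k-means restarts).
#' @param resolution Defuzzification grid size.
#' @param resolve_contradictions Passed to [extract_rule_base()].
#' @param name System name.
#' @return An object of class `fz_kb`: the assembled `$system`, the
#'   `$cluster_models`, the `$rules`, `$class_codes` and `$features`.
#' @export
build_knowledge_base <- function(data, outcome, features = NULL,
                                 k_inputs = NULL, k_output = NULL,
                                 method = c("auto", "ward", "kmeans"),
                                 nominal = NULL, seed = 1L,
                                 resolution = 1001L,
                                 resolve_contradictions = FALSE,
                                 name = "fuzzydx") {
  method <- match.arg(method)
  data <- as.data.frame(data)
  if (nrow(data) == 0) rlang::abort("empty training set")
  if (!outcome %in% names(data)) {
    rlang::abort(sprintf("outcome column '%s' not found", outcome))
  }
  if (is.null(features)) features <- setdiff(names(data), outcome)
  if (!all(features %in% names(data))) rlang::abort("unknown feature column(s)")
  if (method == "auto") method <- if (nrow(data) <= 10000) "ward" else "kmeans"

  if (is.null(k_inputs)) {
    k_inputs <- vapply(data[features], optimal_cluster_count, integer(1))
  }
  k_inputs <- rep_len(as.integer(k_inputs), length(features))
  if (is.null(k_output)) k_output <- optimal_cluster_count(data[[outcome]])

  cms <- purrr::map2(features, k_inputs, function(f, k) {
    if (f %in% nominal) cluster_nominal(data[[f]], variable = f)
    else cluster_variable(data[[f]], k, method = method, seed = seed, variable = f)
  })
  cm_out <- cluster_variable(data[[outcome]], k_output, method = method,
                             seed = seed, variable = outcome)

  input_vars <- lapply(cms, mfs_from_cluster_model)
  output_var <- mfs_from_cluster_model(cm_out)

  clustered <- stats::setNames(
    as.data.frame(c(lapply(cms, `[[`, "labels"), list(cm_out$labels))),
    c(features, outcome)
  )
  rules <- extract_rule_base(clustered, n_outputs = 1L,
                             resolve_contradictions = resolve_contradictions)

  # class code per output MF: modal raw outcome value inside the cluster
  class_codes <- vapply(seq_len(cm_out$k), function(i) {
    vals <- data[[outcome]][cm_out$labels == i]
    tab <- sort(table(vals), decreasing = TRUE)
    as.numeric(names(tab)[1])
  }, numeric(1))

  system <- fz_system(input_vars, list(output_var), rules, name = name,
                      resolution = resolution)
  structure(
    list(system = system, cluster_models = c(cms, list(cm_out)),
         rules = rules, class_codes = class_codes,
         features = features, outcome = outcome,
         method = method, k_inputs = k_inputs, k_output = cm_out$k,
         n_train = nrow(data)),
    class = "fz_kb"
  )
}

#' @export
print.fz_kb <- function(x, ...) {
  cat(sprintf(
    "<fz_kb> %d feature(s) [%s], %d rule(s), method=%s, trained on %d row(s)\n",
    length(x$features), paste(x$features, collapse = ", "),
    length(x$rules), x$method, x$n_train))
  invisible(x)
}

#' @method glance fz_kb
#' @export
glance.fz_kb <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$features),
    features = paste(x$features, collapse = ","),
    k_inputs = paste(x$k_inputs, collapse = ","),
    k_output = x$k_output,
    n_rules = length(x$rules),
    method = x$method,
    n_train = x$n_train
  )
}

#' @method tidy fz_kb
#' @export
tidy.fz_kb <- function(x, ...) tidy(x$system)
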