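#' Generate a classification dataset with known cluster structure
#'
#' Emulates the statistical shape of small clinical tables: informative
#' features draw from class-specific value bands (truncated-normal bands for
#' continuous features, contiguous code blocks for integer-coded features),
#' noise features draw identically for every class, class labels are balanced
#' (or follow `class_weights`), and a fraction of informative cells can be
#' knocked out as missing. Band edges of different classes are separated by
#' `separation` within-band spreads, so any positive separation makes the
#' class bands disjoint; `separation = 0` instead draws informative features
#' from the same pooled distribution as noise, making them uninformative.
#'
#' @param n_rows Number of rows.
#' @param n_informative,n_noise Feature counts (`n_informative >= 1`).
#' @param n_classes Number of classes (codes `1..n_classes`).
#' @param clusters_per_feature Sub-bands per class on each informative
#'   feature.
#' @param separation Gap between class bands in units of within-band spread
#'   (continuous: one standard deviation; integer codes: one code).
#' @param feature_kind `"continuous"`, `"integer_code"` or `"nominal"`
#'   (nominal behaves like integer codes drawn per class block).
#' @param code_range Inclusive code range for integer features.
#' @param missing_rate Fraction of informative cells set to `NA`.
#' @param class_weights Optional class prevalence weights (default equal).
#' @param seed Integer seed; everything is deterministic given it.
#' @return A list with `data` (a tibble `feature_1..feature_p`, `class`) and
#'   `truth`: informative indices, the per-class band table and each row's
#'   band assignment.
#' @export
generate_fuzzy_data <- function(n_rows = 300L, n_informative = 2L,
                                n_noise = 3L, n_classes = 2L,
                                clusters_per_feature = 1L, separation = 3,
                                feature_kind = c("continuous", "integer_code",
                                                 "nominal"),
                                code_range = c(1, 10), missing_rate = 0,
                                class_weights = NULL, seed = 1L) {
  feature_kind <- match.arg(feature_kind)
  stopifnot(n_informative >= 1, n_noise >= 0, n_classes >= 2,
            clusters_per_feature >= 1, separation >= 0,
            missing_rate >= 0, missing_rate < 1)
  n_rows <- as.integer(n_rows)
  n_bands <- n_classes * clusters_per_feature
  integerish <- feature_kind %in% c("integer_code", "nominal")

  if (integerish) {
    # contiguous code blocks per (class, sub-band), separated by `separation`
    # codes between classes; sub-bands of one class sit side by side
    span <- code_range[2] - code_range[1] + 1
    gap <- round_half_up(separation)
    width <- (span - gap * (n_classes - 1)) %/% n_bands
    if (width < 1) {
      rlang::abort("class bands exceed `code_range`: infeasible separation")
    }
    lo <- code_range[1] +
      (seq_len(n_bands) - 1) * width +
      rep(seq_len(n_classes) - 1, each = clusters_per_feature) * gap
    bands <- tibble::tibble(
      class = rep(seq_len(n_classes), each = clusters_per_feature),
      band = seq_len(n_bands), lo = lo, hi = lo + width - 1
    )
  } else {
    # truncated-normal bands (mean +- 2 sd), adjacent class band edges
    # `separation` sd apart
    centres <- (seq_len(n_bands) - 1) * (4 + separation)
    bands <- tibble::tibble(
      class = rep(seq_len(n_classes), each = clusters_per_feature),
      band = seq_len(n_bands), lo = centres - 2, hi = centres + 2,
      centre = centres, sd = 1
    )
  }

  if (is.null(class_weights)) class_weights <- rep(1, n_classes)
  counts <- round_half_up(n_rows * class_weights / sum(class_weights))
  counts[1] <- counts[1] + n_rows - sum(counts)

  withr::with_seed(seed, {
    classes <- sample(rep(seq_len(n_classes), times = counts))
    # sample() treats a length-1 x as 1:x; always pass an explicit set
    sample_codes <- function(codes, n) codes[sample.int(length(codes), n,
                                                        replace = TRUE)]
    draw_band <- function(b, n) {
      if (integerish) {
        sample_codes(seq(bands$lo[b], bands$hi[b]), n)
      } else {
        # truncated normal on centre +- 2 sd via inverse-cdf
        p <- stats::runif(n, stats::pnorm(-2), stats::pnorm(2))
        bands$centre[b] + bands$sd[b] * stats::qnorm(p)
      }
    }
    pooled_draw <- function(n) {
      if (integerish) {
        sample_codes(seq(code_range[1], code_range[2]), n)
      } else {
        stats::runif(n, min(bands$lo) - 1, max(bands$hi) + 1)
      }
    }
    row_bands <- matrix(NA_integer_, n_rows, n_informative)
    X <- matrix(NA_real_, n_rows, n_informative + n_noise)
    for (j in seq_len(n_informative)) {
      if (separation == 0) {
        X[, j] <- pooled_draw(n_rows)
        row_bands[, j] <- 1L
      } else {
        for (cl in seq_len(n_classes)) {
          idx <- which(classes == cl)
          cl_bands <- bands$band[bands$class == cl]
          chosen <- cl_bands[sample.int(length(cl_bands), length(idx),
                                        replace = TRUE)]
          row_bands[idx, j] <- chosen
          for (b in unique(chosen)) {
            sel <- idx[chosen == b]
            X[sel, j] <- draw_band(b, length(sel))
          }
        }
      }
    }
    for (j in seq_len(n_noise)) {
      X[, n_informative + j] <- pooled_draw(n_rows)
    }
    if (missing_rate > 0) {
      cells <- which(stats::runif(n_rows * n_informative) < missing_rate)
      X[cbind((cells - 1) %% n_rows + 1, (cells - 1) %/% n_rows + 1)] <- NA
    }
  })

  data <- tibble::as_tibble(as.data.frame(X))
  names(data) <- paste0("feature_", seq_len(ncol(X)))
  data$class <- classes
  truth <- list(
    informative = seq_len(n_informative),
    bands = bands,
    row_bands = tibble::as_tibble(as.data.frame(row_bands),
                                  .name_repair = ~paste0("feature_", seq_len(n_informative))),
    classes = classes,
    feature_kind = feature_kind
  )
  list(data = data, truth = truth)
}

#' Generate a dataset shaped like the Wisconsin breast-cancer table
#'
#' Nine integer-coded cytology-like features on a 1-10 scale, a binary class
#' coded 1 (benign) / 2 (malignant) with roughly 65/35 prevalence, five
#' informative features, and an optional missing-cell rate concentrated on
#' the sixth feature (mirroring a marker with laboratory dropouts).
#'
#' @param n_rows Number of rows (`>= 10`).
#' @param seed Integer seed.
#' @param missing_rate Fraction of cells of the sixth feature set missing.
#' @return As [generate_fuzzy_data()]: `list(data, truth)`.
#' @export
generate_wbcd_like <- function(n_rows = 699L, seed = 1L, missing_rate = 0.02) {
  stopifnot(n_rows >= 10)
  gen <- generate_fuzzy_data(
    n_rows = n_rows, n_informative = 5L, n_noise = 4L, n_classes = 2L,
    clusters_per_feature = 1L, separation = 1,
    feature_kind = "integer_code", code_range = c(1, 10),
    missing_rate = 0, class_weights = c(0.655, 0.345), seed = seed
  )
  if (missing_rate > 0) {
    miss <- withr::with_seed(seed + 1L,
                             stats::runif(n_rows) < missing_rate)
    gen$data$feature_6[miss] <- NA
  }
  gen
}

#' Expected rule count under a perfect clustering
#'
#' Counts the distinct (band combination, class) patterns realised by the
#' generated rows: the number of rules a rule base would hold if every
#' informative feature were clustered exactly onto its generating bands.
#' When `ks` requests fewer clusters than a feature has bands, adjacent
#' bands are merged proportionally before counting.
#'
#' @param truth The `truth` element of [generate_fuzzy_data()].
#' @param ks Optional integer vector of cluster counts, one per informative
#'   feature (default: one cluster per band).
#' @return The implied rule count.
#' @export
implied_rules <- function(truth, ks = NULL) {
  rb <- truth$row_bands
  n_bands <- max(truth$bands$band)
  if (!is.null(ks)) {
    ks <- rep_len(as.integer(ks), ncol(rb))
    for (j in seq_len(ncol(rb))) {
      k <- min(ks[j], n_bands)
      rb[[j]] <- ceiling(rb[[j]] * k / n_bands)
    }
  }
  rb$class <- truth$classes
  nrow(dplyr::distinct(rb))
}
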