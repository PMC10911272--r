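#' Remove a blocking factor from a score table
#'
#' Per site, subtracts the factor-level mean (e.g. the donor mean) and adds
#' back the site's grand mean, both computed over valid scores. This is the
#' embedding-side counterpart of blocking in the ANOVA: after elimination,
#' samples no longer separate by the factor, exposing growth-state structure.
#' The operation is idempotent and preserves the validity mask.
#'
#' @param scores An `rms_scores` tibble at the biological-sample level.
#' @param design Design tibble with the factor column.
#' @param factor_name Column of `design` to eliminate (default `"donor"`).
#' @return An `rms_scores` tibble of the same shape with adjusted scores.
#' @export
eliminate_factor <- function(scores, design, factor_name = "donor") {
  design <- validate_design(design)
  bio <- bio_design(design)
  if (!factor_name %in% names(bio)) {
    abort(paste0("Unknown factor: ", factor_name))
  }
  samples <- unique(scores$sample_id)
  lvl <- bio[[factor_name]][match(samples, bio$bio_id)]
  if (anyNA(lvl)) {
    abort(paste0("Sample(s) missing a ", factor_name, " label: ",
                 paste(samples[is.na(lvl)], collapse = ", ")),
          class = "ribomethr_lookup_error")
  }
  lut <- stats::setNames(lvl, samples)
  out <- scores |>
    mutate(.lvl = lut[.data$sample_id]) |>
    group_by(.data$label) |>
    mutate(.grand = mean(.data$score[.data$valid])) |>
    group_by(.data$label, .data$.lvl) |>
    mutate(.lvl_mean = mean(.data$score[.data$valid])) |>
    ungroup() |>
    mutate(score = ifelse(.data$valid,
                          .data$score - .data$.lvl_mean + .data$.grand,
                          .data$score)) |>
    select(-".lvl", -".grand", -".lvl_mean")
  class(out) <- c("rms_scores", class(out))
  out
}

#' Embed samples in two dimensions
#'
#' Places biological samples in a 2-D map from their site-score profiles,
#' either by exact t-SNE (Barnes-Hut turned off; suitable for the small
#' sample numbers of donor studies) or by principal components. Masked
#' scores are imputed with the site mean before embedding. The perplexity
#' is clamped to `(n - 2) / 3` so the affinity calibration is well posed at
#' small n.
#'
#' @param scores An `rms_scores` tibble (use [eliminate_factor()] first to
#'   remove a batch factor).
#' @param seed Integer seed; fixed seed gives deterministic coordinates.
#' @param method `"tsne"` (default) or `"pca"`.
#' @param perplexity Requested t-SNE perplexity (default 3, clamped).
#' @param eliminated_factor Annotation recorded in the result (`"none"` or
#'   the factor name); purely descriptive.
#' @return A tibble of class `rms_embedding` with columns `sample_id`,
#'   `dim1`, `dim2`, and attributes `method`, `seed`, `eliminated_factor`.
#' @export
embed_samples <- function(scores, seed = 1L, method = c("tsne", "pca"),
                          perplexity = 3, eliminated_factor = "none") {
  method <- match.arg(method)
  m <- scores_to_matrix(scores)          # sites x samples
  n <- ncol(m)
  if (n < 3) {
    abort("Embedding needs >= 3 samples.", class = "ribomethr_parameter_error")
  }
  # site-mean imputation of masked cells
  site_means <- rowMeans(m, na.rm = TRUE)
  idx <- which(is.na(m), arr.ind = TRUE)
  if (nrow(idx) > 0) m[idx] <- site_means[idx[, 1]]
  if (anyNA(m)) {
    abort("Sites with no valid score in any sample cannot be imputed; drop them first.")
  }
  x <- t(m)                              # samples x sites
  coords <- if (method == "tsne") {
    if (n < 5) {
      abort("t-SNE needs >= 5 samples; use method = 'pca'.",
            class = "ribomethr_parameter_error")
    }
    perp <- min(perplexity, (n - 2) / 3)
    with_seed(seed, {
      Rtsne::Rtsne(x, dims = 2, perplexity = perp, theta = 0,
                   check_duplicates = FALSE, pca = FALSE, max_iter = 1000)$Y
    })
  } else {
    p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    k <- min(2, ncol(p$x))
    cbind(p$x[, seq_len(k)], matrix(0, nrow = n, ncol = 2 - k))
  }
  out <- tibble(sample_id = rownames(x),
                dim1 = coords[, 1], dim2 = coords[, 2])
  attr(out, "method") <- method
  attr(out, "seed") <- as.integer(seed)
  attr(out, "eliminated_factor") <- eliminated_factor
  class(out) <- c("rms_embedding", class(out))
  out
}

#' Silhouette-optimal number of clusters
#'
#' Partitions 2-D embedding coordinates with seeded k-means for each k in
#' `k_range` and returns the k maximising the mean silhouette width, ties
#' broken towards smaller k. Following the usual silhouette reading
#' (mean width above ~0.5 indicating a reasonable partition, below it weak
#' or artificial structure), a maximum mean silhouette below `weak_cutoff`
#' flags weak cluster structure.
#'
#' @param coords An `rms_embedding` tibble, or a 2-column matrix.
#' @param k_range Candidate cluster counts (within `[2, n - 1]`).
#' @param seed Integer seed for k-means starts.
#' @param weak_cutoff Mean-silhouette level below which structure is flagged
#'   weak (default 0.5).
#' @return Integer k, with attributes `silhouette` (named vector of mean
#'   widths) and `weak` (logical).
#' @export
silhouette_optimal_k <- function(coords, k_range = 2:6, seed = 1L,
                                 weak_cutoff = 0.5) {
  x <- if (inherits(coords, "rms_embedding")) {
    as.matrix(coords[, c("dim1", "dim2")])
  } else {
    as.matrix(coords)
  }
  n <- nrow(x)
  if (n < 3) abort("Need >= 3 points.", class = "ribomethr_parameter_error")
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (length(k_range) == 0) abort("k_range must intersect [2, n - 1].")
  d <- stats::dist(x)
  sil <- with_seed(seed, {
    purrr::map_dbl(k_range, function(k) {
      cl <- stats::kmeans(x, centers = k, nstart = 25)$cluster
      mean(cluster::silhouette(cl, d)[, "sil_width"])
    })
  })
  names(sil) <- k_range
  best <- k_range[which.max(sil)]   # which.max takes the first (smallest) tie
  structure(as.integer(best), silhouette = sil,
            weak = max(sil) < weak_cutoff)
}

#' Plot a 2-D sample embedding
#'
#' @param object An `rms_embedding`.
#' @param design Optional design tibble; when given, points are coloured by
#'   state and shaped by donor.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rms_embedding
#' @export
autoplot.rms_embedding <- function(object, design = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2))
  if (!is.null(design)) {
    bio <- bio_design(validate_design(design))
    df <- left_join(df, bio, by = c(sample_id = "bio_id"))
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                          colour = .data$state,
                                          shape = .data$donor))
  }
  p + ggplot2::geom_point(size = 3) +
    ggplot2::labs(
      title = paste0("Sample embedding (", attr(object, "method"), ")"),
      subtitle = if (identical(attr(object, "eliminated_factor"), "none")) {
        "raw scores"
      } else {
        paste0("after eliminating factor '", attr(object, "eliminated_factor"), "'")
      }) +
    ggplot2::theme_minimal()
}
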