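#' Merge technical replicates by summing end counts
#'
#' RiboMeth-seq libraries sequenced as technical replicates of one
#' biological sample are pooled position-wise before scoring, which is
#' equivalent to scoring the summed cleavage evidence.
#'
#' @param counts An `end_counts` tibble (columns `sample_id`, `subunit`,
#'   `position`, `count`).
#' @param design Design tibble mapping `sample_id` to `bio_id`.
#' @return An `end_counts` tibble with one profile per biological sample
#'   (`sample_id` set to the biological id).
#' @export
merge_technical_replicates <- function(counts, design) {
  design <- validate_design(design)
  unknown <- setdiff(unique(counts$sample_id), design$sample_id)
  if (length(unknown) > 0) {
    abort(paste0("Sample(s) absent from design: ",
                 paste(unknown, collapse = ", ")),
          class = "ribomethr_lookup_error")
  }
  # replicates must cover identical bond sets
  shapes <- counts |>
    left_join(select(design, "sample_id", "bio_id"), by = "sample_id") |>
    group_by(.data$bio_id, .data$sample_id) |>
    summarise(n = n(), .groups = "drop_last") |>
    summarise(k = n_distinct(.data$n), .groups = "drop")
  if (any(shapes$k > 1)) {
    abort(paste0("Technical replicates differ in profile length for: ",
                 paste(shapes$bio_id[shapes$k > 1], collapse = ", ")),
          class = "ribomethr_shape_error")
  }
  out <- counts |>
    left_join(select(design, "sample_id", "bio_id"), by = "sample_id") |>
    group_by(sample_id = .data$bio_id, .data$subunit, .data$position) |>
    summarise(count = sum(.data$count), .groups = "drop")
  class(out) <- c("end_counts", class(out))
  out
}

#' Compute per-site RMS methylation scores
#'
#' The methylated fraction of molecules at a catalogued site protects the
#' bond 3' of the site from alkaline cleavage, depleting fragment ends
#' there relative to its flanks. The score is the flank-normalised
#' protection
#' \deqn{score = clip(1 - n_{site} / \bar{n}_{flank},\ 0,\ 1)}
#' where \eqn{\bar{n}_{flank}} is the arithmetic mean of the counts at the
#' up to `2 * window` flanking bonds (`window` per side). Flanking bonds
#' that are themselves catalogued site bonds are excluded, so clustered
#' sites do not deflate each other's local cleavage baseline. A score is
#' masked (missing, `valid = FALSE`) when the flank mean falls below
#' `min_flank_mean` (coverage QC), when no eligible flank remains, or when
#' the site lies within `window` bonds of a reference end.
#'
#' @param counts An `end_counts` tibble, typically after
#'   [merge_technical_replicates()].
#' @param catalog A `site_catalog`.
#' @param window Flanking bonds per side (default 2).
#' @param min_flank_mean Minimum flank mean count for a valid score
#'   (default 10).
#' @return A tibble of class `rms_scores`: one row per (site, sample) with
#'   `label`, `sample_id`, `n_site`, `flank_mean`, `score` (in [0,1] or NA)
#'   and `valid`.
#' @examples
#' catalog <- load_site_catalog()
#' design <- study_design(donors = "d1", states = "P", tech_reps = 1)
#' truth <- build_truth(catalog, design, base_level = 0.9, seed = 1)
#' counts <- simulate_end_counts(truth, catalog, design, seed = 1)
#' scores <- compute_rms_scores(counts, catalog)
#' @export
compute_rms_scores <- function(counts, catalog, window = 2, min_flank_mean = 10) {
  if (window < 1) abort("`window` must be >= 1.")
  ref_len <- attr(catalog, "reference_lengths")
  site_key <- paste(catalog$subunit, catalog$position)

  out <- purrr::map_dfr(unique(counts$sample_id), function(id) {
    prof <- filter(counts, .data$sample_id == id)
    purrr::map_dfr(split(catalog, as.character(catalog$subunit)), function(cat_s) {
      if (nrow(cat_s) == 0) return(NULL)
      s <- as.character(cat_s$subunit[1])
      L <- ref_len[[s]]
      vec <- rep(NA_real_, L - 1L)
      sub_prof <- filter(prof, .data$subunit == s,
                         .data$position >= 1, .data$position <= L - 1L)
      vec[sub_prof$position] <- sub_prof$count
      is_site <- logical(L - 1L)
      is_site[cat_s$position[cat_s$position <= L - 1L]] <- TRUE
      purrr::map_dfr(seq_len(nrow(cat_s)), function(i) {
        p <- cat_s$position[i]
        flank_idx <- setdiff(seq(p - window, p + window), p)
        edge <- any(flank_idx < 1 | flank_idx > L - 1L) || p > L - 1L
        if (edge) {
          return(tibble(label = cat_s$label[i], sample_id = id,
                        n_site = NA_real_, flank_mean = NA_real_,
                        score = NA_real_, valid = FALSE))
        }
        flank_idx <- flank_idx[!is_site[flank_idx]]
        flanks <- vec[flank_idx]
        n_site <- vec[p]
        fm <- if (length(flanks) == 0 || anyNA(flanks)) NA_real_ else mean(flanks)
        ok <- !is.na(fm) && !is.na(n_site) && fm >= min_flank_mean
        tibble(label = cat_s$label[i], sample_id = id,
               n_site = as.numeric(n_site), flank_mean = fm,
               score = if (ok) clip01(1 - n_site / fm) else NA_real_,
               valid = ok)
      })
    })
  })
  out <- out |>
    mutate(label = factor(.data$label, levels = catalog$label)) |>
    arrange(.data$label, .data$sample_id) |>
    mutate(label = as.character(.data$label))
  class(out) <- c("rms_scores", class(out))
  out
}

#' Summarise score validity
#'
#' @param scores An `rms_scores` tibble.
#' @return A list with `per_sample` and `per_site` tibbles of valid-score
#'   counts and `fraction_valid` overall (NA for an empty table).
#' @export
score_validity_summary <- function(scores) {
  list(
    per_sample = scores |>
      group_by(.data$sample_id) |>
      summarise(n_valid = sum(.data$valid), n_total = n(), .groups = "drop"),
    per_site = scores |>
      group_by(.data$label) |>
      summarise(n_valid = sum(.data$valid), n_total = n(), .groups = "drop"),
    fraction_valid = if (nrow(scores) == 0) NA_real_ else mean(scores$valid)
  )
}

# sites x samples matrix of scores (NA where masked)
scores_to_matrix <- function(scores) {
  wide <- scores |>
    select("label", "sample_id", "score") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "score")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$label
  m
}

# long scores from a matrix (helper for matrix-level operations)
matrix_to_scores <- function(m) {
  out <- as_tibble(m, rownames = "label") |>
    tidyr::pivot_longer(-"label", names_to = "sample_id", values_to = "score") |>
    mutate(valid = !is.na(.data$score))
  class(out) <- c("rms_scores", class(out))
  out
}

#' Write / read an RMS score table
#'
#' TSV with rows = site labels, columns = sample ids, masked scores as empty
#' cells.
#'
#' @param scores An `rms_scores` tibble.
#' @param path File path.
#' @return `write_rms_scores()` returns `path` invisibly; `read_rms_scores()`
#'   an `rms_scores` tibble.
#' @export
write_rms_scores <- function(scores, path) {
  wide <- scores |>
    select("label", "sample_id", "score") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "score")
  readr::write_tsv(wide, path, na = "")
  invisible(path)
}

#' @rdname write_rms_scores
#' @export
read_rms_scores <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide[[1]]
  matrix_to_scores(m)
}
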