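#' Relative snoRNA expression from stem-loop qPCR Ct values
#'
#' Comparative-Ct quantification with amplification efficiency fixed at 2:
#' `dCt = Ct_target - Ct_reference` (reference 5.8S rRNA by convention), and
#' per target `relative = 2^-(dCt - mean dCt over P samples)`, so the
#' proliferating-state mean is 1 by construction.
#'
#' @param records Tibble with columns `sample_id`, `target`, `ct_target`,
#'   `ct_reference`.
#' @param design Design tibble giving each sample's `state` (and `donor`).
#' @param reference_state State used as the unit baseline (default `"P"`).
#' @return Tibble with columns `target`, `sample_id`, `donor`, `state`,
#'   `dct`, `relative_expression`.
#' @examples
#' design <- study_design(tech_reps = 1)
#' recs <- tibble::tibble(
#'   sample_id = design$bio_id[design$donor == "HDF76"],
#'   target = "SNORD87", ct_target = c(20, 19, 21), ct_reference = 10)
#' relative_expression(recs, design)
#' @export
relative_expression <- function(records, design, reference_state = "P") {
  needed <- c("sample_id", "target", "ct_target", "ct_reference")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("Ct table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "ribomethr_format_error")
  }
  bad <- records |>
    filter(!is.finite(.data$ct_target) | !is.finite(.data$ct_reference) |
             .data$ct_target <= 0 | .data$ct_reference <= 0)
  if (nrow(bad) > 0) {
    abort(paste0("Non-finite or non-positive Ct for sample(s): ",
                 paste(unique(bad$sample_id), collapse = ", ")),
          class = "ribomethr_validation_error")
  }
  design <- validate_design(design)
  bio <- bio_design(design)
  dat <- records |>
    left_join(bio, by = c(sample_id = "bio_id")) |>
    mutate(dct = .data$ct_target - .data$ct_reference)
  if (anyNA(dat$state)) {
    abort(paste0("Sample(s) absent from design: ",
                 paste(unique(dat$sample_id[is.na(dat$state)]), collapse = ", ")),
          class = "ribomethr_lookup_error")
  }
  dat |>
    group_by(.data$target) |>
    mutate(relative_expression =
             2^(-(.data$dct - mean(.data$dct[.data$state == reference_state])))) |>
    ungroup() |>
    select("target", "sample_id", "donor", "state", "dct",
           "relative_expression")
}

#' Normalise northern-blot band intensities to a loading control
#'
#' Divides each lane's signal by the lane's control signal (e.g. the
#' invariant SNORD57 band for snoRNA blots), then rescales per target so
#' the mean of the reference state (proliferating cells) is 1. Lanes with
#' a missing or non-positive control are excluded with a warning.
#'
#' @param bands Tibble with columns `sample_id` (lane), `species` (band
#'   identity), `intensity`, plus design columns or a `design` to join.
#' @param control Name of the loading-control species.
#' @param design Design tibble.
#' @param reference_state Baseline state (default `"P"`).
#' @return Tibble with `species`, `sample_id`, `state`, `normalized`
#'   (control-divided, reference-state mean 1).
#' @export
normalize_northern <- function(bands, control, design, reference_state = "P") {
  ctrl <- bands |>
    filter(.data$species == control) |>
    select("sample_id", control_intensity = "intensity")
  dat <- bands |>
    filter(.data$species != control) |>
    left_join(ctrl, by = "sample_id")
  bad <- is.na(dat$control_intensity) | dat$control_intensity <= 0
  if (any(bad)) {
    warn(paste0("Excluding lane(s) with missing/non-positive control '",
                control, "': ",
                paste(unique(dat$sample_id[bad]), collapse = ", ")))
    dat <- dat[!bad, ]
  }
  design <- validate_design(design)
  bio <- bio_design(design)
  dat |>
    left_join(bio, by = c(sample_id = "bio_id")) |>
    mutate(ratio = .data$intensity / .data$control_intensity) |>
    group_by(.data$species) |>
    mutate(normalized = .data$ratio /
             mean(.data$ratio[.data$state == reference_state])) |>
    ungroup() |>
    select("species", "sample_id", "donor", "state", "normalized")
}

#' Two-tailed one-sample t-test against an expected value
#'
#' Standard one-sample t on fold-change style data: after normalisation to
#' the proliferating state, values are tested against an expected value of 1.
#' Zero sample variance is an explicit error (the statistic is undefined),
#' not an infinite t.
#'
#' @param values Numeric vector, length >= 2.
#' @param expected Null value (default 1).
#' @return A tibble with `estimate`, `t`, `df`, `p_value`, `n`.
#' @examples
#' one_sample_t(c(1.2, 1.3, 1.4)) # t = 5.196, df = 2, p ~ 0.035
#' @export
one_sample_t <- function(values, expected = 1) {
  values <- values[!is.na(values)]
  if (length(values) < 2) {
    abort("Need >= 2 values for a one-sample t-test.",
          class = "ribomethr_parameter_error")
  }
  if (stats::sd(values) == 0) {
    abort("Sample standard deviation is zero; the t statistic is undefined.",
          class = "ribomethr_undefined_result")
  }
  ht <- stats::t.test(values, mu = expected, alternative = "two.sided")
  tibble(estimate = unname(ht$estimate), t = unname(ht$statistic),
         df = unname(ht$parameter), p_value = ht$p.value,
         n = length(values))
}

#' Correlate site methylation with guide-snoRNA expression
#'
#' For each requested site, computes the Pearson correlation (with a
#' Spearman rank correlation as a secondary, outlier-robust readout)
#' between the site's RMS scores and the expression of its guide snoRNA
#' across biological samples. Guide groups that a single assay cannot
#' resolve (e.g. `SNORD88A/B/C`) are matched as one aggregate series named
#' by joining the group members with `/`.
#'
#' @param scores An `rms_scores` tibble at the biological-sample level.
#' @param expr Expression tibble with columns `target`, `bio_id` (or
#'   `sample_id`), and an expression column (`expression` or
#'   `relative_expression`).
#' @param catalog A `site_catalog` (guide annotations).
#' @param sites Site labels to correlate; defaults to all catalogued sites
#'   with at least one guide and expression data.
#' @return Tibble with one row per site: `label`, `target`, `n`,
#'   `pearson_r`, `spearman_rho`, `status` (`"ok"` or
#'   `"insufficient_data"`).
#' @export
correlate_expression_methylation <- function(scores, expr, catalog,
                                             sites = NULL) {
  if (!"bio_id" %in% names(expr) && "sample_id" %in% names(expr)) {
    expr <- rename(expr, bio_id = "sample_id")
  }
  expr_col <- intersect(c("expression", "relative_expression"), names(expr))[1]
  if (is.na(expr_col)) {
    abort("Expression table needs an `expression` or `relative_expression` column.",
          class = "ribomethr_format_error")
  }
  guide_of <- stats::setNames(
    purrr::map_chr(catalog$guides, paste, collapse = "/"), catalog$label)
  if (is.null(sites)) {
    sites <- catalog$label[nzchar(guide_of) &
                             guide_of %in% unique(expr$target)]
  }
  purrr::map_dfr(sites, function(lab) {
    target <- guide_of[[lab]]
    if (!nzchar(target)) {
      abort(paste0("Site ", lab, " has no guide snoRNA annotation."),
            class = "ribomethr_lookup_error")
    }
    paired <- scores |>
      filter(.data$label == lab, .data$valid) |>
      inner_join(expr |>
                   filter(.data$target == !!target) |>
                   select("bio_id", e = all_of(expr_col)),
                 by = c(sample_id = "bio_id"))
    if (nrow(paired) < 3) {
      return(tibble(label = lab, target = target, n = nrow(paired),
                    pearson_r = NA_real_, spearman_rho = NA_real_,
                    status = "insufficient_data"))
    }
    tibble(label = lab, target = target, n = nrow(paired),
           pearson_r = stats::cor(paired$score, paired$e, method = "pearson"),
           spearman_rho = stats::cor(paired$score, paired$e, method = "spearman"),
           status = "ok")
  })
}

ratio_defs <- list(
  "47S:28S" = c("47S", "28S"), "21S:47S" = c("21S", "47S"),
  "18S-E:47S" = c("18S-E", "47S"), "30S:41S" = c("30S", "41S"),
  "30S:47S" = c("30S", "47S"), "41S:47S" = c("41S", "47S")
)

#' Pre-rRNA processing ratios with one-sample tests
#'
#' Steady-state precursor ratios (47S:28S, 21S:47S, 18S-E:47S, 30S:41S,
#' 30S:47S, 41S:47S) computed per biological sample from northern band
#' intensities, normalised to the proliferating-state mean, and tested per
#' non-reference state with a two-tailed one-sample t-test against 1.
#'
#' @param bands Tibble with columns `bio_id` (or `sample_id`), `species`,
#'   `intensity`, and optionally `donor`/`state` (joined from `design`
#'   otherwise).
#' @param design Design tibble.
#' @param ratios Character vector of ratios to compute (default all six).
#' @param reference_state Baseline state (default `"P"`).
#' @return A list with `per_sample` (tibble: `ratio`, `bio_id`, `donor`,
#'   `state`, `value`, `normalized`) and `tests` (tibble: `ratio`, `state`,
#'   `mean_normalized`, `t`, `df`, `p_value`, `n`).
#' @export
processing_ratios <- function(bands, design, ratios = names(ratio_defs),
                              reference_state = "P") {
  bad_ratio <- setdiff(ratios, names(ratio_defs))
  if (length(bad_ratio) > 0) {
    abort(paste0("Unknown ratio(s): ", paste(bad_ratio, collapse = ", ")),
          class = "ribomethr_parameter_error")
  }
  if (!"bio_id" %in% names(bands) && "sample_id" %in% names(bands)) {
    bands <- rename(bands, bio_id = "sample_id")
  }
  design <- validate_design(design)
  bio <- bio_design(design)
  if (!all(c("donor", "state") %in% names(bands))) {
    bands <- left_join(bands, bio, by = "bio_id")
  }
  wide <- bands |>
    select("bio_id", "donor", "state", "species", "intensity") |>
    tidyr::pivot_wider(names_from = "species", values_from = "intensity")

  per_sample <- purrr::map_dfr(ratios, function(r) {
    sp <- ratio_defs[[r]]
    if (!all(sp %in% names(wide))) {
      warn(paste0("Ratio ", r, " skipped: species ",
                  paste(setdiff(sp, names(wide)), collapse = ", "),
                  " not measured."))
      return(NULL)
    }
    df <- wide |>
      mutate(ratio = r, value = .data[[sp[1]]] / .data[[sp[2]]]) |>
      select("ratio", "bio_id", "donor", "state", "value")
    miss <- is.na(df$value)
    if (any(miss)) {
      warn(paste0("Ratio ", r, " missing for sample(s): ",
                  paste(df$bio_id[miss], collapse = ", ")))
      df <- df[!miss, ]
    }
    df |>
      mutate(normalized = .data$value /
               mean(.data$value[.data$state == reference_state]))
  })

  tests <- per_sample |>
    filter(.data$state != reference_state) |>
    group_by(.data$ratio, .data$state) |>
    group_modify(function(df, key) {
      # noiseless data (e.g. a zero-CV simulation) has no testable variance
      tt <- tryCatch(one_sample_t(df$normalized, expected = 1),
                     ribomethr_undefined_result = function(e) NULL)
      tibble(mean_normalized = mean(df$normalized),
             t = if (is.null(tt)) NA_real_ else tt$t,
             df = if (is.null(tt)) NA_real_ else tt$df,
             p_value = if (is.null(tt)) NA_real_ else tt$p_value,
             n = nrow(df),
             note = if (is.null(tt)) "zero_variance" else "ok")
    }) |>
    ungroup()

  list(per_sample = per_sample, tests = tests)
}
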