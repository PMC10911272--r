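# tolerance below which a sum of squares is treated as exactly zero,
# relative to the total SS (absolute floor guards the all-identical case)
.ss_tol <- function(ss_total) max(ss_total * 1e-12, 1e-24)

# per-site complete balanced check; returns NULL if ok, reason string if not
check_cells <- function(df, donors, states) {
  cells <- table(factor(df$donor, levels = donors),
                 factor(df$state, levels = states))
  if (any(cells == 0)) return("incomplete donor x state crossing")
  if (length(unique(as.vector(cells))) != 1) {
    return("unbalanced donor x state crossing")
  }
  NULL
}

#' Donor-blocked two-factor ANOVA per methylation site
#'
#' For each site, fits the additive fixed-effects model
#' `score ~ donor + state` on the biological samples and tests the
#' growth-state factor with `F = MS_state / MS_residual` on
#' `(a - 1)` and `(n - a - b + 1)` degrees of freedom for `a` states and
#' `b` donors. The donor term absorbs the between-donor batch effect
#' (blocking), so the state test is adjusted for donor. Only complete,
#' balanced donor-by-state crossings are fitted; sites with missing cells
#' are skipped with a reason, and unbalanced crossings are rejected.
#'
#' Degenerate fits are handled explicitly: an exactly additive table
#' (zero residual variance) with a non-zero state effect reports `p = 0`
#' with flag `"zero_residual"`; zero residual and zero effect reports
#' `F = 0`, `p = 1`.
#'
#' @param scores An `rms_scores` tibble at the biological-sample level
#'   (after [merge_technical_replicates()] and [compute_rms_scores()]).
#' @param design Design tibble; `donor` and `state` are looked up by
#'   `bio_id`/`sample_id`.
#' @return A tibble with one row per site: per-state means (`mean_<state>`),
#'   `F_state`, `p_state`, `df_state`, `df_residual`, `ms_residual`,
#'   `n_obs` and `flag` (`"ok"`, `"zero_residual"` or `"skipped: <reason>"`).
#' @export
fit_blocked_anova <- function(scores, design) {
  design <- validate_design(design)
  bio <- bio_design(design)
  dat <- scores |>
    filter(.data$valid) |>
    inner_join(bio, by = c(sample_id = "bio_id"))
  if (nrow(dat) == 0) abort("No valid scores match the design's biological samples.")
  donors <- unique(bio$donor)
  states <- unique(bio$state)
  if (length(donors) < 2 || length(states) < 2) {
    abort("The blocked model needs >= 2 donors and >= 2 states.",
          class = "ribomethr_parameter_error")
  }

  purrr::map_dfr(split(dat, dat$label), function(df) {
    means <- df |>
      group_by(.data$state) |>
      summarise(m = mean(.data$score), .groups = "drop")
    mean_cols <- stats::setNames(
      as.list(means$m[match(states, means$state)]),
      paste0("mean_", states))
    base_row <- tibble(label = df$label[1], !!!mean_cols, n_obs = nrow(df))

    bad <- check_cells(df, donors, states)
    if (!is.null(bad)) {
      return(base_row |>
               mutate(F_state = NA_real_, p_state = NA_real_,
                      df_state = NA_real_, df_residual = NA_real_,
                      ms_residual = NA_real_, flag = paste0("skipped: ", bad)))
    }
    fit <- stats::lm(score ~ donor + state, data = df)
    # anova.lm warns on essentially perfect fits; degenerate SS handled below
    an <- suppressWarnings(stats::anova(fit))
    ss <- an[["Sum Sq"]]
    names(ss) <- rownames(an)
    df_state <- an["state", "Df"]
    df_res <- an["Residuals", "Df"]
    tol <- .ss_tol(sum(ss))
    if (ss[["Residuals"]] <= tol) {
      if (ss[["state"]] <= tol) {
        res <- list(F_state = 0, p_state = 1, ms = 0, flag = "zero_residual")
      } else {
        res <- list(F_state = Inf, p_state = 0, ms = 0, flag = "zero_residual")
      }
    } else {
      res <- list(F_state = an["state", "F value"],
                  p_state = an["state", "Pr(>F)"],
                  ms = an["Residuals", "Mean Sq"], flag = "ok")
    }
    base_row |>
      mutate(F_state = res$F_state, p_state = res$p_state,
             df_state = df_state, df_residual = df_res,
             ms_residual = res$ms, flag = res$flag)
  }) |>
    arrange(match(.data$label, unique(scores$label)))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment
#' `q_(i) = min over j >= i of (p_(j) * m / j)`, capped at 1, with the input
#' order restored. Missing p-values propagate as missing and do not count
#' towards `m`.
#'
#' @param p_values Numeric vector of p-values in [0, 1] (NA allowed).
#' @return Numeric vector of q-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    abort("p-values must lie in [0, 1].", class = "ribomethr_domain_error")
  }
  out <- rep(NA_real_, length(p_values))
  out[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  out
}

#' Tukey range test for pairwise state contrasts at one site
#'
#' Post-hoc studentized-range comparisons between growth states, using the
#' residual mean square and residual degrees of freedom of the donor-blocked
#' ANOVA at that site, with state means taken over donors. For equal group
#' sizes n, the statistic for states u, v is
#' `q = |mean_u - mean_v| / sqrt(ms_residual / n)` and the p-value is the
#' upper tail of the studentized range distribution with `a` means and the
#' blocked model's residual df.
#'
#' @inheritParams fit_blocked_anova
#' @param site Site label to test.
#' @return A tibble with one row per state pair: `pair` (e.g. `"P-Q"`),
#'   `diff` (difference of means), `q_stat`, `p_tukey`, `flag`.
#' @export
tukey_pairwise <- function(scores, design, site) {
  fit <- fit_blocked_anova(filter(scores, .data$label == site), design)
  if (nrow(fit) == 0) {
    abort(paste0("No valid scores for site ", site),
          class = "ribomethr_lookup_error")
  }
  if (startsWith(fit$flag, "skipped")) {
    abort(paste0("Site ", site, " ", fit$flag), class = "ribomethr_parameter_error")
  }
  design <- validate_design(design)
  bio <- bio_design(design)
  dat <- scores |>
    filter(.data$valid, .data$label == site) |>
    inner_join(bio, by = c(sample_id = "bio_id"))
  gm <- dat |>
    group_by(.data$state) |>
    summarise(m = mean(.data$score), n = n(), .groups = "drop")
  a <- nrow(gm)
  pairs <- utils::combn(seq_len(a), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    d <- gm$m[i] - gm$m[j]
    if (fit$flag == "zero_residual") {
      p <- if (abs(d) <= 1e-12) 1 else 0
      return(tibble(pair = paste(gm$state[i], gm$state[j], sep = "-"),
                    diff = d, q_stat = if (p == 0) Inf else 0,
                    p_tukey = p, flag = "zero_residual"))
    }
    se <- sqrt(fit$ms_residual / 2 * (1 / gm$n[i] + 1 / gm$n[j]))
    q <- abs(d) / se
    tibble(pair = paste(gm$state[i], gm$state[j], sep = "-"),
           diff = d, q_stat = q,
           p_tukey = stats::ptukey(q, nmeans = a, df = fit$df_residual,
                                   lower.tail = FALSE),
           flag = "ok")
  })
}

#' Classify sites by methylation level and state-dependence
#'
#' Three classes: `variable` (state-dependent methylation, `q < q_cutoff`),
#' `constitutive_high` (stable and nearly fully methylated, grand mean score
#' above `high_cutoff`), and `substoichiometric_stable` (stable but not fully
#' methylated).
#'
#' @param results Tibble from [fit_blocked_anova()] with a `q_state` column
#'   (see [bh_adjust()]).
#' @param scores The `rms_scores` used for testing (grand means).
#' @param high_cutoff Grand-mean score above which a stable site is called
#'   constitutively high (default 0.9).
#' @param q_cutoff FDR cutoff for calling a site variable (default 0.1).
#' @return `results` with `grand_mean` and `classification` columns added.
#' @export
classify_sites <- function(results, scores, high_cutoff = 0.9, q_cutoff = 0.1) {
  if (!"q_state" %in% names(results)) {
    abort("`results` needs a `q_state` column; run bh_adjust() first.")
  }
  gm <- scores |>
    filter(.data$valid) |>
    group_by(.data$label) |>
    summarise(grand_mean = mean(.data$score), .groups = "drop")
  results |>
    left_join(gm, by = "label") |>
    mutate(classification = case_when(
      !is.na(.data$q_state) & .data$q_state < q_cutoff ~ "variable",
      .data$grand_mean > high_cutoff ~ "constitutive_high",
      TRUE ~ "substoichiometric_stable"
    ))
}

#' Full differential-methylation analysis
#'
#' Convenience wrapper chaining [fit_blocked_anova()], [bh_adjust()],
#' [tukey_pairwise()] (for every tested site) and [classify_sites()] into a
#' single fitted object with [tidy()]/[glance()]/[ggplot2::autoplot()]
#' methods.
#'
#' @inheritParams fit_blocked_anova
#' @inheritParams classify_sites
#' @return An object of class `rms_diff`.
#' @export
diff_methylation <- function(scores, design, high_cutoff = 0.9, q_cutoff = 0.1) {
  res <- fit_blocked_anova(scores, design) |>
    mutate(q_state = bh_adjust(.data$p_state))
  tukey <- purrr::map_dfr(res$label, function(lab) {
    row <- res[res$label == lab, ]
    if (startsWith(row$flag, "skipped")) return(NULL)
    tukey_pairwise(scores, design, lab) |>
      mutate(label = lab, .before = 1)
  })
  tukey_wide <- tukey |>
    select("label", "pair", "p_tukey") |>
    tidyr::pivot_wider(names_from = "pair", values_from = "p_tukey",
                       names_prefix = "p_tukey_")
  table <- res |>
    left_join(tukey_wide, by = "label") |>
    classify_sites(scores, high_cutoff = high_cutoff, q_cutoff = q_cutoff)
  structure(
    list(table = table, tukey = tukey,
         params = list(high_cutoff = high_cutoff, q_cutoff = q_cutoff),
         n_samples = length(unique(scores$sample_id))),
    class = "rms_diff")
}

#' @export
print.rms_diff <- function(x, ...) {
  cls <- table(x$table$classification)
  cat("Differential rRNA 2'-O-methylation analysis\n")
  cat("  sites tested:", sum(x$table$flag != "skipped"), "of",
      nrow(x$table), "\n")
  cat("  q cutoff:", x$params$q_cutoff,
      " high-methylation cutoff:", x$params$high_cutoff, "\n")
  for (k in names(cls)) cat("  ", k, ": ", cls[[k]], "\n", sep = "")
  invisible(x)
}

#' @rdname diff_methylation
#' @param x An `rms_diff` object.
#' @param ... Unused.
#' @method tidy rms_diff
#' @export
tidy.rms_diff <- function(x, ...) as_tibble(x$table)

#' @rdname diff_methylation
#' @method glance rms_diff
#' @export
glance.rms_diff <- function(x, ...) {
  tibble(n_sites = nrow(x$table),
         n_tested = sum(!startsWith(x$table$flag, "skipped")),
         n_variable = sum(x$table$classification == "variable", na.rm = TRUE),
         q_cutoff = x$params$q_cutoff,
         high_cutoff = x$params$high_cutoff,
         n_samples = x$n_samples)
}

#' Plot a differential-methylation result
#'
#' Grand-mean methylation score against FDR-adjusted significance, coloured
#' by site classification.
#'
#' @param object An `rms_diff` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rms_diff
#' @export
autoplot.rms_diff <- function(object, ...) {
  df <- object$table |>
    filter(!is.na(.data$q_state)) |>
    mutate(neglog_q = -log10(pmax(.data$q_state, 1e-300)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$grand_mean, y = .data$neglog_q,
                                   colour = .data$classification)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = -log10(object$params$q_cutoff),
                        linetype = "dashed") +
    ggplot2::labs(x = "grand mean RMS score", y = "-log10(q)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
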