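#' Default run configuration
#'
#' Assembles the full configuration for [run_full_pipeline()]: input paths,
#' scoring parameters, statistical cutoffs (q < 0.1 for discovery, grand
#' mean > 0.9 for constitutively high methylation, alpha 0.05), embedding
#' parameters and the root seed. Any part can be overridden via `...` using
#' the same nesting, or loaded from a YAML file with [read_run_config()].
#'
#' @param out_dir Output directory for run artifacts.
#' @param ... Named overrides merged over the defaults (e.g.
#'   `cutoffs = list(q_cutoff = 0.05)`).
#' @return A nested list of class `run_config`.
#' @export
default_run_config <- function(out_dir = tempfile("rms_run_"), ...) {
  cfg <- list(
    paths = list(catalog = NULL, counts_dir = NULL, design = NULL,
                 expression = NULL, bands = NULL, out_dir = out_dir),
    score = list(window = 2, min_flank_mean = 10,
                 end_convention = "five_prime"),
    cutoffs = list(q_cutoff = 0.1, high_cutoff = 0.9, alpha = 0.05),
    simulate = list(enabled = TRUE, preset = "senescence", donor_sd = 0.01),
    embedding = list(method = "tsne", perplexity = 3),
    seed = 1L
  )
  cfg <- utils::modifyList(cfg, list(...))
  stopifnot(cfg$cutoffs$q_cutoff > 0, cfg$cutoffs$q_cutoff < 1,
            cfg$cutoffs$high_cutoff > 0, cfg$cutoffs$high_cutoff < 1)
  class(cfg) <- "run_config"
  cfg
}

#' @param path YAML file with the same nesting as [default_run_config()].
#' @rdname default_run_config
#' @export
read_run_config <- function(path, ...) {
  do.call(default_run_config,
          c(utils::modifyList(yaml::read_yaml(path), list(...))))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("Pipeline stage '", name, "' failed: ", conditionMessage(e)),
          class = "ribomethr_stage_error", parent = e)
  })
}

#' Run the full RiboMeth-seq analysis pipeline
#'
#' Orchestrates merge of technical replicates, RMS scoring, donor-blocked
#' differential testing with Benjamini-Hochberg adjustment, Tukey range
#' post-hoc contrasts and site classification, raw and donor-eliminated
#' 2-D embeddings, and — when expression or band-intensity inputs are
#' available — guide-snoRNA correlation and pre-rRNA processing-ratio
#' stages. All tables are written as TSV under the configured output
#' directory together with a YAML manifest (config hash, seed, per-stage
#' row counts); identical config and seed reproduce byte-identical outputs.
#'
#' With `simulate$enabled = TRUE` (the default when no counts directory is
#' given) the run starts by generating a ground-truthed synthetic dataset
#' under `<out_dir>/sim`.
#'
#' @param config A `run_config` from [default_run_config()] /
#'   [read_run_config()].
#' @return Invisibly, a list with the main in-memory results (`scores`,
#'   `diff`, `embedding_raw`, `embedding_adjusted`, `correlation`, `ratios`)
#'   and `out_dir`.
#' @export
run_full_pipeline <- function(config = default_run_config()) {
  out_dir <- config$paths$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_rows <- list()
  seed <- config$seed

  catalog <- run_stage("catalog", {
    if (is.null(config$paths$catalog)) load_site_catalog()
    else load_site_catalog(config$paths$catalog)
  })

  sim <- NULL
  if (isTRUE(config$simulate$enabled) || is.null(config$paths$counts_dir)) {
    sim <- run_stage("simulate", {
      preset <- senescence_preset(donor_sd = config$simulate$donor_sd)
      simulate_rms_run(file.path(out_dir, "sim"), catalog = catalog,
                       design = study_design(), preset = preset,
                       seed = substream_seed(seed, "simulation"))
    })
    design <- study_design()
    counts <- sim$counts
    expr <- sim$expression
    bands <- sim$bands
  } else {
    design <- run_stage("design", read_design(config$paths$design))
    counts <- run_stage("read_counts", {
      paths <- list.files(config$paths$counts_dir, pattern = "\\.counts\\.tsv$",
                          full.names = TRUE)
      got <- sub("\\.counts\\.tsv$", "", basename(paths))
      missing <- setdiff(design$sample_id, got)
      if (length(missing) > 0) {
        abort(paste0("No count file for sample(s): ",
                     paste(missing, collapse = ", ")))
      }
      read_end_counts(paths, end_convention = config$score$end_convention)
    })
    expr <- if (!is.null(config$paths$expression)) {
      readr::read_tsv(config$paths$expression, show_col_types = FALSE)
    }
    bands <- if (!is.null(config$paths$bands)) {
      readr::read_tsv(config$paths$bands, show_col_types = FALSE)
    }
  }

  merged <- run_stage("merge", merge_technical_replicates(counts, design))
  scores <- run_stage("score", {
    compute_rms_scores(merged, catalog, window = config$score$window,
                       min_flank_mean = config$score$min_flank_mean)
  })
  write_rms_scores(scores, file.path(out_dir, "rms_scores.tsv"))
  stage_rows$score <- nrow(scores)

  diff <- run_stage("differential", {
    diff_methylation(scores, design,
                     high_cutoff = config$cutoffs$high_cutoff,
                     q_cutoff = config$cutoffs$q_cutoff)
  })
  readr::write_tsv(tidy(diff), file.path(out_dir, "differential_sites.tsv"))
  stage_rows$differential <- nrow(diff$table)

  emb_seed <- substream_seed(seed, "embedding")
  emb_raw <- run_stage("embed_raw", {
    embed_samples(scores, seed = emb_seed,
                  method = config$embedding$method,
                  perplexity = config$embedding$perplexity)
  })
  emb_adj <- run_stage("embed_adjusted", {
    embed_samples(eliminate_factor(scores, design, "donor"), seed = emb_seed,
                  method = config$embedding$method,
                  perplexity = config$embedding$perplexity,
                  eliminated_factor = "donor")
  })
  readr::write_tsv(as_tibble(emb_raw), file.path(out_dir, "embedding_raw.tsv"))
  readr::write_tsv(as_tibble(emb_adj),
                   file.path(out_dir, "embedding_donor_eliminated.tsv"))
  stage_rows$embedding <- nrow(emb_raw)

  correlation <- NULL
  if (!is.null(expr)) {
    correlation <- run_stage("correlate", {
      correlate_expression_methylation(scores, expr, catalog)
    })
    readr::write_tsv(correlation,
                     file.path(out_dir, "snorna_correlation.tsv"))
    stage_rows$correlate <- nrow(correlation)
  }
  ratios <- NULL
  if (!is.null(bands)) {
    ratios <- run_stage("ratios", processing_ratios(bands, design))
    readr::write_tsv(ratios$per_sample,
                     file.path(out_dir, "processing_ratios.tsv"))
    readr::write_tsv(ratios$tests,
                     file.path(out_dir, "processing_ratio_tests.tsv"))
    stage_rows$ratios <- nrow(ratios$per_sample)
  }

  manifest <- list(
    pipeline = "ribomethr::run_full_pipeline",
    version = as.character(utils::packageVersion("ribomethr")),
    seed = as.integer(seed),
    config_hash = rlang::hash(unclass(config)),
    stage_rows = stage_rows,
    config = rapply(unclass(config), function(x) x, how = "replace")
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(scores = scores, diff = diff, embedding_raw = emb_raw,
                 embedding_adjusted = emb_adj, correlation = correlation,
                 ratios = ratios, design = design, catalog = catalog,
                 out_dir = out_dir))
}

#' Plot per-state score distributions for selected sites
#'
#' Strip plot of per-sample RMS scores by growth state, one panel per site —
#' the standard way of inspecting substoichiometric sites.
#'
#' @param scores An `rms_scores` tibble.
#' @param design Design tibble.
#' @param sites Site labels to show.
#' @return A ggplot.
#' @export
plot_site_scores <- function(scores, design, sites) {
  bio <- bio_design(validate_design(design))
  df <- scores |>
    filter(.data$label %in% sites, .data$valid) |>
    left_join(bio, by = c(sample_id = "bio_id"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$state, y = .data$score,
                                   colour = .data$state)) +
    ggplot2::geom_jitter(width = 0.1, height = 0, size = 2) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3, colour = "grey30") +
    ggplot2::facet_wrap(~label, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "RMS score", colour = NULL) +
    ggplot2::theme_minimal()
}
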