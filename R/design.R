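#' Build a study design table
#'
#' The default design mirrors a three-donor primary-fibroblast study:
#' three human dermal fibroblast donors (HDF76, HDF85, HDF161), each profiled
#' in the proliferating (P), contact-inhibited quiescent (Q) and
#' stress-induced premature senescent (SIPS) state, sequenced with two
#' technical replicates per biological sample (18 libraries).
#'
#' @param donors Character vector of donor labels.
#' @param states Character vector of growth-state labels.
#' @param tech_reps Number of technical replicates per biological sample.
#' @return A tibble with columns `sample_id` (library id), `bio_id`
#'   (biological sample id), `donor`, `state`, `tech_rep`.
#' @examples
#' study_design() # 18 libraries: 3 donors x 3 states x 2 technical replicates
#' @export
study_design <- function(donors = c("HDF76", "HDF85", "HDF161"),
                         states = c("P", "Q", "SIPS"),
                         tech_reps = 2) {
  d <- tidyr::expand_grid(donor = donors, state = states,
                          tech_rep = seq_len(tech_reps)) |>
    mutate(bio_id = paste(.data$donor, .data$state, sep = "_"),
           sample_id = paste0(.data$bio_id, "_r", .data$tech_rep)) |>
    select("sample_id", "bio_id", "donor", "state", "tech_rep")
  validate_design(d)
}

validate_design <- function(design) {
  needed <- c("sample_id", "donor", "state", "tech_rep")
  missing_cols <- setdiff(needed, names(design))
  if (length(missing_cols) > 0) {
    abort(paste0("Design is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "ribomethr_format_error")
  }
  if (!"bio_id" %in% names(design)) {
    design <- mutate(design, bio_id = paste(.data$donor, .data$state, sep = "_"))
  }
  if (anyDuplicated(design$sample_id)) {
    abort("Duplicate sample_id in design.", class = "ribomethr_validation_error")
  }
  key <- paste(design$donor, design$state, design$tech_rep)
  if (anyDuplicated(key)) {
    abort("Duplicate (donor, state, tech_rep) in design.",
          class = "ribomethr_validation_error")
  }
  as_tibble(design)
}

# one row per biological sample
bio_design <- function(design) {
  design |>
    distinct(.data$bio_id, .data$donor, .data$state)
}

#' Read / write a design table
#'
#' TSV with columns `sample_id`, `donor`, `state`, `tech_rep` (and optional
#' `bio_id`).
#'
#' @param path File path.
#' @return `read_design()` returns a validated design tibble;
#'   `write_design()` returns `path` invisibly.
#' @export
read_design <- function(path) {
  validate_design(readr::read_tsv(path, show_col_types = FALSE))
}

#' @param design Design tibble as returned by [study_design()].
#' @rdname read_design
#' @export
write_design <- function(design, path) {
  readr::write_tsv(design, path)
  invisible(path)
}
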