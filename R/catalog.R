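#' Default mature-rRNA reference lengths
#'
#' Lengths (nucleotides) of the mature human rRNA species on which catalog
#' positions are expressed. Coordinates throughout the package are 1-based
#' positions on these mature sequences.
#'
#' @return Named integer vector with entries `18S`, `5.8S` and `28S`.
#' @export
default_reference_lengths <- function() {
  c(`18S` = 1869L, `5.8S` = 157L, `28S` = 5070L)
}

subunit_levels <- c("18S", "5.8S", "28S")

#' Load a 2'-O-methylation site catalog
#'
#' Reads a tab-separated catalog of ribose-methylated rRNA positions with
#' columns `subunit`, `position`, `nucleotide`, `label` and `guides`
#' (comma-separated guide snoRNA names, empty allowed). Lines starting with
#' `#` are comments. The catalog is validated: unknown subunits, duplicate
#' `(subunit, position)` pairs and positions beyond the reference length are
#' rejected.
#'
#' @param path Path to the catalog TSV. Defaults to the packaged catalog of
#'   104 human rRNA sites.
#' @param reference_lengths Named vector mapping subunit to mature-rRNA
#'   length; positions must not exceed these.
#' @return A tibble of class `site_catalog` with columns `subunit` (factor),
#'   `position`, `nucleotide`, `label`, `guides` (list column of character
#'   vectors), plus a `reference_lengths` attribute. File order is preserved.
#' @examples
#' catalog <- load_site_catalog()
#' nrow(catalog) # 104
#' @export
load_site_catalog <- function(path = system.file("extdata", "sites_human_rrna.tsv",
                                                 package = "ribomethr"),
                              reference_lengths = default_reference_lengths()) {
  if (!file.exists(path)) abort(paste0("Catalog file not found: ", path))
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  needed <- c("subunit", "position", "nucleotide", "label", "guides")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Catalog is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "ribomethr_format_error")
  }
  sites <- raw |>
    mutate(position = as.integer(.data$position),
           guides = purrr::map(.data$guides, split_guides))
  validate_site_catalog(sites, reference_lengths)
}

split_guides <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, ",", fixed = TRUE)[[1]])
}

validate_site_catalog <- function(sites, reference_lengths) {
  bad_sub <- setdiff(unique(sites$subunit), subunit_levels)
  if (length(bad_sub) > 0) {
    abort(paste0("Unknown subunit(s): ", paste(bad_sub, collapse = ", ")),
          class = "ribomethr_validation_error")
  }
  if (any(is.na(sites$position)) || any(sites$position < 1)) {
    abort("Positions must be integers >= 1.",
          class = "ribomethr_validation_error")
  }
  dup <- sites |>
    count(.data$subunit, .data$position) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("Duplicate (subunit, position) entries: ",
                 paste(paste0(dup$subunit, ":", dup$position), collapse = ", ")),
          class = "ribomethr_validation_error")
  }
  missing_len <- setdiff(unique(sites$subunit), names(reference_lengths))
  if (length(missing_len) > 0) {
    abort(paste0("No reference length for subunit(s): ",
                 paste(missing_len, collapse = ", ")),
          class = "ribomethr_validation_error")
  }
  over <- sites$position > reference_lengths[as.character(sites$subunit)]
  if (any(over)) {
    abort(paste0("Position(s) beyond reference length: ",
                 paste(sites$label[over], collapse = ", ")),
          class = "ribomethr_range_error")
  }
  out <- sites |>
    mutate(subunit = factor(.data$subunit, levels = subunit_levels))
  attr(out, "reference_lengths") <- reference_lengths
  class(out) <- c("site_catalog", class(out))
  out
}

#' Write a site catalog to TSV
#'
#' Inverse of [load_site_catalog()]: a written catalog loads back identically.
#'
#' @param catalog A `site_catalog` tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_site_catalog <- function(catalog, path) {
  out <- catalog |>
    mutate(subunit = as.character(.data$subunit),
           guides = purrr::map_chr(.data$guides, paste, collapse = ",")) |>
    select("subunit", "position", "nucleotide", "label", "guides")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Parse a site label into subunit, nucleotide and position
#'
#' Site labels follow the field's `SSU-G436` / `LSU-G3723` convention:
#' `SSU` maps to 18S, `LSU` to 28S, followed by the methylated nucleotide and
#' its 1-based mature-rRNA position. A bare `G436` form is accepted when the
#' subunit is supplied via `subunit`.
#'
#' @param label Character vector of site labels.
#' @param subunit Optional explicit subunit (`"18S"`, `"5.8S"` or `"28S"`)
#'   used for bare labels without an SSU/LSU prefix.
#' @return A tibble with columns `label`, `subunit`, `nucleotide`, `position`.
#' @examples
#' parse_site_label("LSU-G3723") # 28S, G, 3723
#' @export
parse_site_label <- function(label, subunit = NULL) {
  m <- stringr::str_match(label, "^(?:(SSU|LSU)-)?([ACGU])([0-9]+)$")
  bad <- is.na(m[, 1]) | (is.na(m[, 2]) & is.null(subunit))
  if (any(bad)) {
    abort(paste0("Malformed site label(s): ",
                 paste(unique(label[bad]), collapse = ", ")),
          class = "ribomethr_parse_error")
  }
  sub <- ifelse(is.na(m[, 2]),
                if (is.null(subunit)) NA_character_ else as.character(subunit),
                c(SSU = "18S", LSU = "28S")[m[, 2]])
  tibble(label = label,
         subunit = factor(sub, levels = subunit_levels),
         nucleotide = m[, 3],
         position = as.integer(m[, 4]))
}

# resolve a label to its catalog row; error if absent
lookup_site <- function(catalog, label) {
  hit <- which(catalog$label == label)
  if (length(hit) != 1L) {
    abort(paste0("Site label not in catalog: ", label),
          class = "ribomethr_lookup_error")
  }
  catalog[hit, ]
}

#' Nucleotide distance between two catalogued sites
#'
#' Absolute distance in nucleotides between two sites on the same subunit;
#' for example the clustered pair LSU-C3680 / LSU-G3723 lies 43 nt apart.
#'
#' @param catalog A `site_catalog`.
#' @param label_a,label_b Catalogued site labels on the same subunit.
#' @return Non-negative integer distance.
#' @export
site_distance <- function(catalog, label_a, label_b) {
  a <- lookup_site(catalog, label_a)
  b <- lookup_site(catalog, label_b)
  if (as.character(a$subunit) != as.character(b$subunit)) {
    abort(paste0("Sites are on different subunits: ", label_a, " (", a$subunit,
                 ") vs ", label_b, " (", b$subunit, ")"),
          class = "ribomethr_domain_error")
  }
  abs(a$position - b$position)
}
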