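#' Default simulation preset for a senescence-style methylation study
#'
#' Encodes the study conditions the generator emulates: 104 catalogued sites
#' of which 95 are near-fully methylated (base level 0.97) and nine are
#' substoichiometric (base 0.60-0.90) with planted growth-state effects of
#' 0.04-0.10 on the methylated fraction. Six of the nine differ between
#' proliferating (P) cells and both non-proliferating states; three
#' (LSU-A2388, LSU-G3723, LSU-G4588) additionally differ between quiescent
#' (Q) and senescent (SIPS) cells. Donor batch offsets are drawn per
#' (site, donor) from a centred normal with standard deviation `donor_sd`.
#'
#' @param donor_sd Standard deviation of the per-(site, donor) batch offset on
#'   the methylated fraction. The default 0.01 reflects modest donor
#'   variability; 0.04 gives a donor-dominant dataset in which donor identity,
#'   not growth state, is the leading variance axis (useful for studying
#'   batch-factor elimination).
#' @return A list with elements `base_level`, `base_overrides` (named numeric,
#'   per-site base methylated fraction), `variable_sites` (named list of
#'   per-state offsets), `donor_sd`, `depth_per_bond` and `protection`.
#' @export
senescence_preset <- function(donor_sd = 0.01) {
  vs <- list(
    "SSU-G436"  = c(P = -0.08, Q = 0,     SIPS = 0),
    "SSU-C797"  = c(P = -0.10, Q = 0,     SIPS = 0),
    "SSU-G867"  = c(P = -0.06, Q = 0,     SIPS = 0),
    "SSU-C1272" = c(P = -0.05, Q = 0,     SIPS = 0),
    "LSU-G1303" = c(P = -0.07, Q = 0,     SIPS = 0),
    "LSU-A2388" = c(P = 0,     Q = 0.04,  SIPS = 0.10),
    "LSU-G2411" = c(P = -0.06, Q = 0,     SIPS = 0),
    "LSU-G3723" = c(P = -0.10, Q = 0,     SIPS = 0.06),
    "LSU-G4588" = c(P = -0.06, Q = 0,     SIPS = 0.05)
  )
  base <- c(
    "SSU-G436" = 0.75, "SSU-C797" = 0.70, "SSU-G867" = 0.80,
    "SSU-C1272" = 0.85, "LSU-G1303" = 0.78, "LSU-A2388" = 0.72,
    "LSU-G2411" = 0.82, "LSU-G3723" = 0.65, "LSU-G4588" = 0.88
  )
  list(base_level = 0.97, base_overrides = base, variable_sites = vs,
       donor_sd = donor_sd, depth_per_bond = 3000, protection = 1)
}

#' Ground-truth methylated fractions for a simulated study
#'
#' Builds the per-site, per-biological-sample true methylated fraction
#' `m = clip(base + donor_offset + state_offset, 0, 1)`. State offsets are
#' fixed (planted) effects; donor offsets are drawn once per (site, donor)
#' from `Normal(0, donor_sd)`. Technical replicates of a biological sample
#' share the same truth by construction.
#'
#' @param catalog A `site_catalog`.
#' @param design Design tibble from [study_design()].
#' @param base_level Default base methylated fraction for sites without an
#'   override.
#' @param variable_sites Named list: site label -> named numeric of per-state
#'   offsets. Sites not listed get state offset 0.
#' @param base_overrides Named numeric of per-site base levels.
#' @param donor_sd Standard deviation of donor offsets (>= 0).
#' @param seed Integer seed; fixed seed reproduces the truth exactly.
#' @return A tibble of class `methylation_truth` with one row per
#'   (site, biological sample): `label`, `bio_id`, `donor`, `state`, `base`,
#'   `donor_offset`, `state_offset`, `m`, `variable`.
#' @export
build_truth <- function(catalog, design, base_level = 0.97,
                        variable_sites = list(), base_overrides = numeric(0),
                        donor_sd = 0.01, seed = 1L) {
  if (donor_sd < 0) abort("`donor_sd` must be >= 0.")
  unknown <- setdiff(c(names(variable_sites), names(base_overrides)),
                     catalog$label)
  if (length(unknown) > 0) {
    abort(paste0("variable_sites/base_overrides name uncatalogued site(s): ",
                 paste(unknown, collapse = ", ")),
          class = "ribomethr_lookup_error")
  }
  bio <- bio_design(design)
  donors <- unique(bio$donor)
  states <- unique(bio$state)

  donor_off <- with_seed(seed, {
    matrix(stats::rnorm(nrow(catalog) * length(donors), sd = donor_sd),
           nrow = nrow(catalog), ncol = length(donors),
           dimnames = list(catalog$label, donors))
  })

  state_off <- matrix(0, nrow = nrow(catalog), ncol = length(states),
                      dimnames = list(catalog$label, states))
  for (lab in names(variable_sites)) {
    off <- variable_sites[[lab]]
    bad <- setdiff(names(off), states)
    if (length(bad) > 0) {
      abort(paste0("Unknown state(s) in variable_sites[['", lab, "']]: ",
                   paste(bad, collapse = ", ")))
    }
    state_off[lab, names(off)] <- as.numeric(off)
  }
  base <- stats::setNames(rep(base_level, nrow(catalog)), catalog$label)
  base[names(base_overrides)] <- base_overrides

  truth <- tidyr::expand_grid(label = catalog$label, bio_id = bio$bio_id) |>
    left_join(bio, by = "bio_id") |>
    mutate(base = base[.data$label],
           donor_offset = donor_off[cbind(.data$label, .data$donor)],
           state_offset = state_off[cbind(.data$label, as.character(.data$state))],
           m = clip01(.data$base + .data$donor_offset + .data$state_offset),
           variable = .data$label %in% names(variable_sites))
  class(truth) <- c("methylation_truth", class(truth))
  truth
}

#' Simulate RiboMeth-seq fragment end counts
#'
#' Measurement model for alkaline-hydrolysis sequencing: every
#' phosphodiester bond of each rRNA species accumulates fragment ends
#' independently, `count ~ Poisson(depth_per_bond * (1 - m * protection))`,
#' where `m` is the true methylated fraction if the bond sits 3' of a
#' catalogued site in that sample and 0 otherwise. Bonds are indexed
#' 1..(reference length - 1); the bond protected by methylation of
#' nucleotide p is bond p. Each library (technical replicate) is drawn
#' independently, so replicates differ only by counting noise.
#'
#' @param truth `methylation_truth` from [build_truth()].
#' @param catalog The `site_catalog` used to build the truth.
#' @param design Design tibble; one library is simulated per `sample_id`.
#' @param depth_per_bond Expected cleavage events per unmethylated bond
#'   (lambda); must be positive.
#' @param protection Fractional cleavage reduction at a fully methylated
#'   site, in [0, 1].
#' @param seed Integer seed; fixed seed reproduces counts exactly.
#' @return A tibble of class `end_counts` with columns `sample_id`, `subunit`,
#'   `position` (bond index) and `count`.
#' @export
simulate_end_counts <- function(truth, catalog, design,
                                depth_per_bond = 3000, protection = 1,
                                seed = 1L) {
  if (depth_per_bond <= 0) {
    abort("`depth_per_bond` must be positive.", class = "ribomethr_parameter_error")
  }
  if (protection < 0 || protection > 1) {
    abort("`protection` must lie in [0, 1].", class = "ribomethr_parameter_error")
  }
  ref_len <- attr(catalog, "reference_lengths")
  subs <- as.character(unique(catalog$subunit))
  if (any(!subs %in% names(ref_len))) {
    abort("Every catalog subunit needs a reference length.")
  }
  bonds <- purrr::map_dfr(subs, function(s) {
    tibble(subunit = s, position = seq_len(ref_len[[s]] - 1L))
  })
  site_idx <- match(paste(bonds$subunit, bonds$position),
                    paste(catalog$subunit, catalog$position))

  m_wide <- truth |>
    select("label", "bio_id", "m") |>
    tidyr::pivot_wider(names_from = "bio_id", values_from = "m")
  m_mat <- as.matrix(m_wide[, -1, drop = FALSE])
  rownames(m_mat) <- m_wide$label

  design <- validate_design(design)
  counts <- with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(design)), function(i) {
      bio <- design$bio_id[i]
      m_b <- rep(0, nrow(bonds))
      hit <- !is.na(site_idx)
      m_b[hit] <- m_mat[catalog$label[site_idx[hit]], bio]
      lambda <- depth_per_bond * (1 - m_b * protection)
      tibble(sample_id = design$sample_id[i],
             subunit = bonds$subunit,
             position = bonds$position,
             count = stats::rpois(nrow(bonds), lambda))
    })
  })
  class(counts) <- c("end_counts", class(counts))
  counts
}

#' Simulate guide-snoRNA expression coupled to site methylation
#'
#' Emulates the observation that methylation at substoichiometric sites
#' tracks the expression of the guiding box C/D snoRNA. Per biological
#' sample, `expression = coupling * m + (1 - coupling) * baseline + noise`;
#' guide groups such as `SNORD88A/B/C` are reported as one aggregate series.
#'
#' @param truth `methylation_truth`.
#' @param catalog The `site_catalog` (provides guide annotations).
#' @param sites Site labels to simulate; defaults to the truth's variable
#'   sites. Each must carry at least one guide snoRNA in the catalog.
#' @param coupling Fraction of expression variance tracking methylation, in
#'   [0, 1].
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param baseline Constant expression component.
#' @param seed Integer seed.
#' @return Tibble with columns `target` (aggregate guide name), `label`,
#'   `bio_id`, `donor`, `state`, `expression`.
#' @export
simulate_snorna_expression <- function(truth, catalog, sites = NULL,
                                       coupling = 0.9, noise_sd = 0.01,
                                       baseline = 0.8, seed = 1L) {
  if (coupling < 0 || coupling > 1) {
    abort("`coupling` must lie in [0, 1].", class = "ribomethr_parameter_error")
  }
  if (is.null(sites)) sites <- unique(truth$label[truth$variable])
  guide_of <- stats::setNames(
    purrr::map_chr(catalog$guides, paste, collapse = "/"), catalog$label)
  no_guide <- sites[!nzchar(guide_of[sites]) | is.na(guide_of[sites])]
  if (length(no_guide) > 0) {
    abort(paste0("Site(s) without guide snoRNA annotation: ",
                 paste(no_guide, collapse = ", ")),
          class = "ribomethr_lookup_error")
  }
  base_tbl <- truth |>
    filter(.data$label %in% sites) |>
    mutate(target = guide_of[.data$label])
  with_seed(seed, {
    base_tbl |>
      mutate(expression = coupling * .data$m + (1 - coupling) * baseline +
               stats::rnorm(n(), sd = noise_sd)) |>
      select("target", "label", "bio_id", "donor", "state", "expression")
  })
}

pre_rrna_species <- c("47S", "45S", "41S", "30S", "21S", "18S-E", "32S",
                      "12S", "28S")

#' Default northern-blot intensity means per growth state
#'
#' Mean band intensities (arbitrary units) for the pre-rRNA processing
#' intermediates, chosen so that the 30S:41S ratio doubles in the
#' non-proliferating states (Q, SIPS) relative to proliferating cells —
#' a shift of precursor flux between the two canonical processing pathways.
#'
#' @return Named list: state -> named numeric of species means.
#' @export
band_preset <- function() {
  p <- c(`47S` = 100, `45S` = 80, `41S` = 60, `30S` = 40, `21S` = 50,
         `18S-E` = 30, `32S` = 70, `12S` = 20, `28S` = 200)
  q <- p; q[c("30S", "41S")] <- c(60, 45)   # 30S:41S doubles vs P
  list(P = p, Q = q, SIPS = q)
}

#' Simulate northern-blot band intensities
#'
#' Per biological sample, each species' intensity is the stated state mean
#' multiplied by lognormal noise with coefficient of variation `noise_cv`
#' (unit mean).
#'
#' @param ratios_by_state Named list: state -> named numeric of mean
#'   intensities per pre-rRNA species (see [band_preset()]).
#' @param design Design tibble.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer seed.
#' @return Tibble with columns `bio_id`, `donor`, `state`, `species`,
#'   `intensity`.
#' @export
simulate_band_intensities <- function(ratios_by_state = band_preset(),
                                      design = study_design(),
                                      noise_cv = 0.05, seed = 1L) {
  for (st in names(ratios_by_state)) {
    sp <- ratios_by_state[[st]]
    bad <- setdiff(names(sp), pre_rrna_species)
    if (length(bad) > 0) {
      abort(paste0("Unknown pre-rRNA species: ", paste(bad, collapse = ", ")),
            class = "ribomethr_parameter_error")
    }
    if (any(sp <= 0)) {
      abort("Band intensity means must be positive.",
            class = "ribomethr_parameter_error")
    }
  }
  bio <- bio_design(validate_design(design))
  bad_state <- setdiff(unique(bio$state), names(ratios_by_state))
  if (length(bad_state) > 0) {
    abort(paste0("No intensity means for state(s): ",
                 paste(bad_state, collapse = ", ")))
  }
  sdlog <- sqrt(log(1 + noise_cv^2))
  with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(bio)), function(i) {
      means <- ratios_by_state[[as.character(bio$state[i])]]
      noise <- if (noise_cv == 0) rep(1, length(means)) else {
        stats::rlnorm(length(means), meanlog = -sdlog^2 / 2, sdlog = sdlog)
      }
      tibble(bio_id = bio$bio_id[i], donor = bio$donor[i],
             state = bio$state[i], species = names(means),
             intensity = unname(means * noise))
    })
  })
}

#' Write / read end-count profiles
#'
#' Profiles are stored one file per library as bedGraph-like TSV with columns
#' `subunit`, `position`, `count5p`, where `position` is the nucleotide whose
#' 5' end was observed; the reader attributes the 5'-end count at position
#' i+1 to the phosphodiester bond i (`end_convention = "five_prime"`, the
#' default). With `"three_prime"` the file position is taken as the bond
#' index directly; `"both"` expects `count5p` and `count3p` columns and sums
#' the two sources of evidence per bond.
#'
#' @param counts An `end_counts` tibble (bond-indexed).
#' @param dir Output directory (created if needed); one
#'   `<sample_id>.counts.tsv` per library.
#' @return `write_end_counts()` returns the written paths invisibly;
#'   `read_end_counts()` returns an `end_counts` tibble.
#' @export
write_end_counts <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- counts |>
    mutate(position = .data$position + 1L) |>   # bond i -> 5' end at i+1
    rename(count5p = "count") |>
    group_by(.data$sample_id) |>
    group_map(function(df, key) {
      p <- file.path(dir, paste0(key$sample_id, ".counts.tsv"))
      readr::write_tsv(df, p)
      p
    })
  invisible(unlist(paths))
}

#' @param paths Files to read (each one library).
#' @param sample_ids Library ids, defaulting to file basenames without the
#'   `.counts.tsv` suffix.
#' @param end_convention How file positions map to bonds.
#' @rdname write_end_counts
#' @export
read_end_counts <- function(paths, sample_ids = NULL,
                            end_convention = c("five_prime", "three_prime", "both")) {
  end_convention <- match.arg(end_convention)
  if (is.null(sample_ids)) {
    sample_ids <- sub("\\.counts\\.tsv$", "", basename(paths))
  }
  out <- purrr::map2_dfr(paths, sample_ids, function(p, id) {
    # subunit must stay character ("18S" would otherwise guess as a number)
    df <- readr::read_tsv(p, show_col_types = FALSE,
                          col_types = readr::cols(
                            subunit = readr::col_character(),
                            position = readr::col_integer(),
                            .default = readr::col_double()))
    if (!"count5p" %in% names(df) && "count" %in% names(df)) {
      df <- rename(df, count5p = "count")
    }
    if (end_convention == "both" && !all(c("count5p", "count3p") %in% names(df))) {
      abort("end_convention 'both' needs count5p and count3p columns.",
            class = "ribomethr_format_error")
    }
    bond <- switch(end_convention,
      five_prime = df |>
        mutate(position = .data$position - 1L, count = .data$count5p) |>
        filter(.data$position >= 1L),
      three_prime = df |>
        mutate(count = if ("count3p" %in% names(df)) .data$count3p else .data$count5p),
      both = {
        five <- df |>
          transmute(subunit = .data$subunit, position = .data$position - 1L,
                    count = .data$count5p) |>
          filter(.data$position >= 1L)
        three <- df |>
          transmute(subunit = .data$subunit, position = .data$position,
                    count = .data$count3p)
        bind_rows(five, three) |>
          group_by(.data$subunit, .data$position) |>
          summarise(count = sum(.data$count), .groups = "drop")
      })
    bond |>
      transmute(sample_id = id, subunit = .data$subunit,
                position = .data$position, count = .data$count)
  })
  class(out) <- c("end_counts", class(out))
  out
}

#' Simulate a complete RiboMeth-seq run directory
#'
#' Generates truth, end counts, snoRNA expression and band intensities under
#' one output directory with a YAML manifest recording all parameters and the
#' seed, so the run is regenerable from the manifest alone.
#'
#' @param dir Output directory.
#' @param catalog A `site_catalog`.
#' @param design Design tibble.
#' @param preset Parameter list as from [senescence_preset()].
#' @param seed Root integer seed; substreams for truth, counts, expression
#'   and bands are derived from it.
#' @return Invisibly, a list with the generated `truth`, `counts`,
#'   `expression`, `bands` and the manifest path.
#' @export
simulate_rms_run <- function(dir, catalog = load_site_catalog(),
                             design = study_design(),
                             preset = senescence_preset(), seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- build_truth(catalog, design,
                       base_level = preset$base_level,
                       variable_sites = preset$variable_sites,
                       base_overrides = preset$base_overrides,
                       donor_sd = preset$donor_sd,
                       seed = substream_seed(seed, "truth"))
  counts <- simulate_end_counts(truth, catalog, design,
                                depth_per_bond = preset$depth_per_bond,
                                protection = preset$protection,
                                seed = substream_seed(seed, "counts"))
  expr <- simulate_snorna_expression(truth, catalog,
                                     seed = substream_seed(seed, "snorna"))
  bands <- simulate_band_intensities(design = design,
                                     seed = substream_seed(seed, "bands"))
  write_design(design, file.path(dir, "design.tsv"))
  readr::write_tsv(truth, file.path(dir, "truth.tsv"))
  write_end_counts(counts, file.path(dir, "counts"))
  readr::write_tsv(expr, file.path(dir, "snorna_expression.tsv"))
  readr::write_tsv(bands, file.path(dir, "band_intensities.tsv"))
  manifest <- list(
    generator = "ribomethr::simulate_rms_run",
    seed = as.integer(seed),
    n_libraries = nrow(design),
    n_sites = nrow(catalog),
    parameters = list(
      base_level = preset$base_level,
      donor_sd = preset$donor_sd,
      depth_per_bond = preset$depth_per_bond,
      protection = preset$protection,
      variable_sites = purrr::map(preset$variable_sites, as.list),
      base_overrides = as.list(preset$base_overrides)
    )
  )
  manifest_path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  invisible(list(truth = truth, counts = counts, expression = expr,
                 bands = bands, manifest = manifest_path))
}
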