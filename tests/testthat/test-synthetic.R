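test_that("build_truth applies the additive effect model with clipping", {
  catalog <- load_site_catalog()
  design <- study_design()

  # no effects at all: m is the base level everywhere
  flat <- build_truth(catalog, design, base_level = 0.9, donor_sd = 0, seed = 1)
  expect_true(all(flat$m == 0.9))
  expect_true(all(flat$state_offset == 0))

  # a single planted state offset is additive
  one <- build_truth(catalog, design, base_level = 0.85,
                     variable_sites = list("LSU-G3723" = c(P = -0.08)),
                     donor_sd = 0, seed = 1)
  at_site <- one[one$label == "LSU-G3723", ]
  expect_true(all(at_site$m[at_site$state == "P"] == 0.77))
  expect_true(all(at_site$m[at_site$state != "P"] == 0.85))
  expect_true(all(one$m[one$label != "LSU-G3723"] == 0.85))

  expect_error(build_truth(catalog, design,
                           variable_sites = list("LSU-G9999" = c(P = 0.1))),
               class = "ribomethr_lookup_error")
})

test_that("default preset plants state effects only at the nine named sites", {
  catalog <- load_site_catalog()
  design <- study_design()
  preset <- senescence_preset()
  truth <- build_truth(catalog, design,
                       base_level = preset$base_level,
                       variable_sites = preset$variable_sites,
                       base_overrides = preset$base_overrides,
                       donor_sd = 0, seed = 3)
  per_state <- truth |>
    dplyr::group_by(label, state) |>
    dplyr::summarise(m = mean(m), .groups = "drop") |>
    dplyr::group_by(label) |>
    dplyr::summarise(spread = diff(range(m)), .groups = "drop")
  differing <- sort(per_state$label[per_state$spread > 1e-12])
  expect_identical(differing, sort(names(preset$variable_sites)))
  expect_identical(length(differing), 9L)
  # only the three senescence-associated sites differ between Q and SIPS
  qs <- truth |>
    dplyr::filter(state %in% c("Q", "SIPS")) |>
    dplyr::group_by(label, state) |>
    dplyr::summarise(m = mean(m), .groups = "drop") |>
    tidyr::pivot_wider(names_from = state, values_from = m) |>
    dplyr::filter(abs(Q - SIPS) > 1e-12)
  expect_identical(sort(qs$label), c("LSU-A2388", "LSU-G3723", "LSU-G4588"))
})

test_that("truth is reproducible and shared across technical replicates", {
  catalog <- load_site_catalog()
  design <- study_design()
  t1 <- build_truth(catalog, design, donor_sd = 0.02, seed = 9)
  t2 <- build_truth(catalog, design, donor_sd = 0.02, seed = 9)
  expect_identical(t1, t2)
  # one truth row per (site, biological sample): replicates share it
  expect_identical(nrow(t1), 104L * 9L)
})

test_that("end counts follow the Poisson protection model", {
  catalog <- tiny_catalog()
  design <- study_design(donors = "d1", states = "P", tech_reps = 1)

  # full methylation, full protection: the site bond never fires
  full <- build_truth(catalog, design, base_level = 1, donor_sd = 0, seed = 1)
  counts <- simulate_end_counts(full, catalog, design,
                                depth_per_bond = 500, protection = 1, seed = 2)
  site_bonds <- counts |>
    dplyr::semi_join(tibble::tibble(subunit = as.character(catalog$subunit),
                                    position = catalog$position),
                     by = c("subunit", "position"))
  expect_true(all(site_bonds$count == 0))

  # no methylation: per-bond mean matches lambda over >= 500 bonds
  none <- build_truth(catalog, design, base_level = 0, donor_sd = 0, seed = 1)
  counts0 <- simulate_end_counts(none, catalog, design,
                                 depth_per_bond = 1000, protection = 1, seed = 3)
  n_bonds <- nrow(counts0)
  expect_gte(n_bonds, 500)
  expect_lt(abs(mean(counts0$count) - 1000), 3 * sqrt(1000 / n_bonds))

  expect_error(simulate_end_counts(none, catalog, design, depth_per_bond = 0),
               class = "ribomethr_parameter_error")
})

test_that("partial methylation and protection scale the site-bond rate", {
  catalog <- tiny_catalog()
  # many independent libraries of the same biological sample
  design <- study_design(donors = "d1", states = "P", tech_reps = 200)
  half <- build_truth(catalog, design, base_level = 0.5, donor_sd = 0, seed = 1)
  counts <- simulate_end_counts(half, catalog, design,
                                depth_per_bond = 1000, protection = 0.9,
                                seed = 4)
  # expected count at a site bond: 1000 * (1 - 0.5 * 0.9) = 550
  site_mean <- counts |>
    dplyr::filter(subunit == "18S", position == 20) |>
    dplyr::summarise(m = mean(count)) |>
    dplyr::pull(m)
  expect_lt(abs(site_mean - 550), 3 * sqrt(550 / 200))

  # E[site] / E[flank] = 1 - m * pi within Monte-Carlo error
  flank_mean <- counts |>
    dplyr::filter(subunit == "18S", position %in% c(18, 19, 21, 22)) |>
    dplyr::summarise(m = mean(count)) |>
    dplyr::pull(m)
  expect_lt(abs(site_mean / flank_mean - 0.55), 0.01)
})

test_that("simulation output is bit-identical for a fixed seed", {
  catalog <- tiny_catalog()
  design <- study_design(donors = c("d1", "d2"), states = c("P", "Q"))
  truth <- build_truth(catalog, design, donor_sd = 0.01, seed = 5)
  c1 <- simulate_end_counts(truth, catalog, design, seed = 6)
  c2 <- simulate_end_counts(truth, catalog, design, seed = 6)
  expect_identical(c1, c2)
  e1 <- simulate_snorna_expression(truth, catalog, sites = "SSU-G20", seed = 7)
  e2 <- simulate_snorna_expression(truth, catalog, sites = "SSU-G20", seed = 7)
  expect_identical(e1, e2)
})

test_that("snoRNA expression couples to methylation as configured", {
  catalog <- load_site_catalog()
  design <- study_design()
  preset <- senescence_preset()
  truth <- build_truth(catalog, design,
                       base_level = preset$base_level,
                       variable_sites = preset$variable_sites,
                       base_overrides = preset$base_overrides,
                       donor_sd = preset$donor_sd, seed = 11)

  # exact linearity at coupling 1, no noise
  ex <- simulate_snorna_expression(truth, catalog, coupling = 1,
                                   noise_sd = 0, seed = 1)
  by_site <- ex |>
    dplyr::left_join(dplyr::select(truth, label, bio_id, m),
                     by = c("label", "bio_id")) |>
    dplyr::group_by(label) |>
    dplyr::summarise(r = stats::cor(expression, m), .groups = "drop")
  expect_true(all(by_site$r > 1 - 1e-12))

  # strong coupling with small noise keeps r high at every planted site
  ex2 <- simulate_snorna_expression(truth, catalog, coupling = 0.9,
                                    noise_sd = 0.01, seed = 2)
  by_site2 <- ex2 |>
    dplyr::left_join(dplyr::select(truth, label, bio_id, m),
                     by = c("label", "bio_id")) |>
    dplyr::group_by(label) |>
    dplyr::summarise(r = stats::cor(expression, m), .groups = "drop")
  expect_true(all(by_site2$r > 0.8))

  # decoupled expression: mean correlation near zero over reruns
  rs <- purrr::map_dbl(1:200, function(s) {
    e <- simulate_snorna_expression(truth, catalog, sites = "LSU-G3723",
                                    coupling = 0, noise_sd = 0.05, seed = s)
    stats::cor(e$expression, truth$m[truth$label == "LSU-G3723"])
  })
  expect_lt(abs(mean(rs)), 0.1)

  expect_error(simulate_snorna_expression(truth, catalog, coupling = 1.5),
               class = "ribomethr_parameter_error")
})

test_that("band intensities reproduce stated means and validate species", {
  design <- study_design()
  exact <- simulate_band_intensities(noise_cv = 0, design = design, seed = 1)
  means <- band_preset()
  for (i in seq_len(nrow(exact))) {
    expect_equal(exact$intensity[i],
                 unname(means[[as.character(exact$state[i])]][exact$species[i]]))
  }
  expect_error(
    simulate_band_intensities(list(P = c(`99S` = 10)), design = design),
    class = "ribomethr_parameter_error")
  expect_error(
    simulate_band_intensities(list(P = c(`47S` = -1)), design = design),
    class = "ribomethr_parameter_error")
})

test_that("end-count TSV round-trip preserves bond-indexed counts", {
  catalog <- tiny_catalog()
  design <- study_design(donors = "d1", states = c("P", "Q"), tech_reps = 1)
  truth <- build_truth(catalog, design, donor_sd = 0, seed = 1)
  counts <- simulate_end_counts(truth, catalog, design, seed = 8)
  dir <- withr::local_tempdir()
  paths <- write_end_counts(counts, dir)
  back <- read_end_counts(sort(paths))
  expect_equal(
    dplyr::arrange(as.data.frame(back), sample_id, subunit, position),
    dplyr::arrange(as.data.frame(counts), sample_id, subunit, position))
})
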