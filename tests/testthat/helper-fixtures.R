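# In-code fixtures shared across test files.

# A small catalog on short mock rRNA species: sites chosen so that
# SSU-G20 / LSU-G150 sit mid-sequence, LSU-C60 / LSU-A62 form a cluster
# within the +/-2 flank window, and SSU-U2 sits at a reference edge.
tiny_catalog <- function() {
  sites <- tibble::tibble(
    subunit = c("18S", "18S", "28S", "28S", "28S"),
    position = c(2L, 20L, 60L, 62L, 150L),
    nucleotide = c("U", "G", "C", "A", "G"),
    label = c("SSU-U2", "SSU-G20", "LSU-C60", "LSU-A62", "LSU-G150"),
    guides = list("SNORDX2", "SNORDX20", "SNORDX60", "SNORDX62", "SNORDX150")
  )
  ribomethr:::validate_site_catalog(sites, c(`18S` = 200L, `28S` = 400L))
}

# constant-count profile over every bond of every subunit in `catalog`,
# with optional per-(subunit,bond) overrides given as a data.frame
flat_profile <- function(catalog, sample_id = "s1", count = 100,
                         overrides = NULL) {
  ref_len <- attr(catalog, "reference_lengths")
  out <- purrr::map_dfr(names(ref_len), function(s) {
    tibble::tibble(sample_id = sample_id, subunit = s,
                   position = seq_len(ref_len[[s]] - 1L), count = count)
  })
  if (!is.null(overrides)) {
    for (i in seq_len(nrow(overrides))) {
      hit <- out$subunit == overrides$subunit[i] &
        out$position == overrides$position[i]
      out$count[hit] <- overrides$count[i]
    }
  }
  class(out) <- c("end_counts", class(out))
  out
}

# long score tibble from a sites x samples matrix of true values plus
# iid gaussian noise (the score-level shortcut used by statistical tests)
scores_from_matrix <- function(m, noise_sd = 0, seed = 1) {
  set.seed(seed)
  m <- m + matrix(rnorm(length(m), sd = noise_sd), nrow(m))
  out <- tibble::as_tibble(m, rownames = "label") |>
    tidyr::pivot_longer(-label, names_to = "sample_id", values_to = "score") |>
    dplyr::mutate(valid = !is.na(score))
  class(out) <- c("rms_scores", class(out))
  out
}

# 3 donors x 3 states, one biological sample each
bio_design_3x3 <- function() {
  study_design(donors = paste0("d", 1:3), tech_reps = 1)
}

# truth matrix (sites x bio samples) for a design, from base + per-state and
# per-donor offsets
truth_matrix <- function(design, n_null = 10, base = 0.8,
                         state_eff = list(), donor_sd = 0, seed = 1) {
  set.seed(seed)
  bio <- unique(design[, c("bio_id", "donor", "state")])
  labs <- c(names(state_eff), paste0("null", seq_len(n_null)))
  don <- matrix(rnorm(length(labs) * length(unique(bio$donor)), sd = donor_sd),
                length(labs),
                dimnames = list(labs, unique(bio$donor)))
  m <- matrix(base, length(labs), nrow(bio), dimnames = list(labs, bio$bio_id))
  for (lab in names(state_eff)) {
    m[lab, ] <- m[lab, ] + state_eff[[lab]][as.character(bio$state)]
  }
  m + don[, bio$donor]
}

# independent sums-of-squares oracle for the balanced two-factor additive
# model: explicit mean decomposition, no lm/aov
anova_ss_oracle <- function(y, donor, state) {
  gm <- mean(y)
  dm <- tapply(y, donor, mean)
  sm <- tapply(y, state, mean)
  a <- length(sm); b <- length(dm); n <- length(y)
  r <- n / (a * b)                       # replicates per cell
  ss_donor <- a * r * sum((dm - gm)^2)
  ss_state <- b * r * sum((sm - gm)^2)
  ss_total <- sum((y - gm)^2)
  ss_res <- ss_total - ss_donor - ss_state
  df_state <- a - 1
  df_res <- n - a - b + 1
  F_state <- (ss_state / df_state) / (ss_res / df_res)
  list(F_state = F_state,
       p_state = stats::pf(F_state, df_state, df_res, lower.tail = FALSE),
       ms_res = ss_res / df_res, df_res = df_res)
}

# the printed toy table used in several oracle comparisons:
# donors d1-d3 within each state
toy_scores <- function() {
  m <- rbind(site1 = c(0.80, 0.82, 0.84, 0.90, 0.93, 0.94, 0.90, 0.92, 0.94))
  colnames(m) <- c("d1_P", "d2_P", "d3_P", "d1_Q", "d2_Q", "d3_Q",
                   "d1_SIPS", "d2_SIPS", "d3_SIPS")
  scores_from_matrix(m)
}
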