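test_that("blocked ANOVA matches the explicit sums-of-squares oracle", {
  design <- bio_design_3x3()
  bio <- unique(design[, c("bio_id", "donor", "state")])

  # the printed toy table
  toy <- toy_scores()
  fit <- fit_blocked_anova(toy, design)
  y <- toy$score[match(bio$bio_id, toy$sample_id)]
  oracle <- anova_ss_oracle(y, bio$donor, bio$state)
  expect_equal(fit$F_state, oracle$F_state, tolerance = 1e-10)
  expect_equal(fit$p_state, oracle$p_state, tolerance = 1e-10)
  expect_equal(fit$df_residual, oracle$df_res)

  # random complete balanced tables, including 2 technical means per cell
  set.seed(101)
  for (rep in 1:20) {
    m <- matrix(runif(9, 0.5, 1), 1,
                dimnames = list("s", bio$bio_id))
    sc <- scores_from_matrix(m)
    f <- fit_blocked_anova(sc, design)
    y <- sc$score[match(bio$bio_id, sc$sample_id)]
    o <- anova_ss_oracle(y, bio$donor, bio$state)
    expect_equal(f$F_state, o$F_state, tolerance = 1e-10)
    expect_equal(f$p_state, o$p_state, tolerance = 1e-10)
  }
})

test_that("degenerate tables get explicit F and p values", {
  design <- bio_design_3x3()
  bio <- unique(design[, c("bio_id", "donor", "state")])

  # all nine values identical: no variance at all
  same <- scores_from_matrix(matrix(0.9, 1, 9,
                                    dimnames = list("s", bio$bio_id)))
  f0 <- fit_blocked_anova(same, design)
  expect_identical(f0$F_state, 0)
  expect_identical(f0$p_state, 1)
  expect_identical(f0$flag, "zero_residual")

  # exactly additive donor + state effects: perfect fit, real effect
  donor_eff <- c(d1 = 0, d2 = 0.01, d3 = 0.02)
  state_eff <- c(P = 0, Q = 0.05, SIPS = 0.05)
  y <- 0.8 + donor_eff[bio$donor] + state_eff[as.character(bio$state)]
  add <- scores_from_matrix(matrix(y, 1, dimnames = list("s", bio$bio_id)))
  fa <- fit_blocked_anova(add, design)
  expect_identical(fa$p_state, 0)
  expect_identical(fa$flag, "zero_residual")
})

test_that("sites with incomplete cells are skipped with a reason", {
  design <- bio_design_3x3()
  bio <- unique(design[, c("bio_id", "donor", "state")])
  sc <- scores_from_matrix(matrix(runif(18), 2, 9,
                                  dimnames = list(c("a", "b"), bio$bio_id)))
  sc$valid[sc$label == "b" & sc$sample_id == "d1_P"] <- FALSE
  sc$score[!sc$valid] <- NA
  fit <- fit_blocked_anova(sc, design)
  expect_identical(fit$flag[fit$label == "a"], "ok")
  expect_match(fit$flag[fit$label == "b"], "^skipped: incomplete")
  expect_true(is.na(fit$p_state[fit$label == "b"]))
})

test_that("Benjamini-Hochberg adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_identical(bh_adjust(1.0), 1.0)
  expect_equal(bh_adjust(c(0.5, 0.5, 0.5)), rep(0.5, 3))
  expect_error(bh_adjust(c(0.1, 1.2)), class = "ribomethr_domain_error")

  # permutation equivariance and NA propagation
  set.seed(5)
  p <- runif(30)
  perm <- sample(30)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  p[c(3, 7)] <- NA
  q <- bh_adjust(p)
  expect_true(all(is.na(q[c(3, 7)])))
  expect_equal(q[-c(3, 7)], bh_adjust(p[-c(3, 7)]))
})

test_that("Tukey pairwise p-values match a studentized-range oracle", {
  design <- bio_design_3x3()
  bio <- unique(design[, c("bio_id", "donor", "state")])
  toy <- toy_scores()
  tk <- tukey_pairwise(toy, design, "site1")

  # oracle: independent recomputation of means and blocked MSE
  y <- toy$score[match(bio$bio_id, toy$sample_id)]
  o <- anova_ss_oracle(y, bio$donor, bio$state)
  gm <- tapply(y, as.character(bio$state), mean)
  for (pp in list(c("P", "Q"), c("P", "SIPS"), c("Q", "SIPS"))) {
    qstat <- abs(gm[pp[1]] - gm[pp[2]]) / sqrt(o$ms_res / 3)
    p_exp <- stats::ptukey(qstat, nmeans = 3, df = o$df_res, lower.tail = FALSE)
    got <- tk$p_tukey[tk$pair %in% c(paste(pp, collapse = "-"),
                                     paste(rev(pp), collapse = "-"))]
    expect_equal(got, unname(p_exp), tolerance = 1e-10)
  }

  # equal group means with positive residual variance: p ~ 1
  set.seed(8)
  flat <- scores_from_matrix(
    matrix(0.8, 1, 9, dimnames = list("s", bio$bio_id)), noise_sd = 0.01)
  y <- flat$score[match(bio$bio_id, flat$sample_id)]
  # impose identical state means exactly, keep donor/residual noise
  y <- y - ave(y, as.character(bio$state)) + 0.8
  flat$score <- y[match(flat$sample_id, bio$bio_id)]
  tk_flat <- tukey_pairwise(flat, design, "s")
  expect_true(all(tk_flat$p_tukey >= 0.999))

  # a 10-residual-sd shift of P separates P pairs, not Q vs SIPS
  set.seed(9)
  base <- matrix(0.8, 1, 9, dimnames = list("s", bio$bio_id))
  base[, bio$state == "P"] <- base[, bio$state == "P"] + 0.08
  shifted <- scores_from_matrix(base, noise_sd = 0.008)
  # hold the Q and SIPS group means exactly equal so that pair is truly null
  y <- shifted$score[match(bio$bio_id, shifted$sample_id)]
  nonP <- bio$state != "P"
  y[nonP] <- y[nonP] - ave(y[nonP], as.character(bio$state[nonP])) + 0.8
  shifted$score <- y[match(shifted$sample_id, bio$bio_id)]
  tk_s <- tukey_pairwise(shifted, design, "s")
  expect_lt(tk_s$p_tukey[tk_s$pair %in% c("P-Q", "Q-P")], 0.001)
  expect_lt(tk_s$p_tukey[tk_s$pair %in% c("P-SIPS", "SIPS-P")], 0.001)
  expect_gt(tk_s$p_tukey[tk_s$pair %in% c("Q-SIPS", "SIPS-Q")], 0.9)

  # degenerate: zero residual, unequal means
  add <- scores_from_matrix(base)
  tk_d <- tukey_pairwise(add, design, "s")
  expect_identical(tk_d$p_tukey[tk_d$pair %in% c("P-Q", "Q-P")], 0)
  expect_identical(tk_d$flag[1], "zero_residual")
})

test_that("site classification applies the q and level cutoffs", {
  design <- bio_design_3x3()
  bio <- unique(design[, c("bio_id", "donor", "state")])
  m <- rbind(high = rep(0.95, 9), mid = rep(0.70, 9), var = rep(0.60, 9))
  colnames(m) <- bio$bio_id
  sc <- scores_from_matrix(m, noise_sd = 0.01, seed = 3)
  res <- fit_blocked_anova(sc, design)
  res$q_state <- c(0.5, 0.5, 0.05)[match(res$label, c("high", "mid", "var"))]
  cls <- classify_sites(res, sc)
  got <- setNames(cls$classification, cls$label)
  expect_identical(unname(got["high"]), "constitutive_high")
  expect_identical(unname(got["mid"]), "substoichiometric_stable")
  expect_identical(unname(got["var"]), "variable")
})

test_that("factor elimination removes donor structure and is idempotent", {
  design <- bio_design_3x3()
  bio <- unique(design[, c("bio_id", "donor", "state")])

  # pure donor effects: adjusted scores are constant per site
  donor_eff <- c(d1 = -0.05, d2 = 0, d3 = 0.05)
  m <- rbind(s1 = 0.8 + donor_eff[bio$donor], s2 = 0.6 + donor_eff[bio$donor])
  colnames(m) <- bio$bio_id
  sc <- scores_from_matrix(m)
  adj <- eliminate_factor(sc, design, "donor")
  spread <- adj |>
    dplyr::group_by(label) |>
    dplyr::summarise(s = diff(range(score)), .groups = "drop")
  expect_true(all(spread$s < 1e-12))

  # no donor effects (pure state effects): identity
  state_eff <- c(P = 0.2, Q = 0.5, SIPS = 0.8)
  m3 <- rbind(s1 = unname(state_eff[as.character(bio$state)]))
  colnames(m3) <- bio$bio_id
  sc3 <- scores_from_matrix(m3)
  adj3 <- eliminate_factor(sc3, design, "donor")
  expect_equal(adj3$score, sc3$score)

  # idempotence on noisy data
  set.seed(12)
  noisy <- scores_from_matrix(matrix(runif(45), 5, 9,
                                     dimnames = list(paste0("s", 1:5),
                                                     bio$bio_id)))
  once <- eliminate_factor(noisy, design, "donor")
  twice <- eliminate_factor(once, design, "donor")
  expect_equal(twice$score, once$score, tolerance = 1e-12)
})

test_that("false-discovery control holds on planted-truth replicates", {
  design <- bio_design_3x3()
  bio <- unique(design[, c("bio_id", "donor", "state")])
  preset <- senescence_preset()
  fdp <- purrr::map_dbl(1:200, function(rep) {
    m <- truth_matrix(design, n_null = 95, base = 0.9,
                      state_eff = preset$variable_sites,
                      donor_sd = preset$donor_sd, seed = 1000 + rep)
    sc <- scores_from_matrix(m, noise_sd = 0.008, seed = 2000 + rep)
    fit <- fit_blocked_anova(sc, design)
    q <- bh_adjust(fit$p_state)
    called <- fit$label[q < 0.1]
    if (length(called) == 0) return(0)
    mean(!called %in% names(preset$variable_sites))
  })
  expect_lte(mean(fdp), 0.1)
})
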