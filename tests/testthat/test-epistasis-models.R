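test_that("intercept-only fit returns the grand mean; R2 grows with terms", {
  sim <- generate_landscape(random_landscape_params(seed = 3, noise_sd = 0.3,
                                                    replicates = 3), seed = 3)
  f0 <- fit_model(sim$measurements, model_spec(character()))
  expect_equal(unname(f0$coefficients["u0"]), mean(sim$measurements$dG))
  expect_equal(f0$r_squared, 0)
  specs <- list(c("P1"), c("P1", "R1_3"), c("P1", "R1_3", "R1_4", "R2"),
                c("P1", "P2", "R1_3", "R1_4", "R2", "X2", "X3"))
  r2 <- vapply(specs, function(g)
    fit_model(sim$measurements, model_spec(g))$r_squared, 0)
  expect_true(all(diff(c(0, r2)) >= -1e-12))
})

test_that("a single injected protein effect is recovered and others are null", {
  params <- landscape_params(protein = c(site25 = 0.65 * 2, site26 = 0,
                                         site29 = 0))
  sim <- generate_landscape(params)
  f <- fit_model(sim$landscape, model_spec(c("P1", "P2", "R1_3", "R1_4",
                                             "R2", "X2", "X3")))
  expect_equal(unname(f$coefficients["a"]), 0.65, tolerance = 1e-12)
  others <- setdiff(names(f$coefficients), c("u0", "a"))
  expect_lt(max(abs(f$coefficients[others])), 1e-9)
})

test_that("coefficients are invariant to which other groups are included", {
  # complete-factorial orthogonality of the abc/WYK encoding
  sim <- generate_landscape(random_landscape_params(seed = 5, noise_sd = 0.2,
                                                    replicates = 3), seed = 5)
  small <- fit_model(sim$measurements, model_spec("P1"))
  big <- fit_model(sim$measurements,
                   model_spec(c("P1", "P2", "R1_3", "R1_4", "R2", "X2", "X3")))
  for (nm in c("a", "b", "c")) {
    expect_lt(abs(small$coefficients[nm] - big$coefficients[nm]),
              1e-9 * max(1, abs(big$coefficients[nm])))
  }
})

test_that("state effects follow the WYK contrast formulas", {
  sim <- generate_landscape(random_landscape_params(seed = 8), seed = 8)
  f <- fit_model(sim$landscape, model_spec(c("R1_3", "R1_4", "R2")))
  co <- f$coefficients
  expect_equal(state_effect(f, 3, "C"),
               unname(-co["w3"] + co["y3"] - co["k3"]))
  expect_equal(state_effect(f, 3, "G"),
               unname(-co["w3"] - co["y3"] + co["k3"]))
  for (site in c(3, 4)) {
    tot <- sum(vapply(c("A", "C", "G", "T"),
                      function(nn) state_effect(f, site, nn), 0))
    expect_lt(abs(tot), 1e-12)
  }
  expect_error(state_effect(fit_model(sim$landscape, model_spec("R1_4")), 3, "G"),
               "R1_3")
})

test_that("the C3/A4 epistasis contrast expands to the nine-term formula", {
  sim <- generate_landscape(random_landscape_params(seed = 9), seed = 9)
  f <- fit_model(sim$landscape, model_spec(c("R1_3", "R1_4", "R2")))
  co <- f$coefficients
  manual <- -co["w3w4"] + co["w3y4"] + co["w3k4"] + co["y3w4"] - co["y3y4"] -
    co["y3k4"] - co["k3w4"] + co["k3y4"] + co["k3k4"]
  expect_equal(pair_epistasis(f, "C", "A"), unname(manual))
  # sign pattern for (G, T) from (-1,-1,1) x (1,1,1)
  manual_gt <- -co["w3w4"] - co["w3y4"] - co["w3k4"] - co["y3w4"] - co["y3y4"] -
    co["y3k4"] + co["k3w4"] + co["k3y4"] + co["k3k4"]
  expect_equal(pair_epistasis(f, "G", "T"), unname(manual_gt))
})

test_that("effects equal brute-force cell-mean contrasts on the factorial", {
  for (seed in c(21, 22, 23)) {
    rp <- random_landscape_params(seed = seed)
    sim <- generate_landscape(rp, seed = seed)
    ls <- sim$landscape
    f <- fit_model(ls, model_spec(c("P1", "P2", "R1_3", "R1_4", "R2", "X2", "X3")))
    for (nn in c("A", "G")) {
      expect_close(state_effect(f, 3, nn), oracle_state_effect(ls, 3, nn))
    }
    expect_close(pair_epistasis(f, "G", "T"), oracle_pair_contrast(ls, "G", "T"))
    expect_close(pair_epistasis(f, "C", "A"), oracle_pair_contrast(ls, "C", "A"))
    expect_close(substitution_effect(f, "site25"), oracle_sub_effect(ls, "site25"))
    expect_close(protein_pair_epistasis(f, "site25", "site29"),
                 oracle_protein_pair(ls, "site25", "site29"))
  }
})

test_that("cross-interface effects equal split-background refits", {
  rp <- random_landscape_params(seed = 31)
  sim <- generate_landscape(rp, seed = 31)
  ls <- sim$landscape
  f <- fit_model(ls, model_spec(c("P1", "P2", "R1_3", "R1_4", "R2", "X2", "X3")))
  pg <- enumerate_protein_genotypes()
  der <- pg$site26[match(ls$protein, pg$label)]
  f_der <- fit_model(ls[der, ], model_spec(c("R1_3", "R1_4", "R2")))
  f_anc <- fit_model(ls[!der, ], model_spec(c("R1_3", "R1_4", "R2")))
  for (nn in c("A", "T")) {
    expect_close(cross_interface_effect(f, "site26", 4, nn),
                 state_effect(f_der, 4, nn) - state_effect(f_anc, 4, nn))
  }
  expect_close(cross_interface_pair_effect(f, "site26", "G", "T"),
               pair_epistasis(f_der, "G", "T") - pair_epistasis(f_anc, "G", "T"))
  # zero cross coefficients give zero shifts, and shifts sum to zero
  sim0 <- generate_landscape(landscape_params(re3 = c(A = -1, C = 0, G = 1, T = 0)))
  f0 <- fit_model(sim0$landscape, model_spec(c("P1", "R1_3", "R1_4", "R2", "X2")))
  for (nn in c("A", "C", "G", "T")) {
    expect_lt(abs(cross_interface_effect(f0, "site25", 3, nn)), 1e-9)
  }
  tot <- sum(vapply(c("A", "C", "G", "T"),
                    function(nn) cross_interface_effect(f, "site26", 4, nn), 0))
  expect_lt(abs(tot), 1e-12)
})

test_that("binary and abc/WYK fits give identical state-level effects", {
  for (seed in c(41, 42)) {
    sim <- generate_landscape(random_landscape_params(seed = seed), seed = seed)
    spec <- model_spec(c("P1", "P2", "R1_3", "R1_4", "R2", "X2"))
    fw <- fit_model(sim$landscape, spec, "abc_wyk")
    fb <- fit_model(sim$landscape, spec, "binary")
    for (nn in c("A", "C", "G", "T")) {
      expect_close(state_effect(fw, 3, nn), state_effect(fb, 3, nn))
      expect_close(state_effect(fw, 4, nn), state_effect(fb, 4, nn))
    }
    expect_close(pair_epistasis(fw, "G", "A"), pair_epistasis(fb, "G", "A"))
    expect_close(substitution_effect(fw, "site29"),
                 substitution_effect(fb, "site29"))
    expect_close(protein_pair_epistasis(fw, "site25", "site26"),
                 protein_pair_epistasis(fb, "site25", "site26"))
    expect_close(cross_interface_effect(fw, "site25", 3, "G"),
                 cross_interface_effect(fb, "site25", 3, "G"))
  }
})

test_that("nested comparison: identical specs give statistic 0, p 1", {
  sim <- generate_landscape(random_landscape_params(seed = 51, noise_sd = 0.2,
                                                    replicates = 3), seed = 51)
  f <- fit_model(sim$measurements, model_spec("P1"))
  cmp <- compare_nested(f, f)
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p, 1)
  f2 <- fit_model(sim$measurements, model_spec(c("P1", "P2")))
  expect_error(compare_nested(f2, f), "not nested")
  cmp2 <- compare_nested(f, f2, family_size = 10)
  expect_equal(cmp2$df, 3L)
  expect_equal(cmp2$p_adj, min(1, cmp2$p * 10))
})

test_that("a strong injected pair interaction is detected with tiny p", {
  params <- landscape_params(re_pair = re_pair_matrix(GT = 0.8),
                             noise_sd = 0.1, replicates = 3)
  sim <- generate_landscape(params, seed = 61)
  f1 <- fit_model(sim$measurements, model_spec(c("R1_3", "R1_4")))
  f2 <- fit_model(sim$measurements, model_spec(c("R1_3", "R1_4", "R2")))
  cmp <- compare_nested(f1, f2)
  expect_lt(cmp$p, 1e-6)
})

test_that("variance partition telescopes and is order-robust on the factorial", {
  sim <- generate_landscape(random_landscape_params(seed = 71, noise_sd = 0.25,
                                                    replicates = 3), seed = 71)
  vp <- variance_partition(sim$measurements,
                           model_spec(c("P1", "P2", "R1_3", "R1_4", "R2",
                                        "X2", "X3")))
  full <- fit_model(sim$measurements,
                    model_spec(c("P1", "P2", "R1_3", "R1_4", "R2", "X2", "X3")))
  expect_equal(sum(vp$r2_increment), full$r_squared, tolerance = 1e-12)
  # raw increment of a group equals its marginal R2 contribution however
  # the other groups are staged (orthogonality)
  vp2 <- variance_partition(sim$measurements, model_spec(c("R2", "P1")))
  inc_r2_alone <- fit_model(sim$measurements, model_spec("R2"))$r_squared
  expect_equal(vp2$r2_increment[vp2$group == "R2"],
               vp$r2_increment[vp$group == "R2"], tolerance = 1e-9)
  expect_equal(inc_r2_alone, vp$r2_increment[vp$group == "R2"], tolerance = 1e-9)
})

test_that("noiseless single-group landscape puts all variance in that group", {
  params <- landscape_params(re3 = c(A = -0.5, C = -0.25, G = 1, T = -0.25))
  sim <- generate_landscape(params)
  vp <- variance_partition(sim$landscape,
                           model_spec(c("P1", "R1_3", "R1_4", "R2")))
  expect_equal(vp$r2_increment[vp$group == "R1_3"], 1, tolerance = 1e-9)
  expect_lt(max(abs(vp$r2_increment[vp$group %in% c("P1", "R1_4", "R2")])), 1e-9)
})

test_that("energy logo has ranked columns, floored widths and stars", {
  params <- landscape_params(
    re3 = c(A = -1 / 3, C = -1 / 3, G = 1, T = -1 / 3),
    re4 = c(A = -0.5 / 3, C = -0.5 / 3, G = -0.5 / 3, T = 0.5),
    re_pair = re_pair_matrix(GT = 0.8, GA = -0.5),
    noise_sd = 0.05, replicates = 3)
  sim <- generate_landscape(params, seed = 81)
  tab <- sim$measurements[sim$measurements$protein == "glu-gly-ala", ]
  logo <- build_energy_logo(tab)
  expect_s3_class(logo, "energy_logo")
  s3 <- logo[logo$column == "site3", ]
  expect_equal(s3$state[1], "G")            # dominant state ranked first
  expect_equal(sum(s3$height), 0, tolerance = 1e-9)
  expect_true(all(logo$width >= 0))
  expect_true(all(logo$star))               # strong effects, all significant
  epi <- logo[logo$column == "epistasis", ]
  expect_equal(epi$state[1], "GT")
  # logo from binary-encoded fits matches
  logo_b <- build_energy_logo(tab, encoding = "binary")
  m <- match(paste(logo$column, logo$state), paste(logo_b$column, logo_b$state))
  expect_close(logo$height, logo_b$height[m], tol = 1e-8)
})

test_that("logo on replicate-free data warns and omits stars", {
  sim <- generate_landscape(preset_ancsr1())
  ls <- sim$landscape[sim$landscape$protein == "glu-gly-ala", ]
  names(ls)[names(ls) == "mean_dG"] <- "dG"
  expect_warning(logo <- build_energy_logo(ls), "stars omitted")
  expect_true(all(is.na(logo$star)))
})

test_that("rank deficiency raises an informative error for abc_wyk", {
  jg <- enumerate_joint_genotypes()
  # only 16 REs of one protein: protein columns are constant -> collinear
  tab <- data.frame(protein = jg$protein[1:16], re = jg$re[1:16],
                    dG = rnorm(16))
  expect_error(fit_model(tab, model_spec(c("P1", "R1_3"))), "rank deficient")
})

test_that("effect recovery is unbiased and 95% CIs calibrate under noise", {
  n_sim <- 500
  true_val <- 1.0
  params <- landscape_params(re3 = c(A = -true_val / 3, C = -true_val / 3,
                                     G = true_val, T = -true_val / 3),
                             noise_sd = 0.2, replicates = 3)
  set.seed(909)
  cover <- logical(n_sim)
  errs <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    sim <- generate_landscape(params)
    tab <- sim$measurements[sim$measurements$protein == "glu-gly-ala", ]
    f <- fit_model(tab, model_spec(c("R1_3", "R1_4", "R2")))
    ci <- state_effect(f, 3, "G", conf = TRUE)
    cover[i] <- ci$lower <= true_val && true_val <= ci$upper
    errs[i] <- ci$value - true_val
  }
  expect_gt(mean(cover), 0.92)
  expect_lt(mean(cover), 0.98)
  # bias indistinguishable from zero at Monte-Carlo resolution
  expect_lt(abs(mean(errs)), 4 * sd(errs) / sqrt(n_sim))
})

test_that("effect_table collects every group the fit contains", {
  sim <- generate_landscape(random_landscape_params(seed = 99), seed = 99)
  f <- fit_model(sim$landscape,
                 model_spec(c("P1", "P2", "R1_3", "R1_4", "R2", "X2", "X3")))
  et <- effect_table(f)
  expect_setequal(unique(et$term_type),
                  c("re_main", "re_pair", "protein_main", "protein_pair",
                    "cross_2", "cross_3_pair", "cross_3_pp"))
  expect_equal(sum(et$term_type == "re_main"), 8L)
  expect_equal(sum(et$term_type == "re_pair"), 16L)
  expect_equal(sum(et$term_type == "cross_2"), 24L)
})
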