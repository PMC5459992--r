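test_that("behaviour simulator is deterministic and respects the session plan", {
  cfg <- behavior_sim_config(n_animals = 12, seed = 42)
  s1 <- simulate_behavior_cohort(cfg)
  s2 <- simulate_behavior_cohort(cfg)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))

  per <- split(s1$sessions, s1$sessions$animal_id)
  for (d in per) {
    expect_equal(d$schedule,
                 c(rep("FR1", 5), rep("FR3", 2), rep("FR5", 5), "PR"))
    expect_true(all(is.na(d$break_point[d$schedule != "PR"])))
    expect_false(is.na(d$break_point[d$schedule == "PR"]))
    inj <- d$injections[d$schedule == "PR"]
    if (inj > 0)
      expect_equal(d$break_point[d$schedule == "PR"],
                   pr_requirement(inj))
  }
})

test_that("with no motivation effect the FR5 mean matches the base rate", {
  cfg <- behavior_sim_config(n_animals = 100, motivation_sd = 0,
                             motivation_effect_fr5 = 0,
                             motivation_effect_bp = 0, seed = 7)
  sim <- simulate_behavior_cohort(cfg)
  fr5 <- sim$sessions$active_presses[sim$sessions$schedule == "FR5"]
  # NB variance mu + mu^2/size = 200 + 5000 = 5200 over 500 sessions
  se <- sqrt((200 + 200^2 / 8) / length(fr5))
  expect_lt(abs(mean(fr5) - 200), 3 * se)
  # identical capacity => identical break points
  expect_equal(length(unique(
    sim$sessions$break_point[sim$sessions$schedule == "PR"])), 1L)
})

test_that("latent motivation drives FR5 pressing when its effect is positive", {
  cfg <- behavior_sim_config(n_animals = 200, motivation_sd = 0.3,
                             motivation_effect_fr5 = 1, seed = 9)
  sim <- simulate_behavior_cohort(cfg)
  scores <- score_cohort(sim$sessions)
  mot <- sim$animals$motivation[match(scores$animal_id,
                                      sim$animals$animal_id)]
  ct <- suppressWarnings(
    cor.test(mot, scores$fr5_mean, method = "spearman"))
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("behaviour config errors name the offending field", {
  expect_error(behavior_sim_config(n_animals = 2), "n_animals")
  expect_error(behavior_sim_config(base_fr5_mean = -1), "base_fr5_mean")
  expect_error(behavior_sim_config(motivation_sd = -0.1), "motivation_sd")
  expect_error(behavior_sim_config(bp_capacity_base = 0), "bp_capacity_base")
})

test_that("methylome simulator is deterministic and conserves counts", {
  cfg <- methyl_sim_config(n_sites = 500, seed = 5)
  s1 <- simulate_methyl_matrix(cfg)
  s2 <- simulate_methyl_matrix(cfg)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))
  expect_true(all(s1$matrix$meth <= s1$matrix$total))
  expect_true(all(s1$matrix$meth >= 0))
  expect_true(all(s1$truth$maintained <= s1$truth$planted))
  expect_equal(sum(s1$truth$planted), 200)
  expect_equal(sum(s1$truth$maintained), 160)
})

test_that("methylome simulator validates its configuration", {
  expect_error(methyl_sim_config(samples_per_group = c("Saline-F0" = 4)),
               "missing required groups")
  expect_error(methyl_sim_config(n_planted_dmcs = 50, n_sites = 20),
               "n_planted_dmcs")
  expect_error(methyl_sim_config(weight_hypo = 1), "weight_hypo")
  expect_error(methyl_sim_config(global_demethylation_shift = 0.2),
               "global_demethylation_shift")
  expect_error(methyl_sim_config(overdispersion = 1), "overdispersion")
})

test_that("null planted effect leaves phenotype differences centred at zero", {
  cfg <- methyl_sim_config(n_sites = 4000, n_planted_dmcs = 0,
                           generation_effect_sd = 0, seed = 13)
  sim <- simulate_methyl_matrix(cfg)
  m <- sim$matrix
  selA <- m$samples$phenotype == "Addict" & m$samples$generation == "F0"
  selN <- m$samples$phenotype == "Non-addict" & m$samples$generation == "F0"
  dif <- rowSums(m$meth[, selA]) / rowSums(m$total[, selA]) -
    rowSums(m$meth[, selN]) / rowSums(m$total[, selN])
  dif <- dif[is.finite(dif)]
  expect_lt(abs(mean(dif)), 2 * sd(dif) / sqrt(length(dif)))
})

test_that("sample methylation converges to the site probability at high coverage", {
  cfg <- methyl_sim_config(n_sites = 300, n_planted_dmcs = 0,
                           global_demethylation_shift = 0,
                           generation_effect_sd = 0,
                           overdispersion = 0, coverage_mean = 5000,
                           coverage_dispersion = 1e6, seed = 21)
  sim <- simulate_methyl_matrix(cfg)
  lev <- methyl_levels(sim$matrix)
  dev <- abs(sweep(lev, 1, sim$truth$baseline))
  expect_lt(max(dev, na.rm = TRUE), 0.05)
})

test_that("planted Addict-vs-Non-addict differences match the closed-form expectation", {
  cfg <- methyl_sim_config(n_sites = 10000, n_planted_dmcs = 200,
                           planted_effect = 1.5, coverage_mean = 30, seed = 3)
  sim <- simulate_methyl_matrix(cfg)
  m <- sim$matrix
  tr <- sim$truth
  pl <- which(tr$planted)
  selA <- m$samples$phenotype == "Addict" & m$samples$generation == "F0"
  selN <- m$samples$phenotype == "Non-addict" & m$samples$generation == "F0"
  obs <- rowSums(m$meth[pl, selA]) / rowSums(m$total[pl, selA]) -
    rowSums(m$meth[pl, selN]) / rowSums(m$total[pl, selN])
  # analytic per-site difference: effect applied to the Addict group on the
  # logit scale, on top of the shared F0 demethylation shift
  l <- qlogis(tr$baseline[pl]) + cfg$global_demethylation_shift
  ana <- plogis(l + tr$sign[pl] * cfg$planted_effect) - plogis(l)
  ok <- is.finite(obs)
  expect_lt(abs(mean(tr$sign[pl][ok] * obs[ok]) -
                  mean(tr$sign[pl][ok] * ana[ok])), 0.05)
})

test_that("generational drift and exposure shift move group methylomes as configured", {
  cfg <- methyl_sim_config(n_sites = 5000, n_planted_dmcs = 0, seed = 17)
  sim <- simulate_methyl_matrix(cfg)
  m <- sim$matrix
  grp <- paste(m$samples$phenotype, m$samples$generation, sep = "-")
  gmean <- vapply(unique(grp), function(g)
    mean(methyl_levels(m)[, grp == g], na.rm = TRUE), numeric(1))
  # exposed F0 groups are globally demethylated relative to Saline F0
  expect_lt(gmean[["Addict-F0"]], gmean[["Saline-F0"]])
  expect_lt(gmean[["Non-addict-F0"]], gmean[["Saline-F0"]])
  # zero-mean per-site drift leaves F1 group means near Saline F0
  expect_lt(abs(gmean[["Addict-F1"]] - gmean[["Saline-F0"]]), 0.02)
})
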