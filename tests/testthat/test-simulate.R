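test_that("noise-free chemistry honours the piecewise zonation model", {
  cp <- core_params("c1", z_ox = 100, z_no3 = 180, o2_surface = 250,
                    noise_sd = 0, depth_grid = c(0, 50, 100, 180, 250))
  prof <- simulate_chemistry(cp, seed = 1)
  expect_equal(prof$O2_uM[prof$depth_cm == 0], 250)
  expect_equal(prof$NH4_uM[prof$depth_cm == 0], 0)
  expect_equal(prof$Mn_uM[prof$depth_cm == 0], 0)
  deep <- prof$depth_cm >= 180
  expect_true(all(prof$O2_uM[deep] == 0))
  expect_true(all(prof$NO3_uM[deep] == 0))
  # manganese appears only below nitrate depletion
  expect_true(all(prof$Mn_uM[prof$depth_cm <= 180] == 0))
  expect_gt(prof$Mn_uM[prof$depth_cm == 250], 0)
})

test_that("chemistry simulation is deterministic and validates its inputs", {
  cp <- core_params("c1", noise_sd = 2)
  expect_identical(simulate_chemistry(cp, seed = 7),
                   simulate_chemistry(cp, seed = 7))
  expect_error(core_params("bad", depth_grid = c(10, 10, 20)),
               "strictly increasing")
  expect_error(core_params("bad", z_ox = 200, z_no3 = 100), "z_ox")
  expect_error(core_params("bad", o2_surface = -1), ">= 0")
})

test_that("zonation ordering holds: strictly at zero noise, O2 = 0 always", {
  cp0 <- core_params("c0", noise_sd = 0, depth_grid = seq(0, 300, by = 10))
  prof0 <- simulate_chemistry(cp0, seed = 1)
  mn0 <- prof0$Mn_uM > 0
  expect_true(all(prof0$NH4_uM[mn0] > 0))
  expect_true(all(prof0$O2_uM[mn0] == 0))
  for (seed in 1:5) {
    # truncation can zero out a small noisy ammonium reading, but a true
    # zero in the oxygen zone structure is never made positive
    cp <- core_params(paste0("c", seed), noise_sd = 5,
                      depth_grid = seq(0, 300, by = 10))
    prof <- simulate_chemistry(cp, seed = seed)
    expect_true(all(prof$O2_uM[prof$Mn_uM > 0] == 0))
    expect_true(all(prof$NH4_uM[prof$O2_uM > 0] == 0))
  }
})

test_that("community counts close to the library size and respond to redox", {
  cp <- core_params("c1", noise_sd = 0, depth_grid = seq(0, 300, by = 20))
  prof <- simulate_chemistry(cp, seed = 1)
  sim <- simulate_community(prof, guild_specs(n_responsive = 3,
                                              n_background = 30),
                            library_size = 5000, seed = 2)
  expect_true(all(colSums(sim$community$counts) == 5000))
  expect_true(all(sim$community$counts >= 0))
  expect_setequal(rownames(sim$community$counts), sim$truth$taxa$taxon)
  expect_error(simulate_community(prof, guild_specs()[0, ]), "empty guild")
})

test_that("a dominant oxygen responder wins oxic samples without Dirichlet noise", {
  cp <- core_params("c1", noise_sd = 0, depth_grid = c(0, 20, 250, 280))
  prof <- simulate_chemistry(cp, seed = 1)
  guilds <- guild_specs(n_responsive = 1, n_background = 20)
  guilds$beta_O2[guilds$guild == "aerobic_nitrifier"] <- 10
  sim <- simulate_community(prof, guilds, library_size = 1000, seed = 3,
                            dm_concentration = Inf)
  oxic_sample <- sim$community$metadata$sample_id[1] # depth 0
  counts <- sim$community$counts[, oxic_sample]
  expect_equal(names(which.max(counts)), "f_aerobic_nitrifier_01")
})

test_that("anaerobic guild enrichment under ammonium matches the softmax expectation", {
  cp <- core_params("c1", z_ox = 100, z_no3 = 180, noise_sd = 0,
                    depth_grid = seq(0, 280, by = 40))
  prof <- simulate_chemistry(cp, seed = 1)
  guilds <- guild_specs(n_responsive = 2, n_background = 20)
  covars <- redoxtaxa:::redox_covariates(prof$O2_uM, prof$NH4_uM, prof$Mn_uM)
  nh4_pos <- prof$NH4_uM > 0
  # per seeded draw: empirical guild share vs the closed-form softmax
  # expectation evaluated at that draw's own planted coefficients
  set.seed(99)
  rel <- replicate(200, {
    sim <- simulate_community(prof, guilds, library_size = 2000,
                              seed = sample.int(1e6, 1))
    g <- sim$truth$taxa$guild == "anaerobic_heterotroph"
    props <- redoxtaxa:::expected_proportions(sim$truth$taxa, covars)
    m <- sim$community$counts / 2000
    c(emp_nh4 = mean(colSums(m[g, nh4_pos, drop = FALSE])),
      emp_oxic = mean(colSums(m[g, !nh4_pos, drop = FALSE])),
      exp_nh4 = mean(colSums(props[g, nh4_pos, drop = FALSE])),
      exp_oxic = mean(colSums(props[g, !nh4_pos, drop = FALSE])))
  })
  expect_gt(mean(rel["emp_nh4", ]), mean(rel["emp_oxic", ]))
  expect_gt(mean(rel["exp_nh4", ]), mean(rel["exp_oxic", ]))
  expect_lt(abs(mean(rel["emp_nh4", ] - rel["exp_nh4", ])), 0.02)
})

test_that("study design arithmetic, truth coverage, and determinism hold", {
  study <- simulate_study(n_areas = 6, cores_per_area = 2,
                          samples_per_core = 20,
                          guilds = guild_specs(n_responsive = 2,
                                               n_background = 10),
                          seed = 11, library_size = 1000)
  ct <- study$community
  expect_equal(ncol(ct$counts), 240)
  expect_equal(length(unique(ct$metadata$area_id)), 6)
  expect_setequal(rownames(ct$counts), study$truth$taxa$taxon)
  study2 <- simulate_study(n_areas = 6, cores_per_area = 2,
                           samples_per_core = 20,
                           guilds = guild_specs(n_responsive = 2,
                                                n_background = 10),
                           seed = 11, library_size = 1000)
  expect_identical(study$community$counts, study2$community$counts)
  expect_identical(study$profiles, study2$profiles)
})

test_that("guild mean CLR of expected abundances is monotone in its driver", {
  cp <- core_params("c1", z_ox = 100, z_no3 = 180, noise_sd = 0,
                    depth_grid = seq(0, 280, by = 20))
  prof <- simulate_chemistry(cp, seed = 1)
  set.seed(4)
  taxa <- redoxtaxa:::draw_taxa(guild_specs(n_responsive = 3,
                                            n_background = 10))
  covars <- redoxtaxa:::redox_covariates(prof$O2_uM, prof$NH4_uM, prof$Mn_uM)
  props <- redoxtaxa:::expected_proportions(taxa, covars)
  clrp <- clr(t(props))
  mean_clr <- function(guild) rowMeans(clrp[, taxa$guild == guild, drop = FALSE])
  oxic <- prof$O2_uM > 0
  expect_equal(cor(mean_clr("aerobic_nitrifier")[oxic], prof$O2_uM[oxic],
                   method = "spearman"), 1)
  nh4_pos <- prof$NH4_uM > 0
  expect_equal(cor(mean_clr("anaerobic_heterotroph")[nh4_pos],
                   prof$NH4_uM[nh4_pos], method = "spearman"), 1)
})
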