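test_that("presence labels follow the detection limit on raw concentrations", {
  chem <- make_chem(O2 = c(0, 5, 0))
  expect_equal(unname(presence_labels(chem, "O2")), c(FALSE, TRUE, FALSE))
  chem2 <- make_chem(O2 = c(0.5, 5, 0))
  expect_equal(unname(presence_labels(chem2, "O2", detection_limit = 1)),
               c(FALSE, TRUE, FALSE))
  chem3 <- make_chem(O2 = c(1, 5, 3))
  expect_error(presence_labels(chem3, "O2"), "degenerate")
  # unavailable samples are dropped; anoxia-imputed zeros count as absent
  chem4 <- make_chem(O2 = c(0, 5, NA, 2))
  chem4$O2[3] <- 0; chem4$O2_flag[3] <- "imputed_anoxic"
  lab <- presence_labels(chem4, "O2")
  expect_equal(unname(lab), c(FALSE, TRUE, FALSE, TRUE))
})

test_that("rank-sum test matches exact enumeration and handles degeneracy", {
  # extreme arrangement of C(6,3) = 20: one-sided 1/20, two-sided 0.1
  expect_equal(rank_sum_test(c(1, 2, 3, 4, 5, 6),
                             c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)), 0.1)
  expect_equal(rank_sum_test(rep(5, 6), rep(c(TRUE, FALSE), each = 3)), 1)
  expect_error(rank_sum_test(1:3, rep(TRUE, 3)), "non-empty")
})

test_that("large-sample approximation agrees with a permutation oracle", {
  set.seed(8)
  x <- rnorm(30) + 0.7
  y <- rnorm(30)
  vals <- c(x, y); labs <- rep(c(TRUE, FALSE), each = 30)
  p_approx <- rank_sum_test(vals, labs)
  # permutation oracle on the rank-sum statistic
  obs <- sum(rank(vals)[labs])
  perm <- replicate(40000, {
    l <- sample(labs)
    sum(rank(vals)[l])
  })
  p_perm <- mean(abs(perm - mean(perm)) >= abs(obs - mean(perm)))
  expect_lt(abs(p_approx - p_perm), 0.01)
})

test_that("storey q-values reproduce the hand-evaluated step-down example", {
  q <- storey_qvalues(c(0.01, 0.02, 0.9, 0.95), lambda = 0.5)
  expect_equal(q, c(0.04, 0.04, 0.95, 0.95))
  expect_equal(storey_qvalues(rep(1, 5)), rep(1, 5))
  expect_error(storey_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("pi0 is near 1 on uniform p-values and q-values are ordered", {
  set.seed(42)
  p <- runif(1000)
  expect_gte(storey_pi0(p), 0.9)
  expect_lte(storey_pi0(p), 1.0)
  q <- storey_qvalues(p)
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-12))
  # q never below the BH-equivalent scaled by pi0
  bh <- stats::p.adjust(p, method = "BH")
  expect_true(all(q >= storey_pi0(p) * bh - 1e-12))
})

test_that("screening yields one row per constituent and is order invariant", {
  set.seed(12)
  n <- 24
  chem <- make_chem(O2 = c(rep(0, 12), runif(12, 50, 100)),
                    NO3 = c(runif(12, 5, 10), rep(0, 12)),
                    NH4 = c(runif(12, 10, 30), rep(0, 12)),
                    Mn = c(runif(12, 1, 5), rep(0, 12)))
  clrm <- clr(matrix(rexp(n * 6) + 0.5, n, 6,
                     dimnames = list(chem$sample_id, paste0("t", 1:6))))
  scr <- screen_taxa(clrm, chem)
  expect_equal(nrow(scr$table), 6 * 4)
  single <- screen_taxa(clrm[, 1, drop = FALSE], chem)
  expect_equal(nrow(single$table), 4)
  # permute samples and taxa: identical statistics
  perm_s <- sample(n); perm_t <- sample(6)
  chem_p <- chem[perm_s, ]
  scr_p <- screen_taxa(clrm[perm_s, perm_t], chem_p)
  m <- merge(scr$table, scr_p$table, by = c("taxon", "constituent"))
  expect_equal(m$p.x, m$p.y)
  expect_equal(m$q.x, m$q.y)
  expect_identical(scr$candidates, scr_p$candidates)
})

test_that("null communities yield few candidates under FDR control", {
  null_guilds <- guild_specs(n_responsive = 0, n_background = 200)
  n_cand <- vapply(1:20, function(s) {
    study <- simulate_study(n_areas = 2, cores_per_area = 1,
                            samples_per_core = 20, guilds = null_guilds,
                            seed = s, library_size = 2000, area_sd = 0)
    fam <- bin_to_family(study$community)
    chem <- impute_anoxia(interpolate_chemistry(study$profiles,
                                                fam$metadata))
    clrm <- clr(zero_impute_counts(t(fam$counts)))
    rownames(clrm) <- colnames(fam$counts)
    length(screen_taxa(clrm, chem)$candidates)
  }, numeric(1))
  # expected false candidates bounded by m * q * pi0 per constituent
  expect_lte(mean(n_cand), 0.05 * 200)
})
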