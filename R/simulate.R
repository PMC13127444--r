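# Synthetic multi-area sediment-core generator: depth-resolved redox
# zonation (oxic -> nitrate -> ammonium/manganese zones) plus planted
# metabolic guilds whose abundances track redox state, sampled with
# Dirichlet-multinomial count noise. Provides ground truth for
# parameter-recovery testing of the downstream pipeline.

#' Parameters of one simulated sediment core
#'
#' Describes the deterministic redox zonation of a core: oxygen decays from
#' `o2_surface` to zero at the oxygen-depletion depth `z_ox` with a power-law
#' shoulder, nitrate rises from half its peak at the surface to `no3_peak`
#' at `z_ox` and is consumed linearly to zero at `z_no3`, ammonium
#' accumulates linearly below `z_ox`, and divalent manganese below `z_no3`.
#'
#' @param core_id,area_id identifiers.
#' @param z_ox oxygen-depletion depth, cm below seafloor.
#' @param z_no3 nitrate-depletion depth, cm; must exceed `z_ox`.
#' @param o2_surface bottom-water oxygen, uM.
#' @param no3_peak peak nitrate, uM.
#' @param nh4_slope ammonium accumulation below `z_ox`, uM per cm.
#' @param mn_slope manganese accumulation below `z_no3`, uM per cm.
#' @param noise_sd measurement noise sd, uM (applied only where the
#'   deterministic concentration is positive; true zeros are reported as 0,
#'   emulating below-detection readings).
#' @param depth_grid strictly increasing measurement depths, cm.
#' @param o2_shape exponent of the oxygen decay shoulder.
#' @return a `core_params` list.
#' @export
core_params <- function(core_id, area_id = "A1",
                        z_ox = 100, z_no3 = 180,
                        o2_surface = 250, no3_peak = 30,
                        nh4_slope = 0.1, mn_slope = 0.05,
                        noise_sd = 1, depth_grid = seq(0, 300, by = 12),
                        o2_shape = 2) {
  p <- list(core_id = as.character(core_id), area_id = as.character(area_id),
            z_ox = z_ox, z_no3 = z_no3, o2_surface = o2_surface,
            no3_peak = no3_peak, nh4_slope = nh4_slope, mn_slope = mn_slope,
            noise_sd = noise_sd, depth_grid = as.numeric(depth_grid),
            o2_shape = o2_shape)
  class(p) <- "core_params"
  validate_core_params(p)
  p
}

validate_core_params <- function(p) {
  if (any(diff(p$depth_grid) <= 0))
    stop_structural("core ", p$core_id, ": depth_grid must be strictly increasing")
  if (!(p$z_ox < p$z_no3))
    stop_structural("core ", p$core_id, ": z_ox must be smaller than z_no3")
  conc <- c(p$o2_surface, p$no3_peak, p$nh4_slope, p$mn_slope, p$noise_sd)
  if (any(conc < 0))
    stop_structural("core ", p$core_id, ": concentration parameters must be >= 0")
  invisible(p)
}

# Deterministic (noise-free) zonation model evaluated at depths z.
chemistry_model <- function(p, z) {
  o2 <- p$o2_surface * pmax(0, 1 - z / p$z_ox)^p$o2_shape
  no3_surface <- p$no3_peak / 2
  no3 <- ifelse(z <= p$z_ox,
                no3_surface + (p$no3_peak - no3_surface) * z / p$z_ox,
                pmax(0, p$no3_peak * (1 - (z - p$z_ox) / (p$z_no3 - p$z_ox))))
  nh4 <- ifelse(z <= p$z_ox, 0, p$nh4_slope * (z - p$z_ox))
  mn <- ifelse(z <= p$z_no3, 0, p$mn_slope * (z - p$z_no3))
  data.frame(depth_cm = z, O2_uM = o2, NO3_uM = no3, NH4_uM = nh4, Mn_uM = mn)
}

#' Simulate a measured pore-fluid depth profile for one core
#'
#' Evaluates the deterministic zonation model of [core_params()] on the
#' core's depth grid and adds truncated Gaussian measurement noise to every
#' positive concentration; concentrations that are exactly zero in the model
#' stay zero (below-detection reporting), so zonation ordering — manganese
#' only below nitrate depletion, ammonium only below oxygen depletion —
#' holds at any noise level.
#'
#' @param params a [core_params()] object.
#' @param seed integer seed; identical seed and parameters give an
#'   identical profile.
#' @return a `pore_fluid` data frame with columns `core_id`, `depth_cm`,
#'   `O2_uM`, `NO3_uM`, `NH4_uM`, `Mn_uM`.
#' @export
simulate_chemistry <- function(params, seed = 1) {
  validate_core_params(params)
  set.seed(seed)
  prof <- chemistry_model(params, params$depth_grid)
  for (col in c("O2_uM", "NO3_uM", "NH4_uM", "Mn_uM")) {
    mu <- prof[[col]]
    pos <- mu > 0
    mu[pos] <- pmax(0, mu[pos] + rnorm(sum(pos), 0, params$noise_sd))
    prof[[col]] <- mu
  }
  out <- cbind(core_id = params$core_id, prof)
  class(out) <- c("pore_fluid", "data.frame")
  out
}

#' Default metabolic guild specifications
#'
#' Four responsive guilds plus an unresponsive background. Response
#' coefficients are log-linear effects on relative abundance per standard
#' deviation of the redox covariates (oxygen, ammonium, manganese, and an
#' oxic indicator): aerobic nitrifiers track oxygen, facultative anaerobic
#' heterotrophs the oxic zone, anammox the suboxic transition (oxygen-
#' depleted but not yet manganese-rich), and anaerobic heterotrophs the
#' ammonium/manganese zone.
#'
#' @param n_responsive taxa per responsive guild.
#' @param n_background unresponsive background taxa.
#' @return data frame with one row per guild.
#' @export
guild_specs <- function(n_responsive = 5, n_background = 200) {
  data.frame(
    guild = c("aerobic_nitrifier", "facultative_heterotroph", "anammox",
              "anaerobic_heterotroph", "background"),
    n_taxa = c(rep(n_responsive, 4), n_background),
    baseline = c(1, 1, 0.5, 1, 0),
    beta_O2 = c(2.5, 1.0, -2.5, -2.0, 0),
    beta_NH4 = c(0, 0, 1.0, 2.5, 0),
    beta_Mn = c(0, 0, -1.0, 2.0, 0),
    beta_oxic = c(1.0, 2.5, -1.0, -1.0, 0),
    stringsAsFactors = FALSE
  )
}

validate_guilds <- function(guilds) {
  if (NROW(guilds) == 0) stop("empty guild list")
  if (anyDuplicated(guilds$guild)) stop("duplicate guild labels")
  if (any(guilds$n_taxa < 0)) stop("guild n_taxa must be >= 0")
  invisible(guilds)
}

# Draw per-taxon baselines and response coefficients from guild-level
# specs. Nonzero coefficients are scaled by a taxon-specific factor in
# [0.4, 1.6] and baselines shifted by N(0, 0.3): members of a guild share
# the response pattern (sign structure) but differ up to four-fold in
# magnitude, so they are correlated yet individually identifiable — with
# a much narrower spread guild members become statistically redundant and
# no greedy tree ever needs more than one of them. Relies on the caller's
# RNG state.
draw_taxa <- function(guilds) {
  validate_guilds(guilds)
  rows <- lapply(seq_len(nrow(guilds)), function(i) {
    g <- guilds[i, ]
    if (g$n_taxa == 0) return(NULL)
    id <- sprintf("f_%s_%02d", g$guild, seq_len(g$n_taxa))
    jit <- matrix(runif(g$n_taxa * 4, 0.4, 1.6), ncol = 4)
    data.frame(taxon = id, guild = g$guild,
               baseline = g$baseline + rnorm(g$n_taxa, 0, 0.3),
               beta_O2 = g$beta_O2 * jit[, 1],
               beta_NH4 = g$beta_NH4 * jit[, 2],
               beta_Mn = g$beta_Mn * jit[, 3],
               beta_oxic = g$beta_oxic * jit[, 4],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Standardized redox covariates from true (noise-free) chemistry:
# O2, NH4, Mn, plus an oxic (O2 > 0) indicator. Constant columns are
# left at zero.
redox_covariates <- function(o2, nh4, mn) {
  std <- function(x) {
    s <- sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  cbind(O2 = std(o2), NH4 = std(nh4), Mn = std(mn),
        oxic = std(as.numeric(o2 > 0)))
}

# Expected relative abundances: softmax over taxa of
# baseline_t + sum_j beta_{t,j} x_j, per sample.
expected_proportions <- function(taxa, covariates) {
  betas <- as.matrix(taxa[, c("beta_O2", "beta_NH4", "beta_Mn", "beta_oxic")])
  eta <- matrix(taxa$baseline, nrow = nrow(taxa), ncol = nrow(covariates)) +
    betas %*% t(covariates)
  eta <- sweep(eta, 2, apply(eta, 2, max)) # stabilize
  e <- exp(eta)
  sweep(e, 2, colSums(e), "/")
}

# Dirichlet-multinomial counts per sample; concentration parameter
# alpha_i = dm_concentration * p_i. Infinite concentration collapses to a
# plain multinomial. Relies on the caller's RNG state.
draw_counts <- function(props, library_size, dm_concentration) {
  n_taxa <- nrow(props)
  counts <- matrix(0L, nrow = n_taxa, ncol = ncol(props))
  for (s in seq_len(ncol(props))) {
    p <- props[, s]
    if (is.finite(dm_concentration)) {
      w <- rgamma(n_taxa, shape = dm_concentration * p, rate = 1)
      p <- if (sum(w) > 0) w / sum(w) else p
    }
    counts[, s] <- rmultinom(1, size = library_size, prob = p)[, 1]
  }
  counts
}

sim_lineage <- function(taxa) {
  sprintf("d__Bacteria; p__Simulated; c__%s; o__%s; f__%s",
          taxa$guild, taxa$guild, taxa$taxon)
}

#' Simulate a community for the samples of one pore-fluid profile
#'
#' Each profile row is treated as one sample; expected relative abundances
#' follow a log-linear (softmax) response of each planted taxon to the
#' standardized redox covariates, and counts are drawn Dirichlet-
#' multinomial with exact library-size column sums.
#'
#' @param profile a `pore_fluid` data frame (one core).
#' @param guilds guild specification, see [guild_specs()].
#' @param library_size reads per sample.
#' @param seed integer seed.
#' @param dm_concentration Dirichlet concentration parameter; `Inf` for a
#'   plain multinomial.
#' @return list with `community` (a [community_table()]) and `truth`
#'   (per-taxon guild labels and response coefficients).
#' @export
simulate_community <- function(profile, guilds = guild_specs(),
                               library_size = 20000, seed = 1,
                               dm_concentration = 50) {
  validate_guilds(guilds)
  if (library_size <= 0) stop("library_size must be > 0")
  set.seed(seed)
  taxa <- draw_taxa(guilds)
  covars <- redox_covariates(profile$O2_uM, profile$NH4_uM, profile$Mn_uM)
  props <- expected_proportions(taxa, covars)
  counts <- draw_counts(props, library_size, dm_concentration)
  sample_id <- sprintf("%s_s%02d", profile$core_id, seq_len(nrow(profile)))
  dimnames(counts) <- list(taxa$taxon, sample_id)
  meta <- data.frame(sample_id = sample_id,
                     core_id = as.character(profile$core_id),
                     area_id = "A1",
                     depth_cm = profile$depth_cm,
                     stringsAsFactors = FALSE)
  taxonomy <- data.frame(taxon_id = taxa$taxon, lineage = sim_lineage(taxa),
                         stringsAsFactors = FALSE)
  list(community = community_table(counts, taxonomy, meta),
       truth = list(taxa = taxa))
}

#' Simulate a complete multi-area sediment study
#'
#' Generates `n_areas * cores_per_area` cores with zonation parameters
#' drawn from configured ranges, measured pore-fluid profiles on a depth
#' grid, microbial samples at depths interior to that grid (so chemistry
#' must be interpolated downstream, as with real data), area-level random
#' intercepts on taxon baselines, and Dirichlet-multinomial counts. The
#' community responds to the *true* noise-free chemistry at the sampling
#' depths; the returned profiles carry measurement noise.
#'
#' @param n_areas,cores_per_area,samples_per_core design sizes (all >= 1).
#' @param guilds guild specification, see [guild_specs()].
#' @param seed master seed; sub-seeds are derived with [derive_seed()].
#' @param library_size reads per sample.
#' @param dm_concentration Dirichlet concentration parameter.
#' @param area_sd sd of area-level random intercepts on taxon baselines.
#' @param ranges list of uniform sampling ranges for core parameters
#'   (`z_ox`, `z_no3_gap`, `o2_surface`, `no3_peak`, `nh4_slope`,
#'   `mn_slope`, `noise_sd`) plus scalars `z_max` and `n_chem`.
#' @return list with `community` (a [community_table()]), `profiles`
#'   (stacked `pore_fluid` rows for all cores), and `truth` (taxa table,
#'   realized core parameters, true sample-level chemistry).
#' @export
simulate_study <- function(n_areas = 6, cores_per_area = 2,
                           samples_per_core = 20, guilds = guild_specs(),
                           seed = 1, library_size = 20000,
                           dm_concentration = 50, area_sd = 0.3,
                           ranges = list()) {
  stopifnot(n_areas >= 1, cores_per_area >= 1, samples_per_core >= 1)
  validate_guilds(guilds)
  rng <- utils::modifyList(list(
    z_ox = c(60, 140), z_no3_gap = c(40, 100), o2_surface = c(150, 300),
    no3_peak = c(20, 40), nh4_slope = c(0.05, 0.2), mn_slope = c(0.02, 0.1),
    noise_sd = c(0.5, 2), z_max = 300, n_chem = samples_per_core + 6
  ), ranges)

  set.seed(derive_seed(seed, 0))
  taxa <- draw_taxa(guilds)
  n_taxa <- nrow(taxa)

  areas <- sprintf("A%d", seq_len(n_areas))
  set.seed(derive_seed(seed, 1))
  area_int <- matrix(rnorm(n_taxa * n_areas, 0, area_sd), nrow = n_taxa,
                     dimnames = list(taxa$taxon, areas))

  # Core-level zonation parameters.
  set.seed(derive_seed(seed, 2))
  cores <- do.call(rbind, lapply(seq_len(n_areas * cores_per_area), function(i) {
    a <- areas[(i - 1) %/% cores_per_area + 1]
    z_ox <- runif(1, rng$z_ox[1], rng$z_ox[2])
    data.frame(core_id = sprintf("%s_C%d", a, (i - 1) %% cores_per_area + 1),
               area_id = a, z_ox = z_ox,
               z_no3 = z_ox + runif(1, rng$z_no3_gap[1], rng$z_no3_gap[2]),
               o2_surface = runif(1, rng$o2_surface[1], rng$o2_surface[2]),
               no3_peak = runif(1, rng$no3_peak[1], rng$no3_peak[2]),
               nh4_slope = runif(1, rng$nh4_slope[1], rng$nh4_slope[2]),
               mn_slope = runif(1, rng$mn_slope[1], rng$mn_slope[2]),
               noise_sd = runif(1, rng$noise_sd[1], rng$noise_sd[2]),
               stringsAsFactors = FALSE)
  }))

  chem_grid <- seq(0, rng$z_max, length.out = rng$n_chem)
  sample_depths <- seq(0.05 * rng$z_max, 0.95 * rng$z_max,
                       length.out = samples_per_core)

  profiles <- list(); meta <- list(); truth_chem <- list(); counts <- list()
  for (i in seq_len(nrow(cores))) {
    cp <- core_params(cores$core_id[i], cores$area_id[i],
                      z_ox = cores$z_ox[i], z_no3 = cores$z_no3[i],
                      o2_surface = cores$o2_surface[i],
                      no3_peak = cores$no3_peak[i],
                      nh4_slope = cores$nh4_slope[i],
                      mn_slope = cores$mn_slope[i],
                      noise_sd = cores$noise_sd[i], depth_grid = chem_grid)
    profiles[[i]] <- simulate_chemistry(cp, seed = derive_seed(seed, 10 + i))
    true_chem <- chemistry_model(cp, sample_depths)
    truth_chem[[i]] <- cbind(core_id = cp$core_id, true_chem)
    meta[[i]] <- data.frame(
      sample_id = sprintf("%s_s%02d", cp$core_id, seq_len(samples_per_core)),
      core_id = cp$core_id, area_id = cp$area_id,
      depth_cm = sample_depths, stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, meta)
  truth_chem <- do.call(rbind, truth_chem)
  profiles <- do.call(rbind, profiles)
  class(profiles) <- c("pore_fluid", "data.frame")

  # Covariates standardized across the whole study; area intercepts enter
  # the linear predictor per taxon.
  covars <- redox_covariates(truth_chem$O2_uM, truth_chem$NH4_uM,
                             truth_chem$Mn_uM)
  props <- matrix(0, nrow = n_taxa, ncol = nrow(meta))
  for (a in areas) {
    sel <- meta$area_id == a
    ta <- taxa
    ta$baseline <- ta$baseline + area_int[, a]
    props[, sel] <- expected_proportions(ta, covars[sel, , drop = FALSE])
  }
  set.seed(derive_seed(seed, 3))
  cnt <- draw_counts(props, library_size, dm_concentration)
  dimnames(cnt) <- list(taxa$taxon, meta$sample_id)
  taxonomy <- data.frame(taxon_id = taxa$taxon, lineage = sim_lineage(taxa),
                         stringsAsFactors = FALSE)
  list(community = community_table(cnt, taxonomy, meta),
       profiles = profiles,
       truth = list(taxa = taxa, cores = cores,
                    sample_chemistry_true = cbind(sample_id = meta$sample_id,
                                                  truth_chem)))
}

#' Planted taxa with a strong response coefficient
#'
#' @param truth the `truth` element returned by [simulate_study()].
#' @param min_beta threshold on the largest absolute response coefficient.
#' @return character vector of taxon ids.
#' @export
responsive_taxa <- function(truth, min_beta = 2) {
  b <- abs(as.matrix(truth$taxa[, c("beta_O2", "beta_NH4", "beta_Mn",
                                    "beta_oxic")]))
  truth$taxa$taxon[apply(b, 1, max) >= min_beta]
}

#' Write a simulated study to TSV/CSV files
#'
#' Emits the same dialects [read_community()] and [read_pore_fluid()] read,
#' plus `truth.tsv` with the planted guild labels and response coefficients.
#'
#' @param study result of [simulate_study()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_synthetic_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_community(study$community, dir)
  write.table(study$profiles, file.path(dir, "pore_fluid.csv"),
              sep = ",", quote = FALSE, row.names = FALSE)
  write.table(study$truth$taxa[, c("taxon", "guild", "beta_O2", "beta_NH4",
                                   "beta_Mn", "beta_oxic")],
              file.path(dir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
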