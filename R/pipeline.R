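# End-to-end orchestration: simulate/read -> preprocess -> screen ->
# mine -> select -> ordinate, with every stage's table written to a run
# directory and full reproducibility from the config echo.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default: pseudo-values
#' (1 count, 0.001 uM), the anoxia assignment rule (ammonium >= 10 uM plus
#' manganese presence), screening (q < 0.05, Storey lambda 0.5), mining
#' (1,000 iterations of 70/30 Monte-Carlo cross-validation, unlimited
#' depth, 5-sample leaves), and selection (k = 20, max-score aggregation).
#'
#' @param ... overrides of the defaults listed above; see source for the
#'   full field list. `simulate` is a list of arguments forwarded to
#'   [simulate_study()] when no community is supplied to [run_pipeline()].
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- utils::modifyList(list(
    count_pseudo = 1, conc_pseudo = 0.001,
    nh4_threshold = 10, require_mn = TRUE, mn_detection_limit = 0,
    detection_limit = 0,
    q_threshold = 0.05, lambda = 0.5,
    n_iter = 1000, train_frac = 0.70,
    max_depth = Inf, min_samples_leaf = 5, min_gain = 0,
    importance_variant = "peak_coverage",
    perm_B = 0, perm_n_iter = 20,
    k = 20, aggregate = "max", selection_task = "regression",
    min_presence_samples = 1,
    chem_mode = "log_center",
    seed = 1,
    simulate = list()
  ), list(...))
  stopifnot(cfg$train_frac > 0, cfg$train_frac < 1, cfg$n_iter >= 1,
            cfg$k >= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

# Regression target for one constituent: log-centered concentrations by
# default, or the within-sample CLR across the four constituents.
chem_target <- function(chem, constituent, rows, mode, pseudo) {
  if (mode == "composition") {
    conc <- as.matrix(chem[rows, CONSTITUENTS])
    return(chem_transform(conc, "composition", pseudo)[, constituent])
  }
  as.numeric(chem_transform(chem[[constituent]][rows], "log_center", pseudo))
}

#' Run the full widespread-taxa pipeline
#'
#' Executes preprocess (family binning, chemistry interpolation, anoxia
#' assignment), compositional transform, screening, Monte-Carlo tree
#' mining (regressor and classifier per constituent), widespread-taxa
#' selection, and ordination, writing each stage's TSV output plus a
#' `run_metadata.tsv` config echo to `out_dir`. Identical config and seed
#' give identical outputs. When `community` is `NULL`, a synthetic study
#' is generated with [simulate_study()] (arguments from `config$simulate`,
#' seed derived from `config$seed`) and its input tables are written too.
#'
#' @param out_dir run directory (created).
#' @param community a [community_table()], or `NULL` to simulate.
#' @param profiles a `pore_fluid` data frame covering the community's
#'   cores (ignored when simulating).
#' @param config a [pipeline_config()].
#' @return list with every stage's result, invisibly.
#' @export
run_pipeline <- function(out_dir, community = NULL, profiles = NULL,
                         config = pipeline_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- NULL
  if (is.null(community)) {
    sim <- with_stage("simulate", {
      args <- utils::modifyList(list(seed = derive_seed(config$seed, 1)),
                                config$simulate)
      do.call(simulate_study, args)
    })
    community <- sim$community
    profiles <- sim$profiles
    truth <- sim$truth
    write_synthetic_study(sim, file.path(out_dir, "input"))
  }
  if (is.null(profiles))
    stop("stage 'preprocess' failed: pore-fluid profiles are missing",
         call. = FALSE)

  fam <- with_stage("preprocess", bin_to_family(community))
  chem <- with_stage("preprocess", {
    ch <- interpolate_chemistry(profiles, fam$metadata)
    impute_anoxia(ch, config$nh4_threshold, config$require_mn,
                  config$mn_detection_limit)
  })
  write_tsv(chem, file.path(out_dir, "sample_chemistry.tsv"))

  clrm <- with_stage("compositional", {
    m <- clr(zero_impute_counts(t(fam$counts), config$count_pseudo))
    rownames(m) <- colnames(fam$counts)
    m
  })

  scr <- with_stage("screen",
    screen_taxa(clrm, chem, q_threshold = config$q_threshold,
                lambda = config$lambda,
                detection_limit = config$detection_limit))
  write_tsv(scr$table, file.path(out_dir, "screening.tsv"))
  if (length(scr$candidates) == 0)
    stop("stage 'screen' failed: no candidate taxa at q < ",
         config$q_threshold, call. = FALSE)

  mined <- with_stage("mine", {
    cons <- unique(scr$table$constituent)
    res <- list(); summary_rows <- list()
    for (i in seq_along(cons)) {
      con <- cons[i]
      avail <- chem_available(chem, con)
      rows <- which(avail & chem$sample_id %in% rownames(clrm))
      ids <- chem$sample_id[rows]
      X <- clrm[ids, scr$candidates, drop = FALSE]
      y_reg <- chem_target(chem, con, rows, config$chem_mode,
                           config$conc_pseudo)
      y_cls <- presence_labels(chem, con, config$detection_limit)[ids]
      for (task in c("regression", "classification")) {
        y <- if (task == "regression") y_reg else y_cls
        mr <- monte_carlo_importance(
          X, y, task = task, n_iter = config$n_iter,
          train_frac = config$train_frac,
          seed = derive_seed(config$seed,
                             100 + 10 * i + (task == "classification")),
          max_depth = config$max_depth,
          min_samples_leaf = config$min_samples_leaf,
          min_gain = config$min_gain, variant = config$importance_variant)
        perm_p <- NA_real_
        if (config$perm_B >= 1)
          perm_p <- permutation_pvalue(
            X, y, task = task, B = config$perm_B,
            n_iter = config$perm_n_iter, train_frac = config$train_frac,
            seed = derive_seed(config$seed, 300 + 10 * i +
                                 (task == "classification")),
            max_depth = config$max_depth,
            min_samples_leaf = config$min_samples_leaf,
            min_gain = config$min_gain)$p
        res[[paste(con, task, sep = ".")]] <- mr
        summary_rows[[paste(con, task, sep = ".")]] <- data.frame(
          constituent = con, task = task, n_iter = config$n_iter,
          n_samples = length(ids),
          mean_accuracy = mean(mr$accuracy, na.rm = TRUE),
          sd_accuracy = sd(mr$accuracy, na.rm = TRUE),
          permutation_p = perm_p, stringsAsFactors = FALSE)
      }
      write_tsv(res[[paste(con, "regression", sep = ".")]]$importance,
                file.path(out_dir, sprintf("importance_%s.tsv", con)))
      write_tsv(res[[paste(con, "classification", sep = ".")]]$importance,
                file.path(out_dir, sprintf("importance_%s_classifier.tsv", con)))
    }
    list(results = res,
         summary = do.call(rbind, c(summary_rows, make.row.names = FALSE)))
  })
  write_tsv(mined$summary, file.path(out_dir, "mining_summary.tsv"))

  widespread <- with_stage("select", {
    pres <- area_presence(fam, config$min_presence_samples)
    cons <- unique(scr$table$constituent)
    imps <- setNames(lapply(cons, function(con) {
      mined$results[[paste(con, config$selection_task, sep = ".")]]
    }), cons)
    select_widespread(imps, pres, k = config$k, aggregate = config$aggregate)
  })
  write_tsv(as.data.frame(widespread), file.path(out_dir, "widespread.tsv"))

  ordination <- with_stage("ordinate", {
    clr_sub <- clrm[, widespread$taxon, drop = FALSE]
    pca <- coda_pca(clr_sub)
    complete <- Reduce(`&`, lapply(CONSTITUENTS,
                                   function(con) chem_available(chem, con)))
    ids <- chem$sample_id[complete]
    ids <- ids[ids %in% rownames(clr_sub)]
    Z <- vapply(CONSTITUENTS, function(con) {
      scale(log(zero_impute_conc(chem[[con]][match(ids, chem$sample_id)],
                                 config$conc_pseudo)))[, 1]
    }, numeric(length(ids)))
    dbr <- db_rda(aitchison_dist(clr_sub[ids, , drop = FALSE]), Z)
    pca_tab <- data.frame(axis = paste0("PC", seq_along(pca$eigenvalues)),
                          eigenvalue = pca$eigenvalues,
                          proportion = pca$proportions)
    write_tsv(pca_tab, file.path(out_dir, "pca.tsv"))
    dbr_tab <- data.frame(axis = paste0("RDA", seq_along(dbr$eigenvalues)),
                          eigenvalue = dbr$eigenvalues,
                          proportion = dbr$proportions)
    write_tsv(dbr_tab, file.path(out_dir, "dbrda.tsv"))
    list(pca = pca, dbrda = dbr, n_dbrda_samples = length(ids))
  })

  scalar <- !vapply(config, is.list, logical(1))
  meta <- data.frame(
    key = c("package_version", names(config)[scalar]),
    value = c(as.character(utils::packageVersion("redoxtaxa")),
              vapply(config[scalar],
                     function(v) paste(format(v), collapse = ","),
                     character(1))))
  write_tsv(meta, file.path(out_dir, "run_metadata.tsv"))

  invisible(list(community = community, family = fam, profiles = profiles,
                 chemistry = chem, clr = clrm, screening = scr,
                 mining = mined, widespread = widespread,
                 ordination = ordination, truth = truth, config = config))
}
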