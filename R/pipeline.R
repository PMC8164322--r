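#' Read a study configuration file
#'
#' YAML with either a `simulation` block (passed to [simulation_config()];
#' a missing `model` means the default transisthmian model) or an `input`
#' block (`loci`, `samples`, `tree` paths), plus optional `datasets` (names
#' like `"Am4s2"`), `inference` (replicates, subset_size, burn_in,
#' n_iterations, sample_every, variable_rates, bands), `calibration`
#' (calibration_ma, pair, mu_mit), `out_dir` and `seed`.
#'
#' @param path YAML file path.
#' @return a list of class `study_config`.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$simulation) == is.null(cfg$input))
    stop("config needs exactly one of 'simulation' or 'input'")
  cfg$seed <- cfg$seed %||% 1L
  cfg$out_dir <- cfg$out_dir %||% "study_out"
  structure(cfg, class = "study_config")
}

# deterministic stage sub-seed below 2^31
stage_seed <- function(seed, tag) {
  (as.integer(seed) * 1009L + sum(utf8ToInt(tag)) * 131L) %% 2147483629L
}

#' Species tree with divergence-time branch lengths
#'
#' The model's topology with branch lengths in tau units (expected
#' substitutions per site), suitable for patristic distances.
#'
#' @param model a [demographic_model()].
#' @return an `ape` `phylo` with branch lengths.
#' @export
species_time_tree <- function(model) {
  phy <- model$tree
  n <- model$n_species
  depth <- model$tau
  phy$edge.length <- depth[phy$edge[, 1]] - depth[phy$edge[, 2]]
  phy
}

# expand a species-level distance matrix to sample level
sample_distance_matrix <- function(species_d, samples) {
  d <- species_d[samples$species_id, samples$species_id, drop = FALSE]
  dimnames(d) <- list(samples$sample_id, samples$sample_id)
  d
}

#' Run the full study pipeline
#'
#' simulate (or load) -> paralog + m/s filter grid -> locus-sharing bias
#' diagnostics -> replicate IM-coalescent inference on random locus subsets
#' of the primary (first) dataset -> calibration. Every stage draws its
#' randomness from a sub-seed derived from the global seed and the stage
#' tag, so stages are individually reproducible and the whole run is
#' byte-deterministic under (config, seed).
#'
#' @param cfg a `study_config` (or path to one).
#' @param quiet suppress progress messages.
#' @return invisibly, a list of artifacts (datasets, bias diagnostics,
#'   traces, summaries, calibrated table, paths); also written under
#'   `cfg$out_dir`.
#' @export
run_study <- function(cfg, quiet = FALSE) {
  if (is.character(cfg)) cfg <- read_study_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cfg$out_dir, "run.log")
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    cat(msg, "\n", file = logf, append = TRUE)
    if (!quiet) message(msg)
  }
  say("study start, seed ", cfg$seed)

  # ---- stage: data ----
  truth <- NULL
  if (!is.null(cfg$simulation)) {
    sc <- cfg$simulation
    model <- transisthmian_model()
    simcfg <- simulation_config(
      model = model,
      n_individuals = sc$n_individuals %||% 4,
      n_loci = sc$n_loci %||% 1000,
      locus_length = sc$locus_length %||% 90,
      rate_alpha = sc$rate_alpha %||% 1,
      site_length = sc$site_length %||% 6,
      dropout = sc$dropout %||% TRUE,
      seed = stage_seed(cfg$seed, "simulate"))
    sim <- simulate_dataset(simcfg)
    ls <- sim$locus_set
    truth <- sim$truth
    write_loci(ls, file.path(cfg$out_dir, "data.loci"))
    utils::write.table(ls$samples, file.path(cfg$out_dir, "samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ape::write.tree(species_time_tree(model),
                    file.path(cfg$out_dir, "species.nwk"))
  } else {
    ls <- read_loci(cfg$input$loci, samples = cfg$input$samples)
    model <- NULL
  }
  say("data: ", n_loci(ls), " loci, ", nrow(ls$samples), " samples")

  # ---- stage: filter grid ----
  names_grid <- unlist(cfg$datasets %||% list("Am4s2"))
  base <- apply_paralog_filters(ls)
  datasets <- list()
  for (nm in names_grid) {
    datasets[[nm]] <- apply_ms_filter(base, nm)
    say("dataset ", nm, ": ", n_loci(datasets[[nm]]), " loci")
  }
  primary <- datasets[[1]]

  # ---- stage: bias diagnostics ----
  bias <- NULL
  if (!is.null(model)) {
    lpa <- build_lpa(primary, exclude = unlist(cfg$exclude %||% list()))
    shared <- shared_locus_summary(lpa)
    jd <- jaccard_distances(lpa)
    ord <- nmds(jd, K = min(3, nrow(jd) - 1), n_restarts = 20,
                seed = stage_seed(cfg$seed, "nmds"))
    spd <- patristic_distances(species_time_tree(model))
    smp <- primary$samples[primary$samples$sample_id %in% rownames(lpa), ]
    fits <- fit_shared_locus_models(
      shared, stats::setNames(smp$reads_passing_filter, smp$sample_id),
      sample_distance_matrix(spd, smp))
    write_matrix(shared$counts, file.path(cfg$out_dir, "shared_counts.tsv"))
    write_matrix(jd, file.path(cfg$out_dir, "jaccard.tsv"))
    write_matrix(ord$coordinates, file.path(cfg$out_dir, "nmds.tsv"))
    bias <- list(shared = shared, jaccard = jd, nmds = ord, models = fits)
    say("bias: NMDS stress ", format(ord$stress, digits = 3),
        ", model B r2 ", format(fits$fitB$r2, digits = 3))
  }

  # ---- stage: inference on the primary dataset ----
  inf <- cfg$inference %||% list()
  n_rep <- inf$replicates %||% 3
  neutral <- partition_neutral(primary,
                               unlist(cfg$coding_ids %||% list()))$neutral
  subset_size <- min(inf$subset_size %||% n_loci(neutral), n_loci(neutral))
  subsets <- random_subsets(neutral, n_rep, subset_size,
                            seed = stage_seed(cfg$seed, "subsets"))
  bands <- if (!is.null(inf$bands))
    do.call(rbind, lapply(inf$bands, as.data.frame)) else NULL
  settings <- mcmc_settings(
    burn_in = inf$burn_in %||% 500,
    n_iterations = inf$n_iterations %||% 2000,
    sample_every = inf$sample_every %||% 10,
    finetune_window = inf$finetune_window %||% 400,
    variable_rates = inf$variable_rates %||% FALSE,
    seed = stage_seed(cfg$seed, "mcmc"))
  tree_nwk <- if (!is.null(model)) ape::write.tree(model$tree)
              else cfg$input$tree
  traces <- lapply(seq_len(n_rep), function(r) {
    s <- settings
    s$seed <- (settings$seed + (r - 1L) * 997L) %% 2147483629L
    tr <- run_mcmc(subsets[[r]], tree_nwk, bands = bands, settings = s)
    tr$replicate <- r
    write_trace(tr, file.path(cfg$out_dir, sprintf("run%d.trace", r)))
    say("replicate ", r, " done")
    tr
  })

  # ---- stage: calibration ----
  cal <- cfg$calibration %||% list()
  summ <- summarize_replicates(traces)
  ccfg <- calibration_config(
    calibration_time_years = (cal$calibration_ma %||% 3) * 1e6,
    calibrated_pair = cal$pair %||% "EC",
    mu_mit = cal$mu_mit)
  pair_labels <- cal$pairs %||% list(WM = "WM", EC = "EC", PF = "PF")
  est <- tryCatch(
    calibrated_estimates(summ, unlist(pair_labels), ccfg),
    error = function(e) { say("calibration skipped: ", conditionMessage(e)); NULL })
  if (!is.null(est))
    utils::write.table(est, file.path(cfg$out_dir, "calibrated.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  say("study done")
  invisible(list(datasets = datasets, truth = truth, bias = bias,
                 traces = traces, summary = summ, calibrated = est,
                 out_dir = cfg$out_dir))
}

#' Align parameter estimates across datasets
#'
#' Long-format table of per-parameter means and credible intervals per
#' dataset, flagging parameters whose CIs fail to overlap between any two
#' datasets (the filter-sensitivity diagnostic).
#'
#' @param summaries named list of [summarize_replicates()] data frames, one
#'   per dataset.
#' @return data frame: `dataset`, `parameter`, `mean`, `lo`, `hi`,
#'   `nonoverlap` (logical).
#' @export
compare_datasets <- function(summaries) {
  if (length(summaries) < 2) stop("need at least two dataset summaries")
  long <- do.call(rbind, lapply(names(summaries), function(nm) {
    df <- summaries[[nm]]
    df$dataset <- nm
    df
  }))
  long$nonoverlap <- FALSE
  for (p in unique(long$parameter)) {
    rows <- which(long$parameter == p)
    for (i in rows) for (j in rows) {
      if (i == j) next
      if (long$hi[i] < long$lo[j] || long$hi[j] < long$lo[i])
        long$nonoverlap[i] <- TRUE
    }
  }
  long[, c("dataset", "parameter", "mean", "lo", "hi", "nonoverlap")]
}
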