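# End-to-end orchestration from a YAML run configuration.
#
# Subcommand-level entry points (run_simulate / run_rates / run_satest) are
# plain functions over a validated RunConfig list; the installed CLI script
# (inst/cli/karyevol.R) is a thin optparse wrapper around them.

#' Read and validate a run configuration
#'
#' YAML with (relevant subsets of): `trees`, `karyotypes` (paths), `out_dir`,
#' `model` ("basic" or "scs"), `groups` (optional path to a tip,family CSV),
#' `exclude_tips` (optional character vector), `mcmc` (`generations`,
#' `burn_in`, `prior_rate`), `mapping` (`maps_per_sample`), `sa_null`
#' (`formulation`, `include_neo`), `hpd_mass`, `k_pad`, `seed`, and for
#' simulation a `simulate` block mirroring [sim_config()] fields.
#'
#' @param path YAML file.
#' @return Validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  stopifnot(file.exists(path))
  cfg <- yaml::read_yaml(path)
  defaults <- list(model = "scs", hpd_mass = 0.95, k_pad = 10, seed = 1,
                   mcmc = list(), mapping = list(), sa_null = list())
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  mcmc_def <- list(generations = 100, burn_in = 0.5, prior_rate = 2)
  for (nm in names(mcmc_def)) {
    if (is.null(cfg$mcmc[[nm]])) cfg$mcmc[[nm]] <- mcmc_def[[nm]]
  }
  if (is.null(cfg$mapping$maps_per_sample)) cfg$mapping$maps_per_sample <- 1
  if (is.null(cfg$sa_null$formulation)) cfg$sa_null$formulation <- "haploid"
  if (is.null(cfg$sa_null$include_neo)) cfg$sa_null$include_neo <- FALSE
  if (!cfg$model %in% c("basic", "scs")) {
    stop("config: model must be 'basic' or 'scs'", call. = FALSE)
  }
  if (cfg$mcmc$burn_in < 0 || cfg$mcmc$burn_in >= 1) {
    stop("config: mcmc.burn_in must be in [0, 1)", call. = FALSE)
  }
  for (p in c("trees", "karyotypes", "groups")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      stop("config: path for '", p, "' does not exist: ", cfg[[p]],
           call. = FALSE)
    }
  }
  class(cfg) <- "run_config"
  cfg
}

# Small deterministic config fingerprint for provenance lines (FNV-1a over
# the serialized config; no cryptographic intent).
config_hash <- function(cfg) {
  bytes <- utf8ToInt(paste(deparse(unclass(cfg)), collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

load_inputs <- function(cfg) {
  trees <- read_trees(cfg$trees)
  records <- read_karyotype_table(cfg$karyotypes)
  if (!is.null(cfg$exclude_tips) && length(cfg$exclude_tips) > 0) {
    drop <- normalize_species(cfg$exclude_tips)
    records <- records[!records$species %in% drop, , drop = FALSE]
    log_stage("input", "excluded ", length(drop), " tip(s) by config")
  }
  list(trees = trees, records = records)
}

# Bounds from the data: k_min = 1 (fusions can in principle run low),
# k_max = observed max + padding to limit boundary truncation.
space_from_records <- function(records, model, k_pad = 10) {
  build_state_space(1L, max(records$haploid_autosomes) + as.integer(k_pad),
                    scs = identical(model, "scs"))
}

group_records <- function(records, cfg) {
  if (is.null(cfg$groups)) return(list(all = records))
  fam <- read.csv(cfg$groups, stringsAsFactors = FALSE)
  names(fam) <- tolower(names(fam))
  stopifnot(all(c("species", "family") %in% names(fam)))
  fam$species <- normalize_species(fam$species)
  out <- list(all = records)
  for (f in unique(fam$family)) {
    sp <- fam$species[fam$family == f]
    out[[f]] <- records[records$species %in% sp, , drop = FALSE]
  }
  out
}

#' Estimate rates of karyotype evolution
#'
#' Runs the multi-tree pooled MCMC for the whole dataset and (if a
#' tip-to-family table is configured) per family, skipping groups with
#' fewer than 3 matched tips. Rates are summarized in both unit systems:
#' per tree unit (10^8 yr) and per million years (rate / 100).
#'
#' @param cfg A `run_config` (or path to one).
#' @param seed Optional override of the config seed.
#' @return List per group: pooled chain, per-parameter summary (mean and
#'   HPD in both unit systems), plus pairwise `verdicts` across groups.
#'   Written to `out_dir` as CSV + JSON when configured.
#' @export
run_rates <- function(cfg, seed = NULL) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  inputs <- load_inputs(cfg)
  groups <- group_records(inputs$records, cfg)
  log_stage("rates", "config hash ", config_hash(cfg), ", seed ", cfg$seed,
            ", model ", cfg$model)

  chains <- list()
  for (gr in names(groups)) {
    recs <- groups[[gr]]
    n_sp <- length(unique(recs$species))
    if (n_sp < 3) {
      warning("group ", gr, " has ", n_sp, " species (<3): skipped")
      next
    }
    space <- space_from_records(recs, cfg$model, cfg$k_pad)
    datasets <- match_tips(inputs$trees, recs)
    log_stage("rates", "group ", gr, ": ", length(datasets), " tree(s), ",
              length(datasets[[1]]$tree$tip.label), " tip(s), ",
              space$size, " states")
    chains[[gr]] <- multi_tree_posterior(
      datasets, space, n_generations = cfg$mcmc$generations,
      burn_in = cfg$mcmc$burn_in, prior_rate = cfg$mcmc$prior_rate,
      seed = cfg$seed)
  }
  if (length(chains) == 0) stop("no group had >= 3 species", call. = FALSE)

  summaries <- lapply(names(chains), function(gr) {
    ch <- chains[[gr]]
    pars <- attr(ch, "params")
    do.call(rbind, lapply(pars, function(p) {
      h <- hpd_interval(ch[[p]], cfg$hpd_mass)
      data.frame(group = gr, parameter = p,
                 mean_per_unit = h$mean, lower_per_unit = h$lower,
                 upper_per_unit = h$upper,
                 mean_per_my = h$mean / 100, lower_per_my = h$lower / 100,
                 upper_per_my = h$upper / 100, stringsAsFactors = FALSE)
    }))
  })
  summary_df <- do.call(rbind, summaries)
  verdicts <- if (length(chains) >= 2) compare_rates(chains, cfg$hpd_mass)$verdicts
              else NULL
  out <- list(chains = chains, summary = summary_df, verdicts = verdicts,
              seed = cfg$seed, config_hash = config_hash(cfg))
  if (!is.null(cfg$out_dir)) write_rates_output(out, cfg)
  out
}

write_rates_output <- function(out, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (gr in names(out$chains)) {
    write.csv(out$chains[[gr]],
              file.path(cfg$out_dir, paste0("posterior_", gr, ".csv")),
              row.names = FALSE)
  }
  jsonlite::write_json(
    list(seed = out$seed, config_hash = out$config_hash,
         summary = out$summary, verdicts = out$verdicts),
    file.path(cfg$out_dir, "rates_summary.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  yaml::write_yaml(unclass(cfg), file.path(cfg$out_dir, "config_used.yaml"))
  log_stage("rates", "outputs written to ", cfg$out_dir)
}

#' Test for SA-fusion excess across the tree sample
#'
#' Requires the SCS model. Per tree: resolves tip records, fits the chain,
#' draws `maps_per_sample` stochastic maps per retained posterior sample
#' (so event-count uncertainty integrates parameter uncertainty), tallies
#' events, and runs the HPD-overlap test; also pools all maps across trees
#' for an overall verdict.
#'
#' @param cfg A `run_config` (or path); `model` must be `"scs"`.
#' @param seed Optional override of the config seed.
#' @return List: `per_tree` (list of `sa_fusion_result`), `tally`
#'   ([per_tree_tally()] output), `pooled` (overall `sa_fusion_result`),
#'   `seed`, `config_hash`.
#' @export
run_satest <- function(cfg, seed = NULL) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (cfg$model != "scs") {
    stop("run_satest requires the SCS model variant", call. = FALSE)
  }
  inputs <- load_inputs(cfg)
  if (!"neoXY" %in% inputs$records$scs && !"XY" %in% inputs$records$scs) {
    stop("karyotype table has no usable sex chromosome systems",
         call. = FALSE)
  }
  space <- space_from_records(inputs$records, "scs", cfg$k_pad)
  datasets <- match_tips(inputs$trees, inputs$records)
  log_stage("satest", "config hash ", config_hash(cfg), ", seed ",
            cfg$seed, ", ", length(datasets), " tree(s)")

  n_gen <- cfg$mcmc$generations
  keep <- ceiling((1 - cfg$mcmc$burn_in) * n_gen)
  per_tree <- vector("list", length(datasets))
  all_tallies <- list()
  for (i in seq_along(datasets)) {
    ds <- datasets[[i]]
    seed_i <- split_seed(cfg$seed, i)
    states <- resolve_tip_states(ds, seed = seed_i)
    chain <- mcmc_run(states, ds$tree, space, n_gen,
                      prior_rate = cfg$mcmc$prior_rate, seed = seed_i)
    retained <- chain[seq.int(n_gen - keep + 1L, n_gen), , drop = FALSE]
    tallies <- list()
    for (j in seq_len(nrow(retained))) {
      Q <- build_rate_matrix(
        as.list(retained[j, c("fission", "fusion", "sa_fusion",
                              "reversion")]), space)
      maps <- sample_history(states, ds$tree, Q,
                             n_maps = cfg$mapping$maps_per_sample,
                             seed = split_seed(seed_i, j))
      tallies <- c(tallies, lapply(maps, tally_events))
    }
    per_tree[[i]] <- sa_fusion_test(
      tallies, mass = cfg$hpd_mass, formulation = cfg$sa_null$formulation,
      include_neo = cfg$sa_null$include_neo)
    all_tallies <- c(all_tallies, tallies)
    log_stage("satest", "tree ", i, ": ", per_tree[[i]]$verdict)
  }
  tally <- per_tree_tally(per_tree)
  pooled <- sa_fusion_test(all_tallies, mass = cfg$hpd_mass,
                           formulation = cfg$sa_null$formulation,
                           include_neo = cfg$sa_null$include_neo)
  out <- list(per_tree = per_tree, tally = tally, pooled = pooled,
              seed = cfg$seed, config_hash = config_hash(cfg))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(seed = out$seed, config_hash = out$config_hash,
           observed_mean = pooled$observed_hpd$mean,
           observed_hpd = c(pooled$observed_hpd$lower,
                            pooled$observed_hpd$upper),
           null_mean = pooled$null_hpd$mean,
           null_hpd = c(pooled$null_hpd$lower, pooled$null_hpd$upper),
           verdict = pooled$verdict,
           n_trees_excess = tally$n_excess,
           n_trees_total = tally$n_trees),
      file.path(cfg$out_dir, "satest_summary.json"),
      auto_unbox = TRUE, digits = NA)
    write.csv(tally$table, file.path(cfg$out_dir, "satest_per_tree.csv"),
              row.names = FALSE)
    log_stage("satest", "outputs written to ", cfg$out_dir)
  }
  out
}

#' Generate a synthetic dataset from a config
#'
#' @param cfg A `run_config` (or path) with a `simulate` block; fields
#'   mirror [sim_config()] arguments. Files go to `out_dir`.
#' @param seed Optional override of the config seed.
#' @return [make_dataset()] result.
#' @export
run_simulate <- function(cfg, seed = NULL) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  sim <- cfg$simulate
  if (is.null(sim)) stop("config has no 'simulate' block", call. = FALSE)
  p <- sim$params
  sc <- sim_config(
    n_tips = sim$n_tips %||% 200, n_trees = sim$n_trees %||% 1,
    birth = sim$birth %||% 3, death = sim$death %||% 0.5,
    depth = sim$depth %||% 1.84,
    params = rate_params(p$fission %||% 0.3, p$fusion %||% 0.7,
                         p$sa_fusion %||% 0.6, p$reversion %||% 0.2),
    root_k = sim$root_k %||% 9, root_system = sim$root_system %||% "XY",
    k_min = sim$k_min %||% 1, k_max = sim$k_max %||% 25,
    multi_record_fraction = sim$multi_record_fraction %||% 0.175,
    jitter_sd = sim$jitter_sd %||% 0.1, seed = cfg$seed)
  log_stage("simulate", "config hash ", config_hash(cfg), ", seed ",
            cfg$seed, ", ", sc$n_tips, " tips x ", sc$n_trees, " tree(s)")
  make_dataset(sc, dir = cfg$out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
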