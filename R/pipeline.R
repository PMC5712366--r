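# Pipeline module: counts -> RPM -> expressed filter -> periodicity ->
# co-expression + ensemble directed network, driven by one validated
# config, with deterministic seeding and a manifest of outputs.

#' Pipeline configuration
#'
#' Builds and validates the configuration for [run_pipeline()] /
#' [simulate_dataset()].  Defaults mirror the study design this package
#' models: min RPM 1, alpha 0.01, 30 permutations, 1000 surrogates,
#' co-expression cutoffs 0.7 and 0.8, ARX orders 1-3, ensemble size 30,
#' confidence threshold 20, hub threshold 50 children, a 20 h light /
#' 4 h dark cycle sampled every 4 h over two days in three replicates.
#'
#' @param counts_path,metadata_path input TSVs (see [read_counts_tsv()]);
#'   may be `NULL` when the config is only used for simulation.
#' @param library_size_column read library sizes from the metadata column
#'   (`TRUE`) or recompute as column sums (`FALSE`).
#' @param min_rpm expressed-gene threshold.
#' @param log2_transform apply `log2(x + 1)` to RPM before analysis.
#' @param omega0,n_surrogates,alpha,n_perm periodicity-screen settings.
#' @param gcn_cutoffs Pearson correlation cutoffs (one network per value).
#' @param orders ARX orders to run (subset of 1:3).
#' @param M ensemble size.
#' @param confidence_threshold strict edge-calling threshold (in (0, M]).
#' @param hub_min_children hub out-degree threshold.
#' @param dark_window `c(start, end)` dark hours of day.
#' @param nlambda,lambda_min_ratio lambda-path settings.
#' @param seed base seed for every stochastic stage.
#' @param simulate named list of generator settings (see
#'   [simulate_dataset()]); missing entries take defaults.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts_path = NULL, metadata_path = NULL,
                            library_size_column = TRUE,
                            min_rpm = 1, log2_transform = FALSE,
                            omega0 = 6, n_surrogates = 1000, alpha = 0.01,
                            n_perm = 30, gcn_cutoffs = c(0.7, 0.8),
                            orders = c(1, 2, 3), M = 30,
                            confidence_threshold = 20,
                            hub_min_children = 50, dark_window = c(22, 2),
                            nlambda = 30, lambda_min_ratio = 0.01,
                            seed = 1L, simulate = list()) {
  sim_defaults <- list(
    n_periodic = 100, n_nonperiodic = 170, n_arx = 30,
    arx_parents = 6, arx_children_per_parent = 3, arx_order = 1,
    arx_coef_magnitude = c(0.4, 0.8), arx_innovation_sd = 0.1,
    arx_baseline = 10, arx_scale = 2,
    amplitude_range = c(4, 12), baseline_range = c(5, 20), noise_sd = 0.5,
    ar_coefficient = 0.3, library_size = 2e7,
    hours_of_day = c(2, 6, 10, 14, 18, 22), n_days = 2, n_reps = 3
  )
  unknown <- setdiff(names(simulate), names(sim_defaults))
  if (length(unknown) > 0) stopf("unknown simulate setting: %s", unknown[1])
  sim <- utils::modifyList(sim_defaults, simulate)
  cfg <- list(counts_path = counts_path, metadata_path = metadata_path,
              library_size_column = isTRUE(library_size_column),
              min_rpm = min_rpm, log2_transform = isTRUE(log2_transform),
              omega0 = omega0, n_surrogates = n_surrogates, alpha = alpha,
              n_perm = n_perm, gcn_cutoffs = gcn_cutoffs, orders = orders,
              M = M, confidence_threshold = confidence_threshold,
              hub_min_children = hub_min_children,
              dark_window = dark_window, nlambda = nlambda,
              lambda_min_ratio = lambda_min_ratio, seed = as.integer(seed),
              simulate = sim)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stopf("alpha must be in (0, 1)")
  if (!all(cfg$orders %in% 1:3)) stopf("orders must be a subset of {1, 2, 3}")
  if (cfg$min_rpm < 0) stopf("min_rpm must be non-negative")
  if (any(cfg$gcn_cutoffs <= 0 | cfg$gcn_cutoffs > 1)) {
    stopf("gcn_cutoffs must lie in (0, 1]")
  }
  if (cfg$confidence_threshold <= 0 || cfg$confidence_threshold > cfg$M) {
    stopf("confidence_threshold must be in (0, M]")
  }
  if (cfg$n_surrogates < 300) stopf("n_surrogates must be >= 300")
  for (p in c("counts_path", "metadata_path")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      stopf("%s does not exist: %s", p, cfg[[p]])
    }
  }
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) stopf("unknown config key: %s", unknown[1])
  do.call(pipeline_config, vals)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(sprintf("  screen: alpha = %g, %d permutations, %d surrogates\n",
              x$alpha, x$n_perm, x$n_surrogates))
  cat(sprintf("  networks: PCC cutoffs %s; ARX orders %s, M = %d, threshold %d\n",
              paste(x$gcn_cutoffs, collapse = "/"),
              paste(x$orders, collapse = ","), x$M, x$confidence_threshold))
  invisible(x)
}

#' Simulate a full synthetic study and write its files
#'
#' Generates a count dataset with the three gene classes the analysis
#' assumes — 24 h sinusoids, AR(1) background, and a sparse ARX system —
#' on the configured sampling grid, plus ground-truth files.  ARX latent
#' series are mapped to the expression scale as
#' `baseline + scale * value` and clipped at zero only for count
#' generation.  Seeds are derived from `config$seed` (offsets 1-4), so
#' the output is a pure function of the config.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return list with file paths (`counts`, `metadata`,
#'   `truth_phases_path`, `truth_network_path`) and in-memory `tensor`,
#'   `truth_phases` (data.frame), `truth_network` (list with
#'   `adjacency`, `coefficients`, `order`), `gene_classes`.
#' @export
simulate_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  s <- config$simulate
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- design_grid(s$hours_of_day, s$n_days, s$n_reps)
  per <- generate_periodic_tensor(s$n_periodic, grid,
                                  amplitude_range = s$amplitude_range,
                                  baseline_range = s$baseline_range,
                                  noise_sd = s$noise_sd,
                                  seed = config$seed + 1L)
  bkg <- generate_nonperiodic_tensor(s$n_nonperiodic, grid,
                                     ar_coefficient = s$ar_coefficient,
                                     noise_sd = s$noise_sd,
                                     baseline = s$arx_baseline,
                                     seed = config$seed + 2L)
  arx <- generate_arx_tensor(s$n_arx, s$arx_parents,
                             s$arx_children_per_parent,
                             order = s$arx_order,
                             coef_magnitude = s$arx_coef_magnitude,
                             innovation_sd = s$arx_innovation_sd,
                             grid_or_length = grid,
                             obs_noise_sd = s$noise_sd,
                             seed = config$seed + 3L)
  arx_vals <- s$arx_baseline + s$arx_scale * arx$tensor$values
  vals <- abind3(per$tensor$values, bkg$values, arx_vals)
  vals <- pmax(vals, 0)  # clip for count generation only
  tensor <- expr_tensor(vals, grid)
  counts <- generate_counts(tensor, library_sizes = s$library_size,
                            seed = config$seed + 4L)
  paths <- list(counts = file.path(out_dir, "counts.tsv"),
                metadata = file.path(out_dir, "metadata.tsv"),
                truth_phases_path = file.path(out_dir, "truth_phases.tsv"),
                truth_network_path = file.path(out_dir, "truth_network.tsv"))
  write_counts_tsv(counts, paths$counts, paths$metadata)
  utils::write.table(per$truth, paths$truth_phases_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tn <- which(arx$truth$adjacency == 1, arr.ind = TRUE)
  ids <- rownames(arx$truth$adjacency)
  truth_net <- data.frame(source = ids[tn[, 1]], target = ids[tn[, 2]],
                          stringsAsFactors = FALSE)
  if (nrow(truth_net) > 0) {
    truth_net$lag <- vapply(seq_len(nrow(truth_net)), function(k) {
      which(arx$truth$coefficients[tn[k, 1], tn[k, 2], ] != 0)[1]
    }, integer(1))
    truth_net$coefficient <- vapply(seq_len(nrow(truth_net)), function(k) {
      arx$truth$coefficients[tn[k, 1], tn[k, 2], truth_net$lag[k]]
    }, numeric(1))
    truth_net <- truth_net[order(truth_net$source, truth_net$target), ]
  }
  utils::write.table(truth_net, paths$truth_network_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gene_classes <- data.frame(
    gene_id = rownames(vals),
    class = rep(c("periodic", "background", "arx"),
                c(s$n_periodic, s$n_nonperiodic, s$n_arx)),
    stringsAsFactors = FALSE
  )
  c(paths, list(tensor = tensor, truth_phases = per$truth,
                truth_network = arx$truth, gene_classes = gene_classes))
}

# bind 3-d arrays along the gene dimension
abind3 <- function(...) {
  parts <- list(...)
  d23 <- dim(parts[[1]])[2:3]
  out <- array(NA_real_, dim = c(sum(vapply(parts, function(x) dim(x)[1],
                                            integer(1))), d23))
  rn <- character(0)
  at <- 0L
  for (x in parts) {
    out[at + seq_len(dim(x)[1]), , ] <- x
    rn <- c(rn, rownames(x))
    at <- at + dim(x)[1]
  }
  rownames(out) <- rn
  out
}

#' Run the full analysis pipeline
#'
#' Counts -> RPM -> expressed filter -> consensus periodicity screen ->
#' co-expression networks over the periodic genes (one per cutoff) ->
#' replicate-resampled ensemble directed networks (one per ARX order) ->
#' summary + manifest.  Every stage writes its outputs under `out_dir`;
#' a stage failure halts the run naming the stage, leaving earlier
#' outputs in place.  Gene exclusions (unexpressed, constant) are listed
#' in the manifest with reasons; the run is a pure function of
#' (inputs, config), so a rerun reproduces identical files.
#'
#' @param config a [pipeline_config()] (or path to a YAML config).
#' @param out_dir output directory.
#' @param counts optional in-memory [count_matrix()] overriding
#'   `config$counts_path`.
#' @return (invisibly) list with the stage results: `tensor`,
#'   `expressed`, `periodicity`, `gcn` (per cutoff), `grn` (per order),
#'   `summary`, `manifest_path`.
#' @export
run_pipeline <- function(config, out_dir, counts = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  exclusions <- data.frame(gene_id = character(0), reason = character(0),
                           stringsAsFactors = FALSE)
  stage <- function(name, expr) {
    message(sprintf("[%s] %s ...", format(Sys.time(), "%H:%M:%S"), name))
    tryCatch(expr, error = function(e) {
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  counts <- stage("read_counts", {
    if (is.null(counts)) {
      if (is.null(config$counts_path)) stopf("no counts given")
      read_counts_tsv(config$counts_path, config$metadata_path,
                      config$library_size_column)
    } else counts
  })
  tensor <- stage("rpm", compute_rpm(counts))

  expressed <- stage("filter_expressed", {
    keep <- filter_expressed(tensor, config$min_rpm)
    dropped <- setdiff(rownames(tensor$values), keep)
    if (length(dropped) > 0) {
      exclusions <- rbind(exclusions,
                           data.frame(gene_id = dropped,
                                      reason = "below min_rpm in every timepoint",
                                      stringsAsFactors = FALSE))
    }
    keep
  })
  tensor_e <- subset_genes(tensor, expressed)
  if (config$log2_transform) tensor_e$values <- log2(tensor_e$values + 1)

  periodicity <- stage("periodicity", {
    res <- consensus_periodicity(tensor_e, n_perm = config$n_perm,
                                 alpha = config$alpha,
                                 n_surrogates = config$n_surrogates,
                                 seed = config$seed,
                                 omega0 = config$omega0)
    path <- file.path(out_dir, "periodicity.tsv")
    utils::write.table(res, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outputs <- c(outputs, path)
    res
  })
  periodic_ids <- periodicity$gene_id[periodicity$is_periodic]

  gcn <- list()
  dark_fraction <- NA_real_
  if (length(periodic_ids) >= 2) {
    gcn <- stage("gcn", {
      tensor_p <- subset_genes(tensor_e, periodic_ids)
      zs <- suppressWarnings(zscore_genes(replicate_mean(tensor_p)))
      if (length(attr(zs, "excluded")) > 0) {
        exclusions <- rbind(exclusions,
                             data.frame(gene_id = attr(zs, "excluded"),
                                        reason = "constant replicate-mean series",
                                        stringsAsFactors = FALSE))
      }
      r <- pcc_matrix(zs)
      out <- list()
      for (cutoff in config$gcn_cutoffs) {
        net <- build_gcn(r, cutoff = cutoff)
        path <- file.path(out_dir, sprintf("gcn_edges_pcc%0.2f.tsv", cutoff))
        write_gcn_tsv(net, path)
        outputs <- c(outputs, path)
        out[[sprintf("%0.2f", cutoff)]] <- net
      }
      out
    })
    dark_fraction <- stage("peak_bins",
                           peak_time_bins(periodicity, config$dark_window))
  }

  grn <- list()
  if (length(periodic_ids) >= 2) {
    grn <- stage("grn_ensemble", {
      tensor_p <- subset_genes(tensor_e, periodic_ids)
      out <- list()
      for (p in config$orders) {
        nets <- ensemble_infer(tensor_p, p = p, M = config$M,
                               base_seed = config$seed + 1000L * p,
                               nlambda = config$nlambda,
                               lambda_min_ratio = config$lambda_min_ratio)
        B <- confidence_matrix(nets)
        called <- call_edges(B, threshold = config$confidence_threshold)
        pt <- stats::setNames(periodicity$peak_time, periodicity$gene_id)
        summ <- network_summary(called, peak_times = pt,
                                hub_min_children = config$hub_min_children)
        cpath <- file.path(out_dir, sprintf("grn_confidence_arx%d.tsv", p))
        epath <- file.path(out_dir, sprintf("grn_edges_arx%d.tsv", p))
        write_confidence_tsv(B, cpath)
        write_network_tsv(called, epath)
        outputs <- c(outputs, cpath, epath)
        out[[sprintf("arx%d", p)]] <- list(confidence = B, network = called,
                                           summary = summ)
      }
      out
    })
  }

  summary <- stage("summary", {
    sm <- list(
      n_genes = nrow(counts$counts),
      n_expressed = length(expressed),
      n_periodic = length(periodic_ids),
      dark_peak_fraction = dark_fraction,
      gcn = lapply(gcn, function(net) {
        st <- gcn_stats(net)
        list(cutoff = net$cutoff, n_nodes = st$n_nodes, n_edges = st$n_edges)
      }),
      grn = lapply(grn, function(g) {
        g$summary[c("n_edges", "n_parents", "n_children", "n_genes")]
      })
    )
    path <- file.path(out_dir, "summary.json")
    jsonlite::write_json(sm, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    outputs <- c(outputs, path)
    sm
  })

  manifest_path <- stage("manifest", {
    cfg_plain <- unclass(config)
    cfg_plain$simulate <- NULL
    manifest <- list(
      package = as.character(utils::packageVersion("dielnet")),
      parameters = cfg_plain,
      seed = config$seed,
      outputs = lapply(stats::setNames(outputs, basename(outputs)),
                       function(f) unname(tools::md5sum(f))),
      exclusions = exclusions
    )
    path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    path
  })

  invisible(list(tensor = tensor, expressed = expressed,
                 periodicity = periodicity, gcn = gcn,
                 dark_fraction = dark_fraction, grn = grn,
                 summary = summary, manifest_path = manifest_path))
}
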