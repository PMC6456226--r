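#' Default run configuration
#'
#' Configuration is a plain named list (serializable to JSON); every
#' source of randomness derives from the single master `seed` via fixed
#' per-stage offsets, so a run is reproducible from config + seed alone.
#'
#' @param seed master seed.
#' @param out_dir output directory.
#' @param stages character subset of
#'   `c("wiring", "laminar", "core", "efficiency")`.
#' @param n_perm permutations for the two-sample tests.
#' @param n_rep out-of-sample repetitions for the laminar stage.
#' @param n_null surrogate networks for core significance.
#' @param n_shuffles label shuffles for the laminar permutation null.
#' @param edge_rule clique projection rule.
#' @param svr_C SVR regularization constant.
#' @param synthetic `NULL`, or a list of [synthetic_spec()] arguments
#'   used to simulate the input cortex (species_b optionally a second
#'   list for the cross-species stage).
#' @param inputs `NULL`, or list of file paths
#'   (`adjacency`, `areas`, `laminar`, optionally `adjacency_b`,
#'   `areas_b`) for real data.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1, out_dir = tempfile("corticonn_run_"),
                       stages = c("wiring", "laminar", "core", "efficiency"),
                       n_perm = 1000, n_rep = 200, n_null = 200,
                       n_shuffles = 100,
                       edge_rule = c("mutual", "any"), svr_C = 1,
                       synthetic = list(), inputs = NULL) {
  stopifnot(n_perm > 0, n_rep > 0, n_null > 0, n_shuffles > 0)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 stages = match.arg(stages, several.ok = TRUE),
                 n_perm = n_perm, n_rep = n_rep, n_null = n_null,
                 n_shuffles = n_shuffles,
                 edge_rule = match.arg(edge_rule), svr_C = svr_C,
                 synthetic = synthetic, inputs = inputs),
            class = "run_config")
}

load_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, cfg)
}

pipeline_inputs <- function(config) {
  if (!is.null(config$inputs)) {
    inp <- config$inputs
    conn <- load_connectome(inp$adjacency, inp$areas,
                            species = inp$species %||% "species_a")
    conn_b <- if (!is.null(inp$adjacency_b))
      load_connectome(inp$adjacency_b, inp$areas_b,
                      species = inp$species_b %||% "species_b")
    laminar <- if (!is.null(inp$laminar))
      laminar_table(read.csv(inp$laminar, stringsAsFactors = FALSE),
                    conn$areas)
    list(connectome = conn, connectome_b = conn_b, laminar = laminar)
  } else {
    args <- config$synthetic
    args_b <- args$species_b
    args$species_b <- NULL
    spec <- do.call(synthetic_spec,
                    utils::modifyList(list(seed = config$seed), args))
    cx <- generate_cortex(spec)
    conn_b <- NULL
    if (!is.null(args_b)) {
      spec_b <- do.call(synthetic_spec,
                        utils::modifyList(list(seed = config$seed + 1000L),
                                          args_b))
      cx_b <- generate_cortex(spec_b)
      conn_b <- cx_b$connectome
      conn_b$species <- "synthetic_b"
    }
    list(connectome = cx$connectome, connectome_b = conn_b,
         laminar = cx$laminar, truth = cx$truth)
  }
}

test_summary <- function(t)
  list(statistic = t$statistic, p_value = t$p_value, n_perm = t$n_perm)

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order (wiring, laminar, core,
#' efficiency) on real or simulated inputs, writing a JSON summary, CSV
#' tables and a log (package version + seeds) to the output directory.
#' Identical configs produce identical outputs.
#'
#' @param config a [run_config()] or path to a JSON file of its fields.
#' @return list of stage results, invisibly; written artifacts under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  inp <- pipeline_inputs(config)
  results <- list(config = unclass(config))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  if ("wiring" %in% config$stages) {
    results$wiring <- stage("wiring", {
      pairs <- build_pair_table(inp$connectome)
      write.csv(pairs, file.path(config$out_dir, "pair_table.csv"),
                row.names = FALSE)
      out <- list(
        present_vs_absent_c01 = test_summary(
          compare_present_absent(pairs, "c01", n_perm = config$n_perm,
                                 seed = config$seed + 10L)),
        present_vs_absent_d01 = test_summary(
          compare_present_absent(pairs, "d01", n_perm = config$n_perm,
                                 seed = config$seed + 11L)),
        fit = {
          f <- fit_logistic(pairs)
          list(coefficients = as.list(f$coefficients),
               standard_error = as.list(f$standard_error),
               wald_p = as.list(f$wald_p),
               log_likelihood = f$log_likelihood, n_obs = f$n_obs,
               converged = f$converged)
        })
      if (!is.null(inp$connectome_b)) {
        pairs_b <- build_pair_table(inp$connectome_b)
        si <- fit_species_interaction(pairs, pairs_b)
        out$species_interaction <- list(
          coefficients = as.list(si$fit$coefficients),
          lr = si$lr, species_levels = si$species_levels)
      }
      out
    })
  }

  if ("laminar" %in% config$stages) {
    results$laminar <- stage("laminar", {
      if (is.null(inp$laminar))
        stop("laminar stage requested but no laminar data available")
      ev_c <- evaluate_out_of_sample(inp$laminar, "cyto_diff",
                                     n_rep = config$n_rep,
                                     svr_C = config$svr_C,
                                     seed = config$seed + 20L)
      ev_r <- evaluate_out_of_sample(inp$laminar, "rc_diff",
                                     n_rep = config$n_rep,
                                     svr_C = config$svr_C,
                                     seed = config$seed + 20L)
      write.csv(data.frame(rep = seq_along(ev_c$rho_per_rep),
                           rho_cyto = ev_c$rho_per_rep),
                file.path(config$out_dir, "laminar_rho.csv"),
                row.names = FALSE)
      null_rho <- permutation_null(inp$laminar, "cyto_diff",
                                   n_shuffles = config$n_shuffles,
                                   seed = config$seed + 21L)
      cmp <- compare_predictor_sets(ev_c, ev_r, n_perm = config$n_perm,
                                    seed = config$seed + 22L)
      list(median_rho_cyto = median(ev_c$rho_per_rep),
           median_rho_rc = median(ev_r$rho_per_rep),
           null_rho_mean = mean(null_rho),
           null_rho_q95 = unname(quantile(null_rho, 0.95)),
           cyto_vs_rc = test_summary(cmp),
           partial_rho_cyto_given_rc = partial_spearman(
             inp$laminar$nsg, inp$laminar$cyto_diff, inp$laminar$rc_diff),
           partial_rho_rc_given_cyto = partial_spearman(
             inp$laminar$nsg, inp$laminar$rc_diff, inp$laminar$cyto_diff))
    })
  }

  core_part <- NULL
  if ("core" %in% config$stages || "efficiency" %in% config$stages) {
    conn_ec <- stage("core", edge_complete_subgraph(inp$connectome))
  }
  if ("core" %in% config$stages) {
    results$core <- stage("core", {
      core_part <- detect_core(conn_ec, edge_rule = config$edge_rule,
                                n_null = config$n_null,
                                seed = config$seed + 30L)
      member <- data.frame(area = c(core_part$core, core_part$periphery))
      for (k in seq_along(core_part$cliques))
        member[[paste0("C", k)]] <-
          as.integer(member$area %in% core_part$cliques[[k]])
      write.csv(member, file.path(config$out_dir, "core_membership.csv"),
                row.names = FALSE)
      write.csv(data.frame(max_clique_size = core_part$null_max_sizes),
                file.path(config$out_dir, "null_clique_sizes.csv"),
                row.names = FALSE)
      cyto <- setNames(conn_ec$areas$cyto, conn_ec$areas$id)
      list(max_clique_size = core_part$max_clique_size,
           n_cliques = length(core_part$cliques),
           core = core_part$core, p_value = core_part$p_value,
           cyto_contrast = test_summary(compare_core_periphery_attribute(
             core_part, cyto, test = "energy", n_perm = config$n_perm,
             seed = config$seed + 31L)))
    })
  }

  if ("efficiency" %in% config$stages) {
    results$efficiency <- stage("efficiency", {
      prof <- efficiency_profile(conn_ec)
      write.csv(prof$per_area,
                file.path(config$out_dir, "efficiency_per_area.csv"),
                row.names = FALSE)
      if (is.null(core_part))
        stop("efficiency comparison requires the core stage")
      tests <- compare_core_periphery_efficiency(
        core_part, prof, n_perm = config$n_perm,
        seed = config$seed + 40L)
      lapply(tests, function(t) c(test_summary(t),
                                  list(median_core = t$median_core,
                                       median_periphery = t$median_periphery)))
    })
  }

  results$log <- list(package_version = as.character(
    utils::packageVersion("corticonn")), seed = config$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(results[setdiff(names(results), "config")],
                       file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(results)
}

#' Command-line entry point
#'
#' Minimal subcommand interface:
#' `simulate` (spec JSON in, connectome/areas/laminar CSVs + truth JSON
#' out), `run-all` / `wiring` / `laminar` / `core` / `efficiency`
#' (config JSON in, stage outputs under `--out`).  Flags: `--config
#' PATH`, `--seed INT`, `--n-perm INT`, `--edge-rule mutual|any`,
#' `--out DIR`.
#'
#' @param args character vector, default the command line.
#' @return exit status 0 invisibly.
#' @export
corticonn_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L)
    stop("usage: corticonn <simulate|run-all|wiring|laminar|core|efficiency> [--config PATH] [--seed INT] [--n-perm INT] [--edge-rule RULE] [--out DIR]")
  cmd <- args[1]
  opts <- list()
  rest <- args[-1]
  while (length(rest)) {
    if (!startsWith(rest[1], "--") || length(rest) < 2)
      stop("malformed option: ", rest[1])
    opts[[sub("^--", "", rest[1])]] <- rest[2]
    rest <- rest[-(1:2)]
  }
  out_dir <- opts$out %||% "corticonn_out"
  seed <- as.integer(opts$seed %||% 1)

  if (cmd == "simulate") {
    spec_args <- if (!is.null(opts$config))
      jsonlite::read_json(opts$config, simplifyVector = TRUE) else list()
    spec <- do.call(synthetic_spec,
                    utils::modifyList(list(seed = seed), spec_args))
    cx <- generate_cortex(spec)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_connectome(cx$connectome,
                     file.path(out_dir, "adjacency.csv"),
                     file.path(out_dir, "areas.csv"),
                     file.path(out_dir, "distance.csv"))
    write.csv(cx$laminar, file.path(out_dir, "laminar.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(spec = unclass(spec), planted_core = cx$truth$planted_core),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
    return(invisible(0L))
  }

  stages <- switch(cmd,
    "run-all" = c("wiring", "laminar", "core", "efficiency"),
    "wiring" = "wiring", "laminar" = "laminar",
    "core" = "core", "efficiency" = c("core", "efficiency"),
    stop("unknown subcommand: ", cmd))
  base <- if (!is.null(opts$config))
    jsonlite::read_json(opts$config, simplifyVector = TRUE) else list()
  base$seed <- seed
  base$out_dir <- out_dir
  base$stages <- stages
  if (!is.null(opts$`n-perm`)) base$n_perm <- as.integer(opts$`n-perm`)
  if (!is.null(opts$`edge-rule`)) base$edge_rule <- opts$`edge-rule`
  run_pipeline(do.call(run_config, base))
  invisible(0L)
}
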