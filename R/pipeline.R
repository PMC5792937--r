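PIPELINE_DEFAULTS <- list(
  min_localities = 4, cor_threshold = 0.7, reg_multiplier = 1,
  max_iterations = 500, null_replicates = 100, n_knots = 50,
  seed = 1, exclude_nonsignificant = TRUE, run_mantel = FALSE,
  mantel_permutations = 999, feature_mode = "auto")

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a list. Fills defaults and returns either a
#' typed config (class `pipeline_config`) or the *exhaustive* list of
#' violations (class `config_errors`) — validation does not stop at the
#' first failure. Inputs may be given as paths (`env_paths`, `occurrences`,
#' `pool`, `tree`, `partition`) or as in-memory objects (an [env_stack()],
#' a data frame, a `phylo`).
#'
#' @param config list or YAML path.
#' @return `pipeline_config` or `config_errors` (character vector of
#'   violations).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      return(structure("config file does not exist", class = "config_errors"))
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config))
    return(structure("config must be a list or a YAML file path",
                     class = "config_errors"))
  errors <- character()
  for (nm in names(PIPELINE_DEFAULTS))
    if (is.null(config[[nm]])) config[[nm]] <- PIPELINE_DEFAULTS[[nm]]

  need_input <- function(key, type_ok, what) {
    v <- config[[key]]
    if (is.null(v)) {
      errors <<- c(errors, sprintf("missing required input '%s'", key))
    } else if (is.character(v)) {
      bad <- v[!file.exists(v)]
      if (length(bad))
        errors <<- c(errors, sprintf("'%s' path does not exist: %s", key,
                                     paste(bad, collapse = ", ")))
    } else if (!type_ok(v)) {
      errors <<- c(errors, sprintf("'%s' must be a path or %s", key, what))
    }
  }
  if (is.null(config$env) && is.null(config$env_paths))
    errors <- c(errors, "missing required input 'env' (env_stack) or 'env_paths'")
  if (!is.null(config$env) && !inherits(config$env, "env_stack"))
    errors <- c(errors, "'env' must be an env_stack")
  if (!is.null(config$env_paths)) {
    bad <- config$env_paths[!file.exists(config$env_paths)]
    if (length(bad)) errors <- c(errors, paste("'env_paths' missing:",
                                               paste(bad, collapse = ", ")))
  }
  need_input("occurrences", is.data.frame, "a data frame")
  need_input("pool", function(v) is.data.frame(v) ||
               inherits(v, "background_pool"), "a data frame or background_pool")
  need_input("tree", function(v) inherits(v, "phylo"), "a phylo object")
  if (!is.null(config$partition) && !is.character(config$partition) &&
      is.null(names(config$partition)))
    errors <- c(errors, "'partition' must be a path or a named species->clade vector")

  range_check <- function(key, lo, hi = Inf) {
    v <- config[[key]]
    if (!is.numeric(v) || length(v) != 1 || v < lo || v > hi)
      errors <<- c(errors, sprintf("'%s' out of range [%g, %g]: %s",
                                   key, lo, hi, paste(v, collapse = ",")))
  }
  range_check("min_localities", 1)
  range_check("cor_threshold", 0, 1)
  range_check("reg_multiplier", 0)
  range_check("max_iterations", 1)
  range_check("null_replicates", 1)
  range_check("seed", -2^31, 2^31)

  if (length(errors)) return(structure(errors, class = "config_errors"))
  structure(config, class = "pipeline_config")
}

load_pipeline_inputs <- function(config) {
  env <- config$env %||% read_env_stack(config$env_paths,
                                        kinds = config$env_kinds %||% "continuous")
  occ <- if (is.data.frame(config$occurrences)) config$occurrences
         else read_occurrences(config$occurrences)
  pool <- config$pool
  if (is.character(pool)) pool <- read_occurrences(pool, require_species = FALSE)
  tree <- if (inherits(config$tree, "phylo")) config$tree
          else read_tree(config$tree)
  partition <- config$partition
  if (is.character(partition) && length(partition) == 1 && file.exists(partition)) {
    ptab <- utils::read.csv(partition, stringsAsFactors = FALSE)
    partition <- stats::setNames(ptab$clade, ptab$species)
  }
  list(env = env, occurrences = occ, pool = pool, tree = tree,
       partition = partition)
}

#' Run the full niche-conservatism pipeline
#'
#' Ingest -> deduplicate/filter -> prune correlated variables -> per-species
#' maxent SDM + target-group null test -> (optionally) drop species whose
#' SDM is not significantly different from random -> pairwise Hellinger's I
#' -> clade overlap summary -> patristic distances -> overlap-vs-distance
#' conservatism test. Record counts are logged after every filtering stage;
#' the full configuration and seed are echoed in the report. Deterministic
#' given (inputs, seed).
#'
#' @param config a [validate_config()] input (list or YAML path).
#' @param quiet suppress stage logging.
#' @return object of class `run_report`: `species_table` (per-species n,
#'   AUC, threshold, significance), `overlap`, `clade_summary`,
#'   `conservatism`, `variable_log`, `maps`, `config`, `elapsed`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  t0 <- Sys.time()
  cfg <- validate_config(config)
  if (inherits(cfg, "config_errors"))
    stop("[config] invalid configuration:\n  - ",
         paste(cfg, collapse = "\n  - "))
  say <- function(...) if (!quiet) pn_log(...)
  inp <- tryCatch(load_pipeline_inputs(cfg),
                  error = function(e) stop("[ingest] ", conditionMessage(e)))
  env <- inp$env
  say("ingest: %d layer(s), %d occurrence record(s), %d pool record(s)",
      length(env$layers), nrow(inp$occurrences),
      if (inherits(inp$pool, "background_pool")) length(inp$pool$cells)
      else nrow(inp$pool))

  occ <- assign_cells(inp$occurrences, env, quiet = quiet)
  occ <- deduplicate(occ, quiet = quiet)
  flt <- filter_min_localities(occ, cfg$min_localities, quiet = quiet)
  if (!length(flt$retained))
    stop("[filter] no species retained: every species has fewer than ",
         cfg$min_localities, " unique localities")
  occ <- flt$occurrences

  sel <- select_variables(env, cfg$cor_threshold)
  env <- sel$stack
  say("select_variables: %d layer(s) retained, %d removed",
      length(env$layers), nrow(sel$log))

  pool <- if (inherits(inp$pool, "background_pool")) inp$pool
          else background_pool(inp$pool, env, provenance = "pipeline pool input")

  species <- sort(unique(occ$species))
  seeds <- as.integer((as.numeric(cfg$seed) * 13 +
                         seq_along(species) * 97003) %% 2147483647)
  rows <- list(); maps <- list()
  for (i in seq_along(species)) {
    sp <- species[i]
    cells <- occ$cell[occ$species == sp]
    feats <- build_features(env, n_presences = length(cells),
                            mode = cfg$feature_mode, n_knots = cfg$n_knots,
                            extra_cells = cells, seed = seeds[i])
    fit <- fit_species_sdm(feats, cells,
                           reg_multiplier = cfg$reg_multiplier,
                           max_iterations = cfg$max_iterations)
    reps <- null_auc_distribution(pool, n = length(cells),
                                  R = cfg$null_replicates, features = feats,
                                  seed = seeds[i],
                                  reg_multiplier = cfg$reg_multiplier,
                                  max_iterations = cfg$max_iterations)
    nt <- null_model_test(fit$auc, reps, seed = seeds[i])
    rows[[i]] <- data.frame(species = sp, n_localities = length(cells),
                            auc = fit$auc, threshold = nt$threshold,
                            significant = nt$significant,
                            converged = fit$model$converged,
                            stringsAsFactors = FALSE)
    maps[[sp]] <- fit$map
    say("sdm: %s (n = %d) AUC %.3f vs threshold %.3f -> %s", sp,
        length(cells), fit$auc, nt$threshold,
        if (nt$significant) "significant" else "NOT significant")
  }
  species_table <- do.call(rbind, rows)

  keep <- if (isTRUE(cfg$exclude_nonsignificant))
    species_table$species[species_table$significant] else species_table$species
  excluded <- setdiff(species_table$species, keep)
  if (length(excluded))
    say("null test: excluding %d species from overlap/conservatism: %s",
        length(excluded), paste(excluded, collapse = ", "))
  if (length(keep) < 2)
    stop("[overlap] fewer than two species left after the null-model filter")

  overlap <- pairwise_overlap(maps[keep])
  clade_summary <- if (!is.null(inp$partition))
    clade_overlap_summary(overlap, inp$partition) else NULL
  dist <- patristic_matrix(inp$tree)
  conservatism <- conservatism_test(overlap, dist,
                                    run_mantel = isTRUE(cfg$run_mantel),
                                    n_perm = cfg$mantel_permutations,
                                    seed = cfg$seed)
  say("conservatism: %d pairs, r = %.4f, R^2 = %.4f, p = %.4g",
      conservatism$n_pairs, conservatism$r, conservatism$r2, conservatism$p)

  report <- structure(
    list(species_table = species_table, excluded_species = excluded,
         overlap = overlap, clade_summary = clade_summary,
         conservatism = conservatism, variable_log = sel$log,
         maps = maps[keep], config = cfg,
         elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "run_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report: %d species modelled, %d excluded by the null test (%.1f s)\n",
              nrow(x$species_table), length(x$excluded_species), x$elapsed))
  print(x$species_table)
  print(x$conservatism)
  invisible(x)
}

#' Write a run report's tables to a directory
#'
#' @param report a [run_pipeline()] report.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$species_table,
                   file.path(dir, "species_table.csv"), row.names = FALSE)
  utils::write.csv(report$overlap, file.path(dir, "overlap_matrix.csv"))
  if (!is.null(report$clade_summary))
    utils::write.csv(report$clade_summary,
                     file.path(dir, "clade_summary.csv"), row.names = FALSE)
  utils::write.csv(report$variable_log,
                   file.path(dir, "variable_removals.csv"), row.names = FALSE)
  cons <- report$conservatism
  utils::write.csv(data.frame(n_pairs = cons$n_pairs, r = cons$r,
                              r2 = cons$r2, p = cons$p,
                              mantel_p = cons$mantel_p %||% NA),
                   file.path(dir, "conservatism.csv"), row.names = FALSE)
  cfg <- unclass(report$config)
  cfg <- cfg[vapply(cfg, function(v) is.atomic(v) && !is.matrix(v), TRUE)]
  yaml::write_yaml(cfg, file.path(dir, "config_echo.yml"))
  invisible(dir)
}
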