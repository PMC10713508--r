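#' Configuration for a full analysis run
#'
#' Collects every stage's settings in one validated, serialisable list. A
#' run is fully reproducible from `(config, master seed)`: the master seed
#' deterministically spawns one sub-seed per stage (simulation, bootstrap,
#' stability, comparison, layout), so re-running any stage in isolation
#' matches the full run.
#'
#' @param input Path to a respondents CSV, or `NULL` to simulate both
#'   packaged presets from a ground-truth network.
#' @param method Correlation method.
#' @param gamma,n_lambdas,lambda_min_ratio Estimation settings.
#' @param bootstrap_B Bootstrap samples for edge accuracy (default 500).
#' @param stability_B Subsamples per drop level (default 50).
#' @param drop_proportions Case-dropping grid.
#' @param n_perm Comparison-test permutations.
#' @param truth_density,truth_p Synthetic ground-truth settings (simulation
#'   input only).
#' @param seed Master seed.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL,
                            method = c("polychoric", "spearman", "pearson"),
                            gamma = 0.5, n_lambdas = 100,
                            lambda_min_ratio = 0.01,
                            bootstrap_B = 500, stability_B = 50,
                            drop_proportions = seq(0.05, 0.75, by = 0.05),
                            n_perm = 1000, truth_p = 25,
                            truth_density = 0.19, seed = 1) {
  method <- match.arg(method)
  if (gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  stopifnot(n_lambdas >= 2, lambda_min_ratio > 0, lambda_min_ratio < 1,
            bootstrap_B >= 1, stability_B >= 1, n_perm >= 1,
            truth_p >= 2, truth_density >= 0, truth_density <= 1)
  structure(list(input = input, method = method, gamma = gamma,
                 n_lambdas = n_lambdas,
                 lambda_min_ratio = lambda_min_ratio,
                 bootstrap_B = bootstrap_B, stability_B = stability_B,
                 drop_proportions = drop_proportions, n_perm = n_perm,
                 truth_p = truth_p, truth_density = truth_density,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# deterministic per-stage seeds from the master seed (kept below 2^31)
.stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, bootstrap = 211L, stability = 307L,
               comparison = 401L, layout = 503L)
  as.integer((as.double(seed) * 7919 + offsets[[stage]]) %% 2147483587)
}

#' Run the full analysis pipeline
#'
#' Scores the cohort, splits it at the median total score, and for each
#' status group runs the whole network workflow: association matrix,
#' regularised network with EBIC selection, summary, centrality,
#' predictability, bootstrap edge accuracy, case-dropping stability and
#' ordinal MDS embedding; the two group networks are then compared by
#' permutation. Every artefact is written under `output_dir` (tables as
#' CSV, structured results as JSON, networks additionally as GraphML) and
#' listed, with MD5 checksums, in `manifest.json`. A stage failure aborts
#' with a stage-tagged error; artefacts already written stay on disk and
#' the manifest is marked incomplete.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Output directory (created if needed).
#' @param quiet Suppress per-stage progress messages.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, output_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(config), artefacts = list(),
                   complete = FALSE)
  say <- function(...) if (!quiet) message("[shsnet] ", sprintf(...))
  put <- function(name, path) {
    manifest$artefacts[[name]] <<- list(
      path = basename(path), md5 = unname(tools::md5sum(path)))
  }
  finish <- function() {
    mpath <- file.path(output_dir, "manifest.json")
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(manifest)
  }
  stage <- function(name, expr) {
    say("stage: %s", name)
    tryCatch(expr, error = function(e) {
      finish()
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  m <- stage("input", {
    if (is.null(config$input)) {
      truth <- shs_truth(p = config$truth_p, density = config$truth_density,
                         seed = .stage_seed(config$seed, "simulate"))
      opt <- generate_cohort(truth, cohort_preset("optimal_like"),
                             seed = .stage_seed(config$seed, "simulate") + 1L)
      sub <- generate_cohort(truth, cohort_preset("suboptimal_like"),
                             seed = .stage_seed(config$seed, "simulate") + 2L)
      both <- likert_matrix(rbind(opt$ratings, sub$ratings),
                            covariates = rbind(opt$covariates,
                                               sub$covariates))
      path <- file.path(output_dir, "cohort.csv")
      write_likert_csv(both, path); put("cohort", path)
      both
    } else {
      read_likert_csv(config$input)
    }
  })

  split <- stage("score", {
    sc <- median_split(shs_scores(m))
    path <- file.path(output_dir, "scores.csv")
    utils::write.csv(sc, path, row.names = FALSE); put("scores", path)
    sc
  })

  groups <- list(
    optimal = m$ratings[split$status == "optimal", , drop = FALSE],
    suboptimal = m$ratings[split$status == "suboptimal", , drop = FALSE])
  nets <- list()
  for (g in names(groups)) {
    X <- groups[[g]]
    net <- stage(paste0("estimate_", g), {
      net <- shs_network(X, method = config$method, gamma = config$gamma,
                         n_lambdas = config$n_lambdas,
                         lambda_min_ratio = config$lambda_min_ratio)
      for (fmt in c("tsv", "graphml")) {
        path <- file.path(output_dir, paste0("network_", g, ".", fmt))
        write_network(net, path, format = fmt)
        put(paste0("network_", g, "_", fmt), path)
      }
      net
    })
    nets[[g]] <- net
    stage(paste0("metrics_", g), {
      cent <- centrality_indices(net)
      path <- file.path(output_dir, paste0("centrality_", g, ".csv"))
      utils::write.csv(cent, path, row.names = FALSE)
      put(paste0("centrality_", g), path)
      pred <- node_predictability(net)
      path <- file.path(output_dir, paste0("predictability_", g, ".csv"))
      utils::write.csv(pred, path, row.names = FALSE)
      put(paste0("predictability_", g), path)
    })
    stage(paste0("accuracy_", g), {
      boot <- bootstrap_edges(X, B = config$bootstrap_B,
                              seed = .stage_seed(config$seed, "bootstrap"),
                              method = config$method, gamma = config$gamma,
                              n_lambdas = config$n_lambdas)
      path <- file.path(output_dir, paste0("edge_cis_", g, ".csv"))
      utils::write.csv(boot$cis, path, row.names = FALSE)
      put(paste0("edge_cis_", g), path)
    })
    stage(paste0("stability_", g), {
      stab <- case_drop_stability(
        X, proportions = config$drop_proportions,
        B_per_level = config$stability_B,
        seed = .stage_seed(config$seed, "stability"),
        method = config$method, gamma = config$gamma,
        n_lambdas = config$n_lambdas)
      path <- file.path(output_dir, paste0("drop_curves_", g, ".csv"))
      utils::write.csv(stab$curves, path, row.names = FALSE)
      put(paste0("drop_curves_", g), path)
      cs <- cs_coefficient(stab)
      path <- file.path(output_dir, paste0("cs_", g, ".json"))
      jsonlite::write_json(as.list(cs), path, auto_unbox = TRUE,
                           digits = NA)
      put(paste0("cs_", g), path)
    })
    stage(paste0("embed_", g), {
      R <- correlation_matrix(X, method = config$method)
      mds <- ordinal_mds(corr_to_dissimilarity(R))
      path <- file.path(output_dir, paste0("mds_", g, ".csv"))
      utils::write.csv(data.frame(node = rownames(mds$points),
                                  x = mds$points[, 1], y = mds$points[, 2],
                                  stress = mds$stress),
                       path, row.names = FALSE)
      put(paste0("mds_", g), path)
    })
  }

  stage("compare", {
    nct <- network_comparison_test(
      groups$optimal, groups$suboptimal, n_perm = config$n_perm,
      seed = .stage_seed(config$seed, "comparison"),
      method = config$method, gamma = config$gamma,
      n_lambdas = config$n_lambdas)
    path <- file.path(output_dir, "comparison.json")
    jsonlite::write_json(
      list(global_strength = as.list(nct$global_strength),
           observed = as.list(nct$observed),
           p_values = as.list(nct$p_values),
           adjacency_correlation = nct$adjacency_correlation,
           n_perm = nct$n_perm),
      path, auto_unbox = TRUE, digits = NA)
    put("comparison", path)
  })

  manifest$complete <- TRUE
  say("done: %d artefacts", length(manifest$artefacts))
  finish()
}
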