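#' Build a pipeline configuration
#'
#' Collects the input paths (or a simulation scenario), every threshold of
#' the analysis, and the master seed into a validated config list.  The
#' config is serialized verbatim into the run record, so a results
#' directory always documents how it was produced.
#'
#' @param table,taxonomy,tree,metadata Input file paths (TSV / newick), or
#'   `NULL` when `scenario` is given.
#' @param scenario `NULL`, or one of `"enterotype_mixture"`, `"neutral"`,
#'   `"selected"` to generate inputs with the bundled simulators.
#' @param scenario_args Named list forwarded to the simulator.
#' @param min_total Low-count ASV filter threshold (pooled reads).
#' @param min_mean_rel Network abundance filter (mean relative abundance).
#' @param rho_threshold,fdr_alpha Network edge criteria.
#' @param k_min,k_max Enterotype cluster-count scan range.
#' @param n_rand Null-model randomizations (betaNTI, Raup-Crick).
#' @param n_perm Permutations (ANOSIM, Mantel).
#' @param filter_before_rarefy Apply the low-count filter before
#'   rarefaction (the canonical order); `FALSE` swaps the two steps.
#' @param seed Master seed; per-stage seeds are derived from it by stage
#'   name so adding a stage never perturbs earlier stages' streams.
#' @param output_dir Where stage outputs are written.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(table = NULL, taxonomy = NULL, tree = NULL,
                            metadata = NULL, scenario = NULL,
                            scenario_args = list(),
                            min_total = 5, min_mean_rel = 1e-4,
                            rho_threshold = 0.6, fdr_alpha = 0.05,
                            k_min = 2, k_max = 6, n_rand = 999, n_perm = 999,
                            filter_before_rarefy = TRUE,
                            seed = 1L, output_dir = tempfile("gutassembly_run_")) {
  if (is.null(scenario) && is.null(table)) {
    stop("either input paths or a simulation scenario must be given")
  }
  if (!is.null(scenario)) {
    scenario <- match.arg(scenario, c("enterotype_mixture", "neutral", "selected"))
  }
  stopifnot(min_total >= 0, min_mean_rel >= 0,
            rho_threshold >= 0, rho_threshold <= 1,
            fdr_alpha > 0, fdr_alpha < 1, n_rand >= 1, n_perm >= 1)
  if (!(2 <= k_min && k_min <= k_max)) stop("need 2 <= k_min <= k_max")
  structure(list(table = table, taxonomy = taxonomy, tree = tree,
                 metadata = metadata, scenario = scenario,
                 scenario_args = scenario_args, min_total = min_total,
                 min_mean_rel = min_mean_rel, rho_threshold = rho_threshold,
                 fdr_alpha = fdr_alpha, k_min = k_min, k_max = k_max,
                 n_rand = n_rand, n_perm = n_perm,
                 filter_before_rarefy = filter_before_rarefy,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

#' Derive a reproducible per-stage seed from a master seed
#'
#' @param seed Master integer seed.
#' @param stage Stage name (keyed into the derivation).
#' @return An integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  key <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + key * 101) %% 2147483629)
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$scenario)) {
    seed <- stage_seed(config$seed, "simulate")
    args <- config$scenario_args
    sim <- switch(config$scenario,
      enterotype_mixture = do.call(simulate_enterotype_mixture,
        utils::modifyList(list(n_samples = 94, n_taxa = 200, depth = 20000,
                               seed = seed), args)),
      neutral = do.call(simulate_neutral,
        utils::modifyList(list(n_samples = 50, n_taxa = 500, depth = 20000,
                               Nm = 2000, seed = seed), args)),
      selected = {
        n_samples <- args$n_samples %||% 40
        n_taxa <- args$n_taxa %||% 200
        tr <- simulate_tree(n_taxa, seed = stage_seed(config$seed, "tree"))
        do.call(simulate_selected, utils::modifyList(
          list(tree = tr, n_samples = n_samples, depth = 20000,
               env_values = rep(0, n_samples), seed = seed),
          args[setdiff(names(args), c("n_samples", "n_taxa"))]))
      })
    table <- sim$table
    taxa <- setdiff(names(table), "sample_id")
    # same stage seed as any tree handed to simulate_selected, so the
    # phylogeny used downstream is the one the traits evolved on
    tree <- simulate_tree(length(taxa), seed = stage_seed(config$seed, "tree"))
    tree$tip.label <- taxa
    taxonomy <- simulate_taxonomy(taxa, seed = stage_seed(config$seed, "taxonomy"))
    metadata <- simulate_metadata(table$sample_id,
                                  seed = stage_seed(config$seed, "metadata"))
    list(table = table, taxonomy = taxonomy, tree = tree, metadata = metadata,
         truth = sim$truth)
  } else {
    list(table = read_asv_table(config$table),
         taxonomy = if (!is.null(config$taxonomy)) read_taxonomy(config$taxonomy),
         tree = if (!is.null(config$tree)) read_tree(config$tree),
         metadata = if (!is.null(config$metadata)) read_metadata(config$metadata),
         truth = NULL)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_stage_json <- function(x, path, provenance = list()) {
  jsonlite::write_json(c(list(provenance = provenance), x), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full enterotype / assembly pipeline
#'
#' Executes the canonical stage order on the configured inputs: low-count
#' filter and rarefaction, genus aggregation, enterotype discovery
#' ([select_k()] on genus-level Bray-Curtis), alpha/beta diversity
#' contrasts (ANOSIM, Wilcoxon on Shannon/Simpson), then per-enterotype
#' co-occurrence networks, Sloan neutral-model fits, betaNTI / Raup-Crick
#' five-process partitioning (when a tree is available), and Mantel tests
#' of betaNTI against metadata factors.  Each stage writes its outputs
#' (TSV with provenance headers, JSON) before the next starts.
#'
#' @param config A [pipeline_config()] list.
#' @return A `run_record` list: config echo, per-stage wall times, output
#'   file digests, and the key in-memory results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  record <- list(config = config, timings = list(), files = character())
  t_stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(code),
                    error = function(e) stop("stage '", name, "' failed: ",
                                             conditionMessage(e), call. = FALSE))
    record$timings[[name]] <<- proc.time()[["elapsed"]] - t0
    res
  }
  out <- function(name) file.path(config$output_dir, name)
  prov <- list(seed = config$seed)

  inputs <- t_stage("load", load_pipeline_inputs(config))

  table <- t_stage("preprocess", {
    tab <- inputs$table
    if (config$filter_before_rarefy) {
      tab <- filter_low_abundance_asvs(tab, config$min_total)
      tab <- rarefy(tab, seed = stage_seed(config$seed, "rarefy"))
    } else {
      tab <- rarefy(tab, seed = stage_seed(config$seed, "rarefy"))
      tab <- filter_low_abundance_asvs(tab, config$min_total)
    }
    write_tsv_provenance(tab, out("asv_table_normalized.tsv"),
                         c(prov, list(min_total = config$min_total,
                                      order = if (config$filter_before_rarefy)
                                        "filter,rarefy" else "rarefy,filter")))
    tab
  })

  genus <- t_stage("aggregate", {
    g <- aggregate_by_genus(table, inputs$taxonomy)
    write_tsv_provenance(g, out("genus_table.tsv"), prov)
    g
  })

  etype <- t_stage("enterotype", {
    dm <- bray_curtis(genus)
    fit <- select_k(dm, config$k_min, config$k_max)
    write_tsv_provenance(tidy(fit), out("enterotype_labels.tsv"), prov)
    write_tsv_provenance(fit$profile, out("enterotype_profile.tsv"), prov)
    fit
  })
  labels <- setNames(etype$labels$cluster, etype$labels$sample_id)

  diversity <- t_stage("diversity", {
    alpha <- alpha_diversity(table)
    write_tsv_provenance(alpha, out("alpha_diversity.tsv"), prov)
    dm <- etype$dm
    ano <- anosim(dm, labels, n_perm = config$n_perm,
                  seed = stage_seed(config$seed, "anosim"))
    contrasts <- list(
      shannon = rank_sum_test(alpha$shannon[labels == 1], alpha$shannon[labels != 1]),
      simpson = rank_sum_test(alpha$simpson[labels == 1], alpha$simpson[labels != 1]))
    write_stage_json(list(anosim = as.list(ano),
                          shannon = as.list(contrasts$shannon),
                          simpson = as.list(contrasts$simpson)),
                     out("diversity_tests.json"), prov)
    list(alpha = alpha, anosim = ano, contrasts = contrasts)
  })

  per_type <- split(names(labels), labels)

  networks <- t_stage("networks", purrr::imap(per_type, function(ids, ty) {
    m <- asv_matrix(table)[ids, , drop = FALSE]
    m <- m[, colSums(m) > 0, drop = FALSE]
    rel <- relative_abundance(as_asv_table(m))
    net <- spearman_edges(filter_for_network(rel, config$min_mean_rel),
                          rho_threshold = config$rho_threshold,
                          fdr_alpha = config$fdr_alpha)
    stats <- network_metrics(net)
    write_tsv_provenance(net$edges, out(paste0("network_edges_type", ty, ".tsv")), prov)
    write_stage_json(as.list(stats), out(paste0("network_stats_type", ty, ".json")), prov)
    list(network = net, stats = stats)
  }))

  ncm <- t_stage("ncm", purrr::imap(per_type, function(ids, ty) {
    tab <- as_asv_table(asv_matrix(table)[ids, , drop = FALSE])
    fit <- ncm_fit(tab)
    write_tsv_provenance(tidy(fit), out(paste0("ncm_asv_type", ty, ".tsv")), prov)
    write_stage_json(as.list(glance(fit)), out(paste0("ncm_fit_type", ty, ".json")), prov)
    fit
  }))

  assembly <- if (!is.null(inputs$tree)) t_stage("assembly", {
    purrr::imap(per_type, function(ids, ty) {
      m <- asv_matrix(table)[ids, , drop = FALSE]
      m <- m[, colSums(m) > 0, drop = FALSE]
      rec <- reconcile_tree_table(as_asv_table(m), inputs$tree)
      rel <- relative_abundance(rec$table)
      bnti <- beta_nti(rel, rec$tree, n_rand = config$n_rand,
                       seed = stage_seed(config$seed, paste0("bnti", ty)))
      rc <- raup_crick_bray(rec$table, n_rand = config$n_rand,
                            seed = stage_seed(config$seed, paste0("rc", ty)))
      part <- partition_processes(bnti, rc, group = ty)
      write_tsv_provenance(part$pairs, out(paste0("assembly_pairs_type", ty, ".tsv")), prov)
      write_stage_json(list(summary = part$summary),
                       out(paste0("assembly_partition_type", ty, ".json")), prov)
      list(beta_nti = bnti, rc = rc, partition = part)
    })
  }) else NULL

  mantel <- if (!is.null(assembly) && !is.null(inputs$metadata)) t_stage("mantel", {
    vars <- intersect(c("altitude", "body_length", "body_weight", "bmi"),
                      names(inputs$metadata))
    res <- purrr::imap_dfr(assembly, function(a, ty) {
      ids <- rownames(a$beta_nti)
      md <- inputs$metadata[match(ids, inputs$metadata$sample_id), ]
      purrr::map_dfr(vars, function(v) {
        dplyr::mutate(
          mantel_test(a$beta_nti, env_distance(md, v), n_perm = config$n_perm,
                      seed = stage_seed(config$seed, paste0("mantel", ty, v))),
          group = ty, variable = v, .before = 1)
      })
    })
    write_tsv_provenance(res, out("mantel_tests.tsv"), prov)
    res
  }) else NULL

  record$files <- {
    fs <- list.files(config$output_dir, full.names = TRUE)
    setNames(as.character(tools::md5sum(fs)), basename(fs))
  }
  record$results <- list(enterotype = etype, diversity = diversity,
                         networks = networks, ncm = ncm, assembly = assembly,
                         mantel = mantel, truth = inputs$truth)
  class(record) <- "run_record"
  record
}

#' Summarize a pipeline run as a plain-text report
#'
#' Writes (and returns) a markdown report mirroring the analysis order:
#' enterotype discovery, diversity contrasts, per-enterotype network
#' topology, neutral-model fits, assembly-process partitioning, Mantel
#' tests.  Stages missing from the record are marked as absent.
#'
#' @param record A `run_record` from [run_pipeline()].
#' @param output_dir Directory the report is written into (must exist).
#' @return The report lines, invisibly; written to `report.md`.
#' @export
summarize_run <- function(record, output_dir = record$config$output_dir) {
  stopifnot(inherits(record, "run_record"))
  if (!dir.exists(output_dir)) stop("output directory does not exist: ", output_dir)
  res <- record$results
  lines <- c("# gutassembly run report", "")
  et <- res$enterotype
  lines <- c(lines, "## Enterotypes",
             sprintf("- k_best = %d; cluster sizes %s", et$k_best,
                     paste(table(et$labels$cluster), collapse = "/")),
             sprintf("- CH profile: %s",
                     paste(sprintf("k=%d:%.2f", et$profile$k, et$profile$ch),
                           collapse = ", ")), "")
  dv <- res$diversity
  lines <- c(lines, "## Diversity",
             sprintf("- ANOSIM R = %.3f, p = %.4g", dv$anosim$statistic,
                     dv$anosim$p_value),
             sprintf("- Shannon contrast p = %.4g; Simpson contrast p = %.4g",
                     dv$contrasts$shannon$p_value, dv$contrasts$simpson$p_value), "")
  lines <- c(lines, "## Network topology")
  for (ty in names(res$networks)) {
    s <- res$networks[[ty]]$stats
    lines <- c(lines, sprintf(
      "- Type%s: nodes %d, edges %d, diameter %g, modularity %.3f, clustering %.3f, density %.3f, avg degree %.3f, avg path length %.3f",
      ty, s$n_nodes, s$n_edges, s$diameter, s$modularity,
      s$clustering_coefficient, s$graph_density, s$average_degree,
      s$average_path_length))
  }
  lines <- c(lines, "", "## Neutral community model")
  for (ty in names(res$ncm)) {
    f <- res$ncm[[ty]]
    lines <- c(lines, sprintf(
      "- Type%s: Nm = %.0f, m = %.4f, R^2 = %.3f, %.2f%% of ASVs within the 95%% band",
      ty, f$Nm, f$m, f$r_squared, 100 * f$fraction_within))
  }
  lines <- c(lines, "", "## Assembly processes")
  if (is.null(res$assembly)) {
    lines <- c(lines, "- skipped (no phylogenetic tree supplied)")
  } else {
    for (ty in names(res$assembly)) {
      s <- res$assembly[[ty]]$partition$summary
      lines <- c(lines, sprintf("- Type%s: %s", ty,
        paste(sprintf("%s %.1f%%", s$process, 100 * s$fraction), collapse = ", ")))
    }
  }
  lines <- c(lines, "", "## Mantel tests")
  if (is.null(res$mantel)) {
    lines <- c(lines, "- skipped (no assembly stage or metadata)")
  } else {
    lines <- c(lines, purrr::pmap_chr(
      res$mantel[, c("group", "variable", "statistic", "p_value")],
      function(group, variable, statistic, p_value)
        sprintf("- Type%s ~ %s: r = %.3f, p = %.4g", group, variable,
                statistic, p_value)))
  }
  writeLines(lines, file.path(output_dir, "report.md"))
  invisible(lines)
}
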