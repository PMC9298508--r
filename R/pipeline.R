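#' Pipeline configuration
#'
#' One object driving the full analysis: synthetic-data settings (or input
#' paths), per-domain rarefaction depths, the dominance threshold, network
#' thresholds, group selectors for per-group networks, the EMF column
#' mapping and permutation-test settings. Validation is fail-fast: every
#' referenced path and column must resolve before any computation starts.
#'
#' @param synthetic List with `design` ([design_config()]), `community`
#'   (named list of [community_config()] per domain) and `gradient`
#'   ([gradient_config()]); `NULL` when reading data from `paths`.
#' @param paths Named list (`counts` = named list of per-domain count-table
#'   TSVs, `frame`, `env`) when not synthesizing.
#' @param depths Named rarefaction depths per domain.
#' @param dominance_threshold Mean relative-abundance cutoff.
#' @param r_threshold,p_threshold,correction Network construction settings.
#' @param groups Character vector of group selectors (e.g. `"PL:G"`) for
#'   which per-group networks are built.
#' @param emf_columns The seven function columns of the environment table.
#' @param n_perm,alpha Permutation-test settings.
#' @param seed Master seed; per-stage streams are derived from it.
#' @param output_dir Directory for stage outputs.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = default_synthetic_config(),
                            paths = NULL,
                            depths = c(bacteria = 2000, fungi = 2000,
                                       archaea = 2000),
                            dominance_threshold = 1e-4,
                            r_threshold = 0.7, p_threshold = 0.05,
                            correction = "none",
                            groups = c("P:G", "PL:G"),
                            emf_columns = EMF_FUNCTIONS,
                            n_perm = 999, alpha = 0.05,
                            seed = 1L,
                            output_dir = tempfile("emfnet_run_")) {
  abort_if(is.null(synthetic) && is.null(paths),
           "either synthetic settings or input paths are required")
  if (!is.null(paths)) {
    for (p in unlist(paths)) {
      abort_if(!file.exists(p), paste0("input path does not exist: ", p))
    }
  }
  abort_if(length(emf_columns) != 7,
           "emf_columns must name exactly 7 function variables")
  if (!is.null(synthetic)) {
    missing <- setdiff(emf_columns, ENV_VARIABLES)
    abort_if(length(missing) > 0,
             paste0("emf column(s) not produced by the gradient model: ",
                    paste(missing, collapse = ", ")))
  }
  abort_if(!all(names(depths) %in% DOMAINS), "depths must be named by domain")
  lapply(groups, parse_group)
  structure(list(synthetic = synthetic, paths = paths, depths = depths,
                 dominance_threshold = dominance_threshold,
                 r_threshold = r_threshold, p_threshold = p_threshold,
                 correction = correction, groups = groups,
                 emf_columns = emf_columns, n_perm = n_perm, alpha = alpha,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

#' Default synthetic settings of the pipeline
#'
#' A scaled-down rendition of the study design with planted structure in
#' every domain: one positive and one negative correlation block per
#' domain, one enriched OTU set in the PL grassland group, and the default
#' environmental gradients.
#'
#' @param seed Integer seed.
#' @export
default_synthetic_config <- function(seed = 1L) {
  block <- function(ids, rho) list(otus = ids, rho = rho)
  comm <- function(n, seed_off) {
    community_config(
      n_otus = n,
      correlation_blocks = list(block(paste0("otu", 1:5), 0.9),
                                block(paste0("otu", 6:7), -0.6)),
      enriched_sets = list(list(group = "PL:G", otus = paste0("otu", 10:14),
                                log2fc = 2)),
      seed = seed + seed_off)
  }
  list(design = design_config(seed = seed),
       community = list(bacteria = comm(120L, 11L),
                        fungi = comm(80L, 23L),
                        archaea = comm(50L, 37L)),
       gradient = gradient_config())
}

#' Run the full analysis pipeline
#'
#' Stages, in order: data generation (or loading), per-domain rarefaction,
#' dominance filtering, alpha diversity, Bray-Curtis similarity, per-group
#' per-domain networks with topology summaries and correlation histograms,
#' the merged cross-domain network with domain-pair edge accounting, EMF
#' scores and group summaries, enrichment ratios, PERMANOVA/Mantel/MRM
#' against the environment, and the EMF-diversity regression. Every stage
#' draws from its own seed stream derived from the master seed, so runs
#' with identical configuration are bit-identical; outputs are written
#' under `cfg$output_dir` and hashed into the run report.
#'
#' @param cfg A [pipeline_config()].
#' @return A `run_report`: list with `outputs` (tibble `stage`, `file`,
#'   `md5`), `warnings`, and the in-memory `results` list.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list()
  warns <- character()
  results <- list()
  emit <- function(stage, name, writer) {
    path <- file.path(cfg$output_dir, name)
    writer(path)
    outputs[[length(outputs) + 1]] <<-
      tibble::tibble(stage = stage, file = name,
                     md5 = unname(tools::md5sum(path)))
    path
  }

  # --- data ---
  if (!is.null(cfg$synthetic)) {
    frame <- generate_design(cfg$synthetic$design)
    counts <- purrr::imap(cfg$synthetic$community, function(cc, dom) {
      generate_counts(frame, cc, dom)
    })
    env <- generate_env(frame, cfg$synthetic$gradient,
                        seed = derive_seed(cfg$seed, "env"))
  } else {
    frame <- read_sample_frame(cfg$paths$frame)
    env <- read_env_table(cfg$paths$env)
    counts <- purrr::imap(cfg$paths$counts, function(p, dom) {
      read_count_table(p, format = "tsv", domain = dom)
    })
  }
  fm <- function_matrix(env, cfg$emf_columns) # fail-fast on the mapping
  emit("data", "sample_frame.tsv", function(p) readr::write_tsv(frame, p))
  emit("data", "env_table.tsv", function(p) readr::write_tsv(env, p))

  # --- rarefy + dominance filter ---
  rare <- purrr::imap(counts, function(ct, dom) {
    depth <- cfg$depths[[dom]] %||% min(rowSums(as_count_matrix(ct)))
    withCallingHandlers(
      rarefy(ct, depth, seed = derive_seed(cfg$seed, paste0("rarefy_", dom))),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  })
  dom_tables <- purrr::map(rare, filter_dominant,
                           threshold = cfg$dominance_threshold)
  for (dom in names(dom_tables)) {
    emit("tables", paste0("counts_", dom, ".tsv"),
         function(p) write_count_table(dom_tables[[dom]], p, "tsv"))
  }

  # --- diversity ---
  alpha <- purrr::imap(rare, function(ct, dom) {
    dplyr::mutate(alpha_diversity(ct), domain = dom)
  })
  emit("diversity", "alpha_diversity.tsv",
       function(p) readr::write_tsv(dplyr::bind_rows(alpha), p))
  beta <- purrr::map(rare, bray_curtis)
  sim <- purrr::imap_dfr(beta, function(d, dom) {
    dplyr::mutate(group_similarity(d, frame), domain = dom)
  })
  emit("diversity", "group_similarity.tsv",
       function(p) readr::write_tsv(sim, p))

  # --- per-group networks ---
  networks <- list()
  topo_rows <- list()
  for (grp in cfg$groups) {
    sel <- parse_group(grp)
    for (dom in names(dom_tables)) {
      sub <- subset_by_group(dom_tables[[dom]], frame,
                             disturbance = sel$disturbance,
                             surface = sel$surface)
      corr <- suppressMessages(spearman_all_pairs(sub))
      hist <- correlation_histogram(corr)
      emit("networks", sprintf("corr_hist_%s_%s.tsv", dom, gsub(":", "", grp)),
           function(p) readr::write_tsv(tibble::as_tibble(hist), p))
      net <- build_network(corr, cfg$r_threshold, cfg$p_threshold,
                           correction = cfg$correction)
      networks[[paste(grp, dom, sep = "/")]] <- net
      topo_rows[[paste(grp, dom, sep = "/")]] <- dplyr::mutate(
        topology_summary(net, community_seed = derive_seed(cfg$seed, "louvain")),
        group = grp, domain = dom, .before = 1)
      emit("networks", sprintf("network_%s_%s.tsv", dom, gsub(":", "", grp)),
           function(p) export_network(net, p, "edge-list-tsv"))
    }
    # cross-domain network of the group
    merged <- merge_domains(purrr::map(dom_tables, subset_by_group,
                                       frame = frame,
                                       disturbance = sel$disturbance,
                                       surface = sel$surface))
    corr_m <- suppressMessages(spearman_all_pairs(merged))
    cross <- cross_domain_filter(
      build_network(corr_m, cfg$r_threshold, cfg$p_threshold,
                    correction = cfg$correction))
    networks[[paste(grp, "cross", sep = "/")]] <- cross
    topo_rows[[paste(grp, "cross", sep = "/")]] <- dplyr::mutate(
      topology_summary(cross, community_seed = derive_seed(cfg$seed, "louvain")),
      group = grp, domain = "cross", .before = 1)
    emit("networks", sprintf("domain_pairs_%s.tsv", gsub(":", "", grp)),
         function(p) readr::write_tsv(domain_pair_summary(cross), p))
    emit("networks", sprintf("network_cross_%s.graphml", gsub(":", "", grp)),
         function(p) export_network(cross, p, "graphml"))
  }
  topo <- dplyr::bind_rows(topo_rows)
  emit("networks", "topology.tsv", function(p) readr::write_tsv(topo, p))

  # --- EMF ---
  scores <- emf_scores(fm)
  emf_groups <- group_emf(scores, frame)
  emit("emf", "emf_scores.tsv",
       function(p) readr::write_tsv(tibble::as_tibble(scores), p))
  emit("emf", "emf_groups.tsv",
       function(p) readr::write_tsv(tibble::as_tibble(emf_groups), p))

  # --- inference ---
  stats_out <- list()
  for (dom in names(rare)) {
    d <- beta[[dom]]
    ids <- attr(d, "Labels")
    lab <- frame$disturbance[match(ids, frame$sample_id)]
    stats_out[[paste0("permanova_disturbance_", dom)]] <-
      tidy_one(permanova(d, lab, n_perm = cfg$n_perm,
                         seed = derive_seed(cfg$seed, paste0("pmv", dom))))
    env_sub <- env[match(ids, env$sample_id), ]
    env_m <- scale(as.matrix(env_sub[ENV_VARIABLES]))
    rownames(env_m) <- env_sub$sample_id
    denv <- stats::dist(env_m)
    stats_out[[paste0("mantel_env_", dom)]] <-
      tidy_one(mantel_test(d, denv, n_perm = cfg$n_perm,
                           seed = derive_seed(cfg$seed, paste0("mtl", dom))))
    stats_out[[paste0("mrm_", dom)]] <- tidy_one(
      mrm(d, list(env = denv,
                  disturbance = stats::dist(as.numeric(factor(lab)))),
          n_perm = cfg$n_perm,
          seed = derive_seed(cfg$seed, paste0("mrm", dom))))
  }
  # EMF ~ bacterial alpha diversity (Chao1)
  ab <- alpha[["bacteria"]]
  joined <- dplyr::inner_join(tibble::as_tibble(scores), ab, by = "sample_id")
  reg <- linear_regression(joined$chao1, joined$emf)
  stats_out[["regression_emf_chao1_bacteria"]] <- tidy_one(reg)
  # enrichment ratios vs the natural meadow
  enr <- purrr::map_dfr(cfg$groups, function(grp) {
    suppressMessages(
      enrichment_ratio(rare[["bacteria"]], frame, focal_group = grp,
                       control_group = "C", alpha = cfg$alpha))
  })
  emit("stats", "enrichment_bacteria.tsv",
       function(p) readr::write_tsv(enr, p))
  emit("stats", "tests.json", function(p) {
    jsonlite::write_json(stats_out, p, auto_unbox = TRUE, digits = NA)
  })

  results <- list(frame = frame, env = env, counts = counts, rarefied = rare,
                  dominant = dom_tables, alpha = alpha, beta = beta,
                  similarity = sim, networks = networks, topology = topo,
                  emf = scores, emf_groups = emf_groups, enrichment = enr,
                  tests = stats_out, regression = reg)
  structure(list(outputs = dplyr::bind_rows(outputs), warnings = warns,
                 config = cfg, results = results),
            class = "run_report")
}

tidy_one <- function(x) {
  if (inherits(x, "emf_mrm")) {
    list(coefficients = x$coefficients, R2 = x$R2,
         n_permutations = x$n_permutations)
  } else if (inherits(x, "emf_regression")) {
    list(slope = x$slope, intercept = x$intercept, R2 = x$R2,
         p_value = x$p_value)
  } else {
    list(statistic = x$statistic, R2 = x$R2 %||% NULL, p_value = x$p_value,
         n_permutations = x$n_permutations)
  }
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("# emfnet run: %d output files in %s\n",
              nrow(x$outputs), x$config$output_dir))
  if (length(x$warnings)) {
    cat(sprintf("# %d warning(s) during the run\n", length(x$warnings)))
  }
  print(x$outputs, ...)
  invisible(x)
}
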