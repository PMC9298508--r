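#' Synthetic study design
#'
#' Emulates the field design of a pika/livestock disturbance survey on an
#' alpine meadow: two blocks per disturbance treatment, five sites per
#' block, and within disturbed blocks one quadrat per surface type of the
#' pika succession (grassland G, new mound N, old mound O, bare land B,
#' inside mound I). Control (C) blocks sample the natural meadow only, so
#' the default design yields 2x5 C samples plus 2x5x5 samples for each of P
#' and PL: 110 samples in total.
#'
#' @param n_blocks_per_treatment Blocks per disturbance treatment.
#' @param treatments Disturbance labels; subset of `c("C", "P", "PL")`.
#' @param surfaces Surface labels sampled in disturbed blocks.
#' @param n_sites_per_block Sites per block.
#' @param seed Integer seed.
#' @return A `design_config` list.
#' @export
design_config <- function(n_blocks_per_treatment = 2,
                          treatments = c("C", "P", "PL"),
                          surfaces = c("G", "N", "O", "B", "I"),
                          n_sites_per_block = 5,
                          seed = 1L) {
  abort_if(length(treatments) == 0, "configuration error: empty treatment list")
  abort_if(!all(treatments %in% c("C", "P", "PL")),
           "treatments must be drawn from {C, P, PL}")
  abort_if(!all(surfaces %in% c("G", "N", "O", "B", "I")),
           "surfaces must be drawn from {G, N, O, B, I}")
  structure(list(n_blocks_per_treatment = as.integer(n_blocks_per_treatment),
                 treatments = treatments, surfaces = surfaces,
                 n_sites_per_block = as.integer(n_sites_per_block),
                 seed = as.integer(seed)),
            class = "design_config")
}

#' Generate the sample frame of a synthetic study
#'
#' One row per soil sample with disturbance, surface, block and site labels.
#' C (natural meadow) samples carry surface label `"G"` so that
#' surface-level contrasts can include them, but keep disturbance `"C"`.
#'
#' @param cfg A [design_config()].
#' @return A sample-frame tibble (`sample_id`, `disturbance`, `surface`,
#'   `block`, `site`).
#' @examples
#' nrow(generate_design(design_config())) # 110
#' @export
generate_design <- function(cfg = design_config()) {
  stopifnot(inherits(cfg, "design_config"))
  rows <- purrr::map_dfr(cfg$treatments, function(tr) {
    surfaces <- if (tr == "C") "G" else cfg$surfaces
    tidyr::expand_grid(block = seq_len(cfg$n_blocks_per_treatment),
                       site = seq_len(cfg$n_sites_per_block),
                       surface = surfaces) |>
      dplyr::mutate(disturbance = tr)
  })
  rows |>
    dplyr::mutate(block = paste0(.data$disturbance, .data$block),
                  sample_id = paste(.data$disturbance, .data$block,
                                    paste0("s", .data$site), .data$surface,
                                    sep = "_")) |>
    dplyr::select("sample_id", "disturbance", "surface", "block", "site") |>
    validate_sample_frame()
}

#' Synthetic community model
#'
#' Latent Gaussian copula over per-sample log abundances: each OTU has a
#' fixed base log abundance (log-normal spread `base_abundance_shape`);
#' per-sample deviations are multivariate normal with sd `noise_sd` and a
#' block-structured correlation matrix (`correlation_blocks` plant latent
#' correlation `rho` within named OTU sets). Enrichment sets add a log2
#' fold-change to their OTUs in the target group before the softmax to
#' composition. Counts are multinomial at a negative-binomial library size
#' (`depth_mean`, size = `depth_dispersion`), with optional per-OTU dropout.
#'
#' @param n_otus Number of OTUs in the domain.
#' @param depth_mean,depth_dispersion Library-size model (NB mean and size).
#' @param base_abundance_shape Log-normal sigma of expected base abundances.
#' @param correlation_blocks List of `list(otus = <ids>, rho = <value>)`.
#' @param enriched_sets List of `list(group = "PL:G", otus = <ids>,
#'   log2fc = <value>)`; `group` is a `"disturbance:surface"` selector.
#' @param noise_sd Latent per-sample log-abundance sd.
#' @param dropout Per-OTU zero-inflation probability after the draw.
#' @param seed Integer seed.
#' @return A `community_config` list.
#' @export
community_config <- function(n_otus = 200,
                             depth_mean = 10000, depth_dispersion = 20,
                             base_abundance_shape = 1,
                             correlation_blocks = list(),
                             enriched_sets = list(),
                             noise_sd = 0.6,
                             dropout = 0,
                             seed = 1L) {
  otu_ids <- paste0("otu", seq_len(n_otus))
  for (b in correlation_blocks) {
    abort_if(length(b$otus) < 2, "each correlation block needs >= 2 OTUs")
    abort_if(abs(b$rho) > 1, "|rho| must be <= 1")
    # equicorrelation is positive definite only for rho > -1/(k - 1)
    abort_if(b$rho <= -1 / (length(b$otus) - 1) + 1e-12,
             sprintf("rho = %.3f infeasible for a block of %d OTUs (needs rho > %.3f)",
                     b$rho, length(b$otus), -1 / (length(b$otus) - 1)))
    abort_if(!all(b$otus %in% otu_ids),
             "correlation block references an OTU outside the table")
  }
  for (e in enriched_sets) {
    abort_if(!all(is.finite(e$log2fc)), "fold-changes must be finite")
    abort_if(!all(e$otus %in% otu_ids),
             "enriched set references an OTU outside the table")
  }
  abort_if(noise_sd < 0, "noise_sd must be >= 0")
  structure(list(n_otus = as.integer(n_otus), otu_ids = otu_ids,
                 depth_mean = depth_mean, depth_dispersion = depth_dispersion,
                 base_abundance_shape = base_abundance_shape,
                 correlation_blocks = correlation_blocks,
                 enriched_sets = enriched_sets,
                 noise_sd = noise_sd, dropout = dropout,
                 seed = as.integer(seed)),
            class = "community_config")
}

#' Default per-domain community configurations
#'
#' Richness mirrors the qualitative Chao1 ordering of soil surveys
#' (bacteria >> fungi ~ archaea); magnitudes are free parameters.
#'
#' @param domain One of `"bacteria"`, `"fungi"`, `"archaea"`.
#' @param ... Overrides passed to [community_config()].
#' @export
default_community_config <- function(domain, ...) {
  abort_if(!domain %in% DOMAINS, paste0("unknown domain label: ", domain))
  n <- c(bacteria = 500L, fungi = 150L, archaea = 60L)[[domain]]
  args <- utils::modifyList(list(n_otus = n), list(...))
  do.call(community_config, args)
}

# Build the block-structured latent correlation matrix.
latent_correlation <- function(cfg) {
  R <- diag(cfg$n_otus)
  rownames(R) <- colnames(R) <- cfg$otu_ids
  for (b in cfg$correlation_blocks) {
    idx <- match(b$otus, cfg$otu_ids)
    R[idx, idx] <- b$rho
  }
  diag(R) <- 1
  R
}

#' Generate a synthetic OTU count table
#'
#' @param design Sample frame from [generate_design()].
#' @param cfg A [community_config()].
#' @param domain Domain label for the resulting table.
#' @return A [count_table()], deterministic given `cfg$seed`.
#' @export
generate_counts <- function(design, cfg, domain) {
  design <- validate_sample_frame(design)
  abort_if(!domain %in% DOMAINS, paste0("unknown domain label: ", domain))
  stopifnot(inherits(cfg, "community_config"))
  n <- nrow(design)
  with_seed(cfg$seed, {
    alpha <- stats::rnorm(cfg$n_otus, 0, cfg$base_abundance_shape)
    R <- latent_correlation(cfg)
    L <- chol(R)
    E <- (matrix(stats::rnorm(n * cfg$n_otus), n) %*% L) * cfg$noise_sd
    eta <- sweep(E, 2, alpha, "+")
    for (e in cfg$enriched_sets) {
      sel <- parse_group(e$group)
      in_group <- design$disturbance == sel$disturbance &
        (is.null(sel$surface) | design$surface == (sel$surface %||% ""))
      eta[in_group, match(e$otus, cfg$otu_ids)] <-
        eta[in_group, match(e$otus, cfg$otu_ids)] + e$log2fc * log(2)
    }
    P <- exp(eta)
    P <- P / rowSums(P)
    depths <- pmax(1L, stats::rnbinom(n, size = cfg$depth_dispersion,
                                      mu = cfg$depth_mean))
    m <- matrix(vapply(seq_len(n),
                       function(i) stats::rmultinom(1, depths[i], P[i, ])[, 1],
                       integer(cfg$n_otus)),
                nrow = n, ncol = cfg$n_otus, byrow = TRUE)
    if (cfg$dropout > 0) {
      keep <- matrix(stats::runif(n * cfg$n_otus) >= cfg$dropout, n)
      m <- m * keep
    }
    dimnames(m) <- list(design$sample_id, cfg$otu_ids)
    count_table(m, domain = domain)
  })
}

#' Environmental gradient model
#'
#' Per-variable intercepts plus per-surface offsets with Gaussian residuals.
#' Defaults encode the qualitative succession signal of pika disturbance:
#' nutrient and vegetation variables decline monotonically along
#' G -> N -> O -> B (with I intermediate), pH drifts slightly upwards.
#'
#' @param intercepts Named numeric vector over the 9 variables.
#' @param surface_offsets Named list: per variable, a named numeric vector of
#'   offsets over surfaces G, N, O, B, I.
#' @param residual_sd Named numeric vector of positive residual sds.
#' @return A `gradient_config` list.
#' @export
gradient_config <- function(intercepts = NULL, surface_offsets = NULL,
                            residual_sd = NULL) {
  vars <- ENV_VARIABLES
  decline <- function(scale) c(G = scale, N = 0.25 * scale, O = -0.25 * scale,
                               B = -scale, I = -0.5 * scale)
  default_int <- c(pH = 7.8, CON = 150, NH4_N = 8, NO3_N = 6, SOC = 45,
                   TN = 4, total_coverage = 70, wet_weight = 60,
                   dry_weight = 25)
  default_off <- list(pH = -decline(0.15), CON = decline(20),
                      NH4_N = decline(2), NO3_N = decline(1.5),
                      SOC = decline(10), TN = decline(0.8),
                      total_coverage = decline(20), wet_weight = decline(15),
                      dry_weight = decline(6))
  default_sd <- c(pH = 0.2, CON = 15, NH4_N = 1.5, NO3_N = 1.2, SOC = 8,
                  TN = 0.6, total_coverage = 8, wet_weight = 10,
                  dry_weight = 4)
  intercepts <- utils::modifyList(as.list(default_int),
                                  as.list(intercepts %||% list()))
  surface_offsets <- utils::modifyList(default_off,
                                       surface_offsets %||% list())
  residual_sd <- utils::modifyList(as.list(default_sd),
                                   as.list(residual_sd %||% list()))
  missing <- setdiff(vars, names(intercepts))
  abort_if(length(missing) > 0,
           paste0("gradient config missing variable(s): ",
                  paste(missing, collapse = ", ")))
  abort_if(any(unlist(residual_sd[vars]) <= 0), "residual sd must be > 0")
  structure(list(intercepts = intercepts, surface_offsets = surface_offsets,
                 residual_sd = residual_sd),
            class = "gradient_config")
}

ENV_VARIABLES <- c("pH", "CON", "NH4_N", "NO3_N", "SOC", "TN",
                   "total_coverage", "wet_weight", "dry_weight")

#' Generate a synthetic environment/function table
#'
#' @param design Sample frame from [generate_design()].
#' @param cfg A [gradient_config()].
#' @param seed Integer seed.
#' @return A tibble, one row per sample, with the 9 environment variables;
#'   expected cell value = intercept + surface offset.
#' @export
generate_env <- function(design, cfg = gradient_config(), seed = 1L) {
  design <- validate_sample_frame(design)
  stopifnot(inherits(cfg, "gradient_config"))
  with_seed(seed, {
    cols <- lapply(ENV_VARIABLES, function(v) {
      off <- cfg$surface_offsets[[v]][design$surface]
      cfg$intercepts[[v]] + off +
        stats::rnorm(nrow(design), 0, cfg$residual_sd[[v]])
    })
    names(cols) <- ENV_VARIABLES
    out <- dplyr::bind_cols(design["sample_id"], tibble::as_tibble(cols))
    out$total_coverage <- pmin(pmax(out$total_coverage, 0), 100)
    out
  })
}

#' Ground truth planted by a community configuration
#'
#' Used to score network edge recovery and enrichment-ratio recovery on
#' synthetic data.
#'
#' @param cfg A [community_config()].
#' @return List with `pairs` (tibble `otu_i`, `otu_j`, `sign`; `otu_i <
#'   otu_j`) and `enriched` (tibble `group`, `otu`, `log2fc`).
#' @export
planted_truth <- function(cfg) {
  stopifnot(inherits(cfg, "community_config"))
  pairs <- purrr::map_dfr(cfg$correlation_blocks, function(b) {
    ids <- sort(b$otus)
    cmb <- utils::combn(ids, 2)
    tibble::tibble(otu_i = cmb[1, ], otu_j = cmb[2, ],
                   sign = ifelse(b$rho >= 0, "+", "-"))
  })
  if (nrow(pairs) == 0) {
    pairs <- tibble::tibble(otu_i = character(), otu_j = character(),
                            sign = character())
  }
  enriched <- purrr::map_dfr(cfg$enriched_sets, function(e) {
    tibble::tibble(group = e$group, otu = e$otus, log2fc = e$log2fc)
  })
  if (nrow(enriched) == 0) {
    enriched <- tibble::tibble(group = character(), otu = character(),
                               log2fc = numeric())
  }
  list(pairs = pairs, enriched = enriched)
}

#' Write the ground-truth record as JSON
#'
#' @param truth Result of [planted_truth()].
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "columns", auto_unbox = TRUE)
  invisible(path)
}
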