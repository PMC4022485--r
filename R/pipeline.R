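#' Analysis run configuration
#'
#' Collects every parameter of the structure-dynamics and coevolution
#' stages with its documented default, so a complete analysis is a pure
#' function of one config object.  Configs serialize to and from JSON (see
#' [write_run_config()]), and all randomness flows from the single
#' `seed`, split per stage.
#'
#' @param structure Path to the structure file (PDB/mmCIF).
#' @param chain Chain id.
#' @param msa Path to the alignment file.
#' @param msa_format Alignment format (`"auto"`, `"fasta"`, `"stockholm"`).
#' @param ref_id,ref_start Reference row and its first residue id for
#'   column mapping.
#' @param domain_map Domain-map tibble (default DnaK).
#' @param groups Interdomain residue groups (default DnaK NBD/SBD).
#' @param gnm_cutoff,anm_cutoff Network cutoffs (Angstrom).
#' @param n_modes Number of slowest GNM modes in the mobility profile.
#' @param hinge_window,hinge_percentile Hinge-detection parameters.
#' @param prs_targets Residue ids whose influence/response profiles are
#'   reported (default: linker residues and detected hinges).
#' @param methods Coevolution methods to run (subset of MIp, OMES, SCA,
#'   DI, PSICOV).
#' @param fraction,min_methods,k_override Consensus parameters.
#' @param identity_threshold Sequence-weighting identity threshold.
#' @param max_gap_fraction Column filter threshold.
#' @param di_pseudocount DI pseudocount fraction.
#' @param psicov_rho PSICOV lasso penalty.
#' @param seed Master seed.
#' @param out_dir Output directory (optional; no files written when NULL).
#' @return A `run_config` list.
#' @export
run_config <- function(structure = NULL, chain = NULL,
                       msa = NULL, msa_format = "auto",
                       ref_id = NULL, ref_start = 1,
                       domain_map = dnak_domain_map(),
                       groups = dnak_groups(),
                       gnm_cutoff = 7.3, anm_cutoff = 13,
                       n_modes = 10, hinge_window = 5, hinge_percentile = 20,
                       prs_targets = NULL,
                       methods = c("MIp", "OMES", "SCA", "DI", "PSICOV"),
                       fraction = 0.0006, min_methods = 2, k_override = NULL,
                       identity_threshold = 0.8, max_gap_fraction = 0.5,
                       di_pseudocount = 0.5, psicov_rho = 0.005,
                       seed = 1, out_dir = NULL) {
  cfg <- list(structure = structure, chain = chain,
              msa = msa, msa_format = msa_format,
              ref_id = ref_id, ref_start = ref_start,
              domain_map = validate_domain_map(domain_map),
              groups = groups,
              gnm_cutoff = gnm_cutoff, anm_cutoff = anm_cutoff,
              n_modes = n_modes, hinge_window = hinge_window,
              hinge_percentile = hinge_percentile,
              prs_targets = prs_targets,
              methods = methods,
              fraction = fraction, min_methods = min_methods,
              k_override = k_override,
              identity_threshold = identity_threshold,
              max_gap_fraction = max_gap_fraction,
              di_pseudocount = di_pseudocount, psicov_rho = psicov_rho,
              seed = seed, out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a run configuration
#' @param config A `run_config`.
#' @param path JSON path.
#' @return `write_run_config` the path invisibly; `read_run_config` a
#'   `run_config`.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$groups <- lapply(x$groups, as.integer)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", dataframe = "columns")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$domain_map <- tibble::as_tibble(x$domain_map)
  do.call(run_config, x)
}

stage_seed <- function(seed, stage) {
  # deterministic per-stage split, kept within 32-bit integer range
  (as.integer(seed) * 97L + stage * 1009L) %% 2000000011L
}

write_tsv <- function(df, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
              row.names = FALSE)
}

write_manifest <- function(config, dir, stage, extra = list()) {
  if (is.null(dir)) return(invisible(NULL))
  x <- unclass(config)
  x$out_dir <- NULL
  jsonlite::write_json(
    c(list(stage = stage,
           package_version = as.character(utils::packageVersion("allomap"))),
      x, extra),
    file.path(dir, paste0("manifest-", stage, ".json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null",
    dataframe = "columns")
}

#' Run the structure-dynamics stage
#'
#' Reads and annotates the structure, builds the Gaussian network, computes
#' the cumulative mobility profile and hinge residues, then runs
#' perturbation-response scanning and reports effector/sensor rankings and
#' the influence and response profiles of the configured target residues
#' (by default the linker residues present plus detected hinges).
#'
#' @param config A [run_config()].
#' @return A list of class `dynamics_report` with the structure, mobility
#'   profile, hinges, PRS map, marginals, rankings and per-target profiles.
#' @export
run_dynamics <- function(config) {
  if (is.null(config$structure) || !file.exists(config$structure))
    abort(paste0("dynamics stage: structure file not found: ",
                 if (is.null(config$structure)) "(unset)" else config$structure))
  st <- read_structure(config$structure, chain = config$chain)
  st <- annotate_domains(st, config$domain_map)

  net <- build_gnm(st, cutoff = config$gnm_cutoff)
  modes <- decompose_gnm(net)
  m <- min(config$n_modes, length(modes$values) - modes$n_zero)
  prof <- cumulative_mobility(modes, m = m)
  hinges <- find_hinges(prof, window = config$hinge_window,
                        percentile = config$hinge_percentile)
  frac <- dynamics_fraction(modes, m)

  anm <- build_anm(st, cutoff = config$anm_cutoff)
  pmap <- prs_map(anm)
  ranks <- rank_effectors_sensors(pmap, top_n = 10)

  targets <- config$prs_targets
  if (is.null(targets)) {
    linker <- st$residue_id[st$domain == "linker"]
    targets <- unique(c(linker, hinges))
  }
  targets <- intersect(targets, st$residue_id)
  profiles <- lapply(targets, function(tr) {
    list(target = tr,
         influence = influence_profile(pmap, tr),
         response = response_profile(pmap, tr))
  })
  names(profiles) <- as.character(targets)

  dir <- config$out_dir
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(dplyr::mutate(as_tibble(prof),
                            label = domain_lookup(prof$residue_id,
                                                  config$domain_map)),
              dir, "mobility_profile.tsv")
    write_tsv(prs_marginals(pmap), dir, "prs_marginals.tsv")
    write_tsv(tibble::tibble(residue_id = hinges), dir, "hinges.tsv")
    write_manifest(config, dir, "dynamics",
                   list(n_modes_used = m, dynamics_fraction = frac))
  }
  structure(list(structure = st, network = net, modes = modes,
                 mobility = prof, hinges = hinges,
                 dynamics_fraction = frac,
                 prs = pmap, marginals = prs_marginals(pmap),
                 effectors = ranks$effectors, sensors = ranks$sensors,
                 target_profiles = profiles, config = config),
            class = "dynamics_report")
}

#' @export
print.dynamics_report <- function(x, ...) {
  cat("Dynamics report:", nrow(x$structure), "residues;",
      length(x$hinges), "hinges;",
      sprintf("%.1f%% of dynamics in %d modes\n",
              100 * x$dynamics_fraction, x$mobility |> attr("mode_range") |> max()))
  invisible(x)
}

run_one_method <- function(method, msa, config) {
  switch(method,
    MIp = mip(msa),
    OMES = omes(msa),
    SCA = sca(msa),
    DI = direct_information(msa, pseudocount_frac = config$di_pseudocount),
    PSICOV = psicov_score(msa, lasso_rho = config$psicov_rho),
    abort(paste0("unknown coevolution method: ", method)))
}

#' Run the sequence-coevolution stage
#'
#' Reads the alignment, maps columns to the reference numbering, weights
#' sequences, filters gapped columns, runs the configured coevolution
#' scorers (a scorer failure is recorded and the pipeline continues while
#' at least two succeed), and synthesises interdomain submatrices, the
#' method consensus and cumulative propensity profiles.
#'
#' @param config A [run_config()].
#' @return A list of class `coevolution_report`.
#' @export
run_coevolution <- function(config) {
  if (length(config$methods) < 2)
    abort("consensus requires at least 2 coevolution methods; configure >= 2")
  if (is.null(config$msa) || !file.exists(config$msa))
    abort(paste0("coevolution stage: alignment file not found: ",
                 if (is.null(config$msa)) "(unset)" else config$msa))
  msa <- read_msa(config$msa, format = config$msa_format)
  if (!is.null(config$ref_id))
    msa <- map_to_reference(msa, config$ref_id, config$ref_start)
  msa <- filter_columns(msa, max_gap_fraction = config$max_gap_fraction)
  msa <- sequence_weights(msa, config$identity_threshold)

  results <- list()
  failures <- list()
  for (m in config$methods) {
    r <- tryCatch(run_one_method(m, msa, config), error = function(e) e)
    if (inherits(r, "error")) failures[[m]] <- conditionMessage(r)
    else results[[m]] <- r
  }
  if (length(results) < 2)
    abort(paste0("fewer than 2 coevolution methods succeeded; failures: ",
                 paste(names(failures), unlist(failures),
                       sep = ": ", collapse = "; ")))

  subs <- lapply(results, interdomain_submatrix, groups = config$groups)
  consensus <- consensus_pairs(results, groups = config$groups,
                               fraction = config$fraction,
                               min_methods = config$min_methods,
                               k_override = config$k_override)
  propensity <- dplyr::bind_rows(lapply(subs, cumulative_propensity))
  entropy <- shannon_entropy(msa)

  dir <- config$out_dir
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (m in names(results)) {
      write_tsv(tidy(results[[m]]), dir, paste0("scores_", m, ".tsv"))
      jsonlite::write_json(results[[m]]$params,
                           file.path(dir, paste0("scores_", m, ".json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    write_tsv(consensus, dir, "consensus_pairs.tsv")
    write_tsv(propensity, dir, "propensity.tsv")
    write_tsv(entropy, dir, "conservation.tsv")
    write_manifest(config, dir, "coevolution",
                   list(methods_succeeded = names(results),
                        methods_failed = failures))
  }
  structure(list(msa = msa, results = results, failures = failures,
                 submatrices = subs, consensus = consensus,
                 propensity = propensity, entropy = entropy,
                 config = config),
            class = "coevolution_report")
}

#' @export
print.coevolution_report <- function(x, ...) {
  cat("Coevolution report:", length(x$results), "methods (",
      paste(names(x$results), collapse = ", "), ");",
      nrow(x$consensus), "consensus pairs\n")
  invisible(x)
}

#' Run the full integrated analysis
#'
#' Runs both stages and cross-references them: for every consensus pair and
#' every hinge residue the joint report lists PRS effectiveness and
#' sensitivity and conservation entropy, giving the per-residue evidence
#' summary that combines dynamics and coevolution.
#'
#' @param config A [run_config()].
#' @return A list of class `allostery_report` with elements `dynamics`,
#'   `coevolution` and `evidence` (the cross-referenced residue table).
#' @export
run_all <- function(config) {
  dyn <- run_dynamics(config)
  coev <- run_coevolution(config)

  cons_res <- unique(c(coev$consensus$residue_a, coev$consensus$residue_b))
  ids <- sort(unique(c(cons_res, dyn$hinges)))
  marg <- dyn$marginals
  ent <- coev$entropy
  evidence <- tibble::tibble(residue_id = ids) |>
    dplyr::mutate(
      hinge = .data$residue_id %in% dyn$hinges,
      in_consensus = .data$residue_id %in% cons_res,
      label = domain_lookup(.data$residue_id, config$domain_map)
    ) |>
    dplyr::left_join(marg, by = "residue_id") |>
    dplyr::left_join(dplyr::select(ent, "residue_id", "entropy"),
                     by = "residue_id")

  dir <- config$out_dir
  if (!is.null(dir)) {
    write_tsv(evidence, dir, "evidence_summary.tsv")
    write_manifest(config, dir, "all")
  }
  structure(list(dynamics = dyn, coevolution = coev, evidence = evidence,
                 config = config),
            class = "allostery_report")
}

#' @export
print.allostery_report <- function(x, ...) {
  print(x$dynamics)
  print(x$coevolution)
  cat("Evidence table:", nrow(x$evidence), "residues\n")
  invisible(x)
}
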