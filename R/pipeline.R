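#' Pipeline configuration
#'
#' A single configuration object drives the end-to-end workflow: synthetic
#' generation (optional), pose screening, WT-vs-mutant comparison, RMSF
#' analysis and kinetics. `demo_pipeline_config()` returns a small,
#' fast-running configuration exercising every stage;
#' `read_pipeline_config()` loads the same structure from a YAML file and
#' `validate_pipeline_config()` checks it before any compute (fail-fast: a
#' bad configuration produces no partial outputs).
#'
#' @param seed master seed; every stage derives its own sub-seed from it.
#' @return a `pipeline_config` list.
#' @export
demo_pipeline_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    ligands = list(
      list(name = "MU", n_conformations = 300, n_hydroxyls = 1,
           wt_fraction = 0.20, mut_fraction = 0.30),
      list(name = "HQ", n_conformations = 300, n_hydroxyls = 2,
           wt_fraction = 0.20, mut_fraction = 0.30)
    ),
    criteria = list(d1_max = 4, d2_max = 4, a1_min = 80, a1_max = 140,
                    strict = TRUE),
    bins = list(d1_bin = 0.25, a1_bin = 5),
    ensemble = list(n_replicas = 5, sim_length_ps = 5000, stride_ps = 50,
                    include_t0 = TRUE),
    trajectory = list(n_residues = 30, n_frames = 200, n_replicas = 5,
                      sigma = 0.5, mut_scale = 0.5,
                      mut_residues = c(14, 15, 16)),
    alpha = 0.05,
    kinetics = list(
      Km = 36.174, Vmax = 0.090, MW = 73044,
      substrate_concs = c(0.4, 1, 2, 5, 10, 25, 50, 100, 200),
      noise_cv = 0.05, replicates = 3),
    products = list(a = 6.80, a_sd = 0.26, b = 4.76, b_sd = 0.02)
  ), class = "pipeline_config")
}

#' @rdname demo_pipeline_config
#' @param path path to a YAML configuration file.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_parse(paste0("config file not found: ", path))
  cfg <- yaml::read_yaml(path)
  cfg <- utils::modifyList(unclass(demo_pipeline_config()), cfg)
  structure(cfg, class = "pipeline_config")
}

#' @rdname demo_pipeline_config
#' @param config a `pipeline_config`.
#' @export
validate_pipeline_config <- function(config) {
  if (!is.list(config)) stop_invalid("config", "must be a list")
  check_number(config$seed, "seed", integerish = TRUE)
  if (length(config$ligands) == 0L)
    stop_invalid("ligands", "at least one ligand required")
  for (lg in config$ligands) {
    if (is.null(lg$name)) stop_invalid("ligands", "each ligand needs a name")
    check_number(lg$n_conformations, "n_conformations", positive = TRUE,
                 integerish = TRUE)
    check_number(lg$wt_fraction, "wt_fraction", nonneg = TRUE)
    check_number(lg$mut_fraction, "mut_fraction", nonneg = TRUE)
  }
  do.call(reactive_criteria, config$criteria)
  do.call(ensemble_definition,
          config$ensemble[c("n_replicas", "sim_length_ps", "stride_ps",
                            "include_t0")])
  check_number(config$alpha, "alpha", nonneg = TRUE)
  kin <- config$kinetics
  kinetic_sim_spec(kin$Km, kin$Vmax, kin$substrate_concs, kin$noise_cv,
                   kin$replicates, seed = config$seed)
  check_number(kin$MW, "MW", positive = TRUE)
  invisible(config)
}

sub_seed <- function(seed, k) (seed * 1000L + k) %% .Machine$integer.max

#' Run the full screening-and-kinetics workflow
#'
#' Executes generate -> screen -> compare -> rmsf -> kinetics on synthetic
#' inputs, writing per-pose CSVs, comparison tables, RMSF profiles, a
#' kinetics report (JSON) and a manifest recording the package version, seed
#' and md5 of every written file. Generated structures pass through the
#' PDBQT/PDB writers and readers, so the run exercises the same file-format
#' path real docking output would take.
#'
#' @param config a `pipeline_config` (see [demo_pipeline_config()]).
#' @param output_dir directory for the report bundle (created if missing).
#' @param plots also write PNG figures (best effort; a missing graphics
#'   device downgrades to a warning).
#' @return (invisibly) a list with the key results: per-ligand geometry
#'   tibbles, conformation maps, the population summary, RMSF comparison and
#'   kinetic fits, plus `manifest`.
#' @export
run_pipeline <- function(config = demo_pipeline_config(),
                         output_dir = tempfile("glycoscreen-run-"),
                         plots = TRUE) {
  validate_pipeline_config(config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  gen_dir <- file.path(output_dir, "generated")
  dir.create(gen_dir, showWarnings = FALSE)
  written <- character(0)
  emit <- function(obj, file, writer = utils::write.csv) {
    path <- file.path(output_dir, file)
    writer(obj, path)
    written <<- c(written, path)
    path
  }
  csv <- function(obj, path) utils::write.csv(obj, path, row.names = FALSE)
  tsv <- function(obj, path) utils::write.table(obj, path, sep = "\t",
                                                row.names = FALSE,
                                                quote = FALSE)

  criteria <- do.call(reactive_criteria, config$criteria)
  maps <- list()
  geoms <- list()
  k <- 0L
  for (lg in config$ligands) {
    per_variant <- list()
    for (variant in c("wt", "mut")) {
      k <- k + 1L
      frac <- if (variant == "wt") lg$wt_fraction else lg$mut_fraction
      spec <- pose_ensemble_spec(
        n_conformations = lg$n_conformations, ligand_name = lg$name,
        n_hydroxyls = lg$n_hydroxyls %||% 1L,
        fraction_reactive_target = frac,
        seed = sub_seed(config$seed, k))
      ens <- generate_pose_ensemble(spec)
      pq <- file.path(gen_dir, paste0(lg$name, "_", variant, ".pdbqt"))
      rc <- file.path(gen_dir, paste0(lg$name, "_", variant,
                                      "_receptor.pdb"))
      write_pdbqt_poses(ens$atoms, pq)
      write_pdb(ens$receptor, rc)
      written <- c(written, pq, rc)
      poses <- read_pdbqt_poses(pq)
      receptor <- read_pdb(rc)
      g <- classify_poses(poses, receptor, ens$site, criteria)
      g$ligand <- lg$name
      g$variant <- variant
      per_variant[[variant]] <- g
      emit(g, paste0("poses_", lg$name, "_", variant, ".csv"), csv)
    }
    geoms[[lg$name]] <- bind_rows(per_variant)
    maps[[lg$name]] <- build_conformation_map(
      per_variant$wt, per_variant$mut, criteria,
      d1_bin = config$bins$d1_bin, a1_bin = config$bins$a1_bin)
    emit(tidy(maps[[lg$name]]),
         paste0("density_diff_", lg$name, ".csv"), csv)
  }
  summary_tbl <- reactive_population_summary(bind_rows(geoms))
  emit(summary_tbl, "reactive_population_summary.tsv", tsv)

  tr <- config$trajectory
  sig_wt <- rep(tr$sigma, tr$n_residues)
  sig_mut <- sig_wt
  sig_mut[tr$mut_residues] <- sig_mut[tr$mut_residues] * tr$mut_scale
  prof <- list()
  for (variant in c("wt", "mut")) {
    sig <- if (variant == "wt") sig_wt else sig_mut
    trajs <- generate_trajectory(trajectory_spec(
      tr$n_residues, tr$n_frames, sig, n_replicas = tr$n_replicas,
      seed = sub_seed(config$seed, if (variant == "wt") 101L else 102L)))
    per_rep <- purrr::imap(trajs, function(t, i) {
      r <- compute_rmsf(t)
      r$replica <- paste0(variant, "_rep", i)
      r
    })
    prof[[variant]] <- aggregate_replicas(bind_rows(per_rep))
    emit(tidy(prof[[variant]]), paste0("rmsf_", variant, ".csv"), csv)
  }
  flex <- compare_flexibility(prof$wt, prof$mut, alpha = config$alpha)
  emit(flex, "flexibility_comparison.csv", csv)

  kin <- config$kinetics
  kdata <- generate_kinetic_data(kinetic_sim_spec(
    kin$Km, kin$Vmax, kin$substrate_concs, kin$noise_cv, kin$replicates,
    seed = sub_seed(config$seed, 201L)))
  emit(kdata, "kinetics_data.csv", csv)
  fit_lb <- derive_kcat(fit_lineweaver_burk(kdata), kin$MW)
  fit_nls <- derive_kcat(fit_mm_nonlinear(kdata), kin$MW)
  pr <- config$products
  fc <- fold_change(pr$a, pr$b, pr$a_sd, pr$b_sd)
  report <- list(
    lineweaver_burk = glance(fit_lb),
    nonlinear = glance(fit_nls),
    fold_change = fc
  )
  emit(report, "kinetics_report.json",
       function(obj, path) jsonlite::write_json(obj, path, digits = 10,
                                                dataframe = "rows"))

  if (plots) {
    tryCatch({
      for (nm in names(maps))
        ggplot2::ggsave(file.path(output_dir,
                                  paste0("density_diff_", nm, ".png")),
                        autoplot(maps[[nm]]), width = 6, height = 4,
                        dpi = 120)
      ggplot2::ggsave(file.path(output_dir, "rmsf_profiles.png"),
                      autoplot(prof$wt, compare = prof$mut),
                      width = 7, height = 4, dpi = 120)
      ggplot2::ggsave(file.path(output_dir, "kinetics_fit.png"),
                      autoplot(fit_lb), width = 5, height = 4, dpi = 120)
      written <- c(written, file.path(output_dir, c(
        paste0("density_diff_", names(maps), ".png"),
        "rmsf_profiles.png", "kinetics_fit.png")))
    }, error = function(e)
      warn(paste0("plot output skipped: ", conditionMessage(e))))
  }

  manifest <- list(
    package = "glycoscreen",
    version = as.character(utils::packageVersion("glycoscreen")),
    seed = config$seed,
    config = unclass(config),
    files = tibble(file = basename(written),
                   md5 = unname(tools::md5sum(written)))
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, dataframe = "rows")

  invisible(list(geometries = geoms, maps = maps, summary = summary_tbl,
                 rmsf = prof, flexibility = flex,
                 fits = list(lineweaver_burk = fit_lb, nonlinear = fit_nls),
                 fold_change = fc, output_dir = output_dir,
                 manifest = manifest))
}
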