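.fmt6 <- function(x) {
  if (is.numeric(x)) sprintf("%.6f", x) else x
}

#' Write a data frame as a diff-stable CSV
#'
#' All floating-point columns are written at fixed 6-decimal formatting so
#' repeated runs with the same configuration produce byte-identical files.
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.6f", out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a run configuration
#'
#' Bundles inputs and the analysis cutoffs into one validated list that is
#' serialised into every output directory. Defaults follow the shipped
#' conventions: contact cutoff 4.5 Angstrom, hydration cutoff 3.0, cluster
#' cutoff 1.0 with 10 clusters, crop preset 60/10, frame interval 0.4 ns.
#'
#' @param structure a `Structure` (or path readable by [read_structure()]).
#' @param trajectory a `Trajectory` (or multi-model PDB path), optional.
#' @param subunits a `SubunitMap`; default inferred from the structure when
#'   needed.
#' @param anchors prime anchors per class.
#' @param ecd upper-ECD ranges (`EcdRanges`).
#' @param ligand_resname residue name of the ligand (default "DHS").
#' @param contact_cutoff,hydration_cutoff,cluster_cutoff,cluster_max,crop
#'   analysis parameters; `crop` is a list(crop_threshold, crop_value) or
#'   NULL.
#' @param pmf optional list(potential, n, step, bin_width, gate_window) for
#'   the sampling + inversion stage.
#' @param seed integer seed for stochastic stages.
#' @param frame_interval ns.
#' @return object of class `RunConfig`.
#' @export
run_config <- function(structure = NULL, trajectory = NULL, subunits = NULL,
                       anchors = gabaa_config()$anchors,
                       ecd = gabaa_config()$ecd_ranges,
                       ligand_resname = "DHS",
                       contact_cutoff = 4.5, hydration_cutoff = 3.0,
                       cluster_cutoff = 1.0, cluster_max = 10L,
                       crop = NULL, pmf = NULL, seed = 1L,
                       frame_interval = 0.4) {
  cfg <- list(structure = structure, trajectory = trajectory,
              subunits = subunits, anchors = anchors, ecd = ecd,
              ligand_resname = ligand_resname,
              contact_cutoff = contact_cutoff,
              hydration_cutoff = hydration_cutoff,
              cluster_cutoff = cluster_cutoff,
              cluster_max = as.integer(cluster_max),
              crop = crop, pmf = pmf, seed = as.integer(seed),
              frame_interval = frame_interval)
  class(cfg) <- "RunConfig"
  cfg
}

.config_digest <- function(cfg) {
  # structural fingerprint of the scalar configuration (no file hashing)
  scalars <- cfg[c("ligand_resname", "contact_cutoff", "hydration_cutoff",
                   "cluster_cutoff", "cluster_max", "seed",
                   "frame_interval")]
  paste(unlist(lapply(scalars, format)), collapse = "|")
}

#' Run analysis recipes end to end
#'
#' Executes the requested stages in dependency order against the configured
#' structure/trajectory, writing one CSV or JSON per stage plus a manifest
#' (inputs, configuration, package version, seed) into `out_dir`. Stages:
#' `pore` (profile + gate report), `ligand` (RMSD/z traces + clustering),
#' `contacts`, `hydration`, `spread`, `pmf`.
#'
#' @param config a `RunConfig`.
#' @param recipes character subset of
#'   `c("pore","ligand","contacts","hydration","spread","pmf")`.
#' @param out_dir output directory (created if needed).
#' @return named list of stage results, invisibly; side effect: files under
#'   `out_dir`.
#' @export
run_pipeline <- function(config, recipes, out_dir) {
  stopifnot(inherits(config, "RunConfig"), length(recipes) >= 1)
  recipes <- match.arg(recipes,
                       c("pore", "ligand", "contacts", "hydration",
                         "spread", "pmf"), several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  manifest <- list(package = "porescope",
                   version = as.character(utils::packageVersion("porescope")),
                   seed = config$seed, config_digest = .config_digest(config),
                   recipes = recipes, stages = list())

  s <- config$structure
  if (is.character(s)) s <- read_structure(s)
  traj <- config$trajectory
  if (is.character(traj))
    traj <- read_trajectory(traj, frame_interval = config$frame_interval)

  need_axis <- any(recipes %in% c("pore", "ligand", "contacts", "hydration",
                                  "spread"))
  sm <- config$subunits
  pm <- NULL
  aligned <- NULL
  if (need_axis) {
    ref <- if (!is.null(s)) s else traj$topology
    if (is.null(ref)) stop("stage needs a structure or trajectory input")
    if (is.null(sm)) sm <- infer_subunit_map(ref, anchors = config$anchors)
    pm <- build_prime_map(ref, sm, anchors = config$anchors)
    aligned <- align_pore_axis(ref, sm, pm)
    if (!is.null(traj)) traj <- transform_trajectory(traj, aligned$transform)
  }

  lig_sel <- function(top)
    select_atoms(top, resid = config$ligand_resname, heavy = TRUE)

  for (r in recipes) {
    res <- switch(r,
      pore = {
        prof <- pore_profile(aligned$structure)
        gates <- gate_diameters(prof, pm, aligned$structure)
        write_result_csv(as.data.frame(prof)[, c("z", "radius")],
                         file.path(out_dir, "pore_profile.csv"))
        jsonlite::write_json(
          setNames(as.list(gates$diameter), as.character(gates$prime)),
          file.path(out_dir, "gate_diameters.json"),
          auto_unbox = TRUE, digits = NA)
        list(profile = prof, gates = gates)
      },
      ligand = {
        lg <- lig_sel(traj$topology)
        tr <- ligand_rmsd_trace(traj, lg,
                                crop_threshold = config$crop$crop_threshold,
                                crop_value = config$crop$crop_value %||% 10)
        zt <- ligand_z_trace(traj, lg)
        cl <- cluster_poses(traj, lg, cutoff = config$cluster_cutoff,
                            max_clusters = config$cluster_max)
        write_result_csv(as.data.frame(tr),
                         file.path(out_dir, "ligand_rmsd.csv"))
        write_result_csv(as.data.frame(zt),
                         file.path(out_dir, "ligand_z.csv"))
        jsonlite::write_json(
          list(populations = cl$populations,
               representatives = cl$representatives, cutoff = cl$cutoff),
          file.path(out_dir, "clusters.json"), auto_unbox = TRUE, digits = NA)
        write_representatives(traj, cl,
                              file.path(out_dir, "representatives.pdb"))
        list(rmsd = tr, z = zt, clusters = cl)
      },
      contacts = {
        ct <- contact_frequencies(traj, lig_sel(traj$topology),
                                  cutoff = config$contact_cutoff)
        ct2 <- annotate_primes(ct, pm)
        write_result_csv(as.data.frame(ct2),
                         file.path(out_dir, "contacts.csv"))
        ct2
      },
      hydration = {
        ht <- hydration_count(traj, prime_map = pm,
                              cutoff = config$hydration_cutoff)
        write_result_csv(as.data.frame(ht),
                         file.path(out_dir, "hydration.csv"))
        ht
      },
      spread = {
        st <- ecd_spread(traj, config$ecd, sm)
        write_result_csv(as.data.frame(st),
                         file.path(out_dir, "ecd_spread.csv"))
        st
      },
      pmf = {
        p <- config$pmf
        if (is.null(p)) stop("pmf stage requested without a pmf config")
        sam <- metropolis_sample(p$potential, n = p$n %||% 1e5,
                                 step = p$step %||% 0.1, seed = config$seed)
        prof <- boltzmann_invert(sam, bin_width = p$bin_width %||% 0.05)
        bh <- barrier_height(prof, p$gate_window %||% c(-0.5, 0.5))
        write_result_csv(as.data.frame(prof)[, c("z", "free_energy", "count")],
                         file.path(out_dir, "pmf_profile.csv"))
        jsonlite::write_json(bh, file.path(out_dir, "pmf_barrier.json"),
                             auto_unbox = TRUE, digits = NA)
        list(samples = sam, profile = prof, barrier = bh)
      })
    results[[r]] <- res
    manifest$stages[[r]] <- list(status = "ok")
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(results)
}
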