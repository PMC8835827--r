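#' Read and validate a pipeline run configuration
#'
#' YAML layout (paths resolved relative to the config file):
#' \preformatted{
#' topology: system.pdb        # single- or multi-model PDB
#' trajectory: traj.dcd        # DCD, or omitted if topology is multi-model
#' domain_map: domains.yaml
#' fit_residues: ["582-688", "769-931"]
#' analysis_stride: 1          # frames (10 ps equivalent at dt = 10 ps)
#' clustering_stride: 10       # frames (100 ps equivalent)
#' temperature: 310
#' fel_bins: 100
#' cluster_cutoffs: [2, 2.5, 3, 3.5, 4, 4.5, 5]
#' seed: 1
#' out_dir: results
#' }
#'
#' @param path YAML config file, or an already-parsed list (then
#'   \code{base_dir} applies).
#' @param base_dir directory for relative paths.
#' @return validated config list of class \code{"run_config"}.
#' @export
read_run_config <- function(path, base_dir = NULL) {
  if (is.character(path)) {
    base_dir <- base_dir %||% dirname(path)
    cfg <- yaml::read_yaml(path)
  } else {
    cfg <- path
    base_dir <- base_dir %||% "."
  }
  rel <- function(p) if (!is.null(p) && !grepl("^(/|[A-Za-z]:)", p))
    file.path(base_dir, p) else p
  cfg$topology <- rel(cfg$topology)
  cfg$trajectory <- rel(cfg$trajectory)
  cfg$domain_map <- rel(cfg$domain_map)
  if (is.null(cfg$topology)) stop("config error: 'topology' path is required")
  for (p in c("topology", "trajectory", "domain_map")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stop("config error: ", p, " path does not exist: ", cfg[[p]])
  }
  cfg$analysis_stride <- as.integer(cfg$analysis_stride %||% 1L)
  cfg$clustering_stride <- as.integer(cfg$clustering_stride %||% 10L)
  if (cfg$analysis_stride < 1 || cfg$clustering_stride < 1)
    stop("config error: strides must be >= 1")
  cfg$temperature <- cfg$temperature %||% 310
  cfg$fel_bins <- cfg$fel_bins %||% 100
  cfg$cluster_cutoffs <- cfg$cluster_cutoffs %||% seq(2, 5, by = 0.5)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$out_dir <- cfg$out_dir %||% "kitdyn_results"
  cfg$fit_residues <- cfg$fit_residues %||% c("582-688", "769-931")
  structure(cfg, class = c("run_config", "list"))
}

parse_ranges <- function(x) {
  unlist(lapply(x, function(r) {
    v <- as.integer(strsplit(as.character(r), "[-:]")[[1]])
    seq.int(v[1], v[2])
  }))
}

#' Run the complete trajectory post-analysis pipeline
#'
#' Executes, in order: superposition normalization; RMSD / RMSF / Rg;
#' secondary-structure timeline; centroid tetrahedron and hint-vector
#' bending / TM kink angles; H-bond and hydrophobic occurrence patterns
#' with regular-structure exclusion; ensemble-clustering cutoff sweep;
#' DCCM, backbone PCA and elastic-network modes; global and per-domain
#' free-energy landscapes.  Every stage writes TSV output under
#' \code{out_dir} and the run ends with a JSON manifest of files, seeds
#' and parameters.  A stage failure aborts with an error naming the stage;
#' outputs of completed stages are preserved.
#'
#' @param config a \code{\link{read_run_config}} result (or path to one).
#' @param stages character vector of stage names to run (default all):
#'   rmsd, secstruct, geometry, hbonds, cluster, dccm, pca, enm, fel.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config,
                         stages = c("rmsd", "secstruct", "geometry", "hbonds",
                                    "cluster", "dccm", "pca", "enm", "fel")) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(f) file.path(config$out_dir, f)
  manifest <- list(package = "kitdyn",
                   version = as.character(utils::packageVersion("kitdyn")),
                   seed = config$seed,
                   parameters = config[setdiff(names(config),
                                               c("out_dir"))],
                   stages = list())
  t_all <- proc.time()[3]
  stage <- function(name, fun) {
    if (!name %in% stages) return(invisible(NULL))
    t0 <- proc.time()[3]
    message(sprintf("[kitdyn] stage %s ...", name))
    files <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    # timings go to stderr only, so the manifest is run-to-run identical
    manifest$stages[[name]] <<- list(files = basename(unlist(files)))
    message(sprintf("[kitdyn] stage %s done (%.1fs)", name,
                    proc.time()[3] - t0))
  }

  sys <- read_pdb_system(config$topology)
  top <- sys$topology
  traj <- if (!is.null(config$trajectory))
    read_dcd_trajectory(config$trajectory, top) else sys$trajectory
  map <- if (!is.null(config$domain_map))
    load_domain_map(config$domain_map, top) else NULL
  fit_res <- parse_ranges(config$fit_residues)
  fit_sel <- selection(residues = fit_res, atom_names = "CA")
  ca_all <- ca_selection(NULL)
  stride <- config$analysis_stride
  sub <- function(tr, by) trajectory(tr$coords[seq(1, n_frames(tr), by = by),
                                               , , drop = FALSE],
                                     time_step_ps = tr$time_step_ps * by)
  atraj <- if (stride > 1) sub(traj, stride) else traj
  # normalization: everything downstream works on the fitted trajectory
  fitted <- fit_trajectory(atraj, fit = fit_sel, top = top)
  ref <- get_frame(fitted, 1)

  stage("rmsd", function() {
    rs <- rmsd_series(fitted, ref, fit = NULL, measure = ca_all, top = top)
    rf <- rmsf(fitted, ref, measure = ca_all, top = top)
    rf$res_index <- top$res_index[rf$atom]
    rg <- rg_series(fitted, top)
    list(write_tsv_table(rs, outfile("rmsd_ca.tsv"), "Calpha RMSD vs t0"),
         write_tsv_table(rf, outfile("rmsf_ca.tsv"), "Calpha RMSF"),
         write_tsv_table(rg, outfile("rg.tsv"), "radius of gyration"))
  })
  ss <- NULL
  stage("secstruct", function() {
    ss <<- ss_timeline(fitted, top)
    write_ss_timeline(ss, outfile("secstruct.tsv"))
    freq <- data.frame(residue = rownames(ss$frequencies),
                       ss$frequencies, check.names = FALSE)
    list(outfile("secstruct.tsv"),
         write_tsv_table(freq, outfile("secstruct_freq.tsv"),
                         "per-residue label frequencies"))
  })
  stage("geometry", function() {
    files <- list()
    if (!is.null(map)) {
      have <- function(nm) nm %in% names(map$domains)
      if (all(vapply(c("NLOBE", "CLOBE", "KID", "CTAIL"), have, TRUE))) {
        nodes <- lapply(c("NLOBE", "CLOBE", "KID", "CTAIL"), function(nm)
          ca_selection(domain_residues(map, nm)))
        names(nodes) <- c("NLOBE", "CLOBE", "KID", "CTAIL")
        tet <- tetrahedron_series(fitted, top, nodes)
        files <- c(files, write_tsv_table(tet, outfile("tetrahedron.tsv"),
                                          "centroid tetrahedron distances"))
      }
      hints <- names(map$hints)
      if (length(hints) >= 2) {
        b <- bending_series(fitted, top, map$hints[[hints[1]]],
                            map$hints[[hints[2]]])
        files <- c(files,
                   write_tsv_table(b, outfile(sprintf("bending_%s_%s.tsv",
                                                      hints[1], hints[2])),
                                   "hint-vector bending angle"))
      }
      if ("TM" %in% hints) {
        hr <- map$hints[["TM"]]
        hinge <- 530L
        if (hinge > hr[1] + 1 && hinge < hr[2] - 1) {
          tm_sel <- ca_selection(seq.int(hr[1], hr[2]))
          tm_fit <- fit_trajectory(atraj, fit = tm_sel, top = top)
          kk <- vapply(seq_len(n_frames(tm_fit)), function(f)
            kink_angle(get_frame(tm_fit, f), top, hr, hinge), numeric(1))
          files <- c(files, write_tsv_table(
            data.frame(frame = seq_along(kk),
                       time_ps = (seq_along(kk) - 1) * atraj$time_step_ps,
                       kink_deg = kk),
            outfile("tm_kink.tsv"), "TM helix kink angle at V530"))
        }
      }
    }
    files
  })
  stage("hbonds", function() {
    hb <- occurrence_pattern(fitted, top, type = "hbond", domains = map)
    hp <- occurrence_pattern(fitted, top, type = "hydrophobic", domains = map)
    files <- list(write_contact_pattern(hb, outfile("hbond_pattern.tsv")),
                  write_contact_pattern(hp, outfile("hydrophobic_pattern.tsv")))
    if (!is.null(ss) && !is.null(map)) {
      ex <- exclude_regular_structure(hb, ss, map)
      files <- c(files,
                 write_contact_pattern(ex, outfile("hbond_interdomain.tsv")))
    }
    files
  })
  stage("cluster", function() {
    cstride <- max(1L, config$clustering_stride %/% stride)
    sw <- cutoff_sweep(fitted, top, ca_all, cutoffs = config$cluster_cutoffs,
                       seed = config$seed, mode = "context", fit = fit_sel,
                       stride = cstride)
    files <- list(write_tsv_table(sw$summary, outfile("cluster_sweep.tsv"),
                                  "cutoff sweep summary"))
    best <- which.max(sw$summary$cumulative_major_pct)
    files <- c(files, write_cluster_table(sw$sets[[best]],
                                          outfile("clusters.tsv")))
    files
  })
  stage("dccm", function() {
    C <- dccm_map(fitted, top, ca_all)
    list(write_dynamics(C, outfile("dccm_trajectory.tsv")))
  })
  pca_res <- NULL
  stage("pca", function() {
    pca_res <<- pca_modes(fitted, top,
                          selection(atom_names = c("N", "H", "CA", "C", "O")),
                          fit = fit_sel)
    vf <- data.frame(mode = seq_along(pca_res$eigenvalues),
                     eigenvalue = pca_res$eigenvalues,
                     variance_fraction = pca_res$variance_fraction,
                     cumulative = cumsum(pca_res$variance_fraction))
    list(write_tsv_table(utils::head(vf, 50), outfile("pca_spectrum.tsv"),
                         "PCA eigenvalue spectrum"),
         write_dynamics(pca_res, outfile("pca_modes.tsv")))
  })
  stage("enm", function() {
    ca_idx <- resolve_selection(ca_all, top)
    mean_ca <- mean_conformation(fitted)[ca_idx, ]
    enm <- enm_modes(mean_ca, temperature = config$temperature)
    C <- enm_dccm(enm)
    sp <- data.frame(mode = seq_along(enm$eigenvalues),
                     eigenvalue = enm$eigenvalues)
    list(write_dynamics(C, outfile("dccm_enm.tsv")),
         write_tsv_table(utils::head(sp, 50), outfile("enm_spectrum.tsv"),
                         "elastic-network spectrum"))
  })
  stage("fel", function() {
    rs <- rmsd_series(fitted, ref, fit = NULL, measure = ca_all, top = top)
    rg <- rg_series(fitted, top)
    files <- list()
    fel_g <- tryCatch(
      free_energy_landscape(rs$rmsd, rg$rg, c("RMSD", "Rg"),
                            bins = config$fel_bins,
                            temperature = config$temperature),
      error = function(e) NULL)
    if (!is.null(fel_g))
      files <- c(files, write_fel(fel_g, outfile("fel_global.tsv"),
                                  wells = find_wells(fel_g)))
    if (!is.null(pca_res) && ncol(pca_res$projections) >= 2) {
      fel_pc <- free_energy_landscape(pca_res$projections[, 1],
                                      pca_res$projections[, 2],
                                      c("PC1", "PC2"),
                                      bins = config$fel_bins,
                                      temperature = config$temperature)
      files <- c(files, write_fel(fel_pc, outfile("fel_pc12.tsv"),
                                  wells = find_wells(fel_pc)))
    }
    if (!is.null(map)) {
      fl <- per_domain_fel(fitted, top, map, fit = fit_sel,
                           bins = config$fel_bins,
                           temperature = config$temperature)
      for (nm in names(fl))
        files <- c(files, write_fel(fl[[nm]],
                                    outfile(sprintf("fel_domain_%s.tsv", nm)),
                                    wells = find_wells(fl[[nm]])))
    }
    files
  })
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  message(sprintf("[kitdyn] pipeline complete in %.1fs -> %s",
                  manifest$elapsed_seconds, config$out_dir))
  invisible(manifest)
}
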