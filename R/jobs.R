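# Job driver: YAML job configuration -> dispatch to the package operations
# -> JSON results + artifacts.  The schema is strict (unknown keys are
# rejected) and all atom index lists in configs are 0-based (stated in the
# CLI help); internally everything is 1-based R indexing.

.check_keys <- function(block, allowed, where) {
  if (is.null(block)) return(invisible(NULL))
  bad <- setdiff(names(block), allowed)
  if (length(bad)) {
    stop("unknown key(s) in ", where, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(NULL)
}

.cfg_fragment <- function(block, where = "fragment") {
  .check_keys(block, c("xyz", "pdb", "fixture", "charge", "mult"), where)
  if (!is.null(block$fixture)) {
    fx <- block$fixture
    # YAML 1.1 parses a bare key `n` as a boolean; accept `size` as the
    # documented key and normalize the boolean-ized spelling
    names(fx)[names(fx) %in% c("FALSE", "n")] <- "size"
    .check_keys(fx, c("kind", "size", "seed", "jitter"), paste0(where, ".fixture"))
    fix <- generate_fixture(fx$kind, n = fx$size %||% 4, seed = fx$seed %||% 1,
                            jitter = fx$jitter %||% 0.05)
    return(list(fragment = fix$fragment, fixture = fix))
  }
  frag <- if (!is.null(block$xyz)) {
    read_xyz(block$xyz, charge = block$charge %||% 0, mult = block$mult %||% 1)
  } else if (!is.null(block$pdb)) {
    read_pdb(block$pdb, charge = block$charge %||% 0, mult = block$mult %||% 1)
  } else stop(where, " needs one of: xyz, pdb, fixture")
  list(fragment = frag, fixture = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.cfg_theory <- function(block, fixture, frag, where = "theory") {
  .check_keys(block, c("type", "name", "embedding", "charge_scheme",
                       "dipole_correction", "qm_atoms", "linkatom",
                       "allow_unusual_boundary", "layers", "components",
                       "weights", "step_ang", "formula"), where)
  type <- block$type %||% stop(where, ": missing type")
  zb <- function(ix) as.integer(ix) + 1L      # 0-based config -> 1-based
  switch(type,
    forcefield = {
      if (is.null(fixture)) stop(where, ": forcefield theory requires a fixture fragment")
      forcefield_theory(fixture$ff_spec)
    },
    mockqm = {
      if (is.null(fixture)) stop(where, ": mockqm theory requires a fixture fragment")
      mockqm_theory(fixture$qm_spec)
    },
    surface2d = surface2d_theory(block$name %||% "muller_brown"),
    qmmm = {
      if (is.null(fixture)) stop(where, ": qmmm theory requires a fixture fragment")
      la <- block$linkatom %||% list()
      .check_keys(la, c("element", "mode", "distance"), paste0(where, ".linkatom"))
      qmmm_theory(fixture$qm_spec, fixture$ff_spec, frag,
                  qm_atoms = zb(block$qm_atoms %||% (fixture$qm_atoms - 1L)),
                  embedding = block$embedding %||% "electrostatic",
                  charge_scheme = block$charge_scheme %||% "shift",
                  dipole_correction = block$dipole_correction %||% TRUE,
                  link_element = la$element %||% "H",
                  link_mode = la$mode %||% "fixed",
                  link_distance = la$distance %||% 1.09,
                  allow_unusual = block$allow_unusual_boundary %||% FALSE)
    },
    oniom = {
      if (is.null(fixture)) stop(where, ": oniom theory requires a fixture fragment")
      layers <- lapply(block$layers, zb)
      oniom_theory(frag, layers,
                   specs = c(list(fixture$qm_spec),
                             rep(list(fixture$ff_spec), length(layers))),
                   embedding = block$embedding %||% "mechanical",
                   allow_unusual = TRUE)
    },
    wrap = {
      comps <- lapply(block$components, .cfg_theory, fixture = fixture,
                      frag = frag, where = paste0(where, ".components"))
      wrap_theory(comps, weights = block$weights %||% rep(1, length(comps)))
    },
    numgrad = {
      inner <- .cfg_theory(block$components[[1]], fixture, frag,
                           paste0(where, ".components"))
      numgrad_theory(inner, step = block$step_ang %||% 1e-3,
                     formula = block$formula %||% "two-point")
    },
    stop(where, ": unknown theory type '", type, "'")
  )
}

.cfg_opt_settings <- function(block) {
  .check_keys(block, c("max_iter", "conv_grad_max", "conv_grad_rms",
                       "conv_step_max", "conv_step_rms", "conv_e_change",
                       "history_size", "max_step", "active_atoms"), "opt")
  s <- opt_settings()
  for (k in intersect(names(block), names(s))) s[[k]] <- block[[k]]
  s
}

#' Run a configured job
#'
#' Dispatches a YAML/list job configuration to the package operations and
#' writes a JSON results file plus artifacts (final geometries as XYZ, scan
#' tables as TSV, trajectories) into the output directory. Atom index lists
#' in configs are 0-based.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @param output_dir overrides the config's output directory.
#' @return invisibly, the results list (also serialized to
#'   \code{results.json}).
#' @export
run_job <- function(config, output_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  .check_keys(cfg, c("job", "seed", "output_dir", "fragment", "product",
                     "theory", "theory2", "opt", "scan", "neb", "md",
                     "numfreq", "gradient"), "config")
  job <- cfg$job %||% stop("config: missing job")
  seed <- cfg$seed %||% 1
  set.seed(seed)
  outdir <- output_dir %||% cfg$output_dir %||% "."
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  fr <- .cfg_fragment(cfg$fragment)
  frag <- fr$fragment
  theory <- .cfg_theory(cfg$theory, fr$fixture, frag)
  results <- list(job = job, seed = seed, n_atoms = n_atoms(frag))
  zb <- function(ix) as.integer(ix) + 1L

  t0 <- Sys.time()
  msg <- function(...) message(sprintf("[mschem %s] %s", job, sprintf(...)))
  msg("starting (seed %d, %d atoms)", seed, n_atoms(frag))

  if (job == "singlepoint") {
    want_grad <- isTRUE(cfg$gradient)
    res <- evaluate(theory, frag, gradient = want_grad)
    results$energy <- res$energy
    if (want_grad) results$gradient <- res$gradient
    if (!is.null(res$extra$breakdown)) results$breakdown <- res$extra$breakdown
  } else if (job == "opt") {
    s <- .cfg_opt_settings(cfg$opt %||% list())
    act <- if (!is.null(cfg$opt$active_atoms)) zb(cfg$opt$active_atoms) else NULL
    opt <- lbfgs_minimize(theory, frag, s, active_atoms = act)
    path <- file.path(outdir, "final.xyz")
    write_xyz(opt$fragment, path, comment = sprintf("E = %.10f", utils::tail(opt$energies, 1)))
    results$energy <- utils::tail(opt$energies, 1)
    results$converged <- opt$converged
    results$iterations <- opt$iterations
    results$final_xyz <- path
  } else if (job == "scan") {
    sc <- cfg$scan
    .check_keys(sc, c("type", "atoms", "values", "type2", "atoms2", "values2",
                      "relaxed"), "scan")
    coords <- list(list(type = sc$type, atoms = zb(sc$atoms)))
    grid <- list(as.numeric(sc$values))
    if (!is.null(sc$type2)) {
      coords <- c(coords, list(list(type = sc$type2, atoms = zb(sc$atoms2))))
      grid <- c(grid, list(as.numeric(sc$values2)))
    }
    tab <- scan_surface(theory, frag, coords, grid,
                        relaxed = sc$relaxed %||% TRUE,
                        settings = .cfg_opt_settings(cfg$opt %||% list()))
    path <- file.path(outdir, "scan.tsv")
    utils::write.table(as.data.frame(tab), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    results$scan_tsv <- path
    results$energies <- tab$energy
  } else if (job == "ts") {
    H <- numerical_hessian(theory, frag)
    opt <- prfo_ts_opt(theory, frag, H, .cfg_opt_settings(cfg$opt %||% list()))
    path <- file.path(outdir, "ts.xyz")
    write_xyz(opt$fragment, path)
    results$energy <- utils::tail(opt$energies, 1)
    results$converged <- opt$converged
    results$neg_eigenvalues <- opt$neg_eigenvalues
    results$final_xyz <- path
  } else if (job == "mecp") {
    theory2 <- .cfg_theory(cfg$theory2, fr$fixture, frag, "theory2")
    opt <- mecp_optimize(theory, theory2, frag, .cfg_opt_settings(cfg$opt %||% list()))
    results$converged <- opt$converged
    results$energy_A <- opt$energies_AB[1]
    results$energy_B <- opt$energies_AB[2]
    results$gap <- abs(diff(opt$energies_AB))
  } else if (job %in% c("neb", "neb-ts")) {
    pr <- .cfg_fragment(cfg$product, "product")
    nb <- cfg$neb %||% list()
    .check_keys(nb, c("n_images", "k_min", "k_max", "climb", "conv_fmax",
                      "loose_fmax"), "neb")
    if (job == "neb") {
      r <- neb_optimize(theory, frag, pr$fragment,
                        n_images = nb$n_images %||% 10,
                        k_min = nb$k_min %||% 0.01, k_max = nb$k_max %||% 0.1,
                        climb = nb$climb %||% TRUE,
                        conv_fmax = nb$conv_fmax %||% 1e-3)
      path <- file.path(outdir, "path.tsv")
      utils::write.table(data.frame(image = seq_along(r$energies),
                                    energy = r$energies),
                         path, sep = "\t", row.names = FALSE, quote = FALSE)
      results$converged <- r$converged
      results$barrier <- max(r$energies) - r$energies[1]
      results$energies <- r$energies
      results$path_tsv <- path
    } else {
      r <- neb_ts(theory, frag, pr$fragment, n_images = nb$n_images %||% 10,
                  loose_fmax = nb$loose_fmax %||% 5e-3)
      results$converged <- r$saddle$converged
      results$saddle_energy <- utils::tail(r$saddle$energies, 1)
      results$saddle_ok <- r$saddle$saddle_ok
      results$n_gradient_calls <- r$n_gradient_calls
    }
  } else if (job == "numfreq") {
    nf <- cfg$numfreq %||% list()
    .check_keys(nf, c("step_ang", "formula", "hess_atoms", "runmode",
                      "thermo"), "numfreq")
    hatoms <- if (!is.null(nf$hess_atoms)) zb(nf$hess_atoms) else NULL
    H <- numerical_hessian(theory, frag,
                           step = nf$step_ang %||% (0.005 * units_au$bohr_to_ang),
                           formula = nf$formula %||% "two-point",
                           hess_atoms = hatoms,
                           runmode = nf$runmode %||% "serial")
    hpath <- file.path(outdir, "hessian.txt")
    write_hessian(H, frag, hpath, step = nf$step_ang %||% NA)
    va <- harmonic_analysis(H, frag, project = is.null(hatoms), atoms = hatoms)
    th <- nf$thermo %||% list()
    .check_keys(th, c("T", "P", "sigma", "quasi_rrho", "cutoff"), "numfreq.thermo")
    tr <- thermochemistry(va, frag, T = th$T %||% 298.15, P = th$P %||% 101325,
                          sigma = th$sigma %||% 1,
                          quasi_rrho = th$quasi_rrho %||% "none",
                          cutoff = th$cutoff %||% 100)
    fpath <- file.path(outdir, "frequencies.tsv")
    utils::write.table(data.frame(mode = seq_along(va$frequencies),
                                  frequency_cm1 = va$frequencies),
                       fpath, sep = "\t", row.names = FALSE, quote = FALSE)
    results$frequencies_cm1 <- va$frequencies
    results$hessian_txt <- hpath
    results$frequencies_tsv <- fpath
    results$thermo <- unclass(tr)
  } else if (job == "md") {
    mdc <- cfg$md %||% list()
    .check_keys(mdc, c("dt_fs", "n_steps", "ensemble", "temperature_K",
                       "friction_ps", "frozen_atoms", "traj_stride"), "md")
    st <- md_settings(dt_fs = mdc$dt_fs %||% 0.5,
                      n_steps = mdc$n_steps %||% 100,
                      ensemble = mdc$ensemble %||% "nve",
                      temperature_K = mdc$temperature_K %||% 300,
                      friction_ps = mdc$friction_ps %||% 1,
                      seed = seed,
                      frozen_atoms = if (!is.null(mdc$frozen_atoms)) zb(mdc$frozen_atoms) else NULL,
                      traj_stride = mdc$traj_stride %||% 1)
    traj <- run_md(theory, frag, st)
    lp <- file.path(outdir, "md_log.tsv")
    xp <- file.path(outdir, "md_traj.xyz")
    write_trajectory(traj, xyz_path = xp, log_path = lp)
    lg <- traj$log
    results$mean_temperature_K <- mean(lg$temperature_K[-1])
    results$energy_drift <- lg$etot[nrow(lg)] - lg$etot[1]
    results$md_log_tsv <- lp
    results$md_traj_xyz <- xp
  } else {
    stop("unknown job type '", job, "'")
  }

  results$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jpath <- file.path(outdir, "results.json")
  jsonlite::write_json(results, jpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  msg("done in %.2f s -> %s", results$elapsed_s, jpath)
  invisible(results)
}
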