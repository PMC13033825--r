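# Theory-agnostic Born-Oppenheimer molecular dynamics: velocity-Verlet NVE
# and BAOAB-split Langevin NVT, driven by any theory's forces.
#
# Interface units: dt in fs, temperature in K, friction in 1/ps.
# Internal units: atomic units throughout (Bohr, electron masses, Hartree,
# atomic time units; 1 a.t.u. = 2.4188843e-2 fs).

#' Molecular-dynamics settings
#'
#' @param dt_fs time step, fs.
#' @param n_steps number of steps.
#' @param ensemble "nve" or "nvt_langevin".
#' @param temperature_K target temperature (NVT), K.
#' @param friction_ps Langevin friction, 1/ps.
#' @param seed integer seed (mandatory for NVT; also used by
#'   \code{\link{initialize_velocities}} when run_md initializes).
#' @param frozen_atoms indices never moved (no velocity accumulated).
#' @param traj_stride store every k-th frame (default 1).
#' @return list of class \code{md_settings}.
#' @export
md_settings <- function(dt_fs, n_steps, ensemble = c("nve", "nvt_langevin"),
                        temperature_K = 300, friction_ps = 1, seed = 1,
                        frozen_atoms = NULL, traj_stride = 1) {
  ensemble <- match.arg(ensemble)
  stopifnot(dt_fs > 0, n_steps >= 1, friction_ps >= 0, traj_stride >= 1)
  if (ensemble == "nvt_langevin" && temperature_K <= 0) {
    stop("NVT requires temperature > 0")
  }
  structure(list(dt_fs = dt_fs, n_steps = as.integer(n_steps),
                 ensemble = ensemble, temperature_K = temperature_K,
                 friction_ps = friction_ps, seed = as.integer(seed),
                 frozen_atoms = frozen_atoms,
                 traj_stride = as.integer(traj_stride)),
            class = "md_settings")
}

#' Maxwell-Boltzmann initial velocities
#'
#' Per-component Gaussians with variance kB T / m_i (atomic units), with
#' the centre-of-mass momentum removed; frozen atoms get zero velocity.
#' Deterministic under the seed.
#'
#' @param frag the \code{fragment}.
#' @param T temperature, K (0 gives zero velocities).
#' @param seed integer seed.
#' @param frozen_atoms optional frozen atom indices.
#' @return N x 3 matrix of velocities in Bohr per atomic time unit.
#' @export
initialize_velocities <- function(frag, T, seed, frozen_atoms = NULL) {
  if (T < 0) stop("temperature must be >= 0")
  n <- n_atoms(frag)
  m <- frag$masses * units_au$amu_to_me
  v <- matrix(0.0, n, 3)
  if (T > 0) {
    set.seed(seed)
    sd <- sqrt(units_au$kB_hartree * T / m)
    v <- matrix(stats::rnorm(3 * n), n, 3) * sd
    active <- setdiff(seq_len(n), frozen_atoms)
    v[setdiff(seq_len(n), active), ] <- 0
    # remove centre-of-mass momentum of the active atoms
    p_com <- colSums(v[active, , drop = FALSE] * m[active]) / sum(m[active])
    v[active, ] <- sweep(v[active, , drop = FALSE], 2, p_com)
  }
  if (!is.null(frozen_atoms)) v[frozen_atoms, ] <- 0
  v
}

#' Run Born-Oppenheimer molecular dynamics
#'
#' NVE uses velocity Verlet; NVT uses the BAOAB splitting of Langevin
#' dynamics (half kick, half drift, Ornstein-Uhlenbeck, half drift, half
#' kick). With friction 0 and the same seed, BAOAB reduces exactly to
#' velocity Verlet. Any theory kind is accepted; a non-finite force aborts
#' with the offending step index.
#'
#' @param theory gradient-capable theory.
#' @param frag starting \code{fragment}.
#' @param settings an \code{\link{md_settings}}.
#' @param velocities optional starting velocities (Bohr/a.t.u.); defaults
#'   to Maxwell-Boltzmann at the target temperature (NVT) or zero (NVE).
#' @return object of class \code{md_trajectory}: data frame \code{log}
#'   (time_fs, epot, ekin, etot in Hartree, temperature_K), list
#'   \code{frames} of coordinate matrices (Angstrom), final
#'   \code{fragment} and \code{velocities}.
#' @export
run_md <- function(theory, frag, settings, velocities = NULL) {
  stopifnot(inherits(settings, "md_settings"))
  n <- n_atoms(frag)
  m <- frag$masses * units_au$amu_to_me
  frozen <- settings$frozen_atoms
  active <- setdiff(seq_len(n), frozen)
  dt <- settings$dt_fs / units_au$au_time_fs     # atomic time units
  kB <- units_au$kB_hartree

  if (is.null(velocities)) {
    velocities <- if (settings$ensemble == "nvt_langevin") {
      initialize_velocities(frag, settings$temperature_K, settings$seed, frozen)
    } else matrix(0.0, n, 3)
  }
  v <- velocities
  v[frozen, ] <- 0
  x <- ang_to_bohr(frag$coords)                  # Bohr

  force_at <- function(xb, step_idx) {
    f2 <- frag
    f2$coords <- bohr_to_ang(xb)
    res <- tryCatch(evaluate(theory, f2, gradient = TRUE),
                    error = function(e) stop("MD aborted at step ", step_idx,
                                             ": ", conditionMessage(e)))
    if (any(!is.finite(res$gradient))) {
      stop("non-finite force at MD step ", step_idx)
    }
    list(F = -res$gradient, e = res$energy)      # Hartree/Bohr
  }

  langevin <- settings$ensemble == "nvt_langevin"
  if (langevin) {
    set.seed(settings$seed + 1L)
    gam <- settings$friction_ps / 1000 * units_au$au_time_fs   # per a.t.u.
    c1 <- exp(-gam * dt)
    c2 <- sqrt(kB * settings$temperature_K * (1 - c1^2) / m)   # per atom
  }

  ekin_of <- function(vv) 0.5 * sum(m[active] * rowSums(vv[active, , drop = FALSE]^2))
  ndof <- 3 * length(active)

  fr <- force_at(x, 0L)
  log_rows <- list()
  frames <- list()
  record <- function(step) {
    ek <- ekin_of(v)
    log_rows[[length(log_rows) + 1]] <<- data.frame(
      step = step, time_fs = step * settings$dt_fs,
      epot = fr$e, ekin = ek, etot = fr$e + ek,
      temperature_K = 2 * ek / (ndof * kB))
    frames[[length(frames) + 1]] <<- bohr_to_ang(x)
  }
  record(0L)

  for (s in seq_len(settings$n_steps)) {
    a <- fr$F / m
    a[frozen, ] <- 0
    if (!langevin) {
      v <- v + 0.5 * dt * a
      x[active, ] <- x[active, , drop = FALSE] + dt * v[active, , drop = FALSE]
      fr <- force_at(x, s)
      a <- fr$F / m; a[frozen, ] <- 0
      v <- v + 0.5 * dt * a
    } else {
      v <- v + 0.5 * dt * a                               # B
      x[active, ] <- x[active, , drop = FALSE] +
        0.5 * dt * v[active, , drop = FALSE]              # A
      noise <- matrix(stats::rnorm(3 * n), n, 3) * c2
      v[active, ] <- c1 * v[active, , drop = FALSE] +
        noise[active, , drop = FALSE]                     # O
      x[active, ] <- x[active, , drop = FALSE] +
        0.5 * dt * v[active, , drop = FALSE]              # A
      fr <- force_at(x, s)
      a <- fr$F / m; a[frozen, ] <- 0
      v <- v + 0.5 * dt * a                               # B
    }
    v[frozen, ] <- 0
    if (s %% settings$traj_stride == 0) record(s)
  }

  out_frag <- frag
  out_frag$coords <- bohr_to_ang(x)
  structure(list(log = do.call(rbind, log_rows), frames = frames,
                 fragment = out_frag, velocities = v,
                 settings = settings),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  lg <- x$log
  cat(sprintf("<md_trajectory: %d frames, %.1f fs, <T> = %.1f K, drift %.3e Hartree>\n",
              nrow(lg), max(lg$time_fs), mean(lg$temperature_K),
              lg$etot[nrow(lg)] - lg$etot[1]))
  invisible(x)
}

#' Write a trajectory as multi-frame XYZ plus a TSV energy log
#'
#' @param traj an \code{md_trajectory}.
#' @param xyz_path multi-frame XYZ output path (optional).
#' @param log_path TSV energy log path (optional).
#' @return invisibly, the trajectory.
#' @export
write_trajectory <- function(traj, xyz_path = NULL, log_path = NULL) {
  if (!is.null(xyz_path)) {
    f <- traj$fragment
    for (i in seq_along(traj$frames)) {
      f$coords <- traj$frames[[i]]
      write_xyz(f, xyz_path, comment = sprintf("frame %d", i), append = i > 1)
    }
  }
  if (!is.null(log_path)) {
    utils::write.table(traj$log, log_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(traj)
}
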