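#' Constant-velocity pulling protocol
#'
#' Describes the stage trajectory and instrument parameters of an
#' AFM-style constant-velocity pull: one or more velocity segments, a
#' sampling rate (default 20 kHz), a cantilever stiffness (default
#' 6 pN/nm) and additive Gaussian force noise (default sd 3 pN).
#'
#' @param segments A data frame with columns `from`, `to` (stage position,
#'   nm) and `speed` (nm/s, strictly positive; direction comes from
#'   `from`/`to`). Segments are executed in order.
#' @param sampling_rate Samples per second, Hz.
#' @param cantilever_stiffness Cantilever spring constant, pN/nm.
#' @param force_noise_sd Gaussian force noise standard deviation, pN.
#' @param seed Integer seed recorded with the protocol and used by
#'   [simulate_pull()].
#' @return A list of class `pulling_protocol`.
#' @examples
#' constant_velocity_protocol(to = 300, speed = 1000)
#' @export
pulling_protocol <- function(segments,
                             sampling_rate = 2e4,
                             cantilever_stiffness = 6,
                             force_noise_sd = 3,
                             seed = 1L) {
  segments <- tibble::as_tibble(segments)
  stopifnot(all(c("from", "to", "speed") %in% names(segments)), nrow(segments) >= 1)
  if (any(segments$speed <= 0)) stop("segment speeds must be positive")
  if (sampling_rate <= 0) stop("`sampling_rate` must be positive")
  if (cantilever_stiffness <= 0) stop("`cantilever_stiffness` must be positive")
  if (force_noise_sd < 0) stop("`force_noise_sd` must be non-negative")
  structure(
    list(
      segments = segments,
      sampling_rate = sampling_rate,
      cantilever_stiffness = cantilever_stiffness,
      force_noise_sd = force_noise_sd,
      seed = as.integer(seed)
    ),
    class = "pulling_protocol"
  )
}

#' @rdname pulling_protocol
#' @param from,to Stage start and end positions, nm.
#' @param speed Pulling speed, nm/s.
#' @param ... Passed on to [pulling_protocol()].
#' @export
constant_velocity_protocol <- function(to, speed, from = 0, ...) {
  pulling_protocol(tibble::tibble(from = from, to = to, speed = speed), ...)
}

#' @rdname pulling_protocol
#' @param cycles Number of stretch-relax cycles.
#' @export
stretch_relax_protocol <- function(from, to, speed, cycles = 1, ...) {
  lo <- from; hi <- to
  seg <- purrr::map_dfr(seq_len(cycles), function(i) {
    tibble::tibble(from = c(lo, hi), to = c(hi, lo), speed = speed)
  })
  pulling_protocol(seg, ...)
}

# Expand protocol segments into a per-sample stage position vector.
protocol_stage <- function(protocol) {
  dt <- 1 / protocol$sampling_rate
  stages <- purrr::map(seq_len(nrow(protocol$segments)), function(i) {
    seg <- protocol$segments[i, ]
    n <- max(1L, round(abs(seg$to - seg$from) / seg$speed / dt))
    seg$from + (seg$to - seg$from) * seq_len(n) / n
  })
  unlist(stages, use.names = FALSE)
}

#' Simulate a constant-velocity pull of a modular filament
#'
#' Forward model of an AFM pulling experiment on a serial Ig/helix
#' filament. At each time step the stage advances by `speed / rate`; the
#' force solves the quasi-static balance
#' `stage = force / stiffness + molecular extension` (Newton iteration,
#' residual below 1e-6 pN); helical linkers draw their folded/unfolded
#' state from the equilibrium occupancy at the current force (or from
#' symmetric-rate kinetics in `helix_mode = "kinetic"`); folded Ig
#' domains unfold irreversibly with per-step probability
#' `1 - exp(-k(F) dt)` under Bell-Evans kinetics. Gaussian force noise is
#' added after the mechanics, so state transitions are noise-free.
#'
#' @param arch A [filament_architecture()].
#' @param protocol A [pulling_protocol()].
#' @param persistence_length Persistence length of unfolded chain, nm.
#' @param temperature Temperature, K.
#' @param folded_compliance `"wlc"` (default) or `"rigid"`; see
#'   [serial_chain_extension()].
#' @param helix_mode `"equilibrium"` (state drawn from the Boltzmann
#'   occupancy each sample) or `"kinetic"` (telegraph process with
#'   symmetric attempt rate `helix_attempt_rate`).
#' @param helix_attempt_rate Attempt frequency for `"kinetic"` mode, 1/s.
#' @param transitions Set `FALSE` to freeze all states (useful for
#'   noise-free reference curves and hysteresis checks).
#' @param log_helix Log every helix toggle in the event table (can be very
#'   large near the midpoint force; toggle counts are always recorded).
#' @return A tibble of class `fe_trace` with columns `time_s`, `stage_nm`,
#'   `extension_nm` (molecular extension, stage minus cantilever
#'   deflection) and `force_pN` (noisy). Attributes: `events` (tibble of
#'   logged transitions with time, label, kind, transition, force),
#'   `helix_toggles` (named toggle counts), `protocol`, `seed`, `params`.
#' @examples
#' arch <- canonical_architecture("monomer")
#' pr <- constant_velocity_protocol(to = 60, speed = 1000, seed = 42)
#' tr <- simulate_pull(arch, pr)
#' @export
simulate_pull <- function(arch, protocol,
                          persistence_length = 0.5,
                          temperature = 298,
                          folded_compliance = c("wlc", "rigid"),
                          helix_mode = c("equilibrium", "kinetic"),
                          helix_attempt_rate = 1e4,
                          transitions = TRUE,
                          log_helix = FALSE) {
  stopifnot(inherits(arch, "filament_architecture"),
            inherits(protocol, "pulling_protocol"))
  folded_compliance <- match.arg(folded_compliance)
  helix_mode <- match.arg(helix_mode)

  kT <- thermal_energy(temperature)
  kc <- protocol$cantilever_stiffness
  dt <- 1 / protocol$sampling_rate
  stage <- protocol_stage(protocol)
  n <- length(stage)
  time <- seq_len(n) * dt

  is_helix <- arch$kind == "helix_linker" & arch$foldable
  is_ig <- arch$kind == "ig_domain" & arch$foldable
  idx_helix <- which(is_helix)
  idx_ig <- which(is_ig)
  n_h <- length(idx_helix)
  n_i <- length(idx_ig)

  base <- sum(arch$folded_extent)
  rigid <- if (folded_compliance == "wlc") 0 else base
  contour0 <- if (folded_compliance == "wlc") base else 0
  gain_h <- arch$contour_gain[idx_helix]
  gain_i <- arch$contour_gain[idx_ig]

  # Helix folding free energies, calibrated so that the constant-force
  # two-state midpoint sits at each helix's midpoint_force: the work
  # available from stretching an extra contour gain dL at force F is
  # dL * (F phi(F) - e(phi(F))), so dG0 = dL * g(F_mid) makes the folded
  # and unfolded branches equally likely at the midpoint.
  mid_h <- arch$midpoint_force[idx_helix]
  phi_mid <- ms_frac_at_force(mid_h, persistence_length, temperature)
  dG0_h <- gain_h * (mid_h * phi_mid -
                       ms_energy_frac(phi_mid, persistence_length, temperature))
  k0_i <- arch$k0[idx_ig]
  dx_i <- arch$delta_x[idx_ig]

  set.seed(protocol$seed)
  u_helix <- if (n_h > 0) stats::runif(n) else NULL
  pick_helix <- if (n_h > 0) sample.int(n_h, n, replace = TRUE) else NULL
  u_ig <- if (n_i > 0) matrix(stats::runif(n * n_i), n, n_i) else NULL
  noise <- if (protocol$force_noise_sd > 0) {
    stats::rnorm(n, sd = protocol$force_noise_sd)
  } else {
    numeric(n)
  }

  helix_unf <- rep(FALSE, n_h)
  ig_unf <- rep(FALSE, n_i)
  toggles <- rep(0L, n_h)

  force_true <- numeric(n)
  extension <- numeric(n)
  ev_time <- numeric(0); ev_label <- character(0)
  ev_kind <- character(0); ev_trans <- character(0); ev_force <- numeric(0)

  phi <- 0
  f_prev <- 0
  kp_over_kT <- persistence_length / kT
  kTp <- kp_over_kT  # alias used inside the solver

  # Solve the quasi-static balance F(phi)/kc + contour*phi = a for phi,
  # Newton with safeguards; returns c(force, phi). `start` warm-starts.
  solve_balance <- function(a, contour, start, step_index) {
    if (a <= 0) return(c(0, 0))
    if (contour <= 0) return(c(kc * a, 0))
    ph <- min(max(start, 1e-6), 1 - 1e-6)
    st <- 1
    for (it in 1:80) {
      fv <- (ph + 1 / (4 * (1 - ph)^2) - 0.25) / kTp
      g <- fv / kc + contour * ph - a
      dg <- (1 + 1 / (2 * (1 - ph)^3)) / (kTp * kc) + contour
      st <- g / dg
      ph_new <- ph - st
      if (ph_new <= 0) ph_new <- ph / 2
      if (ph_new >= 1) ph_new <- (ph + 1) / 2
      ph <- ph_new
      if (abs(st) < 1e-13) break
    }
    if (abs(st) >= 1e-9) {
      stop("quasi-static force balance did not converge at step ", step_index)
    }
    fv <- (ph + 1 / (4 * (1 - ph)^2) - 0.25) / kTp
    if (fv < 0) return(c(0, 0))
    c(fv, ph)
  }

  # total elastic energy of a state (cantilever + chain), pN nm
  elastic_energy <- function(sol, contour) {
    sol[1]^2 / (2 * kc) +
      contour * ms_energy_frac(sol[2], persistence_length, temperature)
  }

  for (i in seq_len(n)) {
    a <- stage[i] - rigid
    ig_pool <- sum(gain_i[ig_unf])

    if (transitions && n_h > 0) {
      # Random-scan Gibbs update: one helix re-equilibrates per sample
      # step (transitions are asynchronous in reality). Because the helix
      # is coupled to the cantilever through the force balance, the
      # correct stage-fixed conditional weighs the total elastic energy
      # difference between the folded and unfolded branches, not the
      # occupancy at the instantaneous force (which would flip-flop:
      # unfolding itself drops the force and would immediately drive
      # refolding).
      j <- pick_helix[i]
      pool_others <- contour0 + ig_pool + sum(gain_h[helix_unf]) -
        if (helix_unf[j]) gain_h[j] else 0
      L_fold <- pool_others
      L_unf <- pool_others + gain_h[j]
      sol_f <- solve_balance(a, L_fold, phi, i)
      sol_u <- solve_balance(a, L_unf, phi, i)
      dG <- dG0_h[j] + elastic_energy(sol_u, L_unf) - elastic_energy(sol_f, L_fold)
      p_unf <- stats::plogis(-dG / kT)
      if (helix_mode == "kinetic") {
        # telegraph with symmetric attempt frequency and detailed balance
        k_switch <- if (helix_unf[j]) {
          helix_attempt_rate * sqrt(max(1 - p_unf, 1e-12) / max(p_unf, 1e-12))
        } else {
          helix_attempt_rate * sqrt(max(p_unf, 1e-12) / max(1 - p_unf, 1e-12))
        }
        p_switch <- 1 - exp(-k_switch * n_h * dt)  # ~n_h steps between visits
        p_unf <- if (u_helix[i] < p_switch) as.numeric(!helix_unf[j]) else as.numeric(helix_unf[j])
      }
      new_state <- u_helix[i] < p_unf
      if (new_state != helix_unf[j]) {
        toggles[j] <- toggles[j] + 1L
        if (log_helix) {
          ev_time <- c(ev_time, time[i])
          ev_label <- c(ev_label, arch$label[idx_helix[j]])
          ev_kind <- c(ev_kind, "helix_linker")
          ev_trans <- c(ev_trans, if (new_state) "unfold" else "refold")
          ev_force <- c(ev_force, f_prev)
        }
        helix_unf[j] <- new_state
      }
      sol <- if (new_state) sol_u else sol_f
      contour <- if (new_state) L_unf else L_fold
    } else {
      contour <- contour0 + ig_pool + sum(gain_h[helix_unf])
      sol <- solve_balance(a, contour, phi, i)
    }
    f <- sol[1]; phi <- sol[2]

    if (transitions && n_i > 0) {
      folded <- which(!ig_unf)
      if (length(folded)) {
        k_f <- k0_i[folded] * exp(f * dx_i[folded] / kT)
        p_unfold <- 1 - exp(-k_f * dt)
        fired <- folded[u_ig[i, folded] < p_unfold]
        if (length(fired)) {
          ig_unf[fired] <- TRUE
          ev_time <- c(ev_time, rep(time[i], length(fired)))
          ev_label <- c(ev_label, arch$label[idx_ig[fired]])
          ev_kind <- c(ev_kind, rep("ig_domain", length(fired)))
          ev_trans <- c(ev_trans, rep("unfold", length(fired)))
          ev_force <- c(ev_force, rep(f, length(fired)))
          contour <- contour + sum(gain_i[fired])
          sol <- solve_balance(a, contour, phi, i)
          f <- sol[1]; phi <- sol[2]
        }
      }
    }

    force_true[i] <- f
    extension[i] <- if (a <= 0) max(0, min(stage[i], rigid)) else rigid + contour * phi
    f_prev <- f
  }

  events <- tibble::tibble(
    time_s = ev_time, label = ev_label, kind = ev_kind,
    transition = ev_trans, force_pN = ev_force
  )
  events <- events[order(events$time_s), ]

  trace <- tibble::tibble(
    time_s = time,
    stage_nm = stage,
    extension_nm = extension,
    force_pN = force_true + noise
  )
  structure(
    trace,
    class = c("fe_trace", class(trace)),
    events = events,
    helix_toggles = stats::setNames(toggles, arch$label[idx_helix]),
    protocol = protocol,
    seed = protocol$seed,
    params = list(
      persistence_length = persistence_length,
      temperature = temperature,
      folded_compliance = folded_compliance,
      helix_mode = helix_mode,
      force_true = force_true
    )
  )
}

#' Simulate several pulls with derived sub-seeds
#'
#' Runs [simulate_pull()] `n_pulls` times, deriving a deterministic
#' sub-seed for pull `k` as `seed + 7919 * k`, and returns the traces as
#' a list.
#'
#' @param arch,protocol,... As in [simulate_pull()].
#' @param n_pulls Number of pulls.
#' @return A list of `fe_trace` tibbles.
#' @export
simulate_pulls <- function(arch, protocol, n_pulls, ...) {
  purrr::map(seq_len(n_pulls), function(k) {
    pk <- protocol
    pk$seed <- as.integer((protocol$seed + 7919 * k) %% .Machine$integer.max)
    simulate_pull(arch, pk, ...)
  })
}

#' Split a trace into stretch and relax phases
#'
#' Cuts a trace at every reversal of the stage direction and returns the
#' phases in order, each tagged `"stretch"` (stage advancing) or
#' `"relax"` (stage retracting).
#'
#' @param trace An `fe_trace` (or any trace tibble).
#' @return A list of trace tibbles; each has a `direction` attribute.
#' @export
trace_phases <- function(trace) {
  check_trace(trace)
  dir <- sign(diff(trace$stage_nm))
  dir <- c(dir[1], dir)
  r <- rle(dir)
  phase <- rep(seq_along(r$lengths), r$lengths)
  purrr::map(seq_along(r$lengths), function(k) {
    ph <- trace[phase == k, ]
    class(ph) <- class(trace)
    attr(ph, "direction") <- if (r$values[k] >= 0) "stretch" else "relax"
    ph
  })
}

#' Events logged by the generator for a simulated trace
#'
#' @param trace An `fe_trace` from [simulate_pull()].
#' @return The event tibble attribute (time, label, kind, transition,
#'   force at transition).
#' @export
trace_events <- function(trace) {
  ev <- attr(trace, "events")
  if (is.null(ev)) {
    tibble::tibble(time_s = numeric(0), label = character(0), kind = character(0),
                   transition = character(0), force_pN = numeric(0))
  } else {
    ev
  }
}
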