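# Cell-cycle dynamics: phase-scheduled permissiveness, checkpoint events,
# per-origin gates with once-per-cycle consumption, and fixed-step Euler
# integration of the readiness dynamic dR/dt = f - g.

.PHASES <- c("G0", "G1", "S", "G2", "M")

#' Phase schedule of cell-cycle permissiveness
#'
#' An ordered list of phase segments, each with a duration and a
#' permissiveness level. Permissiveness is near 0 in G0 and mitosis and
#' near 1 in late G1/S; the G1 segment may ramp linearly (default) so that
#' threshold-crossing times within G1 are non-degenerate.
#'
#' @param phase Character vector of phase labels, each one of
#'   `"G0" "G1" "S" "G2" "M"`.
#' @param duration Positive segment durations (hours).
#' @param phi_start,phi_end Permissiveness at the start and end of each
#'   segment, in \eqn{[0,1]}; a constant segment has `phi_start == phi_end`.
#' @return An object of class `phase_schedule`: a data.frame with columns
#'   `phase, duration, phi_start, phi_end, t_start`, plus a
#'   `total_duration` attribute.
#' @seealso [default_schedule()]
#' @export
phase_schedule <- function(phase, duration, phi_start, phi_end = phi_start) {
  if (!all(phase %in% .PHASES))
    stop("phase labels must be among ", paste(.PHASES, collapse = ", "),
         call. = FALSE)
  if (any(duration <= 0)) stop("durations must be positive", call. = FALSE)
  for (v in c(phi_start, phi_end))
    if (v < 0 || v > 1) stop("phi levels must lie in [0, 1]", call. = FALSE)
  n <- length(phase)
  stopifnot(length(duration) == n, length(phi_start) == n,
            length(phi_end) == n)
  df <- data.frame(phase = phase, duration = as.numeric(duration),
                   phi_start = as.numeric(phi_start),
                   phi_end = as.numeric(phi_end))
  df$t_start <- cumsum(c(0, df$duration[-n]))
  structure(df, class = c("phase_schedule", "data.frame"),
            total_duration = sum(df$duration))
}

#' Default mammalian-like cycle schedule
#'
#' G1 (10 h) ramping from 0.3 to 1.0, S (8 h) at 1.0, G2 (4 h) at 0.3 and
#' M (1 h) at 0.01 — permissiveness essentially vetoed in mitosis,
#' maximal in late G1/S.
#'
#' @param g1_ramp If `TRUE` (default) G1 permissiveness ramps linearly from
#'   0.3 to 1.0; otherwise G1 is constant at 1.0.
#' @return A [phase_schedule()].
#' @export
default_schedule <- function(g1_ramp = TRUE) {
  phase_schedule(phase = c("G1", "S", "G2", "M"),
                 duration = c(10, 8, 4, 1),
                 phi_start = c(if (g1_ramp) 0.3 else 1.0, 1.0, 0.3, 0.01),
                 phi_end = c(1.0, 1.0, 0.3, 0.01))
}

#' Checkpoint event
#'
#' A transient checkpoint activation (e.g. ATR/ATM signalling after DNA
#' damage) covering a time window; while active it multiplies the phase
#' permissiveness by `phi_scale` and the drive component by `D_scale`
#' (CDK inhibition). Overlapping events compose multiplicatively.
#'
#' @param t_start,t_end Window bounds (hours), `t_start < t_end`. A time t
#'   is covered when `t_start <= t < t_end`.
#' @param phi_scale,D_scale Multiplicative scales in \eqn{[0,1]}.
#' @return An object of class `checkpoint_event`.
#' @export
checkpoint_event <- function(t_start, t_end, phi_scale = 1, D_scale = 1) {
  if (!(t_start < t_end)) stop("t_start must be < t_end", call. = FALSE)
  .check_unit(phi_scale, "phi_scale"); .check_unit(D_scale, "D_scale")
  structure(list(t_start = as.numeric(t_start), t_end = as.numeric(t_end),
                 phi_scale = as.numeric(phi_scale),
                 D_scale = as.numeric(D_scale)),
            class = "checkpoint_event")
}

# Product of an event field over all events covering each time in t.
.event_scale <- function(events, t, field) {
  out <- rep(1, length(t))
  for (ev in events) {
    idx <- t >= ev$t_start & t < ev$t_end
    out[idx] <- out[idx] * ev[[field]]
  }
  out
}

#' Phase permissiveness at a time point
#'
#' The scheduled (piecewise-linear) permissiveness at time `t`, multiplied
#' by the `phi_scale` of every checkpoint event whose window covers `t`.
#'
#' @param schedule A [phase_schedule()].
#' @param t Time(s) within `[0, total_duration]`; vectorized.
#' @param events List of [checkpoint_event()]s (may be empty).
#' @return Permissiveness value(s) in \eqn{[0,1]}.
#' @export
phi_at <- function(schedule, t, events = list()) {
  stopifnot(inherits(schedule, "phase_schedule"))
  total <- attr(schedule, "total_duration")
  if (any(t < 0 | t > total))
    stop(sprintf("time outside schedule [0, %g]", total), call. = FALSE)
  ends <- schedule$t_start + schedule$duration
  seg <- findInterval(t, schedule$t_start, rightmost.closed = FALSE)
  seg[t >= total] <- nrow(schedule)  # closed right endpoint
  frac <- (t - schedule$t_start[seg]) / schedule$duration[seg]
  base <- schedule$phi_start[seg] +
    (schedule$phi_end[seg] - schedule$phi_start[seg]) * frac
  base * .event_scale(events, t, "phi_scale")
}

#' Build a table of replication origins
#'
#' Each origin carries its own licensing, drive and chromatin values and its
#' own firing threshold; an origin fires when the time-dependent
#' permissiveness times its component product meets its threshold.
#'
#' @param A,D,C Per-origin components in \eqn{[0,1]} (recycled to a common
#'   length).
#' @param threshold Per-origin thresholds in \eqn{(0,1]}.
#' @param id Optional origin identifiers; defaults to `origin_1 ...`.
#' @return A data.frame of class `origin_frame` with columns
#'   `id, A, D, C, threshold, licensed, fired, fire_time`.
#' @examples
#' origin_frame(A = c(1, 0.45), D = 0.9, C = c(0.7, 0.3), threshold = 0.5)
#' @export
origin_frame <- function(A, D, C, threshold = 0.5, id = NULL) {
  n <- max(length(A), length(D), length(C))
  A <- rep_len(as.numeric(A), n); D <- rep_len(as.numeric(D), n)
  C <- rep_len(as.numeric(C), n)
  threshold <- rep_len(as.numeric(threshold), n)
  if (any(!is.finite(c(A, D, C))) || any(c(A, D, C) < 0 | c(A, D, C) > 1))
    stop("origin components must be finite and in [0, 1]", call. = FALSE)
  if (any(threshold <= 0 | threshold > 1))
    stop("origin thresholds must lie in (0, 1]", call. = FALSE)
  if (is.null(id)) id <- sprintf("origin_%d", seq_len(n))
  structure(data.frame(id = as.character(id), A = A, D = D, C = C,
                       threshold = threshold, licensed = rep(TRUE, n),
                       fired = rep(FALSE, n),
                       fire_time = rep(NA_real_, n)),
            class = c("origin_frame", "data.frame"))
}

#' Integration and noise parameters for cycle simulation
#'
#' @param k_act Activation gain (1/h) of the readiness dynamic
#'   `dR/dt = k_act * h(score) - gamma * R`, with `h` the Hill response.
#' @param gamma Decay gain (1/h).
#' @param dt Euler time step (h); must divide every segment duration.
#'   Default 0.01 h.
#' @param noise_sd Standard deviation of the per-step Gaussian jitter
#'   applied to the cell-level components (0 disables noise).
#' @param seed Integer seed for the noise stream.
#' @return An object of class `dynamic_params`.
#' @export
dynamic_params <- function(k_act = 1, gamma = 1, dt = 0.01, noise_sd = 0,
                           seed = 1L) {
  if (k_act <= 0 || gamma <= 0 || dt <= 0)
    stop("'k_act', 'gamma' and 'dt' must be positive", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  structure(list(k_act = as.numeric(k_act), gamma = as.numeric(gamma),
                 dt = as.numeric(dt), noise_sd = as.numeric(noise_sd),
                 seed = as.integer(seed)),
            class = "dynamic_params")
}

.clamp01 <- function(x) pmin(1, pmax(0, x))

#' Simulate one cell cycle with per-origin gates
#'
#' Fixed-step Euler integration of the aggregate readiness dynamic
#' \eqn{dR/dt = k_{act} h(s) - \gamma R} over the phase schedule, with
#' per-origin hard gates evaluated at every step. An origin fires at the
#' first step where its gate (scheduled permissiveness times its component
#' product, with checkpoint scaling of drive and permissiveness) meets its
#' threshold while it is licensed and unfired. Firing consumes the origin:
#' it is removed from the licensed pool, the aggregate licensing component
#' declines in proportion to the remaining licensed fraction, and no origin
#' relicenses within the cycle — together these enforce the once-per-cycle
#' rule. Optional Gaussian cell-level noise jitters the components at each
#' step (one draw per component per step, shared across origins, truncated
#' to \eqn{[0,1]}).
#'
#' @param origins An [origin_frame()] (may be empty: the run is valid and
#'   produces no firings).
#' @param schedule A [phase_schedule()].
#' @param params A [dynamic_params()].
#' @param events List of [checkpoint_event()]s.
#' @param gate A [gate_params()] used for the graded response in the
#'   dynamic and for arrest reporting.
#' @param stochastic_firing If `TRUE`, an eligible origin whose gate is
#'   satisfied fires with per-step probability equal to its graded
#'   response instead of deterministically. Off by default; note that the
#'   effective firing rate then depends on `dt`.
#' @return An object of class `cycle_trajectory`: a list with `times` and
#'   aggregate series `A, D, C, phi, score, R`; `firings` (data.frame
#'   `id, time`, time-ordered); `arrest_intervals`; the final `origins`
#'   table; and the inputs.
#' @export
simulate_cycle <- function(origins, schedule, params = dynamic_params(),
                           events = list(), gate = gate_params(),
                           stochastic_firing = FALSE) {
  stopifnot(inherits(origins, "origin_frame"),
            inherits(schedule, "phase_schedule"),
            inherits(params, "dynamic_params"),
            inherits(gate, "gate_params"))
  dt <- params$dt
  ratio <- schedule$duration / dt
  if (any(abs(ratio - round(ratio)) > 1e-8 * pmax(1, ratio)))
    stop("'dt' must divide every segment duration", call. = FALSE)
  total <- attr(schedule, "total_duration")
  n_steps <- as.integer(round(total / dt))
  times <- (seq_len(n_steps) - 1L) * dt

  base_phi <- phi_at(schedule, times)
  sc_phi <- .event_scale(events, times, "phi_scale")
  sc_D <- .event_scale(events, times, "D_scale")
  phi_t <- base_phi * sc_phi
  phase_idx <- findInterval(times, schedule$t_start)

  n0 <- nrow(origins)
  licensed <- origins$licensed
  fired <- origins$fired
  fire_time <- origins$fire_time
  n_lic0 <- max(1L, sum(licensed))
  A0 <- if (n0) mean(origins$A) else 0
  D0 <- if (n0) mean(origins$D) else 0
  C0 <- if (n0) mean(origins$C) else 0

  noisy <- params$noise_sd > 0
  if (noisy || stochastic_firing) set.seed(params$seed)
  eps <- if (noisy)
    matrix(stats::rnorm(3L * n_steps, 0, params$noise_sd), ncol = 3L)
  else matrix(0, n_steps, 3L)

  Aser <- Dser <- Cser <- sser <- Rser <- numeric(n_steps)
  R <- 0
  R_max <- params$k_act / params$gamma
  fires <- vector("list", n_steps)

  for (k in seq_len(n_steps)) {
    dA <- eps[k, 1L]; dD <- eps[k, 2L]; dC <- eps[k, 3L]
    if (n0) {
      elig <- licensed & !fired
      if (any(elig)) {
        s_i <- phi_t[k] * .clamp01(origins$A[elig] + dA) *
          .clamp01(origins$D[elig] * sc_D[k] + dD) *
          .clamp01(origins$C[elig] + dC)
        hit <- s_i >= origins$threshold[elig]
        if (stochastic_firing && any(hit)) {
          p <- hill_response(pmin(1, s_i), gate$threshold, gate$sharpness)
          hit <- hit & (stats::runif(length(s_i)) < p)
        }
        if (any(hit)) {
          idx <- which(elig)[hit]
          fired[idx] <- TRUE
          licensed[idx] <- FALSE
          fire_time[idx] <- times[k]
          fires[[k]] <- origins$id[idx]
        }
      }
    }
    lic_frac <- if (n0) sum(licensed) / n_lic0 else 0
    A_t <- .clamp01(A0 * lic_frac + dA)
    D_t <- .clamp01(D0 * sc_D[k] + dD)
    C_t <- .clamp01(C0 + dC)
    s_t <- phi_t[k] * A_t * D_t * C_t
    R <- R + dt * (params$k_act *
                     hill_response(s_t, gate$threshold, gate$sharpness) -
                     params$gamma * R)
    R <- min(R_max, max(0, R))
    Aser[k] <- A_t; Dser[k] <- D_t; Cser[k] <- C_t
    sser[k] <- s_t; Rser[k] <- R
  }

  fl <- !vapply(fires, is.null, logical(1))
  firings <- data.frame(
    id = unlist(fires[fl], use.names = FALSE),
    time = rep(times[fl], vapply(fires[fl], length, integer(1))))
  if (nrow(firings) == 0L)
    firings <- data.frame(id = character(0), time = numeric(0))

  origins$licensed <- licensed
  origins$fired <- fired
  origins$fire_time <- fire_time

  traj <- structure(list(times = times, A = Aser, D = Dser, C = Cser,
                         phi = phi_t, score = sser, R = Rser,
                         phase = schedule$phase[phase_idx],
                         firings = firings, origins = origins,
                         schedule = schedule, params = params,
                         events = events, gate = gate,
                         arrest_intervals = NULL),
                    class = "cycle_trajectory")
  traj$arrest_intervals <- arrest_report(traj)
  traj
}

#' @export
print.cycle_trajectory <- function(x, ...) {
  cat(sprintf(
    "cycle trajectory: %d steps over %.1f h, %d/%d origins fired, %d arrest interval(s)\n",
    length(x$times), attr(x$schedule, "total_duration"),
    sum(x$origins$fired), nrow(x$origins), nrow(x$arrest_intervals)))
  invisible(x)
}

#' Earliest time an origin's gate reaches threshold
#'
#' Exact piecewise-linear solution: within each interval on which the
#' scheduled permissiveness is linear and the checkpoint scales are
#' constant, the first crossing of
#' \eqn{\phi(t) A D C \ge T} is solved in closed form. Origins with higher
#' licensing or accessibility cross earlier under the ramping-G1 schedule,
#' reproducing early/late replication-timing domains.
#'
#' @param origin A single origin: a list or one-row data.frame with fields
#'   `A, D, C, threshold`.
#' @param schedule A [phase_schedule()].
#' @param events List of [checkpoint_event()]s.
#' @return The earliest crossing time (h), or `NA` if the gate is never
#'   reached within the cycle ("none").
#' @examples
#' eu <- list(A = 1, D = 0.9, C = 0.7, threshold = 0.5)
#' time_to_threshold(eu, default_schedule())
#' @export
time_to_threshold <- function(origin, schedule, events = list()) {
  stopifnot(inherits(schedule, "phase_schedule"))
  A <- origin$A; D <- origin$D; C <- origin$C; thr <- origin$threshold
  prod3 <- A * D * C
  if (prod3 == 0) return(NA_real_)
  total <- attr(schedule, "total_duration")
  brk <- sort(unique(c(0, schedule$t_start, total,
                       unlist(lapply(events, function(e)
                         c(e$t_start, e$t_end))))))
  brk <- brk[brk >= 0 & brk <= total]
  for (i in seq_len(length(brk) - 1L)) {
    a <- brk[i]; b <- brk[i + 1L]
    seg <- findInterval(a, schedule$t_start)
    m <- (schedule$phi_end[seg] - schedule$phi_start[seg]) /
      schedule$duration[seg]
    p_a <- schedule$phi_start[seg] + m * (a - schedule$t_start[seg])
    sphi <- .event_scale(events, a, "phi_scale")
    sD <- .event_scale(events, a, "D_scale")
    eff <- prod3 * sphi * sD
    if (eff == 0) next
    req <- thr / eff             # required base permissiveness
    if (p_a >= req) return(a)
    if (m > 0) {
      t_star <- a + (req - p_a) / m
      if (t_star < b) return(t_star)
    }
  }
  # closed right endpoint of the final segment
  p_end <- phi_at(schedule, total) * .event_scale(events, total, "phi_scale")
  if (p_end * prod3 * .event_scale(events, total, "D_scale") >= thr)
    return(total)
  NA_real_
}

#' Arrest intervals of a trajectory
#'
#' Maximal time intervals during which the aggregate readiness score sits
#' below the gate threshold — the below-threshold, non-initiating regime
#' produced by checkpoint activation (or by the schedule itself). For each
#' interval the report notes whether any origin fired after it ended,
#' i.e. whether the arrest was reversible within the cycle.
#'
#' @param trajectory A [simulate_cycle()] result.
#' @param gate A [gate_params()]; defaults to the gate used in the
#'   simulation.
#' @return A data.frame with columns `t_start, t_end, fired_after`
#'   (zero rows when the score never drops below threshold).
#' @export
arrest_report <- function(trajectory, gate = NULL) {
  stopifnot(inherits(trajectory, "cycle_trajectory"))
  if (is.null(gate)) gate <- trajectory$gate
  thr <- gate$threshold
  below <- trajectory$score < thr
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!any(keep))
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      fired_after = logical(0)))
  dt <- trajectory$params$dt
  t0 <- trajectory$times[starts[keep]]
  t1 <- trajectory$times[ends[keep]] + dt
  fired_after <- vapply(t1, function(te)
    any(trajectory$firings$time >= te), logical(1))
  data.frame(t_start = t0, t_end = t1, fired_after = fired_after)
}
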