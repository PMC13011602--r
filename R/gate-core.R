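# Core multiplicative readiness gate: state containers, the composite score,
# the hard and graded (Hill) decision rules, min-max normalization of raw
# correlates, and the threshold surface in component space.

.check_unit <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("component '%s' must be a single finite number", name),
         call. = FALSE)
  if (x < 0 || x > 1)
    stop(sprintf("component '%s' = %g is outside [0, 1]", name, x),
         call. = FALSE)
  as.numeric(x)
}

#' Construct a single-cell (or single-origin) readiness state
#'
#' A readiness state bundles the four normalized control variables of the
#' multiplicative initiation gate: `A`, the origin-licensing architecture
#' (ORC/MCM occupancy, pre-RC integrity); `D`, metabolic and kinase drive
#' (CDK activity, ATP/dNTP pools); `C`, chromatin context (accessibility,
#' nuclear topology); and `phi`, global cell-cycle phase permissiveness
#' (near 0 in G0/mitosis, near 1 in late G1/S). All four are unitless and
#' must lie in the closed interval \eqn{[0, 1]}; out-of-range values are
#' rejected with an error naming the offending field.
#'
#' @param A Licensing architecture, in \eqn{[0,1]}.
#' @param D Metabolic/kinase drive, in \eqn{[0,1]}.
#' @param C Chromatin context, in \eqn{[0,1]}.
#' @param phi Phase permissiveness, in \eqn{[0,1]}; defaults to 1
#'   (fully permissive, late G1/S).
#' @return An object of class `readiness_state`.
#' @examples
#' readiness_state(A = 0.9, D = 0.8, C = 0.7, phi = 0.5)
#' @export
readiness_state <- function(A, D, C, phi = 1) {
  out <- list(A = .check_unit(A, "A"), D = .check_unit(D, "D"),
              C = .check_unit(C, "C"), phi = .check_unit(phi, "phi"))
  class(out) <- "readiness_state"
  out
}

#' @export
print.readiness_state <- function(x, ...) {
  cat(sprintf("readiness state: A=%.3f D=%.3f C=%.3f phi=%.3f (score=%.4f)\n",
              x$A, x$D, x$C, x$phi, composite_readiness(x)))
  invisible(x)
}

#' Gate parameters: initiation threshold and response sharpness
#'
#' @param threshold Minimum composite readiness required for initiation,
#'   in \eqn{(0, 1]}. Default 0.5, the center of the normalized range.
#' @param sharpness Hill exponent of the graded response; larger values give
#'   a steeper, more switch-like response, recovering the hard gate in the
#'   limit. Must be positive. Default 8.
#' @return An object of class `gate_params`.
#' @examples
#' gate_params(threshold = 0.5, sharpness = 8)
#' @export
gate_params <- function(threshold = 0.5, sharpness = 8) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold <= 0 || threshold > 1)
    stop("'threshold' must be a single number in (0, 1]", call. = FALSE)
  if (!is.numeric(sharpness) || length(sharpness) != 1L ||
      !is.finite(sharpness) || sharpness <= 0)
    stop("'sharpness' must be a single positive number", call. = FALSE)
  structure(list(threshold = as.numeric(threshold),
                 sharpness = as.numeric(sharpness)),
            class = "gate_params")
}

#' @export
print.gate_params <- function(x, ...) {
  cat(sprintf("gate: threshold=%.3f sharpness=%.1f\n",
              x$threshold, x$sharpness))
  invisible(x)
}

# Vectorized product score; inputs assumed pre-validated.
.score <- function(A, D, C, phi) phi * A * D * C

#' Composite readiness score
#'
#' The left-hand side of the gate inequality: the product
#' \eqn{\Phi \cdot A \cdot D \cdot C}. The multiplicative form makes each
#' component a necessary condition — if any component is 0 the score is 0
#' regardless of the others (the zero-veto), e.g. full licensing and drive
#' with absent chromatin accessibility gives \eqn{1 \times 1 \times 0 = 0}.
#'
#' @param state A [readiness_state()].
#' @return The score, a number in \eqn{[0, 1]}.
#' @examples
#' composite_readiness(readiness_state(1, 1, 0, 1))    # 0: chromatin veto
#' composite_readiness(readiness_state(0.9, 0.8, 0.7, 0.5)) # 0.252
#' @export
composite_readiness <- function(state) {
  stopifnot(inherits(state, "readiness_state"))
  .score(state$A, state$D, state$C, state$phi)
}

#' Evaluate the hard initiation gate
#'
#' Initiation fires exactly when the composite readiness score meets the
#' threshold (boundary inclusive, score \eqn{\ge} threshold). The result also
#' carries the margin (score minus threshold) and the graded Hill response,
#' useful as a firing probability in stochastic settings.
#'
#' @param state A [readiness_state()].
#' @param params A [gate_params()].
#' @return An object of class `gate_result` with fields `score`, `fired`,
#'   `margin` and `response`.
#' @examples
#' gate_decision(readiness_state(0.9, 0.8, 0.7, 0.5), gate_params(0.5))
#' @export
gate_decision <- function(state, params = gate_params()) {
  stopifnot(inherits(state, "readiness_state"), inherits(params, "gate_params"))
  s <- composite_readiness(state)
  structure(list(score = s,
                 fired = s >= params$threshold,
                 margin = s - params$threshold,
                 response = hill_response(s, params$threshold,
                                          params$sharpness)),
            class = "gate_result")
}

#' @export
print.gate_result <- function(x, ...) {
  cat(sprintf("gate result: score=%.4f fired=%s margin=%+.4f response=%.4f\n",
              x$score, x$fired, x$margin, x$response))
  invisible(x)
}

#' Hill-form graded response
#'
#' Smooth, monotone-nondecreasing version of the hard gate:
#' \deqn{h(s) = \frac{s^k}{s^k + T^k} = \frac{1}{1 + (T/s)^k},}
#' with midpoint exactly 0.5 at \eqn{s = T} and \eqn{h(0) = 0} (the zero-veto
#' is preserved). As the sharpness \eqn{k} grows, \eqn{h} converges pointwise
#' to the hard step at the threshold, so the graded and hard gates agree in
#' the steep limit. Computed as \eqn{1/(1 + (T/s)^k)} for numerical
#' stability at large \eqn{k}.
#'
#' @param score Composite readiness score(s) in \eqn{[0,1]}; vectorized.
#' @param threshold Gate threshold \eqn{T \in (0,1]}.
#' @param sharpness Hill exponent \eqn{k > 0}.
#' @return Response value(s) in \eqn{[0,1]}.
#' @export
hill_response <- function(score, threshold, sharpness) {
  stopifnot(is.numeric(score), all(is.finite(score)),
            all(score >= 0), all(score <= 1))
  out <- numeric(length(score))
  pos <- score > 0
  out[pos] <- 1 / (1 + (threshold / score[pos])^sharpness)
  out
}

#' Graded firing probability of a readiness state
#'
#' Applies the Hill response to the composite readiness of `state`.
#'
#' @inheritParams gate_decision
#' @return A probability in \eqn{[0,1]}.
#' @seealso [hill_response()]
#' @export
graded_response <- function(state, params = gate_params()) {
  stopifnot(inherits(state, "readiness_state"), inherits(params, "gate_params"))
  hill_response(composite_readiness(state), params$threshold, params$sharpness)
}

#' Min-max normalization of a raw measured correlate
#'
#' Raw assay readouts (ORC/MCM occupancy, CDK activity, accessibility scores,
#' checkpoint reporters) are mapped to the unit interval by the linear map
#' \eqn{(raw - lo)/(hi - lo)} before entering the gate.
#'
#' @param lo Raw value mapped to 0.
#' @param hi Raw value mapped to 1; must strictly exceed `lo`.
#' @param clamp If `TRUE` (default), values outside `[lo, hi]` are clipped to
#'   the endpoints; if `FALSE`, out-of-range raw values are an error.
#' @return An object of class `normalization_spec`.
#' @export
normalization_spec <- function(lo, hi, clamp = TRUE) {
  if (!is.numeric(lo) || !is.numeric(hi) || length(lo) != 1L ||
      length(hi) != 1L || !is.finite(lo) || !is.finite(hi))
    stop("'lo' and 'hi' must be single finite numbers", call. = FALSE)
  if (lo >= hi) stop("'lo' must be strictly less than 'hi'", call. = FALSE)
  structure(list(lo = as.numeric(lo), hi = as.numeric(hi),
                 clamp = isTRUE(clamp)),
            class = "normalization_spec")
}

#' @rdname normalization_spec
#' @param raw Raw value(s) in assay units; vectorized.
#' @param spec A `normalization_spec`.
#' @return `normalize_correlate` returns normalized value(s) in \eqn{[0,1]}.
#' @examples
#' sp <- normalization_spec(0, 100)
#' normalize_correlate(50, sp)   # 0.5
#' normalize_correlate(150, sp)  # clamped to 1
#' @export
normalize_correlate <- function(raw, spec) {
  stopifnot(inherits(spec, "normalization_spec"),
            is.numeric(raw), all(is.finite(raw)))
  x <- (raw - spec$lo) / (spec$hi - spec$lo)
  if (spec$clamp) return(pmin(1, pmax(0, x)))
  if (any(x < 0 | x > 1)) {
    bad <- raw[x < 0 | x > 1][1L]
    stop(sprintf("raw value %g outside [%g, %g] and clamp = FALSE",
                 bad, spec$lo, spec$hi), call. = FALSE)
  }
  x
}

#' Minimal chromatin accessibility at which the gate fires
#'
#' Inverts the gate along the chromatin axis: given licensing `A`, drive `D`
#' and permissiveness `phi`, the threshold surface crosses the C-axis at
#' \eqn{C^* = T/(\phi A D)}. When \eqn{\phi A D < T} even fully open
#' chromatin (C = 1) cannot reach the threshold and no competent C exists;
#' when \eqn{\phi A D = 0} the state is vetoed outright. Raising `phi`
#' (e.g. checkpoint release) lowers \eqn{C^*}, expanding the competent
#' region; lowering `phi` raises it.
#'
#' @param A,D,phi Components in \eqn{[0,1]}.
#' @param params A [gate_params()]; only the threshold is used.
#' @return An object of class `surface_point`: a list with `C_star` (the
#'   minimal competent C, or `NA` if undefined), `defined` (logical) and
#'   `reason` (`"ok"`, `"unreachable"` or `"zero-veto"`).
#' @examples
#' threshold_surface_C(A = 1, D = 1, phi = 1, gate_params(0.5))  # C* = 0.5
#' threshold_surface_C(A = 1, D = 0.4, phi = 1, gate_params(0.5)) # unreachable
#' @export
threshold_surface_C <- function(A, D, phi, params = gate_params()) {
  .check_unit(A, "A"); .check_unit(D, "D"); .check_unit(phi, "phi")
  stopifnot(inherits(params, "gate_params"))
  denom <- phi * A * D
  if (denom == 0) {
    out <- list(C_star = NA_real_, defined = FALSE, reason = "zero-veto")
  } else if (denom < params$threshold) {
    out <- list(C_star = NA_real_, defined = FALSE, reason = "unreachable")
  } else {
    c_star <- params$threshold / denom
    # make C* the smallest representable value that actually fires: the
    # division can round the product one ulp below the threshold
    while (denom * c_star < params$threshold && c_star < 1)
      c_star <- min(1, c_star * (1 + .Machine$double.eps))
    out <- list(C_star = c_star, defined = TRUE, reason = "ok")
  }
  class(out) <- "surface_point"
  out
}

#' @export
print.surface_point <- function(x, ...) {
  if (x$defined) cat(sprintf("minimal competent C* = %.4f\n", x$C_star))
  else cat(sprintf("no competent C (%s)\n", x$reason))
  invisible(x)
}

#' Classify a regular lattice in A-D-C space as competent or not
#'
#' Evaluates the hard gate at every point of the inclusive uniform lattice
#' \eqn{\{0, 1/(r-1), \ldots, 1\}^3} over (A, D, C) at a fixed phase
#' permissiveness, mapping the replication-competent region above the
#' threshold surface.
#'
#' @param resolution Number of lattice points per axis, at least 2.
#' @param phi Fixed phase permissiveness in \eqn{[0,1]}.
#' @param params A [gate_params()].
#' @return An object of class `competence_map`: a list with `grid` (a
#'   data.frame with columns A, D, C, score, fired ordered with A varying
#'   fastest), `n_competent`, `resolution`, `phi` and the gate parameters.
#' @examples
#' cm <- classify_grid(11, phi = 1, gate_params(0.5))
#' cm$n_competent
#' @export
classify_grid <- function(resolution, phi = 1, params = gate_params()) {
  if (!is.numeric(resolution) || length(resolution) != 1L ||
      resolution < 2 || resolution != round(resolution))
    stop("'resolution' must be an integer >= 2", call. = FALSE)
  .check_unit(phi, "phi")
  stopifnot(inherits(params, "gate_params"))
  ax <- seq(0, 1, length.out = resolution)
  grid <- expand.grid(A = ax, D = ax, C = ax, KEEP.OUT.ATTRS = FALSE)
  grid$score <- .score(grid$A, grid$D, grid$C, phi)
  grid$fired <- grid$score >= params$threshold
  structure(list(grid = grid, n_competent = sum(grid$fired),
                 resolution = as.integer(resolution), phi = phi,
                 params = params),
            class = "competence_map")
}

#' @export
print.competence_map <- function(x, ...) {
  cat(sprintf("competence map: r=%d, phi=%.2f, T=%.3f -> %d/%d competent\n",
              x$resolution, x$phi, x$params$threshold, x$n_competent,
              nrow(x$grid)))
  invisible(x)
}

#' @export
as.data.frame.competence_map <- function(x, ...) x$grid
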