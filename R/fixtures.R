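# Synthetic "measured correlate" tables: assay-scale stand-ins for the raw
# readouts (ORC/MCM occupancy, CDK activity, chromatin accessibility,
# checkpoint reporter) that normalization maps onto the gate components.
# All values are generated; regimes encode qualitative cell states as
# explicit means/sds on the normalized scale.

.fixture_regimes <- list(
  # normalized-scale means and sds per component, by cell-state regime
  stem = list(mean = c(A = 0.90, D = 0.90, C = 0.85, phi = 0.90),
              sd = c(A = 0.05, D = 0.05, C = 0.05, phi = 0.05)),
  quiescent = list(mean = c(A = 0.90, D = 0.20, C = 0.60, phi = 0.15),
                   sd = c(A = 0.05, D = 0.08, C = 0.10, phi = 0.05)),
  stressed = list(mean = c(A = 0.85, D = 0.40, C = 0.70, phi = 0.15),
                  sd = c(A = 0.05, D = 0.10, C = 0.08, phi = 0.05))
)

# raw assay scales the synthetic generator writes on
.fixture_scales <- list(A = c(lo = 0, hi = 1000),  # occupancy read count
                        D = c(lo = 0, hi = 100),   # kinase activity, AU
                        C = c(lo = 0, hi = 10),    # accessibility score
                        phi = c(lo = 0, hi = 5))   # reporter ratio

#' Normalization specs bundled with the fixture generator
#'
#' One [normalization_spec()] per component, matching the raw assay scales
#' used by [generate_fixture_correlates()].
#'
#' @return Named list with entries `A`, `D`, `C`, `phi`.
#' @export
fixture_normalization <- function() {
  lapply(.fixture_scales, function(s)
    normalization_spec(s[["lo"]], s[["hi"]], clamp = TRUE))
}

#' Generate a synthetic table of raw measured correlates
#'
#' Emulates pre-summarized assay readouts for a population of samples in
#' one of three qualitative regimes: `"stem"` (all components high,
#' checkpoints attenuated so permissiveness is constitutively high),
#' `"quiescent"` (origins stay licensed — architecture high — while drive
#' and permissiveness are low), and `"stressed"` (checkpoint signalling
#' suppresses permissiveness and partially suppresses drive while
#' architecture and chromatin stay intact). Values are Gaussian on the
#' normalized scale (truncated to \eqn{[0,1]}) and mapped onto the raw
#' assay scales of [fixture_normalization()].
#'
#' @param n_samples Number of samples (>= 1).
#' @param seed Integer seed.
#' @param regime `"stem"`, `"quiescent"` or `"stressed"`.
#' @return A data.frame with columns `sample_id, raw_orc_occupancy,
#'   raw_cdk_activity, raw_accessibility, raw_checkpoint_readout`.
#' @examples
#' head(generate_fixture_correlates(5, seed = 1, regime = "quiescent"))
#' @export
generate_fixture_correlates <- function(n_samples, seed = 1L,
                                        regime = c("stem", "quiescent",
                                                   "stressed")) {
  regime <- match.arg(regime)
  if (!is.numeric(n_samples) || n_samples < 1 ||
      n_samples != round(n_samples))
    stop("'n_samples' must be an integer >= 1", call. = FALSE)
  rg <- .fixture_regimes[[regime]]
  set.seed(seed)
  draw <- function(comp) {
    norm <- .clamp01(stats::rnorm(n_samples, rg$mean[[comp]],
                                  rg$sd[[comp]]))
    s <- .fixture_scales[[comp]]
    s[["lo"]] + norm * (s[["hi"]] - s[["lo"]])
  }
  data.frame(sample_id = sprintf("%s_%03d", regime, seq_len(n_samples)),
             raw_orc_occupancy = draw("A"),
             raw_cdk_activity = draw("D"),
             raw_accessibility = draw("C"),
             raw_checkpoint_readout = draw("phi"))
}

#' Normalize a correlate table to gate components
#'
#' Applies the component-wise normalization to a raw correlate table
#' (columns as produced by [generate_fixture_correlates()]).
#'
#' @param table Data.frame with the raw correlate columns.
#' @param specs Named list of [normalization_spec()]s (`A`, `D`, `C`,
#'   `phi`); defaults to [fixture_normalization()].
#' @return A data.frame with columns `sample_id, A, D, C, phi`.
#' @export
normalize_correlates <- function(table, specs = fixture_normalization()) {
  need <- c("sample_id", "raw_orc_occupancy", "raw_cdk_activity",
            "raw_accessibility", "raw_checkpoint_readout")
  if (!all(need %in% names(table)))
    stop("correlate table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (anyNA(table$sample_id) || any(table$sample_id == ""))
    stop("missing sample_id", call. = FALSE)
  data.frame(
    sample_id = table$sample_id,
    A = normalize_correlate(table$raw_orc_occupancy, specs$A),
    D = normalize_correlate(table$raw_cdk_activity, specs$D),
    C = normalize_correlate(table$raw_accessibility, specs$C),
    phi = normalize_correlate(table$raw_checkpoint_readout, specs$phi))
}
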