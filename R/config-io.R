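# YAML configuration for the command-line harness.

#' Read an experiment configuration from YAML
#'
#' Recognised top-level keys mirror [experimentConfig()] (`seed`,
#' `n_sequences`, `soa_s`, `tmin_s`, `tmax_s`, `pipeline`, `offline_runs`,
#' `online_runs`, `trials_per_run`, `bin_s`), a `filter` block (`hp_hz`,
#' `lp_hz`) and a `synth` block (`fs_hz`, `ssr_amplitude_uv`,
#' `noise_sigma_uv`, `one_over_f_exponent`, `latency_jitter_sd_s`,
#' `eog_blink_rate_hz`, `eog_amplitude_uv`, and optional `components`, a
#' list of `{name, center_s, width_s, amplitude_uv}` entries using the
#' default topographies by name). Unspecified keys keep package defaults.
#'
#' @param path YAML file path.
#' @param seed optional seed overriding the file's.
#' @return an [experimentConfig()].
#' @export
readExperimentConfig <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  pick <- function(key, default) if (!is.null(y[[key]])) y[[key]] else default
  if (is.null(seed)) seed <- pick("seed", 1L)
  fl <- y$filter
  filt <- filterSpec(
    hpHz = if (!is.null(fl$hp_hz)) fl$hp_hz else 1,
    lpHz = if (!is.null(fl$lp_hz)) fl$lp_hz else 40)
  sy <- y$synth
  sv <- function(key, default)
    if (!is.null(sy[[key]])) sy[[key]] else default
  comps <- if (!is.null(sy$components)) {
    topoByName <- list(N2 = .topoFrontal, P300 = .topoCentroParietal,
                       N700 = .topoCentral)
    lapply(sy$components, function(cm) {
      topo <- topoByName[[cm$name]]
      if (is.null(topo)) topo <- .topoCentral
      erpComponent(cm$name, cm$center_s, cm$width_s, cm$amplitude_uv, topo)
    })
  } else defaultErpComponents()
  synth <- synthConfig(
    fsHz = sv("fs_hz", 250),
    components = comps,
    ssrAmplitudeUv = sv("ssr_amplitude_uv", 1),
    noiseSigmaUv = sv("noise_sigma_uv", 15),
    oneOverFExponent = sv("one_over_f_exponent", 1),
    latencyJitterSdS = sv("latency_jitter_sd_s", 0.02),
    eogBlinkRateHz = sv("eog_blink_rate_hz", 0),
    eogAmplitudeUv = sv("eog_amplitude_uv", 100),
    seed = seed)
  experimentConfig(
    seed = seed,
    nSequences = pick("n_sequences", 15L),
    soaS = pick("soa_s", 0.2),
    synth = synth,
    filter = filt,
    tminS = pick("tmin_s", -0.1),
    tmaxS = pick("tmax_s", 1.0),
    pipeline = pick("pipeline", "lda"),
    offlineRuns = pick("offline_runs", 6L),
    onlineRuns = pick("online_runs", 3L),
    trialsPerRun = pick("trials_per_run", 5L),
    binS = pick("bin_s", 0.1))
}
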