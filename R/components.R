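#' Define an ERP component for the synthetic generator
#'
#' A component is a scalp topography (one gain per channel), a latency rule
#' tying its peak to an event on each trial, a smooth waveform, and an
#' amplitude rule. Waveforms are band-limited bumps (Gaussian, half-sine)
#' or a pre-movement ramp, compatible with the 0.5-15 Hz analysis band.
#'
#' @param name Component label (e.g. "P2", "N400", "P3", "MRP_MP").
#' @param topography Named numeric vector, one gain per channel.
#' @param latency List: `type` one of `"stimulus"`, `"rt"`, `"cue"`,
#'   `"response"`, `"column"`; `offset` seconds added to the anchoring
#'   event; `jitter_sd` Gaussian latency jitter SD in seconds; `column`
#'   (for type `"column"`) names a trial-table column holding per-trial
#'   latencies in seconds from target onset.
#' @param waveform List: `shape` one of `"gauss"` (width = SD), `"halfsine"`
#'   (width = half-width), `"ramp"` (linear rise over `width` s ending at
#'   the latency); `width_s` in seconds.
#' @param amplitude List: `type` `"constant"` or `"linear_logas"`; `base`
#'   microvolt; `slope` microvolt per latent log-AS unit (linear_logas:
#'   amplitude = base + slope * latent log-AS, with AS = 0 mapped to a
#'   finite floor).
#' @return A `component_spec` list.
#' @export
component_spec <- function(name, topography, latency, waveform, amplitude) {
  stopifnot(is.numeric(topography), !is.null(names(topography)))
  if (!(waveform$width_s > 0)) stopf("component %s: waveform width must be > 0", name)
  latency$offset <- latency$offset %||% 0
  latency$jitter_sd <- latency$jitter_sd %||% 0
  structure(list(name = name, topography = topography, latency = latency,
                 waveform = waveform, amplitude = amplitude),
            class = "component_spec")
}

#' Default component inventory for a condition
#'
#' Speeded condition: stimulus-locked P2 and N400 (N400 amplitude graded in
#' latent log-AS, most negative for unrelated pairs, centro-parietal), a
#' decision-locked P3 whose latency equals RT plus Gaussian jitter
#' (posterior, slightly left), and response-locked motor activity (negative
#' ramp over the 0.3 s before the press plus a bipolar motor potential at
#' press onset). Delayed condition: the same stimulus-locked components, no
#' decision-locked P3 by default, motor activity at the (late) response,
#' and a cue-evoked anterior P2 peaking 0.3 s after the response cue.
#'
#' @param channel_names Montage the topographies are expressed over.
#' @param condition `"speeded"` or `"delayed"`.
#' @param p3_amplitude_uv P3 peak amplitude at its topography maximum.
#' @param p3_jitter_sd SD (s) of the P3-latency jitter around RT.
#' @param n400_base,n400_slope N400 amplitude rule (microvolt;
#'   amplitude = base + slope * latent log-AS).
#' @param include_p3 Override the default P3 presence (e.g. a weak covert
#'   P3 in the delayed condition via `latency$type = "column"` is built by
#'   the caller instead).
#' @return List of `component_spec`s.
#' @export
default_component_specs <- function(channel_names,
                                    condition = c("speeded", "delayed"),
                                    p3_amplitude_uv = 8, p3_jitter_sd = 0.05,
                                    n400_base = -4.5, n400_slope = 0.75,
                                    include_p3 = NULL) {
  condition <- match.arg(condition)
  if (is.null(include_p3)) include_p3 <- condition == "speeded"
  specs <- list(
    component_spec("P2", topo_frontocentral(channel_names),
                   latency = list(type = "stimulus", offset = 0.20),
                   waveform = list(shape = "gauss", width_s = 0.04),
                   amplitude = list(type = "constant", base = 5)),
    component_spec("N400", topo_centroparietal(channel_names),
                   latency = list(type = "stimulus", offset = 0.40),
                   waveform = list(shape = "gauss", width_s = 0.09),
                   amplitude = list(type = "linear_logas",
                                    base = n400_base, slope = n400_slope)),
    component_spec("MRP_NS", topo_frontocentral(channel_names),
                   latency = list(type = "response", offset = 0),
                   waveform = list(shape = "ramp", width_s = 0.3),
                   amplitude = list(type = "constant", base = -2)),
    component_spec("MRP_MP", topo_motor_bipolar(channel_names),
                   latency = list(type = "response", offset = 0),
                   waveform = list(shape = "gauss", width_s = 0.03),
                   amplitude = list(type = "constant", base = 3))
  )
  if (include_p3) {
    specs <- c(specs, list(
      component_spec("P3", topo_posterior_left(channel_names),
                     latency = list(type = "rt", offset = 0,
                                    jitter_sd = p3_jitter_sd),
                     waveform = list(shape = "gauss", width_s = 0.09),
                     amplitude = list(type = "constant",
                                      base = p3_amplitude_uv))
    ))
  }
  if (condition == "delayed") {
    specs <- c(specs, list(
      component_spec("cueP2", topo_anterior_right(channel_names),
                     latency = list(type = "cue", offset = 0.30),
                     waveform = list(shape = "gauss", width_s = 0.04),
                     amplitude = list(type = "constant", base = 4))
    ))
  }
  specs
}

# evaluate a component's waveform at times t (seconds) for peak/end at
# `center`; unit peak amplitude
component_waveform <- function(shape, width, t, center) {
  d <- t - center
  switch(shape,
    gauss = exp(-d^2 / (2 * width^2)),
    halfsine = ifelse(abs(d) <= width, cos(pi * d / (2 * width)), 0),
    # linear rise from 0 at center-width to 1 at center, zero elsewhere
    ramp = ifelse(d >= -width & d <= 0, (d + width) / width, 0),
    stopf("unknown waveform shape '%s'", shape)
  )
}

# time support outside which the waveform is negligible
component_support <- function(shape, width) {
  switch(shape, gauss = 5 * width, halfsine = width, ramp = width)
}

# per-trial peak amplitude in microvolt (at topography gain 1)
component_amplitude <- function(spec, as_score, zero_as_latent = -2) {
  a <- spec$amplitude
  switch(a$type,
    constant = rep(a$base, length(as_score)),
    linear_logas = a$base + a$slope * latent_log_as(as_score, zero_as_latent),
    stopf("unknown amplitude rule '%s'", a$type)
  )
}
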