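#' Standard 32-channel 10-20 montage (plus EOG)
#'
#' Channel labels of the extended 10-20 layout used throughout, in the
#' order signals are stored. An `"EOG"` channel is appended for the ocular
#' artifact channel.
#'
#' @param n Either 32 (full montage) or 9 (a reduced posterior-centred
#'   montage used for faster simulations; always contains Pz).
#' @param eog Logical, append the EOG channel.
#' @return Character vector of channel names.
#' @export
default_montage <- function(n = 32, eog = TRUE) {
  full <- c(
    "Fp1", "AF3", "F7", "F3", "FC1", "FC5", "T7", "C3",
    "CP1", "CP5", "P7", "P3", "Pz", "PO3", "O1", "Oz",
    "O2", "PO4", "P4", "P8", "CP6", "CP2", "C4", "T8",
    "FC6", "FC2", "F4", "F8", "AF4", "Fp2", "Fz", "Cz"
  )
  ch <- switch(as.character(n),
    "32" = full,
    "9"  = c("Fp1", "Fz", "Cz", "C3", "C4", "P3", "Pz", "P4", "Oz"),
    stopf("default_montage: n must be 32 or 9, got %s", n)
  )
  if (eog) ch <- c(ch, "EOG")
  ch
}

# scalp gain profile: named template values for known electrodes, anything
# unnamed gets `other`. Returns a gain per requested channel.
topo_gains <- function(channel_names, gains, other = 0) {
  out <- rep(other, length(channel_names))
  names(out) <- channel_names
  hit <- intersect(names(gains), channel_names)
  out[hit] <- gains[hit]
  out["EOG"] <- 0  # brain components never project to the EOG channel
  out[channel_names]
}

# canonical topographies for the simulated components (unit peak gain)
topo_frontocentral <- function(ch) topo_gains(ch, c(
  Fz = 1, Cz = 0.9, FC1 = 0.8, FC2 = 0.8, F3 = 0.7, F4 = 0.7,
  C3 = 0.6, C4 = 0.6, Fp1 = 0.4, Fp2 = 0.4, AF3 = 0.5, AF4 = 0.5,
  Pz = 0.3, CP1 = 0.4, CP2 = 0.4
), other = 0.1)

topo_centroparietal <- function(ch) topo_gains(ch, c(
  Pz = 1, CP1 = 0.85, CP2 = 0.85, Cz = 0.7, P3 = 0.75, P4 = 0.75,
  PO3 = 0.6, PO4 = 0.6, Oz = 0.4, C3 = 0.5, C4 = 0.5, Fz = 0.3
), other = 0.1)

topo_posterior_left <- function(ch) topo_gains(ch, c(
  Pz = 1, P3 = 0.9, CP1 = 0.8, PO3 = 0.7, CP5 = 0.6, P4 = 0.6,
  CP2 = 0.6, Cz = 0.5, Oz = 0.5, P7 = 0.4
), other = 0.05)

# motor potential: dipole-like, positive left-posterior, negative
# central-frontal (right-hand button press, contralateral M1)
topo_motor_bipolar <- function(ch) topo_gains(ch, c(
  C3 = -1, FC1 = -0.8, Cz = -0.7, FC5 = -0.6, Fz = -0.5, C4 = -0.3,
  CP1 = 0.3, P3 = 0.6, CP5 = 0.5, Pz = 0.4, PO3 = 0.3
), other = 0)

topo_anterior_right <- function(ch) topo_gains(ch, c(
  F4 = 1, FC2 = 0.9, Fz = 0.8, AF4 = 0.7, F8 = 0.6, Cz = 0.6,
  FC6 = 0.6, Fp2 = 0.5, C4 = 0.5, Pz = 0.2
), other = 0.05)

# ocular propagation: strongest frontally, decaying toward posterior sites
default_eog_propagation <- function(channel_names) {
  g <- topo_gains(channel_names, c(
    Fp1 = 0.18, Fp2 = 0.18, AF3 = 0.12, AF4 = 0.12, F7 = 0.08,
    F8 = 0.08, F3 = 0.07, F4 = 0.07, Fz = 0.07, FC1 = 0.04,
    FC2 = 0.04, FC5 = 0.04, FC6 = 0.04, Cz = 0.03, C3 = 0.02,
    C4 = 0.02, T7 = 0.02, T8 = 0.02
  ), other = 0.01)
  g["EOG"] <- 0
  g
}
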