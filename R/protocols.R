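# Imaging protocols ---------------------------------------------------------

#' Describe a single-molecule imaging protocol
#'
#' An imaging protocol bundles the acquisition settings that the simulator and
#' the trajectory analyses need: the frame exposure, the time between frame
#' starts (equal to the exposure for continuous streaming, longer when dark
#' gaps are interspersed for time-lapse acquisition), the pixel size, the
#' localization error and the ensemble photobleaching decay rate measured
#' under continuous imaging.
#'
#' @param exposure_s Exposure time of each frame (s).
#' @param interval_s Time between consecutive frame starts (s); must be at
#'   least `exposure_s`. For time-lapse protocols this is approximately the
#'   dark-gap duration, since the exposure is comparatively negligible.
#' @param pixel_um Camera pixel size in the sample plane (um).
#' @param loc_sigma_um Localization error, standard deviation per axis (um).
#' @param bleach_rate_continuous Ensemble fluorescence decay rate observed
#'   under continuous imaging (1/s). Bleaching happens during exposures only,
#'   so the corresponding per-frame bleaching probability is the same for all
#'   protocols sharing the exposure (see [bleach_frame_prob()]).
#'
#' @return An object of class `imaging_protocol` (a named list).
#' @seealso [protocol_continuous()], [protocol_timelapse()]
#' @export
#' @examples
#' imaging_protocol(interval_s = 0.5)
imaging_protocol <- function(exposure_s = 0.005,
                             interval_s = 1 / 197,
                             pixel_um = 0.160,
                             loc_sigma_um = 0.025,
                             bleach_rate_continuous = 0.34) {
  stopifnot(
    is.numeric(exposure_s), length(exposure_s) == 1L, exposure_s > 0,
    is.numeric(interval_s), length(interval_s) == 1L,
    interval_s >= exposure_s,
    pixel_um > 0, loc_sigma_um >= 0, bleach_rate_continuous >= 0
  )
  structure(
    list(
      exposure_s = exposure_s,
      interval_s = interval_s,
      pixel_um = pixel_um,
      loc_sigma_um = loc_sigma_um,
      bleach_rate_continuous = bleach_rate_continuous
    ),
    class = "imaging_protocol"
  )
}

#' Standard continuous-streaming protocol (197 frames per second)
#'
#' @param ... Overrides passed to [imaging_protocol()].
#' @return An `imaging_protocol`.
#' @export
protocol_continuous <- function(...) {
  imaging_protocol(...)
}

#' Time-lapse protocol with dark gaps between short exposures
#'
#' Short exposures separated by dark periods extend the observation window for
#' long binding events while keeping the per-frame bleaching probability fixed
#' at its continuous-imaging value.
#'
#' @param interval_s Inter-frame time (s), e.g. 0.1, 0.5 or 1.
#' @param ... Overrides passed to [imaging_protocol()].
#' @return An `imaging_protocol`.
#' @export
protocol_timelapse <- function(interval_s, ...) {
  imaging_protocol(interval_s = interval_s, ...)
}

#' Per-frame photobleaching probability of a protocol
#'
#' Bleaching is driven by the light absorbed during exposures, so the
#' probability that a fluorophore photobleaches at any given frame is set by
#' the continuous-imaging decay rate and the continuous inter-frame time,
#' independently of the dark-gap length of the protocol in use.
#'
#' @param protocol An [imaging_protocol()].
#' @param interval_continuous Inter-frame time of the continuous reference
#'   acquisition (s); the default corresponds to 197 frames per second.
#' @return Bleaching probability per acquired frame.
#' @export
#' @examples
#' bleach_frame_prob(protocol_timelapse(1)) # same as for continuous imaging
bleach_frame_prob <- function(protocol, interval_continuous = 1 / 197) {
  stopifnot(inherits(protocol, "imaging_protocol"))
  1 - exp(-protocol$bleach_rate_continuous * interval_continuous)
}

#' @export
print.imaging_protocol <- function(x, ...) {
  cat(sprintf(
    "<imaging_protocol> exposure %.4g s, interval %.4g s, pixel %.3g um,\n  localization sd %.3g um, continuous bleach rate %.3g /s\n",
    x$exposure_s, x$interval_s, x$pixel_um, x$loc_sigma_um,
    x$bleach_rate_continuous
  ))
  invisible(x)
}

#' Short label for a protocol ("continuous" or "tl_<interval>")
#'
#' @param protocol An [imaging_protocol()].
#' @return A character scalar used to tag events and survival curves.
#' @export
protocol_label <- function(protocol) {
  stopifnot(inherits(protocol, "imaging_protocol"))
  if (protocol$interval_s <= 2 * protocol$exposure_s) {
    "continuous"
  } else {
    sprintf("tl_%g", protocol$interval_s)
  }
}
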