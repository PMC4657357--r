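# Scene configuration I/O (YAML) and small CSV emitters.

#' Write a session scene to a YAML config
#'
#' @param scene a [session_scene].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scene_yaml <- function(scene, path) {
  stopifnot(inherits(scene, "session_scene"))
  cfg <- list(
    isolated = scene$isolated,
    n_calls = scene$n_calls,
    snr_db = scene$snr_db,
    seed = scene$seed,
    fs = scene$fs,
    sound_speed = scene$sound_speed,
    hydrophones = apply(scene$hydrophones, 1, as.list),
    isolated_region = apply(scene$isolated_region, 1, as.list),
    group_region = apply(scene$group_region, 1, as.list),
    gap_s = as.list(scene$gap_s),
    isolated_fraction = scene$isolated_fraction,
    noise_low_band_boost = scene$noise_low_band_boost,
    profiles = lapply(scene$profiles, function(p) unclass(p))
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a session scene from a YAML config
#'
#' @param path YAML file written by [write_scene_yaml()].
#' @return a [session_scene].
#' @export
read_scene_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  profiles <- lapply(cfg$profiles, function(p) do.call(individual_profile, p))
  names(profiles) <- vapply(profiles, `[[`, character(1), "label")
  session_scene(
    profiles = profiles,
    isolated = cfg$isolated,
    n_calls = cfg$n_calls,
    snr_db = cfg$snr_db,
    seed = cfg$seed,
    fs = cfg$fs,
    hydrophones = do.call(rbind, lapply(cfg$hydrophones, unlist)),
    sound_speed = cfg$sound_speed,
    isolated_region = do.call(rbind, lapply(cfg$isolated_region, unlist)),
    group_region = do.call(rbind, lapply(cfg$group_region, unlist)),
    gap_s = unlist(cfg$gap_s),
    isolated_fraction = cfg$isolated_fraction,
    noise_low_band_boost = cfg$noise_low_band_boost
  )
}

#' Write a pulse table to CSV
#'
#' One row per detected pulse: call id, channel, peak time and amplitude.
#'
#' @param trains list of `pulse_train` objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pulse_csv <- function(trains, path) {
  rows <- do.call(rbind, lapply(trains, function(tr) {
    if (tr$empty) return(NULL)
    data.frame(call_id = tr$call_id, channel = tr$channel,
               peak_time_s = tr$peak_times,
               amplitude = tr$peak_amplitudes)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
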