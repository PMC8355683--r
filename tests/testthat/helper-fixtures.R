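# Small hand-built and simulated fixtures shared across test files.

utc <- function(x) as.POSIXct(x, tz = "UTC")

# minimal three-station array around a common centre
tiny_stations <- function(ids = c("R1", "R2", "R3")) {
  data.frame(receiver_id = ids,
             lat = 17.19 + seq_along(ids) * 0.02,
             lon = -87.53 + seq_along(ids) * 0.01,
             depth_m = 12,
             stringsAsFactors = FALSE)
}

tiny_sharks <- function(ids = "X", sex = "F", tl = 160,
                        tagged = as.Date("2007-05-01")) {
  data.frame(shark_id = ids, sex = sex, tl_cm = tl,
             date_tagged = rep(as.Date(tagged), length.out = length(ids)),
             capture_date = as.Date(NA),
             stringsAsFactors = FALSE)
}

# build a detection_set from (time, receiver, shark) triples
tiny_ds <- function(times, receivers, sharks_of_events,
                    stations = NULL, sharks = NULL) {
  ids <- unique(sharks_of_events)
  if (is.null(stations)) stations <- tiny_stations(unique(receivers))
  if (is.null(sharks)) sharks <- tiny_sharks(ids, sex = rep("F", length(ids)),
                                             tl = rep(160, length(ids)))
  detection_set(data.frame(timestamp = utc(times),
                           receiver_id = receivers,
                           transmitter_id = sharks_of_events,
                           stringsAsFactors = FALSE),
                stations, sharks)
}

# small seeded simulated cohort used by several files (lossless by default)
small_sim <- function(seed = 11, n_sharks = c(FA = 2, FC = 3), study_days = 30,
                      p_detect = 1, singleton_rate = 0,
                      tagging_window_days = 5, ...) {
  simulate_cohort(simulation_config(seed = seed, n_sharks = n_sharks,
                                    study_days = study_days,
                                    tagging_window_days = tagging_window_days,
                                    p_detect = p_detect,
                                    singleton_rate = singleton_rate, ...))
}

sim_study_config <- function(cfg) {
  study_config(tag_life_days = cfg$tag_life_days,
               study_start = cfg$study_start, study_end = cfg$study_end,
               n_stations = cfg$n_stations, monthly_summary_end = cfg$study_end)
}
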