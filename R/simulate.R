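#' Configuration of a synthetic telemetry cohort
#'
#' Describes a simulated acoustic-telemetry study: an array of receivers, a
#' cohort of tagged animals with heterogeneous residency by sex and size
#' class, per-group hourly movement kernels over the array's nodes plus an
#' absent state, and the detection process (nominal 90 s transmission
#' interval thinned by a within-range detection probability, with optional
#' planted false single detections). Defaults mirror the study conditions the
#' package's analyses assume: an 18-receiver array with 5.5 km mean spacing
#' and two mergeable receiver pairs, a 77-animal cohort with the observed
#' sex-by-size composition, 1877-day tag life and a 2007--2014 deployment.
#'
#' @param seed master RNG seed; fixes the full output. Per-animal substreams
#'   are derived from it, so cohorts are reproducible regardless of order.
#' @param n_sharks named integer vector of animals per group
#'   (`FA, FB, FC, MA, MB, MC`).
#' @param n_stations,spacing_km,center ring-array layout: stations equally
#'   spaced on a circle with the given between-receiver spacing, centred at
#'   `c(lat, lon)`.
#' @param kernels optional named list of row-stochastic hourly transition
#'   matrices (nodes + `"ABSENT"`), one per group; built with
#'   [default_group_kernels()] when `NULL`.
#' @param p_detect probability a transmission within range is logged.
#' @param interval_s nominal transmission interval (s).
#' @param tag_life_days nominal tag life (d).
#' @param study_start study start date.
#' @param study_days length of the simulated deployment in days; the default
#'   runs to the full study end (2014-05-09).
#' @param tagging_window_days animals are tagged uniformly within this many
#'   days of the start (the field campaigns spanned roughly two years).
#' @param singleton_rate probability of injecting one false detection into an
#'   otherwise empty (animal, receiver, day) cell.
#' @return Object of class `"simulation_config"`.
#' @export
simulation_config <- function(seed = 1,
                              n_sharks = c(FA = 14, FB = 5, FC = 20,
                                           MA = 10, MB = 9, MC = 19),
                              n_stations = 18, spacing_km = 5.5,
                              center = c(17.19, -87.53),
                              kernels = NULL,
                              p_detect = 0.5, interval_s = 90,
                              tag_life_days = 1877,
                              study_start = "2007-04-23",
                              study_days = 2573,
                              tagging_window_days = 730,
                              singleton_rate = 0.01) {
  stopifnot(all(n_sharks >= 0), p_detect >= 0, p_detect <= 1,
            interval_s > 0, tag_life_days > 0, study_days > 1,
            singleton_rate >= 0, singleton_rate <= 1)
  if (is.null(names(n_sharks)) ||
      !all(names(n_sharks) %in% c("FA", "FB", "FC", "MA", "MB", "MC")))
    stop("n_sharks must be named with groups among FA, FB, FC, MA, MB, MC")
  structure(list(seed = seed, n_sharks = n_sharks, n_stations = n_stations,
                 spacing_km = spacing_km, center = center, kernels = kernels,
                 p_detect = p_detect, interval_s = interval_s,
                 tag_life_days = tag_life_days,
                 study_start = as.Date(study_start),
                 study_end = as.Date(study_start) + study_days,
                 tagging_window_days = min(tagging_window_days, study_days - 1),
                 singleton_rate = singleton_rate),
            class = "simulation_config")
}

#' Simulated receiver array
#'
#' Places `n_stations` receivers equally spaced on a ring whose circumference
#' gives the configured between-receiver spacing. Station ids run 1..19 with
#' 17 unused, so that the two conventionally merged pairs (15+16, 18+19) sit
#' adjacent on the ring; [default_node_map()] then yields 16 nodes.
#'
#' @param cfg a [simulation_config()].
#' @return Station data.frame (`receiver_id`, `lat`, `lon`, `depth_m`).
#' @export
simulate_array <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  n <- cfg$n_stations
  if (n < 3) stop("degenerate layout: need at least 3 stations")
  ids <- as.character(setdiff(1:(n + 1), 17))[1:n]
  radius <- n * cfg$spacing_km / (2 * pi)
  theta <- 2 * pi * (seq_len(n) - 1) / n
  x <- radius * cos(theta); y <- radius * sin(theta)
  lat <- cfg$center[1] + y / 111.32
  lon <- cfg$center[2] + x / (111.32 * cos(cfg$center[1] * pi / 180))
  set.seed(cfg$seed)
  data.frame(receiver_id = ids, lat = lat, lon = lon,
             depth_m = round(stats::runif(n, 8, 25), 1),
             stringsAsFactors = FALSE)
}

#' Default per-group movement kernels
#'
#' Hourly transition kernels over ring-ordered nodes plus the absent state,
#' parameterised by three rates: the probability of staying at the current
#' node, of leaving the array (to `ABSENT`), and of returning from `ABSENT`.
#' Remaining node mass moves to ring neighbours; returns from absence favour
#' a three-node "corridor" (weight 3), mimicking the concentration of
#' movement on one flank of an atoll. Stationary absent-state mass is
#' `leave/(leave + return)`, set between 0.77 and 0.93 across groups, with
#' mature animals stickier (higher node persistence) and females more
#' resident than males.
#'
#' @param nodes node labels in ring order.
#' @param params optional data.frame overriding the per-group rates (`group`,
#'   `stay`, `leave`, `ret`).
#' @return Named list of row-stochastic matrices over `c(nodes, "ABSENT")`.
#' @export
default_group_kernels <- function(nodes, params = NULL) {
  if (is.null(params))
    params <- data.frame(
      group = c("FA", "FB", "FC", "MA", "MB", "MC"),
      stay  = c(0.78, 0.75, 0.85, 0.72, 0.74, 0.82),
      leave = c(0.05, 0.06, 0.03, 0.06, 0.06, 0.05),
      ret   = c(0.007, 0.006, 0.009, 0.005, 0.006, 0.008),
      stringsAsFactors = FALSE)
  k <- length(nodes)
  corridor <- nodes[pmin(k, 8:10)]  # favoured re-entry flank
  build <- function(stay, leave, ret) {
    states <- c(nodes, "ABSENT")
    K <- matrix(0, k + 1, k + 1, dimnames = list(states, states))
    for (i in seq_len(k)) {
      K[i, i] <- stay
      K[i, k + 1] <- leave
      nb <- c(if (i > 1) i - 1 else k, if (i < k) i + 1 else 1)
      K[i, nb] <- K[i, nb] + (1 - stay - leave) / 2
    }
    w <- ifelse(nodes %in% corridor, 3, 1)
    K[k + 1, seq_len(k)] <- ret * w / sum(w)  # total re-entry mass = ret
    K[k + 1, k + 1] <- 1 - ret
    K
  }
  kern <- lapply(seq_len(nrow(params)), function(i)
    build(params$stay[i], params$leave[i], params$ret[i]))
  names(kern) <- params$group
  kern
}

.ring_nodes <- function(stations) {
  map <- default_node_map(stations$receiver_id)
  # ring order: station order, collapsing merged pairs at first occurrence
  unique(unname(map$mapping[as.character(stations$receiver_id)]))
}

.sim_markov <- function(K, n_steps, start_state) {
  cum <- t(apply(K, 1, cumsum))
  s <- integer(n_steps)
  u <- stats::runif(n_steps - 1)
  s[1] <- start_state
  for (i in seq_len(n_steps - 1))
    s[i + 1] <- findInterval(u[i], cum[s[i], ]) + 1L
  s
}

#' Simulate true hourly movement tracks
#'
#' Draws each animal's hourly state (node or absent) from its group's
#' transition kernel, from a random starting node at tagging until the
#' earlier of tag death and study end. Movement is simulated directly on the
#' node-plus-absent state space — exactly the process the EDMC estimator
#' assumes — so estimated transition matrices can be checked against the
#' generating kernels.
#'
#' @param cfg a [simulation_config()].
#' @return Object of class `"ground_truth"`: `stations`, `sharks` (metadata
#'   table), `states` (per-animal integer state sequences with state labels
#'   in `$state_labels`), `kernels`, `monthly_days` (per-animal per-month
#'   true detection-day counts), and `start_hour` per animal.
#' @export
simulate_tracks <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  stations <- simulate_array(cfg)
  nodes <- .ring_nodes(stations)
  kernels <- if (is.null(cfg$kernels)) default_group_kernels(nodes) else cfg$kernels
  for (K in kernels)
    if (max(abs(rowSums(K) - 1)) > 1e-9) stop("kernels must be row-stochastic")
  groups <- rep(names(cfg$n_sharks), cfg$n_sharks)
  n <- length(groups)
  set.seed(cfg$seed)
  shark_seeds <- sample.int(.Machine$integer.max, n)
  tag_offset <- floor(stats::runif(n, 0, cfg$tagging_window_days + 1))
  tl_range <- list(FA = c(100, 149), FB = c(150, 180), FC = c(181, 235),
                   MA = c(95, 129), MB = c(130, 160), MC = c(161, 210))
  tl <- vapply(seq_len(n), function(i)
    round(stats::runif(1, tl_range[[groups[i]]][1], tl_range[[groups[i]]][2]) * 2) / 2,
    numeric(1))
  ids <- sprintf("S%02d", seq_len(n))
  sharks <- data.frame(shark_id = ids,
                       sex = substr(groups, 1, 1),
                       tl_cm = tl,
                       date_tagged = cfg$study_start + tag_offset,
                       capture_date = as.Date(NA),
                       stringsAsFactors = FALSE)
  sharks$size_class <- assign_size_class(sharks$sex, sharks$tl_cm)
  state_labels <- c(nodes, "ABSENT")
  states <- vector("list", n); names(states) <- ids
  start_hour <- stats::setNames(rep(as.POSIXct(NA, tz = "UTC"), n), ids)
  monthly <- vector("list", n); names(monthly) <- ids
  for (i in seq_len(n)) {
    set.seed(shark_seeds[i])
    t0 <- as.POSIXct(paste(sharks$date_tagged[i], "00:00:00"), tz = "UTC")
    tend <- min(as.POSIXct(paste(sharks$date_tagged[i] + cfg$tag_life_days - 1,
                                 "23:00:00"), tz = "UTC"),
                as.POSIXct(paste(cfg$study_end, "23:00:00"), tz = "UTC"))
    n_steps <- floor(as.numeric(difftime(tend, t0, units = "hours"))) + 1
    K <- kernels[[groups[i]]]
    states[[i]] <- .sim_markov(K, n_steps, start_state = sample(length(nodes), 1))
    start_hour[i] <- t0
    present <- states[[i]] <= length(nodes)
    day <- as.Date(t0 + (seq_len(n_steps) - 1) * 3600, tz = "UTC")[present]
    ym <- format(unique(day), "%Y-%m")
    monthly[[i]] <- table(ym)
  }
  structure(list(stations = stations, sharks = sharks, states = states,
                 state_labels = state_labels, kernels = kernels,
                 groups = stats::setNames(groups, ids),
                 start_hour = start_hour, monthly_days = monthly,
                 config = cfg),
            class = "ground_truth")
}

#' Emit detections from true tracks
#'
#' For every hour an animal spends at a node, transmission times are laid out
#' at the nominal interval from a random phase and each is logged with the
#' configured detection probability at one member receiver of the node. False
#' detections are then planted as single detections in otherwise empty
#' (animal, receiver, day) cells at the configured rate — exactly the pattern
#' the single-detection filter removes.
#'
#' @param truth a `"ground_truth"` from [simulate_tracks()].
#' @param cfg the same [simulation_config()].
#' @return A `"detection_set"`; the planted singletons are recorded in
#'   attribute `"planted_singletons"` (data.frame `shark`, `receiver`, `day`).
#' @export
simulate_detections <- function(truth, cfg = truth$config) {
  stopifnot(inherits(truth, "ground_truth"))
  nodes <- truth$state_labels[truth$state_labels != "ABSENT"]
  map <- default_node_map(truth$stations$receiver_id)
  members <- split(names(map$mapping), unname(map$mapping))
  set.seed(cfg$seed + 1L)
  out_ts <- list(); out_rx <- list(); out_id <- list()
  planted <- list()
  slots <- seq(0, 3599, by = cfg$interval_s)
  for (id in names(truth$states)) {
    st <- truth$states[[id]]
    present <- which(st <= length(nodes))
    if (length(present)) {
      hours0 <- as.numeric(truth$start_hour[id]) + (present - 1) * 3600
      phase <- stats::runif(length(present), 0, cfg$interval_s)
      rx <- vapply(truth$state_labels[st[present]], function(nd)
        members[[nd]][sample.int(length(members[[nd]]), 1)], character(1))
      kept <- lapply(seq_along(present), function(j) {
        keep <- stats::runif(length(slots)) < cfg$p_detect
        hours0[j] + phase[j] + slots[keep]
      })
      nk <- lengths(kept)
      out_ts[[id]] <- unlist(kept)
      out_rx[[id]] <- rep(rx, nk)
      out_id[[id]] <- rep(id, sum(nk))
    }
    # planted false singletons in empty receiver-day cells
    if (cfg$singleton_rate > 0) {
      n_days <- ceiling(length(st) / 24)
      day0 <- as.Date(truth$start_hour[id], tz = "UTC")
      n_cells <- n_days * nrow(truth$stations)
      n_plant <- stats::rbinom(1, n_cells, cfg$singleton_rate)
      if (n_plant > 0) {
        cell <- sample.int(n_cells, n_plant)
        p_day <- day0 + (cell - 1) %/% nrow(truth$stations)
        p_rx <- truth$stations$receiver_id[(cell - 1) %% nrow(truth$stations) + 1]
        occupied <- character()
        if (length(present)) {
          real_day <- as.Date(as.POSIXct(out_ts[[id]], origin = "1970-01-01",
                                         tz = "UTC"), tz = "UTC")
          occupied <- unique(paste(out_rx[[id]], real_day))
        }
        ok <- !(paste(p_rx, p_day) %in% occupied)
        ok <- ok & !duplicated(paste(p_rx, p_day))
        if (any(ok)) {
          t_plant <- as.numeric(as.POSIXct(paste(p_day[ok], "00:00:00"), tz = "UTC")) +
            floor(stats::runif(sum(ok), 0, 86400))
          out_ts[[paste0(id, ".s")]] <- t_plant
          out_rx[[paste0(id, ".s")]] <- p_rx[ok]
          out_id[[paste0(id, ".s")]] <- rep(id, sum(ok))
          planted[[id]] <- data.frame(shark = id, receiver = p_rx[ok],
                                      day = as.character(p_day[ok]),
                                      stringsAsFactors = FALSE)
        }
      }
    }
  }
  events <- data.frame(
    # floor, not round: a transmission must stay inside its hour (and day)
    timestamp = as.POSIXct(floor(unlist(out_ts)), origin = "1970-01-01", tz = "UTC"),
    receiver_id = unlist(out_rx),
    transmitter_id = unlist(out_id),
    stringsAsFactors = FALSE)
  ds <- detection_set(events, truth$stations, truth$sharks)
  attr(ds, "planted_singletons") <-
    if (length(planted)) do.call(rbind, c(planted, make.row.names = FALSE))
    else data.frame(shark = character(), receiver = character(), day = character())
  ds
}

#' Simulate a full cohort
#'
#' Convenience wrapper: [simulate_tracks()] then [simulate_detections()].
#'
#' @param cfg a [simulation_config()].
#' @return List with `truth` (a `"ground_truth"`) and `detections`
#'   (a `"detection_set"`).
#' @export
simulate_cohort <- function(cfg) {
  truth <- simulate_tracks(cfg)
  list(truth = truth, detections = simulate_detections(truth, cfg))
}

#' Parameter-recovery report
#'
#' Runs the cleaning, residency and Markov chain stages on a simulated
#' detection set and measures how well the pipeline recovers the generator's
#' ground truth: transition-kernel error of the pooled empirical chain,
#' residency-index bias, exactness of monthly detection-day counts, and the
#' match between planted and removed false singletons.
#'
#' @param truth a `"ground_truth"`.
#' @param ds the matching raw `"detection_set"` from [simulate_detections()].
#' @return List: `kernel_error_max`, `kernel_error_mean` (pooled empirical
#'   transition matrix vs the pooled generating kernel, over shared states),
#'   `ri_error_max`, `monthly_exact` (logical), `singletons_planted`,
#'   `singletons_removed`.
#' @export
recovery_report <- function(truth, ds) {
  stopifnot(inherits(truth, "ground_truth"), inherits(ds, "detection_set"))
  cfg <- truth$config
  scfg <- study_config(tag_life_days = cfg$tag_life_days,
                       study_start = cfg$study_start, study_end = cfg$study_end,
                       n_stations = cfg$n_stations,
                       monthly_summary_end = cfg$study_end)
  planted <- attr(ds, "planted_singletons")
  clean <- remove_false_detections(ds)
  removed <- sum(clean$filter_log$rows_removed[clean$filter_log$rule == "single_detection"])
  clean <- merge_receiver_nodes(clean)
  if (!all(as.character(ds$sharks$shark_id) %in% names(truth$states)))
    stop("detection set and ground truth carry different animals")

  res <- residency_summary(clean, scfg)
  truth_days <- vapply(names(truth$states), function(id) {
    st <- truth$states[[id]]
    present <- which(st <= length(truth$state_labels) - 1)
    if (!length(present)) return(0)
    length(unique(as.Date(truth$start_hour[id] + (present - 1) * 3600, tz = "UTC")))
  }, numeric(1))
  ri_true <- pmin(truth_days / cfg$tag_life_days, 1)  # keeps names
  m <- match(res$shark_id, names(ri_true))
  ri_error_max <- if (nrow(res)) max(abs(res$ri - ri_true[m])) else NA_real_

  monthly_exact <- all(vapply(res$shark_id, function(id) {
    ser <- compute_monthly_series(clean, id, scfg)
    tr <- truth$monthly_days[[id]]
    ym <- sprintf("%04d-%02d", ser$year, ser$month)
    got <- stats::setNames(ser$days_detected, ym)
    want <- stats::setNames(rep(0L, length(ym)), ym)
    want[intersect(names(tr), ym)] <- as.integer(tr[intersect(names(tr), ym)])
    all(got == want)
  }, logical(1)))

  fit <- edmc(clean, group_by = "pooled")
  P_hat <- fit$chains[[1]]$P
  groups <- truth$groups[names(truth$states)]
  lens <- lengths(truth$states) - 1
  K_pool <- Reduce("+", lapply(unique(groups), function(g)
    truth$kernels[[g]] * sum(lens[groups == g])))
  K_pool <- K_pool / sum(lens)
  shared <- intersect(rownames(P_hat), rownames(K_pool))
  dif <- abs(P_hat[shared, shared] - K_pool[shared, shared])
  list(kernel_error_max = max(dif), kernel_error_mean = mean(dif),
       ri_error_max = ri_error_max, monthly_exact = monthly_exact,
       singletons_planted = nrow(planted), singletons_removed = removed)
}
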