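#' Assemble a detection set
#'
#' Bundles detection events, receiver station metadata and tagged-animal
#' metadata into a single container that the filtering, residency, activity
#' space and Markov chain stages all operate on.
#'
#' @param events data.frame with columns `timestamp` (POSIXct, UTC),
#'   `receiver_id` (character) and `transmitter_id` (character). Events are
#'   sorted by timestamp; ties are broken by receiver id and then input order.
#' @param stations data.frame with columns `receiver_id`, `lat`, `lon`,
#'   `depth_m`. Ids must be unique and coordinates within valid WGS84 ranges.
#' @param sharks data.frame with columns `shark_id`, `sex` (`"F"`/`"M"`),
#'   `tl_cm`, `date_tagged` (Date) and optionally `capture_date` (Date, NA
#'   when the animal was not reported captured). A `size_class` column is
#'   derived with [assign_size_class()] if absent.
#' @param filter_log data.frame recording rows removed per cleaning rule;
#'   usually left `NULL` and grown by the filter functions.
#' @return An object of class `"detection_set"`.
#' @seealso [read_detections()], [remove_false_detections()],
#'   [apply_minimum_days_filter()], [merge_receiver_nodes()]
#' @export
detection_set <- function(events, stations, sharks, filter_log = NULL) {
  stopifnot(is.data.frame(events), is.data.frame(stations), is.data.frame(sharks))
  need <- c("timestamp", "receiver_id", "transmitter_id")
  if (!all(need %in% names(events)))
    stop("events must have columns: ", paste(need, collapse = ", "))
  if (!inherits(events$timestamp, "POSIXct"))
    stop("events$timestamp must be POSIXct")
  attr(events$timestamp, "tzone") <- "UTC"
  events$receiver_id <- as.character(events$receiver_id)
  events$transmitter_id <- as.character(events$transmitter_id)
  if (anyDuplicated(stations$receiver_id))
    stop("duplicate receiver_id in station table")
  if (any(abs(stations$lat) > 90) || any(abs(stations$lon) > 180))
    stop("station coordinates outside valid WGS84 ranges")
  if (nrow(events)) {
    unknown <- setdiff(unique(events$receiver_id), as.character(stations$receiver_id))
    if (length(unknown))
      stop("events reference unknown receivers: ", paste(unknown, collapse = ", "))
  }
  if (!"size_class" %in% names(sharks) && all(c("sex", "tl_cm") %in% names(sharks)))
    sharks$size_class <- assign_size_class(sharks$sex, sharks$tl_cm)
  ord <- order(events$timestamp, events$receiver_id)  # stable: input order last
  events <- events[ord, , drop = FALSE]
  rownames(events) <- NULL
  if (is.null(filter_log))
    filter_log <- data.frame(rule = character(), shark = character(),
                             receiver = character(), day = character(),
                             rows_removed = integer(), stringsAsFactors = FALSE)
  structure(list(events = events, stations = stations, sharks = sharks,
                 filter_log = filter_log),
            class = "detection_set")
}

#' @export
print.detection_set <- function(x, ...) {
  cat("<detection_set>\n")
  cat("  events:  ", nrow(x$events), " detections, ",
      length(unique(x$events$transmitter_id)), " animals\n", sep = "")
  cat("  stations:", nrow(x$stations), "\n")
  cat("  sharks:  ", nrow(x$sharks), " tagged animals\n", sep = "")
  if (nrow(x$filter_log))
    cat("  filtered:", sum(x$filter_log$rows_removed), "rows removed (see $filter_log)\n")
  if (!is.null(x$events$node_id))
    cat("  nodes:   ", length(unique(x$events$node_id)), " (receivers merged)\n", sep = "")
  invisible(x)
}

.parse_timestamp <- function(x) {
  x <- sub("T", " ", as.character(x), fixed = TRUE)
  out <- as.POSIXct(strptime(x, "%Y-%m-%d %H:%M:%OS", tz = "UTC"))
  for (fmt in c("%Y/%m/%d %H:%M:%OS", "%Y-%m-%d")) {
    miss <- is.na(out) & !is.na(x)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = "UTC"))
  }
  out
}

#' Read a detection log with station and animal metadata
#'
#' Reads the standard three-file layout: a detection CSV (`timestamp`,
#' `receiver_id`, `transmitter_id`), a station CSV (`receiver_id`, `lat`,
#' `lon`, `depth_m`) and a shark CSV (`shark_id`, `sex`, `tl_cm`,
#' `date_tagged`, `capture_date`). Rows with unparseable timestamps are
#' rejected with line-level diagnostics; detections at receivers missing from
#' the station table are quarantined with a warning rather than silently
#' dropped.
#'
#' @param path path to the detection CSV.
#' @param stations station CSV path or an equivalent data.frame.
#' @param sharks shark CSV path or an equivalent data.frame.
#' @return A `"detection_set"`. Row-level parse problems are attached as
#'   attribute `"diagnostics"` (a data.frame with `line` and `problem`), and
#'   quarantined unknown-receiver rows as attribute `"quarantine"`.
#' @export
read_detections <- function(path, stations, sharks) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "receiver_id", "transmitter_id")
  if (!all(need %in% names(raw)))
    stop("detection CSV must have columns: ", paste(need, collapse = ", "))
  if (is.character(stations)) stations <- read_stations(stations)
  if (is.character(sharks)) sharks <- read_sharks(sharks)

  ts <- suppressWarnings(.parse_timestamp(raw$timestamp))
  bad <- which(is.na(ts))
  diagnostics <- data.frame(line = bad + 1L,  # +1 for the header line
                            problem = rep("unparseable timestamp", length(bad)),
                            stringsAsFactors = FALSE)
  keep <- raw[setdiff(seq_len(nrow(raw)), bad), , drop = FALSE]
  ts <- ts[setdiff(seq_len(nrow(raw)), bad)]
  unknown <- !(as.character(keep$receiver_id) %in% as.character(stations$receiver_id))
  quarantine <- keep[unknown, , drop = FALSE]
  if (any(unknown))
    warning(sum(unknown), " detections at receivers absent from the station table",
            " were quarantined")
  events <- data.frame(timestamp = ts[!unknown],
                       receiver_id = as.character(keep$receiver_id[!unknown]),
                       transmitter_id = as.character(keep$transmitter_id[!unknown]),
                       stringsAsFactors = FALSE)
  ds <- detection_set(events, stations, sharks)
  attr(ds, "diagnostics") <- diagnostics
  attr(ds, "quarantine") <- quarantine
  ds
}

#' @rdname read_detections
#' @export
read_stations <- function(path) {
  st <- utils::read.csv(path, stringsAsFactors = FALSE)
  st$receiver_id <- as.character(st$receiver_id)
  st
}

#' @rdname read_detections
#' @export
read_sharks <- function(path) {
  sh <- utils::read.csv(path, stringsAsFactors = FALSE)
  sh$shark_id <- as.character(sh$shark_id)
  sh$date_tagged <- as.Date(sh$date_tagged)
  if ("capture_date" %in% names(sh)) {
    sh$capture_date[!nzchar(trimws(ifelse(is.na(sh$capture_date), "", sh$capture_date)))] <- NA
    sh$capture_date <- as.Date(sh$capture_date)
  }
  sh
}

#' Write a detection set to CSV files
#'
#' Writes `detections.csv`, `stations.csv` and `sharks.csv` into `dir`, in
#' the format [read_detections()] reads back.
#'
#' @param ds a `"detection_set"`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_detections <- function(ds, dir) {
  stopifnot(inherits(ds, "detection_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ev <- ds$events[c("timestamp", "receiver_id", "transmitter_id")]
  ev$timestamp <- format(ev$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  paths <- file.path(dir, c("detections.csv", "stations.csv", "sharks.csv"))
  utils::write.csv(ev, paths[1], row.names = FALSE)
  utils::write.csv(ds$stations, paths[2], row.names = FALSE)
  sh <- ds$sharks
  for (col in c("date_tagged", "capture_date"))
    if (col %in% names(sh)) sh[[col]] <- format(sh[[col]], "%Y-%m-%d")
  utils::write.csv(sh, paths[3], row.names = FALSE)
  invisible(paths)
}

.calendar_day <- function(timestamp, tz_offset_hours = 0) {
  as.Date(timestamp + tz_offset_hours * 3600, tz = "UTC")
}

#' Remove potential false detections
#'
#' Drops every detection that is the only one logged for a given animal at a
#' given receiver on a given calendar day. Lone detections are the classic
#' signature of code collisions on 69 kHz receivers, so single
#' (animal, receiver, day) records are treated as unreliable. The rule is
#' idempotent: groups with two or more detections are never touched.
#'
#' @param ds a `"detection_set"`.
#' @param tz_offset_hours hours added to UTC before taking the calendar day.
#'   The day boundary convention is configurable because receiver clocks are
#'   logged in UTC while the biology is local.
#' @param per_receiver if `TRUE` (default) the singleton rule is evaluated per
#'   (animal, receiver, day) triple; if `FALSE`, per (animal, day) across the
#'   whole array.
#' @return The filtered `"detection_set"`; removals are appended to
#'   `$filter_log` under rule `"single_detection"`.
#' @export
remove_false_detections <- function(ds, tz_offset_hours = 0, per_receiver = TRUE) {
  stopifnot(inherits(ds, "detection_set"))
  ev <- ds$events
  if (!nrow(ev)) return(ds)
  day <- .calendar_day(ev$timestamp, tz_offset_hours)
  key <- if (per_receiver)
    paste(ev$transmitter_id, ev$receiver_id, day, sep = "\r")
  else
    paste(ev$transmitter_id, day, sep = "\r")
  n <- ave(seq_along(key), key, FUN = length)
  drop <- n == 1L
  if (any(drop)) {
    dropped <- ev[drop, , drop = FALSE]
    log_add <- data.frame(rule = "single_detection",
                          shark = dropped$transmitter_id,
                          receiver = if (per_receiver) dropped$receiver_id else NA_character_,
                          day = as.character(day[drop]),
                          rows_removed = 1L, stringsAsFactors = FALSE)
    ds$filter_log <- rbind(ds$filter_log, log_add)
    ds$events <- ev[!drop, , drop = FALSE]
    rownames(ds$events) <- NULL
  }
  ds
}

#' Distinct detection days per animal
#'
#' After [remove_false_detections()], every surviving (animal, receiver, day)
#' group holds at least two detections, so a day with any retained detection
#' is automatically a day with at least two — the "daily occurrence" used by
#' the residency metrics.
#'
#' @param ds a `"detection_set"`.
#' @param tz_offset_hours day-boundary offset, as in [remove_false_detections()].
#' @return Named integer vector: distinct detection days per `transmitter_id`.
#' @export
detection_days <- function(ds, tz_offset_hours = 0) {
  ev <- ds$events
  if (!nrow(ev)) return(stats::setNames(integer(), character()))
  day <- .calendar_day(ev$timestamp, tz_offset_hours)
  tapply(day, ev$transmitter_id, function(d) length(unique(d)))[]
}

#' Exclude animals with too few detection days
#'
#' Animals detected on fewer than `min_days` distinct days carry too little
#' information for residency or space-use estimation and are excluded from
#' all downstream analyses.
#'
#' @param ds a `"detection_set"`, already cleaned with
#'   [remove_false_detections()].
#' @param min_days minimum number of distinct detection days (default 5;
#'   animals with *fewer* than this are excluded, so exactly `min_days` days
#'   is retained).
#' @param tz_offset_hours day-boundary offset.
#' @return List with `retained` (the filtered `"detection_set"`, shark table
#'   subset accordingly) and `excluded_ids` (character vector covering both
#'   never-detected and under-detected animals).
#' @export
apply_minimum_days_filter <- function(ds, min_days = 5, tz_offset_hours = 0) {
  stopifnot(inherits(ds, "detection_set"))
  if (min_days < 1) stop("min_days must be >= 1")
  days <- detection_days(ds, tz_offset_hours)
  all_ids <- as.character(ds$sharks$shark_id)
  ndays <- stats::setNames(rep(0L, length(all_ids)), all_ids)
  ndays[names(days)] <- days
  excluded <- names(ndays)[ndays < min_days]
  keep <- !(ds$events$transmitter_id %in% excluded)
  removed <- ds$events[!keep, , drop = FALSE]
  if (nrow(removed)) {
    agg <- stats::aggregate(list(rows_removed = removed$transmitter_id),
                            by = list(shark = removed$transmitter_id), FUN = length)
    ds$filter_log <- rbind(ds$filter_log,
                           data.frame(rule = "min_days", shark = agg$shark,
                                      receiver = NA_character_, day = NA_character_,
                                      rows_removed = agg$rows_removed,
                                      stringsAsFactors = FALSE))
  }
  ds$events <- ds$events[keep, , drop = FALSE]
  rownames(ds$events) <- NULL
  ds$sharks <- ds$sharks[!(as.character(ds$sharks$shark_id) %in% excluded), , drop = FALSE]
  list(retained = ds, excluded_ids = excluded)
}

#' Receiver-to-node mapping
#'
#' A node map collapses receivers that are too close together to yield
#' independent detections into single network nodes. [default_node_map()]
#' reproduces the study array convention: receivers 15 and 16 (two moorings
#' at the Blue Hole) merge into one node, as do 18 and 19 at the northeastern
#' point, turning an 18-receiver array into 16 non-overlapping nodes.
#' Station-level identity is kept alongside node identity because the roaming
#' index divides by receivers (18) while the movement network uses nodes (16).
#'
#' @param mapping named character vector: `receiver_id -> node_id`.
#' @return Object of class `"node_map"`.
#' @export
node_map <- function(mapping) {
  stopifnot(is.character(mapping), !is.null(names(mapping)))
  structure(list(mapping = mapping, nodes = unique(unname(mapping))),
            class = "node_map")
}

#' @rdname node_map
#' @param station_ids receiver ids present in the array.
#' @param merge list of character vectors, each a group of receivers to merge
#'   (merged node id = members joined with `"_"`).
#' @export
default_node_map <- function(station_ids,
                             merge = list(c("15", "16"), c("18", "19"))) {
  station_ids <- as.character(station_ids)
  mapping <- stats::setNames(station_ids, station_ids)
  for (grp in merge) {
    present <- intersect(grp, station_ids)
    if (length(present) > 1)
      mapping[present] <- paste(present, collapse = "_")
  }
  node_map(mapping)
}

#' @export
print.node_map <- function(x, ...) {
  merged <- x$mapping[x$mapping != names(x$mapping)]
  cat("<node_map> ", length(x$mapping), " receivers -> ", length(x$nodes),
      " nodes\n", sep = "")
  if (length(merged))
    for (nd in unique(merged))
      cat("  ", paste(names(merged)[merged == nd], collapse = " + "),
          " -> ", nd, "\n", sep = "")
  invisible(x)
}

#' Relabel detections from receivers to network nodes
#'
#' Adds a `node_id` column to the event table according to a [node_map()].
#' Event count, order and timestamps are untouched and `receiver_id` is kept,
#' so station-level metrics (roaming index) remain computable.
#'
#' @param ds a `"detection_set"`.
#' @param map a `"node_map"`; defaults to [default_node_map()] over the
#'   station table.
#' @return The `"detection_set"` with `events$node_id` set and the map stored
#'   as `$node_map`.
#' @export
merge_receiver_nodes <- function(ds, map = NULL) {
  stopifnot(inherits(ds, "detection_set"))
  if (is.null(map)) map <- default_node_map(ds$stations$receiver_id)
  stopifnot(inherits(map, "node_map"))
  unmapped <- setdiff(as.character(ds$stations$receiver_id), names(map$mapping))
  if (length(unmapped))
    stop("node map does not cover stations: ", paste(unmapped, collapse = ", "))
  ds$events$node_id <- unname(map$mapping[ds$events$receiver_id])
  ds$node_map <- map
  ds
}

#' Assign life-history size class from sex and total length
#'
#' Classifies animals into juvenile (A), subadult (B) and mature (C) stages
#' using sex-specific total-length cut-offs: females are A below 150 cm,
#' B from 150 to 180 cm and C above 180 cm; males are A below 130 cm, B from
#' 130 to 160 cm and C above 160 cm. Band boundaries are inclusive of the
#' subadult class.
#'
#' @param sex character vector of `"F"`/`"M"`.
#' @param tl_cm numeric vector of total lengths (cm), positive.
#' @return Character vector of `"A"`, `"B"` or `"C"`.
#' @export
assign_size_class <- function(sex, tl_cm) {
  sex <- as.character(sex)
  if (!all(sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'")
  if (any(!is.finite(tl_cm)) || any(tl_cm <= 0)) stop("total length must be positive")
  lo <- ifelse(sex == "F", 150, 130)
  hi <- ifelse(sex == "F", 180, 160)
  ifelse(tl_cm < lo, "A", ifelse(tl_cm <= hi, "B", "C"))
}

#' Write the cleaning log
#'
#' @param ds a `"detection_set"`.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_filter_log <- function(ds, path) {
  utils::write.csv(ds$filter_log, path, row.names = FALSE)
  invisible(path)
}
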