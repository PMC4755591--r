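## traffic_io: region keys, traffic panels, voyage records and itinerary
## attribution.

MODE_COLS <- c("passenger_flights", "cargo_flights", "ships")

#' Canonical region label
#'
#' Builds the canonical label for a geopolitical source region: the
#' sub-national unit (state/province/territory) within a country, joined
#' as `"Country—Subdivision"` with an em-dash, or the bare country name
#' for countries without sub-national units (e.g. Singapore, Hong Kong).
#' Labels order lexicographically in the C locale; this ordering is the
#' tie-break used by every ranking function in the package.
#'
#' @param country Character vector of country names.
#' @param subdivision Character vector of subdivision names; `""` or `NA`
#'   for countries without subdivisions.
#' @return Character vector of canonical labels.
#' @examples
#' region_label("New Zealand", "North Island")
#' region_label("Singapore", "")
#' @export
region_label <- function(country, subdivision = "") {
  country <- trimws(as.character(country))
  subdivision <- trimws(as.character(subdivision))
  subdivision[is.na(subdivision)] <- ""
  if (any(!nzchar(country))) {
    stop("country must be non-empty", call. = FALSE)
  }
  ifelse(nzchar(subdivision),
         paste0(country, "\u2014", subdivision),
         country)
}

## Deterministic (C-locale) ordering of region labels, used for every
## tie-break in the package. Radix sort is locale-independent; labels
## are marked UTF-8 first (radix refuses unknown encodings).
order_regions <- function(labels, ...) {
  order(enc2utf8(labels), ..., method = "radix")
}

sort_regions <- function(labels) labels[order_regions(labels)]

#' Construct a traffic panel
#'
#' A traffic panel holds per (region, year) arrival counts for the three
#' traffic modes: passenger flights, cargo flights and ship voyages. It
#' is the substrate of every analysis in the package. Counts are stored
#' as non-negative reals so that fractional journey weights produced by
#' proportional itinerary attribution are represented exactly; integer
#' rounding (half-up) happens only on file export.
#'
#' @param x A data.frame with columns `region`, `year`,
#'   `passenger_flights`, `cargo_flights`, `ships`.
#' @return An object of class `traffic_panel` (a data.frame).
#' @seealso [read_panel()], [write_panel()], [aggregate_records()]
#' @export
traffic_panel <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("region", "year", MODE_COLS)
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    stop("panel is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- x[need]
  x$region <- enc2utf8(as.character(x$region))
  x$year <- as.integer(x$year)
  if (anyNA(x$year)) stop("year must be integer-valued", call. = FALSE)
  for (m in MODE_COLS) {
    v <- as.numeric(x[[m]])
    if (anyNA(v) || any(v < 0) || any(!is.finite(v))) {
      bad <- which(is.na(v) | v < 0 | !is.finite(v))[1L]
      stop(sprintf("invalid %s in row %d: counts must be non-negative", m, bad),
           call. = FALSE)
    }
    x[[m]] <- v
  }
  key <- paste(x$region, x$year, sep = "\r")
  if (anyDuplicated(key)) {
    d <- x[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("duplicate entry for region '%s', year %d", d$region, d$year),
         call. = FALSE)
  }
  x <- x[order_regions(x$region, x$year), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("traffic_panel", "data.frame")
  x
}

#' @export
print.traffic_panel <- function(x, ...) {
  cat(sprintf("Traffic panel: %d regions, years %s\n",
              length(unique(x$region)),
              paste(range(x$year), collapse = "-")))
  print.data.frame(head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat(sprintf("... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Years covered by a panel
#' @param panel A [traffic_panel()].
#' @return Sorted integer vector of years present.
#' @export
panel_years <- function(panel) sort(unique(panel$year))

#' Regions present in a panel (optionally for one year)
#' @param panel A [traffic_panel()].
#' @param year Optional single year.
#' @return Character vector of canonical region labels, C-locale sorted.
#' @export
panel_regions <- function(panel, year = NULL) {
  if (!is.null(year)) panel <- panel[panel$year == year, , drop = FALSE]
  sort_regions(unique(panel$region))
}

## Rows of a panel for one year; errors if the year is absent.
panel_slice <- function(panel, year) {
  stopifnot(length(year) == 1L)
  out <- panel[panel$year == year, , drop = FALSE]
  if (nrow(out) == 0L) {
    stop(sprintf("year %s not present in panel", year), call. = FALSE)
  }
  out
}

detect_delim <- function(header) if (grepl("\t", header, fixed = TRUE)) "\t" else ","

#' Read a traffic panel from delimited text
#'
#' Reads a region-by-year panel with header
#' `region,year,passenger_flights,cargo_flights,ships`. Comma- or
#' tab-delimited files are auto-detected from the header line; files are
#' assumed UTF-8. Blank count cells are read as zero (printed tables
#' commonly leave zero-traffic cells empty); negative or non-integer
#' counts are a validation error naming the offending row.
#'
#' @param path Path to the file.
#' @param dialect `"auto"` (default), `"comma"` or `"tab"`.
#' @return A [traffic_panel()].
#' @examples
#' f <- system.file("extdata", "table1_2012.csv", package = "transportrisk")
#' read_panel(f)
#' @export
read_panel <- function(path, dialect = c("auto", "comma", "tab")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L, encoding = "UTF-8", warn = FALSE)
  if (length(header) == 0L) stop("empty file (no header): ", path, call. = FALSE)
  sep <- switch(dialect, auto = detect_delim(header), comma = ",", tab = "\t")
  df <- read.table(path, header = TRUE, sep = sep, quote = "\"",
                   colClasses = "character", check.names = FALSE,
                   na.strings = character(), fileEncoding = "UTF-8",
                   stringsAsFactors = FALSE)
  need <- c("region", "year", MODE_COLS)
  if (!all(need %in% names(df))) {
    stop("panel header must declare: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) {
    empty <- data.frame(region = character(), year = integer(),
                        passenger_flights = numeric(),
                        cargo_flights = numeric(), ships = numeric(),
                        stringsAsFactors = FALSE)
    return(traffic_panel(empty))
  }
  for (m in MODE_COLS) {
    cell <- trimws(df[[m]])
    cell[!nzchar(cell)] <- "0"
    v <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad)) {
      stop(sprintf(
        "invalid %s '%s' in data row %d of %s: counts must be non-negative integers",
        m, df[[m]][bad[1L]], bad[1L], path), call. = FALSE)
    }
    df[[m]] <- v
  }
  traffic_panel(df)
}

#' Write a traffic panel to delimited text
#'
#' Counts are rounded half-up to integers on export; the in-memory panel
#' is unchanged. The output is a valid [read_panel()] input
#' (round-trips exactly for integer panels).
#'
#' @param panel A [traffic_panel()].
#' @param path Output path.
#' @param dialect `"comma"` (default) or `"tab"`.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, dialect = c("comma", "tab")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(panel, "traffic_panel"))
  out <- as.data.frame(panel)
  for (m in MODE_COLS) out[[m]] <- round_half_up(out[[m]])
  write.table(out, path, sep = if (dialect == "comma") "," else "\t",
              quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

## Half-up rounding; round() rounds half-to-even, which would make
## exported counts depend on parity.
round_half_up <- function(x) floor(x + 0.5)

#' Port-to-region mapping
#'
#' Builds a total mapping from port/airport codes to canonical region
#' labels. Every port appearing in voyage records must be mapped;
#' attribution functions treat unmapped ports as an error rather than
#' dropping traffic silently.
#'
#' @param x A data.frame with columns `port`, `country`, `subdivision`.
#' @return A named character vector (port code -> region label) of class
#'   `port_region_map`.
#' @export
port_region_map <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("port", "country", "subdivision")
  if (!all(need %in% names(x))) {
    stop("port map needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  port <- trimws(as.character(x$port))
  if (anyDuplicated(port)) {
    stop("duplicate port code(s): ",
         paste(unique(port[duplicated(port)]), collapse = ", "), call. = FALSE)
  }
  out <- setNames(region_label(x$country, x$subdivision), port)
  class(out) <- "port_region_map"
  out
}

#' @export
print.port_region_map <- function(x, ...) {
  cat(sprintf("Port-region map: %d ports, %d regions\n",
              length(x), length(unique(unclass(x)))))
  invisible(x)
}

map_ports <- function(map, ports, context = "record") {
  regions <- unclass(map)[ports]
  if (anyNA(regions)) {
    stop(sprintf("unmapped port(s) in %s: %s", context,
                 paste(unique(ports[is.na(regions)]), collapse = ", ")),
         call. = FALSE)
  }
  unname(regions)
}

#' Read a port map file
#' @param path CSV/TSV file with header `port,country,subdivision`.
#' @return A [port_region_map()].
#' @export
read_port_map <- function(path) {
  header <- readLines(path, n = 1L, encoding = "UTF-8", warn = FALSE)
  df <- read.table(path, header = TRUE, sep = detect_delim(header),
                   colClasses = "character", na.strings = character(),
                   fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  port_region_map(df)
}

#' Attribute a flight itinerary to source regions
#'
#' A multi-stop flight record lists every airport visited on the journey,
#' ending at the destination inside the focal country. Two attribution
#' conventions are supported: `last_port` places all journey weight on
#' the region of the final foreign stop (the default throughout the
#' package, and the only convention available for ships); `proportional`
#' splits the journey count equally over all foreign stops, e.g. a
#' London–Singapore–Sydney itinerary counts half to London's region and
#' half to Singapore.
#'
#' @param stops Character vector of port codes in journey order; the last
#'   element is the destination and is never attributed.
#' @param journeys Number of times the journey occurred (>= 1).
#' @param map A [port_region_map()] covering all non-destination stops.
#' @param mode `"last_port"` or `"proportional"`.
#' @return Named numeric vector of fractional journey weights per region,
#'   summing to `journeys`.
#' @examples
#' pm <- port_region_map(data.frame(
#'   port = c("LHR", "SIN"),
#'   country = c("United Kingdom", "Singapore"),
#'   subdivision = c("England", "")))
#' attribute_itinerary(c("LHR", "SIN", "SYD"), 1, pm, "proportional")
#' @export
attribute_itinerary <- function(stops, journeys, map,
                                mode = c("last_port", "proportional")) {
  mode <- match.arg(mode)
  stops <- as.character(stops)
  if (length(stops) < 2L) {
    stop("itinerary must have at least two stops (origin and destination)",
         call. = FALSE)
  }
  journeys <- as.numeric(journeys)
  if (length(journeys) != 1L || is.na(journeys) || journeys < 1) {
    stop("journeys must be a single count >= 1", call. = FALSE)
  }
  origins <- stops[-length(stops)]
  regions <- map_ports(map, origins, context = "itinerary")
  if (mode == "last_port") {
    w <- setNames(journeys, regions[length(regions)])
  } else {
    per_stop <- rep(journeys / length(origins), length(origins))
    agg <- tapply(per_stop, regions, sum)
    w <- setNames(as.numeric(agg), names(agg))
  }
  w[order_regions(names(w))]
}

#' Read voyage-level flight records
#'
#' Pipe-delimited file with fields `stops|journeys|seats|mode|year_month`;
#' `stops` is a "/"-separated list of port codes ending at the
#' destination; `mode` is `passenger` or `cargo` (cargo seats are treated
#' as 0); `year_month` is `YYYY-MM`.
#'
#' @param path Path to the flights file.
#' @return A data.frame with columns `stops` (string), `journeys`,
#'   `seats`, `mode`, `year_month`, `year`.
#' @export
read_flights <- function(path) {
  df <- read.table(path, header = TRUE, sep = "|", colClasses = "character",
                   na.strings = character(), fileEncoding = "UTF-8",
                   stringsAsFactors = FALSE)
  need <- c("stops", "journeys", "seats", "mode", "year_month")
  if (!all(need %in% names(df))) {
    stop("flights file needs fields: ", paste(need, collapse = "|"),
         call. = FALSE)
  }
  df$journeys <- as.numeric(df$journeys)
  df$seats <- as.numeric(df$seats)
  df$seats[df$mode == "cargo"] <- 0
  if (!all(df$mode %in% c("passenger", "cargo"))) {
    stop("flight mode must be 'passenger' or 'cargo'", call. = FALSE)
  }
  df$year <- as.integer(substr(df$year_month, 1L, 4L))
  df
}

#' Read ship arrival records
#' @param path CSV/TSV with header `last_port,count,year`.
#' @return A data.frame with columns `last_port`, `count`, `year`.
#' @export
read_ships <- function(path) {
  header <- readLines(path, n = 1L, encoding = "UTF-8", warn = FALSE)
  df <- read.table(path, header = TRUE, sep = detect_delim(header),
                   colClasses = "character", na.strings = character(),
                   fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  need <- c("last_port", "count", "year")
  if (!all(need %in% names(df))) {
    stop("ships file needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$count <- as.numeric(df$count)
  if (any(df$count < 1)) stop("ship arrival count must be >= 1", call. = FALSE)
  df$year <- as.integer(df$year)
  df
}

#' Write voyage record files
#'
#' Counterparts of [read_flights()], [read_ships()] and
#' [read_port_map()], used by the simulator and the CLI.
#'
#' @param flights,ships Data frames as returned by the readers.
#' @param map A [port_region_map()] or a data.frame with `port`,
#'   `country`, `subdivision`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flights <- function(flights, path) {
  cols <- c("stops", "journeys", "seats", "mode", "year_month")
  write.table(flights[cols], path, sep = "|", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_flights
#' @export
write_ships <- function(ships, path) {
  write.table(ships[c("last_port", "count", "year")], path, sep = ",",
              quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_flights
#' @export
write_port_map <- function(map, path) {
  if (inherits(map, "port_region_map")) {
    lab <- unclass(map)
    parts <- split_region_label(lab)
    map <- data.frame(port = names(lab), country = parts$country,
                      subdivision = parts$subdivision,
                      stringsAsFactors = FALSE)
  }
  write.table(map[c("port", "country", "subdivision")], path, sep = ",",
              quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

split_region_label <- function(labels) {
  parts <- strsplit(labels, "\u2014", fixed = TRUE)
  list(country = vapply(parts, `[`, "", 1L),
       subdivision = vapply(parts, function(p) if (length(p) > 1L) p[2L] else "", ""))
}

#' Aggregate voyage-level records into a traffic panel
#'
#' Sums flight itineraries and ship arrivals into per-region mode counts
#' for one calendar year. Flights are attributed by last port of call or
#' proportionally over their foreign stops (see
#' [attribute_itinerary()]); ships are always attributed to their last
#' port of call, the only history available. Proportional attribution can
#' yield fractional counts, which the panel stores exactly; rounding
#' happens only on export. Total attributed weight always equals total
#' journeys in the records (conservation), and the result is independent
#' of record order.
#'
#' @param flights Data.frame of flight records (see [read_flights()]);
#'   `stops` may be a "/"-joined string or a list of character vectors.
#' @param ships Data.frame of ship arrivals (see [read_ships()]).
#' @param map A [port_region_map()] covering every referenced port.
#' @param year Calendar year to aggregate (records from other years are
#'   ignored; monthly flight records belong to the year of their record
#'   month).
#' @param mode Flight attribution mode: `"last_port"` or
#'   `"proportional"`.
#' @return A [traffic_panel()] for the single `year`.
#' @export
aggregate_records <- function(flights, ships, map, year,
                              mode = c("last_port", "proportional")) {
  mode <- match.arg(mode)
  year <- as.integer(year)
  acc <- new.env(parent = emptyenv())
  add <- function(region, col, w) {
    for (i in seq_along(region)) {
      key <- region[i]
      cur <- if (exists(key, envir = acc, inherits = FALSE)) {
        get(key, envir = acc, inherits = FALSE)
      } else {
        c(passenger_flights = 0, cargo_flights = 0, ships = 0)
      }
      cur[col] <- cur[col] + w[i]
      assign(key, cur, envir = acc)
    }
  }
  if (!is.null(flights) && nrow(flights)) {
    if (is.null(flights[["year"]])) {  # [[ avoids matching year_month
      flights[["year"]] <- as.integer(substr(flights$year_month, 1L, 4L))
    }
    fl <- flights[flights[["year"]] == year, , drop = FALSE]
    for (i in seq_len(nrow(fl))) {
      stops <- fl$stops[[i]]
      if (is.character(stops) && length(stops) == 1L) {
        stops <- strsplit(stops, "/", fixed = TRUE)[[1L]]
      }
      w <- attribute_itinerary(stops, fl$journeys[i], map, mode)
      col <- if (fl$mode[i] == "cargo") "cargo_flights" else "passenger_flights"
      add(names(w), col, as.numeric(w))
    }
  }
  if (!is.null(ships) && nrow(ships)) {
    sh <- ships[ships$year == year, , drop = FALSE]
    if (nrow(sh)) {
      regions <- map_ports(map, as.character(sh$last_port), "ship arrivals")
      add(regions, "ships", as.numeric(sh$count))
    }
  }
  regions <- ls(acc)
  counts <- t(vapply(regions, function(r) get(r, envir = acc),
                     c(passenger_flights = 0, cargo_flights = 0, ships = 0)))
  out <- data.frame(region = regions, year = year,
                    stringsAsFactors = FALSE)
  if (length(regions)) {
    out <- cbind(out, as.data.frame(counts))
  } else {
    out$passenger_flights <- numeric()
    out$cargo_flights <- numeric()
    out$ships <- numeric()
  }
  traffic_panel(out)
}
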