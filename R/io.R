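#' Read and write yield measurements
#'
#' Measurements travel as CSV with header
#' `field_id,group,x,y,area_m2,dry_yield_kg_ha`, or as a GeoJSON
#' FeatureCollection of Point features carrying the same attributes as
#' properties. [read_measurements()] dispatches on the file extension.
#'
#' @param measurements a `yield_measurements` data frame.
#' @param path file path; `.csv`, `.geojson` or `.json`.
#' @return Readers return a `yield_measurements` data frame; writers
#'   return `path` invisibly.
#' @name measurement_io
NULL

as_yield_measurements <- function(df) {
  need <- c("field_id", "group", "x", "y", "area", "dry_yield")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing measurement columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(df$group), c("test", "control"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(df$area <= 0)) stop("polygon areas must be positive", call. = FALSE)
  if (any(df$dry_yield < 0)) stop("dry yields must be >= 0", call. = FALSE)
  df <- df[need]
  class(df) <- c("yield_measurements", "data.frame")
  df
}

#' @rdname measurement_io
#' @export
write_measurements_csv <- function(measurements, path) {
  df <- as.data.frame(measurements)[c("field_id", "group", "x", "y",
                                      "area", "dry_yield")]
  names(df) <- c("field_id", "group", "x", "y", "area_m2", "dry_yield_kg_ha")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname measurement_io
#' @export
read_measurements_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  names(df)[names(df) == "area_m2"] <- "area"
  names(df)[names(df) == "dry_yield_kg_ha"] <- "dry_yield"
  as_yield_measurements(df)
}

#' @rdname measurement_io
#' @export
write_measurements_geojson <- function(measurements, path) {
  df <- as.data.frame(measurements)
  features <- lapply(seq_len(nrow(df)), function(i) {
    list(
      type = "Feature",
      geometry = list(type = "Point", coordinates = c(df$x[i], df$y[i])),
      properties = list(field_id = df$field_id[i], group = df$group[i],
                        area_m2 = df$area[i],
                        dry_yield_kg_ha = df$dry_yield[i])
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname measurement_io
#' @export
read_measurements_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection"))
    stop("not a GeoJSON FeatureCollection", call. = FALSE)
  rows <- lapply(gj$features, function(f) {
    data.frame(field_id = f$properties$field_id, group = f$properties$group,
               x = f$geometry$coordinates[[1]], y = f$geometry$coordinates[[2]],
               area = f$properties$area_m2,
               dry_yield = f$properties$dry_yield_kg_ha,
               stringsAsFactors = FALSE)
  })
  as_yield_measurements(do.call(rbind, rows))
}

#' @rdname measurement_io
#' @export
read_measurements <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         csv = read_measurements_csv(path),
         geojson = ,
         json = read_measurements_geojson(path),
         stop("unrecognised measurement file extension: .", ext, call. = FALSE))
}

#' Read a simulation configuration from YAML
#'
#' Every [sim_config()] parameter has a named key; keys absent from the
#' file keep their documented defaults.
#'
#' @param path YAML file.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  extra <- setdiff(names(vals), known)
  if (length(extra))
    warning("ignoring unknown config key(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  do.call(sim_config, vals[intersect(names(vals), known)])
}

#' Write posterior draws to CSV
#'
#' Serialises a [fit_group()] result as long-format CSV with columns
#' `chain`, `iteration`, `mu`, `sigma` for external inspection.
#'
#' @param posterior a `group_posterior`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_posterior_csv <- function(posterior, path) {
  stopifnot(inherits(posterior, "group_posterior"))
  write.csv(posterior$draws, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
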