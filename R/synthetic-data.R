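#' Describe rectangular field geometries
#'
#' A field layout gives each field an identifier, a treatment group and a
#' rectangle in planar coordinates: `origin_x`/`origin_y` is the corner of
#' the field, `width` extends across the harvest direction (x) and
#' `length` along it (y). All dimensions are metres.
#'
#' @param field_id character vector of unique field identifiers.
#' @param group `"test"` (green manure applied) or `"control"`, recycled.
#' @param origin_x,origin_y numeric, field corner coordinates (m).
#' @param width,length numeric, field extent (m); both must be positive.
#' @return A `field_layout` data frame, one row per field.
#' @examples
#' field_layout(c("A", "B"), c("test", "control"),
#'              origin_x = c(0, 120), origin_y = 0, width = 100, length = 300)
#' @export
field_layout <- function(field_id, group, origin_x = 0, origin_y = 0,
                         width, length) {
  group <- match.arg(group, c("test", "control"), several.ok = TRUE)
  out <- data.frame(
    field_id = as.character(field_id),
    group = rep_len(group, length(field_id)),
    origin_x = rep_len(as.numeric(origin_x), length(field_id)),
    origin_y = rep_len(as.numeric(origin_y), length(field_id)),
    width = rep_len(as.numeric(width), length(field_id)),
    length = rep_len(as.numeric(length), length(field_id)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$field_id))
    stop("field_id values must be unique within a layout", call. = FALSE)
  if (any(out$width <= 0) || any(out$length <= 0))
    stop("field width and length must be positive", call. = FALSE)
  class(out) <- c("field_layout", "data.frame")
  out
}

#' Simulation configuration
#'
#' Bundles the harvester geometry and the statistical parameters of the
#' yield model. Each polygon's nominal area is
#' `swath_width * harvester_speed * measurement_interval`. A measurement is
#' `baseline_mean + treatment_effect (test only) + fertility(x, y) + noise`,
#' where `fertility` is a smooth zero-mean surface with marginal standard
#' deviation `fertility_sd` and correlation length `fertility_scale`, and
#' `noise` is independent `N(0, noise_sd^2)`. With probability
#' `outlier_rate` the noise term is replaced by a gross error of magnitude
#' `outlier_magnitude * noise_sd` (random sign). Yields are clipped at 0.
#'
#' Defaults reflect the conditions of the study the package emulates: a
#' control-group mean of 2550 kg/ha with a +990 kg/ha additive treatment
#' effect, and a mid-size combine (7.2 m header, 2 m/s, 3 s logging).
#'
#' @param swath_width harvester header width (m).
#' @param harvester_speed forward speed (m/s).
#' @param measurement_interval logging interval (s).
#' @param baseline_mean control-group mean dry yield (kg/ha).
#' @param treatment_effect additive shift of the test-group mean (kg/ha).
#' @param fertility_scale correlation length of the fertility surface (m).
#' @param fertility_sd marginal sd of the fertility surface (kg/ha).
#' @param noise_sd sd of the independent measurement noise (kg/ha).
#' @param outlier_rate probability a measurement is a gross outlier.
#' @param outlier_magnitude outlier size in multiples of `noise_sd`.
#' @param seed master seed; all stages derive substreams from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(swath_width = 7.2, harvester_speed = 2,
                       measurement_interval = 3,
                       baseline_mean = 2550, treatment_effect = 990,
                       fertility_scale = 60, fertility_sd = 350,
                       noise_sd = 450, outlier_rate = 0.002,
                       outlier_magnitude = 8, seed = 42L) {
  cfg <- list(
    swath_width = swath_width, harvester_speed = harvester_speed,
    measurement_interval = measurement_interval,
    baseline_mean = baseline_mean, treatment_effect = treatment_effect,
    fertility_scale = fertility_scale, fertility_sd = fertility_sd,
    noise_sd = noise_sd, outlier_rate = outlier_rate,
    outlier_magnitude = outlier_magnitude, seed = as.integer(seed)
  )
  for (p in c("swath_width", "harvester_speed", "measurement_interval",
              "fertility_scale"))
    if (!is.numeric(cfg[[p]]) || cfg[[p]] <= 0)
      stop(sprintf("'%s' must be a positive number", p), call. = FALSE)
  for (p in c("fertility_sd", "noise_sd"))
    if (cfg[[p]] < 0) stop(sprintf("'%s' must be >= 0", p), call. = FALSE)
  if (cfg$outlier_rate < 0 || cfg$outlier_rate > 1)
    stop("'outlier_rate' must lie in [0, 1]", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  polygon: %.1f m x (%.1f m/s x %.1f s) = %.1f m^2\n",
              x$swath_width, x$harvester_speed, x$measurement_interval,
              x$swath_width * x$harvester_speed * x$measurement_interval))
  cat(sprintf("  yield: baseline %.0f + effect %.0f kg/ha (test group)\n",
              x$baseline_mean, x$treatment_effect))
  cat(sprintf("  fertility sd %.0f kg/ha @ %.0f m; noise sd %.0f kg/ha\n",
              x$fertility_sd, x$fertility_scale, x$noise_sd))
  cat(sprintf("  outliers: rate %.4f, magnitude %.1f x noise sd; seed %d\n",
              x$outlier_rate, x$outlier_magnitude, x$seed))
  invisible(x)
}

#' Segment fields into harvest polygons
#'
#' Tiles each field with rectangles of swath width across the harvest
#' direction and `harvester_speed * measurement_interval` along it. Edge
#' polygons are truncated (not dropped), so the polygon areas of a field
#' always sum to its exact area.
#'
#' @param layout a [field_layout()] (one or more fields).
#' @param config a [sim_config()]; only the three geometry parameters are
#'   used.
#' @return Data frame with `field_id`, `group`, centroid `x`, `y` (m) and
#'   `area` (m^2), one row per polygon.
#' @export
segment_polygons <- function(layout, config) {
  stopifnot(inherits(layout, "field_layout"), inherits(config, "sim_config"))
  step <- config$harvester_speed * config$measurement_interval
  sw <- config$swath_width
  pieces <- lapply(seq_len(nrow(layout)), function(i) {
    fld <- layout[i, ]
    if (fld$width < sw || fld$length < step)
      stop(sprintf(
        "field '%s' (%.1f x %.1f m) is smaller than one polygon (%.1f x %.1f m)",
        fld$field_id, fld$width, fld$length, sw, step), call. = FALSE)
    # cut points; last column/row truncated at the field edge
    xb <- unique(c(seq(0, fld$width, by = sw), fld$width))
    yb <- unique(c(seq(0, fld$length, by = step), fld$length))
    wx <- diff(xb); wy <- diff(yb)
    cx <- xb[-length(xb)] + wx / 2
    cy <- yb[-length(yb)] + wy / 2
    grid <- expand.grid(ix = seq_along(cx), iy = seq_along(cy))
    data.frame(
      field_id = fld$field_id, group = fld$group,
      x = fld$origin_x + cx[grid$ix],
      y = fld$origin_y + cy[grid$iy],
      area = wx[grid$ix] * wy[grid$iy],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, pieces)
}

# Smooth Gaussian-kernel surface over an extent (internal workhorse).
# Lattice of iid N(0,1) at spacing scale/2, padded by 3*scale; the value at
# a point is the kernel-weighted sum standardised so the marginal sd is
# exactly `sd` everywhere. Returns a closure f(x, y).
kernel_surface <- function(xlim, ylim, scale, sd, seed) {
  pad <- 3 * scale
  gx <- seq(xlim[1] - pad, xlim[2] + pad, by = scale / 2)
  gy <- seq(ylim[1] - pad, ylim[2] + pad, by = scale / 2)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  z <- matrix(rnorm(length(gx) * length(gy)), length(gx), length(gy))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  function(x, y) {
    if (sd == 0) return(rep(0, length(x)))
    vapply(seq_along(x), function(i) {
      wx <- dnorm(gx, x[i], scale)
      wy <- dnorm(gy, y[i], scale)
      num <- drop(crossprod(wx, z %*% wy))
      den <- sqrt(sum(wx^2) * sum(wy^2))
      sd * num / den
    }, numeric(1))
  }
}

#' Simulate a smooth fertility surface for one field
#'
#' Realises the within-field fertility/moisture trend as a seeded Gaussian
#' random surface: independent normal draws on a lattice, combined with a
#' Gaussian kernel of bandwidth `fertility_scale` and standardised so the
#' marginal standard deviation equals `fertility_sd` at every point.
#'
#' @param layout a single-field [field_layout()] (first row used).
#' @param config a [sim_config()].
#' @return A function `f(x, y)` returning the yield offset (kg/ha) at any
#'   planar coordinates; deterministic given `config$seed`.
#' @export
simulate_fertility_surface <- function(layout, config) {
  stopifnot(inherits(layout, "field_layout"), inherits(config, "sim_config"))
  fld <- layout[1, ]
  kernel_surface(
    xlim = c(fld$origin_x, fld$origin_x + fld$width),
    ylim = c(fld$origin_y, fld$origin_y + fld$length),
    scale = config$fertility_scale, sd = config$fertility_sd,
    seed = derive_seeds(config$seed, 1)[1]
  )
}

#' Simulate yield-monitor measurements for a set of fields
#'
#' Segments every field into harvest polygons and attaches one dry-yield
#' measurement per polygon, combining the group mean, a fertility surface
#' shared across all fields (so neighbouring test and control fields see
#' the same local trends), independent noise, and rare gross outliers.
#' Yields are clipped at zero; the number of clipped values is recorded in
#' the `"n_clipped"` attribute.
#'
#' @param layouts a [field_layout()] containing at least one test and one
#'   control field.
#' @param config a [sim_config()].
#' @return A `yield_measurements` data frame with columns `field_id`,
#'   `group`, `x`, `y`, `area` (m^2), `dry_yield` (kg/ha).
#' @examples
#' ly <- example_layouts(n_pairs = 1, width = 60, length = 120)
#' m <- simulate_measurements(ly, sim_config(seed = 1))
#' head(m)
#' @export
simulate_measurements <- function(layouts, config) {
  stopifnot(inherits(layouts, "field_layout"), inherits(config, "sim_config"))
  if (nrow(layouts) == 0) stop("empty layout", call. = FALSE)
  if (!all(c("test", "control") %in% layouts$group))
    stop("layouts must contain at least one test and one control field",
         call. = FALSE)
  seeds <- derive_seeds(config$seed, 3)
  polys <- segment_polygons(layouts, config)

  surf <- kernel_surface(
    xlim = range(c(layouts$origin_x, layouts$origin_x + layouts$width)),
    ylim = range(c(layouts$origin_y, layouts$origin_y + layouts$length)),
    scale = config$fertility_scale, sd = config$fertility_sd, seed = seeds[1]
  )
  fert <- surf(polys$x, polys$y)

  n <- nrow(polys)
  set.seed(seeds[2])
  noise <- rnorm(n, 0, config$noise_sd)
  set.seed(seeds[3])
  is_out <- runif(n) < config$outlier_rate
  sgn <- sample(c(-1, 1), n, replace = TRUE)
  noise[is_out] <- sgn[is_out] * config$outlier_magnitude * config$noise_sd

  yield <- config$baseline_mean +
    ifelse(polys$group == "test", config$treatment_effect, 0) +
    fert + noise
  n_clipped <- sum(yield < 0)
  yield <- pmax(yield, 0)

  out <- data.frame(polys[c("field_id", "group", "x", "y", "area")],
                    dry_yield = yield, stringsAsFactors = FALSE)
  class(out) <- c("yield_measurements", "data.frame")
  attr(out, "n_clipped") <- n_clipped
  attr(out, "n_outliers") <- sum(is_out)
  if (n_clipped > 0)
    message(sprintf("simulate_measurements: %d yields clipped at 0", n_clipped))
  out
}

#' Paired test/control field layouts
#'
#' Convenience geometry: `n_pairs` side-by-side pairs of equally sized
#' rectangular fields, each pair one test and one neighbouring control
#' field separated by `gap` metres, so unobserved fertility trends affect
#' both members of a pair similarly.
#'
#' @param n_pairs number of test/control pairs.
#' @param width,length field dimensions (m).
#' @param gap spacing between fields (m).
#' @return A [field_layout()] with `2 * n_pairs` rows.
#' @export
example_layouts <- function(n_pairs = 3, width = 100, length = 400, gap = 10) {
  k <- seq_len(2 * n_pairs) - 1
  field_layout(
    field_id = sprintf("F%02d%s", rep(seq_len(n_pairs), each = 2),
                       rep(c("T", "C"), n_pairs)),
    group = rep(c("test", "control"), n_pairs),
    origin_x = k * (width + gap), origin_y = 0,
    width = width, length = length
  )
}
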