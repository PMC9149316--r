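#' Score reference points with a sample's group probabilities
#'
#' Every reference population point receives the predicted probability of
#' the ancestry group it belongs to (uniform within a group).
#'
#' @param prediction a single-row `prediction_result` from
#'   [predict_proba()], or a named probability vector over groups.
#' @param points data.frame with columns `population`, `latitude`,
#'   `longitude`, `group`; every group must have at least one point.
#' @return `points` with a `score` column appended.
#' @export
assign_point_probabilities <- function(prediction, points) {
  if (inherits(prediction, "prediction_result")) {
    prob <- attr(prediction, "probabilities")
    if (nrow(prob) != 1) stop("one sample at a time; got ", nrow(prob))
    prob <- prob[1, ]
  } else prob <- prediction
  req <- c("population", "latitude", "longitude", "group")
  if (!all(req %in% names(points)))
    stop("points must have columns: ", paste(req, collapse = ", "))
  miss <- setdiff(names(prob), points$group)
  if (length(miss)) stop("group(s) without reference points: ",
                         paste(miss, collapse = ", "))
  points$score <- as.numeric(prob[points$group])
  points
}

#' Inverse-distance-weighted probability surface
#'
#' Builds a regular WGS84 lat/lon grid covering the scored points (plus a
#' margin) and interpolates each cell from its `neighbors` nearest points
#' by inverse great-circle distance to the `power`:
#' \deqn{v(cell) = \sum_i d_i^{-p} v_i / \sum_i d_i^{-p}.}
#' A cell coincident with a point takes that point's score exactly, and all
#' interpolated values are convex combinations of the point scores.
#'
#' @param points scored points from [assign_point_probabilities()].
#' @param cell grid cell size in degrees (default 0.5).
#' @param margin margin around the point bounding box in degrees (default 2).
#' @param power inverse-distance exponent (default 2).
#' @param neighbors number of nearest points used per cell (default 8).
#' @return An object of class `geo_surface`: `values` (rows = latitudes,
#'   descending; cols = longitudes, ascending), `lat`, `lon` (cell-centre
#'   coordinates), `cell`, `crs = "WGS84"`, and the input `points`.
#' @export
interpolate_idw <- function(points, cell = 0.5, margin = 2, power = 2,
                            neighbors = 8) {
  if (!nrow(points)) stop("empty point set")
  if (!"score" %in% names(points)) stop("points are not scored")
  lon0 <- min(points$longitude) - margin; lon1 <- max(points$longitude) + margin
  lat0 <- min(points$latitude) - margin;  lat1 <- max(points$latitude) + margin
  lon <- seq(lon0 + cell / 2, lon1, by = cell)
  lat <- seq(lat1 - cell / 2, lat0, by = -cell)
  grid <- cbind(lon = rep(lon, times = length(lat)),
                lat = rep(lat, each = length(lon)))
  pts <- cbind(points$longitude, points$latitude)
  D <- geosphere::distm(grid, pts, fun = geosphere::distHaversine)
  k <- min(neighbors, nrow(points))
  vals <- apply(D, 1, function(d) {
    o <- order(d)[seq_len(k)]
    dk <- d[o]
    if (dk[1] < 1) return(points$score[o[1]])  # coincident (< 1 m)
    w <- dk^(-power)
    sum(w * points$score[o]) / sum(w)
  })
  values <- matrix(vals, nrow = length(lat), ncol = length(lon), byrow = TRUE,
                   dimnames = list(format(lat), format(lon)))
  structure(list(values = values, lat = lat, lon = lon, cell = cell,
                 crs = "WGS84", points = points), class = "geo_surface")
}

#' @export
print.geo_surface <- function(x, ...) {
  cat("geo_surface:", nrow(x$values), "x", ncol(x$values), "cells of",
      x$cell, "deg;", "values in [",
      format(min(x$values), digits = 3), ",",
      format(max(x$values), digits = 3), "]\n")
  invisible(x)
}

#' Likelihood bands of a probability surface
#'
#' Thresholds are fractions of the surface maximum: the "more likely" band
#' holds cells at or above `hi_frac * max`, the "less likely" band cells at
#' or above `lo_frac * max`. With `lo_frac <= hi_frac` the more-likely band
#' is nested inside the less-likely band by construction.
#'
#' @param s a `geo_surface`.
#' @param hi_frac,lo_frac band thresholds as fractions of the maximum
#'   (defaults 0.8 and 0.4).
#' @return list with `summary` (data.frame: band, threshold, n_cells,
#'   groups contained — groups with at least one reference point inside the
#'   band) and `bands` (integer matrix: 2 = more likely, 1 = less likely
#'   only, 0 = outside).
#' @export
band_surface <- function(s, hi_frac = 0.8, lo_frac = 0.4) {
  stopifnot(lo_frac <= hi_frac)
  mx <- max(s$values)
  hi <- s$values >= hi_frac * mx
  lo <- s$values >= lo_frac * mx
  bands <- matrix(0L, nrow(s$values), ncol(s$values))
  bands[lo] <- 1L; bands[hi] <- 2L
  in_band <- function(mask) {
    if (is.null(s$points)) return(NA_character_)
    ri <- findInterval(-s$points$latitude, -s$lat - s$cell / 2)
    ci <- findInterval(s$points$longitude, s$lon - s$cell / 2)
    ok <- ri >= 1 & ri <= nrow(mask) & ci >= 1 & ci <= ncol(mask)
    inside <- logical(length(ri))
    inside[ok] <- mask[cbind(ri[ok], ci[ok])]
    paste(sort(unique(s$points$group[inside])), collapse = ",")
  }
  summary <- data.frame(
    band = c("more_likely", "less_likely"),
    threshold = c(hi_frac * mx, lo_frac * mx),
    n_cells = c(sum(hi), sum(lo)),
    groups = c(in_band(hi), in_band(lo)),
    stringsAsFactors = FALSE)
  list(summary = summary, bands = bands)
}

#' Does a band contain a reference point of a given group?
#'
#' @param s a `geo_surface` (with points).
#' @param group group label to look for.
#' @param hi_frac,lo_frac band thresholds, as in [band_surface()].
#' @param band which band to inspect (default `"more_likely"`).
#' @return `TRUE`/`FALSE`.
#' @export
band_contains_group <- function(s, group, hi_frac = 0.8, lo_frac = 0.4,
                                band = c("more_likely", "less_likely")) {
  band <- match.arg(band)
  bs <- band_surface(s, hi_frac, lo_frac)
  row <- bs$summary[bs$summary$band == band, ]
  group %in% strsplit(row$groups, ",")[[1]]
}

#' Export a probability surface
#'
#' Formats: `ascii_grid` (ESRI ASCII raster, readable back with
#' [read_ascii_grid()]), `geojson_contours` (contour line features at the
#' two band thresholds plus the reference points), `png` (grayscale heat
#' render, reference points burnt in as dark pixels).
#'
#' @param s a `geo_surface`.
#' @param path output file path.
#' @param format one of `"ascii_grid"`, `"geojson_contours"`, `"png"`.
#' @param hi_frac,lo_frac band thresholds for the contour export.
#' @return `path`, invisibly.
#' @export
export_surface <- function(s, path, format = c("ascii_grid",
                                               "geojson_contours", "png"),
                           hi_frac = 0.8, lo_frac = 0.4) {
  format <- match.arg(format)
  if (format == "ascii_grid") {
    hdr <- c(paste("ncols", ncol(s$values)),
             paste("nrows", nrow(s$values)),
             paste("xllcorner", min(s$lon) - s$cell / 2),
             paste("yllcorner", min(s$lat) - s$cell / 2),
             paste("cellsize", s$cell),
             "NODATA_value -9999")
    body <- apply(s$values, 1, function(r)
      paste(formatC(r, format = "g", digits = 17), collapse = " "))
    writeLines(c(hdr, body), path)
  } else if (format == "geojson_contours") {
    mx <- max(s$values)
    # contourLines wants ascending x (lon) and y (lat)
    z <- t(s$values[rev(seq_len(nrow(s$values))), , drop = FALSE])
    lines <- grDevices::contourLines(x = s$lon, y = rev(s$lat), z = z,
                                     levels = unique(c(hi_frac, lo_frac)) * mx)
    feats <- lapply(lines, function(cl) list(
      type = "Feature",
      properties = list(level = cl$level),
      geometry = list(type = "LineString",
                      coordinates = Map(c, cl$x, cl$y))))
    pts <- lapply(seq_len(nrow(s$points)), function(i) list(
      type = "Feature",
      properties = list(population = s$points$population[i],
                        group = s$points$group[i],
                        score = s$points$score[i]),
      geometry = list(type = "Point",
                      coordinates = c(s$points$longitude[i],
                                      s$points$latitude[i]))))
    gj <- list(type = "FeatureCollection", features = c(feats, pts))
    jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  } else {
    mx <- max(s$values)
    img <- if (mx > 0) s$values / mx else s$values
    ri <- findInterval(-s$points$latitude, -s$lat - s$cell / 2)
    ci <- findInterval(s$points$longitude, s$lon - s$cell / 2)
    ok <- ri >= 1 & ri <= nrow(img) & ci >= 1 & ci <= ncol(img)
    img[cbind(ri[ok], ci[ok])] <- 0
    png::writePNG(img, path)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid back into a surface
#'
#' @param path path written by [export_surface()] with `format =
#'   "ascii_grid"`.
#' @return A `geo_surface` (without reference points).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1:6], "\\s+")
  kv <- stats::setNames(vapply(hdr, `[`, "", 2), tolower(vapply(hdr, `[`, "", 1)))
  ncols <- as.integer(kv["ncols"]); nrows <- as.integer(kv["nrows"])
  cell <- as.numeric(kv["cellsize"])
  xll <- as.numeric(kv["xllcorner"]); yll <- as.numeric(kv["yllcorner"])
  vals <- do.call(rbind, lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  stopifnot(nrow(vals) == nrows, ncol(vals) == ncols)
  lon <- xll + cell / 2 + (seq_len(ncols) - 1) * cell
  lat <- yll + cell / 2 + (rev(seq_len(nrows)) - 1) * cell
  structure(list(values = vals, lat = lat, lon = lon, cell = cell,
                 crs = "WGS84", points = NULL), class = "geo_surface")
}

#' Reference points of a training panel
#'
#' Convenience extractor: one point per population with its group label,
#' from the sample metadata of a [genotype_matrix()].
#'
#' @param m a [genotype_matrix()] whose samples carry coordinates and group
#'   labels.
#' @param groups optional named vector population -> group overriding the
#'   `group_label` column.
#' @return data.frame `population`, `latitude`, `longitude`, `group`.
#' @export
reference_points <- function(m, groups = NULL) {
  sm <- m$samples
  agg <- unique(sm[, c("population", "latitude", "longitude", "group_label")])
  names(agg)[4] <- "group"
  if (!is.null(groups)) agg$group <- unname(groups[agg$population])
  if (anyNA(agg$group)) stop("populations without a group label")
  rownames(agg) <- NULL
  agg
}
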