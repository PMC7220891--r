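#' Configuration for a synthetic study world
#'
#' Describes a rectangular planar lattice of unit cells partitioned into
#' countries, first-level (admin1) and second-level (admin2) administrative
#' units, with spatially smooth covariates, a population surface, a land-cover
#' label per cell and a toy LMS growth reference. Distances are Euclidean in
#' cell units; there is no geodesy.
#'
#' Administrative units are axis-aligned blocks: countries are vertical strips,
#' admin1 units split each country horizontally, admin2 units split each admin1
#' vertically, which guarantees strict nesting (admin2 in admin1 in country).
#'
#' @param nx,ny grid dimensions (cells); both must be at least 4.
#' @param n_countries number of countries (vertical strips).
#' @param n_admin1 total number of admin1 units; must be a multiple of
#'   `n_countries`.
#' @param n_admin2 total number of admin2 units; must be a multiple of
#'   `n_admin1`.
#' @param years inclusive integer range of study years (span at least 2).
#' @param n_covariates number of smooth covariate surfaces to generate.
#' @param barren_fraction fraction of cells labelled "barren" (zero
#'   population), in `[0, 1)`.
#' @param pop_scale median total population per non-barren cell.
#' @param under5_fraction under-5 population as a fraction of total population.
#' @param cluster_size mean number of children sampled per survey cluster
#'   (the surveyed-cluster size distribution is a design choice of the
#'   generator, exposed here rather than fixed).
#'
#' @return a list of class `world_config`.
#' @export
world_config <- function(nx = 10, ny = 10, n_countries = 2, n_admin1 = 4,
                         n_admin2 = 8, years = 2000:2017, n_covariates = 3,
                         barren_fraction = 0.05, pop_scale = 200,
                         under5_fraction = 0.15, cluster_size = 30) {
  if (nx < 4 || ny < 4) {
    stop("grid dimensions must be at least 4x4", call. = FALSE)
  }
  years <- as.integer(years)
  if (length(years) < 2 || any(diff(years) != 1L)) {
    stop("`years` must be an inclusive integer range spanning >= 2 years",
         call. = FALSE)
  }
  if (n_countries < 1) stop("need at least one country", call. = FALSE)
  if (n_admin1 %% n_countries != 0) {
    stop("`n_admin1` must be a multiple of `n_countries`", call. = FALSE)
  }
  if (n_admin2 %% n_admin1 != 0) {
    stop("`n_admin2` must be a multiple of `n_admin1`", call. = FALSE)
  }
  if (barren_fraction < 0 || barren_fraction >= 1) {
    stop("`barren_fraction` must be in [0, 1)", call. = FALSE)
  }
  structure(list(nx = nx, ny = ny, n_countries = n_countries,
                 n_admin1 = n_admin1, n_admin2 = n_admin2, years = years,
                 n_covariates = n_covariates,
                 barren_fraction = barren_fraction, pop_scale = pop_scale,
                 under5_fraction = under5_fraction,
                 cluster_size = cluster_size),
            class = "world_config")
}

# Smooth random surface from low-frequency cosine bases, standardized to
# mean 0 / sd 1 over the grid. Low frequencies keep neighbouring cells highly
# correlated, emulating gridded environmental covariates.
smooth_surface <- function(x, y, nx, ny, n_basis = 8) {
  z <- numeric(length(x))
  for (k in seq_len(n_basis)) {
    fx <- sample(0:2, 1)
    fy <- sample(0:2, 1)
    if (fx == 0 && fy == 0) fx <- 1
    amp <- stats::rnorm(1) / sqrt(k)
    phase <- stats::runif(1, 0, 2 * pi)
    z <- z + amp * cos(2 * pi * (fx * x / nx + fy * y / ny) + phase)
  }
  as.numeric(scale(z))
}

# Toy LMS growth reference indexed by (sex, age in months). Rows alternate
# between L = 1 (shifted-power branch) and L = 0 (log branch) so both z-score
# formulas are exercised. M grows with age like a crude median weight curve.
toy_lms_reference <- function() {
  grid <- expand.grid(sex = c("female", "male"), age_months = 0:59,
                      stringsAsFactors = FALSE)
  grid$L <- as.numeric(grid$age_months %% 2L == 0L)
  grid$M <- (3.3 + 0.25 * grid$age_months^0.9) *
    ifelse(grid$sex == "male", 1.03, 1.0)
  grid$S <- 0.12
  grid[order(grid$sex, grid$age_months), c("sex", "age_months", "L", "M", "S")]
}

#' Generate a synthetic study world
#'
#' Builds a seed-reproducible gridded geography with nested administrative
#' units, smooth covariates, a population surface (total and under-5), a
#' land-cover layer including "barren" cells with zero population, and a toy
#' LMS growth reference.
#'
#' @param config a [world_config()].
#' @param seed integer seed; identical `(config, seed)` pairs give
#'   bit-identical worlds.
#'
#' @return a list of class `toy_world` with elements `cells` (data frame:
#'   `cell`, `x`, `y`, `country`, `admin1`, `admin2`, `landcover`, `pop`,
#'   `pop_u5`), `covariates` (cells x covariates matrix), `years`, `lms`,
#'   `config` and `seed`.
#' @export
make_toy_world <- function(config = world_config(), seed = 1L) {
  stopifnot(inherits(config, "world_config"))
  set.seed(as.integer(seed))
  nx <- config$nx; ny <- config$ny
  cells <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  cells <- cells[order(cells$y, cells$x), ]
  cells$cell <- seq_len(nrow(cells))
  n <- nrow(cells)

  # nested block partition: country strips in x, admin1 strips in y within
  # country, admin2 strips in x within admin1
  a1_per_c <- config$n_admin1 / config$n_countries
  a2_per_a1 <- config$n_admin2 / config$n_admin1
  strip <- function(coord, lo, hi, k) {
    pmin(k, pmax(1L, ceiling((coord - lo + 1) / ((hi - lo + 1) / k))))
  }
  cells$country <- strip(cells$x, 1, nx, config$n_countries)
  cwidth <- nx / config$n_countries
  clo <- floor((cells$country - 1) * cwidth) + 1
  chi <- floor(cells$country * cwidth)
  a1_within <- strip(cells$y, 1, ny, a1_per_c)
  cells$admin1 <- (cells$country - 1L) * a1_per_c + a1_within
  a2_within <- strip(cells$x, clo, chi, a2_per_a1)
  cells$admin2 <- (cells$admin1 - 1L) * a2_per_a1 + a2_within

  covariates <- vapply(seq_len(config$n_covariates), function(j) {
    smooth_surface(cells$x, cells$y, nx, ny)
  }, numeric(n))
  colnames(covariates) <- paste0("cov", seq_len(config$n_covariates))

  pop_field <- smooth_surface(cells$x, cells$y, nx, ny)
  cells$pop <- config$pop_scale * exp(0.7 * pop_field)
  cells$landcover <- "vegetated"
  n_barren <- floor(config$barren_fraction * n)
  if (n_barren > 0) {
    barren <- sample.int(n, n_barren)
    cells$landcover[barren] <- "barren"
    cells$pop[barren] <- 0
  }
  cells$pop_u5 <- config$under5_fraction * cells$pop

  rownames(cells) <- NULL
  structure(list(cells = cells[, c("cell", "x", "y", "country", "admin1",
                                   "admin2", "landcover", "pop", "pop_u5")],
                 covariates = covariates, years = config$years,
                 lms = toy_lms_reference(), config = config,
                 seed = as.integer(seed)),
            class = "toy_world")
}

#' @export
print.toy_world <- function(x, ...) {
  cat("Synthetic study world:", nrow(x$cells), "cells (",
      x$config$nx, "x", x$config$ny, "),",
      x$config$n_countries, "countries /", x$config$n_admin1, "admin1 /",
      x$config$n_admin2, "admin2\n")
  cat("  years", min(x$years), "-", max(x$years), ";",
      ncol(x$covariates), "covariates;",
      sum(x$cells$landcover == "barren"), "barren cells\n")
  invisible(x)
}

#' Write world layers to plain-text files
#'
#' Serializes each gridded layer (covariates, population, land cover, admin
#' ids) as an ESRI ASCII grid, the admin2 polygons as GeoJSON (each unit is a
#' rectangle of whole cells by construction), and the LMS reference as CSV.
#'
#' @param world a `toy_world`.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  grid_of <- function(v) {
    matrix(v[order(world$cells$y, world$cells$x)],
           nrow = world$config$ny, byrow = TRUE)
  }
  layers <- c(list(pop = world$cells$pop, pop_u5 = world$cells$pop_u5,
                   country = world$cells$country,
                   admin1 = world$cells$admin1, admin2 = world$cells$admin2,
                   barren = as.numeric(world$cells$landcover == "barren")),
              stats::setNames(lapply(seq_len(ncol(world$covariates)),
                                     function(j) world$covariates[, j]),
                              colnames(world$covariates)))
  for (nm in names(layers)) {
    f <- file.path(dir, paste0(nm, ".asc"))
    write_ascii_grid(grid_of(layers[[nm]]), f)
    files <- c(files, f)
  }
  f <- file.path(dir, "admin2.geojson")
  write_admin_geojson(world, f)
  files <- c(files, f)
  f <- file.path(dir, "lms_reference.csv")
  utils::write.csv(world$lms, f, row.names = FALSE)
  invisible(c(files, f))
}

# ESRI ASCII grid writer (row 1 = northernmost row).
write_ascii_grid <- function(m, path, cellsize = 1) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
               "xllcorner 0", "yllcorner 0",
               paste("cellsize", cellsize), "NODATA_value -9999"), con)
  m[is.na(m)] <- -9999
  utils::write.table(m[rev(seq_len(nrow(m))), , drop = FALSE], con,
                     row.names = FALSE, col.names = FALSE)
}

#' Read an ESRI ASCII grid written by [write_ascii_grid()]
#' @param path file path.
#' @return numeric matrix (row 1 = southernmost row); NODATA becomes `NA`.
#' @export
read_ascii_grid <- function(path) {
  hdr <- utils::read.table(path, nrows = 6,
                           col.names = c("key", "value"))
  vals <- as.matrix(utils::read.table(path, skip = 6))
  nodata <- hdr$value[hdr$key == "NODATA_value"]
  vals[vals == nodata] <- NA
  dimnames(vals) <- NULL
  vals[rev(seq_len(nrow(vals))), , drop = FALSE]
}

# Admin2 units are rectangles of unit cells; emit one GeoJSON Polygon each.
write_admin_geojson <- function(world, path) {
  cells <- world$cells
  feats <- lapply(sort(unique(cells$admin2)), function(a2) {
    sub <- cells[cells$admin2 == a2, ]
    x0 <- min(sub$x) - 1; x1 <- max(sub$x)
    y0 <- min(sub$y) - 1; y1 <- max(sub$y)
    list(type = "Feature",
         properties = list(admin2 = a2, admin1 = sub$admin1[1],
                           country = sub$country[1]),
         geometry = list(type = "Polygon",
                         coordinates = list(list(c(x0, y0), c(x1, y0),
                                                 c(x1, y1), c(x0, y1),
                                                 c(x0, y0)))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
}
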