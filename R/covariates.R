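#' Construct a planar grid
#'
#' A minimal container for a gridded covariate layer on planar metric
#' coordinates: a numeric matrix (rows = northing, first row is the top /
#' maximum y, matching the ESRI ASCII convention), the coordinate of the
#' lower-left corner, and a square cell size in metres. `NA` marks missing
#' cells.
#'
#' @param values Numeric matrix of cell values.
#' @param origin Length-2 numeric, x and y of the lower-left corner.
#' @param cell_size Cell edge length in metres (> 0).
#' @return An object of class `btk_grid`.
#' @export
grid_layer <- function(values, origin = c(0, 0), cell_size = 25) {
  stopifnot(is.matrix(values), is.numeric(cell_size), cell_size > 0,
            length(origin) == 2)
  structure(
    list(values = values, origin = as.numeric(origin),
         cell_size = as.numeric(cell_size)),
    class = "btk_grid"
  )
}

#' @export
print.btk_grid <- function(x, ...) {
  cat(sprintf("<btk_grid> %d x %d cells of %.1f m, origin (%.1f, %.1f)\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1], x$origin[2]))
  invisible(x)
}

#' Read an ESRI ASCII grid
#'
#' Parses the standard ESRI ASCII raster header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, optional `nodata_value`) followed
#' by whitespace-separated rows, top row first.
#'
#' @param path Path to the `.asc` file.
#' @return A [grid_layer()] object.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  needed <- c("ncols", "nrows", "cellsize")
  if (!all(needed %in% names(hdr))) {
    stop("not an ESRI ASCII grid: missing header fields", call. = FALSE)
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  grid_layer(m, origin = c(hdr$xllcorner %||% 0, hdr$yllcorner %||% 0),
             cell_size = hdr$cellsize)
}

#' Write an ESRI ASCII grid
#' @param grid A [grid_layer()] object.
#' @param path Output path.
#' @export
write_ascii_grid <- function(grid, path) {
  v <- grid$values
  v[is.na(v)] <- -9999
  hdr <- sprintf(
    "ncols %d\nnrows %d\nxllcorner %.6f\nyllcorner %.6f\ncellsize %.6f\nnodata_value -9999",
    ncol(v), nrow(v), grid$origin[1], grid$origin[2], grid$cell_size)
  body <- apply(v, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

# Cell centres and the fraction of each cell inside a disc, by regular
# sub-cell sampling (subdiv x subdiv points per cell). Only cells whose
# bounding box touches the disc are considered.
disc_cell_weights <- function(grid, center, radius, subdiv = 32) {
  cs <- grid$cell_size
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  # column j covers x in origin_x + (j-1..j)*cs; row i (top first) covers
  # y in origin_y + (nr-i .. nr-i+1)*cs
  jmin <- max(1L, floor((center[1] - radius - grid$origin[1]) / cs) + 1L)
  jmax <- min(nc, ceiling((center[1] + radius - grid$origin[1]) / cs))
  ytop <- grid$origin[2] + nr * cs
  imin <- max(1L, floor((ytop - (center[2] + radius)) / cs) + 1L)
  imax <- min(nr, ceiling((ytop - (center[2] - radius)) / cs))
  if (jmin > jmax || imin > imax) {
    return(list(value = numeric(0), weight = numeric(0)))
  }
  cells <- expand.grid(i = imin:imax, j = jmin:jmax)
  off <- (seq_len(subdiv) - 0.5) / subdiv # sub-cell sample offsets in [0,1]
  sx <- rep(off, times = subdiv)
  sy <- rep(off, each = subdiv)
  frac <- mapply(function(i, j) {
    x0 <- grid$origin[1] + (j - 1) * cs
    y0 <- ytop - i * cs
    px <- x0 + sx * cs
    py <- y0 + sy * cs
    mean((px - center[1])^2 + (py - center[2])^2 <= radius^2)
  }, cells$i, cells$j)
  vals <- grid$values[cbind(cells$i, cells$j)]
  keep <- frac > 0 & !is.na(vals)
  list(value = vals[keep], weight = frac[keep] * cs^2)
}

#' Area-weighted mean of a grid over a circular buffer
#'
#' The buffer-weighted covariate extraction: each cell contributes its value
#' weighted by the area of its intersection with the disc, so cells that
#' extend beyond the buffer boundary are down-weighted by the excluded
#' fraction. Intersection areas are estimated by regular sub-cell sampling
#' (default 32 x 32 points per cell). Missing cells are excluded from both
#' numerator and denominator.
#'
#' @param grid A [grid_layer()] object.
#' @param center Length-2 numeric, the buffer centre (metres).
#' @param radius Buffer radius in metres (default 150, the study's
#'   covariate buffer).
#' @param subdiv Sub-cell sampling resolution per cell edge.
#' @return The weighted mean (scalar).
#' @export
weighted_disc_mean <- function(grid, center, radius = 150, subdiv = 32) {
  stopifnot(inherits(grid, "btk_grid"), radius > 0)
  w <- disc_cell_weights(grid, center, radius, subdiv)
  if (length(w$value) == 0 || sum(w$weight) == 0) {
    stop("buffer does not intersect any non-missing grid cell", call. = FALSE)
  }
  sum(w$value * w$weight) / sum(w$weight)
}

#' Count points within a circular buffer
#'
#' Used for conflict-report counts around a camera site (default 500 m
#' buffer). A point exactly on the boundary is counted (distance <= radius).
#'
#' @param points Data frame with `x` and `y` columns, or a 2-column matrix.
#' @param center Length-2 numeric.
#' @param radius Buffer radius in metres (default 500).
#' @return Integer count.
#' @export
count_points_in_disc <- function(points, center, radius = 500) {
  stopifnot(radius > 0)
  if (is.data.frame(points)) points <- cbind(points$x, points$y)
  if (length(points) == 0 || nrow(points) == 0) return(0L)
  d2 <- (points[, 1] - center[1])^2 + (points[, 2] - center[2])^2
  sum(d2 <= radius^2)
}

#' Month-weighted vegetation index at a site buffer
#'
#' Satellite vegetation-index composites come in fixed windows (16-day
#' MODIS periods) that straddle calendar months. The monthly value is the
#' average of the per-window buffer means, weighted by the number of days
#' each window overlaps the focal month.
#'
#' @param windows A data frame with columns `start_date` (Date), `length`
#'   (days, default 16) and `grid` (list column of [grid_layer()] objects).
#' @param month Month as `"YYYY-MM"`.
#' @param center,radius,subdiv Passed to [weighted_disc_mean()].
#' @return The weighted mean, or `NA` if no window overlaps the month.
#' @export
monthly_evi <- function(windows, month, center, radius = 150, subdiv = 32) {
  m_start <- as.Date(paste0(month, "-01"))
  m_end <- seq(m_start, by = "month", length.out = 2)[2] # exclusive
  len <- windows$length %||% rep(16, nrow(windows))
  w_start <- as.Date(windows$start_date)
  w_end <- w_start + len # exclusive
  overlap <- pmax(0, as.numeric(pmin(w_end, m_end) - pmax(w_start, m_start)))
  if (sum(overlap) == 0) return(NA_real_)
  use <- overlap > 0
  vals <- vapply(windows$grid[use], weighted_disc_mean, numeric(1),
                 center = center, radius = radius, subdiv = subdiv)
  sum(overlap[use] * vals) / sum(overlap[use])
}

#' Standardize continuous covariates
#'
#' Centres each selected column at its mean and scales by the sample
#' (n - 1) standard deviation, so that effect sizes are directly
#' comparable. Binary and factor columns are left untouched. The means and
#' sds are stored as an attribute for back-transformation, retrievable with
#' [standardization_params()].
#'
#' @param data A data frame.
#' @param cols Columns to standardize (character). Default: all numeric,
#'   non-binary columns.
#' @return `data` with standardized columns and a `"standardization"`
#'   attribute.
#' @export
standardize <- function(data, cols = NULL) {
  if (is.null(cols)) {
    num <- vapply(data, is.numeric, logical(1))
    bin <- vapply(data, function(x) {
      is.numeric(x) && all(x %in% c(0, 1, NA))
    }, logical(1))
    cols <- names(data)[num & !bin]
  }
  params <- purrr::map_dfr(cols, function(cl) {
    x <- data[[cl]]
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      stop("column '", cl, "' is constant; cannot standardize", call. = FALSE)
    }
    tibble::tibble(variable = cl, mean = mean(x, na.rm = TRUE), sd = s)
  })
  for (k in seq_len(nrow(params))) {
    cl <- params$variable[k]
    data[[cl]] <- (data[[cl]] - params$mean[k]) / params$sd[k]
  }
  attr(data, "standardization") <- params
  data
}

#' @rdname standardize
#' @param x A data frame returned by [standardize()].
#' @export
standardization_params <- function(x) attr(x, "standardization")

#' Screen covariate pairs for collinearity
#'
#' Computes the Pearson correlation matrix of the continuous columns and
#' reports every pair with `|r|` at or above the threshold (default 0.7,
#' the conventional cut for dropping one of a collinear pair). An empty
#' result means the covariate set passes.
#'
#' @param data A data frame of covariates.
#' @param threshold Absolute correlation at or above which a pair is
#'   flagged.
#' @param cols Columns to screen; default all numeric columns.
#' @return Tibble with `var1`, `var2`, `r`, ordered by decreasing `|r|`.
#' @export
collinearity_screen <- function(data, threshold = 0.7, cols = NULL) {
  if (is.null(cols)) {
    cols <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  stopifnot(length(cols) >= 2)
  cm <- stats::cor(data[cols], use = "pairwise.complete.obs",
                   method = "pearson")
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  out <- tibble::tibble(
    var1 = rownames(cm)[idx[, 1]],
    var2 = colnames(cm)[idx[, 2]],
    r = cm[idx]
  )
  out <- out[abs(out$r) >= threshold, ]
  dplyr::arrange(out, dplyr::desc(abs(.data$r)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
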