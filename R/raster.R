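#' Lightweight in-memory power raster
#'
#' A minimal single-band raster: a numeric matrix (rows increase southwards,
#' columns eastwards) with a pixel-center registration. Cell `[1, 1]` has
#' its center at `origin`; cell size is `res` map units. `NA` cells are
#' nodata/masked. Multi-band stacks are plain lists of `power_raster`
#' objects (band order Odd, Dbl, Vol, Hlx by convention).
#'
#' @param data numeric matrix of cell values.
#' @param origin length-2 numeric, map coordinates of the center of cell
#'   `[1, 1]` (x, y).
#' @param res cell size in map units (square pixels).
#' @return A `power_raster` object.
#' @export
power_raster <- function(data, origin = c(0, 0), res = 1) {
  if (!is.matrix(data) || !is.numeric(data)) {
    abort("raster data must be a numeric matrix")
  }
  assert_scalar_number(res, "res", min = 0, strict = TRUE)
  structure(list(data = data, origin = as.numeric(origin), res = res),
            class = "power_raster")
}

#' @export
print.power_raster <- function(x, ...) {
  cat("<power_raster> ", nrow(x$data), "x", ncol(x$data),
      " cells, res ", x$res, ", origin (",
      x$origin[1], ", ", x$origin[2], "), ",
      sum(is.na(x$data)), " masked\n", sep = "")
  invisible(x)
}

# Map coordinates -> (row, col) of the containing cell. x grows with
# columns, y decreases with rows (north-up convention).
raster_cell <- function(r, x, y) {
  col <- round((x - r$origin[1]) / r$res) + 1L
  row <- round((r$origin[2] - y) / r$res) + 1L
  c(row = row, col = col)
}

#' Window-averaged plot value from a raster
#'
#' Mean of the `window x window` block of cells centered on the cell
#' containing the plot center — the scale-matching step that brings pixel
#' powers to the footprint of a field plot. Masked (`NA`) cells are
#' ignored; if more than `max_masked_frac` of the window is masked the plot
#' is considered unusable and `NA` is returned.
#'
#' @param raster a [power_raster()].
#' @param x,y plot-center map coordinates.
#' @param window odd window size in cells (default 7).
#' @param max_masked_frac maximum tolerated masked fraction (default 0.5).
#' @return The window mean, or `NA` if unusable.
#' @export
extract_plot_value <- function(raster, x, y, window = 7,
                               max_masked_frac = 0.5) {
  if (window %% 2 != 1 || window < 1) {
    abort("`window` must be a positive odd integer")
  }
  rc <- raster_cell(raster, x, y)
  nr <- nrow(raster$data); nc <- ncol(raster$data)
  if (rc["row"] < 1 || rc["row"] > nr || rc["col"] < 1 || rc["col"] > nc) {
    abort(paste0("plot center (", x, ", ", y, ") falls outside the raster"))
  }
  h <- (window - 1) / 2
  rows <- max(1, rc["row"] - h):min(nr, rc["row"] + h)
  cols <- max(1, rc["col"] - h):min(nc, rc["col"] + h)
  block <- raster$data[rows, cols, drop = FALSE]
  if (mean(is.na(block)) > max_masked_frac) return(NA_real_)
  mean(block, na.rm = TRUE)
}

#' Per-plot feature table from raster stacks
#'
#' Applies [extract_plot_value()] to each band of each acquisition's power
#' stack, then fuses. Shadow-flagged plots are dropped (with a message), as
#' are plots whose extraction window is unusable.
#'
#' @param stacks named list (one element per acquisition label) of named
#'   lists of [power_raster()] bands `odd`, `dbl`, `vol`, `hlx`.
#' @param plots tibble with `plot_id`, `x`, `y` and optional `shadow`.
#' @param window odd extraction window (default 7).
#' @return Feature tibble: `plot_id`, `acquisition`, base powers, fused
#'   features.
#' @export
extract_features <- function(stacks, plots, window = 7) {
  if ("shadow" %in% names(plots) && any(plots$shadow)) {
    inform(paste0("discarding ", sum(plots$shadow),
                  " shadow-flagged plot(s)"))
    plots <- dplyr::filter(plots, !.data$shadow)
  }
  rows <- purrr::imap(stacks, function(bands, label) {
    vals <- purrr::map(bands, function(b) {
      purrr::map_dbl(seq_len(nrow(plots)), function(i) {
        extract_plot_value(b, plots$x[i], plots$y[i], window = window)
      })
    })
    tibble::tibble(plot_id = plots$plot_id, acquisition = label,
                   odd = vals$odd, dbl = vals$dbl,
                   vol = vals$vol, hlx = vals$hlx %||% 0)
  })
  fuse_powers(dplyr::bind_rows(rows))
}

#' Write/read a power raster as plain CSV
#'
#' Persistence for the in-memory raster: a CSV of cell values with a
#' two-line header comment carrying origin and resolution.
#'
#' @param raster a [power_raster()].
#' @param path file path.
#' @export
write_raster_csv <- function(raster, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# origin ", raster$origin[1], " ", raster$origin[2]),
    paste0("# res ", raster$res)
  ), con)
  write.table(raster$data, con, row.names = FALSE, col.names = FALSE,
              sep = ",")
  invisible(path)
}

#' @rdname write_raster_csv
#' @export
read_raster_csv <- function(path) {
  hdr <- readLines(path, n = 2)
  origin <- as.numeric(strsplit(hdr[1], " ")[[1]][3:4])
  res <- as.numeric(strsplit(hdr[2], " ")[[1]][3])
  data <- as.matrix(read.csv(path, skip = 2, header = FALSE))
  dimnames(data) <- NULL
  power_raster(data, origin = origin, res = res)
}
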