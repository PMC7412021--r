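#' Trunk taper models
#'
#' Stem volume is computed from breast-height cross-section area, tree
#' height and a dimensionless trunk taper coefficient `f` that accounts for
#' the narrowing of the stem. Species-specific taper tables map (DBH,
#' height) to `f`; when no table is available a constant coefficient is a
#' common approximation for even-aged plantations.
#'
#' `taper_constant()` returns a taper model with a fixed `f`. It is intended
#' for synthetic scenes and worked examples; analyses of real inventories
#' should supply a species taper table via `taper_table()`.
#'
#' @param f taper coefficient, in (0, 1].
#' @return A function of `(dbh, height)` returning `f`, classed
#'   `"taper_model"`.
#' @examples
#' tp <- taper_constant(0.45)
#' tp(20, 15)
#' @export
taper_constant <- function(f = 0.45) {
  assert_scalar_number(f, "f", min = 0, strict = TRUE)
  if (f > 1) abort("`f` must be in (0, 1]")
  structure(function(dbh, height) rep_len(f, length(dbh)),
            class = "taper_model", kind = "constant", f = f)
}

#' @rdname taper_constant
#' @param table data frame with columns `dbh_min`, `dbh_max`, `f` (height
#'   bins may be added as `height_min`/`height_max`; omitted bounds default
#'   to all heights). Lookup is by half-open bin `[min, max)`.
#' @export
taper_table <- function(table) {
  table <- tibble::as_tibble(table)
  need <- c("dbh_min", "dbh_max", "f")
  if (!all(need %in% names(table))) {
    abort("taper table needs columns dbh_min, dbh_max, f")
  }
  if (any(table$f <= 0 | table$f > 1)) abort("taper f must lie in (0, 1]")
  has_h <- all(c("height_min", "height_max") %in% names(table))
  fn <- function(dbh, height) {
    purrr::map2_dbl(dbh, height, function(d, h) {
      hit <- d >= table$dbh_min & d < table$dbh_max
      if (has_h) hit <- hit & h >= table$height_min & h < table$height_max
      if (!any(hit)) {
        abort(paste0("taper table has no bin for dbh=", d, ", height=", h))
      }
      table$f[which(hit)[1]]
    })
  }
  structure(fn, class = "taper_model", kind = "table")
}

#' Stem volume of a single tree
#'
#' Volume of one stem from DBH (cm) and height (m):
#' `v = g * (H + 3) * f`, where `g = pi * (dbh / 200)^2` is the
#' breast-height cross-section area in m2 and `f` the trunk taper
#' coefficient. Trees below 5 cm DBH are not measured in the field protocol
#' and are rejected here rather than silently dropped.
#'
#' @param dbh diameter at breast height, cm (>= 5).
#' @param height tree height, m (> 0).
#' @param taper a `taper_model` (see [taper_constant()]).
#' @return Stem volume in m3 (vectorised over trees).
#' @examples
#' tree_stem_volume(20, 15, taper_constant(0.5))  # 0.2827 m3
#' @export
tree_stem_volume <- function(dbh, height, taper = taper_constant()) {
  if (length(dbh) != length(height)) abort("dbh and height lengths differ")
  if (length(dbh) == 0L) return(numeric(0))
  if (any(!is.finite(dbh)) || any(!is.finite(height))) {
    abort("dbh and height must be finite")
  }
  if (any(dbh < 5)) {
    abort(paste0(sum(dbh < 5), " tree(s) below the 5 cm DBH measurement ",
                 "threshold; filter them with `filter_trees()` first"))
  }
  if (any(height <= 0)) abort("height must be positive")
  g <- pi * (dbh / 200)^2
  g * (height + 3) * taper(dbh, height)
}

#' Flag-and-filter trees below the measurement threshold
#'
#' @param trees tibble with `dbh_cm`, `height_m` columns.
#' @param min_dbh measurement threshold, cm.
#' @return `trees` restricted to measurable stems, with the number excluded
#'   attached as attribute `"n_excluded"` and reported via a message.
#' @export
filter_trees <- function(trees, min_dbh = 5) {
  drop <- trees$dbh_cm < min_dbh
  if (any(drop)) {
    inform(paste0("excluding ", sum(drop), " tree(s) with DBH < ",
                  min_dbh, " cm"))
  }
  out <- dplyr::filter(trees, .data$dbh_cm >= min_dbh)
  attr(out, "n_excluded") <- sum(drop)
  out
}

#' Plot-level growing stock volume
#'
#' Sums per-tree stem volumes over a square plot and scales to m3/ha:
#' `GSV = sum(v_i) / (side^2 / 10000)`.
#'
#' @param trees tibble of the plot's trees with columns `dbh_cm`,
#'   `height_m`. An empty tibble gives 0.
#' @param side plot side length, m (20 or 30 typical).
#' @param taper a `taper_model`.
#' @return GSV in m3/ha.
#' @examples
#' trees <- tibble::tibble(dbh_cm = c(20, 20), height_m = c(15, 15))
#' plot_gsv(trees, side = 30, taper = taper_constant(0.5))
#' @export
plot_gsv <- function(trees, side, taper = taper_constant()) {
  assert_scalar_number(side, "side", min = 0, strict = TRUE)
  if (nrow(trees) == 0L) return(0)
  v <- tree_stem_volume(trees$dbh_cm, trees$height_m, taper)
  sum(v) / (side^2 / 10000)
}

#' Compute GSV for a table of plots
#'
#' @param plots tibble with one row per plot: `plot_id`, `side_m`, and
#'   optionally `shadow` (logical).
#' @param trees tibble of all trees with `plot_id`, `dbh_cm`, `height_m`.
#' @param taper a `taper_model`.
#' @return `plots` with a `gsv` column (m3/ha) appended.
#' @export
plots_gsv <- function(plots, trees, taper = taper_constant()) {
  gsv <- purrr::map_dbl(seq_len(nrow(plots)), function(i) {
    tr <- dplyr::filter(trees, .data$plot_id == plots$plot_id[i])
    plot_gsv(tr, plots$side_m[i], taper)
  })
  dplyr::mutate(plots, gsv = gsv)
}

#' Read and write inventory tables
#'
#' Plain-CSV interchange: a plots file (`plot_id, x, y, side_m, shadow`)
#' and a trees file (`plot_id, dbh_cm, height_m`).
#'
#' @param path file path.
#' @return A tibble.
#' @export
read_plots_csv <- function(path) {
  out <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  need <- c("plot_id", "side_m")
  if (!all(need %in% names(out))) {
    abort(paste0("plots CSV must have columns: ", paste(need, collapse = ", ")))
  }
  if ("shadow" %in% names(out)) out$shadow <- as.logical(out$shadow)
  out
}

#' @rdname read_plots_csv
#' @export
read_trees_csv <- function(path) {
  out <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  need <- c("plot_id", "dbh_cm", "height_m")
  if (!all(need %in% names(out))) {
    abort(paste0("trees CSV must have columns: ", paste(need, collapse = ", ")))
  }
  out
}

#' @rdname read_plots_csv
#' @param x tibble to write.
#' @export
write_inventory_csv <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}
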