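#' Binary willow mask
#'
#' A thresholded raster marking willow-thicket cover (1 = willow) at a fixed
#' pixel resolution, typically 0.2 m (the resolution of the source aerial
#' photography). Rows map to the y axis, columns to x; `origin` is the world
#' coordinate of the outer corner of pixel `[1, 1]`, so the centre of pixel
#' `(r, c)` sits at `origin + (c - 0.5, r - 0.5) * pixel_size`.
#'
#' @param grid Binary matrix (entries 0/1).
#' @param pixel_size Metres per pixel side (default 0.2).
#' @param origin Numeric `(x, y)` world coordinate of the grid corner.
#' @return Object of class `willow_mask`.
#' @export
willow_mask <- function(grid, pixel_size = 0.2, origin = c(0, 0)) {
  grid <- as.matrix(grid)
  if (!all(grid %in% c(0, 1)))
    stop("mask entries must be 0/1", call. = FALSE)
  if (pixel_size <= 0) stop("pixel_size must be > 0", call. = FALSE)
  storage.mode(grid) <- "integer"
  structure(list(grid = grid, pixel_size = pixel_size,
                 origin = as.numeric(origin)),
            class = "willow_mask")
}

#' @export
print.willow_mask <- function(x, ...) {
  cat(sprintf("willow_mask: %d x %d pixels @ %.2f m (%.1f x %.1f m), %.1f%% willow\n",
              nrow(x$grid), ncol(x$grid), x$pixel_size,
              nrow(x$grid) * x$pixel_size, ncol(x$grid) * x$pixel_size,
              100 * mean(x$grid)))
  invisible(x)
}

#' Square measurement quadrat
#'
#' @param centre World `(x, y)` coordinate of the quadrat centre (the sampling
#'   point).
#' @param side Side length in metres; default 200 m (a 4-ha quadrat matching
#'   the 100 m count radius).
#' @return Object of class `quadrat`.
#' @export
quadrat <- function(centre, side = 200) {
  if (side <= 0) stop("side must be > 0", call. = FALSE)
  structure(list(centre = as.numeric(centre), side = side), class = "quadrat")
}

#' Read / write a mask as a plain text grid
#'
#' Format: three header lines (`nrows`, `ncols`, `pixel_size`) followed by a
#' whitespace-delimited 0/1 grid, one raster row per line.
#'
#' @param path File path.
#' @return [read_mask_text()]: a [willow_mask()].
#' @export
read_mask_text <- function(path) {
  hdr <- readLines(path, n = 3L)
  if (length(hdr) < 3)
    stop("format error: expected 3 header lines (nrows, ncols, pixel_size)",
         call. = FALSE)
  nr <- as.integer(hdr[1]); nc <- as.integer(hdr[2]); px <- as.numeric(hdr[3])
  if (anyNA(c(nr, nc, px)))
    stop("format error: malformed header in '", path, "'", call. = FALSE)
  g <- matrix(scan(path, what = integer(), skip = 3, n = nr * nc,
                   quiet = TRUE),
              nrow = nr, ncol = nc, byrow = TRUE)
  willow_mask(g, pixel_size = px)
}

#' @rdname read_mask_text
#' @param mask A [willow_mask()] to write.
#' @export
write_mask_text <- function(mask, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(nrow(mask$grid)), as.character(ncol(mask$grid)),
               format(mask$pixel_size, digits = 15)), con)
  utils::write.table(mask$grid, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extract the measurement quadrat from a mask
#'
#' Returns the square sub-grid of `side/pixel_size` pixels centred on the
#' quadrat centre. The centre is snapped to the nearest pixel centre (snap
#' distance reported in attribute `snap_m`); an error is raised when the
#' quadrat is not fully inside the raster.
#'
#' @param mask A [willow_mask()].
#' @param quad A [quadrat()].
#' @return A [willow_mask()] covering the quadrat.
#' @export
extract_quadrat <- function(mask, quad) {
  px <- mask$pixel_size
  n <- round(quad$side / px)
  if (n < 1) stop("quadrat smaller than one pixel", call. = FALSE)
  # pixel-centre index nearest the quadrat centre
  cc <- round((quad$centre[1] - mask$origin[1]) / px + 0.5)
  rc <- round((quad$centre[2] - mask$origin[2]) / px + 0.5)
  snap <- sqrt((mask$origin[1] + (cc - 0.5) * px - quad$centre[1])^2 +
               (mask$origin[2] + (rc - 0.5) * px - quad$centre[2])^2)
  r1 <- rc - floor((n - 1) / 2); r2 <- r1 + n - 1
  c1 <- cc - floor((n - 1) / 2); c2 <- c1 + n - 1
  nr <- nrow(mask$grid); nc <- ncol(mask$grid)
  if (r1 < 1 || c1 < 1 || r2 > nr || c2 > nc) {
    ov_r <- max(0, min(r2, nr) - max(r1, 1) + 1)
    ov_c <- max(0, min(c2, nc) - max(c1, 1) + 1)
    stop(sprintf(paste0("quadrat out of bounds: needs rows %d..%d, cols %d..%d",
                        " of a %d x %d raster (overlap %d x %d pixels)"),
                 r1, r2, c1, c2, nr, nc, ov_r, ov_c), call. = FALSE)
  }
  out <- willow_mask(mask$grid[r1:r2, c1:c2, drop = FALSE], pixel_size = px,
                     origin = mask$origin + c((c1 - 1) * px, (r1 - 1) * px))
  attr(out, "snap_m") <- snap
  out
}

#' Label willow patches
#'
#' Connected-component labeling under the 8-neighbour rule, with components
#' whose minimum pixel-centre separation is at most `merge_gap_m` merged into
#' one patch (patches must be more than 2 m apart to count as distinct, by
#' default). Labels are assigned in row-major order of each patch's first
#' pixel; 0 marks background.
#'
#' @param mask A [willow_mask()].
#' @param merge_gap_m Merge components separated by at most this many metres
#'   (exact pairwise pixel-centre distance; default 2).
#' @return List with `labels` (integer matrix) and `n_patches`.
#' @export
label_patches <- function(mask, merge_gap_m = 2) {
  labels <- .cc_label_merge(mask$grid, mask$pixel_size, merge_gap_m)
  list(labels = labels, n_patches = max(0L, max(labels)))
}

#' Willow / non-willow edge length
#'
#' Total length (metres) of interface between willow and non-willow pixels,
#' counted over 4-adjacent pixel pairs inside the grid. By default the grid
#' border itself contributes no edge: edge is a habitat-interface quantity and
#' only boundaries between pixels inside the measurement window count.
#'
#' @param mask A [willow_mask()].
#' @param count_border Also count willow pixel sides lying on the grid border
#'   (default FALSE).
#' @return Edge length in metres.
#' @export
edge_length <- function(mask, count_border = FALSE) {
  g <- mask$grid
  nr <- nrow(g); nc <- ncol(g)
  n_pairs <- 0L
  if (nc > 1) n_pairs <- n_pairs + sum(g[, -1, drop = FALSE] != g[, -nc, drop = FALSE])
  if (nr > 1) n_pairs <- n_pairs + sum(g[-1, , drop = FALSE] != g[-nr, , drop = FALSE])
  len <- n_pairs * mask$pixel_size
  if (count_border) {
    border_sides <- sum(g[1, ]) + sum(g[nr, ]) + sum(g[, 1]) + sum(g[, nc])
    if (nr == 1) border_sides <- border_sides # top and bottom both counted above
    len <- len + border_sides * mask$pixel_size
  }
  len
}

#' Thicket metrics within a quadrat
#'
#' Computes the three landscape covariates on the quadrat centred at a
#' sampling point: `area_pct` (% of the quadrat covered by willow),
#' `patch_density` (number of distinct patches, patches <= 2 m apart counted
#' as one) and `edge_density` (metres of willow/non-willow interface inside
#' the quadrat).
#'
#' @param mask A [willow_mask()] covering at least the quadrat.
#' @param quad A [quadrat()]; when NULL, `mask` is taken to be the quadrat
#'   itself.
#' @param merge_gap_m Patch-distinctness gap in metres (default 2).
#' @return A one-row data frame `(area_pct, patch_density, edge_density)`.
#' @export
thicket_metrics <- function(mask, quad = NULL, merge_gap_m = 2) {
  q <- if (is.null(quad)) mask else extract_quadrat(mask, quad)
  area_pct <- 100 * mean(q$grid)
  pd <- if (area_pct == 0) 0L else label_patches(q, merge_gap_m)$n_patches
  ed <- if (area_pct == 0) 0 else edge_length(q)
  data.frame(area_pct = area_pct, patch_density = pd, edge_density = ed)
}

#' Thicket metrics for a set of sampling points
#'
#' @param masks Named list of [willow_mask()]s, one per sampling point (each
#'   mask is the quadrat for its point), or a single mask shared by all
#'   points with `quads` giving per-point quadrats.
#' @param quads Optional list of [quadrat()]s parallel to `masks`.
#' @param merge_gap_m Patch-distinctness gap in metres.
#' @return Data frame `(point, area_pct, patch_density, edge_density)`.
#' @export
thicket_metrics_table <- function(masks, quads = NULL, merge_gap_m = 2) {
  ids <- names(masks)
  if (is.null(ids)) ids <- as.character(seq_along(masks))
  rows <- lapply(seq_along(masks), function(i) {
    m <- thicket_metrics(masks[[i]],
                         quad = if (is.null(quads)) NULL else quads[[i]],
                         merge_gap_m = merge_gap_m)
    cbind(point = ids[i], m, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
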