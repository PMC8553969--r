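#' Build a rectangular plot layout
#'
#' Plots are axis-aligned pixel rectangles, 0-based and half-open
#' (`x0 <= x < x1`, `y0 <= y < y1`; x = column, y = row), arranged on a grid
#' with a gap between neighbours. Default plot size follows the field
#' planting geometry (3 rows of 11 plants, 30 cm x 18 cm spacing) at the
#' given resolution.
#'
#' @param plot_ids character vector of plot/line ids.
#' @param ncol plots per layout row.
#' @param plot_px `c(width, height)` in pixels; default derived from the
#'   planting geometry at `resolution`.
#' @param gap_px gap between plots in pixels.
#' @param resolution metres per pixel (default 0.002 = 2 mm).
#' @return data.frame `plot_id, x0, y0, x1, y1` with attribute `resolution`.
#' @export
make_plot_layout <- function(plot_ids, ncol = 10L, plot_px = NULL,
                             gap_px = 10L, resolution = 0.002) {
  n <- length(plot_ids)
  if (is.null(plot_px)) {
    plot_px <- c(round(11 * 0.18 / resolution), round(3 * 0.30 / resolution))
  }
  col <- (seq_len(n) - 1L) %% ncol
  row <- (seq_len(n) - 1L) %/% ncol
  x0 <- gap_px + col * (plot_px[1L] + gap_px)
  y0 <- gap_px + row * (plot_px[2L] + gap_px)
  l <- data.frame(plot_id = plot_ids, x0 = x0, y0 = y0,
                  x1 = x0 + plot_px[1L], y1 = y0 + plot_px[2L],
                  stringsAsFactors = FALSE)
  attr(l, "resolution") <- resolution
  l
}

# target CIELAB triples -> 8-bit sRGB rows (clipped)
lab_to_rgb8 <- function(lab) {
  srgb <- grDevices::convertColor(lab, from = "Lab", to = "sRGB")
  round(pmin(pmax(srgb, 0), 1) * 255)
}

#' Render a synthetic orthomosaic + DSM scene
#'
#' Draws each plot's canopy as clustered plant regions around a 3 x 11 grid
#' of plant positions: every pixel's distance to its nearest plant centre is
#' computed and the closest `VF` percent of pixels become plant. Plant pixels
#' get a green colour matched to the requested `-a*` (CIELAB, via the inverse
#' sRGB transform) and a DSM elevation of `baseline + CH`; the rest get soil
#' colour and baseline elevation. The pre-transplant baseline DSM is a flat
#' surface plus optional low-amplitude terrain noise.
#'
#' @param values data.frame with columns `plot_id`, `ch_m` (canopy height in
#'   metres), `vf_pct` in \[0, 100\], `minus_a_star` (target mean -a* of
#'   plant pixels).
#' @param layout plot layout from [make_plot_layout()]; one row per
#'   `values$plot_id`.
#' @param resolution metres per pixel.
#' @param base_elev_m flat baseline elevation.
#' @param terrain_sd_m SD of baseline terrain noise (metres; default 0).
#' @param dsm_noise_sd_m SD of observation-date DSM noise (default 0).
#' @param soil_lab CIELAB soil colour (positive a*).
#' @param seed integer seed.
#' @return A list of class `raster_scene`: `rgb` (H x W x 3 integer, 0-255),
#'   `dsm`, `baseline_dsm` (H x W metres), `resolution`, `layout`, and
#'   `truth_mask` (logical H x W, the rendered ground-truth plant mask).
#' @export
render_scene <- function(values, layout, resolution = 0.002,
                         base_elev_m = 10, terrain_sd_m = 0,
                         dsm_noise_sd_m = 0,
                         soil_lab = c(55, 9, 18), seed) {
  stopifnot(!missing(seed))
  if (any(values$vf_pct < 0 | values$vf_pct > 100)) {
    stop("requested VF outside [0,100]")
  }
  miss <- setdiff(values$plot_id, layout$plot_id)
  if (length(miss)) stop("plot_id not in layout: ", miss[1L])
  set.seed(seed)
  W <- max(layout$x1) + 10L
  H <- max(layout$y1) + 10L
  base <- matrix(base_elev_m, H, W)
  if (terrain_sd_m > 0) base <- base + matrix(stats::rnorm(H * W, 0, terrain_sd_m), H, W)
  dsm <- base
  mask_all <- matrix(FALSE, H, W)

  # soil background with mild lightness texture
  nL <- stats::rnorm(H * W, 0, 2)
  lab_bg <- cbind(soil_lab[1L] + nL, soil_lab[2L], soil_lab[3L])
  rgb8 <- lab_to_rgb8(lab_bg)
  img <- array(0L, c(H, W, 3L))
  for (k in 1:3) img[, , k] <- matrix(rgb8[, k], H, W)

  for (i in seq_len(nrow(values))) {
    v <- values[i, ]
    r <- layout[layout$plot_id == v$plot_id, ]
    cols <- (r$x0 + 1L):r$x1          # 1-based matrix indices
    rows <- (r$y0 + 1L):r$y1
    pw <- length(cols); ph <- length(rows)
    if (v$vf_pct == 0) next
    # plant centres: 3 rows x 11 plants scaled into the plot, small jitter
    cx <- (seq_len(11) - 0.5) / 11 * pw + stats::rnorm(11, 0, 0.5)
    cy <- (seq_len(3) - 0.5) / 3 * ph + stats::rnorm(3, 0, 0.5)
    ctr <- expand.grid(x = cx, y = cy)
    px <- matrix(seq_len(pw) - 0.5, ph, pw, byrow = TRUE)
    py <- matrix(seq_len(ph) - 0.5, ph, pw)
    d2 <- matrix(Inf, ph, pw)
    for (k in seq_len(nrow(ctr))) {
      d2 <- pmin(d2, (px - ctr$x[k])^2 + (py - ctr$y[k])^2)
    }
    if (v$vf_pct >= 100) {
      m <- matrix(TRUE, ph, pw)
    } else {
      thr <- stats::quantile(d2, v$vf_pct / 100, names = FALSE, type = 1L)
      m <- d2 <= thr
    }
    mask_all[rows, cols] <- m
    np <- sum(m)
    lab_p <- cbind(48 + stats::rnorm(np, 0, 2), -v$minus_a_star, 32)
    prgb <- lab_to_rgb8(lab_p)
    for (k in 1:3) {
      ch <- img[rows, cols, k]
      ch[m] <- prgb[, k]
      img[rows, cols, k] <- ch
    }
    dd <- dsm[rows, cols]
    dd[m] <- dd[m] + v$ch_m
    dsm[rows, cols] <- dd
  }
  if (dsm_noise_sd_m > 0) dsm <- dsm + matrix(stats::rnorm(H * W, 0, dsm_noise_sd_m), H, W)
  storage.mode(img) <- "integer"
  structure(list(rgb = img, dsm = dsm, baseline_dsm = base,
                 resolution = resolution, layout = layout,
                 truth_mask = mask_all),
            class = "raster_scene")
}
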