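#' Convert an 8-bit RGB image to CIELAB
#'
#' Standard sRGB (D65) to CIELAB transform, applied per pixel via
#' [grDevices::convertColor()].
#'
#' @param rgb H x W x 3 array of 8-bit values (0-255).
#' @return H x W x 3 array with channels L*, a*, b*.
#' @export
rgb_to_lab <- function(rgb) {
  d <- dim(rgb)
  if (length(d) != 3L || d[3L] != 3L) {
    stop("expected an H x W x 3 RGB array")
  }
  flat <- cbind(as.vector(rgb[, , 1L]), as.vector(rgb[, , 2L]),
                as.vector(rgb[, , 3L])) / 255
  lab <- grDevices::convertColor(flat, from = "sRGB", to = "Lab")
  out <- array(0, d)
  for (k in 1:3) out[, , k] <- matrix(lab[, k], d[1L], d[2L])
  out
}

#' Otsu's threshold
#'
#' Quantises the observed range into 256 bins and returns the bin boundary
#' maximising the between-class variance of the two-class split; ties are
#' broken toward the lower threshold.
#'
#' @param x numeric vector, matrix or array of finite values.
#' @return The threshold value (a bin boundary).
#' @export
otsu_threshold <- function(x) {
  x <- as.vector(x)
  x <- x[is.finite(x)]
  if (length(x) < 2L) stop("degenerate histogram: fewer than 2 values")
  rng <- range(x)
  if (diff(rng) == 0) stop("degenerate histogram: constant input")
  breaks <- seq(rng[1L], rng[2L], length.out = 257L)
  bin <- findInterval(x, breaks, all.inside = TRUE)
  cnt <- tabulate(bin, 256L)
  if (sum(cnt > 0L) < 2L) stop("degenerate histogram: single occupied bin")
  mids <- (breaks[-257L] + breaks[-1L]) / 2
  w <- cumsum(cnt)
  s <- cumsum(cnt * mids)
  N <- w[256L]; S <- s[256L]
  # split after bin t: class0 = bins 1..t, class1 = bins t+1..256
  t <- 1:255
  w0 <- w[t]; w1 <- N - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- s[t] / w0
  mu1 <- (S - s[t]) / w1
  bcv <- ifelse(valid, w0 * w1 * (mu0 - mu1)^2, -Inf)
  k <- which.max(bcv)    # first maximum = lower threshold on ties
  breaks[k + 1L]
}

crop_region <- function(m, region) {
  if (is.null(region)) return(m)
  stopifnot(all(c("x0", "y0", "x1", "y1") %in% names(region)))
  d <- if (length(dim(m)) == 3L) dim(m)[1:2] else dim(m)
  if (region$x0 < 0 || region$y0 < 0 || region$x1 > d[2L] ||
      region$y1 > d[1L] || region$x1 <= region$x0 || region$y1 <= region$y0) {
    stop("plot region outside image")
  }
  if (length(dim(m)) == 3L) {
    m[(region$y0 + 1L):region$y1, (region$x0 + 1L):region$x1, , drop = FALSE]
  } else {
    m[(region$y0 + 1L):region$y1, (region$x0 + 1L):region$x1, drop = FALSE]
  }
}

#' Vegetation fraction of a plot
#'
#' Segments plant pixels by Otsu thresholding of the CIELAB a* channel within
#' the plot region: the class on the greener (more negative a*) side of the
#' threshold is plant. If the within-plot a* histogram is degenerate (uniform
#' colour), segmentation falls back to an absolute a* cutoff with a warning,
#' which forces VF to 0 or 100.
#'
#' @param rgb H x W x 3 8-bit RGB image (ignored if `lab` given).
#' @param region plot rectangle (`x0,y0,x1,y1`, 0-based half-open) or `NULL`
#'   for the whole image.
#' @param lab optional precomputed CIELAB array (avoids reconversion).
#' @param fallback_a_cut absolute a* cutoff used when Otsu is degenerate
#'   (default -10: pixels with a* <= -10 are plant).
#' @param min_separation smallest a* distance between the two Otsu class
#'   means for the split to count as soil-vs-plant (default 8; plant and
#'   soil a* typically differ by > 20). Below it the plot is treated as
#'   single-class and the absolute cutoff decides, which forces VF to 0 or
#'   100 on uniform plots.
#' @return list with `vf` (percent), `mask` (logical matrix over the region),
#'   `threshold` (a* threshold used, `NA` for fallback),
#'   `n_plant_pixels`.
#' @export
vegetation_fraction <- function(rgb = NULL, region = NULL, lab = NULL,
                                fallback_a_cut = -10, min_separation = 8) {
  if (is.null(lab)) lab <- rgb_to_lab(rgb)
  a <- crop_region(lab[, , 2L], region)
  thr <- tryCatch(otsu_threshold(a), error = function(e) NA_real_)
  if (!is.na(thr)) {
    m0 <- a < thr
    if (sum(m0) == 0L || sum(!m0) == 0L ||
        abs(mean(a[m0]) - mean(a[!m0])) < min_separation) {
      thr <- NA_real_   # split is within one colour class, not soil/plant
    }
  }
  if (is.na(thr)) {
    warning("degenerate or single-class a* histogram; falling back to ",
            "absolute cutoff ", fallback_a_cut)
    mask <- a <= fallback_a_cut
  } else {
    mask <- a < thr
    # guard inverted scenes: plant class must be the greener (lower-a*) one
    if (sum(mask) > 0L && sum(!mask) > 0L &&
        mean(a[mask]) > mean(a[!mask])) {
      mask <- !mask
    }
  }
  list(vf = 100 * sum(mask) / length(mask), mask = mask,
       threshold = thr, n_plant_pixels = sum(mask))
}

#' Mean leaf colour (-a*) over plant pixels
#'
#' @param lab CIELAB array (full image).
#' @param mask logical plant mask over `region` (from
#'   [vegetation_fraction()]).
#' @param region plot rectangle or `NULL`.
#' @return Mean of -a* over plant pixels; `NA` with a warning when the mask
#'   is empty.
#' @export
leaf_colour <- function(lab, mask, region = NULL) {
  a <- crop_region(lab[, , 2L], region)
  stopifnot(identical(dim(a), dim(mask)))
  if (!any(mask)) {
    warning("empty plant mask; leaf colour undefined")
    return(NA_real_)
  }
  mean(-a[mask])
}

#' Canopy height from DSM differencing
#'
#' CH = observation-date DSM minus pre-transplant baseline DSM over the plot
#' region, summarised by a configurable statistic. The default, the 95th
#' percentile of within-plot differences, is robust to soil gaps between
#' plants; `mean`/`median` restrict to the plant mask when one is supplied.
#' Negative differences are permitted and reported.
#'
#' @param dsm,baseline_dsm aligned elevation matrices (metres).
#' @param region plot rectangle or `NULL`.
#' @param mask optional logical plant mask over the region.
#' @param stat summary statistic: `"p95"` (default), `"mean"`, `"median"`.
#' @return CH in metres.
#' @export
canopy_height <- function(dsm, baseline_dsm, region = NULL, mask = NULL,
                          stat = c("p95", "mean", "median")) {
  stat <- match.arg(stat)
  if (!identical(dim(dsm), dim(baseline_dsm))) {
    stop("dsm and baseline_dsm shapes differ")
  }
  d <- crop_region(dsm, region) - crop_region(baseline_dsm, region)
  if (!is.null(mask) && stat != "p95") d <- d[mask]
  switch(stat,
         p95 = stats::quantile(d, 0.95, names = FALSE),
         mean = mean(d),
         median = stats::median(d))
}

#' Extract per-plot measurements from a rendered or loaded scene
#'
#' Runs [vegetation_fraction()], [leaf_colour()] and [canopy_height()] over
#' every plot of a scene's layout.
#'
#' @param scene a `raster_scene` (see [render_scene()] / [read_scene()]).
#' @param stat CH summary statistic (see [canopy_height()]).
#' @param fallback_a_cut see [vegetation_fraction()].
#' @return data.frame `plot_id, ch_m, ch_cm, vf_pct, minus_a_star,
#'   n_plant_pixels`.
#' @export
measure_plots <- function(scene, stat = "p95", fallback_a_cut = -10) {
  lab <- rgb_to_lab(scene$rgb)
  res <- lapply(seq_len(nrow(scene$layout)), function(i) {
    r <- scene$layout[i, ]
    vf <- vegetation_fraction(lab = lab, region = r,
                              fallback_a_cut = fallback_a_cut)
    ma <- if (vf$n_plant_pixels > 0L) leaf_colour(lab, vf$mask, r) else NA_real_
    ch <- canopy_height(scene$dsm, scene$baseline_dsm, r,
                        mask = vf$mask, stat = stat)
    data.frame(plot_id = r$plot_id, ch_m = ch, ch_cm = 100 * ch,
               vf_pct = vf$vf, minus_a_star = ma,
               n_plant_pixels = vf$n_plant_pixels, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
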