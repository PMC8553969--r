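#' @name io_tables
#' @title Tabular readers and writers
#'
#' @description
#' All tables travel as RFC-4180 CSV or tab-separated TSV with a header row;
#' missing values are empty fields. Genomic positions are 1-based inclusive
#' bp; pixel rectangles are 0-based half-open. Readers validate schemas and
#' name the offending row or column in their error messages.
#'
#' * haplotype matrix — TSV, first column `line_id`, one column per SNP,
#'   entries are founder codes (or empty for missing);
#' * SNP panel — TSV `snp_id, chrom, pos_bp`;
#' * trait table — CSV `line_id, trait, year, dat, value`;
#' * scan — TSV `snp_id, chrom, pos_bp, H, df, k, n, p, p_bonf`;
#' * QTL table — TSV mirroring [call_qtls()] columns;
#' * plot layout — TSV `plot_id, x0, y0, x1, y1`.
NULL

#' @rdname io_tables
#' @param haps,path,founders see Description.
#' @export
write_haplotypes <- function(haps, path, founders = attr(haps, "founders")) {
  codes <- matrix(founders[haps], nrow(haps), ncol(haps),
                  dimnames = dimnames(haps))
  codes[is.na(codes)] <- ""
  d <- data.frame(line_id = rownames(haps), codes, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io_tables
#' @export
read_haplotypes <- function(path, founders = magic_founders()) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                         colClasses = "character")
  if (names(d)[1L] != "line_id") stop("first column must be line_id")
  codes <- as.matrix(d[, -1L, drop = FALSE])
  rownames(codes) <- d$line_id
  bad <- setdiff(unique(codes[codes != ""]), founders)
  if (length(bad)) stop("unknown founder label: ", bad[1L])
  m <- matrix(match(codes, founders), nrow(codes), ncol(codes),
              dimnames = dimnames(codes))
  hap_matrix(m, founders)
}

#' @rdname io_tables
#' @param panel a [snp_panel()].
#' @export
write_panel <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname io_tables
#' @export
read_panel <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos_bp")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("panel missing column: ", miss[1L])
  snp_panel(d$snp_id, d$chrom, d$pos_bp)
}

#' @rdname io_tables
#' @param traits long trait table.
#' @export
write_traits <- function(traits, path) {
  utils::write.csv(traits, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname io_tables
#' @export
read_traits <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(line_id = "character",
                                      year = "character"))
  need <- c("line_id", "trait", "year", "dat", "value")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("trait table missing column: ", miss[1L])
  key <- paste(d$line_id, d$trait, d$year, d$dat, sep = "|")
  if (anyDuplicated(key)) {
    stop("duplicate trait row for key (line_id|trait|year|dat): ",
         key[duplicated(key)][1L])
  }
  d
}

#' @rdname io_tables
#' @param scan a `scan_result`.
#' @export
write_scan <- function(scan, path) {
  utils::write.table(scan, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname io_tables
#' @export
read_scan <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  class(d) <- c("scan_result", "data.frame")
  d
}

#' @rdname io_tables
#' @param qtls a `qtl_table`.
#' @export
write_qtls <- function(qtls, path) {
  utils::write.table(qtls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname io_tables
#' @export
read_qtls <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  class(d) <- c("qtl_table", "data.frame")
  d
}

#' @rdname io_tables
#' @param layout plot layout frame.
#' @export
write_plot_layout <- function(layout, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# pixel rectangles, 0-based half-open: x0 <= x < x1, y0 <= y < y1",
             con)
  utils::write.table(layout, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname io_tables
#' @export
read_plot_layout <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                         stringsAsFactors = FALSE)
  need <- c("plot_id", "x0", "y0", "x1", "y1")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("layout missing column: ", miss[1L])
  if (any(d$x1 <= d$x0 | d$y1 <= d$y0)) {
    bad <- which(d$x1 <= d$x0 | d$y1 <= d$y0)[1L]
    stop("empty rectangle for plot ", d$plot_id[bad])
  }
  d
}

# ---- rasters: plain-text formats -------------------------------------------
# RGB as ASCII PPM (P3); elevation as ESRI ASCII grid. Both are standard
# text formats, chosen because the runtime has no TIFF codec; round-trips
# are exact.

write_ppm <- function(rgb, path) {
  d <- dim(rgb)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(d[2L], d[1L]), "255"), con)
  # row-major pixel order, one image row per line
  rows <- vapply(seq_len(d[1L]), function(r) {
    paste(as.vector(rbind(rgb[r, , 1L], rgb[r, , 2L], rgb[r, , 3L])),
          collapse = " ")
  }, character(1L))
  writeLines(rows, con)
  invisible(path)
}

read_ppm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1L] != "P3") stop("not an ASCII PPM (P3) file: ", path)
  w <- as.integer(toks[2L]); h <- as.integer(toks[3L])
  vals <- as.integer(toks[-(1:4)])
  stopifnot(length(vals) == w * h * 3L)
  px <- matrix(vals, nrow = 3L)   # channels fastest
  img <- array(0L, c(h, w, 3L))
  for (k in 1:3) img[, , k] <- matrix(px[k, ], h, w, byrow = TRUE)
  img
}

write_asc <- function(m, path, cellsize = 1) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
               "xllcorner 0", "yllcorner 0",
               paste("cellsize", format(cellsize, digits = 12)),
               "NODATA_value -9999"), con)
  writeLines(apply(m, 1L, function(r) {
    paste(format(r, digits = 12, trim = TRUE, scientific = FALSE),
          collapse = " ")
  }), con)
  invisible(path)
}

read_asc <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(tolower(hdr), "\\s+")
  get <- function(key) {
    for (x in kv) if (x[1L] == key) return(as.numeric(x[2L]))
    stop("ASCII grid missing header field ", key, " in ", path)
  }
  nc <- as.integer(get("ncols")); nr <- as.integer(get("nrows"))
  vals <- scan(path, skip = 6L, quiet = TRUE)
  stopifnot(length(vals) == nc * nr)
  m <- matrix(vals, nr, nc, byrow = TRUE)
  attr(m, "cellsize") <- get("cellsize")
  m
}

#' Write / read a raster scene
#'
#' Persists a scene as four sibling text files: `<prefix>_rgb.ppm` (ASCII
#' PPM), `<prefix>_dsm.asc` and `<prefix>_base.asc` (ESRI ASCII grids, cell
#' size = resolution in metres) and `<prefix>_layout.tsv`.
#'
#' @param scene a `raster_scene`.
#' @param prefix file path prefix.
#' @return `write_scene` the prefix, invisibly; `read_scene` the scene.
#' @export
write_scene <- function(scene, prefix) {
  write_ppm(scene$rgb, paste0(prefix, "_rgb.ppm"))
  write_asc(scene$dsm, paste0(prefix, "_dsm.asc"), scene$resolution)
  write_asc(scene$baseline_dsm, paste0(prefix, "_base.asc"),
            scene$resolution)
  write_plot_layout(scene$layout, paste0(prefix, "_layout.tsv"))
  invisible(prefix)
}

#' @rdname write_scene
#' @export
read_scene <- function(prefix) {
  rgb <- read_ppm(paste0(prefix, "_rgb.ppm"))
  dsm <- read_asc(paste0(prefix, "_dsm.asc"))
  base <- read_asc(paste0(prefix, "_base.asc"))
  if (!identical(dim(dsm), dim(base)) ||
      !identical(dim(dsm), dim(rgb)[1:2])) {
    stop("raster dimensions disagree under prefix ", prefix)
  }
  structure(list(rgb = rgb, dsm = dsm, baseline_dsm = base,
                 resolution = attr(dsm, "cellsize"),
                 layout = read_plot_layout(paste0(prefix, "_layout.tsv")),
                 truth_mask = NULL),
            class = "raster_scene")
}

#' Export a QTL cluster tree as Newick text
#'
#' @param hc an [stats::hclust] from [cluster_qtls()].
#' @param path output file.
#' @export
write_cluster_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
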