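#' Build a pipeline run configuration
#'
#' Collects all tunables of the end-to-end run: population and panel sizes,
#' planted QTL architecture, trait-noise level, the per-year DAT grids with
#' their cross-year pairing, scan/selection thresholds, and imaging options.
#' Defaults restate the study design: 165 lines, 8 founders, six paired
#' timepoints over two seasons, selection at p < 1e-2 in both years with
#' product < 1e-5, 2 Mb QTL merging, and the n < 4 class-size rule.
#'
#' @param seed master seed; stage seeds are derived from it.
#' @param n_lines,n_snps,n_chrom,chrom_len_bp,recomb_rate,founder_freq,missing_rate
#'   population simulator parameters (see [simulate_magic_population()]).
#' @param qtl_specs list of [qtl_effect_spec()] (or plain lists with the same
#'   fields, as parsed from a JSON config).
#' @param growth,noise_sd trait simulator parameters.
#' @param pairing DAT pairing frame (default [dat_pairing()]).
#' @param years year labels, first = year 1 of the pairing.
#' @param scan_trait trait scanned (default "CH").
#' @param p_cut,product_cut,merge_gap_bp,min_class_size scan thresholds.
#' @param render_and_extract if `TRUE` the time-course traits are re-derived
#'   by rendering each timepoint's scene and extracting CH/VF/-a* with the
#'   imaging stage (desk-scale: use a coarse `render_resolution`).
#' @param render_resolution metres per pixel for rendered scenes.
#' @param ch_stat,fallback_a_cut imaging options (see [canopy_height()],
#'   [vegetation_fraction()]).
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(seed = 1L, n_lines = 165L, n_snps = 1000L,
                            n_chrom = 5L, chrom_len_bp = 30e6,
                            recomb_rate = 3e-7,
                            founder_freq = rep(1 / 8, 8), missing_rate = 0,
                            qtl_specs = list(), growth = growth_params(),
                            noise_sd = 5, pairing = dat_pairing(),
                            years = c("2019", "2018"), scan_trait = "CH",
                            p_cut = 1e-2, product_cut = 1e-5,
                            merge_gap_bp = 2e6, min_class_size = 4L,
                            render_and_extract = FALSE,
                            render_resolution = 0.02,
                            ch_stat = "p95", fallback_a_cut = -10) {
  stopifnot(p_cut > 0, product_cut > 0, merge_gap_bp > 0, min_class_size > 0)
  qtl_specs <- lapply(qtl_specs, function(sp) {
    if (inherits(sp, "qtl_effect_spec")) sp else
      qtl_effect_spec(sp$snp_id, unlist(sp$ch_effects),
                      stages = unlist(sp$stages),
                      vf_effects = if (!is.null(sp$vf_effects))
                        unlist(sp$vf_effects),
                      ma_effects = if (!is.null(sp$ma_effects))
                        unlist(sp$ma_effects),
                      pleiotropy = lapply(sp$pleiotropy, unlist))
  })
  structure(list(seed = as.integer(seed), n_lines = n_lines,
                 n_snps = n_snps, n_chrom = n_chrom,
                 chrom_len_bp = chrom_len_bp, recomb_rate = recomb_rate,
                 founder_freq = founder_freq, missing_rate = missing_rate,
                 qtl_specs = qtl_specs, growth = growth, noise_sd = noise_sd,
                 pairing = pairing, years = years, scan_trait = scan_trait,
                 p_cut = p_cut, product_cut = product_cut,
                 merge_gap_bp = merge_gap_bp,
                 min_class_size = min_class_size,
                 render_and_extract = render_and_extract,
                 render_resolution = render_resolution, ch_stat = ch_stat,
                 fallback_a_cut = fallback_a_cut),
            class = "run_config")
}

config_hash <- function(config) {
  plain <- rapply(unclass(config), unclass, how = "replace")
  txt <- jsonlite::toJSON(plain, auto_unbox = TRUE, digits = NA,
                          force = TRUE)
  f <- tempfile()
  writeLines(txt, f)
  on.exit(unlink(f))
  unname(tools::md5sum(f))
}

stage_guard <- function(manifest, stage, hash, files) {
  done <- !is.null(manifest[[stage]]) && all(file.exists(files))
  if (done && !identical(manifest[[stage]], hash)) {
    stop("stage '", stage, "' has on-disk intermediates from a different ",
         "configuration; refusing to resume (delete the output directory ",
         "or change it)")
  }
  done
}

#' Run the full pipeline
#'
#' Orchestrates simulation -> (optional rendered imaging) -> haplotype scan
#' -> QTL calling -> effect profiling from one configuration, writing every
#' intermediate as plain CSV/TSV under `outdir`. Reruns with the same
#' configuration resume from on-disk intermediates; intermediates written
#' under a different configuration abort the run.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return Invisibly, a list with `panel`, `haps`, `traits`, `scans`,
#'   `selections`, `qtls`, `effects` and `log`.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  man_path <- file.path(outdir, "manifest.json")
  manifest <- if (file.exists(man_path)) {
    jsonlite::read_json(man_path, simplifyVector = TRUE)
  } else list()
  log <- list(config_hash = hash, seed = config$seed,
              r_version = as.character(getRversion()), stages = list())
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    log$stages[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  save_manifest <- function(stage) {
    manifest[[stage]] <<- hash
    jsonlite::write_json(manifest, man_path, auto_unbox = TRUE)
  }

  # ---- stage: simdata ------------------------------------------------------
  f_panel <- file.path(outdir, "panel.tsv")
  f_haps <- file.path(outdir, "haplotypes.tsv")
  f_traits <- file.path(outdir, "traits.csv")
  if (stage_guard(manifest, "simdata", hash, c(f_panel, f_haps, f_traits))) {
    panel <- read_panel(f_panel)
    haps <- read_haplotypes(f_haps)
    traits <- read_traits(f_traits)
  } else {
    timed("simdata", {
      panel <- simulate_snp_panel(config$n_snps, config$n_chrom,
                                   config$chrom_len_bp, seed = config$seed)
      haps <- simulate_magic_population(
        config$n_lines, panel, config$recomb_rate, config$founder_freq,
        config$missing_rate, seed = config$seed + 1L)
      tp <- list(config$pairing$dat_y1, config$pairing$dat_y2)
      names(tp) <- config$years
      traits <- simulate_traits(haps, config$qtl_specs, config$growth,
                                 config$noise_sd, timepoints = tp,
                                 seed = config$seed + 2L)
      NULL
    })
    write_panel(panel, f_panel)
    write_haplotypes(haps, f_haps)
    write_traits(traits, f_traits)
    save_manifest("simdata")
  }

  # ---- stage: imaging (optional) ------------------------------------------
  if (config$render_and_extract) {
    f_meas <- file.path(outdir, "plot_measurements.csv")
    if (stage_guard(manifest, "imaging", hash, f_meas)) {
      meas <- utils::read.csv(f_meas, stringsAsFactors = FALSE,
                              colClasses = c(line_id = "character",
                                             year = "character"))
    } else {
      meas <- timed("imaging", extract_rendered_traits(traits, config))
      utils::write.csv(meas, f_meas, row.names = FALSE)
      save_manifest("imaging")
    }
    traits <- replace_timecourse(traits, meas)
    write_traits(traits, file.path(outdir, "traits_extracted.csv"))
  }

  # ---- stage: gwas ---------------------------------------------------------
  if (!all(config$years %in% traits$year)) {
    stop("the two-year selection rule requires trait data for both years (",
         paste(config$years, collapse = ", "), ")")
  }
  scans_y1 <- list(); scans_y2 <- list(); selections <- list()
  timed("gwas", {
    for (i in seq_len(nrow(config$pairing))) {
      d1 <- config$pairing$dat_y1[i]; d2 <- config$pairing$dat_y2[i]
      key <- paste0(d1, "_", d2)
      s1 <- haplotype_scan(trait_slice(traits, config$scan_trait,
                                       config$years[1L], d1),
                           haps, panel, config$min_class_size)
      s2 <- haplotype_scan(trait_slice(traits, config$scan_trait,
                                       config$years[2L], d2),
                           haps, panel, config$min_class_size)
      scans_y1[[key]] <- s1
      scans_y2[[key]] <- s2
      selections[[key]] <- select_snps(s1, s2, config$p_cut,
                                        config$product_cut)
      write_scan(s1, file.path(outdir, sprintf("scan_%s_%s_dat%03d.tsv",
                                               config$scan_trait,
                                               config$years[1L], d1)))
      write_scan(s2, file.path(outdir, sprintf("scan_%s_%s_dat%03d.tsv",
                                               config$scan_trait,
                                               config$years[2L], d2)))
    }
    NULL
  })
  qtls <- call_qtls(selections, scans_y1, scans_y2, panel,
                    config$merge_gap_bp, config$scan_trait)
  write_qtls(qtls, file.path(outdir, "qtl_table.tsv"))
  save_manifest("gwas")

  # ---- stage: effects ------------------------------------------------------
  eff <- NULL
  if (nrow(qtls) > 0L) {
    tp <- list(config$pairing$dat_y1, config$pairing$dat_y2)
    names(tp) <- config$years
    eff <- timed("effects",
                 effect_profile(traits, haps, qtls, config$scan_trait,
                                timepoints = tp, config$min_class_size))
    utils::write.csv(eff$profile, file.path(outdir, "effect_profile.csv"),
                     row.names = FALSE)
    utils::write.csv(eff$quadratic,
                     file.path(outdir, "effect_quadratic.csv"),
                     row.names = FALSE)
    if (length(unique(eff$profile$qtl)) >= 2L) {
      hc <- cluster_qtls(effect_matrix(eff$profile))
      write_cluster_newick(hc, file.path(outdir, "qtl_clusters.nwk"))
      eff$cluster <- hc
    }
    save_manifest("effects")
  }

  log$n_lines <- nrow(haps)
  log$n_snps <- nrow(panel)
  log$n_qtls <- nrow(qtls)
  jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE)
  invisible(list(panel = panel, haps = haps, traits = traits,
                 scans = list(y1 = scans_y1, y2 = scans_y2),
                 selections = selections, qtls = qtls, effects = eff,
                 log = log))
}

# render one scene per (year, DAT) and extract CH/VF/-a* from the rasters
extract_rendered_traits <- function(traits, config) {
  out <- list()
  tp <- list(config$pairing$dat_y1, config$pairing$dat_y2)
  names(tp) <- config$years
  sd_offset <- 1000L
  for (year in config$years) {
    for (t in tp[[year]]) {
      ch <- trait_slice(traits, "CH", year, t)
      vf <- trait_slice(traits, "VF", year, t)
      ma <- trait_slice(traits, "minus_a_star", year, t)
      ids <- names(ch)
      layout <- make_plot_layout(ids, ncol = 15L,
                                 resolution = config$render_resolution)
      values <- data.frame(plot_id = ids, ch_m = pmax(ch, 0) / 100,
                           vf_pct = vf, minus_a_star = ma,
                           stringsAsFactors = FALSE)
      scene <- render_scene(values, layout,
                            resolution = config$render_resolution,
                            seed = config$seed + sd_offset)
      sd_offset <- sd_offset + 1L
      m <- measure_plots(scene, stat = config$ch_stat,
                         fallback_a_cut = config$fallback_a_cut)
      out[[length(out) + 1L]] <- data.frame(
        line_id = m$plot_id, year = year, dat = t, ch_cm = m$ch_cm,
        vf_pct = m$vf_pct, minus_a_star = m$minus_a_star,
        n_plant_pixels = m$n_plant_pixels, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# swap extracted plot measurements into the long trait table
replace_timecourse <- function(traits, meas) {
  cols <- c(CH = "ch_cm", VF = "vf_pct", minus_a_star = "minus_a_star")
  for (tr in names(cols)) {
    idx <- match(paste(traits$line_id, traits$year, traits$dat),
                 paste(meas$line_id, meas$year, meas$dat))
    sel <- traits$trait == tr & !is.na(idx)
    traits$value[sel] <- meas[[cols[[tr]]]][idx[sel]]
  }
  traits
}
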