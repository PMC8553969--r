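#' Default canopy growth-curve parameters
#'
#' The baseline canopy-height (CH) template rises from `start_cm` at
#' transplanting to `peak_cm` at `peak_dat` days after transplanting (DAT)
#' via a smooth quadratic, then declines linearly at `decline_cm_per_day`
#' (stems and panicles droop during maturation). Defaults put the peak at
#' 83 DAT, the timepoint where phenotypic variation is widest.
#'
#' @return Named list of parameters (cm, days).
#' @export
growth_params <- function() {
  list(start_cm = 10, peak_cm = 110, peak_dat = 83, decline_cm_per_day = 0.25)
}

#' Baseline canopy height at a set of timepoints
#'
#' @param dat DAT values.
#' @param p parameter list as from [growth_params()].
#' @return CH in cm.
#' @export
ch_baseline <- function(dat, p = growth_params()) {
  u <- pmin(dat / p$peak_dat, 1)
  rise <- p$start_cm + (p$peak_cm - p$start_cm) * (2 * u - u^2)
  decl <- pmax(dat - p$peak_dat, 0) * p$decline_cm_per_day
  rise - decl
}

# logistic rise of canopy closure, saturating near 95 %
vf_baseline <- function(dat) 95 / (1 + exp(-(dat - 45) / 12))

# greenness (-a*) rises to early heading then falls with senescence
minus_a_baseline <- function(dat) pmax(22 - 0.004 * (dat - 75)^2, 5)

#' Specify a planted QTL effect
#'
#' Describes one simulated QTL: the target SNP, per-founder additive effects
#' on canopy height (cm) that apply only at timepoints within the given
#' developmental stages, and optional pleiotropic per-founder effects on
#' other traits (shares on the time-course traits VF and -a*, and additive
#' effects on the endpoint traits CL, PL, PN, PW, SLW in their units).
#'
#' @param snp_id target SNP (must exist in the haplotype matrix).
#' @param ch_effects named numeric, one entry per founder code; unnamed
#'   founders get 0.
#' @param stages subset of `c("tillering","heading","maturation")`; CH effects
#'   are zero outside these stages.
#' @param vf_effects,ma_effects optional per-founder effects on VF (percent)
#'   and -a* (units), applied in the same stage window.
#' @param pleiotropy optional named list of per-founder effect vectors for
#'   endpoint traits, e.g. `list(PW = c(RU = -3), SLW = c(RU = 4))`.
#' @return A list of class `qtl_effect_spec`.
#' @export
qtl_effect_spec <- function(snp_id,
                            ch_effects,
                            stages = c("tillering", "heading", "maturation"),
                            vf_effects = NULL, ma_effects = NULL,
                            pleiotropy = list()) {
  stages <- match.arg(stages, several.ok = TRUE)
  fill <- function(x) {
    v <- stats::setNames(numeric(8L), magic_founders())
    if (!is.null(x)) {
      if (is.null(names(x))) stop("effect vectors must be named by founder")
      bad <- setdiff(names(x), magic_founders())
      if (length(bad)) stop("unknown founder code: ", bad[1L])
      v[names(x)] <- x
    }
    if (any(!is.finite(v))) stop("effects must be finite")
    v
  }
  structure(list(snp_id = snp_id, ch_effects = fill(ch_effects),
                 stages = stages, vf_effects = fill(vf_effects),
                 ma_effects = fill(ma_effects),
                 pleiotropy = lapply(pleiotropy, fill)),
            class = "qtl_effect_spec")
}

#' Simulate time-course and endpoint trait tables
#'
#' Generates the long-format trait table consumed by the scan:
#' time-course traits CH (cm), VF (percent) and `minus_a_star` at the DAT
#' grids of two years, plus per-year endpoint traits CL, PL, PN, PW, SLW,
#' TW (= PW + SLW exactly) and SDW.
#'
#' The generative model is additive:
#' `CH(line, t) = baseline(t) + sum_q effect_q(founder at q, stage(t)) + N(0, noise_sd)`.
#' CL is an affine function of each line's genetic CH at the peak timepoint
#' plus noise, reproducing the strong CH-CL correlation; PW and SLW carry the
#' per-founder pleiotropy of the specs (opposite signs at a trade-off QTL
#' make CH correlate negatively with PW/SLW at the haplotype level).
#'
#' @param haps a [hap_matrix()].
#' @param qtl_specs list of [qtl_effect_spec()].
#' @param growth growth-curve parameters ([growth_params()]).
#' @param noise_sd CH residual SD in cm (no field replicates: this is the
#'   free line-level noise; default 5).
#' @param timepoints named list of DAT vectors, one per year; default the
#'   two-season grid of [dat_pairing()].
#' @param endpoint_noise_sd named residual SDs for endpoint traits.
#' @param seed integer seed.
#' @return data.frame `line_id, trait, year, dat, value` (endpoint traits have
#'   `dat = NA`).
#' @export
simulate_traits <- function(haps, qtl_specs = list(),
                            growth = growth_params(), noise_sd = 5,
                            timepoints = NULL,
                            endpoint_noise_sd = c(CL = 3, PL = 1.5, PN = 1.5,
                                                  PW = 3, SLW = 3, SDW = 3),
                            seed) {
  stopifnot(!missing(seed))
  if (is.null(timepoints)) {
    pr <- dat_pairing()
    timepoints <- list("2019" = pr$dat_y1, "2018" = pr$dat_y2)
  }
  for (sp in qtl_specs) {
    if (!sp$snp_id %in% colnames(haps)) {
      stop("QTL target SNP not in panel: ", sp$snp_id)
    }
  }
  set.seed(seed)
  lines <- rownames(haps)
  n <- length(lines)
  founders <- attr(haps, "founders")

  # per-line stage-dependent genetic effect for one component of the specs
  genetic <- function(component, stage) {
    g <- numeric(n)
    for (sp in qtl_specs) {
      if (!stage %in% sp$stages) next
      lab <- haps[, sp$snp_id]
      eff <- sp[[component]][lab]         # NA label -> NA effect
      eff[is.na(eff)] <- 0
      g <- g + eff
    }
    g
  }

  out <- list()
  add <- function(trait, year, dat, value) {
    out[[length(out) + 1L]] <<- data.frame(
      line_id = lines, trait = trait, year = year,
      dat = if (is.null(dat)) NA_integer_ else dat,
      value = value, stringsAsFactors = FALSE)
  }

  for (year in names(timepoints)) {
    dats <- timepoints[[year]]
    stages <- stage_of_index(length(dats))
    for (j in seq_along(dats)) {
      t <- dats[j]
      g_ch <- genetic("ch_effects", stages[j])
      add("CH", year, t, ch_baseline(t, growth) + g_ch +
            stats::rnorm(n, 0, noise_sd))
      vf <- vf_baseline(t) + genetic("vf_effects", stages[j]) +
        stats::rnorm(n, 0, 2)
      add("VF", year, t, pmin(pmax(vf, 0), 100))
      add("minus_a_star", year, t,
          minus_a_baseline(t) + genetic("ma_effects", stages[j]) +
            stats::rnorm(n, 0, 1))
    }
    # endpoint traits: driven by the genetic CH value at the peak timepoint
    peak_stage <- stages[which.min(abs(dats - growth$peak_dat))]
    g_peak <- genetic("ch_effects", peak_stage)
    ep_noise <- function(tr) stats::rnorm(n, 0, endpoint_noise_sd[[tr]])
    pleio <- function(tr) {
      g <- numeric(n)
      for (sp in qtl_specs) {
        if (!tr %in% names(sp$pleiotropy)) next
        eff <- sp$pleiotropy[[tr]][haps[, sp$snp_id]]
        eff[is.na(eff)] <- 0
        g <- g + eff
      }
      g
    }
    cl <- 20 + 0.75 * g_peak + 0.6 * (ch_baseline(growth$peak_dat, growth) -
                                        growth$start_cm) + ep_noise("CL")
    add("CL", year, NULL, cl)
    add("PL", year, NULL, 20 + pleio("PL") + ep_noise("PL"))
    add("PN", year, NULL,
        pmax(round(12 + pleio("PN") + ep_noise("PN")), 0))
    pw <- pmax(30 + pleio("PW") + ep_noise("PW"), 1)
    slw <- pmax(40 + pleio("SLW") + ep_noise("SLW"), 1)
    add("PW", year, NULL, pw)
    add("SLW", year, NULL, slw)
    add("TW", year, NULL, pw + slw)
    add("SDW", year, NULL, pmax(0.8 * slw + ep_noise("SDW"), 0))
  }
  do.call(rbind, out)
}

#' Extract one trait slice as a named value vector
#'
#' @param traits long trait table.
#' @param trait,year trait and year labels.
#' @param dat DAT timepoint; `NA` selects an endpoint trait.
#' @return Named numeric vector (names = line ids).
#' @export
trait_slice <- function(traits, trait, year, dat = NA) {
  sel <- traits$trait == trait & traits$year == year &
    (if (is.na(dat)) is.na(traits$dat) else !is.na(traits$dat) &
       traits$dat == dat)
  x <- traits[sel, ]
  if (nrow(x) == 0L) {
    stop("no rows for trait=", trait, " year=", year, " dat=", dat)
  }
  stats::setNames(x$value, x$line_id)
}
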