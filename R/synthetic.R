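# Synthetic induced-CD/UV data generator.
#
# The forward model is linear (Beer-Lambert): for a mixture, the UV trace is
# the total concentration of each analyte times its molar UV basis, and the
# CD trace is the (R minus S) concentration difference times the R-adduct
# molar CD basis -- enantiomers share the UV basis and have exactly
# mirror-image CD bases. Basis spectra are sums of Gaussian bands, a
# standard parameterization of broad electronic CD/UV bands.

.ANALYTES <- c("PEA", "PMP", "PGL", "PPA")

#' Gaussian band on a wavelength grid
#'
#' `v(lambda) = amplitude * exp(-4 ln2 (lambda - center)^2 / fwhm^2)`, so the
#' value at `center +/- fwhm/2` is exactly half the peak amplitude.
#'
#' @param grid `wl_grid` or numeric wavelengths (nm).
#' @param center_nm band centre (nm), within [230, 470].
#' @param fwhm_nm full width at half maximum (nm), > 0.
#' @param amplitude signed peak response per mM.
#' @return numeric vector of intensities on `grid`.
#' @export
gaussian_band <- function(grid, center_nm, fwhm_nm, amplitude) {
  if (!is.finite(fwhm_nm) || fwhm_nm <= 0) {
    stop("fwhm_nm must be positive", call. = FALSE)
  }
  if (center_nm < 230 || center_nm > 470) {
    stop("band centre must lie within [230, 470] nm", call. = FALSE)
  }
  wl <- as.numeric(grid)
  amplitude * exp(-4 * log(2) * (wl - center_nm)^2 / fwhm_nm^2)
}

band <- function(center_nm, fwhm_nm, amplitude) {
  list(center_nm = center_nm, fwhm_nm = fwhm_nm, amplitude = amplitude)
}

render_bands <- function(grid, bands) {
  v <- numeric(length(grid))
  for (b in bands) {
    v <- v + gaussian_band(grid, b$center_nm, b$fwhm_nm, b$amplitude)
  }
  v
}

# Preset band tables -----------------------------------------------------
# Constants chosen to reproduce the qualitative spectral facts of the
# coumarin-probe adducts:
#  * PMP CD crosses zero at 340 nm (two opposite bands symmetric about
#    340 nm) and is nearly solvent-independent (no intramolecular H bond).
#  * PEA CD is silent at 400 nm (all bands centred <= 340 nm with modest
#    widths) but strong at 340 nm, and changes shape markedly with solvent.
#  * PPA likewise is strongly solvent-dependent; PGL sits in between.
#  * CD mass lives in ~270-320 and ~360-430 nm; UV mass in ~270-330 and
#    ~400-450 nm.
# Amplitudes are responses per mM: CD in mdeg/mM (per unit R-S difference),
# UV in AU/mM (per unit total). They are presets, not fits.

# UV bands are deliberately distinct across analytes: the probe was chosen
# because each adduct shows a characteristic UV change (sensors whose
# adducts gave essentially identical UV spectra are useless for
# concentration unmixing). PEA and PPA share nearly the same UV shape in
# MeOH but differ strongly in DCE, reproducing the solvent-dependence that
# motivates the two-solvent multiblock design.
.PRESETS <- list(
  PEA = list(
    DCE = list(
      cd = list(band(292, 36, 3.2), band(332, 32, -2.6)),
      uv = list(band(296, 40, 0.28), band(404, 40, 0.10))
    ),
    MeOH = list(
      cd = list(band(286, 40, 1.6), band(330, 30, 2.4)),
      uv = list(band(290, 42, 0.25), band(412, 38, 0.11))
    )
  ),
  PMP = list(
    DCE = list(
      cd = list(band(300, 46, 3.0), band(380, 46, -3.0)),
      uv = list(band(318, 42, 0.20), band(442, 30, 0.18))
    ),
    MeOH = list(
      cd = list(band(300, 48, 2.7), band(380, 48, -2.7)),
      uv = list(band(314, 44, 0.19), band(438, 32, 0.16))
    )
  ),
  PGL = list(
    DCE = list(
      cd = list(band(288, 34, 2.2), band(398, 44, 1.5)),
      uv = list(band(280, 36, 0.26), band(426, 34, 0.13))
    ),
    MeOH = list(
      cd = list(band(292, 36, 1.9), band(402, 46, 1.0), band(330, 30, -0.7)),
      uv = list(band(284, 38, 0.24), band(420, 36, 0.12))
    )
  ),
  PPA = list(
    DCE = list(
      cd = list(band(302, 38, -2.4), band(372, 42, 1.8)),
      uv = list(band(334, 40, 0.22), band(388, 44, 0.12))
    ),
    MeOH = list(
      cd = list(band(286, 34, 1.5), band(352, 40, -1.9), band(414, 34, 0.9)),
      uv = list(band(292, 42, 0.24), band(414, 38, 0.10))
    )
  )
)

#' Preset component basis for an analyte
#'
#' Returns the per-solvent molar UV and CD basis band lists for one of the
#' four built-in analytes. The CD bands describe the (R)-enantiomer adduct
#' (for PPA, the (1R,2S) diastereomer); the (S) basis is exactly its
#' negative, and the UV basis is shared by both enantiomers.
#'
#' @param analyte one of `"PEA"`, `"PMP"`, `"PGL"`, `"PPA"`.
#' @return list of class `component_basis` with fields `analyte` and one
#'   entry per solvent holding `cd_bands` and `uv_bands`.
#' @export
make_preset_basis <- function(analyte) {
  if (!analyte %in% names(.PRESETS)) {
    stop(sprintf("no preset basis for analyte '%s' (have: %s)",
                 analyte, paste(names(.PRESETS), collapse = ", ")),
         call. = FALSE)
  }
  structure(c(list(analyte = analyte), .PRESETS[[analyte]]),
            class = "component_basis")
}

#' Render a component basis on a grid
#'
#' @param basis `component_basis`.
#' @param solvent `"DCE"` or `"MeOH"`.
#' @param enantiomer `"R"` or `"S"` (CD sign flips for S; UV is identical).
#' @param grid wavelength grid (default canonical).
#' @return list with numeric vectors `cd` (mdeg/mM) and `uv` (AU/mM).
#' @export
render_basis <- function(basis, solvent, enantiomer = "R",
                         grid = default_grid()) {
  stopifnot(inherits(basis, "component_basis"))
  solvent <- match.arg(solvent, .SOLVENTS)
  enantiomer <- match.arg(enantiomer, c("R", "S"))
  sgn <- if (enantiomer == "R") 1 else -1
  list(
    cd = sgn * render_bands(grid, basis[[solvent]]$cd),
    uv = render_bands(grid, basis[[solvent]]$uv)
  )
}

# Compositions and noise -------------------------------------------------

#' Mixture composition
#'
#' Per-analyte (R, S) enantiomer concentrations in mM. For PPA "R" denotes
#' the (1R,2S) diastereomer and "S" its (1S,2R) mirror image.
#'
#' @param ... named numeric vectors `c(R = , S = )`, one per analyte,
#'   e.g. `composition(PEA = c(R = 3, S = 1))`.
#' @return list of class `mix_composition`.
#' @export
composition <- function(...) {
  comps <- list(...)
  if (length(comps) == 0L) stop("empty composition", call. = FALSE)
  for (nm in names(comps)) {
    v <- comps[[nm]]
    if (!all(c("R", "S") %in% names(v)) || anyNA(v) || any(!is.finite(v)) ||
        any(v < 0)) {
      stop(sprintf("composition for '%s' needs finite non-negative R and S", nm),
           call. = FALSE)
    }
  }
  structure(comps, class = "mix_composition")
}

comp_total <- function(comp) vapply(comp, function(v) unname(v["R"] + v["S"]), 0)
comp_diff <- function(comp) vapply(comp, function(v) unname(v["R"] - v["S"]), 0)

#' Instrument noise model
#'
#' Each simulated point y becomes `y * (1 + N(0, multiplicative_sd)) +
#' N(0, additive_sd_fraction * max|signal|)` where the max is taken per
#' modality over the whole (noiseless) dataset, mimicking a fixed
#' instrument noise floor plus proportional error.
#'
#' @param multiplicative_sd unitless fraction (default 0.01).
#' @param additive_sd_fraction fraction of the per-modality max absolute
#'   signal (default 0.003).
#' @return list of class `noise_model`.
#' @export
noise_model <- function(multiplicative_sd = 0.01, additive_sd_fraction = 0.003) {
  if (multiplicative_sd < 0 || additive_sd_fraction < 0) {
    stop("noise standard deviations must be >= 0", call. = FALSE)
  }
  structure(list(multiplicative_sd = multiplicative_sd,
                 additive_sd_fraction = additive_sd_fraction),
            class = "noise_model")
}

# Stable per-sample seed stream: adding samples to a design never
# reshuffles the noise of existing ones.
sample_seed <- function(master_seed, sample_id) {
  h <- 0
  for (b in utf8ToInt(paste0("s", sample_id))) h <- (h * 131 + b) %% 2147483647
  as.integer((h + as.numeric(master_seed) * 2654435761) %% 2147483647)
}

apply_noise <- function(y, noise, add_sd, rng_seed) {
  if (is.null(noise)) return(y)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(rng_seed)
  y * (1 + stats::rnorm(length(y), 0, noise$multiplicative_sd)) +
    stats::rnorm(length(y), 0, add_sd)
}

#' Simulate the CD and UV spectra of one mixture
#'
#' Noiseless forward model: `CD(l) = sum_i (cR_i - cS_i) * dEps_i(l)`,
#' `UV(l) = sum_i (cR_i + cS_i) * Eps_i(l)`. A racemic mixture is CD-silent;
#' swapping every R and S negates CD and leaves UV unchanged.
#'
#' @param bases list of `component_basis`, one per analyte in `comp`.
#' @param comp `mix_composition`.
#' @param solvent `"DCE"` or `"MeOH"`.
#' @param noise `noise_model` or `NULL` for noiseless.
#' @param grid wavelength grid.
#' @param sample_id id stored in the returned spectra (also seeds the
#'   per-sample noise stream together with `seed`).
#' @param seed master seed for the noise stream (ignored when `noise` is
#'   `NULL`).
#' @param reference_max optional named list `list(CD = , UV = )` of
#'   dataset-wide max absolute signals used to scale the additive noise;
#'   defaults to this spectrum pair's own maxima.
#' @return list with elements `cd` and `uv`, both `spectrum` objects.
#' @export
simulate_mixture <- function(bases, comp, solvent, noise = NULL,
                             grid = default_grid(), sample_id = "mix",
                             seed = 1L, reference_max = NULL) {
  stopifnot(inherits(comp, "mix_composition"))
  names(bases) <- vapply(bases, function(b) b$analyte, "")
  missing <- setdiff(names(comp), names(bases))
  if (length(missing)) {
    stop(sprintf("no basis supplied for analyte(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  totals <- comp_total(comp)
  diffs <- comp_diff(comp)
  cd <- numeric(length(grid)); uv <- numeric(length(grid))
  for (nm in names(comp)) {
    rb <- render_basis(bases[[nm]], solvent, "R", grid)
    cd <- cd + diffs[[nm]] * rb$cd
    uv <- uv + totals[[nm]] * rb$uv
  }
  if (!is.null(noise)) {
    ref <- reference_max
    if (is.null(ref)) ref <- list(CD = max(abs(cd)), UV = max(abs(uv)))
    s0 <- sample_seed(seed, sample_id)
    cd <- apply_noise(cd, noise, noise$additive_sd_fraction * ref$CD, s0)
    uv <- apply_noise(uv, noise, noise$additive_sd_fraction * ref$UV, s0 + 1L)
  }
  list(
    cd = spectrum(grid, cd, "CD", solvent, sample_id),
    uv = spectrum(grid, uv, "UV", solvent, sample_id)
  )
}

# Experiment designs -----------------------------------------------------

design_spec <- function(design) {
  switch(design,
    quaternary = list(analytes = c("PEA", "PMP"), solvents = "DCE",
                      conc_range = c(0, 13)),
    octonary = list(analytes = c("PEA", "PMP", "PGL", "PPA"),
                    solvents = c("DCE", "MeOH"), conc_range = c(0, 5)),
    stop(sprintf("unknown design '%s'", design), call. = FALSE)
  )
}

#' Simulate a full calibration campaign
#'
#' The quaternary design mirrors the two-analyte (PEA + PMP) experiment:
#' CD and UV blocks in DCE, four enantiomer concentration channels,
#' enantiomer concentrations drawn uniformly on (0, 13) mM. The octonary
#' design mirrors the four-analyte experiment: four blocks (CD and UV in
#' DCE and MeOH), eight channels, concentrations uniform on (0, 5) mM.
#'
#' @param design `"quaternary"` or `"octonary"`.
#' @param n_train,n_test numbers of training and test mixtures.
#' @param seed master seed; the same seed always reproduces the same
#'   dataset, and per-sample noise streams are keyed by (seed, sample id).
#' @param noise `noise_model` or `NULL`.
#' @param conc_range optional `(lo, hi)` mM override of the design default.
#' @param grid wavelength grid.
#' @return `multiblock_dataset` (see [multiblock_dataset()]) with an extra
#'   attribute `roles` marking rows `"train"`/`"test"`.
#' @export
simulate_design <- function(design = c("quaternary", "octonary"),
                            n_train = if (design == "quaternary") 16L else 24L,
                            n_test = if (design == "quaternary") 5L else 6L,
                            seed = 1L, noise = noise_model(),
                            conc_range = NULL, grid = default_grid()) {
  design <- match.arg(design)
  spec <- design_spec(design)
  if (is.null(conc_range)) conc_range <- spec$conc_range
  n_chan <- 2L * length(spec$analytes)
  if (n_train < n_chan) {
    stop(sprintf("ill-posed design: n_train = %d < %d enantiomer channels",
                 n_train, n_chan), call. = FALSE)
  }
  bases <- lapply(spec$analytes, make_preset_basis)
  names(bases) <- spec$analytes

  n <- n_train + n_test
  ids <- sprintf("%s_%02d", c(rep("train", n_train), rep("test", n_test)),
                 c(seq_len(n_train), seq_len(n_test)))
  roles <- c(rep("train", n_train), rep("test", n_test))

  # compositions: per-sample streams so the design is extensible
  Y <- matrix(0, n, n_chan)
  channel_names <- as.vector(t(outer(spec$analytes, c("R", "S"), paste,
                                     sep = "_")))
  colnames(Y) <- channel_names
  comps <- vector("list", n)
  for (i in seq_len(n)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(sample_seed(seed, paste0("comp_", ids[i])))
    draw <- stats::runif(n_chan, conc_range[1], conc_range[2])
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    Y[i, ] <- draw
    cl <- lapply(seq_along(spec$analytes), function(a) {
      c(R = draw[2 * a - 1], S = draw[2 * a])
    })
    names(cl) <- spec$analytes
    comps[[i]] <- do.call(composition, cl)
  }

  # noiseless signal pass to fix the per-modality additive noise scale
  block_names <- as.vector(outer(c("CD", "UV"), spec$solvents, paste,
                                 sep = "_"))
  noiseless <- lapply(block_names, function(bn) {
    matrix(0, n, length(grid))
  })
  names(noiseless) <- block_names
  for (i in seq_len(n)) {
    for (sv in spec$solvents) {
      sp <- simulate_mixture(bases, comps[[i]], sv, noise = NULL, grid = grid,
                             sample_id = ids[i])
      noiseless[[paste0("CD_", sv)]][i, ] <- sp$cd$intensities
      noiseless[[paste0("UV_", sv)]][i, ] <- sp$uv$intensities
    }
  }
  ref <- list(CD = max(abs(unlist(noiseless[grep("^CD_", block_names)]))),
              UV = max(abs(unlist(noiseless[grep("^UV_", block_names)]))))

  blocks <- lapply(block_names, function(bn) {
    modality <- sub("_.*$", "", bn)
    M <- noiseless[[bn]]
    if (!is.null(noise)) {
      add_sd <- noise$additive_sd_fraction * ref[[modality]]
      for (i in seq_len(n)) {
        M[i, ] <- apply_noise(M[i, ], noise, add_sd,
                              sample_seed(seed, paste0(bn, "_", ids[i])))
      }
    }
    rownames(M) <- ids
    spectral_block(bn, M, grid, ids)
  })
  names(blocks) <- block_names

  ds <- multiblock_dataset(blocks, Y, channel_names, sample_ids = ids)
  attr(ds, "roles") <- roles
  attr(ds, "design") <- design
  ds
}

#' Split a simulated dataset into its train and test parts
#'
#' @param dataset `multiblock_dataset` carrying a `roles` attribute.
#' @return list with `train` and `test` datasets.
#' @export
split_design <- function(dataset) {
  roles <- attr(dataset, "roles")
  if (is.null(roles)) stop("dataset has no roles attribute", call. = FALSE)
  list(train = subset_dataset(dataset, roles == "train"),
       test = subset_dataset(dataset, roles == "test"))
}

#' Export a simulated design as spectrum CSVs plus a JSON manifest
#'
#' @param dataset `multiblock_dataset` from [simulate_design()].
#' @param dir output directory (created if absent).
#' @return path of the manifest file, invisibly.
#' @export
export_design <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  roles <- attr(dataset, "roles")
  ids <- dataset$sample_ids
  samples <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    files <- list()
    for (bn in names(dataset$blocks)) {
      bl <- dataset$blocks[[bn]]
      modality <- sub("_.*$", "", bn)
      solvent <- sub("^[^_]*_", "", bn)
      f <- file.path(dir, sprintf("%s_%s.csv", ids[i], bn))
      write_spectrum_csv(
        spectrum(bl$grid, bl$matrix[i, ], modality, solvent, ids[i]), f)
      files[[bn]] <- basename(f)
    }
    chans <- dataset$channel_names
    analytes <- unique(sub("_[RS]$", "", chans))
    compo <- lapply(analytes, function(a) {
      list(R_mM = unname(dataset$Y[i, paste0(a, "_R")]),
           S_mM = unname(dataset$Y[i, paste0(a, "_S")]))
    })
    names(compo) <- analytes
    samples[[i]] <- list(id = ids[i],
                         role = if (is.null(roles)) "train" else roles[i],
                         composition = compo, files = files)
  }
  man <- file.path(dir, "manifest.json")
  write_manifest(list(samples = samples), man)
  invisible(man)
}

#' Load a dataset written by [export_design()]
#'
#' @param manifest_path path to the JSON/YAML manifest.
#' @param grid target wavelength grid; spectra are resampled onto it.
#' @return `multiblock_dataset` with a `roles` attribute.
#' @export
load_design <- function(manifest_path, grid = default_grid()) {
  man <- read_manifest(manifest_path)
  dir <- dirname(manifest_path)
  ids <- vapply(man$samples, `[[`, "", "id")
  roles <- vapply(man$samples, `[[`, "", "role")
  block_names <- sort(names(man$samples[[1]]$files))
  blocks <- lapply(block_names, function(bn) {
    M <- t(vapply(man$samples, function(s) {
      sp <- read_spectrum_csv(file.path(dir, s$files[[bn]]))
      resample(sp, grid)$intensities
    }, numeric(length(grid))))
    rownames(M) <- ids
    spectral_block(bn, M, grid, ids)
  })
  names(blocks) <- block_names
  analytes <- names(man$samples[[1]]$composition)
  channel_names <- as.vector(t(outer(analytes, c("R", "S"), paste, sep = "_")))
  Y <- t(vapply(man$samples, function(s) {
    unlist(lapply(analytes, function(a) {
      cc <- s$composition[[a]]
      c(if (is.null(cc$R_mM)) NA_real_ else cc$R_mM,
        if (is.null(cc$S_mM)) NA_real_ else cc$S_mM)
    }))
  }, numeric(2 * length(analytes))))
  colnames(Y) <- channel_names
  rownames(Y) <- ids
  ds <- multiblock_dataset(blocks, Y, channel_names, sample_ids = ids)
  attr(ds, "roles") <- roles
  ds
}
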