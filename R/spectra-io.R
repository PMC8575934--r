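# Wavelength grids -------------------------------------------------------

#' Construct a wavelength grid
#'
#' A wavelength grid is a strictly increasing numeric vector of wavelengths
#' in nanometres, restricted to the 200--600 nm window within which the
#' probe chemistry produces induced CD/UV signal.
#'
#' @param values numeric vector of wavelengths (nm), strictly increasing.
#' @return numeric vector of class `wl_grid`.
#' @examples
#' g <- wl_grid(seq(250, 450, by = 1))
#' length(g)  # 201
#' @export
wl_grid <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) {
    stop("wavelength grid must contain at least one point", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("wavelength grid must be finite", call. = FALSE)
  }
  if (any(diff(values) <= 0)) {
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  }
  if (min(values) < 200 || max(values) > 600) {
    stop("wavelengths must lie within [200, 600] nm", call. = FALSE)
  }
  structure(values, class = "wl_grid")
}

#' Canonical 250--450 nm grid at 1 nm resolution (201 points)
#'
#' All presets and simulated designs use this grid; it covers the full
#' spectral window in which the coumarin probe adducts absorb.
#'
#' @return `wl_grid` of 201 wavelengths.
#' @export
default_grid <- function() wl_grid(seq(250, 450, by = 1))

#' @export
print.wl_grid <- function(x, ...) {
  cat(sprintf("<wl_grid> %d points, %.6g--%.6g nm\n",
              length(x), min(x), max(x)))
  invisible(x)
}

# Spectrum ---------------------------------------------------------------

.MODALITIES <- c("CD", "UV")
.SOLVENTS <- c("DCE", "MeOH")

#' Construct a spectrum
#'
#' One measurement trace: intensities on a wavelength grid, tagged with
#' modality (CD in millidegrees of ellipticity, UV in absorbance units),
#' solvent, and a sample identifier.
#'
#' @param grid `wl_grid` (or numeric vector coerced to one).
#' @param intensities numeric vector, same length as `grid`.
#' @param modality `"CD"` or `"UV"`.
#' @param solvent `"DCE"` or `"MeOH"`.
#' @param sample_id character scalar.
#' @return object of class `spectrum`.
#' @export
spectrum <- function(grid, intensities, modality, solvent, sample_id = "") {
  if (!inherits(grid, "wl_grid")) grid <- wl_grid(grid)
  intensities <- as.numeric(intensities)
  modality <- match.arg(modality, .MODALITIES)
  solvent <- match.arg(solvent, .SOLVENTS)
  if (length(intensities) != length(grid)) {
    stop("intensities and grid must have the same length", call. = FALSE)
  }
  if (anyNA(intensities) || any(!is.finite(intensities))) {
    stop("intensities must be finite", call. = FALSE)
  }
  structure(
    list(grid = grid, intensities = intensities, modality = modality,
         solvent = solvent, sample_id = as.character(sample_id)[1]),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s/%s sample='%s', %d points %.6g--%.6g nm, range [%.4g, %.4g]\n",
              x$modality, x$solvent, x$sample_id, length(x$grid),
              min(x$grid), max(x$grid),
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

# CSV I/O ----------------------------------------------------------------
# Dialect: '#'-prefixed "key: value" metadata header, then a
# "wavelength_nm,value" column header and comma-separated rows with '.'
# decimal separator. Values are printed with 10 significant digits so a
# write/read round trip is lossless at that precision.

#' Write a spectrum to CSV
#'
#' @param s `spectrum`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_spectrum_csv()]
#' @export
write_spectrum_csv <- function(s, path) {
  stopifnot(inherits(s, "spectrum"))
  lines <- c(
    sprintf("# modality: %s", s$modality),
    sprintf("# solvent: %s", s$solvent),
    sprintf("# sample_id: %s", s$sample_id),
    "wavelength_nm,value",
    sprintf("%.10g,%.10g", as.numeric(s$grid), s$intensities)
  )
  ok <- tryCatch({
    writeLines(lines, path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop(sprintf("cannot write spectrum to '%s'", path), call. = FALSE)
  invisible(path)
}

#' Read a spectrum from CSV
#'
#' Rows are sorted by wavelength on read, so row order in the file is
#' irrelevant; duplicate wavelengths are rejected.
#'
#' @param path input file path.
#' @return `spectrum`.
#' @export
read_spectrum_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", h))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- trimws(m[3])
  }
  for (key in c("modality", "solvent", "sample_id")) {
    if (is.null(meta[[key]])) {
      stop(sprintf("spectrum CSV '%s' is missing header key '%s'", path, key),
           call. = FALSE)
    }
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  # drop the column header line if present
  if (length(body) && grepl("^\\s*wavelength", body[1], ignore.case = TRUE)) {
    body <- body[-1]
  }
  if (length(body) == 0L) {
    stop(sprintf("spectrum CSV '%s' contains no data rows", path), call. = FALSE)
  }
  parts <- strsplit(body, ",", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop(sprintf("malformed data row in '%s'", path), call. = FALSE)
  }
  wl <- as.numeric(vapply(parts, `[[`, "", 1L))
  val <- as.numeric(vapply(parts, `[[`, "", 2L))
  if (anyNA(wl) || anyNA(val)) {
    stop(sprintf("non-numeric data in '%s'", path), call. = FALSE)
  }
  o <- order(wl)
  wl <- wl[o]; val <- val[o]
  if (any(diff(wl) == 0)) {
    stop(sprintf("duplicate wavelengths in '%s'", path), call. = FALSE)
  }
  spectrum(wl_grid(wl), val, meta$modality, meta$solvent, meta$sample_id)
}

# Resampling -------------------------------------------------------------

#' Resample a spectrum onto a new grid by linear interpolation
#'
#' No extrapolation: the requested grid must lie inside the spectrum's
#' wavelength range.
#'
#' @param s `spectrum`.
#' @param grid target `wl_grid`.
#' @return `spectrum` on `grid` with modality/solvent/sample_id preserved.
#' @export
resample <- function(s, grid) {
  stopifnot(inherits(s, "spectrum"))
  if (!inherits(grid, "wl_grid")) grid <- wl_grid(grid)
  rng <- range(as.numeric(s$grid))
  if (min(grid) < rng[1] || max(grid) > rng[2]) {
    stop(sprintf(
      "requested grid [%.6g, %.6g] nm extends beyond data range [%.6g, %.6g] nm",
      min(grid), max(grid), rng[1], rng[2]), call. = FALSE)
  }
  y <- stats::approx(as.numeric(s$grid), s$intensities, xout = as.numeric(grid),
                     method = "linear", ties = "ordered")$y
  spectrum(grid, y, s$modality, s$solvent, s$sample_id)
}

# Dataset manifests ------------------------------------------------------

#' Read a dataset manifest (JSON or YAML)
#'
#' A manifest maps sample ids to spectrum files per (modality, solvent)
#' block and, for training samples, the known per-enantiomer composition
#' in mM. Structure:
#' `samples[].{id, role, composition{analyte{R_mM,S_mM}}, files{CD_DCE,...}}`.
#'
#' @param path `.json`, `.yml` or `.yaml` file.
#' @return list of class `dataset_manifest` with element `samples`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("manifest not found: '%s'", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  man <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML manifests", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  validate_manifest(man)
}

#' Write a dataset manifest as JSON
#'
#' @param manifest `dataset_manifest` (or compatible list).
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  manifest <- validate_manifest(unclass(manifest))
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

validate_manifest <- function(man) {
  if (is.null(man$samples) || length(man$samples) == 0L) {
    stop("manifest has no samples", call. = FALSE)
  }
  keysets <- lapply(man$samples, function(s) sort(names(s$files)))
  if (length(unique(keysets)) != 1L) {
    stop("all samples must reference the same set of (modality, solvent) blocks",
         call. = FALSE)
  }
  for (s in man$samples) {
    if (is.null(s$id) || is.null(s$role)) {
      stop("every manifest sample needs 'id' and 'role'", call. = FALSE)
    }
    if (!s$role %in% c("train", "test")) {
      stop(sprintf("sample '%s': role must be 'train' or 'test'", s$id),
           call. = FALSE)
    }
    if (identical(s$role, "train") && is.null(s$composition)) {
      stop(sprintf("training sample '%s' lacks a known composition", s$id),
           call. = FALSE)
    }
  }
  structure(man, class = "dataset_manifest")
}

# Minimal JCAMP-DX import ------------------------------------------------

#' Read a minimal JCAMP-DX spectrum
#'
#' Supports only the fixed-abscissa AFFN form `##XYDATA=(X++(Y..Y))` with
#' `##FIRSTX`, `##LASTX`, `##NPOINTS` and optional `##YFACTOR`/`##XFACTOR`.
#' Any other data class (XYPOINTS, PEAK TABLE, compressed ASDF/DIFDUP
#' encodings) is rejected as unsupported.
#'
#' @param path JCAMP-DX file.
#' @param modality,solvent,sample_id metadata for the returned spectrum
#'   (JCAMP titles rarely carry these fields unambiguously).
#' @return `spectrum`.
#' @export
read_jcampdx <- function(path, modality = "UV", solvent = "DCE",
                         sample_id = "") {
  if (!file.exists(path)) {
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  ldr <- function(name) {
    hit <- grep(sprintf("^##%s=", name), lines, value = TRUE)
    if (length(hit) == 0L) return(NULL)
    trimws(sub(sprintf("^##%s=", name), "", hit[1]))
  }
  xy <- grep("^##XYDATA=", lines)
  if (length(xy) == 0L) {
    stop("unsupported JCAMP-DX dialect: no ##XYDATA record", call. = FALSE)
  }
  form <- gsub("\\s", "", sub("^##XYDATA=", "", lines[xy[1]]))
  if (form != "(X++(Y..Y))") {
    stop(sprintf("unsupported JCAMP-DX dialect: XYDATA=%s", form), call. = FALSE)
  }
  firstx <- as.numeric(ldr("FIRSTX")); lastx <- as.numeric(ldr("LASTX"))
  npts <- as.integer(ldr("NPOINTS"))
  if (is.null(firstx) || is.null(lastx) || is.null(npts) ||
      anyNA(c(firstx, lastx, npts))) {
    stop("unsupported JCAMP-DX dialect: need FIRSTX, LASTX, NPOINTS",
         call. = FALSE)
  }
  yf <- ldr("YFACTOR"); yf <- if (is.null(yf)) 1 else as.numeric(yf)
  end <- grep("^##END", lines)
  end <- if (length(end)) end[1] else length(lines) + 1L
  data_lines <- lines[(xy[1] + 1L):(end - 1L)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  # AFFN only: plain numbers separated by whitespace (or +/- signs attached)
  if (any(grepl("[A-DF-Za-df-z%@]", data_lines))) {
    stop("unsupported JCAMP-DX dialect: compressed (ASDF) data", call. = FALSE)
  }
  ys <- unlist(lapply(data_lines, function(l) {
    toks <- strsplit(trimws(l), "[,[:space:]]+")[[1]]
    as.numeric(toks[-1])  # first token on each line is the X start value
  }))
  if (anyNA(ys)) stop("malformed AFFN data in JCAMP-DX file", call. = FALSE)
  if (length(ys) != npts) {
    stop(sprintf("JCAMP-DX NPOINTS=%d but %d Y values found", npts, length(ys)),
         call. = FALSE)
  }
  wl <- seq(firstx, lastx, length.out = npts)
  if (firstx > lastx) { wl <- rev(wl); ys <- rev(ys) }
  spectrum(wl_grid(wl), ys * yf, modality, solvent, sample_id)
}
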