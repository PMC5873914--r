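# Reflectance-spectrum utilities: interpolation to the 1-nm grid, window
# binning, the red:far-red ratio, and a configurable band-math engine for
# vegetation indices (the named indices' formulas come from external
# references and are supplied via configuration, not hard-coded).

#' Construct a spectrum
#'
#' @param wavelength Strictly increasing wavelength grid (nm).
#' @param reflectance Reflectance values aligned with `wavelength`.
#' @return A `spectrum` data.frame with columns `wavelength`,
#'   `reflectance`.
#' @export
spectrum <- function(wavelength, reflectance) {
  if (length(wavelength) != length(reflectance))
    stop("wavelength and reflectance lengths differ", call. = FALSE)
  if (any(diff(wavelength) <= 0))
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  if (any(!is.finite(reflectance)))
    stop("reflectance values must be finite", call. = FALSE)
  structure(data.frame(wavelength = wavelength, reflectance = reflectance),
            class = c("spectrum", "data.frame"))
}

#' Interpolate a spectrum to the 1-nm grid
#'
#' Linear interpolation of an instrument-native sampling (e.g. 1.4 nm in
#' the VIS/NIR, 2 nm in the SWIR) onto one point per nanometer over
#' 350-2500 nm (2151 points), the grid the binning and index operations
#' expect.
#'
#' @param spec A `spectrum` (or coercible data.frame).
#' @param grid Target wavelength grid (default `350:2500`).
#' @return An interpolated `spectrum`.
#' @export
interpolate_1nm <- function(spec, grid = 350:2500) {
  spectrum(grid, stats::approx(spec$wavelength, spec$reflectance,
                               xout = grid, rule = 2)$y)
}

#' Mean reflectance over a wavelength window
#'
#' Arithmetic mean of the reflectance at wavelengths within
#' `[lo, hi]`, both endpoints inclusive.
#'
#' @param spec A `spectrum`.
#' @param lo,hi Window bounds in nm, `lo < hi`.
#' @return Mean reflectance (scalar).
#' @export
bin_mean <- function(spec, lo, hi) {
  if (lo >= hi) stop("'lo' must be below 'hi'", call. = FALSE)
  sel <- spec$wavelength >= lo & spec$wavelength <= hi
  if (!any(sel))
    stop("no wavelengths in window [", lo, ", ", hi, "]", call. = FALSE)
  mean(spec$reflectance[sel])
}

#' Red : far-red reflectance ratio
#'
#' Binned ratio `(655-665 nm) / (725-735 nm)` of mean reflectance.
#'
#' @param spec A `spectrum` covering both windows.
#' @return The R:FR ratio (scalar).
#' @export
rfr_ratio <- function(spec) {
  denom <- bin_mean(spec, 725, 735)
  if (denom <= 0) stop("far-red window mean must be positive", call. = FALSE)
  bin_mean(spec, 655, 665) / denom
}

#' Define a band-math index
#'
#' A named index is an arithmetic expression over named bands, each band
#' being a wavelength window summarized by its mean reflectance.
#'
#' @param name Index name.
#' @param expr Expression string over band names, e.g. `"(A - B)/(A + B)"`.
#' @param bands Named list of 2-vectors `c(lo, hi)` in nm.
#' @return A `band_index` definition.
#' @export
band_index <- function(name, expr, bands) {
  parsed <- tryCatch(str2lang(expr),
                     error = function(e) stop("malformed index expression: ",
                                              expr, call. = FALSE))
  used <- all.vars(parsed)
  missing_bands <- setdiff(used, names(bands))
  if (length(missing_bands))
    stop("expression references undefined bands: ",
         paste(missing_bands, collapse = ", "), call. = FALSE)
  structure(list(name = name, expr = parsed, bands = bands),
            class = "band_index")
}

#' Evaluate a band-math index on a spectrum
#'
#' Replaces every band by its window mean ([bin_mean()]) and evaluates
#' the definition's expression.
#'
#' @param spec A `spectrum`.
#' @param def A [band_index()] definition.
#' @return Index value (scalar).
#' @export
evaluate_index <- function(spec, def) {
  if (!inherits(def, "band_index"))
    stop("'def' must be a band_index", call. = FALSE)
  env <- new.env(parent = baseenv())
  for (b in names(def$bands))
    assign(b, bin_mean(spec, def$bands[[b]][1], def$bands[[b]][2]),
           envir = env)
  eval(def$expr, env)
}

#' Read band-index definitions from a YAML config
#'
#' Expected layout: a top-level `indices` map whose entries have `expr`
#' and `bands` (band name -> `[lo, hi]`).  Entries without a formula
#' (`expr` empty) are skipped: the named literature indices ship as empty
#' placeholders to be filled from their references.
#'
#' @param path YAML file path.
#' @return Named list of [band_index()] definitions.
#' @export
read_index_defs <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read index configs",
         call. = FALSE)
  cfg <- yaml::read_yaml(path)
  defs <- list()
  for (nm in names(cfg$indices)) {
    entry <- cfg$indices[[nm]]
    if (is.null(entry$expr) || !nzchar(entry$expr)) next
    defs[[nm]] <- band_index(nm, entry$expr,
                             lapply(entry$bands, as.numeric))
  }
  defs
}

#' Compute indices for a matrix of spectra
#'
#' @param wavelength Shared wavelength grid.
#' @param reflectance Matrix, plants x wavelengths.
#' @param defs Named list of [band_index()] definitions.
#' @param rfr Include the built-in R:FR ratio column (default TRUE).
#' @return data.frame, one row per plant, one column per index.
#' @export
spectra_indices <- function(wavelength, reflectance, defs = list(),
                            rfr = TRUE) {
  out <- data.frame(row.names = seq_len(nrow(reflectance)))
  for (i in seq_len(nrow(reflectance))) {
    sp <- spectrum(wavelength, reflectance[i, ])
    if (rfr) out[i, "RFR"] <- rfr_ratio(sp)
    for (nm in names(defs)) out[i, nm] <- evaluate_index(sp, defs[[nm]])
  }
  out
}
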