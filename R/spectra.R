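#' Spectral data container
#'
#' A `spectra` object holds a sample-by-wavelength matrix together with its
#' wavelength grid (nm), sample identifiers, and a mode flag saying whether
#' the values are reflectance (in `(0, 1]`) or absorbance (`>= 0`,
#' `log10(1/R)` units). All downstream stages (preprocessing, PCA, subset
#' selection, calibration) operate on this container.
#'
#' Invariants enforced at construction:
#' * wavelengths strictly increasing, all within 350--2500 nm;
#' * reflectance values in `(0, 1]`, absorbance values `>= 0`;
#' * no missing or non-finite cells (spectra are never imputed);
#' * sample ids unique, one per row.
#'
#' @param values numeric matrix, samples in rows, wavelengths in columns.
#' @param wavelengths numeric vector of wavelengths in nm, one per column.
#' @param mode `"reflectance"` or `"absorbance"`.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to the rownames of `values`, or `S1..Sn` if absent.
#' @return An object of class `spectra`: a list with elements `wavelengths`,
#'   `values` (with sample ids as rownames), `mode`, `sample_ids`.
#' @examples
#' m <- matrix(runif(6, 0.2, 0.8), 2, 3)
#' s <- spectra(m, c(500, 510, 520), "reflectance", c("A", "B"))
#' s
#' @export
spectra <- function(values, wavelengths,
                    mode = c("reflectance", "absorbance"),
                    sample_ids = NULL) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  wavelengths <- as.numeric(wavelengths)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  }
  sample_ids <- as.character(sample_ids)

  if (length(wavelengths) != ncol(values))
    stop("length(wavelengths) must equal ncol(values)")
  if (anyNA(wavelengths) || any(!is.finite(wavelengths)))
    stop("wavelengths must be finite numbers")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (min(wavelengths) < 350 || max(wavelengths) > 2500)
    stop("wavelengths must lie within [350, 2500] nm")
  if (length(sample_ids) != nrow(values))
    stop("one sample id per row required")
  if (anyDuplicated(sample_ids)) {
    dup <- unique(sample_ids[duplicated(sample_ids)])
    stop("duplicate sample ids: ", paste(dup, collapse = ", "))
  }
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at sample '%s', wavelength %g nm",
                 sample_ids[bad[1]], wavelengths[bad[2]]))
  }
  if (mode == "reflectance" && (any(values <= 0) || any(values > 1))) {
    bad <- which(values <= 0 | values > 1, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "reflectance must be in (0, 1]; offending cell: sample '%s', %g nm, value %g",
      sample_ids[bad[1]], wavelengths[bad[2]], values[bad[1], bad[2]]))
  }
  if (mode == "absorbance" && any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("absorbance must be >= 0; offending cell: sample '%s', %g nm",
                 sample_ids[bad[1]], wavelengths[bad[2]]))
  }
  dimnames(values) <- list(sample_ids, format_wl(wavelengths))
  structure(list(wavelengths = wavelengths, values = values,
                 mode = mode, sample_ids = sample_ids),
            class = "spectra")
}

# canonical wavelength header formatting (full precision, locale-free)
format_wl <- function(x) formatC(x, digits = 17, format = "g")

# full-precision numeric formatting for on-disk round trips: 17 significant
# digits guarantee bit-identical double -> text -> double
format_full <- function(x) formatC(x, digits = 17, format = "g")

#' @export
print.spectra <- function(x, ...) {
  cat(sprintf("<spectra> %d samples x %d wavelengths (%g-%g nm), mode = %s\n",
              nrow(x$values), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths), x$mode))
  invisible(x)
}

#' @export
dim.spectra <- function(x) dim(x$values)

#' Subset a spectra object by sample
#'
#' @param x a [spectra] object.
#' @param i row (sample) index: integer, logical, or sample-id character.
#' @param ... unused.
#' @return a `spectra` object with the selected samples, in the order given.
#' @export
`[.spectra` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$sample_ids)
  spectra(x$values[i, , drop = FALSE], x$wavelengths, x$mode,
          x$sample_ids[i])
}

#' Read a spectral table
#'
#' Reads the canonical wide CSV dialect (first column `sample_id`, remaining
#' headers numeric wavelengths in nm) or the long dialect (columns
#' `sample_id, wavelength, value`). Wavelength columns are sorted ascending;
#' sample order follows first appearance in the file. Duplicate sample ids,
#' duplicate wavelengths, non-numeric headers and out-of-range reflectance
#' are hard errors.
#'
#' @param path path to a CSV file.
#' @param layout `"wide"` (default) or `"long"`.
#' @param mode value mode of the stored spectra, `"reflectance"` (default)
#'   or `"absorbance"`.
#' @return a [spectra] object.
#' @seealso [write_spectra()]
#' @export
read_spectra <- function(path, layout = c("wide", "long"),
                         mode = c("reflectance", "absorbance")) {
  layout <- match.arg(layout)
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path)
  if (layout == "wide") {
    df <- utils::read.csv(path, check.names = FALSE,
                          colClasses = "character")
    if (names(df)[1] != "sample_id")
      stop("wide layout requires first column 'sample_id'")
    wl <- suppressWarnings(as.numeric(names(df)[-1]))
    if (anyNA(wl))
      stop("non-numeric wavelength header(s): ",
           paste(names(df)[-1][is.na(wl)], collapse = ", "))
    if (anyDuplicated(wl)) stop("duplicated wavelength columns")
    ids <- df[[1]]
    vals <- vapply(df[-1], as.numeric, numeric(nrow(df)))
    vals <- matrix(vals, nrow = nrow(df))
    o <- order(wl)
    spectra(vals[, o, drop = FALSE], wl[o], mode, ids)
  } else {
    df <- utils::read.csv(path, check.names = FALSE,
                          colClasses = "character")
    need <- c("sample_id", "wavelength", "value")
    if (!all(need %in% names(df)))
      stop("long layout requires columns: ", paste(need, collapse = ", "))
    ids <- unique(df$sample_id)
    wl <- sort(unique(as.numeric(df$wavelength)))
    if (anyDuplicated(paste(df$sample_id, df$wavelength)))
      stop("duplicated (sample_id, wavelength) entries")
    vals <- matrix(NA_real_, length(ids), length(wl))
    ri <- match(df$sample_id, ids)
    ci <- match(as.numeric(df$wavelength), wl)
    vals[cbind(ri, ci)] <- as.numeric(df$value)
    if (anyNA(vals)) stop("long table is not a complete sample x wavelength grid")
    spectra(vals, wl, mode, ids)
  }
}

#' Write a spectral table
#'
#' Writes a [spectra] object in the wide or long CSV dialect read by
#' [read_spectra()]. Values are written with 17 significant digits, so a
#' read/write/read cycle reproduces the doubles bit for bit.
#'
#' @param x a [spectra] object.
#' @param path output file path.
#' @param layout `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(x, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  stopifnot(inherits(x, "spectra"))
  if (layout == "wide") {
    header <- c("sample_id", format_wl(x$wavelengths))
    rows <- vapply(seq_along(x$sample_ids), function(i) {
      paste(c(x$sample_ids[i], format_full(x$values[i, ])), collapse = ",")
    }, character(1))
    writeLines(c(paste(header, collapse = ","), rows), path)
  } else {
    n <- length(x$sample_ids); p <- length(x$wavelengths)
    lines <- paste(rep(x$sample_ids, each = p),
                   rep(format_wl(x$wavelengths), n),
                   format_full(as.vector(t(x$values))), sep = ",")
    writeLines(c("sample_id,wavelength,value", lines), path)
  }
  invisible(path)
}

#' Read a sample metadata table
#'
#' Fixed-header CSV `sample_id,chlorophyll,species,month,replicate`.
#' Chlorophyll is in mg per g fresh weight and may be missing for
#' prediction-only samples; month is the calendar month of sampling within
#' the February--November study window.
#'
#' @param path path to the metadata CSV.
#' @return a validated `data.frame`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  validate_metadata(df)
}

validate_metadata <- function(df) {
  need <- c("sample_id", "chlorophyll", "species", "month", "replicate")
  if (!all(need %in% names(df)))
    stop("metadata requires columns: ", paste(need, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$chlorophyll <- as.numeric(df$chlorophyll)
  df$month <- as.integer(df$month)
  df$replicate <- as.integer(df$replicate)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in metadata")
  chl <- df$chlorophyll[!is.na(df$chlorophyll)]
  if (any(!is.finite(chl)) || any(chl < 0))
    stop("chlorophyll must be finite and >= 0 where present")
  if (any(df$month < 2 | df$month > 11, na.rm = TRUE))
    stop("month must be within the February-November study window (2-11)")
  df
}

#' Join spectra with sample metadata
#'
#' Inner-joins a [spectra] object with a metadata table on `sample_id`,
#' preserving the spectra's sample order. In strict mode every spectrum must
#' have metadata; in lenient mode unmatched spectra are dropped with a
#' warning reporting the count.
#'
#' @param x a [spectra] object.
#' @param meta a metadata `data.frame` as returned by [read_metadata()].
#' @param strict if `TRUE` (default), any spectrum without metadata is an
#'   error; if `FALSE`, unmatched spectra are dropped.
#' @return a `leaf_dataset`: list with elements `spectra` (subset, original
#'   order) and `meta` (rows aligned to the spectra), with attribute
#'   `dropped` giving the number of spectra discarded.
#' @export
join_metadata <- function(x, meta, strict = TRUE) {
  stopifnot(inherits(x, "spectra"))
  meta <- validate_metadata(meta)
  hit <- x$sample_ids %in% meta$sample_id
  if (!any(hit)) stop("no sample ids shared between spectra and metadata")
  if (strict && !all(hit))
    stop("metadata missing for sample(s): ",
         paste(utils::head(x$sample_ids[!hit], 5), collapse = ", "))
  dropped <- sum(!hit)
  if (dropped > 0)
    warning(sprintf("dropped %d spectra without metadata", dropped))
  keep <- x$sample_ids[hit]
  out <- structure(
    list(spectra = x[keep],
         meta = meta[match(keep, meta$sample_id), , drop = FALSE]),
    class = "leaf_dataset")
  rownames(out$meta) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' @export
print.leaf_dataset <- function(x, ...) {
  cat(sprintf("<leaf_dataset> %d samples, %d wavelengths, mode = %s\n",
              nrow(x$spectra$values), length(x$spectra$wavelengths),
              x$spectra$mode))
  cat(sprintf("  species: %s\n",
              paste(unique(x$meta$species), collapse = ", ")))
  invisible(x)
}
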