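#' Construct a SpectralSet
#'
#' @param intensity numeric matrix of detector counts, wavelengths in rows
#'   and spectra in columns (`L x N`).
#' @param wavelengths numeric vector of length `L`, strictly increasing, nm.
#' @param classes class (origin) label per spectrum; character or factor of
#'   length `N`. Factor level order defines the class order (the first level
#'   is the "positive" class in two-class evaluation).
#' @param tablets tablet (pellet replicate) identifier per spectrum.
#'   Defaults to one pseudo-tablet per class.
#' @param sampleIds opaque per-spectrum identifiers; defaults to
#'   `spec_00001, ...`.
#' @param shotIndex integer shot index within tablet (>= 0); defaults to a
#'   running index within each tablet.
#' @param classNames optional explicit class-level order.
#' @return A [SpectralSet-class] object.
#' @examples
#' s <- SpectralSet(matrix(runif(20), nrow = 5), seq(400, 500, length.out = 5),
#'                  classes = rep(c("A", "B"), each = 2))
#' s
#' @export
SpectralSet <- function(intensity, wavelengths, classes, tablets = NULL,
                        sampleIds = NULL, shotIndex = NULL,
                        classNames = NULL) {
  intensity <- as.matrix(intensity)
  storage.mode(intensity) <- "double"
  n <- ncol(intensity)
  if (length(wavelengths) != nrow(intensity))
    stop("length(wavelengths) must equal nrow(intensity)", call. = FALSE)
  if (length(classes) != n)
    stop("one class label per spectrum required", call. = FALSE)
  if (is.null(classNames))
    classNames <- if (is.factor(classes)) levels(classes) else unique(as.character(classes))
  classes <- factor(as.character(classes), levels = classNames)
  if (anyNA(classes))
    stop("class labels outside classNames", call. = FALSE)
  if (is.null(tablets))
    tablets <- if (n) paste0("tab_", as.integer(classes)) else character()
  tablets <- as.character(tablets)
  if (is.null(sampleIds))
    sampleIds <- sprintf("spec_%05d", seq_len(n))
  if (is.null(shotIndex)) {
    shotIndex <- integer(n)
    for (tb in unique(tablets)) {
      i <- which(tablets == tb)
      shotIndex[i] <- seq_along(i) - 1L
    }
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensity),
    rowData = S4Vectors::DataFrame(wavelength_nm = as.numeric(wavelengths)),
    colData = S4Vectors::DataFrame(sample_id = as.character(sampleIds),
                                   class = classes,
                                   tablet = tablets,
                                   shot_index = as.integer(shotIndex),
                                   row.names = make.unique(as.character(sampleIds))))
  new("SpectralSet", se)
}

#' @describeIn SpectralSet wavelength grid (nm).
#' @param x a `SpectralSet`
#' @export
setMethod("wavelengths", "SpectralSet", function(x)
  as.numeric(SummarizedExperiment::rowData(x)$wavelength_nm))

#' @describeIn SpectralSet intensity matrix (`L x N`).
#' @export
setMethod("intensities", "SpectralSet", function(x)
  SummarizedExperiment::assay(x, "intensity"))

#' @describeIn SpectralSet per-spectrum class factor.
#' @export
setMethod("classLabels", "SpectralSet", function(x)
  SummarizedExperiment::colData(x)$class)

#' @describeIn SpectralSet ordered class names.
#' @export
setMethod("spectrumClasses", "SpectralSet", function(x)
  levels(SummarizedExperiment::colData(x)$class))

#' @describeIn SpectralSet per-spectrum tablet identifiers.
#' @export
setMethod("tabletIds", "SpectralSet", function(x)
  SummarizedExperiment::colData(x)$tablet)

#' @describeIn SpectralSet per-spectrum shot indices.
#' @export
setMethod("shotIndices", "SpectralSet", function(x)
  SummarizedExperiment::colData(x)$shot_index)

#' @describeIn SpectralSet per-spectrum opaque identifiers.
#' @export
setMethod("sampleIds", "SpectralSet", function(x)
  SummarizedExperiment::colData(x)$sample_id)

setMethod("show", "SpectralSet", function(object) {
  wl <- wavelengths(object)
  cl <- classLabels(object)
  cat(sprintf("SpectralSet: %d spectra x %d wavelength points (%.2f-%.2f nm)\n",
              ncol(object), nrow(object),
              if (length(wl)) min(wl) else NA, if (length(wl)) max(wl) else NA))
  tab <- table(cl)
  cat(sprintf("classes: %s\n",
              paste(sprintf("%s (%d)", names(tab), tab), collapse = ", ")))
  cat(sprintf("tablets: %d\n", length(unique(tabletIds(object)))))
})

.delim_for <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

#' Write a SpectralSet to delimited text
#'
#' Writes one wide table (rows = spectra, columns = wavelengths, first
#' column `sample_id`) and a side-car manifest (`<stem>_manifest.<ext>`)
#' mapping each `sample_id` to its class, tablet and shot index. Numbers
#' are serialized with 17 significant digits so that
#' `readSpectra(writeSpectra(x))` round-trips intensities bitwise.
#'
#' @param ds a [SpectralSet-class]
#' @param path output file; `.csv` writes comma-separated, `.tsv`/`.txt`
#'   tab-separated.
#' @return invisibly, a character vector of the two files written.
#' @export
writeSpectra <- function(ds, path) {
  stopifnot(is(ds, "SpectralSet"))
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop(sprintf("unwritable path: directory '%s' does not exist", dir),
         call. = FALSE)
  sep <- .delim_for(path)
  wl <- wavelengths(ds)
  mat <- t(intensities(ds))                      # spectra x wavelengths
  txt <- matrix(sprintf("%.17g", mat), nrow = nrow(mat))
  dt <- data.table::data.table(sample_id = sampleIds(ds))
  if (nrow(mat) == 0L) {
    # header-only file for an empty dataset
    header <- paste(c("sample_id", sprintf("%.17g", wl)), collapse = sep)
    writeLines(header, path)
  } else {
    wide <- data.table::as.data.table(txt)
    data.table::setnames(wide, sprintf("%.17g", wl))
    dt <- cbind(dt, wide)
    data.table::fwrite(dt, path, sep = sep, quote = FALSE)
  }
  man_path <- .manifest_path(path)
  man <- data.table::data.table(sample_id = sampleIds(ds),
                                class = as.character(classLabels(ds)),
                                tablet = tabletIds(ds),
                                shot_index = shotIndices(ds))
  data.table::fwrite(man, man_path, sep = sep, quote = FALSE)
  invisible(c(path, man_path))
}

.manifest_path <- function(path)
  sub("\\.([A-Za-z0-9]+)$", "_manifest.\\1", path)

#' Read spectra and a label manifest from delimited text
#'
#' Reads the wide spectra table written by [writeSpectra()] (or any
#' delimited table whose header row holds the wavelength grid and whose
#' first column holds spectrum ids), plus a manifest mapping ids to class,
#' tablet and shot index. `path` may also be a directory of such tables,
#' all of which must share an identical wavelength grid.
#'
#' @param path spectra file (or directory of files); `.csv` or `.tsv`.
#' @param manifest manifest file; defaults to the side-car name used by
#'   [writeSpectra()].
#' @param classNames optional explicit class-level order; default is order
#'   of first appearance in the manifest.
#' @return A [SpectralSet-class]; row order of the input is preserved.
#' @export
readSpectra <- function(path, manifest = NULL, classNames = NULL) {
  files <- if (dir.exists(path)) {
    f <- list.files(path, pattern = "\\.(csv|tsv|txt)$", full.names = TRUE)
    f[!grepl("_manifest\\.", f)]
  } else path
  if (!length(files) || !all(file.exists(files)))
    stop(sprintf("no spectra files found at '%s'", path), call. = FALSE)
  if (is.null(manifest)) manifest <- .manifest_path(files[[1L]])
  if (!file.exists(manifest))
    stop(sprintf("manifest '%s' does not exist", manifest), call. = FALSE)

  wl <- NULL
  ids <- character()
  mats <- list()
  for (f in files) {
    dt <- data.table::fread(f, sep = .delim_for(f), header = TRUE)
    this_wl <- suppressWarnings(as.numeric(colnames(dt)[-1L]))
    if (anyNA(this_wl))
      stop(sprintf("file '%s': header is not a numeric wavelength grid", f),
           call. = FALSE)
    if (length(this_wl) > 1L && any(diff(this_wl) <= 0))
      stop(sprintf("file '%s': wavelength grid is not strictly increasing", f),
           call. = FALSE)
    if (is.null(wl)) wl <- this_wl
    else if (!identical(wl, this_wl))
      stop(sprintf("file '%s': wavelength grid differs from '%s'",
                   f, files[[1L]]), call. = FALSE)
    if (nrow(dt)) {
      ids <- c(ids, as.character(dt[[1L]]))
      mats[[length(mats) + 1L]] <-
        t(as.matrix(dt[, -1L, with = FALSE]))
    }
  }
  man <- data.table::fread(manifest, sep = .delim_for(manifest), header = TRUE,
                           colClasses = list(character = "sample_id"))
  need <- c("sample_id", "class", "tablet", "shot_index")
  if (!all(need %in% colnames(man)))
    stop("manifest must have columns sample_id, class, tablet, shot_index",
         call. = FALSE)
  missing <- setdiff(ids, man$sample_id)
  if (length(missing))
    stop(sprintf("manifest is missing labels for: %s",
                 paste(head(missing, 5L), collapse = ", ")), call. = FALSE)
  inten <- if (length(mats)) do.call(cbind, mats) else
    matrix(numeric(), nrow = length(wl), ncol = 0L)
  ord <- match(ids, man$sample_id)
  if (is.null(classNames)) classNames <- unique(man$class)
  SpectralSet(inten, wl,
              classes = man$class[ord],
              tablets = as.character(man$tablet[ord]),
              sampleIds = ids,
              shotIndex = man$shot_index[ord],
              classNames = classNames)
}
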