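#' Reflectance spectra collections
#'
#' A `spectra` object holds one or more reflectance curves measured on a
#' common, strictly increasing wavelength grid (nm).  Reflectance is stored
#' as a fraction relative to a white standard, so values slightly above 1
#' are possible (glossy petals); negative values are clipped to 0 on read.
#'
#' @param wl numeric vector of wavelengths in nm, strictly increasing.
#' @param refl numeric matrix, one column per curve, `length(wl)` rows.
#' @param meta data.frame with one row per column of `refl`; must contain
#'   columns `id` and `species` (and optionally `replicate`, `n_reps`).
#' @return An object of class `spectra`.
#' @export
spectra <- function(wl, refl, meta = NULL) {
  refl <- as.matrix(refl)
  wl <- as.numeric(wl)
  if (nrow(refl) != length(wl))
    stop("wavelength and reflectance lengths differ")
  if (any(diff(wl) <= 0))
    stop("wavelengths must be strictly increasing")
  if (any(!is.finite(refl)))
    stop("non-finite reflectance values")
  if (any(refl < 0))
    stop("negative reflectance; clip before construction")
  if (is.null(colnames(refl)))
    colnames(refl) <- sprintf("spec%d", seq_len(ncol(refl)))
  if (is.null(meta))
    meta <- data.frame(id = colnames(refl), species = colnames(refl),
                       stringsAsFactors = FALSE)
  stopifnot(nrow(meta) == ncol(refl), all(c("id", "species") %in% names(meta)))
  structure(list(wl = wl, refl = refl, meta = meta), class = "spectra")
}

#' @export
print.spectra <- function(x, ...) {
  cat(sprintf("spectra: %d curve(s), %d species, %g-%g nm (%d points)\n",
              ncol(x$refl), length(unique(x$meta$species)),
              min(x$wl), max(x$wl), length(x$wl)))
  invisible(x)
}

#' @export
as.data.frame.spectra <- function(x, ...) {
  data.frame(wl = x$wl, x$refl, check.names = FALSE)
}

#' @export
`[.spectra` <- function(x, j) {
  if (is.character(j)) j <- match(j, colnames(x$refl))
  spectra(x$wl, x$refl[, j, drop = FALSE], x$meta[j, , drop = FALSE])
}

#' Number of curves in a spectra object
#' @param x a `spectra` object.
#' @export
n_spectra <- function(x) ncol(x$refl)

## --- reading -------------------------------------------------------------

default_dialect <- function() {
  list(format = "auto", wavelength = NULL, reflectance = NULL,
       species = NULL, replicate = NULL, sep = NULL, percent = "auto")
}

#' Read reflectance spectra from delimited text
#'
#' Accepts a single file or a directory of files.  Three layouts are
#' understood: two-column (wavelength, reflectance; one curve per file),
#' wide (wavelength column followed by one column per curve), and long
#' (wavelength, reflectance, species and optionally replicate columns).
#' Column names and layout can be forced through `dialect`, a list or a
#' YAML file with fields `format` ("two_column", "wide", "long"),
#' `wavelength`, `reflectance`, `species`, `replicate`, `sep` and
#' `percent`.
#'
#' Wavelengths given in descending order are sorted ascending; duplicated
#' wavelengths are an error (the offending row is named).  Negative
#' reflectance (instrument noise near the dark reference) is clipped to 0
#' with a warning stating how many values were affected.  Values above 1
#' are kept.  If the data look like percentages (maximum above 5) they are
#' rescaled to fractions unless `percent` says otherwise.
#'
#' @param path file or directory path.
#' @param dialect list or YAML file path describing the column mapping.
#' @return A [spectra] object; the attribute `clipped` records the number
#'   of negative values clipped, `outside_range` the number of rows
#'   outside 300-700 nm (rows are retained).
#' @export
read_spectra <- function(path, dialect = NULL) {
  d <- default_dialect()
  if (is.character(dialect)) dialect <- yaml::read_yaml(dialect)
  if (!is.null(dialect)) d[names(dialect)] <- dialect
  if (!file.exists(path)) stop("no such file or directory: ", path)
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(csv|tsv|txt)$", full.names = TRUE)
    if (!length(files)) stop("no delimited files found in ", path)
    parts <- lapply(files, read_spectra, dialect = d)
    return(bind_spectra(parts))
  }
  sep <- d$sep
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else if (grepl(";", first)) ";" else ","
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  num <- vapply(tab, is.numeric, logical(1))
  fmt <- d$format
  if (identical(fmt, "auto")) {
    fmt <- if (!is.null(d$species) && d$species %in% names(tab)) "long"
    else if (all(c("species") %in% names(tab))) "long"
    else if (sum(num) == 2 && ncol(tab) == 2) "two_column"
    else "wide"
  }
  wcol <- d$wavelength
  if (is.null(wcol)) {
    cand <- grep("^(wl|wave|wavelength|lambda|nm)$", names(tab),
                 ignore.case = TRUE, value = TRUE)
    wcol <- if (length(cand)) cand[1] else names(tab)[which(num)[1]]
  }
  if (!wcol %in% names(tab) || !is.numeric(tab[[wcol]]))
    stop("wavelength column '", wcol, "' missing or non-numeric in ", path)

  if (fmt == "long") {
    scol <- if (!is.null(d$species)) d$species else "species"
    rcol <- if (!is.null(d$replicate)) d$replicate else
      intersect(c("replicate", "rep", "flower"), names(tab))[1]
    vcol <- d$reflectance
    if (is.null(vcol)) {
      cand <- grep("^(refl|reflectance|value)", names(tab),
                   ignore.case = TRUE, value = TRUE)
      vcol <- if (length(cand)) cand[1] else
        setdiff(names(tab)[num], wcol)[1]
    }
    if (!all(c(scol, vcol) %in% names(tab)))
      stop("long format needs species and reflectance columns")
    rep_id <- if (!is.na(rcol) && !is.null(rcol)) as.character(tab[[rcol]]) else "1"
    id <- paste(tab[[scol]], rep_id, sep = "__")
    wls <- sort(unique(tab[[wcol]]))
    ids <- unique(id)
    refl <- matrix(NA_real_, length(wls), length(ids),
                   dimnames = list(NULL, ids))
    refl[cbind(match(tab[[wcol]], wls), match(id, ids))] <- tab[[vcol]]
    if (anyNA(refl)) stop("long-format spectra are not on a common grid")
    meta <- data.frame(id = ids,
                       species = sub("__[^_]*$", "", ids),
                       replicate = sub("^.*__", "", ids),
                       stringsAsFactors = FALSE)
    return(finish_read(wls, refl, meta, path))
  }

  ## two-column or wide
  wl <- tab[[wcol]]
  vals <- tab[, setdiff(names(tab)[num], wcol), drop = FALSE]
  if (ncol(vals) < 1) stop("need at least 2 numeric columns in ", path)
  if (fmt == "two_column") vals <- vals[, 1, drop = FALSE]
  m <- as.matrix(vals)
  base <- sub("\\.(csv|tsv|txt)$", "", basename(path))
  if (ncol(m) == 1 && fmt == "two_column") colnames(m) <- base
  sp <- sub("__[^_]*$", "", colnames(m))
  rep_lab <- ifelse(grepl("__", colnames(m)), sub("^.*__", "", colnames(m)), "1")
  meta <- data.frame(id = colnames(m), species = sp, replicate = rep_lab,
                     stringsAsFactors = FALSE)
  finish_read(wl, m, meta, path)
}

finish_read <- function(wl, refl, meta, path) {
  dup <- which(duplicated(wl))
  if (length(dup))
    stop("duplicated wavelength at row ", dup[1], " in ", path)
  o <- order(wl)
  wl <- wl[o]; refl <- refl[o, , drop = FALSE]
  percent_like <- max(refl, na.rm = TRUE) > 5
  if (percent_like) refl <- refl / 100
  nneg <- sum(refl < 0)
  if (nneg > 0) {
    warning(sprintf("clipped %d negative reflectance value(s) to 0", nneg))
    refl[refl < 0] <- 0
  }
  out <- spectra(wl, refl, meta)
  attr(out, "clipped") <- nneg
  attr(out, "outside_range") <- sum(wl < 300 | wl > 700)
  out
}

#' Combine spectra objects measured on identical grids
#' @param x list of `spectra` objects.
#' @export
bind_spectra <- function(x) {
  wl <- x[[1]]$wl
  for (s in x)
    if (!isTRUE(all.equal(s$wl, wl)))
      stop("spectra are on different grids; resample first")
  out <- spectra(wl, do.call(cbind, lapply(x, `[[`, "refl")),
                 do.call(rbind, lapply(x, `[[`, "meta")))
  attr(out, "clipped") <- sum(vapply(x, function(s)
    `%||%`(attr(s, "clipped"), 0L), numeric(1)))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## --- resampling and averaging -------------------------------------------

#' Resample spectra onto a wavelength grid
#'
#' Linear interpolation onto `grid`; grid points already present in the
#' data are reproduced exactly.  Requesting points outside the measured
#' span is an error (no extrapolation).
#'
#' @param x a `spectra` object.
#' @param grid target wavelengths in nm (default 300-700 at 1 nm).
#' @return A `spectra` object on `grid`.
#' @export
resample <- function(x, grid = 300:700) {
  stopifnot(inherits(x, "spectra"))
  if (min(grid) < min(x$wl) || max(grid) > max(x$wl))
    stop(sprintf("grid [%g, %g] outside measured span [%g, %g]; refusing to extrapolate",
                 min(grid), max(grid), min(x$wl), max(x$wl)))
  refl <- apply(x$refl, 2, function(y)
    stats::approx(x$wl, y, xout = grid, method = "linear")$y)
  refl <- matrix(refl, nrow = length(grid),
                 dimnames = list(NULL, colnames(x$refl)))
  spectra(grid, refl, x$meta)
}

#' Average replicate spectra within species
#'
#' Pointwise arithmetic mean of all replicates of each species, the
#' averaging order used throughout the pipeline (spectra are averaged
#' before visual modelling).  The replicate count is recorded in the
#' returned metadata.
#'
#' @param x a `spectra` object whose metadata carries a `species` column.
#' @return A `spectra` object with one curve per species.
#' @export
average_replicates <- function(x) {
  stopifnot(inherits(x, "spectra"))
  sp <- unique(x$meta$species)
  refl <- vapply(sp, function(s) {
    cols <- which(x$meta$species == s)
    rowMeans(x$refl[, cols, drop = FALSE])
  }, numeric(length(x$wl)))
  refl <- matrix(refl, nrow = length(x$wl), dimnames = list(NULL, sp))
  meta <- data.frame(id = sp, species = sp,
                     n_reps = as.integer(table(x$meta$species)[sp]),
                     stringsAsFactors = FALSE)
  spectra(x$wl, refl, meta)
}

#' Write spectra to CSV (wide layout: wl column then one column per curve)
#' @param x a `spectra` object.
#' @param path output file.
#' @export
write_spectra <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
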