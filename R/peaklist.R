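# CID peak-list container and readers/writers (two-column CSV and a minimal
# single-spectrum MGF dialect).

#' Construct a peak list
#'
#' @param mz,intensity numeric vectors of equal length; intensities must be
#'   non-negative. Peaks are stored in ascending m/z order.
#' @param precursor_mz optional precursor m/z.
#' @param metadata named list of acquisition metadata.
#' @return object of class \code{peaklist}.
#' @export
peaklist <- function(mz, intensity, precursor_mz = NA_real_, metadata = list()) {
  if (length(mz) != length(intensity)) stop("mz and intensity lengths differ")
  if (any(!is.finite(mz)) || any(!is.finite(intensity))) stop("non-finite peak values")
  if (any(intensity < 0)) stop("negative intensity")
  o <- order(mz)
  structure(list(
    peaks = data.frame(mz = mz[o], intensity = intensity[o]),
    precursor_mz = precursor_mz,
    metadata = metadata
  ), class = "peaklist")
}

#' @export
print.peaklist <- function(x, ...) {
  cat("<peaklist> ", nrow(x$peaks), " peaks",
      if (!is.na(x$precursor_mz)) paste0(", precursor m/z ", round(x$precursor_mz, 4)),
      "\n", sep = "")
  invisible(x)
}

#' Read a CID peak list
#'
#' Supports two-column CSV (\code{mz,intensity}, header optional) and a
#' standard MGF dialect with one spectrum per \code{BEGIN IONS} block
#' (\code{PEPMASS} becomes the precursor m/z). Malformed records are
#' reported with their line numbers.
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"csv"} or \code{"mgf"}.
#' @return a [peaklist()].
#' @export
read_peaklist <- function(path, format = c("auto", "csv", "mgf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mgf$", path, ignore.case = TRUE)) "mgf" else "csv"
  }
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(nzchar(trimws(lines)))) stop("empty peak-list file: ", path)
  if (format == "csv") .read_peaklist_csv(lines, path) else .read_peaklist_mgf(lines, path)
}

.read_peaklist_csv <- function(lines, path) {
  keep <- which(nzchar(trimws(lines)))
  first <- strsplit(trimws(lines[keep[1]]), "[,;\t]")[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  rows <- if (has_header) keep[-1] else keep
  if (!length(rows)) stop("no peaks in ", path)
  mz <- numeric(0); int <- numeric(0)
  for (ln in rows) {
    f <- strsplit(trimws(lines[ln]), "[,;\t]")[[1]]
    v <- suppressWarnings(as.numeric(f[1:2]))
    if (length(f) < 2L || any(is.na(v))) {
      stop("malformed peak record at line ", ln, " of ", path, ": ", lines[ln])
    }
    mz <- c(mz, v[1]); int <- c(int, v[2])
  }
  peaklist(mz, int, metadata = list(source = path, format = "csv"))
}

.read_peaklist_mgf <- function(lines, path) {
  begin <- which(trimws(lines) == "BEGIN IONS")
  end <- which(trimws(lines) == "END IONS")
  if (!length(begin) || !length(end) || end[1] < begin[1]) {
    stop("no BEGIN IONS/END IONS block in ", path)
  }
  block <- (begin[1] + 1L):(end[1] - 1L)
  prec <- NA_real_; meta <- list(source = path, format = "mgf")
  mz <- numeric(0); int <- numeric(0)
  for (ln in block) {
    l <- trimws(lines[ln])
    if (!nzchar(l)) next
    if (grepl("=", l, fixed = TRUE)) {
      kv <- strsplit(l, "=", fixed = TRUE)[[1]]
      key <- toupper(kv[1])
      if (key == "PEPMASS") {
        prec <- suppressWarnings(as.numeric(strsplit(kv[2], "[[:space:]]+")[[1]][1]))
      } else meta[[tolower(key)]] <- kv[2]
      next
    }
    f <- strsplit(l, "[[:space:]]+")[[1]]
    v <- suppressWarnings(as.numeric(f[1:2]))
    if (length(f) < 2L || any(is.na(v))) {
      stop("malformed peak record at line ", ln, " of ", path, ": ", lines[ln])
    }
    mz <- c(mz, v[1]); int <- c(int, v[2])
  }
  if (!length(mz)) stop("MGF block contains no peaks in ", path)
  peaklist(mz, int, precursor_mz = prec, metadata = meta)
}

#' Write a peak list
#'
#' \code{write_peaklist_csv()} writes the two-column CSV dialect;
#' \code{write_mgf()} writes a single-spectrum MGF block.
#'
#' @param pl a [peaklist()].
#' @param path output file.
#' @param title TITLE field for MGF output.
#' @return the path, invisibly.
#' @export
write_peaklist_csv <- function(pl, path) {
  utils::write.csv(pl$peaks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_peaklist_csv
#' @export
write_mgf <- function(pl, path, title = "spectrum") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("BEGIN IONS", con)
  writeLines(paste0("TITLE=", title), con)
  if (!is.na(pl$precursor_mz)) writeLines(paste0("PEPMASS=", format(pl$precursor_mz, digits = 10)), con)
  writeLines("CHARGE=1+", con)
  writeLines(sprintf("%.6f %.6f", pl$peaks$mz, pl$peaks$intensity), con)
  writeLines("END IONS", con)
  invisible(path)
}
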