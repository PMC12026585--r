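# Normaliz classic plain-format interchange.
#
# Input dialect (.in): row count, column count, integer rows, then an
# input-type keyword (default "integral_closure").  Output parsing (.out)
# keys on the section heading "N Hilbert basis elements".

#' Read and write cones in Normaliz plain format
#'
#' @param path file path.
#' @param cone a [rational_cone()].
#' @param type input-type keyword written after the matrix.
#' @return `read_normaliz()` returns a `rational_cone`; `write_normaliz()`
#'   returns `path` invisibly.  Write-then-read is the identity on the
#'   matrix content.
#' @examples
#' f <- tempfile(fileext = ".in")
#' write_normaliz(rational_cone(diag(3)), f)
#' read_normaliz(f)
#' @export
write_normaliz <- function(cone, path, type = "integral_closure") {
  stopifnot(inherits(cone, "rational_cone"))
  G <- cone$generators
  lines <- c(nrow(G), ncol(G),
             apply(G, 1, paste, collapse = " "),
             type)
  writeLines(as.character(lines), path)
  invisible(path)
}

.parse_int_line <- function(line, lineno, expected = NULL) {
  toks <- strsplit(trimws(line), "\\s+")[[1]]
  vals <- suppressWarnings(as.numeric(toks))
  if (length(vals) == 0L || any(is.na(vals)) || any(vals != round(vals))) {
    stop("parse error at line ", lineno, ": expected integers, got '",
         line, "'")
  }
  if (!is.null(expected) && length(vals) != expected) {
    stop("parse error at line ", lineno, ": expected ", expected,
         " entries, got ", length(vals))
  }
  vals
}

#' @rdname write_normaliz
#' @export
read_normaliz <- function(path) {
  raw <- readLines(path)
  keep <- which(nzchar(trimws(raw)))
  if (length(keep) < 3L) stop("parse error: file has fewer than 3 lines")
  nr <- .parse_int_line(raw[keep[1]], keep[1], expected = 1L)
  nc <- .parse_int_line(raw[keep[2]], keep[2], expected = 1L)
  if (nr < 1 || nc < 1) stop("parse error at line ", keep[1],
                             ": non-positive matrix dimensions")
  if (length(keep) < 2L + nr) {
    stop("parse error: header declares ", nr, " rows but only ",
         length(keep) - 2L, " remain")
  }
  rows <- t(vapply(seq_len(nr), function(i) {
    ln <- keep[2L + i]
    .parse_int_line(raw[ln], ln, expected = nc)
  }, numeric(nc)))
  if (nc == 1L) rows <- matrix(rows, ncol = 1L)
  rational_cone(rows)
}

#' Parse the Hilbert-basis block of a Normaliz output file
#'
#' Scans for the heading `"<N> Hilbert basis elements"` and reads the `N`
#' integer vectors that follow, so that a Normaliz run (when the external
#' binary is available) can be cross-validated against [hilbert_basis()].
#'
#' @param path a Normaliz `.out` file.
#' @param cone optional [rational_cone()] attached to the returned basis.
#' @return a `hilbert_basis` object (its `cone` may be `NULL` when unknown).
#' @export
parse_normaliz_output <- function(path, cone = NULL) {
  raw <- readLines(path)
  head_re <- "^\\s*(\\d+)\\s+Hilbert basis elements"
  hit <- grep(head_re, raw)
  if (length(hit) == 0L) {
    stop("parse error: no 'Hilbert basis elements' section in ", path)
  }
  hit <- hit[1]
  nel <- as.integer(sub("^\\s*(\\d+)\\s+Hilbert basis elements.*$", "\\1",
                        raw[hit]))
  body <- which(nzchar(trimws(raw)))
  body <- body[body > hit][seq_len(nel)]
  if (any(is.na(body))) {
    stop("parse error: Hilbert basis section at line ", hit,
         " declares ", nel, " elements but the file ends early")
  }
  first <- .parse_int_line(raw[body[1]], body[1])
  rows <- t(vapply(body, function(ln) {
    .parse_int_line(raw[ln], ln, expected = length(first))
  }, numeric(length(first))))
  if (length(first) == 1L) rows <- matrix(rows, ncol = 1L)
  structure(list(elements = .sort_rows(rows), cone = cone),
            class = "hilbert_basis")
}

#' Write a Hilbert basis as a Normaliz-like output block
#'
#' @param basis a [hilbert_basis()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hilbert_block <- function(basis, path) {
  stopifnot(inherits(basis, "hilbert_basis"))
  E <- basis$elements
  lines <- c(paste(nrow(E), "Hilbert basis elements:"),
             apply(E, 1, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' JSON export of a Hilbert basis
#'
#' Writes `{"elements": [[...]], "cone": [[...]]}`.
#'
#' @param basis a [hilbert_basis()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hilbert_json <- function(basis, path) {
  stopifnot(inherits(basis, "hilbert_basis"))
  doc <- list(elements = basis$elements,
              cone = if (!is.null(basis$cone)) basis$cone$generators)
  jsonlite::write_json(doc, path, digits = NA, matrix = "rowmajor")
  invisible(path)
}
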