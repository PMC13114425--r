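# Packaged datasets and plain-text sample I/O.

.uasrd_builtin <- list(
  # 30 tensile-strength measurements of polyester fibers (proportions
  # of maximum stress before failure), listed in ascending order
  "tensile-strength" = c(
    0.023, 0.032, 0.054, 0.069, 0.081, 0.094, 0.105, 0.127, 0.148, 0.169,
    0.188, 0.216, 0.255, 0.277, 0.311, 0.361, 0.376, 0.395, 0.432, 0.463,
    0.481, 0.519, 0.529, 0.567, 0.642, 0.674, 0.752, 0.823, 0.887, 0.926),
  # 21 computing times of P3 algorithms (normalised), as reported
  "p3-times" = c(
    0.853, 0.759, 0.874, 0.800, 0.716, 0.557, 0.503, 0.399, 0.334, 0.207,
    0.118, 0.097, 0.078, 0.067, 0.056, 0.044, 0.036, 0.026, 0.019, 0.014,
    0.010))

#' Built-in unit-interval datasets
#'
#' Two classical bounded-data examples used throughout the package
#' documentation and tests: `"tensile-strength"`, 30 observations of
#' the tensile strength of polyester fibers (the maximum stress
#' sustainable before failure), and `"p3-times"`, 21 measurements of
#' the computing times of P3 algorithms.  Both consist of values
#' strictly inside (0, 1).
#'
#' @param name dataset name.
#' @return Numeric vector of observations.
#' @examples
#' length(uasrd_data("tensile-strength"))  # 30
#' @export
uasrd_data <- function(name = c("tensile-strength", "p3-times")) {
  if (!is.character(name) || !(name[1L] %in% names(.uasrd_builtin)))
    stop("unknown dataset; available: ",
         paste(names(.uasrd_builtin), collapse = ", "))
  .uasrd_builtin[[name[1L]]]
}

#' Read and write unit-interval samples as plain text
#'
#' `read_unit_sample` reads one value per line (or a one-column CSV; a
#' non-numeric first line is treated as a header and skipped, and lines
#' starting with `#` are comments).  Every value must lie strictly
#' inside (0, 1); offending rows are reported by number.
#' `write_unit_sample` writes a sample one value per line, optionally
#' with a provenance comment header recording the generating shape,
#' sample size and seed, so that synthetic fixtures are reproducible
#' and self-describing.
#'
#' @param path file path.
#' @param x numeric sample in (0, 1).
#' @param zeta,seed optional provenance (generating shape and RNG seed)
#'   recorded in the header.
#' @return `read_unit_sample` the numeric vector;
#'   `write_unit_sample` the path, invisibly.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' write_unit_sample(ruasrd(5, 1), f, zeta = 1, seed = NULL)
#' read_unit_sample(f)
#' @export
read_unit_sample <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty file: ", path)
  vals <- suppressWarnings(as.numeric(sub(",.*$", "", lines)))
  if (is.na(vals[1L]) && length(lines) > 1L) {  # header line
    lines <- lines[-1L]
    vals <- suppressWarnings(as.numeric(sub(",.*$", "", lines)))
  }
  bad <- which(is.na(vals))
  if (length(bad))
    stop("non-numeric rows: ", paste(utils::head(bad, 5L), collapse = ", "))
  out_of_range <- which(vals <= 0 | vals >= 1)
  if (length(out_of_range))
    stop("values outside (0, 1) at rows: ",
         paste(utils::head(out_of_range, 5L), collapse = ", "))
  vals
}

#' @rdname read_unit_sample
#' @export
write_unit_sample <- function(x, path, zeta = NULL, seed = NULL) {
  check_unit_interior(x, "x")
  hdr <- c(sprintf("# unit-interval sample, n = %d", length(x)),
           if (!is.null(zeta)) sprintf("# zeta = %.15g", zeta),
           if (!is.null(seed)) sprintf("# seed = %d", seed))
  writeLines(c(hdr, format(x, digits = 15, trim = TRUE, scientific = FALSE)),
             path)
  invisible(path)
}

#' Generate a reproducible synthetic sample fixture
#'
#' Draws `n` inverse-transform variates under `seed` and writes them
#' with a provenance header via [write_unit_sample()].
#'
#' @param zeta positive shape.
#' @param n sample size.
#' @param seed RNG seed.
#' @param path output file.
#' @return The path, invisibly.
#' @export
generate_fixture <- function(zeta, n, seed, path) {
  set.seed(seed)
  write_unit_sample(ruasrd(n, zeta), path, zeta = zeta, seed = seed)
}
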