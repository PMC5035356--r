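#' Rewrite the MASS block of an AMBER prmtop file
#'
#' Applies a uniform mass scaling to the `%FLAG MASS` section of an AMBER
#' topology file and writes the result to `path_out`.  Every byte outside the
#' MASS value lines is preserved verbatim; the scaled values are re-emitted
#' in the FORTRAN edit descriptor declared by the section's `%FORMAT` line
#' (normally `5E16.8`).  No derived section is renormalised: uniform scaling
#' leaves pointers and parameters valid.
#'
#' @param path_in path to an existing prmtop file.
#' @param spec a [mass_scale_spec()] or bare positive factor.
#' @param path_out output path (may equal `path_in` only at your own risk).
#' @return Invisibly, a report list: `n_masses`, `factor`, `lines_changed`
#'   (indices of rewritten lines).
#' @export
rewrite_prmtop_masses <- function(path_in, spec, path_out) {
  if (is.numeric(spec)) spec <- mass_scale_spec(spec)
  if (!file.exists(path_in)) stop("prmtop file not found: ", path_in)
  lines <- readLines(path_in, warn = FALSE)

  flag_idx <- grep("^%FLAG\\s+MASS\\s*$", lines)
  if (length(flag_idx) == 0L) stop("no %FLAG MASS section in ", path_in)
  flag_idx <- flag_idx[1L]
  if (flag_idx + 1L > length(lines) ||
      !grepl("^%FORMAT\\(", lines[flag_idx + 1L])) {
    stop("%FLAG MASS is not followed by a %FORMAT line")
  }
  fmt <- regmatches(lines[flag_idx + 1L],
                    regexec("^%FORMAT\\(\\s*(\\d+)[eE](\\d+)\\.(\\d+)\\s*\\)",
                            lines[flag_idx + 1L]))[[1L]]
  if (length(fmt) != 4L) {
    stop("unsupported MASS %FORMAT descriptor: ", lines[flag_idx + 1L])
  }
  per_line <- as.integer(fmt[2L])
  width <- as.integer(fmt[3L])
  digits <- as.integer(fmt[4L])

  first <- flag_idx + 2L
  last <- first - 1L
  while (last + 1L <= length(lines) && !grepl("^%", lines[last + 1L])) {
    last <- last + 1L
  }
  if (last < first) stop("MASS section contains no value lines")

  masses <- as.numeric(unlist(lapply(lines[first:last], function(l) {
    strsplit(trimws(l), "\\s+")[[1L]]
  })))
  if (any(is.na(masses))) stop("non-numeric value in MASS section")
  scaled <- scale_masses(masses, spec)

  cfmt <- sprintf("%%%d.%dE", width, digits)
  vals <- sprintf(cfmt, scaled)
  rows <- split(vals, (seq_along(vals) - 1L) %/% per_line)
  new_lines <- vapply(rows, paste0, character(1L), collapse = "")
  lines <- append(lines[-(first:last)], new_lines, after = first - 1L)

  con <- file(path_out, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(list(n_masses = length(masses), factor = spec$factor,
                 lines_changed = seq(first, first + length(new_lines) - 1L)))
}
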