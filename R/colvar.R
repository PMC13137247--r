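#' Collective-variable trajectory
#'
#' A data frame of per-frame collective variables (named columns such as
#' `d1`, `d0`, `h0`, `h1`, `s0`, `chi2`, `d_COM`, `psi1..psiN`) with a
#' `time` column and, for biased runs, a `metad.bias` column holding the
#' instantaneous bias energy. Metadata (temperature, Hamiltonian scaling
#' lambda, system label, seed) is carried in attributes.
#'
#' @param df data frame of frames; all columns must be equal-length finite
#'   numerics.
#' @param temperature K.
#' @param lambda Hamiltonian scaling of the generating replica (1 =
#'   unscaled).
#' @param system free-form system label ("aPET", "cPET", "toy", ...).
#' @param seed RNG seed of the generating run, if any.
#' @param extra named list of additional metadata.
#' @param subclass optional extra S3 class (e.g. "torsion_trajectory").
#' @return The data frame with class `cv_trajectory`.
#' @export
cv_trajectory <- function(df, temperature = 300, lambda = 1,
                          system = "unknown", seed = NULL, extra = list(),
                          subclass = NULL) {
  stopifnot(is.data.frame(df))
  num <- vapply(df, is.numeric, logical(1))
  if (!all(num)) stop("all trajectory columns must be numeric")
  if (nrow(df) > 0 && !all(vapply(df, function(x) all(is.finite(x)), logical(1))))
    stop("non-finite values in trajectory")
  attr(df, "temperature") <- temperature
  attr(df, "lambda") <- lambda
  attr(df, "system") <- system
  attr(df, "seed") <- seed
  for (nm in names(extra)) attr(df, nm) <- extra[[nm]]
  class(df) <- unique(c(subclass, "cv_trajectory", "data.frame"))
  df
}

#' Read a COLVAR-dialect table
#'
#' Reads the whitespace-delimited table format written by metadynamics
#' engines: a first line `#! FIELDS <name> <name> ...` declaring the
#' columns, optional further `#!` metadata lines, then one row of numbers
#' per frame. Ragged or non-numeric rows are reported with their line
#' number.
#'
#' @param path file to read.
#' @param as_trajectory return a [cv_trajectory()] (default) or a bare data
#'   frame.
#' @param temperature,system metadata attached when `as_trajectory` is TRUE.
#' @return A data frame with one named column per declared field.
#' @export
read_colvar <- function(path, as_trajectory = TRUE, temperature = 300,
                        system = "unknown") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) == 0 || !grepl("^#!\\s*FIELDS\\s+", lines[1]))
    stop("missing '#! FIELDS' header in ", path)
  fields <- strsplit(sub("^#!\\s*FIELDS\\s+", "", lines[1]), "\\s+")[[1]]
  body_idx <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  rows <- strsplit(trimws(lines[body_idx]), "\\s+")
  n_bad <- which(lengths(rows) != length(fields))
  if (length(n_bad) > 0)
    stop("ragged row at line ", body_idx[n_bad[1]], ": expected ",
         length(fields), " cells, found ", lengths(rows)[n_bad[1]])
  if (length(body_idx) == 0) {
    df <- as.data.frame(matrix(numeric(0), 0, length(fields)))
  } else {
    vals <- suppressWarnings(
      t(vapply(rows, as.numeric, numeric(length(fields)))))
    if (length(fields) == 1L) vals <- t(vals)
    if (anyNA(vals))
      stop("non-numeric cell at line ", body_idx[which(apply(vals, 1, anyNA))[1]])
    df <- as.data.frame(vals)
  }
  names(df) <- fields
  if (as_trajectory) cv_trajectory(df, temperature = temperature,
                                   system = system) else df
}

#' Write a COLVAR-dialect table
#'
#' Writes a data frame (typically a [cv_trajectory()] or an FES profile)
#' with a `#! FIELDS` header. Values are printed with 15 significant
#' digits, so a write/read round trip is value-identical.
#'
#' @param df data frame of numeric columns.
#' @param path output file.
#' @param digits significant digits to print.
#' @return `path`, invisibly.
#' @export
write_colvar <- function(df, path, digits = 15) {
  stopifnot(is.data.frame(df))
  fmt <- paste0("%.", digits, "g")
  header <- paste("#! FIELDS", paste(names(df), collapse = " "))
  body <- if (nrow(df) > 0)
    apply(as.matrix(df), 1, function(r) paste(sprintf(fmt, r), collapse = " "))
  else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}
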