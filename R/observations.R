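#' Read and write observation datasets
#'
#' An observation dataset is a data.frame with one behavioral
#' observation per row and one column per scheme variable, cells holding
#' state labels (missing values allowed).  On disk it is a plain CSV
#' with a header row; empty cells and the token `NA` denote missing.
#'
#' Reading validates every cell against the scheme (labels are matched
#' case-insensitively after trimming and stored in canonical spelling);
#' an invalid label or unknown column is an error reporting the row
#' concerned.  Writing then reading a dataset reproduces it
#' record-for-record.
#'
#' @param path file path of the CSV.
#' @param scheme a [variable_scheme()]; default [default_scheme()].
#' @return `read_observations()` returns a data.frame of class
#'   `c("observations", "data.frame")` with the scheme attached as
#'   attribute `"scheme"`.
#' @export
read_observations <- function(path, scheme = default_scheme()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                 na.strings = c("", "NA"), colClasses = "character")
  as_observations(df, scheme)
}

#' @rdname read_observations
#' @param data a data.frame of state labels (columns named by scheme
#'   variables).
#' @export
as_observations <- function(data, scheme = default_scheme()) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  unknown <- setdiff(names(data), names(scheme$variables))
  if (length(unknown))
    stop("unknown column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (nm in names(data)) {
    states <- scheme_states(scheme, nm)
    idx <- match_states(data[[nm]], states)
    bad <- attr(idx, "bad")
    if (length(bad))
      stop("invalid state '", data[[nm]][bad[1]], "' for variable '", nm,
           "' at row ", bad[1], call. = FALSE)
    data[[nm]] <- states[idx]
  }
  structure(data, scheme = scheme,
            class = c("observations", "data.frame"))
}

#' @rdname read_observations
#' @param data an observation dataset (data.frame of state labels).
#' @export
write_observations <- function(data, path) {
  write.csv(as.data.frame(data), path, row.names = FALSE, na = "")
  invisible(path)
}

# Encode an observation data.frame as an integer state matrix
# (n x #columns), NA preserved; columns restricted to scheme variables.
encode_observations <- function(data, scheme) {
  data <- as.data.frame(data)
  unknown <- setdiff(names(data), names(scheme$variables))
  if (length(unknown))
    stop("unknown column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  vars <- intersect(names(scheme$variables), names(data))
  m <- matrix(NA_integer_, nrow(data), length(vars),
              dimnames = list(NULL, vars))
  for (nm in vars) {
    idx <- match_states(data[[nm]], scheme_states(scheme, nm))
    bad <- attr(idx, "bad")
    if (length(bad))
      stop("invalid state '", data[[nm]][bad[1]], "' for variable '", nm,
           "' at row ", bad[1], call. = FALSE)
    m[, nm] <- as.integer(idx)
  }
  m
}

# Decode an integer state matrix back into an observations data.frame.
decode_observations <- function(m, scheme) {
  out <- as.data.frame(lapply(colnames(m), function(nm)
    scheme_states(scheme, nm)[m[, nm]]), stringsAsFactors = FALSE)
  names(out) <- colnames(m)
  structure(out, scheme = scheme, class = c("observations", "data.frame"))
}
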