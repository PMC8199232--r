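# Spectral table I/O. CSV (RFC-4180, dot decimal) is the sole interchange
# format; provenance (seed, config hash) travels in "#"-prefixed comment
# lines above the header.

#' Read and validate a spectral CSV table
#'
#' Expects a header row; column names are normalized to lower case. The
#' wavelength column must be strictly increasing with no duplicates, and
#' any R/T-like column (`m_r`, `m_t`, `r_diffuse`, `r_specular`, `t`,
#' `value`, `reflectance`, `transmittance`) must contain finite values
#' in \[0, 1\]. Lines starting with `#` are provenance comments and are
#' skipped (and returned in the `provenance` attribute).
#'
#' @param path Path to a CSV file.
#' @return Data frame with normalized column names; attribute
#'   `provenance` holds any comment lines.
#' @export
read_spectrum_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  prov <- grep("^#", lines, value = TRUE)
  tab <- tryCatch(
    utils::read.csv(text = lines[!grepl("^#", lines)],
                    stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  names(tab) <- tolower(names(tab))
  if (!"wavelength_nm" %in% names(tab))
    stop("missing required column wavelength_nm in ", path, call. = FALSE)
  wl <- tab$wavelength_nm
  if (any(!is.finite(wl)))
    stop("non-numeric wavelength at row ",
         which(!is.finite(wl))[1], call. = FALSE)
  dup <- which(duplicated(wl))
  if (length(dup))
    stop("duplicate wavelength ", wl[dup[1]], " nm at row ", dup[1],
         call. = FALSE)
  if (any(diff(wl) <= 0))
    stop("wavelengths not strictly increasing at row ",
         which(diff(wl) <= 0)[1] + 1L, call. = FALSE)
  rt_cols <- intersect(c("m_r", "m_t", "r_diffuse", "r_specular", "t",
                         "value", "reflectance", "transmittance"),
                       names(tab))
  for (cn in rt_cols) {
    v <- tab[[cn]]
    bad <- which(!is.finite(v) | v < 0 | v > 1)
    if (length(bad))
      stop("column ", cn, " outside [0, 1] at row ", bad[1],
           " (value ", v[bad[1]], ")", call. = FALSE)
  }
  attr(tab, "provenance") <- prov
  tab
}

#' Write a spectral table with provenance comments
#'
#' @param tab Data frame including a `wavelength_nm` column.
#' @param path Output path.
#' @param config Optional object whose JSON serialization is hashed
#'   (md5) into the provenance header.
#' @param seed Optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(tab, path, config = NULL, seed = NULL) {
  hdr <- c(sprintf("# drsdepth %s",
                   as.character(utils::packageVersion("drsdepth"))))
  if (!is.null(config)) hdr <- c(hdr, paste0("# config_hash=",
                                             config_hash(config)))
  if (!is.null(seed)) hdr <- c(hdr, paste0("# seed=", format(seed)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

# md5 of the canonical JSON serialization of an arbitrary config object.
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tf))
}
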