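#' Frequency band definitions
#'
#' EPG band power is computed over named frequency intervals borrowed from
#' EEG practice. `default_bands()` returns the seven conventional bands:
#' low (0--0.5 Hz), delta (0.5--4), theta (4--8), mu (9--11), alpha (8--13),
#' beta (13--30) and gamma (20--100 Hz). Bands may overlap (mu lies inside
#' alpha; beta and gamma share 20--30 Hz) and are always analysed
#' independently, never merged.
#'
#' @return A tibble with columns `name`, `f_lo_hz`, `f_hi_hz`.
#' @examples
#' default_bands()
#' @export
default_bands <- function() {
  tibble(
    name    = c("low", "delta", "theta", "mu", "alpha", "beta", "gamma"),
    f_lo_hz = c(0,     0.5,     4,       9,    8,       13,     20),
    f_hi_hz = c(0.5,   4,       8,       11,   13,      30,     100)
  )
}

#' Read band definitions from JSON
#'
#' The file must hold a JSON array of objects with fields `name`, `f_lo_hz`
#' and `f_hi_hz`. Order and case are preserved; overlapping bands are legal.
#' With `path = NULL` the seven default bands are returned.
#'
#' @param path Path to a bands JSON file, or `NULL` for [default_bands()].
#' @return A validated tibble of band definitions.
#' @export
read_bands <- function(path = NULL) {
  if (is.null(path)) return(default_bands())
  if (!file.exists(path)) {
    stop_electrome(sprintf("bands file not found: %s", path), "missing_file")
  }
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (!is.data.frame(raw) || !all(c("name", "f_lo_hz", "f_hi_hz") %in% names(raw))) {
    stop_electrome("bands JSON must be an array of {name, f_lo_hz, f_hi_hz} objects",
                   "bad_bands")
  }
  bands <- as_tibble(raw)[, c("name", "f_lo_hz", "f_hi_hz")]
  validate_bands(bands)
}

#' Validate a band definition table
#'
#' Checks that every band has a non-negative lower edge strictly below its
#' upper edge and that names are unique (case-sensitive).
#'
#' @param bands A data frame with columns `name`, `f_lo_hz`, `f_hi_hz`.
#' @return The bands as a tibble, invisibly usable downstream.
#' @export
validate_bands <- function(bands) {
  if (!is.data.frame(bands) || !all(c("name", "f_lo_hz", "f_hi_hz") %in% names(bands))) {
    stop_electrome("`bands` must be a data frame with columns name, f_lo_hz, f_hi_hz",
                   "bad_bands")
  }
  bands <- as_tibble(bands)
  if (nrow(bands) == 0L) stop_electrome("`bands` has no rows", "bad_bands")
  if (any(!is.finite(bands$f_lo_hz)) || any(!is.finite(bands$f_hi_hz))) {
    stop_electrome("band edges must be finite", "bad_bands")
  }
  if (any(bands$f_lo_hz < 0)) {
    stop_electrome("band edges must be non-negative", "bad_bands")
  }
  bad <- bands$f_lo_hz >= bands$f_hi_hz
  if (any(bad)) {
    stop_electrome(sprintf("band `%s` has an empty interval (f_lo >= f_hi)",
                           bands$name[which(bad)[1]]), "bad_bands")
  }
  if (anyDuplicated(bands$name)) {
    stop_electrome(sprintf("duplicate band name `%s`",
                           bands$name[duplicated(bands$name)][1]), "bad_bands")
  }
  bands
}

# Coerce a one-row data frame / named list to a band record.
as_band <- function(band) {
  if (is.data.frame(band)) {
    if (nrow(band) != 1L) stop_electrome("expected a single band", "bad_bands")
    band <- as.list(band)
  }
  if (!all(c("name", "f_lo_hz", "f_hi_hz") %in% names(band))) {
    stop_electrome("a band needs fields name, f_lo_hz, f_hi_hz", "bad_bands")
  }
  validate_bands(tibble(name = band$name, f_lo_hz = band$f_lo_hz,
                        f_hi_hz = band$f_hi_hz))
}
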