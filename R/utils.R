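# Internal helpers: calendar-month arithmetic on "YYYY-MM" strings and
# scoped seeding. Months are kept as strings throughout because that is the
# Google Trends export dialect; arithmetic goes through a linear month index.

#' @keywords internal
ym_to_index <- function(ym) {
  ok <- grepl("^\\d{4}-(0[1-9]|1[0-2])$", ym)
  if (!all(ok)) {
    stop("malformed month string(s): ", paste(ym[!ok], collapse = ", "),
         " (expected 'YYYY-MM')", call. = FALSE)
  }
  y <- as.integer(substr(ym, 1, 4))
  m <- as.integer(substr(ym, 6, 7))
  y * 12L + (m - 1L)
}

#' @keywords internal
index_to_ym <- function(idx) {
  sprintf("%04d-%02d", idx %/% 12L, idx %% 12L + 1L)
}

#' Sequence of consecutive calendar months
#'
#' @param start,end months as `"YYYY-MM"` strings, inclusive.
#' @return character vector of consecutive months.
#' @examples
#' month_seq("2004-01", "2004-04")
#' @export
month_seq <- function(start, end) {
  a <- ym_to_index(start)
  b <- ym_to_index(end)
  if (b < a) stop("end month precedes start month", call. = FALSE)
  index_to_ym(seq.int(a, b))
}

#' @keywords internal
month_of <- function(ym) as.integer(substr(ym, 6, 7))

MONTH_NAMES <- c("January", "February", "March", "April", "May", "June",
                 "July", "August", "September", "October", "November",
                 "December")

# Run code with a temporary RNG seed, restoring the caller's RNG state.
# Mersenne-Twister has pure integer state, so seeded draws are bit-identical
# across platforms.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  code
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
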