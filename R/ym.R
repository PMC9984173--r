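#' Year-month index helpers
#'
#' Months are represented throughout the package as an integer index
#' `year * 12 + (month - 1)`, so that arithmetic on months is plain integer
#' arithmetic (e.g. `ym(2016, 1) - 3` is October 2015).
#'
#' @param year integer year(s)
#' @param month integer month(s) in 1..12
#' @return integer month index
#' @examples
#' ym(2016, 1) - ym(2015, 10)  # 3 months apart
#' @export
ym <- function(year, month) {
  stopifnot(all(month >= 1 & month <= 12))
  as.integer(year) * 12L + (as.integer(month) - 1L)
}

#' @rdname ym
#' @param x integer month index
#' @export
ym_year <- function(x) as.integer(x) %/% 12L

#' @rdname ym
#' @export
ym_month <- function(x) as.integer(x) %% 12L + 1L

#' @rdname ym
#' @export
ym_format <- function(x) sprintf("%04d-%02d", ym_year(x), ym_month(x))

#' @rdname ym
#' @param s character "YYYY-MM"
#' @export
ym_parse <- function(s) {
  m <- regmatches(s, regexec("^([0-9]{4})-([0-9]{2})$", s))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("invalid year-month string(s): ", paste(s[bad], collapse = ", "))
  vapply(m, function(p) ym(as.integer(p[2]), as.integer(p[3])), integer(1))
}
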