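#' Parse a molecular formula into element counts
#'
#' Accepts Hill-order (or any-order) formulas such as `"C5H13CuN2O5"`.
#' Charge is never part of the formula string; it is tracked separately.
#' The sentinel values `""`, `"-"` and `"."` denote an empty composition
#' (used for the electron pseudo-species).
#'
#' @param formula character scalar.
#' @return named integer vector of element counts (possibly empty).
#' @examples
#' parse_formula("C3H4N2")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  formula <- trimws(formula)
  if (formula %in% c("", "-", ".")) {
    return(stats::setNames(integer(0), character(0)))
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula, perl = TRUE)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (!length(tokens) || sum(attr(m, "match.length")) != nchar(formula)) {
    stop("cannot parse formula: '", formula, "'")
  }
  elems <- sub("[0-9]+$", "", tokens)
  counts <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                              sub("^[A-Za-z]+", "", tokens), "1"))
  out <- tapply(counts, elems, sum)
  stats::setNames(as.integer(out), names(out))
}

#' Format element counts as a Hill-order formula string
#'
#' Carbon first, then hydrogen, then the remaining elements alphabetically
#' (plain alphabetical when no carbon is present).
#'
#' @param composition named integer vector of element counts.
#' @return character scalar ("-" for an empty composition).
#' @export
format_formula <- function(composition) {
  composition <- composition[composition != 0]
  if (!length(composition)) return("-")
  elems <- names(composition)
  if ("C" %in% elems) {
    ord <- c(intersect(c("C", "H"), elems), sort(setdiff(elems, c("C", "H"))))
  } else {
    ord <- sort(elems)
  }
  paste0(vapply(ord, function(e) {
    n <- composition[[e]]
    if (n == 1L) e else paste0(e, n)
  }, character(1)), collapse = "")
}

# Sum two element-count vectors (names may differ).
add_compositions <- function(a, b, sign = 1L) {
  elems <- union(names(a), names(b))
  out <- stats::setNames(integer(length(elems)), elems)
  out[names(a)] <- out[names(a)] + as.integer(a)
  out[names(b)] <- out[names(b)] + sign * as.integer(b)
  out[out != 0L]
}

# Normalize unicode minus (U+2212) and thin spaces to ASCII so numeric
# columns copied from typeset tables parse cleanly.
normalize_minus <- function(x) {
  x <- gsub("\u2212", "-", x)
  gsub("[\u00a0\u2009\u202f]", "", x)
}
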