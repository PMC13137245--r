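#' Monoisotopic element masses
#'
#' CODATA/IUPAC monoisotopic masses (Da) for the elements handled by the
#' package, the heavy-oxygen isotope \code{O18}, and the electron mass used
#' when converting a neutral mass to a cation m/z.
#'
#' @format Named numeric vector with elements \code{H, C, N, O, O18, Na} and
#'   \code{electron}.
#' @export
element_masses <- c(
  H  = 1.0078250319,
  C  = 12.0,
  N  = 14.0030740052,
  O  = 15.9949146221,
  O18 = 17.9991604,
  Na = 22.98976928,
  electron = 0.0005485799
)

.comp_elements <- c("C", "H", "N", "O", "O18", "Na")

#' Elemental composition vectors
#'
#' A composition is a named integer vector over \code{C,H,N,O,O18,Na}.
#' \code{comp()} builds one, \code{comp_add()}/\code{comp_sub()} combine them,
#' \code{comp_mass()} returns the monoisotopic mass and
#' \code{comp_formula()} a compact formula string (18O written \code{[18O]}).
#'
#' @param C,H,N,O,O18,Na atom counts.
#' @return \code{comp()}, \code{comp_add()}, \code{comp_sub()}: a composition
#'   vector; \code{comp_mass()}: numeric Da; \code{comp_formula()}: character.
#' @examples
#' comp_mass(comp(C = 6, H = 12, O = 6))  # 180.0634
#' @export
comp <- function(C = 0, H = 0, N = 0, O = 0, O18 = 0, Na = 0) {
  x <- c(C = C, H = H, N = N, O = O, O18 = O18, Na = Na)
  storage.mode(x) <- "double"
  x
}

#' @rdname comp
#' @param a,b compositions.
#' @export
comp_add <- function(a, b) {
  a[.comp_elements] <- a[.comp_elements] + b[.comp_elements]
  a
}

#' @rdname comp
#' @export
comp_sub <- function(a, b) {
  a[.comp_elements] <- a[.comp_elements] - b[.comp_elements]
  if (any(a < 0)) stop("negative atom count in composition difference")
  a
}

#' @rdname comp
#' @param x a composition.
#' @export
comp_mass <- function(x) {
  sum(x[.comp_elements] * element_masses[.comp_elements])
}

#' @rdname comp
#' @export
comp_formula <- function(x) {
  lab <- c(C = "C", H = "H", N = "N", O = "O", O18 = "[18O]", Na = "Na")
  parts <- character(0)
  for (el in .comp_elements) {
    n <- x[[el]]
    if (n > 0) parts <- c(parts, paste0(lab[[el]], if (n > 1) n else ""))
  }
  if (!length(parts)) "" else paste(parts, collapse = "")
}

# scale a composition by an integer multiplier
comp_times <- function(x, k) {
  x[.comp_elements] <- x[.comp_elements] * k
  x
}

.comp_h2o <- function() comp(H = 2, O = 1)
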