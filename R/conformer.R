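# Conformer-ensemble container, geometric descriptors (Cremer-Pople ring
# puckering, Na-O coordination number, USR shape moments) and the
# reactant-candidate selection procedure.

#' Construct a conformer ensemble
#'
#' @param elements character vector of element symbols (shared across
#'   frames).
#' @param coords list of numeric n-by-3 coordinate matrices (Angstrom).
#' @param energy numeric vector of relative energies (kJ/mol), one per
#'   frame.
#' @return object of class \code{conformer_ensemble}.
#' @export
conformer_ensemble <- function(elements, coords, energy) {
  n <- length(elements)
  if (length(coords) != length(energy)) stop("coords and energy lengths differ")
  for (m in coords) {
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != 3) {
      stop("every frame must be an n-by-3 matrix with constant atom count")
    }
  }
  if (any(!is.finite(energy))) stop("energies must be finite")
  structure(list(elements = elements, coords = coords, energy = energy),
            class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat("<conformer_ensemble> ", length(x$coords), " conformers, ",
      length(x$elements), " atoms\n", sep = "")
  invisible(x)
}

#' @export
length.conformer_ensemble <- function(x) length(x$coords)

#' Read / write multi-frame XYZ with energies
#'
#' Standard multi-frame XYZ: atom-count line, comment line carrying
#' \code{E=<kJ/mol>}, then one \code{element x y z} line per atom.
#'
#' @param path file path.
#' @return \code{read_xyz()}: a [conformer_ensemble()].
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  i <- 1L
  elements <- NULL; coords <- list(); energy <- numeric(0)
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) stop("malformed atom-count line ", i, " in ", path)
    comment <- lines[i + 1L]
    em <- regmatches(comment, regexpr("E=\\s*[-+0-9.eE]+", comment))
    e <- if (length(em)) as.numeric(sub("E=\\s*", "", em)) else NA_real_
    block <- lines[(i + 2L):(i + 1L + nat)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    el <- vapply(parts, `[[`, character(1), 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(!is.finite(xyz))) stop("malformed coordinates near line ", i, " in ", path)
    if (is.null(elements)) elements <- el
    else if (!identical(elements, el)) stop("atom ordering changes between frames in ", path)
    coords[[length(coords) + 1L]] <- xyz
    energy <- c(energy, e)
    i <- i + 2L + nat
  }
  if (anyNA(energy)) stop("missing E=<kJ/mol> in a comment line of ", path)
  conformer_ensemble(elements, coords, energy)
}

#' @rdname read_xyz
#' @param ens a [conformer_ensemble()].
#' @export
write_xyz <- function(ens, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- length(ens$elements)
  for (f in seq_along(ens$coords)) {
    writeLines(as.character(n), con)
    writeLines(sprintf("E=%.6f", ens$energy[f]), con)
    m <- ens$coords[[f]]
    writeLines(sprintf("%-3s %14.8f %14.8f %14.8f",
                       ens$elements, m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

# --- descriptors -----------------------------------------------------------

#' Cremer-Pople puckering coordinates of a six-membered ring
#'
#' Ring atoms must be supplied in the conventional order O5, C1, C2, C3,
#' C4, C5. Returns the total puckering amplitude Q and the spherical-polar
#' angles theta/phi in the standard Cremer-Pople phase convention (theta 0
#' or 180 degrees for ideal chairs). Invariant under rigid motion.
#'
#' @param ring_coords 6-by-3 matrix of Cartesian coordinates (Angstrom).
#' @return named numeric vector \code{c(q, theta, phi)} (Angstrom, degrees,
#'   degrees).
#' @export
puckering <- function(ring_coords) {
  if (!is.matrix(ring_coords) || nrow(ring_coords) != 6 || ncol(ring_coords) != 3) {
    stop("ring_coords must be a 6x3 matrix")
  }
  r <- sweep(ring_coords, 2, colMeans(ring_coords))
  j <- 0:5
  R1 <- colSums(r * sin(2 * pi * j / 6))
  R2 <- colSums(r * cos(2 * pi * j / 6))
  nvec <- c(R1[2] * R2[3] - R1[3] * R2[2],
            R1[3] * R2[1] - R1[1] * R2[3],
            R1[1] * R2[2] - R1[2] * R2[1])
  nn <- sqrt(sum(nvec^2))
  if (nn < 1e-12) stop("degenerate (collinear) ring geometry")
  nvec <- nvec / nn
  z <- as.numeric(r %*% nvec)
  q2c <- sqrt(2 / 6) * sum(z * cos(4 * pi * j / 6))
  q2s <- -sqrt(2 / 6) * sum(z * sin(4 * pi * j / 6))
  q3 <- sqrt(1 / 6) * sum(z * (-1)^j)
  Q <- sqrt(sum(z^2))
  if (Q < 1e-10) return(c(q = 0, theta = 0, phi = 0))
  theta <- acos(max(-1, min(1, q3 / Q))) * 180 / pi
  phi <- atan2(q2s, q2c) * 180 / pi
  if (phi < 0) phi <- phi + 360
  c(q = Q, theta = theta, phi = phi)
}

#' Sodium-oxygen coordination number
#'
#' Rational switching function summed over oxygen positions:
#' sum (1-(r/r0)^n) / (1-(r/r0)^m), continuous at r = r0 where the limit is
#' n/m. The functional form and its defaults (r0 = 2.5 A, n = 6, m = 12)
#' are package defaults, not literature-fitted values.
#'
#' @param na_pos numeric length-3 sodium position.
#' @param o_positions k-by-3 matrix of oxygen positions.
#' @param r0 switching radius (Angstrom), > 0.
#' @param n,m integer exponents, m > n.
#' @return numeric coordination number.
#' @export
coordination_number <- function(na_pos, o_positions, r0 = 2.5, n = 6L, m = 12L) {
  stopifnot(r0 > 0, m > n)
  if (is.null(dim(o_positions))) o_positions <- matrix(o_positions, ncol = 3)
  d <- sqrt(rowSums(sweep(o_positions, 2, na_pos)^2))
  x <- d / r0
  s <- ifelse(abs(x - 1) < 1e-9, n / m, (1 - x^n) / (1 - x^m))
  sum(s)
}

#' Ultrafast shape recognition (USR) descriptors and similarity
#'
#' Twelve-component shape vector: the first three moments (mean, spread,
#' cube-rooted skew) of the atom-distance distributions to four reference
#' points (centroid; atom farthest from the centroid; atom farthest from
#' that atom; atom closest to the centroid). Rotation/translation
#' invariant. Similarity between two conformers is 1/(1 + mean absolute
#' descriptor difference), in (0, 1].
#'
#' @param coords n-by-3 coordinate matrix, n >= 4.
#' @return numeric vector of length 12.
#' @export
usr_descriptors <- function(coords) {
  if (!is.matrix(coords) || nrow(coords) < 4 || ncol(coords) != 3) {
    stop("usr_descriptors requires an n-by-3 matrix with n >= 4")
  }
  dists_to <- function(p) sqrt(rowSums(sweep(coords, 2, p)^2))
  ctd <- colMeans(coords)
  d_ctd <- dists_to(ctd)
  fct <- coords[which.max(d_ctd), ]
  d_fct <- dists_to(fct)
  ftf <- coords[which.max(d_fct), ]
  d_ftf <- dists_to(ftf)
  cst <- coords[which.min(d_ctd), ]
  d_cst <- dists_to(cst)
  moments <- function(d) {
    mu <- mean(d)
    m2 <- mean((d - mu)^2)
    m3 <- mean((d - mu)^3)
    c(mu, sqrt(m2), sign(m3) * abs(m3)^(1 / 3))
  }
  c(moments(d_ctd), moments(d_fct), moments(d_ftf), moments(d_cst))
}

#' @rdname usr_descriptors
#' @param a,b descriptor vectors from \code{usr_descriptors()} (or n-by-3
#'   coordinate matrices, which are converted).
#' @export
usr_similarity <- function(a, b) {
  if (is.matrix(a)) a <- usr_descriptors(a)
  if (is.matrix(b)) b <- usr_descriptors(b)
  1 / (1 + mean(abs(a - b)))
}

#' Remove highly similar conformers
#'
#' Greedy energy-ordered deduplication: conformers are visited from lowest
#' to highest energy (stable index tie-break) and kept iff their USR
#' similarity to every already-kept conformer is below \code{threshold}.
#' Deterministic given the input.
#'
#' @param ens a [conformer_ensemble()].
#' @param threshold similarity threshold in (0, 1); default 0.97.
#' @return integer indices (into the ensemble) of the retained conformers.
#' @export
dedup <- function(ens, threshold = 0.97) {
  stopifnot(threshold > 0, threshold < 1)
  desc <- lapply(ens$coords, usr_descriptors)
  ord <- order(ens$energy, seq_along(ens$energy))
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (k in kept) {
      if (usr_similarity(desc[[i]], desc[[k]]) >= threshold) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  sort(kept)
}

# --- candidate selection ---------------------------------------------------

#' Geometric criteria for reactant-candidate selection
#'
#' A conformer is a reaction candidate when (1) the sodium ion coordinates
#' the hydrogen donor or acceptor oxygen within \code{na_o_max} and (2) the
#' donor-acceptor distance lies in \code{[dd_min, dd_max]}. When fewer than
#' \code{min_candidates} conformers qualify, \code{dd_max} is widened in
#' \code{widen_step} increments up to \code{dd_hard_max}.
#'
#' @param na_o_max maximum Na-O coordination distance (A, default 2.5).
#' @param dd_min,dd_max donor-acceptor window (A, defaults 3.0-3.5).
#' @param min_candidates target candidate count (default 2000).
#' @param widen_step widening increment (A, default 0.5).
#' @param dd_hard_max absolute upper bound for widening (A, default 6.0).
#' @return list of class \code{candidate_criteria}.
#' @export
candidate_criteria <- function(na_o_max = 2.5, dd_min = 3.0, dd_max = 3.5,
                               min_candidates = 2000L, widen_step = 0.5,
                               dd_hard_max = 6.0) {
  stopifnot(dd_min < dd_max, dd_max <= dd_hard_max, widen_step > 0)
  structure(list(na_o_max = na_o_max, dd_min = dd_min, dd_max = dd_max,
                 min_candidates = as.integer(min_candidates),
                 widen_step = widen_step, dd_hard_max = dd_hard_max),
            class = "candidate_criteria")
}

#' Select reactant candidates from a conformer ensemble
#'
#' Applies the geometric criteria with adaptive widening of the
#' donor-acceptor window, then returns the lowest-energy candidates (stable
#' sort with index tie-break), at most \code{min_candidates} of them.
#'
#' @param ens a [conformer_ensemble()].
#' @param roles named list of atom indices: \code{na}, \code{donor},
#'   \code{acceptor}.
#' @param criteria a [candidate_criteria()].
#' @return list with \code{indices} (selected conformers, energy order),
#'   \code{passing} (all conformers satisfying the final window),
#'   \code{window} (the donor-acceptor window actually used) and
#'   \code{iterations} (data.frame logging each widening step).
#' @export
select_candidates <- function(ens, roles, criteria = candidate_criteria()) {
  if (!length(ens$coords)) stop("empty ensemble")
  for (nm in c("na", "donor", "acceptor")) {
    if (is.null(roles[[nm]])) stop("roles must name atom indices na, donor, acceptor")
  }
  d_na_don <- vapply(ens$coords, function(m) sqrt(sum((m[roles$na, ] - m[roles$donor, ])^2)), numeric(1))
  d_na_acc <- vapply(ens$coords, function(m) sqrt(sum((m[roles$na, ] - m[roles$acceptor, ])^2)), numeric(1))
  d_dd <- vapply(ens$coords, function(m) sqrt(sum((m[roles$donor, ] - m[roles$acceptor, ])^2)), numeric(1))
  na_ok <- d_na_don < criteria$na_o_max | d_na_acc < criteria$na_o_max

  dd_hi <- criteria$dd_max
  iterations <- data.frame(dd_max = numeric(0), n_pass = integer(0))
  repeat {
    pass <- na_ok & d_dd >= criteria$dd_min & d_dd <= dd_hi
    iterations <- rbind(iterations, data.frame(dd_max = dd_hi, n_pass = sum(pass)))
    if (sum(pass) >= criteria$min_candidates || dd_hi >= criteria$dd_hard_max) break
    dd_hi <- min(dd_hi + criteria$widen_step, criteria$dd_hard_max)
  }
  passing <- which(pass)
  ord <- passing[order(ens$energy[passing], passing)]
  sel <- ord[seq_len(min(length(ord), criteria$min_candidates))]
  list(indices = sel, passing = passing, window = c(criteria$dd_min, dd_hi),
       iterations = iterations)
}
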