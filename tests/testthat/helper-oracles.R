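# Independent oracles used to cross-check the implementation. These
# re-derive the expected results with deliberately plain, separate code.

# Brute-force enumeration of primary reducing-end pathways on a single
# hexose chain: all hydrogen-shift sequences up to L moves followed by one
# beta-rule retro-aldol cleavage. `carbonyl0` is the carbonyl position
# after ring opening; `blocked` lists oxygen positions without a free OH
# (glycosidic attachment, OMe, NAc).
oracle_primary_pathways <- function(carbonyl0, blocked = integer(0), L = 3) {
  res <- character(0)
  rec <- function(co, steps, remaining) {
    for (k in 1:5) {
      donor <- NA_integer_
      if (co == k - 1) donor <- k + 1L
      if (co == k + 2) donor <- k
      if (!is.na(donor) && donor >= 1 && donor <= 6 && !(donor %in% blocked)) {
        res <<- c(res, paste(c(steps, paste0("c", k)), collapse = ">"))
      }
    }
    if (remaining > 0) {
      for (j in 1:6) {
        allowed <- abs(co - j) == 1 || (min(co, j) == 1 && max(co, j) %in% 4:6)
        if (j != co && allowed && !(j %in% blocked)) {
          rec(j, c(steps, paste0("m", co, "_", j)), remaining - 1)
        }
      }
    }
  }
  rec(carbonyl0, "RO", L)
  sort(res)
}

# primary reducing-end pathway labels from the package, same format
package_primary_pathways <- function(glycan_string, L = 3) {
  g <- parse_glycan(glycan_string)
  cfg <- cr_config(max_shifts = L, secondary_depth = 1L,
                   include_non_reducing = FALSE)
  paths <- enumerate_pathways(g, cfg)
  sort(vapply(paths, function(p) paste(p$steps, collapse = ">"), character(1)))
}

# Direct re-evaluation of the USR formula, written independently with
# explicit loops.
oracle_usr <- function(coords) {
  n <- nrow(coords)
  dist_all <- function(p) {
    out <- numeric(n)
    for (i in 1:n) out[i] <- sqrt(sum((coords[i, ] - p)^2))
    out
  }
  ctd <- c(mean(coords[, 1]), mean(coords[, 2]), mean(coords[, 3]))
  d1 <- dist_all(ctd)
  d2 <- dist_all(coords[which.max(d1), ])
  d3 <- dist_all(coords[which.max(d2), ])
  d4 <- dist_all(coords[which.min(d1), ])
  m3 <- function(d) {
    mu <- sum(d) / n
    v <- sum((d - mu)^2) / n
    s <- sum((d - mu)^3) / n
    c(mu, sqrt(v), sign(s) * abs(s)^(1 / 3))
  }
  c(m3(d1), m3(d2), m3(d3), m3(d4))
}

oracle_usr_similarity <- function(a, b) {
  1 / (1 + sum(abs(oracle_usr(a) - oracle_usr(b))) / 12)
}

# random rigid motion applied to a coordinate matrix (seeded by caller)
rigid_motion <- function(coords) {
  th <- stats::runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])), c(0, sin(th[1]), cos(th[1])))
  Ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0), c(-sin(th[2]), 0, cos(th[2])))
  Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0), c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  sweep(coords %*% (Rx %*% Ry %*% Rz), 2, stats::runif(3, -5, 5), `+`)
}

# ideal pyranose-like ring: planar hexagon with alternating +/- z
make_ring <- function(radius = 1.45, pucker = 0) {
  t(vapply(0:5, function(j) {
    c(radius * cos(pi * j / 3), radius * sin(pi * j / 3), pucker * (-1)^j)
  }, numeric(3)))
}

man_candidates <- c("Manb1-2Manb", "Manb1-3Manb", "Manb1-4Manb", "Manb1-6Manb")
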