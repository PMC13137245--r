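# Seeded generators: conformer ensembles with planted screening ground
# truth, and CID peak lists with known fragment/tier structure. All
# randomness flows from the single seed argument; the caller's RNG state is
# left untouched.

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# random unit vector
.runitvec <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

#' Generate a conformer ensemble with planted screening ground truth
#'
#' Builds \code{n} conformers of a small synthetic Na+/sugar-like cluster
#' (one Na, a donor O, an acceptor O, and a 9-atom carbon skeleton).
#' Exactly \code{n_pass} conformers satisfy the default geometric criteria
#' by construction (Na within 2.5 A of the donor oxygen; donor-acceptor
#' distance inside [3.0, 3.5] A); the remainder violate at least one
#' criterion (sodium placed beyond 2.5 A from both oxygens on the far side
#' of the donor, or a donor-acceptor distance below 3 A or beyond the 6 A
#' widening bound). Relative energies are exponential with mean 20 kJ/mol.
#' Bit-reproducible for a given seed.
#'
#' @param n ensemble size.
#' @param n_pass number of planted candidates, \code{n_pass <= n}.
#' @param seed integer seed.
#' @param skeleton_atoms number of inert skeleton atoms (default 9).
#' @return list with \code{ensemble} (a [conformer_ensemble()]),
#'   \code{roles} (na/donor/acceptor atom indices) and \code{truth}
#'   (data.frame: conformer, pass, violation).
#' @export
gen_ensemble <- function(n, n_pass, seed = 1L, skeleton_atoms = 9L) {
  if (n_pass > n) stop("n_pass must not exceed n")
  if (n < 1L) stop("infeasible geometry parameters: n must be positive")
  .with_seed(seed, {
    elements <- c("Na", "O", "O", rep("C", skeleton_atoms))
    roles <- list(na = 1L, donor = 2L, acceptor = 3L)
    pass_flag <- sample(rep(c(TRUE, FALSE), c(n_pass, n - n_pass)))
    violations <- c("na_far", "dd_short", "dd_long")
    coords <- vector("list", n)
    viol <- character(n)
    for (i in seq_len(n)) {
      donor <- c(0, 0, 0)
      u <- .runitvec()
      if (pass_flag[i]) {
        dd <- stats::runif(1, 3.0, 3.5)
        na_d <- stats::runif(1, 1.8, 2.4)
        viol[i] <- ""
      } else {
        viol[i] <- violations[(i %% 3L) + 1L]
        dd <- switch(viol[i],
          na_far = stats::runif(1, 3.0, 3.5),
          dd_short = stats::runif(1, 1.6, 2.7),
          dd_long = stats::runif(1, 6.5, 8.0))
        na_d <- if (viol[i] == "na_far") stats::runif(1, 2.7, 4.0) else stats::runif(1, 1.8, 2.4)
      }
      acceptor <- donor + dd * u
      # sodium on the opposite side of the donor from the acceptor, so a
      # "na_far" sodium is guaranteed > 2.5 A from both oxygens
      na <- donor - na_d * u
      skel <- matrix(stats::rnorm(3 * skeleton_atoms, sd = 1.2), ncol = 3)
      skel <- sweep(skel, 2, (donor + acceptor) / 2 + c(0, 2.5, 0), `+`)
      m <- rbind(na, donor, acceptor, skel)
      dimnames(m) <- NULL
      coords[[i]] <- m
    }
    energy <- stats::rexp(n, rate = 1 / 20)
    list(
      ensemble = conformer_ensemble(elements, coords, energy),
      roles = roles,
      truth = data.frame(conformer = seq_len(n), pass = pass_flag,
                         violation = viol, stringsAsFactors = FALSE)
    )
  })
}

#' Generate a synthetic CID peak list with known ground truth
#'
#' Places peaks at the predicted fragment m/z of a glycan with tier-ordered
#' intensities (major 100 : minor 5 : trace 1 by default), optional
#' Gaussian m/z jitter and intensity noise, plus uniform-random noise peaks
#' kept more than 1 Da away from every true peak so the ground truth stays
#' unambiguous at the default matching tolerance.
#'
#' @param g glycan or glycan string.
#' @param n_noise_peaks number of added noise peaks.
#' @param intensity_cv coefficient of variation of multiplicative
#'   intensity noise.
#' @param mz_jitter standard deviation (Da) of m/z jitter.
#' @param seed integer seed.
#' @param cfg a [cr_config()].
#' @return list with \code{peaklist} (a [peaklist()]) and \code{truth}
#'   (data.frame: mz_true, mz_nominal, tier, pathways, is_noise).
#' @export
gen_spectrum <- function(g, n_noise_peaks = 0L, intensity_cv = 0,
                         mz_jitter = 0, seed = 1L, cfg = cr_config()) {
  if (is.character(g)) g <- parse_glycan(g)
  pred <- predict_spectrum(g, cfg)
  prec <- attr(pred, "precursor_mz")
  .with_seed(seed, {
    mz <- pred$mz + stats::rnorm(nrow(pred), 0, mz_jitter)
    int <- pred$intensity * pmax(0.05, 1 + stats::rnorm(nrow(pred), 0, intensity_cv))
    truth <- data.frame(
      mz_true = pred$mz, mz_nominal = pred$mz_nominal, tier = pred$tier,
      pathways = pred$pathways, is_noise = FALSE, stringsAsFactors = FALSE
    )
    if (n_noise_peaks > 0L) {
      noise_mz <- numeric(0)
      lo <- 50; hi <- max(prec - 5, 60)
      while (length(noise_mz) < n_noise_peaks) {
        cand <- stats::runif(1, lo, hi)
        if (all(abs(cand - pred$mz) > 1) && (!length(noise_mz) || all(abs(cand - noise_mz) > 0.5))) {
          noise_mz <- c(noise_mz, cand)
        }
      }
      noise_int <- stats::runif(n_noise_peaks, 0.2, 3)
      mz <- c(mz, noise_mz); int <- c(int, noise_int)
      truth <- rbind(truth, data.frame(
        mz_true = noise_mz, mz_nominal = as.integer(round(noise_mz)),
        tier = NA_character_, pathways = NA_character_, is_noise = TRUE,
        stringsAsFactors = FALSE
      ))
    }
    o <- order(mz)
    list(
      peaklist = peaklist(mz, int, precursor_mz = prec,
                          metadata = list(glycan = serialize_glycan(g), seed = seed)),
      truth = truth[o, , drop = FALSE]
    )
  })
}
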