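# Matching experimental peaks to predicted fragments and calling the
# reducing-end glycosidic linkage from the cross-ring intensity pattern.

#' Annotate a peak list against predicted fragments
#'
#' Each observed peak is matched to the nearest predicted fragment within
#' \code{tol}. Peaks matching a nominal m/z reached by several distinct
#' pathways, or lying within tolerance of more than one predicted peak, are
#' flagged ambiguous.
#'
#' @param pl a [peaklist()].
#' @param g glycan (or string) whose predicted spectrum is matched.
#' @param tol absolute m/z tolerance in Da (default 0.3, unit-resolution
#'   ion trap).
#' @param cfg a [cr_config()].
#' @return data.frame with one row per observed peak: \code{mz, intensity,
#'   matched, pred_mz, mz_nominal, tier, neutral_loss_nominal,
#'   label_retained, pathways, mass_error, ambiguous}.
#' @export
annotate <- function(pl, g, tol = 0.3, cfg = cr_config()) {
  stopifnot(tol > 0)
  if (is.character(g)) g <- parse_glycan(g)
  pred <- predict_spectrum(g, cfg)
  n <- nrow(pl$peaks)
  out <- data.frame(
    peak = seq_len(n), mz = pl$peaks$mz, intensity = pl$peaks$intensity,
    matched = FALSE, pred_mz = NA_real_, mz_nominal = NA_integer_,
    tier = NA_character_, neutral_loss_nominal = NA_integer_,
    label_retained = NA, pathways = NA_character_,
    mass_error = NA_real_, ambiguous = FALSE, stringsAsFactors = FALSE
  )
  if (!nrow(pred)) return(out)
  for (i in seq_len(n)) {
    d <- abs(pred$mz - pl$peaks$mz[i])
    hits <- which(d <= tol)
    if (!length(hits)) next
    j <- hits[which.min(d[hits])]
    out$matched[i] <- TRUE
    out$pred_mz[i] <- pred$mz[j]
    out$mz_nominal[i] <- pred$mz_nominal[j]
    out$tier[i] <- pred$tier[j]
    out$neutral_loss_nominal[i] <- pred$neutral_loss_nominal[j]
    out$label_retained[i] <- pred$label_retained[j]
    out$pathways[i] <- pred$pathways[j]
    out$mass_error[i] <- pl$peaks$mz[i] - pred$mz[j]
    out$ambiguous[i] <- length(hits) > 1L || pred$n_pathways[j] > 1L
  }
  attr(out, "glycan") <- serialize_glycan(g)
  attr(out, "tol") <- tol
  out
}

#' Call the reducing-end linkage from a CID peak list
#'
#' Scores each candidate glycan by rank-based agreement between the
#' observed cross-ring intensity pattern and the candidate's predicted
#' tiers: predicted major fragments are rewarded in proportion to their
#' observed relative intensity; observed peaks explained as predicted
#' minor/trace fragments are rewarded when small and penalized when as
#' intense as the base peak (a dominant "minor" contradicts the candidate);
#' observed cross-ring peaks a candidate cannot explain count against it.
#' Minor peaks that the dissociation mechanisms explain therefore never
#' force a mixture call. Scores are invariant to uniform intensity
#' rescaling and the ranking is deterministic (score, then candidate
#' order).
#'
#' @param pl a [peaklist()].
#' @param candidates list of glycans or glycan strings differing in the
#'   linkage to the reducing end.
#' @param tol m/z tolerance in Da.
#' @param cfg a [cr_config()].
#' @return data.frame ranked by score with columns \code{candidate, score,
#'   major_agreement, explained_fraction, rank}; attributes
#'   \code{uninformative} (no cross-ring peak matched any candidate) and
#'   \code{mixture_required} (top candidate leaves cross-ring peaks
#'   unexplained).
#' @export
infer_linkage <- function(pl, candidates, tol = 0.3, cfg = cr_config()) {
  if (!length(candidates)) stop("at least one candidate glycan is required")
  glys <- lapply(candidates, function(x) if (is.character(x)) parse_glycan(x) else x)
  preds <- lapply(glys, predict_spectrum, cfg = cfg)

  obs_mz <- pl$peaks$mz
  obs_int <- pl$peaks$intensity
  # cross-ring peaks: observed peaks within tol of any candidate prediction
  xr <- rep(FALSE, length(obs_mz))
  for (pred in preds) {
    for (m in pred$mz) xr <- xr | abs(obs_mz - m) <= tol
  }
  res <- data.frame(
    candidate = vapply(glys, serialize_glycan, character(1)),
    score = NA_real_, major_agreement = NA_real_, explained_fraction = NA_real_,
    stringsAsFactors = FALSE
  )
  if (!any(xr)) {
    res$rank <- NA_integer_
    attr(res, "uninformative") <- TRUE
    attr(res, "mixture_required") <- NA
    return(res)
  }
  imax <- max(obs_int[xr])
  xr_idx <- which(xr)

  explained_top <- NULL
  for (ci in seq_along(preds)) {
    pred <- preds[[ci]]
    majors <- pred[pred$tier == "major", , drop = FALSE]
    # observed relative intensity at each predicted major peak
    r_major <- vapply(majors$mz, function(m) {
      hit <- which(abs(obs_mz - m) <= tol)
      if (!length(hit)) 0 else max(obs_int[hit]) / imax
    }, numeric(1))
    s_major <- if (length(r_major)) mean(r_major) else 0
    minor_terms <- numeric(0)
    unexplained <- numeric(0)
    explained <- logical(length(xr_idx))
    for (k in seq_along(xr_idx)) {
      i <- xr_idx[k]
      d <- abs(pred$mz - obs_mz[i])
      j <- which(d <= tol)
      if (!length(j)) { unexplained <- c(unexplained, obs_int[i] / imax); next }
      explained[k] <- TRUE
      tierk <- pred$tier[j[which.min(d[j])]]
      if (tierk != "major") {
        minor_terms <- c(minor_terms, 1 - 2 * obs_int[i] / imax)
      }
    }
    s_minor <- if (length(minor_terms)) 0.5 * mean(minor_terms) else 0
    s_unex <- if (length(unexplained)) sum(unexplained) else 0
    res$score[ci] <- 2 * s_major + s_minor - s_unex
    res$major_agreement[ci] <- s_major
    res$explained_fraction[ci] <- mean(explained)
    if (ci == 1L || res$score[ci] > max(res$score[seq_len(ci - 1L)], na.rm = TRUE)) {
      explained_top <- explained
    }
  }
  o <- order(-res$score, seq_len(nrow(res)))
  res <- res[o, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  attr(res, "uninformative") <- FALSE
  attr(res, "mixture_required") <- !all(explained_top)
  res
}
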