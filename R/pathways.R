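# Enumeration of cross-ring dissociation pathways, barrier-driven tier
# classification, and theoretical spectrum prediction.

#' Pipeline configuration
#'
#' @param max_shifts maximum number of hydrogen shifts per dissociation
#'   stage (default 3).
#' @param secondary_depth maximum number of sequential dissociation stages;
#'   2 means one primary and one secondary cleavage.
#' @param window classification window (kJ/mol): reducing-end pathways whose
#'   rate-limiting barrier lies within this window of the minimum are minor,
#'   beyond it trace (default 50).
#' @param t_eff effective temperature (K) for the optional Boltzmann
#'   intensity weights. Not derived from experiment; default 800.
#' @param tol m/z matching tolerance in Da (unit-resolution ion trap
#'   default 0.3).
#' @param tier_intensity relative intensities assigned per tier in
#'   theoretical spectra.
#' @param include_non_reducing include the table-driven non-reducing-end
#'   pathway catalog.
#' @return list of class \code{cr_config}.
#' @export
cr_config <- function(max_shifts = 3L, secondary_depth = 2L, window = 50,
                      t_eff = 800, tol = 0.3,
                      tier_intensity = c(major = 100, minor = 5, trace = 1),
                      include_non_reducing = TRUE) {
  structure(list(max_shifts = as.integer(max_shifts),
                 secondary_depth = as.integer(secondary_depth),
                 window = window, t_eff = t_eff, tol = tol,
                 tier_intensity = tier_intensity,
                 include_non_reducing = include_non_reducing),
            class = "cr_config")
}

# is retro_aldol(s, k) applicable (beta-cleavage rule + free beta hydroxyl)?
.cleavable <- function(s, k) {
  a <- s$range[1]; b <- s$range[2]
  if (k < a || k + 1L > b) return(FALSE)
  co <- s$carbonyl
  if (identical(co, k - 1L)) return(.free_oxygen(s, k + 1L))
  if (identical(co, k + 2L)) return(.free_oxygen(s, k))
  FALSE
}

# pick the retained (ion) piece indices: the partition carrying the
# glycosidically linked moiety, or for a free chain the partition opposite
# the carbonyl-bearing lost piece
.retained_indices <- function(pieces) {
  att <- which(vapply(pieces, `[[`, logical(1), "has_attachment"))
  if (length(att) >= 1L) return(att)
  co <- which(vapply(pieces, `[[`, logical(1), "has_carbonyl"))
  if (length(co) == 1L) return(setdiff(1:2, co))
  1L  # degenerate; deterministic
}

#' Enumerate cross-ring dissociation pathways
#'
#' Exhaustively enumerates reducing-end pathways (ring opening, up to
#' \code{max_shifts} hydrogen shifts per stage, beta-rule retro-aldol
#' cleavage, and secondary dissociation of the retained piece up to
#' \code{secondary_depth} stages), plus the table-driven non-reducing-end
#' pathway catalog (RO1', RO2', c0',3' and their follow-up shifts) for every
#' unsubstituted aldo-hexose whose anomeric oxygen is blocked.
#'
#' @param g glycan.
#' @param cfg a [cr_config()].
#' @return list of pathway records (steps, stages, site, cumulative lost and
#'   retained compositions, label bookkeeping).
#' @export
enumerate_pathways <- function(g, cfg = cr_config()) {
  total <- glycan_comp(g)
  out <- new.env(parent = emptyenv())
  out$paths <- list()
  emit <- function(p) { out$paths[[length(out$paths) + 1L]] <- p; p }

  explore <- function(state, steps, stages, cum_lost, label_lost, stage, shifts_used) {
    a <- state$range[1]; b <- state$range[2]
    for (k in a:(b - 1L)) {
      if (b - a < 1L) break
      if (!.cleavable(state, k)) next
      pieces <- retro_aldol(state, k)
      for (ri in .retained_indices(pieces)) {
        retained <- pieces[[ri]]
        lost <- pieces[[setdiff(1:2, ri)[1]]]
        new_lost <- comp_add(cum_lost, lost$comp)
        new_label_lost <- label_lost || lost$label
        p <- list(
          site = "reducing_end",
          steps = c(steps, paste0("c", k)),
          stages = c(stages, stage),
          lost_comp = new_lost,
          retained_comp = comp_sub(total, new_lost),
          label_retained = !new_label_lost,
          n_steps = length(steps) + 1L,
          stage_depth = stage
        )
        emit(p)
        if (stage < cfg$secondary_depth && retained$range[2] > retained$range[1]) {
          explore(.piece_state(state, retained), p$steps, p$stages,
                  new_lost, new_label_lost, stage + 1L, 0L)
        }
      }
    }
    if (shifts_used < cfg$max_shifts && state$form == "linear") {
      i <- state$carbonyl
      for (j in a:b) {
        if (!.shift_allowed(i, j) || !.free_oxygen(state, j)) next
        explore(apply_shift(state, i, j),
                c(steps, paste0("m", i, "_", j)), c(stages, stage),
                cum_lost, label_lost, stage, shifts_used + 1L)
      }
    }
  }

  s0 <- chain_state(g)
  opened <- tryCatch(ring_open(s0), error = function(e) NULL)
  if (!is.null(opened)) {
    explore(opened, "RO", 1L, comp(), FALSE, 1L, 0L)
  }

  if (cfg$include_non_reducing) {
    for (p in .nonreducing_pathways(g, total)) emit(p)
  }
  out$paths
}

# catalog of non-reducing-end pathways: (step sequence, neutral-loss
# composition). Products: RO1'/RO2' lose three CH2O units, c0',3' loses
# four; follow-up migrations m2'_3'/m4'_5'/m5'_6' lose one/two/four.
.nr_catalog <- function() {
  u <- function(n) comp(C = n, H = 2 * n, O = n)
  list(
    list(steps = "c0p3p", loss = u(4)),
    list(steps = "RO1p", loss = u(3)),
    list(steps = "RO2p", loss = u(3)),
    list(steps = c("RO1p", "m2p_3p"), loss = u(1)),
    list(steps = c("RO1p", "m4p_5p"), loss = u(2)),
    list(steps = c("RO1p", "m5p_6p"), loss = u(4)),
    list(steps = c("RO2p", "m2p_3p"), loss = u(1)),
    list(steps = c("RO2p", "m4p_5p"), loss = u(2)),
    list(steps = c("RO2p", "m5p_6p"), loss = u(4))
  )
}

.nonreducing_pathways <- function(g, total) {
  eligible <- integer(0)
  for (i in seq_along(g$residues)) {
    r <- g$residues[[i]]
    if (length(r$substituents) && !identical(names(r$substituents), "1")) next
    if (r$carbonyl_position != 1L) next
    blocked <- identical(r$substituents[["1"]], "OMe") ||
      any(g$linkages$child == i)
    if (blocked) eligible <- c(eligible, i)
  }
  paths <- list()
  for (i in eligible) {
    for (row in .nr_catalog()) {
      paths[[length(paths) + 1L]] <- list(
        site = "non_reducing_end",
        residue = i,
        steps = row$steps,
        stages = rep(1L, length(row$steps)),
        lost_comp = row$loss,
        retained_comp = comp_sub(total, row$loss),
        label_retained = TRUE,
        n_steps = length(row$steps),
        stage_depth = 1L
      )
    }
  }
  paths
}

# --- classification --------------------------------------------------------

# barrier info for one pathway: numeric rate-limiting barrier, ordinal rank,
# gt_300 flag, accessibility rank
.pathway_energetics <- function(p, red_rows, nr_rows) {
  rows <- if (p$site == "reducing_end") red_rows else nr_rows
  hit <- rows[rows$step %in% p$steps, , drop = FALSE]
  barr <- hit$barrier_kJ_mol[!is.na(hit$barrier_kJ_mol)]
  rk <- hit$rank[!is.na(hit$rank)]
  list(
    rl_barrier = if (length(barr)) max(barr) else NA_real_,
    rl_rank = if (length(rk)) max(rk) else NA_integer_,
    gt_300 = any(hit$qualifier == "gt_300", na.rm = TRUE),
    accessibility = max(vapply(p$steps, .accessibility_rank, integer(1)))
  )
}

.tier_levels <- c("major", "minor", "trace")

# diagnostic dominant-loss map per linkage position (Fig 1b logic)
.diagnostic_losses <- function(pos) {
  switch(as.character(pos), "2" = 120, "3" = 90, "4" = 60,
         "6" = c(60, 90, 120), numeric(0))
}

# nominal loss with 18O counted as 16O (diagnostic losses are quoted for
# the unlabeled species)
.unlabeled_nominal <- function(x) {
  x["O"] <- x["O"] + x["O18"]; x["O18"] <- 0
  as.integer(round(comp_mass(x)))
}

#' Classify pathways into major/minor/trace tiers
#'
#' The major pathway is the reducing-end primary pathway ranked first by
#' (step count, rate-limiting barrier or ordinal rank, reactant-state
#' accessibility, step label). Other reducing-end primaries are minor when
#' their rate-limiting barrier lies within \code{window} kJ/mol of the
#' minimum (or when only ordinal information exists), trace beyond it.
#' Secondary dissociation products of major/minor pathways are minor;
#' non-reducing-end pathways and ">300 kJ/mol" entries are trace. For
#' species absent from the barrier table, the dominant-loss diagnostic map
#' (1->2: 120; 1->3: 90; 1->4: 60; 1->6: 60, 90 and 120) assigns major tiers.
#'
#' @param pathways list from [enumerate_pathways()].
#' @param g the glycan they were enumerated for.
#' @param cfg a [cr_config()].
#' @return the pathway list with \code{tier}, \code{rl_barrier},
#'   \code{rl_rank} and \code{accessibility} filled in.
#' @export
classify <- function(pathways, g, cfg = cr_config()) {
  if (!length(pathways)) return(pathways)
  sig <- .species_signature(g)
  red_rows <- .species_barriers(sig, "reducing_end")
  if (!nrow(red_rows) && length(g$residues) == 1L &&
      !length(g$residues[[1]]$substituents) &&
      g$residues[[1]]$carbonyl_position == 1L) {
    red_rows <- .species_barriers("Glc", "reducing_end")  # generic aldo-hexose
  }
  nr_rows <- .species_barriers(sig, "non_reducing_end")
  if (!nrow(nr_rows)) nr_rows <- .species_barriers("Man-OMe", "non_reducing_end")

  en <- lapply(pathways, .pathway_energetics, red_rows = red_rows, nr_rows = nr_rows)
  for (i in seq_along(pathways)) {
    pathways[[i]]$rl_barrier <- en[[i]]$rl_barrier
    pathways[[i]]$rl_rank <- en[[i]]$rl_rank
    pathways[[i]]$accessibility <- en[[i]]$accessibility
  }

  is_red <- vapply(pathways, function(p) p$site == "reducing_end", logical(1))
  is_prim <- vapply(pathways, function(p) p$stage_depth == 1L, logical(1))
  labels <- vapply(pathways, function(p) paste(p$steps, collapse = ">"), character(1))

  prim_idx <- which(is_red & is_prim)
  tier <- rep("trace", length(pathways))

  major_idx <- integer(0)
  if (length(prim_idx)) {
    keyord <- order(
      vapply(pathways[prim_idx], `[[`, integer(1), "n_steps"),
      vapply(pathways[prim_idx], function(p) ifelse(is.na(p$rl_barrier), Inf, p$rl_barrier), numeric(1)),
      vapply(pathways[prim_idx], function(p) ifelse(is.na(p$rl_rank), Inf, as.numeric(p$rl_rank)), numeric(1)),
      vapply(pathways[prim_idx], `[[`, integer(1), "accessibility"),
      labels[prim_idx]
    )
    major_idx <- prim_idx[keyord[1]]

    # diagnostic-map override for species without barrier data
    root_att <- g$linkages[g$linkages$parent == g$root, , drop = FALSE]
    if (!nrow(red_rows) && length(g$residues) > 1L && nrow(root_att) == 1L) {
      diag <- .diagnostic_losses(root_att$parent_pos[1])
      if (length(diag)) {
        losses <- vapply(pathways[prim_idx], function(p) .unlabeled_nominal(p$lost_comp), integer(1))
        major_idx <- integer(0)
        for (d in diag) {
          cand <- prim_idx[losses == d]
          if (!length(cand)) next
          co <- order(
            vapply(pathways[cand], `[[`, integer(1), "n_steps"),
            vapply(pathways[cand], `[[`, integer(1), "accessibility"),
            labels[cand]
          )
          major_idx <- c(major_idx, cand[co[1]])
        }
        if (!length(major_idx)) major_idx <- prim_idx[keyord[1]]
      }
    }

    barrs <- vapply(pathways[prim_idx], `[[`, numeric(1), "rl_barrier")
    min_b <- suppressWarnings(min(barrs, na.rm = TRUE))
    for (ii in prim_idx) {
      p <- pathways[[ii]]
      if (ii %in% major_idx) { tier[ii] <- "major"; next }
      if (en[[ii]]$gt_300) { tier[ii] <- "trace"; next }
      if (is.na(p$rl_barrier) || !is.finite(min_b)) tier[ii] <- "minor"
      else tier[ii] <- if (p$rl_barrier <= min_b + cfg$window) "minor" else "trace"
    }
    # secondary products of major/minor pathways are minor
    for (ii in which(is_red & !is_prim)) {
      p <- pathways[[ii]]
      prim_steps <- p$steps[p$stages == 1L]
      parent_lab <- paste(prim_steps, collapse = ">")
      parent <- which(labels == parent_lab & is_prim & is_red)
      ptier <- if (length(parent)) tier[parent[1]] else "minor"
      tier[ii] <- if (ptier %in% c("major", "minor")) "minor" else "trace"
    }
  }
  for (i in seq_along(pathways)) pathways[[i]]$tier <- tier[i]
  pathways
}

# --- fragment ions ---------------------------------------------------------

#' Fragment ion produced by a pathway
#'
#' @param p classified pathway record.
#' @param g the glycan.
#' @return one-row data.frame: pathway label, site, tier, monoisotopic and
#'   nominal m/z, neutral-loss masses, retained/lost formulas and the
#'   label-retention flag.
#' @export
fragment_ion <- function(p, g) {
  lm <- loss_mass(p$lost_comp)
  mz <- .comp_mz(p$retained_comp, g$adduct)
  lab <- paste(ifelse(p$stages > 1L, paste0(p$steps, "*"), p$steps), collapse = ">")
  # Domon-Costello cross-ring label (annotation metadata only): ring bonds
  # cleaved are 0 (ring opening) and k for a single-stage reducing-end
  # retro-aldol; the c0',3' reaction cleaves bonds 0 and 3 of a
  # non-reducing residue
  dc <- NA_character_
  cleaves <- grep("^c[0-9]$", p$steps, value = TRUE)
  if (p$site == "reducing_end" && p$stage_depth == 1L && length(cleaves) == 1L) {
    dc <- sprintf("0,%sA%d", sub("^c", "", cleaves), length(g$residues))
  } else if (p$site == "non_reducing_end" && "c0p3p" %in% p$steps) {
    dc <- sprintf("0,3A%d", length(.subtree(g, p$residue)))
  }
  data.frame(
    pathway = lab,
    site = p$site,
    tier = if (is.null(p$tier)) NA_character_ else p$tier,
    n_steps = p$n_steps,
    stage_depth = p$stage_depth,
    mz_monoisotopic = mz,
    mz_nominal = as.integer(round(mz)),
    neutral_loss = lm$monoisotopic,
    neutral_loss_nominal = lm$nominal,
    retained_formula = comp_formula(p$retained_comp),
    lost_formula = comp_formula(p$lost_comp),
    dc_label = dc,
    label_retained = p$label_retained,
    rl_barrier = if (is.null(p$rl_barrier)) NA_real_ else p$rl_barrier,
    accessibility = if (is.null(p$accessibility)) NA_integer_ else p$accessibility,
    stringsAsFactors = FALSE
  )
}

#' Enumerate, classify and tabulate all fragment ions of a glycan
#'
#' @param g glycan or glycan string.
#' @param cfg a [cr_config()].
#' @return data.frame of fragment ions (one row per pathway).
#' @export
fragments <- function(g, cfg = cr_config()) {
  if (is.character(g)) g <- parse_glycan(g)
  paths <- classify(enumerate_pathways(g, cfg), g, cfg)
  if (!length(paths)) {
    return(fragment_ion(list(steps = character(0), stages = integer(0),
                             site = "reducing_end", lost_comp = comp(),
                             retained_comp = glycan_comp(g),
                             label_retained = TRUE, n_steps = 0L,
                             stage_depth = 1L, tier = NA_character_), g)[0, ])
  }
  do.call(rbind, lapply(paths, fragment_ion, g = g))
}

# --- theoretical spectrum --------------------------------------------------

.kB_kJ <- 8.314462618e-3  # kJ/mol/K

#' Predict the theoretical CID peak list of a sodiated glycan
#'
#' Enumerates and classifies all pathways, then collapses fragment ions to
#' unique nominal m/z peaks. Peak tier is the best tier among contributing
#' pathways; relative intensity follows \code{cfg$tier_intensity}. A
#' Boltzmann weight exp(-E/kT_eff)/accessibility is reported where numeric
#' barriers exist (an ordering aid, not an intensity model).
#'
#' @param g glycan or glycan string.
#' @param cfg a [cr_config()].
#' @return data.frame of peaks (mz, intensity, mz_nominal, tier,
#'   neutral_loss_nominal, label_retained, pathways) with attributes
#'   \code{precursor_mz}, \code{precursor_nominal} and \code{glycan}.
#' @examples
#' sp <- predict_spectrum("Manb1-2Manb-18O1")
#' sp[sp$tier == "major", "mz_nominal"]  # 247
#' @export
predict_spectrum <- function(g, cfg = cr_config()) {
  if (is.character(g)) g <- parse_glycan(g)
  fr <- fragments(g, cfg)
  pm <- precursor_mz(g)
  tier_num <- match(fr$tier, .tier_levels)
  ord <- order(fr$mz_nominal, tier_num, fr$n_steps, fr$pathway)
  fr <- fr[ord, , drop = FALSE]
  peaks <- do.call(rbind, lapply(split(fr, fr$mz_nominal), function(d) {
    best <- d[1, ]  # best tier first within each nominal m/z
    w <- NA_real_
    if (!is.na(best$rl_barrier)) {
      w <- exp(-best$rl_barrier / (.kB_kJ * cfg$t_eff)) /
        max(1L, best$accessibility, na.rm = TRUE)
    }
    data.frame(
      mz = best$mz_monoisotopic,
      intensity = unname(cfg$tier_intensity[best$tier]),
      mz_nominal = best$mz_nominal,
      tier = best$tier,
      neutral_loss_nominal = best$neutral_loss_nominal,
      label_retained = best$label_retained,
      n_pathways = nrow(d),
      pathways = paste(unique(d$pathway), collapse = "; "),
      boltzmann_weight = w,
      stringsAsFactors = FALSE
    )
  }))
  peaks <- peaks[order(peaks$mz), , drop = FALSE]
  rownames(peaks) <- NULL
  attr(peaks, "precursor_mz") <- pm$mz_monoisotopic
  attr(peaks, "precursor_nominal") <- pm$mz_nominal
  attr(peaks, "glycan") <- serialize_glycan(g)
  peaks
}
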