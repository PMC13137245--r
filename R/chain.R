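# Linear-chain state of the reducing-end residue and the three elementary
# moves of the cross-ring mechanism: ring opening, hydrogen shifts that
# relocate the carbonyl, and the retro-aldol C-C cleavage.

#' Chain state of a (reducing-end) hexose
#'
#' Builds the mechanistic state for the root residue of a glycan: cyclic at
#' first, with per-carbon unit compositions (CH2O units adjusted for
#' substituents, glycosidic attachments and 18O labels) used later for
#' atom-level fragment partitioning.
#'
#' @param g glycan.
#' @param residue_idx residue to model; defaults to the root (reducing end).
#' @return object of class \code{chain_state}.
#' @export
chain_state <- function(g, residue_idx = g$root) {
  r <- g$residues[[residue_idx]]
  nC <- r$carbon_count
  lk <- g$linkages
  att <- lk[lk$parent == residue_idx, , drop = FALSE]
  attachments <- structure(att$child, names = as.character(att$parent_pos))
  blocked <- as.integer(names(r$substituents))
  # a residue glycosylated through its own anomeric carbon lost its
  # anomeric hydroxyl on condensation: no reducing-end chemistry
  if (any(lk$child == residue_idx)) blocked <- c(blocked, r$carbonyl_position)
  units <- vector("list", nC)
  glyco <- vector("list", nC)
  for (i in seq_len(nC)) {
    p <- as.character(i)
    u <- comp(C = 1, H = 2, O = 1)
    tok <- r$substituents[[p]]
    if (!is.null(tok)) {
      if (tok == "NAc") u <- comp(C = 3, H = 5, N = 1, O = 1)
      else if (tok == "OMe") u <- comp(C = 2, H = 4, O = 1)
      else stop("unsupported substituent: ", tok)
    }
    if (!is.null(r$labels[[p]])) u <- comp_add(comp_sub(u, comp(O = 1)), comp(O18 = 1))
    if (p %in% names(attachments)) {
      u <- comp_sub(u, comp(H = 1))
      glyco[[i]] <- .glycosyl_comp(g, attachments[[p]])
    }
    units[[i]] <- u
  }
  structure(list(
    glycan = g, residue_idx = residue_idx,
    form = "cyclic", carbonyl = NA_integer_,
    range = c(1L, nC),
    carbonyl_position = r$carbonyl_position,
    attachment_positions = as.integer(names(attachments)),
    label_positions = as.integer(names(r$labels)),
    blocked_positions = blocked,
    units = units, glycosyl = glyco
  ), class = "chain_state")
}

# can the oxygen at position p donate/accept an OH hydrogen?
.free_oxygen <- function(s, p) {
  p >= s$range[1] && p <= s$range[2] &&
    !(p %in% s$attachment_positions) &&
    !(p %in% s$blocked_positions) &&
    !identical(p, s$carbonyl)
}

#' Ring opening of the reducing-end hexose
#'
#' Hydrogen transfer from the anomeric oxygen to O5 with cleavage of the
#' O5-C1 bond (O5-C2 for keto-hexoses), converting the pyranose to its
#' open-chain carbonyl form. Only possible when the anomeric oxygen is free:
#' a methyl glycoside or a residue glycosylated at its anomeric position has
#' no reducing-end ring opening.
#'
#' @param s chain_state (cyclic).
#' @return chain_state in linear form with the carbonyl at the anomeric
#'   carbon; oxygen labels are unchanged (the hydrogen moves, not the oxygen).
#' @export
ring_open <- function(s) {
  if (s$form != "cyclic") stop("ring_open requires the cyclic form")
  ap <- s$carbonyl_position
  if (ap %in% s$attachment_positions || ap %in% s$blocked_positions) {
    stop("no reducing-end ring opening: anomeric oxygen is blocked")
  }
  s$form <- "linear"
  s$carbonyl <- as.integer(ap)
  s
}

# allowed hydrogen-shift moves: adjacent 1,2-shifts plus the long-range
# O1-mediated 1<->4, 1<->5, 1<->6 shifts
.shift_allowed <- function(i, j) {
  if (i == j) return(FALSE)
  abs(i - j) == 1L || (min(i, j) == 1L && max(i, j) %in% 4:6)
}

#' Hydrogen shift relocating the carbonyl
#'
#' Moves the carbonyl from carbon \code{i} to carbon \code{j} by hydrogen
#' migration from O_j to O_i. Requires the linear form, the carbonyl at
#' \code{i}, an allowed (i,j) pair (adjacent, or 1<->4/5/6), and a free
#' hydroxyl at O_j.
#'
#' @param s chain_state (linear).
#' @param i,j carbon positions.
#' @return updated chain_state; composition and labels unchanged.
#' @export
apply_shift <- function(s, i, j) {
  if (s$form != "linear") stop("hydrogen shift requires the linear form")
  if (!identical(s$carbonyl, as.integer(i))) stop("carbonyl is not at C", i)
  if (!.shift_allowed(i, j)) stop("disallowed hydrogen shift ", i, "->", j)
  if (j < s$range[1] || j > s$range[2]) stop("shift target outside chain")
  if (!.free_oxygen(s, as.integer(j))) stop("no free hydroxyl at O", j)
  s$carbonyl <- as.integer(j)
  s
}

# composition of carbons a..b of the chain, including glycosyl groups
.piece_comp <- function(s, a, b) {
  x <- comp()
  for (i in a:b) {
    x <- comp_add(x, s$units[[i]])
    if (!is.null(s$glycosyl[[i]])) x <- comp_add(x, s$glycosyl[[i]])
  }
  x
}

#' Retro-aldol cleavage of a chain C-C bond
#'
#' Cleaves the bond between C_k and C_{k+1}. The beta-cleavage rule requires
#' the carbonyl at C_{k-1} or C_{k+2}; the concomitant hydrogen transfer
#' additionally requires a free hydroxyl on the beta carbon (O_{k+1} when the
#' carbonyl is at C_{k-1}, O_k when it is at C_{k+2}). Returns the two atom
#' partitions; compositions sum exactly to the parent.
#'
#' @param s chain_state (linear).
#' @param k bond index (1-5; bond 0 is the ring O5-C1 bond, which is opened
#'   by [ring_open()], not by retro-aldol).
#' @return list of two pieces, each with carbon \code{range}, \code{comp},
#'   \code{has_attachment}, \code{has_carbonyl}, \code{label} flag, and the
#'   re-evaluated \code{carbonyl} position the piece would carry if it
#'   re-enters enumeration.
#' @export
retro_aldol <- function(s, k) {
  if (s$form != "linear") stop("retro-aldol requires the linear form")
  k <- as.integer(k)
  a <- s$range[1]; b <- s$range[2]
  if (k < a || k + 1L > b) stop("bond ", k, " is not within the chain")
  co <- s$carbonyl
  if (!(identical(co, k - 1L) || identical(co, k + 2L))) {
    stop("not a retro-aldol-accessible bond: carbonyl at C", co,
         " cannot cleave bond ", k)
  }
  donor <- if (identical(co, k - 1L)) k + 1L else k
  if (!.free_oxygen(s, donor)) {
    stop("not a retro-aldol-accessible bond: no free hydroxyl at O", donor)
  }
  piece <- function(lo, hi) {
    has_co <- !is.na(co) && co >= lo && co <= hi
    list(
      range = c(lo, hi),
      comp = .piece_comp(s, lo, hi),
      has_attachment = any(s$attachment_positions >= lo & s$attachment_positions <= hi),
      has_carbonyl = has_co,
      label = any(s$label_positions >= lo & s$label_positions <= hi),
      # enol piece tautomerizes: carbonyl re-forms at the cleavage carbon
      carbonyl = if (has_co) co else if (hi == k) k else k + 1L
    )
  }
  list(piece(a, k), piece(k + 1L, b))
}

# derive the sub-chain state for a retained piece entering secondary
# dissociation
.piece_state <- function(s, piece) {
  s$range <- piece$range
  s$carbonyl <- as.integer(piece$carbonyl)
  s$form <- "linear"
  s
}
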