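#' Supported monosaccharide residues
#'
#' Residue tokens the parser accepts. Stereochemistry is carried as a name
#' tag only (Glc/Man/Gal are mass-identical hexoses); Fru is the keto-hexose
#' with its carbonyl at C2; HexNAc residues carry an N-acetyl at C2.
#'
#' @format data.frame with columns \code{name}, \code{carbon_count},
#'   \code{carbonyl_position} and \code{nac} (logical, N-acetyl at C2).
#' @export
residue_table <- data.frame(
  name = c("Glc", "Man", "Gal", "Hex", "Fru", "GlcNAc", "GalNAc", "HexNAc"),
  carbon_count = 6L,
  carbonyl_position = c(1L, 1L, 1L, 1L, 2L, 1L, 1L, 1L),
  nac = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
  stringsAsFactors = FALSE
)

.residue_info <- function(name) {
  i <- match(name, residue_table$name)
  if (is.na(i)) stop("unknown residue token: ", name)
  residue_table[i, ]
}

.new_residue <- function(name, anomeric = "") {
  info <- .residue_info(name)
  subst <- list()
  if (info$nac) subst[["2"]] <- "NAc"
  list(
    name = name,
    anomeric = anomeric,
    carbon_count = info$carbon_count,
    carbonyl_position = info$carbonyl_position,
    substituents = subst,
    labels = list()
  )
}

# --- parsing ---------------------------------------------------------------

# normalize extended IUPAC-ish notation (Greek letters, arrows, parentheses)
# into the condensed grammar: "GlcNAcβ-(1→2)-Man" -> "GlcNAcb1-2Man"
.normalize_glycan_string <- function(text) {
  s <- text
  s <- gsub("β", "b", s)
  s <- gsub("α", "a", s)
  s <- gsub("→", ">", s)
  s <- gsub("->", ">", s, fixed = TRUE)
  s <- gsub("-\\((\\d)>(\\d)\\)-?", "\\1-\\2", s)
  s <- gsub("(\\d)>(\\d)", "\\1-\\2", s)
  s <- gsub("]-", "]", s, fixed = TRUE)
  gsub("[[:space:]]", "", s)
}

.residue_pattern <- function() {
  # longest tokens first so GlcNAc is not read as Glc
  nm <- residue_table$name[order(nchar(residue_table$name), decreasing = TRUE)]
  paste0("^(", paste(nm, collapse = "|"), ")")
}

#' Parse a condensed glycan string
#'
#' Grammar: residue tokens (see [residue_table]) optionally followed by an
#' anomeric letter \code{a}/\code{b}; non-terminal residues carry a linkage
#' \code{<anomeric carbon>-<parent position>} to the residue that follows;
#' branches are bracketed and precede their parent; the rightmost residue is
#' the reducing end and may carry suffixes \code{-OMe} (O1 methylated) and
#' \code{-18O<pos>} (heavy-oxygen label). Extended notation such as
#' \code{"GlcNAcβ-(1→2)-Man"} is normalized to the condensed form
#' before parsing.
#'
#' @param text glycan string, e.g. \code{"Manb1-2Manb-18O1"}.
#' @param adduct charge carrier, default sodium.
#' @return A \code{glycan} object: residue list, linkage table, root index
#'   and adduct.
#' @examples
#' parse_glycan("Manb1-2Manb")
#' parse_glycan("Manb-OMe")      # blocked reducing end
#' parse_glycan("Manb1-2Manb-18O1")
#' @export
parse_glycan <- function(text, adduct = "Na") {
  s <- .normalize_glycan_string(text)
  if (!nzchar(s)) stop("empty glycan string")
  st <- .parse_chain(s)
  if (nzchar(st$rest)) stop("trailing input in glycan string: ", st$rest)
  if (!is.null(st$pending_link)) {
    stop("glycan string ends with a dangling linkage")
  }
  g <- structure(list(
    residues = st$residues,
    linkages = st$linkages,
    root = st$root,
    adduct = adduct,
    source = text
  ), class = "glycan")
  validate_glycan(g)
}

# recursive-descent chain parser; returns residues, linkage rows, root index,
# an optional dangling linkage (inside brackets), and unconsumed input.
.parse_chain <- function(s) {
  residues <- list()
  links <- list()
  pending <- list()   # children (index + link info) awaiting their parent
  repeat {
    if (startsWith(s, "[")) {
      # bracketed branch: parse balanced group, must end in a dangling link
      depth <- 0L
      chars <- strsplit(s, "", fixed = TRUE)[[1]]
      close <- NA_integer_
      for (i in seq_along(chars)) {
        if (chars[i] == "[") depth <- depth + 1L
        if (chars[i] == "]") {
          depth <- depth - 1L
          if (depth == 0L) { close <- i; break }
        }
      }
      if (is.na(close)) stop("unbalanced bracket in glycan string")
      inner <- substr(s, 2L, close - 1L)
      st <- .parse_chain(inner)
      if (nzchar(st$rest)) stop("trailing input in branch: ", st$rest)
      if (is.null(st$pending_link)) stop("branch must end with a linkage")
      off <- length(residues)
      residues <- c(residues, st$residues)
      for (l in st$linkages_list) {
        l$child <- l$child + off; l$parent <- l$parent + off
        links[[length(links) + 1L]] <- l
      }
      pl <- st$pending_link
      pl$child <- st$root + off
      pending[[length(pending) + 1L]] <- pl
      s <- substr(s, close + 1L, nchar(s))
      next
    }
    m <- regmatches(s, regexpr(.residue_pattern(), s))
    if (!length(m)) stop("unknown residue token at: ", s)
    name <- m
    s <- substr(s, nchar(name) + 1L, nchar(s))
    anomeric <- ""
    if (grepl("^[ab]", s)) {
      anomeric <- substr(s, 1L, 1L)
      s <- substr(s, 2L, nchar(s))
    }
    res <- .new_residue(name, anomeric)
    # reducing-end / terminal suffixes
    repeat {
      sm <- regmatches(s, regexpr("^-(OMe|18O[1-6])", s))
      if (!length(sm)) break
      if (sm == "-OMe") {
        res$substituents[["1"]] <- "OMe"
      } else {
        pos <- sub("^-18O", "", sm)
        res$labels[[pos]] <- "18O"
      }
      s <- substr(s, nchar(sm) + 1L, nchar(s))
    }
    residues[[length(residues) + 1L]] <- res
    idx <- length(residues)
    # attach pending children to this residue
    for (pl in pending) {
      links[[length(links) + 1L]] <- list(
        child = pl$child, parent = idx,
        child_carbon = pl$child_carbon, parent_pos = pl$parent_pos,
        config = pl$config
      )
    }
    pending <- list()
    lm <- regmatches(s, regexpr("^([1-2])-([1-9])", s))
    if (length(lm)) {
      digs <- as.integer(strsplit(lm, "-", fixed = TRUE)[[1]])
      s <- substr(s, nchar(lm) + 1L, nchar(s))
      link <- list(child_carbon = digs[1], parent_pos = digs[2],
                   config = anomeric)
      if (!nzchar(s) || startsWith(s, "]")) {
        # dangling linkage: chain is a branch rooted at idx
        return(list(residues = residues, linkages_list = links,
                    linkages = .links_df(links), root = idx,
                    pending_link = c(link, list(child = idx)), rest = s))
      }
      pending[[length(pending) + 1L]] <- c(link, list(child = idx))
      next
    }
    # no linkage: idx is the (local) root
    return(list(residues = residues, linkages_list = links,
                linkages = .links_df(links), root = idx,
                pending_link = NULL, rest = s))
  }
}

.links_df <- function(links) {
  if (!length(links)) {
    return(data.frame(child = integer(0), parent = integer(0),
                      child_carbon = integer(0), parent_pos = integer(0),
                      config = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(links, function(l) {
    data.frame(child = l$child, parent = l$parent,
               child_carbon = l$child_carbon, parent_pos = l$parent_pos,
               config = l$config, stringsAsFactors = FALSE)
  }))
}

#' Validate a glycan object
#'
#' Checks tree shape (single root, acyclic, connected), linkage positions
#' (parent oxygen in 2/3/4/6, child carbon equal to the child's carbonyl
#' position), and that no oxygen carries both a glycosidic bond and a methyl
#' or label conflict.
#'
#' @param g glycan.
#' @return \code{g}, invisibly unchanged, or an error.
#' @export
validate_glycan <- function(g) {
  n <- length(g$residues)
  lk <- g$linkages
  if (nrow(lk) != n - 1L) stop("glycan is not a tree (wrong linkage count)")
  if (n > 1L) {
    has_parent <- tabulate(lk$child, n)
    if (any(has_parent > 1L)) stop("cyclic or multiply-linked residue")
    roots <- which(has_parent == 0L)
    if (length(roots) != 1L || roots != g$root) stop("glycan must have exactly one root")
    # connectivity: walk from root
    seen <- logical(n); seen[g$root] <- TRUE
    frontier <- g$root
    while (length(frontier)) {
      kids <- lk$child[lk$parent %in% frontier]
      kids <- kids[!seen[kids]]
      seen[kids] <- TRUE
      frontier <- kids
    }
    if (!all(seen)) stop("glycan tree is not connected")
  }
  for (i in seq_len(nrow(lk))) {
    if (!lk$parent_pos[i] %in% c(2L, 3L, 4L, 6L)) {
      stop("invalid linkage position: ", lk$parent_pos[i])
    }
    child <- g$residues[[lk$child[i]]]
    if (lk$child_carbon[i] != child$carbonyl_position) {
      stop("child anomeric carbon must equal its carbonyl position")
    }
    if (length(child$labels) &&
        as.character(child$carbonyl_position) %in% names(child$labels)) {
      stop("anomeric oxygen of a linked residue cannot carry a label")
    }
    # a parent oxygen may not carry both a linkage and a substituent
    parent <- g$residues[[lk$parent[i]]]
    if (!is.null(parent$substituents[[as.character(lk$parent_pos[i])]])) {
      stop("position ", lk$parent_pos[i], " carries both a linkage and a substituent")
    }
  }
  for (r in g$residues) {
    bad <- as.integer(names(r$labels)) > r$carbon_count
    if (length(bad) && any(bad)) stop("label position exceeds carbon count")
  }
  g
}

# --- serialization ---------------------------------------------------------

#' Serialize a glycan back to its condensed string
#'
#' Inverse of [parse_glycan()] on the supported grammar: the highest-position
#' child is written on the main chain, remaining children are bracketed.
#'
#' @param g glycan.
#' @return character scalar.
#' @export
serialize_glycan <- function(g) {
  ser <- function(idx) {
    r <- g$residues[[idx]]
    kids <- g$linkages[g$linkages$parent == idx, , drop = FALSE]
    kids <- kids[order(-kids$parent_pos), , drop = FALSE]
    pre <- ""
    if (nrow(kids)) {
      main <- kids[1, ]
      pre <- paste0(ser(main$child), main$child_carbon, "-", main$parent_pos)
      if (nrow(kids) > 1L) {
        for (j in 2:nrow(kids)) {
          b <- kids[j, ]
          pre <- paste0(pre, "[", ser(b$child), b$child_carbon, "-", b$parent_pos, "]")
        }
      }
    }
    suff <- ""
    if (identical(r$substituents[["1"]], "OMe")) suff <- paste0(suff, "-OMe")
    for (p in names(r$labels)) suff <- paste0(suff, "-18O", p)
    paste0(pre, r$name, r$anomeric, suff)
  }
  ser(g$root)
}

#' @export
print.glycan <- function(x, ...) {
  cat("<glycan> ", serialize_glycan(x), "  [M+", x$adduct, "]+\n", sep = "")
  cat("  residues: ", length(x$residues),
      "  formula: ", comp_formula(glycan_comp(x)),
      "  neutral mass: ", sprintf("%.4f", neutral_mass(x)), " Da\n", sep = "")
  invisible(x)
}

# --- composition -----------------------------------------------------------

#' Elemental composition of a monosaccharide
#'
#' @param m a residue entry of a glycan (or a residue name).
#' @param as_residue if TRUE return the glycosyl residue composition
#'   (free form minus H2O); otherwise the free monosaccharide.
#' @return composition vector (see [comp()]).
#' @examples
#' comp_formula(residue_formula("Glc"))                     # C6H12O6
#' comp_formula(residue_formula("GlcNAc", as_residue = TRUE)) # C8H13NO5
#' @export
residue_formula <- function(m, as_residue = FALSE) {
  if (is.character(m)) m <- .new_residue(m)
  x <- comp(C = 6, H = 12, O = 6)  # hexose, free
  for (pos in names(m$substituents)) {
    tok <- m$substituents[[pos]]
    if (tok == "NAc") {
      # OH at that carbon replaced by NH-C(=O)-CH3
      x <- comp_add(comp_sub(x, comp(O = 1, H = 1)), comp(C = 2, H = 4, N = 1, O = 1))
    } else if (tok == "OMe") {
      x <- comp_add(x, comp(C = 1, H = 2))
    } else stop("unsupported substituent: ", tok)
  }
  for (pos in names(m$labels)) {
    x <- comp_add(comp_sub(x, comp(O = 1)), comp(O18 = 1))
  }
  if (as_residue) x <- comp_sub(x, .comp_h2o())
  x
}

#' Neutral elemental composition of a glycan
#'
#' Sum of free residue compositions minus one water per glycosidic bond.
#'
#' @param g glycan.
#' @return composition vector.
#' @export
glycan_comp <- function(g) {
  x <- comp()
  for (r in g$residues) x <- comp_add(x, residue_formula(r))
  n_links <- nrow(g$linkages)
  if (n_links > 0L) x <- comp_sub(x, comp_times(.comp_h2o(), n_links))
  x
}

# residue indices of the subtree rooted at idx (inclusive)
.subtree <- function(g, idx) {
  out <- idx
  frontier <- idx
  while (length(frontier)) {
    kids <- g$linkages$child[g$linkages$parent %in% frontier]
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

# composition of the glycosyl group (subtree of idx) as attached to a parent
# oxygen: subtree neutral composition minus OH (the anomeric OH lost on
# condensation; the bridging oxygen belongs to the parent).
.glycosyl_comp <- function(g, idx) {
  ids <- .subtree(g, idx)
  x <- comp()
  for (i in ids) x <- comp_add(x, residue_formula(g$residues[[i]]))
  inner <- sum(g$linkages$parent %in% ids & g$linkages$child %in% ids)
  if (inner > 0L) x <- comp_sub(x, comp_times(.comp_h2o(), inner))
  comp_sub(x, comp(O = 1, H = 1))
}

#' JSON serialization of a glycan
#'
#' @param g glycan.
#' @param path optional file path; if NULL the JSON string is returned.
#' @return JSON string (invisibly if written to file).
#' @export
glycan_to_json <- function(g, path = NULL) {
  obj <- list(
    glycan = serialize_glycan(g),
    adduct = g$adduct,
    residues = lapply(g$residues, function(r) {
      list(name = r$name, anomeric = r$anomeric,
           carbonyl_position = r$carbonyl_position,
           substituents = r$substituents, labels = r$labels)
    }),
    linkages = g$linkages,
    root = g$root,
    formula = comp_formula(glycan_comp(g)),
    neutral_mass = neutral_mass(g)
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
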