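# Assembly, serialization and parsing of the canonical RInChI string.
#
# A RInChI is three groups of InChI bodies (the two sides of the arrow and
# the agents) plus a direction layer.  Identity of the string is the whole
# point, so the canonical form is fixed here once: per-group byte-wise
# sorting, byte-wise comparison of the two sides to decide which is
# group1, a single version header, and no trailing separators.

RINCHI_VERSION <- "0.02"
INCHI_VERSION <- "1S"
RINCHI_HEADER <- paste0("RInChI=", RINCHI_VERSION, ".", INCHI_VERSION, "/")

new_rinchi <- function(group1, group2, group3, direction,
                       extras = character()) {
  structure(
    list(group1 = as.character(group1), group2 = as.character(group2),
         group3 = as.character(group3), direction = direction,
         extras = as.character(extras)),
    class = "rinchi"
  )
}

#' @export
print.rinchi <- function(x, ...) {
  cat(rinchi_serialize(x), "\n")
  invisible(x)
}

#' @export
format.rinchi <- function(x, ...) rinchi_serialize(x)

#' Coerce to a `rinchi` object
#'
#' @param x A `rinchi` object or a RInChI string.
#' @return A `rinchi` object.
#' @export
as_rinchi <- function(x) {
  if (inherits(x, "rinchi")) return(x)
  if (is.character(x) && length(x) == 1L) return(rinchi_parse(x))
  stop_validation("cannot interpret input as a RInChI", rule = "type")
}

strip_inchi_prefix <- function(inchi) {
  if (!startsWith(inchi, "InChI=1S/"))
    stop_validation(
      sprintf("molecule InChI %s is not version 1S", dQuote(inchi)),
      rule = "inchi_version")
  substr(inchi, nchar("InChI=1S/") + 1L, nchar(inchi))
}

strip_auxinfo_prefix <- function(auxinfo) {
  if (is.null(auxinfo) || !nzchar(auxinfo)) return("")
  sub("^AuxInfo=1/", "", auxinfo)
}

#' Sort a group of InChI bodies
#'
#' The canonical group order.  `"bytewise"` reproduces `LC_ALL=C sort`
#' semantics on the full body, the behaviour the 0.02 identifier is
#' defined by.  `"major_then_minor"` sorts on the major-layer substring
#' first with the full body as tiebreak, an opt-in mode that keeps
#' molecules differing only in minor layers (e.g. enantiomers) adjacent
#' regardless of how the minor layers compare.  Duplicate entries are
#' preserved, never collapsed: they are the only stoichiometry-like signal
#' the identifier carries.
#'
#' @param inchis Character vector of InChI bodies (no `InChI=1S/` prefix).
#' @param mode `"bytewise"` (default) or `"major_then_minor"`.
#' @return The sorted character vector.
#' @export
sort_group <- function(inchis, mode = c("bytewise", "major_then_minor")) {
  mode <- match.arg(mode)
  if (length(inchis) <= 1L) return(as.character(inchis))
  if (mode == "bytewise") return(c_sort(inchis))
  majors <- vapply(inchis, function(b) split_major_minor(b)$major, character(1))
  inchis[c_order(majors, inchis)]
}

#' Build the canonical RInChI (and RAuxInfo) of a reaction
#'
#' Sorts the reactant and product InChIs within their groups, compares the
#' two sorted groups byte-wise and stores the smaller as group 1, records
#' the direction accordingly (`/d+` when the reactants ended up in group
#' 1, `/d-` when in group 2, `/d=` for an equilibrium reaction, no layer
#' when the direction is unknown), and carries the sorted agents as group
#' 3.  When exactly one side of the reaction is empty the populated side
#' becomes group 1, so a reaction with, say, no known product shows only
#' its first group.  When both sides are identical the direction layer is
#' dropped: forward and backward would be indistinguishable.  AuxInfo
#' entries are permuted identically into an aligned RAuxInfo.
#'
#' @param rxn A `reaction_record`.
#' @param sort_mode Passed to [sort_group()].
#' @return A list with elements `rinchi` (a `rinchi` object) and
#'   `rauxinfo` (a `rauxinfo` object).
#' @export
build_rinchi <- function(rxn, sort_mode = "bytewise") {
  stopifnot(inherits(rxn, "reaction_record"))

  side <- function(mols) {
    bodies <- vapply(mols, function(m) {
      if (is.null(m$inchi))
        stop_validation("all molecules need InChIs before a RInChI can be built",
                        rule = "missing_inchi")
      strip_inchi_prefix(m$inchi)
    }, character(1))
    aux <- vapply(mols, function(m) strip_auxinfo_prefix(m$auxinfo), character(1))
    ord <- if (length(bodies) > 1L) {
      if (sort_mode == "bytewise") c_order(bodies)
      else c_order(vapply(bodies, function(b) split_major_minor(b)$major,
                          character(1)), bodies)
    } else seq_along(bodies)
    list(bodies = unname(bodies[ord]), aux = unname(aux[ord]))
  }

  reactants <- rxn$reactants
  products <- rxn$products
  swapped_input <- identical(rxn$direction, "backward")
  if (swapped_input) { tmp <- reactants; reactants <- products; products <- tmp }

  r <- side(reactants)
  p <- side(products)
  a <- side(rxn$agents)

  rc <- paste(r$bodies, collapse = "")
  pc <- paste(p$bodies, collapse = "")

  reactants_first <-
    if (length(r$bodies) == 0L && length(p$bodies) > 0L) FALSE
    else if (length(p$bodies) == 0L) TRUE
    else c_order(c(rc, pc))[1L] == 1L   # byte-wise; stable order keeps ties TRUE

  g1 <- if (reactants_first) r else p
  g2 <- if (reactants_first) p else r

  direction <-
    if (identical(rxn$direction, "equilibrium")) "equilibrium"
    else if (identical(rxn$direction, "unspecified")) "omitted"
    else if (identical(rc, pc)) "omitted"     # identity reaction: +/- is meaningless
    else if (reactants_first) "plus"
    else "minus"

  list(
    rinchi = new_rinchi(g1$bodies, g2$bodies, a$bodies, direction),
    rauxinfo = structure(
      list(group1 = g1$aux, group2 = g2$aux, group3 = a$aux),
      class = "rauxinfo")
  )
}

# Groups as they appear in the serialized string: trailing empty groups
# (and their separators) are omitted.
rinchi_groups_for_output <- function(r) {
  groups <- list(r$group1, r$group2, r$group3)
  while (length(groups) > 0L && length(groups[[length(groups)]]) == 0L)
    groups[[length(groups)]] <- NULL
  groups
}

#' Serialize a RInChI to its canonical string
#'
#' `RInChI=0.02.1S/` followed by the groups -- InChI bodies joined by `//`
#' within a group, groups joined by `///` -- and the direction layer
#' (`/d+`, `/d-`, `/d=`, or nothing).  Trailing empty groups are omitted
#' together with their separators.  Serialization is injective: equal
#' strings mean equal identifiers.
#'
#' @param r A `rinchi` object.
#' @return The RInChI string.
#' @export
rinchi_serialize <- function(r) {
  stopifnot(inherits(r, "rinchi"))
  groups <- rinchi_groups_for_output(r)
  body <- paste(vapply(groups, paste, character(1), collapse = "//"),
                collapse = "///")
  dir_txt <- switch(r$direction, plus = "/d+", minus = "/d-",
                    equilibrium = "/d=", omitted = "")
  extras <- if (length(r$extras)) paste0("/", r$extras, collapse = "") else ""
  paste0(RINCHI_HEADER, body, dir_txt, extras)
}

#' Parse a RInChI string
#'
#' Exact inverse of [rinchi_serialize()].  Both header spellings seen in
#' the wild (`0.02.1S` and `0.02.1.S`) are accepted, as is one trailing
#' slash.  Groups must already be in canonical order: an unsorted group,
#' or a group 1 that compares byte-wise greater than group 2, is a
#' validation error, not something to repair silently.  Unknown layers
#' following the direction layer are preserved and re-emitted verbatim.
#'
#' @param text A string starting `RInChI=`.
#' @return A `rinchi` object.
#' @export
rinchi_parse <- function(text) {
  if (!is.character(text) || length(text) != 1L || !startsWith(text, "RInChI="))
    stop_validation("RInChI strings start with 'RInChI='", rule = "header")
  rest <- substr(text, nchar("RInChI=") + 1L, nchar(text))
  hdr <- regmatches(rest, regexec("^0\\.02\\.(1S|1\\.S)/", rest))[[1L]]
  if (length(hdr) == 0L)
    stop_validation(
      sprintf("unsupported RInChI version header in %s", dQuote(text)),
      rule = "header")
  rest <- substr(rest, nchar(hdr[1L]) + 1L, nchar(rest))
  rest <- sub("/$", "", rest)   # tolerated trailing slash

  direction <- "omitted"
  extras <- character()
  m <- regexpr("/d[+=-]", rest)
  if (m > 0L) {
    tail <- substr(rest, m, nchar(rest))
    rest <- substr(rest, 1L, m - 1L)
    dir_ch <- substr(tail, 3L, 3L)
    direction <- switch(dir_ch, "+" = "plus", "-" = "minus", "=" = "equilibrium")
    after <- substr(tail, 4L, nchar(tail))
    if (nzchar(after)) {
      if (!startsWith(after, "/"))
        stop_validation(sprintf("malformed direction layer in %s", dQuote(text)),
                        rule = "direction")
      extras <- strsplit(substr(after, 2L, nchar(after)), "/", fixed = TRUE)[[1L]]
    }
  }

  group_txt <- strsplit(rest, "///", fixed = TRUE)[[1L]]
  if (length(group_txt) > 3L)
    stop_validation("more than three molecule groups", rule = "group_count")
  groups <- lapply(seq_len(3L), function(i) {
    if (i > length(group_txt) || !nzchar(group_txt[i])) return(character())
    strsplit(group_txt[i], "//", fixed = TRUE)[[1L]]
  })

  for (i in 1:2) {
    g <- groups[[i]]
    if (length(g) > 1L && !identical(g, c_sort(g)))
      stop_validation(
        sprintf("group %d is not in canonical byte-wise order", i),
        rule = "group_sorted")
  }
  if (length(groups[[1L]]) == 0L && length(groups[[2L]]) > 0L)
    stop_validation("group 1 is empty while group 2 is not", rule = "group_order")
  if (length(groups[[1L]]) > 0L && length(groups[[2L]]) > 0L) {
    cc <- c(paste(groups[[1L]], collapse = ""), paste(groups[[2L]], collapse = ""))
    if (!identical(cc[1L], cc[2L]) && c_order(cc)[1L] != 1L)
      stop_validation("group 1 must compare byte-wise before group 2",
                      rule = "group_order")
  }

  new_rinchi(groups[[1L]], groups[[2L]], groups[[3L]], direction, extras)
}

# ---- RAuxInfo --------------------------------------------------------------

RAUXINFO_HEADER <- "RAuxInfo=0.02.1/"

#' Serialize / parse the RAuxInfo companion string
#'
#' The RAuxInfo mirrors the RInChI exactly: one AuxInfo body per molecule,
#' in the same groups and the same order, with the same `//` and `///`
#' separators under a `RAuxInfo=0.02.1/` label.  Molecules without
#' auxiliary information hold an empty slot.
#'
#' @param raux A `rauxinfo` object (aligned with its `rinchi`).
#' @return `rauxinfo_serialize()`: the string. `rauxinfo_parse()`: a
#'   `rauxinfo` object.
#' @export
rauxinfo_serialize <- function(raux) {
  stopifnot(inherits(raux, "rauxinfo"))
  groups <- list(raux$group1, raux$group2, raux$group3)
  while (length(groups) > 0L && length(groups[[length(groups)]]) == 0L)
    groups[[length(groups)]] <- NULL
  paste0(RAUXINFO_HEADER,
         paste(vapply(groups, paste, character(1), collapse = "//"),
               collapse = "///"))
}

#' @rdname rauxinfo_serialize
#' @param text A string starting `RAuxInfo=`.
#' @export
rauxinfo_parse <- function(text) {
  if (!startsWith(text, RAUXINFO_HEADER))
    stop_validation("RAuxInfo strings start with 'RAuxInfo=0.02.1/'",
                    rule = "header")
  rest <- substr(text, nchar(RAUXINFO_HEADER) + 1L, nchar(text))
  group_txt <- strsplit(rest, "///", fixed = TRUE)[[1L]]
  groups <- lapply(seq_len(3L), function(i) {
    if (i > length(group_txt) || !nzchar(group_txt[i])) return(character())
    strsplit(group_txt[i], "//", fixed = TRUE)[[1L]]
  })
  structure(list(group1 = groups[[1L]], group2 = groups[[2L]],
                 group3 = groups[[3L]]),
            class = "rauxinfo")
}

#' @export
print.rauxinfo <- function(x, ...) {
  cat(rauxinfo_serialize(x), "\n")
  invisible(x)
}

# ---- decoding --------------------------------------------------------------

#' Reconstruct a reaction from a RInChI
#'
#' Orients the groups by the direction layer (for `/d-` group 2 holds the
#' reactants), optionally regenerates molfiles through the InChI engine --
#' with coordinates when a RAuxInfo is supplied, at the origin otherwise
#' -- and returns a `reaction_record` ready for [write_rxn()].
#'
#' @param r A `rinchi` object or RInChI string.
#' @param rauxinfo Optional `rauxinfo` object or string.
#' @param molfiles Regenerate structure tables through the engine
#'   (default `TRUE`); with `FALSE` the records carry InChIs only.
#' @return A `reaction_record`.
#' @export
rinchi_to_reaction <- function(r, rauxinfo = NULL, molfiles = TRUE) {
  r <- as_rinchi(r)
  if (is.character(rauxinfo)) rauxinfo <- rauxinfo_parse(rauxinfo)

  mk_group <- function(bodies, aux) {
    lapply(seq_along(bodies), function(i) {
      inchi <- paste0("InChI=1S/", bodies[i])
      ai <- if (!is.null(aux) && length(aux) >= i && nzchar(aux[i]))
        paste0("AuxInfo=1/", aux[i]) else NULL
      mf <- if (molfiles) inchi_to_molfile(inchi, ai) else NA_character_
      mol_record(mf, inchi, ai)
    })
  }

  g1 <- mk_group(r$group1, rauxinfo$group1)
  g2 <- mk_group(r$group2, rauxinfo$group2)
  g3 <- mk_group(r$group3, rauxinfo$group3)

  if (identical(r$direction, "minus")) {
    reactants <- g2; products <- g1; dir <- "forward"
  } else {
    reactants <- g1; products <- g2
    dir <- switch(r$direction, plus = "forward",
                  equilibrium = "equilibrium", omitted = "unspecified")
  }
  reaction_record(reactants, products, g3, direction = dir,
                  source_id = rinchi_serialize(r))
}
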