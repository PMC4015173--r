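# Minimal MDL CTAB (molfile) V2000 reader/writer.
#
# Only the parts of the connection table that this package manipulates are
# modelled: the counts line, the atom block (coordinates + element symbol)
# and the bond block.  Property lines between the bond block and "M  END"
# are carried through verbatim so charges, isotopes etc. survive a
# read/write cycle.  V3000 input is rejected: the identifier tooling this
# package implements predates V3000-era reaction files.

#' Parse a V2000 molfile
#'
#' @param text A single string (or character vector of lines) holding one
#'   MDL molfile.
#' @return A list of class `ctab` with elements `title`, `program`,
#'   `comment`, `atoms` (data frame: `x`, `y`, `z`, `symbol`), `bonds`
#'   (data frame: `from`, `to`, `order`, `stereo`) and `properties`
#'   (character vector of raw property lines, excluding `M  END`).
#' @keywords internal
read_ctab <- function(text) {
  lines <- split_lines(text)
  if (length(lines) < 4L)
    stop_parse("molfile truncated: fewer than 4 header lines", line = length(lines))
  counts <- lines[4L]
  if (grepl("V3000", counts, fixed = TRUE))
    stop_parse("V3000 connection tables are not supported; supply V2000", line = 4L)
  natoms <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(natoms) || is.na(nbonds))
    stop_parse(sprintf("unreadable counts line: %s", dQuote(counts)), line = 4L)

  need <- 4L + natoms + nbonds
  if (length(lines) < need)
    stop_parse(sprintf("molfile declares %d atoms and %d bonds but ends early",
                       natoms, nbonds),
               line = length(lines))

  atoms <- if (natoms > 0L) {
    al <- lines[4L + seq_len(natoms)]
    data.frame(
      x = as.numeric(substr(al, 1L, 10L)),
      y = as.numeric(substr(al, 11L, 20L)),
      z = as.numeric(substr(al, 21L, 30L)),
      symbol = trimws(substr(al, 31L, 33L)),
      # columns after the symbol field (mass difference, charge, parity,
      # ...) are carried through verbatim so stereo parity survives
      tail = substr(al, 35L, nchar(al))
    )
  } else {
    data.frame(x = numeric(), y = numeric(), z = numeric(),
               symbol = character(), tail = character())
  }
  if (natoms > 0L && anyNA(atoms$x))
    stop_parse("unreadable atom coordinates",
               line = 4L + which(is.na(atoms$x))[1L])

  bonds <- if (nbonds > 0L) {
    bl <- lines[4L + natoms + seq_len(nbonds)]
    data.frame(
      from   = as.integer(substr(bl, 1L, 3L)),
      to     = as.integer(substr(bl, 4L, 6L)),
      order  = as.integer(substr(bl, 7L, 9L)),
      stereo = {
        s <- suppressWarnings(as.integer(substr(bl, 10L, 12L)))
        ifelse(is.na(s), 0L, s)
      }
    )
  } else {
    data.frame(from = integer(), to = integer(), order = integer(),
               stereo = integer())
  }
  if (nbonds > 0L &&
      (anyNA(bonds$from) || any(bonds$from > natoms) || any(bonds$to > natoms)))
    stop_parse("bond block references atoms outside the atom block",
               line = 4L + natoms + 1L)

  rest <- if (length(lines) > need) lines[(need + 1L):length(lines)] else character()
  endq <- which(trimws(rest) == "M  END")
  if (length(endq) == 0L)
    stop_parse("molfile has no 'M  END' terminator", line = length(lines))
  properties <- if (endq[1L] > 1L) rest[seq_len(endq[1L] - 1L)] else character()

  structure(
    list(title = lines[1L], program = lines[2L], comment = lines[3L],
         atoms = atoms, bonds = bonds, properties = properties),
    class = "ctab"
  )
}

#' Serialize a `ctab` back to V2000 molfile text
#'
#' @param ctab A list as returned by [read_ctab()].
#' @return A single string ending in `M  END` (no trailing newline).
#' @keywords internal
write_ctab <- function(ctab) {
  natoms <- nrow(ctab$atoms)
  nbonds <- nrow(ctab$bonds)
  counts <- sprintf("%3d%3d  0  0  1  0  0  0  0  0999 V2000", natoms, nbonds)
  tails <- ctab$atoms$tail
  if (is.null(tails) || all(!nzchar(tails)))
    tails <- rep(" 0  0  0  0  0  0  0  0  0  0  0  0", natoms)
  atom_lines <- if (natoms > 0L)
    sprintf("%10.4f%10.4f%10.4f %-3s%s",
            ctab$atoms$x, ctab$atoms$y, ctab$atoms$z, ctab$atoms$symbol,
            tails)
  else character()
  bond_lines <- if (nbonds > 0L)
    sprintf("%3d%3d%3d%3d  0  0  0",
            ctab$bonds$from, ctab$bonds$to, ctab$bonds$order, ctab$bonds$stereo)
  else character()
  paste(c(ctab$title %||% "", ctab$program %||% "", ctab$comment %||% "",
          counts, atom_lines, bond_lines, ctab$properties, "M  END"),
        collapse = "\n")
}

# Number of atoms declared by a molfile without fully parsing it.
ctab_atom_count <- function(text) {
  lines <- split_lines(text)
  if (length(lines) < 4L) return(NA_integer_)
  suppressWarnings(as.integer(substr(lines[4L], 1L, 3L)))
}
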