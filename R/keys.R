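# Hashed keys.
#
# Two families live here.  First, a from-scratch implementation of the
# standard InChIKey: SHA-256 digests of the major and minor layer parts,
# mapped to uppercase letters through the official base-26 triplet/doublet
# encoding.  It reproduces the official key byte for byte and is the
# building block of the long reaction keys.  Second, the reaction-level
# hashed blocks (hash_block) used by the four RInChIKey variants; these use
# the same SHA-256 + base-26 letter encoding with a caller-chosen length.

# ---- base-26 encoding ------------------------------------------------------

# The official letter tables.  Triplets encode 14 bits each: all three-
# letter strings whose first letter is not 'E', in lexicographic order,
# with the contiguous block "TAA".."TTV" removed to leave exactly 2^14
# entries.  Doublets encode 9 bits: plain base-26 pairs "AA".."TR".
.b26 <- new.env(parent = emptyenv())

b26_tables <- function() {
  if (is.null(.b26$trip)) {
    a25 <- LETTERS[-5L]
    full <- paste0(rep(a25, each = 26L * 26L),
                   rep(rep(LETTERS, each = 26L), times = 25L),
                   rep(LETTERS, times = 25L * 26L))
    .b26$trip <- full[-(12169:12684)]            # drop "TAA".."TTV"
    stopifnot(length(.b26$trip) == 16384L)
    .b26$dub <- paste0(rep(LETTERS, each = 26L), LETTERS)[1:512]
  }
  list(trip = .b26$trip, dub = .b26$dub)
}

sha256_raw <- function(text) {
  digest::digest(text, algo = "sha256", serialize = FALSE, raw = TRUE)
}

# n-bit little-endian value starting at bit `lo` (0-based) of a raw digest:
# bit j of the stream is bit (j mod 8) of byte j %/% 8.
bits_le <- function(bytes, lo, n) {
  v <- 0L
  for (k in 0:(n - 1L)) {
    j <- lo + k
    bit <- bitwAnd(bitwShiftR(bytes[j %/% 8L + 1L], j %% 8L), 1L)
    v <- v + bitwShiftL(bit, k)
  }
  v
}

# `ntrip` triplets followed by one doublet -- the layout of both InChIKey
# hash blocks (4 triplets + doublet for the skeleton, 2 + doublet for the
# stereo block).
digest_block <- function(text, ntrip) {
  tb <- b26_tables()
  d <- as.integer(sha256_raw(text))
  out <- character(ntrip + 1L)
  for (i in seq_len(ntrip))
    out[i] <- tb$trip[bits_le(d, 14L * (i - 1L), 14L) + 1L]
  out[ntrip + 1L] <- tb$dub[bits_le(d, 14L * ntrip, 9L) + 1L]
  paste(out, collapse = "")
}

#' Hash text to a fixed-length block of uppercase letters
#'
#' SHA-256 of the UTF-8 text, encoded through the official InChIKey
#' base-26 triplet tables and truncated to `length` letters.  Truncation
#' is a prefix operation: `hash_block(s, n)` is always a prefix of
#' `hash_block(s, n + 1)`.  The empty string hashes like any other input.
#'
#' @param text Character scalar to hash.
#' @param length Number of letters to return (1--54).
#' @return A string of `length` uppercase letters.
#' @export
hash_block <- function(text, length) {
  stopifnot(length >= 1L, length <= 54L)
  tb <- b26_tables()
  d <- as.integer(sha256_raw(text))
  ntrip <- ceiling(length / 3)
  letters54 <- vapply(seq_len(ntrip), function(i)
    tb$trip[bits_le(d, 14L * (i - 1L), 14L) + 1L], character(1))
  substr(paste(letters54, collapse = ""), 1L, length)
}

# ---- standard InChIKey -----------------------------------------------------

# 'N' means net protonation zero; +1.. counts up through O, P, ..., -1..
# counts down through M, L, ...; out-of-range values clamp with a warning.
protonation_letter <- function(p) {
  idx <- 14L + p
  if (idx < 1L || idx > 26L) {
    warning(sprintf("protonation %+d outside encodable range; clamping", p))
    idx <- min(26L, max(1L, idx))
  }
  substr("ABCDEFGHIJKLMNOPQRSTUVWXYZ", idx, idx)
}

#' Standard InChIKey of an InChI
#'
#' Computes the 27-character standard InChIKey from an `InChI=1S/...`
#' string: a 14-letter hash of the major layers (formula, connectivity,
#' hydrogens, charge), a hyphen, an 8-letter hash of the remaining layers
#' plus the standard/version letters `SA`, a hyphen, and the protonation
#' letter.  The minor part, when shorter than 255 bytes, is extended by
#' one copy of itself before hashing, matching the official algorithm; the
#' result is byte-identical to the key the official InChI software prints.
#'
#' @param inchi A standard InChI string.
#' @return The 27-character InChIKey.
#' @export
inchikey <- function(inchi) {
  if (!is.character(inchi) || length(inchi) != 1L || !startsWith(inchi, "InChI=1S/"))
    stop_validation("inchikey() requires a standard InChI ('InChI=1S/...')",
                    rule = "inchi_prefix")
  body <- substr(inchi, nchar("InChI=1S/") + 1L, nchar(inchi))
  sp <- split_major_minor(body)
  minor <- sp$minor
  if (nzchar(minor)) {
    minor <- paste0("/", minor)
    if (nchar(minor) < 255L) minor <- paste0(minor, minor)
  }
  paste0(digest_block(sp$major, 4L), "-",
         digest_block(minor, 2L), "SA-",
         protonation_letter(sp$protonation))
}

# ---- reaction keys ---------------------------------------------------------

direction_letter <- function(direction) {
  switch(direction, plus = "F", minus = "B", equilibrium = "E", omitted = "U",
         stop_validation(sprintf("unknown direction %s", dQuote(direction)),
                         rule = "direction"))
}

# The "additional layers" of a RInChI are everything after the three
# molecule groups: today the direction layer plus any preserved unknown
# trailing layers.
reaction_layer_string <- function(r, include_direction = TRUE) {
  dir_txt <- switch(r$direction, plus = "/d+", minus = "/d-",
                    equilibrium = "/d=", omitted = "")
  extras <- if (length(r$extras)) paste0("/", r$extras, collapse = "") else ""
  if (include_direction) paste0(dir_txt, extras) else extras
}

key_block1 <- function(version) paste0(tolower(version), "SA")

key_block2 <- function(r, version) {
  if (version == "A") {
    hash_block(reaction_layer_string(r, include_direction = TRUE), 5L)
  } else {
    paste0(direction_letter(r$direction),
           hash_block(reaction_layer_string(r, include_direction = FALSE), 4L))
  }
}

#' Long RInChIKey
#'
#' Variable-length key listing the standard InChIKey of every molecule in
#' the reaction, in RInChI group order.  Block 1 identifies the key
#' version (`aSA`/`bSA`), block 2 hashes the additional reaction layers
#' (version A) or spells the direction as `F`/`B`/`E`/`U` followed by a
#' hash of the remaining additional layers (version B).  Molecules within
#' a group are joined by single hyphens; the group boundaries that a
#' RInChI marks with `///` appear as a double hyphen.
#'
#' @param r A `rinchi` object (or RInChI string).
#' @param version `"A"` or `"B"`; the two differ only in block 2.
#' @return The key string.
#' @export
long_rinchikey <- function(r, version = c("A", "B")) {
  version <- match.arg(version)
  r <- as_rinchi(r)
  groups <- rinchi_groups_for_output(r)
  group_txt <- vapply(groups, function(g)
    paste(vapply(g, function(b) inchikey(paste0("InChI=1S/", b)), character(1)),
          collapse = "-"),
    character(1))
  head <- paste0(key_block1(version), "-", key_block2(r, version))
  if (length(group_txt) == 0L) return(head)
  paste0(head, "-", paste(group_txt, collapse = "--"))
}

#' Short RInChIKey
#'
#' Fixed-length key hashed directly from the RInChI string, independent of
#' the number of molecules.  Version A follows block 1 and the version-A
#' block 2 with exactly three 15-letter blocks, one per molecule group
#' (hashed even when the group is empty).  Version B carries the direction
#' letter in block 2, then three 10-letter hashes of the groups' major
#' layers (formula, connectivity, hydrogens, charge), then three 5-letter
#' minor blocks whose first letter encodes the group's net protonation and
#' whose remaining four letters hash the minor layers.
#'
#' @inheritParams long_rinchikey
#' @return The key string.
#' @export
short_rinchikey <- function(r, version = c("A", "B")) {
  version <- match.arg(version)
  r <- as_rinchi(r)
  groups <- list(r$group1, r$group2, r$group3)
  head <- paste0(key_block1(version), "-", key_block2(r, version))
  if (version == "A") {
    blocks <- vapply(groups, function(g)
      hash_block(paste(unlist(g), collapse = "//"), 15L), character(1))
    return(paste(c(head, blocks), collapse = "-"))
  }
  majors <- character(3); minors <- character(3)
  for (i in 1:3) {
    sp <- lapply(groups[[i]], split_major_minor)
    majors[i] <- hash_block(
      paste(vapply(sp, `[[`, character(1), "major"), collapse = "//"), 10L)
    p <- sum(vapply(sp, `[[`, numeric(1), "protonation"))
    minors[i] <- paste0(
      protonation_letter(as.integer(p)),
      hash_block(paste(vapply(sp, `[[`, character(1), "minor"), collapse = "//"), 4L))
  }
  paste(c(head, majors, minors), collapse = "-")
}

#' All four hashed keys of a RInChI
#'
#' @inheritParams long_rinchikey
#' @return A list of class `rinchi_key_bundle` with elements `long_a`,
#'   `long_b`, `short_a`, `short_b`.
#' @export
rinchikey_bundle <- function(r) {
  r <- as_rinchi(r)
  structure(
    list(long_a = long_rinchikey(r, "A"),
         long_b = long_rinchikey(r, "B"),
         short_a = short_rinchikey(r, "A"),
         short_b = short_rinchikey(r, "B")),
    class = "rinchi_key_bundle"
  )
}

#' @export
print.rinchi_key_bundle <- function(x, ...) {
  cat("Long-RInChIKey-A =", x$long_a, "\n")
  cat("Long-RInChIKey-B =", x$long_b, "\n")
  cat("Short-RInChIKey-A =", x$short_a, "\n")
  cat("Short-RInChIKey-B =", x$short_b, "\n")
  invisible(x)
}
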