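# Decomposition of InChI strings into layers.
#
# The identifier's layered grammar is parsed far enough to support the
# reaction-level tooling: the connectivity layer becomes an explicit edge
# list (so rings can be counted without ever touching a structure file),
# stereo layers become entry counts, and the layers are split into the
# major part (formula, connectivity, hydrogens, charge) and the minor part
# (everything else) that the hashed short keys are built from.

LAYER_PREFIXES <- c("c", "h", "q", "p", "b", "t", "m", "s", "i")
MAJOR_PREFIXES <- c("c", "h", "q")

# ---- formula ---------------------------------------------------------------

# "C6H12O6" -> named integer vector of element counts.
parse_formula_counts <- function(formula) {
  if (!nzchar(formula)) return(integer())
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1L]]
  toks <- regmatches(formula, list(m))[[1L]]
  el <- sub("[0-9]*$", "", toks)
  n <- sub("^[A-Z][a-z]?", "", toks)
  counts <- ifelse(nzchar(n), suppressWarnings(as.integer(n)), 1L)
  if (anyNA(counts))
    stop_parse(sprintf("unreadable formula %s", dQuote(formula)))
  stats::setNames(as.integer(counts), el)
}

heavy_atom_count <- function(formula) {
  counts <- parse_formula_counts(formula)
  sum(counts[names(counts) != "H"])
}

# Split a Hill formula of a (possibly multi-component) InChI into one
# formula per component: "2C2H6O.H2O" -> c("C2H6O","C2H6O","H2O").
split_formula_components <- function(formula) {
  if (!nzchar(formula)) return(character())
  parts <- strsplit(formula, ".", fixed = TRUE)[[1L]]
  out <- character()
  for (p in parts) {
    m <- regmatches(p, regexec("^([0-9]+)([A-Z].*)$", p))[[1L]]
    if (length(m) == 3L) {
      out <- c(out, rep(m[3L], as.integer(m[2L])))
    } else {
      out <- c(out, p)
    }
  }
  out
}

# Expand a ';'-separated per-component layer, honouring "n*" repetition:
# "2*1-2-3;4-5" -> c("1-2-3","1-2-3","4-5").  Empty slots stay "".
split_layer_components <- function(text, n_components) {
  if (is.null(text) || !nzchar(text)) return(rep("", n_components))
  parts <- strsplit(text, ";", fixed = TRUE)[[1L]]
  if (length(parts) == 0L) parts <- ""
  out <- character()
  for (p in parts) {
    m <- regmatches(p, regexec("^([0-9]+)\\*(.*)$", p))[[1L]]
    if (length(m) == 3L) {
      out <- c(out, rep(m[3L], as.integer(m[2L])))
    } else {
      out <- c(out, p)
    }
  }
  length(out) <- n_components
  out[is.na(out)] <- ""
  out
}

# ---- connectivity layer ----------------------------------------------------

# Decode one component's c-layer into an edge matrix.  The grammar is the
# published InChI connection-table walk: numbers are atoms in canonical
# order, '-' continues a chain, parentheses open branches, ',' starts a
# sibling branch from the same branch point, and a repeated number closes a
# ring.  Ring closures are what make edges - atoms + 1 the ring count, so
# they must be decoded as real edges, not skipped.
parse_clayer <- function(text, n_heavy, layer_name = "c") {
  if (!nzchar(text))
    return(matrix(integer(), ncol = 2L, dimnames = list(NULL, c("from", "to"))))
  toks <- regmatches(text, gregexpr("[0-9]+|[()\\,-]|\\?|\\*", text))[[1L]]
  if (sum(nchar(toks)) != nchar(text))
    stop_parse(sprintf("malformed %s layer: %s", layer_name, dQuote(text)))
  cur <- NA_integer_
  stack <- integer()
  from <- integer(); to <- integer()
  for (tok in toks) {
    if (tok == "(") {
      stack <- c(stack, cur)
    } else if (tok == ")") {
      if (length(stack) == 0L)
        stop_parse(sprintf("unbalanced ')' in %s layer %s", layer_name, dQuote(text)))
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (tok == ",") {
      if (length(stack) == 0L)
        stop_parse(sprintf("',' outside a branch in %s layer %s", layer_name, dQuote(text)))
      cur <- stack[length(stack)]
    } else if (tok == "-" || tok == "?" || tok == "*") {
      # '-' separates numbers; '?'/'*' markers carry no connectivity here
    } else {
      n <- as.integer(tok)
      if (n < 1L || n > n_heavy)
        stop_parse(sprintf("atom %d outside formula heavy-atom count %d in %s layer",
                           n, n_heavy, layer_name))
      if (!is.na(cur)) { from <- c(from, cur); to <- c(to, n) }
      cur <- n
    }
  }
  cbind(from = from, to = to)
}

# ---- layered InChI ---------------------------------------------------------

# Raw split of an InChI body into the formula and a named list of prefixed
# layers (first occurrence wins; standard InChIs do not repeat layers).
split_inchi_layers <- function(body) {
  parts <- strsplit(body, "/", fixed = TRUE)[[1L]]
  formula <- if (length(parts) >= 1L) parts[1L] else ""
  layers <- list()
  extra <- character()
  for (p in parts[-1L]) {
    if (!nzchar(p)) next
    pre <- substr(p, 1L, 1L)
    if (pre %in% LAYER_PREFIXES && is.null(layers[[pre]])) {
      layers[[pre]] <- substr(p, 2L, nchar(p))
    } else {
      extra <- c(extra, p)
    }
  }
  list(formula = formula, layers = layers, extra = extra)
}

# Sum a charge-like layer ("+1", "-2;+1", "2*-1") across components.
sum_charge_layer <- function(text) {
  if (is.null(text) || !nzchar(text)) return(0L)
  total <- 0L
  for (p in strsplit(text, ";", fixed = TRUE)[[1L]]) {
    if (!nzchar(p)) next
    m <- regmatches(p, regexec("^([0-9]+)\\*(.*)$", p))[[1L]]
    mult <- 1L
    if (length(m) == 3L) { mult <- as.integer(m[2L]); p <- m[3L] }
    v <- suppressWarnings(as.integer(p))
    if (is.na(v)) stop_parse(sprintf("unreadable charge layer entry %s", dQuote(p)))
    total <- total + mult * v
  }
  total
}

count_stereo_entries <- function(text) {
  if (!nzchar(text)) return(character())
  ent <- strsplit(text, ",", fixed = TRUE)[[1L]]
  ent[nzchar(ent)]
}

#' Parse an InChI string into layers
#'
#' Splits a standard InChI into its named layers, decodes the connectivity
#' layer into an explicit heavy-atom edge list, and separates the major
#' part (formula, connectivity, hydrogens, charge) from the minor part
#' (stereo, isotope and protonation layers).
#'
#' @param inchi A string beginning `"InChI=1S/"`.
#' @return An object of class `parsed_inchi`: a list with the full
#'   `formula`, a global `connectivity` edge matrix (atom indices offset so
#'   components do not overlap), `h_layer`, `charge_q`, `protonation_p`,
#'   stereo descriptor vectors `stereo_t`, `stereo_b`, `stereo_m_s`,
#'   `component_count`, `n_heavy`, per-component detail under `components`,
#'   and the `major`/`minor` layer strings.
#' @export
parse_inchi_layers <- function(inchi) {
  if (!is.character(inchi) || length(inchi) != 1L || !startsWith(inchi, "InChI=1S/"))
    stop_validation("expected a standard InChI beginning 'InChI=1S/'",
                    rule = "inchi_prefix")
  body <- substr(inchi, nchar("InChI=1S/") + 1L, nchar(inchi))
  sp <- split_inchi_layers(body)

  formulas <- split_formula_components(sp$formula)
  ncomp <- max(1L, length(formulas))
  if (length(formulas) == 0L) formulas <- ""

  c_comp <- split_layer_components(sp$layers[["c"]], ncomp)
  h_comp <- split_layer_components(sp$layers[["h"]], ncomp)
  t_comp <- split_layer_components(sp$layers[["t"]], ncomp)
  b_comp <- split_layer_components(sp$layers[["b"]], ncomp)
  m_comp <- split_layer_components(sp$layers[["m"]], ncomp)
  s_layer <- sp$layers[["s"]] %||% ""

  components <- vector("list", ncomp)
  offset <- 0L
  all_from <- integer(); all_to <- integer()
  for (i in seq_len(ncomp)) {
    nh <- heavy_atom_count(formulas[i])
    edges <- parse_clayer(c_comp[i], nh)
    components[[i]] <- list(
      formula = formulas[i],
      n_heavy = nh,
      edges = edges,
      h = h_comp[i],
      t = count_stereo_entries(t_comp[i]),
      b = count_stereo_entries(b_comp[i]),
      m = m_comp[i],
      # one connected piece: independent rings = edges - atoms + 1
      rings = if (nh > 0L) nrow(edges) - nh + 1L else 0L
    )
    if (nrow(edges) > 0L) {
      all_from <- c(all_from, edges[, 1L] + offset)
      all_to <- c(all_to, edges[, 2L] + offset)
    }
    offset <- offset + nh
  }

  major <- paste(
    c(sp$formula,
      unlist(lapply(MAJOR_PREFIXES, function(p)
        if (!is.null(sp$layers[[p]])) paste0(p, sp$layers[[p]]) else character()))),
    collapse = "/")
  minor_layers <- setdiff(names(sp$layers), MAJOR_PREFIXES)
  minor <- paste(
    vapply(minor_layers, function(p) paste0(p, sp$layers[[p]]), character(1)),
    collapse = "/")

  structure(
    list(
      inchi = inchi,
      formula = sp$formula,
      connectivity = cbind(from = all_from, to = all_to),
      h_layer = sp$layers[["h"]] %||% "",
      charge_q = sum_charge_layer(sp$layers[["q"]]),
      protonation_p = sum_charge_layer(sp$layers[["p"]]),
      stereo_t = unlist(lapply(components, `[[`, "t")) %||% character(),
      stereo_b = unlist(lapply(components, `[[`, "b")) %||% character(),
      stereo_m_s = c(m = sp$layers[["m"]] %||% "", s = s_layer),
      component_count = ncomp,
      n_heavy = offset,
      components = components,
      major = major,
      minor = minor,
      extra = sp$extra
    ),
    class = "parsed_inchi"
  )
}

#' @export
print.parsed_inchi <- function(x, ...) {
  cat("<parsed_inchi>", x$inchi, "\n")
  cat(sprintf("  %d heavy atoms, %d edges, %d component(s), %d ring(s)\n",
              x$n_heavy, nrow(x$connectivity), x$component_count,
              inchi_ring_count(x)))
  invisible(x)
}

#' Cyclomatic ring count of a parsed InChI
#'
#' Independent rings of the heavy-atom graph: edges - atoms + components.
#'
#' @param parsed A `parsed_inchi` (or an InChI string, parsed on the fly).
#' @return Integer ring count.
#' @export
inchi_ring_count <- function(parsed) {
  if (is.character(parsed)) parsed <- parse_inchi_layers(parsed)
  # summed per component so hydrogen-only components (0 heavy atoms)
  # contribute nothing
  sum(vapply(parsed$components, `[[`, integer(1), "rings"))
}

# Major/minor split of a bare InChI body (no "InChI=1S/" prefix), as used
# by the short-B key blocks.  Returns the two substrings plus the total
# protonation so the flag letter can be derived without reparsing.
split_major_minor <- function(body) {
  sp <- split_inchi_layers(body)
  major <- paste(
    c(sp$formula,
      unlist(lapply(MAJOR_PREFIXES, function(p)
        if (!is.null(sp$layers[[p]])) paste0(p, sp$layers[[p]]) else character()))),
    collapse = "/")
  minor_layers <- setdiff(names(sp$layers), c(MAJOR_PREFIXES, "p"))
  minor <- paste(
    vapply(minor_layers, function(p) paste0(p, sp$layers[[p]]), character(1)),
    collapse = "/")
  list(major = major, minor = minor,
       protonation = sum_charge_layer(sp$layers[["p"]]))
}
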