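# Peptidoform: a peptide sequence plus its modifications (charge-agnostic).

#' Construct a peptidoform
#'
#' @param sequence Peptide sequence (canonical one-letter codes).
#' @param mods Tibble/data frame with columns `position` (1-based residue
#'   index, 0 for the N-terminus), `mass_delta` (Da) and `name`, or `NULL`
#'   for an unmodified peptide.
#'
#' @return An object of class `peptidoform`.
#' @export
peptidoform <- function(sequence, mods = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) >= 1L)
  residues <- strsplit(sequence, "")[[1]]
  bad <- setdiff(residues, names(AA_MONO))
  if (length(bad) > 0L) {
    stop("non-canonical residue(s) in sequence: ", paste(unique(bad), collapse = ", "))
  }
  if (is.null(mods)) {
    mods <- tibble::tibble(position = integer(), mass_delta = numeric(), name = character())
  } else {
    mods <- tibble::as_tibble(mods)
    stopifnot(all(c("position", "mass_delta", "name") %in% names(mods)))
    if (any(mods$position < 0L | mods$position > nchar(sequence))) {
      stop("modification position outside [0, peptide length]")
    }
    mods <- dplyr::arrange(mods, .data$position)
  }
  structure(list(sequence = sequence, mods = mods), class = "peptidoform")
}

#' @export
print.peptidoform <- function(x, ...) {
  cat("<peptidoform>", format_modified_sequence(x), "\n")
  invisible(x)
}

#' @export
length.peptidoform <- function(x) nchar(x$sequence)

#' Parse a modified peptide sequence
#'
#' Parses UniMod parenthetical notation as used in DIA-NN style reports, e.g.
#' `"PEPTC(UniMod:4)K"`. Mass deltas are resolved from the internal
#' modification table (see [modification_table()]); a tag immediately
#' following the opening residue position applies to that residue, and a tag
#' before the first residue applies to the N-terminus (position 0).
#'
#' @param text Modified sequence string.
#' @param notation Only `"unimod_parenthetical"` is supported.
#'
#' @return A [peptidoform()].
#' @export
#'
#' @examples
#' parse_modified_sequence("PEPTC(UniMod:4)K")
parse_modified_sequence <- function(text, notation = "unimod_parenthetical") {
  notation <- match.arg(notation, "unimod_parenthetical")
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "")[[1]]
  seq_chars <- character(0)
  positions <- integer(0)
  deltas <- numeric(0)
  mod_names <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "(") {
      j <- which(chars[-seq_len(i)] == ")")[1]
      if (is.na(j)) stop("unbalanced '(' in modified sequence: ", text)
      tag <- paste(chars[(i + 1L):(i + j - 1L)], collapse = "")
      hit <- match(tag, UNIMOD_TABLE$tag)
      if (is.na(hit)) stop("unknown modification tag: ", tag)
      positions <- c(positions, length(seq_chars))
      deltas <- c(deltas, UNIMOD_TABLE$mass_delta[hit])
      mod_names <- c(mod_names, UNIMOD_TABLE$name[hit])
      i <- i + j + 1L
    } else {
      seq_chars <- c(seq_chars, ch)
      i <- i + 1L
    }
  }
  peptidoform(
    paste(seq_chars, collapse = ""),
    if (length(positions)) {
      tibble::tibble(position = positions, mass_delta = deltas, name = mod_names)
    } else NULL
  )
}

#' Format a peptidoform back to UniMod parenthetical notation
#'
#' Inverse of [parse_modified_sequence()].
#'
#' @param pf A [peptidoform()].
#' @return A modified-sequence string.
#' @export
format_modified_sequence <- function(pf) {
  stopifnot(inherits(pf, "peptidoform"))
  if (nrow(pf$mods) == 0L) return(pf$sequence)
  tags <- UNIMOD_TABLE$tag[match(pf$mods$name, UNIMOD_TABLE$name)]
  if (anyNA(tags)) stop("modification not in internal table: ",
                        paste(pf$mods$name[is.na(tags)], collapse = ", "))
  chars <- strsplit(pf$sequence, "")[[1]]
  out <- character(0)
  for (p in 0:length(chars)) {
    if (p > 0L) out <- c(out, chars[p])
    sel <- which(pf$mods$position == p)
    for (s in sel) out <- c(out, paste0("(", tags[s], ")"))
  }
  paste(out, collapse = "")
}

# per-residue mod mass deltas (index 1..L; N-term delta folded into residue 1)
mod_deltas_by_residue <- function(pf) {
  d <- numeric(length(pf))
  if (nrow(pf$mods) > 0L) {
    for (k in seq_len(nrow(pf$mods))) {
      pos <- max(1L, pf$mods$position[k])
      d[pos] <- d[pos] + pf$mods$mass_delta[k]
    }
  }
  d
}

# 1-based positions carrying a phospho group
phospho_positions <- function(pf) {
  if (nrow(pf$mods) == 0L) return(integer(0))
  pmax(1L, pf$mods$position[pf$mods$name == "Phospho"])
}
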