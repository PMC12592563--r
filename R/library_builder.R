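# In silico digestion, peptidoform/precursor expansion, prediction
# orchestration, filtering and library emission.

#' Digestion and precursor-expansion parameters
#'
#' Defaults mirror common DIA search settings: Trypsin/P (cleave after K/R,
#' no proline suppression), one missed cleavage, peptide length 7-35,
#' carbamidomethyl C fixed, charges 2-4. N-terminal methionine excision is
#' not applied.
#'
#' @param enzyme Only `"trypsin_p"` is supported.
#' @param max_missed_cleavages Maximum internal cleavage sites per peptide.
#' @param length_range Peptide length range (amino acids).
#' @param fixed_mods Named numeric-free spec: character vector of
#'   `residue = modification name` pairs, default carbamidomethyl on C.
#' @param variable_mods As `fixed_mods`; applied combinatorially up to
#'   `max_variable_mods` per peptide. Default none; phospho mode sets
#'   `c(S = "Phospho", T = "Phospho", Y = "Phospho")`.
#' @param max_variable_mods Maximum number of variable modifications.
#' @param charge_range Precursor charges to enumerate.
#' @return A `digest_params` list.
#' @export
digest_params <- function(enzyme = "trypsin_p", max_missed_cleavages = 1L,
                          length_range = c(7L, 35L),
                          fixed_mods = c(C = "Carbamidomethyl"),
                          variable_mods = character(0),
                          max_variable_mods = 1L,
                          charge_range = 2:4) {
  enzyme <- match.arg(enzyme, "trypsin_p")
  if (length_range[1] < 1L) stop("configuration error: min peptide length >= 1")
  if (length(charge_range) == 0L) stop("configuration error: empty charge range")
  structure(list(enzyme = enzyme,
                 max_missed_cleavages = as.integer(max_missed_cleavages),
                 length_range = as.integer(length_range),
                 fixed_mods = fixed_mods, variable_mods = variable_mods,
                 max_variable_mods = as.integer(max_variable_mods),
                 charge_range = as.integer(charge_range)),
            class = "digest_params")
}

fasta_as_vector <- function(fasta) {
  if (is.character(fasta) && length(fasta) == 1L && grepl(">", fasta, fixed = TRUE) &&
      grepl("\n", fasta, fixed = TRUE)) {
    tmp <- tempfile(fileext = ".fasta")
    on.exit(unlink(tmp))
    writeLines(fasta, tmp)
    return(read_fasta(tmp))
  }
  if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    return(read_fasta(fasta))
  }
  if (is.character(fasta) && !is.null(names(fasta))) return(fasta)
  stop("data error: fasta must be FASTA text, a file path, or a named ",
       "character vector of protein sequences")
}

#' In silico tryptic digestion
#'
#' Cleaves after every K/R (Trypsin/P: no proline suppression), joins up to
#' `max_missed_cleavages` adjacent fully-cleaved segments, filters by length
#' and maps every peptide to all proteins it occurs in.
#'
#' @param fasta FASTA text, a path, or a named character vector of protein
#'   sequences.
#' @param params A [digest_params()].
#' @return Tibble with columns `peptide` and `protein_ids` (semicolon-joined
#'   source protein identifiers).
#' @export
#'
#' @examples
#' digest_fasta(c(p1 = "MKRAAAKLLLR"), digest_params())
digest_fasta <- function(fasta, params = digest_params()) {
  proteins <- fasta_as_vector(fasta)
  if (length(proteins) == 0L) stop("data error: empty FASTA")
  acc <- new.env(parent = emptyenv())
  for (pi in seq_along(proteins)) {
    prot <- proteins[[pi]]
    id <- names(proteins)[pi]
    segs <- tryptic_segments(prot)
    nseg <- length(segs)
    if (nseg == 0L) next
    for (i in seq_len(nseg)) {
      for (m in 0:params$max_missed_cleavages) {
        j <- i + m
        if (j > nseg) break
        pep <- paste(segs[i:j], collapse = "")
        L <- nchar(pep)
        if (L < params$length_range[1] || L > params$length_range[2]) next
        if (grepl("[^A-Z]", pep) ||
            !all(strsplit(pep, "")[[1]] %in% names(AA_MONO))) next
        prev <- acc[[pep]]
        acc[[pep]] <- if (is.null(prev)) id else union(prev, id)
      }
    }
  }
  peps <- ls(acc)
  if (length(peps) == 0L) {
    return(tibble::tibble(peptide = character(), protein_ids = character()))
  }
  tibble::tibble(
    peptide = peps,
    protein_ids = vapply(peps, function(p) paste(sort(acc[[p]]), collapse = ";"),
                         character(1), USE.NAMES = FALSE)
  )
}

# fully-cleaved tryptic segments (cut after each K or R)
tryptic_segments <- function(protein) {
  chars <- strsplit(protein, "")[[1]]
  cuts <- which(chars %in% c("K", "R"))
  bounds <- unique(c(0L, cuts, length(chars)))
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  substring(protein, starts, ends)
}

#' Expand peptides to modified precursors
#'
#' Applies fixed modifications to every matching residue, enumerates
#' variable-modification combinations up to `max_variable_mods`, and crosses
#' with the precursor charge range.
#'
#' @param peptides Tibble from [digest_fasta()] (columns `peptide`,
#'   `protein_ids`) or a character vector of peptide sequences.
#' @param params A [digest_params()].
#' @return Tibble with `modified_sequence`, `charge`, `precursor_mz`,
#'   `protein_ids`.
#' @export
expand_precursors <- function(peptides, params = digest_params()) {
  if (is.character(peptides)) {
    peptides <- tibble::tibble(peptide = peptides, protein_ids = NA_character_)
  }
  forms <- purrr::map(peptides$peptide, peptidoform_variants, params = params)
  out <- tibble::tibble(
    modified_sequence = unlist(forms),
    protein_ids = rep(peptides$protein_ids, lengths(forms))
  )
  out <- tidyr::expand_grid(out, charge = params$charge_range)
  out$precursor_mz <- purrr::map2_dbl(
    out$modified_sequence, out$charge,
    ~ precursor_mz(parse_modified_sequence(.x), .y)
  )
  dplyr::select(out, "modified_sequence", "charge", "precursor_mz", "protein_ids")
}

peptidoform_variants <- function(peptide, params) {
  chars <- strsplit(peptide, "")[[1]]
  tag_for <- function(name) UNIMOD_TABLE$tag[match(name, UNIMOD_TABLE$name)]
  fixed_at <- function(pos) {
    nm <- params$fixed_mods[chars[pos]]
    if (!is.na(nm)) paste0("(", tag_for(nm), ")") else ""
  }
  render <- function(var_positions, var_names) {
    paste(vapply(seq_along(chars), function(p) {
      tag <- fixed_at(p)
      v <- match(p, var_positions)
      if (!is.na(v)) tag <- paste0(tag, "(", tag_for(var_names[v]), ")")
      paste0(chars[p], tag)
    }, character(1)), collapse = "")
  }
  variants <- render(integer(0), character(0))
  if (length(params$variable_mods) > 0L && params$max_variable_mods > 0L) {
    var_sites <- which(chars %in% names(params$variable_mods))
    k_max <- min(params$max_variable_mods, length(var_sites))
    if (k_max >= 1L) {
      for (k in seq_len(k_max)) {
        combos <- utils::combn(var_sites, k, simplify = FALSE)
        variants <- c(variants, vapply(combos, function(cc) {
          render(cc, unname(params$variable_mods[chars[cc]]))
        }, character(1)))
      }
    }
  }
  variants
}

#' Build an in silico spectral library
#'
#' Predicts fragment intensities and retention times for every precursor,
#' drops precursors and fragment ions outside the training run's m/z scan
#' range, keeps the `top_n` most intense fragments per precursor
#' (filter-by-range first, then top-n), renormalizes the kept set to max 1
#' and converts normalized RTs back to minutes with `rt_factor`.
#'
#' @param intensity_model A trained intensity model (or a
#'   [ground_truth_model()], useful for simulation studies).
#' @param rt_model A trained RT model (or a [ground_truth_model()]).
#' @param precursors Tibble from [expand_precursors()].
#' @param scan_range Length-2 numeric, acquired fragment m/z range.
#' @param rt_factor RT normalization factor in minutes (see
#'   [rt_normalization_factor()]).
#' @param top_n Maximum fragments per precursor (default 20).
#' @param nce,instrument Prediction metadata.
#' @param mode `"global"` or `"phospho"`.
#' @return Library tibble, one row per retained fragment (see
#'   [write_library_tsv()] for the column semantics), with dropped-precursor
#'   counts in attribute `"filter_log"`.
#' @export
build_library <- function(intensity_model, rt_model, precursors, scan_range,
                          rt_factor, top_n = 20L, nce = 30,
                          instrument = "Lumos", mode = "global") {
  precursors <- tibble::as_tibble(precursors)
  stopifnot(length(scan_range) == 2L, rt_factor > 0)
  n_all <- nrow(precursors)
  keep <- precursors$precursor_mz >= scan_range[1] &
    precursors$precursor_mz <= scan_range[2]
  precursors <- precursors[keep, ]
  if (nrow(precursors) == 0L) stop("data error: no precursors within scan range")
  pfs <- lapply(precursors$modified_sequence, parse_modified_sequence)
  pred <- predict_intensity(intensity_model, precursors$modified_sequence,
                            precursors$charge, nce = nce,
                            instrument = instrument, mode = mode)
  rt_norm <- predict_rt(rt_model, precursors$modified_sequence)
  n_empty <- 0L
  rows <- vector("list", nrow(precursors))
  for (i in seq_len(nrow(precursors))) {
    fr <- enumerate_fragments(pfs[[i]], precursors$charge[i], mode)
    layout <- fragment_layout(mode)
    fr$intensity <- pred[[i]][cbind(fr$row, match(fr$col, layout))]
    fr <- fr[fr$mz >= scan_range[1] & fr$mz <= scan_range[2] & fr$intensity > 0, ]
    if (nrow(fr) == 0L) { n_empty <- n_empty + 1L; next }
    fr <- fr[order(fr$intensity, decreasing = TRUE), ]
    fr <- fr[seq_len(min(top_n, nrow(fr))), ]
    rows[[i]] <- tibble::tibble(
      modified_sequence = precursors$modified_sequence[i],
      charge = precursors$charge[i],
      precursor_mz = precursors$precursor_mz[i],
      rt = rt_norm[i] * rt_factor,
      series = fr$series, ordinal = fr$ordinal,
      fragment_charge = fr$charge,
      loss = ifelse(fr$loss == "none", "noloss", "H3PO4"),
      fragment_mz = fr$mz,
      relative_intensity = fr$intensity / max(fr$intensity),
      protein_ids = precursors$protein_ids[i]
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "filter_log") <- tibble::tibble(
    n_precursors = n_all,
    n_outside_scan_range = n_all - sum(keep),
    n_zero_fragments = n_empty,
    n_in_library = dplyr::n_distinct(out$modified_sequence, out$charge)
  )
  out
}
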