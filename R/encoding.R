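#' Watson-Crick complement
#'
#' Base-wise complement (A<->T, C<->G) preserving order. No reversal is
#' performed: a sticker aligned antiparallel to an input-strand segment reads,
#' in input-strand order, as the base-wise complement of that segment, which
#' is exactly how the sticker tables are printed (3'->5'). The orientation
#' label of the result is the flip of the input's.
#'
#' @param seq Character vector of nucleotide strings over `{A,C,G,T}`.
#' @return Character vector of complements, same lengths.
#' @examples
#' wc_complement("GCCAGAA") # "CGGTCTT"
#' @export
wc_complement <- function(seq) {
  if (any(grepl("[^ACGT]", seq)))
    stop("sequence contains non-ACGT characters", call. = FALSE)
  chartr("ACGT", "TGCA", seq)
}

spacer_block <- function(codebook) paste(codebook$spacers, collapse = "")

# X_{from}..X_{to} as one string ("" when from > to)
spacer_range <- function(codebook, from, to) {
  if (from > to) return("")
  paste(codebook$spacers[(from:to) + 1L], collapse = "")
}

new_strand <- function(id, role, pairing = NULL, sequence = NULL,
                       from = NA_integer_, letter = NA_character_,
                       to = NA_integer_) {
  # `sequence` is stored 5'->3'; `pairing` is the base-wise complement of the
  # input-strand segment the sticker covers, in input-strand order (the
  # conventional 3'->5' table writing). For stickers sequence = reverse(pairing).
  if (is.null(sequence)) sequence <- rev_string(pairing)
  if (is.null(pairing)) pairing <- NA_character_
  tibble::tibble(id = id, role = role, from = from, letter = letter, to = to,
                 pairing = pairing, sequence = sequence,
                 length = nchar(sequence))
}

rev_string <- function(x) {
  vapply(strsplit(x, NULL), function(ch) paste(rev(ch), collapse = ""),
         character(1))
}

#' Encode an input run as a single strand
#'
#' A word `a1..an` becomes the 5'->3' strand
#' `I1 X0..Xm C(a1) X0..Xm C(a2) ... C(an) X0..Xm I2`: every letter codeword
#' is preceded by a full spacer block, a final spacer block precedes the
#' terminator. The empty word encodes as `I1 X0..Xm I2`.
#'
#' @param letters Character vector of codebook letters (possibly empty).
#' @param codebook A [codebook()].
#' @return One-row strand tibble (columns `id`, `role`, `sequence`, ...), with
#'   `sequence` 5'->3'.
#' @export
encode_input_run <- function(letters, codebook) {
  stopifnot(inherits(codebook, "codebook"))
  letters <- as.character(letters)
  missing <- setdiff(letters, names(codebook$letters))
  if (length(missing) > 0L)
    stop("no codeword for letter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  blk <- spacer_block(codebook)
  seq <- paste0(codebook$I1,
                paste0(vapply(letters, function(a)
                  paste0(blk, codebook$letters[[a]]), character(1)),
                  collapse = ""),
                blk, codebook$I2)
  new_strand(id = paste0("run:", paste(letters, collapse = ",")),
             role = "input-run", sequence = seq,
             letter = paste(letters, collapse = ","))
}

#' Trim a run strand to its transition core
#'
#' Every run molecule starts with `I1 X0..Xi` (covered by the initial-state
#' sticker for initial state `i`) and ends with `X_{j+1}..Xm I2` (covered by
#' the acceptance sticker for accepting state `j`). Stripping both leaves the
#' core `d` that the transition stickers must tile.
#'
#' @param run_strand Strand tibble from [encode_input_run()] (or a bare
#'   5'->3' sequence string).
#' @param codebook A [codebook()].
#' @param initial_index Initial state index `i`.
#' @param accepting_index Accepting state index `j`.
#' @return One-row strand tibble with role `"core"`.
#' @export
trim_to_core <- function(run_strand, codebook, initial_index,
                         accepting_index) {
  seq <- if (is.character(run_strand)) run_strand else run_strand$sequence
  stopifnot(length(seq) == 1L)
  pre <- paste0(codebook$I1, spacer_range(codebook, 0L, initial_index))
  suf <- paste0(spacer_range(codebook, accepting_index + 1L, codebook$m),
                codebook$I2)
  if (!startsWith(seq, pre))
    stop("run strand does not start with I1 X0..X", initial_index,
         ": encoding inconsistency", call. = FALSE)
  if (!endsWith(seq, suf))
    stop("run strand does not end with X", accepting_index + 1L, "..Xm I2",
         ": encoding inconsistency", call. = FALSE)
  core <- substr(seq, nchar(pre) + 1L, nchar(seq) - nchar(suf))
  new_strand(id = "core", role = "core", sequence = core)
}

#' Encode a transition as a sticker
#'
#' The transition `t(s_i, a) = s_j` is the sticker
#' `3' comp(X_{i+1}..Xm C(a) X_0..X_j) 5'`: it finishes the spacer block the
#' previous sticker left at depth `i`, covers the letter codeword, and reaches
#' depth `j` into the next block — which is how the target state index is
#' carried along the strand.
#'
#' @param i Source state index.
#' @param letter Codebook letter consumed.
#' @param j Target state index.
#' @param codebook A [codebook()].
#' @return One-row strand tibble; `pairing` holds the 3'->5' table writing.
#' @export
encode_transition <- function(i, letter, j, codebook) {
  stopifnot(inherits(codebook, "codebook"))
  if (i < 0L || i > codebook$m || j < 0L || j > codebook$m)
    stop("state index out of range 0..m", call. = FALSE)
  if (!letter %in% names(codebook$letters))
    stop("no codeword for letter ", letter, call. = FALSE)
  segment <- paste0(spacer_range(codebook, i + 1L, codebook$m),
                    codebook$letters[[letter]],
                    spacer_range(codebook, 0L, j))
  new_strand(id = paste0("t", i, letter, j), role = "transition",
             pairing = wc_complement(segment),
             from = as.integer(i), letter = letter, to = as.integer(j))
}

#' Encode the initial state as a sticker
#'
#' Initial state `s_i` is `3' comp(I1 X0..Xi) 5'`.
#'
#' @param i Initial state index.
#' @param codebook A [codebook()].
#' @return One-row strand tibble.
#' @export
encode_initial <- function(i, codebook) {
  stopifnot(inherits(codebook, "codebook"))
  if (i < 0L || i > codebook$m)
    stop("initial state index out of range 0..m", call. = FALSE)
  segment <- paste0(codebook$I1, spacer_range(codebook, 0L, i))
  new_strand(id = paste0("init", i), role = "initial",
             pairing = wc_complement(segment), to = as.integer(i))
}

#' Encode an acceptance state as a sticker
#'
#' Acceptance state `s_j` is `3' comp(X_{j+1}..Xm I2) 5'`. At least one
#' trailing spacer is required (`j <= m - 1`), otherwise the sticker would
#' collapse to the bare terminator complement and could not register the
#' state index.
#'
#' @param j Accepting state index.
#' @param codebook A [codebook()].
#' @return One-row strand tibble.
#' @export
encode_acceptance <- function(j, codebook) {
  stopifnot(inherits(codebook, "codebook"))
  if (j < 0L || j > codebook$m - 1L)
    stop("acceptance state index out of range 0..m-1", call. = FALSE)
  segment <- paste0(spacer_range(codebook, j + 1L, codebook$m), codebook$I2)
  new_strand(id = paste0("acc", j), role = "acceptance",
             pairing = wc_complement(segment), from = as.integer(j))
}

#' Build the full sticker set of an automaton
#'
#' One initial-state sticker, one acceptance sticker per accepting state, and
#' one sticker per transition, reproducing the printed sticker tables of the
#' reference automata byte-for-byte.
#'
#' @param fsa An [fsa()].
#' @param codebook A [codebook()] covering the automaton's alphabet.
#' @return A tibble of strands (class `sticker_set`), one row per sticker.
#' @export
build_sticker_set <- function(fsa, codebook) {
  stopifnot(inherits(fsa, "fsa"), inherits(codebook, "codebook"))
  rep_ok <- validate_codebook(codebook, fsa)
  if (!attr(rep_ok, "valid"))
    stop("codebook does not cover the automaton:\n",
         paste(rep_ok$check[!rep_ok$ok], collapse = "; "), call. = FALSE)
  rows <- c(
    list(encode_initial(fsa$initial, codebook)),
    lapply(fsa$accepting, encode_acceptance, codebook = codebook),
    purrr::pmap(fsa$transitions, function(from, letter, to)
      encode_transition(from, letter, to, codebook))
  )
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sticker_set", class(out))
  out
}

#' Export strands to FASTA
#'
#' Writes one record per strand, header `id role` (plus transition metadata),
#' sequence written 5'->3'. Round-trips through [read_strand_fasta()].
#'
#' @param strands Strand tibble (e.g. a sticker set or input runs).
#' @param file Path to write.
#' @return Invisibly, `file`.
#' @export
export_fasta <- function(strands, file) {
  stopifnot(nrow(strands) > 0L)
  ids <- paste0(strands$id, " ", strands$role)
  set <- Biostrings::DNAStringSet(strands$sequence)
  names(set) <- ids
  Biostrings::writeXStringSet(set, filepath = file)
  invisible(file)
}

#' Read strands from FASTA
#'
#' @param file FASTA path written by [export_fasta()] (or any DNA FASTA).
#' @return Strand tibble with `id`, `role` (second header token, `"unknown"`
#'   if absent), and 5'->3' `sequence`.
#' @export
read_strand_fasta <- function(file) {
  set <- Biostrings::readDNAStringSet(file)
  hdr <- strsplit(names(set), " ", fixed = TRUE)
  seqs <- unname(as.character(set))
  tibble::tibble(
    id = vapply(hdr, `[`, character(1), 1),
    role = vapply(hdr, function(h) if (length(h) > 1) h[2] else "unknown",
                  character(1)),
    sequence = seqs,
    length = nchar(seqs))
}
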