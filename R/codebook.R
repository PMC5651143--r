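#' Construct a DNA codebook
#'
#' A codebook maps every alphabet letter to a nucleotide codeword and supplies
#' the positional spacers `X0..Xm`, the initiator `I1` and the terminator `I2`
#' used by the sticker encoding. Letters may carry Boolean conditions over
#' atomic propositions (e.g. `u = ¬p ∧ ¬q`): a letter is admissible at a system
#' state iff its condition holds under the state's truth assignment.
#'
#' @param letters Named character vector of codewords, e.g.
#'   `c(p = "CGA", q = "CCC")`. All codewords must have equal length.
#' @param spacers Character vector `X0..Xm` (all equal length).
#' @param I1,I2 Initiator and terminator sequences.
#' @param conditions Named list giving, per letter, a list with character
#'   vectors `pos` and `neg`: the letter's condition is the conjunction of the
#'   `pos` propositions and the negations of the `neg` propositions. Letters
#'   without an entry default to requiring the proposition of the same name.
#' @param name Optional identifier.
#' @return An object of class `codebook`.
#' @examples
#' cb <- codebook(c(p = "CGA", q = "CCC"),
#'                spacers = c("GAA", "TTG", "CAA"),
#'                I1 = "GCCA", I2 = "CGTC")
#' @export
codebook <- function(letters, spacers, I1, I2, conditions = list(),
                     name = NULL) {
  stopifnot(is.character(letters), !is.null(names(letters)),
            is.character(spacers), length(spacers) >= 1L,
            is.character(I1), is.character(I2))
  chk <- function(x) all(grepl("^[ACGT]+$", x))
  if (!chk(letters) || !chk(spacers) || !chk(I1) || !chk(I2))
    stop("codebook sequences must be over {A,C,G,T}", call. = FALSE)
  for (a in names(letters)) {
    if (is.null(conditions[[a]]))
      conditions[[a]] <- list(pos = a, neg = character())
    conditions[[a]]$pos <- as.character(conditions[[a]]$pos %||% character())
    conditions[[a]]$neg <- as.character(conditions[[a]]$neg %||% character())
  }
  structure(
    list(letters = letters, spacers = spacers, I1 = I1, I2 = I2,
         m = length(spacers) - 1L,
         conditions = conditions[names(letters)], name = name),
    class = "codebook")
}

#' @export
print.codebook <- function(x, ...) {
  cat("<codebook", if (!is.null(x$name)) paste0("'", x$name, "'"), ">\n")
  cat("  I1 =", x$I1, "  I2 =", x$I2, "\n")
  cat("  spacers X0..X", x$m, ": ", paste(x$spacers, collapse = " "), "\n",
      sep = "")
  for (a in names(x$letters)) {
    cond <- x$conditions[[a]]
    lits <- c(cond$pos, if (length(cond$neg)) paste0("¬", cond$neg))
    cat("  ", format(a, width = 3), "= ", x$letters[[a]],
        "   [", paste(lits, collapse = " ∧ "), "]\n", sep = "")
  }
  invisible(x)
}

#' Validate a codebook against an automaton
#'
#' Checks the structural constraints the sticker encoding relies on: every
#' alphabet letter has a codeword, codewords are pairwise distinct and of
#' uniform length, spacers are uniform and distinct, no letter codeword equals
#' a spacer, and the spacer count suffices for the automaton's state indices
#' (an acceptance sticker for state `j` needs at least one trailing spacer, so
#' `j <= m - 1` must hold for every accepting state). Thermodynamic design
#' quality is out of scope; this is the combinatorial half of codeword design.
#'
#' @param codebook A [codebook()].
#' @param fsa Optionally, an [fsa()] the codebook must cover.
#' @return A tibble with columns `check`, `ok`, `detail`; attribute `valid`
#'   (and `valid` column conjunction) indicates overall validity.
#' @export
validate_codebook <- function(codebook, fsa = NULL) {
  stopifnot(inherits(codebook, "codebook"))
  rows <- list()
  add <- function(check, ok, detail = "") {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      check = check, ok = ok, detail = detail)
  }
  lw <- nchar(codebook$letters)
  add("letter lengths uniform", length(unique(lw)) == 1L,
      paste(sort(unique(lw)), collapse = ","))
  add("letter codewords distinct",
      anyDuplicated(codebook$letters) == 0L,
      paste(names(codebook$letters)[duplicated(codebook$letters) |
                                      duplicated(codebook$letters,
                                                 fromLast = TRUE)],
            collapse = ","))
  sw <- nchar(codebook$spacers)
  add("spacer lengths uniform", length(unique(sw)) == 1L,
      paste(sort(unique(sw)), collapse = ","))
  add("spacers distinct", anyDuplicated(codebook$spacers) == 0L)
  add("no letter equals a spacer",
      !any(codebook$letters %in% codebook$spacers),
      paste(names(codebook$letters)[codebook$letters %in% codebook$spacers],
            collapse = ","))
  if (!is.null(fsa)) {
    missing <- setdiff(fsa$alphabet, names(codebook$letters))
    add("alphabet covered", length(missing) == 0L,
        paste(missing, collapse = ","))
    add("spacer count sufficient for states",
        fsa$n_states - 1L <= codebook$m,
        paste0("max state ", fsa$n_states - 1L, ", m = ", codebook$m))
    add("spare spacer for acceptance stickers",
        length(fsa$accepting) == 0L || max(fsa$accepting) <= codebook$m - 1L,
        paste0("max accepting ",
               if (length(fsa$accepting)) max(fsa$accepting) else NA,
               ", m = ", codebook$m))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "valid") <- all(out$ok)
  out
}

#' Letters admissible at a system state
#'
#' Evaluates every codebook letter's Boolean condition under the state's truth
#' assignment and returns those that hold, optionally restricted to the
#' letters that actually occur in a formula automaton's transitions.
#' Propositions with no truth value at the state are taken as false (closed
#' world), so formulas over foreign propositions are simply unsatisfiable
#' there. A state where no codebook letter (unrestricted) is admissible
#' indicates a labeling/codebook mismatch and raises an error; an *empty
#' restricted* set is a legitimate outcome (the state contributes no run
#' through that automaton).
#'
#' @param state State index of `model`.
#' @param model A [system_model()].
#' @param codebook A [codebook()] with letter conditions.
#' @param restrict_to Optional character vector (e.g. an automaton alphabet).
#' @return Character vector of admissible letters, in codebook order.
#' @export
admissible_letters <- function(state, model, codebook, restrict_to = NULL) {
  stopifnot(inherits(model, "system_model"), inherits(codebook, "codebook"))
  lab <- model$labels[[as.character(state)]]
  if (is.null(lab)) stop("state ", state, " is not labeled", call. = FALSE)
  holds <- vapply(codebook$conditions, function(cond) {
    # closed world: a proposition with no truth value at this state is false
    pos_val <- cond$pos %in% names(lab) & lab[cond$pos]
    neg_val <- cond$neg %in% names(lab) & lab[cond$neg]
    all(pos_val) && !any(neg_val)
  }, logical(1))
  adm <- names(codebook$letters)[holds]
  if (length(adm) == 0L)
    stop("no codebook letter is admissible at state ", state,
         ": labeling/codebook mismatch", call. = FALSE)
  if (!is.null(restrict_to)) adm <- intersect(adm, restrict_to)
  adm
}

`%||%` <- function(a, b) if (is.null(a)) b else a
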