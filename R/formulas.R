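#' Reference formula automata
#'
#' Returns the finite-word automaton of a supported basic temporal-logic
#' formula:
#'
#' * `"phi1"` — A1 for `¬p U-- ¬q` (the dual used to decide `EpUq`):
#'   3 states, accepting `{2}`, five transitions over letters `s`, `u`, `q`.
#' * `"phi2"` — A2 for the interval chop `(p1 U q1); (p2 U q2)`.
#' * `"phi3"` — A3 for the interval star `(p U q)*` (states 0 and 2 of the
#'   merged ITL automaton; state 1 is unused but kept so the sticker encoding
#'   addresses the same spacer depths as the merged table).
#' * `"phi4"` — A4 for the projection formula
#'   `((p1 U q1), (p2 U q2)) prj (p3 ∧ X q3)`: 5 states, 8 transitions over
#'   the compound letters `m1..m4` and `p1, q1, p2, q2`.
#' * `"A5"` — the merged ITL automaton (A2 and A3 share states and strands).
#' * `"pUq"` — the core until automaton of Fig.-6 shape.
#' * `"Fp"`, `"Gp"`, `"Xp"` (and `"Fnotp"`, `"Gnotp"`, `"Xnotp"` on the
#'   negated letter `r = ¬p`) — finite-word eventually/globally/next
#'   automata; `F` and `X` loop on every alphabet letter, `G` loops on its
#'   target letter only.
#'
#' @param formula Formula name (see above).
#' @param alphabet Alphabet for the `F`/`X` loops; defaults to the letters of
#'   the phi1 codebook, `c("p","q","r","s","u")`.
#' @return An [fsa()].
#' @examples
#' automaton_for("phi1")
#' accepts(automaton_for("pUq"), c("p", "p", "q"))
#' @export
automaton_for <- function(formula, alphabet = NULL) {
  alphabet <- alphabet %||% c("p", "q", "r", "s", "u")
  tr <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    tibble::tibble(from = as.integer(m[, 1]), letter = m[, 2],
                   to = as.integer(m[, 3]))
  }
  switch(
    formula,
    phi1 = fsa(c("q", "s", "u"), 3L,
               tr(0, "s", 0,  0, "u", 1,  0, "s", 2,  1, "s", 1,  1, "q", 2),
               initial = 0L, accepting = 2L, name = "A1"),
    phi2 = fsa(c("p1", "q1", "p2", "q2"), 3L,
               tr(0, "p1", 0,  0, "q1", 1,  1, "p2", 1,  1, "q2", 2),
               initial = 0L, accepting = 2L, name = "A2"),
    phi3 = fsa(c("p", "q"), 3L,
               tr(0, "p", 0,  0, "q", 2,  2, "p", 0,  2, "q", 2),
               initial = 0L, accepting = 2L, name = "A3"),
    A5 = fsa(c("p1", "q1", "p2", "q2", "p", "q"), 3L,
             tr(0, "p1", 0,  0, "p", 0,  0, "q1", 1,  0, "q", 2,
                1, "p2", 1,  1, "q2", 2,  2, "p", 0,  2, "q", 2),
             initial = 0L, accepting = 2L, name = "A5"),
    phi4 = fsa(c("m1", "m2", "p1", "q1", "m3", "m4", "p2", "q2"), 5L,
               tr(0, "m1", 1,  0, "m2", 2,  1, "p1", 1,  1, "q1", 2,
                  2, "m3", 3,  2, "m4", 4,  3, "p2", 3,  3, "q2", 4),
               initial = 0L, accepting = 4L, name = "A4"),
    pUq = fsa(c("p", "q"), 2L, tr(0, "p", 0,  0, "q", 1),
              initial = 0L, accepting = 1L, name = "pUq"),
    Fp = ltl_automaton("F", "p", alphabet),
    Gp = ltl_automaton("G", "p", alphabet),
    Xp = ltl_automaton("X", "p", alphabet),
    Fnotp = ltl_automaton("F", "r", alphabet),
    Gnotp = ltl_automaton("G", "r", alphabet),
    Xnotp = ltl_automaton("X", "r", alphabet),
    stop("unsupported formula: ", formula, call. = FALSE)
  )
}

#' Finite-word automata for the eventually/globally/next operators
#'
#' `F a`: two states, loops on every letter, jumps to the accepting sink on
#' `a`. `G a`: a single accepting state looping on `a` only (every consumed
#' letter must be `a`; the empty word holds vacuously). `X a`: requires `a`
#' as the second letter, any letters elsewhere. These realize the finite-word
#' languages of the three operators; negated propositions are handled by
#' passing the fresh letter that carries the negation (e.g. `r = ¬p`).
#'
#' @param kind One of `"F"`, `"G"`, `"X"`.
#' @param letter Target letter `a`.
#' @param alphabet Full alphabet for the unconstrained loops.
#' @return An [fsa()].
#' @export
ltl_automaton <- function(kind = c("F", "G", "X"), letter, alphabet) {
  kind <- match.arg(kind)
  stopifnot(letter %in% alphabet)
  any_at <- function(from, to)
    tibble::tibble(from = as.integer(from), letter = alphabet,
                   to = as.integer(to))
  nm <- paste0(kind, letter)
  switch(
    kind,
    F = fsa(alphabet, 2L,
            dplyr::bind_rows(any_at(0, 0),
                             tibble::tibble(from = 0L, letter = letter,
                                            to = 1L),
                             any_at(1, 1)),
            initial = 0L, accepting = 1L, name = nm),
    G = fsa(alphabet, 1L,
            tibble::tibble(from = 0L, letter = letter, to = 0L),
            initial = 0L, accepting = 0L, name = nm),
    X = fsa(alphabet, 3L,
            dplyr::bind_rows(any_at(0, 1),
                             tibble::tibble(from = 1L, letter = letter,
                                            to = 2L),
                             any_at(2, 2)),
            initial = 0L, accepting = 2L, name = nm)
  )
}

#' Existential-to-universal duality reduction
#'
#' Each existential basic CTL formula is decided by checking a universal core
#' and negating the result: `EpUq` via `phi1` (= `¬p U-- ¬q`), `EFp` via
#' `G¬p`, `EGp` via `F¬p`, `EXp` via `X¬p`.
#'
#' @param existential_name One of `"EpUq"`, `"EFp"`, `"EGp"`, `"EXp"`.
#' @return List with `core` (formula name understood by [automaton_for()]),
#'   `core_label` (human-readable core formula) and `negate` (always `TRUE`).
#' @examples
#' dual_reduction("EFp")
#' @export
dual_reduction <- function(existential_name) {
  table <- list(
    EpUq = list(core = "phi1", core_label = "φ1"),
    EFp  = list(core = "Gnotp", core_label = "G¬p"),
    EGp  = list(core = "Fnotp", core_label = "F¬p"),
    EXp  = list(core = "Xnotp", core_label = "X¬p"))
  if (!existential_name %in% names(table))
    stop(existential_name, " is not an existential basic CTL formula",
         call. = FALSE)
  c(table[[existential_name]], list(negate = TRUE))
}
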