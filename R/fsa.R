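#' Construct a finite-state automaton
#'
#' An FSA is the five-tuple (alphabet, states, transitions, initial, accepting).
#' States are addressed by dense integer indices `0..n_states-1` because the
#' sticker encoding addresses a state by how far its sticker reaches into the
#' spacer block. Transitions are nondeterministic: several targets per
#' (state, letter) pair are allowed.
#'
#' @param alphabet Character vector of letter symbols.
#' @param n_states Number of states; indices are `0..n_states-1`.
#' @param transitions Data frame (or tibble) with columns `from`, `letter`,
#'   `to`; `from`/`to` are state indices, `letter` an alphabet symbol.
#' @param initial Initial state index.
#' @param accepting Integer vector of accepting state indices.
#' @param name Optional identifier carried in reports.
#' @return An object of class `fsa`.
#' @examples
#' a <- fsa(c("p", "q"), 2,
#'          data.frame(from = c(0, 0), letter = c("p", "q"), to = c(0, 1)),
#'          initial = 0, accepting = 1)
#' accepts(a, c("p", "p", "q"))
#' @export
fsa <- function(alphabet, n_states, transitions, initial, accepting,
                name = NULL) {
  stopifnot(is.character(alphabet), length(alphabet) >= 1L,
            n_states >= 1L)
  transitions <- tibble::as_tibble(transitions)
  stopifnot(all(c("from", "letter", "to") %in% names(transitions)))
  transitions$from <- as.integer(transitions$from)
  transitions$to <- as.integer(transitions$to)
  initial <- as.integer(initial)
  accepting <- as.integer(accepting)
  idx <- seq_len(n_states) - 1L
  if (!initial %in% idx)
    stop("initial state ", initial, " is not a state index", call. = FALSE)
  if (!all(accepting %in% idx))
    stop("accepting states outside 0..", n_states - 1L, call. = FALSE)
  if (nrow(transitions) > 0L) {
    if (!all(transitions$from %in% idx) || !all(transitions$to %in% idx))
      stop("transition references an unknown state", call. = FALSE)
    if (!all(transitions$letter %in% alphabet))
      stop("transition references an unknown letter", call. = FALSE)
  }
  structure(
    list(alphabet = alphabet, n_states = as.integer(n_states),
         transitions = transitions[order(transitions$from,
                                         match(transitions$letter, alphabet),
                                         transitions$to), ],
         initial = initial, accepting = sort(unique(accepting)),
         name = name),
    class = "fsa")
}

#' @export
print.fsa <- function(x, ...) {
  cat("<fsa", if (!is.null(x$name)) paste0("'", x$name, "'"), ">\n")
  cat("  alphabet: {", paste(x$alphabet, collapse = ", "), "}\n")
  cat("  states:   0..", x$n_states - 1L,
      "  initial: ", x$initial,
      "  accepting: {", paste(x$accepting, collapse = ", "), "}\n", sep = "")
  cat("  transitions:", nrow(x$transitions), "\n")
  invisible(x)
}

#' Tidy the transition table of an automaton
#'
#' @param x An `fsa`.
#' @param ... Unused.
#' @return A tibble with one row per transition.
#' @export
tidy.fsa <- function(x, ...) x$transitions

#' Does the automaton accept a finite word?
#'
#' Standard nondeterministic acceptance on finite words: the word is accepted
#' iff some transition path consumes it entirely from the initial state to an
#' accepting state. The empty word is accepted iff the initial state is
#' accepting. Implemented by forward subset propagation (the set of states
#' reachable after each prefix).
#'
#' @param fsa An [fsa()].
#' @param word Character vector of letters (possibly empty).
#' @return Logical scalar.
#' @export
accepts <- function(fsa, word) {
  stopifnot(inherits(fsa, "fsa"))
  word <- as.character(word)
  bad <- setdiff(word, fsa$alphabet)
  if (length(bad) > 0L)
    stop("letters not in the automaton alphabet: ",
         paste(bad, collapse = ", "), call. = FALSE)
  current <- fsa$initial
  tr <- fsa$transitions
  for (a in word) {
    current <- unique(tr$to[tr$from %in% current & tr$letter == a])
    if (length(current) == 0L) return(FALSE)
  }
  any(current %in% fsa$accepting)
}

#' Construct a labeled system model
#'
#' A system model is a directed graph with one initial state and a per-state
#' truth assignment over atomic propositions (a Label-FSA: propositions hold
#' in states, not on transitions). States with no outgoing edge are terminal.
#'
#' @param n_states Number of states, indices `0..n_states-1`.
#' @param edges Data frame with integer columns `from`, `to`.
#' @param labels Named list: `labels[[as.character(state)]]` is a named logical
#'   vector of atomic-proposition truth values at that state.
#' @param initial Initial state index (default 0).
#' @param intervals Optional named list annotating prefix/suffix intervals for
#'   the sequential-composition bound, e.g.
#'   `list(prefix = list(nodes = 2, edges = 2), suffix = list(nodes = 2, edges = 1))`.
#' @param name Optional identifier.
#' @return An object of class `system_model`.
#' @export
system_model <- function(n_states, edges, labels, initial = 0L,
                         intervals = NULL, name = NULL) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("from", "to") %in% names(edges)))
  edges$from <- as.integer(edges$from)
  edges$to <- as.integer(edges$to)
  idx <- seq_len(n_states) - 1L
  stopifnot(all(edges$from %in% idx), all(edges$to %in% idx),
            as.integer(initial) %in% idx)
  labels <- labels[order(as.integer(names(labels)))]
  if (!identical(as.integer(names(labels)), idx))
    stop("labels must cover every state exactly once", call. = FALSE)
  structure(
    list(n_states = as.integer(n_states),
         edges = edges[order(edges$from, edges$to), ],
         labels = lapply(labels, function(l) {
           stopifnot(is.logical(l), !is.null(names(l)))
           l
         }),
         initial = as.integer(initial),
         intervals = intervals, name = name),
    class = "system_model")
}

#' @export
print.system_model <- function(x, ...) {
  cat("<system_model", if (!is.null(x$name)) paste0("'", x$name, "'"), ">\n")
  cat("  states: ", x$n_states, " (initial ", x$initial,
      ", terminal {", paste(terminal_states(x), collapse = ", "), "})\n",
      sep = "")
  cat("  edges:  ", paste(paste0(x$edges$from, "→", x$edges$to),
                          collapse = ", "), "\n")
  for (s in names(x$labels)) {
    l <- x$labels[[s]]
    cat("  state ", s, ": ",
        paste(ifelse(l, names(l), paste0("¬", names(l))),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Terminal states of a system model
#'
#' @param model A [system_model()].
#' @return Integer vector of states with no outgoing edge.
#' @export
terminal_states <- function(model) {
  idx <- seq_len(model$n_states) - 1L
  setdiff(idx, unique(model$edges$from))
}
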