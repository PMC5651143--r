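#' Write / read an automaton or system model as JSON
#'
#' Automata serialize as
#' `{alphabet, n_states, transitions: [[src, letter, dst], ...], initial,
#' accepting}`; system models as `{n_states, edges: [[src, dst], ...],
#' initial, labels: {state: {prop: bool}}, intervals?}`. Both round-trip
#' unchanged.
#'
#' @param x An [fsa()] or [system_model()].
#' @param file Path to write.
#' @return Invisibly, `file`.
#' @export
write_model_json <- function(x, file) {
  if (inherits(x, "fsa")) {
    obj <- list(type = "fsa", name = x$name, alphabet = x$alphabet,
                n_states = x$n_states,
                transitions = unname(purrr::pmap(x$transitions,
                  function(from, letter, to) list(from, letter, to))),
                initial = x$initial, accepting = x$accepting)
  } else if (inherits(x, "system_model")) {
    obj <- list(type = "system_model", name = x$name,
                n_states = x$n_states,
                edges = unname(purrr::pmap(x$edges,
                  function(from, to) list(from, to))),
                initial = x$initial,
                labels = lapply(x$labels, as.list),
                intervals = x$intervals)
  } else stop("cannot serialize object of class ", class(x)[1],
              call. = FALSE)
  jsonlite::write_json(obj, file, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(file)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(file) {
  obj <- jsonlite::read_json(file)
  if (identical(obj$type, "fsa")) {
    tr <- if (length(obj$transitions))
      tibble::tibble(
        from = vapply(obj$transitions, function(t) as.integer(t[[1]]),
                      integer(1)),
        letter = vapply(obj$transitions, function(t) as.character(t[[2]]),
                        character(1)),
        to = vapply(obj$transitions, function(t) as.integer(t[[3]]),
                    integer(1)))
    else tibble::tibble(from = integer(), letter = character(),
                        to = integer())
    fsa(unlist(obj$alphabet), obj$n_states, tr, obj$initial,
        unlist(obj$accepting), name = obj$name)
  } else if (identical(obj$type, "system_model")) {
    ed <- if (length(obj$edges))
      tibble::tibble(
        from = vapply(obj$edges, function(e) as.integer(e[[1]]), integer(1)),
        to = vapply(obj$edges, function(e) as.integer(e[[2]]), integer(1)))
    else tibble::tibble(from = integer(), to = integer())
    system_model(obj$n_states, ed,
                 labels = lapply(obj$labels, function(l)
                   vapply(l, isTRUE, logical(1))),
                 initial = obj$initial,
                 intervals = obj$intervals, name = obj$name)
  } else stop("unrecognized JSON model file", call. = FALSE)
}

#' Write / read a codebook as YAML
#'
#' Layout: `{letters: {p: CGA, ...}, spacers: [...], I1: ..., I2: ...,
#' conditions: {r: {neg: [p]}, ...}}`.
#'
#' @param codebook A [codebook()].
#' @param file Path.
#' @return Invisibly, `file`.
#' @export
write_codebook_yaml <- function(codebook, file) {
  obj <- list(name = codebook$name,
              letters = as.list(codebook$letters),
              spacers = as.list(codebook$spacers),
              I1 = codebook$I1, I2 = codebook$I2,
              conditions = codebook$conditions)
  yaml::write_yaml(obj, file)
  invisible(file)
}

#' @rdname write_codebook_yaml
#' @export
read_codebook_yaml <- function(file) {
  obj <- yaml::read_yaml(file)
  codebook(unlist(obj$letters), unlist(obj$spacers), obj$I1, obj$I2,
           conditions = lapply(obj$conditions, function(cond)
             list(pos = unlist(cond$pos), neg = unlist(cond$neg))),
           name = obj$name)
}

#' Serialize a model-checking result to a report list
#'
#' JSON-ready shape of an `mc_result`: verdict, formula, model, bound, the
#' per-path table, and the decision basis.
#'
#' @param result An `mc_result`.
#' @return A plain list suitable for [jsonlite::write_json()].
#' @export
mc_report <- function(result) {
  stopifnot(inherits(result, "mc_result"))
  list(model = result$model, formula = result$formula,
       verdict = result$verdict, bound = result$bound,
       negated = result$negated,
       decision_basis = result$decision_basis,
       paths = result$paths)
}
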