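#' DNA-route model checking: the TL-MC-DNA loop
#'
#' Checks whether a labeled system model satisfies the formula encoded by
#' `formula_fsa`, by the sticker-automaton route: every path family up to the
#' exploration bound is enumerated; each path's admissible runs (one codebook
#' letter per state, restricted to the automaton's alphabet) are encoded as
#' input strands and annealed in silico against the automaton's sticker set;
#' a path is satisfied iff some admissible run forms a complete double
#' strand, and the model satisfies the formula iff every path is satisfied.
#'
#' Runs are evaluated exhaustively (every run encoded and tiled, early exit
#' at the first complete double strand) while the path's run count is at most
#' `max_runs`. Beyond that the admissible-run language is searched by exact
#' dynamic programming over (path position, automaton state); a witness run,
#' when one exists, is still certified by encoding and tiling. The two routes
#' agree because a strand tiles completely iff its word is accepted.
#'
#' @param model A [system_model()].
#' @param formula_fsa The formula automaton ([fsa()]).
#' @param codebook A [codebook()] covering the automaton alphabet.
#' @param bound Number of path families to check; defaults to
#'   `run_length_bound(|V|, |E|)` of the model.
#' @param max_runs Per-path exhaustive-enumeration ceiling (default 512).
#' @param formula Optional formula label for reports.
#' @return An object of class `mc_result`; see [tidy.mc_result()].
#' @examples
#' res <- tl_mc_dna(fixture("M1"), automaton_for("phi1"),
#'                  fixture("codebook-phi1"))
#' res$verdict
#' @export
tl_mc_dna <- function(model, formula_fsa, codebook, bound = NULL,
                      max_runs = 512L, formula = NULL) {
  stopifnot(inherits(model, "system_model"), inherits(formula_fsa, "fsa"),
            inherits(codebook, "codebook"))
  rep_ok <- validate_codebook(codebook, formula_fsa)
  if (!attr(rep_ok, "valid"))
    stop("codebook/automaton mismatch: ",
         paste(rep_ok$check[!rep_ok$ok], collapse = "; "), call. = FALSE)
  bound <- bound %||% run_length_bound(model$n_states, nrow(model$edges))
  stickers <- build_sticker_set(formula_fsa, codebook)
  cov <- sticker_covers(stickers)
  paths <- enumerate_paths(model, bound)
  rows <- purrr::imap(paths, function(path, k) {
    ev <- evaluate_path(path, model, formula_fsa, cov, codebook,
                        max_runs)
    len <- length(path)
    tibble::tibble(k = k, path = paste(path, collapse = ","),
                   n_states = len, n_runs = ev$n_runs,
                   satisfied = ev$satisfied, witness = ev$witness,
                   method = ev$method)
  })
  path_table <- dplyr::bind_rows(rows)
  structure(
    list(verdict = nrow(path_table) > 0L && all(path_table$satisfied),
         formula = formula %||% (formula_fsa$name %||% "formula"),
         model = model$name %||% "model",
         bound = bound,
         paths = path_table,
         decision_basis = NULL, negated = FALSE),
    class = "mc_result")
}

# Decide one path: admissible letter sets per position, then either
# exhaustive tiling over all runs or DP witness search + witness tiling.
evaluate_path <- function(path, model, fsa, cov, codebook, max_runs) {
  adm <- lapply(path, function(s)
    admissible_letters(s, model, codebook, restrict_to = fsa$alphabet))
  sizes <- lengths(adm)
  n_runs <- prod(sizes)
  if (any(sizes == 0L))
    return(list(satisfied = FALSE, witness = NA_character_, n_runs = 0,
                method = "no-admissible-run"))
  blk <- spacer_block(codebook)
  encode_seq <- function(word)
    paste0(codebook$I1,
           paste0(blk, codebook$letters[word], collapse = ""),
           blk, codebook$I2)
  if (n_runs <= max_runs) {
    idx <- rep(1L, length(adm))
    repeat {
      word <- mapply(function(a, i) a[i], adm, idx)
      if (tile_complete(encode_seq(word), cov, mode = "full"))
        return(list(satisfied = TRUE,
                    witness = paste(word, collapse = ","),
                    n_runs = n_runs, method = "tiling-exhaustive"))
      # odometer, last position fastest (lexicographic run order)
      pos <- length(idx)
      while (pos >= 1L && idx[pos] == sizes[pos]) {
        idx[pos] <- 1L
        pos <- pos - 1L
      }
      if (pos < 1L) break
      idx[pos] <- idx[pos] + 1L
    }
    return(list(satisfied = FALSE, witness = NA_character_,
                n_runs = n_runs, method = "tiling-exhaustive"))
  }
  word <- witness_run(adm, fsa)
  if (is.null(word))
    return(list(satisfied = FALSE, witness = NA_character_,
                n_runs = n_runs, method = "dp-no-witness"))
  if (!tile_complete(encode_seq(word), cov, mode = "full"))
    stop("internal inconsistency: DP witness run does not tile; ",
         "the codebook may be ambiguous", call. = FALSE)
  list(satisfied = TRUE, witness = paste(word, collapse = ","),
       n_runs = n_runs, method = "tiling-witness")
}

# Exact product DP over (position, automaton state): forward reachable state
# sets under the admissible letter choices, then deterministic backward
# extraction of one accepted run (letters preferred in codebook order,
# predecessor states smallest-first).
witness_run <- function(adm, fsa) {
  tr <- fsa$transitions
  n <- length(adm)
  layers <- vector("list", n + 1L)
  layers[[1L]] <- fsa$initial
  for (i in seq_len(n)) {
    cur <- layers[[i]]
    layers[[i + 1L]] <-
      sort(unique(tr$to[tr$from %in% cur & tr$letter %in% adm[[i]]]))
    if (length(layers[[i + 1L]]) == 0L) return(NULL)
  }
  final <- intersect(layers[[n + 1L]], fsa$accepting)
  if (length(final) == 0L) return(NULL)
  word <- character(n)
  state <- min(final)
  for (i in rev(seq_len(n))) {
    cand <- tr[tr$to == state & tr$letter %in% adm[[i]] &
                 tr$from %in% layers[[i]], ]
    cand <- cand[order(match(cand$letter, adm[[i]]), cand$from), ]
    word[i] <- cand$letter[1L]
    state <- cand$from[1L]
  }
  word
}

#' @export
print.mc_result <- function(x, ...) {
  cat("<mc_result> ", x$model, " ⊨ ", x$formula, "?  ",
      if (x$verdict) "YES" else "NO", "\n", sep = "")
  if (!is.null(x$decision_basis))
    cat("  via: ", x$decision_basis, "\n", sep = "")
  if (nrow(x$paths) > 0L)
    cat("  ", if (x$negated) "core-check paths" else "paths",
        " satisfied: ", sum(x$paths$satisfied), "/", nrow(x$paths),
        " (bound ", x$bound, ")\n", sep = "")
  invisible(x)
}

#' Per-path verdict table of a model-checking result
#'
#' One row per checked path family `k`: the state sequence, the number of
#' admissible runs, whether the path satisfies the formula and the
#' witnessing run — the shape of the printed per-path result tables.
#'
#' @param x An `mc_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mc_result <- function(x, ...) x$paths

#' One-row summary of a model-checking result
#' @param x An `mc_result`.
#' @param ... Unused.
#' @return Tibble with `model`, `formula`, `verdict`, `bound`,
#'   `paths_satisfied`, `paths_total`, `negated`, `decision_basis`.
#' @export
glance.mc_result <- function(x, ...) {
  tibble::tibble(model = x$model, formula = x$formula, verdict = x$verdict,
                 bound = x$bound,
                 paths_satisfied = sum(x$paths$satisfied),
                 paths_total = nrow(x$paths),
                 negated = x$negated,
                 decision_basis = x$decision_basis %||% NA_character_)
}

#' Plot per-path verdicts
#' @param object An `mc_result`.
#' @param ... Unused.
#' @return A ggplot bar chart of satisfied/unsatisfied paths by `k`.
#' @export
autoplot.mc_result <- function(object, ...) {
  ggplot2::ggplot(object$paths,
                  ggplot2::aes(x = .data$k, fill = .data$satisfied)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "path family k", y = NULL,
                  title = paste0(object$model, " vs ", object$formula,
                                 ": ", if (object$verdict) "satisfied"
                                 else "not satisfied")) +
    ggplot2::theme_minimal()
}

#' Check a universal basic CTL formula
#'
#' `ApUq`, `AFp`, `AGp`, `AXp` have the same finite-path semantics as the
#' LTL formulas `pUq`, `Fp`, `Gp`, `Xp`, so the TL-MC-DNA loop is called
#' unchanged on the corresponding automaton.
#'
#' @param model A [system_model()] labeled over `p`, `q`.
#' @param name One of `"ApUq"`, `"AFp"`, `"AGp"`, `"AXp"`.
#' @param codebook Codebook (default: the phi1 codebook, whose letters cover
#'   `p`, `q` and their negations).
#' @param bound Optional path bound.
#' @param ... Passed to [tl_mc_dna()].
#' @return An `mc_result`.
#' @export
check_universal_ctl <- function(model, name, codebook = NULL, bound = NULL,
                                ...) {
  core <- switch(name, ApUq = "pUq", AFp = "Fp", AGp = "Gp", AXp = "Xp",
                 stop("unsupported universal CTL formula: ", name,
                      call. = FALSE))
  codebook <- codebook %||% fixture("codebook-phi1")
  res <- tl_mc_dna(model, automaton_for(core, names(codebook$letters)),
                   codebook, bound = bound, formula = name, ...)
  res$decision_basis <- paste0("TL-MC-DNA on ", core)
  res
}

#' Check an existential basic CTL formula via duality
#'
#' Applies the duality reduction ([dual_reduction()]), checks the universal
#' core with the TL-MC-DNA loop, and negates the verdict; the decision basis
#' records which core was checked.
#'
#' @inheritParams check_universal_ctl
#' @param name One of `"EpUq"`, `"EFp"`, `"EGp"`, `"EXp"`.
#' @return An `mc_result` (with `negated = TRUE`).
#' @export
check_existential_ctl <- function(model, name, codebook = NULL, bound = NULL,
                                  ...) {
  rule <- dual_reduction(name)
  codebook <- codebook %||% fixture("codebook-phi1")
  core_res <- tl_mc_dna(model,
                        automaton_for(rule$core, names(codebook$letters)),
                        codebook, bound = bound, formula = rule$core_label,
                        ...)
  res <- core_res
  res$verdict <- !core_res$verdict
  res$formula <- name
  res$negated <- TRUE
  res$decision_basis <- paste0(
    model$name %||% "model",
    if (core_res$verdict) " satisfies " else " does not satisfy ",
    rule$core_label, "; verdict negated")
  res
}

#' Check any basic CTL formula
#'
#' Dispatches universal formulas (`A..`) to [check_universal_ctl()] and
#' existential ones (`E..`) to [check_existential_ctl()].
#'
#' @inheritParams check_universal_ctl
#' @param name A basic CTL formula name.
#' @return An `mc_result`.
#' @export
check_ctl <- function(model, name, codebook = NULL, bound = NULL, ...) {
  if (name %in% c("ApUq", "AFp", "AGp", "AXp"))
    check_universal_ctl(model, name, codebook, bound, ...)
  else if (name %in% c("EpUq", "EFp", "EGp", "EXp"))
    check_existential_ctl(model, name, codebook, bound, ...)
  else stop(name, " is not a basic CTL formula", call. = FALSE)
}

#' Check a basic ITL formula
#'
#' `phi2` (the chop `(p1Uq1);(p2Uq2)`) uses automaton A2 and, when the model
#' carries a prefix/suffix interval annotation, the sequential-composition
#' bound; `phi3` (the star `(pUq)*`) uses A3 with the plain run-length bound.
#'
#' @inheritParams check_universal_ctl
#' @param name `"phi2"` or `"phi3"`.
#' @return An `mc_result`.
#' @export
check_itl <- function(model, name, codebook = NULL, bound = NULL, ...) {
  if (!name %in% c("phi2", "phi3"))
    stop(name, " is not a basic ITL formula", call. = FALSE)
  codebook <- codebook %||% fixture("codebook-ITL")
  if (is.null(bound) && name == "phi2" && !is.null(model$intervals)) {
    iv <- model$intervals
    bound <- composite_bound(iv$prefix$nodes, iv$prefix$edges,
                             iv$suffix$nodes, iv$suffix$edges)
  }
  tl_mc_dna(model, automaton_for(name), codebook, bound = bound,
            formula = name, ...)
}

#' Check the basic PTL projection formula
#'
#' `phi4` = `((p1Uq1),(p2Uq2)) prj (p3 ∧ X q3)`, checked with automaton A4
#' over the compound letters `m1..m4` and the standard loop otherwise.
#'
#' @inheritParams check_universal_ctl
#' @param name Must be `"phi4"`.
#' @return An `mc_result`.
#' @export
check_ptl <- function(model, name = "phi4", codebook = NULL, bound = NULL,
                      ...) {
  if (!identical(name, "phi4"))
    stop(name, " is not the basic PTL formula", call. = FALSE)
  codebook <- codebook %||% fixture("codebook-phi4")
  tl_mc_dna(model, automaton_for("phi4"), codebook, bound = bound,
            formula = name, ...)
}

#' Check a formula by name
#'
#' Front door used by the command-line interface: dispatches any supported
#' formula name — the eight basic CTL formulas, `phi1..phi4`, and the LTL
#' basics `pUq`, `Fp`, `Gp`, `Xp` — to the appropriate checker.
#'
#' @inheritParams check_universal_ctl
#' @param name Formula name.
#' @return An `mc_result`.
#' @export
check_model <- function(model, name, codebook = NULL, bound = NULL, ...) {
  ctl <- c("ApUq", "AFp", "AGp", "AXp", "EpUq", "EFp", "EGp", "EXp")
  if (name %in% ctl) return(check_ctl(model, name, codebook, bound, ...))
  if (name %in% c("phi2", "phi3"))
    return(check_itl(model, name, codebook, bound, ...))
  if (name == "phi4") return(check_ptl(model, name, codebook, bound, ...))
  if (name %in% c("phi1", "pUq", "Fp", "Gp", "Xp")) {
    codebook <- codebook %||% fixture("codebook-phi1")
    return(tl_mc_dna(model,
                     automaton_for(name, names(codebook$letters)),
                     codebook, bound = bound, formula = name, ...))
  }
  stop("unsupported formula: ", name, call. = FALSE)
}
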