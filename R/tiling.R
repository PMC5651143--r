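#' In-silico annealing: tile an input strand with stickers
#'
#' Decides whether the input strand can be exactly partitioned, left to
#' right, into segments that are each the Watson-Crick complement of one of
#' the supplied stickers — the idealized outcome of the annealing step in
#' which a complete double strand forms iff the encoded word is accepted.
#' The search is an exact dynamic program over strand positions, so a tiling
#' is found iff one exists; hybridization is idealized as perfect-complement,
#' zero-mismatch pairing.
#'
#' In `"full"` mode the first segment must come from an initial-state sticker
#' and the last from an acceptance sticker (the molecule must begin at the
#' initiator and terminate at the terminator); `"core"` mode (a strand
#' trimmed with [trim_to_core()]) places any supplied sticker anywhere.
#'
#' For incomplete tilings the reported witness maximizes the covered prefix
#' length (ties broken by sticker row order), and the uncovered positions are
#' listed — the in-silico analogue of the "various lengths" electrophoresis
#' signal.
#'
#' @param input_strand Strand tibble (one row) or a bare 5'->3' sequence.
#' @param stickers Strand tibble; rows with roles `initial`, `acceptance`,
#'   `transition` (role is only enforced in `"full"` mode).
#' @param mode `"full"` or `"core"`.
#' @return Object of class `tiling`: list with `complete`, `placements`
#'   (tibble: `id`, `role`, `start`, `end`, 1-based closed intervals),
#'   `uncovered` (integer positions), `mode`, `strand_length`.
#' @examples
#' cb <- fixture("codebook-phi1")
#' d <- trim_to_core(encode_input_run(c("s", "u", "q"), cb), cb, 0, 2)
#' a1 <- build_sticker_set(automaton_for("phi1"), cb)
#' tile(d, a1[a1$id %in% c("t0s0", "t0u1", "t1q2"), ], mode = "core")
#' @export
tile <- function(input_strand, stickers, mode = c("full", "core")) {
  mode <- match.arg(mode)
  seq <- if (is.character(input_strand)) input_strand else input_strand$sequence
  stopifnot(length(seq) == 1L)
  L <- nchar(seq)
  n <- nrow(stickers)
  covers <- character(n)
  if (n > 0L) {
    # segment a sticker covers = complement of its pairing string; fall back
    # to the stored 5'->3' sequence (reverse complement) for plain strands
    pairing <- stickers[["pairing"]] %||% rep(NA_character_, n)
    has_pairing <- !is.na(pairing)
    covers[has_pairing] <- wc_complement(pairing[has_pairing])
    covers[!has_pairing] <-
      wc_complement(rev_string(stickers$sequence[!has_pairing]))
  }
  lens <- nchar(covers)
  roles <- if ("role" %in% names(stickers)) stickers$role else rep("transition", n)

  # DP: pred_sticker/pred_pos give, for each reachable end position, the
  # first (row-order) placement reaching it
  reached <- c(TRUE, rep(FALSE, L))          # index = position + 1
  pred_sticker <- rep(NA_integer_, L + 1L)
  pred_pos <- rep(NA_integer_, L + 1L)
  worklist <- 0L
  while (length(worklist) > 0L) {
    pos <- worklist[1L]
    worklist <- worklist[-1L]
    for (s in seq_len(n)) {
      if (mode == "full") {
        if (pos == 0L && roles[s] != "initial") next
        if (pos > 0L && roles[s] == "initial") next
        if (roles[s] == "acceptance" && pos + lens[s] != L) next
        if (pos + lens[s] == L && roles[s] != "acceptance") next
      }
      end <- pos + lens[s]
      if (end > L || reached[end + 1L]) next
      if (substr(seq, pos + 1L, end) == covers[s]) {
        reached[end + 1L] <- TRUE
        pred_sticker[end + 1L] <- s
        pred_pos[end + 1L] <- pos
        worklist <- c(worklist, end)
      }
    }
  }
  complete <- reached[L + 1L]
  tip <- if (complete) L else max(which(reached)) - 1L
  placements <- backtrack_placements(tip, pred_sticker, pred_pos, stickers)
  structure(
    list(complete = complete,
         placements = placements,
         uncovered = if (tip < L) seq.int(tip + 1L, L) else integer(),
         mode = mode, strand_length = L),
    class = "tiling")
}

# Precompute the covered-segment strings of a sticker set once, so repeated
# completeness checks skip per-call tibble work.
sticker_covers <- function(stickers) {
  n <- nrow(stickers)
  covers <- character(n)
  pairing <- stickers[["pairing"]] %||% rep(NA_character_, n)
  has_pairing <- !is.na(pairing)
  covers[has_pairing] <- wc_complement(pairing[has_pairing])
  covers[!has_pairing] <-
    wc_complement(rev_string(stickers$sequence[!has_pairing]))
  list(covers = covers, lens = nchar(covers),
       roles = if ("role" %in% names(stickers)) stickers$role
               else rep("transition", n))
}

# Completeness-only DP (same search as tile(), no placement bookkeeping).
tile_complete <- function(seq, cov, mode = "full") {
  L <- nchar(seq)
  n <- length(cov$covers)
  reached <- c(TRUE, rep(FALSE, L))
  worklist <- 0L
  while (length(worklist) > 0L) {
    pos <- worklist[1L]
    worklist <- worklist[-1L]
    for (s in seq_len(n)) {
      if (mode == "full") {
        if (pos == 0L && cov$roles[s] != "initial") next
        if (pos > 0L && cov$roles[s] == "initial") next
        end0 <- pos + cov$lens[s]
        if (cov$roles[s] == "acceptance" && end0 != L) next
        if (end0 == L && cov$roles[s] != "acceptance") next
      }
      end <- pos + cov$lens[s]
      if (end > L || reached[end + 1L]) next
      if (substr(seq, pos + 1L, end) == cov$covers[s]) {
        if (end == L) return(TRUE)
        reached[end + 1L] <- TRUE
        worklist <- c(worklist, end)
      }
    }
  }
  reached[L + 1L]
}

backtrack_placements <- function(tip, pred_sticker, pred_pos, stickers) {
  rows <- list()
  pos <- tip
  while (pos > 0L && !is.na(pred_sticker[pos + 1L])) {
    s <- pred_sticker[pos + 1L]
    start <- pred_pos[pos + 1L] + 1L
    rows[[length(rows) + 1L]] <- tibble::tibble(
      id = stickers$id[s],
      role = if ("role" %in% names(stickers)) stickers$role[s] else
        "transition",
      start = start, end = pos)
    pos <- start - 1L
  }
  if (length(rows) == 0L)
    return(tibble::tibble(id = character(), role = character(),
                          start = integer(), end = integer()))
  dplyr::arrange(dplyr::bind_rows(rev(rows)), .data$start)
}

#' @export
print.tiling <- function(x, ...) {
  cat("<tiling: ", if (x$complete) "complete" else "incomplete",
      " (", x$mode, " mode, ", x$strand_length, " nt)>\n", sep = "")
  if (nrow(x$placements) > 0L) print(x$placements, n = Inf)
  if (length(x$uncovered) > 0L)
    cat("uncovered positions:", x$uncovered[1], "..",
        x$uncovered[length(x$uncovered)], "\n")
  invisible(x)
}

#' Tidy tiling placements
#' @param x A `tiling`.
#' @param ... Unused.
#' @return The placements tibble.
#' @export
tidy.tiling <- function(x, ...) x$placements

#' One-row tiling summary
#' @param x A `tiling`.
#' @param ... Unused.
#' @return Tibble with `complete`, `n_placements`, `covered`, `strand_length`.
#' @export
glance.tiling <- function(x, ...) {
  tibble::tibble(complete = x$complete, n_placements = nrow(x$placements),
                 covered = x$strand_length - length(x$uncovered),
                 strand_length = x$strand_length)
}

#' Plot a tiling as covered intervals along the strand
#' @param object A `tiling`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tiling <- function(object, ...) {
  pl <- object$placements
  ggplot2::ggplot(pl) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                       y = .data$id, yend = .data$id,
                                       colour = .data$role),
                          linewidth = 3) +
    ggplot2::xlim(1, object$strand_length) +
    ggplot2::labs(x = "input strand position (5'->3')", y = NULL,
                  title = if (object$complete) "complete double strand"
                  else "incomplete tiling") +
    ggplot2::theme_minimal()
}

#' Combinatorial group experiments
#'
#' Enumerates every size-`group_size` subset of the supplied sticker species
#' in deterministic [utils::combn()] order, tiles the input strand against
#' each subset, and reports which groups form a complete double strand — the
#' in-silico version of running one annealing tube per sticker combination.
#'
#' @param input_strand Strand tibble or sequence (typically a trimmed core).
#' @param species Strand tibble of candidate stickers.
#' @param group_size Number of species per group.
#' @param mode Tiling mode, default `"core"`.
#' @return Tibble with `group`, `members`, `complete`, `covered`; attribute
#'   `n_complete`.
#' @export
group_experiments <- function(input_strand, species, group_size,
                              mode = "core") {
  stopifnot(group_size >= 1L, group_size <= nrow(species))
  combos <- utils::combn(nrow(species), group_size, simplify = FALSE)
  rows <- purrr::imap(combos, function(idx, g) {
    res <- tile(input_strand, species[idx, ], mode = mode)
    tibble::tibble(group = g,
                   members = paste(species$id[idx], collapse = ","),
                   complete = res$complete,
                   covered = res$strand_length - length(res$uncovered))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n_complete") <- sum(out$complete)
  out
}

#' Path verdict from per-run tiling results
#'
#' A path satisfies the formula iff at least one of its admissible runs forms
#' a complete double strand (runs are evaluated in isolation, one tube per
#' run); the witnessing run is recorded. Zero runs means vacuous failure.
#'
#' @param results List of `tiling` objects (or logical vector of
#'   completeness flags), one per admissible run of the path.
#' @param run_labels Optional character labels for the runs.
#' @return List with `satisfied` (logical) and `witness` (label or `NA`).
#' @export
readout <- function(results, run_labels = NULL) {
  flags <- if (is.logical(results)) results else
    vapply(results, function(r) r$complete, logical(1))
  if (is.null(run_labels))
    run_labels <- if (length(flags)) as.character(seq_along(flags))
                  else character()
  hit <- which(flags)
  list(satisfied = length(hit) > 0L,
       witness = if (length(hit) > 0L) run_labels[hit[1L]] else NA_character_)
}
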