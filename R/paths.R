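#' Run-length exploration bound
#'
#' A system satisfies a pUq-like formula iff all runs shorter than
#' `|V| * 2^(|V|-1) + |E|` satisfy it, where `|V|` and `|E|` count the nodes
#' and edges of the system automaton. The bound therefore delimits how many
#' path families the check must explore.
#'
#' @param n_nodes Number of nodes (>= 1).
#' @param n_edges Number of edges (>= 0).
#' @return Integer bound.
#' @examples
#' run_length_bound(3, 3) # 15
#' run_length_bound(2, 2) # 6
#' @export
run_length_bound <- function(n_nodes, n_edges) {
  stopifnot(n_nodes >= 1, n_edges >= 0)
  as.integer(n_nodes * 2^(n_nodes - 1) + n_edges)
}

#' Composite bound for sequentially composed (chop) formulas
#'
#' The interval chop formula `(p1 U q1); (p2 U q2)` decomposes a path into a
#' prefix and a suffix interval; its exploration bound is the sum of the
#' run-length bounds of the two intervals.
#'
#' @param prefix_nodes,prefix_edges Node/edge counts of the prefix interval.
#' @param suffix_nodes,suffix_edges Node/edge counts of the suffix interval.
#' @return Integer bound.
#' @examples
#' composite_bound(2, 2, 2, 1) # 11
#' @export
composite_bound <- function(prefix_nodes, prefix_edges,
                            suffix_nodes, suffix_edges) {
  run_length_bound(prefix_nodes, prefix_edges) +
    run_length_bound(suffix_nodes, suffix_edges)
}

#' Enumerate the k-indexed maximal paths of a system model
#'
#' Reproduces the k-indexed path families of cyclic system models: when a
#' unique simple cycle is reachable from the initial state, path `k` repeats
#' the cycle block `k` times and then proceeds along the (unique shortest)
#' tail to a terminal state — e.g. `(0,1)^k, 2`. For models without that
#' structure, the generic fallback enumerates all walks from the initial
#' state of length at most `run_length_bound(|V|, |E|)`, each ending at a
#' terminal state or truncated at the bound, deduplicated and ordered
#' deterministically (k ascending; ties by lexicographic state sequence).
#'
#' @param model A [system_model()].
#' @param k_max Number of path families to return (>= 1).
#' @return List of integer state vectors, each starting at the initial state.
#' @export
enumerate_paths <- function(model, k_max) {
  stopifnot(inherits(model, "system_model"), k_max >= 1L)
  k_max <- as.integer(k_max)
  term <- terminal_states(model)
  if (model$n_states == 1L && nrow(model$edges) == 0L)
    return(list(model$initial))
  fam <- cycle_family(model)
  if (!is.null(fam)) {
    return(lapply(seq_len(k_max), function(k)
      c(rep(fam$cycle, k), fam$tail)))
  }
  paths <- bounded_walks(model,
                         run_length_bound(model$n_states, nrow(model$edges)),
                         k_max)
  if (length(paths) == 0L) {
    warning("no path from the initial state", call. = FALSE)
    return(list())
  }
  keys <- vapply(paths, function(p) paste(p, collapse = ","), character(1))
  paths <- paths[!duplicated(keys)]
  ord <- order(lengths(paths),
               vapply(paths, function(p)
                 paste(sprintf("%06d", p), collapse = ","), character(1)))
  paths <- paths[ord]
  paths[seq_len(min(k_max, length(paths)))]
}

# Detect a unique simple cycle through the initial component plus its exit
# tail. Returns list(cycle=, tail=) or NULL when the model does not have the
# single-cycle shape.
cycle_family <- function(model) {
  edges <- model$edges
  succ <- split(edges$to, factor(edges$from,
                                 levels = seq_len(model$n_states) - 1L))
  # walk from initial until a state repeats
  path <- model$initial
  repeat {
    nxt <- succ[[as.character(path[length(path)])]]
    if (length(nxt) == 0L) return(NULL)             # acyclic from initial
    nonterm <- setdiff(nxt, terminal_states(model))
    if (any(nxt %in% path)) {
      close_at <- nxt[nxt %in% path][1]
      cyc <- path[which(path == close_at)[1]:length(path)]
      if (close_at != model$initial) return(NULL)   # cycle must start the path
      # exits from the cycle
      exits <- edges[edges$from %in% cyc & !(edges$to %in% cyc), ]
      if (nrow(exits) == 0L) return(list(cycle = cyc, tail = integer()))
      if (nrow(exits) > 1L) return(NULL)
      tail <- tail_to_terminal(model, exits$to[1])
      if (is.null(tail)) return(NULL)
      return(list(cycle = cyc, tail = tail))
    }
    if (length(nonterm) != 1L) return(NULL)
    path <- c(path, nonterm[1])
    if (length(path) > model$n_states + 1L) return(NULL)
  }
}

# unique deterministic chain from `from` to a terminal state, or NULL
tail_to_terminal <- function(model, from) {
  succ <- split(model$edges$to,
                factor(model$edges$from, levels = seq_len(model$n_states) - 1L))
  out <- from
  while (!(out[length(out)] %in% terminal_states(model))) {
    nxt <- succ[[as.character(out[length(out)])]]
    if (length(nxt) != 1L || nxt %in% out) return(NULL)
    out <- c(out, nxt)
  }
  out
}

# All walks from the initial state, ending at a terminal state or truncated
# at `cap` states. Breadth-first by length so walks complete in (length, lex)
# order; expansion stops once `want` walks have completed, which keeps the
# generic fallback tractable on branching models.
bounded_walks <- function(model, cap, want = Inf) {
  succ <- split(model$edges$to,
                factor(model$edges$from, levels = seq_len(model$n_states) - 1L))
  term <- terminal_states(model)
  frontier <- list(model$initial)
  out <- list()
  while (length(frontier) > 0L && length(out) < want) {
    nxt_frontier <- list()
    for (path in frontier) {
      last <- path[length(path)]
      if (last %in% term || length(path) >= cap) {
        out[[length(out) + 1L]] <- path
      } else {
        for (s in sort(succ[[as.character(last)]]))
          nxt_frontier[[length(nxt_frontier) + 1L]] <- c(path, s)
      }
    }
    # keep the enumeration tractable on branching cyclic models: partial
    # walks are generated in lexicographic order, so truncating the frontier
    # keeps exactly the walks that can still rank among the first k_max
    if (length(nxt_frontier) > 5000L)
      nxt_frontier <- nxt_frontier[seq_len(5000L)]
    frontier <- nxt_frontier
  }
  out
}
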