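# Independent oracles and random-instance generators shared by the suite.

# Brute-force NFA acceptance: depth-first enumeration of all transition
# paths, independent of the subset-propagation implementation in accepts().
oracle_accepts <- function(fsa, word) {
  dfs <- function(state, i) {
    if (i > length(word)) return(state %in% fsa$accepting)
    tr <- fsa$transitions
    nxt <- tr$to[tr$from == state & tr$letter == word[i]]
    for (s in nxt) if (dfs(s, i + 1L)) return(TRUE)
    FALSE
  }
  dfs(fsa$initial, 1L)
}

# Pure-logic model-check oracle: same path families, but each path is decided
# by evaluating the formula automaton directly over the admissible runs with
# a memoized backward recursion — no DNA encoding or tiling anywhere, and a
# different traversal than the implementation's forward subset DP. For short
# paths every run is additionally enumerated and fed to oracle_accepts.
oracle_path_satisfied <- function(adm, fsa) {
  n <- length(adm)
  if (any(lengths(adm) == 0L)) return(FALSE)
  tr <- fsa$transitions
  memo <- matrix(NA, nrow = n + 1L, ncol = fsa$n_states)
  sat <- function(i, state) {
    if (i > n) return(state %in% fsa$accepting)
    if (!is.na(memo[i, state + 1L])) return(memo[i, state + 1L])
    ok <- FALSE
    for (a in adm[[i]]) {
      for (nxt in tr$to[tr$from == state & tr$letter == a])
        if (sat(i + 1L, nxt)) { ok <- TRUE; break }
      if (ok) break
    }
    memo[i, state + 1L] <<- ok
    ok
  }
  sat(1L, fsa$initial)
}

oracle_check <- function(model, fsa, codebook, bound) {
  paths <- enumerate_paths(model, bound)
  sat <- vapply(paths, function(path) {
    adm <- lapply(path, function(s)
      admissible_letters(s, model, codebook, restrict_to = fsa$alphabet))
    res <- oracle_path_satisfied(adm, fsa)
    if (length(adm) <= 6L && all(lengths(adm) > 0L)) {
      runs <- expand.grid(adm, stringsAsFactors = FALSE)
      brute <- FALSE
      for (r in seq_len(nrow(runs)))
        if (oracle_accepts(fsa, as.character(runs[r, ]))) {
          brute <- TRUE
          break
        }
      stopifnot(identical(res, brute))
    }
    res
  }, logical(1))
  length(sat) > 0L && all(sat)
}

random_fsa <- function(n_states = sample(2:5, 1), n_letters = sample(1:3, 1),
                       density = 0.5) {
  letters_ <- paste0("a", seq_len(n_letters))
  combos <- expand.grid(from = seq_len(n_states) - 1L, letter = letters_,
                        to = seq_len(n_states) - 1L,
                        stringsAsFactors = FALSE)
  keep <- stats::runif(nrow(combos)) < density
  tr <- combos[keep, , drop = FALSE]
  if (nrow(tr) == 0L) tr <- combos[1, , drop = FALSE]
  fsa(letters_, n_states, tr,
      initial = sample(seq_len(n_states) - 1L, 1),
      accepting = sample(seq_len(n_states) - 1L,
                         sample(seq_len(n_states), 1)))
}

# Random structurally valid codebook for an automaton: distinct codewords
# and spacers, enough spacers for every state index plus a spare.
random_codebook <- function(fsa, letter_len = 3L) {
  n_letters <- length(fsa$alphabet)
  n_spacers <- fsa$n_states + 1L
  pool <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), letter_len)),
                1, paste, collapse = "")
  words <- sample(pool, n_letters + n_spacers)
  codebook(stats::setNames(words[seq_len(n_letters)], fsa$alphabet),
           spacers = words[n_letters + seq_len(n_spacers)],
           I1 = paste(sample(c("A", "C", "G", "T"), 4, replace = TRUE),
                      collapse = ""),
           I2 = paste(sample(c("A", "C", "G", "T"), 4, replace = TRUE),
                      collapse = ""))
}

random_word <- function(alphabet, max_len = 6L) {
  n <- sample(0:max_len, 1)
  if (n == 0L) character() else sample(alphabet, n, replace = TRUE)
}

# Random labeled system model over propositions p, q: every state gets a
# random truth assignment (the phi1 codebook always admits some letter), and
# every non-terminal state keeps at least one outgoing edge by construction.
random_model <- function(n_states = sample(2:4, 1)) {
  idx <- seq_len(n_states) - 1L
  edges <- do.call(rbind, lapply(idx, function(s) {
    n_out <- sample(0:2, 1)
    if (n_out == 0L) return(NULL)
    data.frame(from = s, to = sample(idx, n_out))
  }))
  if (is.null(edges) || !0L %in% edges$from)
    edges <- rbind(edges, data.frame(from = 0L, to = sample(idx, 1)))
  edges <- unique(edges)
  labels <- stats::setNames(lapply(idx, function(s)
    c(p = sample(c(TRUE, FALSE), 1), q = sample(c(TRUE, FALSE), 1))),
    as.character(idx))
  system_model(n_states, edges, labels, initial = 0L)
}

strip_ws <- function(x) gsub("[[:space:]]", "", x)
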