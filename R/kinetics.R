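#' Construct a hybridization reaction network
#'
#' A small container for exact stochastic simulation: named species with
#' initial molecule counts, and mass-action reactions (reactant multiset ->
#' product multiset with a stochastic rate constant). The `composition`
#' attribute maps each species to the multiset of elementary strands it
#' contains, which is what the mass-conservation law is stated over.
#'
#' @param species Character vector of species names.
#' @param reactions Tibble/list-columns: `reactants` and `products` are lists
#'   of character vectors (species names, duplicated for stoichiometry > 1),
#'   `rate` numeric stochastic rate constants (> 0).
#' @param counts Named integer vector of initial counts (missing species
#'   default to 0).
#' @param volume Container volume in liters (bookkeeping; default 1e-15).
#' @param composition Optional named list: species -> character vector of
#'   elementary strand names (with multiplicity).
#' @return Object of class `reaction_network`.
#' @export
reaction_network <- function(species, reactions, counts, volume = 1e-15,
                             composition = NULL) {
  reactions <- tibble::as_tibble(reactions)
  if (nrow(reactions) > 0L) {
    stopifnot(all(c("reactants", "products", "rate") %in% names(reactions)),
              all(reactions$rate > 0))
    refs <- unique(unlist(c(reactions$reactants, reactions$products)))
    stopifnot(all(refs %in% species))
  }
  x0 <- stats::setNames(rep(0, length(species)), species)
  x0[names(counts)] <- counts
  stopifnot(all(x0 >= 0))
  structure(list(species = species, reactions = reactions, counts = x0,
                 volume = volume,
                 composition = composition),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network: ", length(x$species), " species, ",
      nrow(x$reactions), " reactions, V = ", format(x$volume), " L>\n",
      sep = "")
  invisible(x)
}

#' Exact stochastic simulation (Gillespie direct method)
#'
#' Simulates the reaction network with the direct method: exponential waiting
#' times with total propensity `a0`, next reaction chosen with probability
#' proportional to its mass-action propensity. Statistically identical to
#' next-reaction-method simulators; deterministic given `seed`.
#'
#' @param network A [reaction_network()].
#' @param t_end Stop time in seconds; `Inf` (default) runs until no reaction
#'   has positive propensity.
#' @param seed Integer seed for reproducibility (`NULL` = current RNG state).
#' @param record_every Record the state every this many reaction events
#'   (the initial and final states are always recorded).
#' @param max_events Safety cap on simulated events.
#' @return Object of class `ssa_trajectory`: `time` vector and `counts`
#'   matrix (snapshots x species); see [tidy.ssa_trajectory()].
#' @examples
#' net <- reaction_network(
#'   c("A", "B", "AB"),
#'   tibble::tibble(reactants = list(c("A", "B")), products = list("AB"),
#'                  rate = 1e-3),
#'   counts = c(A = 100, B = 100))
#' traj <- simulate_ssa(net, seed = 1)
#' @export
simulate_ssa <- function(network, t_end = Inf, seed = NULL,
                         record_every = 100L, max_events = 2e6) {
  stopifnot(inherits(network, "reaction_network"))
  if (!is.null(seed)) set.seed(seed)
  if (length(network$species) == 0L) stop("empty network", call. = FALSE)
  x <- network$counts
  rx <- network$reactions
  nr <- nrow(rx)
  # integer index representation of reactant/product multisets; reactant
  # stoichiometry precomputed once so the event loop stays cheap
  r_idx <- lapply(rx$reactants, match, network$species)
  p_idx <- lapply(rx$products, match, network$species)
  r_stoich <- lapply(r_idx, function(idx) {
    cnt <- table(idx)
    cbind(sp = as.integer(names(cnt)), n = as.integer(cnt))
  })
  rates <- rx$rate
  propensity <- function(x) {
    vapply(seq_len(nr), function(j) {
      st <- r_stoich[[j]]
      h <- 1
      for (row in seq_len(nrow(st))) {
        # falling factorial for identical reactants
        h <- h * prod(x[st[row, 1L]] - seq_len(st[row, 2L]) + 1)
      }
      rates[j] * h
    }, numeric(1))
  }
  times <- numeric(0)
  snaps <- list()
  record <- function(t) {
    times[length(times) + 1L] <<- t
    snaps[[length(snaps) + 1L]] <<- x
  }
  t <- 0
  record(t)
  ev <- 0L
  while (ev < max_events) {
    a <- if (nr > 0L) propensity(x) else numeric(0)
    a0 <- sum(a)
    if (a0 <= 0) break
    dt <- stats::rexp(1, a0)
    if (t + dt > t_end) { t <- t_end; break }
    t <- t + dt
    j <- sample.int(nr, 1L, prob = a)
    for (i in r_idx[[j]]) x[i] <- x[i] - 1
    for (i in p_idx[[j]]) x[i] <- x[i] + 1
    ev <- ev + 1L
    if (ev %% record_every == 0L) record(t)
  }
  record(t)
  structure(list(time = times,
                 counts = do.call(rbind, snaps),
                 species = network$species,
                 n_events = ev,
                 network = network),
            class = "ssa_trajectory")
}

#' @export
print.ssa_trajectory <- function(x, ...) {
  cat("<ssa_trajectory: ", x$n_events, " events, t = [0, ",
      format(max(x$time)), "], ", length(x$species), " species>\n", sep = "")
  invisible(x)
}

#' Long-format tidy trajectory
#' @param x An `ssa_trajectory`.
#' @param ... Unused.
#' @return Tibble with `time`, `species`, `count`.
#' @export
tidy.ssa_trajectory <- function(x, ...) {
  df <- tibble::as_tibble(as.data.frame(x$counts))
  names(df) <- x$species
  df$time <- x$time
  tidyr::pivot_longer(df, -"time", names_to = "species",
                      values_to = "count")
}

#' Plot species counts over time
#' @param object An `ssa_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ssa_trajectory <- function(object, ...) {
  ggplot2::ggplot(tidy.ssa_trajectory(object),
                  ggplot2::aes(x = .data$time, y = .data$count,
                               colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "molecules") +
    ggplot2::theme_minimal()
}

#' Per-strand conservation totals along a trajectory
#'
#' For every elementary strand named in the network's composition map, sums
#' its copies across all complexes at each recorded time. Under any
#' trajectory these totals are constant (strands are neither created nor
#' destroyed, only combined).
#'
#' @param trajectory An `ssa_trajectory` from a network with a composition
#'   attribute.
#' @return Tibble with `time` and one column per elementary strand.
#' @export
conservation_totals <- function(trajectory) {
  comp <- trajectory$network$composition
  stopifnot(!is.null(comp))
  strands <- unique(unlist(comp))
  mult <- vapply(strands, function(st)
    vapply(trajectory$species, function(sp)
      sum(comp[[sp]] == st), numeric(1)),
    numeric(length(trajectory$species)))
  totals <- trajectory$counts %*% mult
  out <- tibble::as_tibble(as.data.frame(totals))
  names(out) <- strands
  out$time <- trajectory$time
  dplyr::relocate(out, "time")
}

#' Build the stepwise annealing network for a tiling
#'
#' Species are the free input strand, the free stickers, and every partial
#' assembly consistent with the tiling's placements (stickers bind
#' independently, so an assembly is any subset of placed stickers bound to
#' one input molecule). Reactions add one placed sticker at a time,
#' irreversibly and with a common rate constant — rate constants are not
#' dictated by the underlying chemistry here and default to equal. The
#' complete duplex (all placements bound, strand fully covered) exists as a
#' species only when the tiling is complete.
#'
#' @param input_strand Strand tibble or 5'->3' sequence.
#' @param stickers Sticker strand tibble.
#' @param mode Tiling mode (default `"core"`).
#' @param rate Common stochastic association rate constant.
#' @param n_copies Initial copies of the input strand and of every sticker
#'   species (default 60000).
#' @param volume Container volume in liters (default 1e-15).
#' @return A [reaction_network()]; attribute `complete_species` names the
#'   complete-duplex species (`NA` when the tiling is incomplete).
#' @export
build_annealing_network <- function(input_strand, stickers, mode = "core",
                                    rate = 1e-4, n_copies = 60000,
                                    volume = 1e-15) {
  tl <- tile(input_strand, stickers, mode = mode)
  pl <- tl$placements
  npl <- nrow(pl)
  if (npl > 12L)
    stop("assembly space 2^", npl, " too large for explicit enumeration",
         call. = FALSE)
  sticker_ids <- unique(stickers$id)
  subset_name <- function(sel) {
    if (!any(sel)) return("input")
    paste0("input+", paste(pl$id[sel], collapse = "+"))
  }
  assemblies <- lapply(seq_len(2^npl) - 1L, function(code)
    as.logical(bitwAnd(code, 2^(seq_len(npl) - 1L)) > 0L))
  asm_names <- vapply(assemblies, subset_name, character(1))
  species <- c(asm_names, sticker_ids)
  composition <- c(
    lapply(assemblies, function(sel) c("input", pl$id[sel])),
    lapply(sticker_ids, function(id) id))
  names(composition) <- species
  rows <- list()
  for (ai in seq_along(assemblies)) {
    sel <- assemblies[[ai]]
    for (j in which(!sel)) {
      sel2 <- sel
      sel2[j] <- TRUE
      rows[[length(rows) + 1L]] <- tibble::tibble(
        reactants = list(c(asm_names[ai], pl$id[j])),
        products = list(subset_name(sel2)),
        rate = rate)
    }
  }
  reactions <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(reactants = list(), products = list(), rate = numeric())
  counts <- stats::setNames(rep(0, length(species)), species)
  counts["input"] <- n_copies
  counts[sticker_ids] <- n_copies
  net <- reaction_network(species, reactions, counts, volume = volume,
                          composition = composition)
  attr(net, "complete_species") <-
    if (tl$complete && npl > 0L) subset_name(rep(TRUE, npl)) else NA_character_
  attr(net, "tiling") <- tl
  net
}
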