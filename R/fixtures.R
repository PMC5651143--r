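#' Built-in reference fixtures
#'
#' The three system models and three codebooks used throughout the reference
#' experiments:
#'
#' * `"M1"` — 3 states, edges `0->1, 1->0, 1->2`, labeled over `p`, `q`
#'   (state 0: `p`; state 1: neither; state 2: `q`). State 2's `p` value is
#'   unconstrained by any printed verdict and is fixed to `FALSE`.
#' * `"M2"` — 4 states, edges `0->1, 1->0, 1->2, 2->3`, labeled over
#'   `p1, q1, p2, q2, p3, q3` (state 0: `p1, p3`; state 1: `p1, q1`;
#'   state 2: `p2`; state 3: `q2`). Carries the prefix/suffix interval
#'   annotation (2 nodes/2 edges and 2 nodes/1 edge) used by the
#'   sequential-composition bound.
#' * `"M3"` — 2 states cycling `0->1->0`, state 0: `p`, state 1: `q`.
#' * `"codebook-phi1"` — 3-nt letters `p, q, r = ¬p, s = ¬q, u = ¬p∧¬q`,
#'   spacers `X0..X3`, `I1 = GCCA`, `I2 = CGTC`.
#' * `"codebook-ITL"` — 3-nt letters `p1, p2, q1, q2, p, q`, spacers
#'   `X0..X3`, `I1 = CGCT`, `I2 = CGGC` (shared by the two ITL formulas).
#' * `"codebook-phi4"` — 4-nt letters including the compound
#'   `m1 = p1∧p3 .. m4 = q2∧q3`, spacers `X0..X7`, `I1 = GCAG`, `I2 = AACC`.
#'
#' @param name Fixture name (aliases `"codebook-phi2"`/`"codebook-phi3"` map
#'   to `"codebook-ITL"`).
#' @return A [system_model()] or [codebook()].
#' @examples
#' fixture("M1")
#' fixture("codebook-phi1")
#' @export
fixture <- function(name) {
  switch(
    name,
    M1 = system_model(
      3L,
      data.frame(from = c(0, 1, 1), to = c(1, 0, 2)),
      labels = list(`0` = c(p = TRUE,  q = FALSE),
                    `1` = c(p = FALSE, q = FALSE),
                    `2` = c(p = FALSE, q = TRUE)),
      initial = 0L, name = "M1"),
    M2 = system_model(
      4L,
      data.frame(from = c(0, 1, 1, 2), to = c(1, 0, 2, 3)),
      labels = list(
        `0` = c(p1 = TRUE,  q1 = FALSE, p2 = FALSE, q2 = FALSE,
                p3 = TRUE,  q3 = FALSE),
        `1` = c(p1 = TRUE,  q1 = TRUE,  p2 = FALSE, q2 = FALSE,
                p3 = FALSE, q3 = FALSE),
        `2` = c(p1 = FALSE, q1 = FALSE, p2 = TRUE,  q2 = FALSE,
                p3 = FALSE, q3 = FALSE),
        `3` = c(p1 = FALSE, q1 = FALSE, p2 = FALSE, q2 = TRUE,
                p3 = FALSE, q3 = FALSE)),
      initial = 0L,
      intervals = list(prefix = list(nodes = 2L, edges = 2L),
                       suffix = list(nodes = 2L, edges = 1L)),
      name = "M2"),
    M3 = system_model(
      2L,
      data.frame(from = c(0, 1), to = c(1, 0)),
      labels = list(`0` = c(p = TRUE,  q = FALSE),
                    `1` = c(p = FALSE, q = TRUE)),
      initial = 0L, name = "M3"),
    `codebook-phi1` = codebook(
      c(p = "CGA", q = "CCC", r = "CGC", s = "AGC", u = "GCG"),
      spacers = c("GAA", "TTG", "CAA", "GGC"),
      I1 = "GCCA", I2 = "CGTC",
      conditions = list(
        r = list(neg = "p"),
        s = list(neg = "q"),
        u = list(neg = c("p", "q"))),
      name = "codebook-phi1"),
    `codebook-ITL` = ,
    `codebook-phi2` = ,
    `codebook-phi3` = codebook(
      c(p1 = "GAT", p2 = "GAA", q1 = "ATA", q2 = "TTC",
        p = "TAT", q = "TGA"),
      spacers = c("CGA", "ATC", "GGA", "ATG"),
      I1 = "CGCT", I2 = "CGGC",
      name = "codebook-ITL"),
    `codebook-phi4` = codebook(
      c(p1 = "CCGC", q1 = "ATCC", p2 = "CAAA", q2 = "GGGA",
        p3 = "TTAC", q3 = "ATAT",
        m1 = "GTGA", m2 = "GACC", m3 = "AACG", m4 = "GACG"),
      spacers = c("TCGG", "CGCA", "TCAT", "GTGG",
                  "TCTT", "TGCA", "TGGA", "CGTA"),
      I1 = "GCAG", I2 = "AACC",
      conditions = list(
        m1 = list(pos = c("p1", "p3")),
        m2 = list(pos = c("q1", "p3")),
        m3 = list(pos = c("p2", "q3")),
        m4 = list(pos = c("q2", "q3"))),
      name = "codebook-phi4"),
    stop("unknown fixture: ", name, call. = FALSE)
  )
}

#' Names of all built-in fixtures
#' @return Character vector accepted by [fixture()].
#' @export
fixture_names <- function() {
  c("M1", "M2", "M3", "codebook-phi1", "codebook-ITL", "codebook-phi4")
}
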