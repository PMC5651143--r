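# stickermc

Model checking of basic CTL, ITL and PTL formulas by DNA computing with
**sticker automata**, simulated in silico.

## The problem

Molecular model checking encodes both a system and a temporal-logic formula
as DNA and lets hybridization do the verification work. A formula's
nondeterministic finite automaton becomes a pool of short "sticker" strands;
a run of the system becomes one long input strand

    5′ I1 X0…Xm C(a1) X0…Xm C(a2) … C(an) X0…Xm I2 3′

(letter codewords C(a) separated by positional spacer blocks X0…Xm, bounded
by an initiator I1 and terminator I2). Each transition t(s_i, a) = s_j is the
Watson–Crick complement of `X_{i+1}…Xm C(a) X0…Xj`: how deep a sticker
reaches into the next spacer block carries the automaton's state index, so
stickers chain only along valid transition paths. The input strand anneals
into a **complete double strand iff the word is accepted** — a single
uniform electrophoresis band is the molecular "yes".

On top of that primitive, a labeled system model M satisfies a formula iff
every path up to the exploration bound

    |V| · 2^(|V|−1) + |E|

(summed over prefix/suffix intervals for the interval chop formula) has at
least one admissible run whose strand anneals completely. Universal CTL
formulas (ApUq, AFp, AGp, AXp) are checked directly via their LTL cores;
existential ones (EpUq, EFp, EGp, EXp) by checking the dual core (φ1 = the
dual-until automaton, G¬p, F¬p, X¬p) and negating the verdict. The ITL chop
`(p1Uq1);(p2Uq2)`, the ITL star `(pUq)*` and the PTL projection
`((p1Uq1),(p2Uq2)) prj (p3 ∧ Xq3)` use the purpose-built automata A2, A3
and A4.

`stickermc` implements the whole pipeline: strand encoding (byte-exact
against the published sticker tables), exact annealing simulation
(dynamic-programming tiling), combinatorial group experiments, the
model-checking loop with its duality reductions, and a Gillespie stochastic
simulator for the competitive hybridization kinetics. The three reference
system models (M1, M2, M3) and the three published codebooks ship as
fixtures.

## A worked example

Check the dual-until formula φ1 on the 3-state cyclic model M1 (3 nodes,
3 edges, so 3·2² + 3 = 15 path families):

```r
library(stickermc)

res <- tl_mc_dna(fixture("M1"), automaton_for("phi1"),
                 fixture("codebook-phi1"), formula = "phi1")
res
#> <mc_result> M1 ⊨ phi1?  YES
#>   paths satisfied: 15/15 (bound 15)

tidy(res)[1:3, ]
#> # A tibble: 3 × 7
#>       k path          n_states n_runs satisfied witness       method
#>   <int> <chr>            <int>  <dbl> <lgl>     <chr>         <chr>
#> 1     1 0,1,2                3      2 TRUE      s,u,q         tiling-exhaustive
#> 2     2 0,1,0,1,2            5      4 TRUE      s,s,s,u,q     tiling-exhaustive
#> 3     3 0,1,0,1,0,1,2        7      8 TRUE      s,s,s,s,s,u,q tiling-exhaustive
```

Every path family k = (0,1)^k,2 is satisfied, witnessed by the run that
stays on `s` (= ¬q) and switches to `u` (= ¬p∧¬q) just before `q` — so M1
satisfies φ1, and by duality does **not** satisfy EpUq. The underlying
molecular event for path 1 is visible directly:

```r
cb <- fixture("codebook-phi1")
d  <- trim_to_core(encode_input_run(c("s", "u", "q"), cb), cb, 0, 2)
ss <- build_sticker_set(automaton_for("phi1"), cb)
tile(d, ss[match(c("t0s0", "t0u1", "t1q2"), ss$id), ], mode = "core")
#> <tiling: complete (core mode, 51 nt)>
#> # A tibble: 3 × 4
#>   id    role       start   end
#>   <chr> <chr>      <int> <int>
#> 1 t0s0  transition     1    15
#> 2 t0u1  transition    16    33
#> 3 t1q2  transition    34    51
```

The 51-nt trimmed run strand is paired wall-to-wall at sites 1–15, 16–33
and 34–51 — the complete double strand. `group_experiments()` confirms this
is the *only* one of the C(5,3) = 10 sticker trios that completes, and an
existential check rides the same machinery:

```r
check_ctl(fixture("M1"), "EFp")
#> <mc_result> M1 ⊨ EFp?  YES
#>   via: M1 does not satisfy G¬p; verdict negated
#>   core-check paths satisfied: 0/15 (bound 15)
```

A command-line front end is installed with the package
(`exec/stickermc`): `stickermc check --model M1 --formula EFp`,
`stickermc encode --formula phi1 --out stickers.fasta`,
`stickermc tile`, `stickermc kinetics`, `stickermc fixtures`,
`stickermc validate`.

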