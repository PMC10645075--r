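# fcdnet

Energy-based flowing-network toy models of open ecological systems, and
the machinery to evolve them under systemic or "greedy" goal functions
and compare the outcomes.

Natural systems can be abstracted as open networks of energy
transformation: energy enters from the environment, is passed among
internal energy forms, and eventually dissipates back out.  `fcdnet`
implements this abstraction as *flowing connected directed networks*
(FCDNs) and asks a question relevant to sustainability research: when a
consumer strategy inside the system (think of modern human
appropriation of biospheric energy flows) starts steering evolution
toward its own local demands instead of system-wide orientors, can it
match or surpass what systemic evolution would have achieved — in
performance, and in the ability to ride out energy scarcity?

The package is aimed at researchers in ecological network analysis,
ecosystem energetics and socio-metabolic modelling who want a small,
fully reproducible simulation laboratory for these questions.

## The model

An FCDN on `N` core nodes is a weighted digraph with adjacency matrix
`A` in which `A[i, j]` is the *share* of node `i`'s outflow sent to
node `j`.  One input node feeds the core, one output node collects
dissipation; rows of the input and core nodes sum to one, self-loops
are forbidden, every core node is reachable from the input and reaches
the output.  Under a constant input `u` the throughflow vector obeys
the synchronous map

    x(t+1) = x(t) %*% A_core + u

whose fixed point `x* = u (I − A_core)^{-1}` exists because
dissipation keeps the spectral radius of the core block below one.
Realized fluxes are `T[i, j] = x*[i] A[i, j]`.

From `T` the package computes the classical systemic indexes of
ecological network analysis:

- **TST** — total system throughflow, `Σ_{i,j core} T[i,j]` (system "power");
- **AMI** — average mutual information of the flow distribution (bits);
- **ASC** — ascendency, `AMI × TST` (joint growth-and-development);
- **EDiff** — entropy of output flows minus entropy of input-adjacent
  throughflows (exported entropy proxy);
- **Finn** — fraction of flow that cycles, from the diagonal of the
  Leontief inverse `L = (I − A_core)^{-1}`, total and per node;
- **b** — energy-flux decay rate `E_max(A_core) − 1 ∈ [−1, 0)`: the
  asymptotic per-iteration energy loss once the input is cut.  `b`
  close to 0 means the network holds energy long under scarcity
  ("scarcity tolerance").

Evolution is hill-climbing: one mutation per iteration, accepted iff
the chosen goal function strictly increases.  Large time-scale
mutations restructure the core (add/delete/reweight arcs); short
time-scale mutations only nudge existing weights by ±10%.  Goal
functions are either systemic (TST, AMI, ASC, EDiff) or greedy
(absolute/proportional flow or per-node cycling summed over a
designated greedy node set).  The experiment driver evolves ensembles
under a systemic goal, then branches each network into a paired
control (same goal) and greedy short-scale evolution, and reports the
share of replicates in which the greedy branch surpasses its control
in scarcity tolerance and/or goal performance, via the normalized
differences `b_diff = (b_control − b_greedy) / (|b_control| +
|b_greedy|)` (negative = greedy wins) and `goal_diff` (same form).

It also counts directed simple cycles (Johnson-style blocked search in
C++): the complete 10-node digraph already holds 1,112,073 of them.

## Worked example

```r
library(fcdnet)

net <- random_fcdn(n_core = 30, connectance = 0.20, seed = 42)
index_bundle(net)
#> systemic indexes
#>   TST   16.2167 energy/iter
#>   AMI   2.47701 bits
#>   ASC   40.1689 bits*energy/iter
#>   EDiff 0.113954 bits (S_out 2.68117 - S_in 2.56721)
#>   Finn  0.362496 (cycled fraction)
#>   b     -0.0584878 (scarcity tolerance)
```

The random 30-node network already cycles 36% of its flow and loses
about 5.8% of its stored energy per iteration under scarcity.  Five
hundred large time-scale iterations of TST maximization reorganize it
drastically:

```r
ev <- evolve(net, "TST", mutation_policy("large"), n_iter = 500,
             seed = 42, record_b = FALSE)
ev
#> evolution trace: 500 iterations (large scale), goal TST
#>   goal: 16.2167 -> 1724.68; acceptance rate 0.460
decay_rate(ev$net)
#> [1] -0.0005744822
```

TST grew a hundredfold and the decay rate moved within 6e-4 of zero:
maximizing power builds heavily recycling, scarcity-tolerant networks.
A small paired comparison (10 replicates; the full study uses 100):

```r
cfg <- experiment_config(sizes = 30, replicates = 10, goals = "TST",
                         greedy_scenarios = "ABS_FLOW",
                         greedy_fractions = 0.5, master_seed = 7)
res <- run_experiment(cfg)
res$summary[, c("n", "pct_b_surpass", "pct_goal_surpass", "pct_both_surpass")]
#>    n pct_b_surpass pct_goal_surpass pct_both_surpass
#> 1 10            50               50               50
diff_scatter_stats(res$records)[c("n", "slope", "r")]
#> $n
#> [1] 5
#> $slope
#> [1] 1.000738
#> $r
#> [1] 0.9999997
```

Here 5 of 10 greedy branches surpassed their control in scarcity
tolerance — and exactly those same replicates surpassed it in
performance, with the two normalized gains on a slope-one line: greedy
strategies that beat systemic evolution do so by boosting tolerance
and power together.

A thin command-line front end wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "fcdnet.R", package = "fcdnet"))')" \
    generate --n 30 --connectance 0.2 --seed 1 --out net.tsv
```

with subcommands `generate`, `indexes`, `evolve`, `experiment` (YAML
config) and `report`.

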