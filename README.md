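# netstab

Stabilizing structured recurrent networks through node self-coupling.

## What it is for

The connectivity–stability dilemma says that a large dynamical system whose
components interact densely and randomly is almost surely unstable: the
probability that all eigenvalues of a random $N \times N$ Jacobian $W$ lie
in the left half-plane collapses as size and connectance grow. Yet real
networks — neural circuits, ecosystems, power grids — are both connected and
stable, and they are rarely *random*: their topologies are small-world,
scale-free, or hierarchical. One generic stabilizing mechanism is
self-regulation: sufficiently negative diagonal entries (node
self-couplings) restore asymptotic stability.

`netstab` is a Monte-Carlo pipeline for measuring how much self-coupling
structured networks need, and how that requirement scales with network size:

1. **Generate** random interaction matrices with small-world (exact-count
   Watts–Strogatz rewiring), scale-free (preferential attachment with the
   smoothed kernel $\Pi(k_i) \propto k_i + 1$), Kronecker self-similar, or
   Erdős–Rényi topology; assign each edge two independent directed weights
   from $U[-1, +1]$; draw the diagonal self-couplings from a negative
   interval.
2. **Test stability** by the spectral abscissa: the system is asymptotically
   stable iff $\max_i \mathrm{Re}\,\lambda_i(W) < 0$.
3. **Estimate** the probability of stability over $T$ trials,
   $P = \frac{1}{T}\sum_i s_i$, with errors $\sqrt{P(1-P)/T} \le 1/\sqrt{T}$.
4. **Fit** the stability transition with the Hill function
   $P(\text{stable} \mid x) = |x|^n / (c + |x|^n)$ and extract the
   stabilization parameter $\mu = c^{1/n}$, the mean self-coupling strength
   at which half of the sampled networks are stable.
5. **Scale**: repeat over network sizes and fit
   $\mu(N) = A\,(N-1)^p$ — the headline result being that $p \ll 1$: the
   self-coupling needed grows far more slowly than the network.

It is aimed at researchers in systems biology, theoretical neuroscience, and
network science who want reproducible stability phase diagrams for
structured random ensembles, or who want to test their own matrices (dense
CSV / MatrixMarket input is supported).

## A worked example

```r
library(netstab)
cfg <- net_config("smallworld", n_nodes = 100)   # k_nn = 4, p_rew = 0.05

# one network, one trial
M <- generate_network(cfg, rng_seed = 1)
M <- add_self_coupling(M, varied_interval(-1.1), rng_seed = 2)
M
#> <interaction_matrix: 100 x 100, topology 'smallworld', 400 nonzero off-diagonal entries>
spectral_abscissa(M)
#> [1] -0.2213101        # negative: this sample is asymptotically stable

# the full stability transition at N = 100 (varied-position intervals [x-0.9, x])
curve <- sweep_auto(cfg, "varied_position", n_trials = 200, rng_seed = 42)
as.data.frame(curve)
#>   abscissa probability n_trials n_stable error_propagated error_bound
#> 1    -1.09       0.010      200        2          0.00704      0.0707
#> 2    -1.21       0.055      200       11          0.01612      0.0707
#> 3    -1.34       0.185      200       37          0.02746      0.0707
#> 4    -1.46       0.425      200       85          0.03496      0.0707
#> 5    -1.58       0.710      200      142          0.03209      0.0707
#> 6    -1.70       0.890      200      178          0.02212      0.0707
#> 7    -1.82       0.950      200      190          0.01541      0.0707
fit_hill(curve)
#> <hill_fit (varied_position): c = 320.3 +/- 35, n = 14.6 +/- 0.27, mu = 1.4846 +/- 0.0021>
```

Reading the output: at a mean self-coupling of $-1.09$ almost no sampled
network is stable, at $-1.82$ nearly all are, and the fitted Hill curve puts
the half-stability point at a mean self-coupling strength of
$\mu \approx 1.48$ — each of the 100 nodes needs self-inhibition of roughly
that magnitude (against coupling weights of order 1) for stability to
become the typical outcome. Growing the network from 100 to 500 nodes moves
$\mu$ only from about 1.48 to about 1.70: the sublinear power law
($p \approx 0.08$ for small-world networks) returned by

```r
sc <- scaling_curve(cfg, c(100, 200, 300, 400, 500), "varied_position",
                    n_trials = 100, rng_seed = 101)
fit_power_law(sc)
#> <power_law_fit: mu(N) = A (N-1)^p, A = 0.9836 +/- 0.0415, p = 0.0888 +/- 0.0075>
```

A thin command-line wrapper over the same functions lives at
`inst/cli/netstab.R` (verbs: `generate`, `metrics`, `stability`, `sweep`,
`scaling`, `replicate-table2`).

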