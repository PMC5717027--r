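# memoryfoam

Unsupervised, online category learning as a *plastic energy landscape*.

`memoryfoam` implements a gradient dynamical system

```
dx/dt = -∇V(x, t)
```

whose scalar energy landscape `V` is itself dynamic: every incoming stimulus
sample `η(t)` presses a bell-shaped dent into the landscape (like a weight on
memory foam), and an elasticity term `k` lets the foam slowly flatten back —
forgetting. In the raw form the field `U` obeys

```
∂U/∂t = -g(x - η(t)) - k U,
```

with the dent kernel (note the non-standard exponent; its integral is 1/√2)

```
g(z) = (2π σ_z²)^(-1/2) exp(-z²/σ_z²),
```

and the de-trended landscape `V = U/t` obeys

```
∂V/∂t = -(V + g(x - η(t)))/t - k V.
```

For `k = 0` and a stationary stimulus with density `p`, `V` converges to the
negative kernel-smoothed density `-(g ∗ p)`: each well of the landscape is a
learned **category**, its minimum the category prototype, and a new stimulus
is **recognised** by resetting the state to the stimulus value and letting
gradient descent carry it to the bottom of whichever basin it falls in.
Memories form at predictable locations, there are no spurious attractors,
and learning is online and unsupervised throughout.

The package is aimed at computational-neuroscience and dynamical-systems
practitioners who want a concrete, testable implementation of this
memory-as-landscape mechanism: it provides exact and grid-based integrators
for the landscape equations, random-restart discovery of all memorised
minima, synthetic stimulus generators with closed-form ground truth, and a
monophonic audio front end (short-time Fourier pitch tracking, resampling,
delay embedding into multi-note phrase vectors).

## Worked example

A stream of 20,000 i.i.d. samples from a two-peak density is absorbed into a
1-D landscape; the two categories are then discovered by random-restart
descent:

```r
library(memoryfoam)

stim <- gen_iid_bimodal(20000, seed = 1)        # two-mode stimulus stream
L    <- learn_landscape(stim, foam_kernel(sqrt(0.1)))
find_minima(L, n_starts = 100, seed = 2)
#> <minima_set> 2 minima (deepest first), merge_radius = 0.158114, 2 non-converged restart(s)
#>          x1      depth basin_count
#> 1 -1.545844 -0.4606511          55
#> 2  1.489528 -0.2332257          43
```

The two minima sit at the modes of the kernel-smoothed stimulus density
(the heavier left mode is deeper and captures more restarts), i.e. the
stream's two categories were discovered without supervision. Recognition of
a new value is one call:

```r
mins <- find_minima(L, n_starts = 100, seed = 2)
recognize(L, -1.2, mins)    # -> 1: the deeper (left) category
```

The same mechanism applied to a jittered three-note melody stream
(`gen_melody()`) carves one minimum per musical note, and applied to 4-D
delay-embedded phrase vectors (`delay_embed()`) it memorises the song's
four-beat phrases, deepest-first by how often each phrase occurs. See the
methods vignette (`vignettes/memory-foam-landscapes.Rmd`) for the full
account, and the `memoryfoam` CLI script (`exec/memoryfoam`) for the
shell-level pipeline (`simulate`, `learn`, `minima`, `recognize`,
`audio-pitch`, `phrases`, `fixture`).

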