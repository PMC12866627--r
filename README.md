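# gapmotif

Bayesian discovery of **gapped (noncontiguous) sequence motifs** from
collections of biological sequences whose motif labels are only **partially
observed**.

Classical motif models assume a conserved pattern occupies a contiguous
window of fixed length. Structural evidence — most prominently for peptides
bound to MHC Class I molecules — shows that the residues that actually
matter can be *scattered*, separated by gaps of variable length, especially
in longer peptides. `gapmotif` implements a generative model and MCMC
sampler for exactly this setting, together with a seeded synthetic-data
generator, recovery metrics, gap-profile analyses with a permutation test
for central bulging, and a small command-line interface. It is aimed at
computational immunologists and anyone doing sequence-motif methodology who
needs a motif model with explicit spacing structure and principled handling
of unlabeled sequences.

## The model

Each of $n$ sequences $r_i$ (length $L_i$, alphabet size $p$) carries a
label $w_i \in \{1,\dots,K+1\}$: motif $k \le K$ or pure background
($K+1$). Labels may be masked (`NA`) and are then imputed. A motif $k$ of
length $J_k$ is a column-stochastic matrix $\Theta_k$ ($p \times J_k$); a
sequence carrying it has strictly increasing binding positions
$a_{i1k} < \cdots < a_{iJ_kk}$ with $a_{ijk} \le L_i - J_k + j$. Letters at
binding positions are emitted by the corresponding motif column, all others
by a shared background $\theta_0$:

$$
p(r_i \mid w_i = k, a_{i\cdot k}) \;=\;
\theta_0^{h(r_i,\,\{a_{i\cdot k}\}^c)} \prod_{j=1}^{J_k}
\Theta_{\cdot jk}^{h(r_i,\,a_{ijk})},
$$

where $h(\cdot)$ is the letter-count vector. Gaps between consecutive
positions follow a truncated Poisson prior with slot-specific rate
$\lambda_{kj}$, renormalized over the feasible range; the first position is
uniform. Priors: Dirichlet(1) on $\theta_0$ and motif columns, Gamma(1, 1)
on the rates, uniform labels.

Inference is Gibbs sampling with conjugate parameter updates, an $O(nL)$
sequential sweep over binding positions, exact dynamic-programming
marginalization over positions for masked-label updates, and a
Metropolis–Hastings **block shift move** that jointly re-proposes binding
positions, motif columns and gap rates so the chain can escape modes where
the whole alignment sits at a one-column offset. Point estimates are
marginal posterior modes (discrete) and posterior means (continuous).

## Worked example

```r
library(gapmotif)

cfg <- simulation_config(n = 80, L = 10, motif_lengths = 4, eta = 0.1,
                         rates = c(0.5, 1, 1.5), seed = 7)
sim <- simulate_dataset(cfg)      # 80 protein sequences, 20% labels masked
sim$data
#> <sequence_dataset> n = 80 sequences over protein alphabet (p = 20), lengths 10..10

trace <- run_mcmc(sim$data, sim$labels, cfg$motif_lengths,
                  config = mcmc_config(n_iter = 400, burn_in = 200, seed = 8))
trace
#> <mcmc_trace> 400 iterations (200 burn-in), K = 1, n = 80; final loglik -1888.02; shift acceptance 0.10

map <- map_estimates(trace)
metric_report(map, sim$truth, sim$labels$known)
#> <metric_report> KL: 1.110 | L1(theta0) 0.0086 | L1(theta): 0.0245 | acc W (masked) 1.000 | acc A 0.845
```

Reading the report: the sampler recovered the labels of all 16 masked
sequences (`acc W`), placed 84.5% of the binding positions exactly
(`acc A`), and the recovered motif matrix sits 1.11 nats (column-summed KL,
true vs estimate) from the sharply peaked truth — most of which is the
irreducible Dirichlet-smoothing floor at 64 motif-bearing sequences, not
misalignment. Per-sequence L1 errors on the background and motif
probabilities are below 0.025.

Spacing structure of the fitted alignment:

```r
gap_profile(map$positions[[1]], sim$data$lengths)$by_length
#>    flank_start gap1 gap2 gap3 flank_end
#> 10        2.86 1.52  1.3  1.3      2.02
```

and `central_bulge_permutation_test()` tests whether designated central
gaps are systematically inflated.

A command-line wrapper covers the same pipeline
(`gapmotif simulate | fit | predict | evaluate | gap-profile | perm-test`);
see `exec/gapmotif` and `?gapmotif_cli`.

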