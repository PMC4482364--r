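# phylobeta

Bayesian phylogenetic beta regression for proportion-valued traits, built
for comparative analyses of extinction risk — in particular, modelling the
proportional geographic-range decline of species (such as Australia's
native rodents) as a function of ecological and life-history traits while
accounting for shared evolutionary history.

## The model

Each analysis taxon *i* (a species, or a species-by-region population for
species present in both regions) has a response $y_i \in (0,1)$, modelled
with the mean–dispersion parameterisation of the beta distribution:

$$y_i \sim \mathrm{Beta}(\alpha_i, \beta_i), \qquad
  \alpha_i = \mu_i\gamma, \quad \beta_i = (1-\mu_i)\gamma,$$

so that $\mu_i$ is the mean and $\gamma$ the concentration. The mean is
logit-linear in the predictors with phylogenetically correlated species
effects:

$$\mathrm{logit}(\mu_i) = \mathbf{x}_i^\top\boldsymbol\theta + u_i, \qquad
  \mathbf{u} \sim \mathrm{MVN}(\mathbf{0}, C_\lambda),$$

where $C$ is the phylogenetic variance–covariance matrix (entry $(i,j)$ is
the branch-length distance from the root to the most recent common
ancestor of $i$ and $j$) and $C_\lambda$ is its Pagel's-λ transform:
off-diagonal entries multiplied by λ, diagonal untouched. λ = 0 is a star
phylogeny (no signal); λ = 1 is pure Brownian-motion covariance.

Priors: $\theta_j \sim N(0, 1000^2)$, $\lambda \sim U(0, 1.2)$,
$\gamma \sim \mathrm{Gamma}(0.001, \text{rate}=0.001)$. Two design forms
are supported: main effects (intercept, region NS, log range, log female
mass, log rainfall, habitat-openness rank, log litter size; 7 columns) and
the same plus all five region-by-trait interactions (12 columns).
Posteriors are sampled by an adaptive Metropolis-within-Gibbs sampler
(compiled core) with split-chain Gelman–Rubin, effective-sample-size,
autocorrelation and Monte Carlo standard-error diagnostics, and effects
are reported as posterior means with 95% highest-posterior-density (HPD)
intervals; an effect is flagged *notable* when its 95% HPD interval
excludes zero.

A synthetic-data generator (Yule trees, trait tables with straddling
species duplicated across regions, beta responses drawn from the exact
model) makes every stage testable without external data.

## Worked example

```r
library(phylobeta)

cfg  <- synthetic_config(seed = 42)        # ~60 species, study-like truth
dat  <- simulate_dataset(cfg)              # tree + traits + beta responses
prep <- prepare_predictors(dat$table, squeeze = "none")
spec <- model_spec()                       # main-effects form
X    <- build_design(prep, spec)
fit  <- fit_model(prep$y, X, dat$cov, spec, seed = 7)
summarize_posterior(fit)
```

```
        parameter    mean   mcse           95% HPDI      ess     rhat
        Intercept -2.7658 0.0280 (-4.3014, -1.2379) 768.5961 1.005067 *
               NS  0.6953 0.0190  (-0.0948, 1.5089) 484.7182 1.005846
        log Range -0.4049 0.0087  (-0.8413, 0.0279) 674.1813 1.004630
  log Female mass -0.0346 0.0086  (-0.4663, 0.4429) 717.1079 1.006177
     log Rainfall -0.3537 0.0082  (-0.7903, 0.0887) 742.3660 1.005844
 Habitat openness -0.5761 0.0110 (-0.9218, -0.2180) 276.8248 1.012761 *
       log Litter  0.0911 0.0093  (-0.3649, 0.5413) 639.8440 1.004159
            gamma  0.3768 0.0076   (0.1494, 0.6500) 342.1487 1.015685 *
           lambda  0.7482 0.0170   (0.3741, 0.9966) 135.0795 1.012333 *
```

The generating values here were intercept −1.66, NS 1.22, log Range
−0.45, habitat openness −0.61, γ = 0.5, λ = 0.8: every true coefficient
lies inside its 95% HPD interval, the habitat effect is correctly flagged
notable (more open habitat → greater decline, since openness is ranked 0 =
grassland to 4 = rainforest), and the phylogenetic-signal posterior sits
near its true value. `gamma` and `lambda` rows are always starred as
reported model parameters; a sign test is meaningless for
positive-support parameters.

For real data, `read_trait_table()` ingests a CSV/XLSX of taxon rows
(decline in [0,1], the Table-style predictors, region or centroid
latitude), `read_newick()` the phylogeny, and `fit_pipeline(run_config(...))`
runs both model forms end to end, writing chain CSVs, posterior summaries,
decline tabulations by region and genus, regional mass descriptives and a
manifest. Exact-zero declines are compressed into (0,1) with the
Smithson–Verkuilen rule `(y(n-1)+0.5)/n` (configurable).

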