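# osteopem

Quantitative inference of resting metabolic rate (RMR) and periosteal bone
growth rate in extinct vertebrates from bone-histological vascular density,
using phylogenetic eigenvector maps (PEM).

The package is aimed at vertebrate palaeontologists and comparative
physiologists who have (i) a time-calibrated phylogeny connecting extinct
taxa of interest to extant species with measured physiology, and (ii)
thin-section measurements of **primary osteon density** — the fraction of
cortical bone area occupied by primary osteons, each measured *including*
the lamellar infill of its vascular canal, so that actively growing extant
bone (open canals) and fossil bone (infilled osteons) are measured on the
same footing. Because it is an area fraction, this measure is insensitive
to vascular canal orientation, unlike canal-count densities.

## The model

A rooted time tree with `n` training tips and `m` edges is encoded by its
**influence matrix** `B` (`n x m`, `B[i,j] = 1` iff edge `j` lies on the
root-to-tip path of tip `i`). Each edge of length `b_j` (Ma) is weighted

```
w_j = psi * b_j^((1 - a)/2),      a in [0, 1],  psi > 0
```

where the steepness `a` controls how trait divergence scales with time
(`a = 0`: Brownian-motion-like square-root weighting, and
`(Bw)(Bw)'` is exactly the BM phylogenetic covariance; `a = 1`: no
branch-length dependence). Column-centering the weighted influence matrix
and taking its thin SVD gives orthonormal phylogenetic eigenvectors `U`
(the PEM basis). The trait model is ordinary least squares on the log10
scale,

```
log10(y_i) = beta0 + sum_k gamma_k U[i,k] + beta1 * log10(d_i) + e_i
```

with `d_i` the primary osteon density. Eigenvectors enter by forward
selection in order of decreasing singular value and the steepness is chosen
on a grid, both by minimum small-sample-corrected AIC
(`AICc = n ln(RSS/n) + 2k + 2k(k+1)/(n-k-1)`); the fit is validated by
leave-one-out cross-validation (PRESS). A fossil tip grafted onto the tree
is projected into the training basis via its own influence row
(`s = (row_w - colmeans) V diag(1/d)`), predicted, and reported with a 95%
prediction interval on both scales. Finally, maximum-likelihood ancestral
states under Brownian motion are reconstructed over the complete sample set
(measured + predicted values) for colour-coded tree maps.

## Worked example

A small fully synthetic dataset (generated by the package's own simulators,
see `inst/extdata/synthetic_example_*`) ships with the package: 10 extant
"training" species with measured response and 4 fossil targets on a 34-Ma
deep tree.

```r
library(osteopem)

res <- run_analysis(list(
  tree   = system.file("extdata", "synthetic_example_tree.nwk",  package = "osteopem"),
  traits = system.file("extdata", "synthetic_example_traits.csv", package = "osteopem"),
  out_dir = "example_out",
  response_label = "RMR", response_units = "mL O2/h/g^0.67"))

res$fit
#> PEM regression fit
#>   training species: 10
#>   steepness a:0 (forward eigenvector selection)
#>   selected eigenvectors: none
#>   AICc: -1.664314   residual variance: 0.3893456
#>   coefficients (log10 scale):
#> (Intercept) log_density
#>   1.4940089   0.7117124

res$predictions
#>   rank  species log_point log_lwr log_upr point    lwr upr
#> 1    1 fossil_A     0.555  -1.025    2.13  3.59 0.0943 136
#> 2    2 fossil_D     0.810  -0.700    2.32  6.46 0.1993 209
#> 3    3 fossil_C     1.073  -0.476    2.62 11.84 0.3340 419
#> 4    4 fossil_B     1.165  -0.424    2.75 14.61 0.3769 566
```

Reading the output: the AICc search settled on steepness `a = 0`
(BM-like weighting) and kept no eigenvectors — with 10 training species the
AICc penalty is severe, so the phylogenetic structure is carried by the
residual variance rather than explicit eigenvector terms. The slope 0.71 on
log10 density means a ten-fold increase in primary osteon density predicts
a ~5-fold (`10^0.71`) increase in the response. Each fossil gets a point
estimate and a 95% prediction interval in natural units (`point`, `lwr`,
`upr`); `example_out/` additionally holds the LOOCV table, the ancestral
node/edge tables for tree colour maps, and a `run.log` recording every
decision.

Histology side, densities come from labelled section masks
(0 = background, 1 = compact bone, 2 = primary osteon incl. infill):

```r
sim <- simulate_section_mask(0.25, seed = 4)
osteon_density(sim$mask)     # 0.2503144 == sim$achieved, >= the 0.25 target
```

A thin command-line wrapper with subcommands `run`, `simulate`
(tree/traits/mask) and `measure-density` is installed at
`system.file("cli", "osteopem.R", package = "osteopem")`.

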