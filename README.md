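# sindyic

Data-driven discovery of governing equations with principled model
selection. `sindyic` combines **sparse identification of nonlinear
dynamics** (SINDy) — sparse regression of measured derivatives onto a
library of candidate terms — with **corrected Akaike information criterion
(AICc) ranking** of the resulting candidate models, so that selection among
a combinatorially large model space reduces to simulating and
cross-validating a few dozen candidates near the accuracy–parsimony Pareto
front.

It is written for researchers in systems biology, epidemiology and applied
dynamics who have multi-trajectory time-series data (or want to study the
method on synthetic benchmarks) and need more than a Pareto elbow to decide
*which* sparse model the data actually support.

## The method in brief

For states $\mathbf{x} \in \mathbb{R}^n$ governed by
$\dot{\mathbf{x}} = f(\mathbf{x})$, evaluate a library
$\Theta(X) \in \mathbb{R}^{m\times p}$ of candidate terms (monomials, or
$u^a\,\partial_x^b u$ products for PDE data) on the measurements and solve

$$\dot X = \Theta(X)\,\Xi$$

for sparse $\Xi$ by **sequential thresholded least squares** (STLSQ; the
ridge-regularized **STRidge** variant for PDE data; exhaustive subset
enumeration for small libraries). Sweeping the sparsity threshold yields a
small candidate set out of the $2^p - 1$ models the library spans. Each
candidate is then simulated from every validation initial condition;
counting one complete validation trajectory as one observation, with
per-trajectory average absolute error $E_{\mathrm{avg}}$,

$$\mathrm{AIC} = m \ln\!\Big(\tfrac{1}{m}\textstyle\sum_{i=1}^m E_{\mathrm{avg}}(i)\Big) + 2k,
\qquad
\mathrm{AICc} = \mathrm{AIC} + \tfrac{2(k+1)(k+2)}{m-k-2},$$

and relative scores $\Delta_j = \mathrm{AICc}_j - \mathrm{AICc}_{\min}$
classify each candidate: $\Delta \le 2$ strong support, $4 \le \Delta \le 7$
weak, $\Delta \ge 10$ none (with the gaps reported as borderline, and
divergent candidates as unstable).

Five ground-truth generators ship with the package: a 1-D polynomial
system, a 2-D cubic oscillator, a discrete SEIR epidemic map, the Lorenz
equations and Burgers' equation.

## Worked example

Enumerate all 63 models of the degree-5 polynomial library, fit each by
least squares on three noisy training series of
$\dot x = x - 0.2x^3 - 0.1x^4$ (noise sd $10^{-3}$, exact derivatives), and
rank them against 100 validation trajectories:

```r
library(sindyic)

feature_library(1, 5)
#> Feature library (poly): 6 terms over 1 state variable(s)
#>   1, x, x^2, x^3, x^4, x^5

report <- run_selection(
  selection_config("poly1d", mode = "exhaustive", n_valid = 100, seed = 42))
report
#> Selection report: 63 candidates, 100 validation trajectories
#>   support counts: strong 1 | borderline 3 | weak 5 | none 53 | unstable 1
#>   selected model (delta = 0, k = 3):
#>     x' = 1*x - 0.2001*x^3 - 0.09999*x^4
#>   true support recovered: TRUE
#>  k             terms      aicc    delta   category
#>  3         x+x^3+x^4 -705.9030 0.000000     strong
#>  4     x+x^2+x^3+x^4 -703.7118 2.191225 borderline
#>  4       1+x+x^3+x^4 -703.7076 2.195437 borderline
#>  4     x+x^3+x^4+x^5 -703.6975 2.205502 borderline
#>  5   1+x+x^2+x^3+x^4 -701.4445 4.458541       weak
#>  ...
```

The only strongly supported model is the true 3-term system, with
coefficients recovered to three decimals; 4-term supersets pay the
information-criterion penalty for their extra parameter ($\Delta \approx
2.2$), and everything else — including a model that blows up in finite time
and is flagged unstable — is rejected. The same pipeline runs the other
examples (`"seir"`, `"lorenz"`, `"burgers"`, `"cubic2d"`), a sweep mode
(`mode = "stlsq"`, the default) for libraries too large to enumerate, and
file-based data via `load_trajectories()`. `sensitivity_experiment()`
tabulates how selection degrades with noise level, validation-set size or
validation horizon. A thin command-line wrapper over the same functions is
provided in `inst/cli/sindyic.R`.

See the vignette (`vignettes/model-selection.Rmd`) for the model and its
assumptions, every tunable parameter, and known limitations.

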