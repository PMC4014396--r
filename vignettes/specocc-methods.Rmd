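---
title: "Specular highlights and perceived convexity: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Specular highlights and perceived convexity: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specocc)
```

## The scientific problem

A smoothly shaded object seen monocularly under orthographic projection is
ambiguous: the same image is consistent with a convex surface lit from one
direction and a concave surface lit from the opposite direction (the
bas-relief ambiguity). Human observers resolve the ambiguity with priors —
light tends to come from above, objects tend to be convex — and, the topic of
this package, with specular highlights: the presence of a highlight biases
reports toward "convex". This package implements the geometric explanation of
that bias and a Bayesian ideal-observer model of the two-object, 2AFC
convex/concave judgement task, together with everything needed to exercise
the pipeline end to end on simulated observers.

## Occlusion geometry

The stimulus cross-section (in the plane of the view and illuminant vectors)
is a semi-ellipse of unit half-width and depth expansion factor $d$:
$x^2 + z^2/d^2 = 1$. A specular highlight sits where the surface normal
bisects the view and illuminant directions; on the concave section the
bisector condition reduces to

$$\frac{x_s}{\sqrt{1-x_s^2}} = \frac{\tan(\theta_l/2)}{d},$$

with $\theta_l$ the illuminant slant. Because the observer knows neither $d$
nor $\theta_l$ exactly, a highlight observed at $x_s$ is consistent with a
one-parameter family of concave interpretations: for an assumed depth
$\hat d$ the required slant is $\theta_l(\hat d) = 2\arctan(\hat d\, x_s /
\sqrt{1 - x_s^2})$, strictly increasing in $\hat d$. But a concave
interpretation is only physically realizable while the illuminant clears the
rim: the rim angle seen from the candidate highlight position,
$\theta_r(\hat d) = \arctan\!\big((1 + x_s)/(\hat d\sqrt{1-x_s^2})\big)$, is
strictly decreasing in $\hat d$, so the two curves cross once.
`feasibility_curve()` brackets the crossing on a 512-point grid and bisects
to $10^{-6}$ (bisection rather than a derivative method because the curves
are smooth, monotone, and cheap — robustness is worth more than iteration
count here). For the rendered configuration $(d = 0.5,\ \theta_l =
68^\circ)$ the crossing sits near $\hat d \approx 0.61$ and $\theta \approx
79^\circ$: an observer who overestimates depth by roughly 20% (and hence
slant by roughly 16%) finds the concave reading impossible — which is why a
visible highlight is evidence for convexity.

`occlusion_probability()` turns this hard boundary into a graded probability
by sampling $\hat d$ from a log-normal centred on the true depth (the spread
is the package's single depth-uncertainty knob) and following the bas-relief
family, optionally with extra slant jitter; the returned value is the
fraction of samples falling in the infeasible region. The log-normal
respects the one-dimensional structure of the ambiguity: depth and slant are
not independently uncertain, they slide together along the solution family.

The dome stimuli of the third experiment are spherical caps of unit
half-width and depth ratio $h$, cut from a sphere of radius
$R = (1 + h^2)/(2h)$; sphere normals are radial, so the highlight's
image-plane eccentricity is $R\sin(\sigma/2)$ at slant $\sigma$ —
increasing in slant but *decreasing* in depth, which is what makes the dome
experiment diagnostic: the behavioural bias grows with depth even though the
highlight moves toward the centre. The thin smoothing fillet joining dome
and background in the rendered stimuli is ignored here; its extra sliver of
specularity is not part of the geometry that matters for the occlusion
argument.

## The generative observer model

One trial shows two objects with opposed gradient tilts
($\theta_2 = \theta_1 + \pi$), with highlights present or absent
($\delta_i$) at tilts $\gamma_i$. The hidden scene variables are the number
of primary illuminants $\alpha \in \{1, 2\}$ (one global light field, or two
"windowed" illuminants each acting on one object), per-object curvature sign
$\tau_i$, specular index $\chi_i$, local-illuminant flag $\beta_i$ (a
spotlight-like secondary source that can put a highlight on a matte
surface), and — for concave objects with an active cause — occlusion
indicators. The nine free parameters are the light-prior mean and
concentration ($\mu$, $\kappa_\phi$), the four prior probabilities
$p(\tau{=}\mathrm{convex})$, $p(\alpha{=}1)$, $p(\chi{=}\mathrm{shiny})$,
$p(\beta{=}\mathrm{present})$, the two occlusion probabilities $p_{os}$ and
$p_{om}$, and the observation-noise concentration $\kappa_n$ shared between
gradient noise and highlight misalignment.

A hypothesis is admitted for a trial exactly when its predicted number of
*visible* highlights per object matches the observed $\delta_i$: a visible
highlight needs an unoccluded cause, occlusion is possible only on concave
objects, and a convex shiny object with a local illuminant is excluded for
$\delta = 1$ because it would show two highlights. For a concave object with
both causes active and one highlight observed, exactly one of the two causes
must be occluded, and both single-occlusion configurations are
enumerated. Occlusion indicators are
independent across objects and causes — nothing in the task couples them.

Conditional on a hypothesis, all angular observations are von Mises kernels
in the object's illuminant tilt $\phi$: the gradient kernel is centred on
$\phi$ for convex and $\phi + \pi$ for concave objects (concentration
$\kappa_n$); a specularly caused highlight contributes a second kernel at
the gradient-consistent position with the same $\kappa_n$, referenced to
$\phi$ inside the integral; a local-illuminant highlight is uniform,
$1/2\pi$. The tilt itself is marginalized in closed form: a product of von
Mises kernels collapses to a single cosine whose amplitude is the resultant
length $R$ of the summed $(\kappa, \text{phase})$ terms, so each marginal is
a ratio of Bessel functions, $I_0(R)$ over the kernel normalizers
(`phi_marginal()`). Under $\alpha = 1$ both objects (and any specular
kernels) share one $\phi$ integrated against the light prior; under
$\alpha = 2$ the marginal factorizes per object, each with the same
$(\mu, \kappa_\phi)$ prior — the experiment gives no reason to endow the two
windowed illuminants with different priors. Everything is computed with
log-$I_0$ (via the exponentially scaled Bessel), since fitted
concentrations reach 20 and the near-delta fixed value used by the reduced
variants is 100.

One structural property of this model deserves emphasis. Because the
posterior conditions on each trial's observed highlight pattern, the five
prior probabilities $p_\tau$, $p_\chi$, $p_\beta$, $p_{os}$, $p_{om}$ enter
the response probabilities only through four functions: the
convex/concave prior-mass ratio for a highlight-free object,

$$r_0 \;=\; \frac{1-p_\tau}{p_\tau}\cdot
\frac{(1-p_\chi+p_\chi p_{os})(1-p_\beta+p_\beta p_{om})}
     {(1-p_\chi)(1-p_\beta)},$$

and the three ratios among the four cause classes of a highlighted object
(convex-specular, convex-local, concave-specular, concave-local). The model
is therefore *exactly non-identified* along a one-dimensional ridge: for
instance, lowering $p(\chi{=}\mathrm{shiny})$ while raising $p_{os}$ (with
compensating moves of $p_\tau$, $p_\beta$, $p_{om}$) can leave every
predicted response probability unchanged to machine precision — the test
suite constructs such a ridge partner explicitly. The consequence for
fitting is that $\mu$, $\kappa_\phi$, $p(\alpha{=}1)$ and $\kappa_n$ are
recovered sharply from simulated data, while the five cause/occlusion
priors are recovered only up to the ridge: the maximized likelihood pins
the four ratios, and where along the ridge an individual fit rests is
decided by the optimizer's starting points. Any single reported value of
$p_{os}$ from such a fit should be read with that caveat.

Same-sign curvature assignments under a single illuminant are not
structurally excluded — they are merely crushed by the gradient-noise
likelihood, since the two opposed gradients cannot both match one light.
This keeps the hypothesis space a plain product space (the highlight count
is the only filter) and reproduces the forced-opposite behaviour in the
near-delta noise limit.

The decision rule is probability matching: the probability of a "convex"
report equals the posterior probability that the target is convex,
optionally mixed with a lapse (default 0). The fitted group-average curves
this model is meant to produce are smooth and graded; a MAP rule would
produce step functions. A consequence of the coherent generative semantics
worth knowing: the *absence* of a highlight is itself informative (a concave
object can hide its highlight, a convex one cannot), so opposite-gradient
posteriors sum exactly to one only when the highlight-bearing hypotheses are
switched off ($p_\chi = p_\beta = 0$); with them active the sum deviates by
a percent or two, matching the "almost exactly one" character of the
behavioural regularity.

## Fitting and model comparison

`fit_ml()` maximizes the Bernoulli likelihood of a response sequence by
Nelder–Mead on transformed parameters (logit for probabilities, log for
concentrations, identity for the wrapped $\mu$), with seeded uniform
multi-starts (probabilities in $[0.05, 0.95]$, $\kappa$ in $[0.5, 25]$,
$\mu$ within $\pm 45^\circ$; default 20 starts — the nine-dimensional
surface has genuine secondary modes in which, e.g., a near-zero
$p(\chi{=}\mathrm{shiny})$ trades against a large $p_{os}$). Trials are
collapsed to unique stimulus cells with binomial counts before optimization;
this is an exact reformulation of the Bernoulli likelihood and is what makes
a fit on tens of thousands of simulated trials take about a minute.
Predicted probabilities are clipped at $10^{-9}$ so the objective is finite
everywhere. Termination is the simplex's relative-tolerance criterion
($10^{-7}$) or 20000 evaluations, whichever first; the best start is then
re-polished by repeated simplex runs until a round gains less than
$10^{-3}$ in negative log-likelihood. Both thresholds sit far below any
statistically meaningful likelihood difference at these trial counts;
without the stall rule, fits drifting toward a boundary of the flat
cause/occlusion ridge (below) creep indefinitely for irrelevant gains.
Refitting with the same seed is bit-identical.

The nested ladder M1 (2 parameters: light prior only, single illuminant,
uniform curvature prior, highlights ignored) ⊂ M2 (4: adds the convexity
prior and the two-illuminant option; still highlight-blind) ⊂ M3 (6: adds
$p_\chi$ and $p_{os}$; every highlight is attributed to specular reflection
and its angular offset ignored) ⊂ full (9) is compared by
$\mathrm{BIC} = -2\log L + k\log n$ with $n$ the observer's total trial
count. M1 and M2 strip the highlight observables before evaluation — their
parameter set contains nothing that could generate a highlight, so scoring
$\delta = 1$ trials literally would zero the likelihood; blinding the model
to the cue is the only coherent reading of a highlight-free variant. In the
reduced variants $\kappa_n$ is pinned at 100 (near-delta) rather than
removed, so one likelihood code path serves all four; this also resolves the
tension that the two-illuminant interpretation formally needs gradient noise
while the four-parameter variant lists none.

## Synthetic observers

The three design generators reproduce the factorial structures exactly
(1536, 3840 and 2016 trials). Grid phases are anchored at 0 degrees —
the factor counts and spacings are fixed by the designs, the absolute phase
is not, and 0 is the conventional anchor. Trial order is a seeded uniform
shuffle. `simulate_observer()` draws each report from the model's
convex-report probability; for dome designs an optional `"geometry"` mode
replaces the scalar $p_{os}$ with the Monte-Carlo occlusion probability of
each (depth, slant) cell, using the semi-elliptical section of matching
depth ratio as the cross-section model — that approximation (segment vs
ellipse) only shifts the absolute feasibility boundary slightly and
preserves the monotone structure that matters. The default depth
uncertainty in that mode is 0.35 (log-normal sdlog, i.e. roughly ±35%
depth uncertainty), a value in the range psychophysical depth-scaling
studies would call realistic; $p_{om}$ stays scalar, since the occlusion
statistics of local illuminants have no comparable geometry.

What the simulants do *not* emulate: real observers' lapses, sequential
dependencies, learning, and any image-domain limits on extracting tilts
from pixels — the model consumes abstract tilts and flags. Passing tests
therefore certify the computational pipeline and the internal consistency
of the model, not the behaviour of human observers.

## Numerical choices and problem sizes

Study sizes used by the test suite and the acceptance script, chosen as the
smallest at which each property is comfortably resolved: oracle equivalence
(closed-form Bessel marginal vs 10^4-node trapezoid quadrature with
exhaustive enumeration) is checked to $10^{-6}$ absolute posterior
difference; MI convergence uses 10^4 trials per cell on a reduced design;
the parameter-recovery study simulates 10 observers at the reference mean
parameters over 10 sessions of the combined first two designs (53760 trials
per observer — at one session the ML surface's shiny/local trade-off ridge
is still wide enough to swallow the occlusion parameter) and refits with 3
restarts; the model-comparison check simulates 10 sessions and fits all
four variants with 2 restarts. The feasibility bisection tolerance is
$10^{-6}$ in $\hat d$; ties at the crossing cannot occur (strict
monotonicity both ways). Degenerate inputs fail loudly: a highlight with no
admissible cause, an empty contingency table, psychometric data without a
spanning transition.

## Known limitations

The likelihood factorization is a reconstruction from the model's stated
structure; where the original equations are not public, the package's
semantics are pinned by its own oracle tests (quadrature and brute-force
enumeration), not by comparison with the authors' code. Per-observer fits
to *human* data, and the published empirical percentages that depend on
them, are out of reach without the response tables; the package replaces
them with property-based checks and parameter recovery on simulants. The
plug-in MI estimator carries the usual small-sample positive bias (no
correction is applied; design cell counts make it a fraction of the effects
of interest). The psychometric baseline for dome stimuli folds tilt about
180 degrees before fitting, because the generative convex-report curve is
symmetric there; a real observer with a strongly tilted light prior would
break that symmetry, and the folded fit would blur it.
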