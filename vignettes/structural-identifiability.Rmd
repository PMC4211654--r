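---
title: "Structural identifiability and identifiable parameter combinations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural identifiability and identifiable parameter combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the package answers

A system-experiment model in this package is a rational-function ODE system

$$\dot{x} = f(x, u, p), \qquad y = g(x, p), \qquad x(0) = x_0(p),$$

with states $x \in \mathbb{R}^n$ (species amounts, compartment contents),
test inputs $u \in \mathbb{R}^r$, measured outputs $y \in \mathbb{R}^m$, and
unknown parameters $p \in \mathbb{R}^P$, assumed positive. Structural
identifiability asks: from *ideal, noise-free* input-output data of the
stated experiment, which parameters can be recovered at all? A parameter is
**uniquely (globally) structurally identifiable** if exactly one value is
consistent with the data, **locally (nonuniquely) identifiable** if a finite
number greater than one is, and **unidentifiable** if infinitely many are.
The question is about the model-experiment pair, not about data quality: an
unidentifiable parameter cannot be estimated from the experiment no matter
how good the data, and attempting to fit it produces arbitrary numbers.

When some parameters are unidentifiable, there always exist **identifiable
combinations** — functions of the parameters (sums of rate constants,
products across unobserved compartments, ratios) that *are* pinned down by
the data. Knowing the combinations explicitly matters in practice: they are
the quantities a fit can actually estimate, they let the model be
reparameterized into an input-output-equivalent form that can be simulated,
and they tell the experimenter which single parameter, measured
independently, would unlock the rest.

## The method

The pipeline implemented by `run_analysis()` has five stages.

**1. Reduction of constant trajectories.** If known initial conditions make
a subset of states a fixed point of their own equations (each $f_i$ vanishes
identically once the candidate states are frozen at their initial values),
those states remain constant for all time and are substituted out first.
This is the mechanism by which *particular* initial conditions — e.g.
starting an autocatalytic species at zero — can destroy identifiability that
holds for generic ones. The check is symbolic (the substituted right-hand
side must be the zero rational function), and the closure is computed by
fixed-point iteration: any candidate whose equation fails the test is
removed and the remaining set is re-tested. Reduction is idempotent. The
package does not attempt general accessibility analysis; reducible models
with non-constant but inaccessible trajectories are outside its scope.

**2. Input-output equations.** Each output is differentiated repeatedly
along the vector field, substituting $f$ for state derivatives; inputs are
treated as known time functions whose derivatives are free symbols (a
persistently exciting input), unless an input is declared constant, in which
case its derivatives are zero (a step of unknown magnitude). The resulting
relations are polynomial after clearing denominators, and the states are
eliminated. States that occur linearly with a state-free coefficient — every
state of a linear compartmental model, and most states of rational-function
biology models, because each unobserved species is typically reached through
a chain of linear transfer terms — are removed by solve-and-substitute
(pseudo-division by the pivot coefficient, whose powers are divided back out
of the result and which joins the set of quantities constrained nonzero).
Any states left over are eliminated with a Groebner basis under a block
order ranking states above everything else. The derivative order starts at
$n$ and is raised to at most $2n$; if some output still has no state-free
relation there, the analysis stops and reports that differential elimination
did not complete — the known failure mode of this model class.

**3. The exhaustive summary.** Each state-free equation is normalized by the
parameter coefficient of its highest-ranked derivative monomial (ranking:
output-derivative order descending, then total degree, then lexicographic).
The remaining coefficients $c_1(p), \dots, c_K(p)$ — rational functions of
the parameters, deduplicated, constants dropped — carry exactly the
information ideal data provide: two parameter vectors produce identical
input-output behaviour precisely when their coefficient vectors agree. For a
linear single-input single-output model the $c_i$ are (generate the same
field as) the transfer-function numerator and denominator coefficients, and
the test suite checks this agreement numerically against an independent
characteristic-polynomial computation.

**4. Fiber classification.** A pseudo-random integer point $p^*$ (distinct
values in 2..97) is drawn; points where a coefficient denominator vanishes
or where the Jacobian of $c$ drops below its generic rank are rejected. The
polynomial system $c(p) = c(p^*)$, with denominators forced nonzero through
a saturation variable ($z \cdot \prod \text{den} = 1$), is the **fiber**:
the set of parameter vectors indistinguishable from $p^*$. When known
initial conditions are present, the elimination by-products that solve each
state in terms of the data are evaluated at $t = 0$ — with the derivative
symbols valued exactly on the $p^*$ trajectory — and the resulting
polynomial relations join the fiber system. For each parameter $p_i$, the
elimination ideal retaining only $p_i$ is computed (Groebner basis modulo a
31-bit prime under an elimination order); a univariate eliminant exists iff
$p_i$ takes finitely many values, and the degree of its squarefree part
(computed by a modular gcd with the derivative) is the maximum number of
distinct solutions. Counts are taken over the complex numbers, matching the
convention that the reported number is an upper bound: real positive
(feasible) solutions may be fewer, and the report does not attempt to
separate them. A single numeric $p^*$ is tested; the counts are generically
independent of the point, and the suite verifies they are stable across
seeds.

**5. Identifiable combinations.** Only when the model is unidentifiable are
further bases computed. For $P$ parameters, $3P$ lexicographic parameter
orderings are scheduled: the $P$ cyclic shifts of $(p_1,\dots,p_P)$, then
the $P$ shifts of the interleaved reordering $(p_1, p_3, \dots, p_2, p_4,
\dots)$, then of the reordering applied twice — so every parameter is ranked
last (eliminated never) at least three times, each time with different
neighbours. Each ordering yields one Groebner basis of the fiber system, and
every basis element free of the saturation variable is mined for *decoupled*
forms:

* a rational multiple of a polynomial plus a constant, $a\,q(p) + b$, whose
  nonconstant part $q$ is fixed on the fiber;
* a binomial $a\,m_1 + b\,m_2$ in two monomials, giving the ratio
  $m_1/m_2$;
* an element univariate in a single monomial power, giving that monomial
  (with a finite number of values — this is how products such as exchange
  fluxes across an unobserved compartment are found when they carry two or
  more branches);
* an element quadratic in its leading variable with constant leading
  coefficient, giving the linear core $2Av + B$, whose square is fixed.

The original coefficients $c_i$ join the candidate pool. Candidates are
sorted by simplicity — total degree, then number of terms, then number of
distinct parameters, then largest coefficient magnitude, then a canonical
string — and selected greedily while the Jacobian of the selected set **at
$p^*$** gains rank, stopping at the generic rank of $c$; each accepted
candidate must also be verified finite on the fiber (this is what rejects
linear relations that merely vanish at the sampled point). Each selected
combination finally receives its own solution count by adjoining $w =
\text{combo}(p)$ and eliminating the parameters. The schedule is a
computability compromise: searching all $P!$ orderings would be complete but
prohibitive, so the reported set is a simplest *found* set, not provably the
simplest possible.

For identifiable models the combination search is skipped entirely — the
parameters themselves are the identifiable quantities — which is why such
models analyse in a fraction of the time.

## Numerical and implementation choices

* **Exact arithmetic throughout the symbolic layer.** Decimal literals in
  model text are converted exactly to rationals; elimination over the
  integers is fraction-free with arbitrary-precision coefficients. No
  floating point enters any identifiability decision.
* **Two primes.** Per-parameter eliminants and solution counts run modulo
  $2^{31}-1$ (residues exact in doubles, fastest arithmetic). Combination
  harvesting runs modulo the largest prime below $2^{53}$: basis
  coefficients there are products of $p^*$ coordinates and can reach $10^8$,
  beyond the rational-reconstruction bound of a 31-bit prime. Residues close
  to $0 \pmod P$ are read as plain integers before rational reconstruction
  is attempted; elements with unreconstructible coefficients are skipped.
  A wrong reconstruction cannot produce a wrong reported combination,
  because every candidate is re-verified by its exact solution count.
* **Degenerate points.** $p^*$ is resampled (up to 100 times) until all
  denominators are nonzero and the Jacobian rank of $c$ matches its generic
  rank estimated at independent random points. Unknown initial values and
  input derivative values needed for the $t=0$ relations are sampled from
  the same deterministic stream.
* **Tie-breaks.** Canonical forms everywhere: polynomials are primitive with
  positive leading coefficient under descending lexicographic term order;
  ratios are oriented by the lexicographically larger monomial; candidates
  deduplicate up to rational scalar multiples and inversion.
* **Budgets.** Every basis computation carries a step and wall-clock budget
  (default 300 s). A per-parameter budget overrun reports the parameter as
  `undetermined` rather than guessing; an overrun ordering is skipped with a
  note. Model text is capped at 60 parameters by default.
* **Determinism.** All randomness flows from the single `seed` argument;
  two runs with the same model, seed and settings produce byte-identical
  JSON reports.

## The built-in models and what passing tests show

The registry in `builtin_examples()` covers the classical desk-scale models
of the identifiability literature: 2- and 3-compartment exchange models and
their identifiable variants, a 4-compartment mammillary model with and
without known initial conditions, a nonlinear HIV infection model, a
reducible nonlinear model whose special initial conditions freeze two
states, a target-cell-limited viral dynamics model driven by a step of
unknown magnitude, and reparameterized closure fixtures. `generate_test_model()`
produces the five generic linear benchmark families (full $n \times n$
parameter matrix, single input in the first compartment, outputs per
family). Problem sizes used throughout the tests are $n \le 4$ states and
$P \le 10$ parameters — the desk scale at which every analysis completes in
seconds and at which published per-parameter verdicts and solution counts
exist to compare against.

These fixtures exercise exact symbolic structure, not data: passing tests
show the algebra (elimination, exhaustive summary, fiber counts,
combination mining) is correct on rational models of this class. They say
nothing about estimation from noisy data, about models with
non-rational terms (Hill exponents entered as unknown reals, delays,
transcendental kinetics), or about practical identifiability. Three further
limitations are inherited by design: solution counts are complex-root
counts (feasibility filtering is the user's task); only constant-trajectory
inaccessibility is handled, not the general inaccessible-initial-state
problem; and for models whose states cannot be reached by linear
solve-and-substitute the Groebner fallback may hit its budget — the analysis
then says so rather than returning a partial answer silently.

## Worked example

```{r example}
library(identicombo)

m <- builtin_examples("2comp")
m
rep <- run_analysis(m, seed = 1)
rep

# machine-readable form
cat(format_report(rep, "json"))

# per-parameter table and one-line summary
tidy(rep)
glance(rep)
```

A model file can equally be analysed from the shell with the bundled
script:

```sh
Rscript inst/cli/identicombo analyze model.txt --seed 1 --json report.json
Rscript inst/cli/identicombo examples run mammillary4 --seed 1
```
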