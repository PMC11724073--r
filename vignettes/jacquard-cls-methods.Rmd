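---
title: "Methods: constrained least-squares estimation of condensed identity coefficients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constrained least-squares estimation of condensed identity coefficients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jacquardcls)
```

## The model

For an ordered pair of individuals, the four alleles at a locus occupy one
of nine condensed identity-by-descent states with probabilities
$\Delta_1,\dots,\Delta_9$ on the simplex
$S^9=\{\Delta_k\ge 0,\ \sum_k\Delta_k=1\}$. States 1–6 involve at least one
within-individual IBD pair (inbreeding); states 3/5 and 4/6 swap when the
two individuals are interchanged, which is why the package stores the
coefficients as nine $n\times n$ matrices with
$\boldsymbol\Delta_3=\boldsymbol\Delta_5'$,
$\boldsymbol\Delta_4=\boldsymbol\Delta_6'$ and the remaining matrices
symmetric. A self pair can only be in state 1 (the two alleles IBD) or 7,
so the diagonals of $\boldsymbol\Delta_1$ and $\boldsymbol\Delta_7$ sum to
one and $F_i = \Delta_1^{(i,i)}$ is the individual inbreeding coefficient.

At a bi-allelic locus with minor-allele probability $p$ the joint genotype
probabilities of the pair are $\mathbf g = \mathbf M(p)\,\boldsymbol\Delta$
with $\mathbf M(p)$ the $9\times 9$ matrix of conditional joint genotype
probabilities (`condensed_matrix()`). Two row constraints,
$\mathbf 1'\mathbf M=\mathbf 1'$ and $\mathbf a'\mathbf M=\mathbf 0'$ with
$\mathbf a'=(0,-1,-2,1,0,-1,2,1,0)$, make $\mathbf M$ structurally
singular: its rank is 7 for generic $p$ and 5 at $p=\tfrac12$. The null
space is spanned by

$$\mathbf z_1=(0,1,0,-1,0,-1,-1,2,0)',\qquad
  \mathbf z_2=(0,0,0,0,0,0,1,-2,1)' + pq\,(-1,-1,2,0,2,0,-2,0,0)',$$

so the coefficients are not identifiable from bi-allelic data. (The $-2$ in
the eighth entry of $\mathbf z_2$'s constant part is required for
$\mathbf M\mathbf z_2=\mathbf 0$; the package verifies both null-space
identities to machine precision in its tests.) The five parameters
$\boldsymbol\theta=\mathbf Q\boldsymbol\Delta$ — coancestry $\theta_1$, the
pairwise inbreeding-type parameters $\theta_{2i},\theta_{2j}$, $\theta_3$
and $\theta_4$ — are identifiable because $\mathbf Q$ (rank 5) annihilates
$\mathbf z_1$ and $\mathbf z_2$. Every fit therefore reports
$\hat{\boldsymbol\theta}=\mathbf Q\hat{\boldsymbol\Delta}$ alongside
$\hat{\boldsymbol\Delta}$, and the documentation consistently warns that
$\hat{\boldsymbol\Delta}$ itself is one representative of a solution set.

## Estimation

Averaging over $L$ SNPs gives $\bar{\mathbf g}=\bar{\mathbf M}\boldsymbol\Delta$
with $\bar{\mathbf M}=\frac1L\sum_l \mathbf M(p_l)$; powers of $p$ are
averaged as averages of per-locus powers, with no small-sample bias
correction of the frequency moments. For observed proportions the system is
inconsistent and the package minimizes the residual sum of squares
$\sigma(\boldsymbol\Delta)=(\bar{\mathbf g}-\bar{\mathbf M}\boldsymbol\Delta)'(\bar{\mathbf g}-\bar{\mathbf M}\boldsymbol\Delta)$
over the simplex — a convex quadratic program whose global optimum is
well-defined even though the minimizer may be a face of the simplex.

**Solver.** The QP is solved in two stages. An accelerated projected
gradient method (FISTA with adaptive restart, compiled) starts from the
uniform point $\Delta_k=1/9$ and runs until the projected-gradient step
falls below one tenth of the configured tolerance (default tolerance
$10^{-8}$, `fit_config()`). Because $\bar{\mathbf M}$ is structurally
singular and typically has additional *near*-null directions (singular
values around $10^{-4}$ arise from averaging; they are data-determined, not
structural), first-order iterations stall along the flat directions. A
second, active-set stage therefore refines the solution exactly: on the
detected support it solves the equality-constrained least-squares problem
through the pseudoinverse of the KKT system (computed as a minimum-norm
correction from the current feasible point), steps back to the boundary
when a coefficient would go negative, and adds the most violating zero
coordinate until the KKT conditions hold. The pseudoinverse cutoff is
$10^{-12}$ relative to the largest singular value: small enough to keep the
ill-conditioned data-determined directions, large enough to discard the
structural null space (relative singular values $\sim 10^{-35}$ in the
normal equations). On exact input the two-stage solver reproduces
$\mathbf Q\boldsymbol\Delta^*$ to near machine precision; the test suite
checks $10^{-6}$ over hundreds of random cases and cross-checks optimality
against brute-force candidate sets.

**Modes.** `full9` fits all nine coefficients. `reduced7` merges the
transpose-pair states, fitting $\Delta_3+\Delta_5$ and $\Delta_4+\Delta_6$
as single parameters; the merged column of the design matrix is the mean of
its two parents, so the merged parameter is the total under an equal-split
convention, and fits are reported expanded back to nine slots with the
split made explicit while $\theta_{2i}$, $\theta_{2j}$ and $\theta_4$ —
which depend on the split — are reported as `NA`. Note that both null
directions respect the merge symmetry, so the reduced design matrix still
has rank 5: the reduction halves the transpose redundancy but does not
restore identifiability. `cotterman` fixes $\Delta_1..\Delta_6=0$
(no-inbreeding estimation); optionally the genealogical-feasibility
constraint $\Delta_8^2\ge 4\Delta_7\Delta_9$ is imposed. That constraint is
non-convex; when the unconstrained Cotterman optimum violates it, the
boundary curve $(a^2,\,2a(1-a),\,(1-a)^2)$, $a\in[0,1]$, is searched by a
dense grid plus local refinement, together with the two feasible simplex
edges, and the best candidate is returned. `unrelated` fixes all related
states ($\Delta_1,\Delta_3,\Delta_5,\Delta_7,\Delta_8$) at zero. `self`
restricts to $\alpha\mathbf e_1+(1-\alpha)\mathbf e_7$, a one-dimensional
problem solved in closed form with $\hat\alpha$ clipped to $[0,1]$;
$\hat\alpha$ estimates the inbreeding coefficient.

Each unordered pair is fitted once (order $i<j$); the reverse ordered pair
follows from the 3/5, 4/6 category swap, which halves the work and enforces
the transpose structure exactly. A pair whose solver did not reach its
tolerance is flagged, never fatal.

## The exact solver and the solution polygon

When $\mathbf g$ and $\mathbf M$ share the same $p$ (exact data), the
consistent singular system is solved by the Moore–Penrose inverse or by
Gaussian elimination with free variables set to zero — the latter yields
$\hat\Delta_8=\hat\Delta_9=0$, a vivid reminder that individual
coefficients can be zeroed at will. Non-negativity of
$\tilde{\boldsymbol\Delta}=\hat{\boldsymbol\Delta}+\xi\mathbf z_1+\eta\mathbf z_2$
intersects nine half-planes in $(\xi,\eta)$; the polygon is built by
enumerating pairwise line intersections (tolerance $10^{-10}$, vertex
deduplication at $10^{-8}$ — adequate for 2-D geometry with nine
constraints), per-coefficient attainable ranges are read off the vertices,
and a canonical representative is the Chebyshev centre, computed exactly by
enumerating triples of active constraints of the three-variable linear
program. The centre is a display convention, not an estimate. An empty
polygon is reported as such. Degenerate cases are common and meaningful:
whenever the generating vector has zeros in the constraining coordinates
(e.g. a non-inbred parent–offspring pair), the polygon collapses to a
single point and the coefficients happen to be identified.

## The simulator and what it emulates

`generate_pedigree()` builds non-overlapping generations from a founder
population (default 10 males + 10 females). Each generation, a random half
of the males breed (`male_breeding_fraction = 0.5`, which concentrates
paternity and speeds up the build-up of relatedness); each female is
assigned one breeding male uniformly at random and leaves a
Poisson-distributed number of offspring with mean `fertility = 2`, sex
drawn evenly. A deterministic two-offspring rule would fix the population
at 140 individuals for the default configuration; the Poisson choice keeps
the expected size at 140 while making single realizations range over
roughly 90–220, matching the scale (about 111) of published single
realizations. Small populations can die out; that is reported as an error
and callers redraw.

`gene_drop()` labels the two haplotypes of every founder distinctly, draws
founder alleles independently per locus from Beta(1, 10) frequencies
(right-skewed: many rare variants, median MAF below 7%), and transmits
labels and alleles together. Each meiosis draws a Poisson number of
crossovers with mean equal to the map length (default 5 Morgans for 20,000
equally spaced loci), places them uniformly on the integer positions
$0..L-1$ (a crossover at $x$ switches the source haplotype between markers
$x$ and $x+1$; duplicate positions cancel in pairs), and starts from a
random parental haplotype. Realized ("gold") coefficients are the per-pair
fractions of loci in each condensed state computed from the labels; they
satisfy the transpose/diagonal structure exactly and differ from pedigree
expectations through meiotic randomness — which is precisely why they are
the right reference for RMSE evaluation.

What the simulator does **not** emulate: genotyping error and missingness,
mutation, selection, overlapping generations, multiple chromosomes, sex
chromosomes, and coalescent variation among founders (founders are
unrelated by construction). Passing tests on simulated data therefore
demonstrates correctness of the estimator under the model's own sampling
assumptions, not robustness to assay artefacts; the reader should expect
e.g. sequencing error at rare variants to degrade real-data performance in
ways these tests cannot reveal.

## Evaluation harness

`run_benchmark()` simulates one dataset and scores every scenario against
the same gold values: estimated coefficients against realized ones (RMSE
with the $\hat{\boldsymbol\Delta}_1$/$\hat{\boldsymbol\Delta}_7$ diagonals
excluded, since self pairs are fitted under their own constraint), pairwise
parameters on ordered off-diagonal entries, per-individual vectors on all
entries. Relative coancestry and inbreeding
$\psi_1=(\theta_1-\theta_S)/(1-\theta_S)$, $\psi_2=(F-\theta_S)/(1-\theta_S)$
use the estimated average coancestry $\hat\theta_S$ for estimates and the
gold $\theta_S$ for gold values, so the relative comparison penalizes a
biased $\hat\theta_S$. Pairwise inbreeding estimates
$\hat\theta_{2i}^{(i,j)}$ are scored against the gold inbreeding of
individual $i$, which is constant across partners $j$ by construction
(states 1–4 are exactly those in which $i$'s alleles are IBD at a locus).
Monomorphic loci are included unless a MAF filter is requested: leaving
them in does not hurt, while filtering at 1% or 5% demonstrably inflates
the RMSE.

Typical problem sizes: the routine test suite uses pedigrees of 20–80
individuals with 200–5,000 loci; the acceptance-level checks run the full
default configuration (20 founders, seven generations, 20,000 loci) for a
single realization plus five replicate seeds for the qualitative orderings,
and 200 independent nuclear families for the full-sib distribution. The
589- and 4,037-individual configurations are supported (`sim_config()`
takes any founder count) and are treated as extended checks rather than
routine ones.

## Known limitations

* Non-negativity is never relaxed; like any probabilistically constrained
  estimator, the fit floors coancestry and inbreeding at zero, which pulls
  the average coancestry toward zero and with it the relative estimates.
* The allele-frequency moments entering $\bar{\mathbf M}$ are plug-in
  averages; no correction for statistical or genetic sampling of the
  frequencies is applied, so estimates are best with founder frequencies
  and deteriorate when frequencies are estimated from few, related, or
  late-generation individuals.
* Multi-allelic variants are out of scope (records are rejected or
  skipped); so are genotype likelihoods and phasing.
* Missing genotypes are handled by pairwise-complete deletion per locus,
  a choice that is exact for the simulator (which produces none) and
  standard, if not information-optimal, for real data.
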