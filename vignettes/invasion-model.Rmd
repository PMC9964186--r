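---
title: "Modelling competitive epithelial invasion with cpmcompete"
author: "cpmcompete authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling competitive epithelial invasion with cpmcompete}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpmcompete)
```

## The model

`cpmcompete` simulates competition between two epithelial cell populations in
a two-dimensional cellular Potts model (CPM). Each cell is the set of lattice
pixels carrying its integer index; a configuration has energy

$$E \;=\; \lambda_{area}\sum_\alpha (A_\alpha - A_0)^2
\;+\; \lambda_{cont}\sum_\alpha L_\alpha^2
\;+\; \sum_{\langle i,j\rangle} \phi(\alpha_i, \alpha_j)\,
      \bigl(1 - \delta(\alpha_i,\alpha_j)\bigr),$$

where $A_\alpha$ is the area (pixel count) of cell $\alpha$, $L_\alpha$ its
perimeter (count of order-1 links to pixels it does not own), and $\phi$ the
boundary energy per link: zero against the immutable wall ring that surrounds
the domain, and for two cells the arithmetic mean of their adhesion
coefficients $\lambda_{adh}$ (see *Design choices*). $\lambda_{adh} < 0$, so
cells prefer to share boundary with other cells rather than with walls; this
is balanced by the quadratic perimeter contractility, which stands in for
cortical actomyosin tension. High $\lambda_{cont}$ (e.g. 7) produces compact,
quasi-hexagonal cells (the *hard* regime); low values (e.g. 0.5) give
irregular, strongly fluctuating outlines (the *soft* regime).

Dynamics are elementary pixel copies: an attempt draws a random lattice site
and a random 4-neighbour, and proposes copying the site's index into the
neighbour. The proposal is accepted with probability 1 if the energy change
$\Delta E \le 0$ and with probability $e^{-\Delta E/T}$ otherwise. The
fluctuation temperature defaults to $T = 50$, which yields realistic shapes
in both regimes. One Monte Carlo step (MCS) — the unit of time — is as many
attempts as there are non-wall pixels.

Turnover makes competition possible. Within every MCS, after the sweep:

* each live cell dies with its type's probability $M$; a dead cell switches
  to $\lambda_{cont} = 0$, $\lambda_{adh} = 0$, $A_0 = 0$ and
  $\lambda_{area} = 200$, so it is squeezed out by its neighbours within a
  few tens of MCS and removed when its area reaches zero;
* each live cell that has reached its target area ($A_\alpha \ge A_0$)
  divides with probability $B$ into two daughters of roughly $A_0/2$, which
  then regrow towards $A_0$.

Because division requires $A_\alpha \ge A_0$ and the domain is finite, the
homogeneous layer equilibrates at a density slightly above the neutral
$A_\alpha = A_0$ packing: division is suppressed by crowding everywhere
except next to recent death events. Requiring a dead cell's $N_c$ live
neighbours to be able to reach $A_0$ bounds the mean live-cell area below by
$A_0 N_c/(1+N_c)$ and hence the live count above by
`crowding_bound(free_area, A0, Nc)` $= \mathrm{free\_area}\,(1+N_c)/(A_0
N_c)$. With $N_c = 6$ this is $\approx 467$ cells for the standard
$200\times200$ domain; rounding the minimum size to $5A_0/6$ gives the
operative bound of 480 used when quoting results.

## The two protocols

**Homogeneous equilibrium** (`run_homogeneous_equilibrium()`): a single type
tiles the interior as $10\times10$ squares at $A_0 = 100$ (400 cells on the
default $200\times200$ domain) and runs with turnover until the total count
is stationary — two consecutive windows (default 500 MCS) whose means differ
by less than 2% — then for a further measurement window (default 1500 MCS)
over which means and SDs are reported. The cap is 5000 MCS; hitting it flags
the run non-stationary.

**Three-stage invasion** (`run_invasion()`): two types tile the left and
right halves, separated by a full-height barrier strip that behaves exactly
like wall. Stage 1 (default 500 MCS) relaxes shapes with turnover off; stage
2 turns turnover on until each side's count is stationary (cap 3000 MCS);
stage 3 removes the barrier and runs until one type has no live cells (cap
50000 MCS, configurable). Runs that hit the cap are flagged incomplete and a
winner is still inferred from the live-count trend when it is significant.

## Measuring invasion speed

After barrier removal the winning type's total count grows approximately
linearly — the signature of a front advancing at constant speed. With the
domain width perpendicular to the invasion as the length unit ($L = 1$), the
front speed is

$$v = \frac{\Delta N/\Delta t}{L\,\rho},$$

where the slope comes from an OLS fit (`fit_linear_growth()`, windowed by
default from barrier removal to 80% of the loser's extinction time) and
$\rho$ is the invader's single-type equilibrium density in cells per squared
width, measured separately with `run_homogeneous_equilibrium()`. Speeds are
therefore in widths per MCS, closed under this unit convention without any
pixel-to-micron calibration.

## The reaction–diffusion counterpart

The front speeds are interpreted through a two-species competition model,

$$\partial_t\rho_i = b_i\,\rho_i(1-\rho_1-\rho_2) - m_i\rho_i + D\nabla^2\rho_i,$$

whose uniform steady states are $(0,0)$, $(1-m_1/b_1,\,0)$ and
$(0,\,1-m_2/b_2)$; the species with the larger $b/m$ owns the only stable
state (`rd_steady_states()`, `rd_stability()`). With spatially separated
initial conditions the stable state invades as a Fisher–Kolmogorov *pulled*
front whose speed is fixed by the linear instability at the leading edge:

$$v = 2\sqrt{D\,\frac{b_1 m_2 - b_2 m_1}{b_2}} \qquad (b_1 m_2 > b_2 m_1).$$

We treat this expression as canonical; the equal-mortality and
equal-division specialisations are algebraic consequences
($2\sqrt{Dm(b_1-b_2)/b_2}$ and $2\sqrt{D(m_2-m_1)}$), and both the general
form and the classical single-species limit $v = 2\sqrt{rD}$ are verified
against the package's explicit finite-difference solver (`rd_solve_1d()`,
central differences, no-flux boundaries, $dt \le 0.4\,dx^2/2D$) to within
5%. Pulled fronts approach their asymptotic speed like $1/t$, so
cross-validation runs integrate to horizons scaled as $1/v^2$. This
correspondence predicts the qualitative CPM behaviour — the invader is the
type with higher $B$ or lower $M$, with speed growing like
$\sqrt{M(1-B_2/B_1)}$ and $\sqrt{M_2-M_1}$ — but not absolute speeds: the
CPM has no single parameter playing the role of $D$, so the proportionality
constant is implementation specific and is deliberately not treated as a
reproducible quantity.

## Design choices

Where the modelling literature leaves details open, the package fixes the
following conventions:

* **Cross-type adhesion.** A single $\lambda_{adh}$ is defined per type; a
  contact between different types costs the arithmetic mean of the two
  effective values. This is symmetric, reduces to the common value for
  same-type contacts, and combined with the wall rule gives 0 against walls
  and $\lambda_{adh}/2$ against fully switched-off dead cells.
* **Neighbourhood order.** Order 1 (4-neighbour) everywhere: copy-candidate
  selection, boundary-link counting and contact energy. This is the simplest
  self-consistent convention; it makes perimeters locally updatable and the
  incremental $\Delta E$ exact, at the price of a mild lattice anisotropy.
* **Perimeter definition.** $L_\alpha$ counts boundary *links* (owned pixel
  to non-owned 4-neighbour), not boundary pixels.
* **No connectivity constraint.** Cells may transiently fragment; fragments
  keep the parent's id and parameters.
* **Division geometry.** The pixel set is cut by a straight line through the
  area centroid at a uniformly random orientation (orientation-unbiased,
  area-balanced in expectation); an empty side triggers up to 8 redraws and
  then a pixel-count median split along the longer bounding-box axis.
* **Event order within an MCS** is fixed as sweep, deaths, divisions, purge,
  with one uniform draw per (eligible) cell in registry-id order, so equal
  seeds reproduce runs bit-identically.
* **Barrier geometry and removal.** The barrier is a strip one cell-side
  wide between the two tiled halves (so both halves tile exactly; the
  nominal full-scale geometry is realised as $300+10+300 \times 300$ with
  900 cells per side). On removal the strip becomes a transient placeholder
  with the dead-cell parameter set, so both sides claim it through ordinary
  dynamics within a few MCS rather than by an ad hoc assignment that could
  bias the front.
* **Stationarity.** Sliding-window criterion (two consecutive windows, 2%
  relative tolerance) on total counts; per side independently in stage 2.
* **RNG.** One seeded R-side generator serves the whole simulation; the
  compiled core consumes the same stream in a documented order (site,
  neighbour, acceptance; then turnover draws).

## What the generators emulate — and what they do not

All inputs are generated in code: square-tiled monolayers at the study-scale
defaults ($A_0 = 100$, $T = 50$, $\lambda_{adh} = -10$, soft-cell
$\lambda_{area} = 10, \lambda_{cont} = 0.5$, turnover $B = 0.03$,
$M \le 0.003$ — death rates above that leave an unrealistically large dead
fraction in the layer), plus small random multi-cell lattices for the energy
oracle and synthetic moving-front series with exactly known speeds for the
measurement pipeline. These capture crowding, turnover and front propagation
in an idealised homogeneous sheet; they do not emulate real-tissue features
such as substrate interaction, signalling-dependent division or death,
oriented mitosis, or three-dimensional extrusion mechanics, so passing tests
demonstrate internal consistency and agreement with the continuum theory,
not quantitative agreement with any particular experiment.

Reduced problem sizes are used throughout the test suite as a deliberate
design point: invasion direction and speed-trend checks run on a
$150\times80$ lattice (56 cells per side, 5 seeds per configuration; stage 1
= 300 MCS, stage 2 capped at 1500, stage 3 at 30000, window 400), densities
on $80\times80$, and solver cross-checks on grids of 1500–3000 points. At
these sizes every qualitative ordering of the full-scale study is already
reproducible.

## Numerical notes and limitations

* Energies are doubles; integer quantities (areas, perimeters, link counts)
  are exact, and the incremental $\Delta E$ agrees with full recomputation
  to $10^{-9}$.
* A dying cell surrounded by a *static* neighbourhood can stall at a few
  pixels when its neighbours are already far above their target area;
  in a turnover-active layer daughters replenish the pressure and corpses
  clear completely. Extreme toy fixtures without turnover can exhibit the
  stall.
* Degenerate inputs: `b = 0` single-species states are flagged undefined;
  `b1/m1 = b2/m2` is reported as degenerate (no invasion direction);
  division of 1-pixel cells is skipped with a warning; live cells of zero
  area are an integrity error, never silently purged.
* The lattice is square with closed walls — no periodic boundaries, no
  hexagonal variant, no 3D, no chemotaxis, and no front-roughness
  statistics.

## A minimal session

```{r example, eval = FALSE}
library(cpmcompete)

# homogeneous layer at the standard soft-cell parameters
eq <- run_homogeneous_equilibrium(experiment_config(seed = 1))
eq$summary

# reduced-scale invasion: higher division rate invades
cfg <- experiment_config(
  width = 150, height = 80,
  cell_types = list(cell_type(1, 70, 7, -10, 100, 0.9, 0.003),
                    cell_type(2, 70, 7, -10, 100, 0.1, 0.003)),
  stage1_mcs = 300, stage2_max_mcs = 1500, stage3_max_mcs = 30000,
  window = 400, seed = 1)
inv <- run_invasion(cfg)
inv$winner
fit_linear_growth(inv$series, inv$winner)$slope

# continuum prediction for a dominant species
rd_front_speed(rd_params(b1 = 2, b2 = 1, m1 = 0.25, m2 = 0.5, D = 1))
```
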