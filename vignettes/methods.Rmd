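---
title: "Methods: jurisdictional gain-loss accounting with comprehensive uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: jurisdictional gain-loss accounting with comprehensive uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(juriflux)
```

## The accounting model

`juriflux` estimates the annual net forest carbon flux of a jurisdiction
as the difference between gross stock losses and gross gains over a
reference period of `tp` years (default 10):

$$\Delta C = \Delta C_l - \Delta C_g$$

$$\Delta C_l = \Big(\sum_h AFd_h \, Cd_h \, LFd_h + AWd \cdot SEFd +
Asl \cdot EFsl\Big) \div tp, \qquad
\Delta C_g = \big(Ar \cdot SFr + Asl \cdot SFsl\big) \div tp$$

All internal arithmetic is in MgC; CO~2~ equivalents use the molecular
weight ratio 44/12 and appear only at reporting.  The model assumes no
net soil carbon flux on aerated (oxic) mineral soils; soil carbon is
emitted only when forest is lost on anoxic wetland substrates (peat,
mangrove).  Transitions from secondary to mature forest are neglected,
appropriate for an early frontier landscape where almost all original
forest is still standing.

### The benchmark biomass map (`Cd_h`)

Per-stratum aboveground carbon comes from a "stratify and multiply"
map: plot-scale lidar-footprint biomass estimates are averaged within
forest biomass classes defined by disturbance (primary / non-primary /
secondary), elevation class and substrate group, and each forested pixel
inherits its class mean.  Candidate classes are only retained when the
footprint data support them: a one-way ANOVA with Tukey's multiple
comparison test (α = 0.05) is run, and while any retained pair fails to
differ significantly the non-significant pair with the smallest absolute
mean difference is lumped and the test repeated.  This greedy,
smallest-gap-first order makes lumping deterministic; the final
partition is always a coarsening of the candidates.  Competing
stratification systems are ranked by their overall ANOVA F statistic.
Elevation class edges (100/300/900/1500 m) are closed on the left and
open on the right, so a value exactly on an edge joins the upper class.

### The forest loss factor (`LFd_h`)

`LFd_h` is the fraction of the stratum's aboveground live carbon emitted
within the reference window per hectare cleared, built from a committed
pool per unit of aboveground live carbon: on-site material is the
unextracted aboveground share plus roots (root:shoot ratio) and
necromass.  Of the on-site pool, the burned-and-combusted share
(burned fraction × combustion completeness) emits immediately except for
the recalcitrant charcoal fraction; the rest decays linearly at rate
0.24 yr⁻¹.  Clearing is spread uniformly over the period, and a cohort
cleared at the end of year *t* has `min(1, 0.24 · (tp − t))` of its dead
wood emitted by the end of the window — averaging to 0.74 over ten
end-of-year cohorts.  Extracted roundwood enters a wood-product pool
decaying first-order with a 5-year half-life, a short-lived-products
assumption consistent with the large mill-loss and short service life of
most tropical roundwood; the same schedule serves wood products removed
by logging.  End-of-year cohort timing is the default (a config switch),
the conservative choice because it gives each cohort the least decay
time.

### Wetland soils, logging and sequestration

Mangrove loss emits 75% of the top-layer (30 cm) soil carbon stock and
35% of the remainder, a "heavier activities" assumption appropriate
where cleared mangroves become aquaculture.  Cleared peat is assumed
drained to 60 cm and burned, emitting 100% of the carbon in the drained
layer, capped at the actual peat depth.  Selective-logging degradation
has four components: felling and skidding (per-hectare factors applied
to the annual logged area), haul roads (full canopy loss, computed with
the same `AFd·Cd·LFd` machinery over road-labelled pixels), and wood
products.  Sequestration uses type-specific rates — fiber plantation
9.8, oil palm 2.97, native regrowth 3.85 MgC ha⁻¹ yr⁻¹ — with regrowth
typed by permit overlay (fiber permit wins, then oil-palm permit, else
native).

Because the gain band is not annual, a regrowth cohort's age is unknown;
the package uses the cohort-mean convention, accruing each type's rate
for `tp/2` years on average (`accumYears`, exposed in every entry
point).  The same convention is applied to the post-logging growth
response `SFsl` (0.368 MgC ha⁻¹ yr⁻¹ accruing on logged cohorts): the
printed form of the gain equation applies `SFsl` to the period's logged
area once, but treating it as an annual response rate accruing per
cohort is dimensionally consistent with the regrowth term and reproduces
the magnitude of reported post-logging offsets far better than the
one-shot reading; the choice is a config argument, not a constant.

### Haul-road labelling

Loss pixels inside licensed concessions that form corridors at most
3 pixels (90 m) wide are logging roads.  The reference procedure was
heads-up digitization, which cannot be reproduced mechanically; the
package's deterministic analogue is a morphological opening with a 4×4
box structuring element — whatever the opening removes is at most three
pixels wide and becomes road, the surviving cores are conversion.
Scattered sub-4-pixel conversion patches inside concessions are
therefore labelled road; this moves emissions between the haul-road and
forest-loss lines but, because both use the identical per-pixel
calculation, leaves the jurisdiction total unchanged.

## Uncertainty

Parameters are split into those with empirical SEMs (stratum biomass
means, SEM = sd/√n of the footprint samples) and those assigned a
default category of percent error at the 95% CI — Very High 100%, High
50%, Medium 20%, Low 10% — converted to an SEM by dividing by 1.96.
Activity areas enter as unit-mean multiplier parameters so that every
term of the equation has a defined distribution: loss area Low, wetland
loss Medium, regrowth area High (gain detection is much weaker than loss
detection), logged area Medium.  Category choices for the process
parameters (decay High, fire parameters High/Very High, necromass High,
roots Medium, wetland soil stocks High/Very High, sequestration rates
Medium) were made once against the literature ranges and are stored,
with units and attribution groups, in the flat parameter table
(`defaultParameters()`), which can be written and re-read as
tab-separated text.

Draws are normal, truncated to each parameter's physical bounds (zero
for non-negative quantities, [0, 1] for fractions) by redrawing
out-of-range values; without truncation the Very High category would go
negative about 2.5% of the time.  Redrawing (rather than clipping)
keeps the retained distribution a proper conditional normal; a retry
budget turns a persistently invalid specification into an error naming
the parameter.  Confidence intervals are percentile-based (2.5/97.5)
rather than mean ± 1.96 sd, robust to the skew truncation induces.  The
default 10⁵ iterations hold the percentile estimator's own noise well
below the reported widths; 10⁶ is available by argument.  Draw order is
canonical (parameter name order), so results are invariant to the row
order of the parameter table.

Source attribution re-runs the Monte Carlo once per parameter group with
that group's distributions replaced by their means; the reduction in the
net-flux CI half-width is the group's contribution.  Raw reductions are
reported alongside contributions normalized to sum to exactly 100%,
because independent groups' raw reductions need not be additive.

## The synthetic jurisdiction

The generator builds a complete, internally consistent jurisdiction so
the whole pipeline can be verified against known truth.  The default
configuration emulates a scaled-down Bornean frontier regency on a
120×195 pixel 30 m grid: 13 biomass classes (means 28–260 MgC/ha,
multiplicative lognormal footprint noise with CV 0.20) in equal column
bands crossing three zone bands (non-forest-designation APL 30%,
production forest 55%, protection forest 15% of forest rows), permits
(oil-palm HGU, fiber HTI, logging HA, mining PKP2B with overlap
precedence), peat and mangrove substrate bands, total forest loss of
0.7%/yr split over oil palm 0.20, agriculture 0.35, fiber 0.12 and
mining 0.03 %/yr placed uniformly over years 1–10 within each type's
eligible zone, one 2×10-pixel haul-road corridor per year inside the
concession, gain at 0.2%/yr over a 12-year source band (placement
on-loss / non-forest / mixed is a config choice because the true spatial
pattern of gain relative to loss is not knowable), and a 20-permit
concession logging 6.5 ha/yr at 31.9 m³/ha with records for 57% of
permit-years.  One seed drives everything through fixed offsets
(landscape +0, footprints +1, logging records +2, Monte Carlo +3), so a
config reproduces byte-identical outputs.

Footprint sampling mirrors the screening applied to real spaceborne
lidar estimates: only pixels forested at the period start with no
intervening loss through the screening year are eligible.  Lognormal
noise with exact unit mean keeps stratum sample means unbiased, so the
pipeline's only systematic deviation from truth is sampling noise.

What the generator does *not* emulate: classification error in the loss
and gain rasters, spatial autocorrelation of biomass within strata,
attribution mistakes, cloud-cover gaps, or boundary misalignment between
permits and zones.  Passing tests therefore demonstrate that the
accounting machinery is correct and that stated parameter uncertainty
propagates faithfully — not that real-world map error is absent.

## Numerical and interface choices

Pixel area is (pixel size)² with no projection correction, matching
practice on 30 m equal-area-ish grids at these extents.  Rasters
persist as ESRI ASCII grids, a plain-text interchange format; the
loss-year band is 0 = no loss, 1..tp = year index, documented
bit-exactly.  Logging-record scale-up for incomplete archives defaults
to the observed-mean convention (mean per recorded permit-year × all
permit-years), unbiased when recorded permit-years are representative;
proportional-total is the alternative switch.  Degenerate inputs are
defined rather than accidental: zero-variance samples lump all strata
and report a degenerate ANOVA, a constant activity series returns slope
0 / R² = 0, a single-class stratification reports F as undefined, empty
strata and empty record tables warn and drop out.  The stratum-mean SEM
uses the Bessel-corrected sample sd.

Problem sizes in the shipped tests and acceptance script — 300
footprints per stratum, 10⁵ Monte Carlo iterations for propagation
checks, 4×10³ iterations × 25–50 replicates for coverage runs on a
60×130 grid — were chosen as the smallest sizes at which the targeted
statistics are stable to well within their test tolerances.

## Known limitations

Illegal logging, fuelwood and escaped-fire degradation are outside the
model, as are oxic-soil fluxes and secondary-to-mature succession.  The
ledger's zone/permit precedence (permit label wins) is one defensible
resolution of overlapping designations.  Reported overall uncertainty
is the relative 95% half-width of the net flux; with asymmetric
(truncated) inputs the upper and lower half-widths differ slightly, and
both endpoints are reported.
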