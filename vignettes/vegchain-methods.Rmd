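---
title: "Modelling perishable vegetable supply chains with vegchain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling perishable vegetable supply chains with vegchain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vegchain)
library(dplyr)
```

## The problem and the model

Vegetables in low-resource supply chains pass from farms through village
markets and wholesale markets to retailers, degrading the whole way.
`vegchain` simulates this journey as a discrete event system to study two
linked outcomes: how often consumers find what they came to buy (*demand
fulfillment*), and how much of what entered the chain is lost before
anyone can buy it (*total loss*, split into *expiration* — running out of
lifespan — and *breakage* — handling damage). The central experiment the
package supports is the production multiplier: scale up the amount
entering the chain while holding the chain itself fixed, and watch whether
availability improves or losses absorb the increase.

The system state is a set of age-tracked lots of produce held at
locations or riding on vehicles. Events — production entries, vehicle
departures and arrivals, consumer arrivals, daily demand reviews, export
draws, expiration sweeps — advance a continuous clock in hours. Ties at
one instant resolve by a fixed priority (arrivals before departures before
reviews before consumer arrivals) so goods landing at time *t* are
sellable at time *t*.

## Structure of the chain

Three levels, connected by proximity:

* **Village markets** receive all production (all of it marketed surplus;
  farms are implicit) and push everything beyond a local reserve to the
  nearest wholesale market each morning.
* **Wholesale markets** form a tiered trade network: a few high-volume
  Tier 1/2 markets interconnected with each other, and many Tier 3
  markets with exactly one trading partner each. Markets share demand
  estimates daily; a market projecting less than one day of cover
  requests stock from the direct partner with the largest surplus. No
  market sees beyond its partners and no new trading relationships form —
  bounded information is a deliberate structural feature, not a
  simplification, because it produces the model's characteristic
  behaviour: surplus accumulating and expiring in one region while demand
  goes unmet in another.
* **Retailers** (or one surrogate retail node per wholesale catchment, to
  stand in for many small shops) fetch from their wholesale market under
  an order-up-to policy.

Consumers arrive at every selling location as a Poisson count per day:
5% of the local catchment buys directly at village markets, 5% at
wholesale markets, and retailers serve the remaining 90% of purchases.
Each arrival requests one person-day of each crop's demand; the request is
binary-fulfilled (a partial quantity is sold but counted unfulfilled).
Demand is constant across the year, although the seasonality hook exists
for supply.

## Perishability

Lots age linearly until they reach the crop's ambient lifespan, then
expire (closed boundary: age ≥ lifespan). Cold storage would slow aging by
a per-crop factor, but the default networks contain none, reflecting the
near-absence of cold storage for vegetables in the setting modelled; the
mechanism exists for extensions. Transit ages produce at the ambient rate.

Breakage is a Poisson draw once per storage stage entered and once per
transport leg: broken units ~ `Pois(rate × mass / unit_mass)`, at 2% mean
per stage, discretised in 1 kg units (the Poisson law needs a countable
unit; 1 kg is small against lot sizes, and the draw is capped so breakage
never exceeds the lot). Applying the draw per stage rather than per stored
day is what makes a three-stage path lose `1 − (1−r)³ ≈ 5.9%` in
expectation, the anchor the cumulative calibration checks.

Dispatch is first-expire-first-out everywhere (sales, shipments), and
vehicle loading is most-perishable-first with lot splitting at the volume
boundary, so scarce transport space carries the goods that cannot wait.

## Supply, imports and exports

Statewide daily demand per crop is the population-weighted per-capita
demand over all selling locations. Annual in-state production is a
per-crop multiple of annual demand (`production_ratio`), spread across
village markets by catchment population and across months by the crop's
seasonal weights, with unit-mean lognormal day-to-day noise (σ = 0.1; the
noise law is a modelling choice — only its unit mean matters for the
calibration). Each month, production deficits are imported at Tier 1
markets (split equally) and surpluses exported from Tier 1/2 markets, so
supply equals demand in expectation every month. The production
multiplier scales in-state production only; imports stay fixed. This
isolates the effect of local production growth — and it is configurable
(`scale_imports`).

## Replenishment arithmetic

Three calibration details matter for anyone reading the code, all of them
consequences of tracing steady-state stock through the daily cycle:

* **Pass-through stock.** A Tier 1/2 market that is the sole supplier of
  Tier 3 partners counts those partners' downstream demand *twice* in its
  own order-up-to estimate. The pass-through pipeline is two review
  periods long (the child's request one day, the onward transfer the
  next); with only one period's allowance the child converges to half its
  demand.
* **Export reserve.** Exports are an external-sink demand served last
  (local consumers are prioritised over trade). The evening export draw
  holds back the local direct-sale reserve plus two review periods of
  attached-retailer demand — the stock downstream policies will claim the
  next morning — and nothing for Tier 3 pass-through, because the day's
  lateral transfers have already departed by then.
* **Daily rhythm.** Vehicle departures jitter around their mean hour by a
  mean-zero Poisson offset (`K − λ`, `K ~ Pois(λ)`, λ = 2, integer
  hours), clamped so deliveries complete in the morning; consumer
  arrivals jitter the same way, clamped to end before the 15:00 review.
  Without the clamps, a late consumer crowd could be reviewed as unsold
  stock, silently skipping a day's replenishment.

## Randomness and reproducibility

All stochasticity flows through four labelled L'Ecuyer-CMRG streams —
supply noise, breakage, consumer arrivals, departure jitter — each a
deterministic function of `(seed, label)`. A run is therefore bit-for-bit
reproducible from `(network, crops, config, seed)`, and because the
production multiplier only rescales masses without touching the supply
stream's consumption, doubling the multiplier doubles every entering mass
exactly at a fixed seed. Scenario iterations use seeds
`seed, seed + 1, …` and report arithmetic means; the iteration count
defaults to 5.

## Synthetic networks: what they emulate and what they do not

`generate_network()` builds scaled-down networks with the structural
statistics of the full system: the 4 : 8 : 395 wholesale tier ratio
(default scaled to 1/2/10), lognormal village catchments with mean 7,800
persons so 5% direct sales average ~390 consumers per village market,
wholesale catchments equal to the sum of their villages' (both layers
cover the whole population), and 12 retailers per wholesale market
jointly serving 90% of the catchment. Default vehicle volumes (200 m³
village, 20 m³ retail, 80 m³ lateral; a "vehicle" abstracts a day's total
haulage on a link) are sized so transport capacity does not bind at
baseline — losses in this model are driven by accumulation and
expiration, not by storage or transport space, and storage is unbounded
by default for the same reason.

The five default crops are synthetic parameter sets anchored to printed
ranges, stored in `inst/extdata/default_crops_synthetic.csv`, never
hard-coded: lifespans potato 21 d, onion 15 d, cabbage 7 d, tomato 6 d,
brinjal 4 d; per-capita demands summing to 266 g/person/day (the split
across crops is a labelled assumption); potato and onion harvested 2–3
months of the year, tomato and brinjal near-year-round; brinjal produced
at 5.2x demand and potato at 0.4x (import-dependent). Bulk densities are
round literature-magnitude values.

What the synthetic networks do **not** emulate: real geography and market
registries, census-derived spatial production patterns, empirical
wholesale transaction volumes, prices and behavioural response, or
demand-side seasonality. Tests passing on these networks show that the
mechanisms are implemented correctly and that their interactions produce
the expected directional behaviour at desk scale; they do not reproduce
any real region's headline percentages, which depend on full empirical
inputs.

## Numerical choices and degenerate inputs

* Mass balance is exact by construction; the audit contract used in every
  test is |residual| ≤ 10⁻⁶ × entered (observed ~10⁻¹⁵).
* Partial-lot arithmetic clamps masses at ~10⁻¹² kg to keep cumulative-sum
  dispatch stable against floating-point dust.
* The expiration boundary is closed (age ≥ lifespan expires), making
  boundary cases deterministic.
* Nearest-market and partner ties break by lowest location id; equal-time
  events by kind priority then insertion order.
* A zero-arrival scope makes fulfillment undefined (`NA` with a warning),
  never 0. A zero-day horizon yields an empty but well-formed result.
* The calendar is a fixed 365-day year starting January 1; runs longer
  than a year wrap the seasonal weights.

## Problem sizes used by the test suite

The suite runs everything at desk scale, chosen as the package's own
defaults for fast, deterministic verification: the 10-village /
5-wholesale / 20-retailer toy for engine properties (8–20 day horizons),
the default 50-village network with a 90-day horizon for the
demand-allocation check, 30-day horizons with multipliers {1, 2, 5} and 5
seeds for the multiplier-response properties, and a 3-node minimal chain
for the loss-free 100%-fulfillment identity. Full-year, full-ratio runs
are supported (`scenario_suite()` defaults to 365-day horizons) and
behave identically, just longer.

## Known limitations

Prices, behavioural and economic response, end-of-market-day discards,
quality grading below the expiration threshold, demand elasticity and
crop substitution are all out of scope. Fulfillment percentages on
synthetic networks are systematically higher than a fully parameterised
regional model would produce, because synthetic catchments are internally
balanced; the loss mechanisms, orderings and multiplier responses are the
meaningful outputs at this scale.
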